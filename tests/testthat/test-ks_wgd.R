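test_that("NG86 reproduces hand-worked codon arithmetic", {
  ident <- ks_ng86("TTTGATGCC", "TTTGATGCC")
  expect_equal(ident$Ks, 0)
  expect_equal(ident$Ka, 0)

  # one synonymous third-position change: S = 5/3, ps = 0.6
  est <- ks_ng86("TTTGATGCC", "TTCGATGCC")
  expect_equal(est$S, 5 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$ps, 0.6)
  expect_equal(est$Ks, -0.75 * log(0.2))
  expect_equal(est$Ka, 0)

  # one nonsynonymous change: Ks stays 0, Ka > 0
  est2 <- ks_ng86("TTTGATGCC", "TTTCATGCC")   # Asp -> His
  expect_equal(est2$Ks, 0)
  expect_gt(est2$Ka, 0)
})

test_that("NG86 site and pathway counts match enumeration on random codon pairs", {
  tb <- ng86_tables()
  set.seed(7)
  for (k in 1:40) {
    i <- sample(61, 1); j <- sample(61, 1)
    sites <- oracle_codon_sites(tb$codons[i])
    expect_equal(tb$S[i], sites[["S"]])
    paths <- oracle_codon_paths(tb$codons[i], tb$codons[j])
    expect_equal(tb$sd[i, j], paths[["sd"]])
    expect_equal(tb$nd[i, j], paths[["nd"]])
  }
  # gap- or N-containing codons and stops are excluded from the comparison
  with_gap <- ks_ng86("TTT---GCC", "TTCGATGCC")
  expect_equal(with_gap$codons_used, 2)
  expect_equal(with_gap$Sd, 1)
})

test_that("estimated Ks agrees with the realized truth of simulated pairs", {
  sp <- simulate_paralog_pairs(data.frame(mean = c(0.2, 0.8),
                                          sd = 0.05, weight = c(0.5, 0.5)),
                               n_pairs = 40, n_codons = 300, seed = 12)
  est <- ks_ng86_pairs(sp$pairs)
  expect_lt(mean(abs(est$Ks - sp$truth$realized_ks)), 0.02)
})

test_that("tandem pairs are removed by the rank-gap rule", {
  positions <- data.frame(gene = sprintf("g%d", 1:12),
                          chrom = rep(c("c1", "c2"), each = 6),
                          rank = c(0:5, 0:5), stringsAsFactors = FALSE)
  pairs <- data.frame(
    gene_a = c("g1", "g1", "g1", "g7", "g2", "g3"),
    gene_b = c("g2", "g6", "g7", "g8", "g8", "g9"),
    stringsAsFactors = FALSE)
  # tandem: g1-g2 (gap 1), g7-g8 (gap 1), g1-g6 (gap 5) on one chromosome
  kept <- remove_tandem_pairs(pairs, positions, max_rank_gap = 5)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$gene_a %in% c("g1", "g2", "g3")))
  # same chromosome but far apart is kept
  far <- data.frame(gene = c("x1", "x2"), chrom = "c9", rank = c(0, 50))
  keepfar <- remove_tandem_pairs(
    data.frame(gene_a = "x1", gene_b = "x2"), far)
  expect_equal(nrow(keepfar), 1)
})

test_that("chaining recovers identity, inverted and planted blocks", {
  ident <- data.frame(rank_a = 0:9, rank_b = 0:9)
  bl <- find_collinear_blocks(ident)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$n_anchors, 10)
  expect_equal(bl[[1]]$orientation, "same")

  anti <- data.frame(rank_a = 0:9, rank_b = 9:0)
  bl <- find_collinear_blocks(anti)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$orientation, "inverted")

  # block below min_anchors is not reported
  short <- data.frame(rank_a = 0:3, rank_b = 0:3)
  expect_length(find_collinear_blocks(short, min_anchors = 5), 0)

  so <- simulate_gene_orders(500, list(
    list(start_a = 10, start_b = 60, length = 12),
    list(start_a = 100, start_b = 400, length = 8,
         orientation = "inverted"),
    list(start_a = 300, start_b = 200, length = 6)),
    noise_anchors = 50, seed = 15)
  bl <- find_collinear_blocks(so$anchors)
  expect_length(bl, 3)   # all three planted blocks, no spurious block >= 5
  # every planted anchor run is contained in exactly one reported block
  # (a noise anchor may legitimately extend a chain within the rank gap)
  for (tr in so$truth) {
    containing <- vapply(bl, function(b) {
      all(paste(tr$rank_a, tr$rank_b) %in%
            paste(b$anchors$rank_a, b$anchors$rank_b))
    }, logical(1))
    expect_equal(sum(containing), 1)
  }
})

test_that("first extracted chain is optimal against the memoized oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    anchors <- data.frame(rank_a = sample.int(200, n) - 1L,
                          rank_b = sample.int(200, n) - 1L)
    anchors <- unique(anchors)
    bl <- find_collinear_blocks(anchors, min_anchors = 1)
    first_len <- if (length(bl) > 0) bl[[1]]$n_anchors else 0L
    expect_equal(first_len,
                 oracle_chain_max(anchors$rank_a, anchors$rank_b))
  }
})

test_that("block median Ks follows the even-count and saturation rules", {
  block <- list(anchors = data.frame(rank_a = 0:2, rank_b = 0:2,
                                     pair_id = c("p1", "p2", "p3")))
  expect_equal(block_median_ks(block, c(p1 = 0.1, p2 = 0.2, p3 = 0.9)), 0.2)
  block2 <- list(anchors = data.frame(rank_a = 0:1, rank_b = 0:1,
                                      pair_id = c("p1", "p2")))
  expect_equal(block_median_ks(block2, c(p1 = 0.1, p2 = 0.3)), 0.2)
  # saturated anchors are excluded; all-saturated is undatable
  block5 <- list(anchors = data.frame(rank_a = 0:4, rank_b = 0:4,
                                      pair_id = paste0("p", 1:5)))
  ks <- c(p1 = 0.1, p2 = 0.2, p3 = NA, p4 = 0.4, p5 = 0.6)
  expect_equal(block_median_ks(block5, ks), 0.3)
  expect_true(is.na(block_median_ks(block2, c(p1 = NA, p2 = NA))))
})

test_that("Ks peak detection finds planted modes and collapses ties", {
  set.seed(19)
  one <- rnorm(500, 0.6, 0.05)
  pk <- ks_distribution_peaks(one)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(pk$peaks$location - 0.6), pk$bandwidth)

  two <- c(rnorm(500, 0.13, 0.03), rnorm(500, 0.6, 0.03))
  pk2 <- ks_distribution_peaks(two)
  expect_equal(nrow(pk2$peaks), 2)

  same <- rep(0.42, 100)
  pks <- ks_distribution_peaks(same)
  expect_equal(nrow(pks$peaks), 1)
  expect_lt(abs(pks$peaks$location - 0.42), 0.01)

  expect_error(ks_distribution_peaks(runif(10)), "too few")
})

test_that("proportional WGD dating matches the reported calibration", {
  expect_equal(date_wgd(0.125, 1.51, 117)$t_event, 9.69)
  expect_equal(date_wgd(1.51, 1.51, 117)$t_event, 117)
  expect_equal(date_wgd(0, 1.51, 117)$t_event, 0)
  expect_error(date_wgd(0.5, 0, 117), "positive")
  # homogeneous of degree 1 in the calibration age
  expect_equal(date_wgd(0.4, 1.51, 234)$t_event,
               round(2 * 117 * 0.4 / 1.51, 2))
})

test_that("syntenic depth ratio reports modal coverage per genome", {
  # two A-regions each covered twice, B covered once: 2:1
  blocks <- list(
    list(anchors = data.frame(rank_a = 0:9, rank_b = 0:9)),
    list(anchors = data.frame(rank_a = 0:9, rank_b = 10:19)),
    list(anchors = data.frame(rank_a = 10:19, rank_b = 20:29)),
    list(anchors = data.frame(rank_a = 10:19, rank_b = 30:39))
  )
  res <- syntenic_depth_ratio(blocks, n_genes_a = 20, n_genes_b = 40)
  expect_equal(res$ratio, "2:1")

  single <- list(list(anchors = data.frame(rank_a = 0:9, rank_b = 0:9)))
  expect_equal(syntenic_depth_ratio(single, 10, 10)$ratio, "1:1")
  expect_error(syntenic_depth_ratio(list(), 10, 10), "no collinear")
})
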