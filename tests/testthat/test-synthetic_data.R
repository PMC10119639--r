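test_that("generators are deterministic under a fixed seed", {
  a <- simulate_ltr_landscape(genome_length = 2e5, n_elements = 10,
                              ltr_length = 500, internal_length = 100,
                              seed = 42)
  b <- simulate_ltr_landscape(genome_length = 2e5, n_elements = 10,
                              ltr_length = 500, internal_length = 100,
                              seed = 42)
  expect_identical(a, b)
  h1 <- simulate_kmer_histogram(1e5, 20, 0.1, seed = 9)
  h2 <- simulate_kmer_histogram(1e5, 20, 0.1, seed = 9)
  expect_identical(h1, h2)
})

test_that("zero-age elements carry identical terminal repeats", {
  sim <- simulate_ltr_landscape(genome_length = 3e5, n_elements = 10,
                                time_sampler = function(n) rep(0, n),
                                ltr_length = 800, internal_length = 200,
                                solo_fraction = 0, seed = 3)
  for (i in seq_len(nrow(sim$elements))) {
    e <- sim$elements[i, ]
    s5 <- substr(sim$genome[["chr1"]], e$ltr5_start + 1, e$ltr5_end)
    s3 <- substr(sim$genome[["chr1"]], e$ltr3_start + 1, e$ltr3_end)
    expect_identical(s5, s3)
  }
})

test_that("LTR pair divergence matches the Jukes-Cantor closed form", {
  # r = 1.33e-9, t = 1e6, 10-kb LTRs, 200 elements:
  # expected pairwise per-site difference 3/4 (1 - exp(-8 r t / 3))
  r <- 1.33e-9; t_age <- 1e6; L <- 10000; n <- 200
  sim <- simulate_ltr_landscape(genome_length = 9e6, n_elements = n,
                                time_sampler = function(k) rep(t_age, k),
                                r = r, ltr_length = L,
                                internal_length = 100,
                                solo_fraction = 0, seed = 17)
  g <- sim$genome[["chr1"]]
  mism <- vapply(seq_len(nrow(sim$elements)), function(i) {
    e <- sim$elements[i, ]
    a <- strsplit(substr(g, e$ltr5_start + 1, e$ltr5_end), "")[[1]]
    b <- strsplit(substr(g, e$ltr3_start + 1, e$ltr3_end), "")[[1]]
    sum(a != b)
  }, numeric(1))
  p_hat <- sum(mism) / (n * L)
  p_exp <- 0.75 * (1 - exp(-8 * r * t_age / 3))
  se <- sqrt(p_exp * (1 - p_exp) / (n * L))
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("solo fraction yields the exact solo segment count and complete truth", {
  sim <- simulate_ltr_landscape(genome_length = 1e6, n_elements = 100,
                                ltr_length = 300, internal_length = 100,
                                solo_fraction = 0.5, seed = 5)
  expect_equal(nrow(sim$solo_candidates), 50)
  expect_equal(nrow(sim$elements), 50)
  expect_equal(nrow(sim$truth), 100)
  expect_setequal(sim$truth$element_id,
                  c(sim$elements$element_id, sim$solo_candidates$element_id))
  expect_error(
    simulate_ltr_landscape(genome_length = 1e4, n_elements = 100,
                           ltr_length = 300, internal_length = 100),
    "infeasible packing")
})

test_that("paralog pairs realize their planted Ks targets", {
  sp <- simulate_paralog_pairs(data.frame(mean = 0.6, sd = 0.001,
                                          weight = 1),
                               n_pairs = 50, n_codons = 300, seed = 8)
  expect_true(all(sp$truth$realized_ks >= 0.55 &
                    sp$truth$realized_ks <= 0.65))
  # sequence lengths preserved (substitution-only)
  expect_true(all(vapply(sp$pairs, function(p) {
    nchar(p[1]) == 900 && nchar(p[2]) == 900
  }, logical(1))))
  expect_equal(nrow(sp$truth), 50)
})

test_that("a zero Ks target leaves the pair identical", {
  sp <- simulate_paralog_pairs(data.frame(mean = 0, sd = 0, weight = 1),
                               n_pairs = 3, n_codons = 50, seed = 2)
  expect_true(all(sp$truth$realized_ks == 0))
  for (p in sp$pairs) expect_identical(p[1], p[2])
})

test_that("well-separated planted peaks produce a bimodal realized-Ks set", {
  sp <- simulate_paralog_pairs(
    data.frame(mean = c(0.13, 1.51), sd = c(0.03, 0.05),
               weight = c(0.5, 0.5)),
    n_pairs = 120, n_codons = 200, seed = 13)
  lo <- sum(sp$truth$realized_ks < 0.5)
  hi <- sum(sp$truth$realized_ks > 1.0)
  expect_gt(lo, 30)
  expect_gt(hi, 30)
  expect_equal(lo + hi, 120)   # nothing lands between the modes
})

test_that("selfing genotypes follow the inbreeding-equilibrium frequencies", {
  # complete selfing: no heterozygotes at all
  g1 <- simulate_selfing_genotypes(n_ind = 20, n_sites = 2000, F_true = 1,
                                   seed = 4)
  expect_equal(sum(g1$table$gt == 1L), 0)
  # HWE limit at p = 0.5: het fraction ~ 1/2 within 3 SE
  g0 <- simulate_selfing_genotypes(
    n_ind = 20, n_sites = 2000,
    freq_sampler = function(n) rep(0.5, n), F_true = 0, seed = 4)
  het <- mean(g0$table$gt == 1L)
  se <- sqrt(0.5 * 0.5 / (20 * 2000))
  expect_lt(abs(het - 0.5), 3 * se)
  expect_equal(g0$truth$F_true, 0)
  expect_length(g0$truth$allele_freqs, 2000)
})

test_that("k-mer histograms carry a coverage peak and optional error tail", {
  h0 <- simulate_kmer_histogram(2e5, 20, 0, seed = 6)
  pk <- find_main_peak(h0)
  # at integer coverage the raw mode sits on either flank of lambda - 1/2;
  # the fitted peak coverage recovers the simulated mean depth
  expect_true(pk$peak_depth %in% c(19L, 20L))
  expect_equal(estimate_genome_size(h0)$peak_coverage, 20, tolerance = 0.02)
  h3 <- simulate_kmer_histogram(2e5, 20, 0.3, seed = 6)
  # valley between the error tail (depth 1-2) and the coverage peak
  pk3 <- find_main_peak(h3)
  expect_gt(pk3$valley_depth, 1)
  expect_lt(pk3$valley_depth, 20)
  e <- h3$entries
  expect_gt(e$count[e$depth == 1], e$count[e$depth == 5])
})

test_that("gene-order anchors embed planted monotone blocks exactly once", {
  so <- simulate_gene_orders(
    300, list(list(start_a = 5, start_b = 40, length = 10)),
    noise_anchors = 0, seed = 1)
  expect_equal(nrow(so$anchors), 10)
  o <- order(so$anchors$rank_a)
  expect_true(all(diff(so$anchors$rank_a[o]) == 1))
  expect_true(all(diff(so$anchors$rank_b[o]) == 1))
  expect_error(
    simulate_gene_orders(300, list(
      list(start_a = 5, start_b = 40, length = 10),
      list(start_a = 8, start_b = 100, length = 5)), seed = 1),
    "overlap")
})
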