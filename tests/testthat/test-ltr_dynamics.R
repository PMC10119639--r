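test_that("global alignment handles identity, substitution and deletion", {
  a <- random_seq(100)
  al <- align_ltr_pair(a, a)
  expect_equal(al$score, 100)
  expect_identical(al$aligned_a, al$aligned_b)

  b <- a
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 50, 50))[1]
  al <- align_ltr_pair(a, b)
  d <- ltr_divergence(al)
  expect_equal(d$aligned_sites, 100)
  expect_equal(d$mismatches, 1)

  del <- paste0(substr(a, 1, 40), substr(a, 44, 100))  # 3-bp deletion
  al <- align_ltr_pair(a, del)
  gaps <- sum(strsplit(al$aligned_b, "")[[1]] == "-")
  expect_equal(gaps, 3)
  expect_equal(nchar(al$aligned_a), 100)
})

test_that("alignment scores match an exhaustive enumeration oracle", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_seq(sample(3:7, 1))
    b <- random_seq(sample(3:7, 1))
    al <- align_ltr_pair(a, b)
    expect_equal(al$score, oracle_align_score(a, b), info = paste(a, b))
  }
})

test_that("divergence converts p-distance to insertion time via JC", {
  mk_aln <- function(n, mism) {
    a <- strsplit(random_seq(n), "")[[1]]
    b <- a
    idx <- seq_len(mism)
    b[idx] <- vapply(a[idx], function(x)
      setdiff(c("A", "C", "G", "T"), x)[1], character(1))
    list(aligned_a = paste(a, collapse = ""),
         aligned_b = paste(b, collapse = ""))
  }
  d0 <- ltr_divergence(mk_aln(200, 0))
  expect_equal(d0$K, 0)
  expect_equal(d0$T_years, 0)

  d5 <- ltr_divergence(mk_aln(1000, 50), r = 1.33e-9)   # p = 0.05
  expect_equal(d5$p_distance, 0.05)
  expect_equal(d5$K, 0.0517447, tolerance = 1e-5)
  expect_equal(d5$T_years, 1.94529e7, tolerance = 1e-5)

  # exact arithmetic of T = K / (2 r)
  p_for_K <- 0.75 * (1 - exp(-4 * 2.66e-3 / 3))
  d <- ltr_divergence(mk_aln(1e6, round(p_for_K * 1e6)), r = 1.33e-9)
  expect_equal(d$T_years, 1e6, tolerance = 1e-3)

  # saturation: p >= 0.75 is undatable
  dsat <- ltr_divergence(mk_aln(100, 80))
  expect_true(dsat$saturated)
  expect_true(is.na(dsat$T_years))
})

test_that("gap and N columns are excluded from both numerator and denominator", {
  aln <- list(aligned_a = "ACGTNAC-GT", aligned_b = "ACTT-ACAGG")
  d <- ltr_divergence(aln)
  # usable columns: positions 1,2,3,4,6,7,9,10 minus gap/N cols 5,8 -> 8
  expect_equal(d$aligned_sites, 8)
  expect_equal(d$mismatches, 2)   # pos 3 G/T, pos 10 T/G
})

test_that("solo screening applies the strict-overlap rule", {
  elements <- data.frame(element_id = "e1", chrom = "chr1",
                         element_start = 100, element_end = 200,
                         ltr5_start = 100, ltr5_end = 120,
                         ltr3_start = 180, ltr3_end = 200,
                         superfamily = "Gypsy", stringsAsFactors = FALSE)
  cands <- data.frame(chrom = "chr1",
                      start = c(150, 300, 500),
                      end = c(170, 400, 600),
                      element_id = c("c1", "c2", "c3"),
                      stringsAsFactors = FALSE)
  res <- classify_solo_ltrs(cands, elements)
  expect_equal(res$n_solo, 2)         # c1 is inside the element
  expect_equal(res$n_paired, 1)
  # brute-force overlap agreement
  brute <- vapply(seq_len(nrow(cands)), function(i) {
    !(cands$start[i] < elements$element_end &
        elements$element_start < cands$end[i])
  }, logical(1))
  expect_setequal(res$solo$element_id, cands$element_id[brute])

  # abutting (half-open touch) does not overlap
  touch <- data.frame(chrom = "chr1", start = 200, end = 260,
                      element_id = "t1", stringsAsFactors = FALSE)
  expect_equal(classify_solo_ltrs(touch, elements)$n_solo, 1)

  # empty element list: everything is solo
  expect_equal(classify_solo_ltrs(cands, elements[0, ])$n_solo, 3)
})

test_that("solo:paired ratio reproduces the reported comparisons", {
  expect_equal(solo_paired_ratio(28714, 18445), 1.56)
  expect_equal(solo_paired_ratio(12766, 9889), 1.29)
  expect_equal(solo_paired_ratio(100, 100), 1.00)
  expect_error(solo_paired_ratio(10, 0), "undefined")
})

test_that("rate curve bins insertions in half-open 0.1-My bins", {
  rc <- transposition_rate_curve(c(0.05, 0.15, 0.15, 1.05) * 1e6)
  expect_equal(rc$bins$insertions[1], 1)
  expect_equal(rc$bins$insertions[2], 2)
  expect_equal(rc$bins$insertions[11], 1)
  expect_equal(sum(rc$bins$insertions), 4)
  expect_true(all(diff(rc$bins$accumulation) >= 0))

  empty <- transposition_rate_curve(numeric(0))
  expect_true(all(empty$bins$insertions == 0))

  # conservation: bins + beyond-horizon = dated elements
  tt <- runif(300, 0, 2e7)
  rc <- transposition_rate_curve(tt)
  expect_equal(sum(rc$bins$insertions) + rc$n_beyond_horizon, 300)
})

test_that("uniform insertion ages give uniform bin counts", {
  sim_T <- local({
    set.seed(33)
    runif(500, 0, 2e6)
  })
  rc <- transposition_rate_curve(sim_T)
  counts <- rc$bins$insertions[1:20]
  lambda <- 500 / 20
  expect_true(all(abs(counts - lambda) <= 3 * sqrt(lambda)))
})

test_that("superfamily masses give genome fractions and fold ratio", {
  sm <- superfamily_masses(c(Gypsy = 1672.59, Copia = 287.66),
                           genome_length = 3028)
  expect_equal(sm$gypsy_copia_fold, 5.81)
  cop <- sm$masses[sm$masses$superfamily == "Copia", ]
  expect_equal(cop$fraction_of_genome, 9.50)

  eq <- superfamily_masses(c(Gypsy = 10, Copia = 10), 100)
  expect_equal(eq$gypsy_copia_fold, 1.00)
  none <- superfamily_masses(c(Gypsy = 10, Copia = 0), 100)
  expect_true(is.na(none$gypsy_copia_fold))
})

test_that("insertion ages are recovered from a simulated landscape", {
  sim <- simulate_ltr_landscape(genome_length = 2.5e6, n_elements = 60,
                                time_sampler = function(n)
                                  runif(n, 5e5, 4e6),
                                ltr_length = 2000, internal_length = 500,
                                solo_fraction = 0.2, seed = 29)
  dated <- date_ltr_elements(sim$genome, sim$elements)
  truth <- sim$truth[!sim$truth$is_solo, ]
  expect_identical(dated$element_id, truth$element_id)
  rel <- abs(mean(dated$T_years) - mean(truth$true_insertion_time)) /
    mean(truth$true_insertion_time)
  expect_lt(rel, 0.05)
  # K is monotone in p and approaches p for small p
  p <- c(0.001, 0.01, 0.1, 0.3, 0.5)
  K <- jc_correct(p)
  expect_true(all(diff(K) > 0))
  expect_equal(K[1], 0.001, tolerance = 1e-3)
})
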