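# SNP filter cascade and selfing/diversity statistics.
#
# The cascade mirrors post-variant-calling hygiene for a resequenced cohort:
# site quality, per-genotype depth band and genotype quality, indel
# proximity, missingness, minor-allele frequency, Hardy-Weinberg exactness
# and repeat masking, applied in a fixed order with per-rule accounting.

#' Filter cascade configuration
#'
#' Defaults follow the study conditions: quality >= 20, per-genotype depth
#' within (site mean / 3, 3 x site mean), genotypes with GQ < 10 masked,
#' sites within 5 bp of an indel dropped, missing fraction <= 0.3,
#' MAF >= 0.05, exact Hardy-Weinberg test at alpha = 0.001, repeat-masked
#' sites dropped. Set `indel_margin` or a rule threshold to `NA` to disable
#' that rule.
#'
#' @param min_qual Minimum site QUAL.
#' @param depth_band_factor Per-genotype depth must lie strictly within
#'   `(site_mean / f, f * site_mean)` with `f` this factor.
#' @param min_gq Minimum genotype quality; lower calls are masked.
#' @param indel_margin Distance (bp) to an indel at or within which a site
#'   is dropped; `NA` disables the rule.
#' @param max_missing_fraction Maximum tolerated missing-call fraction.
#' @param min_maf Minimum minor-allele frequency.
#' @param hwe_alpha Significance level of the exact HWE test; `NA` disables.
#' @param mask_repeats If `TRUE`, a repeat mask must be supplied and
#'   masked sites are dropped.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_qual = 20, depth_band_factor = 3,
                          min_gq = 10, indel_margin = 5,
                          max_missing_fraction = 0.3, min_maf = 0.05,
                          hwe_alpha = 0.001, mask_repeats = TRUE) {
  stopifnot(min_qual > 0, depth_band_factor > 1, min_gq >= 0,
            max_missing_fraction > 0, min_maf >= 0)
  structure(list(min_qual = min_qual,
                 depth_band_factor = depth_band_factor,
                 min_gq = min_gq, indel_margin = indel_margin,
                 max_missing_fraction = max_missing_fraction,
                 min_maf = min_maf, hwe_alpha = hwe_alpha,
                 mask_repeats = mask_repeats),
            class = "filter_config")
}

#' Exact Hardy-Weinberg test for one biallelic site
#'
#' Two-sided conditional exact test: the p-value is the total probability,
#' given the observed allele counts, of heterozygote counts no more
#' probable than the observed one (Wigginton-style SNP-HWE).
#'
#' @param n_het Observed heterozygotes.
#' @param n_hom_ref,n_hom_alt Observed homozygote counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized log-probabilities P(het = h | allele counts)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

subset_sites <- function(tab, keep) {
  genotype_table(individuals = tab$individuals,
                 sites = tab$sites[keep, , drop = FALSE],
                 gt = tab$gt[keep, , drop = FALSE],
                 dp = tab$dp[keep, , drop = FALSE],
                 gq = tab$gq[keep, , drop = FALSE])
}

#' Apply the SNP filter cascade
#'
#' Rules, in order: (1) drop non-biallelic sites and sites with
#' QUAL < `min_qual`; (2) mask genotypes with depth outside the per-site
#' band or GQ below `min_gq` (call set missing; depth/GQ retained);
#' (3) drop sites at or within `indel_margin` bp of an indel; (4) drop
#' sites with missing fraction above `max_missing_fraction`; (5) drop
#' sites with MAF below `min_maf`; (6) drop sites failing the exact HWE
#' test at `hwe_alpha`; (7) drop sites inside repeat-mask intervals.
#' Re-running the cascade on its own output removes nothing.
#'
#' @param tab A `genotype_table` (raw, with qual/DP/GQ).
#' @param cfg A [filter_config()].
#' @param indel_positions Data frame chrom, pos (1-based) of indels;
#'   required while the indel rule is enabled.
#' @param repeat_mask Data frame chrom, start, end (0-based half-open, as
#'   from [read_bed()]); required while `mask_repeats` is `TRUE`.
#' @return List: `table` (filtered `genotype_table`), `removed` (named
#'   integer vector of sites removed per rule; `genotypes_masked` counts
#'   rule-2 maskings), `n_input`, `n_output`.
#' @export
filter_snps <- function(tab, cfg = filter_config(), indel_positions = NULL,
                        repeat_mask = NULL) {
  stopifnot(inherits(tab, "genotype_table"))
  if (!is.na(cfg$indel_margin) && is.null(indel_positions)) {
    stop("filter config error: indel rule enabled but no indel positions ",
         "supplied")
  }
  if (isTRUE(cfg$mask_repeats) && is.null(repeat_mask)) {
    stop("filter config error: repeat masking enabled but no mask supplied")
  }
  removed <- c(qual_or_multiallelic = 0L, near_indel = 0L,
               missingness = 0L, maf = 0L, hwe = 0L, repeat_mask = 0L)
  masked <- 0L

  # (1) biallelic + site quality
  keep <- !tab$sites$multiallelic &
    !is.na(tab$sites$qual) & tab$sites$qual >= cfg$min_qual
  removed["qual_or_multiallelic"] <- sum(!keep)
  tab <- subset_sites(tab, keep)

  # (2) per-genotype depth band and GQ masking
  if (nrow(tab$sites) > 0) {
    site_mean <- rowMeans(tab$dp, na.rm = TRUE)
    lo <- site_mean / cfg$depth_band_factor
    hi <- site_mean * cfg$depth_band_factor
    bad_dp <- !is.na(tab$dp) & (tab$dp <= lo | tab$dp >= hi)
    bad_gq <- !is.na(tab$gq) & tab$gq < cfg$min_gq
    bad <- (bad_dp | bad_gq) & !is.na(tab$gt)
    masked <- sum(bad)
    tab$gt[bad] <- NA_integer_
  }

  # (3) indel proximity
  if (!is.na(cfg$indel_margin) && nrow(tab$sites) > 0) {
    near <- rep(FALSE, nrow(tab$sites))
    for (ch in unique(tab$sites$chrom)) {
      ip <- indel_positions$pos[indel_positions$chrom == ch]
      if (length(ip) == 0) next
      si <- which(tab$sites$chrom == ch)
      dmin <- vapply(tab$sites$pos[si],
                     function(p) min(abs(p - ip)), numeric(1))
      near[si] <- dmin <= cfg$indel_margin
    }
    removed["near_indel"] <- sum(near)
    tab <- subset_sites(tab, !near)
  }

  # (4) missingness
  if (nrow(tab$sites) > 0) {
    miss <- rowMeans(is.na(tab$gt))
    keep <- miss <= cfg$max_missing_fraction
    removed["missingness"] <- sum(!keep)
    tab <- subset_sites(tab, keep)
  }

  # (5) minor-allele frequency
  if (nrow(tab$sites) > 0) {
    called <- rowSums(!is.na(tab$gt))
    alt <- rowSums(tab$gt, na.rm = TRUE)
    p <- ifelse(called > 0, alt / (2 * called), NA_real_)
    maf <- pmin(p, 1 - p)
    keep <- !is.na(maf) & maf >= cfg$min_maf
    removed["maf"] <- sum(!keep)
    tab <- subset_sites(tab, keep)
  }

  # (6) exact HWE
  if (!is.na(cfg$hwe_alpha) && nrow(tab$sites) > 0) {
    pvals <- vapply(seq_len(nrow(tab$sites)), function(i) {
      g <- tab$gt[i, ]
      hwe_exact_test(sum(g == 1L, na.rm = TRUE),
                     sum(g == 0L, na.rm = TRUE),
                     sum(g == 2L, na.rm = TRUE))
    }, numeric(1))
    keep <- pvals >= cfg$hwe_alpha
    removed["hwe"] <- sum(!keep)
    tab <- subset_sites(tab, keep)
  }

  # (7) repeat mask
  if (isTRUE(cfg$mask_repeats) && nrow(tab$sites) > 0) {
    inside <- rep(FALSE, nrow(tab$sites))
    for (ch in unique(tab$sites$chrom)) {
      mk <- repeat_mask[repeat_mask$chrom == ch, , drop = FALSE]
      if (nrow(mk) == 0) next
      si <- which(tab$sites$chrom == ch)
      p0 <- tab$sites$pos[si] - 1L   # 1-based point -> 0-based offset
      inside[si] <- vapply(p0, function(x) {
        any(x >= mk$start & x < mk$end)
      }, logical(1))
    }
    removed["repeat_mask"] <- sum(inside)
    tab <- subset_sites(tab, !inside)
  }

  list(table = tab, removed = removed, genotypes_masked = masked,
       n_output = nrow(tab$sites))
}

#' Per-individual inbreeding coefficients
#'
#' Moment estimator `F_i = 1 - O_i / E_i`, with `O_i` the observed
#' heterozygous-call count of individual i over its non-missing sites and
#' `E_i` the Hardy-Weinberg expectation `sum 2 p (1 - p)` over the same
#' sites, using allele frequencies from all non-missing calls.
#'
#' @param tab A `genotype_table` with at least 2 individuals.
#' @return Data frame: individual, n_sites (non-missing), obs_het,
#'   exp_het, F (`NA` when an individual has no informative site).
#' @export
individual_inbreeding <- function(tab) {
  stopifnot(inherits(tab, "genotype_table"))
  if (length(tab$individuals) < 2) stop("need at least 2 individuals")
  called <- rowSums(!is.na(tab$gt))
  alt <- rowSums(tab$gt, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  exp_site <- 2 * p * (1 - p)
  rows <- lapply(seq_along(tab$individuals), function(i) {
    g <- tab$gt[, i]
    use <- !is.na(g) & !is.na(exp_site)
    O <- sum(g[use] == 1L)
    E <- sum(exp_site[use])
    data.frame(individual = tab$individuals[i], n_sites = sum(use),
               obs_het = O, exp_het = E,
               F = if (E > 0) 1 - O / E else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Selfing rate from an inbreeding coefficient
#'
#' At inbreeding equilibrium under partial self-fertilization,
#' `s = 2 F / (1 + F)`.
#'
#' @param F Inbreeding coefficient(s), each > -1.
#' @return Selfing rate(s), on `[0, 1]` for `F` in `[0, 1]`.
#' @export
selfing_rate <- function(F) {
  if (any(F <= -1, na.rm = TRUE)) {
    stop("selfing rate undefined for F <= -1")
  }
  2 * F / (1 + F)
}

#' Sliding-window nucleotide diversity
#'
#' Per-site pi is the fraction of differing pairs among the non-missing
#' alleles (alt count a, ref count b: `a*b / choose(a+b, 2)`). Window pi
#' sums site pi over a window and divides by the window length in bp, so
#' monomorphic and unobserved positions contribute zero. Windows tile each
#' chromosome from 0 at `step` intervals; only full-length windows are
#' reported.
#'
#' @param tab A `genotype_table` of diploid calls.
#' @param window Window span in bp (default 50,000).
#' @param step Step between window starts in bp (default 25,000); must
#'   divide `window`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return Data frame (BED-like, 0-based half-open): chrom, start, end,
#'   n_sites, pi.
#' @export
sliding_pi <- function(tab, window = 50000, step = 25000, chrom_lengths) {
  stopifnot(inherits(tab, "genotype_table"))
  if (window < step) stop("window smaller than step")
  if (window %% step != 0) stop("window must be a multiple of step")
  called <- rowSums(!is.na(tab$gt))
  alt <- rowSums(tab$gt, na.rm = TRUE)
  n_alleles <- 2 * called
  ref <- n_alleles - alt
  pairs <- choose(n_alleles, 2)
  site_pi <- ifelse(pairs > 0, alt * ref / pairs, 0)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    if (len < window) next
    starts <- seq(0, len - window, by = step)
    si <- which(tab$sites$chrom == ch)
    pos0 <- tab$sites$pos[si] - 1L
    for (s in starts) {
      in_win <- si[pos0 >= s & pos0 < s + window]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + window,
        n_sites = length(in_win),
        pi = sum(site_pi[in_win]) / window,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      pi = numeric(0)))
  }
  do.call(rbind, out)
}
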