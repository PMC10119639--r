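# Genome-size estimation from a k-mer depth histogram:
# genome size = total number of k-mer instances / peak depth,
# with the low-depth sequencing-error tail excluded below the first valley.

#' Locate the error valley and the main coverage peak
#'
#' Scans count-vs-depth for the first local minimum (the valley separating
#' the sequencing-error tail from the coverage peak), then takes the peak
#' as the count argmax at depths beyond the valley. Optional 3-bin
#' moving-average smoothing (off by default) for ragged histograms.
#'
#' @param hist A `kmer_histogram`.
#' @param smooth If `TRUE`, apply a 3-bin moving average before scanning.
#' @return List: `valley_depth` (0 when no error tail exists),
#'   `peak_depth`.
#' @export
find_main_peak <- function(hist, smooth = FALSE) {
  e <- hist$entries
  if (nrow(e) == 0) stop("empty histogram")
  counts <- e$count
  if (smooth && nrow(e) >= 3) {
    counts <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
    counts[is.na(counts)] <- e$count[is.na(counts)]
    counts <- as.numeric(counts)
  }
  n <- length(counts)
  if (n == 1) {
    return(list(valley_depth = 0L, peak_depth = e$depth[1]))
  }
  if (counts[2] > counts[1]) {
    # histogram rises from the start: no error tail
    valley_idx <- 0L
  } else {
    rises <- which(diff(counts) > 0)
    if (length(rises) == 0) {
      stop("monotone histogram: no valley between error tail and coverage ",
           "peak; supply a manual low-depth cutoff")
    }
    valley_idx <- rises[1]
  }
  valley_depth <- if (valley_idx == 0L) 0L else e$depth[valley_idx]
  after <- which(e$depth > valley_depth)
  peak_depth <- e$depth[after[which.max(counts[after])]]
  list(valley_depth = valley_depth, peak_depth = peak_depth)
}

# Refine the integer histogram mode into a real-valued peak coverage.
# The coverage peak is modelled as locally Poisson: a mean-shift pass
# centres a window of half-width h on the peak, then the Poisson rate is
# fit by matching the truncated mean over that window. This resolves the
# half-count ambiguity of a raw argmax (for rate lambda the histogram mode
# sits near lambda - 1/2, and at integer lambda the two flanking depths
# carry equal mass, so the argmax is a coin flip of the sampling noise).
fit_peak_coverage <- function(entries, peak_depth, valley_depth) {
  h <- max(2, round(peak_depth / 4))
  lam <- peak_depth
  for (i in 1:60) {
    w <- entries$depth > valley_depth &
      entries$depth >= lam - h & entries$depth <= lam + h
    new <- sum(entries$depth[w] * entries$count[w]) / sum(entries$count[w])
    if (abs(new - lam) < 1e-9) break
    lam <- new
  }
  w <- entries$depth > valley_depth &
    entries$depth >= lam - h & entries$depth <= lam + h
  dd <- entries$depth[w]
  cc <- entries$count[w]
  if (length(dd) < 3) return(as.numeric(peak_depth))
  m_obs <- sum(dd * cc) / sum(cc)
  f <- function(l) {
    p <- stats::dpois(dd, l)
    sum(dd * p) / sum(p) - m_obs
  }
  lo <- max(1e-3, m_obs - 4)
  hi <- m_obs + 4
  if (f(lo) * f(hi) >= 0) return(as.numeric(peak_depth))
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Estimate genome size from a k-mer histogram
#'
#' Genome size = (total k-mer instances at depths above the low-depth
#' cutoff) / peak coverage. With `low_depth_cutoff = "auto"` the cutoff is
#' the valley found by [find_main_peak()], which removes the
#' sequencing-error tail from the numerator. The peak coverage is, by
#' default, a local Poisson fit around the histogram mode
#' (`peak_method = "poisson_fit"`), which removes the half-count bias a raw
#' integer mode carries; `peak_method = "argmax"` divides by the raw mode.
#'
#' @param hist A `kmer_histogram`.
#' @param low_depth_cutoff `"auto"` or an integer depth; only depths
#'   strictly greater contribute.
#' @param peak_method `"poisson_fit"` (default) or `"argmax"`.
#' @param smooth Passed to [find_main_peak()].
#' @return List of class `genome_size_estimate`: `peak_depth` (integer
#'   histogram mode), `peak_coverage` (the divisor actually used),
#'   `total_kmers_used`, `genome_size` (bp, real-valued),
#'   `excluded_low_depth` (the cutoff used), `k`.
#' @export
estimate_genome_size <- function(hist, low_depth_cutoff = "auto",
                                 peak_method = c("poisson_fit", "argmax"),
                                 smooth = FALSE) {
  peak_method <- match.arg(peak_method)
  pk <- find_main_peak(hist, smooth = smooth)
  cutoff <- if (identical(low_depth_cutoff, "auto")) {
    pk$valley_depth
  } else {
    as.numeric(low_depth_cutoff)
  }
  if (cutoff >= pk$peak_depth) {
    stop("low-depth cutoff (", cutoff, ") at or above the coverage peak (",
         pk$peak_depth, ")")
  }
  coverage <- if (peak_method == "poisson_fit") {
    fit_peak_coverage(hist$entries, pk$peak_depth, cutoff)
  } else {
    as.numeric(pk$peak_depth)
  }
  total <- total_kmer_instances(hist, min_depth = cutoff)
  structure(list(peak_depth = pk$peak_depth,
                 peak_coverage = coverage,
                 total_kmers_used = total,
                 genome_size = total / coverage,
                 excluded_low_depth = cutoff,
                 k = hist$k),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "genome size estimate: %.4g bp (peak depth %d, peak coverage %.2f, %.4g k-mer instances, depth cutoff %g)\n",
    x$genome_size, x$peak_depth, x$peak_coverage, x$total_kmers_used,
    x$excluded_low_depth))
  invisible(x)
}
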