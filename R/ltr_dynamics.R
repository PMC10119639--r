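# LTR retrotransposon insertion dating and genome-dynamics summaries.
#
# A full-length LTR-RT carries two terminal repeats that were identical at
# insertion; their divergence K (Jukes-Cantor corrected) dates the insertion
# as T = K / (2 r), with r the neutral substitution rate per site per year
# (both repeats accumulate substitutions independently, hence the factor 2).

#' Globally align a 5'/3' LTR pair
#'
#' Needleman-Wunsch with affine gaps (match +1, mismatch -1, gap open -2,
#' gap extend -0.5) and deterministic tie-breaking (diagonal preferred,
#' then a gap in the second sequence).
#'
#' @param seq5,seq3 Nucleotide strings (the two terminal repeats).
#' @return List of class `ltr_alignment`: `aligned_a`, `aligned_b`, `score`.
#' @export
align_ltr_pair <- function(seq5, seq3) {
  seq5 <- toupper(as.character(seq5))
  seq3 <- toupper(as.character(seq3))
  if (!nzchar(seq5) || !nzchar(seq3)) stop("empty sequence in LTR pair")
  aln <- nw_align_cpp(seq5, seq3)
  class(aln) <- "ltr_alignment"
  aln
}

#' Divergence and insertion time from an aligned LTR pair
#'
#' Columns containing a gap or an N in either sequence are excluded from
#' both the numerator and the denominator of the p-distance. K is the
#' Jukes-Cantor correction of p; T = K / (2 r).
#'
#' @param alignment An `ltr_alignment` (or list with `aligned_a`,
#'   `aligned_b`).
#' @param r Neutral substitution rate, substitutions/site/year
#'   (default 1.33e-9).
#' @return List: `aligned_sites`, `mismatches`, `p_distance`, `K`,
#'   `T_years`, `saturated`.
#' @export
ltr_divergence <- function(alignment, r = 1.33e-9) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  usable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  aligned_sites <- sum(usable)
  if (aligned_sites == 0) stop("no gap- and N-free aligned sites")
  mismatches <- sum(a[usable] != b[usable])
  p <- mismatches / aligned_sites
  if (p >= 0.75) {
    return(list(aligned_sites = aligned_sites, mismatches = mismatches,
                p_distance = p, K = NA_real_, T_years = NA_real_,
                saturated = TRUE))
  }
  K <- jc_correct(p)
  list(aligned_sites = aligned_sites, mismatches = mismatches,
       p_distance = p, K = K, T_years = K / (2 * r), saturated = FALSE)
}

#' Date every element of an LTR table against its genome
#'
#' Extracts both terminal repeats of each full-length element, aligns them,
#' and converts divergence to insertion time.
#'
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param elements LTR element data frame ([read_ltr_table()] layout,
#'   0-based half-open coordinates).
#' @param r Substitution rate per site per year.
#' @return Data frame: element_id, superfamily, aligned_sites, mismatches,
#'   p_distance, K, T_years, saturated.
#' @export
date_ltr_elements <- function(genome, elements, r = 1.33e-9) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    chrom_seq <- genome[[e$chrom]]
    if (is.null(chrom_seq) || is.na(chrom_seq)) {
      stop("chromosome not in genome: ", e$chrom)
    }
    s5 <- substr(chrom_seq, e$ltr5_start + 1L, e$ltr5_end)
    s3 <- substr(chrom_seq, e$ltr3_start + 1L, e$ltr3_end)
    d <- ltr_divergence(align_ltr_pair(s5, s3), r = r)
    data.frame(element_id = e$element_id, superfamily = e$superfamily,
               aligned_sites = d$aligned_sites, mismatches = d$mismatches,
               p_distance = d$p_distance, K = d$K, T_years = d$T_years,
               saturated = d$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen candidate segments for solo-LTRs
#'
#' A candidate segment is a solo-LTR iff it overlaps no full-length element
#' interval by at least 1 bp (intervals are 0-based half-open, so merely
#' abutting segments do not overlap).
#'
#' @param candidates Data frame chrom, start, end (0-based half-open).
#' @param elements Full-length element table (`element_start`/`element_end`).
#' @return List: `solo` (the surviving candidate rows), `n_solo`,
#'   `n_paired` (number of full-length elements).
#' @export
classify_solo_ltrs <- function(candidates, elements) {
  if (nrow(candidates) == 0) {
    return(list(solo = candidates, n_solo = 0L, n_paired = nrow(elements)))
  }
  overlapped <- rep(FALSE, nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == ch)
    ei <- which(elements$chrom == ch)
    if (length(ei) == 0) next
    # half-open -> closed integer ranges for IRanges
    cr <- IRanges::IRanges(start = candidates$start[ci] + 1L,
                           end = candidates$end[ci])
    er <- IRanges::IRanges(start = elements$element_start[ei] + 1L,
                           end = elements$element_end[ei])
    hits <- IRanges::overlapsAny(cr, er, minoverlap = 1L)
    overlapped[ci] <- hits
  }
  solo <- candidates[!overlapped, , drop = FALSE]
  list(solo = solo, n_solo = nrow(solo), n_paired = nrow(elements))
}

#' Solo-LTR to paired-LTR ratio
#'
#' @param n_solo,n_paired Counts of solo-LTRs and of full-length
#'   (paired-LTR) elements.
#' @return The ratio rounded to 2 decimals.
#' @export
solo_paired_ratio <- function(n_solo, n_paired) {
  if (n_paired <= 0) stop("undefined ratio: no paired-LTR elements")
  round(n_solo / n_paired, 2)
}

#' Transposition-rate and accumulation curves
#'
#' Bins dated insertions into half-open age bins `[i*w, (i+1)*w)` up to a
#' horizon; the accumulation curve is the cumulative count from the present
#' backwards. Elements older than the horizon are excluded from the bins
#' and reported separately.
#'
#' @param T_years Vector of insertion times (years); `NA` (saturated)
#'   entries are dropped.
#' @param bin_width Bin width in years (default 1e5 = 0.1 My).
#' @param horizon Oldest age binned (default 1e7 = 10 My).
#' @return List of class `rate_curve`: `bins` (data frame age_lo, age_hi,
#'   insertions, accumulation), `n_dated`, `n_beyond_horizon`, `bin_width`,
#'   `horizon`.
#' @export
transposition_rate_curve <- function(T_years, bin_width = 1e5,
                                     horizon = 1e7) {
  T_years <- T_years[!is.na(T_years)]
  if (any(T_years < 0)) stop("negative insertion times")
  n_bins <- as.integer(ceiling(horizon / bin_width))
  in_range <- T_years < horizon
  idx <- floor(T_years[in_range] / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  bins <- data.frame(
    age_lo = (seq_len(n_bins) - 1) * bin_width,
    age_hi = seq_len(n_bins) * bin_width,
    insertions = counts,
    accumulation = cumsum(counts)
  )
  structure(list(bins = bins, n_dated = length(T_years),
                 n_beyond_horizon = sum(!in_range),
                 bin_width = bin_width, horizon = horizon),
            class = "rate_curve")
}

#' Superfamily mass accounting
#'
#' Per-superfamily genome occupancy and the Gypsy:Copia fold ratio.
#'
#' @param bp_by_superfamily Named numeric vector of total bp per
#'   superfamily (names e.g. "Gypsy", "Copia").
#' @param genome_length Genome length in the same unit as the masses.
#' @param counts Optional named vector of full-length element counts.
#' @return List: `masses` (data frame superfamily, total_bp,
#'   fraction_of_genome as percent to 2 decimals, n_elements) and
#'   `gypsy_copia_fold` (2 decimals; `NA` if Copia mass is zero or absent).
#' @export
superfamily_masses <- function(bp_by_superfamily, genome_length,
                               counts = NULL) {
  if (genome_length <= 0) stop("genome_length must be positive")
  sf <- names(bp_by_superfamily)
  masses <- data.frame(
    superfamily = sf,
    total_bp = as.numeric(bp_by_superfamily),
    fraction_of_genome = round(100 * bp_by_superfamily / genome_length, 2),
    n_elements = if (is.null(counts)) NA_integer_ else
      as.integer(counts[sf]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  fold <- NA_real_
  if ("Gypsy" %in% sf && "Copia" %in% sf &&
      bp_by_superfamily[["Copia"]] > 0) {
    fold <- round(bp_by_superfamily[["Gypsy"]] /
                    bp_by_superfamily[["Copia"]], 2)
  }
  list(masses = masses, gypsy_copia_fold = fold)
}
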