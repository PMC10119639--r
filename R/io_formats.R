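# File formats: FASTA, LTR element TSV, VCF genotypes, k-mer histograms, BED.
#
# Coordinate convention: on-disk interval formats are 1-based inclusive
# (VCF/GFF style) except BED, which is already 0-based half-open. All
# in-memory intervals are 0-based half-open; conversion happens exactly once,
# in the readers/writers below. Point positions (VCF POS) stay 1-based.

#' Read a nucleotide FASTA file
#'
#' Sequences are uppercased and U is mapped to T, so RNA input is accepted.
#' Only the alphabet `{A, C, G, T, N}` is permitted after normalization.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A named character vector of sequences; names are the full header
#'   lines without the leading `>`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- names(set)
  if (any(!nzchar(names(seqs)))) {
    stop("FASTA format error: empty header for record ",
         which(!nzchar(names(seqs)))[1])
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    stop("FASTA format error: empty sequence for record '",
         names(seqs)[empty[1]], "'")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA format error: non-ACGTN characters in record '",
         names(seqs)[which(bad)[1]], "'")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.ltr_table_cols <- c("element_id", "chrom", "element_start", "element_end",
                     "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                     "superfamily")

#' Read an LTR-RT element table
#'
#' The table is a TSV with a header row naming nine fields: `element_id`,
#' `chrom`, `element_start`, `element_end`, `ltr5_start`, `ltr5_end`,
#' `ltr3_start`, `ltr3_end`, `superfamily`. On disk all coordinates are
#' 1-based inclusive; the returned data frame holds 0-based half-open
#' intervals. `superfamily` is normalized to `Gypsy`, `Copia` or `unknown`.
#'
#' @param path Path to the TSV.
#' @return A data frame, one row per full-length element, with 0-based
#'   half-open `*_start`/`*_end` columns.
#' @export
read_ltr_table <- function(path) {
  if (!file.exists(path)) stop("LTR table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ltr_table_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("LTR table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, .ltr_table_cols]
  coord_cols <- grep("_(start|end)$", names(df), value = TRUE)
  for (cc in coord_cols) {
    if (!is.numeric(df[[cc]])) stop("LTR table format error: non-numeric ", cc)
  }
  # 1-based inclusive -> 0-based half-open
  for (cc in grep("_start$", names(df), value = TRUE)) df[[cc]] <- df[[cc]] - 1L
  df$superfamily <- normalize_superfamily(df$superfamily)
  validate_ltr_elements(df)
  df
}

#' @rdname read_ltr_table
#' @param elements Data frame as returned by [read_ltr_table()].
#' @export
write_ltr_table <- function(elements, path) {
  validate_ltr_elements(elements)
  out <- elements[, .ltr_table_cols]
  for (cc in grep("_start$", names(out), value = TRUE)) out[[cc]] <- out[[cc]] + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_superfamily <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- ifelse(lx == "gypsy", "Gypsy",
                ifelse(lx == "copia", "Copia", "unknown"))
  out
}

validate_ltr_elements <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    ok <- r$ltr5_start < r$ltr5_end && r$ltr3_start < r$ltr3_end &&
      r$element_start < r$element_end &&
      r$ltr5_end <= r$ltr3_start &&
      r$ltr5_start >= r$element_start && r$ltr3_end <= r$element_end
    if (!ok) {
      stop("LTR element validation error for '", r$element_id,
           "': LTR intervals must satisfy 5'-LTR before 3'-LTR, both within ",
           "the element, lengths >= 1")
    }
  }
  invisible(df)
}

#' Read diploid genotypes from a VCF file
#'
#' Builds a genotype table: individuals x biallelic sites with per-call
#' genotype (0/1/2 alternate-allele dosage), depth and genotype quality.
#' Multi-allelic records are retained and flagged (`multiallelic`) so the
#' filter cascade can count them; missing genotypes (`./.`) become `NA`.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @return An object of class `genotype_table`: a list with `individuals`,
#'   `sites` (data frame: chrom, pos, ref, alt, qual, multiallelic),
#'   and matrices `gt`, `dp`, `gq` (sites x individuals).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, "FORMAT"]
  if (nrow(v@gt) > 0 && !all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF format error: GT key absent from FORMAT")
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(g, "/"), function(a) {
             ai <- suppressWarnings(as.integer(a))
             if (anyNA(ai)) NA_integer_ else sum(ai > 0L)
           }, integer(1)))
  }
  gt <- apply(gt_chr, 2, dosage)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(gt_chr),
                                     dimnames = dimnames(gt_chr))
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    multiallelic = grepl(",", fix$ALT),
    stringsAsFactors = FALSE
  )
  genotype_table(individuals = colnames(gt), sites = sites,
                 gt = gt, dp = dp, gq = gq)
}

#' Construct a genotype table
#'
#' @param individuals Character vector of individual ids.
#' @param sites Data frame with columns chrom, pos (1-based), ref, alt,
#'   qual and optionally multiallelic.
#' @param gt Integer matrix (sites x individuals) of alt-allele dosages
#'   0/1/2, `NA` = missing.
#' @param dp,gq Numeric matrices (sites x individuals) of read depth and
#'   genotype quality; may be `NA`.
#' @return A `genotype_table` object.
#' @export
genotype_table <- function(individuals, sites, gt, dp = NULL, gq = NULL) {
  n_sites <- nrow(sites)
  n_ind <- length(individuals)
  stopifnot(nrow(gt) == n_sites, ncol(gt) == n_ind)
  if (is.null(dp)) dp <- matrix(NA_real_, n_sites, n_ind)
  if (is.null(gq)) gq <- matrix(NA_real_, n_sites, n_ind)
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  # positions strictly increasing within chrom
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("genotype_table: positions must be strictly increasing within ",
           "chromosome ", ch)
    }
  }
  storage.mode(gt) <- "integer"
  structure(list(individuals = individuals, sites = sites,
                 gt = gt, dp = dp, gq = gq),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x",
      length(x$individuals), "individuals\n")
  cat("  missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(x$gt))), "\n")
  invisible(x)
}

#' Write a genotype table as VCF 4.2
#'
#' Emits GT:DP:GQ per call; used for simulated cohorts and filtered output.
#'
#' @param tab A `genotype_table`.
#' @param path Output path.
#' @export
write_vcf_genotypes <- function(tab, path) {
  stopifnot(inherits(tab, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tab$individuals), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[tab$gt + 1L],
                   nrow = nrow(tab$gt))
  gt_str[is.na(tab$gt)] <- "./."
  dp_str <- ifelse(is.na(tab$dp), ".", format(tab$dp, trim = TRUE,
                                              scientific = FALSE))
  gq_str <- ifelse(is.na(tab$gq), ".", format(tab$gq, trim = TRUE,
                                              scientific = FALSE))
  calls <- matrix(paste(gt_str, dp_str, gq_str, sep = ":"),
                  nrow = nrow(gt_str))
  qual <- ifelse(is.na(tab$sites$qual), ".",
                 format(tab$sites$qual, trim = TRUE, scientific = FALSE))
  lines <- paste(tab$sites$chrom, tab$sites$pos, ".", tab$sites$ref,
                 tab$sites$alt, qual, "PASS", ".", "GT:DP:GQ",
                 apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a k-mer depth histogram
#'
#' Two-column whitespace-delimited text: depth, count of distinct k-mers at
#' that depth. Entries are sorted by depth on read.
#'
#' @param path Path to the histogram file.
#' @param k The k-mer length the histogram was computed with (default 17).
#' @return A `kmer_histogram`: list with `entries` (data frame depth, count)
#'   and `k`.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  if (!file.exists(path)) stop("histogram file not found: ", path)
  raw <- utils::read.table(path, header = FALSE,
                           colClasses = c("character", "character"))
  depth <- suppressWarnings(as.numeric(raw[[1]]))
  count <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(depth) || anyNA(count) ||
      any(depth != round(depth)) || any(count != round(count))) {
    stop("histogram format error: non-integer field")
  }
  kmer_histogram(depth = as.integer(depth), count = count, k = k)
}

#' Construct a k-mer histogram
#'
#' @param depth Integer vector of depths (positive).
#' @param count Numeric vector of distinct-k-mer counts (non-negative).
#' @param k The k-mer length.
#' @export
kmer_histogram <- function(depth, count, k = 17L) {
  if (any(depth < 1)) stop("histogram error: depths must be positive")
  if (any(count < 0)) stop("histogram error: counts must be non-negative")
  if (anyDuplicated(depth)) stop("histogram error: duplicated depth")
  o <- order(depth)
  structure(list(entries = data.frame(depth = depth[o], count = count[o]),
                 k = as.integer(k)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("kmer_histogram (k =", x$k, "):", nrow(x$entries), "depth bins,",
      format(total_kmer_instances(x), big.mark = ","), "k-mer instances\n")
  invisible(x)
}

#' Total number of k-mer instances in a histogram
#'
#' @param hist A `kmer_histogram`.
#' @param min_depth Only depths strictly greater than this contribute.
#' @export
total_kmer_instances <- function(hist, min_depth = 0) {
  e <- hist$entries
  sum(e$depth[e$depth > min_depth] * e$count[e$depth > min_depth])
}

#' @rdname read_kmer_histogram
#' @param hist A `kmer_histogram`.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist$entries, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk, which matches the in-memory convention,
#' so coordinates pass through unchanged.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return Data frame with chrom, start, end (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED format error: fewer than 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("BED format error: end <= start")
  out
}
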