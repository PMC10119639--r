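# Nei-Gojobori (1986) synonymous/nonsynonymous substitution estimation.
#
# Site counting: at each codon position the synonymous-site fraction is the
# share of the three possible single-nucleotide changes that preserve the
# amino acid; changes creating a stop codon count as nonsynonymous. Sites are
# averaged over the two sequences. Difference counting: codons differing at
# d positions are resolved over all d! orderings of the single-base steps;
# orderings passing through a stop codon are discarded and the survivors
# weighted equally (if every ordering is blocked, all are retained).
# Proportions are distance-corrected with Jukes-Cantor,
# d = -(3/4) ln(1 - (4/3) p), undefined (saturated) at p >= 3/4.

.ng86_cache <- new.env(parent = emptyenv())

.codon_alphabet <- c("T", "C", "A", "G")

all_codons <- function() {
  g <- expand.grid(p3 = .codon_alphabet, p2 = .codon_alphabet,
                   p1 = .codon_alphabet, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Nei-Gojobori codon tables
#'
#' Precomputes, for the 61 sense codons of the standard genetic code, the
#' fractional synonymous and nonsynonymous site counts, and for every ordered
#' sense-codon pair the pathway-averaged synonymous and nonsynonymous
#' difference counts. Cached after first use.
#'
#' @return List with `codons` (61 sense codons), `S`/`N` (per-codon site
#'   counts), and 61 x 61 matrices `sd`/`nd` (pathway-averaged differences).
#' @export
ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- all_codons()
  sense <- codons[code[codons] != "*"]
  n <- length(sense)

  # per-codon fractional sites
  S <- numeric(n)
  for (i in seq_len(n)) {
    cod <- sense[i]
    aa <- code[[cod]]
    syn_frac <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.codon_alphabet, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        if (code[[mut]] != "*" && code[[mut]] == aa) syn_frac <- syn_frac + 1
      }
    }
    S[i] <- syn_frac / 3
  }
  N <- 3 - S

  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      counts <- codon_pathway_counts(sense[i], sense[j], code)
      sd[i, j] <- counts[1]
      nd[i, j] <- counts[2]
    }
  }
  .ng86_cache$tables <- list(codons = sense, S = S, N = N, sd = sd, nd = nd)
  .ng86_cache$tables
}

# average (syn, nonsyn) step counts over equally weighted shortest pathways
codon_pathway_counts <- function(from, to, code = Biostrings::GENETIC_CODE) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  d <- length(diff_pos)
  if (d == 0) return(c(0, 0))
  perms <- permutations_of(diff_pos)
  path_syn <- numeric(0)
  path_non <- numeric(0)
  blocked <- logical(0)
  for (ord in perms) {
    cur <- from
    syn <- 0; non <- 0; hit_stop <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      if (code[[nxt]] == "*") hit_stop <- TRUE
      if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") {
        syn <- syn + 1
      } else {
        non <- non + 1
      }
      cur <- nxt
    }
    path_syn <- c(path_syn, syn)
    path_non <- c(path_non, non)
    blocked <- c(blocked, hit_stop)
  }
  keep <- if (all(blocked)) rep(TRUE, length(blocked)) else !blocked
  c(mean(path_syn[keep]), mean(path_non[keep]))
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' @param p Observed proportion of differing sites.
#' @return Corrected substitutions per site; `NA` where `p >= 0.75`
#'   (saturation).
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - (4 / 3) * p))
}

# split an in-frame sequence into codons; returns indices into the sense
# codon table, NA for codons containing gaps/N or encoding a stop
codon_indices <- function(seq, tables) {
  seq <- toupper(seq)
  nc <- nchar(seq)
  if (nc %% 3 != 0) stop("coding sequence length not a multiple of 3")
  starts <- seq.int(1L, nc, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  match(cods, tables$codons)   # NA for anything not a sense ACGT codon
}

#' Estimate Ks and Ka for an aligned in-frame sequence pair (NG86)
#'
#' Codons containing a gap, an ambiguous base, or a stop in either sequence
#' are excluded. Proportions of synonymous and nonsynonymous differences are
#' Jukes-Cantor corrected; a proportion at or beyond 3/4 is reported as
#' saturated (`NA` with the corresponding flag set).
#'
#' @param seq_a,seq_b Aligned, equal-length, in-frame nucleotide strings.
#' @return List with `Ks`, `Ka`, site counts `S`, `N`, difference counts
#'   `Sd`, `Nd`, proportions `ps`, `pn`, `codons_used`, and flags
#'   `ks_saturated`, `ka_saturated`.
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must be aligned to equal length")
  }
  tb <- ng86_tables()
  ia <- codon_indices(seq_a, tb)
  ib <- codon_indices(seq_b, tb)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no comparable codons in pair")
  ia <- ia[keep]; ib <- ib[keep]
  S <- (sum(tb$S[ia]) + sum(tb$S[ib])) / 2
  N <- (sum(tb$N[ia]) + sum(tb$N[ib])) / 2
  Sd <- sum(tb$sd[cbind(ia, ib)])
  Nd <- sum(tb$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  list(Ks = Ks, Ka = Ka, S = S, N = N, Sd = Sd, Nd = Nd,
       ps = ps, pn = pn, codons_used = length(ia),
       ks_saturated = is.na(Ks), ka_saturated = is.na(Ka))
}

#' Estimate Ks for many aligned pairs
#'
#' @param pairs A list; each element a character vector of two aligned
#'   in-frame sequences (or a list with `$a` and `$b`).
#' @return Data frame with one row per pair: Ks, Ka, saturation flags.
#' @export
ks_ng86_pairs <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.list(p)) p <- c(p$a, p$b)
    est <- ks_ng86(p[1], p[2])
    data.frame(pair = if (!is.null(names(pairs))) names(pairs)[i] else i,
               Ks = est$Ks, Ka = est$Ka,
               ks_saturated = est$ks_saturated,
               ka_saturated = est$ka_saturated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
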