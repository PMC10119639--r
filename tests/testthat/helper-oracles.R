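# Independent oracles used to check the package's implementations.
# Each is a deliberately naive computation (exhaustive enumeration, direct
# formula, O(n^2) counting) kept separate from the code paths it audits.

# Exhaustive global-alignment score: recursively enumerates every alignment
# path with affine gap costs (first gap column = open, later = extend).
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(a)) {
      g <- if (state == "X") gap_extend else gap_open
      best <- max(best, g + rec(i + 1, j, "X"))
    }
    if (j <= length(b)) {
      g <- if (state == "Y") gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# Direct NG86 codon-pair oracle: fractional sites by explicit mutation
# enumeration; pathway counts by recursive expansion of every substitution
# order, dropping orders that visit a stop codon (kept if all do).
oracle_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("T", "C", "A", "G")
  syn <- 0
  for (pos in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (code[[mut]] == code[[codon]] && code[[mut]] != "*") syn <- syn + 1
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

oracle_codon_paths <- function(from, to) {
  code <- Biostrings::GENETIC_CODE
  expand <- function(cur, remaining) {
    if (length(remaining) == 0) {
      return(list(list(syn = 0, non = 0, stop = FALSE)))
    }
    out <- list()
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      step_syn <- (code[[nxt]] == code[[cur]] && code[[nxt]] != "*")
      step_stop <- code[[nxt]] == "*"
      for (tail in expand(nxt, remaining[-k])) {
        out[[length(out) + 1]] <- list(
          syn = tail$syn + as.integer(step_syn),
          non = tail$non + as.integer(!step_syn),
          stop = tail$stop || step_stop)
      }
    }
    out
  }
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diff_pos) == 0) return(c(sd = 0, nd = 0))
  paths <- expand(from, diff_pos)
  blocked <- vapply(paths, `[[`, logical(1), "stop")
  keep <- if (all(blocked)) paths else paths[!blocked]
  c(sd = mean(vapply(keep, `[[`, numeric(1), "syn")),
    nd = mean(vapply(keep, `[[`, numeric(1), "non")))
}

# Longest monotone chain by memoized recursion on "best chain starting at
# anchor i"; returns the maximum over both rank_b directions.
oracle_chain_max <- function(rank_a, rank_b, max_rank_gap = 25) {
  n <- length(rank_a)
  best_dir <- function(direction) {
    memo <- rep(NA_integer_, n)
    longest_from <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      best <- 1L
      for (j in seq_len(n)) {
        da <- rank_a[j] - rank_a[i]
        db <- (rank_b[j] - rank_b[i]) * direction
        if (da >= 1 && da <= max_rank_gap && db >= 1 && db <= max_rank_gap) {
          best <- max(best, 1L + longest_from(j))
        }
      }
      memo[i] <<- best
      best
    }
    max(vapply(seq_len(n), longest_from, integer(1)))
  }
  max(best_dir(+1L), best_dir(-1L))
}

# Windowed nucleotide diversity by explicit enumeration of haplotype pairs.
oracle_window_pi <- function(gt, pos, start, window) {
  in_win <- which(pos - 1 >= start & pos - 1 < start + window)
  total <- 0
  for (s in in_win) {
    alleles <- unlist(lapply(gt[s, ], function(g) {
      if (is.na(g)) NULL else c(rep(1, g), rep(0, 2 - g))
    }))
    k <- length(alleles)
    if (k < 2) next
    diffs <- 0
    for (x in seq_len(k - 1)) {
      for (y in (x + 1):k) diffs <- diffs + (alleles[x] != alleles[y])
    }
    total <- total + diffs / choose(k, 2)
  }
  total / window
}

# Exact HWE p-value from the conditional distribution written out directly
# with factorials (no log-space tricks, usable for small counts).
oracle_hwe_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  na <- 2 * n_hom_ref + n_het
  nb <- 2 * n_hom_alt + n_het
  prob <- function(h) {
    hr <- (na - h) / 2
    ha <- (nb - h) / 2
    if (hr < 0 || ha < 0 || hr != round(hr)) return(0)
    factorial(n) / (factorial(h) * factorial(hr) * factorial(ha)) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  }
  hets <- 0:min(na, nb)
  ps <- vapply(hets, prob, numeric(1))
  obs <- prob(n_het)
  sum(ps[ps <= obs * (1 + 1e-12)])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# small genotype table built directly from a dosage matrix
toy_genotype_table <- function(gt, pos = NULL, chrom = "chr1",
                               qual = 100, dp = 20, gq = 99) {
  n_sites <- nrow(gt)
  n_ind <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n_sites) * 10L
  genotype_table(
    individuals = sprintf("ind%02d", seq_len(n_ind)),
    sites = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                       qual = qual, multiallelic = FALSE,
                       stringsAsFactors = FALSE),
    gt = gt,
    dp = matrix(dp, n_sites, n_ind),
    gq = matrix(gq, n_sites, n_ind))
}
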