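# Seeded synthetic-data generators.
#
# Each generator emulates the statistical structure one analysis stage
# assumes and returns a truth table for parameter-recovery tests. All
# randomness flows from the single `seed` argument.

#' Jukes-Cantor substitution operator
#'
#' Mutates a nucleotide string under JC69 for an expected number of
#' substitutions per site `d`: each site changes with probability
#' `3/4 (1 - exp(-4 d / 3))`, uniformly to one of the other three bases.
#' Substitution-only: sequence length is preserved.
#'
#' @param seq Nucleotide string over ACGT.
#' @param d Expected substitutions per site on the branch.
#' @return The mutated string.
#' @export
jc_mutate <- function(seq, d) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "")[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(stats::runif(length(x)) < p)
  if (length(hit) > 0) {
    cur <- match(x[hit], bases)
    shift <- sample.int(3, length(hit), replace = TRUE)
    x[hit] <- bases[((cur - 1 + shift) %% 4) + 1]
  }
  paste(x, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with an LTR retrotransposon landscape
#'
#' Plants `n_elements` LTR-RTs without overlap into a random genome. Each
#' full-length element carries two copies of an ancestral terminal repeat,
#' independently mutated under JC69 for the element's age `t` at rate `r`
#' (per-branch expected substitutions `r t`, so the pair diverges by `2 r t`
#' in expectation). A `solo_fraction` of elements is emitted as a single
#' LTR segment, absent from the full-length table, mimicking solo-LTRs
#' left by unequal recombination.
#'
#' @param genome_length Genome length in bp.
#' @param n_elements Number of elements to plant.
#' @param time_sampler Function `n -> n` insertion ages in years.
#' @param r Substitution rate, per site per year.
#' @param ltr_length Terminal-repeat length in bp.
#' @param internal_length Internal-domain length in bp.
#' @param solo_fraction Fraction of elements emitted as solo segments.
#' @param gypsy_fraction Probability an element is Gypsy (else Copia).
#' @param seed Integer seed.
#' @return List: `genome` (named character vector, one chromosome),
#'   `elements` (full-length table, [read_ltr_table()] layout), `solo_candidates`
#'   (data frame chrom, start, end, element_id), `truth` (data frame
#'   element_id, true_insertion_time, superfamily, is_solo).
#' @export
simulate_ltr_landscape <- function(genome_length = 1.2e7, n_elements = 500,
                                   time_sampler = function(n)
                                     stats::runif(n, 0, 5e6),
                                   r = 1.33e-9, ltr_length = 5000,
                                   internal_length = 1000,
                                   solo_fraction = 0.1,
                                   gypsy_fraction = 0.7, seed = 1) {
  set.seed(seed)
  full_len <- 2 * ltr_length + internal_length
  if (n_elements * full_len > genome_length / 2) {
    stop("infeasible packing: elements exceed half the genome")
  }
  n_solo <- round(solo_fraction * n_elements)
  is_solo <- rep(FALSE, n_elements)
  if (n_solo > 0) is_solo[sample.int(n_elements, n_solo)] <- TRUE
  lens <- ifelse(is_solo, ltr_length, full_len)
  ages <- time_sampler(n_elements)
  if (any(ages < 0)) stop("time_sampler produced negative ages")
  superfamily <- ifelse(stats::runif(n_elements) < gypsy_fraction,
                        "Gypsy", "Copia")

  # place without overlap: spread the slack uniformly between elements
  slack <- genome_length - sum(lens)
  gaps <- floor(sort(stats::runif(n_elements, 0, slack)))
  starts <- gaps + cumsum(c(0, lens[-n_elements]))   # 0-based

  genome <- strsplit(random_dna(genome_length), "")[[1]]
  elements <- list()
  solo <- list()
  for (i in seq_len(n_elements)) {
    d <- r * ages[i]
    ancestral <- random_dna(ltr_length)
    s <- starts[i]
    if (is_solo[i]) {
      seg <- jc_mutate(ancestral, d)
      genome[(s + 1):(s + ltr_length)] <- strsplit(seg, "")[[1]]
      solo[[length(solo) + 1L]] <- data.frame(
        chrom = "chr1", start = s, end = s + ltr_length,
        element_id = sprintf("solo%04d", i), stringsAsFactors = FALSE)
    } else {
      ltr5 <- jc_mutate(ancestral, d)
      ltr3 <- jc_mutate(ancestral, d)
      body <- random_dna(internal_length)
      el <- paste0(ltr5, body, ltr3)
      genome[(s + 1):(s + full_len)] <- strsplit(el, "")[[1]]
      elements[[length(elements) + 1L]] <- data.frame(
        element_id = sprintf("ltr%04d", i), chrom = "chr1",
        element_start = s, element_end = s + full_len,
        ltr5_start = s, ltr5_end = s + ltr_length,
        ltr3_start = s + ltr_length + internal_length,
        ltr3_end = s + full_len,
        superfamily = superfamily[i], stringsAsFactors = FALSE)
    }
  }
  truth <- data.frame(
    element_id = ifelse(is_solo, sprintf("solo%04d", seq_len(n_elements)),
                        sprintf("ltr%04d", seq_len(n_elements))),
    true_insertion_time = ages,
    superfamily = superfamily,
    is_solo = is_solo, stringsAsFactors = FALSE)
  list(genome = c(chr1 = paste(genome, collapse = "")),
       elements = do.call(rbind, elements),
       solo_candidates = if (length(solo) > 0) do.call(rbind, solo) else
         data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), element_id = character(0)),
       truth = truth)
}

# synonymous single-nucleotide neighbours of every sense codon
syn_neighbours <- function() {
  if (!is.null(.ng86_cache$syn_nb)) return(.ng86_cache$syn_nb)
  tb <- ng86_tables()
  code <- Biostrings::GENETIC_CODE
  nb <- lapply(tb$codons, function(cod) {
    out <- integer(0)
    for (pos in 1:3) {
      for (nt in setdiff(.codon_alphabet, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        if (code[[mut]] != "*" && code[[mut]] == code[[cod]]) {
          out <- c(out, match(mut, tb$codons))
        }
      }
    }
    out
  })
  .ng86_cache$syn_nb <- nb
  nb
}

ng86_from_indices <- function(ia, ib, tb) {
  S <- (sum(tb$S[ia]) + sum(tb$S[ib])) / 2
  Sd <- sum(tb$sd[cbind(ia, ib)])
  ps <- Sd / S
  jc_correct(ps)
}

#' Simulate paralog pairs at planted Ks values
#'
#' Samples a target Ks from a Gaussian mixture, then applies synonymous
#' single-nucleotide substitutions (alternating randomly between the two
#' copies of an initially identical random coding sequence) until the
#' NG86-measured Ks of the pair first reaches the target. The realized
#' (measured) Ks is stored as truth, so truth and estimator share a scale.
#' Pairs whose target cannot be reached before synonymous saturation are
#' regenerated with a warning.
#'
#' @param peaks Data frame (or list) with `mean`, `sd`, `weight`
#'   (weights summing to 1, means > 0).
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence (default 300).
#' @param seed Integer seed.
#' @return List: `pairs` (list of length-2 character vectors of in-frame
#'   sequences), `fasta` (named vector, `pair<i>_a`/`_b`), `truth`
#'   (data frame pair_id, target_ks, realized_ks).
#' @export
simulate_paralog_pairs <- function(peaks, n_pairs, n_codons = 300,
                                   seed = 1) {
  set.seed(seed)
  peaks <- as.data.frame(peaks)
  stopifnot(abs(sum(peaks$weight) - 1) < 1e-8, all(peaks$mean >= 0))
  tb <- ng86_tables()
  nb <- syn_neighbours()
  mutable <- which(vapply(nb, length, integer(1)) > 0)
  max_steps <- 60L * n_codons

  pairs <- vector("list", n_pairs)
  truth <- data.frame(pair_id = sprintf("pair%04d", seq_len(n_pairs)),
                      target_ks = NA_real_, realized_ks = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    repeat {
      comp <- sample.int(nrow(peaks), 1, prob = peaks$weight)
      target <- stats::rnorm(1, peaks$mean[comp], peaks$sd[comp])
      if (target >= 0) break
    }
    repeat {
      ia <- sample(mutable, n_codons, replace = TRUE)
      ib <- ia
      ks <- 0
      steps <- 0L
      ok <- TRUE
      while (ks < target) {
        steps <- steps + 1L
        if (steps > max_steps) {
          warning("pair ", i, ": target Ks ", signif(target, 3),
                  " beyond synonymous saturation; regenerating")
          ok <- FALSE
          break
        }
        j <- sample.int(n_codons, 1)
        if (stats::runif(1) < 0.5) {
          opts <- nb[[ia[j]]]
          if (length(opts) == 0) next
          ia[j] <- opts[sample.int(length(opts), 1)]
        } else {
          opts <- nb[[ib[j]]]
          if (length(opts) == 0) next
          ib[j] <- opts[sample.int(length(opts), 1)]
        }
        ks <- ng86_from_indices(ia, ib, tb)
        if (is.na(ks)) { ks <- Inf }   # saturated past target
      }
      if (ok) {
        realized <- ng86_from_indices(ia, ib, tb)
        pairs[[i]] <- c(paste(tb$codons[ia], collapse = ""),
                        paste(tb$codons[ib], collapse = ""))
        truth$target_ks[i] <- target
        truth$realized_ks[i] <- realized
        break
      }
    }
  }
  fasta <- unlist(lapply(seq_len(n_pairs), function(i) {
    stats::setNames(pairs[[i]],
                    paste0(truth$pair_id[i], c("_a", "_b")))
  }))
  list(pairs = pairs, fasta = fasta, truth = truth)
}

#' Simulate diploid genotypes under partial selfing
#'
#' Per site with derived-allele frequency `p`, genotypes are drawn with
#' `P(hom-ref) = (1-p)^2 + F p (1-p)`, `P(het) = 2 p (1-p) (1-F)`,
#' `P(hom-alt) = p^2 + F p (1-p)` — the inbreeding-equilibrium genotype
#' frequencies at inbreeding coefficient `F_true`.
#'
#' @param n_ind Number of individuals.
#' @param n_sites Number of biallelic sites.
#' @param freq_sampler Function `n -> n` allele frequencies in (0, 1).
#' @param F_true Inbreeding coefficient in `[0, 1]`.
#' @param chrom_length Chromosome length in bp over which sites are
#'   placed (default `100 * n_sites`).
#' @param mean_depth Mean simulated read depth (default 20).
#' @param seed Integer seed.
#' @return List: `table` (a `genotype_table`), `truth` (list `F_true`,
#'   `allele_freqs`, `chrom_length`).
#' @export
simulate_selfing_genotypes <- function(n_ind = 30, n_sites = 50000,
                                       freq_sampler = function(n)
                                         stats::runif(n, 0.05, 0.95),
                                       F_true = 0, chrom_length = NULL,
                                       mean_depth = 20, seed = 1) {
  stopifnot(F_true >= 0, F_true <= 1)
  set.seed(seed)
  if (is.null(chrom_length)) chrom_length <- 100 * n_sites
  p <- freq_sampler(n_sites)
  stopifnot(all(p > 0), all(p < 1))
  p0 <- (1 - p)^2 + F_true * p * (1 - p)
  p1 <- 2 * p * (1 - p) * (1 - F_true)
  u <- matrix(stats::runif(n_sites * n_ind), n_sites, n_ind)
  gt <- (u > p0) + (u > p0 + p1)
  storage.mode(gt) <- "integer"
  pos <- sort(sample.int(chrom_length, n_sites))
  inds <- sprintf("ind%02d", seq_len(n_ind))
  colnames(gt) <- inds
  sites <- data.frame(chrom = "chr1", pos = pos,
                      ref = "A", alt = "T", qual = 100,
                      multiallelic = FALSE, stringsAsFactors = FALSE)
  dp <- matrix(stats::rpois(n_sites * n_ind, mean_depth), n_sites, n_ind)
  gq <- matrix(99, n_sites, n_ind)
  tab <- genotype_table(inds, sites, gt, dp, gq)
  list(table = tab,
       truth = list(F_true = F_true, allele_freqs = p,
                    chrom_length = chrom_length))
}

#' Simulate a k-mer depth histogram
#'
#' Genomic k-mers receive Poisson depths around the mean coverage; error
#' k-mers (a chosen fraction of all distinct k-mers) sit at depth 1-2,
#' forming the low-depth tail real surveys show.
#'
#' @param genome_size Number of distinct genomic k-mers (~ genome bp).
#' @param coverage Mean sequencing depth (>= 5).
#' @param error_kmer_fraction Fraction of distinct k-mers that are errors.
#' @param k k-mer length recorded on the histogram.
#' @param seed Integer seed.
#' @return A `kmer_histogram`.
#' @export
simulate_kmer_histogram <- function(genome_size = 1e6, coverage = 20,
                                    error_kmer_fraction = 0.1, k = 17L,
                                    seed = 1) {
  if (coverage < 5) stop("coverage must be >= 5")
  stopifnot(error_kmer_fraction >= 0, error_kmer_fraction < 1)
  set.seed(seed)
  depths <- stats::rpois(genome_size, coverage)
  depths <- depths[depths > 0]
  n_err <- round(genome_size * error_kmer_fraction /
                   (1 - error_kmer_fraction))
  if (n_err > 0) {
    err_depths <- sample(1:2, n_err, replace = TRUE, prob = c(0.8, 0.2))
    depths <- c(depths, err_depths)
  }
  tab <- tabulate(depths)
  keep <- which(tab > 0)
  kmer_histogram(depth = keep, count = tab[keep], k = k)
}

#' Simulate gene-order anchors with planted collinear blocks
#'
#' Planted blocks are strictly monotone runs of anchors (collinear gene
#' pairs); noise anchors are uniform over the rank grid. Blocks must not
#' overlap in either genome.
#'
#' @param n_genes Genes per genome (rank space `0..n_genes-1`).
#' @param planted_blocks List of lists with `start_a`, `start_b`,
#'   `length`, and optional `orientation` ("same"/"inverted").
#' @param noise_anchors Number of uniform noise anchors.
#' @param seed Integer seed.
#' @return List: `anchors` (data frame rank_a, rank_b, pair_id, shuffled),
#'   `truth` (list of planted blocks with their anchor ranks).
#' @export
simulate_gene_orders <- function(n_genes, planted_blocks,
                                 noise_anchors = 0, seed = 1) {
  set.seed(seed)
  used_a <- integer(0); used_b <- integer(0)
  anchors <- list(); truth <- list()
  for (bi in seq_along(planted_blocks)) {
    b <- planted_blocks[[bi]]
    ori <- if (is.null(b$orientation)) "same" else b$orientation
    ra <- b$start_a + 0:(b$length - 1)
    rb <- if (ori == "same") b$start_b + 0:(b$length - 1) else
      b$start_b - 0:(b$length - 1)
    if (any(ra >= n_genes) || any(rb >= n_genes) || any(rb < 0)) {
      stop("planted block ", bi, " exceeds the rank grid")
    }
    if (any(ra %in% used_a) || any(rb %in% used_b)) {
      stop("planted blocks overlap in one genome")
    }
    used_a <- c(used_a, ra); used_b <- c(used_b, rb)
    anchors[[bi]] <- data.frame(
      rank_a = ra, rank_b = rb,
      pair_id = sprintf("blk%d_%02d", bi, seq_along(ra)),
      stringsAsFactors = FALSE)
    truth[[bi]] <- list(rank_a = ra, rank_b = rb, orientation = ori)
  }
  anchors <- do.call(rbind, anchors)
  if (noise_anchors > 0) {
    seen <- paste(anchors$rank_a, anchors$rank_b)
    noise <- data.frame(rank_a = integer(0), rank_b = integer(0))
    while (nrow(noise) < noise_anchors) {
      cand <- data.frame(
        rank_a = sample.int(n_genes, noise_anchors, replace = TRUE) - 1L,
        rank_b = sample.int(n_genes, noise_anchors, replace = TRUE) - 1L)
      cand <- cand[!paste(cand$rank_a, cand$rank_b) %in% seen, ,
                   drop = FALSE]
      cand <- cand[!duplicated(paste(cand$rank_a, cand$rank_b)), ,
                   drop = FALSE]
      take <- head(cand, noise_anchors - nrow(noise))
      noise <- rbind(noise, take)
      seen <- c(seen, paste(take$rank_a, take$rank_b))
    }
    noise$pair_id <- sprintf("noise%03d", seq_len(nrow(noise)))
    anchors <- rbind(anchors, noise)
  }
  anchors <- anchors[sample.int(nrow(anchors)), , drop = FALSE]
  rownames(anchors) <- NULL
  list(anchors = anchors, truth = truth)
}
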