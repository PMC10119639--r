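# Collinear (syntenic) block chaining over gene-order anchors, tandem-pair
# screening, block median Ks and syntenic depth ratios.

#' Remove tandem duplicate pairs
#'
#' A pair is tandem iff both genes lie on the same chromosome within a
#' small gene-rank distance; such pairs reflect local duplication, not
#' whole-genome events, and are dropped before Ks analysis.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param positions Data frame with columns `gene`, `chrom`, `rank`
#'   (0-based gene order index along the chromosome).
#' @param max_rank_gap Rank distance at or below which a same-chromosome
#'   pair counts as tandem (default 5).
#' @return The non-tandem subset of `pairs`.
#' @export
remove_tandem_pairs <- function(pairs, positions, max_rank_gap = 5) {
  pos <- positions[match(pairs$gene_a, positions$gene), ]
  pos_b <- positions[match(pairs$gene_b, positions$gene), ]
  if (anyNA(pos$gene) || anyNA(pos_b$gene)) {
    stop("gene position missing for some pair members")
  }
  tandem <- pos$chrom == pos_b$chrom &
    abs(pos$rank - pos_b$rank) <= max_rank_gap
  pairs[!tandem, , drop = FALSE]
}

# longest chain strictly increasing in rank_a, monotone in rank_b
# (direction +1/-1), consecutive anchors within max_rank_gap on both axes.
# O(n^2) DP; deterministic tie-break: earlier predecessor index wins.
best_chain_dp <- function(ra, rb, direction, max_rank_gap) {
  n <- length(ra)
  o <- order(ra, rb * direction)
  ra <- ra[o]; rb <- rb[o]
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- (rb[i] - rb[j]) * direction
      if (da >= 1 && da <= max_rank_gap && db >= 1 && db <= max_rank_gap) {
        if (len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
  }
  end <- which.max(len)
  chain <- integer(0)
  k <- end
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- prev[k]
  }
  list(length = len[end], members = o[chain])
}

#' Longest collinear chain among anchors
#'
#' One dynamic-programming pass per orientation; returns the single best
#' chain (the first chain [find_collinear_blocks()] would extract).
#'
#' @param anchors Data frame with `rank_a`, `rank_b`.
#' @param max_rank_gap Maximum rank gap between consecutive anchors.
#' @return List: `length`, `members` (row indices into `anchors`, in chain
#'   order), `orientation`.
#' @export
longest_collinear_chain <- function(anchors, max_rank_gap = 25) {
  fwd <- best_chain_dp(anchors$rank_a, anchors$rank_b, +1L, max_rank_gap)
  rev <- best_chain_dp(anchors$rank_a, anchors$rank_b, -1L, max_rank_gap)
  if (fwd$length >= rev$length) {
    list(length = fwd$length, members = fwd$members, orientation = "same")
  } else {
    list(length = rev$length, members = rev$members,
         orientation = "inverted")
  }
}

#' Chain anchors into collinear blocks
#'
#' Blocks are maximal chains of anchors, strictly increasing in `rank_a`
#' and strictly monotone in `rank_b` (same or inverted orientation), with
#' consecutive anchors within `max_rank_gap` on both axes. Blocks are
#' extracted greedily: the longest chain is found by dynamic programming,
#' removed, and the search repeated until no chain reaches `min_anchors`.
#' Each anchor belongs to at most one block.
#'
#' @param anchors Data frame with columns `rank_a`, `rank_b` (0-based gene
#'   order indices) and optionally `pair_id`.
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors on
#'   either axis (default 25).
#' @return List of blocks; each a list with `anchors` (data frame rows in
#'   chain order), `orientation` ("same"/"inverted") and `n_anchors`.
#' @export
find_collinear_blocks <- function(anchors, min_anchors = 5,
                                  max_rank_gap = 25) {
  anchors <- unique(anchors)
  if (is.null(anchors$pair_id)) {
    anchors$pair_id <- paste0("anchor", seq_len(nrow(anchors)))
  }
  remaining <- anchors
  blocks <- list()
  while (nrow(remaining) > 0) {
    best <- longest_collinear_chain(remaining, max_rank_gap)
    if (best$length < min_anchors) break
    blocks[[length(blocks) + 1L]] <- list(
      anchors = remaining[best$members, , drop = FALSE],
      orientation = best$orientation,
      n_anchors = best$length
    )
    remaining <- remaining[-best$members, , drop = FALSE]
  }
  blocks
}

#' Median Ks of a collinear block
#'
#' Saturated anchors are excluded; with an even count the mean of the two
#' middle values is taken.
#'
#' @param block A block from [find_collinear_blocks()].
#' @param ks_map Named numeric vector mapping `pair_id` to Ks (`NA` =
#'   saturated).
#' @return The median Ks, or `NA` (block undatable) if every anchor is
#'   saturated.
#' @export
block_median_ks <- function(block, ks_map) {
  ks <- ks_map[block$anchors$pair_id]
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0) return(NA_real_)
  stats::median(ks)
}

#' Syntenic depth ratio between two genomes
#'
#' Each gene's depth is the number of collinear blocks whose rank span on
#' that genome covers it; the reported ratio is the modal nonzero depth in
#' genome A against the modal nonzero depth in genome B.
#'
#' @param blocks Blocks from [find_collinear_blocks()].
#' @param n_genes_a,n_genes_b Gene counts of the two genomes.
#' @return List: `ratio` (e.g. "2:1"), `depth_a`, `depth_b` (per-gene
#'   depth vectors).
#' @export
syntenic_depth_ratio <- function(blocks, n_genes_a, n_genes_b) {
  if (length(blocks) == 0) stop("no collinear blocks: depth ratio undefined")
  depth_a <- integer(n_genes_a)
  depth_b <- integer(n_genes_b)
  for (b in blocks) {
    ra <- range(b$anchors$rank_a)
    rb <- range(b$anchors$rank_b)
    ia <- (ra[1]:ra[2]) + 1L
    ib <- (rb[1]:rb[2]) + 1L
    depth_a[ia] <- depth_a[ia] + 1L
    depth_b[ib] <- depth_b[ib] + 1L
  }
  modal <- function(d) {
    d <- d[d > 0]
    if (length(d) == 0) stop("no covered genes: depth ratio undefined")
    tab <- table(d)
    as.integer(names(tab)[which.max(tab)])
  }
  ma <- modal(depth_a); mb <- modal(depth_b)
  list(ratio = paste0(ma, ":", mb), depth_a = depth_a, depth_b = depth_b)
}
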