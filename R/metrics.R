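# distances between aligned C1' partners under the alignment's superposition
.pair_dists <- function(aln, A, B) {
  xa <- sweep(.c1(A, aln$pairs[, 1]) %*% t(aln$sup$rotation), 2,
              aln$sup$translation, "+")
  xb <- .c1(B, aln$pairs[, 2])
  sqrt(rowSums((xa - xb)^2))
}

#' Aligned Connected Structures of an alignment
#'
#' An ACS is a connected component of the graph on aligned nucleotide pairs
#' in which two pairs are linked when they are within `acs_gap` sequence
#' positions of each other, or base-paired to each other, in either
#' structure. For each component the number of member pairs whose
#' post-superposition C1' distance is at most `metric_dist` (`n_within`) and
#' the number of conserved aligned base pairs with both partners within
#' `metric_dist` (`bp_within`) are reported.
#'
#' @param aln a `circstar_alignment`.
#' @param A,B the structures.
#' @param pairs_a,pairs_b base-pair data frames of the two structures
#'   (canonical pairs are used).
#' @param params `circstar_params`.
#' @return list of ACS records sorted by size (descending):
#'   `list(members, n_within, bp_within)` where `members` indexes rows of
#'   `aln$pairs`.
#' @export
find_acs <- function(aln, A, B, pairs_a, pairs_b,
                     params = circstar_params()) {
  m <- nrow(aln$pairs)
  if (m == 0L) return(list())
  a <- aln$pairs[, 1]; b <- aln$pairs[, 2]
  pa <- pairs_a[pairs_a$canonical, , drop = FALSE]
  pb <- pairs_b[pairs_b$canonical, , drop = FALSE]
  bp_a <- paste(pa$i, pa$j); bp_b <- paste(pb$i, pb$j)
  # union-find over aligned pairs
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[min(rx, ry)] <<- parent[max(rx, ry)] <<- min(rx, ry)
  }
  conserved <- logical(m)                 # pair k base-paired to some pair l
  bp_partner <- rep(NA_integer_, m)
  for (k in seq_len(m - 1L)) {
    for (l in (k + 1L):m) {
      near <- abs(a[k] - a[l]) <= params$acs_gap ||
        abs(b[k] - b[l]) <= params$acs_gap
      bp <- paste(min(a[k], a[l]), max(a[k], a[l])) %in% bp_a ||
        paste(min(b[k], b[l]), max(b[k], b[l])) %in% bp_b
      if (near || bp) union_(k, l)
      cons <- paste(min(a[k], a[l]), max(a[k], a[l])) %in% bp_a &&
        paste(min(b[k], b[l]), max(b[k], b[l])) %in% bp_b
      if (cons) { bp_partner[k] <- l; bp_partner[l] <- k }
    }
  }
  within <- .pair_dists(aln, A, B) <= params$metric_dist
  roots <- vapply(seq_len(m), find, integer(1))
  comps <- split(seq_len(m), roots)
  acs <- lapply(comps, function(idx) {
    bp_ok <- 0L
    for (k in idx) {
      l <- bp_partner[k]
      if (!is.na(l) && l > k && within[k] && within[l]) bp_ok <- bp_ok + 1L
    }
    list(members = idx, n_within = sum(within[idx]), bp_within = bp_ok)
  })
  acs[order(-vapply(acs, function(x) length(x$members), integer(1)),
            -vapply(acs, `[[`, integer(1), "n_within"))]
}

.largest_acs <- function(aln, A, B, pairs_a, pairs_b, params) {
  acs <- find_acs(aln, A, B, pairs_a, pairs_b, params)
  if (length(acs) == 0L) NULL else acs[[1]]
}

#' Percentage of Connected Structural Identity (PCSI)
#'
#' Fraction of aligned nucleotides within `metric_dist` (4 Angstrom) in the
#' largest ACS, relative to the length of the shorter sequence.
#'
#' @inheritParams find_acs
#' @return value in `[0, 1]`; 0 for an empty alignment.
#' @export
pcsi <- function(aln, A, B, pairs_a, pairs_b, params = circstar_params()) {
  top <- .largest_acs(aln, A, B, pairs_a, pairs_b, params)
  if (is.null(top)) return(0)
  top$n_within / min(A$n, B$n)
}

#' Percentage of aligned Connected Secondary Structure (PCSS)
#'
#' Fraction of aligned base pairs within `metric_dist` in the largest ACS,
#' relative to the smaller canonical base-pair count of the two structures.
#' A base pair counts when the pairing exists between the corresponding
#' aligned partners in both structures and both partner distances are within
#' threshold.
#'
#' @inheritParams find_acs
#' @return value in `[0, 1]`, or `NA` when a structure has no canonical
#'   pairs.
#' @export
pcss <- function(aln, A, B, pairs_a, pairs_b, params = circstar_params()) {
  denom <- min(sum(pairs_a$canonical), sum(pairs_b$canonical))
  if (denom == 0L) return(NA_real_)
  top <- .largest_acs(aln, A, B, pairs_a, pairs_b, params)
  if (is.null(top)) return(0)
  top$bp_within / denom
}
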