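# positions of a circular gap, 0-based, in circular 5'->3' order
.gap_positions <- function(gap, n) {
  if (gap$len == 0L) return(integer(0))
  (gap$start + 0:(gap$len - 1L)) %% n
}

#' Build the circular consensus of a compatible stack-pair set
#'
#' Traverses the circular interval labeling once, emitting the corresponding
#' loop-interval pairs between consecutive stack strands. Across the rotation
#' seam, an interval of structure A may map to an interval of B spanning B's
#' 3'/5' junction, in which case B's 3'-end material is aligned before its
#' 5'-end material (the interval is traversed in circular order).
#'
#' @param members list of stack pairs (a compatible set), or a compatible-set
#'   object from [extend_seed()].
#' @param n_a,n_b chain lengths.
#' @return list of entries `list(a, b, seam_a, seam_b)` where `a`, `b` are
#'   circular intervals `list(start, len)` and the seam flags mark intervals
#'   crossing the respective 3'/5' junction.
#' @export
build_circular_consensus <- function(members, n_a, n_b) {
  if (!is.null(members$members)) members <- members$members
  lab <- label_intervals(members, n_a, n_b)
  lapply(seq_along(lab$gaps_a), function(k) {
    ga <- lab$gaps_a[[k]]; gb <- lab$gaps_b[[lab$a2b[k]]]
    list(a = ga, b = gb,
         seam_a = ga$start + ga$len > n_a,
         seam_b = gb$start + gb$len > n_b)
  })
}

#' Align two loop intervals under a fixed superposition
#'
#' Order-preserving (global within the interval) dynamic-programming alignment
#' of two nucleotide position lists, scored purely structurally: a match
#' contributes `max(0, 1 - d / metric_dist)` where `d` is the Euclidean C1'
#' distance after applying the guiding superposition, and each gapped position
#' costs `gap_weight`. Matched pairs further apart than `metric_dist` are
#' discarded after traceback and counted as a deletion plus an insertion.
#'
#' @param pos_a,pos_b 0-based nucleotide positions (B taken in circular
#'   order when the interval crosses the seam).
#' @param sup guiding superposition (of A onto B), e.g. the compatible set's
#'   joint superposition.
#' @param A,B the structures.
#' @param params `circstar_params`.
#' @return list with `pairs` (two-column matrix of aligned positions),
#'   `n_del`, `n_ins`.
#' @export
align_loop_interval <- function(pos_a, pos_b, sup, A, B,
                                params = circstar_params()) {
  na <- length(pos_a); nb <- length(pos_b)
  empty <- matrix(integer(0), 0, 2)
  if (na == 0L || nb == 0L)
    return(list(pairs = empty, n_del = na, n_ins = nb))
  xa <- sweep(.c1(A, pos_a) %*% t(sup$rotation), 2, sup$translation, "+")
  xb <- .c1(B, pos_b)
  d <- sqrt(outer(xa[, 1], xb[, 1], "-")^2 + outer(xa[, 2], xb[, 2], "-")^2 +
            outer(xa[, 3], xb[, 3], "-")^2)
  s <- matrix(pmax(0, 1 - d / params$metric_dist), na, nb)
  g <- params$gap_weight
  F <- matrix(0, na + 1L, nb + 1L)
  F[, 1] <- -g * (0:na); F[1, ] <- -g * (0:nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      F[i + 1L, j + 1L] <- max(F[i, j] + s[i, j], F[i, j + 1L] - g,
                               F[i + 1L, j] - g)
  i <- na; j <- nb; pr <- list()
  while (i > 0L && j > 0L) {
    if (F[i + 1L, j + 1L] == F[i, j] + s[i, j]) {
      pr[[length(pr) + 1L]] <- c(i, j); i <- i - 1L; j <- j - 1L
    } else if (F[i + 1L, j + 1L] == F[i, j + 1L] - g) i <- i - 1L
    else j <- j - 1L
  }
  if (length(pr) == 0L)
    return(list(pairs = empty, n_del = na, n_ins = nb))
  idx <- do.call(rbind, rev(pr))
  keep <- d[idx] <= params$metric_dist
  idx <- idx[keep, , drop = FALSE]
  list(pairs = cbind(pos_a[idx[, 1]], pos_b[idx[, 2]]),
       n_del = na - nrow(idx), n_ins = nb - nrow(idx))
}

#' Assemble a compatible stack-pair set into a circular alignment
#'
#' Concatenates the member stacks' nucleotide correspondences with the
#' dynamic-programming alignments of the loop intervals along the circular
#' consensus, recomputes the superposition over all aligned C1' pairs, and
#' drops the candidate when the final RMSD exceeds `params$rmsd_cutoff`.
#' The rotation offset reported is the position in structure A at which
#' structure B's 5' end aligns (0 for a purely direct alignment), so that
#' aligning a structure against its circular permutation at pivot `p`
#' recovers `p`.
#'
#' @param cset a compatible set from [extend_seed()] (or a plain member
#'   list).
#' @param A,B the structures.
#' @param params `circstar_params`.
#' @param scheme atom scheme.
#' @return a `circstar_alignment` object, or `NULL` when the candidate fails
#'   the RMSD filter.
#' @export
assemble <- function(cset, A, B, params = circstar_params(),
                     scheme = "c1_prime") {
  members <- if (!is.null(cset$members)) cset$members else cset
  sup0 <- .combined_sup(members, A, B, scheme)
  consensus <- build_circular_consensus(members, A$n, B$n)
  pairs <- .members_corr(members)
  n_del_loops <- 0L; n_ins_loops <- 0L
  for (entry in consensus) {
    pa <- .gap_positions(entry$a, A$n)
    pb <- .gap_positions(entry$b, B$n)
    if (length(pa) == 0L && length(pb) == 0L) next
    al <- align_loop_interval(pa, pb, sup0, A, B, params)
    if (nrow(al$pairs)) pairs <- rbind(pairs, al$pairs)
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  sup <- superpose(.c1(A, pairs[, 1]), .c1(B, pairs[, 2]))
  if (sup$rmsd > params$rmsd_cutoff) return(NULL)
  n_aligned <- nrow(pairs)
  n_deleted <- A$n - n_aligned
  n_inserted <- B$n - n_aligned
  b <- pairs[, 2]
  wraps <- which(diff(b) < 0)
  rotation_offset <- if (length(wraps) == 0L) 0L
                     else pairs[wraps[1] + 1L, 1]
  structure(list(pairs = pairs, n_aligned = n_aligned,
                 n_deleted = n_deleted, n_inserted = n_inserted,
                 rotation_offset = as.integer(rotation_offset),
                 sup = sup, rmsd = sup$rmsd,
                 score = score_alignment(n_aligned, n_deleted, n_inserted,
                                         params),
                 members = members,
                 a_id = A$structure_id, b_id = B$structure_id,
                 n_a = A$n, n_b = B$n),
            class = "circstar_alignment")
}

#' Alignment score
#'
#' `score = n_aligned - gap_weight * (n_deleted + n_inserted)`; the gap
#' weight defaults to 0.5 and is recorded in all output headers so scores
#' remain interpretable.
#'
#' @param n_aligned,n_deleted,n_inserted non-negative counts.
#' @param params `circstar_params`.
#' @return numeric score.
#' @export
score_alignment <- function(n_aligned, n_deleted, n_inserted,
                            params = circstar_params()) {
  stopifnot(n_aligned >= 0, n_deleted >= 0, n_inserted >= 0)
  n_aligned - params$gap_weight * (n_deleted + n_inserted)
}

#' Rank alignments and collapse near-duplicates
#'
#' Descending score, ties broken by ascending RMSD, then by (A start, B
#' start) for determinism. Alignments sharing at least 90% of their aligned
#' pairs with a better-ranked alignment are collapsed onto it.
#'
#' @param alignments list of `circstar_alignment` objects.
#' @param overlap_collapse share of common pairs above which two alignments
#'   are considered duplicates (default 0.9).
#' @return sorted, deduplicated list.
#' @export
rank_alignments <- function(alignments, overlap_collapse = 0.9) {
  if (length(alignments) <= 1L) return(alignments)
  o <- order(-vapply(alignments, `[[`, numeric(1), "score"),
             vapply(alignments, `[[`, numeric(1), "rmsd"),
             vapply(alignments, function(x) x$pairs[1, 1], numeric(1)),
             vapply(alignments, function(x) x$pairs[1, 2], numeric(1)))
  alignments <- alignments[o]
  keys <- lapply(alignments, function(x)
    paste(x$pairs[, 1], x$pairs[, 2], sep = "-"))
  keep <- rep(TRUE, length(alignments))
  for (k in seq_along(alignments)[-1]) {
    for (l in seq_len(k - 1L)) {
      if (!keep[l]) next
      shared <- length(intersect(keys[[k]], keys[[l]])) /
        min(length(keys[[k]]), length(keys[[l]]))
      if (shared >= overlap_collapse) { keep[k] <- FALSE; break }
    }
  }
  alignments[keep]
}
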