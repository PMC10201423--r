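#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' equally sized point sets, by singular value decomposition of the
#' cross-covariance matrix with the usual determinant correction so that no
#' reflection is returned.
#'
#' @param source,target numeric matrices with 3 columns and equal row counts;
#'   row k of `source` corresponds to row k of `target`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `source %*% t(rotation) + translation` best fits `target`, `rmsd`
#'   in Angstrom, and `unique` (FALSE when fewer than 3 points or the points
#'   are degenerate, in which case the rotation is not uniquely determined
#'   although the rmsd is still valid).
#' @export
superpose <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("point counts differ (", nrow(source), " vs ", nrow(target), ")")
  n <- nrow(source)
  if (n == 0L) stop("cannot superpose empty point sets")
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  A <- sweep(source, 2, mu_s); B <- sweep(target, 2, mu_t)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  resid <- A %*% t(R) - B
  rmsd <- sqrt(sum(resid^2) / n)
  uniq <- n >= 3L && sv$d[2] > 1e-8 && (sv$d[2] + d * sv$d[3]) > 1e-8
  list(rotation = R, translation = as.numeric(mu_t - R %*% mu_s),
       rmsd = rmsd, unique = uniq)
}

# ---- stack primitives -------------------------------------------------------

# a stack is (i, j, L): pairs (i+t, j-t) for t = 0..L-1
.stack <- function(i, j, L) list(i = as.integer(i), j = as.integer(j),
                                 L = as.integer(L))

# the two strand intervals, half-open, rows = (5' strand, 3' strand)
.stack_strands <- function(s)
  rbind(c(s$i, s$i + s$L), c(s$j - s$L + 1L, s$j + 1L))

# does the stack contain base pair (pi, pj)?
.stack_has_pair <- function(s, pi, pj) {
  t <- pi - s$i
  t >= 0L && t < s$L && (s$j - t) == pj
}

#' Enumerate maximal stacks
#'
#' A stack is a run of consecutive nested base pairs `(i+t, j-t)`. Maximal
#' runs are extracted from the nested pairs and, separately, from
#' mutually-nested runs within the crossing (pseudoknot-candidate) pairs;
#' runs shorter than `min_stack_len` are discarded. Shorter sub-stacks are
#' derived lazily during conserved-stack-pair enumeration.
#'
#' @param ss `secondary_structure`.
#' @param params `circstar_params`.
#' @return list of stacks, each `list(i, j, L)`.
#' @export
find_stacks <- function(ss, params = circstar_params()) {
  runs_of <- function(pr) {
    if (nrow(pr) == 0L) return(list())
    pr <- pr[order(pr$i), , drop = FALSE]
    out <- list(); s <- 1L
    for (k in seq_len(nrow(pr))) {
      nxt <- k + 1L
      extend <- nxt <= nrow(pr) && pr$i[nxt] == pr$i[k] + 1L &&
        pr$j[nxt] == pr$j[k] - 1L
      if (!extend) {
        L <- k - s + 1L
        out[[length(out) + 1L]] <- .stack(pr$i[s], pr$j[s], L)
        s <- nxt
      }
    }
    out
  }
  st <- c(runs_of(ss$nested), runs_of(ss$crossing))
  Filter(function(s) s$L >= params$min_stack_len, st)
}

#' Stacks containing a loop's closing pairs
#'
#' @param loop a loop from [extract_loops()].
#' @param stacks stacks from [find_stacks()] for the same structure.
#' @return the stacks containing at least one closing pair of the loop.
#' @export
stacks_closing_loop <- function(loop, stacks) {
  Filter(function(s) {
    any(vapply(seq_len(nrow(loop$closing)), function(k)
      .stack_has_pair(s, loop$closing$i[k], loop$closing$j[k]), logical(1)))
  }, stacks)
}

# nucleotide correspondence implied by a (window_a, window_b, orientation)
# match; columns = (index in A, index in B), ordered 5' strand of A first.
# direct: pair t of A matches pair t of B, strand roles preserved;
# rotated: pair t of A matches pair L-1-t of B, strand roles exchanged.
.stack_pair_corr <- function(wa, wb, orientation) {
  L <- wa$L
  t <- 0:(L - 1L)
  if (orientation == "direct")
    rbind(cbind(wa$i + t, wb$i + t),
          cbind(wa$j - L + 1L + t, wb$j - L + 1L + t))
  else
    rbind(cbind(wa$i + t, wb$j - L + 1L + t),
          cbind(wa$j - L + 1L + t, wb$i + t))
}

.stack_pair <- function(wa, wb, orientation, sup, corr) {
  list(a = wa, b = wb, orientation = orientation, corr = corr, sup = sup,
       key = paste0(orientation, ":", paste(corr[, 1], corr[, 2],
                                            sep = "-", collapse = ",")))
}

# equal-length window placements of a stack: offsets 0..L-len
.windows <- function(s, len) {
  lapply(0:(s$L - len), function(o) .stack(s$i + o, s$j - o, len))
}

# does the window contain any pair from the closing-pair table?
.window_has_closing <- function(w, closing) {
  if (is.null(closing) || nrow(closing) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(closing)), function(k)
    .stack_has_pair(w, closing$i[k], closing$j[k]), logical(1)))
}

#' Enumerate conserved stack pairs
#'
#' For every pair of maximal stacks from the two structures, both orientations
#' (direct and strand-exchanged rotated) are tried over equal-length window
#' alignments: full-length windows of the shorter stack slid over the longer,
#' plus shorter windows down to `min_stack_len` that contain a loop-closing
#' base pair in at least one structure (the closing-pair restriction keeps the
#' sub-stack enumeration tractable; pass `exhaustive = TRUE` to lift it).
#' A window pair is retained when the C1' superposition RMSD over its implied
#' nucleotide correspondence is at most `params$rmsd_cutoff`. Identical
#' correspondences are deduplicated.
#'
#' @param stacks_a,stacks_b maximal stacks of the two structures.
#' @param A,B the two `rna_structure` objects.
#' @param params `circstar_params`.
#' @param closing_a,closing_b optional base-pair data frames of loop-closing
#'   pairs (from [extract_loops()]) steering the sub-window restriction.
#' @param exhaustive enumerate all sub-windows regardless of closing pairs.
#' @param scheme atom scheme for the superposition (default C1').
#' @return list of stack pairs, each with fields `a`, `b` (windows),
#'   `orientation`, `corr` (two-column 0-based index matrix), `sup`
#'   (superposition of A onto B), `key`.
#' @export
enumerate_conserved_stack_pairs <- function(stacks_a, stacks_b, A, B,
                                            params = circstar_params(),
                                            closing_a = NULL,
                                            closing_b = NULL,
                                            exhaustive = FALSE,
                                            scheme = "c1_prime") {
  out <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
  for (sa in stacks_a) {
    for (sb in stacks_b) {
      Lmax <- min(sa$L, sb$L)
      if (Lmax < params$min_stack_len) next
      for (len in Lmax:params$min_stack_len) {
        restrict <- len < Lmax && !exhaustive &&
          !(is.null(closing_a) && is.null(closing_b))
        for (wa in .windows(sa, len)) {
          wa_cl <- .window_has_closing(wa, closing_a)
          if (restrict && !wa_cl) next
          for (wb in .windows(sb, len)) {
            if (restrict && !.window_has_closing(wb, closing_b)) next
            for (orientation in c("direct", "rotated")) {
              corr <- .stack_pair_corr(wa, wb, orientation)
              sp <- .make_checked_pair(wa, wb, orientation, corr, A, B,
                                       params, scheme)
              if (is.null(sp) ||
                  exists(sp$key, envir = seen, inherits = FALSE)) next
              assign(sp$key, TRUE, envir = seen)
              out[[length(out) + 1L]] <- sp
            }
          }
        }
      }
    }
  }
  out
}

# drop stack pairs whose correspondence is contained in another pair's
# correspondence of the same orientation; sub-windows of a retained window
# contribute nothing to compatible-set growth and only multiply the search
.prune_subwindow_pairs <- function(sps) {
  if (length(sps) <= 1L) return(sps)
  keys <- lapply(sps, function(p) paste(p$corr[, 1], p$corr[, 2]))
  orient <- vapply(sps, `[[`, character(1), "orientation")
  sizes <- lengths(keys)
  o <- order(-sizes)
  keep_idx <- integer(0)
  for (k in o) {
    sub <- FALSE
    for (l in keep_idx) {
      if (orient[l] == orient[k] && sizes[l] > sizes[k] &&
          all(keys[[k]] %in% keys[[l]])) { sub <- TRUE; break }
    }
    if (!sub) keep_idx <- c(keep_idx, k)
  }
  sps[sort(keep_idx)]
}

.make_checked_pair <- function(wa, wb, orientation, corr, A, B, params,
                               scheme) {
  pa <- representative_coords(A, corr[, 1], scheme)
  pb <- representative_coords(B, corr[, 2], scheme)
  if (nrow(pa) != nrow(pb) || nrow(pa) == 0L) return(NULL)
  sup <- superpose(pa, pb)
  if (sup$rmsd > params$rmsd_cutoff) return(NULL)
  .stack_pair(wa, wb, orientation, sup, corr)
}
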