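# ---- circular interval labeling --------------------------------------------

# strand table for a set of stack pairs: one row per strand, columns
# member, side (1 = 5' strand, 2 = 3' strand), s, e (half-open interval)
.strand_table <- function(members, side_of) {
  m <- length(members)
  out <- matrix(0L, 2L * m, 4,
                dimnames = list(NULL, c("member", "side", "s", "e")))
  for (k in seq_len(m)) {
    st <- .stack_strands(side_of(members[[k]]))
    out[2L * k - 1L, ] <- c(k, 1L, st[1, 1], st[1, 2])
    out[2L * k, ] <- c(k, 2L, st[2, 1], st[2, 2])
  }
  out
}

# B-side strand (member, side) corresponding to A-side strand (member, side);
# strand correspondences preserve within-strand 5'->3' direction in both
# orientations, so only the side may flip
.b_side <- function(member_obj, a_side) {
  if (member_obj$orientation == "direct") a_side else 3L - a_side
}

#' Label the circular intervals induced by a compatible stack-pair set
#'
#' The strands of the member stacks cut each RNA's backbone circle (5' and 3'
#' ends adjacent) into circularly ordered intervals; corresponding intervals
#' receive the same label through the strand correspondences. The labeling
#' exists only when the two cyclic strand orders agree under the
#' correspondence; otherwise the set is topologically inconsistent and an
#' error is raised.
#'
#' @param members list of stack pairs (mutually compatible).
#' @param n_a,n_b chain lengths of the two structures.
#' @return list with sorted strand tables (`sa`, `sb`), circular gap lists
#'   (`gaps_a`, `gaps_b`; each gap is `list(start, len)` on the circle) and
#'   the label bijection `a2b`/`b2a` (gap index maps).
#' @export
label_intervals <- function(members, n_a, n_b) {
  if (length(members) == 0L)
    return(list(sa = NULL, sb = NULL,
                gaps_a = list(list(start = 0L, len = as.integer(n_a))),
                gaps_b = list(list(start = 0L, len = as.integer(n_b))),
                a2b = 1L, b2a = 1L))
  sa <- .strand_table(members, function(m) m$a)
  sb <- .strand_table(members, function(m) m$b)
  check_disjoint <- function(tab, n, what) {
    if (min(tab[, "s"]) < 0 || max(tab[, "e"]) > n)
      stop("strand outside chain in ", what)
    tab <- tab[order(tab[, "s"]), , drop = FALSE]
    if (nrow(tab) > 1L &&
        any(tab[-nrow(tab), "e"] > tab[-1, "s"]))
      stop("overlapping stack strands in ", what)
    tab
  }
  sa <- check_disjoint(sa, n_a, "structure A")
  sb <- check_disjoint(sb, n_b, "structure B")
  m <- nrow(sa)
  # position in sb of the B strand corresponding to each sorted A strand
  img <- vapply(seq_len(m), function(k) {
    mb <- members[[sa[k, "member"]]]
    side_b <- .b_side(mb, sa[k, "side"])
    which(sb[, "member"] == sa[k, "member"] & sb[, "side"] == side_b)
  }, integer(1))
  nxt <- function(k, mm) if (k == mm) 1L else k + 1L
  for (k in seq_len(m)) {
    if (img[nxt(k, m)] != nxt(img[k], m))
      stop("inconsistent interval correspondence: cyclic strand orders differ")
  }
  gaps <- function(tab, n) {
    mm <- nrow(tab)
    lapply(seq_len(mm), function(k) {
      st <- tab[k, "e"] %% n
      list(start = as.integer(st),
           len = as.integer((tab[nxt(k, mm), "s"] - tab[k, "e"]) %% n))
    })
  }
  list(sa = sa, sb = sb, gaps_a = gaps(sa, n_a), gaps_b = gaps(sb, n_b),
       a2b = img, b2a = order(img))
}

# is half-open interval [s, e) entirely inside the circular gap?
.gap_contains <- function(gap, s, e, n) {
  len <- e - s
  if (len == 0L) return(TRUE)
  off <- (s - gap$start) %% n
  off + len <= gap$len
}

# index of the gap containing [s, e), or NA
.which_gap <- function(gaps, s, e, n) {
  for (k in seq_along(gaps))
    if (gaps[[k]]$len > 0L && .gap_contains(gaps[[k]], s, e, n)) return(k)
  NA_integer_
}

.strands_overlap <- function(st1, st2) {
  for (u in seq_len(nrow(st1)))
    for (v in seq_len(nrow(st2)))
      if (st1[u, 1] < st2[v, 2] && st2[v, 1] < st1[u, 2]) return(TRUE)
  FALSE
}

# membership test against a precomputed labeling (hot path of the search)
.is_compatible_lab <- function(candidate, lab, ma, mb, n_a, n_b) {
  ca <- .stack_strands(candidate$a); cb <- .stack_strands(candidate$b)
  if (.strands_overlap(ca, ma) || .strands_overlap(cb, mb)) return(FALSE)
  for (side in 1:2) {
    ga <- .which_gap(lab$gaps_a, ca[side, 1], ca[side, 2], n_a)
    side_b <- .b_side(candidate, side)
    gb <- .which_gap(lab$gaps_b, cb[side_b, 1], cb[side_b, 2], n_b)
    if (is.na(ga) || is.na(gb)) return(FALSE)
    if (lab$a2b[ga] != gb) return(FALSE)
  }
  TRUE
}

#' Circular interval compatibility of a candidate stack pair with a set
#'
#' A candidate is compatible when its strands do not overlap any member
#' stack's strands and, for each of its two strand correspondences, the
#' interval of structure A containing the A strand carries the same label as
#' the interval of structure B containing the corresponding B strand.
#' Crossed (pseudoknotted) placements that satisfy the interval test are
#' accepted.
#'
#' @param candidate a stack pair.
#' @param members current compatible set (list of stack pairs).
#' @param n_a,n_b chain lengths.
#' @return logical.
#' @export
is_compatible <- function(candidate, members, n_a, n_b) {
  ca <- .stack_strands(candidate$a); cb <- .stack_strands(candidate$b)
  if (length(members) == 0L)
    return(ca[1, 1] >= 0 && ca[2, 2] <= n_a &&
           cb[1, 1] >= 0 && cb[2, 2] <= n_b)
  lab <- tryCatch(label_intervals(members, n_a, n_b),
                  error = function(e) NULL)
  if (is.null(lab)) return(FALSE)
  ma <- .strand_table(members, function(m) m$a)
  mb <- .strand_table(members, function(m) m$b)
  .is_compatible_lab(candidate, lab, ma[, c("s", "e"), drop = FALSE],
                     mb[, c("s", "e"), drop = FALSE], n_a, n_b)
}

# ---- combined superposition -------------------------------------------------

.members_corr <- function(members) {
  corr <- do.call(rbind, lapply(members, `[[`, "corr"))
  corr[!duplicated(paste(corr[, 1], corr[, 2])), , drop = FALSE]
}

.combined_sup <- function(members, A, B, scheme = "c1_prime") {
  corr <- .members_corr(members)
  superpose(representative_coords(A, corr[, 1], scheme),
            representative_coords(B, corr[, 2], scheme))
}

#' RMSD of the joint superposition of a stack-pair set
#'
#' One Kabsch superposition over the union of all member correspondences.
#'
#' @param members list of stack pairs.
#' @param A,B the two structures.
#' @param scheme atom scheme (default C1').
#' @return RMSD in Angstrom.
#' @export
combined_rmsd <- function(members, A, B, scheme = "c1_prime") {
  .combined_sup(members, A, B, scheme)$rmsd
}

# ---- maximal compatible set enumeration ------------------------------------

# minimum sequence gap between the candidate's strands and the member strands,
# in both structures; adjacency requires both within ext_dist
.adjacent <- function(candidate, members, ext_dist) {
  gap_min <- function(cs, tab) {
    g <- Inf
    for (u in seq_len(nrow(cs)))
      for (v in seq_len(nrow(tab)))
        g <- min(g, .interval_gap(cs[u, 1], cs[u, 2], tab[v, 1], tab[v, 2]),
                 .interval_gap(tab[v, 1], tab[v, 2], cs[u, 1], cs[u, 2]))
    g
  }
  ma <- do.call(rbind, lapply(members, function(m) .stack_strands(m$a)))
  mb <- do.call(rbind, lapply(members, function(m) .stack_strands(m$b)))
  gap_min(.stack_strands(candidate$a), ma) <= ext_dist &&
    gap_min(.stack_strands(candidate$b), mb) <= ext_dist
}

# full set-level verification used by the enumerator and by tests
.set_feasible <- function(members, A, B, params, scheme = "c1_prime") {
  ok <- tryCatch({ label_intervals(members, A$n, B$n); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(FALSE)
  if (combined_rmsd(members, A, B, scheme) > params$rmsd_cutoff) return(FALSE)
  if (length(members) > 1L) {
    for (k in seq_along(members))
      if (!is_compatible(members[[k]], members[-k], A$n, B$n)) return(FALSE)
  }
  TRUE
}

# deterministic candidate order: (A start, B start, orientation)
.order_pairs <- function(pairs) {
  if (length(pairs) == 0L) return(pairs)
  o <- order(vapply(pairs, function(p) p$a$i, integer(1)),
             vapply(pairs, function(p) p$b$i, integer(1)),
             vapply(pairs, function(p) p$orientation, character(1)),
             vapply(pairs, function(p) p$a$L, integer(1)))
  pairs[o]
}

.set_key <- function(members)
  paste(sort(vapply(members, `[[`, character(1), "key")), collapse = "|")

# recursive enumeration of maximal feasible supersets of `pinned`;
# eligibility of a candidate depends on the current set (interval
# compatibility, incremental RMSD feasibility and, when requested, the
# ext_dist sequence-adjacency constraint), so candidates are re-screened at
# every level instead of using a static pivot
.enumerate_maximal <- function(pinned, candidates, A, B, params,
                               use_adjacency = TRUE, scheme = "c1_prime") {
  candidates <- .order_pairs(candidates)
  results <- list(); seen <- character(0)
  node_ctx <- function(R) {
    if (length(R) == 0L)
      return(list(lab = label_intervals(R, A$n, B$n),
                  ma = matrix(numeric(0), 0, 2), mb = matrix(numeric(0), 0, 2)))
    lab <- tryCatch(label_intervals(R, A$n, B$n), error = function(e) NULL)
    if (is.null(lab)) return(NULL)
    list(lab = lab,
         ma = do.call(rbind, lapply(R, function(m) .stack_strands(m$a))),
         mb = do.call(rbind, lapply(R, function(m) .stack_strands(m$b))))
  }
  can_add <- function(v, R, ctx) {
    if (length(R) > 0L) {
      if (use_adjacency && !.adjacent(v, R, params$ext_dist)) return(FALSE)
      if (!.is_compatible_lab(v, ctx$lab, ctx$ma, ctx$mb, A$n, B$n))
        return(FALSE)
    }
    Rv <- c(R, list(v))
    ok <- tryCatch({ label_intervals(Rv, A$n, B$n); TRUE },
                   error = function(e) FALSE)
    ok && combined_rmsd(Rv, A, B, scheme) <= params$rmsd_cutoff
  }
  recurse <- function(R, P, X) {
    ctx <- node_ctx(R)
    if (is.null(ctx)) return(invisible())
    elig <- Filter(function(v) can_add(v, R, ctx), P)
    eligX <- Filter(function(v) can_add(v, R, ctx), X)
    if (length(elig) == 0L) {
      if (length(eligX) == 0L && length(R) > 0L) {
        key <- .set_key(R)
        if (!key %in% seen) {
          seen <<- c(seen, key)
          results[[length(results) + 1L]] <<- R
        }
      }
      return(invisible())
    }
    X_loc <- X
    P_loc <- P
    for (v in elig) {
      P_loc <- Filter(function(w) !identical(w$key, v$key), P_loc)
      recurse(c(R, list(v)), P_loc, X_loc)
      X_loc <- c(X_loc, list(v))
    }
    invisible()
  }
  recurse(pinned, candidates, list())
  # drop non-maximal leftovers (possible with order-dependent feasibility)
  if (length(results) > 1L) {
    keys <- lapply(results, function(R) sort(vapply(R, `[[`, character(1),
                                                    "key")))
    keep <- vapply(seq_along(results), function(k) {
      !any(vapply(seq_along(results), function(l)
        l != k && length(keys[[l]]) > length(keys[[k]]) &&
          all(keys[[k]] %in% keys[[l]]), logical(1)))
    }, logical(1))
    results <- results[keep]
  }
  results <- Filter(function(R) .set_feasible(R, A, B, params, scheme),
                    results)
  if (length(results) == 0L) return(results)
  o <- order(-vapply(results, length, integer(1)),
             vapply(results, function(R) combined_rmsd(R, A, B, scheme),
                    numeric(1)))
  results[o]
}

#' Extend a seed loop into maximal compatible stack-pair sets
#'
#' Starting from the seed's closing stack matches (pinned: they are never
#' removed), candidate stack pairs within `ext_dist` nucleotides of the
#' current set's strand boundaries (in both structures) that pass the circular
#' interval-compatibility test and keep the joint RMSD under
#' `params$rmsd_cutoff` are added by a Bron-Kerbosch style recursive
#' enumeration with an exclusion set, yielding all maximal compatible sets.
#'
#' @param seed a matched loop pair from [select_seed_loops()].
#' @param all_pairs the full conserved stack-pair list.
#' @param A,B the two structures.
#' @param params `circstar_params`.
#' @param scheme atom scheme.
#' @return list of compatible sets sorted by member count (descending) then
#'   combined RMSD (ascending); each is `list(members, pinned_keys, sup,
#'   rmsd)`.
#' @export
extend_seed <- function(seed, all_pairs, A, B, params = circstar_params(),
                        scheme = "c1_prime") {
  pinned <- seed$closing_matches
  pk <- vapply(pinned, `[[`, character(1), "key")
  cand <- Filter(function(p) !(p$key %in% pk), all_pairs)
  sets <- .enumerate_maximal(pinned, cand, A, B, params,
                             use_adjacency = TRUE, scheme = scheme)
  lapply(sets, function(R) {
    sup <- .combined_sup(R, A, B, scheme)
    list(members = R, pinned_keys = pk, sup = sup, rmsd = sup$rmsd)
  })
}
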