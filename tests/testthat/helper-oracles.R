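# Independent oracles and fixture helpers shared across the suite.
# Every oracle here is implemented by a different route than the code it
# checks (quaternion eigenvalue vs SVD Kabsch, exhaustive enumeration vs
# recursive search, brute force vs dynamic programming).

# Horn's quaternion-eigenvalue superposition RMSD: the largest eigenvalue of
# the 4x4 key matrix gives the optimal residual in closed form.
quat_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X)); yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(xc, yc)            # S[a, b] = sum_k x_ka * y_kb
  N <- rbind(
    c(S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1]),
    c(S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3]),
    c(S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2]),
    c(S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]))
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(xc^2) + sum(yc^2) - 2 * lam) / n)
}

# brute-force maximum mutually nested subset (inputs with few pairs)
brute_max_nested <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^m - 1L)) {
    idx <- which(bitwAnd(mask, 2^(0:(m - 1L))) > 0L)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1L) {
      for (u in idx) for (v in idx) {
        if (u >= v) next
        i1 <- pairs$i[u]; j1 <- pairs$j[u]; i2 <- pairs$i[v]; j2 <- pairs$j[v]
        lo <- min(i1, i2); hi <- if (lo == i1) i2 else i1
        jlo <- if (lo == i1) j1 else j2; jhi <- if (lo == i1) j2 else j1
        # pairs (lo,jlo), (hi,jhi) with lo < hi: compatible iff jlo < hi
        # (side by side) or jhi < jlo (enclosed)
        if (!(jlo < hi || jhi < jlo)) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    if (ok) best <- length(idx)
  }
  best
}

# exhaustive enumeration of all monotone matchings between two interval
# position lists, maximising total match score minus gap penalties
brute_best_matching <- function(s, g) {
  na <- nrow(s); nb <- ncol(s)
  best <- -Inf
  rec <- function(i, j, total, m) {
    if (i > na || j > nb) {
      score <- total - g * (na + nb - 2 * m)
      if (score > best) best <<- score
      return(invisible())
    }
    rec(i + 1L, j, total, m)                       # skip a position of A
    rec(i, j + 1L, total, m)                       # skip a position of B
    rec(i + 1L, j + 1L, total + s[i, j], m + 1L)   # match (i, j)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# brute-force enumeration of maximal feasible pinned supersets: all subsets
# of the candidate pool that contain the pinned pairs, are memberwise
# interval-compatible with consistent labeling, stay under the RMSD cutoff
# and are adjacency-reachable from the pinned set
brute_maximal_sets <- function(pinned, candidates, A, B, params) {
  feasible <- function(S) {
    ok <- tryCatch({ label_intervals(S, A$n, B$n); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(FALSE)
    if (combined_rmsd(S, A, B) > params$rmsd_cutoff) return(FALSE)
    if (length(S) > 1L)
      for (k in seq_along(S))
        if (!is_compatible(S[[k]], S[-k], A$n, B$n)) return(FALSE)
    TRUE
  }
  reachable <- function(S) {
    npin <- length(pinned)
    if (length(S) == npin) return(TRUE)
    cur <- seq_len(npin)
    rest <- setdiff(seq_along(S), cur)
    repeat {
      added <- FALSE
      for (k in rest) {
        if (circstar:::.adjacent(S[[k]], S[cur], params$ext_dist)) {
          cur <- c(cur, k); rest <- setdiff(rest, k); added <- TRUE
        }
      }
      if (length(rest) == 0L) return(TRUE)
      if (!added) return(FALSE)
    }
  }
  m <- length(candidates)
  feas <- list()
  for (mask in 0:(2^m - 1L)) {
    idx <- which(bitwAnd(mask, 2^(0:(m - 1L))) > 0L)
    S <- c(pinned, candidates[idx])
    if (feasible(S) && reachable(S)) feas[[length(feas) + 1L]] <- S
  }
  keys <- lapply(feas, function(S)
    sort(vapply(S, `[[`, character(1), "key")))
  maximal <- vapply(seq_along(feas), function(k) {
    !any(vapply(seq_along(feas), function(l)
      l != k && length(keys[[l]]) > length(keys[[k]]) &&
        all(keys[[k]] %in% keys[[l]]), logical(1)))
  }, logical(1))
  unique(keys[maximal])
}

# ---- fixture helpers --------------------------------------------------------

# raw stack pair for topology-only tests (no coordinates involved)
mk_stack_pair <- function(ia, ja, La, ib, jb, Lb, orientation = "direct") {
  wa <- circstar:::.stack(ia, ja, La)
  wb <- circstar:::.stack(ib, jb, Lb)
  corr <- circstar:::.stack_pair_corr(wa, wb, orientation)
  circstar:::.stack_pair(wa, wb, orientation, list(rmsd = 0), corr)
}

# apply a rigid transform to every atom of a structure
transform_structure <- function(st, R, shift) {
  at <- st$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]; at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  circstar:::new_rna_structure(st$structure_id, st$base, st$author$num,
                               st$author$ins, at, st$model)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y)),
        c(2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x)),
        c(2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)))
}

# hinge-bend a helix: rotate everything above pair t_hinge about a
# perpendicular axis through the helix axis at that height
bend_helix <- function(st, angle_deg, t_hinge = 3.5) {
  at <- st$atoms
  zmid <- t_hinge * 2.81
  th <- angle_deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  sel <- at$z > zmid
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  xyz[, 3] <- xyz[, 3] - zmid
  xyz <- xyz %*% t(R)
  xyz[, 3] <- xyz[, 3] + zmid
  at[sel, c("x", "y", "z")] <- xyz
  circstar:::new_rna_structure(paste0(st$structure_id, "_bent"), st$base,
                               st$author$num, st$author$ins, at, st$model)
}

# random junction spec drawn under the study conditions: 3-5 stems of
# 4-8 bp, junction segments 2-4 nt, hairpins 3-6 nt
random_junction_spec <- function(seed) {
  set.seed(seed)
  n_stem <- sample(3:5, 1)
  junction_spec(stem_lengths = sample(4:8, n_stem, replace = TRUE),
                loop_lengths = sample(2:4, n_stem, replace = TRUE),
                hairpin_lengths = sample(3:6, max(1, n_stem - 1),
                                         replace = TRUE),
                seed = seed)
}
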