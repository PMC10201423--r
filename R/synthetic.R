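# A-form-like helix constants used by the generator: helical twist per step,
# rise along the axis, C1' radial distance and the inter-strand angular
# offset chosen so the intra-pair C1'-C1' distance is ~10.4 A
.HELIX <- list(twist = 32.7 * pi / 180, rise = 2.81, radius = 9.4,
               strand_offset = 67.2 * pi / 180)

.COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

# run expr with a reproducible RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
.unit <- function(v) v / sqrt(sum(v^2))

# atoms of one ideal base pair in the canonical helix frame (axis = z).
# Each nucleotide gets C1', a glycosidic nitrogen and two Watson-Crick edge
# atoms placed so that the intra-pair edge-atom contacts are well under the
# 3.5 A hydrogen-bond threshold of the geometric detector while all
# inter-pair contacts stay above it.
.pair_atoms <- function(t, base1, base2) {
  alpha <- t * .HELIX$twist; z <- t * .HELIX$rise; r <- .HELIX$radius
  p1 <- c(r * cos(alpha), r * sin(alpha), z)
  p2 <- c(r * cos(alpha + .HELIX$strand_offset),
          r * sin(alpha + .HELIX$strand_offset), z)
  m <- (p1 + p2) / 2
  u <- .unit(p2 - p1)
  w <- .unit(.cross3(u, c(0, 0, 1)))
  glyco <- function(base) if (base %in% c("A", "G")) "N9" else "N1"
  edge <- function(base) .EDGE_ATOMS[[base]][1:2]
  nt_atoms <- function(p, base, sgn) {
    e <- edge(base)
    rbind(
      data.frame(atom = "C1'", x = p[1], y = p[2], z = p[3]),
      data.frame(atom = glyco(base),
                 x = p[1] + 1.5 * .unit(m - p)[1],
                 y = p[2] + 1.5 * .unit(m - p)[2],
                 z = p[3] + 1.5 * .unit(m - p)[3]),
      data.frame(atom = e,
                 x = m[1] + sgn * 1.2 * u[1] + c(1.1, -1.1) * w[1],
                 y = m[2] + sgn * 1.2 * u[2] + c(1.1, -1.1) * w[2],
                 z = m[3] + sgn * 1.2 * u[3] + c(1.1, -1.1) * w[3]))
  }
  list(nt1 = nt_atoms(p1, base1, -1), nt2 = nt_atoms(p2, base2, +1),
       c1_1 = p1, c1_2 = p2)
}

.apply_frame <- function(df, R, shift) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}

#' Generate an ideal double helix with ground truth
#'
#' Builds an idealised A-form-like RNA helix (twist 32.7 degrees per step,
#' rise 2.81 Angstrom) with a random complementary Watson-Crick sequence.
#' C1' and base-edge atoms are placed so that [detect_pairs_geometric()]
#' recovers every intended pair. The chain runs 5' strand first (positions
#' `0..n_bp-1`) then the antiparallel complement, so pair `t` joins positions
#' `t` and `2*n_bp-1-t`.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param seed RNG seed for the sequence; the same seed gives a bit-identical
#'   structure.
#' @return list with `structure` (an `rna_structure`) and `truth`
#'   (`intended_pairs`, `permutation_pivot = NA`, identity
#'   `correspondence_to_parent`).
#' @export
build_ideal_helix <- function(n_bp, seed = 1L) {
  stopifnot(n_bp >= 1)
  .with_seed(seed, {
    s1 <- sample(names(.COMPLEMENT), n_bp, replace = TRUE)
    s2 <- unname(.COMPLEMENT[s1])
    n <- 2L * n_bp
    atom_rows <- vector("list", n)
    for (t in 0:(n_bp - 1L)) {
      pa <- .pair_atoms(t, s1[t + 1L], s2[t + 1L])
      atom_rows[[t + 1L]] <- cbind(seq = t, pa$nt1)
      atom_rows[[n - t]] <- cbind(seq = n - 1L - t, pa$nt2)
    }
    atoms <- do.call(rbind, atom_rows)
    st <- new_rna_structure(sprintf("helix%d_seed%d", n_bp, seed),
                            base = c(s1, rev(s2)),
                            author_num = 1:n, author_ins = rep("", n),
                            atoms = atoms)
    truth <- list(intended_pairs = base_pairs(0:(n_bp - 1L),
                                              (n - 1L):n_bp),
                  permutation_pivot = NA_integer_,
                  correspondence_to_parent = 0:(n - 1L))
    list(structure = st, truth = truth)
  })
}

#' Junction specification
#'
#' @param stem_lengths base-pair counts; the first stem is the outer
#'   (closing) helix, the rest are hairpin stems around the junction.
#' @param loop_lengths unpaired junction-segment lengths between consecutive
#'   stems (one per stem; recycled).
#' @param hairpin_lengths terminal loop sizes for the inner stems
#'   (recycled over stems `2..n`).
#' @param seed RNG seed for sequence generation.
#' @return a `junction_spec` list.
#' @export
junction_spec <- function(stem_lengths, loop_lengths = 3L,
                          hairpin_lengths = 4L, seed = 1L) {
  n <- length(stem_lengths)
  stopifnot(n >= 2, all(stem_lengths >= 1))
  structure(list(stem_lengths = as.integer(stem_lengths),
                 loop_lengths = rep_len(as.integer(loop_lengths), n),
                 hairpin_lengths = rep_len(as.integer(hairpin_lengths),
                                           max(1L, n - 1L)),
                 seed = as.integer(seed)),
            class = "junction_spec")
}

#' Build a synthetic n-way junction structure with ground truth
#'
#' Places the outer stem and `n - 1` hairpin stems as ideal helices radiating
#' from a junction at distinct orientations, connected by unpaired junction
#' segments, so that the nested skeleton decomposes into exactly one
#' multiloop with `n` closing pairs (an internal loop for `n = 2`). The
#' geometry is rejected and rebuilt with a wider junction if any non-bonded
#' C1' contact falls below 2.5 Angstrom.
#'
#' The ground truth records the intended pairs, the junction closing pairs,
#' per-stem position tables and `pivot_options`: the chain positions at the
#' boundary between each inner stem's 5' strand and its terminal hairpin
#' loop. Circularly permuting at such a pivot preserves every loop while
#' rotating the stem order, which is the scenario a circular aligner must
#' recover.
#'
#' @param spec a [junction_spec()].
#' @return list with `structure` and `truth`.
#' @export
build_junction_structure <- function(spec) {
  stopifnot(inherits(spec, "junction_spec"))
  n_stem <- length(spec$stem_lengths)
  for (attempt in 0:5) {
    res <- .try_build_junction(spec, attempt)
    if (!is.null(res)) return(res)
  }
  stop("infeasible junction geometry after bounded retries")
}

.try_build_junction <- function(spec, attempt) {
  n_stem <- length(spec$stem_lengths)
  R0 <- max(13, 11.5 / sin(pi / n_stem)) + 3 * attempt
  bump0 <- 3 + 0.7 * attempt
  .with_seed(spec$seed + attempt, {
    Ry90 <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
    frames <- lapply(seq_len(n_stem), function(k) {
      beta <- 2 * pi * (k - 1) / n_stem
      Rz <- rbind(c(cos(beta), -sin(beta), 0),
                  c(sin(beta), cos(beta), 0), c(0, 0, 1))
      list(R = Rz %*% Ry90, shift = c(cos(beta), sin(beta), 0) * R0)
    })
    stems <- lapply(seq_len(n_stem), function(k) {
      L <- spec$stem_lengths[k]
      s1 <- sample(names(.COMPLEMENT), L, replace = TRUE)
      s2 <- unname(.COMPLEMENT[s1])
      list(L = L, s1 = s1, s2 = s2,
           pairs = lapply(0:(L - 1L), function(t)
             .pair_atoms(t, s1[t + 1L], s2[t + 1L])))
    })
    # chain assembly: blocks in 5'->3' order
    base <- character(0); atoms <- list(); pos <- 0L
    add_nt <- function(b, df) {
      base <<- c(base, b)
      atoms[[length(atoms) + 1L]] <<- cbind(seq = pos, df)
      pos <<- pos + 1L
    }
    add_point <- function(b, p)
      add_nt(b, data.frame(atom = "C1'", x = p[1], y = p[2], z = p[3]))
    glob <- function(k, p) as.numeric(frames[[k]]$R %*% p + frames[[k]]$shift)
    pair_df <- function(k, t, side) {
      pa <- stems[[k]]$pairs[[t + 1L]]
      .apply_frame(if (side == 1L) pa$nt1 else pa$nt2,
                   frames[[k]]$R, frames[[k]]$shift)
    }
    hairpin_arc <- function(k, h) {
      L <- stems[[k]]$L
      pa <- stems[[k]]$pairs[[L]]
      a1 <- pa$c1_1; a2 <- pa$c1_2
      m <- (a1 + a2) / 2; u <- .unit(a2 - a1)
      rho <- max(6, (h + 1) * 2.9 / pi)
      lapply(seq_len(h), function(j) {
        th <- pi * j / (h + 1)
        glob(k, m - u * 5.2 * cos(th) + c(0, 0, 1) * rho * sin(th))
      })
    }
    seg_points <- function(from, to, m, sgn) {
      lapply(seq_len(m), function(j) {
        f <- j / (m + 1)
        from + (to - from) * f + c(0, 0, 1) * sgn * bump0 * sin(pi * f)
      })
    }
    stem_pos <- vector("list", n_stem)   # chain positions per stem strand
    pivot_options <- integer(0)
    # outer stem 5' strand: chain ascending = pair index descending
    L1 <- stems[[1]]$L
    stem_pos[[1]] <- list(s1 = integer(L1), s2 = integer(L1))
    for (p in 0:(L1 - 1L)) {
      t <- L1 - 1L - p
      stem_pos[[1]]$s1[t + 1L] <- pos
      add_nt(stems[[1]]$s1[t + 1L], pair_df(1L, t, 1L))
    }
    junction_anchor <- function(k, side, t = 0L) {
      pa <- stems[[k]]$pairs[[t + 1L]]
      glob(k, if (side == 1L) pa$c1_1 else pa$c1_2)
    }
    for (j in seg_points(junction_anchor(1L, 1L),
                         if (n_stem >= 2) junction_anchor(2L, 1L)
                         else junction_anchor(1L, 2L),
                         spec$loop_lengths[1], +1))
      add_point(sample(names(.COMPLEMENT), 1L), j)
    for (k in 2:n_stem) {
      Lk <- stems[[k]]$L
      h <- spec$hairpin_lengths[k - 1L]
      stem_pos[[k]] <- list(s1 = integer(Lk), s2 = integer(Lk))
      for (t in 0:(Lk - 1L)) {
        stem_pos[[k]]$s1[t + 1L] <- pos
        add_nt(stems[[k]]$s1[t + 1L], pair_df(k, t, 1L))
      }
      pivot_options <- c(pivot_options, pos)   # start of hairpin loop
      for (p in hairpin_arc(k, h))
        add_point(sample(names(.COMPLEMENT), 1L), p)
      for (t in (Lk - 1L):0) {
        stem_pos[[k]]$s2[t + 1L] <- pos
        add_nt(stems[[k]]$s2[t + 1L], pair_df(k, t, 2L))
      }
      nxt_anchor <- if (k < n_stem) junction_anchor(k + 1L, 1L)
                    else junction_anchor(1L, 2L)
      for (j in seg_points(junction_anchor(k, 2L), nxt_anchor,
                           spec$loop_lengths[k], (-1)^k))
        add_point(sample(names(.COMPLEMENT), 1L), j)
    }
    for (t in 0:(L1 - 1L)) {
      stem_pos[[1]]$s2[t + 1L] <- pos
      add_nt(stems[[1]]$s2[t + 1L], pair_df(1L, t, 2L))
    }
    n <- pos
    atoms <- do.call(rbind, atoms)
    st <- new_rna_structure(
      sprintf("junction%dway_seed%d", n_stem, spec$seed),
      base = base, author_num = 1:n, author_ins = rep("", n), atoms = atoms)
    # steric feasibility: non-bonded C1' contacts must stay above 2.5 A
    c1 <- st$c1
    d <- as.matrix(stats::dist(c1))
    diag(d) <- Inf
    for (k in seq_len(n - 1L)) d[k, k + 1L] <- d[k + 1L, k] <- Inf
    if (min(d, na.rm = TRUE) < 2.5) return(NULL)
    pi_ <- integer(0); pj <- integer(0)
    for (k in seq_len(n_stem)) {
      pi_ <- c(pi_, stem_pos[[k]]$s1)
      pj <- c(pj, stem_pos[[k]]$s2)
    }
    intended <- base_pairs(pi_, pj)
    closing <- base_pairs(
      vapply(seq_len(n_stem), function(k) stem_pos[[k]]$s1[1L], integer(1)),
      vapply(seq_len(n_stem), function(k) stem_pos[[k]]$s2[1L], integer(1)))
    truth <- list(intended_pairs = intended,
                  junction_closing_pairs = closing,
                  stem_positions = stem_pos,
                  pivot_options = pivot_options,
                  permutation_pivot = NA_integer_,
                  correspondence_to_parent = 0:(n - 1L))
    list(structure = st, truth = truth)
  })
}

#' Circularly permute a structure
#'
#' Moves the 5' end so that the nucleotide at `pivot` becomes position 0;
#' atomic coordinates are untouched, only the sequence order rotates. Author
#' residue identifiers follow their nucleotides.
#'
#' @param structure an `rna_structure`.
#' @param pivot 0-based position to become the new 5' end.
#' @param pairs optional base-pair data frame to re-index alongside.
#' @return list with `structure` and `truth` (`permutation_pivot`,
#'   `correspondence_to_parent` mapping new to old positions, and
#'   `intended_pairs` when `pairs` was given).
#' @export
circular_permute <- function(structure, pivot, pairs = NULL) {
  n <- structure$n
  if (pivot < 0 || pivot >= n) stop("pivot out of range")
  old_of_new <- (0:(n - 1L) + pivot) %% n
  atoms <- structure$atoms
  atoms$seq <- (atoms$seq - pivot) %% n
  atoms <- atoms[order(atoms$seq), , drop = FALSE]
  st <- new_rna_structure(paste0(structure$structure_id, "_perm", pivot),
                          base = structure$base[old_of_new + 1L],
                          author_num = structure$author$num[old_of_new + 1L],
                          author_ins = structure$author$ins[old_of_new + 1L],
                          atoms = atoms, model = structure$model)
  truth <- list(permutation_pivot = as.integer(pivot),
                correspondence_to_parent = old_of_new)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    truth$intended_pairs <- base_pairs((pairs$i - pivot) %% n,
                                       (pairs$j - pivot) %% n,
                                       pairs$family, pairs$canonical)
  }
  list(structure = st, truth = truth)
}

#' Add reproducible Gaussian coordinate noise
#'
#' Independent normal displacement (standard deviation `sigma` per
#' coordinate) applied to every atom.
#'
#' @param structure an `rna_structure`.
#' @param sigma standard deviation in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return a jittered `rna_structure`.
#' @export
jitter_structure <- function(structure, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(structure)
  .with_seed(seed, {
    atoms <- structure$atoms
    m <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(m, 0, sigma)
    atoms$y <- atoms$y + stats::rnorm(m, 0, sigma)
    atoms$z <- atoms$z + stats::rnorm(m, 0, sigma)
    new_rna_structure(paste0(structure$structure_id, "_jit"),
                      structure$base, structure$author$num,
                      structure$author$ins, atoms, structure$model)
  })
}

#' Write a DSSR-dialect JSON annotation for a set of base pairs
#'
#' Emits the minimal schema read back by [read_dssr_pairs()]: a `pairs`
#' array with `nt1`, `nt2` (chain.BASEnumber using author numbering),
#' `name` ("WC"/"Wobble" for canonical, the family tag otherwise) and `LW`.
#'
#' @param pairs base-pair data frame.
#' @param structure the structure the pairs refer to.
#' @param path output JSON file.
#' @param chain chain label used in residue ids.
#' @return `path`, invisibly.
#' @export
write_dssr_json <- function(pairs, structure, path, chain = "A") {
  nt_id <- function(k) {
    ins <- structure$author$ins[k + 1L]
    paste0(chain, ".", structure$base[k + 1L], structure$author$num[k + 1L],
           if (ins != "") paste0("^", ins) else "")
  }
  plist <- lapply(seq_len(nrow(pairs)), function(r) {
    gu <- paste0(structure$base[pairs$i[r] + 1L],
                 structure$base[pairs$j[r] + 1L]) %in% c("GU", "UG")
    list(nt1 = nt_id(pairs$i[r]), nt2 = nt_id(pairs$j[r]),
         name = if (!pairs$canonical[r]) pairs$family[r]
                else if (gu) "Wobble" else "WC",
         LW = pairs$family[r])
  })
  jsonlite::write_json(list(pairs = plist), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a ground-truth sidecar file
#'
#' JSON serialisation of a generator ground-truth record so that tests and
#' downstream tools never re-derive intent from geometry.
#'
#' @param truth ground-truth list from a generator.
#' @param path JSON file.
#' @return `path` (writer) / the truth list (reader).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("intended_pairs", "junction_closing_pairs"))
    if (!is.null(gt[[nm]])) gt[[nm]] <- as.data.frame(gt[[nm]])
  gt
}
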