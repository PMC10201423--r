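# normalise a pairs argument: NULL -> geometric detector, path -> DSSR JSON,
# data frame -> as-is; then canonical filter + multiplet resolution
.resolve_pairs <- function(pairs, structure) {
  if (is.null(pairs)) pairs <- detect_pairs_geometric(structure)
  else if (is.character(pairs)) pairs <- read_dssr_pairs(pairs, structure)
  all_pairs <- pairs
  can <- pairs[pairs$canonical, , drop = FALSE]
  can <- resolve_multiplets(can, structure)
  list(all = all_pairs, canonical = can)
}

.as_structure <- function(x, chain = NULL, model = 1L) {
  if (inherits(x, "rna_structure")) return(x)
  if (is.character(x)) return(read_rna_structure(x, chain, model))
  stop("expected an rna_structure or a file path")
}

#' Circular alignment of two RNA 3D structures
#'
#' Runs the full stack-anchored circular matching pipeline: base-pair
#' annotation (supplied or detected geometrically), nested-skeleton and loop
#' decomposition, conserved stack-pair enumeration in direct and rotated
#' orientation, rotated-matched seed-loop selection, compatible-set extension
#' and assembly into scored, RMSD-filtered nucleotide-level alignments.
#' Alignment relies on structural information only; base identity is never
#' scored.
#'
#' @param a,b `rna_structure` objects or file paths (PDB / mmCIF).
#' @param pairs_a,pairs_b base-pair annotations: a data frame (see
#'   [base_pairs()]), a DSSR-style JSON path, or `NULL` to use the built-in
#'   geometric detector.
#' @param params `circstar_params`.
#' @param chain_a,chain_b,model chain/model selection when `a`/`b` are paths.
#' @param top report at most this many alignments (default 2).
#' @param min_score drop alignments scoring below this (default `-Inf`;
#'   the command-line tool uses 0, reporting positive scores only).
#' @param exhaustive lift the closing-pair restriction on sub-stack windows.
#' @param scheme atom scheme for all superpositions.
#' @return object of class `circstar`: ranked alignments plus run metadata.
#'   With no conserved stacks or no rotated-matched seed loop the object
#'   contains zero alignments (an explicit "no circular match" outcome).
#' @export
circular_align <- function(a, b, pairs_a = NULL, pairs_b = NULL,
                           params = circstar_params(),
                           chain_a = NULL, chain_b = NULL, model = 1L,
                           top = 2L, min_score = -Inf, exhaustive = FALSE,
                           scheme = "c1_prime") {
  A <- .as_structure(a, chain_a, model)
  B <- .as_structure(b, chain_b, model)
  pa <- .resolve_pairs(pairs_a, A)
  pb <- .resolve_pairs(pairs_b, B)
  ss_a <- extract_nested(pa$canonical)
  ss_b <- extract_nested(pb$canonical)
  loops_a <- extract_loops(ss_a, A$n)
  loops_b <- extract_loops(ss_b, B$n)
  stacks_a <- find_stacks(ss_a, params)
  stacks_b <- find_stacks(ss_b, params)
  closing_tab <- function(loops) {
    if (length(loops$loops) == 0L) return(.empty_pairs()[, c("i", "j")])
    unique(do.call(rbind, lapply(loops$loops, function(l)
      l$closing[, c("i", "j")])))
  }
  sps <- enumerate_conserved_stack_pairs(
    stacks_a, stacks_b, A, B, params,
    closing_a = closing_tab(loops_a), closing_b = closing_tab(loops_b),
    exhaustive = exhaustive, scheme = scheme)
  sps <- .prune_subwindow_pairs(sps)
  matched <- find_matched_loops(loops_a$loops, loops_b$loops, sps, A, B,
                                params, scheme)
  seeds <- select_seed_loops(matched)
  alignments <- list()
  for (seed in seeds) {
    for (cset in extend_seed(seed, sps, A, B, params, scheme)) {
      aln <- assemble(cset, A, B, params, scheme)
      if (!is.null(aln)) alignments[[length(alignments) + 1L]] <- aln
    }
  }
  alignments <- rank_alignments(alignments)
  alignments <- Filter(function(x) x$score >= min_score, alignments)
  if (is.finite(top) && length(alignments) > top)
    alignments <- alignments[seq_len(top)]
  structure(list(alignments = alignments, params = params,
                 a = A, b = B, pairs_a = pa$canonical, pairs_b = pb$canonical,
                 n_stack_pairs = length(sps), n_matched_loops = length(matched),
                 n_seeds = length(seeds), scheme = scheme),
            class = "circstar")
}

#' @export
print.circstar_alignment <- function(x, ...) {
  cat(sprintf(
    "circular alignment %s ~ %s: score %.1f, rmsd %.3f A, %d aligned (%d del, %d ins), rotation offset %d\n",
    x$a_id, x$b_id, x$score, x$rmsd, x$n_aligned, x$n_deleted, x$n_inserted,
    x$rotation_offset))
  invisible(x)
}

#' @export
as.data.frame.circstar_alignment <- function(x, ...) {
  data.frame(a = x$pairs[, 1], b = x$pairs[, 2])
}

#' @export
print.circstar <- function(x, ...) {
  cat(sprintf("circstar: %s (%d nt) vs %s (%d nt)\n",
              x$a$structure_id, x$a$n, x$b$structure_id, x$b$n))
  cat(sprintf("  %d conserved stack pair(s), %d matched loop(s), %d rotated seed(s)\n",
              x$n_stack_pairs, x$n_matched_loops, x$n_seeds))
  if (length(x$alignments) == 0L) {
    cat("  no circular match\n")
    return(invisible(x))
  }
  for (k in seq_along(x$alignments)) {
    a <- x$alignments[[k]]
    cat(sprintf("  #%d score %.1f rmsd %.3f A aligned %d del %d ins %d offset %d\n",
                k, a$score, a$rmsd, a$n_aligned, a$n_deleted, a$n_inserted,
                a$rotation_offset))
  }
  invisible(x)
}

#' @export
summary.circstar <- function(object, ...) {
  x <- object
  print(x)
  if (length(x$alignments)) {
    cat("alignment quality (largest ACS):\n")
    for (k in seq_along(x$alignments)) {
      a <- x$alignments[[k]]
      v_pcsi <- pcsi(a, x$a, x$b, x$pairs_a, x$pairs_b, x$params)
      v_pcss <- pcss(a, x$a, x$b, x$pairs_a, x$pairs_b, x$params)
      cat(sprintf("  #%d PCSI %.3f PCSS %s\n", k, v_pcsi,
                  if (is.na(v_pcss)) "n/a" else sprintf("%.3f", v_pcss)))
    }
  }
  invisible(x)
}

#' Dot plot of the aligned correspondence
#'
#' Plots aligned positions of structure A against structure B; a circular
#' match shows up as two monotone segments separated by the rotation seam
#' (dashed line).
#'
#' @param x a `circstar` or `circstar_alignment`.
#' @param which alignment rank to plot when `x` is a `circstar`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.circstar <- function(x, which = 1L, ...) {
  if (length(x$alignments) == 0L) stop("no alignments to plot")
  plot(x$alignments[[which]], ...)
}

#' @export
plot.circstar_alignment <- function(x, ...) {
  graphics::plot(x$pairs[, 1], x$pairs[, 2], pch = 16, cex = 0.5,
                 xlab = paste0(x$a_id, " (position)"),
                 ylab = paste0(x$b_id, " (position)"),
                 main = sprintf("score %.1f, rmsd %.2f A, offset %d",
                                x$score, x$rmsd, x$rotation_offset), ...)
  if (x$rotation_offset > 0)
    graphics::abline(v = x$rotation_offset - 0.5, lty = 2, col = "grey40")
  invisible(x)
}

#' Evaluate an alignment with the ACS metrics
#'
#' Convenience wrapper computing the ACS list, PCSI and PCSS for one
#' alignment of a `circstar` result.
#'
#' @param x a `circstar` object.
#' @param which alignment rank (default 1).
#' @return list with `acs`, `pcsi`, `pcss`.
#' @export
evaluate_alignment <- function(x, which = 1L) {
  stopifnot(inherits(x, "circstar"), length(x$alignments) >= which)
  a <- x$alignments[[which]]
  list(acs = find_acs(a, x$a, x$b, x$pairs_a, x$pairs_b, x$params),
       pcsi = pcsi(a, x$a, x$b, x$pairs_a, x$pairs_b, x$params),
       pcss = pcss(a, x$a, x$b, x$pairs_a, x$pairs_b, x$params))
}
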