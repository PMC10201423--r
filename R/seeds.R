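#' Find matched loop pairs closed by conserved stack pairs
#'
#' For every (internal or multiloop) loop pair, one from each structure, the
#' conserved stack pairs whose A window contains a closing pair of the first
#' loop and whose B window contains a closing pair of the second are
#' collected; every maximal mutually compatible subset (under the circular
#' interval relation, with joint RMSD at most `params$rmsd_cutoff`) is emitted
#' as a separate matched loop pair. Hairpins never participate: with a single
#' loop region they admit no circular match, although their material can be
#' absorbed later during extension and assembly.
#'
#' @param loops_a,loops_b loop lists from [extract_loops()] (hairpins are
#'   filtered out here).
#' @param stack_pairs conserved stack pairs from
#'   [enumerate_conserved_stack_pairs()].
#' @param A,B the two structures.
#' @param params `circstar_params`.
#' @param scheme atom scheme.
#' @return list of matched loop pairs: `list(loop_a, loop_b, closing_matches,
#'   has_rotated)`.
#' @export
find_matched_loops <- function(loops_a, loops_b, stack_pairs, A, B,
                               params = circstar_params(),
                               scheme = "c1_prime") {
  la <- Filter(function(l) l$kind %in% c("internal", "multiloop"), loops_a)
  lb <- Filter(function(l) l$kind %in% c("internal", "multiloop"), loops_b)
  out <- list()
  for (a in la) {
    for (b in lb) {
      cand <- Filter(function(sp)
        .window_has_closing(sp$a, a$closing) &&
          .window_has_closing(sp$b, b$closing), stack_pairs)
      if (length(cand) == 0L) next
      sets <- .enumerate_maximal(list(), cand, A, B, params,
                                 use_adjacency = FALSE, scheme = scheme)
      for (R in sets) {
        out[[length(out) + 1L]] <- list(
          loop_a = a, loop_b = b, closing_matches = R,
          has_rotated = any(vapply(R, `[[`, character(1), "orientation") ==
                              "rotated"))
      }
    }
  }
  out
}

#' Keep only rotated-matched seed loops
#'
#' The seeds of the circular search are the matched loop pairs closed by at
#' least one rotated (strand-exchanged) stack match; direct-only matched
#' loops are discarded. Input order is preserved and the operation is
#' idempotent.
#'
#' @param matched list from [find_matched_loops()].
#' @return the members with `has_rotated = TRUE`.
#' @export
select_seed_loops <- function(matched) {
  Filter(function(m) isTRUE(m$has_rotated), matched)
}
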