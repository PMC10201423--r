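#' Pipeline parameters
#'
#' Bundles every numeric threshold used by the circular alignment pipeline.
#' Defaults follow the published tool: a 4 Angstrom RMSD cutoff is applied to
#' conserved stack pairs, to compatible stack-pair sets and to assembled
#' alignments; extension looks for new stack pairs within 15 nucleotides of the
#' current set; ACS connectivity uses a 5-nucleotide sequence gap; PCSI/PCSS
#' count aligned nucleotides within 4 Angstrom.
#'
#' @param rmsd_cutoff RMSD threshold in Angstrom for conserved stack pairs,
#'   compatible sets and final alignments (default 4).
#' @param ext_dist sequence-adjacency distance in nucleotides used during local
#'   extension (default 15).
#' @param min_stack_len minimum number of consecutive nested base pairs for a
#'   stack to be considered (default 2).
#' @param acs_gap sequence-distance threshold in nucleotides for ACS
#'   connectivity (default 5).
#' @param metric_dist distance threshold in Angstrom for "within" counts in
#'   PCSI/PCSS and for loop-alignment match acceptance (default 4).
#' @param gap_weight per-nucleotide gap penalty in the alignment score
#'   `n_aligned - gap_weight * (n_deleted + n_inserted)` (default 0.5).
#' @return an object of class `circstar_params`.
#' @export
circstar_params <- function(rmsd_cutoff = 4, ext_dist = 15, min_stack_len = 2,
                            acs_gap = 5, metric_dist = 4, gap_weight = 0.5) {
  p <- list(rmsd_cutoff = rmsd_cutoff, ext_dist = ext_dist,
            min_stack_len = min_stack_len, acs_gap = acs_gap,
            metric_dist = metric_dist, gap_weight = gap_weight)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  p$min_stack_len <- as.integer(p$min_stack_len)
  class(p) <- "circstar_params"
  p
}

#' @export
print.circstar_params <- function(x, ...) {
  cat("circstar parameters:\n")
  for (nm in setdiff(names(x), "scheme"))
    cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# positive modulus (R's %% already returns non-negative for positive modulus,
# kept explicit for readability at call sites)
.mod <- function(x, n) x %% n

# gap in nucleotides between two half-open intervals [a,b) and [c,d) on a line;
# 0 when they touch or overlap
.interval_gap <- function(a, b, c, d) max(0L, c - b, a - d)
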