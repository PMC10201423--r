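# Watson-Crick / wobble edge atoms (N/O donors and acceptors) per base,
# used both by the geometric detector and by the synthetic generator
.EDGE_ATOMS <- list(A = c("N1", "N6"),
                    U = c("N3", "O4", "O2"),
                    G = c("N1", "O6", "N2"),
                    C = c("N3", "N4", "O2"))
.COMPLEMENTARY <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE,
                    GU = TRUE, UG = TRUE)

.empty_pairs <- function() {
  data.frame(i = integer(0), j = integer(0), family = character(0),
             canonical = logical(0), stringsAsFactors = FALSE)
}

#' Assemble a base-pair table
#'
#' @param i,j 0-based partner indices (reordered so `i < j`).
#' @param family annotation tag, e.g. "cWW".
#' @param canonical logical: cis Watson-Crick AU/GC or wobble GU.
#' @return data frame with columns `i`, `j`, `family`, `canonical`.
#' @export
base_pairs <- function(i, j, family = "cWW", canonical = TRUE) {
  if (length(i) == 0L) return(.empty_pairs())
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("a base pair cannot involve one nucleotide twice")
  data.frame(i = as.integer(lo), j = as.integer(hi),
             family = rep_len(as.character(family), length(i)),
             canonical = rep_len(as.logical(canonical), length(i)),
             stringsAsFactors = FALSE)
}

#' Read base pairs from a DSSR-style JSON annotation
#'
#' Accepts the JSON dialect written by DSSR's `--json` mode, reduced to the
#' `pairs` array: each element needs `nt1`, `nt2` (residue ids of the form
#' `chain.BASEnumber`, e.g. `"A.G12"`, insertion codes appended as `^X`) and
#' `name` (`"WC"` and `"Wobble"` map to canonical). An `LW` field, when
#' present, is kept as the pair family. Pairs referencing residues absent from
#' the chain are dropped with a warning.
#'
#' @param path JSON file.
#' @param structure the `rna_structure` the annotation refers to (used to map
#'   author residue numbers to sequence indices).
#' @return base-pair data frame (see [base_pairs()]).
#' @export
read_dssr_pairs <- function(path, structure) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse DSSR JSON: ",
                                           conditionMessage(e)))
  prs <- doc$pairs
  if (is.null(prs) || length(prs) == 0L) return(.empty_pairs())
  akey <- paste(structure$author$num, structure$author$ins, sep = "_")
  parse_nt <- function(s) {
    s <- sub("^[^.]*\\.", "", s)            # strip chain
    ins <- ""
    if (grepl("\\^", s)) { ins <- sub("^.*\\^", "", s); s <- sub("\\^.*$", "", s) }
    num <- suppressWarnings(as.integer(sub("^[A-Za-z']*", "", s)))
    if (is.na(num)) return(NA_integer_)
    m <- match(paste(num, ins, sep = "_"), akey)
    if (is.na(m)) NA_integer_ else m - 1L
  }
  i <- integer(0); j <- integer(0); fam <- character(0); can <- logical(0)
  dropped <- 0L
  for (p in prs) {
    a <- parse_nt(p$nt1); b <- parse_nt(p$nt2)
    if (is.na(a) || is.na(b)) { dropped <- dropped + 1L; next }
    i <- c(i, a); j <- c(j, b)
    fam <- c(fam, if (!is.null(p$LW)) p$LW else as.character(p$name))
    can <- c(can, p$name %in% c("WC", "Wobble"))
  }
  if (dropped > 0L)
    warning(dropped, " pair(s) referenced residues outside the chain and were dropped")
  if (length(i) == 0L) return(.empty_pairs())
  base_pairs(i, j, fam, can)
}

# hydrogen-bond distances (edge N/O atoms within hbond_max) between two
# nucleotides; returns sorted distances, empty when bases not complementary
.hbond_dists <- function(structure, i, j, hbond_max = 3.5) {
  bi <- structure$base[i + 1L]; bj <- structure$base[j + 1L]
  if (is.na(.COMPLEMENTARY[paste0(bi, bj)])) return(numeric(0))
  ai <- structure$atoms[structure$atoms$seq == i &
                        structure$atoms$atom %in% .EDGE_ATOMS[[bi]], ,
                        drop = FALSE]
  aj <- structure$atoms[structure$atoms$seq == j &
                        structure$atoms$atom %in% .EDGE_ATOMS[[bj]], ,
                        drop = FALSE]
  if (nrow(ai) == 0L || nrow(aj) == 0L) return(numeric(0))
  d <- sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
            outer(ai$z, aj$z, "-")^2)
  sort(d[d <= hbond_max])
}

#' Detect canonical base pairs geometrically
#'
#' Fallback annotator used when no DSSR-style file is supplied. A pair is
#' reported when the bases are complementary (AU, GC or GU), the C1'-C1'
#' distance lies in 8-12 Angstrom, and at least two Watson-Crick-edge N/O
#' donor-acceptor contacts are within 3.5 Angstrom. Conflicts are resolved
#' greedily by ascending hydrogen-bond distance sum so that each nucleotide
#' appears in at most one reported pair.
#'
#' @param structure an `rna_structure` with base edge atoms.
#' @return base-pair data frame with `canonical = TRUE` throughout.
#' @export
detect_pairs_geometric <- function(structure) {
  n <- structure$n
  if (n < 2L) return(.empty_pairs())
  c1 <- structure$c1
  ok <- stats::complete.cases(c1)
  cand_i <- integer(0); cand_j <- integer(0); score <- numeric(0)
  d2 <- as.matrix(stats::dist(ifelse(is.na(c1), Inf, c1)))
  for (i in seq_len(n - 1L)) {
    if (!ok[i]) next
    for (j in (i + 1L):n) {
      if (!ok[j]) next
      dij <- d2[i, j]
      if (is.na(dij) || dij < 8 || dij > 12) next
      hb <- .hbond_dists(structure, i - 1L, j - 1L)
      if (length(hb) < 2L) next
      cand_i <- c(cand_i, i - 1L); cand_j <- c(cand_j, j - 1L)
      score <- c(score, sum(hb))
    }
  }
  if (length(cand_i) == 0L) return(.empty_pairs())
  ord <- order(score, cand_i, cand_j)
  used <- logical(n)
  keep <- logical(length(ord))
  for (k in ord) {
    if (used[cand_i[k] + 1L] || used[cand_j[k] + 1L]) next
    used[cand_i[k] + 1L] <- TRUE; used[cand_j[k] + 1L] <- TRUE
    keep[k] <- TRUE
  }
  base_pairs(cand_i[keep], cand_j[keep], "cWW", TRUE)
}

#' Resolve multiplet conflicts
#'
#' Keeps at most one pair per nucleotide, preferring the pair with the best
#' (lowest) hydrogen-bond distance sum when coordinates permit, otherwise the
#' smaller sequence span. Dropped pairs trigger a warning.
#'
#' @param pairs base-pair data frame.
#' @param structure the corresponding `rna_structure` (optional, improves the
#'   geometric tie-break).
#' @return conflict-free base-pair data frame.
#' @export
resolve_multiplets <- function(pairs, structure = NULL) {
  if (nrow(pairs) <= 1L) return(pairs)
  score <- vapply(seq_len(nrow(pairs)), function(k) {
    if (is.null(structure)) return(pairs$j[k] - pairs$i[k])
    hb <- .hbond_dists(structure, pairs$i[k], pairs$j[k])
    if (length(hb) >= 2L) sum(hb) else 1e6 + pairs$j[k] - pairs$i[k]
  }, numeric(1))
  ord <- order(score, pairs$i, pairs$j)
  used <- integer(0)
  keep <- logical(nrow(pairs))
  for (k in ord) {
    if (pairs$i[k] %in% used || pairs$j[k] %in% used) next
    used <- c(used, pairs$i[k], pairs$j[k])
    keep[k] <- TRUE
  }
  if (!all(keep))
    warning(sum(!keep), " multiplet pair(s) dropped")
  pairs[keep, , drop = FALSE]
}

#' Split canonical pairs into a maximum nested subset and crossing remainder
#'
#' Dynamic programming over pair endpoints finds a maximum-cardinality
#' mutually nested subset of the input pairs; everything else is returned as
#' crossing (pseudoknot-candidate) pairs, which re-enter the pipeline only as
#' candidate stacks during extension.
#'
#' @param pairs conflict-free base-pair data frame (one partner per
#'   nucleotide; see [resolve_multiplets()]).
#' @return object of class `secondary_structure`: list with `nested` and
#'   `crossing` base-pair data frames.
#' @export
extract_nested <- function(pairs) {
  out <- function(nested, crossing)
    structure(list(nested = nested, crossing = crossing),
              class = "secondary_structure")
  if (nrow(pairs) == 0L) return(out(pairs, pairs))
  nts <- c(pairs$i, pairs$j)
  if (anyDuplicated(nts))
    stop("conflicting partners: nucleotide(s) ",
         paste(unique(nts[duplicated(nts)]), collapse = ","),
         " appear in more than one pair; resolve multiplets first")
  n <- max(pairs$j) + 1L
  partner <- rep(NA_integer_, n)
  partner[pairs$i + 1L] <- pairs$j
  # M[l+1, r+2] = max nested pairs selectable within [l, r] (1-based storage,
  # column offset by one so r = l-1 is representable)
  M <- matrix(0L, n, n + 1L)
  for (len in 2:n) {
    for (l in 0:(n - len)) {
      r <- l + len - 1L
      best <- M[l + 2L, r + 2L]          # skip position l
      k <- partner[l + 1L]
      if (!is.na(k) && k <= r) {
        v <- 1L + (if (k - 1L >= l + 1L) M[l + 2L, k + 1L] else 0L) +
          (if (r >= k + 1L) M[k + 2L, r + 2L] else 0L)
        if (v > best) best <- v
      }
      M[l + 1L, r + 2L] <- best
    }
  }
  chosen <- matrix(integer(0), 0, 2)
  trace <- function(l, r) {
    while (l < r) {
      k <- partner[l + 1L]
      take <- FALSE
      if (!is.na(k) && k <= r) {
        v <- 1L + (if (k - 1L >= l + 1L) M[l + 2L, k + 1L] else 0L) +
          (if (r >= k + 1L) M[k + 2L, r + 2L] else 0L)
        take <- v >= M[l + 1L, r + 2L]
      }
      if (take) {
        chosen <<- rbind(chosen, c(l, k))
        if (k - 1L >= l + 1L) trace(l + 1L, k - 1L)
        l <- k + 1L
      } else l <- l + 1L
    }
  }
  trace(0L, n - 1L)
  sel <- paste(pairs$i, pairs$j) %in% paste(chosen[, 1], chosen[, 2])
  out(pairs[sel, , drop = FALSE], pairs[!sel, , drop = FALSE])
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d nested pair(s), %d crossing pair(s)\n",
              nrow(x$nested), nrow(x$crossing)))
  invisible(x)
}

#' Dot-bracket view of a secondary structure
#'
#' Debug helper: nested pairs become `()`, crossing pairs `[]`.
#'
#' @param ss `secondary_structure`.
#' @param n chain length.
#' @return character scalar of length-`n` symbols.
#' @export
dot_bracket <- function(ss, n) {
  s <- rep(".", n)
  if (nrow(ss$nested)) {
    s[ss$nested$i + 1L] <- "("; s[ss$nested$j + 1L] <- ")"
  }
  if (nrow(ss$crossing)) {
    s[ss$crossing$i + 1L] <- "["; s[ss$crossing$j + 1L] <- "]"
  }
  paste(s, collapse = "")
}

#' Decompose the nested skeleton into loops
#'
#' Emits every face of the nested structure's tree as a hairpin (one closing
#' pair), internal loop (two) or multiloop (three or more), each with its
#' closing pairs and the unpaired segments between them in 5'-to-3' order
#' (half-open intervals). Directly stacked pairs (helix interiors) produce no
#' loop. The exterior region (dangling ends and material between top-level
#' helices) is not a loop but is returned alongside for assembly.
#'
#' @param ss `secondary_structure`.
#' @param n chain length.
#' @return list with `loops` (list of loop objects: `kind`, `closing`
#'   base-pair data frame, `segments` list of `c(start, end)` intervals) and
#'   `exterior` (list of intervals).
#' @export
extract_loops <- function(ss, n) {
  np <- ss$nested
  if (nrow(np) == 0L)
    return(list(loops = list(),
                exterior = if (n > 0) list(c(0L, n)) else list()))
  np <- np[order(np$i), , drop = FALSE]
  m <- nrow(np)
  parent <- rep(0L, m)                    # 0 = virtual root
  stack <- integer(0)
  for (k in seq_len(m)) {
    while (length(stack) && np$j[stack[length(stack)]] < np$i[k])
      stack <- stack[-length(stack)]
    parent[k] <- if (length(stack)) stack[length(stack)] else 0L
    stack <- c(stack, k)
  }
  children <- split(seq_len(m), factor(parent, levels = 0:m))
  loops <- list()
  for (k in seq_len(m)) {
    ch <- children[[as.character(k)]]
    i <- np$i[k]; j <- np$j[k]
    if (length(ch) == 1L && np$i[ch] == i + 1L && np$j[ch] == j - 1L)
      next                                # stacked pair, helix interior
    segs <- list(); start <- i + 1L
    for (c_ in ch) {
      segs[[length(segs) + 1L]] <- c(start, np$i[c_])
      start <- np$j[c_] + 1L
    }
    segs[[length(segs) + 1L]] <- c(start, j)
    kind <- if (length(ch) == 0L) "hairpin"
            else if (length(ch) == 1L) "internal" else "multiloop"
    loops[[length(loops) + 1L]] <-
      list(kind = kind,
           closing = np[c(k, ch), c("i", "j"), drop = FALSE],
           segments = segs)
  }
  top <- children[["0"]]
  ext <- list(); start <- 0L
  for (c_ in top) {
    ext[[length(ext) + 1L]] <- c(start, np$i[c_])
    start <- np$j[c_] + 1L
  }
  ext[[length(ext) + 1L]] <- c(start, n)
  list(loops = loops, exterior = ext)
}
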