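#' @importFrom stats rnorm complete.cases dist
#' @importFrom utils write.table
NULL

# residues mapped to a parent base when read from a file; anything else with a
# ribose C1' atom is kept as base "other"
.MODIFIED_PARENT <- c(
  PSU = "U", "5MU" = "U", "4SU" = "U", H2U = "U", OMU = "U", UR3 = "U",
  "5MC" = "C", OMC = "C", "4OC" = "C",
  "1MA" = "A", MA6 = "A", "6MA" = "A", A2M = "A", RIA = "A",
  "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", "1MG" = "G", YG = "G",
  G7M = "G", QUO = "G"
)
.NON_RNA <- c("HOH", "WAT", "DA", "DC", "DG", "DT", "DI", "DU")

#' Construct an RNA structure object
#'
#' Internal constructor shared by the file readers and the synthetic
#' generators. Sequence positions (`seq_index`) are 0-based and consecutive;
#' intervals elsewhere in the package are half-open `[start, end)`.
#'
#' @param structure_id identifier, e.g. "1abc_A".
#' @param base character vector of base codes ("A","C","G","U","other").
#' @param author_num integer author residue numbers (reporting only).
#' @param author_ins insertion codes ("" when absent).
#' @param atoms data frame with columns `seq` (0-based nucleotide index),
#'   `atom`, `x`, `y`, `z`.
#' @param model model number the coordinates came from.
#' @return object of class `rna_structure`.
#' @keywords internal
new_rna_structure <- function(structure_id, base, author_num, author_ins,
                              atoms, model = 1L) {
  n <- length(base)
  stopifnot(length(author_num) == n, length(author_ins) == n)
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atomic coordinate")
  if (n > 0 && (min(atoms$seq) < 0 || max(atoms$seq) >= n))
    stop("atom nucleotide index out of range")
  c1 <- matrix(NA_real_, n, 3)
  sel <- atoms$atom == "C1'"
  if (any(sel))
    c1[atoms$seq[sel] + 1L, ] <- cbind(atoms$x[sel], atoms$y[sel],
                                       atoms$z[sel])
  structure(list(structure_id = structure_id, model = as.integer(model),
                 n = n, base = base,
                 author = data.frame(num = as.integer(author_num),
                                     ins = as.character(author_ins),
                                     stringsAsFactors = FALSE),
                 atoms = atoms, c1 = c1),
            class = "rna_structure")
}

#' Read one RNA chain from a PDB or PDBx/mmCIF file
#'
#' Parses the file with bio3d and reduces it to a single-chain RNA model:
#' only residues carrying a ribose C1' atom are kept (ions, waters, amino
#' acids and DNA are dropped), in file order, with 0-based sequence indices.
#' Modified ribonucleotides are mapped to their parent base when known,
#' otherwise kept with base "other". Hydrogens are discarded.
#'
#' @param path PDB (`.pdb`, `.ent`) or PDBx/mmCIF (`.cif`, `.mmcif`) file.
#' @param chain chain identifier; `NULL` picks the first chain containing RNA.
#' @param model model number (1-based; default 1).
#' @return an `rna_structure`.
#' @export
read_rna_structure <- function(path, chain = NULL, model = 1L) {
  if (!file.exists(path)) stop("input file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  obj <- if (is_cif) suppressWarnings(bio3d::read.cif(path, multi = TRUE))
         else suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  at <- obj$atom
  at$elety <- gsub("\"", "", gsub("\\*", "'", trimws(at$elety)))
  at$resid <- trimws(at$resid)
  at$insert[is.na(at$insert)] <- ""
  n_models <- max(1L, nrow(obj$xyz))
  if (model < 1L || model > n_models)
    stop("model ", model, " not present (file has ", n_models, ")")
  if (model > 1L) {
    xyz <- matrix(obj$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- NULL
    for (ch in chains) {
      sub <- at[at$chain == ch, ]
      if (any(sub$elety == "C1'" & !(sub$resid %in% .NON_RNA))) {
        chain <- ch; break
      }
    }
    if (is.null(chain)) stop("no RNA in chain: no chain contains ribonucleotides")
  }
  if (!chain %in% chains)
    stop("chain not found: '", chain, "' (available: ",
         paste(chains, collapse = ","), ")")
  at <- at[at$chain == chain & !grepl("^[0-9]*H", at$elety), , drop = FALSE]
  key <- paste(at$resno, at$insert, sep = "_")
  res_keys <- unique(key)
  keep <- character(0); base <- character(0)
  a_num <- integer(0); a_ins <- character(0)
  for (k in res_keys) {
    rows <- at[key == k, , drop = FALSE]
    resid <- rows$resid[1]
    if (resid %in% .NON_RNA || !any(rows$elety == "C1'")) next
    b <- if (resid %in% c("A", "C", "G", "U")) resid
         else if (resid %in% names(.MODIFIED_PARENT)) .MODIFIED_PARENT[[resid]]
         else "other"
    keep <- c(keep, k); base <- c(base, b)
    a_num <- c(a_num, rows$resno[1]); a_ins <- c(a_ins, rows$insert[1])
  }
  if (length(keep) == 0L) stop("no RNA in chain '", chain, "'")
  sel <- key %in% keep
  at <- at[sel, , drop = FALSE]
  seq0 <- match(paste(at$resno, at$insert, sep = "_"), keep) - 1L
  atoms <- data.frame(seq = seq0, atom = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  id <- paste0(sub("\\.[A-Za-z]+$", "", basename(path)), "_", chain)
  new_rna_structure(id, base, a_num, a_ins, atoms, model)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure '%s': %d nucleotides (model %d)\n",
              x$structure_id, x$n, x$model))
  if (x$n > 0) {
    s <- paste(ifelse(x$base == "other", "x", x$base), collapse = "")
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat("  5'-", s, "-3'\n", sep = "")
  }
  invisible(x)
}

#' @export
length.rna_structure <- function(x) x$n

# atom names entering each representation scheme for a given base
.scheme_atoms <- function(scheme, base, available) {
  switch(scheme,
    c1_prime = "C1'",
    backbone_glyco = c("P", "C1'", if (base %in% c("A", "G")) "N9" else "N1"),
    all_heavy = available,
    stop("unknown atom scheme: ", scheme))
}

#' Representative coordinates for a set of nucleotides
#'
#' Extracts the atoms of an `AtomScheme` for the requested nucleotides, in the
#' order given. Nucleotides missing a scheme atom contribute no point for that
#' atom and are reported in the `"flagged"` attribute. The default scheme,
#' one C1' atom per nucleotide, is used for every RMSD computation in the
#' pipeline.
#'
#' @param structure an `rna_structure`.
#' @param indices 0-based nucleotide indices (default: all).
#' @param scheme one of `"c1_prime"`, `"backbone_glyco"`, `"all_heavy"`.
#' @return numeric matrix with 3 columns, one row per available (nucleotide,
#'   scheme atom); attribute `"flagged"` holds the 0-based indices of
#'   nucleotides missing at least one scheme atom.
#' @export
representative_coords <- function(structure, indices = NULL,
                                  scheme = "c1_prime") {
  if (is.null(indices)) indices <- seq_len(structure$n) - 1L
  if (length(indices) == 0L) {
    out <- matrix(numeric(0), 0, 3)
    attr(out, "flagged") <- integer(0)
    return(out)
  }
  if (min(indices) < 0 || max(indices) >= structure$n)
    stop("nucleotide index out of range")
  if (scheme == "c1_prime") {
    out <- structure$c1[indices + 1L, , drop = FALSE]
    miss <- indices[!stats::complete.cases(out)]
    out <- out[stats::complete.cases(out), , drop = FALSE]
    attr(out, "flagged") <- as.integer(miss)
    return(out)
  }
  rows <- list(); flagged <- integer(0)
  for (i in indices) {
    sub <- structure$atoms[structure$atoms$seq == i, , drop = FALSE]
    want <- .scheme_atoms(scheme, structure$base[i + 1L], sub$atom)
    got <- sub[match(want, sub$atom), , drop = FALSE]
    if (anyNA(got$x)) flagged <- c(flagged, i)
    got <- got[!is.na(got$x), , drop = FALSE]
    if (nrow(got)) rows[[length(rows) + 1L]] <- cbind(got$x, got$y, got$z)
  }
  out <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, 3)
  attr(out, "flagged") <- as.integer(flagged)
  out
}

# C1' coordinate matrix for 0-based indices; errors if any is missing
.c1 <- function(structure, indices) {
  m <- structure$c1[indices + 1L, , drop = FALSE]
  if (anyNA(m)) stop("missing C1' coordinate for nucleotide ",
                     paste(indices[!stats::complete.cases(m)], collapse = ","))
  m
}

#' Write an RNA structure as minimal PDBx/mmCIF
#'
#' Emits a single `atom_site` loop sufficient for `read_rna_structure` (and
#' bio3d) to round-trip the structure. Coordinates are written with three
#' decimals, the format's customary precision.
#'
#' @param structure an `rna_structure`.
#' @param path output file.
#' @param chain chain identifier to write (default "A").
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(structure, path, chain = "A") {
  at <- structure$atoms
  comp <- ifelse(structure$base[at$seq + 1L] == "other", "UNK",
                 structure$base[at$seq + 1L])
  ins <- structure$author$ins[at$seq + 1L]
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$structure_id)),
    "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
             "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf(paste0("ATOM %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f 1.00",
                   " 0.00 ? %d %s %s \"%s\" %d"),
            seq_len(nrow(at)), substr(at$atom, 1, 1), at$atom, comp, chain,
            at$seq + 1L, ifelse(ins == "", "?", ins),
            at$x, at$y, at$z,
            structure$author$num[at$seq + 1L], comp, chain, at$atom,
            structure$model),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Write an RNA structure (optionally transformed) as a PDB file
#'
#' Plain ATOM-record output used for visualising superposed structures.
#'
#' @param structure an `rna_structure`.
#' @param path output file.
#' @param chain chain identifier (single character).
#' @param transform optional list with `rotation` (3x3) and `translation`
#'   (length 3) applied to every coordinate before writing.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, chain = "A",
                                transform = NULL) {
  at <- structure$atoms
  xyz <- cbind(at$x, at$y, at$z)
  if (!is.null(transform))
    xyz <- sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
  comp <- ifelse(structure$base[at$seq + 1L] == "other", "UNK",
                 structure$base[at$seq + 1L])
  name4 <- sprintf("%-4s", substr(at$atom, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)), name4, comp, chain,
    structure$author$num[at$seq + 1L], xyz[, 1], xyz[, 2], xyz[, 3],
    substr(at$atom, 1, 1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
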