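#' Atomic structure container
#'
#' A `StructureModel` is an ordered table of atom records — the universal
#' input/output of every stage in this package. Columns: `chain`, `resno`
#' (author numbering), `ins` (insertion code, "" if none), `resname` (3-letter
#' code), `atom` (atom name), `element` (element symbol), `x`, `y`, `z`
#' (Angstrom), `occ` (occupancy), `altloc`.
#'
#' @param atoms data.frame with the columns above (missing optional columns
#'   `ins`, `element`, `occ`, `altloc` are filled with defaults).
#' @param label provenance tag (free text).
#' @return Object of class `StructureModel`.
#' @export
structure_model <- function(atoms, label = "") {
  req <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty model: no atom records")
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom records")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom records after altloc resolution, e.g. ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "StructureModel")
}

atom_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|")
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

guess_element <- function(atom_names) {
  e <- sub("^[0-9]*", "", atom_names)
  ifelse(substr(e, 1, 1) %in% c("C", "N", "O", "S", "P", "H"),
         substr(e, 1, 1), substr(toupper(e), 1, 2))
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel%s: %d atoms, %d residues, chains %s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(a), length(unique(residue_key(a))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' @export
summary.StructureModel <- function(object, ...) {
  a <- object$atoms
  cat(sprintf("StructureModel [%s]\n", object$label))
  for (ch in unique(a$chain)) {
    s <- a[a$chain == ch, ]
    cat(sprintf("  chain %s: residues %d-%d (%d residues, %d atoms)\n",
                ch, min(s$resno), max(s$resno),
                length(unique(residue_key(s))), nrow(s)))
  }
  invisible(object)
}

#' Atom coordinates of a model
#' @param model A [structure_model()].
#' @return n x 3 numeric matrix, Angstrom.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates of a model
#' @param model A [structure_model()].
#' @param xyz n x 3 matrix matching the model's atom count.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Apply a rigid transform to a whole model
#' @param model A [structure_model()].
#' @param transform A [rigid_transform()].
#' @export
transform_model <- function(model, transform) {
  set_coords(model, apply_transform(transform, coords(model)))
}

# Expand a list of inclusive residue ranges (or plain vectors) to numbers.
# Ranges are author-numbered and inclusive on both ends.
expand_ranges <- function(ranges) {
  if (is.null(ranges)) return(NULL)
  if (!is.list(ranges)) ranges <- list(ranges)
  unique(unlist(lapply(ranges, function(r) {
    if (length(r) == 2 && r[1] <= r[2]) seq(r[1], r[2]) else as.numeric(r)
  })))
}

#' Select atoms from a model
#'
#' Returns atoms in a deterministic order: residues in ascending
#' `(resno, ins)` order (restricted to the request), and within each residue
#' the fixed order of `atoms` as given (default backbone N, CA, C, O). The
#' order is independent of the atom order in the source file.
#'
#' @param model A [structure_model()].
#' @param chain chain id; `NULL` selects the first chain in the model.
#' @param residues inclusive residue range `c(from, to)`, list of ranges, or
#'   vector of residue numbers; `NULL` selects all.
#' @param atoms character vector of atom names defining the within-residue
#'   order; `NULL` keeps every atom (file order within residue).
#' @param strict if `TRUE` (default), a requested atom missing from a selected
#'   residue is an error naming the residue; if `FALSE`, missing atoms are
#'   reported in the `missing` attribute of the result.
#' @param allow_empty if `FALSE` (default), an empty selection is an error.
#' @return A data.frame of the selected atom records (ordered), with the
#'   coordinate matrix in attribute `xyz` and any tolerated omissions in
#'   attribute `missing`.
#' @export
select_atoms <- function(model, chain = NULL, residues = NULL,
                         atoms = c("N", "CA", "C", "O"),
                         strict = TRUE, allow_empty = FALSE) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  if (!chain %in% a$chain) stop("chain \"", chain, "\" not present in model")
  a <- a[a$chain == chain, , drop = FALSE]
  resnos <- expand_ranges(residues)
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  a <- a[order(a$resno, a$ins), , drop = FALSE]
  missing <- character(0)
  if (!is.null(atoms)) {
    pieces <- list()
    for (rk in unique(residue_key(a))) {
      res <- a[residue_key(a) == rk, , drop = FALSE]
      hit <- atoms %in% res$atom
      if (!all(hit)) {
        msg <- sprintf("residue %s %s missing atom(s) %s", res$resname[1], rk,
                       paste(atoms[!hit], collapse = ","))
        if (strict) stop(msg)
        missing <- c(missing, msg)
      }
      pieces[[rk]] <- res[match(atoms[hit], res$atom), , drop = FALSE]
    }
    a <- if (length(pieces))
      do.call(rbind, c(pieces, list(make.row.names = FALSE)))
    else model$atoms[0, , drop = FALSE]
  }
  if (!nrow(a) && !allow_empty) stop("selection is empty")
  rownames(a) <- NULL
  attr(a, "xyz") <- as.matrix(a[, c("x", "y", "z")])
  attr(a, "missing") <- missing
  a
}

# Backbone coordinate matrix for a residue set; convenience over select_atoms.
backbone_xyz <- function(model, chain = NULL, residues = NULL, strict = TRUE) {
  sel <- select_atoms(model, chain, residues, c("N", "CA", "C", "O"),
                      strict = strict, allow_empty = FALSE)
  attr(sel, "xyz")
}

# Three-letter to one-letter amino-acid code; nonstandard residues map to "X",
# except common modified residues with a clear parent (MSE -> M, etc.).
AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S", TPO = "T")

#' Extract the one-letter sequence of a chain
#'
#' @param model A [structure_model()].
#' @param chain chain id; `NULL` selects the first chain.
#' @return List with `sequence` (one-letter string, nonstandard residues as
#'   "X") and `numbers` (parallel vector of author residue numbers; numbering
#'   gaps are reflected in `numbers`, the sequence carries no gap character).
#' @export
extract_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  if (!chain %in% a$chain) stop("chain \"", chain, "\" not present in model")
  a <- a[a$chain == chain, , drop = FALSE]
  a <- a[order(a$resno, a$ins), , drop = FALSE]
  keep <- !duplicated(residue_key(a))
  res <- a[keep, , drop = FALSE]
  letters1 <- unname(AA_321[res$resname])
  letters1[is.na(letters1)] <- "X"
  list(sequence = paste(letters1, collapse = ""), numbers = res$resno)
}
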