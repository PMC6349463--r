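#' Read a macromolecular structure file
#'
#' Parses PDB or mmCIF (dispatched on file extension: `.cif`/`.mmcif` vs
#' anything else) via bio3d and returns a [structure_model()]. Hydrogens are
#' always dropped and waters always excluded; heteroatom residues (ligands,
#' lipids) are kept only when `het = TRUE`. Alternate locations are resolved
#' per `altloc_policy`.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model_index 1-based model number for multi-model files.
#' @param chains chain ids to keep; `NULL` keeps all. A requested chain absent
#'   from the file is an error naming the chain.
#' @param altloc_policy `"highest"` (default: keep the highest-occupancy
#'   altloc of each atom, ties broken in favour of altloc "A"), or a single
#'   letter to keep that altloc (plus un-lettered atoms).
#' @param het keep non-water heteroatom records? Default `FALSE` (all metrics
#'   in this package are protein-only).
#' @return A [structure_model()] labelled with the file name.
#' @export
read_structure <- function(path, model_index = 1, chains = NULL,
                           altloc_policy = "highest", het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                               rm.alt = FALSE, verbose = FALSE))
  n_models <- max(1L, nrow(pdb$xyz))
  if (model_index < 1 || model_index > n_models)
    stop("model ", model_index, " not present (file has ", n_models, " model(s))")
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$chain[is.na(at$chain)] <- " "
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(at$chain))
    if (length(absent))
      stop("chain \"", paste(absent, collapse = "\",\""),
           "\" not present in ", path)
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  elesy <- at$elesy
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess_element(at$elety[is.na(elesy) | !nzchar(elesy)])
  at <- at[toupper(elesy) != "H", , drop = FALSE]
  if (!nrow(at)) stop("no atoms left after filtering in ", path)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at <- resolve_altlocs(at, altloc_policy)
  atoms <- data.frame(chain = at$chain, resno = at$resno, ins = at$insert,
                      resname = at$resid, atom = at$elety,
                      element = toupper(at$elesy), x = at$x, y = at$y, z = at$z,
                      occ = pmin(1, pmax(0, at$o)), altloc = at$alt,
                      stringsAsFactors = FALSE)
  atoms$element[is.na(atoms$element) | !nzchar(atoms$element)] <-
    guess_element(atoms$atom[is.na(atoms$element) | !nzchar(atoms$element)])
  structure_model(atoms, label = basename(path))
}

resolve_altlocs <- function(at, policy) {
  if (!any(nzchar(at$alt))) return(at)
  if (identical(policy, "highest")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    # order: occupancy descending, then altloc letter ascending ("" sorts first,
    # which only matters for malformed duplicates); keep the first of each key
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at[order(as.integer(rownames(at))), , drop = FALSE]
  } else if (is.character(policy) && nchar(policy) == 1) {
    at[at$alt %in% c("", policy), , drop = FALSE]
  } else stop("unknown altloc policy: ", policy)
}

fmt_pdb_atom_name <- function(name, element) {
  # standard PDB alignment: element symbol occupies columns 13-14
  ifelse(nchar(name) >= 4, substr(paste0(name, "   "), 1, 4),
         ifelse(nchar(element) == 2, substr(paste0(name, "    "), 1, 4),
                substr(paste0(" ", name, "   "), 1, 4)))
}

pdb_atom_lines <- function(atoms, serial_start = 1L) {
  n <- nrow(atoms)
  serial <- (serial_start:(serial_start + n - 1L)) %% 100000L
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, fmt_pdb_atom_name(atoms$atom, atoms$element),
          substr(paste0(atoms$altloc, " "), 1, 1),
          atoms$resname, substr(paste0(atoms$chain, " "), 1, 1),
          atoms$resno %% 10000L, substr(paste0(atoms$ins, " "), 1, 1),
          round(atoms$x, 3), round(atoms$y, 3), round(atoms$z, 3),
          atoms$occ, 0, atoms$element)
}

#' Write a structure (or trajectory) as PDB
#'
#' Single models are written as plain ATOM records; a list of models (e.g. the
#' `frames` of a [interpolate_states()] trajectory) becomes a multi-model PDB
#' with `MODEL`/`ENDMDL` blocks. Coordinates are serialized to 3 decimals.
#'
#' @param model A [structure_model()], a `StateModel`, a `Trajectory`, or a
#'   list of `StructureModel`/`StateModel` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  models <- if (inherits(model, "StructureModel")) list(model)
    else if (inherits(model, "StateModel")) list(model$model)
    else if (inherits(model, "Trajectory")) lapply(model$frames, function(f) f$model)
    else if (is.list(model)) lapply(model, function(m)
      if (inherits(m, "StateModel")) m$model else m)
    else stop("cannot write object of class ", paste(class(model), collapse = "/"))
  if (!length(models)) stop("empty model list")
  for (m in models) if (!inherits(m, "StructureModel") || !nrow(m$atoms))
    stop("empty or invalid model")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (i in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(models[[i]]$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write chain sequences as FASTA
#'
#' @param model A [structure_model()].
#' @param path output file path.
#' @param chains chains to write; `NULL` writes all.
#' @export
write_fasta <- function(model, path, chains = NULL) {
  if (is.null(chains)) chains <- unique(model$atoms$chain)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    s <- extract_sequence(model, ch)
    writeLines(c(sprintf(">%s_%s", model$label, ch),
                 gsub("(.{60})", "\\1\n", s$sequence)), con)
  }
  invisible(path)
}
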