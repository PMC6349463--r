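#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `mobile` onto `target` over paired
#' coordinates. The optimal rotation is obtained from the SVD of the
#' covariance of the centered point sets, with the reflection corrected so the
#' result is always a proper rotation. The returned transform maps mobile
#' coordinates into the target frame; the RMSD is computed after applying it.
#'
#' @param mobile,target n x 3 paired coordinate matrices (n >= 3,
#'   non-collinear).
#' @return Object of class `SuperpositionResult`: `transform`
#'   ([rigid_transform()]), `rmsd` (Angstrom), `n_atoms_used`,
#'   `n_atoms_input`, `rejected_residues` (empty here), `cycles` (1).
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3)
  if (nrow(mobile) != nrow(target)) stop("point sets differ in length")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points, got ", n)
  mc <- colMeans(mobile); tc <- colMeans(target)
  P <- sweep(mobile, 2, mc); Q <- sweep(target, 2, tc)
  C <- crossprod(P, Q)
  sv <- svd(C)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) geometry: rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- tc - drop(R %*% mc)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(transform = rigid_transform(R, tvec), rmsd = rmsd,
                 n_atoms_used = n, n_atoms_input = n,
                 rejected_residues = character(0), cycles = 1L),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d/%d atoms (%d cycle%s%s)\n",
              x$rmsd, x$n_atoms_used, x$n_atoms_input, x$cycles,
              if (x$cycles == 1) "" else "s",
              if (length(x$rejected_residues))
                paste0("; rejected ", length(x$rejected_residues), " residue(s)")
              else ""))
  invisible(x)
}

#' Rigid superposition with iterative per-residue outlier rejection
#'
#' Emulates the cycle-and-reject behaviour of interactive alignment tools:
#' fit, reject every residue whose mean atom deviation exceeds
#' `cutoff_factor` times the current RMSD, and refit, until no residue is
#' rejected, fewer than 50% of the input atoms would remain, or `max_cycles`
#' is reached.
#'
#' @inheritParams kabsch
#' @param residue_ids character or numeric vector, one entry per atom row,
#'   grouping atoms into residues.
#' @param cutoff_factor rejection threshold as a multiple of the current
#'   RMSD (> 1; default 2).
#' @param max_cycles maximum fit/reject cycles (default 5).
#' @return A `SuperpositionResult` with `rejected_residues` and `cycles` set.
#' @export
iterative_superpose <- function(mobile, target, residue_ids,
                                cutoff_factor = 2, max_cycles = 5) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(length(residue_ids) == nrow(mobile),
            nrow(mobile) == nrow(target))
  if (cutoff_factor <= 1) stop("cutoff_factor must be > 1")
  residue_ids <- as.character(residue_ids)
  n_input <- nrow(mobile)
  keep <- rep(TRUE, n_input)
  rejected <- character(0)
  fit <- NULL
  for (cycle in seq_len(max_cycles)) {
    fit <- kabsch(mobile[keep, , drop = FALSE], target[keep, , drop = FALSE])
    dev <- sqrt(rowSums((apply_transform(fit$transform, mobile[keep, , drop = FALSE]) -
                           target[keep, , drop = FALSE])^2))
    res_dev <- tapply(dev, residue_ids[keep], mean)
    bad <- names(res_dev)[res_dev > cutoff_factor * fit$rmsd]
    if (!length(bad) || fit$rmsd == 0) break
    would_keep <- keep & !(residue_ids %in% bad)
    if (sum(would_keep) < 0.5 * n_input || sum(would_keep) < 3) break
    keep <- would_keep
    rejected <- union(rejected, bad)
    if (cycle == max_cycles) break
  }
  if (!any(keep)) stop("all residues rejected")
  fit$n_atoms_input <- n_input
  fit$n_atoms_used <- sum(keep)
  fit$rejected_residues <- rejected
  fit$cycles <- cycle
  fit
}

#' Global sequence alignment and residue correspondence
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap opening
#' 10, gap extension 0.5 by default), as a pinned, reproducible stand-in for
#' interactive alignment tools. Percent identity is the number of identical
#' aligned pairs divided by the number of alignment columns excluding
#' terminal gap columns.
#'
#' @param seq_a,seq_b one-letter amino-acid strings (uppercase; "X" allowed).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return Object of class `CorrespondenceMap`: data.frame with 1-based
#'   aligned positions `pos_a`, `pos_b` (strictly increasing in both), and
#'   attribute `percent_identity`.
#' @export
align_sequences <- function(seq_a, seq_b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ga <- a == "-"; gb <- b == "-"
  core <- which(!ga & !gb)
  if (!length(core)) stop("alignment has no aligned columns")
  # columns excluding end gaps: inside the span where both sequences have begun
  # and neither has ended
  span <- seq(min(which(!ga)), max(which(!ga)))
  span <- intersect(span, seq(min(which(!gb)), max(which(!gb))))
  ident <- sum(a[core] == b[core])
  pid <- 100 * ident / length(span)
  map <- data.frame(pos_a = cumsum(!ga)[core], pos_b = cumsum(!gb)[core])
  structure(map, percent_identity = pid, score = Biostrings::score(aln),
            class = c("CorrespondenceMap", "data.frame"))
}

#' @export
print.CorrespondenceMap <- function(x, ...) {
  cat(sprintf("CorrespondenceMap: %d aligned pairs, %.1f%% identity\n",
              nrow(x), attr(x, "percent_identity")))
  invisible(x)
}

#' Translate an alignment into residue-number pairs
#'
#' @param cmap a [align_sequences()] result (sequence-position pairs).
#' @param numbers_a,numbers_b residue-number vectors parallel to the two
#'   sequences (e.g. from [extract_sequence()]).
#' @return data.frame `resno_a`, `resno_b` with the alignment's attributes.
#' @export
correspondence_residues <- function(cmap, numbers_a, numbers_b) {
  out <- data.frame(resno_a = numbers_a[cmap$pos_a],
                    resno_b = numbers_b[cmap$pos_b])
  attr(out, "percent_identity") <- attr(cmap, "percent_identity")
  class(out) <- c("CorrespondenceMap", "data.frame")
  out
}

#' Per-residue Calpha displacement field between two models
#'
#' For each mapped residue pair, the distance between the Calpha of model A
#' (optionally after a global rigid fit of all mapped Calpha onto model B)
#' and the Calpha of model B.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param correspondence data.frame with `resno_a`, `resno_b` (see
#'   [correspondence_residues()]); for a shared numbering, pass identical
#'   columns.
#' @param frame `"global-fit"` (default: superpose all mapped Calpha first)
#'   or `"none"` (use raw coordinates).
#' @param chain_a,chain_b chain ids (`NULL`: first chain).
#' @return data.frame `resno_a`, `resno_b`, `displacement` (Angstrom).
#' @export
displacement_field <- function(model_a, model_b, correspondence,
                               frame = c("global-fit", "none"),
                               chain_a = NULL, chain_b = NULL) {
  frame <- match.arg(frame)
  if (!nrow(correspondence)) stop("empty correspondence")
  ca_a <- select_atoms(model_a, chain_a, correspondence$resno_a, "CA")
  ca_b <- select_atoms(model_b, chain_b, correspondence$resno_b, "CA")
  xa <- attr(ca_a, "xyz")[match(correspondence$resno_a, ca_a$resno), , drop = FALSE]
  xb <- attr(ca_b, "xyz")[match(correspondence$resno_b, ca_b$resno), , drop = FALSE]
  if (anyNA(xa) || anyNA(xb)) stop("Calpha missing for mapped residues")
  if (frame == "global-fit") xa <- apply_transform(kabsch(xa, xb)$transform, xa)
  data.frame(resno_a = correspondence$resno_a,
             resno_b = correspondence$resno_b,
             displacement = sqrt(rowSums((xa - xb)^2)))
}
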