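#' Fit a helix axis to Calpha coordinates
#'
#' Uses the bisector construction: for each interior Calpha the vector
#' `(p[i-1] - p[i]) + (p[i+1] - p[i])` points perpendicularly from the helix
#' toward the axis, so cross products of consecutive bisectors lie exactly
#' along the axis for ideal helical geometry, independent of segment length.
#' The direction is the (sign-aligned) mean of those cross products,
#' oriented N-to-C; if the bisectors are degenerate (straight chain) the
#' principal component of the Calpha cloud is used instead. The fit quality
#' is the fraction of positional variance of one-turn (4-residue) window
#' averages explained by the axis direction.
#'
#' @param ca n x 3 Calpha coordinate matrix in N-to-C residue order (n >= 4).
#' @return Object of class `HelixAxis`: `point` (centroid of the windowed
#'   trace), `direction` (unit vector, N->C), `fit_quality`.
#' @export
fit_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 Calpha positions, got ", n)
  H <- ca[1:(n - 2), , drop = FALSE] + ca[3:n, , drop = FALSE] -
    2 * ca[2:(n - 1), , drop = FALSE]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  chord <- ca[n, ] - ca[1, ]
  pairs <- which(upper.tri(diag(nrow(H))), arr.ind = TRUE)
  axes <- t(vapply(seq_len(nrow(pairs)), function(k)
    cr(H[pairs[k, 1], ], H[pairs[k, 2], ]), numeric(3)))
  norms <- sqrt(rowSums(axes^2))
  ok <- norms > 1e-9
  if (any(ok)) {
    axes <- axes[ok, , drop = FALSE] / norms[ok]
    flip <- axes %*% chord < 0
    axes[flip, ] <- -axes[flip, , drop = FALSE]
    dir <- colSums(axes)
  } else {
    dir <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
    if (sum(dir * chord) < 0) dir <- -dir
  }
  dir <- dir / sqrt(sum(dir^2))
  pts <- if (n >= 5) {
    w <- min(4L, n - 1L)
    t(vapply(seq_len(n - w + 1L), function(i)
      colMeans(ca[i:(i + w - 1L), , drop = FALSE]), numeric(3)))
  } else ca
  X <- sweep(pts, 2, colMeans(pts))
  fit_quality <- if (nrow(pts) > 1 && sum(X^2) > 0)
    sum((X %*% dir)^2) / sum(X^2) else 1
  structure(list(point = colMeans(pts), direction = dir,
                 fit_quality = fit_quality),
            class = "HelixAxis")
}

#' @export
print.HelixAxis <- function(x, ...) {
  cat(sprintf("HelixAxis: direction (%.3f, %.3f, %.3f), %.1f%% variance explained\n",
              x$direction[1], x$direction[2], x$direction[3],
              100 * x$fit_quality))
  invisible(x)
}

#' Helix kink angle at a break residue
#'
#' Fits independent axes to the `flank` residues on either side of
#' `break_residue` (the break residue itself belongs to neither fit) and
#' reports the angle between the two N-to-C directions. A straight helix
#' gives ~0 degrees; the angle grows as the helix bends.
#'
#' @param model A [structure_model()].
#' @param helix_span inclusive residue range `c(from, to)` of the helix.
#' @param break_residue residue number of the kink pivot; must be at least
#'   `flank + 1` residues from each end of the span.
#' @param flank residues per side used for the axis fits (default 7, about
#'   two helical turns).
#' @param chain chain id (`NULL`: first chain).
#' @return Object of class `KinkMeasurement`: `break_residue`, `angle_deg`
#'   in `[0, 180)`, and the two `HelixAxis` fits (`n_side_axis`,
#'   `c_side_axis`).
#' @export
kink_angle <- function(model, helix_span, break_residue, flank = 7,
                       chain = NULL) {
  if (break_residue - flank < helix_span[1] ||
      break_residue + flank > helix_span[2])
    stop("break residue ", break_residue, " is closer than flank+1 = ",
         flank + 1, " residues to an end of span ",
         helix_span[1], "-", helix_span[2])
  n_ca <- select_atoms(model, chain, c(break_residue - flank, break_residue - 1), "CA")
  c_ca <- select_atoms(model, chain, c(break_residue + 1, break_residue + flank), "CA")
  ax_n <- fit_axis(attr(n_ca, "xyz"))
  ax_c <- fit_axis(attr(c_ca, "xyz"))
  ct <- sum(ax_n$direction * ax_c$direction)
  structure(list(break_residue = break_residue,
                 angle_deg = acos(min(1, max(-1, ct))) * 180 / pi,
                 n_side_axis = ax_n, c_side_axis = ax_c),
            class = "KinkMeasurement")
}

#' @export
print.KinkMeasurement <- function(x, ...) {
  cat(sprintf("Kink at residue %d: %.1f deg\n", x$break_residue, x$angle_deg))
  invisible(x)
}
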