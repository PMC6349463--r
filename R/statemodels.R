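#' Conformational state model container
#'
#' Wraps a [structure_model()] with its state assignment and provenance, plus
#' the per-element rigid transforms that produced it.
#'
#' @param model A [structure_model()].
#' @param state_label one of `"c"`, `"m"`, `"occluded"`, `"frame"`.
#' @param provenance one of `"crystal"`, `"hybrid"`, `"symmetrized"`,
#'   `"interpolated"`.
#' @param element_transforms named list of [rigid_transform()] objects.
#' @param info free-form list (axis estimates, fit diagnostics, flags).
#' @return Object of class `StateModel`.
#' @export
state_model <- function(model, state_label = c("c", "m", "occluded", "frame"),
                        provenance = c("crystal", "hybrid", "symmetrized",
                                       "interpolated"),
                        element_transforms = list(), info = list()) {
  structure(list(model = model, state_label = match.arg(state_label),
                 provenance = match.arg(provenance),
                 element_transforms = element_transforms, info = info),
            class = "StateModel")
}

#' @export
print.StateModel <- function(x, ...) {
  cat(sprintf("StateModel: %s-state (%s), %d atoms, %d element transform(s)\n",
              x$state_label, x$provenance, nrow(x$model$atoms),
              length(x$element_transforms)))
  invisible(x)
}

#' Symmetry-related residue triples across the three domains
#'
#' Aligns domain 1 to domain 2 and domain 2 to domain 3 (global alignment of
#' the domain subsequences) and returns the residue triples placed by both
#' alignments — the symmetry-related positions used for axis estimation and
#' symmetrization.
#'
#' @param topology A [carrier_topology()].
#' @param sequence,numbers chain sequence and parallel residue numbers (from
#'   [extract_sequence()]).
#' @param min_triples minimum acceptable triple count (default 50); fewer
#'   indicates misconfigured or too-divergent domains and is an error.
#' @return data.frame `r1`, `r2`, `r3` of residue numbers.
#' @export
repeat_correspondence <- function(topology, sequence, numbers,
                                  min_triples = 50) {
  sub_dom <- function(d) {
    s <- topology$domain_spans[[d]]
    i <- which(numbers >= s[1] & numbers <= s[2])
    list(seq = paste(strsplit(sequence, "")[[1]][i], collapse = ""),
         num = numbers[i])
  }
  d1 <- sub_dom(1); d2 <- sub_dom(2); d3 <- sub_dom(3)
  a12 <- correspondence_residues(align_sequences(d1$seq, d2$seq), d1$num, d2$num)
  a23 <- correspondence_residues(align_sequences(d2$seq, d3$seq), d2$num, d3$num)
  shared <- intersect(a12$resno_b, a23$resno_a)
  triples <- data.frame(
    r1 = a12$resno_a[match(shared, a12$resno_b)],
    r2 = shared,
    r3 = a23$resno_b[match(shared, a23$resno_a)])
  if (nrow(triples) < min_triples)
    stop("only ", nrow(triples), " symmetry-related triples found (need ",
         min_triples, "); domains too divergent or misconfigured")
  triples
}

# Least-squares point on the rotation axis: solve (I - R) p = t by
# pseudoinverse (the axis direction is in the null space).
axis_point <- function(R, tvec) {
  A <- diag(3) - R
  sv <- svd(A)
  keep <- sv$d > 1e-8 * max(sv$d)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% tvec) / sv$d[keep]))
}

triplet_ca <- function(model, triples, chain = NULL) {
  lapply(1:3, function(d) {
    resnos <- triples[[d]]
    sel <- select_atoms(model, chain, resnos, "CA")
    xyz <- attr(sel, "xyz")[match(resnos, sel$resno), , drop = FALSE]
    if (anyNA(xyz)) stop("Calpha missing for symmetry triple residues")
    xyz
  })
}

#' Estimate the pseudo-C3 axis from domain triples
#'
#' Computes the rigid transforms domain1 -> domain2 and domain2 -> domain3
#' over the triplet Calpha sets; the axis is the mean rotation axis and the
#' per-transform residual is the deviation of the rotation angle from 120
#' degrees.
#'
#' @param model A [structure_model()].
#' @param triples A [repeat_correspondence()] result (>= 3 rows; the
#'   carrier-scale default minimum of 50 is enforced upstream).
#' @param chain chain id (`NULL`: first chain).
#' @return Object of class `AxisEstimate`: `point`, `direction` (unit),
#'   `residuals_deg` (named: D1D2, D2D3), `angles_deg`.
#' @export
estimate_c3_axis <- function(model, triples, chain = NULL) {
  X <- triplet_ca(model, triples, chain)
  f12 <- kabsch(X[[1]], X[[2]])
  f23 <- kabsch(X[[2]], X[[3]])
  a12 <- rotation_angle(f12$transform)
  a23 <- rotation_angle(f23$transform)
  if (a12$angle_deg < 30 || a23$angle_deg < 30)
    stop("degenerate inter-domain rotation (angle < 30 deg); no C3 axis")
  ax2 <- if (sum(a12$axis * a23$axis) < 0) -a23$axis else a23$axis
  dir <- a12$axis + ax2
  dir <- dir / sqrt(sum(dir^2))
  p12 <- axis_point(f12$transform$rotation, f12$transform$translation)
  p23 <- axis_point(f23$transform$rotation, f23$transform$translation)
  structure(list(point = (p12 + p23) / 2, direction = dir,
                 residuals_deg = c(D1D2 = abs(a12$angle_deg - 120),
                                   D2D3 = abs(a23$angle_deg - 120)),
                 angles_deg = c(D1D2 = a12$angle_deg, D2D3 = a23$angle_deg)),
            class = "AxisEstimate")
}

#' @export
print.AxisEstimate <- function(x, ...) {
  cat(sprintf("AxisEstimate: direction (%.3f, %.3f, %.3f); angle residuals %.2f / %.2f deg\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$residuals_deg[1], x$residuals_deg[2]))
  invisible(x)
}

#' Symmetrization parameters
#'
#' @param weight symmetry-restraint weight; retained for documentation of
#'   the emulated protocol. The domains are kept exactly rigid, which is the
#'   rigid-body (large-weight) limit, so the value does not enter the
#'   computation.
#' @param tol convergence tolerance: maximum per-atom displacement between
#'   iterations, A (default 0.01).
#' @param max_iter maximum iterations (default 50).
#' @export
symmetrize_params <- function(weight = 2, tol = 0.01, max_iter = 50) {
  stopifnot(weight > 0, tol > 0, max_iter >= 1)
  structure(list(weight = weight, tol = tol, max_iter = max_iter),
            class = "SymmetrizeParams")
}

# Robust C3-axis estimate used inside the symmetrization loop. Each of the
# three pairwise inter-domain transforms defines a candidate axis
# (orientation chosen so D(d) -> D(d+1) is the +120-degree sense); a domain
# displaced as a rigid body corrupts the two transforms that involve it but
# leaves the third exact, so the candidate whose two source domains agree
# best after sector mapping is selected (leave-one-domain-out consensus).
c3_axis_robust <- function(model, triples, chain = NULL) {
  X <- triplet_ca(model, triples, chain)
  fits <- list(kabsch(X[[2]], X[[3]]),   # excludes domain 1
               kabsch(X[[3]], X[[1]]),   # excludes domain 2
               kabsch(X[[1]], X[[2]]))   # excludes domain 3
  included <- list(c(2, 3), c(3, 1), c(1, 2))
  best <- NULL
  for (k in 1:3) {
    ra <- rotation_angle(fits[[k]]$transform)
    if (ra$angle_deg < 30) next
    p <- axis_point(fits[[k]]$transform$rotation,
                    fits[[k]]$transform$translation)
    cand <- list(direction = ra$axis, point = p)
    dd <- included[[k]]
    Y <- lapply(dd, function(d)
      apply_transform(rotation_about_line(cand$direction, -120 * (d - 1),
                                          cand$point), X[[d]]))
    resid <- mean(rowSums((Y[[1]] - Y[[2]])^2))
    if (is.null(best) || resid < best$resid)
      best <- c(cand, list(resid = resid))
  }
  if (is.null(best)) stop("degenerate inter-domain rotations; no C3 axis")
  best[c("direction", "point")]
}

# Blend atoms outside the listed rigid blocks between the flanking block
# transforms, linearly in residue number. blocks: data.frame(start, end) with
# parallel list of cumulative RigidTransforms; orig_xyz are untransformed
# coordinates.
blend_linkers <- function(atoms, orig_xyz, blocks, transforms) {
  out <- orig_xyz
  ord <- order(blocks$start)
  blocks <- blocks[ord, , drop = FALSE]
  transforms <- transforms[ord]
  in_block <- rep(NA_integer_, nrow(atoms))
  for (b in seq_len(nrow(blocks)))
    in_block[atoms$resno >= blocks$start[b] & atoms$resno <= blocks$end[b]] <- b
  for (b in seq_len(nrow(blocks))) {
    i <- which(in_block == b)
    out[i, ] <- apply_transform(transforms[[b]], orig_xyz[i, , drop = FALSE])
  }
  link <- which(is.na(in_block))
  for (i in link) {
    rn <- atoms$resno[i]
    prev <- which(blocks$end < rn)
    nxt <- which(blocks$start > rn)
    if (!length(prev)) {
      out[i, ] <- apply_transform(transforms[[min(nxt)]], orig_xyz[i, ])
    } else if (!length(nxt)) {
      out[i, ] <- apply_transform(transforms[[max(prev)]], orig_xyz[i, ])
    } else {
      b1 <- max(prev); b2 <- min(nxt)
      w <- (rn - blocks$end[b1]) / (blocks$start[b2] - blocks$end[b1])
      out[i, ] <- (1 - w) * apply_transform(transforms[[b1]], orig_xyz[i, ]) +
        w * apply_transform(transforms[[b2]], orig_xyz[i, ])
    }
  }
  out
}

#' Symmetrize a carrier structure about its pseudo-C3 axis
#'
#' Iteratively (1) maps each domain's triplet Calpha set into a common
#' sector by rotating it -0/-120/-240 degrees about the current axis,
#' (2) averages the three copies into a template, (3) rigidly fits each
#' domain of the crystal structure onto the template rotated back into its
#' sector (domains move as rigid bodies; internal geometry is untouched),
#' and (4) re-estimates the axis — until the largest per-atom move drops
#' below `params$tol` or `max_iter` is reached. The result is finally
#' re-anchored on domain 2 (the least-displaced domain in the inhibited
#' m-state) by superposing its triplet Calpha back onto the input.
#' Inter-domain linker atoms are blended linearly between the flanking
#' domain transforms.
#'
#' @param model A [structure_model()].
#' @param topology A [carrier_topology()].
#' @param triples A [repeat_correspondence()] result.
#' @param params A [symmetrize_params()].
#' @param chain chain id (`NULL`: first chain).
#' @return A [state_model()] with provenance `"symmetrized"`, per-domain
#'   transforms in `element_transforms` (D1, D2, D3), and `info` carrying
#'   the final `axis`, `converged` flag and iteration count.
#' @export
symmetrize <- function(model, topology, triples, params = symmetrize_params(),
                       chain = NULL) {
  atoms <- model$atoms
  orig_xyz <- coords(model)
  blocks <- data.frame(
    start = vapply(topology$domain_spans, `[`, numeric(1), 1),
    end = vapply(topology$domain_spans, `[`, numeric(1), 2))
  transforms <- list(rigid_transform(), rigid_transform(), rigid_transform())
  current <- model
  prev_xyz <- orig_xyz
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(params$max_iter)) {
    ax <- c3_axis_robust(current, triples, chain)
    X <- triplet_ca(current, triples, chain)
    Y <- lapply(1:3, function(d)
      apply_transform(rotation_about_line(ax$direction, -120 * (d - 1), ax$point),
                      X[[d]]))
    template <- (Y[[1]] + Y[[2]] + Y[[3]]) / 3
    # consensus weighting (iteratively reweighted): a domain displaced from
    # the template (e.g. by inhibitor binding) must not drag it along
    for (round in 1:5) {
      w <- vapply(Y, function(y)
        1 / (mean(rowSums((y - template)^2)) + 0.04), numeric(1))
      w <- w / sum(w)
      template <- w[1] * Y[[1]] + w[2] * Y[[2]] + w[3] * Y[[3]]
    }
    for (d in 1:3) {
      target <- apply_transform(
        rotation_about_line(ax$direction, 120 * (d - 1), ax$point), template)
      rt <- kabsch(X[[d]], target)$transform
      transforms[[d]] <- compose_transforms(rt, transforms[[d]])
    }
    new_xyz <- blend_linkers(atoms, orig_xyz, blocks, transforms)
    current <- set_coords(current, new_xyz)
    shift <- max(sqrt(rowSums((new_xyz - prev_xyz)^2)))
    prev_xyz <- new_xyz
    if (shift < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("symmetrize did not converge in ", params$max_iter, " iterations")
  # anchor the frame on domain 2
  r2 <- triples$r2
  sel <- select_atoms(current, chain, r2, "CA")
  now2 <- attr(sel, "xyz")[match(r2, sel$resno), , drop = FALSE]
  sel0 <- select_atoms(model, chain, r2, "CA")
  was2 <- attr(sel0, "xyz")[match(r2, sel0$resno), , drop = FALSE]
  anchor <- kabsch(now2, was2)$transform
  current <- transform_model(current, anchor)
  transforms <- lapply(transforms, function(tt) compose_transforms(anchor, tt))
  names(transforms) <- paste0("D", 1:3)
  final_axis <- estimate_c3_axis(current, triples, chain)
  state_model(current, "m", "symmetrized", transforms,
              info = list(axis = final_axis, converged = converged,
                          iterations = iter, params = params))
}

#' Build the uninhibited m-state model
#'
#' The uninhibited m-state is the pseudo-C3 symmetrized model of the
#' (inhibitor-displaced) m-state crystal structure; this is a thin wrapper
#' over [symmetrize()] with the state label set.
#'
#' @inheritParams symmetrize
#' @export
build_uninhibited_m <- function(model, topology, triples,
                                params = symmetrize_params(), chain = NULL) {
  symmetrize(model, topology, triples, params, chain)
}

# Backbone atom pairing between corresponding residues of two models.
paired_backbone <- function(model_a, resnos_a, model_b, resnos_b,
                            chain_a = NULL, chain_b = NULL) {
  sa <- select_atoms(model_a, chain_a, resnos_a, c("N", "CA", "C", "O"),
                     strict = FALSE, allow_empty = TRUE)
  sb <- select_atoms(model_b, chain_b, resnos_b, c("N", "CA", "C", "O"),
                     strict = FALSE, allow_empty = TRUE)
  ka <- paste(match(sa$resno, resnos_a), sa$atom)
  kb <- paste(match(sb$resno, resnos_b), sb$atom)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  list(xyz_a = attr(sa, "xyz")[ia, , drop = FALSE],
       xyz_b = attr(sb, "xyz")[ib, , drop = FALSE],
       resno_a = sa$resno[ia])
}

#' Build the uninhibited c-state model by element transplantation
#'
#' Each of the six core/gate elements of the m-state structure is
#' independently superposed (backbone least squares) onto the corresponding
#' residues of the c-state template; iterative outlier rejection is applied
#' only to the elements distorted by inhibitor binding in the template
#' (core element 2 and the H2 gate element by default). Linker residues
#' between elements are bridged by per-atom linear blending between the
#' flanking element placements.
#'
#' @param m_model m-state [structure_model()] providing the elements.
#' @param c_template c-state [structure_model()] providing the target frame.
#' @param elements A [derive_elements()] decomposition on `m_model`
#'   numbering.
#' @param correspondence data.frame `resno_a` (m numbering), `resno_b`
#'   (template numbering); for a shared numbering pass identical columns.
#' @param outlier_elements element ids fit with [iterative_superpose()]
#'   (default `c("core2", "gate1")`, i.e. core element 2 and the H2 gate).
#' @param chain_m,chain_c chain ids (`NULL`: first chain).
#' @return A [state_model()] with provenance `"hybrid"`, the six element
#'   transforms, and per-element fit diagnostics in `info$fits`.
#' @export
build_uninhibited_c <- function(m_model, c_template, elements, correspondence,
                                outlier_elements = c("core2", "gate1"),
                                chain_m = NULL, chain_c = NULL) {
  specs <- list()
  for (d in 1:3) {
    specs[[paste0("core", d)]] <- elements$core[[d]]
    specs[[paste0("gate", d)]] <- list(elements$gate[[d]])
  }
  fits <- list(); transforms <- list()
  blocks <- data.frame(start = numeric(0), end = numeric(0))
  for (id in names(specs)) {
    resnos_m <- expand_ranges(specs[[id]])
    sub <- correspondence[correspondence$resno_a %in% resnos_m &
                            !is.na(correspondence$resno_b), , drop = FALSE]
    if (nrow(sub) < 3)
      stop("element ", id, " has fewer than 3 matched residues")
    pb <- paired_backbone(m_model, sub$resno_a, c_template, sub$resno_b,
                          chain_m, chain_c)
    fit <- if (id %in% outlier_elements)
      iterative_superpose(pb$xyz_a, pb$xyz_b, pb$resno_a)
    else kabsch(pb$xyz_a, pb$xyz_b)
    fits[[id]] <- fit
    transforms[[id]] <- fit$transform
    rng <- range(resnos_m)
    blocks <- rbind(blocks, data.frame(start = rng[1], end = rng[2]))
  }
  new_xyz <- blend_linkers(m_model$atoms, coords(m_model), blocks, transforms)
  state_model(set_coords(m_model, new_xyz), "c", "hybrid", transforms,
              info = list(fits = fits))
}
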