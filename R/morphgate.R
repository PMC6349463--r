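#' Gate/accessibility parameters
#'
#' @param probe_radius solvent probe radius, A (default 1.4, a water).
#' @param grid_spacing grid cell edge, A (default 1.0; must not exceed the
#'   probe radius).
#' @param site_contact_distance a side counts as open when its solvent flood
#'   reaches a free cell within this distance of a binding-site atom
#'   (default 4.0 A).
#' @param channel_radius radial bound, A, about the axis within which the
#'   solvent flood is propagated (default 10). The membrane prevents lateral
#'   solvent passage around the protein, so accessibility is evaluated along
#'   the translocation channel only; without this bound the two face floods
#'   would trivially merge in the bulk solvent surrounding the molecule.
#' @param axis membrane normal (the pseudo-C3 axis), unit 3-vector.
#' @param matrix_side_sign +1 if the matrix side is the +axis face, -1 for
#'   the -axis face.
#' @param axis_point a point on the axis (default origin).
#' @export
gate_params <- function(probe_radius = 1.4, grid_spacing = 1.0,
                        site_contact_distance = 4.0, channel_radius = 10,
                        axis = c(0, 0, 1), matrix_side_sign = -1,
                        axis_point = c(0, 0, 0)) {
  if (grid_spacing > probe_radius)
    stop("grid_spacing must not exceed probe_radius")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 site_contact_distance = site_contact_distance,
                 channel_radius = channel_radius, axis = axis,
                 matrix_side_sign = sign(matrix_side_sign),
                 axis_point = as.numeric(axis_point)),
            class = "GateParams")
}

VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

#' Steric clash count
#'
#' Counts atom pairs from different, non-adjacent residues (|resno
#' difference| > 1 within a chain) closer than `clash_distance`.
#'
#' @param model A [structure_model()].
#' @param clash_distance A (default 2.6).
#' @return Integer pair count.
#' @export
clash_score <- function(model, clash_distance = 2.6) {
  a <- model$atoms
  if (nrow(a) < 2) return(0L)
  d <- as.matrix(stats::dist(coords(model)))
  close <- which(upper.tri(d) & d < clash_distance, arr.ind = TRUE)
  if (!nrow(close)) return(0L)
  i <- close[, 1]; j <- close[, 2]
  same_chain <- a$chain[i] == a$chain[j]
  bonded <- same_chain & abs(a$resno[i] - a$resno[j]) <= 1
  sum(!bonded)
}

# Frontier-based 3D flood fill over a logical free-cell array, vectorized
# over the frontier. seeds: linear indices.
flood_fill3d <- function(free, seeds, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  reached <- logical(length(free))
  frontier <- seeds[free[seeds]]
  reached[frontier] <- TRUE
  steps <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
  # x/y coordinates are needed to forbid wrap-around at grid faces
  ix <- function(idx) ((idx - 1L) %% nx) + 1L
  iy <- function(idx) (((idx - 1L) %/% nx) %% ny) + 1L
  while (length(frontier)) {
    nbrs <- integer(0)
    x <- ix(frontier); y <- iy(frontier)
    for (s in seq_along(steps)) {
      cand <- frontier + steps[s]
      ok <- cand >= 1L & cand <= length(free)
      if (s == 1) ok <- ok & x > 1L
      if (s == 2) ok <- ok & x < nx
      if (s == 3) ok <- ok & y > 1L
      if (s == 4) ok <- ok & y < ny
      nbrs <- c(nbrs, cand[ok])
    }
    nbrs <- unique(nbrs)
    nbrs <- nbrs[free[nbrs] & !reached[nbrs]]
    reached[nbrs] <- TRUE
    frontier <- nbrs
  }
  reached
}

#' Per-side accessibility of the substrate-binding site
#'
#' Operationalizes alternating access as a grid flood fill: a regular grid
#' (6 A margin around the model) is blocked wherever a cell center lies
#' within (atom vdW radius + probe radius) of an atom; the free cells are
#' flooded separately from the +axis and -axis faces of the box. A membrane
#' side is "accessible" when its flood reaches a free cell within
#' `site_contact_distance` of a binding-site residue atom; the state is
#' occluded when neither side is. The gate thickness is the axial extent of
#' the widest contiguous slab (restricted to within 8 A of the axis and to
#' the model's axial extent) containing no solvent-connected free cell.
#'
#' @param model A [structure_model()].
#' @param topology A [carrier_topology()] supplying `binding_site` residues.
#' @param params A [gate_params()].
#' @return Object of class `GateMetrics`: `accessible_from_matrix`,
#'   `accessible_from_cytoplasm`, `occluded`, `gate_thickness` (A),
#'   `clash_count`.
#' @export
gate_metrics <- function(model, topology, params = gate_params()) {
  site_res <- topology$binding_site
  if (!length(site_res)) stop("topology has no binding-site residues")
  a <- model$atoms
  site_sel <- a$resno %in% site_res
  if (!any(site_sel)) stop("binding-site residues missing from model")
  # rotate so the membrane normal is +z
  u <- params$axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  B <- rbind(e1, e2, u)                 # rows: new basis
  xyz <- coords(model) %*% t(B)
  axis_p <- drop(B %*% params$axis_point)
  h <- params$grid_spacing
  margin <- 6
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  gx <- seq(lo[1], hi[1], by = h); gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  blocked <- array(FALSE, c(nx, ny, nz))
  radii <- VDW_RADII[a$element]
  radii[is.na(radii)] <- 1.7
  rr <- radii + params$probe_radius
  for (i in seq_len(nrow(xyz))) {
    r <- rr[i]
    xi <- which(abs(gx - xyz[i, 1]) <= r)
    yi <- which(abs(gy - xyz[i, 2]) <= r)
    zi <- which(abs(gz - xyz[i, 3]) <= r)
    if (!length(xi) || !length(yi) || !length(zi)) next
    dx2 <- (gx[xi] - xyz[i, 1])^2
    dy2 <- (gy[yi] - xyz[i, 2])^2
    dz2 <- (gz[zi] - xyz[i, 3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    blocked[xi, yi, zi] <- blocked[xi, yi, zi] | within
  }
  free <- !as.vector(blocked)
  # restrict the solvent flood to the translocation channel: cells outside
  # channel_radius of the axis are off-limits (the membrane forbids lateral
  # passage around the protein)
  in_channel <- as.vector(
    array(outer((gx - axis_p[1])^2, (gy - axis_p[2])^2, `+`) <=
            params$channel_radius^2, c(nx, ny, nz)))
  free_ch <- free & in_channel
  cell_of <- function(k) {
    # linear indices of all cells in z-layer k
    base <- (k - 1L) * nx * ny
    base + seq_len(nx * ny)
  }
  reach_minus <- flood_fill3d(free_ch, cell_of(1L), c(nx, ny, nz))
  reach_plus <- flood_fill3d(free_ch, cell_of(nz), c(nx, ny, nz))
  # free cells near the binding site
  site_xyz <- xyz[site_sel, , drop = FALSE]
  near_site <- logical(length(free))
  sc <- params$site_contact_distance
  for (i in seq_len(nrow(site_xyz))) {
    xi <- which(abs(gx - site_xyz[i, 1]) <= sc)
    yi <- which(abs(gy - site_xyz[i, 2]) <= sc)
    zi <- which(abs(gz - site_xyz[i, 3]) <= sc)
    if (!length(xi) || !length(yi) || !length(zi)) next
    within <- outer(outer((gx[xi] - site_xyz[i, 1])^2,
                          (gy[yi] - site_xyz[i, 2])^2, `+`),
                    (gz[zi] - site_xyz[i, 3])^2, `+`) <= sc^2
    m <- array(FALSE, c(nx, ny, nz)); m[xi, yi, zi] <- within
    near_site <- near_site | as.vector(m)
  }
  acc_plus <- any(reach_plus & near_site & free)
  acc_minus <- any(reach_minus & near_site & free)
  if (params$matrix_side_sign > 0) {
    acc_matrix <- acc_plus; acc_cyto <- acc_minus
  } else {
    acc_matrix <- acc_minus; acc_cyto <- acc_plus
  }
  # gate thickness: widest contiguous axial slab, near the axis, with no
  # solvent-connected free cell; restricted to the model's axial extent
  reached <- (reach_plus | reach_minus) & free
  rad_ok <- outer((gx - axis_p[1])^2, (gy - axis_p[2])^2, `+`) <= 64
  z_in <- which(gz >= min(xyz[, 3]) & gz <= max(xyz[, 3]))
  open_layer <- vapply(z_in, function(k) {
    idx <- (k - 1L) * nx * ny + which(as.vector(rad_ok))
    any(reached[idx])
  }, logical(1))
  thickness <- 0
  if (length(open_layer)) {
    runs <- rle(!open_layer)
    if (any(runs$values)) thickness <- max(runs$lengths[runs$values]) * h
  }
  structure(list(accessible_from_matrix = acc_matrix,
                 accessible_from_cytoplasm = acc_cyto,
                 occluded = !acc_matrix && !acc_cyto,
                 gate_thickness = thickness,
                 clash_count = clash_score(model)),
            class = "GateMetrics")
}

#' @export
print.GateMetrics <- function(x, ...) {
  cat(sprintf("GateMetrics: matrix %s | cytoplasm %s | %s | gate %.1f A | %d clash(es)\n",
              if (x$accessible_from_matrix) "open" else "closed",
              if (x$accessible_from_cytoplasm) "open" else "closed",
              if (x$occluded) "OCCLUDED" else "accessible",
              x$gate_thickness, x$clash_count))
  invisible(x)
}

#' Element-wise morph between two conformational states
#'
#' For each core/gate element the A-to-B rigid transform is fitted (Kabsch
#' over the element atoms, which must correspond one-to-one by residue
#' number and atom name) and decomposed into a rotation about the element
#' centroid — interpolated at constant angular velocity about the fixed
#' rotation axis — and a linear centroid translation. Any residual
#' non-rigid difference is blended in linearly so the endpoints reproduce
#' the inputs exactly. Linker atoms are interpolated linearly.
#'
#' @param state_a,state_b [state_model()] (or bare [structure_model()])
#'   objects sharing residue numbering and atom composition.
#' @param elements A [derive_elements()] decomposition.
#' @param n_frames number of frames including both endpoints (>= 2).
#' @return Object of class `Trajectory`: `frames` (list of `StateModel`
#'   frames), `n_frames`.
#' @export
interpolate_states <- function(state_a, state_b, elements, n_frames = 21) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("n_frames must be >= 2")
  ma <- if (inherits(state_a, "StateModel")) state_a$model else state_a
  mb <- if (inherits(state_b, "StateModel")) state_b$model else state_b
  ka <- atom_key(ma$atoms); kb <- atom_key(mb$atoms)
  if (!identical(sort(ka), sort(kb)))
    stop("states do not share atom composition")
  mb_matched <- mb$atoms[match(ka, kb), , drop = FALSE]
  xa <- coords(ma)
  xb <- as.matrix(mb_matched[, c("x", "y", "z")])
  specs <- list()
  for (d in 1:3) {
    specs[[paste0("core", d)]] <- elements$core[[d]]
    specs[[paste0("gate", d)]] <- list(elements$gate[[d]])
  }
  parts <- lapply(names(specs), function(id) {
    sel <- ma$atoms$resno %in% expand_ranges(specs[[id]])
    if (sum(sel) < 3) stop("element ", id, " has fewer than 3 atoms")
    A <- xa[sel, , drop = FALSE]; Bm <- xb[sel, , drop = FALSE]
    fit <- kabsch(A, Bm)
    ra <- rotation_angle(fit$transform)
    cA <- colMeans(A); cB <- colMeans(Bm)
    resid <- Bm - apply_transform(fit$transform, A)
    list(id = id, sel = sel, angle = ra$angle_deg, axis = ra$axis,
         cA = cA, cB = cB, resid = resid)
  })
  in_element <- Reduce(`|`, lapply(parts, `[[`, "sel"))
  fracs <- seq(0, 1, length.out = n_frames)
  frames <- lapply(fracs, function(s) {
    if (s == 0)
      return(state_model(set_coords(ma, xa), "frame", "interpolated",
                         info = list(fraction = 0)))
    xyz <- (1 - s) * xa + s * xb        # linkers (and default)
    for (p in parts) {
      A <- xa[p$sel, , drop = FALSE]
      Rs <- rotation_about_axis(p$axis, s * p$angle)
      moved <- sweep(sweep(A, 2, p$cA) %*% t(Rs), 2,
                     p$cA + s * (p$cB - p$cA), `+`)
      xyz[p$sel, ] <- moved + s * p$resid
    }
    state_model(set_coords(ma, xyz), "frame", "interpolated",
                info = list(fraction = s))
  })
  # endpoint fidelity is exact by construction for s = 0; enforce bit-equality
  # for the final frame as well (guards rounding in the transform path)
  frames[[n_frames]]$model <- set_coords(ma, xb)
  structure(list(frames = frames, n_frames = n_frames), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms\n", x$n_frames,
              nrow(x$frames[[1]]$model$atoms)))
  invisible(x)
}

#' Occluded frames of a trajectory
#'
#' @param trajectory A [interpolate_states()] result (>= 3 frames), or any
#'   `Trajectory`.
#' @param topology A [carrier_topology()] with binding-site residues.
#' @param params A [gate_params()].
#' @return Integer vector of frame indices whose [gate_metrics()] report
#'   `occluded`; possibly empty.
#' @export
find_occluded_frames <- function(trajectory, topology, params = gate_params()) {
  if (trajectory$n_frames < 3) stop("trajectory must have at least 3 frames")
  occ <- vapply(trajectory$frames, function(f)
    gate_metrics(f$model, topology, params)$occluded, logical(1))
  which(occ)
}
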