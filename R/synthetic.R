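# Synthetic idealized helical bundles with known ground truth.
#
# These generators emulate the mitochondrial-carrier fold — six transmembrane
# helices around a central cavity with approximate C3 pseudosymmetry — well
# enough that every downstream stage (axis/kink fitting, superposition,
# network detection, symmetrization, morphing) can be tested against planted
# parameters without any structure downloads.

# Ideal alpha-helix cylindrical backbone template: radius (A), phase offset
# (deg) and axial offset (A) per backbone atom, relative to the Calpha.
HELIX_TEMPLATE <- data.frame(
  atom    = c("N", "CA", "C", "O"),
  element = c("N", "C", "C", "O"),
  r       = c(1.58, 2.30, 2.00, 2.00),
  dphi    = c(-28.0, 0.0, 26.0, 33.0),
  dz      = c(-0.90, 0.00, 0.55, 1.75)
)

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate an ideal alpha-helix, optionally kinked
#'
#' Backbone atoms (N, CA, C, O) are placed on an idealized cylindrical
#' alpha-helix (rise 1.5 A/residue, twist 100 deg/residue, Calpha radius
#' 2.3 A) running along +z from the origin. If a kink is requested, residues
#' after `kink_at` are rigidly rotated by `kink_angle` about an axis
#' perpendicular to the helix axis through the Calpha of the kink residue, so
#' the downstream axis direction is rotated by exactly `kink_angle`.
#'
#' @param n_res number of residues (>= 8).
#' @param kink_at 1-based residue index of the kink pivot, or `NULL` for a
#'   straight helix; must be at least 4 residues from either end.
#' @param kink_angle kink angle in degrees, in `[0, 120)`.
#' @param rise,twist,ca_radius helical parameters (A/residue, deg/residue, A).
#' @param chain,start_resno,resname identity of the generated residues.
#' @return A [structure_model()].
#' @export
make_ideal_helix <- function(n_res, kink_at = NULL, kink_angle = 0,
                             rise = 1.5, twist = 100, ca_radius = 2.3,
                             chain = "A", start_resno = 1, resname = "ALA") {
  if (n_res < 8) stop("n_res must be >= 8, got ", n_res)
  if (!is.null(kink_at)) {
    if (kink_at < 5 || kink_at > n_res - 4)
      stop("kink_at = ", kink_at, " is closer than 4 residues to a helix end")
    if (kink_angle < 0 || kink_angle >= 120)
      stop("kink_angle must be in [0, 120)")
  }
  tpl <- HELIX_TEMPLATE
  tpl$r <- tpl$r * (ca_radius / 2.30)
  idx <- rep(seq_len(n_res), each = nrow(tpl))
  phi <- ((idx - 1) * twist + tpl$dphi[rep(seq_len(nrow(tpl)), n_res)]) * pi / 180
  r <- tpl$r[rep(seq_len(nrow(tpl)), n_res)]
  z <- (idx - 1) * rise + tpl$dz[rep(seq_len(nrow(tpl)), n_res)]
  xyz <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(kink_at) && kink_angle > 0) {
    pivot <- xyz[(kink_at - 1) * nrow(tpl) + 2, ]   # CA of the kink residue
    after <- idx > kink_at
    R <- rotation_about_axis(c(1, 0, 0), kink_angle)
    xyz[after, ] <- sweep(sweep(xyz[after, , drop = FALSE], 2, pivot) %*% t(R),
                          2, pivot, `+`)
  }
  structure_model(data.frame(
    chain = chain, resno = start_resno + idx - 1, ins = "",
    resname = resname, atom = tpl$atom[rep(seq_len(nrow(tpl)), n_res)],
    element = tpl$element[rep(seq_len(nrow(tpl)), n_res)],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, altloc = "",
    stringsAsFactors = FALSE), label = "ideal-helix")
}

#' Specification of a synthetic pseudo-C3 bundle
#'
#' Captures every knob of the generator so that an identical spec and seed
#' give bit-identical output.
#'
#' @param n_helices total helix count, divisible by 3 (default 6: one odd and
#'   one even transmembrane helix per domain, as in the carrier fold).
#' @param residues_per_helix residues per helix (>= 8; default 30,
#'   approximately a membrane-spanning helix).
#' @param helix_rise,twist,ca_radius ideal helix parameters.
#' @param bundle_radius distance of each helix axis from the bundle (z) axis,
#'   A (default 8, giving a carrier-sized central cavity).
#' @param kinks data.frame with columns `helix`, `residue` (index within the
#'   helix), `angle` (deg); may be empty.
#' @param planted_pairs data.frame with columns `res_a`, `res_b` (bundle
#'   residue numbers), `distance` (A), `class` ("salt_bridge" or
#'   "hbond_brace"); may be empty.
#' @param perturbations list of `list(element = c(from, to), transform =
#'   rigid_transform)` applied about each element's centroid.
#' @param noise_sigma isotropic Gaussian coordinate noise, A (>= 0).
#' @param seed integer RNG seed for the noise.
#' @return A list of class `SyntheticBundleSpec`.
#' @export
synthetic_bundle_spec <- function(n_helices = 6, residues_per_helix = 30,
                                  helix_rise = 1.5, twist = 100,
                                  ca_radius = 2.3, bundle_radius = 8,
                                  kinks = NULL, planted_pairs = NULL,
                                  perturbations = list(),
                                  noise_sigma = 0, seed = 1) {
  if (n_helices %% 3 != 0) stop("n_helices must be divisible by 3")
  if (residues_per_helix < 8) stop("residues_per_helix must be >= 8")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(kinks) && nrow(kinks) &&
      any(kinks$angle < 0 | kinks$angle >= 120))
    stop("kink angles must be in [0, 120)")
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 helix_rise = helix_rise, twist = twist,
                 ca_radius = ca_radius, bundle_radius = bundle_radius,
                 kinks = kinks, planted_pairs = planted_pairs,
                 perturbations = perturbations,
                 noise_sigma = noise_sigma, seed = seed),
            class = "SyntheticBundleSpec")
}

# Residue-number layout: domain d (1..3) is offset by (d-1)*100; helix j
# within a domain starts at offset (j-1)*40 + 1. The numbering gap between
# helices stands in for the loops, which carry no atoms.
bundle_helix_span <- function(d, j, L) {
  s <- (d - 1) * 100 + (j - 1) * 40 + 1
  c(s, s + L - 1)
}

#' Generate a pseudo-C3 helical bundle with ground-truth annotation
#'
#' Helices of each domain are generated along +z (even-indexed helices
#' antiparallel), placed at `bundle_radius` from the z axis, and the domain
#' placements are related by exact 0/120/240-degree rotations about z, so an
#' unperturbed bundle is exactly C3-symmetric. Charged pseudo-atom pairs,
#' per-element rigid perturbations and Gaussian noise are then planted per
#' the spec, and their ground truth is returned alongside the topology.
#'
#' @param spec A [synthetic_bundle_spec()].
#' @return List with `model` (a [structure_model()]), `topology` (the
#'   ground-truth [carrier_topology()]), and `truth` (planted kinks, pairs
#'   and perturbation transforms).
#' @export
make_pseudo_c3_bundle <- function(spec) {
  stopifnot(inherits(spec, "SyntheticBundleSpec"))
  k <- spec$n_helices / 3
  L <- spec$residues_per_helix
  pieces <- list()
  for (d in 1:3) for (j in seq_len(k)) {
    h_global <- (d - 1) * k + j
    kk <- spec$kinks
    kk <- if (!is.null(kk) && nrow(kk)) kk[kk$helix == h_global, , drop = FALSE] else NULL
    span <- bundle_helix_span(d, j, L)
    h <- make_ideal_helix(L,
                          kink_at = if (!is.null(kk) && nrow(kk)) kk$residue[1] else NULL,
                          kink_angle = if (!is.null(kk) && nrow(kk)) kk$angle[1] else 0,
                          rise = spec$helix_rise, twist = spec$twist,
                          ca_radius = spec$ca_radius,
                          start_resno = span[1])
    xyz <- coords(h)
    zc <- mean(range(xyz[, 3]))
    if (j %% 2 == 0)   # antiparallel: flip about x through the helix mid-plane
      xyz <- apply_transform(rotation_about_line(c(1, 0, 0), 180, c(0, 0, zc)), xyz)
    xyz[, 1] <- xyz[, 1] + spec$bundle_radius
    az <- (d - 1) * 120 + (j - 1) * (120 / (k + 0.2))
    xyz <- xyz %*% t(rotation_about_axis(c(0, 0, 1), az))
    h <- set_coords(h, xyz)
    pieces[[h_global]] <- h$atoms
  }
  atoms <- do.call(rbind, pieces)
  # plant charged pseudo-atom pairs at exact distances
  pair_truth <- spec$planted_pairs
  if (!is.null(pair_truth) && nrow(pair_truth)) {
    for (i in seq_len(nrow(pair_truth))) {
      p <- pair_truth[i, ]
      types <- if (p$class == "salt_bridge")
        list(a = c("LYS", "NZ", "N"), b = c("ASP", "OD1", "O"))
      else list(a = c("TYR", "OH", "O"), b = c("ASP", "OD1", "O"))
      ca_a <- atoms[atoms$resno == p$res_a & atoms$atom == "CA", ]
      ca_b <- atoms[atoms$resno == p$res_b & atoms$atom == "CA", ]
      if (!nrow(ca_a) || !nrow(ca_b))
        stop("planted pair residue not in bundle: ", p$res_a, "/", p$res_b)
      A <- as.numeric(ca_a[1, c("x", "y", "z")])
      B <- as.numeric(ca_b[1, c("x", "y", "z")])
      u <- (B - A) / sqrt(sum((B - A)^2))
      m <- (A + B) / 2
      pa <- m - u * p$distance / 2
      pb <- m + u * p$distance / 2
      atoms$resname[atoms$resno == p$res_a] <- types$a[1]
      atoms$resname[atoms$resno == p$res_b] <- types$b[1]
      atoms <- rbind(atoms,
        data.frame(chain = "A", resno = c(p$res_a, p$res_b), ins = "",
                   resname = c(types$a[1], types$b[1]),
                   atom = c(types$a[2], types$b[2]),
                   element = c(types$a[3], types$b[3]),
                   x = c(pa[1], pb[1]), y = c(pa[2], pb[2]),
                   z = c(pa[3], pb[3]), occ = 1, altloc = "",
                   stringsAsFactors = FALSE))
    }
  }
  # binding-site pseudo side chains: a CB on each contact-point residue,
  # displaced radially toward the bundle axis so the substrate-binding site
  # lines the central cavity (as the carrier's binding-site side chains do)
  for (d in 1:3) {
    s <- bundle_helix_span(d, k, L)
    cp_res <- s[1] + ceiling(L / 2)
    ca <- atoms[atoms$resno == cp_res & atoms$atom == "CA", ]
    v <- as.numeric(ca[1, c("x", "y")])
    v <- v * (5.5 / sqrt(sum(v^2)))
    atoms <- rbind(atoms, data.frame(chain = "A", resno = cp_res, ins = "",
                                     resname = ca$resname[1], atom = "CB",
                                     element = "C", x = v[1], y = v[2],
                                     z = ca$z[1], occ = 1, altloc = "",
                                     stringsAsFactors = FALSE))
  }
  atoms <- atoms[order(atoms$resno, match(atoms$atom, c("N", "CA", "C", "O", "CB", "OH", "NZ", "OD1"))), ]
  model <- structure_model(atoms, label = "synthetic-c3-bundle")
  # ground-truth topology
  helix_spans <- list()
  for (d in 1:3) for (j in seq_len(k))
    helix_spans[[paste0("H", (d - 1) * k + j)]] <- bundle_helix_span(d, j, L)
  domain_spans <- lapply(1:3, function(d)
    c(bundle_helix_span(d, 1, L)[1], bundle_helix_span(d, k, L)[2]))
  names(domain_spans) <- paste0("D", 1:3)
  contact <- vapply(1:3, function(d) {
    s <- bundle_helix_span(d, k, L)
    s[1] + ceiling(L / 2)
  }, numeric(1))
  names(contact) <- paste0("H", (1:3) * k)
  net_sets <- list(matrix = integer(0), cyto = integer(0), braces = integer(0))
  if (!is.null(pair_truth) && nrow(pair_truth)) {
    ca <- atoms[atoms$atom == "CA", ]
    for (i in seq_len(nrow(pair_truth))) {
      p <- pair_truth[i, ]
      zc <- mean(ca$z[ca$resno %in% c(p$res_a, p$res_b)])
      if (p$class == "hbond_brace")
        net_sets$braces <- c(net_sets$braces, p$res_a, p$res_b)
      else if (zc >= 0)
        net_sets$cyto <- c(net_sets$cyto, p$res_a, p$res_b)
      else net_sets$matrix <- c(net_sets$matrix, p$res_a, p$res_b)
    }
  }
  topo <- carrier_topology(helix_spans = helix_spans,
                           domain_spans = domain_spans,
                           contact_points = contact,
                           binding_site = unname(contact),
                           matrix_network = unique(net_sets$matrix),
                           cytoplasmic_network = unique(net_sets$cyto),
                           braces = unique(net_sets$braces),
                           protein = "synthetic")
  # perturbations (recorded as global transforms about each element centroid)
  perturb_truth <- list()
  for (p in spec$perturbations) {
    res <- apply_rigid_perturbation(model, p$element, p$transform,
                                    noise_sigma = 0, seed = spec$seed)
    model <- res$model
    perturb_truth[[length(perturb_truth) + 1]] <-
      list(element = p$element, transform = res$truth)
  }
  if (spec$noise_sigma > 0) {
    xyz <- coords(model)
    noise <- with_local_seed(spec$seed,
      matrix(stats::rnorm(length(xyz), 0, spec$noise_sigma), ncol = 3))
    model <- set_coords(model, xyz + noise)
  }
  list(model = model, topology = topo,
       truth = list(kinks = spec$kinks, planted_pairs = pair_truth,
                    perturbations = perturb_truth))
}

#' Rigidly perturb one element of a model, with recorded ground truth
#'
#' The transform's rotation is applied about the element centroid and its
#' translation added on top; Gaussian noise (if any) is added to all atoms of
#' the model. The returned `truth` is the equivalent global
#' [rigid_transform()], so a downstream superposition of the element onto its
#' unperturbed copy should recover exactly its inverse.
#'
#' @param model A [structure_model()].
#' @param element inclusive residue range `c(from, to)` (or list of ranges).
#' @param transform A [rigid_transform()]; rotation taken about the element
#'   centroid.
#' @param noise_sigma Gaussian coordinate noise sd, A (applied to all atoms).
#' @param seed RNG seed for the noise.
#' @return List with `model` and `truth` (global `RigidTransform`).
#' @export
apply_rigid_perturbation <- function(model, element, transform,
                                     noise_sigma = 0, seed = 1) {
  resnos <- expand_ranges(element)
  sel <- model$atoms$resno %in% resnos
  if (!any(sel)) stop("element selects no atoms")
  xyz <- coords(model)
  ctr <- colMeans(xyz[sel, , drop = FALSE])
  R <- transform$rotation
  t_global <- ctr + transform$translation - drop(R %*% ctr)
  truth <- rigid_transform(R, t_global)
  xyz[sel, ] <- apply_transform(truth, xyz[sel, , drop = FALSE])
  if (noise_sigma > 0)
    xyz <- xyz + with_local_seed(seed,
      matrix(stats::rnorm(length(xyz), 0, noise_sigma), ncol = 3))
  list(model = set_coords(model, xyz), truth = truth)
}

#' Generate a matched pair of synthetic conformational states
#'
#' State A is an unperturbed pseudo-C3 bundle; state B applies, in every
#' domain, the same local rotations to the core element (a "rocking" motion
#' about the tangential axis through the core centroid) and the gate element
#' (an inward rotation about the tangential axis through its centroid),
#' rotated into each domain's sector so that state B is exactly C3 whenever
#' state A is. The planted per-element transforms are returned as ground
#' truth for superposition, model building and morph metrics.
#'
#' @param spec A [synthetic_bundle_spec()] for the base bundle.
#' @param core_rotation_deg rocking angle of each core element (default 15).
#' @param gate_rotation_deg inward rotation of each gate element (default 12).
#' @return List with `state_a`, `state_b` (each `model` + `topology`),
#'   `elements` (the [derive_elements()] decomposition) and `truth`
#'   (per-element global transforms A -> B).
#' @export
make_synthetic_state_pair <- function(spec = synthetic_bundle_spec(),
                                      core_rotation_deg = 15,
                                      gate_rotation_deg = 12) {
  a <- make_pseudo_c3_bundle(spec)
  elements <- derive_elements(a$topology)
  model_b <- a$model
  truth <- list()
  Rz <- function(d) rotation_about_axis(c(0, 0, 1), 120 * (d - 1))
  xyz <- coords(a$model)
  for (d in 1:3) {
    for (kind in c("core", "gate")) {
      rng <- if (kind == "core") elements$core[[d]] else list(elements$gate[[d]])
      resnos <- expand_ranges(rng)
      sel <- a$model$atoms$resno %in% resnos
      ctr <- colMeans(xyz[sel, , drop = FALSE])
      # tangential axis for domain 1, rotated into domain d's sector
      az <- atan2(ctr[2], ctr[1])
      axis <- c(-sin(az), cos(az), 0)
      ang <- if (kind == "core") core_rotation_deg else gate_rotation_deg
      rt <- rotation_about_line(axis, ang, ctr)
      sel_b <- model_b$atoms$resno %in% resnos
      xb <- coords(model_b)
      xb[sel_b, ] <- apply_transform(rt, xb[sel_b, , drop = FALSE])
      model_b <- set_coords(model_b, xb)
      truth[[paste0(kind, d)]] <- rt
    }
  }
  list(state_a = a, state_b = list(model = model_b, topology = a$topology),
       elements = elements, truth = truth)
}
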