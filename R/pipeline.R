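#' Full m-state vs c-state structural comparison
#'
#' Drives the element-level analysis end to end: residue correspondence
#' between the two proteins, core/gate element decomposition, the six
#' element backbone superpositions (with outlier-rejected refits for the
#' inhibitor-distorted elements), kink angles of helix H3 at its signature
#' proline in both states, polar-contact networks of both states, and the
#' global-fit Calpha displacement field. Deterministic given inputs and
#' configuration.
#'
#' @param m_model m-state [structure_model()] (or `StateModel`).
#' @param c_model c-state [structure_model()] (or `StateModel`).
#' @param topology_m [carrier_topology()] on the m-model numbering.
#' @param topology_c topology on the c-model numbering; `NULL` derives it
#'   from `topology_m` through the sequence correspondence.
#' @param kink_flank flank length for kink-angle fits (default 7).
#' @param sb_cutoff,hb_cutoff polar-contact cutoffs, A.
#' @param chain_m,chain_c chain ids (`NULL`: first chain of each model).
#' @return Object of class `AnalysisReport`: `correspondence`, `elements`,
#'   `element_rmsds` (named per element), `element_fits`, `kink_angles`
#'   (per state), `networks` (per state, classified), `displacements`,
#'   `network_displacements` (cytoplasmic-network residues only).
#' @export
run_state_comparison <- function(m_model, c_model, topology_m,
                                 topology_c = NULL, kink_flank = 7,
                                 sb_cutoff = 4.0, hb_cutoff = 3.6,
                                 chain_m = NULL, chain_c = NULL) {
  if (inherits(m_model, "StateModel")) m_model <- m_model$model
  if (inherits(c_model, "StateModel")) c_model <- c_model$model
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop("stage [", what, "]: ", conditionMessage(e), call. = FALSE))
  seq_m <- stage("sequence", extract_sequence(m_model, chain_m))
  seq_c <- stage("sequence", extract_sequence(c_model, chain_c))
  cmap <- stage("correspondence",
                correspondence_residues(
                  align_sequences(seq_m$sequence, seq_c$sequence),
                  seq_m$numbers, seq_c$numbers))
  if (is.null(topology_c))
    topology_c <- stage("topology", map_topology(topology_m, cmap,
                                                 protein = "c-state"))
  elements <- stage("elements", derive_elements(topology_m))
  specs <- list()
  for (d in 1:3) {
    specs[[paste0("core", d)]] <- elements$core[[d]]
    specs[[paste0("gate", d)]] <- list(elements$gate[[d]])
  }
  fits <- list()
  for (id in names(specs)) {
    resnos_m <- expand_ranges(specs[[id]])
    sub <- cmap[cmap$resno_a %in% resnos_m, , drop = FALSE]
    pb <- stage(paste0("fit-", id),
                paired_backbone(m_model, sub$resno_a, c_model, sub$resno_b,
                                chain_m, chain_c))
    fits[[id]] <- stage(paste0("fit-", id), kabsch(pb$xyz_a, pb$xyz_b))
    fits[[paste0(id, "_rejected")]] <- stage(paste0("fit-", id),
      iterative_superpose(pb$xyz_a, pb$xyz_b, pb$resno_a))
  }
  rmsds <- vapply(names(specs), function(id) fits[[id]]$rmsd, numeric(1))
  # H3 kink at the signature proline of domain 2, both states
  kinks <- list()
  p_m <- topology_m$signature_prolines
  p_m <- p_m[residue_domain(p_m, topology_m) == 2]
  if (length(p_m) == 1 && !is.null(topology_m$helix_spans$H3)) {
    kinks$m <- stage("kink", kink_angle(m_model, topology_m$helix_spans$H3,
                                        p_m, kink_flank, chain_m))
    p_c <- cmap$resno_b[match(p_m, cmap$resno_a)]
    if (!is.na(p_c) && !is.null(topology_c$helix_spans$H3))
      kinks$c <- stage("kink", kink_angle(c_model, topology_c$helix_spans$H3,
                                          p_c, kink_flank, chain_c))
  }
  networks <- list(
    m = stage("networks", classify_network(
      find_polar_contacts(m_model, topology_m, sb_cutoff, hb_cutoff, chain_m),
      topology_m)),
    c = stage("networks", classify_network(
      find_polar_contacts(c_model, topology_c, sb_cutoff, hb_cutoff, chain_c),
      topology_c)))
  disp <- stage("displacements",
                displacement_field(m_model, c_model, cmap, "global-fit",
                                   chain_m, chain_c))
  net_disp <- disp[disp$resno_a %in% topology_m$cytoplasmic_network, ,
                   drop = FALSE]
  structure(list(correspondence = cmap, elements = elements,
                 element_rmsds = rmsds, element_fits = fits,
                 kink_angles = kinks, networks = networks,
                 displacements = disp, network_displacements = net_disp),
            class = "AnalysisReport")
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport\n  element backbone RMSDs (A):\n")
  for (id in names(x$element_rmsds))
    cat(sprintf("    %-6s %.2f\n", id, x$element_rmsds[[id]]))
  if (length(x$kink_angles))
    for (st in names(x$kink_angles))
      cat(sprintf("  H3 kink (%s-state): %.1f deg\n", st,
                  x$kink_angles[[st]]$angle_deg))
  if (nrow(x$network_displacements))
    cat(sprintf("  cytoplasmic-network Calpha displacements: %.1f-%.1f A\n",
                min(x$network_displacements$displacement),
                max(x$network_displacements$displacement)))
  if (!is.null(x$rocking_angles))
    cat(sprintf("  core rocking angles: %s deg\n",
                paste(sprintf("%.1f", x$rocking_angles), collapse = ", ")))
  invisible(x)
}

#' Build uninhibited models, morph, and score the gates
#'
#' Builds the uninhibited m-state (pseudo-C3 symmetrization of the m-state
#' structure) and uninhibited c-state (element transplantation onto the
#' c-state template), aligns the c-state model onto the m-state frame,
#' interpolates an element-wise morph, and computes per-frame gate metrics
#' and the core-element rocking angles between the two built states.
#'
#' @inheritParams run_state_comparison
#' @param n_frames morph frame count (default 21).
#' @param params_sym A [symmetrize_params()].
#' @param params_gate A [gate_params()]; `NULL` derives the axis from the
#'   pseudo-C3 estimate and the matrix side from the matrix-network
#'   residues' axial position.
#' @param min_triples minimum symmetry-triple count (see
#'   [repeat_correspondence()]).
#' @return List of class `MorphReport`: `model_c`, `model_m` (StateModels),
#'   `trajectory`, `rocking_angles` (named per core element, degrees),
#'   `gate_table` (per-frame data.frame), `occluded_frames`, `axis`.
#' @export
run_model_building_and_morph <- function(m_model, c_model, topology_m,
                                         topology_c = NULL, n_frames = 21,
                                         params_sym = symmetrize_params(),
                                         params_gate = NULL,
                                         min_triples = 50,
                                         chain_m = NULL, chain_c = NULL) {
  if (inherits(m_model, "StateModel")) m_model <- m_model$model
  if (inherits(c_model, "StateModel")) c_model <- c_model$model
  seq_m <- extract_sequence(m_model, chain_m)
  seq_c <- extract_sequence(c_model, chain_c)
  cmap <- correspondence_residues(
    align_sequences(seq_m$sequence, seq_c$sequence),
    seq_m$numbers, seq_c$numbers)
  elements <- derive_elements(topology_m)
  triples <- repeat_correspondence(topology_m, seq_m$sequence, seq_m$numbers,
                                   min_triples = min_triples)
  built_m <- build_uninhibited_m(m_model, topology_m, triples, params_sym,
                                 chain_m)
  built_c <- build_uninhibited_c(m_model, c_model, elements, cmap,
                                 chain_m = chain_m, chain_c = chain_c)
  # bring the c-state model into the m-state frame before morphing
  shared <- intersect(built_c$model$atoms$resno, built_m$model$atoms$resno)
  ca_c <- select_atoms(built_c$model, chain_m, shared, "CA")
  ca_m <- select_atoms(built_m$model, chain_m, shared, "CA")
  common <- intersect(ca_c$resno, ca_m$resno)
  align <- kabsch(attr(ca_c, "xyz")[match(common, ca_c$resno), ],
                  attr(ca_m, "xyz")[match(common, ca_m$resno), ])
  built_c$model <- transform_model(built_c$model, align$transform)
  # core rocking: per-core-element rigid fit between the built states
  rocking <- vapply(1:3, function(d) {
    resnos <- expand_ranges(elements$core[[d]])
    pb <- paired_backbone(built_c$model, resnos, built_m$model, resnos,
                          chain_m, chain_m)
    rotation_angle(kabsch(pb$xyz_a, pb$xyz_b)$transform)$angle_deg
  }, numeric(1))
  names(rocking) <- paste0("core", 1:3)
  trajectory <- interpolate_states(built_c, built_m, elements, n_frames)
  if (is.null(params_gate)) {
    ax <- built_m$info$axis
    mat_res <- topology_m$matrix_network
    side <- 1
    if (length(mat_res)) {
      sel <- m_model$atoms$resno %in% mat_res
      proj <- coords(m_model)[sel, , drop = FALSE] %*% ax$direction
      all_proj <- coords(m_model) %*% ax$direction
      side <- if (mean(proj) < mean(all_proj)) -1 else 1
    }
    params_gate <- gate_params(axis = ax$direction, matrix_side_sign = side,
                               axis_point = ax$point)
  }
  gm <- lapply(trajectory$frames, function(f)
    gate_metrics(f$model, topology_m, params_gate))
  gate_table <- data.frame(
    frame = seq_along(gm),
    accessible_from_matrix = vapply(gm, `[[`, logical(1), "accessible_from_matrix"),
    accessible_from_cytoplasm = vapply(gm, `[[`, logical(1), "accessible_from_cytoplasm"),
    occluded = vapply(gm, `[[`, logical(1), "occluded"),
    gate_thickness = vapply(gm, `[[`, numeric(1), "gate_thickness"),
    clash_count = vapply(gm, `[[`, numeric(1), "clash_count"))
  structure(list(model_c = built_c, model_m = built_m,
                 trajectory = trajectory, rocking_angles = rocking,
                 gate_table = gate_table,
                 occluded_frames = which(gate_table$occluded),
                 axis = built_m$info$axis),
            class = "MorphReport")
}

#' @export
print.MorphReport <- function(x, ...) {
  cat(sprintf("MorphReport: %d frames; core rocking %s deg; %d occluded frame(s)\n",
              x$trajectory$n_frames,
              paste(sprintf("%.1f", x$rocking_angles), collapse = "/"),
              length(x$occluded_frames)))
  invisible(x)
}

#' Export a superposition or transform set as JSON
#'
#' @param x a `SuperpositionResult`, `RigidTransform`, or named list of
#'   either.
#' @param path output file.
#' @export
write_transforms_json <- function(x, path) {
  enc <- function(v) {
    if (inherits(v, "SuperpositionResult"))
      list(rotation = v$transform$rotation, translation = v$transform$translation,
           rmsd = v$rmsd, n_atoms_used = v$n_atoms_used,
           n_atoms_input = v$n_atoms_input,
           rejected_residues = v$rejected_residues, cycles = v$cycles)
    else if (inherits(v, "RigidTransform"))
      list(rotation = v$rotation, translation = v$translation)
    else lapply(v, enc)
  }
  jsonlite::write_json(enc(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
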