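bundle_with_triples <- function(spec = synthetic_bundle_spec()) {
  b <- make_pseudo_c3_bundle(spec)
  s <- extract_sequence(b$model)
  b$triples <- repeat_correspondence(b$topology, s$sequence, s$numbers)
  b
}

test_that("identical repeats correspond residue-for-residue", {
  b <- bundle_with_triples()
  expect_identical(nrow(b$triples), 60L)
  expect_equal(b$triples$r2, b$triples$r1 + 100)
  expect_equal(b$triples$r3, b$triples$r1 + 200)
})

test_that("a repeat insertion is skipped by the triple correspondence", {
  # hand-built sequence/numbering: domain 2 carries a 2-residue insertion
  dom <- "GAVLIMFWPSTCYNQDEKRHGAVLIMFWPSTCYNQDEKRHGAVLIMFWPS"
  ins <- paste0(substr(dom, 1, 25), "WW", substr(dom, 26, 50))
  seqs <- paste0(dom, ins, dom)
  numbers <- c(1:50, 101:152, 201:250)
  topo <- carrier_topology(
    helix_spans = list(H2 = c(1, 50), H4 = c(101, 152), H6 = c(201, 250)),
    domain_spans = list(D1 = c(1, 50), D2 = c(101, 152), D3 = c(201, 250)),
    contact_points = c(H2 = 25, H4 = 125, H6 = 225), protein = "synthetic")
  tr <- repeat_correspondence(topo, seqs, numbers, min_triples = 40)
  expect_identical(nrow(tr), 50L)
  # insertion positions of domain 2 (126, 127) are in no triple
  expect_false(any(tr$r2 %in% c(126, 127)))
  expect_equal(tr$r3, tr$r1 + 200)
  expect_error(repeat_correspondence(topo, seqs, numbers, min_triples = 60),
               "triples")
})

test_that("the C3 axis is recovered, also after a global rotation", {
  b <- bundle_with_triples()
  ax <- estimate_c3_axis(b$model, b$triples)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), cos(1 * pi / 180))
  expect_lt(max(ax$residuals_deg), 0.5)
  R <- rotation_about_axis(c(1, 1, 0), 40)
  moved <- transform_model(b$model, rigid_transform(R, c(3, -2, 7)))
  ax2 <- estimate_c3_axis(moved, b$triples)
  expect_gt(abs(sum(ax2$direction * drop(R %*% c(0, 0, 1)))),
            cos(1 * pi / 180))
})

test_that("symmetrization is idempotent and keeps domains internally rigid", {
  b <- bundle_with_triples()
  rt <- rotation_about_line(c(0.3, 0.2, 0.93), 8, c(5, -3, 10))
  pert <- apply_rigid_perturbation(b$model, c(1, 70), rt)
  sm <- symmetrize(pert$model, b$topology, b$triples)
  expect_true(sm$info$converged)
  # idempotence: a second pass moves nothing beyond the tolerance
  sm2 <- symmetrize(sm$model, b$topology, b$triples)
  expect_lt(max_coord_dev(sm2$model, sm$model), 0.01)
  # internal geometry of each domain preserved exactly
  for (d in 1:3) {
    sel <- pert$model$atoms$resno %in%
      seq(b$topology$domain_spans[[d]][1], b$topology$domain_spans[[d]][2])
    d_before <- stats::dist(coords(pert$model)[sel, ][1:40, ])
    d_after <- stats::dist(coords(sm$model)[sel, ][1:40, ])
    expect_lt(max(abs(d_before - d_after)), 1e-6)
  }
})

test_that("symmetrization removes a planted single-domain displacement", {
  b <- bundle_with_triples()
  for (rt in list(rotation_about_line(c(0.3, 0.2, 0.93), 8, c(5, -3, 10)),
                  rigid_transform(diag(3), c(2, -1, 1.5)))) {
    pert <- apply_rigid_perturbation(b$model, c(1, 70), rt)
    sm <- symmetrize(pert$model, b$topology, b$triples)
    ca <- sm$model$atoms$atom == "CA"
    rmsd <- sqrt(mean(rowSums(
      (coords(sm$model)[ca, ] - coords(b$model)[ca, ])^2)))
    expect_lt(rmsd, 0.5)
    # the displaced domain moves back; the others barely move
    shifts <- vapply(sm$element_transforms, function(tt)
      rotation_angle(tt)$angle_deg +
        sqrt(sum(tt$translation^2)) / 10, numeric(1))
    expect_gt(shifts[["D1"]], 2 * shifts[["D2"]])
    expect_gt(shifts[["D1"]], 2 * shifts[["D3"]])
  }
})

test_that("the m-state builder lowers the axis residuals of its input", {
  b <- bundle_with_triples()
  pert <- apply_rigid_perturbation(b$model, c(1, 70),
                                   rotation_about_line(c(0, 1, 0), 10, c(8, 0, 20)))
  before <- estimate_c3_axis(pert$model, b$triples)
  built <- build_uninhibited_m(pert$model, b$topology, b$triples)
  expect_identical(built$state_label, "m")
  expect_identical(built$provenance, "symmetrized")
  after <- built$info$axis
  expect_lt(max(after$residuals_deg), max(before$residuals_deg))
})

test_that("hybrid c-state building is exact on self and on planted states", {
  sp <- make_synthetic_state_pair()
  resnos <- sort(unique(sp$state_a$model$atoms$resno))
  cmap <- data.frame(resno_a = resnos, resno_b = resnos)
  self <- build_uninhibited_c(sp$state_a$model, sp$state_a$model,
                              sp$elements, cmap)
  expect_lt(max_coord_dev(self$model, sp$state_a$model), 1e-9)
  for (tt in self$element_transforms)
    expect_lt(rotation_angle(tt)$angle_deg, 1e-4)
  # transplanting perturbed elements onto the unperturbed template recovers it
  rebuilt <- build_uninhibited_c(sp$state_b$model, sp$state_a$model,
                                 sp$elements, cmap)
  expect_lt(max_coord_dev(rebuilt$model, sp$state_a$model), 1e-9)
  expect_identical(rebuilt$provenance, "hybrid")
  expect_length(rebuilt$element_transforms, 6)
  # too-sparse correspondence errors with the element name
  expect_error(build_uninhibited_c(sp$state_b$model, sp$state_a$model,
                                   sp$elements, cmap[cmap$resno_a > 250, ]),
               "core1")
})
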