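test_that("clash counting skips bonded neighbors", {
  one_res <- structure_model(data.frame(
    chain = "A", resno = 1, resname = "GLY",
    atom = c("N", "CA", "C"), x = c(0, 1, 2), y = 0, z = 0))
  expect_identical(clash_score(one_res), 0L)
  two_res <- structure_model(data.frame(
    chain = "A", resno = c(1, 5), resname = "GLY", atom = "CA",
    x = c(0, 2), y = 0, z = 0))
  expect_identical(clash_score(two_res), 1L)
  adjacent <- structure_model(data.frame(
    chain = "A", resno = c(1, 2), resname = "GLY", atom = "CA",
    x = c(0, 2), y = 0, z = 0))
  expect_identical(clash_score(adjacent), 0L)
  b <- make_pseudo_c3_bundle(synthetic_bundle_spec())
  expect_identical(clash_score(b$model), 0L)
})

test_that("morph endpoints are bit-equal to the input states", {
  sp <- make_synthetic_state_pair()
  trj <- interpolate_states(sp$state_a$model, sp$state_b$model, sp$elements, 7)
  expect_identical(coords(trj$frames[[1]]$model), coords(sp$state_a$model))
  expect_identical(coords(trj$frames[[7]]$model), coords(sp$state_b$model))
  trj2 <- interpolate_states(sp$state_a$model, sp$state_b$model, sp$elements, 2)
  expect_identical(coords(trj2$frames[[1]]$model), coords(sp$state_a$model))
  expect_identical(coords(trj2$frames[[2]]$model), coords(sp$state_b$model))
  expect_error(interpolate_states(sp$state_a$model, sp$state_b$model,
                                  sp$elements, 1), "n_frames")
})

test_that("the midpoint frame carries half of each element rotation", {
  sp <- make_synthetic_state_pair(core_rotation_deg = 30, gate_rotation_deg = 30)
  trj <- interpolate_states(sp$state_a$model, sp$state_b$model, sp$elements, 3)
  mid <- trj$frames[[2]]$model
  for (d in 1:3) {
    resnos <- carriergate:::expand_ranges(sp$elements$core[[d]])
    sel <- sp$state_a$model$atoms$resno %in% resnos
    ang <- rotation_angle(kabsch(coords(sp$state_a$model)[sel, ],
                                 coords(mid)[sel, ])$transform)$angle_deg
    expect_lt(abs(ang - 15), 1e-6)
  }
})

test_that("morphing is frame-wise symmetric under state exchange", {
  sp <- make_synthetic_state_pair()
  fwd <- interpolate_states(sp$state_a$model, sp$state_b$model, sp$elements, 5)
  rev <- interpolate_states(sp$state_b$model, sp$state_a$model, sp$elements, 5)
  el_resnos <- unique(unlist(lapply(1:3, function(d)
    c(carriergate:::expand_ranges(sp$elements$core[[d]]),
      carriergate:::expand_ranges(list(sp$elements$gate[[d]]))))))
  el_sel <- sp$state_a$model$atoms$resno %in% el_resnos
  for (i in 1:5) {
    dev <- max(abs(coords(fwd$frames[[i]]$model)[el_sel, ] -
                     coords(rev$frames[[6 - i]]$model)[el_sel, ]))
    expect_lt(dev, 1e-9)
  }
})

test_that("a closed shell is occluded and a funnel is one-sided", {
  shell <- gate_metrics(make_cage(0), cage_topology)
  expect_false(shell$accessible_from_matrix)
  expect_false(shell$accessible_from_cytoplasm)
  expect_true(shell$occluded)
  expect_gt(shell$gate_thickness, 0)
  funnel <- gate_metrics(make_cage(55), cage_topology)  # open toward +z
  expect_true(funnel$accessible_from_cytoplasm)         # default: cyto = +axis
  expect_false(funnel$accessible_from_matrix)
  expect_false(funnel$occluded)
  # flipping the matrix-side convention swaps the booleans
  flipped <- gate_metrics(make_cage(55), cage_topology,
                          gate_params(matrix_side_sign = 1))
  expect_true(flipped$accessible_from_matrix)
  expect_false(flipped$accessible_from_cytoplasm)
})

test_that("accessibility booleans are stable under grid refinement", {
  fine <- gate_params(grid_spacing = 0.5)
  shell <- gate_metrics(make_cage(0), cage_topology, fine)
  funnel <- gate_metrics(make_cage(55), cage_topology, fine)
  expect_true(shell$occluded)
  expect_true(funnel$accessible_from_cytoplasm)
  expect_false(funnel$accessible_from_matrix)
})

test_that("gate metrics are invariant under a rigid motion of model plus axis", {
  rt <- rotation_about_line(c(1, -1, 2), 55, c(4, 8, -3))
  m0 <- make_cage(55)
  g0 <- gate_metrics(m0, cage_topology)
  axis2 <- drop(rt$rotation %*% c(0, 0, 1))
  point2 <- apply_transform(rt, c(0, 0, 0))
  g1 <- gate_metrics(transform_model(m0, rt), cage_topology,
                     gate_params(axis = axis2, axis_point = point2))
  expect_identical(g1$accessible_from_matrix, g0$accessible_from_matrix)
  expect_identical(g1$accessible_from_cytoplasm, g0$accessible_from_cytoplasm)
  expect_identical(g1$occluded, g0$occluded)
})

test_that("occluded frames are the closed middle of an open-closed-open path", {
  open_only <- make_cage_trajectory(c(55, 55, 55))
  expect_length(find_occluded_frames(open_only, cage_topology), 0)
  path <- make_cage_trajectory(c(55, 40, 0, 40, 55))
  occ <- find_occluded_frames(path, cage_topology)
  expect_identical(occ, 3L)
  expect_error(find_occluded_frames(make_cage_trajectory(c(55, 0)),
                                    cage_topology), "3 frames")
})
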