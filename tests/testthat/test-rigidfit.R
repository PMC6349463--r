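test_that("superposition recovers exact transforms and degenerate input errors", {
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  fit0 <- kabsch(X, X)
  expect_lt(fit0$rmsd, 1e-12)
  expect_lt(max(abs(fit0$transform$rotation - diag(3))), 1e-12)
  set.seed(3)
  for (i in 1:10) {
    R <- random_rotation()
    tv <- rnorm(3, sd = 10)
    Y <- X %*% t(R) + matrix(tv, 10, 3, byrow = TRUE)
    fit <- kabsch(X, Y)
    expect_lt(max(abs(fit$transform$rotation - R)), 1e-8)
    expect_lt(max(abs(fit$transform$translation - tv)), 1e-8)
    expect_lt(fit$rmsd, 1e-9)
  }
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("least-squares fit beats a brute-force rotation grid", {
  set.seed(17)
  for (i in 1:3) {
    n <- sample(4:10, 1)
    X <- matrix(rnorm(3 * n, sd = 4), n, 3)
    Y <- X %*% t(random_rotation()) + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    expect_lte(kabsch(X, Y)$rmsd, grid_superpose_rmsd(X, Y) + 1e-9)
  }
})

test_that("rotation angles and axes follow the trace convention", {
  expect_identical(rotation_angle(rigid_transform())$angle_deg, 0)
  ra <- rotation_angle(rigid_transform(rotation_about_axis(c(0, 0, 1), 15)))
  expect_lt(abs(ra$angle_deg - 15), 1e-10)
  expect_lt(max(abs(ra$axis - c(0, 0, 1))), 1e-10)
  # half-turn edge case keeps a valid axis
  ra180 <- rotation_angle(rotation_about_axis(c(1, 1, 0), 180))
  expect_lt(abs(ra180$angle_deg - 180), 1e-5)
  expect_lt(min(sum((ra180$axis - c(1, 1, 0) / sqrt(2))^2),
                sum((ra180$axis + c(1, 1, 0) / sqrt(2))^2)), 1e-10)
  # property: the fitted rotation of (X, R X) has the angle of R
  set.seed(5)
  X <- matrix(rnorm(60, sd = 5), 20, 3)
  for (i in 1:10) {
    R <- random_rotation()
    got <- rotation_angle(kabsch(X, X %*% t(R))$transform)$angle_deg
    expect_lt(abs(got - rotation_angle(R)$angle_deg), 1e-6)
  }
})

test_that("outlier rejection removes displaced residues and then matches the plain fit", {
  h <- make_ideal_helix(20)
  bb <- select_atoms(h)
  X <- attr(bb, "xyz")
  ids <- bb$resno
  # clean case: identical to kabsch in one cycle
  fit <- iterative_superpose(X, X, ids)
  expect_identical(fit$cycles, 1L)
  expect_length(fit$rejected_residues, 0)
  # displace one residue by 10 A in the copy
  Y <- X
  Y[ids == 7, ] <- Y[ids == 7, ] + 10
  fit2 <- iterative_superpose(X, Y, ids)
  expect_identical(fit2$rejected_residues, "7")
  expect_lt(fit2$rmsd, 0.01)
  expect_identical(fit2$n_atoms_used, sum(ids != 7))
  plain <- kabsch(X, Y)
  expect_gt(plain$rmsd, 1)
  # invariant to atom order within residues
  perm <- order(ids, sample(seq_along(ids)))
  fit3 <- iterative_superpose(X[perm, ], Y[perm, ], ids[perm])
  expect_equal(fit3$rmsd, fit2$rmsd, tolerance = 1e-12)
  expect_identical(sort(fit3$rejected_residues), sort(fit2$rejected_residues))
  expect_error(iterative_superpose(X, Y, ids, cutoff_factor = 0.5), "> 1")
})

test_that("global alignment maps residues across an insertion", {
  a <- align_sequences("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(attr(a, "percent_identity"), 100)
  expect_identical(a$pos_a, a$pos_b)
  b <- align_sequences("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKWWLMNPQRSTVWY")
  off <- b$pos_b - b$pos_a
  expect_identical(unique(off[b$pos_a <= 9]), 0L)
  expect_identical(unique(off[b$pos_a >= 10]), 2L)
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("alignment matches an independent dynamic-programming oracle", {
  sa <- "MKTAYIAKQRQISFVK"
  sb <- "MKTAYIKQRQISFVK"    # unambiguous single deletion
  got <- align_sequences(sa, sb)
  oracle <- nw_align_pairs(sa, sb)
  expect_identical(got$pos_a, oracle$pos_a)
  expect_identical(got$pos_b, oracle$pos_b)
})

test_that("displacement fields report planted shifts in the requested frame", {
  b <- make_pseudo_c3_bundle(synthetic_bundle_spec())
  resnos <- sort(unique(b$model$atoms$resno))
  cmap <- data.frame(resno_a = resnos, resno_b = resnos)
  d0 <- displacement_field(b$model, b$model, cmap)
  expect_lt(max(d0$displacement), 1e-12)
  # translate one helix by 5 A, frame "none": exactly 5 for that subset
  shifted <- b$model
  sel <- shifted$atoms$resno %in% 1:30
  xyz <- coords(shifted)
  xyz[sel, 1] <- xyz[sel, 1] + 5
  shifted <- set_coords(shifted, xyz)
  d1 <- displacement_field(b$model, shifted, cmap, frame = "none")
  expect_equal(unique(round(d1$displacement[d1$resno_a <= 30], 9)), 5)
  expect_equal(unique(round(d1$displacement[d1$resno_a > 30], 9)), 0)
  # global-fit frame is invariant to rigid pre-transformation of either model
  d2 <- displacement_field(b$model, shifted, cmap, frame = "global-fit")
  moved <- transform_model(shifted,
                           rotation_about_line(c(1, 2, 3), 35, c(4, 0, -2)))
  d3 <- displacement_field(b$model, moved, cmap, frame = "global-fit")
  expect_equal(d3$displacement, d2$displacement, tolerance = 1e-9)
  expect_error(displacement_field(b$model, b$model, cmap[0, ]), "empty")
})
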