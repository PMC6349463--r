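# Shared fixtures: spherical cages for accessibility tests, a rotation-grid
# superposition oracle, and a small dynamic-programming alignment oracle.

fib_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * sin(phi) * cos(th), r * sin(phi) * sin(th), r * cos(phi))
}

# Closed pseudo-atom shell of radius r around a central binding-site atom
# (residue 1); aperture_deg > 0 removes the polar cap around +z, opening a
# funnel toward +z.
make_cage <- function(aperture_deg = 0, r = 9, n = 420) {
  p <- fib_sphere(n, r)
  if (aperture_deg > 0)
    p <- p[acos(pmin(1, p[, 3] / r)) * 180 / pi > aperture_deg, , drop = FALSE]
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(p)) + 100, ins = "",
                      resname = "GLY", atom = "CA", element = "C",
                      x = p[, 1], y = p[, 2], z = p[, 3], occ = 1, altloc = "")
  atoms <- rbind(atoms,
                 data.frame(chain = "A", resno = 1, ins = "", resname = "GLY",
                            atom = "CA", element = "C", x = 0, y = 0, z = 0,
                            occ = 1, altloc = ""))
  structure_model(atoms, "synthetic-cage")
}

cage_topology <- list(binding_site = 1)

# Trajectory of cage frames with varying aperture (open -> closed -> open).
make_cage_trajectory <- function(apertures) {
  frames <- lapply(apertures, function(a)
    state_model(make_cage(a), "frame", "interpolated"))
  structure(list(frames = frames, n_frames = length(frames)),
            class = "Trajectory")
}

# Brute-force rotation-grid superposition: best RMSD over a grid of Euler
# angles with centroid-matched translation. Independent of the SVD path.
grid_superpose_rmsd <- function(mobile, target, step_deg = 15) {
  mc <- colMeans(mobile); tc <- colMeans(target)
  P <- sweep(mobile, 2, mc); Q <- sweep(target, 2, tc)
  best <- Inf
  for (a in seq(0, 360 - step_deg, by = step_deg) * pi / 180)
    for (b in seq(0, 180, by = step_deg) * pi / 180)
      for (g in seq(0, 360 - step_deg, by = step_deg) * pi / 180) {
        Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
        Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
        Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
        R <- Rz1 %*% Ry %*% Rz2
        rmsd <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
        if (rmsd < best) best <- rmsd
      }
  best
}

# Minimal global Needleman-Wunsch with linear gaps, returning aligned index
# pairs; used only on instances where the optimum is unambiguous.
nw_align_pairs <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap; S[1, ] <- (0:m) * gap
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + if (A[i] == B[j]) match else mismatch,
                           S[i, j + 1] + gap, S[i + 1, j] + gap)
  pairs <- NULL
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) i <- i - 1
    else j <- j - 1
  }
  out <- as.data.frame(pairs)
  names(out) <- c("pos_a", "pos_b")
  out$pos_a <- as.integer(out$pos_a)
  out$pos_b <- as.integer(out$pos_b)
  out
}

# Brute-force motif scan, written position-by-position (independent of the
# regex engine used by detect_motif).
oracle_motif_starts <- function(sequence, pattern_id) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  classes <- list(
    signature = list("P", NULL, c("D", "E"), NULL, NULL, c("K", "R")),
    cyto_motif = list(c("Y", "F"), c("D", "E"), NULL, NULL, c("K", "R")),
    GxxxG = list("G", NULL, NULL, NULL, "G"),
    pixxxpi = list(c("G", "A", "S"), NULL, NULL, NULL, c("G", "A", "S")))
  cls <- classes[[pattern_id]]
  L <- length(cls)
  hits <- integer(0)
  for (s in seq_len(max(0, n - L + 1))) {
    ok <- TRUE
    for (k in seq_len(L))
      if (!is.null(cls[[k]]) && !(ch[s + k - 1] %in% cls[[k]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

max_coord_dev <- function(m1, m2) {
  max(sqrt(rowSums((coords(m1) - coords(m2))^2)))
}
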