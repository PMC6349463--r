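test_that("PDB write/read round-trip preserves identities and coordinates", {
  b <- make_pseudo_c3_bundle(synthetic_bundle_spec())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$model, f)
  m2 <- read_structure(f)
  expect_identical(nrow(m2$atoms), nrow(b$model$atoms))
  expect_identical(carriergate:::atom_key(m2$atoms),
                   carriergate:::atom_key(b$model$atoms))
  expect_identical(m2$atoms$resname, b$model$atoms$resname)
  # serialized to 3 decimals
  expect_lt(max(abs(coords(m2) - coords(b$model))), 5.01e-4)
  # second round trip is exact (values already on the 3-decimal lattice)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  expect_identical(coords(read_structure(f2)), coords(m2))
})

test_that("coordinates are serialized with 3-decimal rounding", {
  m <- structure_model(data.frame(chain = "A", resno = 1, resname = "ALA",
                                  atom = "CA", x = 1.23456, y = 0, z = 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  expect_match(readLines(f)[1], "   1.235   0.000   0.000", fixed = TRUE)
})

test_that("trajectories become multi-model PDB files", {
  sp <- make_synthetic_state_pair(synthetic_bundle_spec(residues_per_helix = 12))
  trj <- interpolate_states(sp$state_a$model, sp$state_b$model, sp$elements, 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(trj, f)
  lines <- readLines(f)
  expect_identical(sum(grepl("^MODEL", lines)), 5L)
  expect_identical(sum(grepl("^ENDMDL", lines)), 5L)
  m3 <- read_structure(f, model_index = 3)
  expect_identical(nrow(m3$atoms), nrow(sp$state_a$model$atoms))
  expect_error(read_structure(f, model_index = 9), "model 9")
})

test_that("missing chains and models are reported by name", {
  m <- make_ideal_helix(10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  expect_error(read_structure(f, chains = "Z"), "\"Z\"")
  expect_silent(mm <- read_structure(f, chains = "A"))
  expect_identical(unique(mm$atoms$chain), "A")
})

test_that("altlocs resolve to the highest-occupancy copy, ties to A", {
  fixture <- function(occ_a, occ_b) {
    lines <- c(
      "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
      sprintf("ATOM      2  CA AALA A   1       1.000   0.000   0.000 %5.2f  0.00           C", occ_a),
      sprintf("ATOM      3  CA BALA A   1       2.000   0.000   0.000 %5.2f  0.00           C", occ_b),
      "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
      "ATOM      5  O   ALA A   1       4.000   0.000   0.000  1.00  0.00           O",
      "END")
    f <- tempfile(fileext = ".pdb")
    writeLines(lines, f)
    f
  }
  m <- read_structure(fixture(0.6, 0.4))
  expect_identical(m$atoms$x[m$atoms$atom == "CA"], 1.0)
  m <- read_structure(fixture(0.4, 0.6))
  expect_identical(m$atoms$x[m$atoms$atom == "CA"], 2.0)
  m <- read_structure(fixture(0.5, 0.5))          # tie -> altloc A
  expect_identical(m$atoms$x[m$atoms$atom == "CA"], 1.0)
  m <- read_structure(fixture(0.4, 0.6), altloc_policy = "A")
  expect_identical(m$atoms$x[m$atoms$atom == "CA"], 1.0)
  expect_identical(sum(m$atoms$atom == "CA"), 1L)
})

test_that("mmCIF files parse with author numbering", {
  cif <- c("data_test", "loop_", "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
           "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 5 ALA A N 1",
           "ATOM 2 C CA . ALA A 1 1 ? 1.500 0.000 0.000 1.00 10.00 ? 5 ALA A CA 1",
           "ATOM 3 C C . ALA A 1 1 ? 2.000 0.000 0.000 1.00 10.00 ? 5 ALA A C 1",
           "ATOM 4 O O . ALA A 1 1 ? 3.000 0.000 0.000 1.00 10.00 ? 5 ALA A O 1",
           "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  m <- read_structure(f)
  expect_identical(m$atoms$resno, rep(5L, 4))
  expect_identical(m$atoms$atom, c("N", "CA", "C", "O"))
  expect_identical(m$atoms$x[2], 1.5)
})

test_that("sequences extract with X for nonstandard residues and true numbering gaps", {
  ala10 <- make_ideal_helix(10)
  s <- extract_sequence(ala10)
  expect_identical(s$sequence, "AAAAAAAAAA")
  a <- ala10$atoms
  a$resname[a$resno == 3] <- "MSE"
  a$resname[a$resno == 4] <- "XYZ"
  a$resno[a$resno >= 6] <- a$resno[a$resno >= 6] + 44   # gap 5 -> 50
  m <- structure_model(a)
  s2 <- extract_sequence(m)
  expect_identical(s2$sequence, "AAMXAAAAAA")  # MSE maps to M, unknown to X
  expect_identical(s2$numbers, c(1:5, 50:54))
})

test_that("atom selection is ordered, strict about missing atoms, and inclusive", {
  h <- make_ideal_helix(20)
  sel <- select_atoms(h, residues = c(13, 15))
  expect_identical(nrow(sel), 12L)                       # 3 residues x backbone
  expect_identical(sel$resno, rep(13:15, each = 4))
  expect_identical(sel$atom, rep(c("N", "CA", "C", "O"), 3))
  # order independent of file atom order
  shuffled <- structure_model(h$atoms[rev(seq_len(nrow(h$atoms))), ])
  sel2 <- select_atoms(shuffled, residues = c(13, 15))
  expect_identical(attr(sel2, "xyz"), attr(sel, "xyz"))
  # missing atom: error in strict mode naming the residue, reported otherwise
  broken <- structure_model(h$atoms[!(h$atoms$resno == 14 & h$atoms$atom == "O"), ])
  expect_error(select_atoms(broken, residues = c(13, 15)), "14")
  sel3 <- select_atoms(broken, residues = c(13, 15), strict = FALSE)
  expect_identical(nrow(sel3), 11L)
  expect_match(attr(sel3, "missing"), "O")
  expect_error(select_atoms(h, residues = c(900, 910)), "empty")
  expect_silent(select_atoms(h, residues = c(900, 910), allow_empty = TRUE))
})
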