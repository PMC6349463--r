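test_that("motif scanning finds the conserved carrier patterns", {
  hits <- detect_motif("APLDQLKV", "signature")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 2L)
  expect_identical(hits$matched, "PLDQLK")
  expect_identical(nrow(detect_motif("AAAAAA", "GxxxG")), 0L)
  # [YF][DE]xx[KR], as in the Y-D...K arrangement of the cytoplasmic network
  hits <- detect_motif("AAYDAAKAA", "cyto_motif")
  expect_identical(hits$start, 3L)
  expect_identical(hits$matched, "YDAAK")
  # overlapping starts are all reported
  hits <- detect_motif("GAAAGAAAG", "GxxxG")
  expect_identical(hits$start, c(1L, 5L))
  expect_error(detect_motif("AAAA", "nope"), "unknown pattern")
})

test_that("motif scanning agrees with a position-by-position oracle", {
  set.seed(42)
  for (pat in c("signature", "cyto_motif", "GxxxG", "pixxxpi")) {
    for (rep in 1:20) {
      s <- random_aa_seq(60)
      expect_identical(as.integer(detect_motif(s, pat)$start),
                       oracle_motif_starts(s, pat), label = paste(pat, s))
    }
  }
})

test_that("the built-in TtAac topology matches the carrier annotation", {
  topo <- ttaac_topology()
  expect_identical(unname(topo$contact_points), c(88, 192, 287))
  expect_identical(topo$domain_spans$D1, c(13, 107))
  expect_identical(topo$domain_spans$D2, c(116, 211))
  expect_identical(topo$domain_spans$D3, c(220, 306))
  expect_setequal(topo$matrix_network, c(37, 40, 142, 145, 242, 245))
  expect_setequal(topo$cytoplasmic_network, c(101, 104, 205, 208, 299, 302))
  expect_setequal(topo$braces, c(100, 204, 298))
  expect_setequal(topo$hydrophobic_plug, c(97, 201, 295))
  el <- derive_elements(topo)
  expect_identical(el$gate[[1]], c(88, 107))
  expect_identical(el$core[[1]][[1]], c(13, 87))
})

test_that("topology validation rejects malformed configurations", {
  hs <- list(H2 = c(10, 30), H4 = c(40, 60), H6 = c(70, 90))
  ds <- list(D1 = c(1, 30), D2 = c(35, 60), D3 = c(65, 90))
  cp <- c(H2 = 20, H4 = 50, H6 = 80)
  expect_silent(carrier_topology(hs, ds, cp))
  expect_error(carrier_topology(hs, list(D1 = c(1, 40), D2 = c(35, 60),
                                         D3 = c(65, 90)), cp), "overlap")
  expect_error(carrier_topology(hs, ds, c(H2 = 35, H4 = 50, H6 = 80)),
               "outside helix")
  expect_error(carrier_topology(hs, ds, cp, matrix_network = c(1, 2, 3)),
               "6 members")
})

test_that("elements partition each domain, pivot residue on the gate side", {
  partition_check <- function(topo) {
    el <- derive_elements(topo)
    for (d in 1:3) {
      span <- topo$domain_spans[[d]]
      core <- carriergate:::expand_ranges(el$core[[d]])
      gate <- carriergate:::expand_ranges(list(el$gate[[d]]))
      expect_length(intersect(core, gate), 0)
      expect_setequal(c(core, gate), seq(span[1], span[2]))
      expect_true(topo$contact_points[[d]] %in% gate)
    }
  }
  partition_check(ttaac_topology())
  partition_check(make_pseudo_c3_bundle(synthetic_bundle_spec())$topology)
})

test_that("a contact point at the domain boundary is rejected", {
  hs <- list(H2 = c(10, 30), H4 = c(40, 60), H6 = c(70, 90))
  ds <- list(D1 = c(1, 30), D2 = c(35, 60), D3 = c(65, 90))
  topo <- carrier_topology(hs, ds, c(H2 = 30, H4 = 50, H6 = 80))
  expect_error(derive_elements(topo), "empty element")
})

test_that("topologies map onto homolog numbering through a correspondence", {
  topo <- make_pseudo_c3_bundle(synthetic_bundle_spec())$topology
  resnos <- sort(unique(unlist(lapply(topo$domain_spans, function(s)
    seq(s[1], s[2])))))
  cmap <- data.frame(resno_a = resnos, resno_b = resnos + 8)
  mapped <- map_topology(topo, cmap, protein = "synthetic")
  expect_identical(unname(mapped$contact_points),
                   unname(topo$contact_points) + 8)
  expect_identical(mapped$domain_spans$D2, topo$domain_spans$D2 + 8)
})

test_that("topology configs read from structured text match the built-in", {
  f <- system.file("extdata", "ttaac_topology.yaml", package = "carriergate")
  topo <- read_topology(f)
  builtin <- ttaac_topology()
  expect_identical(topo$domain_spans, builtin$domain_spans)
  expect_identical(topo$contact_points, builtin$contact_points)
  expect_setequal(topo$cytoplasmic_network, builtin$cytoplasmic_network)
  expect_identical(derive_elements(topo)$gate[[3]],
                   derive_elements(builtin)$gate[[3]])
  # a malformed config is rejected by the same validation
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("protein: broken", "helix_spans: {H2: [10, 30]}",
               "domain_spans: {D1: [1, 40], D2: [35, 60], D3: [65, 90]}",
               "contact_points: {H2: 20}"), bad)
  expect_error(read_topology(bad), "overlap|three")
})
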