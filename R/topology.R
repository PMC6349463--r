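#' Carrier fold annotation
#'
#' A `CarrierTopology` annotates the three-domain mitochondrial-carrier fold
#' on author residue numbering: transmembrane and matrix helix spans, domain
#' spans, the substrate-binding contact points at the even-helix kink pivots,
#' and the functional residue sets (binding site, matrix and cytoplasmic
#' salt-bridge networks, braces, hydrophobic plug, ceiling, signature
#' prolines). All ranges are inclusive on both ends.
#'
#' @param helix_spans named list of `c(from, to)` ranges (H1..H6 and
#'   optionally matrix helices h12/h34/h56).
#' @param domain_spans named list `D1`, `D2`, `D3` of `c(from, to)` ranges;
#'   must be non-overlapping and in order.
#' @param contact_points named numeric vector, one residue per even helix;
#'   each must lie strictly inside its helix span.
#' @param binding_site,matrix_network,cytoplasmic_network,braces,
#'   hydrophobic_plug,ceiling,signature_prolines residue-number vectors
#'   (possibly empty). When fully specified, the two network sets have
#'   exactly 6 members each.
#' @param protein free-text tag.
#' @return Object of class `CarrierTopology`.
#' @export
carrier_topology <- function(helix_spans, domain_spans, contact_points,
                             binding_site = integer(0),
                             matrix_network = integer(0),
                             cytoplasmic_network = integer(0),
                             braces = integer(0),
                             hydrophobic_plug = integer(0),
                             ceiling = integer(0),
                             signature_prolines = integer(0),
                             protein = "") {
  if (length(domain_spans) != 3) stop("exactly three domain spans required")
  if (is.null(names(domain_spans))) names(domain_spans) <- paste0("D", 1:3)
  for (i in 1:3) {
    d <- domain_spans[[i]]
    if (length(d) != 2 || d[1] > d[2]) stop("invalid span for domain ", i)
  }
  for (i in 1:2)
    if (domain_spans[[i]][2] >= domain_spans[[i + 1]][1])
      stop("domain spans overlap or are out of order: ",
           names(domain_spans)[i], " vs ", names(domain_spans)[i + 1])
  if (length(contact_points) != 3) stop("exactly three contact points required")
  for (nm in names(contact_points)) {
    cp <- contact_points[[nm]]
    hs <- helix_spans[[nm]]
    if (is.null(hs)) stop("contact point names an unknown helix: ", nm)
    if (cp < hs[1] || cp > hs[2])
      stop("contact point ", cp, " lies outside helix ", nm,
           " span ", hs[1], "-", hs[2])
  }
  for (set_name in c("matrix_network", "cytoplasmic_network")) {
    s <- get(set_name)
    if (length(s) && length(s) != 6 && protein != "synthetic")
      stop(set_name, " must have exactly 6 members when specified, got ",
           length(s))
  }
  structure(list(helix_spans = helix_spans, domain_spans = domain_spans,
                 contact_points = contact_points, binding_site = binding_site,
                 matrix_network = matrix_network,
                 cytoplasmic_network = cytoplasmic_network,
                 braces = braces, hydrophobic_plug = hydrophobic_plug,
                 ceiling = ceiling, signature_prolines = signature_prolines,
                 protein = protein),
            class = "CarrierTopology")
}

#' @export
print.CarrierTopology <- function(x, ...) {
  cat(sprintf("CarrierTopology [%s]: domains %s; contact points %s\n",
              x$protein,
              paste(vapply(x$domain_spans, function(d)
                paste(d, collapse = "-"), ""), collapse = ", "),
              paste(x$contact_points, collapse = ", ")))
  invisible(x)
}

#' Built-in topology of the T. thermophila ADP/ATP carrier
#'
#' Domain spans, contact points and functional residue sets of TtAac. Helix
#' spans are annotations chosen from the deposited model's helical regions
#' and are configurable; they are not derived algorithmically.
#'
#' @return A [carrier_topology()].
#' @export
ttaac_topology <- function() {
  carrier_topology(
    helix_spans = list(H1 = c(16, 45), h12 = c(52, 62), H2 = c(74, 107),
                       H3 = c(116, 145), h34 = c(155, 165), H4 = c(177, 211),
                       H5 = c(220, 250), h56 = c(258, 268), H6 = c(273, 306)),
    domain_spans = list(D1 = c(13, 107), D2 = c(116, 211), D3 = c(220, 306)),
    contact_points = c(H2 = 88, H4 = 192, H6 = 287),
    binding_site = c(30, 88, 192, 193, 196, 238, 287),
    matrix_network = c(37, 40, 142, 145, 242, 245),
    cytoplasmic_network = c(101, 104, 205, 208, 299, 302),
    braces = c(100, 204, 298),
    hydrophobic_plug = c(97, 201, 295),
    ceiling = c(96, 200, 294),
    signature_prolines = c(35, 140, 240),
    protein = "TtAac")
}

#' Read a carrier topology from a structured text (YAML) config
#'
#' The config names the helix spans, domain spans, contact points and
#' functional residue sets on author numbering; see
#' `system.file("extdata", "ttaac_topology.yaml", package = "carriergate")`
#' for the shipped TtAac example. Validation is identical to
#' [carrier_topology()].
#'
#' @param path path to a YAML topology config.
#' @return A [carrier_topology()].
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("helix_spans", "domain_spans", "contact_points")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("topology config is missing: ", paste(miss, collapse = ", "))
  num <- function(x) if (is.null(x)) integer(0) else as.numeric(unlist(x))
  carrier_topology(
    helix_spans = lapply(cfg$helix_spans, function(s) as.numeric(unlist(s))),
    domain_spans = lapply(cfg$domain_spans, function(s) as.numeric(unlist(s))),
    contact_points = vapply(cfg$contact_points, as.numeric, numeric(1)),
    binding_site = num(cfg$binding_site),
    matrix_network = num(cfg$matrix_network),
    cytoplasmic_network = num(cfg$cytoplasmic_network),
    braces = num(cfg$braces),
    hydrophobic_plug = num(cfg$hydrophobic_plug),
    ceiling = num(cfg$ceiling),
    signature_prolines = num(cfg$signature_prolines),
    protein = if (is.null(cfg$protein)) "" else cfg$protein)
}

#' Map a topology onto a homolog through a residue correspondence
#'
#' Translates every residue number of a topology into a homolog's numbering
#' via an alignment-derived correspondence (e.g. to carry the TtAac
#' annotation onto ScAac2). Residues without a counterpart are dropped from
#' sets; a span or contact point without a counterpart is an error.
#'
#' @param topology A [carrier_topology()] in frame A.
#' @param correspondence data.frame `resno_a`, `resno_b` (see
#'   [correspondence_residues()]).
#' @param protein tag for the mapped topology.
#' @return A [carrier_topology()] in frame B.
#' @export
map_topology <- function(topology, correspondence, protein = "mapped") {
  m <- function(r) correspondence$resno_b[match(r, correspondence$resno_a)]
  map_span <- function(s, what) {
    # nearest mapped residue at or inside each end of the span
    inside <- correspondence$resno_a[correspondence$resno_a >= s[1] &
                                       correspondence$resno_a <= s[2]]
    if (!length(inside)) stop("no mapped residues inside ", what)
    c(m(min(inside)), m(max(inside)))
  }
  cp <- vapply(topology$contact_points, function(r) {
    v <- m(r)
    if (is.na(v)) stop("contact point ", r, " has no counterpart")
    v
  }, numeric(1))
  carrier_topology(
    helix_spans = mapply(map_span, topology$helix_spans,
                         paste("helix", names(topology$helix_spans)),
                         SIMPLIFY = FALSE),
    domain_spans = mapply(map_span, topology$domain_spans,
                          paste("domain", names(topology$domain_spans)),
                          SIMPLIFY = FALSE),
    contact_points = cp,
    binding_site = stats::na.omit(m(topology$binding_site)),
    matrix_network = stats::na.omit(m(topology$matrix_network)),
    cytoplasmic_network = stats::na.omit(m(topology$cytoplasmic_network)),
    braces = stats::na.omit(m(topology$braces)),
    hydrophobic_plug = stats::na.omit(m(topology$hydrophobic_plug)),
    ceiling = stats::na.omit(m(topology$ceiling)),
    signature_prolines = stats::na.omit(m(topology$signature_prolines)),
    protein = protein)
}

#' Decompose domains into core and gate elements
#'
#' Each domain's gate element is the C-terminal part of its even-numbered
#' helix, from the contact point (inclusive: the pivot residue moves with the
#' kink) to the domain end; the core element is the remainder of the domain
#' (odd helix, matrix helix, linker and the N-terminal third of the even
#' helix).
#'
#' @param topology A [carrier_topology()].
#' @return Object of class `ElementSet`: `core` (list of residue-range lists
#'   per domain) and `gate` (list of ranges per domain).
#' @export
derive_elements <- function(topology) {
  core <- list(); gate <- list()
  cps <- sort(unname(unlist(topology$contact_points)))
  for (d in 1:3) {
    span <- topology$domain_spans[[d]]
    cp <- cps[cps >= span[1] & cps <= span[2]]
    if (length(cp) != 1)
      stop("expected exactly one contact point in domain ", d, ", found ",
           length(cp))
    if (cp >= span[2] || cp <= span[1])
      stop("contact point ", cp, " at domain ", d,
           " boundary leaves an empty element")
    core[[d]] <- list(c(span[1], cp - 1))
    gate[[d]] <- c(cp, span[2])
  }
  structure(list(core = core, gate = gate), class = "ElementSet")
}

#' @export
print.ElementSet <- function(x, ...) {
  for (d in 1:3)
    cat(sprintf("domain %d: core %s | gate %d-%d\n", d,
                paste(vapply(x$core[[d]], function(r)
                  paste(r, collapse = "-"), ""), collapse = ","),
                x$gate[[d]][1], x$gate[[d]][2]))
  invisible(x)
}

MOTIF_PATTERNS <- c(
  signature = "P.[DE]..[KR]",     # Px[DE]xx[KR], odd-helix signature motif
  cyto_motif = "[YF][DE]..[KR]",  # [YF][DE]xx[KR], even-helix network motif
  GxxxG = "G...G",
  pixxxpi = "[GAS]...[GAS]"       # small-residue class {G, A, S}
)

#' Scan a sequence for conserved carrier motifs
#'
#' Finds all matches (including overlapping ones at different start
#' positions) of one of the conserved mitochondrial-carrier motifs:
#' `signature` (Px\[DE\]xx\[KR\]), `cyto_motif` (\[YF\]\[DE\]xx\[KR\]),
#' `GxxxG`, or `pixxxpi` (small residues \{G, A, S\} spaced four apart).
#'
#' @param sequence uppercase one-letter amino-acid string.
#' @param pattern_id one of `"signature"`, `"cyto_motif"`, `"GxxxG"`,
#'   `"pixxxpi"`.
#' @param numbers optional residue-number vector parallel to the sequence;
#'   default 1-based positions.
#' @return data.frame of class `MotifHits`: `pattern_id`, `start` (residue
#'   number), `matched` (matched text).
#' @export
detect_motif <- function(sequence, pattern_id, numbers = NULL) {
  if (!pattern_id %in% names(MOTIF_PATTERNS))
    stop("unknown pattern id: ", pattern_id, " (known: ",
         paste(names(MOTIF_PATTERNS), collapse = ", "), ")")
  if (is.null(numbers)) numbers <- seq_len(nchar(sequence))
  pat <- paste0("(?=(", MOTIF_PATTERNS[[pattern_id]], "))")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(structure(data.frame(pattern_id = character(0),
                                start = numeric(0), matched = character(0)),
                     class = c("MotifHits", "data.frame")))
  starts <- as.integer(m)
  len <- attr(m, "capture.length")[, 1]
  structure(data.frame(pattern_id = pattern_id, start = numbers[starts],
                       matched = substring(sequence, starts, starts + len - 1),
                       stringsAsFactors = FALSE),
            class = c("MotifHits", "data.frame"))
}

# Residue number -> domain index (1..3), NA outside all domains.
residue_domain <- function(resno, topology) {
  out <- rep(NA_integer_, length(resno))
  for (d in 1:3) {
    s <- topology$domain_spans[[d]]
    out[resno >= s[1] & resno <= s[2]] <- d
  }
  out
}
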