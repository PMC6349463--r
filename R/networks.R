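# Polar-contact detection: salt bridges and brace hydrogen bonds.
#
# Distance-only criteria on charged-group / polar side-chain atoms; no
# hydrogen placement and no angular terms. Cutoff defaults (4.0 A N-O for
# salt bridges, 3.6 A for brace hydrogen bonds) are conventional and
# configurable.

# Side-chain atom classes. Histidine is counted as a positively charged
# donor (inclusive default).
POSITIVE_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
POLAR_ATOMS <- list(TYR = "OH", SER = "OG", THR = "OG1",
                    ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"))

atom_class <- function(resname, atom) {
  cls <- rep("", length(resname))
  for (rn in names(POSITIVE_ATOMS))
    cls[resname == rn & atom %in% POSITIVE_ATOMS[[rn]]] <- "pos"
  for (rn in names(ACIDIC_ATOMS))
    cls[resname == rn & atom %in% ACIDIC_ATOMS[[rn]]] <- "acid"
  for (rn in names(POLAR_ATOMS))
    cls[resname == rn & atom %in% POLAR_ATOMS[[rn]]] <- "polar"
  cls
}

#' Detect polar inter-residue contacts
#'
#' A residue pair forms a `salt_bridge` when any side-chain nitrogen of
#' K/R/H lies within `sb_cutoff` of any side-chain carboxylate oxygen of
#' D/E, and an `hbond_brace` when a hydroxyl/amide side-chain atom (Y-OH,
#' S-OG, T-OG1, N/Q amide) lies within `hb_cutoff` of a charged side-chain
#' O/N. Each residue pair is reported once, at its minimum-distance atom
#' pair; salt bridges take precedence over braces for pairs satisfying both.
#' Topology residues listed in the network/brace sets but missing from the
#' model are reported in the `unevaluable` attribute, never silently
#' dropped.
#'
#' @param model A [structure_model()].
#' @param topology A [carrier_topology()] (for domain assignment and the
#'   missing-residue report); may be `NULL`.
#' @param sb_cutoff salt-bridge N-O cutoff, A (default 4.0).
#' @param hb_cutoff brace hydrogen-bond cutoff, A (default 3.6).
#' @param chain chain id (`NULL`: first chain).
#' @return data.frame of class `PolarContacts`: `res_a`, `res_b` (residue
#'   numbers, `res_a < res_b`), `resname_a/b`, `atom_a/b`, `distance`,
#'   `contact_class`, `domain_relation` ("intra"/"inter"/NA).
#' @export
find_polar_contacts <- function(model, topology = NULL, sb_cutoff = 4.0,
                                hb_cutoff = 3.6, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  cls <- atom_class(a$resname, a$atom)
  cand <- a[cls != "", , drop = FALSE]
  ccls <- cls[cls != ""]
  empty <- data.frame(res_a = numeric(0), res_b = numeric(0),
                      resname_a = character(0), resname_b = character(0),
                      atom_a = character(0), atom_b = character(0),
                      distance = numeric(0), contact_class = character(0),
                      domain_relation = character(0))
  unevaluable <- character(0)
  if (!is.null(topology)) {
    listed <- unique(c(topology$matrix_network, topology$cytoplasmic_network,
                       topology$braces))
    present <- listed %in% a$resno[atom_class(a$resname, a$atom) != ""]
    if (any(!present))
      unevaluable <- paste0("residue ", listed[!present],
                            ": no charged/polar side-chain atom in model")
  }
  result <- empty
  if (nrow(cand) >= 2) {
    xyz <- as.matrix(cand[, c("x", "y", "z")])
    dmat <- as.matrix(stats::dist(xyz))
    max_cut <- max(sb_cutoff, hb_cutoff)
    idx <- which(upper.tri(dmat) & dmat <= max_cut, arr.ind = TRUE)
    rows <- list()
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (cand$resno[i] == cand$resno[j]) next
      pair_cls <- sort(c(ccls[i], ccls[j]))
      d <- dmat[i, j]
      cc <- NULL
      if (identical(pair_cls, c("acid", "pos")) && d <= sb_cutoff)
        cc <- "salt_bridge"
      else if ("polar" %in% pair_cls &&
               any(c("acid", "pos") %in% pair_cls) && d <= hb_cutoff)
        cc <- "hbond_brace"
      if (is.null(cc)) next
      swap <- cand$resno[i] > cand$resno[j]
      ii <- if (swap) j else i; jj <- if (swap) i else j
      rows[[length(rows) + 1]] <- data.frame(
        res_a = cand$resno[ii], res_b = cand$resno[jj],
        resname_a = cand$resname[ii], resname_b = cand$resname[jj],
        atom_a = cand$atom[ii], atom_b = cand$atom[jj],
        distance = d, contact_class = cc, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      result <- do.call(rbind, rows)
      # one contact per residue pair: salt bridge preferred, then min distance
      pref <- order(result$res_a, result$res_b,
                    result$contact_class != "salt_bridge", result$distance)
      result <- result[pref, , drop = FALSE]
      result <- result[!duplicated(result[, c("res_a", "res_b")]), , drop = FALSE]
      result$domain_relation <- NA_character_
      if (!is.null(topology)) {
        da <- residue_domain(result$res_a, topology)
        db <- residue_domain(result$res_b, topology)
        result$domain_relation <- ifelse(is.na(da) | is.na(db), NA_character_,
                                         ifelse(da == db, "intra", "inter"))
      }
      rownames(result) <- NULL
    }
  }
  attr(result, "unevaluable") <- unevaluable
  class(result) <- c("PolarContacts", "data.frame")
  result
}

#' Classify contacts into the matrix and cytoplasmic networks
#'
#' A contact belongs to the cytoplasmic network when both residues are in
#' the topology's cytoplasmic-network or brace sets, to the matrix network
#' when both are in the matrix-network set; all other contacts are "other".
#'
#' @param contacts A [find_polar_contacts()] result.
#' @param topology A [carrier_topology()].
#' @return Named list of `SaltBridgeNetwork` objects (`matrix`,
#'   `cytoplasmic`, `other`), each with `contacts`, `network_label` and
#'   `n_interdomain_polar`.
#' @export
classify_network <- function(contacts, topology) {
  cyto_set <- c(topology$cytoplasmic_network, topology$braces)
  mat_set <- topology$matrix_network
  lab <- rep("other", nrow(contacts))
  lab[contacts$res_a %in% cyto_set & contacts$res_b %in% cyto_set] <- "cytoplasmic"
  lab[contacts$res_a %in% mat_set & contacts$res_b %in% mat_set] <- "matrix"
  out <- lapply(c(matrix = "matrix", cytoplasmic = "cytoplasmic",
                  other = "other"), function(l) {
    sub <- contacts[lab == l, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(contacts = sub, network_label = l,
                   n_interdomain_polar =
                     sum(sub$domain_relation == "inter", na.rm = TRUE)),
              class = "SaltBridgeNetwork")
  })
  out
}

#' @export
print.SaltBridgeNetwork <- function(x, ...) {
  cat(sprintf("SaltBridgeNetwork [%s]: %d contact(s), %d inter-domain\n",
              x$network_label, nrow(x$contacts), x$n_interdomain_polar))
  if (nrow(x$contacts))
    print.data.frame(x$contacts[, c("res_a", "res_b", "atom_a", "atom_b",
                                    "distance", "contact_class")],
                     digits = 3)
  invisible(x)
}

contact_keys <- function(network) {
  ct <- if (inherits(network, "SaltBridgeNetwork")) network$contacts else network
  if (!nrow(ct)) return(character(0))
  paste(pmin(ct$res_a, ct$res_b), pmax(ct$res_a, ct$res_b), sep = "-")
}

#' Compare salt-bridge networks between two states
#'
#' Set differences of residue-pair contacts: `formed` are present in
#' `network_to` only, `broken` in `network_from` only, `retained` in both.
#' Both networks must share a residue-numbering frame (same protein, or one
#' mapped through a correspondence beforehand).
#'
#' @param network_from,network_to `SaltBridgeNetwork` objects (or bare
#'   `PolarContacts` tables).
#' @return List of data.frames `formed`, `broken`, `retained`.
#' @export
compare_states <- function(network_from, network_to) {
  cf <- if (inherits(network_from, "SaltBridgeNetwork")) network_from$contacts else network_from
  ct <- if (inherits(network_to, "SaltBridgeNetwork")) network_to$contacts else network_to
  kf <- contact_keys(cf); kt <- contact_keys(ct)
  list(formed = ct[!kt %in% kf, , drop = FALSE],
       broken = cf[!kf %in% kt, , drop = FALSE],
       retained = ct[kt %in% kf, , drop = FALSE])
}
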