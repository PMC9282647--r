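# SIFt-style per-residue interaction fingerprints. For each binding-site
# residue, nine binary detectors are evaluated against the docked pose in
# every monomer and OR-merged: a bit is 1 if the interaction occurs in at
# least one of the (four) identical channel subunits.

#' The fixed interaction-type order of the nine-bit residue string
#' @export
IF_TYPES <- c("contact", "backbone", "sidechain", "polar", "hydrophobic",
              "hbond_acceptor", "hbond_donor", "aromatic", "charged")

#' Geometric rules for interaction detection
#'
#' The interaction types follow the SIFt convention: a residue is in contact
#' when any heavy-atom pair is within \code{contact_max_A}; class bits
#' (polar/hydrophobic/aromatic/charged) are contacts with residues in the
#' corresponding class set; hydrogen bonds use a donor-acceptor heavy-atom
#' distance cutoff, with a D-H...A angle test applied only when explicit
#' hydrogens are available. All cutoffs and class sets are configurable and
#' recorded in run manifests.
#'
#' @param contact_max_A any-contact heavy-atom cutoff (default 4.5)
#' @param hbond_dist_max_A donor-acceptor heavy-atom cutoff (default 3.5)
#' @param hbond_angle_min_deg minimal D-H...A angle when hydrogens exist
#' @param hydrophobic,aromatic,polar,charged residue class sets (3-letter
#'   codes; overlaps intentional)
#' @return an object of class \code{geometry_rules}
#' @export
geometry_rules <- function(contact_max_A = 4.5,
                           hbond_dist_max_A = 3.5,
                           hbond_angle_min_deg = 120,
                           hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET",
                                           "PHE", "TRP", "PRO", "TYR"),
                           aromatic = c("PHE", "TYR", "TRP", "HIS"),
                           polar = c("SER", "THR", "ASN", "GLN", "CYS",
                                     "TYR", "HIS"),
                           charged = c("ASP", "GLU", "LYS", "ARG", "HIS")) {
  stop_if_not(contact_max_A > 0 && hbond_dist_max_A > 0, "cutoffs must be > 0")
  # side-chain H-bond atom typing by residue; backbone N donates, O/OXT accept
  donors <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                 GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
                 ARG = c("NE", "NH1", "NH2"), TRP = "NE1")
  acceptors <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                    GLN = "OE1", HIS = c("ND1", "NE2"),
                    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  structure(list(contact_max_A = contact_max_A,
                 hbond_dist_max_A = hbond_dist_max_A,
                 hbond_angle_min_deg = hbond_angle_min_deg,
                 class_sets = list(hydrophobic = hydrophobic,
                                   aromatic = aromatic,
                                   polar = polar, charged = charged),
                 donors = donors, acceptors = acceptors),
            class = "geometry_rules")
}

lig_heavy <- function(pose) pose$atoms[pose$atoms$element != "H", , drop = FALSE]

min_cross_dist2 <- function(ax, ay, az, bx, by, bz) {
  # all-pairs squared distances between two atom sets; returns the matrix
  outer(ax, bx, "-")^2 + outer(ay, by, "-")^2 + outer(az, bz, "-")^2
}

#' Define the common binding site around a reference pose
#'
#' Residues with any heavy atom within \code{cutoff_A} of any heavy atom of
#' the reference pose (conventionally the best-scoring docked molecule), in
#' any monomer. Keys are monomer-collapsed (residue number + name): the four
#' chain copies of a channel residue count once.
#'
#' @param receptor a \code{\link{read_receptor}} result
#' @param reference_pose a \code{\link{ligand_pose}} (typically the best
#'   scorer)
#' @param cutoff_A site radius in Angstrom (default 9)
#' @return a \code{binding_site}: data.frame (resno, resid) sorted by resno
#' @export
define_binding_site <- function(receptor, reference_pose, cutoff_A = 9) {
  stop_if_not(cutoff_A > 0, "cutoff_A must be > 0")
  lig <- lig_heavy(reference_pose)
  stop_if_not(nrow(lig) > 0, "reference pose has no heavy atoms")
  rec <- receptor[receptor$element != "H", , drop = FALSE]
  d2 <- min_cross_dist2(rec$x, rec$y, rec$z, lig$x, lig$y, lig$z)
  near <- apply(d2, 1, min) <= cutoff_A^2
  keys <- unique(rec[near, c("resno", "resid")])
  stop_if_not(nrow(keys) > 0,
              "no residue within %g A of the reference pose (pose outside receptor?)",
              cutoff_A)
  keys <- keys[order(keys$resno, keys$resid), , drop = FALSE]
  stop_if_not(!anyDuplicated(keys$resno),
              "residue-number collision across chains with different residue names")
  rownames(keys) <- NULL
  structure(keys, class = c("binding_site", "data.frame"))
}

# ligand H-bond typing; unknown n_H treats N/O as donor (logged upstream)
lig_donor_idx <- function(lig) {
  which((lig$element %in% c("N", "O")) &
          (is.na(lig$n_H) | lig$n_H >= 1 | (lig$element == "N" & lig$charge > 0)))
}
lig_acceptor_idx <- function(lig) {
  which((lig$element %in% c("N", "O")) & lig$charge <= 0)
}

# evaluate the nine detectors for one residue copy (single chain) against the
# ligand heavy atoms; returns a logical vector over IF_TYPES
residue_bits <- function(res_atoms, lig, rules) {
  bits <- setNames(rep(FALSE, length(IF_TYPES)), IF_TYPES)
  ra <- res_atoms[res_atoms$element != "H", , drop = FALSE]
  if (nrow(ra) == 0 || nrow(lig) == 0) return(bits)
  d2 <- min_cross_dist2(ra$x, ra$y, ra$z, lig$x, lig$y, lig$z)
  contact_pair <- d2 <= rules$contact_max_A^2
  if (!any(contact_pair)) return(bits)
  bits["contact"] <- TRUE
  in_contact_atom <- rowSums(contact_pair) > 0
  bits["backbone"] <- any(ra$backbone & in_contact_atom)
  bits["sidechain"] <- any(!ra$backbone & in_contact_atom)
  resname <- ra$resid[1]
  cs <- rules$class_sets
  bits["polar"] <- resname %in% cs$polar
  bits["hydrophobic"] <- resname %in% cs$hydrophobic
  bits["aromatic"] <- resname %in% cs$aromatic
  bits["charged"] <- resname %in% cs$charged
  # H-bonds: BS acceptor takes from a ligand donor; BS donor gives to a
  # ligand acceptor. Heavy-atom distance criterion; angle only with explicit H.
  hb2 <- rules$hbond_dist_max_A^2
  acc_atoms <- which((ra$backbone & ra$elety %in% c("O", "OXT")) |
                       (!ra$backbone & ra$elety %in% (rules$acceptors[[resname]] %||% character(0))))
  don_atoms <- which((ra$backbone & ra$elety == "N" & resname != "PRO") |
                       (!ra$backbone & ra$elety %in% (rules$donors[[resname]] %||% character(0))))
  ld <- lig_donor_idx(lig)
  la <- lig_acceptor_idx(lig)
  if (length(acc_atoms) && length(ld)) {
    bits["hbond_acceptor"] <- any(d2[acc_atoms, ld, drop = FALSE] <= hb2)
  }
  if (length(don_atoms) && length(la)) {
    bits["hbond_donor"] <- any(d2[don_atoms, la, drop = FALSE] <= hb2)
  }
  bits
}

#' Compute the nine-bit interaction fingerprint of a docked pose
#'
#' Per site residue, the nine detectors are evaluated against each monomer
#' copy and OR-merged: bit = 1 when the interaction is present in at least
#' one monomer. All specific bits imply the contact bit.
#'
#' @param receptor a receptor
#' @param pose the (best-scoring) \code{\link{ligand_pose}} of a compound
#' @param site a \code{\link{define_binding_site}} result
#' @param rules a \code{\link{geometry_rules}}
#' @return integer matrix (site residues x 9 types) of 0/1, dimnames
#'   (\code{"NNN_NAME"}, \code{IF_TYPES}); class \code{interaction_fp} with
#'   attribute \code{compound_id}
#' @export
compute_fingerprint <- function(receptor, pose, site, rules = geometry_rules()) {
  lig <- lig_heavy(pose)
  if (any(is.na(lig$n_H) & lig$element %in% c("N", "O"))) {
    # heavy-atom-only pose: N/O typed as both donor and acceptor
    attr(lig, "typing") <- "distance_only"
  }
  bits <- matrix(0L, nrow = nrow(site), ncol = length(IF_TYPES),
                 dimnames = list(paste0(site$resno, "_", site$resid), IF_TYPES))
  for (r in seq_len(nrow(site))) {
    hit <- receptor$resno == site$resno[r] & receptor$resid == site$resid[r]
    stop_if_not(any(hit), "site residue %d %s absent from receptor",
                site$resno[r], site$resid[r])
    for (ch in unique(receptor$chain[hit])) {
      res_atoms <- receptor[hit & receptor$chain == ch, , drop = FALSE]
      b <- residue_bits(res_atoms, lig, rules)
      bits[r, ] <- bits[r, ] | b
    }
  }
  # implication invariant: a residue without contact has no specific bits
  bits[bits[, "contact"] == 0L, ] <- 0L
  structure(bits, class = c("interaction_fp", class(bits)),
            compound_id = pose$compound_id)
}

#' Fingerprint table for a set of complexes
#'
#' One row per compound; columns in deterministic order (residue number
#' ascending, then the fixed nine-type order), labelled \code{"NNN_type"}
#' (e.g. \code{557_aromatic}).
#'
#' @param receptor shared receptor
#' @param poses list of \code{\link{ligand_pose}} (one per compound)
#' @param site shared binding site
#' @param rules geometry rules
#' @return integer 0/1 matrix (compounds x residue-type bits) with compound
#'   ids as row names
#' @export
fingerprint_matrix <- function(receptor, poses, site, rules = geometry_rules()) {
  ids <- vapply(poses, `[[`, "", "compound_id")
  stop_if_not(!anyDuplicated(ids), "duplicate compound ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- as.vector(t(outer(site$resno, IF_TYPES, paste, sep = "_")))
  m <- matrix(0L, nrow = length(poses), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(poses)) {
    fp <- compute_fingerprint(receptor, poses[[i]], site, rules)
    m[i, ] <- as.vector(t(unclass(fp)))
  }
  m
}

#' Write / read a fingerprint table with its geometry manifest
#'
#' @param fp_matrix a \code{\link{fingerprint_matrix}} result
#' @param path output CSV; a JSON manifest with the geometry rules and site
#'   is written to \code{<path>.manifest.json}
#' @param site,rules objects recorded in the manifest (optional)
#' @return invisibly, \code{path}
#' @export
write_fingerprints <- function(fp_matrix, path, site = NULL, rules = NULL) {
  df <- data.frame(compound_id = rownames(fp_matrix), fp_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  manifest <- list(columns = colnames(fp_matrix))
  if (!is.null(site)) manifest$site <- as.list(as.data.frame(site))
  if (!is.null(rules)) manifest$rules <- unclass(rules)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "compound_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$compound_id
  m
}
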