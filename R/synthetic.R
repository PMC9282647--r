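# Synthetic fixtures: toy tetrameric receptors with controlled ligand
# geometry, and score/fingerprint/IC50 datasets with planted statistical
# structure. Everything the pipeline consumes can be generated here, so no
# docking engine or download is ever needed to exercise it end to end.

# one representative side-chain atom per residue type (poly-ALA-like
# backbones plus this atom are sufficient for all nine interaction
# detectors)
SIDECHAIN_ATOM <- c(ALA = "CB", VAL = "CB", LEU = "CB", ILE = "CB",
                    MET = "SD", PHE = "CZ", TRP = "NE1", PRO = "CB",
                    TYR = "OH", SER = "OG", THR = "OG1", ASN = "OD1",
                    GLN = "OE1", CYS = "SG", HIS = "NE2", ASP = "OD1",
                    GLU = "OE1", LYS = "NZ", ARG = "NH1")

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}

#' Build a toy C-symmetric receptor with a geometrically controlled ligand
#'
#' Generates an \code{n_chains}-fold symmetric receptor (mimicking the
#' tetrameric channel) whose chains carry short poly-alanine-style backbones
#' with one representative side-chain atom per residue, arranged around a
#' central axis. Ligand atoms are placed at exact requested distances from
#' named receptor atoms (along the inward direction, toward the central
#' cavity), or at absolute coordinates.
#'
#' @param residues character vector of 3-letter residue names per chain
#' @param n_chains number of identical chains (default 4)
#' @param ring_radius distance of each chain from the central axis (A)
#' @param spacing spacing between consecutive residues along the axis (A)
#' @param resno_start first residue number (default 551, near the channel
#'   cavity numbering)
#' @param ligand_atoms data.frame describing ligand atoms; either placement
#'   columns (chain, res_index, atom, distance, element) or absolute
#'   coordinates (x, y, z, element); optional charge, n_H columns
#' @param score docking score attached to the pose
#' @param compound_id pose compound id
#' @param lower_is_better score orientation
#' @param pdb_path,sdf_path optional paths: the receptor/pose are also
#'   written to disk in the formats the pipeline reads
#' @return list(receptor, pose)
#' @export
make_toy_complex <- function(residues = c("PHE", "SER", "ALA"),
                             n_chains = 4, ring_radius = 12, spacing = 5,
                             resno_start = 551,
                             ligand_atoms = data.frame(element = "C",
                                                       chain = "A",
                                                       res_index = 1,
                                                       atom = "CZ",
                                                       distance = 3.5),
                             score = -8, compound_id = "LIG1",
                             lower_is_better = TRUE,
                             pdb_path = NULL, sdf_path = NULL) {
  stop_if_not(n_chains >= 1, "n_chains must be >= 1")
  stop_if_not(all(residues %in% names(SIDECHAIN_ATOM) | residues == "GLY"),
              "unknown residue name(s): %s",
              paste(setdiff(residues, c(names(SIDECHAIN_ATOM), "GLY")), collapse = ", "))
  # local backbone template (A), side-chain atom pointing inward (-x)
  template <- rbind(N = c(0.0, 1.4, 0.0), CA = c(0, 0, 0),
                    C = c(1.5, 0.0, 0.0), O = c(1.5, 1.0, 0.9))
  rows <- list()
  for (ci in seq_len(n_chains)) {
    theta <- 2 * pi * (ci - 1) / n_chains
    rot <- rot_z(theta)
    base <- drop(rot %*% c(ring_radius, 0, 0))
    for (ri in seq_along(residues)) {
      res <- residues[ri]
      atoms <- template
      sc <- SIDECHAIN_ATOM[res]
      if (!is.na(sc)) {
        atoms <- rbind(atoms, matrix(c(-1.8, -0.8, 0.4), 1, 3,
                                     dimnames = list(sc, NULL)))
      }
      coords <- t(rot %*% t(atoms)) +
        matrix(base + c(0, 0, (ri - 1) * spacing), nrow(atoms), 3, byrow = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = LETTERS[ci], resno = resno_start + ri - 1L, resid = res,
        elety = rownames(atoms),
        element = substr(gsub("[0-9]", "", rownames(atoms)), 1, 1),
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        backbone = rownames(atoms) %in% BACKBONE_ATOMS,
        stringsAsFactors = FALSE)
    }
  }
  receptor <- structure(do.call(rbind, rows), class = c("receptor", "data.frame"))
  rownames(receptor) <- NULL

  la <- ligand_atoms
  if (is.null(la$charge)) la$charge <- 0
  if (is.null(la$n_H)) la$n_H <- NA_integer_
  coords <- matrix(NA_real_, nrow(la), 3)
  for (i in seq_len(nrow(la))) {
    if (!is.null(la$x) && !is.na(la$x[i])) {
      coords[i, ] <- c(la$x[i], la$y[i], la$z[i])
      next
    }
    stop_if_not(la$distance[i] > 0, "requested placement distance must be > 0")
    hit <- receptor$chain == la$chain[i] &
      receptor$resno == resno_start + la$res_index[i] - 1L &
      receptor$elety == la$atom[i]
    stop_if_not(sum(hit) == 1, "anchor atom %s/%d/%s not found (or ambiguous)",
                la$chain[i], la$res_index[i], la$atom[i])
    p <- as.numeric(receptor[hit, c("x", "y", "z")])
    axis_point <- c(0, 0, p[3])                    # inward, toward the axis
    u <- axis_point - p
    nu <- sqrt(sum(u^2))
    stop_if_not(nu > 0, "anchor atom lies on the symmetry axis; placement infeasible")
    coords[i, ] <- p + la$distance[i] / nu * u
  }
  atoms <- data.frame(element = toupper(la$element),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      charge = la$charge, n_H = la$n_H,
                      stringsAsFactors = FALSE)
  pose <- ligand_pose(compound_id, atoms, score,
                      lower_is_better = lower_is_better)
  if (!is.null(pdb_path)) write_receptor(receptor, pdb_path)
  if (!is.null(sdf_path)) write_poses(list(pose), sdf_path)
  list(receptor = receptor, pose = pose)
}

#' Specification of a planted-structure synthetic dataset
#'
#' The defaults define the package's reference study conditions: two
#' docking-score populations separated by two standard deviations (the
#' binder mean more favourable, GLIDE-like kcal/mol scale), a
#' three-residue-site fingerprint (27 columns) with a few bits enriched in
#' binders, a log-normal IC50 background (median 10 uM, geometric SD 10,
#' clipped to 1 nM - 1 mM) and a multiplicative IC50 effect for planted
#' bits.
#'
#' @param n_binders,n_nonbinders class sizes (>= 60 each so the 50+50
#'   resampling protocol remains feasible)
#' @param ds_mean_binder,ds_mean_nonbinder,ds_sd docking-score Gaussians
#' @param site_resnos residue numbers of the synthetic site
#' @param planted_bits data.frame (label, p_binder, p_nonbinder) of
#'   informative fingerprint columns
#' @param noise_prob Bernoulli probability of all remaining (uninformative)
#'   columns, identical in both classes
#' @param ic50_effect multiplicative IC50 shift applied once per planted bit
#'   set to 1 (e.g. 0.01 = hundredfold lower IC50)
#' @param seed RNG seed
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_binders = 300, n_nonbinders = 300,
                           ds_mean_binder = -8, ds_mean_nonbinder = -6,
                           ds_sd = 1,
                           site_resnos = c(557, 624, 656),
                           planted_bits = data.frame(
                             label = c("557_aromatic", "557_hydrophobic",
                                       "656_contact"),
                             p_binder = c(0.75, 0.70, 0.70),
                             p_nonbinder = c(0.25, 0.30, 0.30),
                             stringsAsFactors = FALSE),
                           noise_prob = 0.3,
                           ic50_effect = 0.1,
                           seed = 1) {
  stop_if_not(ds_sd > 0, "ds_sd must be > 0")
  if (!is.null(planted_bits) && nrow(planted_bits)) {
    stop_if_not(all(planted_bits$p_binder >= 0 & planted_bits$p_binder <= 1 &
                      planted_bits$p_nonbinder >= 0 & planted_bits$p_nonbinder <= 1),
                "planted-bit probabilities must lie in [0, 1]")
    cols <- as.vector(t(outer(site_resnos, IF_TYPES, paste, sep = "_")))
    stop_if_not(all(planted_bits$label %in% cols),
                "planted bit labels must be site columns (NNN_type)")
  }
  structure(list(n_binders = n_binders, n_nonbinders = n_nonbinders,
                 ds_mean_binder = ds_mean_binder,
                 ds_mean_nonbinder = ds_mean_nonbinder, ds_sd = ds_sd,
                 site_resnos = site_resnos, planted_bits = planted_bits,
                 noise_prob = noise_prob, ic50_effect = ic50_effect,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic docking-score / fingerprint / IC50 dataset
#'
#' Docking scores are class-conditional Gaussians; fingerprint bits are
#' independent Bernoulli draws with class-specific probabilities for the
#' planted columns; IC50 values are log-normal with a multiplicative shift
#' per planted bit present. Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @return list with ds (named scores), if_table (0/1 matrix), ic50_uM,
#'   labels (factor nonbinder/binder), and truth (the spec)
#' @export
make_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stop_if_not(spec$n_binders >= 60 && spec$n_nonbinders >= 60,
              "need at least 60 compounds per class for the resampling protocol")
  set.seed(spec$seed)
  n <- spec$n_binders + spec$n_nonbinders
  is_binder <- rep(c(TRUE, FALSE), c(spec$n_binders, spec$n_nonbinders))
  ids <- sprintf("SYN%05d", seq_len(n))
  ds <- rnorm(n, ifelse(is_binder, spec$ds_mean_binder, spec$ds_mean_nonbinder),
              spec$ds_sd)
  names(ds) <- ids
  cols <- as.vector(t(outer(spec$site_resnos, IF_TYPES, paste, sep = "_")))
  probs <- matrix(spec$noise_prob, n, length(cols),
                  dimnames = list(ids, cols))
  pb <- spec$planted_bits
  if (!is.null(pb) && nrow(pb)) {
    for (k in seq_len(nrow(pb))) {
      probs[, pb$label[k]] <- ifelse(is_binder, pb$p_binder[k], pb$p_nonbinder[k])
    }
  }
  if_table <- matrix(rbinom(length(probs), 1L, probs), n,
                     dimnames = dimnames(probs))
  # IC50: log-normal background, median 10 uM, geometric SD 10
  ic50 <- 10^(1 + rnorm(n, 0, 1))
  if (!is.null(pb) && nrow(pb)) {
    n_planted_on <- rowSums(if_table[, pb$label, drop = FALSE])
    ic50 <- ic50 * spec$ic50_effect^n_planted_on
  }
  ic50 <- pmin(pmax(ic50, 1e-3), 1e3)
  labels <- factor(ifelse(is_binder, "binder", "nonbinder"),
                   levels = c("nonbinder", "binder"))
  list(ds = ds, if_table = if_table, ic50_uM = ic50, labels = labels,
       truth = spec)
}
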