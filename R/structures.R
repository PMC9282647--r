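# Receptor and pose I/O. PDB handling goes through bio3d; SDF pose files
# through ChemmineR. The in-memory receptor is a plain data.frame (one row
# per atom) — all geometry downstream is heavy-atom based and works without
# hydrogens.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a receptor structure from PDB
#'
#' Parses standard-amino-acid ATOM records; HETATM ligands, waters and
#' non-standard residues are excluded. Alternate locations keep the
#' highest-occupancy copy. Chains are the monomer ids of the (tetrameric)
#' channel.
#'
#' @param path PDB file
#' @return a \code{receptor}: data.frame with columns chain, resno, resid,
#'   elety (atom name), element, x, y, z, backbone
#' @export
read_receptor <- function(path) {
  stop_if_not(file.exists(path), "PDB file not found: %s", path)
  pdb <- try(suppressWarnings(bio3d::read.pdb(path)), silent = TRUE)
  stop_if_not(!inherits(pdb, "try-error"), "could not parse PDB file %s", path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  stop_if_not(nrow(at) > 0, "no standard amino-acid ATOM records in %s", path)
  # altloc: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    at <- at[order(key, -replace(at$o, is.na(at$o), 1)), , drop = FALSE]
    dup <- duplicated(paste(at$chain, at$resno, at$elety))
    if (any(dup & !is.na(at$alt))) {
      message(sum(dup), " alternate-location atom(s) dropped (kept highest occupancy)")
    }
    at <- at[!dup, , drop = FALSE]
    at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]
  }
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- substr(gsub("[0-9]", "", at$elety[missing_el]), 1, 1)
  rec <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, element = toupper(element),
                    x = at$x, y = at$y, z = at$z,
                    backbone = at$elety %in% BACKBONE_ATOMS,
                    stringsAsFactors = FALSE)
  stop_if_not(all(is.finite(c(rec$x, rec$y, rec$z))), "non-finite coordinates in %s", path)
  structure(rec, class = c("receptor", "data.frame"))
}

#' Write a receptor back to PDB
#'
#' @param receptor a \code{receptor} data.frame
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_receptor <- function(receptor, path) {
  bio3d::write.pdb(pdb = NULL,
                   xyz = as.numeric(t(receptor[, c("x", "y", "z")])),
                   resno = receptor$resno, chain = receptor$chain,
                   resid = receptor$resid, elety = receptor$elety,
                   elesy = receptor$element, file = path)
  invisible(path)
}

#' Construct a ligand pose
#'
#' @param compound_id compound identifier
#' @param atoms data.frame with columns element, x, y, z and optionally
#'   charge (formal) and n_H (attached explicit/implicit hydrogens, used for
#'   H-bond donor typing; NA = unknown)
#' @param score docking score
#' @param units score units tag ("kcal/mol" for GLIDE-like, "kJ/mol" for
#'   GOLD-like conventions)
#' @param lower_is_better score orientation; never inferred from the data
#' @return an object of class \code{ligand_pose}
#' @export
ligand_pose <- function(compound_id, atoms, score, units = "kcal/mol",
                        lower_is_better = TRUE) {
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$n_H)) atoms$n_H <- NA_integer_
  stop_if_not(sum(atoms$element != "H") >= 1, "pose needs at least one heavy atom")
  stop_if_not(is.finite(score), "docking score must be finite")
  stop_if_not(all(is.finite(c(atoms$x, atoms$y, atoms$z))),
              "non-finite pose coordinates")
  structure(list(compound_id = compound_id, atoms = atoms, score = score,
                 units = units, lower_is_better = lower_is_better),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s: %d atoms, score %.3f %s (%s)\n",
              x$compound_id, nrow(x$atoms), x$score, x$units,
              if (x$lower_is_better) "lower is better" else "higher is better"))
  invisible(x)
}

# V2000 old-style charge codes in atom-block column 5
OLD_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                `6` = -2, `7` = -3)

# split an SDF file into per-record line blocks and parse the fixed-width
# V2000 fields of one record. A dedicated parser is used here because
# docking tools routinely emit pose records without bond blocks
# (disconnected atom clouds), which general-purpose SDF readers reject or
# misparse.
parse_sdf_record <- function(lines) {
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1) return(NULL)
  atom_lines <- lines[5:(4 + natoms)]
  el <- toupper(trimws(substr(atom_lines, 32, 34)))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  chg <- OLD_CHARGE[as.character(chg_code)]
  chg[is.na(chg)] <- 0
  atoms <- data.frame(
    element = el,
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    charge = unname(chg), stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.na(nbonds) && nbonds > 0) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(
      from = as.integer(substr(bond_lines, 1, 3)),
      to = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
  }
  # M CHG property lines override old-style charge codes
  for (ml in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", ml)), "\\s+")[[1]])
    k <- f[1]
    if (!is.na(k) && k >= 1) {
      atoms$charge[] <- 0
      for (q in seq_len(k)) atoms$charge[f[2 * q]] <- f[2 * q + 1]
    }
  }
  # data tags
  tags <- list()
  tag_idx <- grep("^> ", lines)
  for (ti in tag_idx) {
    name <- sub(".*<([^>]+)>.*", "\\1", lines[ti])
    if (ti < length(lines)) tags[[name]] <- lines[ti + 1]
  }
  list(id = trimws(lines[1]), atoms = atoms, bonds = bonds, tags = tags)
}

#' Read docked ligand poses from an SDF file
#'
#' One pose per SDF record; the docking score comes from an SDF data tag
#' (\code{score_field}) or from a sidecar table of (compound_id, score).
#' Records without a score are skipped with a message — mirroring the
#' exclusion of undocked molecules. With \code{best_only}, only the
#' best-scoring pose per compound is retained (orientation-aware).
#'
#' @param path SDF (V2000) file
#' @param score_field name of the SDF data tag holding the score
#' @param scores optional sidecar data.frame (compound_id, score) or CSV path
#' @param best_only keep only the best pose per compound (default TRUE)
#' @param lower_is_better score orientation (GLIDE kcal/mol convention TRUE;
#'   GOLD fitness FALSE)
#' @param units score units tag
#' @return list of \code{\link{ligand_pose}} objects; attribute
#'   \code{"skipped"} counts records without a score
#' @export
read_poses <- function(path, score_field = NULL, scores = NULL,
                       best_only = TRUE, lower_is_better = TRUE,
                       units = "kcal/mol") {
  stop_if_not(file.exists(path), "SDF file not found: %s", path)
  all_lines <- readLines(path)
  rec_breaks <- c(0, grep("^\\$\\$\\$\\$", all_lines))
  if (is.character(scores) && length(scores) == 1) scores <- read.csv(scores)
  poses <- list()
  skipped <- 0L
  for (i in seq_len(length(rec_breaks) - 1)) {
    block <- all_lines[(rec_breaks[i] + 1):(rec_breaks[i + 1] - 1)]
    rec <- parse_sdf_record(block)
    if (is.null(rec)) next
    sc <- NA_real_
    if (!is.null(score_field) && !is.null(rec$tags[[score_field]])) {
      sc <- suppressWarnings(as.numeric(rec$tags[[score_field]]))
    }
    if (is.na(sc) && !is.null(scores)) {
      hit <- match(rec$id, scores$compound_id)
      if (!is.na(hit)) sc <- as.numeric(scores$score[hit])
    }
    if (is.na(sc)) { skipped <- skipped + 1L; next }
    atoms <- rec$atoms
    n_H <- integer(nrow(atoms))
    if (!is.null(rec$bonds) && nrow(rec$bonds) > 0) {
      for (k in seq_len(nrow(rec$bonds))) {
        a <- rec$bonds$from[k]; b <- rec$bonds$to[k]
        if (atoms$element[b] == "H") n_H[a] <- n_H[a] + 1L
        if (atoms$element[a] == "H") n_H[b] <- n_H[b] + 1L
      }
    } else {
      n_H[] <- NA_integer_
    }
    atoms$n_H <- n_H
    poses[[length(poses) + 1L]] <- ligand_pose(rec$id, atoms, sc, units = units,
                                               lower_is_better = lower_is_better)
  }
  if (skipped > 0) message(skipped, " SDF record(s) without a docking score skipped")
  if (best_only && length(poses)) {
    by_id <- split(poses, vapply(poses, `[[`, "", "compound_id"))
    poses <- lapply(by_id, function(ps) {
      sc <- vapply(ps, `[[`, 0, "score")
      ps[[if (lower_is_better) which.min(sc) else which.max(sc)]]
    })
    poses <- unname(poses[order(names(by_id))])
  }
  attr(poses, "skipped") <- skipped
  poses
}

#' Write ligand poses to an SDF file with a score tag
#'
#' @param poses list of \code{\link{ligand_pose}}
#' @param path output SDF path
#' @param score_field data-tag name for the score (default "docking_score")
#' @return invisibly, \code{path}
#' @export
write_poses <- function(poses, path, score_field = "docking_score") {
  con <- file(path, "w")
  on.exit(close(con))
  rev_charge <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  for (p in poses) {
    a <- p$atoms
    writeLines(c(p$compound_id, "  hergsift", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), 0L), con)
    for (i in seq_len(nrow(a))) {
      code <- rev_charge[as.character(a$charge[i])]
      if (is.na(code)) code <- 0
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                         a$x[i], a$y[i], a$z[i], a$element[i], code), con)
    }
    writeLines("M  END", con)
    writeLines(c(sprintf(">  <%s>", score_field), format(p$score), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
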