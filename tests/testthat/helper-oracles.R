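# Independent reference implementations ("oracles") used to validate the
# package's fast paths. Deliberately written as plain scalar loops with no
# code shared with the implementation under test.

`%||%` <- function(a, b) if (is.null(a)) b else a

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# brute-force all-pairs interaction fingerprint: triple loop over site
# residues, chains and atom pairs
oracle_fingerprint <- function(receptor, pose, site, rules) {
  lig <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  types <- c("contact", "backbone", "sidechain", "polar", "hydrophobic",
             "hbond_acceptor", "hbond_donor", "aromatic", "charged")
  out <- matrix(0L, nrow(site), length(types),
                dimnames = list(paste0(site$resno, "_", site$resid), types))
  backbone_names <- c("N", "CA", "C", "O", "OXT")
  side_don <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                   GLN = "NE2", HIS = c("ND1", "NE2"), LYS = "NZ",
                   ARG = c("NE", "NH1", "NH2"), TRP = "NE1")
  side_acc <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                   GLN = "OE1", HIS = c("ND1", "NE2"),
                   ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  for (r in seq_len(nrow(site))) {
    resname <- site$resid[r]
    for (ch in unique(receptor$chain)) {
      ra <- receptor[receptor$chain == ch & receptor$resno == site$resno[r] &
                       receptor$resid == resname &
                       receptor$element != "H", , drop = FALSE]
      if (nrow(ra) == 0) next
      contact <- FALSE; bb <- FALSE; sc <- FALSE; acc <- FALSE; don <- FALSE
      for (i in seq_len(nrow(ra))) {
        pa <- c(ra$x[i], ra$y[i], ra$z[i])
        atom_name <- ra$elety[i]
        is_bb <- atom_name %in% backbone_names
        is_acc_atom <- (is_bb && atom_name %in% c("O", "OXT")) ||
          (!is_bb && atom_name %in% (side_acc[[resname]] %||% character(0)))
        is_don_atom <- (is_bb && atom_name == "N" && resname != "PRO") ||
          (!is_bb && atom_name %in% (side_don[[resname]] %||% character(0)))
        for (j in seq_len(nrow(lig))) {
          la <- c(lig$x[j], lig$y[j], lig$z[j])
          d <- dist3(pa, la)
          if (d <= rules$contact_max_A) {
            contact <- TRUE
            if (is_bb) bb <- TRUE else sc <- TRUE
          }
          if (d <= rules$hbond_dist_max_A) {
            el <- lig$element[j]
            lig_don <- el %in% c("N", "O") &&
              (is.na(lig$n_H[j]) || lig$n_H[j] >= 1 ||
                 (el == "N" && lig$charge[j] > 0))
            lig_acc <- el %in% c("N", "O") && lig$charge[j] <= 0
            if (is_acc_atom && lig_don) acc <- TRUE
            if (is_don_atom && lig_acc) don <- TRUE
          }
        }
      }
      if (contact) {
        out[r, "contact"] <- 1L
        if (bb) out[r, "backbone"] <- 1L
        if (sc) out[r, "sidechain"] <- 1L
        if (resname %in% rules$class_sets$polar) out[r, "polar"] <- 1L
        if (resname %in% rules$class_sets$hydrophobic) out[r, "hydrophobic"] <- 1L
        if (resname %in% rules$class_sets$aromatic) out[r, "aromatic"] <- 1L
        if (resname %in% rules$class_sets$charged) out[r, "charged"] <- 1L
        if (acc) out[r, "hbond_acceptor"] <- 1L
        if (don) out[r, "hbond_donor"] <- 1L
      }
    }
  }
  out
}

# brute-force AUC by pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exact two-sample KS statistic by ECDF evaluation at pooled points
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# exact permutation p-value: enumerate all choose(n+m, n) label assignments
oracle_ks_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- oracle_ks_stat(a, b)
  combos <- utils::combn(length(pooled), n)
  count <- 0
  for (k in seq_len(ncol(combos))) {
    aa <- pooled[combos[, k]]
    bb <- pooled[-combos[, k]]
    if (oracle_ks_stat(aa, bb) >= d_obs - 1e-12) count <- count + 1
  }
  count / ncol(combos)
}

# random toy complex for fingerprint fuzzing
random_complex <- function(seed) {
  set.seed(seed)
  res_pool <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                "TYR", "SER", "THR", "ASN", "GLN", "CYS", "HIS", "ASP",
                "GLU", "LYS", "ARG")
  residues <- sample(res_pool, sample(2:4, 1), replace = TRUE)
  n_chains <- sample(1:4, 1)
  n_lig <- sample(1:4, 1)
  anchors <- data.frame(
    element = sample(c("C", "N", "O"), n_lig, replace = TRUE),
    chain = LETTERS[sample(n_chains, n_lig, replace = TRUE)],
    res_index = sample(length(residues), n_lig, replace = TRUE),
    atom = "CA",
    distance = runif(n_lig, 2.0, 11),
    charge = sample(c(0, 0, 0, 1, -1), n_lig, replace = TRUE),
    n_H = sample(c(NA, 0L, 1L, 2L), n_lig, replace = TRUE),
    stringsAsFactors = FALSE)
  make_toy_complex(residues = residues, n_chains = n_chains,
                   ring_radius = runif(1, 8, 15),
                   ligand_atoms = anchors, score = rnorm(1, -7),
                   compound_id = sprintf("RND%d", seed))
}

# rigid-body motion helpers
rotate_translate <- function(xyz, angle, shift) {
  rot <- matrix(c(cos(angle), sin(angle), 0,
                  -sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3)
  sweep(t(rot %*% t(as.matrix(xyz))), 2, -shift)
}
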