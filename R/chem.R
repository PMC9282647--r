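# Small-molecule utilities: SMILES parsing, desalting, canonical keys,
# molecular weights and circular atom-environment fingerprints.
# Structure handling is delegated to ChemmineR/ChemmineOB (OpenBabel); the
# fingerprint itself is computed here on the molecular graph.

#' Parse SMILES strings into an SDFset
#'
#' Invalid SMILES do not abort the batch: they are dropped and reported via
#' the \code{"failed"} attribute (indices into \code{smiles}).
#'
#' @param smiles character vector of SMILES; names are used as compound ids
#' @return a \code{ChemmineR::SDFset} for the valid molecules, with attribute
#'   \code{"failed"} giving the positions of unparsable inputs
#' @export
parse_smiles <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- paste0("cmp", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ok <- ChemmineR::validSDF(sdf)
  out <- sdf[ok]
  attr(out, "failed") <- unname(which(!ok))
  out
}

#' Keep the largest organic fragment of a SMILES (desalting)
#'
#' Counterions and solvents are recorded as dot-separated fragments in ChEMBL
#' exports; the parent is taken to be the fragment with the most atoms
#' (ties: the longer SMILES string).
#'
#' @param smiles character vector
#' @return character vector of parent-fragment SMILES
#' @export
desalt_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    # heavy-atom count approximated by letters outside brackets' charges;
    # adequate for fragment ranking
    n_atoms <- vapply(frags, function(f) {
      sum(gregexpr("[A-Za-z]", gsub("\\[.*?\\]", "X", f))[[1]] > 0) +
        lengths(regmatches(f, gregexpr("\\[", f)))
    }, numeric(1))
    frags[order(-n_atoms, -nchar(frags))][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical SMILES via OpenBabel
#'
#' Used as the duplicate key during curation (on the desalted parent).
#' Unparsable inputs return \code{NA}.
#'
#' @param smiles character vector
#' @return character vector of canonical SMILES (NA where invalid)
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    res <- try(suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\tm\n"))
    ), silent = TRUE)
    if (!inherits(res, "try-error") && nzchar(res)) {
      out[i] <- strsplit(res, "[\t\n]")[[1]][1]
    }
  }
  out
}

#' Molecular weight (Da, implicit hydrogens included) from SMILES
#'
#' @param smiles character vector
#' @return numeric vector of molecular weights; NA for invalid SMILES
#' @export
smiles_mw <- function(smiles) {
  out <- rep(NA_real_, length(smiles))
  sdf <- parse_smiles(smiles)
  failed <- attr(sdf, "failed")
  keep <- setdiff(seq_along(smiles), failed)
  if (length(keep)) {
    props <- suppressWarnings(ChemmineR::propOB(sdf))
    out[keep] <- props$MW
  }
  out
}

# default valences for implicit-hydrogen estimation (adjusted by formal
# charge; elements not listed get no implicit hydrogens)
DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                     F = 1, CL = 1, BR = 1, I = 1)

# molecular graph (elements, bonds, charges) from one ChemmineR SDF
sdf_graph <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elements <- sub("_\\d+$", "", rownames(ab))
  n <- length(elements)
  charges <- rep(0, n)
  if ("C5" %in% colnames(ab)) {
    chg <- OLD_CHARGE[as.character(ab[, "C5"])]
    charges <- ifelse(is.na(chg), 0, chg)
  }
  adj <- vector("list", n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (k in seq_len(nrow(bb))) {
      i <- bb[k, 1]; j <- bb[k, 2]; o <- bb[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  list(elements = elements, adj = adj, charges = charges)
}

# iterated atom-environment identifiers (Morgan algorithm on the heavy-atom
# graph): identifiers from all radii 0..radius are pooled. The initial atom
# invariant is (element, heavy degree, total H count), with implicit
# hydrogens estimated from default valence minus the bond-order sum.
morgan_identifiers <- function(graph, radius = 2) {
  el <- graph$elements
  heavy <- which(el != "H")
  deg <- vapply(seq_along(el), function(i) {
    a <- graph$adj[[i]]
    if (is.null(a)) 0L else sum(el[a[, 1]] != "H")
  }, integer(1))
  nh_exp <- vapply(seq_along(el), function(i) {
    a <- graph$adj[[i]]
    if (is.null(a)) 0L else sum(el[a[, 1]] == "H")
  }, integer(1))
  bond_sum <- vapply(seq_along(el), function(i) {
    a <- graph$adj[[i]]
    if (is.null(a)) 0 else sum(a[, 2])
  }, numeric(1))
  val <- DEFAULT_VALENCE[toupper(el)]
  nh <- nh_exp + pmax(0, ifelse(is.na(val), 0, val + graph$charges - bond_sum))
  ids <- paste0(el, ":", deg, ":", nh)[heavy]
  names(ids) <- as.character(heavy)
  all_ids <- ids
  cur <- ids
  r <- 0
  while (r < radius) {
    nxt <- cur
    for (idx in seq_along(heavy)) {
      i <- heavy[idx]
      a <- graph$adj[[i]]
      if (is.null(a)) next
      nb <- a[el[a[, 1]] != "H", , drop = FALSE]
      if (nrow(nb) == 0) next
      parts <- paste0(nb[, 2], "|", cur[as.character(nb[, 1])])
      nxt[idx] <- paste0("(", cur[idx], ")[", paste(sort(parts), collapse = ","), "]")
    }
    cur <- nxt
    all_ids <- c(all_ids, cur)
    r <- r + 1
  }
  unique(unname(all_ids))
}

#' Circular (Morgan-style) atom-environment fingerprint
#'
#' Radius-2 hashed circular fingerprints over the heavy-atom graph, the
#' standard choice for measuring dataset diversity. Environment identifiers
#' (element, heavy degree, attached-H count, iterated over bonded neighbours)
#' are folded into \code{n_bits} positions; with \code{n_bits = NULL} the raw
#' identifier strings are returned instead, which is useful for exact
#' set-based comparisons.
#'
#' @param smiles character vector of SMILES
#' @param radius environment radius (bond steps), default 2
#' @param n_bits fingerprint length (power of two), default 2048; NULL for
#'   unhashed identifier sets
#' @return a list (one element per molecule) of sorted integer bit positions
#'   (1-based), or of identifier character vectors when \code{n_bits} is NULL;
#'   NULL entries mark unparsable SMILES
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  if (!is.null(n_bits)) {
    stop_if_not(n_bits > 0 && bitwAnd(n_bits, n_bits - 1L) == 0,
                "n_bits must be a power of two")
  }
  sdf <- parse_smiles(smiles)
  failed <- attr(sdf, "failed")
  keep <- setdiff(seq_along(smiles), failed)
  out <- vector("list", length(smiles))
  for (k in seq_along(keep)) {
    ids <- morgan_identifiers(sdf_graph(sdf[[k]]), radius = radius)
    out[[keep[k]]] <- if (is.null(n_bits)) sort(ids) else
      sort(unique(as.integer(hash_string(ids) %% n_bits) + 1L))
  }
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b fingerprints as vectors of set positions (or identifier strings)
#' @return |intersection| / |union|, in [0, 1]; 1 when both are empty
#' @export
tanimoto_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

# dense 0/1 matrix (molecules x bits) from a list of bit-position fingerprints
fp_bit_matrix <- function(fps, n_bits) {
  m <- matrix(0L, nrow = length(fps), ncol = n_bits)
  for (i in seq_along(fps)) if (length(fps[[i]])) m[i, fps[[i]]] <- 1L
  m
}
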