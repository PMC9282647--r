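# Bioactivity curation: ChEMBL-style activity tables -> labelled
# binder/nonbinder datasets, internal diversity, representative selection.

#' Read a ChEMBL-style activity table
#'
#' Accepts CSV or TSV exports in the dialect of ChEMBL activity downloads.
#' Column names are matched case-insensitively against a configurable map;
#' both the web-export headers ("Molecule ChEMBL ID", "Standard Value", ...)
#' and their snake_case equivalents are recognised out of the box.
#'
#' @param path file path (.csv or .tsv/.txt; delimiter sniffed from the header)
#' @param col_map named list overriding default column-name candidates; keys:
#'   compound_id, smiles, standard_type, value, units, assay_type, organism,
#'   validity, mw
#' @return data.frame of activity records with normalised column names
#'   (compound_id, smiles, standard_type, value, units, assay_type, organism,
#'   validity, mw where available)
#' @export
read_activity_table <- function(path, col_map = list()) {
  stop_if_not(file.exists(path), "activity table not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
                 quote = "\"", comment.char = "")
  defaults <- list(
    compound_id   = c("molecule chembl id", "molecule_chembl_id", "compound_id"),
    smiles        = c("smiles", "canonical_smiles"),
    standard_type = c("standard type", "standard_type"),
    value         = c("standard value", "standard_value", "value", "ic50_nM"),
    units         = c("standard units", "standard_units", "units"),
    assay_type    = c("assay type", "assay_type"),
    organism      = c("target organism", "target_organism", "organism"),
    validity      = c("data validity comment", "data_validity_comment"),
    mw            = c("molecular weight", "molecular_weight", "molecular_weight_Da", "mw")
  )
  for (k in names(col_map)) defaults[[k]] <- c(col_map[[k]], defaults[[k]])
  lower <- tolower(names(df))
  out <- list()
  for (k in names(defaults)) {
    hit <- match(tolower(defaults[[k]]), lower)
    hit <- hit[!is.na(hit)]
    if (length(hit)) out[[k]] <- df[[hit[1]]]
  }
  stop_if_not(!is.null(out$compound_id) && !is.null(out$smiles),
              "could not locate compound id / SMILES columns in %s", path)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Curation policy
#'
#' Defaults reproduce the hERG dataset-construction filters: IC50-only
#' entries, human target, binding ("B") assays, no data-validity warnings,
#' molecular weight within [200, 600] Da, duplicates collapsed on the
#' canonical desalted parent structure.
#'
#' @param require_ic50 keep only records whose standard type is IC50
#' @param organism required target organism (NULL disables)
#' @param assay_type required assay type code (NULL disables)
#' @param reject_validity_warnings drop records with a non-empty
#'   data-validity comment
#' @param mw_min_Da,mw_max_Da molecular-weight window in Da
#' @param dedup collapse structural duplicates (canonical parent key),
#'   keeping the record with the lowest IC50
#' @return an object of class \code{curation_policy}
#' @export
curation_policy <- function(require_ic50 = TRUE,
                            organism = "Homo sapiens",
                            assay_type = "B",
                            reject_validity_warnings = TRUE,
                            mw_min_Da = 200,
                            mw_max_Da = 600,
                            dedup = TRUE) {
  stop_if_not(mw_min_Da < mw_max_Da, "mw_min_Da must be < mw_max_Da")
  structure(list(require_ic50 = require_ic50, organism = organism,
                 assay_type = assay_type,
                 reject_validity_warnings = reject_validity_warnings,
                 mw_min_Da = mw_min_Da, mw_max_Da = mw_max_Da, dedup = dedup),
            class = "curation_policy")
}

# normalise the activity value column: numeric nM (or per units column) to
# uM; the ChEMBL "not a number" sentinel (any case) and blank values map to
# NaN, which downstream labelling treats as a nonbinder annotation
normalize_ic50_uM <- function(value, units = NULL) {
  raw <- trimws(as.character(value))
  sentinel <- is.na(raw) | raw == "" |
    tolower(raw) %in% c("not a number", "nan", "na")
  num <- suppressWarnings(as.numeric(raw))
  out <- ifelse(sentinel, NaN, num)
  if (is.null(units)) units <- rep("nM", length(out))
  units <- tolower(trimws(as.character(units)))
  units[is.na(units) | units == ""] <- "nm"
  scale <- c(nm = 1e-3, um = 1, "µm" = 1, mm = 1e3, m = 1e6,
             pm = 1e-6)
  fac <- unname(scale[units])
  fac[is.na(fac)] <- 1e-3
  out * fac
}

#' Curate activity records
#'
#' Applies the curation filters in sequence and records a per-filter audit
#' count. IC50 values are converted to uM internally (ChEMBL standard values
#' are nM; a units column overrides). Records whose SMILES cannot be parsed
#' are rejected, not fatal. Molecular weight is taken from the table when
#' present and computed from the (desalted) structure otherwise.
#'
#' @param records data.frame from \code{\link{read_activity_table}} (or of the
#'   same shape)
#' @param policy a \code{\link{curation_policy}}
#' @return list with elements \code{records} (the curated data.frame, with
#'   added columns ic50_uM, parent_smiles, parent_key, mw) and \code{audit}
#'   (named integer vector: records remaining after each filter)
#' @export
curate_activities <- function(records, policy = curation_policy()) {
  stopifnot(inherits(policy, "curation_policy"))
  audit <- c(input = nrow(records))
  if (nrow(records) == 0) {
    return(list(records = records, audit = audit))
  }
  df <- records
  df$ic50_uM <- normalize_ic50_uM(df$value %||% df$ic50_nM, df$units)

  if (isTRUE(policy$require_ic50) && !is.null(df$standard_type)) {
    df <- df[!is.na(df$standard_type) &
               toupper(trimws(df$standard_type)) == "IC50", , drop = FALSE]
  }
  audit <- c(audit, ic50_only = nrow(df))

  if (!is.null(policy$organism) && !is.null(df$organism)) {
    df <- df[!is.na(df$organism) & df$organism == policy$organism, , drop = FALSE]
  }
  audit <- c(audit, organism = nrow(df))

  if (!is.null(policy$assay_type) && !is.null(df$assay_type)) {
    df <- df[!is.na(df$assay_type) &
               trimws(df$assay_type) == policy$assay_type, , drop = FALSE]
  }
  audit <- c(audit, assay_type = nrow(df))

  if (isTRUE(policy$reject_validity_warnings) && !is.null(df$validity)) {
    df <- df[is.na(df$validity) | trimws(df$validity) == "", , drop = FALSE]
  }
  audit <- c(audit, validity = nrow(df))

  # structure-dependent filters
  if (nrow(df) > 0) {
    df$parent_smiles <- desalt_smiles(df$smiles)
    df$parent_key <- canonical_smiles(df$parent_smiles)
    parsable <- !is.na(df$parent_key)
    df <- df[parsable, , drop = FALSE]
  }
  audit <- c(audit, smiles_valid = nrow(df))

  if (nrow(df) > 0) {
    mw <- suppressWarnings(as.numeric(df$mw %||% rep(NA_real_, nrow(df))))
    need <- is.na(mw)
    if (any(need)) mw[need] <- smiles_mw(df$parent_smiles[need])
    df$mw <- mw
    df <- df[!is.na(df$mw) & df$mw >= policy$mw_min_Da & df$mw <= policy$mw_max_Da,
             , drop = FALSE]
  }
  audit <- c(audit, mw_window = nrow(df))

  if (isTRUE(policy$dedup) && nrow(df) > 0) {
    # keep the lowest-IC50 record per canonical parent (conservative for
    # toxicity: the most potent measurement wins); NaN sorts last
    key <- df$parent_key
    ord <- order(key, ifelse(is.nan(df$ic50_uM), Inf, df$ic50_uM))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$parent_key), , drop = FALSE]
    df <- df[order(match(df$compound_id, records$compound_id)), , drop = FALSE]
  }
  audit <- c(audit, dedup = nrow(df))

  rownames(df) <- NULL
  list(records = df, audit = audit)
}

#' Labelling policy (binder / nonbinder IC50 thresholds)
#'
#' @param active_max_uM binders have IC50 at or below this (default 1 uM)
#' @param inactive_min_uM nonbinders have IC50 above this (the inactivity
#'   threshold; the study grid is 1, 10, 20, ..., 80 uM)
#' @param nan_is_negative treat the "not a number" IC50 sentinel as a
#'   nonbinder annotation (default TRUE)
#' @return an object of class \code{labeling_policy}
#' @export
labeling_policy <- function(active_max_uM = 1, inactive_min_uM = 80,
                            nan_is_negative = TRUE) {
  stop_if_not(inactive_min_uM >= active_max_uM,
              "inactive_min_uM (%g) must be >= active_max_uM (%g)",
              inactive_min_uM, active_max_uM)
  structure(list(active_max_uM = active_max_uM,
                 inactive_min_uM = inactive_min_uM,
                 nan_is_negative = nan_is_negative),
            class = "labeling_policy")
}

#' Assign binder/nonbinder labels
#'
#' Binders: IC50 <= active_max_uM. Nonbinders: IC50 > inactive_min_uM, plus
#' sentinel ("not a number") records when \code{nan_is_negative}. Records
#' strictly between the bounds are excluded from the labelled set.
#'
#' @param records curated data.frame with columns compound_id and ic50_uM
#' @param policy a \code{\link{labeling_policy}}
#' @return data.frame (compound_id, ic50_uM, label) of class
#'   \code{labeled_dataset} with attribute \code{threshold_uM}; label is a
#'   factor with levels nonbinder, binder
#' @export
assign_labels <- function(records, policy = labeling_policy()) {
  stopifnot(inherits(policy, "labeling_policy"))
  ic50 <- records$ic50_uM
  binder <- !is.na(ic50) & !is.nan(ic50) & ic50 <= policy$active_max_uM
  nonbinder <- (!is.na(ic50) & !is.nan(ic50) & ic50 > policy$inactive_min_uM) |
    (is.nan(ic50) & isTRUE(policy$nan_is_negative))
  keep <- binder | nonbinder
  out <- data.frame(compound_id = records$compound_id[keep],
                    ic50_uM = ic50[keep],
                    label = factor(ifelse(binder[keep], "binder", "nonbinder"),
                                   levels = c("nonbinder", "binder")),
                    stringsAsFactors = FALSE)
  stop_if_not(!anyDuplicated(out$compound_id),
              "duplicate compound ids in labelled set; curate with dedup first")
  structure(out, threshold_uM = policy$inactive_min_uM, class = c("labeled_dataset", "data.frame"))
}

#' Internal diversity of a compound set
#'
#' Mean over all unordered pairs of (1 - Tanimoto similarity) of hashed
#' circular fingerprints; 0 for a set of identical structures, approaching 1
#' for a maximally diverse set. The pairwise loop is exact (no sampling),
#' computed via bit-matrix cross products.
#'
#' @param smiles character vector (at least 2 molecules)
#' @param radius,n_bits fingerprint parameters (defaults: radius 2, 2048 bits)
#' @return mean pairwise Tanimoto distance in [0, 1]
#' @export
internal_diversity <- function(smiles, radius = 2, n_bits = 2048) {
  stop_if_not(length(smiles) >= 2, "internal diversity needs >= 2 molecules")
  fps <- morgan_fingerprint(smiles, radius = radius, n_bits = n_bits)
  ok <- !vapply(fps, is.null, logical(1))
  stop_if_not(sum(ok) >= 2, "fewer than 2 parsable molecules")
  m <- fp_bit_matrix(fps[ok], n_bits)
  counts <- rowSums(m)
  inter <- tcrossprod(m)                       # |A n B|
  un <- outer(counts, counts, "+") - inter     # |A u B|
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1))
  n <- nrow(m)
  dist_sum <- sum(1 - sim[upper.tri(sim)])
  dist_sum / (n * (n - 1) / 2)
}

#' Select representative compounds by fingerprint k-means clustering
#'
#' Clusters hashed circular fingerprints (binary vectors) with k-means and
#' returns, per cluster, the compound with the lowest IC50 — the protocol
#' used to pick representative high-affinity binders for induced-fit
#' docking. Deterministic under a fixed seed.
#'
#' @param records data.frame with columns compound_id, smiles (or
#'   parent_smiles) and ic50_uM (all numeric)
#' @param k number of clusters (default 5)
#' @param radius,n_bits fingerprint parameters
#' @param seed RNG seed for the k-means initialisation
#' @param nstart k-means restarts
#' @return character vector of k compound ids, ordered by cluster size
#'   (largest first)
#' @export
select_representatives <- function(records, k = 5, radius = 2, n_bits = 2048,
                                   seed = 1, nstart = 10) {
  smiles <- records$parent_smiles %||% records$smiles
  ic50 <- records$ic50_uM
  stop_if_not(all(is.finite(ic50)), "all records need a numeric IC50")
  stop_if_not(k >= 1 && k <= nrow(records),
              "k (%d) must be between 1 and the number of compounds (%d)",
              k, nrow(records))
  fps <- morgan_fingerprint(smiles, radius = radius, n_bits = n_bits)
  ok <- !vapply(fps, is.null, logical(1))
  stop_if_not(all(ok), "unparsable SMILES among records: %s",
              paste(records$compound_id[!ok], collapse = ", "))
  m <- fp_bit_matrix(fps, n_bits)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (k == nrow(records)) {
    cl <- seq_len(nrow(records))
  } else {
    set.seed(seed)
    cl <- kmeans(m, centers = k, nstart = nstart, iter.max = 100)$cluster
  }
  reps <- vapply(split(seq_len(nrow(records)), cl), function(idx) {
    records$compound_id[idx[which.min(ic50[idx])]]
  }, character(1))
  sizes <- table(cl)
  unname(reps[order(-as.numeric(sizes), names(sizes))])
}

#' Write a curated set with its audit trail
#'
#' @param curated result of \code{\link{curate_activities}}
#' @param path output CSV path; the audit counts are written alongside as
#'   \code{<path>.audit.json}
#' @return invisibly, the two paths written
#' @export
write_curated <- function(curated, path) {
  write.csv(curated$records, path, row.names = FALSE)
  audit_path <- paste0(path, ".audit.json")
  jsonlite::write_json(as.list(curated$audit), audit_path, auto_unbox = TRUE)
  invisible(c(path, audit_path))
}
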