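# Activity-table curation, labelling, diversity, representative selection

fixture_records <- function() {
  # 10 records engineered so each filter removes a known subset:
  # 2 non-human, 1 functional assay, 1 low-MW (cyclohexane, 84 Da), and one
  # structural duplicate pair (diphenhydramine twice) -> 5 survive
  data.frame(
    compound_id = paste0("CPD", 1:10),
    smiles = c("CN(C)CCOC(c1ccccc1)c1ccccc1",     # diphenhydramine, keep
               "CN(C)CCOC(c1ccccc1)c1ccccc1",     # duplicate of CPD1
               "C1CCCCC1",                        # MW 84 -> removed
               "c1ccc2c(c1)Cc1ccccc1C2CCN(C)C",   # keep
               "CCOC(=O)c1ccccc1NCCc1ccccc1",     # keep
               "CCOC(=O)c1ccccc1NCCCc1ccccc1",    # non-human
               "Cc1ccccc1CCN(C)CC(O)c1ccccc1",    # keep
               "COc1ccccc1CCN1CCC(O)CC1",         # keep
               "COc1ccccc1CCN1CCC(N)CC1",         # non-human
               "Oc1ccc2c(c1)CCN(CCCc1ccccc1)C2"), # functional assay
    standard_type = "IC50",
    value = c(500, 2000, 100, 50, 1000, 1000, 120000, 90000, 300, 10),
    units = "nM",
    assay_type = c("B", "B", "B", "B", "B", "B", "B", "B", "B", "F"),
    organism = c(rep("Homo sapiens", 5), "Rattus norvegicus", "Homo sapiens",
                 "Homo sapiens", "Rattus norvegicus", "Homo sapiens"),
    validity = "",
    stringsAsFactors = FALSE)
}

test_that("curation applies each filter and reports an audit trail", {
  res <- curate_activities(fixture_records(),
                           curation_policy(mw_min_Da = 200, mw_max_Da = 600))
  expect_equal(nrow(res$records), 5L)
  expect_setequal(res$records$compound_id, c("CPD1", "CPD4", "CPD5", "CPD7", "CPD8"))
  aud <- res$audit
  expect_equal(unname(aud[["input"]]), 10L)
  expect_equal(unname(aud[["organism"]]), 8L)     # two rat records out
  expect_equal(unname(aud[["assay_type"]]), 7L)   # one functional assay out
  expect_equal(unname(aud[["mw_window"]]), 6L)    # cyclohexane + aspirin dup remain until dedup
  expect_equal(unname(aud[["dedup"]]), 5L)
  # the duplicate kept is the lower-IC50 aspirin record
  expect_true("CPD1" %in% res$records$compound_id)
  expect_false("CPD2" %in% res$records$compound_id)
})

test_that("curation is idempotent and empty input passes through", {
  res1 <- curate_activities(fixture_records())
  res2 <- curate_activities(res1$records)
  expect_equal(res2$records$compound_id, res1$records$compound_id)
  expect_equal(res2$records$ic50_uM, res1$records$ic50_uM)
  empty <- curate_activities(fixture_records()[0, , drop = FALSE])
  expect_equal(nrow(empty$records), 0L)
})

test_that("IC50 values convert to uM and the NaN sentinel is recognised", {
  df <- data.frame(compound_id = c("a", "b", "c", "d"),
                   smiles = "CCO",
                   value = c("1000", "Not A Number", "nan", "2.5"),
                   units = c("nM", "nM", "nM", "uM"),
                   stringsAsFactors = FALSE)
  ic50 <- hergsift:::normalize_ic50_uM(df$value, df$units)
  expect_equal(ic50[1], 1)
  expect_true(is.nan(ic50[2]) && is.nan(ic50[3]))
  expect_equal(ic50[4], 2.5)
})

test_that("labels follow the binder/nonbinder thresholds with a gap", {
  rec <- data.frame(compound_id = paste0("c", 1:5),
                    ic50_uM = c(1.0, 0.2, 40, 100, NaN))
  lab <- assign_labels(rec, labeling_policy(active_max_uM = 1,
                                            inactive_min_uM = 80))
  got <- setNames(as.character(lab$label), lab$compound_id)
  expect_equal(got[["c1"]], "binder")        # boundary: IC50 <= 1 uM
  expect_equal(got[["c2"]], "binder")
  expect_false("c3" %in% names(got))         # 40 uM falls in the gap
  expect_equal(got[["c4"]], "nonbinder")
  expect_equal(got[["c5"]], "nonbinder")     # "not a number" sentinel
  expect_error(labeling_policy(active_max_uM = 10, inactive_min_uM = 1),
               "must be >=")
})

test_that("labelling partitions the curated set; nonbinders shrink as the threshold rises", {
  set.seed(11)
  rec <- data.frame(compound_id = paste0("m", 1:200),
                    ic50_uM = c(10^runif(180, -2, 3), rep(NaN, 20)))
  prev_nonbinders <- Inf
  for (thr in c(1, 10, 20, 40, 80)) {
    lab <- assign_labels(rec, labeling_policy(inactive_min_uM = thr))
    n_b <- sum(lab$label == "binder")
    n_n <- sum(lab$label == "nonbinder")
    excluded <- setdiff(rec$compound_id, lab$compound_id)
    expect_equal(n_b + n_n + length(excluded), nrow(rec))
    expect_lte(n_n, prev_nonbinders)
    prev_nonbinders <- n_n
  }
})

test_that("representative selection returns the lowest-IC50 member of each cluster", {
  # two planted similarity blocks: alkyl amines vs phenothiazine-like aromatics
  rec <- data.frame(
    compound_id = paste0("R", 1:6),
    smiles = c("CCCCCCN", "CCCCCCCN", "CCCCCN",
               "c1ccc2c(c1)Sc1ccccc1N2CCCN(C)C",
               "c1ccc2c(c1)Sc1ccccc1N2CCCN(C)CC",
               "c1ccc2c(c1)Sc1ccccc1N2CCN(C)C"),
    ic50_uM = c(5, 0.5, 7, 2, 0.01, 3),
    stringsAsFactors = FALSE)
  reps <- select_representatives(rec, k = 2, seed = 7)
  expect_setequal(reps, c("R2", "R5"))
  # k = n returns everyone; k > n errors
  expect_setequal(select_representatives(rec, k = 6, seed = 1), rec$compound_id)
  expect_error(select_representatives(rec, k = 7), "between 1")
  # deterministic under a fixed seed
  expect_identical(select_representatives(rec, k = 2, seed = 7), reps)
})

test_that("activity tables read from both export dialects", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("Molecule ChEMBL ID\tSmiles\tStandard Type\tStandard Value\tStandard Units\tAssay Type\tTarget Organism\tData Validity Comment",
               "CHEMBL1\tCCO\tIC50\t1000\tnM\tB\tHomo sapiens\t"), tf)
  df <- read_activity_table(tf)
  expect_equal(df$compound_id, "CHEMBL1")
  expect_equal(df$value, 1000)
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("molecule_chembl_id,canonical_smiles,standard_type,standard_value,standard_units,assay_type,target_organism,data_validity_comment",
               "CHEMBL2,CCN,IC50,500,nM,B,Homo sapiens,"), tf2)
  df2 <- read_activity_table(tf2)
  expect_equal(df2$compound_id, "CHEMBL2")
})
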