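# Curation: parsing, filtering, deduplication, kinase coverage.

make_table <- function(...) {
  tibble::tibble(...)
}

base_rows <- function() {
  make_table(
    compound_smiles = c(
      "C=CC(=O)Nc1ccccc1", # acrylamide anilide, warhead 1
      "O=Cc1ccccc1", # benzaldehyde, warhead 26
      "CC#CC(=O)Nc1ccncc1" # butynamide, warhead 4
    ),
    kinase_id = c("EGFR", "BTK", "JAK3"),
    assay_type = c("IC50", "Ki", "Kd"),
    value_nM = c("12.5", "400", "9999"),
    confidence = c("9", "9", "9"),
    source = "chembl"
  )
}

test_that("well-formed tables parse and bad rows are dropped with counts", {
  tab <- base_rows()
  path <- write_activity_fixture(tab)
  rec <- read_activity_table(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$value_nM, c(12.5, 400, 9999))

  tab2 <- dplyr::bind_rows(
    tab,
    make_table(
      compound_smiles = c("not-a-smiles", "CCO"),
      kinase_id = c("EGFR", "EGFR"), assay_type = c("IC50", "IC50"),
      value_nM = c("55", "n/a"), confidence = c("9", "9"), source = "chembl"
    )
  )
  rec2 <- read_activity_table(write_activity_fixture(tab2))
  expect_equal(nrow(rec2), 3L)
  log <- attr(rec2, "curation_log")
  expect_equal(log$n_bad_smiles, 1L)
  expect_equal(log$n_bad_value, 1L)
  # conservation: every input row is accounted for exactly once
  expect_equal(log$n_rows, log$n_records + log$n_bad_smiles + log$n_bad_value)
})

test_that("a table lacking a required column raises a schema error", {
  tab <- base_rows()[, c("compound_smiles", "assay_type", "value_nM")]
  expect_error(
    read_activity_table(write_activity_fixture(tab)),
    "kinase_id"
  )
})

test_that("dialect mapping renames columns and reads CSV", {
  tab <- base_rows()
  names(tab) <- c("smiles_col", "target", "type", "val", "conf", "src")
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  rec <- read_activity_table(path, dialect = list(
    smiles = "smiles_col", kinase = "target", assay_type = "type",
    value = "val", confidence = "conf", source = "src"
  ))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$kinase_id, c("EGFR", "BTK", "JAK3"))
})

test_that("activity, confidence and whitelist filters behave as specified", {
  rec <- make_table(
    compound_smiles = "C=CC(=O)Nc1ccccc1",
    kinase_id = c("EGFR", "EGFR", "EGFR", "NOTAKINASE", "EGFR", "EGFR", "EGFR"),
    assay_type = "IC50",
    value_nM = c(15000, 5, 10000, 5, 5, 9000, 12000),
    value_qualifier = c("", "", "", "", "", "<", "<"),
    confidence = c(9L, 9L, 9L, 9L, 8L, 9L, 9L),
    source = "chembl"
  )
  out <- apply_filters(rec, curation_config())
  # row 1: 15000 nM excluded; row 2 retained; row 3 exactly at the
  # threshold excluded (strict "<"); row 4 off-whitelist; row 5 low
  # confidence; row 6 "<9000" retained; row 7 "<12000" excluded
  expect_equal(nrow(out), 2L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_in, 7L)
  expect_equal(rep$n_retained + rep$n_excluded, rep$n_in)
  # rows 1 (15000), 3 (exactly 10000, strict "<") and 7 ("<12000") fail
  expect_equal(rep$n_over_threshold, 3L)
  expect_equal(rep$n_low_confidence, 1L)
  expect_equal(rep$n_off_whitelist, 1L)
})

test_that("confidence enforcement honours per-source exemptions", {
  rec <- make_table(
    compound_smiles = "C=CC(=O)Nc1ccccc1",
    kinase_id = "EGFR", assay_type = "Ki",
    value_nM = c(10, 10, 10),
    value_qualifier = "",
    confidence = c(7L, NA, 7L),
    source = c("chembl", "bindingdb", "bindingdb")
  )
  # enforce everywhere a score exists: NA-confidence record is exempt
  out <- apply_filters(rec, curation_config())
  expect_equal(nrow(out), 1L)
  # enforce only for chembl: bindingdb rows pass regardless
  out2 <- apply_filters(rec, curation_config(enforce_confidence = "chembl"))
  expect_equal(nrow(out2), 2L)
  out3 <- apply_filters(rec, curation_config(enforce_confidence = FALSE))
  expect_equal(nrow(out3), 3L)
})

test_that("filtering is idempotent and monotone", {
  batch <- test_batch()
  tab <- generate_activity_table(
    batch,
    noise = list(n_over_threshold = 8, n_low_confidence = 5, n_off_whitelist = 4),
    seed = 11L
  )
  cfg <- curation_config()
  once <- apply_filters(tab, cfg)
  twice <- apply_filters(once, cfg)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once), ignore_attr = TRUE)
  # tightening the threshold can only shrink the result
  n_prev <- Inf
  for (thr in c(10000, 1000, 100, 10)) {
    n_now <- nrow(apply_filters(tab, curation_config(activity_threshold_nM = thr)))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  # shrinking the whitelist can only shrink the result
  small <- apply_filters(tab, curation_config(kinase_whitelist = c("EGFR", "BTK")))
  expect_lte(nrow(small), nrow(once))
})

test_that("kinase identifiers are normalised through the alias map", {
  expect_equal(normalize_kinase_ids(c("erk2", "Egfr", "HER2")), c("MAPK1", "EGFR", "ERBB2"))
})

test_that("CKI set construction dedupes pairs and drops warhead-free compounds", {
  lib <- test_lib()
  rec <- make_table(
    compound_smiles = c(
      "C=CC(=O)Nc1ccccc1", "C=CC(=O)Nc1ccccc1", # same compound+kinase, two assays
      "C=CC(=O)Nc1ccccc1", # same compound, second kinase
      "CCO" # passes filters but has no warhead
    ),
    kinase_id = c("EGFR", "EGFR", "BTK", "EGFR"),
    assay_type = c("IC50", "Ki", "IC50", "IC50"),
    value_nM = c(7, 90, 3, 1),
    value_qualifier = "",
    confidence = 9L,
    source = "chembl"
  )
  cki <- build_cki_set(apply_filters(rec), lib)
  expect_s3_class(cki, "cki_set")
  expect_equal(nrow(cki), 2L)
  expect_equal(sort(cki$kinase_id), c("BTK", "EGFR"))
  expect_equal(dplyr::n_distinct(cki$canonical_smiles), 1L)
  expect_true(all(lengths(cki$warhead_ids) >= 1L))
  rep <- attr(cki, "cki_report")
  expect_equal(rep$n_no_warhead_compounds, 1L)
  expect_equal(rep$n_duplicate_pairs, 1L)
  # dedup is idempotent
  again <- build_cki_set(apply_filters(rec), lib)
  expect_equal(as.data.frame(again), as.data.frame(cki))
})

test_that("canonicalisation is invariant to atom ordering of the input", {
  variants <- c(
    "C=CC(=O)Nc1ccccc1",
    "O=C(/C=C)Nc1ccccc1",
    "c1ccccc1NC(=O)C=C",
    "c1ccc(NC(=O)C=C)cc1"
  )
  canon <- canonicalize_smiles(variants)
  expect_equal(dplyr::n_distinct(canon$canonical_smiles), 1L)
})

test_that("kinase coverage recovers a planted allocation exactly", {
  lib <- test_lib()
  design <- tibble::tibble(
    warhead_part = "acrylamide",
    fragment_part = c("piperidine", "piperidine", "benzenamine", "piperazine", "pyrrolidine"),
    scaffold_part = c("phenyl", "quinazolinyl", "phenyl", "phenyl", "phenyl"),
    kinase_id = c("EGFR", "EGFR", "EGFR", "BTK", "BTK"),
    n = 1L
  )
  batch <- generate_cki_batch(design = design, library = lib)
  tab <- generate_activity_table(batch, seed = 3L)
  cki <- build_cki_set(apply_filters(tab), lib)
  cov <- summarize_kinase_coverage(cki)
  expect_equal(cov$kinase_id, c("EGFR", "BTK"))
  expect_equal(cov$n_ckis, c(3L, 2L))
  expect_equal(nrow(summarize_kinase_coverage(cki[0, ])), 0L)
  expect_equal(summarize_kinase_coverage(cki, top = 1)$kinase_id, "EGFR")
})
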