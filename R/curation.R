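# Curation of raw kinase bioactivity tables into the CKI data set:
# activity threshold, assay confidence, accessible-cysteine kinase
# whitelist, desalting/canonicalisation, warhead requirement and
# kinase-compound deduplication.

#' Packaged accessible-cysteine kinase whitelist
#'
#' Returns the 208 human kinase gene symbols shipped with the package
#' as the default curation whitelist. The list is a synthetic
#' reconstruction: it contains real human kinase symbols chosen to
#' represent the kinases with a cysteine accessible from the ATP
#' pocket, and includes all kinases named in the package documentation
#' (EGFR, BTK, JAK3, FGFR2, FGFR4, ...). It is not a copy of any
#' database export.
#'
#' @return Character vector of 208 gene symbols.
#' @export
default_kinase_whitelist <- function() {
  path <- system.file("extdata", "kinase_whitelist_synthetic.txt", package = "ckifrags")
  readr::read_lines(path, skip_empty_rows = TRUE) |>
    (\(x) x[!startsWith(x, "#")])()
}

#' @noRd
kinase_alias_map <- function() {
  path <- system.file("extdata", "kinase_aliases.tsv", package = "ckifrags")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Normalise kinase identifiers to upper-case gene symbols
#'
#' Upper-cases identifiers, strips surrounding whitespace and applies
#' the packaged alias map (e.g. `ERK2 -> MAPK1`). Identifiers with no
#' alias entry pass through unchanged.
#'
#' @param kinase_id Character vector of kinase identifiers.
#' @return Character vector of normalised symbols.
#' @export
normalize_kinase_ids <- function(kinase_id) {
  x <- toupper(trimws(kinase_id))
  al <- kinase_alias_map()
  hit <- match(x, al$alias)
  x[!is.na(hit)] <- al$symbol[hit[!is.na(hit)]]
  x
}

#' Curation settings
#'
#' @param activity_threshold_nM Retain records strictly below this
#'   potency value (default 10000 nM).
#' @param required_confidence Required assay confidence score where
#'   enforced (default 9, the top ChEMBL-style score).
#' @param kinase_whitelist Gene symbols to retain
#'   (default [default_kinase_whitelist()]).
#' @param enforce_confidence `TRUE` to require the confidence score on
#'   every record that reports one (records with a missing score are
#'   exempt, matching sources that define no such concept), `FALSE` to
#'   ignore confidence, or a character vector of `source` tags for
#'   which the score is enforced.
#' @return A list of class `cki_curation_config`.
#' @export
curation_config <- function(activity_threshold_nM = 10000,
                            required_confidence = 9L,
                            kinase_whitelist = default_kinase_whitelist(),
                            enforce_confidence = TRUE) {
  stopifnot(activity_threshold_nM > 0, length(kinase_whitelist) > 0)
  structure(
    list(
      activity_threshold_nM = activity_threshold_nM,
      required_confidence = as.integer(required_confidence),
      kinase_whitelist = toupper(kinase_whitelist),
      enforce_confidence = enforce_confidence
    ),
    class = "cki_curation_config"
  )
}

default_dialect <- function() {
  list(
    smiles = "compound_smiles", kinase = "kinase_id", assay_type = "assay_type",
    value = "value_nM", confidence = "confidence", source = "source"
  )
}

#' Read a raw bioactivity table
#'
#' Parses a TSV/CSV export into activity records. Rows with an
#' unparseable SMILES or a non-numeric activity value are dropped and
#' counted; qualified values (`"<100"`, `">10000"`) keep their
#' qualifier in a separate column for the filtering step. The
#' per-cause drop counts are attached as the `"curation_log"`
#' attribute and always satisfy
#' `n_rows == n_records + n_bad_smiles + n_bad_value`.
#'
#' @param path File to read.
#' @param dialect Named list mapping the roles `smiles`, `kinase`,
#'   `assay_type`, `value`, `confidence`, `source` to column names in
#'   the file; roles missing from the list use the standard names
#'   (`compound_smiles`, `kinase_id`, `assay_type`, `value_nM`,
#'   `confidence`, `source`). `confidence` and `source` columns are
#'   optional in the file. May also be a path to a YAML/JSON file
#'   holding that mapping.
#' @param delim Field delimiter, guessed from the extension by default.
#' @return A tibble of activity records with columns `compound_smiles`,
#'   `kinase_id`, `assay_type`, `value_nM`, `value_qualifier`,
#'   `confidence`, `source`.
#' @export
read_activity_table <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("activity table not found: %s", path))
  }
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- if (grepl("[.]ya?ml$", dialect)) {
      yaml::read_yaml(dialect)
    } else {
      jsonlite::read_json(dialect, simplifyVector = TRUE)
    }
  }
  dialect <- utils::modifyList(default_dialect(), as.list(dialect %||% list()))
  if (is.null(delim)) {
    delim <- if (grepl("[.]csv$", path)) "," else "\t"
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (role in c("smiles", "kinase", "assay_type", "value")) {
    if (!dialect[[role]] %in% names(raw)) {
      abort(sprintf(
        "activity table lacks required column '%s' (role '%s')",
        dialect[[role]], role
      ))
    }
  }
  rec <- tibble(
    compound_smiles = raw[[dialect$smiles]],
    kinase_id = raw[[dialect$kinase]],
    assay_type = raw[[dialect$assay_type]],
    value_raw = raw[[dialect$value]],
    confidence = if (dialect$confidence %in% names(raw)) {
      suppressWarnings(as.integer(raw[[dialect$confidence]]))
    } else {
      NA_integer_
    },
    source = if (dialect$source %in% names(raw)) {
      raw[[dialect$source]]
    } else {
      NA_character_
    }
  )
  rec <- mutate(
    rec,
    value_qualifier = dplyr::case_when(
      grepl("^\\s*<", .data$value_raw) ~ "<",
      grepl("^\\s*>", .data$value_raw) ~ ">",
      TRUE ~ ""
    ),
    value_nM = suppressWarnings(as.numeric(sub("^\\s*[<>]\\s*", "", .data$value_raw)))
  )
  bad_value <- is.na(rec$value_nM) | rec$value_nM <= 0 |
    !rec$assay_type %in% c("Ki", "Kd", "IC50")
  ok_smiles <- rep(FALSE, nrow(rec))
  chk <- !bad_value
  if (any(chk)) {
    ok_smiles[chk] <- canonicalize_smiles(rec$compound_smiles[chk])$ok
  }
  keep_rows <- !bad_value & ok_smiles
  out <- select(
    rec[keep_rows, ],
    "compound_smiles", "kinase_id", "assay_type", "value_nM",
    "value_qualifier", "confidence", "source"
  )
  log <- list(
    n_rows = nrow(rec),
    n_records = nrow(out),
    n_bad_value = sum(bad_value),
    n_bad_smiles = sum(!bad_value & !ok_smiles)
  )
  attr(out, "curation_log") <- log
  out
}

record_keep_flags <- function(records, config) {
  thr <- config$activity_threshold_nM
  qual <- records[["value_qualifier"]] %||% rep("", nrow(records))
  # strict "<" for plain values; a qualified "<x" passes when x <= thr
  # (the true value is below x); ">x" is excluded outright
  value_ok <- dplyr::case_when(
    qual == ">" ~ FALSE,
    qual == "<" ~ records$value_nM <= thr,
    TRUE ~ records$value_nM < thr
  )
  enforce <- config$enforce_confidence
  enforced <- if (isTRUE(enforce)) {
    !is.na(records$confidence)
  } else if (isFALSE(enforce)) {
    rep(FALSE, nrow(records))
  } else {
    !is.na(records$confidence) & records$source %in% enforce
  }
  conf_ok <- !enforced |
    (!is.na(records$confidence) & records$confidence == config$required_confidence)
  kin_ok <- normalize_kinase_ids(records$kinase_id) %in% config$kinase_whitelist
  list(value_ok = value_ok, conf_ok = conf_ok, kin_ok = kin_ok)
}

#' Apply the curation filters to activity records
#'
#' Retains records with activity strictly below the threshold, the
#' required confidence score (where enforced) and a whitelisted kinase.
#' The filter is order-independent and idempotent; per-cause exclusion
#' counts are attached as the `"filter_report"` attribute (a record
#' failing several filters is counted once per cause, and
#' `n_in == n_retained + n_excluded`).
#'
#' @param records Activity records from [read_activity_table()].
#' @param config A [curation_config()].
#' @return The retained records, kinase identifiers normalised.
#' @export
apply_filters <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "cki_curation_config"))
  if (nrow(records) == 0) {
    out <- records
    attr(out, "filter_report") <- list(
      n_in = 0L, n_retained = 0L, n_excluded = 0L,
      n_over_threshold = 0L, n_low_confidence = 0L, n_off_whitelist = 0L
    )
    return(out)
  }
  flags <- record_keep_flags(records, config)
  keep_rows <- flags$value_ok & flags$conf_ok & flags$kin_ok
  out <- records[keep_rows, ]
  out$kinase_id <- normalize_kinase_ids(out$kinase_id)
  attr(out, "filter_report") <- list(
    n_in = nrow(records),
    n_retained = sum(keep_rows),
    n_excluded = sum(!keep_rows),
    n_over_threshold = sum(!flags$value_ok),
    n_low_confidence = sum(!flags$conf_ok),
    n_off_whitelist = sum(!flags$kin_ok)
  )
  out
}

#' Build the curated CKI set
#'
#' Desalts and canonicalises compounds, drops compounds carrying no
#' warhead, and collapses duplicate (compound, kinase) pairs to a
#' single record regardless of their assay values. The result is
#' sorted by canonical SMILES then kinase for deterministic output.
#'
#' @param records Filtered activity records ([apply_filters()]).
#' @param library A [warhead_library()].
#' @return A tibble of class `cki_set` with columns `canonical_smiles`,
#'   `kinase_id` and the list-column `warhead_ids` (non-empty for every
#'   row). A `"cki_report"` attribute counts pairs in/out, dropped
#'   no-warhead compounds and collapsed duplicates.
#' @export
build_cki_set <- function(records, library = warhead_library()) {
  if (nrow(records) == 0) {
    out <- tibble(
      canonical_smiles = character(), kinase_id = character(),
      warhead_ids = list()
    )
    class(out) <- c("cki_set", class(out))
    attr(out, "cki_report") <- list(
      n_pairs_in = 0L, n_pairs_out = 0L, n_no_warhead_compounds = 0L,
      n_duplicate_pairs = 0L
    )
    return(out)
  }
  canon <- canonicalize_smiles(records$compound_smiles)
  pairs <- distinct(tibble(
    canonical_smiles = canon$canonical_smiles,
    kinase_id = normalize_kinase_ids(records$kinase_id)
  ))
  n_dup <- nrow(records) - nrow(pairs)
  compounds <- unique(pairs$canonical_smiles)
  cls <- classify_compounds(compounds, library)
  with_wh <- filter(cls, .data$class != "no_warhead")
  out <- inner_join(
    pairs,
    select(with_wh, canonical_smiles = "smiles", "warhead_ids"),
    by = "canonical_smiles"
  )
  out <- arrange(out, .data$canonical_smiles, .data$kinase_id)
  class(out) <- c("cki_set", class(out))
  attr(out, "cki_report") <- list(
    n_pairs_in = nrow(records),
    n_pairs_out = nrow(out),
    n_no_warhead_compounds = length(compounds) - nrow(with_wh),
    n_duplicate_pairs = n_dup
  )
  out
}

#' Count curated CKIs per kinase
#'
#' @param cki_set A curated set from [build_cki_set()].
#' @param top Optionally keep only the `top` best-covered kinases.
#' @param min_ckis Optionally keep only kinases with at least this many
#'   unique CKIs.
#' @return Tibble `kinase_id`, `n_ckis`, ordered by descending count.
#' @export
summarize_kinase_coverage <- function(cki_set, top = NULL, min_ckis = NULL) {
  out <- summarise(
    group_by(as_tibble(cki_set), .data$kinase_id),
    n_ckis = dplyr::n_distinct(.data$canonical_smiles),
    .groups = "drop"
  )
  out <- arrange(out, desc(.data$n_ckis), .data$kinase_id)
  if (!is.null(min_ckis)) {
    out <- filter(out, .data$n_ckis >= min_ckis)
  }
  if (!is.null(top)) {
    out <- slice_head(out, n = top)
  }
  out
}
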