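# End-to-end orchestration: curate -> match -> extract -> profile ->
# cluster, writing checksummed artifacts so identical configs give
# byte-identical runs.

#' Pipeline configuration
#'
#' @param input Path to a raw activity table (TSV/CSV), or a data frame
#'   of activity records.
#' @param outdir Output directory for run artifacts.
#' @param warhead_file Warhead definition file
#'   (default [default_warhead_file()]).
#' @param whitelist Kinase whitelist (character vector or file with one
#'   symbol per line; default the packaged 208-kinase list).
#' @param dialect Column mapping for [read_activity_table()].
#' @param activity_threshold_nM,required_confidence,enforce_confidence
#'   Curation parameters, see [curation_config()].
#' @param fallback Extraction fallback mode ([extract_fragments()]).
#' @param k Cluster count (default 7).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `cki_pipeline_config`.
#' @export
pipeline_config <- function(input, outdir,
                            warhead_file = default_warhead_file(),
                            whitelist = NULL,
                            dialect = NULL,
                            activity_threshold_nM = 10000,
                            required_confidence = 9L,
                            enforce_confidence = TRUE,
                            fallback = FALSE,
                            k = 7L,
                            seed = 1L) {
  if (is.character(input) && !file.exists(input)) {
    abort(sprintf("input not found: %s", input))
  }
  if (!file.exists(warhead_file)) {
    abort(sprintf("warhead file not found: %s", warhead_file))
  }
  if (is.character(whitelist) && length(whitelist) == 1 && file.exists(whitelist)) {
    whitelist <- readr::read_lines(whitelist, skip_empty_rows = TRUE)
    whitelist <- whitelist[!startsWith(whitelist, "#")]
  }
  stopifnot(k >= 1)
  structure(
    list(
      input = input, outdir = outdir, warhead_file = warhead_file,
      whitelist = whitelist, dialect = dialect,
      activity_threshold_nM = activity_threshold_nM,
      required_confidence = required_confidence,
      enforce_confidence = enforce_confidence,
      fallback = fallback, k = as.integer(k), seed = as.integer(seed)
    ),
    class = "cki_pipeline_config"
  )
}

write_tsv_artifact <- function(x, path) {
  flat <- mutate(as_tibble(x), across(
    dplyr::where(is.list),
    ~ map_chr(.x, function(v) paste(v, collapse = ";"))
  ))
  readr::write_tsv(flat, path)
}

#' Run the full pipeline
#'
#' Stages: curate the input table, build the CKI set, extract adjacent
#' fragments, aggregate and profile the fragment library, cluster it,
#' and write all artifacts plus a manifest with an md5 checksum per
#' file. Identical config and inputs give byte-identical artifacts.
#' On a stage failure the artifacts written so far are retained next
#' to a `FAILED` marker naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory. Artifacts:
#'   `curated_set.tsv`, `fragment_library.tsv`, `crosstab.tsv`,
#'   `density_summaries.json`, `clusters.tsv`, `extraction_report.json`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cki_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
  }
  result <- tryCatch(
    {
      stage <- "curate"
      library <- warhead_library(config$warhead_file)
      records <- if (is.data.frame(config$input)) {
        config$input
      } else {
        read_activity_table(config$input, dialect = config$dialect)
      }
      cfg <- curation_config(
        activity_threshold_nM = config$activity_threshold_nM,
        required_confidence = config$required_confidence,
        kinase_whitelist = config$whitelist %||% default_kinase_whitelist(),
        enforce_confidence = config$enforce_confidence
      )
      filtered <- apply_filters(records, cfg)
      cki <- build_cki_set(filtered, library)
      emit("curated_set.tsv", function(p) write_tsv_artifact(cki, p))

      stage <- "extract"
      hits <- extract_fragments(cki, library, fallback = config$fallback)
      emit("extraction_report.json", function(p) {
        jsonlite::write_json(
          c(
            extraction_report(hits),
            list(filter_report = attr(filtered, "filter_report"))
          ),
          p,
          auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
      })

      stage <- "profile"
      flib <- build_fragment_library(hits, cki)
      emit("fragment_library.tsv", function(p) write_tsv_artifact(flib, p))
      emit("crosstab.tsv", function(p) {
        readr::write_tsv(crosstab_fragment_warhead(hits), p)
      })
      emit("density_summaries.json", function(p) {
        prof <- if (nrow(flib) > 0) profile_descriptors(flib) else tibble()
        jsonlite::write_json(prof, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      })

      stage <- "cluster"
      if (nrow(flib) > 0) {
        if (config$k > nrow(flib)) {
          abort(sprintf(
            "k = %d exceeds the %d unique fragments", config$k, nrow(flib)
          ))
        }
        cl <- cluster_fragments(flib, k = config$k)
        emit("clusters.tsv", function(p) readr::write_tsv(cl$labels, p))
      } else {
        emit("clusters.tsv", function(p) {
          readr::write_tsv(tibble(item = character(), cluster = integer()), p)
        })
      }

      stage <- "manifest"
      manifest <- list(
        config = config[setdiff(names(config), c("input", "outdir"))],
        seed = config$seed,
        artifacts = lapply(
          setNames(artifacts, basename(artifacts)),
          function(p) unname(tools::md5sum(p))
        )
      )
      jsonlite::write_json(
        manifest, file.path(config$outdir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
      )
      config$outdir
    },
    error = function(e) {
      writeLines(
        sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
        file.path(config$outdir, "FAILED")
      )
      abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
        parent = e
      )
    }
  )
  invisible(result)
}

#' Summarise a completed pipeline run
#'
#' Reads the artifacts of a run directory and prints headline counts:
#' records in/out per filter, unique CKIs and kinases, fragments, top
#' fragments with their warhead and kinase coverage, and the
#' reversible/irreversible split.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param top Number of top fragments to show (default 6).
#' @return Invisibly, a list with the summary tables.
#' @export
report_summary <- function(run_dir, top = 6L) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest found in %s (incomplete run?)", run_dir))
  }
  rep <- jsonlite::read_json(file.path(run_dir, "extraction_report.json"))
  cki <- readr::read_tsv(file.path(run_dir, "curated_set.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  flib <- readr::read_tsv(file.path(run_dir, "fragment_library.tsv"),
    col_types = readr::cols(.default = readr::col_guess())
  )
  fr <- rep$filter_report
  cat("== pipeline run summary ==\n")
  cat(sprintf(
    "records: %d in, %d retained (%d over threshold, %d low confidence, %d off whitelist)\n",
    fr$n_in %||% 0, fr$n_retained %||% 0, fr$n_over_threshold %||% 0,
    fr$n_low_confidence %||% 0, fr$n_off_whitelist %||% 0
  ))
  n_cki <- dplyr::n_distinct(cki$canonical_smiles)
  n_kin <- dplyr::n_distinct(cki$kinase_id)
  cat(sprintf(
    "curated set: %d kinase-CKI pairs, %d unique CKIs, %d kinases\n",
    nrow(cki), if (nrow(cki)) n_cki else 0L, if (nrow(cki)) n_kin else 0L
  ))
  cat(sprintf(
    "extraction: %d molecules, %d with hits, %d unresolved, %d without warhead; %d hits, %d unique fragments\n",
    rep$n_molecules, rep$n_with_hits, rep$n_unresolved, rep$n_no_warhead,
    rep$n_hits, rep$n_unique_fragments
  ))
  top_tbl <- head(flib, top)
  if (nrow(top_tbl) > 0) {
    cat(sprintf("top %d fragments:\n", nrow(top_tbl)))
    for (i in seq_len(nrow(top_tbl))) {
      cat(sprintf(
        "  %s  count=%d warheads={%s} kinases=%d\n",
        top_tbl$fragment_smiles_clean[i], top_tbl$count[i],
        top_tbl$warhead_ids[i], top_tbl$n_kinases[i] %||% NA
      ))
    }
  }
  if (nrow(cki) > 0) {
    lib <- warhead_library()
    sets <- map(strsplit(cki$warhead_ids, ";"), as.integer)
    rev_of <- setNames(lib$reversibility, as.character(lib$id))
    cls <- map_chr(sets, function(ids) {
      u <- unique(rev_of[as.character(ids)])
      if (length(u) > 1) "mixed" else u
    })
    split_tbl <- table(cls)
    cat(
      "reversibility split (records): ",
      paste(sprintf("%s=%d", names(split_tbl), as.integer(split_tbl)), collapse = ", "),
      "\n"
    )
  } else {
    split_tbl <- table(character(0))
  }
  invisible(list(
    filter_report = fr, extraction = rep, cki = cki,
    top_fragments = top_tbl, reversibility = split_tbl
  ))
}
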