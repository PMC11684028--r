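# Physicochemical profiling and frequency cross-tabulations of the
# adjacent-fragment library, including reversibility-class subsets.

#' Physicochemical descriptors of fragments
#'
#' Molecular weight (g/mol), Crippen atomic-contribution logP, and
#' Lipinski-style hydrogen-bond acceptor (N/O) and donor (NH/OH)
#' counts. Identical canonical SMILES always give identical profiles.
#'
#' @param smiles Character vector of SMILES, or a data frame with a
#'   `smiles` column.
#' @return Tibble `smiles`, `MW`, `logP`, `HBA`, `HBD`.
#' @export
#' @examples
#' \dontrun{
#' compute_descriptors(c("C1CCNCC1", "Nc1ccccc1"))
#' }
compute_descriptors <- function(smiles) {
  if (is.data.frame(smiles)) {
    smiles <- smiles[["fragment_smiles_clean"]] %||% smiles[["smiles"]]
  }
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(tibble(
      smiles = character(), MW = numeric(), logP = numeric(),
      HBA = integer(), HBD = integer()
    ))
  }
  res <- chem_backend("descriptors", list(smiles = as.list(smiles)))$results
  bad <- smiles[!map_lgl(res, ~ isTRUE(.x$ok))]
  if (length(bad) > 0) {
    abort(sprintf("unparseable SMILES: %s", paste(unique(bad), collapse = ", ")))
  }
  tibble(
    smiles = smiles,
    MW = map_dbl(res, "MW"),
    logP = map_dbl(res, "logP"),
    HBA = map_int(res, ~ as.integer(.x$HBA)),
    HBD = map_int(res, ~ as.integer(.x$HBD))
  )
}

# normal-reference (Scott 1992) bandwidth: 1.06 * min(sd, IQR/1.34) *
# n^(-1/5), guarded against a zero IQR (common for integer-valued
# descriptors) by taking the smallest positive spread estimate
kde_bandwidth <- function(x) {
  n <- length(x)
  if (n < 2) {
    return(0)
  }
  spread <- c(stats::sd(x), diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)) / 1.34)
  spread <- spread[is.finite(spread) & spread > 0]
  if (length(spread) == 0) {
    return(0)
  }
  1.06 * min(spread) * n^(-1 / 5)
}

#' Summarise a property distribution by range, mode and mean
#'
#' The mode is the abscissa of the maximum of a Gaussian kernel density
#' estimate with the normal-reference (Scott 1992) bandwidth
#' `1.06 min(sd, IQR/1.34) n^(-1/5)` — guarded against a zero IQR by
#' falling back to the smallest positive spread estimate — evaluated
#' on a 512-point uniform grid spanning `[min - 3h, max + 3h]`; on a
#' tied argmax the lowest abscissa wins, and the mode is clamped into
#' `[min, max]`. Degenerate samples (n = 1, or zero spread, where no
#' bandwidth is defined) report the observed value as min = mode = max.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return One-row tibble of class `cki_density`: `min`, `max`, `mode`,
#'   `mean`, `n`, `bw` (the bandwidth used), with the density curve in
#'   the `"density"` attribute for plotting.
#' @export
density_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("density_summary() needs at least one finite value")
  }
  lo <- min(values)
  hi <- max(values)
  h <- kde_bandwidth(values)
  if (!is.finite(h) || h <= 0) {
    out <- tibble(
      min = lo, max = hi, mode = lo, mean = mean(values),
      n = length(values), bw = 0
    )
    class(out) <- c("cki_density", class(out))
    return(out)
  }
  d <- density(values,
    bw = h, kernel = "gaussian", n = 512,
    from = lo - 3 * h, to = hi + 3 * h
  )
  mode <- d$x[which.max(d$y)] # which.max takes the first (lowest) abscissa
  mode <- min(max(mode, lo), hi)
  out <- tibble(
    min = lo, max = hi, mode = mode, mean = mean(values),
    n = length(values), bw = h
  )
  attr(out, "density") <- tibble(x = d$x, y = d$y)
  class(out) <- c("cki_density", class(out))
  out
}

#' Profile the distributions of all fragment descriptors
#'
#' Applies [density_summary()] to each of MW, logP, HBA and HBD over a
#' fragment library (or any table carrying those columns).
#'
#' @param library A [build_fragment_library()] result.
#' @param weighted Weight each fragment by its occurrence `count`
#'   (default `FALSE`: unique fragments).
#' @return Tibble with one row per descriptor: `variable`, `min`,
#'   `max`, `mode`, `mean`, `n`.
#' @export
profile_descriptors <- function(library, weighted = FALSE) {
  vars <- c("MW", "logP", "HBA", "HBD")
  stopifnot(all(vars %in% names(library)))
  bind_rows(map(vars, function(v) {
    x <- library[[v]]
    if (weighted && "count" %in% names(library)) {
      x <- rep(x, library$count)
    }
    mutate(as_tibble(density_summary(x)), variable = v, .before = 1)
  }))
}

#' Cross-tabulate fragments against warheads
#'
#' Counts fragment occurrences per (fragment, warhead) pair from the
#' hit table. Marginal sums equal the total hit count exactly.
#'
#' @param hits Fragment hits from [extract_fragments()] (hit-level
#'   counts are needed; an aggregated library entry no longer knows how
#'   its occurrences split across warheads).
#' @return Long tibble `fragment_smiles_clean`, `warhead_id`, `count`.
#' @export
crosstab_fragment_warhead <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(
      fragment_smiles_clean = character(), warhead_id = integer(),
      count = integer()
    ))
  }
  out <- count(hits, .data$fragment_smiles_clean, .data$warhead_id, name = "count")
  arrange(out, .data$fragment_smiles_clean, .data$warhead_id)
}

#' Number of distinct fragments per warhead
#'
#' @param hits Fragment hits.
#' @return Tibble `warhead_id`, `n_fragments`.
#' @export
fragments_per_warhead <- function(hits) {
  ct <- crosstab_fragment_warhead(hits)
  arrange(
    summarise(group_by(ct, .data$warhead_id),
      n_fragments = dplyr::n_distinct(.data$fragment_smiles_clean),
      .groups = "drop"
    ),
    desc(.data$n_fragments), .data$warhead_id
  )
}

#' Number of distinct warheads per fragment
#'
#' @param hits Fragment hits.
#' @return Tibble `fragment_smiles_clean`, `n_warheads`.
#' @export
warheads_per_fragment <- function(hits) {
  ct <- crosstab_fragment_warhead(hits)
  arrange(
    summarise(group_by(ct, .data$fragment_smiles_clean),
      n_warheads = dplyr::n_distinct(.data$warhead_id),
      .groups = "drop"
    ),
    desc(.data$n_warheads), .data$fragment_smiles_clean
  )
}

#' Kinase coverage per warhead or per fragment
#'
#' Counts the distinct kinases reached, as the cardinality of the
#' union of kinase sets. For `by = "warhead"` pass a curated `cki_set`
#' (its `warhead_ids` are unnested, and warheads may also be
#' aggregated by family); for `by = "fragment"` pass a fragment
#' library built with a `cki_set`.
#'
#' @param x A `cki_set` or `cki_fragment_library`.
#' @param by `"warhead"` or `"fragment"`.
#' @param aggregate_family With `by = "warhead"`, collapse warheads to
#'   their family label (so e.g. the cyanoacrylamide variants report
#'   one coverage). Needs `library`.
#' @param library A [warhead_library()] (only used for family
#'   aggregation).
#' @return Tibble with the grouping column and `n_kinases`.
#' @export
kinase_coverage <- function(x, by = c("warhead", "fragment"),
                            aggregate_family = FALSE,
                            library = NULL) {
  by <- match.arg(by)
  if (by == "fragment") {
    stopifnot("kinases" %in% names(x))
    out <- tibble(
      fragment_smiles_clean = x$fragment_smiles_clean,
      n_kinases = map_int(x$kinases, ~ length(unique(.x)))
    )
    return(arrange(out, desc(.data$n_kinases), .data$fragment_smiles_clean))
  }
  stopifnot(all(c("warhead_ids", "kinase_id") %in% names(x)))
  long <- tidyr::unnest(
    select(as_tibble(x), "kinase_id", "warhead_ids"),
    "warhead_ids"
  )
  long <- rename(long, warhead_id = "warhead_ids")
  if (aggregate_family) {
    if (is.null(library)) {
      library <- warhead_library()
    }
    long <- left_join(long, select(library, warhead_id = "id", "family"),
      by = "warhead_id"
    )
    out <- summarise(group_by(long, .data$family),
      n_kinases = dplyr::n_distinct(.data$kinase_id),
      .groups = "drop"
    )
    return(arrange(out, desc(.data$n_kinases), .data$family))
  }
  out <- summarise(group_by(long, .data$warhead_id),
    n_kinases = dplyr::n_distinct(.data$kinase_id),
    .groups = "drop"
  )
  arrange(out, desc(.data$n_kinases), .data$warhead_id)
}

#' Subset hits or a CKI set by warhead reversibility class
#'
#' For hit tables each row carries one warhead, so `"irreversible"` and
#' `"reversible"` select rows by that warhead's class. For curated CKI
#' records (which carry a warhead id set) the classes partition the
#' records: `"mixed"` selects records carrying both classes, and the
#' pure classes exclude them, so no record is counted twice.
#'
#' @param x Fragment hits or a `cki_set`.
#' @param class `"irreversible"`, `"reversible"` or `"mixed"` (the
#'   latter only for record-level input).
#' @param library A [warhead_library()].
#' @return Same shape as `x`, subset to the requested class.
#' @export
subset_by_reversibility <- function(x, class, library = warhead_library()) {
  classes <- c("irreversible", "reversible", "mixed")
  if (!is.character(class) || length(class) != 1 || !class %in% classes) {
    abort(sprintf("unknown reversibility class: %s", paste(class, collapse = ", ")))
  }
  rev_of <- setNames(library$reversibility, as.character(library$id))
  if ("warhead_id" %in% names(x)) {
    if (class == "mixed") {
      abort("class 'mixed' applies to record-level input (one warhead per hit)")
    }
    return(filter(x, rev_of[as.character(.data$warhead_id)] == class))
  }
  stopifnot("warhead_ids" %in% names(x))
  rec_class <- map_chr(x$warhead_ids, function(ids) {
    cls <- unique(rev_of[as.character(ids)])
    if (length(cls) > 1) "mixed" else cls
  })
  x[rec_class == class, ]
}
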