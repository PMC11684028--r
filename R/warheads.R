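# The warhead library: 30 electrophile substructure definitions with
# reversibility classes and an explicit match-priority total order.

#' Path to the packaged warhead definition file
#'
#' A tab-separated table of the 30 electrophilic warheads used to flag
#' covalent kinase inhibitors: 22 irreversible (ids 1-22) and 8
#' reversible (ids 23-30). Each row carries a SMARTS pattern, a
#' reversibility class, a family label used for aggregate reporting
#' (e.g. the three cyanoacrylamide variants 23-25 share one family), an
#' integer match priority (lower is matched first, so more-substituted
#' electrophiles outrank plain acrylamide on shared atoms) and an
#' exemplar SMILES that the pattern must recognise.
#'
#' @return File path of the default warhead TSV.
#' @export
default_warhead_file <- function() {
  system.file("extdata", "warheads.tsv", package = "ckifrags")
}

#' Load a warhead definition library
#'
#' Reads and validates warhead definitions. Validation enforces: unique
#' ids covering `1:n`, a reversibility class in
#' `c("irreversible", "reversible")` for every entry, tie-free integer
#' priorities, SMARTS that parse, and (for the packaged default) the
#' 22/8 irreversible/reversible split across ids 1-22 and 23-30.
#'
#' @param path Warhead definition file (TSV with columns `id`, `name`,
#'   `smarts`, `reversibility`, `family`, `priority`, `exemplar_smiles`).
#'   Defaults to the packaged 30-warhead library.
#' @return A tibble of class `cki_warhead_library`, ordered by priority.
#' @export
#' @examples
#' \dontrun{
#' lib <- warhead_library()
#' dplyr::count(lib, reversibility)
#' }
warhead_library <- function(path = default_warhead_file()) {
  if (!file.exists(path)) {
    abort(sprintf("warhead file not found: %s", path))
  }
  lib <- readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(),
      name = readr::col_character(),
      smarts = readr::col_character(),
      reversibility = readr::col_character(),
      family = readr::col_character(),
      priority = readr::col_integer(),
      exemplar_smiles = readr::col_character()
    )
  )
  required <- c("id", "name", "smarts", "reversibility", "family", "priority", "exemplar_smiles")
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0) {
    abort(sprintf("warhead file lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dup <- lib$id[duplicated(lib$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate warhead id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (!setequal(lib$id, seq_len(nrow(lib)))) {
    abort("warhead ids must exactly cover 1..n")
  }
  if (!all(lib$reversibility %in% c("irreversible", "reversible"))) {
    abort("reversibility must be 'irreversible' or 'reversible'")
  }
  if (anyDuplicated(lib$priority) > 0) {
    abort("warhead priorities must be a total order (no ties)")
  }
  parsed <- chem_backend("parse_smarts", list(
    patterns = unname(pmap(lib[c("id", "smarts")], function(id, smarts) {
      list(id = id, smarts = smarts)
    }))
  ))$results
  bad <- map_int(keep(parsed, ~ !isTRUE(.x$ok)), ~ as.integer(.x$id))
  if (length(bad) > 0) {
    abort(sprintf("malformed SMARTS for warhead id(s): %s", paste(bad, collapse = ", ")))
  }
  lib <- arrange(lib, .data$priority)
  class(lib) <- c("cki_warhead_library", class(lib))
  lib
}

resolve_matches <- function(raw, library) {
  # priority resolution: sort raw matches by (priority, atom indices) and
  # greedily keep those whose atom set does not overlap an accepted one
  if (length(raw) == 0) {
    return(list())
  }
  prio <- setNames(library$priority, as.character(library$id))
  ord <- order(
    prio[as.character(map_int(raw, ~ as.integer(.x$id)))],
    map_chr(raw, ~ paste(sprintf("%06d", unlist(.x$atoms)), collapse = ","))
  )
  accepted <- list()
  used <- integer(0)
  for (m in raw[ord]) {
    atoms <- as.integer(unlist(m$atoms))
    if (length(intersect(atoms, used)) > 0) {
      next
    }
    accepted[[length(accepted) + 1L]] <- m
    used <- c(used, atoms)
  }
  accepted
}

#' Match warhead patterns against molecules
#'
#' Runs every warhead SMARTS against each molecule and resolves
#' overlaps: when two patterns claim overlapping atoms only the
#' higher-priority (more specific) warhead is reported, so e.g. a
#' cyanoacrylamide is never double-counted as a plain acrylamide.
#' Matches of distinct, non-overlapping atom sets are all reported.
#' Inputs are desalted and canonicalised first; atom indices refer to
#' the canonical form.
#'
#' @param smiles Character vector of SMILES, or a data frame with a
#'   `smiles` column.
#' @param library A [warhead_library()].
#' @param canonicalize Desalt/canonicalise inputs first (default `TRUE`).
#' @return A tibble with one row per accepted match: `smiles`,
#'   `canonical_smiles`, `warhead_id`, `name`, `family`, `reversibility`,
#'   and list-columns `atom_indices`, `attachment_atoms` (0-based atom
#'   indices of the canonical molecule). Unparseable inputs raise an
#'   error naming the offending SMILES.
#' @export
match_warheads <- function(smiles, library = warhead_library(), canonicalize = TRUE) {
  if (is.data.frame(smiles)) {
    smiles <- smiles$smiles
  }
  stopifnot(is.character(smiles))
  empty <- tibble(
    smiles = character(), canonical_smiles = character(),
    warhead_id = integer(), name = character(), family = character(),
    reversibility = character(), atom_indices = list(), attachment_atoms = list()
  )
  if (length(smiles) == 0) {
    return(empty)
  }
  if (canonicalize) {
    canon <- canonicalize_smiles(smiles)
    if (any(!canon$ok)) {
      abort(sprintf(
        "unparseable SMILES: %s",
        paste(unique(smiles[!canon$ok]), collapse = ", ")
      ))
    }
    target <- canon$canonical_smiles
  } else {
    target <- smiles
  }
  res <- backend_match(unique(target), library)
  names(res) <- unique(target)
  info <- select(library, "id", "name", "family", "reversibility")
  rows <- imap(res, function(r, canon_smi) {
    if (!isTRUE(r$ok)) {
      abort(sprintf("unparseable SMILES: %s", canon_smi))
    }
    acc <- resolve_matches(r$matches, library)
    if (length(acc) == 0) {
      return(NULL)
    }
    tibble(
      canonical_smiles = canon_smi,
      warhead_id = map_int(acc, ~ as.integer(.x$id)),
      atom_indices = map(acc, ~ as.integer(unlist(.x$atoms))),
      attachment_atoms = map(acc, ~ as.integer(unlist(.x$attachments)))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(empty)
  }
  out <- left_join(tibble(smiles = smiles, canonical_smiles = target), out,
    by = "canonical_smiles"
  )
  out <- filter(out, !is.na(.data$warhead_id))
  out <- left_join(out, info, by = c(warhead_id = "id"))
  out <- arrange(
    out,
    match(.data$smiles, smiles),
    match(.data$warhead_id, library$id),
    map_chr(.data$atom_indices, ~ paste(sprintf("%06d", .x), collapse = ","))
  )
  select(
    out, "smiles", "canonical_smiles", "warhead_id", "name", "family",
    "reversibility", "atom_indices", "attachment_atoms"
  )
}

#' Classify compounds by warhead reversibility
#'
#' A compound is `irreversible` or `reversible` when all its
#' priority-resolved warhead matches fall in that class, `mixed` when it
#' carries both, and `no_warhead` when no pattern matches.
#'
#' @inheritParams match_warheads
#' @return A tibble with `smiles`, `canonical_smiles`, `class` and the
#'   list-column `warhead_ids`.
#' @export
classify_compounds <- function(smiles, library = warhead_library()) {
  if (is.data.frame(smiles)) {
    smiles <- smiles$smiles
  }
  matches <- match_warheads(smiles, library)
  per <- summarise(
    group_by(matches, .data$smiles, .data$canonical_smiles),
    warhead_ids = list(sort(unique(.data$warhead_id))),
    n_irrev = sum(.data$reversibility == "irreversible"),
    n_rev = sum(.data$reversibility == "reversible"),
    .groups = "drop"
  )
  canon <- canonicalize_smiles(smiles)
  out <- left_join(
    tibble(smiles = smiles, canonical_smiles = canon$canonical_smiles),
    per,
    by = c("smiles", "canonical_smiles")
  )
  mutate(
    out,
    warhead_ids = map(.data$warhead_ids, ~ if (is.null(.x)) integer(0) else .x),
    class = dplyr::case_when(
      is.na(.data$n_irrev) ~ "no_warhead",
      .data$n_irrev > 0 & .data$n_rev > 0 ~ "mixed",
      .data$n_rev > 0 ~ "reversible",
      TRUE ~ "irreversible"
    ),
    n_irrev = NULL, n_rev = NULL
  )
}
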