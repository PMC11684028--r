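# Adjacent-fragment extraction: locate warhead leaves in RECAP
# hierarchies and harvest the sibling leaves that bridge warhead and
# scaffold.

# A leaf "is" a warhead when one of its embeddings into the root
# molecule covers all atoms of a priority-resolved warhead match and the
# leaf carries at most two heavy atoms beyond that match (RECAP leaves
# keep attachment context, so exact equality would be too brittle,
# while unlimited excess would misclassify scaffolds with embedded
# amides).
leaf_warhead_ids <- function(placements, matches, slack = 2L) {
  if (length(placements) == 0 || nrow(matches) == 0) {
    return(integer(0))
  }
  hits <- map(seq_len(nrow(matches)), function(i) {
    atoms <- matches$atom_indices[[i]]
    ok <- any(map_lgl(placements, function(p) {
      all(atoms %in% p$covered) && length(p$real) <= length(atoms) + slack
    }))
    if (ok) matches$warhead_id[[i]] else NULL
  })
  sort(unique(unlist(hits)))
}

molecule_hits <- function(nodes, matches) {
  # warhead ids per leaf node
  leaf_ids <- map(seq_len(nrow(nodes)), function(i) {
    if (!nodes$is_leaf[i] || nodes$depth[i] == 0) {
      return(integer(0))
    }
    leaf_warhead_ids(nodes$placements[[i]], matches)
  })
  is_wh_leaf <- lengths(leaf_ids) > 0
  out <- list()
  for (parent in nodes$node_id[!nodes$is_leaf]) {
    kids <- which(!is.na(nodes$parent_id) & nodes$parent_id == parent & nodes$is_leaf)
    wh_kids <- kids[is_wh_leaf[kids]]
    if (length(wh_kids) == 0) {
      next
    }
    # siblings at the same branch: other children leaves that are not
    # themselves warhead leaves and that bridge (>= 2 attachment points)
    sib <- kids[!is_wh_leaf[kids]]
    sib <- sib[nodes$n_dummies[sib] >= 2]
    if (length(sib) == 0) {
      next
    }
    wids <- sort(unique(unlist(leaf_ids[wh_kids])))
    for (w in wids) {
      out[[length(out) + 1L]] <- tibble(
        warhead_id = w,
        fragment_smiles_marked = nodes$smiles_marked[sib],
        fragment_smiles_clean = nodes$smiles_clean[sib],
        n_attachments = nodes$n_dummies[sib],
        node_depth = nodes$depth[sib]
      )
    }
  }
  hits <- bind_rows(out)
  if (nrow(hits) == 0) {
    return(hits)
  }
  # per-molecule dedup of identical (warhead, fragment) pairs
  hits <- arrange(hits, .data$warhead_id, .data$fragment_smiles_clean, .data$node_depth)
  distinct(hits, .data$warhead_id, .data$fragment_smiles_clean, .keep_all = TRUE)
}

empty_hits <- function() {
  tibble(
    parent_smiles = character(), warhead_id = integer(),
    fragment_smiles_marked = character(), fragment_smiles_clean = character(),
    n_attachments = integer(), node_depth = integer(), method = character()
  )
}

drop_warhead_fragments <- function(hits, library) {
  # a bridging fragment must not itself contain a warhead after
  # priority resolution (hydrogen-capped form)
  if (nrow(hits) == 0) {
    return(hits)
  }
  frags <- unique(hits$fragment_smiles_clean)
  m <- match_warheads(frags, library, canonicalize = FALSE)
  filter(hits, !.data$fragment_smiles_clean %in% unique(m$canonical_smiles))
}

#' Find adjacent fragments in RECAP trees
#'
#' Traverses each molecule's RECAP hierarchy looking for branches whose
#' children include a warhead leaf; the other leaves at the same branch
#' are adjacent-fragment candidates. Candidates with a single
#' attachment point sit at the distal end of the molecule and are
#' excluded; candidates with two or more bridge the warhead and the
#' scaffold and are returned. Candidates that still contain a warhead
#' themselves are dropped. Identical (warhead, fragment) pairs are
#' reported once per molecule.
#'
#' @param tree A [recap_decompose()] result (one or more molecules).
#' @param library A [warhead_library()].
#' @param matches Optional precomputed [match_warheads()] result for the
#'   tree's molecules (computed internally when `NULL`). Must have been
#'   matched against the same SMILES strings the tree was built from.
#' @return A tibble of fragment hits: `parent_smiles`, `warhead_id`,
#'   `fragment_smiles_marked`, `fragment_smiles_clean`,
#'   `n_attachments`, `node_depth`, `method`. The `"molecule_status"`
#'   attribute maps each molecule to `"ok"`, `"unresolved"` (warhead
#'   present but no warhead leaf/bridging sibling) or `"no_warhead"`.
#' @export
find_adjacent_fragments <- function(tree, library = warhead_library(), matches = NULL) {
  mols <- unique(tree$smiles)
  if (is.null(matches)) {
    matches <- match_warheads(mols, library, canonicalize = FALSE)
  }
  rows <- list()
  status <- character(length(mols))
  names(status) <- mols
  for (smi in mols) {
    m <- filter(matches, .data$smiles == smi)
    if (nrow(m) == 0) {
      status[smi] <- "no_warhead"
      next
    }
    nodes <- filter(tree, .data$smiles == smi)
    hits <- molecule_hits(nodes, m)
    if (nrow(hits) == 0) {
      status[smi] <- "unresolved"
      next
    }
    status[smi] <- "ok"
    rows[[smi]] <- mutate(hits, parent_smiles = smi, method = "recap")
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- empty_hits()
  }
  out <- drop_warhead_fragments(out, library)
  # dropping may empty a molecule's hits: re-flag it unresolved
  emptied <- setdiff(names(status)[status == "ok"], unique(out$parent_smiles))
  status[emptied] <- "unresolved"
  out <- select(
    out, "parent_smiles", "warhead_id", "fragment_smiles_marked",
    "fragment_smiles_clean", "n_attachments", "node_depth", "method"
  )
  attr(out, "molecule_status") <- tibble(smiles = mols, status = unname(status[mols]))
  out
}

fallback_hits <- function(smiles, matches, library) {
  if (length(smiles) == 0) {
    return(empty_hits())
  }
  payload <- map(smiles, function(smi) {
    m <- filter(matches, .data$smiles == smi)
    list(
      smiles = smi,
      matches = map(seq_len(nrow(m)), function(i) {
        list(
          id = m$warhead_id[[i]],
          atoms = as.list(m$atom_indices[[i]]),
          attachments = as.list(m$attachment_atoms[[i]])
        )
      })
    )
  })
  res <- chem_backend("fallback", list(molecules = payload))$results
  rows <- map2(res, smiles, function(r, smi) {
    if (!isTRUE(r$ok) || length(r$candidates) == 0) {
      return(NULL)
    }
    tibble(
      parent_smiles = smi,
      warhead_id = map_int(r$candidates, ~ as.integer(.x$warhead_id)),
      fragment_smiles_marked = map_chr(r$candidates, ~ .x$marked),
      fragment_smiles_clean = map_chr(r$candidates, ~ .x$clean),
      n_attachments = map_int(r$candidates, ~ as.integer(.x$n_attach)),
      node_depth = NA_integer_,
      method = "fallback"
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(empty_hits())
  }
  out <- arrange(out, .data$parent_smiles, .data$warhead_id, .data$fragment_smiles_clean)
  distinct(out, .data$parent_smiles, .data$warhead_id, .data$fragment_smiles_clean,
    .keep_all = TRUE
  )
}

#' Extract adjacent fragments from a curated CKI set
#'
#' Runs warhead matching and RECAP traversal over every unique
#' compound, harvesting the adjacent fragments. Per-molecule parse
#' failures are logged in the report, never aborting the batch.
#'
#' With `fallback = TRUE`, molecules whose warhead is not isolated by
#' any RECAP rule (e.g. aryl aldehydes) get a second pass that cuts
#' the acyclic single bonds at the warhead periphery and RECAPs the
#' remainder; hits found this way carry `method = "fallback"`. The
#' default follows the RECAP-only procedure and flags such molecules
#' `"unresolved"`.
#'
#' @param x A `cki_set` from [build_cki_set()], a data frame with a
#'   `canonical_smiles` or `smiles` column, or a character vector of
#'   SMILES.
#' @param library A [warhead_library()].
#' @param fallback Also harvest warhead-periphery fragments for
#'   unresolved molecules (default `FALSE`).
#' @return A tibble of fragment hits (see [find_adjacent_fragments()]);
#'   the `"extraction_report"` attribute (also via
#'   [extraction_report()]) counts `n_molecules`, `n_with_hits`,
#'   `n_unresolved`, `n_no_warhead`, `n_failed`, `n_hits`,
#'   `n_unique_fragments`, and the `"molecule_status"` attribute gives
#'   the per-molecule outcome.
#' @export
extract_fragments <- function(x, library = warhead_library(), fallback = FALSE) {
  smiles <- if (is.data.frame(x)) {
    x[["canonical_smiles"]] %||% x[["smiles"]]
  } else {
    x
  }
  stopifnot(is.character(smiles))
  mols <- unique(smiles)
  canon <- canonicalize_smiles(mols)
  failed <- mols[!canon$ok]
  parse_ok <- canon$canonical_smiles[canon$ok]
  compounds <- unique(parse_ok)
  hits <- empty_hits()
  status <- tibble(smiles = character(), status = character())
  if (length(compounds) > 0) {
    matches <- match_warheads(compounds, library, canonicalize = FALSE)
    tree <- recap_decompose(compounds)
    hits <- find_adjacent_fragments(tree, library, matches)
    status <- attr(hits, "molecule_status")
    if (fallback) {
      unresolved <- status$smiles[status$status == "unresolved"]
      fb <- drop_warhead_fragments(
        fallback_hits(unresolved, matches, library), library
      )
      if (nrow(fb) > 0) {
        hits <- bind_rows(hits, fb)
        status$status[status$smiles %in% unique(fb$parent_smiles)] <- "ok"
      }
    }
  }
  if (length(failed) > 0) {
    status <- bind_rows(status, tibble(smiles = failed, status = "failed"))
  }
  hits <- arrange(
    hits, .data$parent_smiles, .data$warhead_id, .data$fragment_smiles_clean
  )
  report <- list(
    n_molecules = length(mols),
    n_with_hits = sum(status$status == "ok"),
    n_unresolved = sum(status$status == "unresolved"),
    n_no_warhead = sum(status$status == "no_warhead"),
    n_failed = length(failed),
    n_hits = nrow(hits),
    n_unique_fragments = dplyr::n_distinct(hits$fragment_smiles_clean)
  )
  attr(hits, "molecule_status") <- status
  attr(hits, "extraction_report") <- report
  class(hits) <- c("cki_hits", class(hits))
  hits
}

#' Extraction report of a fragment-hit table
#'
#' @param hits Result of [extract_fragments()].
#' @return The report list.
#' @export
extraction_report <- function(hits) {
  attr(hits, "extraction_report")
}

#' Aggregate fragment hits into an adjacent-fragment library
#'
#' Groups hits by the hydrogen-capped fragment; each entry carries the
#' occurrence count, the warheads it pairs with, the kinases it reaches
#' (joined from the curated set) and a physicochemical descriptor
#' profile. Entries are sorted by descending count with a
#' lexicographic tie-break on the fragment SMILES, which makes the
#' library byte-identical across reruns.
#'
#' @param hits Fragment hits from [extract_fragments()].
#' @param cki_set Optional curated set used to attach kinase coverage.
#' @param descriptors Attach MW/logP/HBA/HBD columns (default `TRUE`).
#' @return A tibble of class `cki_fragment_library`:
#'   `fragment_smiles_clean`, `count`, `n_parents`, list-columns
#'   `warhead_ids`, `marked_forms`, `kinases`, plus `n_warheads`,
#'   `n_kinases` and descriptor columns.
#' @export
build_fragment_library <- function(hits, cki_set = NULL, descriptors = TRUE) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    out <- tibble(
      fragment_smiles_clean = character(), count = integer(),
      n_parents = integer(), warhead_ids = list(), n_warheads = integer(),
      marked_forms = list(), kinases = list(), n_kinases = integer()
    )
    if (descriptors) {
      out <- mutate(out,
        MW = numeric(), logP = numeric(), HBA = integer(), HBD = integer()
      )
    }
    class(out) <- c("cki_fragment_library", class(out))
    return(out)
  }
  if (!is.null(cki_set)) {
    kin <- summarise(
      group_by(
        inner_join(
          select(hits, "parent_smiles", "fragment_smiles_clean"),
          select(as_tibble(cki_set), parent_smiles = "canonical_smiles", "kinase_id"),
          by = "parent_smiles", relationship = "many-to-many"
        ),
        .data$fragment_smiles_clean
      ),
      kinases = list(sort(unique(.data$kinase_id))),
      .groups = "drop"
    )
  } else {
    kin <- tibble(fragment_smiles_clean = character(), kinases = list())
  }
  out <- summarise(
    group_by(hits, .data$fragment_smiles_clean),
    count = n(),
    n_parents = dplyr::n_distinct(.data$parent_smiles),
    warhead_ids = list(sort(unique(.data$warhead_id))),
    marked_forms = list(sort(unique(.data$fragment_smiles_marked))),
    .groups = "drop"
  )
  out <- mutate(out, n_warheads = lengths(.data$warhead_ids))
  out <- left_join(out, kin, by = "fragment_smiles_clean")
  out <- mutate(
    out,
    kinases = map(.data$kinases, ~ if (is.null(.x)) character(0) else .x),
    n_kinases = lengths(.data$kinases)
  )
  if (descriptors) {
    prof <- compute_descriptors(out$fragment_smiles_clean)
    out <- left_join(out, select(prof, fragment_smiles_clean = "smiles", "MW", "logP", "HBA", "HBD"),
      by = "fragment_smiles_clean"
    )
  }
  out <- arrange(out, desc(.data$count), .data$fragment_smiles_clean)
  class(out) <- c("cki_fragment_library", class(out))
  out
}
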