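# Synthetic CKI generator: assembles warhead + bridging fragment +
# scaffold molecules from SMILES templates with recorded ground truth,
# plus raw bioactivity tables with exactly planted curation violations.

#' Default parts library for the synthetic CKI generator
#'
#' Warhead parts cover both reversibility classes (acrylamide,
#' substituted acrylamide, butynamide, two cyanoacrylamides, aldehyde);
#' bridging fragment parts are the frequently observed motifs
#' benzenamine, piperidine, pyrrolidine, piperazine and quinazoline,
#' each with exactly two attachment points; scaffold parts are aryl
#' units with one attachment point. Junction chemistry defaults to
#' amide/amine/aromatic couplings so that RECAP rules cleave every
#' junction ("cleavable" parts); the aldehyde warhead attaches through
#' a plain C-C bond that no RECAP rule cuts, exercising the unresolved
#' path.
#'
#' Templates are SMILES fragments: warheads are acyl/carbonyl units,
#' fragments carry a `{s}` placeholder for the scaffold, and the
#' `w_mode`/`s_mode` columns say which junction is built on each side
#' (`ringN`: the warhead's amide nitrogen is the fragment's ring
#' nitrogen; `arylN`: anilide nitrogen retained by the fragment;
#' `arylC`: N-methyl amide to an aromatic fragment carbon; `directC`:
#' plain C-C bond; `NH`: scaffold linked through an exocyclic amine;
#' `aryl`: direct (hetero)aryl coupling).
#'
#' @return A list of tibbles `warheads`, `fragments`, `scaffolds` of
#'   class `cki_parts`.
#' @export
default_parts_library <- function() {
  warheads <- tibble(
    part = c(
      "acrylamide", "propiolamide", "butynamide",
      "cyanoacrylamide", "cyanoacrylamide_beta", "aldehyde"
    ),
    warhead_id = c(1L, 3L, 4L, 23L, 24L, 26L),
    template = c(
      "C=CC(=O)", "C#CC(=O)", "CC#CC(=O)",
      "C=C(C#N)C(=O)", "C/C=C(\\C#N)C(=O)", "O=C"
    ),
    w_mode = c("acyl", "acyl", "acyl", "acyl", "acyl", "directC"),
    cleavable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  fragments <- tibble(
    part = c("piperidine", "pyrrolidine", "piperazine", "benzenamine", "quinazoline"),
    # n_template: fragment as attached through an amide nitrogen;
    # c_template: fragment as attached through a ring carbon (directC warheads)
    n_template = c(
      "N1CCC({s})CC1", "N1CC({s})CC1", "N1CCN({s})CC1",
      "Nc1ccc({s})cc1", "N(C)c1ncnc2ccc({s})cc12"
    ),
    c_template = c(
      NA, NA, NA,
      "c1ccc({s})cc1N", "c1ncnc2ccc({s})cc12"
    ),
    s_mode = c("NH", "NH", "aryl", "aryl", "aryl"),
    n_attachments = 2L,
    # the N-linked fragments keep the amide nitrogen they contribute
    # (anilide N stays with the aryl leaf), hence the amine forms
    truth_smiles = c(
      "C1CCNCC1", "C1CCNC1", "C1CNCCN1", "Nc1ccccc1", "CNc1ncnc2ccccc12"
    )
  )
  scaffolds <- tibble(
    part = c(
      "phenyl", "quinazolinyl", "pyridinyl", "pyrimidinyl",
      "naphthyl", "thienyl", "chlorophenyl", "anisolyl"
    ),
    aryl = c(
      "c4ccccc4", "c4ncnc5ccccc45", "c4ccncc4", "c4ncncc4",
      "c4ccc5ccccc5c4", "c4cccs4", "c4ccc(Cl)cc4", "c4ccc(OC)cc4"
    ),
    n_attachments = 1L
  )
  structure(
    list(warheads = warheads, fragments = fragments, scaffolds = scaffolds),
    class = "cki_parts"
  )
}

#' Default kinase panel of the generator
#'
#' Ten accessible-cysteine kinases commonly targeted covalently.
#'
#' @return Character vector of 10 gene symbols.
#' @export
default_kinase_panel <- function() {
  c(
    "EGFR", "BTK", "JAK3", "FGFR4", "FGFR2",
    "BMX", "ITK", "TEC", "BLK", "MAP2K7"
  )
}

# pure string assembly: no chemistry backend involved
assemble_smiles <- function(warhead, fragment, scaffold, parts) {
  w <- filter(parts$warheads, .data$part == warhead)
  f <- filter(parts$fragments, .data$part == fragment)
  s <- filter(parts$scaffolds, .data$part == scaffold)
  if (nrow(w) != 1 || nrow(f) != 1 || nrow(s) != 1) {
    abort("unknown part name")
  }
  if (f$n_attachments != 2L) {
    abort(sprintf(
      "fragment part '%s' has %d attachment point(s); bridging needs 2",
      fragment, f$n_attachments
    ))
  }
  if (s$n_attachments != 1L) {
    abort(sprintf("scaffold part '%s' must have exactly 1 attachment point", scaffold))
  }
  frag_t <- if (w$w_mode == "directC") f$c_template else f$n_template
  if (is.na(frag_t)) {
    abort(sprintf(
      "fragment '%s' has no carbon-attachment form for warhead '%s'",
      fragment, warhead
    ))
  }
  s_part <- if (f$s_mode == "NH") paste0("N", s$aryl) else paste0("-", s$aryl)
  tibble(
    smiles = paste0(w$template, sub("{s}", s_part, frag_t, fixed = TRUE)),
    warhead_id = w$warhead_id,
    warhead_part = warhead,
    fragment_part = fragment,
    fragment_truth_smiles = f$truth_smiles,
    scaffold_part = scaffold,
    cleavable = w$cleavable
  )
}

#' Assemble one synthetic CKI from named parts
#'
#' Joins warhead, bridging fragment and scaffold at their attachment
#' points with single-bond junction chemistry taken from the parts
#' table, records the ground truth, and verifies that the assembled
#' molecule parses and still matches the planted warhead pattern.
#'
#' @param warhead,fragment,scaffold Part names from the parts library.
#' @param parts A [default_parts_library()]-shaped list.
#' @param library Warhead library used for the post-assembly check.
#' @return One-row tibble: `smiles`, `warhead_id`, `warhead_part`,
#'   `fragment_part`, `fragment_truth_smiles`, `scaffold_part`,
#'   `cleavable`.
#' @export
assemble_cki <- function(warhead, fragment, scaffold,
                         parts = default_parts_library(),
                         library = warhead_library()) {
  raw <- assemble_smiles(warhead, fragment, scaffold, parts)
  finalize_assembly(raw, library)
}

# batch validation of assembled molecules: canonicalise, check the
# planted warhead still matches, canonicalise the truth fragments
finalize_assembly <- function(raw, library) {
  canon <- canonicalize_smiles(raw$smiles)
  if (any(!canon$ok)) {
    abort(sprintf(
      "assembled SMILES does not parse: %s",
      paste(raw$smiles[!canon$ok], collapse = ", ")
    ))
  }
  raw$smiles <- canon$canonical_smiles
  m <- match_warheads(unique(raw$smiles), library, canonicalize = FALSE)
  matched <- distinct(select(m, smiles = "canonical_smiles", "warhead_id"))
  chk <- anti_join(raw, matched, by = c("smiles", "warhead_id"))
  if (nrow(chk) > 0) {
    abort(sprintf(
      "assembled molecule %s does not match its planted warhead %d",
      chk$smiles[1], chk$warhead_id[1]
    ))
  }
  truth <- canonicalize_smiles(unique(raw$fragment_truth_smiles))
  raw$fragment_truth_smiles <- truth$canonical_smiles[
    match(raw$fragment_truth_smiles, truth$smiles)
  ]
  raw
}

compatible_combos <- function(parts, cleavable_only = TRUE) {
  combos <- tidyr::expand_grid(
    warhead_part = parts$warheads$part,
    fragment_part = parts$fragments$part,
    scaffold_part = parts$scaffolds$part
  )
  w <- select(parts$warheads, warhead_part = "part", "w_mode", "cleavable")
  f <- select(parts$fragments, fragment_part = "part", "c_template")
  combos <- left_join(combos, w, by = "warhead_part")
  combos <- left_join(combos, f, by = "fragment_part")
  combos <- filter(combos, .data$w_mode != "directC" | !is.na(.data$c_template))
  if (cleavable_only) {
    combos <- filter(combos, .data$cleavable)
  }
  select(combos, "warhead_part", "fragment_part", "scaffold_part")
}

#' Generate a batch of synthetic CKIs with known ground truth
#'
#' Assembles `n` molecules from the parts library. The default design
#' cycles deterministically through all compatible
#' (warhead, fragment, scaffold) combinations in seed-shuffled order
#' and assigns kinases round-robin from the panel; an explicit design
#' table fixes exact combination counts instead. The same seed always
#' reproduces the same batch (integer sampling only).
#'
#' @param n Batch size (ignored when `design` gives exact counts).
#' @param parts A [default_parts_library()]-shaped list.
#' @param kinase_panel Kinase symbols to spread molecules over.
#' @param seed Integer seed.
#' @param design Optional tibble with columns `warhead_part`,
#'   `fragment_part`, `scaffold_part`, `kinase_id` (optional) and `n`:
#'   each row is replicated exactly `n` times.
#' @param cleavable_only Restrict the default design to parts with
#'   RECAP-cleavable junctions (default `TRUE`); explicit designs are
#'   taken as-is.
#' @param library Warhead library for assembly checks.
#' @return Tibble of class `cki_batch`: one row per molecule with
#'   assembly ground truth and `kinase_id`.
#' @export
generate_cki_batch <- function(n = 50L,
                               parts = default_parts_library(),
                               kinase_panel = default_kinase_panel(),
                               seed = 1L,
                               design = NULL,
                               cleavable_only = TRUE,
                               library = warhead_library()) {
  if (length(parts$warheads$part) == 0 || length(parts$fragments$part) == 0 ||
    length(parts$scaffolds$part) == 0) {
    abort("parts library must provide warheads, fragments and scaffolds")
  }
  if (is.null(design)) {
    stopifnot(n >= 1)
    combos <- compatible_combos(parts, cleavable_only = cleavable_only)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    idx <- sample.int(nrow(combos))
    pick <- combos[rep(idx, length.out = n), ]
    pick$kinase_id <- rep(kinase_panel, length.out = n)
  } else {
    stopifnot(all(c("warhead_part", "fragment_part", "scaffold_part", "n") %in% names(design)))
    pick <- tidyr::uncount(as_tibble(design), weights = .data$n)
    if (!"kinase_id" %in% names(pick)) {
      pick$kinase_id <- rep(kinase_panel, length.out = nrow(pick))
    }
  }
  key <- distinct(pick, .data$warhead_part, .data$fragment_part, .data$scaffold_part)
  assembled <- bind_rows(pmap(key, function(warhead_part, fragment_part, scaffold_part) {
    assemble_smiles(warhead_part, fragment_part, scaffold_part, parts)
  }))
  assembled <- finalize_assembly(assembled, library)
  out <- left_join(pick, assembled,
    by = c("warhead_part", "fragment_part", "scaffold_part")
  )
  out <- select(
    out, "smiles", "warhead_id", "warhead_part", "fragment_part",
    "fragment_truth_smiles", "scaffold_part", "cleavable", "kinase_id"
  )
  class(out) <- c("cki_batch", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a raw activity table with exactly planted violations
#'
#' Produces one bioactivity record per batch molecule that passes
#' every curation filter (activity sampled log-uniformly below the
#' threshold, confidence 9, panel kinase), then plants violations on
#' disjoint, seed-shuffled row subsets: activity at or above the
#' 10,000 nM threshold, confidence below 9, an off-whitelist kinase
#' tag. Duplicate (compound, kinase) pairs are appended as extra rows
#' with different assay values. Counts are exact, so the post-curation
#' content is fully predictable: curation retains
#' `nrow(batch) - n_over_threshold - n_low_confidence - n_off_whitelist`
#' records.
#'
#' @param batch A [generate_cki_batch()] result.
#' @param noise List with integer counts `n_over_threshold`,
#'   `n_low_confidence`, `n_off_whitelist`, `n_duplicates` (defaults 0;
#'   fractions in `[0, 1)` are also accepted and scaled by the batch
#'   size, rounded down).
#' @param seed Integer seed.
#' @return Tibble shaped like a raw export: `compound_smiles`,
#'   `kinase_id`, `assay_type`, `value_nM`, `confidence`, `source`,
#'   with the planted truth in the `"noise_plan"` attribute.
#' @export
generate_activity_table <- function(batch, noise = list(), seed = 1L) {
  n <- nrow(batch)
  counts <- lapply(
    list(
      n_over_threshold = noise$n_over_threshold %||% 0,
      n_low_confidence = noise$n_low_confidence %||% 0,
      n_off_whitelist = noise$n_off_whitelist %||% 0,
      n_duplicates = noise$n_duplicates %||% 0
    ),
    function(v) {
      if (v < 0) abort("noise counts/fractions must be non-negative")
      if (v > 0 && v < 1) as.integer(floor(v * n)) else as.integer(v)
    }
  )
  n_violate <- counts$n_over_threshold + counts$n_low_confidence + counts$n_off_whitelist
  if (n_violate > n) {
    abort("more planted violations than records")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # log-uniform passing activity in [0.1, 9999) nM via integer grid
  grid <- exp(seq(log(0.1), log(9999), length.out = 10000L))
  tab <- tibble(
    compound_smiles = batch$smiles,
    kinase_id = batch$kinase_id,
    assay_type = c("Ki", "Kd", "IC50")[sample.int(3L, n, replace = TRUE)],
    value_nM = grid[sample.int(10000L, n, replace = TRUE)],
    confidence = 9L,
    source = "synthetic"
  )
  rows <- sample.int(n)
  take <- function(k) {
    picked <- rows[seq_len(k)]
    rows <<- rows[-seq_len(k)]
    picked
  }
  over <- take(counts$n_over_threshold)
  lowc <- take(counts$n_low_confidence)
  offw <- take(counts$n_off_whitelist)
  hi_grid <- exp(seq(log(10000), log(50000), length.out = 1000L))
  tab$value_nM[over] <- hi_grid[sample.int(1000L, length(over), replace = TRUE)]
  tab$confidence[lowc] <- sample.int(9L, length(lowc), replace = TRUE) - 1L
  tab$kinase_id[offw] <- sprintf("FAKEKIN%d", seq_along(offw))
  dup_rows <- integer(0)
  if (counts$n_duplicates > 0) {
    clean <- setdiff(seq_len(n), c(over, lowc, offw))
    if (length(clean) == 0) {
      abort("no clean records left to duplicate")
    }
    dup_rows <- clean[(seq_len(counts$n_duplicates) - 1L) %% length(clean) + 1L]
    dup <- tab[dup_rows, ]
    dup$assay_type <- c("Ki", "Kd", "IC50")[sample.int(3L, nrow(dup), replace = TRUE)]
    dup$value_nM <- grid[sample.int(10000L, nrow(dup), replace = TRUE)]
    tab <- bind_rows(tab, dup)
  }
  attr(tab, "noise_plan") <- c(counts, list(
    rows_over_threshold = sort(over),
    rows_low_confidence = sort(lowc),
    rows_off_whitelist = sort(offw),
    rows_duplicated = sort(unique(dup_rows))
  ))
  tab
}
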