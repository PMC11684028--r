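# RECAP decomposition and adjacent-fragment extraction.

test_that("RECAP trees reproduce the rule-based hierarchy", {
  tr <- recap_decompose("CC(=O)Nc1ccccc1")
  kids <- tr$smiles_marked[!is.na(tr$parent_id) & tr$parent_id == 0]
  # amide cleavage into acetyl and aniline leaves
  expect_setequal(kids, c("*C(C)=O", "*Nc1ccccc1"))
  expect_true(all(tr$is_leaf[tr$node_id != 0]))

  # benzene has no cleavable bond: root-only tree
  tr2 <- recap_decompose("c1ccccc1")
  expect_equal(nrow(tr2), 1L)
  expect_true(tr2$is_leaf)
  expect_equal(tr2$depth, 0L)

  # N-phenylacrylamide yields an acrylamide acyl leaf
  tr3 <- recap_decompose("C=CC(=O)Nc1ccccc1")
  expect_true("*C(=O)C=C" %in% tr3$smiles_marked[tr3$is_leaf])

  expect_error(recap_decompose("(((("), "unparseable")
})

test_that("child fragments stay within their parent molecule", {
  tr <- recap_decompose("C=CC(=O)N1CCC(Nc2ccccc2)CC1")
  n_root <- tr$n_heavy[tr$depth == 0]
  expect_true(all(tr$n_heavy <= n_root))
  leaves <- tr[tr$is_leaf & tr$depth > 0, ]
  ok <- ckifrags:::backend_substruct(leaves$smiles_clean, rep(tr$smiles[1], nrow(leaves)))
  expect_true(all(ok))
})

test_that("planted fragments are recovered from assembled molecules", {
  lib <- test_lib()
  a <- assemble_cki("acrylamide", "piperidine", "phenyl", library = lib)
  h <- extract_fragments(a$smiles, lib)
  expect_equal(nrow(h), 1L)
  expect_equal(h$warhead_id, 1L)
  expect_equal(h$fragment_smiles_clean, "C1CCNCC1")
  expect_gte(h$n_attachments, 2L)

  b <- assemble_cki("acrylamide", "benzenamine", "quinazolinyl", library = lib)
  h2 <- extract_fragments(b$smiles, lib)
  expect_equal(h2$fragment_smiles_clean, "Nc1ccccc1")
})

test_that("warhead-bearing molecules without a warhead leaf are flagged unresolved", {
  lib <- test_lib()
  h <- extract_fragments("O=Cc1ccccc1", lib)
  expect_equal(nrow(h), 0L)
  st <- attr(h, "molecule_status")
  expect_equal(st$status, "unresolved")
  rep <- extraction_report(h)
  expect_equal(rep$n_unresolved, 1L)
})

test_that("batch extraction is robust, conserving and deterministic", {
  lib <- test_lib()
  batch <- test_batch()
  mols <- c(batch$smiles[1:10], "broken(((smiles", "CCO")
  h <- extract_fragments(mols, lib)
  rep <- extraction_report(h)
  expect_equal(rep$n_failed, 1L)
  expect_equal(rep$n_no_warhead, 1L)
  expect_equal(
    rep$n_with_hits + rep$n_unresolved + rep$n_no_warhead + rep$n_failed,
    rep$n_molecules
  )
  # empty input gives a zeroed report
  h0 <- extract_fragments(character(0), lib)
  expect_equal(extraction_report(h0)$n_molecules, 0L)
  expect_equal(nrow(h0), 0L)
  # byte-identical rerun
  h2 <- extract_fragments(mols, lib)
  expect_identical(as.data.frame(h), as.data.frame(h2))
})

test_that("extraction invariants hold over a seeded batch", {
  lib <- test_lib()
  batch <- test_batch()
  hits <- test_hits()
  # bridging rule: every hit has >= 2 attachment points
  expect_true(all(hits$n_attachments >= 2L))
  # substructure soundness: every clean fragment is contained in its parent
  ok <- ckifrags:::backend_substruct(hits$fragment_smiles_clean, hits$parent_smiles)
  expect_true(all(ok))
  # no returned fragment itself contains a warhead after resolution
  m <- match_warheads(unique(hits$fragment_smiles_clean), lib, canonicalize = FALSE)
  expect_equal(nrow(m), 0L)
  # ground truth: every cleavable molecule yields its planted fragment
  truth <- dplyr::distinct(
    batch[batch$cleavable, c("smiles", "warhead_id", "fragment_truth_smiles")]
  )
  joined <- dplyr::inner_join(
    truth,
    as.data.frame(hits[c("parent_smiles", "warhead_id", "fragment_smiles_clean")]),
    by = c(smiles = "parent_smiles", "warhead_id")
  )
  recovered <- dplyr::distinct(
    joined[joined$fragment_smiles_clean == joined$fragment_truth_smiles, "smiles"]
  )
  expect_equal(nrow(recovered), dplyr::n_distinct(truth$smiles))
})

test_that("fallback mode recovers fragments next to aryl aldehydes", {
  lib <- test_lib()
  a <- assemble_cki("aldehyde", "benzenamine", "quinazolinyl", library = lib)
  expect_false(a$cleavable)
  # default: unresolved
  h <- extract_fragments(a$smiles, lib)
  expect_equal(nrow(h), 0L)
  # fallback cuts at the warhead periphery and recovers the planted unit
  h2 <- extract_fragments(a$smiles, lib, fallback = TRUE)
  expect_gte(nrow(h2), 1L)
  expect_true("Nc1ccccc1" %in% h2$fragment_smiles_clean)
  expect_true(all(h2$method == "fallback"))
  expect_true(all(h2$n_attachments >= 2L))
})

test_that("fragment libraries aggregate counts, warheads and kinases", {
  lib <- test_lib()
  hits <- tibble::tibble(
    parent_smiles = c("P1", "P2", "P3", "P3"),
    warhead_id = c(1L, 23L, 1L, 4L),
    fragment_smiles_marked = c("*C1CCN(*)CC1", "*C1CCN(*)CC1", "*C1CCN(*)CC1", "*Nc1ccc(*)cc1"),
    fragment_smiles_clean = c("C1CCNCC1", "C1CCNCC1", "C1CCNCC1", "Nc1ccccc1"),
    n_attachments = 2L, node_depth = 2L, method = "recap"
  )
  cki <- tibble::tibble(
    canonical_smiles = c("P1", "P2", "P3"),
    kinase_id = c("EGFR", "BTK", "EGFR"),
    warhead_ids = list(1L, 23L, c(1L, 4L))
  )
  flib <- build_fragment_library(hits, cki)
  expect_s3_class(flib, "cki_fragment_library")
  expect_equal(flib$fragment_smiles_clean, c("C1CCNCC1", "Nc1ccccc1"))
  expect_equal(flib$count, c(3L, 1L))
  expect_equal(flib$warhead_ids[[1]], c(1L, 23L))
  expect_equal(flib$kinases[[1]], c("BTK", "EGFR"))
  expect_equal(flib$n_kinases, c(2L, 1L))
  expect_true(all(c("MW", "logP", "HBA", "HBD") %in% names(flib)))
  # empty input gives an empty library
  expect_equal(nrow(build_fragment_library(hits[0, ])), 0L)
})

test_that("generator kinase spreads propagate into the fragment library", {
  lib <- test_lib()
  kinases <- c("EGFR", "BTK", "JAK3", "FGFR4")
  design <- tibble::tibble(
    warhead_part = "acrylamide", fragment_part = "piperidine",
    scaffold_part = rep(c("phenyl", "pyridinyl", "naphthyl", "thienyl"), 1L),
    kinase_id = kinases, n = 1L
  )
  batch <- generate_cki_batch(design = design, library = lib)
  tab <- generate_activity_table(batch, seed = 5L)
  cki <- build_cki_set(apply_filters(tab), lib)
  hits <- extract_fragments(cki, lib)
  flib <- build_fragment_library(hits, cki)
  pip <- flib[flib$fragment_smiles_clean == "C1CCNCC1", ]
  expect_equal(pip$n_kinases, 4L)
  expect_setequal(pip$kinases[[1]], kinases)
})
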