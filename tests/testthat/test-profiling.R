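# Descriptors, density summaries, cross-tabulations, subsetting.

test_that("descriptors match fixed published definitions", {
  d <- compute_descriptors(c("c1ccccc1", "Nc1ccccc1", "C1CCNCC1"))
  # benzene: no heteroatoms at all
  expect_equal(d$HBA[1], 0L)
  expect_equal(d$HBD[1], 0L)
  # benzenamine donates through its NH2
  expect_equal(d$HBD[2], 1L)
  # piperidine molecular weight by atomic-mass summation:
  # 5 C (12.011) + 1 N (14.007) + 11 H (1.008) = 85.14
  expect_equal(d$MW[3], 5 * 12.011 + 14.007 + 11 * 1.008, tolerance = 1e-3)
  # determinism: identical SMILES give identical profiles
  d2 <- compute_descriptors(c("C1CCNCC1", "C1CCNCC1"))
  expect_equal(d2[1, -1], d2[2, -1])
  expect_error(compute_descriptors("x((x"), "unparseable")
})

test_that("density summaries report range, mode and mean correctly", {
  s <- density_summary(c(5, 5, 5))
  expect_equal(s$min, 5)
  expect_equal(s$max, 5)
  expect_equal(s$mode, 5)
  expect_equal(s$mean, 5)
  expect_equal(s$n, 3L)
  s1 <- density_summary(42)
  expect_equal(unlist(s1[c("min", "max", "mode", "mean")]), rep(42, 4), ignore_attr = TRUE)
  expect_error(density_summary(numeric(0)), "at least one")
})

test_that("the KDE mode matches an explicit Gaussian-sum oracle", {
  x <- c(1, 2, 2, 2, 9)
  s <- density_summary(x)
  # zero-IQR sample: bandwidth falls back to the sd-based estimate
  expect_equal(s$bw, 1.06 * stats::sd(x) * 5^(-1 / 5), tolerance = 1e-12)
  expect_equal(s$mode, oracle_kde_mode(x, s$bw), tolerance = 1e-8)
  expect_lt(abs(s$mode - 2), 0.5)

  set.seed(2024)
  z <- rnorm(10000)
  sz <- density_summary(z)
  # normal reference rule on a well-behaved sample
  expect_equal(
    sz$bw,
    1.06 * min(stats::sd(z), stats::IQR(z) / 1.34) * 10000^(-1 / 5),
    tolerance = 1e-12
  )
  expect_lt(abs(sz$mode), 0.1)
  expect_equal(sz$mode, oracle_kde_mode(z, sz$bw), tolerance = 1e-6)
})

test_that("min <= mode <= max and min <= mean <= max on random samples", {
  set.seed(7)
  for (i in 1:25) {
    x <- switch(1 + (i %% 3),
      rnorm(sample(2:200, 1)),
      rexp(sample(2:200, 1)),
      sample(0:5, sample(2:50, 1), replace = TRUE)
    )
    s <- density_summary(x)
    expect_gte(s$mode, s$min)
    expect_lte(s$mode, s$max)
    expect_gte(s$mean, s$min)
    expect_lte(s$mean, s$max)
  }
})

test_that("crosstab marginals conserve total hit counts", {
  hits <- test_hits()
  ct <- crosstab_fragment_warhead(hits)
  expect_equal(sum(ct$count), nrow(hits))
  by_frag <- dplyr::count(as.data.frame(hits), fragment_smiles_clean)
  marg <- dplyr::summarise(
    dplyr::group_by(ct, fragment_smiles_clean),
    n = sum(count), .groups = "drop"
  )
  expect_equal(
    dplyr::arrange(marg, fragment_smiles_clean),
    dplyr::arrange(by_frag, fragment_smiles_clean),
    ignore_attr = TRUE
  )
  # single entry and empty cases
  one <- hits[1, ]
  expect_equal(crosstab_fragment_warhead(one)$count, 1L)
  expect_equal(nrow(crosstab_fragment_warhead(hits[0, ])), 0L)
})

test_that("the crosstab recovers a planted design matrix exactly", {
  lib <- test_lib()
  design <- tibble::tibble(
    warhead_part = c("acrylamide", "acrylamide", "butynamide", "cyanoacrylamide"),
    fragment_part = c("piperidine", "benzenamine", "piperidine", "pyrrolidine"),
    scaffold_part = "phenyl",
    n = c(3L, 2L, 2L, 1L)
  )
  batch <- generate_cki_batch(design = design, library = lib)
  hits <- extract_fragments(batch$smiles, lib)
  # count hits per planted occurrence (batch rows repeat combinations)
  ct <- crosstab_fragment_warhead(
    dplyr::inner_join(
      as.data.frame(batch[, c("smiles", "warhead_id")]),
      as.data.frame(hits),
      by = c(smiles = "parent_smiles", "warhead_id")
    )
  )
  expect_equal(sum(ct$count), 8L)
  want <- tibble::tibble(
    fragment_smiles_clean = c("C1CCNCC1", "Nc1ccccc1", "C1CCNCC1", "C1CCNC1"),
    warhead_id = c(1L, 1L, 4L, 23L),
    count = c(3L, 2L, 2L, 1L)
  )
  expect_equal(
    dplyr::arrange(ct, fragment_smiles_clean, warhead_id),
    dplyr::arrange(want, fragment_smiles_clean, warhead_id)
  )
})

test_that("kinase coverage counts set unions once", {
  flib <- tibble::tibble(
    fragment_smiles_clean = c("A", "B"),
    kinases = list(c("EGFR", "BTK"), c("EGFR", "EGFR"))
  )
  cov <- kinase_coverage(flib, by = "fragment")
  expect_equal(cov$n_kinases[cov$fragment_smiles_clean == "A"], 2L)
  expect_equal(cov$n_kinases[cov$fragment_smiles_clean == "B"], 1L)

  cki <- tibble::tibble(
    canonical_smiles = c("m1", "m2", "m3"),
    kinase_id = c("EGFR", "BTK", "EGFR"),
    warhead_ids = list(1L, 1L, c(1L, 26L))
  )
  cov2 <- kinase_coverage(cki, by = "warhead")
  expect_equal(cov2$n_kinases[cov2$warhead_id == 1], 2L)
  expect_equal(cov2$n_kinases[cov2$warhead_id == 26], 1L)
})

test_that("reversibility subsets partition records without double counting", {
  lib <- test_lib()
  hits <- tibble::tibble(
    parent_smiles = c("a", "b"),
    warhead_id = c(1L, 26L),
    fragment_smiles_clean = c("C1CCNCC1", "Nc1ccccc1")
  )
  rev <- subset_by_reversibility(hits, "reversible", lib)
  expect_equal(rev$warhead_id, 26L)
  irr <- subset_by_reversibility(hits, "irreversible", lib)
  expect_equal(irr$warhead_id, 1L)
  expect_equal(nrow(subset_by_reversibility(hits[hits$warhead_id == 26, ], "irreversible", lib)), 0L)
  expect_error(subset_by_reversibility(hits, "covalent", lib), "unknown reversibility")

  cki <- tibble::tibble(
    canonical_smiles = c("m1", "m2", "m3"),
    kinase_id = "EGFR",
    warhead_ids = list(1L, 26L, c(1L, 26L))
  )
  pieces <- lapply(
    c("irreversible", "reversible", "mixed"),
    function(cl) subset_by_reversibility(cki, cl, lib)
  )
  expect_equal(vapply(pieces, nrow, integer(1)), c(1L, 1L, 1L))
  expect_setequal(
    unlist(lapply(pieces, function(p) p$canonical_smiles)),
    cki$canonical_smiles
  )
})

test_that("a generated class mixture splits exactly", {
  lib <- test_lib()
  design <- tibble::tibble(
    warhead_part = c("acrylamide", "butynamide", "cyanoacrylamide"),
    fragment_part = "piperidine",
    scaffold_part = c("phenyl", "pyridinyl", "naphthyl"),
    n = c(2L, 1L, 3L)
  )
  batch <- generate_cki_batch(design = design, library = lib)
  hits <- extract_fragments(batch$smiles, lib)
  joined <- dplyr::inner_join(
    as.data.frame(batch[, c("smiles", "warhead_id")]),
    as.data.frame(hits),
    by = c(smiles = "parent_smiles", "warhead_id")
  )
  # per planted occurrence: 3 cyanoacrylamide rows are reversible,
  # 2 acrylamide + 1 butynamide rows are irreversible
  expect_equal(nrow(subset_by_reversibility(joined, "reversible", lib)), 3L)
  expect_equal(nrow(subset_by_reversibility(joined, "irreversible", lib)), 3L)
})

test_that("profile_descriptors summarises each variable over the library", {
  flib <- tibble::tibble(
    fragment_smiles_clean = c("C1CCNCC1", "Nc1ccccc1", "C1CCNC1"),
    count = c(3L, 2L, 1L)
  )
  flib <- dplyr::bind_cols(
    flib,
    compute_descriptors(flib$fragment_smiles_clean)[, c("MW", "logP", "HBA", "HBD")]
  )
  prof <- profile_descriptors(flib)
  expect_equal(prof$variable, c("MW", "logP", "HBA", "HBD"))
  expect_true(all(prof$n == 3L))
  expect_true(all(prof$min <= prof$mode & prof$mode <= prof$max))
})
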