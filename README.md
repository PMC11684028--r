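# ckifrags

Extended-warhead analysis for covalent kinase inhibitors (CKIs):
curate kinase bioactivity tables into a CKI data set, match a
prioritised library of 30 electrophilic warhead patterns, extract the
**adjacent fragments** that bridge each warhead to its scaffold by
traversing RECAP fragmentation hierarchies, and characterise the
resulting fragment library — occurrence frequencies, warhead and
kinase coverage, physicochemical profiles, and fingerprint clustering.

## Who this is for

Medicinal and computational chemists studying cysteine-directed
covalent inhibitors. The limiting resource in covalent design is the
small set of usable electrophiles (acrylamide, alkynamides,
haloacetamides; cyanoacrylamide and aldehyde for reversible covalent
binding). The unit this package quantifies is the *extended warhead*:
the warhead plus the fragment bonded directly to it, which together
determine how the electrophile is presented to the pocket cysteine.

## Method at a glance

1. **Curation.** Keep records with potency (Ki, Kd or IC50) strictly
   below 10,000 nM, top confidence score 9 where the source defines
   one, and a target on the 208-kinase accessible-cysteine whitelist;
   desalt and canonicalise compounds; drop warhead-free molecules;
   collapse duplicate (compound, kinase) pairs.
2. **Warhead matching.** 30 SMARTS patterns, ids 1–22 irreversible and
   23–30 reversible, with an explicit priority order so that on shared
   atoms only the most specific electrophile is reported (a
   cyanoacrylamide never double-counts as acrylamide).
3. **Fragment extraction.** RECAP-decompose each CKI into its
   fragmentation hierarchy; at any branch whose leaves include the
   warhead, the sibling leaves with ≥ 2 attachment points are the
   bridging adjacent fragments (single-attachment leaves are distal
   and excluded). Fragments are hydrogen-capped and canonicalised.
4. **Profiling.** MW, Crippen logP, Lipinski HBA/HBD; distribution
   summaries (min, max, mean, and the mode of a Gaussian KDE with the
   Scott normal-reference bandwidth); fragment-by-warhead crosstabs
   whose marginals conserve hit counts; kinase coverage as set-union
   cardinalities; reversible/irreversible/mixed subsetting.
5. **Clustering.** Morgan fingerprints (radius 2, 2048 bits), cosine
   similarity `|A∩B|/√(|A||B|)`, average-linkage agglomeration on
   `1 − s` with a documented deterministic tie rule, cut at `k`
   clusters (default 7).

Chemistry primitives run through a bundled RDKit batch worker
(`inst/python/chem_backend.py`); see `SystemRequirements`. A synthetic
CKI generator (`generate_cki_batch()`) assembles
warhead–fragment–scaffold molecules with recorded ground truth so the
whole pipeline is testable offline.

## Worked example

Simulate a 60-molecule CKI batch with planted curation violations and
run the full pipeline:

```r
library(ckifrags)

batch <- generate_cki_batch(60, seed = 42)
tab <- generate_activity_table(
  batch,
  noise = list(n_over_threshold = 6, n_low_confidence = 4, n_duplicates = 5),
  seed = 42
)
path <- tempfile(fileext = ".tsv")
readr::write_tsv(tab, path)

outdir <- file.path(tempdir(), "demo_run")
run_pipeline(pipeline_config(path, outdir, k = 3, seed = 42))
report_summary(outdir, top = 3)
```

```
== pipeline run summary ==
records: 65 in, 55 retained (6 over threshold, 4 low confidence, 0 off whitelist)
curated set: 50 kinase-CKI pairs, 50 unique CKIs, 10 kinases
extraction: 50 molecules, 50 with hits, 0 unresolved, 0 without warhead; 50 hits, 5 unique fragments
top 3 fragments:
  C1CCNCC1  count=13 warheads={1;3;23;24} kinases=9
  C1CCNC1  count=10 warheads={3;4;23;24} kinases=6
  C1CNCCN1  count=10 warheads={1;4;23;24} kinases=6
reversibility split (records):  irreversible=29, reversible=21
```

Reading the output: the 65 input records (60 molecules + 5 planted
duplicates) lose exactly the 6 over-threshold and 4 low-confidence
records; duplicate kinase–compound pairs collapse, leaving 50 curated
pairs. Extraction recovers an adjacent fragment for every molecule —
piperidine (`C1CCNCC1`) is the most frequent bridging unit, appearing
with four different warheads across nine kinases, exactly the kind of
plasticity the extended-warhead view is meant to surface. Artifacts
(curated set, fragment library with descriptors, crosstab, density
summaries, cluster assignments, extraction report, md5 manifest) are
written to `outdir`; reruns with the same seed are byte-identical.

Individual stages compose with the pipe as plain functions:
`read_activity_table() |> apply_filters() |> build_cki_set() |>
extract_fragments() |> build_fragment_library() |> cluster_fragments()`,
with `tidy()`/`glance()` on clusterings and `autoplot()` on densities,
libraries and clusterings. A thin command-line wrapper with
`simulate` / `run` / `report` subcommands ships at
`inst/cli/ckifrags.R`.

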