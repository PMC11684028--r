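---
title: "Extended warheads: curating covalent kinase inhibitors and extracting adjacent fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended warheads: curating covalent kinase inhibitors and extracting adjacent fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Covalent kinase inhibitors (CKIs) pair a reversibly binding scaffold —
typically a hinge-binding heteroaromatic — with an electrophilic
*warhead* that reacts with a nucleophilic cysteine in or near the ATP
pocket. The palette of usable electrophiles is small (acrylamides
dominate, with alkynamides, haloacetamides and, for reversible covalent
binding, cyanoacrylamides and aldehydes), so a productive way to widen
the design space is to study the *adjacent fragment*: the structural
unit bonded directly to the warhead that bridges it to the scaffold.
Warhead plus adjacent fragment together form an *extended warhead*, a
reusable design unit.

`ckifrags` implements that analysis as a reproducible pipeline:

1. **Curation** — normalise raw kinase bioactivity exports into a
   deduplicated CKI set.
2. **Warhead matching** — a prioritised library of 30 electrophile
   SMARTS patterns (22 irreversible, ids 1–22; 8 reversible, ids
   23–30).
3. **Adjacent-fragment extraction** — RECAP-fragment each CKI, find the
   branch whose leaves contain the warhead, and harvest the bridging
   sibling leaves.
4. **Profiling** — occurrence counts, fragment-by-warhead
   cross-tabulations, kinase coverage, and MW/logP/HBA/HBD
   distributions summarised by range, mode and mean.
5. **Clustering** — average-linkage clustering of Morgan-fingerprint
   cosine similarities, cut at *k* clusters (default 7).

A synthetic CKI generator with recorded ground truth makes every stage
testable without any database access.

## Chemistry backend

All chemistry primitives — SMILES parsing and canonicalisation, SMARTS
matching with atom indices, RECAP decomposition, descriptors, Morgan
fingerprints, substructure verification — are computed by a bundled
RDKit batch worker (`inst/python/chem_backend.py`) that the package
drives through single-process batched JSON calls. Every user-facing
function is vectorised so one call covers a whole data set; a curated
table of thousands of compounds costs a handful of worker launches.
The interpreter is resolved once per session
(`options(ckifrags.python=)`, `CKIFRAGS_PYTHON`, then `python3`/
`python` on `PATH`). All analysis logic — overlap resolution, tree
traversal, curation rules, clustering, statistics — is R code in this
package.

## The warhead library

The 30 patterns ship as a versioned TSV
(`system.file("extdata", "warheads.tsv", package = "ckifrags")`) with,
per warhead: a SMARTS pattern, a reversibility class, a family label,
an integer match priority and an exemplar SMILES. The patterns were
encoded for this package from the published names and structures of
commonly used cysteine-directed electrophiles; each is validated at
load time (ids exactly 1–30, classes legal, priorities tie-free,
SMARTS parse) and each exemplar must be recognised by its own pattern
— a 30/30 self-recognition test runs in the suite.

Two conventions matter:

* **Priority resolution.** When two patterns claim overlapping atoms,
  only the higher-priority (more specific) warhead is reported. The
  cyanoacrylamide variants outrank the generic substituted acrylamide,
  which outranks plain acrylamide; maleimide outranks the substituted
  acrylamide embedded in it, and so on. This is what makes per-warhead
  counts disjoint. Non-overlapping matches are all reported, so a
  molecule with two remote acrylamides counts once per warhead but
  remains a single compound in unique-CKI counts.
* **Desalting.** Inputs keep only the largest organic component
  (carbon-bearing preferred, then heavy-atom count, then lexicographic
  canonical SMILES) before matching, since database exports routinely
  carry counterions.

## Curation rules

`read_activity_table()` accepts TSV/CSV with a *dialect* mapping for
column names and logs per-cause drop counts (unparseable SMILES,
non-numeric or non-positive values, assay types other than
Ki/Kd/IC50). `apply_filters()` retains records with

* activity strictly below 10,000 nM (a record at exactly 10,000 nM is
  excluded; a qualified `"<x"` passes when `x` itself is at or below
  the threshold, while `">x"` is always excluded, the conservative
  reading of an upper-bounded potency);
* the top confidence score 9 where enforced — enforcement applies to
  records that carry a score (or to named sources), so export styles
  without a confidence concept are not penalised;
* a kinase on the accessible-cysteine whitelist, after upper-casing
  and alias normalisation (`ERK2 → MAPK1`, ...).

The packaged whitelist holds 208 human kinase gene symbols
representing the kinome's accessible-cysteine subset. It is a
synthetic reconstruction assembled for this package (the file is named
`kinase_whitelist_synthetic.txt` accordingly): the symbols are real
human kinases, chosen to include all kinases discussed in the package
documentation, but the file is not a copy of any external table.

`build_cki_set()` canonicalises, drops warhead-free compounds and
collapses duplicate (compound, kinase) pairs regardless of their assay
values, yielding one record per kinase–CKI pair.

## Extracting adjacent fragments

Each compound is decomposed with the RECAP retrosynthetic rules into a
hierarchy whose leaves are fragments no rule cleaves further, with
dummy atoms (`*`) marking broken bonds. The extraction walks every
branch: if among a node's children there is a *warhead leaf*, its
sibling leaves are adjacent-fragment candidates; candidates with one
attachment point sit at the distal end of the molecule and are
discarded, those with two or more bridge warhead and scaffold and are
kept, hydrogen-capped and canonicalised for library identity (the
marked form is retained for audit and reassembly).

"This leaf is the warhead" needs care, because RECAP's amide rule
splits an acrylamide across the cleaved C–N bond: the acyl leaf
`*C(=O)C=C` no longer contains the amide nitrogen of the pattern. The
package therefore embeds each dummy-marked leaf back into its parent
molecule — dummy atoms acting as wildcards — and declares it a warhead
leaf when a priority-resolved, parent-level warhead match is contained
in the leaf's covered atoms and the leaf carries at most two heavy
atoms beyond that match. The slack tolerates attachment context
without letting whole scaffolds that merely embed an amide pass as
warheads. Candidates that still contain a warhead themselves are
dropped, and identical (warhead, fragment) pairs are reported once per
molecule; multiplicity across molecules is what the frequency analysis
counts.

Molecules whose warhead no RECAP rule isolates are flagged
`"unresolved"` rather than force-cut. Two gaps are worth knowing:

* **Aryl aldehydes.** No RECAP rule cleaves the C–C bond between an
  aldehyde and a ring, so aldehyde CKIs are unresolved by the default
  procedure.
* **β-substituted acrylamides with α/β C–H.** RECAP's olefin rule cuts
  any acyclic `C=C`, so e.g. a dimethylamino-crotonamide warhead is
  itself fragmented before it can surface as a leaf. (Cyanoacrylamides
  are unaffected — their α-carbon carries the nitrile.)

An optional fallback (`extract_fragments(..., fallback = TRUE)`,
default off) handles the first gap: it cuts the acyclic single bonds
at the warhead periphery — pattern atoms inside rings count as
scaffold-side anchors, so the cut lands between the electrophilic core
and the ring system — RECAPs the remainder, and keeps the leaf that
covers the cut point and still has at least two attachments. Fallback
hits are labelled `method = "fallback"`.

## Profiling

Descriptors are molecular weight, the Crippen atomic-contribution
logP, and Lipinski-style N/O acceptor and NH/OH donor counts, so any
toolkit reimplementation can match them. Distributions are summarised
by minimum, maximum, mean and *mode*, the mode being the argmax of a
Gaussian KDE with the normal-reference (Scott 1992) bandwidth
`1.06 min(sd, IQR/1.34) n^(-1/5)` on a 512-point grid over
`[min − 3h, max + 3h]`, lowest abscissa winning a tied argmax and the
result clamped into `[min, max]`. Integer-valued descriptors often
have zero IQR, where the rule would degenerate; the bandwidth then
falls back to the smallest positive spread estimate, and a sample with
no spread at all reports its value as min = mode = max. Both mean and
mode are always reported for all four variables.

Cross-tabulations are computed at hit level (an aggregated library
entry no longer knows how its occurrences split across warheads), and
their marginals always sum to the total hit count. Reversibility
subsets operate per hit (each hit has one warhead) or per record,
where `irreversible` / `reversible` / `mixed` partition the curated
set: records carrying both classes go to `mixed` only, so nothing is
double-counted — the convention behind the reversible-CKI
sub-analyses (cyanoacrylamide family 23–25 aggregated, aldehyde 26).

## Clustering

Unique fragments are fingerprinted (Morgan, radius 2, 2048 bits),
pairwise cosine similarity is computed — for binary vectors this is
`|A∩B|/sqrt(|A||B|)`, which the tests verify to 1e-12 against set
arithmetic — and average-linkage (UPGMA) agglomeration runs on the
dissimilarity `1 − similarity`. `k` is a plain parameter (default 7,
with no automatic selection, since no selection criterion is part of
the method); `cut_clusters()` re-cuts the merge record at any `k`.

Determinism needs an explicit tie rule: cosines of binary vectors are
ratios of integers and tie exactly all the time, while iterated
Lance-Williams updates reproduce a tied average only to rounding
error. Candidate merges within `1e-12` of the minimal height are
therefore treated as tied, and the lowest slot pair `(i, j)` wins,
a cluster's slot being the smallest original item index it contains.
The test suite checks the resulting partitions against a naive
from-scratch agglomeration oracle under the same rule, and the merge
heights against `stats::hclust(method = "average")`. Duplicate
fragments are clustered once, with multiplicity carried as a weight
column.

## The synthetic generator

`generate_cki_batch()` assembles warhead–fragment–scaffold molecules
from SMILES templates: six warhead parts (acrylamide, propiolamide,
butynamide, two cyanoacrylamides, aldehyde), five bridging fragments
with exactly two attachment points (piperidine, pyrrolidine,
piperazine, benzenamine, quinazoline — the frequently observed
bridging motifs), and eight one-point aryl scaffolds. Junctions are
amide, amine or aromatic couplings precisely so that RECAP cleaves
them ("cleavable" parts); the aldehyde attaches through a plain C–C
bond and is deliberately *not* cleavable, exercising the unresolved
path, and `assemble_cki()` refuses arity-incompatible parts. Every
assembled molecule is verified to still match its planted warhead.

Two ground-truth conventions follow from the junction chemistry:
fragments joined through an anilide nitrogen keep that nitrogen after
cleavage, so the planted truth for the benzenamine part is aniline and
for the quinazoline part N-methylquinazolin-4-amine; the ring-nitrogen
fragments (piperidine, pyrrolidine, piperazine) cap back to the plain
amine.

Default batches cycle deterministically through all compatible part
combinations in seed-shuffled order (integer sampling only, so seeds
reproduce byte-identically across platforms) and spread molecules over
a 10-kinase panel of commonly covalently targeted kinases. An explicit
design table fixes exact combination and kinase counts instead.
`generate_activity_table()` emits one passing record per molecule —
activity log-uniform on [0.1, 10,000) nM so both sides of the
threshold occur in noisy mode, confidence 9, panel kinase — then
plants violations (over-threshold values in [10,000, 50,000] nM,
confidence below 9, off-whitelist kinase tags) on disjoint
seed-shuffled subsets and appends duplicate pairs, all in exact
counts, so the post-curation content is fully predictable.

What the generator does *not* emulate: real chemical-space
distributions, assay noise structure, activity–structure correlation,
or molecules whose warheads sit inside rings. Passing round-trip tests
therefore demonstrate correctness of the mechanics (matching,
traversal, bookkeeping), not field performance on arbitrary medicinal
chemistry; on real exports the unresolved fraction will be dominated
by the RECAP gaps listed above.

## Operating sizes and determinism

The shipped tests and the acceptance script run the round trip on 200
assembled molecules, curation exactness on 120 molecules with 45
planted violations, clustering oracles at n = 20 fingerprints and the
KDE check on 10,000 normal draws — sizes chosen so the whole suite
exercises every stage in a couple of minutes on one core while leaving
the statistics stable. All randomness flows from explicit integer
seeds; two runs of `run_pipeline()` on the same input and config
produce byte-identical artifacts, which the manifest's md5 checksums
make easy to confirm.

## Known limitations

* Warhead SMARTS are this package's encodings of the named
  electrophile classes; other encodings of the same names can fish
  different compound sets.
* RECAP-only extraction misses aryl-aldehyde and crotonamide-style
  warheads (see above); the fallback mode recovers the former but is
  heuristic and off by default.
* The accessible-cysteine whitelist is a synthetic stand-in; swap in a
  curated list via `curation_config(kinase_whitelist = ...)` for real
  analyses.
* Clustering is O(n²) in memory and O(n³) worst-case in time; fine for
  fragment libraries of a few thousand uniques, not for millions.
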