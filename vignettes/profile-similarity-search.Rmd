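---
title: "Target-enhanced 2D similarity searching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-enhanced 2D similarity searching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Conventional 2D similarity search (CSS) ranks a screening database by the
Tanimoto similarity between each database compound and a single query
fingerprint. It uses none of the other information a curated activity
class carries: for a well-studied protein target there are typically
hundreds of annotated actives — and, just as importantly, annotated
inactives, including "activity cliff" compounds that look like actives
but are not. `profsearch` implements a family of search engines that feed
this target-specific knowledge back into the similarity search, together
with the curation, splitting and evaluation protocol needed to benchmark
them fairly.

## Similarity measures

All engines operate on fixed-length binary fingerprints (default 1024
bits, hashed circular/ECFP-type features at radius 2). Two measures are
used:

* binary Tanimoto, $T_c(A,B) = c/(a+b-c)$, with $a$, $b$ the popcounts
  and $c$ the intersection popcount;
* continuous Tanimoto,
  $T_c(A,B) = \sum_i a_i b_i \,/\, \sum_i (a_i^2 + b_i^2 - a_i b_i)$,
  defined for real-valued vectors in $[0,1]$ and identical to the binary
  form on binary inputs.

The continuous form exists because reference groups are summarized by
**average (AVE) profiles**: the element-wise mean of the members'
fingerprints, $\mathrm{AVE} = \sum_N FP(i)/N$. A profile of one
fingerprint *is* that fingerprint, which gives every profile engine a
clean degeneracy path back to the fingerprint engine it extends.

Two all-zero vectors are assigned similarity 0 rather than the 0/0 of the
formula: a featureless molecule should not match everything.

## The six engines

Every enhanced engine starts from the query's **neighbor list**: all
reference compounds with binary Tanimoto strictly greater than 0.3 to the
query, split into active and inactive references. The query's own
fingerprint is always included among the active units, so an empty
neighbor list reduces every engine to CSS rather than leaving it
undefined.

* **CSS** — rank by $T_c$(query, compound).
* **PBSS** — build one AVE profile from the query plus its active
  neighbors; rank by continuous $T_c$(profile, compound).
* **ISS** — score each database compound by MAX group fusion,
  $\max(T_{c_1},\dots,T_{c_{n_{ref}}})$, over the active units.
* **ISC** — ISS plus neighbor classification: a compound whose maximal
  similarity to the *inactive* references is at least its maximal
  similarity to the active references is rejected from the hit list
  before ranking (ties reject; a config switch flips this). Rejected
  compounds keep a $-\infty$ score in the full score vector so that a
  falsely rejected active shows up as lost AUC.
* **PBISS** — the active units are compressed first: Taylor–Butina
  clustering of the active references at cutoff 0.4, one AVE profile per
  cluster; then MAX fusion over profiles.
* **PBISC** — all references are clustered together; a pure cluster
  yields one labeled profile, a mixed cluster is split by label into two.
  Classification then runs on profile maxima. The ratio of references to
  profile units is recorded as the **compression ratio**, the quantity
  that makes the iterative search cheaper.

Hit lists are truncated to the top $k = \lfloor 0.01\,|db|\rfloor$
(4941 for the canonical 494,199-compound database), ranked by descending
score with ties broken by ascending compound id for determinism.

## Curation and splitting protocol

Raw end-point tables (compound, class, IC50/EC50/Ki in µM, or an explicit
label) are curated in three steps: concentration end points are labeled
active below 10 µM and inactive above 30 µM (the 10–30 µM gray zone is
undetermined; explicit annotations pass through); classes where more than
5% of end points belong to compounds with conflicting labels are dropped;
remaining conflicted compounds are removed, and classes are kept only if
actives and inactives each exceed 70.

Each class is split deterministically given a seed: the query set is the
set of Taylor–Butina cluster centroids of the actives (one structurally
representative query per scaffold cluster — the same clustering yields
the class's diversity index $H = -\sum_i (n_i/n)\log_2(n_i/n)$);
remaining actives and the inactives are randomly halved into reference
and test sets, except that classes with more than 20,000 inactives cap
the reference share at one fourth. The 50/50 allocation for the uncapped
case is a package choice (only "random assignment" is prescribed by the
protocol); it is exposed as `ref_frac`. An optional thinning step caps
inactive references at five per active reference; it is off by default.
Query and reference compounds are always excluded from the screening
database before scoring.

## Taylor–Butina details

The implementation is the classic sphere-exclusion algorithm: neighbor
lists at similarity $\ge$ cutoff (inclusive, the conventional reading),
candidates visited in order of decreasing original neighbor count with
ties broken by input position, false singletons left as singletons. The
cutoff used for query-set extraction / the diversity index is a required
parameter (`div_cutoff`, benchmark default 0.4, matching the profiling
cutoff); no separate value is prescribed by the protocol itself.

## The synthetic activity-class generator

Real benchmark classes come from large bioactivity databases that cannot
be bundled; the generator emulates their structure so the full pipeline
is testable end to end:

* **Scaffold families.** Each class draws `n_scaffolds` prototype
  fingerprints; every active is a prototype with each bit flipped
  independently with probability `flip_rate`. Actives from one bioassay
  series share a scaffold, so within-family similarity is high
  (≈ 0.74 at the defaults).
* **A shared class core.** All prototypes of a class share a common core
  bit vector (half of the 0.3 prototype density). Ligands of one target
  carry common substructure even across chemotypes, and this is precisely
  the condition the target-enhanced engines exploit: cross-family actives
  sit at ≈ 0.35–0.42 similarity — above the 0.3 neighbor cutoff, so
  references from other families can extend a query's reach — while
  unrelated compounds stay near 0.18.
* **Activity-cliff decoys.** Near-inactives derive from the same
  prototypes at a three-fold flip rate (≈ 0.57 similarity to their
  family): similar enough to contaminate CSS hit lists and to enter
  neighbor lists as inactive references, which is what ISC's
  classification is for.
* **Background.** Far inactives and the unknown-label background are
  i.i.d. random fingerprints whose density matches the expected active
  popcount, so popcount alone cannot separate them.

Defaults are desk-scale: 8 scaffolds × 25 actives, 100 near + 100 far
inactives, 2000 background compounds, M = 1024, flip rate 0.05. These
sizes keep a 20-class, six-engine benchmark in the low minutes on one
CPU while preserving the qualitative structure of curated classes: the
same generator at larger counts produces proportionally harder classes.

What the generator does **not** emulate: real substructure-hash
correlation between bits, heavy-tailed family sizes, assay noise beyond
label flips, and any actual chemistry. Passing benchmarks therefore
demonstrate that the engines behave as designed under the stated
geometry, not that any particular performance level transfers to real
screening data.

## Numerical choices

* Similarity of two all-zero vectors is 0 by convention everywhere.
* Classification ties (`max_active == max_inactive`) reject, the literal
  reading of the rule; `reject_ties = FALSE` keeps them. Note that for
  profile engines a mathematical tie sits on a floating-point knife edge:
  two correct implementations can decide it differently.
* Ranking ties break by ascending compound id; clustering ties (equal
  neighbor counts) break by input position. Both make every pipeline
  stage bit-reproducible under a fixed seed.
* Undefined metrics (recall with no test actives, precision with no
  labeled hits, AUC without both labels present) propagate as `NA` and
  are excluded from class means with an explicit count — never folded in
  as 0.
* AUC is computed rank-based (Mann–Whitney form, ties at ½) over the
  full score vector, not the truncated hit list, where a 1% cut would be
  nearly degenerate.
* The enrichment factor is the standard top-k form, hit-rate divided by
  prevalence; it is a package reconstruction, as the benchmark protocol
  reports enrichments without printing a formula.

## Known limitations

* PBISC can trail fingerprint-based ISC on the synthetic classes: mixed
  clusters average activity-cliff decoys into inactive profiles (and
  tight scaffold families into diluted active profiles), which both
  softens the classification boundary and falsely rejects edge actives.
  The compression ratio it buys is the compensating benefit.
* The chemistry layer (SMILES/SDF reading, circular fingerprints) is
  optional and backed by OpenBabel's ECFP implementation folded to the
  configured width; bit patterns are not interchangeable with other
  toolkits' Morgan fingerprints, so precomputed fingerprint files from
  different toolkits should not be mixed in one database. Molecules with
  no bonds (single heavy atom) are rejected by the structure validator.
* Assay merging by target-sequence similarity is out of scope; the
  curation stage takes class membership as given.
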