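---
title: "Rule-based detection of biosynthetic gene clusters with bgcscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based detection of biosynthetic gene clusters with bgcscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcscout)
library(dplyr)
```

## The problem

Microbial genomes encode the biosynthesis of specialized metabolites in
biosynthetic gene clusters (BGCs): groups of co-located genes that
together build one natural product. Genome mining finds these clusters by
scanning protein-coding genes for biosynthetic protein domains with
profile hidden Markov models (pHMMs) and asking, per genomic
neighbourhood, whether the combination of detected functions is
sufficient to call a cluster of a given product type.

bgcscout implements that detection core as a library: a declarative rule
language over pHMM hits, distance-based grouping of hit-bearing genes,
and origin-aware coordinate arithmetic so that clusters spanning the
origin of replication of a circular chromosome or plasmid are detected
and reported as single regions rather than being split in two or missed.
Downstream of detection it annotates regions with NRPS/PKS module
structure, terpene product predictions, tailoring-enzyme categories and
known-cluster similarity tiers.

The pHMM scan itself is out of scope by design: hits are consumed as a
table (a fixed subset of HMMER's per-domain output), which keeps the
engine testable without multi-hundred-megabyte profile libraries, and
lets dynamic, code-defined profiles feed the same contract
(`dynamic_profile_motif()` is a worked example). The package likewise
never calls genes; inputs are annotated GenBank records with
translations, and users of unannotated genomes should run a dedicated
gene caller first.

## The detection model

A detection rule is

```
RULE <name> CATEGORY <product> CUTOFF <kb> NEIGHBOURHOOD <kb>
  CONDITIONS <expression> [EXTENDS <expression>]
```

with expressions over `and`, `or`, `not` (precedence `not` > `and` >
`or`), parentheses, bare profile names, `minimum(n, [p1, ...])` (at
least *n* distinct profiles hit) and `minscore(p, s)` (a hit to *p* with
at least *s* bits). Evaluation is over the pooled hits of a candidate
gene group:

1. **Grouping.** Genes carrying hits to profiles the rule mentions are
   connected whenever the gap between them is at most the cutoff
   distance; connected components are the candidate groups. Component
   semantics (rather than sliding windows) make the result independent
   of gene order and stable under rotation of a circular contig.
2. **Evaluation.** The rule condition is tested against each component's
   pooled hits. In a satisfied component, every individually satisfied
   atomic condition marks the hits that satisfy it (for `minscore`, only
   hits reaching the score; atoms under `not` never mark), and genes
   carrying marked hits become the core.
3. **Locations.** The core location is the shortest single arc covering
   the core genes — on circular contigs this arc may cross the origin —
   and the full protocluster extends the core by the neighbourhood
   distance both ways, wrapping on circular contigs and clamping on
   linear ones. A region that would cover the whole contig is clamped to
   `[0, length)`: a whole-contig region has no meaningful origin break.
4. **EXTENDS.** If the rule has an `EXTENDS` condition, any gene whose
   own hits satisfy it and whose gap to the current core arc is at most
   the cutoff joins the core; core and full locations are recomputed and
   the step repeats to a fixpoint. The core only grows and is bounded by
   the gene count, so termination is guaranteed. This is what lets the
   chained module-bearing genes of a trans-AT PKS join a cluster whose
   single trans-acting acyltransferase gene sits far away; measuring
   from the growing core arc (not from the nearest core gene) is this
   package's definition, chosen because chained extension requires it.
5. **Regions.** Protoclusters from all rules whose full locations
   overlap or abut merge transitively into regions, numbered along the
   contig; an origin-spanning region sorts by the start of its wrapping
   arc. Rule hierarchies ("superiors") are not modeled; overlapping
   rules simply coexist within a region.

### Coordinates

Internally all coordinates are 0-based half-open; GenBank's 1-based
inclusive form is converted at the I/O boundary, where a two-segment
`join` wrapping the contig end reads (and writes) as a single
origin-spanning feature. An origin-spanning location is stored as
`(start, end, crosses_origin = TRUE)` with covered set
`[start, L) ∪ [0, end)`; all distance arithmetic goes through this
two-arc definition, which stays unambiguous even when a region covers
more than half the contig. Strand is carried for output but never enters
distance computations — detection rules are strand-agnostic.

One subtlety found by property testing: the shortest covering arc is
ambiguous when two complement gaps tie exactly. Ties are resolved by
comparing the cyclic pattern of arc and gap lengths read from each
candidate, which is invariant under rotation, so detected regions rotate
with their genome; only a perfectly periodic gene arrangement would
remain ambiguous (and then the smallest start wins).

## Downstream analyses

**NRPS/PKS modules.** Hits whose profile metadata carries a
`domain_kind` become domain annotations (overlaps on one gene keep the
higher bitscore). Domains are ordered by gene position along the region
arc, then by alignment position, and split greedily into modules: a
module opens at a condensation (C), ketosynthase (KS) or CoA-ligase
(CAL) domain — or at a leading adenylation/acyltransferase domain for a
starter — accumulates modification domains (KR, DH, ER, E,
β-hydroxylase, interface), and closes at a carrier protein (CP). A
thioesterase or α/β-hydrolase directly after a closed module attaches to
it as the termination domain. CAL-opened modules are starters: CoA
ligases load fatty-acid-derived starter units in lipopeptide systems. A
module is *complete* when it has a carrier protein plus a loader (A, AT
or CAL) — deliberately strict, so a trans-AT module lacking its own AT
reports `complete = FALSE` while still being part of the cluster.
Condensation and epimerization domains are checked for catalytic
residues: a configurable motif (default `HH[ILV].{2}DG`, the HHxxxDG
core with the second histidine catalytic) is searched in a window at a
configurable offset from the domain alignment start with ±10 aa slack;
domains without the motif are flagged inactive but still counted in
modules — how an inactive epimerization domain changes product
stereochemistry is left to the user. A-domains get a link-out URL to an
external substrate-specificity predictor; no network access is
performed.

**Terpene products.** Prediction is a pure table lookup: each
terpene-synthase profile maps to terpenoid class and chain length
(always present) plus subclass, initial cyclization and product name(s)
where the subfamily is specific enough. Per gene, only the
highest-specificity matching entries report (ties all report), and one
enzyme may predict several products — the shipped table's
geosmin-synthase-like entry lists both germacradienol and geosmin. When
two synthase genes in one region disagree, both predictions are listed.

**Tailoring enzymes.** Genes with tailoring-profile hits are grouped by
top-level Enzyme Commission category (oxidoreductases, transferases,
hydrolases, lyases, isomerases, ligases); only categories with members
are reported. Every gene's predictions are ranked by detail:
smCOG-style generic annotations (rank 0), family-level profile calls
(rank 1–2), motif-graded halogenase predictions (up to regioselectivity,
rank 3), and reference-set cross-links, emitted when global percent
identity to a reference entry reaches 60% (inclusive; all passing
entries, not just the best). The summary shown per gene is always the
highest-ranked prediction. Halogenases sit under transferases in the
shipped map, following the reference interface's placement.

**Known-cluster similarity.** For each reference cluster, the score is
the percentage of *reference* genes with at least one region gene at
≥30% identity (inclusive; the denominator choice is pinned to reference
genes, the established convention for this comparison). Scores map to
confidence tiers — high ≥75%, medium [50, 75), low [15, 50) — and below
15% the hit is hidden from the overview. The lower-inclusive half-open
intervals follow from the inclusive top-tier bound.

### Percent identity

Both thresholded comparisons share one pinned definition: a global
(Needleman–Wunsch) alignment under BLOSUM62 with gap opening 10 and gap
extension 0.5, and identity = identical columns / all alignment columns
(gap columns included) × 100. The denominator matters at the boundary —
alternatives (shorter sequence length, aligned columns only) shift which
pairs pass — so it is fixed and tested. Whether established tools use
local rather than global identity for the 30% rule is left open
upstream; global is this package's documented choice.

## Synthetic fixtures and what they show

`generate_fixture_bundle()` builds a deterministic, fully in-silico
study set: a circular 250 kb genome with five planted clusters (a
geosmin-like terpene cluster spanning the origin, a two-gene NRPS with a
CAL-loaded starter module, a trans-AT PKS with a distant AT gene and
three chained module genes reachable only through EXTENDS, an
azole-containing RiPP pair, and a balhimycin-style tailoring demo with
four P450s, a tryptophan-6 halogenase and a glycosyltransferase), plus a
hit table, rule/profile/annotation tables, and reference clusters
derived from the NRPS genes at identity levels pinning the high, low and
hidden tiers. Ground truth (region spans, products, module roles,
tailoring counts, confidence tiers) is computed in closed form from the
layout, never by running the engine, and depends only on the layout —
re-seeding changes filler sequence and translations but not the truth.

Choices a reader should know:

* Gene sizes (400–1100 aa), gaps (0.2–9 kb), cutoffs (5–20 kb) and
  neighbourhoods (5–20 kb) are in the ranges typical of bacterial BGC
  practice; bitscores sit comfortably above the per-profile trusted
  cutoffs except where a test pins a boundary.
* Divergence targets for reference sets use point substitutions only, so
  identity is exactly controllable; threshold-bracketing pairs use
  conservative substitutions (non-negative BLOSUM62 partners), which
  keep the gapless alignment optimal. Random substitution at low
  identity would instead let the aligner open gaps and drift off target.
* Filler DNA is uniform random; coding sequence does not encode the
  stored translations (the `/translation` qualifier is authoritative,
  as it is for the package's readers). No codon usage, GC skew, or
  pseudogenes are emulated.

Consequently, passing tests show the *logic* is right — grouping,
wrapping, thresholds, fixpoints, partitions — on data whose every
property is known. They do not show robustness to real-genome
messiness: overlapping genes, frameshifts, contig breaks, profile
false positives, or hit tables from scans with different cutoff
conventions.

## Numerical and scale choices

* All randomness in fixtures runs behind one seeded generator that
  restores the session RNG state; identical seeds give identical bytes.
* Property suites run at deliberately small scale so the whole suite
  stays interactive: exhaustive-subset oracles use genomes of ≤7–8
  hit-bearing genes on 3 kb contigs (where brute force over all 2^n
  subsets is feasible), 200 seeded cases; rotation equivariance uses 50
  circular genomes × 10 rotations. The engine itself has no scale
  constants; the 250 kb bundle exercises realistic coordinates.
* Score and identity threshold comparisons are inclusive (≥) throughout,
  matching the trusted-cutoff convention and the printed tier bounds.
* Degenerate inputs: empty hit tables, regions without the relevant
  protocluster category, and genomes without CDS all return empty
  results rather than errors; a reference cluster with zero genes, an
  out-of-range similarity, or an origin-spanning feature on a linear
  record are errors.

## Known limitations

* The shipped rules, profiles and annotation tables are fixtures that
  exercise the machinery; they are not a curated biological rule set,
  and profile names are placeholders for real pHMM libraries.
* Rule hierarchies, per-gene condition scoping (`cds(...)`-style
  constraints), and dynamic profiles beyond the single worked example
  are not modeled.
* GenBank support covers the subset the pipeline needs (LOCUS, CDS with
  translations, join/complement locations, the package's own region and
  protocluster features); rich qualifier semantics and multi-interval
  spliced genes reduce to their hull.
* Similarity search is exhaustive global alignment — appropriate for
  reference sets of tens of clusters, not a database-scale replacement.
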