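# bgcscout

Rule-based detection and annotation of biosynthetic gene clusters (BGCs)
in annotated microbial genomes, with first-class support for circular
replicons and clusters spanning the origin of replication.

Microbes encode specialized metabolites — antibiotics, siderophores,
pigments, volatiles — in clusters of co-located genes. Genome miners find
them by scanning protein translations with profile hidden Markov models
(pHMMs) and asking, per genomic neighbourhood, whether the combination of
biosynthetic functions is sufficient to call a cluster of a given product
type. bgcscout implements that core for R users who want a scriptable,
testable detection engine: a rule DSL over pHMM hit tables, origin-aware
coordinate arithmetic, and the downstream analyses that make a detected
region interpretable.

## What it computes

**Detection.** A rule
`RULE <name> CATEGORY <product> CUTOFF <kb> NEIGHBOURHOOD <kb>
CONDITIONS <expr> [EXTENDS <expr>]` is evaluated over per-gene pHMM hits
(TSV; HMMER `domtblout` adapter included). Genes with hits to profiles a
rule mentions are grouped into connected components under
gap ≤ cutoff; a satisfied component's core genes (those carrying hits to
satisfied atomic conditions) are covered by the shortest arc — possibly
crossing the origin of a circular contig — and extended by the
neighbourhood into a protocluster. An `EXTENDS` condition absorbs
distant qualifying genes (e.g. chained trans-AT PKS module genes) to a
fixpoint measured from the growing core arc. Overlapping protoclusters
merge into numbered regions. Detection is deterministic and
rotation-equivariant: rotating a circular genome rotates the regions.

**Per-region analyses.**

* NRPS/PKS domains ordered along the assembly line and split into
  modules (CoA-ligase loaded starters included); condensation /
  epimerization active sites checked against the HHxxxDG catalytic motif
  and flagged inactive when the residues are missing; A-domain link-outs
  to an external substrate predictor.
* Terpene product prediction from a subfamily table: terpenoid class and
  chain length always; subclass, initial cyclization and product name(s)
  for specific subfamilies (one synthase may predict several products,
  e.g. germacradienol *and* geosmin).
* Tailoring enzymes grouped by Enzyme Commission category with
  detail-ranked predictions (smCOG-level up to halogenase
  regioselectivity) and cross-links to a reaction reference set at
  ≥ 60% global amino-acid identity.
* Known-cluster similarity: percent of a reference cluster's genes with
  a region gene at ≥ 30% identity, shown as confidence tiers —
  high ≥ 75%, medium [50, 75), low [15, 50), hidden < 15%.

A deterministic fixture generator (`generate_fixture_bundle()`,
`generate_genome()`, `generate_reference_set()`) produces toy genomes
with planted clusters — including origin-spanning ones — plus hit
tables, rule files and reference sets with closed-form ground truth, so
everything above is testable without external databases.

## Worked example

```r
library(bgcscout)
library(dplyr)

b <- generate_fixture_bundle(seed = 1)          # 250 kb circular genome, 5 planted BGCs
hits <- apply_cutoffs(b$genome$hits, fixture_profiles())
regions <- detect_regions(b$genome$record, hits, fixture_rules())
tidy(regions)
#> # A tibble: 5 × 8
#>   record_id region_number  start    end crosses_origin length_nt n_protoclusters
#>   <chr>             <int>  <int>  <int> <lgl>              <int>           <int>
#> 1 FIXBUNDLE             1  15000  60206 FALSE              45206               1
#> 2 FIXBUNDLE             2  65000 150315 FALSE              85315               1
#> 3 FIXBUNDLE             3 155000 177616 FALSE              22616               1
#> 4 FIXBUNDLE             4 185000 204108 FALSE              19108               1
#> 5 FIXBUNDLE             5 239000  11163 TRUE               22163               1
```

Region 5 is the planted geosmin-like terpene cluster: it starts at
239 000, wraps the origin and ends at 11 163 — one region, not two
halves. Annotating the NRPS region (number 1):

```r
ana <- analyze_region(regions$regions[[1]], b$genome$record, hits,
                      fixture_profiles(),
                      motif_specs = fixture_motif_specs(),
                      references = b$references)
ana$modules %>% select(module, role, complete)
#>   module role     complete
#> 1      1 starter  TRUE
#> 2      2 extender TRUE
ana$active_sites %>% select(cds_id, domain_kind, observed, active)
#>   cds_id     domain_kind observed active
#> 1 nrps_nrpsB C           HHILADG  TRUE
ana$similarity %>% select(cluster_id, similarity_percent, confidence)
#>   cluster_id      similarity_percent confidence
#> 1 ref_nrps_high                  100 high
#> 2 ref_nrps_medium                 25 low
#> 3 ref_unrelated                    0 hidden
```

The CAL-opened starter module and the C–A–CP(–TE) extender were
recovered, the condensation domain's catalytic HHxxxDG residues are
present (`active = TRUE`), and the three reference clusters land in the
expected similarity tiers — the 25% cluster is shown as `low`
confidence, the unrelated one falls under the 15% display floor. The
terpene region predicts both germacradienol and geosmin from the single
synthase gene:

```r
analyze_region(regions$regions[[5]], b$genome$record, hits,
               fixture_profiles(),
               terpene_table = fixture_terpene_table())$terpene %>%
  select(cds_id, terpenoid_class, chain_length, product_name)
#>   cds_id    terpenoid_class chain_length product_name
#> 1 terp_geoA sesquiterpene             15 germacradienol
#> 2 terp_geoA sesquiterpene             15 geosmin
```

A command-line driver wraps the same pipeline
(`inst/scripts/bgcscout.R` with subcommands `detect`,
`generate-fixtures` and `explain-rule`), reading GenBank plus the rule,
profile and annotation tables and writing a JSON report and annotated
GenBank per record.

## Package layout

* `R/location.R`, `R/record.R`, `R/genbank.R` — coordinate model,
  records, GenBank I/O
* `R/hits.R`, `R/rules.R`, `R/detect.R` — hit tables, rule DSL,
  protocluster/region engine
* `R/nrps_pks.R`, `R/terpene.R`, `R/tailoring.R`, `R/similarity.R` —
  per-region analyses
* `R/pipeline.R`, `R/tidy.R` — end-to-end driver, tidiers, plotting
* `R/fixtures.R` — synthetic data with ground truth
* `vignettes/bgc-detection.Rmd` — the model, its assumptions and design
  choices in detail
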