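---
title: "Detecting variants that disrupt miRNA binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variants that disrupt miRNA binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsitevar)
```

## The problem

miRNAs repress gene expression by pairing with sites in the 3'UTR of their
target mRNAs; the dominant determinant of recognition is the *seed*,
nucleotides 2–8 of the mature miRNA. A single-nucleotide variant inside a
binding site can weaken or abolish that pairing, releasing the target from
repression. In a cross of an obesity/diabetes-prone mouse strain against a
lean control, such variants are candidate *cis* drivers of the elevated
expression seen in metabolically relevant tissues — provided the affected
gene also maps to an obesity or diabetes QTL and, ideally, the interaction
is conserved in humans.

`mirsitevar` implements that reasoning as a reproducible funnel:

1. keep miRNAs expressed above a read-count threshold (strictly `> 5`);
2. accept a miRNA–transcript interaction only when at least 3 of 5
   prediction tools report it, taking site coordinates exclusively from the
   designated site-defining tool (a miRanda analog);
3. intersect the sites, projected to genomic coordinates, with strain SNVs;
4. keep genes up-regulated in at least one tissue (`p <= 0.05`,
   `|log2FC| >= 0.7`, both inclusive, up only) and located inside a
   significant QTL (LOD strictly `> 3`);
5. keep interactions whose miRNA is seed-conserved in human and whose
   ortholog target carries a MirSNP-style record;
6. annotate the survivors with knockout-phenotype, GWAS and eQTL evidence,
   test for enrichment, and assemble miRNA–gene–phenotype networks.

Every stage is exposed as a package function; the numbered scripts under
`analysis/` run them in order over a synthetic bundle.

## Statistical machinery

**2×2 contingency tests.** Enrichment of candidate genes among genes with a
metabolic knockout phenotype, and of site-SNP genes inside QTL among
up-regulated genes, is tested with the plain chi-square on 1 df
(`chi_square_2x2()`), confirmed by the two-sided Fisher exact test. *No
Yates continuity correction is applied*: reproducing the published
reference values for the knockout-phenotype tables (p = 0.016 and 0.005,
odds ratios 2.81 and 3.24, bracketed expectations 17 and 22) requires the
uncorrected statistic — with correction the same cells give ≈ 0.035 and
≈ 0.014, so the choice is empirically forced. The odds ratio is the plain
cross-product with the enriched cell in the numerator, so `OR > 1` exactly
when the observed enriched cell exceeds its expectation.

**Set overlap.** The overlap of two gene sets in a universe of `N` genes is
scored with the upper-tail hypergeometric probability `P(X >= k)` and the
*representation factor* `k·N/(nA·nB)` (observed over expected overlap).

**Multiple testing.** Families of p-values are corrected with
Benjamini–Hochberg (`p.adjust` step-up). The tissue-level QTL enrichment
tests form one four-member family; per-QTL tests are corrected within their
own family. Note that step-up BH is *not* idempotent — re-adjusting
adjusted values changes them — so the package asserts order preservation
and monotonicity in sorted order, not idempotency.

**Conservation.** Mature mouse and human miRNAs are aligned with a
hand-written Smith–Waterman local aligner (match +1, mismatch −1, linear
gap −2, deterministic traceback with tie order diagonal > up > left). A
pair is accepted when the score reaches `min_score = 14` (≈ 70 % identity
on a 22-mer) *and* the 7mer seed (positions 2–8, after U/T normalisation)
is identical. The seed requirement does the real work; the score is a loose
sanity bound, because no published alignment threshold exists for this
step. Both are configurable. The aligner is cross-checked in the test suite
against `Biostrings::pairwiseAlignment` and against exhaustive enumeration
on short sequences.

## Coordinate conventions and numerical choices

* All internal coordinates are 0-based half-open. GFF3 (1-based inclusive)
  and VCF POS are shifted on ingest; BED is native. One convention
  everywhere removes off-by-one drift between UTR-relative site coordinates,
  genomic projections and variant positions.
* Only single-nucleotide substitutions are analysed; indels are counted and
  reported, never intersected.
* UTR-relative intervals are projected through the transcript's ordered UTR
  exons; on the minus strand transcript-ascending positions map to
  genome-descending positions, and a site spanning a UTR intron projects to
  several genomic blocks whose lengths sum to the site length. Projection
  is validated base-by-base in the tests.
* Disruption is *positional containment only* — any SNV inside a consensus
  site counts. A stricter flag (`in_seed_region`, offset within the 8 nt at
  the site's 3' end, where the seed pairs) is emitted as an informational
  column but never filtered on.
* The SNP-frequency track counts variants within a closed symmetric 50-kb
  flank; the genome-wide grid step defaults to 100 kb.
* The consensus vote is taken per (miRNA, transcript): distinct tools only,
  sites merged by interval union, and pairs that pass the vote without a
  site in the site-defining tool are dropped and counted — they cannot be
  intersected with variants.
* Gene–QTL membership is any-overlap (≥ 1 bp) of the gene body; QTL are
  megabase-scale, so any-overlap and containment rarely differ, and
  any-overlap is the weaker assumption. Contingency tables with an empty
  margin are flagged untestable and excluded from the BH family rather than
  silently producing NaN statistics.

## The synthetic-data generator

Raw inputs of the original study (strain sequencing, arrays, linkage data,
public human databases) are emulated by `generate_bundle()`, which plants
known signal and writes a *truth manifest* so every stage can be scored.

What is planted, and the defaults:

* a 2 × 5 Mb genome with 300 genes (one transcript each; 20 % of UTRs have
  two exons), 50 miRNAs of 22 nt, 4 significant QTL of 500 kb plus 2
  sub-threshold decoys — sizes chosen so that a full pipeline run takes a
  few seconds and a 100-bundle recovery study stays within a desk-test
  budget;
* true binding sites as exact complements of the miRNA's 7mer seed written
  into the UTR sequence, each reported as a miRanda-style ~21-nt footprint
  (seed ± 7 nt); a naive scanner (`scan_seed_sites()`) can rediscover them;
* five tool tables: true sites kept with per-tool sensitivity 0.95 plus 0.5
  Poisson false sites per transcript. With a 3-of-5 vote and sites taken
  from one tool, the expected end-to-end recovery of a true interaction is
  ≈ 0.95 × P(≥ 2 of the other 4 tools) ≈ 0.95 — which is why the planted-
  signal acceptance threshold of 0.9 sensitivity is attainable without
  being trivially safe;
* SNVs at a baseline density of 1/350 bp (the genome-wide density implied
  by ~7.25 M SNPs on the ~2.6 Gb mouse genome), multiplied by 2.5 inside
  significant QTL; reference alleles agree with the planted UTR sequence
  where a variant falls inside a UTR;
* per-tissue up-regulation with probability 0.5 for genes owning a
  disrupted site versus 0.15 otherwise (effect sizes
  `|N(1.5, 0.5)| + 0.7`, p-values `U(0, 0.05)`), giving a realistic
  candidate enrichment (representation factor ≈ 1.3–1.6) rather than a
  separation so extreme that the statistics are never exercised;
* a human mirror: 60 % of miRNAs copied with 1–3 mutations outside
  positions 2–8 (seed intact, score well above `min_score`), 20 extra human
  miRNAs with non-matching seeds, orthologs for 80 % of genes
  (transparently named `h_<gene>`), and MirSNP-style records covering 80 %
  of disrupted-and-conserved interactions plus background records that are
  explicitly sampled to avoid colliding with any translated impaired pair.

The manifest's conserved-impaired set conditions on everything the pipeline
itself requires — realized up-regulation under the DE filter, miRNA
expression, QTL membership, seed conservation, orthology, MirSNP coverage —
so the only stochastic loss between truth and pipeline output is prediction-
tool dropout, and the only possible false positives are chance collisions,
which the background-exclusion rule makes negligible.

One global random stream is seeded once; sub-generators draw in a fixed
order, so the same `(config, seed)` pair yields byte-identical bundles.

What the generator does **not** emulate: linkage disequilibrium, realistic
mutation spectra, expression covariance between tissues or genes, probe-
level array artefacts, and miRNA family structure beyond shared seeds.
Passing the recovery tests therefore demonstrates that the funnel logic,
coordinate arithmetic and statistics are correct — not that the pipeline's
operating characteristics on real mouse data match the synthetic ones.

## Problem sizes used in validation

The test suite runs the oracle-equivalence checks on hundreds of small
random instances (interval intersection vs nested loops, alignment vs
exhaustive search on ≤ 10-nt sequences, hypergeometric tails vs direct
summation for universes ≤ 60, Venn counts vs membership tallies, Fisher vs
fixed-margin enumeration). The planted-signal study pools 100 default
bundles for sensitivity/FDR and 200 no-signal bundles (QTL multiplier 1,
equal up-regulation probabilities) for type-I calibration of the tissue-
level chi-square at α = 0.05; with ≈ 45 up-regulated genes per tissue the
smallest expected cells are around 3–4, close to the classical validity
boundary of the chi-square approximation, which is why calibration is
checked against binomial bounds rather than asserted exactly.

## Known limitations

* The vote granularity is the (miRNA, transcript) pair; per-site voting
  would be stricter but contradicts the design this package mirrors.
* Orthology is symbol-level; there is no genomic liftover between species.
* Expression statistics arrive precomputed per (gene, tissue); the package
  does not fit differential-expression models and requires probe-collapsed
  input.
* The MGI-style relevant-term curation (hundreds of free-text phenotypes)
  must be user-supplied; only the 12 standardized metabolic terms ship as
  the default screen (`impc_metabolic_terms()`).
* `run_pipeline()`'s resume is file-level: outputs of stages whose
  parameters and inputs are unchanged are left untouched and reported as
  cached; invalidating any stage recomputes the analysis in memory from the
  start, which is cheap at these problem sizes.
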