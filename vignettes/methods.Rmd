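---
title: "Models and methods behind pleionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pleionet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleionet)
```

## The scientific problem

Most trait-associated variants from genome-wide association studies fall in
non-coding DNA. A common working model is that they mark regulatory
elements: a variant is an expression quantitative trait locus (eQTL) when
its genotype correlates with a gene's transcript level. Physical chromatin
contacts (Hi-C) give that correlation a spatial footing — if the restriction
fragment carrying a SNP touches a fragment overlapping a gene, the SNP is a
plausible *spatially constrained* regulator of that gene. pleionet builds
such spatially constrained eQTL gene regulatory networks (GRNs), then asks
three downstream questions:

1. **Which other traits share regulatory variants with a query condition?**
   (multi-level protein-interaction expansion + hypergeometric enrichment +
   a resampling null)
2. **Which GRN genes are putatively causal for the condition?** (two-sample
   Mendelian randomisation)
3. **Which conditions actually co-occur with the index condition in coded
   health records?** (Fisher exact odds ratios)

Every stage runs on synthetic data with planted ground truth, so the
pipeline's recovery properties are measurable rather than assumed.

## Spatial GRN construction

A candidate pair (SNP *s*, gene *g*) exists when the fragment containing
*s* forms a chromatin contact with any fragment overlapping *g*, or is
itself such a fragment (same-fragment pairs are included by default and
configurable: a SNP inside a gene's own fragment is trivially spatially
proximal, and excluding it would discard promoter-proximal regulation).
Rare variants (MAF < 0.05) are removed before testing. Association
p-values for the surviving candidates are corrected by Benjamini–Hochberg
in **one family covering all candidate pairs of the run** — not
per-chromosome or per-gene — and records with adjusted p ≤ 0.05 are
retained. Each record is annotated as

* `cis` — same chromosome, SNP-to-gene distance < 1 Mb;
* `trans_intrachromosomal` — same chromosome, ≥ 1 Mb;
* `trans_interchromosomal` — different chromosomes.

Distance is measured from the SNP to the nearest gene boundary and is 0
inside the gene; exactly 1 Mb classifies as trans, since the cis
definition is strictly "within" 1 Mb. Contacts are unordered and
deduplicated; whether the contact must reach the gene's TSS fragment
specifically was an open design point — pleionet uses *any*
gene-overlapping fragment, which is the weaker and more inclusive gate,
and exposes the same-fragment switch for sensitivity analyses.

## LD expansion and clumping

Query SNP sets are expanded with linkage disequilibrium partners at
r² ≥ 0.8 within a 5,000 bp window. The window is interpreted as ±5,000 bp
around the index SNP (the common tooling semantics; the alternative
"total span" reading is narrower, and the parameter is exposed).
Each added SNP is tagged with its best index: highest r², ties broken by
distance and then lexicographic id, so output is deterministic. Missing
pairs in the sparse r² table mean "unlinked" (r² = 0).

Instrument clumping for Mendelian randomisation is the standard greedy
rule: sort by p-value, accept a SNP iff its r² with every previously
accepted SNP within the window is below the threshold. Defaults are
r² < 0.001 within 10 Mb, the convention of the established two-sample MR
tooling; the trait-discovery expansion and the instrument clumping
deliberately use different defaults because they serve opposite goals
(capture a locus vs. guarantee independence).

## Multi-level trait discovery

Proteins encoded by the level-0 genes (GRN targets of the query SNPs)
seed a breadth-first expansion of the protein-interaction graph,
thresholded at interaction score ≥ 0.7 (the conventional high-confidence
cutoff; the threshold is inclusive and configurable). Level *L* contains
exactly the proteins at shortest-path distance *L* from the seed set, so
levels are disjoint by construction; expansion stops at level 4. At each
level the member genes re-query the GRN for their significant eQTLs, and
those eQTL sets are tested for over-representation of each catalog
trait's SNP set with the upper-tail hypergeometric probability
P(X ≥ k) — the observed count included, the standard
over-representation convention. The universe is all distinct SNPs in the
supplied catalog: the most conservative self-contained choice, since the
package cannot know the catalog's sampling frame.

### The bootstrap null

Hypergeometric p-values ignore the topology of the GRN and the
interaction graph; a trait can look enriched simply because the network
funnels many eQTLs through a hub. The resampling null addresses this: in
each of `n_iter` iterations a random SNP set of the same size as the
expanded query is drawn from the catalog universe (without replacement,
no LD matching — the resampling scheme deliberately mirrors a plain
random catalog draw), the whole discovery chain is rerun, and the
per-(trait, level) overlap is recorded. The bootstrap p-value is

$$p = \frac{\#\{\text{iterations with overlap} \ge \text{observed}\}}{n_\text{iter}}$$

implemented verbatim, so p = 0 is possible and p is always a multiple of
1/`n_iter`; a `conservative` flag switches to (b+1)/(n+1). Whether
per-iteration draws should themselves be LD-expanded is unspecified in
the procedure the package follows; the default is no expansion, which
keeps observed and resampled pipelines identical in every respect except
the SNP identities. Two significance conventions circulate for this
statistic (0.01 and 0.05); `bootstrap_config(threshold=)` supports
either, defaulting to 0.01.

## Two-sample Mendelian randomisation

GRN eQTL–gene pairs are the exposure instruments. Instruments with
exposure p > 1e-5 are removed, the rest clumped to independence, and
exposure/outcome tables harmonised: allele-swapped rows have their
outcome effect negated, palindromic SNPs (A/T, C/G) are dropped outright
(outcome allele frequencies are not part of the data contract, so
frequency-based rescue is impossible), and unresolvable mismatches are
dropped with a log message. Genes are then routed by instrument count:

* 1 instrument — **Wald ratio** $\hat\theta = \beta_Y/\beta_X$, delta-method
  SE $se_Y/|\beta_X|$;
* ≥ 2 — **fixed-effects IVW**, weighted regression through the origin with
  weights $1/se_Y^2$: $\hat\theta = \sum w\beta_X\beta_Y / \sum w\beta_X^2$,
  $se = (\sum w\beta_X^2)^{-1/2}$;
* ≥ 3 — additionally **MR-Egger** (weighted regression with intercept,
  exposure effects oriented non-negative first); the intercept estimates
  directional pleiotropy.

The IVW estimate is the primary result for multi-instrument genes, with
Egger reported as a sensitivity analysis — the procedure names both
estimators without designating one, and the IVW-primary convention
follows the established framework. Fixed-effects weighting (no
overdispersion scaling) is the simplest defensible default. Significance
is Bonferroni-controlled at α/(genes actually tested): correcting over
performed tests, not over all GRN genes, matches the stated intent of
correcting "for multiple tests".

The synthetic generator draws instrument effects
$\beta_X \sim N(0.2, 0.05^2)$ reported without measurement error, so the
IVW model is exactly specified and 95% CI coverage is nominal — the
package's coverage check (93–97% over 1,000 simulated genes) verifies
implementation, not robustness to weak instruments, which real data
would add.

## Comorbidity in coded admission records

Counting is person-level: a person with twenty admissions of one code
counts once per cell. For every non-index ICD-10 code the 2×2 table
against the index condition gives the *sample* odds ratio ad/bc (the
Fisher conditional MLE is deliberately not used, because the planted
generator and the reported quantity are both defined on the sample OR),
a two-sided Fisher exact p, and a Woolf log-OR 95% CI with Haldane 0.5
correction when any cell is zero. Multiple-testing correction defaults
to Benjamini–Hochberg with Bonferroni as an option — which correction
the reference procedure used is unstated, so the package does not guess
but exposes both. Codes are compared at the granularity supplied (no
hierarchical roll-up), and no age/sex adjustment is attempted.

The admissions generator solves the 2×2 cell probabilities exactly from
(index prevalence, code base rate, odds ratio) via the quadratic in
P(index ∧ code), so the planted OR is the population OR by construction;
any (prevalence, rate, OR) triple with positive rates strictly inside
(0, 1) is feasible, and boundary inputs are rejected as configuration
errors. Individuals with no sampled condition receive a generic
examination code so every person appears in the denominator.

## What the synthetic world does and does not emulate

`gen_world()` produces: a fragment-partitioned genome (0-based half-open
coordinates, the BED convention, used consistently everywhere); genes
with log-normal TPM; SNPs placed in tight positional blocks with
within-block r² drawn directly (LD is represented as r² because every
consumer of LD in the pipeline reads r², never genotypes); unordered
fragment contacts; and a scored protein-interaction graph with a
gene–protein map (a small fraction of genes is left unmapped on purpose,
to exercise the skip path). Planted truth: true SNP–gene pairs whose
supporting contact is guaranteed and whose SNPs have MAF ≥ 0.05 so they
survive the common-variant filter; one causal gene whose instruments sit
in distinct LD blocks so they survive clumping; planted pleiotropic
traits sharing a configurable fraction of the query eQTLs; planted
comorbidity odds ratios. True-pair p-values are drawn as 10^(−U),
U ~ Uniform(6, 12) — guaranteed BH survival at desk scale without
modelling sample size; null p-values are Uniform(0, 1).

Not emulated: genotype-level LD (no coalescent structure), Hi-C read
counts or contact strength (contacts are a presence/absence gate, which
is all the spatial filter consumes), expression quantification from
reads, and the triple (beta, se, p) of null associations is internally
uncoupled. Consequently, passing tests demonstrate the correctness and
calibration of the statistical machinery — they do not demonstrate
robustness to the failure modes of real cohort data (population
stratification, weak instruments, assay batch effects).

## Numerical and scale choices

Default desk-scale study conditions: two 1 Mb chromosomes in 4 kb
fragments, 300 SNPs, 40 genes, 20 planted true pairs of which 5
instrument one causal gene with effect θ = 0.5; 30-trait catalogs of 20
SNPs with one planted trait sharing 80% of the query eQTLs; bootstrap
nulls at 200 iterations in the bundled demonstration (1,000 remains the
`bootstrap_config()` default for real analyses); comorbidity cohorts of
50,000 (demo) or 200,000 (parameter-recovery checks) with a planted
OR = 4 at 1% index prevalence and 5% base rate. These sizes were chosen
once as the smallest at which every planted signal is comfortably
detectable by design rather than by luck, and are stated here as the
package's own simulation conditions.

Other numerics worth knowing: BH uses `stats::p.adjust`; hypergeometric
tails use `stats::phyper(k − 1, …, lower.tail = FALSE)`; Fisher p uses
`stats::fisher.test` with the conventional 1 + 1e-7 relative tolerance
on "as extreme" tables; Egger uses `stats::lm` weighted least squares
and reports its model-based standard errors; graph levels use
`igraph::distances`, with ties to multiple seeds resolved by minimum
distance; all generators restore the caller's RNG state and derive
child seeds below 2^31. Deterministic orderings (records by adjusted p,
traits by level/p/name, LD indices by r²/distance/id) make every output
byte-reproducible under a fixed seed.

## Known limitations

* The enrichment universe is catalog-defined; with a biased catalog the
  hypergeometric p is biased the same way (the bootstrap null partially
  compensates, since it resamples from the same universe).
* Levels are tested without cross-level correction, mirroring the
  multi-level procedure; an analyst testing many traits at many levels
  should treat single-level p-values as descriptive and lean on the
  bootstrap flag.
* Palindromic instruments are discarded rather than rescued, shrinking
  the instrument set.
* The comorbidity stage estimates association, not direction or
  causation, and performs no covariate adjustment.
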