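---
title: "Candidate-gene prioritization in recombinant inbred panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene prioritization in recombinant inbred panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysgenet)
```

`sysgenet` chains the standard stages of a systems-genetics
candidate-gene study — normalization, correlation screens, mixed-model
eQTL mapping, set enrichment, PPI neighborhood analysis, case/control
differential expression, and a composite evidence score — into tested,
composable functions.  This vignette documents the models, the defaults
and why they are what they are, the synthetic-cohort generator used for
validation, and the design decisions taken where the methodology was
genuinely open.

## Expression scale and normalization

All expression values are treated as log2-scale intensities.
`normalize_2z8()` applies the affine map

$$x' = 2\,\frac{x - \bar{x}}{s} + 8$$

per normalization unit, yielding mean 8 and sample SD 2 exactly (the
display convention of GeneNetwork, chosen there to keep log2 values
positive).  The default unit is the strain (array) row, matching how the
archived RI expression datasets were processed; `unit = "gene"` is
available for column-wise standardization.  Sample SD (n−1 denominator)
is used everywhere in the package.  A zero-variance unit is a hard error
naming the offending unit: silently passing it through would propagate
NaNs into every downstream correlation.

`strain_summary()` reports, per gene, the panel mean, SD, and the fold
difference $2^{\max - \min}$ across strain values — the linear-scale
ratio between the highest- and lowest-expressing strain, the usual
headline statistic for "is there heritable variation worth mapping".

## Correlation screens

`pearson()` computes the product-moment correlation on
pairwise-complete observations with the two-sided p-value from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df.  Pairwise-complete deletion
(rather than casewise) is the convention for RI phenome archives, where
each trait was measured on a different strain subset.

`correlated_genes()` screens the transcriptome against a focal gene and
keeps partners with $|r| \ge 0.3$, $p < 0.05$ and mean expression
$\ge 7.1$ on the 2Z+8 scale.  The mean floor removes genes near the
array noise floor whose correlations are unstable; 7.1 is the
conventional "expressed" cutoff on this scale.  No multiplicity
correction is applied inside this screen — it is deliberately an
inclusive co-expression net whose output feeds enrichment and network
stages; FDR control is applied where decisions are made (enrichment,
differential expression, phenome scan).  Duplicate probe symbols are
collapsed to the probe with the higher mean before screening, so counts
are gene-level.  `cross_tissue_membership()` then intersects per-tissue
lists ("present in at least 3 of 4 brain regions" by default) and
reports the full Venn partition alongside.

## Mixed-model eQTL mapping

`lmm_scan()` fits, for every marker,

$$y = \mu + x\beta + g + e, \qquad
  g \sim N(0, \sigma_g^2 K), \quad e \sim N(0, \sigma_e^2 I)$$

where $K$ is the centered marker-based kinship
$K = \tfrac{1}{M}\sum_m (x_m-\bar x_m)(x_m-\bar x_m)^{\top}$
(`kinship_matrix()`).  With LOCO (the default), the kinship used for
markers on chromosome $c$ is rebuilt from all other chromosomes, so the
tested marker's own chromosome contributes nothing to the polygenic
term and local associations are not over-corrected.

Numerically the solver follows the EMMA rotation: one
eigendecomposition of $K$ per chromosome, after which the model is a
weighted regression with weights $1/(\delta\lambda_i + 1)$ in the
variance ratio $\delta = \sigma_g^2/\sigma_e^2$.  $\delta$ is estimated
per marker by maximum likelihood on a log10 grid from $10^{-5}$ to
$10^5$ (100 points) followed by local refinement with `optimize()`
between the bracketing grid points.  ML rather than REML is the
default (the model class matches GEMMA's; a REML criterion changes
p-values negligibly at these panel sizes and would complicate the
identity-kinship equivalence below).  Negative kinship eigenvalues from
floating-point noise are clamped at zero.

The test for $\beta = 0$ is a Wald F-test with the residual-df variance
estimate: $\hat\sigma^2 = \mathrm{RSS}_w/(n-2)$ and
$F = \hat\beta^2/\widehat{\mathrm{Var}}(\hat\beta)$ referred to
$F(1, n-2)$.  This convention makes the scan reduce *exactly* to the
single-marker OLS F-test when $K = I$ (the test suite checks agreement
to $10^{-6}$ on the −log10 scale), and it is also the small-sample
reference GEMMA's own Wald test uses; a $\chi^2_1$ reference would be
anti-conservative at $n \approx 30$–$70$ strains.  Markers monomorphic
in the analyzed strain subset are reported with $p = 1$ and zero
effect.

Reporting follows RI-panel convention: suggestive and significant lines
at $-\log_{10}(p)$ of 2.5 and 4.0.  `qtl_interval()` returns the Mb
span of the contiguous run of markers above the significant threshold
through the peak.  The field reports intervals by several rules
(LOD-drop, Bayes credible, threshold run); the threshold-run rule was
chosen because it needs no additional tuning parameter and reproduces
printed spans of the form "significant eQTL within X–Y Mb".
`classify_eqtl()` calls the scan *cis* when the significant interval
lies on the gene's own chromosome within `cis_window` of the gene
position (distance 0 if the gene falls inside the interval), *trans*
when significance is elsewhere, *none* otherwise.  The default window
of 10 Mb reflects typical RI mapping resolution ("overlapping or
neighboring the gene locus") and is configurable.

`phenome_scan()` applies the same model to one locus against a trait
panel (a PheWAS-style reverse scan), with BH q-values across traits and
two reporting thresholds, q < 0.05 and a stringent q < 0.001.  This is
a deliberate simplification of multi-locus mixed-model PheWAS: the
single-marker scan preserves the kinship correction and the q-value
reporting while remaining fully specified and testable.
Eigendecompositions are cached per strain-coverage pattern, since
archived traits often share coverage.

## Enrichment, network, and differential expression

`ora()` is upper-tail hypergeometric over-representation,
$p = P(X \ge x)$ for overlap $x$ between an $n$-gene query and a
$K$-gene set inside an $N$-gene reference universe, with enrichment
ratio $(x/n)/(K/N)$.  Depletion is not tested.  Sets with fewer than 5
reference genes are dropped before testing (tiny sets produce unstable
ratios), and BH FDR < 0.1 flags significance.  The reference universe
is user-supplied — normally all genes on the platform, which is what
the data support even when "all protein-coding genes" is the nominal
universe.  Ties in the ranked output are broken by larger enrichment
ratio, then set ID, so output is deterministic.

`ego_interactors()` extracts the focal gene's primary (distance-1) and
secondary (distance-2) interactors by BFS and computes node degrees
within the induced subgraph of {focal} ∪ primary ∪ secondary — the
degree a hub-analysis plugin reports when run on the displayed ego
network.  A `full_graph_degree` flag switches to whole-graph degrees;
the two coincide for the focal gene's direct neighborhood but can
differ for peripheral nodes, and the published degree values for such
networks do not always state which was used.

`de_test()` is a per-gene Welch two-sample t (unequal variances) with
BH FDR at 0.1.  A moderated-variance estimator would gain power at
3–8 samples per group, but the downstream use is a binary
"differential in any cohort" flag feeding a composite score, and the
Welch test is fully specified, assumption-light, and exactly matched by
a permutation oracle in the tests.  Genes with zero variance in both
groups report $p = 1$.  `overlap_with_interactors()` builds the
disjunctive flag — significant in *any* supplied cohort — with genes
absent from a cohort counting as not significant there.

## The composite score

The scoring universe is the interactor set: primary and secondary
interactors of the focal gene.  For each gene, `score_gene()` awards

| channel | criterion | points |
|---|---|---|
| network connectivity | PPI degree > 1 | 1 |
| co-expression | correlated with the focal gene (p < 0.05) in ≥ 1 tissue | 2 |
| disease annotation | on the supplied autism-annotation list | 1 |
| differential expression | significant (FDR < 0.1) in ≥ 1 case/control cohort | 1 |

for a maximum of 5; `select_candidates()` keeps genes with total ≥ 4
(80% of the maximum).  Two wordings of the selection rule circulate
("≥ 4" and "exceeding 4"); ≥ 4 is implemented, since the published
eight-gene outcome includes genes with total exactly 4.  The tissue
channel is flat — the per-gene count of significant tissues is reported
for context but does not scale the 2 points; evidence in one region is
treated as sufficient co-expression support.  The score is monotone in
every channel by construction (verified exhaustively in the tests).

## The synthetic cohort generator

`simulate_cohort()` produces a full study's inputs from one master
seed, with per-component seed streams so any stage can be regenerated
alone.  What it emulates, and how:

- **Genotypes** (`simulate_ri_genotypes()`): fully homozygous RI
  strains, coded 0/1 for the two parental alleles.  Each chromosome is
  a Markov chain: adjacent markers switch with probability equal to the
  RI-by-sibling-mating expansion $R = 4r/(1+6r)$ of the per-meiosis
  fraction $r$, itself from Haldane's map function on the inter-marker
  distance.  Physical distance converts to genetic distance at
  0.5 cM/Mb, the mouse genome-wide average.  The default map is 19
  autosomes × 10 markers at 10 Mb spacing — desk-scale but with real
  linkage structure.
- **Expression** (`simulate_expression()`): the focal gene is
  `baseline + cis_effect × allele + N(0, noise_sd)` with the allele
  taken at the marker nearest its locus, i.e. a planted cis-eQTL.  The
  default `cis_effect = 0.45` with `noise_sd = 0.3` is a 1.5-SD allele
  effect — a strong but realistic cis signal.  Each planted correlate
  is $y = r\,z(x) + \sqrt{1-r^2}\,\varepsilon$ rescaled to the display
  scale, so its expected correlation with the focal gene is exactly the
  target; defaults span $|r|$ 0.45–0.8, the range where co-expression
  screens operate.  Background genes are independent noise centered at
  8 with SD 0.4.
- **Traits** (`simulate_traits()`): same construction against the focal
  expression vector, defaults $r$ −0.4 to −0.6 (the magnitude of
  reported gene–behavior genetic correlations in RI panels), plus
  independent null traits and an optional missing-data mask.
- **PPI** (`simulate_ppi()`): the focal gene is adjacent to exactly the
  planted primary interactors; secondaries attach round-robin to
  primaries; background edges avoid the focal gene and primaries so
  the radius-2 ego set is exactly the planted one.
- **Case/control** (`simulate_case_control()`): i.i.d. normal genes
  with stated shifts (in SD units) planted in the case group; default
  8 vs 8 samples, the size of a typical archived cohort comparison.

What it does **not** emulate: probe-level intensity structure, batch
effects, heteroskedastic or heavy-tailed expression noise, linkage
disequilibrium between the focal gene's regulators and other loci,
epistasis, and correlated null genes.  Passing the recovery tests
therefore shows the pipeline is correct and well calibrated under its
own model assumptions — not that those assumptions hold in any given
real dataset.

## Validation strategy and problem sizes

The test suite checks every statistical engine against an independent
oracle: the identity-kinship mixed model against the OLS F-test
(agreement to $10^{-6}$), ORA against one-sided Fisher's exact on 50
random tables, Pearson and Welch p-values against 10,000-permutation
oracles at $n \le 8$, and ego extraction against a hand-rolled BFS on
50 random graphs.  Recovery is then checked at the study's scale:
60-strain cohorts on the 19 × 10 map, 50 replicates of cis-eQTL
recovery (peak on the right chromosome within 10 Mb and called cis),
25 end-to-end pipeline replicates in which a fully evidenced planted
candidate must be selected, and 20 replicates of 100-trait null
phenome scans that must stay empty at q < 0.001.  These replicate
counts keep the full suite around a minute on one core while leaving
the pass thresholds (≥ 90%, ≥ 90%, ≥ 95%) binomially comfortable.

## Known limitations

- The LMM estimates one variance ratio per marker by ML; standard, but
  at very small panels (< 15 strains) the Wald F-test can still be
  optimistic relative to permutation-based thresholds, which the
  package does not implement (fixed 2.5/4.0 lines are used instead).
- The phenome scan tests a single marker; a multi-locus scan would
  change q-values where traits have several QTL.
- The composite score's annotation channel is only as good as the
  supplied annotation list; the package deliberately takes it as a
  flat file rather than querying live databases.
- Human-to-mouse symbol mapping for cross-species DE cohorts is the
  caller's responsibility; matching is exact-symbol.
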