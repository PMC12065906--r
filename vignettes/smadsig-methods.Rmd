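---
title: "Methods: Smad4-dependent TGF-beta target signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Smad4-dependent TGF-beta target signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smadsig implements the statistical machinery used to identify TGF-beta
target genes whose response depends on the co-Smad transcription factor
Smad4, and to validate the resulting gene signature in a human tumour
cohort and in single-cell cluster compositions. This vignette describes
the models, the rule systems, the tunable parameters and the design
choices, and what the bundled simulators do and do not emulate.

## The experimental design being modelled

The bulk machinery assumes a two-genotype (Smad4-proficient "WT" versus
Smad4-deficient "KO" adenoma organoids), three-timepoint (0, 1 and 12 h of
TGF-beta1 exposure), replicated RNA-seq design — 18 samples with three
biological replicates per genotype-by-time cell. Downstream of it sit
three further data shapes: a tumour cohort carrying per-sample pathway
variant flags, RSEM-like expression and right-censored survival; and a
single-cell experiment reduced to per-cell cluster labels plus QC metrics.

## Differential expression

Counts are filtered first (a gene is kept when it has at least 5 reads in
at least 3 samples — the permissive reading of the filter, logged at run
time), then normalised with median-of-ratios size factors computed over
genes expressed in every sample.

Each gene is modelled as negative binomial with mean $\mu$ and dispersion
$\alpha$ (variance $\mu + \alpha\mu^2$), fitted as a log-linear GLM with
the log size factor as offset. The Wald statistic for a two-group
contrast is $z = \widehat{\mathrm{lfc}} / \mathrm{se}$ with a two-sided
normal p-value; the time-course test is a likelihood-ratio test of a
genotype-by-time interaction against the additive model, referred to a
chi-square with the difference in model rank as degrees of freedom.
Benjamini-Hochberg adjustment is applied within each contrast.

**Dispersion estimation.** Per-gene dispersions maximise the Cox-Reid
adjusted profile likelihood (APL) on a fixed 25-point log-spaced grid
spanning $10^{-6}$ to $20$, estimated from *all* samples of the matrix
under the full one-factor group design, not from the two contrast groups
alone. The per-gene APL curve is then combined with the mean APL curve
across genes using a fixed prior weight of 10 pseudo-degrees of freedom
before maximising (weighted-likelihood moderation), with a quadratic
interpolation step between grid points and a floor of $10^{-8}$. The
moderation matters: with three replicates per group, raw per-gene maximum
likelihood dispersions are noisy enough that the Wald test's type-I error
rises to roughly 0.07 at a nominal 0.05; sharing information across genes
restores calibration (the acceptance suite verifies 0.05 ± 0.015 on an
all-null simulation). There is deliberately no dispersion trend on the
mean, no outlier refitting and no fold-change shrinkage by default; an
optional `shrink` flag reports an approximate normal-prior posterior mean
of the fold change alongside the unshrunk estimate, because the intended
shrinkage estimator could not be pinned down and the unshrunk MLE is the
transparent default.

Genes with zero counts throughout a contrast get $p = 1$; genes with an
all-zero group keep their Wald p-value but have the fold change
recomputed from normalised group means with a pseudo-count of 0.5, and
both cases are flagged in the output.

**Thresholds.** A gene is called differentially expressed at
$|\mathrm{lfc}| \ge 1.5$ (inclusive) and adjusted $p < 0.05$ (strict);
the baseline cross-species signature uses the stricter
$|\mathrm{lfc}| \ge 2$ at the same FDR.

## Target classification

The classifier consumes seven Wald contrasts (WT and KO time courses plus
the genotype contrast at baseline) and applies, with precedence
transient > early > late:

* **early** — significant at WT 1 h vs 0 h;
* **transient** — early, with a significant opposite-direction change at
  12 h vs 0 h and/or 12 h vs 1 h ("and/or" resolved as logical OR, the
  permissive reading);
* **late** — not early, significant at WT 12 h vs 0 h and/or 12 h vs 1 h;
* **Smad4-independent** — a target gene with a significant
  *same-direction* response in the KO genotype versus its own baseline;
  opposite-sign significance counts as dependent, mirroring the
  direction logic of the cohort decision rule;
* a target gene whose baseline (KO vs WT, 0 h) difference opposes its
  TGF-beta response direction is reassigned Smad4-dependent and removed
  from the baseline list;
* genes significant only in the KO time course are reported as class
  `none` / `not_applicable` rather than guessed.

Significance always means BH-adjusted $p < 0.05$ within the individual
contrast. The classifier is deterministic and invariant to gene order.

## CERNO enrichment

For a module $M$ and a ranking of $N$ genes (rank 1 = most significant),
the CERNO statistic is $-2\sum_{g \in M}\ln(r_g/N)$, chi-square with
$2|M|$ degrees of freedom under the null; the per-module AUC is the
Mann-Whitney U statistic of member ranks scaled to $[0,1]$. Modules are
called positive at AUC $\ge 0.5$ and BH-adjusted $p < 0.05$. Rankings
supplied as (gene, statistic) tables are sorted ascending (suiting
p-values) with ties broken by original order for determinism; ortholog
conversion before enrichment reuses the same ortholog map as the
signature construction, dropping unmapped genes with a logged count.

## Cohort validation and the three-criterion decision

Pathway variant flags follow fixed catalog gene lists (Wnt/beta-catenin,
TP53, PI3K, RTK-RAS, TGF-beta, BMP), with SMAD4 flagged separately from
the rest of the TGF-beta pathway. Cohort selection requires the Wnt
variant in both arms; the mutant arm is SMAD4-variant with no other
TGF-beta pathway variant, the control arm is free of TGF-beta pathway
variants entirely.

Subgroups cross SMAD4 status with a second-pathway context variant; which
of each pair carries the variant is not fixed by the source material, so
the package adopts the convention odd = variant absent, even = present
(G1/G2 SMAD4-WT, G3/G4 SMAD4-mutant) and echoes it in the pipeline log.
Per gene and context: a tie-corrected Kruskal-Wallis test across G1-G4
(BH across genes within a context — the adjustment scope was not
specified and this is the documented default), and Dunn z tests from
pooled ranks for all six pairs, Holm-adjusted within the gene. The
mutant-vs-control volcano uses a two-sided Mann-Whitney test per gene and
a median log2 fold-change with pseudo-count 1 on the RSEM-like medians;
a Shapiro-Wilk pre-screen is deliberately not used to switch tests — the
nonparametric test is always applied.

A gene is SMAD4-dependent when (1) every cross-status pair (G1-G3, G1-G4,
G2-G3, G2-G4) differs significantly, (2) neither within-status pair
(G1-G2, G3-G4) does, and (3) the human direction matches the mouse
direction — criteria 1-2 in *every* tested context by default (the gene
should be the least affected by co-existing second-pathway variants),
with an any-context mode available.

## Survival

Kaplan-Meier curves and the two-group log-rank test delegate to the
survival package. The cut-point search is implemented here: the
standardized log-rank statistic (hypergeometric variance, so that
$z^2$ equals the log-rank chi-square at any fixed cut) is evaluated at
every midpoint between adjacent distinct expression values leaving at
least `minprop` (default 0.1, the conventional choice; the source
analysis does not report its setting) of samples on each side; the "high"
group is expression strictly above the cut and ties share a side. The
selection p-value is a permutation p — expression shuffled against fixed
survival, add-one smoothing $(b+1)/(B+1)$ — rather than an
improved-Bonferroni or asymptotic approximation: it is exact in
distribution, cheap at these sizes, and has no approximation drift. The
scan precomputes the risk-set structure once, so each permutation costs
one cumulative-sum pass.

## Single-cell proportions

Cells pass QC when detected genes lie in [250, 7000], UMI > 500,
mitochondrial fraction < 0.15 and log10 genes-per-UMI > 0.80; a
precomputed `doublet` flag column is honoured when present (doublet
detection itself is out of scope). The cluster-proportion test permutes
condition labels over cells (a per-sample option is a deliberate
non-default: the reference implementation permutes cells), with
`obs_log2FC = log2(prop_b / prop_a)` (second condition over first,
stated in the output header), two-sided permutation p-values with
add-one smoothing, percentile bootstrap intervals from resampling cells
within condition, BH across clusters, and a flagged one-cell pseudo-count
for clusters absent from one condition. Marker detection and the
pseudo-bulk comparison use Wilcoxon rank-sum tests (log2 fold-change
pre-filter 0.25, detection fraction 0.25 on at least one side, Bonferroni
over the gene panel); the original hurdle-model scRNA DE is replaced by
this simpler test, so single-cell effect sizes are procedural stand-ins,
not reproductions.

## What the simulators emulate — and what they do not

`simulate_bulk_counts()` draws NB counts for the 18-sample design with
log-normal baseline means (meanlog log 200, sdlog 1), constant dispersion
0.1, scalar library-size factors (sdlog 0.1) and a planted log2 effect of
3 — effect classes are generated exactly as the classifier defines them
(early sustained, transient reversing by 12 h, late only at 12 h,
dependence via genotype), so recovery is well-posed. It does not simulate
reads, gene-gene correlation, dispersion trends or library-size
confounding beyond scalar factors; passing recovery tests therefore shows
the rule system and NB machinery are correct, not that real organoid data
will be as clean.

`simulate_cohort()` plants three gene classes on a log2 scale (shift 2
for SMAD4-dependent genes in every SMAD4-variant sample; shift 2 for
confounded genes only with their second-pathway variant; noise sd 1),
exponentiates to RSEM-like positive values (rank tests do not need count
modelling), draws variants per pathway at colorectal-cancer-like
prevalences (WNT 0.98, SMAD4 0.30, RTK-RAS 0.50, TP53 0.50, PI3K 0.40,
other TGF-beta 0.08, BMP 0.05), and generates exponential survival whose
hazard quadruples above the 40th-percentile cut of a dedicated marker
gene, with uniform administrative censoring tuned to a 30% rate. Real
cohorts have correlated variants, heavier-tailed expression and
non-proportional hazards; none of that is modelled.

`simulate_cells()` draws multinomial cluster labels per sample (defaults
echoing the observed adenoma shifts, e.g. a progenitor cluster at 2.5%
vs 10.5%) and log-normal/beta QC marginals; it does not generate count
matrices, so only label-level statistics can be exercised.

## Numerical choices and degenerate inputs

* Dispersion grid $10^{-6}$–$20$, 25 points, prior df 10, floor
  $10^{-8}$; GLM fits capped at 50 IRLS iterations.
* BH/Holm go through `stats::p.adjust`; NaN p-values propagate and are
  excluded from the number of tests.
* All-identical Kruskal-Wallis inputs give $p = 1$ by convention, as do
  zero-event log-rank comparisons.
* Every stochastic stage takes an explicit seed; the pipeline derives
  independent stage sub-seeds from the master seed so toggling stages
  does not shift the other streams.
* Problem sizes used by the verification suite: 2000-gene simulations
  for DE calibration/recovery and classification, a 400-sample cohort,
  500 replicates for permutation-calibration checks, 100 replicates for
  cut-point recovery, and an 80-gene demonstration pipeline. These are
  the package's chosen verification sizes; the statistical conclusions
  are size-stable.

## Known limitations

* No empirical-Bayes dispersion *trend* and no outlier handling: genes
  with extreme mean-dispersion relationships are less well served than by
  a full production DE framework.
* The Wald test relies on a normal reference; at two-to-three replicates
  per group residual type-I inflation of a percentage point or two
  remains even with moderated dispersions.
* The three-criterion decision inherits the discreteness of Holm-adjusted
  Dunn p-values at small subgroup sizes; groups below 3 samples are
  refused outright.
* The permutation p-value of the cut-point search ignores the
  correlation between overlapping cuts only in the sense that it is a
  global maximum test; it is exact for the selection procedure as a
  whole but non-deterministic across different permutation counts.
* Single-cell statistics operate on cluster labels taken as given;
  clustering uncertainty is not propagated.
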