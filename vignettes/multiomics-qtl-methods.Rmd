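---
title: "Multi-omics QTL mapping and trans-regulatory network analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics QTL mapping and trans-regulatory network analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moqtl)
```

## Scope

`moqtl` implements a complete analysis chain for cohorts measured on three
coupled data types — genotypes, transcript abundances and protein
abundances from the same tissue samples — aimed at two questions:

1. **Cis**: which nearby variants regulate a gene, and is that regulation
   visible on the transcript level, the protein level, or both?
2. **Trans**: where do the many small genome-wide effects of a complex
   disease (here modelled after atrial fibrillation, AF) accumulate, and
   through which transcription-factor (TF) networks do they propagate to
   protein endpoints?

Because the motivating cohort data of this kind are typically
access-restricted, the package ships a synthetic cohort generator with a
machine-readable truth registry; every stage is validated by recovering
what the generator planted.

## The core models

### Cis-QTL scans

Every association statistic in the package is the two-sided t-test on one
coefficient of an ordinary-least-squares fit,

$$y_g \sim \beta_0 + \beta_1 \cdot \text{dosage} + \sum_k \gamma_k c_k + \varepsilon,$$

where $y_g$ is one gene's abundance on one layer, dosage counts alt
alleles (0/1/2), and the $c_k$ are covariates. The residual degrees of
freedom are always $n - p$ with $p$ the number of fitted parameters; the
package reports $n$ and df with every record because the analysis design
leans on these numbers (e.g. a cis-eQTL scan with 12 latent factors at
$n = 75$ has df = 61). The scan is evaluated in a vectorized block (the
covariates are residualized out of both expression and dosage once, by
the Frisch–Waugh identity), which is algebraically identical to the
per-pair regression; the test suite checks equality to relative 1e-8.

A pair (variant, gene) is *cis* when both share a chromosome and the
variant lies within 1 Mb of the gene body (closed boundaries, gene-body
anchoring; the anchor is configurable because conventions differ between
scan tools).

Five phenotype layers are scanned: mRNA, protein, the cross-layer
residuals (mRNA adjusted for protein and vice versa, per gene, no other
covariates), and the protein-per-mRNA ratio, computed as protein − mRNA
after per-gene inverse-normal transformation of both layers — a
difference of normalized values standing in for a ratio of raw ones.

### Latent-factor adjustment

Expression confounders are captured by a deterministic principal-factor
estimate: the top-$k$ factors of the standardized expression matrix
(optionally after regressing out known covariates), sign-fixed by making
each factor's largest-magnitude loading positive. This is a
confounder-capture device in the spirit of the Bayesian factor models
commonly used for QTL scans; the part of the procedure that matters for
the analysis — choosing $k$ to maximize the number of genes with at
least one FDR < 0.05 association — is implemented exactly
(`optimize_factor_count()`, ties towards smaller $k$). The method tag on
the factor object records the estimator.

### Regulatory categories

For each gene's lead SNP the four per-layer FDR values (eQTL, pQTL,
residual-eQTL, residual-pQTL; BH adjustment always per layer) are
combined into a rule table:

| category | eQTL | pQTL | res-eQTL | res-pQTL |
|---|---|---|---|---|
| shared | < α | < α | ≥ α | ≥ α |
| independent eQTL | < α | ≥ α | < α | ≥ α |
| independent pQTL | ≥ α | < α | ≥ α | < α |

Everything else is `unclassified`. The logic: if one causal signal is
transmitted from mRNA to protein, adjusting either layer for the other
removes it (shared); a transcript-only effect survives in the mRNA
residual but never reaches protein (independent eQTL); and symmetrically
for post-transcriptional regulation.

Loci are defined by greedy LD clumping (r² ≥ 0.5 within 250 kb of the
lead, the two p-value regimes exposed as parameters; ties on p broken by
position then id). Joint clumping across the two omic layers uses the
per-variant minimum p.

### Colocalization

Within a locus, each variant's effect estimate yields a Wakefield
approximate Bayes factor,
$\log \text{ABF} = \tfrac12 \log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$
with $V = \text{se}^2$, $W$ the prior effect variance and $z = \beta/\text{se}$.
Posteriors for the five hypotheses (no signal; one trait only ×2; two
distinct causal variants; one shared causal variant) use priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior sd $W^{1/2} = 0.15$,
the method's standard quantitative-trait defaults. A locus is
labelled `shared_causal` at pp4 > 0.5 and `independent_signals` when
pp1+pp2+pp3 > 0.5.

### PRS, eQTS/pQTS and candidate selection

The polygenic risk score is the weighted sum of risk-allele dosages;
variants absent from the genotypes contribute their expectation
$2 \cdot \text{weight} \cdot \text{frequency}$. Raw scores are converted
to percentiles within a pooled cohort + reference panel vector, and the
percentiles are what enters the regressions (the raw score is kept
alongside). Each gene is then regressed on the PRS with clinical
covariates (age, sex, BMI, systolic blood pressure, CRP, NT-proBNP), the
layer's technical covariate (RIN for mRNA, protein concentration for
protein), and the gene's cis lead SNPs; the t-statistic on the PRS
coefficient ranks genes by aggregated trans effects (eQTS/pQTS).

Preranked GSEA on that ranking uses the weighted Kolmogorov–Smirnov
running sum (weight exponent 1), gene-label permutations with
sign-matched normalization, and a permutation-p floor of
$1/(n_{\text{perm}}+1)$. The ES is the running-sum extremum of largest
magnitude; an exact magnitude tie resolves to the positive extremum — a
knife-edge that does occur in small universes and must be pinned down
for reproducibility. Genes recurring in the leading edge of at least
`min_sets` significantly enriched sets (default 14, matching a GO-style
collection of hundreds of sets; the synthetic workflow scales this to
its smaller collection) become trans candidates.

The candidate count is capped by an F-test power analysis: the largest
$k$ such that a regression explaining $r^2$ of variance (default 0.218,
a strong reference trans effect) still has ≥ 50% power at the
Bonferroni level $\alpha/(n_{\text{SNPs}} \cdot k)$. The power function
uses $u = 1$, $v = n - 2$, noncentrality $f^2(u+v+1)$. The 50%
requirement is read at percent resolution (the way a threshold is read
off a power curve reported in percent): at $n = 74$, $r^2 = 0.218$, 108
SNPs this gives $k_{\max} = 23$, with power 49.8% at $k = 23$ and 49.3%
at $k = 24$; a strict comparison (`resolution = 0`) is one argument away
and would give 22. The covariate-adjusted alternative
(`n_covariates > 0`) is likewise exposed.

### Trans scans, TF activity and mediation

Targeted trans scans run the same OLS engine over candidates × trait
SNPs (MAF ≥ 0.1, LD-pruned at r² > 0.5) with clinical covariates, the
fibroblast score and the layer's technical covariate — deliberately
without latent factors, which can absorb genuine trans signal — and flag
records at FDR < 0.2 per layer. Two keep-rules for the LD pruning are
provided — retain the group's smallest or its largest GWAS p-value (the
latter appears in some published workflows, plausibly as a transcription
slip for the former); `lowest_p` is the default.

TF activity per sample is the binding-site-count weighted sum of target
transcript expression (after optional covariate residualization and
per-gene inverse-normal transformation). Functional binding sites come
from ChIP peaks filtered for log2 enrichment > 0 and −log10 P > 1.301,
merged when overlapping, required to overlap an open-chromatin state by
≥ 25 bp, and assigned to a gene when they hit its promoter or a region
linked to it by promoter-capture interaction data. The open-chromatin
default is the permissive promoter/enhancer state set of the 15-state
chromatin model (TssA, TssAFlnk, TssBiv, EnhG, Enh, BivFlnk, EnhBiv),
supplied as a BED file.

The mediation filter asks, per annotated target gene, whether (a) it has
a functional binding site, (b) its transcript is associated with the
TF-driving SNP with a sign concordant with the SNP→TF direction
(P < 0.05; the literal "negative β" rule of a repressive risk allele is
available as `sign_rule = "negative"`), (c) that association vanishes
(P > 0.2) once TF expression enters the model, and (d) its protein is
positively associated with TF expression at BH FDR < 0.05, with the FDR
computed only over the (a–c) survivors. The final functional flag is the
conjunction. Criterion (c) deserves emphasis: it demands a
*non*-significant coefficient, so even under perfect mediation it has an
intrinsic ~20% miss rate, and shared confounding between TF and target
expression adds a collider-induced inflation on top — the filter is
designed for specificity, not sensitivity, and the recovery tests set
their expectations accordingly.

Differential protein analysis for disease status uses the stringent
covariate set (age, sex, BMI, diabetes, sysBP, hypertension medication,
myocardial infarction, smoking, fibroblast score, protein
concentration); a replication-style check then runs single-set GSEA of
the identified target set against the differential ranking, with a
ranking helper that orders significant genes ahead of non-significant
ones when only fold changes and significance flags are available.

## The synthetic cohort generator

`simulate_cohort()` produces, deterministically per seed:

- **Genotypes** in Hardy–Weinberg proportions at MAFs drawn from
  `maf_range`, in LD blocks via a Gaussian copula (latent AR(1) with
  parameter `ld_rho`, thresholded at the HWE quantiles). Blocks are laid
  out 3 Mb apart so a gene's 1 Mb cis window never spans two blocks.
- **Cis classes**: each planted gene's causal variant explains `cis_r2`
  of its layer's variance. Shared genes transmit the full mRNA signal to
  protein at fraction `mrna_to_protein_r2`; for the independent classes
  the two layers are fully decoupled, because any cross-layer coupling
  re-injects the cis signal into the other layer's residual with
  opposite sign and blurs the category definitions — a real phenomenon
  the classification must tolerate in real data, but one that would make
  planted-truth recovery rates measure the wrong thing.
- **Confounders**: `n_latent_factors` Gaussian factors loading on both
  layers (`factor_strength` variance each); the fibroblast score
  covariate is tied to the first factor. Clinical covariates are
  simulated as plausible correlated Gaussians/Bernoullis with CRP and
  NT-proBNP log-normal.
- **Trans architecture**: PRS weights on dedicated variants (one per
  block, disjoint from all cis-causal variants); core genes receive
  `core_r2` of the standardized score, transmitted to protein; the first
  core gene is the TF, additionally driven *negatively* by its own trans
  variant (`tf_trans_r2`); targets depend on TF mRNA proportionally to
  their binding-site count (strongest target at `tf_target_r2`), again
  transmitted to protein; decoy genes carry binding-site annotations
  without any dependence, so specificity is actually exercised.
- **Disease status** from a logistic model on core-gene protein levels,
  and ~0.5% of protein entries missing at random to exercise imputation
  (deliberately above the per-mille rate typical of matched proteomics
  data).

Defaults were fixed a priori from power arithmetic at the benchmark
cohort size (n = 300): `cis_r2 = 0.1` gives per-pair t ≈ 5.8;
`mrna_to_protein_r2 = 0.8` keeps the residual leakage of shared genes
near the significance boundary (a deliberate stress);
`tf_target_r2 = 0.5` with binding-site counts 2–6 keeps the weakest
target's SNP association detectable through criterion (b). The effect
sizes are free parameters of the generator, not estimates of any real
cohort.

What the generator does **not** emulate: population structure and
relatedness, raw measurement pipelines (probe intensities, spectra),
realistic LD beyond block-local AR(1) correlation, non-Gaussian
expression marginals, and cell-type mixtures beyond the single
factor-linked fibroblast score. Passing recovery tests therefore show
that the estimators are correct and calibrated under the stated model,
not that they are robust to everything real tissue data can do.

## Numerical choices

- **HWE exact test**: full enumeration over heterozygote counts
  conditional on allele counts, standard two-sided (non-mid-P) tail
  summation — no χ² approximation, matching the "exact test" QC
  convention. QC thresholds: MAF > 0.01, HWE P > 1e-6, call rate > 98%;
  homozygous-minor calls carried by < 3 samples are recoded to
  heterozygous.
- **Inverse-normal transform**: $\Phi^{-1}((\text{rank} - 0.5)/n)$, ties
  by average rank; a constant vector maps to zeros with a warning. The
  0.5 offset is the package-wide convention and configurable at the call
  sites that expose it.
- **KNN imputation**: k = 10 neighbour genes, Euclidean distance scaled
  over shared observed samples; neighbours must be observed in the gap's
  sample; observed values are never altered.
- **Coordinates**: 1-based inclusive internally; BED's 0-based half-open
  convention is converted at the single read/write boundary.
- **Rank deficiency**: aliased design columns are dropped in column
  order (cis SNPs last, so collinear SNPs are dropped in id order) and
  recorded; a dropped dosage column marks the record unusable rather
  than reporting a misleading zero.
- **Determinism**: one seeded generator stream per simulation stage
  (genotypes, multi-omics layers, trans architecture, gene sets) with a
  documented offset from the master seed, so each stage is reproducible
  in isolation.

## Problem sizes used in the validation suite

The benchmark conditions are part of the package: category recovery runs
one cohort of 300 samples with 100 genes per planted cis class
(`category_study_config()`); the trans pipeline runs 50 replicate
cohorts of 300 samples and 100 genes each (`trans_study_config()`),
every replicate executing the full PRS → eQTS → GSEA → trans scan →
mediation chain; GSEA equivalence is checked exhaustively on all
universe sizes up to 20 and against an independent implementation at
10,000 permutations; the analytic power function is checked against
20,000 simulated F-tests. These sizes keep each suite reproducible on a
single CPU in minutes while leaving the Monte-Carlo error well below the
margins being asserted.

## Known limitations

- The latent-factor stand-in shares only the purpose, not the posterior,
  of Bayesian factor models; factor *counts* tuned on real data with
  such models do not transfer one-to-one.
- NES values from permutation GSEA depend on the permutation
  normalization convention; minor numeric differences from other
  implementations are expected even where ES agrees exactly.
- The mediation filter's criterion (c) caps sensitivity by construction
  (see above); interpreting its output as a complete target list would
  be wrong — it is a high-confidence shortlist.
- LD is computed from the supplied genotypes only; there is no external
  reference panel, no conditional/stepwise cis analysis, and no mixed
  models or kinship correction.
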