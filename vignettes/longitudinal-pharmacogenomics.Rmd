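---
title: "Longitudinal pharmacogenomics: models, parameters and design choices"
author: "longipharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal pharmacogenomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longipharm)
```

`longipharm` analyses cohorts of serially sampled tumors (typically
patient-derived cancer cells from liquid biopsies) profiled at 2–4
timepoints with targeted sequencing, bulk RNA expression and a
drug-response screen. This vignette states the models each stage
assumes, the tunable parameters and their defaults, what the bundled
synthetic-cohort generator does and does not emulate, and the numerical
and design choices made where the problem left them open.

## Evolution typing

A variant is *present* in a sample when it has at least `min_alt = 3`
supporting reads **and** VAF ≥ `min_vaf = 0.02`. This deterministic rule
stands in for probabilistic phylogeny-based presence calls: at the
typical targeted-sequencing depth of ~200×, three reads at 2% VAF is a
conservative detection floor, and a deterministic rule makes every
downstream classification exactly testable. Both thresholds are
unitless and exposed via `presence_rule()`.

For a focal gene (EGFR and TP53 are the canonical choices in EGFR–TKI
cohorts), let *A* and *B* be the sets of distinct protein changes
present at the earlier and later timepoint. The call is the pattern
`|A|>|B|` and label persistence (*A* = *B* ≠ ∅), extinction (*A* ≠ ∅,
*B* = ∅), expansion (*B* ⊋ *A*, including de novo acquisition 0>1), and
otherwise *complex*. The complex label is our own addition: a turnover
such as {L858R} → {T790M} has equal counts but different identity, and
no established name; collapsing it into any of the three canonical
classes would overstate what the data show. Counting distinct protein
changes (rather than inferred clones) makes the secondary-mutation case
L858R → L858R + I744M read as 1>2 expansion, which is the convention the
pattern notation implies.

## Heterogeneity and selection statistics

**MATH.** `math_score()` computes
100 · 1.4826 · median(|VAFᵢ − median(VAF)|) / median(VAF). The 1.4826
factor is the usual Gaussian consistency constant on the MAD; with it,
the score is the standard MATH definition — zero iff all VAFs are
equal, invariant to rescaling all VAFs by a constant, and undefined
below two variants (flagged `NA` rather than guessed).

**dN/dS.** `dnds_ratio()` is a counting (Nei–Gojobori-style) estimator:
each observed single-nucleotide mutation is classified
synonymous/nonsynonymous by codon translation under the standard
genetic code, and the expected site counts are obtained by enumerating
all 9 single-nucleotide changes of every codon, each contributing 1/3
site (changes to stop codons count as nonsynonymous, so N + S = 3 per
codon exactly). ω = (n/N)/(s/S). No multiple-hit or trinucleotide-rate
correction is applied: per-sample somatic counts in targeted panels are
small (a handful to tens of mutations), where such corrections are
immaterial against the counting noise. ω is flagged undefined when no
synonymous mutations are observed rather than reported as infinite.
Neutral calibration uses 10,000 mutations drawn uniformly over the full
opportunity space of a 300-codon CDS; we draw them as whole permuted
enumerations of the 2,700 possible changes plus a without-replacement
remainder — the marginal distribution is identical to iid uniform
draws, but the balanced design shrinks the sd of ω from ≈0.021 to
≈0.005 so the neutrality check reflects the estimator, not the
sampling noise of the mutation draw.

**Fusions and metastasis association.** Fusion dynamics are pure set
algebra (maintained/vanished/acquired) with two conservation identities
that are property-tested. The 2×2 mutation × metastasis test is the
Pearson chi-squared without continuity correction — chosen because it
equals the closed form n(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) used as the
test oracle; the odds ratio is flagged infinite when bc = 0.

## Paired drug-response shifts

AUC here is the area under the dose–response curve from viability
screening, normalized to [0, 1]; *higher = more resistant*. For a drug
and an evolution group, `paired_shift()` computes the mean over
patients of log₂(AUC at Tₙ₊₁ / AUC at Tₙ). The mean of paired
log-ratios (not the ratio of group means) respects the pairing and is
invariant to per-patient scale. The test is a paired *t* on the log₂
values by default, with a Wilcoxon signed-rank alternative — both are
offered because the field uses both for this design, and the choice is
a config option rather than a silent decision. Candidates require
*P* < 0.1 **and** |log₂FC| > 0.2; the magnitude rule is two-sided, with
the sign giving direction (≤ −0.2 sensitization, ≥ +0.2 resistance).
No multiple-testing correction is applied at this screening stage —
the cutoffs are deliberately permissive and candidates are meant for
downstream validation (synergy, signatures), not inference.

Pairs with zero variance of the differences are flagged not-testable
rather than assigned *P* = 0 or 1; fewer than two complete pairs is
likewise flagged.

## Drug gene signatures

`grid_search_fit()` regresses AUC on per-gene z-scored expression with
a small feedforward network: ReLU hidden layers, linear output,
full-batch Adam, and L1/L2 weight penalties (dropout available). Two
numerical choices matter:

- The target is centered and the **output layer is initialized at
  zero**, so the initial model is exactly the mean predictor. Without
  this, a network with more genes than samples interpolates even a
  constant target with large weights and generalizes terribly; with it,
  weight norm grows only as the signal warrants.
- The default grid is one hidden layer of 16 units, epochs 150,
  L2 = 10⁻³, and **L1 ∈ {10⁻³, 3·10⁻³}** searched by 5-fold
  cross-validated RMSE. The L1 penalty is the decisive hyperparameter
  when the true signal is sparse (a few response-driving genes among
  thousands); the grid search picks its strength per drug. Ties in CV
  RMSE are broken by grid enumeration order.

Signatures come from **permutation feature importance**: the mean (over
5 repeats) increase in RMSE when a gene's column is permuted, floored
at zero. Permutation importance was chosen over any network-internal
weight heuristic because it is model-agnostic, has a direct predictive
interpretation, and is exactly reproducible given a seed. One sample
permutation per repeat is shared across genes, and first-layer
pre-activations are cached so each gene costs a rank-one update —
O(n·h) per gene instead of a full forward pass over all genes. The
signature is the top K = 100 genes (a K = 500 variant is a config
override), ties broken by gene symbol.

Everything — fold assignment, initialization, dropout, permutations —
derives from explicit seeds, so fits are bit-reproducible.

## Enrichment

`preranked_gsea()` is the weighted Kolmogorov–Smirnov running sum:
genes ordered by decreasing statistic, hits incrementing by
|stat|^p / Σ|stat|^p (p = 1 by default) and misses decrementing by
1/(N − |set|); the ES is the signed maximum deviation. A running sum
can attain +M and −M exactly (miss-runs at both ends of the list), so
the tie is broken toward the positive peak with a 10⁻¹² tolerance —
without an explicit rule the reported sign would depend on
floating-point accumulation order. The null permutes gene labels
(appropriate for preranked input), *P* uses add-one smoothing (minimum
1/(n_perm + 1)), and NES divides by the mean |permuted ES| of the same
sign.

`sample_set_score()` is an ssGSEA-style per-sample score: genes ranked
by expression within each sample, a weighted running sum with rank
weights raised to α = 0.25, score = Σ(hit CDF − miss CDF). Being purely
rank-based it is invariant to any strictly monotone transform of a
sample's expression — the property that makes cross-sample score
deltas meaningful without cross-sample normalization assumptions. This
rank statistic deliberately stands in for kernel-CDF variants of
per-sample scoring: both are rank-based set scores, and the simpler
statistic is exactly testable against a brute-force oracle. A set with
no expressed member in the matrix is flagged missing, not zero.

Timepoint deltas (`score_delta()`) are mean(Tₙ₊₁) − mean(Tₙ) over
paired patients with a paired *t* by default (Welch as the unpaired
option for group-vs-group contrasts).

## Drug-tolerant subclone profiling

Single-cell QC drops cells with mitochondrial UMI fraction strictly
above 30% or detected features strictly below 200 / above 6,000 —
strict inequalities, so boundary cells are kept, matching the usual
reading of "> 30%" rules; mito fraction is computed on raw counts.
Marker signatures use a two-sided Wilcoxon rank-sum per gene on
counts-per-10k log1p-normalized values with log₂((mean+1)/(mean+1))
fold changes, ordered by *P* then fold change.

Bulk deconvolution solves, per sample, min‖bulk − fᵀ·ref‖₂ subject to
f ≥ 0 by NNLS and renormalizes f to sum to one. Plain NNLS replaces
cross-subject variance weighting schemes: with synthetic reference
profiles the weighting has nothing to estimate, and NNLS keeps the
exact-recovery property (zero-noise mixtures are recovered to machine
precision) that anchors the tests. A rank-deficient reference is an
error, not a silent pseudo-inverse.

Treatment staging follows the EGFR–TKI sequence BASELINE (naive),
POST1 (1st/2nd-generation TKI, no T790M), POST2 (T790M acquired after
TKI), POST3 (osimertinib-treated), with precedence POST3 > POST2 >
POST1 and contradiction checks (osimertinib without any TKI history is
an error). ROC AUC is the closed-form midrank Mann–Whitney statistic,
P(s⁺ > s⁻) + ½P(tie).

## Synergy

Inhibition is 1 − viability normalized to the untreated (0, 0) well.
The HSA score is 100 × the mean, over all combination wells, of the
excess over the best constituent single agent — the per-well excess
convention of common synergy software, stated explicitly because
published single-number HSA scores rarely say how wells are aggregated.
The median-effect fit regresses log₁₀(fa/(1−fa)) on log₁₀(D) (slope m,
Dm = 10^(−intercept/m)), excluding fa ∉ (0, 1) with a warning; the
combination index at effect fa is CI = d₁/Dx₁ + d₂/Dx₂ with
Dx = Dm(fa/(1−fa))^(1/m). `synergy_summary()` evaluates CI at each
combination well's achieved inhibition — the interpolation-free choice
when the full grid is available.

## Survival

Subjects are dichotomized at score quartiles (type-7 quantiles; ties at
a boundary are included in the corresponding group, so no subject's
group depends on sort order), the middle half excluded. Follow-up is
administratively censored at 60 months ("5-year" tests); truncation is
idempotent. The comparison is the log-rank test and a univariate Cox
model with Efron tie handling (the more accurate choice under heavy
ties, and the convention of the `survival` package this stage is built
on). Hazard ratios are reported for the high-vs-low group indicator —
the natural reading of quartile-based survival figures — with Wald 95%
intervals and both Wald and score-test *P* values.

## The synthetic cohort generator

`generate_cohort()` plants ground truth for every stage. Defaults are
chosen once to emulate a realistic refractory-lung-cancer PDC cohort:
30 patients × 2 timepoints, ~200× depth (Poisson), truncal VAFs
Beta(8, 12) (mean 0.4), passenger VAFs Beta(2, 8), ~5 passenger
variants per sample, a 48-drug screen with 8 drugs shifted by
log₂FC = −0.5 in the extinction group at σ = 0.1 (log₂-scale noise),
bulk expression as Dirichlet(1) mixtures of 7 log-normal cell-type
profiles with 5% additive noise, exponential survival with hazard ratio
2, and Hill-model (m = 2, Dm = 10) dose–response grids. Planted-present
variants have read counts resampled until they pass the presence rule,
so classification tests measure the classifier, not binomial sampling
accidents. The planted AUC shift is applied on the log₂ scale (the
scale of the test statistic); AUC is clamped to [10⁻⁴, 1].

Combination wells are **Loewe-additive by construction** — the effect
level solving d₁/Dx₁(fa) + d₂/Dx₂(fa) = 1 — plus an additive inhibition
offset. Zero offset therefore yields CI = 1 exactly, and a positive
offset yields CI < 1, giving the synergy stage a sharp planted truth.

Dedicated helpers cover the stages whose natural scale differs from the
cohort: `simulate_signature_data()` (500 samples × 2,000 genes, 20
informative genes whose z-scored expression drives AUC with signal sd
0.15 against residual noise sd 0.05), `simulate_cell_counts()` /
`simulate_cluster_counts()` (negative-binomial UMI toys for QC and
marker tests), `simulate_survival()` (exponential times, optional
exponential censoring; `censor_rate = 0` gives fully observed data),
and `simulate_dose_grid()`.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: copy-number-driven VAF distortion, tumor
purity, shared passenger mutations and mutational signatures;
between-patient correlation of drug response; nonlinear
expression–response relationships (the planted signal is linear, so
signature recovery measures the pipeline under its own model);
single-cell dropout structure, doublets and batch effects; and
non-proportional hazards. Results on real cohorts depend on upstream
variant calling and expression quantification, which are out of scope
here (cluster labels, AUC values and variant tables are inputs).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the smallest sizes at which each property is statistically
sharp: 30-patient cohorts for classification exactness, 200 simulated
cohorts for type-I calibration and power of the paired test, 10,000
mutations for dN/dS neutrality, 1,000 random instances for the GSEA and
ROC oracles, 500 × 2,000 signature recovery over 20 seeds (5 in the
acceptance script), 100 samples for deconvolution error, and 100
simulations of n = 500 for Cox recovery. Every stochastic quantity
derives from an explicit seed through `child_seed()`, so reruns are
bit-reproducible.

One calibration fact worth stating plainly: with n = 500 subjects and
all events observed, the Cox log-HR estimator for a balanced binary
covariate at HR = 2 has sd ≈ 0.10, so the recovery band [1.7, 2.35] is
approximately the estimator's 90% interval — a 100-simulation recovery
experiment is expected to land ~90 ± 3 inside the band, and realized
counts on either side of 90 reflect that sampling noise, not the
estimator.

## Known limitations

- The evolution classifier sees presence/absence only; it does not
  model VAF trajectories, copy number, or clonal nesting, and the
  `complex` label absorbs everything the three canonical classes do not
  cover.
- The dN/dS estimator is unadjusted for mutational context; cohort
  comparisons are meaningful, absolute values on biased panels less so.
- The network regressor is a deliberately small, fully reproducible
  model; it is not a substitute for large-scale architecture search,
  and its importances are predictive, not causal.
- NNLS deconvolution assumes the reference spans the bulk mixture;
  missing cell types are redistributed over the provided ones.
- HSA and CI summarize a grid; they do not model dose–response
  interaction surfaces (no Bliss/Loewe/ZIP response-surface fitting).
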