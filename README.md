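# longipharm

Longitudinal pharmacogenomic analysis of serially sampled tumors in R.

Refractory lung cancers under targeted therapy (e.g. EGFR–TKIs) evolve:
truncal driver mutations can persist, vanish, or gain secondary hits
between consecutive patient samples, and drug sensitivity shifts with
them. `longipharm` implements the full desk-side analysis for cohorts of
patient-derived cancer cells profiled at 2–4 timepoints with targeted
sequencing, bulk transcriptomes and drug-response screens:

- **Evolution typing.** A read-level presence rule (alt reads ≥ 3 and
  VAF ≥ 0.02) partitions variants into truncal and private sets. For a
  focal gene *g* with variant sets *A* at *T*ₙ and *B* at *T*ₙ₊₁ the call
  is the pattern `|A|>|B|` with label *persistence* (A = B ≠ ∅),
  *extinction* (A ≠ ∅, B = ∅), *expansion* (B ⊋ A, or de novo), else
  *complex*.
- **Heterogeneity and selection.** MATH score
  `100 · 1.4826 · MAD(VAF) / median(VAF)`; a counting dN/dS estimator
  ω = (n/N)/(s/S) with per-codon site expectations from exhaustive
  enumeration of all 9 single-nucleotide changes; fusion
  maintained/vanished/acquired dynamics; mutation × metastasis odds
  ratios with Pearson chi-squared tests.
- **Longitudinal drug response.** Per evolution group and drug, the mean
  paired log₂(AUCₙ₊₁/AUCₙ) with a paired *t* (or Wilcoxon signed-rank)
  test; candidates selected at *P* < 0.1 and |log₂FC| > 0.2 (sign gives
  direction: sensitization vs resistance).
- **Drug gene signatures.** A feedforward regression network (ReLU,
  Adam, L1/L2, optional dropout) predicts AUC from per-gene z-scored
  expression; hyperparameters are grid-searched by k-fold
  cross-validated RMSE; signatures are the top-100 genes by permutation
  feature importance.
- **Enrichment.** Preranked GSEA (weighted Kolmogorov–Smirnov running
  sum, gene-label permutation null, add-one-smoothed *P*) and
  ssGSEA-style per-sample gene-set scores with *T*ₙ₊₁ − *T*ₙ deltas.
- **Drug-tolerant subclone profiling.** Single-cell QC (mito > 30%,
  features < 200 or > 6,000 dropped), rank-sum cluster marker
  signatures, NNLS deconvolution of bulk samples into cell-type
  fractions, EGFR–TKI treatment staging (BASELINE/POST1/POST2/POST3) and
  Mann–Whitney ROC AUC.
- **Synergy.** Highest-single-agent excess score
  `100 · mean[inh(i,j) − max(inh(i,0), inh(0,j))]` and the Chou–Talalay
  combination index `CI = d₁/Dx₁ + d₂/Dx₂` from median-effect fits
  `log₁₀(fa/(1−fa)) = m·log₁₀(D) − m·log₁₀(Dm)`.
- **Survival.** Quartile dichotomization of subclone scores, 5-year
  (60-month) administrative censoring, log-rank and univariate Cox
  (Efron ties) comparison.
- **Synthetic cohorts.** `generate_cohort()` and the `simulate_*()`
  helpers plant known evolution classes, drug shifts, sparse
  response-driving genes, Dirichlet cell-type mixtures, hazard ratios
  and synergy offsets, so every stage is testable without patient data.

## Worked example

```r
library(longipharm)

b <- generate_cohort(sim_params(n_patients = 30), seed = 1)
calls <- classify_evolution(b$variants, "EGFR", b$params$presence)
table(calls$pattern, calls$label)
#>       expansion extinction persistence
#>   1>0         0         10           0
#>   1>1         0          0          10
#>   1>2        10          0           0

math_score(c(0.2, 0.4, 0.6))
#> MATH score: 74.13 (MAD 0.2965 / median VAF 0.4000, n = 3)

resp <- drug_response_table(b$auc, b$sample_info)
shifts <- shift_all_drugs(resp, b$truth$target_group, "EGFR_extinction")
select_candidates(shifts, p_cut = 0.1, lfc_cut = 0.2)$sensitive
#> [1] "drug08" "drug07" "drug05" "drug02" "drug01" "drug04" "drug06" "drug03"
```

The cohort plants ten patients per evolution class; the classifier
recovers all thirty patterns exactly. The planted drug-sensitivity shift
(log₂FC −0.5 in the extinction group) surfaces all eight designated
drugs as sensitization candidates.

A thin command-line wrapper over the same functions is installed at
`inst/cli/longipharm.R`:

```sh
Rscript inst/cli/longipharm.R simulate --out cohort/
Rscript inst/cli/longipharm.R evolve --variants cohort/variants.tsv --genes EGFR --out calls/
```

Every CLI run writes a JSON provenance record (config, config hash,
seed, package version).

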