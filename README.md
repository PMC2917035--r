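# pathscore

Dual-platform molecular-signature scoring of PI3K pathway activity in ER+
breast cancer.

The PI3K pathway (PI3K → AKT → mTOR/S6K/S6, antagonized by PTEN) is among the
most frequently deregulated signaling axes in breast cancer, and its
hyperactivity in ER+ tumors is associated with lower estrogen-receptor
output and the aggressive luminal B subtype. `pathscore` implements, as a
tested R pipeline, the quantitative workflow behind that analysis — for
computational biologists who want to derive perturbation signatures, score
cohorts on both expression and RPPA platforms, and reproduce the association
statistics on data with known ground truth.

What it computes:

* **Signature derivation** — per-gene two-sided *t* tests (pooled-variance
  Student by default) on a treated-vs-control log2 expression matrix, with
  Storey q-value FDR control ($\hat\pi_0$ by spline-smoothed λ-tuning);
  genes with *p* < 0.01 and *q* < 0.1 form induced/repressed sets.
* **mRNA activity score** — within each sample, the pooled two-sample *t*
  statistic comparing median-centered expression of the signature's induced
  vs repressed genes; for an inhibition-derived signature the score is −*t*,
  so high score = high inferred pathway activity.
* **Protein activity score** — the signed sum of mean-centered RPPA
  endpoints, score = pAkt + pmTOR + pGSK3 + pS6K + pS6 − PTEN, with an
  explicit policy for combining the two AKT phosphosites.
* **Luminal A/B classification** — mean-centroid Pearson correlation for
  expression profiles; the weighted "luminalness" marker score with a fixed
  cutoff (−0.907) for RPPA profiles.
* **Association statistics** — tie-aware Spearman correlation of scores with
  ER/PR levels (exact permutation p below n = 10), luminal B vs A score
  comparison, cross-platform concordance.
* **Assay arithmetic** — qPCR relative expression by 2^−ΔΔCt and
  growth-inhibition percentages, with their *t*/ANOVA group tests.
* **Synthetic cohorts** — a generator in which one latent activity variable
  drives signature genes, ER/PR levels, subtype shifts and a matched protein
  panel, providing ground truth for every stage.

## Worked example

Derive a signature from a simulated inhibitor experiment, score a simulated
ER+ tumor cohort, and quantify the score–receptor associations:

```r
library(pathscore)

sim <- simulate_perturbation_experiment(perturbation_config(seed = 101))
sig <- derive_signature(sim$matrix, sim$treated, sim$control)
sig
#> Gene signature: signature
#>   induced:   130 genes
#>   repressed: 135 genes
#>   derivation meaning: inhibition (high activity = anticorrelated with signature)
#>   per-gene stats for 10000 genes attached

co     <- simulate_tumor_cohort(cohort_config(seed = 1), sig)
scores <- score_cohort_activity(co$matrix, sig)
scores
#> Activity scores: 400 samples ( mrna platform )
#>   centering: median
#>   score range: [-26.665, 32.780], median -1.026

report <- association_report(scores, co$annotations)
print(report, digits = 3)
#>       analysis   n estimate statistic  p_value                           note
#> 1     score~ER 400   -0.263        NA 9.88e-08 average ranks; t approximation
#> 2     score~PR 400   -0.249        NA 4.54e-07 average ranks; t approximation
#> 3 lumB_vs_lumA 400    9.713       -11 1.06e-24                    lumB higher
```

Reading the output: of 10,000 simulated genes, 265 pass the conjunctive
*p*/*q* thresholds and split into induced/repressed sets by the sign of the
treated−control difference. Scoring the 400-tumor cohort with that signature
recovers the planted structure: activity scores correlate negatively with ER
(Spearman ρ = −0.26) and PR (ρ = −0.25), and luminal B tumors score on
average 9.7 *t*-units higher than luminal A (pooled *t* = 11, p ≈ 1e-24) —
the qualitative pattern the scoring method was designed to expose in real
ER+ cohorts.

A matched protein panel sharing the cohort's latent activity can be scored
and compared the same way:

```r
rp <- simulate_rppa_cohort(cohort_config(n_tumors = 40, seed = 1),
                           shared_truth = co$truth[1:40, ])
ps <- pi3k_protein_score(rp$matrix)       # pAkt+pmTOR+pGSK3+pS6K+pS6-PTEN
association_report(scores[1:40, ], co$annotations[1:40, ], scores2 = ps)
```

A thin command-line front end over the same functions ships in
`inst/cli/pathscore.R` (subcommands `simulate`, `derive-signature`,
`score-mrna`, `score-protein`, `classify`, `associate`, `assay`).

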