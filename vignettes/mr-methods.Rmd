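---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The estimation problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. Because alleles are randomized at conception, a variant
that (i) is robustly associated with the exposure, (ii) shares no common
cause with the outcome, and (iii) affects the outcome only through the
exposure supports an unconfounded causal contrast. In the *two-sample*
design the instrument–exposure and instrument–outcome associations come
from different GWAS samples, so the entire analysis consumes only published
per-SNP summary statistics: effect sizes on the log-odds scale with their
standard errors.

mrpipe implements this design end to end for case–control exposure and
outcome traits — the motivating application is estimating the effect of
genetic liability to schizophrenia on breast cancer risk, overall and by
estrogen-receptor status — but nothing in the code is specific to those
traits.

## Model and estimators

Write $\gamma_i$ for the effect of SNP $i$ on the exposure and $\beta_i$
for its effect on the outcome, with standard error
$\operatorname{se}(\beta_i)$. Under the exclusion restriction all SNPs
share one proportionality constant $\alpha$, the causal log-odds effect:
$\beta_i = \alpha\,\gamma_i$.

**Wald ratio.** Each SNP alone estimates
$\hat\alpha_i = \beta_i/\gamma_i$ with first-order variance
$v_i = (\operatorname{se}(\beta_i)/\gamma_i)^2$. The exposure standard
error does not enter this approximation; it presumes instrument effects
measured essentially without error (the "NOME" condition), which holds
well for genome-wide-significant instruments from very large GWAS.

**IVW.** With weights $w_i = 1/v_i$, the inverse-variance-weighted
estimate is $\hat\alpha = \sum_i w_i \hat\alpha_i / \sum_i w_i$ with
fixed-effect standard error $(\sum_i w_i)^{-1/2}$ — equivalently a
weighted regression of $\beta_i$ on $\gamma_i$ through the origin.
`mr_fit(..., method = "ivw_random")` applies the multiplicative
random-effects correction used by the standard two-sample MR software:
the fixed-effect SE is inflated by $\max(1, \sqrt{Q/(n-1)})$, where $Q$
is Cochran's statistic below. The point estimate is unchanged; the SE
never shrinks below the fixed-effect value under under-dispersion. The
literal fixed-effect formula remains available as `method = "ivw_fixed"`.
The two flavors in the literature (multiplicative vs additive
DerSimonian–Laird) differ slightly in how they spread the extra
heterogeneity; we implement the multiplicative form and report any
residual discrepancy with other software as observed rather than
reconciling it.

**Heterogeneity.** $Q = \sum_i w_i (\hat\alpha_i - \hat\alpha)^2$ is
referred to $\chi^2_{n-1}$, and $I^2 = \max(0, (Q - \mathrm{df})/Q)
\times 100$ summarizes the share of variation in the ratio estimates
beyond sampling noise. Large $Q$ signals violations of the one-slope
model, most commonly horizontal pleiotropy.

**Weighted median.** Ordering the ratios $\hat\alpha_{(1)} \le \dots \le
\hat\alpha_{(n)}$ with normalized weights, the estimate interpolates the
ordered ratios at standardized cumulative weight
$s_j = (\sum_{k \le j} w_k - w_j/2)/\sum_k w_k = 0.5$. It is consistent
when valid instruments carry at least half the total weight, so it
tolerates up to 50% invalid instruments. Its SE comes from a parametric
bootstrap (default 1000 replicates): $\gamma_i$ and $\beta_i$ are redrawn
from normal distributions at the observed values and SEs and the estimate
recomputed; a seed is mandatory so results are exactly reproducible.

Confidence intervals use the 1.96 normal multiplier throughout (not a
*t* quantile — conventional in summary-data MR at instrument counts in
the tens to hundreds), and p-values are two-sided normal. Odds ratios are
`exp(alpha)`; displays round ORs to 2 decimals and p-values to 2
significant figures.

## Harmonization rules

Summary tables from different consortia disagree on which allele is the
"effect" allele and occasionally on strand. `harmonize()` applies, in
order: (1) orient every exposure record so $\gamma_i \ge 0$ (the effect
allele becomes the exposure-risk-increasing allele; estimators are
nevertheless invariant to joint sign flips, which the tests check);
(2) align each outcome record to the exposure alleles, negating $\beta_i$
when the pair is swapped; (3) try the strand complement (A↔T, C↔G) before
declaring an allele mismatch; (4) treat palindromic variants (A/T, C/G)
specially, since labels cannot resolve their strand. The default policy
`infer_by_eaf` orients them by comparing effect-allele frequencies to 0.5
on both sides and drops those with either frequency inside 0.42–0.58
(window configurable, half-width 0.08) or missing — the common practice in
two-sample MR pipelines; `drop_ambiguous` and `keep` are available.
Indels and multi-allelic records are rejected at read time. Every
exclusion carries a reason and survives into the pipeline's audit log.

## Instrument selection

* **Significance:** `filter_by_pvalue()` keeps `p < 5e-8` (strict
  inequality, the genome-wide convention).
* **LD pruning:** `ld_prune()` is greedy by p-value: take the most
  significant remaining SNP, drop everything with $r^2$ above the
  threshold (default 0.1) against it, repeat. Ties on p break
  lexicographically by rsID so results are platform-independent. The
  postcondition — no retained pair above threshold — is re-verified
  exhaustively on every call. Position-windowed clumping is deliberately
  not implemented; the $r^2$ matrix comes from `compute_ld_r2()` on a
  reference dosage matrix (squared Pearson correlation) or from a file.
* **Imputation quality:** `filter_by_info()` removes instruments with
  info strictly below the cutoff (default 0.8); the boundary value is
  kept by default because the conventions "remove < 0.8" and "keep > 0.8"
  disagree only there, and the inclusive reading retains data. Missing
  scores are retained with a log entry (configurable).

## Pleiotropy exclusion (MR-PRESSO style)

`mr_presso()` detects instruments whose outcome effects are inconsistent
with a single causal slope. The observed statistic is the weighted
residual sum of squares around leave-one-out fixed-effect IVW estimates,
$\mathrm{RSS} = \sum_i w_i(\beta_i - \hat\alpha_{(-i)}\gamma_i)^2$; its
null distribution is built by parametric simulation
($\gamma^*_i \sim N(\gamma_i, \operatorname{se}(\gamma_i))$,
$\beta^*_i \sim N(\hat\alpha_{(-i)}\gamma_i, \operatorname{se}(\beta_i))$,
leave-one-out estimates recomputed per simulated dataset). Empirical
p-values carry the add-one correction, so they are bounded below by
$1/(n_{\mathrm{sim}}+1)$ and never zero. Per-SNP residuals are compared
with their own simulated nulls and flagged at the Bonferroni threshold
$0.05/n$; the default $n_{\mathrm{sim}} = 5000$ exists precisely so the
empirical floor resolves thresholds near $0.05/176 \approx 2.8\times
10^{-4}$ — with only 1000 simulations the floor $1/1001$ exceeds the
Bonferroni cutoff at $n > 50$ and nothing can ever be flagged. The
distortion test compares the estimate shift after removing flagged SNPs
with removals of random same-size subsets of the *non-flagged* SNPs
(two-sided empirical p). In the pipeline the exclusion list is computed
once on the first (overall) outcome stratum and applied to every stratum,
mirroring the single pre-analysis exclusion list of the motivating study;
per-stratum testing sits behind `presso$per_stratum`.

A sharpness caveat, verified by simulation during development: a gross
outlier contaminates the leave-one-out estimates of the *clean* SNPs by
roughly $0.2\,\operatorname{se}(\beta)$ at $n \approx 50$, so the
per-family false-flag probability sits a little above the nominal
Bonferroni level (≈3–5% per run in our planted-outlier experiments).
This is a property of the published construction, not of this
implementation.

## The synthetic-data generator

`simulate_mr_data()` generates both summary tables plus a truth table so
every stage is testable without consortium data. Defaults were fixed once
to emulate the motivating study's regime and are not tuning knobs:

* 170 instruments; causal effect `true_alpha = 0.04` (log-odds; OR 1.04);
* instrument strengths $|N(0.09, 0.025)|$ with exposure SE 0.01 — the
  scale of a ~10⁵-sample case–control exposure GWAS (mean instrument
  F ≈ 80);
* outcome SE 0.008, the scale of a ~2×10⁵-sample outcome GWAS; per-SNP
  Wald SEs land around 0.02–0.1;
* balanced pleiotropy $N(0, 0.007)$ by default, calibrated analytically
  (extra $Q \approx n\,\sigma_p^2/\operatorname{se}(\beta)^2$) so
  expected $I^2$ is in the 40–50% band reported for the real instrument
  panel; directional pleiotropy and a configurable fraction of gross
  outliers (`outlier_shift` in units of the outcome SE) provide the
  violations the robust estimators and PRESSO are meant to handle;
* info scores skewed toward 1 (Beta(1,7) from the top of the support) so
  a few percent of instruments fall below the conventional 0.8 cutoff,
  as in well-imputed panels;
* allele pairs exclude palindromes by default so that harmonization of
  simulated data is lossless and stage counts are exact; palindrome
  handling is exercised on hand-built records in the tests.

What the generator does **not** emulate: logistic/liability-scale
generation of the binary traits (summary statistics are drawn directly on
the log-odds scale, because every downstream computation consumes only
(beta, SE) pairs), winner's-curse selection of instruments in the
discovery GWAS, sample overlap between the two GWAS, and LD among the
instruments themselves (LD enters only through `simulate_ld_block()`,
which builds haplotype Markov chains with adjacent-pair $r^2$ equal to a
target for testing the pruner). Consequently, passing recovery tests here
demonstrates correctness of the estimators under the stated generative
model — not robustness to those additional features of real data. Note
also that the generator does not truncate instrument strength at the
significance threshold, so the pipeline's `p < 5e-8` stage trims the
weakest few simulated instruments; a real instrument table arrives
pre-selected.

Two regimes are used deliberately in the validation experiments: the
parameter-recovery and coverage experiments set the exposure SE to 0.001
so the NOME condition behind the first-order weights holds and the
experiment isolates estimator error; at the realistic default SE (0.01)
the known regression-dilution of ratio estimators appears — about 0.5–1%
of the effect size here — and a dedicated test documents that it stays
below 2%. Neither number is hidden in the other's experiment.

## Numerical and degenerate-input choices

* $\gamma_i = 0$ is a hard error ("undefined ratio"), not a silent drop;
  upstream significance filtering makes it unreachable on real data.
* A single instrument: IVW collapses to the Wald ratio; random-effects
  mode falls back to fixed with a message; $Q$ is guarded (requires
  $n \ge 2$); the weighted median requires $n \ge 3$.
* Bootstrap draws that land exactly on $\gamma^* = 0$ are nudged by the
  machine epsilon.
* All Monte-Carlo procedures require explicit integer seeds and are
  bit-reproducible given them; the pipeline's outputs are byte-identical
  across reruns of one configuration.
* Problem sizes in the shipped test-suite experiments (1000 oracle
  comparisons, 1000 recovery replicates, 500 robustness replicates, 100
  planted-outlier runs at 5000 simulations each) were chosen so the whole
  suite completes in well under a minute on one core while keeping
  Monte-Carlo error far below every asserted margin.

## Known limitations

Beyond the generator's non-goals above: no MR-Egger, mode-based or
multivariable estimators (the motivating analysis used IVW and the
weighted median only); no Steiger filtering; no proxy-SNP lookup,
liftover or GWAS-VCF input; binary-exposure non-collapsibility means the
causal odds ratio should be read as an average association of genetically
predicted liability rather than a literal intervention effect.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_mr_data(n_snps = 176, true_alpha = log(1.04),
                        outlier_fraction = 6 / 176, seed = 11)
paths <- write_mr_sim(sim, tempdir())
report <- mr_pipeline(list(
  exposure_path = unname(paths["exposure"]),
  outcome_paths = list(overall = unname(paths["outcome"])),
  min_info = 0.8,
  presso = list(n_sim = 5000, seed = 12),
  estimator = list(n_boot = 1000, seed = 13)))
print(report)
```
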