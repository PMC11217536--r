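---
title: "Methods: two-sample Mendelian randomization in mrscreen"
author: "mrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from two independent sets of GWAS summary
statistics. For each genetic variant $j$ we observe the estimated effect on
the exposure $\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$ and the
effect on the outcome $\hat\beta_{Yj}$ (log-odds for a binary outcome) with
standard error $\sigma_{Yj}$. A variant is a valid instrument when it (i) is
associated with the exposure, (ii) shares no confounder with the
exposure–outcome relation, and (iii) affects the outcome only through the
exposure. Under these assumptions each variant supplies a Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ estimating the common
causal effect $\theta$.

`mrscreen` was built for screens of the kind used in microbiome
epidemiology: abundances of ~200 bacterial taxa (exposures measured in a
GWAS meta-analysis of 18,340 participants) screened against a rare binary
disease outcome (1,076 cases, 381,977 controls). Those cohort sizes drive
every default in the synthetic-data generator, and the pipeline mirrors the
screening workflow: instrument selection, harmonization, estimation,
sensitivity analysis, and a significant-trait subtable.

## Instrument selection

* **P-value filter.** Variants with exposure association $p < 10^{-5}$ are
  retained (`filter_by_pvalue`), the suggestive threshold typically used
  when genome-wide significant hits are too few per taxon. The comparison
  is strict, so a variant at exactly the threshold is excluded.
* **LD clumping.** `clump` is a greedy pruner: visit variants by ascending
  p-value (ties broken by chromosome, position, variant id, so the result
  does not depend on input order) and discard every undecided variant on
  the same chromosome within 10,000 kb whose $r^2$ with the retained
  variant exceeds 0.001. LD is supplied as a long-format table; absent
  pairs count as $r^2 = 0$, which matches reference-panel exports that omit
  pairs below a reporting floor.
* **Instrument strength.** For each variant,
  $R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ and
  $F = R^2 (n - k - 1) / (k (1 - R^2))$. `instrument_strength` reports the
  per-variant form ($k = 1$), the conventional weak-instrument screen with
  the $F > 10$ rule of thumb; `instrument_strength_aggregate` reports the
  model-level form with $k$ equal to the instrument count. Both are
  provided because the formula is used both ways in applied work; the
  pipeline records the per-variant minimum and applies $F > 10$ as a
  report-only flag by default (`apply_f_filter = TRUE` makes it a hard
  exclusion).

## Harmonization

`harmonize_pair` aligns outcome effects to the exposure's effect allele.
Swapped alleles negate the outcome beta (and reflect its allele
frequency); alleles reported on the opposite strand are rescued by
complementing, and the rescue is logged distinctly so users can audit it.
Palindromic variants (A/T, C/G) are dropped unconditionally — their strand
cannot be resolved across cohorts without frequency heuristics, and the
screening design favors fidelity over data retention. The per-variant
action log partitions the input exactly; `harmonization_report` tallies it.

## Estimators

All estimators consume the harmonized arrays and emit the estimate with
standard error, odds ratio, 95% CI, and a two-sided normal p-value.

* **IVW** (primary): the precision-weighted mean of Wald ratios with
  weights $w_j = \hat\beta_{Xj}^2 / \sigma_{Yj}^2$, algebraically the
  weighted least-squares slope of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin. The fixed-effect standard error is $(\sum_j w_j)^{-1/2}$;
  when Cochran's Q signals heterogeneity ($p < 0.05$) the pipeline's
  `auto` mode switches to a multiplicative random-effects model that
  inflates the standard error by $\max(1, \sqrt{Q/(J-1)})$. The selected
  branch is recorded in the output, since the point estimate is identical
  under both.
* **MR-Egger**: weighted regression with an unconstrained intercept after
  orienting each variant so $\hat\beta_{Xj} \ge 0$. The intercept estimates
  the average directional pleiotropic effect; intercept $p < 0.05$ flags
  horizontal pleiotropy. Standard errors use multiplicative
  overdispersion with the residual scale floored at 1 (df $J-2$).
* **Weighted median**: the median of the ratio estimates under normalized
  IVW weights, interpolating the cumulative midpoint percentiles
  $p_j = (S_j - w_j/2)/S_J$ at 0.5; consistent while valid instruments
  carry more than half the weight. Its standard error is the standard
  deviation over parametric-bootstrap replicates (default 1000, seeded;
  the caller's RNG state is untouched).
* **Maximum likelihood**: the joint normal model
  $\hat\beta_{Xj} \sim N(\xi_j, \sigma_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\theta \xi_j, \sigma_{Yj}^2)$, maximized by BFGS
  with an analytic gradient (relative tolerance $10^{-10}$), initialized
  at the IVW estimate and the observed exposure effects. Unlike IVW it
  models the exposure measurement error. The standard error comes from
  the observed information; because the information matrix is an
  arrow matrix (one $\theta$ row bordering a diagonal $\xi$ block), the
  $\theta$ variance is computed from the Schur complement in $O(J)$, which
  stays numerically stable even as $\sigma_{Xj} \to 0$.

P-values are normal for all methods for consistency with the OR/CI
construction; MR-Egger can use $t_{J-2}$ p-values via `use_t = TRUE`.
A single instrument is accepted by IVW (collapsing to the Wald ratio, with
a warning) so a catalog-wide screen never hard-fails on a sparse taxon.

## Sensitivity diagnostics

* **Cochran's Q** with $J-1$ degrees of freedom; $p < 0.05$ selects the
  random-effects IVW branch.
* **MR-PRESSO**: the observed residual sum of squares
  $\sum_j w_j(\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$ uses
  leave-one-out IVW estimates; its null distribution is simulated by
  redrawing effects from their reported sampling distributions (default
  1000 replicates, seed 42). Monte-Carlo p-values use the add-one
  estimator $(b+1)/(m+1)$, so they are never zero and never below
  $1/(m+1)$. Per-variant outlier p-values are Bonferroni-multiplied by
  $J$; the distortion test compares the raw-vs-corrected shift against
  shifts from removing 1000 random subsets of the same size. The whole
  procedure is vectorized, so a 20-variant analysis at 1000 replicates
  costs a few milliseconds.
* **Plot data**: `plot_data` tabulates the scatter (effects with error
  bars and per-method fitted lines — through the origin except MR-Egger)
  and funnel (ratio vs precision with the pooled IVW reference); ggplot2
  renderings are available via `mr_scatter_plot` / `mr_funnel_plot`.

## The synthetic-data generator

`simulate_summary_pair` draws true instrument effects
$\gamma_j \sim N(0.1, 0.02^2)$ and observes
$\hat\beta_{Xj} = \gamma_j + \varepsilon_{Xj}$,
$\hat\beta_{Yj} = \theta\gamma_j + \alpha_j + \varepsilon_{Yj}$, where
$\alpha_j$ is the horizontal-pleiotropy effect (zero for valid variants).
Standard errors are calibrated to the target cohorts:
$\sigma_X = 1/\sqrt{2p(1-p)\,n}$ for a standardized quantitative exposure
with $n = 18{,}340$ and $\sigma_Y = 1/\sqrt{2p(1-p)\,n_\mathrm{eff}}$ with
$n_\mathrm{eff} = 4/(1/1{,}076 + 1/381{,}977) \approx 4{,}292$ for the
binary outcome, with allele frequencies $p \sim U(0.05, 0.95)$. The
$\gamma$ distribution was chosen so per-variant F-statistics span roughly
20–140 (mean ≈ 70) at these cohort sizes — the range reported for
suggestive-threshold microbiome instruments. Pleiotropy can be balanced or
directional (`alpha_mean`), and `inside_correlation` links $\alpha_j$ to
instrument strength to violate the InSIDE assumption. Palindromic allele
pairs, LD blocks (within-block $r^2$ constant, blocks 20 Mb apart so they
never share a clumping window), and unnamed-taxon catalog entries are all
plantable, and every draw is bookkept in a truth object that tests check
against rather than regenerate.

What the generator does **not** emulate: winner's curse from selecting
instruments in the same sample (effects are drawn, then filtered), sample
overlap between cohorts, non-normal effect distributions, real LD decay,
and compositional correlation among taxa. Passing tests therefore show the
estimators behave correctly under the stated sampling model, not that any
particular real-data finding is correct.

## Numerical choices and degenerate inputs

* P-values of exactly 0 on input are floored to the smallest positive
  double (with a warning) so log transforms are defined.
* Non-SNV alleles are dropped on read with a warning count; the
  harmonization rules are defined for single-nucleotide variants only.
* Self-pairs in the LD table are ignored; `lookup(a, a)` is 1 by
  construction, and duplicate pairs collapse to the last value.
* A zero exposure effect makes the Wald ratio undefined and raises a
  degenerate-instrument error rather than returning infinity.
* Clumping ties in p-value break by (chromosome, position, variant id) so
  the retained set is order-invariant.
* Monte-Carlo and bootstrap components take explicit seeds and restore the
  caller's RNG state.

## Screening pipeline

`run_screen` removes unnamed taxa (labels containing "unknown",
"unclassified", or "incertae"), runs the per-trait pipeline, and flags
traits with IVW $p < 0.05$. Multiple-testing correction defaults to
**none** — the screen is explicitly hypothesis-generating, and borderline
rows are recorded verbatim for the reader — with Bonferroni and
Benjamini–Hochberg as opt-in flags that adjust the significance flags. The
significant subtable is exactly a post-hoc filter of the full table, with
no hidden criteria. Per-method failures (e.g. too few instruments for
MR-Egger) become recorded error cells, not aborts, and every catalog trait
appears in the output, possibly as a skip row with a reason.

## Test and simulation scale

The validation suite checks oracle equivalences (IVW against weighted
least squares through the origin; MR-Egger against weighted least squares
with intercept, both to $10^{-10}$), single-instrument reductions, and
calibration properties at the following sizes, chosen to give Monte-Carlo
standard errors comfortably below the acceptance bands while keeping the
default test run fast: type-I error at 2000 replicates ($J = 20$),
recovery/coverage at 1000 replicates ($J = 50$, $\theta = 0.5$),
robustness ordering at 500 replicates (30% invalid instruments,
$\alpha_j \sim N(0.02, 0.005^2)$), and MR-PRESSO planted-outlier detection
at 200 replicates of 1000 simulations each.

## Known limitations

* The IVW weights treat $\hat\beta_{Xj}$ as fixed, so with moderately
  strong instruments (mean $F \approx 70$) the estimate carries a small
  regression-dilution bias toward zero (about 1.5% of the effect in the
  default calibration); CI coverage sits slightly below nominal
  (~0.93–0.96) rather than at 0.95.
* The MR-Egger intercept is an unbiased pleiotropy estimate only when
  exposure effects are measured without error or the causal effect is
  null; otherwise slope dilution leaks $\theta\bar\gamma(1-\lambda)$ into
  the intercept, where $\lambda$ is the regression-dilution factor. This
  is a property of the method, not of the implementation — the
  intercept-recovery test is therefore run at $\theta = 0$.
* After MR-PRESSO removes a single gross outlier from $J$ instruments, the
  probability that the corrected estimate lands closer to the truth than
  the raw one is bounded near $\Phi\!\big(a/(2\sqrt{J})\big)$ for an
  outlier of $a$ outcome standard errors (≈0.87 for $a = 10$, $J = 20$,
  and lower under weight heterogeneity): removal eliminates bias but the
  remaining sampling error is shared. Corrected estimates should be judged
  by their bias, not by per-dataset wins.
* Palindromic variants are always discarded; no allele-frequency inference
  is attempted, which loses roughly the A/T+C/G fraction of instruments.
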