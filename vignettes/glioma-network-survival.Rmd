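---
title: "Diagnostic gene networks and prognostic signatures for glioma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic gene networks and prognostic signatures for glioma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`glionet` implements a two-step variable-selection workflow for glioma
transcriptomics, run in parallel under two classification schemes of the
same cohort (a 2016-like scheme in which a subset of diagnoses follows
histology, and a 2021-like scheme fully determined by molecular markers:
IDH mutation and 1p/19q codeletion).

1. **Diagnostic step.** For each glioma type (astrocytoma,
   oligodendroglioma, GBM), a sparse Gaussian graphical model is
   estimated by the graphical lasso. Genes that remain connected in the
   estimated network are *selected*; genes whose connectivity percentile
   exceeds a threshold are *hubs*.
2. **Prognostic step.** The selected gene sets feed an l1-penalized Cox
   proportional-hazards model over all glioma samples, capped by the
   10-events-per-variable rule. The fitted prognostic index stratifies
   patients into high- and low-risk groups at the local minimum of its
   kernel density estimate, and the split is evaluated with Kaplan-Meier
   curves and the log-rank test.

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` are thin drivers over the functions documented here, writing
their tables under `results/`.

# Models and assumptions

## Gaussian graphical model and the graphical lasso

Expression profiles $X = (X_1, \dots, X_p)$ are modelled as multivariate
normal, $X \sim N_p(0, \Sigma)$, with precision matrix
$\Theta = \Sigma^{-1}$. A zero off-diagonal entry $\theta_{ij} = 0$
encodes conditional independence of genes $i$ and $j$ given the rest, so
the support of $\Theta$ is the gene network. `glasso_fit()` maximizes the
penalized log-likelihood

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \rho\,\|\Theta\|_1,$$

with $S$ the empirical covariance (`empirical_covariance()`, $1/n$
normalization) and $\rho \ge 0$ the sparsity penalty. The l1 norm is read
literally over *all* entries, so the diagonal is penalized by default;
connectivity-based selection depends only on off-diagonals, and
`penalize_diag = FALSE` provides the off-diagonal-only variant for
cross-checks. The solver is the classical block coordinate descent over
columns with an inner soft-thresholding lasso solve, written in C++;
convergence is declared when the maximum absolute change of the working
covariance per sweep falls below `1e-5 * mean(|diag(S)|)` (cap 500
sweeps, error on non-convergence with the partial state attached). Inner
soft-thresholding produces exact zeros; the `1e-8` zero tolerance used by
`select_connected()` only guards round-off.

At a high penalty most genes end up unconnected, which is what turns the
network estimate into a variable-selection device. Hub scoring uses two
measures per connected gene: the *weight* $m^w_i = \sum_{j \ne i}
|\theta_{ij}|$ and the *count* $m^c_i$ of nonzero partners. Each measure
is rescaled to percentiles by `percentile_rescale()` — ascending average
ranks mapped to $100 (r_i - 1)/(K - 1)$, the only reading of "uniformly
distributed in [0, 100]" under which the hub threshold $t$ acts as a
percentile — and a gene is a hub when either percentile exceeds $t$
(union of the two subsets). Percentiles are computed over the selected
genes only: ranking the unselected genes, which all tie at zero, would
flatten the scale.

## Preprocessing

The Gaussian assumption is enforced in two steps
(`npn_transform()`, `filter_normal()`):

* **Nonparanormal transform.** Each gene is mapped through its truncated
  empirical CDF and the standard-normal quantile function, with the
  canonical truncation constant
  $\delta_n = 1/(4 n^{1/4} \sqrt{\pi \log n})$, then scaled to unit
  standard deviation. The transform depends only on ranks (ties get
  average ranks), so it is invariant to monotone marginal distortions and
  idempotent up to rescaling. Constant columns are an error, named.
* **Jarque-Bera filter.** Genes whose moment-based JB statistic
  $\frac{n}{6}(s^2 + (k - 3)^2/4)$ has $p \le \alpha$ against
  $\chi^2_2$ are dropped; $\alpha = 0.05$, matching the significance
  convention used elsewhere in the workflow. `alpha = 0` disables the
  filter (p-values can underflow to exactly zero, so the boundary is
  special-cased).

The default order is npn first, then the filter — the filter then
removes genuinely non-Gaussian-shaped genes rather than merely
distorted ones; `run_config(npn_first = FALSE)` swaps the order for
comparison.

## Penalized Cox regression and risk stratification

With survival times $Y_i$ and event indicators $\delta_i$, the Cox model
$h(t \mid x_i) = h_0(t) \exp(x_i^\top \beta)$ is fitted by maximizing the
Breslow partial log-likelihood minus $\lambda \|\beta\|_1$; the baseline
hazard cancels and is never estimated. `cox_lasso_path()` delegates the
path computation to glmnet (100 log-spaced $\lambda$ values from
$\lambda_{\max}$, the smallest all-zero-solution penalty computed from
the null-model score, down to $0.01\,\lambda_{\max}$), standardizing
features before fitting and returning coefficients on the original
scale. `cox_penalized_loglik()` implements the objective directly and is
used to verify the fits against an independent proximal-gradient solver
in the tests. The number of active genes is capped by the 10-EPV rule,
$p_{\max} = \lceil \text{events}/10 \rceil$ (`compute_pmax()`), and
`select_model()` returns the densest path solution not exceeding the cap
(the all-zero model always qualifies; `pmax = 0` returns it with a
warning).

The prognostic index $PI_i = x_i^\top \hat\beta$ is thresholded by
`kde_threshold()`: a Gaussian KDE with the rule-of-thumb bandwidth
$0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.34)\, n^{-1/5}$ on a 512-point grid
spanning the data ± 3 bandwidths. When the density is genuinely bimodal
the threshold is the argmin between the two highest local maxima — the
median split is wrong for imbalanced bimodal PI distributions, which is
exactly the situation this workflow targets; otherwise the median is the
fallback. "Genuinely bimodal" is operationalized with two guards chosen
to be robust to the minor spurious maxima kernel estimates produce:
local maxima below 25% of the highest peak are ignored, and the valley
must dip below 90% of the lower peak. On clean Gaussian samples these
guards reduce false bimodal splits from roughly a third of samples to
below 1%, while even a 1:3 mixture of well-separated components is
always split at the valley. Samples with $PI \le \widehat{PI}$ are
low-risk (the boundary is low-risk), the rest high-risk; groups are
compared with the Kaplan-Meier estimator and the two-group log-rank test
at significance level 0.05 (both via the survival package).

## Case datasets and scheme comparison

The survival step runs on three nested Pan-Glioma case datasets per
scheme (`build_case_dataset()`): case 1 pools every per-type selected
gene, case 2 the per-type exclusives (selected for exactly one type),
case 3 the hubs pooled over the three types (paralleling the pooling of
cases 1-2). Case 2 and 3 genes are contained in case 1 by construction,
and the invariant is asserted end to end in the tests. Risk-group
composition is cross-tabulated against glioma types
(`tabulate_stratification()`; percentages are stored exact and printed
either one-decimal or integer via `format_pct()`, as both conventions
appear in practice), and `stability_overlap()` measures how consistently
samples keep their risk label across the cases.

# The synthetic cohort generator

No real TCGA data ships with the package; `simulate_cohort()` generates
a cohort with the statistical structure the analysis assumes, plus
ground truth for recovery tests.

* **Networks.** Per-type precision matrices are block-diagonal with unit
  diagonal: fully connected blocks of constant partial correlation
  (default magnitude 0.2), genes outside blocks isolated. The sign of
  the precision entries is negative (positive partial correlations — a
  co-activated module) whenever positive definiteness allows, i.e. for
  magnitudes below $1/(b-1)$ for a $b$-gene block; otherwise positive.
  This choice matters: with negative entries a 5-gene block at magnitude
  0.2 yields marginal correlations of 0.5, emulating the strong
  co-expression modules of real transcriptomes, whereas equicorrelated
  blocks with positive entries cap marginal correlations near
  $1/(b-1)$ however strong the partial correlations. The three types
  share block positions but rotate activity (block 1 shared by all,
  blocks 2-4 exclusive to one type each, and so on), so shared and
  exclusive selection sets are nontrivial by construction.
* **Expression.** Each type's samples are drawn from the zero-mean
  multivariate normal with covariance $\Theta^{-1}$; a seeded fraction
  (default 30%) of gene columns is then passed through `exp()` — a
  monotone, rank-preserving distortion that the nonparanormal transform
  can undo, which lets the tests separate the JB-filter path from the
  npn path.
* **Labels.** Molecular flags follow each sample's generating type;
  scheme-B (2021-like) labels are deterministic from the flags
  (IDH-mutant + codeletion → oligodendroglioma, IDH-mutant without →
  astrocytoma, IDH-wildtype → GBM). A seeded fraction (default 15%) of
  samples gets a discordant histology flag, and their scheme-A
  (2016-like) label follows histology instead.
* **Survival.** Event times are exponential with rate
  $h_0 \exp(x_i^\top \beta^\ast)$ (exponential baseline, the simplest
  proportional-hazards-compatible choice; the baseline cancels in the
  partial likelihood anyway), where $\beta^\ast$ has `n_prognostic`
  nonzeros (default 5) of magnitude `effect_size` (default 0.5) with
  alternating signs. The true prognostic genes are spread across shared
  and type-exclusive blocks so every case dataset contains part of the
  signal. Censoring times are Uniform$(0, c)$ with $c$ solved
  numerically so the expected censoring fraction hits `censor_rate`
  (default 0.3) — transparent and monotone in $c$. Survival is generated
  from the latent Gaussian expression, the scale the analysis recovers
  after gaussianization.

Each generator stage derives a sub-seed from the configuration seed, so
a fixed seed reproduces the cohort bit for bit.

**What the generator does not emulate:** RNA-seq count noise,
library-size and batch effects, mean expression shifts between types
(all types are zero-mean, so risk-group/type cross-tabulations are
near-uniform by construction, unlike the GBM-dominated high-risk groups
of real glioma cohorts), and effect sizes calibrated to TCGA. Passing
tests therefore show that the procedure recovers the structures it
assumes, not that it would perform identically on real data.

# Parameter defaults

| Parameter | Default | Role |
|---|---|---|
| `rho` (`glasso_fit`) | 0.9 | penalty used on full-transcriptome glioma data, where co-expression correlations approach 1 |
| `rho` (`run_config`) | 0.35 | matched to the synthetic cohort's correlation scale (block correlations 0.5, noise correlations below ~0.35 at $n = 150$/type); 0.9 would select nothing at desk scale |
| `hub_t` | 60 | hub percentile threshold; the value at which a GBM-style ranking splits into two clearly separated groups |
| `jb_alpha` | 0.05 | JB significance level |
| `nlambda`, `lambda_min_ratio` | 100, 0.01 | standard Cox path grid |
| `peak_frac`, `valley_frac` | 0.25, 0.9 | KDE bimodality guards (see above) |
| generator defaults | 150/type, $p = 120$, 12 blocks of 5, partial corr 0.2, 5 prognostic genes at 0.5, censoring 0.3, distortion 0.3, discordance 0.15 | the package's standing study conditions |

# Numerical choices and degenerate inputs

* Graphical-lasso convergence `1e-5 * mean(|diag S|)` (tighter
  tolerances are passed in oracle-comparison tests); exact zeros from
  soft-thresholding; symmetry enforced by averaging the two columnwise
  solves, keeping an entry zero only when both solves agree.
* Breslow convention for tied event times throughout (partial
  likelihood, glmnet, `coxph` cross-checks).
* Ranks use average ties everywhere (npn, percentiles).
* Errors on: constant columns (npn, KDE), empty filter output, zero
  events, empty case gene sets (named by pipeline stage), non-positive-
  definite precision constructions (with the advice to lower
  `partial_corr`), mismatched gene names in `prognostic_index()`.
* `stratify()` assigns the exact threshold value to the low-risk group.

# Test and verification design

Every solver is checked against an independent route: the graphical
lasso against a FISTA proximal-gradient solver (objective agreement to
1e-6 on random $p \le 6$ instances), closed forms for diagonal $S$ and
the 2x2 no-edge condition $|s_{12}| \le \rho$; the penalized Cox fits
against a proximal-gradient oracle, `coxph` at $\lambda = 0$, and a
direct-summation partial likelihood; the log-rank statistic against the
O/E/V formula. Recovery studies run at desk scale: graphical-lasso
selection F1 on $n = 800$, $p = 60$ block data (20 seeds, median 1.0 at
the best grid $\rho$), prognostic-gene recovery on $n = 600$ cohorts
under the EPV cap (20 seeds), log-rank null calibration over 500
simulations, and the pipeline smoke/determinism runs use 48-60 gene
cohorts. These sizes were chosen so the whole suite exercises every
claim in seconds while leaving the asymptotic regime to the
full-transcriptome setting.

# Known limitations

* The graphical lasso is fitted per type without sample-size weighting;
  types with few samples get noisier networks (as in the real study).
* $\rho$ is a fixed input, not tuned by stability selection or an
  information criterion — the selection is meant to be interpretable,
  not optimal.
* The KDE split assumes at most two risk populations; more modes fall
  back to the two highest peaks.
* Percentile hub scoring over selected genes makes hub sets sensitive
  to the selection size; with saturated selections (as on the default
  synthetic cohort, where both schemes select exactly the active block
  genes) hub rankings, not selections, carry the scheme differences.
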