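---
title: "Randomized functional-link networks and imputation benchmarking for incomplete clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized functional-link networks and imputation benchmarking for incomplete clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrvfl)
```

## The problem

Staging early cognitive impairment — separating cognitively normal (CN)
participants from those with mild cognitive impairment (MCI) — from a
baseline clinical table is hard for two reasons: the class signal is
spread across heterogeneous modalities (demographics, genotype, clinical
and cognitive assessments, CSF chemistry, structural MRI volumetry, and
PET uptake ratios), and those modalities are missing in large,
class-dependent blocks. Amyloid-PET, for example, can be absent for
essentially every CN participant. Discarding incomplete records throws
away most of such a cohort, so the practical question this package
addresses is: *which single-imputation strategy, combined with which
classifier, best survives this missingness structure?*

The package provides every stage as a testable unit: a synthetic cohort
generator with controllable class structure and block missingness,
fit-on-train imputation, one-hot/z-score encoding, three randomized
functional-link classifiers solved in closed form, a repeated stratified
holdout protocol, and rank-based statistical comparison.

## The classifiers

A random vector functional link network (RVFL) is a single-hidden-layer
network whose hidden ("enhancement") weights $w_j$ and biases $b_j$ are
drawn once from uniform distributions — here $w \sim U[-1,1]$,
$b \sim U[0,1]$ — and never trained. With activation $g$ (ReLU by
default) the prediction is

$$\hat y_i = \sum_{j=1}^{h} \beta_j\, g(w_j x_i + b_j)
          + \sum_{j=h+1}^{h+n} \beta_j\, x_{i},$$

the second sum being the *direct links* from the $n$ input features to
the output. Collecting hidden activations and inputs row-wise into
$H = [\,g(XW + \mathbf{1}b^\top)\; X\,]$, the only learned parameters
are the output weights

$$\beta = \arg\min_\beta \tfrac12\lVert H\beta - Y\rVert^2
        + \tfrac{\eta}{2}\lVert\beta\rVert^2
 = \begin{cases}
 (H^\top H + \eta I)^{-1} H^\top Y, & h+n \le N,\\[2pt]
 H^\top (H H^\top + \eta I)^{-1} Y, & N < h+n,
 \end{cases}$$

with the primal/dual branch chosen by shape (the two forms are
algebraically identical; the test suite checks their agreement to
$10^{-8}$ on random systems). At $\eta = 0$ a singular system falls back
to the Moore–Penrose pseudo-inverse with a warning.

Two deep variants stack $L$ random layers:

* **Stacked deep network (`drvfl`)** — layer $\ell > 1$ transforms only
  the previous activations, $H^{(\ell)} = g(H^{(\ell-1)} W^{(\ell)})$,
  and a single solve is done on the concatenation
  $D = [H^{(1)} \cdots H^{(L)}\, X]$.
* **Deep ensemble (`edrvfl`)** — layer $\ell > 1$ sees the previous
  activations *and* the raw features,
  $H^{(\ell)} = g([H^{(\ell-1)}\, X] W^{(\ell)})$, and every layer is a
  base classifier solved on $[H^{(\ell)}\, X]$. Predictions aggregate by
  score averaging (default) or majority vote; vote ties resolve to the
  MCI label, which is the cautious direction for a screening task.

Although the stacked update equations are usually written without bias
terms, the single-layer definition includes them and the sampling range
for biases is part of the reference configuration, so biases are
included in every layer here. With $L=1$ all three variants coincide
exactly — a degeneracy the tests assert prediction-for-prediction.

Randomness is controlled by a single integer seed per model; one
independent stream per layer is derived from it, so `fit + predict` is a
pure function of `(X, y, config)`.

## The synthetic cohort generator

Because the motivating cohort is registration-gated, the package ships a
generator rather than data. Its defaults *are* the study conditions: 503
participants (124 CN / 379 MCI), 44 real-valued feature columns
(everyday-cognition ECog as a 14-vector, ADAS-Cog as a 3-vector, RAVLT
as a 4-vector, the rest scalars) and categoricals one-hot-expanding to
29 columns, for an encoded width of 73.

The reference accounting never itemizes the 29 one-hot columns; the
listed categories (gender 2, ethnicity 2, race 6, marital status 4,
APOE4 allele count 3) sum to 17. Education is listed among the *missing
categorical variables*, so it is modelled as a categorical with 12
year-levels (9–20 completed years, discretized from the per-class
normal summaries), which closes the gap; the level count is a single
schema knob and no particular decomposition is treated as authoritative.

Variables with published per-class baseline summaries (age, education,
APOE4, CDR sum-of-boxes, MMSE) use those means/SDs/allele frequencies as
generation parameters. All other parameters are package defaults chosen
to be realistic for an elderly memory-clinic population (e.g. CSF
amyloid-beta ≈ 1100 ± 440 pg/ml in CN, hippocampal volume ≈ 7400 ± 900
mm³, FDG SUVR ≈ 1.31 ± 0.12).

Per participant a latent severity score $s \sim N(0,1)$ is drawn, and a
numeric element with per-class mean $\mu$, SD $\sigma$ and loading
$\lambda \in [0,1]$ is generated as

$$x = \mu + \sigma\big(\lambda s + \sqrt{1-\lambda^2}\,\varepsilon\big),
\qquad \varepsilon \sim N(0,1),$$

so per-class means and SDs match the schema *exactly* while loaded
variables co-vary within class. For variables without reference
summaries the MCI mean is displaced from the CN mean by
$\pm\,\lambda \cdot w \cdot \sigma$ along the clinically sensible
direction (cognitive scores down, pathology markers up), where the
severity weight $w = 2$ by default. No generative model accompanies the reference summaries of
these data; a single shared factor is the minimal structure that makes
features jointly informative of the label, which is what a
classifier-comparison experiment needs. The generator deliberately does
**not** attempt richer inter-feature correlation, longitudinal
follow-up, non-Gaussian shapes, or informative (non-MCAR) missingness —
so a pipeline that performs well here demonstrates correctness of the
machinery, not clinical performance on real data.

Missingness is stamped on afterwards, missing-completely-at-random
within (modality, class) blocks at the published per-modality rates
(`table4_missingness()`), up to 100% for amyloid PET in CN. Whether
cells drop independently (`per_cell`, default) or whole modality blocks
drop jointly (`per_block`) is configurable, since the reference rates
are modality-level percentages and do not say which; both are tested.

## Imputation

Categorical gaps always take the training mode (equal weights over
non-missing training values; ties break lexicographically for
determinism). Six numeric strategies are available: zero, mean, median,
Winsorized mean, k-nearest-neighbour, and multivariate-normal EM.

* **Winsorized mean** uses the symmetric count-based definition: with
  $m = \lfloor \alpha n \rfloor$, the $m$ smallest values are replaced
  by the $(m{+}1)$-th smallest and the $m$ largest by the $(m{+}1)$-th
  largest before averaging; $\alpha = 10\%$ by default.
* **KNN** fills a gap with the mean of the $k = 5$ nearest training
  rows under the partial Euclidean distance
  $d^2 = \frac{p}{|S|}\sum_{j \in S}(x_j - t_j)^2$ over the mutually
  observed coordinates $S$; only rows observed in the target column are
  candidates; distance ties resolve by training-row order. A query row
  with no observed numeric cell falls back to column means (logged, not
  an error). The reference protocol fixes neither $k$ nor the
  distance convention; $k=5$ and the scaled partial distance are the
  standard defaults.
* **EM** fits a multivariate normal $(\mu, \Sigma)$ by
  expectation–maximization on the observed data and imputes each row's
  missing block with its conditional mean
  $\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(x_o - \mu_o)$. The distributional
  family and stopping rule are left open by the reference protocol; the classical
  multivariate-normal formulation is assumed, stopping when the
  observed-data log-likelihood changes by less than `em_tol` ($10^{-6}$)
  or after `em_max_iter` (200) iterations. Columns are standardized
  internally (EM is exactly equivariant under per-column scaling) so the
  covariance ridge (`em_ridge`, $10^{-6}$ on the diagonal) acts relative
  to each column's variance — necessary because some modalities can be
  nearly 100% missing in one class, making $\Sigma$ near-singular. Under
  the default block-missingness the likelihood is still climbing
  slowly at the iteration cap (the amyloid-PET columns carry extreme
  missing-information fractions), which is the intended behaviour of a
  capped EM; the per-iteration log-likelihood trace is retained and
  asserted non-decreasing. The E-step runs in compiled code.

A numeric column with zero observed training values takes a
configurable `fallback_fill` (default 0, with a warning) and is excluded
from the EM/KNN models — motivated by the all-missing amyloid-PET block.

All imputers are **fit on training rows only** and applied to
validation/test rows. The reference protocol states this for the
categorical modes; extending it to the numeric strategies is the
standard leakage-avoiding choice and is applied uniformly (per split and
per fold).

## Encoding

Categoricals expand to full one-hot indicators — no reference level is
dropped, both because the ridge penalty absorbs the collinearity and
because the 73-column accounting is only consistent with full expansion.
Numeric columns are z-scored with training-row statistics using the
population (divide-by-$N$) convention; the choice is immaterial after
ridge but is fixed for bit-reproducibility. A zero-variance training
column is flagged and given a unit-SD sentinel so it encodes to zeros.
Unseen categories at transform time encode as all-zero indicators with a
warning rather than an error, because small stratified splits of a
synthetic cohort can lack rare categories. Whether standardization
should use train-only or pooled statistics is left open; train-only
is implemented as the leakage-free reading.

## Evaluation protocol

Each experiment repeat draws a stratified 80/20 holdout split.
Hyperparameters are tuned on the training side by stratified 5-fold
cross-validation with imputation and encoding re-fit inside every fold;
the default grids are $h \in \{10, 20, \ldots, 100\}$ and
$\eta \in 2^{\{-6,-4,\ldots,12\}}$, with 2 versus 3 layers tuned for the
deep variants. Ties in mean validation accuracy break toward smaller
$h$, then larger $\eta$ (parsimony), then grid order.

The final model is chosen from an 11-member committee of random
initializations, each evaluated on a 20% stratified validation carve-out
of the training split. Because training is a closed-form solve,
"validation loss for early stopping" cannot mean epoch-wise stopping;
it is interpreted as (a) truncating each deep member at the depth
$\ell \in \{1..L\}$ minimizing validation squared loss and (b) returning
the member with minimal validation loss. Whether the committee should
instead average its members is ambiguous in the reference protocol;
best-member is the default and the committee internals are exposed so
averaging can be layered on.

Metrics use the confusion-matrix definitions with MCI as the positive
class; a rate with an empty denominator is reported as 0 and flagged
rather than NaN. All seeds derive deterministically from one master
seed (master → repeat → stage → member), so a `result_grid` is a pure
function of its inputs.

The bundled analysis drivers run 5 repeats and the test suite runs 10;
both are the package's choice of desk-scale defaults for a
demonstration cohort of 503 rows — cell means there carry SDs of about
0.01–0.03, which is ample for the qualitative ranking questions the
workflow answers. For publication-grade SDs raise `n_repeats` to the
protocol's 100.

## Statistical comparison

Classifiers are compared across conditions (the imputation methods, as
the "datasets" of the rank test) on mean accuracy. Average ranks with
tie-averaging feed the Friedman statistic

$$\chi_F^2 = \frac{12 D}{c(c+1)}\Big[\sum_j R_j^2
 - \frac{c(c+1)^2}{4}\Big],$$

referred to $\chi^2$ with $c-1$ degrees of freedom, and the Nemenyi
post-hoc critical difference

$$CD = q_\alpha \sqrt{\frac{c(c+1)}{6D}},$$

where $q_\alpha$ is the Studentized-range critical value for $c$ groups
at infinite degrees of freedom divided by $\sqrt2$. `qtukey()` supplies
$q_\alpha$ directly — it reproduces the published two-decimal q-table
values (e.g. CD = 6.163 at $\alpha=.05$ and 5.701 at $\alpha=.10$ for
$c=11$, $D=6$ within the table-rounding band of ±0.005), so no bundled
table is needed and any $\alpha$ is supported. Whether multiple metrics
should enter the ranking is ambiguous in the reference description;
single-metric ranking on accuracy is implemented, which is the
convention the reference CD arithmetic ($D = 6$) matches.

The critical-difference diagram places classifiers at their average
ranks and joins maximal groups whose ranks differ by at most CD
(maximal cliques of the non-significance relation, which on a line are
maximal windows). It is emitted as hand-generated SVG plus a plain-text
twin so renders are deterministic and diffable.

```{r example, eval = TRUE}
perf <- rbind(zero = c(0.97, 0.98, 0.95), mean = c(0.96, 0.98, 0.94),
              knn = c(0.97, 0.99, 0.93))
colnames(perf) <- c("rvfl", "edrvfl", "logistic")
rk <- average_ranks(perf)
friedman_test(rk)$p_value
nemenyi_cd(3, 3, 0.05)$cd
```

## Known limitations

* The generator's one-factor Gaussian model makes the task easier than
  real multimodal staging; absolute accuracies here say nothing about
  clinical accuracy, only about the relative behaviour of the pipeline
  components under controlled missingness.
* Only single deterministic imputation is supported — no multiple
  imputation or uncertainty propagation, matching the benchmarked
  protocol.
* The task is strictly binary (CN vs MCI, with dementia diagnoses
  mapped to MCI at label ingestion upstream of the package); no
  multiclass head is provided.
* EM assumes joint normality and MCAR; under informative missingness
  its conditional means are biased, which is a property of the method,
  not of the implementation.
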