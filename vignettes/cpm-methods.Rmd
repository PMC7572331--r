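---
title: "Connectome-based predictive modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncpm)
```

## The model

Connectome-based predictive modelling (CPM) relates a continuous
behavioural score $y$ (here, full-scale or verbal IQ in score points) to a
functional connectome: a symmetric $R \times R$ matrix of Pearson
correlations between regional resting-state fMRI signals, $R = 116$ under
the AAL atlas.  The feature unit is the *edge* — one off-diagonal entry per
unordered ROI pair, $E = R(R-1)/2$ of them (6,670 at $R = 116$), extracted
in a fixed row-major upper-triangle order.  The diagonal (self-connection)
is never a feature.

For one training set the pipeline is:

1. **Edge screening.**  Each edge's weights across training subjects are
   regressed against the score with a robust linear fit; the edge gets an
   association value $r$ and a two-tailed $p$-value for its slope.  Edges
   with $p < \alpha$ (default $\alpha = 0.01$, the conventional raw
   threshold; no multiple-testing correction, since cross-validated
   prediction, not the screen, carries the inferential burden) are
   selected and split by sign into a *positive network* ($r > 0$) and a
   *negative network* ($r < 0$).
2. **Summary values.**  Each subject is collapsed to two numbers: the sum
   of their edge weights over the positive network and over the negative
   network.  This sidesteps the varying size of the selected set.
3. **Univariate models.**  Two simple OLS regressions map positive and
   negative summary values, respectively, to the score.
4. **Prediction.**  The left-out subject's summary values are computed
   *with the training set's masks* and fed to the two fitted models.
5. **Edge ranking.**  Across all $N$ leave-one-out folds each edge $f_k$
   receives a normalized rank
   $\mathrm{score}(f_k) = \frac{1}{N}\sum_{i=1}^{N} \delta_{i}(f_k)\,
   |r_i(f_k)|$, where $\delta_i(f_k)$ indicates selection in fold $i$ and
   $r_i(f_k)$ is that fold's association value.  We read the formula as
   one term per fold per selected edge: an edge occupies exactly one
   position in a fold's selection, so a nested sum over within-fold rank
   positions collapses.  Under this reading the score is a
   selection-frequency-weighted mean absolute association, bounded in
   $[0, 1]$, zero iff never selected — properties the test suite checks
   against an explicit brute-force double loop (`rank_oracle()`).

Positive and negative models are always reported side by side; the package
never silently picks one.  Cohorts are population-specific (one group per
cohort, enforced at construction): models trained on mixed populations
could not isolate population-specific markers.

## The robust screen

"Robust regression" is implemented as iteratively reweighted least squares
with Huber weights $w = \min(1, c\,s/|e|)$, tuning constant $c = 1.345$
(95% Gaussian efficiency, the standard default), and scale
$s = 1.4826 \cdot \mathrm{median}(|e|)$ re-estimated from the current
residuals each iteration.  Iteration stops when the largest coefficient
change falls below $10^{-8}$ or after 50 iterations (the last iterate is
then used, with a warning).  A zero residual MAD — residuals numerically
identical — reduces the fit to OLS.  The slope $p$-value is the two-tailed
$t$-test with $n - 2$ degrees of freedom using the final weighted
covariance; the reported association $r$ is the weighted Pearson
correlation under the final weights, which shares the slope's sign by
construction.  Single-edge fits agree with `MASS::rlm(psi = psi.huber,
k = 1.345)` to within the two implementations' convergence details; the
package's own sweep exists because the leave-one-out loop needs all $E$
edges fitted simultaneously (the sweep is vectorized across edges, with an
active set that drops edges as they converge).

Two behaviours worth knowing:

* On *exactly* well-behaved data — every residual inside the Huber
  threshold, $\max|e| \le 1.994\,\mathrm{median}|e|$ — all weights are 1
  and the robust fit *equals* OLS.  On unbounded Gaussian noise this never
  quite happens: the Huber rule always downweights the ~18% of points
  beyond $1.345\sigma$ (the weights are scale-free), so robust and Pearson
  associations then agree only to about $10^{-2}$, not machine precision.
  The tests exercise the exact collapse with bounded residuals and the
  approximate agreement with Gaussian noise.
* Under response outliers (a corrupted recorded score), robust slopes move
  far less than OLS slopes — on the synthetic benchmark below, less than
  half as much.  This is the failure mode the robust screen defends
  against.

A constant edge carries no information and gets $r = 0$, $p = 1$ (never
selected) rather than an error: a single flat feature must not abort a
6,670-edge sweep.  An edge with $p < \alpha$ but $r$ exactly zero (a
measure-zero event) joins neither network, keeping the sign split
exclusive and exhaustive over selected edges.

## Summing "positive values": raw vs clipped

The protocol's summary step sums "positive values in the positive matrix".
A positively-*correlated* edge can still carry a negative *weight* in some
subject, so two readings exist: sum the raw signed weights of the
positive-network edges (the summary-score convention of the protocol this
package follows), or clip to positive weights first.  The package defaults
to `summary = "raw"` and exposes `summary = "clipped"` in `cpm_config()`;
the choice applies symmetrically to the negative side.

## Degenerate folds and evaluation

A fold whose screen selects no edges on one side has constant (all-zero)
summary values; its model is flagged degenerate and predicts the training
mean.  Such folds still count toward $N$ — dropping them would silently
change the evaluation sample — and their count is reported.  Evaluation is
the Pearson correlation $r$ between out-of-fold predictions and observed
scores, its square $r^2$, and the conventional two-tailed $t$-based
$p$-value (the same machinery as the screen; a permutation $p$ would be a
reasonable alternative but is not what the headline numbers use).

One consequence deserves emphasis: **on null data the out-of-fold $r$ is
biased negative, not centred at zero.**  A degenerate fold predicts its
training mean, $(\sum_j y_j - y_k)/(N-1)$, a strictly decreasing function
of the left-out score $y_k$ — perfectly anti-correlated with it.  With
$\alpha = 0.01$ and a few hundred edges, null cohorts produce many
degenerate folds, and evaluation $r$ around $-0.2$ is typical.  This is
the classic pessimism of leave-one-out correlation, not information
leakage (leakage would push $r$ positive, which is what the calibration
test bounds).

## The synthetic cohort generator

Real multi-site consortium data cannot ship with a package, so validation
runs on seeded synthetic cohorts that emulate exactly the structure CPM
assumes: (1) scores $y_i \sim \mathcal{N}(\mu, \sigma_y)$ (defaults
$106.5 \pm 15.2$ points, an adolescent IQ distribution); (2) per-subject
standardized scores $z_i$; (3) background edge weights
$\mathcal{N}(0, \sigma_e)$ with $\sigma_e = 0.25$, a typical off-diagonal
functional-connectivity scale; (4) planted coupling
$w_{ik} \mathrel{+}= \pm\beta z_i$ on disjoint positive/negative edge
sets; (5) `tanh` squashing into $(-1, 1)$ so downstream code always sees
genuine correlation-like entries; (6) optional corruption of a fraction of
*recorded* scores by $\pm 5$ SD with alternating sign (the response-outlier
scenario the robust screen targets — the connectomes stay clean); (7) one
global seed, bit-identical reruns.

The closed form $\rho = \beta/\sqrt{\beta^2 + \sigma_e^2}$ calibrates
$\beta$ to a target edge-score correlation (`effect_for_correlation()`);
the default plants $\rho \approx 0.4$.  The squashed matrices are
symmetric with unit diagonal but **not** guaranteed positive semidefinite;
CPM treats edges as independent features and nowhere relies on
definiteness.  The generator deliberately omits site effects, motion
artefacts, inter-edge covariance and BOLD dynamics — so a passing test
suite demonstrates the pipeline's statistical machinery (calibration,
recovery, leakage-freedom, robustness), not performance on real
consortium data, whose headline correlations depend on cohort composition
and preprocessing.

Validation problem sizes, chosen to make the expected behaviour sharp while
keeping runs desk-scale: type-I calibration on 50 null cohorts ($N = 100$,
$R = 30$); recovery, prediction and robustness on 10 cohorts of $N = 150$,
$R = 20$ with 5 + 5 planted edges at $\rho \approx 0.4$ (per-edge screening
power is then effectively 1, so recovery failures would indicate
implementation faults, not low power); generator calibration checked at
$N = 2000$.

## Numerical and interface choices

* Edge order: row-major strict upper triangle; indices are 1-based
  everywhere in the R API and in written files.
* File asymmetry up to $10^{-6}$ is repaired by averaging (round-trip
  noise); beyond that it is an error naming the worst cell.
* Ties in the top-$k$ table break by ascending edge index, making reports
  byte-reproducible.
* `alpha = 1` is allowed (vacuous screen): every non-constant edge lands
  in exactly one network — useful for exercising the sign split.
* The simulated score is recorded under both `fiq` and `viq` manifest
  columns, so a simulated cohort can be analysed under either target;
  missing-score exclusion is per-target (a subject missing VIQ still
  participates in FIQ analyses) and logged.
* Leave-one-out is the only cross-validation scheme offered; a $k$-fold
  variant would change which method is being validated.

## Limitations

Only pairwise (low-order) connectivity is modelled; the two summary models
are univariate and linear by design; the screen's threshold is fixed
rather than tuned by nested cross-validation; and the normalized-rank
formula's within-fold rank index is interpreted (one term per fold) rather
than fully specified by the protocol — the brute-force oracle pins down
the implemented meaning.
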