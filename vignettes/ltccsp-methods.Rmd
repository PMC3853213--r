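---
title: "Locally temporally weighted covariance estimation for motor-imagery CSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally temporally weighted covariance estimation for motor-imagery CSP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltccsp)
```

## The model

A two-class motor-imagery trial is an $N \times S$ matrix $X$ of channel
recordings. CSP seeks a filter matrix $\Gamma$ maximizing the ratio of
projected class variances
$\Gamma^\top \bar R_X \Gamma \,/\, \Gamma^\top \bar R_Y \Gamma$, where
$\bar R_X, \bar R_Y$ are the class averages of the per-trial
trace-normalized covariances $X X^\top / \operatorname{tr}(X X^\top)$.
The solution is obtained by simultaneous diagonalization: with
$(U, D)$ the eigendecomposition of $\bar R_X + \bar R_Y$ and $V$ the
eigenvector matrix of $D^{-1/2} U^\top \bar R_X U D^{-1/2}$,

$$\Gamma = U D^{-1/2} V,$$

whose columns satisfy $\Gamma^\top (\bar R_X + \bar R_Y)\Gamma = I$ and
diagonalize each class covariance with paired eigenvalues
$\lambda_j \in [0,1]$, $\lambda_j^X + \lambda_j^Y = 1$. The $M$ columns
with the largest and the $M$ with the smallest class-X eigenvalues are
the spatial filters.

The quadratic form underlying each per-trial covariance can be written
as a sum over *pairs of time points*: for row-centered trials,

$$\gamma^\top X X^\top \gamma
  = \frac{1}{2S}\sum_{l,m}(\gamma^\top x_l - \gamma^\top x_m)^2 .$$

The weighted estimators insert a nonnegative symmetric weight $W_{lm}$
into this double sum. Collecting terms gives the graph-Laplacian form

$$\tfrac{1}{2}\sum_{l,m} W_{lm}(x_l - x_m)(x_l - x_m)^\top = X L X^\top,
  \qquad L = D - W,\; D_{ll} = \sum_m W_{lm},$$

and the per-trial estimate becomes
$X L X^\top / \operatorname{tr}(X L X^\top)$. $L$ is positive
semidefinite and annihilates the constant vector, so the estimate is a
genuine covariance. The scalar $1/2S$ cancels under trace normalization
and is dropped.

Two weight functions are provided, both restricted to a temporal band
$|l - m| < \tau$:

- **Euclidean (LTCSP):** $W_{lm} = \exp(-\lVert x_l - x_m\rVert^2/\sigma)$.
- **Correlation (LTCCSP):** $W_{lm} = \exp(\mathrm{corr}(x_l, x_m))$,
  the Pearson correlation across the $N$ channels.

The correlation weight is the interesting one for robustness. It is
bounded — in-band weights live in $[e^{-1}, e]$ — and it is *exactly*
invariant to adding a constant vector $c\mathbf{1}$ to a sample: a
transient baseline shift that hits all channels equally leaves every
weight unchanged, whereas the Euclidean weight of the same pair decays
to zero as $c$ grows, wrongly suppressing genuine signal. Conversely an
impulsive outlier, being decorrelated from its neighbours, receives a
neutral weight $e^0 = 1$ against the $\approx e$ of well-correlated
neighbouring samples, so its contribution to the covariance is relatively
attenuated, while plain CSP gives it full weight.

## Feature extraction

Online, a trial $C$ is filtered as $Z = \Gamma_{sel}^\top C L^{1/2}$,
with $L$ built from the trial's own data using the fitted method's
weight function, and the features are the log sample variances of the
$2M$ rows of $Z$ (for plain CSP the $L^{1/2}$ step is the identity). Two
conventions are fixed for reproducibility: filters act by transposition
($\gamma^\top X$), and "variance" is the sample variance about the row
mean with denominator $S-1$.

Since $L\mathbf{1} = 0$ implies $L^{1/2}\mathbf{1} = 0$, every row of
$Z$ has exactly zero mean, and the variance reduces to the quadratic
form $\gamma^\top C L C^\top \gamma/(S-1)$. The implementation uses this
identity — no $S \times S$ eigendecomposition per trial — and
accumulates $X L X^\top$ lag by lag over the band, never materializing
$W$ or $L$; the test suite checks both shortcuts against the explicit
$L^{1/2}$ construction and a brute-force pairwise double sum.

## Parameters

- **$\tau$ (samples)** — the local temporal range; weights vanish for
  $|l-m| \ge \tau$. Selected from the grid $\{2,\dots,12\}$ by
  stratified 10-fold cross-validation of the full
  fit–extract–classify chain on the training set, ties going to the
  smallest $\tau$. The same fold split is reused across the whole grid
  so candidates are compared as paired samples. $\tau$ is an index
  distance: it does not rescale with the sampling rate.
- **$\sigma$ (squared amplitude units, LTCSP only)** — the Euclidean
  kernel scale, default $7\sigma_0$, where $\sigma_0$ is the
  *population* standard deviation of the squared norms
  $\lVert x_l \rVert^2$ pooled over every time sample of every training
  trial. Population vs sample standard deviation is immaterial at
  $SK \gg 1$ but fixed for reproducibility. During $\tau$ selection
  $\sigma$ is computed once from the full training set rather than per
  fold: it is a gross amplitude statistic whose per-fold variation is
  negligible, and freezing it keeps the paired comparison about $\tau$
  alone.
- **$M$ (filter pairs)** — default 3, the standard choice for
  motor-imagery work; requires $2M \le N$.
- **Band-pass** — zero-phase (forward–backward) Butterworth of order 4,
  8–30 Hz, covering the mu and beta rhythms whose event-related
  (de)synchronization carries the class information. Zero-phase
  filtering is used because group delay would otherwise distort
  variance-based features.
- **Classifier** — linear-kernel SVM, cost 1, features standardized by
  the training set. On $2M = 6$ log-variance features a linear decision
  function is the conservative standard; the kernel and cost are
  configurable (`eval_config(classifier = ...)`) precisely so that this
  choice is not load-bearing.

## Numerical choices

- Positive-semidefiniteness is enforced with relative tolerance
  $10^{-10}$: eigenvalues in $[-10^{-10}\lambda_{max}, 0)$ are clipped
  to zero; anything lower is an error.
- $\bar R_X + \bar R_Y$ must be positive definite to the same relative
  tolerance; rank deficiency (dead or duplicated channels) raises an
  explicit conditioning error. No silent regularization is applied — a
  ridge $\delta I$ exists but defaults to $\delta = 0$, because hidden
  regularization would contaminate comparisons between estimators.
- Eigenvector sign is fixed by making each filter's largest-magnitude
  coefficient positive; eigenvalue ties keep the eigensolver's stable
  order. Both conventions are non-semantic.
- A zero-variance sample vector (flat across channels) has no defined
  correlation; its weight is set to $e^0 = 1$, imposing neither
  attraction nor suppression.
- $\tau = 1$ makes $W$ diagonal and $L = 0$; this is rejected as a
  degenerate input rather than silently producing a zero covariance.

## The synthetic generator

`generate_trials()` draws $n_s$ white Gaussian sources per trial,
band-passes them to 8–30 Hz (so the signal model is consistent with the
preprocessing), rescales each source to its exact class variance, mixes
through a seeded random orthonormal $N \times n_s$ matrix $A$, and adds
white sensor noise. Because $A^\top A = I$, column $A_{\cdot j}$ is both
the mixing pattern and the unmixing filter of source $j$ — the ground
truth for filter-recovery tests. A train/test pair from the same
simulated subject shares `mixing_seed` (the forward model) while
differing in `seed` (the realizations).

Default study conditions, chosen once: $N = 15$ channels, $S = 500$
samples at 250 Hz (a 2-s imagery window), $K = 50$ trials per class,
$n_s = N$ sources of which two are discriminative with mirrored
variances 4 vs 1 (lateralized ERD/ERS on a strong rhythm), sensor noise
0.5. Outlier contamination follows the impulsive model: each of
$\mathrm{round}(f \cdot n)$ events adds independent per-channel draws
from $N(\mu + 30\sigma, (30\sigma)^2)$ — $\mu, \sigma$ the pooled mean
and standard deviation of the clean training data — to one distinct
(trial, time-point) position of the training set; the test set stays
clean. Variants (`mode = "constant"` for a same-draw-on-all-channels
baseline shift, `"single_channel"` for a one-electrode artifact) are
exposed because the impulsive model does not pin down how an event
spans channels.

What the generator does *not* emulate: volume-conduction forward models
(mixing is random orthonormal, not a head model), nonstationary
background rhythms, eye/muscle artifacts with spatial structure,
session-to-session covariate shift, or class-dependent temporal
autocorrelation. Passing the benchmark therefore demonstrates
correctness of the estimators and pipeline and their relative robustness
to impulsive contamination — not performance on real EEG.

At these conditions the planted effect is deliberately strong, and all
three methods sit at or near 100 % accuracy both clean and at the
highest contamination level (the zero-phase band-pass also spreads and
attenuates single-sample impulses). The benchmark's ordering checks —
contaminated CSP no better than clean CSP, correlation weighting no
worse than CSP under contamination — hold at this ceiling as equalities;
the benchmark sizes (10 repetitions, frequencies 0–0.4) were chosen to
keep the full comparison to a few minutes on one CPU.

## Known limitations

- Strictly two-class; multiclass extensions (one-vs-rest, joint
  diagonalization) are out of scope.
- No covariance shrinkage or Riemannian averaging; the estimators are
  exactly the trace-normalized forms above.
- Trial epoching, montage handling and artifact rejection are the
  caller's responsibility; `read_trialset()` expects already-epoched
  matrices.
- The correlation weight's robustness argument concerns offsets common
  to all channels and impulsive contamination; structured artifacts
  (e.g. single-electrode drift) are better served by the
  `single_channel` contamination model when testing.
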