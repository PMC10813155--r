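---
title: "Classifying balance control from raw center-of-pressure trajectories with Gaussian-mixture HMMs"
author: "copHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying balance control from raw center-of-pressure trajectories with Gaussian-mixture HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copHMM)
```

## The problem

During quiet standing, the center of pressure (COP) under a subject's feet
drifts continuously as the nervous system corrects postural sway. A force
plate records this drift as two displacement time series: medial–lateral
(ML, left–right) and anterior–posterior (AP, forward–backward). Parkinsonian
balance control alters the temporal structure of this sway, and copHMM
classifies a subject as healthy or parkinsonian (PD) **directly from the raw
trajectories**, with no feature extraction: each class is summarised by a
generative sequence model, and a test subject is assigned to the class whose
model explains their recording better.

## The model

Each class is modelled by a hidden Markov model $\lambda = (\pi, A, B)$ with
$K$ hidden states and Gaussian-mixture emissions. The hidden chain
$z_1, \dots, z_n$ is first order: $p(z_i \mid z_{i-1}, \dots, z_1) =
p(z_i \mid z_{i-1})$, with initial distribution $\pi$ and row-stochastic
transition matrix $A = (a_{kl})$. Conditional on state $k$, the observed
displacement vector $x_i \in \mathbb{R}^d$ (one or two COP channels, in mm)
is drawn from a Gaussian mixture

$$p(x_i \mid z_i = k) = \sum_{j=1}^{J} w_{kj}\,
  \mathcal{N}(x_i;\, \mu_{kj}, \Sigma_{kj}),$$

where $J = 1$ reduces to a plain Gaussian state density. The hidden states
play the role of sway regimes (for example drifting near the preferred
stance point versus corrective excursions); the transition matrix captures
how quickly the subject moves between regimes.

The three classical HMM computations are all provided as exact dynamic
programs:

* **Evaluation** — `forwardLogLik()` computes $\log p(X \mid \lambda)$ with
  the forward recursion.
* **Decoding** — `viterbiDecode()` returns the single most probable state
  path and its log joint probability.
* **Learning** — `baumWelchFit()` runs expectation–maximisation
  (Baum–Welch). The E-step (`forwardBackward()`) produces the state
  posteriors $\tau_{ik} = p(z_i = k \mid X)$, per-component posteriors, and
  expected transition counts; the M-step re-estimates every parameter by
  posterior-weighted averages, e.g.

$$\mu_k^{(q+1)} = \frac{\sum_i \tau_{ik}^{(q)} x_i}{\sum_i \tau_{ik}^{(q)}},
  \qquad
  \Sigma_k^{(q+1)} = \frac{\sum_i \tau_{ik}^{(q)}
    (x_i - \mu_k^{(q+1)})(x_i - \mu_k^{(q+1)})^\top}{\sum_i \tau_{ik}^{(q)}},$$

generalised to mixtures via component responsibilities, with the analogous
normalised-count updates for $\pi$, $A$ and the mixture weights.

## Two-model classification

`trainClassifier()` fits one model to the healthy training subjects
(H-HMM) and one to the PD training subjects (PD-HMM), with identical
configuration and seed. `classifySubject()` evaluates both total
log-likelihoods on the test recording and assigns the class with the larger
one. Because all recordings in a cohort share the same duration and
sampling rate, total (rather than per-sample) log-likelihood is the
comparison; both values are returned for audit. An *exact* tie — which has
probability zero for continuous data but occurs when both models are
parameter-identical — is resolved to PD, the clinically conservative call.

Channel use mirrors the two natural designs: a single-channel classifier
(`channelMode = "ML"` or `"AP"`, $d = 1$) or the combined classifier
(`"MLAP"`). For the combined case the default is one **bivariate** model per
class ($d = 2$ with full covariances), which subsumes any linear ML/AP
correlation; `fusion = "loglik_sum"` instead trains independent per-channel
models and sums their log-likelihoods, provided as the simpler alternative
reading of "combining both signals".

## Default configuration and what the knobs mean

`fitConfig()` defaults are the classifier's standard operating point:

| parameter | default | meaning |
|---|---|---|
| `nStates` | 3 | sway regimes per model |
| `nComponents` | 2 | Gaussians per state emission |
| `nIter` | 15 | EM iterations (the log-likelihood plateaus by then) |
| `tol` | 0 | no early stop: exactly `nIter` E/M pairs run |
| `covFloorScale` | 1e-6 | covariance eigenvalue floor, as a fraction of pooled data variance |
| `seed` | 1 | K-means and re-seeding RNG seed |
| `kmeansRestarts` | 5 | K-means restarts; best within-cluster SS wins |

We count an "iteration" as one E/M pair starting from the K-means
initialisation. The iteration cap (rather than a tolerance) is the default
stopping rule so that runs are exactly reproducible in length; a positive
`tol` is available when adaptive stopping is wanted.

## Initialisation

`kmeansInit()` pools the samples of all training sequences and clusters
them into `nStates * nComponents` centroids (`stats::kmeans`, Lloyd's
algorithm, best of `kmeansRestarts` seeded restarts). Centroids are sorted
lexicographically and assigned to states in contiguous blocks, so the
initial model is fully determined by the data and the seed. Component means
start at the centroids, covariances at the within-cluster covariance
(1/n normalisation, floored), mixture weights at the within-state cluster
proportions; $\pi$ and $A$ start uniform, leaving the temporal structure
entirely to EM.

## Numerical choices

* **Underflow.** A 60 s recording at 1000 Hz has 60,000 samples, so raw
  probability products underflow catastrophically. Emission densities are
  computed in log space; the forward–backward recursions use per-step
  rescaling (normalised forward variables plus a per-step max subtraction on
  the emission column), accumulating the log-likelihood from the log scale
  factors. A pure log-space forward pass is retained as a second code path
  (`method = "logspace"`) and the two agree to ~1e-10 on short sequences.
* **Covariance flooring.** After every M-step (and at initialisation),
  covariance eigenvalues are clamped at `covFloorScale` times the pooled
  per-channel data variance. Without this, EM on short segments can drive a
  component's variance toward zero around a few points and the likelihood
  diverges.
* **Component starvation.** If a component's pooled posterior mass falls
  below 1e-10, it is re-seeded (with a warning) at the training sample least
  covered by any state, with the pooled covariance.
* **Viterbi ties** are broken toward the lower state index, making decoded
  paths deterministic.
* **Multi-sequence training** pools sufficient statistics across subjects
  and estimates $\pi$ from the per-sequence initial posteriors; sequences
  are never concatenated, which would fabricate transitions across subject
  boundaries.
* **Higher-order chains** are representable in `MarkovChain` (the `order`
  slot) but inference deliberately rejects `order > 1`; only first-order
  models are used.

## Evaluation protocol

`kfoldCrossValidate()` uses stratified 10-fold cross-validation by default:
subjects are shuffled within class (seeded) and fold labels are dealt
round-robin across the whole cohort, so folds stay balanced in size and in
class composition, and `k = n` degenerates to leave-one-out. Each fold's
held-out subjects are classified by a model pair trained only on the other
folds; confusion counts are pooled over folds.

Metrics follow the healthy-positive convention: **sensitivity** is the
percentage of healthy subjects classified healthy, **specificity** the
percentage of PD subjects classified PD, **accuracy** the overall
percentage correct. (This is the reverse of common clinical usage, where
the disease class is "positive"; the functions document it explicitly.)
The reported `accuracySpread` is the sample standard deviation of per-fold
accuracies — a fold-to-fold stability figure, not a confidence interval.

`hyperparameterSweep()` repeats the CV over a grid of state and mixture
counts with the folds held fixed (same seed), so differences between rows
reflect the hyperparameters, not fold luck.

## The synthetic cohort

Real clinical stabilometry of this kind is not publicly available, so
`simulateCohort()` generates cohorts with known ground truth. The default
geometry matches the study conditions the classifier targets: 28 healthy
and 32 PD subjects, 60 s of quiet standing each, two channels. Two
generator families are provided:

* **`mode = "hmm"`** (default): each class is a 3-state bivariate Gaussian
  HMM. The PD generator differs from the healthy one by an amount
  proportional to `separation`: state means displaced (by `3 * separation`
  mm along seeded random directions), sway variance inflated (factor
  `1 + 0.8 * separation`), and dwell times shortened (off-diagonal
  transition mass scaled by `1 + 1.5 * separation`) — larger, faster,
  less regular sway, the qualitative signature of impaired postural
  control. `separation = 0` makes the classes literally identical, the
  null condition for chance-level checks. Hidden paths are returned so
  recovery tests can compare against truth.
* **`mode = "ar2"`**: each channel is a stable AR(2) process with
  class-dependent coefficients and innovation variance. Real COP is
  smoother than regime-switching output, and an AR(2) is the classic
  minimal model of damped postural sway; this mode exists so the classifier
  is also exercised on data that do *not* come from its own model family.
  Coefficient settings that leave the stationarity triangle raise an error.

The default simulated rate is 100 Hz rather than 1000 Hz: the HMM is
rate-agnostic (dwell times simply rescale), and 6,000-sample sequences let
a full 10-fold protocol run in minutes on one core. The 1000 Hz geometry
remains available (`samplingRate = 1000`), and the I/O layer and inference
are routinely tested at 60,000 samples.

What the simulator does **not** emulate: biomechanics (no inverted-pendulum
dynamics, no 1/f-like long-range correlations), measurement noise and
drift of a real force plate, age or disease-severity strata, and any
within-class heterogeneity beyond sampling noise. A pass on synthetic data
therefore demonstrates the correctness and statistical behaviour of the
pipeline — likelihood computations, EM, the decision rule, the CV harness —
not clinical performance on real cohorts.

## Problem sizes used by the test suite

The packaged checks run, among others: oracle comparisons of the dynamic
programs against full path enumeration on 50 random instances
($K \le 3$, $n \le 8$); EM monotonicity over 20 seeded random starts of the
default 3-state/2-mixture fit; parameter recovery from 20 sequences of
2,000 samples of a well-separated 3-state bivariate generator (means
recovered within 10%, transition probabilities within 0.1 after permutation
alignment); and the full cross-validated protocol on the default 28 + 32
cohort at 100 Hz, where a well-separated cohort must reach at least 95%
pooled accuracy and an identical-generator cohort must land inside the
central 99% binomial band around 50%. These sizes were chosen so the whole
suite completes on a single core in well under half an hour while still
exercising every code path at the study geometry.

## Known limitations

* The likelihood surface of a mixture HMM is multimodal; EM finds a local
  optimum that depends on the K-means start. The seeded-restart policy
  makes this reproducible, not globally optimal.
* Gaussian emissions assign density to physically impossible displacements;
  for COP signals measured in mm around the stance point this is harmless
  but means the model is not a biomechanical one.
* Total-likelihood comparison assumes equal recording lengths across
  subjects (true for the supported protocols); mixing durations would bias
  the decision toward the shorter-variance model and would require
  per-sample normalisation.
* The discrete-alphabet HMM type supports evaluation only; Baum–Welch is
  implemented for the Gaussian family the classifier uses.
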