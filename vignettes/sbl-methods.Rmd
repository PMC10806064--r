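---
title: "Decoding limb-movement intention from sEMG with a sine-BWOA-tuned LSSVM"
author: "emgSBL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding limb-movement intention from sEMG with a sine-BWOA-tuned LSSVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgSBL)
```

## The decoding problem

Surface electromyography (sEMG) measures the electrical activity of
skeletal muscle at the skin. When a subject flexes a shoulder, elbow or
hip, a characteristic subset of muscles activates, and a multichannel
montage over those muscles carries enough information to identify the
movement. This package implements a complete decoding chain for seven
classes — six limb movements (LS-FLX, LE-FLX, RS-FLX, RE-FLX, LH-FLX,
RH-FLX: left/right shoulder, elbow and hip flexion/extension) plus a
no-movement rest state (NM) — recorded on 16 channels placed over the
deltoid, biceps brachii, triceps brachii and brachioradialis of each arm
and the biceps femoris, semitendinosus, adductor magnus and tensor
fasciae latae of each leg.

Two experimental regimes are supported. In the *discrete* regime each
trial is a single isolated movement of roughly 4–5 s and yields one
composite feature vector. In the *continuous* regime the subject performs
the "marching in place with arm swinging" task: 19 sub-movements of 3 s
each, organized in 4 phases (`marchingSchedule()`), decoded with sliding
windows and scored per segment.

## The synthetic data generator

No public recordings exist for this montage and protocol, so the
generator is a first-class, tested module rather than a fixture. Its
signal model for channel $c$ under class $k$ is

$$ s_c(t) = g_c \, w_{kc} \, e(t) \, \eta_c(t)
          + \sigma_n \epsilon(t) + A_p \sin(2\pi f_p t + \phi)
          + A_d \sin(2\pi f_d t + \psi), $$

where $w_{kc} \in (0,1]$ is the class-specific activation gain of the
channel (rest level 0.05 on inactive channels and for NM), $e(t)$ a
trapezoidal burst envelope (0.3 s rise and fall), $\eta_c$ a unit-RMS
Gaussian carrier band-limited to 20–450 Hz by a 4th-order zero-phase
Butterworth filter, $\sigma_n = 0.05$ a white noise floor,
$A_p = 0.02$ a 50 Hz powerline component, $A_d = 0.01$ a 0.4 Hz baseline
drift, and $g_c$ a per-subject log-normal gain (sd 0.15) emulating
electrode placement and physiology differences. The sampling rate
defaults to 1000 Hz — a typical research sEMG rate chosen because the
acquisition hardware this emulates does not pin one down — and satisfies
the Nyquist constraint for the 450 Hz band edge.

What the generator deliberately does **not** emulate: motor-unit action
potential shapes and firing statistics, inter-muscle crosstalk, fatigue
(spectral compression over time), electrode lift-off artifacts, or
movement-process overlap between consecutive sub-movements. Classes
differ only through their activation maps, and the maps are well
separated by construction. Tests passing on these data therefore
demonstrate that the *machinery* is correct — features measure what they
claim, selection finds informative dimensions, the tuner finds workable
hyperparameters, the decoder aggregates windows correctly — not that the
pipeline would reach any particular accuracy on human recordings, where
class overlap is the dominant difficulty.

Schedule timing follows a machine-readable convention: entry $i$ of the
continuous task occupies the half-open interval $[3(i-1), 3i)$ s, with
configurable NM lead-in/lead-out padding around the scheduled block, and
sample indices are 0-based half-open throughout.

## Preprocessing

Bias removal subtracts the channel mean. Denoising applies a zero-phase
(forward–backward) Butterworth band-pass of order 4 between 20 and
450 Hz plus a 2nd-order band-stop notch at 50 ± 2 Hz; zero-phase
filtering avoids latency distortion of burst onsets at the cost of being
non-causal, which is acceptable for offline analysis. The passband,
notch and order are conventional for sEMG and configurable
(`filterConfig()`), since nothing in the protocol fixes them.

Amplitude normalization deserves care. Three modes are provided:

* `"global"` (default for discrete trials): divide the whole recording by
  its single maximum absolute value. This removes overall gain but
  preserves the **inter-channel amplitude pattern**, which is where the
  class information lives.
* `"peak"`: classical per-channel max-abs scaling. Applied per trial this
  erases the inter-channel pattern (every channel, active or silent, ends
  with peak 1) and demonstrably collapses class separability on synthetic
  data; it is retained because per-channel scaling against a *calibration*
  recording is standard practice, and the operation itself is
  well-defined and tested.
* `"none"`.

The continuous path (`streamFeatures()`, `decodeContinuous()`) applies
**no** per-recording normalization: a causal online decoder cannot know a
stream's future maximum, and whole-recording rescaling inflates
low-activity streams (a rest-only stream would have its noise scaled up
to unit peak). Amplitude consistency between training and decoding comes
instead from the feature standardization stored in the fitted model (see
below).

## Features

Per channel and analysis window: MAV, RMS, unbiased VAR (the $N-1$
denominator is declared so tests are exact), iEMG $= N \cdot$ MAV, and
from the spectrum the mean frequency and the median power frequency.
The PSD is a Welch estimate — Hamming-windowed segments of length
$\min(256, N)$ with 50 % overlap, one-sided scaling chosen so that
$\sum P_j \, \Delta f$ matches the window's mean square — because single
periodograms are too variable on 250 ms windows. The median power
frequency interpolates linearly inside the bin where cumulative power
crosses half the total. Zero-power channels make the spectral features
undefined; such windows keep their time-domain zeros, receive NA spectral
entries and are flagged invalid rather than silently dropped.

Features are assembled channel-major into a flat vector
(`<channel>_<feature>` naming), giving $16 \times 6 = 96$ dimensions for
the default montage; whole discrete trials are treated as one window,
continuous streams use 250 ms windows with 125 ms step by default (250 ms
is a common compromise between spectral resolution and decoding latency;
both are configurable).

## Fisher-dispersion feature selection

Subsets are scored by the prior-weighted multi-class dispersion

$$ J_d = \sum_{i=1}^{c} P_i \left[ \frac{1}{n_i} \sum_{k=1}^{n_i}
   \lVert x_k^{(i)} - m_i \rVert^2 + \lVert m_i - m \rVert^2 \right], $$

computed on the masked dimensions, with empirical class priors by
default. Larger values indicate better separability. Note that $J_d$ is
*not* scale-normalized: multiplying all features by $a$ multiplies $J_d$
by $a^2$, and no normalization onto a fixed interval is imposed.

The search over cardinality-$d$ masks uses a genetic algorithm: binary
tournament selection, uniform crossover (rate 0.9), per-bit mutation at
rate $1/D$, repair of each child back to exactly $d$ selected bits by
random flips, elitism 1, population 50, 100 generations by default. Exact
fitness ties break toward the lexicographically smallest mask so runs are
reproducible bit-for-bit under a seed. For $D \le 12$ the GA at this
budget reproduces exhaustive enumeration, which the tests verify. A
`dimensionSweep()` helper tabulates the best $J_d$ per candidate $d$;
its `"greedy"` mode uses nested forward selection, for which the score is
provably non-decreasing in $d$ — the GA mode makes no such promise.

## LSSVM and the one-vs-one ensemble

The binary least squares SVM replaces the SVM's inequality constraints
with equalities, so training reduces to one symmetric linear system

$$ \begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
   \begin{bmatrix} b \\ \alpha \end{bmatrix} =
   \begin{bmatrix} 0 \\ 1 \end{bmatrix}, \qquad
   \Omega_{kl} = y_k y_l K(x_k, x_l), $$

with the RBF kernel $K(x,z) = \exp(-\lVert x-z \rVert^2 / \mathrm{sig2})$.
The parameter names `gam` (regularization) and `sig2` (squared bandwidth)
follow the established LSSVM toolbox convention. The solve uses block
elimination on $H = \Omega + I/\gamma$ (two right-hand sides, then
$b = y^\top H^{-1} 1 / y^\top H^{-1} y$), falls back to a pseudo-inverse
with a warning when the reciprocal condition number drops below $10^{-12}$,
and records the relative residual of the full system (healthy solves sit
at machine precision, far below the $10^{-8}$ contract).

Multiclass assembly is one-vs-one — $C(C-1)/2$ balanced machines for $C$
classes, a better fit than one-vs-all for 6–7 roughly balanced classes —
with majority voting; ties break toward the largest summed absolute
decision value among the tied classes, then class order. Per-class score
traces (summed signed decision values) feed the ROC analysis.

Before training, the masked feature columns are standardized to zero
mean and unit variance on the training set, and the scaling is stored in
the model and applied to every query. This is a deliberate addition: the
six features live on scales separated by orders of magnitude (VAR of a
normalized signal vs. iEMG of a 4 s trial vs. frequencies in Hz), and a
single RBF bandwidth cannot absorb that anisotropy.

## The sine-chaotic black widow optimizer

Hyperparameters $(\gamma, \mathrm{sig2})$ are tuned by minimizing
stratified $k$-fold cross-validation error (default $k = 5$, reduced with
a warning when a class is smaller) over the box
$\gamma \in [10^{-2}, 10^{4}]$, $\mathrm{sig2} \in [10^{-2}, 10^{3}]$,
searched in $\log_{10}$ space. The fold assignment is fixed once per
tuning call so the objective is deterministic.

The optimizer's population of candidate positions evolves through:

1. **Sine-chaotic initialization.** Per dimension the map
   $x_{k+1} = a \sin(\pi x_k)$, $a \in (0, 1]$ (default 1), is iterated
   from a seeded start in $(0,1)$ and the orbit is mapped affinely onto
   the bounds. The map's published form is ambiguous about the exponent
   and range of $a$; the standard sine chaotic map is adopted. Orbits
   that hit the absorbing point 0 are reseeded from the RNG to preserve
   coverage (50 draws cover at least 8 of 10 equal bins in the tests).
2. **Movement.** With probability 0.3 the linear form
   $x^* - m\, x_{r1}$ ($m$ uniform in $[0.4, 0.9]$, $r1 \ne i$), otherwise
   the spiral form $x^* - \cos(2\pi\beta)\, x_i$ ($\beta$ uniform in
   $[-1, 1]$), clamped to bounds. The acceptance rule is not part of the
   published recipe; candidates here replace the individual only when
   fitter, which keeps the walk productive and makes the best-so-far
   history monotone by construction.
3. **Pheromone replacement.** Fitness maps onto pheromone
   $\mathit{ph}_i = (f_{max} - f_i)/(f_{max} - f_{min})$ — best individual
   exactly 1, worst exactly 0; when the spread falls below
   $\varepsilon = 10^{-8}$ all pheromones are 0 by convention, avoiding
   the zero division. Individuals with $\mathit{ph} \le 0.3$ (never the
   current leader) are replaced by
   $x^* + \tfrac{1}{2}[x_{r1} - (-1)^\sigma x_{r2}]$, $r1 \ne r2$,
   $\sigma \in \{0, 1\}$ random.
4. **Procreation, cannibalism, mutation.** The fittest PP = 0.8 fraction
   pairs up; each pair produces the complementary offspring
   $\alpha \circ x_1 + (1-\alpha) \circ x_2$ and its mirror with
   per-dimension uniform $\alpha$. Within each family the worst CR
   fraction is cannibalized (CR is given no published value; default
   0.5, and at least the family best always survives). A PM = 0.4
   fraction of the retained individuals has two random coordinates
   swapped (swap rather than resampling, following the original
   formulation of the metaheuristic), clamped to bounds. Survivors pool
   with the current population and the best `popSize` individuals
   continue — the elitist population update.

The per-iteration ordering of stages 2–4 is this package's declaration;
published descriptions of the algorithm mix two lineages (movement and
pheromone equations vs. five named stages) without fixing an order.
Defaults are population 20 and 100 iterations. At that budget the
optimizer reaches $\le 10^{-3}$ on the 2-D sphere function and $\le 1$ on
2-D Rastrigin in at least 4 of 5 seeds (in practice it reaches machine
zero), with a monotone non-increasing history and bit-identical runs
under a fixed seed.

## End-to-end pipelines and evaluation

*Discrete*: stratified 70/30 split, GA selection to $d = 48$ of 96 (the
operating dimensionality is a config default, not a derived constant),
tuning, final one-vs-one training, and evaluation with confusion matrix
(predicted × true), per-class accuracy (diagonal over column sum),
overall accuracy in percent, and macro one-vs-rest AUC via `pROC`.

*Continuous*: the NM rest state is trained as a seventh class from the
rest windows of the training stream — a thresholding rest detector was
rejected as harder to test and tune. Windows are classified
independently; each ground-truth segment (scheduled movements plus the
complementary NM gaps) receives the majority label of the windows whose
centers fall inside it, with ties resolving to NM as the conservative
choice. Reported accuracy is per-segment.

`compareBaselines()` fits SVM, a single-hidden-layer backpropagation
network, $k$-NN, random forest and a decision tree on exactly the same
masked, standardized features and split as the SBL model.

## Numerical choices and degenerate inputs

* LSSVM conditioning: pseudo-inverse fallback below rcond $10^{-12}$,
  with a warning; the defining-system residual is stored on the model.
* Non-finite tuning objectives are demoted to worst rank with a warning
  rather than aborting the search.
* Zero-signal windows: time-domain features are exact zeros, spectral
  features NA, window flagged invalid.
* All-zero channels pass through peak normalization untouched.
* Decision ties: binary $f = 0$ maps to the pair's first class; ensemble
  vote ties break by summed $|f|$, then class order; segment-vote ties
  break to NM.
* Seeds: every stochastic stage (generator, splits, GA, optimizer,
  baselines) takes an explicit seed and derives sub-seeds internally, so
  whole pipelines are reproducible bit-for-bit.

## Problem sizes used by the test suite

The shipped tests exercise the full chain at desk scale, chosen to keep
the suite fast while leaving the conclusions unchanged: discrete runs use
3 subjects × 6 classes × 10 trials (70/30 split), GA selection with
population 30 over 40 generations, and a tuner budget of population 8
over 10 iterations; continuous runs train on one marching-task stream and
decode another, with 250 ms non-overlapping windows and a tuner budget of
6 × 8. The optimizer benchmarks run the full published budget
(population 20, 100 iterations, 5 seeds). On the generator's
well-separated classes these sizes already saturate accuracy, so larger
runs would only add runtime, not information.

## Known limitations

* Synthetic classes are separable by construction; absolute accuracies do
  not transfer to human data.
* The Fisher dispersion sums within- and between-class terms rather than
  taking their ratio; with unnormalized features it favors large-scale
  dimensions. Standardize features first if that is not intended.
* One `sig2` is shared across all one-vs-one machines.
* Zero-phase filtering and whole-trial features are offline constructs;
  a streaming deployment would need causal filters and incremental
  windows.
* The GA and the optimizer are heuristics: outside the enumerable regime
  their optima are best-effort, not certified.
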