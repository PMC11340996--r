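---
title: "Methods: personalized Epileptor network inversion with sodium-MRI priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized Epileptor network inversion with sodium-MRI priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`vepna` implements a complete virtual-epileptic-patient (VEP) workflow on
synthetic or user-supplied data: quantitative multi-echo sodium (^23^Na)
MRI feature extraction, construction of per-region excitability priors
(from SEEG seizure spectra, from a sodium-feature classifier, from a
clinical hypothesis, or uninformative), maximum-a-posteriori (MAP)
inversion of a 2D-reduced Epileptor brain-network model against SEEG
power envelopes, and scoring of the resulting epileptogenic-zone-network
(EZN) estimates. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic experiments do
and do not demonstrate.

# The network model

Each brain region $i$ is a neural mass following the 2D reduction of the
Epileptor:

$$\dot x_i = I_1 - x_i^3 - 2x_i^2 - z_i$$
$$\dot z_i = \frac{1}{\tau_0}\Big(4(x_i - x_{i,0}) - z_i
  + K \sum_j C_{ij}(x_j - x_i)\Big)$$

with external input $I_1 = 3.1$, slow time scale $\tau_0$, global
coupling $K$, and the structural connectome $C$ (diagonal zeroed,
max-normalized). The excitability $x_{i,0}$ controls whether a node can
seize: below roughly $-2.06$ the node has a stable equilibrium
(`find_fixed_points()` computes the cubic's roots and classifies their
Jacobian eigenvalues); at $-1.5$ no stable equilibrium exists and the
node cycles through seizure-like events. The convention used throughout
is $x_0 = -1.5$ for epileptogenic tissue and $x_0 = -3$ for healthy
tissue.

The coupling sign is implemented exactly as written above
(`+K\sum C_{ij}(x_j-x_i)` inside $\dot z$); parts of the VEP literature
use the opposite sign, so `epileptor_params(coupling_sign = -1)` exposes
the alternative.

Integration is stochastic Heun (compiled, `src/epileptor.cpp`) with
additive Gaussian noise on both state variables. Defaults: `dt = 0.05`,
`duration = 6000` time units, `tau0 = 20`, `K = 1` — the source gives no
simulation constants, so these are declared values chosen to resolve the
fast variable and produce several seizure cycles at $\tau_0 \in [10,30]$.
Noise increments are pre-generated per region from `seed + region index`,
which makes a $K=0$ network run bit-identical to the matching
single-region runs (a property the tests assert).

# Sodium quantification

Multi-echo ^23^Na signals decay biexponentially in tissue. Per region the
mean signal at 24 echo times (0.2–70.78 ms; the exact intermediate echoes
are sequence-dependent and the canonical grid here is linearly spaced,
consistent with an even echo train at ~3.07 ms spacing) is fitted with

$$S(TE) = A\big(f\,e^{-TE/T_{2s}^*} + (1-f)\,e^{-TE/T_{2l}^*}\big) + c$$

by bounded Levenberg–Marquardt least squares with 8 deterministic
multi-starts over a log-spaced $(T_{2s}, T_{2l})$ grid; if a start
converges with the components swapped they are canonicalized
($T_{2s} \le T_{2l}$, $f \mapsto 1-f$). The printed source form of the
model is ambiguous between $A$ and $A^2$ and between an additive constant
and a Rician noise floor; the linear-$A$/offset form is the default
(it is the only reading under which $M0_{SF} = A\cdot f$ is dimensionally
consistent) and a Rician-floor variant
$S = \sqrt{M(TE)^2 + c^2}$ is available via `variant = "rician"`.

Phantom calibration is an OLS line $M0 = a\cdot\text{conc} + b$ over the
six reference tubes (two at 25 mM, one at 50, two at 75, one at 100);
concentrations invert as $Na = (M0 - b)/a$. The features are
$Na_{SF} = (A f - b)/a$, $Na_{LF} = (A(1-f) - b)/a$,
$TSC = Na_{SF} + Na_{LF}$ and $f = Na_{SF}/TSC$; the identity
$TSC = Na_{SF}+Na_{LF}$ holds exactly by construction. Negative
calibrated concentrations are kept but flagged so downstream linear
statistics stay unbiased. Both the fitted fraction (`f_fit`) and the
concentration ratio (`f`) are reported; they differ when $b \ne 0$.

**Recovery experiment and the offset.** The noisy round-trip experiment
(`biexp_recovery_experiment()`) generates curves with $c = 0$ at 1%
amplitude noise and asks for $f$ within $\pm 0.05$. With the offset left
free, the Fisher-information bound for $f$ on this 24-echo design is
$\mathrm{sd}(f) \approx 0.031$, so no estimator can reach 95% coverage at
that tolerance; with the nuisance offset pinned at its generating value
the bound is $\approx 0.020$ and the observed coverage is ~98%. The
experiment therefore fixes the offset; the general-purpose fit keeps all
five parameters free.

# Forward model

Vertex areas assign one third of each incident triangle's area to its
vertices, so they sum exactly to the mesh area. The gain from region $j$
to contact $k$ is $g_{jk} = \sum_{i \in j} a_i/d_{ik}^2$ over that
region's vertices; the sensor-to-source matrix instead averages inverse
distances over the region's 60 vertices closest to the contact (all of
them, normalizing by the actual count, when a region has fewer; distance
ties break by vertex index). Simulated SEEG is the matrix product of the
gain (transposed) with the source fast variable. No dipole orientation is
modelled: the 2D reduction removes the current dipole's directionality,
so a scalar inverse-square gain is the appropriate level of detail.

# SEEG onset priors (VEP-M, VEP-W)

The seizure window is cut into 200 equal non-overlapping segments
(remainder dropped); per segment a magnitude-squared FFT gives power per
frequency bin, floored with $\varepsilon = 10^{-12}$ before the log.
Frequency bands combine a lower bound of 10–90 Hz with an upper bound
from lower+10 up to 120 Hz in 10 Hz steps, which enumerates 63 bands
(the prose count of 52 in the source conflicts with its own rule; a cap
of 110 Hz, giving 54, is available via `upper_max` and the discrepancy is
left exposed rather than resolved). Per channel and band, the band-mean
series is thresholded at its own 90th percentile; the onset is the first
window strictly above it (1-based, so the earliest possible onset scores
exactly 1 before normalization), the channel value is the reciprocal
onset, max-normalized per band; channels that never cross score 0.

VEP-M assigns each sensor's value to the region with the strongest
sensor-to-source projection (max rule when several sensors map to one
region); VEP-W takes the weight-normalized mean over sensors per region
(a raw weighted sum is behind `normalize_weights = FALSE`). Band results
are averaged, divided by the max, and binarized: scores strictly above
0.5 become $x_0 = -1.5$, everything else (including exactly 0.5)
$x_0 = -3$. Whether "strongest projection" should use the gain or the
sensor-to-source matrix is not decidable from the source; the
sensor-to-source matrix is used here, and the functions accept either
matrix shape.

# Sodium-feature classifier prior

The classifier predicts binary EZN membership per investigated region
from the four sodium features. The pipeline follows the published
procedure: degree-2 polynomial expansion with interactions (constant +
4 linear + 4 squared + 6 interactions = 15 columns, plus the two lesion
indicator columns = 17 — the stated count of 15 only works if the
constant is included, and that convention is adopted); standardization
with training-set statistics (population-sd convention); a spectral
embedding (Laplacian eigenmaps over a symmetrized 10-nearest-neighbour
graph; the eigenvector sign is fixed so the row with the largest absolute
loading is positive) splits training patients into two pattern subsets by
the sign of each patient's mean first-coordinate over EZN rows;
per-subset nested cross-validation at patient level (outer folds of two
patients) with per-fold resampling — SMOTE-style interpolation (k = 5)
of the minority class to 60 and the majority to 180 points, then
3-nearest-neighbour ENN editing of both classes; cross-validated
permutation importance (10 repeats, selection threshold 0.05 on the mean
balanced-accuracy drop); a grid search whose axes include C, the class
weights (EZN:3/rest:0.6 and EZN:4/rest:0.57) and solver labels "lbfgs"
and "saga"; and the published retention rules — mean CV validation
balanced accuracy above 0.65 and train-validation gap below 0.1 — with
the final model per subset chosen by test balanced accuracy. Decision
thresholds are optimized over midpoints of sorted unique probabilities
(largest optimal midpoint on ties). Predictions convert to
$x_0 \in \{-1.5, -3\}$; uninvestigated regions default to $-3$.

The logistic regression minimizes the cost-sensitive objective
$\tfrac12\lVert\beta\rVert^2 + C\sum_i w_i\log(1+e^{-y_i\eta_i})$
(intercept unpenalized) with analytic gradients under L-BFGS-B. The two
solver labels map to the same deterministic optimizer: they name
different algorithms for the *same* convex objective, so the optimum is
identical and determinism is gained.

# MAP inversion

The data feature $\nu$ is a per-channel power envelope: subtract the
baseline-window mean of the raw signal, partition into `n_windows`
(default 200) equal segments, take mean-of-squares, log, smooth with a
centered moving average (default 5 windows), and subtract the median over
the baseline windows (default fraction 1/10). The predicted feature
applies the *same* operator to the gain-projected simulated sources and
scales it as $\tilde\nu = s\cdot\text{env} + a$. The envelope operator is
a declared contract (the source never defines it); all its parameters are
configurable, and projection-then-power is used (power-then-projection
being the undecidable alternative).

Priors: $x_{i,0}\sim\mathcal N(x_{i,m}, 1)$ with $x_{i,m}\in\{-1.5,-3\}$
from the chosen prior strategy; $\tau_0\sim\mathcal N(20,10)$ truncated
at 5; $s, K, \epsilon_\nu \sim\mathcal N(1,10)$ truncated at 0;
$a\sim\mathcal N(0,10)$; initial states $x_i(t_0)\sim\mathcal N(-2,10)$,
$z_i(t_0)\sim\mathcal N(3.5,10)$. The likelihood is
$\nu \sim \mathcal N(\tilde\nu, \epsilon_\nu)$ over channels and
windows, with $\tilde\nu$ produced by a noiseless simulation from the
candidate parameters. The log posterior is maximized by L-BFGS in an
unconstrained space (bounded parameters log-transformed,
$\tau_0 = 5+e^u$ etc.); no Jacobian term is added, matching the
penalized-ML convention optimization pipelines built on Stan use.
Convergence follows relative objective change ($10^{-8}$) or projected
gradient ($10^{-6}$), capped at 20 000 iterations.

**Multi-start.** The onset-time likelihood is piecewise-flat in the
excitabilities, so a single generic start frequently lands in a wrong
basin. Three deterministic starts are used: (i) the prior modes; (ii) a
data-informed start seeding excitabilities from channel envelope onsets
mapped through the gain matrix; (iii) a greedy scan flipping one region
at a time between $-3$ and $-1.5$ (evaluated jointly over a coarse grid
of shared initial slow-variable values, which set onset timing) until no
flip raises the posterior. The best final posterior wins. Sensor-
bootstrap replicates warm-start from the full-sensor MAP estimate, which
is both faster and appropriate since each replicate differs by one
sensor.

Goodness of fit is $1 - \sum_c\mathrm{var}(\nu-\tilde\nu) /
\sum_c\mathrm{var}(\nu)$ across channels; goodness of convergence is the
fraction of bootstrap runs whose optimizer terminated properly.

# Epileptogenicity values and decisions

Onsets $t_i$ are first crossings of the estimated source $x_i$ above 0
(sentinel 200 when a region never crosses); with $t_0 = \min_i t_i$, raw
values are $-\log(t_i - t_0 + 1)$, min-max normalized per run. The
printed source formula carries an unrecoverable trailing divisor; any
positive constant divisor is inert under min-max normalization, which a
property test asserts. The sensor bootstrap repeats the inversion 100
times (default), each run dropping one sensor drawn with replacement;
per-region medians are min-max normalized and the confidence is the
percentage of successful runs with EV above the threshold ("confidence"
is not defined in the source; this run-fraction reading is the declared
one). A region joins the EZN when median > 0.6 and confidence > 75%
(the 0.5 variant that also appears in the source is a parameter).

Evaluation uses balanced accuracy, $F_{0.5}$, and a bootstrapped paired
t test: the observed paired t statistic is compared against sign-flipped
centered resamples with the $(r+1)/(n+1)$ correction. The exact
resampling recipe is unstated in the source; the sign-flip scheme is the
declared contract.

# Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes: sparse
log-normal connectomes; spherical-cap surfaces with region labels and
sensors placed just outside chosen region centroids (so coverage is known
ground truth); seizure recordings as gain-projected Epileptor activity
plus measurement noise; and labelled sodium cohorts. Cohorts default to
3 EZN / 5 PZ / 20 NIZ regions per patient (the highly imbalanced
SEEG-sampled setting), healthy baselines around
$Na_{SF}=15$, $Na_{LF}=25$ mM ($TSC \approx 40$ mM), EZN mean shifts of
(6, 4) mM and PZ shifts of (3, 2) mM so the EZN > PZ > NIZ gradient holds
by construction, correlated Gaussian feature noise (sd 1.5 mM, r = 0.3),
and two pattern groups separated by 8 mM whose epileptogenic shift loads
differently on the short/long components. Scenario simulations default to
a raised initial slow variable ($z(0) = 4.5$) so a pre-ictal baseline
precedes the first onset.

Passing tests on these data show that the estimation machinery is
internally consistent and recovers known ground truth under the stated
noise models. They do not show clinical validity: real SEEG has artifacts,
montage effects and non-stationary background; real sodium maps have
partial-volume and B0 effects; real connectomes are far denser and the
162-region scale is two orders larger than the 4–6-region test networks.
Patient-level results from the source study are explicitly out of scope.

# Problem sizes and runtime choices

Test and validation experiments use 4–6-region networks, 40–200 envelope
windows, horizons of 60–100 time units, optimizer caps of 25–150
iterations, bootstrap counts of 4–6 (the API default remains 100), 200
biexponential replicates, 10 classifier replicates and 50 split-recovery
replicates. These sizes were chosen so a full virtual trial runs in
minutes on one CPU while every qualitative effect of interest (EZN
recovery, prior benefit at low SNR, split-vs-shuffled classifier gap)
remains decisively measurable.

# Known limitations

- The inversion's multi-start is heuristic; at very low SNR it can settle
  on a parsimonious single-region explanation of multi-region seizures
  (visible in the SNR experiment as ranking errors of the uninformative
  prior).
- The 52-vs-63 band-count conflict and the gain-vs-sensor-to-source
  ambiguity of VEP-M are exposed as options, not resolved.
- Time-delayed coupling, the 6D Epileptor, vertex-level neural fields,
  HMC/NUTS sampling and bipolar montage construction are out of scope.
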