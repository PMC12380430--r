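---
title: "Methods: adaptation-invariant odor coding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptation-invariant odor coding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`odoradapt` implements the analysis chain for asking whether an adapting
olfactory circuit preserves stimulus identity and intensity information.
The chain runs from spike-event tables through Neuron × Time × Trial count
tensors to trilinear decomposition, population-vector geometry and
behavioral statistics, with a first-class synthetic-data generator standing
in for ensemble recordings of antennal-lobe projection neurons (PNs).

The central dissociation is geometric. Write the per-trial population
vector as $X^{(k)} \in \mathbb{R}^{n}$ (one entry per neuron, window-summed
or time-averaged spike counts). Adaptation is modeled as a change of
*length* $\lVert X^{(k)} \rVert$; identity and intensity are carried by
*direction* $X^{(k)} / \lVert X^{(k)} \rVert$. Pearson correlation between
trial vectors is invariant to positive rescaling, so every
correlation-based analysis in the package (similarity matrices, clustering,
classification, catch-trial profiles) probes direction only. This is the
level at which "adaptation-invariant coding" is literally a theorem for the
pure magnitude-scaling model, and an empirical property for everything
else.

## Stimulus protocols

A `stimulus_protocol` fixes the experimental skeleton: blocks of repeated
trials of one stimulus (25 trials per block for neural sessions, 10 for
behavioral ones), a 4-s odor window analyzed in 50-ms half-open bins
(80 bins), a 60-s inter-trial interval, 15-min no-stimulation resets
between blocks, and optionally a catch trial (a single deviant stimulus,
e.g. the 26th trial of a 30-trial block). Trial numbering is 1-based;
spike times are seconds relative to odor onset, and the analysis window is
the half-open interval $[0, 4)$ s, so a spike exactly at 4 s belongs to no
bin. Binning conserves in-window spike mass exactly.

# The synthetic-data generator

The generator defines the study conditions for all property checks; its
defaults were chosen once, for realism, and are not tuned per analysis.

**Spiking model.** Each unit fires as an inhomogeneous Poisson process.
Within the odor window the rate is
$$\lambda_u(t, k) = b + m_k(u)\, g_u(s)\, \kappa(t) - s_k(u),$$
with baseline $b$ (3 Hz — typical PN spontaneous rate), odor-specific gain
$g_u(s)$, temporal kernel $\kappa(t)$, and multiplicative/subtractive
adaptation terms $m_k, s_k$; outside the window the rate is the baseline.
Because the rate is piecewise-constant over bins, drawing a Poisson count
per bin with uniform spike times inside the bin samples the process
exactly — no thinning approximation is involved. A negative effective rate
is a model error and is never silently clipped.

**Tuning.** For each odor, half the units respond (`responsive_fraction`
0.5), with gains drawn Gamma(shape 2, scale 7.5 Hz) — right-skewed, mean
15 Hz at full intensity, the typical range of odor-evoked PN rates.
Low-intensity tuning is `intensity_gain` (0.5) times the high-intensity
tuning for 75% of units; the remaining `rotation_fraction` (0.25) have
their low-intensity tuning re-drawn, which both reduces total ensemble
output and changes the activated combination, including units that prefer
the lower concentration. The rotation fraction is a free parameter: the
size of the real low-intensity ensemble rotation is not quantified
anywhere we could calibrate to, so it is exposed in the model rather than
asserted.

**Temporal kernel.** A rise–plateau–decay shape
$(1 - e^{-t/0.15})(0.45 + 0.55\,e^{-t/2})$, normalized to unit peak —
fast onset, sustained drive, slow decay over the 4-s window.

**Adaptation mechanisms.** Three alternatives, sharing the trial constant
$\phi_k = 1 - e^{-(k-1)/\tau}$ with $\tau = 5$ trials:

* *magnitude_only*: $m_k = p + (1-p)e^{-(k-1)/\tau}$ with plateau
  $p = 0.45$, identical for all units — counts fall to roughly half over
  ~10 trials while the population-vector direction is exactly preserved.
* *vesicle_depletion*: $m_k(u) = 1 - c\,\phi_k\, r_u/\max_v r_v$ with
  $c = 0.6$ — suppression proportional to each unit's own normalized
  drive, so the strongest responders adapt most and the regression of
  response change on trial-1 response has negative slope.
* *lateral_inhibition*:
  $s_k(u) = c\,\phi_k\,\bigl(1 - \min(r_u/\tilde r, 1)\bigr)$ Hz
  subtracted from the unit's rate during the window, with $c = 3$ Hz and
  $\tilde r$ the *median* evoked rate of the responsive units. Weak and
  silent units are suppressed hardest — including below baseline, as
  odor-evoked inhibition of PNs does — while units driven at or above the
  typical level escape entirely, giving the positive regression slope that
  is this mechanism's signature.

The lateral-inhibition form deserves a note, because the obvious
alternative fails. Scaling a weak responder's *evoked* response
multiplicatively by any factor that decreases with drive produces only a
small absolute change for weak units (they have little response to lose),
and for right-skewed gain distributions the resulting regression slope of
$\Delta$ on $r_1$ is *negative* — indistinguishable from depletion. The
mechanism's defining prediction, weak responders losing the most spikes,
requires suppression of total (baseline-inclusive) firing; the subtractive
median-normalized form expresses it robustly while keeping rates
non-negative whenever `strength` does not exceed the baseline rate. The
maximum-normalized subtractive variant was also considered and discarded
during design: most units sit far below the population maximum, which
dilutes the suppression gradient to near the noise floor of the
trial-1-vs-trial-25 count regression (which carries an intrinsic
regression-to-the-mean bias, since trial-1 noise enters both axes).

**Catch trials.** The catch trial presents the deviant stimulus with its
own tuning at an adaptation state interpolated by a cross-adaptation
coefficient: 0 means fully unadapted (expected counts equal the deviant's
own trial-1 counts — the "response recovers" case), 1 means the deviant
inherits the repeated stimulus' full adapted state (the "cross-adapted"
case, as a chemically overlapping mixture would behave). The paper-style
neural catch design (30-trial block, catch at 26) is generated directly; a
follow-up block of the deviant alone is produced as a separate session,
since protocols carry a single trials-per-block count.

**Behavior.** Each animal's palp-opening response on trial $k$ is
Bernoulli with
$p_k = p_\infty + (p_0 - p_\infty)e^{-(k-1)/\tau}$, $p_0 = 0.15$,
$p_\infty$ = 0.6 (high) / 0.35 (low intensity), $\tau = 2$ trials — the
probability facilitates and stabilizes after about five presentations,
with high intensity settling clearly above low. On a catch trial the
deviant is scored at its own unadapted $p_0$ and the repeated stimulus'
facilitation clock does not advance.

**What the generator does not emulate.** No oscillatory synchronization or
spike-timing coherence (counts only); no biophysical membrane dynamics; no
trial-to-trial rate correlations beyond the deterministic adaptation laws
(real PNs show repeatable per-unit temporal pattern changes the Poisson
model cannot produce); no overdispersion relative to Poisson; behavioral
responses are independent across animals and trials given $p_k$. Passing
the property suite therefore demonstrates that the *analysis chain*
recovers what it is supposed to recover under these idealized conditions —
not that real recordings satisfy them.

# Tensor decomposition

`cp_als` fits $x_{ijk} = \sum_{f=1}^{F} a_{if} b_{jf} c_{kf} + e_{ijk}$ by
alternating least squares: each loading matrix is the exact least-squares
solution given the other two (Khatri–Rao normal equations, with a
pseudo-inverse fallback for rank-deficient Gram matrices), so the
reconstruction error is non-increasing by construction and is asserted
per-iteration in the tests.

Numerical choices:

* **Initialization** — uniform random non-negative factors; 10 restarts by
  default, best final fit kept. The restart-stability test (two different
  seed sets agreeing on the attained fit to $10^{-6}$) keeps this
  auditable.
* **Convergence** — relative change of the fit fraction
  $1 - \lVert E\rVert^2/\lVert X\rVert^2$ below $10^{-8}$, or 500
  iterations.
* **Indeterminacy** — columns of $A$ and $B$ are scaled to unit norm with
  all scale pushed into $C$; the largest-magnitude element of each $A$ and
  $B$ column is made positive (compensated in $C$); factors are ordered by
  decreasing $C$-column norm. Refits then differ only by genuine
  permutation/sign ambiguity, which the tests resolve by brute-force
  matching over all $F!$ permutations.
* **No constraints** — non-negativity is available as an exploratory
  switch (projected updates, monotonicity no longer guaranteed) but is off
  by default, since the analysis defines none.

**CORCONDIA.** For fixed loadings the least-squares Tucker core is
$G = X \times_1 A^{+} \times_2 B^{+} \times_3 C^{+}$, and the diagnostic is
$100\,(1 - \sum (g_{lmn} - t_{lmn})^2 / F)$ with $T$ the superdiagonal
identity core. At $F = 1$ the ALS scale optimality forces $g = 1$, so the
value is 100 by construction; it is bounded above by 100 and unbounded
below. `select_num_factors` keeps the largest candidate at or above the
threshold (default 50%, a config parameter rather than a constant, since
it is not obvious whether 50 is a principled cutoff or a description of
one dataset); if none qualifies the smallest candidate is returned with a
warning flag.

**The factor-structured benchmark.** `simulate_factor_tensor`'s default
`"neural"` style builds ground-truth factors the way block-design
ensemble data are structured: sparse gamma unit loadings with partial
overlap, smooth correlated rise–plateau–decay time profiles, and trial
loadings localized to contiguous stimulus blocks with a decaying envelope
(stimulus identity blended into the trial axis), components scaled to
equal Frobenius norm, plus iid Gaussian noise at 0.5 × the signal SD.
This structure matters: with generic iid-normal factors the best-fit
$F+1$ model can simply capture one extra noise direction, in which case
the least-squares core remains near-superdiagonal and the diagnostic stays
high however carefully ALS is run. With the block-structured factors the
over-factored fit must split correlated structure, and the diagnostic
collapses at $F = 4$ while staying high at $F = 3$ — the behavior the
rank-selection rule is built on, and what the acceptance suite measures.
The `"normal"` style is retained for exact-recovery benchmarks.

# Ensemble geometry

**Trajectories.** The denoised tensor $\hat X$ (CP reconstruction) is
unfolded along trials into an $n \times (\text{bins} \cdot \text{trials})$
series (odor-window bins only), bin vectors are centered by the global
mean over all time steps (covariance PCA — centered, unscaled), projected
onto the top-3 eigenvectors (deterministic signs), and each trial's point
sequence is smoothed with a 3-point running average, shrunk to 2-point
windows at the ends so path lengths are not truncated. Exactly constant
activity yields all-zero coordinates rather than an error; between that
degenerate extreme and full rank, fewer than three non-degenerate
covariance eigenvalues raises a degeneracy error.

Two scalar summaries are exported because the raw "mean point direction"
is misleading: global centering necessarily places weakly-responding
trials on the *opposite* side of the origin from strong ones, so the mean
point of a late trial can anti-align with trial 1 even under perfect
magnitude-only adaptation. `trajectory_path_length` tracks response
magnitude (it scales exactly with the adaptation multiplier under
magnitude-only adaptation), and `trajectory_direction_cosine` compares
trial *shapes* after removing each trial's own center — the quantity that
is literally preserved when only magnitude adapts, and the formal version
of "the trajectories shrink but keep their orientation".

**Correlation matrices, clustering, classification.** Trial vectors
default to time-averaged counts (`mean_per_bin`); window sums give
identical correlations (positive scale factor), and a concatenated per-bin
option is provided because the two descriptions of the similarity analysis
are ambiguous between them. Clustering is complete linkage on
$d = 1 - r$ via `stats::hclust` (deterministic for a given input; merge
heights verified against an exhaustive linkage oracle in the tests).
Classification — whose procedure the source analyses leave unspecified —
is implemented as leave-one-trial-out nearest-centroid with Pearson
similarity, centroids recomputed per fold; the report labels the scheme as
this package's interpretation. Chance level is verified by label
permutation.

# Behavior statistics

Per-animal response probabilities over the selected trials are paired
within animal, and intensity discriminability uses a paired left-tailed
t-test (low < high), $p$-values from the $t$ distribution with
$n_\text{pairs} - 1$ degrees of freedom. Identical pairs are defined to
sit at the symmetric null center ($t = 0$, $p = 0.5$) instead of erroring,
keeping pipelines total on degenerate fixtures. No multiple-testing
correction is applied (matching per-odor reporting); a Bonferroni divisor
is the caller's one-liner. The early/late split defaults to trial 5 —
where the facilitation curve has largely saturated — and is a parameter,
since it is unclear whether that split is principled or descriptive.
Test calibration is checked empirically: under the null generator the
rejection rate at $\alpha = 0.05$ over 1000 replicates must fall within
three binomial standard errors of 0.05.

The neural–behavioral regression (OLS of per-trial p(POR) on per-trial
total ensemble counts) reports slope and $R^2$; with decaying counts and
facilitating behavior the slope is negative. $R^2$ under a zero-variance
response is defined as 0 with a degeneracy flag rather than NaN.

**Plateau recovery.** Ensemble count timecourses are fit with
$y_k = y_\infty + (y_1 - y_\infty) e^{-(k-1)/\tau}$ by profiled least
squares (the two linear coefficients are solved in closed form on a
$\tau$ grid, then $\tau$ is refined by golden-section search —
deterministic, no starting-value sensitivity). Because baseline spikes do
not adapt, the evoked plateau is computed after subtracting the expected
baseline mass, estimated from pre-stimulus spikes
(`baseline_window_counts`); the generator emits 1 s of pre/post baseline
padding for exactly this purpose.

# Problem sizes and reproducibility

All stochastic checks fix seeds and state their scale: tensors are
80 × 80 × 25 (80 units, 80 bins, 25 trials — the dataset geometry the
protocol implies); decomposition benchmarks use 10 replicates for the
rank scan and 5 for exact recovery; ensemble-level properties use 20
replicate sessions; mechanism discrimination uses 200-unit sessions, 20
per mechanism; behavioral calibration uses 1000 null replicates of 36
animals. `scripts/acceptance.R` re-derives every headline number from a
single `--seed` in about two minutes on one CPU. On-disk artifacts are
plain text (CSV/YAML) except the tensor container, which is a named-axis
serialized R object with a format tag and full validation on read.

# Known limitations

* The Poisson generator cannot express the repeatable per-unit temporal
  pattern changes or spike-timing phenomena seen in real PNs; conclusions
  from the suite concern the analysis chain, not biology.
* CP-ALS is dense and unconstrained: no missing-data handling, no Tucker
  or sparse variants.
* The classification scheme is a stand-in for an unspecified procedure
  and is flagged as such in its report.
* The QC filter consumes precomputed sorting metrics as reported
  (including the mixed variance/SD units of the waveform criterion) and
  does not recompute them from waveforms.
* Behavior tables key on (animal, trial, stimulus); a protocol repeating
  the same stimulus label in two blocks needs distinct labels on the
  behavioral side.
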