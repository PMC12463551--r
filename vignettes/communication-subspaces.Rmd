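---
title: "Rhythm-gated communication subspaces: models, estimators, and design choices"
author: "neurocomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm-gated communication subspaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Two brain regions that cooperate during behavior — here hippocampal CA1 and
prefrontal cortex (PFC) recorded while a rat runs a W-track spatial
alternation task — do not exchange every spike. A useful abstraction is the
*communication subspace*: the low-dimensional set of source-population
activity directions whose fluctuations actually predict target-population
activity. Directions orthogonal to it are *private*: the source can move
along them without consequence downstream. `neurocomm` implements a complete
pipeline for asking three questions about this subspace:

1. **How big is it, and when?** Reduced-rank regression (RRR) with
   cross-validated rank selection, evaluated inside windows of high or low
   oscillatory state (theta power, ripple power, theta coherence, or running
   speed), with firing-rate mean-matched source/target partitions so that
   CA1→CA1 and CA1→PFC dimensionalities are comparable.
2. **What does its activity encode?** Canonical correlation analysis (CCA)
   gives a continuous temporal readout: per component a CA1 variate $U$ and
   a PFC variate $V$, rotated into *aligned* (shared, reciprocated) activity
   $(U+V)/\sqrt2$ and *local* (unreciprocated) activity $(U-V)/\sqrt2$.
   Behavioral decoders quantify what each carries.
3. **What shape does it have?** A behavior-binned pseudopopulation across
   sessions, embedded by CCA, exposes the geometry (ring-like trajectory
   manifolds) and a distance contrast quantifies their separation.

Because the real recordings cannot ship with a package, all claims are
validated on a synthetic session generator that *plants* the structures the
pipeline is supposed to find, with known ground truth.

# The estimators

## Reduced-rank regression

With z-scored count matrices $X$ ($T \times p$ source units) and $Y$
($T \times q$ targets), the full linear model is $Y = XB + \varepsilon$ with
$B_{OLS} = (X^\top X)^{-1} X^\top Y$ (pseudoinverse fallback above condition
number $10^{10}$, keeping the equation literal rather than ridge-penalized).
The rank-$m$ predictor projects the OLS predictions onto their own top $m$
principal directions: $B_{RRR}(m) = B_{OLS} V_{1:m} V_{1:m}^\top$, where $V$
holds the right singular vectors of $\hat Y = X B_{OLS}$. The prediction
space — not the coefficient matrix — is the object being truncated: among
rank-$m$ projections it is the one that minimizes training error, which is
why $V$ is defined on predictions rather than on $B_{OLS}$ itself.

Performance is the cross-validated $R^2(m) = 1 - SSE/SST$ on held-out
windows, with $SST$ taken around the training mean. Folds (5 by default) are
formed over *windows*, never over bins, because the 6 bins inside one 300 ms
window are strongly autocorrelated and splitting them across folds would
leak. The optimal dimension $\hat m$ is the smallest $m$ whose mean
$R^2(m)$ is within one standard error of the full-rank mean (the
one-standard-error rule).

## Windowing

State windows are cut from any scalar state series. "High" windows of 300 ms
open at upward crossings of the 85th percentile of the state's empirical
distribution, "low" windows at downward crossings of the 15th percentile;
crossings inside an open window are ignored. We read the percentage
thresholds as quantiles of the empirical distribution rather than fractions
of the maximum: the maximum of a band envelope is an extreme order statistic
and would make the threshold sample-size dependent and outlier-driven.
Windows overlapping between different state sets are deleted from *both*
sets (the states are peers; neither outranks the other), and counts are then
equalized across all sets by stratified subsampling over 10 equal time
segments, so that surviving windows are near-uniform over the recording.
When a stratum cannot fill its quota the deficit spills over to a uniform
draw from the remaining windows — a set confined to part of the session can
never be forced to invent coverage elsewhere.

## Mean-matched partitions

Comparing CA1→CA1 against CA1→PFC dimensionality is only meaningful if the
two target populations have the same size and rate statistics. Rates are
binned into 20 equal-width bins spanning the pooled range; each bin
contributes the minimum of the two regions' counts, drawn uniformly without
replacement. Fifty repetitions (configurable) with different random draws
give a sampling distribution over partitions; within one repetition the
same source set serves both target conditions, and the CA1 target pool is
kept disjoint from the sources.

## CCA and the aligned/orthogonal basis

Canonical weights come from the SVD of the whitened cross-covariance
$C_{xx}^{-1/2} C_{xy} C_{yy}^{-1/2}$, with a trace-scaled ridge
($\lambda = 10^{-8}$ by default) on the within-region covariances for rank
safety. CCA solutions are sign- and order-indeterminate; we fix order by
decreasing training correlation and sign so that each training correlation
is non-negative and the largest-magnitude CA1 loading per component is
positive. Cross-validation (5 contiguous time blocks, respecting
autocorrelation) yields held-out canonical correlations used for component
selection; the reported weights come from a final full-data fit, since
there is no canonical way to average fold-wise weight matrices. The
aligned/local rotation $(U \pm V)/\sqrt2$ is an isometry per component, so
row energy is conserved exactly — a property the tests assert at $10^{-12}$.

## Spectral measures

Multitaper coherence uses DPSS tapers computed from the symmetric
tridiagonal eigenproblem, 1 s windows, time–bandwidth 3, 5 tapers —
resolving theta with ~2 Hz bandwidth. With $K$ tapers the coherence of
independent signals is biased upward to roughly $1/K$, which the null tests
use as their floor. The weighted phase lag index is
$|E[\Im S_{xy}]| / E[|\Im S_{xy}|]$ across windows; it discounts zero-lag
(volume-conducted) coupling because a purely real cross-spectrum contributes
nothing to the numerator. Windows with all-zero imaginary parts are
undefined and reported missing rather than zero-filled; the debiased squared
estimator sits behind a flag. Butterworth band filters are order 4 per pass
and applied forward–backward (zero phase); band envelopes are Hilbert
magnitudes smoothed with a 100 ms boxcar.

## Decoding and model comparison

Behavioral decoders consume the top 10 aligned components and the top 10
local components as separate feature sets. Continuous behaviors use a
Student-$t$ likelihood with fixed $\nu = 4$ (a robust compromise: heavy
enough tails to shrug off outliers, finite variance), fitted by an
EM/iteratively-reweighted least squares scheme that is exactly
deterministic; binary behaviors use Bernoulli (logistic) regression.
Coefficient uncertainty is summarized by draws from the asymptotic normal
approximation around the point estimate — a deliberate substitution of a
deterministic approximation for posterior simulation, which keeps the test
suite exactly reproducible; the point estimates are what all headline
metrics use. Held-out performance is $R^2$ for continuous responses and
$F_1$ for binary ones, on a random split of 50,000 training bins (or 70%
when fewer exist; the split denominator is a free choice we document rather
than inherit).

The mixed behavior-by-theta comparison fits $R \sim B$, $R \sim \theta$,
$R \sim B + \theta$, $R \sim B * \theta$ per (animal × epoch × behavior)
split, plus a grouped-intercept variant $R \sim B + \theta + (1\,|\,\text{
animal:epoch})$ on the pooled data via `lme4`, reporting $R^2$ and AIC with
confidence intervals across splits and the per-split AIC winner.

## Manifold geometry

The pseudopopulation has one row per behavioral state (trajectory direction
× turn × linearized-distance bin; 100 bins by default) and one column per
neuron, concatenated across sessions as if simultaneously recorded. Columns
are z-scored across states before the super-animal CCA (rate-scale
invariance across animals); unoccupied states are filled by linear
interpolation along distance within trajectory type, which keeps rows
aligned across animals — dropping rows would misalign the manifolds.
Neuron ordering cannot affect CCA, and a test asserts embedding invariance
under within-block column permutation.

For the ring contrast, each trajectory type traces one manifold. "Between"
distances join states at the same linear-distance bin on different
manifolds; "within" distances join consecutive distance bins along the same
manifold — the local step size of a ring. On two parallel rings offset by
$d$ this statistic recovers $d$ (a constructed-geometry test asserts it),
and on planted trajectory-specific loadings the between/within difference
is strongly positive (rank-sum test). The mean over a ring of same-bin
distances *within* one manifold is degenerate (each state appears once per
manifold), which is why the step-size definition is the meaningful
within-manifold scale at this resolution.

# The synthetic session generator

The generator is first-class, tested code; its defaults *are* the study
conditions the tests and the acceptance script run under.

- **Session structure**: eight 900 s run epochs in one day, behavior sampled
  at 30 samples/s, spike counts on a 50 ms grid, LFP at 1.5 kHz.
- **Behavior**: trials cycle the four W-track trajectory types (C-to-L,
  L-to-C, C-to-R, R-to-C); linearized position runs 0 (center well) to 1
  (side well) with a raised-cosine traverse occupying 60% of each trial
  (`move_frac`, which in turn sets the theta-gate duty cycle); velocity and
  acceleration are smoothed derivatives of the 2-D path over an 80 × 80 cm
  three-arm geometry; IdPhi — the integrated absolute heading change used to
  index vicarious trial and error — is planted directly: baseline noise plus
  a bump in the choice zone (linearized 0.45–0.65) on 25% of outbound
  trials; correct/error labels follow a per-epoch accuracy ramp 0.55 → 0.95,
  a plausible single-day learning curve.
- **Latents**: shared latents are AR(1) with coefficient 0.8 per 50 ms bin —
  smooth but stationary; nothing in the analyses assumes this form, it is
  simply the simplest latent with realistic autocorrelation. The planted
  communication rank is 3; the shared-latent gain is 2.0 in theta-high bins
  and 0.5 in theta-low bins, which is what makes the high/low performance
  contrast a recoverable ground truth. Each region additionally has 3
  private AR(1) latents.
- **Rates and spikes**: per-bin log-rates are
  $\log r = \text{base} + L\,[g(\text{gate})\,z_{shared};\,z_{private}]$
  plus behavior couplings; counts are Poisson, spike times uniform within
  their bin. Base rates are log-uniform on 2–10 Hz. Loadings are Gaussian
  with sd 0.2 on the log scale, so typical rate excursions stay within about
  $e^{\pm 1}$ — a physiological modulation depth. This number matters more
  than it looks: the exponential link makes spike counts a *nonlinear*
  function of the latents, so a linear method sees harmonics of the planted
  latents as extra weak dimensions. At modulation depths far above ~1 the
  cross-validated rank estimator, given enough windows, correctly starts
  resolving those harmonics and $\hat m$ drifts above the planted rank — not
  an estimator failure but a property of the generative nonlinearity. At
  sd 0.2 the linear approximation holds and $\hat m$ concentrates on
  3 ± 1. Windowed CA1→PFC $R^2$ lands around 0.05–0.2, the range typical of
  real cortical communication-subspace fits.
- **Behavior coupling**: by default linearized position enters shared latent
  1's loading columns as a separate, un-gated log-rate term with strength
  2.5 (in latent sd units) — reciprocated across regions, hence decodable
  from aligned activity. The `behavior_target = "private"` negative control
  routes the same signal in *antiphase* through the two regions' loading
  columns: motion along each region's communication axis that the other
  region does not reciprocate, which is precisely what the local axis
  $(U-V)/\sqrt2$ measures. The control's strength must stay below the
  effective gated shared gain (we use 1.5): a dominant antiphase signal
  would itself become the maximally correlated direction, CCA would flip one
  region's sign, and the planted signal would re-label itself as shared.
- **LFP**: an amplitude-modulated theta carrier (envelope tied to movement
  bouts — this defines the gate), ripple bursts (100 ms Hann-windowed
  packets at 180 Hz, Poisson rate 0.1/s during stillness, attenuated 0.3×
  in PFC), a delta carrier, and 1/f noise. The PFC theta component lags CA1
  by `phase_lag_rad` (default π/4), verified by analytic-signal phase in the
  tests. The continuous theta drive also carries small Gaussian jitter
  (sd 0.05) so that its quantiles — and therefore threshold-triggered
  windows — are well defined even during long behavioral plateaus.
- **Determinism**: one master seed feeds named substreams per generator
  stage, so regenerating one component never perturbs another, and identical
  (config, seed) reproduce byte-identical sessions.

## What the generator does and does not emulate

It emulates the *statistical skeleton* the pipeline's claims rest on:
low-rank shared variability, state-gated gain, behaviorally coupled shared
activity, band-structured LFP with a controllable lag, and W-track trial
structure. It does not emulate place-field shapes, theta phase precession,
spike-sorting artifacts, nonstationary rates across epochs, or sleep states.
Consequently, passing tests demonstrate that the estimators recover what
they claim to recover *when the generative assumptions hold approximately*;
they do not demonstrate that real CA1–PFC data satisfy those assumptions.

# Numerical choices and degenerate inputs

- OLS falls back to a Moore–Penrose pseudoinverse above condition number
  $10^{10}$; CCA uses a trace-scaled ridge instead because whitening is
  intrinsically inversion-heavy.
- Zero-variance units at z-scoring time become all-zero columns and are
  flagged, not dropped, preserving unit alignment.
- Constant state series produce empty window sets with a warning; empty
  window sets abort balancing with an error naming the state.
- The Mann–Kendall test switches to exact enumeration of the permutation
  null for $n \le 10$ without ties; with ties it uses the tie-corrected
  normal approximation with continuity correction.
- WPLI windows with all-zero imaginary cross-spectra are missing, not zero.
- Bootstrap intervals are balanced: every group (animal) contributes equal
  samples per draw, so a data-rich animal cannot dominate an epoch mean.
- The final rate-histogram bin is right-closed so the maximum-rate unit is
  always assigned to a bin.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make the recoveries statistically comfortable while
staying desk-scale: rank-recovery and decoding sessions use 20,000 bins
(two 500 s epochs) at 30 + 20 units, CCA recovery uses 50,000 bins at
8 + 8 channels, the manifold session uses 600 s with trajectory-specific
couplings, and LFP-dependent checks use one- to two-minute traces at
1.5 kHz. Twenty seeds back the rank-recovery and state-contrast claims in
the test suite; the acceptance script reports the same quantities over ten.

# Known limitations

- All analyses are linear: strong generative nonlinearity (large modulation
  depth) inflates apparent dimensionality under any linear method, a caveat
  that applies equally to real spiking data with multiplicative gain.
- The MCMC route for decoder uncertainty is not implemented; intervals are
  asymptotic. Point estimates and held-out metrics — everything the
  package's claims rest on — are unaffected.
- Ingestion of NWB recordings is out of scope; sessions enter either from
  the generator or from the plain-text session directory format
  (`writeSession()`/`readSession()`).
- The spectral stack assumes equal sample rates across regions and does not
  implement phase–amplitude coupling or directed measures.
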