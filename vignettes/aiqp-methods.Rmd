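---
title: "Estimating abnormal intra-QRS potentials with an RBF network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating abnormal intra-QRS potentials with an RBF network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiqp)
```

## The estimation problem

An abnormal intra-QRS potential (AIQP) is a random, low-amplitude
(single-digit µV), high-frequency signal superimposed on a QRS complex whose
own amplitude is two orders of magnitude larger. There is no reference
"clean" QRS for a given patient, so the AIQP cannot be obtained by
subtraction of a template; instead the normal wave must be *modelled* and
the AIQP read off as the modelling residual. The model used here is a radial
basis function network,

$$\hat y(n) = \sum_{j=1}^{M} w_j\,\exp\!\left(-\frac{(n-c_j)^2}{2\sigma^2}\right),
\qquad n = 1,\dots,p,$$

with all $M$ Gaussian neurons sharing one spread $\sigma$. The shared spread
is the crux: the basis has a single, controllable smoothness, so the network
can only synthesize structure at least as smooth as $\sigma$, and anything
sharper — the AIQP — is forced into the residual $e = y - \hat y$.
Conceptually the network is a special-purpose filter whose passband is set
by $\sigma$ once $M$ is fixed.

Two residual statistics are reported: the AIQP amplitude
$\mathrm{AIQP} = \sqrt{\tfrac1p\sum_n e^2(n)}$ (µV) and the AIQP-to-QRS
ratio $\mathrm{AQR} = \mathrm{AIQP} / \sqrt{\tfrac1p\sum_n y^2(n)}$. The
ratio matters because the approximation error of the fitted network scales
in proportion to the QRS amplitude (doubling $y$ exactly doubles the
residual, a property the test suite asserts at $10^{-9}$ relative), so raw
AIQP values are not comparable between subjects with different QRS
amplitudes while AQR values are.

## Center selection by orthogonal least squares

Given $(M, \sigma)$, center locations are selected from the candidate set of
*all* integer sample positions $1..p$ by greedy forward selection. At step
$L$, every remaining candidate's RBF column $\phi_k$ is orthogonalized
against the $L-1$ accepted orthogonal vectors $s_1,\dots,s_{L-1}$ (classical
Gram-Schmidt, recomputed from the original column each step), and its error
reduction ratio

$$[\mathrm{err}]_k = \frac{(s_k^\top y)^2}{(s_k^\top s_k)(y^\top y)}$$

— the fraction of signal energy that candidate would explain — is evaluated;
the maximizer is accepted. The error reduction ratios of the accepted
sequence satisfy the energy decomposition
$\sum_L g_L^2 h_L + e^\top e = y^\top y$ with $g_L = s_L^\top y / h_L$ and
$h_L = s_L^\top s_L$, which the suite checks to $10^{-9}$ relative on every
traced fit. The greedy sequence is also verified, over hundreds of random
instances, to coincide with an exhaustive oracle that refits the full
least-squares problem for every candidate and takes the largest SSE
decrease.

Numerical choices, all of which were genuinely open:

* **Tie-breaking.** Candidates whose ratios agree within $10^{-12}$
  relative tie toward the smaller sample index, making selection
  deterministic across platforms.
* **Re-orthogonalization.** The accepted vector receives a second
  Gram-Schmidt pass against the selected basis. Classical single-pass GS
  loses orthogonality on near-dependent candidate sets (large $\sigma$,
  short windows), which would corrupt the traced energy decomposition;
  one extra pass restores it to rounding level without affecting which
  candidate wins.
* **Dependence guard.** A candidate whose orthogonalized vector retains
  less than $10^{-12}$ of its original squared norm is excluded from that
  step; if all remaining candidates are dependent before $M$ centers are
  placed, a partial-selection error carrying the partial model is raised.
  The guard exists to prevent division by (numerical) zero in the gain and
  ratio formulas. A more conservative threshold ($10^{-10}$) was tried
  first and rejected: with the re-orthogonalized basis the ratio statistic
  is still accurate well below that level, and the conservative guard
  occasionally excluded a candidate whose energy contribution was real and
  maximal, breaking agreement with the exhaustive oracle.
* **Final weights.** Weights are re-solved on the selected design matrix by
  SVD pseudo-inverse (relative singular-value cutoff $10^{-10}$) rather
  than back-substituted through the triangular Gram-Schmidt factors. The
  two are equivalent in exact arithmetic; the direct solve is more robust,
  and the triangular coefficients remain available in the trace.
* **One neuron per sample.** When $M = p$ every location is a center and
  greedy selection is neither needed nor numerically possible (the full
  Gaussian design is rank deficient in double precision long before $p$
  columns are orthogonalized). `fit_rbfnn()` therefore places centers
  $1..p$ directly and lets the pseudo-inverse absorb the conditioning; no
  OLS trace is produced in this case. This "maximum number of neurons"
  configuration is the interpolation limit the test suite checks
  (AQR $< 10^{-4}$ on the default synthetic QRS for
  $\sigma \in \{2, 5, 10\}$); it is useful as a sanity bound, not for
  diagnosis, since it absorbs the AIQP along with the normal wave.

`aqr_grid()` exploits the nesting of greedy selection: for each $\sigma$ one
selection at $\max(M)$ is run and smaller neuron counts reuse its leading
centers with re-solved weights, which is exactly equivalent to independent
fits. Grid cells whose selection degenerates are recorded as missing — not
zero, which would bias a downstream discriminant toward the degenerate
configuration; the discriminant instead drops incomplete subjects.

## What the synthetic data emulates

No public recordings of this kind exist, so the package carries a simulator
whose defaults define the conditions of its own studies.

* **Normal QRS** (`simulate_qrs()`): a sum of Gaussian lobes over a 200
  sample (100 ms at 2000 Hz) window — a tri-phasic Q-R-S wave with ~600 µV
  RMS, inside the 380–730 µV range of real signal-averaged leads — plus a
  ±60 µV alternating lobe train forming a ~150 Hz narrow-band ripple. The
  ripple stands in for the high-frequency detail of real QRS complexes: it
  leaves an inherent approximation error of about 5.5 µV (AQR ≈ 0.9%) under
  a 20-neuron, spread-10 network, matching the few-µV inherent error
  observed on real recordings, while remaining inside the numerical span of
  the full $\sigma = 10$ design so the interpolation limit stays reachable.
* **AIQP** (`simulate_aiqp_noise()`): white Gaussian noise filtered forward
  through a 40–250 Hz Butterworth band-pass (analog prototype order 4),
  generated 512 samples long on each side of the target window and trimmed,
  then rescaled so the empirical RMS hits the target *exactly* per
  realization — the studies fix noise amplitude by design, and exact
  scaling removes a nuisance source of between-repetition variance.
* **Cohorts** (`simulate_cohort()`): 42 normal and 30 VT subjects by
  default, three leads each (amplitude- and timing-offset variants of the
  same template), 5% relative jitter on every lobe parameter, per-lead QRS
  RMS drawn uniformly from 380–730 µV, and subject-level AIQP RMS drawn
  from a truncated normal — mean 10 µV (SD 2) for VT subjects, zero for
  normals.

What the simulator does *not* emulate: P/T waves, baseline wander, beat
segmentation from continuous recordings, inter-subject QRS duration
variability, or VLPs at the QRS offset. Passing tests therefore demonstrate
the estimator's behavior under its stated noise model — not clinical
performance; the clean separation achieved on simulated cohorts (TPA near
100%) reflects the simulator's idealized within-group homogeneity, and real
populations are far harder.

Every stochastic routine takes a master seed and derives per-repetition /
per-subject substreams as `(master * 69069 + i) mod 2147483647`, so
extending a study (more repetitions, more subjects) never reshuffles the
realizations already drawn.

## The repetition study and misjudgments

`repetition_study()` formalizes why a single AQR can mislead: the clean QRS
is fitted once, then in each repetition a fresh colored-noise AIQP of fixed
RMS (5 µV by default) is added and the change in residual RMS recorded. The
change is defined as the difference of residual *RMS* values (not SSE),
which keeps it in µV. Because the inherent error and the injected AIQP add
in phase or out of phase at random, individual repetitions can show a
*negative* change — a misjudgment in which the AIQP's presence would be
missed. Networks with different spreads (e.g. spread 10 vs 12) misjudge
different repetitions, so multiple AQR parameters are complementary; the
suite asserts this on a fixed seed family with 50 repetitions per study.

## Preprocessing and VLP indices

The standard chain is provided for completeness: cross-correlation beat
alignment with a 0.98 peak-correlation rejection gate and pointwise
averaging (noise falls as $1/\sqrt N$); zero-phase ("bidirectional")
Butterworth band-pass filtering implemented as a forward and a backward pass
— the magnitude response is squared, so band-edge gain is 1/2 rather than
$1/\sqrt2$ — with odd-reflection padding of three filter lengths to suppress
edge transients; the vector magnitude $\sqrt{x^2+y^2+z^2}$; QRS boundary
detection by a noise-window threshold (mean + 3 SD, 5 ms sustain); and
fQRSD, RMS40 and LAS40. "Fourth order" filters mean analog prototype order
4 before the band-pass transformation, i.e. an order-8 transfer function —
conventions differ between tools, so the package states its own. The LAS40
amplitude threshold defaults to the standard 40 µV and is a parameter.
SAECG quality gating (e.g. requiring noise below 0.7 µV) is left to the
user: the detected noise RMS is exposed rather than enforced.

## Classification

Fisher linear discriminant analysis with the pooled within-class covariance
is used exactly because the feature sets of interest — e.g. the 60-feature
combination AQR(2:40, 10) over three leads on 72 subjects — make the pooled
covariance singular; it is pseudo-inverted (relative tolerance $10^{-10}$)
and a warning names collinear columns. VT is the positive class:
specificity is measured on normals, sensitivity on VT patients. The score
cutoff maximizes training-set total prediction accuracy, ties toward higher
specificity, then toward the smaller cutoff; performance is *apparent*
(training-set) performance, matching how multi-parameter combinations are
conventionally reported in this literature — no cross-validation is applied,
and with 60 correlated features on 72 subjects the apparent figures are
optimistic by construction. AUC is the normalized Mann-Whitney statistic
with ties credited one half, identical to the trapezoidal area under the
empirical ROC.

## Problem sizes

The package's own studies use the default 200-sample window, 50-repetition
detection studies, and 42/30-subject cohorts with the 60-feature grid —
sizes at which a full cohort analysis completes in seconds on one core.
Random-instance checks (greedy-oracle agreement, ROC oracles) run at
$p \le 32$, $M \le 6$, where exhaustive refitting is cheap.

## Known limitations

* The optimal $(M, \sigma)$ is unknown and subject-dependent; any fixed
  choice over- or under-estimates the AIQP for some subjects. Combining
  grids mitigates but does not remove this.
* The residual always mixes true AIQP with inherent approximation error;
  the two cannot be separated for an individual record.
* Greedy OLS selection is not globally optimal for a given $M$; it is,
  however, exactly the nested sequence the AQR grids rely on.
* Large spreads on short windows exhaust the numerically independent
  candidates early; such configurations return partial selections
  (surfaced as missing grid cells) by design.
* Simulated cohorts are idealized (see above); clinical figures cannot be
  inferred from them.
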