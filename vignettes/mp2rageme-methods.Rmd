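---
title: "Signal model and quantification methods in mp2rageme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model and quantification methods in mp2rageme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mp2rageme)
```

## The sequence and its signal model

MP2RAGE-family sequences acquire two spoiled gradient-echo (FLASH) readout
blocks after a single adiabatic inversion pulse, repeating the
inversion--readout--readout cycle until k-space is filled. The ratio
combination of the two block images,

$$\mathrm{UNI} = \frac{S_1 S_2}{S_1^2 + S_2^2} \in [-0.5, 0.5],$$

cancels proton density, receive-field and -- when the combined echoes have
matched TE -- T2\* weighting, leaving a T1-weighted image with only a
residual dependence on the transmit field $B_1^+$. The MP2RAGEME variant
extends the second block to several echoes, so the same scan additionally
yields a multi-echo decay for T2\* mapping and phase data for
susceptibility processing (the latter is outside this package's scope).

`mp2rageme` models the longitudinal magnetization of one cycle as a
composition of affine maps $M_z \mapsto A M_z + B$ (normalized to
$M_0 = 1$):

* inversion: $(A, B) = (-\epsilon, 0)$ with efficiency $\epsilon$;
* free relaxation over $t$: $(E, 1-E)$, $E = e^{-t/T_1}$;
* one excitation-plus-TR period: $(\cos\alpha\, E, 1-E)$.

The $n$ identical periods of a block compose in closed form to
$(A^n,\, B\,\tfrac{1-A^n}{1-A})$, so the cycle map and its fixed point (the
periodic steady state) are exact -- there is no time discretization
anywhere in the model. Echo signals are read at the centre excitation of
each block, $S = M_0 \sin(\alpha)\, M_z\, e^{-TE/T_2^*}$, consistent with
linear (sequential) phase-encode ordering in which the centre of k-space is
acquired at the nominal inversion time. Transverse magnetization is assumed
perfectly spoiled between excitations, the inversion pulse has zero
duration, and the transmit-field factor $b_1$ scales the excitation flip
angles only -- the inversion is adiabatic and unaffected. These are the
standard assumptions under which the MP2RAGE steady state is derived;
`validate_protocol()` additionally checks that the three relaxation gaps
TA/TB/TC around the blocks are nonnegative and partition the cycle TR
exactly.

The test suite validates the closed-form model against an independent
time-marching Bloch integrator (sub-millisecond steps, exact relaxation per
step, instantaneous flips at the exact event times); agreement is within
$10^{-6}$ relative (measured: $10^{-13}$) for both bundled protocols across
T1 from 0.5 to 4 s and transmit factors 0.8--1.2.

## Protocols and tunable parameters

Two inversion-recovery protocols ship as YAML fixtures
(`example_protocol()`): the multi-echo protocol (cycle TR 6.72 s, block TRs
6.2/31.4 ms, TE 3 and 3/11.5/20/28.5 ms, TI 670/3855 ms, flips 7/6°, 150
lines, 147 readouts) and the single-echo reference protocol (cycle TR 6 s,
both block TRs 6.2 ms, TI 1000/3200 ms, same flips and line counts),
plus a plain multi-echo FLASH protocol (TR 31.4 ms, 12°) for SNR
comparisons. Timing is handled internally in milliseconds; only the cycle
TR is specified in seconds, matching how protocols are printed.

`inv_efficiency` defaults to 0.96 in `protocol_params()` -- a typical
adiabatic value -- but the bundled fixtures and all desk simulations use
1.0 (ideal inversion), since the residual-correction framing of the method
treats the inversion as ideal and no measured value is available.

`timing_audit()` reports the scan duration and *two* dead-time figures: the
total of the three relaxation gaps relative to the cycle TR, and the tail
gap TC alone. Neither definition reproduces the dead-time percentages
usually quoted for these protocols (6% multi-echo, ~50% single-echo); for
the bundled protocols they evaluate to 16.1%/7.6% and 69.0%/38.9%
respectively. Because the published definition is ambiguous, both are
reported and neither is asserted in the tests.

## Lookup-table T1 estimation and transmit-field correction

`build_lookup()` tabulates the forward model on a T1 grid of 0.1--6 s at
1 ms steps and a B1 grid of 0.6--1.4 at 0.01 steps (defaults chosen for
sub-millisecond quantization error and generous margin around the realistic
0.8--1.2 transmit span at 7 T). Per B1 column the strictly decreasing
branch of UNI versus T1 is identified; the short-T1 fold-over tail is
excluded, and a protocol whose columns are non-monotone over most of the
grid is rejected outright.

Decoding (`lookup_t1()`, `t1_from_uni()`) interpolates the two
neighbouring B1 columns linearly at each voxel's transmit factor and
inverts the monotone branch by vectorized bisection, with linear
interpolation inside the bracketing 1-ms cell. A monotone spline was
considered for the inversion but would have required quantizing B1 to keep
one spline per quantization bin tractable, and that quantization -- not the
interpolant -- dominated the error budget (several ms at long T1). The
bisection decode is exact in B1: the measured worst-case decoding error is
0.74 ms for continuous B1 in [0.8, 1.2] (dominated by the 0.01 column
spacing) and below $10^{-9}$ ms when B1 lies on a column. Out-of-branch
intensities clamp to the branch ends and clear the validity mask, which
resolves ambiguous intensities conservatively to the long-T1 branch while
flagging them.

Low-resolution transmit-field maps are median-smoothed (3-voxel cube) and
trilinearly resampled onto the UNI grid before decoding; when no map is
available the pipeline decodes at nominal transmit and warns prominently.

## T2\* fitting

`t2star_fit()` uses signal-weighted log-linear least squares (weights
$S^2$), the standard fast estimator for mono-exponential decay; it is exact
on noiseless model-matched data for any T2\* and leaves the median estimate
within 5% under Rician noise at SNR 30 (tested by Monte Carlo). Voxels with
non-decaying signal, all-zero signal or fewer than two usable echoes are
flagged invalid rather than raising errors. Optional per-voxel nonlinear
refinement sits behind a flag (`nonlinear = TRUE`); it is not the default
because the log-linear path is deterministic and an order of magnitude
faster, which matters for volumes. When a background-noise SD is supplied,
echoes below three times that SD are dropped per voxel (always retaining
the two strongest), which debiases fits in low-SNR tissue.

## Transmit-field sensitivity study

`contrast_curves()`, `intensity_range()` and `apparent_t1()` reproduce the
classic $B_1^+$ sensitivity analysis: UNI curves over T1 at transmit
factors 0.8/1.0/1.2, the intensity spread at a reference T1, and the biased
T1 obtained by decoding a shifted intensity through the nominal lookup
column. For white matter (T1 1.15 s) the bundled multi-echo protocol shows
a UNI spread of 0.110 versus 0.056 for the single-echo protocol -- the
multi-echo protocol's shorter first inversion time buys speed at the cost
of roughly doubled transmit sensitivity. The corresponding apparent-T1
spans are 1.037--1.287 s versus 1.081--1.215 s. Published figures for this
experiment quote wider apparent-T1 spans (0.9--1.4 s and 1.0--1.3 s); those
spans are arithmetically inconsistent with the intensity spreads quoted
alongside them (which this package reproduces), since decoding a 0.11-wide
intensity interval through a curve whose local slope is about 0.44 AU/s
cannot move T1 by half a second. The package reports what the model
computes and the acceptance assertions on those two extremes are left
failing rather than tuned.

The reference tissue T1s for this study (WM 1.15 s, GM 1.85 s, CSF 4.0 s,
`simulation_tissues()`) are the ones used in the blurring experiment, kept
identical across both desk studies for internal consistency. B1 is sampled
at exactly the three printed factors; ranges are max minus min over that
three-point set, not over a continuum.

## Segmented k-space blurring simulation

`simulate_segmented_acquisition()` implements the line-by-line experiment:
a centred square of one tissue inside another (default 21 voxels in a
150-square grid, matching the protocol's 150 phase-encode lines), one image
per excitation rendered from the per-excitation steady-state signals,
Fourier transform along the phase-encode axis only, k-space line $i$ taken
from excitation $i$ of its block (sequential ordering, centre line at the
centre excitation), inverse transform, and UNI combination of the two
complex block images. Signals keep the sign of $M_z$ throughout; no
magnitude operation precedes the combination. The readout axis is treated
as fully sampled within each excitation, so blurring can only appear along
the phase encode -- the readout-direction profile stays two-level. The
phase-encode ordering is a modelling choice (the experiment's source does
not state it); sequential ordering is what makes the TI-at-block-centre
convention self-consistent.

Two numerical subtleties are worth recording. First, background-only
columns reconstruct exactly (only the DC line of a constant column is
nonzero), but foreground-plateau columns carry a small constant offset
(about $2\times10^{-4}$ UNI units, 0.1% of the tissue contrast) because
the signal-weighted point-spread function does not integrate to exactly one
over the 21-voxel square. This is a genuine property of segmented k-space,
visible identically in both profile directions, and should not be mistaken
for readout blurring; the frozen-magnetization control (`frozen = TRUE`),
which replaces every excitation's signal by the centre value, reconstructs
exactly and attributes all deviations to signal evolution. Second, the
blurring metric `blur_pct` is the maximum deviation at the four
boundary-adjacent voxels of the phase-encode profile, in percent of the
closed-form UNI difference between the tissues: 2.1% for the gray-matter
square in white matter under the multi-echo protocol, growing with the T1
difference across the boundary (4.2% for the CSF background) and an order
of magnitude smaller for the single-echo protocol's longer first inversion
time. The square size is a parameter: the experiment is described with a
21-voxel square in its methods text and a 30-voxel square in its figure;
both run, the default follows the methods text.

The simulation is noise-free by design -- the published claim is that the
contrast-to-noise required to *see* this blurring exceeds what 0.6-mm
acquisitions achieve, so the deterministic deviation is the quantity of
interest.

## Synthetic phantom and pipeline

`generate_phantom()` builds a nested-ellipsoid head: a CSF shell, a
cortical gray-matter shell, a white-matter core containing two CSF
ventricles and six bilateral deep-gray nuclei. Default tissue T1/T2\*
values are the in-vivo medians measured with this sequence family at 7 T
(e.g. WM 1.19 s/26.7 ms, GM 2.00 s/32.4 ms); relative proton densities are
conventional values (WM 0.70, GM 0.82, CSF 1.00), and CSF T2\* is a nominal
100 ms since a mono-exponential fit is not meaningful in free fluid. The
transmit field is a radial quadratic peaking at the centre (range 0.8--1.2
by default), emulating a head-coil transmit profile; phase is a smooth
synthetic field growing linearly with TE so that outputs are
format-complete for downstream phase processing, with no susceptibility
physics behind it. Noise is i.i.d. Gaussian on both complex channels
(magnitude therefore Rician) with SD equal to the white-matter first-echo
signal of the second block divided by the configured SNR. A seed fully
determines the output and the session RNG is restored afterwards.

What passing the recovery tests shows -- and what it does not: the phantom
is model-matched (its signals come from the same forward model the lookup
inverts), so parameter recovery validates the estimation chain
(combination, inversion, resampling, fitting, summarization) under
realistic noise, not the physics of real acquisitions. Real data add
imperfect spoiling, off-resonance, motion, partial volume and
reconstruction filters that the phantom deliberately omits.

`run_pipeline()` ties the stages together from a YAML or list
configuration and writes NIfTI maps, a per-region CSV and a structured JSON
log. When two sources are configured it computes Bland--Altman agreement
between their T1 maps at the region level (median per labelled region), the
conventional unit of comparison for quantitative maps; the voxel level is
used only when no labels exist. The KS normality check in `bland_altman()`
standardizes by the sample mean and SD, so its p-value carries the usual
Lilliefors caveat.

## Problem sizes and runtime

The defaults used in the tests are a 5901 x 81 lookup table (seconds to
build), 150-line blurring simulations (about a second each) and 32³--48³
phantoms (a full pipeline run takes a couple of seconds). These sizes were
chosen so that every property is exercised at full fidelity -- the lookup
grid, line count and noise level are the study conditions themselves, not
scaled-down stand-ins; only the phantom grid is smaller than a real
320 x 320 x 256 acquisition, which affects voxel counts per region but not
the per-voxel physics.

## Known limitations

* No parallel-imaging sampling, partial Fourier or k-space windowing; the
  blurring simulation encodes one line per excitation along one axis.
* No QSM: phase volumes are synthetic and only format-complete.
* The inversion is ideal (efficiency-independent of B1); protocols relying
  on non-adiabatic inversions would need a B1-dependent efficiency model.
* The FLASH model assumes ideal spoiling; imperfect spoiling biases very
  short-TR protocols in ways the model does not capture.
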