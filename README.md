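# mp2rageme

Bloch simulation and quantitative T1/T2\* mapping for the MP2RAGEME
sequence family in R.

## The problem

MP2RAGE is the workhorse T1-mapping sequence at 7 T: two spoiled
gradient-echo (FLASH) readout blocks follow each adiabatic inversion, and
their ratio combination

UNI = S1·S2 / (S1² + S2²) ∈ [−0.5, 0.5]

is free of proton-density, receive-field and (with matched echo times) T2\*
weighting, so T1 can be estimated by inverting a lookup table of the
sequence's Bloch signal model. MP2RAGEME extends the second readout block
to multiple echoes, filling the sequence's dead time so that T1, T2\* and
susceptibility-weighted phase data come out of a single, intrinsically
coregistered scan. The price is a residual sensitivity to the transmit
field (B1+), which must be removed using a separately acquired
low-resolution B1 map, and some T1-driven blurring along the phase-encode
direction of the segmented readout.

This package is for MR physicists and quantitative-neuroimaging
methodologists who need to

* simulate the periodic steady state of MP2RAGE-family protocols (exact
  affine fixed point, no time stepping),
* build and invert (UNI, B1) → T1 lookup tables with transmit-field
  correction,
* fit mono-exponential T2\* from multi-echo magnitude volumes,
* quantify a protocol's B1 sensitivity (intensity spread, apparent-T1
  bias) and its T1-induced point-spread-function blurring in segmented
  k-space,
* validate the whole chain on a synthetic 3-D multi-tissue phantom with
  Rician noise, with NIfTI-1 input/output.

## Worked example

```r
library(mp2rageme)

p <- example_protocol("mp2rageme")
p
#> MP2RAGE-family protocol 'MP2RAGEME'
#>   cycle TR 6.720 s, 150 lines x 147 readouts
#>   block 1: TI 670 ms, TR 6.2 ms, TE 3.0 ms, flip 7.0 deg
#>   block 2: TI 3855 ms, TR 31.4 ms, TE 3/11.5/20/28.5 ms, flip 6.0 deg
#>   gaps TA/TB/TC = 205/365/510 ms, inversion efficiency 1.00

simulate_cycle(p, simulation_tissues()$wm)
#> echo signals, protocol 'MP2RAGEME', tissue 'WM' (T1 1.150 s), B1 1.00
#>   s1 = 0.00291; s2 = 0.05256, 0.03823, 0.02781, 0.02023
#>   UNI = 0.05520
```

The four second-block signals decay with the echo times (T2\* weighting);
the UNI value 0.055 is what white matter contributes to the combined
T1-weighted image. A full phantom-to-maps run:

```r
res <- run_pipeline(list(protocol = "mp2rageme",
                         phantom = list(grid_shape = c(32, 32, 32),
                                        snr = 30, seed = 1)))
subset(res$roi, n_t1 > 200,
       select = c(name, n_t1, median_t1, median_t2star))
#>  name n_t1 median_t1 median_t2star
#>    WM 5574  1.188333      26.92398
#>    GM 4184  1.997241      32.58806
#>   CSF 4016  3.974330     100.66174
```

The phantom generated white matter at T1 = 1.19 s and T2\* = 26.7 ms; the
pipeline (UNI combination, lookup inversion with B1 correction, log-linear
multi-echo fit, per-region medians) recovers the generating values to well
within the noise at SNR 30.

Protocol-level audits are one-liners:

```r
timing_audit(p)[c("scan_duration", "dead_fraction_total", "dead_fraction_tail")]
#> 987.84 s (16:28), 16.1 %, 7.6 %
snr_ratio(6, 12, 31.4, 1.15)   # 6 deg readout vs the 12 deg Ernst angle, WM
#> 0.751
```

A thin command-line wrapper is installed as `exec/mp2rageme` with
subcommands `phantom`, `fit`, `psf-sim` and `b1-sim`.

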