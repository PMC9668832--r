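---
title: "Backbone dynamics and ligand-binding analytics with relaxmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone dynamics and ligand-binding analytics with relaxmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxmf)
```

## What the package models

relaxmf interprets backbone amide ^15^N spin relaxation of homodimeric
proteins measured at two magnetic fields, and provides the ligand-NMR
analytics (chemical shift perturbations, screening triage, K~d~ fitting)
that together link a protein's backbone dynamics to its ability to bind
small molecules. The motivating system is the BTB domain family:
C2-symmetric dimers of roughly 13 kDa per protomer whose members differ
strikingly in ligandability despite conserved folds, with
microsecond–millisecond dynamics as the distinguishing feature.

Three observables per residue and field — the longitudinal rate R~1~, the
transverse rate R~2~ and the heteronuclear NOE — are linear combinations
of the spectral density J(ω) of the N–H bond reorientation at five
frequencies, through the standard dipolar + CSA relaxation expressions
(see `predict_observables()`; the conventions d² = (μ₀ħγ~H~γ~N~/4πr³)²
with D = d²/4, and C = c² = (ω~N~Δσ)²/3 are fixed in `nmr_constants()`
and shared by every stage). Defaults: r~NH~ = 1.02 Å, Δσ = −160 ppm,
γ~H~ = 2.6752218744×10⁸, γ~N~ = −2.7126×10⁷ rad s⁻¹ T⁻¹; all
configurable.

## Reduced spectral density mapping and the consistency ratio

`reduced_spectral_density()` inverts one field's (R~1~, R~2~, NOE) into
J(0), J(ω~N~) and J(0.87ω~H~) using the single high-frequency reduction:
the three high-frequency densities J(ω~H~±ω~N~), J(ω~H~) are represented
by one value at 0.87ω~H~. The reduction makes J(0) *apparent*: any
exchange contribution R~ex~ to R~2~ inflates it. Because fast-limit
exchange scales with the square of the field while the true J(0) does
not, the ratio of apparent J(0) between two fields —

RC = J(0)~app~(950) / J(0)~app~(700)

— sits at 1 for exchange-free residues and rises above 1 when μs–ms
exchange is present. We define RC as high-field over low-field (one
number per residue); the definition is recorded in the output metadata.
Uncertainties are propagated by Monte-Carlo resampling of the
observables (1000 Gaussian draws by default, fixed seed), and a residue
is flagged for exchange when RC > 1 + 2·RC~err~.

The reduction is an approximation: for a rigid rotor with τ~c~ between
4 and 20 ns the recovered J(0) deviates from (2/5)τ~c~ by well under 5%,
and the deviation largely cancels in the two-field ratio, so RC stays
within 0.001 of 1 without exchange — the tests verify both properties.

### Detection limits of RC

The ratio's sensitivity is bounded by the relaxation-rate precision.
With 2% errors on R~1~/R~2~ at both fields, RC~err~ ≈ 3%, while
R~ex~ = 3 s⁻¹ raises RC by ~9–11% at τ~c~ ≈ 9–11 ns — an effect of
almost exactly three propagated standard deviations. Residues with
R~ex~ right at 3 s⁻¹ and high S² therefore sit *on* the 3σ detection
boundary (margins of ~2.7–3.0σ), and only clear it from R~ex~ ≈ 3.5 s⁻¹
upward; at 1% rate precision the same exchange is a ~6σ effect. This is
a property of the experiment, not of the implementation, and it is why
the exchange flag defaults to the 2σ level while headline claims about
exchange should rest on R~ex~ values comfortably above the boundary.

## The anisotropic model-free model

`mfa()` fits the Lipari–Szabo model on top of fully anisotropic overall
tumbling. The spectral density is the Woessner five-mode expansion: five
correlation times determined by the principal diffusion rates
(D~1~, D~2~, D~3~) and five amplitudes determined by the direction
cosines of the N–H vector in the tensor frame; internal motion of
amplitude S² and correlation time τ~int~ enters each mode through
1/τ′~k~ = 1/τ~k~ + 1/τ~int~. The amplitudes sum to one, and the
isotropic and axially symmetric cases are smooth limits of the same
expression (tested to 10⁻¹⁰).

**The C2 constraint.** For a symmetric homodimer one principal axis must
lie on the two-fold axis. With the structure aligned so that this axis
is z (`align_c2()`), the tensor orientation reduces to a single angle γ
about z — four global parameters (D~1~, D~2~, D~3~, γ) with α = β = 0.
Two representational symmetries are canonicalized in
`diffusion_tensor()`: γ and γ+180° are identical (γ is folded into
[0°, 180°)), and swapping D~1~↔D~2~ while adding 90° to γ is identical
(we order D~1~ ≤ D~2~). Symmetry-equivalent residues of the two chains
give a single peak in the symmetric apo dimer and share one observable
set; chain-qualified ids ("A:57") are used throughout so broken-symmetry
complexes can be represented.

**R~ex~ convention.** R~ex~ is quoted at the reference field (700 MHz)
and scaled with the square of the field ratio (fast-exchange limit);
the convention is stated in the output header.

### Fitting strategy

1. **Rigid subset.** The tensor is anchored on residues without fast
   large-amplitude motion or exchange: NOE(700) > 0.65 and RC within
   1 ± 2·RC~err~. If fewer than 15 residues qualify (possible for
   proteins with extensive fast motion), the NOE cutoff is relaxed by
   taking the highest-NOE exchange-free residues up to 15;
   `fit_global_tensor()` still refuses below 10 anchors.
2. **Multi-start profiled search.** The profiled χ²(D~1~, D~2~, D~3~, γ)
   — with each anchor's (S², τ~int~) profiled out on a 29-point τ grid
   and a closed-form S² on the linearized observables — is minimized by
   Nelder–Mead from 12 starts spanning anisotropy arrangements and γ
   quadrants. Profiling keeps each tensor evaluation cheap and the
   multi-start guards against the γ/anisotropy multimodality.
3. **Joint refinement.** The best start seeds a Levenberg–Marquardt
   refinement of the tensor *and* the anchors' (S², τ~int~) jointly
   (`minpack.lm::nls.lm`, box constraints), which converges to machine
   precision on exact data.
4. **Local models and selection.** Per residue, the nested candidates
   M0 (S²), M1 (S², τ~int~), M2 (S², R~ex~) and M3 (S², τ~int~, R~ex~)
   are fitted by bounded Levenberg–Marquardt against the six observables
   (weighted by the stated errors) from three starts, and the winner
   minimizes AICc = χ² + 2k + 2k(k+1)/(n−k−1) with n = 6, ties broken
   toward fewer parameters. A config switch (`force_model`) forces one
   model everywhere.
5. **Alternation.** Tensor and local fits alternate — after the first
   round the tensor update uses *all* converged residues with their
   selected local models held fixed, which is substantially more
   accurate than staying on the small anchor set — until the global χ²
   changes by less than 10⁻⁶ (relative), at most 20 rounds.
6. **Monte-Carlo errors.** Observables are resampled from Gaussians with
   their stated errors and each residue's selected model is refitted
   with the tensor held fixed (200 minimizations by default); parameter
   standard deviations over iterations are the reported errors, and a
   residue whose iterations fail to converge more than 20% of the time
   is flagged unreliable. Because the tensor is held fixed, its own
   (small) uncertainty is not propagated into S²~err~; the 1σ intervals
   are accordingly expected to cover the truth slightly below the
   nominal 68%.

### Numerical choices

* Zero or missing stated errors fall back to the smallest positive error
  of the same observable; fully error-free (synthetic-exact) data gets a
  tiny nominal tolerance (10⁻⁶ of the observable's median) so that exact
  fits still resolve the generating model under AICc.
* The degenerate corner S² = 0, τ~int~ = 0 predicts all-zero spectral
  densities (undefined NOE); objectives guard it with a large finite
  penalty.
* τ~int~ is bounded at 5 ns, R~ex~ at 100 s⁻¹, S² in [0, 1]; τ~int~ is
  fitted in ns internally so all parameters have comparable scale.
* All randomness (rigid-subset RC errors, Monte-Carlo) derives from one
  seed; rerunning with the same data, config and seed reproduces the
  output tables exactly.

## Ligand analytics

* `csp()` combines proton and nitrogen shift changes as
  √(Δδ~H~² + 0.1·Δδ~N~²) (ppm).
* `seven_pa()` sums the *absolute proton* shift changes of seven
  selected reporter amides in Hz (1 ppm = spectrometer MHz in Hz); the
  selection is a required input since it is instrument- and
  assignment-specific. `triage_screen()` classifies mixtures at the
  100 Hz (hit) and 300 Hz (strong) thresholds and reports the hit rate
  as round(100 · hit mixtures · hits-per-mixture / library size).
* `binding_isotherm()` is the closed-form 1:1 fast-exchange solution
  (the root of the binding quadratic, algebraically identical to
  fraction-bound × δ~b~); `fit_kd()` fits (K~d~, δ~b~) per amide with
  errors from the covariance matrix, flagging fits that do not approach
  saturation. [P~t~] is used exactly as supplied — no monomer/dimer
  conversion is guessed.
* **Why a shared-K~d~ fit exists.** With a four-point titration, a lone
  amide leaves K~d~ and δ~b~ strongly correlated: at 5% point noise the
  Fisher information bounds the relative K~d~ standard error at ~25–35%,
  so no per-amide estimator can reliably land within 15%. Since one
  binding event moves many resonances, `fit_kd_global()` fits one K~d~
  jointly with per-amide δ~b~, sharpening K~d~ by roughly √(n amides);
  `aggregate_kd()` (mean ± sample SD over per-amide fits, with the n = 1
  fit-SE fallback) remains the conventional per-amide report.

## Structure utilities

`read_structure()`/`write_structure()` use fixed-column PDB via bio3d
(highest-occupancy altloc kept, reported). `nh_vectors()` returns unit
N→H vectors, constructing missing amide protons in the peptide plane
opposite the bisector of the C(i−1)–N and CA–N directions at 1.02 Å
(prolines and chain starts skipped with a report). `align_c2()`
superposes chain A onto chain B, takes the rotation axis of that
transform, refuses if the rotation deviates from 180° by more than 15°
(overridable), and moves the assembly so the axis is +z through the
origin — an exact isometry. `write_value_map()` writes any per-residue
scalar (S², R~ex~, CSP) min–max scaled to [0, 99.99] into the B-factor
column, with a lossless sidecar TSV recording raw values and the
scaling.

## The synthetic study

`synth_ground_truth()` + `simulate_observables()` define the study
conditions used throughout the tests: a 60-residue C2 dimer with
D = (1.2, 1.4, 1.9)×10⁷ s⁻¹ (τ~c,eff~ ≈ 11 ns, anisotropy 1.5),
γ = 35°, S² uniform in [0.5, 0.98], τ~int~ uniform in 20–200 ps, R~ex~
of 2–6 s⁻¹ planted in 20% of residues, observed at 700 and 950 MHz with
2% Gaussian noise on the rates. NOE noise follows from the
ratio-of-intensities propagation with a constant spectral noise level —
σ~NOE~ = √(1+NOE²)/SNR — so near-zero NOEs keep realistic absolute
errors. Decay series use the acquisition schedules of sixteen delays to
3520 ms (R~1~) and nineteen to 250.16 ms (R~2~); titrations default to
the four-point 125/250/500/1000 µM scheme at 250 µM protein; screens
default to mixtures of 10 compounds at 500 µM each. Every generator is
a pure function of (parameters, seed) and writes its truth manifest
alongside the data.

What the generator does **not** emulate: peak overlap and lineshape
effects, field-dependent CSA corrections, anisotropic-tumbling
cross-correlation artefacts, titration-induced peak doubling when
ligand binding breaks the dimer symmetry, or non-Gaussian intensity
noise. Passing the recovery tests therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
pathology of real spectra.

## Problem sizes and runtime

The bundled tests and the acceptance script run the full chain at the
study scale — 60 residues × 2 fields, 200 Monte-Carlo minimizations,
50-replicate titration ensembles, a 600-compound screen — which
completes in a few minutes on a single core. Larger proteins scale
linearly in residues for the local stages; the tensor search is
residue-count-insensitive.

## Known limitations

* Single-timescale model-free only (no extended two-timescale model, no
  CPMG dispersion fitting of exchange rates).
* The tensor orientation is restricted to the C2-constrained single
  angle; general (five-angle) anisotropic fitting is out of scope.
* RC exchange detection is bounded by rate precision, as analyzed above.
* PDB is the only structure format written; mmCIF is not.
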