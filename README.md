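# relaxmf

Backbone dynamics and ligand-binding analytics for homodimeric proteins
from solution NMR, in R.

Protein–protein interaction domains such as the BTB domains of
transcription factors (MIZ1, KAISO, LRF, BCL6) share conserved dimeric
folds yet differ sharply in whether small molecules can bind them.
Protein-observed NMR connects the two observations: fragment screens and
titrations quantify binding, while ¹⁵N spin relaxation measured at two
magnetic fields reveals whether the binding site moves on the
microsecond–millisecond timescale. relaxmf implements that analysis
chain for scientists working with C2-symmetric homodimers:

* **Rate extraction** — two-parameter exponential fits of peak-intensity
  decay series, I(t) = I₀·e^(−Rt), with standard errors from the
  variance–covariance matrix; heteronuclear NOE from intensity ratios
  with SNR-propagated errors; a complete-set filter that keeps only
  residues with R₁, R₂ and NOE at every field.
* **Reduced spectral density mapping** — per-field J(0), J(ω_N),
  J(0.87ω_H) from (R₁, R₂, NOE), and the two-field consistency ratio
  RC = J(0)app(950 MHz)/J(0)app(700 MHz), which sits at 1 for
  exchange-free residues and rises above 1 when chemical exchange (R_ex)
  inflates R₂; errors by Monte-Carlo propagation.
* **Anisotropic model-free analysis** — the Lipari–Szabo model on a
  fully anisotropic (Woessner) diffusion tensor constrained by C2
  symmetry to four global parameters (D₁, D₂, D₃, γ with α = β = 0),
  plus per-residue (S², τ_int, R_ex) with AICc model selection and
  Monte-Carlo errors (200 minimizations).
* **Ligand analytics** — CSP = √(Δδ_H² + 0.1·Δδ_N²); the 7PA screening
  statistic (sum of seven reporter amide-proton shifts, in Hz) with
  100/300 Hz hit/strong thresholds and hit-rate arithmetic; 1:1
  fast-exchange K_d fitting from HSQC titrations (per-amide and global
  shared-K_d).
* **Structure utilities** — amide N–H unit vectors from PDB coordinates
  (missing protons rebuilt in the peptide plane), C2-axis alignment of
  dimers, per-residue value maps written into the B-factor column.
* **Synthetic-data generator** — every input above can be generated from
  ground-truth parameters with controlled noise and a single seed, so
  the full pipeline is testable without experimental spectra.

## Worked example

Simulate a two-field relaxation study of a 30-residue C2 dimer
(τ_c ≈ 11 ns, anisotropy 1.5, 2% noise) and fit the model-free model:

```r
library(relaxmf)

truth <- synth_ground_truth(n_residues = 30, seed = 11)
sim   <- simulate_observables(truth, noise = 0.02)
fit   <- mfa(sim$records, truth$nh_vectors, n_mc = 50, seed = 11)
print(fit)
#> Anisotropic model-free fit (C2 dimer constraint)
#>   residues: 30 (15 rigid anchors)   global chi2 = 96.86
#> Rotational diffusion tensor (C2 constraint: alpha = beta = 0)
#>   D1 = 1.1938e+07  D2 = 1.4037e+07  D3 = 1.8868e+07 s^-1
#>   gamma = 43.10 deg   D_iso = 1.4948e+07 s^-1
#>   tau_c(eff) = 11.15 ns   anisotropy 2*D3/(D1+D2) = 1.453
#>   local models: M0=0 M1=24 M2=1 M3=5
```

The planted tensor was D = (1.2, 1.4, 1.9)×10⁷ s⁻¹: the global tumbling
is recovered to ~1%, and the six residues fitted with an R_ex-containing
model (M2/M3) are the ones carrying planted exchange. A segment summary
follows the mean ± sample-SD convention used for secondary-structure
elements:

```r
segment_mean(fit$locals, paste0("A:", 1:6), "B4")
#>   segment n   mean_S2    sd_S2
#> 1      B4 6 0.7700067 0.148411
```

The same records give the two-field consistency ratios; residues with
exchange stand out above 1 by more than twice their propagated error:

```r
jr <- jmap_two_field(sim$records)
head(jr$rc[order(-jr$rc$RC), c("residue_id", "RC", "RC_err",
                               "exchange_flag")], 3)
#>    residue_id       RC     RC_err exchange_flag
#> 4         A:4 1.136857 0.03204381          TRUE
#> 17       A:17 1.099450 0.03214075          TRUE
#> 25       A:25 1.082273 0.02998841          TRUE
```

Titration fitting (four-point scheme, 250 µM protein):

```r
tit <- simulate_titration(68, c("A:3" = 0.30, "A:9" = 0.20), 250,
                          noise_frac = 0.02, seed = 2)
fit_kd(tit[["A:3"]])
#> Kd fit [A:3]: Kd = 58.6 +/- 18 uM, delta_b = 0.294 ppm
```

A single four-point amide determines K_d only loosely (here 58.6 ± 18 µM
against a planted 68 µM); `fit_kd_global()` fits one shared K_d across
several amides and tightens the estimate by roughly √(n amides).

A command-line interface over the same functions lives in
`inst/cli/relaxmf` (subcommands `simulate`, `fit-rates`, `jmap`, `mfa`,
`titrate`, `screen`, `map-structure`, `all`), configured by a YAML file
and a seed; every run echoes its effective configuration and writes a
run log.

See `vignettes/model-free-analysis.Rmd` for the model, the fitting
strategy, numerical choices, and known limitations (including the
detection limit of the consistency ratio at 2% rate precision).

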