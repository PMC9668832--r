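# Shared fixtures: small synthetic studies and an isotropic record builder.

# One-residue two-field record table from the forward model, with stated
# fractional errors but exact values (error propagation fixtures).
exact_record <- function(tensor, v, S2, tau_int, Rex, frac = 0,
                         fields = c(700, 950), id = "A:1") {
  do.call(rbind, lapply(fields, function(f) {
    p <- predict_observables(tensor, v, S2, tau_int, Rex, f)
    data.frame(residue_id = id, field_MHz = f,
               R1 = p[["R1"]], R1_err = frac * p[["R1"]],
               R2 = p[["R2"]], R2_err = frac * p[["R2"]],
               NOE = p[["NOE"]],
               NOE_err = frac * sqrt(1 + p[["NOE"]]^2))
  }))
}

iso_tensor <- function(tauc_ns) {
  D <- 1 / (6 * tauc_ns * 1e-9)
  diffusion_tensor(D, D, D)
}

# Independent isotropic Lipari-Szabo spectral density (dual-route oracle).
iso_J_ref <- function(omega, tauc, S2, tau_int) {
  taup <- if (tau_int > 0) tauc * tau_int / (tauc + tau_int) else 0
  0.4 * (S2 * tauc / (1 + (omega * tauc)^2) +
         (1 - S2) * taup / (1 + (omega * taup)^2))
}
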