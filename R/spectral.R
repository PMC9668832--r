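#' Rotational diffusion tensor of a C2-symmetric dimer
#'
#' Constructs the global rotational diffusion tensor used by the model-free
#' analysis. For a homodimer with exact C2 symmetry one principal axis must
#' coincide with the symmetry axis (taken as the molecular z axis), so the
#' tensor orientation reduces to a single Euler angle `gamma` about z
#' (alpha = beta = 0). `D1` and `D2` are the in-plane principal rates, `D3`
#' the rate about the symmetry axis.
#'
#' The representation is canonicalized: `gamma` is reduced modulo 180
#' degrees (gamma and gamma + 180 describe the same tensor), and the
#' in-plane values are ordered `D1 <= D2` (swapping D1/D2 while adding 90
#' degrees to gamma leaves the tensor unchanged).
#'
#' @param D1,D2,D3 Principal rotational diffusion rates (s^-1), all > 0.
#' @param gamma Rotation (degrees) of the in-plane principal axes about z.
#' @return Object of class `"diffusion_tensor"` with elements `D1`, `D2`,
#'   `D3`, `gamma`, and derived `D_iso = (D1+D2+D3)/3`,
#'   `tauc_eff = 1/(6 D_iso)` (s) and `anisotropy = 3 D3 / (D1 + D2)`.
#' @examples
#' dt <- diffusion_tensor(1.2e7, 1.4e7, 1.9e7, gamma = 35)
#' dt$tauc_eff * 1e9   # effective correlation time, ns
#' @export
diffusion_tensor <- function(D1, D2, D3, gamma = 0) {
  stopifnot(D1 > 0, D2 > 0, D3 > 0, is.finite(gamma))
  gamma <- gamma %% 180
  if (D1 > D2) {           # swap to canonical in-plane ordering
    tmp <- D1; D1 <- D2; D2 <- tmp
    gamma <- (gamma + 90) %% 180
  }
  D_iso <- (D1 + D2 + D3) / 3
  structure(list(D1 = D1, D2 = D2, D3 = D3, gamma = gamma,
                 D_iso = D_iso, tauc_eff = 1 / (6 * D_iso),
                 anisotropy = 3 * D3 / (D1 + D2)),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("Rotational diffusion tensor (C2 constraint: alpha = beta = 0)\n")
  cat(sprintf("  D1 = %.4e  D2 = %.4e  D3 = %.4e s^-1\n", x$D1, x$D2, x$D3))
  cat(sprintf("  gamma = %.2f deg   D_iso = %.4e s^-1\n", x$gamma, x$D_iso))
  cat(sprintf("  tau_c(eff) = %.2f ns   anisotropy 2*D3/(D1+D2) = %.3f\n",
              x$tauc_eff * 1e9, 2 * x$D3 / (x$D1 + x$D2)))
  invisible(x)
}

# Woessner asymmetric-rotor correlation times (length 5, s) and amplitude
# matrix (n x 5) for n unit N-H vectors given in the molecular frame.
# Vectors are first rotated by -gamma about z into the tensor frame.
woessner_modes <- function(tensor, vecs) {
  if (is.null(dim(vecs))) vecs <- matrix(vecs, nrow = 1)
  g <- tensor$gamma * pi / 180
  cg <- cos(g); sg <- sin(g)
  x <- vecs[, 1] * cg + vecs[, 2] * sg
  y <- -vecs[, 1] * sg + vecs[, 2] * cg
  z <- vecs[, 3]

  D1 <- tensor$D1; D2 <- tensor$D2; D3 <- tensor$D3
  Diso <- tensor$D_iso
  L2 <- (D1 * D2 + D1 * D3 + D2 * D3) / 3
  Delta2 <- max(Diso^2 - L2, 0)
  Delta <- sqrt(Delta2)

  tau <- 1 / c(4 * D1 + D2 + D3,
               D1 + 4 * D2 + D3,
               D1 + D2 + 4 * D3,
               6 * (Diso + Delta),
               6 * max(Diso - Delta, .Machine$double.xmin))

  if (Delta > 1e-12 * Diso) {
    del <- (c(D1, D2, D3) - Diso) / Delta
  } else {
    del <- c(0, 0, 0)   # isotropic limit: all tau equal, e-term vanishes
  }
  x2 <- x^2; y2 <- y^2; z2 <- z^2
  dterm <- 0.25 * (3 * (x2^2 + y2^2 + z2^2) - 1)
  eterm <- (del[1] * (3 * x2^2 + 6 * y2 * z2 - 1) +
            del[2] * (3 * y2^2 + 6 * x2 * z2 - 1) +
            del[3] * (3 * z2^2 + 6 * x2 * y2 - 1)) / 12
  A <- cbind(3 * y2 * z2, 3 * x2 * z2, 3 * x2 * y2,
             dterm - eterm, dterm + eterm)
  list(tau = tau, A = A)
}

#' Anisotropic Lipari-Szabo spectral density
#'
#' Evaluates the model-free spectral density for an N-H bond vector
#' reorienting by asymmetric-rotor overall tumbling (Woessner five-mode
#' expansion) with fast internal motion of amplitude `S2` and correlation
#' time `tau_int`:
#' \deqn{J(\omega) = \frac{2}{5}\sum_{k=1}^{5} A_k\left[
#'   \frac{S^2 \tau_k}{1+(\omega\tau_k)^2} +
#'   \frac{(1-S^2) \tau'_k}{1+(\omega\tau'_k)^2}\right]}
#' with \eqn{1/\tau'_k = 1/\tau_k + 1/\tau_{int}}. The amplitudes depend on
#' the direction cosines of the bond vector in the tensor principal frame
#' and sum to one; isotropic and axially symmetric tensors are smooth
#' limits of the same expression.
#'
#' @param omega Angular frequency (rad/s); may be a vector.
#' @param tensor A [diffusion_tensor()].
#' @param nh_vector Unit N-H bond vector (length 3, molecular frame).
#' @param S2 Order parameter in [0, 1].
#' @param tau_int Internal correlation time (s), >= 0.
#' @return J(omega) in s/rad, same length as `omega`.
#' @examples
#' dt <- diffusion_tensor(1.85e7, 1.85e7, 1.85e7)  # tau_c = 9 ns
#' anisotropic_J(0, dt, c(0, 0, 1), S2 = 1, tau_int = 0)  # (2/5) tau_c
#' @export
anisotropic_J <- function(omega, tensor, nh_vector, S2, tau_int = 0) {
  stopifnot(S2 >= 0, S2 <= 1, tau_int >= 0,
            abs(sum(nh_vector^2) - 1) < 1e-6)
  m <- woessner_modes(tensor, nh_vector)
  J_from_modes(omega, m$tau, m$A[1, ], S2, tau_int)
}

# Core Lorentzian sum; omega vectorized. tau: 5 modes; A: 5 amplitudes.
J_from_modes <- function(omega, tau, A, S2, tau_int) {
  taup <- if (tau_int > 0) tau * tau_int / (tau + tau_int) else rep(0, 5)
  sapply(omega, function(w) {
    0.4 * sum(A * (S2 * tau / (1 + (w * tau)^2) +
                   (1 - S2) * taup / (1 + (w * taup)^2)))
  })
}

#' Predict R1, R2 and heteronuclear NOE from a dynamics model
#'
#' Forward model of the three backbone 15N relaxation observables at one
#' magnetic field from the global diffusion tensor and local model-free
#' parameters, using the standard dipolar + CSA relaxation equations with
#' \eqn{D = d^2/4} and \eqn{C = c^2 = (\omega_N\Delta\sigma)^2/3}:
#' \deqn{R_1 = D[J(\omega_H-\omega_N) + 3J(\omega_N) + 6J(\omega_H+\omega_N)]
#'   + C J(\omega_N)}
#' \deqn{R_2 = \tfrac{D}{2}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N)
#'   + 6J(\omega_H) + 6J(\omega_H+\omega_N)]
#'   + \tfrac{C}{6}[4J(0) + 3J(\omega_N)] + R_{ex}(B/B_{ref})^2}
#' \deqn{NOE = 1 + \frac{\gamma_H}{\gamma_N} D
#'   \frac{6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)}{R_1}}
#' `Rex` is quoted at the reference field and scaled quadratically with the
#' field (fast-exchange limit).
#'
#' @param tensor A [diffusion_tensor()].
#' @param nh_vector Unit N-H vector in the molecular frame.
#' @param S2,tau_int,Rex Local model-free parameters (`Rex` in s^-1 at
#'   `ref_field_MHz`).
#' @param field_MHz 1H spectrometer frequency of the prediction.
#' @param constants An [nmr_constants()] object.
#' @param ref_field_MHz Field at which `Rex` is quoted (default 700).
#' @return Named numeric vector `c(R1, R2, NOE)`.
#' @examples
#' dt <- diffusion_tensor(1.85e7, 1.85e7, 1.85e7)
#' predict_observables(dt, c(0, 0, 1), S2 = 0.9, tau_int = 50e-12,
#'                     Rex = 0, field_MHz = 700)
#' @export
predict_observables <- function(tensor, nh_vector, S2, tau_int = 0, Rex = 0,
                                field_MHz = 700,
                                constants = nmr_constants(),
                                ref_field_MHz = 700) {
  ic <- interaction_constants(field_MHz, constants)
  m <- woessner_modes(tensor, nh_vector)
  w <- c(0, ic$wN, ic$wH - ic$wN, ic$wH, ic$wH + ic$wN)
  J <- J_from_modes(w, m$tau, m$A[1, ], S2, tau_int)
  relax_from_J(J, ic, constants, Rex, field_MHz, ref_field_MHz)
}

# J must be ordered (J0, JwN, JwHmN, JwH, JwHpN).
relax_from_J <- function(J, ic, constants, Rex, field_MHz, ref_field_MHz) {
  D <- ic$D; C <- ic$C
  R1 <- D * (J[3] + 3 * J[2] + 6 * J[5]) + C * J[2]
  R2 <- (D / 2) * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] + 6 * J[5]) +
        (C / 6) * (4 * J[1] + 3 * J[2]) +
        Rex * (field_MHz / ref_field_MHz)^2
  NOE <- 1 + (constants$gamma_H / constants$gamma_N) * D *
         (6 * J[5] - J[3]) / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}

# Vectorized forward model: observables for n residues at one field.
# locals: data.frame with S2, tau_int, Rex; vecs: n x 3 matrix.
predict_observables_all <- function(tensor, vecs, locals, field_MHz,
                                    constants = nmr_constants(),
                                    ref_field_MHz = 700) {
  ic <- interaction_constants(field_MHz, constants)
  m <- woessner_modes(tensor, vecs)
  w <- c(0, ic$wN, ic$wH - ic$wN, ic$wH, ic$wH + ic$wN)
  n <- nrow(m$A)
  S2 <- locals$S2; ti <- locals$tau_int
  tau <- m$tau
  # tau'_k per residue: n x 5
  taup <- outer(ti, tau, function(t, tk) ifelse(t > 0, tk * t / (tk + t), 0))
  Jmat <- matrix(0, n, 5)      # columns: J0, JwN, JwHmN, JwH, JwHpN
  for (j in seq_along(w)) {
    lor_tau <- tau / (1 + (w[j] * tau)^2)            # length 5
    lor_taup <- taup / (1 + (w[j] * taup)^2)          # n x 5
    Jmat[, j] <- 0.4 * (S2 * (m$A %*% lor_tau) +
                        (1 - S2) * rowSums(m$A * lor_taup))
  }
  D <- ic$D; C <- ic$C
  R1 <- D * (Jmat[, 3] + 3 * Jmat[, 2] + 6 * Jmat[, 5]) + C * Jmat[, 2]
  R2 <- (D / 2) * (4 * Jmat[, 1] + Jmat[, 3] + 3 * Jmat[, 2] +
                   6 * Jmat[, 4] + 6 * Jmat[, 5]) +
        (C / 6) * (4 * Jmat[, 1] + 3 * Jmat[, 2]) +
        locals$Rex * (field_MHz / ref_field_MHz)^2
  NOE <- 1 + (constants$gamma_H / constants$gamma_N) * D *
         (6 * Jmat[, 5] - Jmat[, 3]) / R1
  data.frame(R1 = R1, R2 = R2, NOE = NOE)
}
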