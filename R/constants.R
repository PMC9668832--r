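#' Physical constants for amide 15N relaxation
#'
#' Bundles the gyromagnetic ratios, N-H bond length and 15N chemical shift
#' anisotropy that enter every relaxation equation in the package, so that
#' the spectral density mapping and the model-free forward model share one
#' source of truth.
#'
#' The dipolar coupling is expressed through
#' \eqn{d = \mu_0 \hbar \gamma_H \gamma_N / (4 \pi r_{NH}^3)} and the CSA
#' interaction through \eqn{c^2 = (\omega_N \Delta\sigma)^2 / 3}; the
#' relaxation equations in [predict_observables()] use \eqn{D = d^2/4} and
#' \eqn{C = c^2}.
#'
#' @param gamma_H 1H gyromagnetic ratio (rad s^-1 T^-1).
#' @param gamma_N 15N gyromagnetic ratio (rad s^-1 T^-1, negative).
#' @param r_NH N-H bond length in Angstrom.
#' @param delta_sigma 15N chemical shift anisotropy in ppm (negative).
#' @return An object of class `"nmr_constants"`: a list with the inputs plus
#'   the derived dipolar constant `d2` (= d^2, rad^2 s^-2).
#' @examples
#' cst <- nmr_constants()
#' cst$r_NH
#' @export
nmr_constants <- function(gamma_H = 2.6752218744e8,
                          gamma_N = -2.7126e7,
                          r_NH = 1.02,
                          delta_sigma = -160) {
  stopifnot(gamma_H > 0, gamma_N < 0, r_NH >= 0.9, r_NH <= 1.1)
  mu0 <- 4e-7 * pi      # T m / A
  hbar <- 1.054571817e-34  # J s
  r_m <- r_NH * 1e-10
  d <- mu0 * hbar * gamma_H * gamma_N / (4 * pi * r_m^3)
  structure(list(gamma_H = gamma_H, gamma_N = gamma_N,
                 r_NH = r_NH, delta_sigma = delta_sigma,
                 d2 = d^2),
            class = "nmr_constants")
}

#' @export
print.nmr_constants <- function(x, ...) {
  cat("15N relaxation constants\n")
  cat(sprintf("  gamma_H     %.10e rad/s/T\n", x$gamma_H))
  cat(sprintf("  gamma_N     %.5e rad/s/T\n", x$gamma_N))
  cat(sprintf("  r_NH        %.3f A\n", x$r_NH))
  cat(sprintf("  delta_sigma %.1f ppm\n", x$delta_sigma))
  invisible(x)
}

# Angular frequencies (rad/s) of 1H and 15N at a given 1H field in MHz.
# J(omega) is even in omega, so magnitudes are used throughout.
larmor_freqs <- function(field_MHz, constants = nmr_constants()) {
  wH <- 2 * pi * field_MHz * 1e6
  wN <- wH * abs(constants$gamma_N) / constants$gamma_H
  list(wH = wH, wN = wN)
}

# Interaction prefactors at one field: D = d^2/4 (s^-2), C = c^2 (s^-2).
interaction_constants <- function(field_MHz, constants = nmr_constants()) {
  w <- larmor_freqs(field_MHz, constants)
  list(D = constants$d2 / 4,
       C = (w$wN * constants$delta_sigma * 1e-6)^2 / 3,
       wH = w$wH, wN = w$wN)
}
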