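#' Reduced spectral density mapping
#'
#' Maps one field's (R1, R2, NOE) record set onto the spectral density at
#' three frequencies using the single high-frequency reduction (all
#' high-frequency terms represented by J(0.87 omega_H)). With
#' \eqn{D = d^2/4}, \eqn{C = c^2} and the cross-relaxation rate
#' \eqn{\sigma_{NH} = R_1 (NOE - 1) \gamma_N / \gamma_H}:
#' \deqn{J(0.87\omega_H) = \sigma_{NH} / (5D)}
#' \deqn{J(\omega_N) = (R_1 - 7 D J(0.87\omega_H)) / (3D + C)}
#' \deqn{J(0)_{app} = \frac{R_2 - \tfrac{D}{2}(13 J(0.87\omega_H)
#'   + 3 J(\omega_N)) - \tfrac{C}{2} J(\omega_N)}{2D + \tfrac{2}{3}C}}
#' J(0) is "apparent": any exchange contribution to R2 inflates it, which
#' is what the two-field consistency ratio exploits.
#'
#' Uncertainties are propagated by Monte-Carlo resampling of (R1, R2, NOE)
#' from Gaussian distributions with the stated errors; with all input
#' errors zero the propagated errors are exactly zero.
#'
#' @param records data.frame with columns residue_id, field_MHz, R1,
#'   R1_err, R2, R2_err, NOE, NOE_err — one field only.
#' @param constants An [nmr_constants()].
#' @param n_mc Monte-Carlo draws for error propagation (default 1000).
#' @param seed RNG seed for the propagation (default 20221116).
#' @param noe_tol NOE values above `1 + noe_tol` are flagged (default 0.05).
#' @return data.frame of class `"jmap"`: residue_id, field_MHz, J0, J0_err,
#'   JwN, JwN_err, JwH087, JwH087_err, flag; the per-residue J(0) draws are
#'   attached as attribute `"J0_draws"` for downstream ratio propagation.
#' @export
reduced_spectral_density <- function(records, constants = nmr_constants(),
                                     n_mc = 1000, seed = 20221116,
                                     noe_tol = 0.05) {
  stopifnot(nrow(records) > 0, length(unique(records$field_MHz)) == 1)
  field <- records$field_MHz[1]
  stopifnot(field > 0)
  ic <- interaction_constants(field, constants)
  gr <- constants$gamma_N / constants$gamma_H

  point <- reduced_map_core(records$R1, records$R2, records$NOE,
                            ic$D, ic$C, gr)
  flag <- ifelse(records$NOE > 1 + noe_tol, "NOE>1",
                 ifelse(point$J0 < 0 | point$JwH < 0, "negative-J", ""))

  n <- nrow(records)
  err0 <- is.na(records$R1_err) | records$R1_err <= 0
  has_err <- any(records$R1_err > 0 | records$R2_err > 0 |
                 records$NOE_err > 0, na.rm = TRUE)
  draws <- matrix(rep(point$J0, n_mc), nrow = n)
  J0e <- JwNe <- JwHe <- rep(0, n)
  if (has_err) {
    withr_seed(seed, {
      r1 <- matrix(stats::rnorm(n * n_mc, records$R1,
                                zero_na(records$R1_err)), nrow = n)
      r2 <- matrix(stats::rnorm(n * n_mc, records$R2,
                                zero_na(records$R2_err)), nrow = n)
      nn <- matrix(stats::rnorm(n * n_mc, records$NOE,
                                zero_na(records$NOE_err)), nrow = n)
    })
    mc <- reduced_map_core(r1, r2, nn, ic$D, ic$C, gr)
    draws <- mc$J0
    J0e <- apply(mc$J0, 1, stats::sd)
    JwNe <- apply(mc$JwN, 1, stats::sd)
    JwHe <- apply(mc$JwH, 1, stats::sd)
  }
  out <- data.frame(residue_id = records$residue_id, field_MHz = field,
                    J0 = point$J0, J0_err = J0e,
                    JwN = point$JwN, JwN_err = JwNe,
                    JwH087 = point$JwH, JwH087_err = JwHe,
                    flag = flag, stringsAsFactors = FALSE)
  # flag negative J beyond propagated error, value retained
  neg <- (out$J0 < -out$J0_err) | (out$JwH087 < -out$JwH087_err)
  out$flag[neg & out$flag == ""] <- "negative-J"
  attr(out, "J0_draws") <- draws
  class(out) <- c("jmap", class(out))
  out
}

zero_na <- function(x) ifelse(is.na(x), 0, x)

# Algebraic core; accepts scalars, vectors or matrices (recycled shapes).
reduced_map_core <- function(R1, R2, NOE, D, C, gamma_ratio) {
  sigma <- R1 * (NOE - 1) * gamma_ratio
  JwH <- sigma / (5 * D)
  JwN <- (R1 - 7 * D * JwH) / (3 * D + C)
  J0 <- (R2 - (D / 2) * (13 * JwH + 3 * JwN) - (C / 2) * JwN) /
        (2 * D + (2 / 3) * C)
  list(J0 = J0, JwN = JwN, JwH = JwH)
}

#' Two-field J(0) consistency ratio (RC)
#'
#' Per-residue ratio of the apparent J(0) at the higher magnetic field to
#' the lower field. Without microsecond-millisecond exchange the apparent
#' J(0) is field-independent and RC sits at 1; an exchange contribution
#' Rex inflates R2 quadratically with the field, so RC rises significantly
#' above 1 for exchange-broadened residues.
#'
#' Errors are propagated by pairing the Monte-Carlo J(0) draws attached to
#' each map (the two fields are independent measurements). Residues whose
#' lower-field J(0) is not positive have an undefined ratio and are
#' flagged.
#'
#' @param map_high,map_low [reduced_spectral_density()] results; the first
#'   must be at the higher field.
#' @param flag_k Exchange is flagged when `RC > 1 + flag_k * RC_err`
#'   (default 2).
#' @return data.frame: residue_id, RC, RC_err, exchange_flag, flag.
#' @export
consistency_ratio <- function(map_high, map_low, flag_k = 2) {
  stopifnot(map_high$field_MHz[1] > map_low$field_MHz[1])
  ids <- intersect(map_high$residue_id, map_low$residue_id)
  ih <- match(ids, map_high$residue_id)
  il <- match(ids, map_low$residue_id)
  J0h <- map_high$J0[ih]; J0l <- map_low$J0[il]
  RC <- ifelse(J0l > 0, J0h / J0l, NA_real_)

  dh <- attr(map_high, "J0_draws"); dl <- attr(map_low, "J0_draws")
  if (!is.null(dh) && !is.null(dl) && ncol(dh) == ncol(dl)) {
    ratio <- dh[ih, , drop = FALSE] / dl[il, , drop = FALSE]
    ratio[!is.finite(ratio)] <- NA
    RC_err <- apply(ratio, 1, stats::sd, na.rm = TRUE)
  } else {
    RC_err <- abs(RC) * sqrt((map_high$J0_err[ih] / J0h)^2 +
                             (map_low$J0_err[il] / J0l)^2)
  }
  RC_err[is.na(RC)] <- NA_real_
  data.frame(residue_id = ids, RC = RC, RC_err = RC_err,
             exchange_flag = !is.na(RC) & RC > 1 + flag_k * RC_err,
             flag = ifelse(is.na(RC), "J0(low)<=0", ""),
             stringsAsFactors = FALSE)
}

#' Spectral density maps and consistency ratios for a two-field record set
#'
#' Convenience wrapper: splits an assembled record table by field, runs
#' [reduced_spectral_density()] on each, and computes the
#' [consistency_ratio()] between the highest and lowest field.
#'
#' @inheritParams reduced_spectral_density
#' @param records Two-field record table (see [assemble_records()]).
#' @return List with `maps` (named by field) and `rc` (ratio table).
#' @export
jmap_two_field <- function(records, constants = nmr_constants(),
                           n_mc = 1000, seed = 20221116) {
  fields <- sort(unique(records$field_MHz))
  stopifnot(length(fields) == 2)
  maps <- lapply(fields, function(f)
    reduced_spectral_density(records[records$field_MHz == f, ],
                             constants, n_mc, seed + round(f)))
  names(maps) <- as.character(fields)
  rc <- consistency_ratio(maps[[2]], maps[[1]])
  list(maps = maps, rc = rc)
}

# Evaluate expr with a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
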