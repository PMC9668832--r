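# Model-free analysis of two-field 15N relaxation for C2-symmetric dimers.
#
# Internal layout: records are reshaped to arrays obs[n, field, 3] with
# matching effective errors; all fitting goes through the Woessner forward
# model in spectral.R. The global tensor is fitted on a rigid subset with
# (S2, tau_int) profiled per residue; local parameters are then fitted per
# residue with AICc model selection; the two stages alternate until the
# global chi-square stabilizes.

OBS_NAMES <- c("R1", "R2", "NOE")

# ---- data preparation -------------------------------------------------------

# Reshape a long record table into arrays aligned with the N-H vector set.
mfa_prep <- function(records, nh_vectors, constants = nmr_constants(),
                     ref_field_MHz = 700) {
  nh <- as_nh_matrix(nh_vectors)
  fields <- sort(unique(records$field_MHz))
  ids <- sort(unique(records$residue_id))
  missing_vec <- setdiff(ids, rownames(nh))
  if (length(missing_vec))
    stop("no N-H vector for residue(s): ",
         paste(utils::head(missing_vec, 5), collapse = ", "))
  ids <- ids[ids %in% rownames(nh)]
  n <- length(ids); nf <- length(fields)
  obs <- err <- array(NA_real_, c(n, nf, 3),
                      dimnames = list(ids, fields, OBS_NAMES))
  for (f in seq_along(fields)) {
    sub <- records[records$field_MHz == fields[f], ]
    i <- match(sub$residue_id, ids)
    obs[i, f, ] <- as.matrix(sub[, c("R1", "R2", "NOE")])
    err[i, f, ] <- as.matrix(sub[, c("R1_err", "R2_err", "NOE_err")])
  }
  if (any(is.na(obs)))
    stop("incomplete observable set; run assemble_records() first")
  # effective errors: zero / NA errors fall back to the smallest positive
  # error of the same observable; exact (error-free) data gets a tiny
  # nominal tolerance so noiseless fits resolve the generating model
  eff <- err
  for (k in 1:3) {
    e <- eff[, , k]
    pos <- e[!is.na(e) & e > 0]
    e[is.na(e) | e <= 0] <- if (length(pos)) min(pos)
                            else 1e-6 * stats::median(abs(obs[, , k]))
    eff[, , k] <- e
  }
  ics <- lapply(fields, interaction_constants, constants = constants)
  list(ids = ids, fields = fields, obs = obs, err = err, eff = eff,
       vecs = nh[ids, , drop = FALSE], ics = ics,
       constants = constants, ref_field = ref_field_MHz)
}

# Accept a structure_frame, a named list, or a matrix with rownames.
as_nh_matrix <- function(x) {
  if (inherits(x, "structure_frame")) x <- x$nh_vectors
  if (is.list(x) && !is.data.frame(x) && is.null(dim(x)))
    x <- do.call(rbind, x)
  stopifnot(is.matrix(x), ncol(x) == 3, !is.null(rownames(x)))
  nrm <- sqrt(rowSums(x^2))
  stopifnot(all(abs(nrm - 1) < 1e-6))
  x / nrm
}

# ---- fast per-residue forward model ----------------------------------------

# Per-field Lorentzian tables for one residue: given mode times tau5 and a
# frequency vector w (J0, JwN, JwHmN, JwH, JwHpN), lor[j, k] = f(tau_k, w_j).
lor_table <- function(w, tau) {
  wt <- outer(w, tau)
  matrix(tau, nrow = length(w), ncol = 5, byrow = TRUE) / (1 + wt^2)
}

# Predicted (R1, R2, NOE) at every field for one residue.
# pre: list with per-field `w`, `lor` (rigid Lorentzian table) and `ic`.
predict_res <- function(pre, tau5, A, S2, tau_int, Rex, constants, fields,
                        ref_field) {
  out <- matrix(NA_real_, length(fields), 3,
                dimnames = list(fields, OBS_NAMES))
  taup <- if (tau_int > 0) tau5 * tau_int / (tau5 + tau_int) else rep(0, 5)
  for (f in seq_along(fields)) {
    lorp <- lor_table(pre[[f]]$w, taup)
    J <- 0.4 * as.vector((S2 * pre[[f]]$lor + (1 - S2) * lorp) %*% A)
    out[f, ] <- relax_from_J(J, pre[[f]]$ic, constants, Rex,
                             fields[f], ref_field)
  }
  out
}

# Precompute per-field frequency grids and rigid Lorentzian tables for a
# tensor (shared across residues; lor depends only on tau5).
precompute_fields <- function(tau5, ics) {
  lapply(ics, function(ic) {
    w <- c(0, ic$wN, ic$wH - ic$wN, ic$wH, ic$wH + ic$wN)
    list(w = w, lor = lor_table(w, tau5), ic = ic)
  })
}

# ---- local fits -------------------------------------------------------------

MODEL_PARS <- list("0" = "S2", "1" = c("S2", "tau_int"),
                   "2" = c("S2", "Rex"), "3" = c("S2", "tau_int", "Rex"))

# chi-square of one residue's 6 observables for given local parameters
chi2_res <- function(pre, tau5, A, S2, tau_int, Rex, obs2, eff2, constants,
                     fields, ref_field) {
  pr <- predict_res(pre, tau5, A, S2, tau_int, Rex, constants, fields,
                    ref_field)
  v <- sum(((obs2 - pr) / eff2)^2)
  if (!is.finite(v)) 1e12 else v   # degenerate corner (all J = 0)
}

# Fit one candidate local model for one residue by bounded least squares.
# Internal parameterization: S2 in [0,1], tau_int in ns, Rex in s^-1.
fit_local_model <- function(model_id, pre, tau5, A, obs2, eff2, constants,
                            fields, ref_field, starts = NULL) {
  pars <- MODEL_PARS[[as.character(model_id)]]
  lower <- c(S2 = 0, tau_int = 0, Rex = 0)[pars]
  upper <- c(S2 = 1, tau_int = 5, Rex = 100)[pars]
  residfun <- function(p) {
    v <- c(S2 = 0.9, tau_int = 0, Rex = 0)
    v[pars] <- p
    pr <- predict_res(pre, tau5, A, v["S2"], v["tau_int"] * 1e-9,
                      v["Rex"], constants, fields, ref_field)
    r <- as.vector((obs2 - pr) / eff2)
    r[!is.finite(r)] <- 1e6    # degenerate corner (all J = 0)
    r
  }
  if (is.null(starts))
    starts <- list(c(S2 = 0.9, tau_int = 0.05, Rex = 0)[pars],
                   c(S2 = 0.7, tau_int = 0.2, Rex = 3)[pars],
                   c(S2 = 0.95, tau_int = 0.02, Rex = 8)[pars])
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(pmin(pmax(s, lower), upper), lower, upper,
                         residfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit$value <- sum(fit$fvec^2)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) return(NULL)
  v <- c(S2 = 0.9, tau_int = 0, Rex = 0)
  v[pars] <- best$par
  list(model_id = model_id, S2 = unname(v["S2"]),
       tau_int = unname(v["tau_int"]) * 1e-9, Rex = unname(v["Rex"]),
       chi2 = best$value, k = length(pars),
       converged = best$info %in% 1:4)
}

#' Select among nested model-free models by AICc
#'
#' Given candidate fits of the nested local models (S2), (S2, tau_int),
#' (S2, Rex) and (S2, tau_int, Rex) against six observables, selects the
#' one minimizing the small-sample-corrected information criterion
#' `AICc = chi2 + 2k + 2k(k+1)/(n-k-1)` (n = 6), with ties broken toward
#' fewer parameters.
#'
#' @param fits List of candidate fits (each with `chi2`, `k`, `model_id`,
#'   `converged`); non-converged candidates are ignored.
#' @param n_obs Number of fitted observables (default 6).
#' @return The selected fit, with `aicc` added.
#' @export
select_model <- function(fits, n_obs = 6) {
  fits <- Filter(function(f) !is.null(f) && isTRUE(f$converged), fits)
  if (length(fits) == 0) return(NULL)
  aicc <- vapply(fits, function(f)
    f$chi2 + 2 * f$k + 2 * f$k * (f$k + 1) / (n_obs - f$k - 1), 0)
  ks <- vapply(fits, function(f) f$k, 0)
  best <- order(round(aicc, 10), ks)[1]   # ties -> fewer parameters
  out <- fits[[best]]
  out$aicc <- aicc[best]
  out
}

#' Fit local model-free parameters for one residue
#'
#' Fits the nested candidate models M0 (S2), M1 (S2, tau_int),
#' M2 (S2, Rex) and M3 (S2, tau_int, Rex) by weighted least squares
#' against the six observables (R1, R2, NOE at two fields) with the global
#' tensor fixed, then applies [select_model()] (or forces one model).
#'
#' @param record_pair data.frame of this residue's records at both fields.
#' @param tensor A [diffusion_tensor()].
#' @param nh_vector Unit N-H vector (molecular frame).
#' @param constants An [nmr_constants()].
#' @param ref_field_MHz Field at which Rex is quoted.
#' @param force_model Optional model id in 0:3 to skip selection.
#' @return List: residue_id, model_id, S2, tau_int (s), Rex (s^-1), chi2,
#'   aicc, converged; `NULL` if no candidate converges.
#' @export
fit_local <- function(record_pair, tensor, nh_vector,
                      constants = nmr_constants(), ref_field_MHz = 700,
                      force_model = NULL) {
  prep <- mfa_prep(record_pair,
                   matrix(nh_vector, 1, 3,
                          dimnames = list(record_pair$residue_id[1])),
                   constants, ref_field_MHz)
  m <- woessner_modes(tensor, prep$vecs)
  pre <- precompute_fields(m$tau, prep$ics)
  obs2 <- prep$obs[1, , ]; eff2 <- prep$eff[1, , ]
  models <- if (is.null(force_model)) 0:3 else force_model
  cand <- lapply(models, fit_local_model, pre = pre, tau5 = m$tau,
                 A = m$A[1, ], obs2 = obs2, eff2 = eff2,
                 constants = constants, fields = prep$fields,
                 ref_field = ref_field_MHz)
  sel <- select_model(cand)
  if (is.null(sel)) return(NULL)
  c(list(residue_id = prep$ids[1]), sel)
}

# Vectorized local fits for all residues in a prep object (internal).
# warm: optional data.frame of starting values per residue.
fit_all_locals <- function(prep, tensor, force_model = NULL, warm = NULL) {
  m <- woessner_modes(tensor, prep$vecs)
  pre <- precompute_fields(m$tau, prep$ics)
  n <- length(prep$ids)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    models <- if (is.null(force_model)) 0:3 else force_model
    cand <- lapply(models, function(mid) {
      s <- NULL
      if (!is.null(warm)) {
        pars <- MODEL_PARS[[as.character(mid)]]
        w <- c(S2 = warm$S2[i], tau_int = warm$tau_int[i] * 1e9,
               Rex = warm$Rex[i])
        s <- list(w[pars],
                  c(S2 = 0.9, tau_int = 0.05, Rex = 0)[pars],
                  c(S2 = 0.7, tau_int = 0.2, Rex = 3)[pars])
      }
      fit_local_model(mid, pre, m$tau, m$A[i, ], prep$obs[i, , ],
                      prep$eff[i, , ], prep$constants, prep$fields,
                      prep$ref_field, starts = s)
    })
    sel <- select_model(cand)
    rows[[i]] <- if (is.null(sel))
      data.frame(residue_id = prep$ids[i], model_id = NA_integer_,
                 S2 = NA_real_, tau_int = NA_real_, Rex = NA_real_,
                 chi2 = NA_real_, converged = FALSE)
    else
      data.frame(residue_id = prep$ids[i], model_id = sel$model_id,
                 S2 = sel$S2, tau_int = sel$tau_int, Rex = sel$Rex,
                 chi2 = sel$chi2, converged = TRUE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# ---- global tensor fit ------------------------------------------------------

# Profiled chi-square of a candidate tensor over the rigid subset:
# (S2, tau_int) per residue from a tau grid with closed-form S2 on the
# linearized observables (R1, R2, sigma_NH), scored by the true chi-square.
tensor_profile_chi2 <- function(theta, prep, tau_grid) {
  tensor <- theta_to_tensor(theta)
  m <- woessner_modes(tensor, prep$vecs)
  pre <- precompute_fields(m$tau, prep$ics)
  n <- nrow(prep$vecs); nf <- length(prep$fields)
  gH <- prep$constants$gamma_H; gN <- prep$constants$gamma_N
  # linearized observed vector (R1, R2, sigma_NH) and errors
  obs_lin <- err_lin <- array(NA_real_, c(n, nf, 3))
  for (f in seq_len(nf)) {
    R1 <- prep$obs[, f, 1]; NOE <- prep$obs[, f, 3]
    obs_lin[, f, 1] <- R1
    obs_lin[, f, 2] <- prep$obs[, f, 2]
    obs_lin[, f, 3] <- R1 * (NOE - 1) * (gN / gH)
    err_lin[, f, 1] <- prep$eff[, f, 1]
    err_lin[, f, 2] <- prep$eff[, f, 2]
    err_lin[, f, 3] <- abs(obs_lin[, f, 3]) *
      sqrt((prep$eff[, f, 1] / R1)^2 +
           (prep$eff[, f, 3] / pmax(abs(NOE - 1), 1e-6))^2)
  }
  # rigid-limit (S2 = 1) linear pieces, per field: u terms
  lin_u <- lin_v <- array(NA_real_, c(n, nf, 3))
  for (f in seq_len(nf)) {
    Ju <- 0.4 * (m$A %*% t(pre[[f]]$lor))          # n x 5 frequencies
    lin_u[, f, ] <- lin_obs_from_J(Ju, pre[[f]]$ic)
  }
  best_chi2 <- rep(Inf, n)
  best_S2 <- rep(1, n); best_tau <- rep(0, n)
  for (tau_i in tau_grid) {
    taup <- if (tau_i > 0) m$tau * tau_i / (m$tau + tau_i) else rep(0, 5)
    for (f in seq_len(nf)) {
      lorp <- lor_table(pre[[f]]$w, taup)
      Jv <- 0.4 * (m$A %*% t(lorp))
      lin_v[, f, ] <- lin_obs_from_J(Jv, pre[[f]]$ic)
    }
    # closed-form weighted S2 on the linearized observables
    num <- den <- rep(0, n)
    for (f in seq_len(nf)) for (k in 1:3) {
      d <- lin_u[, f, k] - lin_v[, f, k]
      w <- 1 / err_lin[, f, k]^2
      num <- num + w * (obs_lin[, f, k] - lin_v[, f, k]) * d
      den <- den + w * d^2
    }
    S2 <- pmin(pmax(num / den, 0), 1)
    # true chi-square at (S2, tau_i)
    chi <- rep(0, n)
    for (f in seq_len(nf)) {
      R1p <- S2 * lin_u[, f, 1] + (1 - S2) * lin_v[, f, 1]
      R2p <- S2 * lin_u[, f, 2] + (1 - S2) * lin_v[, f, 2]
      sig <- S2 * lin_u[, f, 3] + (1 - S2) * lin_v[, f, 3]
      NOEp <- 1 + (gH / gN) * sig / R1p
      chi <- chi + ((prep$obs[, f, 1] - R1p) / prep$eff[, f, 1])^2 +
                   ((prep$obs[, f, 2] - R2p) / prep$eff[, f, 2])^2 +
                   ((prep$obs[, f, 3] - NOEp) / prep$eff[, f, 3])^2
    }
    chi[!is.finite(chi)] <- Inf
    upd <- chi < best_chi2
    best_chi2[upd] <- chi[upd]; best_S2[upd] <- S2[upd]
    best_tau[upd] <- tau_i
  }
  structure(sum(best_chi2), S2 = best_S2, tau_int = best_tau)
}

# (R1, R2, sigma_NH) linear pieces from a J matrix (n x 5 frequencies).
lin_obs_from_J <- function(J, ic) {
  D <- ic$D; C <- ic$C
  cbind(D * (J[, 3] + 3 * J[, 2] + 6 * J[, 5]) + C * J[, 2],
        (D / 2) * (4 * J[, 1] + J[, 3] + 3 * J[, 2] + 6 * J[, 4] +
                   6 * J[, 5]) + (C / 6) * (4 * J[, 1] + 3 * J[, 2]),
        D * (6 * J[, 5] - J[, 3]))
}

theta_to_tensor <- function(theta) {
  diffusion_tensor(exp(theta[1]), exp(theta[2]), exp(theta[3]),
                   theta[4] * 180 / pi)
}

#' Identify the rigid subset used to anchor the diffusion tensor
#'
#' Rigid residues are those without fast large-amplitude motion or
#' chemical exchange: the heteronuclear NOE at the lower field must exceed
#' `noe_min` and the two-field consistency ratio must lie within
#' `1 +/- 2 RC_err`.
#'
#' When fewer than `min_n` residues pass the NOE cutoff, the cutoff is
#' relaxed by falling back to the exchange-free residues with the
#' highest lower-field NOE, up to `min_n` — an under-determined tensor
#' anchored on the most rigid residues available beats an outright
#' failure on proteins with extensive fast motion.
#'
#' @param records Two-field record table.
#' @param constants An [nmr_constants()].
#' @param noe_min Lower-field NOE cutoff (default 0.65).
#' @param min_n Minimum number of anchors before the NOE cutoff is
#'   relaxed (default 15).
#' @param n_mc Monte-Carlo draws for the RC errors.
#' @param seed Seed for the RC propagation.
#' @return Character vector of rigid residue ids.
#' @export
rigid_subset <- function(records, constants = nmr_constants(),
                         noe_min = 0.65, min_n = 15, n_mc = 500,
                         seed = 20221116) {
  fields <- sort(unique(records$field_MHz))
  low <- records[records$field_MHz == fields[1], ]
  jr <- jmap_two_field(records, constants, n_mc = n_mc, seed = seed)
  rc <- jr$rc
  ok_rc <- rc$residue_id[!is.na(rc$RC) &
                         abs(rc$RC - 1) <= 2 * pmax(rc$RC_err, 1e-12)]
  # with exactly zero stated errors RC_err is 0; accept RC within 0.1%
  ok_rc0 <- rc$residue_id[!is.na(rc$RC) & rc$RC_err < 1e-12 &
                          abs(rc$RC - 1) < 1e-3]
  no_exch <- union(ok_rc, ok_rc0)
  ok_noe <- low$residue_id[low$NOE > noe_min]
  out <- intersect(ok_noe, no_exch)
  if (length(out) < min_n) {
    pool <- low[low$residue_id %in% no_exch, ]
    pool <- pool[order(-pool$NOE), ]
    out <- utils::head(pool$residue_id, min_n)
  }
  out
}

#' Fit the global rotational diffusion tensor of a C2 dimer
#'
#' Fits (D1, D2, D3, gamma) by minimizing the summed chi-square over a
#' rigid residue subset, with each residue's (S2, tau_int) profiled out.
#' A multi-start search (grid over anisotropy arrangements and gamma)
#' feeds a Nelder-Mead refinement of the profiled objective; the best
#' start is then polished by alternating continuous local fits and tensor
#' refinement. gamma is canonicalized to [0, 180) with D1 <= D2.
#'
#' @param records Two-field record table (see [assemble_records()]).
#' @param frame A structure frame or named N-H unit-vector matrix.
#' @param rigid_ids Residues to anchor the tensor; default applies
#'   [rigid_subset()]. At least 10 are required.
#' @param constants An [nmr_constants()].
#' @param ref_field_MHz Reference field for Rex (excluded from this fit).
#' @param tauc_guess Optional initial correlation time (s); estimated from
#'   the median R2/R1 ratio when `NULL`.
#' @param n_starts Number of multi-start points (>= 8).
#' @param polish_rounds Alternation rounds for the final refinement.
#' @return A [diffusion_tensor()] with attributes `chi2` (profiled
#'   objective at the optimum) and `rigid_ids`.
#' @export
fit_global_tensor <- function(records, frame, rigid_ids = NULL,
                              constants = nmr_constants(),
                              ref_field_MHz = 700, tauc_guess = NULL,
                              n_starts = 12, polish_rounds = 12) {
  nh <- as_nh_matrix(frame)
  if (is.null(rigid_ids))
    rigid_ids <- rigid_subset(records, constants)
  rigid_ids <- intersect(rigid_ids, rownames(nh))
  if (length(rigid_ids) < 10)
    stop("tensor fit needs >= 10 rigid residues; found ",
         length(rigid_ids),
         " (relax the rigid-subset rule or supply rigid_ids)")
  rec <- records[records$residue_id %in% rigid_ids, ]
  prep <- mfa_prep(rec, nh, constants, ref_field_MHz)

  if (is.null(tauc_guess)) {
    low <- rec[rec$field_MHz == min(rec$field_MHz), ]
    ratio <- stats::median(low$R2 / low$R1)
    wN <- larmor_freqs(min(rec$field_MHz), constants)$wN
    tauc_guess <- sqrt(max(6 * ratio - 7, 0.5)) / (2 * wN)
  }
  Diso0 <- 1 / (6 * tauc_guess)
  tau_grid <- c(0, exp(seq(log(1e-12), log(2e-9), length.out = 28)))

  # multi-start grid: anisotropy arrangements x gamma
  aniso <- rbind(c(1, 1, 1), c(0.9, 1, 1.15), c(0.8, 0.95, 1.35),
                 c(1.15, 1, 0.9), c(0.85, 1.1, 1.1), c(1.1, 1.1, 0.85))
  gammas <- c(20, 65, 110, 155) * pi / 180
  starts <- list()
  for (a in seq_len(nrow(aniso))) for (g in gammas)
    starts[[length(starts) + 1]] <-
      c(log(Diso0 * aniso[a, ]), g)
  starts <- starts[seq_len(max(n_starts, 8))]

  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, tensor_profile_chi2, prep = prep,
                        tau_grid = tau_grid, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  # polish: joint Levenberg-Marquardt refinement of the tensor and the
  # rigid-subset (S2, tau_int), exchange-free by construction
  theta <- best$par
  locals <- fit_all_locals(prep, theta_to_tensor(theta),
                           force_model = c(0, 1))
  locals$Rex <- 0
  locals$S2[!is.finite(locals$S2)] <- 0.9
  locals$tau_int[!is.finite(locals$tau_int)] <- 0
  n <- length(prep$ids)
  par0 <- c(theta, pmin(pmax(locals$S2, 0), 1), locals$tau_int * 1e9)
  lower <- c(rep(-Inf, 3), -Inf, rep(0, n), rep(0, n))
  upper <- c(rep(Inf, 3), Inf, rep(1, n), rep(5, n))
  residfun <- function(p) {
    tn <- theta_to_tensor(p[1:4])
    loc <- data.frame(residue_id = prep$ids, S2 = p[5:(4 + n)],
                      tau_int = p[(5 + n):(4 + 2 * n)] * 1e-9, Rex = 0)
    pr <- predict_two_field(tn, prep, loc)
    as.vector((prep$obs - pr) / prep$eff)
  }
  lm <- minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                           fn = residfun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-14, ptol = 1e-12))
  tensor <- theta_to_tensor(lm$par[1:4])
  attr(tensor, "chi2") <- sum(lm$fvec^2)
  attr(tensor, "rigid_ids") <- rigid_ids
  tensor
}

# Predicted obs array (n x nf x 3) for a locals table aligned with prep$ids.
predict_two_field <- function(tensor, prep, locals) {
  out <- array(NA_real_, dim(prep$obs))
  i <- match(prep$ids, locals$residue_id)
  loc <- locals[i, ]
  for (f in seq_along(prep$fields)) {
    pr <- predict_observables_all(tensor, prep$vecs, loc, prep$fields[f],
                                  prep$constants, prep$ref_field)
    out[, f, ] <- as.matrix(pr)
  }
  out
}

# ---- Monte-Carlo errors -----------------------------------------------------

#' Monte-Carlo uncertainties for local model-free parameters
#'
#' Resamples every observable from a Gaussian centred on the measured
#' value with the stated uncertainty, refits each residue's selected local
#' model with the tensor held fixed, and reports the standard deviation of
#' each active parameter over the iterations (default 200 minimizations).
#' Residues where more than 20 percent of iterations fail to converge are
#' flagged unreliable.
#'
#' @param locals Per-residue fit table (from the `mfa` object's `locals`).
#' @param records Two-field record table.
#' @param tensor The fitted [diffusion_tensor()].
#' @param frame N-H vector source.
#' @param n_iter Number of Monte-Carlo minimizations (default 200).
#' @param seed RNG seed.
#' @param constants,ref_field_MHz As elsewhere.
#' @return `locals` with added S2_err, tau_int_err, Rex_err and
#'   `mc_unreliable`.
#' @export
monte_carlo_errors <- function(locals, records, tensor, frame,
                               n_iter = 200, seed = 20221116,
                               constants = nmr_constants(),
                               ref_field_MHz = 700) {
  prep <- mfa_prep(records, frame, constants, ref_field_MHz)
  m <- woessner_modes(tensor, prep$vecs)
  pre <- precompute_fields(m$tau, prep$ics)
  i_map <- match(locals$residue_id, prep$ids)
  err_draw <- zero_na(prep$err)

  n <- nrow(locals)
  S2e <- tie <- rexe <- rep(NA_real_, n)
  unrel <- rep(FALSE, n)
  withr_seed(seed, {
    for (j in seq_len(n)) {
      if (!isTRUE(locals$converged[j])) next
      i <- i_map[j]
      mid <- locals$model_id[j]
      pars <- MODEL_PARS[[as.character(mid)]]
      warm0 <- c(S2 = locals$S2[j], tau_int = locals$tau_int[j] * 1e9,
                 Rex = locals$Rex[j])[pars]
      draws <- matrix(NA_real_, n_iter, 3,
                      dimnames = list(NULL, c("S2", "tau_int", "Rex")))
      fails <- 0
      for (it in seq_len(n_iter)) {
        obs2 <- prep$obs[i, , ] +
          matrix(stats::rnorm(length(prep$obs[i, , ])),
                 nrow = dim(prep$obs)[2]) * err_draw[i, , ]
        ft <- fit_local_model(mid, pre, m$tau, m$A[i, ], obs2,
                              prep$eff[i, , ], constants, prep$fields,
                              ref_field_MHz, starts = list(warm0))
        if (is.null(ft) || !ft$converged) { fails <- fails + 1; next }
        draws[it, ] <- c(ft$S2, ft$tau_int, ft$Rex)
      }
      S2e[j] <- stats::sd(draws[, 1], na.rm = TRUE)
      tie[j] <- stats::sd(draws[, 2], na.rm = TRUE)
      rexe[j] <- stats::sd(draws[, 3], na.rm = TRUE)
      unrel[j] <- fails > 0.2 * n_iter
    }
  })
  locals$S2_err <- S2e
  locals$tau_int_err <- ifelse(locals$model_id %in% c(1, 3), tie, NA)
  locals$Rex_err <- ifelse(locals$model_id %in% c(2, 3), rexe, NA)
  locals$mc_unreliable <- unrel
  locals
}
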