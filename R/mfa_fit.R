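#' Model-free analysis of two-field 15N relaxation data
#'
#' The main fitting function of the package. Given an assembled two-field
#' relaxation record table and backbone amide N-H unit vectors in a
#' C2-axis-aligned molecular frame, it fits the fully anisotropic
#' Lipari-Szabo model: a global rotational diffusion tensor
#' (D1, D2, D3, gamma; alpha = beta = 0 by the C2 dimer constraint)
#' anchored on a rigid residue subset, plus per-residue local parameters
#' (S2, tau_int, Rex) with AICc model selection. Tensor and local fits are
#' alternated until the global chi-square stabilizes, then parameter
#' uncertainties are estimated by Monte-Carlo resampling of the
#' observables.
#'
#' @param records data.frame with columns residue_id, field_MHz, R1,
#'   R1_err, R2, R2_err, NOE, NOE_err, complete at both fields (see
#'   [assemble_records()]).
#' @param frame A `structure_frame` (see [structure_frame()]) or a
#'   numeric matrix of unit N-H vectors with residue ids as rownames.
#' @param constants An [nmr_constants()] object.
#' @param ref_field_MHz Field (MHz) at which Rex is quoted; Rex at other
#'   fields scales as the square of the field ratio (fast exchange).
#' @param rigid_ids Residues anchoring the tensor; `NULL` applies
#'   [rigid_subset()].
#' @param force_model Force one local model (0-3) for every residue
#'   instead of AICc selection.
#' @param n_mc Monte-Carlo iterations for parameter errors (default 200);
#'   0 skips the error estimation.
#' @param seed Seed controlling every stochastic step.
#' @param max_rounds,tol Alternation control: stop when the relative
#'   change of the global chi-square drops below `tol` (default 1e-6) or
#'   after `max_rounds` (default 20) rounds.
#' @return Object of class `"mfa"`: list with `tensor`
#'   ([diffusion_tensor()]), `locals` (per-residue data.frame with S2,
#'   tau_int, Rex, model_id, chi2 and MC errors), `chi2` (global),
#'   `rigid_ids`, `records`, `frame`, and the call. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' truth <- synth_ground_truth(n_residues = 20, seed = 7)
#' sim <- simulate_observables(truth, noise = 0)
#' fit <- mfa(sim$records, truth$nh_vectors, n_mc = 0)
#' coef(fit)
#' }
#' @export
mfa <- function(records, frame, constants = nmr_constants(),
                ref_field_MHz = 700, rigid_ids = NULL, force_model = NULL,
                n_mc = 200, seed = 20221116, max_rounds = 20, tol = 1e-6) {
  cl <- match.call()
  nh <- as_nh_matrix(frame)
  prep <- mfa_prep(records, nh, constants, ref_field_MHz)
  if (is.null(rigid_ids))
    rigid_ids <- rigid_subset(records, constants, seed = seed)

  tensor <- fit_global_tensor(records, nh, rigid_ids, constants,
                              ref_field_MHz)
  locals <- fit_all_locals(prep, tensor, force_model = force_model)
  chi2 <- global_chi2(tensor, prep, locals)

  for (round in seq_len(max_rounds)) {
    # tensor update with every converged residue's selected local model
    # held fixed (the initial rigid subset only anchors the first tensor;
    # subsequent rounds use the full residue set)
    use <- locals$residue_id[locals$converged]
    loc_r <- locals[locals$residue_id %in% use, ]
    prep_rigid <- mfa_prep(records[records$residue_id %in% use, ],
                           nh, constants, ref_field_MHz)
    theta <- c(log(tensor$D1), log(tensor$D2), log(tensor$D3),
               tensor$gamma * pi / 180)
    opt <- stats::optim(theta, function(th) {
      pr <- predict_two_field(theta_to_tensor(th), prep_rigid, loc_r)
      v <- sum(((prep_rigid$obs - pr) / prep_rigid$eff)^2)
      if (!is.finite(v)) 1e12 else v
    }, method = "Nelder-Mead",
       control = list(maxit = 500, reltol = 1e-12))
    tensor <- theta_to_tensor(opt$par)
    locals <- fit_all_locals(prep, tensor, force_model = force_model,
                             warm = locals)
    chi2_new <- global_chi2(tensor, prep, locals)
    if (abs(chi2 - chi2_new) <= tol * max(chi2, 1e-12)) {
      chi2 <- chi2_new; break
    }
    chi2 <- chi2_new
  }

  if (n_mc > 0)
    locals <- monte_carlo_errors(locals, records, tensor, nh,
                                 n_iter = n_mc, seed = seed,
                                 constants = constants,
                                 ref_field_MHz = ref_field_MHz)
  structure(list(tensor = tensor, locals = locals, chi2 = chi2,
                 rigid_ids = rigid_ids, records = records, frame = nh,
                 constants = constants, ref_field_MHz = ref_field_MHz,
                 seed = seed, call = cl),
            class = "mfa")
}

global_chi2 <- function(tensor, prep, locals) {
  ok <- locals$converged
  if (!any(ok)) return(Inf)
  pr <- predict_two_field(tensor, prep, locals)
  i <- match(locals$residue_id[ok], prep$ids)
  sum(((prep$obs[i, , , drop = FALSE] - pr[i, , , drop = FALSE]) /
       prep$eff[i, , , drop = FALSE])^2)
}

#' @export
print.mfa <- function(x, ...) {
  cat("Anisotropic model-free fit (C2 dimer constraint)\n")
  cat(sprintf("  residues: %d (%d rigid anchors)   global chi2 = %.4g\n",
              nrow(x$locals), length(x$rigid_ids), x$chi2))
  print(x$tensor)
  mi <- table(factor(x$locals$model_id, levels = 0:3))
  cat(sprintf("  local models: M0=%d M1=%d M2=%d M3=%d\n",
              mi[1], mi[2], mi[3], mi[4]))
  invisible(x)
}

#' @export
coef.mfa <- function(object, ...) {
  t <- object$tensor
  c(D1 = t$D1, D2 = t$D2, D3 = t$D3, gamma = t$gamma,
    D_iso = t$D_iso, tauc_eff = t$tauc_eff)
}

#' @export
summary.mfa <- function(object, segments = NULL, ...) {
  loc <- object$locals
  out <- list(tensor = object$tensor, chi2 = object$chi2,
              n_residues = nrow(loc),
              n_exchange = sum(loc$model_id %in% c(2, 3), na.rm = TRUE),
              mean_S2 = mean(loc$S2, na.rm = TRUE),
              locals = loc)
  if (!is.null(segments))
    out$segment_means <- do.call(rbind, lapply(names(segments), function(s)
      segment_mean(loc, segments[[s]], label = s)))
  class(out) <- "summary.mfa"
  out
}

#' @export
print.summary.mfa <- function(x, ...) {
  print(x$tensor)
  cat(sprintf("%d residues, mean S2 = %.2f, %d with exchange (Rex) term\n",
              x$n_residues, x$mean_S2, x$n_exchange))
  if (!is.null(x$segment_means)) {
    cat("Segment mean S2 (+/- sample SD):\n")
    print(x$segment_means, row.names = FALSE)
  }
  invisible(x)
}

#' Mean order parameter over a residue segment
#'
#' Reports mean +/- sample standard deviation of S2 over a set of
#' residues, the convention used to summarize secondary-structure
#' segments (e.g. a beta strand).
#'
#' @param locals Per-residue table with `residue_id` and `S2`.
#' @param ids Residue ids of the segment.
#' @param label Optional segment name.
#' @return One-row data.frame: segment, n, mean_S2, sd_S2.
#' @examples
#' loc <- data.frame(residue_id = c("A:1", "A:2", "A:3"),
#'                   S2 = c(0.92, 0.94, 0.96))
#' segment_mean(loc, loc$residue_id, "B4")
#' @export
segment_mean <- function(locals, ids, label = "segment") {
  v <- locals$S2[locals$residue_id %in% ids]
  data.frame(segment = label, n = length(v), mean_S2 = mean(v),
             sd_S2 = stats::sd(v))
}

#' @export
fitted.mfa <- function(object, ...) {
  predict.mfa(object)
}

#' Predicted relaxation observables from a model-free fit
#'
#' @param object An `mfa` fit.
#' @param fields Fields (MHz) to predict at; default the fitted fields.
#' @param ... Unused.
#' @return data.frame: residue_id, field_MHz, R1, R2, NOE.
#' @export
predict.mfa <- function(object, fields = NULL, ...) {
  if (is.null(fields)) fields <- sort(unique(object$records$field_MHz))
  loc <- object$locals[object$locals$converged, ]
  vecs <- object$frame[loc$residue_id, , drop = FALSE]
  out <- lapply(fields, function(f) {
    pr <- predict_observables_all(object$tensor, vecs, loc, f,
                                  object$constants, object$ref_field_MHz)
    data.frame(residue_id = loc$residue_id, field_MHz = f, pr)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
residuals.mfa <- function(object, ...) {
  pr <- predict.mfa(object)
  m <- merge(object$records, pr, by = c("residue_id", "field_MHz"),
             suffixes = c("", ".pred"))
  m$R1_res <- m$R1 - m$R1.pred
  m$R2_res <- m$R2 - m$R2.pred
  m$NOE_res <- m$NOE - m$NOE.pred
  m[, c("residue_id", "field_MHz", "R1_res", "R2_res", "NOE_res")]
}

#' @export
plot.mfa <- function(x, which = c("S2", "Rex"), ...) {
  which <- match.arg(which)
  loc <- x$locals[x$locals$converged, ]
  res_no <- suppressWarnings(as.numeric(sub("^[^:]*:", "", loc$residue_id)))
  o <- order(res_no)
  if (which == "S2") {
    plot(res_no[o], loc$S2[o], type = "b", pch = 16, ylim = c(0, 1),
         xlab = "residue", ylab = expression(S^2), ...)
    if ("S2_err" %in% names(loc))
      graphics::arrows(res_no[o], loc$S2[o] - loc$S2_err[o],
                       res_no[o], loc$S2[o] + loc$S2_err[o],
                       angle = 90, code = 3, length = 0.02)
  } else {
    plot(res_no[o], loc$Rex[o], type = "h", lwd = 2,
         xlab = "residue", ylab = expression(R[ex] ~ (s^-1)), ...)
  }
  invisible(x)
}

#' Per-residue and tensor output tables of a model-free fit
#'
#' Writes the per-residue dynamics table and a tensor summary block as
#' TSV with unit-annotated header comments.
#'
#' @param fit An `mfa` object.
#' @param path Output file for the per-residue table; the tensor block is
#'   written to `<path>.tensor.tsv`.
#' @return `path`, invisibly.
#' @export
write_mfa <- function(fit, path) {
  loc <- fit$locals
  loc$tau_int_ps <- loc$tau_int * 1e12
  if ("tau_int_err" %in% names(loc))
    loc$tau_int_err_ps <- loc$tau_int_err * 1e12
  keep <- intersect(c("residue_id", "model_id", "S2", "S2_err",
                      "tau_int_ps", "tau_int_err_ps", "Rex", "Rex_err",
                      "chi2", "converged", "mc_unreliable"), names(loc))
  write_tsv_commented(loc[, keep], path, c(
    "per-residue model-free parameters",
    "S2 dimensionless; tau_int in ps; Rex in 1/s at the reference field",
    sprintf("Rex reference field: %g MHz (quadratic field scaling)",
            fit$ref_field_MHz)))
  t <- fit$tensor
  write_tsv_commented(
    data.frame(D1 = t$D1, D2 = t$D2, D3 = t$D3, gamma_deg = t$gamma,
               D_iso = t$D_iso, tauc_eff_ns = t$tauc_eff * 1e9,
               anisotropy = 2 * t$D3 / (t$D1 + t$D2),
               chi2 = fit$chi2),
    paste0(path, ".tensor.tsv"),
    "global diffusion tensor; rates in 1/s; gamma in degrees about z")
  invisible(path)
}
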