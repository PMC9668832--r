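#' Relaxation delay schedules
#'
#' Bundled acquisition schedules for the longitudinal (R1) and transverse
#' (R2) relaxation series: sixteen delays from 0 to 3520 ms for R1 and
#' nineteen delays from 0 to 250.16 ms for R2. Values are returned in
#' seconds, ready for [fit_exponential()].
#'
#' @param experiment `"R1"` or `"R2"`.
#' @return Numeric vector of delays in seconds, strictly increasing.
#' @examples
#' length(delay_schedule("R1"))   # 16
#' max(delay_schedule("R2"))      # 0.25016 s
#' @export
delay_schedule <- function(experiment = c("R1", "R2")) {
  experiment <- match.arg(experiment)
  if (experiment == "R1") seq(0, 3.520, length.out = 16)
  else seq(0, 0.25016, length.out = 19)
}

#' Peak-intensity decay series
#'
#' Container for one residue's peak heights versus relaxation delay.
#'
#' @param residue_id Chain-qualified residue label (e.g. `"A:57"`).
#' @param delays Relaxation delays in seconds, non-decreasing, >= 3 points
#'   (exact duplicates are allowed and fitted jointly as replicates).
#' @param intensities Peak heights (arbitrary units), same length.
#' @param noise Spectral noise level (same units), > 0.
#' @return Object of class `"decay_series"`.
#' @export
decay_series <- function(residue_id, delays, intensities, noise = 1) {
  delays <- as.numeric(delays); intensities <- as.numeric(intensities)
  if (length(delays) < 3) stop("decay series needs at least 3 points")
  if (length(delays) != length(intensities))
    stop("delays and intensities differ in length")
  if (any(delays < 0)) stop("delays must be >= 0")
  if (is.unsorted(delays)) stop("delays must be non-decreasing")
  if (!is.numeric(noise) || noise <= 0) stop("noise must be > 0")
  structure(list(residue_id = as.character(residue_id), delays = delays,
                 intensities = intensities, noise = noise),
            class = "decay_series")
}

#' Fit a two-parameter exponential decay
#'
#' Nonlinear least-squares fit of \eqn{I(t) = I_0 e^{-R t}} to a peak
#' intensity series. Exactly two parameters are fitted (no baseline
#' offset). The rate standard error is taken from the variance-covariance
#' matrix of the fit. Starting values are `I0 = max|I|` and `R` from the
#' log-ratio of the first and last intensities; on failure the fit is
#' retried from 5 perturbed starts before the series is flagged.
#'
#' @param series A [decay_series()].
#' @return List with `residue_id`, `rate` (s^-1), `rate_err`, `I0`,
#'   `I0_err`, and logical `converged`. A non-convergent series is returned
#'   flagged (`converged = FALSE`, parameters `NA`), never as a silent NaN.
#' @examples
#' s <- decay_series("A:1", delay_schedule("R2"),
#'                   100 * exp(-8 * delay_schedule("R2")))
#' fit_exponential(s)$rate
#' @export
fit_exponential <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$delays; y <- series$intensities
  if (diff(range(y)) == 0) stop("intensities are all equal; nothing to fit")
  I0_0 <- max(abs(y))
  i_min <- which.min(t); i_max <- which.max(t)
  ratio <- y[i_min] / y[i_max]
  R_0 <- if (is.finite(ratio) && ratio > 0)
    log(ratio) / (t[i_max] - t[i_min]) else 1
  R_0 <- max(R_0, 1e-3)

  starts <- rbind(c(I0_0, R_0),
                  cbind(I0_0 * c(1.2, 0.8, 1.5, 1.0, 0.5),
                        R_0 * c(1, 1, 0.5, 3, 1)))
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 * exp(-R * t),
                        start = list(I0 = starts[k, 1], R = starts[k, 2]),
                        lower = c(-Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) c(NA_real_, NA_real_))
      return(list(residue_id = series$residue_id,
                  rate = unname(cf["R"]), rate_err = unname(se[2]),
                  I0 = unname(cf["I0"]), I0_err = unname(se[1]),
                  converged = TRUE))
    }
  }
  list(residue_id = series$residue_id, rate = NA_real_, rate_err = NA_real_,
       I0 = NA_real_, I0_err = NA_real_, converged = FALSE)
}

#' Heteronuclear NOE from saturated/reference intensities
#'
#' The steady-state \{1H\}-15N NOE is the ratio of the peak intensity with
#' 1H saturation to the reference intensity; its uncertainty is propagated
#' from the signal-to-noise ratios of the two peaks:
#' \eqn{\sigma_{NOE} = |NOE| \sqrt{SNR_{sat}^{-2} + SNR_{ref}^{-2}}}.
#' Negative NOEs (flexible termini) pass through unchanged.
#'
#' @param intensity_sat,intensity_ref Peak heights; `intensity_ref != 0`.
#' @param snr_sat,snr_ref Signal-to-noise of each peak, > 0.
#' @param residue_id Optional label carried through.
#' @return List with `NOE` and `NOE_err` (and `residue_id`).
#' @examples
#' compute_noe(50, 100, snr_sat = 50, snr_ref = 100)
#' @export
compute_noe <- function(intensity_sat, intensity_ref, snr_sat, snr_ref,
                        residue_id = NA_character_) {
  if (intensity_ref == 0) stop("reference intensity must be nonzero")
  if (snr_sat <= 0 || snr_ref <= 0) stop("SNR values must be > 0")
  noe <- intensity_sat / intensity_ref
  list(residue_id = residue_id, NOE = noe,
       NOE_err = abs(noe) * sqrt(1 / snr_sat^2 + 1 / snr_ref^2))
}

#' Assemble per-residue relaxation records and apply the complete-set filter
#'
#' Joins per-field R1, R2 and NOE results into one table of relaxation
#' records. Only residues with the complete set of all three observables at
#' every requested field are retained for downstream model-free analysis;
#' everything else goes into the exclusion report with the missing
#' observable named.
#'
#' @param fits Named list: `fits[[field]][[experiment]]` is a data.frame
#'   with columns `residue_id`, `rate`, `rate_err` for experiment `"R1"`
#'   and `"R2"`.
#' @param noes Named list: `noes[[field]]` is a data.frame with columns
#'   `residue_id`, `NOE`, `NOE_err`.
#' @param fields Numeric vector of 1H fields in MHz (names of the lists).
#' @return List with `records` (data.frame: residue_id, field_MHz, R1,
#'   R1_err, R2, R2_err, NOE, NOE_err, complete for all fields) and
#'   `excluded` (data.frame: residue_id, missing).
#' @export
assemble_records <- function(fits, noes, fields) {
  fields <- as.numeric(fields)
  fkeys <- as.character(fields)
  per_field <- list(); missing <- list()
  all_ids <- character(0)
  for (fk in fkeys) {
    for (exp in c("R1", "R2")) {
      tb <- fits[[fk]][[exp]]
      if (anyDuplicated(tb$residue_id))
        stop(sprintf("duplicate residue_id in %s MHz %s table", fk, exp))
      all_ids <- union(all_ids, tb$residue_id)
    }
    if (anyDuplicated(noes[[fk]]$residue_id))
      stop(sprintf("duplicate residue_id in %s MHz NOE table", fk))
    all_ids <- union(all_ids, noes[[fk]]$residue_id)
  }
  records <- list(); excluded <- list()
  for (id in all_ids) {
    miss <- character(0)
    for (fk in fkeys) {
      for (exp in c("R1", "R2")) {
        tb <- fits[[fk]][[exp]]
        row <- tb[tb$residue_id == id & !is.na(tb$rate), , drop = FALSE]
        if (nrow(row) == 0) miss <- c(miss, paste0(exp, "@", fk))
      }
      nb <- noes[[fk]]
      if (!id %in% nb$residue_id[!is.na(nb$NOE)])
        miss <- c(miss, paste0("NOE@", fk))
    }
    if (length(miss) > 0) {
      excluded[[id]] <- data.frame(residue_id = id,
                                   missing = paste(miss, collapse = ","))
      next
    }
    for (fk in fkeys) {
      r1 <- fits[[fk]]$R1[fits[[fk]]$R1$residue_id == id, ]
      r2 <- fits[[fk]]$R2[fits[[fk]]$R2$residue_id == id, ]
      nv <- noes[[fk]][noes[[fk]]$residue_id == id, ]
      records[[paste(id, fk)]] <- data.frame(
        residue_id = id, field_MHz = as.numeric(fk),
        R1 = r1$rate, R1_err = r1$rate_err,
        R2 = r2$rate, R2_err = r2$rate_err,
        NOE = nv$NOE, NOE_err = nv$NOE_err)
    }
  }
  rec <- if (length(records)) do.call(rbind, c(records, make.row.names = FALSE))
         else data.frame(residue_id = character(0), field_MHz = numeric(0),
                         R1 = numeric(0), R1_err = numeric(0),
                         R2 = numeric(0), R2_err = numeric(0),
                         NOE = numeric(0), NOE_err = numeric(0))
  exc <- if (length(excluded)) do.call(rbind, c(excluded, make.row.names = FALSE))
         else data.frame(residue_id = character(0), missing = character(0))
  validate_records(rec)
  list(records = rec, excluded = exc)
}

# Basic invariant checks on an assembled record table.
validate_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  stopifnot(all(records$R1 > 0), all(records$R2 > 0),
            all(records$R1_err >= 0 | is.na(records$R1_err)),
            all(records$R2_err >= 0 | is.na(records$R2_err)),
            all(records$NOE_err >= 0 | is.na(records$NOE_err)))
  if (any(records$NOE > 1.05))
    warning("NOE > 1.05 for ", sum(records$NOE > 1.05),
            " record(s); likely artefacts")
  invisible(records)
}

#' Read a long-format decay table and fit all residues
#'
#' Reads a TSV/CSV with columns `residue_id`, `delay_ms`, `intensity`
#' (delays in milliseconds, converted to seconds internally) and fits each
#' residue's series with [fit_exponential()].
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param noise Spectral noise level passed to [decay_series()].
#' @return data.frame: residue_id, rate (s^-1), rate_err, I0, converged.
#' @export
fit_decay_table <- function(path, noise = 1) {
  df <- read_delim_auto(path)
  req <- c("residue_id", "delay_ms", "intensity")
  if (!all(req %in% names(df)))
    stop("decay table needs columns: ", paste(req, collapse = ", "))
  out <- lapply(split(df, df$residue_id), function(d) {
    d <- d[order(d$delay_ms), ]
    f <- fit_exponential(decay_series(d$residue_id[1], d$delay_ms / 1000,
                                      d$intensity, noise))
    data.frame(residue_id = f$residue_id, rate = f$rate,
               rate_err = f$rate_err, I0 = f$I0, converged = f$converged)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Read an NOE intensity table and compute NOEs
#'
#' Columns: `residue_id`, `intensity_sat`, `intensity_ref`, `snr_sat`,
#' `snr_ref`.
#'
#' @param path File path (TSV, or CSV by extension).
#' @return data.frame: residue_id, NOE, NOE_err.
#' @export
noe_table <- function(path) {
  df <- read_delim_auto(path)
  req <- c("residue_id", "intensity_sat", "intensity_ref",
           "snr_sat", "snr_ref")
  if (!all(req %in% names(df)))
    stop("NOE table needs columns: ", paste(req, collapse = ", "))
  out <- mapply(function(id, is, ir, ss, sr) {
    n <- compute_noe(is, ir, ss, sr, id)
    data.frame(residue_id = id, NOE = n$NOE, NOE_err = n$NOE_err)
  }, df$residue_id, df$intensity_sat, df$intensity_ref,
     df$snr_sat, df$snr_ref, SIMPLIFY = FALSE)
  do.call(rbind, c(out, make.row.names = FALSE))
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "#")
}

write_tsv_commented <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
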