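# Ligand-binding analytics: chemical shift perturbations, the 7PA
# fragment-screening statistic with hit triage, and 1:1 Kd fitting from
# HSQC titrations.

#' Combined amide chemical shift perturbation
#'
#' Weighted combination of the proton and nitrogen shift changes of one
#' amide between two states:
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + 0.1\,\Delta\delta_N^2}}
#' The 0.1 weight compresses the wider 15N ppm scale onto the 1H scale.
#'
#' @param delta_H,delta_N Shift changes in ppm (vectorized); signs are
#'   immaterial.
#' @param w_N Nitrogen weight (default 0.1).
#' @return CSP in ppm, >= 0.
#' @examples
#' csp(0.10, 1.00)   # 0.33166
#' @export
csp <- function(delta_H, delta_N, w_N = 0.1) {
  sqrt(delta_H^2 + w_N * delta_N^2)
}

#' Assigned HSQC peak list
#'
#' @param entries data.frame with columns residue_id, dH_ppm, dN_ppm.
#' @param state_label Label of the sample state (e.g. "free", "mix07").
#' @param spectrometer_MHz 1H frequency used for ppm-to-Hz conversion.
#' @return Object of class `"peak_list"`.
#' @export
peak_list <- function(entries, state_label = "free",
                      spectrometer_MHz = 600) {
  req <- c("residue_id", "dH_ppm", "dN_ppm")
  stopifnot(all(req %in% names(entries)), spectrometer_MHz > 0)
  if (anyDuplicated(entries$residue_id))
    stop("duplicate residue_id in peak list")
  structure(list(entries = entries[, req], state_label = state_label,
                 spectrometer_MHz = spectrometer_MHz),
            class = "peak_list")
}

#' Read a peak list (Sparky-style or TSV)
#'
#' Sparky-style lists are whitespace-delimited with columns
#' `Assignment w1 w2` (w1 = 15N ppm, w2 = 1H ppm) and assignments like
#' `A57N-H`; TSV lists have columns residue_id, dH_ppm, dN_ppm.
#'
#' @param path File path.
#' @param format `"tsv"` or `"sparky"` (guessed from the header when
#'   `"auto"`).
#' @param state_label,spectrometer_MHz Passed to [peak_list()].
#' @param chain Chain id used to qualify Sparky residue numbers.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, format = c("auto", "tsv", "sparky"),
                           state_label = basename(path),
                           spectrometer_MHz = 600, chain = "A") {
  format <- match.arg(format)
  first <- readLines(path, n = 1)
  if (format == "auto")
    format <- if (grepl("residue_id", first)) "tsv" else "sparky"
  if (format == "tsv") {
    df <- read_delim_auto(path)
  } else {
    raw <- utils::read.table(path, header = FALSE, skip = 1,
                             stringsAsFactors = FALSE)
    num <- as.integer(gsub("[^0-9]", "", sub("N-H.*", "", raw[[1]])))
    df <- data.frame(residue_id = paste0(chain, ":", num),
                     dH_ppm = raw[[3]], dN_ppm = raw[[2]])
  }
  peak_list(df, state_label, spectrometer_MHz)
}

#' Per-residue CSP profile between two peak lists
#'
#' Matches peaks by residue id (assigned lists, no nearest-neighbour
#' tracking) and computes the combined CSP of every shared residue.
#'
#' @param free,perturbed [peak_list()] objects.
#' @return data.frame: residue_id, dH_ppm, dN_ppm, csp_ppm.
#' @export
csp_profile <- function(free, perturbed) {
  stopifnot(inherits(free, "peak_list"), inherits(perturbed, "peak_list"))
  m <- merge(free$entries, perturbed$entries, by = "residue_id",
             suffixes = c("_free", "_pert"))
  dH <- m$dH_ppm_pert - m$dH_ppm_free
  dN <- m$dN_ppm_pert - m$dN_ppm_free
  data.frame(residue_id = m$residue_id, dH_ppm = dH, dN_ppm = dN,
             csp_ppm = csp(dH, dN))
}

#' 7PA screening statistic
#'
#' Sum of the absolute amide proton shift changes of seven selected
#' residues between the free and compound-mixture spectra, converted to
#' Hz via the 1H spectrometer frequency (1 ppm = `spectrometer_MHz` Hz).
#'
#' @param free,mixed [peak_list()] objects at the same field.
#' @param selection Exactly the selected residue ids (conventionally 7).
#' @return 7PA in Hz (>= 0).
#' @export
seven_pa <- function(free, mixed, selection) {
  stopifnot(free$spectrometer_MHz == mixed$spectrometer_MHz)
  for (lst in list(free, mixed)) {
    miss <- setdiff(selection, lst$entries$residue_id)
    if (length(miss))
      stop("selected residue(s) missing from '", lst$state_label, "': ",
           paste(miss, collapse = ", "))
  }
  f <- free$entries[match(selection, free$entries$residue_id), ]
  x <- mixed$entries[match(selection, mixed$entries$residue_id), ]
  sum(abs(x$dH_ppm - f$dH_ppm)) * free$spectrometer_MHz
}

#' Triage a fragment screen by 7PA thresholds
#'
#' Classifies screening mixtures as `none`, `hit` (7PA above the hit
#' threshold) or `strong` (above the strong threshold), and reports the
#' screen hit rate as a percentage of the compound library, assuming a
#' fixed number of true hits per hit mixture:
#' `hit_rate = round(100 * n_hit_mixtures * hits_per_mixture /
#' library_size)`.
#'
#' @param records data.frame with columns mixture_id, seven_pa (Hz), and
#'   optionally compound_ids (comma-separated manifest entry).
#' @param library_size Total number of compounds screened.
#' @param hits_per_mixture Assumed true hits per hit mixture (default 1).
#' @param thresholds Named vector `c(hit = 100, strong = 300)` in Hz.
#' @return List of class `"screen_triage"`: `table` (ranked mixtures with
#'   hit_class), `hit_rate_percent` (integer), `n_hit`, `n_strong`.
#' @examples
#' rec <- data.frame(mixture_id = 1:60,
#'                   seven_pa = c(rep(150, 40), rep(10, 20)))
#' triage_screen(rec, library_size = 600)$hit_rate_percent   # 7
#' @export
triage_screen <- function(records, library_size, hits_per_mixture = 1,
                          thresholds = c(hit = 100, strong = 300)) {
  stopifnot(all(records$seven_pa >= 0), library_size > 0)
  if (!is.null(records$compound_ids)) {
    comp <- unlist(strsplit(records$compound_ids, ","))
    if (anyDuplicated(comp))
      warning("overlapping mixture compositions; ",
              "hit rate still computed per mixture")
  }
  cls <- ifelse(records$seven_pa > thresholds["strong"], "strong",
                ifelse(records$seven_pa > thresholds["hit"], "hit", "none"))
  tab <- records
  tab$hit_class <- cls
  tab <- tab[order(-tab$seven_pa), ]
  n_hit <- sum(cls != "none")
  structure(list(table = tab,
                 hit_rate_percent =
                   round(100 * n_hit * hits_per_mixture / library_size),
                 n_hit = n_hit, n_strong = sum(cls == "strong"),
                 thresholds = thresholds),
            class = "screen_triage")
}

#' @export
print.screen_triage <- function(x, ...) {
  cat(sprintf(
    "fragment screen: %d hit mixture(s) (>%g Hz), %d strong (>%g Hz)\n",
    x$n_hit, x$thresholds["hit"], x$n_strong, x$thresholds["strong"]))
  cat(sprintf("hit rate: %d%% of the library\n", x$hit_rate_percent))
  invisible(x)
}

#' Fast-exchange 1:1 binding isotherm
#'
#' Observed shift change of an amide at total ligand concentration L for
#' a single-site equilibrium in fast exchange, as the root of the binding
#' quadratic:
#' \deqn{\delta = \{b - \sqrt{b^2 - 4ac}\}/2a,\quad
#'   a = (K_a/\delta_b) P_t,\; b = 1 + K_a(L + P_t),\;
#'   c = \delta_b K_a L}
#' with \eqn{K_a = 1/K_d}. Identical to the fraction-bound solution of
#' the 1:1 equilibrium multiplied by the complex shift `delta_b`.
#'
#' @param L Total ligand concentration(s), uM.
#' @param Kd Dissociation constant, uM.
#' @param delta_b Shift of the resonance in the complex, ppm.
#' @param P_total Total protein concentration, uM (interpreted exactly as
#'   supplied; no monomer/dimer conversion).
#' @return Shift change(s) in ppm, in [0, delta_b].
#' @export
binding_isotherm <- function(L, Kd, delta_b, P_total) {
  stopifnot(Kd > 0, delta_b > 0, P_total > 0, all(L >= 0))
  Ka <- 1 / Kd
  a <- (Ka / delta_b) * P_total
  b <- 1 + Ka * (L + P_total)
  cc <- delta_b * Ka * L
  (b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

#' Titration series of one amide
#'
#' @param residue_id Amide label.
#' @param P_total Total protein concentration (uM).
#' @param L Total ligand concentrations (uM), strictly increasing,
#'   starting at or implicitly including 0.
#' @param delta Observed shift changes (ppm), `delta = 0` at `L = 0`.
#' @return Object of class `"titration_series"`.
#' @export
titration_series <- function(residue_id, P_total, L, delta) {
  stopifnot(P_total > 0, all(L >= 0), !is.unsorted(L, strictly = TRUE),
            length(L) == length(delta))
  if (L[1] == 0 && abs(delta[1]) > 1e-12)
    stop("shift change at zero ligand must be 0")
  structure(list(residue_id = residue_id, P_total = P_total,
                 points = data.frame(L_uM = L, delta_ppm = delta)),
            class = "titration_series")
}

#' Fit a dissociation constant from one amide's titration
#'
#' Least-squares fit of the 1:1 fast-exchange isotherm
#' ([binding_isotherm()]) to shift change versus total ligand
#' concentration, with `Kd` and the complex shift `delta_b` free.
#' Standard errors come from the variance-covariance matrix of the fit;
#' a singular covariance (saturation not approached) flags the fit as
#' poorly determined.
#'
#' @param series A [titration_series()]; at least 3 nonzero-ligand
#'   points.
#' @return Object of class `"kd_fit"`: residue_id, Kd (uM), Kd_err,
#'   delta_b (ppm), delta_b_err, residuals, flag.
#' @examples
#' L <- c(125, 250, 500, 1000)
#' d <- binding_isotherm(L, Kd = 68, delta_b = 0.30, P_total = 250)
#' fit_kd(titration_series("A:57", 250, L, d))$Kd
#' @export
fit_kd <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points[series$points$L_uM > 0, ]
  if (nrow(pts) < 3) stop("need >= 3 nonzero-ligand titration points")
  Pt <- series$P_total
  start <- list(Kd = stats::median(pts$L_uM),
                delta_b = 1.2 * max(abs(pts$delta_ppm)))
  fit <- minpack.lm::nlsLM(
    delta_ppm ~ binding_isotherm(L_uM, Kd, delta_b, Pt),
    data = pts, start = start,
    lower = c(1e-6, 1e-6), upper = c(1e9, 100),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(NA_real_, NA_real_))
  flag <- if (any(!is.finite(se))) "poorly determined" else ""
  # saturation check: highest point must reach a workable fraction of
  # delta_b, else the (Kd, delta_b) pair is only jointly constrained
  if (flag == "" && max(pts$delta_ppm) < 0.3 * cf["delta_b"])
    flag <- "poorly determined"
  structure(list(residue_id = series$residue_id,
                 Kd = unname(cf["Kd"]), Kd_err = unname(se[1]),
                 delta_b = unname(cf["delta_b"]),
                 delta_b_err = unname(se[2]),
                 residuals = stats::residuals(fit), flag = flag),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd fit [%s]: Kd = %.3g +/- %.2g uM, delta_b = %.3g ppm%s\n",
              x$residue_id, x$Kd, x$Kd_err, x$delta_b,
              if (nzchar(x$flag)) paste0(" (", x$flag, ")") else ""))
  invisible(x)
}

#' Aggregate per-amide Kd fits
#'
#' Reports the mean and sample standard deviation of the dissociation
#' constant over several amides. With a single fit the standard
#' deviation is replaced by that fit's standard error and annotated.
#'
#' @param fits List of [fit_kd()] results (>= 1).
#' @return List: Kd_mean, Kd_sd, n, annotation.
#' @examples
#' # three amides reporting 60, 68, 76 uM -> 68 +/- 8
#' @export
aggregate_kd <- function(fits) {
  stopifnot(length(fits) >= 1)
  kd <- vapply(fits, function(f) f$Kd, 0)
  if (length(kd) == 1)
    return(list(Kd_mean = kd, Kd_sd = fits[[1]]$Kd_err, n = 1L,
                annotation = "single amide: SD replaced by fit SE"))
  list(Kd_mean = mean(kd), Kd_sd = stats::sd(kd), n = length(kd),
       annotation = "")
}

#' Fit Kd across the amides of a titration table
#'
#' Selects the amides whose endpoint CSP exceeds `csp_floor`, fits each
#' with [fit_kd()], and aggregates with [aggregate_kd()].
#'
#' @param df Long table: residue_id, L_uM, csp_ppm (CSP relative to the
#'   free state; 0 at L = 0 rows may be omitted).
#' @param P_total Total protein concentration (uM).
#' @param csp_floor Minimum endpoint CSP (ppm) for an amide to be used
#'   (default 0.05).
#' @return List: `fits` (per amide), `aggregate`, `used` (ids).
#' @export
fit_titrations <- function(df, P_total, csp_floor = 0.05) {
  req <- c("residue_id", "L_uM", "csp_ppm")
  stopifnot(all(req %in% names(df)))
  fits <- list()
  for (id in unique(df$residue_id)) {
    d <- df[df$residue_id == id, ]
    d <- d[order(d$L_uM), ]
    if (max(d$csp_ppm) < csp_floor) next
    s <- titration_series(id, P_total, d$L_uM, d$csp_ppm)
    f <- tryCatch(fit_kd(s), error = function(e) NULL)
    if (!is.null(f)) fits[[id]] <- f
  }
  if (length(fits) == 0) stop("no amide exceeds the CSP floor")
  list(fits = fits, aggregate = aggregate_kd(fits), used = names(fits))
}

#' Global shared-Kd fit across several amides
#'
#' Fits one dissociation constant jointly to the titrations of several
#' amides (each with its own complex shift `delta_b`), the estimator of
#' choice when a single 1:1 event moves many resonances: with the
#' four-point schedule a lone amide leaves Kd and delta_b strongly
#' correlated, while n amides sharpen Kd by roughly sqrt(n).
#'
#' @param series_list List of [titration_series()] sharing one protein
#'   concentration.
#' @return List: Kd, Kd_err (from the covariance matrix), delta_b (named
#'   per amide), n_amides.
#' @export
fit_kd_global <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  Pt <- unique(vapply(series_list, function(s) s$P_total, 0))
  stopifnot(length(Pt) == 1)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(id = s$residue_id, L = s$points$L_uM,
               d = s$points$delta_ppm)))
  df <- df[df$L > 0, ]
  ids <- unique(df$id)
  k <- length(ids)
  # parameters: log(Kd), then delta_b per amide
  start <- c(log(stats::median(df$L)),
             vapply(ids, function(i) 1.2 * max(df$d[df$id == i]), 0))
  residfun <- function(p) {
    Kd <- exp(p[1])
    db <- p[-1]
    pred <- binding_isotherm(df$L, Kd, 1, Pt) *
            db[match(df$id, ids)]
    df$d - pred
  }
  fit <- minpack.lm::nls.lm(start, fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  p <- fit$par
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  Kd <- exp(p[1])
  Kd_err <- if (!is.null(cv)) Kd * sqrt(cv[1, 1]) else NA_real_
  list(Kd = Kd, Kd_err = Kd_err,
       delta_b = stats::setNames(p[-1], ids), n_amides = k)
}
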