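# Synthetic-data generator: every input the pipeline consumes can be
# produced from ground-truth parameters with controlled Gaussian noise,
# fully determined by (parameters, seed).

#' Ground truth for a synthetic two-field relaxation study
#'
#' Defines the study conditions emulated by the generator: a C2-symmetric
#' dimer tumbling anisotropically (default anisotropy 1.5, gamma = 35
#' degrees, tau_c about 11 ns — a BTB-domain-sized dimer), per-residue
#' local dynamics with order parameters in [0.5, 0.98], internal times of
#' 20-200 ps, and exchange terms of 2-6 1/s planted in a fraction of
#' residues, observed at 700 and 950 MHz.
#'
#' @param n_residues Number of residues (one observable set per residue:
#'   symmetry-equivalent chain copies share a single peak).
#' @param tensor Planted [diffusion_tensor()].
#' @param fields_MHz Two 1H fields (default c(700, 950)).
#' @param S2_range,tau_range_ps Ranges for uniform draws of S2 and
#'   tau_int.
#' @param rex_fraction Fraction of residues with planted exchange.
#' @param rex_range Range (1/s, at the reference field) of planted Rex.
#' @param nh_vectors Optional unit-vector matrix (rownames = residue
#'   ids); random orientations are drawn when `NULL`.
#' @param seed RNG seed; recorded in the output.
#' @return List of class `"ground_truth"`: tensor, locals (data.frame
#'   residue_id, S2, tau_int, Rex), nh_vectors, fields_MHz, seed.
#' @export
synth_ground_truth <- function(n_residues = 60,
                               tensor = diffusion_tensor(1.2e7, 1.4e7,
                                                         1.9e7, 35),
                               fields_MHz = c(700, 950),
                               S2_range = c(0.5, 0.98),
                               tau_range_ps = c(20, 200),
                               rex_fraction = 0.2,
                               rex_range = c(2, 6),
                               nh_vectors = NULL, seed = 20221116) {
  withr_seed(seed, {
    if (is.null(nh_vectors)) {
      v <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      rownames(v) <- paste0("A:", seq_len(n_residues))
      nh_vectors <- v
    }
    ids <- rownames(nh_vectors)
    n <- length(ids)
    n_rex <- round(rex_fraction * n)
    rex <- rep(0, n)
    if (n_rex > 0)
      rex[sample.int(n, n_rex)] <- stats::runif(n_rex, rex_range[1],
                                                rex_range[2])
    locals <- data.frame(
      residue_id = ids,
      S2 = stats::runif(n, S2_range[1], S2_range[2]),
      tau_int = stats::runif(n, tau_range_ps[1], tau_range_ps[2]) * 1e-12,
      Rex = rex)
  })
  structure(list(tensor = tensor, locals = locals,
                 nh_vectors = nh_vectors,
                 fields_MHz = sort(fields_MHz), seed = seed),
            class = "ground_truth")
}

#' Simulate two-field relaxation observables from ground truth
#'
#' Evaluates the model-free forward model at every field and adds
#' Gaussian noise: fractional `noise` on R1 and R2, and NOE noise
#' propagated from the signal-to-noise of the reference peak
#' (`NOE_err = sqrt(1 + NOE^2) / snr_noe`), mirroring how experimental
#' NOE errors arise from two peaks sharing one spectral noise level — the
#' absolute error stays finite even when the NOE itself is near zero.
#' Stated errors equal the noise actually applied, so zero noise yields
#' exact forward-model values with zero errors.
#'
#' @param truth A [synth_ground_truth()].
#' @param noise Fractional Gaussian noise on R1/R2 (default 0.02).
#' @param snr_noe Synthetic signal-to-noise of the reference peak
#'   (default `1/noise`; ignored when `noise = 0`).
#' @param constants,ref_field_MHz Forward-model conventions.
#' @param seed RNG seed (defaults to the truth's seed + 1).
#' @return List: `records` (two-field table ready for [mfa()]), `truth`.
#' @export
simulate_observables <- function(truth, noise = 0.02, snr_noe = NULL,
                                 constants = nmr_constants(),
                                 ref_field_MHz = 700, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(seed)) seed <- truth$seed + 1
  if (is.null(snr_noe)) snr_noe <- if (noise > 0) 1 / noise else Inf
  recs <- list()
  for (f in truth$fields_MHz) {
    pr <- predict_observables_all(truth$tensor, truth$nh_vectors,
                                  truth$locals, f, constants,
                                  ref_field_MHz)
    noe_err <- if (is.finite(snr_noe)) sqrt(1 + pr$NOE^2) / snr_noe
               else rep(0, nrow(pr))
    recs[[as.character(f)]] <- data.frame(
      residue_id = truth$locals$residue_id, field_MHz = f,
      R1 = pr$R1, R1_err = noise * pr$R1,
      R2 = pr$R2, R2_err = noise * pr$R2,
      NOE = pr$NOE, NOE_err = noe_err)
  }
  rec <- do.call(rbind, c(recs, make.row.names = FALSE))
  if (noise > 0) {
    withr_seed(seed, {
      rec$R1 <- stats::rnorm(nrow(rec), rec$R1, rec$R1_err)
      rec$R2 <- stats::rnorm(nrow(rec), rec$R2, rec$R2_err)
      rec$NOE <- stats::rnorm(nrow(rec), rec$NOE, rec$NOE_err)
    })
  }
  list(records = rec, truth = truth)
}

#' Expand relaxation rates into synthetic peak-intensity decay series
#'
#' Produces the long-format decay tables the rate-extraction stage reads,
#' at the bundled 16-point (R1) or 19-point (R2) delay schedule, with
#' Gaussian intensity noise.
#'
#' @param rates Named numeric vector of decay rates (s^-1), names =
#'   residue ids.
#' @param experiment `"R1"` or `"R2"` (selects the schedule).
#' @param I0 Initial intensity (arbitrary units).
#' @param noise_frac Gaussian noise SD as a fraction of `I0`.
#' @param seed RNG seed.
#' @return data.frame: residue_id, delay_ms, intensity.
#' @export
simulate_decays <- function(rates, experiment = c("R1", "R2"), I0 = 100,
                            noise_frac = 0.02, seed = 20221116) {
  experiment <- match.arg(experiment)
  sched <- delay_schedule(experiment)
  out <- lapply(names(rates), function(id) {
    data.frame(residue_id = id, delay_ms = sched * 1000,
               intensity = I0 * exp(-rates[[id]] * sched))
  })
  df <- do.call(rbind, c(out, make.row.names = FALSE))
  if (noise_frac > 0)
    withr_seed(seed, {
      df$intensity <- df$intensity +
        stats::rnorm(nrow(df), 0, noise_frac * I0)
    })
  df
}

#' Simulate HSQC titration series
#'
#' Per-amide shift changes on the exact 1:1 fast-exchange isotherm plus
#' Gaussian noise, at the default four-point ligand schedule of 125, 250,
#' 500 and 1000 uM.
#'
#' @param Kd Dissociation constant (uM).
#' @param delta_b Named vector of complex shifts (ppm) per amide.
#' @param P_total Protein concentration (uM, default 250).
#' @param L Ligand schedule (uM).
#' @param noise_frac Gaussian noise SD as a fraction of each amide's
#'   `delta_b`.
#' @param seed RNG seed.
#' @return Named list of [titration_series()].
#' @export
simulate_titration <- function(Kd, delta_b, P_total = 250,
                               L = c(125, 250, 500, 1000),
                               noise_frac = 0, seed = 20221116) {
  stopifnot(Kd > 0, all(delta_b > 0), P_total > 0)
  if (is.null(names(delta_b)))
    names(delta_b) <- paste0("A:", seq_along(delta_b))
  out <- list()
  withr_seed(seed, {
    for (id in names(delta_b)) {
      d <- binding_isotherm(L, Kd, delta_b[[id]], P_total)
      if (noise_frac > 0)
        d <- d + stats::rnorm(length(L), 0, noise_frac * delta_b[[id]])
      out[[id]] <- titration_series(id, P_total, L, d)
    }
  })
  out
}

#' Simulate a fragment screen
#'
#' Generates a free-state peak list plus one perturbed list per mixture
#' of a compound library (default 10 compounds per mixture at 500 uM
#' each). Mixtures containing a planted binder shift the selected 7PA
#' reporter protons by amounts drawn from the effect model; all other
#' peaks receive only noise. The truth manifest is always returned.
#'
#' @param library_size Number of compounds (default 600).
#' @param mixture_size Compounds per mixture (default 10).
#' @param n_binder_mixtures Number of mixtures that contain one planted
#'   binder.
#' @param n_residues Residues in the peak list.
#' @param selection Reporter residue ids (default residues 1-7).
#' @param effect_hz Range of per-proton shift magnitudes (Hz) for binder
#'   mixtures.
#' @param noise_hz Gaussian positional noise (Hz) on every proton shift.
#' @param compound_conc_uM,protein_conc_uM Recorded screening conditions.
#' @param spectrometer_MHz 1H frequency of the screen.
#' @param seed RNG seed.
#' @return List: `free` (peak list), `mixtures` (named list of peak
#'   lists), `manifest` (mixture_id, compound_ids, has_binder,
#'   compound_conc_uM, protein_conc_uM), `selection`.
#' @export
simulate_screen <- function(library_size = 600, mixture_size = 10,
                            n_binder_mixtures = 2, n_residues = 100,
                            selection = NULL,
                            effect_hz = c(20, 80), noise_hz = 0,
                            compound_conc_uM = 500, protein_conc_uM = 150,
                            spectrometer_MHz = 600, seed = 20221116) {
  n_mix <- ceiling(library_size / mixture_size)
  stopifnot(n_binder_mixtures <= n_mix)
  ids <- paste0("A:", seq_len(n_residues))
  if (is.null(selection)) selection <- ids[1:7]
  withr_seed(seed, {
    free_df <- data.frame(residue_id = ids,
                          dH_ppm = stats::runif(n_residues, 7.2, 9.5),
                          dN_ppm = stats::runif(n_residues, 105, 130))
    binder_mix <- sample.int(n_mix, n_binder_mixtures)
    mixtures <- list(); manifest <- list()
    for (m in seq_len(n_mix)) {
      comp <- seq((m - 1) * mixture_size + 1,
                  min(m * mixture_size, library_size))
      df <- free_df
      if (noise_hz > 0)
        df$dH_ppm <- df$dH_ppm +
          stats::rnorm(n_residues, 0, noise_hz) / spectrometer_MHz
      if (m %in% binder_mix) {
        shifts <- stats::runif(length(selection), effect_hz[1],
                               effect_hz[2]) *
                  sample(c(-1, 1), length(selection), replace = TRUE)
        i <- match(selection, df$residue_id)
        df$dH_ppm[i] <- df$dH_ppm[i] + shifts / spectrometer_MHz
      }
      mid <- sprintf("mix%02d", m)
      mixtures[[mid]] <- peak_list(df, mid, spectrometer_MHz)
      manifest[[mid]] <- data.frame(
        mixture_id = mid,
        compound_ids = paste0("cmpd", comp, collapse = ","),
        has_binder = m %in% binder_mix,
        compound_conc_uM = compound_conc_uM,
        protein_conc_uM = protein_conc_uM)
    }
  })
  list(free = peak_list(free_df, "free", spectrometer_MHz),
       mixtures = mixtures,
       manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
       selection = selection)
}

#' Idealized C2-symmetric toy dimer
#'
#' Builds a miniature two-chain structure with exact C2 symmetry about
#' z: chain A is an idealized helical backbone (N, CA, C per residue,
#' amide H at 1.02 Angstrom in the peptide plane), chain B is its exact
#' 180-degree rotation about z.
#'
#' @param n_residues_per_chain Residues per chain (>= 3).
#' @param offset Distance (Angstrom) of the chain A helix axis from the
#'   C2 axis.
#' @return A [structure_frame()] with chains A and B.
#' @export
make_toy_dimer <- function(n_residues_per_chain = 12, offset = 8) {
  n <- n_residues_per_chain
  stopifnot(n >= 3)
  # idealized helix: backbone atoms on a spiral (radius 2.3 A, ~0.5 A
  # rise and 33.3 deg twist per backbone atom), axis parallel to z
  t <- 0:(3 * n - 1)
  ang <- t * 33.3 * pi / 180
  xyz <- cbind(offset + 2.3 * cos(ang), 2.3 * sin(ang), 0.5 * t)
  elety <- rep(c("N", "CA", "C"), n)
  resno <- rep(seq_len(n), each = 3)
  atomsA <- data.frame(chain = "A", resno = resno, resid = "ALA",
                       elety = elety, x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], b = 0, o = 1,
                       stringsAsFactors = FALSE)
  # amide H from the standard peptide-plane construction
  hrows <- list()
  for (i in 2:n) {
    N <- xyz[3 * (i - 1) + 1, ]
    CA <- xyz[3 * (i - 1) + 2, ]
    Cprev <- xyz[3 * (i - 2) + 3, ]
    hdir <- -unitv(unitv(Cprev - N) + unitv(CA - N))
    H <- N + 1.02 * hdir
    hrows[[i]] <- data.frame(chain = "A", resno = i, resid = "ALA",
                             elety = "H", x = H[1], y = H[2], z = H[3],
                             b = 0, o = 1, stringsAsFactors = FALSE)
  }
  atomsA <- rbind(atomsA, do.call(rbind, hrows))
  atomsB <- atomsA
  atomsB$chain <- "B"
  atomsB$x <- -atomsA$x   # exact 180-degree rotation about z
  atomsB$y <- -atomsA$y
  atoms <- rbind(atomsA, atomsB)
  atoms <- atoms[order(atoms$chain, atoms$resno,
                       match(atoms$elety, c("N", "H", "CA", "C"))), ]
  rownames(atoms) <- NULL
  structure_frame(atoms, provenance = "synthetic toy dimer")
}
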