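# Ligand analytics: CSP, 7PA triage, binding isotherm, Kd fitting.

test_that("combined CSP follows the weighted proton/nitrogen formula", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.10, 1.00), sqrt(0.01 + 0.1))
  expect_equal(csp(-0.3, -2), csp(0.3, 2))   # sign symmetry
  # zero iff both components are zero
  expect_gt(csp(0, 0.01), 0)
  expect_gt(csp(0.01, 0), 0)
})

test_that("7PA sums selected proton shifts in Hz", {
  ids <- paste0("A:", 1:10)
  free <- peak_list(data.frame(residue_id = ids, dH_ppm = 8,
                               dN_ppm = 120), "free", 600)
  ent <- free$entries
  sel <- ids[1:7]
  # identical lists -> 0
  expect_equal(seven_pa(free, peak_list(ent, "same", 600), sel), 0)
  # each of 7 protons shifted by 20 Hz -> 140 Hz
  ent2 <- ent
  ent2$dH_ppm[1:7] <- ent2$dH_ppm[1:7] +
    20 / 600 * c(1, -1, 1, -1, 1, -1, 1)
  expect_equal(seven_pa(free, peak_list(ent2, "mix", 600), sel), 140)
  # missing selected residue is named
  expect_error(seven_pa(free, peak_list(ent[-1, ], "m", 600), sel), "A:1")
})

test_that("screen triage reproduces the hit-rate arithmetic", {
  rec <- data.frame(mixture_id = 1:60,
                    seven_pa = c(rep(150, 38), 350, 420, rep(10, 20)))
  tri <- triage_screen(rec, library_size = 600)
  expect_equal(tri$hit_rate_percent, 7)    # 40/600 -> 6.67 -> 7
  expect_equal(tri$n_hit, 40)
  expect_equal(tri$n_strong, 2)
  expect_equal(tri$table$hit_class[1], "strong")  # ranked by 7PA
  # no mixture above threshold -> 0%
  none <- triage_screen(data.frame(mixture_id = 1:6, seven_pa = 50), 600)
  expect_equal(none$hit_rate_percent, 0)
  # 7PA of 350 Hz classifies as strong at the 300 Hz threshold
  one <- triage_screen(data.frame(mixture_id = 1, seven_pa = 350), 10)
  expect_equal(one$table$hit_class, "strong")
})

test_that("overlapping mixture compositions warn but still report", {
  rec <- data.frame(mixture_id = 1:2, seven_pa = c(150, 10),
                    compound_ids = c("c1,c2", "c2,c3"))
  expect_warning(tri <- triage_screen(rec, 30), "overlapping")
  expect_equal(tri$n_hit, 1)
})

test_that("the quadratic isotherm equals the brute-force 1:1 equilibrium", {
  PL <- function(L, Kd, Pt) ((Pt + L + Kd) -
                             sqrt((Pt + L + Kd)^2 - 4 * Pt * L)) / 2
  set.seed(14)
  for (i in 1:20) {
    Kd <- runif(1, 5, 2000); Pt <- runif(1, 50, 500)
    db <- runif(1, 0.05, 1); L <- sort(runif(5, 0, 4000))
    expect_equal(binding_isotherm(L, Kd, db, Pt), db * PL(L, Kd, Pt) / Pt,
                 tolerance = 1e-10)
  }
  # delta(0) = 0 and saturation plateau at delta_b
  expect_equal(binding_isotherm(0, 68, 0.3, 250), 0)
  expect_equal(binding_isotherm(1e9, 68, 0.3, 250), 0.3, tolerance = 1e-4)
})

test_that("isotherm is monotone in L with values in [0, delta_b]", {
  L <- seq(0, 5000, by = 50)
  d <- binding_isotherm(L, 425, 0.22, 250)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0 & d <= 0.22))
})

test_that("noiseless titrations refit Kd and delta_b to < 0.1%", {
  schemes <- list("68" = c(125, 250, 500, 1000),
                  "425" = c(250, 500, 1000, 2000),
                  "870" = c(250, 500, 1000, 2000))
  for (kd_chr in names(schemes)) {
    Kd <- as.numeric(kd_chr); L <- schemes[[kd_chr]]
    d <- binding_isotherm(L, Kd, 0.30, 250)
    fit <- fit_kd(titration_series("A:5", 250, L, d))
    expect_lt(abs(fit$Kd - Kd) / Kd, 1e-3)
    expect_lt(abs(fit$delta_b - 0.30) / 0.30, 1e-3)
  }
})

test_that("Kd aggregation reports mean +/- sample SD with n = 1 policy", {
  mk <- function(kd, err = 5) structure(list(Kd = kd, Kd_err = err),
                                        class = "kd_fit")
  agg <- aggregate_kd(list(mk(60), mk(68), mk(76)))
  expect_equal(agg$Kd_mean, 68)
  expect_equal(agg$Kd_sd, 8)
  expect_equal(aggregate_kd(list(mk(70), mk(70), mk(70)))$Kd_sd, 0)
  one <- aggregate_kd(list(mk(68, err = 9)))
  expect_equal(one$Kd_mean, 68)
  expect_equal(one$Kd_sd, 9)
  expect_match(one$annotation, "SE")
})

test_that("global shared-Kd fit matches per-amide fits on exact data", {
  L <- c(125, 250, 500, 1000)
  db <- c("A:3" = 0.30, "A:9" = 0.18)
  tit <- simulate_titration(68, db, 250, L, noise_frac = 0)
  g <- fit_kd_global(tit)
  expect_lt(abs(g$Kd - 68) / 68, 1e-6)
  expect_equal(unname(g$delta_b), unname(db), tolerance = 1e-6)
})

test_that("titration table driver selects amides above the CSP floor", {
  L <- c(125, 250, 500, 1000)
  db <- c("A:3" = 0.30, "A:9" = 0.02)   # second amide below the floor
  tit <- simulate_titration(68, db, 250, L, noise_frac = 0)
  df <- do.call(rbind, lapply(tit, function(s)
    data.frame(residue_id = s$residue_id, L_uM = s$points$L_uM,
               csp_ppm = s$points$delta_ppm)))
  res <- fit_titrations(df, 250)
  expect_equal(res$used, "A:3")
  expect_equal(res$aggregate$n, 1L)
})

test_that("titration series invariants are enforced", {
  expect_error(titration_series("a", 250, c(0, 100, 50), c(0, 1, 2)))
  expect_error(titration_series("a", 250, c(0, 100), c(0.1, 0.2)),
               "zero ligand")
  expect_error(fit_kd(titration_series("a", 250, c(100, 200), c(0.1, 0.2))),
               ">= 3")
})

test_that("peak lists round-trip through Sparky-style and TSV formats", {
  f <- tempfile()
  writeLines(c("Assignment w1 w2",
               "A57N-H 118.32 8.215",
               "A58N-H 121.04 7.934"), f)
  pl <- read_peak_list(f, spectrometer_MHz = 600)
  expect_equal(pl$entries$residue_id, c("A:57", "A:58"))
  expect_equal(pl$entries$dH_ppm, c(8.215, 7.934))
  expect_equal(pl$entries$dN_ppm, c(118.32, 121.04))
  f2 <- tempfile(fileext = ".tsv")
  write.table(pl$entries, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  pl2 <- read_peak_list(f2, spectrometer_MHz = 600)
  expect_equal(pl2$entries, pl$entries)
})
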