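# Anisotropic spectral density and the relaxation forward model.

test_that("isotropic rigid limit gives J(0) = (2/5) tau_c for any vector", {
  tens <- iso_tensor(9)
  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_equal(anisotropic_J(0, tens, v, S2 = 1, tau_int = 0),
                 0.4 * 9e-9, tolerance = 1e-12)
  }
})

test_that("mode amplitudes sum to one for random tensors and vectors", {
  set.seed(8)
  for (i in 1:1000) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    tn <- diffusion_tensor(runif(1, 0.3, 3) * 1e7, runif(1, 0.3, 3) * 1e7,
                           runif(1, 0.3, 3) * 1e7, runif(1, 0, 360))
    m <- relaxmf:::woessner_modes(tn, v)
    expect_equal(sum(m$A), 1, tolerance = 1e-10)
  }
})

test_that("axially symmetric tensor reduces to the 3-exponential form", {
  Dper <- 1.3e7; Dpar <- 2.1e7
  tens <- diffusion_tensor(Dper, Dper, Dpar, 0)
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    S2 <- runif(1, 0.4, 1); ti <- runif(1, 0, 200e-12)
    ct2 <- v[3]^2
    taus <- 1 / c(6 * Dper, 5 * Dper + Dpar, 2 * Dper + 4 * Dpar)
    As <- c((1.5 * ct2 - 0.5)^2, 3 * ct2 * (1 - ct2), 0.75 * (1 - ct2)^2)
    for (w in c(0, 4e8, 4.5e9)) {
      tp <- if (ti > 0) taus * ti / (taus + ti) else rep(0, 3)
      ref <- 0.4 * sum(As * (S2 * taus / (1 + (w * taus)^2) +
                             (1 - S2) * tp / (1 + (w * tp)^2)))
      expect_equal(anisotropic_J(w, tens, v, S2, ti), ref,
                   tolerance = 1e-10)
    }
  }
})

test_that("isotropic, axial and asymmetric branches agree in shared limits", {
  D <- 1.6e7
  v <- c(0.48, -0.36, sqrt(1 - 0.48^2 - 0.36^2))
  iso <- diffusion_tensor(D, D, D)
  ax <- diffusion_tensor(D, D, D * (1 + 1e-12))
  asym <- diffusion_tensor(D * (1 + 1e-12), D * (1 - 1e-12), D, 20)
  for (w in c(0, 5e8, 4e9)) {
    J0 <- anisotropic_J(w, iso, v, 0.85, 40e-12)
    expect_equal(anisotropic_J(w, ax, v, 0.85, 40e-12), J0,
                 tolerance = 1e-10)
    expect_equal(anisotropic_J(w, asym, v, 0.85, 40e-12), J0,
                 tolerance = 1e-10)
  }
})

test_that("J is non-negative and non-increasing in omega for S2 = 1", {
  tens <- diffusion_tensor(1.2e7, 1.4e7, 1.9e7, 35)
  set.seed(6)
  ws <- sort(c(0, 10^seq(6, 10.5, length.out = 40)))
  for (i in 1:5) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    J <- anisotropic_J(ws, tens, v, 1, 0)
    expect_true(all(J >= 0))
    expect_true(all(diff(J) <= 1e-20))
  }
})

test_that("isotropic forward prediction matches an independent
           implementation substituted into the same equations", {
  tauc <- 8e-9; S2 <- 0.87; ti <- 60e-12
  tens <- iso_tensor(8)
  cst <- nmr_constants()
  for (f in c(700, 950)) {
    ic <- relaxmf:::interaction_constants(f, cst)
    w <- c(0, ic$wN, ic$wH - ic$wN, ic$wH, ic$wH + ic$wN)
    J <- vapply(w, iso_J_ref, 0, tauc = tauc, S2 = S2, tau_int = ti)
    D <- ic$D; C <- ic$C
    R1 <- D * (J[3] + 3 * J[2] + 6 * J[5]) + C * J[2]
    R2 <- (D / 2) * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] + 6 * J[5]) +
          (C / 6) * (4 * J[1] + 3 * J[2])
    NOE <- 1 + (cst$gamma_H / cst$gamma_N) * D * (6 * J[5] - J[3]) / R1
    p <- predict_observables(tens, c(0.6, 0.64, 0.48), S2, ti, 0, f)
    expect_equal(p[["R1"]], R1, tolerance = 1e-12)
    expect_equal(p[["R2"]], R2, tolerance = 1e-12)
    expect_equal(p[["NOE"]], NOE, tolerance = 1e-12)
  }
})

test_that("Rex adds exactly to R2 at the reference field and scales as B^2", {
  tens <- diffusion_tensor(1.2e7, 1.4e7, 1.9e7, 35)
  v <- c(0.2, 0.5, sqrt(1 - 0.29))
  p0 <- predict_observables(tens, v, 0.85, 50e-12, 0, 700)
  p5 <- predict_observables(tens, v, 0.85, 50e-12, 5, 700)
  expect_equal(p5[["R2"]] - p0[["R2"]], 5)
  expect_equal(p5[["R1"]], p0[["R1"]])
  expect_equal(p5[["NOE"]], p0[["NOE"]])
  q0 <- predict_observables(tens, v, 0.85, 50e-12, 0, 950)
  q5 <- predict_observables(tens, v, 0.85, 50e-12, 5, 950)
  expect_equal(q5[["R2"]] - q0[["R2"]], 5 * (950 / 700)^2)
})

test_that("extreme narrowing brings R1 and R2 together", {
  tens <- iso_tensor(0.01)   # 10 ps
  # dipolar-dominated limit (negligible CSA): textbook R1 = R2
  cst0 <- nmr_constants(delta_sigma = -1e-6)
  p <- predict_observables(tens, c(0, 0, 1), 1, 0, 0, 700, cst0)
  expect_lt(abs(p[["R2"]] - p[["R1"]]) / p[["R1"]], 0.005)
  # with the 15N CSA the narrowing ratio picks up the 7/6 CSA factor
  pc <- predict_observables(tens, c(0, 0, 1), 1, 0, 0, 700)
  expect_lt(abs(pc[["R2"]] - pc[["R1"]]) / pc[["R1"]], 0.02)
})

test_that("tensor canonicalization folds gamma and orders D1 <= D2", {
  a <- diffusion_tensor(1.4e7, 1.2e7, 1.9e7, 35)
  expect_lte(a$D1, a$D2)
  expect_equal(a$gamma, 125)          # swap adds 90 degrees
  b <- diffusion_tensor(1.2e7, 1.4e7, 1.9e7, 215)
  expect_equal(b$gamma, 35)           # gamma + 180 is the same tensor
  v <- c(0.3, 0.8, sqrt(1 - 0.73))
  J1 <- anisotropic_J(5e8, diffusion_tensor(1.2e7, 1.4e7, 1.9e7, 35),
                      v, 0.9, 0)
  expect_equal(anisotropic_J(5e8, b, v, 0.9, 0), J1, tolerance = 1e-12)
  # rotating the tensor frame by gamma equals rotating the bond vector
  # by -gamma in the gamma = 0 frame
  g <- 35 * pi / 180
  vr <- c(cos(g) * v[1] + sin(g) * v[2],
          -sin(g) * v[1] + cos(g) * v[2], v[3])
  J2 <- anisotropic_J(5e8, diffusion_tensor(1.2e7, 1.4e7, 1.9e7, 0),
                      vr, 0.9, 0)
  expect_equal(J2, J1, tolerance = 1e-12)
})
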