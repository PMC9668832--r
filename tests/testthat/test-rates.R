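# Rate extraction: exponential decay fits, NOE computation, assembly.

test_that("delay schedules match the acquisition description", {
  r1 <- delay_schedule("R1")
  r2 <- delay_schedule("R2")
  expect_length(r1, 16)
  expect_equal(max(r1), 3.520)
  expect_length(r2, 19)
  expect_equal(max(r2), 0.25016)
  expect_true(all(diff(r1) > 0) && all(diff(r2) > 0))
})

test_that("noiseless decays are recovered exactly across the rate range", {
  sched <- delay_schedule("R2")
  f <- fit_exponential(decay_series("A:1", sched, 100 * exp(-8 * sched)))
  expect_equal(f$rate, 8.0, tolerance = 1e-9)
  expect_true(f$converged)
  for (R in c(0.1, 1, 10, 100)) {
    sc <- if (R < 1) delay_schedule("R1") else delay_schedule("R2")
    fr <- fit_exponential(decay_series("x", sc, 50 * exp(-R * sc)))
    expect_lt(abs(fr$rate - R) / R, 1e-8)
  }
})

test_that("noisy decay fit matches a dense grid-search oracle", {
  sched <- delay_schedule("R2")
  set.seed(11)
  y <- 100 * exp(-8 * sched) + rnorm(length(sched), 0, 2)
  fit <- fit_exponential(decay_series("A:1", sched, y))
  # oracle: dense grid over R with I0 profiled in closed form
  grid <- seq(0.5, 30, by = 1e-3)
  sse <- vapply(grid, function(R) {
    e <- exp(-R * sched)
    I0 <- sum(y * e) / sum(e * e)
    sum((y - I0 * e)^2)
  }, 0)
  R_oracle <- grid[which.min(sse)]
  expect_lt(abs(fit$rate - R_oracle), 1e-3 + 1e-6)
})

test_that("rate uncertainty shrinks monotonically with noise level", {
  sched <- delay_schedule("R2")
  errs <- vapply(c(4, 2, 1, 0.25), function(s) {
    reps <- vapply(1:8, function(r) {
      set.seed(100 * s + r)
      y <- 100 * exp(-8 * sched) + rnorm(length(sched), 0, s)
      fit_exponential(decay_series("x", sched, y))$rate_err
    }, 0)
    mean(reps)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("replicate delay points are fitted jointly", {
  sched <- c(0, 0, 0.05, 0.05, 0.1, 0.2)
  f <- fit_exponential(decay_series("A:1", sched, 10 * exp(-5 * sched)))
  expect_equal(f$rate, 5, tolerance = 1e-8)
})

test_that("degenerate decay inputs are rejected", {
  expect_error(decay_series("A:1", c(0, 0.1), c(1, 2)), "at least 3")
  expect_error(decay_series("A:1", c(0, -0.1, 0.2), c(1, 2, 3)), ">= 0")
  expect_error(decay_series("A:1", c(0.2, 0.1, 0.3), c(1, 2, 3)),
               "non-decreasing")
  s <- decay_series("A:1", c(0, 0.1, 0.2), c(5, 5, 5))
  expect_error(fit_exponential(s), "all equal")
})

test_that("NOE ratio and its SNR propagation follow the stated formula", {
  n <- compute_noe(50, 100, snr_sat = 50, snr_ref = 100)
  expect_equal(n$NOE, 0.5)
  expect_equal(n$NOE_err, 0.5 * sqrt(1 / 2500 + 1 / 10000))
  expect_equal(compute_noe(100, 100, 50, 50)$NOE, 1.0)
  expect_equal(compute_noe(-30, 100, 40, 80)$NOE, -0.3)
  # scale invariance of the ratio
  a <- compute_noe(50, 100, 50, 100)
  for (k in c(-3, 0.01, 7)) {
    b <- compute_noe(50 * k, 100 * k, 50, 100)
    expect_equal(b$NOE, a$NOE)
  }
  expect_error(compute_noe(10, 0, 50, 50), "nonzero")
})

test_that("complete-set filter retains exactly the intersection", {
  ids <- paste0("A:", 1:100)
  mk <- function(drop = character(0)) {
    keep <- setdiff(ids, drop)
    data.frame(residue_id = keep, rate = 1.5, rate_err = 0.02)
  }
  mkn <- function(drop = character(0)) {
    keep <- setdiff(ids, drop)
    data.frame(residue_id = keep, NOE = 0.8, NOE_err = 0.01)
  }
  set.seed(3)
  drops <- replicate(6, sample(ids, 10), simplify = FALSE)
  fits <- list("700" = list(R1 = mk(drops[[1]]), R2 = mk(drops[[2]])),
               "950" = list(R1 = mk(drops[[3]]), R2 = mk(drops[[4]])))
  noes <- list("700" = mkn(drops[[5]]), "950" = mkn(drops[[6]]))
  asm <- assemble_records(fits, noes, c(700, 950))
  expected <- Reduce(intersect, lapply(drops, function(d) setdiff(ids, d)))
  expect_setequal(unique(asm$records$residue_id), expected)
  expect_setequal(asm$excluded$residue_id,
                  setdiff(ids, expected))
  # one missing observable is named in the report
  one <- assemble_records(
    list("700" = list(R1 = mk("A:7"), R2 = mk())),
    list("700" = mkn()), 700)
  expect_equal(one$excluded$residue_id, "A:7")
  expect_match(one$excluded$missing, "R1@700")
  # all complete -> empty exclusion report
  full <- assemble_records(list("700" = list(R1 = mk(), R2 = mk())),
                           list("700" = mkn()), 700)
  expect_equal(nrow(full$excluded), 0)
})

test_that("duplicate residue ids within one field table are an error", {
  bad <- data.frame(residue_id = c("A:1", "A:1"), rate = 1, rate_err = 0)
  ok <- data.frame(residue_id = "A:1", rate = 1, rate_err = 0)
  noe <- data.frame(residue_id = "A:1", NOE = 0.8, NOE_err = 0.01)
  expect_error(assemble_records(list("700" = list(R1 = bad, R2 = ok)),
                                list("700" = noe), 700), "duplicate")
})

test_that("decay and NOE tables round-trip through files in ms units", {
  sched <- delay_schedule("R1")
  df <- data.frame(residue_id = rep(c("A:1", "A:2"), each = 16),
                   delay_ms = rep(sched * 1000, 2),
                   intensity = c(90 * exp(-1.2 * sched),
                                 70 * exp(-0.8 * sched)))
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  fits <- fit_decay_table(f)
  expect_equal(fits$rate[fits$residue_id == "A:1"], 1.2, tolerance = 1e-8)
  expect_equal(fits$rate[fits$residue_id == "A:2"], 0.8, tolerance = 1e-8)
})
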