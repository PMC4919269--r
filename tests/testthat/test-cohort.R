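test_that("tissue simulation matches closed forms", {
  sched <- default_sched
  # near-constant input (tiny decay rate): plateau K1*C0/k2
  C0 <- 10
  const_in <- input_function(C0, 1e-8, delay_min = 0)
  ct <- simulate_tissue_tac(const_in, 0.8, 0.15, sched)
  tmid <- frame_midpoints_min(sched)
  expect_equal(ct$values[33] / (0.8 * C0 / 0.15 * (1 - exp(-0.15 * tmid[33]))),
               1, tolerance = 1e-4)
  # zero input -> all-zero TAC
  zero_in <- input_function(0, 1, delay_min = 0)
  expect_equal(simulate_tissue_tac(zero_in, 0.8, 0.15, sched)$values,
               rep(0, 33))
  # k2 = 0 irreversible trapping: C_T = K1 * int_0^t C_p (quadrature oracle)
  f <- input_function(c(50, 5), c(2, 0.05), delay_min = 0.1)
  trap <- simulate_tissue_tac(f, 0.6, 0, sched)
  oracle <- vapply(seq_len(33), function(i) {
    a <- sched$start_s[i] / 60
    b <- a + sched$duration_s[i] / 60
    stats::integrate(function(t)
      vapply(t, function(ti) 0.6 * auc(f, 0, max(ti, 1e-9)), numeric(1)),
      a, b, subdivisions = 500L, rel.tol = 1e-9)$value / (b - a)
  }, numeric(1))
  expect_equal(trap$values, oracle, tolerance = 1e-6)
})

test_that("input scaling propagates linearly to tissue and AUC", {
  f <- default_input_function()
  f3 <- scale_input_function(f, 3)
  ct1 <- simulate_tissue_tac(f, 0.8, 0.15, default_sched)
  ct3 <- simulate_tissue_tac(f3, 0.8, 0.15, default_sched)
  expect_equal(ct3$values, 3 * ct1$values, tolerance = 1e-12)
  expect_equal(auc(f3, 0, 90), 3 * auc(f, 0, 90), tolerance = 1e-12)
})

test_that("noise model has the stated magnitude and is reproducible", {
  sched <- frame_schedule(0, 30)   # one 30-s frame
  base <- tac(sched, 100)
  reps <- vapply(1:1000, function(i)
    add_noise(base, 1.5, seed = i)$values, numeric(1))
  sigma <- 1.5 * sqrt(100 / 0.5)
  expect_equal(sd(reps), sigma, tolerance = 0.05)
  # zero scale is the identity; fixed seed is bitwise reproducible
  expect_identical(add_noise(base, 0, seed = 1)$values, base$values)
  full <- tac(default_sched, rep(50, 33))
  expect_identical(add_noise(full, 2, seed = 9)$values,
                   add_noise(full, 2, seed = 9)$values)
  expect_true(all(add_noise(tac(sched, 0.001), 50, seed = 2)$values >= 0))
})

test_that("cohorts are deterministic, sized correctly and carry truth", {
  p <- default_presets()$Tg
  c1 <- simulate_cohort(p, seed = 11)
  c2 <- simulate_cohort(p, seed = 11)
  expect_equal(length(c1), 8L)
  expect_identical(lapply(c1$subjects, function(s) s$idif$values),
                   lapply(c2$subjects, function(s) s$idif$values))
  expect_identical(lapply(c1$subjects, function(s) s$cortex_left$values),
                   lapply(c2$subjects, function(s) s$cortex_left$values))
  expect_equal(length(simulate_cohort(p, n = 0, seed = 1)), 0L)
  expect_error(simulate_cohort(p, n = -1, seed = 1), ">=")
  s1 <- c1$subjects[[1]]
  expect_s3_class(s1$subject, "subject_record")
  expect_equal(s1$truth$K1, p$true_K1)
  expect_true(s1$subject$body_weight_g > 15)
  expect_true(s1$subject$injected_dose_kBq > 1000)
})

test_that("noiseless cohort TACs reproduce the forward model exactly", {
  p <- default_presets()$WT
  coh <- simulate_cohort(p, n = 1, seed = 3, noise = FALSE)
  s <- coh$subjects[[1]]
  expect_equal(s$cortex_left$values,
               simulate_tissue_tac(s$truth$input_fn, p$true_K1, p$true_k2,
                                   default_sched)$values)
  expect_equal(s$idif$values,
               frame_average(s$truth$input_fn, default_sched)$values)
})

test_that("fitting a noiseless cohort recovers the preset truth to 0.1%", {
  p <- default_presets()$Tg
  coh <- simulate_cohort(p, n = 2, seed = 5, noise = FALSE)
  for (s in coh$subjects) {
    fit <- fit_1tcm(s$cortex_left, s$idif)
    expect_false(fit$excluded)
    expect_lt(abs(coef(fit)[["K1"]] / p$true_K1 - 1), 1e-3)
    expect_lt(abs(coef(fit)[["k2"]] / p$true_k2 - 1), 1e-3)
  }
})

test_that("cohort export writes readable manifests and TACs", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(default_presets()$WT, n = 2, seed = 4)
  export_cohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(man), 2L)
  expect_equal(gt$K1, rep(0.8, 2))
  back <- read_tac(file.path(dir, "WT_01_idif.csv"))
  expect_equal(back$values, coh$subjects[[1]]$idif$values)
})
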