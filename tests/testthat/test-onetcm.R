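test_that("forward prediction matches the mono-exponential closed form", {
  sched <- uniform_frame_schedule(30, 5400)
  in_sched <- uniform_frame_schedule(6, 5400)  # finely sampled input
  A <- 100; lambda <- 0.25; K1 <- 0.8; k2 <- 0.15
  cp <- tac(in_sched, monoexp_frame_avg(A, lambda, in_sched))
  pred <- forward_1tcm(cp, K1, k2, schedule = sched)
  oracle <- monoexp_ct_frame_avg(A, lambda, K1, k2, sched)
  expect_lt(max(abs(pred$values - oracle) / pmax(oracle, max(oracle) * 1e-3)),
            0.005)
})

test_that("forward prediction matches the constant-input closed form", {
  sched <- uniform_frame_schedule(30, 5400)
  C0 <- 10; K1 <- 0.8; k2 <- 0.15
  cp <- tac(sched, rep(C0, sched$count))
  pred <- forward_1tcm(cp, K1, k2)
  a <- sched$start_s / 60; b <- a + 0.5
  oracle <- K1 * C0 / k2 *
    ((b - a) - (exp(-k2 * a) - exp(-k2 * b)) / k2) / (b - a)
  expect_lt(max(abs(pred$values - oracle) / oracle), 0.005)
  # plateau approaches K1 C0 / k2 = 5.333 C0
  expect_equal(pred$values[sched$count], K1 * C0 / k2, tolerance = 1e-4)
  # K1 = 0 gives an all-zero prediction
  expect_equal(forward_1tcm(cp, 0, k2)$values, rep(0, sched$count))
})

test_that("forward prediction is grid-converged", {
  cp <- frame_average(ref_input, default_sched)
  p1 <- forward_1tcm(cp, 0.8, 0.15, fine_dt = 0.0025)
  p2 <- forward_1tcm(cp, 0.8, 0.15, fine_dt = 0.00125)
  expect_lt(max(abs(p1$values - p2$values) /
                  pmax(p2$values, max(p2$values) * 1e-3)), 1e-3)
})

test_that("noiseless roundtrip fit recovers the generating parameters", {
  cp <- frame_average(ref_input, default_sched)
  ct <- forward_1tcm(cp, 0.8, 0.15)
  fit <- fit_1tcm(ct, cp)
  expect_true(fit$converged)
  expect_false(fit$excluded)
  expect_lt(abs(coef(fit)[["K1"]] / 0.8 - 1), 1e-3)
  expect_lt(abs(coef(fit)[["k2"]] / 0.15 - 1), 1e-3)
  expect_lt(fit$rss, 1e-6 * sum(ct$values^2))
  # standard errors are tiny for a noiseless fit
  expect_lt(fit$se[["K1"]] / coef(fit)[["K1"]], 0.05)
})

test_that("RSS at truth is a local minimum over a parameter grid", {
  cp <- frame_average(ref_input, default_sched)
  ct <- simulate_tissue_tac(ref_input, 0.8, 0.15, default_sched)
  rss_at <- function(K1, k2)
    sum((forward_1tcm(cp, K1, k2)$values - ct$values)^2)
  fit <- fit_1tcm(ct, cp)
  rss0 <- rss_at(coef(fit)[["K1"]], coef(fit)[["k2"]])
  grid <- expand.grid(K1 = coef(fit)[["K1"]] * seq(0.9, 1.1, length.out = 5),
                      k2 = coef(fit)[["k2"]] * seq(0.9, 1.1, length.out = 5))
  rss_grid <- mapply(rss_at, grid$K1, grid$k2)
  expect_true(all(rss_grid >= rss0 - 1e-9 * rss0))
})

test_that("degenerate all-zero tissue is pinned at the bound and excluded", {
  cp <- frame_average(ref_input, default_sched)
  ct <- tac(default_sched, rep(0, 33))
  fit <- fit_1tcm(ct, cp)
  expect_equal(coef(fit)[["K1"]], 1e-4)
  expect_true(fit$excluded)
  expect_match(fit$exclusion_reason, "K1 out of range")
})

test_that("physiological gate applies the stated rules", {
  expect_true(is_physiological(list(K1 = 0.8, k2 = 0.15, se_K1 = 0.01))$ok)
  expect_equal(is_physiological(list(K1 = 0.8, k2 = 7))$reason,
               "k2 out of range")
  expect_equal(is_physiological(list(K1 = 0.8, k2 = 0.15, se_K1 = 2.4))$reason,
               "unidentifiable")
  expect_equal(is_physiological(list(K1 = 1e-4, k2 = 0.15))$reason,
               "K1 out of range")
  expect_equal(is_physiological(list(K1 = 12, k2 = 0.15))$reason,
               "K1 out of range")
  expect_equal(is_physiological(list(K1 = 0.8, k2 = 0))$reason,
               "k2 out of range")
  expect_equal(is_physiological(list(K1 = 0.8, k2 = 0.15,
                                     converged = FALSE))$reason,
               "no convergence")
})

test_that("onetcm methods behave like a standard fitted-model object", {
  cp <- frame_average(ref_input, default_sched)
  ct <- simulate_tissue_tac(ref_input, 0.8, 0.15, default_sched)
  fit <- fit_1tcm(ct, cp)
  expect_named(coef(fit), c("K1", "k2"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_equal(fitted(fit) + residuals(fit), ct$values)
  s <- summary(fit)
  expect_equal(s$vt, coef(fit)[["K1"]] / coef(fit)[["k2"]])
  pred <- predict(fit)
  expect_equal(pred$values, fitted(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1, noise_scale = 1)
  expect_length(sims, 2L)
  expect_false(identical(sims[[1]]$values, sims[[2]]$values))
  expect_output(print(fit), "K1")
  expect_output(print(s), "Distribution volume")
})
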