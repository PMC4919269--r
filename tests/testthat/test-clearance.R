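test_that("AUC uses the frame-rectangle rule with partial overlap", {
  expect_equal(auc(tac(default_sched, rep(2, 33)), 0, 90), 180)
  # frames partially inside the window contribute proportionally
  s <- frame_schedule(c(0, 60), c(60, 60))
  expect_equal(auc(tac(s, c(6, 12)), 0.5, 1.5), 6 * 0.5 + 12 * 0.5)
  expect_error(auc(tac(s, c(1, 2)), 1, 1), "> 't0'")
  expect_error(auc(tac(s, c(1, 2)), 0, 5), "within the schedule")
})

test_that("AUC is invariant to refining frames with the same value", {
  s1 <- frame_schedule(c(0, 60), c(60, 120))
  s2 <- frame_schedule(c(0, 30, 60, 120), c(30, 30, 60, 60))
  expect_equal(auc(tac(s1, c(4, 7)), 0, 3), auc(tac(s2, c(4, 4, 7, 7)), 0, 3))
})

test_that("frame-sampled AUC of the default input matches quadrature", {
  fa <- frame_average(ref_input, default_sched)
  direct <- stats::integrate(function(t) predict(ref_input, t), 0, 90,
                             subdivisions = 2000, rel.tol = 1e-10)$value
  expect_equal(auc(fa, 0, 90) / direct, 1, tolerance = 0.02)
})

test_that("TBC implements ID per kg over AUC with the stated units", {
  s <- subject_record("m1", "WT", body_weight_g = 20,
                      injected_dose_kBq = 7700)
  idif <- tac(default_sched, rep(1000 / 90, 33))  # AUC(0-90) = 1000
  res <- tbc(s, idif)
  expect_equal(res$id_per_kg, 385000)
  expect_equal(res$tbc, 385, tolerance = 1e-12)
  # doubling the AUC at fixed dose halves TBC
  res2 <- tbc(s, tac(default_sched, rep(2000 / 90, 33)))
  expect_equal(res2$tbc, res$tbc / 2, tolerance = 1e-12)
  # partial-volume dilution d inflates TBC by 1/d
  d <- 0.8
  diluted <- tac(default_sched, idif$values * d)
  expect_equal(tbc(s, diluted)$tbc, res$tbc / d, tolerance = 1e-12)
  expect_error(tbc(s, tac(default_sched, rep(0, 33))), "zero")
  expect_error(tbc(s, to_suv(idif, s)), "concentration")
})

test_that("TBC is invariant to joint dose and amplitude scaling", {
  coh <- simulate_cohort(default_presets()$WT, n = 1, seed = 8,
                         noise = FALSE)
  s <- coh$subjects[[1]]
  base <- tbc(s$subject, s$idif)$tbc
  s2 <- subject_record("m2", "WT", s$subject$body_weight_g,
                       s$subject$injected_dose_kBq * 3)
  idif2 <- tac(s$idif$schedule, s$idif$values * 3)
  expect_equal(tbc(s2, idif2)$tbc, base, tolerance = 1e-12)
})

test_that("fold change is the ratio of group means with direction", {
  expect_equal(as.numeric(fold_change(c(2, 2), c(1, 1))), 2)
  expect_equal(as.numeric(fold_change(c(3, 3), c(3, 3))), 1)
  expect_equal(attr(fold_change(c(1, 1), c(2, 2)), "direction"), "down")
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero mean")
  # noiseless WT vs Tg TBC fold-change is exactly the plasma scale
  wt <- simulate_cohort(default_presets()$WT, seed = 2, noise = FALSE)
  tg <- simulate_cohort(default_presets()$Tg, seed = 2, noise = FALSE)
  tbc_of <- function(coh)
    vapply(coh$subjects, function(s) tbc(s$subject, s$idif)$tbc, numeric(1))
  expect_equal(as.numeric(fold_change(tbc_of(wt), tbc_of(tg))), 1.8,
               tolerance = 1e-9)
})
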