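test_that("input function is zero before the delay and non-negative after", {
  f <- default_input_function()
  expect_equal(predict(f, c(0, 0.05, 0.0999)), c(0, 0, 0))
  expect_true(all(predict(f, seq(0.1, 90, by = 0.5)) >= 0))
  expect_error(input_function(c(1, 2), c(1, -0.1)), "> 0")
  expect_error(input_function(c(-1), c(1)), "non-negative")
})

test_that("preset scaling multiplies the AUC exactly (quadrature oracle)", {
  ref <- default_input_function()
  quad <- function(f) {
    stats::integrate(function(t) predict(f, t), 0, 90,
                     subdivisions = 2000, rel.tol = 1e-10)$value
  }
  auc_ref <- quad(ref)
  for (ps in c(1, 1.8, 1 / 1.1, 3.0)) {
    preset <- group_preset("x", 1, 0.8, 0.15, ps)
    scaled <- make_input_function(preset, ref)
    expect_equal(quad(scaled) / auc_ref, ps, tolerance = 1e-8)
    expect_equal(auc(scaled, 0, 90) / auc(ref, 0, 90), ps, tolerance = 1e-12)
  }
  # identity case leaves the curve unchanged
  ident <- make_input_function(group_preset("c", 1, 0.8, 0.15, 1), ref)
  expect_equal(predict(ident, c(0.5, 5, 60)), predict(ref, c(0.5, 5, 60)))
  expect_error(group_preset("bad", 1, 0.8, 0.15, 0), "> 0")
})

test_that("frame averages match the analytic integral of the model", {
  f <- input_function(100, 0.3, delay_min = 0)
  fa <- frame_average(f, default_sched)
  expect_equal(fa$values, monoexp_frame_avg(100, 0.3, default_sched),
               tolerance = 1e-10)
})

test_that("bladder curve is the non-decreasing cumulative excretion", {
  b <- bladder_tac(ref_input, default_sched, scale = 0.4)
  expect_true(all(diff(b$values) >= -1e-12))
  # late-frame level approaches scale * total input integral
  expect_equal(b$values[33] / (0.4 * auc(ref_input, 0, 89.9)), 1,
               tolerance = 0.05)
})
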