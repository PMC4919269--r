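# shared fixtures for the test suite

default_sched <- default_frame_schedule()
ref_input <- default_input_function()

# small grid so phantom tests stay fast and light on memory
test_geometry <- function() {
  default_phantom_geometry(dim = c(32, 32, 48), voxel_mm = c(0.8, 0.8, 0.8))
}

# analytic frame averages of the closed-form 1TCM solution for a
# mono-exponential input C_p = A exp(-lambda t) (no delay):
#   C_T(t) = K1 A (exp(-lambda t) - exp(-k2 t)) / (k2 - lambda)
monoexp_ct_frame_avg <- function(A, lambda, K1, k2, schedule) {
  a <- schedule$start_s / 60
  b <- (schedule$start_s + schedule$duration_s) / 60
  int_e <- function(r, t0, t1) {
    if (r == 0) t1 - t0 else (exp(-r * t0) - exp(-r * t1)) / r
  }
  vapply(seq_along(a), function(i) {
    K1 * A * (int_e(lambda, a[i], b[i]) - int_e(k2, a[i], b[i])) /
      (k2 - lambda) / (b[i] - a[i])
  }, numeric(1))
}

# analytic frame averages of a mono-exponential input itself
monoexp_frame_avg <- function(A, lambda, schedule) {
  a <- schedule$start_s / 60
  b <- (schedule$start_s + schedule$duration_s) / 60
  A * (exp(-lambda * a) - exp(-lambda * b)) / (lambda * (b - a))
}
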