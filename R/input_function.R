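#' Tri-exponential bolus plasma input function
#'
#' Analytic model of the arterial/plasma tracer concentration after an
#' intravenous bolus: a sum of decaying exponentials with a short delay,
#' `C_p(t) = sum_i A_i exp(-lambda_i (t - t0))` for `t >= t0` and zero
#' before. The fast term is the distribution phase, the slow tail the body
#' clearance. All rates must be strictly positive and all amplitudes
#' non-negative, so the curve is non-negative everywhere.
#'
#' @param amplitude_kBq_mL numeric vector of term amplitudes `A_i`, kBq/mL.
#' @param rate_per_min numeric vector of rate constants `lambda_i`, 1/min.
#' @param delay_min bolus arrival delay `t0`, minutes.
#' @return An object of class `input_function`.
#' @export
input_function <- function(amplitude_kBq_mL, rate_per_min, delay_min = 0.1) {
  if (!is.numeric(amplitude_kBq_mL) || !is.numeric(rate_per_min) ||
      length(amplitude_kBq_mL) != length(rate_per_min) ||
      length(amplitude_kBq_mL) < 1L)
    stop("amplitudes and rates must be numeric vectors of equal length", call. = FALSE)
  if (any(!is.finite(amplitude_kBq_mL)) || any(amplitude_kBq_mL < 0))
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(rate_per_min)) || any(rate_per_min <= 0))
    stop("all rate constants must be > 0", call. = FALSE)
  .assert_scalar_num(delay_min, "delay_min", 0)
  structure(list(amplitude_kBq_mL = as.numeric(amplitude_kBq_mL),
                 rate_per_min = as.numeric(rate_per_min),
                 delay_min = as.numeric(delay_min)),
            class = "input_function")
}

#' Default reference input function
#'
#' The control-animal plasma curve used by the synthetic cohort: amplitudes
#' 3000, 400, 120 kBq/mL at rates 8, 0.6, 0.02 1/min with a 0.1 min delay.
#' Magnitudes correspond to a ~7.7 MBq bolus distributing into a mouse-scale
#' blood volume; the tail rate sets a realistic body-clearance time scale.
#'
#' @return An [input_function()].
#' @export
default_input_function <- function() {
  input_function(c(3000, 400, 120), c(8, 0.6, 0.02), delay_min = 0.1)
}

#' Evaluate an input function at time points
#'
#' @param object an [input_function()].
#' @param t_min numeric vector of times, minutes.
#' @param ... unused.
#' @return numeric vector of concentrations, kBq/mL (zero before the delay).
#' @export
predict.input_function <- function(object, t_min, ...) {
  s <- outer(t_min - object$delay_min, object$rate_per_min,
             function(s, l) exp(-l * pmax(s, 0)))
  out <- as.numeric(s %*% object$amplitude_kBq_mL)
  out[t_min < object$delay_min] <- 0
  out
}

#' @export
print.input_function <- function(x, ...) {
  cat("Tri-exponential bolus input function\n")
  cat(sprintf("  A (kBq/mL): %s\n", paste(signif(x$amplitude_kBq_mL, 4), collapse = ", ")))
  cat(sprintf("  lambda (1/min): %s; delay %.3g min\n",
              paste(signif(x$rate_per_min, 4), collapse = ", "), x$delay_min))
  cat(sprintf("  AUC(0-90 min) = %.4g kBq*min/mL\n", auc(x, 0, 90)))
  invisible(x)
}

#' Scale an input function
#'
#' Multiplies every amplitude by `factor`; the AUC scales exactly by the
#' same factor.
#'
#' @param object an [input_function()].
#' @param factor positive scalar.
#' @return A scaled [input_function()].
#' @export
scale_input_function <- function(object, factor) {
  .assert_scalar_num(factor, "factor", 0, strict = TRUE)
  input_function(object$amplitude_kBq_mL * factor, object$rate_per_min,
                 object$delay_min)
}

#' Input function for a group preset
#'
#' Returns the reference (control) tri-exponential curve scaled by the
#' preset's `plasma_scale`. A preset with lower clearance has a
#' proportionally larger plasma AUC; by construction the AUC over any
#' window equals `plasma_scale` times the control AUC.
#'
#' @param preset a [group_preset()].
#' @param reference the control curve, default [default_input_function()].
#' @return An [input_function()].
#' @export
make_input_function <- function(preset, reference = default_input_function()) {
  if (!inherits(preset, "group_preset"))
    stop("'preset' must be a group_preset", call. = FALSE)
  scale_input_function(reference, preset$plasma_scale)
}

# exact integral of C_p over [t0_min, t1_min]
.input_integral <- function(object, t0_min, t1_min) {
  d <- object$delay_min
  s0 <- pmax(t0_min - d, 0)
  s1 <- pmax(t1_min - d, 0)
  vapply(seq_along(s0), function(i) {
    sum(object$amplitude_kBq_mL *
          (.int_exp(object$rate_per_min, s1[i]) -
             .int_exp(object$rate_per_min, s0[i])))
  }, numeric(1))
}

#' Frame-average an input function on a schedule
#'
#' Exact analytic frame means of the continuous model: each frame value is
#' the integral of `C_p` over the frame window divided by the frame
#' duration — the quantity a noiseless PET frame of a homogeneous blood
#' region would measure.
#'
#' @param object an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param region_label label attached to the resulting TAC.
#' @return A [tac()].
#' @export
frame_average <- function(object, schedule, region_label = "input") {
  if (!inherits(object, "input_function"))
    stop("'object' must be an input_function", call. = FALSE)
  a <- schedule$start_s / 60
  b <- frame_ends(schedule) / 60
  tac(schedule, .input_integral(object, a, b) / (b - a),
      region_label = region_label)
}

#' Cumulative excretion (bladder) curve
#'
#' The bladder accumulates excreted tracer: its concentration is modelled as
#' proportional to the running integral of the plasma input,
#' `scale * int_0^t C_p`, frame-averaged on the schedule. Non-decreasing
#' over frames by construction.
#'
#' @param object an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param scale unitless proportionality (excretion flux over bladder volume).
#' @return A [tac()] labelled `"bladder"`.
#' @export
bladder_tac <- function(object, schedule, scale = 0.5) {
  .assert_scalar_num(scale, "scale", 0)
  a <- schedule$start_s / 60
  b <- frame_ends(schedule) / 60
  d <- object$delay_min
  # frame average of scale * int_0^t C_p dt == scale/(b-a) * int_a^b int_0^t C_p
  vals <- vapply(seq_along(a), function(i) {
    s0 <- max(a[i] - d, 0); s1 <- max(b[i] - d, 0)
    sum(object$amplitude_kBq_mL *
          (.conv_int(object$rate_per_min, 0, s1) -
             .conv_int(object$rate_per_min, 0, s0))) / (b[i] - a[i])
  }, numeric(1))
  tac(schedule, scale * vals, region_label = "bladder")
}
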