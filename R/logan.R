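#' Logan graphical analysis of the total distribution volume
#'
#' Ordinary least squares of the Logan transform over late frames: for
#' frames with midpoint at or after `t_star`,
#' `y_i = int_0^{t_i} C_T / C_T(t_i)` is regressed on
#' `x_i = int_0^{t_i} C_p / C_T(t_i)`. For a reversible tracer the
#' asymptotic slope is the total distribution volume `V_T` (equal to
#' `K1/k2` for the one-tissue model). Running integrals use the
#' frame-rectangle rule (value times duration, half the current frame up
#' to its midpoint), exact for frame-averaged data.
#'
#' @param tissue_tac tissue [tac()].
#' @param input_tac input [tac()] on the same schedule.
#' @param t_star start of the linear window, minutes (default 20).
#' @return An object of class `logan_fit` with `slope` (V_T, mL/mL),
#'   `intercept` (min), `t_star`, `r_squared` and `n_points`.
#' @examples
#' sched <- default_frame_schedule()
#' cp <- frame_average(default_input_function(), sched)
#' ct <- simulate_tissue_tac(default_input_function(), 0.8, 0.15, sched)
#' logan_vt(ct, cp)$slope  # ~ 0.8 / 0.15
#' @export
logan_vt <- function(tissue_tac, input_tac, t_star = 20) {
  if (!inherits(tissue_tac, "tac") || !inherits(input_tac, "tac"))
    stop("tissue and input must be tac objects", call. = FALSE)
  if (!schedules_equal(tissue_tac$schedule, input_tac$schedule))
    stop("tissue and input must share one schedule", call. = FALSE)
  .assert_scalar_num(t_star, "t_star", 0)
  sch <- tissue_tac$schedule
  mid <- frame_midpoints_min(sch)
  dur <- sch$duration_s / 60
  sel <- which(mid >= t_star)
  if (length(sel) < 3L)
    stop("fewer than 3 frames with midpoint >= t_star", call. = FALSE)
  ct <- tissue_tac$values
  if (any(ct[sel] <= 0))
    stop("non-positive tissue values in the Logan window", call. = FALSE)
  # running integral to each frame midpoint: full earlier frames plus half
  # of the current frame
  cum_to_mid <- function(v) cumsum(v * dur) - v * dur / 2
  x <- cum_to_mid(input_tac$values)[sel] / ct[sel]
  y <- cum_to_mid(ct)[sel] / ct[sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 t_star = t_star, r_squared = r2,
                 n_points = length(sel), x = x, y = y,
                 region_label = tissue_tac$region_label),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("Logan analysis (%s), t* = %g min, %d points\n",
              x$region_label, x$t_star, x$n_points))
  cat(sprintf("  V_T (slope) = %.4g mL/mL, intercept = %.4g min, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.logan_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
plot.logan_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16,
                 xlab = "int C_p / C_T (min)", ylab = "int C_T / C_T (min)",
                 main = sprintf("Logan plot, V_T = %.3g", x$slope), ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  invisible(x)
}
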