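#' Time-activity curve
#'
#' Frame-averaged radioactivity concentration for one region on a frame
#' schedule. Values are decay-corrected concentrations in kBq/mL
#' (`units_mode = "concentration"`) or dimensionless standard uptake values
#' (`units_mode = "SUV"`, which requires an attached subject record).
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one value per frame.
#' @param region_label character region name.
#' @param units_mode `"concentration"` or `"SUV"`.
#' @param subject optional [subject_record()]; required in SUV mode.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region_label = "region",
                units_mode = c("concentration", "SUV"), subject = NULL) {
  units_mode <- match.arg(units_mode)
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  if (!is.numeric(values) || length(values) != schedule$count)
    stop("'values' must be numeric with one value per frame", call. = FALSE)
  if (any(!is.finite(values)))
    stop("TAC values must be finite", call. = FALSE)
  if (units_mode == "SUV" && !inherits(subject, "subject_record"))
    stop("SUV mode requires an attached subject_record", call. = FALSE)
  structure(list(schedule = schedule, values = as.numeric(values),
                 region_label = as.character(region_label),
                 units_mode = units_mode, subject = subject),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, %.1f min, units: %s\n",
              x$region_label, x$schedule$count,
              frame_ends(x$schedule)[x$schedule$count] / 60,
              if (x$units_mode == "SUV") "SUV" else "kBq/mL"))
  cat(sprintf("  peak %.3g at %.2f min; last frame %.3g\n",
              max(x$values), frame_midpoints_min(x$schedule)[which.max(x$values)],
              x$values[length(x$values)]))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_s = x$schedule$start_s,
             frame_duration_s = x$schedule$duration_s,
             concentration_kBq_per_mL = x$values)
}

#' @export
plot.tac <- function(x, ..., log_time = FALSE) {
  t <- frame_midpoints_min(x$schedule)
  graphics::plot(t, x$values, type = "b", pch = 16, cex = 0.6,
                 log = if (log_time) "x" else "",
                 xlab = "Time (min)",
                 ylab = if (x$units_mode == "SUV") "SUV" else "Concentration (kBq/mL)",
                 main = x$region_label, ...)
  invisible(x)
}

#' Read / write a time-activity curve as delimited text
#'
#' CSV with columns `frame_start_s`, `frame_duration_s`,
#' `concentration_kBq_per_mL`.
#'
#' @param path file path.
#' @param x a [tac()].
#' @param region_label region name attached on read.
#' @return `read_tac` returns a [tac()]; `write_tac` returns `path`
#'   invisibly.
#' @export
read_tac <- function(path, region_label = "region") {
  d <- utils::read.csv(path)
  tac(frame_schedule(d$frame_start_s, d$frame_duration_s),
      d$concentration_kBq_per_mL, region_label = region_label)
}

#' @rdname read_tac
#' @export
write_tac <- function(x, path) {
  d <- as.data.frame(x)
  for (nm in names(d)) d[[nm]] <- sprintf("%.17g", d[[nm]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a concentration TAC to standard uptake values
#'
#' SUV = concentration (kBq/mL) x body weight (g) / injected dose (kBq).
#' Applying the conversion twice is an error: an SUV-mode curve cannot be
#' converted again.
#'
#' @param x a [tac()] in concentration units.
#' @param subject a [subject_record()] supplying body weight and dose.
#' @return A [tac()] in SUV mode.
#' @examples
#' s <- subject_record("m1", "WT", body_weight_g = 20, injected_dose_kBq = 7700)
#' tt <- tac(default_frame_schedule(), rep(5, 33))
#' to_suv(tt, s)$values[1]  # 5 * 20 / 7700
#' @export
to_suv <- function(x, subject) {
  if (!inherits(x, "tac")) stop("'x' must be a tac", call. = FALSE)
  if (x$units_mode == "SUV")
    stop("TAC is already in SUV mode; refusing double conversion", call. = FALSE)
  if (!inherits(subject, "subject_record"))
    stop("'subject' must be a subject_record", call. = FALSE)
  tac(x$schedule, x$values * subject$body_weight_g / subject$injected_dose_kBq,
      region_label = x$region_label, units_mode = "SUV", subject = subject)
}

#' Add duration-scaled Gaussian measurement noise to a TAC
#'
#' Each frame value receives independent Gaussian noise with standard
#' deviation `noise_scale * sqrt(max(value, floor) / duration_min)`: short
#' frames and hot frames are noisier, mimicking count statistics in
#' reconstructed PET frames. Negative results are clipped at zero.
#' Reproducible for a fixed seed.
#'
#' @param x a [tac()].
#' @param noise_scale unitless noise magnitude (0 = no noise).
#' @param seed integer seed.
#' @param floor noise floor, kBq/mL, so cold frames keep nonzero variance.
#' @return A [tac()] with noisy values.
#' @export
add_noise <- function(x, noise_scale, seed, floor = 0.01) {
  if (!inherits(x, "tac")) stop("'x' must be a tac", call. = FALSE)
  .assert_scalar_num(noise_scale, "noise_scale", 0)
  if (noise_scale == 0) return(x)
  dur_min <- x$schedule$duration_s / 60
  sigma <- noise_scale * sqrt(pmax(x$values, floor) / dur_min)
  noisy <- with_seed(seed, x$values + stats::rnorm(length(sigma), 0, sigma))
  tac(x$schedule, pmax(noisy, 0), region_label = x$region_label,
      units_mode = x$units_mode, subject = x$subject)
}
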