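#' Area under a concentration-time curve
#'
#' Generic AUC in kBq*min/mL over a time window `[t0, t1]` (minutes). For a
#' [tac()], integration uses the frame-rectangle rule — each frame value is
#' a time average, so `value * overlap` is the exact integral of the
#' underlying curve over the overlap of the frame window with `[t0, t1]`;
#' frames partially inside contribute proportionally. For an
#' [input_function()] the integral is the analytic closed form.
#'
#' @param x a [tac()] or an [input_function()].
#' @param t0,t1 window bounds, minutes; `t1 > t0` and within the schedule
#'   span for TACs.
#' @param ... unused.
#' @return AUC in kBq*min/mL.
#' @examples
#' auc(tac(default_frame_schedule(), rep(2, 33)), 0, 90)  # 360
#' @export
auc <- function(x, t0 = 0, t1 = 90, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.tac <- function(x, t0 = 0, t1 = 90, ...) {
  .assert_scalar_num(t0, "t0", 0)
  .assert_scalar_num(t1, "t1")
  if (t1 <= t0) stop("'t1' must be > 't0'", call. = FALSE)
  sch <- x$schedule
  a <- sch$start_s / 60
  b <- frame_ends(sch) / 60
  tol <- 1e-9 * max(1, b[length(b)])
  if (t0 < a[1L] - tol || t1 > b[length(b)] + tol)
    stop("[t0, t1] must lie within the schedule span", call. = FALSE)
  overlap <- pmax(pmin(b, t1) - pmax(a, t0), 0)
  sum(x$values * overlap)
}

#' @rdname auc
#' @export
auc.input_function <- function(x, t0 = 0, t1 = 90, ...) {
  .assert_scalar_num(t0, "t0", 0)
  .assert_scalar_num(t1, "t1")
  if (t1 <= t0) stop("'t1' must be > 't0'", call. = FALSE)
  .input_integral(x, t0, t1)
}

#' Total body clearance from the image-derived input function
#'
#' `TBC = ID / AUC(0-90 min)`, where ID is the injected dose per kilogram
#' body weight (kBq/kg) and the AUC is that of the image-derived input
#' function (kBq*min/mL), giving clearance in mL/min/kg.
#'
#' @param subject a [subject_record()].
#' @param idif image-derived input function [tac()] in concentration units.
#' @param t0,t1 AUC window, minutes (default 0-90).
#' @return An object of class `clearance` with `auc_0_90` (kBq*min/mL),
#'   `id_per_kg` (kBq/kg) and `tbc` (mL/min/kg).
#' @examples
#' s <- subject_record("m1", "WT", 20, 7700)
#' idif <- tac(default_frame_schedule(), rep(1000 / 90, 33))
#' tbc(s, idif)$tbc  # 385000 / 1000
#' @export
tbc <- function(subject, idif, t0 = 0, t1 = 90) {
  if (!inherits(subject, "subject_record"))
    stop("'subject' must be a subject_record", call. = FALSE)
  if (!inherits(idif, "tac")) stop("'idif' must be a tac", call. = FALSE)
  if (idif$units_mode != "concentration")
    stop("'idif' must be in concentration units", call. = FALSE)
  a <- auc(idif, t0, t1)
  if (a <= 0) stop("input-function AUC is zero", call. = FALSE)
  id_per_kg <- subject$injected_dose_kBq / (subject$body_weight_g / 1000)
  structure(list(auc_0_90 = a, id_per_kg = id_per_kg, tbc = id_per_kg / a),
            class = "clearance")
}

#' @export
print.clearance <- function(x, ...) {
  cat(sprintf("TBC = %.4g mL/min/kg (ID %.4g kBq/kg / AUC %.4g kBq*min/mL)\n",
              x$tbc, x$id_per_kg, x$auc_0_90))
  invisible(x)
}

#' Fold-change between two groups
#'
#' Ratio of arithmetic group means, `mean(a) / mean(b)`, the convention
#' used for reporting group effects. A `direction` attribute records
#' whether group a is above (`"up"`) or below (`"down"`) group b. A
#' geometric-mean variant is available behind a flag.
#'
#' @param a,b numeric vectors of per-subject values; both means must be
#'   positive.
#' @param geometric use geometric means instead (default `FALSE`).
#' @return The ratio, with attribute `direction`.
#' @examples
#' fold_change(c(2, 2), c(1, 1))  # 2
#' @export
fold_change <- function(a, b, geometric = FALSE) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  ma <- if (geometric) exp(mean(log(a))) else mean(a)
  mb <- if (geometric) exp(mean(log(b))) else mean(b)
  if (!is.finite(mb) || mb == 0) stop("zero mean denominator", call. = FALSE)
  if (!is.finite(ma) || ma <= 0 || mb < 0)
    stop("group means must be positive", call. = FALSE)
  structure(ma / mb, direction = if (ma >= mb) "up" else "down")
}
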