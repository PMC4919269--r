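# One-tissue compartment model: forward prediction from a sampled input
# TAC and Levenberg-Marquardt estimation of (K1, k2).

# reconstruct the continuous input on a fine uniform grid (minutes)
# "integral": monotone-cubic interpolation of the exact cumulative frame
#   integrals, differentiated -- preserves every frame integral, so the
#   reconstruction carries no systematic AUC bias on coarse late frames.
# "linear": piecewise-linear interpolation through frame midpoints.
.reconstruct_input <- function(input_tac, tgrid,
                               method = c("integral", "linear")) {
  method <- match.arg(method)
  sch <- input_tac$schedule
  if (method == "integral") {
    bounds <- c(sch$start_s, frame_ends(sch)[sch$count]) / 60
    cum <- c(0, cumsum(input_tac$values * sch$duration_s / 60))
    if (bounds[1L] > 0) { bounds <- c(0, bounds); cum <- c(0, cum) }
    f <- stats::splinefun(bounds, cum, method = "monoH.FC")
    cp <- f(pmin(tgrid, bounds[length(bounds)]), deriv = 1)
    cp[tgrid > bounds[length(bounds)]] <-
      input_tac$values[sch$count]  # hold last frame level beyond the scan
    pmax(cp, 0)
  } else {
    m <- frame_midpoints_min(sch)
    v <- input_tac$values
    if (m[1L] > 0) { m <- c(0, m); v <- c(0, v) }
    stats::approx(m, v, xout = tgrid, rule = 2)$y
  }
}

# exact convolution of a piecewise-linear grid curve with K1*exp(-k2 t):
# first-order recursion evaluated by stats::filter (O(n), no overflow)
.conv_grid <- function(cp, dt, K1, k2) {
  n <- length(cp)
  if (n < 2L) return(numeric(n))
  E <- exp(-k2 * dt)
  w0 <- .int_exp(k2, dt)          # int_0^dt exp(-k2 s) ds
  w1 <- .conv_int(k2, k2, dt)     # int_0^dt s exp(-k2 s) ds
  b <- K1 * (cp[-n] * (w1 / dt) + cp[-1L] * (w0 - w1 / dt))
  c(0, as.numeric(stats::filter(b, E, method = "recursive")))
}

# weights such that (W %*% y) gives frame means of the piecewise-linear
# curve y on the uniform grid tgrid
.frame_weights <- function(tgrid, schedule) {
  n <- length(tgrid)
  dt <- tgrid[2L] - tgrid[1L]
  W <- matrix(0, schedule$count, n)
  a_all <- schedule$start_s / 60
  b_all <- frame_ends(schedule) / 60
  tmax <- tgrid[n]
  for (i in seq_len(schedule$count)) {
    a <- max(a_all[i], tgrid[1L]); b <- min(b_all[i], tmax)
    if (b <= a) next
    k0 <- min(max(floor((a - tgrid[1L]) / dt) + 1, 1L), n - 1L)
    k1 <- min(max(ceiling((b - tgrid[1L]) / dt), 1L), n - 1L)
    w <- numeric(n)
    for (k in c(k0, k1)) {  # (possibly partial) boundary segments
      u <- max(a, tgrid[k]); v <- min(b, tgrid[k + 1L])
      if (v <= u) next
      w[k] <- w[k] + (v - u) * (tgrid[k + 1L] - (u + v) / 2) / dt
      w[k + 1L] <- w[k + 1L] + (v - u) * ((u + v) / 2 - tgrid[k]) / dt
    }
    if (k1 > k0 + 1L) {  # full interior segments
      ks <- (k0 + 1L):(k1 - 1L)
      w[ks] <- w[ks] + dt / 2
      w[ks + 1L] <- w[ks + 1L] + dt / 2
    }
    if (k1 == k0) {  # single segment counted twice above
      u <- max(a, tgrid[k0]); v <- min(b, tgrid[k0 + 1L])
      w[k0] <- (v - u) * (tgrid[k0 + 1L] - (u + v) / 2) / dt
      w[k0 + 1L] <- (v - u) * ((u + v) / 2 - tgrid[k0]) / dt
    }
    W[i, ] <- w / (b_all[i] - a_all[i])
  }
  W
}

.fine_grid <- function(t_end_min, fine_dt) {
  n <- ceiling(t_end_min / fine_dt) + 1L
  seq(0, by = fine_dt, length.out = n)
}

#' One-tissue compartment forward prediction from a sampled input
#'
#' Predicts the tissue curve `C_T(t) = K1 (C_p * exp(-k2 t))(t)` by exact
#' convolution of the reconstructed continuous input on a fine uniform grid
#' (first-order exponential recursion, exact for a piecewise-linear input),
#' then frame-averages the prediction on the output schedule. The input
#' may be sampled on a different (e.g. finer) schedule than the output.
#'
#' @param input_tac input function as a [tac()].
#' @param K1 influx rate constant, 1/min (>= 0).
#' @param k2 backflux rate constant, 1/min (>= 0).
#' @param schedule output [frame_schedule()]; default the input's.
#' @param fine_dt convolution grid step, minutes (default 0.0025 = 0.15 s).
#' @param input_interp input reconstruction: `"integral"` (integral
#'   preserving monotone-cubic, default) or `"linear"` (piecewise linear
#'   through frame midpoints).
#' @param region_label label for the predicted TAC.
#' @return A [tac()] of predicted frame means.
#' @export
forward_1tcm <- function(input_tac, K1, k2, schedule = input_tac$schedule,
                         fine_dt = 0.0025,
                         input_interp = c("integral", "linear"),
                         region_label = "model") {
  if (!inherits(input_tac, "tac"))
    stop("'input_tac' must be a tac", call. = FALSE)
  .assert_scalar_num(K1, "K1", 0)
  .assert_scalar_num(k2, "k2", 0)
  input_interp <- match.arg(input_interp)
  tgrid <- .fine_grid(frame_ends(schedule)[schedule$count] / 60, fine_dt)
  cp <- .reconstruct_input(input_tac, tgrid, input_interp)
  W <- .frame_weights(tgrid, schedule)
  y <- .conv_grid(cp, fine_dt, K1, k2)
  tac(schedule, pmax(as.numeric(W %*% y), 0), region_label = region_label)
}

#' Physiological plausibility gate for a one-tissue fit
#'
#' Policy used to flag non-physiological parameter estimates: a fit fails
#' if it did not converge, if `K1` is at/below 1e-4 or at/above 10 1/min,
#' if `k2` is non-positive or at/above 5 1/min, or if the relative
#' standard error of `K1` exceeds 2 (unidentifiable). The thresholds are a
#' package policy (labelled in output), not measured physiology.
#'
#' @param fit an [fit_1tcm()] result, or a list with elements `K1`, `k2`
#'   and optionally `se_K1`, `converged`.
#' @return A list with `ok` (logical) and `reason` (character or `NA`).
#' @examples
#' is_physiological(list(K1 = 0.8, k2 = 7))$reason
#' @export
is_physiological <- function(fit) UseMethod("is_physiological")

#' @export
is_physiological.onetcm <- function(fit) {
  is_physiological.default(list(K1 = fit$coefficients[["K1"]],
                                k2 = fit$coefficients[["k2"]],
                                se_K1 = fit$se[["K1"]],
                                converged = fit$converged))
}

#' @export
is_physiological.default <- function(fit) {
  K1 <- fit$K1; k2 <- fit$k2
  se_K1 <- fit$se_K1 %||% NA_real_
  converged <- fit$converged %||% TRUE
  if (!isTRUE(converged))
    return(list(ok = FALSE, reason = "no convergence"))
  if (!is.finite(K1) || K1 <= 1e-4 || K1 >= 10)
    return(list(ok = FALSE, reason = "K1 out of range"))
  if (!is.finite(k2) || k2 <= 0 || k2 >= 5)
    return(list(ok = FALSE, reason = "k2 out of range"))
  if (is.finite(se_K1) && K1 > 0 && se_K1 / K1 > 2)
    return(list(ok = FALSE, reason = "unidentifiable"))
  list(ok = TRUE, reason = NA_character_)
}

#' Fit the one-tissue compartment model to a tissue TAC
#'
#' Estimates the influx rate constant `K1` and backflux rate constant `k2`
#' by minimising the (by default unweighted) residual sum of squares over
#' all frames with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). Asymptotic standard errors come from the
#' Jacobian at the optimum. The physiological gate
#' ([is_physiological()]) is applied and sets the `excluded` flag; a fit
#' that fails to converge is returned flagged, never raised as an error.
#'
#' @param tissue_tac tissue [tac()] (defines the fitting schedule).
#' @param input_tac input-function [tac()]; may be on a finer schedule.
#' @param init initial `c(K1, k2)`, default `c(0.1, 0.1)`.
#' @param lower,upper parameter bounds, default `K1` in `[1e-4, 10]`, `k2`
#'   in `[0, 5]` 1/min.
#' @param weight_frames if `TRUE`, residuals are weighted by the square
#'   root of the frame duration; default `FALSE` (unweighted RSS).
#' @param fine_dt,input_interp forwarded to [forward_1tcm()].
#' @param max_iter maximum LM iterations (default 500).
#' @param ftol relative RSS convergence tolerance (default 1e-10).
#' @return An object of class `onetcm` with components `coefficients`
#'   (named `K1`, `k2`), `se`, `rss`, `df.residual`, `converged`,
#'   `excluded`, `exclusion_reason`, `fitted.values` and the data. Methods:
#'   [coef()], [vcov()], [print()], [summary()], [predict()], [fitted()],
#'   [residuals()], [plot()], [simulate()].
#' @examples
#' sched <- default_frame_schedule()
#' cp <- frame_average(default_input_function(), sched)
#' ct <- forward_1tcm(cp, 0.8, 0.15)
#' fit <- fit_1tcm(ct, cp)
#' coef(fit)
#' @export
fit_1tcm <- function(tissue_tac, input_tac, init = c(K1 = 0.1, k2 = 0.1),
                     lower = c(K1 = 1e-4, k2 = 0),
                     upper = c(K1 = 10, k2 = 5),
                     weight_frames = FALSE, fine_dt = 0.0025,
                     input_interp = c("integral", "linear"),
                     max_iter = 500, ftol = 1e-10) {
  if (!inherits(tissue_tac, "tac") || !inherits(input_tac, "tac"))
    stop("tissue and input must be tac objects", call. = FALSE)
  input_interp <- match.arg(input_interp)
  sched <- tissue_tac$schedule
  obs <- tissue_tac$values
  wts <- if (weight_frames) sqrt(sched$duration_s / 60) else rep(1, sched$count)

  tgrid <- .fine_grid(frame_ends(sched)[sched$count] / 60, fine_dt)
  cp <- .reconstruct_input(input_tac, tgrid, input_interp)
  W <- .frame_weights(tgrid, sched)
  predict_par <- function(par) {
    pmax(as.numeric(W %*% .conv_grid(cp, fine_dt, par[1L], par[2L])), 0)
  }
  resid_fn <- function(par) wts * (predict_par(par) - obs)

  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = unname(init), lower = unname(lower),
                       upper = unname(upper), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = ftol, ptol = 1e-12)),
    error = function(e) e)

  if (inherits(lm_fit, "error")) {
    par <- unname(init); se <- c(K1 = NA_real_, k2 = NA_real_)
    rss <- sum(resid_fn(par)^2); converged <- FALSE
    fitted_vals <- predict_par(par); niter <- 0L
    vc <- matrix(NA_real_, 2, 2, dimnames = list(c("K1", "k2"), c("K1", "k2")))
  } else {
    par <- lm_fit$par
    rss <- stats::deviance(lm_fit)
    converged <- lm_fit$info %in% 1:4
    niter <- lm_fit$niter
    fitted_vals <- predict_par(par)
    dof <- max(length(obs) - 2L, 1L)
    vc <- tryCatch({
      h <- solve(lm_fit$hessian) * rss / dof
      dimnames(h) <- list(c("K1", "k2"), c("K1", "k2"))
      h
    }, error = function(e)
      matrix(NA_real_, 2, 2, dimnames = list(c("K1", "k2"), c("K1", "k2"))))
    se <- sqrt(pmax(diag(vc), 0))
  }
  names(par) <- c("K1", "k2")
  names(se) <- c("K1", "k2")

  out <- structure(list(coefficients = par, se = se, rss = rss,
                        df.residual = length(obs) - 2L,
                        converged = converged, excluded = FALSE,
                        exclusion_reason = NA_character_,
                        fitted.values = fitted_vals,
                        tissue = tissue_tac, input = input_tac,
                        niter = niter, vcov = vc,
                        control = list(fine_dt = fine_dt,
                                       input_interp = input_interp,
                                       weight_frames = weight_frames),
                        call = match.call()),
                   class = "onetcm")
  gate <- is_physiological(out)
  out$excluded <- !gate$ok
  out$exclusion_reason <- gate$reason
  out
}

#' @export
coef.onetcm <- function(object, ...) object$coefficients

#' @export
vcov.onetcm <- function(object, ...) object$vcov

#' @export
fitted.onetcm <- function(object, ...) object$fitted.values

#' @export
residuals.onetcm <- function(object, ...) object$tissue$values - object$fitted.values

#' @export
print.onetcm <- function(x, ...) {
  cat("One-tissue compartment fit\n")
  cat(sprintf("  K1 = %.4g (se %.3g) 1/min, k2 = %.4g (se %.3g) 1/min\n",
              x$coefficients[["K1"]], x$se[["K1"]],
              x$coefficients[["k2"]], x$se[["k2"]]))
  cat(sprintf("  RSS = %.6g on %d frames; %s%s\n", x$rss,
              x$tissue$schedule$count,
              if (x$converged) "converged" else "NOT converged",
              if (x$excluded) sprintf("; EXCLUDED (%s)", x$exclusion_reason) else ""))
  invisible(x)
}

#' @export
summary.onetcm <- function(object, ...) {
  k1 <- object$coefficients[["K1"]]; k2 <- object$coefficients[["k2"]]
  tab <- cbind(Estimate = c(k1, k2),
               `Std. Error` = c(object$se[["K1"]], object$se[["k2"]]))
  rownames(tab) <- c("K1", "k2")
  structure(list(coefficients = tab, rss = object$rss,
                 sigma = sqrt(object$rss / max(object$df.residual, 1L)),
                 vt = if (k2 > 0) k1 / k2 else Inf,
                 converged = object$converged, excluded = object$excluded,
                 exclusion_reason = object$exclusion_reason,
                 n = object$tissue$schedule$count),
            class = "summary.onetcm")
}

#' @export
print.summary.onetcm <- function(x, ...) {
  cat("One-tissue compartment model (K1, k2), Levenberg-Marquardt fit\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nRSS %.6g over %d frames, residual sigma %.4g kBq/mL\n",
              x$rss, x$n, x$sigma))
  cat(sprintf("Distribution volume K1/k2 = %.4g mL/mL\n", x$vt))
  if (x$excluded)
    cat(sprintf("Flagged non-physiological: %s\n", x$exclusion_reason))
  invisible(x)
}

#' @export
predict.onetcm <- function(object, schedule = object$tissue$schedule, ...) {
  forward_1tcm(object$input, object$coefficients[["K1"]],
               object$coefficients[["k2"]], schedule = schedule,
               fine_dt = object$control$fine_dt,
               input_interp = object$control$input_interp,
               region_label = paste0(object$tissue$region_label, "_fit"))
}

#' @export
plot.onetcm <- function(x, ...) {
  t <- frame_midpoints_min(x$tissue$schedule)
  graphics::plot(t, x$tissue$values, pch = 16, cex = 0.7,
                 xlab = "Time (min)", ylab = "Concentration (kBq/mL)",
                 main = sprintf("1TCM fit: K1=%.3g, k2=%.3g 1/min",
                                x$coefficients[["K1"]], x$coefficients[["k2"]]),
                 ...)
  graphics::lines(t, x$fitted.values, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("data", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate noisy tissue curves from a fitted model
#'
#' Draws `nsim` noisy replicates of the fitted tissue curve using the
#' duration-scaled noise model of [add_noise()].
#'
#' @param object an [fit_1tcm()] result.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param noise_scale noise magnitude (see [add_noise()]).
#' @param ... unused.
#' @return A list of [tac()] objects.
#' @export
simulate.onetcm <- function(object, nsim = 1, seed = 1L, noise_scale = 2, ...) {
  clean <- tac(object$tissue$schedule, object$fitted.values,
               region_label = object$tissue$region_label)
  lapply(seq_len(nsim), function(i)
    add_noise(clean, noise_scale, seed = substream_seed(seed, paste0("sim", i))))
}
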