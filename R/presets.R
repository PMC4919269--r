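#' Group preset with known ground-truth kinetics
#'
#' A preset bundles the ground truth behind one experimental group: the
#' renal-cortex one-tissue rate constants (`true_K1`, `true_k2`), the
#' multiplier on the control plasma curve (`plasma_scale`; a group whose
#' total body clearance is c-fold lower has a c-fold larger plasma AUC),
#' the default group size, the TAC noise magnitude and the heart
#' partial-volume dilution applied to the image-derived input function.
#'
#' @param name preset name.
#' @param n_default default number of animals.
#' @param true_K1 influx rate constant, 1/min.
#' @param true_k2 backflux rate constant, 1/min.
#' @param plasma_scale unitless multiplier on the control input function.
#' @param noise_scale unitless TAC noise magnitude (see [add_noise()]).
#' @param idif_dilution factor in (0, 1] modelling partial-volume dilution
#'   of the heart region.
#' @return An object of class `group_preset`.
#' @export
group_preset <- function(name, n_default, true_K1, true_k2, plasma_scale,
                         noise_scale = 2, idif_dilution = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .assert_scalar_num(n_default, "n_default", 0)
  .assert_scalar_num(true_K1, "true_K1", 0, strict = TRUE)
  .assert_scalar_num(true_k2, "true_k2", 0, strict = TRUE)
  .assert_scalar_num(plasma_scale, "plasma_scale", 0, strict = TRUE)
  .assert_scalar_num(noise_scale, "noise_scale", 0)
  .assert_scalar_num(idif_dilution, "idif_dilution", 0, strict = TRUE)
  if (idif_dilution > 1)
    stop("'idif_dilution' must be in (0, 1]", call. = FALSE)
  structure(list(name = name, n_default = as.integer(n_default),
                 true_K1 = true_K1, true_k2 = true_k2,
                 plasma_scale = plasma_scale, noise_scale = noise_scale,
                 idif_dilution = idif_dilution),
            class = "group_preset")
}

#' Default study presets
#'
#' The five groups of the CKD mouse study plus the pooled control, with
#' ground truth chosen so that the group fold-changes in K1 and total body
#' clearance equal the reported values by construction:
#'
#' * `control` / `WT`: K1 = 0.80, k2 = 0.15 1/min, plasma_scale 1, n = 5.
#' * `Tg` (TGF-beta1 transgenic CKD): K1 = 0.80/2.2, same k2 (backflux did
#'   not differ between groups), plasma_scale 1.8, n = 8.
#' * `oct12_ko` (OCT1/2 knock-out): K1 = 0.80/3.0, plasma_scale 3.0, n = 4.
#' * `cimetidine` (OCT1/2 inhibitor): K1 = 0.80/2.5, plasma_scale 2.5, n = 5.
#' * `pyrimethamine` (MATE1 inhibitor): control kinetics, plasma_scale
#'   1/1.1 (clearance slightly increased), n = 4.
#'
#' @return Named list of [group_preset()] objects.
#' @export
default_presets <- function() {
  list(
    control       = group_preset("control", 5, 0.80, 0.15, 1.0),
    WT            = group_preset("WT", 5, 0.80, 0.15, 1.0),
    Tg            = group_preset("Tg", 8, 0.80 / 2.2, 0.15, 1.8),
    oct12_ko      = group_preset("oct12_ko", 4, 0.80 / 3.0, 0.15, 3.0),
    cimetidine    = group_preset("cimetidine", 5, 0.80 / 2.5, 0.15, 2.5),
    pyrimethamine = group_preset("pyrimethamine", 4, 0.80, 0.15, 1 / 1.1)
  )
}

#' Subject record
#'
#' Dosimetry metadata for one animal: body weight, injected dose, group
#' label and the heart partial-volume dilution factor.
#'
#' @param subject_id character id.
#' @param group group/preset name.
#' @param body_weight_g body weight, grams (> 0).
#' @param injected_dose_kBq injected dose, kBq (> 0).
#' @param idif_dilution factor in (0, 1].
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, body_weight_g,
                           injected_dose_kBq, idif_dilution = 1) {
  stopifnot(length(subject_id) == 1L, length(group) == 1L)
  .assert_scalar_num(body_weight_g, "body_weight_g", 0, strict = TRUE)
  .assert_scalar_num(injected_dose_kBq, "injected_dose_kBq", 0, strict = TRUE)
  .assert_scalar_num(idif_dilution, "idif_dilution", 0, strict = TRUE)
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 body_weight_g = body_weight_g,
                 injected_dose_kBq = injected_dose_kBq,
                 idif_dilution = idif_dilution),
            class = "subject_record")
}

#' @export
print.group_preset <- function(x, ...) {
  cat(sprintf("Preset '%s': n=%d, K1=%.4g, k2=%.4g 1/min, plasma_scale=%.4g, noise=%.3g\n",
              x$name, x$n_default, x$true_K1, x$true_k2, x$plasma_scale,
              x$noise_scale))
  invisible(x)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %.3g g, %.4g kBq injected\n",
              x$subject_id, x$group, x$body_weight_g, x$injected_dose_kBq))
  invisible(x)
}
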