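#' Noiseless one-tissue-compartment tissue curve from an analytic input
#'
#' Forward model of tissue concentration
#' `C_T(t) = K1 * int_0^t C_p(tau) exp(-k2 (t - tau)) dtau`,
#' evaluated exactly (term-by-term closed form for the tri-exponential
#' input) and frame-averaged on the schedule. This is the generator-side
#' forward model; [forward_1tcm()] is the estimation-side counterpart that
#' works from a sampled input TAC.
#'
#' @param input_fn an [input_function()].
#' @param K1 influx rate constant, 1/min (>= 0).
#' @param k2 backflux rate constant, 1/min (>= 0).
#' @param schedule a [frame_schedule()].
#' @param region_label label for the resulting TAC.
#' @return A [tac()] of noiseless frame means, non-negative.
#' @examples
#' ct <- simulate_tissue_tac(default_input_function(), 0.8, 0.15,
#'                           default_frame_schedule())
#' @export
simulate_tissue_tac <- function(input_fn, K1, k2, schedule,
                                region_label = "tissue") {
  if (!inherits(input_fn, "input_function"))
    stop("'input_fn' must be an input_function", call. = FALSE)
  .assert_scalar_num(K1, "K1", 0)
  .assert_scalar_num(k2, "k2", 0)
  a <- schedule$start_s / 60
  b <- frame_ends(schedule) / 60
  d <- input_fn$delay_min
  vals <- vapply(seq_along(a), function(i) {
    s0 <- max(a[i] - d, 0); s1 <- max(b[i] - d, 0)
    K1 * sum(input_fn$amplitude_kBq_mL *
               (.conv_int(input_fn$rate_per_min, k2, s1) -
                  .conv_int(input_fn$rate_per_min, k2, s0))) / (b[i] - a[i])
  }, numeric(1))
  tac(schedule, pmax(vals, 0), region_label = region_label)
}

#' Simulate a cohort of subjects with known ground truth
#'
#' For each subject: body weight is drawn from Normal(25 g, 2 g) truncated
#' at 15 g, injected dose from Normal(7700 kBq, 1000 kBq) truncated at
#' 1000 kBq; the subject's plasma input is the preset-scaled reference
#' curve further scaled by `(dose / 7700) * (25 / body_weight)` so the
#' plasma concentration tracks the dose per unit distribution volume; the
#' image-derived input function is the frame-averaged input times the
#' preset's `idif_dilution` plus noise; left and right renal-cortex TACs
#' come from [simulate_tissue_tac()] at the preset's true (K1, k2) plus
#' independent noise. Ground truth (including the subject's exact input
#' model) is retained for recovery studies.
#'
#' A single global seed fans out to per-subject substreams by stable
#' hashing of the subject id ([substream_seed()]), so results for one
#' subject never depend on the others.
#'
#' @param preset a [group_preset()].
#' @param n number of subjects (>= 0); default the preset's `n_default`.
#' @param seed integer global seed.
#' @param schedule a [frame_schedule()].
#' @param reference control input function, default
#'   [default_input_function()].
#' @param noise logical; `FALSE` forces noiseless TACs regardless of the
#'   preset's `noise_scale`.
#' @return An object of class `pet_cohort`: a list of subjects, each a list
#'   with elements `subject` ([subject_record()]), `idif`, `cortex_left`,
#'   `cortex_right` ([tac()]s) and `truth` (list with `K1`, `k2`,
#'   `plasma_scale`, `noise_scale`, `idif_dilution`, `input_fn`).
#' @export
simulate_cohort <- function(preset, n = preset$n_default, seed = 1L,
                            schedule = default_frame_schedule(),
                            reference = default_input_function(),
                            noise = TRUE) {
  if (!inherits(preset, "group_preset"))
    stop("'preset' must be a group_preset", call. = FALSE)
  .assert_scalar_num(n, "n", 0)
  if (n != round(n)) stop("'n' must be an integer", call. = FALSE)
  ns <- if (noise) preset$noise_scale else 0
  subjects <- lapply(seq_len(n), function(i) {
    sid <- sprintf("%s_%02d", preset$name, i)
    sseed <- substream_seed(seed, sid)
    draws <- with_seed(sseed, {
      bw <- stats::rnorm(1, 25, 2)
      while (bw < 15) bw <- stats::rnorm(1, 25, 2)
      dose <- stats::rnorm(1, 7700, 1000)
      while (dose < 1000) dose <- stats::rnorm(1, 7700, 1000)
      list(bw = bw, dose = dose)
    })
    subj <- subject_record(sid, preset$name, draws$bw, draws$dose,
                           idif_dilution = preset$idif_dilution)
    input_fn <- scale_input_function(make_input_function(preset, reference),
                                     (draws$dose / 7700) * (25 / draws$bw))
    idif_clean <- frame_average(input_fn, schedule, region_label = "idif")
    idif_clean$values <- idif_clean$values * preset$idif_dilution
    cortex_clean <- simulate_tissue_tac(input_fn, preset$true_K1,
                                        preset$true_k2, schedule)
    idif <- add_noise(idif_clean, ns, seed = substream_seed(sseed, "idif"))
    cl <- add_noise(cortex_clean, ns, seed = substream_seed(sseed, "cortex_L"))
    cr <- add_noise(cortex_clean, ns, seed = substream_seed(sseed, "cortex_R"))
    cl$region_label <- "kidney_cortex_l"
    cr$region_label <- "kidney_cortex_r"
    list(subject = subj, idif = idif, cortex_left = cl, cortex_right = cr,
         truth = list(K1 = preset$true_K1, k2 = preset$true_k2,
                      plasma_scale = preset$plasma_scale,
                      noise_scale = ns,
                      idif_dilution = preset$idif_dilution,
                      input_fn = input_fn))
  })
  structure(list(preset = preset, seed = as.integer(seed),
                 schedule = schedule, subjects = subjects),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PET cohort '%s': %d subjects, seed %d\n",
              x$preset$name, length(x$subjects), x$seed))
  invisible(x)
}

#' @export
length.pet_cohort <- function(x) length(x$subjects)

#' Export a cohort as delimited text
#'
#' Writes one TAC file per subject and region
#' (`<subject>_<region>.csv` with columns `frame_start_s`,
#' `frame_duration_s`, `concentration_kBq_per_mL`), a cohort manifest
#' (`manifest.csv`: subject_id, group, body_weight_g, injected_dose_kBq,
#' seed) and a ground-truth table (`ground_truth.csv`: K1, k2,
#' plasma_scale).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "pet_cohort")) stop("not a pet_cohort", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject$subject_id, group = s$subject$group,
               body_weight_g = sprintf("%.17g", s$subject$body_weight_g),
               injected_dose_kBq = sprintf("%.17g", s$subject$injected_dose_kBq),
               seed = cohort$seed)))
  gt <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject$subject_id,
               K1 = sprintf("%.17g", s$truth$K1),
               k2 = sprintf("%.17g", s$truth$k2),
               plasma_scale = sprintf("%.17g", s$truth$plasma_scale))))
  if (is.null(man)) {
    man <- data.frame(subject_id = character(), group = character(),
                      body_weight_g = character(),
                      injected_dose_kBq = character(), seed = integer())
    gt <- data.frame(subject_id = character(), K1 = character(),
                     k2 = character(), plasma_scale = character())
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in cohort$subjects) {
    for (reg in c("idif", "cortex_left", "cortex_right")) {
      write_tac(s[[reg]], file.path(dir, sprintf("%s_%s.csv",
                                                 s$subject$subject_id, reg)))
    }
  }
  invisible(dir)
}
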