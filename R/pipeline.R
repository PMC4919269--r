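# End-to-end study orchestration: simulate -> (optional phantom) ->
# fit -> clearance -> statistics, with deterministic report output.

#' Study configuration
#'
#' Validated configuration for [run_study()]. All randomness flows from the
#' single `seed`; per-subject substreams are derived by stable hashing of
#' subject ids, so adding a subject never perturbs the others.
#'
#' @param groups named integer vector of group sizes, names referring to
#'   `presets`; default the preset defaults for WT and Tg.
#' @param control name of the control group for the comparisons.
#' @param seed integer seed (must be set; no implicit randomness).
#' @param noise logical; simulate with each preset's noise_scale.
#' @param t_star Logan start time, minutes.
#' @param phantom if `TRUE`, TACs are extracted from rendered phantoms via
#'   [build_idif()] and [organ_mask()] instead of taken directly from the
#'   cohort generator.
#' @param phantom_geometry geometry used when `phantom = TRUE`.
#' @param idif_circle_px,idif_slices IDIF extraction parameters in phantom
#'   mode.
#' @param presets named list of [group_preset()]s.
#' @param schedule a [frame_schedule()].
#' @param reference control [input_function()].
#' @param zero_cortex character vector of subject ids whose cortex TACs are
#'   zeroed (exercises the exclusion path).
#' @param fine_dt convolution grid step for the fits, minutes.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = c(WT = 5L, Tg = 8L), control = "WT",
                         seed = 1L, noise = TRUE, t_star = 20,
                         phantom = FALSE,
                         phantom_geometry = default_phantom_geometry(),
                         idif_circle_px = 15, idif_slices = 6,
                         presets = default_presets(),
                         schedule = default_frame_schedule(),
                         reference = default_input_function(),
                         zero_cortex = character(0), fine_dt = 0.0025) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector of group sizes", call. = FALSE)
  missing_presets <- setdiff(c(names(groups), control), names(presets))
  if (length(missing_presets) > 0L)
    stop(sprintf("presets missing for: %s",
                 paste(missing_presets, collapse = ", ")), call. = FALSE)
  if (!control %in% names(groups))
    stop("'control' must be one of the groups", call. = FALSE)
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be set to a finite integer", call. = FALSE)
  structure(list(groups = groups, control = control,
                 seed = as.integer(seed), noise = isTRUE(noise),
                 t_star = t_star, phantom = isTRUE(phantom),
                 phantom_geometry = phantom_geometry,
                 idif_circle_px = idif_circle_px, idif_slices = idif_slices,
                 presets = presets, schedule = schedule,
                 reference = reference, zero_cortex = zero_cortex,
                 fine_dt = fine_dt),
            class = "study_config")
}

# serialisable echo of a config (numbers only, for provenance)
.config_echo <- function(config) {
  list(groups = as.list(config$groups), control = config$control,
       seed = config$seed, noise = config$noise, t_star = config$t_star,
       phantom = config$phantom,
       presets = lapply(config$presets, function(p) unclass(p)),
       schedule = list(frame_start_s = config$schedule$start_s,
                       frame_duration_s = config$schedule$duration_s),
       reference_input = unclass(config$reference),
       zero_cortex = config$zero_cortex, fine_dt = config$fine_dt,
       package_version = as.character(utils::packageVersion("metkin")))
}

# fit one subject: both kidneys, Logan, clearance
.analyse_subject <- function(s, config, log) {
  sid <- s$subject$subject_id
  fits <- lapply(list(L = s$cortex_left, R = s$cortex_right), function(ct)
    fit_1tcm(ct, s$idif, fine_dt = config$fine_dt))
  ok <- !vapply(fits, `[[`, logical(1), "excluded")
  excluded <- !any(ok)
  reason <- if (excluded) fits[[1L]]$exclusion_reason else NA_character_
  k1 <- if (any(ok)) mean(vapply(fits[ok], function(f) coef(f)[["K1"]], 0)) else NA_real_
  k2 <- if (any(ok)) mean(vapply(fits[ok], function(f) coef(f)[["k2"]], 0)) else NA_real_
  vt <- tryCatch({
    lg <- lapply(list(s$cortex_left, s$cortex_right), logan_vt,
                 input_tac = s$idif, t_star = config$t_star)
    mean(vapply(lg, `[[`, numeric(1), "slope"))
  }, error = function(e) NA_real_)
  cl <- tryCatch(tbc(s$subject, s$idif), error = function(e) NULL)
  log(sprintf("fit\t%s\t%s\tK1=%.6g k2=%.6g", sid,
              if (excluded) "excluded" else "ok", k1, k2))
  data.frame(subject_id = sid, group = s$subject$group,
             body_weight_g = s$subject$body_weight_g,
             injected_dose_kBq = s$subject$injected_dose_kBq,
             K1 = k1, k2 = k2,
             se_K1 = mean(vapply(fits, function(f) f$se[["K1"]], 0)),
             se_k2 = mean(vapply(fits, function(f) f$se[["k2"]], 0)),
             rss = mean(vapply(fits, `[[`, numeric(1), "rss")),
             converged = all(vapply(fits, `[[`, logical(1), "converged")),
             excluded = excluded, exclusion_reason = reason,
             logan_vt = vt,
             auc_0_90 = if (is.null(cl)) NA_real_ else cl$auc_0_90,
             id_per_kg = if (is.null(cl)) NA_real_ else cl$id_per_kg,
             tbc = if (is.null(cl)) NA_real_ else cl$tbc,
             stringsAsFactors = FALSE)
}

# route cohort TACs through the imaging layer when phantom mode is on
.phantom_subject <- function(s, config) {
  organ_tacs <- list(heart = s$idif, kidney_cortex_l = s$cortex_left,
                     kidney_cortex_r = s$cortex_right,
                     bladder = bladder_tac(s$truth$input_fn,
                                           s$idif$schedule))
  ph <- render_phantom(organ_tacs, config$phantom_geometry)
  s$idif <- build_idif(ph, circle_diameter_px = config$idif_circle_px,
                       n_slices = config$idif_slices)
  s$cortex_left <- extract_tac(ph, organ_mask(ph, "kidney_cortex_l"))
  s$cortex_right <- extract_tac(ph, organ_mask(ph, "kidney_cortex_r"))
  s
}

#' Run the full simulation-to-statistics study
#'
#' Simulates every configured group, optionally routes the TACs through
#' the phantom imaging layer, fits the one-tissue model per kidney (per
#' subject K1/k2 are the means over both kidneys of non-excluded fits),
#' computes Logan V_T and total body clearance per subject, and builds the
#' group-comparison and correlation tables against the control group.
#' Excluded subjects stay in the subject table but are omitted from group
#' statistics. Fully deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report` with data frames `subjects`,
#'   `comparisons` (endpoints K1, k2, tbc per contrast), `correlations`
#'   (TBC vs K1 per group), the provenance echo and the run log.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config"))
    stop("'config' must be a study_config", call. = FALSE)
  log_lines <- character(0)
  log <- function(line) log_lines[[length(log_lines) + 1L]] <<- line

  subjects <- NULL
  for (g in names(config$groups)) {
    log(sprintf("simulate\t%s\tn=%d", g, config$groups[[g]]))
    coh <- simulate_cohort(config$presets[[g]], n = config$groups[[g]],
                           seed = config$seed, schedule = config$schedule,
                           reference = config$reference,
                           noise = config$noise)
    for (s in coh$subjects) {
      if (s$subject$subject_id %in% config$zero_cortex) {
        s$cortex_left$values[] <- 0
        s$cortex_right$values[] <- 0
        log(sprintf("degrade\t%s\tcortex zeroed", s$subject$subject_id))
      }
      if (config$phantom) s <- .phantom_subject(s, config)
      subjects <- rbind(subjects, .analyse_subject(s, config, log))
    }
  }

  kept <- subjects[!subjects$excluded, , drop = FALSE]
  ctrl <- kept[kept$group == config$control, , drop = FALSE]
  comparisons <- NULL
  for (g in setdiff(names(config$groups), config$control)) {
    grp <- kept[kept$group == g, , drop = FALSE]
    for (endpoint in c("K1", "k2", "tbc")) {
      a <- ctrl[[endpoint]]; b <- grp[[endpoint]]
      if (length(a) < 2L || length(b) < 2L) next
      cmp <- compare_groups(a, b)
      comparisons <- rbind(comparisons, data.frame(
        endpoint = endpoint, group_a = config$control, group_b = g,
        n_a = cmp$n_a, n_b = cmp$n_b,
        mean_a = cmp$mean_a, sem_a = cmp$sem_a,
        mean_b = cmp$mean_b, sem_b = cmp$sem_b,
        test_used = cmp$test_used, statistic = cmp$statistic,
        p_value = cmp$p_value, fold_change = cmp$fold_change,
        direction = if (cmp$fold_change >= 1) "up" else "down",
        significant = cmp$significant, stringsAsFactors = FALSE))
      log(sprintf("stats\t%s vs %s\t%s\tp=%.6g", config$control, g,
                  endpoint, cmp$p_value))
    }
  }

  correlations <- NULL
  for (g in names(config$groups)) {
    grp <- kept[kept$group == g, , drop = FALSE]
    if (nrow(grp) < 3L) next
    pr <- tryCatch(pearson_r(grp$tbc, grp$K1), error = function(e) NULL)
    if (is.null(pr)) next
    correlations <- rbind(correlations, data.frame(
      group = g, n = nrow(grp), r = pr$r, p_value = pr$p_value,
      stringsAsFactors = FALSE))
    log(sprintf("correlate\t%s\tTBC~K1\tr=%.4f", g, pr$r))
  }

  structure(list(subjects = subjects, comparisons = comparisons,
                 correlations = correlations,
                 provenance = .config_echo(config), log = log_lines),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  n_exc <- sum(x$subjects$excluded)
  cat(sprintf("Study report: %d subjects (%d excluded), %d comparisons\n",
              nrow(x$subjects), n_exc,
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons)))
  if (!is.null(x$comparisons)) {
    show <- x$comparisons[, c("endpoint", "group_b", "fold_change",
                              "direction", "p_value", "test_used")]
    show$fold_change <- signif(show$fold_change, 3)
    show$p_value <- signif(show$p_value, 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

# full-precision deterministic CSV writer
.write_report_csv <- function(d, path) {
  if (is.null(d)) d <- data.frame()
  for (nm in names(d))
    if (is.numeric(d[[nm]])) d[[nm]] <- sprintf("%.17g", d[[nm]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a study report to CSV files
#'
#' Writes `subjects.csv`, `comparisons.csv`, `correlations.csv`, the
#' provenance echo `config.json` and the run log `run_log.txt` into
#' `outdir`. Numbers are serialised at full double precision, so identical
#' config and seed give byte-identical files.
#'
#' @param report a [run_study()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!inherits(report, "study_report"))
    stop("'report' must be a study_report", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .write_report_csv(report$subjects, file.path(outdir, "subjects.csv"))
  .write_report_csv(report$comparisons, file.path(outdir, "comparisons.csv"))
  .write_report_csv(report$correlations, file.path(outdir, "correlations.csv"))
  jsonlite::write_json(report$provenance, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Group fold-change summary table (treatment presets vs control)
#'
#' For each treatment preset, simulates the preset and the control under
#' the config seed, computes per-subject total body clearance, and reports
#' the group-mean TBC fold-change relative to control with a direction
#' arrow and the gated comparison P value. With noise off, the fold-change
#' column equals each preset's plasma_scale (or its reciprocal for
#' increased clearance) exactly.
#'
#' @param config a [study_config()]; its presets must include `control`
#'   plus the requested treatments.
#' @param treatments preset names to compare against `"control"`.
#' @return A data frame with class `tbc_table`: group, n, fold_change
#'   (always >= 1), direction (`"down"` = clearance lower than control),
#'   p_value.
#' @export
report_table1 <- function(config = study_config(),
                          treatments = c("Tg", "oct12_ko", "cimetidine",
                                         "pyrimethamine")) {
  needed <- c("control", treatments)
  missing_presets <- setdiff(needed, names(config$presets))
  if (length(missing_presets) > 0L)
    stop(sprintf("presets missing for: %s",
                 paste(missing_presets, collapse = ", ")), call. = FALSE)
  tbc_of <- function(name) {
    p <- config$presets[[name]]
    coh <- simulate_cohort(p, n = p$n_default, seed = config$seed,
                           schedule = config$schedule,
                           reference = config$reference,
                           noise = config$noise)
    vapply(coh$subjects, function(s) tbc(s$subject, s$idif)$tbc, numeric(1))
  }
  ctrl <- tbc_of("control")
  rows <- lapply(treatments, function(g) {
    v <- tbc_of(g)
    r <- mean(ctrl) / mean(v)  # >1 means clearance lower than control
    cmp <- compare_groups(ctrl, v)
    data.frame(group = g, n = length(v),
               fold_change = max(r, 1 / r),
               direction = if (r >= 1) "down" else "up",
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tbc_table", "data.frame")
  out
}

#' @export
print.tbc_table <- function(x, ...) {
  cat("Fold-change in TBC relative to control\n")
  arrows <- ifelse(x$direction == "down", "v", "^")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s (n=%d)  %.3g %s  P=%.3g\n", x$group[i], x$n[i],
                x$fold_change[i], arrows[i], x$p_value[i]))
  invisible(x)
}

#' Read / write a study configuration as JSON
#'
#' The JSON mirrors the fields of [study_config()]: group sizes, control
#' group, seed, noise flag, Logan `t_star`, preset definitions, the frame
#' schedule and the reference input function. Fields left out fall back to
#' the package defaults. The same format is echoed into every report
#' directory as `config.json`, so a run can be reproduced from its own
#' output.
#'
#' @param path JSON file path.
#' @param config a [study_config()].
#' @return `read_study_config` returns a [study_config()];
#'   `write_study_config` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  presets <- default_presets()
  if (!is.null(j$presets)) {
    presets <- lapply(j$presets, function(p)
      group_preset(p$name, p$n_default, p$true_K1, p$true_k2,
                   p$plasma_scale,
                   noise_scale = p$noise_scale %||% 2,
                   idif_dilution = p$idif_dilution %||% 1))
    names(presets) <- vapply(presets, `[[`, character(1), "name")
  }
  schedule <- if (!is.null(j$schedule))
    frame_schedule(j$schedule$frame_start_s, j$schedule$frame_duration_s)
  else default_frame_schedule()
  reference <- if (!is.null(j$reference_input))
    input_function(j$reference_input$amplitude_kBq_mL,
                   j$reference_input$rate_per_min,
                   j$reference_input$delay_min %||% 0.1)
  else default_input_function()
  groups <- unlist(j$groups)
  study_config(groups = groups,
               control = j$control %||% names(groups)[1L],
               seed = j$seed %||% 1L, noise = j$noise %||% TRUE,
               t_star = j$t_star %||% 20,
               phantom = isTRUE(j$phantom),
               presets = presets, schedule = schedule,
               reference = reference,
               zero_cortex = as.character(j$zero_cortex %||% character(0)),
               fine_dt = j$fine_dt %||% 0.0025)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(.config_echo(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
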