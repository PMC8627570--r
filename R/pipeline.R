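## Orchestration: wire simulate -> track -> kinematics -> performance ->
## stats into one reproducible run with per-stage artifacts.

#' Build a pipeline run configuration
#'
#' A flat, declarative configuration: one block per stage, every tolerance
#' explicit, echoed verbatim into the run's provenance record so that no
#' threshold is applied silently.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed integer seed driving every random draw of the run.
#' @param input_midlines optional path to a midline CSV; when given, the
#'   simulate/render/track stages are skipped and kinematics start from the
#'   file.
#' @param cohort a [cohort_spec()] (its seed is overridden by `seed`).
#' @param duration_s,frame_rate_hz length and rate of each simulated trial.
#' @param n_points midline points per frame.
#' @param from_images if TRUE each simulated trial is rendered to
#'   silhouette frames and re-tracked (the full image pipeline); if FALSE
#'   (default) kinematics run on the generated midlines directly.
#' @param render a [render_spec()] used when `from_images` is TRUE.
#' @param steady_tol steady-state cycle-speed tolerance.
#' @param amplitude Strouhal amplitude convention ("half_pp" or "pp").
#' @param alpha significance level for the statistics stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input_midlines = NULL,
                       cohort = cohort_spec(), duration_s = 2,
                       frame_rate_hz = 250, n_points = 100,
                       from_images = FALSE, render = render_spec(follow = TRUE),
                       steady_tol = 0.15, amplitude = "half_pp",
                       alpha = 0.05) {
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required")
  if (!is.null(input_midlines) && !file.exists(input_midlines))
    stop("input_midlines path does not exist: ", input_midlines)
  stopifnot(inherits(cohort, "cohort_spec"), duration_s > 0,
            frame_rate_hz > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_midlines = input_midlines, cohort = cohort,
                 duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 n_points = n_points, from_images = from_images,
                 render = render, steady_tol = steady_tol,
                 amplitude = amplitude, alpha = alpha),
            class = "run_config")
}

config_echo <- function(config) {
  list(seed = config$seed, input_midlines = config$input_midlines,
       duration_s = config$duration_s,
       frame_rate_hz = config$frame_rate_hz, n_points = config$n_points,
       from_images = config$from_images, steady_tol = config$steady_tol,
       amplitude = config$amplitude, alpha = config$alpha,
       cohort = list(n = as.list(config$cohort$n),
                     means = config$cohort$means, sds = config$cohort$sds,
                     regen_range = config$cohort$regen_range,
                     trials_per_individual =
                       config$cohort$trials_per_individual,
                     within_sd_frac = config$cohort$within_sd_frac),
       render = if (config$from_images)
         list(pixels_per_bl = config$render$pixels_per_bl,
              follow = config$render$follow) else NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing per-stage artifacts into
#' `config$out_dir`: `midlines.csv` (generated or echoed input),
#' `kinematics.csv` (one row per trial with QC flags),
#' `trials.csv` (kinematics joined with cohort metadata and performance
#' indices), `stats.json` and `summary.txt` (group-mean tables and the
#' statistical battery), and `provenance.json` (config echo, package
#' version, seed, per-stage row counts). A stage failure halts the run; the
#' artifacts written so far are retained and a `FAILED` marker names the
#' stage. Identical configuration and seed give byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the trial table, the stats report and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- "setup"
  on.exit({
    if (!identical(stage, "done"))
      writeLines(stage, file.path(config$out_dir, "FAILED"))
  })

  if (is.null(config$input_midlines)) {
    stage <- "simulate"
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
    params <- attr(cohort, "params")
    n_frames <- round(config$duration_s * config$frame_rate_hz)
    seqs <- vector("list", nrow(cohort))
    meta <- cohort[, c("individual_id", "treatment", "regeneration_pct",
                       "trial")]
    names(meta)[1] <- "individual"
    for (i in seq_len(nrow(cohort))) {
      sq <- generate_midline_sequence(params[[i]], config$frame_rate_hz,
                                      n_frames, n_points = config$n_points)
      if (config$from_images) {
        stk <- render_frames(sq, config$render)
        sq <- track_frames(stk, n_points = config$n_points)
      }
      seqs[[i]] <- sq
    }
    write_midline_csv(seqs, file.path(config$out_dir, "midlines.csv"),
                      meta = meta)
    counts$simulate <- length(seqs)
  } else {
    stage <- "read_midlines"
    seqs <- read_midline_csv(config$input_midlines)
    meta <- attr(seqs, "meta")
    file.copy(config$input_midlines,
              file.path(config$out_dir, "midlines.csv"), overwrite = TRUE)
    sc <- sub("\\.csv$", ".json", config$input_midlines)
    if (file.exists(sc))
      file.copy(sc, file.path(config$out_dir, "midlines.json"),
                overwrite = TRUE)
    counts$read_midlines <- length(seqs)
  }

  stage <- "kinematics"
  kin <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    row <- tryCatch(wave_kinematics(seqs[[i]], steady_tol = config$steady_tol),
                    error = function(e) conditionMessage(e))
    if (is.character(row)) {
      kin[[i]] <- NULL
      meta$qc_excluded[i] <- row
    } else {
      kin[[i]] <- cbind(meta[i, c("individual", "treatment",
                                  "regeneration_pct", "trial")], row)
    }
  }
  kin <- do.call(rbind, kin)
  if (is.null(kin) || nrow(kin) == 0) stop("no trial passed kinematics QC")
  names(kin)[names(kin) == "individual"] <- "individual_id"
  write.csv(kin, file.path(config$out_dir, "kinematics.csv"),
            row.names = FALSE)
  counts$kinematics <- nrow(kin)

  stage <- "performance"
  trials <- performance_indices(kin, amplitude = config$amplitude)
  write.csv(trials, file.path(config$out_dir, "trials.csv"),
            row.names = FALSE)
  counts$performance <- nrow(trials)

  stage <- "stats"
  rep <- stats_report(trials, alpha = config$alpha)
  writeLines(jsonlite::toJSON(list(
    anova = rep$anova, posthoc = rep$posthoc,
    regressions = rep$regressions,
    mixed_model = if (inherits(rep$mixed_model, "mixed_model_fit"))
      rep$mixed_model[c("fixed", "random_intercept_sd", "residual_sd",
                        "method")] else rep$mixed_model,
    alpha = rep$alpha), auto_unbox = TRUE, digits = NA, na = "null"),
    file.path(config$out_dir, "stats.json"))
  counts$stats <- nrow(rep$anova)

  stage <- "report"
  con <- file(file.path(config$out_dir, "summary.txt"), "w")
  grp <- aggregate(trials[, intersect(c("speed_bl_s", "frequency_hz",
                                        "amp_pp_bl", "wavelength_bl",
                                        "waves_per_body", "amp_ratio",
                                        "strouhal", "stride_length_bl"),
                                      names(trials))],
                   by = list(treatment = trials$treatment), FUN = mean)
  writeLines("Group means (per trial):", con)
  utils::capture.output(print(grp, digits = 3), file = con, append = TRUE)
  writeLines("", con)
  st_tab <- table(trials$treatment, classify_strouhal(trials$strouhal))
  writeLines("Strouhal classification (trials):", con)
  utils::capture.output(print(st_tab), file = con, append = TRUE)
  writeLines("", con)
  utils::capture.output(print(rep), file = con, append = TRUE)
  close(con)

  jsonlite::write_json(list(package_version =
                              as.character(packageVersion("swimkin")),
                            config = config_echo(config),
                            row_counts = counts),
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- "done"
  invisible(list(trials = trials, stats = rep, out_dir = config$out_dir))
}
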