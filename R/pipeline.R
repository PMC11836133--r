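#' Configuration for an end-to-end run
#'
#' @param experiment `"main"` or `"pilot"`.
#' @param n_participants Cohort size (48 main / 23 pilot are the study's
#'   analysed sizes).
#' @param seed Master seed; every random draw in the run derives from it.
#' @param cohort_args Named list of overrides for [sim_cohort()].
#' @param slope_fixed Fixed response-function slope for block fits; `NULL`
#'   estimates it from the data.
#' @param sign_convention Error-signal convention for [fit_block()].
#' @param jnd_convention JND convention for [fit_psychometric()].
#' @param bootstrap_reps Repetitions for the parameter-table CIs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = c("main", "pilot"),
                       n_participants = 48L, seed = 1L,
                       cohort_args = list(), slope_fixed = NULL,
                       sign_convention = "stable",
                       jnd_convention = "sd",
                       bootstrap_reps = 10000L) {
  experiment <- match.arg(experiment)
  bad <- setdiff(names(cohort_args), names(formals(sim_participant)))
  if (length(bad))
    stop("unknown cohort_args key(s): ", paste(bad, collapse = ", "))
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed), cohort_args = cohort_args,
                 slope_fixed = slope_fixed,
                 sign_convention = sign_convention,
                 jnd_convention = jnd_convention,
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, fits the response-function slope and the block-wise
#' adaptation model, scores the 2AFC responses, fits detection trends and
#' psychometric functions, and runs the study's inferential tests. All
#' tables are returned and, when `output_dir` is given, written as CSVs
#' together with a manifest recording the full configuration and seed (the
#' run is reproducible from the manifest alone).
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory for CSV outputs.
#' @return A list of tibbles: `trials`, `slopes`, `fits`,
#'   `fit_summary` (mean A and b with bootstrap CIs per schedule x
#'   magnitude), `trends`, `psychometric`, `stats` (schedule effects on b,
#'   JND comparison, detection-adaptation correlations).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- do.call(sim_cohort, c(list(n = config$n_participants),
                                  config$cohort_args))
  sim <- simulate_experiment(cohort, config$experiment, seed = config$seed)
  trials <- sim$trials

  slopes <- fit_response_slope(trials)
  fits <- fit_blocks(trials,
                     slope_fixed = config$slope_fixed %||% slopes$mean_slope,
                     sign_convention = config$sign_convention)
  fit_summary <- fits |>
    dplyr::group_by(.data$schedule_kind, .data$magnitude) |>
    dplyr::group_modify(function(d, key) {
      ca <- bootstrap_ci(d$A, reps = config$bootstrap_reps,
                         seed = config$seed)
      cb <- bootstrap_ci(d$b, reps = config$bootstrap_reps,
                         seed = config$seed + 1L)
      tibble::tibble(A = ca$estimate, A_lo = ca$lo, A_hi = ca$hi,
                     b = cb$estimate, b_lo = cb$lo, b_hi = cb$hi,
                     n_blocks = nrow(d))
    }) |>
    dplyr::ungroup()

  scored <- score_responses(trials)
  trends <- fit_detection_trend(scored)
  psy <- fit_psychometrics(scored, jnd_convention = config$jnd_convention)

  # schedule effect on b (rmANOVA over schedule x |magnitude| plus paired
  # Bayesian t-test on participant means), JND comparison, correlation panel
  b_cells <- fits |>
    dplyr::mutate(magnitude_abs = abs(.data$magnitude))
  anova_b <- rm_anova_2way(b_cells, dv = "b", factor1 = "schedule_kind",
                           factor2 = "magnitude_abs")
  b_by_ps <- b_cells |>
    dplyr::group_by(.data$participant, .data$schedule_kind) |>
    dplyr::summarise(b = mean(.data$b), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "schedule_kind", values_from = "b")
  t_b <- paired_t(b_by_ps$abrupt, b_by_ps$sinusoidal, bayes = TRUE)
  jnd_wide <- psy |>
    dplyr::select("participant", "schedule_kind", "jnd") |>
    tidyr::pivot_wider(names_from = "schedule_kind", values_from = "jnd")
  t_jnd <- paired_t(jnd_wide$abrupt, jnd_wide$sinusoidal, bayes = TRUE)

  person <- dplyr::inner_join(
    b_by_ps |> tidyr::pivot_longer(-"participant", names_to = "schedule_kind",
                                   values_to = "b"),
    psy |> dplyr::select("participant", "schedule_kind", "jnd"),
    by = c("participant", "schedule_kind"))
  cors <- person |>
    dplyr::group_by(.data$schedule_kind) |>
    dplyr::group_modify(function(d, key) correlation_test(d$jnd, d$b)) |>
    dplyr::ungroup()

  stats_tbl <- list(anova_b = anova_b,
                    t_b = t_b, t_jnd = t_jnd, correlations = cors)

  out <- list(config = config, trials = trials,
              slopes = slopes$by_participant,
              mean_slope = slopes$mean_slope,
              fits = fits, fit_summary = fit_summary, trends = trends,
              psychometric = psy, stats = stats_tbl)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm)
      utils::write.csv(x, file.path(output_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    wr(trials, "trials"); wr(slopes$by_participant, "slopes")
    wr(fits, "fits"); wr(fit_summary, "fit_summary")
    wr(trends, "trends"); wr(psy, "psychometric")
    wr(anova_b, "anova_b"); wr(t_b, "t_b"); wr(t_jnd, "t_jnd")
    wr(cors, "correlations")
    dput(unclass(config), file.path(output_dir, "manifest.R"))
  }
  out
}

#' Import an external trial table into the canonical layout
#'
#' Maps a deposited dataset's column names onto the canonical trial columns
#' and runs unit sanity checks (sizes in mm, MGAs within 10-200 mm). The
#' required canonical columns are `participant`, `block_id`,
#' `schedule_kind`, `magnitude`, `trial`, `v_mm`, `h_mm`, `mga_mm`; the
#' optional `response` column enables the detection analyses.
#'
#' @param path A CSV file.
#' @param column_map Named character vector: canonical name -> column name in
#'   the file.
#' @return A canonical trial tibble (with `mismatch_mm` derived).
#' @export
import_external <- function(path, column_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  required <- c("participant", "block_id", "schedule_kind", "magnitude",
                "trial", "v_mm", "h_mm", "mga_mm")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map))
    stop("column_map is missing required field(s): ",
         paste(missing_map, collapse = ", "))
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop("file lacks mapped column(s): ", paste(absent, collapse = ", "))
  out <- raw[, unname(column_map)]
  names(out) <- names(column_map)
  mga <- out$mga_mm[!is.na(out$mga_mm)]
  if (length(mga) && (any(mga < 10) || any(mga > 200)))
    stop("unit sanity check failed: MGAs outside 10-200 mm ",
         "(are the units mm?)")
  if (any(out$v_mm < 10 | out$v_mm > 200, na.rm = TRUE))
    stop("unit sanity check failed: seen sizes outside 10-200 mm")
  dplyr::mutate(out, mismatch_mm = .data$h_mm - .data$v_mm)
}

#' Summarise a completed run directory
#'
#' Writes (and returns) a plain-markdown summary of a [run_pipeline()]
#' output directory: configuration, mean adaptation parameters per schedule,
#' detection-trend means, JND comparison and correlations.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param file Optional path for the markdown summary (default
#'   `summary.md` inside `run_dir`).
#' @return The summary lines, invisibly.
#' @export
report_run <- function(run_dir, file = file.path(run_dir, "summary.md")) {
  need <- c("fits.csv", "trends.csv", "psychometric.csv", "manifest.R")
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent))
    stop("incomplete run: missing ", paste(absent, collapse = ", "))
  cfg <- dget(file.path(run_dir, "manifest.R"))
  fits <- utils::read.csv(file.path(run_dir, "fits.csv"))
  trends <- utils::read.csv(file.path(run_dir, "trends.csv"))
  psy <- utils::read.csv(file.path(run_dir, "psychometric.csv"))
  mean_by <- function(d, col)
    tapply(d[[col]], d$schedule_kind, mean, na.rm = TRUE)
  b_means <- mean_by(fits, "b"); a_means <- mean_by(fits, "A")
  sl_means <- mean_by(trends, "slope"); jnd_means <- mean_by(psy, "jnd")
  fmt <- function(v) paste(sprintf("%s = %.3g", names(v), v), collapse = ", ")
  lines <- c(
    "# Run summary",
    "",
    sprintf("- experiment: %s, participants: %d, seed: %d",
            cfg$experiment, cfg$n_participants, cfg$seed),
    sprintf("- retention A (mean per schedule): %s", fmt(a_means)),
    sprintf("- error-correction b (mean per schedule): %s", fmt(b_means)),
    sprintf("- detection-trend slope %%/trial (mean per schedule): %s",
            fmt(sl_means)),
    sprintf("- JND mm (mean per schedule): %s", fmt(jnd_means)))
  if (file.exists(file.path(run_dir, "t_jnd.csv"))) {
    tj <- utils::read.csv(file.path(run_dir, "t_jnd.csv"))
    lines <- c(lines, sprintf(
      "- JND abrupt vs sinusoidal: t(%d) = %.2f, p = %.3g, d = %.2f%s",
      tj$df, tj$t, tj$p, tj$cohens_d,
      if ("bf10" %in% names(tj)) sprintf(", BF10 = %.3g", tj$bf10) else ""))
  } else {
    lines <- c(lines, "- psychometric comparison: absent")
  }
  writeLines(lines, file)
  invisible(lines)
}
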