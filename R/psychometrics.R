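#' Score 2AFC size judgments
#'
#' Assigns correctness: a response is correct when its direction agrees with
#' the sign of the mismatch (felt minus seen size). Trials with zero mismatch
#' have no correct answer — the forced choice offered only "larger" and
#' "smaller" — so their correctness is undefined (`NA`) and they are excluded
#' from correctness analyses. Trials with a missing response are dropped with
#' a message.
#'
#' @param trials A tibble with columns `mismatch_mm` and `response`
#'   (`"felt_larger"` / `"felt_smaller"`).
#' @return `trials` with a logical `correct` column (`NA` when
#'   `mismatch_mm == 0`), rows with missing responses removed.
#' @export
score_responses <- function(trials) {
  stopifnot(all(c("mismatch_mm", "response") %in% names(trials)))
  n_miss <- sum(is.na(trials$response))
  if (n_miss > 0) {
    message("dropping ", n_miss, " trial(s) with missing response")
    trials <- dplyr::filter(trials, !is.na(.data$response))
  }
  bad <- setdiff(unique(trials$response), c("felt_larger", "felt_smaller"))
  if (length(bad))
    stop("unknown response value(s): ", paste(bad, collapse = ", "))
  dplyr::mutate(trials, correct = dplyr::case_when(
    .data$mismatch_mm == 0 ~ NA,
    .data$mismatch_mm > 0 ~ .data$response == "felt_larger",
    .data$mismatch_mm < 0 ~ .data$response == "felt_smaller"))
}

#' Mean percent correct per trial position
#'
#' Averages correctness over participants for each trial position within a
#' condition (schedule kind x peak magnitude). Zero-mismatch trials are
#' omitted from the denominators; a condition x trial cell with no usable
#' trials yields `NA`, never zero.
#'
#' @param scored Output of [score_responses()] with columns `schedule_kind`,
#'   `magnitude`, `trial`.
#' @return A tibble: `schedule_kind`, `magnitude_abs`, `trial`,
#'   `pct_correct`, `n`.
#' @export
percent_correct_by_trial <- function(scored) {
  scored |>
    dplyr::mutate(magnitude_abs = abs(.data$magnitude)) |>
    dplyr::group_by(.data$schedule_kind, .data$magnitude_abs, .data$trial) |>
    dplyr::summarise(
      n = sum(!is.na(.data$correct)),
      pct_correct = ifelse(n > 0, 100 * mean(.data$correct, na.rm = TRUE),
                           NA_real_),
      .groups = "drop")
}

#' Participant-wise linear trend of percent correct over trials
#'
#' Ordinary least squares of per-trial correctness (scored 0/100) on trial
#' index, per participant x schedule kind x peak magnitude. The slope is in
#' percentage points per trial; a declining slope in a condition means
#' detection worsened as the block progressed.
#'
#' @param scored Output of [score_responses()] with columns `participant`,
#'   `schedule_kind`, `magnitude`, `trial`.
#' @return A tibble: `participant`, `schedule_kind`, `magnitude_abs`,
#'   `slope` (%/trial), `intercept` (%), `n`.
#' @export
fit_detection_trend <- function(scored) {
  scored |>
    dplyr::mutate(magnitude_abs = abs(.data$magnitude)) |>
    dplyr::filter(!is.na(.data$correct)) |>
    dplyr::group_by(.data$participant, .data$schedule_kind,
                    .data$magnitude_abs) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L)
        stop("need >= 3 usable trials to fit a trend (participant ",
             key$participant, ")")
      if (dplyr::n_distinct(d$trial) < 2L)
        stop("degenerate predictor: all trials share one index")
      co <- coef(lm(I(100 * correct) ~ trial, data = d))
      tibble::tibble(intercept = co[[1]], slope = co[[2]], n = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Fold sinusoidal blocks into half-cycle positions
#'
#' In a sinusoidal block the absolute mismatch repeats every half period, and
#' one half-cycle contains each magnitude exactly once — so averaging by
#' position within the half-cycle summarises detection without confounding it
#' with perturbation magnitude. Position `p` of trial `t` is
#' `((t - 1) mod (P/2)) + 1` for period `P`. Positions whose mismatch is zero
#' have undefined correctness and yield `NA`.
#'
#' @param scored Scored sinusoidal trials with columns `trial`, `correct`,
#'   `schedule_kind`.
#' @param period Trials per full cycle (12 in the printed designs).
#' @return A tibble: `position` (1..P/2), `pct_correct`, `n`,
#'   `abs_mismatch_mean`.
#' @export
fold_half_cycle <- function(scored, period = 12L) {
  if (!all(scored$schedule_kind == "sinusoidal"))
    stop("fold_half_cycle applies to sinusoidal blocks only")
  if (period %% 2L != 0L) stop("period must be even")
  scored |>
    dplyr::mutate(position = ((.data$trial - 1L) %% (period %/% 2L)) + 1L) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n = sum(!is.na(.data$correct)),
      pct_correct = ifelse(n > 0, 100 * mean(.data$correct, na.rm = TRUE),
                           NA_real_),
      abs_mismatch_mean = mean(abs(.data$mismatch_mm)),
      .groups = "drop")
}

#' Fit a cumulative-normal psychometric function
#'
#' Maximum-likelihood fit of `P(felt larger | mismatch) =
#' Phi((mismatch - pse) / sigma)` to binary responses (a probit regression on
#' the mismatch). The just-noticeable difference defaults to `sigma`, the
#' distance from the PSE to the 84.1% point; the alternative convention —
#' half the 25-75% spread, `0.6745 * sigma` — is available via
#' `jnd_convention = "quartile"`. With `lapse > 0` the function becomes
#' `lapse/2 + (1 - lapse) * Phi(...)`, fitted by direct ML.
#'
#' @param trials A tibble with columns `mismatch_mm` and `response`.
#' @param jnd_convention `"sd"` (default) or `"quartile"`.
#' @param lapse Fixed lapse rate in `[0, 1)` (default 0).
#' @return An object of class `psychometric_fit`: `pse`, `sigma`, `jnd`,
#'   `loglik`, `n_trials`, `separation` (TRUE when the responses are
#'   perfectly separable and sigma collapses towards zero).
#' @export
fit_psychometric <- function(trials, jnd_convention = c("sd", "quartile"),
                             lapse = 0) {
  jnd_convention <- match.arg(jnd_convention)
  stopifnot(lapse >= 0, lapse < 1)
  y <- trials$response == "felt_larger"
  x <- trials$mismatch_mm
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (dplyr::n_distinct(x) < 2L)
    stop("need >= 2 distinct mismatch levels")
  if (all(y) || all(!y))
    stop("responses are all identical: psychometric function not estimable")

  separation <- FALSE
  if (lapse == 0) {
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial(link = "probit")),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- coef(fit)
    if (co[[2]] <= 0)
      stop("fitted psychometric slope is non-positive; responses do not ",
           "increase with the mismatch")
    sigma <- 1 / co[[2]]
    pse <- -co[[1]] / co[[2]]
    ll <- as.numeric(stats::logLik(fit))
  } else {
    nll <- function(p) {
      pr <- lapse / 2 + (1 - lapse) * pnorm((x - p[1]) / exp(p[2]))
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      -sum(ifelse(y, log(pr), log(1 - pr)))
    }
    start <- c(0, log(max(sd(x) / 2, 0.5)))
    op <- optim(start, nll, method = "BFGS")
    pse <- op$par[1]; sigma <- exp(op$par[2]); ll <- -op$value
  }
  if (is.finite(sigma) && sigma > 0 && sigma < 1e-3) separation <- TRUE
  if (separation)
    warning("perfect or near-perfect separation: sigma at its lower bound")
  jnd <- if (jnd_convention == "sd") sigma else qnorm(0.75) * sigma
  structure(list(pse = pse, sigma = sigma, jnd = jnd,
                 jnd_convention = jnd_convention, lapse = lapse,
                 loglik = ll, n_trials = length(y), separation = separation),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>  PSE = ", signif(x$pse, 4), " mm, sigma = ",
      signif(x$sigma, 4), " mm, JND = ", signif(x$jnd, 4), " mm (",
      x$jnd_convention, " convention), n = ", x$n_trials,
      if (x$separation) "  [separation]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x,object A `psychometric_fit`.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("pse", "sigma", "jnd"),
                 estimate = c(x$pse, x$sigma, x$jnd))
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(pse = x$pse, sigma = x$sigma, jnd = x$jnd,
                 loglik = x$loglik, n_trials = x$n_trials,
                 separation = x$separation)
}

#' @rdname fit_psychometric
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(
    mismatch_mm = seq(object$pse - 4 * object$sigma,
                      object$pse + 4 * object$sigma, length.out = 200))
  grid$p <- object$lapse / 2 + (1 - object$lapse) *
    pnorm((grid$mismatch_mm - object$pse) / object$sigma)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$mismatch_mm, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$pse, linetype = 3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "Mismatch felt - seen (mm)",
                  y = "P(respond 'felt larger')") +
    ggplot2::theme_minimal()
}

#' Psychometric fits for every participant x schedule kind
#'
#' @param scored Scored trials with `participant`, `schedule_kind`,
#'   `mismatch_mm`, `response`.
#' @param ... Passed to [fit_psychometric()].
#' @return A tibble with one row per participant x schedule kind:
#'   `pse`, `sigma`, `jnd`, `loglik`, `n_trials`, `separation`.
#' @export
fit_psychometrics <- function(scored, ...) {
  scored |>
    dplyr::group_by(.data$participant, .data$schedule_kind) |>
    dplyr::group_modify(function(d, key) glance(fit_psychometric(d, ...))) |>
    dplyr::ungroup()
}

#' Plot percent correct over trials
#'
#' One line per peak magnitude, faceted by schedule kind.
#'
#' @param pct Output of [percent_correct_by_trial()].
#' @return A ggplot object.
#' @export
plot_percent_correct <- function(pct) {
  ggplot2::ggplot(pct,
                  ggplot2::aes(x = .data$trial, y = .data$pct_correct,
                               colour = factor(.data$magnitude_abs))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$schedule_kind)) +
    ggplot2::labs(x = "Trial", y = "% correct", colour = "Peak |mismatch| (mm)") +
    ggplot2::theme_minimal()
}
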