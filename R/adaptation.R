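#' Linear grip-aperture response function
#'
#' People open their grip wider than the object and scale it imperfectly with
#' object size, so the comfortable maximum grip aperture (MGA) for an object
#' of size v is modelled as a line: `MGA = intercept + slope * v`. Under
#' adaptation the visuomotor-mapping state x is added to the seen size before
#' the line is applied.
#'
#' @param intercept Intercept in mm.
#' @param slope Dimensionless scaling of MGA with object size.
#' @return A list of class `response_function`.
#' @export
response_function <- function(intercept, slope) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(intercept = intercept, slope = slope),
            class = "response_function")
}

#' Predicted MGA for a seen size under an adaptation state
#'
#' `intercept + slope * (v + x)`: the state shifts the effective seen size.
#' With `x = 0` this is the unperturbed response function.
#'
#' @param rf A [response_function()].
#' @param v Seen size in mm.
#' @param x Adaptation state in mm (default 0).
#' @return Predicted MGA in mm.
#' @examples
#' predict_mga(response_function(50, 0.5), v = 40)        # 70
#' predict_mga(response_function(50, 0.5), v = 40, x = 12) # 76
#' @export
predict_mga <- function(rf, v, x = 0) {
  rf$intercept + rf$slope * (v + x)
}

#' Trial-wise error signal driving state updates
#'
#' The error signal compares the executed grip with the grip that would have
#' been comfortable for the object actually felt in the hand:
#' `E = MGA_observed - (intercept + slope * h)` under the default
#' `"stable"` convention, so E > 0 means the grasp was too large and the
#' state is corrected downwards. The `"printed"` convention is the opposite
#' sign (`(intercept + slope * h) - MGA_observed`), which combined with the
#' state update `x' = A x - b E` produces positive feedback; it is provided
#' for audit only (see the methods vignette).
#'
#' @param rf A [response_function()].
#' @param h Felt size in mm.
#' @param mga_observed Measured MGA in mm.
#' @param sign_convention `"stable"` (default) or `"printed"`.
#' @return Error signal in mm of aperture.
#' @export
error_signal <- function(rf, h, mga_observed,
                         sign_convention = c("stable", "printed")) {
  sign_convention <- match.arg(sign_convention)
  e <- mga_observed - (rf$intercept + rf$slope * h)
  if (sign_convention == "printed") -e else e
}

#' One step of the linear state-space update
#'
#' `x' = A * x - b * E`. A is the retention of the previous state (A = 1:
#' perfect retention; A = 0: none); b is the fraction of the error corrected
#' on the next trial (b = 0: no correction).
#'
#' @param A Retention in `[0, 1]`.
#' @param b Error-correction rate in `[0, 1]`.
#' @param x Current state in mm.
#' @param E Error signal in mm.
#' @return Next state in mm.
#' @export
update_state <- function(A, b, x, E) {
  if (A < 0 || A > 1 || b < 0 || b > 1)
    stop("A and b must lie in [0, 1]")
  A * x - b * E
}

#' Run the state-space model forward over a schedule
#'
#' Starting from `x[1] = 0`, predicts the MGA on each trial and updates the
#' state from the trial's error signal. When `observed_mgas` is supplied the
#' error uses the observed MGA (closed loop on data, as in fitting); when it
#' is `NULL` the model is self-driven and the error uses its own prediction
#' (simulation mode). `NA`s in `observed_mgas` (e.g. excluded trials) fall
#' back to the model's prediction for the state update and are flagged.
#'
#' @param A,b State-space parameters in `[0, 1]`.
#' @param rf A [response_function()].
#' @param schedule A schedule tibble (columns `v_mm`, `h_mm`).
#' @param observed_mgas Optional numeric vector of measured MGAs (mm), same
#'   length as the schedule; may contain `NA`.
#' @param sign_convention Passed to [error_signal()].
#' @return A tibble with columns `trial`, `v_mm`, `h_mm`, `state_x`,
#'   `mga_pred`, `error`.
#' @export
run_forward <- function(A, b, rf, schedule, observed_mgas = NULL,
                        sign_convention = c("stable", "printed")) {
  sign_convention <- match.arg(sign_convention)
  n <- nrow(schedule)
  if (!is.null(observed_mgas) && length(observed_mgas) != n)
    stop("observed_mgas has length ", length(observed_mgas),
         " but the schedule has ", n, " trials")
  v <- schedule$v_mm
  h <- schedule$h_mm
  int <- rf$intercept
  sl <- rf$slope
  sgn <- if (sign_convention == "printed") -1 else 1
  fwd <- forward_core(A, b, rf$intercept, rf$slope, v, h, observed_mgas, sgn)
  tibble::tibble(trial = seq_len(n), v_mm = v, h_mm = h,
                 state_x = fwd$x, mga_pred = fwd$pred, error = fwd$err)
}

# Lean forward recursion shared by run_forward() and the fit objective
forward_core <- function(A, b, int, sl, v, h, obs, sgn) {
  n <- length(v)
  x <- numeric(n)
  pred <- numeric(n)
  err <- numeric(n)
  xt <- 0
  for (t in seq_len(n)) {
    x[t] <- xt
    pred[t] <- int + sl * (v[t] + xt)
    mga_t <- if (is.null(obs) || is.na(obs[t])) pred[t] else obs[t]
    err[t] <- sgn * (mga_t - (int + sl * h[t]))
    xt <- A * xt - b * err[t]
  }
  list(x = x, pred = pred, err = err)
}

# RMSE of the closed-loop prediction against observed MGAs; NA observations
# (excluded trials) propagate the state but drop out of the objective.
block_rmse <- function(par, rf_slope, schedule, observed_mgas,
                       sign_convention = "stable") {
  sgn <- if (sign_convention == "printed") -1 else 1
  fwd <- forward_core(par[["A"]], par[["b"]], par[["intercept"]], rf_slope,
                      schedule$v_mm, schedule$h_mm, observed_mgas, sgn)
  keep <- !is.na(observed_mgas)
  sqrt(mean((fwd$pred[keep] - observed_mgas[keep])^2))
}

#' Fit the state-space adaptation model to one block
#'
#' Estimates retention `A`, error-correction `b` (both box-constrained to
#' `[0, 1]`) and the response-function intercept by minimising the RMSE
#' between observed and model-predicted MGAs over the whole block, with the
#' slope held fixed at the cohort-level estimate (see
#' [fit_response_slope()]). The optimiser is a deterministic coarse grid
#' over (A, b) — intercept started from the mean over baseline (unperturbed)
#' trials — followed by box-constrained quasi-Newton refinement from the
#' best grid starts.
#'
#' @param observed_mgas Measured MGAs in mm, one per trial; `NA` for excluded
#'   trials (the state still propagates across them via the model's own
#'   prediction; their residuals are omitted from the RMSE).
#' @param schedule The block's schedule tibble.
#' @param slope_fixed Fixed response-function slope.
#' @param sign_convention Passed to [error_signal()].
#' @param grid_A,grid_b Grid start values for A and b.
#' @param n_refine Number of best grid points refined by `optim`.
#' @return An object of class `adaptation_fit`: a list with elements `A`,
#'   `b`, `intercept`, `slope_fixed`, `rmse`, `n` (usable trials),
#'   `convergence`, `flat_ridge` (TRUE when the objective is insensitive to
#'   b, e.g. an unperturbed block), and `trials` (per-trial tibble with
#'   states, predictions and errors).
#' @examples
#' sp <- schedule_spec("abrupt", magnitude = 12)
#' sch <- make_abrupt_schedule(sp, rep(44, 24))
#' rf <- response_function(24, 0.93)
#' mga <- run_forward(0.95, 0.2, rf, sch)$mga_pred
#' fit <- fit_block(mga, sch, slope_fixed = 0.93)
#' round(c(fit$A, fit$b), 3)
#' @export
fit_block <- function(observed_mgas, schedule, slope_fixed,
                      sign_convention = c("stable", "printed"),
                      grid_A = seq(0.1, 0.9, by = 0.2),
                      grid_b = c(0.05, 0.15, 0.3, 0.5),
                      n_refine = 3L) {
  sign_convention <- match.arg(sign_convention)
  n_usable <- sum(!is.na(observed_mgas))
  if (n_usable < 6L)
    stop("fit_block needs at least 6 usable trials, got ", n_usable)
  if (length(observed_mgas) != nrow(schedule))
    stop("observed_mgas and schedule lengths differ")

  base <- schedule$mismatch_mm == 0 & !is.na(observed_mgas)
  int0 <- if (any(base)) {
    mean(observed_mgas[base] - slope_fixed * schedule$v_mm[base])
  } else {
    mean(observed_mgas - slope_fixed * schedule$v_mm, na.rm = TRUE)
  }

  # optimise the mean squared error (same argmin as the RMSE but smooth at a
  # perfect fit, where the square root has a kink); report RMSE
  sgn <- if (sign_convention == "printed") -1 else 1
  v <- schedule$v_mm; h <- schedule$h_mm
  keep <- !is.na(observed_mgas)
  obj <- function(p) {
    fwd <- forward_core(p[1], p[2], p[3], slope_fixed, v, h,
                        observed_mgas, sgn)
    mean((fwd$pred[keep] - observed_mgas[keep])^2)
  }
  starts <- expand.grid(A = grid_A, b = grid_b)
  starts$val <- vapply(seq_len(nrow(starts)), function(i)
    obj(c(starts$A[i], starts$b[i], int0)), numeric(1))
  starts <- starts[order(starts$val), , drop = FALSE]

  best <- NULL
  for (i in seq_len(min(n_refine, nrow(starts)))) {
    res <- tryCatch(
      optim(c(starts$A[i], starts$b[i], int0), obj, method = "L-BFGS-B",
            lower = c(0, 0, int0 - 50), upper = c(1, 1, int0 + 50),
            control = list(factr = 1e2, pgtol = 1e-12,
                           ndeps = rep(1e-7, 3))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("block fit failed to converge from any start")

  A <- best$par[1]; b <- best$par[2]; int <- best$par[3]
  rmse <- sqrt(best$value)
  # flat ridge in b: objective unchanged (to within noise resolution) when b
  # is perturbed — typical of unperturbed blocks where b is unidentified
  ridge <- abs(obj(c(A, min(b + 0.2, 1), int)) - best$value) < 1e-8 &&
    abs(obj(c(A, max(b - 0.2, 0), int)) - best$value) < 1e-8
  fwd <- run_forward(A, b, response_function(int, slope_fixed), schedule,
                     observed_mgas, sign_convention)
  fwd$mga_obs <- observed_mgas
  structure(
    list(A = A, b = b, intercept = int, slope_fixed = slope_fixed,
         rmse = rmse, n = n_usable, convergence = best$convergence,
         flat_ridge = ridge, sign_convention = sign_convention,
         trials = fwd),
    class = "adaptation_fit")
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat("<adaptation_fit>  A = ", signif(x$A, 4), ", b = ", signif(x$b, 4),
      ", intercept = ", signif(x$intercept, 5), " mm (slope fixed at ",
      signif(x$slope_fixed, 4), ")\n  RMSE = ", signif(x$rmse, 5),
      " mm over ", x$n, " trials",
      if (x$flat_ridge) "  [flat ridge: b unidentified]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_block
#' @param x An `adaptation_fit`.
#' @param ... Unused.
#' @export
tidy.adaptation_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "b", "intercept"),
                 estimate = c(x$A, x$b, x$intercept))
}

#' @rdname fit_block
#' @export
glance.adaptation_fit <- function(x, ...) {
  tibble::tibble(A = x$A, b = x$b, intercept = x$intercept,
                 slope_fixed = x$slope_fixed, rmse = x$rmse, n = x$n,
                 flat_ridge = x$flat_ridge)
}

#' @rdname fit_block
#' @param object An `adaptation_fit`.
#' @export
autoplot.adaptation_fit <- function(object, ...) {
  d <- object$trials
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$h_mm - .data$v_mm),
                       colour = "forestgreen", linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mga_obs), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mga_pred), colour = "firebrick") +
    ggplot2::labs(x = "Trial", y = "MGA (mm); dotted: mismatch (mm)",
                  title = sprintf("A = %.2f, b = %.2f, RMSE = %.2f mm",
                                  object$A, object$b, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Estimate the response-function slope across participants
#'
#' Ordinary least squares of the participant's mean MGA per seen size on the
#' seen size, per participant; the across-participant mean slope is the
#' `slope_fixed` used by [fit_block()].
#'
#' @param trials A tibble with columns `participant`, `v_mm`, `mga_mm`
#'   (excluded trials already removed or `NA`).
#' @return A list with `by_participant` (tibble: `participant`, `slope`,
#'   `intercept`) and `mean_slope`.
#' @export
fit_response_slope <- function(trials) {
  stopifnot(all(c("participant", "v_mm", "mga_mm") %in% names(trials)))
  by_p <- trials |>
    dplyr::filter(!is.na(.data$mga_mm)) |>
    dplyr::group_by(.data$participant, .data$v_mm) |>
    dplyr::summarise(mga = mean(.data$mga_mm), .groups = "drop") |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$v_mm) < 2L)
        stop("participant ", key$participant,
             ": need >= 2 distinct seen sizes to estimate a slope")
      co <- coef(lm(mga ~ v_mm, data = d))
      tibble::tibble(intercept = co[[1]], slope = co[[2]])
    }) |>
    dplyr::ungroup()
  list(by_participant = by_p, mean_slope = mean(by_p$slope))
}

#' Fit the adaptation model to every block of a trial table
#'
#' Groups a trial table by participant and block and fits [fit_block()] to
#' each, returning one row per block in the style of a model-parameter table.
#'
#' @param trials Tibble with columns `participant`, `block_id`,
#'   `schedule_kind`, `magnitude`, `trial`, `v_mm`, `h_mm`, `mismatch_mm`,
#'   `mga_mm` (NA = excluded).
#' @param slope_fixed Fixed slope; when `NULL`, estimated from the data via
#'   [fit_response_slope()].
#' @param ... Passed to [fit_block()].
#' @return A tibble with one row per participant x block: parameters, RMSE,
#'   and trial counts.
#' @export
fit_blocks <- function(trials, slope_fixed = NULL, ...) {
  if (is.null(slope_fixed))
    slope_fixed <- fit_response_slope(trials)$mean_slope
  trials |>
    dplyr::group_by(.data$participant, .data$block_id,
                    .data$schedule_kind, .data$magnitude) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$trial)
      fit <- fit_block(d$mga_mm, d, slope_fixed, ...)
      glance(fit)
    }) |>
    dplyr::ungroup()
}
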