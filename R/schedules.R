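#' Round sizes to the apparatus step size
#'
#' Felt-object lengths are realised by physical cuboids machined in fixed
#' increments, so simulated felt sizes must be snapped to that grid.
#' Rounds to the nearest multiple of `quantum`, ties away from zero.
#'
#' @param x Numeric vector of sizes or mismatches (mm).
#' @param quantum Step size in mm (default 0.5, the printed designs' step).
#' @return Numeric vector, each element a multiple of `quantum`, never more
#'   than `quantum / 2` away from the input.
#' @examples
#' quantize_size(10.392)        # 10.5
#' quantize_size(10.25)         # 10.5 (tie away from zero)
#' quantize_size(-10.25)        # -10.5
#' @export
quantize_size <- function(x, quantum = 0.5) {
  stopifnot(is.numeric(quantum), length(quantum) == 1L, quantum > 0)
  # round half away from zero (base round() rounds half to even)
  sign(x) * floor(abs(x) / quantum + 0.5) * quantum
}

#' Specify a perturbation schedule
#'
#' Captures the geometry of one experimental block: how the mismatch between
#' the felt and the seen object size evolves over trials. Two kinds are
#' supported: `"abrupt"` (a constant mismatch bracketed by unperturbed
#' baseline and washout trials) and `"sinusoidal"` (the mismatch follows a
#' sine over trials, starting at zero).
#'
#' @param schedule_kind `"abrupt"` or `"sinusoidal"`.
#' @param magnitude Signed peak mismatch in mm (felt minus seen).
#' @param n_trials Number of trials in the block (24 abrupt / 36 sinusoidal
#'   in the printed designs).
#' @param n_cycles Number of full sine cycles (sinusoidal only; 3 printed).
#' @param baseline_len Unperturbed trials at each end (abrupt only; 4 printed).
#' @param seen_sizes Candidate seen sizes in mm.
#' @param seen_assignment `"fixed_per_block"` or `"randomized_per_trial"`.
#' @param quantum Felt-size step in mm.
#' @param start_sign `"positive"` or `"negative"`: sign of the first
#'   half-cycle (sinusoidal only).
#' @return A list of class `schedule_spec`.
#' @export
schedule_spec <- function(schedule_kind = c("abrupt", "sinusoidal"),
                          magnitude,
                          n_trials = if (schedule_kind == "abrupt") 24L else 36L,
                          n_cycles = 3L,
                          baseline_len = 4L,
                          seen_sizes = c(40, 44, 48),
                          seen_assignment = c("randomized_per_trial",
                                              "fixed_per_block"),
                          quantum = 0.5,
                          start_sign = c("positive", "negative")) {
  schedule_kind <- match.arg(schedule_kind)
  seen_assignment <- match.arg(seen_assignment)
  start_sign <- match.arg(start_sign)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L,
            quantum > 0, n_trials >= 1)
  if (schedule_kind == "sinusoidal") {
    if (n_trials %% n_cycles != 0L)
      stop("sinusoidal schedule: n_trials (", n_trials,
           ") must be divisible by n_cycles (", n_cycles, ")")
  } else {
    if (2L * baseline_len >= n_trials)
      stop("abrupt schedule: baseline_len too long for n_trials")
  }
  structure(
    list(schedule_kind = schedule_kind, magnitude = magnitude,
         n_trials = as.integer(n_trials), n_cycles = as.integer(n_cycles),
         baseline_len = as.integer(baseline_len), seen_sizes = seen_sizes,
         seen_assignment = seen_assignment, quantum = quantum,
         start_sign = start_sign),
    class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat("<schedule_spec> ", x$schedule_kind,
      ", magnitude ", x$magnitude, " mm, ", x$n_trials, " trials",
      if (x$schedule_kind == "sinusoidal")
        paste0(", ", x$n_cycles, " cycles (", x$start_sign, " start)")
      else paste0(", baseline ", x$baseline_len, " trials each end"),
      "\n", sep = "")
  invisible(x)
}

schedule_tibble <- function(spec, v, mismatch) {
  h <- quantize_size(v + mismatch, spec$quantum)
  tibble::tibble(
    trial = seq_along(v),
    schedule_kind = spec$schedule_kind,
    magnitude = spec$magnitude,
    v_mm = v,
    h_mm = h,
    mismatch_mm = h - v
  )
}

#' Build an abrupt perturbation schedule
#'
#' The mismatch is zero on the `baseline_len` trials at each end of the block
#' and equal to `spec$magnitude` on every trial in between (the printed
#' design: 4 + 16 + 4 = 24 trials). Felt sizes are the seen sizes plus the
#' mismatch, snapped to the felt-size step.
#'
#' @param spec A [schedule_spec()] with `schedule_kind = "abrupt"`.
#' @param seen_sequence Seen sizes in mm, one per trial
#'   (length `spec$n_trials`).
#' @return A tibble with columns `trial`, `schedule_kind`, `magnitude`,
#'   `v_mm`, `h_mm`, `mismatch_mm`.
#' @examples
#' sp <- schedule_spec("abrupt", magnitude = 12)
#' make_abrupt_schedule(sp, rep(40, 24))
#' @export
make_abrupt_schedule <- function(spec, seen_sequence) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (spec$schedule_kind != "abrupt")
    stop("spec is not an abrupt schedule_spec")
  if (length(seen_sequence) != spec$n_trials)
    stop("seen_sequence has length ", length(seen_sequence),
         " but spec$n_trials is ", spec$n_trials)
  n <- spec$n_trials
  bl <- spec$baseline_len
  mismatch <- rep(0, n)
  mismatch[(bl + 1L):(n - bl)] <- spec$magnitude
  schedule_tibble(spec, seen_sequence, mismatch)
}

#' Build a sinusoidal perturbation schedule
#'
#' The mismatch on trial t is `sign * M * sin(2*pi*(t - 1) / P)` with period
#' `P = n_trials / n_cycles`, quantized to the felt-size step; trial 1 is
#' therefore exactly unperturbed. `start_sign = "negative"` flips the sign
#' of the whole sine.
#'
#' @inheritParams make_abrupt_schedule
#' @param start_sign Optional override of `spec$start_sign`.
#' @return A tibble, as [make_abrupt_schedule()].
#' @examples
#' sp <- schedule_spec("sinusoidal", magnitude = 12)
#' make_sinusoidal_schedule(sp, rep(44, 36))
#' @export
make_sinusoidal_schedule <- function(spec, seen_sequence, start_sign = NULL) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (spec$schedule_kind != "sinusoidal")
    stop("spec is not a sinusoidal schedule_spec")
  if (length(seen_sequence) != spec$n_trials)
    stop("seen_sequence has length ", length(seen_sequence),
         " but spec$n_trials is ", spec$n_trials)
  start_sign <- start_sign %||% spec$start_sign
  if (spec$n_trials %% spec$n_cycles != 0L)
    stop("n_trials must be divisible by n_cycles")
  P <- spec$n_trials / spec$n_cycles
  sgn <- if (identical(start_sign, "negative")) -1 else 1
  t <- seq_len(spec$n_trials)
  raw <- sgn * spec$magnitude * sin(2 * pi * (t - 1) / P)
  mismatch <- quantize_size(raw, spec$quantum)
  out <- schedule_tibble(spec, seen_sequence, mismatch)
  # seen sizes are integers and the mismatch is already on the quantum grid,
  # so h - v reproduces the quantized mismatch exactly
  out
}

#' Build a schedule of any kind from its spec
#'
#' Thin dispatcher over [make_abrupt_schedule()] and
#' [make_sinusoidal_schedule()].
#'
#' @inheritParams make_abrupt_schedule
#' @return A schedule tibble.
#' @export
make_schedule <- function(spec, seen_sequence) {
  if (spec$schedule_kind == "abrupt") {
    make_abrupt_schedule(spec, seen_sequence)
  } else {
    make_sinusoidal_schedule(spec, seen_sequence)
  }
}

#' Draw a seen-size sequence for a schedule spec
#'
#' Under `"randomized_per_trial"` (main experiment) each trial's seen size is
#' drawn uniformly from `spec$seen_sizes`; under `"fixed_per_block"` (pilot)
#' one size is used throughout the block.
#'
#' @param spec A [schedule_spec()].
#' @param seed Integer seed; the draw is deterministic given it.
#' @param fixed_size For `"fixed_per_block"`, the block's seen size
#'   (defaults to the first of `spec$seen_sizes`).
#' @return Numeric vector of length `spec$n_trials`.
#' @export
draw_seen_sequence <- function(spec, seed, fixed_size = NULL) {
  if (spec$seen_assignment == "fixed_per_block") {
    rep(fixed_size %||% spec$seen_sizes[[1L]], spec$n_trials)
  } else {
    withr::with_seed(seed,
      sample(spec$seen_sizes, spec$n_trials, replace = TRUE))
  }
}

#' Enumerate the 12 experimental block specs of an experiment
#'
#' Both experiments comprise 12 experimental blocks: six abrupt (one per
#' signed magnitude) and six sinusoidal (one per signed peak magnitude).
#' The main experiment uses magnitudes +/-3, +/-6, +/-12 mm with seen sizes
#' \{40, 44, 48\} mm randomized per trial; in the main experiment half of the
#' sinusoidal blocks start with a negative half-cycle. The pilot uses
#' +/-4, +/-8, +/-12 mm with seen sizes \{40, 45\} mm fixed per block and all
#' sinusoidal blocks starting positive (a negative magnitude with a positive
#' start is a sine whose peaks point downward, which is how the pilot's
#' negative peak mismatches arise).
#'
#' @param experiment `"main"` or `"pilot"`.
#' @return A list of 12 [schedule_spec()] objects, abrupt first.
#' @export
enumerate_block_set <- function(experiment = c("main", "pilot")) {
  experiment <- match.arg(experiment)
  if (experiment == "main") {
    mags <- c(-12, -6, -3, 3, 6, 12)
    seen <- c(40, 44, 48)
    assign <- "randomized_per_trial"
    # half of the sinusoidal blocks start with a negative perturbation
    starts <- rep(c("positive", "negative"), 3L)
  } else {
    mags <- c(-12, -8, -4, 4, 8, 12)
    seen <- c(40, 45)
    assign <- "fixed_per_block"
    starts <- rep("positive", 6L)
  }
  abrupt <- lapply(mags, function(m)
    schedule_spec("abrupt", magnitude = m, seen_sizes = seen,
                  seen_assignment = assign))
  sinus <- lapply(seq_along(mags), function(i)
    schedule_spec("sinusoidal", magnitude = mags[[i]], seen_sizes = seen,
                  seen_assignment = assign, start_sign = starts[[i]]))
  c(abrupt, sinus)
}

#' Plot a perturbation schedule
#'
#' Mismatch (felt minus seen size) over trials.
#'
#' @param schedule A schedule tibble.
#' @return A ggplot object.
#' @export
plot_schedule <- function(schedule) {
  ggplot2::ggplot(schedule,
                  ggplot2::aes(x = .data$trial, y = .data$mismatch_mm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_step(colour = "forestgreen") +
    ggplot2::geom_point(size = 1, colour = "forestgreen") +
    ggplot2::labs(x = "Trial", y = "Mismatch felt - seen (mm)") +
    ggplot2::theme_minimal()
}
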