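#' Define a simulated participant
#'
#' Bundles the generative parameters of one synthetic participant: the
#' state-space adaptation parameters that produce their grip apertures, the
#' motor noise added to each MGA, and the observer model that produces their
#' 2AFC size judgments. Defaults follow the reference simulation values
#' (A = 0.95, b = 0.2) with a response function giving a typical ~20 mm grasp
#' margin over the object, 2 mm motor noise, and a 4 mm-SD comparison
#' observer fully coupled to the adaptation state.
#'
#' The observer model: the decision variable on a trial is
#' `d = h - (v + kappa * x) - obs_bias + eta`, `eta ~ N(0, obs_sigma)`, and
#' the response is "felt larger" iff `d > 0`. With `kappa = 1` the internal
#' reference against which the felt size is compared is shifted by the full
#' adaptation state, so adapted trials carry a reduced effective mismatch;
#' `kappa = 0` decouples perception from adaptation. This operationalises the
#' hypothesis that adaptation shrinks the error signal available for
#' detection; it is a simulation device, not an estimated model.
#'
#' @param A_true,b_true Generating retention and error-correction, in `[0,1]`.
#' @param intercept_true Response-function intercept (mm).
#' @param slope_true Response-function slope (dimensionless).
#' @param motor_noise_sd SD of additive MGA noise (mm).
#' @param obs_sigma SD of the 2AFC decision noise (mm).
#' @param obs_bias Constant shift of the point of subjective equality (mm).
#' @param kappa Adaptation-perception coupling in `[0, 1]`.
#' @return A one-row tibble of class `sim_participant`.
#' @export
sim_participant <- function(A_true = 0.95, b_true = 0.2,
                            intercept_true = 24, slope_true = 0.93,
                            motor_noise_sd = 2, obs_sigma = 4,
                            obs_bias = 0, kappa = 1) {
  stopifnot(A_true >= 0, A_true <= 1, b_true >= 0, b_true <= 1,
            kappa >= 0, kappa <= 1, motor_noise_sd >= 0, obs_sigma >= 0)
  out <- tibble::tibble(A_true = A_true, b_true = b_true,
                        intercept_true = intercept_true,
                        slope_true = slope_true,
                        motor_noise_sd = motor_noise_sd,
                        obs_sigma = obs_sigma, obs_bias = obs_bias,
                        kappa = kappa)
  class(out) <- c("sim_participant", class(out))
  out
}

#' Define a cohort of simulated participants
#'
#' @param n Number of participants.
#' @param ... Passed to [sim_participant()]; vectors are recycled across
#'   participants.
#' @return A tibble with one row per participant and a `participant` id
#'   column.
#' @export
sim_cohort <- function(n, ...) {
  args <- list(...)
  rows <- lapply(seq_len(n), function(i) {
    a <- lapply(args, function(v) v[[((i - 1L) %% length(v)) + 1L]])
    do.call(sim_participant, a)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(participant = seq_len(n), .before = 1)
}

#' Simulate maximum grip apertures over a schedule
#'
#' Runs the state-space model in closed loop with its own noisy output:
#' `MGA_t = intercept + slope * (v_t + x_t) + eps_t`,
#' `eps_t ~ N(0, motor_noise_sd)`, and the state update uses the *noisy*
#' observed MGA in the error signal, so random grip errors propagate into the
#' next trial's correction — matching how the model is fitted to measured
#' MGAs. `x_1 = 0`.
#'
#' @param participant A [sim_participant()] (one row).
#' @param schedule A schedule tibble.
#' @param seed Integer seed (draws are deterministic given it).
#' @return The schedule tibble with added columns `state_x`, `mga_mm`.
#' @export
simulate_mgas <- function(participant, schedule, seed = 1L) {
  p <- as.list(participant[1, ])
  n <- nrow(schedule)
  eps <- if (p$motor_noise_sd > 0) {
    withr::with_seed(seed, rnorm(n, 0, p$motor_noise_sd))
  } else {
    numeric(n)
  }
  v <- schedule$v_mm; h <- schedule$h_mm
  x <- numeric(n); mga <- numeric(n)
  xt <- 0
  for (t in seq_len(n)) {
    x[t] <- xt
    mga[t] <- p$intercept_true + p$slope_true * (v[t] + xt) + eps[t]
    E <- mga[t] - (p$intercept_true + p$slope_true * h[t])
    xt <- p$A_true * xt - p$b_true * E
  }
  dplyr::mutate(schedule, state_x = x, mga_mm = mga)
}

#' Simulate 2AFC size judgments
#'
#' Applies the noisy-comparison observer (see [sim_participant()]) to trials
#' that carry the adaptation state: response is `"felt_larger"` iff
#' `h - (v + kappa * x) - obs_bias + eta > 0`.
#'
#' @param participant A [sim_participant()].
#' @param trials Tibble with columns `v_mm`, `h_mm`, `state_x` (e.g. the
#'   output of [simulate_mgas()]).
#' @param seed Integer seed.
#' @return `trials` with a `response` column
#'   (`"felt_larger"` / `"felt_smaller"`).
#' @export
simulate_responses <- function(participant, trials, seed = 1L) {
  p <- as.list(participant[1, ])
  n <- nrow(trials)
  eta <- if (p$obs_sigma > 0) {
    withr::with_seed(seed, rnorm(n, 0, p$obs_sigma))
  } else {
    numeric(n)
  }
  d <- trials$h_mm - (trials$v_mm + p$kappa * trials$state_x) -
    p$obs_bias + eta
  dplyr::mutate(trials,
                response = ifelse(d > 0, "felt_larger", "felt_smaller"))
}

#' Specify simulated motion capture
#'
#' @param sampling_rate Frames per second (200 pilot / 500 main).
#' @param duration Recorded duration in s (5 pilot / 3 main).
#' @param movement_time Reach duration in s.
#' @param mga_fraction Fraction of movement time at which the aperture peaks.
#' @param dropout_prob Per-frame, per-marker probability of a missing sample.
#' @param marker_noise_sd SD of additive Gaussian marker noise (mm).
#' @param lead_time Stationary time before movement onset (s).
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(sampling_rate = 500, duration = 3,
                            movement_time = 0.7, mga_fraction = 0.7,
                            dropout_prob = 0, marker_noise_sd = 0,
                            lead_time = 0.4) {
  stopifnot(mga_fraction > 0, mga_fraction < 1,
            dropout_prob >= 0, dropout_prob < 1,
            movement_time >= 0, duration > 0,
            lead_time + movement_time < duration)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 movement_time = movement_time, mga_fraction = mga_fraction,
                 dropout_prob = dropout_prob,
                 marker_noise_sd = marker_noise_sd, lead_time = lead_time),
            class = "trajectory_spec")
}

# Minimum-jerk position fraction s(tau) on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Grip-aperture profile (mm) at time u since movement onset.
#
# Opening: velocity ramps to V, holds, then decays linearly to zero at the
# peak, i.e. the aperture is an exact parabola over the final `w` seconds —
# wide enough (100 ms) that a 200-ms order-3 Savitzky-Golay window centred
# on the peak reproduces it exactly, so smoothing does not bias the MGA.
# Closing: velocity ramps from -V to -Vc and holds, with Vc chosen so the
# aperture reaches the object size exactly at movement end; the stop at
# contact is abrupt, as when real closure is truncated by the object. The
# closing speed stays well above segmentation thresholds, so the only slow
# aperture-velocity zone outside contact is the (momentary) one at the peak.
aperture_profile <- function(u, mt, mga, object_size, a_start,
                             mga_fraction, w = 0.1, wr = 0.05) {
  if (mt <= 0) return(rep(a_start, length(u)))
  tp <- mga_fraction * mt
  r1 <- 0.15 * tp
  w <- min(w, (tp - r1) / 2, (mt - tp) / 2)
  wr <- min(wr, (mt - tp) / 4)
  d_rise <- mga - a_start
  d_close <- mga - object_size
  stopifnot(d_rise > 0, d_close > 0)
  V <- d_rise / (tp - r1 / 2 - w / 2)
  c_cap <- V / (2 * w)                       # peak-cap curvature
  a1 <- mga - c_cap * w^2                    # aperture entering the close
  t1 <- tp + w
  # land on object_size at mt: ramp -V -> -Vc over wr, then constant -Vc
  Vc <- (d_close - c_cap * w^2 - wr * V / 2) / (mt - t1 - wr / 2)
  a <- numeric(length(u))
  for (i in seq_along(u)) {
    t <- u[i]
    a[i] <- if (t <= 0) {
      a_start
    } else if (t <= r1) {
      a_start + V * t^2 / (2 * r1)
    } else if (t <= tp - w) {
      a_start + V * r1 / 2 + V * (t - r1)
    } else if (t <= tp + w) {
      mga - c_cap * (t - tp)^2
    } else if (t <= t1 + wr) {
      a1 - V * (t - t1) - (Vc - V) * (t - t1)^2 / (2 * wr)
    } else {
      max(object_size,
          a1 - wr * (V + Vc) / 2 - Vc * (t - t1 - wr))
    }
  }
  a
}

#' Simulate a reach-to-grasp marker trajectory
#'
#' Constructs thumb, index, wrist and reference markers for one trial: the
#' thumb-index midpoint follows a minimum-jerk transport (zero velocity at
#' both ends) from the start position to the object centre over
#' `movement_time`; the inter-digit aperture opens to exactly `mga_mm` at
#' `mga_fraction` of movement time and closes onto `object_size_mm` at
#' movement end. Gaussian marker noise and random per-frame dropouts are
#' applied afterwards.
#'
#' @param spec A [trajectory_spec()].
#' @param mga_mm Programmed maximum grip aperture (mm); must exceed
#'   `object_size_mm`.
#' @param object_size_mm Felt-object length (mm).
#' @param object_position Numeric length-3, object centre in mm.
#' @param start_position Numeric length-3, midpoint start in mm.
#' @param a_start Aperture at rest (mm).
#' @param seed Integer seed for noise and dropouts.
#' @return A long tibble: `t_s`, `marker` (thumb/index/wrist/reference),
#'   `x_mm`, `y_mm`, `z_mm`; missing frames have `NA` coordinates. The
#'   sampling rate is recoverable from the time stamps.
#' @export
simulate_trajectory <- function(spec, mga_mm, object_size_mm,
                                object_position = c(0, 400, 0),
                                start_position = c(0, 0, 0),
                                a_start = 10, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (mga_mm <= object_size_mm)
    stop("invalid fixture: mga_mm (", mga_mm,
         ") must exceed object_size_mm (", object_size_mm, ")")
  dt <- 1 / spec$sampling_rate
  t_s <- seq(0, spec$duration, by = dt)
  u <- t_s - spec$lead_time                      # time since movement onset
  tau <- if (spec$movement_time > 0) u / spec$movement_time else rep(0, length(u))
  s <- min_jerk(tau)
  mid <- outer(s, object_position - start_position) +
    matrix(start_position, nrow = length(s), ncol = 3, byrow = TRUE)
  ap <- aperture_profile(u, spec$movement_time, mga_mm, object_size_mm,
                         a_start, spec$mga_fraction)
  lateral <- c(1, 0, 0)                          # aperture opens along x
  markers <- list(
    thumb = mid - outer(ap / 2, lateral),
    index = mid + outer(ap / 2, lateral),
    wrist = mid + matrix(c(0, -80, -30), nrow = length(s), ncol = 3,
                         byrow = TRUE),
    reference = matrix(object_position + c(0, 30, 0), nrow = length(s),
                       ncol = 3, byrow = TRUE)
  )
  noise_needed <- spec$marker_noise_sd > 0 || spec$dropout_prob > 0
  if (noise_needed) {
    withr::with_seed(seed, {
      for (m in names(markers)) {
        if (spec$marker_noise_sd > 0)
          markers[[m]] <- markers[[m]] +
            matrix(rnorm(length(markers[[m]]), 0, spec$marker_noise_sd),
                   ncol = 3)
        if (spec$dropout_prob > 0) {
          drop <- rbinom(length(s), 1, spec$dropout_prob) == 1
          markers[[m]][drop, ] <- NA_real_
        }
      }
    })
  }
  purrr::imap(markers, function(pos, nm)
    tibble::tibble(t_s = t_s, marker = nm,
                   x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3])) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$t_s, .data$marker)
}

#' Simulate a complete experiment
#'
#' Generates, for each participant of a cohort, the full 12-block design of
#' the chosen experiment: schedules via [enumerate_block_set()], MGAs via
#' [simulate_mgas()], and 2AFC responses via [simulate_responses()].
#' Optionally also generates a marker trajectory per trial realising the
#' simulated MGA (off by default: no analysis stage needs trajectories for a
#' full cohort, and they are large; the motion-capture pipeline is exercised
#' on small cohorts).
#'
#' @param cohort A [sim_cohort()] tibble (or single [sim_participant()]).
#' @param experiment `"main"` or `"pilot"`.
#' @param seed Master integer seed; all draws derive from it.
#' @param generate_trajectories Logical; also simulate marker trajectories.
#' @param trajectory_args List of overrides for [trajectory_spec()] /
#'   [simulate_trajectory()] (e.g. `dropout_prob`).
#' @return A list with `trials` (one row per trial: participant, block_id,
#'   schedule_kind, magnitude, trial, v_mm, h_mm, mismatch_mm, state_x,
#'   mga_mm, response), `trajectories` (named list of trajectory tibbles
#'   keyed `"p<participant>_b<block>_t<trial>"`; empty when not generated)
#'   and `manifest` (a tibble linking trials to trajectory keys).
#' @export
simulate_experiment <- function(cohort, experiment = c("main", "pilot"),
                                seed = 1L, generate_trajectories = FALSE,
                                trajectory_args = list()) {
  experiment <- match.arg(experiment)
  if (!"participant" %in% names(cohort))
    cohort <- dplyr::mutate(cohort, participant = dplyr::row_number(),
                            .before = 1)
  stopifnot(nrow(cohort) >= 1)
  specs <- enumerate_block_set(experiment)
  n_p <- nrow(cohort)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_p * length(specs) * 3L),
           nrow = n_p))

  tspec_args <- trajectory_args[names(trajectory_args) %in%
                                  names(formals(trajectory_spec))]
  if (experiment == "pilot" && !"sampling_rate" %in% names(tspec_args))
    tspec_args <- c(tspec_args, list(sampling_rate = 200, duration = 5))
  tspec <- do.call(trajectory_spec, tspec_args)

  trajectories <- list()
  all_trials <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    part <- cohort[i, ]
    blocks <- vector("list", length(specs))
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      s_seen <- seeds[i, 3L * (j - 1L) + 1L]
      s_mga <- seeds[i, 3L * (j - 1L) + 2L]
      s_resp <- seeds[i, 3L * (j - 1L) + 3L]
      fixed <- if (experiment == "pilot") sp$seen_sizes[(j %% 2L) + 1L] else NULL
      seen <- draw_seen_sequence(sp, seed = s_seen, fixed_size = fixed)
      sch <- make_schedule(sp, seen)
      sim <- simulate_mgas(part, sch, seed = s_mga)
      sim <- simulate_responses(part, sim, seed = s_resp)
      sim$block_id <- j
      blocks[[j]] <- sim
      if (generate_trajectories) {
        for (k in seq_len(nrow(sim))) {
          key <- sprintf("p%d_b%d_t%d", part$participant, j, k)
          trajectories[[key]] <- simulate_trajectory(
            tspec, mga_mm = sim$mga_mm[k], object_size_mm = sim$h_mm[k],
            seed = (s_mga + k) %% .Machine$integer.max)
        }
      }
    }
    all_trials[[i]] <- dplyr::bind_rows(blocks) |>
      dplyr::mutate(participant = part$participant, .before = 1)
  }
  trials <- dplyr::bind_rows(all_trials) |>
    dplyr::relocate("participant", "block_id")
  manifest <- trials |>
    dplyr::transmute(.data$participant, .data$block_id, .data$trial,
                     trajectory_key = sprintf("p%d_b%d_t%d",
                                              .data$participant,
                                              .data$block_id, .data$trial),
                     present = generate_trajectories)
  list(trials = trials, trajectories = trajectories, manifest = manifest)
}
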