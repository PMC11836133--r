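#' Sampling rate of a trajectory
#'
#' Inferred from the median spacing of the time stamps.
#'
#' @param traj A long trajectory tibble (`t_s`, `marker`, `x_mm`, `y_mm`,
#'   `z_mm`).
#' @return Sampling rate in Hz.
#' @export
traj_sampling_rate <- function(traj) {
  ts <- sort(unique(traj$t_s))
  1 / median(diff(ts))
}

# Long tibble -> list of per-marker n x 3 matrices on the common time grid
traj_matrices <- function(traj) {
  ts <- sort(unique(traj$t_s))
  out <- lapply(split(traj, traj$marker), function(d) {
    d <- d[match(ts, d$t_s), ]
    cbind(d$x_mm, d$y_mm, d$z_mm)
  })
  attr(out, "t_s") <- ts
  out
}

matrices_to_traj <- function(mats) {
  ts <- attr(mats, "t_s")
  purrr::imap(mats, function(m, nm)
    tibble::tibble(t_s = ts, marker = nm,
                   x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3])) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$t_s, .data$marker)
}

#' Fill missing motion-capture frames by cubic-spline interpolation
#'
#' Interior gaps in each marker coordinate are filled with a cubic spline
#' through the observed samples; observed samples are returned unchanged.
#' Leading and trailing missing frames are never extrapolated — they stay
#' missing (and count towards the missing-data exclusion rule).
#'
#' @param traj A long trajectory tibble; missing frames have `NA`
#'   coordinates.
#' @return `traj` with interior gaps filled and a logical `interpolated`
#'   column marking filled frames.
#' @export
interpolate_missing <- function(traj) {
  mats <- traj_matrices(traj)
  ts <- attr(mats, "t_s")
  interp <- setNames(vector("list", length(mats)), names(mats))
  for (m in names(mats)) {
    pos <- mats[[m]]
    miss_any <- rowSums(is.na(pos)) > 0
    obs <- which(!miss_any)
    if (length(obs) < 4L)
      stop("marker '", m, "': fewer than 4 observed frames; trial unusable")
    lo <- min(obs); hi <- max(obs)
    filled <- rep(FALSE, length(ts))
    for (j in 1:3) {
      na <- which(is.na(pos[, j]))
      inner <- na[na > lo & na < hi]
      if (length(inner)) {
        ok <- which(!is.na(pos[, j]))
        f <- splinefun(ts[ok], pos[ok, j], method = "fmm")
        pos[inner, j] <- f(ts[inner])
        filled[inner] <- TRUE
      }
    }
    mats[[m]] <- pos
    interp[[m]] <- filled
  }
  out <- matrices_to_traj(mats)
  imask <- tibble::tibble(
    t_s = rep(ts, length(interp)),
    marker = rep(names(interp), each = length(ts)),
    interpolated = unlist(interp, use.names = FALSE))
  dplyr::left_join(out, imask, by = c("t_s", "marker")) |>
    dplyr::arrange(.data$t_s, .data$marker)
}

#' Savitzky-Golay smoothing of marker positions
#'
#' Each coordinate of each marker is smoothed with a least-squares local
#' polynomial filter. The window length is `round(window_s * sampling_rate)`
#' frames, forced odd; default 200 ms, polynomial order 3 (a standard choice
#' for grasp kinematics). Constant and linear signals pass unchanged.
#' Leading/trailing missing frames are preserved; the observed run must be at
#' least as long as the window.
#'
#' @param traj A long trajectory tibble (interior gaps already filled).
#' @param window_s Window length in seconds.
#' @param poly_order Polynomial order of the local fit.
#' @return The smoothed trajectory tibble (extra columns such as
#'   `interpolated` are carried through).
#' @export
smooth_trajectory <- function(traj, window_s = 0.2, poly_order = 3) {
  rate <- traj_sampling_rate(traj)
  win <- round(window_s * rate)
  if (win %% 2 == 0) win <- win + 1L
  extra <- dplyr::select(traj, -dplyr::any_of(c("x_mm", "y_mm", "z_mm")))
  mats <- traj_matrices(traj)
  for (m in names(mats)) {
    pos <- mats[[m]]
    ok <- which(rowSums(is.na(pos)) == 0)
    if (!length(ok)) next
    lo <- min(ok); hi <- max(ok)
    if (hi - lo + 1L < win)
      stop("marker '", m, "': observed trace (", hi - lo + 1L,
           " frames) shorter than smoothing window (", win, " frames)")
    for (j in 1:3) {
      pos[lo:hi, j] <- signal::sgolayfilt(pos[lo:hi, j], p = poly_order,
                                          n = win)
    }
    mats[[m]] <- pos
  }
  dplyr::left_join(extra, matrices_to_traj(mats), by = c("t_s", "marker")) |>
    dplyr::arrange(.data$t_s, .data$marker)
}

# Central-difference velocity (rows of an n x k matrix or a vector), ends
# one-sided; NA-aware only at the boundaries of the observed run.
central_diff <- function(x, dt) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 2L) stop("need >= 2 frames for differentiation")
  idx_f <- c(2:n, n)
  idx_b <- c(1, 1:(n - 1))
  denom <- (idx_f - idx_b) * dt
  if (is.matrix(x)) (x[idx_f, , drop = FALSE] - x[idx_b, , drop = FALSE]) / denom
  else (x[idx_f] - x[idx_b]) / denom
}

marker_speed <- function(pos, dt) {
  v <- central_diff(pos, dt)
  sqrt(rowSums(v^2))
}

# First index at which `cond` is TRUE for `sustain` consecutive frames
first_sustained <- function(cond, sustain) {
  cond[is.na(cond)] <- FALSE
  if (sustain <= 1L) return(if (any(cond)) which(cond)[1L] else NA_integer_)
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= sustain)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Detect movement start from thumb and index speed
#'
#' First frame at which both thumb and index 3-D speed exceed the threshold
#' and remain above it for a sustain window (25 ms by default), suppressing
#' single-frame noise spikes. Velocities are central differences of the
#' (smoothed) positions.
#'
#' @param traj A smoothed trajectory tibble.
#' @param threshold Speed threshold in m/s (default 0.05).
#' @param sustain_s Sustain window in seconds.
#' @return Frame index on the trajectory's time grid.
#' @export
detect_movement_start <- function(traj, threshold = 0.05,
                                  sustain_s = 0.025) {
  mats <- traj_matrices(traj)
  dt <- 1 / traj_sampling_rate(traj)
  thr <- threshold * 1000                         # mm/s
  sp_t <- marker_speed(mats$thumb, dt)
  sp_i <- marker_speed(mats$index, dt)
  sustain <- max(1L, round(sustain_s / dt))
  idx <- first_sustained(sp_t > thr & sp_i > thr, sustain)
  if (is.na(idx))
    stop("no movement detected: speed criterion (", threshold,
         " m/s) never met")
  idx
}

#' Detect the touch event
#'
#' First frame after `start` at which the aperture speed (absolute rate of
#' change of the thumb-index distance) falls below the threshold while the
#' thumb-index midpoint is within `radius` of the object centre, sustained
#' for `sustain_s`. Thresholds default to the main-experiment values
#' (0.075 m/s, 150 mm); the pilot used 0.1 m/s and 300 mm. The sustain
#' window (250 ms by default) distinguishes the sustained stop at contact
#' from the momentary zero-crossing of aperture velocity around the MGA,
#' which after 200-ms smoothing can sit below threshold well past 100 ms.
#'
#' @param traj A smoothed trajectory tibble.
#' @param start Frame index of movement start.
#' @param object_center Numeric length-3, object centre (mm).
#' @param experiment `"main"` or `"pilot"`; sets the default thresholds.
#' @param threshold Aperture-speed threshold in m/s (overrides the
#'   experiment default).
#' @param radius Midpoint-to-object distance criterion in mm (overrides the
#'   experiment default).
#' @param sustain_s Sustain window in seconds.
#' @return Frame index of the touch event.
#' @export
detect_touch <- function(traj, start, object_center,
                         experiment = c("main", "pilot"),
                         threshold = NULL, radius = NULL,
                         sustain_s = 0.25) {
  experiment <- match.arg(experiment)
  threshold <- threshold %||% if (experiment == "main") 0.075 else 0.1
  radius <- radius %||% if (experiment == "main") 150 else 300
  mats <- traj_matrices(traj)
  dt <- 1 / traj_sampling_rate(traj)
  ap <- sqrt(rowSums((mats$thumb - mats$index)^2))
  ap_vel <- abs(central_diff(ap, dt))
  mid <- (mats$thumb + mats$index) / 2
  dist_obj <- sqrt(rowSums(
    (mid - matrix(object_center, nrow = nrow(mid), ncol = 3, byrow = TRUE))^2))
  cond <- ap_vel < threshold * 1000 & dist_obj < radius
  cond[seq_len(start)] <- FALSE
  sustain <- max(1L, round(sustain_s / dt))
  idx <- first_sustained(cond, sustain)
  if (is.na(idx))
    stop("no touch detected: aperture-velocity/position criterion never met")
  idx
}

#' Extract the maximum grip aperture
#'
#' Maximum thumb-index Euclidean distance over frames in `[start, touch)`;
#' the earliest frame wins ties.
#'
#' @param traj A trajectory tibble.
#' @param start,touch Frame indices from segmentation.
#' @return A list with `mga_mm` and `mga_index`.
#' @export
extract_mga <- function(traj, start, touch) {
  stopifnot(start < touch)
  mats <- traj_matrices(traj)
  ap <- sqrt(rowSums((mats$thumb - mats$index)^2))
  win <- start:(touch - 1L)
  i <- win[which.max(ap[win])]
  list(mga_mm = ap[i], mga_index = i)
}

#' Segment one trial: interpolate, smooth, detect start/touch, extract MGA
#'
#' Convenience wrapper running the full per-trial motion-capture pipeline.
#' The missing fraction counts frames between movement start and touch where
#' thumb or index was missing in the raw data; `mga_on_interpolated` flags an
#' MGA frame whose thumb or index position was spline-filled.
#'
#' @param traj A raw long trajectory tibble.
#' @param object_center Numeric length-3 (mm).
#' @param experiment `"main"` or `"pilot"`.
#' @param ... Passed on to [detect_touch()].
#' @return A one-row tibble: `start_index`, `touch_index`, `mga_mm`,
#'   `mga_index`, `movement_time_s`, `time_to_mga_s`, `missing_fraction`,
#'   `mga_on_interpolated`.
#' @export
segment_trajectory <- function(traj, object_center,
                               experiment = c("main", "pilot"), ...) {
  experiment <- match.arg(experiment)
  dt <- 1 / traj_sampling_rate(traj)
  raw <- traj_matrices(traj)
  filled <- interpolate_missing(traj)
  smoothed <- smooth_trajectory(filled)
  start <- detect_movement_start(smoothed)
  touch <- detect_touch(smoothed, start, object_center, experiment, ...)
  mga <- extract_mga(smoothed, start, touch)

  raw_missing <- rowSums(is.na(raw$thumb)) > 0 | rowSums(is.na(raw$index)) > 0
  win <- start:touch
  fmask <- filled |>
    dplyr::filter(.data$marker %in% c("thumb", "index")) |>
    dplyr::group_by(.data$t_s) |>
    dplyr::summarise(interp = any(.data$interpolated), .groups = "drop")
  tibble::tibble(
    start_index = start, touch_index = touch,
    mga_mm = mga$mga_mm, mga_index = mga$mga_index,
    movement_time_s = (touch - start) * dt,
    time_to_mga_s = (mga$mga_index - start) * dt,
    missing_fraction = mean(raw_missing[win]),
    mga_on_interpolated = fmask$interp[mga$mga_index])
}

#' Apply the four per-trial exclusion rules
#'
#' Flags each trial if (i) the MGA lay on a spline-interpolated stretch of
#' the trajectory, (ii) more than 20% of frames between movement start and
#' touch were missing, (iii) the MGA was implausibly small — smaller than the
#' felt (grasped) object length — or (iv) the MGA is an outlier, more than 3
#' interquartile ranges from the participant's median MGA for the same seen
#' and felt size. Rule (iv) is participant-relative and is skipped (with a
#' warning) in cells with fewer than 2 trials.
#'
#' @param results A tibble with columns `participant`, `v_mm`, `h_mm`,
#'   `mga_mm`, `mga_on_interpolated`, `missing_fraction`.
#' @param missing_limit Maximum tolerated missing fraction (default 0.2).
#' @param iqr_mult Outlier cut in interquartile ranges (default 3).
#' @return `results` with logical columns `mga_on_interpolated_flag`,
#'   `too_many_missing`, `mga_below_object`, `mga_outlier`, `excluded`.
#' @export
apply_exclusions <- function(results, missing_limit = 0.2, iqr_mult = 3) {
  small_cells <- results |>
    dplyr::count(.data$participant, .data$v_mm, .data$h_mm) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(small_cells))
    warning(nrow(small_cells),
            " (seen, felt) cell(s) with < 2 trials: outlier rule skipped there")
  results |>
    dplyr::group_by(.data$participant, .data$v_mm, .data$h_mm) |>
    dplyr::mutate(
      mga_outlier = dplyr::n() >= 2L &
        abs(.data$mga_mm - median(.data$mga_mm)) > iqr_mult * IQR(.data$mga_mm)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mga_on_interpolated_flag = .data$mga_on_interpolated,
      too_many_missing = .data$missing_fraction > missing_limit,
      mga_below_object = .data$mga_mm < .data$h_mm,
      excluded = .data$mga_on_interpolated_flag | .data$too_many_missing |
        .data$mga_below_object | .data$mga_outlier)
}
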