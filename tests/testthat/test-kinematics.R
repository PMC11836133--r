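# Shared noise-free fixture: one clean main-experiment reach
clean_traj <- function(mga = 80, obj = 40, ...) {
  simulate_trajectory(trajectory_spec(...), mga_mm = mga,
                      object_size_mm = obj)
}
OBJ_CENTER <- c(0, 400, 0)

test_that("interpolation fills interior gaps exactly on polynomial motion", {
  # cubic motion: an interpolating cubic spline must reproduce it exactly
  t <- seq(0, 1, by = 0.01)
  poly <- function(t) 5 + 3 * t - 2 * t^2 + 0.5 * t^3
  traj <- tidyr::expand_grid(t_s = t, marker = c("thumb", "index",
                                                 "wrist", "reference")) |>
    dplyr::mutate(x_mm = poly(.data$t_s), y_mm = 2 * poly(.data$t_s),
                  z_mm = 1)
  gap <- traj$marker == "thumb" & abs(traj$t_s - 0.5) < 1e-9
  traj_g <- traj
  traj_g[gap, c("x_mm", "y_mm", "z_mm")] <- NA
  out <- interpolate_missing(traj_g)
  filled <- dplyr::filter(out, .data$marker == "thumb",
                          abs(.data$t_s - 0.5) < 1e-9)
  expect_equal(filled$x_mm, poly(0.5), tolerance = 1e-9)
  expect_equal(filled$y_mm, 2 * poly(0.5), tolerance = 1e-9)
  expect_true(all(filled$interpolated))
  expect_equal(sum(out$interpolated), sum(gap))
  # untouched input comes back identical with an empty mask
  out0 <- interpolate_missing(traj)
  expect_equal(out0$x_mm, traj$x_mm)
  expect_false(any(out0$interpolated))
})

test_that("leading and trailing gaps are flagged missing, not extrapolated", {
  t <- seq(0, 1, by = 0.01)
  traj <- tidyr::expand_grid(t_s = t, marker = c("thumb", "index")) |>
    dplyr::mutate(x_mm = .data$t_s, y_mm = 0, z_mm = 0)
  lead <- traj$marker == "thumb" & traj$t_s < 0.03
  traj[lead, c("x_mm", "y_mm", "z_mm")] <- NA
  out <- interpolate_missing(traj)
  out_lead <- dplyr::filter(out, .data$marker == "thumb", .data$t_s < 0.03)
  expect_true(all(is.na(out_lead$x_mm)))
  expect_false(any(out_lead$interpolated))
  # an all-missing marker is unusable
  traj_bad <- traj
  traj_bad[traj_bad$marker == "index", c("x_mm", "y_mm", "z_mm")] <- NA
  expect_error(interpolate_missing(traj_bad), "unusable")
})

test_that("Savitzky-Golay smoothing preserves polynomials and attenuates noise", {
  t <- seq(0, 2, by = 0.002)
  base <- tidyr::expand_grid(marker = c("thumb", "index"), t_s = t)
  const <- dplyr::mutate(base, x_mm = 7, y_mm = -3, z_mm = 100)
  sm_const <- smooth_trajectory(const)
  expect_equal(sort(sm_const$x_mm), sort(const$x_mm), tolerance = 1e-9)
  ramp <- dplyr::mutate(base, x_mm = 10 * .data$t_s, y_mm = 0, z_mm = 0)
  sm_ramp <- smooth_trajectory(ramp)
  expect_equal(dplyr::arrange(sm_ramp, .data$marker, .data$t_s)$x_mm,
               dplyr::arrange(ramp, .data$marker, .data$t_s)$x_mm,
               tolerance = 1e-9)
  # noisy sine: residual variance to the clean signal must shrink
  clean <- sin(2 * pi * 1 * t)
  noisy <- clean + withr::with_seed(4, rnorm(length(t), 0, 0.3))
  nz <- dplyr::mutate(base, x_mm = rep(noisy, 2), y_mm = 0, z_mm = 0)
  sm <- smooth_trajectory(nz)
  v_in <- var(noisy - clean)
  v_out <- var(sm$x_mm[sm$marker == "thumb"] - clean)
  expect_lt(v_out, v_in / 2)
  # trace shorter than the window is refused
  short <- dplyr::filter(base, .data$t_s < 0.1) |>
    dplyr::mutate(x_mm = 1, y_mm = 1, z_mm = 1)
  expect_error(smooth_trajectory(short), "window")
})

test_that("movement start is found at the sustained speed crossing", {
  tr <- clean_traj()
  sm <- smooth_trajectory(interpolate_missing(tr))
  start <- detect_movement_start(sm)
  # ground truth: minimum-jerk speed crosses 0.05 m/s
  spec <- trajectory_spec()
  d <- 400
  tau <- seq(0, 1, by = 1e-4)
  speed <- 30 * tau^2 * (1 - tau)^2 * d / spec$movement_time
  t_cross <- spec$lead_time + tau[which(speed > 50)[1]] * spec$movement_time
  rate <- traj_sampling_rate(tr)
  expect_lt(abs((start - 1) / rate - t_cross), 0.025 + 2 / rate)
  # single-frame blips do not trigger: inject a one-frame jump pre-movement
  blip <- tr
  i <- which(blip$marker %in% c("thumb", "index") & blip$t_s == 0.1)
  blip$y_mm[i] <- blip$y_mm[i] + 5
  sm_b <- smooth_trajectory(interpolate_missing(blip))
  expect_equal(detect_movement_start(sm_b), start, tolerance = 3)
})

test_that("touch detection uses the experiment thresholds and conjunction", {
  tr <- clean_traj()
  sm <- smooth_trajectory(interpolate_missing(tr))
  start <- detect_movement_start(sm)
  touch <- detect_touch(sm, start, OBJ_CENTER, "main")
  spec <- trajectory_spec()
  rate <- traj_sampling_rate(tr)
  t_touch <- (touch - 1) / rate
  # the hand stops on the object at lead_time + movement_time
  expect_lt(abs(t_touch - (spec$lead_time + spec$movement_time)), 0.06)
  # decelerating far from the object must not trigger: an object centre
  # far away keeps the position criterion false until very late
  expect_error(detect_touch(sm, start, c(0, 2000, 0), "main"), "no touch")
  # pilot thresholds work on a pilot-rate trajectory
  trp <- clean_traj(mga = 75, obj = 44, sampling_rate = 200, duration = 5)
  smp <- smooth_trajectory(interpolate_missing(trp))
  sp2 <- detect_movement_start(smp)
  tp2 <- detect_touch(smp, sp2, OBJ_CENTER, "pilot")
  expect_gt(tp2, sp2)
})

test_that("MGA extraction recovers the programmed aperture on clean data", {
  for (mga in c(60, 75, 90)) {
    tr <- clean_traj(mga = mga)
    seg <- segment_trajectory(tr, OBJ_CENTER, "main")
    expect_lt(abs(seg$mga_mm - mga), 0.5)
    expect_equal(seg$missing_fraction, 0)
    expect_false(seg$mga_on_interpolated)
    expect_true(seg$start_index < seg$mga_index)
    expect_true(seg$mga_index <= seg$touch_index)
  }
})

test_that("MGA extraction tie-breaks to the earliest frame and respects bounds", {
  # monotone closing aperture: maximum sits at the first window frame
  t <- seq(0, 1, by = 0.002)
  ap <- 80 - 30 * t
  traj <- dplyr::bind_rows(
    tibble::tibble(t_s = t, marker = "thumb", x_mm = -ap / 2, y_mm = 0, z_mm = 0),
    tibble::tibble(t_s = t, marker = "index", x_mm = ap / 2, y_mm = 0, z_mm = 0))
  out <- extract_mga(traj, start = 10, touch = 200)
  expect_equal(out$mga_index, 10)
  expect_equal(out$mga_mm, ap[10])
  # two equal maxima -> earliest
  ap2 <- c(rep(50, 5), 60, 55, 60, rep(40, 5))
  t2 <- seq_along(ap2) * 0.01
  traj2 <- dplyr::bind_rows(
    tibble::tibble(t_s = t2, marker = "thumb", x_mm = -ap2 / 2, y_mm = 0, z_mm = 0),
    tibble::tibble(t_s = t2, marker = "index", x_mm = ap2 / 2, y_mm = 0, z_mm = 0))
  expect_equal(extract_mga(traj2, 1, 13)$mga_index, 6)
})

test_that("segmentation output is invariant to rigid translation", {
  tr <- clean_traj()
  shift <- c(123, -45, 67)
  tr2 <- dplyr::mutate(tr, x_mm = .data$x_mm + shift[1],
                       y_mm = .data$y_mm + shift[2],
                       z_mm = .data$z_mm + shift[3])
  s1 <- segment_trajectory(tr, OBJ_CENTER, "main")
  s2 <- segment_trajectory(tr2, OBJ_CENTER + shift, "main")
  expect_equal(s1$mga_mm, s2$mga_mm, tolerance = 1e-9)
  expect_equal(s1$start_index, s2$start_index)
  expect_equal(s1$touch_index, s2$touch_index)
})

test_that("each exclusion rule fires on its constructed violation", {
  base <- tibble::tibble(
    participant = 1L, v_mm = 40, h_mm = 40,
    mga_mm = c(74, 75, 76, 75, 74, 75),
    mga_on_interpolated = FALSE, missing_fraction = 0)

  # (i) MGA on an interpolated stretch
  r1 <- base; r1$mga_on_interpolated[1] <- TRUE
  f1 <- apply_exclusions(r1)
  expect_true(f1$excluded[1]); expect_false(any(f1$excluded[-1]))

  # (ii) > 20% missing frames
  r2 <- base; r2$missing_fraction[2] <- 0.25
  f2 <- apply_exclusions(r2)
  expect_true(f2$too_many_missing[2]); expect_true(f2$excluded[2])
  expect_false(apply_exclusions(base)$too_many_missing[2])

  # (iii) MGA below the felt object length
  r3 <- base; r3$mga_mm[3] <- 38; r3$h_mm <- 40
  f3 <- apply_exclusions(r3)
  expect_true(f3$mga_below_object[3])

  # (iv) outlier beyond 3 IQRs from the cell median
  mgas <- c(73, 74, 75, 76, 77, 95)
  r4 <- tibble::tibble(participant = 1L, v_mm = 40, h_mm = 40,
                       mga_mm = mgas, mga_on_interpolated = FALSE,
                       missing_fraction = 0)
  cut <- median(mgas) + 3 * IQR(mgas)
  expect_gt(95, cut)
  f4 <- apply_exclusions(r4)
  expect_true(f4$mga_outlier[6])
  expect_false(any(f4$mga_outlier[1:5]))
  expect_equal(f4$excluded,
               f4$mga_on_interpolated_flag | f4$too_many_missing |
                 f4$mga_below_object | f4$mga_outlier)

  # single-trial cells skip the outlier rule with a warning
  r5 <- base[1:2, ]; r5$h_mm <- c(40, 44)
  expect_warning(f5 <- apply_exclusions(r5), "cell")
  expect_false(any(f5$mga_outlier))
})

test_that("heavy dropout in the movement window trips the missing-data rule", {
  tr <- simulate_trajectory(trajectory_spec(dropout_prob = 0.25),
                            mga_mm = 80, object_size_mm = 40, seed = 12)
  seg <- segment_trajectory(tr, OBJ_CENTER, "main")
  expect_gt(seg$missing_fraction, 0.2)
  res <- dplyr::bind_cols(
    tibble::tibble(participant = 1L, v_mm = 40, h_mm = 40), seg["mga_mm"],
    seg["mga_on_interpolated"], seg["missing_fraction"])
  expect_warning(flags <- apply_exclusions(res), "cell")
  expect_true(flags$too_many_missing[1])
  expect_true(flags$excluded[1])
})

test_that("noise-free pipeline over simulated trials excludes nothing", {
  p <- sim_participant(motor_noise_sd = 0)
  sch <- make_abrupt_schedule(schedule_spec("abrupt", magnitude = -12),
                              rep(44, 24))
  trials <- simulate_mgas(p, sch)[1:8, ] |>
    dplyr::mutate(participant = 1L)
  tsp <- trajectory_spec()
  segs <- purrr::map_dfr(seq_len(nrow(trials)), function(k) {
    tr <- simulate_trajectory(tsp, mga_mm = trials$mga_mm[k],
                              object_size_mm = trials$h_mm[k])
    segment_trajectory(tr, OBJ_CENTER, "main")
  })
  expect_true(all(abs(segs$mga_mm - trials$mga_mm) < 0.5))
  res <- dplyr::bind_cols(
    dplyr::select(trials, "participant", "v_mm", "h_mm"),
    dplyr::select(segs, "mga_mm", "mga_on_interpolated", "missing_fraction"))
  flags <- suppressWarnings(apply_exclusions(res))
  expect_equal(sum(flags$excluded), 0)
})
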