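#' Detect per-foot gait events from foot angular velocity
#'
#' Initial Contact (IC) and Final Contact (FC) are located on each foot's
#' mediolateral angular velocity: the signal is low-pass filtered (4th-order
#' Butterworth, 10 Hz cutoff, zero-phase), swings appear as prominent
#' positive lobes (prominence at least 50 deg/s, with an adaptive fallback
#' at 0.4 times the signal maximum for degraded gait), and each swing is
#' bounded by the last local minimum before its peak (FC) and the first
#' local minimum after it (IC). Swing peaks closer than 0.2 s are merged,
#' keeping the more prominent one.
#'
#' @param trial An [imu_trial()].
#' @return A tibble of class `gait_events` with one row per detected swing:
#'   columns `foot` (`"left"`/`"right"`), `fc` and `ic` (seconds).
#' @export
detect_gait_events <- function(trial) {
  stopifnot(inherits(trial, "imu_trial"))
  fs <- trial$sample_rate
  out <- lapply(c(left = "left_foot", right = "right_foot"), function(site) {
    s <- trial_stream(trial, site)
    x <- lowpass(s$gyr_ML, fs, 10)
    prom_floor <- 50
    peaks <- find_peaks(x, prom_floor, min_dist = round(0.2 * fs))
    if (length(peaks) == 0) {
      adaptive <- 0.4 * max(x)
      if (adaptive > 0) {
        peaks <- find_peaks(x, adaptive, min_dist = round(0.2 * fs))
      }
    }
    if (length(peaks) < 4) {
      abort(sprintf("insufficient gait: %d swing(s) detected on %s",
                    length(peaks), site))
    }
    mins <- local_minima(x)
    fc <- ic <- rep(NA_real_, length(peaks))
    for (k in seq_along(peaks)) {
      before <- mins[mins < peaks[k]]
      after <- mins[mins > peaks[k]]
      if (length(before) > 0) fc[k] <- s$t[max(before)]
      if (length(after) > 0) ic[k] <- s$t[min(after)]
    }
    keep <- !is.na(fc) & !is.na(ic)
    tibble(foot = sub("_foot", "", site), fc = fc[keep], ic = ic[keep])
  })
  ev <- bind_rows(out) |> arrange(.data$foot, .data$ic)
  # enforce strictly increasing, alternating FC -> IC within each foot
  ev <- ev |>
    group_by(.data$foot) |>
    dplyr::filter(.data$fc < .data$ic,
                  is.na(dplyr::lag(.data$ic)) | .data$fc > dplyr::lag(.data$ic)) |>
    ungroup()
  for (f in c("left", "right")) {
    if (sum(ev$foot == f) < 4) {
      abort(sprintf("insufficient gait: fewer than 4 strides on %s foot", f))
    }
  }
  structure(ev, class = c("gait_events", class(ev)))
}

#' Detect the U-turn from the trunk craniocaudal angular velocity
#'
#' The trunk craniocaudal angular velocity is integrated (trapezoidal rule)
#' into an angular position trace. A linear drift is removed by assuming the
#' walker faces 0 deg before the turn and ±180 deg after it: the drift line
#' is fitted jointly on the pre- and post-turn plateaus. Turn boundaries are
#' the shoulder points where the smoothed (1 Hz low-pass) angular velocity
#' leaves, respectively re-enters, 2% of its turn peak, which places them
#' where the angle trace leaves its plateaus. Left turns (-180 deg) are
#' folded so the corrected trace always ends near +180.
#'
#' @param trial An [imu_trial()].
#' @return A list of class `uturn_interval` with elements `start`, `end`
#'   (seconds), `angle` (tibble `t`, `angle_deg`: the drift-corrected,
#'   sign-folded trace) and `direction` (`"right"` or `"left"`).
#' @export
detect_uturn <- function(trial) {
  stopifnot(inherits(trial, "imu_trial"))
  fs <- trial$sample_rate
  s <- trial_stream(trial, "lower_back")
  g <- s$gyr_CC
  t <- s$t
  theta_raw <- cumtrapz_int(t, g)

  w <- lowpass(g, fs, 1)
  ipk <- which.max(abs(w))
  dir_sign <- sign(w[ipk])
  if (dir_sign == 0) abort("no U-turn: flat angular velocity")
  ws <- dir_sign * w
  thr <- 0.02 * ws[ipk]
  above <- ws >= thr
  # walk outward from the peak, tolerating sub-threshold dips shorter than
  # 0.2 s (noise riding on the shoulder)
  tol <- round(0.2 * fs)
  n <- length(t)
  walk <- function(from, step) {
    i <- from
    repeat {
      j <- i + step
      if (j < 1 || j > n) break
      if (above[j]) {
        i <- j
      } else {
        run <- j
        while (run + step >= 1 && run + step <= n && !above[run + step] &&
                 abs(run - j) < tol) run <- run + step
        if (run + step >= 1 && run + step <= n && above[run + step] &&
              abs(run - j) < tol) i <- run + step else break
      }
    }
    i
  }
  i0 <- walk(ipk, -1L)
  i1 <- walk(ipk, 1L)

  # Before assuming a 0 -> 180 transition, verify a half revolution exists:
  # detrend by the drift estimated on the pre-turn plateau alone.
  guard <- round(0.2 * fs)
  pre <- seq_len(max(i0 - guard, 2))
  post <- seq(min(i1 + guard, n - 1), n)
  pre_fit <- stats::lm.fit(cbind(1, t[pre]), theta_raw[pre])
  theta_detr <- theta_raw - pre_fit$coefficients[1] -
    pre_fit$coefficients[2] * t
  if (max(abs(theta_detr)) < 120) {
    abort("no U-turn: maximal angular displacement below 120 deg")
  }

  # joint drift fit on the plateaus (0 deg before, 180*sign after)
  idx <- c(pre, post)
  target <- c(rep(0, length(pre)), rep(180 * dir_sign, length(post)))
  fit <- stats::lm.fit(cbind(1, t[idx]), theta_raw[idx] - target)
  theta_c <- dir_sign * (theta_raw - fit$coefficients[1] -
                           fit$coefficients[2] * t)

  if (max(abs(theta_c)) < 120) {
    abort("no U-turn: maximal angular displacement below 120 deg")
  }
  structure(list(
    start = t[i0], end = t[i1],
    angle = tibble(t = t, angle_deg = theta_c),
    direction = if (dir_sign > 0) "right" else "left"
  ), class = "uturn_interval")
}

#' @export
print.uturn_interval <- function(x, ...) {
  cat(sprintf("<uturn_interval> %.2f - %.2f s (%.1f s, %s turn)\n",
              x$start, x$end, x$end - x$start, x$direction))
  invisible(x)
}

#' Assemble the valid-stride segmentation of a trial
#'
#' Combines detected gait events and the U-turn into the segmentation used
#' by every gait parameter: valid strides (outside the U-turn, after the
#' initiation stride of each foot), merged step events, and the straight
#' walking windows that additionally exclude the terminal stride (used for
#' trunk-signal measures).
#'
#' @param events A `gait_events` tibble from [detect_gait_events()].
#' @param uturn A `uturn_interval` from [detect_uturn()].
#' @param trial_span Numeric `c(start, end)` of the trial in seconds.
#' @return A list of class `trial_segmentation`: `uturn`, `events`,
#'   `strides` (tibble `foot`, `ic_start`, `ic_end`), `steps` (sorted IC
#'   times of both feet outside the turn), `straight_windows` (tibble
#'   `start`, `end`) and `swings` (tibble `foot`, `fc`, `ic` of valid
#'   swings).
#' @export
segment_trial <- function(events, uturn, trial_span) {
  stopifnot(inherits(uturn, "uturn_interval"), length(trial_span) == 2)
  span <- trial_span[2] - trial_span[1]
  if ((uturn$end - uturn$start) > 0.8 * span) {
    abort("degenerate segmentation: U-turn covers more than 80% of the trial")
  }
  in_turn <- function(a, b) pmax(a, uturn$start) < pmin(b, uturn$end)

  strides <- events |>
    group_by(.data$foot) |>
    mutate(ic_start = .data$ic, ic_end = dplyr::lead(.data$ic),
           rank = dplyr::row_number()) |>
    ungroup() |>
    dplyr::filter(!is.na(.data$ic_end), .data$rank > 1,
                  !in_turn(.data$ic_start, .data$ic_end)) |>
    select("foot", "ic_start", "ic_end") |>
    arrange(.data$ic_start)
  if (nrow(strides) == 0) {
    abort("degenerate segmentation: no valid stride outside the U-turn")
  }

  steps <- sort(events$ic[events$ic < uturn$start | events$ic > uturn$end])
  if (length(steps) < 4) {
    abort("degenerate segmentation: fewer than 4 steps outside the U-turn")
  }

  # swings surviving the same exclusions (initiation swing dropped per foot)
  swings <- events |>
    group_by(.data$foot) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    dplyr::filter(.data$rank > 1, !in_turn(.data$fc, .data$ic)) |>
    select("foot", "fc", "ic")

  # straight windows: exclude turn, initiation stride and terminal stride
  init_end <- events |>
    group_by(.data$foot) |>
    summarise(second = dplyr::nth(.data$ic, 2), .groups = "drop")
  w1_start <- max(init_end$second)
  term_start <- events |>
    group_by(.data$foot) |>
    summarise(penult = dplyr::nth(.data$ic, -2L), .groups = "drop")
  w2_end <- min(term_start$penult)
  windows <- tibble(start = c(w1_start, uturn$end),
                    end = c(uturn$start, w2_end)) |>
    dplyr::filter(.data$end > .data$start)
  if (nrow(windows) < 2) {
    warn("only one straight-walking window available")
  }
  if (nrow(windows) == 0) {
    abort("degenerate segmentation: no straight-walking window")
  }

  structure(list(uturn = uturn, events = events, strides = strides,
                 steps = steps, straight_windows = windows, swings = swings),
            class = "trial_segmentation")
}

#' @export
print.trial_segmentation <- function(x, ...) {
  cat(sprintf(
    "<trial_segmentation> %d valid strides, %d steps, U-turn %.2f-%.2f s, %d window(s)\n",
    nrow(x$strides), length(x$steps), x$uturn$start, x$uturn$end,
    nrow(x$straight_windows)))
  invisible(x)
}

#' Run event detection, U-turn detection and segmentation on a trial
#'
#' @param trial An [imu_trial()].
#' @return A `trial_segmentation` (see [segment_trial()]).
#' @export
segment_imu_trial <- function(trial) {
  events <- detect_gait_events(trial)
  uturn <- detect_uturn(trial)
  ts <- trial_stream(trial, "lower_back")$t
  segment_trial(events, uturn, range(ts))
}

#' Export gait events as a delimited file
#'
#' Writes the three-column event table `time_s, foot, event_type` (IC|FC).
#'
#' @param events A `gait_events` tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gait_events <- function(events, path) {
  long <- bind_rows(
    tibble(time_s = events$fc, foot = events$foot, event_type = "FC"),
    tibble(time_s = events$ic, foot = events$foot, event_type = "IC")
  ) |> arrange(.data$time_s)
  readr::write_csv(long, path)
  invisible(path)
}
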