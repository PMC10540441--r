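#' Specification of a synthetic walker
#'
#' Describes the out-and-back 10-m walking trial emitted by
#' [generate_trial()]: two straight bouts separated by a half-revolution
#' U-turn, with per-cycle stride-time noise, asymmetric swing times, a
#' stride-locked trunk harmonic series and an impulsive foot signature at
#' each gait event. The defaults emulate a healthy adult whose gait
#' parameters sit at the packaged normative reference means (stride time
#' 1.10 s, step length 0.68 m, double stance 23.34% of the cycle, swing-time
#' ratio 0.96, trunk ML RMS 1.28 m/s², U-turn 2.62 s over a 20-m path).
#'
#' @param stride_time_s Mean stride (cycle) duration in seconds.
#' @param stride_time_cv Coefficient of variation of the per-cycle stride
#'   time (fraction, e.g. 0.0234 for 2.34%).
#' @param step_length_m Commanded step length in metres; together with
#'   `path_length_m` it fixes the number of steps on the path.
#' @param double_stance_fraction Total double-support time as a fraction of
#'   the gait cycle (both periods summed), in (0, 0.5).
#' @param swing_asymmetry Target ratio of the shorter to the longer mean
#'   swing time, in (0, 1].
#' @param amplitude_asymmetry Ratio of left to right foot swing-pulse
#'   amplitude (1 = symmetric).
#' @param trunk_ml_rms_target Target RMS of the trunk mediolateral
#'   acceleration in m/s².
#' @param smoothness_noise Amplitude (m/s²) of an 8-Hz intermittency
#'   component added to the trunk AP acceleration; raises jerk and lowers
#'   the smoothness indices.
#' @param uturn_duration_s Duration of the U-turn rotation in seconds.
#' @param turn_direction `"right"` (+180°) or `"left"` (-180°).
#' @param gyro_drift_dps Constant additive drift on the trunk craniocaudal
#'   gyroscope in deg/s (emulates an uncalibrated rate offset).
#' @param path_length_m Total walked path in metres (default 20: 10 m out
#'   and 10 m back).
#' @param sample_rate Sampling frequency in Hz.
#' @param seed Integer seed; fixes the whole trial bit-exactly.
#'
#' @return A list of class `walker_spec`.
#' @export
walker_spec <- function(stride_time_s = 1.10,
                        stride_time_cv = 0.0234,
                        step_length_m = 0.68,
                        double_stance_fraction = 0.2334,
                        swing_asymmetry = 0.96,
                        amplitude_asymmetry = 1,
                        trunk_ml_rms_target = 1.28,
                        smoothness_noise = 0.10,
                        uturn_duration_s = 2.62,
                        turn_direction = c("right", "left"),
                        gyro_drift_dps = 0,
                        path_length_m = 20,
                        sample_rate = 100,
                        seed = 1L) {
  turn_direction <- match.arg(turn_direction)
  spec <- list(
    stride_time_s = stride_time_s, stride_time_cv = stride_time_cv,
    step_length_m = step_length_m,
    double_stance_fraction = double_stance_fraction,
    swing_asymmetry = swing_asymmetry,
    amplitude_asymmetry = amplitude_asymmetry,
    trunk_ml_rms_target = trunk_ml_rms_target,
    smoothness_noise = smoothness_noise,
    uturn_duration_s = uturn_duration_s,
    turn_direction = turn_direction,
    gyro_drift_dps = gyro_drift_dps,
    path_length_m = path_length_m,
    sample_rate = sample_rate,
    seed = as.integer(seed)
  )
  validate_walker_spec(spec)
  structure(spec, class = "walker_spec")
}

validate_walker_spec <- function(s) {
  stopifnot(s$stride_time_s > 0, s$stride_time_cv >= 0,
            s$step_length_m > 0, s$path_length_m > 0,
            s$sample_rate > 0, s$uturn_duration_s > 0)
  if (s$double_stance_fraction <= 0 || s$double_stance_fraction >= 0.5) {
    abort("double_stance_fraction must lie in (0, 0.5)")
  }
  if (s$swing_asymmetry <= 0 || s$swing_asymmetry > 1) {
    abort("swing_asymmetry must lie in (0, 1]")
  }
  # Both swings plus both double supports must fit in one cycle.
  sw_total <- 1 - s$double_stance_fraction
  if (sw_total <= 0) abort("infeasible spec: double stance and swings exceed the cycle")
  invisible(s)
}

#' Generate a synthetic three-sensor walking trial with ground truth
#'
#' Emits an [imu_trial()] whose signals encode the walker described by
#' `spec`, together with the exact event times and realized series used to
#' construct them. Foot mediolateral angular velocity carries one smooth
#' raised-cosine swing lobe per stride flanked by sharp negative dips at
#' Final and Initial Contact; foot acceleration carries a damped 15-Hz
#' impact transient at each Initial Contact; the trunk carries a
#' stride-locked harmonic series on all three acceleration axes (even
#' harmonics dominant on AP/CC, odd on ML), periodic angular velocity, and
#' on the craniocaudal gyroscope a raised-cosine turn pulse integrating to
#' ±180° plus an optional constant drift.
#'
#' @param spec A [walker_spec()].
#' @return A list with elements `trial` (the [imu_trial()]) and `truth`, a
#'   list holding `events` (tibble `foot`, `ic`, `fc`), `uturn`
#'   (`c(start, end)` in s), `stride_times`, `double_stance` (per-cycle %
#'   series), `swing_times` (per foot), `n_steps` (on the path, outside the
#'   turn) and `targets` (commanded parameter values where defined).
#' @export
#' @examples
#' g <- generate_trial(walker_spec(seed = 42))
#' g$truth$uturn
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "walker_spec"))
  rng_seed <- string_seed("trial", spec$seed)
  withr_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(withr_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", withr_seed, envir = globalenv())
  })
  set.seed(rng_seed)

  fs <- spec$sample_rate
  T0 <- spec$stride_time_s
  step0 <- T0 / 2
  lead_in <- 1.6

  # -- event schedule ------------------------------------------------------
  n_steps <- max(8L, 2L * round(spec$path_length_m / spec$step_length_m / 2))
  n_cycles <- n_steps %/% 2L
  c1 <- n_cycles %/% 2L          # cycles before the turn
  c2 <- n_cycles - c1            # cycles after the turn

  sw_frac_total <- 1 - spec$double_stance_fraction
  r <- spec$swing_asymmetry
  sw_frac <- c(left = sw_frac_total * r / (1 + r),
               right = sw_frac_total / (1 + r))
  fc_jitter <- 0.010             # s; puts double-stance CV near its norm

  # Per-cycle durations; cycle i spans left IC i .. left IC i+1. The cycle
  # bridging the turn is replaced by the turn gap.
  Tc_all <- T0 * (1 + spec$stride_time_cv * stats::rnorm(n_cycles))
  Tc_all <- pmax(Tc_all, 0.4 * T0)

  left_ic <- numeric(n_cycles)
  left_ic[1] <- lead_in
  for (i in seq_len(c1 - 1)) left_ic[i + 1] <- left_ic[i] + Tc_all[i]
  right_ic <- left_ic + step0    # provisional; completed after the turn gap
  turn_start <- left_ic[c1] + step0 + 0.20
  turn_end <- turn_start + spec$uturn_duration_s
  left_ic[c1 + 1] <- turn_end + 0.25 + sw_frac[["left"]] * T0
  for (i in (c1 + 1):(n_cycles - 1)) left_ic[i + 1] <- left_ic[i] + Tc_all[i]
  right_ic <- left_ic + step0
  n_all <- n_cycles

  # Swing-aligned FCs: fc[j] is the Final Contact opening the swing that
  # lands at ic[j]; swing duration scales with the enclosing cycle.
  swing_dur <- function(j, foot) {
    Tloc <- if (j <= 1 || j == c1 + 1) T0 else Tc_all[j - 1]
    sw_frac[[foot]] * Tloc + fc_jitter * stats::rnorm(1)
  }
  left_fc <- vapply(seq_len(n_all), function(j) {
    left_ic[j] - swing_dur(j, "left")
  }, numeric(1))
  right_fc <- vapply(seq_len(n_all), function(j) {
    right_ic[j] - swing_dur(j, "right")
  }, numeric(1))

  events <- bind_rows(
    tibble(foot = "left", fc = left_fc, ic = left_ic),
    tibble(foot = "right", fc = right_fc, ic = right_ic)
  )

  t_end <- max(right_ic) + 1.6
  t <- seq(0, t_end, by = 1 / fs)
  n <- length(t)

  # -- foot signals --------------------------------------------------------
  raised_cos <- function(t, center, width) {
    u <- (t - center) / width
    ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  }
  # Swing rotation lobe kept clear of the contact dips (rotation peaks
  # mid-swing; brief plateaus follow toe-off and precede landing) so the
  # filtered local minima stay centred on FC and IC.
  swing_lobe <- function(t, fc, ic) {
    inset <- min(0.15 * (ic - fc), 0.06)
    a <- fc + inset
    b <- ic - inset
    u <- (t - a) / (b - a)
    ifelse(u > 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  }
  foot_gyr_ml <- function(ics, fcs, amp) {
    g <- stats::rnorm(n, sd = 3)
    for (i in seq_along(fcs)) {
      g <- g + amp * swing_lobe(t, fcs[i], ics[i]) -
        25 * raised_cos(t, fcs[i], 0.12) -
        25 * raised_cos(t, ics[i], 0.12)
    }
    g
  }
  foot_acc_cc <- function(ics) {
    a <- stats::rnorm(n, sd = 0.3) + 9.81
    for (ic in ics) {
      dt <- t - ic
      hit <- dt >= 0 & dt < 0.3
      a[hit] <- a[hit] + 3 * exp(-20 * dt[hit]) * sin(2 * pi * 15 * dt[hit])
    }
    a
  }
  amp_l <- 250 * spec$amplitude_asymmetry
  amp_r <- 250
  lf_gyr_ml <- foot_gyr_ml(left_ic, left_fc, amp_l)
  rf_gyr_ml <- foot_gyr_ml(right_ic, right_fc, amp_r)

  # -- trunk signals -------------------------------------------------------
  # Gait phase: 2*pi per cycle, anchored at the left ICs, frozen during the
  # turn gap only in the sense that no cycles are scheduled there.
  phase <- approx(left_ic, 2 * pi * (seq_len(n_all) - 1), xout = t,
                  rule = 2)$y
  # extend with the mean cadence outside the anchored range
  before <- t < left_ic[1]
  after <- t > left_ic[n_all]
  phase[before] <- 2 * pi * (t[before] - left_ic[1]) / T0
  phase[after] <- 2 * pi * (n_all - 1) + 2 * pi * (t[after] - left_ic[n_all]) / T0

  acc_cc <- 1.5 * cos(2 * phase) + 0.5 * cos(4 * phase + 0.8) +
    0.10 * cos(phase + 0.2) + 0.05 * cos(3 * phase + 1.1) +
    stats::rnorm(n, sd = 0.53)
  acc_ap <- 1.0 * cos(2 * phase + 0.3) + 0.2 * cos(4 * phase + 0.9) +
    0.05 * cos(phase) + stats::rnorm(n, sd = 0.15) +
    spec$smoothness_noise * cos(2 * pi * 8 * t + 0.7)
  ml_det_rms2 <- max(spec$trunk_ml_rms_target^2 - 0.2^2, 1e-6)
  a1 <- sqrt(2 * ml_det_rms2 / (1 + 0.25^2 + 0.06^2))
  acc_ml <- a1 * cos(phase + 1.0) + 0.25 * a1 * cos(3 * phase + 0.4) +
    0.06 * a1 * cos(2 * phase + 0.9) + stats::rnorm(n, sd = 0.2)

  turn_sign <- if (spec$turn_direction == "right") 1 else -1
  pulse <- raised_cos(t, (turn_start + turn_end) / 2, spec$uturn_duration_s)
  pulse_amp <- 180 / (spec$uturn_duration_s / 2)
  gyr_cc <- turn_sign * pulse_amp * pulse + spec$gyro_drift_dps +
    8 * cos(2 * phase + 0.5) + stats::rnorm(n, sd = 1)
  gyr_ap <- 20 * cos(phase + 0.5) + stats::rnorm(n, sd = 2)
  gyr_ml <- 30 * cos(2 * phase + 1.2) + stats::rnorm(n, sd = 2)

  zero <- stats::rnorm(n, sd = 0.2)
  mk <- function(site, acc_AP, acc_ML, acc_CC, gyr_AP, gyr_ML, gyr_CC) {
    tibble(t = t, site = site, acc_AP = acc_AP, acc_ML = acc_ML,
           acc_CC = acc_CC, gyr_AP = gyr_AP, gyr_ML = gyr_ML, gyr_CC = gyr_CC)
  }
  data <- bind_rows(
    mk("left_foot", zero + 0.5, stats::rnorm(n, sd = 0.3),
       foot_acc_cc(left_ic), stats::rnorm(n, sd = 2), lf_gyr_ml,
       stats::rnorm(n, sd = 2)),
    mk("right_foot", zero - 0.2, stats::rnorm(n, sd = 0.3),
       foot_acc_cc(right_ic), stats::rnorm(n, sd = 2), rf_gyr_ml,
       stats::rnorm(n, sd = 2)),
    mk("lower_back", acc_ap, acc_ml, acc_cc, gyr_ap, gyr_ml, gyr_cc)
  )

  trial <- imu_trial(data, sample_rate = fs,
                     meta = list(generator = "synthetic-walker",
                                 seed = spec$seed))

  # -- ground truth --------------------------------------------------------
  # cycle indices that do not bridge the turn
  in_bout <- setdiff(seq_len(n_all - 1), c1)
  stride_times <- c(diff(left_ic)[in_bout], diff(right_ic)[in_bout])

  # per-cycle double-stance percentage (cycle i: left IC i .. left IC i+1)
  dst <- vapply(in_bout, function(i) {
    ds1 <- right_fc[i] - left_ic[i]        # right FC follows left IC
    ds2 <- left_fc[i + 1] - right_ic[i]    # left FC follows right IC
    100 * (ds1 + ds2) / (left_ic[i + 1] - left_ic[i])
  }, numeric(1))

  swings <- list(
    left = (left_ic - left_fc)[in_bout + 1L],
    right = (right_ic - right_fc)[in_bout + 1L]
  )
  mean_sw <- vapply(swings, mean, numeric(1))

  truth <- list(
    events = events,
    uturn = c(start = turn_start, end = turn_end),
    stride_times = stride_times,
    double_stance = dst,
    swing_times = swings,
    n_steps = n_steps,
    targets = tibble(
      V = spec$path_length_m /
        (max(right_ic) - min(left_fc) - spec$uturn_duration_s),
      StrT = mean(stride_times),
      UtrT = spec$uturn_duration_s,
      CV_StrT = 100 * sd(stride_times) / mean(stride_times),
      SteL = spec$path_length_m / n_steps,
      dstT = mean(dst),
      swTr = min(mean_sw) / max(mean_sw),
      RMS_aML = spec$trunk_ml_rms_target
    )
  )
  list(trial = trial, truth = truth)
}

#' Generate a labelled cohort of synthetic trials
#'
#' Mirrors a longitudinal test-retest design: each subject is measured at
#' each session with `trials_per_session` repeated trials. Trials are
#' deterministic functions of `(seed, subject, session, trial)`, so any
#' subset can be regenerated independently. `between_sd` perturbs each
#' subject's mean stride time and step length (stable across sessions);
#' `within_sd` perturbs them again per trial.
#'
#' @param specs Either a single [walker_spec()] used as the population
#'   template, or a list with one spec per subject.
#' @param n_subjects Number of subjects (ignored when `specs` is a list).
#' @param trials_per_session,sessions Repeats per visit and number of visits.
#' @param between_sd,within_sd Relative between-subject and within-trial
#'   perturbation of stride time and step length (fractions).
#' @param seed Cohort-level integer seed.
#' @return Tibble with columns `subject`, `session`, `trial`, `spec`
#'   (list-column of [walker_spec()]s) ready for [generate_trial()].
#' @export
cohort_specs <- function(specs = walker_spec(), n_subjects = 5,
                         trials_per_session = 2, sessions = 2,
                         between_sd = 0.05, within_sd = 0.01,
                         seed = 1L) {
  if (inherits(specs, "walker_spec")) {
    template <- specs
    subjects <- sprintf("S%02d", seq_len(n_subjects))
    base <- lapply(subjects, function(s) template)
  } else {
    base <- specs
    subjects <- sprintf("S%02d", seq_along(specs))
  }
  grid <- tidyr::expand_grid(
    subject = subjects,
    session = sprintf("M%d", 6 * (seq_len(sessions) - 1)),
    trial = seq_len(trials_per_session)
  )
  grid$spec <- purrr::pmap(grid, function(subject, session, trial) {
    sp <- base[[match(subject, subjects)]]
    subj_rng <- string_seed(seed, subject)
    set.seed(subj_rng)
    subj_mult <- 1 + between_sd * stats::rnorm(2)
    trial_rng <- string_seed(seed, subject, session, trial)
    set.seed(trial_rng)
    trial_mult <- 1 + within_sd * stats::rnorm(2)
    sp$stride_time_s <- sp$stride_time_s * subj_mult[1] * trial_mult[1]
    sp$step_length_m <- sp$step_length_m * subj_mult[2] * trial_mult[2]
    sp$seed <- trial_rng
    validate_walker_spec(sp)
    structure(sp, class = "walker_spec")
  })
  grid
}
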