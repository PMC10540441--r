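# The 17 gait parameters. Core numeric routines take plain vectors so they
# can be tested against independent oracles; trial-level wrappers extract
# the right stream/segment combination.

#' Walking velocity
#'
#' Total path length divided by the duration from the first to the last gait
#' event after exclusion of the U-turn.
#'
#' @param seg A `trial_segmentation`.
#' @param path_length Path length in metres (default 20: 10 m out and back).
#' @return Velocity in m/s.
#' @export
gait_velocity <- function(seg, path_length = 20) {
  stopifnot(path_length > 0)
  ev <- seg$events
  t0 <- min(ev$fc, ev$ic)
  t1 <- max(ev$fc, ev$ic, na.rm = TRUE)
  dur <- (t1 - t0) - (seg$uturn$end - seg$uturn$start)
  if (dur <= 0) abort("invalid segmentation: non-positive effective duration")
  path_length / dur
}

#' Mean stride time
#'
#' IC-to-next-IC durations of the valid strides, both feet pooled.
#'
#' @param seg A `trial_segmentation`.
#' @return Mean stride time in seconds.
#' @export
stride_time <- function(seg) {
  st <- stride_time_series(seg)
  if (length(st) < 2) abort("insufficient strides")
  mean(st)
}

stride_time_series <- function(seg) {
  seg$strides$ic_end - seg$strides$ic_start
}

#' U-turn duration
#' @param seg A `trial_segmentation` (or a `uturn_interval`).
#' @return Duration in seconds.
#' @export
uturn_time <- function(seg) {
  ut <- if (inherits(seg, "uturn_interval")) seg else seg$uturn
  ut$end - ut$start
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, as a
#' percentage. Scale invariant.
#'
#' @param values Positive numeric series of at least 3 values.
#' @return CV in percent.
#' @export
variation_coefficient <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("insufficient data: need at least 3 values")
  m <- mean(values)
  if (m <= 0) abort("insufficient data: non-positive mean")
  100 * sd(values) / m
}

#' Spectral arc length (SPARC) smoothness index
#'
#' Arc length of the normalized Fourier magnitude spectrum over an adaptive
#' frequency band. The spectrum is computed on a zero-padded FFT (at least
#' 4096 points, at least 8 times the signal length), normalized by its
#' maximal magnitude (for the non-negative gyration-magnitude signals the
#' index targets, this equals the zero-frequency value); the band extends
#' to the last frequency at which
#' the normalized spectrum still exceeds `amp_threshold` (capped at
#' `max_cutoff_hz`). More negative values mean a less smooth signal.
#'
#' @param x Numeric signal (the trunk gyration magnitude for the SPARC-G
#'   parameter).
#' @param rate Sampling rate in Hz.
#' @param max_cutoff_hz Upper bound for the adaptive cutoff (default 20 Hz).
#' @param amp_threshold Normalized-amplitude threshold for the adaptive band
#'   (default 0.05).
#' @return The (negative) spectral arc length.
#' @export
gait_sparc <- function(x, rate, max_cutoff_hz = 20, amp_threshold = 0.05) {
  if (all(x == 0)) abort("degenerate spectrum: all-zero signal")
  nfft <- 2^ceiling(log2(max(4096, 8 * length(x))))
  spec <- Mod(fft(c(x, rep(0, nfft - length(x)))))
  freq <- (seq_len(nfft) - 1) * rate / nfft
  half <- seq_len(nfft %/% 2 + 1)
  spec <- spec[half]
  freq <- freq[half]
  shat <- spec / max(spec)

  sel <- freq <= max_cutoff_hz
  f_sel <- freq[sel]
  s_sel <- shat[sel]
  over <- which(s_sel >= amp_threshold)
  cut <- if (length(over) > 0) min(max(over) + 1L, length(f_sel)) else length(f_sel)
  f_b <- f_sel[seq_len(cut)]
  s_b <- s_sel[seq_len(cut)]
  f_c <- f_b[length(f_b)]

  df <- diff(f_b) / f_c                 # band-normalized frequency steps
  ds <- diff(s_b)
  -sum(sqrt(df^2 + ds^2))
}

#' Log dimensionless jerk (acceleration variant)
#'
#' \code{-ln((T / a_peak^2) * integral of squared jerk)} over a window of
#' duration `T`, where jerk is the time derivative of the acceleration. The
#' signal is low-pass filtered before differentiation (centered finite
#' differences) because differentiation amplifies noise; set
#' `lowpass_hz = NULL` to differentiate the raw signal.
#'
#' @param x Acceleration signal in m/s².
#' @param rate Sampling rate in Hz.
#' @param lowpass_hz Pre-differentiation low-pass cutoff (default 10 Hz).
#' @return The (negative) log dimensionless jerk.
#' @export
gait_ldlj <- function(x, rate, lowpass_hz = 10) {
  if (!is.null(lowpass_hz)) x <- lowpass(x, rate, lowpass_hz)
  a_peak <- max(abs(x))
  if (a_peak == 0) abort("degenerate signal: zero peak acceleration")
  n <- length(x)
  h <- 1 / rate
  jerk <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  tt <- (seq_len(n - 2)) * h
  duration <- (n - 1) * h
  integral <- trapz_int(tt, jerk^2)
  -log(duration / a_peak^2 * integral)
}

#' Unbiased normalized autocorrelation regularity peaks
#'
#' Mean-removed, unbiased normalized autocorrelation of a trunk
#' craniocaudal acceleration window. `P1` is the maximum in the lag window
#' `step_lag * [0.5, 1.5]` (step regularity), `P2` the maximum in
#' `stride_lag * [0.75, 1.25]` (stride regularity); both lie in [-1, 1].
#'
#' @param x Signal window.
#' @param rate Sampling rate in Hz.
#' @param step_lag,stride_lag Expected step and stride durations in seconds
#'   (seeded from the detected mean step and stride times).
#' @return Named numeric `c(P1, P2)`.
#' @export
autocorr_peaks <- function(x, rate, step_lag, stride_lag) {
  n <- length(x)
  if (n < 2 * stride_lag * rate) {
    abort("insufficient window: need at least two stride durations")
  }
  xc <- x - mean(x)
  denom <- sum(xc^2) / n
  ac_at <- function(lag) {
    sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / (n - lag) / denom
  }
  peak_in <- function(lo, hi) {
    lags <- seq(max(1, floor(lo * rate)), min(n - 2, ceiling(hi * rate)))
    max(vapply(lags, ac_at, numeric(1)))
  }
  c(P1 = peak_in(0.5 * step_lag, 1.5 * step_lag),
    P2 = peak_in(0.75 * stride_lag, 1.25 * stride_lag))
}

#' Step length
#'
#' Path length divided by the number of steps outside the U-turn.
#'
#' @param seg A `trial_segmentation`.
#' @param path_length Path length in metres.
#' @return Step length in metres.
#' @export
step_length <- function(seg, path_length = 20) {
  n <- length(seg$steps)
  if (n == 0) abort("no steps outside the U-turn")
  path_length / n
}

#' Root mean square of the trunk mediolateral acceleration
#'
#' Dispersion relative to zero (not to the window mean), pooled over the
#' straight-walking windows.
#'
#' @param x Numeric samples (concatenated straight-window ML acceleration).
#' @return RMS in the units of `x`.
#' @export
rms_amplitude <- function(x) sqrt(mean(x^2))

#' Improved harmonic ratio (iHR)
#'
#' For each stride, the signal is decomposed into its stride-locked Fourier
#' series (harmonics 1..`n_harmonics`); the iHR is the percentage of the
#' harmonic power carried by the intrinsic harmonics -- even harmonics for
#' the anteroposterior and craniocaudal axes, odd harmonics for the
#' mediolateral axis -- averaged over strides. Ranges from 0 to 100.
#'
#' @param x Trunk acceleration signal (one axis, full trial).
#' @param t Time stamps of `x` in seconds.
#' @param strides Tibble with `ic_start`, `ic_end` of the strides to use.
#' @param axis `"AP"`, `"ML"` or `"CC"`.
#' @param n_harmonics Number of stride-locked harmonics (default 20).
#' @return iHR in percent.
#' @export
gait_ihr <- function(x, t, strides, axis = c("AP", "ML", "CC"),
                     n_harmonics = 20) {
  axis <- match.arg(axis)
  if (nrow(strides) < 3) abort("insufficient strides: need at least 3")
  intrinsic_even <- axis %in% c("AP", "CC")
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(strides))) {
    sel <- t >= strides$ic_start[i] & t < strides$ic_end[i]
    xs <- x[sel]
    L <- length(xs)
    if (L < 2 * n_harmonics) {
      skipped <- skipped + 1L
      next
    }
    co <- fft(xs) / L
    power <- Mod(co[1 + seq_len(n_harmonics)])^2
    k <- seq_len(n_harmonics)
    intr <- if (intrinsic_even) k %% 2 == 0 else k %% 2 == 1
    tot <- sum(power)
    if (tot == 0) {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, 100 * sum(power[intr]) / tot)
  }
  if (skipped > 0) {
    warn(sprintf("%d stride(s) skipped in iHR (too short or flat)", skipped))
  }
  if (length(vals) == 0) abort("insufficient strides: none usable for iHR")
  mean(vals)
}

#' Swing-time symmetry ratio and autocorrelation peak ratio
#'
#' `swTr` is the smaller of the two per-foot mean swing times (FC to next
#' IC) divided by the larger, in (0, 1]; `P1P2` is the ratio of the step to
#' the stride autocorrelation peak.
#'
#' @param swings Tibble `foot`, `fc`, `ic` of valid swings.
#' @param P1,P2 Autocorrelation peaks from [autocorr_peaks()].
#' @return Named numeric `c(swTr, P1P2)`.
#' @export
symmetry_ratios <- function(swings, P1, P2) {
  ms <- swings |>
    mutate(dur = .data$ic - .data$fc) |>
    group_by(.data$foot) |>
    summarise(m = mean(.data$dur), n = dplyr::n(), .groups = "drop")
  if (nrow(ms) < 2 || any(ms$n < 2)) {
    abort("insufficient swings: need at least 2 per foot")
  }
  if (P2 == 0) abort("undefined ratio: P2 is zero")
  c(swTr = min(ms$m) / max(ms$m), P1P2 = P1 / P2)
}

#' Double-stance time
#'
#' For each valid stride cycle, the two double-support periods (from the IC
#' of one foot to the FC of the contralateral foot) are summed and divided
#' by the cycle duration. Cycles with a negative double-support interval
#' (event-ordering violation) are discarded with a warning.
#'
#' @param seg A `trial_segmentation`.
#' @return A list with `dstT` (mean percentage of the gait cycle) and
#'   `series` (per-cycle percentages, feeding the CV of double stance).
#' @export
double_stance <- function(seg) {
  ev <- seg$events
  per_cycle <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(seg$strides))) {
    f <- seg$strides$foot[i]
    t0 <- seg$strides$ic_start[i]
    t1 <- seg$strides$ic_end[i]
    contra <- ev[ev$foot != f, ]
    ipsi <- ev[ev$foot == f, ]
    # first support: own IC at t0 until the contralateral FC that follows
    fc1 <- min(contra$fc[contra$fc > t0], Inf)
    ic_c <- min(contra$ic[contra$ic > t0], Inf)
    # second support: contralateral IC until own FC (opening the swing that
    # lands at t1)
    fc2 <- ipsi$fc[match(t1, ipsi$ic)]
    if (!is.finite(fc1) || !is.finite(ic_c) || is.na(fc2)) next
    ds1 <- fc1 - t0
    ds2 <- fc2 - ic_c
    if (ds1 < 0 || ds2 < 0 || fc1 > t1) {
      dropped <- dropped + 1L
      next
    }
    per_cycle <- c(per_cycle, 100 * (ds1 + ds2) / (t1 - t0))
  }
  if (dropped > 0) {
    warn(sprintf("%d cycle(s) with violated event ordering discarded", dropped))
  }
  if (length(per_cycle) == 0) abort("no usable double-stance cycle")
  list(dstT = mean(per_cycle), series = per_cycle)
}

# Duration-weighted mean of a per-window statistic computed on a trunk
# signal column over the straight-walking windows (windows shorter than
# `min_dur` are skipped).
window_stat <- function(trunk, windows, col, min_dur, f) {
  vals <- numeric(0)
  durs <- numeric(0)
  for (i in seq_len(nrow(windows))) {
    sel <- trunk$t >= windows$start[i] & trunk$t <= windows$end[i]
    dur <- windows$end[i] - windows$start[i]
    if (dur < min_dur || sum(sel) < 4) next
    vals <- c(vals, f(trunk[[col]][sel]))
    durs <- c(durs, dur)
  }
  if (length(vals) == 0) abort("insufficient window: no straight window usable")
  sum(vals * durs) / sum(durs)
}

#' Compute all 17 gait parameters of a trial
#'
#' Runs event detection, U-turn detection and segmentation, then evaluates
#' every parameter: V, StrT, UtrT, SPARC_G, LDLJ_A, CV_StrT, CV_dstT,
#' P1_aCC, P2_aCC, SteL, RMS_aML, iHR_aAP, iHR_aML, iHR_aCC, P1P2_aCC, swTr
#' and dstT. Deterministic: identical input gives identical output.
#'
#' @param trial An [imu_trial()].
#' @param path_length Walked path in metres (default 20).
#' @param seg Optionally a precomputed `trial_segmentation`.
#' @return A one-row tibble of class `gait_parameters` with the 17
#'   parameter columns; the segmentation is attached as attribute
#'   `segmentation` and per-parameter notes as attribute `qc`.
#' @export
#' @examples
#' g <- generate_trial(walker_spec(seed = 3))
#' compute_gait_parameters(g$trial)
compute_gait_parameters <- function(trial, path_length = 20, seg = NULL) {
  stopifnot(inherits(trial, "imu_trial"))
  if (is.null(seg)) seg <- segment_imu_trial(trial)
  fs <- trial$sample_rate
  trunk <- trial_stream(trial, "lower_back")
  qc <- character(0)
  note <- function(msg) qc <<- c(qc, msg)

  V <- gait_velocity(seg, path_length)
  strt_series <- stride_time_series(seg)
  StrT <- stride_time(seg)
  UtrT <- uturn_time(seg)
  SteL <- step_length(seg, path_length)

  step_lag <- mean(diff(seg$steps[seg$steps < seg$uturn$start]))
  gyr_mag <- sqrt(trunk$gyr_AP^2 + trunk$gyr_ML^2 + trunk$gyr_CC^2)
  trunk2 <- mutate(trunk, gyr_mag = gyr_mag)

  SPARC_G <- window_stat(trunk2, seg$straight_windows, "gyr_mag", 2,
                         function(x) gait_sparc(x, fs))
  LDLJ_A <- window_stat(trunk2, seg$straight_windows, "acc_AP", 2,
                        function(x) gait_ldlj(x, fs))
  RMS_aML <- {
    sel <- rep(FALSE, nrow(trunk))
    for (i in seq_len(nrow(seg$straight_windows))) {
      sel <- sel | (trunk$t >= seg$straight_windows$start[i] &
                      trunk$t <= seg$straight_windows$end[i])
    }
    rms_amplitude(trunk$acc_ML[sel])
  }
  p12 <- tryCatch(
    window_stat(trunk2, seg$straight_windows, "acc_CC", 2 * StrT,
                function(x) autocorr_peaks(x, fs, step_lag, StrT)["P1"]),
    error = function(e) NA_real_)
  p22 <- tryCatch(
    window_stat(trunk2, seg$straight_windows, "acc_CC", 2 * StrT,
                function(x) autocorr_peaks(x, fs, step_lag, StrT)["P2"]),
    error = function(e) NA_real_)
  if (is.na(p12) || is.na(p22)) note("autocorrelation windows too short")

  ihr_of <- function(col, axis) {
    withCallingHandlers(
      gait_ihr(trunk[[col]], trunk$t, seg$strides, axis),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  iHR_aAP <- ihr_of("acc_AP", "AP")
  iHR_aML <- ihr_of("acc_ML", "ML")
  iHR_aCC <- ihr_of("acc_CC", "CC")

  ds <- withCallingHandlers(double_stance(seg), warning = function(w) {
    note(conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  sym <- symmetry_ratios(seg$swings, p12, p22)

  out <- tibble(
    V = V, StrT = StrT, UtrT = UtrT,
    SPARC_G = SPARC_G, LDLJ_A = LDLJ_A,
    CV_StrT = variation_coefficient(strt_series),
    CV_dstT = variation_coefficient(ds$series),
    P1_aCC = p12, P2_aCC = p22,
    SteL = SteL, RMS_aML = RMS_aML,
    iHR_aAP = iHR_aAP, iHR_aML = iHR_aML, iHR_aCC = iHR_aCC,
    P1P2_aCC = unname(sym["P1P2"]), swTr = unname(sym["swTr"]),
    dstT = ds$dstT
  )
  attr(out, "segmentation") <- seg
  attr(out, "qc") <- qc
  class(out) <- c("gait_parameters", class(out))
  out
}

#' Parameter units
#'
#' @return Named character vector mapping the 17 parameter names to units.
#' @export
parameter_units <- function() {
  c(V = "m/s", StrT = "s", UtrT = "s", SPARC_G = "-", LDLJ_A = "-",
    CV_StrT = "%", CV_dstT = "%", P1_aCC = "-", P2_aCC = "-", SteL = "m",
    RMS_aML = "m/s^2", iHR_aAP = "%", iHR_aML = "%", iHR_aCC = "%",
    P1P2_aCC = "-", swTr = "-", dstT = "%")
}

#' Serialize a parameter set
#'
#' Writes the 17 parameters either as flat JSON or as one row of a wide CSV
#' whose columns are exactly the parameter symbols.
#'
#' @param params A `gait_parameters` row.
#' @param path Output file; format chosen by extension (`.json` or `.csv`).
#' @return Invisibly, `path`.
#' @export
write_gait_parameters <- function(params, path) {
  flat <- as.list(params[1, names(parameter_units())])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(as_tibble(flat), path)
  }
  invisible(path)
}
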