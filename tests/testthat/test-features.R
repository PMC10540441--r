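# Parameter operations, each checked against an independent oracle or a
# closed form where the definition admits one.

test_that("velocity and step length follow their defining arithmetic", {
  lic <- seq(0, 10, by = 1)
  ev <- stub_events(rep(c("left", "right"), each = 11),
                    c(lic - 0.4, lic + 0.1), c(lic, lic + 0.5))
  seg <- segment_trial(ev, stub_uturn(5.05, 5.45), c(-1, 12))
  # event span (-0.4 .. 10.5) minus 0.4 s turn
  expect_equal(gait_velocity(seg, path_length = 20),
               20 / ((10.5 - (-0.4)) - 0.4), tolerance = 1e-12)
  expect_equal(step_length(seg, 20), 20 / length(seg$steps), tolerance = 1e-12)
  # doubling the declared path doubles both
  expect_equal(gait_velocity(seg, 40), 2 * gait_velocity(seg, 20))
  expect_equal(step_length(seg, 40), 2 * step_length(seg, 20))
  # U-turn longer than the event span is invalid
  expect_error(gait_velocity(segment_trial(ev, stub_uturn(0.2, 10.3), c(-1, 13)),
                             20),
               "invalid segmentation|degenerate")
})

test_that("stride, U-turn and CV operations match hand arithmetic", {
  lic <- seq(0, 11, by = 1.1)
  ev <- stub_events(rep(c("left", "right"), each = 11),
                    c(lic - 0.4, lic + 0.15), c(lic, lic + 0.55))
  seg <- segment_trial(ev, stub_uturn(5.46, 5.49), c(-1, 13))
  expect_equal(stride_time(seg), 1.1, tolerance = 1e-9)
  expect_equal(uturn_time(stub_uturn(12, 14.6)), 2.6)

  expect_equal(variation_coefficient(c(1, 1, 1, 1)), 0)
  expect_equal(variation_coefficient(c(1.0, 1.1, 1.2)), 100 * 0.1 / 1.1,
               tolerance = 1e-9)
  x <- c(0.9, 1.3, 1.1, 1.05)
  expect_equal(variation_coefficient(3 * x), variation_coefficient(x),
               tolerance = 1e-12)
  expect_error(variation_coefficient(c(1, 2)), "insufficient data")
})

test_that("SPARC matches a direct-DFT oracle and behaves monotonically", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)

  # oracle: O(N^2) DFT + explicit trapezoid arc length, same nominal grid
  sparc_oracle <- function(x, fs, oversample = 1) {
    nfft <- oversample * 2^ceiling(log2(max(4096, 8 * length(x))))
    k <- 0:(nfft %/% 2)
    n <- seq_along(x) - 1
    spec <- vapply(k, function(kk) {
      Mod(sum(x * exp(-2i * pi * kk * n / nfft)))
    }, numeric(1))
    freq <- k * fs / nfft
    shat <- spec / max(spec)
    sel <- which(freq <= 20)
    over <- which(shat[sel] >= 0.05)
    cut <- min(max(over) + 1L, length(sel))
    fb <- freq[seq_len(cut)]
    sb <- shat[seq_len(cut)]
    fc <- fb[cut]
    total <- 0
    for (i in 2:cut) {
      total <- total + sqrt(((fb[i] - fb[i - 1]) / fc)^2 + (sb[i] - sb[i - 1])^2)
    }
    -total
  }
  got <- gait_sparc(x, fs)
  expect_equal(got, sparc_oracle(x, fs), tolerance = 1e-6)
  # refining the frequency grid by 8x moves the arc length only modestly
  # (the spectrum's sidelobe ripples limit polyline convergence)
  expect_lt(abs(got - sparc_oracle(x, fs, oversample = 8)), 0.5)

  # an added 8 Hz component of half amplitude is strictly less smooth
  y <- x + 0.5 * sin(2 * pi * 8 * t)
  expect_lt(gait_sparc(y, fs), got)

  expect_error(gait_sparc(numeric(100), fs), "degenerate spectrum")
})

test_that("LDLJ matches its discrete closed form on a sinusoid", {
  fs <- 100
  T_dur <- 10
  t <- seq(0, T_dur, by = 1 / fs)
  x <- sin(2 * pi * t)

  # Exact closed form of the implementation's discrete pipeline (no filter):
  # centered difference of sin(w t) has amplitude sin(w h)/h; the trapezoid
  # sum of cos^2 over the interior grid is evaluated via geometric cosine
  # sums, independent of the numeric path.
  w <- 2 * pi
  h <- 1 / fs
  amp <- sin(w * h) / h
  interior <- t[2:(length(t) - 1)]
  # sum of cos(2 w t) over the interior grid via the Dirichlet closed form
  m <- length(interior)
  a0 <- 2 * w * interior[1]
  d <- 2 * w * h
  cos_sum <- cos(a0 + (m - 1) * d / 2) * sin(m * d / 2) / sin(d / 2)
  sq_sum <- m / 2 + cos_sum / 2                 # sum cos^2(w t_i)
  ends <- (cos(w * interior[1])^2 + cos(w * interior[m])^2) / 2
  integral <- amp^2 * h * (sq_sum - ends)       # trapezoid rule, closed form
  a_peak <- max(abs(x))
  expected <- -log(T_dur / a_peak^2 * integral)
  expect_equal(gait_ldlj(x, fs, lowpass_hz = NULL), expected,
               tolerance = 1e-9)

  # continuous closed form -ln(T * (2 pi)^2 T / 2) at coarser tolerance
  expect_equal(gait_ldlj(x, fs, lowpass_hz = NULL),
               -log(T_dur * (2 * pi)^2 * T_dur / 2), tolerance = 1e-2)

  # added in-band high-frequency content strictly lowers the index
  noisy <- x + 0.1 * sin(2 * pi * 8 * t)
  expect_lt(gait_ldlj(noisy, fs), gait_ldlj(x, fs))

  expect_error(gait_ldlj(numeric(200), fs), "degenerate signal")
})

test_that("autocorrelation peaks match a brute-force oracle", {
  fs <- 100
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  stride_T <- 1.2

  # perfectly periodic with identical half-period steps: P1 = P2 = 1
  x <- cos(2 * pi * t / (stride_T / 2))
  p <- autocorr_peaks(x, fs, step_lag = stride_T / 2, stride_lag = stride_T)
  expect_equal(unname(p["P1"]), 1, tolerance = 1e-6)
  expect_equal(unname(p["P2"]), 1, tolerance = 1e-6)

  # alternating step amplitudes: stride peak above step peak
  y <- cos(2 * pi * t / (stride_T / 2)) + 0.5 * cos(2 * pi * t / stride_T)
  py <- autocorr_peaks(y, fs, stride_T / 2, stride_T)
  expect_gt(py["P2"], py["P1"])

  # brute-force lag-domain oracle on a generated trunk window
  g <- default_gait()
  tr <- dplyr::filter(g$trial$data, site == "lower_back")
  seg <- attr(compute_gait_parameters(g$trial), "segmentation")
  w <- seg$straight_windows[1, ]
  z <- tr$acc_CC[tr$t >= w$start & tr$t <= w$end]
  oracle <- function(x, lag) {
    xc <- x - mean(x)
    n <- length(xc)
    num <- 0
    for (i in 1:(n - lag)) num <- num + xc[i] * xc[i + lag]
    (num / (n - lag)) / (sum(xc^2) / n)
  }
  step_lag <- 0.55
  got <- autocorr_peaks(z, fs, step_lag, 1.1)
  lags1 <- seq(floor(0.5 * step_lag * fs), ceiling(1.5 * step_lag * fs))
  brute1 <- max(vapply(lags1, function(l) oracle(z, l), numeric(1)))
  expect_equal(unname(got["P1"]), brute1, tolerance = 1e-9)
})

test_that("RMS is zero-referenced and matches closed forms", {
  expect_equal(rms_amplitude(numeric(100)), 0)
  t <- seq(0, 10 - 0.01, by = 0.01)
  expect_equal(rms_amplitude(2.5 * sin(2 * pi * t)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(rms_amplitude(rep(-0.7, 500)), 0.7)   # offset, not dispersion
})

test_that("iHR attains its bounds and the equal-power midpoint", {
  fs <- 100
  stride_T <- 1.0
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  strides <- tibble::tibble(ic_start = 0:4, ic_end = 1:5)

  even_only <- sin(2 * pi * 2 * t / stride_T) + 0.3 * sin(2 * pi * 4 * t / stride_T)
  expect_equal(gait_ihr(even_only, t, strides, "AP"), 100, tolerance = 1e-9)

  odd_only <- sin(2 * pi * 1 * t / stride_T)
  expect_equal(gait_ihr(odd_only, t, strides, "AP"), 0, tolerance = 1e-9)
  # the same signal is fully intrinsic on the ML axis
  expect_equal(gait_ihr(odd_only, t, strides, "ML"), 100, tolerance = 1e-9)

  both <- sin(2 * pi * t / stride_T) + sin(2 * pi * 2 * t / stride_T + 0.4)
  expect_equal(gait_ihr(both, t, strides, "AP"), 50, tolerance = 1e-6)

  expect_error(gait_ihr(even_only, t, strides[1:2, ], "AP"),
               "insufficient strides")
})

test_that("symmetry ratios follow their definitions", {
  sw <- tibble::tibble(foot = rep(c("left", "right"), each = 3),
                       fc = c(0, 1, 2, 0.5, 1.5, 2.5),
                       ic = c(0.40, 1.40, 2.40, 1.00, 2.00, 3.00))
  s <- symmetry_ratios(sw, P1 = 0.8, P2 = 0.9)
  expect_equal(unname(s["swTr"]), 0.40 / 0.50, tolerance = 1e-12)
  expect_equal(unname(s["P1P2"]), 0.8 / 0.9, tolerance = 1e-12)

  equal <- dplyr::mutate(sw, ic = fc + 0.42)
  expect_equal(unname(symmetry_ratios(equal, 1, 1)["swTr"]), 1)
  expect_error(symmetry_ratios(sw, 0.5, 0), "undefined ratio")
})

test_that("double stance matches hand arithmetic on a constructed cycle", {
  # left ICs at 0,1,2,...; right ICs at 0.5,...; contact pattern with
  # ds1 = ds2 = 0.12 in every 1.0 s cycle
  lic <- 0:9
  ric <- lic + 0.5
  # right FC follows left IC by 0.12; left FC follows right IC by 0.12
  ev <- stub_events(rep(c("left", "right"), each = 10),
                    c(lic - 0.38, ric - 0.38),
                    c(lic, ric))
  seg <- segment_trial(ev, stub_uturn(4.76, 4.80), c(-1, 11))
  ds <- suppressWarnings(double_stance(seg))
  expect_equal(ds$dstT, 24, tolerance = 1e-9)
  expect_true(all(abs(ds$series - 24) < 1e-9))
})

test_that("all parameters recover the simulated walker within tolerance", {
  g <- default_gait()
  p <- compute_gait_parameters(g$trial)
  tg <- g$truth$targets

  expect_equal(p$V, tg$V, tolerance = 0.05 / tg$V)
  expect_equal(p$StrT, tg$StrT, tolerance = 0.02 / tg$StrT)
  expect_equal(p$SteL, tg$SteL, tolerance = 0.04 / tg$SteL)
  expect_equal(p$dstT, tg$dstT, tolerance = 1.5 / tg$dstT)
  expect_equal(p$swTr, tg$swTr, tolerance = 0.02 / tg$swTr)
  expect_equal(p$RMS_aML, tg$RMS_aML, tolerance = 0.1 / tg$RMS_aML)
  expect_lt(abs(p$CV_StrT - tg$CV_StrT), 1)

  # invariants of the parameter set
  for (col in c("iHR_aAP", "iHR_aML", "iHR_aCC")) {
    expect_gte(p[[col]], 0); expect_lte(p[[col]], 100)
  }
  expect_gt(p$swTr, 0); expect_lte(p$swTr, 1)
  expect_gt(p$dstT, 0); expect_lt(p$dstT, 100)
  expect_gte(p$CV_StrT, 0); expect_gte(p$CV_dstT, 0)
  for (col in c("V", "StrT", "UtrT", "SteL", "RMS_aML")) {
    expect_gt(p[[col]], 0)
  }
})

test_that("a default walker lands inside the normative plausibility bands", {
  p <- compute_gait_parameters(default_gait()$trial)
  ref <- gait_reference()
  for (i in seq_len(nrow(ref))) {
    v <- p[[ref$parameter[i]]]
    expect_lt(abs(v - ref$mean[i]), 3 * ref$sd[i],
              label = sprintf("%s = %.3f vs %.2f +/- 3*%.2f", ref$parameter[i],
                              v, ref$mean[i], ref$sd[i]))
  }
})

test_that("the parameter pipeline is deterministic and mirror-symmetric", {
  g <- default_gait()
  p1 <- compute_gait_parameters(g$trial)
  p2 <- compute_gait_parameters(g$trial)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  sw <- g$trial
  sw$data$site <- dplyr::recode(sw$data$site, left_foot = "right_foot",
                                right_foot = "left_foot")
  ps <- compute_gait_parameters(imu_trial(sw$data, sw$sample_rate))
  for (col in names(parameter_units())) {
    expect_equal(ps[[col]], p1[[col]], tolerance = 1e-9,
                 label = paste("mirrored", col))
  }
})

test_that("time shifting the trial leaves every parameter unchanged", {
  g <- default_gait()
  p0 <- compute_gait_parameters(g$trial)
  sh <- g$trial
  sh$data$t <- sh$data$t + 0.5
  p1 <- compute_gait_parameters(sh)
  for (col in setdiff(names(parameter_units()), "UtrT")) {
    expect_equal(p1[[col]], p0[[col]], tolerance = 1e-6,
                 label = paste("shifted", col))
  }
  expect_equal(p1$UtrT, p0$UtrT, tolerance = 0.05)
})

test_that("parameter serialization round-trips as JSON and wide CSV", {
  p <- compute_gait_parameters(default_gait()$trial)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gait_parameters(p, json)
  write_gait_parameters(p, csv)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$StrT, p$StrT, tolerance = 1e-12)
  wide <- readr::read_csv(csv, show_col_types = FALSE)
  expect_identical(names(wide), names(parameter_units()))
  expect_equal(wide$dstT, p$dstT, tolerance = 1e-12)
})
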