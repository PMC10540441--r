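# Shared fixtures. Trials are generated in code; the default healthy trial
# is memoised because several files reuse it.

.fixture_env <- new.env(parent = emptyenv())

default_gait <- function(seed = 1) {
  key <- paste0("gait_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_trial(walker_spec(seed = seed))
  }
  .fixture_env[[key]]
}

# Minimal trial whose three sites carry caller-supplied signals (defaults:
# flat noise-free streams). Useful for driving single detectors directly.
flat_trial <- function(duration = 30, rate = 100,
                       lower_back = list(), left_foot = list(),
                       right_foot = list()) {
  t <- seq(0, duration, by = 1 / rate)
  blank <- function() numeric(length(t))
  mk <- function(site, over) {
    s <- tibble::tibble(t = t, site = site, acc_AP = blank(),
                        acc_ML = blank(), acc_CC = blank(),
                        gyr_AP = blank(), gyr_ML = blank(), gyr_CC = blank())
    for (nm in names(over)) s[[nm]] <- over[[nm]]
    s
  }
  imu_trial(dplyr::bind_rows(mk("lower_back", lower_back),
                             mk("left_foot", left_foot),
                             mk("right_foot", right_foot)),
            sample_rate = rate)
}

raised_cosine <- function(t, center, width) {
  u <- (t - center) / width
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# Match detected swings to ground-truth swings within a tolerance; returns
# precision/recall counts for F1-style assertions.
match_events <- function(detected, truth, tol = 0.05) {
  tp <- 0L
  used <- logical(nrow(truth))
  for (i in seq_len(nrow(detected))) {
    j <- which(truth$foot == detected$foot[i] &
                 abs(truth$ic - detected$ic[i]) <= tol &
                 abs(truth$fc - detected$fc[i]) <= tol & !used)
    if (length(j) > 0) {
      tp <- tp + 1L
      used[j[1]] <- TRUE
    }
  }
  list(tp = tp, fp = nrow(detected) - tp, fn = nrow(truth) - tp)
}

# Hand-built uturn_interval for segmentation tests that bypass detection.
stub_uturn <- function(start, end) {
  structure(list(start = start, end = end,
                 angle = tibble::tibble(t = numeric(0),
                                        angle_deg = numeric(0)),
                 direction = "right"),
            class = "uturn_interval")
}

# Hand-built gait_events tibble.
stub_events <- function(foot, fc, ic) {
  ev <- tibble::tibble(foot = foot, fc = fc, ic = ic)
  structure(ev, class = c("gait_events", class(ev)))
}
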