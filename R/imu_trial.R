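#' IMU walking-trial container
#'
#' An `imu_trial` bundles the synchronized tri-axial accelerometer and
#' gyroscope streams of the three sensor sites used by the semiogram
#' protocol: `left_foot`, `right_foot` and `lower_back`. All signals are
#' stored in an anatomically aligned frame (AP = anteroposterior,
#' ML = mediolateral, CC = craniocaudal), accelerations in m/s² and angular
#' velocities in deg/s, on a single uniform time grid.
#'
#' @param data Tibble with columns `t` (seconds), `site` (one of
#'   `left_foot`, `right_foot`, `lower_back`), `acc_AP`, `acc_ML`, `acc_CC`
#'   (m/s²), `gyr_AP`, `gyr_ML`, `gyr_CC` (deg/s). Every site must be
#'   present with identical time stamps.
#' @param sample_rate Sampling frequency in Hz (nominal 100).
#' @param meta Named list of free-form trial metadata (subject id, session
#'   label, trial index, ...).
#'
#' @return An object of class `imu_trial`: a list with elements `data`
#'   (long tibble as above), `sample_rate` and `meta`.
#' @export
#' @examples
#' tr <- generate_trial(walker_spec(seed = 1))$trial
#' tr
imu_trial <- function(data, sample_rate, meta = list()) {
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1, sample_rate > 0)
  data <- as_tibble(data)
  needed <- c("t", "site", signal_cols())
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  sites <- sort(unique(data$site))
  if (!identical(sites, sort(trial_sites()))) {
    abort("incomplete sensor set: need exactly left_foot, right_foot, lower_back")
  }
  lens <- table(data$site)
  if (length(unique(as.integer(lens))) != 1) {
    abort("sensor streams differ in length")
  }
  n <- as.integer(lens[[1]])
  if ((n - 1) / sample_rate < 5) {
    abort("trial too short: a walking trial must last at least 5 s")
  }
  for (col in signal_cols()) {
    if (any(!is.finite(data[[col]]))) {
      abort(sprintf("non-finite samples in %s; repair at load time", col))
    }
  }
  data <- arrange(data, .data$site, .data$t)   # canonical ordering
  structure(list(data = data, sample_rate = sample_rate, meta = meta),
            class = "imu_trial")
}

trial_sites <- function() c("left_foot", "right_foot", "lower_back")

signal_cols <- function() {
  c("acc_AP", "acc_ML", "acc_CC", "gyr_AP", "gyr_ML", "gyr_CC")
}

#' @export
print.imu_trial <- function(x, ...) {
  n <- nrow(x$data) / 3
  cat(sprintf("<imu_trial> %d samples/site at %g Hz (%.1f s)\n",
              n, x$sample_rate, (n - 1) / x$sample_rate))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# One site's stream as a tibble (t + six signal columns).
trial_stream <- function(trial, site) {
  stopifnot(site %in% trial_sites())
  dplyr::filter(trial$data, .data$site == !!site)
}

trial_duration <- function(trial) {
  ts <- trial_stream(trial, "lower_back")$t
  ts[length(ts)] - ts[1]
}

#' Read an IMU trial from per-site delimited text files
#'
#' Each site is a CSV with columns `t, acc_AP, acc_ML, acc_CC, gyr_AP,
#' gyr_ML, gyr_CC`; `t` in seconds; lines starting with `#` are comments.
#' A dialect describes deviations from the internal conventions and is
#' applied at load time: gyroscopes in rad/s are converted to deg/s, raw
#' sensor axes are mapped to the anatomical frame by a per-site static
#' re-labelling (with optional sign flips), and streams not on the nominal
#' grid are linearly resampled to it.
#'
#' Up to 1% non-finite samples per channel are linearly interpolated with a
#' warning; more is rejected as a corrupt stream.
#'
#' @param paths Named character vector of file locations with names
#'   `left_foot`, `right_foot`, `lower_back`.
#' @param dialect A list (or path to a YAML file) with optional entries
#'   `sample_rate` (Hz, default 100), `gyro_units` (`"deg/s"` default or
#'   `"rad/s"`), and `axis_map`, a per-site named list mapping anatomical
#'   axes to source column suffixes, e.g.
#'   `list(lower_back = c(AP = "X", ML = "-Y", CC = "Z"))`.
#' @param meta Metadata list attached to the trial.
#'
#' @return An [imu_trial()].
#' @export
read_imu_trial <- function(paths, dialect = list(), meta = list()) {
  if (is.character(dialect)) dialect <- yaml::read_yaml(dialect)
  rate <- dialect$sample_rate %||% 100
  gyro_units <- dialect$gyro_units %||% "deg/s"
  missing_sites <- setdiff(trial_sites(), names(paths))
  if (length(missing_sites) > 0) {
    abort(paste0("incomplete sensor set: missing ",
                 paste(missing_sites, collapse = ", ")))
  }
  streams <- lapply(trial_sites(), function(site) {
    path <- paths[[site]]
    if (!file.exists(path)) {
      abort(sprintf("incomplete sensor set: file not found for %s: %s",
                    site, path))
    }
    raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    raw <- apply_axis_map(raw, dialect$axis_map[[site]])
    if (any(diff(raw$t) <= 0)) {
      abort(sprintf("unordered samples: non-monotonic timestamps in %s", site))
    }
    for (col in signal_cols()) {
      raw[[col]] <- repair_nonfinite(raw[[col]],
                                     label = paste(site, col, sep = "/"))
    }
    if (identical(gyro_units, "rad/s")) {
      for (col in c("gyr_AP", "gyr_ML", "gyr_CC")) {
        raw[[col]] <- raw[[col]] * 180 / pi
      }
    }
    resample_stream(raw, rate)
  })
  names(streams) <- trial_sites()
  grid <- streams[["lower_back"]]$t
  data <- bind_rows(lapply(trial_sites(), function(site) {
    s <- streams[[site]]
    if (nrow(s) != length(grid)) {
      m <- min(nrow(s), length(grid))
      s <- s[seq_len(m), ]
      s$t <- grid[seq_len(m)]
    }
    mutate(s, site = site)
  }))
  n <- min(table(data$site))
  data <- data |>
    group_by(.data$site) |>
    dplyr::slice_head(n = n) |>
    ungroup()
  imu_trial(data, sample_rate = rate, meta = meta)
}

# Map raw column suffixes to anatomical axes, e.g. AP = "-Y" takes the
# negated *_Y columns.
apply_axis_map <- function(raw, axis_map) {
  if (is.null(axis_map)) return(raw)
  out <- tibble(t = raw$t)
  for (axis in c("AP", "ML", "CC")) {
    src <- axis_map[[axis]]
    if (is.null(src)) src <- axis
    sign <- 1
    if (startsWith(src, "-")) {
      sign <- -1
      src <- substring(src, 2)
    }
    out[[paste0("acc_", axis)]] <- sign * raw[[paste0("acc_", src)]]
    out[[paste0("gyr_", axis)]] <- sign * raw[[paste0("gyr_", src)]]
  }
  out
}

# Linear resampling onto the uniform grid at `rate`, no-op when already there.
resample_stream <- function(s, rate) {
  t0 <- s$t[1]
  t1 <- s$t[nrow(s)]
  grid <- seq(t0, t1, by = 1 / rate)
  dt <- diff(s$t)
  if (nrow(s) == length(grid) && max(abs(dt - 1 / rate)) < 1e-9) {
    s$t <- t0 + (seq_len(nrow(s)) - 1) / rate
    return(s)
  }
  out <- tibble(t = grid)
  for (col in signal_cols()) {
    out[[col]] <- approx(s$t, s[[col]], xout = grid, rule = 2)$y
  }
  out
}

#' Write an IMU trial to per-site CSV files
#'
#' Inverse of [read_imu_trial()]: writes one CSV per sensor site into `dir`
#' (`left_foot.csv`, `right_foot.csv`, `lower_back.csv`) in the internal
#' dialect (anatomical axes, m/s², deg/s), with the sample rate and the
#' metadata embedded in `#` comment headers so that a round trip reproduces
#' the trial.
#'
#' @param trial An [imu_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_imu_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "imu_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    sprintf("# sample_rate: %s", format(trial$sample_rate, digits = 15)),
    sprintf("# meta: %s", jsonlite::toJSON(trial$meta, auto_unbox = TRUE))
  )
  paths <- vapply(trial_sites(), function(site) {
    path <- file.path(dir, paste0(site, ".csv"))
    s <- trial_stream(trial, site) |> select(-"site")
    con <- file(path, "w")
    writeLines(header, con)
    close(con)
    readr::write_csv(s, path, append = TRUE, col_names = TRUE)
    path
  }, character(1))
  invisible(paths)
}

#' Reload a trial written by [write_imu_trial()]
#'
#' @param dir Directory holding the three per-site CSVs.
#' @return An [imu_trial()] with the stored metadata and sample rate.
#' @export
read_imu_trial_dir <- function(dir) {
  paths <- c(left_foot = file.path(dir, "left_foot.csv"),
             right_foot = file.path(dir, "right_foot.csv"),
             lower_back = file.path(dir, "lower_back.csv"))
  if (!file.exists(paths[["lower_back"]])) {
    abort(sprintf("incomplete sensor set: %s not found", paths[["lower_back"]]))
  }
  hdr <- readLines(paths[["lower_back"]], n = 2)
  rate <- as.numeric(sub("# sample_rate: ", "", hdr[1], fixed = TRUE))
  meta <- jsonlite::fromJSON(sub("# meta: ", "", hdr[2], fixed = TRUE),
                             simplifyVector = TRUE)
  if (length(meta) == 0) meta <- list()
  read_imu_trial(paths, dialect = list(sample_rate = rate),
                 meta = as.list(meta))
}
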