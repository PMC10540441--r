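# Z-normalization against a reference population and assembly of the seven
# criterion partial scores (plus the speed score): the semiogram's numbers.

criterion_order <- function() {
  c("sturdiness", "springiness", "steadiness", "stability", "smoothness",
    "synchronization", "symmetry")
}

#' Normative reference statistics
#'
#' Loads a reference table giving, for each of the 17 gait parameters, the
#' mean and standard deviation in a reference population (native units) and
#' the z-coefficient (+1 when an increase is beneficial, -1 when it is
#' pathological). The packaged default describes a healthy adult reference
#' group measured with the 10-m out-and-back protocol. A note on the
#' default: the shipped z-coefficient of SPARC_G is -1 as published for
#' that reference table, although a *less* negative spectral arc length
#' conventionally means a smoother movement; see the methods vignette.
#'
#' @param path YAML file with the structure of the packaged
#'   `reference_norms.yaml`; defaults to the packaged table.
#' @return A tibble of class `reference_stats` with columns `parameter`,
#'   `criterion`, `mean`, `sd`, `z_coefficient`, `unit`; the provenance
#'   label is attached as attribute `provenance`.
#' @export
gait_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_norms.yaml",
                        package = "semiogram", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  tbl <- purrr::imap(raw$parameters, function(p, name) {
    tibble(parameter = name, criterion = p$criterion, mean = p$mean,
           sd = p$sd, z_coefficient = p$z_coefficient, unit = p$unit)
  }) |> bind_rows()
  validate_reference(tbl)
  attr(tbl, "provenance") <- raw$provenance %||% "unspecified"
  class(tbl) <- c("reference_stats", class(tbl))
  tbl
}

validate_reference <- function(tbl) {
  expected <- names(parameter_units())
  if (!setequal(tbl$parameter, expected) || anyDuplicated(tbl$parameter)) {
    abort("reference must cover all 17 parameters exactly once")
  }
  if (any(tbl$sd <= 0)) abort("reference SDs must be positive")
  if (!all(tbl$z_coefficient %in% c(-1, 1))) {
    abort("z-coefficients must be +1 or -1")
  }
  invisible(tbl)
}

#' Derive reference statistics from a cohort of parameter sets
#'
#' Utility for building a custom reference table: means and SDs are
#' computed over the supplied trials; z-coefficients and criterion
#' membership are inherited from the packaged defaults.
#'
#' @param params_tbl Tibble with one row per trial and the 17 parameter
#'   columns (e.g. stacked [compute_gait_parameters()] rows).
#' @param provenance Label describing the cohort.
#' @return A `reference_stats` tibble.
#' @export
build_reference <- function(params_tbl, provenance = "user cohort") {
  base <- gait_reference()
  stats_tbl <- params_tbl |>
    tidyr::pivot_longer(dplyr::all_of(base$parameter),
                        names_to = "parameter", values_to = "value") |>
    group_by(.data$parameter) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  out <- base |>
    select(-"mean", -"sd") |>
    left_join(stats_tbl, by = "parameter") |>
    select("parameter", "criterion", "mean", "sd", "z_coefficient", "unit")
  validate_reference(out)
  attr(out, "provenance") <- provenance
  class(out) <- c("reference_stats", class(out))
  out
}

#' Write a reference table as YAML
#'
#' @param ref A `reference_stats` tibble.
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
write_reference <- function(ref, path) {
  params <- lapply(seq_len(nrow(ref)), function(i) {
    list(criterion = ref$criterion[i], mean = ref$mean[i], sd = ref$sd[i],
         z_coefficient = ref$z_coefficient[i], unit = ref$unit[i])
  })
  names(params) <- ref$parameter
  yaml::write_yaml(list(provenance = attr(ref, "provenance") %||% "unspecified",
                        parameters = params), path, precision = 15)
  invisible(path)
}

#' Signed parameter z-scores
#'
#' `z = z_coefficient * (x - mean) / sd`, so a positive z-score always
#' means better than the reference, whatever the parameter's pathological
#' direction.
#'
#' @param params One-row tibble of the 17 parameters
#'   (e.g. from [compute_gait_parameters()]).
#' @param ref A `reference_stats` tibble (default: packaged norms).
#' @return Tibble `parameter`, `criterion`, `value`, `z`.
#' @export
zscore_parameters <- function(params, ref = gait_reference()) {
  validate_reference(ref)
  missing_p <- setdiff(ref$parameter, names(params))
  if (length(missing_p) > 0) {
    abort(paste0("incomplete parameter set: missing ",
                 paste(missing_p, collapse = ", ")))
  }
  vals <- vapply(ref$parameter, function(p) params[[p]][1], numeric(1))
  if (any(!is.finite(vals))) {
    abort("incomplete parameter set: non-finite parameter value")
  }
  tibble(parameter = ref$parameter, criterion = ref$criterion,
         value = unname(vals),
         z = ref$z_coefficient * (unname(vals) - ref$mean) / ref$sd)
}

#' Assemble a semiogram from parameter z-scores
#'
#' Each criterion partial score is the arithmetic mean of the signed
#' z-scores of its member parameters (springiness: StrT, UtrT; smoothness:
#' LDLJ_A, SPARC_G; steadiness: CV_StrT, CV_dstT, P1_aCC, P2_aCC;
#' sturdiness: SteL; stability: RMS_aML; symmetry: iHR_aAP, iHR_aML,
#' iHR_aCC, P1P2_aCC, swTr; synchronization: dstT); the speed z-score is
#' carried separately and drives the chart colour.
#'
#' @param x Either a `gait_parameters` row, an [imu_trial()], or a z-score
#'   tibble from [zscore_parameters()].
#' @param ref A `reference_stats` tibble.
#' @param meta Session metadata list.
#' @param ... Passed to [compute_gait_parameters()] when `x` is a trial.
#' @return An object of class `semiogram`: list with `speed_z`, `criteria`
#'   (tibble `criterion`, `score` in the fixed axis order), `parameter_z`
#'   and `meta`.
#' @export
#' @examples
#' ref <- gait_reference()
#' probe <- as.list(stats::setNames(ref$mean, ref$parameter))
#' semiogram(tibble::as_tibble(probe))   # all-zero semiogram
semiogram <- function(x, ref = gait_reference(), meta = list(), ...) {
  if (inherits(x, "imu_trial")) {
    x <- compute_gait_parameters(x, ...)
  }
  zt <- if (is.data.frame(x) && all(c("parameter", "z") %in% names(x))) {
    x
  } else {
    zscore_parameters(x, ref)
  }
  crit <- zt |>
    dplyr::filter(.data$criterion != "speed") |>
    group_by(.data$criterion) |>
    summarise(score = mean(.data$z), .groups = "drop")
  crit <- crit[match(criterion_order(), crit$criterion), ]
  structure(list(
    speed_z = zt$z[zt$parameter == "V"],
    criteria = crit,
    parameter_z = zt,
    meta = meta
  ), class = "semiogram")
}

#' @export
print.semiogram <- function(x, ...) {
  cat(sprintf("<semiogram> speed z = %+.2f\n", x$speed_z))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  %-15s %+.2f\n", x$criteria$criterion[i],
                x$criteria$score[i]))
  }
  invisible(x)
}

#' @describeIn semiogram Criterion scores and speed as a tidy tibble.
#' @export
tidy.semiogram <- function(x, ...) {
  bind_rows(tibble(criterion = "speed", score = x$speed_z), x$criteria)
}

#' @describeIn semiogram One-row summary (speed z, mean and worst criterion).
#' @export
glance.semiogram <- function(x, ...) {
  tibble(speed_z = x$speed_z,
         mean_score = mean(x$criteria$score),
         worst_criterion = x$criteria$criterion[which.min(x$criteria$score)],
         worst_score = min(x$criteria$score))
}

#' Summarise the repeated trials of one session
#'
#' Per criterion (and for the speed z-score): arithmetic mean, minimum and
#' maximum over the session's trials. The mean is the plain line of the
#' semiogram chart; min and max bound the session band.
#'
#' @param semiograms List of [semiogram()] objects (one per trial, at least
#'   one).
#' @param label Session label.
#' @return An object of class `semiogram_session`: list with `label`,
#'   `speed_z` (mean over trials), `criteria` (tibble `criterion`, `mean`,
#'   `min`, `max`) and `n_trials`.
#' @export
session_summary <- function(semiograms, label = "session") {
  if (inherits(semiograms, "semiogram")) semiograms <- list(semiograms)
  stopifnot(length(semiograms) >= 1)
  scores <- purrr::map_dfr(semiograms, function(s) {
    tidyr::pivot_wider(s$criteria, names_from = "criterion",
                       values_from = "score")
  })
  stat <- function(f) {
    unname(vapply(criterion_order(), function(cr) f(scores[[cr]]), numeric(1)))
  }
  crit <- tibble(criterion = criterion_order(), mean = stat(mean),
                 min = stat(min), max = stat(max))
  structure(list(
    label = label,
    speed_z = mean(vapply(semiograms, function(s) s$speed_z, numeric(1))),
    criteria = crit,
    n_trials = length(semiograms)
  ), class = "semiogram_session")
}

#' @export
print.semiogram_session <- function(x, ...) {
  cat(sprintf("<semiogram_session> '%s': %d trial(s), speed z = %+.2f\n",
              x$label, x$n_trials, x$speed_z))
  invisible(x)
}

#' @describeIn session_summary Per-criterion mean/min/max as a tibble.
#' @export
tidy.semiogram_session <- function(x, ...) {
  mutate(x$criteria, session = x$label, .before = 1)
}

#' Serialize a session summary as JSON
#'
#' @param session A `semiogram_session`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  payload <- list(
    label = session$label,
    speed_z = session$speed_z,
    n_trials = session$n_trials,
    criteria = session$criteria
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a session summary written by [write_session()]
#' @param path JSON file.
#' @return A `semiogram_session`.
#' @export
read_session <- function(path) {
  p <- jsonlite::fromJSON(path)
  crit <- as_tibble(p$criteria)
  crit <- crit[match(criterion_order(), crit$criterion), ]
  structure(list(label = p$label, speed_z = p$speed_z,
                 criteria = crit, n_trials = p$n_trials),
            class = "semiogram_session")
}
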