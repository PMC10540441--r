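# Test-retest reliability machinery: ICC(1,1), ICC(3,1), SEM,
# heteroskedasticity screening, group differences, clinical correlations.

# Coerce subjects x repeats input (matrix or data frame with a subject
# column) to a complete numeric matrix; rows with missing repeats dropped.
as_repeat_matrix <- function(measures, subject_col = "subject") {
  if (is.data.frame(measures)) {
    m <- measures
    if (subject_col %in% names(m)) {
      rn <- m[[subject_col]]
      m <- m[setdiff(names(m), subject_col)]
    } else {
      rn <- seq_len(nrow(m))
    }
    measures <- as.matrix(m)
    rownames(measures) <- as.character(rn)
  }
  storage.mode(measures) <- "double"
  complete <- stats::complete.cases(measures)
  if (any(!complete)) {
    warn(sprintf("%d row(s) with missing repeats dropped", sum(!complete)))
    measures <- measures[complete, , drop = FALSE]
  }
  if (nrow(measures) < 3 || ncol(measures) < 2) {
    abort("need at least 3 subjects and 2 repeats")
  }
  measures
}

#' Intraclass correlation coefficient for single measurements
#'
#' `ICC(1,1)` (one-way random model) treats all within-subject variability
#' as measurement error: `(BMS - WMS) / (BMS + (k-1) WMS)`. `ICC(3,1)`
#' (two-way mixed, consistency) removes a systematic per-repeat bias:
#' `(BMS - EMS) / (BMS + (k-1) EMS)`, with mean squares from the two-way
#' ANOVA without interaction. `k` is the number of repeats.
#'
#' @param measures Subjects x repeats numeric matrix, or a data frame with
#'   a `subject` column and one column per repeat.
#' @param model `"one_way"` (ICC(1,1)) or `"two_way_mixed"` (ICC(3,1)).
#' @return A list of class `gait_icc`: `icc`, `model`, `n` (subjects), `k`
#'   (repeats), the ANOVA mean squares, and `degenerate` (TRUE when there
#'   is no between-subject spread).
#' @export
#' @examples
#' m <- cbind(test = c(1, 2, 3, 4), retest = c(1.1, 2.0, 3.2, 3.9))
#' icc(m, "one_way")$icc
icc <- function(measures, model = c("one_way", "two_way_mixed")) {
  model <- match.arg(model)
  m <- as_repeat_matrix(measures)
  n <- nrow(m)
  k <- ncol(m)
  df <- tibble(
    value = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    repeat_id = factor(rep(seq_len(k), each = n))
  )
  if (model == "one_way") {
    fit <- aov(value ~ subject, data = df)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    bms <- ms[1]
    wms <- ms[2]
    val <- (bms - wms) / (bms + (k - 1) * wms)
    out <- list(icc = val, model = "ICC(1,1)", n = n, k = k,
                ms = c(BMS = bms, WMS = wms))
  } else {
    fit <- aov(value ~ subject + repeat_id, data = df)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    bms <- ms[1]
    ems <- ms[3]
    val <- (bms - ems) / (bms + (k - 1) * ems)
    out <- list(icc = val, model = "ICC(3,1)", n = n, k = k,
                ms = c(BMS = bms, JMS = ms[2], EMS = ems))
  }
  subj_means <- rowMeans(m)
  out$degenerate <- isTRUE(var(subj_means) < .Machine$double.eps * 100)
  if (out$degenerate) {
    warn("degenerate (no subject spread): ICC defined but uninformative")
  }
  structure(out, class = "gait_icc")
}

#' @export
print.gait_icc <- function(x, ...) {
  cat(sprintf("<%s> %.3f (%d subjects x %d repeats)%s\n", x$model, x$icc,
              x$n, x$k, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @describeIn icc ICC as a one-row tibble with its agreement band.
#' @export
tidy.gait_icc <- function(x, ...) {
  tibble(model = x$model, icc = x$icc, n_subjects = x$n, k_repeats = x$k,
         band = reliability_band(x$icc), degenerate = x$degenerate)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)` where SD pools all observations; an absolute
#' (same-unit) complement to the relative ICC.
#'
#' @param measures Subjects x repeats input as for [icc()].
#' @param icc_value An ICC in `(-Inf, 1]`, or a `gait_icc` object.
#' @return SEM in the measurement's native units.
#' @export
sem_measurement <- function(measures, icc_value) {
  if (inherits(icc_value, "gait_icc")) icc_value <- icc_value$icc
  stopifnot(icc_value <= 1)
  m <- as_repeat_matrix(measures)
  sd(as.vector(m)) * sqrt(1 - icc_value)
}

#' Agreement band for an ICC
#'
#' At least 0.75 is `"excellent"`, 0.4 to 0.75 `"moderate-to-high"`, and
#' below 0.4 `"low"`. Exactly 0.75 counts as excellent and exactly 0.4 as
#' moderate-to-high.
#'
#' @param icc_value Numeric ICC value(s).
#' @return Character vector of band labels.
#' @export
reliability_band <- function(icc_value) {
  dplyr::case_when(
    icc_value >= 0.75 ~ "excellent",
    icc_value >= 0.4 ~ "moderate-to-high",
    TRUE ~ "low"
  )
}

#' Heteroskedasticity screen for a test-retest pair
#'
#' Pearson correlation between the absolute test-retest differences and the
#' individual means, with a two-sided test against zero correlation. A
#' significant positive correlation signals variability growing with the
#' measured value, which distorts the ICC.
#'
#' @param measures Subjects x 2 input as for [icc()].
#' @return A list `r`, `p`, `degenerate` (TRUE when the differences are
#'   constant, in which case `r` is reported as 0).
#' @export
heteroskedasticity <- function(measures) {
  m <- as_repeat_matrix(measures)
  if (ncol(m) != 2) abort("heteroskedasticity screen needs exactly 2 repeats")
  d <- abs(m[, 1] - m[, 2])
  mu <- rowMeans(m)
  if (sd(d) < .Machine$double.eps * 100 || sd(mu) < .Machine$double.eps * 100) {
    warn("degenerate heteroskedasticity screen: constant differences or means")
    return(list(r = 0, p = 1, degenerate = TRUE))
  }
  ct <- stats::cor.test(d, mu, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Group difference on z-scores (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with tie-corrected normal approximation
#' (exact enumeration for small, tie-free samples), with Bonferroni
#' adjustment over `n_tests` comparisons.
#'
#' @param a,b Numeric score vectors for the two groups (each of size >= 3).
#' @param n_tests Bonferroni family size (default 8: speed plus the seven
#'   criteria).
#' @return A list `U`, `p`, `p_adj`.
#' @export
group_difference <- function(a, b, n_tests = 8) {
  if (length(a) < 3 || length(b) < 3) abort("each group needs >= 3 values")
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       p_adj = min(1, wt$p.value * n_tests))
}

#' Correlation of criterion scores with a clinical scale
#'
#' Pearson correlation with a two-sided test via the Fisher
#' z-transformation.
#'
#' @param scores,clinical Paired numeric vectors (>= 4 pairs).
#' @param n_tests Optional Bonferroni family size (default 1).
#' @return A list `r`, `p`, `p_adj`, `n`.
#' @export
clinical_correlation <- function(scores, clinical, n_tests = 1) {
  ok <- is.finite(scores) & is.finite(clinical)
  scores <- scores[ok]
  clinical <- clinical[ok]
  n <- length(scores)
  if (n < 4) abort("need at least 4 paired observations")
  if (sd(scores) == 0 || sd(clinical) == 0) {
    abort("zero variance in scores or clinical scale")
  }
  r <- cor(scores, clinical)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    z <- atanh(r) * sqrt(n - 3)
    p <- 2 * pnorm(-abs(z))
  }
  list(r = r, p = p, p_adj = min(1, p * n_tests), n = n)
}

#' Test-retest reliability report
#'
#' Computes ICC(1,1), ICC(3,1), SEM, the agreement band and the
#' heteroskedasticity screen for each measure of a wide test-retest table,
#' mirroring the layout used when screening gait parameters for inclusion.
#'
#' @param data Long tibble with columns `subject`, `measure` (parameter or
#'   criterion name), `repeat_id` and `value`; or a wide subjects x repeats
#'   table for a single measure.
#' @return A tibble with one row per measure: `measure`, `icc11`, `icc31`,
#'   `sem`, `band` (based on ICC(1,1)), `hetero_r`, `hetero_p`.
#' @export
reliability_report <- function(data) {
  if (!all(c("subject", "measure", "repeat_id", "value") %in% names(data))) {
    data <- as_repeat_matrix(data)
    data <- tibble(
      subject = rep(rownames(data) %||% seq_len(nrow(data)), ncol(data)),
      measure = "measure",
      repeat_id = rep(colnames(data) %||% seq_len(ncol(data)),
                      each = nrow(data)),
      value = as.vector(data)
    )
  }
  data |>
    group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, names_from = "repeat_id",
                                 values_from = "value")
      m <- as_repeat_matrix(wide)
      i11 <- icc(m, "one_way")
      i31 <- icc(m, "two_way_mixed")
      het <- if (ncol(m) == 2) heteroskedasticity(m) else
        list(r = NA_real_, p = NA_real_)
      tibble(icc11 = i11$icc, icc31 = i31$icc,
             sem = sem_measurement(m, i11),
             band = reliability_band(i11$icc),
             hetero_r = het$r, hetero_p = het$p)
    }) |>
    ungroup()
}
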