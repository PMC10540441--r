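# Shared numeric helpers: filtering, integration, peak finding.

# Zero-phase low-pass Butterworth filter. `cutoff` in Hz; order refers to the
# one-pass filter (filtfilt doubles the effective order).
lowpass <- function(x, rate, cutoff, order = 4) {
  stopifnot(cutoff > 0, rate > 0)
  if (cutoff >= rate / 2) {
    return(x)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Trapezoidal integration on a uniform or non-uniform grid.
trapz_int <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2)
}

cumtrapz_int <- function(t, y) {
  n <- length(t)
  c(0, cumsum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2))
}

# Indices of strict local maxima (plateau-free signals assumed after
# filtering; ties broken by first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Topographic prominence of each candidate peak: height above the higher of
# the two key saddles toward the nearest higher terrain (or signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- 1L
    for (q in rev(peaks[peaks < p])) if (x[q] > h) { left <- q; break }
    right <- length(x)
    for (q in peaks[peaks > p]) if (x[q] > h) { right <- q; break }
    lmin <- min(x[left:p])
    rmin <- min(x[p:right])
    h - max(lmin, rmin)
  }, numeric(1))
}

# Peak picking with a prominence floor and a minimum separation; among peaks
# closer than `min_dist` samples the more prominent one is kept.
find_peaks <- function(x, min_prominence, min_dist = 0L) {
  cand <- local_maxima(x)
  if (length(cand) == 0) return(integer(0))
  prom <- peak_prominence(x, cand)
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (min_dist > 0 && length(cand) > 1) {
    ord <- order(prom, decreasing = TRUE)
    taken <- logical(0)
    sel <- integer(0)
    for (i in ord) {
      if (all(abs(cand[sel] - cand[i]) >= min_dist)) sel <- c(sel, i)
    }
    cand <- sort(cand[sel])
  }
  cand
}

# Deterministic 32-bit string hash (FNV-1a) used to derive per-trial RNG
# seeds from labels; arithmetic kept in doubles below 2^53.
string_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Linear interpolation over non-finite samples; the share of repaired samples
# must stay at or below `max_frac`.
repair_nonfinite <- function(x, max_frac = 0.01, label = "stream") {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  frac <- mean(bad)
  if (frac > max_frac) {
    abort(sprintf("corrupt stream: %.1f%% non-finite samples in %s",
                  100 * frac, label))
  }
  idx <- seq_along(x)
  x[bad] <- approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
  warn(sprintf("%d non-finite sample(s) in %s linearly interpolated",
               sum(bad), label))
  x
}
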