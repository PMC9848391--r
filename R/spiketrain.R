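# Basic spiking properties, principal/interneuron classification, and the
# circular-shift shuffle engine that normalizes every downstream statistic.

#' Basic spiking and waveform properties of one cell
#'
#' Mean rate is total spikes over the task hour. The coefficient of
#' variation is sd/mean of firing rates in 50 ms bins. The burst ratio is
#' the count of short inter-spike intervals (< 10 ms) over long ones
#' (> 125 ms, about one theta cycle); a zero denominator is flagged
#' undefined (`NA`), never reported as zero.
#'
#' @param times sorted spike times (s).
#' @param spike_width_us spike width metadata (us), passed through.
#' @param session_duration session length (s), default 3600.
#' @param cv_binwidth bin width for the CV computation (s), default 0.05.
#' @return one-row data.frame: `mean_rate`, `cv`, `median_isi`, `isi_sd`,
#'   `burst_ratio`, `spike_width`, plus `isi_defined` flag.
#' @export
basic_properties <- function(times, spike_width_us = NA_real_,
                             session_duration = 3600, cv_binwidth = 0.05) {
  stopifnot(!is.unsorted(times))
  n <- length(times)
  mean_rate <- n / session_duration
  counts <- tabulate(pmin(floor(times / cv_binwidth) + 1L,
                          ceiling(session_duration / cv_binwidth)),
                     nbins = ceiling(session_duration / cv_binwidth))
  rates <- counts / cv_binwidth
  cv <- if (mean(rates) > 0) sd(rates) / mean(rates) else NA_real_
  if (n >= 2) {
    isi <- diff(times)
    n_short <- sum(isi < 0.010)
    n_long <- sum(isi > 0.125)
    data.frame(mean_rate = mean_rate, cv = cv,
               median_isi = median(isi), isi_sd = sd(isi),
               burst_ratio = if (n_long > 0) n_short / n_long else NA_real_,
               spike_width = spike_width_us, isi_defined = TRUE)
  } else {
    data.frame(mean_rate = mean_rate, cv = cv, median_isi = NA_real_,
               isi_sd = NA_real_, burst_ratio = NA_real_,
               spike_width = spike_width_us, isi_defined = FALSE)
  }
}

#' Classify a cell as principal cell or interneuron
#'
#' Deterministic side-of-line rule in (spike width, firing rate) space.
#' The boundary is a configurable line `a*width + b*rate = c`; points with
#' `a*width + b*rate < c` (narrow, fast-firing) are interneurons. Points
#' exactly on the line are principal, with a message. The reference
#' boundary was drawn by hand on real data, so it must be supplied to
#' match any particular population.
#'
#' @param mean_rate Hz.
#' @param spike_width_us microseconds.
#' @param boundary named numeric `c(w=, r=, c=)` line coefficients.
#' @return character, `"principal"` or `"interneuron"` (vectorized).
#' @export
classify_cell <- function(mean_rate, spike_width_us,
                          boundary = c(w = 1, r = -10, c = 350)) {
  s <- boundary[["w"]] * spike_width_us + boundary[["r"]] * mean_rate -
    boundary[["c"]]
  if (any(s == 0)) rrow_log("cell exactly on class boundary -> principal")
  ifelse(s < 0, "interneuron", "principal")
}

#' Circularly shift a spike train on the session circle
#'
#' @param times spike times (s).
#' @param shift shift amount (s).
#' @param period session length (s), default 3600.
#' @return shifted, re-sorted spike times.
#' @export
circular_shift <- function(times, shift, period = 3600) {
  sort((times + shift) %% period)
}

#' Shuffle-normalize a spike-train statistic
#'
#' Computes `statistic(train)` minus the mean of the statistic over
#' `n_shuffles` circularly time-shifted copies of the train, each shifted
#' by an independent uniform draw from `shift_range` (1 to 59 min of the
#' 1 hr session by default). The statistic may return a scalar or a
#' vector (e.g. a PETH); normalization is elementwise.
#'
#' @param statistic function of a numeric spike-time vector.
#' @param times spike times (s).
#' @param n_shuffles number of shuffles, default 30.
#' @param shift_range uniform shift range (s), default `c(60, 3540)`.
#' @param period session circle length (s), default 3600.
#' @param seed optional seed for the shift draws.
#' @return list: `raw`, `null_mean`, `normalized`, `shifts`.
#' @export
shuffle_normalize <- function(statistic, times, n_shuffles = 30,
                              shift_range = c(60, 3540), period = 3600,
                              seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  raw <- statistic(times)
  shifts <- with_seed(seed, runif(n_shuffles, shift_range[1], shift_range[2]))
  null <- vapply(shifts,
                 function(s) as.numeric(statistic(circular_shift(times, s, period))),
                 numeric(length(raw)))
  null_mean <- if (length(raw) == 1L) mean(null) else rowMeans(matrix(null, nrow = length(raw)))
  list(raw = raw, null_mean = null_mean, normalized = raw - null_mean,
       shifts = shifts)
}
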