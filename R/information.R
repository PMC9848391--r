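# Plug-in mutual information between binned firing rates and task
# variables, shuffle-normalized against circularly shifted spike trains.

#' Discretize a continuous variable into uniform-width bins
#'
#' Bins span `[min, max]` of the observed finite values; the top edge is
#' closed so the maximum lands in the last bin. Factors and character
#' vectors pass through with their natural categories. A constant input
#' collapses into a single occupied bin with a warning (MI against it
#' will be 0).
#'
#' @param values numeric, factor, or character.
#' @param n_bins number of uniform bins, default 5.
#' @return integer bin codes (or the input categories as a factor).
#' @export
discretize <- function(values, n_bins = 5L) {
  if (is.factor(values) || is.character(values) || is.logical(values))
    return(as.integer(factor(values)))
  stopifnot(any(is.finite(values)))
  lo <- min(values, na.rm = TRUE); hi <- max(values, na.rm = TRUE)
  if (hi == lo) {
    warning("constant input: all values in one bin")
    return(rep(1L, length(values)))
  }
  w <- (hi - lo) / n_bins
  b <- pmin(as.integer(floor((values - lo) / w)) + 1L, as.integer(n_bins))
  b[!is.finite(values)] <- NA_integer_
  b
}

#' Plug-in mutual information between two discrete sequences
#'
#' `MI = sum p(B,S) log2[p(B,S) / (p(B) p(S))]` with probabilities taken
#' from the empirical joint counts and the convention `0 log 0 = 0`.
#'
#' @param b,s equal-length discrete sequences (binned behavior, binned
#'   spiking). Pairs with an `NA` in either are dropped.
#' @return MI in bits (nonnegative).
#' @export
mutual_information <- function(b, s) {
  stopifnot(length(b) == length(s))
  ok <- !is.na(b) & !is.na(s)
  b <- b[ok]; s <- s[ok]
  if (length(b) == 0) stop("empty input", call. = FALSE)
  joint <- table(b, s)
  mi_from_joint(joint)
}

#' Mutual information from a joint count table
#'
#' @param joint matrix/table of joint counts.
#' @return MI in bits.
#' @export
mi_from_joint <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  pb <- rowSums(p); ps <- colSums(p)
  terms <- p * log2(p / outer(pb, ps))
  sum(terms[p > 0])
}

# shared engine: MI per time bin between across-visit rate vectors and a
# per-visit variable, with per-time-bin discretization of the rates.
mi_bins <- function(per_visit_rates, variable, n_bins = 5L) {
  vb <- discretize(variable, n_bins)
  apply(per_visit_rates, 2, function(r) {
    ok <- is.finite(r) & !is.na(vb)
    if (sum(ok) < 2) return(NA_real_)
    tab <- table(vb[ok])
    if (any(tab < 2) || length(tab) < 2) return(NA_real_)
    rb <- suppressWarnings(discretize(r[ok], n_bins))
    mi_from_joint(table(vb[ok], rb))
  })
}

#' Shuffle-normalized mutual-information time course
#'
#' Computes, at each PETH time bin treated independently, the MI between
#' the across-visit firing rates (discretized into 5 uniform bins using
#' that time bin's own range) and a per-visit task variable, then
#' subtracts the mean MI over circularly shifted spike trains. Bins where
#' any variable category has fewer than 2 visits are flagged `NA`.
#'
#' @param times spike times (s).
#' @param events alignment events as for [peth()].
#' @param variable per-visit variable (numeric or categorical), one entry
#'   per row/element of `events`.
#' @param spec a [bin_spec()].
#' @param n_bins discretization bins, default 5.
#' @param n_shuffles circular shuffles, default 30.
#' @param shift_range,period see [shuffle_normalize()].
#' @param seed optional seed for shuffle shifts.
#' @return data.frame: `bin`, `raw`, `null_mean`, `normalized`.
#' @export
mi_timecourse <- function(times, events, variable, spec = bin_spec(),
                          n_bins = 5L, n_shuffles = 30,
                          shift_range = c(60, 3540), period = 3600,
                          seed = NULL) {
  stat <- function(tt) {
    p <- suppressWarnings(peth(tt, events, spec))
    mi_bins(p$per_visit, variable, n_bins)
  }
  out <- shuffle_normalize(stat, times, n_shuffles = n_shuffles,
                           shift_range = shift_range, period = period,
                           seed = seed)
  data.frame(bin = seq_along(out$raw), raw = out$raw,
             null_mean = out$null_mean, normalized = out$normalized)
}

#' Session-level shuffle-normalized MI between zone firing rate and a variable
#'
#' One sample per visit: the mean firing rate inside the visit's zone
#' interval, discretized into 5 uniform bins, against the per-visit
#' variable.
#'
#' @param times spike times (s).
#' @param intervals data.frame `enter`, `exit`, one row per visit.
#' @param variable per-visit variable.
#' @inheritParams mi_timecourse
#' @return one-row data.frame: `raw`, `null_mean`, `normalized`, `n`.
#' @export
mi_session <- function(times, intervals, variable, n_bins = 5L,
                       n_shuffles = 30, shift_range = c(60, 3540),
                       period = 3600, seed = NULL) {
  zone_rate <- function(tt) {
    mapply(function(lo, hi) count_in(tt, lo, hi) / (hi - lo),
           intervals$enter, intervals$exit)
  }
  stat <- function(tt) {
    r <- zone_rate(tt)
    vb <- discretize(variable, n_bins)
    rb <- suppressWarnings(discretize(r, n_bins))
    mutual_information(vb, rb)
  }
  out <- shuffle_normalize(stat, times, n_shuffles = n_shuffles,
                           shift_range = shift_range, period = period,
                           seed = seed)
  data.frame(raw = out$raw, null_mean = out$null_mean,
             normalized = out$normalized, n = nrow(intervals))
}

#' MI for a variable recomputed within each level of a conditioning variable
#'
#' The motivating case: MI between firing and offer delay is positive for
#' choice-tuned cells because choice and delay are correlated; splitting
#' visits by OZ choice (accept vs skip) and recomputing the delay MI
#' within each split removes that route. Empty or near-empty conditions
#' are omitted.
#'
#' @param times spike times (s).
#' @param intervals per-visit zone intervals (`enter`, `exit`).
#' @param variable per-visit variable of interest (e.g. offer delay).
#' @param condition per-visit conditioning variable (e.g. OZ choice).
#' @inheritParams mi_session
#' @return data.frame, one row per condition level: `condition`, `raw`,
#'   `null_mean`, `normalized`, `n`.
#' @export
mi_conditioned <- function(times, intervals, variable, condition,
                           n_bins = 5L, n_shuffles = 30,
                           shift_range = c(60, 3540), period = 3600,
                           seed = NULL) {
  lev <- unique(as.character(condition))
  out <- lapply(lev, function(l) {
    sel <- as.character(condition) == l
    if (sum(sel) < 2 * n_bins) return(NULL)
    r <- mi_session(times, intervals[sel, , drop = FALSE], variable[sel],
                    n_bins = n_bins, n_shuffles = n_shuffles,
                    shift_range = shift_range, period = period, seed = seed)
    cbind(condition = l, r)
  })
  do.call(rbind, out)
}
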