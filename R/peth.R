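# Peri-event time histograms, in absolute time (Wait Zone analyses,
# 100 ms bins) or zone-normalized time (Offer and Reward Zone analyses:
# 20 in-zone bins of 5% zone time plus 3 context bins of 10% of the
# flanking zones' time on each side, 26 bins total).

#' Bin specification for PETHs
#'
#' @param type `"absolute"` or `"normalized"`.
#' @param window for absolute: `c(start, stop)` seconds around the event.
#' @param binwidth for absolute: bin width (s), default 0.1.
#' @param n_zone for normalized: in-zone bin count, default 20.
#' @param n_context for normalized: retained context bins per side (of
#'   the 10 computed 10%-of-flanking-zone bins), default 3.
#' @return a `bin_spec` list.
#' @export
bin_spec <- function(type = c("absolute", "normalized"),
                     window = c(-1, 3), binwidth = 0.1,
                     n_zone = 20L, n_context = 3L) {
  type <- match.arg(type)
  structure(list(type = type, window = window, binwidth = binwidth,
                 n_zone = as.integer(n_zone), n_context = as.integer(n_context)),
            class = "bin_spec")
}

count_in <- function(times, lo, hi) {
  # spikes in [lo, hi); times sorted
  findInterval(hi - 1e-9, times) - findInterval(lo - 1e-9, times)
}

#' Peri-event time histogram
#'
#' Per-visit firing rates per bin (count divided by that visit's bin
#' duration) and their unweighted mean across visits.
#'
#' For `type = "absolute"`, `events` is a numeric vector of alignment
#' times. For `type = "normalized"`, `events` is a data.frame with
#' columns `enter`, `exit` (the zone interval) and optionally `pre_enter`
#' and `post_exit` bounding the flanking zones; visits shorter than 20 ms
#' are dropped with a warning, and context bins without flanking-zone
#' information are `NA`.
#'
#' @param times sorted spike times (s).
#' @param events alignment times or zone-interval data.frame.
#' @param spec a [bin_spec()].
#' @return list of class `rrow_peth`: `per_visit` (visits x bins rate
#'   matrix), `mean` (across visits), `bin_centers` (absolute: seconds
#'   from event; normalized: bin index 1..26 with in-zone bins 4..23),
#'   `spec`, `n_visits`.
#' @export
peth <- function(times, events, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  if (spec$type == "absolute") {
    stopifnot(is.numeric(events), length(events) >= 1)
    edges <- seq(spec$window[1], spec$window[2], by = spec$binwidth)
    nb <- length(edges) - 1L
    per <- matrix(NA_real_, nrow = length(events), ncol = nb)
    for (v in seq_along(events)) {
      lo <- events[v] + edges[-length(edges)]
      hi <- events[v] + edges[-1]
      per[v, ] <- mapply(count_in, lo = lo, hi = hi, MoreArgs = list(times = times)) /
        spec$binwidth
    }
    centers <- edges[-length(edges)] + spec$binwidth / 2
  } else {
    stopifnot(is.data.frame(events), nrow(events) >= 1)
    keep <- (events$exit - events$enter) >= 0.020
    if (!all(keep)) {
      warning(sum(!keep), " visit(s) shorter than 20 ms dropped from ",
              "normalized PETH")
      events <- events[keep, , drop = FALSE]
    }
    if (nrow(events) == 0) stop("no usable visits", call. = FALSE)
    nb <- spec$n_zone + 2L * spec$n_context
    per <- matrix(NA_real_, nrow = nrow(events), ncol = nb)
    for (v in seq_len(nrow(events))) {
      en <- events$enter[v]; ex <- events$exit[v]
      zw <- (ex - en) / spec$n_zone
      zl <- en + (seq_len(spec$n_zone) - 1L) * zw
      rates <- rep(NA_real_, nb)
      rates[spec$n_context + seq_len(spec$n_zone)] <-
        mapply(count_in, lo = zl, hi = zl + zw, MoreArgs = list(times = times)) / zw
      pre0 <- if ("pre_enter" %in% names(events)) events$pre_enter[v] else NA
      if (is.finite(pre0) && en - pre0 > 0) {
        pw <- (en - pre0) / 10           # 10% of the preceding zone's time
        lo <- en - rev(seq_len(spec$n_context)) * pw
        rates[seq_len(spec$n_context)] <-
          mapply(count_in, lo = lo, hi = lo + pw, MoreArgs = list(times = times)) / pw
      }
      post1 <- if ("post_exit" %in% names(events)) events$post_exit[v] else NA
      if (is.finite(post1) && post1 - ex > 0) {
        pw <- (post1 - ex) / 10
        lo <- ex + (seq_len(spec$n_context) - 1L) * pw
        rates[spec$n_context + spec$n_zone + seq_len(spec$n_context)] <-
          mapply(count_in, lo = lo, hi = lo + pw, MoreArgs = list(times = times)) / pw
      }
      per[v, ] <- rates
    }
    centers <- seq_len(nb)
  }
  structure(list(per_visit = per,
                 mean = colMeans(per, na.rm = TRUE),
                 bin_centers = centers, spec = spec, n_visits = nrow(per)),
            class = "rrow_peth")
}

#' Shuffle-normalized mean PETH
#'
#' Convenience wrapper: the mean PETH minus its expectation under 30
#' circular shifts of the spike train.
#'
#' @inheritParams peth
#' @inheritParams shuffle_normalize
#' @return list as from [shuffle_normalize()]; entries are bin vectors.
#' @export
peth_normalized <- function(times, events, spec = bin_spec(),
                            n_shuffles = 30, shift_range = c(60, 3540),
                            period = 3600, seed = NULL) {
  shuffle_normalize(function(tt) peth(tt, events, spec)$mean, times,
                    n_shuffles = n_shuffles, shift_range = shift_range,
                    period = period, seed = seed)
}
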