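# Population-level quantifications: firing-behavior correlations, the
# two stepwise-regression procedures, net choice firing preferences,
# subsampling controls, session blocks, and windowed rate correlations
# against offer delay and linger time.

zone_bounds <- function(visits, zone = c("OZ", "WZ", "RZ")) {
  zone <- match.arg(zone)
  switch(zone,
    OZ = data.frame(enter = visits$oz_enter, exit = visits$oz_exit),
    WZ = data.frame(enter = visits$wz_enter, exit = visits$wz_exit),
    RZ = data.frame(enter = visits$reward_time, exit = visits$rz_exit))
}

visit_zone_rate <- function(times, intervals) {
  r <- rep(NA_real_, nrow(intervals))
  ok <- is.finite(intervals$enter) & is.finite(intervals$exit) &
    intervals$exit > intervals$enter
  r[ok] <- mapply(function(lo, hi) count_in(times, lo, hi) / (hi - lo),
                  intervals$enter[ok], intervals$exit[ok])
  r
}

#' Correlation between per-visit zone firing rate and a behavioral variable
#'
#' Pearson correlation between the mean firing rate in the given task
#' zone on each visit and the per-visit variable, compared against the
#' distribution of the same correlation under 30 circular shifts of the
#' spike train.
#'
#' @param times spike times (s).
#' @param visits visit table.
#' @param variable per-visit numeric vector (same order as `visits`).
#' @param zone `"OZ"`, `"WZ"` or `"RZ"`.
#' @param n_shuffles,shift_range,period,seed see [shuffle_normalize()].
#' @return one-row data.frame: `r`, `null_mean`, `normalized`, `n`;
#'   `NA` with a warning if rate or variable has zero variance.
#' @export
rate_behavior_correlation <- function(times, visits, variable, zone = "WZ",
                                      n_shuffles = 30,
                                      shift_range = c(60, 3540),
                                      period = 3600, seed = NULL) {
  iv <- zone_bounds(visits, zone)
  ok <- is.finite(iv$enter) & is.finite(iv$exit) & is.finite(variable)
  if (sum(ok) < 3) stop("need >= 3 visits with defined variable", call. = FALSE)
  iv <- iv[ok, , drop = FALSE]; v <- variable[ok]
  stat <- function(tt) {
    r <- visit_zone_rate(tt, iv)
    if (sd(r, na.rm = TRUE) == 0 || sd(v) == 0) return(NA_real_)
    cor(r, v, use = "complete.obs")
  }
  raw <- stat(times)
  if (is.na(raw)) {
    warning("zero-variance rate or variable: correlation undefined")
    return(data.frame(r = NA_real_, null_mean = NA_real_,
                      normalized = NA_real_, n = sum(ok)))
  }
  out <- shuffle_normalize(stat, times, n_shuffles = n_shuffles,
                           shift_range = shift_range, period = period,
                           seed = seed)
  data.frame(r = out$raw, null_mean = out$null_mean,
             normalized = out$normalized, n = sum(ok))
}

step_fit <- function(resid, v) {
  ok <- is.finite(resid) & is.finite(v)
  if (sum(ok) < 3 || sd(v[ok]) == 0) {
    return(list(coef = 0, ve = 0, p = NA_real_, resid = resid,
                degenerate = TRUE))
  }
  fit <- lm(resid ~ v, subset = ok)
  s <- summary(fit)
  new_resid <- resid
  new_resid[ok] <- stats::residuals(fit)
  ve <- s$r.squared
  list(coef = coef(fit)[["v"]], ve = ve,
       p = s$coefficients["v", "Pr(>|t|)"], resid = new_resid,
       degenerate = FALSE)
}

#' Stepwise regression of firing on behavioral variables, fixed order
#'
#' Sequential univariate ordinary-least-squares fits: each variable in
#' the supplied order is fit to the residual rates left by the previous
#' steps. Residual variance is nonincreasing across steps.
#'
#' @param rates per-visit firing rates (one cell).
#' @param X data.frame of per-visit behavioral variables.
#' @param order character vector naming the fitting order (must cover
#'   `names(X)`).
#' @param alpha significance level for the per-step flag, default 0.05.
#' @return data.frame ladder: `step`, `variable`, `coef`,
#'   `var_explained` (share of the residual variance at that step),
#'   `residual_var`, `significant`.
#' @export
stepwise_fixed <- function(rates, X, order = names(X), alpha = 0.05) {
  stopifnot(all(sort(order) == sort(names(X))))
  resid <- rates - mean(rates, na.rm = TRUE)
  out <- vector("list", length(order))
  for (k in seq_along(order)) {
    f <- step_fit(resid, X[[order[k]]])
    if (f$degenerate)
      warning("degenerate step for variable ", order[k], ": coefficient 0")
    resid <- f$resid
    out[[k]] <- data.frame(step = k, variable = order[k], coef = f$coef,
                           var_explained = f$ve,
                           residual_var = var(resid, na.rm = TRUE),
                           significant = !is.na(f$p) && f$p < alpha)
  }
  do.call(rbind, out)
}

#' Stepwise regression, per-cell greedy order
#'
#' At each step the variable explaining the most residual variance
#' enters next (the regression rank); ties resolve in `names(X)` order.
#'
#' @inheritParams stepwise_fixed
#' @return ladder as [stepwise_fixed()], with the greedy `variable` order.
#' @export
stepwise_percell <- function(rates, X, alpha = 0.05) {
  resid <- rates - mean(rates, na.rm = TRUE)
  remaining <- names(X)
  out <- list()
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    ve <- vapply(remaining, function(nm) step_fit(resid, X[[nm]])$ve,
                 numeric(1))
    pick <- remaining[which.max(ve)]   # which.max: first max, config order
    f <- step_fit(resid, X[[pick]])
    resid <- f$resid
    out[[k]] <- data.frame(step = k, variable = pick, coef = f$coef,
                           var_explained = f$ve,
                           residual_var = var(resid, na.rm = TRUE),
                           significant = !is.na(f$p) && f$p < alpha)
    remaining <- setdiff(remaining, pick)
  }
  do.call(rbind, out)
}

#' Net firing-rate choice preference of one cell
#'
#' Mean epoch firing rate on one choice category minus the other
#' (skip - accept for Offer Zone choices, quit - earn for Wait Zone
#' choices).
#'
#' @param times spike times (s).
#' @param visits visit table.
#' @param choice `"oz"` (skip vs accept) or `"wz"` (quit vs earn).
#' @param zone epoch zone over which rates are averaged, default `"OZ"`.
#' @return one-row data.frame: `net_rate`, `preference` (sign label),
#'   `n_a`, `n_b`; `NA` when a category is absent.
#' @export
net_choice_rate <- function(times, visits, choice = c("oz", "wz"),
                            zone = "OZ") {
  choice <- match.arg(choice)
  if (choice == "oz") {
    a <- visits$outcome == "skip"; b <- visits$outcome != "skip"
    lab <- c("skip", "accept")
  } else {
    a <- visits$outcome == "quit"; b <- visits$outcome == "earn"
    lab <- c("quit", "earn")
  }
  if (!any(a) || !any(b)) {
    return(data.frame(net_rate = NA_real_, preference = NA_character_,
                      n_a = sum(a), n_b = sum(b)))
  }
  r <- visit_zone_rate(times, zone_bounds(visits, zone))
  net <- mean(r[a], na.rm = TRUE) - mean(r[b], na.rm = TRUE)
  data.frame(net_rate = net,
             preference = if (net > 0) lab[1] else if (net < 0) lab[2]
               else "none",
             n_a = sum(a), n_b = sum(b))
}

#' Chi-square test of a population choice-preference proportion
#'
#' @param preferences character vector of per-cell preference labels.
#' @param category the category tested against a 50/50 split.
#' @return `chisq.test` result on the 1-df proportion.
#' @export
choice_proportion_test <- function(preferences, category) {
  pref <- preferences[!is.na(preferences) & preferences != "none"]
  k <- sum(pref == category)
  chisq.test(c(k, length(pref) - k), p = c(0.5, 0.5))
}

#' Repeat an analysis on random subsets matched to a target count
#'
#' Cell-count matching (e.g. down to the 72 ACC cells) or pair-count
#' matching (334 within-region / 397 across-region pairs). Sampled
#' indices are sorted, so subsampling the full population without
#' replacement reproduces the unsubsampled result exactly.
#'
#' @param items vector (or list) of unit identifiers to sample from.
#' @param analysis_fn function of a subset of `items` returning any
#'   result.
#' @param target_n subset size, default 72.
#' @param n_iter iterations, default 500.
#' @param replace sample with replacement (required, with a flag, if
#'   `target_n > length(items)`).
#' @param seed RNG seed.
#' @return list of `n_iter` analysis results, with attribute
#'   `"replace_used"`.
#' @export
subsample_match <- function(items, analysis_fn, target_n = 72L,
                            n_iter = 500L, replace = FALSE, seed = 1L) {
  n <- length(items)
  if (target_n > n && !replace)
    stop("target_n exceeds population; set replace = TRUE", call. = FALSE)
  with_seed(seed, {
    out <- vector("list", n_iter)
    for (i in seq_len(n_iter)) {
      idx <- sort(sample.int(n, target_n, replace = replace))
      out[[i]] <- analysis_fn(items[idx])
    }
    attr(out, "replace_used") <- replace
    out
  })
}

#' Recompute an analysis in contiguous session blocks
#'
#' The session is cut into `n_blocks` equal durations (5 blocks of 12 min
#' for TE analyses, 3 blocks of 20 min for MI/firing-rate analyses) and
#' the analysis is recomputed restricted to each.
#'
#' @param analysis_fn function of `(t_start, t_end)` seconds.
#' @param n_blocks 3 or 5.
#' @param session_duration seconds, default 3600.
#' @return list of per-block results; blocks whose analysis errors are
#'   `NA` with the condition message attached.
#' @export
session_blocks <- function(analysis_fn, n_blocks, session_duration = 3600) {
  if (!n_blocks %in% c(3L, 5L))
    stop("n_blocks must be 3 or 5", call. = FALSE)
  edges <- seq(0, session_duration, length.out = n_blocks + 1)
  lapply(seq_len(n_blocks), function(b) {
    tryCatch(analysis_fn(edges[b], edges[b + 1]),
             error = function(e) structure(NA, message = conditionMessage(e)))
  })
}

#' Windows for rate-vs-delay and rate-vs-linger correlations
#'
#' WZ windows are absolute seconds around entry/exit; RZ windows are
#' normalized-PETH bin ranges (3 context bins pre, first and second 10
#' in-zone bins, 3 context bins post).
#'
#' @return named list of window definitions.
#' @export
default_windows <- function() {
  list(
    WZ = list(PreWZ = list(ref = "enter", lo = -1, hi = 0),
              EarlyWZ = list(ref = "enter", lo = 0, hi = 3),
              LateWZ = list(ref = "exit", lo = -3, hi = 0),
              PostWZ = list(ref = "exit", lo = 0, hi = 1)),
    RZ = list(PreRZ = 1:3, EarlyRZ = 4:13, LateRZ = 14:23, PostRZ = 24:26))
}

#' Windowed correlation between population firing and a behavioral bin
#'
#' For each rat, visits are grouped into 6 behavioral bins (offer delay:
#' uniform 5 s bins over 1-30 s; linger: 0-30% of the session's
#' 1st-99th percentile linger range in 5% steps) and a mean rate is
#' computed per bin per analysis window across the rat's cells. Each
#' window's Pearson correlation is computed across the up-to-48
#' (rat x bin) points against the bin centers.
#'
#' @param sessions list of sessions; each a list with `trains` (list of
#'   spike-time vectors), `visits`, and `rat` (id).
#' @param variable `"offer_delay"` or `"linger_fraction"`.
#' @param windows from [default_windows()].
#' @param n_bins behavioral bins, default 6.
#' @return data.frame: `window`, `r`, `n_points`.
#' @export
windowed_rate_correlation <- function(sessions,
                                      variable = c("offer_delay",
                                                   "linger_fraction"),
                                      windows = default_windows(),
                                      n_bins = 6L) {
  variable <- match.arg(variable)
  wz_mode <- variable == "offer_delay"
  wspec <- if (wz_mode) windows$WZ else windows$RZ
  pts <- list()
  for (ses in sessions) {
    visits <- ses$visits
    if (wz_mode) {
      keep <- visits$outcome %in% c("earn", "quit")
      visits <- visits[keep, , drop = FALSE]
      edges <- seq(1, 30, length.out = n_bins + 1)
      bin <- pmin(findInterval(visits$offer_delay, edges,
                               rightmost.closed = TRUE), n_bins)
      centers <- (edges[-1] + edges[-length(edges)]) / 2
    } else {
      keep <- visits$outcome == "earn"
      visits <- visits[keep, , drop = FALSE]
      bounds <- linger_percentile_bounds(visits$linger_time)
      frac <- 100 * (visits$linger_time - bounds[1]) / diff(bounds)
      edges <- seq(0, 30, by = 5)
      inr <- frac >= 0 & frac <= 30
      visits <- visits[inr, , drop = FALSE]
      bin <- pmin(findInterval(frac[inr], edges, rightmost.closed = TRUE),
                  n_bins)
      centers <- (edges[-1] + edges[-length(edges)]) / 2
    }
    if (!nrow(visits)) next
    for (b in seq_len(n_bins)) {
      vb <- visits[bin == b, , drop = FALSE]
      if (nrow(vb) < 2) next
      for (w in names(wspec)) {
        rates <- vapply(ses$trains, function(tt) {
          if (wz_mode) {
            wd <- wspec[[w]]
            ref <- if (wd$ref == "enter") vb$wz_enter else vb$wz_exit
            mean(mapply(function(t0) count_in(tt, t0 + wd$lo, t0 + wd$hi),
                        ref) / (wd$hi - wd$lo))
          } else {
            p <- suppressWarnings(peth(tt, data.frame(
              enter = vb$reward_time, exit = vb$rz_exit,
              pre_enter = vb$wz_enter, post_exit = vb$rz_exit + 2),
              bin_spec("normalized")))
            mean(p$mean[wspec[[w]]], na.rm = TRUE)
          }
        }, numeric(1))
        pts[[length(pts) + 1L]] <- data.frame(
          rat = ses$rat, window = w, bin_center = centers[b],
          rate = mean(rates, na.rm = TRUE))
      }
    }
  }
  pts <- do.call(rbind, pts)
  out <- lapply(split(pts, pts$window), function(d) {
    r <- if (nrow(d) >= 3 && sd(d$rate) > 0 && sd(d$bin_center) > 0)
      cor(d$rate, d$bin_center) else NA_real_
    data.frame(window = d$window[1], r = r, n_points = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
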