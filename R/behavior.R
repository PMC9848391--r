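# Behavioral economics of Restaurant Row: visits, thresholds, subjective
# value, restaurant ranking, and cross-session threshold consistency.

#' Parse an event log into per-visit records
#'
#' One visit per Offer Zone entry. Outcomes: `skip` (never entered the
#' WZ), `quit` (left the WZ before the delay elapsed), `earn` (reward
#' delivered). Reaction time is OZ occupancy; quit time is WZ occupancy
#' for quits; linger time is RZ occupancy after reward delivery.
#'
#' @param events event-log data.frame from [simulate_session()] or a
#'   bundle's `events.csv`.
#' @return A data.frame of visits with timing columns and `outcome`.
#' @export
parse_visits <- function(events) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  if (is.unsorted(events$time_s))
    stop("event log not chronologically ordered near t=",
         events$time_s[which(diff(events$time_s) < 0)[1] + 1L], call. = FALSE)
  starts <- which(events$event == "oz_enter")
  if (length(starts) == 0) stop("no visits (no oz_enter events)", call. = FALSE)
  ends <- c(starts[-1] - 1L, nrow(events))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    ev <- events[starts[k]:ends[k], , drop = FALSE]
    g <- function(name) {
      i <- which(ev$event == name)
      if (length(i) == 0) NA_real_ else ev$time_s[i[1]]
    }
    oz_enter <- g("oz_enter"); oz_exit <- g("oz_exit")
    wz_enter <- g("wz_enter"); wz_exit <- g("wz_exit")
    reward <- g("reward"); rz_exit <- g("rz_exit")
    delay <- ev$offer_delay_s[1]
    bad <- function(msg, t) stop(sprintf(
      "visit parse error at t=%.3f (restaurant %d, lap %d): %s",
      t, ev$restaurant[1], ev$lap[1], msg), call. = FALSE)
    if (is.na(oz_exit)) bad("dangling visit without oz_exit", oz_enter)
    outcome <- if (!is.na(reward)) "earn"
      else if (!is.na(wz_enter) && !is.na(wz_exit)) "quit"
      else if (is.na(wz_enter)) "skip"
      else bad("WZ entered but neither reward nor wz_exit follows",
               wz_enter)
    if (outcome == "earn" && is.na(wz_enter))
      bad("reward without wz_enter", reward)
    if (outcome == "earn") wz_exit <- reward   # WZ/RZ spatially coincident
    out[[k]] <- data.frame(
      restaurant = ev$restaurant[1], lap = ev$lap[1], offer_delay = delay,
      outcome = outcome,
      oz_enter = oz_enter, oz_exit = oz_exit,
      wz_enter = wz_enter, wz_exit = wz_exit,
      reward_time = reward, rz_exit = rz_exit,
      reaction_time = oz_exit - oz_enter,
      quit_time = if (outcome == "quit") wz_exit - wz_enter else NA_real_,
      linger_time = if (outcome == "earn") rz_exit - reward else NA_real_,
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, out)
  qt <- visits$outcome == "quit"
  if (any(qt & !(visits$quit_time < visits$offer_delay)))
    stop("quit_time >= offer delay at t=",
         visits$wz_enter[which(qt & !(visits$quit_time < visits$offer_delay))[1]],
         call. = FALSE)
  visits
}

#' Fit a per-restaurant economic threshold by least-squares Heaviside fit
#'
#' The earn indicator (quits and skips both count as not earned) is fit
#' as a Heaviside step of offer delay: predicted earn iff
#' `delay <= threshold`. Candidates are the odd-half grid
#' `delay_min - 0.5, delay_min + 0.5, ..., delay_max + 0.5`; ties at the
#' minimal sum of squared errors are resolved by the midpoint of the
#' tying run (the longest run if several, with a warning). All-earn and
#' no-earn sessions map to `delay_max + 0.5` and `delay_min - 0.5`.
#'
#' @param visits data.frame of visits for one restaurant.
#' @param delay_range offered delay range, default `c(1, 30)` s.
#' @return A one-row data.frame: `restaurant`, `threshold`, `sse`,
#'   `n_visits`, `n_earned`.
#' @export
fit_threshold <- function(visits, delay_range = c(1, 30)) {
  stopifnot(is.data.frame(visits))
  if (nrow(visits) == 0) stop("no visits to fit", call. = FALSE)
  earned <- as.numeric(visits$outcome == "earn")
  delay <- visits$offer_delay
  restaurant <- visits$restaurant[1]
  grid <- seq(delay_range[1] - 0.5, delay_range[2] + 0.5, by = 1)
  sse <- vapply(grid, function(c) sum((earned - (delay <= c))^2), numeric(1))
  if (all(earned == 1)) {
    thr <- delay_range[2] + 0.5
  } else if (all(earned == 0)) {
    thr <- delay_range[1] - 0.5
  } else {
    amin <- which(sse == min(sse))
    runs <- split(amin, cumsum(c(1, diff(amin) != 1)))
    lens <- lengths(runs)
    if (length(runs) > 1 && sum(lens == max(lens)) > 1)
      warning("multiple tying candidate runs; taking the first longest")
    run <- runs[[which.max(lens)]]
    thr <- mean(grid[range(run)])
  }
  data.frame(restaurant = restaurant, threshold = thr, sse = min(sse),
             n_visits = nrow(visits), n_earned = sum(earned == 1))
}

#' Subjective value of an offer: signed distance from threshold
#'
#' @param threshold restaurant threshold (s).
#' @param delay offered delay (s).
#' @return `threshold - delay`, seconds.
#' @export
subjective_value <- function(threshold, delay) threshold - delay

#' Rank restaurants by decision threshold
#'
#' Rank 1 is the largest threshold (the reward the agent will wait
#' longest for). Exact threshold ties are broken by the larger number of
#' earned rewards; a residual tie falls back to restaurant id order with
#' a warning.
#'
#' @param fits data.frame of [fit_threshold()] rows, one per restaurant.
#' @return `fits` with a `rank` column, ordered rank 1 first.
#' @export
rank_restaurants <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1)
  key <- order(-fits$threshold, -fits$n_earned, fits$restaurant)
  dup <- duplicated(fits[, c("threshold", "n_earned")]) |
    duplicated(fits[, c("threshold", "n_earned")], fromLast = TRUE)
  if (any(dup))
    warning("threshold and earn-count tie; falling back to restaurant id order")
  out <- fits[key, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold consistency across sessions
#'
#' Compares the variance of each restaurant's threshold across sessions
#' with the variance across restaurants within each session, and
#' correlates the 4-element threshold vectors between every pair of
#' sessions.
#'
#' @param threshold_matrix numeric matrix, sessions in rows, restaurants
#'   in columns.
#' @return list with `across_session_var` (per restaurant),
#'   `within_session_var` (per session), and `correlation`
#'   (session-by-session Pearson matrix; `NA` where a vector is constant).
#' @export
threshold_consistency <- function(threshold_matrix) {
  m <- as.matrix(threshold_matrix)
  if (nrow(m) < 2) stop("need at least 2 sessions", call. = FALSE)
  cors <- suppressWarnings(cor(t(m)))
  list(across_session_var = apply(m, 2, var),
       within_session_var = apply(m, 1, var),
       correlation = cors)
}

#' Per-session linger-time clipping bounds (1st-99th percentile)
#'
#' @param linger numeric vector of linger times for one session.
#' @return length-2 numeric, the 1st and 99th percentiles.
#' @export
linger_percentile_bounds <- function(linger) {
  linger <- linger[is.finite(linger)]
  quantile(linger, c(0.01, 0.99), names = FALSE)
}
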