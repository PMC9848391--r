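# Synthetic Restaurant Row sessions: a threshold-governed agent foraging
# among 4 reward sites, producing the behavioral event log that the rest of
# the pipeline consumes.

#' Configuration for a synthetic Restaurant Row session
#'
#' The task: on each restaurant visit a delay offer (integer seconds,
#' uniform on `delay_range`) is cued in the Offer Zone (OZ). The agent
#' accepts (moves to the Wait Zone, WZ) with probability
#' `plogis(accept_noise * (threshold - delay))`; an accepted offer is
#' earned when the full delay elapses, unless the agent quits first.
#' Quitting follows a constant hazard `quit_hazard_scale *
#' exp(-(threshold - delay) / 4)` per second: negligible for offers well
#' above threshold, appreciable for marginal and bad accepted offers. After an earn the agent lingers
#' in the Reward Zone (RZ) for a log-normal time, then travels through the
#' Transition Zone (TZ) to the next restaurant.
#'
#' @param n_restaurants number of reward sites (4 in the task).
#' @param session_duration session length in seconds (1 hr task).
#' @param delay_range integer second range of offers, default `c(1, 30)`.
#' @param thresholds per-restaurant decision thresholds in seconds; the
#'   delay below which the agent reliably earns.
#' @param accept_noise logistic slope (1/s of subjective value). `Inf`
#'   gives a noiseless step-function agent.
#' @param quit_hazard_scale per-second hazard per second of negative value.
#' @param linger_distribution list with `meanlog`, `sdlog` (log-seconds)
#'   and `value_coef` (shift of `meanlog` per second of value).
#' @param reaction_distribution list with `meanlog`, `sdlog`, `value_coef`
#'   (negative: better offers get faster OZ decisions).
#' @param travel_time seconds spent in the TZ between restaurants.
#' @param seed integer RNG seed.
#' @return A `session_config` list.
#' @export
session_config <- function(n_restaurants = 4L,
                           session_duration = 3600,
                           delay_range = c(1L, 30L),
                           thresholds = c(22, 17, 12, 7),
                           accept_noise = 1.5,
                           quit_hazard_scale = 0.05,
                           linger_distribution = list(meanlog = log(5),
                                                      sdlog = 0.5,
                                                      value_coef = 0.02),
                           reaction_distribution = list(meanlog = log(1.2),
                                                        sdlog = 0.35,
                                                        value_coef = -0.01),
                           travel_time = 4,
                           seed = 1L) {
  assert_that(session_duration > 0, "session_duration must be > 0")
  assert_that(length(delay_range) == 2 && delay_range[1] >= 0 &&
                delay_range[2] >= delay_range[1],
              "delay_range must be an increasing pair")
  assert_that(length(thresholds) == n_restaurants,
              "need one threshold per restaurant")
  assert_that(all(thresholds >= delay_range[1] - 0.5) &&
                all(thresholds <= delay_range[2] + 0.5),
              "thresholds must lie within delay_range (or at its edges)")
  if (travel_time + delay_range[1] >= session_duration)
    stop("no visit can complete: travel_time + minimum delay exceeds ",
         "session_duration", call. = FALSE)
  structure(list(n_restaurants = as.integer(n_restaurants),
                 session_duration = session_duration,
                 delay_range = as.integer(delay_range),
                 thresholds = thresholds,
                 accept_noise = accept_noise,
                 quit_hazard_scale = quit_hazard_scale,
                 linger_distribution = linger_distribution,
                 reaction_distribution = reaction_distribution,
                 travel_time = travel_time,
                 seed = as.integer(seed)),
            class = "session_config")
}

p_accept <- function(value, slope) {
  # noiseless agent follows the Heaviside convention: accept at value 0
  if (is.infinite(slope)) return(ifelse(value >= 0, 1, 0))
  plogis(slope * value)
}

#' Simulate one Restaurant Row session
#'
#' Generates a chronologically ordered behavioral event log of
#' OZ -> (WZ -> (RZ | quit) | skip) -> TZ cycles until the session clock
#' runs out. Earned rewards are delivered exactly when the elapsed WZ time
#' equals the offered delay; quit times are strictly less than the
#' accepted delay. Timestamps are on a 1 ms grid.
#'
#' @param config a [session_config()].
#' @return A data.frame event log with columns `time_s`, `event`
#'   (`oz_enter`, `oz_exit`, `wz_enter`, `wz_exit`, `reward`, `rz_exit`,
#'   `tz_enter`), `restaurant`, `lap`, `offer_delay_s`; the config is
#'   attached as attribute `"config"`.
#' @export
simulate_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    dur <- config$session_duration
    rows <- list(); nr <- 0L
    add <- function(time, event, restaurant, lap, delay) {
      nr <<- nr + 1L
      rows[[nr]] <<- list(time_s = snap_ms(time), event = event,
                          restaurant = restaurant, lap = lap,
                          offer_delay_s = delay)
    }
    t <- 0; lap <- 1L; r <- 1L
    repeat {
      delay <- sample(seq(config$delay_range[1], config$delay_range[2]), 1L)
      value <- config$thresholds[r] - delay
      rd <- config$reaction_distribution
      reaction <- rlnorm(1, rd$meanlog + rd$value_coef * value, rd$sdlog)
      reaction <- max(reaction, 0.2)
      accept <- runif(1) < p_accept(value, config$accept_noise)
      # project the visit; commit it only if it completes within the session
      ev <- list()
      push <- function(time, event) ev[[length(ev) + 1L]] <<- c(time, event)
      t0 <- t
      push(t0, "oz_enter")
      t1 <- t0 + reaction
      push(t1, "oz_exit")
      if (!accept) {
        push(t1, "tz_enter")
        t_end <- t1 + config$travel_time
      } else {
        push(t1, "wz_enter")
        hz <- config$quit_hazard_scale * exp(-value / 4)
        quit_at <- if (hz > 0) rexp(1, hz) else Inf
        if (quit_at < delay) {
          # keep the strict quit_time < delay invariant on the 1 ms grid
          qt <- min(snap_ms(quit_at), delay - 0.001)
          push(t1 + qt, "wz_exit")
          push(t1 + qt, "tz_enter")
          t_end <- t1 + qt + config$travel_time
        } else {
          tr <- snap_ms(t1) + delay   # exact: WZ duration == delay
          push(tr, "reward")
          ld <- config$linger_distribution
          linger <- rlnorm(1, ld$meanlog + ld$value_coef * value, ld$sdlog)
          linger <- max(linger, 0.25)
          push(tr + linger, "rz_exit")
          push(tr + linger, "tz_enter")
          t_end <- tr + linger + config$travel_time
        }
      }
      if (t_end > dur) break
      for (e in ev) add(as.numeric(e[1]), e[2], r, lap, delay)
      t <- t_end
      r <- r + 1L
      if (r > config$n_restaurants) { r <- 1L; lap <- lap + 1L }
    }
    if (nr == 0L) stop("session too short for a single visit", call. = FALSE)
    rows <- rows[seq_len(nr)]
    out <- data.frame(
      time_s = vapply(rows, function(x) x$time_s, numeric(1)),
      event = vapply(rows, function(x) x$event, character(1)),
      restaurant = vapply(rows, function(x) x$restaurant, integer(1)),
      lap = vapply(rows, function(x) x$lap, integer(1)),
      offer_delay_s = vapply(rows, function(x) x$offer_delay_s, numeric(1)),
      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    out
  })
}
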