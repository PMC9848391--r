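# behavior: visit parsing, Heaviside threshold fit, value, ranks.

test_that("parse_visits computes the worked timing examples", {
  v <- parse_visits(tiny_events())
  expect_equal(v$outcome, c("earn", "skip", "quit"))
  expect_equal(v$reaction_time, c(2.5, 3.0, 2.0))
  expect_equal(v$linger_time[1], 7.5)
  expect_equal(v$quit_time[3], 6.0)
  expect_true(is.na(v$wz_enter[2]))
  # earn: wz_exit coincides with reward delivery
  expect_equal(v$wz_exit[1], v$reward_time[1])
})

test_that("parse_visits rejects malformed logs with the offending time", {
  ev <- tiny_events()
  ev$time_s[4] <- 5   # out of order
  expect_error(parse_visits(ev), "not chronologically ordered")
  ev2 <- tiny_events()[1:2, ]   # dangling OZ without outcome
  ev2 <- rbind(ev2, data.frame(time_s = 13, event = "wz_enter",
                               restaurant = 1L, lap = 1L,
                               offer_delay_s = 10))
  expect_error(parse_visits(ev2), "t=13")
})

test_that("fit_threshold reproduces the worked tie-break example", {
  v <- fake_visits(5, outcomes = c("earn", "earn", "earn", "skip", "skip"),
                   delays = c(2, 5, 10, 20, 28))
  f <- fit_threshold(v)
  expect_equal(f$threshold, 15.0)
  expect_equal(f$sse, 0)
  expect_equal(f$n_earned, 3L)
})

test_that("degenerate sessions map to the range edges", {
  all_earn <- fake_visits(6, outcomes = rep("earn", 6),
                          delays = c(3, 9, 12, 20, 25, 28))
  expect_equal(fit_threshold(all_earn)$threshold, 30.5)
  none <- fake_visits(6, outcomes = rep("skip", 6),
                      delays = c(3, 9, 12, 20, 25, 28))
  expect_equal(fit_threshold(none)$threshold, 0.5)
  expect_error(fit_threshold(fake_visits(0, outcomes = character(0),
                                         delays = numeric(0))))
})

test_that("fitted threshold attains the grid-minimal SSE on random data", {
  grid <- seq(0.5, 30.5, by = 1)
  for (s in 1:5) {
    set.seed(s)
    v <- fake_visits(100, outcomes = sample(c("earn", "skip"), 100, TRUE),
                     seed = s)
    f <- fit_threshold(v)
    earned <- as.numeric(v$outcome == "earn")
    sse_at <- vapply(grid, function(c) sum((earned - (v$offer_delay <= c))^2),
                     numeric(1))
    expect_true(all(f$sse <= sse_at))
    # invariance to order and duplication
    expect_equal(fit_threshold(v[sample(nrow(v)), ])$threshold, f$threshold)
    expect_equal(fit_threshold(rbind(v, v))$threshold, f$threshold)
  }
})

test_that("noiseless agent recovery is within half a grid step", {
  # pool three sessions of the same agent so every delay adjacent to a
  # threshold is observed (a single session can miss one of the 30
  # integer delays at a restaurant, which widens the tie run)
  cfg <- session_config(thresholds = c(25, 18, 11, 4), accept_noise = Inf,
                        quit_hazard_scale = 0, seed = 12)
  v <- do.call(rbind, lapply(12:14, function(s) parse_visits(
    simulate_session(session_config(thresholds = cfg$thresholds,
                                    accept_noise = Inf,
                                    quit_hazard_scale = 0, seed = s)))))
  expect_true(all(table(v$restaurant) >= 40))
  fits <- do.call(rbind, lapply(split(v, v$restaurant), fit_threshold))
  expect_true(all(abs(fits$threshold - cfg$thresholds) <= 0.5))
  ranked <- rank_restaurants(fits)
  expect_equal(ranked$restaurant, 1:4)
})

test_that("subjective value is the signed distance from threshold", {
  expect_equal(subjective_value(12, 5), 7)
  expect_equal(subjective_value(12, 12), 0)
  expect_equal(subjective_value(3, 30), -27)
  for (thr in c(0.5, 13, 30.5)) for (d in c(1, 17, 30))
    expect_identical(subjective_value(thr, d) + d, thr)
})

test_that("rank_restaurants applies the earn-count tie-break", {
  fits <- data.frame(restaurant = 1:4, threshold = c(20, 12, 12, 5),
                     sse = 0, n_visits = 50, n_earned = c(45, 40, 10, 3))
  r <- rank_restaurants(fits)
  expect_equal(r$restaurant, c(1, 2, 3, 4))
  expect_equal(r$rank, 1:4)
  # full tie falls back to id order with a warning
  fits$threshold <- 10; fits$n_earned <- 5
  expect_warning(r2 <- rank_restaurants(fits), "tie")
  expect_equal(r2$restaurant, 1:4)
})

test_that("threshold consistency separates within-rat from between-rat", {
  expect_error(threshold_consistency(matrix(1:4, 1)), "2 sessions")
  m <- matrix(rep(c(20, 15, 10, 5), 3), nrow = 3, byrow = TRUE)
  out <- threshold_consistency(m)
  expect_equal(unname(out$across_session_var), rep(0, 4))
  expect_true(all(out$correlation == 1))
  # planted rat-specific vectors + jitter: within-rat correlations beat
  # between-rat on average over draws
  set.seed(42)
  ratA <- c(25, 18, 10, 4); ratB <- c(6, 22, 14, 28)
  win <- btw <- c()
  for (i in 1:50) {
    a1 <- ratA + rnorm(4); a2 <- ratA + rnorm(4); b1 <- ratB + rnorm(4)
    cc <- threshold_consistency(rbind(a1, a2, b1))$correlation
    win <- c(win, cc[1, 2]); btw <- c(btw, cc[1, 3], cc[2, 3])
  }
  expect_gt(mean(win), mean(btw) + 0.5)
  # unrelated random vectors: mean between-rat correlation near 0
  set.seed(9)
  r0 <- replicate(400, threshold_consistency(
    matrix(runif(8, 1, 30), 2, byrow = TRUE))$correlation[1, 2])
  expect_lt(abs(mean(r0)), 0.1)
})
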