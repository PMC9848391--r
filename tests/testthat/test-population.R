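# population_stats: correlations, stepwise regressions, choice
# preferences, subsampling, session blocks, windowed correlations.

test_that("rate_behavior_correlation recovers a perfect linear relation", {
  v <- fake_visits(30, outcomes = rep("earn", 30))
  # spikes at a rate proportional to the delay inside each WZ interval
  tt <- sort(unlist(mapply(function(lo, hi, d) {
    seq(lo, hi, length.out = max(2, round(2 * d * (hi - lo))))
  }, v$wz_enter, v$wz_exit, v$offer_delay)))
  r <- rate_behavior_correlation(tt, v, v$offer_delay, zone = "WZ",
                                 seed = 2)
  expect_gt(r$r, 0.99)
  expect_warning(
    r0 <- rate_behavior_correlation(tt, v, rep(5, 30), zone = "WZ",
                                    seed = 2),
    "undefined")
  expect_true(is.na(r0$r))
  expect_error(rate_behavior_correlation(tt, v[1:2, ], v$offer_delay[1:2]),
               ">= 3")
})

test_that("untuned cell correlation sits inside the shuffled null", {
  v <- fake_visits(60, outcomes = rep("earn", 60))
  tt <- poisson_train(5, seed = 33)
  r <- rate_behavior_correlation(tt, v, v$offer_delay, zone = "WZ",
                                 seed = 3)
  expect_lt(abs(r$r), 0.35)
  expect_lt(abs(r$normalized), 0.4)
})

test_that("stepwise_fixed recovers planted slopes regardless of order", {
  set.seed(41)
  n <- 200
  X <- data.frame(v1 = rnorm(n), v2 = rnorm(n))
  rates <- 2 * X$v1 + 0.8 * X$v2 + rnorm(n, 0, 0.3)
  for (ord in list(c("v1", "v2"), c("v2", "v1"))) {
    lad <- stepwise_fixed(rates, X, order = ord)
    co <- lad$coef[match(c("v1", "v2"), lad$variable)]
    expect_equal(co, c(2, 0.8), tolerance = 0.1)
    expect_true(all(diff(lad$residual_var) <= 1e-12))
  }
  # rate depends only on the second-entered variable
  rates2 <- 1.5 * X$v2 + rnorm(n, 0, 0.2)
  lad2 <- stepwise_fixed(rates2, X, order = c("v1", "v2"))
  expect_lt(abs(lad2$coef[1]), 0.15)
  expect_equal(lad2$coef[2], 1.5, tolerance = 0.1)
  expect_false(lad2$significant[1] && lad2$var_explained[1] > 0.05)
})

test_that("stepwise_percell enters the dominant variable first", {
  set.seed(42)
  n <- 200
  X <- data.frame(weak = rnorm(n), strong = rnorm(n))
  rates <- 3 * X$strong + 0.3 * X$weak + rnorm(n, 0, 0.5)
  lad <- stepwise_percell(rates, X)
  expect_equal(lad$variable, c("strong", "weak"))
  expect_true(all(diff(lad$residual_var) <= 1e-12))
  # exact tie resolves in config order (first column)
  Xt <- data.frame(a = X$strong, b = X$strong)
  # perfect collinear fit at step 1 leaves zero residual variance;
  # summary()'s perfect-fit warning is expected
  ladt <- suppressWarnings(stepwise_percell(3 * X$strong, Xt))
  expect_equal(ladt$variable[1], "a")
  # pure-noise cell: significant steps are rare
  set.seed(43)
  sig <- replicate(40, any(stepwise_percell(rnorm(n), X)$significant))
  expect_lt(mean(sig), 0.35)
})

test_that("net_choice_rate signs the skip-accept difference", {
  v <- fake_visits(40, outcomes = rep(c("skip", "earn"), 20))
  # cell firing only during skip-visit OZ occupancy
  skips <- v[v$outcome == "skip", ]
  tt <- sort(unlist(mapply(seq, skips$oz_enter, skips$oz_exit,
                           MoreArgs = list(by = 0.05))))
  r <- net_choice_rate(tt, v, "oz")
  expect_gt(r$net_rate, 0)
  expect_equal(r$preference, "skip")
  # absent category -> undefined
  allskip <- fake_visits(10, outcomes = rep("skip", 10))
  expect_true(is.na(net_choice_rate(tt, allskip, "oz")$net_rate))
})

test_that("population choice-preference proportion test", {
  set.seed(44)
  pref <- ifelse(runif(100) < 0.68, "skip", "accept")
  ts <- choice_proportion_test(pref, "skip")
  expect_lt(ts$p.value, 0.05)
  bal <- rep(c("skip", "accept"), 50)
  expect_gt(choice_proportion_test(bal, "skip")$p.value, 0.9)
})

test_that("subsample identity and determinism contracts", {
  items <- 1:30
  stat <- function(s) mean(s)
  full <- subsample_match(items, stat, target_n = 30, n_iter = 3, seed = 9)
  expect_true(all(vapply(full, identical, logical(1), stat(items))))
  a <- subsample_match(items, stat, target_n = 10, n_iter = 20, seed = 5)
  b <- subsample_match(items, stat, target_n = 10, n_iter = 20, seed = 5)
  expect_identical(a, b)
  expect_error(subsample_match(items, stat, target_n = 50), "replace")
  with_rep <- subsample_match(items, stat, target_n = 50, n_iter = 2,
                              replace = TRUE, seed = 1)
  expect_true(attr(with_rep, "replace_used"))
})

test_that("session blocks partition the session and validate n_blocks", {
  expect_error(session_blocks(function(a, b) NULL, 4), "3 or 5")
  got <- list()
  out <- session_blocks(function(a, b) c(a, b), 5)
  edges <- do.call(rbind, out)
  expect_equal(edges[, 1], seq(0, 2880, by = 720))
  expect_equal(edges[, 2], seq(720, 3600, by = 720))
  expect_equal(edges[-1, 1], edges[-5, 2])   # no overlap, no gap
  # stationary ensemble: block rates statistically flat
  tt <- poisson_train(6, seed = 55)
  rates <- unlist(session_blocks(function(a, b)
    sum(tt >= a & tt < b) / (b - a), 3))
  expect_lt(max(rates) - min(rates), 0.5)
  # planted early-session elevation shows in block 1 vs 3
  e <- simulate_session(session_config(seed = 45))
  ens <- simulate_ensemble(e, ensemble_config(
    n_cells = 1, tuning = data.frame(time_slope = -0.8), seed = 46))
  t2 <- spike_trains(ens$spikes, 1)[[1]]
  r2 <- unlist(session_blocks(function(a, b)
    sum(t2 >= a & t2 < b) / (b - a), 3))
  expect_gt(r2[1], r2[3])
})

test_that("windowed correlation finds delay tuning in the right window", {
  # rates proportional to offer delay in EarlyWZ only
  sessions <- lapply(1:4, function(rat) {
    set.seed(rat)
    v <- fake_visits(120, outcomes = rep("earn", 120), seed = rat)
    dur <- max(v$rz_exit, na.rm = TRUE) + 10
    bg <- sort(runif(rpois(1, 2 * dur), 0, dur))   # 2 Hz background
    tt <- sort(c(bg, unlist(mapply(function(wz, d) {
      n <- rpois(1, 2 * d * 3)
      runif(n, wz, wz + 3)
    }, v$wz_enter, v$offer_delay))))
    list(trains = list(tt), visits = v, rat = rat)
  })
  out <- windowed_rate_correlation(sessions, "offer_delay")
  expect_gt(out$r[out$window == "EarlyWZ"], 0.8)
  expect_lt(abs(out$r[out$window == "PreWZ"]), 0.4)
  expect_true(all(out$n_points <= 4 * 6))
})
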