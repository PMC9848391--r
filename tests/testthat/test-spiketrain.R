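# spiketrain_core: basic properties, classification, circular shifts,
# shuffle normalization, PETHs.

test_that("basic properties of a periodic train", {
  tt <- seq(0.025, 3600, by = 0.05)   # 20 Hz metronome, 1 spike per 50 ms bin
  p <- basic_properties(tt, spike_width_us = 480)
  expect_equal(p$mean_rate, length(tt) / 3600)
  expect_lt(p$cv, 1e-10)              # identical count in every bin
  expect_equal(p$median_isi, 0.05)
  # ISIs neither short (<10 ms) nor long (>125 ms): ratio undefined, not 0
  expect_true(is.na(p$burst_ratio))
  # train with long ISIs present but no short ones: ratio exactly 0
  p2 <- basic_properties(seq(0.1, 3600, by = 0.2))
  expect_equal(p2$burst_ratio, 0)
})

test_that("Poisson train ISI stats match the exponential closed form", {
  tt <- poisson_train(5, seed = 77)
  p <- basic_properties(tt)
  expect_lt(abs(p$median_isi - log(2) / 5), 0.01)
  expect_lt(abs(p$cv - sqrt(1 / (5 * 0.05))), 0.2)  # count CV ~ 1/sqrt(lambda)
})

test_that("degenerate trains flag ISI fields instead of faking zeros", {
  p1 <- basic_properties(c(0.000, 0.005))
  expect_true(is.na(p1$burst_ratio))   # 1 short ISI over 0 long ones
  p2 <- basic_properties(1.5)
  expect_false(p2$isi_defined)
  expect_true(is.na(p2$median_isi))
})

test_that("classification is a deterministic side-of-line rule", {
  expect_equal(classify_cell(15, 220), "interneuron")
  expect_equal(classify_cell(1, 520), "principal")
  # planted bimodal population recovered at >= 95%
  set.seed(3)
  n <- 400
  is_int <- runif(n) < 0.3
  width <- ifelse(is_int, rnorm(n, 220, 30), rnorm(n, 500, 50))
  rate <- ifelse(is_int, runif(n, 6, 25), runif(n, 0.5, 8))
  cls <- classify_cell(rate, width)
  agree <- mean((cls == "interneuron") == is_int)
  expect_gte(agree, 0.95)
})

test_that("circular shifting preserves counts and the ISI multiset", {
  tt <- poisson_train(4, seed = 5)
  sh <- circular_shift(tt, 1234.5)
  expect_equal(length(sh), length(tt))
  expect_false(is.unsorted(sh))
  # all but the wrap ISI are preserved
  isi0 <- sort(diff(tt)); isi1 <- sort(diff(sh))
  expect_gte(sum(round(isi1, 9) %in% round(isi0, 9)), length(isi1) - 2)
})

test_that("shuffle_normalize of the spike count is exactly zero", {
  tt <- poisson_train(3, seed = 6)
  out <- shuffle_normalize(length, tt, n_shuffles = 30, seed = 2)
  expect_equal(out$normalized, 0)
  expect_error(shuffle_normalize(length, tt, n_shuffles = 0), "n_shuffles")
  expect_true(all(out$shifts >= 60 & out$shifts <= 3540))
})

test_that("shuffle_normalize centers an untuned window rate at zero", {
  window_rate <- function(x) sum(x >= 1000 & x < 1100) / 100
  vals <- vapply(1:12, function(s) {
    tt <- poisson_train(5, seed = 100 + s)
    shuffle_normalize(window_rate, tt, seed = s)$normalized
  }, numeric(1))
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)) + 0.05)
})

test_that("absolute PETH recovers a flat rate and a locked response", {
  tt <- poisson_train(10, seed = 8)
  al <- seq(100, 3500, by = 40)
  p <- peth(tt, al, bin_spec("absolute", window = c(-1, 1), binwidth = 0.1))
  expect_equal(length(p$mean), 20)
  expect_true(all(abs(p$mean - 10) < 2))
  # empty train -> all-zero PETH
  p0 <- peth(numeric(0), al, bin_spec("absolute"))
  expect_true(all(p0$mean == 0))
  # event-locked cell: normalized PETH peak positive at the locked bin
  locked <- sort(c(poisson_train(1, seed = 9),
                   rep(al, each = 2) + runif(2 * length(al), 0, 0.1)))
  out <- peth_normalized(locked, al,
                         bin_spec("absolute", window = c(-1, 1)), seed = 3)
  expect_gt(out$normalized[11], 1)   # bin [0, 0.1) after the event
  expect_equal(which.max(out$normalized), 11)
})

test_that("normalized PETH bins by fraction of zone time", {
  # single 2 s visit, spikes only in the first 0.1 s of the zone
  ev <- data.frame(enter = 10, exit = 12, pre_enter = 9, post_exit = 13)
  tt <- c(10.01, 10.05, 10.09)
  p <- peth(tt, ev, bin_spec("normalized"))
  expect_equal(length(p$mean), 26)
  expect_equal(p$mean[4], 3 / 0.1)   # first in-zone bin (after 3 context)
  expect_true(all(p$mean[5:23] == 0))
  # too-short visit dropped with warning
  ev2 <- rbind(ev, data.frame(enter = 20, exit = 20.005, pre_enter = 19,
                              post_exit = 21))
  expect_warning(p2 <- peth(tt, ev2, bin_spec("normalized")), "dropped")
  expect_equal(p2$n_visits, 1L)
})

test_that("peth across concatenated visit sets is the visit-weighted mean", {
  tt <- poisson_train(6, seed = 11)
  a1 <- seq(200, 1000, by = 37); a2 <- seq(1500, 3300, by = 53)
  sp <- bin_spec("absolute", window = c(-0.5, 0.5))
  p1 <- peth(tt, a1, sp); p2 <- peth(tt, a2, sp)
  p12 <- peth(tt, c(a1, a2), sp)
  expect_equal(p12$mean,
               (length(a1) * p1$mean + length(a2) * p2$mean) /
                 (length(a1) + length(a2)))
})
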