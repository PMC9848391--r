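# infoflow: TE estimator, surrogate normalization, spatial aggregation,
# boundary detection, subregion statistics, phase restriction.

test_that("bin_spikes binarizes on the 10 ms grid", {
  v <- bin_spikes(c(0.005, 0.012), session_duration = 1)
  expect_equal(which(v == 1L), c(1L, 2L))
  expect_equal(length(v), 100)
  expect_true(all(bin_spikes(numeric(0), session_duration = 1) == 0L))
  # multi-spike bins collapse to 1
  burst <- seq(1.0005, 1.05, by = 0.005)   # 200 Hz burst
  vb <- bin_spikes(burst, session_duration = 2)
  expect_true(all(vb[101:105] == 1L))
  expect_equal(sum(vb), 5)
})

test_that("transfer entropy matches the brute-force oracle", {
  # hand-built 20-symbol pair
  x <- c(1,0,1,1,0,0,1,0,1,1,0,1,0,0,1,1,1,0,0,1)
  y <- c(0,1,0,1,1,0,0,1,0,1,1,0,1,0,0,1,1,1,0,0)
  expect_equal(transfer_entropy(x, y), te_oracle(x, y), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:200) {
    n <- sample(5:20, 1)
    x <- rbinom(n, 1, runif(1, .2, .8)); y <- rbinom(n, 1, runif(1, .2, .8))
    expect_equal(transfer_entropy(x, y), te_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(transfer_entropy(c(1, 0), c(0, 1)), "length >= 3")
})

test_that("TE analytic limits: lag-copy 1 bit, self-copy 0, constant X 0", {
  set.seed(15)
  x <- rbinom(1e5, 1, 0.5)
  y <- c(0L, x[-1e5])
  expect_lt(abs(transfer_entropy(x, y) - 1), 0.02)
  expect_identical(transfer_entropy(x, rep(1L, 1e5)), 0)       # y self-det.
  expect_identical(transfer_entropy(rep(0L, 1e5), y), 0)       # constant x
  # asymmetry on the lag-copy pair
  expect_gt(transfer_entropy(x, y) - transfer_entropy(y, x), 0.5)
  # invariance to relabeling of X symbols
  expect_equal(transfer_entropy(x, y), transfer_entropy(1L - x, y),
               tolerance = 1e-12)
})

test_that("te_normalized: zero-spike input and surrogate centering", {
  t2 <- poisson_train(5, seed = 16)
  z <- te_normalized(numeric(0), t2, seed = 1)
  expect_equal(z$norm_te, 0)
  nt <- vapply(1:12, function(s)
    te_normalized(poisson_train(4, seed = 200 + s),
                  poisson_train(4, seed = 300 + s), seed = s)$norm_te,
    numeric(1))
  expect_lt(abs(mean(nt)), 2 * sd(nt) / sqrt(12) + 1e-5)
})

test_that("planted coupled pair yields clearly positive normalized TE", {
  pos <- vapply(1:5, function(s) {
    e <- simulate_session(session_config(seed = s))
    ens <- simulate_ensemble(e, ensemble_config(
      n_cells = 2,
      coupling = data.frame(input = 1, recipient = 2, lag_bins = 1,
                            excess_prob = 0.3), seed = s + 50))
    tr <- spike_trains(ens$spikes, 2)
    te_normalized(tr[[1]], tr[[2]], seed = s)$norm_te
  }, numeric(1))
  expect_true(all(pos > 0))
  expect_gt(min(pos), 1e-3)
})

test_that("te_spatial_map conserves pairs and respects direction", {
  cells <- data.frame(cell_id = 1:4, dv_um = c(50, 150, 950, 1000))
  pairs <- data.frame(input_id = c(1, 2, 3, 4, 1),
                      recipient_id = c(2, 1, 4, 3, 3),
                      norm_te = c(.1, .2, .3, .5, .9))
  map <- te_spatial_map(pairs, cells)
  expect_equal(sum(map$count), nrow(pairs))
  # direction: (1->2) and (2->1) occupy transposed bins
  expect_equal(map$mean[1, 2], .1)
  expect_equal(map$mean[2, 1], .2)
  # both cells of the deep pair share one bin
  expect_equal(map$mean[10, 10], mean(c(.3, .5)))
  expect_equal(map$count[1, 10], 1L)
})

test_that("diagonal_profile averages occupied bins near the diagonal", {
  cells <- data.frame(cell_id = 1:2, dv_um = c(0, 1000))
  pairs <- data.frame(input_id = c(1, 2), recipient_id = c(2, 1),
                      norm_te = c(1, 1))
  # constant map -> constant profile where defined
  allp <- expand.grid(input_id = 1:2, recipient_id = 1:2)
  allp <- allp[allp$input_id != allp$recipient_id, ]
  allp$norm_te <- 0.7
  prof <- diagonal_profile(te_spatial_map(allp, cells), window = 2000)
  expect_true(all(abs(prof$value - 0.7) < 1e-12))
  # single occupied on-diagonal bin: defined only within the window
  one <- data.frame(input_id = 1, recipient_id = 2, norm_te = 0.4)
  cells2 <- data.frame(cell_id = 1:2, dv_um = c(500, 510))
  map2 <- te_spatial_map(one, cells2,
                         origin = 0)
  prof2 <- diagonal_profile(map2, window = 200)
  expect_true(all(is.na(prof2$value[abs(prof2$depth_um - 550) > 250])))
  expect_true(all(prof2$value[abs(prof2$depth_um - 550) <= 150] == 0.4))
})

test_that("find_boundaries detects interior minima with guards", {
  prof <- structure(data.frame(depth_um = seq(100, 700, by = 100),
                               value = c(3, 1, 3, 1, 3, 1, 3)),
                    class = c("rrow_dvprofile", "data.frame"))
  b <- find_boundaries(prof, min_separation = 0, min_prominence = 0)
  expect_equal(b$boundary_depths, c(200, 400, 600))
  expect_equal(b$labels, c("ACC", "dPL", "vPL", "IL"))
  # strictly monotone profile: no boundaries, single region
  mono <- structure(data.frame(depth_um = seq(100, 700, by = 100),
                               value = 1:7),
                    class = c("rrow_dvprofile", "data.frame"))
  b2 <- find_boundaries(mono)
  expect_length(b2$boundary_depths, 0)
  expect_equal(b2$labels, "region_1")
  # plateau minimum reports its midpoint
  plat <- structure(data.frame(depth_um = seq(100, 800, by = 100),
                               value = c(3, 3, 1, 1, 3, 1, 0.5, 3)),
                    class = c("rrow_dvprofile", "data.frame"))
  b3 <- find_boundaries(plat, min_separation = 0, min_prominence = 0,
                        refine = FALSE)
  expect_equal(b3$boundary_depths, c(350, 700))
  # separation guard keeps the deeper of two close valleys
  b4 <- find_boundaries(plat, min_separation = 400, min_prominence = 0,
                        refine = FALSE)
  expect_equal(b4$boundary_depths, 700)
  # parabolic refinement: symmetric minima unmoved, asymmetric ones
  # shift toward the lower flank, never more than half a grid step
  asym <- structure(data.frame(depth_um = seq(100, 700, by = 100),
                               value = c(5, 4, 1, 2, 5, 5, 6)),
                    class = c("rrow_dvprofile", "data.frame"))
  br <- find_boundaries(asym, min_prominence = 0)
  expect_gt(br$boundary_depths, 300)   # pulled toward the lower (2) flank
  expect_lte(br$boundary_depths, 350)  # bounded by half a step
  expect_equal(find_boundaries(prof, min_separation = 0,
                               min_prominence = 0)$boundary_depths,
               c(200, 400, 600))              # symmetric: unmoved
  expect_error(find_boundaries(mono[1:3, ]), ">= 5")
})

test_that("assign_subregions puts boundary cells in the dorsal interval", {
  cells <- data.frame(cell_id = 1:5,
                      dv_um = c(100, 750, 751, 2250, 2900))
  b <- structure(list(boundary_depths = c(750, 1500, 2250),
                      labels = c("ACC", "dPL", "vPL", "IL")),
                 class = "rrow_bounds")
  lab <- assign_subregions(cells, b)
  expect_equal(as.character(lab$region),
               c("ACC", "ACC", "dPL", "vPL", "IL"))
  expect_equal(lab$region_index, c(1, 1, 2, 3, 4))
})

test_that("region_te_stats orders step groups for block coupling", {
  set.seed(18)
  cells <- data.frame(cell_id = 1:40, dv_um = runif(40, 0, 2000))
  cells$region_index <- ifelse(cells$dv_um > 1000, 2L, 1L)
  pr <- expand.grid(input_id = 1:40, recipient_id = 1:40)
  pr <- pr[pr$input_id != pr$recipient_id, ]
  same <- cells$region_index[pr$input_id] == cells$region_index[pr$recipient_id]
  pr$norm_te <- rnorm(nrow(pr), ifelse(same, 0.02, 0), 0.005)
  st <- region_te_stats(pr, cells)
  expect_gt(st$intra_mean, st$inter_mean)
  expect_lt(st$test$p.value, 1e-6)
  expect_equal(st$by_step$step, c(0, 1))
  # single-region labels: inter empty, flagged
  cells$region_index <- 1L
  st2 <- region_te_stats(pr, cells)
  expect_null(st2$test)
  expect_match(st2$note, "empty")
})

test_that("phase masking: whole-session mask equals te_normalized", {
  e <- simulate_session(session_config(seed = 19))
  visits <- parse_visits(e)
  ens <- simulate_ensemble(e, ensemble_config(
    n_cells = 2, coupling = data.frame(input = 1, recipient = 2,
                                       lag_bins = 1, excess_prob = 0.3),
    seed = 20))
  tr <- spike_trains(ens$spikes, 2)
  full <- te_pairs(tr, cbind(1L, 2L), seed = 7)
  masked <- te_pairs(tr, cbind(1L, 2L), seed = 7,
                     mask = rep(TRUE, 360000))
  expect_equal(masked$raw_te, full$raw_te, tolerance = 1e-12)
  expect_equal(masked$null_mean, full$null_mean, tolerance = 1e-12)
  # phase-restricted TE keeps sign of coupling present throughout
  oz <- te_by_phase(tr, visits, "OZ", pairs = cbind(1L, 2L), seed = 7,
                    min_bins = 100)
  expect_gt(oz$norm_te, 0)
  expect_lt(oz$n_bins_used, full$n_bins_used)
  # empty mask errors
  novisits <- visits[0, ]
  expect_error(te_by_phase(tr, novisits, "OZ", pairs = cbind(1L, 2L)))
})

test_that("phase occupancy below min_bins yields NA", {
  e <- simulate_session(session_config(seed = 19))
  visits <- parse_visits(e)[1:2, ]
  tr <- list(poisson_train(3, seed = 1), poisson_train(3, seed = 2))
  r <- te_by_phase(tr, visits, "OZ", pairs = cbind(1L, 2L),
                   min_bins = 3000)
  expect_true(is.na(r$norm_te))
})
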