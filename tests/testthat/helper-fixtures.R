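# Shared fixtures, built in code at test time.

# hand-written event log: one earn, one skip, one quit, with timings
# chosen so every derived quantity is checkable by hand
tiny_events <- function() {
  data.frame(
    time_s = c(10.0, 12.5, 12.5, 22.5, 30.0, 30.0,
               40.0, 43.0, 43.0,
               50.0, 52.0, 52.0, 58.0, 58.0),
    event = c("oz_enter", "oz_exit", "wz_enter", "reward", "rz_exit",
              "tz_enter",
              "oz_enter", "oz_exit", "tz_enter",
              "oz_enter", "oz_exit", "wz_enter", "wz_exit", "tz_enter"),
    restaurant = c(rep(1L, 6), rep(2L, 3), rep(3L, 5)),
    lap = 1L,
    offer_delay_s = c(rep(10, 6), rep(5, 3), rep(20, 5)),
    stringsAsFactors = FALSE)
}

# homogeneous Poisson train on [0, duration]
poisson_train <- function(rate, duration = 3600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sort(runif(rpois(1, rate * duration), 0, duration))
}

# deterministic visit table with n visits of given outcomes
fake_visits <- function(n = 40, outcomes = NULL, delays = NULL,
                        seed = 1) {
  set.seed(seed)
  if (is.null(outcomes))
    outcomes <- sample(c("earn", "skip", "quit"), n, TRUE,
                       prob = c(.5, .4, .1))
  if (is.null(delays)) delays <- sample(1:30, n, TRUE)
  start <- cumsum(c(5, rep(40, n - 1)))
  oz_exit <- start + 2
  wz <- ifelse(outcomes == "skip", NA, oz_exit)
  wz_exit <- ifelse(outcomes == "earn", wz + delays,
                    ifelse(outcomes == "quit", wz + pmax(delays - 1, 0.5),
                           NA))
  reward <- ifelse(outcomes == "earn", wz_exit, NA)
  rz_exit <- ifelse(outcomes == "earn", reward + 3, NA)
  data.frame(restaurant = rep_len(1:4, n), lap = seq_len(n),
             offer_delay = delays, outcome = outcomes,
             oz_enter = start, oz_exit = oz_exit, wz_enter = wz,
             wz_exit = wz_exit, reward_time = reward, rz_exit = rz_exit,
             reaction_time = oz_exit - start,
             quit_time = ifelse(outcomes == "quit", wz_exit - wz, NA),
             linger_time = ifelse(outcomes == "earn", rz_exit - reward, NA))
}

# small planted-block ensemble for TE-chain tests
planted_ensemble <- function(seed, n_cells = 120, p_within = 0.2,
                             excess = 0.3) {
  e <- simulate_session(session_config(seed = derive_seed(seed, "sess")))
  ec <- ensemble_config(n_cells = n_cells, seed = derive_seed(seed, "ens"))
  ens0 <- simulate_ensemble(e, ec)
  cp <- block_coupling(ens0$cells$dv_um, ec$block_bounds,
                       p_within = p_within, excess_prob = excess,
                       seed = derive_seed(seed, "cp"))
  ec2 <- ensemble_config(n_cells = n_cells, coupling = cp,
                         seed = derive_seed(seed, "ens"))
  ens <- simulate_ensemble(e, ec2)
  ens$events <- e
  ens
}

# brute-force plug-in TE oracle: explicit loop over the 8 symbol patterns
te_oracle <- function(x, y) {
  n <- length(x)
  cnt <- array(0, c(2, 2, 2)) # [yt+1, yl+1, xl+1]
  for (t in 2:n)
    cnt[y[t] + 1, y[t - 1] + 1, x[t - 1] + 1] <-
      cnt[y[t] + 1, y[t - 1] + 1, x[t - 1] + 1] + 1
  N <- n - 1
  te <- 0
  for (yt in 0:1) for (yl in 0:1) for (xl in 0:1) {
    c3 <- cnt[yt + 1, yl + 1, xl + 1]
    if (c3 == 0) next
    p3 <- c3 / N
    p_cond_joint <- c3 / sum(cnt[, yl + 1, xl + 1])
    p_cond_self <- sum(cnt[yt + 1, yl + 1, ]) / sum(cnt[, yl + 1, ])
    te <- te + p3 * log2(p_cond_joint / p_cond_self)
  }
  te
}

# brute-force plug-in MI oracle from a joint count table
mi_oracle <- function(joint) {
  n <- sum(joint)
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] == 0) next
    pij <- joint[i, j] / n
    mi <- mi + pij * log2(pij / (sum(joint[i, ]) / n * sum(joint[, j]) / n))
  }
  mi
}
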