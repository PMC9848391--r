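# Synthetic spike ensembles with planted ground truth: task-variable
# tuning (multiplicative gains), a slow session-time trend, and directed
# pairwise coupling organized into blocks along the dorso-ventral axis.

#' Configuration for a synthetic spike ensemble
#'
#' Each cell is an inhomogeneous Poisson process whose instantaneous rate
#' is `base_rate * phase_gain * session_trend * rank_gain * choice_gain`,
#' evaluated on the piecewise-constant task-phase segmentation of the
#' session. Coupled pairs add excess recipient spikes one coupling lag
#' after each input spike. Cell depths are uniform over `dv_span`;
#' `block_bounds` are the planted subregion boundaries that downstream
#' transfer-entropy parcellation should recover.
#'
#' @param n_cells number of cells.
#' @param dv_span depth range (micrometers), default `c(0, 3000)` (~3 mm
#'   medial wall).
#' @param block_bounds strictly increasing boundary depths inside
#'   `dv_span`; default quartile bounds `c(750, 1500, 2250)`.
#' @param base_rate_range per-cell base rate drawn uniformly (Hz),
#'   default `c(2, 8)`.
#' @param tuning optional data.frame of per-cell multiplicative gains with
#'   columns among `gain_oz`, `gain_wz`, `gain_rz`, `gain_tz` (task
#'   phase), `time_slope` (rate multiplier `1 + slope*(t/T - 0.5)`),
#'   `gain_rank1..gain_rank4` (restaurant rank), `gain_skip`,
#'   `gain_accept` (choice, applied during the visit's OZ occupancy).
#'   `NULL` means untuned (all gains 1).
#' @param coupling optional data.frame with columns `input`, `recipient`
#'   (cell indices), `lag_bins` (>= 1, in 10 ms bins), `excess_prob`
#'   (probability an input spike begets an extra recipient spike).
#' @param spike_width_distribution list of two normal components
#'   (`mean_us`, `sd_us`, `prop`): wide principal cells and narrow
#'   interneurons.
#' @param te_bin bin used to express coupling lags (s), default 0.010.
#' @param seed integer RNG seed.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_cells = 40L,
                            dv_span = c(0, 3000),
                            block_bounds = c(750, 1500, 2250),
                            base_rate_range = c(2, 8),
                            tuning = NULL,
                            coupling = NULL,
                            spike_width_distribution = list(
                              principal = list(mean_us = 500, sd_us = 50, prop = 0.75),
                              interneuron = list(mean_us = 220, sd_us = 30, prop = 0.25)),
                            te_bin = 0.010,
                            seed = 1L) {
  assert_that(all(diff(block_bounds) > 0), "block_bounds must be strictly increasing")
  assert_that(all(block_bounds > dv_span[1]) && all(block_bounds < dv_span[2]),
              "block_bounds must lie strictly inside dv_span")
  assert_that(base_rate_range[1] >= 0, "rates must be nonnegative")
  if (!is.null(coupling)) {
    stopifnot(all(c("input", "recipient", "lag_bins", "excess_prob") %in%
                    names(coupling)))
    assert_that(all(coupling$lag_bins >= 1), "coupling lag must be >= 1 bin")
    assert_that(all(coupling$input != coupling$recipient),
                "self-coupling not allowed")
  }
  structure(list(n_cells = as.integer(n_cells), dv_span = dv_span,
                 block_bounds = block_bounds,
                 base_rate_range = base_rate_range, tuning = tuning,
                 coupling = coupling,
                 spike_width_distribution = spike_width_distribution,
                 te_bin = te_bin, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Within-block directed coupling for a planted-block ensemble
#'
#' Helper building the `coupling` table of [ensemble_config()]. With
#' `method = "systematic"` (default) every cell sends edges to an evenly
#' spread, deterministic fraction `p_within` of its within-block
#' partners (chosen by depth-rank stride), so coupling density is
#' homogeneous inside each block and the only randomness left in the
#' recovery problem is the spiking itself. With `method = "bernoulli"`
#' each ordered within-block pair is coupled independently with
#' probability `p_within` (and cross-block pairs with `p_between`).
#'
#' @param depths per-cell depths (um).
#' @param block_bounds planted boundaries (um).
#' @param p_within,p_between coupling densities.
#' @param lag_bins,excess_prob coupling parameters for every edge.
#' @param method `"systematic"` or `"bernoulli"`.
#' @param seed RNG seed (used by the Bernoulli method).
#' @return coupling data.frame.
#' @export
block_coupling <- function(depths, block_bounds, p_within = 0.3,
                           p_between = 0, lag_bins = 1L, excess_prob = 0.35,
                           method = c("systematic", "bernoulli"),
                           seed = 1L) {
  method <- match.arg(method)
  blk <- depth_block(depths, block_bounds)
  n <- length(depths)
  if (method == "systematic") {
    out <- list()
    for (b in unique(blk)) {
      members <- which(blk == b)
      members <- members[order(depths[members])]
      nb <- length(members)
      if (nb < 2) next
      m <- max(1L, round(p_within * (nb - 1)))
      offs <- unique(round(seq(1, nb - 1, length.out = m)))
      for (a in seq_len(nb)) {
        rec <- members[((a - 1L + offs) %% nb) + 1L]
        out[[length(out) + 1L]] <- data.frame(input = members[a],
                                              recipient = rec)
      }
    }
    out <- do.call(rbind, out)
    out <- out[out$input != out$recipient, , drop = FALSE]
    if (p_between > 0)
      warning("systematic method plants no cross-block edges; ",
              "p_between ignored")
  } else {
    out <- with_seed(seed, {
      pairs <- expand.grid(input = seq_len(n), recipient = seq_len(n))
      pairs <- pairs[pairs$input != pairs$recipient, ]
      p <- ifelse(blk[pairs$input] == blk[pairs$recipient], p_within,
                  p_between)
      pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    })
  }
  out$lag_bins <- as.integer(lag_bins)
  out$excess_prob <- excess_prob
  rownames(out) <- NULL
  out
}

depth_block <- function(depths, bounds) {
  vapply(depths, function(d) sum(d > bounds) + 1L, integer(1))
}

# piecewise-constant task-phase segmentation from a visit table
phase_segments <- function(visits, session_duration = 3600) {
  seg <- list()
  addseg <- function(lo, hi, phase, visit) {
    if (is.finite(lo) && is.finite(hi) && hi > lo)
      seg[[length(seg) + 1L]] <<- data.frame(lo = lo, hi = hi, phase = phase,
                                             visit = visit)
  }
  for (i in seq_len(nrow(visits))) {
    v <- visits[i, ]
    addseg(v$oz_enter, v$oz_exit, "OZ", i)
    if (v$outcome != "skip") addseg(v$wz_enter, v$wz_exit, "WZ", i)
    if (v$outcome == "earn") addseg(v$reward_time, v$rz_exit, "RZ", i)
  }
  seg <- do.call(rbind, seg)
  seg <- seg[order(seg$lo), ]
  # everything else is transition/travel
  gaps_lo <- c(0, seg$hi); gaps_hi <- c(seg$lo, session_duration)
  tz <- data.frame(lo = gaps_lo, hi = gaps_hi, phase = "TZ", visit = NA)
  tz <- tz[tz$hi - tz$lo > 1e-9, ]
  out <- rbind(seg, tz)
  out[order(out$lo), ]
}

#' Simulate a spike ensemble over a behavioral session
#'
#' @param events event log from [simulate_session()].
#' @param config an [ensemble_config()]. If `config$coupling` references
#'   cells, lags are `lag_bins * te_bin` seconds.
#' @param session_duration session length (s), default taken from the
#'   session config attached to `events`.
#' @return list: `spikes` (data.frame `cell_id`, `time_s`), `cells`
#'   (metadata: `cell_id`, `probe_id`, `channel`, `dv_um`,
#'   `spike_width_us`, `base_rate`, `block`), `config`, and `visits`
#'   (the parsed visit table used for tuning).
#' @export
simulate_ensemble <- function(events, config = ensemble_config(),
                              session_duration = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  scfg <- attr(events, "config")
  dur <- session_duration %||% (if (!is.null(scfg)) scfg$session_duration else 3600)
  visits <- parse_visits(events)
  with_seed(config$seed, {
    n <- config$n_cells
    # stratified uniform over the span: marginally uniform but evenly
    # spread, as cells recorded on regularly spaced probe contacts are
    slot <- sample.int(n) - 1L
    depths <- config$dv_span[1] +
      (slot + runif(n)) * diff(config$dv_span) / n
    base <- runif(n, config$base_rate_range[1], config$base_rate_range[2])
    swd <- config$spike_width_distribution
    is_int <- runif(n) < swd$interneuron$prop
    widths <- ifelse(is_int,
                     rnorm(n, swd$interneuron$mean_us, swd$interneuron$sd_us),
                     rnorm(n, swd$principal$mean_us, swd$principal$sd_us))
    seg <- phase_segments(visits, dur)
    # restaurant rank per visit from fitted thresholds (planted agent)
    fits <- do.call(rbind, lapply(split(visits, visits$restaurant),
                                  fit_threshold))
    ranked <- rank_restaurants(fits)
    rank_of <- integer(max(ranked$restaurant))
    rank_of[ranked$restaurant] <- ranked$rank
    seg_rank <- ifelse(is.na(seg$visit), NA_integer_,
                       rank_of[visits$restaurant[seg$visit]])
    seg_choice <- ifelse(is.na(seg$visit), NA_character_,
                         ifelse(visits$outcome[seg$visit] == "skip",
                                "skip", "accept"))
    tun <- config$tuning
    gain_col <- function(col, i, default = 1) {
      if (is.null(tun) || !(col %in% names(tun))) default else tun[[col]][i]
    }
    spk <- vector("list", n)
    clipped <- FALSE
    for (i in seq_len(n)) {
      g_phase <- c(OZ = gain_col("gain_oz", i), WZ = gain_col("gain_wz", i),
                   RZ = gain_col("gain_rz", i), TZ = gain_col("gain_tz", i))
      g_rank <- c(gain_col("gain_rank1", i), gain_col("gain_rank2", i),
                  gain_col("gain_rank3", i), gain_col("gain_rank4", i))
      g_choice <- c(skip = gain_col("gain_skip", i),
                    accept = gain_col("gain_accept", i))
      slope <- gain_col("time_slope", i, 0)
      rate <- base[i] * g_phase[seg$phase]
      rk <- ifelse(is.na(seg_rank), 1, g_rank[pmin(seg_rank, 4L)])
      # choice gain applies during the visit's OZ occupancy only
      ch <- ifelse(seg$phase == "OZ" & !is.na(seg$visit),
                   g_choice[seg_choice], 1)
      rate <- rate * ifelse(is.na(rk), 1, rk) * ifelse(is.na(ch), 1, ch)
      if (any(rate < 0)) {
        rate <- pmax(rate, 0); clipped <- TRUE
      }
      # inhomogeneous Poisson by segment, thinned for the linear trend
      tmax <- max(1, 1 + abs(slope) / 2)
      times <- vector("list", nrow(seg))
      for (s in seq_len(nrow(seg))) {
        lam <- rate[s] * tmax
        L <- seg$hi[s] - seg$lo[s]
        m <- rpois(1, lam * L)
        if (m > 0) times[[s]] <- runif(m, seg$lo[s], seg$hi[s])
      }
      tt <- sort(unlist(times))
      if (length(tt)) {
        trend <- 1 + slope * (tt / dur - 0.5)
        trend <- pmax(trend, 0)
        tt <- tt[runif(length(tt)) < trend / tmax]
      }
      spk[[i]] <- tt
    }
    if (clipped) rrow_log("negative instantaneous rate clipped at 0")
    # directed coupling: excess recipient spikes at the stated lag,
    # driven by the input cell's own (pre-coupling) spikes so that
    # chained edges do not cascade
    if (!is.null(config$coupling) && nrow(config$coupling)) {
      cp <- config$coupling
      base_spk <- spk
      for (k in seq_len(nrow(cp))) {
        src <- base_spk[[cp$input[k]]]
        if (!length(src)) next
        sel <- runif(length(src)) < cp$excess_prob[k]
        if (!any(sel)) next
        # land in the bin `lag_bins` after the input spike's bin
        b <- floor(src[sel] / config$te_bin) + cp$lag_bins[k]
        extra <- (b + runif(sum(sel))) * config$te_bin
        extra <- extra[extra < dur]
        j <- cp$recipient[k]
        spk[[j]] <- sort(c(spk[[j]], extra))
      }
    }
    spikes <- data.frame(
      cell_id = rep(seq_len(n), vapply(spk, length, integer(1))),
      time_s = unlist(spk))
    # approximate probe metadata: one 64ch/20um probe per 1260 um of span
    tipd <- ceiling(depths / 1260) * 1260
    probe_id <- as.integer(ceiling(depths / 1260))
    channel <- pmax(0L, pmin(63L, as.integer(round((tipd - depths) / 20))))
    cells <- data.frame(cell_id = seq_len(n), probe_id = probe_id,
                        channel = channel, dv_um = depths,
                        spike_width_us = widths, base_rate = base,
                        block = depth_block(depths, config$block_bounds))
    list(spikes = spikes, cells = cells, config = config, visits = visits)
  })
}

#' Split a spikes table into per-cell sorted spike-time vectors
#'
#' @param spikes data.frame with `cell_id`, `time_s`.
#' @param n_cells total cell count (cells without spikes get empty trains).
#' @return named list of numeric vectors.
#' @export
spike_trains <- function(spikes, n_cells = max(spikes$cell_id)) {
  out <- vector("list", n_cells)
  sp <- split(spikes$time_s, factor(spikes$cell_id, levels = seq_len(n_cells)))
  for (i in seq_len(n_cells)) out[[i]] <- sort(sp[[i]] %||% numeric(0))
  names(out) <- seq_len(n_cells)
  out
}
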