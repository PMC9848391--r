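# Pairwise transfer entropy on 10 ms binarized spike trains with a
# circular-shift surrogate null applied to the input (predictor) cell only.

#' Binarize a spike train into fixed-width time bins
#'
#' One symbol per bin: 1 if the bin holds at least one spike, else 0.
#' At cortical rates multi-spike 10 ms bins are rare, so the binary
#' alphabet loses little.
#'
#' @param times spike times (s).
#' @param bin bin width (s), default 0.010.
#' @param session_duration session length (s), default 3600.
#' @return integer 0/1 vector of length `ceiling(session_duration/bin)`.
#' @export
bin_spikes <- function(times, bin = 0.010, session_duration = 3600) {
  n <- as.integer(ceiling(session_duration / bin))
  v <- integer(n)
  if (length(times)) {
    b <- pmin(pmax(as.integer(floor(times / bin)) + 1L, 1L), n)
    v[unique(b)] <- 1L
  }
  v
}

# occupied-bin indices (0-based) for the sparse C++ path
occupied_bins <- function(times, bin = 0.010, session_duration = 3600) {
  n <- as.integer(ceiling(session_duration / bin))
  if (!length(times)) return(integer(0))
  sort(unique(pmin(pmax(as.integer(floor(times / bin)), 0L), n - 1L)))
}

#' Plug-in transfer entropy between two binary sequences
#'
#' `TE(X -> Y) = sum p(Yt, Yt-1, Xt-1) log2[ p(Yt | Yt-1, Xt-1) /
#' p(Yt | Yt-1) ]`, with order-1 histories for both sequences,
#' probabilities from the empirical joint counts over `t = 2..n`, and
#' `0 log 0 = 0`. TE is directional: `transfer_entropy(x, y)` measures
#' flow from X into Y.
#'
#' @param x,y equal-length 0/1 integer sequences (length >= 3).
#' @return TE in bits (nonnegative).
#' @export
transfer_entropy <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("sequences must have length >= 3", call. = FALSE)
  .te_dense_cpp(as.integer(x != 0), as.integer(y != 0))
}

#' Shuffle-normalized transfer entropy for one cell pair
#'
#' Raw TE minus the mean TE over `n_shuffles` circular shifts of the
#' input train X only (the recipient Y is never shifted), each shift an
#' independent uniform draw from `shift_range` expressed in whole bins.
#'
#' @param x_times input-cell spike times (s).
#' @param y_times recipient-cell spike times (s).
#' @param n_shuffles default 30.
#' @param shift_range shift range (s), default `c(60, 3540)`.
#' @param bin TE bin (s), default 0.010.
#' @param session_duration session length (s), default 3600.
#' @param seed optional seed for the shift draws.
#' @return one-row data.frame: `raw_te`, `null_mean`, `norm_te`,
#'   `n_bins_used`.
#' @export
te_normalized <- function(x_times, y_times, n_shuffles = 30,
                          shift_range = c(60, 3540), bin = 0.010,
                          session_duration = 3600, seed = NULL) {
  res <- te_pairs(list(x_times, y_times), pairs = cbind(1L, 2L),
                  n_shuffles = n_shuffles, shift_range = shift_range,
                  bin = bin, session_duration = session_duration,
                  seed = seed)
  res[, c("raw_te", "null_mean", "norm_te", "n_bins_used")]
}

#' Shuffle-normalized transfer entropy for many pairs at once
#'
#' Batch engine behind [te_normalized()], [te_all_pairs()] and
#' [te_by_phase()]. Shifts are drawn per input cell per shuffle from a
#' seeded generator and reused across that cell's pairs; when a phase
#' mask is supplied, X is shifted on the full session circle before
#' masking, and only (Yt, Yt-1, Xt-1) triplets with both bins `t` and
#' `t-1` inside the mask are counted.
#'
#' @param trains list of spike-time vectors.
#' @param pairs 2-column integer matrix of (input, recipient) indices.
#' @param mask optional logical vector over time bins (in-phase bins).
#' @param min_bins minimum masked bin count required, default 0; pairs on
#'   a session with fewer usable bins get `NA`.
#' @inheritParams te_normalized
#' @return data.frame: `input_id`, `recipient_id`, `raw_te`, `null_mean`,
#'   `norm_te`, `n_bins_used`.
#' @export
te_pairs <- function(trains, pairs, n_shuffles = 30,
                     shift_range = c(60, 3540), bin = 0.010,
                     session_duration = 3600, seed = NULL, mask = NULL,
                     min_bins = 0L) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2)
  if (any(pairs[, 1] == pairs[, 2]))
    stop("input and recipient must differ", call. = FALSE)
  n <- as.integer(ceiling(session_duration / bin))
  xb <- lapply(trains, occupied_bins, bin = bin,
               session_duration = session_duration)
  lo <- as.integer(round(shift_range[1] / bin))
  hi <- as.integer(round(shift_range[2] / bin))
  shifts <- with_seed(seed,
    matrix(sample(seq.int(lo, hi), n_shuffles * length(trains),
                  replace = TRUE),
           nrow = n_shuffles))
  n_used <- if (is.null(mask)) n - 1L else {
    stopifnot(length(mask) == n)
    sum(mask[-1] & mask[-n])
  }
  res <- .te_pairs_cpp(xb, n, pairs, shifts,
                       if (is.null(mask)) NULL else as.logical(mask))
  out <- data.frame(input_id = pairs[, 1], recipient_id = pairs[, 2],
                    raw_te = res[, 1], null_mean = res[, 2],
                    norm_te = res[, 1] - res[, 2], n_bins_used = n_used)
  if (n_used < min_bins) {
    out$raw_te <- out$null_mean <- out$norm_te <- NA_real_
  }
  out
}

#' All ordered pairs of an ensemble
#'
#' @param trains list of per-cell spike-time vectors.
#' @inheritParams te_pairs
#' @return as [te_pairs()], over all `n*(n-1)` ordered pairs.
#' @export
te_all_pairs <- function(trains, n_shuffles = 30, shift_range = c(60, 3540),
                         bin = 0.010, session_duration = 3600, seed = NULL) {
  n <- length(trains)
  pr <- expand.grid(input = seq_len(n), recipient = seq_len(n))
  pr <- as.matrix(pr[pr$input != pr$recipient, ])
  te_pairs(trains, pr, n_shuffles = n_shuffles, shift_range = shift_range,
           bin = bin, session_duration = session_duration, seed = seed)
}

#' Phase-restricted shuffle-normalized transfer entropy
#'
#' TE computed from only the 10 ms bins in which the animal occupied the
#' task phase of interest. The circular shift of X is applied on the full
#' session timeline before masking, preserving X's structure relative to
#' the mask.
#'
#' @param trains list of per-cell spike-time vectors.
#' @param visits visit table from [parse_visits()].
#' @param phase one of `"OZ"`, `"WZ"`, `"RZ"`, `"TZ"`.
#' @param pairs pair matrix; default all ordered pairs.
#' @param min_bins minimum in-phase bin count (default 3000); sessions
#'   with less phase occupancy yield `NA` rows.
#' @inheritParams te_pairs
#' @return as [te_pairs()].
#' @export
te_by_phase <- function(trains, visits, phase = c("OZ", "WZ", "RZ", "TZ"),
                        pairs = NULL, n_shuffles = 30,
                        shift_range = c(60, 3540), bin = 0.010,
                        session_duration = 3600, seed = NULL,
                        min_bins = 3000L) {
  phase <- match.arg(phase)
  if (is.null(pairs)) {
    n <- length(trains)
    pr <- expand.grid(input = seq_len(n), recipient = seq_len(n))
    pairs <- as.matrix(pr[pr$input != pr$recipient, ])
  }
  mask <- phase_mask(visits, phase, bin = bin,
                     session_duration = session_duration)
  if (!any(mask)) stop("phase mask is empty", call. = FALSE)
  te_pairs(trains, pairs, n_shuffles = n_shuffles,
           shift_range = shift_range, bin = bin,
           session_duration = session_duration, seed = seed,
           mask = mask, min_bins = min_bins)
}

#' Logical occupancy mask over TE time bins for one task phase
#'
#' A bin is in-phase when its start time falls inside one of the phase's
#' intervals.
#'
#' @inheritParams te_by_phase
#' @return logical vector over bins.
#' @export
phase_mask <- function(visits, phase, bin = 0.010, session_duration = 3600) {
  seg <- phase_segments(visits, session_duration)
  seg <- seg[seg$phase == phase, , drop = FALSE]
  n <- as.integer(ceiling(session_duration / bin))
  mask <- logical(n)
  # bin k (1-based) starts at (k-1)*bin; in-phase iff lo <= start < hi
  k_lo <- pmax(1L, as.integer(ceiling(seg$lo / bin - 1e-9)) + 1L)
  k_hi <- pmin(n, as.integer(ceiling(seg$hi / bin - 1e-9)))
  for (i in seq_len(nrow(seg)))
    if (k_lo[i] <= k_hi[i]) mask[k_lo[i]:k_hi[i]] <- TRUE
  mask
}
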