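# Hartigan's dip statistic for unimodality, implemented from the
# published algorithm (AS 217): the empirical cdf's greatest convex
# minorant and least concave majorant are compared over a candidate modal
# interval that shrinks iteratively; the dip is half the largest
# deviation encountered, in ecdf step units. A bootstrap p-value under
# the uniform null completes the test. Used to establish that the
# dorso-ventral TE profile is multimodal before reading off its local
# minima.

#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest achievable sup-distance between
#' its empirical cdf and any unimodal cdf. A constant sample has dip 0
#' (degenerate, flagged by a message); any non-degenerate sample has dip
#' at least `1/(2n)`.
#'
#' @param x numeric sample.
#' @return the dip statistic (scalar).
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 2) return(0)
  if (x[n] == x[1]) {
    rrow_log("constant sample: dip = 0 (degenerate)")
    return(0)
  }
  # predecessor pointers of the greatest convex minorant (heights = ecdf
  # step indices) and successor pointers of the least concave majorant
  mn <- integer(n); mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1):1) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }
  low <- 1L; high <- n
  dip <- 1   # in step units; 1/(2n) after final scaling
  repeat {
    # convex-minorant change points from high down to low
    gcm <- high
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    l_gcm <- length(gcm)
    # concave-majorant change points from low up to high
    lcm <- low
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_lcm <- length(lcm)
    ig <- l_gcm; ih <- l_lcm
    ix <- l_gcm - 1L; iv <- 2L
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # deviation at an lcm vertex lying under a gcm segment
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          # deviation at a gcm vertex lying under an lcm segment
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx > d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }
    if (d < dip) break
    # deviations of the ecdf from the fitted envelopes outside the new
    # modal interval [gcm[ig], lcm[ih]]
    dl <- 0
    if (gcm[ig] != gcm[1L] && ig < l_gcm) {
      for (j in ig:(l_gcm - 1L)) {
        j_b <- gcm[j + 1L]; j_e <- gcm[j]
        if (j_e - j_b > 1L && x[j_e] != x[j_b]) {
          C <- (j_e - j_b) / (x[j_e] - x[j_b])
          for (jb in j_b:j_e) {
            t <- (jb - j_b + 1) - (x[jb] - x[j_b]) * C
            if (dl < t) dl <- t
          }
        }
      }
    }
    du <- 0
    if (lcm[ih] != lcm[l_lcm] && ih < l_lcm) {
      for (j in ih:(l_lcm - 1L)) {
        j_b <- lcm[j]; j_e <- lcm[j + 1L]
        if (j_e - j_b > 1L && x[j_e] != x[j_b]) {
          C <- (j_e - j_b) / (x[j_e] - x[j_b])
          for (jb in j_b:j_e) {
            t <- (j_e - jb + 1) - (x[j_e] - x[jb]) * C
            if (du < t) du <- t
          }
        }
      }
    }
    dx <- max(dl, du)
    if (dip < dx) dip <- dx
    if (low == gcm[ig] && high == lcm[ih]) {
      if (dip < d) dip <- d
      break
    }
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Dip test of unimodality with a uniform-null bootstrap p-value
#'
#' @param x numeric sample (>= 4 finite values).
#' @param n_boot bootstrap replicates under the uniform null, default
#'   1000.
#' @param seed optional seed for the bootstrap.
#' @return list: `dip`, `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(x, n_boot = 1000, seed = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need >= 4 values for the dip test", call. = FALSE)
  d <- dip_stat(x)
  n <- length(x)
  boot <- with_seed(seed,
    vapply(seq_len(n_boot), function(i) dip_stat(runif(n)), numeric(1)))
  p <- (sum(boot >= d) + 1) / (n_boot + 1)
  list(dip = d, p_value = p, n = n, n_boot = n_boot)
}

#' Expand a DV profile into a depth sample weighted by its values
#'
#' The profile is treated as an (unnormalized) density of communication
#' over depth: each depth contributes copies proportional to its value
#' after shifting the profile minimum to zero. Feeds the dip test with a
#' sample on the depth axis.
#'
#' @param profile a [diagonal_profile()] data.frame.
#' @param resolution copies for the largest value, default 100.
#' @return numeric vector of depths.
#' @export
profile_depth_sample <- function(profile, resolution = 100) {
  ok <- is.finite(profile$value)
  d <- profile$depth_um[ok]; v <- profile$value[ok]
  w <- v - min(v)
  if (max(w) == 0) return(d)
  reps <- round(w / max(w) * resolution)
  rep(d, reps)
}
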