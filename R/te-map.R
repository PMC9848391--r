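# Anatomical organization of pairwise transfer entropy: the 2D depth map,
# the near-diagonal dorso-ventral profile, boundary detection at its local
# minima, subregion assignment, and region-level TE statistics.

#' 2D anatomical histogram of normalized TE
#'
#' Each directed pair contributes once at (input depth bin, recipient
#' depth bin) on a 100 um grid anchored at the dorsal-most recorded
#' depth; bin values are the mean normalized TE of the pairs they hold.
#'
#' @param pairs data.frame from [te_pairs()] (needs `input_id`,
#'   `recipient_id`, `norm_te`).
#' @param cells metadata with `cell_id` and `dv_um`.
#' @param bin_um spatial resolution (um), default 100.
#' @param origin grid origin (um); default the dorsal-most recorded depth.
#' @return list of class `rrow_temap`: `mean` and `count` matrices
#'   (input bin x recipient bin), `bin_um`, `origin`, `centers` (bin
#'   center depths).
#' @export
te_spatial_map <- function(pairs, cells, bin_um = 100, origin = NULL) {
  dv <- cells$dv_um[match(pairs$input_id, cells$cell_id)]
  dvr <- cells$dv_um[match(pairs$recipient_id, cells$cell_id)]
  ok <- is.finite(dv) & is.finite(dvr) & is.finite(pairs$norm_te)
  if (!all(ok)) warning(sum(!ok), " pair(s) without usable depth/TE dropped")
  dv <- dv[ok]; dvr <- dvr[ok]; te <- pairs$norm_te[ok]
  origin <- origin %||% min(cells$dv_um, na.rm = TRUE)
  K <- as.integer(floor((max(cells$dv_um, na.rm = TRUE) - origin) / bin_um)) + 1L
  bi <- as.integer(floor((dv - origin) / bin_um)) + 1L
  bj <- as.integer(floor((dvr - origin) / bin_um)) + 1L
  inside <- bi >= 1 & bi <= K & bj >= 1 & bj <= K
  if (!all(inside)) {
    warning(sum(!inside), " pair(s) outside the depth grid dropped")
    bi <- bi[inside]; bj <- bj[inside]; te <- te[inside]
  }
  cnt <- matrix(0L, K, K); mn <- matrix(NA_real_, K, K)
  idx <- (bj - 1L) * K + bi
  sums <- tapply(te, idx, sum)
  ns <- tapply(te, idx, length)
  cells_idx <- as.integer(names(sums))
  cnt[cells_idx] <- as.integer(ns)
  mn[cells_idx] <- sums / ns
  structure(list(mean = mn, count = cnt, bin_um = bin_um, origin = origin,
                 centers = origin + (seq_len(K) - 0.5) * bin_um),
            class = "rrow_temap")
}

#' Near-diagonal dorso-ventral TE profile
#'
#' At each depth grid point, the mean of the occupied 2D map bins whose
#' input AND recipient centers both lie within `window` of that depth —
#' communication between cells at similar dorso-ventral positions.
#'
#' @param map a [te_spatial_map()].
#' @param window half-width (um), default 200.
#' @return data.frame of class `rrow_dvprofile`: `depth_um`, `value`
#'   (`NA` where no occupied bin falls in the window).
#' @export
diagonal_profile <- function(map, window = 200) {
  stopifnot(inherits(map, "rrow_temap"))
  ctr <- map$centers
  K <- length(ctr)
  occ <- which(map$count > 0, arr.ind = TRUE)
  vals <- map$mean[occ]
  di <- ctr[occ[, 1]]; dj <- ctr[occ[, 2]]
  value <- vapply(ctr, function(d) {
    sel <- abs(di - d) <= window & abs(dj - d) <= window
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  structure(data.frame(depth_um = ctr, value = value),
            class = c("rrow_dvprofile", "data.frame"))
}

#' Detect subregion boundaries as interior local minima of the DV profile
#'
#' A boundary is an interior local minimum of the (optionally smoothed)
#' profile; an exactly flat valley bottom reports its midpoint depth,
#' and a single-point minimum is refined to the vertex of the parabola
#' through it and its two neighbors (standard sub-grid localization of
#' an extremum on a sampled curve; the shift is bounded by half a grid
#' step). Two further guards
#' stabilize detection on a noisy empirical curve: a valley must have
#' topographic prominence of at least `min_prominence` times the
#' profile's range (walk outward from the valley until a lower value or
#' the profile edge; the prominence is the lower of the two highest
#' values passed, minus the valley value), and reported minima closer
#' than `min_separation` are pruned keeping the deeper valley. A profile
#' with no interior minimum yields a single-region result with zero
#' boundaries, flagged by a message.
#'
#' @param profile a [diagonal_profile()] data.frame.
#' @param smooth apply a width-3 moving average first, default `FALSE`.
#' @param min_separation minimum depth between reported minima (um),
#'   default 200.
#' @param min_prominence minimum valley prominence as a fraction of the
#'   profile range, default 0.25 (a subregion boundary should carve a
#'   substantial valley, as the reference profiles do); set 0 to disable.
#' @param refine parabolic sub-grid refinement of single-point minima,
#'   default `TRUE`.
#' @param region_names labels for the intervals, dorsal to ventral;
#'   default `ACC, dPL, vPL, IL` when 4 regions result, else `region_k`.
#' @return list of class `rrow_bounds`: `boundary_depths` (ordered um),
#'   `labels`.
#' @export
find_boundaries <- function(profile, smooth = FALSE, min_separation = 200,
                            min_prominence = 0.25, refine = TRUE,
                            region_names = NULL) {
  ok <- is.finite(profile$value)
  d <- profile$depth_um[ok]; v <- profile$value[ok]
  if (length(v) < 5) stop("profile needs >= 5 defined points", call. = FALSE)
  if (smooth && length(v) >= 3) {
    v <- c(v[1], (v[-c(1, 2)] + v[-c(1, length(v))] + v[-c(length(v) - 1, length(v))]) / 3,
           v[length(v)])
  }
  # interior minima: strictly lower than both flanking values; runs of
  # exactly equal values collapse to their midpoint
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  mins <- c(); min_idx <- c()
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next
    if (r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L]) {
      if (refine && r$lengths[k] == 1L) {
        # parabola through the minimum and its neighbors; vertex offset
        # is bounded by half the local grid step
        i <- starts[k]
        a <- v[i - 1L]; b <- v[i]; cc <- v[i + 1L]
        h <- (d[i + 1L] - d[i - 1L]) / 2
        mins <- c(mins, d[i] + h / 2 * (a - cc) / (a - 2 * b + cc))
      } else {
        mins <- c(mins, mean(d[starts[k]:ends[k]]))
      }
      min_idx <- c(min_idx, starts[k])
    }
  }
  if (length(mins) && min_prominence > 0) {
    rng <- diff(range(v))
    prom <- vapply(min_idx, function(i) {
      val <- v[i]
      left <- if (i > 1) v[seq_len(i - 1)] else val
      right <- if (i < length(v)) v[seq.int(i + 1, length(v))] else val
      below_l <- which(rev(left) < val)
      peak_l <- if (length(below_l)) max(rev(left)[seq_len(below_l[1])])
        else max(left)
      below_r <- which(right < val)
      peak_r <- if (length(below_r)) max(right[seq_len(below_r[1])])
        else max(right)
      min(peak_l, peak_r) - val
    }, numeric(1))
    keep <- prom >= min_prominence * rng
    mins <- mins[keep]; min_idx <- min_idx[keep]
  }
  if (length(mins) > 1) {
    depth_val <- function(x) v[which.min(abs(d - x))]
    mins <- sort(mins)
    repeat {
      gaps <- diff(mins)
      j <- which(gaps < min_separation)
      if (!length(j)) break
      j <- j[1]
      drop <- if (depth_val(mins[j]) <= depth_val(mins[j + 1])) j + 1 else j
      mins <- mins[-drop]
    }
  }
  if (!length(mins)) rrow_log("no interior minima: single-region profile")
  nreg <- length(mins) + 1L
  labels <- region_names %||%
    (if (nreg == 4L) c("ACC", "dPL", "vPL", "IL")
     else paste0("region_", seq_len(nreg)))
  structure(list(boundary_depths = as.numeric(mins), labels = labels),
            class = "rrow_bounds")
}

#' Assign cells to subregions from boundary depths
#'
#' Cells are labeled by the depth interval containing them; a cell
#' exactly on a boundary joins the dorsal (shallower) interval.
#'
#' @param cells metadata with `dv_um`.
#' @param bounds a `rrow_bounds` (or numeric boundary depths).
#' @return `cells` with added `region` (factor, dorsal to ventral) and
#'   `region_index`.
#' @export
assign_subregions <- function(cells, bounds) {
  bd <- if (inherits(bounds, "rrow_bounds")) bounds$boundary_depths else bounds
  labels <- if (inherits(bounds, "rrow_bounds")) bounds$labels
    else paste0("region_", seq_len(length(bd) + 1L))
  idx <- vapply(cells$dv_um, function(x) sum(x > bd) + 1L, integer(1))
  cells$region_index <- idx
  cells$region <- factor(labels[idx], levels = labels)
  cells
}

#' Region-level TE statistics by subregion step distance
#'
#' Groups normalized TE of directed pairs by the number of steps between
#' the two cells' subregions (0 = within region, 1 = adjacent, ...),
#' reports group means and sizes, and compares intra- vs inter-regional
#' TE with a Mann-Whitney rank-sum test.
#'
#' @param pairs data.frame from [te_pairs()].
#' @param cells output of [assign_subregions()] (needs `cell_id`,
#'   `region_index`).
#' @return list: `by_step` (data.frame `step`, `mean`, `n`),
#'   `intra_mean`, `inter_mean`, `test` (htest or `NULL` if a side is
#'   empty, with a note).
#' @export
region_te_stats <- function(pairs, cells) {
  ri <- cells$region_index[match(pairs$input_id, cells$cell_id)]
  rr <- cells$region_index[match(pairs$recipient_id, cells$cell_id)]
  step <- abs(ri - rr)
  ok <- is.finite(step) & is.finite(pairs$norm_te)
  step <- step[ok]; te <- pairs$norm_te[ok]
  by_step <- data.frame(step = sort(unique(step)))
  by_step$mean <- vapply(by_step$step, function(s) mean(te[step == s]),
                         numeric(1))
  by_step$n <- vapply(by_step$step, function(s) sum(step == s), integer(1))
  intra <- te[step == 0]; inter <- te[step > 0]
  test <- NULL; note <- NULL
  if (length(intra) && length(inter)) {
    test <- wilcox.test(intra, inter, alternative = "greater", exact = FALSE)
  } else note <- "intra or inter group empty; rank-sum comparison omitted"
  list(by_step = by_step,
       intra_mean = if (length(intra)) mean(intra) else NA_real_,
       inter_mean = if (length(inter)) mean(inter) else NA_real_,
       test = test, note = note)
}
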