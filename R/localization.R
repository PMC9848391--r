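# Reconstruction of each cell's standardized 3D position from probe
# geometry and turning records: the step that gives every cell the
# dorso-ventral coordinate used by the TE parcellation.

#' Probe record
#'
#' @param probe_id identifier.
#' @param n_channels contact count, default 64.
#' @param channel_spacing contact pitch (um), default 20 (1260 um span).
#' @param turn_log per-session cumulative tip depth along the trajectory
#'   (um); must be nondecreasing (probes are only ever turned ventral).
#' @param entry_point,tip_point standardized 3D coordinates of the
#'   trajectory entry and of the tip at its final (deepest) position.
#' @param shrinkage_factor optional histology shrinkage (unitless); kept
#'   for completeness, not applied to synthetic data.
#' @return a `probe_record` list.
#' @export
probe_record <- function(probe_id, turn_log, entry_point, tip_point,
                         n_channels = 64L, channel_spacing = 20,
                         shrinkage_factor = NULL) {
  assert_that(!is.unsorted(turn_log), "turn_log must be nondecreasing")
  structure(list(probe_id = probe_id, n_channels = as.integer(n_channels),
                 channel_spacing = channel_spacing, turn_log = turn_log,
                 entry_point = entry_point, tip_point = tip_point,
                 shrinkage_factor = shrinkage_factor),
            class = "probe_record")
}

#' Putative cell-body channel from per-channel waveform amplitudes
#'
#' The channel with the maximal amplitude. Ties resolve to the largest
#' channel index, with a warning. Channel indices are 0-based with
#' channel 0 at the ventral tip.
#'
#' @param amplitudes numeric vector of 64 per-channel amplitudes.
#' @return 0-based channel index.
#' @export
peak_channel <- function(amplitudes) {
  if (all(amplitudes == 0)) stop("all-zero amplitude profile", call. = FALSE)
  mx <- which(amplitudes == max(amplitudes))
  if (length(mx) > 1) warning("amplitude tie: taking the largest channel index")
  max(mx) - 1L
}

#' Locate a cell in standardized space from its peak channel
#'
#' Channel 0 is the ventral tip contact; `distance_from_tip =
#' channel_index * spacing`; the cell's depth along the trajectory is the
#' session's tip turn depth minus that distance; its standardized
#' position interpolates linearly between the trajectory entry point and
#' the tip point (which marks the maximal turned depth).
#'
#' @param channel_index 0-based channel.
#' @param probe a [probe_record()].
#' @param session session index into `probe$turn_log`.
#' @return one-row data.frame: `channel_index`, `distance_from_tip`,
#'   `depth_um` (= `dv_um`), `x`, `y`, `z`, `valid` (`FALSE` if the
#'   computed depth is above the brain surface).
#' @export
locate_cell <- function(channel_index, probe, session = length(probe$turn_log)) {
  stopifnot(inherits(probe, "probe_record"))
  if (session < 1 || session > length(probe$turn_log))
    stop("no turn-log entry for session ", session, call. = FALSE)
  dist <- channel_index * probe$channel_spacing
  if (dist < 0 || dist > (probe$n_channels - 1L) * probe$channel_spacing)
    stop("channel index outside the probe", call. = FALSE)
  depth <- probe$turn_log[session] - dist
  valid <- depth >= 0
  if (!valid) rrow_log("cell located above the brain surface: flagged invalid")
  traj_len <- max(probe$turn_log)
  frac <- depth / traj_len
  xyz <- probe$entry_point + frac * (probe$tip_point - probe$entry_point)
  data.frame(channel_index = channel_index, distance_from_tip = dist,
             depth_um = depth, dv_um = depth,
             x = xyz[1], y = xyz[2], z = xyz[3], valid = valid)
}
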