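# Session-bundle readers and writers. A bundle is a directory holding
# config.json, events.csv, spikes.csv, cells.csv, optionally probes.json,
# and a manifest with schema version, seeds and a parameter hash.

BUNDLE_SCHEMA <- "rrowflow-bundle/1"

#' Write a simulated session bundle to disk
#'
#' @param dir target directory (created if missing).
#' @param events event log from [simulate_session()].
#' @param ensemble result of [simulate_ensemble()] (or `NULL` for a
#'   behavior-only bundle).
#' @param probes optional list of [probe_record()]s.
#' @param seed master seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(dir, events, ensemble = NULL, probes = NULL,
                         seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- attr(events, "config")
  data.table::fwrite(events, file.path(dir, "events.csv"))
  cfg <- list(session = unclass(scfg))
  if (!is.null(ensemble)) {
    ecfg <- ensemble$config
    data.table::fwrite(ensemble$spikes, file.path(dir, "spikes.csv"))
    data.table::fwrite(ensemble$cells, file.path(dir, "cells.csv"))
    cfg$ensemble <- unclass(ecfg)
  }
  if (!is.null(probes)) {
    jsonlite::write_json(lapply(probes, unclass),
                         file.path(dir, "probes.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(schema = BUNDLE_SCHEMA, seed = seed,
                   parameter_hash = rlang::hash(cfg),
                   files = c("events.csv",
                             if (!is.null(ensemble)) c("spikes.csv", "cells.csv"),
                             if (!is.null(probes)) "probes.json"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read and validate a session bundle
#'
#' Checks the manifest schema, spike-time ordering and bounds, and
#' cell-id consistency across files.
#'
#' @param dir bundle directory.
#' @param require_probes error if `probes.json` is missing (needed for
#'   localization), default `FALSE`.
#' @return list: `events`, `spikes`, `cells`, `probes` (or `NULL`),
#'   `config`, `manifest`.
#' @export
read_bundle <- function(dir, require_probes = FALSE) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$schema, BUNDLE_SCHEMA))
    stop("schema mismatch: found '", manifest$schema, "', expected '",
         BUNDLE_SCHEMA, "'", call. = FALSE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  events <- as.data.frame(data.table::fread(file.path(dir, "events.csv")))
  dur <- config$session$session_duration %||% 3600
  spikes <- cells <- NULL
  sp_path <- file.path(dir, "spikes.csv")
  if (file.exists(sp_path)) {
    spikes <- as.data.frame(data.table::fread(sp_path))
    bad <- which(spikes$time_s < 0 | spikes$time_s > dur)
    if (length(bad))
      stop("spikes.csv row ", bad[1], ": time ", spikes$time_s[bad[1]],
           " outside [0, ", dur, "]", call. = FALSE)
    cells <- as.data.frame(data.table::fread(file.path(dir, "cells.csv")))
    orphan <- setdiff(unique(spikes$cell_id), cells$cell_id)
    if (length(orphan))
      stop("orphan cell id(s) in spikes.csv: ",
           paste(head(orphan, 5), collapse = ", "), call. = FALSE)
    for (tr in split(spikes$time_s, spikes$cell_id))
      if (is.unsorted(tr)) stop("unsorted spike times in spikes.csv",
                                call. = FALSE)
  }
  probes <- NULL
  pb_path <- file.path(dir, "probes.json")
  if (file.exists(pb_path)) {
    pl <- jsonlite::read_json(pb_path, simplifyVector = TRUE)
    probes <- lapply(pl, function(p)
      probe_record(p$probe_id, p$turn_log, unlist(p$entry_point),
                   unlist(p$tip_point), p$n_channels, p$channel_spacing,
                   p$shrinkage_factor))
  } else if (require_probes) {
    stop("probes.json missing but localization was requested", call. = FALSE)
  }
  list(events = events, spikes = spikes, cells = cells, probes = probes,
       config = config, manifest = manifest)
}
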