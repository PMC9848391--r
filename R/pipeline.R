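# Seeded end-to-end orchestration: behavior -> spiking properties ->
# information (MI) / information flow (TE, parcellation) over a session
# bundle, with deterministic per-stage sub-seeds and machine-readable
# outputs.

#' Run the analysis pipeline on a session bundle
#'
#' Stages (selectable): `"behavior"` (visits, thresholds, ranks),
#' `"properties"` (basic spiking properties), `"mi"` (session-level
#' shuffle-normalized MI per cell for offer delay, OZ choice and
#' restaurant identity), `"infoflow"` (all-pairs normalized TE, 2D depth
#' map, DV profile, boundaries, subregion assignment, region stats).
#' Every stochastic stage derives its sub-seed from the master seed via
#' [derive_seed()], so a fixed seed gives byte-identical outputs.
#'
#' @param bundle list from [read_bundle()] (or a bundle directory path).
#' @param out output directory.
#' @param stages character subset of
#'   `c("behavior", "properties", "mi", "infoflow")`.
#' @param seed master seed, default 1.
#' @param n_shuffles surrogate count, default 30.
#' @return (invisibly) list of in-memory results; files are written
#'   under `out` together with `summary.json` and `run_log.json`.
#' @export
run_pipeline <- function(bundle, out,
                         stages = c("behavior", "properties", "mi",
                                    "infoflow"),
                         seed = 1L, n_shuffles = 30) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dur <- bundle$config$session$session_duration %||% 3600
  res <- list()
  failures <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      rrow_log("stage ", name, " failed: ", conditionMessage(e),
               level = "error")
      NULL
    })
  }

  visits <- parse_visits(bundle$events)
  if ("behavior" %in% stages) {
    res$behavior <- run_stage("behavior", function() {
      fits <- do.call(rbind, lapply(split(visits, visits$restaurant),
                                    fit_threshold))
      ranked <- rank_restaurants(fits)
      data.table::fwrite(visits, file.path(out, "visits.csv"))
      data.table::fwrite(ranked, file.path(out, "thresholds.csv"))
      list(visits = visits, thresholds = ranked)
    })
  }

  trains <- NULL
  if (!is.null(bundle$spikes)) {
    trains <- spike_trains(bundle$spikes,
                           n_cells = max(bundle$cells$cell_id))
  }

  if ("properties" %in% stages && !is.null(trains)) {
    res$properties <- run_stage("properties", function() {
      props <- do.call(rbind, lapply(seq_along(trains), function(i) {
        w <- bundle$cells$spike_width_us[match(i, bundle$cells$cell_id)]
        cbind(cell_id = i,
              basic_properties(trains[[i]], w, session_duration = dur))
      }))
      props$cell_class <- classify_cell(props$mean_rate, props$spike_width)
      data.table::fwrite(props, file.path(out, "properties.csv"))
      props
    })
  }

  if ("mi" %in% stages && !is.null(trains)) {
    res$mi <- run_stage("mi", function() {
      oz <- data.frame(enter = visits$oz_enter, exit = visits$oz_exit)
      vars <- list(offer_delay = visits$offer_delay,
                   oz_choice = ifelse(visits$outcome == "skip", "skip",
                                      "accept"),
                   restaurant = factor(visits$restaurant))
      rows <- list()
      for (i in seq_along(trains)) {
        for (v in names(vars)) {
          m <- mi_session(trains[[i]], oz, vars[[v]],
                          n_shuffles = n_shuffles, period = dur,
                          seed = derive_seed(seed, paste0("mi_", v, "_", i)))
          rows[[length(rows) + 1L]] <- cbind(cell_id = i, variable = v, m)
        }
      }
      mi <- do.call(rbind, rows)
      data.table::fwrite(mi, file.path(out, "mi.csv"))
      mi
    })
  }

  if ("infoflow" %in% stages && !is.null(trains)) {
    res$infoflow <- run_stage("infoflow", function() {
      pairs <- te_all_pairs(trains, n_shuffles = n_shuffles,
                            session_duration = dur,
                            seed = derive_seed(seed, "te"))
      data.table::fwrite(pairs, file.path(out, "te_pairs.csv"))
      map <- te_spatial_map(pairs, bundle$cells)
      mapdf <- data.frame(which(map$count > 0, arr.ind = TRUE))
      names(mapdf) <- c("input_bin", "recipient_bin")
      mapdf$mean <- map$mean[map$count > 0]
      mapdf$count <- map$count[map$count > 0]
      data.table::fwrite(mapdf, file.path(out, "te_map.csv"))
      profile <- diagonal_profile(map)
      data.table::fwrite(profile, file.path(out, "profile.csv"))
      # boundary detection needs a well-populated profile; a sparse
      # session still gets its TE outputs
      bounds <- tryCatch(find_boundaries(profile), error = function(e) {
        failures[["boundaries"]] <<- conditionMessage(e)
        NULL
      })
      labeled <- stats <- NULL
      if (!is.null(bounds)) {
        labeled <- assign_subregions(bundle$cells, bounds)
        stats <- region_te_stats(pairs, labeled)
        jsonlite::write_json(
          list(boundary_depths = bounds$boundary_depths,
               labels = bounds$labels),
          file.path(out, "bounds.json"), auto_unbox = FALSE, digits = NA)
      }
      list(pairs = pairs, map = map, profile = profile, bounds = bounds,
           cells = labeled, region_stats = stats)
    })
  }

  summary <- list(
    seed = seed,
    parameter_hash = bundle$manifest$parameter_hash,
    n_visits = nrow(visits),
    thresholds = if (!is.null(res$behavior))
      res$behavior$thresholds$threshold,
    boundary_depths = if (!is.null(res$infoflow))
      res$infoflow$bounds$boundary_depths,
    region_labels = if (!is.null(res$infoflow))
      res$infoflow$bounds$labels,
    failures = failures)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(
    list(package = "rrowflow",
         version = as.character(utils::packageVersion("rrowflow")),
         seed = seed, n_shuffles = n_shuffles, stages = stages),
    file.path(out, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
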