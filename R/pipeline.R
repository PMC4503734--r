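# End-to-end orchestration: territories per group, band analysis per
# eligible caller, border/neighbour analyses, the four paired comparisons
# and the mass-cost test, assembled into a reproducible report object.

#' Default analysis configuration
#'
#' @param levels isopleth levels (default 0.5/0.75/0.95).
#' @param a hull budget in metres, or `NULL` for the max-pairwise-distance
#'   default, or a fraction via `a_fraction`.
#' @param a_fraction if not `NULL`, `a` is this fraction of each group's max
#'   pairwise fix distance.
#' @param buffer_m neighbour buffer radius (default 100 m).
#' @param min_calls caller eligibility threshold (default 10).
#' @param relatedness_threshold related-group cut-off (default 0.25).
#' @param adult_age_days adult age threshold (default 365).
#' @param min_bouts calling-day threshold for the mass analysis (default 6).
#' @param pairing_window_days mass-pairing window (default 14).
#' @param location_round_m calling-location rounding (default 1 m).
#' @param reference_date date at which ages/membership are evaluated;
#'   `NULL` uses the median fix date.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(levels = c(0.5, 0.75, 0.95), a = NULL,
                            a_fraction = NULL, buffer_m = 100,
                            min_calls = 10, relatedness_threshold = 0.25,
                            adult_age_days = 365, min_bouts = 6,
                            pairing_window_days = 14, location_round_m = 1,
                            reference_date = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full audience analysis
#'
#' Fits an a-LoCoH territory per group, selects eligible callers (at least
#' `min_calls` located calls), classifies their calls into territory bands
#' and tests the pooled counts against the movement-proportional
#' 0.5/0.25/0.20 expectations (df = 2); builds 100 m buffer inclusion areas
#' against every neighbouring group with a shared border, tests pooled
#' related- vs unrelated-border counts against area-proportional
#' expectations (df = 1), runs the four paired neighbour comparisons and the
#' mass-cost pairing, each with paired t tests on both call and location
#' rates. Exclusions (ineligible callers, unpaired weight days, tie-breaks,
#' multi-assigned border calls) are recorded in the report log.
#'
#' @param dataset a `"call_dataset"` (from [read_dataset()] or
#'   [simulate_dataset()]).
#' @param config an [analysis_config()].
#' @param territories optional precomputed named list of `"locoh"` fits
#'   (e.g. the `"territories"` attribute of a simulated dataset); fitted
#'   from the fixes when `NULL`.
#' @return an object of class `"audience_report"`.
#' @export
run_audience_analysis <- function(dataset, config = analysis_config(),
                                  territories = NULL) {
  validate_dataset(dataset)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  gids <- sort(unique(dataset$fixes$group_id))
  if (is.null(territories)) {
    territories <- lapply(gids, function(g) {
      pts <- dataset$fixes[dataset$fixes$group_id == g, c("x", "y")]
      a <- config$a
      if (is.null(a) && !is.null(config$a_fraction))
        a <- config$a_fraction * choose_a(as.matrix(pts))
      locoh(pts, a = a, levels = config$levels, group_id = g)
    })
    names(territories) <- gids
  }

  ref_date <- config$reference_date
  if (is.null(ref_date)) ref_date <- as.Date(stats::median(dataset$fixes$timestamp))

  eligible <- filter_eligible_callers(dataset$calls, config$min_calls)
  dropped <- setdiff(unique(dataset$calls$caller_id), eligible)
  if (length(dropped))
    note("ineligible callers (<", config$min_calls, " calls): ",
         paste(dropped, collapse = ", "))

  A <- relatedness_matrix(dataset$pedigree)
  grp_of <- stats::setNames(dataset$individuals$group_id, dataset$individuals$id)

  # ---- band analysis ----------------------------------------------------
  band_rows <- list()
  obs_calls <- obs_locs <- stats::setNames(numeric(4), band_names())
  exp_calls <- exp_locs <- stats::setNames(numeric(3), band_names()[1:3])
  for (cl in eligible) {
    cc <- dataset$calls[dataset$calls$caller_id == cl, ]
    terr <- territories[[grp_of[[cl]]]]
    bc <- band_counts(cc, terr, config$location_round_m)
    obs_calls <- obs_calls + bc$counts[band_names()]
    obs_locs <- obs_locs + bc$location_counts[band_names()]
    exp_calls <- exp_calls + bc$expected
    exp_locs <- exp_locs + bc$expected_locations
    band_rows[[cl]] <- data.frame(caller = cl, group = grp_of[[cl]],
                                  t(bc$counts[band_names()]),
                                  stringsAsFactors = FALSE)
  }
  band_table <- if (length(band_rows)) do.call(rbind, band_rows) else NULL
  band_test_calls <- if (sum(obs_calls) > 0)
    chisq_gof(obs_calls[1:3], exp_calls) else NULL
  band_test_locs <- if (sum(obs_locs) > 0)
    chisq_gof(obs_locs[1:3], exp_locs) else NULL

  # ---- border / neighbour analysis -------------------------------------
  # buffer each territory once; inclusion polygons are shared by all
  # callers of a group
  buffers <- lapply(territories, function(t)
    buffer_polygon(t$isopleths[["0.95"]], config$buffer_m))
  inclusions <- list()
  for (g in gids) {
    inclusions[[g]] <- list()
    for (og in setdiff(gids, g)) {
      inc <- poly_intersect(territories[[g]]$isopleths[["0.95"]],
                            buffers[[og]])
      if (area_hectares(inc) > 0) inclusions[[g]][[og]] <- inc
    }
  }

  profiles <- list()
  stats_rows <- list()
  for (cl in eligible) {
    g <- grp_of[[cl]]
    if (dataset$individuals$sex[dataset$individuals$id == cl] == "unknown") {
      note("caller ", cl, " skipped in border analysis: unknown sex")
      next
    }
    cc <- dataset$calls[dataset$calls$caller_id == cl, ]
    focal_ha <- area_hectares(territories[[g]]$isopleths[["0.95"]])
    assigned <- integer(nrow(cc))
    for (og in names(inclusions[[g]])) {
      inc <- inclusions[[g]][[og]]
      bs <- border_stat_from_poly(cc, focal_ha, inc, og,
                                  config$location_round_m)
      assigned <- assigned + points_in_poly(cc$x, cc$y, inc)
      pr <- profile_neighbour(cl, og, dataset$individuals, A, ref_date,
                              config$relatedness_threshold,
                              config$adult_age_days)
      profiles[[paste(cl, og)]] <- pr
      stats_rows[[paste(cl, og)]] <- cbind(focal_caller = cl, bs,
                                           stringsAsFactors = FALSE)
    }
    if (any(assigned > 1L))
      note("caller ", cl, ": ", sum(assigned > 1L),
           " call(s) fall in overlapping buffers of two neighbours (counted toward both)")
  }
  profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL
  border_stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(border_stats)) rownames(border_stats) <- NULL
  if (!is.null(profiles)) rownames(profiles) <- NULL

  # pooled related/unrelated chi-squared (df = 1), area-proportional null
  rel_test_calls <- rel_test_locs <- NULL
  if (!is.null(border_stats)) {
    m <- merge(profiles, border_stats,
               by.x = c("focal_caller", "neighbour_group"),
               by.y = c("focal_caller", "neighbour"))
    if (any(m$related) && any(!m$related)) {
      oc <- c(related = sum(m$observed_calls[m$related]),
              unrelated = sum(m$observed_calls[!m$related]))
      ec <- c(related = sum(m$expected_calls[m$related]),
              unrelated = sum(m$expected_calls[!m$related]))
      ol <- c(related = sum(m$observed_locations[m$related]),
              unrelated = sum(m$observed_locations[!m$related]))
      el <- c(related = sum(m$expected_locations[m$related]),
              unrelated = sum(m$expected_locations[!m$related]))
      if (all(ec > 0)) rel_test_calls <- chisq_gof(oc, ec)
      if (all(el > 0)) rel_test_locs <- chisq_gof(ol, el)
    }
  }

  # ---- paired comparisons ----------------------------------------------
  paired_tables <- NULL
  paired_tests <- list()
  if (!is.null(border_stats) && nrow(border_stats)) {
    paired_tables <- paired_border_tables(profiles, border_stats)
    for (tie in attr(paired_tables, "ties")) note("tie-break: ", tie)
    for (nm in names(paired_tables)) {
      tab <- paired_tables[[nm]]
      for (dr in attr(tab, "excluded"))
        note("caller ", dr, " excluded from ", nm)
      if (nrow(tab) >= 2L) {
        paired_tests[[nm]] <- list(
          calls = paired_t(tab$calls_per_ha_high, tab$calls_per_ha_low),
          locations = paired_t(tab$locations_per_ha_high,
                               tab$locations_per_ha_low))
      }
    }
  }

  # ---- mass cost --------------------------------------------------------
  wp <- weight_cost_pairs(dataset$weights, config$min_bouts,
                          config$pairing_window_days)
  unpaired <- setdiff(unique(dataset$weights$individual_id), wp$individual_id)
  if (length(unpaired))
    note("individuals without a valid weight pair: ",
         paste(unpaired, collapse = ", "))
  weight_test <- if (nrow(wp) >= 2L)
    paired_t(wp$change_calling, wp$change_noncalling) else NULL

  structure(list(
    territories = territories,
    eligible_callers = eligible,
    band_table = band_table,
    band_observed = list(calls = obs_calls, locations = obs_locs),
    band_expected = list(calls = exp_calls, locations = exp_locs),
    band_test = list(calls = band_test_calls, locations = band_test_locs),
    neighbour_profiles = profiles,
    border_stats = border_stats,
    related_test = list(calls = rel_test_calls, locations = rel_test_locs),
    paired_tables = paired_tables,
    paired_tests = paired_tests,
    weight_pairs = wp,
    weight_test = weight_test,
    log = log,
    provenance = list(config = config,
                      a_values = vapply(territories, `[[`, numeric(1), "a"),
                      version = as.character(utils::packageVersion("callscape")),
                      date = format(Sys.Date()))),
    class = "audience_report")
}

#' @export
print.audience_report <- function(x, ...) {
  cat("Audience-targeting analysis report\n")
  cat("  eligible callers:", length(x$eligible_callers), "\n")
  if (!is.null(x$band_test$calls)) {
    cat("  band test (calls):     "); print(x$band_test$calls)
    cat("  band test (locations): "); print(x$band_test$locations)
  }
  if (!is.null(x$related_test$calls)) {
    cat("  related/unrelated border test (calls):     ")
    print(x$related_test$calls)
    if (!is.null(x$related_test$locations)) {
      cat("  related/unrelated border test (locations): ")
      print(x$related_test$locations)
    }
  }
  for (nm in names(x$paired_tests)) {
    cat("  ", nm, " (calls/ha):     ", sep = ""); print(x$paired_tests[[nm]]$calls)
    cat("  ", nm, " (locations/ha): ", sep = ""); print(x$paired_tests[[nm]]$locations)
  }
  if (!is.null(x$weight_test)) {
    cat("  mass cost of calling:  "); print(x$weight_test)
  }
  if (length(x$log)) cat("  log entries:", length(x$log), "\n")
  invisible(x)
}

#' @export
summary.audience_report <- function(object, ...) {
  tests <- list(band_calls = object$band_test$calls,
                band_locations = object$band_test$locations,
                related_calls = object$related_test$calls,
                related_locations = object$related_test$locations)
  for (nm in names(object$paired_tests)) {
    tests[[paste0(nm, "_calls")]] <- object$paired_tests[[nm]]$calls
    tests[[paste0(nm, "_locations")]] <- object$paired_tests[[nm]]$locations
  }
  tests$weight <- object$weight_test
  rows <- lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    if (is.null(t)) return(NULL)
    if (inherits(t, "chisq_gof"))
      data.frame(test = nm, statistic = t$statistic, df = t$df, p = t$p,
                 n = sum(t$observed), stringsAsFactors = FALSE)
    else
      data.frame(test = nm, statistic = t$t, df = t$df, p = t$p, n = t$n,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the report's tables to a directory
#'
#' Emits `band_counts.csv`, `border_stats.csv`, `paired_tables.csv`,
#' `weight_pairs.csv`, `tests.csv`, a GeoJSON of the territory isopleths
#' and the run log.
#'
#' @param report an `"audience_report"`.
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) if (!is.null(df) && nrow(df))
    utils::write.table(df, file.path(dir, file), sep = ",",
                       row.names = FALSE, quote = FALSE)
  wr(report$band_table, "band_counts.csv")
  wr(report$border_stats, "border_stats.csv")
  if (!is.null(report$paired_tables)) {
    filled <- Filter(nrow, report$paired_tables)
    if (length(filled)) {
      all_pairs <- do.call(rbind, lapply(names(filled), function(nm)
        cbind(comparison = nm, filled[[nm]], stringsAsFactors = FALSE)))
      wr(all_pairs, "paired_tables.csv")
    }
  }
  wr(report$weight_pairs, "weight_pairs.csv")
  wr(summary(report), "tests.csv")
  write_polygons(report$territories, file.path(dir, "territories.geojson"))
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
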