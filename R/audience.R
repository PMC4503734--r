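# Audience analysis: where calls fall within the territory (band
# classification against movement-proportional expectations), how calling
# concentrates in 100 m border zones with neighbouring territories
# (area-proportional expectations), the four paired neighbour comparisons,
# and the body-mass cost pairing.

#' Deduplicate a caller's calls into calling locations
#'
#' Calls are grouped by coordinate equality after rounding to
#' `round_m` metres (GPS accuracy makes sub-metre distinctions
#' meaningless); each location carries the number of calls given from it,
#' in order of first occurrence.
#'
#' @param calls data frame of one caller's calls with columns `x`, `y`.
#' @param round_m rounding grid in metres (default 1).
#' @return data frame with columns `x`, `y` (rounded coordinates) and
#'   `n_calls`.
#' @export
dedupe_locations <- function(calls, round_m = 1) {
  if (nrow(calls) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), n_calls = integer(0)))
  rx <- round(calls$x / round_m) * round_m
  ry <- round(calls$y / round_m) * round_m
  key <- paste(rx, ry)
  first <- !duplicated(key)
  counts <- table(factor(key, levels = key[first]))
  data.frame(x = rx[first], y = ry[first],
             n_calls = as.integer(counts), row.names = NULL)
}

#' Callers with enough located calls for analysis
#'
#' @param calls calls data frame (column `caller_id`).
#' @param min_calls minimum located calls per caller-season (default 10,
#'   inclusive).
#' @return character vector of eligible caller ids.
#' @export
filter_eligible_callers <- function(calls, min_calls = 10) {
  if (nrow(calls) == 0L) return(character(0))
  tab <- table(calls$caller_id)
  sort(names(tab)[tab >= min_calls])
}

#' Expected calls per territory band under the movement null
#'
#' Under the null that calling follows group movement, the expected counts
#' in the three bands are 0.5, 0.25 and 0.20 of the total — deliberately
#' unnormalised (they sum to 0.95 of the total; the remaining 5 percent of
#' movement lies outside the 95 percent isopleth), giving the three-category
#' df = 2 test.
#'
#' @param total_calls total calls by the caller (>= 0).
#' @return named numeric vector with elements `core50`, `band50_75`,
#'   `band75_95`.
#' @examples
#' expected_band_counts(40)  # 20, 10, 8
#' @export
expected_band_counts <- function(total_calls) {
  if (total_calls < 0) stop("total_calls must be >= 0", call. = FALSE)
  c(core50 = 0.5, band50_75 = 0.25, band75_95 = 0.20) * total_calls
}

#' Observed and expected band counts for one caller
#'
#' Classifies the caller's calls (and deduplicated locations) into
#' territory bands and attaches the movement-null expectations.
#'
#' @param calls one caller's calls (`x`, `y`).
#' @param territory the caller's group's `"locoh"` fit (levels
#'   0.5/0.75/0.95).
#' @param round_m location rounding for the location-level counts.
#' @return list with `counts` (named vector over the four bands),
#'   `location_counts` (same for deduplicated locations), `expected`,
#'   `expected_locations` (three-band expectations).
#' @export
band_counts <- function(calls, territory, round_m = 1) {
  band <- predict(territory, calls)
  counts <- table(band)
  locs <- dedupe_locations(calls, round_m)
  lband <- predict(territory, locs)
  lcounts <- table(lband)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       location_counts = stats::setNames(as.integer(lcounts), names(lcounts)),
       expected = expected_band_counts(nrow(calls)),
       expected_locations = expected_band_counts(nrow(locs)))
}

#' Border statistics for one caller against one neighbour
#'
#' Computes the inclusion area (focal 95 percent isopleth clipped to the
#' neighbour's 100 m buffer), the observed calls and deduplicated calling
#' locations inside it (boundary inclusive), the area-proportional expected
#' count — total calls divided by the focal 95 percent area (ha) times the
#' inclusion area (ha) — and per-hectare rates.
#'
#' @param caller_calls one caller's calls (`x`, `y`).
#' @param focal_territory the caller's group's `"locoh"` fit.
#' @param neighbour_territory the neighbouring group's `"locoh"` fit.
#' @param distance buffer radius in metres (default 100).
#' @param round_m location rounding (default 1 m).
#' @return one-row data frame: `neighbour`, `inclusion_area_ha`,
#'   `observed_calls`, `observed_locations`, `expected_calls`,
#'   `expected_locations`, `calls_per_ha`, `locations_per_ha`. Rates are
#'   `NA` (with a warning if calls were observed) when the inclusion area
#'   is empty.
#' @export
border_stat <- function(caller_calls, focal_territory, neighbour_territory,
                        distance = 100, round_m = 1) {
  focal95 <- focal_territory$isopleths[["0.95"]]
  if (is.null(focal95) || area_hectares(focal95) <= 0)
    stop("focal territory needs a positive-area 0.95 isopleth", call. = FALSE)
  inc <- inclusion_area(focal95, neighbour_territory$isopleths[["0.95"]],
                        distance)
  border_stat_from_poly(caller_calls, area_hectares(focal95), inc,
                        if (is.na(neighbour_territory$group_id)) "neighbour"
                        else neighbour_territory$group_id,
                        round_m)
}

# Border statistics against a precomputed inclusion polygon (the pipeline
# shares inclusion polygons across the callers of a group).
border_stat_from_poly <- function(caller_calls, focal_ha, inc, neighbour_id,
                                  round_m = 1) {
  inc_ha <- area_hectares(inc)
  total <- nrow(caller_calls)
  locs <- dedupe_locations(caller_calls, round_m)
  obs_c <- sum(points_in_poly(caller_calls$x, caller_calls$y, inc))
  obs_l <- sum(points_in_poly(locs$x, locs$y, inc))
  if (inc_ha == 0 && obs_c > 0)
    warning("calls observed inside an empty inclusion area (call outside mapped territory?)")
  data.frame(
    neighbour = neighbour_id,
    inclusion_area_ha = inc_ha,
    observed_calls = obs_c,
    observed_locations = obs_l,
    expected_calls = total / focal_ha * inc_ha,
    expected_locations = nrow(locs) / focal_ha * inc_ha,
    calls_per_ha = if (inc_ha > 0) obs_c / inc_ha else NA_real_,
    locations_per_ha = if (inc_ha > 0) obs_l / inc_ha else NA_real_,
    stringsAsFactors = FALSE)
}

#' Four paired neighbour-comparison tables
#'
#' Builds the per-caller paired call and location rates for:
#' \describe{
#'   \item{related_vs_unrelated}{pooled rate at related borders vs pooled
#'     rate at unrelated borders (callers with at least one of each);
#'     pooling sums observed counts and inclusion areas within each class.}
#'   \item{largest_vs_smallest}{the neighbour with the most adults vs the
#'     fewest (callers with >= 2 neighbours).}
#'   \item{max_vs_min_partners}{most vs fewest potential breeding partners
#'     (unrelated opposite-sex adults).}
#'   \item{max_vs_min_same_sex}{most vs fewest unrelated same-sex adults
#'     (control comparison).}
#' }
#' Ties in a selection metric are broken by lexicographically smallest
#' group id (and logged in the `ties` attribute); when the maximiser and
#' minimiser coincide under ties, the minimiser takes the next group.
#'
#' @param profiles data frame of neighbour profiles (rows from
#'   [profile_neighbour()], several callers stacked).
#' @param border_stats data frame with one row per (caller, neighbour):
#'   columns `focal_caller`, `neighbour`, `inclusion_area_ha`,
#'   `observed_calls`, `observed_locations`, `calls_per_ha`,
#'   `locations_per_ha`.
#' @return named list of four data frames, each one row per eligible caller
#'   with columns `caller`, `high_group`, `low_group`, `calls_per_ha_high`,
#'   `calls_per_ha_low`, `locations_per_ha_high`, `locations_per_ha_low`;
#'   attribute `"excluded"` lists callers dropped per table, attribute
#'   `"ties"` the logged tie-breaks.
#' @export
paired_border_tables <- function(profiles, border_stats) {
  merged <- merge(profiles, border_stats,
                  by.x = c("focal_caller", "neighbour_group"),
                  by.y = c("focal_caller", "neighbour"))
  callers <- sort(unique(merged$focal_caller))
  ties <- character(0)
  excluded <- list()

  pick <- function(rows, metric, decreasing) {
    v <- rows[[metric]]
    target <- if (decreasing) max(v) else min(v)
    cand <- sort(rows$neighbour_group[v == target])
    if (length(cand) > 1L)
      ties <<- c(ties, paste0(rows$focal_caller[1L], ":", metric, ":",
                              paste(cand, collapse = "/")))
    cand
  }

  rate_row <- function(caller, hi, lo, rows) {
    h <- rows[rows$neighbour_group == hi, ]
    l <- rows[rows$neighbour_group == lo, ]
    data.frame(caller = caller, high_group = hi, low_group = lo,
               calls_per_ha_high = h$calls_per_ha,
               calls_per_ha_low = l$calls_per_ha,
               locations_per_ha_high = h$locations_per_ha,
               locations_per_ha_low = l$locations_per_ha,
               stringsAsFactors = FALSE)
  }

  select_table <- function(metric) {
    out <- list()
    dropped <- character(0)
    for (cl in callers) {
      rows <- merged[merged$focal_caller == cl, ]
      if (nrow(rows) < 2L || all(is.na(rows$calls_per_ha))) {
        dropped <- c(dropped, cl); next
      }
      hi <- pick(rows, metric, TRUE)[1L]
      lo_cand <- pick(rows, metric, FALSE)
      lo <- setdiff(lo_cand, hi)[1L]
      if (is.na(lo)) { dropped <- c(dropped, cl); next }
      out[[cl]] <- rate_row(cl, hi, lo, rows)
    }
    tab <- if (length(out)) do.call(rbind, out) else empty_pair_table()
    attr(tab, "excluded") <- dropped
    tab
  }

  # Table 1: related vs unrelated, pooled within class per caller
  rel_tab <- list()
  rel_dropped <- character(0)
  for (cl in callers) {
    rows <- merged[merged$focal_caller == cl, ]
    rel <- rows[rows$related, ]
    unr <- rows[!rows$related, ]
    if (nrow(rel) == 0L || nrow(unr) == 0L) { rel_dropped <- c(rel_dropped, cl); next }
    pool <- function(rr) {
      a <- sum(rr$inclusion_area_ha)
      if (a == 0) return(c(NA_real_, NA_real_))
      c(sum(rr$observed_calls) / a, sum(rr$observed_locations) / a)
    }
    pr <- pool(rel); pu <- pool(unr)
    if (any(is.na(c(pr, pu)))) { rel_dropped <- c(rel_dropped, cl); next }
    rel_tab[[cl]] <- data.frame(
      caller = cl,
      high_group = paste(sort(unr$neighbour_group), collapse = "+"),
      low_group = paste(sort(rel$neighbour_group), collapse = "+"),
      calls_per_ha_high = pu[1L], calls_per_ha_low = pr[1L],
      locations_per_ha_high = pu[2L], locations_per_ha_low = pr[2L],
      stringsAsFactors = FALSE)
  }
  related_vs_unrelated <- if (length(rel_tab)) do.call(rbind, rel_tab)
                          else empty_pair_table()
  attr(related_vs_unrelated, "excluded") <- rel_dropped

  out <- list(
    related_vs_unrelated = related_vs_unrelated,
    largest_vs_smallest = select_table("n_adults"),
    max_vs_min_partners = select_table("n_potential_partners"),
    max_vs_min_same_sex = select_table("n_same_sex_unrelated_adults"))
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  attr(out, "ties") <- ties
  out
}

empty_pair_table <- function() {
  data.frame(caller = character(0), high_group = character(0),
             low_group = character(0), calls_per_ha_high = numeric(0),
             calls_per_ha_low = numeric(0), locations_per_ha_high = numeric(0),
             locations_per_ha_low = numeric(0), stringsAsFactors = FALSE)
}

#' Pair calling and non-calling days for the mass-cost comparison
#'
#' For each individual, days with at least `min_bouts` advertisement
#' calling bouts are candidate calling days and days with zero bouts are
#' candidate controls; each calling day is matched to the nearest-in-time
#' zero-bout day within `window_days`, and one pair per individual is kept
#' (the smallest date gap; earliest calling date on ties). Daily mass
#' change is `mass_end - mass_start`.
#'
#' @param weights weighing-session data frame (see [read_weights()]).
#' @param min_bouts minimum bouts defining a calling day (default 6,
#'   inclusive).
#' @param window_days maximum pairing gap in days (default 14, inclusive).
#' @return data frame with one row per paired individual: `individual_id`,
#'   `calling_date`, `noncalling_date`, `gap_days`, `change_calling`,
#'   `change_noncalling` (grams).
#' @export
weight_cost_pairs <- function(weights, min_bouts = 6, window_days = 14) {
  out <- list()
  for (id in sort(unique(weights$individual_id))) {
    w <- weights[weights$individual_id == id, ]
    calling <- w[w$n_calling_bouts >= min_bouts, ]
    control <- w[w$n_calling_bouts == 0, ]
    if (nrow(calling) == 0L || nrow(control) == 0L) next
    best <- NULL
    for (i in order(calling$date)) {
      gaps <- abs(as.numeric(calling$date[i] - control$date))
      j <- which(gaps == min(gaps))[1L]
      if (gaps[j] > window_days) next
      cand <- list(gap = gaps[j], ci = i, cj = j)
      if (is.null(best) || cand$gap < best$gap) best <- cand
    }
    if (is.null(best)) next
    cd <- calling[best$ci, ]
    nd <- control[best$cj, ]
    out[[id]] <- data.frame(
      individual_id = id,
      calling_date = cd$date, noncalling_date = nd$date,
      gap_days = best$gap,
      change_calling = cd$mass_end - cd$mass_start,
      change_noncalling = nd$mass_end - nd$mass_start,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(0), calling_date = as.Date(character(0)),
               noncalling_date = as.Date(character(0)), gap_days = numeric(0),
               change_calling = numeric(0), change_noncalling = numeric(0))
  rownames(res) <- NULL
  res
}
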