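# Synthetic-data generator. Emulates the study system at the scales the
# field protocol describes: cohesive group movement around a territory
# centre (~300 fixes per group-season), social groups of 2-15 birds with a
# single dominant pair, neighbouring territories on a (jittered) grid,
# subordinate callers producing 10-38 located loud-calls with configurable
# border and partner bias, and daily weighing sessions with a configurable
# mass cost of calling.

#' Simulation configuration
#'
#' Bundles all generator parameters with field-realistic defaults. The same
#' seed always yields an identical dataset.
#'
#' @param n_groups number of social groups (>= 2).
#' @param grid_ncol columns of the territory grid; default a near-square
#'   layout, `n_groups` gives a linear chain of territories (every shared
#'   border then has comparable strip geometry).
#' @param territory_spacing grid spacing of territory centres, metres.
#' @param centre_jitter uniform jitter applied to each centre, metres
#'   (0 keeps centres exactly on the grid).
#' @param n_fixes_per_group GPS fixes per group-season (default 300).
#' @param theta mean-reversion fraction per 15-minute step, in (0, 1].
#' @param sigma step noise, metres.
#' @param max_radius optional hard territory radius, metres: the walk is
#'   reflected back to this distance from the centre, emulating a defended
#'   territory boundary. `Inf` (default) gives the plain mean-reverting
#'   walk.
#' @param n_calls located calls per caller (the field filter accepts 10-38).
#' @param border_bias probability a call is placed in a border inclusion
#'   area rather than at a movement fix, in [0, 1].
#' @param partner_exponent preference exponent gamma: border choice
#'   probability is proportional to `(1 + n_potential_partners)^gamma`
#'   over unrelated neighbours.
#' @param group_size_range inclusive group-size bounds (default 2-15).
#' @param group_sizes optional explicit group sizes (recycled over groups);
#'   overrides the random draw from `group_size_range` when experiments
#'   need a controlled composition contrast between neighbours.
#' @param sex_ratio probability a subordinate is male.
#' @param related_fraction fraction of adjacent territory pairs made
#'   related: the second group's dominant female becomes a dispersed
#'   offspring of the first group's dominant pair (r = 0.5 to the first
#'   group's subordinates, r = 0.25 from the second group's subordinates to
#'   the first group's dominants, so the link is related in both
#'   directions).
#' @param n_callers_per_group subordinates per group that produce located
#'   calls (capped by the number of known-sex subordinates).
#' @param baseline_gain mean daily mass gain, grams.
#' @param calling_effect additional mass change on heavy calling days,
#'   grams (negative = cost).
#' @param noise_sd daily mass-change noise, grams.
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_groups = 4, grid_ncol = ceiling(sqrt(n_groups)),
                       territory_spacing = 800,
                       centre_jitter = 0, n_fixes_per_group = 300,
                       theta = 0.15, sigma = 120, max_radius = Inf,
                       n_calls = 25, border_bias = 0.5,
                       partner_exponent = 0,
                       group_size_range = c(2, 15), group_sizes = NULL,
                       sex_ratio = 0.5,
                       related_fraction = 0.5, n_callers_per_group = 1,
                       baseline_gain = 2, calling_effect = 0, noise_sd = 1,
                       seed = 1L) {
  stopifnot(n_groups >= 2, territory_spacing > 0,
            theta > 0, theta <= 1, sigma > 0,
            n_calls >= 1, border_bias >= 0, border_bias <= 1,
            partner_exponent >= 0,
            group_size_range[1] >= 2, group_size_range[2] <= 15,
            noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

# Territory pairs whose centres are within 1.2 grid spacings (the grid's
# rook-adjacent neighbours; diagonals excluded), ordered deterministically.
adjacent_pairs <- function(centres, spacing) {
  gids <- rownames(centres)
  out <- list()
  n <- nrow(centres)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(sum((centres[i, ] - centres[j, ])^2))
      if (d <= 1.2 * spacing)
        out[[length(out) + 1L]] <- data.frame(g = gids[i], h = gids[j],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(g = character(0), h = character(0)))
  do.call(rbind, out)
}

#' Simulate the social landscape
#'
#' Places territory centres on a jittered grid, draws group compositions
#' (one dominant pair plus subordinates within the size range) and builds
#' the pedigree: subordinates are offspring of their group's dominant pair;
#' for a configurable subset of neighbour groups the dominant female is
#' replaced by a dispersed offspring of the focal (first) group's dominant
#' pair, making that neighbour related (r = 0.5) to the focal subordinates.
#'
#' @param config a [sim_config()].
#' @return list with `centres` (matrix), `individuals` (data frame),
#'   `pedigree` (data frame), `reference_date`.
#' @export
simulate_landscape <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_groups
  ncol_grid <- if (is.null(config$grid_ncol)) ceiling(sqrt(n))
               else config$grid_ncol
  gx <- ((seq_len(n) - 1L) %% ncol_grid) * config$territory_spacing
  gy <- ((seq_len(n) - 1L) %/% ncol_grid) * config$territory_spacing
  if (config$centre_jitter > 0) {
    gx <- gx + stats::runif(n, -config$centre_jitter, config$centre_jitter)
    gy <- gy + stats::runif(n, -config$centre_jitter, config$centre_jitter)
  }
  centres <- cbind(x = gx, y = gy)
  rownames(centres) <- sprintf("G%02d", seq_len(n))

  ref_date <- as.Date("2011-01-15")
  ind <- list()
  ped <- list()
  add <- function(id, sex, age_days, group, rank, dam = NA, sire = NA) {
    ind[[length(ind) + 1L]] <<- data.frame(
      id = id, sex = sex, hatch_date = ref_date - age_days,
      group_id = group, rank = rank, stringsAsFactors = FALSE)
    ped[[length(ped) + 1L]] <<- data.frame(
      id = id, dam = dam, sire = sire, stringsAsFactors = FALSE)
  }
  sizes <- if (!is.null(config$group_sizes)) {
    rep_len(as.integer(config$group_sizes), n)
  } else {
    sample(seq(config$group_size_range[1], config$group_size_range[2]),
           n, replace = TRUE)
  }
  if (any(sizes < 2L | sizes > 15L))
    stop("group sizes must lie in [2, 15]", call. = FALSE)
  for (g in seq_len(n)) {
    gid <- rownames(centres)[g]
    dm <- paste0(gid, "_DM"); df_ <- paste0(gid, "_DF")
    add(dm, "male", round(stats::runif(1, 1500, 3000)), gid, "dominant")
    add(df_, "female", round(stats::runif(1, 1500, 3000)), gid, "dominant")
    for (s in seq_len(sizes[g] - 2L)) {
      sid <- sprintf("%s_S%02d", gid, s)
      add(sid, if (stats::runif(1) < config$sex_ratio) "male" else "female",
          round(stats::runif(1, 330, 1500)), gid, "subordinate",
          dam = df_, sire = dm)
    }
  }
  individuals <- do.call(rbind, ind)
  pedigree <- do.call(rbind, ped)

  # Relatedness links between adjacent territories: for the selected pairs
  # (g, h), group h's dominant female is replaced by a dispersed offspring
  # of g's dominant pair — the realistic dispersal route to a neighbouring
  # dominance vacancy. Each group's dominant female is replaced at most
  # once.
  adj <- adjacent_pairs(centres, config$territory_spacing)
  n_rel <- round(config$related_fraction * nrow(adj))
  replaced <- character(0)
  k <- 0L
  if (n_rel > 0 && nrow(adj)) {
    for (p in seq_len(nrow(adj))) {
      if (k >= n_rel) break
      g <- adj$g[p]; h <- adj$h[p]
      if (h %in% replaced) next
      old <- paste0(h, "_DF")
      individuals <- individuals[individuals$id != old, ]
      pedigree <- pedigree[pedigree$id != old, ]
      newid <- paste0(h, "_DFkin")
      individuals <- rbind(individuals, data.frame(
        id = newid, sex = "female",
        hatch_date = ref_date - round(stats::runif(1, 800, 1500)),
        group_id = h, rank = "dominant", stringsAsFactors = FALSE))
      pedigree <- rbind(pedigree, data.frame(
        id = newid, dam = paste0(g, "_DF"), sire = paste0(g, "_DM"),
        stringsAsFactors = FALSE))
      replaced <- c(replaced, h)
      k <- k + 1L
    }
  }
  rownames(individuals) <- rownames(pedigree) <- NULL
  list(centres = centres, individuals = individuals, pedigree = pedigree,
       reference_date = ref_date, adjacency = adj)
}

#' Simulate cohesive group movement
#'
#' Discrete mean-reverting (AR(1)) walk around the territory centre:
#' `x[t+1] = x[t] + theta (centre - x[t]) + sigma e[t]` with standard
#' bivariate normal steps, starting at the centre. Fixes are stamped every
#' 15 minutes.
#'
#' @param centre length-2 numeric (x, y), metres.
#' @param n_fixes number of fixes.
#' @param theta mean reversion in (0, 1].
#' @param sigma step noise, metres (> 0... `sigma = 0` collapses all fixes
#'   onto the centre and is allowed for degenerate tests).
#' @param max_radius hard territory radius, metres; positions beyond it are
#'   reflected back to the boundary (defended-territory emulation).
#'   `Inf` disables the bound.
#' @param seed integer seed.
#' @param group_id label for the output.
#' @param start_time first timestamp.
#' @return fixes data frame (`group_id`, `timestamp`, `x`, `y`).
#' @export
simulate_movement <- function(centre, n_fixes, theta, sigma, seed,
                              max_radius = Inf, group_id = "G01",
                              start_time = as.POSIXct("2010-09-01 06:00:00",
                                                      tz = "UTC")) {
  stopifnot(theta > 0, theta <= 1, sigma >= 0, n_fixes >= 1,
            max_radius > 0)
  set.seed(as.integer(seed))
  x <- numeric(n_fixes); y <- numeric(n_fixes)
  x[1L] <- centre[1L]; y[1L] <- centre[2L]
  if (n_fixes > 1L) {
    ex <- stats::rnorm(n_fixes - 1L); ey <- stats::rnorm(n_fixes - 1L)
    for (t in seq_len(n_fixes - 1L)) {
      nx <- x[t] + theta * (centre[1L] - x[t]) + sigma * ex[t]
      ny <- y[t] + theta * (centre[2L] - y[t]) + sigma * ey[t]
      if (is.finite(max_radius)) {
        r <- sqrt((nx - centre[1L])^2 + (ny - centre[2L])^2)
        if (r > max_radius) {
          # reflect the overshoot back inside the territory boundary
          pull <- (2 * max_radius - r) / r
          pull <- max(pull, 0)
          nx <- centre[1L] + (nx - centre[1L]) * pull
          ny <- centre[2L] + (ny - centre[2L]) * pull
        }
      }
      x[t + 1L] <- nx
      y[t + 1L] <- ny
    }
  }
  data.frame(group_id = group_id,
             timestamp = start_time + 900 * (seq_len(n_fixes) - 1L),
             x = x, y = y, stringsAsFactors = FALSE)
}

#' Simulate a caller's located loud-calls
#'
#' Each call independently: with probability `border_bias` it is placed
#' uniformly inside one neighbour's inclusion area, the neighbour chosen
#' among unrelated neighbours with probability proportional to
#' `(1 + n_potential_partners)^partner_exponent`; otherwise the call is
#' placed at a uniformly chosen movement fix. If border placement is
#' requested but no unrelated neighbour has a non-empty inclusion area,
#' placement falls back to movement fixes (recorded in the
#' `"fallback_calls"` attribute).
#'
#' @param caller caller id.
#' @param group_id the caller's group.
#' @param fixes the group's movement fixes.
#' @param inclusion_polys named list (by neighbour group) of inclusion-area
#'   polygons for the caller's group.
#' @param profiles neighbour profiles data frame for this caller
#'   (`neighbour_group`, `related`, `n_potential_partners`).
#' @param n_calls number of calls (field range 10-38).
#' @param border_bias,partner_exponent see [sim_config()].
#' @param seed integer seed.
#' @return calls data frame (`caller_id`, `group_id`, `timestamp`, `x`,
#'   `y`, `session_id`).
#' @export
simulate_calls <- function(caller, group_id, fixes, inclusion_polys,
                           profiles, n_calls, border_bias,
                           partner_exponent, seed) {
  set.seed(as.integer(seed))
  unrel <- profiles[!profiles$related, , drop = FALSE]
  # a usable border needs a non-negligible inclusion area (> 10 m^2);
  # hair-thin intersection slivers are not plausible call targets and
  # defeat rejection sampling
  unrel <- unrel[vapply(unrel$neighbour_group, function(g)
    area_hectares(inclusion_polys[[g]]) > 1e-3, logical(1)), , drop = FALSE]
  wts <- if (nrow(unrel)) (1 + unrel$n_potential_partners)^partner_exponent
         else numeric(0)
  xs <- numeric(n_calls); ys <- numeric(n_calls)
  fallback <- 0L
  for (k in seq_len(n_calls)) {
    at_border <- stats::runif(1) < border_bias
    if (at_border && nrow(unrel) == 0L) {
      at_border <- FALSE
      fallback <- fallback + 1L
    }
    if (at_border) {
      g <- if (nrow(unrel) == 1L) unrel$neighbour_group else
        sample(unrel$neighbour_group, 1L, prob = wts)
      p <- sample_in_polygon(inclusion_polys[[g]], 1L)
      xs[k] <- p[1L, 1L]; ys[k] <- p[1L, 2L]
    } else {
      i <- sample.int(nrow(fixes), 1L)
      xs[k] <- fixes$x[i]; ys[k] <- fixes$y[i]
    }
  }
  day <- sort(sample.int(240, n_calls, replace = TRUE))
  ts <- as.POSIXct("2010-09-01 07:00:00", tz = "UTC") + day * 86400
  out <- data.frame(caller_id = caller, group_id = group_id,
                    timestamp = ts, x = xs, y = ys,
                    session_id = format(ts, "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  attr(out, "fallback_calls") <- fallback
  out
}

#' Simulate daily weighing sessions
#'
#' For each individual, generates paired observation days: a calling day
#' (6-12 advertisement bouts) and a matched zero-bout day 2-11 days away.
#' The daily mass change is `baseline_gain + calling_effect * is_calling +
#' noise`; start mass is drawn around 85 g.
#'
#' @param ids individual ids to weigh.
#' @param n_pairs_per_individual paired day sets per individual.
#' @param calling_effect,baseline_gain,noise_sd grams; see [sim_config()].
#' @param seed integer seed.
#' @return weighing-session data frame (see [read_weights()]).
#' @export
simulate_weights <- function(ids, n_pairs_per_individual = 1,
                             calling_effect = 0, baseline_gain = 2,
                             noise_sd = 1, seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  base_date <- as.Date("2010-10-01")
  for (id in ids) {
    for (p in seq_len(n_pairs_per_individual)) {
      d0 <- base_date + round(stats::runif(1, 0, 150)) + 40 * (p - 1L)
      gap <- sample(2:11, 1L)
      m0 <- stats::rnorm(1, 85, 4)
      m1 <- stats::rnorm(1, 85, 4)
      chg_call <- baseline_gain + calling_effect + stats::rnorm(1, 0, noise_sd)
      chg_ctrl <- baseline_gain + stats::rnorm(1, 0, noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id,
        date = c(d0, d0 + gap),
        mass_start = c(m0, m1),
        mass_end = c(m0 + chg_call, m1 + chg_ctrl),
        n_calling_bouts = c(sample(6:12, 1L), 0L),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Inclusion polygons for every ordered group pair, buffering each
# territory once.
pairwise_inclusions <- function(terrs, distance = 100) {
  gids <- names(terrs)
  buffers <- lapply(terrs, function(t)
    buffer_polygon(t$isopleths[["0.95"]], distance))
  out <- list()
  for (g in gids) {
    out[[g]] <- lapply(setdiff(gids, g), function(og)
      poly_intersect(terrs[[g]]$isopleths[["0.95"]], buffers[[og]]))
    names(out[[g]]) <- setdiff(gids, g)
  }
  out
}

# Generate the call stream for all callers on a fixed landscape.
generate_calls <- function(gids, ind, A, terrs, fixes, config,
                           reference_date, call_seed, inclusions = NULL) {
  if (is.null(inclusions)) inclusions <- pairwise_inclusions(terrs)
  calls <- list()
  k <- 0L
  n_per <- if (is.null(config$n_callers_per_group)) 1L
           else config$n_callers_per_group
  for (g in gids) {
    subs <- sort(ind$id[ind$group_id == g & ind$rank == "subordinate" &
                        ind$sex != "unknown"])
    if (!length(subs)) next
    others <- setdiff(gids, g)
    incs <- inclusions[[g]]
    for (caller in subs[seq_len(min(n_per, length(subs)))]) {
      profs <- do.call(rbind, lapply(others, function(og)
        profile_neighbour(caller, og, ind, A, reference_date)))
      k <- k + 1L
      calls[[caller]] <- simulate_calls(
        caller, g, fixes[fixes$group_id == g, ], incs, profs,
        config$n_calls, config$border_bias, config$partner_exponent,
        seed = derive_seed(call_seed, 200L + k))
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  calls
}

#' Regenerate only the call stream of a simulated dataset
#'
#' Holds the landscape, movement fixes and territories of an existing
#' simulated dataset fixed and redraws the calls with a new seed — used by
#' replicate studies that average over call-placement randomness.
#'
#' @param ds a dataset from [simulate_dataset()].
#' @param call_seed integer seed for the new call stream.
#' @return the dataset with a fresh `calls` component.
#' @export
resimulate_calls <- function(ds, call_seed) {
  config <- attr(ds, "config")
  terrs <- attr(ds, "territories")
  if (is.null(config) || is.null(terrs))
    stop("dataset lacks simulation attributes; use simulate_dataset()",
         call. = FALSE)
  A <- relatedness_matrix(ds$pedigree)
  ds$calls <- generate_calls(names(terrs), ds$individuals, A, terrs,
                             ds$fixes, config, attr(ds, "reference_date"),
                             call_seed, inclusions = attr(ds, "inclusions"))
  ds
}

#' Simulate a complete dataset
#'
#' Runs the landscape, movement, territory, call and weighing generators in
#' sequence and returns a validated `"call_dataset"`. One subordinate per
#' group with at least one subordinate acts as a caller. Territories are
#' fitted internally (needed to plant border-biased calls) and returned in
#' the `"territories"` attribute so downstream analyses can reuse them.
#'
#' @param config a [sim_config()].
#' @param a_fraction hull budget as a fraction of the max pairwise fix
#'   distance used when fitting the generator's internal territories
#'   (default 0.25; see the methods vignette).
#' @return a `"call_dataset"` with attributes `"territories"` (named list of
#'   `"locoh"` fits) and `"config"`.
#' @export
simulate_dataset <- function(config, a_fraction = 0.25) {
  land <- simulate_landscape(config)
  gids <- rownames(land$centres)

  fixes <- do.call(rbind, lapply(seq_along(gids), function(g)
    simulate_movement(land$centres[g, ], config$n_fixes_per_group,
                      config$theta, config$sigma,
                      seed = derive_seed(config$seed, 100L + g),
                      max_radius = if (is.null(config$max_radius)) Inf
                                   else config$max_radius,
                      group_id = gids[g])))

  terrs <- lapply(gids, function(g) {
    pts <- fixes[fixes$group_id == g, c("x", "y")]
    locoh(pts, a = a_fraction * choose_a(as.matrix(pts)), group_id = g)
  })
  names(terrs) <- gids

  A <- relatedness_matrix(land$pedigree)
  ind <- land$individuals
  # an optional separate call-stream seed lets replicate studies vary the
  # calls while holding the landscape and movement fixed
  call_seed <- if (!is.null(config$call_seed)) config$call_seed else config$seed
  inclusions <- pairwise_inclusions(terrs)
  calls <- generate_calls(gids, ind, A, terrs, fixes, config,
                          land$reference_date, call_seed, inclusions)

  weights <- simulate_weights(unique(calls$caller_id),
                              n_pairs_per_individual = 1,
                              calling_effect = config$calling_effect,
                              baseline_gain = config$baseline_gain,
                              noise_sd = config$noise_sd,
                              seed = derive_seed(config$seed, 300L))

  ds <- structure(list(fixes = fixes, calls = calls,
                       individuals = land$individuals,
                       pedigree = land$pedigree, weights = weights),
                  class = "call_dataset")
  validate_dataset(ds)
  attr(ds, "territories") <- terrs
  attr(ds, "inclusions") <- inclusions
  attr(ds, "config") <- config
  attr(ds, "reference_date") <- land$reference_date
  ds
}
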