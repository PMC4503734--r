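# Shared fixtures and independent oracles, built in code.

# Axis-aligned square as a single-ring polygon (CCW).
square_poly <- function(side, x0 = 0, y0 = 0) {
  list(list(x = x0 + c(0, side, side, 0), y = y0 + c(0, 0, side, side)))
}

# A hand-built territory fit with concentric square isopleths centred on
# the origin: 0.5 -> side 100, 0.75 -> side 200, 0.95 -> side 300.
concentric_territory <- function(group_id = "G") {
  iso <- list("0.5" = square_poly(100, -50, -50),
              "0.75" = square_poly(200, -100, -100),
              "0.95" = square_poly(300, -150, -150))
  structure(list(isopleths = iso,
                 areas_ha = vapply(iso, area_hectares, numeric(1)),
                 levels = c(0.5, 0.75, 0.95),
                 coverage = c(`0.5` = 0L, `0.75` = 0L, `0.95` = 0L),
                 n_hulls_used = c(`0.5` = 0L, `0.75` = 0L, `0.95` = 0L),
                 a = NA_real_, n = 0L,
                 points = cbind(x = numeric(0), y = numeric(0)),
                 group_id = group_id, season = NA_character_),
            class = "locoh")
}

# Exhaustive oracle for adaptive neighbour selection: try every prefix
# length explicitly.
neighbour_oracle <- function(points, root, a) {
  d <- sqrt((points[, 1] - points[root, 1])^2 +
            (points[, 2] - points[root, 2])^2)
  others <- setdiff(seq_len(nrow(points)), root)
  ord <- others[order(d[others], others)]
  best <- integer(0)
  for (k in seq_along(ord)) {
    if (sum(d[ord[seq_len(k)]]) <= a) best <- ord[seq_len(k)] else break
  }
  c(root, best)
}

# Wright's path-counting oracle for the relatedness of two non-inbred
# individuals: sum over common ancestors A and pairs of ancestral paths
# (i -> A, j -> A) that share no individual except A, of (1/2)^(L1 + L2).
# Valid when common ancestors are themselves non-inbred.
path_counting_r <- function(ped, i, j) {
  parents <- function(id) {
    row <- ped[ped$id == id, ]
    if (nrow(row) == 0) return(character(0))
    stats::na.omit(c(row$dam, row$sire))
  }
  # all ascending paths from id, as vectors id, parent, ..., ancestor
  paths_up <- function(id) {
    out <- list(c(id))
    for (p in parents(id)) {
      for (sub in paths_up(p)) out[[length(out) + 1L]] <- c(id, sub)
    }
    out
  }
  pi_ <- paths_up(i)
  pj <- paths_up(j)
  r <- 0
  for (a in pi_) for (b in pj) {
    A <- a[length(a)]
    if (A != b[length(b)]) next
    shared <- intersect(a, b)
    if (!identical(shared, A)) next
    r <- r + 0.5^((length(a) - 1) + (length(b) - 1))
  }
  r
}

# Random non-inbred pedigree: founders in generation 0; each later
# individual's parents are a male/female pair from earlier generations with
# oracle relatedness 0 (so all matings are between unrelated individuals).
random_noninbred_pedigree <- function(n_founders = 6, n_generations = 3,
                                      per_generation = 4) {
  ped <- data.frame(id = sprintf("F%02d", seq_len(n_founders)),
                    dam = NA_character_, sire = NA_character_,
                    stringsAsFactors = FALSE)
  sex <- stats::setNames(rep(c("female", "male"), length.out = n_founders),
                         ped$id)
  for (g in seq_len(n_generations)) {
    for (k in seq_len(per_generation)) {
      dams <- names(sex)[sex == "female"]
      sires <- names(sex)[sex == "male"]
      pair <- NULL
      for (try in 1:30) {
        d <- sample(dams, 1)
        s <- sample(sires, 1)
        if (path_counting_r(ped, d, s) == 0) { pair <- c(d, s); break }
      }
      if (is.null(pair)) next
      id <- sprintf("G%d_%02d", g, k)
      ped <- rbind(ped, data.frame(id = id, dam = pair[1], sire = pair[2],
                                   stringsAsFactors = FALSE))
      sex[id] <- sample(c("female", "male"), 1)
    }
  }
  ped
}

# Individuals table builder for profile/related-group tests.
make_individuals <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], sex = r[[2]],
               hatch_date = as.Date(r[[3]]), group_id = r[[4]],
               rank = r[[5]], stringsAsFactors = FALSE)))
}

# Minimal consistent dataset for io round-trips and pipeline edge cases.
tiny_dataset <- function(n_calls_per_caller = 12) {
  fixes <- rbind(
    data.frame(group_id = "A",
               timestamp = as.POSIXct("2010-09-01 06:00:00", tz = "UTC") +
                 900 * 0:49,
               x = rep(c(0, 100, 100, 0, 50), 10),
               y = rep(c(0, 0, 100, 100, 50), 10)),
    data.frame(group_id = "B",
               timestamp = as.POSIXct("2010-09-01 06:00:00", tz = "UTC") +
                 900 * 0:49,
               x = 250 + rep(c(0, 100, 100, 0, 50), 10),
               y = rep(c(0, 0, 100, 100, 50), 10)))
  individuals <- make_individuals(
    list("A_DM", "male", "2005-01-01", "A", "dominant"),
    list("A_DF", "female", "2005-01-01", "A", "dominant"),
    list("A_S1", "male", "2008-01-01", "A", "subordinate"),
    list("B_DM", "male", "2005-01-01", "B", "dominant"),
    list("B_DF", "female", "2005-01-01", "B", "dominant"))
  calls <- data.frame(
    caller_id = "A_S1", group_id = "A",
    timestamp = as.POSIXct("2010-10-01 08:00:00", tz = "UTC") +
      86400 * seq_len(n_calls_per_caller),
    x = seq(10, 90, length.out = n_calls_per_caller),
    y = rep(50, n_calls_per_caller), stringsAsFactors = FALSE)
  calls$session_id <- format(calls$timestamp, "%Y-%m-%d")
  pedigree <- data.frame(
    id = c("A_DM", "A_DF", "A_S1", "B_DM", "B_DF"),
    dam = c(NA, NA, "A_DF", NA, NA),
    sire = c(NA, NA, "A_DM", NA, NA), stringsAsFactors = FALSE)
  weights <- data.frame(
    individual_id = "A_S1",
    date = as.Date("2010-10-05") + c(0, 4),
    mass_start = c(80.2, 81.0), mass_end = c(83.1, 83.0),
    n_calling_bouts = c(7L, 0L), stringsAsFactors = FALSE)
  structure(list(fixes = fixes, calls = calls, individuals = individuals,
                 pedigree = pedigree, weights = weights),
            class = "call_dataset")
}
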