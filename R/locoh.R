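# Adaptive sphere-of-influence local convex hull (a-LoCoH) territory
# estimation. One convex hull is rooted at every GPS fix, built from the
# nearest neighbours whose cumulative distance to the root fits within the
# budget a; hulls are unioned densest-first until each isopleth level's
# coverage threshold is met.

#' Adaptive neighbour selection for a local hull
#'
#' Returns the root together with the maximal prefix of the remaining points,
#' taken in order of ascending distance to the root, whose running sum of
#' distances does not exceed the budget `a`. Distance ties are broken by
#' ascending point index, so the selection is deterministic.
#'
#' @param points two-column matrix (x, y) of fix coordinates in metres.
#' @param root index of the root fix.
#' @param a cumulative-distance budget in metres (>= 0).
#' @return integer vector of selected indices (always contains `root`;
#'   duplicates of the root, at distance zero, are always included).
#' @export
select_neighbours_adaptive <- function(points, root, a) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (root < 1L || root > n) stop("root index out of range", call. = FALSE)
  if (a < 0) stop("a must be >= 0", call. = FALSE)
  d <- sqrt((points[, 1L] - points[root, 1L])^2 +
            (points[, 2L] - points[root, 2L])^2)
  others <- setdiff(seq_len(n), root)
  ord <- others[order(d[others], others)]
  cum <- cumsum(d[ord])
  keep <- ord[cum <= a]
  c(root, keep)
}

#' Build one local convex hull per fix
#'
#' @param points two-column matrix (x, y), metres.
#' @param a cumulative-distance budget in metres.
#' @return a list of hulls; each has `root` (index), `members` (index vector,
#'   includes root), `polygon` (CCW single-ring polygon, or `list()` when the
#'   members are fewer than 3 distinct non-collinear points) and `area_m2`
#'   (0 for degenerate hulls).
#' @export
build_local_hulls <- function(points, a) {
  points <- as.matrix(points)
  n <- nrow(points)
  lapply(seq_len(n), function(i) {
    mem <- select_neighbours_adaptive(points, i, a)
    poly <- convex_hull_poly(points[mem, 1L], points[mem, 2L])
    list(root = i, members = mem, polygon = poly,
         area_m2 = poly_area_m2(poly))
  })
}

#' Default hull budget: maximum pairwise distance among fixes
#'
#' The customary starting heuristic for the adaptive local convex hull
#' method; user-overridable wherever `a` is accepted.
#'
#' @param points two-column matrix (x, y), metres (>= 2 points).
#' @return the maximum pairwise Euclidean distance, metres.
#' @export
choose_a <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  m <- max(stats::dist(points))
  if (m == 0) stop("all points identical; cannot choose a", call. = FALSE)
  m
}

# Order hulls ascending by area; ties by descending member count, then
# ascending root index (densest-first union, deterministic).
order_hulls <- function(hulls) {
  areas <- vapply(hulls, `[[`, numeric(1), "area_m2")
  nmem <- vapply(hulls, function(h) length(h$members), integer(1))
  roots <- vapply(hulls, `[[`, integer(1), "root")
  order(areas, -nmem, roots)
}

# Which of the fixes indexed by `subset` does a hull cover? Non-degenerate:
# boundary-inclusive point-in-polygon. Degenerate (< 3 distinct members):
# exactly the fixes coinciding with a member coordinate. `points` is always
# the full fix matrix the hull indices refer to.
hull_covers <- function(hull, points, subset = seq_len(nrow(points))) {
  px <- points[subset, 1L]
  py <- points[subset, 2L]
  if (length(hull$polygon) > 0L) {
    points_in_poly(px, py, hull$polygon)
  } else {
    key <- paste(points[hull$members, 1L], points[hull$members, 2L])
    paste(px, py) %in% key
  }
}

# Union contribution of a hull. Degenerate hulls (collinear or < 3 distinct
# members) cover exactly their member fixes; they enter the union as
# millimetre-scale squares around those fixes so that the isopleth polygon
# contains every counted fix (the area contribution is ~1e-10 ha).
hull_patch_polygon <- function(hull, points, half_width = 1e-3) {
  if (length(hull$polygon) > 0L) return(hull$polygon)
  mem <- unique(points[hull$members, , drop = FALSE])
  lapply(seq_len(nrow(mem)), function(i) {
    list(x = mem[i, 1L] + half_width * c(-1, 1, 1, -1),
         y = mem[i, 2L] + half_width * c(-1, -1, 1, 1))
  })
}

#' Compute density isopleths from local hulls
#'
#' Hulls are sorted ascending by area (ties: descending member count, then
#' ascending root index) and unioned in that order; the isopleth at level q
#' is the union of the minimal prefix whose member hulls jointly cover at
#' least `ceiling(q * n)` fixes (boundary-inclusive; duplicate fixes each
#' count).
#'
#' @param hulls output of [build_local_hulls()].
#' @param levels isopleth levels, fractions in (0, 1].
#' @param points the fix coordinates the hulls were built from.
#' @return a list with `isopleths` (named list of polygons, names like
#'   `"0.5"`), `areas_ha`, `coverage` (fixes covered at each level),
#'   `n_hulls_used` (prefix length per level).
#' @export
compute_isopleths <- function(hulls, levels, points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]", call. = FALSE)
  if (nrow(unique(points)) < 2L)
    stop("degenerate territory: all fixes identical", call. = FALSE)
  lv <- sort(unique(levels))
  thresholds <- ceiling(lv * n)

  ord <- order_hulls(hulls)
  covered <- logical(n)
  prefix_for <- integer(length(lv))    # hulls needed per level
  cover_at <- integer(length(lv))
  pending <- 1L
  for (k in seq_along(ord)) {
    h <- hulls[[ord[k]]]
    todo <- which(!covered)
    if (length(todo)) {
      hit <- hull_covers(h, points, todo)
      covered[todo[hit]] <- TRUE
    }
    nc <- sum(covered)
    while (pending <= length(lv) && nc >= thresholds[pending]) {
      prefix_for[pending] <- k
      cover_at[pending] <- nc
      pending <- pending + 1L
    }
    if (pending > length(lv)) break
  }
  if (pending <= length(lv))
    stop("internal error: union of all hulls failed to cover requested levels",
         call. = FALSE)

  iso <- vector("list", length(lv))
  u <- list()
  k <- 0L
  for (j in seq_along(lv)) {
    while (k < prefix_for[j]) {
      k <- k + 1L
      pg <- hull_patch_polygon(hulls[[ord[k]]], points)
      if (length(pg) > 0L) u <- poly_union(u, pg)
    }
    iso[[j]] <- poly_clean(u)
  }
  names(iso) <- as.character(lv)
  list(isopleths = iso,
       areas_ha = stats::setNames(vapply(iso, area_hectares, numeric(1)), names(iso)),
       levels = lv,
       coverage = stats::setNames(cover_at, names(iso)),
       n_hulls_used = stats::setNames(prefix_for, names(iso)))
}

#' Fit an a-LoCoH territory from GPS fixes
#'
#' The central estimator: builds one local convex hull per fix under the
#' cumulative-distance budget `a`, then unions hulls densest-first into
#' nested density isopleths — the smallest hull-union area encompassing each
#' requested fraction of the fixes. The defaults follow common field
#' practice: levels 50/75/95 percent, with the 95 percent isopleth taken as
#' the territory.
#'
#' @param fixes a data frame with numeric columns `x` and `y` (planar
#'   metres), or a two-column matrix. Duplicate fixes are retained; each
#'   counts toward coverage (duplicates encode utilisation intensity).
#' @param a hull budget in metres; default [choose_a()] (max pairwise
#'   distance).
#' @param levels isopleth levels, fractions in (0, 1].
#' @param group_id,season optional labels stored in the fit.
#' @return an object of class `"locoh"`: a list with `isopleths` (named list
#'   of polygons), `areas_ha`, `levels`, `coverage`, `a`, `n`, `points`,
#'   `group_id`, `season`.
#' @examples
#' set.seed(1)
#' fx <- data.frame(x = rnorm(100, sd = 150), y = rnorm(100, sd = 150))
#' fit <- locoh(fx)
#' summary(fit)
#' @export
locoh <- function(fixes, a = NULL, levels = c(0.5, 0.75, 0.95),
                  group_id = NA_character_, season = NA_character_) {
  pts <- fixes_matrix(fixes)
  if (nrow(pts) < 3L) stop("need at least 3 fixes", call. = FALSE)
  if (is.null(a)) a <- choose_a(pts)
  hulls <- build_local_hulls(pts, a)
  iso <- compute_isopleths(hulls, levels, pts)
  structure(list(isopleths = iso$isopleths,
                 areas_ha = iso$areas_ha,
                 levels = iso$levels,
                 coverage = iso$coverage,
                 n_hulls_used = iso$n_hulls_used,
                 a = a,
                 n = nrow(pts),
                 points = pts,
                 group_id = group_id,
                 season = season),
            class = "locoh")
}

fixes_matrix <- function(fixes) {
  if (is.matrix(fixes)) {
    pts <- fixes[, 1:2, drop = FALSE]
  } else if (is.data.frame(fixes)) {
    if (!all(c("x", "y") %in% names(fixes)))
      stop("fixes data frame needs columns x and y", call. = FALSE)
    pts <- cbind(fixes$x, fixes$y)
  } else stop("fixes must be a matrix or data frame", call. = FALSE)
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("non-finite fix coordinates", call. = FALSE)
  colnames(pts) <- c("x", "y")
  pts
}

#' @export
print.locoh <- function(x, ...) {
  cat("a-LoCoH territory fit\n")
  if (!is.na(x$group_id)) cat("  group:", x$group_id,
                              if (!is.na(x$season)) paste0("(", x$season, ")"), "\n")
  cat(sprintf("  fixes: %d   a: %.1f m\n", x$n, x$a))
  cat("  isopleth areas (ha):\n")
  print(round(x$areas_ha, 3))
  invisible(x)
}

#' @export
summary.locoh <- function(object, ...) {
  out <- data.frame(level = object$levels,
                    area_ha = as.numeric(object$areas_ha),
                    fixes_covered = as.integer(object$coverage),
                    fixes_required = ceiling(object$levels * object$n),
                    hulls_used = as.integer(object$n_hulls_used))
  structure(list(table = out, a = object$a, n = object$n,
                 group_id = object$group_id, season = object$season),
            class = "summary.locoh")
}

#' @export
print.summary.locoh <- function(x, ...) {
  cat(sprintf("a-LoCoH fit: %d fixes, a = %.1f m\n", x$n, x$a))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Classify points into territory bands
#'
#' Assigns each new point the innermost isopleth band that contains it
#' (boundary inclusive): `core50`, `band50_75`, `band75_95`, or `outside95`.
#' Requires a fit with levels 0.5, 0.75 and 0.95.
#'
#' @param object a `"locoh"` fit.
#' @param newdata data frame or matrix with `x`, `y` columns.
#' @param ... unused.
#' @return factor with levels `core50`, `band50_75`, `band75_95`,
#'   `outside95`.
#' @export
predict.locoh <- function(object, newdata, ...) {
  pts <- fixes_matrix(newdata)
  needed <- c("0.5", "0.75", "0.95")
  if (!all(needed %in% names(object$isopleths)))
    stop("band classification needs isopleth levels 0.5, 0.75 and 0.95",
         call. = FALSE)
  in50 <- points_in_poly(pts[, 1L], pts[, 2L], object$isopleths[["0.5"]])
  in75 <- points_in_poly(pts[, 1L], pts[, 2L], object$isopleths[["0.75"]])
  in95 <- points_in_poly(pts[, 1L], pts[, 2L], object$isopleths[["0.95"]])
  band <- rep("outside95", nrow(pts))
  band[in95] <- "band75_95"
  band[in75] <- "band50_75"
  band[in50] <- "core50"
  factor(band, levels = band_names())
}

band_names <- function() c("core50", "band50_75", "band75_95", "outside95")

#' Band of a single point within a fitted territory
#'
#' Convenience wrapper around [predict.locoh()] for one point.
#'
#' @param point numeric length-2 vector (x, y) or 1-row data frame.
#' @param territory a `"locoh"` fit with levels 0.5/0.75/0.95.
#' @return a length-1 factor (`core50`, `band50_75`, `band75_95`,
#'   `outside95`).
#' @export
classify_band <- function(point, territory) {
  if (is.numeric(point) && length(point) == 2L)
    point <- data.frame(x = point[1L], y = point[2L])
  predict(territory, point)
}

#' Plot a fitted territory
#'
#' Draws the nested isopleths (lightest = outermost) with the fixes
#' overlaid.
#'
#' @param x a `"locoh"` fit.
#' @param show_fixes overlay the fix locations.
#' @param ... passed to [graphics::plot()].
#' @export
plot.locoh <- function(x, show_fixes = TRUE, ...) {
  bb <- poly_bbox(x$isopleths[[length(x$isopleths)]])
  graphics::plot(NA, xlim = bb[1:2], ylim = bb[3:4], asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = if (!is.na(x$group_id)) paste("Territory", x$group_id)
                        else "a-LoCoH territory", ...)
  shades <- grDevices::grey.colors(length(x$isopleths), start = 0.85, end = 0.5)
  for (j in rev(seq_along(x$isopleths))) {
    for (ring in x$isopleths[[j]]) {
      graphics::polygon(ring$x, ring$y, col = shades[j], border = "grey30")
    }
  }
  if (show_fixes)
    graphics::points(x$points[, 1L], x$points[, 2L], pch = 16, cex = 0.4,
                     col = grDevices::rgb(0, 0, 0, 0.4))
  invisible(x)
}
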