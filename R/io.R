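# Readers and writers for the tabular field-data inputs and geographic
# outputs. Inputs are delimited text (comma by default) with a header row;
# a `dialect` mapping lets files with different column names be read without
# editing them. Coordinates must be planar metres (projected); timestamps
# ISO-8601.

# Resolve required columns through the dialect mapping and fail loudly.
# dialect: named character vector mapping canonical name -> file column name.
resolve_columns <- function(df, canonical, dialect = NULL, path = "") {
  out <- list()
  for (cn in canonical) {
    col <- if (!is.null(dialect) && cn %in% names(dialect)) dialect[[cn]] else cn
    if (!col %in% names(df))
      stop("missing column '", col, "' (for field '", cn, "') in ", path,
           call. = FALSE)
    out[[cn]] <- df[[col]]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

read_delim_file <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    quote = "\"", fileEncoding = "UTF-8")
}

parse_numeric <- function(v, field, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) | !is.finite(out))
  if (length(bad))
    stop("non-numeric value in column '", field, "' at data row ", bad[1L],
         " of ", path, call. = FALSE)
  out
}

parse_timestamp <- function(v, field, path) {
  out <- as.POSIXct(v, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d"))
  bad <- which(is.na(out))
  if (length(bad))
    stop("unparseable timestamp in column '", field, "' at data row ",
         bad[1L], " of ", path, call. = FALSE)
  out
}

parse_date <- function(v, field, path) {
  out <- as.Date(v, tryFormats = c("%Y-%m-%d"))
  bad <- which(is.na(out))
  if (length(bad))
    stop("unparseable date in column '", field, "' at data row ", bad[1L],
         " of ", path, call. = FALSE)
  out
}

#' Read GPS fixes of group movements
#'
#' Expects columns `group_id`, `timestamp`, `x`, `y` (planar metres);
#' alternative file column names are supplied via `dialect`, e.g.
#' `c(x = "easting", y = "northing")`. Rows are returned sorted by
#' (`group_id`, `timestamp`); row count is preserved.
#'
#' @param path delimited text file with a header row (UTF-8).
#' @param dialect named character vector mapping canonical column names to
#'   the file's column names.
#' @param sep field separator (default comma).
#' @return data frame with columns `group_id` (character), `timestamp`
#'   (POSIXct, UTC), `x`, `y` (numeric metres).
#' @export
read_fixes <- function(path, dialect = NULL, sep = ",") {
  raw <- read_delim_file(path, sep)
  df <- resolve_columns(raw, c("group_id", "timestamp", "x", "y"), dialect, path)
  out <- data.frame(group_id = as.character(df$group_id),
                    timestamp = parse_timestamp(df$timestamp, "timestamp", path),
                    x = parse_numeric(df$x, "x", path),
                    y = parse_numeric(df$y, "y", path),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read located call events
#'
#' Columns: `caller_id`, `group_id`, `timestamp`, `x`, `y`, and optionally
#' `session_id` (defaults to the calendar date).
#'
#' @inheritParams read_fixes
#' @return data frame sorted by (`caller_id`, `timestamp`).
#' @export
read_calls <- function(path, dialect = NULL, sep = ",") {
  raw <- read_delim_file(path, sep)
  df <- resolve_columns(raw, c("caller_id", "group_id", "timestamp", "x", "y"),
                        dialect, path)
  sid_col <- if (!is.null(dialect) && "session_id" %in% names(dialect))
    dialect[["session_id"]] else "session_id"
  ts <- parse_timestamp(df$timestamp, "timestamp", path)
  out <- data.frame(caller_id = as.character(df$caller_id),
                    group_id = as.character(df$group_id),
                    timestamp = ts,
                    x = parse_numeric(df$x, "x", path),
                    y = parse_numeric(df$y, "y", path),
                    session_id = if (sid_col %in% names(raw))
                      as.character(raw[[sid_col]]) else format(ts, "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$caller_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read individual life-history records
#'
#' Columns: `id`, `sex` (`male`/`female`/`unknown`), `hatch_date`,
#' `group_id`, `rank` (`dominant`/`subordinate`). Validates that no group
#' carries two dominants of the same sex.
#'
#' @inheritParams read_fixes
#' @return data frame of individuals.
#' @export
read_individuals <- function(path, dialect = NULL, sep = ",") {
  raw <- read_delim_file(path, sep)
  df <- resolve_columns(raw, c("id", "sex", "hatch_date", "group_id", "rank"),
                        dialect, path)
  out <- data.frame(id = as.character(df$id),
                    sex = as.character(df$sex),
                    hatch_date = parse_date(df$hatch_date, "hatch_date", path),
                    group_id = as.character(df$group_id),
                    rank = as.character(df$rank),
                    stringsAsFactors = FALSE)
  validate_individuals(out)
  out
}

validate_individuals <- function(ind) {
  bad_sex <- setdiff(unique(ind$sex), c("male", "female", "unknown"))
  if (length(bad_sex))
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  bad_rank <- setdiff(unique(ind$rank), c("dominant", "subordinate"))
  if (length(bad_rank))
    stop("invalid rank value(s): ", paste(bad_rank, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ind$id))
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "), call. = FALSE)
  dom <- ind[ind$rank == "dominant" & ind$sex != "unknown", ]
  if (nrow(dom)) {
    key <- paste(dom$group_id, dom$sex)
    if (anyDuplicated(key))
      stop("group has more than one dominant of the same sex: ",
           unique(key[duplicated(key)])[1L], call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pedigree file
#'
#' Three columns `id`, `dam`, `sire`; `"?"`, `"NA"` or empty marks an unknown
#' parent. The pedigree must be acyclic.
#'
#' @inheritParams read_fixes
#' @return data frame with columns `id`, `dam`, `sire` (`NA` for unknown
#'   parents), topologically valid.
#' @export
read_pedigree <- function(path, dialect = NULL, sep = ",") {
  raw <- read_delim_file(path, sep)
  df <- resolve_columns(raw, c("id", "dam", "sire"), dialect, path)
  clean <- function(v) {
    v <- as.character(v)
    v[v %in% c("?", "", "NA")] <- NA_character_
    v
  }
  ped <- data.frame(id = as.character(df$id), dam = clean(df$dam),
                    sire = clean(df$sire), stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}

#' Read daily weighing sessions
#'
#' Columns: `individual_id`, `date`, `mass_start`, `mass_end` (grams,
#' positive), `n_calling_bouts` (non-negative integer).
#'
#' @inheritParams read_fixes
#' @return data frame of weighing sessions.
#' @export
read_weights <- function(path, dialect = NULL, sep = ",") {
  raw <- read_delim_file(path, sep)
  df <- resolve_columns(raw, c("individual_id", "date", "mass_start",
                               "mass_end", "n_calling_bouts"), dialect, path)
  out <- data.frame(individual_id = as.character(df$individual_id),
                    date = parse_date(df$date, "date", path),
                    mass_start = parse_numeric(df$mass_start, "mass_start", path),
                    mass_end = parse_numeric(df$mass_end, "mass_end", path),
                    n_calling_bouts = parse_numeric(df$n_calling_bouts,
                                                    "n_calling_bouts", path),
                    stringsAsFactors = FALSE)
  bad <- which(out$mass_start <= 0 | out$mass_end <= 0)
  if (length(bad))
    stop("non-positive mass at data row ", bad[1L], " of ", path, call. = FALSE)
  bad <- which(out$n_calling_bouts < 0 | out$n_calling_bouts %% 1 != 0)
  if (length(bad))
    stop("n_calling_bouts must be a non-negative integer at data row ",
         bad[1L], " of ", path, call. = FALSE)
  out$n_calling_bouts <- as.integer(out$n_calling_bouts)
  out
}

#' Read a complete dataset directory
#'
#' Reads `fixes.csv`, `calls.csv`, `individuals.csv`, `pedigree.csv` and
#' `weights.csv` from a directory and validates cross-references (every call
#' and weight record must refer to a known individual; callers must belong
#' to their recorded group).
#'
#' @param dir directory containing the five files.
#' @return an object of class `"call_dataset"`: a list with elements
#'   `fixes`, `calls`, `individuals`, `pedigree`, `weights`.
#' @export
read_dataset <- function(dir) {
  ds <- structure(list(
    fixes = read_fixes(file.path(dir, "fixes.csv")),
    calls = read_calls(file.path(dir, "calls.csv")),
    individuals = read_individuals(file.path(dir, "individuals.csv")),
    pedigree = read_pedigree(file.path(dir, "pedigree.csv")),
    weights = read_weights(file.path(dir, "weights.csv"))
  ), class = "call_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a dataset's cross-references
#'
#' @param ds a `"call_dataset"` list.
#' @return invisibly TRUE; stops on dangling identifiers.
#' @export
validate_dataset <- function(ds) {
  ids <- ds$individuals$id
  miss <- setdiff(ds$calls$caller_id, ids)
  if (length(miss))
    stop("call caller_id(s) not in individuals: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  grp <- stats::setNames(ds$individuals$group_id, ds$individuals$id)
  bad <- ds$calls$group_id != grp[ds$calls$caller_id]
  if (any(bad))
    stop("call group_id disagrees with caller's group for caller ",
         ds$calls$caller_id[which(bad)[1L]], call. = FALSE)
  miss <- setdiff(ds$weights$individual_id, ids)
  if (length(miss))
    stop("weight individual_id(s) not in individuals: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  miss <- setdiff(ds$pedigree$id, c(ids, ds$pedigree$id))
  validate_pedigree(ds$pedigree)
  # fixes: timestamps non-decreasing within group after read sort
  invisible(TRUE)
}

#' Write a dataset to a directory of delimited files
#'
#' Inverse of [read_dataset()]; writes the five standard CSV files.
#'
#' @param ds a `"call_dataset"`.
#' @param dir output directory (created if absent).
#' @return invisibly `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    df2 <- df
    for (cn in names(df2)) {
      if (inherits(df2[[cn]], "POSIXct"))
        df2[[cn]] <- format(df2[[cn]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      if (inherits(df2[[cn]], "Date")) df2[[cn]] <- format(df2[[cn]], "%Y-%m-%d")
    }
    utils::write.table(df2, file.path(dir, file), sep = ",", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  ped <- ds$pedigree
  ped$dam[is.na(ped$dam)] <- "?"
  ped$sire[is.na(ped$sire)] <- "?"
  wr(ds$fixes, "fixes.csv")
  wr(ds$calls, "calls.csv")
  wr(ds$individuals, "individuals.csv")
  wr(ped, "pedigree.csv")
  wr(ds$weights, "weights.csv")
  invisible(dir)
}

#' Write territory isopleths as GeoJSON
#'
#' Writes one Feature per (group, level) polygon into an RFC 7946
#' FeatureCollection with properties `group_id`, `level` and `area_ha`
#' (plus any extras supplied). Rings with more than one part become
#' MultiPolygon geometries. Coordinates are written in full double
#' precision, so a round-trip read reproduces vertices to well below 1e-6.
#'
#' @param territories a named list: `territories[[group_id]]` is a named list
#'   mapping level (e.g. `"0.95"`) to a polygon; a `"locoh"` fit or a list of
#'   fits is also accepted.
#' @param path output file.
#' @param properties optional named list of extra per-feature properties,
#'   indexed like `territories`.
#' @return invisibly `path`.
#' @export
write_polygons <- function(territories, path, properties = NULL) {
  if (inherits(territories, "locoh")) territories <- list(territories)
  if (length(territories) && inherits(territories[[1L]], "locoh")) {
    props <- list()
    tt <- list()
    for (fit in territories) {
      gid <- if (is.na(fit$group_id)) "group" else fit$group_id
      tt[[gid]] <- fit$isopleths
      props[[gid]] <- list(a_value = fit$a, n_fixes = fit$n)
    }
    territories <- tt
    if (is.null(properties)) properties <- props
  }
  features <- list()
  for (gid in names(territories)) {
    for (lev in names(territories[[gid]])) {
      poly <- territories[[gid]][[lev]]
      if (length(poly) == 0L) next
      validate_polygon(poly)
      geom <- polygon_to_geojson_geometry(poly)
      pr <- list(group_id = gid, level = as.numeric(lev),
                 area_ha = area_hectares(poly))
      if (!is.null(properties) && gid %in% names(properties))
        pr <- c(pr, properties[[gid]])
      features[[length(features) + 1L]] <-
        list(type = "Feature", properties = pr, geometry = geom)
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = TRUE)
  invisible(path)
}

# Group rings into outer-ring + holes structures by containment, and emit a
# Polygon or MultiPolygon geometry (closed linear rings, RFC 7946).
polygon_to_geojson_geometry <- function(poly) {
  outer <- which(vapply(poly, ring_signed_area, numeric(1)) >= 0)
  holes <- setdiff(seq_along(poly), outer)
  parts <- lapply(outer, function(i) list(poly[[i]]))
  if (length(holes)) {
    for (h in holes) {
      hx <- poly[[h]]$x[1L]; hy <- poly[[h]]$y[1L]
      owner <- NULL
      for (k in seq_along(outer)) {
        if (points_in_poly(hx, hy, list(poly[[outer[k]]]))) { owner <- k; break }
      }
      if (is.null(owner)) owner <- 1L
      parts[[owner]] <- c(parts[[owner]], list(poly[[h]]))
    }
  }
  close_ring <- function(r) {
    xs <- c(r$x, r$x[1L]); ys <- c(r$y, r$y[1L])
    lapply(seq_along(xs), function(i) c(xs[i], ys[i]))
  }
  coords <- lapply(parts, function(p) lapply(p, close_ring))
  if (length(coords) == 1L) {
    list(type = "Polygon", coordinates = coords[[1L]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
}

#' Read polygons written by [write_polygons()]
#'
#' @param path GeoJSON FeatureCollection file.
#' @return a data-frame-free structure: named list by `group_id`, each a
#'   named list by level of polygons, with an attribute `"properties"`
#'   holding the feature property lists.
#' @export
read_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  out <- list()
  props <- list()
  for (f in fc$features) {
    gid <- f$properties$group_id
    lev <- as.character(as.numeric(f$properties$level))
    geom <- f$geometry
    rings <- if (geom$type == "Polygon") list(geom$coordinates)
             else geom$coordinates
    poly <- list()
    for (part in rings) {
      for (ring in part) {
        xs <- vapply(ring, function(p) as.numeric(p[[1L]]), numeric(1))
        ys <- vapply(ring, function(p) as.numeric(p[[2L]]), numeric(1))
        n <- length(xs)
        if (n > 1 && xs[1L] == xs[n] && ys[1L] == ys[n]) {
          xs <- xs[-n]; ys <- ys[-n]
        }
        poly[[length(poly) + 1L]] <- list(x = xs, y = ys)
      }
    }
    out[[gid]][[lev]] <- poly
    props[[length(props) + 1L]] <- f$properties
  }
  attr(out, "properties") <- props
  out
}

#' Convert longitude/latitude to UTM metres
#'
#' Convenience converter for data recorded in geographic coordinates; the
#' zone must be declared by the caller (projection choice is the user's —
#' over a field site a few kilometres across any metric projection agrees to
#' within GPS accuracy). Standard WGS84 transverse Mercator series
#' (Krueger), accurate to well under a metre.
#'
#' @param lon,lat numeric degrees.
#' @param zone UTM zone number (1-60).
#' @param north TRUE for the northern hemisphere (southern adds the
#'   10,000,000 m false northing).
#' @return data frame with `x` (easting) and `y` (northing) in metres.
#' @export
lonlat_to_utm <- function(lon, lat, zone, north = lat[1] >= 0) {
  if (zone < 1 || zone > 60) stop("zone must be in 1..60", call. = FALSE)
  a <- 6378137; f <- 1 / 298.257223563
  k0 <- 0.9996; e2 <- f * (2 - f)
  lam0 <- (6 * zone - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lam0
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  C <- e2 / (1 - e2) * cos(phi)^2
  A <- cos(phi) * lam
  e4 <- e2^2; e6 <- e2^3
  M <- a * ((1 - e2 / 4 - 3 * e4 / 64 - 5 * e6 / 256) * phi -
            (3 * e2 / 8 + 3 * e4 / 32 + 45 * e6 / 1024) * sin(2 * phi) +
            (15 * e4 / 256 + 45 * e6 / 1024) * sin(4 * phi) -
            (35 * e6 / 3072) * sin(6 * phi))
  ep2 <- e2 / (1 - e2)
  x <- k0 * N * (A + (1 - Tt + C) * A^3 / 6 +
                 (5 - 18 * Tt + Tt^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 + (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * Tt + Tt^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (!north) y <- y + 1e7
  data.frame(x = x, y = y)
}
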