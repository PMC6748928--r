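# Reading, validating and writing the file formats the pipeline touches:
# GPS fix CSV, accelerometer CSV, scat CSV, GeoJSON and ESRI ASCII rasters.
# Coordinates are required in projected meters throughout; all distance
# thresholds in the analysis (50-m cluster radius, 30-m raster cells, ...)
# are metric.

#' Construct a trajectory
#'
#' A trajectory is the unit of movement analysis: the time-ordered GPS fixes
#' of one animal over one season, with a nominal fix interval.
#'
#' @param fixes data.frame with columns `timestamp` (POSIXct, UTC), `x`, `y`
#'   (projected meters) and optionally `dop`, `n_sats`, `error_sd`.
#' @param animal_id identifier of the collared animal.
#' @param nominal_interval nominal fix spacing in seconds (default 900,
#'   i.e. 15-minute fixes).
#' @param season_window optional `Date` vector of length 2 giving the season
#'   the fixes belong to.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(fixes, animal_id, nominal_interval = 900,
                       season_window = NULL) {
  stopifnot(is.data.frame(fixes))
  need <- c("timestamp", "x", "y")
  miss <- setdiff(need, names(fixes))
  if (length(miss))
    stop_bad_arg("fixes are missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(fixes) > 1L) {
    ts <- as.numeric(fixes$timestamp)
    if (any(diff(ts) <= 0))
      stop_bad_arg("fix timestamps must be strictly increasing; ",
                   "use read_fixes() to sort and deduplicate raw data")
  }
  for (col in c("dop", "n_sats", "error_sd"))
    if (is.null(fixes[[col]])) fixes[[col]] <- NA_real_
  structure(
    list(animal_id = as.character(animal_id),
         fixes = fixes,
         nominal_interval = nominal_interval,
         season_window = season_window),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s: %d fixes", x$animal_id, nrow(x$fixes)))
  if (nrow(x$fixes)) {
    cat(sprintf(", %s to %s",
                format(min(x$fixes$timestamp), "%Y-%m-%d %H:%M", tz = "UTC"),
                format(max(x$fixes$timestamp), "%Y-%m-%d %H:%M", tz = "UTC")))
  }
  cat("\n")
  invisible(x)
}

#' Number of fixes in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_fixes <- function(traj) nrow(traj$fixes)

.parse_iso8601 <- function(s) {
  s2 <- sub("Z$", "", sub("T", " ", trimws(s), fixed = TRUE))
  out <- as.POSIXct(strptime(s2, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(s2[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read GPS fixes from CSV into per-animal trajectories
#'
#' Expects a header with columns `animal_id`, `timestamp` (ISO-8601), `x`,
#' `y` and optionally `dop`, `n_sats`. Rows outside `season_window` are
#' dropped; rows are sorted by time within animal; duplicate timestamps are
#' resolved by keeping the first occurrence (a message reports how many were
#' dropped). Coordinates are never altered.
#'
#' @param path CSV file path.
#' @param nominal_interval nominal fix spacing in seconds.
#' @param season_window optional `Date` length-2 vector (start, end),
#'   inclusive; e.g. `as.Date(c("2010-05-01", "2010-08-31"))`.
#' @return list of `trajectory`, one per animal, in animal-id order.
#' @export
read_fixes <- function(path, nominal_interval = 900, season_window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  for (col in need)
    if (is.null(df[[col]]))
      stop_bad_arg("fix CSV is missing mandatory column `", col, "`")
  if (nrow(df) == 0L) return(list())
  ts <- .parse_iso8601(as.character(df$timestamp))
  bad <- which(is.na(ts))
  if (length(bad))
    stop_bad_arg("unparseable timestamp(s) at data line(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  df$timestamp <- ts
  if (!is.null(season_window)) {
    d <- as.Date(ts, tz = "UTC")
    keep <- d >= season_window[1] & d <= season_window[2]
    if (any(!keep))
      message(sum(!keep), " fix(es) outside the season window dropped")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(list())
  out <- list()
  for (id in sort(unique(df$animal_id))) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    sub <- sub[order(as.numeric(sub$timestamp)), , drop = FALSE]
    dup <- duplicated(as.numeric(sub$timestamp))
    if (any(dup)) {
      message(sum(dup), " duplicate timestamp(s) for animal ", id,
              " dropped (first kept)")
      sub <- sub[!dup, , drop = FALSE]
    }
    rownames(sub) <- NULL
    keep_cols <- intersect(c("timestamp", "x", "y", "dop", "n_sats",
                             "error_sd"), names(sub))
    out[[id]] <- trajectory(sub[, keep_cols, drop = FALSE], animal_id = id,
                            nominal_interval = nominal_interval,
                            season_window = season_window)
  }
  out
}

#' Write trajectories to a fix CSV
#'
#' Inverse of [read_fixes()]: timestamps are written as ISO-8601 UTC.
#'
#' @param trajs a `trajectory` or list of trajectories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    f <- tr$fixes
    data.frame(animal_id = rep(tr$animal_id, nrow(f)),
               timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               x = f$x, y = f$y,
               dop = f$dop, n_sats = f$n_sats,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(animal_id = character(), timestamp = character(),
                                    x = numeric(), y = numeric(),
                                    dop = numeric(), n_sats = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assign per-fix location error standard deviations
#'
#' The collar reports a dilution-of-precision (DOP) value per fix; the
#' location-error standard deviation is modelled as `dop * uere` (user
#' equivalent range error), the conventional GPS error budget. Fixes without
#' DOP receive `default_sd`. A 1-m floor prevents degenerate zero-error
#' fixes.
#'
#' @param traj a `trajectory`.
#' @param uere meters of error per unit DOP (default 5).
#' @param default_sd fallback standard deviation in meters when DOP is
#'   missing (default 20).
#' @param floor_sd minimum error sd in meters (default 1).
#' @return the trajectory with `error_sd` filled in.
#' @export
assign_error <- function(traj, uere = 5, default_sd = 20, floor_sd = 1) {
  check_scalar(uere, "uere", positive = TRUE)
  check_scalar(default_sd, "default_sd", positive = TRUE)
  dop <- traj$fixes$dop
  sd <- ifelse(is.na(dop), default_sd, dop * uere)
  traj$fixes$error_sd <- pmax(sd, floor_sd)
  traj
}

## ---- activity CSV ----------------------------------------------------------

#' Read accelerometer activity records from CSV
#'
#' Columns: `animal_id`, `timestamp` (ISO-8601), `x_axis`, `y_axis` — the
#' side-to-side and front-to-back axis values averaged over 5-minute
#' periods. Activity is their sum. Negative raw axis values are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with columns animal_id, timestamp, x_axis, y_axis,
#'   activity, sorted by animal then time.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("animal_id", "timestamp", "x_axis", "y_axis"))
    if (is.null(df[[col]]))
      stop_bad_arg("activity CSV is missing mandatory column `", col, "`")
  if (nrow(df)) {
    ts <- .parse_iso8601(as.character(df$timestamp))
    if (anyNA(ts)) stop_bad_arg("unparseable timestamp(s) in activity CSV")
    df$timestamp <- ts
    if (any(df$x_axis < 0 | df$y_axis < 0))
      stop_bad_arg("negative accelerometer values are invalid")
    df$activity <- df$x_axis + df$y_axis
    df <- df[order(df$animal_id, as.numeric(df$timestamp)), , drop = FALSE]
    rownames(df) <- NULL
  } else df$activity <- numeric(0)
  df
}

#' Write activity records to CSV
#' @param records data.frame as returned by [read_activity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity <- function(records, path) {
  out <- data.frame(animal_id = records$animal_id,
                    timestamp = format(records$timestamp,
                                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    x_axis = records$x_axis, y_axis = records$y_axis,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## ---- scat CSV --------------------------------------------------------------

.scat_fixed_cols <- c("scat_id", "area_label", "diameter", "tracks_present",
                      "species_assignment", "species_true")

#' Read scat records from CSV
#'
#' Fixed columns: `scat_id`, `area_label`, `diameter` (mm),
#' `tracks_present` (logical). Any additional numeric columns are treated as
#' per-prey percent-volume composition (0--100).
#'
#' @param path CSV file path.
#' @return data.frame of scat records with attribute `prey_cols`.
#' @export
read_scats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("scat_id", "area_label", "diameter", "tracks_present"))
    if (is.null(df[[col]]))
      stop_bad_arg("scat CSV is missing mandatory column `", col, "`")
  df$tracks_present <- as.logical(df$tracks_present)
  if (nrow(df) && any(df$diameter <= 0))
    stop_bad_arg("scat diameters must be positive")
  prey <- setdiff(names(df), .scat_fixed_cols)
  attr(df, "prey_cols") <- prey
  df
}

#' Write scat records to CSV
#' @param scats scat data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scats <- function(scats, path) {
  utils::write.csv(scats, path, row.names = FALSE)
  invisible(path)
}

## ---- GeoJSON ---------------------------------------------------------------

.close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

.ring_coords <- function(m) {
  m <- .close_ring(m)
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write clusters or polygons to a GeoJSON FeatureCollection
#'
#' Clusters become Point features carrying member count, duration and site
#' class; isopleths and MCPs become (Multi)Polygon features carrying level
#' and area in km². Rings are closed (first vertex repeated). The CRS code
#' is recorded as a foreign member `crs_code` on the collection (GeoJSON
#' itself is CRS-agnostic).
#'
#' @param objects a `cluster_set`, an `isopleth`, an `mcp`, or a list of
#'   `isopleth`/`mcp` objects.
#' @param path output file path.
#' @param crs_code character CRS identifier, e.g. `"EPSG:32616"`.
#' @return `path`, invisibly.
#' @export
write_geo <- function(objects, path, crs_code = "EPSG:32616") {
  feats <- list()
  add_poly <- function(obj) {
    if (inherits(obj, "isopleth")) {
      coords <- lapply(obj$polygons, function(sq) list(.ring_coords(sq)))
      list(type = "Feature",
           geometry = list(type = "MultiPolygon", coordinates = coords),
           properties = list(level = obj$level, area_km2 = obj$area_km2))
    } else if (inherits(obj, "mcp")) {
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(.ring_coords(obj$coords))),
           properties = list(level = 1.0, area_km2 = obj$area_km2))
    } else stop_bad_arg("cannot write object of class ",
                        paste(class(obj), collapse = "/"))
  }
  if (inherits(objects, "cluster_set")) {
    feats <- lapply(seq_len(nrow(objects)), function(i) {
      cl <- objects[i, ]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(cl$centroid_x, cl$centroid_y)),
           properties = list(cluster_id = cl$cluster_id,
                             animal_id = cl$animal_id,
                             n_fixes = cl$n_fixes,
                             duration_h = cl$duration_h,
                             site_class = cl$site_class))
    })
  } else if (inherits(objects, c("isopleth", "mcp"))) {
    feats <- list(add_poly(objects))
  } else if (is.list(objects)) {
    feats <- lapply(objects, add_poly)
  } else stop_bad_arg("unsupported object for write_geo()")
  fc <- list(type = "FeatureCollection", crs_code = crs_code,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON file written by [write_geo()]
#' @param path file path.
#' @return the parsed FeatureCollection as a nested list.
#' @export
read_geo <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

## ---- ESRI ASCII grid -------------------------------------------------------

#' Write a utilization-distribution raster as an ESRI ASCII grid
#'
#' Header lines: ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value;
#' data rows run north to south.
#'
#' @param ud a `ud_raster`.
#' @param path output file path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(ud, path, nodata = -9999) {
  stopifnot(inherits(ud, "ud_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ud$ncol),
               sprintf("nrows %d", ud$nrow),
               sprintf("xllcorner %.10g", ud$xll),
               sprintf("yllcorner %.10g", ud$yll),
               sprintf("cellsize %.10g", ud$cell_size),
               sprintf("NODATA_value %d", nodata)), con)
  # internal storage: row 1 = southmost; ASCII grid wants north first
  for (r in seq(ud$nrow, 1L)) {
    writeLines(paste(sprintf("%.10e", ud$p[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid into a `ud_raster`
#' @param path file path.
#' @return a `ud_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- lapply(lines[7:(6 + hdr$nrows)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)          # row 1 = north
  m <- m[seq(nrow(m), 1L), , drop = FALSE]  # store south-first
  structure(list(xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cell_size = hdr$cellsize,
                 ncol = as.integer(hdr$ncols), nrow = as.integer(hdr$nrows),
                 p = m),
            class = "ud_raster")
}
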