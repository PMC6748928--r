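# Spatiotemporal GPS cluster detection: >= min_fixes locations within a
# fixed radius of a seed fix within a time window, scanned greedily in
# chronological order. Clusters flag revisited or prolonged-use sites
# (kills, carcass dumps, beds); their site classes are field labels, never
# inferred here.

.site_classes <- c("DEN", "PREDATION_SCAVENGING", "LCD", "UNDETERMINED",
                   "BED_RENDEZVOUS", "UNVISITED")

#' Cluster detection configuration
#'
#' @param min_fixes minimum member count (the field protocol used 8 for
#'   2009--2011 collars and 4 for 2013--2015 collars).
#' @param radius membership radius in meters (default 50).
#' @param time_window window length in hours anchored at the seed fix
#'   (default 24).
#' @param den_exclusion_radius meters; clusters with centroids this close
#'   to a den are excluded from use analyses (default 100).
#' @param buffer_radii buffer radii in meters for use counts
#'   (default c(50, 200)).
#' @param recollect logical; if TRUE, after a cluster forms, membership is
#'   re-collected once around the final centroid (sensitivity switch,
#'   default FALSE: membership is measured from the seed fix).
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(min_fixes = 4, radius = 50, time_window = 24,
                           den_exclusion_radius = 100,
                           buffer_radii = c(50, 200),
                           recollect = FALSE) {
  if (min_fixes < 2) stop_bad_arg("`min_fixes` must be >= 2")
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(time_window, "time_window", positive = TRUE)
  check_scalar(den_exclusion_radius, "den_exclusion_radius", positive = TRUE)
  structure(list(min_fixes = as.integer(min_fixes), radius = radius,
                 time_window = time_window,
                 den_exclusion_radius = den_exclusion_radius,
                 buffer_radii = buffer_radii, recollect = recollect),
            class = "cluster_config")
}

.empty_cluster_set <- function(animal_id = character(0)) {
  df <- data.frame(cluster_id = character(0), animal_id = character(0),
                   n_fixes = integer(0), centroid_x = numeric(0),
                   centroid_y = numeric(0), start = numeric(0),
                   end = numeric(0), duration_h = numeric(0),
                   site_class = character(0), stringsAsFactors = FALSE)
  df$member_indices <- list()
  class(df) <- c("cluster_set", "data.frame")
  df
}

#' Detect spatiotemporal GPS clusters
#'
#' Chronological greedy scan: the earliest unassigned fix becomes the seed;
#' candidate members are unassigned fixes within `time_window` hours after
#' the seed's timestamp AND within `radius` meters of the seed (closed
#' disc). If at least `min_fixes` candidates exist (seed included) they
#' form a cluster and are marked assigned; otherwise the scan advances.
#' The centroid is the arithmetic mean of member coordinates. Clusters are
#' disjoint in membership and returned sorted by start time. With
#' `config$recollect`, membership is re-collected once among unassigned
#' fixes around the final centroid and the centroid recomputed.
#'
#' @param traj a [trajectory()].
#' @param config a [cluster_config()].
#' @return a `cluster_set` data.frame (columns cluster_id, animal_id,
#'   n_fixes, centroid_x/y, start/end in epoch seconds, duration_h,
#'   site_class, list-column member_indices). Site classes start as NA.
#' @export
detect_clusters <- function(traj, config = cluster_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(config, "cluster_config"))
  f <- traj$fixes
  n <- nrow(f)
  out <- .empty_cluster_set()
  if (n == 0L) return(out)
  tsec <- as.numeric(f$timestamp)
  wsec <- config$time_window * 3600
  assigned <- rep(FALSE, n)
  rows <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    cand <- which(!assigned &
                    tsec >= tsec[seed] & tsec <= tsec[seed] + wsec)
    d <- sqrt((f$x[cand] - f$x[seed])^2 + (f$y[cand] - f$y[seed])^2)
    members <- cand[d <= config$radius]
    if (length(members) < config$min_fixes) next
    cen <- c(mean(f$x[members]), mean(f$y[members]))
    if (config$recollect) {
      cand2 <- which(!assigned &
                       tsec >= tsec[seed] & tsec <= tsec[seed] + wsec)
      d2 <- sqrt((f$x[cand2] - cen[1])^2 + (f$y[cand2] - cen[2])^2)
      members2 <- sort(unique(c(members, cand2[d2 <= config$radius])))
      if (length(members2) >= config$min_fixes) {
        members <- members2
        cen <- c(mean(f$x[members]), mean(f$y[members]))
      }
    }
    assigned[members] <- TRUE
    rows[[length(rows) + 1L]] <- list(members = members, centroid = cen)
  }
  if (!length(rows)) return(out)
  df <- data.frame(
    cluster_id = sprintf("%s_C%03d", traj$animal_id, seq_along(rows)),
    animal_id = traj$animal_id,
    n_fixes = vapply(rows, function(r) length(r$members), integer(1)),
    centroid_x = vapply(rows, function(r) r$centroid[1], numeric(1)),
    centroid_y = vapply(rows, function(r) r$centroid[2], numeric(1)),
    start = vapply(rows, function(r) min(tsec[r$members]), numeric(1)),
    end = vapply(rows, function(r) max(tsec[r$members]), numeric(1)),
    site_class = NA_character_,
    stringsAsFactors = FALSE)
  df$duration_h <- (df$end - df$start) / 3600
  df$member_indices <- lapply(rows, function(r) r$members)
  df <- df[order(df$start), , drop = FALSE]
  df$cluster_id <- sprintf("%s_C%03d", traj$animal_id, seq_len(nrow(df)))
  rownames(df) <- NULL
  class(df) <- c("cluster_set", "data.frame")
  df
}

#' Remove clusters near denning sites
#'
#' Den-adjacent clusters reflect pup-rearing attendance rather than
#' foraging and are excluded from use analyses. A cluster is removed when
#' its centroid lies within `den_exclusion_radius` of any den (closed
#' disc: a centroid at exactly the radius is removed).
#'
#' @param clusters a `cluster_set`.
#' @param den_xy_list list of den coordinates (each length 2); may be
#'   empty, in which case the input is returned unchanged.
#' @param den_exclusion_radius meters (default 100).
#' @return the filtered `cluster_set`; removals are reported via message.
#' @export
exclude_near_dens <- function(clusters, den_xy_list,
                              den_exclusion_radius = 100) {
  check_scalar(den_exclusion_radius, "den_exclusion_radius", positive = TRUE)
  if (!length(den_xy_list) || nrow(clusters) == 0L) return(clusters)
  cen <- cbind(clusters$centroid_x, clusters$centroid_y)
  near <- rep(FALSE, nrow(clusters))
  for (den in den_xy_list)
    near <- near | dist_to_point(cen, den) <= den_exclusion_radius
  if (any(near))
    message(sum(near), " cluster(s) within ", den_exclusion_radius,
            " m of a den excluded")
  out <- clusters[!near, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Count GPS locations within buffers around cluster centroids
#'
#' For each cluster and each buffer radius, counts all of the animal's
#' fixes over the whole season (cluster members included) within the
#' radius of the centroid — closed disc, so a fix at exactly the radius
#' counts. Records carry the LCD / non-LCD contrast used by the mixed
#' count model.
#'
#' @param traj the [trajectory()] the clusters came from.
#' @param clusters a `cluster_set` of the same animal with site classes
#'   assigned.
#' @param buffer_radii numeric radii in meters (default c(50, 200)).
#' @return data.frame with columns animal_id, cluster_id, radius, count,
#'   is_lcd.
#' @export
buffer_use_counts <- function(traj, clusters, buffer_radii = c(50, 200)) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(clusters) &&
      any(clusters$animal_id != traj$animal_id))
    stop_bad_arg("clusters belong to a different animal than the trajectory")
  f <- traj$fixes
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cen <- c(clusters$centroid_x[i], clusters$centroid_y[i])
    d <- sqrt((f$x - cen[1])^2 + (f$y - cen[2])^2)
    for (r in buffer_radii) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = traj$animal_id,
        cluster_id = clusters$cluster_id[i],
        radius = r,
        count = sum(d <= r),
        is_lcd = identical(clusters$site_class[i], "LCD"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(animal_id = character(0), cluster_id = character(0),
                      radius = numeric(0), count = integer(0),
                      is_lcd = logical(0)))
  do.call(rbind, rows)
}

#' Summarise site-use determinations of visited clusters
#'
#' Percentage of clusters per site class among visited clusters
#' (UNVISITED and unlabelled clusters are excluded). Rows follow the
#' conventional class order; percentages sum to 100.
#'
#' @param clusters a `cluster_set` with site classes assigned.
#' @return data.frame with columns site_class, n, percent (only classes
#'   present). Zero visited clusters gives an empty table with a warning.
#' @export
site_use_summary <- function(clusters) {
  visited <- clusters[!is.na(clusters$site_class) &
                        clusters$site_class != "UNVISITED", , drop = FALSE]
  if (nrow(visited) == 0L) {
    warning("no visited clusters to summarise")
    return(data.frame(site_class = character(0), n = integer(0),
                      percent = numeric(0)))
  }
  cls <- factor(visited$site_class,
                levels = setdiff(.site_classes, "UNVISITED"))
  tab <- table(cls)
  tab <- tab[tab > 0]
  data.frame(site_class = names(tab),
             n = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(visited),
             stringsAsFactors = FALSE)
}
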