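# Scat-based diet analysis: diameter cut-off from track-verified scats,
# wolf/unknown classification, and percent-by-volume composition tables.

#' First-quartile scat-diameter cut-off
#'
#' The cut-off separating wolf from smaller sympatric-canid (coyote) scats
#' is the first quartile of track-verified wolf scat diameters, computed by
#' linear interpolation on the sorted sample: index `h = (n - 1) * 0.25 +
#' 1`, interpolating between the floor(h)-th and ceiling(h)-th order
#' statistics (the dominant quantile convention in scientific software;
#' quartile definitions differ, so the convention is fixed here). The
#' unrounded quartile is returned; callers may round.
#'
#' @param track_verified_diameters numeric vector of diameters (mm) of
#'   scats with wolf tracks nearby; at least 4 values.
#' @return cut-off in mm.
#' @export
derive_diameter_cutoff <- function(track_verified_diameters) {
  d <- track_verified_diameters
  if (length(d) < 4L)
    stop_bad_arg("need at least 4 track-verified diameters")
  if (any(!is.finite(d)) || any(d <= 0))
    stop_bad_arg("diameters must be positive and finite")
  s <- sort(d)
  n <- length(s)
  h <- (n - 1) * 0.25 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Classify scats as wolf or unknown
#'
#' Track evidence dominates: a scat with wolf tracks nearby is WOLF
#' regardless of diameter. Otherwise a diameter at or above the cut-off is
#' WOLF and strictly below it is UNKNOWN (the rule excludes scats *under*
#' the cut-off, so a diameter exactly at it passes).
#'
#' @param scats scat data.frame (columns `diameter`, `tracks_present`).
#' @param cutoff diameter cut-off in mm (see [derive_diameter_cutoff()]).
#' @return the scat data.frame with a `species_assignment` column
#'   (`"WOLF"` or `"UNKNOWN"`).
#' @export
classify_scat <- function(scats, cutoff) {
  check_scalar(cutoff, "cutoff", positive = TRUE)
  scats$species_assignment <-
    ifelse(scats$tracks_present, "WOLF",
           ifelse(scats$diameter >= cutoff, "WOLF", "UNKNOWN"))
  scats
}

#' Percent-by-volume diet composition of wolf-classified scats
#'
#' Per prey category, the arithmetic mean of per-scat percent volumes
#' across WOLF-classified scats. Trace occurrences (entries <= 1% in a
#' scat) are zeroed before averaging — trace items are not identified to
#' species in the field protocol, so they cannot contribute volume.
#' UNKNOWN scats are excluded, never imputed.
#'
#' @param scats scat data.frame carrying `species_assignment` and percent
#'   columns.
#' @param area_label optional: restrict to one area.
#' @param prey_cols character vector of composition columns; defaults to
#'   the data.frame's `prey_cols` attribute, else [prey_categories()]
#'   intersected with the columns present.
#' @param trace_threshold percent at or below which an entry is zeroed
#'   (default 1).
#' @return one-row data.frame: `area_label`, `n_scats`, and one mean
#'   percent column per prey category.
#' @export
diet_composition <- function(scats, area_label = NULL, prey_cols = NULL,
                             trace_threshold = 1) {
  prey_cols <- prey_cols %||% attr(scats, "prey_cols") %||%
    intersect(prey_categories(), names(scats))
  if (!length(prey_cols))
    stop_bad_arg("no prey composition columns found")
  sub <- scats
  if (!is.null(area_label))
    sub <- sub[sub$area_label == area_label, , drop = FALSE]
  if (is.null(sub$species_assignment))
    stop_bad_arg("scats are unclassified; run classify_scat() first")
  sub <- sub[sub$species_assignment == "WOLF", , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_bad_arg("no wolf-classified scats",
                 if (!is.null(area_label)) paste0(" in area ", area_label)
                 else "")
  comp <- as.matrix(sub[, prey_cols, drop = FALSE])
  comp[comp <= trace_threshold] <- 0
  out <- data.frame(area_label = area_label %||% "ALL",
                    n_scats = nrow(sub), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(t(colMeans(comp))))
}

#' Coyote misclassification rate at a diameter cut-off
#'
#' Monte-Carlo fraction of coyote-scat diameters, drawn from the given
#' normal distribution, that fall at or above the cut-off and would
#' therefore pass as wolf.
#'
#' @param cutoff diameter cut-off in mm.
#' @param coyote_mu_sd length-2 c(mean, sd) of coyote diameters, mm
#'   (default c(25.1, 4.4)).
#' @param n_sim number of draws (>= 1000).
#' @param seed RNG seed.
#' @return probability in \[0, 1\].
#' @export
misclassification_rate <- function(cutoff, coyote_mu_sd = c(25.1, 4.4),
                                   n_sim = 1e5, seed = 1L) {
  check_scalar(cutoff, "cutoff", positive = TRUE)
  if (n_sim < 1000) stop_bad_arg("`n_sim` must be >= 1000")
  withr::with_seed(seed, {
    mean(stats::rnorm(n_sim, coyote_mu_sd[1], coyote_mu_sd[2]) >= cutoff)
  })
}
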