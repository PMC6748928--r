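# Synthetic scat data: diameters from the wolf/coyote mixture the diameter
# classifier assumes, and Dirichlet percent-volume compositions.

#' Simulate scat diameters for a wolf/coyote mixture
#'
#' Wolf diameters are drawn Normal(33.3, 6.1) mm and coyote diameters
#' Normal(25.1, 4.4) mm by default (field means of track-verified wolf
#' scats and of coyote scats), truncated above 5 mm by rejection. Track
#' evidence occurs only next to (true) wolf scats, with probability
#' `track_prob`. The true species is retained as a hidden label so
#' classifier performance can be scored.
#'
#' @param seed integer RNG seed.
#' @param n_wolf,n_coyote record counts (>= 0).
#' @param wolf_mu_sd,coyote_mu_sd length-2 vectors c(mean, sd) in mm.
#' @param track_prob probability that a wolf scat has tracks nearby.
#' @param area_label area label stamped on all records.
#' @return scat data.frame (columns scat_id, area_label, diameter,
#'   tracks_present, species_true).
#' @export
simulate_scats <- function(seed, n_wolf, n_coyote,
                           wolf_mu_sd = c(33.3, 6.1),
                           coyote_mu_sd = c(25.1, 4.4),
                           track_prob = 0.3,
                           area_label = "AREA") {
  if (n_wolf < 0 || n_coyote < 0)
    stop_bad_arg("scat counts must be non-negative")
  if (wolf_mu_sd[2] <= 0 || coyote_mu_sd[2] <= 0)
    stop_bad_arg("diameter standard deviations must be > 0")
  if (track_prob < 0 || track_prob > 1)
    stop_bad_arg("`track_prob` must lie in [0, 1]")
  n_wolf <- as.integer(n_wolf); n_coyote <- as.integer(n_coyote)
  if (n_wolf + n_coyote == 0L)
    return(data.frame(scat_id = character(0), area_label = character(0),
                      diameter = numeric(0), tracks_present = logical(0),
                      species_true = character(0)))
  rtruncnorm_min <- function(n, mu, sd, lo = 5) {
    out <- stats::rnorm(n, mu, sd)
    while (any(bad <- out <= lo))
      out[bad] <- stats::rnorm(sum(bad), mu, sd)
    out
  }
  withr::with_seed(seed, {
    dw <- if (n_wolf) rtruncnorm_min(n_wolf, wolf_mu_sd[1], wolf_mu_sd[2])
          else numeric(0)
    dc <- if (n_coyote) rtruncnorm_min(n_coyote, coyote_mu_sd[1],
                                       coyote_mu_sd[2]) else numeric(0)
    tw <- if (n_wolf) stats::runif(n_wolf) < track_prob else logical(0)
    data.frame(
      scat_id = sprintf("S%04d", seq_len(n_wolf + n_coyote)),
      area_label = area_label,
      diameter = c(dw, dc),
      tracks_present = c(tw, rep(FALSE, n_coyote)),
      species_true = c(rep("WOLF", n_wolf), rep("COYOTE", n_coyote)),
      stringsAsFactors = FALSE)
  })
}

#' Default prey categories for scat composition
#' @return character vector of category names.
#' @export
prey_categories <- function() {
  c("adult_deer", "fawn_deer", "cattle", "lagomorph", "rodent")
}

#' Simulate per-scat percent-volume compositions
#'
#' Each scat's composition vector is drawn Dirichlet(`dirichlet_weights`)
#' and scaled to percentages, so entries sum to 100 and the long-run mean
#' share of category j is `100 * w_j / sum(w)`. Zero weights are replaced
#' by `1e-6` (a category that is effectively absent); negative weights are
#' rejected.
#'
#' @param seed integer RNG seed.
#' @param n number of scats.
#' @param area_label area label stamped on the records.
#' @param dirichlet_weights named positive weights, one per prey category.
#' @return data.frame with scat_id, area_label and one percent column per
#'   category; attribute `prey_cols` lists the categories.
#' @export
simulate_scat_compositions <- function(seed, n, area_label = "AREA",
                                       dirichlet_weights =
                                         c(adult_deer = 62, fawn_deer = 8,
                                           cattle = 22, lagomorph = 6,
                                           rodent = 2)) {
  if (n < 0) stop_bad_arg("`n` must be non-negative")
  if (any(dirichlet_weights < 0))
    stop_bad_arg("Dirichlet weights must be non-negative")
  w <- dirichlet_weights
  w[w == 0] <- 1e-6
  k <- length(w)
  nm <- names(w) %||% paste0("prey", seq_len(k))
  out <- withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n * k, shape = rep(w, each = n), rate = 1),
                nrow = n, ncol = k)
    g / rowSums(g) * 100
  })
  if (n == 0L) out <- matrix(numeric(0), 0, k)
  colnames(out) <- nm
  df <- data.frame(scat_id = sprintf("S%04d", seq_len(n)),
                   area_label = rep(area_label, n),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(out))
  attr(df, "prey_cols") <- nm
  df
}
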