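# Dynamic Brownian bridge movement model (dBBMM) utilization distributions.
#
# The Brownian bridge conditions on consecutive GPS fixes: between fixes i
# and i+1 (time gap dt), the position at fraction alpha is bivariate normal
# with mean (1-alpha) z_i + alpha z_{i+1} and isotropic variance
#   dt * alpha * (1-alpha) * sigma2_m + (1-alpha)^2 delta_i^2
#                                     + alpha^2 delta_{i+1}^2,
# where sigma2_m is the Brownian motion variance (m^2/s) and delta the
# per-fix location-error sd. sigma2_m is estimated by leave-one-out: every
# second interior fix is predicted from its neighbours and the likelihood
# maximized. The *dynamic* variant re-estimates sigma2_m in sliding windows
# and allows one behavioural breakpoint per window, selected by BIC, so the
# UD tightens where movement is slow and spreads where it is fast.

#' dBBMM configuration
#'
#' @param window sliding-window length in fixes (default 25).
#' @param margin minimum fixes on each side of a candidate breakpoint
#'   (default 11); `window > 2 * margin` is required.
#' @param time_step bridge integration step in seconds (default 60).
#' @param cell_size raster cell size in meters (default 30).
#' @param max_bridge_gap seconds; fix pairs further apart contribute no
#'   bridge (default 3600 = four nominal 15-min intervals — bridges across
#'   long dropouts are unreliable).
#' @param sigma_grid length-2 search bounds for the motion variance,
#'   m²/s (default c(1e-8, 1e6)).
#' @param breakpoints logical; allow the two-segment window model
#'   (default TRUE). FALSE reduces the dynamic estimator to a static one.
#' @return object of class `dbbmm_config`.
#' @export
dbbmm_config <- function(window = 25, margin = 11, time_step = 60,
                         cell_size = 30, max_bridge_gap = 3600,
                         sigma_grid = c(1e-8, 1e6), breakpoints = TRUE) {
  if (window <= 2 * margin)
    stop_bad_arg("`window` must exceed 2 * `margin`")
  check_scalar(time_step, "time_step", positive = TRUE)
  check_scalar(cell_size, "cell_size", positive = TRUE)
  check_scalar(max_bridge_gap, "max_bridge_gap", positive = TRUE)
  if (length(sigma_grid) != 2L || any(sigma_grid <= 0) ||
      sigma_grid[1] >= sigma_grid[2])
    stop_bad_arg("`sigma_grid` must be an increasing positive pair")
  structure(list(window = as.integer(window), margin = as.integer(margin),
                 time_step = time_step, cell_size = cell_size,
                 max_bridge_gap = max_bridge_gap, sigma_grid = sigma_grid,
                 breakpoints = breakpoints),
            class = "dbbmm_config")
}

#' Brownian bridge variance at a fraction along a fix pair
#'
#' @param dt time gap between the fixes, seconds.
#' @param alpha fraction along the bridge in \[0, 1\].
#' @param sigma2 Brownian motion variance, m²/s.
#' @param err1,err2 location-error standard deviations (m) of the two
#'   fixes.
#' @return per-axis variance in m².
#' @export
bridge_variance <- function(dt, alpha, sigma2, err1, err2) {
  dt * alpha * (1 - alpha) * sigma2 +
    (1 - alpha)^2 * err1^2 + alpha^2 * err2^2
}

# Leave-one-out terms for a run of fixes: centres are every second interior
# fix (2, 4, ...). Returns parallel vectors used by the profile likelihood.
.loo_terms <- function(tsec, x, y, err_sd) {
  n <- length(tsec)
  ctr <- seq(2L, n - 1L, by = 2L)
  lo <- ctr - 1L; hi <- ctr + 1L
  Tt <- tsec[hi] - tsec[lo]
  alpha <- (tsec[ctr] - tsec[lo]) / Tt
  mux <- x[lo] + alpha * (x[hi] - x[lo])
  muy <- y[lo] + alpha * (y[hi] - y[lo])
  list(center = ctr,
       Tt = Tt, alpha = alpha,
       dsq = (x[ctr] - mux)^2 + (y[ctr] - muy)^2,
       e_lo = err_sd[lo]^2, e_hi = err_sd[hi]^2)
}

# Bivariate-normal LOO log likelihood at a given sigma2 over a term subset
.loo_loglik <- function(sigma2, tm, idx = seq_along(tm$center)) {
  a <- tm$alpha[idx]
  s2 <- tm$Tt[idx] * a * (1 - a) * sigma2 +
    (1 - a)^2 * tm$e_lo[idx] + a^2 * tm$e_hi[idx]
  s2 <- pmax(s2, 1e-12)
  sum(-log(2 * pi * s2) - tm$dsq[idx] / (2 * s2))
}

# Golden-section maximization of the LOO log likelihood over log(sigma2)
.fit_sigma2 <- function(tm, idx, sigma_grid, tol = 1e-4) {
  f <- function(u) .loo_loglik(exp(u), tm, idx)
  a <- log(sigma_grid[1]); b <- log(sigma_grid[2])
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  u <- (a + b) / 2
  list(sigma2 = exp(u), loglik = f(u))
}

#' Leave-one-out Brownian motion variance for a run of fixes
#'
#' Every second interior fix i is predicted from its neighbours: with
#' `alpha_i = (t_i - t_{i-1}) / (t_{i+1} - t_{i-1})` and
#' `T_i = t_{i+1} - t_{i-1}`, the predicted mean is the linear
#' interpolation of the neighbour positions and the predicted per-axis
#' variance `T_i alpha_i (1 - alpha_i) sigma2 + (1-alpha_i)^2 delta_{i-1}^2
#' + alpha_i^2 delta_{i+1}^2`. The bivariate-normal log likelihood summed
#' over these terms is maximized over `log(sigma2)` by golden-section
#' search.
#'
#' @param fixes data.frame with columns `timestamp`, `x`, `y`, `error_sd`
#'   (a trajectory's `$fixes`); at least 3 rows.
#' @param sigma_grid search bounds in m²/s (default c(1e-8, 1e6)).
#' @param tol golden-section tolerance on log(sigma2) (default 1e-4).
#' @return estimated motion variance, m²/s.
#' @export
loo_motion_variance <- function(fixes, sigma_grid = c(1e-8, 1e6),
                                tol = 1e-4) {
  if (nrow(fixes) < 3L)
    stop_bad_arg("motion variance needs at least 3 fixes")
  if (anyNA(fixes$error_sd))
    stop_bad_arg("all fixes need `error_sd`; run assign_error() first")
  tm <- .loo_terms(as.numeric(fixes$timestamp), fixes$x, fixes$y,
                   fixes$error_sd)
  fit <- .fit_sigma2(tm, seq_along(tm$center), sigma_grid, tol)
  if (!is.finite(fit$loglik))
    stop("non-finite motion-variance likelihood (check coordinates and ",
         "error_sd)", call. = FALSE)
  fit$sigma2
}

#' Admissible breakpoint positions in a window
#'
#' Candidate breakpoints must leave at least `margin` fixes on each side:
#' positions `margin + 1` through `window - margin` (a breakpoint at b
#' splits the window's leave-one-out terms by their centre fix: centres
#' <= b belong to the first segment).
#'
#' @param window,margin window length and margin, in fixes.
#' @return integer vector of admissible positions.
#' @export
admissible_breakpoints <- function(window, margin) {
  seq.int(margin + 1L, window - margin)
}

#' Sliding-window dynamic motion variance
#'
#' A window of `config$window` consecutive fixes slides one fix at a time.
#' Within each window a one-variance model and, for every admissible
#' breakpoint, a two-variance model (both segments scored on the window's
#' common leave-one-out term set, split by term centre) are fitted; the
#' model with the lowest BIC (`k log n` penalty, n = LOO terms in the
#' window) wins. The winning model's variances are recorded for the
#' window's central fixes (positions margin+1 ... window-margin); the final
#' per-fix estimate is the mean over all windows covering that fix, and
#' leading/trailing fixes inherit the nearest interior estimate. Tracks
#' shorter than one window fall back to a single global estimate.
#'
#' @param traj a [trajectory()] with `error_sd` assigned.
#' @param config a [dbbmm_config()].
#' @return object of class `motion_variance_profile`: data.frame with
#'   per-fix `sigma2` (m²/s) and `n_support` (windows contributing);
#'   attribute `breakpoint_windows` is a logical vector, one per window.
#' @export
dynamic_motion_variance <- function(traj, config = dbbmm_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(config, "dbbmm_config"))
  f <- traj$fixes
  n <- nrow(f)
  if (n < 3L) stop_bad_arg("motion variance needs at least 3 fixes")
  if (anyNA(f$error_sd))
    stop_bad_arg("all fixes need `error_sd`; run assign_error() first")
  tsec <- as.numeric(f$timestamp)
  w <- config$window; m <- config$margin

  if (n < w) {
    s2 <- loo_motion_variance(f, config$sigma_grid)
    prof <- data.frame(sigma2 = rep(s2, n), n_support = rep(1L, n))
    attr(prof, "breakpoint_windows") <- logical(0)
    class(prof) <- c("motion_variance_profile", "data.frame")
    return(prof)
  }

  acc <- numeric(n); cnt <- integer(n)
  n_win <- n - w + 1L
  bp_flag <- logical(n_win)
  brk <- admissible_breakpoints(w, m)
  for (ws in seq_len(n_win)) {
    idx <- ws:(ws + w - 1L)
    tm <- .loo_terms(tsec[idx], f$x[idx], f$y[idx], f$error_sd[idx])
    nt <- length(tm$center)
    fit0 <- .fit_sigma2(tm, seq_len(nt), config$sigma_grid)
    best <- list(bic = -2 * fit0$loglik + log(nt),
                 sig_of_pos = function(pos) fit0$sigma2, bp = FALSE)
    if (config$breakpoints) {
      for (b in brk) {
        left <- which(tm$center <= b)
        right <- which(tm$center > b)
        if (!length(left) || !length(right)) next
        fl <- .fit_sigma2(tm, left, config$sigma_grid)
        fr <- .fit_sigma2(tm, right, config$sigma_grid)
        bic <- -2 * (fl$loglik + fr$loglik) + 2 * log(nt)
        if (bic < best$bic) {
          best <- list(bic = bic, bp = TRUE,
                       sig_of_pos = local({
                         bb <- b; sl <- fl$sigma2; sr <- fr$sigma2
                         function(pos) ifelse(pos <= bb, sl, sr)
                       }))
        }
      }
    }
    bp_flag[ws] <- best$bp
    central <- (m + 1L):(w - m)
    sig <- vapply(central, best$sig_of_pos, numeric(1))
    at <- ws + central - 1L
    acc[at] <- acc[at] + sig
    cnt[at] <- cnt[at] + 1L
  }
  sigma2 <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  interior <- which(cnt > 0)
  lo <- min(interior); hi <- max(interior)
  if (lo > 1L) sigma2[seq_len(lo - 1L)] <- sigma2[lo]
  if (hi < n) sigma2[(hi + 1L):n] <- sigma2[hi]
  prof <- data.frame(sigma2 = sigma2, n_support = cnt)
  attr(prof, "breakpoint_windows") <- bp_flag
  class(prof) <- c("motion_variance_profile", "data.frame")
  prof
}

#' Build the utilization-distribution raster
#'
#' Integrates the Brownian bridge of every consecutive fix pair with time
#' gap at most `max_bridge_gap` at `time_step` increments (midpoint rule);
#' each evaluation deposits a bivariate-normal kernel (variance from
#' [bridge_variance()], with the pair's motion variance the mean of the two
#' endpoint per-fix estimates) weighted by `time_step` onto cell centres.
#' The grid covers the fix bounding box padded by three maximal bridge
#' standard deviations. The raster is normalized to total mass 1. Pairs
#' spanning longer gaps contribute nothing and are counted in a message.
#'
#' @param traj a [trajectory()] with `error_sd` assigned.
#' @param profile a `motion_variance_profile` aligned to `traj`.
#' @param config a [dbbmm_config()].
#' @return object of class `ud_raster`: list with `xll`, `yll` (grid
#'   corner), `cell_size`, `ncol`, `nrow` and probability matrix `p`
#'   (row 1 = southmost row).
#' @export
build_ud <- function(traj, profile, config = dbbmm_config()) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(profile, "motion_variance_profile"))
  f <- traj$fixes
  n <- nrow(f)
  if (nrow(profile) != n)
    stop_bad_arg("motion-variance profile is not aligned to the trajectory")
  tsec <- as.numeric(f$timestamp)
  cs <- config$cell_size
  dt <- diff(tsec)
  use <- which(dt > 0 & dt <= config$max_bridge_gap)
  skipped <- (n - 1L) - length(use)
  if (skipped > 0)
    message(skipped, " fix pair(s) spanning gaps > ",
            config$max_bridge_gap, " s contribute no bridge")
  if (!length(use))
    stop_bad_arg("no usable fix pairs within `max_bridge_gap`")

  s2p <- (profile$sigma2[use] + profile$sigma2[use + 1L]) / 2
  vmax <- max(dt[use] * 0.25 * s2p +
                pmax(f$error_sd[use], f$error_sd[use + 1L])^2)
  pad <- 3 * sqrt(vmax)
  xll <- floor((min(f$x) - pad) / cs) * cs
  yll <- floor((min(f$y) - pad) / cs) * cs
  ncol <- ceiling((max(f$x) + pad - xll) / cs)
  nrow <- ceiling((max(f$y) + pad - yll) / cs)
  if (ncol < 2L || nrow < 2L)
    stop_bad_arg("degenerate UD grid (", nrow, " x ", ncol,
                 " cells); reduce `cell_size`")
  xc <- xll + (seq_len(ncol) - 0.5) * cs
  yc <- yll + (seq_len(nrow) - 0.5) * cs
  M <- matrix(0, nrow, ncol)

  for (k in seq_along(use)) {
    i <- use[k]
    nstep <- max(1L, as.integer(round(dt[i] / config$time_step)))
    alphas <- (seq_len(nstep) - 0.5) / nstep
    for (a in alphas) {
      mx <- (1 - a) * f$x[i] + a * f$x[i + 1L]
      my <- (1 - a) * f$y[i] + a * f$y[i + 1L]
      v <- bridge_variance(dt[i], a, s2p[k], f$error_sd[i],
                           f$error_sd[i + 1L])
      sd <- sqrt(v)
      if (6 * sd < cs) {
        # kernel narrower than a cell: deposit on the containing cell
        ci <- min(max(1L, 1L + floor((mx - xll) / cs)), ncol)
        ri <- min(max(1L, 1L + floor((my - yll) / cs)), nrow)
        M[ri, ci] <- M[ri, ci] + config$time_step
      } else {
        r <- 4.5 * sd
        crange <- max(1L, 1L + floor((mx - r - xll) / cs)):
          min(ncol, 1L + floor((mx + r - xll) / cs))
        rrange <- max(1L, 1L + floor((my - r - yll) / cs)):
          min(nrow, 1L + floor((my + r - yll) / cs))
        wx <- stats::dnorm(xc[crange], mx, sd)
        wy <- stats::dnorm(yc[rrange], my, sd)
        M[rrange, crange] <- M[rrange, crange] +
          (wy %o% wx) * config$time_step
      }
    }
  }
  tot <- sum(M)
  if (tot <= 0) stop("UD accumulated zero mass", call. = FALSE)
  structure(list(xll = xll, yll = yll, cell_size = cs,
                 ncol = ncol, nrow = nrow, p = M / tot),
            class = "ud_raster")
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf("<ud_raster> %d x %d cells of %g m, total mass %.6f\n",
              x$nrow, x$ncol, x$cell_size, sum(x$p)))
  invisible(x)
}

#' Cut an isopleth from a utilization distribution
#'
#' Cells are sorted by probability (descending) and the smallest set whose
#' cumulative mass reaches `level` is selected; the area is the cell count
#' times the cell area. The isopleth polygon is the union of the selected
#' cell squares, represented as one square ring per cell — bit-reproducible
#' areas, no contour interpolation.
#'
#' @param ud a `ud_raster`.
#' @param level isopleth level in (0, 1), e.g. 0.99 for the home range,
#'   0.50 for the core area.
#' @return object of class `isopleth`: list with `level`, `area_km2`,
#'   `n_cells`, `cells` (linear indices into the raster) and `polygons`
#'   (list of 4x2 corner matrices).
#' @export
isopleth_area <- function(ud, level) {
  stopifnot(inherits(ud, "ud_raster"))
  if (level <= 0 || level >= 1)
    stop_bad_arg("`level` must lie strictly between 0 and 1")
  p <- as.vector(ud$p)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(ord)
  cells <- ord[seq_len(k)]
  cs <- ud$cell_size
  ri <- ((cells - 1L) %% ud$nrow) + 1L
  ci <- ((cells - 1L) %/% ud$nrow) + 1L
  polys <- lapply(seq_len(k), function(j) {
    x0 <- ud$xll + (ci[j] - 1L) * cs
    y0 <- ud$yll + (ri[j] - 1L) * cs
    cbind(c(x0, x0 + cs, x0 + cs, x0), c(y0, y0, y0 + cs, y0 + cs))
  })
  structure(list(level = level, area_km2 = k * cs^2 / 1e6,
                 n_cells = k, cells = cells, polygons = polys),
            class = "isopleth")
}

#' Minimum convex polygon of a trajectory
#'
#' Convex hull of the fix coordinates with area by the shoelace formula.
#' `fraction < 1` peels the points farthest from the centroid before
#' hulling (the conventional percent-MCP); the default 1.0 uses all fixes.
#'
#' @param traj a [trajectory()] or a 2-column coordinate matrix.
#' @param fraction fraction of points retained (default 1.0).
#' @return object of class `mcp`: list with `coords` (hull vertices,
#'   counter-clockwise, not closed) and `area_km2`.
#' @export
mcp <- function(traj, fraction = 1.0) {
  xy <- if (inherits(traj, "trajectory"))
    cbind(traj$fixes$x, traj$fixes$y) else as.matrix(traj)
  if (fraction <= 0 || fraction > 1)
    stop_bad_arg("`fraction` must lie in (0, 1]")
  if (fraction < 1) {
    cen <- colMeans(xy)
    d <- dist_to_point(xy, cen)
    keep <- d <= stats::quantile(d, fraction, type = 7)
    xy <- xy[keep, , drop = FALSE]
  }
  if (nrow(xy) < 3L)
    stop_bad_arg("MCP needs at least 3 fixes")
  h <- grDevices::chull(xy)          # clockwise order
  hull <- xy[rev(h), , drop = FALSE] # counter-clockwise
  if (nrow(hull) < 3L)
    stop_bad_arg("MCP is degenerate: fixes are collinear")
  x <- hull[, 1]; y <- hull[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2
  if (area == 0)
    stop_bad_arg("MCP is degenerate: fixes are collinear")
  structure(list(coords = hull, area_km2 = area / 1e6), class = "mcp")
}

#' Point-in-home-range test
#'
#' Containment in a convex polygon (an MCP); the boundary counts as
#' inside, so events on a vertex or edge are within the home range.
#'
#' @param poly an `mcp` or a matrix of convex-polygon vertices in order.
#' @param event_xy length-2 coordinate.
#' @return logical.
#' @export
point_in_home_range <- function(poly, event_xy) {
  v <- if (inherits(poly, "mcp")) poly$coords else as.matrix(poly)
  n <- nrow(v)
  vn <- v[c(2:n, 1), , drop = FALSE]
  cross <- (vn[, 1] - v[, 1]) * (event_xy[2] - v[, 2]) -
    (vn[, 2] - v[, 2]) * (event_xy[1] - v[, 1])
  scale <- max(abs(v)) + 1
  eps <- 1e-9 * scale^2
  all(cross >= -eps) || all(cross <= eps)
}

#' Home-range result for one animal
#'
#' Convenience wrapper: dynamic motion variance, UD, and the 99%/50%
#' isopleths in one call.
#'
#' @param traj a [trajectory()] with `error_sd` assigned.
#' @param config a [dbbmm_config()].
#' @param resident logical metadata flag (residency is a field judgment,
#'   supplied by the analyst, never inferred).
#' @return object of class `home_range_result`: list with `animal_id`,
#'   `ud`, `isopleth_99`, `isopleth_50`, `area_99`, `area_50` (km²),
#'   `resident`.
#' @export
home_range_dbbmm <- function(traj, config = dbbmm_config(),
                             resident = TRUE) {
  prof <- dynamic_motion_variance(traj, config)
  ud <- build_ud(traj, prof, config)
  i99 <- isopleth_area(ud, 0.99)
  i50 <- isopleth_area(ud, 0.50)
  structure(list(animal_id = traj$animal_id, ud = ud,
                 isopleth_99 = i99, isopleth_50 = i50,
                 area_99 = i99$area_km2, area_50 = i50$area_km2,
                 resident = resident),
            class = "home_range_result")
}

#' @export
print.home_range_result <- function(x, ...) {
  cat(sprintf(
    "<home_range_result> animal %s: 99%% UD %.3f km2, 50%% UD %.3f km2\n",
    x$animal_id, x$area_99, x$area_50))
  invisible(x)
}
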