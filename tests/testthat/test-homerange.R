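test_that("bridge variance matches the closed form", {
  # 30-min pair, sigma2 = 0.1 m2/s, both errors 20 m, midpoint:
  # 1800*0.25*0.1 + 0.25*400 + 0.25*400 = 245
  expect_equal(bridge_variance(1800, 0.5, 0.1, 20, 20), 245,
               tolerance = 1e-9)
  expect_equal(bridge_variance(1800, 0, 0.1, 20, 5), 400)   # endpoint
  expect_equal(bridge_variance(1800, 1, 0.1, 20, 5), 25)
})

test_that("motion variance estimator behaves at the limits", {
  # all fixes at one point: estimate collapses to the lower search bound
  tr <- make_traj(matrix(rep(c(10, 10), each = 9), ncol = 2),
                  error_sd = 1)
  est <- loo_motion_variance(tr$fixes)
  expect_lt(est, 1.01e-8)

  expect_error(loo_motion_variance(tr$fixes[1:2, ]), "at least 3")
})

test_that("attributing more noise to GPS error lowers the estimate", {
  tr <- make_brownian_traj(101, sigma2 = 0.3, error_sd = 0, seed = 5)
  f <- tr$fixes
  ests <- vapply(c(1, 5, 10, 20, 40), function(d) {
    f$error_sd <- d
    loo_motion_variance(f)
  }, numeric(1))
  expect_true(all(diff(ests) <= 1e-12))
})

test_that("admissible breakpoints leave a margin on both sides", {
  expect_equal(admissible_breakpoints(25, 11), 12:14)
  expect_equal(length(admissible_breakpoints(25, 11)), 3L)
  expect_equal(admissible_breakpoints(9, 4), c(5L))
})

test_that("dynamic variance recovers a motion-variance switch", {
  # sigma2 jumps 0.05 -> 2.0 at the midpoint
  origin <- t_origin
  n <- 120; dt <- 900
  s2v <- c(rep(0.05, n / 2), rep(2.0, n / 2))
  z <- withr::with_seed(43, {
    steps <- matrix(rnorm(2 * (n - 1), 0, sqrt(s2v[-1] * dt)), n - 1, 2)
    rbind(c(0, 0), apply(steps, 2, cumsum))
  })
  tr <- make_traj(z, dt = dt, error_sd = 5)
  prof <- dynamic_motion_variance(tr, dbbmm_config())
  expect_gt(mean(prof$sigma2[(n / 2 + 1):n]), mean(prof$sigma2[1:(n / 2)]))
  expect_true(all(is.finite(prof$sigma2)) && all(prof$sigma2 >= 0))
})

test_that("BIC guards against spurious breakpoints on homogeneous tracks", {
  tr <- make_brownian_traj(200, sigma2 = 0.3, dt = 900, error_sd = 10,
                           seed = 42)
  prof <- dynamic_motion_variance(tr, dbbmm_config())
  expect_lt(mean(attr(prof, "breakpoint_windows")), 0.20)
})

test_that("short tracks fall back to one global estimate", {
  tr <- make_brownian_traj(15, sigma2 = 0.2, error_sd = 5, seed = 9)
  prof <- dynamic_motion_variance(tr, dbbmm_config(window = 25))
  expect_equal(length(unique(prof$sigma2)), 1L)
  expect_equal(prof$sigma2[1], loo_motion_variance(tr$fixes))
})

test_that("UD integrates to one and concentrates where the animal was", {
  tr <- make_brownian_traj(60, sigma2 = 0.5, dt = 900, error_sd = 15,
                           seed = 2)
  prof <- dynamic_motion_variance(tr, dbbmm_config())
  ud <- build_ud(tr, prof, dbbmm_config())
  expect_equal(sum(ud$p), 1, tolerance = 1e-6)
  expect_true(all(ud$p >= 0))

  # stationary 10-fix track, 5-m error: mass stays within 30 m
  trs <- make_traj(matrix(rep(c(0, 0), each = 10), ncol = 2) +
                     withr::with_seed(4, matrix(rnorm(20, 0, 2), 10, 2)),
                   error_sd = 5)
  profs <- dynamic_motion_variance(trs, dbbmm_config(window = 9,
                                                     margin = 4))
  uds <- build_ud(trs, profs, dbbmm_config(cell_size = 5))
  xc <- uds$xll + (seq_len(uds$ncol) - 0.5) * uds$cell_size
  yc <- uds$yll + (seq_len(uds$nrow) - 0.5) * uds$cell_size
  d2 <- outer(yc, xc, function(y, x) x^2 + y^2)
  expect_gte(sum(uds$p[d2 <= 30^2]), 0.99)
})

test_that("bridges across long gaps are skipped with a message", {
  xy <- matrix(c(0, 0, 50, 0, 5000, 0, 5050, 0), ncol = 2, byrow = TRUE)
  ts <- t_origin + c(0, 900, 90000, 90900)   # 1-day dropout in the middle
  tr <- trajectory(data.frame(timestamp = ts, x = xy[, 1], y = xy[, 2],
                              dop = NA, n_sats = NA, error_sd = 10), "G1")
  prof <- structure(data.frame(sigma2 = rep(0.1, 4),
                               n_support = rep(1L, 4)),
                    class = c("motion_variance_profile", "data.frame"))
  expect_message(ud <- build_ud(tr, prof, dbbmm_config()), "no bridge")
  expect_equal(sum(ud$p), 1, tolerance = 1e-6)
})

test_that("isopleth areas follow mass ordering and uniform arithmetic", {
  # uniform UD over a 10 x 10 block of 30-m cells
  ud <- structure(list(xll = 0, yll = 0, cell_size = 30,
                       ncol = 10L, nrow = 10L,
                       p = matrix(1 / 100, 10, 10)),
                  class = "ud_raster")
  i50 <- isopleth_area(ud, 0.50)
  expect_equal(i50$n_cells, 50L)
  expect_equal(i50$area_km2, 50 * 900 / 1e6)

  # point mass: one cell at any level
  pm <- ud; pm$p <- matrix(0, 10, 10); pm$p[5, 5] <- 1
  expect_equal(isopleth_area(pm, 0.99)$area_km2, 0.0009)
  expect_equal(isopleth_area(pm, 0.50)$area_km2, 0.0009)

  tr <- make_brownian_traj(60, sigma2 = 0.5, dt = 900, error_sd = 15,
                           seed = 3)
  u <- build_ud(tr, dynamic_motion_variance(tr, dbbmm_config()),
                dbbmm_config())
  expect_gte(isopleth_area(u, 0.99)$area_km2,
             isopleth_area(u, 0.50)$area_km2)
})

test_that("UD mass placement is stable under sub-cell origin shifts", {
  tr <- make_brownian_traj(40, sigma2 = 0.8, dt = 900, error_sd = 25,
                           seed = 6)
  cfg <- dbbmm_config()
  prof <- dynamic_motion_variance(tr, cfg)
  n1 <- isopleth_area(build_ud(tr, prof, cfg), 0.5)$n_cells
  tr2 <- tr
  tr2$fixes$x <- tr2$fixes$x + 11   # < one 30-m cell
  tr2$fixes$y <- tr2$fixes$y + 17
  n2 <- isopleth_area(build_ud(tr2, prof, cfg), 0.5)$n_cells
  expect_lte(abs(n1 - n2), 2L)
})

test_that("MCP area, idempotence and interior-point invariance", {
  tri <- rbind(c(0, 0), c(3000, 0), c(0, 4000))
  m <- mcp(tri)
  expect_equal(m$area_km2, 6)

  m2 <- mcp(m$coords)            # hull of hull
  expect_equal(m2$area_km2, m$area_km2)

  m3 <- mcp(rbind(tri, c(500, 500)))   # interior point changes nothing
  expect_equal(m3$area_km2, 6)

  expect_error(mcp(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(mcp(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("point-in-home-range uses closed boundaries", {
  m <- mcp(rbind(c(0, 0), c(3000, 0), c(0, 4000)))
  expect_true(point_in_home_range(m, c(1000, 1000)))    # centroid
  expect_false(point_in_home_range(m, c(4000, 4000)))   # well outside
  expect_true(point_in_home_range(m, c(0, 0)))          # vertex
  expect_true(point_in_home_range(m, c(1500, 0)))       # edge midpoint
})
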