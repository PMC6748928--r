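test_that("degenerate and invalid configurations are handled", {
  cfg <- sim_config(seed = 1, n_days = 0)
  s <- simulate_track(cfg)
  expect_equal(n_fixes(s$trajectory), 0L)
  expect_equal(nrow(s$activity), 0L)
  expect_length(s$truth$state_sequence, 0L)

  expect_error(sim_config(state_dwell_means = c(DEN_REST = -1, TRAVEL = 2,
                                                FORAGE = 3, SITE_VISIT = 3)),
               "dwell")
  expect_error(sim_config(step_scale_travel = 0), "step_scale_travel")
  expect_error(sim_config(fix_loss_prob = 1), "fix_loss_prob")
  expect_error(sim_config(activity_interval = 400), "divide")
})

test_that("fix timestamps fall on the nominal 15-min schedule", {
  s <- simulate_track(sim_config(seed = 5, n_days = 3, fix_interval = 900))
  gaps <- diff(as.numeric(s$trajectory$fixes$timestamp))
  expect_true(all(gaps %% 900 == 0))
  expect_true(all(gaps > 0))
})

test_that("identical seed and config reproduce bit-identical output", {
  cfg <- sim_config(seed = 99, n_days = 2, lcd_xy_list = list(c(500, 500)),
                    lcd_attraction = 2)
  a <- simulate_track(cfg, "W1")
  b <- simulate_track(cfg, "W1")
  expect_identical(a$trajectory$fixes, b$trajectory$fixes)
  expect_identical(a$activity, b$activity)
  expect_identical(a$truth$state_sequence, b$truth$state_sequence)
})

test_that("state sequence covers every scheduled fix slot before loss", {
  cfg <- sim_config(seed = 3, n_days = 2, fix_loss_prob = 0.2)
  s <- simulate_track(cfg)
  n_slots <- 2 * 86400 / 900
  expect_length(s$truth$state_sequence, n_slots)
  expect_length(s$truth$kept, n_slots)
  expect_equal(n_fixes(s$trajectory), sum(s$truth$kept))
})

test_that("LCD attraction raises the share of fixes near LCDs", {
  lcds <- list(c(1500, 800), c(-1200, 900))
  base <- list(seed = 21, n_days = 10, lcd_xy_list = lcds)
  cfg0 <- do.call(sim_config, c(base, lcd_attraction = 0))
  cfg5 <- do.call(sim_config, c(base, lcd_attraction = 5))
  frac_near <- function(s) {
    f <- s$trajectory$fixes
    near <- rep(FALSE, nrow(f))
    for (L in lcds)
      near <- near | sqrt((f$x - L[1])^2 + (f$y - L[2])^2) <= 200
    mean(near)
  }
  s0 <- simulate_track(cfg0); s5 <- simulate_track(cfg5)
  expect_gt(frac_near(s5), frac_near(s0))
  # attraction zero must produce zero LCD site targets
  expect_false(any(s0$truth$visited_sites$type == "LCD"))
})

test_that("activity emissions are separable at the 30.8 threshold", {
  s <- simulate_track(sim_config(seed = 8, n_days = 40))
  act <- s$activity
  expect_gte(nrow(act), 10000)
  rest <- act$activity[act$true_state %in% c("DEN_REST", "SITE_VISIT")]
  active <- act$activity[act$true_state %in% c("TRAVEL", "FORAGE")]
  expect_lt(mean(rest > 30.8), 0.01)
  expect_gt(mean(active > 30.8), 0.97)
  expect_true(all(act$activity >= 0))
})

test_that("den-rest fixes stay near the den (central-place property)", {
  s <- simulate_track(sim_config(seed = 12, n_days = 10))
  st <- s$truth$state_sequence[s$truth$kept]
  f <- s$trajectory$fixes
  d <- sqrt(f$x[st == "DEN_REST"]^2 + f$y[st == "DEN_REST"]^2)
  expect_gte(mean(d <= 100), 0.99)
})

test_that("scat diameters follow the configured mixtures", {
  expect_equal(nrow(simulate_scats(1, 0, 0)), 0L)
  expect_error(simulate_scats(1, -1, 5), "non-negative")

  sc <- simulate_scats(7, n_wolf = 10000, n_coyote = 0, track_prob = 0.3)
  expect_lt(abs(mean(sc$diameter) - 33.3), 0.2)
  expect_true(all(sc$diameter > 5))

  sc2 <- simulate_scats(7, n_wolf = 50, n_coyote = 50)
  expect_false(any(sc2$tracks_present[sc2$species_true == "COYOTE"]))
  expect_identical(simulate_scats(7, 50, 50), sc2)  # seeded reproducibility
})

test_that("scat compositions are Dirichlet with the right means", {
  one <- simulate_scat_compositions(1, 1,
                                    dirichlet_weights = rep(1, 5))
  pc <- attr(one, "prey_cols")
  expect_equal(sum(one[, pc]), 100, tolerance = 1e-9)

  w <- c(adult_deer = 62, fawn_deer = 8, cattle = 22, lagomorph = 6,
         rodent = 2)
  big <- simulate_scat_compositions(2, 10000, dirichlet_weights = w)
  expect_lt(abs(mean(big$cattle) - 22), 0.5)

  w0 <- w; w0["cattle"] <- 0
  z <- simulate_scat_compositions(3, 5000, dirichlet_weights = w0)
  expect_lt(mean(z$cattle), 0.01)
  expect_error(simulate_scat_compositions(1, 5,
                                          dirichlet_weights = c(a = -1)),
               "non-negative")
})
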