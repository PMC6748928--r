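act_df <- function(times, act, id = "T1") {
  data.frame(animal_id = rep(id, length(times)),
             timestamp = t_origin + times,
             x_axis = act / 2, y_axis = act / 2, activity = act,
             stringsAsFactors = FALSE)
}

test_that("mean activity is an order-invariant arithmetic mean", {
  expect_equal(mean_activity(act_df(c(0, 300, 600), c(10, 20, 30))), 20)
  expect_equal(mean_activity(act_df(0, 42.26)), 42.26)
  shuffled <- act_df(c(600, 0, 300), c(30, 10, 20))
  expect_equal(mean_activity(shuffled), 20)
  expect_error(mean_activity(act_df(numeric(0), numeric(0))), "no activity")
})

test_that("activity aligns to fixes over a closed 450-s window", {
  # fixes an hour apart so each record can only touch one fix
  tr <- make_traj(cbind(0:2 * 100, 0), dt = 3600)
  ft <- as.numeric(tr$fixes$timestamp - t_origin)
  rec <- act_df(c(ft[1] - 300, ft[1], ft[1] + 300,   # around fix 1
                  ft[2] + 450),                      # boundary of fix 2
                c(30, 40, 50, 77))
  al <- align_activity_to_fixes(tr, rec)
  expect_equal(al[1], 40)          # mean(30, 40, 50)
  expect_equal(al[2], 77)          # record at exactly 450 s included
  expect_true(is.na(al[3]))        # nothing within 450 s
})

test_that("the 30.8 threshold is strict and missing maps to inactive", {
  cls <- classify_active(c(30.8, 30.81, NA), threshold = 30.8)
  expect_identical(as.logical(cls), c(FALSE, TRUE, FALSE))
  expect_identical(attr(cls, "missing"), c(FALSE, FALSE, TRUE))
})

test_that("relative turning angles follow the wrap convention", {
  expect_equal(as.numeric(turning_angles(
    make_traj(rbind(c(0, 0), c(1, 0), c(2, 0))))), 0)
  expect_equal(as.numeric(turning_angles(
    make_traj(rbind(c(0, 0), c(1, 0), c(1, 1))))), 90)
  expect_equal(as.numeric(turning_angles(
    make_traj(rbind(c(0, 0), c(1, 0), c(0, 0))))), 180)   # reversal -> +180
  expect_length(turning_angles(make_traj(rbind(c(0, 0), c(1, 0)))), 0L)

  # zero-length middle step skipped
  expect_message(
    a <- turning_angles(make_traj(rbind(c(0, 0), c(1, 0), c(1, 0),
                                        c(2, 0)))),
    "zero-length")
  expect_length(a, 0L)
})

test_that("turning angles and tortuosity are rotation invariant", {
  xy <- withr::with_seed(10, matrix(cumsum(rnorm(80, 0, 50)), ncol = 2))
  base <- turning_angles(make_traj(xy))
  for (theta in c(0.3, 1.1, 2.8)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    rot <- turning_angles(make_traj(xy %*% R))
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("active tortuosity averages |angles| on fully active runs", {
  zig <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 2))
  tr <- make_traj(zig)
  tort <- mean_active_tortuosity(tr, rep(TRUE, nrow(zig)))
  expect_equal(tort, 90)                      # alternating +/-90 zigzag

  straight <- make_traj(cbind(0:5 * 100, 0))
  expect_equal(mean_active_tortuosity(straight, rep(TRUE, 6)), 0)

  expect_warning(
    na <- mean_active_tortuosity(tr, rep(FALSE, nrow(zig))),
    "no qualifying")
  expect_true(is.na(na))

  # interior fix must have both adjoining steps between active fixes
  act <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  t2 <- mean_active_tortuosity(tr, act)
  expect_equal(t2, 90)   # only fix 2 qualifies
})

test_that("tortuosity stays within [0, 180] on random walks", {
  for (seed in c(1, 2, 3)) {
    xy <- withr::with_seed(seed,
                           matrix(cumsum(rnorm(120, 0, 30)), ncol = 2))
    tr <- make_traj(xy)
    tort <- mean_active_tortuosity(tr, rep(TRUE, nrow(xy)))
    expect_gte(tort, 0); expect_lte(tort, 180)
  }
})

test_that("straighter simulated movement scores lower tortuosity", {
  base <- list(seed = 31, n_days = 4, fix_loss_prob = 0,
               state_dwell_means = c(DEN_REST = 0.5, TRAVEL = 8,
                                     FORAGE = 0.5, SITE_VISIT = 0.5))
  straight <- do.call(sim_config,
                      c(base, list(turn_concentration = c(TRAVEL = 0.95,
                                                          FORAGE = 0.4))))
  wiggly <- do.call(sim_config,
                    c(base, list(turn_concentration = c(TRAVEL = 0.1,
                                                        FORAGE = 0.4))))
  tort_of <- function(cfg) {
    s <- simulate_track(cfg)
    per_fix <- align_activity_to_fixes(s$trajectory, s$activity)
    suppressMessages(mean_active_tortuosity(s$trajectory,
                                            classify_active(per_fix)))
  }
  expect_lt(tort_of(straight), tort_of(wiggly))
})

test_that("activity classification recovers true behavioural states", {
  s <- simulate_track(sim_config(seed = 17, n_days = 6))
  per_fix <- align_activity_to_fixes(s$trajectory, s$activity)
  pred <- classify_active(per_fix)
  true_state <- s$truth$state_sequence[s$truth$kept]
  truth <- true_state %in% c("TRAVEL", "FORAGE")
  expect_gte(mean(pred == truth), 0.95)
})
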