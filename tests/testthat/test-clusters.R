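test_that("simple cluster geometries come out as expected", {
  # 5 identical coordinates in one hour -> one cluster of 5
  tr <- make_traj(matrix(rep(c(100, 200), each = 5), ncol = 2), dt = 900)
  cl <- detect_clusters(tr, cluster_config(min_fixes = 4))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_fixes, 5L)
  expect_equal(c(cl$centroid_x, cl$centroid_y), c(100, 200))

  # distances (0, 10, 49, 60, 10) m from the seed: the 60-m fix is out
  xy <- rbind(c(0, 0), c(10, 0), c(49, 0), c(60, 0), c(0, 10))
  cl <- detect_clusters(make_traj(xy, dt = 900),
                        cluster_config(min_fixes = 4, radius = 50))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_fixes, 4L)
  expect_false(4L %in% cl$member_indices[[1]])

  # empty trajectory
  expect_equal(nrow(detect_clusters(make_traj(cbind(numeric(0),
                                                    numeric(0))),
                                    cluster_config())), 0L)
})

test_that("greedy detector matches the brute-force oracle", {
  cfg <- cluster_config(min_fixes = 4, radius = 50, time_window = 24)
  for (seed in 1:30) {
    tr <- random_small_traj(seed)
    got <- detect_clusters(tr, cfg)
    want <- brute_force_clusters(tr, cfg)
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    for (k in seq_along(want)) {
      expect_equal(sort(got$member_indices[[k]]), sort(want[[k]]$members),
                   info = paste("seed", seed, "cluster", k))
    }
  }
})

test_that("cluster membership is disjoint and within radius of the seed", {
  cfg <- cluster_config(min_fixes = 3, radius = 50)
  for (seed in c(101, 102, 103)) {
    tr <- random_small_traj(seed)
    cl <- detect_clusters(tr, cfg)
    all_members <- unlist(cl$member_indices)
    expect_false(any(duplicated(all_members)))
    for (k in seq_len(nrow(cl))) {
      mem <- cl$member_indices[[k]]
      seed_fix <- mem[which.min(as.numeric(tr$fixes$timestamp[mem]))]
      d <- sqrt((tr$fixes$x[mem] - tr$fixes$x[seed_fix])^2 +
                  (tr$fixes$y[mem] - tr$fixes$y[seed_fix])^2)
      expect_true(all(d <= cfg$radius))
      expect_lte(cl$duration_h[k], cfg$time_window)
    }
  }
})

test_that("lowering min_fixes never decreases the cluster count", {
  for (seed in c(7, 8, 9)) {
    tr <- random_small_traj(seed)
    n8 <- nrow(detect_clusters(tr, cluster_config(min_fixes = 8)))
    n4 <- nrow(detect_clusters(tr, cluster_config(min_fixes = 4)))
    n2 <- nrow(detect_clusters(tr, cluster_config(min_fixes = 2)))
    expect_gte(n4, n8)
    expect_gte(n2, n4)
  }
})

test_that("den exclusion removes centroids within the radius", {
  cl <- detect_clusters(make_traj(matrix(rep(c(99, 0), each = 5),
                                         ncol = 2)),
                        cluster_config(min_fixes = 4))
  expect_equal(nrow(suppressMessages(
    exclude_near_dens(cl, list(c(0, 0)), 100))), 0L)   # 99 m: removed

  cl2 <- detect_clusters(make_traj(matrix(rep(c(101, 0), each = 5),
                                          ncol = 2)),
                         cluster_config(min_fixes = 4))
  expect_equal(nrow(exclude_near_dens(cl2, list(c(0, 0)), 100)), 1L)

  expect_identical(exclude_near_dens(cl, list(), 100), cl)  # no dens
})

test_that("buffer counts use the whole season and closed discs", {
  # 6 tight fixes forming the cluster, plus one fix at exactly 200 m
  xy <- rbind(matrix(rep(c(0, 0), each = 6), ncol = 2), c(200, 0))
  tr <- make_traj(xy)
  cl <- detect_clusters(tr, cluster_config(min_fixes = 4))
  cl$site_class <- "LCD"
  rec <- buffer_use_counts(tr, cl, c(50, 200))
  expect_equal(rec$count[rec$radius == 50], 6L)
  expect_equal(rec$count[rec$radius == 200], 7L)  # boundary fix included
  expect_true(all(rec$is_lcd))

  tr2 <- make_traj(xy, animal_id = "OTHER")
  expect_error(buffer_use_counts(tr2, cl), "different animal")
})

test_that("LCD-attracted animals pile fixes on LCD clusters", {
  s <- simulate_track(scenario_config("LCDP", seed = 12, n_days = 8), "W")
  cl <- label_clusters_from_truth(
    detect_clusters(s$trajectory, cluster_config()), s$truth)
  cl <- suppressMessages(exclude_near_dens(cl, list(c(0, 0)), 100))
  rec <- buffer_use_counts(s$trajectory, cl, 50)
  expect_true(any(rec$is_lcd) && any(!rec$is_lcd))
  expect_gt(mean(rec$count[rec$is_lcd]), mean(rec$count[!rec$is_lcd]))
})

test_that("site-use summary gives percentages over visited clusters", {
  cl <- detect_clusters(make_traj(matrix(rep(0, 10), ncol = 2)),
                        cluster_config(min_fixes = 2))
  cl <- cl[rep(1, 4), ]
  cl$site_class <- c("DEN", "LCD", "LCD", "BED_RENDEZVOUS")
  su <- site_use_summary(cl)
  expect_equal(sum(su$percent), 100, tolerance = 0.1)
  expect_equal(su$percent[su$site_class == "LCD"], 50)
  expect_equal(su$percent[su$site_class == "DEN"], 25)

  cl$site_class <- "UNVISITED"
  expect_warning(empty <- site_use_summary(cl), "no visited")
  expect_equal(nrow(empty), 0L)
})
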