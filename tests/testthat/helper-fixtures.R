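# fixtures and independent oracles shared across tests

t_origin <- as.POSIXct("2010-05-01 00:00:00", tz = "UTC")

# trajectory from a coordinate matrix at a fixed time step
make_traj <- function(xy, dt = 900, error_sd = 10, animal_id = "T1",
                      t0 = t_origin) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  trajectory(data.frame(timestamp = t0 + (seq_len(n) - 1L) * dt,
                        x = xy[, 1], y = xy[, 2],
                        dop = rep(NA_real_, n), n_sats = rep(NA_real_, n),
                        error_sd = rep(error_sd, length.out = n)),
             animal_id = animal_id, nominal_interval = dt)
}

# pure Brownian-motion track with optional iid location error
make_brownian_traj <- function(n, sigma2, dt = 900, error_sd = 0,
                               seed = 1, animal_id = "B1") {
  withr::with_seed(seed, {
    steps <- matrix(rnorm(2 * (n - 1), 0, sqrt(sigma2 * dt)), n - 1, 2)
    z <- rbind(c(0, 0), apply(steps, 2, cumsum))
    if (error_sd > 0) z <- z + matrix(rnorm(2 * n, 0, error_sd), n, 2)
    make_traj(z, dt = dt, error_sd = error_sd, animal_id = animal_id)
  })
}

# Independent brute-force cluster oracle: literal restatement of the rule,
# trying every fix as a seed in chronological order, no vectorisation.
brute_force_clusters <- function(traj, config) {
  f <- traj$fixes
  n <- nrow(f)
  tsec <- as.numeric(f$timestamp)
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    members <- integer(0)
    for (j in seq_len(n)) {
      if (assigned[j]) next
      if (tsec[j] < tsec[seed]) next
      if (tsec[j] > tsec[seed] + config$time_window * 3600) next
      d <- sqrt((f$x[j] - f$x[seed])^2 + (f$y[j] - f$y[seed])^2)
      if (d <= config$radius) members <- c(members, j)
    }
    if (length(members) >= config$min_fixes) {
      for (j in members) assigned[j] <- TRUE
      clusters[[length(clusters) + 1L]] <-
        list(members = members,
             centroid = c(mean(f$x[members]), mean(f$y[members])))
    }
  }
  clusters
}

# random small trajectory for oracle-equivalence sweeps
random_small_traj <- function(seed, max_fixes = 50) {
  withr::with_seed(seed, {
    n <- sample(5:max_fixes, 1)
    ts <- sort(sample.int(200, n)) * 900  # strictly increasing, gaps vary
    xy <- matrix(runif(2 * n, 0, 250), n, 2)
    trajectory(data.frame(timestamp = t_origin + ts,
                          x = xy[, 1], y = xy[, 2],
                          dop = NA_real_, n_sats = NA_real_,
                          error_sd = 10),
               animal_id = "R1")
  })
}
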