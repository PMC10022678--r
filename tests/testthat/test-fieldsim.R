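test_that("field construction meets occupancy, spacing and shape contracts", {
  # no clumps -> all middle
  empty <- build_field(field_spec(occupancy_fast = 0, occupancy_slow = 0),
                       seed = 1)
  expect_true(all(empty$grid == 2L))

  # 4% slow occupancy with 250-nm clumps on a 10-um field = 64 clumps
  sp <- field_spec(occupancy_fast = 0, occupancy_slow = 4)
  map <- build_field(sp, seed = 2)
  clump_cells <- (250 / 10)^2
  expect_equal(sum(map$grid == 3L) / clump_cells, 64)
  expect_equal(unname(map$fractions["slow"]), 0.04, tolerance = 1e-9)

  # control-like field passes the fast/slow non-adjacency audit
  ctrl <- build_field(field_spec(), seed = 3)
  expect_true(field_audit(ctrl))
  expect_true(all(abs(ctrl$fractions[c("fast", "slow")] - c(0.05, 0.30)) /
                    c(0.05, 0.30) < 0.10))

  # circle variant: same area within rasterization tolerance, still audited
  circ <- circle_clump_variant(field_spec(occupancy_fast = 2,
                                          occupancy_slow = 10), seed = 4)
  expect_true(field_audit(circ))
  expect_equal(unname(circ$fractions["slow"]), 0.10, tolerance = 0.05)

  # deterministic under seed
  expect_identical(build_field(field_spec(), seed = 5)$grid,
                   build_field(field_spec(), seed = 5)$grid)
})

test_that("homogeneous-field simulation reduces to free diffusion at D_middle", {
  sp <- field_spec(occupancy_fast = 0, occupancy_slow = 0)
  map <- build_field(sp, seed = 1)
  ts <- simulate_particles(map, n_traj = 2000, n_frames = 50, burn_in = 10,
                           seed = 6)
  fit <- fit_msd(compute_msd(ts))
  expect_lt(abs(fit$D - sp$D[2]) / sp$D[2], 0.05)
  # conservation through reflection breaking
  expect_equal(nrow(ts$tracks) + attr(ts, "n_positions_dropped"),
               attr(ts, "n_positions_total"))
  # seeded runs are bit-reproducible
  ts2 <- simulate_particles(map, n_traj = 2000, n_frames = 50, burn_in = 10,
                            seed = 6)
  expect_identical(ts$tracks, ts2$tracks)
})

test_that("particles accumulate in slow regions beyond their area fraction", {
  sp <- field_spec(occupancy_fast = 0, occupancy_slow = 20)
  map <- build_field(sp, seed = 7)
  ts <- simulate_particles(map, n_traj = 1500, n_frames = 60, burn_in = 120,
                           seed = 8)
  slow_frac <- mean(ts$tracks$state == 3L)
  expect_gt(slow_frac, unname(map$fractions["slow"]) + 0.05)

  # independent single-particle oracle: a plain-R reimplementation of the
  # step rule, run long, agrees on the slow-time fraction
  set.seed(9)
  x <- runif(1, 0, 10); y <- runif(1, 0, 10)
  dt <- 1 / 30; slow_time <- 0; n_steps <- 40000
  for (i in seq_len(n_steps)) {
    reg <- map$grid[min(max(floor(x / map$res_um) + 1, 1), nrow(map$grid)),
                    min(max(floor(y / map$res_um) + 1, 1), nrow(map$grid))]
    if (i > 3000) slow_time <- slow_time + (reg == 3L)
    dr <- sqrt(-4 * sp$D[reg] * dt * log(runif(1)))
    th <- runif(1) * 2 * pi
    x <- x + dr * cos(th); y <- y + dr * sin(th)
    if (x < 0) x <- -x; if (x > 10) x <- 20 - x
    if (y < 0) y <- -y; if (y > 10) y <- 20 - y
  }
  expect_equal(slow_frac, slow_time / (n_steps - 3000), tolerance = 0.12)
})

test_that("state-dependent localization error perturbs positions as configured", {
  sp <- field_spec(occupancy_fast = 0, occupancy_slow = 0)
  map <- build_field(sp, seed = 1)
  ts <- simulate_particles(map, n_traj = 1500, n_frames = 40, burn_in = 5,
                           seed = 10)
  # eps = 0 is the identity
  same <- add_localization_error(ts, eps_um = c(0, 0, 0), seed = 11)
  expect_equal(same$tracks$x, ts$tracks$x)
  # homogeneous field + eps = 20 nm: MSD intercept near 4 eps^2
  noisy <- add_localization_error(ts, eps_um = c(0.02, 0.02, 0.02), seed = 11)
  fit <- fit_msd(compute_msd(noisy))
  expect_equal(fit$eps, 0.02, tolerance = 0.2)
})

test_that("interruption cuts conserve positions, avoid slow starts and enrich fast starts", {
  gen <- control_hmm()
  ts <- simulate_hmm_trajectories(gen, n = 1200, len = 40, seed = 12)
  expect_identical(apply_interruptions(ts, 0, seed = 1), ts)

  cut <- apply_interruptions(ts, n_cuts = 800, seed = 13)
  expect_equal(nrow(cut$tracks), nrow(ts$tracks))
  expect_gt(n_tracks(cut), n_tracks(ts))
  expect_true(all(track_lengths(cut) >= 2))

  # no new track starts in the slow state
  firsts <- cut$tracks[!duplicated(cut$tracks$track_id), ]
  new_starts <- firsts[firsts$frame != 1, ]
  expect_true(all(new_starts$state != 3L))

  # monotonicity: more cuts -> larger fast fraction at track starts
  start_fast <- function(x) {
    f <- x$tracks[!duplicated(x$tracks$track_id), ]
    mean(f$state == 1L)
  }
  light <- apply_interruptions(ts, n_cuts = 200, seed = 13)
  expect_gt(start_fast(cut), start_fast(light))
  expect_gt(start_fast(light), start_fast(ts) - 1e-12)
})

test_that("interruption-count matching solves the start-count ratio equations", {
  # fixed point: target equal to the uninterrupted start fractions
  res <- match_interruption_counts(c(0.2, 0.5, 0.3), c(200, 500, 300))
  expect_equal(res$total, 0)

  # brute-force integer search oracle for F = M = S with doubled fast target
  Fc <- 300; Mc <- 300; Sc <- 300
  target <- c(0.4, 0.35, 0.25)
  best <- NULL
  for (f in 0:2000) for (m in seq(0, 2000, by = 10)) {
    p <- c(Fc + f, Mc + m, Sc) / (Fc + Mc + Sc + f + m)
    err <- sum(abs(p - target))
    if (is.null(best) || err < best$err) best <- list(f = f, m = m, err = err)
  }
  res2 <- match_interruption_counts(target, c(Fc, Mc, Sc))
  expect_lt(abs(res2$f - best$f), 15)
  expect_lt(abs(res2$m - best$m), 15)
  # slow cuts are never allocated (s = 0 by construction)
  expect_named(res2, c("f", "m", "total", "achieved_p0"))
})

test_that("HMM trajectory generator honors its chain and emission laws", {
  dt <- 1 / 30
  # identity transitions freeze each track in its initial state
  frozen <- hmm_model(c(0.3, 0.3, 0.4), diag(3), c(0.1, 0.03, 0.008), dt)
  ts <- simulate_hmm_trajectories(frozen, n = 200, len = 20, seed = 15)
  per_track <- tapply(ts$tracks$state, ts$tracks$track_id,
                      function(s) length(unique(s)))
  expect_true(all(per_track == 1))

  # empirical transition frequencies approach A
  gen <- control_hmm(dt)
  big <- simulate_hmm_trajectories(gen, n = 5000, len = 100, seed = 16)
  st <- big$tracks$state
  id <- big$tracks$track_id
  n <- length(st)
  same <- id[-1] == id[-n]
  from <- st[-n][same]; to <- st[-1][same]
  Ahat <- prop.table(table(from, to), margin = 1)
  expect_true(max(abs(Ahat - gen$A)) < 0.02)
})

test_that("lifetimes grow with clump size", {
  sp <- field_spec(occupancy_fast = 0, occupancy_slow = 15)
  curve <- lifetime_vs_size(c(50, 250), kind = "slow", base_spec = sp,
                            n_traj = 600, n_frames = 60, burn_in = 60,
                            seed = 17, hmm_restarts = 2)
  expect_true(all(is.finite(curve$tau)))
  expect_gt(curve$tau[2], curve$tau[1])
})

test_that("occupancy calibration closes the loop on a known field", {
  base <- field_spec()
  truth <- sptfield:::analyze_sim_field(
    field_spec(occupancy_fast = 5, occupancy_slow = 25),
    n_traj = 700, n_frames = 60, burn_in = 80, dt = 1 / 30, seed = 18,
    hmm_restarts = 2)
  target <- list(D_M = truth$D_M, p_S = as.numeric(truth$occupancy),
                 tau = truth$lifetimes$tau)
  cal <- calibrate_field(target, base,
                         occupancy_fast_grid = c(0, 5, 10),
                         occupancy_slow_grid = c(15, 25, 35),
                         n_traj = 700, n_frames = 60, burn_in = 80,
                         seed = 19, hmm_restarts = 2)
  expect_equal(cal$best_spec$occupancy_fast, 5)
  expect_equal(cal$best_spec$occupancy_slow, 25)
  # running best objective is non-increasing along the trace
  expect_true(all(diff(cal$trace$best_so_far) <= 1e-12))

  # all-middle target selects zero occupancies
  mid <- sptfield:::analyze_sim_field(
    field_spec(occupancy_fast = 0, occupancy_slow = 0),
    n_traj = 500, n_frames = 50, burn_in = 30, dt = 1 / 30, seed = 20,
    hmm_restarts = 2)
  cal0 <- calibrate_field(list(D_M = mid$D_M, p_S = as.numeric(mid$occupancy)),
                          base,
                          occupancy_fast_grid = c(0, 5),
                          occupancy_slow_grid = c(0, 20),
                          n_traj = 500, n_frames = 50, burn_in = 30,
                          seed = 21, hmm_restarts = 2)
  expect_equal(cal0$best_spec$occupancy_fast, 0)
  expect_equal(cal0$best_spec$occupancy_slow, 0)
})
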