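test_that("emission density is a normalized Rayleigh law shared with the mixture", {
  dt <- 1 / 30; D <- 0.03
  expect_equal(integrate(emission_density, 0, Inf, D = D, dt = dt)$value, 1,
               tolerance = 1e-6)
  r <- seq(0, 0.4, by = 0.005)
  expect_equal(emission_density(r, D, dt),
               mixture_pdf(r, mixture_model(1, D, dt)))
  # at small fixed dr a larger D flattens the density
  expect_lt(emission_density(0.01, 0.1, dt), emission_density(0.01, 0.008, dt))
})

test_that("k-means initialization lands near well-separated diffusion coefficients", {
  dt <- 1 / 30
  dr <- sample_mixture_dr(6000, c(1, 1, 1) / 3, c(0.2, 0.02, 0.002), dt,
                          seed = 3)
  ds <- make_disp_set(dr, dt)
  init <- init_hmm(ds, N = 3, seed = 4)
  D0 <- sort(init$D, decreasing = TRUE)
  # k-means on the right-skewed per-step coefficients splits the fast
  # tail rather than recovering the component means exactly, so the
  # contract is order-of-magnitude coverage: distinct positive centres
  # inside the data range, spanning from the slow scale to the fast tail
  d_mom <- dr^2 / (4 * dt)
  expect_true(all(D0 > 0) && all(diff(D0) < 0))
  expect_true(min(D0) < 3 * 0.002 + 0.02 && max(D0) <= max(d_mom))
  expect_true(all(D0 >= min(d_mom) & D0 <= max(d_mom)))
  # N = 1 reduces to the moment estimate
  expect_equal(init_hmm(ds, N = 1, seed = 4)$D,
               mean(dr^2) / (4 * dt), tolerance = 1e-9)
  # determinism under the seed
  expect_identical(init_hmm(ds, N = 3, seed = 4), init_hmm(ds, N = 3, seed = 4))
})

test_that("scaled forward-backward equals brute-force path enumeration", {
  dt <- 1 / 30
  p0 <- c(0.6, 0.4)
  A <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  D <- c(0.08, 0.005)
  model <- hmm_model(p0, A, D, dt)
  set.seed(77)
  lens <- c(1, 2, 4, 7, 8)
  dr_list <- lapply(lens, function(L) sqrt(-4 * 0.02 * dt * log(runif(L))))
  tab <- do.call(rbind, lapply(seq_along(dr_list), function(i)
    traj_from_dr(dr_list[[i]], dt, id = sprintf("t%02d", i))))
  ts <- traj_set(tab, dt)

  pk <- sptfield:::pack_sequences(ts)
  fb <- sptfield:::forward_backward_packed(pk, model, want_gamma = TRUE)
  oracle <- lapply(dr_list, brute_force_fb, p0 = p0, A = A, D = D, dt = dt)
  expect_equal(fb$logL, sum(vapply(oracle, `[[`, numeric(1), "logL")),
               tolerance = 1e-10)
  # per-step posteriors, matched through the packing order
  for (i in seq_along(dr_list)) {
    row <- match(sprintf("t%02d", i), pk$track_ids)
    L <- lens[i]
    got <- sapply(seq_len(L), function(t) fb$gamma[row, t, ])
    expect_equal(t(got), oracle[[i]]$gamma, tolerance = 1e-10)
  }
})

test_that("Baum-Welch increases the likelihood and reduces to the Rayleigh MLE at N = 1", {
  dt <- 1 / 30
  gen <- control_hmm(dt)
  ts <- simulate_hmm_trajectories(gen, n = 150, len = 40, seed = 9)
  init <- init_hmm(displacements(ts), N = 3, seed = 2)
  fit <- baum_welch(ts, init, max_iter = 40, trace = TRUE)
  path <- attr(fit, "logL_path")
  expect_true(all(diff(path) > -1e-6 * abs(path[-length(path)])))

  dr <- displacements(ts)$steps$dr
  init1 <- init_hmm(displacements(ts), N = 1, seed = 2)
  fit1 <- baum_welch(ts, init1, max_iter = 50)
  expect_equal(fit1$D, sum(dr^2) / (4 * dt * length(dr)), tolerance = 1e-6)
})

test_that("Baum-Welch recovers a known generator on clean data, also after interruptions", {
  dt <- 1 / 30
  gen <- control_hmm(dt)
  errs <- c(); Aerrs <- c()
  for (s in 1:3) {
    ts <- simulate_hmm_trajectories(gen, n = 600, len = 60, seed = 100 + s)
    fit <- fit_hmm(ts, N = 3, seed = 200 + s, n_restarts = 2)
    errs <- c(errs, max(abs(fit$D - gen$D) / gen$D))
    Aerrs <- c(Aerrs, max(abs(fit$A - gen$A)))
  }
  expect_lt(median(errs), 0.10)
  expect_lt(median(Aerrs), 0.05)

  # recovery is robust to random track cutting (tracking interruptions)
  ts <- simulate_hmm_trajectories(gen, n = 600, len = 60, seed = 321)
  cut <- apply_interruptions(ts, n_cuts = 500, seed = 5)
  expect_gt(n_tracks(cut), n_tracks(ts))
  fit_cut <- fit_hmm(cut, N = 3, seed = 7, n_restarts = 2)
  expect_true(all(abs(fit_cut$D - gen$D) / gen$D < 0.15))
})

test_that("Viterbi paths have the right length and follow dominated likelihoods", {
  dt <- 1 / 30
  model <- hmm_model(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)),
                     c(0.1, 0.001), dt)
  tiny <- traj_from_dr(rep(0.002, 10), dt, "tiny")
  huge <- traj_from_dr(rep(0.3, 7), dt, "huge")
  ts <- traj_set(rbind(tiny, huge), dt)
  paths <- viterbi(ts, model)
  expect_equal(nrow(paths$steps), nrow(displacements(ts)$steps))
  expect_true(all(paths$steps$state[paths$steps$track_id == "tiny"] == 2))
  expect_true(all(paths$steps$state[paths$steps$track_id == "huge"] == 1))
  expect_equal(rowSums(paths$posterior), rep(1, nrow(paths$steps)),
               tolerance = 1e-9)
})

test_that("occupancy averages posteriors to a simplex and matches the generator", {
  dt <- 1 / 30
  gen <- control_hmm(dt)
  ts <- simulate_hmm_trajectories(gen, n = 800, len = 60, seed = 55)
  fit <- fit_hmm(ts, N = 3, seed = 56, n_restarts = 2)
  paths <- viterbi(ts, fit)
  occ <- occupancy(paths)
  expect_equal(sum(occ), 1, tolerance = 1e-9)
  expect_true(all(abs(occ - stationary_dist(gen$A)) < 0.03))
  occ_v <- occupancy(paths, method = "viterbi")
  expect_equal(sum(occ_v), 1, tolerance = 1e-12)
})

test_that("per-state MSD segmentation is the identity on single-state data", {
  dt <- 1 / 30
  gen <- hmm_model(1, matrix(1), 0.02, dt)
  ts <- simulate_hmm_trajectories(gen, n = 300, len = 30, seed = 66)
  model <- hmm_model(1, matrix(1), 0.021, dt)
  paths <- viterbi(ts, model)
  sm <- state_msd_fit(ts, paths)
  whole <- fit_msd(compute_msd(ts))
  expect_equal(sm$D_S[1], whole$D, tolerance = 1e-9)
  expect_equal(sm$eps_S[1], whole$eps, tolerance = 1e-9)
})

test_that("transition rates are per-frame probabilities over dt", {
  A <- rbind(c(0.967, 0.033, 0), c(0.05, 0.93, 0.02), c(0, 0.07, 0.93))
  model <- hmm_model(c(1, 0, 0) + c(-2e-7, 1e-7, 1e-7),
                     A, c(0.1, 0.03, 0.008), dt = 1 / 30)
  r <- transition_rates(model)
  expect_equal(r["fast", "middle"], 0.033 * 30, tolerance = 1e-9)
  expect_equal(r["fast", "slow"], 0)
  expect_true(all(is.na(diag(r))))
})
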