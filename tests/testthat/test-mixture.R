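test_that("mixture density is normalized, peaks at the Rayleigh mode, and is linear in weights", {
  dt <- 1 / 30
  m1 <- mixture_model(1, 0.03, dt)
  expect_equal(integrate(function(r) mixture_pdf(r, m1), 0, Inf)$value, 1,
               tolerance = 1e-6)
  mode <- optimize(function(r) -mixture_pdf(r, m1), c(0, 1))$minimum
  expect_equal(mode, sqrt(2 * 0.03 * dt), tolerance = 1e-4)

  m2 <- mixture_model(c(0.5, 0.5), c(0.1, 0.008), dt)
  ma <- mixture_model(1, 0.1, dt); mb <- mixture_model(1, 0.008, dt)
  r <- seq(0, 0.5, by = 0.01)
  expect_equal(mixture_pdf(r, m2),
               0.5 * mixture_pdf(r, ma) + 0.5 * mixture_pdf(r, mb))
  expect_error(mixture_model(1, -0.1, dt), "positive")
})

test_that("single-state MLE equals the closed-form Rayleigh estimate", {
  dt <- 1 / 30
  dr <- sample_mixture_dr(50000, 1, 0.02, dt, seed = 101)
  ds <- make_disp_set(dr, dt)
  fit <- fit_mle(ds, N = 1, seed = 1)
  expect_equal(fit$D, sum(dr^2) / (4 * dt * length(dr)), tolerance = 1e-9)
  expect_lt(abs(fit$D - 0.02) / 0.02, 0.02)
})

test_that("three-state mixture parameters are recovered from simulated data", {
  dt <- 1 / 30
  p_true <- c(0.05, 0.55, 0.40); D_true <- c(0.1, 0.03, 0.008)
  dr <- sample_mixture_dr(40000, p_true, D_true, dt, seed = 7)
  fit <- fit_mle(make_disp_set(dr, dt), N = 3, seed = 3, n_restarts = 5)
  expect_true(all(abs(fit$D - D_true) / D_true < 0.15))
  expect_true(all(abs(fit$weights - p_true) < 0.05))

  # likelihood at the MLE is at least that at the generating parameters
  truth <- mixture_model(p_true, D_true, dt)
  ll_truth <- sum(log(mixture_pdf(dr, truth)))
  expect_gte(fit$logL, ll_truth)
})

test_that("duplicating every displacement doubles the log-likelihood, not the estimates", {
  dt <- 1 / 30
  dr <- sample_mixture_dr(6000, c(0.6, 0.4), c(0.05, 0.008), dt, seed = 11)
  f1 <- fit_mle(make_disp_set(dr, dt), N = 2, seed = 5, n_restarts = 4)
  f2 <- fit_mle(make_disp_set(rep(dr, 2), dt), N = 2, seed = 5, n_restarts = 4)
  expect_equal(f2$D, f1$D, tolerance = 1e-4)
  expect_equal(f2$weights, f1$weights, tolerance = 1e-4)
  expect_equal(f2$logL, 2 * f1$logL, tolerance = 1e-6)
})

test_that("AIC bookkeeping is consistent and selection favors the generating order", {
  dt <- 1 / 30
  dr <- sample_mixture_dr(20000, c(0.5, 0.5), c(0.08, 0.006), dt, seed = 13)
  sel <- select_states(make_disp_set(dr, dt), N_max = 3, seed = 9,
                       n_restarts = 4)
  ll <- vapply(sel$models, function(m) m$logL, numeric(1))
  expect_equal(sel$aic, -2 * ll + 2 * (2 * seq_along(ll) - 1))
  expect_equal(sel$chosen_N, 2)
  expect_true(all(is.finite(sel$aic)))

  # selection consistency improves with M on well-separated single-state data
  dr1 <- sample_mixture_dr(5000, 1, 0.02, dt, seed = 17)
  sel1 <- select_states(make_disp_set(dr1, dt), N_max = 3, seed = 9,
                        n_restarts = 4)
  expect_equal(sel1$chosen_N, 1)
})

test_that("relative likelihood follows the AIC difference identity", {
  expect_equal(relative_likelihood(10, 10), 1.0)
  expect_equal(relative_likelihood(8, 10), exp(-1))
  a <- 123.4; b <- 120.1
  expect_equal(relative_likelihood(a, b) * relative_likelihood(b, a), 1)
})
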