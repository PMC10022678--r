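#' Rayleigh mixture model of the displacement distribution
#'
#' Under 2-D free diffusion with coefficient `D`, the step length over one
#' frame interval `dt` is Rayleigh distributed with density
#' `f(dr) = dr/(2 D dt) * exp(-dr^2 / (4 D dt))`. A molecule switching
#' between `N` mobility states produces a weighted mixture of such
#' densities. Localization error is deliberately not part of this model:
#' the fitted `D` are apparent diffusion coefficients, used only to choose
#' the number of states; state-wise errors are recovered later from
#' per-state MSD fits.
#'
#' States are stored sorted by decreasing `D` (fast first).
#'
#' @param weights mixture weights, positive, summing to 1.
#' @param D apparent diffusion coefficients (um^2/s), strictly positive.
#' @param dt frame interval (s).
#' @param logL,aic optional fit statistics.
#' @return an object of class `rayleigh_mix`.
#' @export
mixture_model <- function(weights, D, dt, logL = NA_real_, aic = NA_real_) {
  stopifnot(length(weights) == length(D))
  if (any(D <= 0)) stopf("diffusion coefficients must be strictly positive")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stopf("weights must be positive and sum to 1")
  ord <- order(D, decreasing = TRUE)
  structure(
    list(n_states = length(D), weights = weights[ord], D = D[ord], dt = dt,
         logL = logL, aic = aic),
    class = "rayleigh_mix"
  )
}

#' @export
print.rayleigh_mix <- function(x, ...) {
  cat(sprintf("Rayleigh mixture, N = %d (dt = %.4g s)\n", x$n_states, x$dt))
  for (i in seq_len(x$n_states))
    cat(sprintf("  state %d: p = %.3f, D = %.5g um^2/s\n", i, x$weights[i], x$D[i]))
  if (is.finite(x$logL)) cat(sprintf("  logL = %.4f, AIC = %.4f\n", x$logL, x$aic))
  invisible(x)
}

#' Mixture displacement density
#'
#' @param dr displacement magnitudes (um), `>= 0`.
#' @param model a `rayleigh_mix`.
#' @return density values (per um).
#' @export
mixture_pdf <- function(dr, model) {
  stopifnot(inherits(model, "rayleigh_mix"))
  if (any(dr < 0)) stopf("displacements must be nonnegative")
  dens <- numeric(length(dr))
  for (i in seq_len(model$n_states)) {
    s2 <- 2 * model$D[i] * model$dt   # per-axis variance of the step
    dens <- dens + model$weights[i] * dr / s2 * exp(-dr^2 / (2 * s2))
  }
  dens
}

# Log-density matrix (M x N) of each displacement under each component.
# dr == 0 (possible in synthetic data) is floored to keep the log finite.
rayleigh_logdens_matrix <- function(dr, D, dt) {
  floor_at <- sqrt(.Machine$double.eps) * max(mean(dr), .Machine$double.eps)
  n0 <- sum(dr < floor_at)
  if (n0 > 0) dr <- pmax(dr, floor_at)
  out <- matrix(0, length(dr), length(D))
  for (i in seq_along(D)) {
    s2 <- 2 * D[i] * dt
    out[, i] <- log(dr) - log(s2) - dr^2 / (2 * s2)
  }
  attr(out, "n_floored") <- n0
  out
}

log_row_sum_exp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Maximum-likelihood fit of an N-state Rayleigh mixture
#'
#' Fits weights and apparent diffusion coefficients by EM with
#' responsibilities. The M-step is closed form:
#' `D_n = sum_j r_jn dr_j^2 / (4 dt sum_j r_jn)`. Multiple seeded random
#' restarts are run and the best log-likelihood is kept.
#'
#' @param ds a `disp_set` from [displacements()].
#' @param N number of states (1..4 is the supported range).
#' @param seed RNG seed for the restarts.
#' @param n_restarts random restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per restart (default 2000).
#' @return a fitted `rayleigh_mix` with `logL` and `aic` (using
#'   `k = 2N - 1` free parameters) filled in.
#' @export
fit_mle <- function(ds, N, seed = 1, n_restarts = 10, tol = 1e-8, max_iter = 2000) {
  stopifnot(inherits(ds, "disp_set"))
  if (!is_count(N) || N > 4) stopf("N must be an integer in 1..4")
  dr <- ds$steps$dr
  M <- length(dr)
  if (M < 10 * (2 * N - 1)) stopf("too few displacements (%d) for N = %d", M, N)
  dt <- ds$dt
  d_mom <- dr^2 / (4 * dt)               # per-step apparent D
  if (N == 1) {
    D_hat <- mean(d_mom)                 # closed-form Rayleigh MLE
    ll <- sum(rayleigh_logdens_matrix(dr, D_hat, dt))
    return(mixture_model(1, D_hat, dt, logL = ll, aic = -2 * ll + 2 * 1))
  }
  qs <- stats::quantile(d_mom, c(0.02, 0.98))
  best <- NULL
  seeds <- derive_seeds(seed, n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- with_seed(seeds[r], {
      D0 <- sort(exp(stats::runif(N, log(max(qs[1], 1e-12)), log(qs[2]))),
                 decreasing = TRUE)
      w0 <- stats::runif(N, 0.2, 1); w0 <- w0 / sum(w0)
      em_rayleigh_mix(dr, dt, w0, D0, tol, max_iter)
    })
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  if (is.null(best) || !is.finite(best$logL))
    stopf("mixture EM failed to converge for N = %d after %d restarts", N, n_restarts)
  k <- 2 * N - 1
  mixture_model(best$w, best$D, dt, logL = best$logL, aic = -2 * best$logL + 2 * k)
}

em_rayleigh_mix <- function(dr, dt, w, D, tol, max_iter) {
  M <- length(dr)
  N <- length(D)
  floor_at <- sqrt(.Machine$double.eps) * max(mean(dr), .Machine$double.eps)
  dr <- pmax(dr, floor_at)
  ldr <- log(dr)
  dr2 <- dr^2
  lm_ <- matrix(0, M, N)
  ll_old <- -Inf
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(N)) {
      s2 <- 2 * D[i] * dt
      lm_[, i] <- log(w[i]) + ldr - log(s2) - dr2 / (2 * s2)
    }
    lse <- log_row_sum_exp(lm_)
    ll <- sum(lse)
    resp <- exp(lm_ - lse)
    nk <- colSums(resp)
    w <- nk / M
    D <- pmax(colSums(resp * dr2) / (4 * dt * nk), 1e-12)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(w = w, D = D, logL = ll)
}

#' AIC selection of the number of diffusion states
#'
#' Fits mixtures with `N = 1..N_max` states and picks the `N` minimizing
#' `AIC_N = -2 logL_N + 2 k_N` with `k_N = 2N - 1` (N diffusion
#' coefficients plus N-1 free weights). Ties are broken toward the
#' smaller N.
#'
#' @inheritParams fit_mle
#' @param N_max largest state count to consider (default 4).
#' @return a `state_selection` list: `models` (one `rayleigh_mix` per N),
#'   `aic` vector, `chosen_N`, and `relative_likelihood` between
#'   consecutive model orders (`exp((AIC_{N+1} - AIC_N)/2)`).
#' @export
select_states <- function(ds, N_max = 4, seed = 1, ...) {
  models <- lapply(seq_len(N_max), function(N) fit_mle(ds, N, seed = seed, ...))
  aic <- vapply(models, function(m) m$aic, numeric(1))
  if (any(!is.finite(aic))) stopf("non-finite AIC for some model order")
  chosen <- which(aic <= min(aic) + 1e-9)[1]   # parsimony on ties
  rl <- if (N_max > 1) exp((aic[-1] - aic[-N_max]) / 2) else numeric(0)
  structure(
    list(models = models, aic = aic, chosen_N = chosen,
         relative_likelihood = rl),
    class = "state_selection"
  )
}

#' @export
print.state_selection <- function(x, ...) {
  cat("AIC model selection over Rayleigh mixtures\n")
  for (N in seq_along(x$aic))
    cat(sprintf("  N = %d: AIC = %.2f%s\n", N, x$aic[N],
                if (N == x$chosen_N) "  <- chosen" else ""))
  invisible(x)
}

#' Relative likelihood of two models from their AIC values
#'
#' `exp((aic_a - aic_b) / 2)`: how probable model `a` is relative to model
#' `b` in the information-theoretic sense; values below 1 favour `a`.
#'
#' @param aic_a,aic_b AIC values.
#' @export
relative_likelihood <- function(aic_a, aic_b) {
  stopifnot(is.finite(aic_a), is.finite(aic_b))
  exp((aic_a - aic_b) / 2)
}

#' Displacement histogram with fitted mixture overlay
#'
#' Exports (or plots) the binned displacement distribution with the fitted
#' mixture and its per-state components. Default bin width 3 nm.
#'
#' @param ds a `disp_set`.
#' @param model a fitted `rayleigh_mix`.
#' @param bin_um histogram bin width in um (default 0.003).
#' @return invisibly, a data frame with the bin centres, empirical density
#'   and fitted total and per-component densities.
#' @export
displacement_histogram <- function(ds, model, bin_um = 0.003) {
  dr <- ds$steps$dr
  breaks <- seq(0, max(dr) + bin_um, by = bin_um)
  h <- graphics::hist(dr, breaks = breaks, plot = FALSE)
  out <- data.frame(dr = h$mids, density = h$density,
                    fit = mixture_pdf(h$mids, model))
  for (i in seq_len(model$n_states)) {
    comp <- mixture_model(1, model$D[i], model$dt)
    out[[paste0("component_", i)]] <- model$weights[i] * mixture_pdf(h$mids, comp)
  }
  invisible(out)
}
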