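#' Extract state dwell times from decoded paths
#'
#' Collects the durations of maximal same-state runs along each decoded
#' trajectory (run length in displacements times `dt`). Runs truncated by
#' the start or end of a track are flagged as censored; they are included
#' by default downstream because track interruptions are frequent and the
#' exponential tail is dominated by uncensored runs, but a strict mode
#' excluding them is available in [fit_lifetimes()].
#'
#' @param paths a `state_paths` from [viterbi()].
#' @param dt frame interval (s); defaults to the one stored in `paths`.
#' @return a `dwell_set`: data frame with `state`, `duration_s`,
#'   `censored`.
#' @export
extract_dwells <- function(paths, dt = paths$dt) {
  stopifnot(inherits(paths, "state_paths"))
  runs <- state_runs(paths)
  out <- data.frame(state = runs$state, duration_s = runs$len * dt,
                    censored = runs$censored)
  attr(out, "dt") <- dt
  attr(out, "n_states") <- paths$n_states
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' Exponential lifetime fit of dwell times
#'
#' Builds the dwell-time histogram in cumulative (survival) form,
#' `N(t) = #\{dwell >= t\}` on a grid of bin width `bin`, and fits
#' `C * exp(-lambda * t)` by unweighted least squares on bins with at
#' least `min_count` dwells. The state lifetime is `tau = 1/lambda`.
#'
#' @param durations numeric vector of dwell durations (s) for one state.
#' @param bin histogram bin width in seconds (default: the smallest
#'   duration present, i.e. one frame).
#' @param min_count bins with fewer dwells are dropped from the fit.
#' @return a `lifetime_fit` list: `lambda` (1/s), `tau` (s), `C`,
#'   `residual`, `n_dwells`, and the fitted survival table.
#' @export
fit_lifetime <- function(durations, bin = NULL, min_count = 5) {
  durations <- durations[is.finite(durations) & durations > 0]
  if (length(durations) < 20) stopf("need at least 20 dwells for a lifetime fit")
  if (is.null(bin)) bin <- min(durations)
  tgrid <- seq(0, max(durations), by = bin)
  counts <- vapply(tgrid, function(t) sum(durations >= t), numeric(1))
  keep <- counts >= min_count
  t_fit <- tgrid[keep]; c_fit <- counts[keep]
  if (length(t_fit) < 3) stopf("fewer than 3 usable survival bins")
  if (c_fit[length(c_fit)] >= c_fit[1]) stopf("survival histogram does not decay")
  # log-linear start, then unweighted nonlinear least squares
  lf <- stats::lm(log(c_fit) ~ t_fit)
  start <- list(C = exp(unname(stats::coef(lf)[1])),
                lambda = max(-unname(stats::coef(lf)[2]), 1e-8))
  fit <- tryCatch(
    stats::nls(c_fit ~ C * exp(-lambda * t_fit), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    lambda <- start$lambda; C <- start$C
    resid <- sum((c_fit - C * exp(-lambda * t_fit))^2)
  } else {
    cf <- stats::coef(fit)
    lambda <- unname(cf["lambda"]); C <- unname(cf["C"])
    resid <- sum(stats::resid(fit)^2)
  }
  if (lambda <= 0) stopf("fitted decay rate is not positive")
  structure(
    list(lambda = lambda, tau = 1 / lambda, C = C, residual = resid,
         n_dwells = length(durations),
         survival = data.frame(t = t_fit, count = c_fit)),
    class = "lifetime_fit"
  )
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("lifetime fit: tau = %.4g s (lambda = %.4g 1/s, n = %d dwells)\n",
              x$tau, x$lambda, x$n_dwells))
  invisible(x)
}

#' Per-state lifetimes from a dwell set
#'
#' @param dwells a `dwell_set` from [extract_dwells()].
#' @param include_censored include runs truncated by track ends (default
#'   `TRUE`; `FALSE` gives the strict mode).
#' @param ... passed to [fit_lifetime()].
#' @return data frame with one row per state: `state`, `label`, `tau`,
#'   `lambda`, `n_dwells` (states with too few dwells are `NA`).
#' @export
fit_lifetimes <- function(dwells, include_censored = TRUE, ...) {
  stopifnot(inherits(dwells, "dwell_set"))
  N <- attr(dwells, "n_states")
  d <- dwells
  if (!include_censored) d <- d[!d$censored, , drop = FALSE]
  out <- data.frame(state = seq_len(N), label = state_labels(N),
                    tau = NA_real_, lambda = NA_real_, n_dwells = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_len(N)) {
    dk <- d$duration_s[d$state == k]
    out$n_dwells[k] <- length(dk)
    fit <- tryCatch(fit_lifetime(dk, ...), error = function(e) NULL)
    if (!is.null(fit)) {
      out$tau[k] <- fit$tau
      out$lambda[k] <- fit$lambda
    }
  }
  out
}
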