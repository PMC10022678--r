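#' Bootstrap resampling of trajectories
#'
#' Creates `B` datasets by sampling tracks with replacement (overlap
#' allowed), each of the same size as the original set. Resampled tracks
#' get fresh unique ids so that repeated draws of the same track stay
#' distinct downstream.
#'
#' @param ts a [traj_set].
#' @param B number of replicates (default 10).
#' @param seed RNG seed.
#' @return list of `B` [traj_set] objects.
#' @export
bootstrap_trajectories <- function(ts, B = 10, seed = 1) {
  stopifnot(inherits(ts, "traj_set"))
  ids <- unique(ts$tracks$track_id)
  if (length(ids) == 0) stopf("empty trajectory set")
  idx <- split(seq_len(nrow(ts$tracks)), factor(ts$tracks$track_id, levels = ids))
  with_seed(seed, lapply(seq_len(B), function(b) {
    pick <- sample.int(length(ids), length(ids), replace = TRUE)
    rows <- idx[pick]
    nrep <- lengths(rows)
    tab <- ts$tracks[unlist(rows, use.names = FALSE), , drop = FALSE]
    tab$track_id <- rep(sprintf("bs%d_%05d", b, seq_along(pick)), nrep)
    traj_set(tab, dt = ts$dt,
             provenance = sprintf("%s [bootstrap %d]", ts$provenance, b))
  }))
}

#' Bootstrap resampling of displacements
#'
#' Displacement-level resampling with replacement, used for the AIC-based
#' model-count selection.
#'
#' @param ds a `disp_set`.
#' @param B number of replicates (default 10).
#' @param seed RNG seed.
#' @return list of `B` `disp_set` objects.
#' @export
bootstrap_displacements <- function(ds, B = 10, seed = 1) {
  stopifnot(inherits(ds, "disp_set"))
  M <- nrow(ds$steps)
  if (M == 0) stopf("empty displacement set")
  with_seed(seed, lapply(seq_len(B), function(b) {
    pick <- sample.int(M, M, replace = TRUE)
    structure(list(steps = ds$steps[pick, , drop = FALSE], dt = ds$dt),
              class = "disp_set")
  }))
}

#' Summarize bootstrap replicate estimates
#'
#' Mean and 95% confidence half-width over replicate estimates. The
#' default interval is the Student-t interval on the `B` replicates; a
#' percentile interval is available for skewed estimators.
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @param method `"t"` or `"percentile"`.
#' @return a `bootstrap_summary` list: `mean`, `ci95` (half-width),
#'   `lower`, `upper`, `B`, `estimates`.
#' @export
summarize_bootstrap <- function(estimates, method = c("t", "percentile")) {
  method <- match.arg(method)
  bad <- !is.finite(estimates)
  if (any(bad)) {
    warnf("summarize_bootstrap: excluded %d non-finite estimate(s)", sum(bad))
    estimates <- estimates[!bad]
  }
  B <- length(estimates)
  if (B < 2) stopf("need at least 2 finite estimates")
  m <- mean(estimates)
  if (method == "t") {
    hw <- stats::qt(0.975, df = B - 1) * stats::sd(estimates) / sqrt(B)
    lower <- m - hw; upper <- m + hw
  } else {
    q <- stats::quantile(estimates, c(0.025, 0.975), names = FALSE)
    lower <- q[1]; upper <- q[2]
    hw <- (upper - lower) / 2
  }
  structure(
    list(mean = m, ci95 = hw, lower = lower, upper = upper, B = B,
         estimates = estimates),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap: mean %.4g +/- %.4g (95%% c.i., B = %d)\n",
              x$mean, x$ci95, x$B))
  invisible(x)
}
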