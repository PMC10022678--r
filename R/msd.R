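#' Mean square displacement of a trajectory set
#'
#' For each lag `n` (in frames), averages the squared displacement
#' `(x(t + n dt) - x(t))^2 + (y(t + n dt) - y(t))^2` over all admissible
#' start times within each trajectory and over trajectories
#' (time-and-ensemble average). With `ensemble_only = TRUE` only the first
#' position of each track is used as a start time (pure ensemble average).
#'
#' @param ts a [traj_set].
#' @param n_max largest lag in frames (default 15).
#' @param ensemble_only use only `t = 0` of every track as the start time.
#' @return an `msd_curve`: data frame with columns `lag`, `t_s`, `msd`
#'   (um^2) and `n_pairs`, with the frame interval in `attr(, "dt")`.
#'   Lags with no pairs are dropped.
#' @export
compute_msd <- function(ts, n_max = 15, ensemble_only = FALSE) {
  stopifnot(inherits(ts, "traj_set"))
  tr <- ts$tracks
  if (nrow(tr) < 2) stopf("need at least one trajectory with >= 2 positions")
  id <- tr$track_id
  x <- tr$x
  y <- tr$y
  nr <- nrow(tr)
  first <- c(TRUE, id[-1] != id[-nr])
  lag <- integer(0); msd <- numeric(0); npairs <- integer(0)
  for (n in seq_len(n_max)) {
    if (n >= nr) break
    i <- seq_len(nr - n)
    ok <- id[i] == id[i + n]
    if (ensemble_only) ok <- ok & first[i]
    m <- sum(ok)
    if (m == 0) next
    sq <- (x[i + n][ok] - x[i][ok])^2 + (y[i + n][ok] - y[i][ok])^2
    lag <- c(lag, n); msd <- c(msd, mean(sq)); npairs <- c(npairs, m)
  }
  if (length(lag) == 0) stopf("no lag has any displacement pair")
  out <- data.frame(lag = lag, t_s = lag * ts$dt, msd = msd, n_pairs = npairs)
  attr(out, "dt") <- ts$dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Linear MSD fit for diffusion coefficient and localization error
#'
#' Fits the free-diffusion law `MSD(t) = 4 D t + 4 eps^2` to an MSD curve
#' by ordinary (unweighted) least squares. The slope gives the diffusion
#' coefficient `D = slope / 4` and the intercept the per-coordinate
#' localization error `eps = sqrt(intercept / 4)`.
#'
#' A negative fitted intercept (possible by chance on clean data) is
#' reported as `eps = 0` with `flags` recording `"negative_intercept"`; a
#' negative slope is clamped to `D = 0` with flag `"negative_slope"` and a
#' warning, since free diffusion cannot have decreasing MSD.
#'
#' @param curve an `msd_curve` from [compute_msd()].
#' @param lags optional subset of lags to fit (default: all retained lags).
#' @return an `msd_fit` list with elements `D` (um^2/s), `eps` (um),
#'   `slope`, `intercept`, `residual` (sum of squared residuals),
#'   `n_lags` and `flags`.
#' @export
fit_msd <- function(curve, lags = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  dat <- as.data.frame(curve)
  if (!is.null(lags)) dat <- dat[dat$lag %in% lags, , drop = FALSE]
  if (nrow(dat) < 2) stopf("need at least 2 lags to fit the MSD line")
  fit <- stats::lm(msd ~ t_s, data = dat)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  flags <- character(0)
  D <- slope / 4
  if (slope < 0) {
    warnf("fit_msd: negative MSD slope (%.3g um^2/s); D clamped to 0", slope)
    D <- 0
    flags <- c(flags, "negative_slope")
  }
  if (intercept < 0) {
    eps <- 0
    flags <- c(flags, "negative_intercept")
  } else {
    eps <- sqrt(intercept / 4)
  }
  structure(
    list(D = D, eps = eps, slope = slope, intercept = intercept,
         residual = sum(stats::resid(fit)^2), n_lags = nrow(dat), flags = flags),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD fit: D = %.4g um^2/s, eps = %.4g um (intercept %.3g um^2, %d lags)\n",
              x$D, x$eps, x$intercept, x$n_lags))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$t_s, x$msd, xlab = "lag time (s)", ylab = expression(MSD ~ (mu * m^2)),
                 pch = 16, ...)
  if (!is.null(fit)) graphics::abline(fit$intercept, fit$slope, col = "red3")
  invisible(x)
}

#' Write an MSD curve as CSV
#' @param curve an `msd_curve`.
#' @param path output CSV path.
#' @export
write_msd_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
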