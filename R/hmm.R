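#' Hidden Markov model over displacement sequences
#'
#' States are diffusion regimes; the emission of state `k` is the Rayleigh
#' step-length density with apparent diffusion coefficient `D[k]`
#' (localization error is deliberately not modelled in the emission — it
#' is state dependent and is recovered afterwards from per-state MSD
#' fits). Transition structure is a first-order Markov chain shared by all
#' trajectories, with a common initial distribution `p0`.
#'
#' @param p0 initial state probabilities (sums to 1).
#' @param A row-stochastic transition matrix.
#' @param D per-state apparent diffusion coefficients (um^2/s).
#' @param dt frame interval (s).
#' @param logL optional fitted log-likelihood.
#' @return an object of class `spt_hmm`.
#' @export
hmm_model <- function(p0, A, D, dt, logL = NA_real_) {
  N <- length(D)
  A <- as.matrix(A)
  stopifnot(length(p0) == N, nrow(A) == N, ncol(A) == N)
  if (any(D <= 0)) stopf("diffusion coefficients must be strictly positive")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-6) stopf("p0 must be a probability vector")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-6)) stopf("A must be row-stochastic")
  structure(
    list(n_states = N, p0 = as.numeric(p0), A = unname(A), D = as.numeric(D),
         dt = dt, logL = logL),
    class = "spt_hmm"
  )
}

#' Conventional mobility-state labels
#'
#' Three states are labelled fast/middle/slow by decreasing diffusion
#' coefficient, matching the package's reporting convention; other state
#' counts fall back to generic labels.
#'
#' @param N number of states.
#' @export
state_labels <- function(N) {
  if (N == 3) c("fast", "middle", "slow")
  else if (N == 2) c("fast", "slow")
  else paste0("state", seq_len(N))
}

#' @export
print.spt_hmm <- function(x, ...) {
  lab <- state_labels(x$n_states)
  cat(sprintf("%d-state diffusion HMM (dt = %.4g s)\n", x$n_states, x$dt))
  cat("  D (um^2/s):", paste(sprintf("%s %.4g", lab, x$D), collapse = ", "), "\n")
  cat("  p0:", paste(sprintf("%.3f", x$p0), collapse = " "), "\n")
  cat("  A:\n")
  m <- format(round(x$A, 4))
  for (i in seq_len(x$n_states)) cat("    ", m[i, ], "\n")
  if (is.finite(x$logL)) cat(sprintf("  logL = %.4f\n", x$logL))
  invisible(x)
}

# Reorder states so that D is decreasing (fast first); relabels p0 and A.
sort_hmm_states <- function(model) {
  ord <- order(model$D, decreasing = TRUE)
  hmm_model(model$p0[ord], model$A[ord, ord, drop = FALSE], model$D[ord],
            model$dt, logL = model$logL)
}

#' Rayleigh emission density of a diffusion state
#'
#' `dr/(2 D dt) * exp(-dr^2/(4 D dt))` — the 2-D free-diffusion step-length
#' density, identical in form to the single-state displacement mixture
#' component.
#'
#' @param dr displacement magnitudes (um).
#' @param D diffusion coefficient (um^2/s), `> 0`.
#' @param dt frame interval (s).
#' @export
emission_density <- function(dr, D, dt) {
  if (any(dr < 0)) stopf("displacements must be nonnegative")
  if (any(D <= 0)) stopf("D must be strictly positive")
  s2 <- 2 * D * dt
  dr / s2 * exp(-dr^2 / (2 * s2))
}

#' Data-driven HMM initialization
#'
#' Per-state diffusion coefficients are initialized from the k-means
#' cluster centres of the per-step apparent coefficients `dr^2/(4 dt)`;
#' the initial distribution and transition matrix are drawn at random
#' (rows normalized). Degenerate clusterings are retried with fresh seeds.
#'
#' @param ds a `disp_set`.
#' @param N number of states.
#' @param seed RNG seed.
#' @param max_retries retries on degenerate clustering.
#' @return an `spt_hmm` (unsorted; sorting happens after fitting).
#' @export
init_hmm <- function(ds, N, seed = 1, max_retries = 10) {
  stopifnot(inherits(ds, "disp_set"))
  dr <- ds$steps$dr
  if (length(dr) < 10 * N) stopf("need at least %d displacements for N = %d", 10 * N, N)
  d_mom <- dr^2 / (4 * ds$dt)
  seeds <- derive_seeds(seed, max_retries)
  for (r in seq_len(max_retries)) {
    res <- with_seed(seeds[r], {
      centers <- if (N == 1) mean(d_mom) else {
        km <- tryCatch(stats::kmeans(d_mom, centers = N, nstart = 3, iter.max = 50),
                       error = function(e) NULL)
        if (is.null(km) || any(km$size == 0)) NULL else as.numeric(km$centers)
      }
      if (is.null(centers)) NULL else {
        p0 <- stats::runif(N); p0 <- p0 / sum(p0)
        A <- matrix(stats::runif(N * N), N, N)
        A <- A / rowSums(A)
        hmm_model(p0, A, pmax(centers, 1e-10), ds$dt)
      }
    })
    if (!is.null(res)) return(res)
  }
  stopf("k-means initialization degenerate after %d retries", max_retries)
}

# ---- internal: padded displacement sequences -------------------------------

# Pack per-track displacement sequences into a matrix (tracks x steps,
# NA-padded), rows sorted by decreasing length so that the set of tracks
# still active at step t is always a leading block of rows.
pack_sequences <- function(ts) {
  ds <- displacements(ts)
  st <- ds$steps
  ids <- unique(st$track_id)
  lens <- as.integer(table(factor(st$track_id, levels = ids)))
  ord <- order(lens, decreasing = TRUE)
  rank_of <- integer(length(ids)); rank_of[ord] <- seq_along(ids)
  row <- rank_of[match(st$track_id, ids)]
  col <- sequence(lens)   # steps arrive grouped by track, frame-ordered
  drmat <- matrix(NA_real_, length(ids), max(lens))
  drmat[cbind(row, col)] <- st$dr
  list(drmat = drmat, lens = lens[ord], track_ids = ids[ord],
       n_active = vapply(seq_len(max(lens)), function(t) sum(lens[ord] >= t),
                         integer(1)),
       dt = ds$dt)
}

# Emission log-density array (tracks x steps x N) for packed sequences.
packed_log_emissions <- function(drmat, D, dt) {
  ntr <- nrow(drmat); L <- ncol(drmat); N <- length(D)
  dr <- drmat
  floor_at <- sqrt(.Machine$double.eps) * max(mean(dr, na.rm = TRUE), 1e-300)
  dr[!is.na(dr) & dr < floor_at] <- floor_at
  logB <- array(NA_real_, c(ntr, L, N))
  for (k in seq_len(N)) {
    s2 <- 2 * D[k] * dt
    logB[, , k] <- log(dr) - log(s2) - dr^2 / (2 * s2)
  }
  logB
}

# Slice arr[rows, t, ] as a guaranteed length(rows) x N matrix.
mslice <- function(arr, rows, t) {
  m <- arr[rows, t, , drop = FALSE]
  dim(m) <- c(length(rows), dim(arr)[3])
  m
}

# Scaled forward-backward over packed sequences.
#
# want_gamma = FALSE   -> log-likelihood only
# want_gamma = "stats" -> logL + the Baum-Welch sufficient statistics
#                         (gamma1, xi_sum, and per-state posterior sums
#                         gsum / gd = sum(gamma), sum(gamma * dr^2))
# want_gamma = TRUE    -> additionally the full posterior array
forward_backward_packed <- function(pk, model, want_gamma = TRUE) {
  drmat <- pk$drmat; lens <- pk$lens; n_active <- pk$n_active
  N <- model$n_states; L <- ncol(drmat); ntr <- nrow(drmat)
  A <- model$A; p0 <- model$p0
  full <- isTRUE(want_gamma)
  logB <- packed_log_emissions(drmat, model$D, model$dt)
  # per-cell shift so the largest emission is 1 (protects against underflow)
  shift <- logB[, , 1]
  if (N > 1) for (k in 2:N) shift <- pmax(shift, logB[, , k])
  if (!is.matrix(shift)) shift <- matrix(shift, ntr, L)
  Blist <- vector("list", L)      # shifted emissions, active rows only
  for (t in seq_len(L)) {
    rows <- seq_len(n_active[t])
    if (length(rows))
      Blist[[t]] <- exp(mslice(logB, rows, t) - shift[rows, t])
  }
  alpha <- vector("list", L)
  logc <- matrix(0, ntr, L)   # log of per-step scaling constants (incl. shift)
  rows <- seq_len(n_active[1])
  a <- matrix(p0, n_active[1], N, byrow = TRUE) * Blist[[1]]
  cs <- rowSums(a)
  alpha[[1]] <- a / cs
  logc[rows, 1] <- log(cs) + shift[rows, 1]
  for (t in seq_len(L - 1) + 1) {
    na_t <- n_active[t]
    if (na_t == 0) break
    rows <- seq_len(na_t)
    a <- (alpha[[t - 1]][rows, , drop = FALSE] %*% A) * Blist[[t]]
    cs <- rowSums(a)
    alpha[[t]] <- a / cs
    logc[rows, t] <- log(cs) + shift[rows, t]
  }
  logL <- sum(logc[cbind(rep(seq_len(ntr), lens), sequence(lens))])
  if (identical(want_gamma, FALSE)) return(list(logL = logL))

  xi_sum <- matrix(0, N, N)
  gsum <- numeric(N)
  gd <- numeric(N)
  gamma <- if (full) array(0, c(ntr, L, N)) else NULL
  # each track's final step has beta = 1, so gamma there is just alpha
  for (t in unique(lens)) {
    idx <- which(lens == t)
    g <- alpha[[t]][idx, , drop = FALSE]
    gsum <- gsum + colSums(g)
    gd <- gd + colSums(g * drmat[idx, t]^2)
    if (full) gamma[cbind(rep(idx, N), t, rep(seq_len(N), each = length(idx)))] <- g
  }
  gamma1 <- matrix(NA_real_, ntr, N)
  one_step <- which(lens == 1L)
  if (length(one_step)) gamma1[one_step, ] <- alpha[[1]][one_step, , drop = FALSE]
  beta <- matrix(1, ntr, N)     # beta at each track's current last level
  if (L > 1) for (t in seq(L - 1, 1)) {
    rows_next <- seq_len(n_active[t + 1])          # tracks with a step at t+1
    if (length(rows_next) > 0) {
      Bb <- Blist[[t + 1]] * beta[rows_next, , drop = FALSE]
      csn <- exp(logc[rows_next, t + 1] - shift[rows_next, t + 1])
      al <- alpha[[t]][rows_next, , drop = FALSE]
      # xi_sum[i, j] += A[i, j] * sum_r alpha[r, i]/c[r] * Bb[r, j]
      xi_sum <- xi_sum + A * crossprod(al / csn, Bb)
      bnew <- (Bb / csn) %*% t(A)
      beta[rows_next, ] <- bnew
      g <- al * bnew
      g <- g / rowSums(g)
      gsum <- gsum + colSums(g)
      gd <- gd + colSums(g * drmat[rows_next, t]^2)
      if (full) gamma[cbind(rep(rows_next, N), t, rep(seq_len(N), each = length(rows_next)))] <- g
      if (t == 1L) gamma1[rows_next, ] <- g
    }
    # tracks whose last step is exactly t restart with beta = 1
    ending <- which(lens == t)
    if (length(ending)) beta[ending, ] <- 1
  }
  list(logL = logL, gamma = gamma, xi_sum = xi_sum, gamma1 = gamma1,
       gsum = gsum, gd = gd)
}

#' Baum-Welch estimation of the diffusion HMM
#'
#' Standard multi-sequence EM with scaled forward-backward. The M-step for
#' the diffusion coefficients is closed form,
#' `D_k = sum(gamma_k * dr^2) / (4 dt sum(gamma_k))`. The log-likelihood is
#' non-decreasing over iterations (an EM guarantee that the test suite
#' checks).
#'
#' @param ts a [traj_set]; every track contributes one displacement
#'   sequence.
#' @param init an `spt_hmm` starting point (see [init_hmm()]).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param trace if `TRUE`, attach the per-iteration log-likelihood path.
#' @return a fitted `spt_hmm` (states in the order of `init`; use
#'   [fit_hmm()] for sorted fast-to-slow output).
#' @export
baum_welch <- function(ts, init, tol = 1e-6, max_iter = 500, trace = FALSE) {
  stopifnot(inherits(ts, "traj_set"), inherits(init, "spt_hmm"))
  pk <- pack_sequences(ts)
  model <- init
  ll_path <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    e <- forward_backward_packed(pk, model, want_gamma = "stats")
    if (!is.finite(e$logL))
      stopf("non-finite log-likelihood at Baum-Welch iteration %d", it)
    ll_path <- c(ll_path, e$logL)
    # M-step
    p0 <- colMeans(e$gamma1)
    A <- e$xi_sum / rowSums(e$xi_sum)
    D <- ifelse(e$gsum > 1e-10, e$gd / (4 * model$dt * e$gsum), model$D)
    D <- pmax(D, 1e-12)
    model <- hmm_model(p0, A, D, model$dt, logL = e$logL)
    if (is.finite(ll_old) &&
        abs(e$logL - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) break
    ll_old <- e$logL
  }
  if (trace) attr(model, "logL_path") <- ll_path
  model
}

#' Fit the diffusion HMM with seeded restarts
#'
#' Runs [init_hmm()] + [baum_welch()] `n_restarts` times with derived
#' seeds, keeps the fit with the best log-likelihood, and relabels states
#' fast-to-slow by decreasing diffusion coefficient.
#'
#' @param ts a [traj_set].
#' @param N number of states (default 3).
#' @param seed RNG seed.
#' @param n_restarts restarts (default 5).
#' @param ... passed to [baum_welch()] (`tol`, `max_iter`).
#' @return a fitted, state-sorted `spt_hmm`.
#' @export
fit_hmm <- function(ts, N = 3, seed = 1, n_restarts = 5, ...) {
  ds <- displacements(ts)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- init_hmm(ds, N, seed = seeds[r])
    fit <- baum_welch(ts, init, ...)
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  sort_hmm_states(best)
}

#' Viterbi decoding of mobility states
#'
#' Returns the most probable state path for every trajectory (log-space
#' dynamic program; ties broken deterministically toward the lower state
#' index, i.e. the faster state when the model is sorted) together with
#' the per-step posterior state probabilities from the forward-backward
#' recursion.
#'
#' @param ts a [traj_set].
#' @param model a fitted `spt_hmm`.
#' @return a `state_paths` object: data frame `steps` with `track_id`,
#'   `frame` (frame at the start of the step), `state` (1 = fastest), and
#'   matrix `posterior` (one row per step), plus `n_states`, `dt`.
#' @export
viterbi <- function(ts, model) {
  stopifnot(inherits(ts, "traj_set"), inherits(model, "spt_hmm"))
  pk <- pack_sequences(ts)
  N <- model$n_states; L <- ncol(pk$drmat); ntr <- nrow(pk$drmat)
  logA <- log(model$A + 1e-300)
  logB <- packed_log_emissions(pk$drmat, model$D, model$dt)
  delta <- matrix(rep(log(model$p0 + 1e-300), each = ntr), ntr, N) + logB[, 1, ]
  if (N == 1) delta <- matrix(delta, ntr, 1)
  psi <- array(1L, c(ntr, L, N))
  states <- matrix(NA_integer_, ntr, L)
  if (L > 1) for (t in 2:L) {
    na_t <- pk$n_active[t]
    if (na_t == 0) break
    rows <- seq_len(na_t)
    newdelta <- matrix(-Inf, na_t, N)
    for (j in seq_len(N)) {
      cand <- delta[rows, , drop = FALSE] +
        matrix(logA[, j], na_t, N, byrow = TRUE)
      arg <- max.col(cand, ties.method = "first")
      psi[rows, t, j] <- arg
      newdelta[, j] <- cand[cbind(seq_len(na_t), arg)] + logB[rows, t, j]
    }
    # tracks ending at t-1: terminal argmax from their final delta
    ended <- which(pk$lens == t - 1)
    if (length(ended))
      states[cbind(ended, t - 1L)] <-
        max.col(delta[ended, , drop = FALSE], ties.method = "first")
    delta[rows, ] <- newdelta
  }
  for (len in unique(pk$lens)) {
    rows <- which(pk$lens == len)
    rows <- rows[is.na(states[cbind(rows, len)])]
    if (length(rows))
      states[cbind(rows, len)] <- max.col(delta[rows, , drop = FALSE],
                                          ties.method = "first")
  }
  if (L > 1) for (t in seq(L - 1, 1)) {
    rows <- seq_len(pk$n_active[t + 1])
    if (length(rows))
      states[cbind(rows, t)] <- psi[cbind(rows, t + 1L, states[cbind(rows, t + 1L)])]
  }
  # posteriors
  fb <- forward_backward_packed(pk, model, want_gamma = TRUE)
  # unpack in the original displacement order
  ds <- displacements(ts)
  st <- ds$steps[, c("track_id", "frame")]
  ids <- unique(ds$steps$track_id)
  row_of <- match(st$track_id, pk$track_ids)
  lens_orig <- as.integer(table(factor(st$track_id, levels = ids)))
  col_of <- sequence(lens_orig)
  st$state <- states[cbind(row_of, col_of)]
  post <- matrix(NA_real_, nrow(st), N)
  for (k in seq_len(N)) post[, k] <- fb$gamma[cbind(row_of, col_of, rep(k, nrow(st)))]
  colnames(post) <- state_labels(N)
  structure(
    list(steps = st, posterior = post, n_states = N, dt = model$dt,
         logL = fb$logL),
    class = "state_paths"
  )
}

#' @export
print.state_paths <- function(x, ...) {
  cat(sprintf("state_paths: %d steps over %d tracks, %d states\n",
              nrow(x$steps), length(unique(x$steps$track_id)), x$n_states))
  tab <- table(factor(x$steps$state, levels = seq_len(x$n_states)))
  names(tab) <- state_labels(x$n_states)
  print(round(tab / sum(tab), 3))
  invisible(x)
}

# Contiguous same-state runs. Returns one row per run: track, state,
# start frame, run length in displacements, and whether the run touches
# either end of its track (censored dwell).
state_runs <- function(paths) {
  st <- paths$steps
  n <- nrow(st)
  new_run <- c(TRUE, st$track_id[-1] != st$track_id[-n] | st$state[-1] != st$state[-n])
  run_id <- cumsum(new_run)
  start <- which(new_run)
  len <- diff(c(start, n + 1L))
  end <- start + len - 1L
  new_track <- c(TRUE, st$track_id[-1] != st$track_id[-n])
  track_start <- which(new_track)
  track_of_run <- cumsum(new_track)[start]
  track_end <- c(track_start[-1] - 1L, n)
  data.frame(
    track_id = st$track_id[start],
    state = st$state[start],
    start_row = start,
    len = len,
    censored = start %in% track_start | end %in% track_end,
    stringsAsFactors = FALSE
  )
}

#' Per-state MSD fit along decoded trajectories
#'
#' Extracts maximal same-state segments as sub-trajectories (a run of `L`
#' displacements contributes `L + 1` positions), pools the segments of
#' each state, and runs the MSD analysis on each pool to estimate the
#' state's diffusion coefficient `D_S` and localization error `eps_S`.
#' States whose segments support fewer than two MSD lags are returned as
#' `NA` with `flag = "insufficient_segments"`.
#'
#' @param ts the [traj_set] that was decoded.
#' @param paths the matching `state_paths` from [viterbi()].
#' @param n_max largest MSD lag (default 15).
#' @return a data frame with one row per state: `state`, `label`, `D_S`,
#'   `eps_S`, `n_segments`, `n_steps`, `flag`.
#' @export
state_msd_fit <- function(ts, paths, n_max = 15) {
  stopifnot(inherits(ts, "traj_set"), inherits(paths, "state_paths"))
  runs <- state_runs(paths)
  tr <- ts$tracks
  # map displacement row -> position row: each preceding track "loses" one row
  st <- paths$steps
  ids <- unique(st$track_id)
  ord_pos <- order(tr$track_id, tr$frame)
  tr <- tr[ord_pos, , drop = FALSE]
  track_ordinal <- cumsum(c(TRUE, st$track_id[-1] != st$track_id[-nrow(st)]))
  pos_row_of_disp <- seq_len(nrow(st)) + track_ordinal - 1L
  N <- paths$n_states
  lab <- state_labels(N)
  out <- data.frame(state = seq_len(N), label = lab, D_S = NA_real_,
                    eps_S = NA_real_, n_segments = 0L, n_steps = 0L,
                    flag = "", stringsAsFactors = FALSE)
  for (k in seq_len(N)) {
    rk <- runs[runs$state == k, , drop = FALSE]
    if (nrow(rk) == 0) { out$flag[k] <- "insufficient_segments"; next }
    pos_start <- pos_row_of_disp[rk$start_row]
    seg_len <- rk$len + 1L
    rows <- sequence(seg_len) - 1L + rep(pos_start, seg_len)
    seg_tracks <- data.frame(
      track_id = rep(sprintf("seg%06d", seq_len(nrow(rk))), seg_len),
      frame = sequence(seg_len),
      x = tr$x[rows], y = tr$y[rows],
      stringsAsFactors = FALSE
    )
    seg_ts <- traj_set(seg_tracks, dt = ts$dt, provenance = paste0("state-", lab[k]))
    curve <- tryCatch(compute_msd(seg_ts, n_max = n_max), error = function(e) NULL)
    out$n_segments[k] <- nrow(rk)
    out$n_steps[k] <- sum(rk$len)
    if (is.null(curve) || nrow(curve) < 2) { out$flag[k] <- "insufficient_segments"; next }
    fit <- suppressWarnings(fit_msd(curve))   # clamps are recorded in `flag`
    out$D_S[k] <- fit$D
    out$eps_S[k] <- fit$eps
    if (length(fit$flags)) out$flag[k] <- paste(fit$flags, collapse = ";")
  }
  out
}

#' Steady-state occupancy of each mobility state
#'
#' Averages the posterior state probabilities over all steps and
#' trajectories (default), or alternatively counts Viterbi-state
#' fractions.
#'
#' @param paths a `state_paths`.
#' @param method `"posterior"` (average of forward-backward posteriors) or
#'   `"viterbi"` (fraction of decoded steps).
#' @return named numeric vector summing to 1.
#' @export
occupancy <- function(paths, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  if (method == "posterior") {
    p <- colMeans(paths$posterior)
  } else {
    tab <- tabulate(paths$steps$state, nbins = paths$n_states)
    p <- tab / sum(tab)
    names(p) <- state_labels(paths$n_states)
  }
  p / sum(p)
}

#' First-order transition rate constants
#'
#' Converts off-diagonal per-frame transition probabilities to rates,
#' `k_ij = A_ij / dt` (1/s); the diagonal is left `NA`.
#'
#' @param model a fitted `spt_hmm`.
#' @return an `N x N` matrix of rates with `NA` diagonal, labelled by
#'   state.
#' @export
transition_rates <- function(model) {
  stopifnot(inherits(model, "spt_hmm"))
  r <- model$A / model$dt
  diag(r) <- NA_real_
  lab <- state_labels(model$n_states)
  dimnames(r) <- list(from = lab, to = lab)
  r
}
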