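# Shared fixtures and independent oracles for the test suite.

# Build a disp_set directly from a vector of step lengths.
make_disp_set <- function(dr, dt = 1 / 30) {
  structure(
    list(steps = data.frame(track_id = "t1", frame = seq_along(dr), dr = dr,
                            stringsAsFactors = FALSE),
         dt = dt),
    class = "disp_set"
  )
}

# A 1-D trajectory whose displacement magnitudes are exactly `dr`.
traj_from_dr <- function(dr, dt = 1 / 30, id = "t1") {
  data.frame(track_id = id, frame = seq_len(length(dr) + 1),
             x = cumsum(c(0, dr)), y = 0, stringsAsFactors = FALSE)
}

# Sample M displacements from a Rayleigh mixture (independent generator,
# used as the oracle for mixture fitting).
sample_mixture_dr <- function(M, weights, D, dt, seed) {
  withr::with_seed(seed, {
    st <- sample(seq_along(weights), M, replace = TRUE, prob = weights)
    sqrt(-4 * D[st] * dt * log(runif(M)))
  })
}

# The control-like transition matrix used throughout the HMM tests:
# diagonals ~ (0.3, 0.95, 0.93) (fast dwell ~0.05 s, slow ~0.5 s) and
# near-zero direct fast<->slow exchange.
control_A <- function() {
  rbind(c(0.30, 0.695, 0.005),
        c(0.03, 0.95, 0.02),
        c(0.005, 0.065, 0.93))
}

control_D <- function() c(0.10, 0.03, 0.008)
control_eps <- function() c(0.088, 0.012, 0.010)

stationary_dist <- function(A) {
  ev <- eigen(t(A))
  p <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  p / sum(p)
}

control_hmm <- function(dt = 1 / 30) {
  A <- control_A()
  hmm_model(stationary_dist(A), A, control_D(), dt = dt)
}

# Brute-force forward-backward by full path enumeration: exact likelihood
# and posteriors for one displacement sequence. Exponential in length --
# only usable for short sequences and small N.
brute_force_fb <- function(dr, p0, A, D, dt) {
  L <- length(dr)
  N <- length(p0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), L)))
  B <- vapply(seq_len(N), function(k) emission_density(dr, D[k], dt),
              numeric(L))
  if (L == 1) B <- matrix(B, 1, N)
  probs <- apply(paths, 1, function(s) {
    p <- p0[s[1]] * B[1, s[1]]
    if (L > 1) for (t in 2:L) p <- p * A[s[t - 1], s[t]] * B[t, s[t]]
    p
  })
  total <- sum(probs)
  gamma <- matrix(0, L, N)
  for (t in seq_len(L)) for (k in seq_len(N))
    gamma[t, k] <- sum(probs[paths[, t] == k]) / total
  list(logL = log(total), gamma = gamma)
}

# Naive per-trajectory MSD (double loop) -- oracle for compute_msd.
naive_msd <- function(tracks_df, dt, n_max) {
  ids <- unique(tracks_df$track_id)
  out <- sapply(seq_len(n_max), function(n) {
    sq <- c()
    for (id in ids) {
      tr <- tracks_df[tracks_df$track_id == id, ]
      tr <- tr[order(tr$frame), ]
      L <- nrow(tr)
      if (L > n) for (i in seq_len(L - n))
        sq <- c(sq, (tr$x[i + n] - tr$x[i])^2 + (tr$y[i + n] - tr$y[i])^2)
    }
    if (length(sq)) mean(sq) else NA_real_
  })
  out
}

# Minimal hand-made state_paths object (for run-length / dwell tests).
fake_paths <- function(track_id, state, dt = 1 / 30, n_states = 3) {
  steps <- data.frame(track_id = track_id, state = state,
                      stringsAsFactors = FALSE)
  steps$frame <- stats::ave(seq_len(nrow(steps)), steps$track_id,
                            FUN = seq_along)
  post <- matrix(0, nrow(steps), n_states)
  post[cbind(seq_len(nrow(steps)), state)] <- 1
  structure(list(steps = steps[, c("track_id", "frame", "state")],
                 posterior = post, n_states = n_states, dt = dt),
            class = "state_paths")
}
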