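#' Mosaic membrane field specification
#'
#' Describes a square membrane patch tiled by three viscosity regions:
#' fast and slow microdomain clumps placed at random on a middle-mobility
#' background. Four parameters shape the mosaic: the side lengths of the
#' fast and slow clumps and their occupied percentage areas. Each region
#' carries its own diffusion coefficient and (state-dependent)
#' localization error.
#'
#' Fast and slow regions must never adjoin: clump placement keeps a
#' buffer (default 50 nm) between clumps of opposite kind, reflecting the
#' near-absence of direct fast/slow transitions in decoded trajectories.
#'
#' @param field_size_um side of the square field (um, default 10 -- about
#'   one cell footprint; 5 um is a common alternative for display).
#' @param clump_fast_nm,clump_slow_nm clump side lengths (nm).
#' @param occupancy_fast,occupancy_slow occupied area (% of field).
#' @param D named diffusion coefficients `c(fast=, middle=, slow=)` in
#'   um^2/s, strictly decreasing.
#' @param eps_um named per-region localization errors (um, per
#'   coordinate).
#' @param grid_nm raster resolution for region lookup (nm).
#' @param buffer_nm minimum spacing between fast and slow clumps (nm).
#' @param shape clump shape, `"square"` or `"circle"` (equal-area discs).
#' @return a `field_spec` list.
#' @export
field_spec <- function(field_size_um = 10,
                       clump_fast_nm = 50, clump_slow_nm = 250,
                       occupancy_fast = 5, occupancy_slow = 30,
                       D = c(fast = 0.10, middle = 0.03, slow = 0.008),
                       eps_um = c(fast = 0.088, middle = 0.012, slow = 0.010),
                       grid_nm = 10, buffer_nm = 50,
                       shape = c("square", "circle")) {
  shape <- match.arg(shape)
  stopifnot(length(D) == 3, length(eps_um) == 3)
  D <- unname(D); eps_um <- unname(eps_um)
  if (!(D[1] > D[2] && D[2] > D[3]))
    stopf("require D_fast > D_middle > D_slow")
  if (occupancy_fast < 0 || occupancy_slow < 0 ||
      occupancy_fast + occupancy_slow >= 100)
    stopf("occupancies must be nonnegative and sum to < 100%%")
  if (clump_fast_nm < grid_nm || clump_slow_nm < grid_nm)
    stopf("clump sizes must be at least the grid resolution")
  structure(
    list(field_size_um = field_size_um, clump_fast_nm = clump_fast_nm,
         clump_slow_nm = clump_slow_nm, occupancy_fast = occupancy_fast,
         occupancy_slow = occupancy_slow, D = D, eps_um = eps_um,
         grid_nm = grid_nm, buffer_nm = buffer_nm, shape = shape),
    class = "field_spec"
  )
}

# Cell offsets of one clump footprint (square side s cells, or the
# equal-area disc), relative to the top-left corner.
clump_footprint <- function(s_cells, shape) {
  if (shape == "square") {
    expand.grid(di = seq_len(s_cells) - 1L, dj = seq_len(s_cells) - 1L)
  } else {
    r <- s_cells / sqrt(pi)            # equal-area disc radius in cells
    half <- ceiling(r)
    g <- expand.grid(di = seq(-half, half), dj = seq(-half, half))
    g <- g[(g$di)^2 + (g$dj)^2 <= r^2, , drop = FALSE]
    g$di <- g$di + half; g$dj <- g$dj + half
    g
  }
}

#' Build a rasterized mosaic field
#'
#' Places the requested number of slow clumps, then fast clumps, at
#' uniform random positions with rejection of overlaps; fast clumps are
#' additionally rejected within `buffer_nm` of any slow cell so that the
#' two kinds never adjoin. Deterministic under `seed`.
#'
#' @param spec a [field_spec()].
#' @param seed RNG seed.
#' @param max_attempts_per_clump rejection-sampling budget.
#' @return a `field_map`: integer raster `grid` (1 = fast, 2 = middle,
#'   3 = slow), the spec, cell size, and realized area fractions.
#' @export
build_field <- function(spec, seed = 1, max_attempts_per_clump = 500) {
  stopifnot(inherits(spec, "field_spec"))
  res <- spec$grid_nm
  G <- round(spec$field_size_um * 1000 / res)
  grid <- matrix(2L, G, G)
  with_seed(seed, {
    for (kind in c("slow", "fast")) {
      s_nm <- if (kind == "slow") spec$clump_slow_nm else spec$clump_fast_nm
      occ <- if (kind == "slow") spec$occupancy_slow else spec$occupancy_fast
      s_cells <- max(1L, round(s_nm / res))
      fp <- clump_footprint(s_cells, spec$shape)
      cells_per <- nrow(fp)
      n_clumps <- round(occ / 100 * G^2 / cells_per)
      if (n_clumps == 0) next
      lab <- if (kind == "slow") 3L else 1L
      buf <- ceiling(spec$buffer_nm / res)
      span <- max(fp$di) + 1L
      placed <- 0L
      attempts <- 0L
      budget <- max_attempts_per_clump * n_clumps
      while (placed < n_clumps && attempts < budget) {
        attempts <- attempts + 1L
        i <- sample.int(G - span + 1L, 1L)
        j <- sample.int(G - span + 1L, 1L)
        rows <- i + fp$di; cols <- j + fp$dj
        cells <- grid[cbind(rows, cols)]
        if (any(cells != 2L)) next
        if (kind == "fast" && buf > 0) {
          ri <- max(1L, i - buf):min(G, i + span - 1L + buf)
          rj <- max(1L, j - buf):min(G, j + span - 1L + buf)
          if (any(grid[ri, rj] == 3L)) next
        }
        grid[cbind(rows, cols)] <- lab
        placed <- placed + 1L
      }
      if (placed < n_clumps)
        stopf("could not place all %s clumps: %d of %d (achieved %.2f%% of %.2f%%)",
              kind, placed, n_clumps,
              100 * placed * cells_per / G^2, occ)
    }
  })
  frac <- c(fast = mean(grid == 1L), middle = mean(grid == 2L),
            slow = mean(grid == 3L))
  structure(
    list(grid = grid, spec = spec, res_um = res / 1000, fractions = frac,
         seed = seed),
    class = "field_map"
  )
}

#' Equal-area circular-clump variant of a field
#'
#' Convenience wrapper building the same field spec with clumps rasterized
#' as discs whose area matches the squares.
#'
#' @inheritParams build_field
#' @export
circle_clump_variant <- function(spec, seed = 1, ...) {
  spec$shape <- "circle"
  build_field(spec, seed = seed, ...)
}

#' Audit fast/slow adjacency of a field
#'
#' Checks the invariant that no fast cell is 8-adjacent to a slow cell.
#'
#' @param map a `field_map`.
#' @return `TRUE` if the field passes; otherwise `FALSE`.
#' @export
field_audit <- function(map) {
  g <- map$grid
  G <- nrow(g)
  fast <- g == 1L
  slow <- g == 3L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(G) + di; rj <- seq_len(G) + dj
    ok_i <- ri >= 1 & ri <= G; ok_j <- rj >= 1 & rj <= G
    if (any(fast[ok_i, ok_j] & slow[ri[ok_i], rj[ok_j]])) return(FALSE)
  }
  TRUE
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map: %.3g um square, %d x %d cells (%.3g nm)\n",
              x$spec$field_size_um, nrow(x$grid), ncol(x$grid),
              x$res_um * 1000))
  cat(sprintf("  area fractions: fast %.3f, middle %.3f, slow %.3f\n",
              x$fractions["fast"], x$fractions["middle"], x$fractions["slow"]))
  invisible(x)
}

#' @export
plot.field_map <- function(x, ...) {
  cols <- c("#4477dd", "#eedd66", "#cc4433")   # fast, middle, slow
  graphics::image(seq_len(nrow(x$grid)) * x$res_um,
                  seq_len(ncol(x$grid)) * x$res_um,
                  matrix(as.numeric(x$grid), nrow(x$grid)),
                  col = cols, zlim = c(1, 3), useRaster = TRUE,
                  xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

#' Write a field raster as CSV
#' @param map a `field_map`.
#' @param path output path.
#' @export
write_field_csv <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

region_lookup <- function(map, x, y) {
  G <- nrow(map$grid)
  ix <- pmin(pmax(floor(x / map$res_um) + 1L, 1L), G)
  iy <- pmin(pmax(floor(y / map$res_um) + 1L, 1L), G)
  map$grid[cbind(ix, iy)]
}

#' Simulate particle diffusion on a mosaic field
#'
#' Each particle starts at a uniform random position. Per frame: the
#' region at the particle's current position is looked up, a step length
#' is drawn from the Rayleigh law of that region's diffusion coefficient,
#' a direction is drawn uniformly, and the particle moves (no sub-stepping
#' across boundaries: the region is only checked at the step's start).
#' Particles leaving the field are reflected specularly at the boundary,
#' and the trajectory is broken at the reflected frame -- the continuation
#' gets a new track id, as if a new molecule had flowed in.
#'
#' The first `burn_in` frames are discarded so that the spatial
#' distribution (which becomes enriched in slow regions) reaches steady
#' state. The recorded `state` column holds the ground-truth region label
#' (1 = fast, 2 = middle, 3 = slow) at every retained frame.
#'
#' Fragments of a single frame (created when a reflection hits the last
#' recorded frame) cannot form a trajectory and are dropped; the counts
#' are kept in attributes `n_positions_total` / `n_positions_dropped`.
#'
#' @param map a `field_map` from [build_field()].
#' @param n_traj number of particles (default 5000).
#' @param n_frames retained frames per particle (default 100).
#' @param burn_in discarded initial frames (default 100).
#' @param dt frame interval (s, default 1/30).
#' @param seed RNG seed.
#' @return a [traj_set] with ground-truth `state`, provenance
#'   `"fieldsim"`.
#' @export
simulate_particles <- function(map, n_traj = 5000, n_frames = 100,
                               burn_in = 100, dt = 1 / 30, seed = 1) {
  stopifnot(inherits(map, "field_map"))
  if (!is_count(n_traj) || !is_count(n_frames, 2) || !is_count(burn_in, 0))
    stopf("n_traj, n_frames, burn_in must be positive counts")
  L <- map$spec$field_size_um
  Dreg <- map$spec$D
  total <- burn_in + n_frames
  X <- matrix(NA_real_, n_traj, n_frames)
  Y <- matrix(NA_real_, n_traj, n_frames)
  S <- matrix(NA_integer_, n_traj, n_frames)
  BRK <- matrix(FALSE, n_traj, n_frames)   # frame starts a new fragment
  with_seed(seed, {
    x <- stats::runif(n_traj) * L
    y <- stats::runif(n_traj) * L
    pending_break <- rep(FALSE, n_traj)
    for (f in seq_len(total)) {
      reg <- region_lookup(map, x, y)
      if (f > burn_in) {
        k <- f - burn_in
        X[, k] <- x; Y[, k] <- y; S[, k] <- reg
        BRK[, k] <- pending_break
      }
      dr <- rrayleigh_step(n_traj, Dreg[reg], dt)
      th <- stats::runif(n_traj) * 2 * pi
      x <- x + dr * cos(th)
      y <- y + dr * sin(th)
      refl <- x < 0 | x > L | y < 0 | y > L
      while (any(x < 0 | x > L)) { x <- ifelse(x < 0, -x, x); x <- ifelse(x > L, 2 * L - x, x) }
      while (any(y < 0 | y > L)) { y <- ifelse(y < 0, -y, y); y <- ifelse(y > L, 2 * L - y, y) }
      pending_break <- refl
    }
  })
  BRK[, 1] <- TRUE                          # every particle starts a fragment
  # fragment ids: particle-major flattening, row = particle
  brk_vec <- as.vector(t(BRK))              # frames contiguous per particle
  frag <- cumsum(brk_vec)
  tab <- data.frame(
    track_id = sprintf("f%07d", frag),
    frame = rep(seq_len(n_frames), n_traj),
    x = as.vector(t(X)), y = as.vector(t(Y)),
    state = as.vector(t(S)),
    stringsAsFactors = FALSE
  )
  frag_len <- tabulate(frag)
  keep <- frag_len[frag] >= 2L
  dropped <- sum(!keep)
  ts <- traj_set(tab[keep, , drop = FALSE], dt = dt, provenance = "fieldsim")
  attr(ts, "n_positions_total") <- n_traj * n_frames
  attr(ts, "n_positions_dropped") <- dropped
  ts
}

#' Add state-dependent localization error to positions
#'
#' Adds i.i.d. Gaussian noise of per-coordinate standard deviation
#' `eps_um[state]` to every position, using the ground-truth `state`
#' column of the trajectory set. `eps = 0` is the identity.
#'
#' @param ts a [traj_set] with a `state` column.
#' @param eps_um numeric vector of per-state localization s.d. (um),
#'   indexed by state code.
#' @param seed RNG seed.
#' @return a [traj_set] with perturbed coordinates.
#' @export
add_localization_error <- function(ts, eps_um, seed = 1) {
  stopifnot(inherits(ts, "traj_set"))
  if (is.null(ts$tracks$state)) stopf("trajectory set has no ground-truth state column")
  eps_um <- unname(eps_um)
  n <- nrow(ts$tracks)
  sd_vec <- eps_um[ts$tracks$state]
  with_seed(seed, {
    ts$tracks$x <- ts$tracks$x + stats::rnorm(n, 0, sd_vec)
    ts$tracks$y <- ts$tracks$y + stats::rnorm(n, 0, sd_vec)
  })
  ts
}

#' Cut trajectories to mimic tracking interruptions
#'
#' Splits tracks at randomly chosen internal junctions: the part after a
#' cut becomes a new track with a fresh id, shifting the state mix seen at
#' track starts toward faster states (interrupted tracking preferentially
#' re-exposes fast molecules at track starts). Cuts are never placed where
#' the new start would land in the slow state (the slow-state interruption
#' count is assumed zero). Both resulting parts keep at least two
#' positions, so positions are conserved.
#'
#' @param ts a [traj_set] (with a `state` column if slow-state exclusion
#'   is to apply).
#' @param n_cuts number of cuts (0 = identity).
#' @param seed RNG seed.
#' @return a [traj_set] with more, shorter tracks.
#' @export
apply_interruptions <- function(ts, n_cuts, seed = 1) {
  stopifnot(inherits(ts, "traj_set"))
  if (!is_count(n_cuts, 0)) stopf("n_cuts must be a nonnegative integer")
  if (n_cuts == 0) return(ts)
  tr <- ts$tracks
  n <- nrow(tr)
  id <- tr$track_id
  new_track <- c(TRUE, id[-1] != id[-n])
  ordinal <- cumsum(new_track)
  len_of <- tabulate(ordinal)
  pos_in_track <- sequence(len_of)
  # junction after position p (cut between p and p+1): need p >= 2 and
  # p <= len - 2; new start is position p + 1
  eligible <- pos_in_track >= 2 & pos_in_track <= len_of[ordinal] - 2
  if (!is.null(tr$state)) {
    new_start_state <- c(tr$state[-1], NA)
    eligible <- eligible & !is.na(new_start_state) & new_start_state != 3L
  }
  elig_idx <- which(eligible)
  if (n_cuts > length(elig_idx))
    stopf("n_cuts (%d) exceeds the %d eligible junctions", n_cuts, length(elig_idx))
  cuts <- with_seed(seed, {
    chosen <- integer(0)
    pool <- elig_idx
    for (iter in seq_len(100)) {
      need <- n_cuts - length(chosen)
      if (need <= 0 || length(pool) == 0) break
      cand <- sample(pool, min(need, length(pool)))
      all_c <- sort(c(chosen, cand))
      # enforce >= 2 positions between cuts within the same track
      bad <- c(FALSE, ordinal[all_c[-1]] == ordinal[all_c[-length(all_c)]] &
                 diff(all_c) < 2)
      chosen <- all_c[!bad]
      pool <- setdiff(pool, all_c)
    }
    chosen
  })
  if (length(cuts) < n_cuts)
    warnf("apply_interruptions: placed %d of %d requested cuts", length(cuts), n_cuts)
  starts_new <- rep(FALSE, n)
  starts_new[cuts + 1L] <- TRUE
  part <- cumsum(new_track | starts_new)
  tr$track_id <- sprintf("c%07d", part)
  ts$tracks <- tr
  ts
}

#' Solve interruption counts reproducing target initial probabilities
#'
#' Given the state counts `(F, M, S)` at track starts of an uninterrupted
#' simulation and a target initial-state distribution, solves for the
#' numbers of cuts `(f, m)` whose new start falls in the fast and middle
#' states (slow cuts are fixed at zero) such that
#' `p0 = (F + f, M + m, S) / (F + M + S + f + m)`.
#'
#' @param target_p0 target initial probabilities (length 3, sums to 1).
#' @param start_counts integer counts `c(F, M, S)` at uninterrupted track
#'   starts.
#' @return list with `f`, `m`, `total`, and `achieved_p0` after integer
#'   rounding; if the target is infeasible (would need negative cuts),
#'   counts are clamped at zero and the closest achievable distribution is
#'   reported with a warning.
#' @export
match_interruption_counts <- function(target_p0, start_counts) {
  stopifnot(length(target_p0) == 3, length(start_counts) == 3)
  if (abs(sum(target_p0) - 1) > 1e-6) stopf("target_p0 must sum to 1")
  Fc <- start_counts[1]; Mc <- start_counts[2]; Sc <- start_counts[3]
  T0 <- Fc + Mc + Sc
  if (target_p0[3] <= 0) stopf("target slow probability must be positive (s = 0 rule)")
  total_target <- Sc / target_p0[3]        # T0 + f + m
  f <- target_p0[1] * total_target - Fc
  m <- target_p0[2] * total_target - Mc
  f <- max(0, round(f)); m <- max(0, round(m))
  achieved <- c(Fc + f, Mc + m, Sc) / (T0 + f + m)
  if (max(abs(achieved - target_p0)) > 0.02)
    warnf("target initial probabilities not exactly achievable; closest: %s",
          paste(sprintf("%.3f", achieved), collapse = ", "))
  list(f = f, m = m, total = f + m, achieved_p0 = achieved)
}

#' Generate trajectories from a diffusion HMM
#'
#' Spatially unstructured generator used for validation: a Markov state
#' sequence is drawn per track from `(p0, A)`, each step length from the
#' occupied state's Rayleigh law with a uniform direction, and optional
#' state-dependent Gaussian localization noise is added to every position.
#' The `state` column records the ground-truth state governing the step
#' that leaves each frame (the last frame inherits the final step's
#' state).
#'
#' @param model an `spt_hmm` (the generating model).
#' @param n number of tracks.
#' @param len frames per track.
#' @param eps_um optional per-state localization s.d. (um).
#' @param seed RNG seed.
#' @return a [traj_set] with ground truth `state`.
#' @export
simulate_hmm_trajectories <- function(model, n, len, eps_um = NULL, seed = 1) {
  stopifnot(inherits(model, "spt_hmm"))
  if (!is_count(n) || !is_count(len, 2)) stopf("n and len must be positive counts")
  N <- model$n_states
  with_seed(seed, {
    cumA <- t(apply(model$A, 1, cumsum))
    if (N == 1) cumA <- matrix(1, 1, 1)
    st <- matrix(NA_integer_, n, len - 1)    # state of each displacement
    u <- stats::runif(n)
    s <- rowSums(outer(u, cumsum(model$p0), ">")) + 1L
    st[, 1] <- s
    if (len > 2) for (t in 2:(len - 1)) {
      u <- stats::runif(n)
      thr <- cumA[s, , drop = FALSE]
      s <- rowSums(u > thr) + 1L
      s <- pmin(s, N)
      st[, t] <- s
    }
    Dstep <- matrix(model$D[st], n, len - 1)
    dr <- sqrt(-4 * Dstep * model$dt * log(stats::runif(n * (len - 1))))
    th <- stats::runif(n * (len - 1)) * 2 * pi
    dx <- matrix(dr * cos(th), n, len - 1)
    dy <- matrix(dr * sin(th), n, len - 1)
    if (len > 2) for (j in 2:(len - 1)) {   # row-wise cumulative sums
      dx[, j] <- dx[, j - 1] + dx[, j]
      dy[, j] <- dy[, j - 1] + dy[, j]
    }
    X <- cbind(0, dx)
    Y <- cbind(0, dy)
    frame_state <- cbind(st, st[, len - 1])  # last frame inherits last step
    if (!is.null(eps_um)) {
      eps_um <- unname(eps_um)
      sdv <- matrix(eps_um[frame_state], n, len)
      X <- X + stats::rnorm(n * len, 0, sdv)
      Y <- Y + stats::rnorm(n * len, 0, sdv)
    }
    tab <- data.frame(
      track_id = rep(sprintf("h%06d", seq_len(n)), each = len),
      frame = rep(seq_len(len), n),
      x = as.vector(t(X)), y = as.vector(t(Y)),
      state = as.vector(t(frame_state)),
      stringsAsFactors = FALSE
    )
    traj_set(tab, dt = model$dt, provenance = "hmmsim")
  })
}

#' Decoding accuracy against ground truth
#'
#' Fraction of displacement steps whose decoded state matches the
#' ground-truth `state` column carried by the trajectory set.
#'
#' @param paths a `state_paths` from [viterbi()].
#' @param ts the decoded [traj_set] (must carry ground truth `state`).
#' @return accuracy in `[0, 1]`.
#' @export
state_accuracy <- function(paths, ts) {
  ds <- displacements(ts)
  if (is.null(ds$steps$state)) stopf("trajectory set has no ground-truth state column")
  stopifnot(nrow(ds$steps) == nrow(paths$steps))
  mean(paths$steps$state == ds$steps$state)
}

#' State lifetime as a function of clump size
#'
#' For each candidate clump size, builds the field, simulates particles,
#' runs the HMM + dwell-time analysis, and records the fitted lifetime of
#' the corresponding state. Larger clumps take longer to escape, so the
#' curve increases with size; it is the inversion of this curve that fixes
#' clump sizes from measured lifetimes.
#'
#' @param sizes_nm clump side lengths to evaluate (nm).
#' @param kind `"fast"` or `"slow"` -- which clump size is varied.
#' @param base_spec the [field_spec()] providing all other parameters.
#' @param n_traj,n_frames,burn_in,dt simulation scale.
#' @param seed RNG seed.
#' @param hmm_restarts Baum-Welch restarts per size (small by default;
#'   this is a calibration sweep, not a final fit).
#' @return data frame `size_nm`, `tau` (s), `D_S` (um^2/s) for the varied
#'   state.
#' @export
lifetime_vs_size <- function(sizes_nm, kind = c("slow", "fast"), base_spec,
                             n_traj = 1000, n_frames = 100, burn_in = 100,
                             dt = 1 / 30, seed = 1, hmm_restarts = 2) {
  kind <- match.arg(kind)
  state_idx <- if (kind == "fast") 1L else 3L
  out <- data.frame(size_nm = sizes_nm, tau = NA_real_, D_S = NA_real_)
  seeds <- derive_seeds(seed, length(sizes_nm))
  for (i in seq_along(sizes_nm)) {
    spec <- base_spec
    if (kind == "fast") spec$clump_fast_nm <- sizes_nm[i]
    else spec$clump_slow_nm <- sizes_nm[i]
    res <- analyze_sim_field(spec, n_traj, n_frames, burn_in, dt,
                             seed = seeds[i], hmm_restarts = hmm_restarts)
    out$tau[i] <- res$lifetimes$tau[state_idx]
    out$D_S[i] <- res$state_msd$D_S[state_idx]
  }
  out
}

# One simulate-and-analyze cycle on a field spec (internal driver shared
# by the calibration sweeps).
analyze_sim_field <- function(spec, n_traj, n_frames, burn_in, dt, seed,
                              hmm_restarts = 2) {
  map <- build_field(spec, seed = seed)
  ts <- simulate_particles(map, n_traj = n_traj, n_frames = n_frames,
                           burn_in = burn_in, dt = dt, seed = seed + 1L)
  ts <- add_localization_error(ts, spec$eps_um, seed = seed + 2L)
  model <- fit_hmm(ts, N = 3, seed = seed + 3L, n_restarts = hmm_restarts)
  paths <- viterbi(ts, model)
  msd_fit_all <- fit_msd(compute_msd(ts))
  list(
    map = map, ts = ts, model = model, paths = paths,
    D_M = msd_fit_all$D,
    occupancy = occupancy(paths),
    state_msd = state_msd_fit(ts, paths),
    lifetimes = fit_lifetimes(extract_dwells(paths))
  )
}

#' Calibrate field occupancies against measured state summaries
#'
#' Grid search over the occupied percentage areas of the fast and slow
#' clumps (clump sizes held fixed, typically chosen beforehand by
#' inverting [lifetime_vs_size()]): each candidate field is simulated and
#' analyzed, and a weighted mean relative error against the measured
#' targets (whole-set `D_M`, state occupancies `p_S`, lifetimes `tau`) is
#' minimized.
#'
#' @param target list with any of: `D_M` (um^2/s), `p_S` (length-3
#'   occupancy vector), `tau` (length-3 lifetimes, NA allowed).
#' @param base_spec the [field_spec()] holding everything but the
#'   occupancies.
#' @param occupancy_fast_grid,occupancy_slow_grid candidate occupancies
#'   (%).
#' @param n_traj,n_frames,burn_in,dt simulation scale per grid point.
#' @param seed RNG seed.
#' @param weights named weights for the `D_M`, `p_S`, `tau` error terms.
#' @param hmm_restarts Baum-Welch restarts per grid point.
#' @return a `field_calibration` list: `best_spec`, `best_objective`,
#'   `trace` (one row per evaluated grid point, in evaluation order, with
#'   the running best objective in `best_so_far`), `best_metrics`.
#' @export
calibrate_field <- function(target, base_spec,
                            occupancy_fast_grid, occupancy_slow_grid,
                            n_traj = 1000, n_frames = 100, burn_in = 100,
                            dt = 1 / 30, seed = 1,
                            weights = c(D_M = 1, p_S = 1, tau = 1),
                            hmm_restarts = 2) {
  pts <- expand.grid(occupancy_fast = occupancy_fast_grid,
                     occupancy_slow = occupancy_slow_grid)
  trace <- cbind(pts, objective = NA_real_, best_so_far = NA_real_)
  best <- NULL
  seeds <- derive_seeds(seed, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    spec <- base_spec
    spec$occupancy_fast <- pts$occupancy_fast[i]
    spec$occupancy_slow <- pts$occupancy_slow[i]
    res <- tryCatch(
      analyze_sim_field(spec, n_traj, n_frames, burn_in, dt,
                        seed = seeds[i], hmm_restarts = hmm_restarts),
      error = function(e) NULL
    )
    obj <- if (is.null(res)) Inf else {
      terms <- c()
      if (!is.null(target$D_M))
        terms <- c(terms, weights[["D_M"]] * abs(res$D_M - target$D_M) / target$D_M)
      if (!is.null(target$p_S))
        terms <- c(terms, weights[["p_S"]] * mean(abs(res$occupancy - target$p_S)))
      if (!is.null(target$tau)) {
        ok <- is.finite(target$tau) & is.finite(res$lifetimes$tau)
        if (any(ok))
          terms <- c(terms, weights[["tau"]] *
                       mean(abs(res$lifetimes$tau[ok] - target$tau[ok]) / target$tau[ok]))
      }
      if (length(terms) == 0) stopf("no usable targets supplied")
      mean(terms)
    }
    trace$objective[i] <- obj
    if (is.null(best) || obj < best$objective)
      best <- list(spec = spec, objective = obj, metrics = res)
    trace$best_so_far[i] <- best$objective
  }
  if (!is.finite(best$objective))
    warnf("calibrate_field: no grid point produced a finite objective")
  structure(
    list(best_spec = best$spec, best_objective = best$objective,
         trace = trace, best_metrics = best$metrics),
    class = "field_calibration"
  )
}
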