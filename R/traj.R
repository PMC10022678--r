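#' Trajectory set
#'
#' Container for 2-D single-molecule trajectories sharing one frame
#' interval. Positions are stored in a single long-format data frame with
#' columns `track_id`, `frame`, `x`, `y` (micrometres) and optionally
#' `state` (ground-truth or decoded mobility state, integer).
#'
#' Invariants enforced at construction: every track has at least two
#' positions, frames within a track increase in unit steps (tracking was
#' done with no gap closing, so a gap means a broken track and is an
#' error), and all coordinates are finite.
#'
#' @param tracks data frame with columns `track_id`, `frame`, `x`, `y`
#'   and optionally `state`.
#' @param dt frame interval in seconds.
#' @param provenance free-text label describing the data source.
#' @return an object of class `traj_set`.
#' @export
traj_set <- function(tracks, dt, provenance = "") {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stopf("tracks is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stopf("dt must be a single positive number (seconds)")
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  validate_tracks(tracks)
  structure(
    list(tracks = tracks, dt = dt, provenance = provenance),
    class = "traj_set"
  )
}

validate_tracks <- function(tracks) {
  if (nrow(tracks) == 0) return(invisible(TRUE))
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y)))
    stopf("non-finite coordinates in trajectory table")
  id <- tracks$track_id
  frame <- tracks$frame
  n <- length(id)
  same <- id[-1] == id[-n]
  dframe <- frame[-1] - frame[-n]
  bad_gap <- same & dframe != 1L
  if (any(bad_gap)) {
    stopf("track '%s' has a frame gap or non-monotonic frames (no gap closing allowed)",
          id[which(bad_gap)[1]])
  }
  len <- tabulate(factor(id, levels = unique(id)))
  if (any(len < 2))
    stopf("track '%s' has fewer than 2 positions", unique(id)[which(len < 2)[1]])
  invisible(TRUE)
}

#' @export
print.traj_set <- function(x, ...) {
  nt <- n_tracks(x)
  cat(sprintf("traj_set: %d tracks, %d positions, dt = %.4g s", nt,
              nrow(x$tracks), x$dt))
  if (nzchar(x$provenance)) cat(sprintf(" [%s]", x$provenance))
  cat("\n")
  if (nt > 0) {
    len <- track_lengths(x)
    cat(sprintf("  track length: min %d, median %g, max %d frames\n",
                min(len), stats::median(len), max(len)))
  }
  invisible(x)
}

#' Number of tracks in a trajectory set
#' @param ts a `traj_set`.
#' @export
n_tracks <- function(ts) length(unique(ts$tracks$track_id))

#' Track lengths (positions per track)
#' @param ts a `traj_set`.
#' @return named integer vector of positions per track.
#' @export
track_lengths <- function(ts) {
  id <- ts$tracks$track_id
  tab <- tabulate(factor(id, levels = unique(id)))
  names(tab) <- unique(id)
  tab
}

#' Read a TrackMate-style CSV export
#'
#' Parses the spot table exported by TrackMate (or any CSV with per-spot
#' track id, frame and position columns) into a [traj_set]. TrackMate
#' exports positions either in pixels or in calibrated physical units;
#' `units = "px"` multiplies coordinates by `pixel_size_um`.
#'
#' Tracks whose frames are not consecutive raise an error naming the
#' track: the upstream linking is expected to run with no gap closing, so
#' a gap indicates a corrupt export.
#'
#' @param path CSV file path.
#' @param dt_s frame interval in seconds.
#' @param pixel_size_um pixel size in micrometres (required when
#'   `units = "px"`).
#' @param units `"um"` (already calibrated) or `"px"`.
#' @param cols named character vector mapping the roles `track`, `frame`,
#'   `x`, `y` to column names in the file.
#' @return a [traj_set].
#' @export
read_trackmate_csv <- function(path, dt_s, pixel_size_um = NULL,
                               units = c("um", "px"),
                               cols = c(track = "TRACK_ID", frame = "FRAME",
                                        x = "POSITION_X", y = "POSITION_Y")) {
  units <- match.arg(units)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  # TrackMate puts up to three header-ish rows below the column names; keep
  # only rows where the frame column parses as a number.
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stopf("file '%s' lacks required column(s): %s", path, paste(miss, collapse = ", "))
  fr <- suppressWarnings(as.numeric(raw[[cols[["frame"]]]]))
  raw <- raw[!is.na(fr), , drop = FALSE]
  tracks <- data.frame(
    track_id = as.character(raw[[cols[["track"]]]]),
    frame = as.integer(as.numeric(raw[[cols[["frame"]]]])),
    x = as.numeric(raw[[cols[["x"]]]]),
    y = as.numeric(raw[[cols[["y"]]]]),
    stringsAsFactors = FALSE
  )
  if (units == "px") {
    if (is.null(pixel_size_um))
      stopf("pixel_size_um is required when units = 'px'")
    tracks$x <- tracks$x * pixel_size_um
    tracks$y <- tracks$y * pixel_size_um
  }
  traj_set(tracks, dt = dt_s, provenance = basename(path))
}

#' Drop tracks shorter than a minimum duration
#'
#' Retains tracks with at least `min_frames` positions. The default of 3
#' positions (hence at least 2 displacements) mirrors the track-duration
#' filter applied at the tracking stage.
#'
#' @param ts a [traj_set].
#' @param min_frames minimum number of positions (>= 2).
#' @param quiet suppress the message reporting how many tracks were removed.
#' @return a filtered [traj_set].
#' @export
filter_min_duration <- function(ts, min_frames = 3, quiet = FALSE) {
  stopifnot(inherits(ts, "traj_set"))
  if (!is_count(min_frames, min = 2)) stopf("min_frames must be an integer >= 2")
  len <- track_lengths(ts)
  keep_ids <- names(len)[len >= min_frames]
  removed <- length(len) - length(keep_ids)
  if (!quiet && removed > 0)
    message(sprintf("filter_min_duration: removed %d of %d tracks (< %d frames)",
                    removed, length(len), min_frames))
  ts$tracks <- ts$tracks[ts$tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(ts$tracks) <- NULL
  ts
}

#' Per-step displacements
#'
#' Extracts the Euclidean step length between consecutive frames of every
#' track, pooled over the whole set with track/frame provenance. The step
#' leaving frame `f` is recorded at `frame = f`; if the trajectory table
#' carries a `state` column, each displacement inherits the state of its
#' starting frame.
#'
#' @param ts a [traj_set].
#' @return a `disp_set`: data frame `steps` with columns `track_id`,
#'   `frame`, `dr` (micrometres) and optionally `state`, plus the common `dt`.
#' @export
displacements <- function(ts) {
  stopifnot(inherits(ts, "traj_set"))
  tr <- ts$tracks
  if (nrow(tr) == 0) stopf("empty trajectory set")
  n <- nrow(tr)
  same <- tr$track_id[-1] == tr$track_id[-n]
  dx <- tr$x[-1] - tr$x[-n]
  dy <- tr$y[-1] - tr$y[-n]
  steps <- data.frame(
    track_id = tr$track_id[-n][same],
    frame = tr$frame[-n][same],
    dr = sqrt(dx[same]^2 + dy[same]^2),
    stringsAsFactors = FALSE
  )
  if (!is.null(tr$state)) steps$state <- tr$state[-n][same]
  structure(list(steps = steps, dt = ts$dt), class = "disp_set")
}

#' @export
print.disp_set <- function(x, ...) {
  cat(sprintf("disp_set: %d displacements, dt = %.4g s\n", nrow(x$steps), x$dt))
  if (nrow(x$steps) > 0)
    cat(sprintf("  |dr| (um): median %.4g, max %.4g\n",
                stats::median(x$steps$dr), max(x$steps$dr)))
  invisible(x)
}

#' Write / read the internal trajectory format
#'
#' The internal format is a plain CSV (`track_id, frame, x_um, y_um[,
#' state]`) with a JSON sidecar `<path>.json` holding `dt` and the
#' provenance label, so that a round trip is lossless.
#'
#' @param ts a [traj_set].
#' @param path CSV path to write.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a [traj_set].
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "traj_set"))
  out <- ts$tracks
  names(out)[names(out) == "x"] <- "x_um"
  names(out)[names(out) == "y"] <- "y_um"
  # %.17g keeps doubles exact through the text round trip
  out$x_um <- sprintf("%.17g", out$x_um)
  out$y_um <- sprintf("%.17g", out$y_um)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(dt = ts$dt, provenance = ts$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "x_um"] <- "x"
  names(tab)[names(tab) == "y_um"] <- "y"
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stopf("sidecar metadata '%s' not found", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  traj_set(tab, dt = meta$dt, provenance = meta$provenance %||% "")
}
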