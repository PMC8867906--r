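## Drift-corrected mean-squared displacement and effective diffusion
## coefficient from particle-tracking trajectories.

#' Particle trajectory set
#'
#' @param tracks data.frame with columns `frame`, `id`, `x`, `y` (frames
#'   strictly increasing within each id), or a list of per-particle
#'   data.frames with `frame`, `x`, `y`.
#' @param frame_interval seconds per frame (default 1/15 s, a 15 fps camera).
#' @return object of class `track_set` storing the long-format data.frame.
#' @export
track_set <- function(tracks, frame_interval = 1 / 15) {
  if (frame_interval <= 0) stop("track_set(): frame_interval must be positive")
  if (is.list(tracks) && !is.data.frame(tracks)) {
    tracks <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      d <- tracks[[i]]
      data.frame(frame = d$frame, id = i, x = d$x, y = d$y)
    }))
  }
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(tracks)))
    stop("track_set(): tracks must have columns frame, id, x, y")
  tracks <- tracks[order(tracks$id, tracks$frame), need]
  bad <- tapply(tracks$frame, tracks$id, function(f) any(diff(f) <= 0))
  if (any(unlist(bad)))
    stop("track_set(): frames must be strictly increasing within each track")
  ts <- list(tracks = tracks, frame_interval = frame_interval)
  class(ts) <- "track_set"
  ts
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d points, frame interval %.4g s\n",
              length(unique(x$tracks$id)), nrow(x$tracks), x$frame_interval))
  invisible(x)
}

#' Remove collective drift from trajectories
#'
#' Estimates, for every consecutive frame pair, the ensemble mean (or median)
#' displacement of all particles present in both frames and subtracts the
#' accumulated drift from every position -- removing stage drift exactly while
#' leaving relative positions untouched.  Frames with fewer than two common
#' particles inherit the neighbouring drift estimate (zero increment), with a
#' warning.
#'
#' @param ts a [track_set()].
#' @param estimator `"mean"` (default) or the outlier-robust `"median"`.
#' @return drift-corrected [track_set()].
#' @export
drift_correct <- function(ts, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  frames <- sort(unique(tr$frame))
  if (length(frames) < 2) return(ts)
  est <- if (estimator == "mean") mean else stats::median
  ddx <- numeric(length(frames)); ddy <- numeric(length(frames))
  warned <- FALSE
  by_frame <- split(tr[, c("id", "x", "y")], tr$frame)
  for (k in 2:length(frames)) {
    a <- by_frame[[as.character(frames[k - 1])]]
    b <- by_frame[[as.character(frames[k])]]
    common <- intersect(a$id, b$id)
    if (length(common) < 1) {
      warned <- TRUE        # carry drift over: zero increment
      next
    }
    if (length(common) < 2) warned <- TRUE
    ia <- match(common, a$id); ib <- match(common, b$id)
    ddx[k] <- est(b$x[ib] - a$x[ia])
    ddy[k] <- est(b$y[ib] - a$y[ia])
  }
  if (warned)
    warning("drift_correct(): frames with < 2 shared particles; drift carried over")
  drift_x <- cumsum(ddx); drift_y <- cumsum(ddy)
  idx <- match(tr$frame, frames)
  tr$x <- tr$x - drift_x[idx]
  tr$y <- tr$y - drift_y[idx]
  out <- ts
  out$tracks <- tr
  out
}

#' Time- and ensemble-averaged mean-squared displacement
#'
#' `MSD(dt) = < (r_i(t0 + dt) - r_i(t0))^2 >_{t0, i}` averaged over all valid
#' origin/particle pairs, at every integer frame lag up to `max_lag`.
#'
#' @param ts a [track_set()].
#' @param max_lag largest lag in frames; default one quarter of the longest
#'   track (variance control at long lags).
#' @return object of class `msd_curve`: `lag_frames`, `lag_times` (s), `msd`,
#'   `n_pairs`.
#' @export
msd <- function(ts, max_lag = NULL) {
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  by_id <- split(tr[, c("frame", "x", "y")], tr$id)
  longest <- max(vapply(by_id, nrow, integer(1)))
  if (is.null(max_lag)) max_lag <- max(1L, longest %/% 4L)
  if (max_lag >= longest)
    stop("msd(): max_lag must be smaller than the longest track")
  sums <- numeric(max_lag); npairs <- integer(max_lag)
  for (d in by_id) {
    # frames may be irregular; index displacements by frame difference
    nf <- nrow(d)
    if (nf < 2) next
    for (i in seq_len(nf - 1)) {
      lag <- d$frame[(i + 1):nf] - d$frame[i]
      keep <- lag >= 1 & lag <= max_lag
      if (!any(keep)) next
      j <- which(keep) + i
      dr2 <- (d$x[j] - d$x[i])^2 + (d$y[j] - d$y[i])^2
      l <- lag[keep]
      sums[l] <- sums[l] + dr2
      npairs[l] <- npairs[l] + 1L
    }
  }
  lag_frames <- seq_len(max_lag)
  msd_vals <- ifelse(npairs > 0, sums / pmax(npairs, 1L), NA_real_)
  curve <- list(lag_frames = lag_frames,
                lag_times = lag_frames * ts$frame_interval,
                msd = msd_vals, n_pairs = npairs,
                frame_interval = ts$frame_interval)
  class(curve) <- "msd_curve"
  curve
}

#' @export
print.msd_curve <- function(x, ...) {
  ok <- which(x$n_pairs > 0)
  cat(sprintf("msd_curve: %d lags up to %.4g s; MSD(last) = %.4g\n",
              length(ok), max(x$lag_times[ok]), x$msd[ok[length(ok)]]))
  invisible(x)
}

#' Effective diffusion coefficient at a reference lag
#'
#' `D_eff = MSD(dt ~ t_ref) / (4 t_ref)`, read off at the available lag
#' closest to `t_ref` (default 55 s).
#'
#' @param curve an [msd_curve()].
#' @param t_ref reference lag time in seconds.
#' @return list with `D_eff`, the `lag_used` (s) and its offset from `t_ref`.
#' @export
effective_diffusion <- function(curve, t_ref = 55) {
  stopifnot(inherits(curve, "msd_curve"))
  ok <- which(curve$n_pairs > 0)
  if (!length(ok)) stop("effective_diffusion(): empty MSD curve")
  tmin <- min(curve$lag_times[ok]); tmax <- max(curve$lag_times[ok])
  if (t_ref < tmin - curve$frame_interval / 2 ||
      t_ref > tmax + curve$frame_interval / 2)
    stop(sprintf(
      "effective_diffusion(): t_ref = %g s outside the lag range [%g, %g] s",
      t_ref, tmin, tmax))
  i <- ok[which.min(abs(curve$lag_times[ok] - t_ref))]
  lag_used <- curve$lag_times[i]
  list(D_eff = curve$msd[i] / (4 * lag_used),
       lag_used = lag_used, offset = lag_used - t_ref)
}
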