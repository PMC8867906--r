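## Seed-deterministic generators for reference structures and trajectories:
## hexagonal crystals, Poisson fluids, chainlike aggregates and 2D Brownian
## tracks with optional stage drift.

#' Triangular (hexagonal) lattice configuration
#'
#' Fills the box with a triangular lattice of the requested spacing.  To keep
#' the lattice periodic across the box boundaries, the spacing is adjusted to
#' the nearest commensurate value (with a warning when the adjustment exceeds
#' 2 %).  The reference structure with psi6 = 1 and g(r) peak ratios
#' 1 : sqrt(3) : 2.
#'
#' @param spacing target nearest-neighbour distance.
#' @param box side lengths `c(Lx, Ly)`; a scalar gives a square box.
#' @return periodic [configuration2d()].
#' @export
gen_hexagonal <- function(spacing, box) {
  if (spacing <= 0) stop("gen_hexagonal(): spacing must be positive")
  if (length(box) == 1) box <- c(box, box)
  nx <- round(box[1] / spacing)
  ny <- round(box[2] / (spacing * sqrt(3) / 2))
  if (nx < 1 || ny < 1)
    stop("gen_hexagonal(): box too small for one lattice cell")
  if (ny %% 2 == 1) ny <- ny + 1   # even row count keeps the wrap periodic
  ax <- box[1] / nx
  ay <- box[2] / ny
  if (abs(ax - spacing) / spacing > 0.02 ||
      abs(ay - spacing * sqrt(3) / 2) / (spacing * sqrt(3) / 2) > 0.02)
    warning("gen_hexagonal(): spacing adjusted to fit the box periodically")
  pts <- matrix(NA_real_, nx * ny, 2)
  k <- 0L
  for (j in seq_len(ny) - 1L) {
    offs <- if (j %% 2 == 1) ax / 2 else 0
    for (i in seq_len(nx) - 1L) {
      k <- k + 1L
      pts[k, ] <- c((i * ax + offs) %% box[1], j * ay)
    }
  }
  configuration2d(pts, box, periodic = TRUE)
}

#' Square lattice configuration
#'
#' Periodic square lattice; the four-fold reference for which every particle's
#' six-fold order parameter vanishes.
#'
#' @inheritParams gen_hexagonal
#' @return periodic [configuration2d()].
#' @export
gen_square <- function(spacing, box) {
  if (spacing <= 0) stop("gen_square(): spacing must be positive")
  if (length(box) == 1) box <- c(box, box)
  nx <- max(1, round(box[1] / spacing)); ny <- max(1, round(box[2] / spacing))
  pts <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * box[1] / nx,
                               y = (seq_len(ny) - 1) * box[2] / ny))
  configuration2d(pts, box, periodic = TRUE)
}

#' Homogeneous Poisson (ideal-gas) configuration
#'
#' Uniform independent points: the structureless reference with g(r) = 1 and
#' low psi6.
#'
#' @param n number of points.
#' @param box side lengths.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return periodic [configuration2d()].
#' @export
gen_poisson <- function(n, box, seed = NULL) {
  if (n < 1) stop("gen_poisson(): n must be >= 1")
  if (length(box) == 1) box <- c(box, box)
  if (!is.null(seed)) set.seed(seed)
  pts <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]))
  configuration2d(pts, box, periodic = TRUE)
}

#' Chainlike aggregate configuration
#'
#' Self-avoiding strings of touching particles at the bond distance plus a
#' fraction of isolated singles, emulating the stringlike morphology of a
#' weakly aggregated fluid: interior chain particles have two neighbours, the
#' chain-length distribution is broad (geometric), and the mean coordination
#' approaches 2 for long chains.
#'
#' @param n_chains number of chains.
#' @param mean_length mean chain length (geometric distribution, min 2).
#' @param singles_frac additional isolated particles as a fraction of the
#'   chained particle count.
#' @param bond_distance distance between bonded neighbours.
#' @param box side lengths.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param max_turn maximum bond-angle change along a chain, radians
#'   (default 30 degrees: gently curved strings).
#' @return periodic [configuration2d()].
#' @export
gen_chains <- function(n_chains, mean_length = 5, singles_frac = 0.2,
                       bond_distance = 1, box = c(20, 20), seed = NULL,
                       max_turn = pi / 6) {
  if (length(box) == 1) box <- c(box, box)
  if (!is.null(seed)) set.seed(seed)
  lengths <- 2 + stats::rgeom(n_chains, prob = 1 / max(mean_length - 1, 1))
  pts <- matrix(NA_real_, 0, 2)
  # non-bonded pairs are kept clearly beyond the bond distance so bonded
  # contacts are unambiguous
  min_sep <- 1.1 * bond_distance
  place_ok <- function(cand, exclude_last = 0) {
    if (nrow(pts) == 0) return(TRUE)
    keep <- seq_len(max(0, nrow(pts) - exclude_last))
    if (!length(keep)) return(TRUE)
    dx <- abs(pts[keep, 1] - cand[1]); dy <- abs(pts[keep, 2] - cand[2])
    dx <- pmin(dx, box[1] - dx); dy <- pmin(dy, box[2] - dy)
    all(dx^2 + dy^2 >= min_sep^2)
  }
  for (len in lengths) {
    placed <- FALSE
    for (try in 1:500) {
      start <- stats::runif(2) * box
      if (!place_ok(start)) next
      ang <- stats::runif(1, 0, 2 * pi)
      chain <- matrix(start, 1, 2)
      ok <- TRUE
      while (nrow(chain) < len) {
        ang <- ang + stats::runif(1, -max_turn, max_turn)
        cand <- (chain[nrow(chain), ] +
                   bond_distance * c(cos(ang), sin(ang))) %% box
        # bonded predecessor sits exactly at the bond distance; check others
        prev <- chain[nrow(chain), ]
        pts_tmp <- rbind(pts, chain[-nrow(chain), , drop = FALSE])
        dxx <- abs(pts_tmp[, 1] - cand[1]); dyy <- abs(pts_tmp[, 2] - cand[2])
        if (nrow(pts_tmp)) {
          dxx <- pmin(dxx, box[1] - dxx); dyy <- pmin(dyy, box[2] - dyy)
          if (any(dxx^2 + dyy^2 < min_sep^2)) { ok <- FALSE; break }
        }
        chain <- rbind(chain, cand)
      }
      if (ok) {
        pts <- rbind(pts, chain)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("gen_chains(): placement failed; reduce n_chains or chain length")
  }
  n_singles <- round(singles_frac * nrow(pts))
  for (s in seq_len(n_singles)) {
    for (try in 1:200) {
      cand <- stats::runif(2) * box
      if (place_ok(cand)) { pts <- rbind(pts, cand); break }
    }
  }
  configuration2d(pts, box, periodic = TRUE)
}

#' Brownian trajectories with optional stage drift
#'
#' Independent 2D Gaussian random walks with per-step variance
#' `2 * D * frame_interval` per axis, plus an optional uniform drift
#' velocity (linear stage drift).
#'
#' @param n number of particles.
#' @param D diffusion coefficient (length^2 / s); `D = 0` gives stationary
#'   tracks.
#' @param n_frames frames per track.
#' @param frame_interval seconds between frames.
#' @param drift drift velocity `c(vx, vy)` (length / s).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a [track_set()].
#' @export
gen_brownian_tracks <- function(n, D, n_frames, frame_interval = 1 / 15,
                                drift = c(0, 0), seed = NULL) {
  if (D < 0) stop("gen_brownian_tracks(): D must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * frame_interval)
  tracks <- lapply(seq_len(n), function(i) {
    x0 <- stats::runif(2, 0, 100)
    steps_x <- stats::rnorm(n_frames - 1, drift[1] * frame_interval, sd_step)
    steps_y <- stats::rnorm(n_frames - 1, drift[2] * frame_interval, sd_step)
    data.frame(frame = seq_len(n_frames), id = i,
               x = x0[1] + c(0, cumsum(steps_x)),
               y = x0[2] + c(0, cumsum(steps_y)))
  })
  track_set(do.call(rbind, tracks), frame_interval = frame_interval)
}
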