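## 2D Metropolis Monte Carlo of disks with competing short-range attraction
## (blunt-end stacking) and Yukawa repulsion.  Lengths in sigma0 units,
## energies in k_B*T.

#' Pair-potential parameters for the competing-interaction disks
#'
#' The interaction is a steep 100-200 Lennard-Jones term -- near-hard disks of
#' diameter `sigma` followed by a short attractive well of strength set by
#' `V1` -- plus a repulsive Yukawa tail `V2 * exp(-r/lambda)/(r/lambda)`
#' modelling the residual electrostatics of nearly neutralized brushes.  The
#' potential is truncated (not shifted) at `r_c`.  Defaults are the
#' representative parameter set `V1 = 1.43 kT`, `V2 = 0.28 kT`,
#' `lambda = 1.5 sigma0`, `r_c = 3.5 sigma`.
#'
#' @param sigma steric disk diameter (shrinks with packing).
#' @param sigma0 dilute-limit diameter; the unit of length.
#' @param V1 attraction strength, k_B*T.
#' @param V2 Yukawa repulsion strength, k_B*T.
#' @param lambda Yukawa screening length.
#' @param r_c cutoff radius.
#' @param lj_convention `"4v1"` for `4*V1*[(sigma/r)^200 - (sigma/r)^100]`
#'   (default; zero crossing at `r = sigma`) or `"well"` for
#'   `V1*[(sigma/r)^200 - 2*(sigma/r)^100]` (well depth exactly `V1`).
#' @return An object of class `pair_potential_params`.
#' @export
pair_potential_params <- function(sigma = 1, sigma0 = 1, V1 = 1.43, V2 = 0.28,
                                  lambda = 1.5 * sigma0, r_c = 3.5 * sigma,
                                  lj_convention = c("4v1", "well")) {
  lj_convention <- match.arg(lj_convention)
  vals <- c(sigma = sigma, sigma0 = sigma0, V1 = V1, V2 = V2,
            lambda = lambda, r_c = r_c)
  if (any(vals < 0) || sigma <= 0 || sigma0 <= 0 || lambda <= 0)
    stop("pair_potential_params(): parameters must be positive")
  if (sigma > sigma0 * (1 + 1e-12))
    stop("pair_potential_params(): sigma cannot exceed sigma0")
  if (r_c <= sigma)
    stop("pair_potential_params(): r_c must exceed sigma")
  p <- list(sigma = sigma, sigma0 = sigma0, V1 = V1, V2 = V2,
            lambda = lambda, r_c = r_c, lj_convention = lj_convention)
  class(p) <- "pair_potential_params"
  p
}

#' Evaluate the pair potential
#'
#' @param r separation(s), same units as `sigma`; must be > 0.
#' @param p a [pair_potential_params()].
#' @return potential in k_B*T; exactly 0 for `r >= r_c`.
#' @export
pair_potential <- function(r, p) {
  stopifnot(inherits(p, "pair_potential_params"))
  if (any(r <= 0)) stop("pair_potential(): separations must be positive")
  conv <- if (p$lj_convention == "4v1") 0L else 1L
  pair_potential_cpp(as.numeric(r), p$sigma, p$V1, p$V2, p$lambda, p$r_c, conv)
}

#' Periodic 2D particle configuration
#'
#' @param positions N x 2 matrix of coordinates.
#' @param box side lengths `c(Lx, Ly)`.
#' @param periodic logical; periodic coordinates are wrapped into `[0, L)`.
#' @return An object of class `configuration2d`.
#' @export
configuration2d <- function(positions, box, periodic = TRUE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("configuration2d(): positions must be N x 2")
  if (any(!is.finite(positions))) stop("configuration2d(): non-finite coordinates")
  if (length(box) == 1) box <- c(box, box)
  if (any(box <= 0)) stop("configuration2d(): box sides must be positive")
  if (periodic) positions <- sweep(positions, 2, box, function(x, L) x %% L)
  if (nrow(positions) > 1 && anyDuplicated(positions))
    stop("configuration2d(): duplicated particle coordinates")
  cfg <- list(positions = positions, box = as.numeric(box), periodic = periodic)
  class(cfg) <- "configuration2d"
  cfg
}

#' @export
print.configuration2d <- function(x, ...) {
  cat(sprintf("configuration2d: %d particles in %.4g x %.4g box (%s)\n",
              nrow(x$positions), x$box[1], x$box[2],
              if (x$periodic) "periodic" else "open"))
  invisible(x)
}

#' Total interaction energy of a configuration
#'
#' Sum of [pair_potential()] over all pairs within the cutoff, with the
#' minimum-image convention for periodic boxes.
#'
#' @param cfg a [configuration2d()].
#' @param p a [pair_potential_params()].
#' @return energy in k_B*T.
#' @export
total_energy <- function(cfg, p) {
  stopifnot(inherits(cfg, "configuration2d"), inherits(p, "pair_potential_params"))
  conv <- if (p$lj_convention == "4v1") 0L else 1L
  total_energy_cpp(cfg$positions, cfg$box[1], cfg$box[2], cfg$periodic,
                   p$sigma, p$V1, p$V2, p$lambda, p$r_c, conv)
}

#' Run Metropolis sweeps
#'
#' Performs `n_sweeps` sweeps of N single-particle trial moves, each accepted
#' with probability `min(1, exp(-dE))`.  The trajectory is fully determined by
#' the R RNG state (`set.seed()` before calling).  Energies are tracked
#' incrementally; see the test suite for the bookkeeping cross-check.
#'
#' @param cfg a periodic [configuration2d()].
#' @param p a [pair_potential_params()].
#' @param n_sweeps number of sweeps.
#' @param max_disp trial displacement amplitude (moves are uniform in
#'   `[-max_disp, max_disp]` per axis).
#' @param tune auto-tune `max_disp` toward 30-50 % acceptance during the
#'   first `tune_until` sweeps, then freeze.
#' @param tune_until sweep index up to which tuning is allowed.
#' @param sample_every store a snapshot every this many sweeps (0 = none).
#' @return A list: final `configuration`, per-sweep `energy` and `acceptance`
#'   vectors, `snapshots` (list of [configuration2d()]), `snapshot_sweeps`
#'   and the final `max_disp`.
#' @export
metropolis_sweep <- function(cfg, p, n_sweeps = 1, max_disp = 0.1 * p$sigma,
                             tune = FALSE, tune_until = n_sweeps,
                             sample_every = 0) {
  stopifnot(inherits(cfg, "configuration2d"), inherits(p, "pair_potential_params"))
  if (!cfg$periodic)
    stop("metropolis_sweep(): simulation configurations must be periodic")
  conv <- if (p$lj_convention == "4v1") 0L else 1L
  out <- mc_run_cpp(cfg$positions, cfg$box[1], cfg$box[2],
                    p$sigma, p$V1, p$V2, p$lambda, p$r_c, conv,
                    as.integer(n_sweeps), max_disp,
                    tune, as.integer(tune_until), as.integer(sample_every))
  snaps <- lapply(out$snapshots, configuration2d, box = cfg$box, periodic = TRUE)
  list(configuration = configuration2d(out$positions, cfg$box, periodic = TRUE),
       energy = out$energy, acceptance = out$acceptance,
       snapshots = snaps, snapshot_sweeps = out$snapshot_sweeps,
       max_disp = out$max_disp)
}

#' Packing fraction of disks in a box
#'
#' `eta = (N / (Lx * Ly)) * pi * sigma0^2 / 4`, the area fraction computed
#' with the dilute-limit diameter.
#'
#' @param N particle count.
#' @param sigma0 dilute diameter.
#' @param box side lengths `c(Lx, Ly)`.
#' @return packing fraction.
#' @export
packing_fraction <- function(N, sigma0, box) {
  if (length(box) == 1) box <- c(box, box)
  A <- box[1] * box[2]
  if (A <= 0) stop("packing_fraction(): box area must be positive")
  if (N < 0 || sigma0 <= 0) stop("packing_fraction(): invalid N or sigma0")
  (N / A) * pi * sigma0^2 / 4
}

#' Measured diameter-shrinking trend
#'
#' Approximate experimental steric diameters sigma/sigma0 at the canonical
#' state points, read from the reported first-peak positions r_p of the
#' measured g(r) (shortest interparticle distance; values between 1.05 and
#' 0.70 sigma0 with the minimum at eta = 0.73).  This is the diameter table
#' the simulations use by default -- the simulated size reduction follows the
#' measured one, the cell model's relative curve being available through
#' [sigma_of_eta()] as an alternative.
#'
#' @return data.frame with columns `eta` and `sigma` (in sigma0 units).
#' @export
experimental_sigma_table <- function() {
  data.frame(eta = c(0.40, 0.57, 0.68, 0.73, 0.87, 1.17),
             sigma = c(0.88, 0.89, 0.82, 0.70, 0.73, 0.78))
}

#' Canonical simulated state points
#'
#' The six packing fractions studied in a 20 x 20 sigma0 box with their
#' particle counts and full-length sweep numbers.
#'
#' @return data.frame with columns `eta`, `N`, `n_steps`.
#' @export
paper_state_points <- function() {
  data.frame(eta = c(0.40, 0.57, 0.68, 0.73, 0.87, 1.17),
             N = c(196L, 289L, 342L, 380L, 441L, 600L),
             n_steps = c(1e5, 1e5, 1e6, 1e6, 1e6, 2e6))
}

#' Simulation run configuration
#'
#' @param box side lengths in sigma0 units (default 20 x 20).
#' @param N particle count; if `NULL`, derived from `eta` at run time.
#' @param n_steps MC sweeps; if `NULL`, the per-state-point default is used.
#' @param seed RNG seed applied before the run (`NULL` = leave RNG alone).
#' @param max_disp initial trial displacement; auto-tuned during
#'   equilibration.
#' @param sample_every production snapshot interval in sweeps.
#' @param equilibration_fraction fraction of the run discarded before
#'   sampling (default 0.3, within the 0.2-0.5 equilibration window).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(box = c(20, 20), N = NULL, n_steps = NULL, seed = NULL,
                       max_disp = NULL, sample_every = NULL,
                       equilibration_fraction = 0.3) {
  if (length(box) == 1) box <- c(box, box)
  if (any(box <= 0)) stop("sim_config(): box sides must be positive")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("sim_config(): equilibration_fraction must be in [0, 1)")
  cfg <- list(box = box, N = N, n_steps = n_steps, seed = seed,
              max_disp = max_disp, sample_every = sample_every,
              equilibration_fraction = equilibration_fraction)
  class(cfg) <- "sim_config"
  cfg
}

# initial placement: random sequential insertion with overlap rejection,
# falling back (or jumping directly, at high packing) to a diluted
# triangular lattice
.init_positions <- function(N, box, sigma, eta) {
  if (eta <= 0.8) {
    pos <- matrix(NA_real_, N, 2)
    placed <- 0L
    for (attempt in seq_len(400 * N)) {
      cand <- stats::runif(2) * box
      ok <- TRUE
      if (placed > 0) {
        dx <- abs(pos[seq_len(placed), 1] - cand[1])
        dy <- abs(pos[seq_len(placed), 2] - cand[2])
        dx <- pmin(dx, box[1] - dx); dy <- pmin(dy, box[2] - dy)
        ok <- all(dx * dx + dy * dy >= (0.95 * sigma)^2)
      }
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
        if (placed == N) return(pos)
      }
    }
    # fall through to lattice if insertion stalls
  }
  lat <- .triangular_lattice_points(box, spacing = NULL, n_min = N)
  if (nrow(lat) < N)
    stop(".init_positions(): cannot place ", N, " particles; box too small")
  lat[sample.int(nrow(lat), N), , drop = FALSE]
}

# triangular lattice covering the box with at least n_min sites (spacing
# chosen from the site density unless given); rows jittered to fit the box
.triangular_lattice_points <- function(box, spacing = NULL, n_min = NULL) {
  if (is.null(spacing)) {
    # site density of a triangular lattice: 2/(sqrt(3) a^2)
    a <- sqrt(2 * box[1] * box[2] / (sqrt(3) * n_min))
    nx <- ceiling(box[1] / a); ny <- ceiling(box[2] / (a * sqrt(3) / 2))
    # stretch to fill exactly
  } else {
    a <- spacing
    nx <- max(1, round(box[1] / a)); ny <- max(1, round(box[2] / (a * sqrt(3) / 2)))
  }
  ax <- box[1] / nx; ay <- box[2] / ny
  pts <- matrix(NA_real_, nx * ny, 2)
  k <- 0L
  for (j in seq_len(ny) - 1L) {
    offs <- if (j %% 2 == 1) ax / 2 else 0
    for (i in seq_len(nx) - 1L) {
      k <- k + 1L
      pts[k, ] <- c((i * ax + offs) %% box[1], j * ay)
    }
  }
  pts
}

#' Simulate one packing-fraction state point
#'
#' Sets the particle count from the canonical state-point table (or from the
#' packing-fraction formula for non-tabulated eta), shrinks the steric
#' diameter according to `sigma`, initializes the particles, equilibrates
#' with move-size auto-tuning and collects production snapshots.
#'
#' @param eta packing fraction (computed with sigma0).
#' @param sigma steric diameter for this eta in sigma0 units: a number, a
#'   `function(eta)`, or a data.frame with columns `eta` and `sigma` to
#'   interpolate.  The default is the measured shrinking trend
#'   [experimental_sigma_table()]; pass `sigma = "theory"` for the cell-model
#'   curve via [sigma_of_eta()].
#' @param config a [sim_config()].
#' @param potential a [pair_potential_params()] evaluated at `sigma`; if
#'   `NULL`, defaults with `sigma` from above.
#' @param geom [brush_geometry()] used only when `sigma` is `NULL`.
#' @return An object of class `mc_trajectory`: production `snapshots`,
#'   `energy`/`acceptance` series, the equilibrated `configuration`, `eta`,
#'   `sigma`, `potential` and bookkeeping fields.
#' @export
run_state_point <- function(eta, sigma = experimental_sigma_table(),
                            config = sim_config(),
                            potential = NULL,
                            geom = experimental_brush_params()) {
  stopifnot(inherits(config, "sim_config"))
  box <- config$box
  sp <- paper_state_points()
  hit <- which(abs(sp$eta - eta) < 1e-9)
  N <- config$N
  if (is.null(N))
    N <- if (length(hit)) sp$N[hit] else round(4 * eta * box[1] * box[2] / pi)
  n_steps <- config$n_steps
  if (is.null(n_steps)) n_steps <- if (length(hit)) sp$n_steps[hit] else 1e5

  sig <- if (is.null(sigma) ||
             (is.character(sigma) && identical(sigma, "theory"))) {
    sigma_of_eta(eta, geom = geom)
  } else if (is.function(sigma)) {
    sigma(eta)
  } else if (is.data.frame(sigma)) {
    stats::approx(sigma$eta, sigma$sigma, xout = eta, rule = 2)$y
  } else {
    as.numeric(sigma)
  }
  if (is.null(potential)) potential <- pair_potential_params(sigma = sig)

  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- .init_positions(N, box, sig, eta)
  cfg0 <- configuration2d(pos, box, periodic = TRUE)

  n_eq <- max(1L, as.integer(round(config$equilibration_fraction * n_steps)))
  n_prod <- as.integer(n_steps) - n_eq
  sample_every <- config$sample_every
  if (is.null(sample_every)) sample_every <- max(1L, n_prod %/% 40L)
  max_disp <- config$max_disp
  if (is.null(max_disp)) max_disp <- 0.25 * sig

  eq <- metropolis_sweep(cfg0, potential, n_sweeps = n_eq,
                         max_disp = max_disp, tune = TRUE,
                         tune_until = n_eq, sample_every = 0)
  prod <- metropolis_sweep(eq$configuration, potential, n_sweeps = n_prod,
                           max_disp = eq$max_disp, tune = FALSE,
                           sample_every = sample_every)
  traj <- list(eta = eta, sigma = sig, N = N, box = box,
               potential = potential,
               snapshots = prod$snapshots,
               snapshot_sweeps = n_eq + prod$snapshot_sweeps,
               energy = c(eq$energy, prod$energy),
               acceptance = c(eq$acceptance, prod$acceptance),
               configuration = prod$configuration,
               n_equilibration = n_eq, n_steps = n_steps,
               max_disp = eq$max_disp)
  class(traj) <- "mc_trajectory"
  traj
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "mc_trajectory: eta = %.2f, N = %d, sigma = %.3f sigma0, %d sweeps (%d equil.)\n",
    x$eta, x$N, x$sigma, as.integer(x$n_steps), x$n_equilibration))
  cat(sprintf("  %d production snapshots, final E = %.4g kT, <acc> = %.2f\n",
              length(x$snapshots), x$energy[length(x$energy)],
              mean(x$acceptance[-seq_len(x$n_equilibration)])))
  invisible(x)
}

#' Theory-derived diameter shrinking curve
#'
#' Steric diameter sigma(eta)/sigma0 obtained from the cell-model
#' [size_vs_packing()] curve, rescaled so that the dilute limit equals 1
#' (the model underestimates the absolute dilute size; only its relative
#' shrinking is carried into the simulations).  Results are cached per
#' geometry within a session.
#'
#' @param eta packing fraction(s).
#' @param geom a [brush_geometry()].
#' @param eta_ref dilute reference packing used for the rescaling.
#' @return sigma/sigma0 value(s) in (0, 1].
#' @export
sigma_of_eta <- function(eta, geom = experimental_brush_params(),
                         eta_ref = 0.01) {
  key <- paste0(format(c(geom$f, geom$N, geom$R_PS, geom$b, geom$R_m, geom$d),
                       digits = 12), collapse = "_")
  cache <- .sigma_cache
  curve <- cache[[key]]
  need <- sort(unique(c(eta_ref, eta)))
  if (is.null(curve) || !all(need %in% curve$eta)) {
    missing_eta <- if (is.null(curve)) need else setdiff(need, curve$eta)
    new <- size_vs_packing(geom, missing_eta)
    curve <- if (is.null(curve)) new else rbind(curve, new)
    curve <- curve[order(curve$eta), ]
    cache[[key]] <- curve
  }
  ref <- curve$sigma[match(eta_ref, curve$eta)]
  pmin(1, curve$sigma[match(eta, curve$eta)] / ref)
}

.sigma_cache <- new.env(parent = emptyenv())
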