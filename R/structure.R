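## Structural analysis of 2D configurations: radial distribution function,
## first-peak metrics, neighbour statistics and the six-fold bond-orientational
## order parameter psi-6.

# all pair displacement components with minimum image for periodic boxes;
# returns the full (unordered, each pair once) dx, dy vectors
.pair_displacements <- function(cfg) {
  pos <- cfg$positions
  n <- nrow(pos)
  if (n < 2) return(list(dx = numeric(0), dy = numeric(0)))
  dx <- outer(pos[, 1], pos[, 1], "-")[upper.tri(diag(n))]
  dy <- outer(pos[, 2], pos[, 2], "-")[upper.tri(diag(n))]
  if (cfg$periodic) {
    dx <- dx - cfg$box[1] * round(dx / cfg$box[1])
    dy <- dy - cfg$box[2] * round(dy / cfg$box[2])
  }
  list(dx = dx, dy = dy)
}

#' Radial distribution function g(r)
#'
#' Histogram of pair distances normalized per central particle by the
#' ideal-gas shell count `2 pi n r dr`, averaged over configurations:
#' `g(r) = N(r) / (2 pi n r dr)`.  Periodic configurations use the
#' minimum-image convention; open (experimental-style) configurations use a
#' guard region: only particles at least `r_max` from every edge act as
#' centres, all particles count as neighbours.
#'
#' @param configs a [configuration2d()] or list of them (same box/periodicity).
#' @param dr bin width (default 0.02 in the configuration's length unit).
#' @param r_max histogram range; at most half the smallest box side for
#'   periodic data.
#' @return An object of class `radial_distribution`: `bin_centers`, `g`,
#'   `dr`, `n_density`, `n_configs`, `counts`.
#' @export
radial_distribution <- function(configs, dr = 0.02, r_max = NULL) {
  if (inherits(configs, "configuration2d")) configs <- list(configs)
  if (!length(configs)) stop("radial_distribution(): no configurations")
  stopifnot(all(vapply(configs, inherits, TRUE, "configuration2d")))
  if (dr <= 0) stop("radial_distribution(): dr must be positive")
  box <- configs[[1]]$box
  periodic <- configs[[1]]$periodic
  if (is.null(r_max)) r_max <- min(box) / 2
  if (periodic && r_max > min(box) / 2 + 1e-12)
    stop("radial_distribution(): r_max exceeds half the smallest box side")
  if (!periodic && 2 * r_max >= min(box))
    stop("radial_distribution(): guard regions leave no interior centres")

  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, breaks[length(breaks)] + dr)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)      # neighbour counts accumulated over centres
  n_centers <- 0
  dens <- numeric(length(configs))

  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    pos <- cfg$positions
    n <- nrow(pos)
    dens[k] <- n / (box[1] * box[2])
    if (periodic) {
      pd <- .pair_displacements(cfg)
      r <- sqrt(pd$dx^2 + pd$dy^2)
      r <- r[r < r_max]
      # each unordered pair contributes a neighbour to both centres
      counts <- counts + 2 * .bincount(r, breaks)
      n_centers <- n_centers + n
    } else {
      interior <- pos[, 1] >= r_max & pos[, 1] <= box[1] - r_max &
        pos[, 2] >= r_max & pos[, 2] <= box[2] - r_max
      if (!any(interior)) next
      ic <- which(interior)
      for (i in ic) {
        d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
        d <- d[-i]
        counts <- counts + .bincount(d[d < r_max], breaks)
      }
      n_centers <- n_centers + length(ic)
    }
  }
  if (n_centers == 0) stop("radial_distribution(): no valid centre particles")
  n_density <- mean(dens)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 2 * pi * centers * dr * n_density
  g <- (counts / n_centers) / shell
  rdf <- list(bin_centers = centers, g = g, dr = dr, n_density = n_density,
              n_configs = length(configs), counts = counts)
  class(rdf) <- "radial_distribution"
  rdf
}

.bincount <- function(x, breaks) {
  if (!length(x)) return(numeric(length(breaks) - 1L))
  tabulate(findInterval(x, breaks, rightmost.closed = FALSE,
                        left.open = TRUE),
           nbins = length(breaks) - 1L)
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf(
    "radial_distribution: %d bins (dr = %.3g) over %d configuration(s), n = %.4g\n",
    length(x$g), x$dr, x$n_configs, x$n_density))
  invisible(x)
}

#' @export
plot.radial_distribution <- function(x, ...) {
  plot(x$bin_centers, x$g, type = "l", xlab = "r", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

# positions (indices) of local maxima/minima of a vector, interior points only
.local_extrema <- function(y, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  if (what == "max") i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  else i[y[i] < y[i - 1] & y[i] <= y[i + 1]]
}

# parabolic sub-bin refinement around a discrete extremum index
.parabolic_refine <- function(xs, ys, i) {
  if (i <= 1 || i >= length(ys)) return(c(xs[i], ys[i]))
  y1 <- ys[i - 1]; y2 <- ys[i]; y3 <- ys[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(c(xs[i], ys[i]))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  h <- xs[2] - xs[1]
  c(xs[i] + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

#' First peak of g(r)
#'
#' Position and height of the first local maximum of g(r) exceeding 1, with
#' parabolic refinement over the three bins around the discrete maximum.
#'
#' @param rdf a [radial_distribution()].
#' @param min_height peaks must exceed this g value (default 1).
#' @return list with `r_p`, `g_p` and `found`; when g has no peak above
#'   `min_height` (e.g. a structureless fluid), `found = FALSE` and the
#'   positions are `NA` -- the absent-peak flag.
#' @export
first_peak <- function(rdf, min_height = 1) {
  stopifnot(inherits(rdf, "radial_distribution"))
  im <- .local_extrema(rdf$g, "max")
  im <- im[rdf$g[im] > min_height]
  if (!length(im))
    return(list(r_p = NA_real_, g_p = NA_real_, found = FALSE))
  ref <- .parabolic_refine(rdf$bin_centers, rdf$g, im[1])
  list(r_p = ref[1], g_p = ref[2], found = TRUE)
}

#' Neighbour cutoff distance from g(r)
#'
#' Two particles are neighbours when closer than the steric diameter plus
#' half the distance between the first maximum and the first minimum of
#' g(r): `cutoff = sigma + (r_min - r_max)/2`.  When raw extrema detection
#' fails (e.g. tightly binned crystals), a 3-bin moving average is applied
#' before the scan.
#'
#' @param rdf a [radial_distribution()].
#' @param sigma current steric diameter supplied by the caller.
#' @return cutoff distance.
#' @export
neighbor_cutoff <- function(rdf, sigma) {
  stopifnot(inherits(rdf, "radial_distribution"))
  ext <- .first_max_min(rdf$bin_centers, rdf$g)
  if (is.null(ext)) {
    g_s <- stats::filter(rdf$g, rep(1 / 3, 3), sides = 2)
    g_s[is.na(g_s)] <- rdf$g[is.na(g_s)]
    ext <- .first_max_min(rdf$bin_centers, as.numeric(g_s))
  }
  if (is.null(ext))
    stop("neighbor_cutoff(): no first maximum/minimum pair in g(r)")
  unname(sigma + (ext["rmin"] - ext["rmax"]) / 2)
}

.first_max_min <- function(xs, ys) {
  imax <- .local_extrema(ys, "max")
  imax <- imax[ys[imax] > 1]
  if (!length(imax)) return(NULL)
  i1 <- imax[1]
  n <- length(ys)
  if (i1 >= n - 1) return(NULL)
  # The first minimum is searched between the first peak and the next peak of
  # *prominent* height on a smoothed curve, so that bin noise on the shoulder
  # of the contact peak cannot truncate the search window early.
  z <- as.numeric(stats::filter(ys, rep(1 / 5, 5), sides = 2))
  z[is.na(z)] <- ys[is.na(z)]
  prom <- max(0.1 * (ys[i1] - 1), 0.05)
  cand <- .local_extrema(z, "max")
  cand <- cand[cand > i1 + 2 & z[cand] > 1]
  iend <- n
  for (k in cand) {
    dip <- min(z[(i1 + 1):k])
    if (z[k] - dip >= prom) { iend <- k; break }
  }
  if (iend <= i1 + 1) return(NULL)
  seg <- (i1 + 1):iend
  imin <- seg[which.min(z[seg])]
  # refine both extrema on the raw histogram near the smoothed locations
  w <- max(1, imin - 2):min(n, imin + 2)
  imin <- w[which.min(ys[w])]
  c(rmax = .parabolic_refine(xs, ys, i1)[1],
    rmin = .parabolic_refine(xs, ys, imin)[1])
}

# per-particle neighbour index list within cutoff (minimum image if periodic)
.neighbor_angles <- function(cfg, cutoff) {
  pos <- cfg$positions
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  if (cfg$periodic) {
    dx <- dx - cfg$box[1] * round(dx / cfg$box[1])
    dy <- dy - cfg$box[2] * round(dy / cfg$box[2])
  }
  r2 <- dx^2 + dy^2
  diag(r2) <- Inf
  nb <- r2 < cutoff^2
  list(nb = nb, theta = atan2(dy, dx))
}

#' Six-fold bond-orientational order parameter
#'
#' For each particle i, `psi6_i = |1/N_b sum_j exp(6 i theta_ij)|` over its
#' `N_b` neighbours within `cutoff`, with `theta_ij` the bond angle against a
#' fixed axis; particles without neighbours score 0.  A perfect triangular
#' lattice scores 1 everywhere, a square lattice 0.
#'
#' @param cfg a [configuration2d()].
#' @param cutoff neighbour distance.
#' @param combine `"magnitude"` (default): `mean_psi6` is the average of the
#'   per-particle magnitudes; `"complex"`: the magnitude of the complex mean
#'   of the per-particle psi6 values.
#' @return list with `psi6_per_particle` (magnitudes in [0, 1]) and
#'   `mean_psi6`.
#' @export
psi6 <- function(cfg, cutoff, combine = c("magnitude", "complex")) {
  combine <- match.arg(combine)
  stopifnot(inherits(cfg, "configuration2d"))
  if (cutoff <= 0) stop("psi6(): cutoff must be positive")
  na <- .neighbor_angles(cfg, cutoff)
  z <- exp(6i * na$theta)
  z[!na$nb] <- 0
  nb_count <- rowSums(na$nb)
  psi_complex <- rowSums(z) / pmax(nb_count, 1)
  psi_complex[nb_count == 0] <- 0
  mags <- Mod(psi_complex)
  mean_psi6 <- if (combine == "magnitude") mean(mags)
  else Mod(mean(psi_complex))
  list(psi6_per_particle = mags, mean_psi6 = mean_psi6,
       n_neighbors = nb_count)
}

#' Mean number of neighbours per particle
#'
#' Average over particles of the number of others within `cutoff`.  Periodic
#' configurations use minimum-image distances; open configurations average
#' only over particles at least `cutoff` from every edge (guard region).
#'
#' @inheritParams psi6
#' @return mean neighbour count.
#' @export
mean_neighbors <- function(cfg, cutoff) {
  stopifnot(inherits(cfg, "configuration2d"))
  if (cutoff <= 0) stop("mean_neighbors(): cutoff must be positive")
  na <- .neighbor_angles(cfg, cutoff)
  counts <- rowSums(na$nb)
  if (!cfg$periodic) {
    pos <- cfg$positions
    box <- cfg$box
    interior <- pos[, 1] >= cutoff & pos[, 1] <= box[1] - cutoff &
      pos[, 2] >= cutoff & pos[, 2] <= box[2] - cutoff
    if (any(interior)) counts <- counts[interior]
  }
  mean(counts)
}

#' Full structural summary of a set of configurations
#'
#' Convenience wrapper chaining [radial_distribution()], [first_peak()],
#' [neighbor_cutoff()], [psi6()] and [mean_neighbors()], the pipeline applied
#' to every simulated or experimental state point.
#'
#' @param configs list of [configuration2d()].
#' @param sigma steric diameter used in the neighbour rule.
#' @param dr,r_max passed to [radial_distribution()].
#' @return list of class `order_metrics`: `rdf`, `r_p`, `g_p`,
#'   `neighbor_cutoff`, `mean_psi6`, `psi6_per_particle` (last
#'   configuration), `mean_neighbors`.
#' @export
order_metrics <- function(configs, sigma, dr = 0.02, r_max = NULL) {
  if (inherits(configs, "configuration2d")) configs <- list(configs)
  rdf <- radial_distribution(configs, dr = dr, r_max = r_max)
  pk <- first_peak(rdf)
  cut <- tryCatch(neighbor_cutoff(rdf, sigma), error = function(e) NA_real_)
  if (is.na(cut)) {
    res <- list(rdf = rdf, r_p = pk$r_p, g_p = pk$g_p,
                neighbor_cutoff = NA_real_, mean_psi6 = NA_real_,
                psi6_per_particle = NULL, mean_neighbors = NA_real_)
    class(res) <- "order_metrics"
    return(res)
  }
  ps <- vapply(configs, function(c) psi6(c, cut)$mean_psi6, numeric(1))
  nb <- vapply(configs, function(c) mean_neighbors(c, cut), numeric(1))
  res <- list(rdf = rdf, r_p = pk$r_p, g_p = pk$g_p, neighbor_cutoff = cut,
              mean_psi6 = mean(ps),
              psi6_per_particle = psi6(configs[[length(configs)]], cut)$psi6_per_particle,
              mean_neighbors = mean(nb))
  class(res) <- "order_metrics"
  res
}

#' @export
print.order_metrics <- function(x, ...) {
  cat(sprintf(
    "order_metrics: r_p = %.4g, g_p = %.4g, cutoff = %.4g, <psi6> = %.3f, <N_b> = %.2f\n",
    x$r_p, x$g_p, x$neighbor_cutoff, x$mean_psi6, x$mean_neighbors))
  invisible(x)
}
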