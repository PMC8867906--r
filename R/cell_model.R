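## Wigner-Seitz cell model of a spherical polyelectrolyte brush.
##
## Conventions used throughout this file: lengths in nm, energies in units of
## k_B*T, charges in units of the elementary charge e.  The brush is a hard
## core of radius R_PS carrying f chains of N monovalent charged monomers at
## spacing b; counterions partition into condensed (N1), brush-absorbed (N2)
## and escaped (N3) populations inside a spherical cell of radius R_W.

# CODATA values, SI units
.const <- list(
  e    = 1.602176634e-19,   # C
  eps0 = 8.8541878128e-12,  # F/m
  kB   = 1.380649e-23       # J/K
)

#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two elementary charges in a medium
#' of relative permittivity `eps_r` equals the thermal energy `k_B T`.
#'
#' @param T temperature in kelvin.
#' @param eps_r relative permittivity of the solvent (dimensionless).
#' @return Bjerrum length in nm (about 0.71 nm for water at 298 K).
#' @examples
#' bjerrum_length(298, 78.5)
#' @export
bjerrum_length <- function(T, eps_r) {
  if (any(T <= 0) || any(eps_r <= 0))
    stop("bjerrum_length(): T and eps_r must be strictly positive")
  lb_m <- .const$e^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * T)
  lb_m * 1e9
}

#' Physical parameters of one spherical polyelectrolyte brush
#'
#' Bundles the geometry and solvent conditions of a brush and precomputes the
#' derived electrostatic scales: contour length `L_C = N*b`, Bjerrum length
#' `lambda_B` and Manning parameter `xi = lambda_B/b`.
#'
#' @param f number of grafted chains (functionality).
#' @param N charged monomers (and released monovalent counterions) per chain.
#' @param R_PS core radius, nm.
#' @param b spacing between adjacent charges along a chain, nm
#'   (0.17 nm for dsDNA: two charges per 0.34 nm base-pair rise).
#' @param R_m monomer radius used for the excluded-volume term, nm.
#' @param d counterion diameter used in the entropy terms, nm.
#' @param T temperature, K.
#' @param eps_r relative permittivity of the solvent.
#' @return An object of class `brush_geometry`.
#' @seealso [experimental_brush_params()], [miniature_brush_params()]
#' @export
brush_geometry <- function(f, N, R_PS, b, R_m = 1, d = 0.7,
                           T = 298, eps_r = 78.5) {
  vals <- c(f = f, N = N, R_PS = R_PS, b = b, R_m = R_m, d = d,
            T = T, eps_r = eps_r)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("brush_geometry(): all parameters must be finite and strictly positive")
  lambda_B <- bjerrum_length(T, eps_r)
  geom <- list(f = f, N = N, R_PS = R_PS, b = b, R_m = R_m, d = d,
               T = T, eps_r = eps_r,
               L_C = N * b, lambda_B = lambda_B, xi = lambda_B / b)
  class(geom) <- "brush_geometry"
  geom
}

#' @export
print.brush_geometry <- function(x, ...) {
  cat("Spherical polyelectrolyte brush geometry\n")
  cat(sprintf("  f = %.4g chains, N = %.4g charges/chain (Nf = %.3g)\n",
              x$f, x$N, x$N * x$f))
  cat(sprintf("  R_PS = %.4g nm, L_C = %.4g nm, b = %.3g nm\n",
              x$R_PS, x$L_C, x$b))
  cat(sprintf("  T = %g K, eps_r = %g, lambda_B = %.3f nm, xi = %.3f\n",
              x$T, x$eps_r, x$lambda_B, x$xi))
  invisible(x)
}

#' Experimental dsDNA-brush geometry
#'
#' The dilute-solution geometry of the 10 kbp dsDNA-coated polystyrene
#' particles: f = 1e5 grafted fragments, contour length 3.4 um (10 kbp at
#' 0.34 nm rise), one charge per b = 0.17 nm giving N = 2e4 per chain, core
#' radius 0.49 um, water at 298 K.
#'
#' @inheritParams brush_geometry
#' @return A `brush_geometry`.
#' @export
experimental_brush_params <- function(R_m = 1, d = 0.7, T = 298, eps_r = 78.5) {
  brush_geometry(f = 1e5, N = 3400 / 0.17, R_PS = 490, b = 0.17,
                 R_m = R_m, d = d, T = T, eps_r = eps_r)
}

#' Miniature-brush geometry
#'
#' A scaled-down brush with N = 40 charges per chain and core radius 10 nm,
#' keeping the grafting density f/(4 pi R_PS^2) of the experimental system,
#' i.e. f = 1e5 * (10/490)^2.
#'
#' @inheritParams brush_geometry
#' @return A `brush_geometry`.
#' @export
miniature_brush_params <- function(R_m = 1, d = 0.7, T = 298, eps_r = 78.5) {
  f_mini <- 1e5 * (10 / 490)^2
  brush_geometry(f = f_mini, N = 40, R_PS = 10, b = 0.17,
                 R_m = R_m, d = d, T = T, eps_r = eps_r)
}

#' Number of Manning-condensed counterions
#'
#' Counterions condense onto the chains until one net elementary charge per
#' Bjerrum length remains, so for Manning parameter `xi > 1` a fraction
#' `1 - 1/xi` of all `N*f` counterions is condensed; below the threshold none
#' are.
#'
#' @param geom a [brush_geometry()].
#' @return N1, the (continuous) condensed-counterion count.
#' @export
manning_condensed <- function(geom) {
  stopifnot(inherits(geom, "brush_geometry"))
  if (geom$xi <= 1) return(0)
  geom$N * geom$f * (1 - 1 / geom$xi)
}

#' Counterion partition and brush extension inside one Wigner-Seitz cell
#'
#' Fixes the condensed population `N1` from Manning condensation, takes the
#' escaped population `N3` as given and assigns the remainder
#' `N2 = N*f - N1 - N3` to the brush interior (charge neutrality).
#'
#' @param geom a [brush_geometry()].
#' @param R_W Wigner-Seitz cell radius, nm.
#' @param L brush thickness, nm; must satisfy `0 <= L <= L_C` and
#'   `R_PS + L <= R_W`.
#' @param N3 escaped (outside-brush) counterion count.
#' @return An object of class `cell_state` with fields `R_W`, `L`, `R`,
#'   `N1`, `N2`, `N3`.
#' @export
cell_state <- function(geom, R_W, L, N3) {
  stopifnot(inherits(geom, "brush_geometry"))
  if (L < 0 || L > geom$L_C)
    stop("cell_state(): L must lie in [0, L_C]")
  if (geom$R_PS + L > R_W)
    stop("cell_state(): brush radius R_PS + L exceeds the cell radius R_W")
  N1 <- manning_condensed(geom)
  Nf <- geom$N * geom$f
  if (N3 < 0 || N3 > Nf - N1)
    stop("cell_state(): N3 must lie in [0, N*f - N1]")
  st <- list(R_W = R_W, L = L, R = geom$R_PS + L,
             N1 = N1, N2 = Nf - N1 - N3, N3 = N3)
  class(st) <- "cell_state"
  st
}

#' Net charge density profile in the cell
#'
#' Piecewise profile in units of e/nm^3: zero in the core, net negative
#' density falling off as r^-2 through the brush (stretched chains minus the
#' absorbed counterions that track them, a total of -e*N3), and a uniform
#' positive density +e*N3 in the outer shell `R < r < R_W`.  The volume
#' integral over the cell vanishes by construction.
#'
#' @param r radius or vector of radii, nm, in `[0, R_W]`.
#' @param state a [cell_state()].
#' @param geom a [brush_geometry()].
#' @return charge density at `r`, e/nm^3.
#' @export
charge_density <- function(r, state, geom) {
  stopifnot(inherits(state, "cell_state"))
  if (any(r < 0) || any(r > state$R_W))
    stop("charge_density(): r outside [0, R_W]")
  rho <- numeric(length(r))
  brush <- r >= geom$R_PS & r < state$R
  shell <- r >= state$R
  if (state$L > 0)
    rho[brush] <- -state$N3 / (4 * pi * r[brush]^2 * state$L)
  if (state$R_W > state$R)
    rho[shell] <- 3 * state$N3 / (4 * pi * (state$R_W^3 - state$R^3))
  rho
}

# cumulative charge q(r) (units of e) enclosed within radius r for the
# charge_density() profile; vectorised in r
.enclosed_charge <- function(r, state) {
  q <- numeric(length(r))
  R_PS <- state$R - state$L
  brush <- r >= R_PS & r < state$R
  shell <- r >= state$R
  if (state$L > 0)
    q[brush] <- -state$N3 * (r[brush] - R_PS) / state$L
  if (state$R_W > state$R) {
    q[shell] <- -state$N3 * (state$R_W^3 - pmin(r[shell], state$R_W)^3) /
      (state$R_W^3 - state$R^3)
  }
  q
}

#' Hartree electrostatic energy of the cell
#'
#' Mean-field Coulomb energy (1/2) int int rho(r) rho(r') / (4 pi eps |r-r'|)
#' of the [charge_density()] profile.  By spherical symmetry this equals the
#' field energy `int q(r)^2 / (8 pi eps r^2) dr`, which is evaluated either
#' from closed-form antiderivatives of the piecewise profile (`"analytic"`,
#' default) or by adaptive radial quadrature (`"quadrature"`), the two serving
#' as mutual cross-checks.
#'
#' @param state a [cell_state()].
#' @param geom a [brush_geometry()].
#' @param method `"analytic"` or `"quadrature"`.
#' @return energy in k_B*T; zero when no charge escapes (N3 = 0).
#' @export
hartree_energy <- function(state, geom, method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "cell_state"), inherits(geom, "brush_geometry"))
  if (state$N3 == 0) return(0)
  pref <- geom$lambda_B / 2           # 1/(8 pi eps) in kT*nm/e^2
  R_PS <- state$R - state$L; R <- state$R; R_W <- state$R_W
  if (method == "analytic") {
    # brush region: q = -N3 (r - R_PS)/L; integrand (q/N3)^2/r^2 expands to
    # (1 - 2 R_PS/r + R_PS^2/r^2)/L^2
    I1 <- if (state$L > 0) {
      ((R - R_PS) - 2 * R_PS * log(R / R_PS) + R_PS^2 * (1 / R_PS - 1 / R)) /
        state$L^2
    } else 0
    # outer shell: q = -N3 (R_W^3 - r^3)/(R_W^3 - R^3);
    # (R_W^3 - r^3)^2/r^2 = R_W^6/r^2 - 2 R_W^3 r + r^4
    I2 <- if (R_W > R) {
      c6 <- R_W^3
      num <- (c6^2 * (1 / R - 1 / R_W) - c6 * (R_W^2 - R^2) +
                (R_W^5 - R^5) / 5)
      num / (R_W^3 - R^3)^2
    } else 0
    return(pref * state$N3^2 * (I1 + I2))
  }
  .radial_field_energy(function(r) .enclosed_charge(r, state),
                       c(R_PS, R, R_W), geom$lambda_B)
}

# Electrostatic field energy (k_B T) of a spherically symmetric charge
# distribution given its cumulative charge q(r) in units of e:
# U = (lambda_B / 2) * int q(r)^2 / r^2 dr, integrated piecewise between
# `breaks` (which may end at Inf for unscreened profiles).
.radial_field_energy <- function(q_of_r, breaks, lambda_B) {
  f <- function(r) q_of_r(r)^2 / r^2
  tot <- 0
  for (i in seq_len(length(breaks) - 1)) {
    if (breaks[i + 1] > breaks[i]) {
      q <- stats::integrate(f, breaks[i], breaks[i + 1],
                            rel.tol = 1e-10, subdivisions = 500L)
      if (q$message != "OK")
        stop("radial field energy quadrature failed: ", q$message)
      tot <- tot + q$value
    }
  }
  lambda_B / 2 * tot
}

#' Chain-stretching elastic free energy
#'
#' Gaussian entropic elasticity of f chains stretched to end-to-end distance
#' L: `F_el = (3/2) f L^2 / (N b^2)` in k_B*T.  Strictly increasing in L and
#' proportional to f.
#'
#' @inheritParams hartree_energy
#' @return energy in k_B*T.
#' @export
elastic_energy <- function(state, geom) {
  stopifnot(inherits(state, "cell_state"), inherits(geom, "brush_geometry"))
  if (state$L > geom$L_C)
    stop("elastic_energy(): L exceeds the contour length")
  1.5 * geom$f * state$L^2 / (geom$N * geom$b^2)
}

# brush shell volume, nm^3
.brush_volume <- function(state, geom) {
  4 / 3 * pi * (state$R^3 - geom$R_PS^3)
}

#' Flory excluded-volume free energy
#'
#' Mean-field self-avoidance of the N*f chain monomers spread homogeneously
#' through the brush shell, with excluded volume equal to the volume of one
#' monomer of radius R_m: `F_Fl = (1/2) v (Nf)^2 / V_brush`, `v = (4/3) pi
#' R_m^3`.
#'
#' @inheritParams hartree_energy
#' @return energy in k_B*T.
#' @export
flory_energy <- function(state, geom) {
  stopifnot(inherits(state, "cell_state"), inherits(geom, "brush_geometry"))
  V <- .brush_volume(state, geom)
  if (V <= 0) stop("flory_energy(): zero brush volume")
  v <- 4 / 3 * pi * geom$R_m^3
  0.5 * v * (geom$N * geom$f)^2 / V
}

# fraction of the brush shell not occupied by chain monomers
.free_volume_fraction <- function(state, geom) {
  v <- 4 / 3 * pi * geom$R_m^3
  1 - v * geom$N * geom$f / .brush_volume(state, geom)
}

#' Counterion translational entropy terms
#'
#' Ideal-gas entropic free energy `-T S_i = int n_i [ln(n_i d^3) - 1] dV` of
#' the mobile counterions, with densities from the [charge_density()]
#' profiles: inside the brush n_2 tracks the stretched chains (r^-2) and the
#' available volume is reduced by the chain monomers (n_2 -> n_2/phi_free);
#' outside, n_3 is homogeneous in the shell `R < r < R_W`.  The de Broglie
#' length-scale constant is omitted; it shifts F by a constant.
#'
#' @inheritParams hartree_energy
#' @param region `"inside"` (population N2) or `"outside"` (N3).
#' @return the -T*S contribution in k_B*T; zero for an empty population.
#' @export
counterion_entropy <- function(state, geom, region = c("inside", "outside")) {
  region <- match.arg(region)
  stopifnot(inherits(state, "cell_state"), inherits(geom, "brush_geometry"))
  d3 <- geom$d^3
  if (region == "inside") {
    if (state$N2 == 0) return(0)
    if (state$L <= 0) stop("counterion_entropy(): N2 > 0 requires L > 0")
    phi <- .free_volume_fraction(state, geom)
    if (phi <= 0)
      stop("counterion_entropy(): monomers overfill the brush (unphysical state)")
    R_PS <- geom$R_PS; R <- state$R
    A <- state$N2 / (4 * pi * state$L)      # n2(r) = A / r^2
    # int n2 ln(n2) dV = N2 ln A - 8 pi A [r ln r - r]_{R_PS}^{R}
    int_nlogn <- state$N2 * log(A) -
      8 * pi * A * ((R * log(R) - R) - (R_PS * log(R_PS) - R_PS))
    return(int_nlogn + state$N2 * (log(d3 / phi) - 1))
  }
  if (state$N3 == 0) return(0)
  V_out <- 4 / 3 * pi * (state$R_W^3 - state$R^3)
  if (V_out <= 0) stop("counterion_entropy(): no outside volume but N3 > 0")
  n3 <- state$N3 / V_out
  state$N3 * (log(n3 * d3) - 1)
}

#' Osmotic insertion free energy
#'
#' Cost of inserting one brush of radius R into the suspension of its
#' neighbours: the expelled volume ~ R^3 times the osmotic pressure of the
#' trapped counterions, Pi(R_W) ~ N2 k_B T / R_W^3, giving `F_p = N2 k_B T
#' (R/R_W)^3`.  Meaningful in the osmotic regime N2 >> N3; the returned value
#' carries an attribute `warn_regime = TRUE` when that limit is violated.
#'
#' @inheritParams hartree_energy
#' @return energy in k_B*T (>= 0).
#' @export
insertion_free_energy <- function(state, geom) {
  stopifnot(inherits(state, "cell_state"))
  if (state$R > state$R_W)
    stop("insertion_free_energy(): R exceeds R_W")
  val <- state$N2 * (state$R / state$R_W)^3
  if (state$N2 < 10 * state$N3)
    attr(val, "warn_regime") <- TRUE
  val
}

#' Total variational free energy of the cell
#'
#' Sum of the six contributions: Hartree electrostatics, chain elasticity,
#' Flory excluded volume, the two counterion entropy terms (returned with
#' their -T*S sign) and the osmotic insertion term.
#'
#' @param L brush thickness, nm.
#' @param N3 escaped counterion count.
#' @param geom a [brush_geometry()].
#' @param R_W Wigner-Seitz radius, nm.
#' @return An object of class `free_energy_breakdown`: list with `U_H`,
#'   `F_el`, `F_Fl`, `TS2`, `TS3` (the signed -T*S contributions), `F_p` and
#'   `total`, all in k_B*T.
#' @export
total_free_energy <- function(L, N3, geom, R_W) {
  st <- cell_state(geom, R_W, L, N3)
  br <- list(
    U_H  = hartree_energy(st, geom),
    F_el = elastic_energy(st, geom),
    F_Fl = flory_energy(st, geom),
    TS2  = counterion_entropy(st, geom, "inside"),
    TS3  = counterion_entropy(st, geom, "outside"),
    F_p  = as.numeric(insertion_free_energy(st, geom))
  )
  br$total <- br$U_H + br$F_el + br$F_Fl + br$TS2 + br$TS3 + br$F_p
  br$state <- st
  class(br) <- "free_energy_breakdown"
  br
}

#' @export
print.free_energy_breakdown <- function(x, ...) {
  cat("Free-energy breakdown (k_B T):\n")
  for (nm in c("U_H", "F_el", "F_Fl", "TS2", "TS3", "F_p", "total"))
    cat(sprintf("  %-5s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

# objective on the (L, N3) box; returns total free energy, Inf when infeasible
.fe_objective <- function(L, N3, geom, R_W) {
  ok <- tryCatch({
    total_free_energy(L, N3, geom, R_W)$total
  }, error = function(e) Inf)
  if (!is.finite(ok)) Inf else ok
}

#' Minimize the cell free energy over brush thickness and escaped counterions
#'
#' Coarse scan on a grid -- linear in L over `[L_min_frac*L_C, min(L_C, R_W -
#' R_PS)]`, logarithmic in N3 (it spans many decades) plus the N3 = 0 edge --
#' followed by a Nelder-Mead polish in (L, log N3).  `converged` is TRUE when
#' the polish improves on the grid optimum and the relative change is below
#' `tol`.
#'
#' @param geom a [brush_geometry()].
#' @param R_W Wigner-Seitz radius, nm; must exceed `R_PS`.
#' @param n_L,n_N3 grid resolution of the coarse scan.
#' @param L_min_frac lower bound on L as a fraction of the contour length
#'   (keeps the entropy and Flory terms finite).
#' @param tol relative convergence tolerance on the total free energy.
#' @return An object of class `equilibrium_result`: `L_star`, `N3_star`,
#'   `breakdown`, `release_fraction = N3_star/(N*f)` and `converged`.
#' @export
minimize_free_energy <- function(geom, R_W, n_L = 48, n_N3 = 48,
                                 L_min_frac = 0.05, tol = 1e-6) {
  stopifnot(inherits(geom, "brush_geometry"))
  if (R_W <= geom$R_PS) stop("minimize_free_energy(): R_W must exceed R_PS")
  L_max <- min(geom$L_C, R_W - geom$R_PS)
  L_min <- L_min_frac * geom$L_C
  if (L_min >= L_max) L_min <- 0.5 * L_max
  N1 <- manning_condensed(geom)
  N3_max <- geom$N * geom$f - N1
  L_grid <- seq(L_min, L_max, length.out = n_L)
  # log grid over many decades, plus the empty-shell edge
  N3_grid <- c(0, pmin(10^seq(log10(N3_max) - 12, log10(N3_max),
                              length.out = n_N3), N3_max))
  vals <- outer(L_grid, N3_grid,
                Vectorize(function(L, N3) .fe_objective(L, N3, geom, R_W)))
  if (!any(is.finite(vals)))
    stop("minimize_free_energy(): no feasible point on the scan grid")
  idx <- arrayInd(which.min(vals), dim(vals))
  L0 <- L_grid[idx[1]]; N30 <- N3_grid[idx[2]]
  f_grid <- vals[idx[1], idx[2]]

  # profile polish: the landscape is smooth but strongly anisotropic (N3
  # spans decades), so minimize over log N3 at fixed L, then over L
  lt_lo <- log(N3_max) - 32; lt_hi <- log(N3_max)
  best_N3 <- function(L) {
    o <- stats::optimize(function(t) .fe_objective(L, exp(t), geom, R_W),
                         c(lt_lo, lt_hi), tol = 1e-8)
    f_edge <- .fe_objective(L, 0, geom, R_W)
    if (f_edge < o$objective) list(N3 = 0, f = f_edge)
    else list(N3 = exp(o$minimum), f = o$objective)
  }
  dL <- L_grid[2] - L_grid[1]
  lo <- max(L_min, L0 - 2 * dL); hi <- min(L_max, L0 + 2 * dL)
  optL <- stats::optimize(function(L) best_N3(L)$f, c(lo, hi),
                          tol = max(tol * L_max, 1e-10))
  L_star <- optL$minimum
  inner <- best_N3(L_star)
  N3_star <- inner$N3; f_star <- inner$f
  converged <- is.finite(f_star) &&
    (f_star <= f_grid + tol * abs(f_grid) + 1e-12)
  if (f_star > f_grid) { L_star <- L0; N3_star <- N30; f_star <- f_grid }
  res <- list(L_star = L_star, N3_star = N3_star,
              breakdown = total_free_energy(L_star, N3_star, geom, R_W),
              release_fraction = N3_star / (geom$N * geom$f),
              converged = converged, R_W = R_W)
  class(res) <- "equilibrium_result"
  res
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "Cell-model equilibrium: L* = %.4g nm, N3* = %.4g (release fraction %.3g)\n",
    x$L_star, x$N3_star, x$release_fraction))
  cat(sprintf("  R_W = %.4g nm, total F = %.6g kT, converged: %s\n",
              x$R_W, x$breakdown$total, x$converged))
  invisible(x)
}

#' Equilibrium brush diameter versus packing fraction
#'
#' Maps each packing fraction to a cell radius through the 3D convention
#' `eta = R_0^3 / R_W^3` with `R_0 = R_PS + L_C`, minimizes the free energy
#' and reports the shrunken diameter `sigma(eta) = 2 (R_PS + L*)` relative to
#' the dilute diameter `sigma_0 = 2 R_0`.
#'
#' @param geom a [brush_geometry()].
#' @param eta_grid packing fractions, each in (0, ~1.3].
#' @param ... passed to [minimize_free_energy()].
#' @return A data.frame with one row per eta: `eta`, `R_W`, `L_star`, `N1`,
#'   `N2`, `N3`, `release_fraction`, `sigma`, `sigma_ratio` (= sigma/sigma_0)
#'   and the six free-energy terms.
#' @export
size_vs_packing <- function(geom, eta_grid, ...) {
  stopifnot(inherits(geom, "brush_geometry"))
  if (any(eta_grid <= 0) || any(eta_grid > 1.35))
    stop("size_vs_packing(): eta values must lie in (0, 1.35]")
  R_0 <- geom$R_PS + geom$L_C
  sigma0 <- 2 * R_0
  rows <- lapply(eta_grid, function(eta) {
    R_W <- R_0 * eta^(-1 / 3)
    eq <- minimize_free_energy(geom, R_W, ...)
    br <- eq$breakdown
    data.frame(eta = eta, R_W = R_W, L_star = eq$L_star,
               N1 = br$state$N1, N2 = br$state$N2, N3 = br$state$N3,
               release_fraction = eq$release_fraction,
               sigma = 2 * (geom$R_PS + eq$L_star),
               sigma_ratio = 2 * (geom$R_PS + eq$L_star) / sigma0,
               U_H = br$U_H, F_el = br$F_el, F_Fl = br$F_Fl,
               TS2 = br$TS2, TS3 = br$TS3, F_p = br$F_p, total = br$total)
  })
  do.call(rbind, rows)
}
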