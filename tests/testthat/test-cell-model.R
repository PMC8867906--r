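# Cell model: electrostatic scales, free-energy terms, minimization.

test_that("Bjerrum length has the right value, scaling and limits", {
  # CODATA evaluation for water at 298 K: e^2/(4 pi eps0 * 78.5 * kB * 298)
  expect_equal(bjerrum_length(298, 78.5), 0.7143, tolerance = 1e-3)
  # inverse proportionality in the permittivity
  expect_equal(bjerrum_length(298, 2 * 78.5) / bjerrum_length(298, 78.5), 0.5,
               tolerance = 1e-12)
  # vanishes for a perfectly screening medium
  expect_lt(bjerrum_length(298, 1e12), 1e-10)
  expect_error(bjerrum_length(-1, 80))
  expect_error(bjerrum_length(298, 0))
})

test_that("Manning condensation leaves one charge per Bjerrum length", {
  # below the threshold (b > lambda_B, xi < 1) nothing condenses
  g_sub <- brush_geometry(f = 30, N = 40, R_PS = 10, b = 1)
  expect_lt(g_sub$xi, 1)
  expect_identical(manning_condensed(g_sub), 0)
  # xi = 2 exactly: N1 = (1 - 1/2) * N * f
  lb <- bjerrum_length(298, 78.5)
  g2 <- brush_geometry(f = 30, N = 40, R_PS = 10, b = lb / 2)
  expect_equal(manning_condensed(g2), 600, tolerance = 1e-10)
  # dsDNA spacing: condensed fraction 1 - 1/xi with xi from the
  # independently computed Bjerrum length
  g <- brush_geometry(f = 1e5, N = 2e4, R_PS = 490, b = 0.17)
  xi_oracle <- bjerrum_length(298, 78.5) / 0.17
  expect_equal(manning_condensed(g) / (g$N * g$f), 1 - 1 / xi_oracle,
               tolerance = 1e-12)
})

test_that("charge density is piecewise, r^-2 in the brush, and neutral overall", {
  st <- mini_state(L = 4, N3 = 50)
  g <- mini_geom()
  # core region carries no charge
  expect_equal(charge_density(c(0, g$R_PS / 2), st, g), c(0, 0))
  # r^-2 profile inside the brush (small core so 2r stays within the brush)
  gl <- brush_geometry(f = 5, N = 100, R_PS = 1, b = 0.17)
  stl <- cell_state(gl, 100, 10, 20)
  expect_equal(charge_density(2, stl, gl) / charge_density(4, stl, gl), 4,
               tolerance = 1e-12)
  # overall neutrality: int rho 4 pi r^2 dr = 0, integrated piecewise
  # (charge of either sign = N3)
  q_in <- stats::integrate(function(r) charge_density(r, st, g) * 4 * pi * r^2,
                           g$R_PS, st$R, subdivisions = 1000L, rel.tol = 1e-10)
  q_out <- stats::integrate(function(r) charge_density(r, st, g) * 4 * pi * r^2,
                            st$R, st$R_W, subdivisions = 1000L, rel.tol = 1e-10)
  expect_lt(abs(q_in$value + q_out$value) / st$N3, 1e-6)
  # no escaped counterions, no charge anywhere
  st0 <- cell_state(g, st$R_W, 4, 0)
  rs <- seq(0, st0$R_W, length.out = 50)
  expect_true(all(charge_density(rs, st0, g) == 0))
  expect_error(charge_density(st$R_W + 1, st, g))
})

test_that("Hartree energy: closed form matches quadrature and scales as 1/eps", {
  st <- mini_state(L = 4, N3 = 100)
  g <- mini_geom()
  ua <- hartree_energy(st, g, method = "analytic")
  uq <- hartree_energy(st, g, method = "quadrature")
  expect_gt(ua, 0)
  expect_equal(ua, uq, tolerance = 1e-8)
  # neutral everywhere when N3 = 0
  expect_identical(hartree_energy(cell_state(g, st$R_W, 4, 0), g), 0)
  # halving the permittivity doubles the energy (the profile of the escaped
  # charge is geometry-only, so the comparison is at equal N3)
  g_half <- brush_geometry(f = g$f, N = g$N, R_PS = g$R_PS, b = g$b,
                           eps_r = g$eps_r / 2)
  st_half <- cell_state(g_half, st$R_W, 4, 100)
  expect_equal(hartree_energy(st_half, g_half) / ua, 2, tolerance = 1e-10)
})

test_that("uniform-sphere self energy reproduces the (3/5) Q^2/(4 pi eps R) form", {
  # independent closed-form oracle for the radial field-energy engine
  lambda_B <- bjerrum_length(298, 78.5)
  Q <- 1000; R <- 25
  q_uniform <- function(r) ifelse(r < R, Q * (r / R)^3, Q)
  u <- brushpack:::.radial_field_energy(q_uniform, c(0, R, Inf), lambda_B)
  u_exact <- 3 / 5 * lambda_B * Q^2 / R
  expect_equal(u, u_exact, tolerance = 1e-3)   # within 0.1 %
})

test_that("elastic energy is monotone in L and proportional to f", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  Ls <- seq(0.5, g$L_C * 0.99, length.out = 8)
  fe <- vapply(Ls, function(L) elastic_energy(cell_state(g, RW, L, 0), g),
               numeric(1))
  expect_true(all(diff(fe) > 0))
  g2 <- brush_geometry(f = 2 * g$f, N = g$N, R_PS = g$R_PS, b = g$b)
  expect_equal(elastic_energy(cell_state(g2, RW, 4, 0), g2) /
                 elastic_energy(cell_state(g, RW, 4, 0), g), 2,
               tolerance = 1e-12)
  # transcription oracle: (3/2) f L^2 / (N b^2) at the miniature geometry
  expect_equal(elastic_energy(cell_state(g, RW, 4, 0), g),
               1.5 * g$f * 16 / (40 * 0.17^2), tolerance = 1e-12)
})

test_that("Flory term scales with monomer count squared and dilutes away", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  st <- cell_state(g, RW, 4, 0)
  g2 <- brush_geometry(f = 2 * g$f, N = g$N, R_PS = g$R_PS, b = g$b)
  st2 <- cell_state(g2, RW, 4, 0)
  expect_equal(flory_energy(st2, g2) / flory_energy(st, g), 4,
               tolerance = 1e-12)
  # larger brush volume at fixed monomer number means less crowding
  expect_gt(flory_energy(cell_state(g, RW, 2, 0), g),
            flory_energy(cell_state(g, RW, 6, 0), g))
  # transcription oracle: v (N f)^2 / (2 V_shell)
  v <- 4 / 3 * pi * g$R_m^3
  Vsh <- 4 / 3 * pi * ((g$R_PS + 4)^3 - g$R_PS^3)
  expect_equal(flory_energy(st, g), v * (g$N * g$f)^2 / (2 * Vsh),
               tolerance = 1e-12)
})

test_that("counterion entropy terms: empty populations, volume trends, ideal gas", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  # no escaped counterions: outside term vanishes
  expect_identical(counterion_entropy(cell_state(g, RW, 4, 0), g, "outside"), 0)
  # more outside volume, more entropy (more negative free energy)
  s_small <- counterion_entropy(cell_state(g, RW, 4, 100), g, "outside")
  s_large <- counterion_entropy(cell_state(g, 2 * RW, 4, 100), g, "outside")
  expect_lt(s_large, s_small)
  # thin-shell ideal-gas check: for R_PS >> L the r^-2 profile is nearly
  # uniform, so the inside term approaches N2 (ln(nbar d^3) - 1) with the
  # monomer excluded volume switched off (tiny R_m)
  gg <- brush_geometry(f = 5, N = 10, R_PS = 1000, b = 0.17, R_m = 1e-4)
  stt <- cell_state(gg, 5000, 1, 0)
  nbar <- stt$N2 / (4 / 3 * pi * ((gg$R_PS + 1)^3 - gg$R_PS^3))
  closed <- stt$N2 * (log(nbar * gg$d^3) - 1)
  expect_equal(counterion_entropy(stt, gg, "inside"), closed, tolerance = 1e-4)
  # monomers overfilling the brush is rejected as unphysical
  g_fat <- brush_geometry(f = 200, N = 40, R_PS = 10, b = 0.17, R_m = 1.5)
  expect_error(counterion_entropy(cell_state(g_fat, 200, 2, 0), g_fat, "inside"),
               "unphysical")
})

test_that("insertion term: empty, cell-filling and cubic-scaling limits", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  N3_max <- g$N * g$f - manning_condensed(g)
  # all free counterions escaped: N2 = 0, no osmotic pressure
  st_empty <- cell_state(g, RW, 4, N3_max)
  expect_equal(as.numeric(insertion_free_energy(st_empty, g)), 0)
  # brush filling the cell: F_p = N2 (prefactor 1)
  st_full <- cell_state(g, g$R_PS + g$L_C, g$L_C, 0)
  expect_equal(as.numeric(insertion_free_energy(st_full, g)), st_full$N2,
               tolerance = 1e-12)
  # cubic scaling in R at fixed N2 and R_W (geometry with a long contour so
  # the doubled radius stays below L_C)
  gl <- brush_geometry(f = 5, N = 100, R_PS = 1, b = 0.17)
  RWl <- 100
  f1 <- as.numeric(insertion_free_energy(cell_state(gl, RWl, 1, 10), gl))
  f2 <- as.numeric(insertion_free_energy(cell_state(gl, RWl, 3, 10), gl))
  expect_equal(f2 / f1, 8, tolerance = 1e-12)   # R: 2 -> 4
})

test_that("total free energy is the bookkeeping sum and finite on a sweep", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  br <- total_free_energy(4, 50, g, RW)
  expect_equal(br$total,
               br$U_H + br$F_el + br$F_Fl + br$TS2 + br$TS3 + br$F_p,
               tolerance = 1e-12)
  # charge partition closes exactly
  expect_equal(br$state$N1 + br$state$N2 + br$state$N3, g$N * g$f,
               tolerance = 1e-12)
  # 50 x 50 sweep of the (L, N3) box stays finite (slim monomers so the
  # whole L range keeps a positive free volume)
  gs <- brush_geometry(f = g$f, N = g$N, R_PS = g$R_PS, b = g$b, R_m = 0.3)
  N3_max <- gs$N * gs$f - manning_condensed(gs)
  Ls <- seq(0.1 * gs$L_C, gs$L_C, length.out = 50)
  N3s <- c(0, pmin(10^seq(-3, log10(N3_max), length.out = 49), N3_max))
  vals <- outer(Ls, N3s, Vectorize(function(L, N3)
    total_free_energy(L, N3, gs, RW)$total))
  expect_true(all(is.finite(vals)))
})

test_that("minimizer lands on an optimum of the free-energy landscape", {
  g <- mini_geom()
  RW <- 8 * (g$R_PS + g$L_C)
  eq <- minimize_free_energy(g, RW)
  expect_true(eq$converged)
  expect_gte(eq$release_fraction, 0)
  expect_lte(eq$release_fraction, 1)
  # optimality against the 8 neighbouring points of a local grid
  f0 <- eq$breakdown$total
  for (dl in c(-1, 0, 1)) {
    for (dn in c(-1, 0, 1)) {
      if (dl == 0 && dn == 0) next
      L <- eq$L_star * (1 + 0.005 * dl)
      N3 <- max(eq$N3_star * (1 + 0.02 * dn), 0)
      fn <- tryCatch(total_free_energy(L, N3, g, RW)$total,
                     error = function(e) Inf)
      expect_gte(fn, f0 - 1e-9 * abs(f0))
    }
  }
})

test_that("release fraction falls with functionality and rises with cell size", {
  # functionality sweep at miniature scale (grafting density around the
  # experimental value); the electrostatic penalty grows with f
  fs <- c(8, 15, 30, 55, 85)
  rel_f <- vapply(fs, function(ff) {
    gg <- brush_geometry(f = ff, N = 40, R_PS = 10, b = 0.17)
    minimize_free_energy(gg, 8 * (gg$R_PS + gg$L_C))$release_fraction
  }, numeric(1))
  expect_true(all(diff(rel_f) < 0))
  # dilution sweep: beyond the insertion-dominated regime, a larger cell
  # means more entropy for escaped counterions
  g <- mini_geom()
  R0 <- g$R_PS + g$L_C
  rel_RW <- vapply(c(4, 6, 8, 12, 16), function(m)
    minimize_free_energy(g, m * R0)$release_fraction, numeric(1))
  expect_true(all(diff(rel_RW) > 0))
})

test_that("equilibrium diameter shrinks monotonically with packing", {
  g <- mini_geom()
  curve <- size_vs_packing(g, c(0.05, 0.2, 0.5, 0.8, 1.1, 1.3))
  expect_true(all(diff(curve$sigma_ratio) <= 1e-9))
  expect_true(all(curve$sigma_ratio > 0 & curve$sigma_ratio <= 1))
  expect_error(size_vs_packing(g, c(-0.1, 0.5)))
})
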