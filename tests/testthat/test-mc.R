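# Pair potential and Metropolis Monte Carlo engine.

test_that("pair potential: truncation, zero crossing and well position", {
  p <- pair_potential_params(sigma = 1)
  # truncated to exactly zero beyond the cutoff
  expect_identical(pair_potential(c(3.5, 4, 10), p), c(0, 0, 0))
  # at r = sigma the 100-200 term vanishes, leaving the Yukawa value
  yuk <- function(r) p$V2 * exp(-r / p$lambda) / (r / p$lambda)
  expect_equal(pair_potential(1, p), yuk(1), tolerance = 1e-12)
  # minimum of the LJ part alone sits at sigma * 2^(1/100): locate it
  # numerically on a fine grid with the repulsion switched off
  plj <- pair_potential_params(sigma = 1, V2 = 0)
  rs <- seq(1.001, 1.02, by = 1e-5)
  r_min <- rs[which.min(pair_potential(rs, plj))]
  expect_equal(r_min, 2^(1 / 100), tolerance = 1e-4)
  # well depth of the 4*V1 convention is V1
  expect_equal(min(pair_potential(rs, plj)), -p$V1, tolerance = 1e-4)
  expect_error(pair_potential(c(1, -0.5), p))
})

test_that("both printed normalizations of the steep LJ term are available", {
  r <- seq(0.99, 1.2, by = 0.005)
  p4 <- pair_potential_params(sigma = 1, V2 = 0, lj_convention = "4v1")
  pw <- pair_potential_params(sigma = 1, V2 = 0, lj_convention = "well")
  s100 <- (1 / r)^100
  expect_equal(pair_potential(r, p4), 4 * p4$V1 * (s100^2 - s100),
               tolerance = 1e-12)
  expect_equal(pair_potential(r, pw), pw$V1 * (s100^2 - 2 * s100),
               tolerance = 1e-12)
  # the "well" convention reaches depth V1 exactly at r = sigma
  expect_equal(pair_potential(1, pw), -pw$V1, tolerance = 1e-12)
})

test_that("total energy matches symmetry cases and the brute-force oracle", {
  p <- pair_potential_params(sigma = 1)
  # two distant particles
  cfg2 <- configuration2d(rbind(c(1, 1), c(5, 1)), c(20, 20))
  expect_identical(total_energy(cfg2, p), 0)
  # equilateral triangle: three identical pair contributions
  a <- 1.05
  tri <- rbind(c(5, 5), c(5 + a, 5), c(5 + a / 2, 5 + a * sqrt(3) / 2))
  cfg3 <- configuration2d(tri, c(20, 20))
  expect_equal(total_energy(cfg3, p), 3 * pair_potential(a, p),
               tolerance = 1e-12)
  # random 20-particle fixture against the O(N^2) double loop
  set.seed(42)
  cfg <- gen_poisson(20, 6)
  expect_equal(total_energy(cfg, p), brute_energy(cfg$positions, cfg$box, p),
               tolerance = 1e-12)
})

test_that("Metropolis sweeps: free gas accepts everything, seeds reproduce", {
  p0 <- pair_potential_params(sigma = 1, V1 = 0, V2 = 0)
  cfg <- gen_poisson(50, 10, seed = 3)
  set.seed(11)
  out <- metropolis_sweep(cfg, p0, n_sweeps = 5, max_disp = 0.3)
  expect_true(all(out$acceptance == 1))
  # determinism: identical seed and configuration give identical trajectories
  p <- pair_potential_params(sigma = 1)
  set.seed(7); run1 <- metropolis_sweep(cfg, p, n_sweeps = 20, max_disp = 0.2)
  set.seed(7); run2 <- metropolis_sweep(cfg, p, n_sweeps = 20, max_disp = 0.2)
  expect_identical(run1$configuration$positions, run2$configuration$positions)
  expect_identical(run1$energy, run2$energy)
  set.seed(8); run3 <- metropolis_sweep(cfg, p, n_sweeps = 20, max_disp = 0.2)
  expect_false(identical(run1$configuration$positions,
                         run3$configuration$positions))
})

test_that("incremental energy bookkeeping matches a fresh recomputation", {
  p <- pair_potential_params(sigma = 1)
  # overlap-free fluid start: pre-equilibrate from a lattice, then audit a
  # fresh run's running energy against a full recomputation
  start <- gen_hexagonal(1.3, c(13, 10 * 1.3 * sqrt(3) / 2))
  set.seed(13)
  warm <- metropolis_sweep(start, p, n_sweeps = 50, max_disp = 0.15)
  out <- metropolis_sweep(warm$configuration, p, n_sweeps = 100,
                          max_disp = 0.15)
  e_run <- out$energy[length(out$energy)]
  e_fresh <- total_energy(out$configuration, p)
  expect_equal(e_run, e_fresh, tolerance = 1e-8)
})

test_that("packing fraction bookkeeping reproduces the tabulated state points", {
  expect_equal(round(packing_fraction(441, 1, c(20, 20)), 2), 0.87)
  expect_equal(round(packing_fraction(289, 1, c(20, 20)), 2), 0.57)
  expect_identical(packing_fraction(0, 1, c(20, 20)), 0)
  expect_equal(packing_fraction(100, 1, c(40, 20)),
               packing_fraction(100, 1, c(20, 20)) / 2, tolerance = 1e-12)
  expect_error(packing_fraction(10, 1, c(0, 20)))
  # the canonical table pairs the printed counts with the printed etas
  sp <- paper_state_points()
  expect_equal(sp$N[sp$eta == 0.87], 441L)
  expect_equal(sp$N[sp$eta == 0.57], 289L)
})

test_that("ideal gas sampled by the engine has a flat g(r)", {
  p0 <- pair_potential_params(sigma = 1, V1 = 0, V2 = 0)
  cfg <- gen_poisson(200, 15, seed = 21)
  set.seed(21)
  out <- metropolis_sweep(cfg, p0, n_sweeps = 60, max_disp = 1.5,
                          sample_every = 3)
  rdf <- radial_distribution(out$snapshots, dr = 0.25)
  keep <- rdf$bin_centers > 1.5
  # each bin within 3 standard errors of 1 (Poisson counting noise)
  n_per_bin <- rdf$counts[keep] / rdf$n_configs
  se <- 1 / sqrt(pmax(rdf$counts[keep], 1))
  expect_true(all(abs(rdf$g[keep] - 1) < 3.5 * pmax(se, 0.02)))
  expect_lt(abs(mean(rdf$g[keep]) - 1), 0.02)
})

test_that("attraction raises the contact peak over a purely repulsive run", {
  cfgs <- list()
  for (v1 in c(0, 1.43)) {
    p <- pair_potential_params(sigma = 0.88, sigma0 = 1, V1 = v1)
    tr <- run_state_point(0.40, sigma = 0.88, potential = p,
                          config = sim_config(seed = 31, n_steps = 4000))
    cfgs[[length(cfgs) + 1]] <- first_peak(radial_distribution(tr$snapshots))
  }
  expect_true(cfgs[[2]]$g_p > cfgs[[1]]$g_p)
})

test_that("production energies show no residual equilibration trend", {
  tr <- run_state_point(0.40, config = sim_config(seed = 17, n_steps = 8000))
  e_prod <- tr$energy[-seq_len(tr$n_equilibration)]
  blocks <- split(e_prod, cut(seq_along(e_prod), 8))
  bm <- vapply(blocks, mean, numeric(1))
  fit <- stats::lm(bm ~ seq_along(bm))
  # slope consistent with zero at 95 %
  ci <- stats::confint(fit, level = 0.95)[2, ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("state-point runner wires N, sigma and equilibration together", {
  tr <- run_state_point(0.40, config = sim_config(seed = 23, n_steps = 300))
  expect_equal(tr$N, 196L)
  expect_equal(tr$sigma, 0.88, tolerance = 1e-12)  # measured-trend table
  expect_true(length(tr$snapshots) > 0)
  expect_true(all(tr$acceptance >= 0 & tr$acceptance <= 1))
  expect_true(all(is.finite(tr$energy)))
  # non-tabulated eta falls back to the area-fraction formula
  tr2 <- run_state_point(0.30, sigma = 0.9,
                         config = sim_config(seed = 23, n_steps = 100))
  expect_equal(tr2$N, round(4 * 0.30 * 400 / pi))
})
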