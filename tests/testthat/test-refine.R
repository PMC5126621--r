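test_that("Metropolis criterion: downhill always, uphill by Boltzmann", {
  set.seed(1)
  expect_true(metropolis_accept(-15, -10, 3))   # downhill
  expect_false(metropolis_accept(-9, -10, 1e-9))  # zero-temperature limit
  expect_error(metropolis_accept(NaN, 0, 1), "non-finite")
  expect_error(metropolis_accept(0, 0, 0))
  # empirical acceptance at dE = kT ln 2 is 1/2 within 3 sigma
  for (kt in c(1, 3)) {
    set.seed(123)
    de <- kt * log(2)
    acc <- mean(vapply(1:10000, function(i)
      metropolis_accept(de, 0, kt), TRUE))
    expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 10000))
  }
})

test_that("annealing schedule interpolates kT 3.0 -> 1.0 monotonically", {
  cfg <- refinement_config()
  expect_equal(anneal_kt(cfg, 0), 3.0)
  expect_equal(anneal_kt(cfg, cfg$outer_cycles - 1), 1.0)
  kts <- vapply(seq_len(cfg$outer_cycles) - 1, anneal_kt, numeric(1),
                cfg = cfg)
  expect_true(all(diff(kts) <= 0))
  expect_error(anneal_kt(cfg, -1), "range")
  expect_error(anneal_kt(cfg, cfg$outer_cycles), "range")
  # single outer cycle pins kT at the start value
  expect_equal(anneal_kt(refinement_config(outer_cycles = 1,
                                           kt_start = 2, kt_end = 2), 0), 2)
})

test_that("DFP minimiser solves analytic problems", {
  # 1-D harmonic: start 30 degrees from the minimum at 12
  fn <- function(x) 0.5 * (x - 12)^2
  res <- dfp_minimize(fn, 42, gtol = 1e-6, max_step = 100)
  expect_equal(res$x, 12, tolerance = 1e-3)
  expect_true(res$converged)
  # 2-DOF anisotropic quadratic vs a dense grid search
  qf <- function(x) 3 * (x[1] - 1)^2 + 0.5 * (x[2] + 2)^2 +
    0.4 * x[1] * x[2]
  res2 <- dfp_minimize(qf, c(5, 5), gtol = 1e-8, max_iter = 500,
                       max_step = 10)
  grid <- expand.grid(x = seq(-4, 4, by = 0.05), y = seq(-6, 2, by = 0.05))
  vals <- 3 * (grid$x - 1)^2 + 0.5 * (grid$y + 2)^2 + 0.4 * grid$x * grid$y
  gbest <- grid[which.min(vals), ]
  expect_equal(res2$x[1], gbest$x, tolerance = 0.05)
  expect_equal(res2$x[2], gbest$y, tolerance = 0.05)
  expect_lte(res2$value, min(vals))
})

test_that("structure minimisation never raises the energy", {
  p <- default_energy_params()
  sys <- test_system()
  s_p <- perturb_pose(sys, 1.0, seed = 4)
  e_in <- complex_energy(s_p, p)$total
  mn <- minimize_energy(s_p, p, flexible_ids = character(), max_iter = 40)
  expect_lte(mn$energy, e_in)
  expect_equal(complex_energy(mn$structure, p)$total, mn$energy,
               tolerance = 1e-8)
  expect_error(minimize_energy(subset_components(sys$structure,
                                                 character()),
                               p, flexible_ids = character()),
               "degrees of freedom")
})

test_that("decoy trajectories are seeded, instrumented and valid", {
  p <- default_energy_params()
  sys <- test_system()
  s_p <- perturb_pose(sys, 1.0, seed = 2)
  cfg <- fast_cfg()
  d1 <- generate_decoy(s_p, cfg, p, first_cycle = TRUE, seed = 77)
  d2 <- generate_decoy(s_p, cfg, p, first_cycle = TRUE, seed = 77)
  expect_identical(d1$energy, d2$energy)     # bit-identical under a seed
  expect_identical(coords(d1$structure), coords(d2$structure))
  expect_equal(d1$n_steps, total_cycles(cfg))  # instrumented counter
  expect_true(is.finite(d1$energy))
  expect_true(validate_structure(d1$structure))
})

test_that("an optimization round selects the lowest-energy decoy", {
  p <- default_energy_params()
  sys <- test_system()
  s_p <- perturb_pose(sys, 1.0, seed = 3)
  cfg <- fast_cfg(seed = 11, n_decoys = 4)
  rd <- optimization_round(s_p, cfg, p)
  expect_length(rd$round_energies, 4)
  expect_equal(rd$energy, min(rd$round_energies))
  expect_equal(rd$index, which.min(rd$round_energies))
  # n_decoys = 1 reduces to a single seeded trajectory
  cfg1 <- fast_cfg(seed = 11, n_decoys = 1)
  rd1 <- optimization_round(s_p, cfg1, p)
  set.seed(cfg1$seed)
  child <- sample.int(2147483646L, 1)
  d <- generate_decoy(s_p, cfg1, p, seed = child)
  expect_equal(rd1$energy, d$energy)
})

test_that("refinement traces are non-increasing and converge", {
  p <- default_energy_params()
  sys <- test_system()
  s_p <- perturb_pose(sys, 1.5, seed = 6)
  cfg <- fast_cfg(seed = 21, max_K = 5)
  res <- refine_to_convergence(s_p, cfg, p)
  tr <- res$trace
  expect_equal(tr$K, length(tr$cycle_energies))
  expect_true(all(diff(tr$cycle_energies) <= 0))
  expect_true(tr$converged)
  # max_K = 1 cannot compare two rounds, so it cannot converge
  res1 <- refine_to_convergence(s_p, fast_cfg(seed = 21, max_K = 1), p)
  expect_false(res1$trace$converged)
  expect_equal(res1$trace$K, 1)
})

test_that("the planted pose is not beaten by decoys from perturbed starts", {
  p <- default_energy_params()
  sys <- test_system()
  e0 <- complex_energy(sys$structure, p)$total
  cfg <- fast_cfg()
  for (sd in 1:5) {
    s_p <- perturb_pose(sys, 1.5, seed = sd)
    d <- generate_decoy(s_p, cfg, p, first_cycle = TRUE, seed = 500 + sd)
    expect_gte(d$energy, e0 - 0.1)  # micro-minima granularity
  }
})
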