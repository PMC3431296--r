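# Elementary reaction networks: propensities, exact SSA, tau-leaping,
# mean-field steady states, stationary windows.

test_that("propensities follow CME conventions", {
  sys <- reaction_system(
    species_table(c("A", "B", "C"), c(2, 3, 0)),
    list(reaction(reactants = c(A = 1L, B = 1L), products = c(C = 1L),
                  law = rl_mass_action(2), name = "bi"),
         reaction(reactants = c(A = 2L), products = c(C = 1L),
                  law = rl_mass_action(2), name = "dimer"),
         reaction(reactants = c(C = 1L), law = rl_mass_action(5),
                  name = "needs_C")))
  a <- propensity_vector(sys, c(A = 2, B = 3, C = 0))$propensity
  expect_equal(a[1], 2 * 2 * 3)          # k*a*b/omega at omega = 1
  expect_equal(a[2], 2 * 2 * 1 / 2)      # k*a*(a-1)/(2*omega)
  expect_equal(a[3], 0)                  # required reactant absent
  expect_error(propensity_vector(sys, c(A = -1, B = 3, C = 0)), "negative")

  mm <- reaction_system(
    species_table(c("S", "E", "P"), c(100, 5, 0)),
    list(reaction(reactants = c(S = 1L), products = c(P = 1L),
                  law = rl_mm(10, 100, "S"), modifiers = "E")))
  expect_equal(propensity_vector(mm, c(S = 100, E = 5, P = 0))$propensity,
               10 * 5 * 100 / (100 + 100)) # half saturation: 25/s
  expect_equal(propensity_vector(mm, c(S = 0, E = 5, P = 0))$propensity, 0)
})

test_that("volume scales bimolecular but not unimolecular propensities", {
  mk <- function(omega) reaction_system(
    species_table(c("A", "B"), c(4, 6)),
    list(reaction(reactants = c(A = 1L, B = 1L), law = rl_mass_action(1)),
         reaction(reactants = c(A = 1L), law = rl_mass_action(1))),
    omega = omega)
  a1 <- propensity_vector(mk(1), c(A = 4, B = 6))$propensity
  a2 <- propensity_vector(mk(2), c(A = 4, B = 6))$propensity
  expect_equal(a2[1], a1[1] / 2)
  expect_equal(a2[2], a1[2])
})

test_that("SSA samples the exact birth-death stationary law", {
  bd <- birth_death_system()
  finals <- vapply(1:2000, function(i)
    simulate_ssa(bd, 120, c(0, 120), seed = i)$X[2], numeric(1))
  expect_equal(mean(finals), 10, tolerance = 0.03)
  expect_equal(stats::var(finals), 10, tolerance = 0.1)
  # chi-square goodness of fit against Poisson(10)
  ks <- 0:25
  probs <- stats::dpois(ks, 10)
  probs[length(probs)] <- probs[length(probs)] + stats::ppois(25, 10,
                                                             lower.tail = FALSE)
  obs <- tabulate(pmin(finals, 25) + 1, nbins = 26)
  keep <- probs * 2000 >= 5
  p <- suppressWarnings(stats::chisq.test(
    c(obs[keep], sum(obs[!keep])),
    p = c(probs[keep], sum(probs[!keep]))))$p.value
  expect_gt(p, 0.01)
})

test_that("SSA is deterministic under seed and freezes without reactions", {
  bd <- birth_death_system()
  t1 <- simulate_ssa(bd, 500, seed = 7)
  t2 <- simulate_ssa(bd, 500, seed = 7)
  expect_identical(t1, t2)
  dead <- birth_death_system(k = 0, x0 = 50)
  tr <- simulate_ssa(dead, 500, seed = 3)
  expect_true(all(diff(tr$X) <= 0)) # monotone decay, then frozen at 0
  expect_equal(tr$X[length(tr$X)], 0)
})

test_that("tau-leaping tracks the exact law and falls back when scarce", {
  big <- birth_death_system(k = 20, gamma = 0.1) # mean 200
  tr <- simulate_tau_leap(big, 600, seq(0, 600, 1), seed = 5, epsilon = 0.03)
  expect_equal(mean(tr$X[tr$time > 150]), 200, tolerance = 0.02)
  # distributional agreement with SSA at the final time
  f_ssa <- vapply(1:800, function(i)
    simulate_ssa(big, 80, c(0, 80), seed = i)$X[2], numeric(1))
  f_tau <- vapply(1:800, function(i)
    simulate_tau_leap(big, 80, c(0, 80), seed = 5000 + i)$X[2], numeric(1))
  p <- suppressWarnings(stats::ks.test(f_ssa, f_tau))$p.value
  expect_gt(p, 0.01)
  # all counts below the exact threshold: every step is exact, so the
  # trajectory is bitwise identical to SSA under the same seed
  small <- birth_death_system(k = 0.5, gamma = 0.1) # mean 5 < 10
  expect_identical(
    simulate_tau_leap(small, 300, seed = 11)$X,
    simulate_ssa(small, 300, seed = 11)$X)
  expect_error(simulate_tau_leap(small, 300, epsilon = 0.5), "epsilon")
})

test_that("mean-field steady state solves fixed points and flags divergence", {
  expect_equal(steady_state_mean_field(birth_death_system())$state[["X"]], 10)
  # conserved promoter unit stays at total occupancy 1
  sys <- build_expression("cotranslated", bursting_params())
  ss <- steady_state_mean_field(sys)
  expect_false(ss$diverged)
  expect_equal(ss$state[["g_on"]] + ss$state[["g_off"]], 1, tolerance = 1e-8)
  expect_equal(ss$state[["g_on"]], burst_duty_cycle(bursting_params()),
               tolerance = 1e-6)
  # influx past the downstream enzyme capacity: no finite steady state
  mod <- module_defaults("branch_point")
  over <- operonoise:::ratio_system("branch_point", mod, 1.3, 53)
  res <- steady_state_mean_field(over)
  expect_true(res$diverged)
  expect_match(res$message, "no finite steady state")
})

test_that("stationary_window trims, flags drift, and keeps the mean", {
  times <- seq(0, 100, 1)
  const <- fake_ensemble(list(matrix(5, 101, 1)), times, "X")
  w <- stationary_window(const, 0.3)
  expect_equal(length(w$times), sum(times >= 30))
  expect_false(attr(w, "stationary_flag"))
  ramp <- fake_ensemble(list(matrix(seq(0, 100, 1) + rnorm(101, 0, 0.1),
                                    ncol = 1)), times, "X")
  expect_true(attr(stationary_window(ramp, 0.3), "stationary_flag"))
  expect_error(stationary_window(const, 1), "burn_in")

  bd <- birth_death_system()
  ens <- simulate_ensemble(bd, 200, 400, seed = 9, init = "steady_state")
  w <- stationary_window(ens, 0.5)
  m <- vapply(w$trajectories, function(x) mean(x[, 1]), numeric(1))
  se <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 10), 3 * se)
})

test_that("conserved promoter units hold their total along trajectories", {
  sys <- build_module("linear_pathway", "cotranslated",
                      bursting = bursting_params())
  tr <- simulate_ssa(sys, 5000, seed = 4)
  expect_true(all(tr$g_on + tr$g_off == 1))
  expect_true(all(tr$S == 1000)) # clamped boundary species never moves
})

test_that("reaction systems round-trip through JSON", {
  sys <- build_module("dual_regulators_or", "uncoupled",
                      bursting = bursting_params())
  path <- withr::local_tempfile(fileext = ".json")
  write_reaction_system(sys, path)
  back <- read_reaction_system(path)
  expect_equal(back$species, sys$species)
  expect_equal(back$nu, sys$nu)
  expect_equal(propensity_vector(back, initial_state(back))$propensity,
               propensity_vector(sys, initial_state(sys))$propensity)
})

test_that("tau-leap agrees with SSA on every module fixture", {
  # the module fixtures all carry low-copy reactants (mRNAs near one copy,
  # scarce monomers), so the conservative fallback makes every tau-leap
  # step exact: the agreement is bitwise under a shared seed
  for (cls in setdiff(module_classes(), "lac_reduced")) {
    sys <- build_module(cls, "cotranslated", bursting = no_bursting())
    a <- simulate_ssa(sys, 6000, seed = 9)
    b <- simulate_tau_leap(sys, 6000, seed = 9)
    expect_identical(as.matrix(a), as.matrix(b), label = cls)
  }
  # a genuinely leaping system (all reactant counts large): statistical
  # agreement of stationary mean and CV within Monte-Carlo error
  big <- birth_death_system(k = 50, gamma = 0.1, x0 = 500) # mean 500
  st <- function(method, seed) {
    ens <- stationary_window(simulate_ensemble(
      big, 200, 200, seed = seed, method = method), 0.5)
    s <- summarize_ensemble(ens, n_boot = 200)$species
    s[s$species == "X", ]
  }
  a <- st("ssa", 301)
  b <- st("tau", 302)
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$sd_mean^2 + b$sd_mean^2))
  expect_lt(abs(a$cv - b$cv), 3 * sqrt(a$sd_cv^2 + b$sd_cv^2))
})
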