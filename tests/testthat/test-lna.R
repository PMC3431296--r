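# Linear noise approximation: fluctuation-dissipation matrices, Lyapunov
# covariances, the closed-form operon covariance, logarithmic gains, and the
# per-module noise-difference sign table.

test_that("birth-death LNA reproduces the textbook fluctuation-dissipation", {
  m <- build_lna(birth_death_system())
  expect_equal(unname(m$M), matrix(-0.1), tolerance = 1e-6)
  expect_equal(unname(m$N), matrix(2), tolerance = 1e-9) # both fluxes = k
  r <- solve_lyapunov(m)
  expect_equal(unname(diag(r$Sigma)), 10, tolerance = 1e-8) # Poisson
  expect_equal(unname(r$cv2[["X"]]), 1 / 10, tolerance = 1e-8)
  expect_true(all(Re(m$eigenvalues) < 0))
})

test_that("independent species have exactly zero LNA covariance", {
  r <- lna_analysis(double_birth_death())
  expect_lt(abs(r$Sigma["X", "Y"]), 1e-10)
})

test_that("two-stage expression CV2 matches the cascade closed form", {
  k_tx <- 0.05; delta_m <- 0.005; k_tl <- 0.1; k_deg <- log(2) / 1800
  r <- lna_analysis(two_stage_system(k_tx, delta_m, k_tl, k_deg))
  m_mean <- k_tx / delta_m
  p_mean <- k_tl * m_mean / k_deg
  tau_m <- 1 / delta_m; tau_p <- 1 / k_deg
  closed <- 1 / p_mean + (1 / m_mean) * tau_m / (tau_m + tau_p)
  expect_equal(unname(r$cv2[["P"]]), closed, tolerance = 1e-8)
  expect_equal(unname(r$mean[["P"]]), p_mean, tolerance = 1e-6)
})

test_that("closed-form operon covariance equals the Lyapunov solution", {
  for (expr in list(expression_params(),
                    expression_params(k_tx = 0.02, k_tl = 0.05,
                                      delta_m = 0.01, k_deg = 1e-3))) {
    for (mode in c("cotranslated", "cotranscribed", "uncoupled")) {
      r <- lna_analysis(build_expression(mode, no_bursting(), expr))
      eta <- if (mode == "uncoupled") 0 else r$eta["A", "B"]
      expect_equal(eta, eta_operon_closed_form(expr, mode),
                   tolerance = 1e-8)
    }
  }
})

test_that("operon covariance vanishes as mRNA turnover outpaces protein", {
  # tau_m/tau_p -> 0 at fixed mRNA and protein means
  etas <- vapply(c(0.005, 0.05, 0.5), function(dm) {
    e <- expression_params(k_tx = dm, delta_m = dm,      # <m> fixed at 1
                           k_tl = 0.0204, k_deg = log(2) / 1800)
    eta_operon_closed_form(e, "cotranscribed")
  }, numeric(1))
  expect_true(all(diff(etas) < 0))
  expect_lt(etas[3] / etas[1], 0.02)
})

test_that("logarithmic gains have their closed forms and bounds", {
  x <- c(s = 500, E = 5)
  expect_equal(log_gain(function(z) z[["s"]], x, "s"), 1, tolerance = 1e-6)
  # Michaelis-Menten flux: gain K_m/(K_m+s), vanishing at saturation
  K_m <- 100
  mmflux <- function(z) 10 * z[["E"]] * z[["s"]] / (K_m + z[["s"]])
  expect_equal(log_gain(mmflux, x, "s"), K_m / (K_m + 500), tolerance = 1e-5)
  x2 <- c(s = 1e6, E = 5)
  expect_lt(log_gain(mmflux, x2, "s"), 1e-3)
  # hyperbolic regulator gains of the OR-gate production flux are bounded
  # by 1 in magnitude (single regulator: gain = 1 - h)
  or_flux <- function(z) {
    hA <- z[["A"]] / (53 + z[["A"]]); hB <- z[["B"]] / (53 + z[["B"]])
    1 - (1 - hA) * (1 - hB)
  }
  for (xa in c(5, 53, 400)) for (xb in c(5, 53, 400)) {
    g <- log_gain(or_flux, c(A = xa, B = xb), "A")
    expect_lte(abs(g), 1 + 1e-6)
    expect_gt(g, 0)
  }
  expect_error(log_gain(function(z) 0 * z[["s"]], x, "s"), "positive")
})

test_that("module log gains carry the qualitative signs the theory uses", {
  # redundant product: both gains positive -> uncoupled configuration wins
  mod <- module_defaults("redundant_enzymes")
  ss <- steady_state_mean_field(
    build_module("redundant_enzymes", "uncoupled", no_bursting()))$state
  pflux <- function(z) {
    sat <- mod$S / (mod$K_m1 + mod$S)
    (mod$k_cat1 * z[["A"]] + mod$k_cat2 * z[["B"]]) * sat
  }
  expect_gt(log_gain(pflux, ss, "A"), 0)
  expect_gt(log_gain(pflux, ss, "B"), 0)
  # branch substrate: flux-ratio gain in s is negative, small at saturation
  modb <- module_defaults("branch_point")
  ssb <- steady_state_mean_field(
    build_module("branch_point", "uncoupled", no_bursting()))$state
  ratio <- function(z) modb$J /
    ((modb$k_cat1 * z[["A"]] + modb$k_cat2 * z[["B"]]) *
       z[["s"]] / (modb$K_m1 + z[["s"]]))
  expect_lt(log_gain(ratio, ssb, "s"), 0)
  # the consuming enzymes lower the production/consumption ratio
  expect_lt(log_gain(ratio, ssb, "A"), 0)
})

test_that("LNA noise differences carry the predicted sign for every class", {
  signs <- c(linear_pathway = 1, redundant_enzymes = -1, branch_point = -1,
             dual_regulators_or = -1, physical_interaction = 1,
             covalent_modification = 1)
  for (cls in names(signs)) {
    d <- delta_cv2(comparison_pair(cls, bursting = no_bursting()))
    expect_equal(sign(d$value), unname(signs[cls]), label = cls)
  }
  # heterodimer: negative and small next to the monomer difference
  d <- delta_cv2(comparison_pair("physical_interaction",
                                 bursting = no_bursting()),
                 c("A", "AB"))
  expect_lt(d$value[d$species == "AB"], 0)
  expect_lt(abs(d$value[d$species == "AB"]),
            abs(d$value[d$species == "A"]))
  # covalent modified form: small next to the unmodified difference
  d <- delta_cv2(comparison_pair("covalent_modification",
                                 bursting = no_bursting()),
                 c("A", "Astar"))
  expect_lt(abs(d$value[d$species == "Astar"]),
            abs(d$value[d$species == "A"]))
})

test_that("predict_sign encodes the module sign table", {
  expect_equal(predict_sign("covalent_modification", "A"), "positive")
  expect_equal(predict_sign("linear_pathway", "P"), "small_either")
  expect_equal(predict_sign("dual_regulators_or", "P"), "negative")
  expect_equal(predict_sign("branch_point", "s"), "negative")
  expect_equal(predict_sign("physical_interaction", "AB"), "negative")
  expect_error(predict_sign("linear_pathway", "Q"), "no sign prediction")
})

test_that("unstable or diverging systems are rejected with named eigenvalues", {
  # autocatalytic growth: x' = k x with no degradation
  grow <- reaction_system(
    species_table("X", 5),
    list(reaction(products = c(X = 1L), law = rl_mass_action(0.1),
                  modifiers = "X")))
  expect_error(build_lna(grow), "LNA unavailable|eigenvalue")
})
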