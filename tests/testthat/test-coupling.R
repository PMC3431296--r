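# Coupling configurations and interaction modules: builder topology, burst
# duty cycle, matched controls, and the extrinsic-noise perturbation.

test_that("build_expression produces the right species and translation wiring", {
  unc <- build_expression("uncoupled", no_bursting())
  expect_true(all(c("m1", "m2", "A", "B") %in% unc$species$name))
  cot <- build_expression("cotranscribed", no_bursting())
  expect_true("m12" %in% cot$species$name)
  expect_false(any(c("m1", "m2") %in% cot$species$name))
  # cotranslation: one translation channel increments A and B together
  ctl <- build_expression("cotranslated", no_bursting())
  tl <- Filter(function(r) r$class == "translation", ctl$reactions)
  expect_length(tl, 1)
  expect_equal(sort(names(tl[[1]]$products)), c("A", "B"))
  tl2 <- Filter(function(r) r$class == "translation", cot$reactions)
  expect_length(tl2, 2)
  # with bursting each transcription unit gets a conserved on/off promoter
  bu <- build_expression("uncoupled", bursting_params())
  expect_true(all(c("gA_on", "gA_off", "gB_on", "gB_off") %in%
                    bu$species$name))
})

test_that("mean protein is the product of cascade means", {
  expr <- expression_params(k_tx = 0.05, delta_m = 0.005, k_tl = 0.1,
                            k_deg = log(2) / 1800)
  ss <- steady_state_mean_field(build_expression("uncoupled", no_bursting(),
                                                 expr))
  expect_equal(ss$state[["A"]], (0.05 / 0.005) * (0.1 / (log(2) / 1800)),
               tolerance = 1e-6) # = 10 * 259.7 ~ 2597
  expect_equal(ss$state[["A"]], ss$state[["B"]], tolerance = 1e-6)
})

test_that("burst duty cycle is the two-state occupancy", {
  expect_equal(burst_duty_cycle(bursting_params(0.0028, 0.00045)),
               0.00045 / (0.00045 + 0.0028))
  expect_equal(round(burst_duty_cycle(bursting_params()), 4), 0.1385)
  expect_equal(burst_duty_cycle(bursting_params(k_goff = 0, k_gon = 1e-3)), 1)
  expect_equal(burst_duty_cycle(bursting_params(1e-3, 1e-3)), 0.5)
  expect_equal(burst_duty_cycle(no_bursting()), 1)
})

test_that("comparison pairs differ only in transcription topology", {
  pair <- comparison_pair("physical_interaction", bursting = no_bursting())
  post <- function(sys) lapply(
    Filter(function(r) r$class == "module", sys$reactions),
    function(r) list(r$name, r$reactants, r$products, r$modifiers, r$law))
  expect_equal(post(pair$coupled_system), post(pair$uncoupled_system))
  expect_error(build_module("no_such_class", "uncoupled"), "arg")
})

test_that("cotranslation narrows the protein difference A - B", {
  expr <- expression_params()
  vard <- function(mode) {
    ens <- stationary_window(simulate_ensemble(
      build_expression(mode, no_bursting(), expr), 200, 24000, seed = 61,
      init = "steady_state"), 0.5)
    d <- vapply(ens$trajectories, function(m)
      mean((m[, "A"] - m[, "B"])^2), numeric(1))
    mean(d)
  }
  v_ct <- vard("cotranslated")
  v_un <- vard("uncoupled")
  expect_lt(v_ct, v_un)
  # degradation-only difference: Var(A-B) = <A> for cotranslation (death
  # events are the only source of divergence, relaxing at k_deg)
  expect_equal(v_ct, 53, tolerance = 0.25)
})

test_that("uncoupled proteins are uncorrelated, coupled ones are not", {
  get_eta <- function(mode, seed) {
    ens <- stationary_window(simulate_ensemble(
      build_expression(mode, no_bursting()), 300, 24000, seed = seed,
      init = "steady_state"), 0.5)
    s <- summarize_ensemble(ens, n_boot = 200)
    s$pairs[s$pairs$species_a == "A" & s$pairs$species_b == "B", ]
  }
  un <- get_eta("uncoupled", 71)
  expect_lt(abs(un$eta), 3 * un$sd_eta)
  ct <- get_eta("cotranslated", 72)
  cs <- get_eta("cotranscribed", 73)
  expect_gt(ct$eta - cs$eta, -3 * sqrt(ct$sd_eta^2 + cs$sd_eta^2))
  expect_gt(cs$eta - un$eta, 3 * sqrt(cs$sd_eta^2 + un$sd_eta^2))
})

test_that("matched controls pass at shared parameters and fail otherwise", {
  pair <- comparison_pair("physical_interaction", bursting = no_bursting())
  ens_c <- stationary_window(simulate_ensemble(
    pair$coupled_system, 400, 24000, seed = 81, init = "steady_state"), 0.5)
  ens_u <- stationary_window(simulate_ensemble(
    pair$uncoupled_system, 400, 24000, seed = 82, init = "steady_state"), 0.5)
  rep <- verify_matched_controls(pair, ens_c, ens_u)
  expect_true(attr(rep, "pass"))
  # doubling one side's transcription must fail on the mean
  expr2 <- expression_params(k_tx = 0.01)
  bad <- build_module("physical_interaction", "uncoupled", no_bursting(),
                      expr = expr2)
  ens_b <- stationary_window(simulate_ensemble(
    bad, 400, 24000, seed = 83, init = "steady_state"), 0.5)
  rep2 <- verify_matched_controls(pair, ens_c, ens_b)
  expect_false(attr(rep2, "pass"))
  bad_rows <- rep2[!rep2$pass, ]
  expect_true("mean" %in% bad_rows$statistic)
})

test_that("extrinsic randomization perturbs rate classes globally", {
  sys <- build_expression("uncoupled", no_bursting())
  expect_equal(randomize_extrinsic(sys, 0, seed = 1)$reactions,
               sys$reactions)
  pert <- randomize_extrinsic(sys, 0.4, seed = 9)
  k <- function(s, nm) Filter(function(r) r$name == nm, s$reactions)[[1]]$law$k
  # one common multiplier per class: both genes scale identically
  r_tx <- k(pert, "tx_m1") / k(sys, "tx_m1")
  expect_equal(k(pert, "tx_m2") / k(sys, "tx_m2"), r_tx, tolerance = 1e-12)
  expect_true(r_tx >= 0.6 && r_tx <= 1.4 && r_tx != 1)
  # degradation classes untouched
  expect_equal(k(pert, "deg_A"), k(sys, "deg_A"))
  expect_error(randomize_extrinsic(sys, 0.9), "cv_ext")
})

test_that("global extrinsic noise correlates even uncoupled proteins", {
  sys <- build_expression("uncoupled", no_bursting())
  ens <- stationary_window(simulate_ensemble(
    sys, 300, 24000, seed = 91, init = "steady_state",
    extrinsic = list(cv_ext = 0.25)), 0.5)
  s <- summarize_ensemble(ens, n_boot = 200)
  pr <- s$pairs[s$pairs$species_a == "A" & s$pairs$species_b == "B", ]
  expect_gt(pr$r, 3 * pr$sd_r) # r > 0, clearly
})

test_that("module fixtures are stable and carry the measured burst rates", {
  for (cls in module_classes()) {
    fx <- gen_module_fixture(cls)
    expect_equal(fx$bursting$k_goff, 0.0028)
    expect_equal(fx$bursting$k_gon, 0.00045)
    expect_equal(fx$expr$k_deg, log(2) / 1800)
    sys <- build_module(cls, "cotranslated", bursting = no_bursting(),
                        expr = fx$expr, mod = fx$mod)
    r <- lna_analysis(sys) # stable steady state for every class fixture
    expect_true(all(is.finite(r$cv2)))
  }
})

test_that("lac-like cascade couples permease and galactosidase dynamics", {
  get <- function(mode, seed) {
    sys <- build_module("lac_reduced", mode, bursting = no_bursting())
    ens <- stationary_window(simulate_ensemble(
      sys, 100, 20000, seed = seed, init = "steady_state"), 0.5)
    s <- summarize_ensemble(ens, n_boot = 200)
    list(cv_alac = s$species$cv[s$species$species == "Alac"],
         cc = cross_correlation(ens, "A", "B", lags = 0))
  }
  ct <- get("cotranslated", 95)
  un <- get("uncoupled", 96)
  expect_gt(un$cv_alac, ct$cv_alac)
  expect_gt(ct$cc$value - un$cc$value,
            2 * sqrt(ct$cc$sem^2 + un$cc$sem^2))
})
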