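# Small fixture systems shared across test files.

birth_death_system <- function(k = 1, gamma = 0.1, x0 = 0) {
  reaction_system(
    species_table("X", x0),
    list(reaction(products = c(X = 1L), law = rl_mass_action(k),
                  name = "birth"),
         reaction(reactants = c(X = 1L), law = rl_mass_action(gamma),
                  name = "death")))
}

# two independent birth-death species (block-diagonal covariance fixture)
double_birth_death <- function(k = 1, gamma = 0.1) {
  reaction_system(
    species_table(c("X", "Y"), c(0, 0)),
    list(reaction(products = c(X = 1L), law = rl_mass_action(k)),
         reaction(reactants = c(X = 1L), law = rl_mass_action(gamma)),
         reaction(products = c(Y = 1L), law = rl_mass_action(k)),
         reaction(reactants = c(Y = 1L), law = rl_mass_action(gamma))))
}

# constitutive two-stage expression: mRNA -> protein cascade
two_stage_system <- function(k_tx = 0.05, delta_m = 0.005, k_tl = 0.1,
                             k_deg = log(2) / 1800) {
  reaction_system(
    species_table(c("m", "P"), c(round(k_tx / delta_m), 0)),
    list(reaction(products = c(m = 1L), law = rl_mass_action(k_tx),
                  class = "transcription"),
         reaction(reactants = c(m = 1L), law = rl_mass_action(delta_m),
                  class = "mrna_deg"),
         reaction(products = c(P = 1L), law = rl_mass_action(k_tl),
                  modifiers = "m", class = "translation"),
         reaction(reactants = c(P = 1L), law = rl_mass_action(k_deg),
                  class = "protein_deg")))
}

# hand-built ensemble from a list of state matrices (for estimator tests)
fake_ensemble <- function(mats, times, species) {
  structure(list(trajectories = mats, times = times, species = species,
                 seeds = seq_along(mats)),
            class = "operon_ensemble")
}

# windowed stationary ensemble for a module/mode at the package defaults
module_ensemble <- function(cls, mode, n_runs, seed, t_end = 24000,
                            bursting = no_bursting(), burn_in = 0.5) {
  sys <- build_module(cls, mode, bursting = bursting)
  stationary_window(
    simulate_ensemble(sys, n_runs, t_end, seed = seed,
                      init = "steady_state"),
    burn_in)
}
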