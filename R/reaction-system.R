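#' Build a species table
#'
#' Species are counted in copies per cell. Conserved units (e.g. a promoter
#' whose on/off states always sum to one copy) are flagged so conservation can
#' be checked on trajectories and eliminated before solving the linear noise
#' approximation. Clamped species are boundary conditions: reactions may read
#' them but never change their copy number (e.g. an external substrate pool).
#'
#' @param name character vector of unique species names.
#' @param initial non-negative integer initial copy numbers.
#' @param conserved logical; member of a conserved unit.
#' @param clamped logical; held constant throughout simulation.
#' @return a tibble with one row per species.
#' @export
species_table <- function(name, initial, conserved = FALSE, clamped = FALSE) {
  stopifnot(!anyDuplicated(name), all(initial >= 0))
  tibble::tibble(
    name = as.character(name),
    initial = as.numeric(initial),
    conserved = rep_len(as.logical(conserved), length(name)),
    clamped = rep_len(as.logical(clamped), length(name))
  )
}

#' Rate laws
#'
#' Propensities follow chemical-master-equation conventions with copy numbers
#' as the state and cell volume `omega` (femtoliters) scaling bimolecular and
#' higher-order collisions:
#' * `rl_mass_action(k)`: for reactants with counts a, b the propensity is
#'   `k*a*b/omega`, and `k*a*(a-1)/(2*omega)` for a homodimerization step;
#'   linear scale modifiers (catalysts, promoter states) multiply in the same
#'   way.
#' * `rl_mm(k_cat, K_m, substrate)`: single-step Michaelis--Menten propensity
#'   `k_cat*E*s/(K_m+s)` with `E` the product of the reaction's modifier
#'   counts and `s` the named substrate's count.
#' * `rl_hill(V_max, K, n, regulator, repressor=FALSE)`: Hill propensity
#'   `V_max*x^n/(K^n+x^n)` (or its complement for a repressor).
#' * `rl_hill_or(...)`: probabilistic-OR of two Hill activators,
#'   `V_max*(1-(1-hA)(1-hB))`, which saturates at `V_max` so either regulator
#'   alone has the full effect.
#'
#' All kinetic constants must be non-negative; a propensity is zero whenever a
#' required reactant is absent.
#'
#' @param k,k_cat,K_m,V_max,K,n,K_a,n_a,K_b,n_b non-negative kinetic constants.
#' @param substrate,regulator,regulator_a,regulator_b species names.
#' @param repressor logical; Hill law acts as a repressor.
#' @return a rate-law object.
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
rl_mass_action <- function(k) {
  stopifnot(is.numeric(k), k >= 0)
  structure(list(kind = "mass_action", k = k), class = "operon_rate_law")
}

#' @rdname rate_laws
#' @export
rl_mm <- function(k_cat, K_m, substrate) {
  stopifnot(k_cat >= 0, K_m >= 0)
  structure(list(kind = "michaelis_menten", k_cat = k_cat, K_m = K_m,
                 substrate = substrate), class = "operon_rate_law")
}

#' @rdname rate_laws
#' @export
rl_hill <- function(V_max, K, n, regulator, repressor = FALSE) {
  stopifnot(V_max >= 0, K >= 0, n >= 1)
  structure(list(kind = "hill", V_max = V_max, K = K, n = n,
                 regulator = regulator, repressor = repressor),
            class = "operon_rate_law")
}

#' @rdname rate_laws
#' @export
rl_hill_or <- function(V_max, K_a, n_a, K_b, n_b, regulator_a, regulator_b) {
  stopifnot(V_max >= 0, K_a >= 0, K_b >= 0, n_a >= 1, n_b >= 1)
  structure(list(kind = "hill_or", V_max = V_max, K_a = K_a, n_a = n_a,
                 K_b = K_b, n_b = n_b, regulator_a = regulator_a,
                 regulator_b = regulator_b), class = "operon_rate_law")
}

#' Define a reaction
#'
#' @param reactants named integer vector of consumed species (multiset).
#' @param products named integer vector of produced species.
#' @param law a rate law from [rate_laws].
#' @param modifiers character vector of species that linearly scale the
#'   propensity without being consumed (enzymes, promoter states).
#' @param class free-text label used by [randomize_extrinsic()] to group
#'   reactions into rate classes ("transcription", "translation", ...).
#' @param name optional reaction label.
#' @return a reaction object.
#' @export
reaction <- function(reactants = NULL, products = NULL, law,
                     modifiers = character(), class = "other", name = NULL) {
  stopifnot(inherits(law, "operon_rate_law"))
  as_multiset <- function(v) {
    if (is.null(v)) return(integer())
    if (is.null(names(v))) stop("reactants/products must be named vectors")
    stopifnot(all(v == round(v)), all(v > 0))
    v
  }
  structure(list(reactants = as_multiset(reactants),
                 products = as_multiset(products),
                 modifiers = as.character(modifiers),
                 law = law, class = class,
                 name = name %||% law$kind),
            class = "operon_reaction")
}

law_code <- function(law, idx_of) {
  switch(law$kind,
    mass_action = list(law = 0L, par = law$k),
    michaelis_menten = list(law = 1L,
      par = c(law$k_cat, law$K_m, idx_of(law$substrate))),
    hill = list(law = 2L,
      par = c(law$V_max, law$K, law$n, idx_of(law$regulator),
              as.numeric(isTRUE(law$repressor)))),
    hill_or = list(law = 3L,
      par = c(law$V_max, law$K_a, law$n_a, law$K_b, law$n_b,
              idx_of(law$regulator_a), idx_of(law$regulator_b))),
    stop("unknown rate-law kind: ", law$kind)
  )
}

#' Assemble a reaction system
#'
#' The common substrate for stochastic simulation, mean-field steady-state
#' solving, and the linear noise approximation. Copy numbers are the state;
#' time is in seconds; `omega` is the cell volume in femtoliters (default 1 fL
#' so 1 copy/fL corresponds to 1 copy).
#'
#' @param species a [species_table()].
#' @param reactions list of [reaction()] objects.
#' @param omega cell volume in femtoliters, > 0.
#' @return an object of class `reaction_system`.
#' @export
reaction_system <- function(species, reactions, omega = 1) {
  stopifnot(omega > 0, nrow(species) >= 1)
  if (inherits(reactions, "operon_reaction")) reactions <- list(reactions)
  nsp <- nrow(species)
  nm <- species$name
  idx_of <- function(x) {
    i <- match(x, nm)
    if (anyNA(i)) stop("unknown species: ", paste(x[is.na(i)], collapse = ", "))
    i - 1L # 0-based for C++
  }
  nr <- length(reactions)
  nu <- matrix(0L, nsp, nr, dimnames = list(nm, NULL))
  rxn_enc <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    stopifnot(inherits(r, "operon_reaction"))
    for (sp in names(r$reactants)) nu[match(sp, nm), j] <- nu[match(sp, nm), j] - r$reactants[[sp]]
    for (sp in names(r$products))  nu[match(sp, nm), j] <- nu[match(sp, nm), j] + r$products[[sp]]
    idx_of(c(names(r$reactants), names(r$products), r$modifiers)) # validate
    lc <- law_code(r$law, idx_of)
    rxn_enc[[j]] <- list(law = lc$law, par = as.numeric(lc$par),
                         ridx = as.integer(idx_of(names(r$reactants))),
                         rst = as.integer(unname(r$reactants)),
                         midx = as.integer(idx_of(r$modifiers)))
  }
  nu[species$clamped, ] <- 0L
  structure(list(species = species, reactions = reactions, omega = omega,
                 nu = nu,
                 enc = list(nsp = nsp, omega = omega, nu = nu, rxn = rxn_enc)),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, omega = ", x$omega, " fL\n", sep = "")
  invisible(x)
}

#' Per-reaction propensities at a state
#'
#' @param system a [reaction_system()].
#' @param state copy-number vector (named or in species order).
#' @param discrete use combinatorial (falling-factorial) kinetics (`TRUE`,
#'   the stochastic convention) or macroscopic rates (`FALSE`).
#' @return tibble with reaction name, class, and propensity in 1/s.
#' @export
propensity_vector <- function(system, state, discrete = TRUE) {
  state <- as_state(system, state)
  if (any(state < 0)) stop("negative copy numbers are not allowed")
  a <- cpp_propensities(system$enc, state, discrete)
  tibble::tibble(
    reaction = vapply(system$reactions, function(r) r$name, character(1)),
    class = vapply(system$reactions, function(r) r$class, character(1)),
    propensity = a
  )
}

as_state <- function(system, state) {
  nm <- system$species$name
  if (!is.null(names(state))) {
    stopifnot(setequal(names(state), nm))
    state <- state[nm]
  }
  stopifnot(length(state) == length(nm))
  as.numeric(state)
}

#' Macroscopic rate vector and net derivative
#'
#' `macro_rates()` evaluates the macroscopic (mean-field) rate of every
#' reaction; `macro_deriv()` returns the net time derivative of each species,
#' i.e. the stoichiometry matrix times the rate vector (clamped species have
#' zero derivative).
#'
#' @inheritParams propensity_vector
#' @return numeric vector.
#' @export
macro_rates <- function(system, state) {
  cpp_propensities(system$enc, as_state(system, state), FALSE)
}

#' @rdname macro_rates
#' @export
macro_deriv <- function(system, state) {
  drop(system$nu %*% macro_rates(system, state))
}

initial_state <- function(system) {
  stats::setNames(system$species$initial, system$species$name)
}

#' Serialize a reaction system to/from JSON
#'
#' @param system a [reaction_system()].
#' @param path file path.
#' @return `read_reaction_system()` returns a [reaction_system()].
#' @export
write_reaction_system <- function(system, path) {
  doc <- list(
    species = purrr::pmap(system$species, function(name, initial, conserved, clamped)
      list(name = name, initial = initial, conserved = conserved, clamped = clamped)),
    reactions = purrr::map(system$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           modifiers = r$modifiers, class = r$class, name = r$name,
           law = unclass(r$law))),
    omega = system$omega
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reaction_system
#' @export
read_reaction_system <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- purrr::map_dfr(doc$species, tibble::as_tibble)
  rxns <- purrr::map(doc$reactions, function(r) {
    law <- r$law
    rl <- switch(law$kind,
      mass_action = rl_mass_action(law$k),
      michaelis_menten = rl_mm(law$k_cat, law$K_m, law$substrate),
      hill = rl_hill(law$V_max, law$K, law$n, law$regulator,
                     isTRUE(law$repressor)),
      hill_or = rl_hill_or(law$V_max, law$K_a, law$n_a, law$K_b, law$n_b,
                           law$regulator_a, law$regulator_b))
    reaction(reactants = unlist(r$reactants), products = unlist(r$products),
             law = rl, modifiers = unlist(r$modifiers) %||% character(),
             class = r$class, name = r$name)
  })
  reaction_system(species_table(sp$name, sp$initial, sp$conserved, sp$clamped),
                  rxns, omega = doc$omega)
}

#' Convert a concentration in micromolar to copies per cell
#'
#' Uses the Avogadro constant; at the default 1 fL cell volume,
#' 1 uM is ~602 molecules per cell.
#'
#' @param uM concentration in micromolar.
#' @param omega cell volume in femtoliters.
#' @return copies per cell (not rounded).
#' @export
uM_to_copies <- function(uM, omega = 1) {
  uM * 1e-6 * 6.02214076e23 * omega * 1e-15
}
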