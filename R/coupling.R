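# Builders for the two-gene expression configurations (cotranslated,
# cotranscribed with separate ribosome binding sites, uncoupled) and their
# composition with the six protein-interaction module classes plus a reduced
# lac-like cascade.

#' Coupling modes and module classes
#'
#' `coupling_modes()` returns the three transcriptional coupling
#' configurations; `module_classes()` the interaction module classes.
#'
#' @return character vector.
#' @name module_classes
#' @export
coupling_modes <- function() c("cotranslated", "cotranscribed", "uncoupled")

#' @rdname module_classes
#' @export
module_classes <- function() c("linear_pathway", "redundant_enzymes",
                               "branch_point", "dual_regulators_or",
                               "physical_interaction",
                               "covalent_modification", "lac_reduced")

#' Gene-expression parameters
#'
#' Production and degradation rates are identical for genes A and B so that
#' coupled and uncoupled configurations have matched per-gene means.
#' Defaults give a mean of 1 mRNA and ~53 proteins per gene (the low
#' expression preset), an mRNA lifetime of 200 s, and a protein dilution
#' rate corresponding to a cell doubling every half hour.
#'
#' @param k_tx mRNA/s per (active) promoter.
#' @param k_tl protein/s per mRNA.
#' @param delta_m 1/s mRNA degradation (1/tau_mRNA).
#' @param k_deg 1/s protein dilution/degradation (1/tau_protein).
#' @return an `expression_params` list.
#' @export
expression_params <- function(k_tx = 0.005, k_tl = 0.0204, delta_m = 0.005,
                              k_deg = log(2) / 1800) {
  stopifnot(k_tx > 0, k_tl > 0, delta_m > 0, k_deg > 0)
  structure(list(k_tx = k_tx, k_tl = k_tl, delta_m = delta_m, k_deg = k_deg),
            class = "expression_params")
}

#' Expression-level presets
#'
#' Low/mid/high mean protein copy numbers per gene (53, 529, 5285), realized
#' by scaling the translation rate at fixed mRNA statistics.
#'
#' @param level `"low"`, `"mid"`, or `"high"`.
#' @return an [expression_params()] object.
#' @export
expression_preset <- function(level = c("low", "mid", "high")) {
  level <- match.arg(level)
  target <- c(low = 53, mid = 529, high = 5285)[[level]]
  e <- expression_params()
  m_mean <- e$k_tx / e$delta_m
  e$k_tl <- target * e$k_deg / m_mean
  e
}

#' Promoter bursting parameters
#'
#' Two-state (on/off) promoter switching; the default rates are the
#' estimated switching rates for bursty transcription in E. coli
#' (k_goff = 0.0028 1/s to the off state, k_gon = 0.00045 1/s to the on
#' state). While bursting is enabled the transcription rate in the on state
#' is divided by the duty cycle so the mean mRNA (and hence protein) is
#' unchanged -- bursting then raises CV at fixed means.
#'
#' @param k_goff on-to-off switching rate (1/s).
#' @param k_gon off-to-on switching rate (1/s).
#' @param enabled logical.
#' @return a `bursting_params` list.
#' @export
bursting_params <- function(k_goff = 0.0028, k_gon = 0.00045,
                            enabled = TRUE) {
  if (enabled) stopifnot(k_goff > 0 || k_gon > 0, k_gon > 0 || k_goff == 0)
  structure(list(k_goff = k_goff, k_gon = k_gon, enabled = enabled),
            class = "bursting_params")
}

#' No-bursting convenience constructor
#' @export
#' @rdname bursting_params
no_bursting <- function() bursting_params(enabled = FALSE)

#' Fraction of time a bursting promoter spends in the on state
#'
#' `k_gon / (k_gon + k_goff)`; returns 1 when bursting is disabled or
#' `k_goff = 0`.
#'
#' @param bursting a [bursting_params()] object.
#' @return occupancy in (0, 1].
#' @export
burst_duty_cycle <- function(bursting) {
  if (!bursting$enabled) return(1)
  if (bursting$k_goff == 0) return(1)
  bursting$k_gon / (bursting$k_gon + bursting$k_goff)
}

# expression reactions for one transcription unit
expression_unit <- function(promoter, mrna, bursting, expr, tx_law = NULL) {
  duty <- burst_duty_cycle(bursting)
  rxns <- list()
  mods <- character()
  if (bursting$enabled) {
    on <- paste0(promoter, "_on"); off <- paste0(promoter, "_off")
    rxns <- c(rxns, list(
      reaction(reactants = c(stats::setNames(1L, on)),
               products = c(stats::setNames(1L, off)),
               law = rl_mass_action(bursting$k_goff), class = "promoter",
               name = paste0(promoter, "_off_switch")),
      reaction(reactants = c(stats::setNames(1L, off)),
               products = c(stats::setNames(1L, on)),
               law = rl_mass_action(bursting$k_gon), class = "promoter",
               name = paste0(promoter, "_on_switch"))))
    mods <- on
  }
  law <- if (is.null(tx_law)) rl_mass_action(expr$k_tx / duty) else tx_law
  rxns <- c(rxns, list(
    reaction(products = stats::setNames(1L, mrna), law = law,
             modifiers = mods, class = "transcription",
             name = paste0("tx_", mrna)),
    reaction(reactants = stats::setNames(1L, mrna),
             law = rl_mass_action(expr$delta_m), class = "mrna_deg",
             name = paste0("deg_", mrna))))
  rxns
}

translation_rxns <- function(mode, expr) {
  k <- expr$k_tl
  switch(mode,
    cotranslated = list(
      reaction(products = c(A = 1L, B = 1L), law = rl_mass_action(k),
               modifiers = "m12", class = "translation", name = "tl_AB")),
    cotranscribed = list(
      reaction(products = c(A = 1L), law = rl_mass_action(k),
               modifiers = "m12", class = "translation", name = "tl_A"),
      reaction(products = c(B = 1L), law = rl_mass_action(k),
               modifiers = "m12", class = "translation", name = "tl_B")),
    uncoupled = list(
      reaction(products = c(A = 1L), law = rl_mass_action(k),
               modifiers = "m1", class = "translation", name = "tl_A"),
      reaction(products = c(B = 1L), law = rl_mass_action(k),
               modifiers = "m2", class = "translation", name = "tl_B")))
}

expression_species <- function(mode, bursting, expr) {
  duty <- burst_duty_cycle(bursting)
  m_mean <- expr$k_tx / expr$delta_m
  p_mean <- round(expr$k_tl * m_mean / expr$k_deg)
  sp <- tibble::tibble(name = character(), initial = numeric(),
                       conserved = logical(), clamped = logical())
  add <- function(sp, name, initial, conserved = FALSE, clamped = FALSE)
    dplyr::bind_rows(sp, tibble::tibble(name = name, initial = initial,
                                        conserved = conserved,
                                        clamped = clamped))
  promoters <- if (mode == "uncoupled") c("gA", "gB") else "g"
  if (bursting$enabled)
    for (p in promoters) {
      sp <- add(sp, paste0(p, "_on"), 1, conserved = TRUE)
      sp <- add(sp, paste0(p, "_off"), 0, conserved = TRUE)
    }
  mrnas <- if (mode == "uncoupled") c("m1", "m2") else "m12"
  for (m in mrnas) sp <- add(sp, m, round(m_mean))
  sp <- add(sp, "A", p_mean)
  add(sp, "B", p_mean)
}

#' Build a two-gene expression system for one coupling configuration
#'
#' Produces the reaction system for proteins A and B expressed either from
#' one operon (a single promoter and one polycistronic mRNA `m12`, with one
#' shared translation channel when `mode = "cotranslated"` or two
#' independent ribosome binding sites when `mode = "cotranscribed"`), or
#' from two independent transcription units (`mode = "uncoupled"`, mRNAs
#' `m1`, `m2`). All mRNAs degrade at `delta_m` and proteins at `k_deg`.
#'
#' @param mode one of [coupling_modes()].
#' @param bursting a [bursting_params()] object.
#' @param expr an [expression_params()] object.
#' @param omega cell volume (fL).
#' @return a [reaction_system()].
#' @export
build_expression <- function(mode = coupling_modes(),
                             bursting = bursting_params(),
                             expr = expression_params(), omega = 1) {
  mode <- match.arg(mode)
  sp <- expression_species(mode, bursting, expr)
  units <- if (mode == "uncoupled")
    list(c("gA", "m1"), c("gB", "m2")) else list(c("g", "m12"))
  rxns <- purrr::flatten(purrr::map(units, function(u)
    expression_unit(u[1], u[2], bursting, expr)))
  rxns <- c(rxns, translation_rxns(mode, expr), list(
    reaction(reactants = c(A = 1L), law = rl_mass_action(expr$k_deg),
             class = "protein_deg", name = "deg_A"),
    reaction(reactants = c(B = 1L), law = rl_mass_action(expr$k_deg),
             class = "protein_deg", name = "deg_B")))
  reaction_system(species_table(sp$name, sp$initial, sp$conserved, sp$clamped),
                  rxns, omega = omega)
}

#' Default kinetic parameters for each interaction module class
#'
#' Versioned defaults chosen to put each module in its physiologically
#' motivated regime at the low expression preset (~53 proteins/gene):
#' metabolic enzymes near saturation (substrate ~10x K_m, mean
#' production/consumption capacity ratio ~0.8), strong heterodimer binding
#' (K_d ~ 0.1 copies), covalent modification flux >= 10x the degradation
#' flux. See the methods vignette for the rationale behind every value.
#'
#' @param cls a module class from [module_classes()].
#' @return named list of kinetic constants.
#' @export
module_defaults <- function(cls) {
  cls <- match.arg(cls, module_classes())
  switch(cls,
    linear_pathway = list(S = 1000, k_cat1 = 0.02, K_m1 = 100,
                          k_cat2 = 0.0227, K_m2 = 25, k_out = 0.01),
    redundant_enzymes = list(S = 1000, k_cat1 = 0.01, K_m1 = 100,
                             k_cat2 = 0.01, K_m2 = 100, k_out = 0.005),
    branch_point = list(J = 1.5, k_cat1 = 0.0236, K_m1 = 20,
                        k_cat2 = 0.0236, K_m2 = 20, k_out = 0.01),
    dual_regulators_or = list(V_max = 0.01, K = 53, n = 2, delta_mp = 0.005,
                              k_tl_p = 0.02, k_deg_p = log(2) / 1800),
    physical_interaction = list(k_b = 0.01, k_unb = 0.001),
    covalent_modification = list(k_p = 0.002, k_demod = 0.02,
                                 k_cat_p = 0.0094, K_p = 5,
                                 V_d = 0.5, K_d = 5),
    lac_reduced = list(L_ext = 50000, k_cat_y = 0.05, K_m_y = 5e4,
                       k_cat_z1 = 0.1, K_m_z1 = 500,
                       k_cat_z2 = 0.1, K_m_z2 = 500, k_out = 0.01,
                       R_tot = 10, k_ra = 0.001, k_rd = 0.1,
                       K_R = 2, n_R = 2))
}

#' Designated readout species of each module class
#'
#' The physiologically relevant output whose noise difference between
#' configurations the theory predicts: metabolic intermediate `I`
#' (linear pathway), product `P` (redundant enzymes, OR-gate regulators),
#' substrate `s` (branch point), free monomer `A` (physical interaction),
#' unmodified protein `A` (covalent modification), allolactose `Alac`
#' (reduced lac cascade).
#'
#' @inheritParams module_defaults
#' @return species name.
#' @export
module_readout <- function(cls) {
  cls <- match.arg(cls, module_classes())
  c(linear_pathway = "I", redundant_enzymes = "P", branch_point = "s",
    dual_regulators_or = "P", physical_interaction = "A",
    covalent_modification = "A", lac_reduced = "Alac")[[cls]]
}

add_species <- function(sp, name, initial, conserved = FALSE,
                        clamped = FALSE) {
  dplyr::bind_rows(sp, tibble::tibble(name = name, initial = initial,
                                      conserved = conserved,
                                      clamped = clamped))
}

module_block <- function(cls, mod, mm_kinetics = FALSE, p_mean = 53,
                         bursting = NULL, expr = NULL, mode = NULL) {
  sp <- tibble::tibble(name = character(), initial = numeric(),
                       conserved = logical(), clamped = logical())
  rxns <- list()
  mmod <- function(...) reaction(..., class = "module")
  switch(cls,
    linear_pathway = {
      r <- mod$k_cat1 * p_mean * mod$S / (mod$K_m1 + mod$S) /
        (mod$k_cat2 * p_mean)
      sp <- add_species(sp, "S", mod$S, clamped = TRUE)
      sp <- add_species(sp, "I", round(mod$K_m2 * min(r, 0.95) / max(1 - r, 0.05)))
      sp <- add_species(sp, "P", 10)
      rxns <- list(
        mmod(reactants = c(S = 1L), products = c(I = 1L),
             law = rl_mm(mod$k_cat1, mod$K_m1, "S"), modifiers = "A",
             name = "S_to_I"),
        mmod(reactants = c(I = 1L), products = c(P = 1L),
             law = rl_mm(mod$k_cat2, mod$K_m2, "I"), modifiers = "B",
             name = "I_to_P"),
        mmod(reactants = c(P = 1L), law = rl_mass_action(mod$k_out),
             name = "P_removal"))
    },
    redundant_enzymes = {
      sp <- add_species(sp, "S", mod$S, clamped = TRUE)
      sp <- add_species(sp, "P", 10)
      rxns <- list(
        mmod(reactants = c(S = 1L), products = c(P = 1L),
             law = rl_mm(mod$k_cat1, mod$K_m1, "S"), modifiers = "A",
             name = "S_to_P_via_A"),
        mmod(reactants = c(S = 1L), products = c(P = 1L),
             law = rl_mm(mod$k_cat2, mod$K_m2, "S"), modifiers = "B",
             name = "S_to_P_via_B"),
        mmod(reactants = c(P = 1L), law = rl_mass_action(mod$k_out),
             name = "P_removal"))
    },
    branch_point = {
      sp <- add_species(sp, "s", 10)
      sp <- add_species(sp, "P1", 10)
      sp <- add_species(sp, "P2", 10)
      rxns <- list(
        mmod(products = c(s = 1L), law = rl_mass_action(mod$J),
             name = "s_influx"),
        mmod(reactants = c(s = 1L), products = c(P1 = 1L),
             law = rl_mm(mod$k_cat1, mod$K_m1, "s"), modifiers = "A",
             name = "s_to_P1"),
        mmod(reactants = c(s = 1L), products = c(P2 = 1L),
             law = rl_mm(mod$k_cat2, mod$K_m2, "s"), modifiers = "B",
             name = "s_to_P2"),
        mmod(reactants = c(P1 = 1L), law = rl_mass_action(mod$k_out),
             name = "P1_removal"),
        mmod(reactants = c(P2 = 1L), law = rl_mass_action(mod$k_out),
             name = "P2_removal"))
    },
    dual_regulators_or = {
      sp <- add_species(sp, "mP", 1)
      sp <- add_species(sp, "P", 50)
      rxns <- list(
        mmod(products = c(mP = 1L),
             law = rl_hill_or(mod$V_max, mod$K, mod$n, mod$K, mod$n,
                              "A", "B"), name = "tx_mP"),
        mmod(reactants = c(mP = 1L), law = rl_mass_action(mod$delta_mp),
             name = "deg_mP"),
        mmod(products = c(P = 1L), law = rl_mass_action(mod$k_tl_p),
             modifiers = "mP", name = "tl_P"),
        mmod(reactants = c(P = 1L), law = rl_mass_action(mod$k_deg_p),
             name = "deg_P"))
    },
    physical_interaction = {
      sp <- add_species(sp, "AB", round(p_mean * 0.9))
      rxns <- list(
        mmod(reactants = c(A = 1L, B = 1L), products = c(AB = 1L),
             law = rl_mass_action(mod$k_b), name = "bind"),
        mmod(reactants = c(AB = 1L), products = c(A = 1L, B = 1L),
             law = rl_mass_action(mod$k_unb), name = "unbind"),
        mmod(reactants = c(AB = 1L), law = rl_mass_action(expr$k_deg),
             name = "deg_AB"))
    },
    covalent_modification = {
      sp <- add_species(sp, "Astar", round(p_mean * 0.8))
      mod_rxn <- if (mm_kinetics)
        mmod(reactants = c(A = 1L), products = c(Astar = 1L),
             law = rl_mm(mod$k_cat_p, mod$K_p, "A"), modifiers = "B",
             name = "modify")
      else
        mmod(reactants = c(A = 1L), products = c(Astar = 1L),
             law = rl_mass_action(mod$k_p), modifiers = "B",
             name = "modify")
      demod_rxn <- if (mm_kinetics)
        mmod(reactants = c(Astar = 1L), products = c(A = 1L),
             law = rl_mm(mod$V_d, mod$K_d, "Astar"), name = "demodify")
      else
        mmod(reactants = c(Astar = 1L), products = c(A = 1L),
             law = rl_mass_action(mod$k_demod), name = "demodify")
      rxns <- list(mod_rxn, demod_rxn,
                   mmod(reactants = c(Astar = 1L),
                        law = rl_mass_action(expr$k_deg), name = "deg_Astar"))
    },
    lac_reduced = {
      sp <- add_species(sp, "Lext", mod$L_ext, clamped = TRUE)
      sp <- add_species(sp, "Lin", 100)
      sp <- add_species(sp, "Alac", 100)
      sp <- add_species(sp, "Prod", 100)
      sp <- add_species(sp, "R", mod$R_tot, conserved = TRUE)
      sp <- add_species(sp, "RA", 0, conserved = TRUE)
      rxns <- list(
        mmod(reactants = c(Lext = 1L), products = c(Lin = 1L),
             law = rl_mm(mod$k_cat_y, mod$K_m_y, "Lext"), modifiers = "A",
             name = "import"),
        mmod(reactants = c(Lin = 1L), products = c(Alac = 1L),
             law = rl_mm(mod$k_cat_z1, mod$K_m_z1, "Lin"), modifiers = "B",
             name = "convert"),
        mmod(reactants = c(Alac = 1L), products = c(Prod = 1L),
             law = rl_mm(mod$k_cat_z2, mod$K_m_z2, "Alac"), modifiers = "B",
             name = "cleave"),
        mmod(reactants = c(Prod = 1L), law = rl_mass_action(mod$k_out),
             name = "product_removal"),
        mmod(reactants = c(R = 1L, Alac = 1L), products = c(RA = 1L),
             law = rl_mass_action(mod$k_ra), name = "repressor_bind"),
        mmod(reactants = c(RA = 1L), products = c(R = 1L, Alac = 1L),
             law = rl_mass_action(mod$k_rd), name = "repressor_release"))
    },
    stop("unknown module class: ", cls))
  list(species = sp, reactions = rxns)
}

#' Build a full coupling-configuration + interaction-module system
#'
#' Appends the posttranslational reactions of a module class to the two-gene
#' expression system of the requested coupling mode. The posttranslational
#' reaction set and parameters are identical across modes, so coupled and
#' uncoupled systems differ only in transcription topology.
#'
#' For `lac_reduced`, A plays the permease (LacY) role and B the
#' beta-galactosidase (LacZ) role; transcription of both genes is gated by
#' the free repressor `R`, which the metabolic intermediate allolactose
#' (`Alac`) sequesters -- the positive-feedback topology of the lac operon.
#'
#' @param cls a module class from [module_classes()].
#' @param mode coupling mode.
#' @param bursting,expr,omega as in [build_expression()].
#' @param mod module kinetic constants; defaults to [module_defaults()].
#' @param mm_kinetics use saturating Michaelis--Menten kinetics for the
#'   covalent modification cycle (zero-order regime) instead of the default
#'   mass-action kinetics.
#' @return a [reaction_system()].
#' @export
build_module <- function(cls, mode = coupling_modes(),
                         bursting = bursting_params(),
                         expr = expression_params(),
                         mod = NULL, mm_kinetics = FALSE, omega = 1) {
  cls <- match.arg(cls, module_classes())
  mode <- match.arg(mode)
  mod <- mod %||% module_defaults(cls)
  p_mean <- expr$k_tl * expr$k_tx / expr$delta_m / expr$k_deg

  sp <- expression_species(mode, bursting, expr)
  if (cls == "lac_reduced") {
    # repressor-gated transcription replaces the constitutive law
    duty <- burst_duty_cycle(bursting)
    tx_law <- rl_hill(expr$k_tx / duty, mod$K_R, mod$n_R, "R",
                      repressor = TRUE)
    units <- if (mode == "uncoupled")
      list(c("gA", "m1"), c("gB", "m2")) else list(c("g", "m12"))
    rxns <- purrr::flatten(purrr::map(units, function(u)
      expression_unit(u[1], u[2], bursting, expr, tx_law = tx_law)))
  } else {
    units <- if (mode == "uncoupled")
      list(c("gA", "m1"), c("gB", "m2")) else list(c("g", "m12"))
    rxns <- purrr::flatten(purrr::map(units, function(u)
      expression_unit(u[1], u[2], bursting, expr)))
  }
  rxns <- c(rxns, translation_rxns(mode, expr), list(
    reaction(reactants = c(A = 1L), law = rl_mass_action(expr$k_deg),
             class = "protein_deg", name = "deg_A"),
    reaction(reactants = c(B = 1L), law = rl_mass_action(expr$k_deg),
             class = "protein_deg", name = "deg_B")))
  blk <- module_block(cls, mod, mm_kinetics = mm_kinetics, p_mean = p_mean,
                      bursting = bursting, expr = expr, mode = mode)
  sp <- dplyr::bind_rows(sp, blk$species)
  rxns <- c(rxns, blk$reactions)
  sys <- reaction_system(
    species_table(sp$name, sp$initial, sp$conserved, sp$clamped),
    rxns, omega = omega)
  attr(sys, "module_class") <- cls
  attr(sys, "coupling_mode") <- mode
  sys
}

# species making up the total protein of each gene, per module class
gene_totals <- function(cls) {
  base <- list(A = "A", B = "B")
  if (is.null(cls)) return(base)
  switch(cls,
    physical_interaction = list(A = c("A", "AB"), B = c("B", "AB")),
    covalent_modification = list(A = c("A", "Astar"), B = "B"),
    base)
}

#' Construct a matched coupled/uncoupled comparison pair
#'
#' Builds two systems that differ only in transcription topology: one in the
#' requested coupled mode (cotranslated by default, mirroring the main-text
#' comparisons) and one uncoupled, sharing all expression and
#' posttranslational parameters.
#'
#' @param cls module class, or `NULL` for the pure two-gene expression pair.
#' @param coupled_mode `"cotranslated"` or `"cotranscribed"`.
#' @inheritParams build_module
#' @return an object of class `comparison_pair` with `coupled_system`,
#'   `uncoupled_system`, `readout`, `totals`, `module_class`.
#' @export
comparison_pair <- function(cls = NULL,
                            coupled_mode = c("cotranslated", "cotranscribed"),
                            bursting = bursting_params(),
                            expr = expression_params(), mod = NULL,
                            mm_kinetics = FALSE, omega = 1) {
  coupled_mode <- match.arg(coupled_mode)
  if (is.null(cls)) {
    cup <- build_expression(coupled_mode, bursting, expr, omega)
    unc <- build_expression("uncoupled", bursting, expr, omega)
    readout <- c("A", "B")
  } else {
    cls <- match.arg(cls, module_classes())
    cup <- build_module(cls, coupled_mode, bursting, expr, mod, mm_kinetics,
                        omega)
    unc <- build_module(cls, "uncoupled", bursting, expr, mod, mm_kinetics,
                        omega)
    readout <- module_readout(cls)
  }
  structure(list(coupled_system = cup, uncoupled_system = unc,
                 readout = readout, totals = gene_totals(cls),
                 module_class = cls, coupled_mode = coupled_mode,
                 bursting = bursting, expr = expr,
                 mod = mod %||% if (!is.null(cls)) module_defaults(cls)),
            class = "comparison_pair")
}

#' @export
print.comparison_pair <- function(x, ...) {
  cat("<comparison_pair> ", x$module_class %||% "expression only", ": ",
      x$coupled_mode, " vs uncoupled; readout ",
      paste(x$readout, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Check that coupled and uncoupled configurations are matched controls
#'
#' For each gene, the total protein (free plus bound/modified forms) mean
#' and CV must agree between configurations within `tol_sigma` Monte-Carlo
#' standard errors -- this is the control that makes noise differences in
#' module outputs attributable to coupling topology alone.
#'
#' @param pair a [comparison_pair()].
#' @param ensemble_coupled,ensemble_uncoupled stationary ensembles (already
#'   windowed with [stationary_window()]) for the two systems.
#' @param tol_sigma tolerance in combined-SE units.
#' @return tibble with one row per gene and statistic (`mean`, `cv`), the
#'   two estimates, the z-score, and `pass`; the whole report carries a
#'   `pass` attribute.
#' @export
verify_matched_controls <- function(pair, ensemble_coupled,
                                    ensemble_uncoupled, tol_sigma = 3) {
  rows <- purrr::map_dfr(names(pair$totals), function(gene) {
    tot <- pair$totals[[gene]]
    sc <- total_protein_stats(ensemble_coupled, tot)
    su <- total_protein_stats(ensemble_uncoupled, tot)
    tibble::tibble(
      gene = gene,
      statistic = c("mean", "cv"),
      coupled = c(sc$mean, sc$cv),
      uncoupled = c(su$mean, su$cv),
      z = c((sc$mean - su$mean) / sqrt(sc$se_mean^2 + su$se_mean^2),
            (sc$cv - su$cv) / sqrt(sc$se_cv^2 + su$se_cv^2)))
  })
  rows$pass <- abs(rows$z) <= tol_sigma
  attr(rows, "pass") <- all(rows$pass)
  rows
}

# mean/CV (with bootstrap SEs over trajectories) of a sum of species
total_protein_stats <- function(ensemble, species, n_boot = 400) {
  idx <- match(species, ensemble$species)
  stopifnot(!anyNA(idx))
  per_mean <- vapply(ensemble$trajectories, function(m)
    mean(rowSums(m[, idx, drop = FALSE])), numeric(1))
  per_m2 <- vapply(ensemble$trajectories, function(m)
    mean(rowSums(m[, idx, drop = FALSE])^2), numeric(1))
  stat <- function(w) {
    mu <- mean(per_mean[w]); v <- mean(per_m2[w]) - mu^2
    c(mu, if (mu > 0 && v > 0) sqrt(v) / mu else 0)
  }
  n <- length(per_mean)
  est <- stat(seq_len(n))
  bs <- vapply(seq_len(n_boot), function(b)
    stat(sample.int(n, n, replace = TRUE)), numeric(2))
  list(mean = est[1], cv = est[2],
       se_mean = stats::sd(bs[1, ]), se_cv = stats::sd(bs[2, ]))
}

#' Apply a global extrinsic-noise perturbation to a system
#'
#' Draws one multiplier per rate class (by default transcription and
#' translation), uniform on `[1 - cv_ext, 1 + cv_ext]`, and applies it to
#' every reaction of that class -- both genes see the same factor, mimicking
#' global extrinsic noise in expression machinery. Simulating an ensemble
#' where each run uses a freshly perturbed system is supported directly by
#' [simulate_ensemble()]'s `extrinsic` argument.
#'
#' @param system a [reaction_system()].
#' @param cv_ext relative half-width in `[0, 0.5]`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param classes reaction classes to perturb.
#' @return a perturbed [reaction_system()].
#' @export
randomize_extrinsic <- function(system, cv_ext, seed = NULL,
                                classes = c("transcription", "translation")) {
  stopifnot(cv_ext >= 0, cv_ext <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (cv_ext == 0) return(system)
  mult <- stats::setNames(stats::runif(length(classes), 1 - cv_ext,
                                       1 + cv_ext), classes)
  rxns <- purrr::map(system$reactions, function(r) {
    if (!r$class %in% classes) return(r)
    f <- mult[[r$class]]
    r$law <- scale_law(r$law, f)
    r
  })
  reaction_system(system$species, rxns, omega = system$omega)
}

scale_law <- function(law, f) {
  switch(law$kind,
    mass_action = { law$k <- law$k * f; law },
    michaelis_menten = { law$k_cat <- law$k_cat * f; law },
    hill = { law$V_max <- law$V_max * f; law },
    hill_or = { law$V_max <- law$V_max * f; law })
}
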