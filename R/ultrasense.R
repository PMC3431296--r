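# Zero-order / titration ultrasensitivity analysis: mean-field response of a
# module readout to the production/consumption flux-capacity ratio V+/V-,
# maximum logarithmic sensitivity, flux-ratio traces on stochastic
# trajectories, and threshold-crossing / spike statistics.

ultra_readout <- function(cls) {
  c(linear_pathway = "I", branch_point = "s", physical_interaction = "A",
    covalent_modification = "A", redundant_enzymes = "P")[[cls]]
}

# module-only deterministic system at a prescribed flux ratio, with protein
# levels held at their mean (p_mean copies per gene)
ratio_system <- function(cls, mod, r, p_mean, k_deg = log(2) / 1800) {
  switch(cls,
    linear_pathway = {
      vminus <- mod$k_cat2 * p_mean
      sat1 <- mod$S / (mod$K_m1 + mod$S)
      k1 <- r * vminus / (p_mean * sat1)
      reaction_system(
        species_table(c("S", "A", "B", "I", "P"),
                      c(mod$S, p_mean, p_mean, 1, 1),
                      clamped = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
        list(reaction(reactants = c(S = 1L), products = c(I = 1L),
                      law = rl_mm(k1, mod$K_m1, "S"), modifiers = "A"),
             reaction(reactants = c(I = 1L), products = c(P = 1L),
                      law = rl_mm(mod$k_cat2, mod$K_m2, "I"), modifiers = "B"),
             reaction(reactants = c(P = 1L), law = rl_mass_action(mod$k_out))))
    },
    redundant_enzymes = {
      vminus <- mod$k_out # linear removal; ratio rescales the influx
      sat <- mod$S / (mod$K_m1 + mod$S)
      flux <- (mod$k_cat1 + mod$k_cat2) * p_mean * sat
      # readout P* = r * flux / k_out: output proportional to the ratio
      reaction_system(
        species_table(c("S", "A", "B", "P"), c(mod$S, p_mean, p_mean, 1),
                      clamped = c(TRUE, TRUE, TRUE, FALSE)),
        list(reaction(products = c(P = 1L), law = rl_mass_action(r * flux)),
             reaction(reactants = c(P = 1L), law = rl_mass_action(mod$k_out))))
    },
    branch_point = {
      vminus <- (mod$k_cat1 + mod$k_cat2) * p_mean
      reaction_system(
        species_table(c("A", "B", "s", "P1", "P2"),
                      c(p_mean, p_mean, 1, 1, 1),
                      clamped = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
        list(reaction(products = c(s = 1L), law = rl_mass_action(r * vminus)),
             reaction(reactants = c(s = 1L), products = c(P1 = 1L),
                      law = rl_mm(mod$k_cat1, mod$K_m1, "s"), modifiers = "A"),
             reaction(reactants = c(s = 1L), products = c(P2 = 1L),
                      law = rl_mm(mod$k_cat2, mod$K_m2, "s"), modifiers = "B"),
             reaction(reactants = c(P1 = 1L), law = rl_mass_action(mod$k_out)),
             reaction(reactants = c(P2 = 1L), law = rl_mass_action(mod$k_out))))
    },
    physical_interaction = {
      pB <- k_deg * p_mean # production flux matching mean B
      reaction_system(
        species_table(c("A", "B", "AB"), c(1, 1, 1)),
        list(reaction(products = c(A = 1L), law = rl_mass_action(r * pB)),
             reaction(products = c(B = 1L), law = rl_mass_action(pB)),
             reaction(reactants = c(A = 1L, B = 1L), products = c(AB = 1L),
                      law = rl_mass_action(mod$k_b)),
             reaction(reactants = c(AB = 1L), products = c(A = 1L, B = 1L),
                      law = rl_mass_action(mod$k_unb)),
             reaction(reactants = c(A = 1L), law = rl_mass_action(k_deg)),
             reaction(reactants = c(B = 1L), law = rl_mass_action(k_deg)),
             reaction(reactants = c(AB = 1L), law = rl_mass_action(k_deg))))
    },
    covalent_modification = {
      # zero-order cycle: r = V+ / V- = V_d / (k_cat_p * B)
      B <- mod$V_d / (mod$k_cat_p * r)
      reaction_system(
        species_table(c("B", "A", "Astar"),
                      c(B, p_mean / 2, p_mean / 2),
                      clamped = c(TRUE, FALSE, FALSE)),
        list(reaction(reactants = c(A = 1L), products = c(Astar = 1L),
                      law = rl_mm(mod$k_cat_p, mod$K_p, "A"), modifiers = "B"),
             reaction(reactants = c(Astar = 1L), products = c(A = 1L),
                      law = rl_mm(mod$V_d, mod$K_d, "Astar"))))
    },
    stop("no response curve defined for class ", cls))
}

#' Mean-field response curve of a module readout to the flux ratio V+/V-
#'
#' For each grid value the relevant production flux is rescaled so the
#' production/consumption capacity ratio equals the grid value (with protein
#' levels held at their mean), and the mean-field steady state of the
#' readout is solved. Grid points with no finite steady state (flux
#' imbalance past saturation) are flagged as diverged.
#'
#' @param cls module class (`linear_pathway`, `redundant_enzymes`,
#'   `branch_point`, `physical_interaction`, `covalent_modification`).
#' @param mod module kinetic constants; defaults to [module_defaults()].
#' @param ratio_grid strictly increasing positive ratio values.
#' @param p_mean mean protein copies per gene at which the curve is taken.
#' @param k_deg protein degradation rate (physical-module production fluxes).
#' @return tibble of class `response_curve`: `ratio`, `output`, `diverged`.
#' @export
response_curve <- function(cls, mod = NULL,
                           ratio_grid = seq(0.1, 1.5, by = 0.05),
                           p_mean = 53, k_deg = log(2) / 1800) {
  cls <- match.arg(cls, module_classes())
  mod <- mod %||% module_defaults(cls)
  stopifnot(all(diff(ratio_grid) > 0), all(ratio_grid > 0))
  readout <- ultra_readout(cls)
  out <- purrr::map_dfr(ratio_grid, function(r) {
    sys <- ratio_system(cls, mod, r, p_mean, k_deg)
    ss <- steady_state_mean_field(sys)
    tibble::tibble(ratio = r,
                   output = if (ss$diverged) NA_real_ else ss$state[[readout]],
                   diverged = ss$diverged)
  })
  attr(out, "readout") <- readout
  attr(out, "module_class") <- cls
  class(out) <- c("response_curve", class(out))
  out
}

#' Maximum logarithmic sensitivity of a response curve
#'
#' `max |d ln(output) / d ln(ratio)|` by central finite differences over the
#' non-diverged, positive part of the curve. A module is called
#' ultrasensitive when this exceeds 1.
#'
#' @param curve a [response_curve()] result.
#' @return scalar sensitivity.
#' @export
effective_sensitivity <- function(curve) {
  ok <- !curve$diverged & is.finite(curve$output) & curve$output > 0
  if (sum(ok) < 3) stop("need at least 3 finite response points")
  lr <- log(curve$ratio[ok])
  lo <- log(curve$output[ok])
  n <- length(lr)
  slopes <- (lo[-(1:2)] - lo[seq_len(n - 2)]) / (lr[-(1:2)] - lr[seq_len(n - 2)])
  max(abs(slopes))
}

#' Flux-capacity ratio V+/V- along a trajectory
#'
#' Computes the class-specific production and consumption capacity fluxes
#' from the enzyme/protein copy numbers at every sample time. Capacities are
#' V_max-type fluxes (not instantaneous realized fluxes), so the
#' ultrasensitive threshold sits exactly at ratio 1:
#' * linear pathway: `V+ = k_cat1 A S/(K_m1+S)`, `V- = k_cat2 B`;
#' * branch point: `V+ = J`, `V- = k_cat1 A + k_cat2 B`;
#' * physical interaction / covalent modification: ratio of the protein
#'   production capacities, i.e. the mRNA ratio `m_A / m_B` (identically 1
#'   for a shared polycistronic mRNA).
#'
#' @param trajectory an `operon_trajectory` tibble or a state matrix with
#'   named columns.
#' @param cls module class.
#' @param mod module constants (defaults to [module_defaults()]).
#' @return numeric vector of ratios; undefined points (zero denominator)
#'   are NA.
#' @export
flux_ratio_trace <- function(trajectory, cls, mod = NULL) {
  cls <- match.arg(cls, module_classes())
  mod <- mod %||% module_defaults(cls)
  m <- if (is.matrix(trajectory)) trajectory else
    as.matrix(trajectory[, setdiff(names(trajectory), "time")])
  col <- function(nm) if (nm %in% colnames(m)) m[, nm] else NULL
  ratio <- switch(cls,
    linear_pathway = {
      vplus <- mod$k_cat1 * col("A") * mod$S / (mod$K_m1 + mod$S)
      vminus <- mod$k_cat2 * col("B")
      vplus / vminus
    },
    branch_point = {
      vminus <- mod$k_cat1 * col("A") + mod$k_cat2 * col("B")
      mod$J / vminus
    },
    physical_interaction = ,
    covalent_modification = {
      ma <- col("m1") %||% col("m12")
      mb <- col("m2") %||% col("m12")
      ma / mb
    },
    redundant_enzymes = {
      sat <- mod$S / (mod$K_m1 + mod$S)
      (mod$k_cat1 * col("A") + mod$k_cat2 * col("B")) * sat /
        (mod$k_out * col("P"))
    },
    stop("no flux ratio defined for class ", cls))
  ratio[!is.finite(ratio)] <- NA_real_
  ratio
}

#' Fraction of stationary time the flux ratio exceeds the threshold
#'
#' Pooled over all trajectories of a (windowed) ensemble: the fraction of
#' sample points with V+/V- > 1, the stochastic proxy for how often the
#' module crosses its ultrasensitive threshold.
#'
#' @param ensemble a windowed ensemble from the matching system.
#' @param cls,mod as in [flux_ratio_trace()].
#' @return list with `fraction`, `se` (binomial-style SE over trajectories),
#'   and `n_points`.
#' @export
crossing_probability <- function(ensemble, cls, mod = NULL) {
  per <- vapply(ensemble$trajectories, function(m) {
    colnames(m) <- ensemble$species
    rat <- flux_ratio_trace(m, cls, mod)
    mean(rat > 1, na.rm = TRUE)
  }, numeric(1))
  per <- per[is.finite(per)]
  list(fraction = mean(per), se = stats::sd(per) / sqrt(length(per)),
       n_points = length(per) * length(ensemble$times))
}

#' Detect spikes in a trajectory
#'
#' A spike is a run of consecutive samples during which the species exceeds
#' `threshold_mult` times the reference level (typically the ensemble
#' median) for at least `min_duration` seconds. Each event records its peak
#' and, when a flux-ratio trace is supplied, whether V+/V- exceeded 1 at any
#' point during the event.
#'
#' @param trajectory an `operon_trajectory` tibble or state matrix.
#' @param species species name.
#' @param reference baseline level (e.g. ensemble median of the species).
#' @param threshold_mult spike threshold multiplier (> 1), default 5.
#' @param min_duration minimum event duration in seconds, default 60.
#' @param times sample times (taken from the trajectory if present).
#' @param ratio optional flux-ratio trace aligned with the samples.
#' @return tibble with `start`, `end`, `peak`, `crossing`.
#' @export
detect_spikes <- function(trajectory, species, reference,
                          threshold_mult = 5, min_duration = 60,
                          times = NULL, ratio = NULL) {
  stopifnot(threshold_mult > 1)
  if (is.matrix(trajectory)) {
    x <- trajectory[, species]
    stopifnot(!is.null(times))
  } else {
    x <- trajectory[[species]]
    times <- times %||% trajectory$time
  }
  above <- x > threshold_mult * reference
  if (!any(above)) return(tibble::tibble(start = numeric(), end = numeric(),
                                         peak = numeric(), crossing = logical()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (times[ends] - times[starts] >= min_duration)
  purrr::map_dfr(which(keep), function(q) {
    i1 <- starts[q]; i2 <- ends[q]
    tibble::tibble(start = times[i1], end = times[i2],
                   peak = max(x[i1:i2]),
                   crossing = if (is.null(ratio)) NA else
                     any(ratio[i1:i2] > 1, na.rm = TRUE))
  })
}

#' Spike statistics over an ensemble
#'
#' Applies [detect_spikes()] to every trajectory using the pooled ensemble
#' median as the reference level and the module flux-ratio trace for the
#' crossing annotation.
#'
#' @param ensemble a windowed ensemble.
#' @param species readout species.
#' @param cls,mod module class/constants for the ratio annotation (optional).
#' @inheritParams detect_spikes
#' @return list with `n_events`, `rate` (events per second per trajectory),
#'   `frac_crossing` (fraction of events with V+/V- > 1), `events` tibble.
#' @export
spike_statistics <- function(ensemble, species, cls = NULL, mod = NULL,
                             threshold_mult = 5, min_duration = 60) {
  i <- match(species, ensemble$species)
  stopifnot(!is.na(i))
  ref <- stats::median(unlist(lapply(ensemble$trajectories,
                                     function(m) m[, i])))
  if (ref == 0) ref <- 1
  span <- diff(range(ensemble$times))
  ev <- purrr::map_dfr(seq_along(ensemble$trajectories), function(q) {
    m <- ensemble$trajectories[[q]]
    colnames(m) <- ensemble$species
    rat <- if (!is.null(cls)) flux_ratio_trace(m, cls, mod) else NULL
    e <- detect_spikes(m, species, ref, threshold_mult, min_duration,
                       times = ensemble$times, ratio = rat)
    if (nrow(e)) e$trajectory <- q
    e
  })
  list(n_events = nrow(ev),
       rate = nrow(ev) / (span * length(ensemble$trajectories)),
       frac_crossing = if (nrow(ev)) mean(ev$crossing, na.rm = TRUE) else NA,
       events = ev)
}
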