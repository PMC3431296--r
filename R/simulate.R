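#' @importFrom rlang %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib operonoise, .registration = TRUE
NULL

default_times <- function(t_end, n = 200) seq(0, t_end, length.out = n + 1)

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one trajectory of the chemical master equation. The same
#' `(system, seed, sampling grid)` triple always yields an identical
#' trajectory. If all propensities vanish the trajectory freezes at its last
#' state (this is not an error).
#'
#' @param system a [reaction_system()].
#' @param t_end end time in seconds (> 0).
#' @param sampling_times optional strictly increasing time grid starting at 0;
#'   defaults to 201 equally spaced points over `[0, t_end]`.
#' @param seed integer RNG seed.
#' @param init optional initial state (defaults to the species table).
#' @param max_events safety cap on the number of reaction events.
#' @return a tibble of class `operon_trajectory`: `time` plus one column per
#'   species.
#' @export
simulate_ssa <- function(system, t_end, sampling_times = NULL, seed = 1L,
                         init = NULL, max_events = Inf) {
  stopifnot(t_end > 0)
  times <- sampling_times %||% default_times(t_end)
  stopifnot(all(diff(times) > 0))
  x0 <- if (is.null(init)) initial_state(system) else as_state(system, init)
  set.seed(seed)
  m <- cpp_ssa(system$enc, x0, times, max_events)
  as_trajectory(m, times, system)
}

#' Approximate stochastic simulation by explicit tau-leaping
#'
#' Uses the epsilon-bounded relative-propensity-change leap criterion and
#' falls back to exact SSA steps whenever any reactant of an active reaction
#' has fewer than `exact_threshold` copies (default 10). Negative-count leap
#' proposals are rejected and retried with a halved leap.
#'
#' @inheritParams simulate_ssa
#' @param epsilon leap-control parameter in (0, 0.1].
#' @param exact_threshold copy-number threshold for exact fallback.
#' @return an `operon_trajectory` tibble (states are non-negative reals).
#' @export
simulate_tau_leap <- function(system, t_end, sampling_times = NULL, seed = 1L,
                              epsilon = 0.03, exact_threshold = 10,
                              init = NULL) {
  stopifnot(t_end > 0, epsilon > 0, epsilon <= 0.1)
  times <- sampling_times %||% default_times(t_end)
  x0 <- if (is.null(init)) initial_state(system) else as_state(system, init)
  set.seed(seed)
  m <- cpp_tau_leap(system$enc, x0, times, epsilon, exact_threshold)
  as_trajectory(m, times, system)
}

as_trajectory <- function(m, times, system) {
  colnames(m) <- system$species$name
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  class(out) <- c("operon_trajectory", class(out))
  attr(out, "species") <- system$species$name
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' A master seed deterministically spawns one sub-seed per run, so the
#' ensemble is reproducible regardless of execution order. By default each
#' trajectory starts from the species table's initial copies; supply
#' `init = "steady_state"` to start from the mean-field fixed point (with
#' conserved promoter units drawn from their stationary occupancy), which
#' shortens the burn-in needed for stationary statistics.
#'
#' @inheritParams simulate_ssa
#' @param n_runs number of trajectories.
#' @param method `"ssa"` or `"tau"`.
#' @param init `NULL`, `"steady_state"`, or a state vector.
#' @param extrinsic optional list `list(cv_ext=, classes=)` passed to
#'   [randomize_extrinsic()]: each run simulates a freshly perturbed system.
#' @param epsilon tau-leap control (when `method = "tau"`).
#' @return an object of class `operon_ensemble`: list with `trajectories`
#'   (list of state matrices), `times`, `species`, `seeds`.
#' @export
simulate_ensemble <- function(system, n_runs, t_end, sampling_times = NULL,
                              seed = 1L, method = c("ssa", "tau"),
                              init = NULL, extrinsic = NULL, epsilon = 0.03) {
  method <- match.arg(method)
  stopifnot(n_runs >= 1)
  times <- sampling_times %||% default_times(t_end)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  x0 <- resolve_init(system, init)
  promoters <- promoter_units(system)
  trajs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    sys_i <- system
    if (!is.null(extrinsic)) {
      sys_i <- randomize_extrinsic(system, cv_ext = extrinsic$cv_ext,
                                   seed = NULL,
                                   classes = extrinsic$classes %||%
                                     c("transcription", "translation"))
    }
    xi <- draw_promoter_states(sys_i, x0, promoters)
    m <- if (method == "ssa") cpp_ssa(sys_i$enc, xi, times, Inf)
         else cpp_tau_leap(sys_i$enc, xi, times, epsilon, 10)
    colnames(m) <- system$species$name
    trajs[[i]] <- m
  }
  structure(list(trajectories = trajs, times = times,
                 species = system$species$name, seeds = seeds),
            class = "operon_ensemble")
}

#' @export
print.operon_ensemble <- function(x, ...) {
  cat("<operon_ensemble> ", length(x$trajectories), " trajectories, ",
      length(x$times), " sample times, species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

resolve_init <- function(system, init) {
  if (is.null(init)) return(initial_state(system))
  if (identical(init, "steady_state")) {
    ss <- steady_state_mean_field(system)
    if (ss$diverged) stop("no finite steady state; cannot initialize there")
    return(ss$state)
  }
  as_state(system, init)
}

# conserved 0/1 promoter pairs (name_on/name_off built by the expression
# builders); used to round a mean-field start into a valid integer state
promoter_units <- function(system) {
  nm <- system$species$name
  on <- grep("_on$", nm, value = TRUE)
  units <- list()
  for (o in on) {
    off <- sub("_on$", "_off", o)
    if (off %in% nm) units[[length(units) + 1L]] <- c(on = o, off = off)
  }
  units
}

draw_promoter_states <- function(system, x0, promoters) {
  xi <- round(x0)
  for (u in promoters) {
    p_on <- x0[[u[["on"]]]] # mean-field occupancy in [0,1]
    state_on <- stats::rbinom(1L, 1L, min(max(p_on, 0), 1))
    xi[[u[["on"]]]] <- state_on
    xi[[u[["off"]]]] <- 1L - state_on
  }
  pmax(xi, 0)
}

#' Extract the stationary window of an ensemble
#'
#' Discards the first `burn_in_fraction` of every trajectory and flags
#' non-stationarity when the ensemble mean of the first and second halves of
#' the retained window differ by more than `flag_sigma` pooled standard
#' errors for any species.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param burn_in_fraction fraction in [0, 1) of each trajectory to drop.
#' @param flag_sigma stationarity flag threshold in pooled SE units.
#' @return an `operon_ensemble` restricted to the retained window, with
#'   attributes `stationary_flag` (logical, TRUE means suspicious drift) and
#'   `drift_z` (per-species z-scores).
#' @export
stationary_window <- function(ensemble, burn_in_fraction = 0.5,
                              flag_sigma = 3) {
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  nt <- length(ensemble$times)
  keep <- ensemble$times >= ensemble$times[1] +
    burn_in_fraction * (ensemble$times[nt] - ensemble$times[1])
  if (!any(keep)) stop("empty stationary window")
  out <- ensemble
  out$times <- ensemble$times[keep]
  out$trajectories <- lapply(ensemble$trajectories,
                             function(m) m[keep, , drop = FALSE])
  ntk <- sum(keep)
  half <- seq_len(ntk) <= ntk / 2
  # per-trajectory half-window means; drift tested across trajectories
  n_traj <- length(out$trajectories)
  z <- vapply(seq_along(ensemble$species), function(i) {
    m1 <- vapply(out$trajectories, function(m) mean(m[half, i]), numeric(1))
    m2 <- vapply(out$trajectories, function(m) mean(m[!half, i]), numeric(1))
    if (n_traj >= 8) { # drift tested across independent trajectories
      d <- m2 - m1
      se <- stats::sd(d) / sqrt(length(d))
      if (se == 0) 0 else mean(d) / se
    } else {           # single/few runs: pooled within-window standard error
      x1 <- unlist(lapply(out$trajectories, function(m) m[half, i]))
      x2 <- unlist(lapply(out$trajectories, function(m) m[!half, i]))
      se <- sqrt(stats::var(x1) / length(x1) + stats::var(x2) / length(x2))
      if (!is.finite(se) || se == 0) 0 else (mean(x2) - mean(x1)) / se
    }
  }, numeric(1))
  names(z) <- ensemble$species
  attr(out, "drift_z") <- z
  attr(out, "stationary_flag") <- any(abs(z) > flag_sigma)
  out
}

#' Write a trajectory as TSV
#'
#' @param trajectory an `operon_trajectory` tibble.
#' @param path output file.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
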