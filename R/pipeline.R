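# Configuration-driven orchestration: build -> simulate -> summarize ->
# compare -> report for the coupling/noise track, and the enrichment /
# median-split bioinformatic track. Every stochastic step draws its seed
# deterministically from the config seed.

#' Build a comparison run configuration
#'
#' @param cls module class from [module_classes()].
#' @param coupled_mode `"cotranslated"` (default, the main-text comparison)
#'   or `"cotranscribed"`.
#' @param bursting logical: promoter bursting on/off. The default (off)
#'   matches the regime of the analytical noise theory, where expression
#'   noise arises from low mRNA copy numbers; bursting comparisons are
#'   available but push the near-threshold metabolic readouts into strongly
#'   bimodal regimes where the CV is a misleading summary.
#' @param n_runs trajectories per configuration (>= 1).
#' @param t_end run length in seconds.
#' @param burn_in burn-in fraction.
#' @param seed master seed.
#' @param level expression preset level.
#' @param with_lna also compute the LNA noise difference (on the
#'   no-bursting counterpart systems, where the approximation applies).
#' @param with_spikes spike statistics for metabolic readouts.
#' @param n_boot bootstrap resamples for summary error bars.
#' @return a `run_config` list.
#' @export
run_config <- function(cls, coupled_mode = "cotranslated", bursting = FALSE,
                       n_runs = 2000, t_end = 24000, burn_in = 0.5,
                       seed = 1L, level = "low", with_lna = TRUE,
                       with_spikes = cls %in% c("linear_pathway",
                                                "branch_point"),
                       n_boot = 1000) {
  cls <- match.arg(cls, module_classes())
  if (n_runs < 1) stop("n_runs must be >= 1")
  stopifnot(t_end > 0, burn_in >= 0, burn_in < 1)
  structure(list(cls = cls, coupled_mode = coupled_mode,
                 bursting = bursting, n_runs = n_runs, t_end = t_end,
                 burn_in = burn_in, seed = as.integer(seed), level = level,
                 with_lna = with_lna, with_spikes = with_spikes,
                 n_boot = n_boot),
            class = "run_config")
}

#' Run a full coupled-vs-uncoupled noise comparison
#'
#' Builds the matched pair of systems, simulates stationary ensembles of
#' both (starting from the mean-field steady state), summarizes noise,
#' computes the SSA noise difference `CV2_uncoupled - CV2_cotranscribed`
#' for the module readout with bootstrap z-scores, the LNA counterpart, the
#' matched-controls report, and (for metabolic readouts) threshold-crossing
#' and spike statistics. Re-running with an identical config reproduces all
#' numbers exactly.
#'
#' @param config a [run_config()].
#' @return object of class `comparison_report`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  burst <- if (config$bursting) bursting_params() else no_bursting()
  expr <- expression_preset(config$level)
  pair <- comparison_pair(config$cls, config$coupled_mode,
                          bursting = burst, expr = expr)
  ens_c <- simulate_ensemble(pair$coupled_system, config$n_runs,
                             config$t_end, seed = seeds[1],
                             init = "steady_state")
  ens_u <- simulate_ensemble(pair$uncoupled_system, config$n_runs,
                             config$t_end, seed = seeds[2],
                             init = "steady_state")
  win_c <- stationary_window(ens_c, config$burn_in)
  win_u <- stationary_window(ens_u, config$burn_in)
  sum_c <- summarize_ensemble(win_c, n_boot = config$n_boot)
  sum_u <- summarize_ensemble(win_u, n_boot = config$n_boot)
  readout <- pair$readout
  dc <- dplyr::inner_join(
    dplyr::select(sum_u$species, species, cv2_uncoupled = "cv2",
                  sd_uncoupled = "sd_cv2"),
    dplyr::select(sum_c$species, species, cv2_cotranscribed = "cv2",
                  sd_cotranscribed = "sd_cv2"),
    by = "species")
  dc <- dplyr::mutate(dc,
    value = .data$cv2_uncoupled - .data$cv2_cotranscribed,
    se = sqrt(.data$sd_uncoupled^2 + .data$sd_cotranscribed^2),
    z = .data$value / .data$se)
  pred <- vapply(dc$species, function(sp)
    tryCatch(predict_sign(config$cls, sp), error = function(e) NA_character_),
    character(1))
  dc$predicted_sign <- unname(pred)
  dc$verdict <- dplyr::case_when(
    is.na(dc$predicted_sign) | dc$predicted_sign == "small_either" ~ NA,
    dc$predicted_sign == "positive" ~ dc$z > 0,
    dc$predicted_sign == "negative" ~ dc$z < 0)
  lna <- if (config$with_lna) {
    pair_nb <- comparison_pair(config$cls, config$coupled_mode,
                               bursting = no_bursting(), expr = expr)
    tryCatch(delta_cv2(pair_nb, readout), error = function(e) NULL)
  }
  controls <- verify_matched_controls(pair, win_c, win_u)
  spikes <- crossing <- NULL
  if (config$with_spikes) {
    spikes <- list(
      coupled = spike_statistics(win_c, readout, config$cls),
      uncoupled = spike_statistics(win_u, readout, config$cls))
  }
  if (config$cls %in% c("linear_pathway", "branch_point",
                        "physical_interaction", "covalent_modification",
                        "redundant_enzymes")) {
    crossing <- list(coupled = crossing_probability(win_c, config$cls),
                     uncoupled = crossing_probability(win_u, config$cls))
  }
  structure(list(config = config, readout = readout,
                 delta_cv2 = dc,
                 summary_coupled = sum_c, summary_uncoupled = sum_u,
                 lna = lna, controls = controls, spikes = spikes,
                 crossing = crossing, seeds = seeds),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$config$cls, " (", x$config$coupled_mode,
      " vs uncoupled, n_runs = ", x$config$n_runs, ")\n", sep = "")
  print(dplyr::filter(x$delta_cv2, .data$species %in% x$readout))
  invisible(x)
}

#' Tidy a comparison report into one row per species
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  dplyr::mutate(x$delta_cv2, module_class = x$config$cls,
                readout = .data$species %in% x$readout)
}

#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  ro <- dplyr::filter(x$delta_cv2, .data$species %in% x$readout)
  tibble::tibble(module_class = x$config$cls, readout = x$readout[1],
                 delta_cv2 = ro$value[1], z = ro$z[1],
                 sign_ok = ro$verdict[1],
                 controls_pass = attr(x$controls, "pass"))
}

#' Run the bioinformatic enrichment / median-split track
#'
#' Consumes gene/pair tables (for the operon-enrichment randomization test)
#' and/or an expression table (for the median split with bootstrap test and
#' per-bin error bars); missing tables are generated synthetically from the
#' specs in `synth`.
#'
#' @param genes,pairs,expression optional tables (see [read_gene_table()]
#'   formats).
#' @param synth optional list of generator specs with elements `universe`
#'   (n_genes, mu_size), `pairs` (n_pairs, f_target), `expression` (n_rows,
#'   beta, ...); used for any table not supplied.
#' @param alternative direction for the randomization test.
#' @param n_reps randomization replicates.
#' @param n_boot bootstrap replicates for the difference test.
#' @param seed master seed.
#' @return list with `enrichment` (a `randomization_result` and its
#'   verdict) and/or `split` (median-split, bootstrap p, bin error bars).
#' @export
run_enrichment <- function(genes = NULL, pairs = NULL, expression = NULL,
                           synth = NULL, alternative = "greater",
                           n_reps = 1000, n_boot = 10000, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6L)
  out <- list()
  if (is.null(genes) && !is.null(synth$universe))
    genes <- do.call(gen_universe, c(synth$universe, list(seed = seeds[1])))
  if (is.null(pairs) && !is.null(synth$pairs) && !is.null(genes))
    pairs <- do.call(gen_pairs, c(list(universe = genes), synth$pairs,
                                  list(seed = seeds[2])))
  if (!is.null(genes) && !is.null(pairs)) {
    rr <- randomize_pairs(pairs, genes, n_reps = n_reps, seed = seeds[3],
                          alternative = alternative)
    verdict <- if (is.na(rr$p) || rr$p >= 0.05) "not significant" else
      if (alternative == "greater") "Coupled" else "Uncoupled"
    out$enrichment <- list(test = rr, verdict = verdict)
  }
  if (is.null(expression) && !is.null(synth$expression))
    expression <- do.call(gen_expression, c(synth$expression,
                                            list(seed = seeds[4])))
  if (!is.null(expression)) {
    ms <- median_split(expression)
    bt <- bootstrap_diff_test(expression, n_reps = n_boot, seed = seeds[5])
    edges <- stats::quantile(expression$copy_number,
                             probs = seq(0, 1, length.out = 7))
    bars <- bin_errorbars(expression, unique(unname(edges)), seed = seeds[6])
    out$split <- list(median_split = ms, p_boot = bt$p_boot, bins = bars)
  }
  if (!length(out)) stop("no tables supplied or generated")
  out
}

#' Write pipeline reports to disk
#'
#' `write_comparison_report()` writes the per-species noise-difference table
#' as CSV and the report verdict plus provenance (config, seeds) as JSON;
#' `write_enrichment_json()` writes a [run_enrichment()] result as JSON.
#' Payloads depend only on the config, so identical configs produce
#' byte-identical files.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @return the output paths, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(report$config$cls, "_delta_cv2.csv"))
  utils::write.csv(report$delta_cv2, csv, row.names = FALSE)
  js <- file.path(dir, paste0(report$config$cls, "_report.json"))
  payload <- list(config = unclass(report$config),
                  seeds = report$seeds,
                  readout = report$readout,
                  glance = as.list(glance(report)),
                  controls_pass = attr(report$controls, "pass"),
                  crossing = report$crossing)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

#' @rdname write_comparison_report
#' @param result a [run_enrichment()] result.
#' @param path output JSON path.
#' @export
write_enrichment_json <- function(result, path) {
  payload <- list()
  if (!is.null(result$enrichment))
    payload$enrichment <- c(as.list(tidy(result$enrichment$test)),
                            list(verdict = result$enrichment$verdict))
  if (!is.null(result$split))
    payload$split <- c(as.list(tidy(result$split$median_split)),
                       list(p_boot = result$split$p_boot,
                            bins = result$split$bins))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
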