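# Synthetic-data generators: gene/operon universes, interacting-pair tables
# with controlled same-operon enrichment, and single-cell copy-number tables
# with a planted (logistic) expression--coupling relationship. These emulate
# the structure of curated operon/interaction datasets so the enrichment and
# median-split machinery can be exercised and calibrated without downloads.

#' Generate a gene/operon universe
#'
#' Genes are partitioned into operons whose sizes follow a geometric law
#' with mean `mu_size`, truncated at `max_size`. `mu_size = 1` makes every
#' gene its own operon.
#'
#' @param n_genes number of genes (>= 2).
#' @param mu_size mean operon size (>= 1).
#' @param max_size truncation for operon sizes.
#' @param seed RNG seed.
#' @return tibble with `gene`, `operon_id`.
#' @export
gen_universe <- function(n_genes, mu_size = 3, max_size = 15, seed = 1L) {
  stopifnot(n_genes >= 2, mu_size >= 1, max_size >= 1)
  set.seed(seed)
  sizes <- integer(0)
  total <- 0L
  while (total < n_genes) {
    s <- if (mu_size == 1) 1L else
      min(1L + stats::rgeom(1L, prob = 1 / mu_size), max_size)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (total - n_genes)
  sizes <- sizes[sizes > 0]
  tibble::tibble(
    gene = sprintf("g%05d", seq_len(n_genes)),
    operon_id = sprintf("op%04d", rep(seq_along(sizes), sizes)))
}

#' Generate an interacting-pair table with controlled operon enrichment
#'
#' Each pair is drawn within an operon with probability `f_target` (uniform
#' over all unordered within-operon gene pairs) and between operons
#' otherwise; `f_target = NULL` draws unordered gene pairs uniformly at
#' random, ignoring operon structure (the unbiased null used for
#' calibration). The realized same-operon fraction is binomial around the
#' target.
#'
#' @param universe a [gen_universe()] table.
#' @param n_pairs number of pairs.
#' @param f_target target same-operon fraction in `[0, 1]`, or `NULL`.
#' @param seed RNG seed.
#' @return pair tibble (`gene_a`, `gene_b`, `same_operon`).
#' @export
gen_pairs <- function(universe, n_pairs, f_target = NULL, seed = 1L) {
  stopifnot(n_pairs >= 1)
  set.seed(seed)
  genes <- universe$gene
  opi <- as.integer(factor(universe$operon_id))
  ng <- length(genes)
  draw_unbiased <- function(m, forbid_same_operon = FALSE) {
    a <- sample.int(ng, m, replace = TRUE)
    b <- sample.int(ng, m, replace = TRUE)
    bad <- if (forbid_same_operon) which(opi[a] == opi[b]) else which(a == b)
    while (length(bad)) {
      b[bad] <- sample.int(ng, length(bad), replace = TRUE)
      bad <- bad[if (forbid_same_operon) opi[a[bad]] == opi[b[bad]]
                 else a[bad] == b[bad]]
    }
    cbind(a, b)
  }
  if (is.null(f_target)) {
    ab <- draw_unbiased(n_pairs)
  } else {
    stopifnot(f_target >= 0, f_target <= 1)
    # all within-operon unordered pairs, uniform over the pool
    ords <- split(seq_len(ng), opi)
    ords <- ords[lengths(ords) >= 2]
    if (f_target > 0 && length(ords) == 0)
      stop("infeasible f_target: no multi-gene operons in the universe")
    pool <- if (length(ords))
      do.call(cbind, lapply(ords, function(ix) utils::combn(ix, 2)))
    else matrix(integer(), 2, 0)
    within <- stats::runif(n_pairs) < f_target
    ab <- matrix(0L, n_pairs, 2)
    if (any(within)) {
      k <- sample.int(ncol(pool), sum(within), replace = TRUE)
      ab[within, ] <- cbind(pool[1, k], pool[2, k])
    }
    if (any(!within)) ab[!within, ] <- draw_unbiased(sum(!within), TRUE)
  }
  tibble::tibble(gene_a = genes[ab[, 1]], gene_b = genes[ab[, 2]],
                 same_operon = opi[ab[, 1]] == opi[ab[, 2]])
}

#' Generate a single-cell copy-number table with a planted coupling trend
#'
#' Copy numbers are log-normal (`log10(copies) ~ Normal(mu_log10,
#' sigma_log10)`), and the probability that a gene's interaction partner is
#' in the same operon follows
#' `logistic(baseline_logodds + beta * log10(copies))`; `beta < 0` plants
#' the trend of higher coupling frequency at lower expression.
#'
#' @param n_rows number of gene rows.
#' @param mu_log10,sigma_log10 log10 copy-number distribution parameters.
#' @param beta log-odds of same-operon interaction per unit log10 copies.
#' @param baseline_logodds intercept at log10(copies) = 0.
#' @param seed RNG seed.
#' @return expression tibble (`gene`, `copy_number`,
#'   `same_operon_interaction`).
#' @export
gen_expression <- function(n_rows, mu_log10 = 1.5, sigma_log10 = 1,
                           beta = -1, baseline_logodds = 0.65, seed = 1L) {
  stopifnot(sigma_log10 > 0, n_rows >= 4)
  set.seed(seed)
  lg <- stats::rnorm(n_rows, mu_log10, sigma_log10)
  cn <- 10^lg
  p <- stats::plogis(baseline_logodds + beta * lg)
  tibble::tibble(gene = sprintf("g%05d", seq_len(n_rows)),
                 copy_number = cn,
                 same_operon_interaction = stats::rbinom(n_rows, 1L, p))
}

#' Default kinetic fixture for a module class
#'
#' Bundles the versioned kinetic defaults of [module_defaults()] with the
#' expression preset (low/mid/high mean protein copies 53/529/5285) and the
#' measured promoter switching rates (k_goff = 0.0028 1/s,
#' k_gon = 0.00045 1/s) into one reproducible parameter fixture.
#'
#' @param cls module class.
#' @param level expression preset level.
#' @param bursting enable promoter bursting in the fixture.
#' @return list with `expr`, `mod`, `bursting`, `cls`.
#' @export
gen_module_fixture <- function(cls, level = "low", bursting = TRUE) {
  cls <- match.arg(cls, module_classes())
  list(cls = cls,
       expr = expression_preset(level),
       mod = module_defaults(cls),
       bursting = if (bursting) bursting_params() else no_bursting())
}
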