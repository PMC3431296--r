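# Operon-enrichment statistics: same-operon fraction of interacting gene
# pairs, the flatten-permute-re-pair randomization test with parametric
# (normal-tail) p-values, the expression-level median split, and bootstrap
# tests / per-bin error bars.

#' Annotate a pair table with same-operon status
#'
#' @param pairs tibble/data frame with columns `gene_a`, `gene_b`.
#' @param genes tibble with columns `gene`, `operon_id` (one operon per
#'   gene, unique gene identifiers).
#' @return `pairs` with a logical `same_operon` column.
#' @export
annotate_pairs <- function(pairs, genes) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)),
            all(c("gene", "operon_id") %in% names(genes)),
            !anyDuplicated(genes$gene))
  if (any(pairs$gene_a == pairs$gene_b)) stop("self-pairs are not allowed")
  oa <- genes$operon_id[match(pairs$gene_a, genes$gene)]
  ob <- genes$operon_id[match(pairs$gene_b, genes$gene)]
  if (anyNA(oa) || anyNA(ob)) stop("pair references a gene absent from the gene table")
  dplyr::mutate(tibble::as_tibble(pairs), same_operon = oa == ob)
}

#' Fraction of interacting pairs sharing an operon
#'
#' @param pairs a pair table; if it lacks a `same_operon` column, a gene
#'   table must be supplied to derive it.
#' @param genes optional gene table for [annotate_pairs()].
#' @return the exact fraction (count same-operon / count all).
#' @export
same_operon_fraction <- function(pairs, genes = NULL) {
  if (nrow(pairs) == 0) stop("empty pair table")
  if (!"same_operon" %in% names(pairs)) {
    if (is.null(genes)) stop("need a gene table to derive same_operon")
    pairs <- annotate_pairs(pairs, genes)
  }
  mean(pairs$same_operon)
}

#' Flatten-permute-re-pair randomization test for operon enrichment
#'
#' Flattens the observed pair list into its gene multiset, randomly permutes
#' the genes and re-pairs consecutive entries, and recomputes the
#' same-operon fraction; repeated `n_reps` times. Operon identities stay
#' attached to the genes, so every replicate preserves the gene multiset and
#' the operon size distribution exactly. The randomized fractions are
#' approximately normal, giving a parametric one-sided p-value
#' `z = (f - mu_r) / sigma_r`. Permutations that produce a self-pair are
#' redrawn (and counted).
#'
#' @param pairs pair table (gene_a, gene_b).
#' @param genes gene table (gene, operon_id).
#' @param n_reps number of randomization replicates (>= 100).
#' @param seed RNG seed.
#' @param alternative `"greater"` (enrichment, coupled trend) or `"less"`
#'   (depletion, uncoupled trend).
#' @return object of class `randomization_result`: list with `f_observed`,
#'   `mu_r`, `sigma_r`, `n_reps`, `z`, `p`, `alternative`, `n_redraws`,
#'   `replicates`.
#' @export
randomize_pairs <- function(pairs, genes, n_reps = 1000, seed = 1L,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n_reps >= 100)
  pairs <- if ("same_operon" %in% names(pairs)) pairs else
    annotate_pairs(pairs, genes)
  f_obs <- mean(pairs$same_operon)
  flat <- c(pairs$gene_a, pairs$gene_b) # flattening g
  gi <- match(flat, genes$gene)         # gene identity, integer-coded
  op <- as.integer(factor(genes$operon_id))[gi]
  n <- length(flat)
  half <- n / 2
  ia <- seq_len(half)
  ib <- half + ia
  set.seed(seed)
  reps <- numeric(n_reps)
  n_redraws <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n)
      if (any(gi[idx[ia]] == gi[idx[ib]])) { n_redraws <- n_redraws + 1L; next }
      reps[b] <- mean(op[idx[ia]] == op[idx[ib]])
      break
    }
  }
  mu <- mean(reps)
  sg <- stats::sd(reps)
  z <- if (sg > 0) (f_obs - mu) / sg else NA_real_
  p <- if (is.na(z)) NA_real_ else
    if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
    else stats::pnorm(z)
  structure(list(f_observed = f_obs, mu_r = mu, sigma_r = sg,
                 n_reps = n_reps, z = z, p = p, alternative = alternative,
                 n_redraws = n_redraws, replicates = reps,
                 p_flagged = is.na(z)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("Operon-enrichment randomization test (", x$n_reps, " replicates)\n",
      "  f observed = ", signif(x$f_observed, 3),
      "; randomized mu = ", signif(x$mu_r, 3),
      " +/- ", signif(x$sigma_r, 3), "\n",
      "  z = ", signif(x$z, 4), ", one-sided p (", x$alternative, ") = ",
      format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy randomization_result
#' @export
tidy.randomization_result <- function(x, ...) {
  tibble::tibble(f_observed = x$f_observed, mu_r = x$mu_r,
                 sigma_r = x$sigma_r, z = x$z, p = x$p,
                 alternative = x$alternative, n_reps = x$n_reps)
}

#' @method glance randomization_result
#' @export
glance.randomization_result <- function(x, ...) tidy(x)

#' Median split of an expression table by copy number
#'
#' Rows with copy number at or below the median go to the low subset (a
#' deterministic, conservative tie rule for the `f_low > f_high`
#' alternative); the coupling fractions of the two subsets and their
#' difference are reported.
#'
#' @param table tibble with `copy_number` (> 0) and binary
#'   `same_operon_interaction` columns; >= 4 rows.
#' @return object of class `median_split_result`: list with `f_low`,
#'   `f_high`, `diff`, `n_low`, `n_high`, `median`.
#' @export
median_split <- function(table) {
  stopifnot(nrow(table) >= 4,
            all(c("copy_number", "same_operon_interaction") %in% names(table)),
            all(table$copy_number > 0))
  med <- stats::median(table$copy_number)
  low <- table$copy_number <= med
  if (all(low) || !any(low)) stop("degenerate split: all copy numbers equal")
  f_low <- mean(table$same_operon_interaction[low])
  f_high <- mean(table$same_operon_interaction[!low])
  structure(list(f_low = f_low, f_high = f_high, diff = f_low - f_high,
                 n_low = sum(low), n_high = sum(!low), median = med),
            class = "median_split_result")
}

#' @export
print.median_split_result <- function(x, ...) {
  cat("Median split: f_low = ", signif(x$f_low, 3), " (n = ", x$n_low,
      "), f_high = ", signif(x$f_high, 3), " (n = ", x$n_high,
      "), diff = ", signif(x$diff, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy median_split_result
#' @export
tidy.median_split_result <- function(x, ...)
  tibble::tibble(f_low = x$f_low, f_high = x$f_high, diff = x$diff,
                 n_low = x$n_low, n_high = x$n_high, median = x$median)

#' Bootstrap test for the low-vs-high coupling-frequency difference
#'
#' Resamples the rows of the expression table with replacement, recomputes
#' the median split and the difference `f_low - f_high` for every replicate,
#' and reports the one-sided bootstrap p-value for the alternative
#' `f_low > f_high` as the fraction of replicates with difference <= 0.
#'
#' @param table expression table as in [median_split()].
#' @param n_reps bootstrap replicates (>= 1000).
#' @param seed RNG seed.
#' @return list with `p_boot`, `diff_observed`, `replicates`.
#' @export
bootstrap_diff_test <- function(table, n_reps = 10000, seed = 1L) {
  stopifnot(n_reps >= 1000)
  obs <- median_split(table)
  n <- nrow(table)
  cn <- table$copy_number
  flag <- as.numeric(table$same_operon_interaction)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n_reps)
  reps <- vapply(seq_len(n_reps), function(b) {
    i <- idx[b, ]
    x <- cn[i]; y <- flag[i]
    med <- stats::median(x)
    low <- x <= med
    if (all(low) || !any(low)) return(NA_real_)
    mean(y[low]) - mean(y[!low])
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  list(p_boot = mean(reps <= 0), diff_observed = obs$diff,
       replicates = reps)
}

#' Per-bin coupling fraction with bootstrap error bars
#'
#' Bins rows by copy number, and within each bin resamples with replacement
#' up to the bin size `n_reps` times to give a bootstrap SD of the coupling
#' fraction. Empty bins are flagged and carry no bar; single-row bins get
#' SD 0 and a low-n flag.
#'
#' @param table expression table.
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @param n_reps bootstrap replicates per bin.
#' @param seed RNG seed.
#' @return tibble with `bin_low`, `bin_high`, `n`, `fraction`, `sd`,
#'   `flagged_low_n`.
#' @export
bin_errorbars <- function(table, bin_edges, n_reps = 1000, seed = 1L) {
  stopifnot(all(diff(bin_edges) > 0), length(bin_edges) >= 2)
  set.seed(seed)
  bins <- cut(table$copy_number, bin_edges, include.lowest = TRUE)
  purrr::map_dfr(seq_len(length(bin_edges) - 1), function(k) {
    w <- which(as.integer(bins) == k)
    nk <- length(w)
    if (nk == 0)
      return(tibble::tibble(bin_low = bin_edges[k], bin_high = bin_edges[k + 1],
                            n = 0L, fraction = NA_real_, sd = NA_real_,
                            flagged_low_n = TRUE))
    y <- as.numeric(table$same_operon_interaction[w])
    frac <- mean(y)
    sdv <- if (nk == 1) 0 else
      stats::sd(vapply(seq_len(n_reps), function(b)
        mean(y[sample.int(nk, nk, replace = TRUE)]), numeric(1)))
    tibble::tibble(bin_low = bin_edges[k], bin_high = bin_edges[k + 1],
                   n = nk, fraction = frac, sd = sdv,
                   flagged_low_n = nk < 5)
  })
}

#' Read the TSV interchange formats for gene, pair, and expression tables
#'
#' Headered TSV files with columns (gene, operon_id), (gene_a, gene_b), and
#' (gene, copy_number, same_operon_interaction) respectively.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_gene_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("gene", "operon_id") %in% names(tb)))
    stop("gene table must have columns: gene, operon_id")
  tb
}

#' @rdname read_gene_table
#' @export
read_pair_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("gene_a", "gene_b") %in% names(tb)))
    stop("pair table must have columns: gene_a, gene_b")
  tb
}

#' @rdname read_gene_table
#' @export
read_expression_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("gene", "copy_number", "same_operon_interaction") %in% names(tb)))
    stop("expression table must have columns: gene, copy_number, same_operon_interaction")
  tb
}

#' @rdname read_gene_table
#' @param table a tibble to write.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
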