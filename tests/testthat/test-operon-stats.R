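# Enrichment statistics: same-operon fractions, the flatten-permute-re-pair
# randomization test, median splits, bootstrap tests, per-bin error bars.

pair_table <- function(n_same, n_total) {
  tibble::tibble(gene_a = sprintf("a%04d", seq_len(n_total)),
                 gene_b = sprintf("b%04d", seq_len(n_total)),
                 same_operon = seq_len(n_total) <= n_same)
}

test_that("same-operon fractions are exact count ratios", {
  expect_equal(same_operon_fraction(pair_table(3, 6)), 0.5)
  expect_equal(signif(same_operon_fraction(pair_table(91, 2417)), 2), 0.038)
  expect_equal(signif(same_operon_fraction(pair_table(46, 201)), 2), 0.23)
  expect_error(same_operon_fraction(pair_table(0, 0)), "empty")
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          operon_id = c("o1", "o1", "o2"))
  pr <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"))
  expect_equal(same_operon_fraction(pr, genes), 0.5)
  # invariant to row order and to swapping the two gene columns
  pr2 <- tibble::tibble(gene_a = c("g3", "g2"), gene_b = c("g1", "g1"))
  expect_equal(same_operon_fraction(pr2, genes), 0.5)
  expect_error(annotate_pairs(tibble::tibble(gene_a = "g1", gene_b = "g1"),
                              genes), "self-pairs")
  expect_error(annotate_pairs(tibble::tibble(gene_a = "g1", gene_b = "gX"),
                              genes), "absent")
})

test_that("randomization preserves the gene multiset and flags degeneracy", {
  uni <- gen_universe(200, mu_size = 4, seed = 5)
  pr <- gen_pairs(uni, 150, f_target = 0.2, seed = 6)
  rr <- randomize_pairs(pr, uni, n_reps = 200, seed = 7)
  expect_equal(rr$f_observed, mean(pr$same_operon))
  expect_true(all(rr$replicates >= 0 & rr$replicates <= 1))
  expect_gte(rr$p, 0)
  # every gene its own operon: all replicates 0, p undefined and flagged
  singles <- gen_universe(100, mu_size = 1, seed = 8)
  pr0 <- gen_pairs(singles, 50, f_target = NULL, seed = 9)
  rr0 <- randomize_pairs(pr0, singles, n_reps = 150, seed = 10)
  expect_equal(rr0$mu_r, 0)
  expect_true(rr0$p_flagged)
  expect_error(randomize_pairs(pr, uni, n_reps = 10), "n_reps")
})

test_that("planted enrichment at database scale is overwhelmingly significant", {
  uni <- gen_universe(4000, mu_size = 5, seed = 123)
  pr <- gen_pairs(uni, 3938, f_target = 0.35, seed = 99)
  rr <- randomize_pairs(pr, uni, n_reps = 300, seed = 100)
  expect_gt(rr$f_observed, 0.3)
  expect_lt(rr$mu_r, 0.01)
  expect_lt(rr$p, 1e-6)
})

test_that("median split obeys its tie rule and degeneracy guards", {
  tb <- tibble::tibble(copy_number = c(1, 2, 3, 4, 5, 6),
                       same_operon_interaction = c(1, 0, 1, 0, 1, 0))
  ms <- median_split(tb)
  expect_equal(ms$n_low, 3) # values at the median go low
  expect_equal(ms$diff, ms$f_low - ms$f_high)
  expect_equal(ms$f_low, 2 / 3)
  # equal coupling in both halves
  tb2 <- tibble::tibble(copy_number = 1:8,
                        same_operon_interaction = rep(c(1, 0), 4))
  expect_equal(median_split(tb2)$diff, 0)
  # permutation invariance
  set.seed(1)
  tb3 <- tb2[sample.int(8), ]
  expect_equal(median_split(tb3)$diff, median_split(tb2)$diff)
  expect_error(median_split(tibble::tibble(copy_number = rep(2, 6),
                                           same_operon_interaction = 0)),
               "degenerate")
})

test_that("bootstrap difference test is stable in its replicate count", {
  tb <- gen_expression(200, beta = -1, seed = 30)
  p1 <- bootstrap_diff_test(tb, n_reps = 2000, seed = 31)$p_boot
  p2 <- bootstrap_diff_test(tb, n_reps = 4000, seed = 31)$p_boot
  expect_lt(abs(p1 - p2), 3 * sqrt(0.25 / 2000) + 1e-12)
  expect_error(bootstrap_diff_test(tb, n_reps = 10), "n_reps")
})

test_that("power rises monotonically with the planted effect size", {
  med_p <- vapply(c(0, -0.6, -1.5), function(beta) {
    ps <- vapply(1:25, function(i) {
      tb <- gen_expression(250, beta = beta, seed = 400 + i)
      bootstrap_diff_test(tb, n_reps = 1000, seed = 500 + i)$p_boot
    }, numeric(1))
    stats::median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
})

test_that("bin error bars follow the binomial spread", {
  all1 <- tibble::tibble(copy_number = runif(40, 1, 9),
                         same_operon_interaction = 1)
  bb <- bin_errorbars(all1, c(0, 10), n_reps = 200, seed = 1)
  expect_equal(bb$fraction, 1)
  expect_equal(bb$sd, 0)
  set.seed(2)
  q <- 0.3; n <- 200
  tb <- tibble::tibble(copy_number = runif(n, 1, 9),
                       same_operon_interaction = rbinom(n, 1, q))
  bb2 <- bin_errorbars(tb, c(0, 10), n_reps = 1000, seed = 3)
  expect_equal(bb2$sd, sqrt(mean(tb$same_operon_interaction) *
                              (1 - mean(tb$same_operon_interaction)) / n),
               tolerance = 0.2)
  one <- tibble::tibble(copy_number = c(1, 20),
                        same_operon_interaction = c(1, 0))
  bb3 <- bin_errorbars(one, c(0, 10, 30), n_reps = 100, seed = 4)
  expect_true(all(bb3$flagged_low_n))
  expect_equal(bb3$sd, c(0, 0))
  # empty bin flagged with no bar
  bb4 <- bin_errorbars(one, c(0, 10, 15, 30), n_reps = 100, seed = 5)
  expect_true(is.na(bb4$fraction[2]))
})

test_that("table TSV interchange round-trips with schema checks", {
  uni <- gen_universe(50, mu_size = 3, seed = 40)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(uni, path)
  expect_equal(read_gene_table(path), uni)
  expect_error(read_pair_table(path), "gene_a")
  tb <- gen_expression(20, seed = 41)
  write_table_tsv(tb, path)
  expect_equal(read_expression_table(path)$copy_number, tb$copy_number)
})
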