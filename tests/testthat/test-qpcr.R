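make_ct <- function(df, ref = "CPSF6") {
  attr(df, "reference_gene") <- ref
  df
}

test_that("dCT subtracts the reference gene per sample", {
  ct <- make_ct(data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3"),
    group = c("RM", "RM", "HN", "HN", "HN"),
    gene = c("CPSF6", "FOS", "CPSF6", "FOS", "FOS"),
    ct = c(22, 25, 21, 21, 30)))
  expect_warning(d <- compute_dct(ct), "s3")
  expect_equal(d$dct[d$sample_id == "s1"], 3)
  expect_equal(d$dct[d$sample_id == "s2"], 0)
  expect_false("s3" %in% d$sample_id)
})

test_that("ddCT folds follow the closed form and invert cleanly", {
  expect_equal(ddct_fold(3, 5), 4)
  expect_equal(ddct_fold(5, 5), 1)
  expect_equal(ddct_fold(3, 5) * ddct_fold(5, 3), 1, tolerance = 1e-15)
})

test_that("direction validation follows the cycle-count sign convention", {
  # fold > 1 in the reference: test expression lower, so test dCT higher
  expect_true(validate_reaction(6, 4, "higher-in-reference"))
  expect_false(validate_reaction(2, 4, "higher-in-reference"))
  expect_true(validate_reaction(2, 4, "higher-in-test"))
  # an exact tie never validates
  expect_false(validate_reaction(4, 4, "higher-in-reference"))
  expect_false(validate_reaction(4, 4, "higher-in-test"))
})

test_that("the one-tailed t-test is half the two-sided p in the predicted direction", {
  set.seed(8)
  ref <- rnorm(8, 4); test <- rnorm(8, 6)  # test dCT higher
  p1 <- group_ttest_one_tailed(test, ref, "higher-in-reference")
  p2 <- t.test(test, ref, var.equal = TRUE)$p.value
  expect_equal(p1, p2 / 2, tolerance = 1e-12)
  expect_equal(p1, pooled_t(test, ref, "greater"), tolerance = 1e-10)
  # identical groups sit at the null midpoint
  expect_equal(group_ttest_one_tailed(c(1, 2, 3), c(1, 2, 3),
                                      "higher-in-reference"), 0.5)
  expect_true(is.na(group_ttest_one_tailed(c(2, 2), c(2, 2),
                                           "higher-in-test")))
})

test_that("zero-noise cohorts validate perfectly and recover folds exactly", {
  folds <- c(FOS = 4, CLU = 0.25)
  ct <- generate_ct_table(folds, c(RM = 5, HN = 5), noise_sd = 0, seed = 2)
  sig <- data.frame(gene = c("FOS", "CLU"), fold = 1 / folds)  # RM over test
  rep <- summarize_validation(ct, sig)
  expect_equal(rep$overall$rate, 1)
  hn <- rep$per_gene[rep$per_gene$group == "HN", ]
  expect_equal(hn$fold[hn$gene == "FOS"], 4, tolerance = 1e-12)
  expect_equal(hn$fold[hn$gene == "CLU"], 0.25, tolerance = 1e-12)
})

test_that("validation is invariant to per-sample CT offsets", {
  folds <- c(FOS = 3)
  ct <- generate_ct_table(folds, c(RM = 6, HN = 6), noise_sd = 0.4, seed = 9)
  sig <- data.frame(gene = "FOS", predicted_direction = "higher-in-test")
  r1 <- summarize_validation(ct, sig)
  shifted <- ct
  for (s in unique(ct$sample_id)) {
    delta <- runif(1, -5, 5)
    shifted$ct[shifted$sample_id == s] <- ct$ct[ct$sample_id == s] + delta
  }
  shifted <- make_ct(shifted)
  r2 <- summarize_validation(shifted, sig)
  expect_equal(r1$overall$rate, r2$overall$rate)
  expect_equal(r1$per_gene$ddct, r2$per_gene$ddct, tolerance = 1e-10)
})

test_that("empty tables and unknown genes are handled gracefully", {
  empty <- make_ct(data.frame(sample_id = character(), group = character(),
                              gene = character(), ct = numeric()))
  rep <- summarize_validation(empty, data.frame(gene = "FOS", fold = 2))
  expect_equal(rep$overall$n_tested, 0L)
  expect_true(is.na(rep$overall$rate))

  ct <- generate_ct_table(c(FOS = 2, XYZ = 2), c(RM = 3, HN = 3),
                          noise_sd = 0, seed = 1)
  expect_warning(rep2 <- summarize_validation(ct, data.frame(gene = "FOS",
                                                             fold = 0.5)),
                 "XYZ")
  expect_false("XYZ" %in% rep2$per_gene$gene)
})

test_that("a prospective cohort with signature folds validates at the analytic rate", {
  # six validation genes with the printed microarray folds; test/ref planted
  # fold is the reciprocal of the RM:HN fold
  t2 <- load_table2()
  genes <- c("AHNAK", "ATF3", "BTG2", "CLU", "EGR1", "FOS")
  rm_hn <- sapply(genes, function(g) t2$fold_rm_hn[which(t2$symbol == g)[1]])
  noise <- 1.0
  ct <- generate_ct_table(setNames(1 / rm_hn, genes), c(RM = 8, HN = 17),
                          noise_sd = noise, seed = 13)
  rep <- summarize_validation(ct, data.frame(gene = genes, fold = rm_hn))
  # oracle: P(validate) = Phi(|log2 fold| / (noise * sqrt(1 + 1/8))) per
  # reaction; compare the pooled rate to a 3.5-sigma binomial band
  p_val <- pnorm(abs(log2(rm_hn)) / (noise * sqrt(1 + 1 / 8)))
  n <- rep$overall$n_tested
  expect_equal(n, 6L * 17L)
  exp_rate <- mean(p_val)
  se <- sqrt(exp_rate * (1 - exp_rate) / n)
  expect_lt(abs(rep$overall$rate - exp_rate), 3.5 * se + 0.02)
})
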