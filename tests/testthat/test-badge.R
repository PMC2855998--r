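cfg10k <- badge_config(n_draws = 10000, seed = 1)

test_that("identical groups score as undecided, fold near 1", {
  set.seed(1)
  x <- exp(rnorm(18, 5, 0.2))
  s <- score_probe(x, x, cfg10k, probe_id = "sym")
  expect_equal(s$p_greater, 0.5, tolerance = 0.02)
  expect_equal(s$p_value, 0.5, tolerance = 0.02)
  expect_equal(s$fold, 1, tolerance = 0.03)
  expect_equal(sum(s$model_weights), 1, tolerance = 1e-9)
})

test_that("swapping the groups flips the directional probability and inverts the fold", {
  set.seed(2)
  x <- exp(rnorm(18, 5, 0.2)); y <- exp(rnorm(18, 5.4, 0.2))
  a <- score_probe(x, y, cfg10k, probe_id = "fwd")
  b <- score_probe(y, x, cfg10k, probe_id = "rev")
  expect_equal(a$p_greater, 1 - b$p_greater, tolerance = 0.02)
  expect_equal(a$fold, 1 / b$fold, tolerance = 0.05)
  expect_equal(a$p_value, b$p_value, tolerance = 0.02)
})

test_that("a planted 2-fold at n=18 per group is decisively detected", {
  # oracle: exact two-sample z on the log scale with known variance says
  # the evidence is overwhelming (z approx 10), so p_value must be < 0.01
  sdlog <- sqrt(log(1 + 0.2^2))
  z <- log(2) / (sdlog * sqrt(2 / 18))
  expect_gt(z, 6)
  set.seed(11)
  g1 <- exp(rnorm(18, 5 + log(2), sdlog)); g2 <- exp(rnorm(18, 5, sdlog))
  s <- score_probe(g1, g2, cfg10k, probe_id = "planted")
  expect_lt(s$p_value, 0.01)
  expect_gt(s$fold, 1.5)
})

test_that("probe scores do not depend on evaluation order", {
  g <- generate_expression(sim_config(n_probes = 20, n_de = 4, seed = 3))
  em <- rescale_samples(g$matrix)
  cfg <- badge_config(n_draws = 1000, seed = 3)
  fwd <- score_matrix(em, "RM", "HN", cfg)
  rev_em <- em_subset(em, probes = rev(rownames(em$intensities)))
  bwd <- score_matrix(rev_em, "RM", "HN", cfg)
  bwd <- bwd[match(fwd$probe_id, bwd$probe_id), ]
  expect_equal(fwd$p_value, bwd$p_value, tolerance = 1e-12)
  expect_equal(fwd$fold, bwd$fold, tolerance = 1e-12)
})

test_that("p-values never exceed 0.5 and planted probes rank first", {
  # score the raw generated matrix: rescaling a tiny matrix with 10%
  # one-sided planted folds shifts every null probe (compositional effect)
  g <- generate_expression(sim_config(n_probes = 100, n_de = 10,
                                      fold_range = c(4, 4), cv = 0.15,
                                      seed = 5))
  em <- g$matrix
  sc <- score_matrix(em, "RM", "HN", badge_config(n_draws = 10000, seed = 5))
  expect_true(all(sc$p_value <= 0.5 + 1e-12))
  top10 <- sc$probe_id[order(sc$p_value)][1:10]
  expect_setequal(top10, g$truth$de_probe_ids)
})

test_that("posterior fold estimates recover planted folds within 15%", {
  g <- generate_expression(sim_config(n_probes = 60, n_de = 20, cv = 0.3,
                                      seed = 21))
  em <- g$matrix  # unscaled: see compositional note above
  sc <- score_matrix(em, "RM", "HN", badge_config(n_draws = 2000, seed = 21))
  de <- g$truth$de_probe_ids
  est <- sc$fold[match(de, sc$probe_id)]
  err <- abs(log(est / g$truth$fold_rm_hn[de]))
  # the mean-ratio estimator itself has sampling sd ~ sqrt(2*log(1+cv^2)/n)
  # (~10% here), so the 15% band is asserted on the average error and a
  # 3.5-sigma band per probe
  expect_lt(mean(err), log(1.15))
  expect_true(all(err < 3.5 * sqrt(2 * log(1 + 0.3^2) / 18)))
})

test_that("the lognormal family wins the model weights on lognormal data", {
  g <- generate_expression(sim_config(n_probes = 200, n_de = 0, cv = 0.25,
                                      n_pm = 0, family = "lognormal",
                                      seed = 17))
  sc <- score_matrix(g$matrix, "RM", "HN", badge_config(n_draws = 1000, seed = 17))
  expect_gte(mean(sc$weight_lognormal > 0.5), 0.8)
})

test_that("invalid inputs are refused with instructive errors", {
  expect_error(score_probe(c(0, 1, 2), c(1, 2, 3)), "floor")
  expect_error(score_probe(c(5), c(1, 2, 3)), "at least 2")
  expect_error(badge_config(n_draws = 10), "at least 1000")
  expect_error(badge_config(families = character(0)))
})

test_that("the log-scale t-test matches the textbook pooled formula", {
  # hand-checkable case: logs are {1,1,1,2} vs {3,3,3,4}; the pooled-variance
  # statistic is t = -2 / sqrt(0.25 * (1/4 + 1/4)) = -sqrt(32), df = 6
  g1 <- exp(c(1, 1, 1, 2)); g2 <- exp(c(3, 3, 3, 4))
  expect_equal(t_test_log(g1, g2), 2 * pt(-sqrt(32), 6), tolerance = 1e-12)
  expect_equal(t_test_log(g1, g2), pooled_t(log(g1), log(g2)),
               tolerance = 1e-10)
  # symmetric identical groups: p = 1
  expect_equal(t_test_log(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  # random input agrees with the oracle
  set.seed(4)
  a <- rexp(9, 0.01) + 1; b <- rexp(12, 0.02) + 1
  expect_equal(t_test_log(a, b), pooled_t(log(a), log(b)), tolerance = 1e-10)
  # zero pooled variance is flagged, not crashed
  expect_true(is.na(t_test_log(c(2, 2, 2), c(2, 2, 2))))
})

test_that("simple_fold is the ratio of group means", {
  expect_equal(simple_fold(c(300, 500), c(50, 150)), 4)
  expect_equal(simple_fold(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(5)
  a <- runif(7); b <- runif(9)
  expect_equal(simple_fold(a, b), mean(a) / mean(b), tolerance = 1e-15)
  expect_error(simple_fold(c(1, 2), c(0, 0)), "denominator")
})
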