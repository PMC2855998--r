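test_that("two samples merge once at their pairwise distance", {
  m <- matrix(c(3, 7), 1, 2, dimnames = list("p1", c("a", "b")))
  tree <- hcluster_samples(m, log_transform = FALSE)
  expect_equal(nrow(tree$merge), 1L)
  expect_equal(tree$height, 4)
  expect_error(hcluster_samples(m[, 1, drop = FALSE]), "at least 2")
})

test_that("forced geometry merges the close pair first", {
  m <- matrix(c(0, 1, 10), 1, 3, dimnames = list("p1", c("a", "b", "c")))
  tree <- hcluster_samples(m, log_transform = FALSE)
  expect_equal(sort(tree$merge[1, ]), c(-2L, -1L))
  part <- cut_two(tree)
  expect_setequal(part[[1]], c("a", "b"))
  expect_setequal(part[[2]], "c")
})

test_that("average and complete linkage agree with the reference implementation on tie-free data", {
  set.seed(6)
  for (linkage in c("average", "complete")) {
    m <- matrix(rnorm(80), 8, 10,
                dimnames = list(NULL, letters[1:10]))
    mine <- hcluster_samples(m, linkage = linkage, log_transform = FALSE)
    ref <- stats::hclust(stats::dist(t(m)), method = linkage)
    expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                 tolerance = 1e-9)
  }
})

test_that("identical samples cluster deterministically via the index tie-break", {
  m <- matrix(5, 2, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  t1 <- hcluster_samples(m)
  t2 <- hcluster_samples(m)
  expect_identical(t1$merge, t2$merge)
  # lowest-index pairs merge first: (1,2), then the {1,2} cluster with 3, ...
  expect_equal(t1$merge[1, ], c(-1L, -2L))
  expect_equal(cut_two(t1), list(c("w", "x", "y"), "z"))
})

test_that("clustering is invariant to probe order", {
  g <- generate_expression(sim_config(n_probes = 50, n_de = 10, seed = 4))
  em <- rescale_samples(g$matrix)
  t1 <- hcluster_samples(em)
  t2 <- hcluster_samples(em_subset(em, probes = rev(rownames(em$intensities))))
  expect_equal(stats::cophenetic(t1), stats::cophenetic(t2),
               tolerance = 1e-9)
})

test_that("well-separated groups are recovered exactly by the two-way cut", {
  g <- generate_expression(sim_config(n_probes = 50, n_de = 50,
                                      fold_range = c(4, 4), cv = 0.1,
                                      n_rm = 9, n_hn = 9, n_pm = 0,
                                      seed = 8))
  em <- rescale_samples(g$matrix)
  part <- cut_two(hcluster_samples(em))
  labs <- em$groups
  blocks <- lapply(part, function(b) sort(unique(unname(labs[b]))))
  expect_setequal(unlist(blocks), c("RM", "HN"))
  expect_true(all(lengths(blocks) == 1))
  pat <- concordance_pattern(part, labs, focal_group = "RM",
                             anchor_group = "HN")
  expect_equal(unname(pat), c(0L, 9L))
})

test_that("unknown probe subsets are refused", {
  g <- generate_expression(sim_config(n_probes = 10, n_de = 0, seed = 1))
  expect_error(hcluster_samples(g$matrix, probe_subset = c("nope", "nada")),
               "disjoint")
})

test_that("concordance patterns count the focal group against the anchor block", {
  part <- list(c("a", "b", "c"), c("d", "e"))
  labs <- c(a = "HN", b = "HN", c = "PM", d = "RM", e = "PM")
  expect_equal(unname(concordance_pattern(part, labs, "PM", "HN")),
               c(1L, 1L))
  expect_error(concordance_pattern(part, labs, "XX", "HN"), "absent")
  expect_error(concordance_pattern(part, labs[1:3], "PM", "HN"), "cover")
  # single focal sample: pattern sums to 1
  labs2 <- c(a = "HN", b = "HN", c = "HN", d = "RM", e = "PM")
  expect_equal(sum(concordance_pattern(part, labs2, "PM", "HN")), 1L)
})

test_that("permuting labels never alters the tree, and matches are counted reproducibly", {
  g <- generate_expression(sim_config(n_probes = 30, n_de = 10, n_rm = 4,
                                      n_hn = 4, n_pm = 0, seed = 10))
  em <- rescale_samples(g$matrix)
  labs <- em$groups
  r1 <- permutation_cluster_test(em, labels = labs, focal_group = "RM",
                                 anchor_group = "HN", n_permutations = 500,
                                 seed = 7)
  r2 <- permutation_cluster_test(em, labels = labs, focal_group = "RM",
                                 anchor_group = "HN", n_permutations = 500,
                                 seed = 7)
  expect_identical(r1$n_matches, r2$n_matches)
  # the tree is a function of the matrix only
  shuffled <- setNames(sample(unname(labs)), names(labs))
  r3 <- permutation_cluster_test(em, labels = shuffled, focal_group = "RM",
                                 anchor_group = "HN", n_permutations = 10,
                                 seed = 1)
  expect_identical(r1$tree$merge, r3$tree$merge)
  expect_equal(r1$tree$height, r3$tree$height)
  expect_error(permutation_cluster_test(em, labels = setNames(rep("RM", 8),
                                                              names(labs)),
                                        focal_group = "RM"),
               "two classes")
})

test_that("empirical match frequency agrees with exhaustive enumeration on 4+4 samples", {
  g <- generate_expression(sim_config(n_probes = 40, n_de = 40,
                                      fold_range = c(5, 5), cv = 0.1,
                                      n_rm = 4, n_hn = 4, n_pm = 0, seed = 12))
  em <- rescale_samples(g$matrix)
  labs <- em$groups
  tree <- hcluster_samples(em)
  part <- cut_two(tree)
  observed <- concordance_pattern(part, labs, "RM", "HN")
  expect_equal(unname(observed), c(0L, 4L))  # perfect separation

  # oracle: enumerate all C(8,4) = 70 labelings
  ids <- names(labs)
  combos <- utils::combn(8, 4)
  hits <- 0L
  for (k in seq_len(ncol(combos))) {
    lab <- setNames(rep("HN", 8), ids)
    lab[combos[, k]] <- "RM"
    if (all(concordance_pattern(part, lab, "RM", "HN") == observed))
      hits <- hits + 1L
  }
  exact <- hits / ncol(combos)
  expect_equal(exact, 2 / 70)  # the labeling and its complement

  r <- permutation_cluster_test(em, labels = labs, focal_group = "RM",
                                anchor_group = "HN",
                                n_permutations = 20000, seed = 3)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(r$match_frequency - exact), 3.5 * se)
})

test_that("spearman correlation matches an independent rank computation", {
  t2 <- load_table2()
  rho <- spearman_fold_correlation(t2$fold_rm_hn, t2$fold_rm_pm)
  expect_equal(rho, rank_rho(t2$fold_rm_hn, t2$fold_rm_pm),
               tolerance = 1e-12)
  x <- c(1, 2.5, 4, 8)
  expect_equal(spearman_fold_correlation(x, x), 1)
  expect_equal(spearman_fold_correlation(x, 1 / x), -1)
  expect_error(spearman_fold_correlation(x, rep(2, 4)), "constant")
  expect_error(spearman_fold_correlation(x, x[1:3]), "equal length")
})
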