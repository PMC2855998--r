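#!/usr/bin/env Rscript
# Stage 4: hierarchical clustering on the selected signature and the Monte
# Carlo label-permutation tests.
#
# Two questions, mirroring the study's two cluster analyses: (a) do RM and
# HN samples separate on the signature, and how often does random labelling
# reproduce the observed concordance pattern (10,000 permutations); (b) do
# the PM samples fall in the HN-majority block when all three groups are
# clustered jointly? Also reports the Spearman correlation of the two
# fold-change spectra over the signature.

suppressPackageStartupMessages(library(bmadex))

em <- read_expression_matrix("results/preprocessed_expression.tsv",
                             "results/preprocessed_detection.tsv")
sig <- read_results_table("results/signature.tsv")
sel <- sig$probe_id[sig$selected %in% TRUE]
stopifnot(length(sel) >= 2)

two_groups <- em_subset(em, samples = c(group_samples(em, "RM"),
                                        group_samples(em, "HN")))
rm_hn <- permutation_cluster_test(two_groups, probe_subset = sel,
                                  labels = two_groups$groups,
                                  focal_group = "RM", anchor_group = "HN",
                                  n_permutations = 10000, seed = 2024)
cat("RM vs HN clustering on the signature:\n")
print(rm_hn)

all3 <- permutation_cluster_test(em, probe_subset = sel,
                                 labels = em$groups,
                                 focal_group = "PM", anchor_group = "HN",
                                 n_permutations = 10000, seed = 2025)
cat("\nPM placement when all three groups are clustered:\n")
print(all3)
cat(sprintf("PM samples in the HN-majority block: %d of %d\n",
            all3$observed_pattern[["in_anchor_block"]],
            sum(em$groups == "PM")))

rmv <- group_samples(em, "RM"); hnv <- group_samples(em, "HN")
pmv <- group_samples(em, "PM")
ints <- em$intensities[sel, , drop = FALSE]
fold_hn <- rowMeans(ints[, rmv]) / rowMeans(ints[, hnv])
fold_pm <- rowMeans(ints[, rmv]) / rowMeans(ints[, pmv])
rho <- spearman_fold_correlation(fold_hn, fold_pm)
cat(sprintf("\nSpearman rho of RM:HN vs RM:PM fold changes over the signature: %.3f\n",
            rho))

summary <- data.frame(
  test = c("rm_vs_hn", "pm_with_hn"),
  pattern_in_anchor = c(rm_hn$observed_pattern[[1]], all3$observed_pattern[[1]]),
  pattern_out_anchor = c(rm_hn$observed_pattern[[2]], all3$observed_pattern[[2]]),
  n_permutations = c(rm_hn$n_permutations, all3$n_permutations),
  n_matches = c(rm_hn$n_matches, all3$n_matches),
  match_frequency = c(rm_hn$match_frequency, all3$match_frequency))
write.table(summary, "results/cluster_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
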