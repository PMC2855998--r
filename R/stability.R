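#' Select probes at a controlled false discovery rate
#'
#' Benjamini-Hochberg step-up on the Bayesian probability scores; probes
#' whose adjusted value is strictly below the threshold are selected.
#'
#' @param scores Data frame with `probe_id` and `p_value` columns (as from
#'   [score_matrix()]), or a numeric vector of p-values named by probe.
#' @param fdr_threshold FDR threshold (default 0.06); selection uses a
#'   strict `<`.
#' @return Character vector of selected probe ids.
#' @export
fdr_select <- function(scores, fdr_threshold = 0.06) {
  if (is.data.frame(scores)) {
    p <- scores$p_value
    ids <- scores$probe_id
  } else {
    p <- as.numeric(scores)
    ids <- names(scores)
  }
  if (!length(p)) stop("'scores' must be nonempty")
  adj <- stats::p.adjust(p, method = "BH")
  ids[adj < fdr_threshold]
}

#' Leave-one-out stability selection around the Bayesian scorer
#'
#' The extrinsic cross-validation wrapper: one run per left-out sample
#' (every sample of the two groups in turn, or one age-matched pair at a
#' time with `leave_out = "pair"`), each run scoring the remaining samples
#' and selecting probes at the FDR threshold; probes selected in at least
#' `frequency_threshold` of runs form the final signature. Final scores and
#' t-test p-values are computed once on all samples.
#'
#' @param em An [expression_matrix()].
#' @param group1,group2 Groups to compare.
#' @param config A [badge_config()].
#' @param fdr_threshold Per-run FDR threshold (default 0.06, strict `<`).
#' @param frequency_threshold Selection-frequency threshold (default 0.80,
#'   inclusive `>=`).
#' @param leave_out `"sample"` (default): each of the `n1 + n2` samples is
#'   left out once. `"pair"`: the i-th sample of each group is removed
#'   together (for matched designs), giving `min(n1, n2)` runs.
#' @return A `selection_result`: list with `probes` (data frame of
#'   per-probe `selection_count`, `selection_frequency`, `selected`, final
#'   `fold`, `p_greater`, `p_value`, `t_p_value`), `n_runs`,
#'   `fdr_threshold`, `frequency_threshold`.
#' @export
loo_stability <- function(em, group1 = "RM", group2 = "HN",
                          config = badge_config(), fdr_threshold = 0.06,
                          frequency_threshold = 0.80,
                          leave_out = c("sample", "pair")) {
  stopifnot(inherits(em, "expr_matrix"))
  leave_out <- match.arg(leave_out)
  s1 <- group_samples(em, group1)
  s2 <- group_samples(em, group2)
  if (length(s1) <= 2L || length(s2) <= 2L)
    stop("each group needs more than 2 samples so any single removal ",
         "leaves at least 2")
  all_samples <- c(s1, s2)
  sub <- em_subset(em, samples = all_samples)
  probes <- rownames(sub$intensities)
  counts <- stats::setNames(integer(length(probes)), probes)

  drops <- if (leave_out == "sample") as.list(all_samples)
           else lapply(seq_len(min(length(s1), length(s2))),
                       function(i) c(s1[i], s2[i]))
  for (drop in drops) {
    run <- em_subset(sub, samples = setdiff(all_samples, drop))
    sel <- fdr_select(score_matrix(run, group1, group2, config),
                      fdr_threshold)
    counts[sel] <- counts[sel] + 1L
  }
  n_runs <- length(drops)
  freq <- counts / n_runs

  final <- score_matrix(sub, group1, group2, config)
  t_p <- vapply(probes, function(pr) {
    t_test_log(pmax(sub$intensities[pr, s1], config$epsilon),
               pmax(sub$intensities[pr, s2], config$epsilon))
  }, numeric(1))

  probes_df <- data.frame(
    probe_id = probes,
    selection_count = unname(counts),
    selection_frequency = unname(freq),
    selected = unname(freq >= frequency_threshold),
    fold = final$fold, p_greater = final$p_greater,
    p_value = final$p_value, t_p_value = unname(t_p),
    stringsAsFactors = FALSE)

  structure(list(probes = probes_df, n_runs = n_runs,
                 fdr_threshold = fdr_threshold,
                 frequency_threshold = frequency_threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d probes, %d leave-one-out runs, FDR < %g, freq >= %g\n",
    nrow(x$probes), x$n_runs, x$fdr_threshold, x$frequency_threshold))
  cat(sprintf("  selected: %d probes\n", sum(x$probes$selected)))
  invisible(x)
}
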