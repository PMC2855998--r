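# Sign convention used throughout: CT is a cycle count, so LOWER dCT means
# HIGHER expression. A microarray fold > 1 in the reference group therefore
# predicts test-sample dCT ABOVE the reference-group mean dCT.

#' Per-sample dCT values
#'
#' dCT = test-gene CT minus reference-gene CT, per sample. Samples lacking a
#' reference-gene CT are excluded with a warning; sample-level offsets
#' (loading, RNA input) cancel in the subtraction.
#'
#' @param ct_table CT table data frame (`sample_id`, `group`, `gene`, `ct`)
#'   with attribute `reference_gene`, or pass `reference_gene` explicitly.
#' @param reference_gene Endogenous control gene name.
#' @return Data frame: `sample_id`, `group`, `gene`, `dct`.
#' @export
compute_dct <- function(ct_table, reference_gene = NULL) {
  if (is.null(reference_gene))
    reference_gene <- attr(ct_table, "reference_gene")
  if (is.null(reference_gene)) stop("no reference gene given")
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!nrow(ref)) stop("reference gene '", reference_gene,
                       "' absent from CT table")
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  test <- ct_table[ct_table$gene != reference_gene, , drop = FALSE]
  missing <- !(test$sample_id %in% names(ref_ct))
  if (any(missing)) {
    warning("excluding ", sum(missing),
            " reactions from samples lacking a reference CT: ",
            paste(unique(test$sample_id[missing]), collapse = ", "))
    test <- test[!missing, , drop = FALSE]
  }
  out <- data.frame(sample_id = test$sample_id, group = test$group,
                    gene = test$gene,
                    dct = test$ct - ref_ct[test$sample_id],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fold change from mean dCT values (the 2^-ddCT method)
#'
#' ddCT = mean test-group dCT minus mean reference-group dCT; the fold
#' change of the test group relative to the reference is `2^-ddCT`
#' (amplification efficiency assumed exactly 2).
#'
#' @param mean_dct_test,mean_dct_reference Finite group mean dCT values.
#' @return Fold change `2^-(mean_dct_test - mean_dct_reference)`.
#' @export
ddct_fold <- function(mean_dct_test, mean_dct_reference) {
  stopifnot(is.finite(mean_dct_test), is.finite(mean_dct_reference))
  2^-(mean_dct_test - mean_dct_reference)
}

#' Does one reaction validate the microarray direction?
#'
#' A test sample validates when its dCT sits on the side of the
#' reference-group mean dCT that the microarray fold predicts: expression
#' higher in the reference group predicts sample dCT above the reference
#' mean (lower expression, more cycles), and vice versa. An exact tie does
#' not validate.
#'
#' @param sample_dct dCT of the test sample (vectorised).
#' @param mean_reference_dct Mean dCT of the reference group.
#' @param predicted_direction `"higher-in-reference"` or `"higher-in-test"`.
#' @return Logical.
#' @export
validate_reaction <- function(sample_dct, mean_reference_dct,
                              predicted_direction = c("higher-in-reference",
                                                      "higher-in-test")) {
  predicted_direction <- match.arg(predicted_direction)
  if (predicted_direction == "higher-in-reference")
    sample_dct > mean_reference_dct
  else
    sample_dct < mean_reference_dct
}

#' One-tailed equal-variance t-test on group dCT values
#'
#' Pooled-variance two-sample t-test with the tail chosen by the predicted
#' direction: expression higher in the reference group means the test
#' group's dCT should be larger, so the alternative is
#' `mean(dcts_test) > mean(dcts_reference)` (and the converse otherwise).
#'
#' @param dcts_test,dcts_reference dCT values (at least 2 per group).
#' @param predicted_direction `"higher-in-reference"` or `"higher-in-test"`.
#' @return One-tailed p-value, or `NA` when the pooled variance is zero.
#' @export
group_ttest_one_tailed <- function(dcts_test, dcts_reference,
                                   predicted_direction = c(
                                     "higher-in-reference",
                                     "higher-in-test")) {
  predicted_direction <- match.arg(predicted_direction)
  if (length(dcts_test) < 2L || length(dcts_reference) < 2L)
    stop("each group needs at least 2 values")
  alt <- if (predicted_direction == "higher-in-reference") "greater" else "less"
  tryCatch(
    stats::t.test(dcts_test, dcts_reference, var.equal = TRUE,
                  alternative = alt)$p.value,
    error = function(e) NA_real_)
}

#' Validation report for a qPCR cohort against microarray predictions
#'
#' For every test gene and test group: mean dCT with its standard error,
#' ddCT against the reference group, the `2^-ddCT` fold, per-reaction
#' direction validation counts, and a one-tailed t-test p-value. The
#' overall validation rate pools all test reactions.
#'
#' @param ct_table CT table with attribute `reference_gene`.
#' @param signature Data frame giving the microarray prediction per gene:
#'   a `gene` column plus either `predicted_direction`
#'   (`"higher-in-reference"` / `"higher-in-test"`) or a `fold` column of
#'   reference-over-test microarray folds (> 1 means higher in reference).
#' @param reference_group Reference sample group (default `"RM"`).
#' @return A `validation_report`: list with `per_gene` (data frame) and
#'   `overall` (`n_validated`, `n_tested`, `rate`; rate is `NA` when no
#'   reactions were tested).
#' @export
summarize_validation <- function(ct_table, signature,
                                 reference_group = "RM") {
  if (is.null(signature$predicted_direction)) {
    if (is.null(signature$fold))
      stop("signature needs 'predicted_direction' or 'fold'")
    signature$predicted_direction <- ifelse(
      signature$fold > 1, "higher-in-reference", "higher-in-test")
  }
  dct <- if (nrow(ct_table)) compute_dct(ct_table) else
    data.frame(sample_id = character(), group = character(),
               gene = character(), dct = numeric())
  unknown <- setdiff(unique(dct$gene), signature$gene)
  if (length(unknown)) {
    warning("genes absent from signature skipped: ",
            paste(unknown, collapse = ", "))
    dct <- dct[dct$gene %in% signature$gene, , drop = FALSE]
  }
  rows <- list()
  total_val <- total_tested <- 0L
  for (gene in unique(dct$gene)) {
    g <- dct[dct$gene == gene, ]
    dir <- signature$predicted_direction[match(gene, signature$gene)]
    ref <- g$dct[g$group == reference_group]
    if (!length(ref)) next
    ref_mean <- mean(ref)
    for (grp in unique(g$group)) {
      d <- g$dct[g$group == grp]
      is_test <- grp != reference_group
      n_val <- if (is_test) sum(validate_reaction(d, ref_mean, dir)) else NA_integer_
      n_tst <- if (is_test) length(d) else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = grp, n = length(d),
        mean_dct = mean(d),
        sem_dct = stats::sd(d) / sqrt(length(d)),
        ddct = if (is_test) mean(d) - ref_mean else NA_real_,
        fold = if (is_test) ddct_fold(mean(d), ref_mean) else NA_real_,
        n_validated = n_val, n_tested = n_tst,
        validation_rate = if (is_test) n_val / n_tst else NA_real_,
        t_p_one_tailed = if (is_test && length(d) >= 2L && length(ref) >= 2L)
          group_ttest_one_tailed(d, ref, dir) else NA_real_,
        predicted_direction = dir, stringsAsFactors = FALSE)
      if (is_test) {
        total_val <- total_val + n_val
        total_tested <- total_tested + n_tst
      }
    }
  }
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), group = character())
  structure(list(
    per_gene = per_gene,
    overall = list(n_validated = total_val, n_tested = total_tested,
                   rate = if (total_tested > 0) total_val / total_tested
                          else NA_real_)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("validation_report: %s of %s reactions validated (%s)\n",
              o$n_validated, o$n_tested,
              if (is.na(o$rate)) "rate undefined"
              else sprintf("%.0f%%", 100 * o$rate)))
  invisible(x)
}
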