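# small builders shared across tests

make_em <- function(ints, groups, detection = NULL) {
  if (is.null(rownames(ints)))
    rownames(ints) <- sprintf("p%02d", seq_len(nrow(ints)))
  if (is.null(colnames(ints)))
    colnames(ints) <- sprintf("s%02d", seq_len(ncol(ints)))
  names(groups) <- colnames(ints)
  expression_matrix(ints, detection, groups)
}

# independent pooled-variance two-sample t-test (textbook formula), the
# oracle for t.test-based operations
pooled_t <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  switch(alternative,
         two.sided = 2 * stats::pt(-abs(t), df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df))
}

# independent Spearman rho via explicit mid-ranks and Pearson on ranks
rank_rho <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
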