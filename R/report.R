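#' Direction split of a signature table
#'
#' How many probe sets are higher in the reference group (fold above 1) and
#' how many in the other group (fold below 1); folds exactly 1 are counted
#' separately rather than forced into either side.
#'
#' @param table A signature table with a `fold_rm_hn` column (see
#'   [load_table2()]).
#' @return Named integer vector
#'   `c(n_higher_ref, n_higher_other, n_tied)`.
#' @export
direction_split <- function(table) {
  f <- table$fold_rm_hn
  stopifnot(all(f > 0))
  c(n_higher_ref = sum(f > 1), n_higher_other = sum(f < 1),
    n_tied = sum(f == 1))
}

#' Sign concordance between two contrasts
#'
#' Counts probe sets whose fold changes point the same way in both contrasts
#' (both above 1 or both below 1) - the check that the high-risk group's
#' expression resembles the case group's relative to the control.
#'
#' @param table A signature table with `fold_rm_hn` and `fold_rm_pm`
#'   columns.
#' @return List: `n_concordant`, `discordant` (data frame of the rows that
#'   disagree).
#' @export
cross_contrast_concordance <- function(table) {
  conc <- (table$fold_rm_hn > 1) == (table$fold_rm_pm > 1)
  list(n_concordant = sum(conc),
       discordant = table[!conc, , drop = FALSE])
}

#' Overlap with a prior probe-set list
#'
#' @param table A signature table with a logical `prior_study` column.
#' @return Count of flagged rows.
#' @export
prior_overlap <- function(table) {
  if (is.null(table$prior_study)) stop("no prior_study column")
  sum(table$prior_study)
}

#' Per-group age summaries
#'
#' @param sample_meta Data frame with `group` and `age` columns (see
#'   [load_table1()]). Samples with missing age are excluded with a
#'   warning.
#' @return Data frame per group: `n`, `mean_age` (full precision),
#'   `mean_age_1dp`, `min_age`, `max_age`.
#' @export
group_age_summary <- function(sample_meta) {
  if (any(is.na(sample_meta$age))) {
    warning("excluding ", sum(is.na(sample_meta$age)),
            " samples with missing age")
    sample_meta <- sample_meta[!is.na(sample_meta$age), , drop = FALSE]
  }
  groups <- unique(sample_meta$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    a <- sample_meta$age[sample_meta$group == g]
    data.frame(group = g, n = length(a), mean_age = mean(a),
               mean_age_1dp = round(mean(a), 1),
               min_age = min(a), max_age = max(a),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
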