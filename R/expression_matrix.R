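#' Construct an expression matrix with detection calls and group labels
#'
#' The central container of the pipeline: a probe-set by sample matrix of
#' MAS5-style linear-scale intensities, a parallel matrix of
#' Present/Marginal/Absent detection calls, and a group label (RM, HN or PM)
#' per sample. Optional per-sample metadata (age and the like) rides along in
#' `sample_meta`.
#'
#' @param intensities Numeric matrix, probes in rows, samples in columns.
#'   Row names are probe ids, column names are sample ids; all values must be
#'   finite and non-negative.
#' @param detection Character matrix of the same dimensions with entries in
#'   `"P"`, `"M"`, `"A"`. Defaults to all-Present when omitted.
#' @param groups Named character vector mapping every sample id to one of
#'   `"RM"`, `"HN"`, `"PM"`.
#' @param sample_meta Optional data frame of per-sample metadata with a
#'   `sample_id` column.
#' @return An object of class `expr_matrix`: a list with elements
#'   `intensities`, `detection`, `groups`, `sample_meta`.
#' @examples
#' x <- matrix(c(100, 200, 300, 400), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' em <- expression_matrix(x, groups = c(s1 = "RM", s2 = "HN"))
#' em
#' @export
expression_matrix <- function(intensities, detection = NULL, groups,
                              sample_meta = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  probe_ids <- rownames(intensities)
  sample_ids <- colnames(intensities)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("'intensities' must have probe row names and sample column names")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0")
  if (is.null(detection)) {
    detection <- matrix("P", nrow(intensities), ncol(intensities),
                        dimnames = dimnames(intensities))
  }
  if (!identical(dim(detection), dim(intensities)))
    stop("'detection' and 'intensities' must have identical dimensions")
  bad <- which(!(detection %in% c("P", "M", "A")))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(detection))
    stop(sprintf("unknown detection symbol '%s' at probe '%s', sample '%s'",
                 detection[bad[1L]], probe_ids[i[1L]], sample_ids[i[2L]]))
  }
  dimnames(detection) <- dimnames(intensities)
  groups <- groups[sample_ids]
  if (any(is.na(groups)))
    stop("every sample needs a group label; missing for: ",
         paste(sample_ids[is.na(groups)], collapse = ", "))
  if (!all(groups %in% c("RM", "HN", "PM")))
    stop("group labels must be RM, HN or PM")
  names(groups) <- sample_ids
  if (!is.null(sample_meta)) {
    if (!is.data.frame(sample_meta) || is.null(sample_meta$sample_id))
      stop("'sample_meta' must be a data frame with a sample_id column")
  }
  structure(list(intensities = intensities, detection = detection,
                 groups = groups, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(factor(x$groups, levels = c("RM", "HN", "PM")))
  cat(sprintf("expr_matrix: %d probe sets x %d samples (RM=%d, HN=%d, PM=%d)\n",
              nrow(x$intensities), ncol(x$intensities),
              tab[["RM"]], tab[["HN"]], tab[["PM"]]))
  cat(sprintf("  Present calls: %.1f%%\n", 100 * mean(x$detection == "P")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensities)

#' Subset an expression matrix by probes and/or samples
#'
#' @param x An `expr_matrix`.
#' @param probes Probe ids (or logical/integer index) to keep; default all.
#' @param samples Sample ids (or index) to keep; default all.
#' @return The subset `expr_matrix`.
#' @export
em_subset <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(probes)) probes <- rownames(x$intensities)
  if (is.null(samples)) samples <- colnames(x$intensities)
  ints <- x$intensities[probes, samples, drop = FALSE]
  det <- x$detection[probes, samples, drop = FALSE]
  meta <- x$sample_meta
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% colnames(ints), , drop = FALSE]
  expression_matrix(ints, det, x$groups[colnames(ints)], meta)
}

#' Sample ids belonging to a group
#'
#' @param x An `expr_matrix`.
#' @param group Group label, one of `"RM"`, `"HN"`, `"PM"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "expr_matrix"))
  names(x$groups)[x$groups == group]
}
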