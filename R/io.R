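#' @importFrom utils read.delim write.table
NULL

# full-precision number formatting so write -> read round-trips exactly
.fmt_num <- function(x, digits = NA) {
  if (is.na(digits)) sprintf("%.17g", x) else sprintf(paste0("%.", digits, "f"), x)
}

.split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1L]]

#' Read a tab-delimited expression matrix
#'
#' Parses the package's GEO-series-matrix-like dialect: optional `!group`
#' header line (one label per sample), a header row `probe_id` followed by
#' sample ids, one probe per row, and Present/Marginal/Absent detection calls
#' either in an embedded `!detection` block at the end of the same file or in
#' a sidecar file of identical layout.
#'
#' @param path Path to the expression file.
#' @param detection_path Optional sidecar file with detection calls; when
#'   `NULL` an embedded `!detection` block is used if present, otherwise all
#'   calls default to Present.
#' @param groups Named character vector of group labels; overrides any
#'   `!group` line in the file.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, detection_path = NULL, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  det_at <- which(lines == "!detection")
  det_lines <- character(0)
  if (length(det_at)) {
    det_lines <- lines[(det_at[1L] + 1L):length(lines)]
    lines <- lines[seq_len(det_at[1L] - 1L)]
  }
  group_line <- grep("^!group\t", lines)
  file_groups <- NULL
  if (length(group_line))
    file_groups <- .split_fields(lines[group_line[1L]])[-1L]
  keep <- which(!startsWith(lines, "!"))
  parsed <- .parse_block(lines[keep], path, numeric = TRUE, lineno = keep)
  ints <- parsed$mat
  if (!is.null(file_groups) && is.null(groups)) {
    if (length(file_groups) != ncol(ints))
      stop("!group line has ", length(file_groups), " labels for ",
           ncol(ints), " samples in ", path)
    groups <- stats::setNames(file_groups, colnames(ints))
  }
  if (is.null(groups))
    stop("no group labels: supply 'groups' or a !group header line")
  det <- NULL
  if (!is.null(detection_path)) {
    det_lines <- readLines(detection_path)
    det_lines <- det_lines[!startsWith(det_lines, "!")]
  }
  if (length(det_lines)) {
    dp <- .parse_block(det_lines, path, numeric = FALSE)
    det <- dp$mat
    if (!identical(dimnames(det), dimnames(ints)))
      stop("detection block and intensity block disagree on probe/sample ids")
  }
  expression_matrix(ints, det, groups)
}

# parse header + probe rows; errors name the offending original line number
.parse_block <- function(lines, path, numeric = TRUE,
                         lineno = seq_along(lines)) {
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) stop("empty table in ", path)
  header <- .split_fields(lines[1L])
  if (header[1L] != "probe_id")
    stop("malformed header in ", path, ": first field must be 'probe_id'")
  sample_ids <- header[-1L]
  n <- length(lines) - 1L
  mat <- matrix(if (numeric) NA_real_ else NA_character_, n, length(sample_ids))
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- .split_fields(lines[i + 1L])
    if (length(f) != length(header))
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   lineno[i + 1L], path, length(f), length(header)))
    ids[i] <- f[1L]
    vals <- f[-1L]
    if (numeric) {
      v <- suppressWarnings(as.numeric(vals))
      if (anyNA(v))
        stop(sprintf("non-numeric value at line %d of %s", lineno[i + 1L],
                     path))
      mat[i, ] <- v
    } else {
      bad <- which(!(vals %in% c("P", "M", "A")))
      if (length(bad))
        stop(sprintf(
          "unknown detection symbol '%s' at line %d, sample '%s' of %s",
          vals[bad[1L]], lineno[i + 1L], sample_ids[bad[1L]], path))
      mat[i, ] <- vals
    }
  }
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("duplicate probe id '%s' at line %d of %s",
                 ids[dup[1L]], lineno[dup[1L] + 1L], path))
  dimnames(mat) <- list(ids, sample_ids)
  list(mat = mat)
}

#' Write an expression matrix in the package dialect
#'
#' @param em An [expression_matrix()].
#' @param path Output path for the intensity table (a `!group` line is
#'   included).
#' @param detection_path Optional sidecar path for the detection calls; when
#'   `NULL` they are embedded as a `!detection` block.
#' @param digits Decimal places to print, or `NA` (default) for full
#'   precision so that a write/read round trip is exact.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, detection_path = NULL,
                                    digits = NA) {
  stopifnot(inherits(em, "expr_matrix"))
  sample_ids <- colnames(em$intensities)
  out <- c(
    paste(c("!group", unname(em$groups[sample_ids])), collapse = "\t"),
    paste(c("probe_id", sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(em$intensities)), function(i) {
      paste(c(rownames(em$intensities)[i],
              .fmt_num(em$intensities[i, ], digits)), collapse = "\t")
    }, character(1))
  )
  det <- c(
    paste(c("probe_id", sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(em$detection)), function(i) {
      paste(c(rownames(em$detection)[i], em$detection[i, ]), collapse = "\t")
    }, character(1))
  )
  if (is.null(detection_path)) {
    writeLines(c(out, "!detection", det), path)
  } else {
    writeLines(out, path)
    writeLines(det, detection_path)
  }
  invisible(path)
}

#' Read a qPCR CT table
#'
#' Tab-delimited with columns `sample_id`, `group`, `gene`, `ct` and an
#' optional `!reference_gene` header line. Missing CTs may simply be absent
#' rows; each (sample, gene) pair must appear at most once.
#'
#' @param path Input path.
#' @param reference_gene Reference (endogenous control) gene; overrides the
#'   header line.
#' @return A data frame with attribute `reference_gene`.
#' @export
read_ct_table <- function(path, reference_gene = NULL) {
  lines <- readLines(path)
  ref_line <- grep("^!reference_gene\t", lines, value = TRUE)
  if (is.null(reference_gene) && length(ref_line))
    reference_gene <- .split_fields(ref_line[1L])[2L]
  body <- lines[!startsWith(lines, "!")]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  key <- paste(df$sample_id, df$gene)
  if (anyDuplicated(key))
    stop("duplicate (sample, gene) pair: ", key[duplicated(key)][1L])
  if (any(!is.finite(df$ct))) stop("CT values must be finite")
  attr(df, "reference_gene") <- reference_gene
  df
}

#' Write a qPCR CT table
#'
#' @param ct_table Data frame as returned by [read_ct_table()] or
#'   [generate_ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  ref <- attr(ct_table, "reference_gene")
  lines <- c(
    if (!is.null(ref)) paste("!reference_gene", ref, sep = "\t"),
    paste(c("sample_id", "group", "gene", "ct"), collapse = "\t"),
    sprintf("%s\t%s\t%s\t%s", ct_table$sample_id, ct_table$group,
            ct_table$gene, .fmt_num(ct_table$ct))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged cohort table (42 microarray cases)
#'
#' Transcription of the study's printed cohort table: sample id, group (RM,
#' HN, PM), age, and for HN samples the distance from the tumour, receptor
#' status (ER/PR/HER2) and stage; `prior_study` flags samples used in the
#' group's earlier report.
#'
#' @return A data frame with 42 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_cases.tsv", package = "bmadex",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "na", ""))
  df$prior_study <- as.logical(df$prior_study)
  df
}

#' Load the packaged 98-probe-set signature table
#'
#' Transcription of the study's printed signature: per probe-set row, gene
#' symbol, RM:HN fold change (RM over HN; values above 1 mean higher
#' expression in RM), the Bayesian probability score, the two-sided t-test
#' p-value on log intensities, the RM:PM fold change, and a flag for probe
#' sets also found in the group's earlier report. Duplicate symbols are
#' genuine distinct probe sets and are keyed by `probe_index`.
#'
#' @return A data frame with 98 rows (class `signature_table`).
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_signature.tsv", package = "bmadex",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$prior_study <- as.logical(df$prior_study)
  stopifnot(all(df$fold_rm_hn > 0), all(df$fold_rm_pm > 0),
            all(df$probability_score >= 0 & df$probability_score <= 1),
            all(df$t_p_value >= 0 & df$t_p_value <= 1))
  class(df) <- c("signature_table", "data.frame")
  df
}

#' Write a differential-expression results table
#'
#' Fixed column order: probe_id, symbol, fold, probability_score, t_p_value,
#' selection_frequency, selected. Output is bit-identical for identical
#' input.
#'
#' @param scores Data frame of model-averaged scores (from [score_matrix()]),
#'   optionally with a `symbol` column.
#' @param selection A `selection_result` (from [loo_stability()]) covering
#'   the same probe sets, or `NULL` to write NA selection columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(scores, selection, path) {
  if (!is.null(selection)) {
    sel <- selection$probes
    if (!setequal(scores$probe_id, sel$probe_id))
      stop("'scores' and 'selection' must cover identical probe sets")
    sel <- sel[match(scores$probe_id, sel$probe_id), ]
    freq <- sel$selection_frequency
    selected <- sel$selected
  } else {
    freq <- rep(NA_real_, nrow(scores))
    selected <- rep(NA, nrow(scores))
  }
  symbol <- if (!is.null(scores$symbol)) scores$symbol else rep(NA_character_, nrow(scores))
  t_p <- if (!is.null(scores$t_p_value)) scores$t_p_value else rep(NA_real_, nrow(scores))
  lines <- c(
    paste(c("probe_id", "symbol", "fold", "probability_score", "t_p_value",
            "selection_frequency", "selected"), collapse = "\t"),
    if (nrow(scores)) sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
            scores$probe_id, symbol,
            .fmt_num(scores$fold), .fmt_num(scores$p_value), .fmt_num(t_p),
            .fmt_num(freq), as.character(selected))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
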