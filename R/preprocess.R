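#' Rescale every sample to a target mean intensity
#'
#' The only normalisation the pipeline applies: each sample column is
#' multiplied by a scalar so that its mean intensity equals `target_mean`
#' (200 by default, the MAS5 convention). Detection calls are untouched.
#' Idempotent.
#'
#' @param em An [expression_matrix()].
#' @param target_mean Target per-sample mean intensity.
#' @return The rescaled [expression_matrix()].
#' @export
rescale_samples <- function(em, target_mean = 200) {
  stopifnot(inherits(em, "expr_matrix"))
  mu <- colMeans(em$intensities)
  zero <- which(mu <= 0)
  if (length(zero))
    stop("cannot rescale all-zero sample: ",
         colnames(em$intensities)[zero[1L]])
  em$intensities <- sweep(em$intensities, 2L, target_mean / mu, "*")
  em
}

#' Remove probes with too few Present detection calls
#'
#' Probes whose fraction of detectable calls across all samples is strictly
#' below `min_detect_frac` are removed; a probe at exactly the threshold is
#' retained. "Detectable" means a Present call; Marginal counts as not
#' detected unless `marginal_as_detected` is set. The filter is computed
#' jointly over all samples, once, before any group comparison.
#'
#' @param em An [expression_matrix()].
#' @param min_detect_frac Removal threshold on the detectable fraction
#'   (default 0.20).
#' @param marginal_as_detected Count Marginal calls as detectable.
#' @return A list: `matrix` (filtered [expression_matrix()]) and
#'   `removed_probe_ids`.
#' @export
filter_detection <- function(em, min_detect_frac = 0.20,
                             marginal_as_detected = FALSE) {
  stopifnot(inherits(em, "expr_matrix"))
  if (min_detect_frac < 0 || min_detect_frac > 1)
    stop("min_detect_frac must lie in [0, 1]")
  ok_calls <- if (marginal_as_detected) c("P", "M") else "P"
  frac <- rowMeans(matrix(em$detection %in% ok_calls, nrow(em$detection)))
  keep <- frac >= min_detect_frac
  list(matrix = em_subset(em, probes = which(keep)),
       removed_probe_ids = rownames(em$intensities)[!keep])
}
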