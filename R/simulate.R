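# Stage-level seed derivation: one global seed, a deterministic child seed
# per named stage, so regenerating a single stage is reproducible.
.stage_seed <- function(seed, stage) {
  h <- seed %% 2147483563
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

#' Configuration for the synthetic expression generator
#'
#' Defaults mirror the study design the pipeline targets: 18 RM (usual-risk
#' control), 18 HN (cancer-adjacent histologically normal) and 6 PM
#' (prophylactic mastectomy) samples; planted fold changes drawn from the
#' 2-6x range the printed signature spans; MAS5-like linear intensities with
#' a lognormal baseline. The generator emits *unscaled* intensities - the
#' pipeline's own [rescale_samples()] brings each sample to mean 200.
#'
#' @param n_probes Number of probe sets.
#' @param n_rm,n_hn,n_pm Samples per group (a group may be 0 to omit it;
#'   otherwise at least 2, since within-group variance is undefined below
#'   that).
#' @param n_de Number of probes with a planted RM:HN fold change.
#' @param fold_range Interval the planted linear-scale folds are drawn from;
#'   lower bound must exceed 1 (direction is planted separately).
#' @param prob_up Probability a planted probe is higher in RM (the observed
#'   signature splits roughly 2:1 in that direction).
#' @param cv Within-group coefficient of variation of intensities.
#' @param baseline_log_mean,baseline_log_sd Normal distribution of per-probe
#'   log baseline means.
#' @param detect_prob_expressed,detect_prob_unexpressed Present-call
#'   probabilities for expressed and unexpressed probes.
#' @param frac_unexpressed Fraction of probes treated as unexpressed for the
#'   detection model (their intensities are still drawn; only calls differ).
#' @param pm_mimics_hn When `TRUE`, PM samples copy the HN direction and
#'   magnitude of every planted fold (the high-risk group resembles cases).
#' @param family Within-group intensity family, `"lognormal"` (default) or
#'   `"gamma"` - the two families the Bayesian scorer averages over.
#' @param detection_mode `"independent"` Bernoulli calls (default) or
#'   `"intensity"`, which forces Absent calls onto the lowest intensity
#'   decile.
#' @param seed Integer seed driving a splittable per-stage generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 1000, n_rm = 18, n_hn = 18, n_pm = 6,
                       n_de = 50, fold_range = c(2, 6), prob_up = 2 / 3,
                       cv = 0.25, baseline_log_mean = 5, baseline_log_sd = 1,
                       detect_prob_expressed = 0.9,
                       detect_prob_unexpressed = 0.05,
                       frac_unexpressed = 0,
                       pm_mimics_hn = TRUE,
                       family = c("lognormal", "gamma"),
                       detection_mode = c("independent", "intensity"),
                       seed = 1L) {
  family <- match.arg(family)
  detection_mode <- match.arg(detection_mode)
  if (n_de > n_probes) stop("n_de must not exceed n_probes")
  if (length(fold_range) != 2L || fold_range[1L] <= 1 ||
      fold_range[2L] < fold_range[1L])
    stop("fold_range must be an interval with lower bound > 1")
  if (cv <= 0) stop("cv must be positive")
  for (n in c(n_rm, n_hn, n_pm))
    if (n == 1L) stop("each group needs 0 or >= 2 samples; ",
                      "variance is undefined for a single sample")
  structure(list(
    n_probes = n_probes, n_rm = n_rm, n_hn = n_hn, n_pm = n_pm, n_de = n_de,
    fold_range = fold_range, prob_up = prob_up, cv = cv,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    detect_prob_expressed = detect_prob_expressed,
    detect_prob_unexpressed = detect_prob_unexpressed,
    frac_unexpressed = frac_unexpressed, pm_mimics_hn = pm_mimics_hn,
    family = family, detection_mode = detection_mode,
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate a synthetic expression matrix with planted fold changes
#'
#' Draws per-probe baselines, plants `n_de` differential probes whose
#' RM-over-HN linear mean ratio is uniform on `fold_range` (inverted with
#' probability `1 - prob_up`), and samples within-group intensities from the
#' configured family with the exact target group means, so the planted fold
#' equals the ratio of true arithmetic means. Detection calls are Bernoulli
#' per the configured probabilities (or tied to the lowest intensity decile
#' in `"intensity"` mode). Fully reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `ground_truth` list: `de_probe_ids`, per-probe
#'   `fold_rm_hn` / `fold_rm_pm`, `groups`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_probes
  probe_ids <- sprintf("probe_%04d", seq_len(p))
  groups <- c(rep("RM", config$n_rm), rep("HN", config$n_hn),
              rep("PM", config$n_pm))
  sample_ids <- sprintf("%s_%02d", groups, stats::ave(
    seq_along(groups), groups, FUN = seq_along))
  names(groups) <- sample_ids
  n <- length(sample_ids)

  set.seed(.stage_seed(config$seed, "baseline"))
  baseline <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)

  set.seed(.stage_seed(config$seed, "folds"))
  fold_rm_hn <- rep(1, p)
  de_idx <- if (config$n_de > 0) sort(sample.int(p, config$n_de)) else integer(0)
  if (length(de_idx)) {
    f <- stats::runif(length(de_idx), config$fold_range[1L], config$fold_range[2L])
    up <- stats::runif(length(de_idx)) < config$prob_up
    fold_rm_hn[de_idx] <- ifelse(up, f, 1 / f)
  }
  fold_rm_pm <- if (config$pm_mimics_hn) fold_rm_hn else rep(1, p)

  # target linear-scale group means; HN carries the baseline
  m_hn <- exp(baseline)
  m_rm <- m_hn * fold_rm_hn
  m_pm <- m_rm / fold_rm_pm
  target <- cbind(RM = m_rm, HN = m_hn, PM = m_pm)

  set.seed(.stage_seed(config$seed, "intensities"))
  ints <- matrix(NA_real_, p, n, dimnames = list(probe_ids, sample_ids))
  sdlog <- sqrt(log(1 + config$cv^2))
  shape <- 1 / config$cv^2
  for (g in c("RM", "HN", "PM")) {
    cols <- which(groups == g)
    if (!length(cols)) next
    m <- target[, g]
    if (config$family == "lognormal") {
      ints[, cols] <- exp(stats::rnorm(p * length(cols),
                                       mean = log(m) - sdlog^2 / 2,
                                       sd = sdlog))
    } else {
      ints[, cols] <- stats::rgamma(p * length(cols), shape = shape,
                                    rate = shape / m)
    }
  }

  set.seed(.stage_seed(config$seed, "detection"))
  n_unexpr <- round(config$frac_unexpressed * p)
  unexpr <- rep(FALSE, p)
  if (n_unexpr > 0) unexpr[sample.int(p, n_unexpr)] <- TRUE
  if (config$detection_mode == "independent") {
    pr <- ifelse(unexpr, config$detect_prob_unexpressed,
                 config$detect_prob_expressed)
    det <- matrix(ifelse(stats::runif(p * n) < rep(pr, n), "P", "A"), p, n,
                  dimnames = dimnames(ints))
  } else {
    det <- matrix("P", p, n, dimnames = dimnames(ints))
    det[ints <= stats::quantile(ints, 0.1)] <- "A"
  }

  truth <- structure(list(
    de_probe_ids = probe_ids[de_idx],
    fold_rm_hn = stats::setNames(fold_rm_hn, probe_ids),
    fold_rm_pm = stats::setNames(fold_rm_pm, probe_ids),
    groups = groups), class = "ground_truth")
  list(matrix = expression_matrix(ints, det, groups), truth = truth)
}

#' Generate a synthetic qPCR CT table with planted fold changes
#'
#' Constructs cycle-threshold values so that the per-sample dCT (test-gene CT
#' minus reference-gene CT) differs between a test group and the reference
#' group by exactly `-log2(fold)` plus Gaussian noise: a planted fold of 4
#' with zero noise yields a group mean ddCT of -2 and a `2^-ddCT` fold of 4.
#' Folds are oriented as expression in the test group relative to the
#' reference group. Sample-level CT offsets (pipetting/loading differences)
#' are included; they cancel in the dCT.
#'
#' @param folds Named numeric vector (single test group) or a genes x groups
#'   matrix/data.frame of planted expression ratios, test over reference;
#'   all must be positive.
#' @param n_samples Named integer vector of samples per group, including the
#'   reference group, e.g. `c(RM = 8, HN = 17)`.
#' @param reference_group Group the folds are relative to (default `"RM"`).
#' @param noise_sd Standard deviation, in cycles, of per-reaction dCT noise.
#' @param seed Integer seed.
#' @param reference_gene Name of the endogenous control gene (planted fold 1
#'   by construction).
#' @param base_ct Mean CT of the reference gene.
#' @param sample_offset_sd Standard deviation of per-sample CT offsets.
#' @return A CT table data frame (`sample_id`, `group`, `gene`, `ct`) with
#'   attribute `reference_gene`.
#' @export
generate_ct_table <- function(folds, n_samples, reference_group = "RM",
                              noise_sd = 0.3, seed = 1L,
                              reference_gene = "CPSF6", base_ct = 22,
                              sample_offset_sd = 0.5) {
  if (is.vector(folds) && !is.list(folds)) {
    test_groups <- setdiff(names(n_samples), reference_group)
    if (length(test_groups) != 1L)
      stop("a fold vector needs exactly one non-reference group in n_samples")
    folds <- matrix(folds, ncol = 1L,
                    dimnames = list(names(folds), test_groups))
  }
  folds <- as.matrix(folds)
  if (is.null(rownames(folds))) stop("folds must be named by gene")
  if (any(folds <= 0)) stop("planted folds must be positive")
  if (!(reference_group %in% names(n_samples)))
    stop("n_samples must include the reference group")
  if (reference_gene %in% rownames(folds))
    stop("unknown gene role: the reference gene cannot carry a planted fold")
  missing_grp <- setdiff(colnames(folds), names(n_samples))
  if (length(missing_grp))
    stop("groups in folds absent from n_samples: ",
         paste(missing_grp, collapse = ", "))

  genes <- rownames(folds)
  set.seed(.stage_seed(as.integer(seed), "qpcr"))
  base_dct <- stats::setNames(stats::runif(length(genes), 1, 6), genes)

  rows <- list()
  for (g in names(n_samples)) {
    ns <- n_samples[[g]]
    if (ns == 0) next
    sample_ids <- sprintf("%s_q%02d", g, seq_len(ns))
    offset <- stats::rnorm(ns, 0, sample_offset_sd)
    ct_ref <- base_ct + offset
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_ids, group = g, gene = reference_gene, ct = ct_ref,
      stringsAsFactors = FALSE)
    for (gene in genes) {
      shift <- if (g == reference_group) 0 else -log2(folds[gene, g])
      ct <- ct_ref + base_dct[[gene]] + shift + stats::rnorm(ns, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids, group = g, gene = gene, ct = ct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  out
}
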