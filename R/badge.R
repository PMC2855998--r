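# Per-probe derived seed: hash of the global seed and the probe id, so probe
# scores do not depend on evaluation order.
.probe_seed <- function(seed, probe_id) {
  h <- as.numeric(seed) %% 2147483563
  for (ch in utf8ToInt(as.character(probe_id)))
    h <- (h * 31 + ch) %% 2147483563
  as.integer(h)
}

#' Configuration for the Bayesian model-averaged scorer
#'
#' The scorer averages over a lognormal and a gamma within-group intensity
#' model. The lognormal family uses a conjugate normal-inverse-gamma prior
#' on log intensities: prior mean centred at the probe's pooled log mean
#' with `kappa0` effective observations, and an inverse-gamma
#' (`a0`, `b0`) prior on the log-scale variance. The gamma family places a
#' wide normal prior (sd `gamma_prior_sd`) on log shape and log rate and is
#' handled by a Laplace approximation with importance-weighted draws.
#'
#' @param families Model families to average over; subset of
#'   `c("lognormal", "gamma")`.
#' @param n_draws Posterior draws per family (at least 1000).
#' @param kappa0 Prior effective sample size for the lognormal mean.
#' @param a0,b0 Inverse-gamma shape/scale for the lognormal variance prior.
#'   `b0 = NULL` (default) scales the prior per probe to
#'   `a0` times the pooled log-scale variance, so the family comparison is
#'   not driven by an arbitrary prior variance scale; pass a number to fix
#'   it.
#' @param gamma_prior_sd Prior standard deviation on the gamma family's log
#'   shape and log rate, centred at the pooled-data estimate (mirroring the
#'   lognormal family's pooled prior mean).
#' @param epsilon Floor applied to non-positive intensities before taking
#'   logs (MAS5 matrices occasionally contain zeros).
#' @param seed Global seed; each probe derives its own stream from it.
#' @return A `badge_config` list.
#' @export
badge_config <- function(families = c("lognormal", "gamma"), n_draws = 10000,
                         kappa0 = 0.1, a0 = 0.5, b0 = NULL,
                         gamma_prior_sd = 3, epsilon = 1, seed = 1L) {
  families <- match.arg(families, c("lognormal", "gamma"), several.ok = TRUE)
  if (!length(families)) stop("'families' must be nonempty")
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  structure(list(families = families, n_draws = as.integer(n_draws),
                 kappa0 = kappa0, a0 = a0, b0 = b0,
                 gamma_prior_sd = gamma_prior_sd, epsilon = epsilon,
                 seed = as.integer(seed)), class = "badge_config")
}

# Conjugate lognormal fit for one group. x: log intensities. m0: prior mean,
# b0: inverse-gamma scale (resolved by the caller when configured as NULL).
# Returns a closure drawing linear-scale group means, and the log marginal
# likelihood on the observed (linear) scale.
.ln_fit <- function(x, m0, b0, cfg) {
  n <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  k0 <- cfg$kappa0; a0 <- cfg$a0
  kn <- k0 + n
  mn <- (k0 * m0 + n * xbar) / kn
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + k0 * n * (xbar - m0)^2 / (2 * kn)
  logm <- -n / 2 * log(2 * pi) + 0.5 * (log(k0) - log(kn)) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0) - sum(x)
  list(
    draw = function(nd) {
      s2 <- bn / stats::rgamma(nd, an)
      mu <- stats::rnorm(nd, mn, sqrt(s2 / kn))
      list(means = exp(mu + s2 / 2), w = NULL)
    },
    logm = logm)
}

# Gamma maximum-likelihood shape via Newton on the profile equation.
.gam_shape_mle <- function(y) {
  s <- max(log(mean(y)) - mean(log(y)), 1e-8)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:30) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    an <- a - f / fp
    if (!is.finite(an) || an <= 0) an <- a / 2
    if (abs(an - a) < 1e-12 * a) { a <- an; break }
    a <- an
  }
  min(a, 1e6)
}

# Gamma fit for one group via Laplace approximation in (log shape, log rate),
# with importance-weighted posterior draws. th0: prior centre (from pooled
# data, mirroring the lognormal family's pooled prior mean).
.gam_fit <- function(y, th0, cfg) {
  n <- length(y)
  S <- sum(y)
  SL <- sum(log(y))
  a <- .gam_shape_mle(y)
  th <- c(log(a), log(a * n / S))
  psd2 <- cfg$gamma_prior_sd^2
  hess <- function(th) {
    a <- exp(th[1L]); b <- exp(th[2L])
    dLda <- n * (log(b) - digamma(a)) + SL
    c(H11 = a * dLda - a^2 * n * trigamma(a) - 1 / psd2,
      H12 = n * a,
      H22 = -b * S - 1 / psd2)
  }
  logpost <- function(th1, th2) {
    a <- exp(th1); b <- exp(th2)
    n * (a * log(b) - lgamma(a)) + (a - 1) * SL - b * S -
      ((th1 - th0[1L])^2 + (th2 - th0[2L])^2) / (2 * psd2) -
      log(2 * pi * psd2)
  }
  for (i in 1:25) { # Newton to the posterior mode
    a <- exp(th[1L]); b <- exp(th[2L])
    g1 <- a * (n * (log(b) - digamma(a)) + SL) - (th[1L] - th0[1L]) / psd2
    g2 <- n * a - b * S - (th[2L] - th0[2L]) / psd2
    H <- hess(th)
    det <- H[["H11"]] * H[["H22"]] - H[["H12"]]^2
    if (!is.finite(det) || det <= 0 || H[["H11"]] >= 0) break
    d1 <- (H[["H22"]] * g1 - H[["H12"]] * g2) / det
    d2 <- (-H[["H12"]] * g1 + H[["H11"]] * g2) / det
    th <- th - c(d1, d2)
    if (max(abs(c(d1, d2))) < 1e-10) break
  }
  H <- hess(th)
  det <- H[["H11"]] * H[["H22"]] - H[["H12"]]^2
  s11 <- -H[["H22"]] / det; s12 <- H[["H12"]] / det; s22 <- -H[["H11"]] / det
  l11 <- sqrt(s11)
  l21 <- s12 / l11
  l22 <- sqrt(max(s22 - l21^2, 1e-12))
  logdetS <- -log(det)
  logm <- logpost(th[1L], th[2L]) + log(2 * pi) + 0.5 * logdetS
  list(
    draw = function(nd) {
      z1 <- stats::rnorm(nd); z2 <- stats::rnorm(nd)
      t1 <- th[1L] + l11 * z1
      t2 <- th[2L] + l21 * z1 + l22 * z2
      lp <- logpost(t1, t2)
      lq <- -log(2 * pi) - 0.5 * logdetS - 0.5 * (z1^2 + z2^2)
      lw <- lp - lq
      w <- exp(lw - max(lw))
      list(means = exp(t1 - t2), w = w / sum(w))
    },
    logm = logm)
}

#' Score one probe for differential expression by model averaging
#'
#' Fits each configured family to the two groups, weights the families by
#' their joint marginal likelihood, draws the posterior of the fold change
#' (group-1 mean over group-2 mean of linear-scale intensities), and reports
#' the posterior probability that the fold exceeds 1. The probability score
#' (p-value) is 1 minus the larger directional probability, so it lies in
#' \[0, 0.5\] and small values indicate strong evidence in either direction.
#' The fold point estimate is the model-averaged posterior median.
#' Deterministic given the seed.
#'
#' @param values_g1,values_g2 Positive intensities (at least 2 per group).
#' @param config A [badge_config()].
#' @param probe_id Optional probe id; used to derive a per-probe seed from
#'   `config$seed` so results do not depend on probe evaluation order.
#' @param seed Explicit seed overriding the derivation.
#' @return A list: `probe_id`, `fold`, `p_greater`, `p_value`,
#'   `model_weights` (named, summing to 1).
#' @export
score_probe <- function(values_g1, values_g2, config = badge_config(),
                        probe_id = NULL, seed = NULL) {
  for (v in list(values_g1, values_g2)) {
    if (length(v) < 2L || any(!is.finite(v)))
      stop("each group needs at least 2 finite intensities")
    if (any(v <= 0))
      stop("non-positive intensity: floor values first, e.g. ",
           "pmax(x, config$epsilon)")
  }
  if (is.null(seed))
    seed <- if (is.null(probe_id)) config$seed
            else .probe_seed(config$seed, probe_id)
  set.seed(seed)
  lx1 <- log(values_g1); lx2 <- log(values_g2)
  m0 <- mean(c(lx1, lx2))
  b0 <- config$b0
  if (is.null(b0)) {
    # scale the variance prior to the probe's pooled log-scale variance so
    # neither family is handicapped by an arbitrary prior scale
    s2p <- (sum((lx1 - mean(lx1))^2) + sum((lx2 - mean(lx2))^2)) /
      max(length(lx1) + length(lx2) - 2L, 1L)
    b0 <- config$a0 * max(s2p, 1e-8)
  }
  nd <- config$n_draws

  fits <- lapply(config$families, function(fam) {
    if (fam == "lognormal") {
      f1 <- .ln_fit(lx1, m0, b0, config)
      f2 <- .ln_fit(lx2, m0, b0, config)
    } else {
      pooled <- c(values_g1, values_g2)
      a_pool <- .gam_shape_mle(pooled)
      th0 <- c(log(a_pool), log(a_pool / mean(pooled)))
      f1 <- .gam_fit(values_g1, th0, config)
      f2 <- .gam_fit(values_g2, th0, config)
    }
    d1 <- f1$draw(nd); d2 <- f2$draw(nd)
    fold <- d1$means / d2$means
    w <- if (is.null(d1$w)) rep(1 / nd, nd) else {
      ww <- d1$w * d2$w
      ww / sum(ww)
    }
    list(fold = fold, w = w, logm = f1$logm + f2$logm)
  })

  logm <- vapply(fits, `[[`, numeric(1), "logm")
  fam_w <- exp(logm - max(logm))
  fam_w <- fam_w / sum(fam_w)
  names(fam_w) <- config$families

  p_greater <- sum(fam_w * vapply(fits, function(f) sum(f$w * (f$fold > 1)),
                                  numeric(1)))
  folds <- unlist(lapply(fits, `[[`, "fold"))
  weights <- unlist(lapply(seq_along(fits),
                           function(i) fam_w[i] * fits[[i]]$w))
  ord <- order(folds)
  cw <- cumsum(weights[ord])
  fold <- folds[ord][which(cw >= 0.5 * cw[length(cw)])[1L]]

  list(probe_id = probe_id, fold = fold, p_greater = p_greater,
       p_value = 1 - max(p_greater, 1 - p_greater), model_weights = fam_w)
}

#' Score every probe of an expression matrix between two groups
#'
#' Vectorised driver over [score_probe()]: intensities are floored at
#' `config$epsilon` before scoring, each probe draws from its own derived
#' seed, and the output preserves the matrix probe order.
#'
#' @param em An [expression_matrix()].
#' @param group1,group2 Group labels to compare (fold is group1 over group2).
#' @param config A [badge_config()].
#' @return A data frame: `probe_id`, `fold`, `p_greater`, `p_value`, and one
#'   weight column per family.
#' @export
score_matrix <- function(em, group1 = "RM", group2 = "HN",
                         config = badge_config()) {
  stopifnot(inherits(em, "expr_matrix"))
  s1 <- group_samples(em, group1)
  s2 <- group_samples(em, group2)
  if (!length(s1) || !length(s2))
    stop("both groups must be present in the matrix")
  probes <- rownames(em$intensities)
  p <- length(probes)
  x1 <- pmax(em$intensities[, s1, drop = FALSE], config$epsilon)
  x2 <- pmax(em$intensities[, s2, drop = FALSE], config$epsilon)
  fold <- p_greater <- p_value <- numeric(p)
  fam_w <- matrix(NA_real_, p, length(config$families),
                  dimnames = list(NULL, paste0("weight_", config$families)))
  for (i in seq_len(p)) {
    sc <- score_probe(x1[i, ], x2[i, ], config, probe_id = probes[i])
    fold[i] <- sc$fold
    p_greater[i] <- sc$p_greater
    p_value[i] <- sc$p_value
    fam_w[i, ] <- sc$model_weights
  }
  out <- data.frame(probe_id = probes, fold = fold, p_greater = p_greater,
                    p_value = p_value, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fam_w))
}

#' Two-sided equal-variance t-test on log intensities
#'
#' The robustness companion to the Bayesian score: a classical pooled
#' t-test on natural-log intensities.
#'
#' @param values_g1,values_g2 Positive intensities (at least 2 per group).
#' @return Two-sided p-value, or `NA` when the pooled variance is zero.
#' @export
t_test_log <- function(values_g1, values_g2) {
  if (length(values_g1) < 2L || length(values_g2) < 2L)
    stop("each group needs at least 2 values")
  if (any(c(values_g1, values_g2) <= 0))
    stop("intensities must be positive for the log transform")
  tryCatch(
    stats::t.test(log(values_g1), log(values_g2), var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
}

#' Ratio of group mean intensities
#'
#' @param values_g1,values_g2 Intensity vectors; the mean of `values_g2`
#'   must be positive.
#' @return `mean(values_g1) / mean(values_g2)`.
#' @export
simple_fold <- function(values_g1, values_g2) {
  m2 <- mean(values_g2)
  if (m2 == 0) stop("zero denominator: mean of group 2 is 0")
  mean(values_g1) / m2
}
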