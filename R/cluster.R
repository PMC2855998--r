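#' Hierarchical clustering of samples with deterministic tie-breaking
#'
#' Agglomerative clustering of samples on a probe subset. Distances default
#' to Euclidean on `log2(intensity + 1)` (linear-scale MAS5 distances are
#' dominated by the brightest probes); linkage defaults to average
#' (UPGMA). Ties in the merge distance are broken deterministically: among
#' equally close pairs, the pair whose clusters contain the lowest original
#' sample indices merges first.
#'
#' @param x An [expression_matrix()] or a plain probes-by-samples numeric
#'   matrix.
#' @param probe_subset Probe ids to cluster on; default all probes. Probes
#'   absent from the matrix are an error.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param linkage `"average"` or `"complete"`.
#' @param log_transform Apply `log2(x + 1)` before distances (default).
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
hcluster_samples <- function(x, probe_subset = NULL,
                             distance = c("euclidean", "correlation"),
                             linkage = c("average", "complete"),
                             log_transform = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  mat <- if (inherits(x, "expr_matrix")) x$intensities else as.matrix(x)
  if (!is.null(probe_subset)) {
    missing <- setdiff(probe_subset, rownames(mat))
    if (length(missing) == length(probe_subset))
      stop("probe subset is disjoint from the matrix")
    if (length(missing))
      stop("probes absent from matrix: ", paste(missing, collapse = ", "))
    mat <- mat[probe_subset, , drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 samples to cluster")
  if (log_transform) mat <- log2(mat + 1)
  D <- if (distance == "euclidean") as.matrix(stats::dist(t(mat)))
       else 1 - stats::cor(mat)
  .agglomerate(D, linkage, colnames(mat))
}

# Deterministic agglomeration over a symmetric distance matrix.
.agglomerate <- function(D, linkage, labels) {
  n <- nrow(D)
  diag(D) <- Inf
  code <- -seq_len(n)        # hclust codes: negative singleton, positive row
  size <- rep(1L, n)
  minmem <- seq_len(n)       # lowest original member index, for tie-breaks
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lowest-index pair first: order candidate pairs by the sorted pair of
    # lowest original member indices
    a <- pmin(minmem[idx[cand[, 1L]]], minmem[idx[cand[, 2L]]])
    b <- pmax(minmem[idx[cand[, 1L]]], minmem[idx[cand[, 2L]]])
    pick <- order(a, b)[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    if (minmem[j] < minmem[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(code[i], code[j])
    height[step] <- h
    # linkage update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- if (linkage == "average")
        (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
      else pmax(D[i, others], D[j, others])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    code[i] <- step
    minmem[i] <- min(minmem[i], minmem[j])
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
  }
  ord <- .leaf_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "see hcluster_samples"),
            class = "hclust")
}

.leaf_order <- function(merge) {
  rec <- function(i) {
    if (i < 0) return(-i)
    c(rec(merge[i, 1L]), rec(merge[i, 2L]))
  }
  rec(nrow(merge))
}

.branch_members <- function(merge, i) {
  if (i < 0) return(-i)
  c(.branch_members(merge, merge[i, 1L]), .branch_members(merge, merge[i, 2L]))
}

#' Two-way partition from a cluster tree
#'
#' The two sample blocks obtained by removing the final merge. The block
#' containing the first sample is listed first.
#'
#' @param tree An `hclust` object with labels.
#' @return List of two character vectors of sample ids.
#' @export
cut_two <- function(tree) {
  m <- tree$merge
  if (is.null(m) || nrow(m) < 1L) stop("tree has a single sample; no split")
  b1 <- sort(.branch_members(m, m[nrow(m), 1L]))
  b2 <- sort(.branch_members(m, m[nrow(m), 2L]))
  if (1L %in% b2) { tmp <- b1; b1 <- b2; b2 <- tmp }
  list(tree$labels[b1], tree$labels[b2])
}

#' Concordance pattern of a focal group against a two-block partition
#'
#' Summarises a cluster result the way the permutation test compares
#' results: the number of focal-group samples falling in the block holding
#' the majority of the anchor group, and the number falling in the other
#' block. A majority tie is broken towards the block containing the sample
#' listed first in `labels`.
#'
#' @param partition List of two sample-id blocks (from [cut_two()]).
#' @param labels Named character vector mapping every partitioned sample to
#'   its group.
#' @param focal_group Group whose placement is summarised.
#' @param anchor_group Group whose majority block anchors the pattern
#'   (default `"HN"`).
#' @return Integer vector `c(in_anchor_block, in_other_block)`.
#' @export
concordance_pattern <- function(partition, labels, focal_group,
                                anchor_group = "HN") {
  samples <- unlist(partition)
  if (!all(samples %in% names(labels)))
    stop("labels must cover all partitioned samples")
  if (!any(labels[samples] == focal_group))
    stop("focal group '", focal_group, "' absent from labels")
  n_anchor <- vapply(partition, function(b) sum(labels[b] == anchor_group),
                     integer(1))
  anchor_block <- if (n_anchor[1L] != n_anchor[2L]) which.max(n_anchor)
                  else which(vapply(partition, function(b)
                    names(labels)[1L] %in% b, logical(1)))[1L]
  n_focal <- vapply(partition, function(b) sum(labels[b] == focal_group),
                    integer(1))
  c(in_anchor_block = n_focal[[anchor_block]],
    in_other_block = sum(n_focal) - n_focal[[anchor_block]])
}

#' Monte Carlo label-permutation test of a cluster result
#'
#' The tree and its two-way partition are computed once (permuting labels
#' cannot change distances); each permutation reassigns the group labels
#' uniformly at random over the samples (the identity assignment is not
#' excluded) and recomputes the concordance pattern. `n_matches` counts
#' permutations whose pattern equals the observed one (`match = "exact"`)
#' or is at least as concordant in the observed direction
#' (`match = "at-least"`).
#'
#' @param x An [expression_matrix()] or probes-by-samples matrix.
#' @param probe_subset Probe ids to cluster on (default all).
#' @param labels Named group labels per sample; must have at least two
#'   distinct classes.
#' @param focal_group,anchor_group Passed to [concordance_pattern()].
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @param match `"exact"` or `"at-least"`.
#' @param ... Further arguments to [hcluster_samples()].
#' @return A `partition_test` list: `tree`, `partition`,
#'   `observed_pattern`, `n_permutations`, `n_matches`, `match_frequency`,
#'   `match`, `seed`.
#' @export
permutation_cluster_test <- function(x, probe_subset = NULL, labels,
                                     focal_group, anchor_group = "HN",
                                     n_permutations = 10000, seed = 1L,
                                     match = c("exact", "at-least"), ...) {
  match <- match.arg(match)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  if (length(unique(labels)) < 2L)
    stop("labels must contain at least two classes")
  tree <- hcluster_samples(x, probe_subset, ...)
  partition <- cut_two(tree)
  observed <- concordance_pattern(partition, labels, focal_group,
                                  anchor_group)
  towards_anchor <- observed[[1L]] >= observed[[2L]]
  set.seed(as.integer(seed))
  ids <- names(labels)
  n_matches <- 0L
  for (k in seq_len(n_permutations)) {
    perm <- stats::setNames(sample(unname(labels)), ids)
    pat <- concordance_pattern(partition, perm, focal_group, anchor_group)
    hit <- if (match == "exact") all(pat == observed)
           else if (towards_anchor) pat[[1L]] >= observed[[1L]]
           else pat[[1L]] <= observed[[1L]]
    if (hit) n_matches <- n_matches + 1L
  }
  structure(list(tree = tree, partition = partition,
                 observed_pattern = observed,
                 n_permutations = n_permutations, n_matches = n_matches,
                 match_frequency = n_matches / n_permutations,
                 match = match, seed = as.integer(seed)),
            class = "partition_test")
}

#' @export
print.partition_test <- function(x, ...) {
  cat(sprintf(
    "partition_test: observed pattern (%d, %d); %d of %d permutations match (frequency %.5f)\n",
    x$observed_pattern[[1L]], x$observed_pattern[[2L]], x$n_matches,
    x$n_permutations, x$match_frequency))
  invisible(x)
}

#' Spearman correlation of two fold-change vectors
#'
#' Rank correlation with mid-ranked ties, used to compare the fold-change
#' spectrum of two contrasts over the same probe sets.
#'
#' @param folds_a,folds_b Equal-length positive vectors, length at least 3.
#' @return Spearman's rho.
#' @export
spearman_fold_correlation <- function(folds_a, folds_b) {
  if (length(folds_a) != length(folds_b)) stop("vectors must be equal length")
  if (length(folds_a) < 3L) stop("need at least 3 pairs")
  if (any(c(folds_a, folds_b) <= 0)) stop("folds must be positive")
  if (stats::sd(folds_a) == 0 || stats::sd(folds_b) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(folds_a, folds_b, method = "spearman")
}
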