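## Morphospace-occupation metrics with rarefaction, bootstrap uncertainty,
## and pairwise bootstrap tests.

#' Retain PC axes above a variance-fraction threshold
#'
#' Keeps, in order, every axis whose proportion of total variance strictly
#' exceeds `threshold` (default 5%, the convention used for both the form
#' and shape analyses).
#'
#' @param pc A `morpho_pca` object.
#' @param threshold Proportion in (0, 1).
#' @return The score submatrix of the retained axes.
#' @export
retain_axes <- function(pc, threshold = 0.05) {
  stopifnot(inherits(pc, "morpho_pca"), threshold > 0, threshold < 1)
  keep <- which(pc$proportion > threshold)
  if (!length(keep)) stop("no axis exceeds the variance threshold", call. = FALSE)
  pc$scores[, keep, drop = FALSE]
}

#' Sum of univariate variances (multivariate variance)
#'
#' @param scores Units x axes score matrix (>= 2 units).
#' @return Non-negative scalar: the sum over axes of the sample variance
#'   (n - 1 denominator).
#' @export
sum_of_variances <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 units", call. = FALSE)
  sum(apply(scores, 2L, stats::var))
}

#' PCA volume of a set of units
#'
#' Product of the positive eigenvalues of the Gower-centered pairwise
#' Euclidean distance matrix, divided by the squared number of units.
#' Eigenvalues below `tol` times the leading eigenvalue are treated as zero.
#'
#' @param scores Units x axes score matrix (>= 2 units).
#' @param tol Relative positivity tolerance (default 1e-12).
#' @return Non-negative scalar (0, with a warning, when all units coincide).
#' @export
pca_volume <- function(scores, tol = 1e-12) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 units", call. = FALSE)
  D2 <- as.matrix(stats::dist(scores))^2
  if (all(D2 == 0)) { warning("all units coincident; volume 0"); return(0) }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > max(ev) * tol]
  prod(pos) / n^2
}

.disparity_metric <- function(name) {
  switch(match.arg(name, c("sum_of_variances", "pca_volume")),
         sum_of_variances = sum_of_variances, pca_volume = pca_volume)
}

#' Rarefied bootstrap disparity estimates per group
#'
#' Each bootstrap replicate resamples each group's units with replacement,
#' then rarefies by drawing `rarefy_to` of the resampled units without
#' replacement (rarefaction subsamples; bootstrap resamples), and computes
#' the metric. Reports the point estimate, bootstrap mean, SD, and 2.5/97.5
#' percentile interval per group.
#'
#' @param scores Units x axes score matrix with unit rownames.
#' @param groups Named group labels covering the rows of `scores`.
#' @param metric `"sum_of_variances"` or `"pca_volume"`.
#' @param rarefy_to Common sample size; default is the smallest group size.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Optional integer seed.
#' @return Data frame, one row per group, columns `group`, `n`,
#'   `rarefied_to`, `estimate`, `boot_mean`, `boot_sd`, `lower`, `upper`.
#' @export
rarefied_bootstrap <- function(scores, groups, metric = "sum_of_variances",
                               rarefy_to = NULL, n_boot = 10000L, seed = NULL) {
  scores <- as.matrix(scores)
  groups <- groups[rownames(scores)]
  if (any(is.na(groups))) stop("groups must cover every unit", call. = FALSE)
  f <- .disparity_metric(metric)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs >= 2 units", call. = FALSE)
  if (is.null(rarefy_to)) rarefy_to <- min(sizes)
  if (rarefy_to > min(sizes)) stop("rarefy_to exceeds the smallest group",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(names(sizes), function(g) {
    idx <- which(groups == g)
    est <- f(scores[idx, , drop = FALSE])
    reps <- vapply(seq_len(n_boot), function(b) {
      bs <- sample(idx, length(idx), replace = TRUE)
      sub <- sample(bs, rarefy_to, replace = FALSE)
      f(scores[sub, , drop = FALSE])
    }, numeric(1))
    data.frame(group = g, n = length(idx), rarefied_to = rarefy_to,
               estimate = est, boot_mean = mean(reps), boot_sd = stats::sd(reps),
               lower = stats::quantile(reps, 0.025, names = FALSE),
               upper = stats::quantile(reps, 0.975, names = FALSE))
  })
  do.call(rbind, res)
}

#' Two-tailed bootstrap test of a disparity difference
#'
#' Bootstrap distribution of the group-A-minus-group-B disparity difference
#' (groups resampled independently with replacement, both rarefied to the
#' smaller group's size); the two-tailed p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))`, capped at 1.
#'
#' @param scores Units x axes score matrix with unit rownames.
#' @param groupA,groupB Character vectors of unit names (disjoint).
#' @param metric `"sum_of_variances"` or `"pca_volume"`.
#' @param n_boot Bootstrap replicates (default 100000).
#' @param seed Optional integer seed.
#' @return List with `p`, `observed_diff`, `boot_diffs` summary.
#' @export
disparity_difference_test <- function(scores, groupA, groupB,
                                      metric = "sum_of_variances",
                                      n_boot = 100000L, seed = NULL) {
  scores <- as.matrix(scores)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ","),
         call. = FALSE)
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  iA <- match(groupA, rownames(scores)); iB <- match(groupB, rownames(scores))
  if (anyNA(iA) || anyNA(iB)) stop("unknown unit names", call. = FALSE)
  f <- .disparity_metric(metric)
  m <- min(length(iA), length(iB))
  if (!is.null(seed)) set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    a <- sample(sample(iA, length(iA), replace = TRUE), m)
    bb <- sample(sample(iB, length(iB), replace = TRUE), m)
    f(scores[a, , drop = FALSE]) - f(scores[bb, , drop = FALSE])
  }, numeric(1))
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  p <- max(p, 1 / n_boot)   # never report exactly 0 from finite resampling
  list(p = p,
       observed_diff = f(scores[iA, , drop = FALSE]) - f(scores[iB, , drop = FALSE]),
       boot_mean = mean(diffs), boot_sd = stats::sd(diffs), n_boot = n_boot)
}
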