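## Complexity-index tabulation and induction-experiment statistics.

#' Complexity index from a structure presence/absence matrix
#'
#' The complexity index of a species is the number of discrete stomatal
#' structures it bears: the row sum of a binary species x structure matrix.
#' Scoring conventions (iterative structures and bilateral duplicates
#' collapsed to single structures) are encoded when the matrix is built,
#' not here.
#'
#' @param m Binary matrix (or data frame) with species rownames.
#' @return Named integer vector of complexity indices.
#' @export
complexity_index <- function(m) {
  m <- as.matrix(m)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop("non-binary entry at [", rc[1], ", ", rc[2], "]: ", m[bad[1]],
         call. = FALSE)
  }
  stats::setNames(as.integer(rowSums(m)), rownames(m))
}

#' Pool replicate induction plates into a 2x2 table
#'
#' Sums Eu and non-Eu counts across plates within each arm.
#'
#' @param plates Data frame with columns `arm` (`"treatment"`/`"control"`),
#'   `n_eu`, `n_total` (one row per plate).
#' @return 2x2 integer matrix, rows = treatment/control, cols = Eu/non-Eu.
#' @export
pool_replicates <- function(plates) {
  stopifnot(all(c("arm", "n_eu", "n_total") %in% names(plates)))
  if (any(plates$n_eu < 0 | plates$n_total < plates$n_eu))
    stop("counts must satisfy 0 <= n_eu <= n_total", call. = FALSE)
  arms <- c("treatment", "control")
  if (!all(plates$arm %in% arms)) stop("arm must be treatment/control", call. = FALSE)
  eu <- tapply(plates$n_eu, factor(plates$arm, arms), sum)
  tot <- tapply(plates$n_total, factor(plates$arm, arms), sum)
  if (anyNA(eu)) stop("need at least one plate per arm", call. = FALSE)
  m <- cbind(Eu = as.integer(eu), nonEu = as.integer(tot - eu))
  rownames(m) <- arms
  m
}

#' Fisher's exact test with conditional-ML odds ratio
#'
#' Two-tailed p-value by the probability-mass rule (sum of hypergeometric
#' probabilities of tables, at fixed margins, no more probable than the
#' observed one) and the conditional maximum-likelihood odds ratio under
#' the noncentral hypergeometric model; the odds ratio is reported as
#' infinite when the table structure forces it.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p`, `odds_ratio`, and `conf_int` (95%).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  ft <- stats::fisher.test(table)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate),
       conf_int = unname(ft$conf.int))
}
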