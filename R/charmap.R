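## Two-state continuous-time Markov inference and stochastic character
## mapping with SIMMAP-style discretized rate/bias priors.

#' Log-likelihood of a binary character under a 2-state Markov model
#'
#' Felsenstein pruning over closed-form 2-state transition probabilities
#' \eqn{P(t) = \exp(Qt)} with \eqn{Q = [[-q01, q01], [q10, -q10]]}.
#'
#' @param tree A rooted `phylo`.
#' @param tip_states Named 0/1 vector covering every tip (no ambiguity codes).
#' @param q01,q10 Gain (0 to 1) and loss (1 to 0) rates, per unit branch length.
#' @param root_distribution `"stationary"` (default), `"flat"`, or a
#'   2-vector of root-state weights.
#' @return The log-likelihood (scalar).
#' @export
mk2_loglik <- function(tree, tip_states, q01, q10,
                       root_distribution = "stationary") {
  stopifnot(q01 >= 0, q10 >= 0)
  tree <- .validate_tree(tree)
  lay <- .tree_layout(tree)
  .mk2_prune(lay, tip_states, q01, q10, root_distribution)$lnL
}

#' Convert between (rate, bias) and (q01, q10) parameterizations
#'
#' The mapping priors are expressed as an overall rate `lambda` and a bias
#' `beta` with `q01 = 2*lambda*beta`, `q10 = 2*lambda*(1 - beta)`, so that
#' `lambda` equals the expected number of transitions per unit length at
#' stationarity when `beta = 1/2`.
#'
#' @param lambda Overall rate (>= 0).
#' @param beta Bias toward gains, in (0, 1).
#' @return Named vector `c(q01, q10)`.
#' @export
rate_bias_to_q <- function(lambda, beta) {
  stopifnot(lambda >= 0, beta > 0, beta < 1)
  c(q01 = 2 * lambda * beta, q10 = 2 * lambda * (1 - beta))
}

#' Maximum-likelihood fit of the 2-state Markov model
#'
#' Optimizes (q01, q10) in log space from multiple starts.
#'
#' @inheritParams mk2_loglik
#' @return Object of class `mk2_fit`: list with `q01`, `q10`, `lnL`.
#' @export
fit_mk2 <- function(tree, tip_states, root_distribution = "stationary") {
  tree <- .validate_tree(tree)
  lay <- .tree_layout(tree)
  negll <- function(p) {
    v <- -.mk2_prune(lay, tip_states, exp(p[1]), exp(p[2]), root_distribution)$lnL
    if (!is.finite(v)) 1e10 else v
  }
  tot <- sum(tree$edge.length)
  starts <- list(log(c(1, 1) / tot), log(c(5, 5) / tot), log(c(0.2, 2) / tot))
  fits <- lapply(starts, function(s)
    stats::optim(s, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  structure(list(q01 = exp(best$par[1]), q10 = exp(best$par[2]),
                 lnL = -best$value), class = "mk2_fit")
}

#' @export
print.mk2_fit <- function(x, ...) {
  cat("2-state Markov fit: q01 =", signif(x$q01, 4),
      " q10 =", signif(x$q10, 4), " lnL =", round(x$lnL, 4), "\n")
  invisible(x)
}

## ---- character histories ---------------------------------------------------

## A character history stores, per edge of `tree` (in tree's own edge order),
## an ordered vector of segment lengths named by state ("0"/"1"),
## rootward to tipward -- the same `maps` convention as SIMMAP-format trees.
.new_history <- function(tree, maps) {
  stopifnot(length(maps) == nrow(tree$edge))
  lens <- vapply(maps, sum, numeric(1))
  if (any(abs(lens - tree$edge.length) > 1e-8 * (1 + tree$edge.length)))
    stop("segment lengths do not sum to branch lengths", call. = FALSE)
  trans <- lapply(maps, function(m) {
    s <- as.integer(names(m))
    if (length(s) > 1L) cbind(from = s[-length(s)], to = s[-1L]) else NULL
  })
  tmat <- do.call(rbind, trans)
  gains <- if (is.null(tmat)) 0L else sum(tmat[, 1] == 0L & tmat[, 2] == 1L)
  losses <- if (is.null(tmat)) 0L else sum(tmat[, 1] == 1L & tmat[, 2] == 0L)
  tip_states <- integer(length(tree$tip.label))
  for (e in seq_len(nrow(tree$edge))) {
    chi <- tree$edge[e, 2L]
    if (chi <= length(tree$tip.label)) {
      m <- maps[[e]]
      tip_states[chi] <- as.integer(names(m)[length(m)])
    }
  }
  names(tip_states) <- tree$tip.label
  structure(list(tree = tree, maps = maps, gains = gains, losses = losses,
                 tip_states = tip_states),
            class = "character_history")
}

#' @export
print.character_history <- function(x, ...) {
  cat("Character history on", length(x$tree$tip.label), "tips:",
      x$gains, "gain(s),", x$losses, "loss(es)\n")
  invisible(x)
}

## endpoint-conditioned path on one branch via uniformization (exact).
## Returns named segment-length vector, rootward first.
.sample_path <- function(a, b, t, q01, q10) {
  if (t <= 0) {
    if (a != b) stop("impossible endpoint pair on zero-length branch", call. = FALSE)
    return(stats::setNames(t, as.character(a)))
  }
  omega <- max(q01, q10)
  if (omega <= 0) {
    if (a != b) stop("impossible endpoint pair under zero rates", call. = FALSE)
    return(stats::setNames(t, as.character(a)))
  }
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  R <- diag(2) + Q / omega
  Pab <- .mk2_P(q01, q10, t)[a + 1L, b + 1L]
  if (Pab <= 0) stop("impossible endpoint pair for this branch", call. = FALSE)
  ## sample number of uniformized jumps N
  u <- stats::runif(1)
  Rpow <- list(diag(2))            # Rpow[[n+1]] = R^n
  cum <- stats::dpois(0, omega * t) * (a == b) / Pab
  N <- 0L
  while (cum < u) {
    N <- N + 1L
    if (N > 5000L) break
    Rpow[[N + 1L]] <- Rpow[[N]] %*% R
    cum <- cum + stats::dpois(N, omega * t) * Rpow[[N + 1L]][a + 1L, b + 1L] / Pab
  }
  if (N == 0L) return(stats::setNames(t, as.character(a)))
  ## bridge-sample the uniformized chain states at the N jumps
  states <- integer(N + 1L); states[1L] <- a
  for (k in seq_len(N)) {
    rem <- N - k
    w <- R[states[k] + 1L, ] * Rpow[[rem + 1L]][, b + 1L]
    states[k + 1L] <- sample.int(2L, 1L, prob = w) - 1L
  }
  if (states[N + 1L] != b) stop("internal error: bridge endpoint mismatch")
  times <- sort(stats::runif(N, 0, t))
  ## collapse virtual (self) jumps into segments
  bounds <- c(0, times, t)
  segstate <- states            # state on interval k is states[k]
  segs <- numeric(0); labs <- character(0)
  start <- 0; cur <- segstate[1L]
  for (k in seq_along(segstate)[-1L]) {
    if (segstate[k] != cur) {
      segs <- c(segs, bounds[k] - start); labs <- c(labs, as.character(cur))
      start <- bounds[k]; cur <- segstate[k]
    }
  }
  segs <- c(segs, t - start); labs <- c(labs, as.character(cur))
  stats::setNames(segs, labs)
}

#' Sample stochastic character histories
#'
#' SIMMAP-style stochastic mapping: compute conditional likelihoods by
#' pruning, draw joint node states root-to-tip, then draw an
#' endpoint-conditioned transition path along every branch by uniformization
#' (exact, no rejection). Model parameters are either fixed `(q01, q10)` or
#' drawn per map from a discretized `prior_grid` (see [calibrate_priors()]).
#'
#' @param tree Rooted `phylo`.
#' @param tip_states Named 0/1 vector.
#' @param q01,q10 Fixed rates (ignored when `prior_grid` given).
#' @param prior_grid Optional `prior_grid` object.
#' @param n_maps Number of histories to sample.
#' @param root_distribution Root-state weighting (see [mk2_loglik()]).
#' @param seed Optional integer seed.
#' @return List of `character_history` objects (class `history_set`).
#' @export
sample_history <- function(tree, tip_states, q01 = NULL, q10 = NULL,
                           prior_grid = NULL, n_maps = 1L,
                           root_distribution = "stationary", seed = NULL) {
  tree <- .validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  lay <- .tree_layout(tree)
  ptree <- lay$tree
  edge <- lay$edge
  n <- lay$n
  ## preorder = reverse postorder
  out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    if (!is.null(prior_grid)) {
      lam <- sample(prior_grid$rate_values, 1L)
      bet <- sample(prior_grid$bias_values, 1L)
      qs <- rate_bias_to_q(lam, bet)
      q01m <- qs[["q01"]]; q10m <- qs[["q10"]]
    } else {
      stopifnot(!is.null(q01), !is.null(q10))
      q01m <- q01; q10m <- q10
    }
    pr <- .mk2_prune(lay, tip_states, q01m, q10m, root_distribution)
    if (!is.finite(pr$lnL)) stop("data impossible under supplied rates", call. = FALSE)
    nnode <- n + ptree$Nnode
    st <- integer(nnode)
    w <- pr$root_prior * pr$partials[lay$root, ]
    st[lay$root] <- sample.int(2L, 1L, prob = w) - 1L
    for (e in rev(seq_len(nrow(edge)))) {   # preorder
      par <- edge[e, 1L]; chi <- edge[e, 2L]
      P <- .mk2_P(q01m, q10m, lay$len[e])
      w <- P[st[par] + 1L, ] * pr$partials[chi, ]
      st[chi] <- sample.int(2L, 1L, prob = w) - 1L
    }
    maps_post <- vector("list", nrow(edge))
    for (e in seq_len(nrow(edge)))
      maps_post[[e]] <- .sample_path(st[edge[e, 1L]], st[edge[e, 2L]],
                                     lay$len[e], q01m, q10m)
    ## re-align maps with the input tree's edge ordering
    key_post <- paste(edge[, 1], edge[, 2])
    key_in <- paste(tree$edge[, 1], tree$edge[, 2])
    maps <- maps_post[match(key_in, key_post)]
    out[[m]] <- .new_history(tree, maps)
  }
  structure(out, class = "history_set")
}

#' Summarize a collection of character histories
#'
#' @param histories A `history_set` (or plain list of `character_history`).
#' @return List with `gain_counts` / `loss_counts` (tables), `joint_mode`
#'   (modal (gains, losses) pair), and, when all histories share one tree,
#'   `branch_state1_prob`: the per-branch time-weighted probability of
#'   state 1 (the density map).
#' @export
summarize_histories <- function(histories) {
  stopifnot(length(histories) >= 1L)
  g <- vapply(histories, `[[`, numeric(1), "gains")
  l <- vapply(histories, `[[`, numeric(1), "losses")
  joint <- table(paste(g, l, sep = ","))
  same_tree <- all(vapply(histories, function(h)
    identical(dim(h$tree$edge), dim(histories[[1]]$tree$edge)) &&
      all(h$tree$edge == histories[[1]]$tree$edge), logical(1)))
  dens <- NULL
  if (same_tree) {
    tr <- histories[[1]]$tree
    p1 <- sapply(histories, function(h)
      vapply(h$maps, function(m) {
        tot <- sum(m)
        if (tot <= 0) as.numeric(names(m)[1] == "1") else sum(m[names(m) == "1"]) / tot
      }, numeric(1)))
    dens <- rowMeans(as.matrix(p1))
  }
  mode_pair <- as.integer(strsplit(names(joint)[which.max(joint)], ",")[[1]])
  list(gain_counts = table(g), loss_counts = table(l),
       joint = joint, joint_mode = c(gains = mode_pair[1], losses = mode_pair[2]),
       mean_gains = mean(g), mean_losses = mean(l),
       branch_state1_prob = dens)
}

#' Calibrate discretized mapping priors by MCMC
#'
#' Samples the overall transition rate `lambda` (gamma prior family) and the
#' gain bias `beta` (beta prior family) of the 2-state model by
#' Metropolis-Hastings on a tree rescaled to total length one, then fits
#' gamma/beta hyperparameters to the posterior draws by moment matching and
#' discretizes each into `k` equal-mass categories represented by their bin
#' medians (the discrete-gamma convention). Default category counts are 90
#' (rate) and 31 (bias).
#'
#' @param tree Consensus `phylo` (will be rescaled to total length 1).
#' @param tip_states Named 0/1 vector.
#' @param generations,sample_every,burnin MCMC control; samples are taken
#'   every `sample_every` generations after discarding a `burnin` fraction.
#' @param k_rate,k_bias Number of discrete categories.
#' @param root_distribution Root-state weighting.
#' @param seed Optional integer seed.
#' @return Object of class `prior_grid`: discretized `rate_values` (length
#'   `k_rate`), `bias_values` (length `k_bias`), fitted hyperparameters,
#'   posterior draws, and effective sample sizes (warns when ESS < 100).
#' @export
calibrate_priors <- function(tree, tip_states, generations = 500000L,
                             sample_every = 100L, burnin = 0.5,
                             k_rate = 90L, k_bias = 31L,
                             root_distribution = "stationary", seed = NULL) {
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  tree <- rescale_total_length(tree, 1)
  if (!is.null(seed)) set.seed(seed)
  lay <- .tree_layout(tree)
  loglik <- function(lam, bet) {
    qs <- rate_bias_to_q(lam, bet)
    .mk2_prune(lay, tip_states, qs[[1]], qs[[2]], root_distribution)$lnL
  }
  ## vague hyperpriors: lambda ~ Exp(mean 10 transitions/tree), beta ~ U(0,1)
  logprior <- function(lam, bet) stats::dexp(lam, rate = 0.1, log = TRUE)
  lam <- 2; bet <- 0.5
  lp <- loglik(lam, bet) + logprior(lam, bet)
  keep_every <- max(1L, as.integer(sample_every))
  n_iter <- as.integer(generations)
  draws <- matrix(NA_real_, floor(n_iter / keep_every), 2L,
                  dimnames = list(NULL, c("lambda", "beta")))
  acc <- 0L
  for (i in seq_len(n_iter)) {
    if (i %% 2L == 1L) {  # rate multiplier move
      lam2 <- lam * exp(stats::runif(1, -1, 1)); bet2 <- bet
      lhr <- log(lam2 / lam)   # Jacobian of multiplier proposal
    } else {               # bias logit random walk
      z <- log(bet / (1 - bet)) + stats::rnorm(1, 0, 0.7)
      bet2 <- 1 / (1 + exp(-z)); lam2 <- lam
      lhr <- log(bet2 * (1 - bet2)) - log(bet * (1 - bet))
    }
    lp2 <- loglik(lam2, bet2) + logprior(lam2, bet2)
    if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp + lhr) {
      lam <- lam2; bet <- bet2; lp <- lp2; acc <- acc + 1L
    }
    if (i %% keep_every == 0L) draws[i / keep_every, ] <- c(lam, bet)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  post <- draws[-seq_len(floor(nrow(draws) * burnin)), , drop = FALSE]
  ess <- apply(post, 2L, function(v) as.numeric(coda::effectiveSize(coda::mcmc(v))))
  if (any(ess < 100)) warning("low effective sample size in prior calibration: ",
                              paste(round(ess), collapse = ", "))
  m <- mean(post[, "lambda"]); v <- stats::var(post[, "lambda"])
  g_shape <- m^2 / v; g_scale <- v / m
  mb <- mean(post[, "beta"]); vb <- stats::var(post[, "beta"])
  common <- max(mb * (1 - mb) / vb - 1, 1e-6)
  b_a <- mb * common; b_b <- (1 - mb) * common
  rate_values <- stats::qgamma((seq_len(k_rate) - 0.5) / k_rate,
                               shape = g_shape, scale = g_scale)
  bias_values <- stats::qbeta((seq_len(k_bias) - 0.5) / k_bias, b_a, b_b)
  structure(list(rate_values = rate_values, bias_values = bias_values,
                 gamma_shape = g_shape, gamma_scale = g_scale,
                 beta_a = b_a, beta_b = b_b, ess = ess,
                 acceptance = acc / n_iter, draws = post),
            class = "prior_grid")
}

#' @export
print.prior_grid <- function(x, ...) {
  cat("Discretized mapping priors:\n",
      " rate  ~ Gamma(shape =", signif(x$gamma_shape, 3),
      ", scale =", signif(x$gamma_scale, 3), "), k =", length(x$rate_values), "\n",
      " bias  ~ Beta(", signif(x$beta_a, 3), ",", signif(x$beta_b, 3),
      "), k =", length(x$bias_values), "\n")
  invisible(x)
}
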