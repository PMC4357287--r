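## Independent brute-force oracles used across the suite. These never call
## the implementation paths they check.

## shared root-to-MRCA path length for every tip pair, by walking node paths
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  path <- function(i) {       # nodes from tip to root
    p <- i
    while (i != root) { i <- parent[i]; p <- c(p, i) }
    p
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:n) for (j in i:n) {
    ## C[i,j] = total length of edges above nodes on both root paths
    common <- setdiff(intersect(path(i), path(j)), root)
    C[i, j] <- C[j, i] <- sum(elen[common])
  }
  C
}

## exhaustive Mk2 likelihood: sum over all internal-node state assignments
oracle_mk2_lik <- function(tree, tip_states, q01, q10, root_dist = c(0.5, 0.5)) {
  P <- function(t) {
    s <- q01 + q10
    if (s == 0) return(diag(2))
    e <- exp(-s * t)
    p0 <- q10 / s; p1 <- q01 / s
    matrix(c(p0 + p1 * e, p1 - p1 * e, p0 - p0 * e, p1 + p0 * e),
           2, 2, byrow = TRUE)
  }
  n <- length(tree$tip.label)
  internals <- (n + 1L):(n + tree$Nnode)
  st <- integer(n + tree$Nnode)
  st[1:n] <- tip_states[tree$tip.label]
  grid <- expand.grid(rep(list(0:1), tree$Nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st[internals] <- as.integer(grid[g, ])
    pr <- root_dist[st[n + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1L]]; b <- st[tree$edge[e, 2L]]
      pr <- pr * P(tree$edge.length[e])[a + 1L, b + 1L]
    }
    tot <- tot + pr
  }
  tot
}

## two-tailed Fisher p by full hypergeometric enumeration (probability-mass
## rule) for a 2x2 table
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## random binary tip states on a tree, both states guaranteed present
rand_states <- function(tree) {
  repeat {
    st <- stats::setNames(stats::rbinom(length(tree$tip.label), 1, 0.5),
                          tree$tip.label)
    if (length(unique(st)) == 2L) return(st)
  }
}

## BM tip values via the dense covariance matrix (independent of pruning)
oracle_bm_sim <- function(tree, sigma2 = 1) {
  C <- ape::vcv.phylo(tree) * sigma2
  x <- as.vector(t(chol(C)) %*% stats::rnorm(nrow(C)))
  stats::setNames(x, rownames(C))
}

## dense-matrix multivariate-normal BM log-likelihood with profiled root
oracle_bm_lnL <- function(V, x) {
  Vi <- solve(V)
  mu <- sum(Vi %*% x) / sum(Vi)
  r <- x - mu
  as.numeric(-0.5 * (length(x) * log(2 * pi) +
                       determinant(V)$modulus + t(r) %*% Vi %*% r))
}
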