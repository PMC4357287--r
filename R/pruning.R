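## Internal likelihood engines shared by the rate and mapping modules.

## Brownian-motion log-likelihood with the root value profiled out
## analytically (GLS). `scaled_len` is a per-edge vector of variance
## contributions (rate x length already multiplied in), aligned with the
## postorder edge matrix of `layout`. Returns lnL, the GLS root, and the
## residual variance at the root. O(n) via Gaussian elimination on the tree
## (Felsenstein pruning); polytomies are merged sequentially, which is
## order-invariant for Gaussian factors.
.bm_profile_lnL <- function(layout, scaled_len, x) {
  cpp_bm_profile_lnL(layout$edge, layout$n, layout$tree$Nnode,
                     scaled_len, as.numeric(x[layout$tree$tip.label]))
}

## 2-state transition probability matrix P(t) = expm(Q t) in closed form,
## rows = from-state (0, 1), cols = to-state.
.mk2_P <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0 || t <= 0) return(diag(2))
  e <- exp(-s * t)
  p0 <- q10 / s   # stationary mass of state 0
  p1 <- q01 / s
  matrix(c(p0 + p1 * e, p1 - p1 * e,
           p0 - p0 * e, p1 + p0 * e), 2, 2, byrow = TRUE)
}

.mk2_root_dist <- function(q01, q10, root_distribution) {
  if (is.numeric(root_distribution)) {
    stopifnot(length(root_distribution) == 2L,
              all(root_distribution >= 0), sum(root_distribution) > 0)
    return(root_distribution / sum(root_distribution))
  }
  switch(match.arg(root_distribution, c("stationary", "flat")),
         stationary = {
           s <- q01 + q10
           if (s <= 0) c(0.5, 0.5) else c(q10, q01) / s
         },
         flat = c(0.5, 0.5))
}

## Felsenstein pruning for a binary character; returns lnL plus the scaled
## partial likelihoods (needed for joint node-state sampling in stochastic
## mapping). tip_states: named 0/1 vector covering all tips.
.mk2_prune <- function(layout, tip_states, q01, q10,
                       root_distribution = "stationary") {
  edge <- layout$edge
  n <- layout$n
  nnode <- n + layout$tree$Nnode
  L <- matrix(0, nnode, 2L)
  st <- tip_states[layout$tree$tip.label]
  if (any(is.na(st))) stop("missing tip state for: ",
                           paste(layout$tree$tip.label[is.na(st)], collapse = ", "),
                           call. = FALSE)
  if (!all(st %in% c(0, 1))) stop("tip states must be 0/1", call. = FALSE)
  L[cbind(seq_len(n), st + 1L)] <- 1
  started <- logical(nnode)
  logscale <- 0
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; chi <- edge[e, 2L]
    P <- .mk2_P(q01, q10, layout$len[e])
    contrib <- as.vector(P %*% L[chi, ])
    if (!started[par]) { L[par, ] <- contrib; started[par] <- TRUE }
    else L[par, ] <- L[par, ] * contrib
    mx <- max(L[par, ])
    if (mx > 0 && mx < 1e-200) { L[par, ] <- L[par, ] / mx; logscale <- logscale + log(mx) }
  }
  pi0 <- .mk2_root_dist(q01, q10, root_distribution)
  lik <- sum(pi0 * L[layout$root, ])
  if (lik <= 0) return(list(lnL = -Inf, partials = L, logscale = logscale, root_prior = pi0))
  list(lnL = log(lik) + logscale, partials = L, logscale = logscale, root_prior = pi0)
}
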