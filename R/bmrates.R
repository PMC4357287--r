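## Multi-rate Brownian-motion inference: ML non-censored rate test with
## AICc/LRT model selection, model averaging, and reversible-jump MCMC of
## branch-specific rates.

## index mapping from the postorder layout's edges to the input tree's edges
.edge_order <- function(tree, lay) {
  match(paste(lay$edge[, 1], lay$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Paint tree regimes from a character history
#'
#' Branches outside the dimorphism clade (tips labelled `"Rh"` in
#' `group_table`) are painted `Rh`; within the clade each history segment in
#' state 1 becomes `Dm` (dimorphic) and in state 0 `Mn` (secondarily
#' monomorphic), splitting branches at the mapped transition points.
#'
#' @param tree Rooted `phylo`.
#' @param history A `character_history` on the same tree.
#' @param group_table Named vector over tips with values `"Rh"` or `"Dip"`.
#' @return Object of class `regime_painting`: `tree` plus per-edge `maps`
#'   of segment lengths named by regime.
#' @export
paint_from_history <- function(tree, history, group_table) {
  tree <- .validate_tree(tree)
  stopifnot(inherits(history, "character_history"))
  miss <- setdiff(tree$tip.label, names(group_table))
  if (length(miss)) stop("tips absent from group_table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  gt <- group_table[tree$tip.label]
  if (!all(gt %in% c("Rh", "Dip"))) stop("group_table values must be Rh/Dip",
                                         call. = FALSE)
  dip <- names(gt)[gt == "Dip"]
  if (length(dip) < 2L) stop("need >= 2 Dip tips to define the clade", call. = FALSE)
  mrca <- ape::getMRCA(tree, dip)
  inside <- .clade_edges(tree, mrca) | tree$edge[, 2] == mrca
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    if (!inside[e]) maps[[e]] <- stats::setNames(tree$edge.length[e], "Rh")
    else {
      m <- history$maps[[e]]
      maps[[e]] <- stats::setNames(as.numeric(m),
                                   ifelse(names(m) == "1", "Dm", "Mn"))
    }
  }
  structure(list(tree = tree, maps = maps), class = "regime_painting")
}

#' Static regime painting from tip groups
#'
#' Paints every edge by the group of its descendant tips; edges whose
#' descendants span several groups (backbone edges) take the majority group
#' among their descendant tips, ties resolved toward the first group in
#' sorted order. A convenience for hypothesis-style paintings.
#'
#' @param tree Rooted `phylo`.
#' @param groups Named vector of group labels per tip.
#' @return A `regime_painting`.
#' @export
paint_from_groups <- function(tree, groups) {
  tree <- .validate_tree(tree)
  gt <- groups[tree$tip.label]
  if (any(is.na(gt))) stop("groups must cover every tip", call. = FALSE)
  lay <- .tree_layout(tree)
  n <- lay$n
  gset <- sort(unique(gt))
  counts <- matrix(0L, n + lay$tree$Nnode, length(gset),
                   dimnames = list(NULL, gset))
  counts[cbind(seq_len(n), match(gt[lay$tree$tip.label], gset))] <- 1L
  for (e in seq_len(nrow(lay$edge)))         # postorder: children known
    counts[lay$edge[e, 1L], ] <- counts[lay$edge[e, 1L], ] +
      counts[lay$edge[e, 2L], ]
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    g <- gset[which.max(counts[tree$edge[e, 2L], ])]
    maps[[e]] <- stats::setNames(tree$edge.length[e], g)
  }
  structure(list(tree = tree, maps = maps), class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  tot <- tapply(unlist(x$maps), unlist(lapply(x$maps, names)), sum)
  cat("Regime painting:",
      paste(sprintf("%s %.3g", names(tot), tot), collapse = ", "),
      "(branch length per regime)\n")
  invisible(x)
}

## per-edge length within each regime, rows in the input tree's edge order
.regime_lengths <- function(painting) {
  regs <- sort(unique(unlist(lapply(painting$maps, names))))
  E <- matrix(0, length(painting$maps), length(regs),
              dimnames = list(NULL, regs))
  for (e in seq_along(painting$maps)) {
    m <- painting$maps[[e]]
    for (g in unique(names(m))) E[e, g] <- E[e, g] + sum(m[names(m) == g])
  }
  E
}

#' Brownian-motion log-likelihood under a regime painting
#'
#' The trait covariance is built from branch segments, each contributing
#' (regime rate) x (segment length) to the shared-ancestry structure; the
#' root value is profiled analytically (GLS). O(n) by pruning.
#'
#' @param tree Rooted `phylo`.
#' @param trait Named per-tip values (e.g. PC1 scores).
#' @param painting A `regime_painting` (or `character_history` with states
#'   as regime names).
#' @param rates Named vector of rates per regime (>= 0, at least one > 0).
#' @return List with `lnL` and `root` (the GLS root estimate).
#' @export
bm_loglik <- function(tree, trait, painting, rates) {
  tree <- .validate_tree(tree)
  if (any(is.na(trait[tree$tip.label])))
    stop("trait missing for some tips", call. = FALSE)
  if (any(rates < 0) || all(rates == 0)) stop("need rates >= 0, one positive",
                                              call. = FALSE)
  E <- .regime_lengths(painting)
  if (!all(colnames(E) %in% names(rates)))
    stop("no rate for regime(s): ",
         paste(setdiff(colnames(E), names(rates)), collapse = ", "), call. = FALSE)
  scaled <- as.vector(E %*% rates[colnames(E)])
  lay <- .tree_layout(tree)
  res <- .bm_profile_lnL(lay, scaled[.edge_order(tree, lay)], trait)
  list(lnL = res$lnL, root = res$root)
}

.model_specs <- list(
  "1,1,1" = c(Rh = 1L, Dm = 1L, Mn = 1L),
  "1,2,2" = c(Rh = 1L, Dm = 2L, Mn = 2L),
  "1,2,1" = c(Rh = 1L, Dm = 2L, Mn = 1L),
  "1,1,2" = c(Rh = 1L, Dm = 1L, Mn = 2L),
  "1,2,3" = c(Rh = 1L, Dm = 2L, Mn = 3L))

#' Fit a multi-rate Brownian-motion model by maximum likelihood
#'
#' The model name maps the regimes (Rh, Dm, Mn) to rate-parameter indices:
#' `"1,1,1"` single rate; `"1,2,2"` separate rate for Diplogastridae;
#' `"1,2,1"` separate rate for dimorphic taxa; `"1,1,2"` separate rate for
#' secondarily monomorphic taxa; `"1,2,3"` all three distinct. Rates are
#' optimized in log space from three starts; the root is profiled (GLS) and
#' counted as a free parameter, so `K = n_rates + 1` and
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n-K-1)` with n the number of tips.
#'
#' @param tree Rooted `phylo`.
#' @param trait Named per-tip values.
#' @param painting A `regime_painting`.
#' @param model One of `"1,1,1"`, `"1,2,2"`, `"1,2,1"`, `"1,1,2"`, `"1,2,3"`,
#'   or a named integer vector mapping regimes to parameter indices.
#' @return Object of class `bm_fit`.
#' @export
fit_multirate <- function(tree, trait, painting, model = "1,2,3") {
  tree <- .validate_tree(tree)
  E <- .regime_lengths(painting)
  present <- colnames(E)
  spec <- if (is.character(model)) {
    if (!model %in% names(.model_specs)) stop("unknown model: ", model, call. = FALSE)
    idx <- .model_specs[[model]]
    if (all(present %in% names(idx))) idx[present]
    else if (length(unique(idx)) == 1L)       # single-rate for any painting
      stats::setNames(rep(1L, length(present)), present)
    else if (length(present) == length(idx))
      stats::setNames(unname(idx), present)   # digits applied in sorted order
    else stop("model '", model, "' does not cover painted regime(s): ",
              paste(setdiff(present, names(idx)), collapse = ", "),
              call. = FALSE)
  } else model[present]
  if (any(is.na(spec))) stop("model does not cover painted regime(s): ",
                             paste(present[is.na(spec)], collapse = ", "),
                             call. = FALSE)
  spec <- stats::setNames(match(spec, sort(unique(spec))), names(spec))  # contiguous
  np <- max(spec)
  lay <- .tree_layout(tree)
  ord <- .edge_order(tree, lay)
  x <- trait[tree$tip.label]
  if (any(is.na(x))) stop("trait missing for some tips", call. = FALSE)
  ## per-edge lengths aggregated per parameter index
  P <- sapply(seq_len(np), function(j)
    rowSums(E[, names(spec)[spec == j], drop = FALSE]))
  P <- matrix(P, ncol = np)[ord, , drop = FALSE]
  negll <- function(lp) {
    s2 <- exp(pmin(pmax(lp, log(1e-10)), log(1e10)))
    v <- tryCatch(-.bm_profile_lnL(lay, as.vector(P %*% s2), x)$lnL,
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  s2_0 <- stats::var(x) / max(1e-12, mean(ape::node.depth.edgelength(tree)[seq_along(x)]))
  starts <- list(rep(log(s2_0), np), rep(log(s2_0 * 10), np), rep(log(s2_0 / 10), np))
  fits <- lapply(starts, function(s)
    if (np == 1L) {
      o <- stats::optimize(function(z) negll(z), interval = s[1] + c(-12, 12))
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(s, negll, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
    })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  s2 <- exp(best$par)
  lnL <- -best$value
  if (!is.finite(lnL) || lnL <= -1e9)
    stop("rate optimization failed; last iterate: ",
         paste(signif(s2, 4), collapse = ", "), call. = FALSE)
  rates_regime <- stats::setNames(s2[spec], names(spec))
  n <- length(tree$tip.label)
  K <- np + 1L
  fin <- .bm_profile_lnL(lay, as.vector(P %*% s2), x)
  structure(list(model = if (is.character(model)) model else
                   paste(spec, collapse = ","),
                 rates = stats::setNames(s2, paste0("sigma2_", seq_len(np))),
                 regime_rates = rates_regime, root = fin$root,
                 lnL = lnL, K = K, n = n,
                 AICc = aicc(lnL, K, n),
                 spec = spec),
            class = "bm_fit")
}

#' Second-order Akaike information criterion
#' @param lnL Log-likelihood. @param K Free parameters. @param n Sample size.
#' @return AICc value.
#' @export
aicc <- function(lnL, K, n) {
  if (n - K - 1 <= 0) stop("AICc undefined: n <= K + 1", call. = FALSE)
  -2 * lnL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Multirate BM fit (", x$model, "): lnL = ", round(x$lnL, 4),
      ", AICc = ", round(x$AICc, 4), "\n  rates: ",
      paste(sprintf("%s = %.4g", names(x$regime_rates), x$regime_rates),
            collapse = ", "), "\n  root: ", signif(x$root, 6), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.bm_fit <- function(object, ...) {
  structure(object$lnL, df = object$K, nobs = object$n, class = "logLik")
}

#' @export
coef.bm_fit <- function(object, ...) c(object$regime_rates, root = object$root)

## is model a nested in model b? (b's regime partition refines a's: whenever
## b equates two regimes, a does too, and a has strictly fewer parameters)
.nested_in <- function(a, b) {
  if (max(a) >= max(b)) return(FALSE)
  nms <- names(a)
  b <- b[nms]
  for (i in seq_along(nms)) for (j in seq_along(nms))
    if (b[i] == b[j] && a[i] != a[j]) return(FALSE)
  TRUE
}

#' Compare fitted multirate BM models
#'
#' Tabulates AICc differences relative to the best model (flagging models
#' with dAICc > 4 as much less supported) and likelihood-ratio tests for
#' nested pairs (chi-square, df = difference in parameter count). Non-nested
#' pairs get no LRT.
#'
#' @param fits List of `bm_fit` objects on the same data/painting.
#' @return List with `table` (data frame) and `lrt` (data frame of nested
#'   pairs).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, logical(1), "bm_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) stop("fits are on different datasets", call. = FALSE)
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    K = vapply(fits, `[[`, numeric(1), "K"),
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    AICc = vapply(fits, `[[`, numeric(1), "AICc"))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$much_less_supported <- tab$dAICc > 4
  w <- exp(-tab$dAICc / 2)
  tab$akaike_weight <- w / sum(w)
  lrt <- list()
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j) next
    a <- fits[[i]]; b <- fits[[j]]
    if (.nested_in(a$spec, b$spec)) {
      if (b$lnL < a$lnL - 1e-6)
        stop("optimization pathology: nested model ", a$model,
             " fits better than ", b$model, call. = FALSE)
      stat <- max(0, 2 * (b$lnL - a$lnL))
      df <- b$K - a$K
      lrt[[length(lrt) + 1L]] <-
        data.frame(null = a$model, alternative = b$model,
                   statistic = stat, df = df,
                   p = stats::pchisq(stat, df, lower.tail = FALSE))
    }
  }
  list(table = tab[order(tab$AICc), ],
       lrt = if (length(lrt)) do.call(rbind, lrt) else NULL)
}

#' Average regime rates across reconstructions (and optionally models)
#'
#' With `scheme = "mean"`, `fits` is a flat list of `bm_fit` objects (e.g.
#' the same model refit across mapped histories and trees) and per-regime
#' rates are averaged directly. With `scheme = "akaike"`, `fits` is a list
#' of lists (one inner list of candidate-model fits per reconstruction);
#' within each reconstruction regime rates are weighted by Akaike weights
#' before averaging across reconstructions.
#'
#' @param fits See Description.
#' @param scheme `"mean"` or `"akaike"`.
#' @return Data frame with `regime`, `mean`, `sd`, `n`.
#' @export
model_average <- function(fits, scheme = c("mean", "akaike")) {
  scheme <- match.arg(scheme)
  per_rec <- if (scheme == "mean") {
    lapply(fits, function(f) f$regime_rates)
  } else {
    lapply(fits, function(fl) {
      a <- vapply(fl, `[[`, numeric(1), "AICc")
      w <- exp(-(a - min(a)) / 2); w <- w / sum(w)
      regs <- names(fl[[1]]$regime_rates)
      stats::setNames(colSums(w * t(vapply(fl, function(f)
        f$regime_rates[regs], numeric(length(regs))))), regs)
    })
  }
  regs <- names(per_rec[[1]])
  M <- t(vapply(per_rec, function(r) r[regs], numeric(length(regs))))
  data.frame(regime = regs, mean = colMeans(M),
             sd = apply(M, 2L, stats::sd), n = nrow(M), row.names = NULL)
}

#' Reversible-jump MCMC over branch-specific Brownian rates
#'
#' Relaxed-Brownian model with at most `max_clocks` local clocks: a set of
#' shift branches partitions the tree into clock classes (each branch takes
#' the clock of its nearest rootward shift, or the background clock).
#' Moves: clock-rate multipliers with log-width `proposal_width`,
#' shift-location moves, and dimension-changing add/delete moves whose new
#' rate is drawn from the prior (making the Green ratio collapse to the
#' likelihood ratio times the clock-number prior ratio). Priors: geometric
#' penalty `clock_penalty^(k-1)` on the number of clocks k (so extra clocks
#' must earn their keep; `clock_penalty = 1` recovers a uniform prior),
#' shift placement uniform over branch sets, rates iid lognormal(0, 2).
#'
#' @param tree Rooted `phylo`.
#' @param trait Named per-tip trait (non-constant).
#' @param max_clocks Maximum number of local clocks (default 3).
#' @param proposal_width Log-width of the rate multiplier (default 1.5).
#' @param generations Generations per chain.
#' @param sample_every Thinning interval (default 5000; lower it for short
#'   desk-scale chains).
#' @param burnin Fraction of generations discarded (default 0.25).
#' @param n_chains Independent chains combined after burn-in (default 3).
#' @param clock_penalty Prior odds of each additional clock (default 0.25).
#' @param seed Optional integer seed.
#' @return Object of class `branch_rates_mcmc`: `rates` (draws x edges
#'   matrix of branch rates in the input tree's edge order), `n_clocks`,
#'   `lnL` traces, `acceptance`, `tree`.
#' @export
mcmc_branch_rates <- function(tree, trait, max_clocks = 3L,
                              proposal_width = 1.5, generations = 100000L,
                              sample_every = 5000L, burnin = 0.25,
                              n_chains = 3L, clock_penalty = 0.25,
                              seed = NULL) {
  tree <- .validate_tree(tree)
  x <- trait[tree$tip.label]
  if (any(is.na(x))) stop("trait missing for some tips", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant trait: zero-variance likelihood",
                              call. = FALSE)
  stopifnot(generations >= sample_every)
  if (!is.null(seed)) set.seed(seed)
  lay <- .tree_layout(tree)
  nE <- nrow(lay$edge)
  ord <- .edge_order(tree, lay)           # postorder row -> input-order index
  ## parent edge index (postorder indexing) for clock propagation
  edge_of_node <- integer(lay$n + lay$tree$Nnode)
  edge_of_node[lay$edge[, 2L]] <- seq_len(nE)
  parent_edge <- edge_of_node[lay$edge[, 1L]]   # 0 for root's children
  preord <- rev(seq_len(nE))
  clock_of_edges <- function(shifts) {
    sc <- integer(nE)
    sc[shifts] <- seq_along(shifts) + 1L
    cl <- integer(nE)
    for (e in preord) {
      cl[e] <- if (sc[e] > 0L) sc[e]
               else if (parent_edge[e] == 0L) 1L else cl[parent_edge[e]]
    }
    cl
  }
  lnprior_rate <- function(r) stats::dlnorm(r, 0, 2, log = TRUE)
  lnL_of <- function(cl, rates)
    .bm_profile_lnL(lay, rates[cl] * lay$len, x)$lnL
  s2_0 <- stats::var(x) / max(1e-12, mean(ape::node.depth.edgelength(tree)[seq_len(lay$n)]))
  total_kept <- 0L
  rate_draws <- list(); k_draws <- c(); ll_draws <- c()
  acc <- c(rate = 0, shift = 0, jump = 0); prop <- c(rate = 0, shift = 0, jump = 0)
  for (ch in seq_len(n_chains)) {
    shifts <- integer(0)
    rates <- max(s2_0, 1e-8)
    cl <- clock_of_edges(shifts)
    ll <- lnL_of(cl, rates)
    keep_from <- ceiling(generations * burnin)
    for (g in seq_len(generations)) {
      u <- stats::runif(1)
      ## with no shifts the shift-location move is unavailable; treat that
      ## draw as a rate move so the jump-move probability stays 0.2 in every
      ## state (dimension balance)
      if (u < 0.6 || (u < 0.8 && length(shifts) == 0L)) {  # rate multiplier
        prop["rate"] <- prop["rate"] + 1
        j <- sample.int(length(rates), 1L)
        r2 <- rates; r2[j] <- rates[j] * exp(proposal_width * stats::runif(1, -0.5, 0.5))
        ll2 <- lnL_of(cl, r2)
        a <- ll2 - ll + lnprior_rate(r2[j]) - lnprior_rate(rates[j]) +
          log(r2[j] / rates[j])
        if (log(stats::runif(1)) < a) { rates <- r2; ll <- ll2; acc["rate"] <- acc["rate"] + 1 }
      } else if (u < 0.8) {               # move a shift
        prop["shift"] <- prop["shift"] + 1
        j <- sample.int(length(shifts), 1L)
        avail <- setdiff(seq_len(nE), shifts)
        s2 <- shifts; s2[j] <- sample(avail, 1L)
        cl2 <- clock_of_edges(s2)
        ll2 <- lnL_of(cl2, rates)
        if (log(stats::runif(1)) < ll2 - ll) {
          shifts <- s2; cl <- cl2; ll <- ll2; acc["shift"] <- acc["shift"] + 1
        }
      } else {                            # add/delete a shift
        prop["jump"] <- prop["jump"] + 1
        add <- if (length(shifts) == 0L) TRUE
               else if (length(shifts) == max_clocks - 1L) FALSE
               else stats::runif(1) < 0.5
        if (add) {
          e_new <- sample(setdiff(seq_len(nE), shifts), 1L)
          r_new <- stats::rlnorm(1, 0, 2)
          s2 <- c(shifts, e_new); r2 <- c(rates, r_new)
          ## account for asymmetric add/delete choice probabilities at the
          ## dimension bounds
          q_fwd <- if (length(shifts) == 0L) 1 else 0.5
          q_rev <- if (length(s2) == max_clocks - 1L) 1 else 0.5
        } else {
          j <- sample.int(length(shifts), 1L)
          s2 <- shifts[-j]; r2 <- rates[-(j + 1L)]
          q_fwd <- if (length(shifts) == max_clocks - 1L) 1 else 0.5
          q_rev <- if (length(s2) == 0L) 1 else 0.5
        }
        cl2 <- clock_of_edges(s2)
        ll2 <- lnL_of(cl2, r2)
        dk <- length(r2) - length(rates)      # +1 add, -1 delete
        if (log(stats::runif(1)) <
            ll2 - ll + dk * log(clock_penalty) + log(q_rev / q_fwd)) {
          shifts <- s2; rates <- r2; cl <- cl2; ll <- ll2
          acc["jump"] <- acc["jump"] + 1
        }
      }
      if (g > keep_from && g %% sample_every == 0L) {
        total_kept <- total_kept + 1L
        br <- rates[cl]                    # postorder edge rates
        rate_draws[[total_kept]] <- br[order(ord)]  # -> input edge order
        k_draws <- c(k_draws, length(rates))
        ll_draws <- c(ll_draws, ll)
      }
    }
  }
  if (!total_kept) stop("no samples kept; increase generations", call. = FALSE)
  R <- do.call(rbind, rate_draws)
  structure(list(rates = R, n_clocks = k_draws, lnL = ll_draws,
                 acceptance = ifelse(prop > 0, acc / prop, NA),
                 tree = tree, max_clocks = max_clocks,
                 proposal_width = proposal_width),
            class = "branch_rates_mcmc")
}

#' @export
print.branch_rates_mcmc <- function(x, ...) {
  cat("rjMCMC branch rates:", nrow(x$rates), "draws on", ncol(x$rates),
      "branches; P(k clocks):",
      paste(sprintf("%d:%.2f", as.integer(names(table(x$n_clocks))),
                    as.vector(table(x$n_clocks)) / length(x$n_clocks)),
            collapse = " "), "\n")
  invisible(x)
}

#' Group-level posterior rates and randomization test
#'
#' Extracts branch-length-weighted posterior mean rates per group, 95% HPD
#' intervals (shortest interval), and pairwise two-tailed randomization
#' p-values obtained by permuting the branch-to-group assignment.
#'
#' @param trace A `branch_rates_mcmc`.
#' @param edge_groups Character vector of group labels, one per edge of the
#'   trace's tree (input edge order); e.g. the dominant regime from a
#'   painting.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Optional integer seed.
#' @return List with `summary` (group, weighted mean, HPD) and `pairwise`
#'   (two-tailed p per group pair).
#' @export
group_rate_test <- function(trace, edge_groups, n_perm = 2000L, seed = NULL) {
  stopifnot(inherits(trace, "branch_rates_mcmc"),
            length(edge_groups) == ncol(trace$rates))
  if (!is.null(seed)) set.seed(seed)
  len <- trace$tree$edge.length
  gset <- if (is.factor(edge_groups)) levels(edge_groups)
          else sort(unique(edge_groups))
  counts <- table(factor(edge_groups, gset))
  if (any(counts == 0)) stop("group with 0 branches: ",
                             paste(gset[counts == 0], collapse = ", "),
                             call. = FALSE)
  if (length(gset) < 2L) stop("need at least two groups", call. = FALSE)
  edge_groups <- as.character(edge_groups)
  ## per-draw weighted mean rate per group
  W <- sapply(gset, function(g) {
    idx <- edge_groups == g
    as.vector(trace$rates[, idx, drop = FALSE] %*% len[idx]) / sum(len[idx])
  })
  W <- matrix(W, ncol = length(gset), dimnames = list(NULL, gset))
  hpd <- coda::HPDinterval(coda::mcmc(W), prob = 0.95)
  summ <- data.frame(group = gset, mean = colMeans(W),
                     hpd_lower = hpd[, 1], hpd_upper = hpd[, 2],
                     row.names = NULL)
  ## randomization test on posterior-mean branch rates
  pm <- colMeans(trace$rates)
  wmean <- function(groups, g) sum(pm[groups == g] * len[groups == g]) /
    sum(len[groups == g])
  pairs <- utils::combn(gset, 2L)
  pw <- apply(pairs, 2L, function(pr) {
    obs <- wmean(edge_groups, pr[1]) - wmean(edge_groups, pr[2])
    perm <- vapply(seq_len(n_perm), function(i) {
      pg <- sample(edge_groups)
      wmean(pg, pr[1]) - wmean(pg, pr[2])
    }, numeric(1))
    (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  })
  list(summary = summ,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = pw))
}

#' Dominant regime per edge of a painting
#'
#' @param painting A `regime_painting`.
#' @return Character vector, one label per edge (majority branch length).
#' @export
edge_regimes <- function(painting) {
  vapply(painting$maps, function(m) {
    tot <- tapply(m, names(m), sum)
    names(tot)[which.max(tot)]
  }, character(1))
}
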