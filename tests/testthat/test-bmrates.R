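star4 <- local({
  s <- ape::stree(4, "star"); s$edge.length <- rep(1, 4)
  s$tip.label <- paste0("t", 1:4); s
})

test_that("BM likelihood under a painting matches dense-matrix algebra", {
  ## 2-tip star, unit branches, traits (0, 2): lnL = log(phi(1)^2)
  star2 <- read_trees("(A:1,B:1);")[[1]]
  p <- paint_from_groups(star2, c(A = "g", B = "g"))
  res <- bm_loglik(star2, c(A = 0, B = 2), p, c(g = 1))
  expect_equal(res$root, 1)
  expect_equal(res$lnL, log(dnorm(1)^2), tolerance = 1e-10)
  ## any painting with equal rates reduces to single-rate BM
  set.seed(41)
  tr <- ape::rtree(20)
  gr <- stats::setNames(sample(c("a", "b"), 20, TRUE), tr$tip.label)
  pa <- paint_from_groups(tr, gr)
  x <- oracle_bm_sim(tr, 1.7)
  two <- bm_loglik(tr, x, pa, c(a = 1.7, b = 1.7))
  one <- bm_loglik(tr, x, paint_from_groups(tr, stats::setNames(rep("a", 20),
                                                                tr$tip.label)),
                   c(a = 1.7))
  expect_equal(two$lnL, one$lnL, tolerance = 1e-8)
  ## dense-matrix oracle on a multi-rate painting
  E <- plastevol:::.regime_lengths(pa)
  rates <- c(a = 0.5, b = 4)
  scl <- as.vector(E %*% rates[colnames(E)])
  V <- matrix(0, 20, 20, dimnames = list(tr$tip.label, tr$tip.label))
  lay <- plastevol:::.tree_layout(tr)
  ## oracle: accumulate shared scaled lengths pair by pair
  tr_scaled <- tr; tr_scaled$edge.length <- scl
  V <- ape::vcv.phylo(tr_scaled)
  expect_equal(bm_loglik(tr, x, pa, rates)$lnL,
               oracle_bm_lnL(V[tr$tip.label, tr$tip.label], x[tr$tip.label]),
               tolerance = 1e-8)
})

test_that("rescaling branches and rates inversely leaves the likelihood fixed", {
  set.seed(42)
  tr <- ape::rtree(15)
  gr <- stats::setNames(rep(c("a", "b"), c(7, 8)), tr$tip.label)
  x <- oracle_bm_sim(tr)
  p1 <- paint_from_groups(tr, gr)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  p2 <- paint_from_groups(tr2, gr)
  l1 <- bm_loglik(tr, x, p1, c(a = 1, b = 2))
  l2 <- bm_loglik(tr2, x, p2, c(a = 1 / 3, b = 2 / 3))
  expect_equal(l1$lnL, l2$lnL, tolerance = 1e-8)
})

test_that("single-rate ML on a star tree is SS/n, and AICc is arithmetic", {
  x <- c(t1 = 0, t2 = 0, t3 = 3, t4 = 3)
  p <- paint_from_groups(star4, stats::setNames(rep("Rh", 4), star4$tip.label))
  f <- fit_multirate(star4, x, p, "1,1,1")
  expect_equal(unname(f$rates[1]), 2.25, tolerance = 1e-4)
  expect_equal(f$K, 2L)
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_equal(f$AICc, aicc(f$lnL, 2, 4))
})

test_that("ML multirate fit agrees with the independent phytools rate test", {
  set.seed(43)
  tr <- ape::rcoal(30)
  clade <- ape::extract.clade(tr, ape::getMRCA(tr, tr$tip.label[1:10]))$tip.label
  gr <- stats::setNames(ifelse(tr$tip.label %in% clade, "b", "a"), tr$tip.label)
  pa <- paint_from_groups(tr, gr)
  E <- plastevol:::.regime_lengths(pa)
  tr_s <- tr; tr_s$edge.length <- as.vector(E %*% c(a = 1, b = 6)[colnames(E)])
  x <- oracle_bm_sim(tr_s)
  ## independent reference: phytools paints the same clade and fits by its
  ## own likelihood machinery
  simtree <- phytools::paintSubTree(tr, node = ape::getMRCA(tr, clade),
                                    state = "b", anc.state = "a", stem = TRUE)
  ref <- phytools::brownie.lite(simtree, x[tr$tip.label])
  mine1 <- fit_multirate(tr, x, pa, "1,1,1")
  expect_equal(mine1$lnL, ref$logL1, tolerance = 1e-4)
  expect_equal(unname(mine1$rates[1]), ref$sig2.single, tolerance = 1e-3)
  mine2 <- fit_multirate(tr, x, pa, stats::setNames(c(1L, 2L), c("a", "b")))
  expect_equal(mine2$lnL, ref$logL.multiple, tolerance = 1e-3)
  expect_equal(sort(unname(mine2$rates)), sort(unname(ref$sig2.multiple)),
               tolerance = 1e-2)
})

test_that("model comparison flags support thresholds and tests nested pairs", {
  set.seed(44)
  d <- simulate_study(seed = 9)
  fits <- lapply(c("1,1,1", "1,2,2", "1,2,1", "1,1,2", "1,2,3"),
                 function(m) fit_multirate(d$tree, d$trait, d$painting, m))
  cmp <- compare_models(fits)
  expect_equal(nrow(cmp$table), 5L)
  expect_equal(cmp$table$dAICc[1], 0)
  expect_equal(sum(cmp$table$akaike_weight), 1)
  ## every nested pair present; chi-square arithmetic on a known quantile
  expect_true(all(c("1,1,1") %in% cmp$lrt$null))
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  ## the generating three-rate model should beat the single-rate model
  daicc_111 <- cmp$table$dAICc[cmp$table$model == "1,1,1"]
  expect_gt(daicc_111, 4)
})

test_that("model averaging combines fits by the requested scheme", {
  f1 <- structure(list(model = "1,1,1", regime_rates = c(Rh = 1, Dm = 1),
                       AICc = 10), class = "bm_fit")
  f2 <- structure(list(model = "1,1,1", regime_rates = c(Rh = 3, Dm = 3),
                       AICc = 10), class = "bm_fit")
  avg <- model_average(list(f1, f2), "mean")
  expect_equal(avg$mean, c(2, 2))
  expect_equal(avg$sd, c(sd(c(1, 3)), sd(c(1, 3))))
  ## identical fits: zero SD
  avg0 <- model_average(list(f1, f1), "mean")
  expect_equal(avg0$sd, c(0, 0))
  ## Akaike weights normalize within each reconstruction
  avg2 <- model_average(list(list(f1, f2)), "akaike")
  expect_equal(avg2$mean, c(2, 2))
})

test_that("painting from a history splits branches at transition points", {
  d <- simulate_study(seed = 5)
  gt <- stats::setNames(ifelse(d$groups == "Rh", "Rh", "Dip"), names(d$groups))
  fit <- fit_mk2(d$tree, d$tip_states)
  h <- sample_history(d$tree, d$tip_states, q01 = fit$q01, q10 = fit$q10,
                      n_maps = 1, seed = 3)[[1]]
  pa <- paint_from_history(d$tree, h, gt)
  lens <- vapply(pa$maps, sum, numeric(1))
  expect_equal(lens, d$tree$edge.length, tolerance = 1e-8)
  regs <- unique(unlist(lapply(pa$maps, names)))
  expect_true(all(regs %in% c("Rh", "Dm", "Mn")))
  ## deterministic painting under a fixed seed
  h2 <- sample_history(d$tree, d$tip_states, q01 = fit$q01, q10 = fit$q10,
                       n_maps = 1, seed = 3)[[1]]
  expect_identical(paint_from_history(d$tree, h2, gt)$maps, pa$maps)
  expect_error(paint_from_history(d$tree, h, gt[-1]), "absent")
})

test_that("rjMCMC prefers one clock on single-rate data and finds real shifts", {
  set.seed(45)
  ## null: single-rate BM
  pref <- 0
  for (i in 1:5) {
    tr <- simulate_tree(50, seed = 150 + i)
    x <- oracle_bm_sim(tr)
    m <- mcmc_branch_rates(tr, x, generations = 6000, sample_every = 10,
                           n_chains = 1, seed = 250 + i)
    pref <- pref + (mean(m$n_clocks == 1) >= 0.5)
  }
  expect_gte(pref, 4)
  ## signal: one clade 20x faster
  hits <- 0
  for (i in 1:5) {
    tr <- simulate_tree(50, seed = 160 + i)
    clade <- ape::extract.clade(tr, 50 + 10)$tip.label
    gr <- stats::setNames(ifelse(tr$tip.label %in% clade, "fast", "slow"),
                          tr$tip.label)
    pa <- paint_from_groups(tr, gr)
    E <- plastevol:::.regime_lengths(pa)
    tr_s <- tr
    tr_s$edge.length <- as.vector(E %*% c(fast = 20, slow = 1)[colnames(E)])
    x <- oracle_bm_sim(tr_s)
    m <- mcmc_branch_rates(tr, x, generations = 8000, sample_every = 10,
                           n_chains = 1, seed = 260 + i)
    pm <- colMeans(m$rates)
    er <- edge_regimes(pa)
    hits <- hits + (mean(pm[er == "fast"]) > mean(pm[er == "slow"]))
  }
  expect_gte(hits, 5)
  ## reproducibility
  tr <- simulate_tree(20, seed = 170)
  x <- oracle_bm_sim(tr)
  m1 <- mcmc_branch_rates(tr, x, generations = 2000, sample_every = 10,
                          n_chains = 1, seed = 7)
  m2 <- mcmc_branch_rates(tr, x, generations = 2000, sample_every = 10,
                          n_chains = 1, seed = 7)
  expect_identical(m1$rates, m2$rates)
  expect_error(mcmc_branch_rates(tr, stats::setNames(rep(1, 20), tr$tip.label)),
               "constant")
})

test_that("group rate extraction weights by branch length and permutes fairly", {
  set.seed(46)
  tr <- simulate_tree(30, seed = 190)
  x <- oracle_bm_sim(tr)
  m <- mcmc_branch_rates(tr, x, generations = 3000, sample_every = 10,
                         n_chains = 1, seed = 8)
  er <- rep(c("A", "B"), length.out = ncol(m$rates))
  g <- group_rate_test(m, er, n_perm = 499, seed = 9)
  expect_equal(nrow(g$summary), 2L)
  expect_true(all(g$summary$hpd_lower <= g$summary$mean &
                    g$summary$mean <= g$summary$hpd_upper))
  ## exchangeable labels on homogeneous data: p typically large
  expect_gt(g$pairwise$p, 0.05)
  expect_error(group_rate_test(m, factor(rep("A", ncol(m$rates)),
                                         levels = c("A", "B"))), "0 branches")
})
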