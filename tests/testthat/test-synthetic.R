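test_that("birth-death tree simulation is reproducible and Yule-consistent", {
  t1 <- simulate_tree(90, seed = 42)
  t2 <- simulate_tree(90, seed = 42)
  expect_equal(length(t1$tip.label), 90L)
  expect_identical(t1$edge.length, t2$edge.length)
  expect_true(all(t1$edge.length > 0))
  expect_equal(length(simulate_tree(2, seed = 1)$tip.label), 2L)
  expect_error(simulate_tree(10, birth = 0.5, death = 0.7), "exceed")
  ## mean root-to-tip depth of a pure-birth tree ~ sum_{k=2}^{n} 1/k
  set.seed(99)
  n <- 8
  depths <- replicate(500, {
    tr <- simulate_tree(n, birth = 1, death = 0)
    mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  })
  expect_equal(mean(depths), sum(1 / (2:n)), tolerance = 0.1)
})

test_that("forward Mk2 simulation matches its Poisson transition budget", {
  tr <- simulate_tree(30, seed = 3)
  ## absorbing case: no gains possible from state 0
  h0 <- simulate_mk2(tr, q01 = 0, q10 = 2, root_state = 0L, seed = 1)
  expect_true(all(h0$tip_states == 0))
  expect_equal(h0$gains + h0$losses, 0L)
  ## reproducibility
  h1 <- simulate_mk2(tr, 0.5, 0.5, seed = 7)
  h2 <- simulate_mk2(tr, 0.5, 0.5, seed = 7)
  expect_identical(h1$maps, h2$maps)
  ## mean transition count ~ q * total length for symmetric rates
  q <- 0.4
  Tlen <- sum(tr$edge.length)
  set.seed(21)
  counts <- replicate(2000, {
    h <- simulate_mk2(tr, q, q, root_state = 0L)
    h$gains + h$losses
  })
  expect_equal(mean(counts), q * Tlen, tolerance = 4 * sd(counts) / sqrt(2000) /
                 (q * Tlen))
  ## segment lengths always sum to branch lengths (validated on construction)
  expect_s3_class(h1, "character_history")
})

test_that("regime BM simulation has the Brownian variance structure", {
  tr <- read_trees("((A:1,B:1):0.5,C:1.5);")[[1]]
  painting <- paint_from_groups(tr, c(A = "g", B = "g", C = "g"))
  ## zero rates: all tips equal the root value
  x0 <- simulate_bm_regimes(tr, painting, c(g = 0), root_value = 3.14, seed = 1)
  expect_equal(unname(x0), rep(3.14, 3))
  set.seed(8)
  X <- replicate(2000, simulate_bm_regimes(tr, painting, c(g = 1)))
  ## Var(tip) ~ root-to-tip depth; Cov(A, B) ~ shared path 0.5
  expect_equal(var(X["A", ]), 1.5, tolerance = 0.15)
  expect_equal(var(X["C", ]), 1.5, tolerance = 0.15)
  expect_equal(cov(X["A", ], X["B", ]), 0.5, tolerance = 0.15)
  expect_error(simulate_bm_regimes(tr, painting, c(other = 1)), "no rate")
})

test_that("landmark simulation is exact at zero noise and reproducible", {
  sp <- data.frame(species = c("s1", "s2"), group = c("a", "a"))
  lm0 <- simulate_landmarks(sp, n_per_species = 3L, noise_sd = 0,
                            size_meanlog = 0, size_sdlog = 0, seed = 5)
  expect_equal(nrow(lm0), 6L)
  ## all specimens congruent to the template: GPA distance ~ 0
  g <- gpa(lm0$coords)
  d <- vapply(g$aligned, procrustes_distance, numeric(1), b = g$consensus)
  expect_true(all(d < 1e-8))
  lm1 <- simulate_landmarks(sp, seed = 9)
  lm2 <- simulate_landmarks(sp, seed = 9)
  expect_identical(lm1$coords, lm2$coords)
  expect_error(simulate_landmarks(sp, template = matrix(1, 11, 2)),
               "degenerate")
})

test_that("threshold-pair generator respects its correlation parameter", {
  tr <- simulate_tree(40, seed = 2)
  ## rho = 1: liabilities perfectly linearly related
  tp <- simulate_threshold_pair(tr, rho = 1, seed = 3)
  expect_equal(abs(cor(tp$liabilities[, 1], tp$liabilities[, 2])), 1,
               tolerance = 1e-10)
  ## rho = 0: liability correlations centered on zero over replicates
  set.seed(13)
  cors <- replicate(300, {
    p <- simulate_threshold_pair(tr, rho = 0)
    cor(p$liabilities[, 1], p$liabilities[, 2])
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(300) + 0.02)
  ## ordinal range honors the cuts
  tp9 <- simulate_threshold_pair(tr, 0.5, ordinal_cuts = seq(-1, 1, length.out = 9),
                                 seed = 4)
  expect_true(all(tp9$ordinal >= 0 & tp9$ordinal <= 9))
  expect_error(simulate_threshold_pair(tr, 0.5, ordinal_cuts = c(1, 0.5)),
               "increasing")
})

test_that("induction generator produces valid, reproducible plate tables", {
  d1 <- simulate_induction(1, 0, seed = 1)
  p <- pool_replicates(d1)
  expect_equal(p["treatment", "nonEu"], 0L)
  expect_equal(p["control", "Eu"], 0L)
  expect_identical(simulate_induction(0.4, 0.1, seed = 6),
                   simulate_induction(0.4, 0.1, seed = 6))
  expect_error(simulate_induction(0.5, 0.5, n_per_plate = 500), "200")
})

test_that("the study preset reproduces the designed history shape", {
  d <- simulate_study(seed = 7)
  expect_equal(length(d$tree$tip.label), 90L)
  expect_equal(sum(d$groups == "Rh"), 33L)
  expect_equal(d$ingroup_history$losses, 10L)
  expect_equal(d$ingroup_history$gains, 0L)  # gain fixed on the stem branch
  expect_true(all(d$complexity >= 0 & d$complexity <= 9))
  expect_equal(sort(unique(as.vector(d$structure_matrix))), c(0L, 1L))
  expect_equal(unname(complexity_index(d$structure_matrix)),
               unname(d$complexity))
  ## regenerates bit-identically from its seed
  d2 <- simulate_study(seed = 7)
  expect_identical(d$trait, d2$trait)
  expect_identical(d$landmarks$coords, d2$landmarks$coords)
  ## every generated input passes the cross-validator
  expect_equal(nrow(validate_inputs(d)), 0L)
})
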