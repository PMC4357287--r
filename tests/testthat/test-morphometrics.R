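square4 <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)

rand_config <- function(k = 11) matrix(stats::rnorm(2 * k), k, 2)

rigid <- function(m, theta = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  scale * m %*% R + rep(shift, each = nrow(m))
}

test_that("centroid size follows its definition and invariances", {
  expect_equal(centroid_size(square4), sqrt(2))
  set.seed(3)
  cfg <- rand_config()
  expect_equal(centroid_size(2 * cfg), 2 * centroid_size(cfg))
  expect_equal(centroid_size(rigid(cfg, 0.7, 1, c(3, -2))),
               centroid_size(cfg), tolerance = 1e-12)
  ## brute-force per-landmark summation oracle
  cen <- colMeans(cfg)
  oracle <- sqrt(sum(apply(cfg, 1, function(p) sum((p - cen)^2))))
  expect_equal(centroid_size(cfg), oracle)
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("TPS reading applies SCALE and validates landmark counts", {
  tf <- tempfile(fileext = ".tps")
  writeLines(c(
    "LM=11", apply(rand_config(), 1, paste, collapse = " "),
    "ID=sp1",
    "LM=11", apply(rand_config(), 1, paste, collapse = " "),
    "SCALE=0.5", "ID=sp2"), tf)
  got <- read_tps(tf)
  expect_equal(nrow(got), 2L)
  expect_equal(got$specimen_id, c("sp1", "sp2"))
  expect_equal(dim(got$coords[[1]]), c(11L, 2L))
  ## write -> read round trip, then SCALE halves coordinates
  tf2 <- tempfile(fileext = ".tps")
  write_tps(got$coords, got$specimen_id, tf2)
  again <- read_tps(tf2)
  expect_equal(again$coords[[2]], got$coords[[2]], tolerance = 1e-10)
  bad <- tempfile(fileext = ".tps")
  writeLines(c("LM=7", apply(rand_config(7), 1, paste, collapse = " ")), bad)
  expect_error(read_tps(bad), "LM=7")
})

test_that("GPA aligns rigidly transformed copies exactly", {
  set.seed(12)
  cfg <- rand_config()
  g <- gpa(list(cfg, rigid(cfg, pi / 6, 2.3, c(5, 1)),
                rigid(cfg, -1.2, 0.4, c(-2, 7))))
  d <- vapply(g$aligned, procrustes_distance, numeric(1), b = g$aligned[[1]])
  expect_true(all(d < 1e-10))
  ## consensus centered and unit-size
  expect_equal(colMeans(g$consensus), c(0, 0), tolerance = 1e-12)
  expect_equal(centroid_size(g$consensus), 1, tolerance = 1e-12)
})

test_that("GPA output is invariant to rigid transforms of any input", {
  set.seed(21)
  cfgs <- replicate(4, rand_config(), simplify = FALSE)
  g1 <- gpa(cfgs)
  cfgs2 <- cfgs
  cfgs2[[2]] <- rigid(cfgs[[2]], 2.2, 3.5, c(-4, 9))
  g2 <- gpa(cfgs2)
  for (i in seq_along(cfgs))
    expect_equal(g2$aligned[[i]], g1$aligned[[i]], tolerance = 1e-8)
  ## noisy squares: consensus within noise of the true square
  sq <- lapply(1:6, function(i) square4 + matrix(rnorm(8, 0, 0.01), 4, 2))
  gs <- gpa(sq)
  ref <- sweep(square4, 2, colMeans(square4))
  ref <- ref / centroid_size(ref)
  rot <- ref %*% plastevol:::.procrustes_rotation(gs$consensus, ref)
  expect_lt(procrustes_distance(gs$consensus, rot), 0.05)
})

test_that("species averaging emits per-morph units for dimorphic species", {
  set.seed(5)
  lm <- data.frame(specimen_id = paste0("s", 1:6),
                   species = c("a", "a", "a", "a", "b", "b"),
                   morph = c("St", "St", "Eu", "Eu",
                             "monomorphic", "monomorphic"))
  lm$coords <- replicate(6, rand_config(), simplify = FALSE)
  av <- species_average(lm)
  expect_setequal(av$unit, c("a_St", "a_Eu", "b"))
  ## unit with one specimen is itself (aligned scale-free copy)
  lone <- data.frame(specimen_id = "x", species = "c", morph = "monomorphic")
  lone$coords <- list(rand_config())
  one <- species_average(lone)
  cfg <- lone$coords[[1]]
  expect_equal(one$coords[[1]],
               sweep(cfg, 2, colMeans(cfg)) / centroid_size(cfg))
  expect_equal(one$centroid_size, centroid_size(cfg))
})

test_that("form space appends natural-log centroid size", {
  set.seed(6)
  units <- data.frame(unit = c("u1", "u2", "u3"),
                      centroid_size = c(exp(1), 1, 2))
  units$coords <- replicate(3, rand_config(), simplify = FALSE)
  X <- form_space(units, form = TRUE)
  expect_equal(ncol(X), 23L)
  expect_equal(unname(X["u1", "logCS"]), 1.0)
  expect_equal(unname(X["u2", "logCS"]), 0.0)
  Xs <- form_space(units, form = FALSE)
  expect_equal(ncol(Xs), 22L)
  units$centroid_size[1] <- -1
  expect_error(form_space(units), "positive")
})

test_that("covariance PCA conserves variance and orders axes", {
  set.seed(7)
  X <- cbind(a = rnorm(20, sd = 3), b = rnorm(20, sd = 1), d = rnorm(20, sd = 0.2))
  p <- morpho_pca(X)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$eigenvalues), sum(apply(X, 2, var)))
  expect_equal(sum(p$proportion), 1)
  ## collinear points: PC1 explains everything
  Z <- cbind(1:10, 2 * (1:10))
  expect_equal(morpho_pca(Z)$proportion[1], 1, tolerance = 1e-12)
  ## reconstruction of the centered data from scores and loadings
  expect_equal(p$scores %*% t(p$loadings), sweep(X, 2, colMeans(X)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("phylogenetic PCA equals standard PCA on a star tree", {
  set.seed(8)
  n <- 12
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(star$tip.label, NULL))
  pp <- phylo_pca(X, star)
  ps <- morpho_pca(X)
  expect_equal(pp$eigenvalues, ps$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(cor(pp$scores[, 1], ps$scores[, 1])), 1, tolerance = 1e-8)
  expect_error(phylo_pca(X[-1, , drop = FALSE], star), "mismatch")
})

test_that("phylogenetic PCA matches the independent phytools implementation", {
  set.seed(9)
  tr <- ape::rtree(15)
  X <- matrix(rnorm(15 * 5), 15, 5,
              dimnames = list(tr$tip.label, paste0("v", 1:5)))
  mine <- phylo_pca(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(unname(mine$eigenvalues[1:5]), unname(diag(ref$Eval)),
               tolerance = 1e-6)
  for (k in 1:3)
    expect_equal(abs(cor(mine$scores[rownames(ref$S), k], ref$S[, k])), 1,
                 tolerance = 1e-6)
})
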