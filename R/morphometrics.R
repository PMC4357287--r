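## Landmark ingestion, generalized Procrustes analysis, form space, and
## standard / phylogenetic PCA.

#' Read a TPS landmark file
#'
#' Parses TPS records (`LM=`, coordinate pairs, optional `ID=`, `IMAGE=`,
#' `SCALE=`). `SCALE` is applied multiplicatively to the raw coordinates.
#'
#' @param file Path to a TPS file.
#' @param n_landmarks Required landmark count per record (default 11).
#' @return Data frame with `specimen_id` and a list-column `coords` of
#'   n x 2 matrices.
#' @export
read_tps <- function(file, n_landmarks = 11L) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", file, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  out <- lapply(seq_along(recs), function(ri) {
    rec <- recs[[ri]]
    lm <- as.integer(sub("^LM\\s*=\\s*", "", rec[1L], ignore.case = TRUE))
    if (is.na(lm) || lm != n_landmarks)
      stop("record ", ri, ": LM=", lm, " but ", n_landmarks,
           " landmarks required", call. = FALSE)
    body <- rec[-1L]
    keyed <- grepl("=", body)
    coords_txt <- body[!keyed]
    nums <- as.numeric(unlist(strsplit(paste(coords_txt, collapse = " "), "\\s+")))
    if (length(nums) != 2L * lm)
      stop("record ", ri, ": expected ", 2L * lm, " coordinates, got ",
           length(nums), call. = FALSE)
    keys <- body[keyed]
    getkey <- function(k) {
      hit <- grep(paste0("^", k, "\\s*="), keys, ignore.case = TRUE, value = TRUE)
      if (length(hit)) sub(paste0("^", k, "\\s*=\\s*"), "", hit[1L],
                           ignore.case = TRUE) else NA_character_
    }
    scale <- suppressWarnings(as.numeric(getkey("SCALE")))
    cfg <- matrix(nums, ncol = 2L, byrow = TRUE)
    if (!is.na(scale)) cfg <- cfg * scale
    id <- getkey("ID"); img <- getkey("IMAGE")
    data.frame(specimen_id = if (!is.na(id)) id else
      if (!is.na(img)) img else paste0("rec", ri))
  })
  df <- do.call(rbind, out)
  df$coords <- lapply(seq_along(recs), function(ri) {
    rec <- recs[[ri]]
    body <- rec[-1L]
    coords_txt <- body[!grepl("=", body)]
    nums <- as.numeric(unlist(strsplit(paste(coords_txt, collapse = " "), "\\s+")))
    keys <- body[grepl("=", body)]
    hit <- grep("^SCALE\\s*=", keys, ignore.case = TRUE, value = TRUE)
    scale <- if (length(hit)) as.numeric(sub("^SCALE\\s*=\\s*", "", hit[1L],
                                             ignore.case = TRUE)) else NA_real_
    cfg <- matrix(nums, ncol = 2L, byrow = TRUE)
    if (!is.na(scale)) cfg <- cfg * scale
    cfg
  })
  df
}

#' Write landmark configurations to a TPS file
#'
#' @param coords List of n x 2 matrices.
#' @param ids Character vector of specimen ids.
#' @param file Output path.
#' @export
write_tps <- function(coords, ids, file) {
  stopifnot(length(coords) == length(ids))
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    writeLines(c(paste0("LM=", nrow(m)),
                 apply(m, 1L, function(r) paste(format(r, digits = 12), collapse = " ")),
                 paste0("ID=", ids[i])), con)
  }
  invisible(file)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the sum of squared distances of the landmarks to their
#' centroid. Invariant to rotation and translation; scales linearly with
#' uniform scaling.
#'
#' @param config n x 2 coordinate matrix with at least two distinct points.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  stopifnot(is.matrix(config), ncol(config) == 2L, nrow(config) >= 2L)
  cen <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, cen)^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks identical",
                    call. = FALSE)
  cs
}

## optimal 2-D rotation of B onto A (both centered), reflections forbidden
.procrustes_rotation <- function(A, B) {
  M <- crossprod(A, B)            # 2x2 cross-covariance
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$v %*% diag(c(1, d)) %*% t(sv$u)
}

#' Generalized Procrustes analysis
#'
#' Iterative full Procrustes superimposition: each configuration is
#' centered, scaled to unit centroid size, and rotated (reflections
#' excluded) onto the current consensus; the consensus is the mean of the
#' aligned configurations, re-normalised to unit size. Iterates until the
#' RMS change of the consensus falls below `tol`.
#'
#' @param configs List of n x 2 matrices with a common landmark count/order.
#' @param tol Consensus RMS-change tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return List of class `gpa_fit`: `aligned` (list of matrices),
#'   `consensus`, `centroid_sizes`, `iterations`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  k <- nrow(configs[[1L]])
  stopifnot(all(vapply(configs, nrow, integer(1)) == k))
  cs <- vapply(configs, centroid_size, numeric(1))
  scaled <- lapply(configs, function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / centroid_size(m)
  })
  if (length(scaled) == 1L)
    return(structure(list(aligned = scaled, consensus = scaled[[1L]],
                          centroid_sizes = cs, iterations = 0L),
                     class = "gpa_fit"))
  consensus <- scaled[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(scaled, function(m) m %*% .procrustes_rotation(consensus, m))
    newcons <- Reduce(`+`, aligned) / length(aligned)
    newcons <- sweep(newcons, 2L, colMeans(newcons))
    newcons <- newcons / centroid_size(newcons)
    delta <- sqrt(mean((newcons - consensus)^2))
    consensus <- newcons
    if (delta < tol) {
      aligned <- lapply(scaled, function(m) m %*% .procrustes_rotation(consensus, m))
      return(structure(list(aligned = aligned, consensus = consensus,
                            centroid_sizes = cs, iterations = it),
                       class = "gpa_fit"))
    }
  }
  stop("GPA did not converge in ", max_iter,
       " iterations (last RMS change ", format(delta), ")", call. = FALSE)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA of", length(x$aligned), "configurations x", nrow(x$consensus),
      "landmarks; converged in", x$iterations, "iteration(s)\n")
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#' @param a,b n x 2 matrices (aligned, unit size).
#' @return Scalar square-root of summed squared landmark differences.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Average specimens into species (or morph) units
#'
#' Specimens within each unit are Procrustes-aligned (GPA within the unit),
#' their aligned coordinates averaged, and their centroid sizes averaged.
#' Averaging pre-aligned specimen coordinates is used because raw-coordinate
#' averages are ill-defined across specimen orientations.
#'
#' @param landmarks Data frame as from [simulate_landmarks()]/[read_tps()]
#'   with columns `species`, optionally `morph`, and list-column `coords`.
#' @return Data frame with `unit` (species, suffixed `_St`/`_Eu` for
#'   dimorphic morphs), `species`, `morph`, `group` (if present), mean
#'   `centroid_size`, and list-column `coords` of unit mean configurations.
#' @export
species_average <- function(landmarks) {
  stopifnot(is.data.frame(landmarks), "coords" %in% names(landmarks))
  if (is.null(landmarks$morph)) landmarks$morph <- "monomorphic"
  key <- ifelse(landmarks$morph %in% c("St", "Eu"),
                paste(landmarks$species, landmarks$morph, sep = "_"),
                landmarks$species)
  units <- unique(key)
  rows <- lapply(units, function(u) {
    idx <- which(key == u)
    if (!length(idx)) stop("unit with no specimens: ", u, call. = FALSE)
    cfgs <- landmarks$coords[idx]
    cs <- vapply(cfgs, centroid_size, numeric(1))
    g <- gpa(cfgs)
    mean_cfg <- Reduce(`+`, g$aligned) / length(g$aligned)
    out <- data.frame(unit = u, species = landmarks$species[idx[1L]],
                      morph = landmarks$morph[idx[1L]],
                      centroid_size = mean(cs))
    if (!is.null(landmarks$group)) out$group <- landmarks$group[idx[1L]]
    out$coords <- list(mean_cfg)
    out
  })
  do.call(rbind, rows)
}

#' Build a shape or form matrix from aligned units
#'
#' Runs GPA across unit mean configurations and flattens the aligned
#' coordinates into a units x 22 shape matrix; with `form = TRUE` a 23rd
#' column of natural-log centroid size (as measured before scaling) is
#' appended, giving Procrustes form space.
#'
#' @param units Data frame from [species_average()] (columns `unit`,
#'   `coords`, `centroid_size`).
#' @param form Append log centroid size? (default TRUE)
#' @return Numeric matrix with unit rownames; attribute `"gpa"` holds the
#'   across-unit `gpa_fit`.
#' @export
form_space <- function(units, form = TRUE) {
  stopifnot(all(c("unit", "coords", "centroid_size") %in% names(units)))
  if (form && any(units$centroid_size <= 0))
    stop("centroid sizes must be positive for form space", call. = FALSE)
  g <- gpa(units$coords)
  X <- t(vapply(g$aligned, function(m) as.vector(t(m)), numeric(2L * nrow(g$consensus))))
  colnames(X) <- paste0(rep(c("x", "y"), nrow(g$consensus)),
                        rep(seq_len(nrow(g$consensus)), each = 2L))
  rownames(X) <- units$unit
  if (form) X <- cbind(X, logCS = log(units$centroid_size))
  attr(X, "gpa") <- g
  X
}

#' Principal component analysis of a shape/form matrix
#'
#' Column-mean-centered covariance PCA (no scaling): with mixed-scale form
#' data, log centroid size dominates exactly when size varies most, which
#' is the intended behaviour of form space.
#'
#' @param X Units x variables matrix.
#' @return Object of class `morpho_pca`: `scores`, `loadings`,
#'   `eigenvalues`, `proportion` (per-axis variance fractions), `center`,
#'   `phylogenetic = FALSE`.
#' @export
morpho_pca <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  if (all(abs(sweep(X, 2L, colMeans(X))) < 1e-300))
    stop("constant matrix: no variance to decompose", call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation, eigenvalues = ev,
                 proportion = ev / sum(ev), center = p$center,
                 phylogenetic = FALSE),
            class = "morpho_pca")
}

#' Phylogenetic principal component analysis
#'
#' PCA of the evolutionary (phylogenetically weighted) covariance matrix:
#' deviations are taken from the GLS mean under the Brownian covariance
#' `C = vcv_matrix(tree)` and the eigen-decomposition is of
#' `t(X - mu) C^{-1} (X - mu) / (n - 1)`. Scores are deviations projected
#' on the eigenvectors. Rows of `X` must match the tree's tips exactly.
#'
#' @param X Units x variables matrix with tip labels as rownames.
#' @param tree Rooted `phylo`.
#' @return A `morpho_pca` with `phylogenetic = TRUE` and `gls_mean`.
#' @export
phylo_pca <- function(X, tree) {
  X <- as.matrix(X)
  tree <- .validate_tree(tree)
  miss <- setdiff(tree$tip.label, rownames(X))
  extra <- setdiff(rownames(X), tree$tip.label)
  if (length(miss) || length(extra))
    stop("row/tip mismatch; missing: ", paste(miss, collapse = ","),
         "; extra: ", paste(extra, collapse = ","), call. = FALSE)
  X <- X[tree$tip.label, , drop = FALSE]
  C <- vcv_matrix(tree)
  Ci <- solve(C)
  one <- rep(1, nrow(X))
  mu <- as.vector(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X)
  D <- sweep(X, 2L, mu)
  R <- t(D) %*% Ci %*% D / (nrow(X) - 1L)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  scores <- D %*% eig$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(eig$vectors) <- colnames(scores)
  rownames(eig$vectors) <- colnames(X)
  structure(list(scores = scores, loadings = eig$vectors, eigenvalues = ev,
                 proportion = ev / sum(ev), gls_mean = mu,
                 phylogenetic = TRUE),
            class = "morpho_pca")
}

#' @export
print.morpho_pca <- function(x, ...) {
  kind <- if (x$phylogenetic) "Phylogenetic PCA" else "PCA"
  cat(kind, "of", nrow(x$scores), "units x", nrow(x$loadings), "variables\n")
  k <- min(4L, length(x$proportion))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$proportion[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.morpho_pca <- function(object, ...) {
  data.frame(axis = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             proportion = object$proportion,
             cumulative = cumsum(object$proportion))
}
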