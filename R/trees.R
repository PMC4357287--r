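#' Read trees from Newick or NEXUS text
#'
#' Parses one or more rooted phylogenies from a file or a character string.
#' Newick files may hold several semicolon-terminated trees; NEXUS files are
#' recognised by their `#NEXUS` header and read through their TREES block.
#' Square-bracket comments are stripped and quoted labels are supported.
#'
#' @param x Path to a `.nwk`/`.tre`/`.nex` file, or a character string
#'   containing Newick text (anything with a parenthesis or semicolon).
#' @return An object of class `multiPhylo` (even for a single tree). All
#'   member trees are checked to share an identical tip-label set.
#' @details Branch lengths are in the units of the source tree; for this
#'   pipeline that is expected substitutions per site ("operational time").
#'   Missing branch lengths are set to 0 with a warning. Duplicate tip labels
#'   are an error.
#' @export
read_trees <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_path <- !grepl("[(;]", x) && file.exists(x)
  txt <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  trees <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    if (is_path) ape::read.nexus(x) else {
      tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
      writeLines(txt, tf)
      ape::read.nexus(tf)
    }
  } else {
    out <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) stop("Newick parse error: ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(out)) stop("Newick parse error: no tree found", call. = FALSE)
    out
  }
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees <- structure(lapply(trees, .validate_tree), class = "multiPhylo")
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(trees) > 1L && !all(vapply(labs, identical, logical(1), labs[[1]])))
    stop("trees in a set must share an identical tip-label set", call. = FALSE)
  trees
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and finite", call. = FALSE)
  tree
}

#' Rescale a tree to a target total branch length
#'
#' Multiplies every branch by a common factor so that the sum of branch
#' lengths equals `target`, preserving all proportions. Stochastic-mapping
#' prior calibration works on trees rescaled to total length one, so that
#' the overall transition rate is expressed per tree.
#'
#' @param tree A `phylo` object with positive total branch length.
#' @param target Positive total length to rescale to (default 1).
#' @return The rescaled `phylo`.
#' @export
rescale_total_length <- function(tree, target = 1) {
  tree <- .validate_tree(tree)
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("tree has zero total branch length", call. = FALSE)
  tree$edge.length <- tree$edge.length * (target / tot)
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' Returns the species-by-species covariance structure C implied by a rooted
#' tree under Brownian motion: `C[i, j]` is the length of the shared
#' root-to-MRCA path of tips i and j, and the diagonal holds root-to-tip
#' distances. C carries the "operational time" weights used by all rate
#' models in this package.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
vcv_matrix <- function(tree) {
  tree <- .validate_tree(tree)
  ## trees are interpreted as rooted at their representation root; basal
  ## polytomies (e.g. star trees) are legitimate rooted shapes here, so the
  ## stricter ape::is.rooted() bifurcation test is not applied
  if (is.null(tree$edge) || nrow(tree$edge) < 2L)
    stop("tree must be rooted with at least two edges", call. = FALSE)
  ape::vcv.phylo(tree)
}

#' Sample trees from a tree set with replacement
#'
#' Draws `n` trees uniformly with replacement from a `multiPhylo` set,
#' reproducibly under a seed. Used to propagate topology and branch-length
#' uncertainty by replicating analyses over posterior trees.
#'
#' @param ts A `multiPhylo` (or single `phylo`) set.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A `multiPhylo` of length `n`.
#' @export
sample_trees <- function(ts, n, seed = NULL) {
  if (inherits(ts, "phylo")) ts <- structure(list(ts), class = "multiPhylo")
  if (length(ts) == 0L) stop("empty tree set", call. = FALSE)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(ts), n, replace = TRUE)
  structure(ts[idx], class = "multiPhylo")
}

## Postorder edge ordering (children before parents); cached layout used by
## the pruning algorithms.
.tree_layout <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  list(tree = tree, n = n, root = n + 1L,
       edge = tree$edge, len = tree$edge.length)
}
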