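## Synthetic-data generators: every input the pipeline consumes, with the
## statistical structure the downstream analyses assume.

#' Simulate a birth-death tree
#'
#' Constant-rate birth-death simulation conditioned on the number of extant
#' tips, used as a stand-in for an inferred phylogeny. Branch lengths play
#' the role of "operational time".
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Per-lineage rates; `birth > death >= 0`.
#' @param seed Optional integer seed.
#' @return A rooted `phylo` with `n_tips` tips labelled `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0)
  if (birth <= death) stop("birth rate must exceed death rate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Simulate a binary character along a tree
#'
#' Forward simulation of a 2-state continuous-time Markov chain from the
#' root, recording the full piecewise-constant state path on every branch.
#'
#' @param tree Rooted `phylo`.
#' @param q01,q10 Gain and loss rates (>= 0).
#' @param root_state Root state, 0 or 1.
#' @param seed Optional integer seed.
#' @return A `character_history`; tip states are in `$tip_states`.
#' @export
simulate_mk2 <- function(tree, q01, q10, root_state = 0L, seed = NULL) {
  stopifnot(q01 >= 0, q10 >= 0, root_state %in% c(0L, 1L))
  tree <- .validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  lay <- .tree_layout(tree)
  edge <- lay$edge
  n <- lay$n
  st <- integer(n + lay$tree$Nnode)
  st[lay$root] <- as.integer(root_state)
  maps_post <- vector("list", nrow(edge))
  rates <- c(q01, q10)   # exit rate from state 0, 1
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    cur <- st[edge[e, 1L]]
    t_rem <- lay$len[e]
    segs <- numeric(0); labs <- character(0)
    repeat {
      r <- rates[cur + 1L]
      wait <- if (r > 0) stats::rexp(1, r) else Inf
      if (wait >= t_rem) { segs <- c(segs, t_rem); labs <- c(labs, as.character(cur)); break }
      segs <- c(segs, wait); labs <- c(labs, as.character(cur))
      t_rem <- t_rem - wait
      cur <- 1L - cur
    }
    maps_post[[e]] <- stats::setNames(segs, labs)
    st[edge[e, 2L]] <- cur
  }
  key_post <- paste(edge[, 1], edge[, 2])
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  .new_history(tree, maps_post[match(key_in, key_post)])
}

#' Simulate a continuous trait under regime-specific Brownian motion
#'
#' Trait increments along each branch segment are Normal with variance
#' (regime rate) x (segment length); increments are summed root to tip.
#' Regimes come either from a `character_history` (states "0"/"1") or a
#' `regime_painting` (see [paint_from_history()]).
#'
#' @param tree Rooted `phylo` (must match the painting's tree).
#' @param painting A `character_history` or `regime_painting`.
#' @param regime_rates Named vector of rates, one per regime label.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm_regimes <- function(tree, painting, regime_rates, root_value = 0,
                                seed = NULL) {
  tree <- .validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  maps <- if (inherits(painting, c("character_history", "regime_painting")))
    painting$maps else stop("painting must be a character_history or regime_painting")
  stopifnot(length(maps) == nrow(tree$edge))
  bad <- setdiff(unique(unlist(lapply(maps, names))), names(regime_rates))
  if (length(bad)) stop("no rate supplied for regime(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(regime_rates < 0)) stop("rates must be >= 0", call. = FALSE)
  lay <- .tree_layout(tree)
  key_post <- paste(lay$edge[, 1], lay$edge[, 2])
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  maps_post <- maps[match(key_post, key_in)]
  n <- lay$n
  x <- numeric(n + lay$tree$Nnode)
  x[lay$root] <- root_value
  for (e in rev(seq_len(nrow(lay$edge)))) {
    vs <- sum(regime_rates[names(maps_post[[e]])] * maps_post[[e]])
    x[lay$edge[e, 2L]] <- x[lay$edge[e, 1L]] + stats::rnorm(1, 0, sqrt(vs))
  }
  stats::setNames(x[seq_len(n)], lay$tree$tip.label)
}

#' Default 11-landmark template
#'
#' A stylised lateral outline of a nematode stoma: a tapering channel with
#' a dorsal tooth apex, expressed as 11 (x, y) coordinates. Used as the base
#' configuration for landmark simulation.
#'
#' @return An 11 x 2 matrix.
#' @export
landmark_template <- function() {
  m <- matrix(c(
    0.0, 0.0,    # 1  ventral cheilostom/lip boundary
    0.1, 0.8,    # 2  ventral cheilostom/gymnostom
    0.15, 1.2,   # 3  ventral gymnostom apex
    0.2, 1.8,    # 4  ventral gymnostom/stegostom
    0.5, 2.4,    # 5  subventral telostegostom curvature
    1.0, 2.6,    # 6  dorsal telostegostom posterior
    1.4, 2.3,    # 7  dorsal gland orifice
    1.6, 1.8,    # 8  dorsal gymnostom/stegostom
    1.75, 1.2,   # 9  dorsal gymnostom apex
    1.9, 0.8,    # 10 dorsal cheilostom/gymnostom
    2.0, 0.0),   # 11 dorsal cheilostom/lip boundary
    ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Simulate landmark configurations for groups of species
#'
#' Each specimen is (template + its group's deformation), scaled by a
#' lognormal size draw, randomly rotated and translated, plus isotropic
#' Gaussian landmark noise. Group deformations are per-landmark offset
#' matrices (affine-free), sufficient to create separable group structure
#' in form space.
#'
#' @param species Data frame with columns `species`, `group`, and optionally
#'   `morph` (defaults to `"monomorphic"`).
#' @param group_deformations Named list of 11 x 2 offset matrices, one per
#'   group value (missing groups get zero deformation).
#' @param n_per_species Specimens per species unit (recycled).
#' @param noise_sd Isotropic landmark noise SD (>= 0).
#' @param size_meanlog,size_sdlog Lognormal centroid-size scaling parameters;
#'   `size_meanlog` may be a vector (recycled over species rows) to give
#'   species-level size structure.
#' @param template 11 x 2 base configuration.
#' @param seed Optional integer seed.
#' @return Data frame with one row per specimen landmark set stored in a
#'   list-column `coords`, plus `specimen_id`, `species`, `morph`, `group`.
#' @export
simulate_landmarks <- function(species, group_deformations = list(),
                               n_per_species = 5L, noise_sd = 0.02,
                               size_meanlog = 0, size_sdlog = 0.3,
                               template = landmark_template(), seed = NULL) {
  stopifnot(is.data.frame(species), all(c("species", "group") %in% names(species)))
  if (nrow(template) != 11L || ncol(template) != 2L)
    stop("template must be 11 x 2", call. = FALSE)
  if (max(dist(template)) <= 0) stop("degenerate template", call. = FALSE)
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species$morph)) species$morph <- "monomorphic"
  reps <- rep_len(n_per_species, nrow(species))
  meanlogs <- rep_len(size_meanlog, nrow(species))
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(species))) {
    def <- group_deformations[[species$group[i]]]
    base <- template + if (is.null(def)) 0 else def
    for (j in seq_len(reps[i])) {
      k <- k + 1L
      size <- stats::rlnorm(1, meanlogs[i], size_sdlog)
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      shift <- stats::rnorm(2, 0, 1)
      cfg <- size * base %*% R +
        rep(shift, each = 11) +
        matrix(stats::rnorm(22, 0, noise_sd), 11, 2)
      rows[[k]] <- data.frame(specimen_id = sprintf("%s_%s_%d", species$species[i],
                                                    species$morph[i], j),
                              species = species$species[i],
                              morph = species$morph[i],
                              group = species$group[i])
      rows[[k]]$coords <- list(cfg)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a correlated binary/ordinal trait pair under the threshold model
#'
#' Two latent liabilities evolve by bivariate Brownian motion with
#' instantaneous correlation `rho`; the binary trait is the indicator of the
#' first liability exceeding `binary_threshold`, and the ordinal trait is
#' the bin index of the second liability under `ordinal_cuts` (0-based, so
#' `length(ordinal_cuts) = 9` yields the 0..9 range of the complexity index).
#'
#' @param tree Rooted `phylo`.
#' @param rho Instantaneous liability correlation, in [-1, 1].
#' @param liability_rates Length-2 vector of BM rates for the two liabilities.
#' @param binary_threshold Threshold on liability 1 (default 0).
#' @param ordinal_cuts Strictly increasing cut points on liability 2; `NULL`
#'   returns the raw liability as the second trait.
#' @param root Length-2 root liabilities.
#' @param seed Optional integer seed.
#' @return List with `binary`, `ordinal` (or continuous), and the raw
#'   `liabilities` matrix (tips x 2).
#' @export
simulate_threshold_pair <- function(tree, rho, liability_rates = c(1, 1),
                                    binary_threshold = 0, ordinal_cuts = NULL,
                                    root = c(0, 0), seed = NULL) {
  stopifnot(abs(rho) <= 1, length(liability_rates) == 2L, all(liability_rates >= 0))
  if (!is.null(ordinal_cuts) && any(diff(ordinal_cuts) <= 0))
    stop("ordinal_cuts must be strictly increasing", call. = FALSE)
  tree <- .validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  S <- diag(sqrt(liability_rates)) %*%
    matrix(c(1, rho, rho, 1), 2, 2) %*% diag(sqrt(liability_rates))
  ## chol of a possibly singular (|rho| = 1) matrix
  ev <- eigen(S, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  lay <- .tree_layout(tree)
  n <- lay$n
  L <- matrix(0, n + lay$tree$Nnode, 2L)
  L[lay$root, ] <- root
  for (e in rev(seq_len(nrow(lay$edge)))) {
    z <- stats::rnorm(2)
    L[lay$edge[e, 2L], ] <- L[lay$edge[e, 1L], ] +
      sqrt(lay$len[e]) * as.vector(A %*% z)
  }
  liab <- L[seq_len(n), , drop = FALSE]
  rownames(liab) <- lay$tree$tip.label
  binary <- stats::setNames(as.integer(liab[, 1] > binary_threshold),
                            rownames(liab))
  second <- if (is.null(ordinal_cuts)) stats::setNames(liab[, 2], rownames(liab))
  else stats::setNames(findInterval(liab[, 2], ordinal_cuts), rownames(liab))
  list(binary = binary, ordinal = second, liabilities = liab)
}

#' Simulate replicate induction-experiment counts
#'
#' Per-plate binomial counts of the induced (Eu) morph in a treatment and a
#' control arm, emulating triplicate plate assays with up to `n_per_plate`
#' scored adults per plate.
#'
#' @param p_treat,p_ctrl Per-individual Eu probabilities in each arm.
#' @param n_per_plate Scored adults per plate (<= 200, the screening cap).
#' @param n_plates Replicate plates per arm.
#' @param seed Optional integer seed.
#' @return Data frame with columns `arm`, `plate`, `n_eu`, `n_total`.
#' @export
simulate_induction <- function(p_treat, p_ctrl, n_per_plate = 200L,
                               n_plates = 3L, seed = NULL) {
  stopifnot(p_treat >= 0, p_treat <= 1, p_ctrl >= 0, p_ctrl <= 1,
            n_per_plate >= 1, n_per_plate <= 200, n_plates >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(n_per_plate, n_plates)
  data.frame(
    arm = rep(c("treatment", "control"), each = n_plates),
    plate = rep(seq_len(n_plates), 2L),
    n_eu = c(stats::rbinom(n_plates, n, p_treat),
             stats::rbinom(n_plates, n, p_ctrl)),
    n_total = rep(n, 2L))
}

## Fitch (unordered parsimony) count of minimal state changes for a binary
## character; used to keep preset histories minimal.
.fitch_changes <- function(tree, tip_states) {
  lay <- .tree_layout(tree)
  n <- lay$n
  sets <- vector("list", n + lay$tree$Nnode)
  st <- tip_states[lay$tree$tip.label]
  for (i in seq_len(n)) sets[[i]] <- st[i]
  changes <- 0L
  ## postorder over edges, combining children at each parent
  for (e in seq_len(nrow(lay$edge))) {
    par <- lay$edge[e, 1L]; chi <- lay$edge[e, 2L]
    if (is.null(sets[[par]])) sets[[par]] <- sets[[chi]]
    else {
      inter <- intersect(sets[[par]], sets[[chi]])
      if (length(inter)) sets[[par]] <- inter
      else { sets[[par]] <- union(sets[[par]], sets[[chi]]); changes <- changes + 1L }
    }
  }
  changes
}

#' Generate a full study-shaped synthetic dataset
#'
#' Reproduces the design of the study this package emulates: 90 species in
#' three groups (3 non-diplogastrid outgroup representatives are kept small
#' here by default for speed at desk scale -- set `n_outgroup = 33` for the
#' full design), a binary dimorphism gained exactly once and lost
#' `n_losses` times (rejection-sampled, and required to be the
#' minimal-change explanation of the resulting tip states), a continuous
#' trait under group-specific BM rates ordered Rh < Dm < Mn, landmark
#' configurations with group-level deformation, a correlated complexity
#' index under the threshold model, and induction count tables.
#'
#' @param n_ingroup,n_outgroup Tip counts for the dimorphism clade and the
#'   outgroup; defaults 57 + 33 give the study's 90 species.
#' @param q01,q10 Gain/loss rates for the binary character (per unit length
#'   of the rescaled ingroup subtree).
#' @param n_losses Required number of losses (gains fixed at 1).
#' @param n_monomorphic_range Accepted range for the number of secondarily
#'   monomorphic species; the default 25-37 brackets the 31 of the study
#'   design, so losses subtend whole clades rather than single twigs.
#' @param regime_rates Named rates for `Rh`, `Dm`, `Mn`.
#' @param rho Threshold-model correlation between dimorphism liability and
#'   complexity liability.
#' @param max_attempts Rejection-sampling cap for the history shape.
#' @param seed Integer seed (required: the dataset is a pure function of it).
#' @return List of class `synthetic_study` with tree, history, states,
#'   traits, landmarks, structure matrix, induction tables, groups, config.
#' @export
simulate_study <- function(n_ingroup = 57L, n_outgroup = 33L,
                           q01 = 0.15, q10 = 3.5, n_losses = 10L,
                           n_monomorphic_range = c(25L, 37L),
                           regime_rates = c(Rh = 1, Dm = 3, Mn = 9),
                           rho = 0.8, max_attempts = 10000L, seed = 1L) {
  set.seed(seed)
  ## one clade for the ingroup grafted onto an outgroup backbone
  repeat {
    ing <- simulate_tree(n_ingroup, birth = 1, death = 0)
    outg <- simulate_tree(n_outgroup + 1L, birth = 0.6, death = 0)
    ing$tip.label <- paste0("dip", seq_len(n_ingroup))
    outg$tip.label <- c(paste0("rh", seq_len(n_outgroup)), "GRAFT")
    tree <- ape::bind.tree(outg, ing, where = which(outg$tip.label == "GRAFT"))
    if (ape::is.binary(tree) && ape::is.rooted(tree)) break
  }
  tree <- rescale_total_length(tree, nrow(tree$edge) * 0.05)
  ingroup <- paste0("dip", seq_len(n_ingroup))
  ## dimorphism history on the ingroup subtree: gained once on its stem,
  ## so simulate state-1 evolution from the ingroup MRCA and require
  ## n_losses losses, no regains, and parsimony-minimality of tip states
  sub <- ape::extract.clade(tree, ape::getMRCA(tree, ingroup))
  ok <- FALSE
  for (att in seq_len(max_attempts)) {
    ## loss rate scaled so E[losses] ~ n_losses over the subtree; no regains
    h <- simulate_mk2(sub, q01 = 0, q10 = n_losses / sum(sub$edge.length),
                      root_state = 1L)
    if (h$losses != n_losses) next
    sts <- h$tip_states
    nmn <- sum(sts == 0L)
    if (nmn < n_monomorphic_range[1] || nmn > n_monomorphic_range[2]) next
    if (.fitch_changes(sub, sts) != n_losses) next
    ## both basal ingroup subclades must retain dimorphic tips, otherwise a
    ## root-state-0 reconstruction (gain below the MRCA) ties the history
    rootkids <- sub$edge[sub$edge[, 1] == length(sub$tip.label) + 1L, 2]
    basal_ok <- all(vapply(rootkids, function(nd) {
      tips <- if (nd <= length(sub$tip.label)) sub$tip.label[nd]
              else ape::extract.clade(sub, nd)$tip.label
      any(sts[tips] == 1L)
    }, logical(1)))
    if (basal_ok) { ok <- TRUE; break }
  }
  if (!ok) stop("could not generate a history with the requested shape in ",
                max_attempts, " attempts", call. = FALSE)
  tip_states <- stats::setNames(integer(length(tree$tip.label)), tree$tip.label)
  tip_states[names(h$tip_states)] <- h$tip_states
  groups <- ifelse(grepl("^rh", tree$tip.label), "Rh",
                   ifelse(tip_states[tree$tip.label] == 1L, "Dm", "Mn"))
  names(groups) <- tree$tip.label
  ## full-tree history: outgroup + ingroup stem painted state 0 is wrong for
  ## regime logic (outgroup is Rh regardless); keep the ingroup history and
  ## record outgroup branches as state 0
  painting <- .study_painting(tree, h, ingroup)
  trait <- simulate_bm_regimes(tree, painting, regime_rates, root_value = 0)
  ## complexity index correlated with the dimorphism via the threshold
  ## construction: draw the dimorphism liability consistent with the tip
  ## states (truncated-MVN Gibbs under the tree covariance), then build the
  ## complexity liability with instantaneous correlation rho and cut it
  l1 <- .liability_given_signs(tree, tip_states)
  C <- vcv_matrix(tree)
  z <- as.vector(t(chol(C)) %*% stats::rnorm(nrow(C)))
  l2 <- rho * l1 + sqrt(1 - rho^2) * z
  l2s <- (l2 - mean(l2)) / stats::sd(l2)
  ci <- stats::setNames(findInterval(l2s, seq(-1.4, 1.9, length.out = 9)),
                        tree$tip.label)
  thr <- list(binary = tip_states, liabilities = cbind(l1 = l1, l2 = l2))
  struct <- t(vapply(ci, function(k) {
    v <- integer(25); if (k > 0) v[seq_len(k)] <- 1L; v
  }, integer(25)))
  colnames(struct) <- paste0("structure_", seq_len(25))
  rownames(struct) <- tree$tip.label
  ## landmarks: one unit per species (two, St and Eu, for dimorphic species)
  ## with species-level shape offsets and size factors whose among-species
  ## spread is largest in the secondarily monomorphic group -- the disparity
  ## signal of the study design (log centroid size dominates form-space PC1)
  sp <- data.frame(species = tree$tip.label, group = groups,
                   stringsAsFactors = FALSE)
  units <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
    if (sp$group[i] == "Dm")
      data.frame(species = sp$species[i], group = sp$group[i],
                 morph = c("St", "Eu"))
    else data.frame(species = sp$species[i], group = sp$group[i],
                    morph = "monomorphic")
  }))
  shape_sd <- c(Rh = 0.05, Dm = 0.06, Mn = 0.30)     # among-species shape spread
  size_sd <- c(Rh = 0.10, Dm = 0.18, Mn = 0.60)      # among-species log-size spread
  eu_widen <- cbind(seq(-0.3, 0.3, length.out = 11), rep(0.12, 11))
  sp_offset <- lapply(stats::setNames(sp$species, sp$species), function(s)
    matrix(stats::rnorm(22, 0, shape_sd[[groups[[s]]]]), 11, 2))
  sp_sizelog <- vapply(sp$species, function(s)
    log(2) + stats::rnorm(1, 0, size_sd[[groups[[s]]]]), numeric(1))
  names(sp_sizelog) <- sp$species
  ## deformation keyed per unit: species offset, plus Eu widening for Eu morphs
  units$defkey <- paste(units$species, units$morph, sep = ".")
  defs <- lapply(seq_len(nrow(units)), function(i)
    sp_offset[[units$species[i]]] +
      if (units$morph[i] == "Eu") eu_widen else 0)
  names(defs) <- units$defkey
  landmarks <- simulate_landmarks(
    data.frame(species = units$species, group = units$defkey,
               morph = units$morph),
    group_deformations = defs, n_per_species = 5L, noise_sd = 0.02,
    size_meanlog = sp_sizelog[units$species] +
      ifelse(units$morph == "Eu", 0.25, 0),
    size_sdlog = 0.08)
  landmarks$group <- units$group[match(paste(landmarks$species, landmarks$morph,
                                             sep = "."), units$defkey)]
  landmarks$group <- ifelse(landmarks$morph %in% c("St", "Eu"),
                            landmarks$morph, landmarks$group)
  induction <- simulate_induction(p_treat = 0.9, p_ctrl = 0.05)
  structure(list(tree = tree, ingroup_history = h, tip_states = tip_states,
                 groups = groups, painting = painting, trait = trait,
                 complexity = ci, structure_matrix = struct,
                 threshold = thr, landmarks = landmarks,
                 induction = induction,
                 config = list(n_ingroup = n_ingroup, n_outgroup = n_outgroup,
                               q01 = q01, q10 = q10, n_losses = n_losses,
                               regime_rates = regime_rates, rho = rho,
                               seed = seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic comparative dataset:", length(x$tree$tip.label), "tips (",
      sum(x$groups == "Rh"), "Rh /", sum(x$groups == "Dm"), "Dm /",
      sum(x$groups == "Mn"), "Mn ); dimorphism history: 1 gain +",
      x$ingroup_history$losses, "loss(es) on the ingroup\n")
  invisible(x)
}

## Build the regime painting for the study preset: outgroup branches (and
## the ingroup stem's rootward part) are Rh; ingroup branches take Dm/Mn
## from the simulated history segments (state 1 -> Dm, 0 -> Mn).
.study_painting <- function(tree, history, ingroup) {
  mrca <- ape::getMRCA(tree, ingroup)
  inside <- .clade_edges(tree, mrca)
  maps <- vector("list", nrow(tree$edge))
  sub <- history$tree
  ## match ingroup-subtree edges to full-tree edges by the tip set below them
  sub_key <- .edge_tipsets(sub)
  full_key <- .edge_tipsets(tree)
  for (e in seq_len(nrow(tree$edge))) {
    if (!inside[e]) { maps[[e]] <- stats::setNames(tree$edge.length[e], "Rh"); next }
    j <- match(full_key[e], sub_key)
    if (is.na(j)) stop("internal error: unmatched ingroup edge")
    m <- history$maps[[j]]
    ## subtree branch lengths equal full-tree lengths inside the clade,
    ## except the stem edge which extract.clade drops; those edges match 1:1
    sc <- tree$edge.length[e] / sum(m)
    maps[[e]] <- stats::setNames(as.numeric(m) * sc,
                                 ifelse(names(m) == "1", "Dm", "Mn"))
  }
  ## the ingroup stem edge is inside 'inside'? extract.clade has no stem;
  ## stem edge leads to mrca and is painted Dm (dimorphism gained on it)
  stem <- which(tree$edge[, 2] == mrca)
  if (length(stem)) maps[[stem]] <- stats::setNames(tree$edge.length[stem], "Dm")
  structure(list(tree = tree, maps = maps), class = "regime_painting")
}

## Draw a unit-rate BM liability at the tips conditional on its sign pattern
## (Gibbs over truncated-normal tip conditionals under the tree covariance).
.liability_given_signs <- function(tree, states, sweeps = 300L) {
  C <- vcv_matrix(tree)
  Ci <- solve(C)
  st <- states[rownames(C)]
  l <- ifelse(st == 1, 0.5, -0.5)
  mu0 <- numeric(length(l))
  for (s in seq_len(sweeps))
    l <- cpp_liability_sweep(Ci, mu0, as.integer(st), as.numeric(l), 1)
  stats::setNames(l, rownames(C))
}

## logical vector over edges: edge lies strictly within the clade below node
.clade_edges <- function(tree, node) {
  desc <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    desc <- c(desc, ch)
    stack <- c(stack, ch[ch > length(tree$tip.label)])
  }
  tree$edge[, 2] %in% desc
}

## canonical string key per edge: sorted tip labels below the edge's child
.edge_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  lay <- .tree_layout(tree)
  sets <- vector("list", n + lay$tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- lay$tree$tip.label[i]
  for (e in seq_len(nrow(lay$edge))) {
    par <- lay$edge[e, 1L]; chi <- lay$edge[e, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  keys_bynode <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
  keys_bynode[tree$edge[, 2]]
}
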