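## Configuration-driven orchestration of the full analysis on a dataset
## (synthetic or ingested), with per-stage toggles and a seed manifest.

#' Cross-check dataset inputs
#'
#' Verifies tip-label agreement across the tree, trait tables, landmark
#' table, and structure matrix. Reports findings (orphans, case or
#' underscore mismatches with a fuzzy-match suggestion) without throwing.
#'
#' @param dataset A list with elements `tree` and any of `tip_states`,
#'   `trait`, `complexity`, `structure_matrix`, `landmarks`.
#' @return Data frame of findings (zero rows when consistent).
#' @export
validate_inputs <- function(dataset) {
  tips <- dataset$tree$tip.label
  findings <- list()
  note <- function(where, what) findings[[length(findings) + 1L]] <<-
    data.frame(where = where, finding = what)
  chk <- function(nms, where) {
    for (o in setdiff(tips, nms)) {
      fz <- nms[tolower(gsub("[ _]", "", nms)) == tolower(gsub("[ _]", "", o))]
      note(where, paste0("tip '", o, "' missing",
                         if (length(fz)) paste0(" (did you mean '", fz[1], "'?)")))
    }
    for (o in setdiff(nms, tips)) note(where, paste0("orphan entry '", o, "'"))
  }
  if (!is.null(dataset$tip_states)) chk(names(dataset$tip_states), "tip_states")
  if (!is.null(dataset$trait)) chk(names(dataset$trait), "trait")
  if (!is.null(dataset$complexity)) chk(names(dataset$complexity), "complexity")
  if (!is.null(dataset$structure_matrix))
    chk(rownames(dataset$structure_matrix), "structure_matrix")
  if (!is.null(dataset$landmarks))
    for (o in setdiff(tips, unique(dataset$landmarks$species)))
      note("landmarks", paste0("tip '", o, "' has no specimens"))
  if (length(findings)) do.call(rbind, findings)
  else data.frame(where = character(0), finding = character(0))
}

#' Run the comparative-analysis pipeline
#'
#' Executes the stages in dependency order on a dataset shaped like the
#' output of [simulate_study()]: morphometrics (species averaging, form
#' space, PCA and phylogenetic PCA), disparity (rarefied bootstrap and
#' pairwise tests), character mapping (ML rates, stochastic histories,
#' gain/loss summary), evolutionary rates (five-model AICc/LRT comparison
#' across mapped histories, model averaging, rjMCMC branch rates with a
#' group randomization test), trait correlation (threshold model and
#' random-walk Bayes factor), and induction statistics. Stage sizes default
#' to desk-scale settings; raise them for full-scale runs.
#'
#' @param dataset Output of [simulate_study()] (or an ingested list with
#'   the same elements).
#' @param stages Character vector of stages to run; any of
#'   `"morphometrics"`, `"disparity"`, `"mapping"`, `"rates"`,
#'   `"correlation"`, `"induction"`.
#' @param control Named list overriding stage sizes: `n_maps`, `n_fit_maps`,
#'   `n_boot`, `n_boot_test`, `mcmc_generations`, `mcmc_sample_every`,
#'   `corr_generations`, `corr_runs`, `bf_generations`, `n_perm`.
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `pipeline_report` with one element per executed
#'   stage plus a `manifest` (seed, stage sizes, package version).
#' @export
run_pipeline <- function(dataset,
                         stages = c("morphometrics", "disparity", "mapping",
                                    "rates", "correlation", "induction"),
                         control = list(), seed = 1L) {
  ctl <- utils::modifyList(list(
    n_maps = 100L, n_fit_maps = 25L, n_boot = 2000L, n_boot_test = 5000L,
    mcmc_generations = 20000L, mcmc_sample_every = 20L,
    corr_generations = 600L, corr_runs = 4L,
    bf_generations = 6000L, n_perm = 999L), control)
  set.seed(seed)
  rep_ <- list()
  tree <- dataset$tree
  groups <- dataset$groups

  if ("morphometrics" %in% stages) {
    units <- species_average(dataset$landmarks)
    X <- form_space(units, form = TRUE)
    pc <- morpho_pca(X)
    ## phylogenetic PCA on one unit per species (St represents dimorphic taxa)
    st_units <- ifelse(groups == "Dm", paste0(names(groups), "_St"), names(groups))
    Xp <- X[st_units, , drop = FALSE]
    rownames(Xp) <- names(groups)
    ppc <- phylo_pca(Xp, tree)
    rep_$morphometrics <- list(units = units, form = X, pca = pc,
                               phylo_pca = ppc,
                               pc1_scores = stats::setNames(ppc$scores[, 1L],
                                                            rownames(ppc$scores)))
  }

  if ("disparity" %in% stages) {
    stopifnot(!is.null(rep_$morphometrics))
    pc <- rep_$morphometrics$pca
    sc <- retain_axes(pc, 0.05)
    units <- rep_$morphometrics$units
    ug <- stats::setNames(units$group, units$unit)
    disp <- rarefied_bootstrap(sc, ug, "sum_of_variances",
                               n_boot = ctl$n_boot, seed = seed + 1L)
    grp_units <- split(units$unit, units$group)
    tests <- list(
      Mn_vs_St = disparity_difference_test(sc, grp_units$Mn, grp_units$St,
                                           n_boot = ctl$n_boot_test, seed = seed + 2L),
      Mn_vs_Eu = disparity_difference_test(sc, grp_units$Mn, grp_units$Eu,
                                           n_boot = ctl$n_boot_test, seed = seed + 3L),
      Dip_vs_Rh = disparity_difference_test(
        sc, unlist(grp_units[c("St", "Mn")]), grp_units$Rh,
        n_boot = ctl$n_boot_test, seed = seed + 4L))
    rep_$disparity <- list(estimates = disp, tests = tests)
  }

  if ("mapping" %in% stages) {
    fit <- fit_mk2(tree, dataset$tip_states)
    maps <- sample_history(tree, dataset$tip_states, q01 = fit$q01,
                           q10 = fit$q10, n_maps = ctl$n_maps,
                           seed = seed + 5L)
    rep_$mapping <- list(mk2_fit = fit, histories = maps,
                         summary = summarize_histories(maps))
  }

  if ("rates" %in% stages) {
    stopifnot(!is.null(rep_$mapping))
    trait <- if (!is.null(rep_$morphometrics)) rep_$morphometrics$pc1_scores
             else dataset$trait
    gt <- ifelse(groups == "Rh", "Rh", "Dip")
    names(gt) <- names(groups)
    hs <- rep_$mapping$histories[seq_len(min(ctl$n_fit_maps,
                                             length(rep_$mapping$histories)))]
    fits_by_map <- lapply(hs, function(h) {
      p <- paint_from_history(tree, h, gt)
      lapply(names(.model_specs), function(m) fit_multirate(tree, trait, p, m))
    })
    cmp <- compare_models(fits_by_map[[1L]])
    avg <- model_average(fits_by_map, scheme = "akaike")
    mcmc <- mcmc_branch_rates(tree, trait, generations = ctl$mcmc_generations,
                              sample_every = ctl$mcmc_sample_every,
                              n_chains = 2L, seed = seed + 6L)
    er <- edge_regimes(paint_from_history(tree, hs[[1L]], gt))
    grt <- group_rate_test(mcmc, er, n_perm = ctl$n_perm, seed = seed + 7L)
    rep_$rates <- list(model_comparison = cmp, model_average = avg,
                       mcmc = mcmc, group_rates = grt)
  }

  if ("correlation" %in% stages) {
    thr <- threshold_corr(tree, dataset$tip_states, dataset$complexity,
                          generations = ctl$corr_generations,
                          n_runs = ctl$corr_runs, seed = seed + 8L)
    bf <- randomwalk_corr_bf(tree, dataset$tip_states, dataset$complexity,
                             generations = ctl$bf_generations,
                             seed = seed + 9L)
    b <- phylo_regression_coefficient(tree, dataset$tip_states,
                                      dataset$complexity)
    rep_$correlation <- list(threshold = thr, random_walk = bf,
                             regression_b = b)
  }

  if ("induction" %in% stages) {
    pooled <- pool_replicates(dataset$induction)
    rep_$induction <- list(pooled = pooled, test = fisher_exact(pooled))
  }

  rep_$manifest <- list(seed = seed, control = ctl,
                        stages = stages,
                        package_version = as.character(utils::packageVersion("plastevol")),
                        timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  structure(rep_, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$manifest$seed, ") with stages:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  if (!is.null(x$mapping))
    cat("  dimorphism history: modal gains/losses =",
        paste(x$mapping$summary$joint_mode, collapse = "/"), "\n")
  if (!is.null(x$rates)) {
    best <- x$rates$model_comparison$table$model[1L]
    cat("  best rate model:", best, "; group rates:",
        paste(sprintf("%s %.3g", x$rates$group_rates$summary$group,
                      x$rates$group_rates$summary$mean), collapse = ", "), "\n")
  }
  if (!is.null(x$correlation))
    cat("  threshold r =", round(x$correlation$threshold$r_mean, 3),
        "; log BF =", round(x$correlation$random_walk$log_bf, 2), "\n")
  invisible(x)
}
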