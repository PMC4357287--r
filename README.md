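# plastevol

Comparative phylogenetic analysis of a developmental polyphenism and its
consequences for morphological diversification. The package asks, for a
clade in which a discrete environmentally switched dimorphism (a
polyphenism) was gained once and repeatedly lost: do lineages with the
polyphenism in their history occupy more morphospace, evolve faster, and
build more complex structures than lineages that never had it — and what
happens after the polyphenism is secondarily lost? It is written for
evolutionary biologists doing landmark-based comparative work on trees
whose branch lengths are expected substitutions per site ("operational
time"), and ships a synthetic-data generator so every stage is testable
without any empirical download.

The motivating system is the mouthpart (stomatal) dimorphism of
diplogastrid nematodes — narrow-mouthed bacterivorous (St) versus
wide-mouthed predatory (Eu) morphs — analysed against monomorphic
relatives, but every stage is generic.

## The analysis pipeline

1. **Geometric morphometrics** — 11 fixed 2-D landmarks per specimen;
   generalized Procrustes analysis (GPA); species/morph averaging;
   Procrustes *form space* (22 shape coordinates + ln centroid size, so
   that PCA captures shape and size jointly); standard and phylogenetic
   PCA. Centroid size is CS = sqrt(sum of squared landmark distances to
   their centroid); the form matrix appends ln CS.
2. **Disparity** — morphospace occupation per group by the sum of
   univariate variances (sum over retained axes k of var(scores_k)) and by
   PCA volume (product of positive eigenvalues of the Gower-centered
   squared-distance matrix, / n^2), with rarefaction to the smallest
   group, 10,000-replicate bootstrap intervals, and two-tailed
   100,000-replicate bootstrap difference tests.
3. **Character history** — two-state continuous-time Markov model
   (rates q01, q10), Felsenstein pruning, ML fitting, MCMC calibration of
   discretized gamma (k = 90) rate and beta (k = 31) bias priors on trees
   rescaled to unit length, and stochastic character mapping with exact
   endpoint-conditioned path sampling by uniformization; gain/loss count
   posteriors and per-branch density maps.
4. **Evolutionary rates** — multi-rate Brownian motion sigma^2 per regime
   painting (non-censored rate test): five models (1,1,1), (1,2,2),
   (1,2,1), (1,1,2), (1,2,3) over the regimes Rh / Dm / Mn, compared by
   AICc (dAICc > 4 rule) and nested LRTs, averaged across mapped
   histories; plus reversible-jump MCMC of branch-specific rates with at
   most 3 local clocks and multiplier proposal width 1.5, with
   branch-length-weighted group rates, 95% HPD intervals, and a two-tailed
   randomization test.
5. **Trait correlation** — threshold model (latent Brownian liability,
   unit rate, threshold 0) Gibbs-sampled against the complexity index;
   constant-variance random-walk (bivariate BM) model with harmonic-mean
   marginal likelihoods and log BF = 2 (lnML_dep − lnML_indep), "very
   strong" support at log BF > 10; GLS regression coefficient
   b = cov_phylo(x, y) / var_phylo(x).
6. **Complexity & induction** — complexity index ci = row sum of a binary
   species x structure matrix (0..9 in the motivating dataset); pooled
   2x2 induction tables tested by Fisher's exact test with the
   conditional-ML odds ratio.

## Worked example

```r
library(plastevol)

d <- simulate_study(seed = 7)   # 90 species: 33 Rh, 29 Dm, 28 Mn
d
#> Synthetic comparative dataset: 90 tips ( 33 Rh / 29 Dm / 28 Mn );
#>   dimorphism history: 1 gain + 10 loss(es) on the ingroup

## stochastic mapping recovers the history shape
fit <- fit_mk2(d$tree, d$tip_states)
maps <- sample_history(d$tree, d$tip_states, q01 = fit$q01, q10 = fit$q10,
                       n_maps = 100, seed = 3)
summarize_histories(maps)$joint_mode
#> gains losses
#>     1     10

## multirate BM on the true painting: rates (1, 3, 9) recovered
fit_multirate(d$tree, d$trait, d$painting, "1,2,3")
#> Multirate BM fit (1,2,3): lnL = -52.0874, AICc = 112.6454
#>   rates: Dm = 2.523, Mn = 9.457, Rh = 0.8774
#>   root: -0.0453421

## dimorphism-complexity correlation under the threshold model
threshold_corr(d$tree, d$tip_states, d$complexity,
               generations = 500, n_runs = 3, seed = 5)
#> Threshold-model correlation: r = 0.794 (mode 0.844, 95% HPD 0.601-0.938, ESS 54)
```

The mapping mode (1 gain, 10 losses) matches the generator's rejection
target; the three fitted rates bracket the generating (1, 3, 9) with the
monomorphic group fastest; and the posterior correlation between
dimorphism and complexity is centered near the generating liability
correlation of 0.8.

`run_pipeline(d, seed = 1)` chains all six stages and returns a
`pipeline_report` with the disparity table, the five-model AICc
comparison, group rates with HPDs, the correlation summaries, and a seed
manifest.

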