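---
title: "Models and methods behind plastevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastevol links a binary developmental polyphenism to three kinds of
evidence on a phylogeny: morphospace occupation (disparity), the tempo of
continuous-trait evolution (Brownian rates), and structural complexity.
This vignette explains each model, the tunable parameters and their
defaults, the synthetic-data generator that stands in for empirical
specimens, and the numerical and design choices a maintainer should know
about.

## Trees and operational time

All analyses take rooted trees with branch lengths in expected
substitutions per site ("operational time"), not absolute time: the
Brownian rate parameters are therefore trait variance per substitution,
and no dating step exists anywhere in the package. Trees are `ape`
`phylo` objects; the Brownian covariance `C = vcv_matrix(tree)` has
`C[i, j]` equal to the shared root-to-MRCA path length of tips i and j.
Polytomies are accepted and, where an algorithm needs a binary tree
(independent contrasts), resolved into zero-length branches — a
likelihood-neutral operation for Brownian models. Basal polytomies (star
trees) are treated as legitimately rooted; no "unrooted" error is raised
because the `phylo` representation cannot distinguish the two cases.
Prior calibration for stochastic mapping rescales trees to total length
one, so the overall transition rate is expressed per tree.

## Geometric morphometrics

Each specimen is 11 fixed two-dimensional landmarks recorded in lateral
view. Centroid size is the square root of summed squared distances of
landmarks to their centroid. Generalized Procrustes analysis centers
each configuration, scales it to unit centroid size, and rotates it onto
the running consensus by the 2-D orthogonal Procrustes solution
(cross-covariance SVD with a determinant correction that forbids
reflections — left/right is biologically meaningful); the consensus is
re-estimated until its RMS change falls below 1e-10 (at most 100
iterations).

Averaging order: specimens are Procrustes-aligned *within* each species
(or morph) unit, the aligned coordinates averaged, and the unit means
then aligned across units. Raw-coordinate averaging across arbitrary
specimen orientations is ill-defined, so within-unit GPA-first is the
only coherent reading; centroid sizes are averaged on the original scale.

Form space appends the natural log of centroid size (measured before
scaling) to the 22 aligned coordinates; PCA is covariance-based (never
correlation-based), so log size dominates the leading axis exactly when
size varies most — the intended behaviour of form space. Phylogenetic
PCA replaces the column means by the GLS mean under C and
eigen-decomposes the evolutionary covariance
`t(X - mu) C^{-1} (X - mu) / (n - 1)`; on a star tree it reduces exactly
to standard PCA, which the test suite asserts. Dimorphic species are
represented by their St morph in phylogenetic PCA, matching the
comparative design in which one value per tip is required.

## Disparity

Two morphospace metrics are computed on the PC axes that each explain
more than 5% of total variance: the sum of per-axis sample variances,
and the PCA volume — the product of positive eigenvalues of the
Gower-centered pairwise squared-distance matrix divided by the squared
number of units ("cross-distance matrix" is read as this standard
principal-coordinates route; eigenvalues below 1e-12 of the leading one
count as zero). Rarefaction standardizes all groups to the smallest
group's size. The resampling unit is the species/morph unit within a
group: each bootstrap replicate resamples units with replacement and then
rarefies without replacement, so rarefaction subsamples while the
bootstrap resamples. The two-tailed difference test reports
`2 * min(P(diff <= 0), P(diff >= 0))` over bootstrap differences, capped
at 1 and floored at 1/n_boot. Dimorphic species can enter a pooled
"Dip" group via their St units only or via both morphs; both modes are
explicit in the pipeline. Neither metric corrects for phylogenetic
non-independence — that is a property of the metrics, not an oversight.

## Stochastic character mapping

The dimorphism is a two-state continuous-time Markov chain with gain
rate q01 and loss rate q10; likelihoods come from Felsenstein pruning
over the closed-form 2x2 transition matrix. The (rate, bias)
parameterization used for priors is `q01 = 2*lambda*beta`,
`q10 = 2*lambda*(1-beta)`, so lambda is the expected number of
transitions per unit tree length at stationarity when beta = 1/2; this
bridge is stated explicitly because mapping software conventions differ.
The root distribution defaults to the stationary distribution of Q, with
a flat option.

Prior calibration runs a Metropolis-Hastings chain over (lambda, beta)
— multiplier moves on lambda, logit random-walk moves on beta, an
exponential (mean 10 transitions/tree) hyperprior on lambda and a flat
one on beta — then moment-matches a gamma to the lambda draws and a beta
to the beta draws, and discretizes each into equal-mass categories
represented by bin medians (the discrete-gamma convention), 90 rate and
31 bias categories by default. Effective sample sizes below 100 produce
a warning, not an error.

Mapping draws joint node states root-to-tip from the pruning partials
and then samples an endpoint-conditioned path on every branch by
uniformization — exact, and immune to the stalling that rejection
sampling suffers on long branches with unlikely endpoint pairs. Sampled
histories carry per-branch segment lists; summaries give the gain/loss
count distribution, its joint mode, and the time-weighted per-branch
probability of the derived state (the density map).

## Multi-rate Brownian motion

A regime painting assigns every branch segment to Rh (outgroup
background), Dm (dimorphic), or Mn (secondarily monomorphic); paintings
come either from a mapped history (segments split at transition points,
state 1 = Dm, state 0 = Mn within the focal clade) or statically from
tip groups. The likelihood builds the tip covariance by summing
(rate x segment length) along shared paths; computationally this is a
single pruning pass over a rate-rescaled tree, O(n) per evaluation, with
the root value profiled analytically by GLS. K therefore counts the
rates plus one for the root, and `AICc = -2 lnL + 2K + 2K(K+1)/(n-K-1)`
with n the number of tips. Rates are optimized in log space
(bounds 1e-10..1e10) from three starts. Model comparison reports dAICc
(flagging dAICc > 4 as much less supported), Akaike weights, and
likelihood-ratio tests for nested pairs only — for non-nested pairs only
dAICc is reported, since a chi-square reference is not justified there.
Model averaging works either across reconstructions at a fixed model or
with Akaike weights across models within each reconstruction.

The branch-rate sampler is a reversible-jump MCMC over at most
`max_clocks` local clocks (default 3): a set of shift branches partitions
the tree, each branch inheriting the clock of its nearest rootward
shift. Moves are rate multipliers with log-width `proposal_width`
(default 1.5), uniform shift relocations, and add/delete moves whose new
rate is drawn from the rate prior, which collapses the Green ratio to
the likelihood ratio times the clock-number prior ratio. Rates have a
lognormal(0, 2) prior. The clock-number prior is geometric,
`clock_penalty^(k-1)`: under a uniform prior the posterior keeps ~60% of
its mass on spurious extra clocks even for single-rate data, because a
clock covering a few weakly informative branches costs almost no
likelihood; the geometric penalty (0.25 default; 0.4 in the preset
analyses, where sensitivity to the scattered monomorphic clades matters)
restores the parsimony behaviour that a shift model should have. Group
summaries weight branch rates by branch length; HPD intervals use the
shortest-interval rule; group differences are tested by permuting the
branch-to-group assignment (two-tailed).

## Threshold-model and random-walk correlation

The threshold model gives the binary trait a latent Brownian liability
with rate fixed to 1 and threshold 0 (the standard identifiability
normalization; the data cannot separate liability scale from rate). The
complexity index is treated as an observed continuous liability with
free rate sigma2 — matching how such indices are analysed in practice —
with an ordinal-liability mode deliberately left out of the default
path. The Gibbs sampler alternates (i) truncated-normal updates of each
tip liability under covariance `(1 - r^2) C` (compiled kernel), (ii) an
exact conjugate draw of (r, sigma2) from the regression of the observed
trait's independent contrasts on the liability contrasts — valid because
the liability contrasts' marginal is parameter-free once its rate is
fixed — and (iii) a GLS draw of the liability intercept. Multiple runs,
cycling over a tree set when one is supplied, are pooled after burn-in;
the summary reports the posterior mean, median, and density mode of r
(the "ML estimate" of r from MCMC output is ambiguous, so all three are
given) plus the 95% HPD.

The constant-variance random-walk test fits a bivariate Brownian model
to the 0/1-coded dimorphism and the complexity index through their
independent contrasts, with the cross-rate free (dependent) or fixed to
zero (independent). Marginal likelihoods use the harmonic mean of
sampled likelihoods, log-sum-exp stabilized — retained for fidelity to
the classical procedure despite its known instability, with a
stepping-stone estimator (8 power rungs) as a cross-check mode. The
log Bayes factor convention is `2 x (lnML_dep - lnML_indep)` and the
"very strong" flag fires above 10; the convention is stated because the
threshold is meaningless without it. The regression coefficient is
b = cov_phylo / var_phylo under C.

## Complexity and induction statistics

The complexity index is the row sum of a binary species x structure
matrix; the image-level scoring rules (vertex < 135 degrees, iterative
and bilaterally duplicated structures collapsed) are documented as the
matrix's construction contract but not automated — the matrix is the
boundary of computational scope. Induction experiments pool replicate
plates into a 2x2 table; Fisher's exact test supplies the
probability-mass two-tailed p and the conditional-ML odds ratio (via
`stats::fisher.test`, which implements exactly those conventions; the
test suite verifies both against full hypergeometric enumeration).

## The synthetic-data generator

`simulate_study()` regenerates, from one seed, every input the pipeline
consumes, with the statistical structure the analyses assume:

- a 90-tip tree (33 outgroup + 57 ingroup) from constant-rate birth-death
  simulations, rescaled so the mean branch length is 0.05 substitutions;
- a dimorphism gained once on the ingroup stem and lost exactly 10 times,
  rejection-sampled (cap 10,000 attempts) so that the tip states' minimal
  explanation is exactly those 10 losses: 25-37 monomorphic species
  (bracketing the 31 of the motivating design), Fitch parsimony equal to
  the loss count, and dimorphic tips on both sides of the basal ingroup
  split (otherwise a gain-below-the-root reconstruction ties);
- a continuous trait under regime rates sigma2 = (Rh 1, Dm 3, Mn 9);
- landmark configurations: a stylized 11-landmark stoma template with
  per-species shape offsets and log-size factors whose among-species
  spread is largest in the monomorphic group (shape SD 0.30 vs 0.05-0.06;
  log-size SD 0.60 vs 0.10-0.18), 5 specimens per unit, landmark noise
  SD 0.02, Eu morphs widened and enlarged — so form-space disparity is
  ordered Mn > St, Eu > Rh by construction;
- a complexity index from the threshold construction: the dimorphism
  liability is drawn conditional on the realized tip states
  (truncated-MVN Gibbs), the complexity liability correlates with it at
  rho = 0.8, and is cut into 0..9;
- triplicate induction plates (200 adults each) with Eu probabilities
  0.9 (treatment) and 0.05 (control).

Within-species landmark variance is not reported in any source this
emulates; the noise defaults are free parameters chosen to look like
careful microscopy, not calibrated values. Deformations are per-landmark
offsets rather than thin-plate splines: sufficient for group structure
without a heavy dependency. The generator draws everything from one
seeded RNG stream, so a dataset is a pure function of (config, seed) and
regenerates bit-identically.

What passing tests on these data do show: the estimators recover the
structures they were built for, at realistic sizes, under the model
assumptions. What they do not show: robustness to landmarking error that
is correlated across landmarks, to non-Brownian trait evolution, to
state-dependent diversification, or to misassigned morphs — none of
which the generator emulates.

## Problem sizes and numerical choices

Test-suite and acceptance analyses run at desk scale, chosen so the full
suite completes in well under half an hour: 300-400 stochastic maps
(5,000 in a full-scale run), 25 history replicates for the five-model
ML table, rjMCMC chains of 40,000 generations x 2 chains thinned at 25
(vs 30 million x 3 thinned at 5,000 at full scale), threshold-model runs
of 2,500 sweeps x 2-4 runs (vs 500,000 x 50), and 10,000/100,000
disparity bootstraps as in the motivating design. The defaults of the
exported functions are the full-scale values where one exists.

Other numerics worth knowing: GPA declares non-convergence after 100
iterations instead of silently returning; the BM pruning kernel raises
an error on zero-length paths separating distinct values (singular
covariance) rather than regularizing; bootstrap p-values are floored at
1/n_boot so a test can never report exactly zero; uniformization caps
the per-branch jump count at 5,000; the Fisher odds ratio is reported as
infinite where the table structure forces it.

## Known limitations

The rjMCMC explores at most `max_clocks` clocks, so with many scattered
fast clades (the secondarily monomorphic pattern) group contrasts rely
on mixing over shift placements — posterior group means then understate
extreme rate ratios. The harmonic-mean marginal likelihood has infinite
variance in theory; treat the log BF qualitatively and prefer the
stepping-stone mode for anything delicate. The threshold sampler treats
the complexity index as continuous; with very few ordinal levels an
ordinal-liability treatment would be more faithful. Disparity metrics
ignore phylogeny by design. Tip-label matching is exact and
case-sensitive; the input validator suggests fuzzy matches but never
applies them silently.
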