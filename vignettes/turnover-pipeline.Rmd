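---
title: "Predicting enzyme turnover numbers and proteome allocation: methods"
author: "turnoverML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enzyme turnover numbers and proteome allocation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices behind
them, and what the synthetic-data tests do and do not establish about
real data.

## Overview

The pipeline has three stages. First, reaction-level features are
assembled: network context (average flux over sampled growth
environments, the generalist property, substrate counts), protein
structure summarized through gene–protein–reaction (GPR) rules, and
biochemistry (thermodynamic efficiency, Michaelis constants, metabolite
concentrations, assay conditions for in vitro data). Second, regression
models of log10 turnover are trained on the reactions with observations
(in vitro k_cat after curation, or in vivo k_app,max computed from
proteomics and fluxes) and extrapolated to all catalyzed reactions as a
twelve-member ensemble. Third, the predicted turnover vector
parameterizes an enzyme-capacity-constrained flux model (MOMENT) whose
optimal enzyme allocation is compared with measured proteome mass
fractions by RMSE on log10 scale.

## Flux states

Flux balance analysis maximizes the flux of a chosen reaction subject to
the steady state `S v = 0` and the flux bounds; parsimonious FBA then
minimizes the total absolute flux at the fixed growth optimum. The L1
objective is linearized by splitting every reaction into non-negative
forward and backward parts. Because flux polytopes are routinely
degenerate, `solvePfba` optionally (and by default) refines the optimum
lexicographically — minimizing each |v_i| in reaction-index order at the
fixed growth and total-flux optima — so that repeated runs report the
same vertex. The environment-averaging loop turns this refinement off:
the average over environments does not depend on which vertex of a
degenerate optimal face is reported, and the refinement multiplies the
LP count by the reaction count.

All linear programs run on a small dense two-phase simplex implemented
in the package (Bland's rule for anti-cycling, feasibility tolerance
1e-9); steady-state residuals of returned flux vectors are below 1e-6 by
construction, and this is asserted in the tests. Problems at the scale
this package targets (tens to a few hundred variables) solve in
milliseconds; the implementation is not intended for genome-scale
performance work. Quadratic stages use an active-set QP solver
(`pracma::quadprog`).

## Environment sampling

One draw opens oxygen with probability 1/2 and, for each of C, N, S and
P, one uniformly chosen source exchange plus k extras,
k ~ Binomial(2, 1/2), drawn without replacement and truncated to the
candidate pool; the binomial draw is made per element. Carbon uptake
lower bounds are normalized to the substrate's carbon count as
−base/n_C with base = 60 mmol carbon/gDW/h (so a six-carbon substrate
gets −10, a common default in flux modelling); nitrogen, sulfur and
phosphate sources, and oxygen when allowed, open at −1000, effectively
unbounded. Draws that cannot sustain growth are rejected and repeated
without counting toward the requested number of environments, up to a
configurable cap (10,000 attempts). The flux feature is the arithmetic
per-reaction mean of the pFBA solutions over the accepted environments.
Distinct environments on a toy network are few, so both growth
feasibility and pFBA solutions are memoised per environment signature;
the result is deterministic given the seed and invariant to the order in
which distinct environments are drawn.

## MFA-constrained flux states

As an alternative flux feature, measured fluxes are fitted in three
stages: (1) a QP minimizing the squared deviation from the measured
values subject to steady state and bounds (a ridge of 1e-8 on the
unmeasured coordinates keeps the Hessian positive definite; its effect
is below the reporting tolerance); (2) an LP maximizing flux through the
ATP-maintenance reaction with the measured reactions pinned at their
stage-1 values; (3) a QP minimizing the Euclidean norm of the full flux
vector with the ATPM flux additionally pinned. Pins are widened by 1e-6
to avoid numerical infeasibility. Stage 3 deliberately minimizes the L2
norm — a distinct objective from pFBA's L1 — and the two are kept as
separate code paths. The Pearson correlation between fitted and measured
fluxes is reported; on self-consistent synthetic data it is 1 within
1e-6.

## Thermodynamic efficiency

For a reaction with equilibrium constant K_eq and reaction quotient
Q = Π x_i^{S_i}, the Gibbs energy is ΔG = RT ln(Q/K_eq)
(R = 8.314 J/mol/K, natural logarithm) and the efficiency is
η_rev = 1 − exp(ΔG/RT) = 1 − Q/K_eq: 0 at equilibrium, approaching 1 as
the reaction becomes perfectly forward-driven, negative if the reaction
runs against its nominal direction. The two forms of η_rev are kept
consistent to 1e-12, which fixes the placement of RT in the ΔG
definition — writing the second term without RT would be dimensionally
inconsistent and break that identity.

Concentrations and equilibrium constants carry uncertainty, so η_rev is
averaged over a sampled distribution: uniform in log-concentration and
log-K_eq within bounds (concentrations span decades, so log-uniform is
the natural choice), constrained so that sign(ΔG) opposes the flux
direction for every reaction with |v| above 0.1 mmol/gDW/h. A strictly
feasible interior point is found by LP (minimizing the worst signed
margin); if none exists the violated reactions are named in the error.
Sampling is hit-and-run with 1000 accepted samples and 100 burn-in steps
by default — enough for the low-dimensional boxes used here, and
configurable. Reactions below the flux threshold are unconstrained but
still evaluated in every sample. Unmeasured metabolites default to
1e-6–1e-1 M, a standard physiological range. Per-reaction means are
averaged across growth conditions to give the feature.

## Feature assembly

The generalist property of a reaction is the maximum, over the genes in
its GPR, of the number of *other* reactions whose GPR uses that gene; an
enzyme used only by its own reaction scores 0. Substrate counts are the
distinct reactant-side metabolites in the given direction, excluding
water and protons matched by chemical formula (H2O, H), not by
identifier. Gene-level structural features are summarized to reactions
recursively over the GPR tree: AND nodes (complexes) sum molecular
weight and average other features; OR nodes (isozymes) average
everything; genes without data are skipped, and a reaction with no
informative gene is masked missing. These summarization rules are a
documented package choice — per-feature summaries could reasonably
differ, and this is the single most likely point of divergence from
other implementations.

Linearization puts flux, molecular weight, K_m, metabolite
concentrations and the turnover outputs on log10 scale (non-positive
values are masked missing with a warning, never −Inf) and replaces assay
temperature in Celsius by the reciprocal absolute temperature, the
Arrhenius form. Natural logarithms appear only inside the
thermodynamics. The transform round-trips to 1e-12.

## Imputation

Missing features are imputed by chained single imputation: continuous
columns by predictive mean matching (regress on the other features,
donate the observed value of one of the k = 5 nearest-prediction
neighbours), binary columns by logistic-regression draws, wider
categoricals by multinomial-regression draws; columns are revisited until
the imputed cells stabilize or 10 passes complete. Component fits use
design matrices built over all rows so that factor levels never go
missing mid-chain. Four strategies control which rows receive
imputations — none, labelled rows only, unlabelled (prediction) rows
only, or all — and the turnover output column is never used as a
predictor, which the tests verify indirectly: models trained on permuted
responses after imputation show no cross-validated signal. Observed
cells are never altered.

## Curation of in vitro records

Turnover records pass a filter cascade: mutant-flagged records are
dropped, then inhibitor-flagged ones; cross-database duplicates of the
same publication and reaction keep BRENDA over MetaCyc over SABIO;
records whose key does not map to a network reaction are dropped; and
remaining same-reaction conflicts are resolved by a deterministic
comparator — in-vivo-like assay conditions first, then recency, then
agreement with the per-reaction median on log scale, with the value and
record id as final tie-breaks. The comparator is a deterministic
stand-in for what is otherwise a manual choice among equally good
sources. Every drop is logged with the rule that fired, and curation is
idempotent.

## In vivo turnover (k_app,max)

Per condition, k_app = v / (3600 · E) converts a flux in mmol/gDW/h and
an abundance in mmol/gDW into 1/s; k_app,max is the maximum over
conditions with positive flux and abundance. The estimate is restricted
to unique homomers — single-gene GPRs whose gene appears in no other
reaction — because only there is the abundance-to-reaction assignment
unambiguous. With noise-free synthetic proteomics generated from a
capacity-constrained solution, the procedure recovers the generating
rates to 1e-6 for every saturated reaction, a closed loop the tests
exercise end to end.

## Regression models and the ensemble

Five algorithms are available: elastic net (glmnet; grid over mixing
parameter and penalty), random forest (500 trees by default; grid over
mtry), a small single-hidden-layer MLP (nnet; random search over hidden
size 2–10 and weight decay 1e-4–1, 50 draws by default — a desk-scale
stand-in for a deep network with a large random discrete search), and,
for comparison only, ordinary linear regression and PLS (mixOmics).
Hyperparameters minimize cross-validated RMSE under five-times-repeated
5-fold CV (one repetition for the MLP); the per-validation R² is
1 − SSE/SST on the validation fold, which can be negative. An optional
20% test split, stratified by response quantile, gives a selection-free
performance estimate. All fold assignments and stochastic fits are
seeded.

The prediction ensemble crosses the three non-comparison algorithms with
the four imputation strategies (twelve members); linear and PLS are
excluded from it. The four strategy variants of an algorithm share the
same CV seed, so on fully observed data they produce identical fits — a
construction-level identity the tests assert. Each member records the
median of its successful training-set predictions as its fallback for
rows it cannot predict, and member predictions are clamped to the
member's training response range: when a model trained on a few dozen
observations is extrapolated to the whole network, imputed feature rows
can land far outside the training support, and an unclamped MLP or
linear member can return values many decades off; the clamp bounds the
damage without touching interpolation. The ensemble output is the
arithmetic mean of the twelve member values on log10 scale,
exponentiated back to 1/s. The global median of the training response
parameterizes the median-imputed baseline.

Permutation feature importance is the random forest's out-of-bag
measure — the mean increase in out-of-bag MSE across trees when a
feature is permuted, scaled by its standard deviation across trees — and
its significance comes from refitting the forest on permuted responses
(500 permutations by default; the desk-scale calibration tests use 99)
with p = (1 + #{null ≥ observed}) / (n + 1), so p is in (0, 1]. Under a
pure-noise response the fraction of features with p ≤ 0.05 is calibrated
at 0.05 within binomial sampling error.

## MOMENT

The capacity-constrained LP maximizes growth over fluxes (reversible
reactions split into directions) and per-(reaction, isozyme-alternative)
enzyme usages y, subject to steady state, bounds, the couplings
v_dir ≤ 3600 · k_eff · Σ_alt y (3600 converts 1/s to 1/h), and the
budget Σ_g MW_g E_g ≤ C with C = 0.32 g protein/gDW; E_g sums the usages
of every AND-complex alternative containing gene g, so each subunit pays
its own mass, and each OR alternative is coupled separately. Reactions
flagged membrane-localized are parameterized with the 65 1/s default
regardless of the supplied vector, matching how such reactions fall
outside the scope of the structural features. Substrate and oxygen
uptake bounds are opened to −1000. Because the optimal enzyme vector is
not unique when growth is limited elsewhere, a second stage minimizes
total enzyme mass at the fixed growth optimum; reported concentrations
are therefore parsimonious and reproducible, and the capacity couplings
of flux-carrying reactions hold with equality — which is also what makes
the k_app,max closed loop exact.

Predicted mass fractions are MW_g E_g normalized over expressed genes.
Comparisons with measured copies/cell convert the measurement to mass
fractions over the matched gene set (the normalization is over matched
genes, not all detected ones — the alternative reading of the
normalization set; fractions are scale-free so only the set matters),
keep genes with predicted fraction and measured copies both positive,
optionally intersect with other parameterizations' matched sets and
exclusion lists, and report the RMSE of log10 fractions.

## Synthetic data: what it emulates and what it does not

The toy-network generator emits mass-balanced networks (C, N, S, P
tracked; H and O deliberately untracked so water and protons can
participate freely) with element-tagged exchanges, carbon sources of
differing yield, a backbone with shortcut and reversible routes, GPRs
mixing single genes, complexes and isozymes with a tunable gene-reuse
probability, and a biomass reaction kept balanced by giving the biomass
metabolite the summed formula of its precursors. An oxygen exchange and
a carbon-wasting oxidase exist but are never required, so oxygen
availability is informative about the sampler, not about growth.

The planted turnover model draws structural and biochemical features
from fixed distributions (depth lognormal around 10 Å, exposure
Beta(2, 5), disorder Beta(2, 8), hydrophobicity normal, K_m and
concentrations lognormal) and sets log10 turnover to a linear
combination with the sign structure expected for catalysis — positive on
flux, negative on active-site depth, solvent exposure and the generalist
count — plus Gaussian noise sized so the population R² of the emitted
dataset equals the requested value exactly (the signal variance is
computed on the emitted rows). Missingness is applied after generation,
feature-wise and as an active-site block. Proteomics are simulated by
solving the capacity-constrained model per condition with the true rates
and multiplying lognormal noise (σ = 0.2 on log10 scale by default, a
typical quantitative-proteomics error); copies/cell use a fixed
conversion of about 1e12 cell equivalents per gram dry weight — only
relative fractions matter downstream.

What passing tests show: the solvers agree with brute-force enumeration;
the sampler and significance tests are calibrated; planted regimes (a
population R² of 0.76, the zero-noise turnover closed loop) are
recovered; and the qualitative parameterization ordering — true rates
best, ensemble-predicted second, median-imputed worst — holds on at
least 80% of seeds. What they do not show: real structural-feature
marginals and correlations (synthetic features are independent, real
ones are not), real flux distributions, real database noise, or the
absolute performance numbers of any real-data study. The synthetic
features are drawn independently, which makes the planted R² an upper
bound on how informative correlated real features of the same strength
would be.

## Problem sizes and protocol constants used by the tests

The test and acceptance suites run at desk scale, chosen to finish on a
single CPU in minutes while leaving the protocol constants intact: the
12-member ensemble and the 25-validation CV protocol are verified as
stated; flux features average 20–100 environments on toy networks (the
`averageSampledFlux` default remains 10,000, the scale appropriate for a
genome-scale study); the sampler frequency check uses 10,000 draws;
type-I calibration uses 40 null replicates of 99 response permutations
on 60-row datasets; planted-R² recovery uses n = 300 over 20 seeds; and
the end-to-end ordering experiment uses 20 seeds of ~30-reaction
networks with three growth conditions, training the ensemble with
3-fold CV and reduced search budgets on the ~20–30 in-vivo-flavoured
observations a toy network yields. With labelled sets that small, the
complete-case ("none" and unlabelled-only) members sometimes cannot
train and are dropped with a warning; the imputing members carry the
ensemble, which is itself an illustration of why the imputation
strategies exist.

## Known limitations

The dense simplex and the brute-force test oracles are exponential or
cubic in problem size and are meant for toy networks only. GPR
summarization rules are fixed package-wide rather than per feature.
The conflict comparator in curation is a deterministic convention, not a
reconstruction of expert judgement. Thermodynamic sampling treats K_eq
and concentration bounds as independent boxes; full thermodynamic flux
analysis with direction binaries is out of scope. The MLP is a small
single-hidden-layer network, not a deep architecture. Ensemble
prediction clamps to the training response range, which biases genuinely
out-of-range extrapolations toward the observed extremes — a deliberate
trade against unbounded extrapolation error at small n.
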