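---
title: "heterosim: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heterosim: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## 1. The metabolic substrate

Phenotypes are computed on a constraint-based metabolic model: a
stoichiometric matrix $S$ (metabolites × reactions), per-reaction bounds
$\alpha_j \le v_j \le \beta_j$, and one biomass objective reaction. Flux
balance analysis maximises $c \cdot v$ subject to $S v = 0$ and the
bounds. Every phenotype in the package is evaluated by *parsimonious* FBA:
the biomass maximum is computed first, then all reversible reactions are
split into non-negative forward/reverse components and the total flux
$\sum_j v_{\mathrm{irrev},j}$ is minimised with biomass pinned at its
optimum. Minimising total flux models efficient enzyme usage, removes
futile cycles, and collapses most of the degeneracy of alternate optima.
Ties in total flux can still exist; downstream code relies only on the
objective value and the total flux being unique, never on the identity of
the flux vector.

### The linear-programming backend

No LP solver package is assumed: the package carries a dense two-phase
primal simplex (Rcpp) with Bland's anti-cycling rule. This is a deliberate
fit to the problem class — toy networks with tens of reactions — not a
general-purpose solver. Numerical choices:

* pivot/reduced-cost tolerance `1e-9`; phase-1 feasibility threshold
  `1e-7`; all user-facing comparisons at `1e-6` relative (standard
  double-precision LP practice);
* infinite bounds are clamped to `1e5` flux units before solving. An
  optimum that reaches 90% of that sentinel is reported as an unbounded
  objective, naming the objective reaction;
* in the pFBA second stage, biomass is pinned through an equality row with
  a bounded slack of `1e-9 · max(1, |v_opt|)`, which keeps the restricted
  problem feasible in floating point while staying far inside the `1e-6`
  comparison tolerance;
* the simplex is cross-checked in the test suite against an independent
  brute-force oracle that enumerates basic solutions of the small
  fixtures, including the $v_j = 0$ hyperplanes that total-flux minima can
  sit on.

Flux variability analysis solves, for each reaction, the min and max flux
subject to biomass staying at or above a fraction of its optimum (the
fraction enters through a slack-bounded inequality row). The default
fraction is 0.95; 0.90 and 0.99 are exercised in tests as the documented
alternatives.

*Biomass coupling.* The classification of reactions "coupled to biomass"
is defined here as: the minimum of $|v_j|$ over the feasible set with
biomass $\ge$ fraction × optimum exceeds `1e-6`. The literature contains
several non-equivalent coupling notions (flux-coupling ratios, directional
coupling); this is the simplest LP-expressible one consistent with
"must carry flux to sustain near-optimal biomass", and it is computed
directly from the FVA envelope. It is an interpretation, and is flagged as
such.

## 2. The genetics layer

Each *internal* reaction is a genetic locus; exchange and biomass
reactions never carry alleles. An allele is a non-negative flux capacity.

**Allele spaces.** A reference flux distribution (RFD) — pFBA on the
unconstrained model — fixes each reaction's working direction and the
total-capacity budget. The FVA envelope at fraction 0.95, restricted to
the RFD direction and mapped to magnitudes, delimits each locus's allele
range; `levels` evenly spaced values (default 101) form the discrete
allele set. Rationale for 101: fine enough that two-allele averages are
nearly continuous, coarse enough that exact value equality — the package's
definition of homozygosity — is reachable by drift in reasonable time.
The FVA restriction emulates standing variation in a population whose
strongly sub-optimal alleles have already been purged by past selection;
widening it would inflate heterosis by crossing what are effectively
mutants.

**Capacity derivation.** A diploid's capacity at a locus is the *additive
mean* of its two allele values (no dominance, no allele-specific noise,
no trans-acting factors — all interactions between loci are mediated by
the network). Capacities are then rescaled by
$\lambda = \min(1,\; T_{\mathrm{RFD}} / T_{\mathrm{raw}})$ where
$T_{\mathrm{RFD}}$ is the summed absolute RFD flux and $T_{\mathrm{raw}}$
the summed per-locus means. Two readings of the normalisation were
possible (rescale *to* the budget vs *cap at* the budget); the package
caps and never scales up, following the operational description of the
procedure. The consequence is that all individuals command at most the
same total enzyme budget, so phenotypic differences reflect allocation
efficiency, not total capacity.

**Bound application.** The capacity tightens the upper bound of a
forward-working reaction, the lower-bound magnitude of a backward-working
one. For loci the RFD leaves idle there is no direction to inherit, so the
capacity caps both sides ($|v_j| \le$ capacity) — the least-assuming
choice.

**Non-viable genotypes.** If the constrained LP is infeasible the
individual gets biomass 0 and a `feasible = FALSE` flag instead of an
exception: selection must be able to discard such genotypes without
aborting a generation.

## 3. Breeding design

Defaults mirror a conventional intense-selection program: 500 individuals
per generation, top 5% (ranked by biomass rate, ties broken by individual
id for determinism) selected as parents, 50 generations, selfing
prevented during inbreeding; F1/F2 populations built by sampling 30% of
each line (without replacement within a line) and drawing parent pairs
uniformly (pairs may repeat; the mating design beyond "crossed together"
was not specified, so the simplest exchangeable scheme is used). Crosses
transmit one uniformly chosen allele per parent per locus, independently
across loci: no linkage, no mutation, no epigenetics. The offspring
genotype records which slot came from which parent; the substitution scan
depends on this.

The fixation experiment selfs one F1 into a large F2 collection, founds
lineages from the top-ranked (selected arm) or uniformly drawn (random
arm) F2s, and then iterates "select 2% (by rate or at random), self each
selected individual with equal probability" per generation. The 2%
selection is interpreted as a parent *pool* in which each selected
individual is equally likely to parent each offspring.

Randomness is split hierarchically (`derive_seed`) from one root seed per
run, so any stage can be reproduced in isolation and evaluation order
cannot affect results; individual evaluation itself is deterministic and
side-effect-free, which is the package's parallelism contract (evaluations
may run in any order or in parallel without changing the outcome).

## 4. Quantifying and decomposing heterosis

Mid-parent heterosis is the F1 biomass rate divided by the mean of the
two parents' rates; the absolute deviation (F1 − mid-parent, flux units)
is carried alongside. The decomposition works on the *absolute* scale:
ratios do not add, so the exact residual identity
`overall = Σ single-locus + multi-locus` is only well defined on flux
units. The package therefore decomposes deviations and reports the ratio
next to every decomposition, so both views are available.

The substitution scan makes the F1 homozygous for each inherited parental
allele at each locus in turn and re-derives constraints from scratch —
including renormalisation, since changing one locus's mean changes
$\lambda$. A `frozen_lambda` switch provides the alternative (hold the
F1's $\lambda$ fixed) for sensitivity analysis. A locus's direct
contribution is F1 biomass minus the mean of the two substituted
biomasses; averaging over the two substitutions is the symmetric choice
among the possible within-locus combinations.

Correlation between heterosis and per-reaction flux is plain Pearson
product-moment, with the heterosis "magnitude" taken as the mid-parent
ratio; reactions with zero flux variance are reported `NA`, never 0. The
"correlated" set uses |r| > 0.90, the "contributing" set uses variance of
direct contributions > 1e-8 across the scanned population.

## 5. The synthetic model generator

All development and testing runs on generated toy networks with known
analytic optima: chains, parallel paths, a bottleneck pair, a futile
cycle, and a short/long branch. The workhorse for population-scale runs
is `parallel_paths` with four 6-step paths of capacity 4 over an input of
10: 24 constrained loci, total path capacity 16 > 10, which keeps every
FVA envelope wide (`[0, 4]`) so alleles have room to vary. The
`bottleneck_pair` topology is the minimal mechanistic fixture: two
consecutive steps whose complementary low capacities in two parents are
both relaxed in the F1 by additive averaging — heterosis from pure
between-locus complementation, with no within-locus dominance anywhere in
the system.

What the toys do *not* emulate: compartments, cofactor stoichiometry,
reversible internal cycles of realistic size, hundreds of loci, and the
redundancy structure of genome-scale networks. A green test on a toy
establishes the correctness of the *procedures* (selection response,
homozygosity dynamics, F2 collapse, decomposition identities), not the
published genome-scale magnitudes (e.g. counts of correlated reactions or
quadrant shares of the single/multi-locus plane), which depend on a
specific large network and are explicitly out of scope.

## 6. Scaled-down acceptance world

The acceptance checks run a deliberately scaled world chosen once:
24 constrained loci and populations of 200 (within the stated 20–30 loci
and 200–500 ranges) so that five 50-generation selection runs finish in
about a minute on one CPU. Observed behaviour on this world matches the
expected breeding dynamics: F1s of everywhere-distinct homozygous lines
are 0% homozygous, their F2s ≈50%, and five-seed median homozygosity
after 50 generations of top-5% selection exceeds 90% while mean biomass
rises towards the network optimum over the first 30 generations. Those
numbers are computed, not asserted: the test suite and
`scripts/acceptance.R` recompute them on every run.

## 7. Known limitations

* The simplex backend is dense and unsuited to genome-scale models
  (hundreds of metabolites); plugging a sparse LP solver behind
  `run_fba`/`run_pfba`/`run_fva` would be the natural extension.
* Homozygosity-by-value means two lineages can become "homozygous" by
  converging on the same allele value; with 101 levels this is the
  intended behaviour (shared values *are* the same allele) but it makes
  homozygosity grid-dependent.
* SBML support covers the Level 3 FBC subset the package itself writes;
  exotic SBML features (rules, events, annotations) are ignored.
* No dominance, linkage, mutation, regulation or feedback — by design,
  since the point is that network epistasis over purely additive
  cis-acting alleles already generates realistic heterosis.
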