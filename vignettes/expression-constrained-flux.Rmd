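---
title: "Expression-constrained flux prediction: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-constrained flux prediction: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcor)
```

## The problem

Constraint-based analysis of a genome-scale metabolic model usually assumes
the cell maximises a biomass objective. That assumption requires a biomass
composition that is rarely known for the condition of interest, produces one
prediction regardless of condition, and is doubtful outside fast-growing
microbes. `fluxcor` implements an alternative, data-driven objective: find
the steady-state flux distribution that agrees as closely as possible with
absolute gene-expression measurements (e.g. RPKM from RNA-Seq), weighted by
the confidence in each measurement.

The steady-state flux space is the usual one,

$$N v = 0, \qquad L_i \le v_i \le U_i,$$

with $N$ the stoichiometric matrix and $L$, $U$ flux bounds. Over that
space the method minimises the weighted absolute deviation

$$Z \;=\; \sum_{i \in \mathcal{S}} \frac{1}{\sigma_i}\,\lvert v_i - d_i\rvert,$$

where $d_i$ is the expression-derived weight of reaction $i$, $\sigma_i$ its
uncertainty, and $\mathcal{S}$ the set of reactions that (a) carry
expression data and (b) have a known flux direction. $Z$ is convex and
linearisable: writing $v_i = s_i d_i + d_i^+ - d_i^-$ with
$d_i^\pm \ge 0$ and direction sign $s_i \in \{+1,-1\}$ turns the problem
into an LP with objective $\sum_i (d_i^+ + d_i^-)/\sigma_i$.

## From genes to reaction weights

Gene–protein–reaction (GPR) rules link expression to reactions:

* **AND (enzyme complex)** — the complex concentration is bounded by its
  least-expressed component, so the evaluated mean is the minimum of the
  child means, and that child's sd is carried along. When two children tie
  on the mean, the smaller sd is taken (the more confident bound).
* **OR (isoenzymes)** — capacities add: means are summed, and variances are
  added under the assumption that the genes are uncorrelated, so
  $\sigma = \sqrt{\sum_k \sigma_k^2}$.

```{r gpr}
pr <- newExpressionProfile(c("YJR109C", "YOR303W", "YJL130C"),
                           mean = c(0.156, 0.0976, 0.126),
                           sd = c(0.083, 0.033, 0.013))
evaluateGpr(parseGpr("(YJR109C and YOR303W) or YJL130C"), pr)
```

Genes absent from the profile are treated as missing data: in an OR the
missing isoenzyme contributes nothing and is dropped; in an AND a missing
component makes the whole complex missing, because a complex cannot be
bounded by an unknown concentration. A reaction whose rule evaluates to
missing (or that has no rule — exchanges, the biomass pseudo-reaction,
spontaneous reactions) gets `hasData = FALSE` and never enters $Z$.

Promiscuous enzymes reuse their full expression value for every reaction
they catalyse; no partitioning is attempted, since flux demand across a
promiscuous enzyme's reactions is unknown a priori.

Zero standard deviations (single observations, or constant counts) are
floored at `sigmaFloor` (default $10^{-6}$ expression units) rather than
excluded, so the weight $1/\sigma_i$ stays finite while such reactions keep
a very strong pull toward their target. Expression values are mapped raw;
no renormalisation is applied, because the glucose rescaling at the end
absorbs any common scale factor (see below).

## Direction assignment by iterated FVA

The objective needs a sign $s_i$ for every scored reaction, but reversible
reactions have no intrinsic direction. The algorithm therefore iterates:

1. minimise $Z$ over the currently irreversible, data-bearing reactions
   (initially those whose bounds already fix a direction: $L_i \ge 0$
   forward, $U_i \le 0$ backward);
2. run flux variability analysis under $Z \le Z^*$: any reversible reaction
   whose attainable flux interval no longer crosses zero has become
   unidirectional;
3. clamp those reactions' bounds to the detected direction, add the
   data-bearing ones to the scored set (target $+d_i$ forward, $-d_i$
   backward), and repeat until no new direction is found.

The irreversible set can only grow, so termination is guaranteed; the
iteration cap (default 100) only guards against numerical pathology.
Reactions still reversible at termination never enter $Z$. Two numerical
choices matter here: the FVA ceiling uses an absolute slack of $10^{-9}$ on
$Z \le Z^*$ (pure equality is brittle), and the same tolerance classifies
directions ($\min \ge -10^{-9}$ counts as forward-only). A reaction whose
interval is pinned to zero on both sides is classified forward with its
lower bound clamped to zero — a deterministic convention; its flux is zero
either way. Each cycle re-solves the enlarged problem freely rather than
keeping earlier objective values as constraints: the earlier optimum
reflected less information about directions, and monotone growth of the
irreversible set — not the objective trace — is what guarantees
termination.

## A unique representative solution

The optimal face $\{v : Nv = 0,\; L \le v \le U,\; Z \le Z^*\}$ is
generally a polytope, not a point. To make results reproducible the package
returns its geometric centre, computed by iterated variability bounding:
compute each reaction's attainable interval over the current polytope, take
the box midpoint, minimise the $L_1$ distance to that midpoint, restrict to
the minimisers, and repeat until the attainable box collapses (maximum
width below $10^{-6}$; at most 50 outer iterations, after which the last
iterate is returned with a warning). On a box-shaped face this returns the
exact midpoint in one round; around an unconstrained internal cycle the
centred solution carries zero net cycle flux by symmetry. Centring is
applied to the full flux vector, not only to exchanges, so internal fluxes
are reproducible too; exchange fluxes of interest sit on the face boundary
or are centred deterministically either way. The LP pivot order is
deterministic, so repeated runs give identical vectors.

## Units and glucose scaling

The LP is solved in expression units: $d_i$ is an RPKM-like number, not a
flux. Physical units enter only at the end, when the whole vector is
rescaled so that the glucose (nutrient) exchange flux magnitude equals the
measured uptake in mmol/h/gDW. Because the rescaling is a single positive
factor, flux ratios are unchanged, and multiplying all $d_i$ by a common
constant leaves the scaled predictions invariant whenever bounds are not
binding — which is why raw expression values can be mapped directly. The
default bounds of $\pm 1000$ for unbounded reactions are large enough to be
non-binding for the toy problems shipped here for the same reason.

## Evaluation

Predictions are compared with measured exometabolome (excreted metabolite)
fluxes via the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$, computed on raw glucose-normalised fluxes.
$R^2 = 1$ is a perfect match, $0$ is what predicting the observed mean
achieves, and negative values are worse than the mean predictor. Matching
of metabolites to exchange reactions is by an explicit user-supplied table,
not name heuristics. Excretion is reported positive and uptake negative;
the sign is derived from the exchange reaction's stoichiometric
coefficient, so models writing exchanges in either orientation are handled.

The package bundles the reference exometabolome tables for yeast cultures
held at 75% and 85% of maximal biomass (`exometabolomeTable()`).
Recomputing $R^2$ from the rounded table values gives 0.961 for the 85%
gene-expression predictions and 0.860 for the 75% ones (the reference
reports 0.96 and 0.87; the 75% gap is attributable to table rounding).

## Baselines

Four reference predictors are included, all consuming the same
`ReactionWeights`, so comparisons isolate the algorithm:

* `standardFBA()` — maximise biomass, centre the optimal face. On a toy
  central-carbon network with fermentation and respiration branches this
  routes every glucose carbon to CO2 and predicts zero excretion of all
  other products — the qualitative failure mode the expression fit is
  designed to avoid.
* `fittedFBA()` — the best fit to the measured exchanges attainable while
  keeping biomass maximal (a two-stage LP): an upper bound on what the
  biomass assumption could ever explain.
* `gimme()` — minimises shortfall-weighted flux through below-threshold
  reactions subject to a biomass fraction. Defaults: threshold at the 25th
  percentile of the data-bearing weights, fraction 0.9.
* `imat()` — a MILP maximising the count of high-expression reactions
  carrying at least `imatEps` flux plus low-expression reactions carrying
  none. Defaults: tertile cut points, `imatEps = 1`. These defaults follow
  the methods' common usage; both are overridable, and numeric reproduction
  of any particular published run is best-effort since such runs rarely
  document their parameterisation.

## The LP engine

All of the above reduces to bounded linear programs. The package carries
its own dense two-phase bounded-variable simplex (`solveLP()`) with Bland
anti-cycling and a deterministic pivot order, plus a depth-first branch and
bound (`solveMILP()`) for the iMAT indicator variables. A dense simplex is
entirely adequate at the scale the package targets in its tests (tens of
reactions); it is validated against an independent vertex-enumeration
oracle on random LPs. For genome-scale models (thousands of reactions) a
sparse industrial solver would be preferable; the LP construction is
separated from the solver call so that swapping the engine is localised.

## What the synthetic generator does and does not emulate

`makeToyModel()` builds a connected backbone chain with uptake and
excretion exchanges, random shortcut reactions, a configurable reversible
fraction and random GPR trees; `plantFluxesAndExpression()` samples a
feasible flux pattern $v^*$ and derives each gene's expression as the
largest $|v^*|$ among its reactions plus truncated-normal noise
(non-negative, like RPKM), with the planted noise level as sd. Taking the
maximum (not the sum) over a promiscuous gene's reactions keeps the planted
expression a conservative upper bound, consistent with the min/sum
evaluation semantics. Depth-1 rules get a dedicated gene per reaction so
that noise-free planting maps back exactly; deeper trees draw from a shared
pool and reintroduce promiscuity.

The generator emulates the premise that expression magnitudes carry flux
information under stoichiometric constraints. It does **not** emulate yeast
network topology, realistic RPKM dynamic range, transcript-vs-protein
discrepancies, or condition-dependent regulation — so passing recovery
tests demonstrates algorithmic correctness, not biological validity on real
data.

## Problem sizes and test budget

The shipped tests run fixtures of 3–8 metabolites and 4–11 reactions,
recovery Monte-Carlo over 10 seeds at three noise levels, and random-LP
validation over dozens of instances — sizes chosen so the entire suite runs
in well under a minute while still exercising every code path, including
degenerate ones (empty scored sets, blocked reactions, free cycles,
redundant constraints).

## Known limitations

* The dense simplex limits practical model size; genome-scale runs need an
  external LP backend.
* Transcript abundance is an imperfect proxy for enzyme activity; the
  method inherits that assumption and offers no protein-level correction.
* The biomass pseudo-reaction is unscored (it has no gene) and keeps its
  model-default bounds: it is neither forced to zero nor maximised.
* Exchange bounds are taken from the model as the growth medium; no
  measured uptake rates other than the final glucose rescaling are imposed.
* GIMME/iMAT are implemented from their cited algorithmic descriptions at
  the fidelity needed for comparative evaluation, not as re-releases of the
  original toolboxes.
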