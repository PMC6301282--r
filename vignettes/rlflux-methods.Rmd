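---
title: "Methods: geometric FBA and multi-omic flux analysis with rlflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric FBA and multi-omic flux analysis with rlflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlflux)
```

`rlflux` models the question "how much rhamnolipid can an engineered
*Pseudomonas* network export, and which genes govern that flux?" as a
chain of constraint-based computations. This vignette is the package's own
account of the underlying methods, the tunable parameters, and the design
choices made where several defensible options existed.

## The constraint-based model

A `metabolic_model` is the stoichiometric matrix $S$ ($m$ metabolites
$\times$ $n$ reactions), flux bounds $V_{\min} \le v \le V_{\max}$ in
mmol/gDW/h, an objective weight vector $c$, and gene–protein–reaction
(GPR) rules. Steady state $S v = 0$ is imposed on every metabolite row;
boundary reactions (exchanges and sinks, recognisable as columns touching
a single metabolite) are the only way mass enters or leaves, which is the
standard way of letting "exchange metabolites" escape the steady-state
assumption without special-casing rows.

Conventions, chosen once and used everywhere:

* **Uptake is negative exchange flux.** A medium supplying a carbon
  source at rate $r$ sets that exchange's lower bound to $-r$
  (`set_medium()`); closed sources get a lower bound of 0. Secretion
  stays allowed. This is the dominant community convention and makes
  reported uptake magnitudes directly comparable with bound settings.
* **Default bounds** are $\pm 1000$ (irreversible: $0..1000$)
  mmol/gDW/h, the usual "effectively infinite" sentinel. Keeping every
  bound finite also guarantees that every linear program the package
  builds is bounded, which simplifies the solver contract.
* **Serialisation.** Three formats round-trip bit-comparably: a minimal
  SBML Level-3/FBC-style subset (bounds as parameters, GPRs as
  `GENE_ASSOCIATION` notes), COBRA-style JSON (readable by cobrapy), and
  a two-file TSV dialect (`metabolites.tsv` + `reactions.tsv`) whose
  virtue is being diffable in code review.

## The linear-programming core

No assumptions are made about which LP engine sits underneath:
`solve_lp()` is a fixed contract (maximise/minimise $c^\top x$ subject to
$A x = b$, $l \le x \le u$). The built-in engine is a dense two-phase
revised simplex with variable bounds (`src/simplex.cpp`), using a Dantzig
entering rule that falls back to Bland's rule after 2000 iterations to
guarantee termination under degeneracy. Basis systems are re-solved from
scratch each iteration rather than updated incrementally: for the model
sizes this package targets (tens to a few hundred reactions) the
numerical freshness is worth more than the speed. Feasibility is declared
at a phase-1 residual below $10^{-6}\cdot\max(1, \lVert b\rVert_\infty)$;
reduced-cost and ratio tolerances are $10^{-9}$.

`fva()` encodes "objective at least a fraction of its optimum" with an
explicit surplus variable so the constraint system stays in equality
form. At fraction 1 the optimal face is fixed exactly.

## Geometric flux balance analysis

FBA optima of realistic networks are degenerate: many flux vectors attain
the same objective, and a bare simplex vertex is an arbitrary,
solver-dependent representative. The geometric centring procedure picks a
unique point of the optimal polytope:

1. fix $c^\top v$ at the FBA optimum (an equality row);
2. compute FVA ranges $[a_j, b_j]$ for all not-yet-converged reactions;
3. find the feasible $v$ minimising
   $\sum_j |v_j - \tfrac{a_j + b_j}{2}|$ — an LP after the usual
   $t^+ - t^-$ splitting;
4. shrink each range to the interval between $v_j$ and the midpoint and
   repeat until the widest range is below `tolerance`.

Step 4 at least halves every active range, so the iteration count is
logarithmic in (initial width / tolerance); the defaults
(`tolerance = 1e-6`, `max_iterations = 200`) leave a wide margin, and a
non-converged result is returned with a warning flag rather than an
error. The L1 distance is used rather than L$\infty$ because it keeps
every step a plain LP with sparse structure; ranges exactly at tolerance
count as converged. Two properties matter downstream and are enforced by
tests: symmetric alternatives (e.g. duplicated transporters) receive
equal shares, and isolated reversible cycles — whose FVA ranges are
symmetric about 0 at the optimum — are centred to zero flux, the
behaviour usually described as removing thermodynamically infeasible
loops. The package deliberately does **not** implement loopless-FBA
integer programming; cycle suppression is exactly the centring behaviour,
no more.

One published description of this style of algorithm motivates it as
minimising enzyme amounts. Whether an extra total-flux minimisation was
ever layered on top is ambiguous in the literature the package follows;
`rlflux` implements centring only, and treats "minimal enzyme" as an
interpretation, not an extra constraint.

## Engineering the rhamnolipid pathway

`rhamnolipid_reaction_set()` returns the five-core-step graft — RHLA
(acyl transfer from ACP to CoA), PHAC and 3H3H (the PHA-synthase-adjacent
dimerisation steps), RHLB (rhamnosylation of HAA to mono-rhamnolipid) and
RHLC (second rhamnosylation to di-rhamnolipid) — plus mono-rhamnolipid
transport and exchange. Stoichiometries are kept **exactly as printed in
the source reaction table**, including PHAC's 1-substrate → 2-product
form, which is not carbon-balanced. This is a deliberate
faithfulness-over-cleanup decision: `check_mass_balance()` exposes the
discrepancy as soon as the participating metabolites carry formulas, and
the grafted route's yield consequently differs from the host's native
route (the toy's engineered optimum is 20/7 rather than 10/6 at glucose
10 — the printed stoichiometry duplicates acyl mass). Curation after
grafting mirrors common practice: an elemental/charge balance report
(exchanges exempt, missing formulas reported as "unchecked") and a
flux-carrying check (FVA over the added reactions; pure proton/water
shuttles excluded as ubiquitous). Di-rhamnolipid gets transport/exchange
only behind a flag, so by default RHLC is a reported dead end — the
pipeline centres on the RhlA/RhlB mono-rhamnolipid product.

## Expression integration

Each sample's normalised expression profile $\theta$ (per-gene mean
across all samples $\equiv 1$; the package chooses this recipe because
"reference level 1" then means "cohort average" with no external
calibrator) is mapped onto reactions through GPR rules with AND = min
(limiting subunit of a complex) and OR = max (best isozyme), and then
onto bounds by

$$\varphi(\theta) = \left[1 + \gamma\,|\log\theta|\right]^{\mathrm{sgn}(\theta - 1)},$$

with natural log (the closed-form identities $\varphi(e) = 1 + \gamma$,
$\varphi(1/e) = (1+\gamma)^{-1}$, $\varphi(\theta)\varphi(1/\theta) = 1$
then hold exactly) and $\mathrm{sgn}(0) = 0$ so $\varphi(1) = 1$. Both
bounds are multiplied by $\varphi$; $\gamma = 1$ by default, giving a
logarithmic, symmetric effect of expression on flux capacity. Only
GPR-bearing reactions are scaled — scaling unannotated reactions would
impose expression effects on steps with no measured enzyme. Genes present
in the matrix but absent from the model are simply not constraints (they
still enter the regression stage). Note the integration is continuous;
discretising schemes that switch reactions off below a threshold are out
of scope by design.

A subtlety worth stating: $\varphi$ only changes the phenotype where the
scaled bound actually binds at the optimum. On loosely bounded reactions
($\pm 1000$) modest expression changes are invisible — which is exactly
why the synthetic generator installs binding caps (below).

## Downstream statistics

* **Differentially active reactions.** Fluxes from batches of constrained
  LPs are bounded, frequently piecewise-constant in the inputs, and not
  remotely Gaussian, so the two-group test is the Wilcoxon rank-sum
  (normal approximation), with Benjamini–Hochberg adjustment and the
  conventional adjusted-$p < 0.05$ cutoff. Reactions numerically constant
  across all samples are excluded from testing (a rank test on constants
  is undefined information-free noise) and reported separately.
* **Elastic net.** For each DAR, its flux vector across samples is
  regressed on the expression matrix with penalty
  $\lambda[(1-\alpha)\lVert\beta\rVert_1 + \alpha\lVert\beta\rVert_2^2]$
  — note $\alpha$ weights the *ridge* term in this convention
  ($\alpha = \lambda_2/(\lambda_1+\lambda_2)$), so the call into glmnet
  uses mixing parameter $1-\alpha$; at the default $\alpha = 0.5$ the two
  conventions coincide. $\lambda$ is chosen at the 10-fold CV-error
  minimum (not the one-standard-error rule — the goal is ranking genes,
  not maximal parsimony), with the fold assignment seeded and recorded.
  Predictors are standardised internally. Top genes are ranked by
  $|\beta|$ with ties broken by gene id for determinism.
* **PCA of flux matrices.** Individuals are reactions, variables are
  growth conditions. Columns are centred and (by default) unit-scaled —
  correlation PCA, matching the correlation-circle style of presentation;
  constant columns (e.g. a condition in which nothing runs) are dropped
  with a warning. From the SVD $Z = U D V^\top$ with eigenvalues
  $d_k^2/(n-1)$: variable coordinates are correlations with components,
  contributions are $100\,v_{jk}^2$ (summing to 100 per component),
  individual contributions $100\,u_{ik}^2$, and cos² the squared
  coordinate over the entity's squared norm. Keeping all components
  reconstructs the input to numerical precision, which the tests assert
  at $10^{-8}$.

## The synthetic data: what it emulates, and what it does not

`toy_model()` is a miniature of the engineered producer: glucose (plus
fructose and glycerol) feeding glucose-6-phosphate; a rhamnose branch
(g6p → g1p → dTDP-sugar, with dTDP recycled catalytically); lumped
glycolysis (1 g6p → 2 acetyl units); fatty-acid synthesis
(5 acetyl + ACP → 1 hydroxyacyl-ACP, with CO$_2$ loss and ACP recycling);
RhlA-like dimerisation (2 acyl → HAA); RhlB-like condensation
(dTDP-sugar + HAA → mono-rhamnolipid); export and a biomass drain. The
stoichiometry makes key optima hand-derivable: at glucose 10 the export
optimum is exactly $10/6$ (each rhamnolipid costs 1 g6p via the rhamnose
branch and 5 via glycolysis/FA synthesis), fully checkable by exhaustive
vertex enumeration at this scale. An optional hydroxy-fatty-acid source
feeds the acyl-CoA pool; under a mixed glucose + fatty-acid feed the
optimum is $35/6$, because the de-novo acyl route keeps running next to
the imported one — a useful reminder that "the FA source supplies the
lipid tail" is a tendency of the optimum, not a constraint. Optional
extras: an isolated 3-reaction reversible loop (to exercise cycle
centring) and duplicated glucose/rhamnolipid transporters (to exercise
symmetric centring). Metabolite formulas are *carbon-skeleton
pseudo-formulas* (carbon counted faithfully; carrier moieties ACP/CoA/dTDP
as single pseudo-elements Q/R/D) so the native network passes the balance
check by construction — they are bookkeeping devices, not chemistry.

`synth_expression()` emulates a wild-type vs transposon-mutant design:
log-normal $\theta$ with log-scale noise $\sigma = 0.25$ in both groups
and a planted $+\delta = \ln 2$ shift on chosen genes in the mutant group
only, 40 samples per group, 200 genes by default. Planted genes are wired
to the duplicated transporters, and each wired reaction's upper bound is
capped at **80% of its unconstrained geometric flux**, so the
$\varphi$-scaled bound binds in both directions and group differences
become visible as flux differences — without a binding cap the
integration rule would be phenotypically silent and nothing downstream
would be testable. Because total uptake is held by the uncapped twin
transporter, only the wired pairs shift between groups; reactions wired
to null genes keep constant flux, which is what makes the
false-positive/recovery contrast sharp.

What the generator does **not** emulate: genome-scale dimensionality
(thousands of genes arrive only via a stress-scale option), realistic
microarray noise structure (probe effects, batch effects, gene–gene
correlation), partial GPR coverage, or growth–production trade-offs.
Passing the recovery tests therefore demonstrates that the pipeline's
machinery is correct and well-calibrated under its stated model, not that
real transcriptomes will yield equally clean separations.

## Problem sizes and reproducibility

The test-suite and acceptance-script study sizes are: the full toy (33
reactions) for all LP properties; vertex enumeration on a reduced toy (21
reactions, 2 degrees of freedom, 840 candidate vertices); 50 seeds of the
40 + 40 × 200-gene recovery design; and 100 seeds of the matching null.
These sizes keep a complete run in the minutes range on one core while
leaving the stochastic estimates tight (binomial SE ≈ 2–4%). Every
stochastic stage takes an explicit integer seed, and batch/pipeline runs
write a log with package version, seed and solver tolerance; rerunning a
study with the same configuration reproduces all numeric artifacts
byte-for-byte.

## Known limitations

* The built-in simplex is dense and single-threaded; genome-scale models
  (thousands of reactions) will solve, but geometric FBA's many FVA
  subproblems make it slow there. The `solve_lp()` contract is the
  intended seam for plugging in an industrial engine.
* Elemental balance checking requires formulas; grafted reactions whose
  new metabolites lack them are only ever "unchecked", by design.
* The condition-specific optimum responds to expression only through
  binding bounds; silent $\varphi$ scalings are not reported as such.
* Pathway attribution divides realised production flux into each
  reporter-substrate pool; it is a bookkeeping of the returned (unique,
  centred) solution, not a causal decomposition over alternate optima.
* No dynamic FBA, no gap-filling, no thermodynamic ($\Delta G$)
  annotation, no pathway-enrichment statistics beyond carrying subsystem
  annotation onto DAR rows.
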