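---
title: "Methods: constraint-based target screening with gemscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based target screening with gemscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemscreen)
```

# The model and its assumptions

A genome-scale metabolic model (GEM) in `gemscreen` is a stoichiometric
matrix $S$ (metabolites $\times$ reactions), flux bounds $l \le v \le u$, a
boolean gene–protein–reaction (GPR) rule per reaction, and a biomass
objective reaction whose flux proxies proliferation. Flux balance analysis
(FBA) solves

$$\max_v \; v_{bio} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u.$$

Two conventions matter throughout:

* **Steady state applies to every metabolite.** Exchange with the
  environment is represented by explicit single-metabolite boundary
  reactions, never by exempting metabolites from the balance. This keeps
  metabolic-task constraints expressible as plain bound overrides on
  exchange and sink reactions.
* **Default bounds** when a file omits them are $(0, 1000)$ for
  irreversible and $(-1000, 1000)$ for reversible reactions — the
  conventional large-but-finite box that keeps every LP bounded. Flux units
  are arbitrary but must be consistent within a model.

## The LP core

No dedicated linear-programming package is assumed; `lp_solve()` is a
bounded-variable two-phase primal simplex written for exactly the problem
shape FBA produces (equality mass balance plus box bounds, often highly
degenerate because most right-hand sides are zero). Numerical choices:

* feasibility tolerance $10^{-9}$; reported objectives are compared at
  $10^{-6}$;
* nonbasic variables sit at a bound; bound flips avoid basis changes;
* the basis inverse is maintained by product-form updates with
  refactorization every 60 pivots;
* the pivot rule is Dantzig's, falling back to Bland's rule after a run of
  degenerate steps longer than $2(n+m)$, which guarantees termination on
  the degenerate systems FBA generates;
* every optimal solution is re-verified on return: steady-state residual
  $\le 10^{-6}$ and bound violations $\le 10^{-9}$, else an error.

The test suite cross-checks the solver against an independently assembled
formulation of the same constraints solved by a second implementation
(`pracma::linprog`) on dozens of random models.

# Gene essentiality

`essential_genes()` knocks out each gene, zeroes the bounds of every
reaction whose GPR evaluates false, and re-maximizes biomass. A gene is
essential when knockout growth falls below `threshold` $\times$ wild type.
The default threshold is $10^{-3}$: "the cell fails its growth objective"
reads as growth indistinguishable from zero at LP tolerances, and any ratio
in $[10^{-6}, 10^{-1}]$ gives identical results on the synthetic models
because knockouts there either leave growth intact or drive it exactly to
zero. The threshold is config-exposed for real models where partial growth
defects occur.

## Logic transformation (LTM)

For fast scans the model is first rewritten so each reaction carries exactly
one gene label. Each GPR is converted to disjunctive normal form (DNF); a
reaction with $d$ disjuncts becomes $d$ parallel duplicates, labeled either
by a single gene or by a composite pseudo-gene (an AND-conjunction whose
knockout is triggered by any constituent). Pure duplication would multiply
capacity, so duplicates share the source reaction's bounds through a
capacity-coupling pseudo-metabolite: each duplicate co-produces one unit per
unit flux and a single spontaneous drain with the original bounds consumes
it, making the summed duplicate flux obey the original box. This preserves
the wild-type optimum exactly, which the suite asserts at $10^{-6}$ along
with per-gene knockout equivalence between the LTM route and direct GPR
evaluation.

DNF can explode combinatorially, so expansion is capped (`max_disjuncts`,
default 64); an oversized rule is left unexpanded and flagged, and knockouts
fall back to direct evaluation for that reaction — degraded speed, identical
results.

Consensus essentiality across an ensemble reports two tallies, because a
gene absent from some member models is ambiguous: `fraction` counts absence
as non-essential (over all models) while `fraction_present` conditions on
the models carrying the gene. The consensus set uses `fraction == 1`.

# Ensemble comparison and merging

The distance between two models is the Hamming distance on reaction-id
sets, $|R_1 \triangle R_2|$ — a true metric, which the tests verify
(symmetry, zero diagonal, triangle inequality). Clustering is agglomerative
(`stats::hclust`) on that matrix, cut into two groups at the top split.
Design choices where the method is genuinely open:

* **Linkage** defaults to complete: reaction-presence clusters in patient
  cohorts appear as compact blocks, and complete linkage avoids the
  chaining that single linkage produces on noisy presence vectors. Average
  and single linkage are selectable.
* **Ties** (equal distances) are resolved by `hclust`'s deterministic
  agglomeration order, so repeated runs on the same matrix give the same
  partition; a fully degenerate (all-equal) matrix yields an arbitrary but
  reproducible 2-split.
* Distances are not normalized before clustering; models in one cohort
  share a reaction namespace, so raw counts are comparable.

Merging takes the union of metabolites, reactions and genes; a shared
reaction id must have identical stoichiometry (anything else is a fixture
error and aborts with the offending id), merged bounds are the widest
member interval, and merged GPRs are the OR over distinct member rules —
a reaction is available if any patient context supports it. If member
objectives disagree, the most frequent objective id wins with a warning and
the minority ids remain ordinary reactions. Components are sorted
canonically so merging is order-invariant. Two consequences are asserted as
properties: merged wild-type growth dominates every member's, and a gene
essential in the merged model (zero-growth reading) is essential in every
member — each member's feasible flux region embeds in the merged one by
zero-extension.

# Metabolic-task toxicity screening

A task asks: can the model produce specified outputs from specified allowed
inputs? `check_task()` closes every boundary exchange, opens per-input
uptake columns bounded by the task's uptake interval, adds per-output sink
columns forced into the production interval, and tests LP feasibility. Sinks
are added per task and discarded, leaving the model untouched between tasks.
A `should_fail` flag inverts the verdict (supported for published task
collections that include negative controls; generated batteries default to
`FALSE`). Tasks naming metabolites the model lacks are *untestable* — a
distinct status, never counted as a pass.

"Reactions coupled to a gene" defaults to knockout-consistent coupling (the
reactions disabled when the gene is knocked out), matching the knockout
semantics used on the tumor side; the stricter "every reaction listing the
gene" mode is selectable because published phrasings of this step are
ambiguous. The screen perturbs the intact healthy model once per candidate
(order-independent by construction, asserted in tests), aborts if the
unperturbed model fails its own battery, and marks candidates absent from
the healthy model nontoxic (they cannot perturb it) with an `absent` flag.
The final shortlist is essential $\cap$ nontoxic, sorted by knockout growth
ratio ascending.

# Reporter metabolites and subnetworks

Differential-expression evidence is aggregated over the model's
gene–metabolite topology. The bipartite graph connects a gene to a
metabolite iff some reaction involving the metabolite carries the gene in
its GPR; twenty currency metabolites (water, ATP/ADP/AMP, NAD(P)H pairs,
phosphates, CoA, ...) are dropped first because they connect unrelated
reactions. Matching is by metabolite name, case-insensitive, with
compartment tags stripped and the unicode minus normalized, since currency
lists are published as names rather than ids.

Per gene, the two-sided DE p-value becomes a directional z-score:
for the "up" run, $p_{dir} = p/2$ if the gene is up-changed else $1 - p/2$,
clamped to $[10^{-15}, 1-10^{-15}]$, and $z = \Phi^{-1}(1 - p_{dir})$. The
analysis runs twice (up and down) rather than once signed, so each
direction gets its own ranking. Per metabolite with $k$ scored neighbors,
$Z_{raw} = \sum_i z_i / \sqrt{k}$ is corrected against a Monte-Carlo
background: $n_{background}$ (default 10000) random draws of $k$ gene
scores from the full scored pool (drawn with replacement, cached per
distinct $k$), giving $\mu_k, \sigma_k$ and
$Z_{corr} = (Z_{raw} - \mu_k)/\sigma_k$ with an upper-tail normal p-value.
Whether source pipelines use one- or two-tailed inputs varies; the
directional transform above is the default and the orientation is explicit
everywhere to prevent silent sign flips. Under a uniform null the suite
requires $Z_{corr}$ to be calibrated: mean within Monte-Carlo error of 0,
variance in $[0.8, 1.2]$, empirical type-I error at $\alpha = 0.05$ inside
$[0.03, 0.07]$.

The reporter subnetwork search maximizes the background-corrected mean gene
z over connected gene sets (connected through shared metabolites). No
canonical algorithm exists, so the implementation is a documented
deterministic heuristic: greedy expansion from the top-scoring gene,
followed by simulated annealing (add/drop moves preserving connectivity,
geometric cooling from $T=1$ by $0.95$ to $0.01$, 60 moves per
temperature), keeping the best set seen. Acceptance is planted-signal
recovery, not exact output: a planted high-z connected cluster must be
recovered at node-recall $\ge 0.9$ averaged over seeds.

# Cohort statistics

Survival stratification keeps patients with vital status "dead", computes
tertile cut points with the linear-interpolation (type-7) quantile rule,
and takes *strictly* below / above the cuts, discarding the middle tertile
— two groups with a real survival gap rather than a mean split.
`simple_de()` is deliberately a stand-in: a per-gene Welch t-test on log2
expression with $\log_2 FC = \bar{x}_{high} - \bar{x}_{low}$, provided so
synthetic runs are self-contained. When an external DE table is supplied
the pipeline never recomputes it; the contrast orientation is a required,
explicit setting, and with the default high-vs-low orientation "up in the
low-survival group" means $\log_2 FC < 0$. Significance is thresholded at
raw $p < 0.05$ by default; the threshold and the column it applies to are
configuration, since upstream multiple-testing policies vary.

Co-expression uses signed Pearson correlation with cutoff 0.99 — read as a
correlation threshold, with a quantile mode (top fraction of pairs)
selectable because "top 1% of pairs" and "$r \ge 0.99$" generally differ.
Communities come from the Walktrap random-walk algorithm (walk length 4,
its customary default) via igraph, and clusters are kept when they have
$\ge 5$ members and mean pairwise correlation $> 0.5$. The 0.5 filter is
computed on the full correlation matrix — against network edge weights it
would be vacuous, as every edge already exceeds 0.99; mean (rather than
minimum or median) intra-cluster correlation is the documented default
reading. Dependency-score validation compares each target's per-cell-line
scores against the mean of all genes' medians with a one-sample t-test.

# Synthetic data: what it emulates, and what it does not

The generators produce the study's input shapes with planted truth:

* `generate_toy_gem()`: independent linear pathways, each fed by an
  exchange (uptake bound 10) and ending in a biomass precursor; chain
  reactions carry single-gene, OR-isozyme, or AND-complex rules in chosen
  proportions. Essentiality truth is known by construction (single and AND
  genes sever their pathway; OR genes have a backup) and is additionally
  verified against an exhaustive knockout oracle in tests.
* `generate_ensemble()`: dispensable dead-end side reactions appended to a
  base model; two archetype presence vectors differing in `separation`
  reactions; members drawn with per-reaction flip noise. Defaults (20
  variable reactions, separation 10, noise 0.05, 30 models) put expected
  noise flips per model (1) an order of magnitude below the archetype
  separation, the regime in which top-split recovery should be exact.
* `generate_expression()`: log-normal expression (gene baselines
  $\mathcal{N}(6, 1.5^2)$, unit noise on log2 scale); survival drawn
  exponential with median 350 days, roughly a poor-prognosis cohort, all
  patients "dead" (the convention the stratifier expects); planted DE genes
  shift by `de_effect` log2 units in the low tertile; co-expression blocks
  share a latent factor with loading $\sqrt{\rho}$, so expected pairwise
  correlation is exactly `block_rho`.
* `generate_tasks()` / `generate_screen_scenario()`: feasible tasks ask
  for a metabolite downstream of an open input; infeasible ones demand an
  output from the wrong pathway (pathways are independent chains, so no
  route exists). The screening scenario shares pathways between tumor and
  healthy models: shared-pathway essentials are planted toxic,
  tumor-private essentials planted nontoxic.
* `generate_dependency_matrix()`: essential genes
  $\mathcal{N}(-1, \sigma^2)$, others $\mathcal{N}(0, \sigma^2)$, per cell
  line.

These fixtures are deliberately simple: linear, loop-free pathways, no
batch effects, no censoring, no count noise, and nothing like the
thousands-of-reactions topology of a real tissue reconstruction. Passing
tests therefore demonstrate correctness of the algorithms and their
contracts — not that a real cohort would yield any particular gene list.
Real-data numbers additionally depend on inputs (cohort expression, curated
patient models, a curated task spreadsheet) that must be supplied to the
same entry points.

# Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately small
scale, chosen so the full planted-truth recovery remains exact and quick:
toy models of 2–4 pathways (≤ 30 reactions), ensembles of 8–30 models,
expression matrices of a few hundred genes by ≤ 120 samples, task
batteries of ~12 tasks, and 10000 Monte-Carlo background draws for
reporter scoring. All stochastic stages take explicit seeds; the pipeline
derives per-stage seeds deterministically from one master seed, and rerunning
with the same configuration reproduces outputs exactly (asserted on
manifest checksums).

# Known limitations

* The simplex is dense; it is comfortable at the hundreds-of-reactions
  scale this package targets but is not tuned for full human
  reconstructions (~10k reactions). The module boundary (`lp_solve()`)
  is the place to swap in a sparse solver.
* SBML support covers the constraint-based subset (species, reactions,
  fbc bounds, gene associations, fbc objectives); kinetic laws, units and
  annotations are ignored on read and absent on write.
* `simple_de()` is not a count-model DE method and should not be used on
  raw counts; supply an external DE table for real data.
* Task semantics cover input/output bounds and the `should_fail` flag;
  richer fields of published task spreadsheets (allowed-reaction lists,
  flux equalities) are reported as unsupported rather than silently
  dropped.
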