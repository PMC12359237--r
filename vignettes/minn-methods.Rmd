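---
title: "Hybrid mechanistic/neural flux prediction: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid mechanistic/neural flux prediction: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minn)
```

## The problem

Constraint-based models of metabolism describe what a cell *could* do: any
flux vector `v` with `S v = 0` (steady state over the stoichiometric matrix
`S`), within reaction bounds, is admissible, and flux balance analysis (FBA)
selects one by optimising an objective such as biomass production. Omics
data describe what the cell *is* doing, but connect to fluxes only
indirectly. This package implements a hybrid estimator that learns the
omics-to-flux map from data while penalising departures from the FBA
constraint set, so its predictions are simultaneously data-faithful and
metabolically plausible.

Two facts shape the design. First, reference flux sets estimated by
isotope-labelling MFA on small core models generally do **not** lie inside
the solution space of a genome-scale model — a full reconstruction must
divert precursors to biomass components the core model ignores — so the
data-driven and mechanistic objectives genuinely conflict and their balance
must be managed, not assumed away. Second, fluxomics datasets are tiny (tens
of samples), so model selection needs a strict nested protocol to avoid
optimistic bias.

## Model and training

All learning happens over a *split* model (`split_reversible()`): each
reversible reaction becomes a forward/reverse pair with non-negative fluxes,
the reverse column negated. Uptake through an exchange reaction is then the
`_rev` direction with positive sign. The estimator is a single-hidden-layer
ReLU network (`nn_forward()`), `V0 = relu(X Wh + bh) Wout + bout`, followed
by the *mechanistic layer* (`mechanistic_refine()`): `k_iter` explicit
gradient-descent steps on

```
L_FBA(V) = (1/m)||S V||^2 + (1/nin)||relu(Pin V − Vin)||^2 + (1/n)||relu(−V)||^2
```

with `m` metabolites, `nin` measured input bounds, `n` split reactions. The
step `V ← V − lr_mech ∂L_FBA/∂V` is unrolled and differentiated exactly in
the backward pass: the Hessian of `L_FBA` is piecewise constant
(`(2/m) S'S + (2/nin) Pin' D1 Pin + (2/n) D2` with ReLU activity masks `D1`,
`D2`), so reverse-mode propagation through the loop is a short recursion
rather than an autodiff tape. Unit tests verify the gradient against central
finite differences to below `1e-5` relative error, both for the layer alone
and end-to-end through the network.

The data loss is the normalized error `NE = ||Pref V − Vref|| / ||Vref||`
per sample, averaged over the batch. We read the displayed definition as a
ratio of Euclidean norms; since the literature source for the metric leaves
room for an element-wise reading, `data_loss(mode = "elementwise")` provides
that variant, but the norm ratio is the default and is what every reported
number uses. Batch aggregation is the mean (not the sum), so learning rates
transfer across batch sizes.

Training (`minn()`) uses Adam with decoupled weight decay on the two weight
matrices only, fan-in-scaled Gaussian initialisation with zero biases,
inverted dropout on the hidden activation, and full-batch updates by default
— with a few tens of chemostat samples there is nothing to gain from
mini-batching. Feature standardisation is fitted on the training fold only;
targets are never scaled because NE is scale-free. Everything is
deterministic given the seed.

### Loss-balancing strategies

`total_loss()` dispatches eight strategies. `mse_base` replaces NE by a mean
squared error; `unbalanced` sums NE and the mechanistic terms directly;
`c_balanced` multiplies the data term by a constant `c` tuned in
cross-validation; `divided` keeps only the data term (the mechanistic layer
still runs forward — this isolates where the regularising effect lives);
`bound` passes the mechanistic sum through a soft hinge, `L ↦ threshold +
factor·(L − threshold)` above the threshold — the source material specifies
a multiplicative penalty beyond a fixed threshold but not its functional
form, and we chose the continuous excess-penalty form because a
discontinuous jump would create an optimisation cliff at the threshold;
`ema` normalises each loss by an exponential moving average of its own
history (decay 0.9, state excluded from gradients, so each term contributes
`L/ema ≈ 1`); `scheduler` interpolates the data/mechanistic weights across
three phases — fixed at 10%/90% for the first 30 epochs, a linear 40-epoch
transition (linearity is our choice; only the endpoints are prescribed), and
a final phase at `final_data_weight ∈ [0.8, 1]`, the single tuned
hyperparameter of that strategy; `scheduler_bound` composes the last two.

The number of mechanistic iterations is exposed rather than fixed: the
formulation displays a single step for clarity, and we default to
`k_iter = 10` with `lr_mech = 0.01`, logging both. Step sizes must respect
the curvature bound `lr_mech < 2/λmax(H)`; the tests verify monotone descent
below that bound, and the trainer aborts with a diagnostic if the loss
overflows.

## The quadratic/linear programming core

No linear-programming backend is available as an R dependency here, so the
package carries its own dense primal-dual interior-point solver
(`solve_qp()`) for convex QPs with equality and box constraints; LPs are the
`Q = NULL` case. Three numerical choices matter. Stoichiometric matrices
have linearly dependent rows (mass conservation), so dependent equality rows
are dropped once by pivoted QR and consistency is checked on the final
iterate. Degenerate optimal faces — ubiquitous in FBA — make the
complementarity gap stall, so the solver tracks the best iterate and accepts
it once it is inside practical LP tolerance and no longer improving.
Finally, accepted iterates are *polished* by alternating projection onto the
equality manifold and the box, which drives `||S v||∞` to ~1e-9 and prevents
error amplification in two-stage solves. Parsimonious FBA pins the
objective at its stage-1 optimum exactly (pinned variables are substituted
out of the program), and only if that stage-2 problem fails — the stage-1
optimum is accurate to solver tolerance, and on tightly constrained models
a slightly-off pinned value can be infeasible — retries with a small band
(1e-4, then 1e-3, of the optimum) before minimising total flux. Accuracy is validated against
brute-force vertex enumeration on random LPs, an independent active-set QP
solver, and frozen reference values for the bundled central-carbon model
(growth rate and pFBA total flux agree with an independent toolbox to 4-7
significant digits).

`fit_to_solution_space()` uses the same engine to find the feasible flux
vector whose projection is closest, in Euclidean distance, to a measured
flux set — the "FBA fit" recalculation of reference data. A measurement-
error weight vector is accepted but off by default, since the procedure we
follow states only minimum Euclidean distance.

## Model reduction

`fva_reduce()` removes reactions whose flux variability span under the
growth medium is below `flux_tol` (default 1e-9, the same tolerance used for
zero-flux classification elsewhere). The FVA is run *without* fixing the
objective at its optimum: requiring optimal growth would delete alternative
pathways that only carry flux in suboptimal states, precisely the states a
data-driven model must be able to represent; an objective-fraction argument
exists for users who want the stricter variant. `fba_sample_reduce()`
instead removes reactions inactive across seeded random simulations (single
gene knockouts × uniform glucose-uptake bounds), using parsimonious
solutions so that arbitrary members of degenerate optimal faces do not
spuriously mark reactions active. Both reducers never remove the objective
or protected exchanges, and drop metabolites left with all-zero rows so the
`1/m` normalisation of the steady-state loss reflects the reduced model.

## The reservoir configuration

`sample_fba_dataset()` draws exchange-flux vectors uniformly within given
ranges, fixes them as tight bound pairs and records the (parsimonious) FBA
solution; `pretrain_block()` trains a network on these pairs into a frozen
FBA surrogate; `train_reservoir_minn()` learns a front network from omics to
the exchange vector through the frozen block (gradients flow through the
block's unrolled refinement and its input scaler, with the block's weights
audited bit-identical before and after); `reservoir_constrain_pfba()` hands
predicted exchanges to pFBA as equality-like bound pairs (±1e-6 by default),
relaxing multiplicatively (1%, 5%, 10%) when the predictions are jointly
infeasible, and failing loudly past that. Parsimonious sampling is a
deliberate deviation from plain FBA sampling: on models with parallel
pathways the FBA optimum is a face, not a point, so the exchange-to-flux
"function" a surrogate must learn is otherwise ill-defined; pFBA selects a
canonical member and keeps the target single-valued. Predicted constraints
should also be clipped to the sampled training ranges before being imposed —
the surrogate has no support outside them, and the package's own evaluation
scripts do so.

## Synthetic data: what it does and does not emulate

`make_toy_gem()` builds a deterministic ~20-reaction network with the
structural features the method cares about: a glucose-like uptake chain, a
capacity-limited short route in parallel with a longer one (so parsimony is
informative), a reversible interconversion, oxygen-dependent energy
production with a free maintenance drain (so exchange fluxes can be fixed
jointly without collapsing the feasible set to measure zero), 1-3 secretion
exchanges, and GPR rules including an isozyme pair. `simulate_omics_dataset()`
mimics a chemostat compendium: wild-type samples across a grid of
glucose-uptake bounds (dilution-rate analogues; default 5 levels over
2-10 mmol·gDW⁻¹·h⁻¹) plus one sample per single-gene knockout at the
mid-range uptake, ground truth from pFBA, omics features as saturating
(Michaelis-Menten-like) or linear functions of weighted random flux subsets
with optional Gaussian noise, and the measured uptakes appearing both as
features and as mechanistic bounds. Feature maps draw only from fluxes that
vary across conditions, with half-saturation constants matched to each
feature's range — constant features carry no signal and make leave-one-out
scaling degenerate. Optionally, per-sample secretion levels are fixed at
random values (regulatory overflow that growth-maximising pFBA cannot
anticipate), and targets can be displaced off the solution space by a
controlled magnitude `δ` along a direction orthogonal to the image of
`null(S)` under the target projection, which guarantees genuine
unreachability and makes `δ` a dial for the data/mechanics conflict.

What passing tests on these fixtures shows: the architecture can recover a
known omics-to-flux map, the losses and protocol behave as specified, and
the reservoir coupling helps exactly when the data contain secretion
behaviour invisible to uptake-only pFBA. What it does not show: performance
on real microarray/LC-MS noise structure, on regulation that violates the
generator's monotone link assumption, or at genome scale (thousands of
reactions), where training cost and the conditioning of `S'S` both grow.

## Evaluation protocol

`nested_loo_cv()` implements the dual-loop protocol: an outer leave-one-out
over samples; within each outer split, an inner 5-fold randomized
hyperparameter search (hidden width, learning rate, dropout, weight decay,
and `c` where the strategy uses it; only the final data weight for the
scheduler), selected by mean validation NE; then retraining on the full
training split and scoring the single held-out sample. R² is computed per
held-out sample across its reference fluxes and then aggregated (mean ± sd
over splits), matching how small-sample flux studies report it; `metric_suite()`
also returns MAE, RMSE and NE, and `steady_state_violation()` reports
`(1/m)||S v||²` as the feasibility proxy. Per-split training-set
fingerprints are stored so leakage is checkable after the fact, and the
whole report is bit-reproducible from its seed. The search ranges default to
wide log-uniform intervals and are overridable via `minn_search_space()`;
at very small sample counts the inner selection is noisy, and narrowing the
ranges (or `search_budget = 1`) gives the stabler protocol-integrity runs
used in the package's own checks.

Problem sizes in the bundled checks are chosen to keep a full run on one CPU
in minutes: ~190-sample synthetic datasets for recovery experiments,
300-record surrogate training sets, 6-8-sample datasets for protocol tests.

## Known limitations

The interior-point solver is dense: fine to a few hundred reactions,
inappropriate for genome-scale FVA (thousands of LPs over thousands of
columns), where a sparse simplex/barrier backend would be needed. On
fully-pinned degenerate instances the two-stage pFBA can return a total flux
slightly above the true minimum (the objective band absorbs solver error).
The split representation admits futile forward/reverse cycles that the
steady-state term cannot see; parsimonious solutions avoid them, but network
predictions may carry small cycle components that only the data term
penalises. And the `e_coli_core` copy shipped with the package is a
convenience fixture for pipeline validation, not a substitute for the
genome-scale reconstructions a real study would download and reduce.
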