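---
title: "Surrogate-assisted optimization of in vitro sterilization protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted optimization of in vitro sterilization protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Establishing plant tissue in sterile culture requires killing surface
microorganisms on the explant without killing the explant. Both failure
modes are routinely scored after ~3 weeks of culture as percentages:
contamination frequency (CF, explants showing microbial growth) and
explant viability (EV, explants still alive). Stronger disinfection —
higher sterilant concentration, longer immersion — pushes CF down and,
beyond a point, pushes EV down too. The protocol-design question is a
two-objective trade-off over a small decision space: which sterilant,
at what concentration, immersed for how long.

`sterilopt` models this trade-off from a published factorial screen of
chrysanthemum leaf explants: six sterilants — NaOCl, Ca(ClO)~2~,
HgCl~2~, H~2~O~2~, AgNO~3~ and colloidal nano-silver (NS) — each
crossed with five concentrations (the zero-dose control included) and
three immersion times. The screen's treatment means and standard
errors are embedded in the package (`load_screen_tables()`, 90
interaction cells). The pipeline is:

1. **Reconstruct** a replicate-level dataset from the printed means and
   SEs (`reconstruct_records()`).
2. **Train** one multilayer-perceptron surrogate per response by
   Levenberg–Marquardt (`train_mlp()`, `fit_surrogates()`).
3. **Optimize** each sterilant's concentration × time box with an
   elitist non-dominated sorting genetic algorithm
   (`nsga2_evolve()`, `optimize_experiment()`).
4. **Select** the compromise protocol nearest the ideal point
   (`select_ideal()`).
5. **Rank** input importance by variable sensitivity ratios
   (`variable_sensitivity()`).

## The data generator: what it emulates and what it cannot

The screen reports, for every treatment cell, `mean ± SE` over three
sub-set scores. The generator treats each nonzero-dose cell as one
treatment and emits `replicates = 3` records per treatment, drawn from

$$ y_{ij} \sim \mathrm{Normal}\!\left(\mu_i,\; s_i\sqrt{3}\right), \quad
   \text{clipped to } [0, 100], $$

where $\mu_i$ and $s_i$ are the printed mean and SE: the SE of a mean
of three sub-sets implies a per-sub-set standard deviation of
$s_i\sqrt{3}$. All eighteen zero-dose cells print the identical outcome
(CF 100, EV 0, SE 0) at every immersion time, so they collapse to one
pooled control treatment with all six dose inputs at zero and the time
input at the modal mid level (10 min) — at zero dose the time carries
no information. That gives 72 + 1 = 73 treatments × 3 replicates = 219
records, the dataset size the original study quotes, splitting 165/54
at the default 75 % training fraction (`ceiling(0.75 × 219) = 165`).

Two features of real screen data are deliberately *not* emulated:
(i) the integer-valued nature of scored proportions (counts out of a
fixed number of explants) — the generator is Gaussian with clipping;
and (ii) any correlation between CF and EV errors within a replicate.
Consequently, passing fit statistics here demonstrate that the
training and evaluation machinery recovers a noisy tabulated response
surface; they are not evidence about organisms or about laboratory
reproducibility.

A consequence worth stating plainly: with SE-calibrated noise the test
partition's labels themselves carry noise of roughly 4–6 percentage
points RMSE. An oracle that predicts every true cell mean exactly
scores a median test RMSE near 5.0 (CF) and 6.3 (EV) over seeded
reconstructions. Published fit statistics computed on the original
(unavailable) replicate data can therefore sit at or below the noise
floor of any reconstruction, and a fitted model's error here is bounded
below by that floor plus its estimation error. The package reports raw
metrics and makes no attempt to tune the generator toward published
values.

## The surrogate: one network per response

Each surrogate is a single-hidden-layer perceptron with hyperbolic
tangent sigmoid hidden units and a linear output,

$$ \hat y = b_0 + \sum_{j=1}^{m} w_j \tanh\!\Big(\sum_{i=1}^{7}
   W_{ji}\, x_i + b_j\Big), $$

over seven inputs: the six dose columns (only one nonzero per record)
and immersion time. One network is trained per response; CF and EV
never share weights. Inputs and the target are affinely scaled to
$[-1, 1]$ on the training extremes (`scale_fit()`), which keeps the
tanh units out of saturation at initialization; predictions are
inverse-scaled back to percent and left *unclipped* for metric
computation, clipping to $[0, 100]$ being applied only inside the
optimization objectives.

Training minimizes the mean squared residual by Levenberg–Marquardt:
steps $\Delta\theta = -(J^\top J + \lambda I)^{-1} J^\top r$ on the
flattened parameter vector, with the residual Jacobian assembled from
backpropagated derivatives. A step is accepted only if the training
loss decreases (then $\lambda \leftarrow \lambda/10$); otherwise
$\lambda \leftarrow 10\lambda$ and the step is retried. Defaults
(`lm_control()`): $\lambda_0 = 10^{-3}$, ceiling $10^{10}$, at most
1000 accepted epochs, gradient tolerance $10^{-7}$, four random
restarts with weights initialized uniformly in $[-0.5, 0.5]$.

Two stabilizers proved necessary on this data and are defaults:

* **Early stopping** (`val_frac = 0.2`, `patience = 6`): a fifth of the
  training records are held out per fit; the returned weights are the
  best-validation snapshot, and a run stops after six accepted steps
  without validation improvement. Without it, fully converged LM fits
  of the noisy reconstruction intermittently develop extrapolation
  spikes (test RMSE outliers of 20–40) that corrupt both architecture
  selection and Pareto fronts. This is the classic guard used by the
  standard neural-network toolboxes this trainer mirrors. Set
  `val_frac = 0` for the pure LM contract (the convergence tests do).
* **Architecture selection by internal cross-validation**
  (`select_architecture()`): candidate hidden-layer sizes — by default
  the field's rules of thumb around $n = 7$ inputs and
  $K \approx 165$ training pairs, i.e. {3, 5, 7, 10, 14}; the pipeline
  searches {3, 7, 14} — are scored by 3-fold cross-validated RMSE
  *inside* the training partition. A single 80/20 fold proved too
  noisy (±1 RMSE on a 33-record fold) to rank sizes reliably. The test
  partition is never consulted.

Fit quality is reported per partition as the coefficient of
determination $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ and
$\mathrm{RMSE} = \sqrt{\sum(y-\hat y)^2 / n}$ (`evaluate_mlp()`).
On a zero-variance target $R^2$ is undefined and reported `NA` with a
warning; negative test $R^2$ is possible and reported as computed.

## The optimizer

`nsga2_evolve()` is a from-scratch elitist NSGA-II over a
two-variable box (concentration, time):

* **Fast non-dominated sorting** into fronts, with ranks; verified in
  the test suite against a brute-force pairwise-dominance oracle.
* **Crowding distance** with infinite boundary distance and
  per-objective normalized neighbor gaps; zero-range objectives
  contribute nothing.
* **Binary tournament** on (rank, crowding), first-drawn on full ties.
* **Simulated binary crossover** ($\eta_c = 15$, $p_c = 0.9$) and
  **polynomial mutation** ($\eta_m = 20$, $p_m = 0.5$ per gene for the
  two-gene decision) — the canonical real-coded operators; children
  are clipped to the box.
* **Elitist replacement**: parents and offspring merge, fronts fill
  the next population, the split front truncated by descending
  crowding.

Defaults are population 100 for 100 generations; on these smooth
two-variable surrogate landscapes the front is visibly converged well
before that. An external archive of all non-dominated points ever
evaluated is kept, and its hypervolume (against the worst point of the
initial generation) is recorded per generation — a non-decreasing
sequence by construction, asserted in tests.

The objectives minimize $(\widehat{CF}, -\widehat{EV})$ with both
predictions clipped to $[0, 100]$; for each experiment the chosen
sterilant's dose occupies its input column, the other five doses are
pinned to zero, mirroring the one-sterilant-per-row structure of the
screen. Time bounds default to the experiment's own printed range
(`time_bounds = "experiment"`); `"global"` widens every experiment to
the pooled 2.5–15 min range, since the original study's reported
optima are not all inside their per-experiment ranges and its actual
bound convention is not recoverable from the text.

## Compromise selection and sensitivity

The ideal point is the observed best of each objective over the full
reconstructed dataset — (CF 0, EV 100) — and the selected protocol
minimizes the squared Euclidean distance
$(CF - 0)^2 + (EV - 100)^2$ on the front. No rescaling is applied:
both objectives are percentages on the same natural scale. Ties break
toward lower predicted CF, then shorter immersion time (cheaper, less
tissue stress), then lower concentration, making the selection
invariant to the ordering of the front.

Input importance uses the exclusion reading of variable sensitivity:
the baseline network's RMSE over all 219 records is compared with that
of a same-architecture network retrained with one input column
removed (VSE); the ratio VSR = VSE / baseline ranks the inputs
(rank 1 = most important). An alternative reading — substituting the
column mean into the fitted baseline network without retraining — was
evaluated and rejected: it pushes off-manifold dose combinations
through the network, inflating VSR far beyond the published magnitude
band and demoting immersion time to last. Note that under the
exclusion reading the pooled-control encoding makes each sterilant's
column highly informative (removing it merges that experiment's dose
rows with the zero-dose control), so immersion time does not
consistently rank first here even though the published analysis placed
it first; the published VSE/VSR procedure is not specified precisely
enough to reproduce its values, and only ranking-level structure
(e.g. AgNO~3~ ranking last) is recovered robustly.

## Numerical choices and degenerate inputs

* Seeds: every stochastic stage draws from an explicitly derived child
  seed (`derive_seed()`, kept below $2^{31}$); no global RNG state
  leaks (`with_seed()` restores the caller's stream).
* The split resamples from derived seeds until every input dimension's
  test range lies inside the training range (interpolation, not
  extrapolation), with a bounded retry budget and an error naming the
  offending dimension on exhaustion.
* Zero-range scaler dimensions map to 0 and invert to the constant.
* Singular LM normal equations fall back to damping increases; a fit
  that cannot decrease the loss below the damping ceiling stops and
  reports its reason (`state$stop_reason`).
* Crowding-distance and hypervolume computations treat duplicated
  points consistently (zero distance, zero added volume).

## Problem sizes used by the shipped checks

The test suite and the acceptance script reproduce the headline
numbers as medians over 10 seeded replications of the full pipeline
(reconstruct → split → architecture search over {3, 7, 14} → train →
optimize NaOCl), with NSGA-II at population 100 × 100 generations; the
property checks (sorting oracle, Schaffer front recovery, Jacobian
versus finite differences, grid-oracle optimum recovery) run at the
sizes stated in their test names' expectations. These sizes were
chosen as the smallest at which the medians are stable across master
seeds.

## Known limitations

* The reconstruction is the only data: nothing here validates the
  surrogates against laboratory measurements. The original study's
  reported statistics, optima and wet-lab validation outcomes ship as
  comparison fixtures (`reported_benchmarks()`) and never enter any
  computation.
* Percentage responses are modeled with Gaussian noise and clipping,
  not binomial counts; SEs of 0 produce exact replicates.
* Single-hidden-layer networks without weight regularization are the
  modeled family; deeper networks, Bayesian regularization and
  alternative trainers are out of scope.
* The optimizer handles box constraints only; no constraint domination
  beyond the bounds.
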