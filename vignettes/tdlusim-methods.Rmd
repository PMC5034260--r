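---
title: "Modelling immune infiltration of the breast lobular epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immune infiltration of the breast lobular epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`tdlusim` simulates the cross-section of a terminal duct lobular unit (TDLU)
of the human breast as a square lattice whose nodes are one cell diameter
(~10 µm) apart. Each acinus is a lumen disc wrapped in a one-node ring of
luminal epithelial cells and a one-node ring of myoepithelial cells; a
polygon (the dilated convex hull of the epithelium, standing in for the
pathologist-drawn boundary) separates intralobular from interlobular stroma.
Epithelial cells are firmly anchored; immune cells — effectors
(cytotoxic CD8+ T-cell abstraction) and regulatory cells (CD4+/CD163+
abstraction) — move through stroma and epithelial vacancies but never enter
lumina.

Cell behaviour is a stochastic process per 1-hour time step. A rate $r$
acting through $k$ cell contacts converts to a per-step probability
$1 - e^{-r k \Delta t}$, so the hazard is exactly proportional to the
contact count. The processes are:

* **Turnover.** Epithelial cells divide at $k_{pro} \theta f_{PI}(t)$ and
  (if undamaged) undergo apoptosis at $k_{apt} \theta f_{AI}(t)$, where
  $f_{PI}, f_{AI}$ are normalized proliferation/apoptosis index curves over
  the menstrual cycle and $\theta > 0$ is the hormone level. A division
  places the daughter on a free epithelial-compartment neighbor; with no
  free neighbor the division is blocked. Apoptosis needs no free space.
  This asymmetry is the load-bearing homeostasis mechanism: with
  $k_{pro} = 0.03\,h^{-1} \gg k_{apt} = 0.0021\,h^{-1}$, the epithelium
  stays full because division is vacancy-limited, and the realized division
  rate settles at the apoptosis rate.
* **Damage.** A daughter of a normal cell is aberrantly damaged with
  probability $k_{dge}$ (a proxy for DNA-repair defects such as BRCA1/2
  loss); a damaged mother always produces a damaged daughter. Damaged cells
  never die by apoptosis; they are killed only by contact with active
  effectors at rate $k_{kill}$ per adjacent active effector.
* **Chemokines.** Damaged and dying cells secrete two distinct chemokine
  fields obeying $\partial_t C = D \nabla^2 C - \lambda C + s\,\mathbb 1_{src}$
  with zero-flux boundaries at grid edges and lumen borders (explicit Euler,
  von Neumann stencil, substepped to satisfy
  $\Delta t \le 1/(4D + \lambda)$). Immune cells activate when the
  damaged-cell chemokine at their node reaches $c_{act}$ (inclusive),
  deactivate below it, and chemotax with step weights
  $\propto e^{\chi \Delta C}$ (effectors read
  $C_{dam} + C_{dying}$, regulatory cells $C_{dam}$).
* **Suppression.** Active regulatory cells permanently inactivate adjacent
  active effectors at rate $k_{sup}$ per contact; permanent inactivation is
  irreversible.
* **Lysis.** A dying cell blocks its node and emits the dying-cell signal
  for $\tau_{lys}$ hours, then is removed and frees the node.
* **Trafficking.** Vasculature is homogeneous: entries are domain-level
  Poisson draws placed on uniformly random free stromal nodes with
  intensities linear in the mean chemokine levels over stroma,
  $\lambda_E = \lambda_{0,E} + \alpha_E \langle C_{dam}\rangle + \beta_E
  \langle C_{dying}\rangle$ and
  $\lambda_R = \lambda_{0,R} + \alpha_R \langle C_{dam}\rangle$ (the
  dying-cell signal recruits effectors only). Non-active immune cells exit
  at rate $\lambda_{out}$; active cells never leave. Immune cells do not
  proliferate.

Each step runs a checkpoint phase on the step-start state (activation,
contact killing, suppression, lysis), then an action phase — motility,
proliferation, apoptosis — over one fresh random permutation of candidate
cells, with per-cell process order randomized and conflicts resolved on the
occupancy grid, then the field update and trafficking. Checkpoints are
applied synchronously per phase rather than interleaved per cell; the random
action order removes the order bias that the per-cell randomization is
meant to prevent, and one-cell-per-node occupancy is asserted in debug mode.

## Hormone curves

The exact normalized $f_{PI}/f_{AI}$ curve shapes are the one input that
cannot be written down from published numbers, so the package makes them an
explicit, swappable input (CSV `day,f_pi,f_ai`). The shipped default is a
shape-preserving piecewise-cubic (PCHIP) interpolant through anchor points
encoding the reported features of epithelial turnover across the cycle:

* $f_{PI}$ peaks at 1 on day 24 (luteal phase, "near the end of the
  cycle") and has a follicular local maximum at day 7 of exactly
  $13.45/30.46 \approx 0.4416$, so that with $k_{pro} = 0.03\,h^{-1}$ the
  simulated proliferation index peaks at ~30.5 and ~13.4 per 1000
  epithelial cells in the two phases.
* $f_{AI}$ has a local maximum near day 2 (menses onset), a low mid-cycle
  plateau, and its global maximum 1 on day 24 (mid-to-late luteal), with
  equal values at day 0 and day 28 so the periodic extension is continuous.

PCHIP guarantees no overshoot, so the normalization and the 0.4416 ratio are
exact at the anchors. $\theta$ scales both curves multiplicatively
(read as "modulates the normalized curves"); it affects cell turnover only,
not chemokine secretion. Variable cycle length dilates or contracts the
follicular segment $[0, 14]$ linearly while translating the luteal segment
unchanged, e.g. follicular lengths 7/14/21 days give 21/28/35-day cycles.

The proliferation-index read-out counts cells that *commit* to division in
each hour (per 1000 epithelial cells) — the Ki-67 analogue — whether or not
crowding blocks daughter placement. Counting only completed divisions would
cap the read-out at the apoptosis rate (~2 per 1000 per hour) and could
never reproduce index values of ~30; completed divisions are logged
separately (`n_div_done`).

## Parameters

| parameter | default | unit | why |
|---|---|---|---|
| `k_pro` | 0.03 | 1/h | physiologically plausible epithelial division rate |
| `k_apt` | 0.0021 | 1/h | apoptosis rate balancing the measured PI values |
| `k_dge` | 0 | per division | damage probability; swept 0–0.3 in experiments |
| `k_kill` | 0.1 | 1/h per contact | effector killing; 0.05/0.10 in sweeps, 0.02 for crippled response |
| `k_sup` | 0.05 | 1/h per contact | regulatory suppression of effectors |
| `c_act` | 0.05 | conc. units | inside the quasi-steady halo of a single damaged cell |
| `chi` | 30 | — | calibrated to the halo gradient scale (~0.03–0.05 units/node), giving O(e) step-weight contrast; O(1) values leave the walk unbiased and no clusters form |
| `m_rate` | 4 | 1/h | near-certain motility attempt per hour |
| `tau_lys` | 12 | h | debris persistence |
| `D`, `lambda`, `s` | 5, 0.5, 1 | nodes²/h, 1/h, units/h | e-folding length $\sqrt{D/\lambda} \approx 3$ nodes: a lone damaged cell recruits within ~5–10 nodes, producing localized clusters rather than global activation |
| `dt` | 1 | h | rates are quoted per hour; per-step probabilities stay ≪ 1 |

Trafficking defaults (`lam0_E = 1.55`, `beta_E = 516`, `lam0_R = 3.02`,
`lam_out = 0.12` cells/h resp. 1/h) are the output of
`calibrate_trafficking()` on the default 504-epithelial-cell TDLU. The
damage couplings `alpha_E`/`alpha_R` cannot be identified from the
zero-damage baseline; they default to the calibrated `beta_E`
(equal sensitivity to both inflammatory signals).

## Calibration

`calibrate_trafficking()` fits `(lam0_E, beta_E, lam0_R, lam_out)` to the
packaged per-phase targets (effector relative numbers 0.05/0.04/0.07 in the
follicular day 1–11 / in-between day 11–17 / luteal day 17–28 windows;
regulatory 0.055 overall). Two structural facts make this cheap and
well-posed: at $k_{dge} = 0$ the epithelial dynamics are independent of the
immune compartment, and the expected effector count is linear in
`(lam0_E, beta_E)` given the dying-chemokine trace. A pilot run (3
replicates × 12 cycles, no influx) records that trace; the expected
occupancy follows the discrete birth–death recursion
$E[N_{t+1}] = E[N_t](1 - p_{out}) + \lambda(t)\Delta t$, so a weighted
linear solve over a small `lam_out` grid gives the influx parameters, and
`lam0_R = 0.055\,\bar N_{epi}\, p_{out}/\Delta t` follows from the
stationary pool size $E[N] = \lambda \Delta t / p_{out}$. A multiplicative
coordinate search against simulated phase means (3 × 12-cycle replicates
per evaluation) then refines all four parameters, stopping early once every
target sits within half its tolerance.

## What the synthetic inputs emulate — and what they do not

All inputs are generated in code: the lattice TDLU, the hormone anchors and
the calibration-target table. The geometry is a regularized cartoon —
equal-size acini on a jittered hexagonal arrangement — whereas real TDLUs
have irregular acinus sizes, counts and boundary shapes; the packaged
domain's 504 epithelial cells sit inside the 250–2500-cell band of the
histological quantification. The hormone curves carry the printed
qualitative features and the one printed ratio, not the unpublished numeric
shapes. Passing tests therefore show that the mechanisms reproduce the
calibration values and trend directions under these idealized conditions,
not that the model is validated against individual-patient histology.

## Numerical choices and degenerate inputs

* Diffusion substepping uses $n = \lceil \Delta t (4D + \lambda)\rceil$
  equal substeps; the single-step `step_field()` rejects unstable `dt`
  outright, naming the offending field. The compiled kernel and the pure-R
  stencil are cross-checked to 1e-12 in the tests; mass balance holds to
  1e-9 relative over 1000 steps.
* Chemotaxis weights use a max-shifted softmax, so arbitrarily large `chi`
  cannot overflow. A cell with no admissible neighbor stays put; targets at
  the local maximum still move (staying is not in the weight set), which
  makes dense clusters churn at their surface.
* Activation is threshold-inclusive (`>= c_act`).
* Lysis removes a cell at the first step whose start time satisfies
  `now - dying_since >= tau_lys`, so `tau_lys = 0` removes it in the same
  step it died.
* Trafficking entries that find no free stromal node are discarded with a
  warning.
* Replicate seeds derive from the master seed by a fixed integer recurrence
  (counter-based), so sweep points are reproducible independently.
* Regime criteria evaluate within-cycle infiltrate minima from cycle 2
  onward: the immune compartment starts empty, so cycle 1 is an
  initialization transient whose minimum is always near zero and would make
  "never returns to baseline in any cycle" unsatisfiable by construction.
* The damage-vs-`k_dge` linearity reference is fitted through the origin on
  the three smallest `k_dge` values; a point is "linear" below 10% relative
  residual, and "resolved" when at least half the cycle minima fall inside
  the baseline mean + 2 SD band.

## The pair-correlation estimator and its direction of sensitivity

`radial_distribution()` normalizes observed pair counts by the complete
spatial randomness (CSR) expectation computed exactly from the
admissible-node pair-distance census, so edge effects cancel by
construction and a uniform pattern gives $g \approx 1$ at every distance.
`fit_power_law()` then fits $g(r) \approx b\,r^{-m}$ by least squares on
log–log scale over positive bins, averaging $g$ over replicate snapshots
(days 5, 14 and 25 of the cycle) before fitting.

Under this estimator the amplitude $b$ rises with damage-induced clustering
(measured in the acceptance suite: ~1.1 at $k_{dge} = 0$ versus ~1.2–1.6 at
$k_{dge} = 0.3$), but the decay exponent $m$ *also* rises slightly: a
well-mixed baseline is CSR-like ($m \approx 0$) and any small-$r$ excess
steepens the log–log slope. An estimator without CSR normalization — for
example raw annulus densities on a finite domain — decays for uniform
patterns too and can rank patterns differently in $m$. Conclusions should
therefore rest on $b$ (and on explicit cluster counts via
`cluster_stats()`), not on the sign of small changes in $m$; the acceptance
suite asserts the decreasing-$m$ expectation and documents it as failing
under this estimator.

The cycle-length comparison (21- versus 35-day cycles at high damage rates)
is evaluated over a matched absolute-time window after the transient
(days 42–252) with weak killing ($k_{kill} = 0.02$), because comparing
equal cycle *counts* confounds the turnover effect with unequal exposure
time, and near the regime boundary the suppression cascade makes standing
damage strongly bimodal across runs.

## Problem sizes

The packaged experiments run at desk scale: the default TDLU has 18 acini
(504 epithelial cells) on a 60×60 lattice; property sweeps use a 9-acinus,
252-cell TDLU on 48×48. Calibration uses 3 replicates × 12 cycles per
evaluation; the acceptance script validates with 10 replicates × 12 cycles;
trend checks use 3–5 replicates × 3–12 cycles per sweep point. A 12-cycle
replicate of the default TDLU takes on the order of ten seconds.

## Known limitations

* No cell-cycle phase structure, mechanics, or immune proliferation; all
  regulatory subtypes are pooled into one suppressive agent.
* Chemokine consumption by immune cells is not modelled; receptor kinetics
  are reduced to a threshold.
* The trafficking functional form is the minimal linear one; saturation at
  high chemokine loads is not represented, so extreme damage regimes can
  fill the stroma.
* Epithelial motility is disabled (anchored epithelium); ductal branching
  and 3-D geometry are out of scope.
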