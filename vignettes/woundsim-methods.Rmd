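---
title: "A hybrid cell-based/finite-element model of post-burn skin contraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid cell-based/finite-element model of post-burn skin contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundsim)
```

## The model

`woundsim` simulates the contraction of a deep dermal (burn) wound over
weeks of healing. It is a hybrid model: cells are discrete agents, while
signalling molecules, tissue mechanics and fibre bundles are continuum
fields discretised with linear finite elements on a deforming
triangulation of a 120 x 80 micrometre tissue slab with a 40 x 30
micrometre rectangular wound.

The moving parts, per time step of `dt = 0.1` h:

1. **Cell events.** Each macrophage, fibroblast and myofibroblast runs
   memoryless exponential clocks; an event with rate $\lambda$ fires in a
   step with probability $1 - e^{-\lambda \Delta t}$. Mature fibroblasts
   divide at rate $20\,c_{TGF}^2 + 2$ while their contact strain energy
   density is below 0.05, differentiate into myofibroblasts at rate
   $60\,c_{TGF}^2 + 10$ once inside the wound with $c_{TGF} > 0.01$, and
   (myo)fibroblasts die at rate 10 when the contact energy reaches 0.07.
   Macrophages appear on fixed wound-edge entry sites as per-site
   Bernoulli trials (rate 0.04/h) while the local PDGF signal persists,
   and are removed by an exponential clock (rate 0.05/h) that latches on
   once that signal fades. Division moves the mother one radius in a
   uniformly random direction and places the daughter diametrically
   opposite; the daughter matures more slowly than the mother.
2. **Chemistry.** PDGF (initially 1 inside the wound), TGF-beta
   (secreted as a Dirac point source of 2.5 per viable macrophage) and
   tPA (a line source on the wound interface) evolve by
   advection-diffusion. Advection by the substrate velocity is handled
   in ALE form: mesh nodes are material points, so the backward-Euler
   step balances the mass matrices of the previous and current
   configurations and no explicit advection term appears. TGF-beta and
   tPA diffusivities interpolate linearly between a fibrin-rich minimum
   and a fibrin-free maximum.
3. **Mechanics.** Quasi-static Kelvin-Voigt viscoelasticity with
   plane-strain Hooke elasticity ($E = 50$, $\nu = 0.48$) and the
   viscous stress weighted by $\eta$ (default 1). Each (myo)fibroblast
   pulls its surroundings inward through three point forces at the
   midpoints of three equal boundary arcs (magnitudes 8.32 and 33.28 per
   unit length for fibroblasts and myofibroblasts). Plastic forces act
   on element edges with magnitude $Q(\tau) = 33\,(1 - e^{-\tau})$,
   where the exposure time $\tau$ of an element integrates
   $c_{TGF} (1 - \alpha_\rho \rho^c) N_{myo}$; they persist after the
   cells die, which is what makes part of the contraction permanent.
   The outer boundary carries a Robin (spring) condition with
   $\kappa_f = 3$.
4. **Cell motion.** Overlapping cells repel along the net Hertz-contact
   direction with drift speed $\alpha_i |\hat M|$
   ($\alpha_i = \beta_i R^3 / (\mu F_i) = 7.8125$); macrophages
   chemotax up the PDGF gradient and (myo)fibroblasts up the TGF-beta
   gradient with saturating speed
   $\mu_c = v (1 - \alpha_\rho(\rho^f + \rho^c)/2)$, the fibroblast
   response being premultiplied by the collagen orientation weighting
   $(1 - \alpha_\rho\rho^c) I + \alpha_\rho \rho^c \hat\Omega^c$; all
   cells convect passively with the substrate and random-walk with
   weight $\sigma_{rw} = 0.01$.
5. **Fibre bundles.** Fibrin and collagen are symmetric 2 x 2
   orientation tensors whose trace is the density. Fibrin decays under
   tPA ($\dot\Omega^f = -\delta_\rho c_{tPA} \Omega^f$); collagen is
   deposited at each (myo)fibroblast position as a rank-1 tensor along
   its active (non-convective) displacement direction, with prefactor
   $1 - \alpha_\rho(\rho^f + \rho^c)$ clamped at zero.

The wound is tracked materially: the nodes that initially form the
wound interface define a polygon whose shoelace area $A(t)$ gives the
contraction ratio $r = A/A_0$.

## Numerical choices

* **Mesh.** A structured boundary-conforming right-triangle mesh whose
  grid lines include the wound rectangle, mirrored across both axes.
  The wound interface is therefore an exact mesh polyline (the tPA line
  source and the wound polygon are exact), and the stiffness matrix is
  an M-matrix.
* **Positivity.** The transport step uses the lumped mass matrix and a
  lumped Robin term. Together with the M-matrix stiffness this makes
  the backward-Euler operator inverse-positive: concentrations driven
  by Dirac and line sources stay non-negative and the discrete maximum
  principle holds without clipping (a guard clip remains and reports
  through an attribute if it ever trims more than 1e-8).
* **Dirac loads** are P1-consistent: each point magnitude is spread
  over the containing triangle by barycentric weights (walk-located
  with an exhaustive fallback; points outside the hull are snapped to
  the nearest element). Plastic edge forces use the exact midpoint
  weights (1/2, 1/2).
* **Collagen deposition is a projected Euler step.** A unit rank-1
  Dirac increment lumped onto one node exceeds the healthy density
  $1/\alpha_\rho$ within a single step, so each nodal increment is
  rescaled to land at most on the remaining capacity
  $\max(0, 1/\alpha_\rho - \rho^f - \rho^c)$; the saturation behaviour
  of the continuous deposition law is recovered exactly, and the
  wound-average collagen ratio approaches 1 from below.
* **Momentum.** The displacement is solved as a total displacement from
  the initial configuration each step, with the strain rate discretised
  by backward Euler; the mesh then moves by the increment, and the
  substrate velocity is the displacement difference quotient. With
  $\kappa_f > 0$ the operator is symmetric positive definite; a zero
  `kappa_f` raises a rigid-mode error rather than returning garbage.
* **Sparsity reuse.** Mesh connectivity never changes, so sparsity
  patterns and the triplet-to-slot maps are computed once; per-step
  assembly only refills matrix values. A full baseline step costs a few
  tens of milliseconds at the default resolution (`target_edge = 5`
  micrometre, one cell diameter).
* **Mesh tangling** aborts the run with an explicit error; the model
  operates in the small-strain regime (5-10% contraction) and never
  remeshes.

## Parameters the tables leave open

* **Robin coefficient for concentrations.** The parameter table's two
  Robin rows are garbled in the source material. We read both rows as
  "value after the truncated equation reference", giving
  $\kappa = 100$ (concentrations, near-absorbing outer boundary) and
  $\kappa_f = 3$ (mechanics). The alternative reading $\kappa = 0$ is
  untenable: it conserves chemical mass exactly, so PDGF could never
  decay, TGF-beta would accumulate without bound and flood the whole
  domain above the 0.01 differentiation threshold, and the resolution
  and recovery phases could not occur. Both coefficients are plain
  config values.
* **Viscoelastic weight.** $\eta$ has no tabulated value; the default
  is 1 and the sensitivity interface exposes it.
* **Macrophage lifecycle.** Neither the removal rate nor the influx
  geometry is specified. Influx uses the 20 equally spaced material
  entry sites that also carry the initial macrophages (a mesh-resolution
  independent choice; one interface node per site would make the
  influx scale with the mesh). Recruitment stops and the removal clock
  (rate 0.05/h) latches on where the local PDGF concentration falls
  below 5% of its initial wound value. With these choices the
  macrophage count accumulates to a peak as recruitment outlasts
  removal, collapses once PDGF fades at around 110 h, and the TGF-beta
  field — whose dynamics track the macrophage count — peaks near 100 h,
  the timing observed experimentally for TGF-beta in healing dermal
  wounds; we use that timing to identify these otherwise free
  constants.
* **Maturation thresholds** ("some time step threshold"): 50 steps
  (5 h) for mothers and 100 steps (10 h) for daughters; only the
  ordering daughter > mother is prescribed.
* **Initial populations**: fibroblasts at 1 per 100 square micrometre
  over the undamaged region (84 cells); 4 resident macrophages on the
  wound edge, with the inflammatory infiltrate supplied by the Poisson
  influx at 20 fixed entry sites. A large fixed initial cohort would
  make the TGF-beta supply independent of the influx rate and erase
  the documented dependence of contraction on the strength of the
  immune response; immune cells arriving over the first days, rather
  than being present at wounding, is also the biologically expected
  picture. All counts are config-exposed.
* **Chemotaxis regulariser** $\gamma = 0.02$ in concentration-gradient
  units. The governing equations introduce $\gamma$ only as a guard
  against a vanishing denominator, but its size sets the chemotactic
  sensitivity scale: with $\gamma$ far below typical wound-edge
  gradients ($\sim 10^{-2}$) the migration speed saturates and
  fibroblast recruitment becomes independent of the TGF-beta level,
  which contradicts the model's own sensitivity behaviour (a weak
  immune signal is supposed to recruit fibroblasts inefficiently).
  Setting $\gamma$ at the gradient scale keeps migration
  signal-responsive.
* **Collagen orientation weighting.** Taken literally, the fibroblast
  chemotaxis weighting adds $\alpha_\rho \rho^c\, \Omega^c$ with
  $\Omega^c$ in density units ($\sim 10^{-4}$), which annihilates the
  anisotropic term. The default normalises $\Omega^c$ by its trace
  (pure orientation); `literal_collagen_weight = TRUE` restores the
  literal form.
* **Sign of the repulsion drift.** The printed drift
  $\alpha_i \hat M \hat z$ combines a non-positive energy with a
  direction already pointing away from the contact pressure, which
  would make overlapping cells attract; the implementation uses
  $\alpha_i |\hat M| \hat z$ (repulsion), consistent with the model's
  own contact assumption.
* **Differentiation is a wound event.** The biological description
  ("when fibroblasts enter the wound region, they can differentiate")
  is implemented literally: the differentiation clock runs only for
  fibroblasts inside the material wound region. Without this gate the
  +10 constant in the differentiation rate converts every fibroblast in
  the domain within minutes of TGF-beta spreading and the population
  goes extinct.

## What the simulations show, and at what scale

The default configuration reproduces the expected healing choreography: a brief
initial widening of the wound while outside fibroblasts pull on it, a
macrophage pulse that drives TGF-beta to its peak near 100 h,
myofibroblast-driven contraction to a minimal area near day 10-16,
and a partial recovery to a permanently contracted state as the
myofibroblasts die and plastic forces remain, while the wound-average
collagen ratio climbs toward 1.

Test and acceptance runs use the default `target_edge = 5` (one cell
diameter) and horizons of 200-500 h; the ensemble tests use 8-12 runs.
These sizes were chosen so the full suite executes in minutes on a
laptop core while keeping every qualitative regime (inflammation, peak
contraction, recovery) inside the simulated window; they are
deliberately smaller than a publication-grade campaign (a 1210-run
ensemble to 700 h), which the same functions run unchanged by raising
`n` and `horizon`.

The Monte Carlo layer samples substrate stiffness (log-normal around
50, the second parameter read as the SD of the log — with 0.1 that
spans about +-20%, matching the description of a small stiffness range;
batch 2 replaces it by Uniform(23.9, 300)), the fibroblast division
constant (Uniform(1.5, 2.5), replacing the +2), the myofibroblast
apoptosis rate (Normal(10, 0.1), replacing the 10) and the macrophage
appearance rate (log-normal, effectively 0.04). Reversed day-4 areas
($y = \max(x) + \varepsilon - x$, $\varepsilon = 10^{-6}\max(x)$) are
fitted by a two-parameter Weibull via maximum likelihood
(`MASS::fitdistr` on standardised data).

## What the synthetic conditions do not capture

The generator emulates the study conditions themselves (geometry,
parameter tables, input distributions); it is not calibrated to
clinical wound data. Real dermal wounds are three-dimensional, have
irregular shapes, heterogeneous and anisotropic stiffness, epidermal
coverage and vascular regrowth, none of which are modelled. Passing
tests therefore demonstrate faithfulness to the stated model, not
predictive validity for real burns. Contraction magnitudes (5-10%)
apply to the small-scale wound modelled here; clinically, large wounds
contract proportionally more.

## Known limitations

* Concentration units are used as printed and are dimensionally
  inconsistent with the rate thresholds; all comparisons are
  value-for-value.
* The viscous trace term uses the printed 2/3 (3D deviatoric) factor in
  a 2D model.
* Plastic forces are formally defined on every element; in practice the
  exposure time is nonzero only where myofibroblasts have been, so the
  force support follows the wound margin.
* Equilibrium detection (`|dA/dt|` below 1e-3 for 50 consecutive
  steps) is a design definition; stochastic forcing means short runs
  usually end at the horizon instead.
* At most one stochastic event fires per cell per step, with priority
  apoptosis > differentiation > division; multi-event probabilities are
  $O((\lambda\Delta t)^2)$.
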