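---
title: "From fundamental to effective receptor-ligand kinetic constants"
author: "kinetrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fundamental to effective receptor-ligand kinetic constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetrans)
```

## The model

Specific binding of a membrane receptor (the motivating system is the T-cell
receptor and its peptide-MHC ligand) proceeds in three reversible steps:

1. **translational diffusion** brings receptor R and ligand L within reaction
   distance, forming the *encounter complex* RL\* (rates $d^+$, $d^-$);
2. **rotational diffusion** aligns the two molecules into the binding-competent
   *oriented complex* RL (rates $e^+$, $e^-$);
3. **chemical binding** docks them into the *bound complex* C (rates $k^+$,
   $k^-$).

Only the first two steps depend on the dimensionality of the setting — whether
both molecules are membrane-anchored (2D) or at least one is in solution (3D) —
while $k^\pm$ are properties of the protein pair alone. Mass action gives the
coupled ODEs

$$
\begin{aligned}
\frac{d[R]}{dt} = \frac{d[L]}{dt} &= -d^+[R][L] + d^-[RL^*] \\
\frac{d[RL^*]}{dt} &= d^+[R][L] - (d^- + e^+)[RL^*] + e^-[RL] \\
\frac{d[RL]}{dt} &= e^+[RL^*] - (e^- + k^+)[RL] + k^-[C] \\
\frac{d[C]}{dt} &= k^+[RL] - k^-[C],
\end{aligned}
$$

with two conservation laws (receptor and ligand mass) and three step
affinities: $K_D = d^+/d^-$, $E = e^+/e^-$, $K_A = k^+/k^-$. Internally, 3D
concentrations are molar and 2D concentrations are mol/µm², so the 2D
diffusion on-rate carries units µm² mol⁻¹ s⁻¹; `stochastic_simulate()`
converts to molecule counts through Avogadro's number and the reaction volume
or contact area, and the same conversion serves as the display adapter to
molecules/µm².

`simulate_kinetics()` integrates this system with `deSolve::lsoda`
(relative tolerance $10^{-10}$, absolute tolerance $10^{-12}\times$ the
largest conserved total) because the regimes of interest — fast transport
against slow chemistry — are stiff by construction. `equilibrium_state()`
solves the equilibrium in closed form: the three detailed-balance relations
collapse all complex species onto $K_D[R][L](1 + E + EK_A)$, and conservation
then leaves a scalar quadratic in free R whose unique non-negative root is
taken analytically. (An equivalent formulation is a scalar polynomial in any
single species; the quadratic in R avoids root bracketing entirely, which is
why it was chosen.) Off-rates of exactly zero are legal in the integrator —
irreversible limits are useful checks — but rejected by the equilibrium
solver, where intermediate species would have no finite equilibrium.

`stochastic_simulate()` is the exact event-driven counterpart (direct-method
sampling over the six reaction channels, with the bimolecular propensity
$d^+ n_R n_L / (N_A V)$ matching the deterministic term). It exists because
two assay classes — thermal fluctuation and adhesion frequency — watch
*single bonds*, which a deterministic model cannot emulate.

## Effective models: what each assay can see

No assay resolves all five species. Each one imposes a grouping, and the
constants it reports are *effective* constants of the grouped system.
`reduce_to_effective()` implements the four groupings in use, with the
mappings derived by quasi-steady-state elimination:

| Model | Grouping | $k_\mathrm{on}$ | $k_\mathrm{off}$ | $K_a$ |
|---|---|---|---|---|
| PBA (2D) | $\langle RL\rangle = RL^* + RL$ | $k^+ E/(1+E)$ | $k^-$ | $E K_A/(1+E)$ |
| PBB (2D/3D) | RL eliminated | $e^+ k^+/(e^- + k^+)$ | $e^- k^-/(e^- + k^+)$ | $E K_A$ |
| FRET (2D) | $\langle R\rangle = R{+}RL^*$, $\langle C\rangle = RL{+}C$ | $K_D e^+$ | $e^-/(1+K_A)$ | $K_D E (1+K_A)$ |
| SS (2D/3D) | bound vs unbound | $d^+e^+k^+/\Delta$ | $d^-e^-k^-/\Delta$ | $K_D E K_A$ |

with $\Delta = d^-e^- + d^-k^+ + e^+k^+$. The assignments: PBA and PBB are the
two readings of the thermal fluctuation assay (does unbinding carry
de-orientation with it, or do multiple binding/unbinding rounds precede it);
PBB in 3D describes bulk solution FRET; the FRET model describes
single-molecule FRET imaging, whose donor channel cannot separate a free
ligand from a merely encountered one, nor the acceptor channel an oriented
complex from a bound one; SS describes the adhesion frequency assay (2D) and
SPR (3D), which only distinguish bound from unbound.

Three structural consequences drive all five case analyses:

* **PBA off-rate identity**: $k_\mathrm{off} = k^-$ exactly, so the thermal
  fluctuation assay measures the fundamental unbinding constant whenever the
  PBA reading applies, i.e. whenever $k^+ \ll e^-$.
* **FRET on-rate is ligand independent** ($K_D e^+$ contains no binding
  constant), and its off-rate $e^-/(1+K_A)$ *falls* with binding affinity:
  single-molecule FRET cannot report $k^\pm$ at all.
* **FRET and SS 2D affinities differ by exactly $(K_A+1)/K_A$** for matched
  ligand-independent constants, which is both a testable identity and the
  handle by which matched assays determine $K_A$ and the rotational constant
  $E$ (`estimate_rotational_constants()`).

In the FRET row, rotation is the *observable* transition: diffusion is
pre-equilibrated below it (hence the $K_D$ factor in the on-rate) and binding
is pre-equilibrated inside $\langle C\rangle$ (hence the $1/(1+K_A)$ factor in
the off-rate). The single-step on-rate obeys the harmonic relation
$1/k_\mathrm{on} = 1/\mathrm{TL} + 1/\mathrm{RL}$ between its
transport-limited ceiling $\mathrm{TL} = d^+e^+/(d^-+e^+)$ and
reaction-limited form $\mathrm{RL} = K_D E k^+$ (`ss_on_rate_bounds()`); over
a ligand series it approaches TL for fast binders and RL for slow ones, which
is precisely why SPR on-rates look ligand independent while adhesion-frequency
on-rates track $k^+$.

## The reduction oracle

Because the algebra above is the scientific load-bearing wall, it is guarded
numerically: `validate_reduction()` scales the grouped fast steps of a model
$s$-fold faster than its observable step, integrates the full model, projects
it onto the assay observables (`project_trajectory()`), runs the reduced
model with the mapped constants, and reports the maximum deviation of the
bound observable relative to its peak. The deviation must fall like $1/s$; if
a mapping were transcribed wrongly, it would plateau at an O(1) value
instead.

The scaling direction per model was chosen so that the quasi-steady-state
error is the *only* error:

* **PBA** scales $e^\pm$ at fixed $E$: the grouped species is explicit, so
  only the internal rotational equilibration matters.
* **PBB** scales the oriented complex's *exit* rates $(e^-, k^+)$ — the
  mathematically correct small parameter for eliminating RL — which leaves
  all three PBB effective constants numerically invariant while the residence
  time of RL shrinks like $1/s$.
* **FRET** scales $(d^\pm, k^\pm)$ at fixed $K_D$ and $K_A$.
* **SS** scales $(d^\pm, e^\pm)$; its two eliminated intermediates relax in
  series, so the separation factor is normalized against the *sum* of their
  residence times.

One caveat is intrinsic rather than numerical: the SS and FRET reduced models
have no state in which to store intermediate mass, so their deviation bottoms
out at the equilibrium occupancy of RL\* ($\approx K_D[L](1+E)$). The oracle
is therefore run at dilute concentrations ($K_D \cdot \mathrm{total} \sim
10^{-5}$) where that floor is negligible — which is also the regime in which
the single-step description of an assay is legitimate in the first place.
The pre-binding models carry their intermediates explicitly and converge at
any concentration.

## Synthetic assays and their study conditions

Each generator is a pure function of parameters and seed, and its noiseless
limit equals the corresponding model solution — that identity is itself
tested. The emulated readouts, noise models, and reference conditions
(`reference_conditions()`):

* **Thermal fluctuation (TF)**: i.i.d. exponential bond lifetimes at the PBA
  off-rate; no noise model (lifetimes are the raw observable). Reference:
  $k^- = 0.2$ s⁻¹, $10^4$ lifetimes.
* **Adhesion frequency (AF)**: generated *mechanistically* — each test cycle
  places free molecules in the contact area, runs the exact stochastic chain
  for the contact duration, and scores adhesion as at least one bound complex
  at contact end — so the noise is exactly binomial in the cycle count and no
  closed-form readout law is assumed by the generator. The fitter
  (`fit_adhesion_curve()`) uses the small-system immigration-death law
  $p(t) = 1 - \exp\{-\mu_\infty(1 - e^{-k_\mathrm{off}t})\}$, the standard
  analysis convention for this assay. Reference conditions: 3 µm² contact
  area, 400 receptors and 400 ligands (≈130 molecules/µm²; the sparse regime
  where encounter complexes hold <2% of the mass, as the single-step analysis
  assumes), $E = 0.04$, per-receptor encounter rate 0.15 s⁻¹, contact times
  2–20 s, 2000 cycles per point.
* **SPR**: closed-form two-phase 1:1 sensorgram with additive Gaussian noise.
  Reference: reaction-limited 3D constants, analyte at twice the effective
  dissociation constant (so amplitude and rate information are balanced and
  $R_\mathrm{max}$ is identifiable), 120 s association, 240 s dissociation,
  500 samples, noise 1% of $R_\mathrm{max}$.
* **FRET**: deterministic trajectory projected onto the meta-states, channel
  gains, additive Gaussian noise.
* **Ligand panels** (`make_ligand_panel()`): six ligands named after the
  ovalbumin-variant convention, with $k^+$ spanning 1000-fold and $k^-$
  10-fold, both increasing with the potency proxy $1/EC_{50}$ (itself
  spanning 1000-fold); all values synthetic. Imposing those two rate
  fold-ranges fixes the implied $K_A$ fold-range at 100 — the published
  ranges are approximate and cannot all hold simultaneously under
  $K_A = k^+/k^-$, so the generator guarantees the two rate ranges exactly
  and documents the consequence. A log-normal jitter (`jitter_sd`) produces
  randomized panels; surface densities and contact areas have no published
  values and are package defaults, flagged as such.

Problem sizes throughout (20 draws per model for the oracle, 100 seeds for
recovery studies, 2000 stochastic replicates) were chosen so the whole
analysis runs at desk scale in a few minutes while keeping Monte-Carlo error
well below the tolerances being tested.

What passing these tests does **not** show: the generators contain no
photophysics (bleaching, blinking), no instrument drift or bulk
refractive-index artefacts, no mechanical force dependence (catch/slip
bonds), and no spatial heterogeneity — the diffusion step is a well-mixed
rate constant. Conclusions about real data inherit those caveats.

## Inference choices

* **Trend lines** are ordinary least squares in $\log_{10}$–$\log_{10}$
  space, with the *constant* regressed on the *potency proxy*. In this
  orientation the framework's algebra is transparent: an effective constant
  that equals a fundamental one times a ligand-independent factor gives an
  identical slope and an intercept offset equal to the log of that factor
  (the horizontal shift between trend lines in the usual potency-vs-constant
  plot). The AF decomposition is evaluated in its reaction-limited form and
  the SPR one in its transport-limited form — the regimes the off-rate
  agreement and on-rate flatness observations respectively pin down — since
  those are the log-decomposable expressions; `effective_panel()` also
  provides the exact forms.
* **"Much less than"** is operationalized as a ratio of at most $10^{-2}$
  (configurable); no published threshold exists.
* **PBA vs PBB for the thermal fluctuation assay**
  (`case1_tf_model_selection()`): PBA requires $k^+ \ll e^-$. PBB would
  require a single ligand-independent $e^-$ lying above every $k^+/$threshold
  yet below every $k^-$, which fails as soon as one ligand binds faster than
  another unbinds; the verdict reports the feasible interval so the rejection
  is auditable.
* **Rotational constants** (`estimate_rotational_constants()`): matched 2D
  FRET and AF affinities give $K_A = K_{AF}/(K_{FRET} - K_{AF})$ per ligand
  and then $E^{2D} = K_{FRET}/(K_D(1+K_A))$. The difference is
  ill-conditioned for strong binders, so the estimate is flagged invalid when
  the panel's median $K_A \ge 1$; the inversion itself is exact on noiseless
  inputs. $E^{3D}$ follows from the bulk-FRET affinity $E^{3D}K_A$, with an
  optional SPR cross-check when the 3D diffusion affinity is known. With one
  ligand the estimate is returned but flagged as lacking a cross-ligand
  consistency check.
* **Ties** in panel constants are legal; rank-based checks use midranks, and
  zero-variance potency is rejected as a degenerate panel.
* **Transport constants**: the 2D encounter rate uses the classical
  diffusion-limited capture form $2\pi D N_A/\ln(b/a)$ and the SPR transport
  coefficient the Lévêque cube-root law
  $1.282\,(vD^2/hL)^{1/3}$, both pinned by golden regression values; every
  conclusion of the framework uses only their ligand *independence*, which
  holds for any admissible form. $E^{2D}$ defaults to the accepted 0.04; a
  3D default does not exist and is never silently invented.

## Known limitations

The single-step and FRET reduced models cannot represent intermediate mass
(see the oracle caveat above); the effective-constant mappings are
quasi-steady-state results and degrade gracefully, like $1/s$, as the
timescale separation weakens; potency enters only as a panel covariate — no
dose-response model is fitted; and the framework stops at the bound complex:
downstream signalling, force-dependent unbinding and conformational-change
extensions are out of scope.
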