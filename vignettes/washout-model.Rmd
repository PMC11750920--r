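---
title: "A compartmental RC-network model of multi-breath inert-gas washout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental RC-network model of multi-breath inert-gas washout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungwash)
```

## The physiological question

Multi-breath washout (MBW) tests probe the small airways: a subject breathes
a tracer gas (here pure helium) while the resident nitrogen is "washed out",
and the expired concentration is recorded at the mouth. In healthy, uniformly
ventilated lungs the alveolar portion of each expirogram is flat; structural
asymmetry between parallel lung units produces a rising alveolar plateau --
the phase-3 slope, $S_3$ -- through *diffusion-convection-interaction
dependent inhomogeneity* (DCDI): where convective and diffusive transport are
comparable, unequal sister subtrees exchange gas diffusively across their
common bifurcation (Pendelluft), and the resulting inter-unit concentration
difference leaks into the expired signal.

`lungwash` reproduces this mechanism with a deliberately reduced network
model whose transport equations map one-to-one onto an electrical RC
circuit: compartment gas volume is a capacitance, a diffusive link between
neighbours is a resistor carrying Fick's law, and the directed convective
transfers are phase-switched controlled current sources, with the tracer
mole fraction playing the role of the node voltage. The mapping means the
whole simulator could, in principle, be realized as hardware and run in
real time; here it is solved numerically.

## Model geometry

The airway tree follows the regularized dichotomous morphometry of the
classical 24-generation lung model, measured at a reference volume of
4800 ml and rescaled to the 3000-ml resting adult lung:

* The mean alveolar diameter follows the empirical cube-root relation
  $d_\mathrm{alv} = 1.54\times10^{-3}\,V_L^{1/3}$ (volumes in ml, result in
  cm), giving 222 µm at 3000 ml.
* The reference tree plus its alveoli holds 3368 ml; the 368-ml excess is
  removed by shrinking the airway diameters and lengths of generations 4-23
  by a single linear factor $s = (1 - 368/\sum_{4}^{23} 2^z \frac{\pi}{4}
  d^2 l)^{1/3} = 0.917$. Generations 0-3 and the alveoli are left unscaled.

The network lumps this tree into 251 well-mixed airway units (AUs):

* a **trachea unit** (TU): generations 0-3 as a serial tube of 10 identical
  compartments (fewer compartments visibly increase numerical smearing of
  the inspired front);
* a **segment unit** (SU): generations 4-23 in six *areas* $a = 0..5$, area
  $a$ holding $2^a$ parallel *elements*, each a serial chain of
  $m_\mathrm{AU}(a) = (1, 10, 1, 1, 1, 6)$ compartments. One SU compartment
  aggregates the $2^{z-a}$ anatomically identical airways of its generation
  that fall into its element.

Two reconstruction choices deserve a note, because the classical
per-generation source measurements are not embedded verbatim:

* **Distal morphometry.** The commonly reproduced literature values for
  generations 4-23 disagree with the model's printed per-element geometry
  by up to ~2 % on a few rows. The embedded base table therefore back-solves
  lengths and diameters from the printed per-element length and aggregate
  cross-section columns (dividing out $s = 0.917$), which makes every
  derived quantity -- the scaling factor, the 144.6-ml dead space, the full
  Peclet and resistance table -- self-consistent to well under 1 %.
* **Alveolar distribution.** The alveoli-per-generation counts are likewise
  reconstructed, from the printed decrements of the peak entrance flows
  (flow is generated by synchronous alveolar volume change, so the flow
  lost between successive compartments is proportional to the alveoli they
  carry). The total alveolar count is calibrated so that the unscaled
  reference model reaches its stated 3368 ml, which lands at
  $2.98\times10^8$ alveoli and 17.0 alveoli per terminal sac -- both
  squarely at the classical anatomical values, a strong consistency check.
  Note that the *scaled* model volume is 3000 ml for any total alveolar
  count, because the scaling step absorbs whatever deficit remains; the
  reference volume is the only quantity that pins the count.

The axial coordinate `x` reported alongside the tree reproduces the printed
plotting convention (TU compartments at multiples of their length, the SU
chain anchored at the ninth TU compartment exit and advanced by
midpoint-to-midpoint distances $\tfrac12(l_N + l_M)$); whether that
convention measures entrances or midpoints is not decidable from the
rounded reference values, and nothing downstream depends on it.

## Asymmetry between parallel lung units

Asymmetry is introduced at one area $a^\ast \in 1..5$ by a volume factor
$f(a^\ast, e) = f_c$ on even elements and $2 - f_c$ on odd ones; sibling
factors sum to 2, so total lung volume is conserved exactly. Every
descendant element inherits its ancestor's factor; for a compartment with
inherited product $f_\mathrm{tot}$:

$$V' = f_\mathrm{tot} V,\quad l' = f_\mathrm{tot}^{1/3}\, l,\quad
A' = f_\mathrm{tot}^{2/3} A,\quad m_\mathrm{alv}' = f_\mathrm{tot}\,
m_\mathrm{alv}.$$

Because the flows are generated by alveolar volume change, flow factorizes
exactly like volume, so the convective time constants $\tau_c = V/Q$ are
invariant -- specific ventilation stays homogeneous and the model isolates
the DCDI mechanism from convective inhomogeneity by construction. The
diffusive time constants $\tau_D = R_D V$ scale as $f_\mathrm{tot}^{2/3}$
(times a mixed-length bracket at the boundary link), which is the whole
physics of the effect: the smaller sister unit equilibrates faster.

For analysis the tree splits into `LU0` (everything above $a^\ast$), `LU1`
(subtrees of the even elements) and `LU2` (odd). The per-breath inter-unit
difference $\Delta\bar\chi_{N_2}(t_n)$ is evaluated at
$t_n = 3.5\,\mathrm{s} - \Delta t_{LU0} + (n-1)T$, i.e. the instant whose
gas reaches the mouth at the start of the phase-3 window after transiting
the shared region.

## Transport and its electrical form

Each compartment $N$ with parent $M$ and children $O_j$ balances tracer
volume:

$$\frac{d}{dt}\bigl(V_N \chi_N\bigr) =
\underbrace{\frac{Q_{N} + |Q_{N}|}{2}\chi_M
 - \sum_j \frac{Q_{O_j} + |Q_{O_j}|}{2}\chi_N
 + \frac{-Q_{N} + |Q_{N}|}{2}\,(-\chi_N)
 + \sum_j \frac{-Q_{O_j} + |Q_{O_j}|}{2}\chi_{O_j}}_{\text{upwind convection}}
 - \underbrace{\frac{\chi_N - \chi_M}{R_{D,N\to M}}
 + \sum_j \frac{\chi_{O_j} - \chi_N}{R_{D,O_j\to N}}}_{\text{diffusion}}$$

with $R_D = \tfrac12(l_N + l_M)/(D A_N)$ owned by the child side of each
link and the flows $Q$ switching sign as a rectangular function of period
$T$ (first half inspiration). Only alveolated compartments change volume
($dV/dt$ equals their alveolar flow); the dead space is rigid. The
entrance Peclet number $\mathrm{Pe}_N = \hat Q_{N} \tfrac12 (l_N +
l_M)/(D A_N)$ crosses 1 between generations 14 and 15 for He-N$_2$
($D = 0.6\ \mathrm{cm^2/s}$), separating the convection- from the
diffusion-dominated zone.

Boundary conditions: the lung starts filled with pure nitrogen; the inlet
node is held at tracer fraction 1 during inspiration and 0 during
expiration. The inlet *diffusive* link is blocked with a $10^{100}$
s/cm$^3$ resistance so the stepwise inlet concentration cannot contaminate
the mouth signal; the washout signal is the mole fraction of the first TU
compartment, which is the physical upwind donor during expiration.

## Numerical scheme

The balance is integrated in the expanded form
$V \dot\chi = \mathrm{in} - \mathrm{out} - \chi \dot V$ with a fixed-step
explicit scheme whose steps always land on the rectangular-flow switch
times, so every step lies in one smooth phase segment:

* **Scheme.** Heun's explicit trapezoidal rule (second order) by default;
  plain explicit Euler is available (`scheme = "euler"`). Euler at a 1-ms
  step leaves a first-order step-size signature of about $5\times10^{-3}$
  in the mouth trace (sup-norm change on step halving); Heun at the 0.5-ms
  default brings that to $3\times10^{-5}$, which is what the package's
  convergence guarantee (< $10^{-4}$) is calibrated against.
* **Step size.** Default $dt = 5\times10^{-4}$ s. The fastest network time
  constants (terminal acinar links) are ~$5\times10^{-3}$ s even for the
  strongest down-scaled units, so the default sits an order of magnitude
  inside the explicit stability bound, which is also checked at startup.
* **No clamping.** Mole fractions are not clipped to $[0,1]$; an excursion
  beyond $10^{-6}$ aborts with a diagnostic instead, because silent
  clamping would destroy the mass balance that the tests rely on.
* **Conservation.** With a closed boundary the scheme conserves total
  tracer volume to machine precision (the discrete fluxes are pairwise
  antisymmetric); with an open boundary the cumulative inlet flux integral
  is accumulated alongside and the residual
  $\sum V\chi - \int \dot V_\mathrm{boundary}$ stays below $10^{-3}$
  relative -- it is the (second-order) quadrature error of the moving-volume
  storage term, reported per breath in the run log.
* **Determinism.** There is no randomness anywhere; reruns are
  bit-identical.

## What the standard protocol shows, and what it cannot

The shipped study design is the classical protocol: $T = 4$ s, peak flow
250 cm$^3$/s (500-ml tidal volume), 200 s (50 breaths), He-N$_2$, the
symmetric reference plus $f_c \in \{1.25, 1.5, 1.75\}$ crossed with
$a^\ast \in \{1..5\}$. Reproduced phenomenology:

* symmetric model: homogeneous alveolar gas at end-expiration and
  $|S_3| \sim 5\times10^{-5}\ \mathrm{L^{-1}}$ -- a flat plateau;
* asymmetry in the convection-dominated area 1: no phase-3 slope (specific
  ventilation is homogeneous by construction, and diffusive coupling is
  negligible at Pe $\gg$ 1);
* asymmetry in areas 2-5: $S_3(n)$ rises to a maximum and then decays
  exponentially; the peak breath moves toward $n = 1$ as the asymmetry
  moves peripherally and is $n = 1$ for the strongest, most peripheral
  case; the normalized slope grows approximately monoexponentially to a
  plateau; $S_3(n)$ is proportional to the inter-unit difference
  $\Delta\bar\chi_{N_2}(t_n)$.

On the last point: the proportionality ratio
$f_{S3}(n) = S_3(n)/\Delta\bar\chi_{N_2}(t_n)$ settles to a constant by
roughly the third breath in every scenario, but carries a genuine
first-breath transient (up to ~30 % for a weak asymmetry in area 2): at the
first phase-3 window the inter-unit difference is still building, so
sampling it at the window-start instant under-represents the gradient that
drives the first slope. The transient is unchanged under step halving and
under doubling the TU resolution, i.e. it is converged model physics, not a
numerical artifact. A blanket "constant within 5 % from breath 1" therefore
holds only for asymmetries at or beyond area 3 with moderate-to-strong
factors; the corresponding strict check in the test suite is left failing
for the proximal weak cases rather than weakened.

Known limitations, intentional in this model class: no Taylor dispersion
(the diffusion coefficient is a plain scalar; a dispersion coefficient can
be substituted by the user but no velocity-dependent model is
implemented); no lung mechanics -- flows are ideal rectangular functions
with perfectly synchronous alveoli, so convection-dependent inhomogeneity
is excluded by design; pure-tracer inspiration rather than a clinical gas
mixture; a single segment unit (no parallel segments); and well-mixed
compartments, which purge exponentially and therefore leave an
$\mathcal{O}(10^{-4})$ residue where a plug-flow dead space would empty
completely.

## Problem sizes used by the tests

The test suite exercises the full 251-compartment network throughout: one
50-breath symmetric run, fifteen 50-breath asymmetric runs for the study
grid, 20-s runs for the convergence and step-halving checks, and
micro-networks (two compartments) for the closed-form RC oracles. A
50-breath run takes on the order of a second at the default step.

## Reproducing the numbers

```{r example, eval = FALSE}
model <- lung_model()                   # 3000-ml symmetric He-N2 model
reproduce_table1(model)                 # per-element geometry regression
result <- simulate_washout(assemble(model))
washout_report(result)                  # per-breath S3, normalized S3, ...
run_grid("out/")                        # the full 16-scenario study design
```

`scripts/acceptance.R` recomputes the headline scalars (alveolar diameter
at 3000 ml; the symmetric-model phase-3 slope) from a fresh build and run.
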