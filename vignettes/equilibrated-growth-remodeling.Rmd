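---
title: "Mechanobiologically equilibrated growth and remodeling of the murine thoracic aorta"
author: "gnreq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanobiologically equilibrated growth and remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnreq)
```

## The model

`gnreq` implements a rate-independent, *mechanobiologically equilibrated*
constrained-mixture model of the arterial wall and applies it to in silico
"numerical knockouts" of a cylindrical segment of the murine descending
thoracic aorta.  The wall is a constrained mixture of three structurally
significant constituents that deform together but have distinct natural
configurations and turnover:

* **elastin-dominated matrix** (`e`): neo-Hookean,
  $\hat W^e = \tfrac{c^e}{2}(\mathrm{tr}(\mathbf F_e^T\mathbf F_e) - 3)$,
  deposited during development with a fixed isochoric prestretch
  $\mathbf G^e = \mathrm{diag}(G_\theta^e, G_z^e, 1/(G_\theta^e G_z^e))$ and
  not produced in maturity — it follows the mixture deformation from the
  original homeostatic configuration and can only be degraded;
* **four collagen fiber families** (circumferential, axial, two symmetric
  diagonals at angle $\alpha_0$ from the axis, fractions $\beta$) and
  **circumferential passive smooth muscle**, with exponential fiber energies
  $\hat W(\lambda) = \tfrac{c_1}{4c_2}\big(e^{c_2(\lambda^2-1)^2}-1\big)$,
  each deposited at its deposition stretch $G^c$ or $G^m$;
* **active smooth muscle tone**, circumferential, with shear-regulated
  magnitude $T(\Delta\tau_w) = T_{max}(1 - e^{-(C_B - C_S\Delta\tau_w)^2})$
  and a length–tension parabola; at equilibrium the active reference length
  has fully adapted, so the active stretch is 1.

Cell-mediated production responds to two stimuli: the intramural stress
stimulus $\sigma_v = \mathrm{tr}(\boldsymbol\sigma)/3$, attenuated by a
mechanosensing-dysfunction fraction $\delta \in [0,1]$, and the flow-induced
wall shear stress, attenuated by an endothelial-dysfunction fraction $\xi$.
With constant flow, $\tau_w/\tau_{wo} = (a_o/a)^3$ at the local deformed
radius.  **Mechanobiological equilibrium** means production exactly balances
removal at every point:

$$\frac{(1-\delta)\,\sigma_v - \sigma_o}{\sigma_o}
  \;-\; \frac{K_{\tau w}}{K_\sigma}\,
  \Big[(1-\xi)\frac{\tau_w}{\tau_{wo}} - 1\Big] \;=\; 0 .$$

Only the gain *ratio* $K_{\tau w}/K_\sigma$ enters; the removal-rate
constants of the transient theory cancel and appear nowhere in the API.
Under this condition the hereditary integrals of the full constrained-mixture
theory collapse: every fiber family sits at its deposition stretch, and both
the stored energy per unit current volume and the Cauchy stress become rules
of mixtures over the *evolved* mass fractions
$\phi_h^\alpha = \phi_o^\alpha\rho^\alpha/J$ with
$J = \phi_o^e + \phi_o^m \rho^m + \phi_o^c \rho^c$ and the turnover coupling
$\rho^m = (\rho^c)^\eta$.  The unknowns at a material point are the mixture
stretches and the referential collagen density $\rho^c$.

The membrane Lagrange multiplier is fixed by the mid-wall radial condition
$\sigma_{rr} = -P/2$.  The homeostatic pressure is **derived**, not
prescribed: $P_o$ is the value that makes the baseline constitutive state an
exact root of the mid-wall Laplace relation,
$P_o = (\hat\sigma_{\theta\theta} - \hat\sigma_{rr})/(a_o/h_o + 1/2)$.  With
the default parameters this gives $P_o \approx 16.34$ kPa
($\approx 122$ mmHg, a physiologic murine systolic pressure) and a stimulus
setpoint $\sigma_o \approx 168$ kPa:

```{r baseline}
pars <- mouse_dta_parameters()
baseline <- homeostatic_baseline(pars)
baseline
```

The two homeostatic anchors computed here — stored energy
$W_o \approx 67.7$ kPa and circumferential material stiffness
$c_{\theta\theta\theta\theta,o} \approx 1423$ kPa — are recomputed from the
parameter table at run time, never stored.

## Material stiffness

The stiffness map reports the circumferential–circumferential component of
the small-on-large linearization about the current loaded state at *frozen
composition*: equivalently the derivative of the Kirchhoff stress with
respect to an imposed circumferential stretch increment,

$$c_{\theta\theta\theta\theta} = 2\,\sigma^{pas}_{\theta\theta}
  + \sum_{fam}\phi_h^{fam}\,\big[\lambda^2\hat W'' - \lambda\hat W'\big]_{\lambda = G}\, m_\theta^4 ,$$

with $m_\theta$ the circumferential component of the (evolved) fiber
direction.  Whether the active tone should contribute a geometric
$2\sigma^{act}$ term was genuinely open; resolving it against the baseline
stiffness value showed that the passive-only definition reproduces the
homeostatic anchor to 0.35%, whereas including the active term overshoots by
5%.  The active term is therefore excluded by default and exposed as the
`include_active` toggle of `material_stiffness_ctttt()`.

## Insult fields and end regions

Localized insults follow the Gaussian-like axial profile
$\vartheta(z) = \vartheta_{end} + (\vartheta_{central}-\vartheta_{end})
\exp(-|{(z - l_o/2)}/{z_{od}}|^{\nu_z})$ with defaults $\nu_z = 5$,
$z_{od} = 3$ mm on the 15-mm segment; an asymmetric variant multiplies an
analogous circumferential factor with apex at $(l_o/2, \pi)$.  The end value
is always the baseline parameter value.  Shear-mediated matrix turnover is
confined to the non-aneurysmal segments: every localized scenario carries a
gain-ratio field with the baseline value 0.35 at the ends and 0 at the
lesion center, with the same profile shape.  In the equilibrated 0-D model
an insult-free end at baseline parameters is exactly homeostatic, so the
turnover-ratio end value defaults to $\eta_{end} = 1$;
`end_region_profiles(solve_end = TRUE)` verifies this against the 0-D
homeostatic residual.

## Solvers

* `solve_uniform()` — simultaneous Newton solve for
  $(\lambda_\theta, \rho^c)$ of a uniform cylinder (axially fixed ends,
  $\lambda_z = 1$; a force-controlled mode frees $\lambda_z$ at constant
  axial force), with quasi-static continuation of insult magnitude and
  pressure in 10 increments and step halving on divergence.
* `solve_scenario()` — axisymmetric nonlinear *membrane* finite elements:
  20 quadratic meridian elements (41 nodes), 3-point Gauss integration,
  follower pressure on the deformed surface, and the pointwise
  mechanobiological constraint at every Gauss point.  The solver is
  monolithic in (geometry, collagen densities), which remains regular where
  the pointwise mass solve alone has a limit point (the local stimulus can
  saturate just below its setpoint — precisely the mechanism that forces
  dilatation).  The consistent tangent assembles exact follower-load terms
  and machine-precision point derivatives via complex-step differentiation;
  a column-wise finite-difference mode provides the independent check.

The membrane equilibrium path can exhibit genuine snap-through folds as the
insult is ramped, which plain load stepping cannot traverse.  Two remedies
are built in and enabled by default (`fem_solve_config(arc_length = TRUE)`):
a field-wise predictor that solves the 0-D problem at every node's local
parameters and starts a full-load Newton solve from the assembled field, and
a Riks-type arc-length continuation.  The instability scan
(`scan_delta_instability()`) deliberately disables both: the critical
mechanosensing level is defined as the largest value for which plain
Newton–Raphson load stepping still converges, and beyond which dilatation
grows without bound.

## The knockout catalog

`knockout_catalog()` enumerates five localized insults — elastic fiber
integrity ($c^e$, mild 32% / severe 62% reduction), collagen cross-linking
($c_1^c$, 9% / 23%), smooth muscle contractility ($T_{max}$, 60% / 100%),
mechanosensing ($\delta$ = 0.075 / 0.185), and mechanoregulation ($G^c$,
0.4% / 1.2% reduction) — each alone and with hypertension (1.5× pressure)
and/or aging (uniform 30% elastin-integrity loss) superimposed, plus
increased collagen-turnover cases ($\eta$), uniform-insult variants, and
asymmetric field specifications (fields only; asymmetric solves are a
documented non-goal).  For the turnover ratio the sources give both a
"5 to 12.5%" mild-to-severe increment and a severe central value 1.05; the
catalog stores mild 1.05 and severe 1.125 and accepts custom values.

```{r severe, eval = FALSE}
mesh <- build_mesh(pars)
res <- run_scenario(scenario_spec("elastin_integrity", "severe"),
                    pars, baseline = baseline, mesh = mesh)
summarize_result(res)
```

Elastin damage is modeled as a loss of load-bearing *integrity at preserved
volume*: the local modulus $c^e$ falls (equivalently, the load-bearing
elastin mass fraction), while the degraded matrix still occupies its
reference volume fraction in $J$.  This choice was settled against the
severe-lesion endpoints (central energy loss near 30% and a roughly two-fold
stiffness rise, both requiring the strongly dilated solution branch);
removing the volume along with the stiffness instead lets fiber mass
concentrate and suppresses the dilatation entirely.

## Numerical choices

* Units kPa/mm; angles stored in radians, printed in degrees.
* Newton tolerances: dimensionless residuals below $10^{-10}$
  (mechanobiological) and $10^{-10}$ of the baseline membrane force scale
  (mechanical); local mass solves to $10^{-12}$.
* Continuation: 10 increments, at most 5 consecutive halvings and a total
  failure budget before a case is declared to have no equilibrium
  (a mechanobiological static instability); metrics of unconverged runs
  describe the last converged state and carry a flag.
* Local mass solve: capped Newton with complex-step derivatives and a
  bracketed scalar fallback; the residual is not monotone in $\rho^c$ at
  large densities (the elastin radial term dominates), so brackets expand
  from the previous converged value.
* Tie-breaks and degenerate inputs: $c_2 = 0$ uses the analytic quadratic
  limit of the fiber energy; $\alpha_0 = \pi/2$ is treated as fixed
  circumferential; $\lambda_M = \lambda_0$ is rejected.

## Problem sizes

All shipped analyses run at the reference resolution of 20 quadratic
elements along the half-symmetric meridian (41 nodes, 60 Gauss points),
which the mesh-refinement check (severe elastin lesion, 20 vs 40 elements,
maximal diameter within 1%) supports as converged for the reported
metrics.  The full axisymmetric catalog (40 core cases) solves in a few
minutes on one CPU; a single lesion solves in about a second.

## What the model does and does not capture

The axisymmetric membrane is a reduction of a one-element-thick 3-D
formulation: through-thickness gradients, bending stiffness at the lesion
shoulder, aortic curvature, pulsatile loading, and fluid–solid-growth
coupling are all absent, and transient trajectories between equilibria are
out of scope by construction.  Consequences observed here and worth knowing:

* The mild localized elastin case alone sits in a narrow no-equilibrium gap
  of the membrane model (verified by continuation from both sides); its
  reported metrics describe the last converged state (~68% of the insult,
  a minor dilatation), flagged unconverged.
* The critical mechanosensing level of the localized lesion computes to
  0.225 on this membrane with plain Newton stepping — above the
  three-dimensional reference value near 0.185, a systematic effect of the
  missing shoulder stiffness and of a solver that tracks the branch closer
  to the actual fold.
* The severe-lesion central stiffness rise computes to ~1.55-fold rather
  than the full two-fold of the 3-D model, again reflecting the membrane's
  smaller central collagen reorientation; the central energy loss (~34%)
  and the catalog's maximal dilatations (~150%) land close to their
  reference values.

Passing tests therefore demonstrate internal consistency of the equilibrated
theory, exactness of the linearization, and reproduction of the study's
quantitative endpoints at membrane fidelity — not predictive validity for
any particular real vessel.

## Virtual mechanical tests

`simulate_equibiaxial()` freezes the remodeled composition of a converged
state (mass fractions, fiber angle, constituent natural configurations),
removes active tone and pressure, unloads to the traction-free configuration
under plane stress and incompressible *elastic* deformation, and stretches
equibiaxially.  Remodeled lesions lose distensibility relative to baseline,
with the smallest change for the contractility knockout — the insult that
alters composition least.
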