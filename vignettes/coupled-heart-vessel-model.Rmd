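---
title: "A desk-scale coupled heart–vessel pulse-wave model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale coupled heart-vessel pulse-wave model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiowave)
```

`cardiowave` simulates the bidirectional interaction between a contracting
cardiac cavity and a compliant arterial network. The arterial side is a
nonlinear one-dimensional (1D) pulse-wave model; the cardiac side is a
reduced-order cavity exposing a pressure–volume relation; the two are coupled
monolithically at every time step by a saddle-point Newton solve for the
cavity pressure. This vignette documents the model equations, the numerical
choices, the default parameters and their rationale, and what the synthetic
benchmark networks do and do not represent.

## The 1D blood-flow model

Each vessel is described by its cross-sectional area $A(x,t)$ and volumetric
flow $Q(x,t)$:

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\alpha \frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = \frac{f}{\rho},$$

with blood density $\rho$, Coriolis (momentum-flux correction) coefficient
$\alpha$, and friction force per unit length $f = -2\pi(\zeta+2)\mu\,u$,
where $u = Q/A$ and $\zeta$ is the velocity-profile constant. The default
$\zeta = 9$ gives $\alpha = (\zeta+2)/(\zeta+1) = 1.1$; $\zeta = 2$ would
recover Poiseuille friction. Pressure closes the system through a Voigt-type
visco-elastic tube law

$$P = P_{ext} + K\,\frac{\sqrt{A}-\sqrt{A_0}}{A_0}
      + G\,\frac{1}{A_0\sqrt{A}}\,\partial_t A, \qquad
  K = \tfrac{4}{3}\sqrt{\pi}\,E h, \quad
  G = \tfrac{2}{3}\sqrt{\pi}\,\varphi h,$$

with Young modulus $E$, wall thickness $h$ and wall viscosity $\varphi$. The
elastic wave speed is $c(A) = \sqrt{K\sqrt{A}/(2\rho A_0)}$ and the Riemann
invariants of the elastic subsystem are $W_{f,b} = u \pm 4\,(c - c_0)$; these
drive every boundary treatment.

All internal quantities are SI (m, s, Pa, kg). Unit conversions (mmHg, mL)
appear only in output and documentation. This removes an entire class of unit
bugs from the coupled Newton system.

### Discretisation

The conservative $(A,Q)$ form is discretised by a second-order finite-volume
MUSCL scheme: limited linear reconstruction (minmod by default; an unlimited
centred slope is available for smooth verification problems), an HLL
approximate Riemann solver with Davis wave-speed estimates, and two-stage
explicit (Heun) time integration. The elastic pressure term is integrated
into the flux, $C_1(A) = K A^{3/2}/(3\rho A_0)$, so the hyperbolic core and
its characteristics are purely elastic. Tapered vessels sample $A_0(x)$,
$K(x)$ per element and add the well-balanced geometric source term, which
vanishes identically at rest.

Two deliberate splittings keep the scheme simple and robust:

* the viscous wall term $G\Psi$ is applied as an operator-split, implicit
  (backward Euler) diffusion step on $Q$ after each hyperbolic substep —
  unconditionally stable, so wall viscosity never restricts the CFL bound;
* boundary states (inlet, terminals, junctions, stenosis interfaces, valve)
  are resolved once per substep from the outgoing characteristics and held
  fixed over the two Heun stages. This makes the boundary coupling formally
  first-order in time but renders the discrete mass balance exact to rounding
  (the conservation tests assert a defect at the $10^{-16}\,\mathrm{m}^3$
  level over multi-beat runs).

An equivalent discontinuous-Galerkin treatment would behave the same for
these smooth flows; the scheme choice is immaterial to the physics, which the
time-step robustness experiment confirms.

### Boundary and interface elements

**Inlet.** A periodic flow (or pressure) waveform is combined with the
backward characteristic of the first element; the remaining variable follows
from the tube law. In coupled mode the inlet is the aortic valve (below).

**RCR Windkessel terminals.** Characteristic impedance $Z$ in series with a
parallel resistance $R$ and compliance $C$ discharging against $P_{out}$. The
capacitor pressure is updated by backward Euler — first-order, tested against
the analytic $RC$ discharge — solved simultaneously with the outgoing
characteristic by a scalar Newton iteration. The governing relation
$Q(1 + Z/R) + CZ\,\dot Q = (P - P_{out})/R + C\,\dot P_e$ is implemented with
$P_e$ identified with the terminal pressure $P$, under which it reduces to
the standard capacitor equation; the steady state is
$P = P_{out} + Q(R + Z)$.

**Junctions.** Mass conservation plus continuity of total pressure
$P + \tfrac12\rho u^2$ (static-pressure matching is available by flag),
solved by a small Newton iteration on the connected end areas, with the
outgoing characteristic of every vessel as constraints. Mass defects are at
rounding level ($< 10^{-13}$ relative in the tree benchmarks).

**Stenosis.** A lumped Young–Tsai-type element embedded at an interior
interface: equal through-flow on both sides and a pressure jump

$$\Delta p = \frac{K_v \mu}{A_0 D_0}\,q
  + \frac{K_t \rho}{2A_0^2}\Bigl(\frac{A_0}{A_s}-1\Bigr)^2 q\,|q|
  + \frac{K_u \rho L_s}{A_0}\,\dot q,$$

with defaults $K_v = 32 L_s/D_0$, $K_t = 1.52$, $K_u = 1.2$, all exposed in
the network file. A "30% stenosis" means $A_s/A_0 = 0.7$. Note that the
inertial term represents the jet through the constriction and does not vanish
as $A_s \to A_0$; the degeneration test therefore disables it.

**Aortic valve.** A Bernoulli resistor with blood inertance acting as a
diode: $p_{cav} - p_{root} = B\,q|q| + L_{in}\dot q$ with $q \ge 0$ (no
regurgitation). Opening occurs when cavity pressure exceeds root pressure;
closure when the implicit flow update becomes non-positive. The default
$B = 4.5\times10^9\ \mathrm{Pa\,s^2/m^6}$ corresponds to an effective orifice
of about $3.5\ \mathrm{cm}^2$; $L_{in} = 5\times10^4\ \mathrm{Pa\,s^2/m^3}$
to a blood column of a few centimetres at that orifice.

## Reduced-order cardiac cavities

Both cavities implement one contract: $V(p,t)$, its derivative
$\partial V/\partial p$, and the inverse $p(V,t)$; the coupling layer is
agnostic to which model stands behind it.

**Active stress transient.** The scalar active stress is the phenomenological
length-dependent transient

$$S_a(t,\lambda) = S_{peak}\,\phi(\lambda)\,
  \tanh^2\!\frac{t_s}{\tau_c}\,\tanh^2\!\frac{t_{dur}-t_s}{\tau_r},
  \qquad 0 < t_s < t_{dur},$$

with $\phi = \tanh(ld\,(\lambda - \lambda_0))$ (clamped at zero below
$\lambda_0$), $\tau_c = \tau_{c0} + ld_{up}(1-\phi)$ and
$t_s = t - t_a - t_{emd}$. The activation time $t_a$ is a plain scalar
parameter (default 0): electrical activation mapping is outside this model's
scope. Ventricular baseline values: $S_{peak} = 60$ kPa, $t_{dur} = 575$ ms,
$\tau_{c0} = 105$ ms, $\tau_r = 90$ ms, $ld = 35$, $ld_{up} = 100$ ms,
$\lambda_0 = 0.7$, $t_{emd} = 15$ ms, cycle 1.231 s. When a different heart
period is used (the tree experiment runs at 0.8 s) all four time constants
are rescaled proportionally.

**Guccione passive law.** Transversely isotropic exponential strain energy
$\Psi = \tfrac{\kappa}{2}(\log J)^2 + \tfrac{C_{guc}}{2}(e^{Q}-1)$ with
$Q = b_f \bar E_{ff}^2 + b_t(\bar E_{ss}^2 + \bar E_{nn}^2 + 2\bar E_{sn}^2)
+ 2 b_{fs}(\bar E_{fs}^2 + \bar E_{fn}^2)$ on the isochoric strain
$\bar E = \tfrac12(J^{-2/3}C - I)$; defaults $b_f = 18.48$, $b_t = 3.58$,
$b_{fs} = 1.627$, $\kappa = 650$ kPa. The analytic second Piola–Kirchhoff
stress $S = 2\,\partial\Psi/\partial C$ is implemented and tested against
numerical differentiation and for frame indifference.

**Active stress tensor.** Orthotropic, with full tension along the fibre and
40% along the sheet direction:
$S_{act} = S_a (f_0\!\cdot\!C f_0)^{-1} f_0\!\otimes\!f_0
+ 0.4\,S_a (s_0\!\cdot\!C s_0)^{-1} s_0\!\otimes\!s_0$, so that
$S_{act}\!:\!C = 1.4\,S_a$ for any metric.

**Thick-walled sphere.** The ventricle surrogate is an incompressible
thick-walled sphere with circumferential fibres, meridional sheets and radial
normals, deforming by the inflation map $r^3 = R^3 + r_i^3 - R_i^3$. Cavity
pressure at a given volume follows from radial equilibrium,

$$p = \int_{r_i}^{r_o}
   \frac{(\sigma_\theta - \sigma_r) + (\sigma_\phi - \sigma_r)}{r}\,dr,$$

where the Cauchy stress differences are $\sigma_a - \sigma_h = \lambda_a^2
S_a$ at $J = 1$, with both the passive and active stresses above. The
integral uses 16-point Gauss quadrature over the reference wall; volume at
given pressure is found by a damped, warm-started Newton inversion. An
exactly spherically symmetric state with in-plane anisotropy is an
idealisation; the two hoop stresses are simply averaged in the equilibrium
integral.

*Calibration of the sphere defaults.* The reference geometry
($R_i = 24.3$ mm, $R_o = 36.9$ mm, i.e. a 60 mL cavity in a 150 mL wall) and
stiffness scaling $C_{guc} = 700$ Pa give an end-diastolic volume of about
97 mL at a 10 mmHg preload. One deliberate deviation from the ventricular
baseline: the sphere measures fibre stretch from its stress-free reference,
where the cycle spans stretches of roughly 1.0–1.2, whereas the tissue-level
transient measures stretch from an end-diastolic reference. With
$\lambda_0 = 0.7$, $ld = 35$ the length dependence is fully saturated over
the sphere's range, and the wall-thinning geometry then gives the cavity a
*negative* end-systolic pressure–volume slope — multiple volumes at one
pressure, which breaks the coupling contract (and is not a property of a real
ventricle, whose Frank–Starling recruitment keeps the end-systolic elastance
positive). The sphere defaults therefore re-centre the length dependence at
$\lambda_0 = 0.90$, $ld = 6$, which restores a strictly monotone $p(V)$ over
45–130 mL across the whole transient (verified by a dedicated test) while
keeping all remaining parameters at their baseline values.

**Time-varying elastance.** A linear surrogate
$p = E(t)\,(V - V_{rest})$ with $E(t)$ interpolating between $E_{min}$ and
$E_{max}$ along the normalised transient shape. It is exactly affine in $p$,
which the Newton tests exploit (one-step convergence), and serves as the
fast stand-in cavity.

**Surface volumes.** For workflows where a cavity is bounded by a
triangulated surface, the enclosed volume is evaluated exactly by the
divergence theorem ($\tfrac13\oint x\cdot n\,d\Gamma$ as a signed tetrahedron
sum) with a closedness/orientation check. Note the volume requires the
deformed *position* in the integrand; an expression in terms of the
displacement alone does not measure the enclosed volume.

## The monolithic coupling

At each coupling step of size `dt3D` the unknown cavity pressure $p$ must
reconcile the cavity's volume with the volume change the vascular system can
accept:

$$r(p) = V^{heart}(p, t^{n+1}) - V^{CS}(p) = 0, \qquad
  V^{CS}(p) = V^n - \int_{t^n}^{t^{n+1}} q(p)\,dt .$$

$V^{CS}(p)$ is evaluated by running the valve and the 1D network — sub-stepped
at `dt1D`, so the coupling always happens at the coarse (heart-side)
resolution — from the committed snapshot with the trial pressure held
constant; the committed state is never touched by trials, and repeated trials
are bit-identical. The block saddle-point system reduces, for a single scalar
pressure unknown, to Newton on $r(p)$ with Jacobian
$dV^{heart}\!/dp - dV^{CS}\!/dp$, where the vascular compliance
$C'(p) = dV^{CS}\!/dp$ is a central finite difference of two trials
($\varepsilon = 10$ Pa by default; an $\varepsilon$-robustness test checks
the estimate is stable under halving).

During isovolumetric phases all valves are closed: $C' = 0$ and
$V^{CS} = V_0$, so the step degenerates to Newton on
$V^{heart}(p, t^{n+1}) = V_0$ with the cavity Jacobian alone.

Convergence uses the absolute tolerance $|r| < \varepsilon_{tol} V_{scale}$
with $\varepsilon_{tol} = 10^{-6}$ and $V_{scale} = 1$ mL (the millilitre is
the natural cavity-volume unit; the scale is exposed in the configuration),
and at most `k_max = 10` Newton steps.

Three safeguards make the scalar solve robust without ever loosening the
tolerance:

* **trend start** — the iteration starts from the pressure extrapolated along
  its recent trajectory, which lands near the root even at ejection onset
  where cavity pressure rises by hundreds of Pa per step;
* **bracketing** — $r(p)$ is increasing in $p$ (cavity volume grows, ejected
  volume grows with pressure), so any sign change brackets the root; Newton
  proposals outside the bracket, or ones that fail to reduce $|r|$, are
  replaced by bisection of the bracket, which handles the kink of
  $V^{CS}(p)$ at the valve-opening pressure;
* **step halving** — a trial pressure that destabilises the 1D solver is
  retried with a halved update (up to 5 times).

In the shipped benchmarks the solve converges in at most 2 iterations with
residuals at the $10^{-13}\,\mathrm{m}^3$ level.

### Cardiac cycle phase machine

`run_cardiac_cycle()` walks the four phases at the coupling step: *filling*
(cavity pressure pinned to a prescribed preload — a constant left-atrial
pressure, 10 mmHg by default; no atrium model, so end-diastolic volume is
set by preload and passive behaviour), *isovolumetric contraction* (entered
once per beat when the active transient onsets at $t_a + t_{emd}$),
*ejection* (entered when cavity pressure exceeds root pressure; the full
coupled Newton step), and *isovolumetric relaxation* (entered at valve
closure, left when pressure falls below preload). Phase triggers carry a
1 Pa hysteresis band against valve chatter. The 1D network keeps running in
every phase — with a closed inlet outside ejection — so diastolic run-off and
wave dynamics continue between beats.

## Synthetic benchmark networks

No external data are used; three generated fixtures emulate the benchmark
configurations:

* `make_single_vessel()` — one uniform vessel with an RCR terminal: 200 mm
  for the time-step robustness experiment, 126 mm for the stiffening and
  coarctation experiments. Defaults (documented, all arguments): 10 mm
  radius, 1.5 mm wall, $E = 0.25\times10^6$ Pa baseline, purely elastic wall
  ($\varphi = 0$); terminal $Z$ matched to the vessel's characteristic
  impedance, $R = 2\times10^8$ Pa s/m³, $C = 9\times10^{-9}$ m³/Pa,
  $P_{out} = 0$, chosen to give an aortic operating point near 120/75 mmHg
  (mean ≈ 93 mmHg) at the default inflow.
* `make_stenotic_vessel()` — the 126 mm vessel with the lumped stenosis at
  half length, area ratio 0.7 by default.
* `make_bifurcating_tree()` — a symmetric surrogate of the path from the
  aortic root towards a peripheral (brachial-like) artery: Murray-ratio
  daughters ($2^{-1/3}$), 10% area taper per vessel, stiffness increasing
  30% per generation, leaf RCR terminals sharing a total peripheral
  resistance of $1.45\times10^8$ Pa s/m³ and compliance of
  $5\times10^{-9}$ m³/Pa. The *aged* profile doubles every Young modulus and
  raises every peripheral resistance by 30% — the textbook stiffening and
  resistance increase of healthy ageing. It is a tree surrogate, not an
  anatomical 116-segment network; quantitative pressures are therefore only
  physiologically plausible, while the qualitative contrasts (peripheral
  amplification, its reduction with age) are the tested content.
* `make_inflow_waveform()` — a half-sine systolic pulse over 30% of the
  cycle followed by zero diastolic flow; defaults give a 70 mL stroke volume
  at the 1.231 s period (peak 300 mL/s), and the 0.8 s tree case uses a
  450 mL/s peak. A measured aortic waveform can be supplied as a sampled
  table instead.

What passing these benchmarks shows — and does not show. The tests verify
wave kinematics against closed forms (transit speed, reflection coefficients,
Windkessel analytics), exact conservation, second-order convergence, the
coupling contract, and the qualitative physiological responses (stiffening →
higher peak pressure and end-systolic volume at unchanged end-diastolic
volume; coarctation → higher cavity peak pressure; ageing → less peripheral
pulse-pressure amplification). They do not validate patient-specific
anatomy, venous return and preload dynamics (filling pressure is prescribed),
atrial contraction, valve regurgitation, or electrophysiological activation
patterns — all outside this package's scope.

## Numerical choices and problem sizes

* Element size defaults to 2.5 mm. The 200 mm robustness fixture is run at
  5 mm: its coarsest benchmark substep ($5\times10^{-4}$ s) must satisfy the
  CFL bound $dt < \Delta x/(|u|+c)$ with $c \approx 5$–6.5 m/s, which a
  2.5 mm grid would violate. This is an a-priori stability constraint, fixed
  before any experiment, and the robustness test itself confirms the traces
  are grid-converged at this resolution (pairwise deviations well below 1%).
* Coupled experiments use `dt3D` = 1 ms, `dt1D` = 0.1 ms, 20 standalone
  initialisation cycles (12 for the tree, whose periodicity threshold is
  reached earlier at the shorter period) and 3 beats; the robustness
  comparison uses 2 beats per setting. The stenosis experiment also runs at
  `dt1D` = 0.1 ms: the implicit interface and terminal solves are stable
  there, with the CFL bound the only step restriction.
* Manufactured-solution convergence uses an unlimited centred slope
  (`limiter = "none"`): minmod clips smooth extrema and would mask the
  scheme's design order on this smooth problem; production runs keep minmod
  for robustness.
* Tolerances: coupling residual $10^{-6}$ mL; junction/boundary Newton
  solves iterate to step sizes of $10^{-14}$ relative; the sphere inversion
  resolves pressure to $10^{-12}$ relative so the coupled residual floor
  stays well below the coupling tolerance.
* Degenerate inputs are rejected at construction (non-positive areas or
  moduli, stenosis ratios outside $(0,1)$, non-tree connectivity, terminals
  on non-leaves); collapse to non-positive area during a run raises an
  instability error naming the vessel and element.

## Known limitations

Single cavity and open-loop afterload only (no atria, no right heart, no
venous return); prescribed preload; no regurgitant valves; elastic
characteristics are used at boundaries even when wall viscosity is active
(the viscous correction is split); the sphere averages its two hoop stresses
in the equilibrium integral; and the Coriolis coefficient enters the flux
but not the characteristic relations (the standard $\alpha = 1$
approximation at boundaries).
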