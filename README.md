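# cardiowave

A desk-scale simulator of heart–vessel interaction: a nonlinear
one-dimensional (1D) arterial pulse-wave solver, monolithically coupled to
reduced-order cardiac cavity models through a saddle-point Newton solve for
the cavity pressure.

Lumped (0D) Windkessel afterloads are the standard boundary condition for
cardiac mechanics models, but they cannot represent pulse-wave transmission:
wave speed, reflections at bifurcations and stenoses, peripheral pulse
pressure amplification, and the premature return of reflected waves in a
stiffened aorta. `cardiowave` is for modellers who want those effects in the
loop with a beating cavity — to study how aortic stiffening, coarctation or
network reflections feed back on ventricular pressure–volume behaviour —
without a 3D finite-element stack.

## Model core

**Vascular side.** Per vessel, cross-sectional area and flow obey

    dA/dt + dQ/dx = 0
    dQ/dt + d(alpha Q^2/A)/dx + (A/rho) dP/dx = f/rho,   f = -2*pi*(zeta+2)*mu*u

closed by the Voigt-type visco-elastic tube law

    P = P_ext + K (sqrt(A) - sqrt(A0))/A0 + G (dA/dt)/(A0 sqrt(A)),
    K = (4/3) sqrt(pi) E h,   G = (2/3) sqrt(pi) phi h

solved with a second-order finite-volume scheme (MUSCL/HLL, two-stage
explicit time stepping, implicit split for the viscous wall term).
Characteristic-based boundary elements: periodic inflow, RCR Windkessel
terminals, total-pressure-matched junctions, a lumped Young–Tsai stenosis,
and a Bernoulli valve with inertance.

**Cardiac side.** Interchangeable cavities behind one contract `V(p, t)`:
a time-varying elastance, and a thick-walled incompressible sphere carrying
the Guccione transversely isotropic passive law plus an orthotropic
length-dependent active stress transient (full tension along the fibre, 40%
along the sheet direction).

**Coupling.** At every step of size `dt3D` the cavity pressure solves

    V_heart(p, t^{n+1}) = V_CS(p) = V^n - integral of the valve flow q(p)

by Newton iteration (`k_max = 10`, absolute residual tolerance `1e-6` on a
1 mL scale), with the vascular compliance `dV_CS/dp` estimated by a central
finite difference of 1D trial runs sub-stepped at `dt1D`. Isovolumetric
phases freeze the vascular volume (`C' = 0`) and adjust pressure to the
evolving active stress. See the methods vignette
(`vignettes/coupled-heart-vessel-model.Rmd`) for the full account.

## Worked example

Simulate three beats of a spherical ventricle ejecting into a 126 mm aortic
segment with an RCR terminal:

```r
library(cardiowave)

net <- make_single_vessel(length = 0.126, E = 0.25e6)  # baseline stiffness
net <- run_standalone(net, n_cycles = 20, dt = 1e-4)   # cycle 1D model to periodicity
attr(net, "standalone")$periodic
#> [1] TRUE

out <- run_cardiac_cycle(sphere_cavity(), net, coupling_config(), n_beats = 3)
round(cbind(out$beats[, c("EDV", "ESV", "SV")] * 1e6, EF = out$beats$EF,
            p_lv_mmHg = out$beats$p_cav_max / 133.322,
            p_ao_mmHg = out$beats$p_root_max / 133.322), 3)
#>      EDV    ESV     SV    EF p_lv_mmHg p_ao_mmHg
#> 1 97.431 48.875 48.556 0.498   115.614   112.645
#> 2 97.405 47.402 50.003 0.513   109.556   106.069
#> 3 97.405 46.688 50.717 0.521   106.406   102.647
```

Each row is one beat: end-diastolic and end-systolic volume and stroke
volume in mL, ejection fraction, and peak cavity/aortic-root pressures in
mmHg — a 97/47 mL pressure–volume loop at an EF of 0.52 settling towards its
periodic state. `out$trace` holds the dense per-step trace (time, phase,
cavity pressure and volume, root pressure, valve flow, Newton diagnostics).
Raising `E` to `0.75e6` Pa raises peak aortic pressure by about 20 mmHg and
shrinks the stroke volume at an unchanged EDV; `make_stenotic_vessel()` and
`make_bifurcating_tree()` build the coarctation and network variants.

A command-line entry point is installed at `inst/cli/cardiowave`
(`run <config.yaml>`, `verify`, `make-fixture`), reading the plain-text
network/waveform/configuration formats documented in `?write_network` and
`?read_run_config`.

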