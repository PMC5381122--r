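---
title: "Models and numerical methods in cytostretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in cytostretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cytostretch characterizes single-cell mechanics from dielectrophoresis
(DEP) based cell stretching. It has two halves: an electrokinetic half that
estimates the stretching force a microfluidic chip applies to a captured
cell, and a mechanical half that simulates the deformation of a
coarse-grained actin cytoskeleton under that force and fits structural
parameters to measured strain-force curves. This vignette records the
models, the numerical choices, and the places where the design was
genuinely open.

## 1. DEP force estimation

A polarizable cell in a non-uniform AC field experiences a time-averaged
DEP force. The package computes it three independent ways.

**Equivalent dipole moment (EDM).** The point-dipole estimate
$F = 2\pi r^3 \varepsilon_0\varepsilon_m\,\mathrm{Re}[K(\omega)]\,\nabla E^2$
with $r$ the cell radius and $E$ the RMS field. `dep_force_edm()` is the
literal formula; the chip pipeline feeds it
$\nabla E_{rms}^2 = \tfrac12\nabla|E|^2$ computed from phasor amplitudes
(`grad_e2_at(..., rms = TRUE)`), which keeps the estimator consistent with
the quarter-factor amplitude convention used in the stress-tensor route.
The Clausius-Mossotti factor uses the homogeneous-sphere model
$K = (\varepsilon_c^* - \varepsilon_m^*)/(\varepsilon_c^* + 2\varepsilon_m^*)$,
$\varepsilon^* = \varepsilon_0\varepsilon - j\sigma/\omega$: the cell is a
uniform dielectric sphere with cytoplasm-like defaults
($\sigma_c = 0.2$ S/m, $\varepsilon_c = 60$, configurable). No membrane
shell is modeled; consequently the homogeneous defaults are pDEP
($\mathrm{Re}[K] \approx 0.92$ at 1 MHz) all the way down to DC, and
`crossover_frequency()` correctly reports no crossover for them — the
low-frequency pDEP-to-nDEP switch seen in experiments is a membrane
(shell) effect, outside this model class. The crossover finder itself is
generic (log-spaced scan plus bisection) and works for any parameter set
whose $\mathrm{Re}[K]$ changes sign.

**Simplified tip-to-tip approximation.**
$F = \tfrac14\varepsilon_0\varepsilon_m (U/d)^2 \cdot 4\pi r^2$, with $U$
the voltage amplitude and $d$ the electrode gap. It ignores frequency and
the actual field geometry and tends to overestimate; it is kept as the
quick, closed-form reference. All package APIs take voltage *amplitudes*;
function-generator peak-to-peak readings are converted with
`vpp_to_amplitude()` ($U = V_{pp}/2$).

**Maxwell stress tensor (MST).** The quasi-electrostatic phasor problem
$-\nabla\cdot((\sigma + j\omega\varepsilon_0\varepsilon)\nabla\phi) = 0$
is solved on a 2D side-view cross-section of the chip, and the
time-averaged tensor
$T = \tfrac14\varepsilon_0\varepsilon_m(EE^* + E^*E - |E|^2 I)$
is integrated around the cell and multiplied by a constant out-of-plane
thickness (default one cell diameter, 14 um).

### Field solver numerics

* Conservative cell-centered finite volumes on a uniform Cartesian grid;
  face conductances are harmonic means of the adjacent complex
  coefficients, so flux continuity at the cell/medium interface is built
  into the discretization. The circular cell is rasterized by cell-center
  material assignment.
* Domain: 100 um x 50 um (channel height 50 um; the full 5 mm channel
  adds nothing near the gap), grid spacing 0.25 um by default. Electrodes
  are zero-thickness Dirichlet segments, 30 um long, on the bottom wall,
  separated by the 20 um gap; all other boundaries insulate. One
  electrode carries the drive amplitude, the other is grounded.
* The complex linear system is solved sparsely; when every material shares
  one complex phase the system is provably real after rescaling and is
  solved as such (the particle-free chip always is). Otherwise the
  block-real form is factored. The relative residual is checked
  ($< 10^{-8}$).
* The captured cell sits at the gap edge of the driven electrode at height
  radius + 1 um. The 1 um standoff keeps the MST contour (which runs two
  grid cells outside the rasterized interface, where interpolated fields
  are smooth) strictly inside the domain. In a source-free medium the
  integral is contour-independent, so the offset costs no accuracy.
* 720 trapezoid points on the contour; field values by bilinear
  interpolation.

Because the problem is linear in $U$, `dep_force_table()` solves the two
field problems once at 1 V and scales forces by $U^2$ across the drive
protocol.

### What the estimators can and cannot reproduce

The reference six-voltage simplified-force column (0.61 to 4.36 nN for
amplitudes 1.5 to 4 V across a 20 um gap) is reproduced to 0.01 nN with
$\varepsilon_m = 80$; with the buffer value 78 every entry sits exactly
78/80 (about 2.6%) lower. Both permittivities are accepted via
configuration; tests pin 80 for the column and document the offset.
Absolute EDM and MST values, by contrast, depend strongly on modeling
choices that vary between chip models — electrode length, the exact
captured-cell position, mesh resolution — so no particular values are
treated as numeric targets; the package instead asserts the physically
meaningful properties: all
three estimators in the nanoNewton range at 1.5-4 V, the ordering
EDM < MST < simplified at every voltage, and the dipole-limit oracle — for
a particle of radius gap/20 the MST force agrees with the in-plane
(cylinder) point-dipole estimate to better than 10%. The cylinder CM
factor $(\varepsilon_c^*-\varepsilon_m^*)/(\varepsilon_c^*+\varepsilon_m^*)$
is the consistent limit for a 2D solver; comparing a planar MST against
the 3D sphere formula would mix geometries (a factor $\sim 2r/t$).

## 2. Coarse-grained actin network

The cell cortex is a spherical shell $[R_I, R_E]$ (defaults 6.21-7.02 um,
leukemia-cell scale) filled with `n_af` straight filament segments:
midpoints uniform in the shell volume, orientations uniform on the sphere,
endpoints kept inside the shell by rejection sampling. Each filament is a
worm-like chain with the MacKintosh-style force-extension law

$$f_a = \frac{81 k_B T L_p^2 L_c^2\,(\Delta r + \delta r_0)}
{(L_c^2 - 6L_p(\Delta r + \delta r_0))^2 (L_c^2 + 3L_p(\Delta r + \delta r_0))}$$

with persistence length $L_p = 10$ um, pre-extension (prestress)
$\delta r_0$, and contour length from the crosslink density $R$, filament
diameter $d_{Actin}$ and F-actin concentration $C_{AF}$:
$L_c = \kappa\,(R^{0.2} d_{Actin}/2)\sqrt{\pi/C_{AF}}$. The inputs mix nm
and uM; $\kappa$ (`lc_scale`, default 100) is the single visible
conversion constant, set so that physiological parameters
($C_{AF}\sim 15$ uM, $d_{Actin} = 7$ nm, $R \in [1, 100]$) give
$L_c$ in the 0.1-3 um range of crosslinked cortical actin.

Filament ends are joined by actin-binding-protein (ABP) crosslinks modeled
as Hookean springs. Wiring rule: endpoint pairs closer than the capture
radius are connected in random order, each end hosting at most
`max_abp_per_end` springs, until the target count
$\mathrm{round}(R \cdot n_{af})$ is reached. The capture radius scales
with the mean endpoint spacing ($2.6\,(V_{shell}/2n_{af})^{1/3}$, about
2 um at the default $n_{af} = 500$) so the wired network percolates pole
to pole at any coarse-graining level. ABP rest lengths equal the as-built
separations: the unloaded, prestress-free network is in equilibrium by
construction.

**Concentration coupling.** Each coarse ABP edge stands for the bundle of
physical crosslinkers in its neighborhood. At fixed $R$ their number
scales with the filament number density
$\propto C_{AF}/L_c \propto C_{AF}^{3/2}$, so the effective edge stiffness
is $k_c^{eff} = k_c (C_{AF}/15\,\mathrm{uM})^{3/2}$ (`kc_effective()`).
This is how F-actin concentration enters the mechanics — denser actin,
stiffer network — and it is what makes $C_{AF}$ identifiable from a
strain-force curve. The base stiffness $k_c = 2\times10^{-3}$ N/m
(filamin-scale pN/nm) was calibrated once so that nanoNewton loads on the
default network give strains on the 0.03-0.2 scale characteristic of
electro-deformation, and then frozen.

**Loading.** The stretching force is split equally over the vertices of
two polar caps (half-angle 30 degrees) along the stretch axis, $+F$ on one
cap and $-F$ on the other (net zero); a `"point"` mode loads one vertex
per side, mimicking an optical-tweezers bead. Load is restricted to cap
vertices in the largest connected component — the part of the network that
can transmit stress between the poles. Strain is read out as
$(r - r_0)/r_0$ with $r$ the half-extent of the vertex cloud along the
stretch axis.

### Relaxation numerics

Equilibrium solves $F_i = \sum f_a + \sum f_c + f_s = 0$ per vertex. Two
integrators are provided:

* `method = "euler"`: the overdamped limit $\eta\dot r_i = F_i$, explicit
  Euler with adaptive step halving on force blow-up.
* `method = "fire"` (default): the inertial form $m_i\ddot r_i = F_i$ with
  FIRE-style velocity mixing and zeroing playing the role of the viscous
  term. Masses are per-vertex, proportional to the sum of incident spring
  stiffnesses (diagonal preconditioning), so the step size is not
  throttled by the stiffest chain. Both methods reach the same equilibria
  on convergent problems; FIRE needs far fewer iterations on stiff
  networks.

Two numerical guards matter:

* **Regularized WLC.** Beyond $(1 - \text{margin})$ of either denominator
  root (margin 0.2) the integrator continues the WLC law linearly (C1).
  The continuation engages only at per-filament tensions far above the
  applied load scale; where a taut chain does cross it, the filament
  length error is bounded at the nanometre scale — negligible against the
  micrometre deformations the strain readout uses. `wlc_force()` itself is
  exact and raises a domain error at the divergence.
* **Load-relative tolerance.** Convergence requires
  $\max_i |F_i| < \max(10^{-13}\,\mathrm{N},\ 0.02 \times s)$ with $s$ the
  per-vertex applied force. Residuals 50x below the local load leave
  position slack far below the deformation being measured.

**The creep caveat.** At nanoNewton loads the default shell network
deforms in a rearrangement-dominated, creep-like fashion: chains rotate
and straighten through nearly flat directions of the energy landscape, so
the force residual decays very slowly at large strain and a strict
force-convergence criterion is unreachable in bounded time. The
quasi-static strain readout is therefore defined by a fixed protocol —
the tolerance above plus a per-level iteration budget (2000 steps by
default in `simulate_stretch_curve()`; analyses that evaluate many curves,
such as the packaged reproduction script, use a smaller 800-step budget).
The protocol is deterministic for fixed seeds, which is exactly what the
downstream fitting machinery needs; but reported strains are
protocol-dependent quantities, and comparisons are only meaningful within
one protocol. Small-load equilibria (as in the two-vertex and load-path
tests) converge fully and are protocol-independent.

## 3. Simulation, synthetic data, fitting

`simulate_stretch_curve()` builds one network per replicate, relaxes it
free of load for the reference radius, then sweeps the increasing force
levels warm-starting each from the previous equilibrium, and reports mean
and standard error over replicates. `generate_strain_force_data()` is the
same machinery per cell plus additive Gaussian observation noise on each
cell's strain (mean, SE $= sd/\sqrt{n}$, $n$ reported per level; default
$n = 50$ cells mirrors the replication of the stretching experiments).
The generator emulates the statistical *structure* of measured
strain-force data — monotone mean curves in the 0-0.3 strain range with
per-level SE — not image-derived measurement artifacts, cell-to-cell
radius variation, or viscoelastic (time-dependent) response; passing tests
on synthetic data therefore validate the machinery and the model's
self-consistency, not the biological accuracy of any particular parameter
value.

`fit_parameters()` minimizes the SE-weighted squared error between
measured and simulated mean strains over box bounds with a Nelder-Mead
simplex (projection onto bounds; reflection/expansion/contraction/shrink;
stop on a simplex-size criterion or an evaluation budget, default 200).
Every loss evaluation reuses one fixed replicate seed set (common random
numbers), making the loss deterministic — the reason a simplex works on a
simulation-based loss at all. Simulation failures at a trial point score
`+Inf` and the search continues. Fitting more than three parameters to a
single curve triggers an identifiability warning. The recovery tests fit
on curves generated by the same protocol and seeds, which isolates
optimizer correctness: the loss vanishes exactly at the truth.

`estimate_modulus()` converts force to stress with an explicit area
convention — cross-section $\pi r_0^2$ (default) or surface
$4\pi r_0^2$ — and fits stress $= E\,\times$ strain through the origin
(zero force implies zero strain by the strain definition), reporting the
through-origin $R^2$. The convention is output metadata: moduli are
comparable only within one convention, and the package does not attempt to
reproduce any particular published modulus value. `compare_groups()`
reports per-level strain differences, the modulus ratio and a
stiffer/softer verdict.

## 4. Problem sizes and determinism

Default problem sizes: 0.25 um grid (400 x 200 cells) for production field
solves, coarser grids in unit tests; $n_{af} = 500$ coarse filaments
(each standing for a bundle of real filaments — Table-scale counts of
$10^5$ filaments are neither tractable nor necessary for the strain
readout), 5 replicates per curve, 5 force levels spanning 0.5-2.9 nN, and
the iteration budgets above. Every random step — placement, wiring, ABP
order, replicate seeds, observation noise — derives from a single integer
seed via isolated RNG scopes, so every artifact (curves, fits, CSV files)
is bitwise reproducible.

## 5. Known limitations

* Homogeneous-sphere dielectric model: no membrane shell, so no
  low-frequency CM crossover; multi-shell models are out of scope.
* 2D field model: out-of-plane effects enter only through a constant
  thickness; the EDM/MST split between 2D and 3D conventions is handled
  explicitly but a genuinely 3D solve is not attempted.
* The network has no microtubules or intermediate filaments, no thermal
  (Brownian) forces, no actin turnover, and no membrane; strain at large
  load is protocol-defined (see the creep caveat).
* Fitted parameters are effective, coarse-grained quantities; they inherit
  the $k_c^{eff}$ coarse-graining rule and are not directly comparable to
  per-molecule constants.
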