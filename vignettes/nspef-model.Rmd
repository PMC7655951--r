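---
title: "A nonlinear dispersive cell model for nanosecond pulsed electric fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nonlinear dispersive cell model for nanosecond pulsed electric fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nspefsim)
```

## The model

`nspefsim` simulates what happens to a single spherical cell placed between
parallel electrodes and hit with nanosecond, kV/cm-scale trapezoidal pulses
(nsPEFs). The cell is a double-shelled dielectric sphere: extracellular
medium, a 10 nm plasma membrane, cytoplasm, a 10 nm nuclear membrane, and
nucleoplasm, each a homogeneous isotropic conductor/dielectric. Three
physical processes are coupled:

1. **Quasi-static field redistribution.** The electric potential obeys the
   charge-conservation equation
   $-\nabla\cdot\partial_t(\varepsilon_0\nabla\varphi + P)
    -\nabla\cdot\sigma\nabla\varphi = 0$,
   solved over all five compartments. The transmembrane potential (TMP) is
   the potential difference between the outer and inner faces of a
   membrane, $\Delta\varphi = \varphi_o - \varphi_i$.

2. **Dielectric dispersion (DP) of both membranes.** The membrane
   permittivity follows a second-order Debye relation
   $\varepsilon(\omega)=\varepsilon_\infty
    + \Delta\varepsilon_1/(1+j\omega\tau_1)
    + \Delta\varepsilon_2/(1+j\omega\tau_2)$,
   carried into the time domain through the polarization vector
   $P = (\varepsilon - \varepsilon_0)E$. With the default relaxation set
   the static relative permittivity is 5.00 and the high-frequency value
   1.57, with relaxation times of 3 ns and 0.46 ns.

3. **Electroporation (EP) of the plasma membrane.** The areal pore density
   $N$ follows the asymptotic Smoluchowski equation
   $dN/dt = \alpha e^{(1-q)(V_m/V_{ep})^2}
    \left(e^{q(V_m/V_{ep})^2} - N/N_0\right)$,
   and the porated membrane conductivity is
   $\sigma_m = \sigma_{m0} + N\pi r_p^2 \sigma_p K(V_m)$ with the standard
   voltage-dependent pore conductance factor $K$ (energy barrier $w_0$,
   relative entrance length $n$). A patch is classified as electroporated
   once $N \ge 10^{15}\,\mathrm{m^{-2}}$.

Seven probes A1–A7 sample the plasma membrane every 15° from the
electrode-facing pole (A1, where TMP is maximal) to the equator (A7).

## Discretization

The geometry is axisymmetric, so the solver works on a spherical $(r,\theta)$
finite-volume tensor grid. Radial faces are placed exactly on the material
interfaces and each membrane is resolved by at least two cell layers across
its 10 nm thickness — pores and polarization live *inside* the membrane
subdomain, not on a surface. Faces between different materials are treated
as two half-cells in series, which yields the harmonic-mean conductance and
keeps each side's displacement history on its own side of the interface.

The far boundary is a sphere of radius 50 µm (ten cell radii) carrying the
uniform-field electrode potential $\varphi = E(t)\,r\cos\theta$. A physical
pulsing chamber has flat plates of finite extent whose finite
plate-length-to-spacing ratio biases the field near the cell; the spherical
far-field boundary is the ideal limit of widening those plates, conforms
exactly to the shell geometry, and removes that bias. At ten radii the
neglected dipole image terms scale as $(R/r)^3 \approx 10^{-3}$.

Time integration is backward Euler on the first step and BDF2 afterwards
(A-stable, second order). The Debye branches are advanced with the exact
exponential solution for a field that is linear over the step — exact for
trapezoidal drives. The pore ODE uses an exponential integrator (the
equation is linear in $N$ for frozen TMP), so the violently stiff creation
term imposes no stability limit; the nonlinear EP–field coupling is closed
by up to three fixed-point sweeps per step (relative TMP tolerance $10^{-6}$).

Verified accuracy on the default mesh (2280 cells, 60 polar cells): DC
conduction agrees with the exact layered-sphere solution to 0.5%; the
single-shell transient reproduces the analytic shelled-sphere response to
0.1% of peak; one refinement level moves results by well under the 2%
mesh-independence criterion.

## The two dispersion drive conventions

This is the one genuinely open design point of the model, and the package
exposes it as `solver_options(dispersion_drive = )`.

* `"local"` — the Debye branches at every membrane sample point are driven
  by the local in-membrane field. This is the fully self-consistent Maxwell
  treatment: under a single-tone drive the time-domain solver then matches
  the exact phasor solution to a fraction of a percent (a property test
  enforces 2%). Because the in-membrane field is the TMP divided by the
  10 nm thickness, the membrane polarization is of order
  $10^{-2}\,\mathrm{C/m^2}$, and the slow branch ($\tau_1 = 3$ ns)
  re-establishes most of the static permittivity within a few nanoseconds:
  dispersion then changes a 10 ns pulse response by only a few tenths of a
  volt.

* `"applied"` (default, the reference convention) — the polarization vector
  on both membranes follows the second-order Debye law driven by the
  *nominal applied field* along the field axis, and the membranes carry
  bare vacuum displacement $\varepsilon_0 E$. Its signatures: the membrane
  polarization peaks at
  $(\varepsilon_{m0}-\varepsilon_0)E_0 \approx 3.5\times10^{-5}\,
  \mathrm{C/m^2}$ for a 10 kV/cm pulse (the `P_applied` diagnostic series),
  the effective membrane capacitance during fast transients collapses to
  $\varepsilon_0/d$, the pole TMP of a 10 ns pulse crosses 1 V within about
  1.3 ns and, without electroporation, runs roughly 3 V above the
  non-dispersive response. All headline dispersive results of this package
  (and its acceptance checks) use this convention.

The frequency-domain solver `solve_frequency_domain()` is always the exact
phasor solution of the layered sphere (membrane permittivity from the Debye
relation when dispersive) — it shows the familiar first-order low-pass
plasma-membrane response and band-pass nuclear-membrane response.

## Waveforms

`standard_pulse()` builds the four reference stimuli: 10 ns at 10 kV/cm,
3 ns at 18.3 kV/cm, and 5 ns bipolar / unipolar pairs at 10 kV/cm separated
by 6 ns, all with 1 ns linear rise and fall and equal nominal power density
$E^2\times$duration (within 0.5%). Pulse duration is read as full width at
half maximum, so an $n$-ns pulse holds its plateau for $n-1$ ns; the 6 ns
interval is the gap between the end of one fall and the start of the next
rise. Both conventions shift timings by at most 1 ns and are exposed as
arguments. The default simulation horizon extends 10 ns past the last fall
so post-pulse relaxation is captured.

## Verification oracles

`schwan_second_order()` extracts the exact Laplace-domain dipole transfer
function of the single-shell membrane-covered sphere and factors it into
relaxation modes; pulse responses are assembled by superposition of ramp
responses. Two parameter-set subtleties are worth knowing:

* With the default table the cytoplasm and extracellular medium are
  electrically identical (0.55 S/m, relative permittivity 67), so the
  nominally second-order transfer function degenerates *exactly* to first
  order (membrane charging time 61 ns). The constructor detects the
  effective order; distinct electrolytes yield the genuine two-time-constant
  response.

* The 100 µs, 1 kV/cm verification pulse is compared against this analytic
  response. The double-shelled model departs from the single-shell analytic
  solution mainly during fast pulse edges, where the nuclear membrane's
  band-pass response is excited. The package uses 1 µs rise/fall (1% of the
  duration, typical of microsecond pulsers) for this comparison, giving a
  maximum deviation of about 1.2% of peak — against about 4% had the edges
  been as sharp as the nanosecond stimuli. The edge time is an argument of
  the pulse, not a hidden constant.

`first_order_plateau()` provides the classical steady state
$1.5\,E R\cos\theta$ with the thin-shell conductivity correction
(0.7499 V at 1 kV/cm for the 5 µm cell) as an independent check of the DC
limit.

## Numerical defaults and problem sizes

* Time step 0.02 ns for nanosecond runs ($\tau_2/23$, and 50 steps across
  each 1 ns edge); halving it changes peak TMP and flat-top pore density by
  under 0.3%. The 100 µs verification run uses 10 ns steps (the fast scale
  there is the 61 ns charging time).
* Default mesh: 38 radial × 60 polar cells (2280 unknowns), membranes two
  layers each, electrolytes geometrically graded toward the membranes;
  `mesh_spec(refine = 2)` doubles every count.
* Probe values at the seven angles are interpolated from polar cell centers
  with even symmetry across the poles.
* The pore-density exponentials are capped just below double-precision
  overflow; the equilibrium density reports saturation explicitly. The pore
  conductance factor $K$ handles its removable singularities
  ($V_m = 0$ and $V_m = \pm w_0 R T/(n F)$, about ±0.45 V) by series
  limits inside a $10^{-8}$ window.
* Everything is deterministic; there is no randomness anywhere in the
  model.

## A worked run

```{r run, eval = FALSE}
params <- default_parameters()
run <- solve_time_domain(params, standard_pulse("p10ns"),
                         solver_options(dispersive = TRUE,
                                        electroporate = TRUE))
run
classify_electroporated_extent(run, params$ep)
```

With both dispersion and electroporation the pole TMP crosses 1 V at about
1.3 ns, peaks near 1.58 V at 2.6 ns and is then clamped by the conductance
of the growing pore population; the pore density at the pole plateaus around
$4\times10^{15}\,\mathrm{m^{-2}}$, the local membrane conductivity rises
almost five orders of magnitude, and slightly more than half of the polar
quadrant porates. In the EP-only mode the same pulse charges the membrane
on the slow 61 ns time constant instead: TMP reaches only about 1.16 V near
the end of the pulse, the pore density barely moves from its resting value,
and the per-angle peak TMP still follows the $\cos\theta$ law that poration
destroys.

## Limitations

* Spherical, concentric geometry only; irregular or real cell shapes are
  out of scope.
* The pore radius is constant; there is no pore-radius evolution equation,
  coalescence, or resealing hysteresis beyond the asymptotic density ODE.
* Electrolyte compartments are non-dispersive (their dielectric relaxation
  matters only for spectra beyond ~20 GHz).
* The nuclear membrane shares the plasma membrane's Debye relaxation set
  (the parameter table lists a single set) and does not electroporate by
  default; `solver_options(nuclear_ep = TRUE)` enables exploratory nuclear
  poration.
* Thermal effects and multi-cell interactions are not modeled.
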