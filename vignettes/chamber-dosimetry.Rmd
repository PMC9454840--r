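---
title: "Electric-field dosimetry for a plate-electrode stimulation well"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electric-field dosimetry for a plate-electrode stimulation well}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimwell)
```

## The physical model

`stimwell` characterizes the electric dose delivered to cells cultured in
one well of a 12-well plate fitted with two parallel graphite plate
electrodes (a plate capacitor immersed in culture medium), driven with
symmetric biphasic rectangular voltage pulses.

Culture medium is a good ionic conductor (here 1.3 S/m) and the
stimulation frequencies are tens of hertz, so the medium response is
treated as purely conductive and electro-quasistatic: at every instant
the potential solves the electrostatic Laplace equation

$$\Delta\varphi = 0,\qquad \mathbf{E} = -\nabla\varphi,$$

with the two electrodes as Dirichlet boundaries at $\pm V/2$ and the
insulating well wall (and the liquid-air surface) as homogeneous Neumann
boundaries. Permittivity and frequency dependence are deliberately not
modeled. Two consequences are used throughout:

* **Linearity in voltage.** The solution at any voltage is a scalar
  multiple of the 1 V solution (`scale_to_voltage()`), so the package
  always solves at 1 V.
* **Linearity in conductivity.** The potential is independent of
  $\sigma$; currents scale linearly with it (`total_current()`).

The well is modeled as a 2D horizontal slice (top view): a disc (the
well wall) minus two electrode rectangles. The slice solution gives the
field map and a current *per unit depth* $I_{2D}$ (A/m); multiplying by
the liquid fill level $h$ gives the total electrode current
$I = \sigma\,h \oint \mathbf{E}\cdot\mathbf{n}\,\mathrm{d}\ell$.

## Geometry reconstruction and its calibration constants

Only some chamber dimensions are documented for this system: the
electrode gap (1.1 cm), the wetted electrode area at 1 mL (0.42 cm²)
and the fill level at 1 mL (3.4 mm). The remaining dimensions of the
default chamber are reconstructions, all overridable in the
configuration file:

| parameter | default | origin |
|---|---|---|
| electrode gap $d$ | 11 mm | documented |
| fill level $h$ at 1 mL | 3.4 mm | documented |
| electrode width | 12.35 mm | 0.42 cm² / 3.4 mm (wetted face of one electrode) |
| well diameter | 22.1 mm | nominal 12-well dish |
| electrode thickness | 1 mm | assumed; affects only the shadow region behind the plates |
| conductivity $\sigma$ | 1.3 S/m | measured medium conductivity |

Two interpretation choices were genuinely open and are resolved as
follows. First, the 0.42 cm² wetted area is read as the wetted face of
*one* electrode; this yields a 12.35 mm plate, which fits plausibly in a
22.1 mm well, whereas splitting it across both electrodes would give an
implausibly narrow 6 mm plate. Second, 1 mL in an ideal 22.1 mm
cylinder would stand only 2.6 mm deep, not the documented 3.4 mm (the
electrodes, coverslip and meniscus displace liquid), so the fill level
is a direct input and volume-to-level conversion goes through an
*effective liquid area* calibration constant (2.94 cm² by default)
rather than $\pi r^2$.

Because the well diameter and electrode width are reconstructed, the
absolute per-depth current carries a few percent of geometric
uncertainty; `perturbed_geometries()` exists precisely to propagate
that uncertainty (a 5% jitter on gap/width/fill moves the midpoint
field by roughly the gap jitter).

## Mesh and solver numerics

The mesh is a deterministic multi-block structured triangulation: a
tensor grid between the electrode faces, two curved "cap" blocks behind
the electrodes, and two curved lens blocks between the electrode span
and the wall, all sharing conforming interface nodes. 1D node
distributions are geometrically graded so edges touching the electrode
corners are about 4 times shorter than the target edge length — the
field has a corner singularity there and the extra resolution is cheap.
Cell diagonals are chosen by length with quadrant-based tie-breaking,
which makes the triangulation (and hence the discrete solution) exactly
mirror-symmetric in both axes; there is no randomness anywhere in the
pipeline.

The solver uses piecewise-linear (P1) triangles: the quantities of
interest (plateau field, boundary flux) are low-order, and the exact
parallel-plate solution lies in the P1 space, which gives a
machine-precision verification case (`parallel_plate_mesh()`). The
reduced system is solved by sparse direct factorization (Matrix).
Dirichlet values are imposed by elimination.

Two post-processing choices matter for accuracy:

* **Currents** use the consistent (residual-based) boundary flux: the
  assembled stiffness residual summed over one electrode's nodes equals
  the flux integral over its boundary. This is superconvergent relative
  to pointwise $\mathbf{E}\cdot\mathbf{n}$ sampling; the two electrodes
  balance to machine precision, and the balance is still asserted at 1%
  as a discretization check.
* **Point values** (centerline profile, midpoint field) interpolate a
  nodal field recovered by area-weighted averaging of the per-triangle
  constant gradients, which smooths the piecewise-constant raw field
  and gives well-defined values on the electrode faces.

At the default 0.3 mm edge length the chamber mesh has ~13k triangles
and solves in well under a second; the midpoint field changes by less
than 0.1% upon further refinement (`convergence_study()`). The test
suite solves at 0.3-0.6 mm; the headline characterization uses 0.2 mm.

```{r field, eval = FALSE}
geom <- default_chamber()
field <- solve_potential(generate_mesh(geom, 3e-4), 1)
centerline_profile(field, 101)      # ~92 V/m at the faces, ~90 V/m mid
electrode_current_per_depth(field, 1)  # ~1.69 A/m
```

Under the reconstructed default geometry the 1 V solve gives a
centerline plateau of 89.6 V/m at the midpoint and 92.2 V/m at the
electrode faces, close to the analytic infinite-plate value
$V/d = 90.9$ V/m. The homogeneous 80-100 V/m band covers ~38% of the
liquid cross-section — essentially exactly the inter-electrode region,
whose share of the liquid area is 0.379; the field outside that region
(behind and beside the plates) is much weaker.

## Pulse waveform and dose metrics

The stimulator delivers symmetric biphasic rectangular pulses. The
pulse duration $\tau$ is the *total* biphasic duration — both
half-pulses — so each polarity lasts $\tau/2$; the four standard
settings are 1 or 5 V at 20 Hz ($\tau$ = 3.6 ms) or 7.9 Hz ($\tau$ =
10 ms). Dose metrics follow from the rectangular shape in closed form:

* duty cycle $D = f\tau$ (0.072 and 0.079 for the two settings);
* average power $P = V I_\text{peak} D$ (the instantaneous power is
  constant while the pulse is on);
* deposited energy $E = P t$ over a stimulation run (default
  $t$ = 600 s, the 10 min protocol);
* adiabatic temperature bound
  $\Delta T_\text{max} = E / (\rho c V_\text{liq})$, with water
  properties (1000 kg/m³, 4184 J/(kg·K)) as medium defaults, stated in
  the table metadata.

The closed forms are cross-checked in the tests against trapezoidal
integration of the sampled waveform. The temperature bound deliberately
ignores all losses, so it is an upper bound: at 5 V / 7.9 Hz the
theoretical-current branch deposits ~9 J per well over 10 min, bounding
the temperature rise at ~2.1 K, comfortably above (and consistent with)
observed rises of 1.4-1.6 K. `dose_table()` uses the *theoretical*
current for its power/energy columns and carries measured currents in a
separate column; an energy computed from the measured currents would be
about 1.6 times larger, and keeping the branches separate makes that
explicit rather than mixing provenance within a column.

## Validation against measured currents

Peak currents measured through a 1 Ω shunt resistor are packaged as a
fixture (`measured_currents()`). Two diagnostics are computed:

* the **voltage-scaling factor** $I(5\,\text{V})/I(1\,\text{V})$ per
  frequency — 5.58 and 5.75 against the ideal 5.0. A relative deviation
  above 5% raises an informational linearity flag: the system is
  approximately, but not perfectly, ohmic;
* the **prediction ratio** measured/predicted per setting — the
  measured 12 mA at 1 V exceeds the predicted 7.5 mA by ~1.6x.

The discrepancy is reported, not modeled: plausible contributors are
electrode-electrolyte interface (double-layer) charging transients in
the measured peaks, conductivity measurement error, capillary-effect
geometry differences, and the reconstructed well dimensions. Measured
peaks are taken at face value (no transient correction).

## Synthetic data

`synth_current_trace()` emulates what the shunt-resistor channel
records: an ideal biphasic rectangular current at the configured timing
and peak, plus additive zero-mean Gaussian noise (an instrumentation-
amplifier noise model; a 50 Hz mains component can be added
explicitly). It does **not** emulate amplifier bandwidth limits, pulse
rise times, double-layer charging overshoot, or the 4x3 well
multiplexing sequence — so tests passing on synthetic traces show that
the peak estimator is correct and noise-robust, not that real traces
are free of shape artifacts. The peak estimator
(`detect_peak_current()`) averages |current| over samples above 80% of
its 99.9th percentile: a pulse-top average, robust to isolated noise
spikes, unlike a raw maximum. Round-trip recovery is within 2% at 5%
relative noise across seeds. Generators take an explicit seed, restore
the global RNG state, and are bit-reproducible per seed.

## Degenerate inputs and numerical tolerances

Geometry validation rejects electrodes that do not fit in the well,
non-positive dimensions, and fill levels inconsistent with a supplied
volume/area pair. A zero applied voltage returns the exact zero field;
rescaling a zero-voltage solution is an error. Zero-area triangles
produced where curved mesh blocks collapse at the chord ends are
dropped at generation. Boundary tagging uses a 1 nm geometric
tolerance; electrode flux balance is asserted at 1%; the discrete
maximum principle is asserted on every production solve with a 1e-9
slack on $\pm V/2$.

## Known limitations

* The model is 2D: end effects at the liquid surface and well bottom,
  meniscus/capillary rise at the plates, and the coverslip are ignored.
* The electrode-electrolyte interface is treated as an ideal conductor
  boundary; interface impedance is the leading explanation for the
  measured-vs-predicted current gap and is deliberately out of scope.
* The absolute per-depth current depends on the reconstructed well
  diameter and electrode width at the few-percent level; the
  reconstructed geometry yields 1.69 A/m per volt at 1 S/m.
* Thermal estimates are adiabatic bounds, not temperature predictions.
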