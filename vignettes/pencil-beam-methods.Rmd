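---
title: "Dose calculation for proton beams in transverse magnetic fields: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose calculation for proton beams in transverse magnetic fields: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(protonPBA)
```

protonPBA computes the dose of scanned proton pencil beams inside a
homogeneous transverse magnetic field (0--3 T), the situation that arises in
MRI-guided proton therapy, where the imaging field bends the beam laterally,
retracts and deforms the Bragg peak, and skews the lateral dose profiles.
The package contains two dose engines that are deliberately locked to the
same underlying interaction physics:

* a **condensed-history Monte Carlo engine** (`simulate_beam()`), used both
  to *calibrate* the pencil-beam look-up tables and as the *benchmark
  reference* the pencil beam is judged against, and
* the **pencil-beam algorithm** itself (`compute_dose()`), which predicts the
  3-D dose analytically from those tables in well under a second per beam.

This self-consistent calibrate-then-benchmark design means the evaluation
battery measures the error of the *pencil-beam approximations* (depth
scaling, lateral factorization, subbeam discretization) rather than the
error of any particular interaction model.

## Geometry and conventions

The beam travels along $+z$ and enters the phantom at $z = 0$; the magnetic
field $\vec B$ points along $+x$; the Lorentz force bends protons toward
$+y$. Voxel grids are voxel-centered with 1 mm spacing by default. The
default region of interest is a crop of a 400 mm cube around the beam and
its bending plane ($x \in [-40, 40]$, $y \in [-60, 160]$,
$z \in [0, 400]$ mm), chosen once from the worst-case geometry: a 240 MeV
beam in a 3 T field deflects by $\approx 91$ mm at range end, which together
with the widest lateral tails stays inside the $y$ window.

## Interaction physics shared by both engines

**Stopping power.** Electronic mass stopping power is the relativistic
Bethe--Bloch formula without shell or density-effect corrections, adequate
above $\approx 10$ MeV and — more importantly — *identical* in the trajectory
integrator, the Monte Carlo engine and the water-equivalent depth scaling,
so that range scalings between the two engines are exactly consistent. At
100 MeV in water it reproduces the published PSTAR value to 0.02%. Transport
stops at 0.5 MeV (residual range $\sim 10\,\mu$m); the remainder is
deposited locally.

**Materials.** The built-in registry is the NIST/PSTAR tissue family
identified by its mean ionization potentials: liquid water
($I = 75$ eV), adipose tissue ICRP ($63.2$ eV, $\rho = 0.92$ g/cm$^3$),
compact bone ICRU ($91.9$ eV, $\rho = 1.85$ g/cm$^3$) and dry air
($85.7$ eV). The ionization potentials printed for these four tissues pin
down which database entries are meant, so densities, $Z/A$ and radiation
lengths are taken from the same entries rather than from a different tissue
report. Custom materials can be registered with `register_material()`.

**Magnetic push.** Over one step the equation of motion
$\frac{d}{dt}(\Gamma m_0 \vec v) = q\, \vec v \times \vec B$ in a uniform
field is solved exactly by a circular arc at the gyroradius of the
step-midpoint momentum, $r = p/(0.3 B)$ (mm, MeV/c, T). This integrator is
exact for the field term; its only discretization error is the coupling to
continuous energy loss, and halving the 1 mm step changes a 240 MeV / 3 T
deflection by well under 0.5%.

## The Monte Carlo engine

Per history: the entrance position is sampled from the Gaussian spot
($\sigma_x = \sigma_y = 3$ mm by default, a typical scanned spot); the beam
is parallel and monoenergetic. Per 1 mm step (refined automatically near
the range end):

* mean Bethe--Bloch loss (midpoint rule), plus **Bohr Gaussian straggling**
  with the relativistic factor $(1-\beta^2/2)/(1-\beta^2)$;
* **Highland multiple Coulomb scattering**,
  $\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta p}\sqrt{t}\,(1 + 0.038\ln t)$
  per step of thickness $t$ radiation lengths, applied as independent
  Gaussian kicks in both transverse planes;
* **nuclear interactions**, modelled analog: the primary is absorbed with an
  energy-independent removal length of 120 g/cm$^2$ (chosen so that
  $\approx 25\%$ of 240 MeV protons in water are removed before the peak,
  the standard first-order figure), active above 20 MeV. On removal, 60% of
  the residual energy (`nuclear_local_frac`) is handed to one
  representative secondary proton carrying half the residual kinetic
  energy, emitted about the primary direction with a Gaussian polar angle
  of RMS 0.5 rad (the quasi-free scattering regime) and transported in a
  straight, field-bent line; the remaining 40% is treated as escaping with
  neutral secondaries. This produces the build-up region and the low-dose
  lateral halo that the look-up tables must encode — a purely local
  deposition of the removed energy would produce no halo at all, which
  both distorts the tail parameters of the lateral model and shrinks the
  set of voxels above the 0.1% inclusion threshold of the gamma analysis.
  A single representative secondary is deliberately simpler than a full
  intranuclear cascade; only self-consistency between the two engines is
  claimed, not agreement with a general-purpose Monte Carlo code.

Each physics process can be toggled independently (`mc_config()`), which the
test suite uses to isolate oracles: with everything off except mean energy
loss the scored peak must sit at the CSDA range; with only multiple
scattering the lateral variance must follow the Fermi--Eyges integral of the
same per-step Highland angles; with the field on, the displacement of the
peak must match the deterministic trajectory integrator.

Energy is conserved exactly per event (scored + escaped + neutral-loss =
input, to 1e-3 relative including discretization), and a fixed `seed` gives
bit-identical dose grids: the engine uses its own 64-bit generator with
Box--Muller normals, independent of R's RNG state.

## Look-up tables

`build_luts()` runs the Monte Carlo engine in water for every requested
(energy, field) pair and tabulates per 1 mm depth bin: the integrated depth
dose $E_{dep}(z)$ (MeV per mm per proton) and the seven parameters of the
lateral model fitted to the XZ- and YZ-projected maps (the plane parallel
and perpendicular to $\vec B$). The classic calibration layout is 40--250
MeV in 10 MeV steps at 0.5 / 1.5 / 3 T; any subset works, because the
cubic-spline energy interpolation is exact at grid nodes — the shipped
benchmark battery calibrates exactly the energies it evaluates. Field
strengths are never interpolated (deflection is strongly nonlinear in $B$);
requesting an uncalibrated field is an error. Spline overshoot of lateral
parameters between energies is clipped back to the model's validity bounds
and, for the tail fractions, renormalized.

Depth spacing follows the 1 mm dose grid; the sub-millimetre structure of
the distal falloff is recovered by linear interpolation (the falloff is
several mm wide due to straggling, so R80 is resolved to $\sim 0.1$ mm).

## The lateral profile model

At each depth the lateral profile is
$$f(x) = A\left[(1 - f_L - f_R)\,G(x) + f_L\,\mathrm{LTail}(x) +
f_R\,\mathrm{RTail}(x)\right]$$
with $G$ the unit Gaussian density at $(x_m, \sigma)$ and LTail / RTail
unit-area exponentially-modified-Gaussian densities whose exponential decay
lengths are $\gamma_L\sigma$ (leftward) and $\gamma_R\sigma$ (rightward).
Because every component has unit area, $\int f = A$ exactly. The two
independent tails are what lets one function describe both the ordinary
symmetric halo at $B = 0$ and the skewed profiles of bent beams.

Two numerical points matter:

* The $e^{u/\gamma}\,\mathrm{erfc}(\cdot)$ products are evaluated through
  the scaled complementary error function,
  $\mathrm{erfcx}(b)\,e^{-u^2/2}$ with
  $b = \pm u/\sqrt2 + 1/(\sqrt2\gamma)$, using an in-package erfcx (direct
  product below $b = 12$, asymptotic series above, and the exact
  $b \ll 0$ limit $e^{u/\gamma + 1/(2\gamma^2)}/\gamma$), so the profile is
  finite and accurate out to 40$\sigma$ and beyond.
* In the fit (`fit_lateral()`, bounded Levenberg--Marquardt with
  Poisson-like weights and moment-based initialization), $\gamma_{L,R}$ are
  bounded below by 1.5. With $\gamma$ free to approach zero an EMG tail
  degenerates into a slightly shifted Gaussian and can trade off against
  the core: two fits of statistically identical profiles were observed to
  differ by 0.36 mm in the fitted center with a tail fraction pinned at its
  upper bound. Requiring the tail decay to exceed $1.5\sigma$ removes the
  degeneracy (center reproducibility $\sim 0.03$ mm) while leaving genuine
  halo and skew shapes expressible. Non-convergent fits fall back to a pure
  Gaussian with a warning and are flagged; a calibration aborts if more
  than 2% of depth fits fail.

## Trajectory and water-equivalent depth

`integrate_trajectory()` integrates the deterministic (mean) proton path
with per-step energy decrement, through an arbitrary material column —
including a column looked up voxel-by-voxel along the bent path of a
subbeam. For materials other than water the look-up tables are indexed at
the water-equivalent depth, accumulated incrementally per step:

$$dz_{eq} = dz\;\frac{S_m(\bar E)}{S_W(\bar E)}\;\frac{\rho_m}{\rho_W}\;
\frac{\cos\theta_W(z_{eq})}{\cos\theta_m(z)}$$

with both stopping powers at the local mean energy of the actual beam. The
last factor is the magnetic path-length correction: the material beam
advances $1/\cos\theta_m(z)$ path-mm per depth-mm at its own current
bending angle, while the table it consumes was recorded by a water beam
advancing $1/\cos\theta_W$ at the *equivalent* depth — the depth at which
the table is actually being read. Evaluating both angles at the same
geometric depth and multiplying the *total* accumulated depth by the ratio
(the more literal reading of the printed formula) is unstable whenever the
material and water beams die at different depths: a $\sim$1% fluctuation of
the angle ratio near range end then scales the whole $\sim$330 mm depth and
produced 3--10 mm range errors for adipose and bone at 3 T, an order of
magnitude worse than the same quantities under the incremental form
(< 0.1 mm). The exported `delta_d()` keeps the same-depth angle-ratio
definition as a diagnostic; the engine uses the incremental form. The
accumulation is midpoint-staggered so that in water the factor is exactly 1
at every step and the engine reduces to an exact replay of the calibration
tables.

Beyond the trajectory's own CSDA endpoint the mapping is extended linearly
with its terminal slope: the straggled distal falloff stored in the
depth-dose table lies beyond the mean range and must still be replayed.
Likewise $\theta_W$ is frozen at its last value once the water reference
beam has stopped (relevant for low-density paths that outlive it).

## The pencil-beam engine

For each subbeam $k$ and depth bin the engine evaluates

$$D_k(x, y, z) = \frac{1}{m_{xyz}}\;E_{dep}(z_{eq})\,\frac{dz_{eq}}{dz}\;
f_x(x; z_{eq})\; f_y(y; z_{eq})$$

and superposes subbeams. Design decisions:

* **Normalization.** The lateral factors are unit-area densities (the
  fitted $A$ is divided out), so $E_{dep}$ alone carries the absolute
  energy per depth. The factor $dz_{eq}/dz$ maps energy per
  water-equivalent mm to energy per geometric mm; without it, dose in bone
  would be wrong by roughly the density ratio. It is taken per depth bin
  from the same piecewise-linear mapping used for the lookup, so energy is
  conserved across material scalings.
* **Dynamic center shifting.** Each subbeam's $y$-center is
  $x_m^{LUT}(z_{eq}) + [y_k(z) - y_W(z_{eq})]$ plus its entrance offset:
  the tabulated profile center (which carries the water deflection and any
  fit-level refinements) is recentered by the difference between the
  subbeam's own trajectory through its actual materials and the water
  reference at the equivalent depth. In homogeneous water the correction
  vanishes identically and the engine replays the tables exactly.
* **Subbeam splitting.** `split_beam()` places $k$ subspots equidistantly
  within $\pm3\sigma$ (odd $k$ along the bending/heterogeneity axis $y$;
  $k = m^2$ with odd $m$ on a 2-D grid; even counts are rejected since a
  center spot anchors the trajectory). Each subspot's entrance sigma is the
  spacing divided by 1.5 and the weights are least-squares fitted to the
  parent Gaussian (entrance fluence reproduced to $\ll 1$% RMS). The
  narrow-subspot choice matters at material boundaries: with subspots as
  wide as their spacing the least-squares weights concentrate on the
  central few subspots (93% of fluence within $|y| \le 2.25$ mm for
  $k = 9$), so a boundary at $y = 0$ is sampled at a 0.73 / 0.27 split
  instead of the physical 0.5 / 0.5; with the narrower subspots the
  weights localize to their own fluence cells and the split is 0.65 / 0.35
  — the residual bias being the half-cell of the central subspot, an
  irreducible discretization of finite $k$.
* **Subbeam profiles.** A subbeam uses the tabulated profile shape with the
  Gaussian-core variance reduced in quadrature,
  $\sigma_{eff}^2 = \sigma_{LUT}^2(z_{eq}) - \sigma_0^2 + \sigma_{sub}^2$,
  which is exact for the Gaussian part of lateral-spreading physics; tail
  fractions and decay rates are inherited unchanged.
* **Material columns** are looked up at the nearest voxel along each
  subbeam's own bent center path, so subbeams entering bone and air acquire
  different ranges and center curves (`shift_centers()`).

## Evaluation battery

`benchmark_battery()` reproduces the full evaluation design at desk scale:
calibration and benchmarking both use $2\times10^5$ histories per run by
default (the published design used $10^7$ on a cluster; at $2\times10^5$
the projected-map noise contributes $\lesssim$0.5% of the maximum in the
high-dose region, well below the 2% gamma criterion) on the cropped ROI
grid. Metrics:

* **IDD metrics** — R80 (80% distal level, linearly interpolated) and the
  signed mean local dose difference with the 1%-of-maximum inclusion rule,
  averaged through a count-weighted histogram with bins centered on
  multiples of 0.1 percentage points; "before the peak" is operationalized
  as $z < R80 - 2\,\mathrm{FWHM}_{peak}$.
* **Profile metrics** — center and FWHM of the Gaussian component at
  20/50/80% of the beam range (30 mm / 50% / 80% for the opposing-slab
  phantom, so the first profile lies inside the heterogeneity).
* **Gamma index** — 2% (of the global reference maximum) / 2 mm, voxels
  above 0.1% of the maximum, computed on the YZ-projected energy maps with
  trilinear sub-voxel interpolation at 0.2 mm sampling within a search
  radius of 3 distance criteria. The early-exit kernel is exact (offsets
  visited in increasing distance; identical results to the brute-force
  oracle `gamma_index_brute()` on the same lattice).

Comparisons are against *independent* Monte Carlo runs (fresh seeds), so
water rows measure table-replay fidelity plus statistics only, and
heterogeneous rows measure the pencil-beam approximations.

## What the Monte Carlo emulates — and what it does not

The engine reproduces the features that drive magnetic-field dose
distortions: continuous slowing down, range straggling, multiple-scattering
broadening, first-order nuclear attenuation with a forward-peaked
charged-secondary halo, and exact magnetic bending. It does *not* model the
full nuclear cascade (no multi-generation secondaries, no neutron dose, no
production-threshold physics) nor the electron return effect at air
cavities, and the Highland log term is applied per step rather than over
the cumulative thickness. Consequently, passing the battery demonstrates
the internal consistency and accuracy of the pencil-beam approximations
against a physically reasonable transport model — not agreement with a
general-purpose Monte Carlo toolkit or with measurements. Halo-sensitive
quantities (tail fractions, gamma statistics at permissive inclusion
thresholds) depend on the nuclear model and can differ between transport
codes for that reason alone.

## Known limitations

* **Bone spot size.** Lateral parameters are interpolated from water tables
  at the equivalent depth, so the extra multiple scattering of bone
  (radiation length 16.6 vs 36.1 g/cm$^2$ per unit mass thickness) is not
  represented: after a 20 mm bone slab the predicted Gaussian-component
  FWHM is $\sim$1--1.5 mm narrow at deep depths, and in full bone several
  mm. A material-dependent scattering-length extension (Fermi--Eyges) would
  fix this but is deliberately out of scope; the effect is the method's
  known worst case.
* **Boundary discretization.** A beam centered exactly on a lateral
  material interface is split 0.65 / 0.35 rather than 0.5 / 0.5 at $k = 9$
  (see above); the inter-peak valley of the opposing-slab phantom is
  correspondingly under-resolved. More subbeams help slowly.
* **Separability.** The $f_x \cdot f_y$ product form is adopted as the
  method defines it; for strongly bent beams the x--y correlation it
  neglects grows with field strength.
* Homogeneous magnetic fields only; no fringe fields, no energy spread, no
  patient geometries.
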