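---
title: "Methods: PMF estimation and ion-atmosphere analysis for parallel nucleic-acid helices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMF estimation and ion-atmosphere analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixpmf)
```

# The problem

Double-stranded nucleic-acid helices are strongly charged polyanions
(two phosphate charges per base pair), yet in solutions of trivalent
cations such as cobalt hexammine (Co(NH~3~)~6~^3+^, "Co-Hex") dsDNA
condenses while dsRNA resists condensation.  The mechanistic picture is
geometric: A-form helices (dsRNA, A-DNA) have a deep, narrow major groove
into which trivalent cations bind *internally* (radial distance
&lt; ~11 Å from the helix axis), where they are unavailable to a
neighbouring helix; B-DNA lacks a deep groove, cations bind *externally*
(11–15 Å, at the outer surface), and an externally bound trivalent ion can
contact phosphates of two adjacent helices at once — an *ion bridge* —
mediating an effective attraction.  The quantitative observable connecting
this picture to experiment is the potential of mean force (PMF) between two
parallel helices as a function of their axis–axis separation, and, through
an additivity assumption, the osmotic pressure of a hexagonal aggregate.

This package implements the complete *post-simulation* computational
pipeline for that analysis — it does not perform molecular dynamics.
Every stage is exercised on synthetic trajectories with known ground truth,
so the statistical machinery can be validated end to end at desk scale.
Units are fixed throughout: Å, ps, kJ/mol, elementary charges; free
energies are reported in units of kT at 298 K (2.4789 kJ/mol).

# The pseudo-spring measurement model

Two rigid helices are tethered through their centres of mass by a harmonic
spring of constant $k$ (conventionally quoted in kJ/(mol·nm²); 1000 by
default, 2000 for strongly interacting systems) and rest length $x_0$.
In equilibrium the mean force between the helices is read from the mean
spring deviation,

$$F = k\,\langle x - x_0\rangle ,$$

with the sign convention that a stretched spring (mean separation beyond
the rest length) means the helices push each other apart: positive force =
repulsion, negative = attraction.  The PMF follows by integrating the mean
force inward from an outer reference separation $x_\mathrm{ref}$ (40 Å by
default, where the interaction has decayed):

$$\Delta G(x) = \int_x^{x_\mathrm{ref}} F(x')\,dx' .$$

Design choices in `mean_force()` / `integrate_pmf()`:

* **Force attribution.**  The estimated force is attributed to the *mean
  retained separation*, not the tether rest length.  Under the stationary
  distribution $\propto e^{-\beta(G + \frac{k}{2}(x-x_0)^2)}$ the identity
  $k\langle x-x_0\rangle = -\langle G'(x)\rangle$ holds exactly, and
  $-\langle G'\rangle \approx -G'(\bar x)$ to second order; attributing the
  force to $\bar x$ therefore removes the leading $-G'/k$ bias that
  attributing to $x_0$ would leave.  The residual bias,
  $\tfrac12\sigma^2 G'''$, is below 0.05 kT/Å for the landscapes shipped
  here.
* **Equilibration.**  The first 1/6 of each series is discarded by default
  (the fraction is configurable), mirroring the usual practice of dropping
  the initial segment of a production run before the tether has
  equilibrated.
* **Errors.**  Standard errors come from block averaging with doubling
  block sizes; the plateau is taken at the first doubling where the blocked
  SEM grows by less than 5 %, falling back to the conservative maximum of
  the curve when no plateau is reached.  For i.i.d. data this reduces to
  the naive SEM; for an AR(1) series with autocorrelation 0.9 it recovers
  the ~4.4-fold variance inflation.
* **Integration.**  Trapezoid rule on the sorted force grid — monotone,
  error-analysable, and free of spline overshoot on sparse grids.  Point
  errors are propagated through the trapezoid weights assuming
  independence between separations (separate tether runs).  If
  $x_\mathrm{ref}$ lies beyond the outermost sampled point the outermost
  force is constant-extrapolated over the gap, with a warning.
  $\Delta G(x_\mathrm{ref}) = 0$ holds exactly in every profile.

# The umbrella-sampling cross-check

`wham_pmf()` implements the standard self-consistent weighted-histogram
iteration over harmonic-bias windows (histogram bin 0.2 Å, tolerance
10⁻⁸ kJ/mol on the window free energies, 10⁵ iteration cap, all
configurable).  Adjacent windows must share at least one occupied bin;
a violating gap is reported by window centre.  Per-bin errors are
approximated as $kT/\sqrt{n_\mathrm{bin}}$ — adequate for flagging poorly
sampled bins but *not* for the accumulated stitching uncertainty, which
random-walks across windows exactly like the integrated spring error.

For this reason the shipped cross-check runs both estimators **on the same
samples**: the spring windows double as umbrella windows (the sampler is
deterministic under its seed).  Shared sampling noise then cancels and the
comparison isolates methodological disagreement, which stays within the
combined two-sigma bands across the grid.  This mirrors how one validates
two estimators on one set of trajectories in practice.

# Fiber-model helices

The paper-scale analyses need only the charge positions and groove
geometry of the helices, so duplexes are reduced to phosphate / sugar /
base pseudo-sites on a uniform helical lattice ("fiber model").  The
parameters live in one editable table:

| form  | rise (Å) | twist (°) | P radius (Å) | major sector (°) | base displacement (Å) |
|-------|----------|-----------|--------------|------------------|----------------------|
| A-RNA | 2.81     | 32.7      | 9.5          | 80               | 4.4                  |
| B-DNA | 3.38     | 36.0      | 9.4          | 216              | 0                    |
| A-DNA | 2.56     | 32.7      | 9.5          | 68               | 4.4                  |

These are canonical fiber values chosen once and documented here; they are
deliberately centralized because downstream geometry (groove sectors,
bridge distances, binding radii) all flows from them.  The A-DNA rise uses
the canonical 2.56 Å fiber value rather than sharing the A-RNA 2.81 Å.
The major-groove sector widths encode the experimental ordering that the
A-DNA major groove is ~2 Å narrower (as arc length at the phosphate
radius) than A-RNA's.  A-form base pairs are displaced 4.4 Å off-axis —
the origin of the deep major groove; B-form base pairs sit on the axis.

Conventions: axis = +z, first base pair at z = 0, right-handed lattice;
no 5′-terminal phosphate, so an N-bp duplex carries exactly 2(N−1)
phosphates of −1 e (30 and −30 e for the standard 16-mer).  The default
16-bp sequence is a de Bruijn cover containing all 16 dinucleotides
(complete only from 17 bases; the 16-bp form warns that one window is
missing).  It is a stand-in with the same coverage property as typical
experimental designs, not any specific published sequence.

**Groove assignment** is by azimuthal sector: at the height of a query
point the two strand phases are interpolated continuously from the
lattice, and the point falls either in the short-way inter-strand sector
(minor groove for B-form, major for A-form) or its complement.  Points
beyond 15 Å radially, or beyond the helix span + 3 Å axially, are "bulk";
points exactly on a strand phase line tie-break to minor.  A
distance-to-nearest-groove-atom assignment would be the main alternative;
the sector method was chosen because it is exact for the fiber lattice,
frame-covariant (rotating helix and points together provably preserves
labels), and cheap.

# Ion-atmosphere statistics

*Radial distance* always means the perpendicular distance to a helix axis.
Profiles restrict ions axially to the helix span ± 3 Å (configurable) to
limit end effects, and normalize each bin by the cylindrical-shell volume
$\pi(r_2^2-r_1^2)L$; concentrations convert via 1 ion/Å³ = 1660.539 mol/L.
Ions beyond the outermost bin are kept in an overflow bucket so that total
occupancy is conserved to numerical precision — the invariant that ties
profiles, binding partitions and raw frame counts together.

The binding taxonomy uses the conventional boundaries: internal
r &lt; 11 Å (within the helix envelope), external 11–15 Å (outer surface),
bulk beyond.  With two helices each ion is assigned to its nearest axis
only (no double counting).  Groove labels are reported for the bound
(non-bulk) population, split by internal/external shell.

Charge-density grids use nearest-voxel assignment (1 Å spacing by
default) of each ion's full charge — a Co-Hex complex is represented by
its cobalt-centre position carrying +3 e — and conserve total charge by
construction.  The conventional display threshold 0.02 e/Å³ is stored
with the grid and applied by `threshold_density()`.

An ion **bridges** two helices in a frame iff it lies within the cutoff of
at least one phosphate of *each* backbone.  The cutoff defaults to 6 Å, a
typical trivalent-ion–phosphate contact-shell distance; it is a package
choice (no published value) and is recorded in every report.  **Water
ordering** accumulates $\cos\theta$ between the water dipole (O → H
midpoint) and the O → nearest-bridging-ion vector for waters within a
4.5 Å shell; an oxygen facing the ion gives $\cos\theta = -1$.

# The simplified Monte Carlo

The ion-number calibration uses a primitive-model electrolyte: charged
hard spheres (defaults: Na⁺ 2.0 Å, Co-Hex 4.0 Å, Cl⁻ 2.0 Å; phosphate
sites 2.0 Å) in a dielectric continuum (ε = 78, 298 K) with pairwise
Coulomb energy $1389.35\,q_iq_j/(\varepsilon r)$ kJ/mol under the
minimum-image convention.  There is no Ewald summation: the module's role
is count calibration and qualitative binding-mode trends, not precise
electrostatics, and the truncation is a documented limitation.  Optional
cylindrical exclusion regions stand in for a fixed water layer filling a
deep groove; enabling one around an A-form helix empties the deep-binding
shell and pushes ions outward, the qualitative internal-to-external
switch.

Metropolis single-ion displacement moves are auto-tuned during a burn-in
(10 % of sweeps, excluded from averages) toward 30–50 % acceptance; for
nearly ideal systems the move size simply grows to its half-box cap, which
maximizes mixing.  The compiled kernel draws from R's RNG, so a single
`set.seed` reproduces entire runs bit for bit.  Bulk concentrations are
measured outside 15 Å of every axis and inside the central 80 % of the
axial span (whole box when no helix is present), with the region volume
computed analytically (circle-union lens formula for two axes).

`calibrate_counts()` iterates a proportional update — multiply each
species count by target/measured bulk — re-imposing electroneutrality
each round through the Cl⁻ count; if the cations do not yet cover the
fixed helix charge, the first cation species is topped up with
neutralizing counterions before balancing.  In desk-scale boxes the count
granularity limits how closely a dilute target can be met (one ion in a
65×40×50 Å box is already 12.8 mM), which is why the shipped calibration
examples use the full-size 130×80×100 Å box for dilute Co-Hex.

# Osmotic pressure of the hexagonal aggregate

Under pairwise additivity each helix in a hexagonal aggregate at spacing
$d$ has six nearest neighbours, each pair shared by two helices, so the
lattice energy per helix is $E(d) = 3\,\Delta G_\mathrm{pair}(d)$
(a second shell at $\sqrt3 d$ is available but off by default — the pair
PMF is short-ranged).  With the per-helix cell volume
$V(d)=\tfrac{\sqrt3}{2}d^2L$,

$$\Pi(d) = -\frac{dE}{dV} = -\frac{1}{\sqrt3\,d\,L}\frac{dE}{dd},$$

evaluated by central differences (one-sided and flagged at the grid ends),
reported in kJ/(mol·Å³) and atm (1 kJ/(mol·Å³) = 16388 atm).  The
pressure crosses zero at the lattice-energy minimum within grid
resolution — the aggregate's equilibrium spacing, which for the shipped
B-DNA-like PMF sits at ~27 Å.

# Synthetic data: what it does and does not emulate

The generators provide every input the pipeline needs, with known answers:

* **Spring samples** are drawn i.i.d. from the exact Boltzmann density of
  ground-truth-PMF + bias by inverse-CDF sampling on a 0.01 Å grid with a
  trapezoidal cumulative (a plain cumulative sum carries a half-bin
  quantile bias that visibly tilts recovered PMFs).  Three calibrated
  landscapes ship: a purely repulsive wall, and wall+Gaussian wells of
  depth −3.5 kT and −4.1 kT at 27 Å — the qualitative regimes of interest
  (low-multivalent repulsion; B-DNA at high Co-Hex; A-RNA at very high
  Co-Hex).  The depths/locations are fixed by a deterministic calibration
  at construction; they are recovery fixtures, not claims about any real
  system's curve.
* **Ion clouds** draw per-shell Poisson counts from a target cylindrical
  concentration profile, uniform within shells (optionally restricted to a
  groove sector), plus a uniform bulk.  Because trajectory containers are
  rectangular, frames are padded to the maximum draw with ions parked in a
  far box corner; parked ions land in the bulk class of every analysis,
  and `fixed_counts = TRUE` avoids padding entirely when exact per-frame
  counts matter.
* **Bridge scenes** construct the two ends of the mechanism: ions at
  midplane points within the cutoff of phosphates of both B-DNA backbones
  (every ion bridges, and sits in the external shell), or ions at r ≈ 8 Å
  inside each A-RNA's major-groove sector (no ion can bridge at 27 Å
  separation).  Expected bridge counts and binding classes are returned
  with the scene.
* **Waters** are rigid three-site molecules (OH 0.9572 Å, HOH 104.52°)
  with dipoles either anti-parallel to the O→ion vector or isotropic.

What the synthetic data deliberately does **not** emulate: frame-to-frame
dynamics (frames are i.i.d.; the correlated-error machinery is tested
separately on AR(1) series), explicit solvent, helix flexibility,
sequence-dependent groove geometry, and ion–ion correlation structure
beyond the imposed profiles.  Passing recovery tests therefore validates
the *statistical pipeline* — estimators, normalizations, bookkeeping,
geometry — not any force field.

# Problem sizes and numerical settings

The shipped analyses and checks use: 21 separations (20–40 Å, 1 Å grid)
× 10⁴ spring samples for PMF recovery (maximum absolute recovery error
~0.1–0.2 kT, dominated by the accumulated statistical error of ~0.09 kT
at the innermost point); 500 frames for radial-profile recovery; 10⁶
steps for the discrete detailed-balance check of the Metropolis sampler
against exhaustive Boltzmann enumeration; 2–3·10³ sweeps for MC
calibrations.  These sizes were chosen so each stage resolves its target
well inside the stated tolerances while an end-to-end run stays in the
minutes range on one core.

# Known limitations

* WHAM per-bin errors understate the stitched profile's absolute
  uncertainty (see above); use the shared-sample cross-check design.
* The primitive-model MC truncates electrostatics at the minimum image and
  is not meant to reproduce published ion counts, only trends and bulk
  calibration.
* The groove sector model is exact only for the idealized fiber lattice.
* Whether a tether series taken at k = 2000 kJ/(mol·nm²) should be merged
  with k = 1000 series is left to the user: each `spring_series` carries
  its own k and the estimators never mix series.
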