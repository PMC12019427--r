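---
title: "Multiplateau DNA overstretching with a bead-spring nonconvex-bond model"
author: "overstretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplateau DNA overstretching with a bead-spring nonconvex-bond model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overstretch)
```

## The model

When double-stranded DNA is pulled beyond its contour length it
overstretches: the force-extension curve develops a near-flat plateau over
which the molecule lengthens roughly 1.7-2x at almost constant force.  The
plateau force is sequence dependent -- about 35 pN for poly(dA-dT), about
75 pN for poly(dG-dC), and about 110 pN for torsionally constrained
lambda-phage DNA.  This package simulates what happens when a single long
molecule is *composed* of such segments in series: each segment
overstretches at its own plateau force, so the composite force-extension
curve shows two or three distinct plateaus, and almost all of the length
gain within one plateau comes from the segment currently in transition.

The chain is a bead-spring polymer of `N = 99` beads; one bead represents
11 bp (one helical turn), so the equilibrium bond length is
`r0 = 11 x 3.38 = 37.18` Angstrom, each bead weighs `11 x 650 = 7150` Da,
and a fragment is 1078 bp with contour length `L0 = 98 r0`.  Three energy
terms define the system:

1. **Bond stretching** `U(r)`, the heart of the model.  Each bond is a
   nonlinear spring: a harmonic branch `(S / 2 r0)(r - r0)^2` up to `ra`;
   a *nonconvex* interval `[ra, rb]` where `U` equals the tangent line at
   `ra` plus a smooth bump of height `delta` (kBT) peaking at the
   midpoint; and a convex harmonic continuation beyond `rb`.  The lower
   convex envelope (Maxwell construction) of `U` replaces the bump by the
   common tangent, whose slope -- `S (ra/r0 - 1)` -- is the coexistence,
   i.e. plateau, force.  `delta` controls how cooperatively bonds jump
   between the slightly stretched (`~ra`) and highly stretched (`~rb`)
   states.
2. **Bending**, a discrete worm-like chain: `(K/2)(pi - phi)^2` per
   interior angle with `K = P kBT / r0` and `P` the persistence length.
3. **An optical trap**: a stiff harmonic spring (`K_trap = 10 S / r0`)
   between the last bead and a fixed anchor.  Because the trap is ~10x
   stiffer than the chain, imposing the anchor position approximates an
   isometric (fixed-extension) experiment; the measured observable is the
   fluctuating trap force.

Segment parameters (stretch modulus `S`, `ra/r0`, `rb/r0`, `delta`, `P`)
for the three built-in types are in `dna_segments()`.  The first bead is
fixed, the last moves along the pulling axis only, and dynamics are
Langevin at 300 K with a deliberately small collision frequency
`gamma = 1/Tp` (the bead oscillation period on the harmonic branch,
~0.023-0.033 ps^-1) to accelerate conformational sampling; equilibrium
averages are unaffected by the friction choice.

## Numerical choices

* **Units.** Internally Angstrom / kBT / Dalton, giving a time unit of
  ~63.3 fs at 300 K; inputs and outputs use Angstrom, pN and ns.  The
  Boltzmann constant is taken exactly (`kBT = 41.419` pN A at 300 K);
  this reproduces the derived trap stiffnesses (e.g. 6.13 kBT/A^2 for
  poly(dA-dT)) to the tabulated digit.
* **Integrator.** BAOAB splitting (velocity Verlet with an exact
  Ornstein-Uhlenbeck velocity update), time step 100 fs -- far below the
  shortest bead oscillation period (~30 ps).  With `gamma = 0` it reduces
  to plain velocity Verlet and conserves energy to <1e-4 relative over
  1e4 steps.  The thermostat uses a xoshiro256++ stream with a
  Marsaglia-polar Gaussian so a replica is bitwise reproducible from its
  integer seed.
* **Bump shape.** `B(s) = sin^2(pi s)` -- smooth, symmetric, `C1` at both
  ends.  Any bump with `B(0) = B(1) = 0`, zero end slopes and
  `B(1/2) = 1` satisfies the model's stated constraints and can be
  supplied to `bond_potential()`; the plateau force is invariant to the
  choice, only the barrier shape (hence kinetics and the fine shape of
  fluctuation corrections) changes.
* **Right-branch curvature.** The stiffness beyond `rb` is not pinned by
  any tabulated constant; we use `S/r0` (same as the B-form branch),
  exposed as `right_curvature`.  This choice sets where each plateau
  *ends*: with `S/r0`, the third plateau of the three-segment fragment
  ends near `Lx/L0 = 1.83`, so a start at 1.85 already probes the stiff
  post-transition branch and yields a force well above the plateau.  A
  softer continuation would extend the plateau; lacking a reference value
  we keep the neutral choice and note the sensitivity.
* **Junction angles.** An angle spanning two segment types takes the mean
  of the two persistence lengths (policies `left` and `min` are
  available); at `N = 99` at most two angles per junction are affected.
  The alternating construct instead uses a single whole-chain persistence
  length of 95.4 Angstrom.
* **Constraint handling.** Constrained components (all of bead 1, y/z of
  bead 99) receive no kick, drift or noise, so fixed coordinates are
  preserved bitwise; zeroing noise and force on those components leaves
  the marginal dynamics of the free coordinates unchanged.
* **Peak detection.** Histogram peaks are local maxima filtered by
  topographic prominence (default 5% of the maximum density) and merged
  within 2 bin widths -- nearby peaks of different segments can appear as
  one broader peak, and this operationalises that observation.  Sampled
  histograms are boxcar-smoothed (5 bins by default) before peak reading:
  at the plateau force the low mode sits on a flat shoulder of the tilted
  density, and the raw argmax of a noisy histogram wanders several bins
  around it.  The
  thresholds are configurable; the reference analyses only report visual
  peak counts.
* **Phase classification.** A bond is "highly stretched" if
  `r/r0 > (ra/r0 + rb/r0)/2` for its segment type.  A segment range is a
  *macroscopic phase* when its largest contiguous low run plus largest
  contiguous high run cover >= 90% of its bonds (i.e. the labels form at
  most ~2 blocks); otherwise it is a *mixed* state.  Both constants are
  arguments of `classify_phases()` -- the underlying notion is
  qualitative and any sharp rule is an operationalisation.

## The stretching protocol

Each force-extension point is an *independent* simulation.  The chain
starts in the "one-phase" conformation -- beads equally spaced at the
target `r/r0`, anchor placed so the trap force is zero, Maxwell
velocities -- then runs an equilibration stage (discarded) and a
production stage during which the trap force and relative extension
`Lx/L0` are accumulated every step and relative bond lengths every
0.1 ns.  `Lx` is the x-separation of beads 1 and 99; the trap spring is
apparatus, not molecule, so it is excluded (including it would shift the
axis by at most `F/(K_trap L0)`, about 0.3%).  Points are replicated with
distinct seeds and reported as mean +/- s.e.m. over replicas.

Two profiles are built in.  The *full* profile (50 ns equilibration,
650 ns production, 5 replicas) matches the long-run reference conditions.
The default *scaled* profile used by the test-suite and the acceptance
script is 50 ns + 300 ns with 3 replicas (~1.5-2 min per point on one
CPU core).  The equilibration length is the sensitive choice: a one-phase
start inside a plateau must phase-separate into coexisting slightly- and
highly-stretched populations, which takes tens of ns at these friction
settings; cutting equilibration to 20 ns leaves a systematic +1-2 pN bias
in the mean force.  Production length mainly narrows the s.e.m. (replica
scatter at mid-plateau points is ~0.5-2 pN at 300 ns).

## Deterministic references

Two non-dynamical references validate the simulations:

* `quasi_static_fec()` replaces every bond potential by its convex hull
  and solves the common-force construction for the series chain at zero
  temperature.  It predicts plateau heights exactly equal to each
  segment's hull slope and the plateau extents, is monotone by
  construction, and ignores bending and thermal fluctuations -- simulated
  forces at mid-plateau sit within ~1-2 pN of it.
* `single_bond_gibbs()` is the fixed-force Boltzmann density
  `rho(r) ~ exp(-(U(r) - f r)/kBT)` of one bond, by quadrature.  For a
  long chain at imposed extension the per-bond length distribution
  approaches this fixed-force reference at the measured mean force
  (ensemble equivalence); at the plateau force it is bimodal with modes
  exactly at `ra` and `rb`, which is where the simulated histogram peaks
  sit.

## What the simulations do and do not emulate

The model reproduces the *mechanics* of overstretching -- plateau forces
and their sequence dependence, multiplateau curves of composite
fragments, extension partitioning, mixed versus macroscopically separated
states -- because these follow from the shape of `U(r)` and basic
statistical mechanics.  It contains no base-pair structure: nothing can
be inferred about S-DNA versus melted states, no torsion, no sequence ->
parameter prediction, no hysteresis or pulling-rate effects (the protocol
is equilibrium, isometric), no excluded volume or electrostatics.  The
11 bp bead builds the experimentally observed cooperativity length of
the transition into the resolution of the model.  Passing tests
demonstrate internal consistency with the stated potentials and
published summary observables, not structural realism.

Known limitations worth restating: the exact closed form of the original
bond potential is reproduced from its stated constraints (harmonic
branch, hull gap `delta` at the midpoint, tangent-slope plateau), so the
bump shape and post-`rb` stiffness are constraint-equivalent choices, and
observables sensitive to them -- plateau *ends*, barrier kinetics --
carry that uncertainty.  The discrete-WLC bending constant
`K = P kBT/r0` maps onto the nominal persistence length only
asymptotically (stiff-angle limit); at `P/r0 ~ 2.6` the realised
tangent-correlation decay length is ~20% below nominal, which is a
property of the discretisation, not a bug -- the package's
tangent-correlation test therefore checks against the exact Boltzmann
average for the harmonic angle potential rather than `exp(-r0/P)`.

## A worked example

```{r example, eval = FALSE}
frag <- fragment_preset("AT-GC")       # 49 AT bonds then 49 GC bonds
qs <- quasi_static_fec(frag)
qs$plateaus
#>  force_pN x_from  x_to
#>     34.93  1.028 1.509
#>     74.56  1.541 1.871

prot <- stretch_protocol(x_grid = 1.275, seed = 103)  # scaled profile
rec <- run_point(frag, 1.275, prot)
rec
#> point_record: r/r0 start 1.275 -> <F_trap> = 34.91 pN (s.e.m. 0.64, n = 3),
#>   <Lx/L0> = 1.2750

# which segment supplies the extension?
ref <- run_point(frag, 1.0, stretch_protocol(x_grid = 1.0, seed = 111))
extension_share(rec$segment_extension_A, ref$segment_extension_A)
#> poly(dA-dT) poly(dG-dC)
#>      0.9617      0.0383

# coexistence structure inside the first plateau
ps <- classify_phases(colMeans(rec$bond_samples), frag)
ps$classification
```

The simulation sizes above (50 + 300 ns, 3 replicas, one extension) are
the package's desk-scale defaults; `stretch_protocol(profile = "full")`
reproduces the long reference conditions.
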