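---
title: "Gating descriptors for pentameric ligand-gated ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating descriptors for pentameric ligand-gated ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescope)
```

## The problem

Pentameric ligand-gated ion channels (Cys-loop receptors: nicotinic
acetylcholine receptors, GluCl, GLIC, ELIC, GABA~A~) open and close a
transmembrane pore lined by five M2 helices, one per subunit.  In
molecular-dynamics simulations, putative open models of these channels
frequently collapse within nanoseconds: the hydrophobic side chains of
the 9', 13' and 16' rings rotate into the lumen, the pore dewets, and
the channel becomes non-conductive.  Deciding whether a simulated
conformation is open or collapsed therefore cannot rest on a single
number; it rests on a battery of geometric and hydration descriptors,
plus — when one wants to *hold* a channel open — a restraint that
penalises gate contraction without biasing an already-open pore.

`porescope` implements that battery and that restraint, together with a
synthetic pentamer generator whose output has closed-form ground truth,
so every descriptor is testable at desk scale.

## Residue bookkeeping

All descriptors address residues through a `channel_topology`: five
ordered chain identifiers, a map from M2 prime indices to author residue
numbers, and named loop spans.  Prime notation counts positions along M2
from a conserved intracellular reference, so 9', 13' and 16' label the
hydrophobic gate rings in any family member.  The shipped default is an
α7-style map anchored at Val246 = 13' (residue = 233 + prime index),
with the C-loop at 179–188, the Cys-loop at 122–136, the binding-site
backwall at 139–140, the β1-β2 loop around Lys40 and the M2-M3 loop
around Pro256.  Because published models rarely print the full map, the
topology is a YAML file the user can replace wholesale; every function
takes it as an argument.

The M2 span is taken as primes −2'…20' inclusive, i.e. 23 residues.
The glycine ring at the intracellular end is indexed −2', with 2'
occupied by serine; the pore lumen is the region between the −2' and
20' ring centers (about 30 Å in the default geometry).

## Geometric conventions

**Axis frame.** The channel symmetry axis `z` is the unit vector from
the −2' Cα ring center to the 20' Cα ring center (intracellular →
extracellular); the origin is the Cα centroid of all five M2 helices.
A chord between ring centers is preferred over an inertia tensor
because the extracellular domain is bulky and asymmetric; a PCA axis is
available as an option.  Each subunit gets a local frame at its M2 Cα
centroid: `x` radial outward, `y = z × x` tangential.

**Helix axis.** The M2 axis is estimated from the Cα trace after a
moving average over 18 consecutive residues — exactly five helical
turns at 3.6 residues/turn — which cancels the helical wobble exactly,
so the smoothed points lie on the helix axis; the direction is the
first principal component through them, oriented by positive projection
on `z`.  Raw PCA of the 23 Cα positions carries a systematic transverse
bias of about 0.14° (23 residues is not an integer number of turns),
which is irrelevant for the polar tilt but corrupts the azimuthal angle
badly at small tilts; the turn-complete average removes it.

**Tilt decomposition.** The polar tilt is the signed angle between `z`
and the helix axis's projection on the local xz plane, positive when
the helix top leans radially outward; the azimuthal tilt is the signed
angle from `x` to the xy projection, positive toward `y`.  When the xy
projection is numerically null (a perfectly vertical helix) the
azimuthal angle is reported as 0 and flagged degenerate.  Note one
consequence of this standard parameterisation: a helix leaning slightly
*inward* (negative polar tilt) with a small tangential lean has an
azimuthal angle near ±180°, not near 0; comparisons of azimuthal angles
must be circular.

**Quaternary twist.** Per subunit, the vectors from the whole-protein
Cα center of mass to the LBD and TMD Cα centers of mass are projected
on the plane ⊥ `z`; the twist is the signed angle from the TMD
projection to the LBD projection, positive counter-clockwise viewed
from the extracellular side.  Whether published twist values are signed
is usually unstated, so both the signed mean and the mean absolute
value are returned.  Larger twist associates with channel closure.

**Crossed distances.** At a given prime ring, the five non-adjacent
subunit pairs (P1-P3, P2-P4, P3-P5, P4-P1, P5-P2) each contribute one
distance.  The default selection is the mass-weighted whole-residue
center of mass — the selection the gate restraint is defined on — with
a Cα-only mode provided because both conventions appear in the
literature; on synthetic data the two modes must (and do) produce the
same ordering of states.  Distance distributions are built by pooling
the five pair series rather than averaging them, so transitions of
individual subunits are not blurred.

**Pore radius.** An axis-sampling minimal-clearance profile (HOLE-like,
without sphere wandering): stations every 0.5 Å along the axis; at each
station the radius is min over protein atoms in the station's slab of
(distance to the axis − van der Waals radius), floored at 0.  Stations
with empty slabs are reported at a configured maximum and flagged.
Radii use Bondi values (C 1.70, O 1.52, N 1.55 Å …).  Off-axis corridor
search is deliberately out of scope; for a pore lined by five helices
the axis-sampled profile is the quantity of interest.

## Hydration and hydrogen bonds

Water positions are their oxygen atoms.  Regions are axial slabs
(half-open, `z_lo ≤ z < z_hi`) bounded laterally by a cylinder of
radius 8 Å by default — wide enough to contain the lumen, narrow enough
to exclude lipid-facing water in a membrane system; the bound is
configurable because published water counts rarely state one.  The two
canonical regions are the full pore lumen (between the −2' and 20'
ring centers) and the hydrophobic-gate slab, 10 Å centered on the 13'
ring center (the Leu9'–Leu16' span is available as an alternative
anchor).

Hydrogen bonds are purely distance-based, matching the common practice
for trajectory surveys:

* water–residue: formed when the minimum over all donor-hydrogen /
  acceptor-heavy-atom combinations, in either direction, is below
  2.0 Å.  The 2.0 Å criterion is interpreted as a hydrogen-to-heavy
  distance; a 2.0 Å heavy–heavy "bond" would be physically impossible.
* intra-protein: formed when a typed heavy donor and acceptor are
  closer than 3.0 Å; same-residue pairs are excluded.

No angular criterion is applied, and both cutoffs are configurable.
Donor/acceptor typing ships as an editable YAML template table.
Persistence of a bond is the percentage of analysed frames in which it
is formed; bonds above 60% mark a tense, collapsed-like network, bonds
below 5% the relaxed open forms.

Dewetting/rewetting events are found by hysteresis threshold crossing:
after the gate count has been above `high` (default 30 waters), a run
of at least `min_duration` frames (default 5) below `low` (default 10)
is a dewetting event, and symmetrically for rewetting.  The thresholds
are this package's own operational choice — event counts in the
literature are typically read off plots — and all three are arguments.

## Binding site and ions

`dCintra` is the distance between the Cα centroids of the C-loop
(179–188) and the backwall (139–140); the interface monitors are the
distances from Pro256's Cα to the Cys-loop Cα centroid and to Lys40's
Cα.  Ligand monitors are named atom- or ring-centroid pairs (ring–ring
contacts use geometric centroids of the listed ring atoms); the default
table covers the epibatidine-style monitor set (amine–hydroxyl,
amine–carbonyl, chlorine–backbone-nitrogen, and three ring–ring
contacts).  Summaries pool mean ± s.d. over subunits and frames.

Ligand orientation is classified from the unit vector between the
ligand centroid and a marker atom (the agonist chlorine by default):
within a 45° cone of ±`z` the pose is axial (up/down); within 22.5° of
the axis-normal plane *and* leaning predominantly toward the pore axis
it is equatorial; anything else is intermediate.  The literature
describes these poses only qualitatively; the cone half-angles are a
documented operationalisation, configurable, and labelled as such.

Ion distributions are axial histograms pooled over frames within a
10 Å lateral cylinder (the extracellular vestibule is wider than the
TMD lumen); occupancy series count ions of one species in a region per
frame and report the maximum simultaneous occupancy.

## The flat-bottom gate restraint

The pore-opening restraint acts on the crossed distances `d_i` between
the residue centers of mass of the 16' (Leu) and 13' (Val) rings on
non-adjacent subunits — ten pairs in a pentamer.  Each pair contributes

    U_i = k/2 (d_i − d0_i)²   if d_i < d0_i,     0 otherwise

with `k = 10 kcal/mol/Å²` and thresholds `d0_i` calibrated on a
reference structure (the initial, open model), so the restraint is
exactly flat there and switches on only when the gate contracts.  The
½k convention is chosen so that `k` carries the stated units and the
restoring force at a 1 Å violation is exactly `k`; since quadratic
restraint conventions differ between codes, a `full_k` switch is
provided.  Forces are the analytic gradient distributed onto the atoms
of each center-of-mass group by mass fraction (the standard COM
restraint chain rule); they vanish pairwise, so the restraint exerts no
net force or torque.  Center-of-mass weighting is by mass; a geometric
option exists via the Cα selection mode.

Two numerical notes.  First, the potential is C¹ but not C² at `d0`:
finite-difference checks of the forces are valid only when no pair
distance lies within the difference stencil of its threshold, and the
test suite filters those configurations.  Second, the energy is exactly
zero iff no pair is below threshold, which the activity log exploits to
select frames where the restraint was inactive — the natural seeds for
subsequent free simulations of the open state.

## The synthetic generator

`build_pentamer()` constructs five ideal α-helical M2 segments (rise
1.5 Å/residue, 100°/residue; these are fixed, not arguments, to keep
the ground truth closed-form) on a circle of configurable radius, each
with a Cα and one side-chain proxy atom per residue.  The proxy sits at
its Cα's height and azimuth, at a prescribed distance from the pore
axis per prime ring — so the pore radius at ring `i` is exactly
`ring_radius[i] − 1.7` and side-chain swing (the mechanism by which
these gates actually open and close) is represented without rotamer
modelling.  An LBD-proxy Cα cloud carries the binding-site loops at a
prescribed twist offset; waters are 3-site (O + 2 H at 0.957 Å,
104.52°) placed uniformly in the prescribed regions at prescribed
occupancy; ions follow a simple axial placement law (cations
−20 < z < 0, anions −30 < z < −20); one 14-atom agonist proxy per
subunit carries the marker atoms of the default monitor table.

Three construction details make the ground truth exact rather than
approximate: the helix template is centered so its Cα centroid lies
exactly on the helix axis (the radial local frame is then exact); with
scalar tilts all five chains are copies rotated by 72°, so the
structure is exactly C5-symmetric and every crossed distance is a
pentagon chord `2 R sin 72°`; and the LBD cloud is placed symmetric
about its central azimuth, computed *after* the TMD, so the measured
twist equals the prescribed offset identically.

The presets encode the two gate states the descriptors must separate:
`blueprint_open()` (gate radius ~5 Å, intracellular constriction ~3 Å,
polar tilt +1.1°, twist 21°, 115 lumen / 40 gate waters) and
`blueprint_collapsed()` (9' constriction ~2 Å, gate ~3 Å, polar tilt
−2°, twist 24°, 60 lumen / 4 gate waters).  These values are the study
conditions the package is built around, not tuning knobs.

`build_trajectory()` interpolates two blueprints linearly and adds
i.i.d. Gaussian noise per atom per frame; waters are re-placed each
frame at the interpolated occupancy, with a constant-size water pool
maintained by parking surplus waters in a distant bulk shell (frame
atom counts must be constant).  `place_hbond_fixture()` toggles a
donor/acceptor pair on a scripted schedule so persistence has the duty
cycle as exact ground truth.

**What the generator does *not* emulate** — and hence what passing
tests do and do not show about real data: there are no sterics, no
membrane, no electrostatics, no solvent structure; noise is isotropic
and uncorrelated, whereas thermal motion in MD is collective and
correlated; waters are uniform in a cylinder rather than layered and
hydrogen-bonded; helices are rigid (no bending, which is acceptable for
α7-like M2 helices but not universally).  The tests therefore validate
the *descriptor implementations* — their geometry, conventions,
invariances and oracle agreement — not the biological discriminating
power of the descriptors on real trajectories.

## Numerical choices

* Half-open axial intervals everywhere (`z_lo ≤ z < z_hi`), so slab
  partitions are exact; lateral bounds are inclusive.
* Helix-axis estimation: turn-complete moving average (window 18),
  then PCA; orientation tie-break by positive dot with `z`.
* Azimuthal tilt below an xy-projection norm of 1e-8 is reported as a
  flagged 0 rather than noise.
* Empty pore-profile slabs report a configured maximum radius with a
  flag instead of NA, so downstream minima are well-defined.
* Descriptor CSVs print full-precision (17 significant digits) values,
  making write→read round trips bit-exact and seeded pipelines
  byte-reproducible.
* All stochastic steps (generator, noise, water/ion placement) are
  driven by one seed and restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: pentamers of ~1000–2500 atoms, trajectories of 3–30 frames,
100-fixture oracle sweeps, and 20-frame noisy trajectories for the
angle-recovery checks (noisy azimuthal recovery is assessed on the
frame-averaged descriptor, which is how tilt distributions are used in
practice; a single 23-residue helix at σ = 0.3 Å cannot localise its
azimuth to 2° at a 5° polar tilt, and averaging is the standard
remedy).  These sizes keep the whole suite under a minute while leaving
every numeric claim at its stated tolerance.

## Limitations

* No corridor/pathway search off the pore axis, and no helix
  bending/kink analysis.
* No force-field energetics: the restraint is an energy/force provider
  and analysis tool, not a simulator plug-in; interaction energies
  between ligand and pocket are out of scope.
* Water analysis is positional only — no orientation, residence-time or
  diffusion kinetics.
* The PDB writer emits fixed-width ATOM records and MODEL blocks only;
  DCD is read (via bio3d) but not written.

## A worked miniature

```{r example, eval = FALSE}
topo <- alpha7_topology()
open_tr <- build_trajectory(blueprint_open(seed = 1), n_frames = 3,
                            noise_sd = 0.1, seed = 1, origin = "open")
coll_tr <- build_trajectory(blueprint_collapsed(seed = 2), n_frames = 3,
                            noise_sd = 0.1, seed = 2, origin = "collapsed")
rep <- run_report(open_tr$trajectory, coll_tr$trajectory, topo,
                  outdir = "report")
rep$summary
```

The summary table shows the discrimination logic in one glance: gate
pore radius, gate water count and the 9'/13'/16' crossed distances all
strictly larger for the open preset, and the twist larger for the
collapsed one.
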