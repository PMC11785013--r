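---
title: "A single-basin structure-based model for domain motion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-basin structure-based model for domain motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmotion)
```

## The question the package addresses

Large ribonucleoprotein assemblies such as the mitoribosomal small subunit
recruit enzymes — for example an rRNA methyltransferase that must bring its
bound cofactor next to a target nucleotide buried on the particle body. A
deposited structure shows only one conformation; whether thermal motion
alone can carry an enzyme domain from a resolved pose to a
catalytically-compatible one is a question about the energetics of
fluctuations *around* that structure. Single-basin structure-based ("Gō-like")
models are the standard tool for this: the experimental structure is defined
to be the global minimum of the potential, and simulations then report the
scale, direction and free-energy cost of excursions from it.

`sbmotion` implements that workflow end to end: force-field construction
from an all-atom reference structure, Langevin dynamics in reduced units,
and a geometric analysis layer (superposition, Euler–Rodrigues rotation/tilt
decomposition, per-residue average spatial deviation, and free-energy
profiles by Boltzmann inversion).

## The potential

All non-hydrogen atoms are retained. With lengths in Å and energies in the
reduced unit $\epsilon$:

$$
U = \sum_{\mathrm{bonds}} \tfrac{\epsilon_r}{2}(r - r_0)^2
  + \sum_{\mathrm{angles}} \tfrac{\epsilon_\theta}{2}(\theta - \theta_0)^2
  + \sum_{\mathrm{impropers}} \tfrac{\epsilon_{\chi\mathrm{imp}}}{2}(\chi - \chi_0)^2
  + \sum_{\mathrm{planars}} \epsilon_{\mathrm{planar}}\,[1 - \cos 2\chi]
$$
$$
  + \sum_{\mathrm{bb\ dihedrals}} \epsilon_{bb}\,F(\phi - \phi_0)
  + \sum_{\mathrm{sc\ dihedrals}} \epsilon_{sc}\,F(\phi - \phi_0)
  + \sum_{\mathrm{contacts}} \epsilon_c\!\left[\left(\tfrac{\sigma_{ij}}{r}\right)^{12}
      - 2\left(\tfrac{\sigma_{ij}}{r}\right)^{6}\right]
  + \sum_{\mathrm{non\text{-}contacts}} \epsilon_{nc}\left(\tfrac{\sigma_{nc}}{r}\right)^{12},
$$

with $F(\phi) = (1-\cos\phi) + \tfrac12(1-\cos 3\phi)$. Fixed weights are
$\epsilon_r = 100\,\epsilon/\text{Å}^2$, $\epsilon_\theta = 80\,\epsilon/\text{rad}^2$,
$\epsilon_{\chi\mathrm{imp}} = 10\,\epsilon/\text{rad}^2$,
$\epsilon_{\mathrm{planar}} = 40\,\epsilon$ (the planar term is
dimensionless, so its weight is a pure energy),
$\epsilon_{nc} = 0.1\,\epsilon$ and $\sigma_{nc} = 2.5$ Å.

Native contacts are detected with a Shadow Contact Map: a pair is a contact
iff its reference distance is at most 6 Å, it is not excluded (same residue,
or a 1-2/1-3/1-4 bonded relationship — those pairs are governed by bonded
terms), and no third atom of radius 1 Å occludes the line of sight. The
occlusion predicate — the projection of the occluder onto the segment falls
strictly between the endpoints and its perpendicular distance is below the
shadow radius — is isolated in one function and checked in the test suite
against an $O(N^3)$ brute-force oracle. Each contact well is placed at
$\sigma_{ij} = 0.96\times$ the native distance, which counteracts the
thermal expansion this potential class otherwise shows. A consequence worth
stating plainly: the reference structure is an exact stationary point of the
bonded, dihedral and planar terms, but the contact sum pulls slightly inward
there, so the *full* potential has its true minimum marginally contracted
from the reference. `validate_forcefield()` checks the first property; the
closed-form energy identity below quantifies the second.

At the reference coordinates every contact contributes exactly
$\epsilon_c(0.96^{12} - 2\cdot 0.96^{6}) \approx -0.9528\,\epsilon_c$, and all
other terms vanish (on the toy system, where bond/angle equilibria are
measured from the reference), so
$U_\mathrm{ref} = -0.9528\sum\epsilon_c$ — an analytic check the test suite
enforces to $10^{-6}$ relative.

### Energy-scale normalization

The stabilizing weights are set by three conditions: the total stabilizing
energy ($\sum \epsilon_c$ over contacts plus $\sum \epsilon$ over proper
dihedrals) equals $N_\mathrm{atoms}\,\epsilon$; contacts carry twice the
dihedral total; and each backbone dihedral carries twice the weight of a
sidechain dihedral, uniform within each class. A proper dihedral is
"backbone" iff all four atoms belong to the backbone atom-name set (protein
N, CA, C, O; nucleic P, O5', C5', C4', C3', O3').

### Bond and angle equilibria

Equilibrium bond lengths and angles for standard residues come from a small
bundled reference table of published force-field values; any (residue, atom
tuple) absent from the table falls back to the value measured in the input
structure, and the fallback count is logged. Dihedral and improper
equilibria are always measured from the input model. The toy alphabet is
deliberately absent from the table, so toy systems are built with measured
equilibria throughout and the reference state is an exact stationary point
of every term whose equilibrium is configurable — this is what makes the
closed-form energy check exact on toys; for real structures with tabulated
equilibria it holds only approximately.

### Disorder and restraints

Regions known to be disordered are handled by removing their stabilizing
contacts and proper dihedrals while keeping bonds, angles, impropers and
planars, so the chain stays covalently intact but explores conformations
freely; removed pairs fall back to the generic excluded-volume repulsion.
Masking happens after normalization and does not rescale the surviving
weights. A harmonic distance restraint $U = \tfrac{k}{2}(r - r_\mathrm{min})^2$
implements the "pull the cofactor toward the target" arm; a spring constant
quoted in $\epsilon/\mathrm{nm}^2$ is converted once at the boundary
($150\,\epsilon/\mathrm{nm}^2 = 1.5\,\epsilon/\text{Å}^2$). All internal
units are Å and $\epsilon$.

## Dynamics

Langevin dynamics with the BAOAB splitting; all atom masses are 1 (this
model family defines no per-atom masses) and temperature is in
$\epsilon/k_B$, with 0.5 the production value. Defaults: timestep 0.002 reduced time, friction
1.0 — conventional stable values for this potential class, both
overridable. With friction 0 the O-step drops out and the integrator is
exactly velocity Verlet; the suite verifies that the secular energy drift
over $10^4$ steps is below $10^{-3}\,\epsilon$ (the bounded symplectic
oscillation of the total energy is larger and scales with the timestep, so
"drift" is measured as the linear trend). Thermostat noise is pre-generated
in R chunk by chunk, so a trajectory is reproducible bit-for-bit from
`set.seed` alone; initial velocities are Maxwell–Boltzmann at the run
temperature.

The non-contact repulsion is truncated at 3.5 Å (where the discarded
per-pair energy is below $2\times10^{-3}\,\epsilon$) and shifted so the
potential is continuous at the cutoff — without the shift, pairs crossing
the cutoff would inject energy and microcanonical runs could not conserve.
Overlapping atoms in any pair term (distance below $10^{-6}$ Å) abort with
an error naming the term, and a diverging run aborts with a diagnostic
coordinate dump.

## Rotation, tilt, a.s.d. and free energy

The analysis layer mirrors the two-protocol geometry pipeline:

1. The **Euler–Rodrigues axis** is defined from a pre/post conformation
   pair: align the pre structure to the post structure on everything except
   the analysed domain, fit the domain orientations, and take the axis/angle
   of the relative rotation.
2. Per frame, **rotation and tilt**: align the frame to the reference on
   the body selection; fit the reference domain onto the frame's domain;
   decompose the resulting rotation in active Z-Y-Z convention in the basis
   whose Z axis is the E-R axis. The rotation angle is
   $\gamma = \phi + \psi$ (motion about the E-R axis) and the tilt is the
   polar angle $\theta$ (motion orthogonal to it). This is the unique
   convention in which $\gamma$ measures rotation about the chosen axis
   while $\theta$ is its orthogonal complement. Near $\theta = 0$ the
   individual $\phi$ and $\psi$ are ill-conditioned (gimbal singularity);
   below $\sin\theta = 10^{-7}$ the implementation reads the combined
   z-rotation directly from the well-conditioned upper-left block, so
   $\gamma$ stays accurate to $10^{-6}$ degrees in the recovery tests.
3. **Average spatial deviation** (a.s.d.): per frame the domain is
   superposed onto itself in the reference (default fit: the domain's
   C$\alpha$ atoms), and the per-residue deviation of a representative atom
   (default C$\alpha$, switchable to all atoms) is averaged over frames.
   Because the fit is domain-onto-domain, a.s.d. measures *intramolecular
   deformation*, not rigid-body motion — the quantity used to argue that a
   domain reorients without unfolding.
4. **Free energy vs tilt**: $F(\theta) = -T\ln P(\theta)$ from a histogram
   (1° bins by default), reported in $k_BT$ with the minimum shifted to
   zero; empty bins are undefined (`NA`), never zero. No Jacobian
   ($\sin\theta$) correction is applied by default — the choice is exposed
   as a flag (`jacobian = TRUE` divides the density by $\sin\theta$)
   because the source analyses of this kind do not state one; note that
   without the correction the entropic factor alone places the most
   probable tilt away from zero.

## The synthetic toy system

`make_toy_two_domain_system()` builds, deterministically, a two-domain
all-atom system that emulates the geometry the analysis assumes: a helical
protein-like *body* (default 18 residues), a two-residue extended hinge
*linker*, a helical *domain* (default 8 residues) carrying a single-atom
pseudo-cofactor, and a single-atom target site on the body at a native
cofactor–target separation near 10 Å (the realized value, about 8.9 Å with
the defaults, is recorded in the metadata). `make_disordered_tail()` adds a
chain-B nucleotide-like polymer lying along the body — close enough that the
Shadow Contact Map finds stabilizing body–tail contacts, which the disorder
mask then removes. Toy residues use a reduced two-letter alphabet (`ALX`, a
protein-like residue with a two-atom sidechain; `NUX`, a nucleotide-like
residue with a two-atom base) so the template tables stay small while every
term class — bond, angle, improper, planar, backbone and sidechain dihedral,
contact — is exercised.

Geometry choices made once, for stated reasons:

* Chains are built from internal coordinates (bond/angle/torsion) with the
  peptide $\omega$ exactly 180°, so planar groups sit exactly at their
  energy minimum and the closed-form reference-energy identity holds
  exactly.
* The linker torsions ($\phi = -120°$, $\psi = 100°$) leave the body helix
  in an extended, sterically clean conformation: at the native state no
  non-excluded non-contact pair falls inside the repulsion cutoff, and a
  handful of body–domain contacts near the hinge give the domain a defined
  orientation to fluctuate about.
* The hinge permits a rigid 15° domain tilt without steric overlap
  (asserted in the tests), so tilt windows of the size the analysis targets
  (roughly 7–12°) are reachable in toy runs.
* The native build is fully deterministic; the seed is recorded in the
  metadata and governs the downstream simulations.

What the toy does *not* emulate: real sidechain chemistry and rotamers,
sequence heterogeneity, the size of a ribonucleoprotein particle
(hundreds of thousands of atoms vs. ~220), and the slow, collective
relaxation times that come with it. Green tests on the toy validate the
*machinery* — term construction, integrator statistics, geometric
decompositions, estimators — not any biological claim about a particular
assembly; reproducing published numbers for a specific particle requires
its deposited structures as input and substantially longer sampling.

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy conformer (ties favour
  altloc "A"); hydrogens and waters are always stripped; heteroatoms are
  kept and flagged. Author chain/residue numbering is used everywhere so
  selections match viewer conventions.
* Single-atom ligand residues are attached by harmonic bonds to their (up
  to two) nearest atoms within 3.5 Å, with measured equilibrium lengths;
  multi-atom ligands without a bundled template can be registered with
  `ligand_template()`, which infers bonds from the observed geometry and
  holds the ligand by bonds and angles alone.
* Collinear superposition selections are rejected (second singular value
  test); the SVD reflection branch is corrected so rotations are always
  proper.
* A rotation angle numerically at zero leaves the E-R axis undefined; the
  result is flagged rather than fabricated.
* Kabsch fits amplify coordinate roundoff into tilt angles of order
  $10^{-6}$ degrees via $\arccos$; recovery tests therefore use a
  $10^{-6}$-degree tolerance rather than exact equality.
* Test problem sizes: the toy system (about 220 atoms with tail), $10^5$
  integration steps for thermostat statistics, $4\times10^6$ steps on a
  two-atom oscillator for the variance check, 50 random configurations of
  up to 200 atoms for the contact-map oracle, and $10^5$ samples for the
  free-energy curvature check. These sizes give sampling errors comfortably
  inside the asserted tolerances.

## Design decisions that were genuinely open

* **Shadowing geometry.** "A third atom occludes the pair" admits several
  operationalizations; the implemented predicate (projection strictly
  between endpoints, perpendicular distance below the shadow radius, any
  atom as occluder) is deterministic, symmetric in the pair, and kept
  behind one function so it can be swapped; the oracle test pins its
  behaviour exactly.
* **Contact exclusions.** Pairs within a residue or within three bonds are
  excluded from both the contact search and the repulsion, standard
  practice for this force-field family.
* **Two-arm design.** `run_pipeline()` makes the restrained/unrestrained
  comparison first-class: one shared force field, arm-specific restraint
  activation and seeds, and a JSON manifest holding the config snapshot,
  seeds, file hashes and stage status, so a rerun with the same config
  reproduces every numerical output byte-for-byte.
* **Trajectory storage.** Frames are kept in memory and exportable as
  multi-MODEL PDB text plus a TSV energy log; no binary trajectory format
  is written.
* **Interfaces.** This is an analysis package: the documented functions,
  `run_pipeline()` with its YAML config, and this vignette are the
  interface; there is no shell executable.

## Known limitations

* Pure repulsion for non-contacts: no electrostatics, no solvent, no
  hydrogen bonding — inherited properties of the model class.
* Single basin only: the model cannot describe transitions between two
  experimentally distinct minima, only fluctuations about one of them.
* The bundled equilibrium-value table covers the standard backbone of
  glycine/alanine plus the toy alphabet; other standard residues currently
  take measured equilibria (logged), which is correct for single-structure
  work but departs from tabulated-parameter practice.
* The O($N^2$) non-contact loop and R-level contact search are sized for
  desk-scale systems (up to a few thousand atoms), not for a full
  ribonucleoprotein particle.

## A worked run

```{r example, eval = FALSE}
native <- make_toy_two_domain_system(toy_spec(seed = 1))
meta <- attr(native, "toy")
wt <- make_disordered_tail(native)
ff <- build_forcefield(wt$structure, disorder = wt$disorder)
ff <- add_distance_restraint(ff, meta$ligand_index, meta$target_index,
                             r_min = 5, k = 1.5)

tr <- run_langevin(ff, sim_config(temperature = 0.5, n_steps = 100000L,
                                  save_interval = 200L, seed = 42))
glance(tr)

pre <- make_rotated_conformation(native, c(0, 0, 1), 45)
er <- er_axis_from_structures(native, pre, meta$body_selection,
                              meta$domain_selection)
rot <- rotation_tilt_timeseries(tr, wt$structure, meta$body_selection,
                                meta$domain_selection, er$axis)
autoplot(free_energy_vs_tilt(rot$theta, temperature = 0.5))
```
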