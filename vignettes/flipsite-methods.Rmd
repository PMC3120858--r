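---
title: "Methods: hydrogen bonds, hydration, and LIE energetics of a base-flipping pocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen bonds, hydration, and LIE energetics of a base-flipping pocket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipsite)
```

## The scientific setting

Some DNA-binding protein domains read epigenetic cytosine marks by
*base flipping*: the modified nucleotide is rotated out of the double
helix into a protein binding pocket, where its 5-substituent — a methyl
group in 5-methylcytosine (5mC), a hydroxymethyl group in
5-hydroxymethylcytosine (5hmC) — is in direct contact with pocket
residues and ordered water. Whether such a pocket discriminates between
the two marks is then a question about (i) the hydrogen-bond network
that holds the flipped base, (ii) the behaviour of water in and around
the pocket, and (iii) the net interaction energetics of the two
complexes.

`flipsite` implements the trajectory-analysis layer for this question:
everything downstream of a molecular-dynamics engine, from structure
and parameter ingest to occupancy timelines, hydration-site tracking,
stability metrics, Linear Interaction Energy (LIE) estimates, and the
quantification of the matching wet-lab competition binding assay.
Running the MD itself (thermostats, PME, constraint algorithms) is out
of scope.

All quantities use one unit system: Angstrom, kcal/mol, picoseconds,
elementary charges.

## Data model

A `topology()` is an ordered atom table (name, element, residue
membership kept verbatim from the source file, partial charge,
Lennard-Jones `epsilon`/`Rmin/2`, mass, and donor / hydrogen / acceptor
/ water roles) plus a bond list. A `trajectory()` is a dense
`atoms x 3 x frames` array with strictly increasing times. Atom indices
are **1-based everywhere**, matching R's native indexing; using a
0-based internal convention in an R package would force a translation
at every subscript and is a classic source of off-by-one defects. The
cost is only that indices printed by other tools differ by one.

Structures arrive as PDB `ATOM`/`HETATM` records (multi-model files
become multi-frame trajectories); per-residue charges, bonds and
donor/acceptor annotations arrive as a CHARMM-RTF-style text
(`RESI`/`PRES`/`ATOM`/`BOND`/`DONO`/`ACCE`) extended with optional
Lennard-Jones columns on `ATOM` lines, since CHARMM itself keeps those
in a separate parameter file. The parser is strict where silence would
corrupt science: parse errors name the offending line, a merge that
leaves any atom without a charge raises, and Unicode prime characters
in atom names are normalized to ASCII apostrophes with a logged
message. Orthorhombic boxes only; triclinic input is an explicit
unsupported-format error. Trajectories interchange as multi-model PDB,
a lossless `xyz-csv` text fallback, or binary DCD (read via `bio3d`;
DCD carries no time axis, so `dt` is a required argument there — the
save interval is not recoverable from the data).

## The 5hmC residue patch

5hmC parameters are built from the 5mC residue by the
hydroxyl-substitution rule: one methyl hydrogen is exchanged for an
O–H group whose charges are copied **byte-for-byte** from a serine
hydroxyl, and the leftover charge is redistributed so the residue's net
charge is exactly conserved. Two details are genuinely open and were
decided as follows:

* *Which methyl hydrogen is replaced*: the first in topology order. At
  the parameter level the three are equivalent; the choice only has to
  be deterministic.
* *How "the CH2 charges are adjusted"*: the residual charge
  `(old methyl sum) − (new unadjusted group sum)` is spread uniformly
  over the CH2 carbon and its two hydrogens. This is the
  smallest-perturbation rule that confines all change to the chemically
  modified group; any scheme that touched ring atoms would contradict
  the stated intent of adjusting only the CH2 group.

`apply_patch()` is an in-memory topology edit (delete, append inside
the residue block, rewire bonds); it refuses double application because
the methyl and the atom names it expects are gone after the first
pass. `format_patch_rtf()` emits the patch as a `PRES` block so it can
be diffed against an external parameter set. Charge conservation is
asserted to 1e-12 e.

## Hydrogen-bond detection and occupancy

A donor–H–acceptor triplet is hydrogen-bonded in a frame when
`d(D, A) <= 3.5` Angstrom and the D–H–A angle (vertex at H) is
`>= 120` degrees — the common geometric convention. The criteria are
plain parameters (`hbond_criteria()`) and travel with every timeline,
because no single geometric definition is canonical; no smoothing is
applied to occurrence records. Pairs within two covalent bonds are
excluded (a hydroxyl O cannot "bond" to its own neighbour); the
exclusion uses the bond graph, not residue membership. Distances are
computed without periodic imaging by default (the complex is assumed
kept whole), with an optional minimum-image mode for boxed systems.

Bond identity across frames is the atom-index triplet, so waters retain
identity by residue — appropriate for following one specific water
bridging pocket and base. Occupancy is the fraction of frames a bond is
present; "stable" means occupancy at or above a threshold (default
0.5). Integer display labels mirroring a figure's numbering are
user-supplied aliases, never derived.

Correctness is anchored to an exhaustive oracle: a test re-detects
bonds by enumerating every triplet with independent code (plain loops,
BFS bond distances) and demands exact set equality on 100 random
configurations.

## Water dynamics

`site_water_occupancy()` counts a water when its oxygen is within a
radius (default 3.5 Angstrom, configurable — "in and around the
binding site" is not a precise radius) of the per-frame centroid of the
site-defining atoms. `conserved_water_sites()` works positionally:
frames are superposed on pocket atoms, water-oxygen positions are
pooled in that common frame and clustered greedily (densest point
seeds; ties broken by earliest frame then lowest atom index, for
determinism; default cluster radius 1.5 Angstrom and minimum residency
0.5, following hydration-site conventions). Site identity is
*positional, not molecular*: a conserved water is a location that stays
occupied even while the occupying molecule exchanges — the generator's
planted-swap test checks exactly this. `compare_to_reference()` is then
a plain Euclidean distance to, e.g., a crystallographic water given in
the same pocket-aligned coordinates.

## Superposition, RMSD, RMSF

Superposition is the SVD form of the Kabsch algorithm with the sign
correction that rejects reflections (an improper rotation silently
deflates RMSD for chiral structures, so this must be explicit). A
quaternion-eigenvalue implementation serves as the independent optimal
check in the tests, together with a random-rotation search bound.

`rmsd_series()` fits each frame on one selection and reports over
another, supporting "subset" reporting such as excluding terminal
residues, which are operationalized as user-listed residue ids — how
many residues count as "terminal" is a judgement call that should stay
with the user. `rmsf()` aligns the window on the first window frame and
computes `sqrt(mean_t |x_i(t) - <x_i>|^2)`, optionally per residue.
Mass-weighting is off by default (the profiles are atom-positional) and
available as an option. On isotropic Gaussian noise of per-coordinate
sigma the expected RMSF is `sigma * sqrt(3)`; the suite checks recovery
within 5% at 5000 frames. Alignment consumes six rigid degrees of
freedom, so measured RMSF sits a factor `sqrt(1 - 6/(3N))` below the
closed form — negligible at the tested sizes but visible for very small
selections.

## LIE energetics

Interaction energies are direct-space pair sums with CHARMM switching
(energy-switched between 12 and 14 Angstrom by default, zero beyond):

```
v_el  = sum 332.0636 q_i q_j / (eps_r r_ij) * S(r_ij)
v_vdw = sum eps_ij [ (Rmin_ij/r_ij)^12 - 2 (Rmin_ij/r_ij)^6 ] * S(r_ij)
```

with CHARMM combining (`Rmin_ij = Rmin_i/2 + Rmin_j/2`,
`eps_ij = sqrt(eps_i eps_j)`) and the Coulomb constant pinned to
332.0636 kcal·Å/(mol·e²) for bit-reproducibility. Lattice-sum
(Ewald) electrostatics are deliberately not used: LIE needs energies
decomposable into group–group pairs, which reciprocal-space terms are
not; the scheme is recorded in every series' metadata rather than
presented as "the" scheme any particular engine used. Pair distances
are computed from explicit coordinate differences — the expanded-norm
shortcut `|a|^2 + |b|^2 - 2ab` loses ~1e-7 kcal/mol to cancellation,
which the oracle tests would catch.

The binding free energy is the linear-response estimate

```
dG = alpha * (<v_el>_bound - <v_el>_free)
   + beta  * (<v_vdw>_bound - <v_vdw>_free),    alpha = 1, beta = 0.5
```

with the bound state pairing the DNA against protein plus solvent and
the free state pairing the DNA against solvent alone — both are just
group selections, no special-casing. Averages are taken over an
explicit window; restricting to the equilibrated tail (e.g. the last
10 ns of a 57 ns run, 2000 frames at 5 ps spacing) is first-class via
`series_last_ns()`. Uncertainty is a block-averaging standard error
(5 contiguous blocks per series by default, combined in quadrature
across states); a single 5-block SE estimate carries ~35% relative
sampling error, which is why the convergence test averages SEs over
replicate series before checking the `1/sqrt(n)` law. `ddg()` is the
difference of two complexes' estimates under identical weights.
Region analyses use `pocket_selection()`: whole residues within a
cutoff (default 15 Angstrom) of the target residue *in the starting
conformation*, fixed thereafter. `flipped_backbone_selection()` exports
the 8-name DNA backbone set (`C4'`, `P`, `O1P`, `O2P`, `O5'`, `C5'`,
`C3'`, `O3'`) used to restrain a free DNA in its flipped conformation.

## The synthetic study and what it can show

Real inputs of this kind — a crystal complex plus tens of nanoseconds
of explicit-solvent trajectories — are far beyond what a test suite
can regenerate, and the original trajectories were never deposited. The
package therefore ships a generator (`make_toy_complex()`,
`make_energy_series()`, `make_fluctuation_trajectory()`) that emits
small systems with *planted ground truth*, and every downstream test
reads its expectations from the truth record, never from magic numbers.

The toy complex is a seven-probe pocket ring around a flipped
methylcytosine fragment (full 8-atom backbone set, patchable C5 methyl)
plus explicit waters, all parameterized through the regular RTF merge
path. Scheduled hydrogen bonds are planted at D–A 2.9 Angstrom and
165 degrees (comfortably inside the 3.5 / 120 defaults) and parked at
4.6 Angstrom outside their frames (comfortably outside); the margin
prevents criterion-boundary flakiness. Water visits place the oxygen on
fixed site centers 4 Angstrom apart. Positional noise is i.i.d.
Gaussian only, because that gives closed-form expectations (RMSF
`sigma*sqrt(3)`, CLT bounds for LIE means); schedule frame ranges are
1-based like everything else. Generators are pure functions of
(spec, seed).

Energy-series defaults in the analysis drivers plant population means
whose closed-form differences equal the reported energetics of the
methyl vs hydroxymethyl complexes (whole-complex −7.94, pocket
−6.65 kcal/mol), with frame-level standard deviations of 10 (el) and
5 (vdw) kcal/mol — fluctuation magnitudes typical of
interaction-energy traces of a protein–DNA complex. What a passing
suite shows is therefore that the *analysis* is correct: schedules are
recovered bitwise, estimators converge at the proven rates, energies
match brute-force sums. What it cannot show is anything about real
conformational dynamics — correlated motions, non-Gaussian
fluctuations, force-field adequacy, sampling convergence of an actual
MD run.

## Assay quantification

The competition pull-down measures two differently labelled DNA
substrates bound to an immobilized fluorescent-protein fusion. Binding
ratios are `(substrate intensity / calibration) / (protein intensity /
calibration)`. The published description of the control correction
("corrected by values from a control experiment using substrates of the
same sequence but different labels") does not print a formula; the
implementation uses the minimal ratiometric model consistent with its
purpose — divide each channel by the control's ratio, i.e. treat label
and detection bias as a per-channel multiplicative factor — and labels
it an assumption in the documentation. After correction, the pair is
normalized by total bound DNA, giving fractions that sum to one;
replicate summaries use the sample (n−1) standard deviation. Exact
invariants (sum-to-one, label-swap antisymmetry, idempotence on the
control) are enforced over 1000 random fixtures. Background subtraction
is upstream; inputs are net intensities. Kd estimation is out of scope:
the assay is single-concentration.

## Problem sizes and numerical choices

The shipped tests and drivers use sizes chosen to make statistical
assertions sharp at interactive runtimes: 100 random configurations for
the H-bond oracle, 50-atom groups for the nonbonded oracle (with a 2
Angstrom minimum separation so r^-12 terms stay within double-precision
absolute tolerances), 2000–5000 frames for RMSD/RMSF closed-form
checks, 10^2–10^4 frames (50 replicates) for the LIE convergence law,
and a 1e-3 Angstrom scan for switching continuity. Ties and seeds are
fixed everywhere a choice could otherwise be nondeterministic.

Known limitations: no energetic (non-geometric) H-bond definition, no
velocity/force trajectories, no PSF or mmCIF input, no grid-based
hydration thermodynamics, no FEP/TI energetics, orthorhombic boxes
only, and the 5hmC charge-adjustment rule is a documented construction
that should be validated against an externally published parameter set
when one is available.
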