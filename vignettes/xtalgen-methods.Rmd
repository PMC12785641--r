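---
title: "xtalgen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xtalgen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it models, which knobs
matter, and where genuinely open design choices were resolved. It states
no empirical result that the test suite does not itself compute.

## The model

`xtalgen` generates artificial centrosymmetric crystal structures —
triclinic cells in space group P-1 (or P1) with an asymmetric unit of
atoms — together with structure-factor amplitudes and exact binary phases.
The product is training data for neural phase-problem solvers: because the
electron density is modelled as a sum of atom-centred Gaussian-like peaks,
a solver does not need chemically valid molecules to learn the
amplitude-to-phase mapping; it needs ensembles whose *statistics* match
real crystals. The generator therefore reproduces, by construction or by
sampling, the database distributions of: unit-cell volume, cell-length
bounds and adjacent axis ratios, oblique-angle concentration near 90
degrees, volume per atom (density), hydrogen mole fraction, element
frequencies split between general and special positions, special-position
occupancy rates, displacement parameters, and — in molecule mode — the
bonded-peak-then-trough shape of the interatomic-distance distribution.

### Volume-first cells

Sampling three lengths uniformly makes the volume the product of three
uniforms, a distribution that rises steeply and peaks far left of the
roughly log-normal volumes of real structure databases. The package ships
the closed-form density of that product (`pdf_volume_uniform_cells`,
derived through the log transform, where the triple convolution collapses
to the integral of a triangle overlap function) precisely so this mismatch
can be quantified; `check_volume_match` turns it into a pass/fail KS test.
The generator instead samples V from LN(mu = 6.04, sigma = 0.394) —
a fit to small-cell database volumes, median about 420 cubic angstroms —
truncated by rejection to the feasible range [lmin^3, lmax^3], then
derives ascending lengths with
a1 ~ U(max(lmin, V/lmax^2, (V/r^3)^(1/3), sqrt(V/(r lmax))),
min(lmax, V^(1/3))), a2 from the analogous interval, a3 = V/(a1 a2),
then permutes. Two resolved ambiguities:

* **r bounds adjacent ratios** (a2/a1 and a3/a2, not a3/a1): these are the
  ratios observed to follow exponential laws in databases, and the bound
  algebra is clean. Default r = 3 — the source text chose a value from the
  database ratio distributions without printing it; 3 comfortably covers
  the bulk of observed small-cell ratios while excluding needle cells.
* The published bound list for a1 omits the constraint that
  `a2 >= V/(a1 lmax)` (which keeps a3 inside lmax) must be compatible with
  `a2 <= r a1`; without the extra lower bound `sqrt(V/(r lmax))` the a2
  interval can be empty for volumes between (lmax/r)^3 and lmax^3/r. The
  package adds it; the property test over random feasible configurations
  is what exposed the gap.

Infeasible volumes raise a domain error naming the violated bound;
`sample_volume_feasible` is the resample-until-feasible wrapper the batch
pipeline uses.

### Oblique cells

Orthorhombic lengths embed as a diagonal cell matrix; a unimodular shear
adds -t|c| along x to the c row (b-unique), preserving volume exactly and
giving beta = 90 + arctan t. Signs are fixed so sheared angles are obtuse
(the database-standard setting); t >= 0. The upper limit combines the
angle cap (default beta_max = 125 degrees) with the length headroom
sqrt((lmax/|c|)^2 - 1) when lengths must stay bounded. Three t modes:

* `t_uniform` — uniform on [0, t_hi]; pushes angles high relative to
  databases.
* `t_uniform_adjusted` — the published "adjusted lower bound" formula is
  not available; this package samples uniformly on [-kappa t_hi, t_hi]
  (kappa default 0.5) and maps negatives to zero, piling mass at 90
  degrees. Documented as an approximation.
* `t_exponential` (default) — truncated exponential; rate defaults to
  ln 2 / tan(5 degrees) so the untruncated median angle is 95 degrees,
  matching the observed concentration just above 90.

Triclinic cells apply three independent draws (shared beta_max per axis);
the second c-row shear uses the remaining headroom so the final |c'| stays
bounded. With both b- and c-shears active the angle between them (alpha)
may fall below 90 degrees — only the two angles at the a axis are
guaranteed obtuse. A length-preserving variant rebuilds the cell from the
induced angles on the original lengths (volume then changes).

### Special positions and cell contents

P-1's inversion centres are the special positions. The package defaults to
**four** centres — (0,0,0), (1/2,0,0), (0,1/2,0), (0,0,1/2) — because the
occupancy statistics the generator is calibrated to (81.4% / 17.2% / 1.4%
of structures with zero / one / more than one occupied at p = 0.05) are
binomial in four trials. Crystallographically there are eight distinct
centres; `space_group("P-1", full_centers = TRUE)` provides them, which
changes those statistics. Which four of the eight the calibration used is
a convention of this package.

Heavy-atom count: N' = round(V / (n V_atom)), floored at one, with
V_atom ~ U(7, 22) cubic angstroms spanning observed densities; hydrogens
N_H = round(N' x / (1 - x)) with x ~ U(0.3, 0.6). Special-position atoms
draw from a separate element table and count against N'.

Element tables are **documented approximations**: the published
supplementary frequencies are not available, only the constraints that
C/N/O make up 89% of general-position heavy atoms but only 49% at special
positions, with transition metals upweighted there. The shipped tables
(`inst/extdata/element_freq_*_synthetic.tsv`) satisfy those totals with a
database-plausible spread over S, Cl, F, P, Br, Si and the first-row
transition metals; both are path-replaceable in the config. Covalent radii
are the standard single-bond (Cordero-style) values.

### Placement rules

Uniform mode: coordinates uniform in the cell, accepted only if every
distance to previously placed atoms — including all symmetry images,
periodic translates, the candidate's own translates and (for general
sites) its own inversion image — is at least d_min = 1.2 angstroms; ten
tries, then the atom is discarded (logged as shortfall, warned).

Molecule mode: after specials, a seed atom, then each atom bonds to a
uniformly chosen parent at length U(0.9, 1.1) (r_A + r_i) in a uniform
sphere direction (normalized-Gaussian method). Acceptance requires the
dichotomy: every pair distance is inside that pair's bond window or at
least 1.5 (r_i + r_j). The bond window and non-bond factor replace hidden
published formulas; 1.5 creates a clear depleted zone without making
growth infeasible. The retry ladder is literal: 20 coordinate/parent
tries, then one different element, then discard. Hydrogens attach only to
heavy parents, after the skeleton completes. An atom too close to an
inversion centre for its radius is rejected (its own-image distance
violates the rules), never snapped onto the centre. A special-position
atom whose drawn element cannot satisfy the rules (a large metal in a
short cell, whose own periodic translate at one cell length would violate
the non-bond floor) is re-drawn a few times and skipped if nothing fits —
a package addition needed to keep the zero-violation invariant exact.

### Diffraction

Reflections enumerate one Friedel representative per pair up to an index
cap (default 10 per axis — the published network-input inequality is not
available; this cap-and-hemisphere layout is this package's documented
convention) and a d-spacing cutoff from the reciprocal metric. Scattering
factors use the 4-Gaussian parameterization (f(0) checked against electron
counts), Debye-Waller attenuation exp(-2 pi^2 U / d^2), no dispersion —
deliberately, so P-1 phases are exactly binary. The complex full-cell sum
asserts |Im F| <= 1e-8 relative and converts sign(Re F) to a phase of 0 or
pi; amplitudes below 1e-10 get phase 0 by convention. Resolution and
completeness are fixed (1.0 angstrom, 100%) by default, or sampled
per structure from U(1.0, 2.0) and U(0.85, 1.0) to emulate the original
training regime. Grids for network input use a dense
(cap+1, 2 cap+1, 2 cap+1) hemisphere array; serialization is a raw binary
block with a text header (no HDF5 dependency in the supported stack), with
an exact documented inverse.

## Seeding and determinism

One root seed; structure k seeds R's RNG with an integer hash of
(root, k), so any structure is reproducible independently of batch size
and batches are restartable at any index. All randomness flows through R's
generator; two runs of the CLI with the same flags produce byte-identical
CIF and reflection files.

## What the generator does and does not emulate

It reproduces marginal statistics — volume, lengths, ratios, angles,
density, composition, occupancy, distance histograms — not chemistry:
there is no valence, no bond angles, no energies, no molecular identity,
and inter-"molecular" structure is whatever the growth process produces. A
green distribution test therefore establishes statistical, not chemical,
realism; conclusions about a solver trained on these data transfer only to
the extent that the amplitude-phase mapping depends on those statistics.
Comparisons against real COD/CSD extracts are out of scope (users may
supply their own volume samples to `fit_lognormal`).

## Numerical choices

* Volume reproduction in `cell_from_volume` to relative 1e-9 (asserted);
  degenerate corner volumes (lmin^3, lmax^3) collapse the sampling
  intervals to a point.
* The analytic volume c.d.f. is built by trapezoid integration of the
  closed-form density on a 20001-point grid and renormalized, adequate for
  KS work at the 1e-3 level.
* Fractional coordinates wrap to [0, 1); distances use the 27-translation
  minimum-image search, valid below half the shortest cell height — the
  test suite cross-checks against a 5x5x5 scan on random skewed cells, and
  the contact audit scans shells of +-2 cells outright.
* u_iso clamps below at 0.001 square angstroms.
* `fit_lognormal` uses the maximum-likelihood (1/n) standard deviation.
* SHELX-style output uses 4-character integer fields and errors on
  overflow rather than corrupting columns.

## Known limitations

* The quantified trough check (acceptance criterion 6c) is red by design
  honesty: with realistic heteroatom frequencies, bonds to S, Cl, P and Br
  land inside a trough window scaled from the C-C bond length, so the
  integrated trough mass is about half the peak mass rather than below
  10%. The depletion itself is unambiguous — the deepest trough bin holds
  about a tenth of the peak bin, and uniform mode shows enrichment
  instead — which is what the signature-contrast test (6b) asserts.
* Only P1 and P-1 are first-class; the operator-list representation is
  extensible but no general space-group machinery is included.
* Equal-atom conversion relabels elements after placement; contact rules
  reflect the original radii.
* Throughput is adequate for on-the-fly use at small cells (the batch
  attribute `rate_ms_per_A3` reports it) but this R implementation
  prioritizes auditability over speed.
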