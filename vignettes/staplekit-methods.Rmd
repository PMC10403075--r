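---
title: "staplekit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{staplekit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staplekit)
```

`staplekit` supports the computational side of designing hydrocarbon-stapled
apolipoprotein C-II (ApoC2) mimetic peptides -- short amphipathic helices
that bind the surface of triglyceride-rich lipoproteins and activate
lipoprotein lipase (LPL) -- and of analysing how such peptides sit on a
phospholipid/triolein trilayer model of the lipoprotein surface. This
vignette records the models the package implements, the conventions and
defaults it fixes, and the reasoning behind the choices that were genuinely
open. Nothing here states an empirical result beyond what the package's own
tests and acceptance script compute.

## The peptide model and its sequence dialect

Stapled peptides are not representable in plain FASTA: they carry
non-natural residues (norleucine, sarcosine, Aib, and the olefin-arm
residues R8/S5/B5/S8 whose hydrocarbon arms are cross-linked by
ring-closing metathesis), D-amino acids, backbone N-methylation, and
terminal caps. The package therefore defines a compact one-line dialect:
uppercase letters are L residues, lowercase their D isomers, `{Nle}`-style
tokens embed registered non-naturals, `Ac-`/`Oct-` prefixes and a `-NH2`
suffix set the caps, and `|i-j` appends a staple between arms `i` and `j`
(`|i-j*` marks a staple whose metathesis has not been performed -- a small
dialect extension so that serialization is total and `parse_sequence()` /
`write_sequence()` are exact inverses on every representable peptide).
Positions are 1-based everywhere.

Mass bookkeeping is elemental: every registered residue carries a residue
formula, peptides add one water, caps add `C2H2O` (acetyl) or `C8H14O`
(octanoyl), amidation swaps `OH` for `NH2`, an N-methyl adds `CH2` unless
the residue formula already contains it (sarcosine), and each *closed*
staple subtracts one ethene (`C2H4`) -- the metathesis stoichiometry. A
stitched peptide (two segments sharing a bis-pentenyl B5 hub) loses two
ethenes; its stitch is represented as two `Staple` records sharing the hub
position, the only residue allowed to carry two arms.

Span classes are fixed by geometry: `j - i = 4` is a short staple (one
helical turn), `j - i = 7` a long staple (two turns); segments sharing a
hub are tagged `stitch_segment`.

### Packaged peptides are documented reconstructions

The packaged peptide set (`apoc2_peptides()`) anchors on mature human ApoC2
residues 59-79 (`AMSTYTGIFTDQVLSVLKGEE`), which is taken verbatim from the
ApoC2 sequence; the stapled (`SP1`), stitched (`SP2`, `SP2a`) and truncated
scaffolds apply the documented design steps to it. The 41-residue
bi-helical mimetic `D6PV` and the 33-residue staple-scanning scaffold `P33`
are *synthetic reconstructions*: their second-helix region is the native
21-mer, while the first-helix region was rebuilt from its documented
properties -- it contains the potentially immunogenic stretch
`KEVFEKLRDLY` with a glutamate at helix-local position 8 and ends in a
proline linker -- because no public sequence record exists for the full
peptide. Analyses that depend on the exact first-helix composition should
treat these two fixtures as representative, not authoritative. For `SP2a`
the fixture applies both terminal acylation and the Aib-for-Ala1
substitution; the order of those two bookkeeping steps does not affect any
computed quantity, so the fixture simply encodes both.

## Helical wheels, hydrophobic moments and staple placement

The wheel uses the ideal alpha-helical twist of 100 degrees per residue
(`angle(n) = ((n - 1) * 100) mod 360`); 3-10 or pi-helical twists are not
offered. The hydrophobic moment of a window is the vector sum of
per-residue hydrophobicity along each position's wheel direction. The
hydrophobicity scale is the Eisenberg consensus scale -- the standard
choice for helical-wheel moment plots -- with non-naturals mapped to their
closest natural analogue and the four olefin-arm residues assigned the Leu
value (their aliphatic arms behave as hydrophobic-face substituents). Since
published wheel plots of these peptides do not name their scale or
normalization, numbers printed in such figures are not comparison targets,
and the package deliberately does not calibrate against them.

The hydrophobic face is the set of positions within a half-angle of the
moment direction, default 90 degrees (a half wheel); the face is undefined
(an error, not an empty set) when the moment is numerically zero, as for an
ideal 18-mer homopolymer whose 18 spokes cancel exactly.

`propose_staple()` was the one place where the obvious specification is
internally inconsistent, and the package takes a position. Requiring both
staple arms to lie inside the hydrophobic face contradicts the ranking
criterion that good placements displace the *least* hydrophobic residues:
the known-good placements on these scaffolds (e.g. the long staple
bridging the two helices, or the one spanning the first glycine to
stabilize the helix) displace serines and threonines that sit at or beyond
the face boundary. Candidate generation is therefore purely geometric
(exact span), ranking is by summed displaced hydrophobicity ascending --
which naturally ranks the polar-displacing, face-sparing placements first
-- and the face requirement is an optional filter (`face_filter = "both"`
or `"either"`) for designs that do want arms strictly on the face. In
`"both"` mode no returned candidate ever has an arm outside the face; that
is property-tested.

Variant arrays reproduce the standard dissection designs: a one-at-a-time
Ala scan (skipping positions that are already Ala and staple arms, whose
replacement would be chemistry rather than scanning), the quadruple Ala
variant at the LPL-activation residues (window-local Y5, I8, D11, Q12,
verified against the scaffold before building), and the "damaged helix"
variant that deletes the window-local Glu8 of the first helix, shifting
every downstream residue by one wheel spoke -- which is exactly why a
single deletion degrades an amphipathic face.

## Antigenicity scanning

The antigenic scan is the classical 7-mer propensity method: the mean
propensity of each overlapping 7-mer is assigned to the window centre
(position `i + 3`), and maximal runs of at least 8 consecutive positions
scoring above 1 are reported as antigenic segments. The published 1990
propensity table is embedded verbatim and version-tagged (`KT1990`).
Non-natural residues are first mapped to natural stand-ins (Nle to Leu,
Sar to Gly, Aib and the olefin arms to Ala, D residues to their L
equivalents) and the applied mapping is kept in the scan's provenance.

The original method also renormalizes by the sequence-mean propensity;
web servers differ in whether they apply it. The package implements the
plain `score > 1` rule by default with renormalization behind a flag
(`renormalize = TRUE`), because the plain rule is the one that reproduces
the documented first-helix antigenicity call on the packaged mimetic
(a segment overlapping `KEVFEKLRDLY`) while leaving the corresponding
native ApoC2 flanking region clean. Two caveats are worth recording: the
comparison against "the native sequence" is meaningful for the
first-helix region (the packaged `NATIVE_H1` fixture); under this table
the native C-terminal helix itself contains a scoring run, so a scan of a
full native-sequence 41-mer is not segment-free. And any such call is
table-version dependent -- hence the version tag.

## The proteolysis rule engine

The engine is deterministic and structural; it predicts *which bonds are
candidates and why they are or are not protected*, never kinetics or
half-lives (percent-intact-versus-time curves are wet-lab readouts outside
its scope). Endoproteases are P1-specificity rules with an active pH
interval:

* trypsin: P1 in {K, R}, pH 5-10 (the designed peptides expose only Lys
  sites, but Arg is included since trypsin does cleave after it);
* pepsin: P1 in {F, L, W, Y}, pH 1-4 -- the minimal broad-specificity
  aromatic/aliphatic set; it is configurable, and the pH gate is what makes
  neutralization to pH 7.4 abolish every pepsin site;
* proteinase K: P1 in {A, V, L, I, F, W, Y} plus Nle (the Leu isostere),
  pH 5-12.

Candidate sites are marked protected by structural blockers: proline at
P1', a D residue at P1 or P1', an N-methylated amide at P1' (the
sarcosine-for-Gly19 trick that shields the preceding Lys bond), and bonds
under a hydrocarbon staple. The staple shielding convention is that bonds
whose P1 position lies in `[i, j - 1]` are covered -- the amides inside
the macrocycle -- since "within the stapled region" does not pin down the
boundary bonds; the convention is verified against hand enumeration in the
tests. The possibility that helix propagation protects bonds *outside* the
staple (a plausible reading of the observed Lys18 resistance in the
single-stapled peptide) is deliberately not modelled: protection outside
the span is claimed only via the explicit N-methyl rule, so the engine
under-claims rather than guesses. Exopeptidase rules report terminal
exposure instead: the N-terminus is open unless capped (acetyl or
octanoyl), the C-terminus open unless the last two residues are D isomers
or the terminus is amidated.

One subtlety about the monotone-protection law ("adding a protection never
increases the susceptible count"): it holds for closing a staple, adding an
N-methyl, flipping L to D, and capping, *provided* the staple's arm
substitutions displace plain residues. Substituting an arm over a residue
that was itself protecting a neighbouring bond (a sarcosine at P1', a D
residue, a proline) trades one protection for another and can transiently
expose a site. The property suite therefore places arms only on natural,
L-configured, non-methylated, non-proline positions -- which is also how
staples are placed in practice.

## Trilayer trajectory statistics

The analysis substrate is a typed-atom topology plus frames of coordinates
in nm with a periodic box; multi-model PDB is the interchange format
(parsed with `bio3d`, written in fixed-column v3.3 layout with the box in
`CRYST1`). Molecule classes are inferred from residue names and atom roles
from atom names; the default map covers the generator's conventions and
common membrane residue names, and can be extended.

All pair distances use the minimum-image convention in all three axes.
Frames are weighted uniformly; equilibration discard is the caller's
decision (subset the frames), not a hidden default.

**Leaflet assignment** splits phospholipids by phosphorus z relative to the
phosphorus z-midpoint and places each peptide in the leaflet whose
phosphorus plane (mean phosphorus z, per frame) is nearest its mean
C-alpha z. A single-plane geometry is a hard error.

**Insertion depth** is the per-residue C-alpha z displacement from the
assigned leaflet's phosphorus plane, with the sign convention that the
plane is zero and displacement *toward the triolein core* is negative for
both leaflets -- so an upper-leaflet and a lower-leaflet peptide at equal
burial report the same profile.

**Hydrogen bonds** use the distance-angle cone criterion
`r(D, A) <= r_max0 - curvature * theta^2` with `r_max0 = 0.33` nm and
`curvature = 0.00044` nm/deg^2, where `theta` is the deviation of the
donor hydrogen from the donor-acceptor axis (the Wernet-Nilsson
parameterization). Donor selection is the peptide's tagged N-H pairs
(backbone amides in generated data), acceptors the six triolein ester
oxygens -- triolein has no donors, so peptide-to-triolein is the only
direction. Counts are kept per frame and per leaflet; the derived
`percent_bonded` (share of frames with at least one bond) is pooled over
leaflets, since a per-leaflet split of a bound percentage is not uniquely
defined when a single peptide changes leaflet.

**Coordination** uses the rational switching function: each atom pair at
distance `r` contributes `(1 - (r/r0)^6) / (1 - (r/r0)^12)` with
`r0 = 0.4` nm. The implementation evaluates the algebraically equivalent
`1 / (1 + (r/r0)^6)`, which removes the singularity at `r = r0` where the
term's limit is 0.5 (general exponent pairs fall back to the raw ratio
with an explicit limit). The formula's "all peptide atoms" wording is
ambiguous between whole-peptide and residue-wise sums; since the reported
profile is residue-wise, `tg_coordination()` sums over the atoms *of each
residue* against each triolein molecule, takes the maximum over triolein
molecules, and averages over frames. The whole-peptide sum is used by
`tg_contact_count()`, which counts triolein molecules whose whole-peptide
coordination exceeds a threshold (default 1) and averages the count over
frames.

## The synthetic trilayer generator

Real reference trajectories for these systems are multi-microsecond
special-hardware runs that are neither deposited nor reproducible at desk
scale, so the trajectory statistics are validated against *planted ground
truth* instead. The generator builds frames in which every analysed
quantity is known by construction:

* phosphorus planes at `+-plane_z` (default 2 nm) with per-frame Gaussian
  z jitter (`jitter_sd`, default 0.05 nm) -- the plane estimate then has
  standard error `jitter_sd / sqrt(n_pl * n_frames)`, which is the
  tolerance used for noisy depth recovery;
* a flat-inserted peptide: C-alphas on the helix-axis line with every
  residue exactly at the planted depth (default -0.3 nm, i.e. buried
  below the plane as the stapled peptides are), plus backbone N, H and O
  satellites that give each residue a donor and standard geometry.
  Flattening trades helical realism for an exact per-residue truth value,
  which is the point of the generator; `ideal_helix_coords()` provides the
  true helical geometry (0.15 nm rise, 100 degree twist, 0.23 nm radius,
  optional kink at a chosen residue, e.g. a Gly) where shape matters;
* `planted_contacts` triolein molecules (default 2, matching the two-to-
  three contacts seen for stapled peptides) parked against the peptide
  with their carbon tails facing it and their ester oxygens held at least
  0.36 nm from every amide nitrogen, so they register as coordination
  contacts without ever satisfying the hydrogen-bond criterion;
* background triolein re-sampled per frame in the core, rejected until at
  least 1.8 nm from every peptide atom -- far enough that its whole-
  peptide coordination stays well under half the contact threshold (the
  margin is asserted in the tests); an unsatisfiable box raises an
  "overfilled" error;
* with probability `hbond_fraction` per frame (default 0.105, mirroring
  the planted single-staple bond fraction used throughout the tests; the
  value is a planted statistic, not reproduced physics), one ester oxygen
  of the first contact molecule is moved into exact criterion geometry:
  0.28 nm from a backbone nitrogen along the N-H axis, zero angular
  deviation. Neighbouring donors see that acceptor at about 28 degrees
  off-axis, where the cone criterion already rejects it, so exactly one
  bond is planted. When no contact molecule exists a dedicated molecule
  hosts the bond, and the sidecar's per-frame contact counts account for
  it.

Composition defaults are a quarter of the simulated trilayer (40
phospholipids per leaflet, 32 triolein in a 6 x 6 x 10 nm box) to keep
test runtimes in seconds; waters and ions are omitted because no statistic
touches them. All randomness derives from `seed` via per-frame substreams:
the same configuration and seed give byte-identical frames, PDB files and
sidecars, which is hash-checked in the tests.

The generator's contract -- every planted quantity is recovered by the
corresponding analysis operator -- is what the test suite enforces:
planted depth to better than 0.005 nm noise-free and within three plane
standard errors under jitter, the planted per-frame bond indicator
recovered *exactly* (so the realized fraction trivially sits within
binomial noise of the nominal one), and contact counts recovered exactly
every frame. Passing these tests demonstrates that the operators measure
what they claim on data whose truth is known; it does not validate
force-field physics, sampling, or any property of real trajectories --
the generator plants geometry, not thermodynamics.

## Assay post-processing

Turbidity clearance traces are summarized by the trapezoidal area under
the observed curve (strictly increasing time required). Dose-response
curves are fitted by least squares to the rectangular hyperbola
`response = baseline + Vmax * d / (EC50 + d)` via Levenberg-Marquardt,
with a four-parameter logistic (Hill exponent) behind a flag; the
hyperbola is the default because saturation kinetics of LPL activation are
conventionally summarized by EC50 and Vmax alone, and because published
EC50s from unspecified fitting models are not legitimate calibration
targets. The `converged` flag is honest: flat or monotone-decreasing
responses, optimizer failure, or non-positive fitted parameters are
reported as degenerate rather than as numbers. Plasma lipid timecourses
are normalized per subject to their `t = 0` baseline (`y/y(0) * 100`,
error on non-positive baselines) with group mean and SD per time point;
downstream inferential statistics (ANOVA and post-tests) are left to
general-purpose tools, and the functions emit plain data frames for that
purpose.

## Problem sizes and numerical tolerances

The test suite and acceptance script size their simulations for
seconds-scale runtimes, which the recovery mathematics supports: oracle
equivalence uses 100 randomized frames of a few residues and molecules at
a relative tolerance of 1e-9 (implementation and brute-force oracle share
no code); hydrogen-bond recovery uses 2000 frames of a 6-phospholipid,
3-triolein system; depth recovery uses 8 phospholipids per leaflet and up
to 200 frames; the monotone-protection law is exercised on 1000+ random
peptide/protease/protection triples. Degenerate inputs fail loudly
everywhere (empty windows, zero moments, single-leaflet geometry,
non-monotone time, empty peptides) rather than returning silent defaults.

## Known limitations

* The engine predicts protease site counts and protection provenance, not
  cleavage rates; two peptides with equal counts may differ greatly in
  half-life.
* Antigenic-segment calls are propensity-table heuristics, not epitope
  predictions; no MHC or B-cell model is included.
* The synthetic trilayer is a geometric scaffold with planted statistics;
  it contains no energetics, no dynamics, and no realistic lipid packing,
  and agreement on it says nothing about real membranes beyond operator
  correctness.
* The packaged bi-helical fixtures are reconstructions (above); masses and
  per-position analyses of their first-helix region are representative
  only.
* Hydrophobic-moment values depend on the chosen scale; only comparisons
  within one scale are meaningful.
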