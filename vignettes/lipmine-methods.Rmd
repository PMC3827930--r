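---
title: "Mining versatile sterol esterases and lipases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining versatile sterol esterases and lipases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipmine)
```

# Scope and model

`lipmine` turns a published-style genome-mining protocol for versatile
sterol esterases/lipases of the *Candida rugosa*-like family into a tested,
reusable pipeline. The underlying biological model is simple and explicit:

* family membership is signalled by two conserved motifs — **GESAG** (the
  catalytic shoulder; the serine of the Ser–Glu–His triad is its third
  residue) and **GGGF** (the oxyanion hole);
* sterol-ester affinity correlates with the number of hydrophobic residues
  in the **lid**, the amphipathic flap strictly between two conserved,
  disulfide-bonded cysteines;
* catalytic efficiency correlates with the geometry of the intramolecular
  tunnels radiating from the catalytic serine: a broad, *straight* exit
  tunnel (the *O. piceae* esterase configuration) versus a *bent* one (the
  Lip3 configuration), and with the hydrophobicity of the residues within
  4 Å of the tunnel.

The pipeline never claims catalytic activity; it ranks candidates by these
structural proxies.

# Stage-by-stage parameters

## Screening

Keyword matching is a case-insensitive *substring* search over the whole
description line — deliberately not word-boundary aware, because it
emulates a portal free-text search. De-duplication is exact residue-string
equality; the protocol's notion of "redundant" is not defined more
precisely anywhere we could anchor to, so clustering at an identity
threshold is out of scope and both dedup-then-filter (default) and
filter-then-dedup orders are exposed in `screen_config()`. Motif matching
is exact substring matching; all (possibly overlapping) occurrence
positions are recorded, 1-based. Records containing non-standard letters
(X, B, Z, `*`) are kept; exact matching guarantees motifs never match
across them.

## Alignment and identity

`global_align()` is Needleman–Wunsch under BLOSUM62 with affine gaps,
backed by `Biostrings::pairwiseAlignment` (end gaps penalised). The gap
convention is the Biostrings one: a gap of length $k$ costs
$\mathrm{open} + k \cdot \mathrm{extend}$, defaults 10 and 0.5. The test
suite checks the scores against an independent oracle that *enumerates
every global alignment* of short sequences and scores them directly.
Percent identity is identical columns divided by **full alignment length,
including gap columns** — one unambiguous convention, applied everywhere
(reported reference identities computed with other tools can differ by a
few points; they are treated as approximate, never asserted). Letters
outside the 20-letter alphabet are mapped to X and score as near-mismatches.

## Family placement

The reference protocol built a MUSCLE + maximum-likelihood tree; that is
not desk-scale reproducible, so placement here is pairwise NW distance
($d = 1 - \mathrm{identity}/100$) + neighbor joining, which is fully
implementable, deterministic, and adequate for *family-level* grouping; a
pre-built Newick tree can be supplied instead. The NJ implementation uses
the Studier–Keppler $Q$ matrix, lexicographic-by-taxon-id tie-breaks, and
clamps negative branch lengths to zero moving the deficit to the sister
edge (the joined pair's path length is preserved). Alignment distances are
not metric; triangle violations are expected and tolerated.

`assign_family()` returns the family of the smallest edge-induced
bipartition side containing the candidate and at least one reference,
provided its references are pure; when several minimal sides tie and
disagree (a candidate at the exact midpoint between two families), the
candidate is `unplaced`. "Most closely related to the versatile set" is
operationalised as the mean alignment distance to the versatile panel
members, ascending, ties by id.

## Feature transfer and the lid statistic

Features are transferred by globally aligning each candidate to the
annotated reference and reading positions through alignment columns;
a feature aligned onto a gap is *absent*, and a mapped cysteine that is
not Cys in the candidate is flagged *mismatch* (warning) while the lid is
still computed from the mapped columns. The lid is the residues strictly
between the two cysteines, mature-chain coordinates, 1-based.

"Hydrophobic" is nowhere given a definition we could anchor to, so the set
is a config value, default `{A, V, L, I, M, F, W, P}`. The calibration
check is that the reference panel reproduces the canonical lid ordering
Lip2 > Lip3 > Lip1 = 12 > 10 > 8 and OPE = 13 under this set — which it
does by construction on the synthetic panel (below).

The "position 222 / position 137" numbering for GESAG/GGGF in Lip3 is
ambiguous between precursor and mature coordinates; this package resolves
it as *precursor motif starts with a 15-residue signal peptide*, which puts
the catalytic serine at mature 209 — the classic *C. rugosa* Ser209 — and
GGGF at mature 122. The packaged annotation records the convention in its
`note` field and is an editable JSON file (`inst/extdata/`), not
hard-coded. The triad is recorded as Ser-Glu-His; the variant "Ser-Gln-His"
that appears in some derived material is treated as a typo for the
conserved Glu.

Signal peptides are *inputs* (SignalP-style prediction is out of scope):
`strip_signal_peptide()` applies an externally supplied cleavage position.
Sequons are all positions with N-X(≠P)-[S/T], overlaps included.

## Tunnel detection

`find_tunnels()` is a simplified, fully-specified replacement for a
Voronoi-based tunnel tool; exact agreement with Caver is explicitly not
promised. Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `grid_step` | 0.8 Å | voxel edge |
| `probe_radius` | 1.4 Å | water probe |
| `atom_radius` | 1.7 Å | united-atom radius for every atom |
| `bulk_margin` | 1.2 Å | extra clearance defining bulk solvent |
| `mouth_sep` | 8 Å | minimum separation between distinct mouths |
| `max_tunnels` | 2 | tunnels returned |

A voxel is free when its center clears every atom by more than
`atom_radius + probe_radius`. The search starts at the free voxel nearest
the seed residue's reference atom (OG if present, else CA); the seed
residue's own atoms are excluded from the obstacle model, since the
catalytic serine itself lines the pocket. BFS runs over the 6-neighbourhood;
a path is truncated at its first *surface contact* (a free voxel within two
voxels of bulk solvent). Truncation at surface contact, rather than at the
grid boundary, is what makes mouth de-duplication meaningful: without it,
every boundary voxel reached by walking around the *outside* of the protein
would count as a mouth. Distinct tunnels must have portals (last interior
voxel) separated by more than `mouth_sep`; ranking is by bottleneck radius,
then arc length.

Raw voxel paths are biased: centers sit up to ~0.7 Å off the medial axis
and the 6-connected staircase inflates arc length. The centerline is
therefore re-centred by greedy local clearance maximisation (displacement
capped at 2.5 grid steps), smoothed by a single 3-point moving average,
re-centred once more with a tight cap (smoothing drags high-curvature
points, e.g. an elbow, off the medial axis), and finally simplified by
collinear-point elision (tolerance 0.01 Å). Lining residues are those with
any atom within 4 Å of the centerline *polyline* (the continuous version of
"within 4 Å of any centerline point", robust to elision). Per-point radius
is clearance minus atom radius; straightness is end-to-end distance over
arc length, and `classify_shape()` calls a tunnel straight at ≥ 0.85 — a
threshold that cleanly separates the two qualitative reference classes
(straightness of a planted bend of angle $\theta$ with equal legs is
$\cos(\theta/2)$: 0.94 at 40°, 0.71 at 90°).

The voxel grid is anchored to a canonical frame derived from the atom
coordinates themselves (leading covariance eigenvector with
skewness-fixed sign; second axis toward the atom farthest from the first
axis; right-handed completion), so tunnel output is *exactly* invariant
under proper rigid motions. For near-spherical atom clouds the leading
eigenvector is unstable and this guarantee weakens; the toys are strongly
elongated, and for real structures the property is approximate anyway.

## Ranking

Affinity classes anchor to the printed reference counts: Lip3's 10 is the
low baseline, OPE's 13 the high mark, so `high ≥ 13`, `low ≤ 10`, 11–12
intermediate. The reference narrative is internally inconsistent at count
12 (one count-12 enzyme called high-affinity, another intermediate); this
package defaults 12 to intermediate and emits the ambiguity as an explicit
report footnote rather than resolving it silently. Efficiency flags map
straight → OPE-like, bent → Lip3-like, missing structure → unknown; no
merged score is produced because no merging rule exists to anchor to.

# The synthetic data: what it emulates, what it does not

## Proteomes

`generate_proteome()` emulates a portal search space: background records
with configurable length range and composition (default uniform with Cys
down-weighted to 0.01 so accidental lid-delimiter cysteines are rare), a
configurable fraction of keyword-bearing headers (default 0.3), and
planted candidates whose GESAG/GGGF positions, Cys pair, lid hydrophobic
count, triad residues and sequon count are exact by construction. Planted
records draw filler residues from the background distribution *excluding
Asn and Cys* (renormalised) so the sequon and Cys ground truth stays
exact, and lid filler additionally excludes Gly so no accidental motif can
arise inside the lid. Background records that happen to contain both
motifs are *collisions*: recorded in the ground-truth table by an
independent scan, never resampled away, so oracle counts stay honest.

## Toy structures

`generate_structure()` builds CA-only shells around a hollow straight or
two-segment bent axis. `tunnel_radius` is defined as the bore radius to the
shell atoms' van der Waals surface (ring radius = tunnel_radius + 1.7 Å),
which makes probe passability exactly `tunnel_radius ≥ 1.4`; the default
2.1 Å guarantees a free axial voxel corridor on the default grid (the
corridor radius is `tunnel_radius − 1.4`, and voxel centers sit up to
0.69 Å off-axis). Bent axes get a miter joint of interpolated elbow rings,
followed by a culling pass that removes any atom intruding into the bore.
The buried end is walled off by extension rings and a cap; the pseudo
catalytic Ser sits *on the axis* at the buried end (or the midpoint for the
two-mouth variant used to test mouth separation). Ground truth lining is
every CA within 4 Å of the axis polyline, by exact point-to-segment
distance; ground-truth straightness is the analytic $\cos(\theta/2)$.

Known limitations, hence what a green test does *not* establish: toys have
no side chains, no realistic fold, and a single-width bore; elbow bends
sharper than ~90° pinch the miter below the default grid resolution, so
detection-based tests stop at 90° (the generator accepts up to 120°, and
the classification boundary is tested analytically across the full range).
Measured straightness of a bent tunnel carries a small positive bias
(~0.01) because any medial path cuts a finite-width corner by roughly the
bore radius; bend tests use 28 Å tunnels so this bias stays well inside the
0.02 recovery tolerance. None of this says anything about agreement with
Voronoi-based tunnel tools on real all-atom models.

## The synthetic reference panel

The real reference panel (UniProt P20261, P32946–P32949, Q2TFW1, the
*M. albomyces* esterase, and representatives of the Yarrowia, brefeldin,
organellar, pancreatic and bacterial families) requires network downloads,
which the build environment does not have. `generate_reference_panel()`
constructs a clearly-labelled synthetic stand-in that *encodes the
documented ground truth* of the real family: 549-residue precursors
(15-residue signal, 534-residue mature chain), motif/triad/Cys layout as
above, lid hydrophobic counts 8/12/10/11/9 for Lip1–5 and 13 for OPE/Malb,
within-family point substitution at 5.5% realising the canonical 77–88%
pairwise identity band, and OPE divergence at 55% realising the
"just above 40%" identity to the Lips. Lip4/Lip5 lid counts (11/9) are not
documented anywhere we could anchor to; they were chosen once inside the
documented family range. The accession-based acceptance checks therefore
validate that the *pipeline recovers these constructed properties*, not
that the real proteins have them — the distinction is deliberate and the
files are named `synthetic_*`.

# Numerical choices and degenerate inputs

* All coordinates are 1-based; spans inclusive; mature-chain after optional
  signal stripping.
* Ties break lexicographically by identifier everywhere (NJ pair choice,
  candidate ranking).
* Distance matrices must be symmetric to 1e-8 and zero-diagonal to 1e-12;
  non-metric inputs are accepted.
* An empty tunnel set is a valid `find_tunnels()` result (buried seed with
  no path); scoring an empty set is an error, as is an absent seed residue.
* `deduplicate()` keeps first occurrences; the removed→kept mapping is
  attached, so nothing is silently dropped.
* Report generation is a pure function of stage outputs; the determinism
  test asserts byte-identical TSV across reruns.

# Design decisions that were genuinely open

* **Dedup vs filter order**: the source protocol does not say which came
  first; default dedup-then-filter, both exposed.
* **NJ instead of ML**: family-level grouping does not need likelihood
  inference; NJ on NW distances is deterministic and testable against
  additive-matrix recovery.
* **Distance to centerline, not to inscribed spheres**: the plain reading
  of "within 4 Å of the tunnel" and the simpler contract.
* **Lining pooled over all tunnels** ("tunnels area") to give one
  per-structure percentage.
* **12 → intermediate** with a surfaced warning, because the reference
  classes contradict each other at that count.
* **JSON instead of YAML** for config/manifest files: no YAML parser among
  the available dependencies, identical content.
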