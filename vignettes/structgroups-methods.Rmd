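---
title: "Methods: grouping, alignment tracks and superposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grouping, alignment tracks and superposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structgroups)
```

This vignette records the models and procedures the package implements,
the assumptions behind them, and the design choices made where several
reasonable options existed. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The data model

Structure collections are projected onto a three-level hierarchy: an
**entry** is one archival record (a deposited structure or a computed
model); an **entity** is one distinct polymer sequence within an entry;
an **instance** is one chain realizing an entity (a homodimer is two
instances of one entity). Entities are the unit of clustering and of
sequence-level grouping; deposition groups aggregate whole entries.

Sequence positions are 1-based and inclusive everywhere (the mmCIF
`label_seq_id` convention), and all alignment columns and tracks inherit
that coordinate system. Legacy PDB insertion codes are renumbered
sequentially at parse time so downstream code sees a single integer
axis.

Provenance (`experimental` vs `computed`) is **declared** metadata — a
sidecar column, a CLI flag, or the mmCIF determination-methodology
item — never inferred from B-factor ranges, which would be fragile.
Computed models carry per-residue pLDDT in the B-factor field; it is in
`[0, 100]` and exists only for computed entities. Modified or unknown
residues map to `'X'` with a warning; water and the twenty standard
amino acids are never ligands, every other non-polymer component is.

## Pairwise alignment and sequence identity

Global alignment is Needleman–Wunsch with affine gaps (Gotoh's
three-state recurrence, implemented in C++), BLOSUM62, gap open 11, gap
extend 1; a gap of length $k$ costs $11 + k$, matching the convention
of `Biostrings::pairwiseAlignment`, which the tests use as an
independent score cross-check alongside a plain-R dynamic-programming
oracle. Traceback tie-breaking is fixed (prefer diagonal, then up, then
left) so aligned-pair lists are deterministic.

Identity is normalized by the shorter sequence:

$$\mathrm{id}(a,b) = \frac{\#\{\text{aligned columns with identical residues}\}}{\min(|a|,|b|)}.$$

With this normalization a full-length chain and its exact fragment score
1.0 and co-cluster at the 100% threshold, which is the behaviour a user
comparing a construct against its parent sequence expects. This is a
deliberate choice among the several identity definitions in circulation
and is not claimed to reproduce any particular clustering tool's mode.

## Clustering

Greedy centroid clustering, CD-HIT style: entities are visited
longest-first (ties by uid ascending); each joins the earliest-founded
cluster whose representative it matches at or above the threshold, else
founds a new cluster. Only member-vs-representative comparisons are
made. The algorithm is transparent, exactly testable at desk scale, and
deterministic; an import path for externally computed cluster files
preserves fidelity for users who run a dedicated clustering engine at
archive scale. Incremental updates scan representatives in cluster-id
order and never disturb existing memberships, mirroring a weekly
archive update. The default ladder is 30/50/70/90/95/100%.

The partition property (disjoint, covering, representative in its own
cluster) is asserted on every pipeline run. Cluster-count monotonicity
across the ladder is a property test, not a theorem: greedy clustering
does not guarantee it in adversarial cases, but it holds across the
seeded mutant-family corpora the suite generates.

## The group alignment

Group alignments are **reference-anchored (star) alignments**: columns
are positions $1..L$ of the reference sequence — the accession
reference for accession groups, the cluster representative for identity
groups — and each member is aligned pairwise to it. This keeps columns
well-defined, cheap, and directly interpretable in reference
coordinates. The cost is that member-vs-member insertions are not
mutually aligned: member insertions relative to the reference are
recorded (position + preceding column) but occupy no column. A full
progressive MSA would align them at the price of unstable columns; for
reference-centric display and track arithmetic the star alignment is
the better trade.

Consensus counts the gap as a symbol: members whose aligned span covers
a column but skip it (a deletion) vote "gap"; members whose span does
not reach the column (terminal truncation) are excluded from that
column's denominator entirely. That distinction — deletion vs absence —
mirrors the modeled/unmodeled display logic. Ties break
residue-over-gap, then alphabetically. Variation is
$1 - \text{modal residue count} / \text{members with a residue}$,
so 0 means perfectly conserved. Large alignments are paginated in
blocks of 50 members.

## Positional tracks and their denominators

Three track families use three deliberately different denominators:

* **Structural features** (helix, strand, domain): fraction over members
  with a *modeled* residue at the column. Unmodeled residues carry no
  geometric information and would dilute the signal.
* **Per-ligand binding**: fraction over members contacting that ligand
  *anywhere*. A ligand bound by one member of a 50-member group still
  shows frequency 1.0 at its contact columns; normalizing by group size
  would bury rare but real sites near zero.
* **Global binding**: raw count of (member, ligand-component) contact
  events per column — an absolute histogram, not a rate.

Contacts are heavy-atom distances: a residue contacts a ligand component
when any non-hydrogen atom pair is within **4.5 Å** (a common literature
convention; configurable). Detection is a brute-force distance scan —
desk-scale structures need no spatial index — and is cross-checked
against an independent all-pairs loop in the tests.

Secondary structure is assigned from **CA geometry only** (P-SEA-style):
helix when $d_3 = 5.3 \pm 0.5$ Å and $d_4 = 6.4 \pm 0.6$ Å, or CA angle
$89 \pm 12^\circ$ with CA dihedral $50 \pm 20^\circ$; strand when
$d_2 = 6.7 \pm 0.6$, $d_3 = 9.9 \pm 0.9$, $d_4 = 12.4 \pm 1.1$ Å, or
angle $124 \pm 14^\circ$ with $|$dihedral$| \ge 145^\circ$. Helix needs
5 consecutive strict hits, strand 4, each extendable by one residue per
side under relaxed criteria; chains (or modeled segments) shorter than
5 residues are all-coil. CA-only rules are self-contained — fixtures
carry backbones, not hydrogen-bond networks — and exactly testable. The
published rescue of 3-residue strands by inter-strand contact counts is
omitted: it requires sheet partners that single-chain corpora do not
have and only adds strands shorter than the 4-seed rule. A
hydrogen-bond method (DSSP) would differ at element boundaries.

pLDDT bins follow the established confidence convention: very-high
$\ge 90$, confident $[70, 90)$, low $[50, 70)$, very-low $< 50$ —
half-open on the lower side, so 69.9 is "low".

## Superposition

Rigid-body fits use the Kabsch SVD solution with reflection correction
(sign flip of the smallest singular vector), fitted over **CA atoms
only**: the alignment yields residue-level, not atom-level,
correspondence. The full structure — all chains and ligands — is then
carried through the transform, so ligand positions can be compared
across superposed members. There is no iterative outlier trimming: a
single least-squares fit is what "rigid-body superposition" means here,
and column-range restriction is the user's tool for conformational
substructure. Fitting on one domain of a hinged pair leaves that domain
at numerically zero RMSD while the mobile domain's RMSD measures the
motion; a full-range fit lands strictly between the two. Fewer than 3
correspondences, or collinear geometry, is an error. The reference
member defaults to the group's first member with coordinates — a
deterministic stand-in for "first loaded".

The implementation is verified against an independent quaternion
(Horn) closed-form solution to $10^{-9}$ Å on seeded random clouds.

## The synthetic corpus

The fixture generator defines the study conditions for all tests:

* backbones built from ideal torsions by natural-extension-of-reference
  (NeRF) with standard bond geometry (N–CA 1.458, CA–C 1.525, C–N
  1.329 Å; trans peptide) — consecutive CA distances come out at the
  canonical 3.8 Å without tuning;
* a default group of **20 variants** of one 80–120-residue ancestral
  sequence at **5% point mutations** per position (a mutated position
  redraws uniformly over the 20 residues, so variant-vs-ancestor
  identity is $1 - \mu \cdot 19/20$ in expectation — the statistic the
  property tests check);
* a fifth of members emitted as computed models with pLDDT
  $\mathcal{N}(85, 8)$ clamped to $[0, 100]$ (a realistic
  high-confidence model profile); experimental members carry one
  unmodeled gap of 5–15 residues with probability 0.1;
* optional hinge motions (every second member rotated about an axis
  through the pivot CA, axis derived from the fixed domain so
  rotations compose) and single-atom ligands placed at a fixed offset
  from an anchor CA, pointing away from the chain centroid;
* the mixed-provenance scenario used throughout the tests — five
  experimental members plus four computed models — is one
  parameterization (`n_entities = 9, n_computed = 4`) of the same
  generator.

One seeded Mersenne-Twister stream per spec, threaded explicitly, makes
every file byte-identical across reruns. What the generator does *not*
emulate: real sidechains, packing, homology beyond point mutations and
deletions, correlated disorder, or experimental noise — so green tests
demonstrate the correctness of the bookkeeping and geometry, not
biological realism of any particular inference.

Problem sizes used by the suite and the acceptance script — 100
ten-point superposition instances, 200 alignment oracle pairs of length
up to 40, three 8-member mutant families for the clustering ladder, a
20-entity pipeline corpus — were chosen as the smallest sizes at which
the properties are non-trivial while the whole suite stays interactive.

## Serialization

Export documents (group provenance, group alignment, group annotations)
follow the group-API vocabulary — aggregation granularity, aligned
regions, member ranking, a histogram flag switching annotations between
aggregated tracks and per-member features — without claiming wire
compatibility with any live service. Shipped JSON schemas
(`inst/schemas/`) are enforced on every export and import by a
structural validator (types, required fields, enums). JSON is written
with stable key order, full numeric precision and no timestamps;
export → import → export is byte-identical, and so are full pipeline
reruns under a fixed seed. Pipeline outputs carry a provenance block
(software version, config hash, seed).

## Known limitations

* Star alignment does not mutually align member insertions; a column
  can only exist where the reference has a residue.
* Greedy clustering is order-dependent by construction (longest-first,
  uid tie-break); it is deterministic but not globally optimal, and
  membership will differ from k-mer-prefiltered or cascaded tools.
* CA-only secondary structure disagrees with hydrogen-bond assignments
  near element termini and for irregular elements.
* Ranking uses reference coverage only (ties by release date, then
  uid); no quality or resolution criteria are applied.
* The mmCIF reader covers the PDBx subset the package writes plus
  standard `atom_site`/`entity_poly` categories; exotic dialects may
  need conversion first.
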