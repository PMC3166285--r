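---
title: "ringscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscan)
```

This vignette explains the models and procedures implemented in `ringscan`,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The biological setting

RING domains are small (roughly 40–60 residue) zinc-binding domains that
confer E3 ubiquitin-ligase activity: the domain docks an E2
ubiquitin-conjugating enzyme and positions it for ubiquitin transfer.  The
fold is held together by two zinc ions coordinated in a cross-brace
topology by eight ordered *metal-ligand positions*, canonically cysteines
and one histidine.  The identity of the residues at those eight positions
names the domain type (C3HC4, C3H2C3, and so on); around them the fold
carries four regions whose backbone conformation is conserved across the
superfamily — the N-terminal loop, the first β-sheet region, the βα-region
and the C-terminal loop — and six additional conserved residues (four
hydrophobic, two polar) that sit in those regions and shape the E2-binding
surface.  `ringscan` implements the machinery to find and quantify all of
these from standard inputs: sequences, alignments, PDB coordinates and
BLAST tabular hit files.

## RING-type classification

`scanLigandPositions()` searches a sequence for admissible 8-position
vectors under a spacing model; `classifyRingType()` maps the 8 letters to a
type label; `classifySequence()` combines the two.

**Spacing model.**  The literature names the types but not a scanning
procedure, so the default spacing model brackets canonical RING spacing
generously:

```
C - x(1,3) - C - x(8,40) - [CHDGST] - x(1,4) - [HC] - x(1,4) - [CHGD]
  - x(1,3) - C - x(3,50) - C - x(1,3) - [CD]
```

with Ser/Thr additionally admitted at positions 2 and 6 so that RING-S/T
patterns (described in plants) are scannable.  Every gap range and every
per-position alphabet is a constructor argument of
`ligandSpacingModel()`; the defaults are deliberately wide so that real
domains are not missed, at the cost of occasional overlapping candidates —
which the best-candidate rule resolves.

**Rule table.**  The decision procedure is keyed on the *substitution set*
relative to the C3HC4 reference `(C,C,C,H,C,C,C,C)`:

| substitutions                  | label    |
|--------------------------------|----------|
| none                           | C3HC4    |
| His at 5                       | C3H2C3   |
| Asp at 8                       | C3HC3D   |
| position 4 → C and 5 → H       | C4HC3    |
| Gly at 5                       | C3HGC3   |
| position 4 → C (all-Cys)       | C4C4     |
| Asp at 5                       | RING-D   |
| Ser/Thr at 2 and/or 6 only     | RING-S/T |
| anything else, or a letter outside {C,H,D,G,S,T} | unclassified |

This formulation is total and deterministic: every combination not named
above fails loudly as `unclassified` rather than being silently absorbed
into a neighbouring type.  An exhaustive enumeration over all `6^8`
letter vectors is compared against an independently coded oracle in the
test suite.

**Best candidate.**  When several admissible position vectors exist, the
one with the fewest substitutions wins; ties go to the leftmost
(lexicographically smallest) vector.  Sequences with no candidate and an
upstream `"U-box"` annotation hint are labelled U-box — U-box domains keep
the RING fold without the metal-chelating residues, so they are not
detectable by a ligand scan and must come from a domain annotation.

**Three-zinc types.**  The 12-ligand C6H3C2D type binds a third zinc ion,
but the ligand order of the third site is not well established.
`scanTripleZinc()` therefore runs a composition test (three His, an
optional Asp restricted to positions 8 or 12, Cys elsewhere) and flags its
output as putative.  It is a separate entry point rather than part of
`classifySequences()`.

## Consensus and conservation

`columnProfile()` scores one alignment column.  The denominator is the
number of non-gap entries; non-standard residues (mapped to `X`) count in
the denominator but belong to no class.  The consensus is:

1. a single letter, if one letter's fraction reaches the level threshold
   (default 0.8);
2. otherwise the first class in preference order whose aggregate fraction
   reaches the threshold;
3. otherwise none.

The preference order is identity first, then the six specific classes from
smallest membership up (alcohol, negative, aliphatic, positive, aromatic,
tiny), then charged, hydrophobic, small, polar, bulky.  Ordering the
specific classes before the broad ones is what makes a column of Ile/Val/
Leu report the aliphatic symbol `l` rather than the hydrophobic `h` that
would also qualify.

**Conservation index.**  The 0–9 index used alongside the consensus level
is defined here as `round(9 · (1 − H/ln 20))`, where `H` is the Shannon
entropy of the non-gap letter frequencies.  The index is a reimplementation
choice: published alignment figures print 0–9 indices produced by external
alignment software whose formula is not stated, so an entropy-based scale
was chosen and the published calling threshold (index strictly greater
than 4) kept as-is.  Rounding uses `floor(x + 0.5)` so that half-values
round up deterministically rather than to even.  A consequence worth
knowing: with very few sequences the sample entropy is bounded by
`ln(n_rows)`, so shallow alignments inflate the index — at four rows any
column with a class consensus scores at least 5.  Conserved-column calling
is therefore only meaningful at realistic alignment depth (tests use 24–40
rows).

**Equivalent residues.**  `assignEquivalentResidues()` maps conserved
non-ligand columns to the six roles by SCR region: N-loop → hydro1,
βα-region in column order → hydro2 and hydro3, C-loop → hydro4; the
βα-region polar column → polar1 and the C-loop polar column → polar2.
Columns whose consensus is an invariant Cys or His are reported separately
as ligand columns and never consume a role.  One deliberate widening: a
column whose identity consensus is Pro qualifies for a hydrophobic role
even though Pro is not a member of the printed hydrophobic class, because
the C-loop hydrophobic role is predominantly proline in real RING domains.
Surplus or missing columns per region are reported as diagnostics, never
silently dropped.

## Superposition and structurally conserved regions

**Superposition** is the Kabsch least-squares fit via singular value
decomposition with reflections excluded (determinant forced to +1).
Degenerate input — fewer than three pairs, or collinear points — raises an
error rather than returning silent NaNs.  The test suite checks the fit
against an independent quaternion (Horn) implementation to 1e-9.

**Per-column RMSD.**  For an ensemble, every structure is superposed onto
a reference (the first structure by default; the frame is configurable
because no canonical frame exists for a progressive superposition), using
the columns ungapped in the pair.  For each column that is gap-free in all
rows and has a C-alpha in every structure, the profile records the RMSD of
the equivalent C-alpha positions from their centroid.  Columns with a gap
or a missing C-alpha are undefined and logged.

**SCR detection.**  Parameters: window `w = 3`, threshold `3.0` Å
(boundary inclusive), minimum length 3, all settable via `scrParams()`;
`threshold = 2.0` is the stricter preset appropriate for describing region
cores rather than detecting them.  The detector marks every window of `w`
consecutive gap-free columns whose mean RMSD is at or below the threshold,
takes maximal runs of qualifying windows as segments, merges segments that
overlap or touch, and discards segments shorter than the minimum length.

Two readings of "extend the seed while the mean stays below the threshold"
were possible: track the mean of the *whole growing segment*, or the mean
of the *trailing window*.  The cumulative reading degenerates: once a
low-RMSD run is longer than a couple of columns, its cumulative mean
absorbs arbitrarily disordered spacers (a 13-column run at 0.5 Å absorbs a
6.6 Å column because `(13·0.5 + 6.6)/14 ≈ 0.94`), and all regions merge
into one segment.  The trailing-window reading keeps segment boundaries
within one column of the true noise boundaries, which is the behaviour a
structurally-conserved-region detector needs; it is what `detectScrs()`
implements.  Scanning *every* window start (rather than resuming only
after an emitted segment) makes the output order-independent and equal to
an exhaustive enumeration of qualifying-window coverage, which is how the
property tests verify it.  The ±1-column fuzz at boundaries is inherent:
a window straddling a region edge can still pass on the strength of its
low-noise columns.

## Hydrophobic core and solvent accessibility

SASA is computed by the Shrake–Rupley sphere-point method over heavy
atoms: each atom's solvent sphere (van der Waals radius + 1.4 Å probe) is
sampled at 960 quasi-uniform golden-spiral points and the accessible
fraction counted against all neighbouring spheres.  Relative SASA divides
the per-residue sum by a theoretical per-residue maximum table.  Method,
probe radius, point count and burial threshold (default 0.10 relative
SASA) are all parameters of `coreParams()` because none of them is forced
by the survey itself; the defaults are the field's customary values.  At
960 points the isolated-sphere and two-sphere analytic checks pass within
2 %.

`hydrophobicNeighbors()` returns hydrophobic-class residues whose minimum
heavy-atom distance to the query is within 4 Å, excluding the query's
sequence neighbours at offset ±1 — otherwise every residue trivially
"contacts" its bonded neighbours.  All-heavy-atom minimum distance was
chosen over side-chain-only or C-beta distances; the choice is stated here
because published descriptions leave it open.  `validatePatch()` encodes
the patch criterion: hydro1, hydro3 and hydro4 must each approach the
central hydro2 residue within the cutoff.

## Interface contacts

`extractContacts()` reports, for every residue pair across two disjoint
chain selections, the minimum heavy-atom distance when it is within 4.0 Å,
tiered as *close* within 3.5 Å (both boundaries inclusive, matching
"within" phrasing).  The close tier is per-residue-pair minimum distance;
atom-selection semantics of interactive viewers differ, and residue-pair
minimum is the reproducible choice.  Backbone hydrogen bonds are
distance-only N···O pairs within 3.5 Å across the interface: crystal
structures usually lack hydrogens, so the amide nitrogen stands in for the
donor proton and no angle criterion is applied.  Contact residues are
assigned to regions I/II/III (N-loop, α-helix of the βα-region, C-loop)
through their alignment columns and the labelled SCR table; β-region
residues map to no roman-numeral region by construction.  For real
complexes the RING-domain side of the selection must be supplied as a
`CHAIN:START-END` spec (conventionally the classifier's ligand span plus a
two-residue flank), since deposited entries do not record a domain
boundary convention.

## Orthology and architectures

`rbbh()` implements reciprocal best hits over two directional BLAST
tabular files.  The ranking key — bit score, then lower e-value, then
higher percent identity, then lexicographic subject id — is the
conventional one, fixed explicitly for determinism; self-hits are removed
before ranking.  `compareArchitectures()` classifies ordered domain-name
lists as identical / insertion / deletion / rearrangement / other, where
insertion and deletion are strict-subsequence relations located by a
leftmost longest-common-subsequence embedding.  The finer labels
(rearrangement, other) exist for reuse; a vertebrate/insect ortholog pair
that gained a CARD domain is the canonical insertion case.

## Synthetic data: what it emulates, and what it does not

All generators run under a single seed (`withr::with_seed`) and are
byte-deterministic, coordinates fixed at 3 decimals in PDB fields.

* `genRingSequences()` plants one ligand pattern per sequence at uniformly
  drawn admissible spacings.  Flanks and spacers draw from an alphabet with
  *no* ligand-capable letters, which makes the planted pattern the unique
  zero-substitution candidate — by design, so recovery is exactly
  checkable.  Real sequences contain stray Cys/His and can yield several
  candidates; the best-candidate rule handles them, but recovery there is
  not 100 % by construction.
* `genEnsemble()` builds a self-avoiding random C-alpha walk (3.8 Å steps)
  and adds per-region isotropic Gaussian noise.  The default study
  condition for SCR recovery is four low-noise regions of 9/7/13/6
  residues at σ = 0.3 Å separated by σ = 4.0 Å spacers of 5–6 residues,
  n = 10 structures — region lengths mirroring the four conserved regions
  of the RING fold at superposition-quality noise versus loop-level
  disorder.  With per-coordinate noise σ the expected column RMSD is
  `σ·sqrt(3(n−1)/n)` (≈ 0.5 Å and ≈ 6.6 Å for the two levels), so the
  3.0 Å threshold separates them cleanly.  What this does not emulate:
  correlated backbone motion, gaps/indels at region boundaries, or real
  side chains — synthetic residues are C-alpha-only alanines, which is
  sufficient for the C-alpha geometry under test but says nothing about
  side-chain packing on real structures.
* `genComplex()` places each planned cross-chain pair as a pair of
  single-atom residues at *exactly* the planned distance (20 Å apart from
  the next pair) with decoy residues ≥ 8 Å from the other chain, so tier
  assignment is exact; it does not emulate a packed interface with
  many-to-many residue contacts.
* `genMsa()` plants class-conserved columns at a target consensus level by
  drawing from a low-entropy subset of the class (so the index threshold
  is passed as well) against uniform random background columns.
* `genHits()` plants mutual best hits (bit 200–500) over strictly
  lower-scoring decoys (30–150) that only ever point at planted subjects,
  so no decoy can close a spurious reciprocal loop.

Passing tests on these generators demonstrate algorithmic correctness
against planted truth under clean conditions; they do not demonstrate
classification accuracy, alignment quality or interface biology on real
data.

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy conformer, ties broken in
  favour of altloc `A`; waters are dropped; the first MODEL is read unless
  another is requested.  These policies produce one deterministic
  conformer for all distance work.
* 1-based inclusive coordinates everywhere: alignment columns, residue
  indices, domain intervals.
* All thresholds compare inclusively (`≤`) where the describing phrase is
  "within"; the SCR seed boundary case (window mean exactly 3.0) therefore
  qualifies.
* All-gap columns profile as no-consensus with index 0; a column with more
  than 50 % gaps is flagged low-support rather than suppressed.
* Empty inputs return empty, well-typed results (`detectScrs` on a short
  profile, `rbbh` on empty tables, generators with count 0); geometric
  impossibilities (collinear superposition input, infeasible planting
  requests) raise errors.

## Problem sizes

The test and acceptance workloads are sized for a single CPU: 100
ensembles of 10 structures for SCR recovery, 200 random systems for the
contact/neighbour oracles, 1 000 random profiles for the SCR oracle, the
full `6^8` enumeration for the rule table, 800 planted sequences for
classifier recovery, and 300×300 proteomes with 200 planted orthologs for
RBBH.  These sizes were chosen so each property is exercised well past the
point where a systematic defect would surface.

## Known limitations

* The conservation index is this package's definition, not a reimplementation
  of any specific program's 0–9 scale; only the calling thresholds are
  portable.
* The SCR detector is one-dimensional in the alignment; it does not refine
  the superposition iteratively against the detected regions.
* U-box assignment requires an external annotation hint; the package does
  not fold-recognise U-boxes from sequence.
* The three-zinc (C6H3C2D) scan is composition-based and flagged putative.
* Survey-scale published counts (type inventories, ortholog fractions of a
  full proteome) depend on era-specific database searches and curated
  alignments and are outside what the package recomputes; the pipeline
  reproduces such tables for whatever inputs it is given.
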