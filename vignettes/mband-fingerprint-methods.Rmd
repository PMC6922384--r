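---
title: "Methods: comparative structural fingerprinting of M-band Ig domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural fingerprinting of M-band Ig domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mbandIg` compares a family of identically folded immunoglobulin (Ig)
domains — the titin M-band domains M1–M10 are the motivating case — and
extracts the per-domain structural signatures that distinguish them: the
hotspot loops where the fold diverges, the conservation class of every
alignment column, the hydrogen-bond complement of the β-sheet core, the
exposure and disulfide potential of each cysteine, and the structural
context of disease-associated missense variants. This vignette explains the
models behind each stage, the tunable parameters, the numerical choices, and
what the synthetic test bed does and does not establish.

## Coordinate handling and dual numbering

Structures are read from PDB files (parsing is delegated to `bio3d`); ATOM
and HETATM records are kept apart, so waters and ligands never enter
residue-level analyses but remain available for metal-site detection. One
analysis chain per structure is selected — chain A whenever present,
matching the convention used for multi-copy crystal forms — and alternate
conformers are collapsed to the highest-occupancy copy, with ties broken
toward altloc "A" (the file's own preferred set). NMR ensembles contribute
model 1 only: ensembles carry no occupancy weighting, and the first model
is the conventional representative. Insertion codes are rejected inside
domains; none occur in the entries this package targets, and silently
renumbering around them would corrupt the dual numbering below.

Every domain carries two numbering schemes: a 1-based local index along the
chain and the position in the full-length titin sequence, connected by a
constant offset (global = local + offset). The offsets for M1, M3, M4, M5
and M10 (32489, 32715, 33294, 33482, 34249; `inst/extdata/mband_numbering.tsv`)
are fixed by the published variant table, in which every row prints both
coordinates. Writing a domain with `numbering = "local"` reproduces a
renumbered coordinate file.

Residues left over from cleaved expression tags can be flagged through the
registry (`tag_local`); they stay in the coordinate set but are excluded
from sequences, Cα extraction and alignments, because they are not titin
sequence.

## Superposition and structure-based alignment

Rigid-body superposition is the standard least-squares solution via SVD of
the weighted covariance matrix, with the determinant-corrected reflection
fix so the result is always a proper rotation. Point sets with fewer than
three points or with rank < 2 (collinear) are rejected: the optimal rotation
is not unique there.

Pairwise correspondence between two domains is built by iterated
superpose-then-match. The seed pairing is sequence order; each iteration
superposes the current core pairs, scores all inter-structure Cα pairs as

\[ s(i,j) = \frac{1}{1 + d(i,j)^2 / d_0^2}, \qquad d_0 = 3\,\text{Å}, \]

and re-matches by global dynamic programming with a flat gap penalty of 0.6
and free end gaps, iterating (at most 20 times) until the pair set is
stable. Ties in the traceback prefer the diagonal, then the vertical move,
so results are deterministic. Pairs farther than the 4.5 Å trim cutoff are
kept in the full correspondence but excluded from the superposition and
flagged non-core; d₀, the gap penalty and the trim cutoff are exposed as
arguments. These defaults make identical folds align end-to-end while
displaced loops drop out of the core — the behaviour the hotspot analysis
relies on. The published comparisons used a different matching engine
(PDBeFold); matched-pair sets differ slightly between correspondence
algorithms, which is why comparisons against printed RMSD/identity values
carry a ±0.3 Å / ±3-point algorithmic tolerance in the acceptance checks.

The RMSD matrix reports the RMSD over each full correspondence (with the
identity matrix filled from the same correspondences); deviation profiles
report per-reference-position Cα distances after core superposition, with
positions above 4 Å flagged as hotspots. The profile reference defaults to
the user's choice; for the M-band set the natural references are M10 or M7.
Same-domain comparisons (two crystal forms, bound/apo states) skip the
structural matching entirely and pair residues by identical numbering. For
the M4 pair the trigonal form (6h4l, higher resolution) is the default
representative; the tetragonal form is compared against it.

The master alignment is reference-anchored: columns are the reference
residues, other domains place residues by their pairwise correspondence to
the reference, non-core pairs are flagged uncertain (rendered lower case),
and unmatched runs become insertion columns. A tensor-style simultaneous
multiple superposition is deliberately out of scope — with one natural
reference the anchored construction is transparent and reproducible.

## Hydrogen bonds, strands, sheets

Backbone hydrogen bonds use the Kabsch–Sander electrostatic model,

\[ E = 0.084 \cdot 332 \cdot \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
  - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \text{kcal/mol}, \]

with a bond when E < −0.5 kcal/mol, candidates limited to N–O distances
below 5.2 Å and sequence separation ≥ 2, at most two acceptors per donor
(best energies), and energies clamped at −9.9 for near-clash geometries.
Amide hydrogens are always reconstructed geometrically (unit bisector of
C(i−1)→N and CA→N, N–H 1.0 Å); hydrogens present in a file are ignored so
that X-ray and NMR entries are treated identically. Proline never donates.
The −0.5 cutoff is the de-facto standard for sheet definition and is
exposed as an argument; conclusions about sheet conservation are phrased as
bounds, not exact counts, precisely because the bond count depends on this
convention.

β-bridges follow the standard antiparallel/parallel two-bond patterns;
strands are maximal runs of bridge-forming residues (≥ 3), sheets are
connected components of strands under bridge connectivity, and a 3₁₀ helix
is two or more consecutive i+3→i bonds. When nine strands in two sheets are
found they receive the canonical Ig labels A, A′, B, C, C′, D, E, F, G in
sequence order, and the sheets are named by their members (ABDE, A′CC′FG);
anything else is labelled best-effort with a warning. Loops are named by
their flanking strands, with the N-tip (BC, DE, FG) and C-tip (A′B, C′D,
EF) groups following the Ig convention. The "C-tip" hydrogen-bond category
used in conservation summaries counts bonds with either partner in a C-tip
loop; the boundary of that category is an interpretation (no formal
definition exists) and is flagged as such in the output.

Cross-structure hydrogen-bond conservation is column-wise: a bond is
structurally identical in two domains when donor and acceptor map to the
same master-alignment columns. Counts are classed n/n, (n−1)/n, … and
summarised per sheet with the C-tip category kept separate.

## Accessibility, cysteines, metals, pI

Solvent-accessible surface areas use the Shrake–Rupley construction with a
1.4 Å probe and 960 sphere points per atom. The point set is a deterministic
golden-angle spiral — no random numbers — so areas are exactly reproducible
and doubling the point count moves per-atom areas by less than 1% of the
sphere area. Radii: C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown elements fall
back to 1.70 Å with a warning. Hydrogens never contribute; hetero-atoms and
waters are excluded from occlusion by default, and accessibility is
computed on the isolated analysis chain (crystallographic symmetry mates
are never generated — analyses of dimeric interfaces require a model that
contains both chains).

Cysteine side-chain accessibility (atoms CB outward) is normalised by the
46.6 Å² cysteine side-chain maximum — taken as a constant, not recomputed —
and classified: another SG within 4.5 Å makes the pair *potential-SS-bridge*
(2.5 Å and below would be a formed bond); otherwise ≥ 5% relative
accessibility is *exposed* and the rest *core-oriented*. The 5% exposure
threshold operationalises "at least partially surface exposed" and is an
argument; raising it can only shrink the accessible count. Metal sites
collect protein N/O/S ligands within 2.8 Å of any mono-atomic metal
HETATM and call the geometry tetrahedral when exactly four ligands sit
within 20° of the 109.5° ideal on all six angles.

Isoelectric points solve Z(pH) = 0 with Henderson–Hasselbalch terms under
the Bjellqvist pKa set (N-terminus 7.5, C-terminus 3.55, D 4.05, E 4.45,
C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0). Bisection runs to a pH interval of
1e−7 rather than stopping at a small |Z|, because the net-charge curve can
be nearly flat around the pI and an |Z| stop alone leaves the root poorly
localised.

## Conservation categories and variants

Cross-species comparisons align single-domain sequences globally
(BLOSUM62, gap open 11, extend 1; the dynamic programming is delegated to
`Biostrings`). Species domain sequences are assigned to the human domain of
highest identity (first maximum on ties, logged), which handles lineages
with missing domains naturally. A pre-computed multiple alignment in FASTA
can be supplied instead wherever a panel is accepted. Identity is counted
over aligned (non-gap) column pairs; percent identity classes use the
> 85 / > 70 / > 50% colour thresholds.

Columns classify as *invariant* (identical in every domain, and in every
species of every domain when a panel is present), *conserved* (one
physicochemical class: ILVM, FYW, KR, DE, ST, NQ — configurable, and
enlarging the classes can only grow this category), *domain-specific
signature* (at least two distinct residues across domains, each domain
invariant across its species), else *variable*. Columns missing in any
domain are variable by definition. The package does not hard-code which
columns are invariant in titin: that is an output, not an input.

Variant annotation maps a full-titin position through the offset registry
(positions in linkers return "inter-domain", not an error; a wild-type
mismatch against the structure sequence is an error). Structural context is
rule-based: relative all-atom residue accessibility (normalised by
theoretical per-residue maxima) below 10% is *hydrophobic core*; otherwise
loop/3₁₀ states are *Loop*, strand states *β-strand, exposed*, and the rest
*Surface*. Glycine needs no special case because the all-atom residue
accessibility covers backbone-only residues.

Predicted impact is a transparent approximation of expert judgement, with
all thresholds exposed: at a core site, a provided stability change at or
below −1.3 kcal/mol predicts *fold destabilization* unless the substitution
is conservative (classes ILVM, FYW, KR, DE, STC — cysteine groups with the
small polar residues because C→S-type swaps preserve the side-chain
envelope in a packed core); with no stability column at all, mutation to
P/G or from W/C at a core site triggers the same call; at a loop site,
glycine wild type or proline mutant predicts *altered loop conformation*; a
core site whose stability field is recorded as NA returns *unassessed*,
kept distinct from *none* because "no annotation" and "no predicted effect"
are different statements. This rule set reproduces the published annotation
table on all structure-resolved rows except one NMR-model row (M5 V→M),
which expert judgement labels destabilizing at a stability change well
above the threshold; NMR rows are excluded from hard assertions throughout.

## The synthetic test bed

`generate_fold()` builds an idealized β-sandwich: strands are grown from
ideal backbone internal coordinates at canonical antiparallel-β dihedrals
(φ = −139°, ψ = 135°), canonicalized, and laid on two flat sheets with the
Ig architecture (spatial orders DEBA and A′GFCC′, giving sheets ABDE and
A′CC′FG). Antiparallel neighbours are related by a two-fold rotation about
the sheet normal; the lateral spacing (4.65 Å) and axial registers were
fixed by construction so that the Kabsch–Sander criterion recovers the full
narrow-pair ladder, and each strand's register is refined against its
already-placed neighbour over a small deterministic candidate set so that
arbitrary strand lengths ladder up. Loops are circular arcs with
alternating carbonyl tilt (so arcs never mimic a 3₁₀ ladder); the EF loop
can carry a genuine 3₁₀ segment built at (−49°, −26°). Residue identities
are sampled per seed; planted cysteines get CB and SG atoms oriented into
or out of the sandwich, inward-facing residues get CB/CG/CD pseudo side
chains so the core is packed, and an optional Zn site with four 2.0 Å
tetrahedral O ligands can be planted near a named loop.

The sheet separation defaults to 8.5 Å: with pseudo side chains truncated
at CD, a wider sandwich leaves the interior solvent-accessible and an
"inward" cysteine would not actually be buried — the ground truth has to be
geometrically true, not just declared. Two inward cysteines planted face to
face across the sandwich fall within disulfide range, and the correct
classification for them is *potential-SS-bridge*; the test bed treats
either buried class as correct for inward plants.

Everything is deterministic per seed; the seed controls residue sampling
and optional coordinate noise, not the architecture. `perturb_fold()`
translates named loops by a stated distance along the outward normal and/or
adds isotropic Gaussian noise, recording what was applied.
`generate_family()` and `generate_species_panel()` plant invariant and
signature columns in sequence families; planted columns are never mutated.

What the synthetic bed emulates: the fold topology, complete hydrogen-bond
ladders, buried/exposed side-chain geometry, localized loop displacements,
and conservation structure. What it does not emulate: real side chains
beyond CB/CG/CD (so absolute accessibility values are not comparable to
real proteins — only classifications and contrasts are meaningful), sheet
twist and pleat irregularity, crystallographic disorder, and sequence-
structure correlation. Passing the synthetic suite therefore demonstrates
algorithmic correctness — planted truths are recovered — not agreement with
any particular experimental structure; the acceptance checks that compare
against published values run only when the corresponding coordinate files
are supplied under `inst/extdata/structures/`.

## Problem sizes and numerical conventions

The test suite works on 100-residue folds (~520 atoms), a six-domain
comparative set, 10⁴-replicate noise simulations, and exhaustive alignment
enumeration up to length 7 — sizes chosen so the whole suite runs in about
a minute while every oracle remains exact or statistically tight.
Deterministic tie-breaks are used everywhere (dynamic-programming
traceback, altloc collapse, identity-assignment ties, register refinement),
so a configuration reruns byte-identically. Degenerate inputs fail loudly
rather than silently: empty files, missing chains, collinear point sets,
empty sequences, non-standard residue letters, out-of-range residue
numbers, and loops too short to span their gap are all errors with
descriptive messages.
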