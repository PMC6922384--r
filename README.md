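# mbandIg

Structural fingerprinting of titin M-band immunoglobulin domains in R.

The C-terminal M-band segment of the muscle protein titin carries ten
immunoglobulin (Ig) domains, M1–M10, that share one β-sandwich fold yet carry
distinct molecular functions. `mbandIg` implements the comparative analysis
that teases those individual fingerprints apart from atomic coordinates: it
is aimed at structural biologists and muscle-disease researchers who want to
compare a family of identically folded domains, locate their
structural-diversity hotspots, characterise their redox-active cysteines, and
map missense variants (titinopathies, cardiomyopathies) onto structure.

## What it computes

* **Rigid-body superposition (Kabsch).** For matched Cα sets *x<sub>i</sub>*,
  *y<sub>i</sub>* the proper rotation *R* and translation *t* minimising
  RMSD = √(1/n Σᵢ ‖R xᵢ + t − yᵢ‖²), via SVD of the covariance matrix with
  reflection correction.
* **Structure-based pairwise alignment.** Iterated superpose-then-match with
  dynamic programming over the score *s(i,j) = 1 / (1 + d²(i,j)/d₀²)*
  (d₀ = 3 Å, flat gap penalty 0.6, core trim 4.5 Å), giving pairwise RMSD and
  structure-based sequence-identity matrices, per-residue spatial deviation
  profiles with hotspot calls (> 4 Å), and a reference-anchored master
  alignment of all domains.
* **Backbone hydrogen bonds and sheet topology.** Kabsch–Sander electrostatic
  energy E = 0.084·332·(1/r<sub>ON</sub> + 1/r<sub>CH</sub> − 1/r<sub>OH</sub>
  − 1/r<sub>CN</sub>) kcal/mol, bond when E < −0.5; β-bridges, the nine
  Ig strands A, A′, B, C, C′, D, E, F, G in two sheets (ABDE and A′CC′FG),
  the EF-loop 3₁₀ helix, and column-wise cross-structure hydrogen-bond
  conservation counts.
* **Solvent accessibility and redox classification.** Shrake–Rupley areas on
  a deterministic spiral lattice; cysteine side-chain accessibility relative
  to the 46.6 Å² maximum, classes *core-oriented* / *potential-SS-bridge*
  (SG–SG ≤ 4.5 Å) / *exposed*; intra/intermolecular disulfide scanning;
  tetrahedral metal-site detection; Bjellqvist isoelectric points.
* **Conservation categories.** Needleman–Wunsch (BLOSUM62, affine gaps 11/1)
  cross-species identities, and per-column classes: invariant, conserved
  (one physicochemical class), domain-specific signature (distinct between
  domains, invariant within each domain across species), variable.
* **Variant annotation.** Full-titin positions mapped through the dual
  numbering (UniProt position = local index + domain offset), structural
  context (hydrophobic core / loop / β-strand exposed / surface) and a
  transparent predicted-impact rule set.

A deterministic generator of idealized β-sandwich folds and sequence
families with planted ground truth (`generate_fold()`, `perturb_fold()`,
`generate_family()`) makes every stage testable without downloading any
structures.

## Worked example

```r
library(mbandIg)

spec <- synthetic_fold_spec(
  cysteine_plan = list(list(strand = "B", offset = 3, orientation = "out"),
                       list(strand = "F", offset = 4, orientation = "in")))
dom <- generate_fold(spec, domain_label = "demo")
dom
#> domain_structure demo ( synthetic ) chain A : 100 residues, 523 atoms

assign_topology(dom)$strands
#>    label from to sheet sheet_name
#> 1      A    3  5     1       ABDE
#> 2     A'   14 16     2    A'CC'FG
#> 4      B   26 31     1       ABDE
#> 5      C   37 43     2    A'CC'FG
#> 6     C'   47 51     2    A'CC'FG
#> 7      D   61 63     1       ABDE
#> 8      E   70 74     1       ABDE
#> 9      F   83 89     2    A'CC'FG
#> 10     G   94 99     2    A'CC'FG
```

The nine strands and both sheets of the Ig fold are recovered from the
hydrogen-bond ladders alone. The planted outward-facing cysteine is called
exposed (38% of the 46.6 Å² side-chain maximum) and the inward-facing one
core-oriented (2%):

```r
classify_cysteines(dom)$report[, c("local_index", "relative_accessibility", "class")]
#>   local_index relative_accessibility         class
#> 1          28              37.951080       exposed
#> 2          86               2.013496 core-oriented
```

Displacing the BC loop by 6 Å and profiling against the unperturbed fold
recovers the perturbation and flags exactly the displaced residues as a
diversity hotspot:

```r
bent <- perturb_fold(dom, c(BC = 6), seed = 2)
prof <- deviation_profile(dom, list(bent))[[1]]
round(max(prof$dist, na.rm = TRUE), 2)
#> [1] 6
prof$position[prof$hotspot]
#> [1] 33 34 35 36
```

`run_fingerprint()` chains all stages from a config (domain registry,
optional species panel and variant TSV) into TSV/JSON reports;
`inst/scripts/fingerprint.R` wraps it for shell use. The registry template
`inst/extdata/mband_registry_template.tsv` carries the M-band numbering
offsets, and `inst/extdata/variants_table4.tsv` the published
disease-variant table used for annotation.

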