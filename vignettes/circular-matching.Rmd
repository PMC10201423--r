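---
title: "Stack-anchored circular matching of RNA 3D structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stack-anchored circular matching of RNA 3D structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circstar)
```

## The problem

Two RNA molecules can fold into essentially the same three-dimensional
architecture even when the backbone visits that architecture in a different
sequence order: moving one RNA's 5' end to another point on its backbone
circle — a circular permutation — can turn one chain into the other. Ordinary
structure aligners require the aligned positions to be collinear in sequence
in both molecules, so they miss such *circular matches* entirely. `circstar`
detects them: given two single-chain RNA 3D structures it reports local
alignments whose nucleotide correspondence is order-consistent only after
rotating the sequence of one input, together with an alignment score, the
superposition RMSD and the rotation seam.

The search is anchored on *stacks*: runs of consecutive nested canonical base
pairs `(i+t, j−t)`, the double-helical building blocks of RNA architecture.
Stacks are rigid and well conserved, which makes them reliable anchors, and a
pair of stacks can be matched in two orientations:

* **direct** — 5' strand onto 5' strand, base pair `t` onto base pair `t`;
* **rotated** — the strands exchange roles (5' onto 3' and vice versa), base
  pair `t` onto pair `L−1−t`. Within each strand the 5'→3' direction is
  preserved; only the strand roles flip. This is the orientation a circular
  permutation induces on a helix whose two strands end up on opposite sides
  of the new chain break.

A *conserved stack pair* is any equal-length window pair, in either
orientation, whose one-point-per-nucleotide superposition RMSD is below a
cutoff (4 Å by default). Base identity is deliberately ignored throughout:
the method aligns shapes, not sequences.

## Pipeline

1. **Annotation.** Base pairs come from a DSSR-style JSON file when supplied;
   otherwise a built-in geometric detector reports canonical pairs
   (complementary bases, C1'–C1' distance 8–12 Å, at least two
   Watson–Crick-edge N/O contacts within 3.5 Å, one partner per nucleotide,
   conflicts resolved greedily by hydrogen-bond distance sum). The canonical
   pairs are split into a maximum mutually-nested subset (dynamic programming
   over pair endpoints) and a crossing remainder; loops (hairpin, internal,
   multiloop) are the faces of the nested skeleton. Crossing pairs re-enter
   only as candidate stacks during extension, which is how pseudoknotted
   anchors are supported.
2. **Conserved stack pairs.** All maximal stacks (length ≥ 2 pairs) are
   compared across the two structures in both orientations. Besides
   full-length windows of each maximal stack pair, shorter windows down to
   the length floor are enumerated when they contain a loop-closing base pair
   in *both* structures; windows whose correspondence is contained in a
   larger retained window are pruned. This closing-pair restriction is what
   keeps the enumeration tractable — ideal helices are translationally
   self-similar, so unrestricted sub-window matching grows quadratically in
   helix length for every stack pair. `exhaustive = TRUE` lifts the
   restriction for small inputs.
3. **Seed loops.** For every pair of internal loops or multiloops, one per
   structure, the stack pairs closing both loops are collected and every
   maximal mutually-compatible subset becomes a matched loop pair. Only
   pairs closed by at least one *rotated* stack match seed the search;
   hairpins never seed (a single loop region admits no circular match),
   though their material is absorbed later. A single rotated closing match
   suffices: real matches are routinely found with only part of the closing
   stacks conserved, and the extension and RMSD filters prune spurious
   seeds.
4. **Extension.** The member stacks' strands cut each backbone circle (5'
   and 3' ends adjacent) into circularly ordered intervals; corresponding
   intervals share a label, and the labeling exists precisely when the two
   cyclic strand orders agree under the correspondence. A candidate stack
   pair is compatible when its strands lie in same-labeled intervals in both
   structures — crossed, pseudoknot-like placements included. Candidates
   must also sit within 15 nucleotides of the current set's strands in both
   sequences, and the joint superposition of the grown set must stay under
   the RMSD cutoff. All maximal sets are enumerated by a Bron–Kerbosch-style
   recursion with an exclusion set; the seed's closing matches are pinned
   and never removed. Pivoting is not used: candidate eligibility depends on
   the current set (adjacency and incremental RMSD), which invalidates the
   static-graph argument behind pivot pruning, and the restricted candidate
   pools keep plain recursion cheap. Candidate pools refresh after every
   addition, so a candidate may become reachable through an intermediate
   one; this matches an exhaustive reachability-filtered enumeration on
   small instances, which the test suite verifies against brute force.
5. **Assembly.** Traversing the circular interval labeling once pairs up the
   loop intervals between consecutive stack strands; across the seam, an
   interval of A maps to an interval of B spanning B's 3'/5' junction and
   B's 3'-end material is aligned before its 5'-end material. Each interval
   pair is aligned by global dynamic programming under the set's
   superposition with match score `max(0, 1 − d/4 Å)` and gap penalty 0.5
   per position; matched pairs further apart than 4 Å are discarded after
   traceback. Stack correspondences are never trimmed. The final
   superposition over all aligned C1' pairs must stay under the RMSD cutoff,
   the score is `n_aligned − 0.5 × (deletions + insertions)`, and candidates
   are ranked by score, then RMSD, with near-duplicates (≥ 90% shared pairs)
   collapsed. The reported `rotation_offset` is the position in the first
   structure at which the second structure's 5' end aligns, so aligning a
   parent against its circular permutation at pivot `p` reports `p`; a
   purely direct alignment reports 0.

## Quality metrics

Fragmented local alignments are scored by Aligned Connected Structures: on
the graph of aligned nucleotide pairs, two pairs are linked when they are
within 5 sequence positions of each other or base-paired to each other in
either structure, and the connected components are the ACSs. PCSI is the
fraction of aligned nucleotides within 4 Å (after the final superposition)
in the largest ACS over the shorter chain length; PCSS is the fraction of
aligned, conserved base pairs with both partners within 4 Å over the smaller
canonical pair count. A base pair counts only when the pairing exists
between corresponding partners in both structures; PCSS is undefined
(reported `NA`) when a structure has no canonical pairs.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `rmsd_cutoff` | 4 Å | ceiling for stack pairs, compatible sets and final alignments |
| `ext_dist` | 15 nt | sequence-adjacency radius during extension |
| `min_stack_len` | 2 bp | shortest stack considered an anchor |
| `acs_gap` | 5 nt | sequence-distance edge threshold for ACS connectivity |
| `metric_dist` | 4 Å | "within" distance for PCSI/PCSS and loop-match acceptance |
| `gap_weight` | 0.5 | per-nucleotide gap penalty in the alignment score |

All superpositions use one C1' atom per nucleotide (`c1_prime`), a choice
that is robust to modified bases and keeps every RMSD on a common scale;
`backbone_glyco` and `all_heavy` schemes are available for sensitivity
analysis. The score formula and the loop-alignment scheme are this package's
own constructions — structure-only by design — and the gap weight is echoed
in every output header so scores remain interpretable.

## The synthetic generator

Validation runs entirely on generated structures with recorded ground truth.
`build_ideal_helix()` places C1' and Watson–Crick-edge atoms on an idealised
A-form-like helix (twist 32.7° per step, rise 2.81 Å — standard A-form
constants adopted as generator conventions) such that the geometric detector
recovers every intended pair; `build_junction_structure()` arranges an outer
stem and `n−1` hairpin stems around a junction so the nested skeleton
decomposes into exactly one multiloop (an internal loop for two stems), with
non-bonded C1' contacts kept above 2.5 Å by bounded retries with a widened
junction. `circular_permute()` rotates the sequence order while leaving every
coordinate in place, and `jitter_structure()` adds reproducible Gaussian
coordinate noise.

The recorded pivot options sit at the boundary between a stem's 5' strand
and its terminal hairpin loop. Cutting there preserves every loop in the
permuted copy (the cut stem simply becomes the outermost stack) while
rotating the stem order, which is precisely the situation a circular aligner
must recognise: the permuted copy's multiloop is closed by the same physical
stacks, two of which now match their parent counterparts in rotated
orientation, and the parent's terminal hairpin maps onto the permuted copy's
dangling ends across the seam. A pivot inside a junction segment would
instead open the multiloop into the exterior face, leaving nothing for an
internal/multiloop seed to match — a scientifically interesting boundary
case, but not a recoverable one by construction.

What the generator does *not* emulate: real backbone torsions, non-canonical
pairing, base-stacking geometry beyond what the pair detector needs,
crystallographic disorder, and modified residues. Passing the recovery suite
therefore demonstrates the correctness of the combinatorial machinery and
the geometric filters, not performance on experimental coordinates; on real
structures the annotation quality (DSSR input is recommended over the
built-in detector) and the 4 Å cutoff dominate behaviour.

## Numerical and design choices

* **Superposition** is Kabsch via SVD with the determinant correction
  (proper rotations only); with fewer than three points or degenerate
  geometry the RMSD is still valid but the rotation is flagged non-unique.
  The suite cross-checks it against an independent quaternion-eigenvalue
  implementation to 10⁻⁶ Å.
* **Nested-subset extraction** maximises cardinality; when several optima
  exist the traceback deterministically prefers taking a pair at the
  leftmost position, so repeated runs agree. Only cardinality is contractual.
* **Determinism.** Candidates are processed in (A start, B start,
  orientation) order; reported sets and alignments are sorted with explicit
  tie-breaks; reruns are byte-identical.
* **Degenerate inputs.** Empty pair lists, loops with empty segments
  (including the zero-length hairpin a permutation can create at the old
  seam), empty loop intervals during assembly and empty alignments are all
  legal and covered by tests.
* **Adjacency** is measured as the minimum sequence gap between strand
  intervals, linearly in each chain, and must hold in both structures.
  Measuring it jointly rather than per-structure is the stricter reading and
  keeps extension local in both molecules.
* **Incremental RMSD pruning** during the search is a heuristic: the joint
  RMSD is not monotone in set growth, so a set whose intermediate stages
  exceed the cutoff is never visited even if its full RMSD would pass. Final
  sets are re-verified. On the noise-free and 0.5 Å-jitter study conditions
  the cutoff never binds mid-search, which is why the brute-force
  equivalence tests hold exactly.
* **Problem sizes.** The validation suite uses junctions of 3–5 stems of
  4–8 bp (roughly 50–120 nt), 20 random fixtures per condition, jitter at
  σ = 0.5 Å, and brute-force oracles on pools of ≤ 10 stack pairs — sizes at
  which exhaustive enumeration is exact and the whole suite runs in minutes.

## Known limitations

Single chain, single model per run; canonical pairs only form stacks (the
full Leontis–Westhof family catalogue is read but not used for anchoring);
no unequal-length stack windows with internal gaps; the score is
size-dependent, so cross-pair comparisons need care; and loop alignment is
purely distance-based — sequence similarity is never consulted. Matching is
quadratic in the number of enumerated windows, so for large RNAs with very
long helices the closing-pair restriction (the default) is essential.
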