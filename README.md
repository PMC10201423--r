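# circstar

Circular matching of RNA 3D structures by conserved stack anchors.

## The problem

Two non-coding RNAs can share essentially the same three-dimensional
architecture while visiting it in a different sequence order: moving one
molecule's 5′ end to another point on the backbone circle (a circular
permutation) turns one chain into the other. Conventional RNA 3D aligners
require aligned positions to be sequence-collinear in both molecules and
therefore cannot see these *circular matches*. `circstar` finds them, for
anyone comparing RNA 3D structures — motif hunters, riboswitch/ribozyme
comparativists, curators of structure databases.

## The method

The unit of comparison is the **stack**: a run of consecutive nested
canonical base pairs (i+t, j−t), the rigid double-helical element of RNA
architecture. Two stacks (one per input) form a **conserved stack pair**
when an equal-length window superposes with RMSD ≤ 4 Å on C1′ atoms, in
either the *direct* orientation (5′ strand ↔ 5′ strand, pair t ↔ pair t) or
the *rotated* orientation (strands exchange roles, pair t ↔ pair L−1−t) —
the orientation a circular permutation induces. The pipeline then:

1. annotates base pairs (DSSR-style JSON input, or a built-in geometric
   detector), extracts the maximum nested skeleton and its loops;
2. enumerates conserved stack pairs in both orientations;
3. keeps matched internal-loop/multiloop pairs closed by conserved stacks
   and selects those with ≥ 1 rotated closing match as **seed loops**;
4. grows each seed into maximal compatible stack-pair sets
   (Bron–Kerbosch-style search over a circular interval-compatibility
   relation, candidates within 15 nt of the current set, joint RMSD ≤ 4 Å;
   pseudoknotted placements allowed, seed anchors never removed);
5. assembles each set along the circular consensus — loop intervals aligned
   by structure-only dynamic programming, possibly across one molecule's
   3′/5′ seam — filters at RMSD ≤ 4 Å, scores with
   `score = n_aligned − 0.5 × (n_deleted + n_inserted)` and ranks by score,
   then RMSD.

Alignment quality of (possibly fragmented) local alignments is assessed with
**ACS** (aligned connected structures: components under 5-nt sequence
proximity or base-pairing), **PCSI** (aligned nucleotides within 4 Å in the
largest ACS / shorter sequence length) and **PCSS** (conserved aligned base
pairs within 4 Å / smaller pair count).

## Worked example

Everything below is generated — no downloads. Build a three-way junction,
circularly permute it at a stem boundary, and align parent against permuted
copy:

```r
library(circstar)

spec <- junction_spec(stem_lengths = c(6, 5, 7), loop_lengths = c(3, 2, 4),
                      hairpin_lengths = c(4, 5), seed = 7)
jb   <- build_junction_structure(spec)
perm <- circular_permute(jb$structure, jb$truth$pivot_options[1],
                         jb$truth$intended_pairs)

res <- circular_align(jb$structure, perm$structure,
                      pairs_a = jb$truth$intended_pairs,
                      pairs_b = perm$truth$intended_pairs)
print(res)
#> circstar: junction3way_seed7 (54 nt) vs junction3way_seed7_perm14 (54 nt)
#>   70 conserved stack pair(s), 26 matched loop(s), 12 rotated seed(s)
#>   #1 score 54.0 rmsd 0.000 A aligned 54 del 0 ins 0 offset 14
#>   #2 score -22.0 rmsd 0.941 A aligned 16 del 38 ins 38 offset 37
```

The top alignment covers all 54 nucleotides at RMSD 0 with rotation offset
14 — exactly the pivot used to manufacture the permutation: the method
recovered the planted circular match. The runner-up is a small spurious
rotated candidate with a negative score; the command-line tool's default
`--min-score 0` filter drops such candidates. `summary(res)` adds PCSI/PCSS
for each alignment, `plot(res)` draws the correspondence dot plot with the
rotation seam, and `as.data.frame(res$alignments[[1]])` exports the
nucleotide pairing.

From a shell, the same run (after `simulate` has written the fixture files):

```sh
exec/circstar simulate --stems 6,5,7 --loops 3,2,4 --hairpins 4,5 --seed 7 --out fx
exec/circstar align fx/parent.cif fx/permuted.cif \
    --annotation1 fx/parent_pairs.json --annotation2 fx/permuted_pairs.json \
    --out fx/out
```

which writes a correspondence table (TSV), a gapped sequence view with the
seam marked, a superposed PDB and a JSON summary.

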