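# csabmine

Discovery and classification of bacterial cis-defensins from protein
sequence sets.

Cis-defensins are small secreted peptides built on the cysteine-stabilised
α-helix/β-sheet (CSαβ) fold: an α-helix tied by two parallel disulfide
bonds to an antiparallel β-sheet, with a third bond closing the frame.
Recently recognised in bacteria, they sort into five structural archetypes
(classes I–V) distinguished by the mature peptide's N-terminal tail length
and by the presence and placement of a fourth disulfide bond. `csabmine`
is for sequence-analysis practitioners who want to mine candidate
CSαβ-defensins from protein FASTA, classify them, remove redundancy, and
verify structural claims — entirely offline and reproducibly.

## What it computes

**Filter cascade** (each stage emits an auditable kept/removed report):

1. *size*: keep precursors of 30–130 residues (inclusive);
2. *motif*: keep sequences matching the six-cysteine spacing pattern
   `CX(2,18)CX(3)CX(2,12)CX(4,17)CXC`, where `X` is any residue
   *including* cysteine (required so 8-cysteine frameworks can match);
   every satisfying cysteine assignment is enumerated;
3. *secretion*: keep sequences with a predicted signal peptide and no
   transmembrane region (Phobius-style file, or a built-in heuristic).

**Framework and classes.** On the mature peptide (after signal-peptide
cleavage) the six framework cysteines define five gaps g1..g5 (g2 = 3,
g5 = 1 always), an N-terminal tail (residues before C1) and loop lengths
(n = g1, m = g3, c = g4). Classes are assigned topology-first:

| class | topology | N-terminal tail |
|---|---|---|
| I | 6 Cys | 1–4 |
| II | 6 Cys | 8–13 |
| III | 8 Cys, extra pair internal (fourth S–S between the extras) | 0–15 |
| IV | 6 Cys | 21–53 |
| V | 8 Cys, extra pair flanking (fourth S–S 1–8, plant-like) | any |

plus per-peptide annotations: γ-core (`GXC` ending at framework C5), KCXN
motif, conserved glycine, and net charge = (#K + #R) − (#D + #E).

**Clustering.** CD-HIT-style greedy redundancy removal at 70% identity
over an exact Needleman–Wunsch aligner (match +1, mismatch 0, gap −1;
identity = matches / shorter-sequence length by default).

**Structural toolkit.** Kabsch superposition; NMR-ensemble backbone RMSD
(mean ± SD to the iteratively refined mean structure); NOE
distance-restraint tallies by residue separation (intraresidue /
sequential / medium |i−j| < 5 / long |i−j| ≥ 5); exact-match in-silico
PCR.

**Synthetic data.** A seeded generator emits labelled precursors per
class and decoys that each violate exactly one filter rule, so the whole
pipeline is testable without downloads. See the methods vignette
(`vignettes/defensin-mining-methods.Rmd`) for every design decision.

## Worked example

```r
library(csabmine)

# one synthetic class II precursor, fully labelled
d <- generate_defensin("II", seed = 7)
d$precursor
#> [1] "MKKIIVVIFVFIVAHADFHNKVRFEQLCWWKHMQIPHFTVCNQPCWAVAPNTCKQSLDPKMRKTGGCDCHELTKT"

fw <- build_framework(d$mature)
fw
#> <cys_framework> mature: tails (11, 6), gaps (12,3,7,13,1), topology SIX_CYS
assign_class(fw)
#> <class_assignment> mature -> II [SIX_CYS,TAIL_II] charge +3
```

The framework line reads: 11 residues of N-terminal tail before the first
framework cysteine and 6 after the last, inter-cysteine gaps
(g1..g5) = (12,3,7,13,1), no extra cysteines. An 11-residue tail on a
six-cysteine framework fires the class II rule (tail 8–13), and the
mature peptide has net charge +3 (K/R minus D/E).

Running the full pipeline on a mixture of 15 positives (3 per class) and
2 spacing-broken decoys:

```r
pos <- do.call(rbind, lapply(c("I", "II", "III", "IV", "V"), function(cl)
  generate_defensin_set(cl, 3, seed = 11)$records))
dec <- generate_decoys("BAD_SPACING", 2, seed = 11)$records
res <- run_pipeline(rbind(pos, dec))

table(res$classification$class)
#>   I  II III  IV   V
#>   3   3   3   3   3
res$reports$motif
#> <filter_report> stage=motif kept=15 removed=2
#> NO_MOTIF
#>        2
```

All 15 positives are recovered in their generated class; both decoys are
removed at the motif stage with reason `NO_MOTIF`. A shell entry point
wrapping the same functions ships in `inst/scripts/csabmine`
(subcommands `mine`, `classify`, `cluster`, `simulate`, `pcr`, `rmsd`).

## Output columns

`write_table()` and the pipeline's `classification.tsv` use the fixed
column order
`id, class, mature_length, net_charge, gamma_core, kcxn, conserved_gly, cluster`
(classification tables add `rationale`, `n_tail_len`, `topology`).
Cluster tables are `cluster, representative, member, identity`; stage
reports are `id, status, reason`.

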