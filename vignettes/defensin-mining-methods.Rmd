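---
title: "Mining and classifying bacterial cis-defensins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and classifying bacterial cis-defensins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csabmine)
```

## The problem

Cis-defensins are small disulfide-stabilised peptides built on the
cysteine-stabilised α-helix/β-sheet (CSαβ) fold: an α-helix tethered by two
parallel disulfide bonds to an antiparallel β-sheet, with a third bond
closing the frame. Long thought to be restricted to plants, fungi and
invertebrates, members of this superfamily have recently been recognised in
bacteria, where they fall into five structural archetypes distinguished by
the length of the N-terminal tail of the mature peptide and by the presence
and placement of a fourth disulfide bond. `csabmine` implements the full
desk-scale discovery pipeline for such peptides — candidate filtering from
protein FASTA, cysteine-framework feature extraction, five-class
assignment, redundancy clustering — together with a small structural
toolkit (ensemble RMSD, NOE restraint accounting, in-silico PCR) and a
seeded synthetic-data generator that makes every stage testable without any
external database or web service.

## The filter cascade

Candidates pass three gates in a fixed order; each gate emits an auditable
report of kept and removed ids with machine-readable reasons, and each
stage's kept set is a subset of the previous stage's.

1. **Size band.** Precursors of 30–130 residues are kept, both bounds
   inclusive. The band is wide enough for a signal peptide, a possible
   pro-region and the mature domain.
2. **Cysteine-spacing motif.** The mining pattern is
   `CX(2,18)CX(3)CX(2,12)CX(4,17)CXC`: six framework cysteines whose five
   inter-cysteine gaps are bounded as written (gap 2 is exactly 3 residues,
   gap 5 exactly 1). Two readings of `X` are possible; `csabmine` lets `X`
   match *any* residue including cysteine. This matters: the 8-cysteine
   archetypes carry extra cysteines inside gap segments, and a reading that
   excluded cysteine from `X` could never match them. `motif_scan()`
   enumerates **every** ordered 6-subset of the sequence's cysteines
   satisfying the bounds (depth-first with pruning) rather than returning a
   first match, so downstream code can disambiguate among assignments.
   The scan is applied to the full precursor during filtering; all class
   features are later measured on the mature region.
3. **Secretion gate.** A candidate must carry a predicted signal peptide
   and no transmembrane region. Annotations normally come from an external
   predictor's tabular output (`read_phobius_short()`); when none is
   supplied, a deliberately simple built-in heuristic
   (`heuristic_signal_predict()`) is used so the pipeline runs
   self-contained. The heuristic calls a signal peptide when a length-7
   window within the first 35 residues has mean Kyte–Doolittle hydropathy
   ≥ 1.5 and at least one Lys/Arg occurs in the 5 residues before the
   window (the classical positively charged n-region); the cleavage site
   is the `-1` position of the first `[AGSCT]-X-[AGS]` match after the
   window (the Ala-X-Ala convention), falling back to window end + 3. A
   transmembrane segment is called when another such hydrophobic window
   starts after position 40. A "window of length ≥ 7" is operationalised
   as "some length-7 window qualifies"; longer hydrophobic stretches
   necessarily contain qualifying length-7 windows. The heuristic is an
   approximation and is bypassed whenever a predictor file is given; its
   thresholds are exposed as parameters.

## Framework features and disulfide topology

For each mature peptide `build_framework()` fixes one canonical cysteine
assignment and derives: the N-terminal tail length (residues before
framework C1 — the primary class discriminator), the five gap lengths, the
C-terminal tail, extra cysteines, and a topology label. The loop
nomenclature used for class grouping maps operationally onto the gaps:
n-loop = gap 1, m-loop = gap 3, c-loop = gap 4. This mapping is a
documented convention of the package (the loop spans are not defined
residue-exactly anywhere authoritative).

When several assignments satisfy the bounds the tie-break is: (a) prefer an
assignment whose extra cysteines flank the framework (first and last
cysteine of the sequence — the plant-like pattern); else (b) smallest
framework span; else (c) leftmost. The preference order is deterministic
and chosen so that flanking-extra sequences are never misread as having
internal extras.

Topology follows from the extras: none → `SIX_CYS`; two extras flanking →
`EIGHT_CYS_FLANKING`, adding a fourth bond between cysteines 1 and 8 in
full numbering; two extras with one before the framework and one strictly
between framework C4 and C6 → `EIGHT_CYS_INTERNAL`, adding a bond between
the two extras; anything else → `OTHER`, flagged unresolved. The canonical
cis-defensin connectivity 1–4, 2–5, 3–6 over the framework cysteines is
reported for every topology. Reporting the internal extra bond by the
extras' observed positions deliberately sidesteps an ambiguity in the
literature about whether the internal archetype's fourth bond is "1–5" or
"1–6": both descriptions refer to the same observed pair once numbering is
fixed by the sequence at hand.

## The five-class rules

`assign_class()` evaluates topology first, then the mature N-terminal tail:

| class | topology | tail (residues) |
|---|---|---|
| I | `SIX_CYS` | 1–4 |
| II | `SIX_CYS` | 8–13 |
| III | `EIGHT_CYS_INTERNAL` | 0–15 |
| IV | `SIX_CYS` | 21–53 |
| V | `EIGHT_CYS_FLANKING` | any |

Anything else is `UNCLASSIFIED` with a reason code (`TAIL_GAP`,
`BAD_TOPOLOGY`). Three boundary decisions were genuinely open and are
resolved as follows, all config-exposed:

* **Class II range (8,13).** Both "9–13" and "8–13" circulate as the class
  II tail description; the union is used.
* **Class IV range (21,53).** Same situation ("21–53" vs "23–53"); union.
* **Tail 0.** A six-cysteine framework with no tail at all is
  `UNCLASSIFIED` by default, since class I is described as having one to
  four tail residues; `classifier_config(tail0_as_I = TRUE)` folds it into
  class I for users who read the class as "shortest tails".
* **Class V without the extra pair.** Rare class V members lack the
  flanking cysteine pair (replaced by tyrosines) and were historically
  resolved by structure alignment, which is out of scope here; such
  sequences are *not* auto-assigned, but a per-id override table
  (`overrides = data.frame(id, class, note)`) records the expert call with
  an `OVERRIDE` rationale code. The third β-strand sometimes cited for
  class V is likewise not predicted from sequence; the flanking topology
  serves as its proxy.

Sequence annotations attached to every assignment: the γ-core (`GXC`
ending at framework C5, i.e. G at position C5−2), the KCXN motif (reported
at every overlapping position; found in some class I peptides and known
from arthropod K⁺-channel toxins), the conserved glycine (by default the
γ-core glycine, reported separately for alignment displays), and the net
"liquid" charge counting only Lys/Arg as +1 and Asp/Glu as −1 (histidine
and termini ignored).

## Redundancy clustering

Redundancy removal mimics CD-HIT at 70% identity, but exactly: sequences
are processed in decreasing length (ties broken by id), each joins the
first cluster whose representative aligns at ≥ 0.70 identity, else founds
a new cluster. Representatives are therefore pairwise below threshold. At
desk scale (≤ 130-residue peptides, hundreds of sequences) no k-mer
prefilter is needed and every comparison is an exact Needleman–Wunsch
global alignment with scores +1/0/−1 (match/mismatch/gap).

Two conventions needed fixing:

* **Identity denominator.** CD-HIT divides matches by the shorter sequence
  length; a common alternative divides by alignment length including gap
  columns. Both are implemented; `shorter` is the default used by the
  clustering step.
* **Which optimal alignment.** Under +1/0/−1, alignments can share the
  optimal score while differing in matched columns (a gap costs −1 but may
  buy an extra +1 match elsewhere). The aligner therefore maximises the
  pair (score, matched columns) lexicographically — both quantities are
  additive along an alignment path, so a single dynamic program computes
  the exact optimum. This makes percent identity well-defined and
  symmetric in its two arguments; residual traceback ties break
  diagonal > up > left.

## Structural verification toolkit

* **Kabsch superposition** (`kabsch_superpose()`): closed-form
  least-squares rigid-body fit via SVD of the 3×3 cross-covariance with
  the determinant sign correction, returning a proper rotation. Tested
  against an independent quaternion (Horn) implementation to 1e−8 and
  against exact recovery of random rigid motions.
* **Ensemble precision** (`ensemble_rmsd()`): NMR ensembles are scored as
  mean ± SD of per-model backbone (N, CA, C) RMSD to the iteratively
  refined mean structure, converged when the mean RMSD changes by < 1e−6 Å.
  Ensemble-RMSD conventions differ between packages (to-mean vs all-pairs);
  the all-pairs mean is also reported, with to-mean as the headline value.
  Multi-model PDB files are read through `bio3d`.
* **Restraint accounting** (`tally_restraints()`): NOE distance restraints
  are classified by residue separation d = |i−j|: d = 0 intraresidue,
  d = 1 sequential, 2 ≤ d ≤ 4 medium range, d ≥ 5 long range — disjoint
  and exhaustive, so the total equals the list length. Readers cover plain
  two-column TSV, CYANA `.upl`, and a minimal NMR-STAR
  `_Gen_dist_constraint` loop; ambiguous restraints count once per row.
* **In-silico PCR** (`insilico_pcr()`): exact matching of the forward
  primer and of the reverse-complemented reverse primer on the plus
  strand; the product spans the outer ends of the two sites, all site
  combinations are reported, and absence of a site is a `NO_PRODUCT`
  result rather than an error. Product length is invariant to flanking
  the template with primer-free sequence.

No deposited structure, restraint list or genome ships with the package;
the structural functions are exercised on synthetic ensembles
(`generate_synthetic_ensemble()`, labelled synthetic) and constructed
templates, and can be pointed at local copies of deposited data when
available.

## The synthetic-data generator

`generate_defensin()` builds a precursor as signal peptide + mature
region: an n-region (`M` + 1–2 Lys/Arg), an h-region of 7–10 strongly
hydrophobic residues, an `A-X-A` cleavage region; then a tail drawn from
the class range, the six-cysteine framework with gaps drawn uniformly
within the motif bounds (clamped so the precursor stays within 30–130
residues), extra cysteines placed internally (class III) or flanking
(class V), the γ-core glycine at C5−2, and a short C-terminal tail.
Background residues are drawn uniformly from the 19 non-cysteine amino
acids: compositional realism is irrelevant to rule-based filters, and a
uniform background makes charge statistics easy to reason about. Class V's
tail range, nowhere pinned down by the classifier (class V is assigned on
topology alone), is set to 1–4 residues — plant-like short tails, with at
least one residue to hold the flanking cysteine.

Every positive is verified at generation time: it must pass the size
filter, match the motif, be called secreted with the intended cleavage
site, round-trip its mature region, rebuild its intended framework, and
classify to its ground-truth label; failing draws are resampled (the draw
budget is generous and exhaustion is an error, not a silent fallback).
This check is what makes "100% recovery on clean synthetic data" a
designed property rather than a statistical accident — without it, rare
background layouts (a hydrophobic window after position 40 that looks
transmembrane, or an extra cysteine landing exactly two before framework
C5 and creating a competing assignment) would leak label noise. The
corollary is worth stating plainly: perfect recovery on this generator
validates the *internal consistency* of the rules and their
implementation, not their performance on real proteomes, where signal
peptides, composition and cysteine spacing do not follow the generator's
idealisations.

Decoys (`generate_decoys()`) each violate exactly one rule — too
short/long, no cysteines, one gap forced outside its bound, no signal
peptide, a transmembrane-like stretch — and are verified at generation to
pass every *other* gate, so each is rejected at its targeted stage with
its targeted reason code. `SHUFFLED_POSITIVE` decoys permute a positive's
mature residues preserving composition; they carry no rejection guarantee
and exist to track the motif's pass rate on composition-matched noise.
`generate_family()` produces point-mutated copies of one defensin
(cysteines never touched) for clustering tests;
`generate_family_benchmark()` additionally verifies — and redraws until —
the separation structure the clustering benchmark assumes (all
within-family identities ≥ 0.8, all between-family identities < 0.5),
which guarantees exactly one cluster per family at the 0.70 threshold.

## Numerical and scale choices

* Coordinates and sequence positions are 1-based and inclusive throughout.
* Superposition rejects fewer than 3 points or rank-deficient coordinate
  sets (second singular value < 1e−10) rather than returning an arbitrary
  rotation.
* "Exactly zero" RMSD claims for identical-model ensembles hold to
  floating-point roundoff (≈ 1e−15 in practice; tests assert ≤ 1e−12).
* Default verification sizes — 1000 sequences against the exhaustive motif
  oracle, 500 synthetic positives per class, 16 short strings (120 pairs)
  against full alignment-path enumeration, 100 random rigid motions,
  10 000 restraint pairs — keep the whole suite under a minute on one CPU
  while exercising every rule branch; they are the package's chosen
  regression scale, and all are driven by a single seed.

## Known limitations

* The secretion heuristic is a coarse stand-in; on real proteomes an
  external predictor's output should be supplied.
* The external structure-evidence step of the published-style workflow
  (profile alignment against solved CSαβ structures) is represented only
  as an optional, externally produced evidence table
  (`pipeline_config(evidence = ...)`) and an override file — profile
  alignment itself is out of scope.
* Classification encodes only the printed, quantitative rules (tail
  ranges, extra-disulfide placement); qualitative criteria such as "short
  n loop" are recorded as loop lengths but not thresholded.
* The greedy clustering reproduces CD-HIT's algorithmic idea, not its
  implementation details (word-size heuristics, banding); results can
  differ from CD-HIT on borderline pairs.
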