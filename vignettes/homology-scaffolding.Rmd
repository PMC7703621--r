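---
title: "Homology-based iterative scaffolding: methods and design notes"
author: "crosscaff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based iterative scaffolding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two draft genome assemblies of the same species — say, two laboratory
strains sequenced by different groups with different technologies — are
fragmented at *different* places. Where one draft breaks, the other often
carries an intact scaffold spanning the break, so each draft holds
long-range ordering information the other lacks. `crosscaff` exploits
this complementarity without any new wet-lab data: it simulates
error-free mate-pair libraries over a ladder of insert sizes from one
draft, places them on the other, keeps only confident concordant pairs,
and uses the pairs that bridge two scaffolds as joining evidence. The
two drafts alternate roles until neither improves appreciably. A second
stage anchors low-resolution physical-map markers (cDNA clones with
known chromosome-arm positions) to the improved scaffolds and stitches
chromosome-arm pseudomolecules.

A crucial property of the approach is that only *ordering* information
flows between the strains: the sequence content of each assembly is
never altered, only rearranged and concatenated with N spacers, so the
result remains a pure single-strain assembly.

## The procedure

One directional round ("scaffold A using B") consists of, per insert
size in ascending order:

1. **Simulation** (`simulateLibrary`): fragments of length
   $N(I, \sigma_I)$ are drawn uniformly from B's scaffolds (never
   crossing a scaffold boundary); the first and last `readLength` bases
   become the forward–reverse read pair. Reads are exact copies — all
   downstream mismatches reflect strain divergence only.
2. **Placement** (`placePairs`): seed-and-extend against A. An exact
   21-mer seed at either read end (both strands) anchors the read; the
   full read is compared ungapped, allowing up to 2 mismatches per 50 bp
   — generous for the ~1 substitution per 80–110 bp typical of
   conspecific strains. A read is *unique* when a single location
   attains the minimal mismatch count and no runner-up lies within 2
   mismatches of it. Because the search is capped at 2 mismatches, a
   runner-up at 3 is invisible; a single-visible-hit read is classed
   unique. At the divergence this method targets, the expected loss from
   this truncation is negligible.
3. **Concordance filtering** (`filterPairs`): both mates unique,
   orientation forward–reverse. Same-scaffold ("internal") pairs must
   satisfy $|\mathrm{span} - I| \le \tau I$; two-scaffold ("linking")
   pairs have no measurable span and are kept whenever the implied join
   geometry is feasible. Each linking pair carries a gap estimate
   $g = I - d_A - d_B$, with $d_A$, $d_B$ the distances from the mates'
   outer edges to the scaffold ends being joined.
4. **Bundling** (`bundleLinks`): linking pairs are grouped by join
   signature — the ordered (scaffold, end) pair, which also fixes the
   relative orientation. The bundle gap is the median of its members'
   estimates.
5. **Joining** (`buildScaffolds`): greedy, in order of descending
   support, with three safeguards described below. Members are
   reverse-complemented as required and concatenated with
   $\max(g, 10)$ Ns.

The driver (`runUntilConverged`) alternates directions; an assembly is
converged when an update round improves both its L50 and N50 by less
than 5% (relative), and the loop stops when both assemblies are
converged or after 6 rounds. Convergence is judged per assembly because
the two drafts saturate at different times.

## Join safeguards

Three rules keep the greedy joiner honest. They address failure modes
that surface as soon as scaffolds shorter than the insert exist —
which, with a 1 kb to 5 Mb ladder, is always.

**Positional chaining.** When several bundles compete for one scaffold
end, their gap estimates are examined first. If the candidate partners
can be ordered along the gap axis such that each fits before the next
(within $0.25 I$), the long-insert bundles are simply seeing *past* the
near partners; only the nearest-gap candidate competes for the end and
the farther ones are satisfied transitively. Only genuinely conflicting
candidates — two partners claiming the same position — trigger the
ambiguity rule: the end is joinable only through its top-supported
bundle, and only if the runner-up has at most 0.7 times its support.

**Transitive reallocation.** The support of short scaffolds is
structurally weak: the number of pairs whose mate fits inside a
scaffold of length $\ell$ scales with $\ell$, independent of genome
size, so at 1x pair coverage a ~500 bp contig expects fewer links than
the support threshold on either side. A "skip" bundle across it,
however, is strong. When a strong bundle's gap exactly accommodates a
scaffold that weak bundles place inside it, every one of its pairs is
evidence for the nested chain, not for the direct join: its support is
donated to the two nested bundles and the skip bundle is dropped.

**Containment gate.** A coherent bundle whose median gap is strongly
negative — beyond $2 r + 3\sigma_I/\sqrt{\mathrm{support}}$, the noise
floor of a median of per-pair estimates — cannot describe an end join
(scaffolds would overlap by far more than estimate noise allows). Such
bundles arise when one scaffold's true position is *inside* another's
span (e.g. within an N gap) and are discarded. Relatedly, the driver
skips libraries whose insert cannot fit unclamped in the longest source
scaffold ($I(1+3\cdot 0.05) > \max \ell$): clamped fragments no longer
follow the declared insert distribution, and their gap estimates are
systematically wrong.

## Pseudomolecule stage

Markers are aligned with a built-in k-mer-anchored ungapped aligner
(exact 21-mer anchors, both strands, full-marker comparison clipped at
scaffold edges; blastn-like +1/−2 scoring with ungapped
Karlin–Altschul statistics, $\lambda = 1.33$, $K = 0.621$). The best
hit per marker is kept iff e-value $\le 10^{-25}$, identity $\ge$ 90%
and alignment length $\ge$ 100 bp; the e-value gate is the stringency
anchor, the other two are configurable secondary gates. Any tabular
local aligner could be substituted — the engine contract is only
"best hit with identity, length, e-value".

Scaffolds are assigned to the arm contributing the most mapped markers;
ties go to the larger $\sum(\mathrm{identity} \times \mathrm{length})$.
A scaffold with markers from both arms of one chromosome, where the
minority markers form a terminal block and both blocks are internally
monotone in rank, is classed *centromere-spanning*: it keeps its
majority arm, and because its mean marker rank is extreme on that arm
it lands at the centromere-proximal end, i.e. at the junction, when the
R and L arms are concatenated (R first) into the AGP chromosome object.
Any other multi-arm scaffold is reported as a conflict and keeps its
majority arm.

Orientation is the sign of the Kendall tau between marker rank and hit
coordinate. Single-marker scaffolds get orientation `unknown` and are
deliberately kept forward and flagged — they appear as pseudo-inversions
in downstream dot plots, which is preferable to guessing. Arms are
stitched in mean-rank order with 1000-N spacers; `linearityScore`
re-locates every marker by offset arithmetic and reports the rank/
position tau plus the fraction of adjacent rank pairs in order.

## The synthetic test bed

`makeStrainPair` emulates the study conditions at desk scale: a uniform
random 2 Mb ancestor; two drafts, each with independent substitutions at
rate 0.01 (matching the ~1-in-80 to 1-in-113 substitution densities
observed between conspecific mosquito lab strains) and independent
fragmentation breakpoints (exponential spacing, mean 10 kb, minimum
500 bp), contigs shuffled and randomly strand-flipped. `makeMarkerSet`
excises 500 bp markers every 20 kb and labels two arms split at the
midpoint — preserving the ratio of marker resolution to genome size of
a low-resolution physical map (~0.6 Mb resolution on a ~200 Mb genome).
A truth table records every contig's ancestral interval and strand, and
`scoreRecovery` compares every join the scaffolder makes against
ancestral adjacency.

What the generator deliberately omits: indels (the placement engine is
ungapped), repeat families, segmental duplication, inversion
polymorphism, sequencing error and real gap structure. Passing tests
therefore demonstrate the correctness of the ordering logic, the
geometry arithmetic and the convergence behaviour under realistic
divergence — not robustness to repeats or structural variation, which
real data would add.

## Defaults at a glance

| parameter | default | note |
|---|---|---|
| insert ladder | 1 k, 5 k, 10 k, 50 k, 100 k, 500 k, 1 M, 2 M, 5 M | applied ascending, each round updating the target |
| read length | 50 bp | |
| pairs per library | 1x read coverage ($L/2r$) | coverage is otherwise unconstrained |
| insert sd | 5% of insert | |
| placement | k = 21, ≤ 2 mismatches, margin 2 | |
| span tolerance τ | 0.25 | internal pairs and join-geometry slack |
| min links | 5 | per bundle, after reallocation |
| ambiguity ratio | 0.7 | second-best/best support |
| gap floor | 10 N | emitted joins |
| convergence ε | 5% | relative L50 and N50, per assembly |
| max rounds | 6 | |
| marker gates | e ≤ 1e−25, id ≥ 90%, len ≥ 100 | |
| stitch spacer | 1000 N | arms; AGP records a centromere gap between arms |

Numerical conventions: internal coordinates are 0-based half-open; FASTA
output wraps at 60 columns; AGP and marker-hit coordinates are 1-based
inclusive. Ties everywhere break deterministically (support, then
absolute gap, then lexicographic signature), so a rerun with the same
seeds is byte-identical and results do not depend on input scaffold
order. Kendall tau of 0 or undefined (single marker, tied coordinates)
yields orientation `unknown`, never a guess.

The test suite exercises the full pipeline on a 2 Mb / ~200-contig /
1%-divergence fixture (the package's standard validation scale, chosen
to preserve the contig-to-insert-ladder and marker-resolution ratios of
a real mosquito-genome application while keeping a complete convergence
run in the low minutes), the 500 kb zero-divergence limit, and smaller
algebraic fixtures for each operation.

## Known limitations

- Ungapped placement: indel divergence between strains would shift
  reads off their loci; real applications at >1% indel density would
  need a gapped placer behind the same interface.
- No misassembly detection: input scaffolds are never broken, so an
  error *inside* a draft scaffold propagates (the method inherits this
  from its design — contigs are trusted, only their order is inferred).
- Repeats: unique-placement filtering discards repeat-borne pairs
  entirely; assemblies of highly repetitive genomes will retain the
  corresponding junctions unjoined.
- Gap estimates are medians of noisy per-pair values; emitted gap
  lengths are indicative, not base-accurate.
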