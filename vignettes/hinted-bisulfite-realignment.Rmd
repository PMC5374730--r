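---
title: "Hinted windowed re-alignment for whole-genome methylation calling"
author: "bsrealign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinted windowed re-alignment for whole-genome methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrealign)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reads methylation by chemistry:
treating DNA with sodium bisulfite converts unmethylated cytosines to
uracil (sequenced as T) while 5-methylcytosines are protected and stay C.
Mapping a converted read back to the reference and comparing base by base
therefore reveals, for every covered cytosine, whether the molecule was
methylated there. The catch is that the conversion itself degrades
mappability: a heavily converted read differs from the reference at every
unmethylated C, and a mapper that penalises those differences both loses
reads and biases the recovered methylation towards methylated (less
converted, easier to map) molecules.

`bsrealign` implements a two-part answer:

1. **Location hints.** Each read arrives with an approximate genomic
   coordinate (from an upstream coarse locator, or from the untreated mate
   — see below). Rather than searching the whole genome, the read is
   re-aligned *locally* inside a window of ±`window_radius` bases
   (default 1000) around the hint. This converts an intractable global
   mapping problem with a degenerate alphabet into a small, exact local
   alignment.
2. **Hybrid read pairs.** Each read group pairs a bisulfite-treated end
   with an *untreated anchor* end from the same molecule. The anchor is
   ordinary DNA, aligns unambiguously, and validates the locus; the treated
   end carries the methylation signal. A group is only trusted if *every*
   member aligns well — a failed anchor means the hint itself was wrong,
   so the treated end's calls would be unsafe no matter how well it
   happens to align.

## The aligner

The core is a Smith–Waterman local alignment over the hinted window with
two deliberate modifications.

**Asymmetric, bisulfite-aware substitution.** With match score $a > 0$ and
mismatch score $b < 0$, the substitution function in `c_to_t` mode is

$$
s(x, y) = \begin{cases}
a & x = y \neq \mathrm{N}\\
a & (x, y) = (\mathrm{T}, \mathrm{C})\\
b & \text{otherwise,}
\end{cases}
$$

for read base $x$ against reference base $y$. Read T over reference C is a
converted cytosine and must not be penalised; read C over reference T
remains a mismatch, because the chemistry only runs one way. Mode `g_to_a`
mirrors the rule — reads representing the opposite strand, compared
against the forward reference, show A where the reference has G — and mode
`none` (used for untreated anchors) is plain symmetric matching. N on
either side always scores as a mismatch: a conservative choice, since an
N column carries no evidence and a neutral zero would let runs of N
inflate alignments.

**Direction recording.** The DP fill

$$
H_{i,j} = \max\bigl(0,\; H_{i-1,j-1} + s(r_i, w_j),\;
H_{i-1,j} + g,\; H_{i,j-1} + g\bigr)
$$

(linear gap penalty $g < 0$, zero floor, zero first row/column) stores in
a parallel matrix *which* argument attained each maximum. Traceback then
walks stored pointers from the best cell to the first zero cell without
re-evaluating the recurrence — no branch re-judgement, one array read per
step. The memory cost is one byte-sized code per cell; for a 50 bp read in
a ~2000 bp window that is negligible, and the windowed design means the
matrix never approaches genome scale (we window the problem rather than
band the matrix).

Determinism is pinned down explicitly, because the pipeline's parallel
contract depends on it: ties in the cell maximum break in the fixed order
diagonal > up > left, a cell points "stop" exactly when its score is zero,
and the alignment ends at the *first* maximal cell in row-major order.
With those rules every alignment, and hence every downstream report byte,
is a pure function of the inputs.

Default scores are match +2, mismatch −3, gap −2 — BLAST-like values that
favour contiguous matches and make a 60 % score threshold meaningful (see
below). They are ordinary tuning parameters, exposed in
`scoring_scheme()` and on the command line. Affine gaps are deliberately
out of scope: hinted windows make long gaps biologically implausible, and
linear gaps keep the direction-recording traceback exact and simple.

The fill is implemented in C++ (Rcpp); traceback, which touches at most
$n+m$ cells, stays in R.

## From alignments to methylation calls

Only treated members of accepted groups generate calls, and only from
*diagonal* (match/mismatch) alignment columns — a gapped column aligns no
read base to the cytosine, so it is silent. At a reference C on the
forward strand: read C ⇒ methylated, read T ⇒ unmethylated, anything else
(sequencing error, variant) ⇒ no call. Reverse-strand cytosines live at
reference G positions and are called from read G/A, reported at the
forward-reference coordinate with strand `-`, the convention CX-style
reports use. Every call is annotated CpG / CHG / CHH from the reference
trinucleotide on the cytosine's own strand (H ∈ {A, C, T}; truncated
trinucleotides at chromosome ends default to CHH; N counts as H).

Untreated anchors contribute no calls at all — their cytosines are
unconverted and therefore uninformative; they exist to validate the locus.
A retained C is always counted as methylated: incomplete bisulfite
conversion is *not* modelled away at calling time, but the simulator's
`conversion_rate` knob lets the resulting upward bias be generated and
measured directly.

The per-group acceptance gate is
`score >= min_score_fraction * read_length * match` for **every** member,
default 0.6. At +2/−3/−2 this tolerates roughly one mismatch per eight
aligned bases of a clean read — loose enough for converted reads with a
few sequencing errors, strict enough that a scrambled or mis-hinted read
(whose best local score in a 2 kb window is far below half-maximal) is
rejected. Raising the threshold can only shrink the accepted set, a
monotonicity the test suite checks.

PCR duplicates are recognised exactly as coordinate-based dedup tools do:
accepted groups whose treated ends occupy the same (chromosome, start,
end, strand) are copies of one molecule; the highest combined group score
survives, ties breaking to the smallest group ID. Deduplication runs per
input chunk. Because the chunk reader never splits an ID run and input is
ID-sorted, duplicates that sit adjacent to their source in the file are
always deduplicated; coincidental same-coordinate molecules arriving in
different chunks would not be, which is the documented trade-off of the
bounded-memory design.

## The execution contract

The pipeline's parallel story is a *contract*, not a mechanism: output
files are byte-identical for any worker count and any legal chunk size.
Three rules make this cheap to guarantee:

- **Chunked input.** Records stream in chunks of `chunk_size` (default
  two million) in one concentrated read per chunk. Nominal cut points sit
  at absolute multiples of `chunk_size` and each moves back to the nearest
  preceding group boundary, so no chunk ever splits a group and the
  concatenated stream is independent of the chunk size. A group wider than
  a whole chunk window is a hard error rather than a silent split.
- **Contiguous partitioning.** Within a chunk, groups are dealt to workers
  in contiguous slices balanced by record count (each partition takes
  groups until it reaches ⌈remaining records / remaining workers⌉). Same-ID
  records always share a worker; concatenating partitions restores input
  order, so merging results is trivial.
- **Order-free aggregation.** Methylation counting is a pure increment on
  a (chromosome, position, strand) key — associative and commutative — so
  per-worker buffers can be flushed into the genome-wide counters in any
  order ("write-through") without changing the result.

Workers are forked processes (`parallel::mclapply`); since group
processing is deterministic and partitioning is fixed before the fork, the
choice of process- versus thread-level parallelism is invisible in the
output.

## The simulator

`simulate_dataset()` generates the full study: an i.i.d. random reference
at a chosen GC fraction (default 0.42), per-cytosine true methylation
levels, and hinted hybrid read pairs with a complete truth table.

Choices worth knowing:

- **Constant per-context levels.** Every cytosine of a context carries
  that context's level (defaults CpG 0.75, CHG 0.02, CHH 0.02 —
  mammalian-like). Each sequenced molecule then draws its state
  Bernoulli(level), so a site's realized methylated fraction is binomial
  in its coverage — exactly the sampling model against which recovery is
  judged.
- **Distinct loci.** Original molecules draw (chromosome, strand, start)
  *without replacement*, so identical mapped coordinates identify planted
  duplicates and nothing else. This matches the operational definition of
  a PCR duplicate that coordinate dedup implements; it is also why the
  duplicate-removal count in a fixture equals the planted count exactly.
- **Duplicates are molecule re-emissions.** A duplicate group copies its
  source molecule's realized methylation (same conversions) with fresh
  sequencing errors and fresh hint jitter, and is emitted immediately
  after its source. The truth table counts each molecule once.
- **Forward orientation.** Both ends are written in forward-reference
  orientation; a reverse-strand molecule shows G→A conversions against
  the forward reference, matching the aligner's `g_to_a` mode. The hinted
  format carries a strand column but does not define read orientation on
  the minus strand, so one convention is fixed and documented.
- **Hints.** Each record's coordinate hint is its true start plus uniform
  jitter up to `hint_jitter` (default 100 bases, emulating a coarse
  upstream locator; required to stay below window radius − read length so
  the truth stays recoverable).

What the simulator does *not* emulate: realistic read-length and quality
distributions, indel sequencing errors, SNPs/CNVs between sample and
reference, PCR error accumulation, M-bias along the read, or
chromosome-scale genomes. Tests passing on these fixtures therefore
demonstrate the *algorithmic* properties — exact recovery in the
noise-free limit, binomial-consistent recovery under substitution noise,
dedup and threshold behaviour, serial/parallel byte-identity — not
performance or robustness on real libraries.

## Numerical and degenerate-input choices

- Scores and the DP are exact integer arithmetic; no floating point enters
  until the final m/(m+u) division, and bedGraph levels are printed with
  `%.6g` so report bytes are reproducible.
- Methylation level at an uncovered site is *undefined* (`NA`), never 0.
- Windows truncate silently at chromosome ends; hints outside the
  chromosome reject the group (logged, counted, never fatal).
- An empty target file is a valid run: empty reports, zero summary.
- Reference bases outside A/C/G/T/N map to N with a warning; N never
  matches during alignment and emits no call.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: the
oracle comparison on 200 random instances (reads and windows up to 12
bases, all three modes); exact-regime recovery on 100 groups over a 20 kb
genome; noisy recovery at ~50× CpG coverage on a 2.5 kb genome
(4500 groups, error rate 0.005, jitter 200); a 3 × 2 grid of worker
counts and chunk sizes on a 100-group fixture; and a 100-group fixture
with 10 % planted duplicates. These sizes give every statistic a
comfortable margin (≈1000 covered sites in the exact regime, ≈190 CpGs at
≈48× in the noisy regime) while keeping a full run in the low minutes on
one core.

## Known limitations

- Groups are judged as a unit; re-pairing ends within a group (choosing a
  best treated/untreated combination among >2 records) is not attempted.
- Dedup across chunks relies on duplicates being ID-adjacent (see above).
- Quality scores do not exist in the input format and are ignored.
- The caller does not model conversion failure; `conversion_rate < 1`
  biases levels upward by design, measurably.
- Only substitution sequencing errors are simulated; indel errors would
  exercise the gap machinery more strongly than the current fixtures do.
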