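---
title: "Exact protein database search with emulated packed lanes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact protein database search with emulated packed lanes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swlanes)
```

## The problem

Protein database search by optimal local alignment ranks every subject
sequence of a database by its Smith-Waterman score against a query. Unlike
seed-and-extend heuristics, the Smith-Waterman algorithm is exact — it never
misses a distantly related sequence because a seed failed — at the price of
a quadratic-time dynamic program per pair. High-throughput implementations
recover speed without giving up exactness by packing many independent
alignments into the lanes of wide integer vectors and by spreading the
database over heterogeneous compute resources. `swlanes` implements that
method as a portable, instrumentable library: a packed-lane
saturating-integer engine with staged overflow recomputation, dual
query-lookup structures, and a device/host workload partitioner, all
emulated deterministically on the CPU so that every policy decision of the
original heterogeneous design can be exercised and verified against an
exact oracle.

## The alignment model

For query $S$ and subject $T$, with substitution matrix $M$ and affine gap
penalties, the recurrence is

$$
H_{i,j} = \max\{H_{i-1,j-1} + M(S[i], T[j]),\; E_{i,j},\; F_{i,j},\; 0\}
$$
$$
E_{i,j} = \max(E_{i-1,j} - \beta,\; H_{i-1,j} - \alpha), \qquad
F_{i,j} = \max(F_{i,j-1} - \beta,\; H_{i,j-1} - \alpha),
$$

initialised to zero on the first row and column. $\alpha$ is the sum of the
gap open and extension penalties and $\beta$ the extension penalty — note
that $\alpha$ is subtracted directly when a gap opens, so a gap of length
$k$ costs $\mathrm{open} + k\,\mathrm{ext}$. The optimal local score is
$\max_{i,j} H_{i,j}$ and is computed in linear space with two row buffers
(for $H$ and $E$) over the subject plus scalar carries for $F$ and the
left/diagonal $H$. `sw_score()` runs this recurrence in unbounded (64-bit)
integers and is the package's ground truth; `sw_matrix()` materialises the
full matrix on small instances as a second, independent oracle.

## Inter-task lanes and saturating arithmetic

The production path is *inter-task* vectorization: one query is aligned
against $W$ subject sequences simultaneously, one alignment per lane of a
$W$-lane signed integer vector ($W = 4$ for the device-style pass, 16 for
the host-style pass). Additions and subtractions saturate to the signed
8-bit range, so lane values never wrap — they clamp at $+127$. A clamped
score is detected by the *overflow limit*: since one cell update can raise
a score by at most $\max M$, any reported score below
$2^{w-1} - \max(M)$ (117 for BLOSUM62 at $w = 8$) is provably exact, and
any score at or above it is recomputed — first with 8-lane 16-bit
saturating arithmetic (limit $32768 - \max M$), and if still at the limit,
with the unbounded scalar engine. The staging is therefore lossless: every
emitted score is exact, while the overwhelming majority of alignments (real
scores are almost always far below 117) never leave the cheap 8-bit pass.

Unequal sequence lengths inside a lane group are handled by a reserved
padding symbol whose substitution score is pinned to $-128$: after one
saturating addition a padded lane's $h$, $e$, $f$ collapse to $\le 0$ and
its running maximum stays frozen at 0, so padding can never produce a hit
or a flag.

The per-cell kernel is specified at the R level by `lane_vector()`,
`sat_arith()` and `cell_update()` — ten saturating/max operations per cell,
plus one maximum update — and executed over whole profiles by a compiled
engine. The test suite drives tiny alignments through `cell_update()` cell
by cell and requires bit-identical agreement with the compiled engine at
both lane widths.

## Lookup structures

Three precomputed structures feed substitution scores to the kernel:

* **Query profile** `build_query_profile()`: row $r$ holds
  $M(r, S[i])$ for all query positions $i$ — one fetch per lane per cell,
  $O(|S| \cdot |\Sigma|)$ memory.
* **Query-profile variant** `build_variant()` ($K = 2$): for every ordered
  residue pair $(r_1, r_2)$, the packed pairs
  $(M(r_1, S[i]), M(r_2, S[i]))$ — one fetch serves two lanes, halving
  lookups, at $O(|S| \cdot |\Sigma|^2)$ memory. Pairs are encoded densely as
  $r_1 |\Sigma| + r_2$; elements are stored as two parallel score planes
  together with a `pack_scores()`/`unpack_scores()` pair proven inverse in
  the tests, so the external contract — which scores reach the kernel — is
  fixed while the emulation avoids committing to a byte layout. The two
  sources must and do produce identical scores on every database; only
  their cost profiles differ.
* **Sequence profiles** `build_sequence_profiles()`: consecutive runs of
  $W$ adjacent sequences of the length-sorted database, padded to the
  longest member. Adjacency in sorted order minimises padded cells; rows
  are additionally counted in fetch groups of 4 (the granularity of one
  packed fetch), an accounting concept only.

## Workload partition and scheduling

The database is length-sorted ascending and split by residue count between
the device-style and host-style passes. The device share is

$$ R = \frac{N_G f_G}{N_G f_G + N_C f_C / C}, $$

with $N_G$ multiprocessors at $f_G$ GHz against $N_C$ host threads at
$f_C$ GHz and a calibration constant $C$ (3.2 for the query profile, 5.1
for the variant — the variant's device pass is faster, so relatively more
work flows to the device). The device takes the shortest prefix of
cap-eligible sequences whose cumulative length reaches
$N_R = \mathrm{round}(R \times \text{total residues})$ ("reaches" read as
the smallest prefix with cumulative length $\ge N_R$; ties in the rounding
go up). Sequences longer than the device cap (default 3072, the length the
statically allocated $H$/$E$ row buffers are sized for; 65,536 is the hard
bound a 512 KB local budget could support) always run host-side. Host
sequences are balanced over threads by greedy longest-first assignment to
the least-loaded thread — the stated goal is equal residue counts per
thread with a sequence as the unit, and greedy longest-first guarantees a
max/min spread of at most one sequence length.

Scheduling policy: databases with population length deviation at most 1% of
the mean (equal-length benchmarks) use static scheduling; all others use
dynamic scheduling, emulated as workers pulling profile blocks off a shared
monotone counter (`dynamic_assign()`, with
$N_T = \lfloor 2 N_{SM} N_{MRT} / N_{TPB} \rfloor$ workers). The score
source is the variant under static scheduling, and under dynamic scheduling
the variant only below a query-length threshold (default 400, the observed
switch point; `"auto"` derives it from a cache budget as
$\lfloor \text{cache} / (2 |\Sigma|^K) \rfloor$, the length at which the
variant's footprint fills the budget). Because the calibration constant
depends on the score source, the pipeline resolves schedule $\to$ score
source $\to$ $C$ $\to$ $R$ $\to$ split, in that order.

All of this is performance policy, not semantics: the pipeline asserts, and
the tests verify, that ranked output is byte-identical across every
schedule, thread count, split fraction and score source.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gap_open`, `gap_extend` | 10, 2 | affine gap charges; $\alpha = 12$, $\beta = 2$ |
| `matrix` | BLOSUM62 | bundled: BLOSUM62, BLOSUM50 (NCBI text format) |
| `n_host_threads`, `host_freq_ghz` | 4, 3.5 | host side of the power model |
| `device_sm_count`, `device_freq_ghz` | 8, 1.06 | device side of the power model |
| `calib_const_profile` / `_variant` | 3.2 / 5.1 | $C$ per score source |
| `device_length_cap` | 3072 | longest device-pass subject |
| `threads_per_block`, `max_resident_threads` | 64, 2048 | dynamic worker sizing |
| `schedule` | auto | 1% population-sd/mean rule |
| `variant_threshold` | 400 | query-length switch; `"auto"` = cache estimate |
| `top_n` | Inf (CLI: 10) | output truncation |

The default gap penalties are the tool family's historical defaults; they
are deliberately configurable because no single pair is canonical.

## The synthetic database generator

`generate_db()` emulates the two benchmark database families: equal-length
databases (`mode = "equal"`, canonical full scale 200,000 sequences of
length 3,000 — 600,000,000 residues — the ideal case in which every lane of
every vector finishes simultaneously and static scheduling wins) and
variable-length databases (`mode = "lognormal"`, defaults mean 350 / sd 300,
matching the right-skewed length distribution of a curated protein database
whose mean length is ≈355) that always trip the 1% rule into dynamic
scheduling. Residues are drawn uniformly from the 20 standard amino acids —
the simulation distribution is not otherwise constrained, and uniform
residues make score statistics conservative (no composition bias inflates
scores). Generation is seeded and chunk-streamed: the file sink, the
in-memory sink and the counting sink consume the generator identically, so
a 600-million-residue database can be counted in bounded memory and small
fixtures are bit-reproducible.

What the generator does *not* emulate: real residue composition, homologous
structure (every pair is effectively unrelated, so true scores concentrate
far below the 8-bit limit), and the long tail of real database lengths
beyond the lognormal. Passing the oracle-equivalence suite on these inputs
demonstrates numerical exactness of the staged engine under realistic
length mixes — it does not demonstrate retrieval quality on real proteomes,
which is a property of the scoring scheme, not of this implementation.
High-scoring behaviour is therefore exercised separately with constructed
self-alignments whose exact scores (116, 117, 118, 130, 40,000) straddle
both overflow limits.

## Numerical choices and degenerate inputs

* Sentinel substitution score $-128$ (the 8-bit minimum) for the padding
  symbol and for alphabet symbols absent from a loaded matrix.
* Unknown residue letters encode as `X` (ambiguous), case-insensitively.
* $N_R$ rounding: nearest integer, ties up (`floor(x + 0.5)`).
* Standard deviation in the 1% rule: population form, as a property of the
  database, not a sample estimate.
* Ranking ties: descending score, then ascending original database
  position — stable and documented.
* The scalar engine switches from 32-bit to 64-bit arithmetic when
  $\max(M) \cdot \min(|S|,|T|)$ approaches the 32-bit range, so arbitrarily
  high scores are exact.
* Empty queries or databases, padding symbols in input, unsorted databases
  handed to the profile packer, and over-cap sequences reaching the device
  pass are all rejected with explicit errors rather than repaired.

## Validation scale

The shipped suite checks oracle equivalence of the full pipeline on 20
seeded databases of 200–1,000 sequences (lengths 20–500) times 5 queries
(lengths 50–600), rotating through a 16-combination grid of schedule,
thread count, split fraction and score source; score-source equivalence on
20 further databases; and a full schedule/thread/split determinism grid on
one database. These sizes exercise every routing path (device, host,
16-bit and exact recomputation) while keeping the whole suite in the
low single-digit minutes on one core.

## Known limitations

* The lane engine emulates saturating SIMD semantics; it does not use real
  vector instructions, and reported GCUPS are those of the emulation.
* Score-only output: no traceback, no alignment strings, no E-value
  statistics.
* Protein alphabets only; no position-specific scoring.
* $K = 2$ is the only supported variant order, and the striped
  (intra-task) vectorization family is intentionally out of scope.
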