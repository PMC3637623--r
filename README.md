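# swlanes

Exact Smith–Waterman protein database search with an emulated packed-lane
saturating-SIMD engine and heterogeneous workload partitioning.

## What it is for

Ranking every sequence of a protein database by its *optimal* local
alignment score against a query — the fully sensitive alternative to
seed-and-extend heuristics — while reproducing, in portable and testable
form, the machinery high-throughput implementations use to make that
affordable: inter-task vectorization (one query against W subjects at once,
one alignment per signed integer lane), saturating 8-bit arithmetic with
staged 16-bit and exact recomputation of potentially overflowed scores,
dual query-lookup structures (sequential query profile and its K=2
packed-pair variant), and a compute-power-driven split of the database
between a device-style quad-lane pass and a host-style 16-lane pass. The
emulation is deterministic, so the package is useful both as a search tool
and as a reference implementation whose every policy decision can be
checked against an exact oracle. Intended users: sequence-analysis
developers and method benchmarkers; anyone who needs exact scores with a
reproducible pipeline.

## The method

For query $S$ and subject $T$ under substitution matrix $M$ with affine gap
penalties ($\alpha$ = open + extend, $\beta$ = extend):

$$H_{i,j} = \max\{H_{i-1,j-1} + M(S[i],T[j]),\ E_{i,j},\ F_{i,j},\ 0\}$$
$$E_{i,j} = \max(E_{i-1,j}-\beta,\ H_{i-1,j}-\alpha),\quad
  F_{i,j} = \max(F_{i,j-1}-\beta,\ H_{i,j-1}-\alpha)$$

The optimal score is $\max H$. The production path computes this per lane
in saturating signed 8-bit arithmetic; any reported score reaching
$128 - \max(M)$ (117 for BLOSUM62) may have clamped and is recomputed with
16-bit lanes, then — if it reaches $32768 - \max(M)$ — with unbounded
integers. Every emitted score is exact; the staging only decides *where*
it gets computed (`compute_path`: `device`, `host`, `recomputed-16`,
`recomputed-exact`). The database split fraction follows
$R = N_G f_G / (N_G f_G + N_C f_C / C)$, scheduling follows the 1%
length-deviation rule (static for equal-length databases, dynamic
otherwise), and ranked output is provably identical under every schedule,
thread count, split fraction and score source. See the methods vignette
(`vignettes/lane-search-methods.Rmd`) for the full design.

## Worked example

```r
library(swlanes)

scheme <- scoring_scheme("BLOSUM62", gap_open = 10, gap_extend = 2)

# Swiss-Prot-like synthetic database: 500 sequences, lognormal lengths
db <- generate_db(db_spec("lognormal", 500, length_mean = 350,
                          length_sd = 300, seed = 42))

query <- encode_sequence(paste0(
  "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVH",
  "SLAKWKRQTLGQHDFSAGEGLYTHMKALRPDEDRLSPLHSVYVDQWDWE"), id = "Q1")

hits <- sw_search(query, db, scheme, sw_config(top_n = 5, verbose = TRUE))
print(hits)
```

```
query Q1 (120 aa) vs 500 seqs (168677 residues): partition 0.002s, lane passes 0.090s,
recompute 0.000s (0 flagged), rank 0.003s; 0.2131 GCUPS [schedule=dynamic source=variant R=0.7554]
<sw_hits> 5 ranked hits (0.2131 GCUPS, schedule=dynamic, source=variant)
  rank score        id description db_index compute_path
1    1    46 sim000153                  153       device
2    2    46 sim000440                  440         host
3    3    41 sim000026                   26       device
4    4    41 sim000494                  494       device
5    5    40 sim000401                  401       device
```

Reading the output: the database's length spread (sd/mean > 1%) selects
dynamic scheduling; the 120-residue query is below the 400-residue switch
point, so the device pass uses the K=2 query-profile variant; with the
default power model (8 multiprocessors at 1.06 GHz vs 4 host threads at
3.5 GHz, C = 5.1 for the variant) 75.5% of residues go to the quad-lane
device pass and the rest to the 16-lane host pass. No alignment reached the
8-bit overflow limit (117), so nothing was recomputed, and the two scores
of 46 are tied and ordered by database position. GCUPS is billions of DP
cell updates per second: query length × database residues / wall time /
10⁹.

The same search from a shell (the `swlanes` script is installed under the
package's `exec/` directory):

```sh
swlanes simdb --mode lognormal --n 500 --mean 350 --sd 300 --seed 42 --out db.fasta
swlanes search --query query.fasta --db db.fasta --topn 5 --out hits.tsv
```

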