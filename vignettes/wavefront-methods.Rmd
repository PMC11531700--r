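---
title: "Methods: lane-group wavefront Smith-Waterman and its performance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lane-group wavefront Smith-Waterman and its performance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swWavefront)
```

## The problem and the model

Protein database search asks, for a query sequence $Q = (q_0 \ldots q_{m-1})$
and each subject $S = (s_0 \ldots s_{n-1})$ in a database, for the optimal
local alignment score under a substitution matrix $\sigma$ and affine gap
penalties: a gap of length $g$ costs $\alpha + (g-1)\beta$. The
Smith-Waterman recurrences over matrices $H$, $E$, $F$ are

$$H(i,j) = \max\{\, H(i-1,j-1) + \sigma(q_{i-1}, s_{j-1}),\; E(i,j),\;
F(i,j),\; 0 \,\}$$
$$E(i,j) = \max\{E(i-1,j) - \beta,\; H(i-1,j) - \alpha\}, \qquad
F(i,j) = \max\{F(i,j-1) - \beta,\; H(i,j-1) - \alpha\}$$

with boundaries $H(i,0) = H(0,j) = 0$, $E(i,0) = -\alpha-(i-1)\beta$,
$F(0,j) = -\alpha-(j-1)\beta$ and the remaining boundary $E$/$F$ at
$-\infty$. The score is $\max_{i,j} H(i,j)$; database search needs no
traceback. `swScoreFull()` and `swScoreLinear()` implement these recurrences
directly (full-matrix and rolling-rows) and serve as the oracle for
everything else in the package.

For the $-\infty$ boundary we use an integer sentinel, `INT_MIN / 4`:
large enough that `sentinel - alpha - n * beta` cannot underflow a 32-bit
integer for any input this package can construct (the `ScoringScheme`
validity method asserts this). The two finite boundary initializations
($E(i,0)$, $F(0,j)$) are stored for fidelity when full matrices are
requested, but are provably never consulted by interior cells, so engines
may treat them as $-\infty$ without observable difference.

## The lane-group wavefront engine

The package's core is a deterministic, single-threaded emulation of a
SIMD-style alignment kernel. A *lane group* is $p \in \{2,4,8,16,32\}$
lockstep lanes, each owning $k \le 40$ consecutive DP columns, so one group
spans subjects up to $n = p \cdot k$. Computation follows an anti-diagonal
wavefront of exactly $m + p$ iterations: at iteration $i$, lane $t$ computes
the $k$ cells of row $i - t$ (lanes outside $1..m$ compute on pad rows whose
results are provably discarded — see "Padding" below). Three mechanisms are
emulated faithfully:

* **Boundary exchange.** After its $k$ cells, each lane passes its rightmost
  $(H, F)$ to the next lane, as a shuffle-style register exchange
  (`shiftUpExchange()` documents the contract: lane $t$ receives lane
  $t-\mathrm{offset}$'s value, out-of-range lanes keep their own). The
  receiving lane uses the incoming $H$ and $F$ as its same-row left
  neighbour, and retains the *previous* exchanged $H$ as the diagonal
  $H(r-1, j)$ — the value exchanged two iterations earlier. The recurrences
  determine this payload: $F$ and same-row $H$ are needed immediately, $E$
  is column-local and never crosses lanes, which is why the exchange carries
  $(H, F)$ and nothing else.
* **Query rotation.** Lanes receive query characters through two registers
  (`cqCurrent`, `cqNext`): every $p$ iterations lane $t$ loads
  $q_{i+t}$ into `cqNext`; each iteration `cqCurrent` is shuffled up one
  lane, lane 0 refills from `cqNext`, and `cqNext` is shuffled down. The net
  schedule delivers $q_{i-t}$ to lane $t$ at iteration $i$
  (`laneQuerySchedule()`; the tests verify the register scheme against this
  closed form, and that the engine's internal rotation agrees). The order of
  the three register moves within an iteration is chosen so that
  simultaneous-read shuffle semantics deliver that schedule. Hardware
  batches these loads four characters at a time; that is a memory-traffic
  optimization with no observable effect on the schedule and is not modeled.
* **Substitution lookups.** Scores are looked up in two stages: the lane's
  current query character selects a matrix row once, and the lane's $k$
  subject characters index into that row. In packed mode the table is laid
  out as $|\Sigma| \times |\Sigma|^2$ packed 16-bit pairs
  (`buildPackedTable()`), so one access scores the query character against
  both packed subjects.

Each lane tracks its running maximum of $H$; the final score is the
reduction of these maxima across lanes. In `wide32` mode this equals the
reference DP exactly — the randomized equivalence suite asserts this across
all $(p, k)$ shapes, and a debug coverage bitmap asserts that the wavefront
computes each real cell exactly once.

### Padding

The hardware algorithm assumes $n = p \cdot k$ exactly; real subjects are
padded. The pad code scores $-(\alpha + \max|\sigma| + 1)$ against
everything, which makes every pad-cell value strictly smaller than some real
cell's value (each pad $H$ is bounded by a real $H$ minus a positive
constant, and $E$/$F$ branches subtract further), so pad cells can neither
create a new running maximum nor raise a spurious overflow flag. This keeps
the emulation branch-free, matching the lockstep design intent: inactive
lanes and pad columns compute like everything else and their results are
simply never able to win.

### Precision modes and overflow

Three arithmetic modes mirror the kernel variants:

* `wide32` — exact 32-bit integers; never flags.
* `int16sat` — every add/subtract saturates to $[-32768, 32767]$; a subject
  is flagged (`saturated16`) once any $H$ reaches 32767. Saturation
  preserves $H' \ge \min(H, 32767)$, so any subject whose true score reaches
  the ceiling is guaranteed to be flagged (no false negatives — tested on
  engineered pairs).
* `fp16emu` — models half-precision float kernels by their conservative
  safeguard only: scores below 2048 are computed in exact integer
  arithmetic, and a subject is flagged (`fp16range`) once any $H$ reaches
  2048, the region where half floats lose integer exactness. Bit-accurate
  half-float rounding is deliberately not simulated: flagged subjects are
  rescored in wide arithmetic anyway, so rounding detail below the recompute
  threshold has no observable consequence.

`genOverflowPair()` constructs adversarial inputs (repeats of the
highest-scoring self-pair residue, W against W) whose oracle score provably
reaches a requested threshold.

### Tiling for long subjects

One group spans at most $32 \cdot 40 = 1280$ columns (k is capped at 40,
mirroring the register-pressure ceiling of the hardware design even though
the emulation has no such limit — keeping the configuration menu identical).
Longer subjects run through `alignTiled()`: $l = \lceil n/(kp) \rceil$
column chunks processed left to right. The rightmost lane's boundary-column
$(H, F)$ values shift into a $p$-slot buffer, flushed in blocks of $p$ rows
(emulating a coalesced write; `flushBoundary()` is the documented
operation), and the next stage's leftmost lane reads exactly those stored
values — stage $s+1$ is forbidden from seeing anything else of stage $s$.
$E$ is not carried across stages: under this row/column orientation $E$ is
column-local, so a carried $E$ would be redundant. The read side of the
boundary is emulated as direct indexed reads; buffering reads like the
hardware does would change memory traffic only, not results. Debug mode
exposes each stage's boundary store, which the tests compare cell-for-cell
against the oracle's $H$ and $F$ boundary columns.

## Database preprocessing and the scan pipeline

`makeDb()` parses FASTA or gzip-compressed FASTA (compression is
transparent: both produce byte-identical databases), encodes residues over
the 24-symbol NCBI BLAST alphabet `ARNDCQEGHILKMFPSTWYVBZX*` (unknown
letters become `X`; a 25th code is reserved for padding), and stores
sequences sorted by ascending length, ties in input order. The on-disk
format is an independent design, documented for bit-exact testing:
little-endian `db.bin` with magic `SWDB`, a u32 version, u64 counts, a u32
length table, a u64 offset table, one residue code per byte, and a header
blob with its own u32 length table; `db.meta` is a JSON summary. Headers
are truncated at the first whitespace for reporting; the full header is
retained.

Scanning dispatches each subject to the kernel shape of its length bin —
bins $[64i+1, 64(i+1)]$ for $i = 0..19$, with $p$ growing as 4/8/16/32 at
$k=32$ up to length 1024, the widest untiled shape $p=32, k=40$ for
1025..1280, and the tiled engine beyond. Batches respect a residue budget
(default 64 Mresidues — the real workflow streams batches to limited device
memory; here it is a configuration knob, exercised at small values in
tests). Under the `auto16` policy the first pass runs `int16sat` and
flagged subjects are rescored in `wide32`; the scan uses unpacked 16-bit
groups — packing two subjects per group is a first-class engine operation
with its own equivalence tests, but pairing subjects inside the batched
scan would add bookkeeping without changing any observable result. Hit
lists rank by descending score with ties broken by ascending subject id and
then database index; id-based tie-breaking keeps results invariant under
permutation of the input FASTA, which index-based tie-breaking alone could
not guarantee. Multi-worker scans partition sequences per bin by greedy
least-loaded balancing (per-bin worker totals provably differ by at most
that bin's longest sequence), and merging per-worker lists reproduces the
single-worker list exactly; workers are a partitioning contract, not a
threading implementation. `searchSession()` holds a loaded database for
repeated queries and counts loads, making the transfer-once property
testable.

## The analytic performance model

The throughput model counts the arithmetic of one cell update: the main
recurrence costs 1 addition and 3 maxima, the optimized gap recurrences 3
subtractions and 2 maxima, and the running-maximum comparison 1 maximum —
10 operations (`baseOpCount()`). Lookup and register-movement operations
are excluded: they can proceed concurrently with arithmetic. Capability
rewrites (`instructionSchedule()`) then model successive hardware
generations: two-way 16-bit packing halves per-cell cost (10 → 5 cycles); a
second issue port takes the 4 add/subtract operations off the critical
path, leaving 6 serialized maxima over 2 packed cells (→ 3); fused add+max
DP instructions compress the packed-pair schedule to 4 serialized
operations (→ 2). The fused endpoint is calibrated to the documented
2-cycles-per-cell figure rather than derived instruction-by-instruction:
the published inner-loop description ("5 max/add instructions plus 2 data
movements per 64 cells") is ambiguous about its normalization unit, and the
three-input-maximum instruction available on one intermediate architecture
is likewise treated as a throughput note rather than a cycle-count change,
matching that device's documented 3-cycle figure.

Theoretical peak performance is then

$$\mathrm{TPP} = \frac{\#\mathrm{SMs} \times
\mathrm{Throughput\_per\_instruction} \times \mathrm{Clock}}
{\mathrm{Cycles\_per\_cell\_update}}$$

reported in TCUPS (`tpp()`). Built-in `ArchSpec` fixtures carry the three
modeled devices (108/142/132 processors; 1.41/2.56/1.98 GHz max clocks;
throughput 64), giving 1.95, 7.75 and 8.36 TCUPS, and `efficiencyPct()`
relates measured throughput to these peaks (e.g. 5.71/8.36 → 68%).
`perfReport()` computes efficiencies against peaks at the table's
two-decimal printing precision, the convention such tables use.

```{r perf}
perfReport()
```

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their parameters and seed.
`genEqualLengthDb()` emulates the equal-length benchmark databases (lengths
128..2048) at any scale. `genDistributedDb()` emulates real-database length
statistics with a log-normal (sdlog fixed at 1, a typical right-skew for
protein lengths) whose meanlog is solved numerically so the *capped* mean
matches the target; defaults are mean 361 and cap 35,213, the published
statistics of a curated protein database. Residues are drawn i.i.d. from
BLOSUM62 background frequencies (more realistic bin occupancy than uniform;
a uniform mode is retained for worst-case tests). What this does not
emulate: homology structure, repeats and low-complexity regions, and real
header taxonomies — so passing tests demonstrate algorithmic correctness
and determinism on realistic length/composition profiles, not retrieval
quality on biological data. Real FASTA databases are supported as input but
not required by any test.

## Problem sizes and numerical choices

Test and demonstration sizes are chosen for seconds-scale runs on one CPU:
the randomized oracle-equivalence suite covers 2,000+ pairs across all 20
$(p, k)$ shapes with queries up to length 100 and subjects up to three tile
stages; pipeline determinism uses a 1,000-sequence length-distributed
database (cap 4,000, long bin populated) with a length-100 query across
worker counts 1, 2, 4 and 8. Scores are integers throughout; all engine
comparisons are exact (`identical`), with no floating-point tolerances
anywhere in the alignment path. The model's TCUPS endpoints are compared at
the precision they are conventionally printed (two decimals).

## Known limitations

* The emulation is deterministic and single-threaded; it models the
  *algorithmic contract* of a lane-parallel kernel (lockstep schedule,
  exchange payloads, precision behaviour), not timing, occupancy, memory
  coalescing or divergence.
* `fp16emu` is a range model, not a bit-accurate half-float simulation (see
  above for why this is unobservable past the recompute).
* E-values/bit scores, traceback, and heuristic prefilters are out of
  scope; scores are raw Smith-Waterman integers.
* The on-disk database format is this package's own; it is not
  interchangeable with any external tool's format.
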