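---
title: "Recalibrating BLAST e-values across growing and partitioned databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating BLAST e-values across growing and partitioned databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incblast)
```

## The problem

The expect value attached to a local-alignment hit is the expected number of
chance alignments of at least that score in a search of a given query against
a given database. It scales with the size of the database, so the same
alignment is reported with a different e-value every time the database grows.
Two practical consequences follow for any long-running annotation project:

* **Temporal**: a search run months ago against `nt` or `nr` cannot simply be
  topped up with a search of the newly added sequences — the old e-values
  were computed against the smaller database and no longer mean what they
  say.
* **Spatial**: searches run independently against disjoint taxon-specific
  databases cannot be concatenated into "the result against the union" —
  each part's e-values refer to that part's size only.

Rerunning everything against the full updated database wastes the work
already done: if the database grew by a fraction $\delta$, a full rerun
costs $(1+\delta)$ units of search where only $\delta$ units are new, so an
incremental strategy is projected to be $(1+\delta)/\delta$ times faster
(`projected_speedup()`). The smaller the growth step, the larger the saving —
10% growth projects an 11-fold speedup.

This package implements the statistics that make the incremental strategy
exact: it recalibrates stored per-part e-values to the union database and
merges per-part results into a single result ranked as a from-scratch search
of the union would rank it. The search itself is delegated to a pluggable
executor (the NCBI binaries, or a deterministic mock for testing); none of
the alignment computation is redone.

## Statistics

BLAST programs fall into two statistical families, and the two families
recalibrate differently.

### Karlin–Altschul programs (`blastn`, `tblastx`)

The e-value of an alignment with raw score $S$ is

$$E = K \, m' n' \, e^{-\lambda S}, \qquad m' = m - \ell,\; n' = n - N\ell,$$

where $m$ is the query length, $n$ the total database length in residues,
$N$ the number of database sequences, and $\lambda, K$ the scoring-system
parameters. The *length adjustment* $\ell$ corrects for edge effects and
solves the fixed point

$$\ell = \frac{\alpha}{\lambda}\,\ln\!\big(K (m-\ell)(n-N\ell)\big) + \beta.$$

`length_adjustment()` iterates this map (at most 20 rounds, stopping when
successive iterates differ by less than one) and then polishes to the exact
integer; the returned value is the largest integer $\ell$ with
$\ell \le f(\ell)$, clamped so $m-\ell \ge 1$ and $n - N\ell \ge 1$. These
integer semantics were validated against the `Statistics_hsp-len` values
reported by NCBI BLAST+ 2.17 across database sizes, query lengths and
scoring schemes, and against an exhaustive integer scan
(`oracle_length_adjustment()`) on randomized instances.

Because $E$ is an explicit function of the raw score, recalibration to a
union database simply re-solves $\ell$ for $(m, n_{total}, N_{total})$ and
re-evaluates $E$ from each stored raw score (`evalue_from_score()`). An
equivalent additive form
$E_{total} = E_{part} + K e^{-\lambda S}(D_{total} - D_{part})$ over
effective search spaces $D = m'n'$ is provided as `correct_evalue_ka()` and
cross-checked against the recompute path in the test suite; the recompute
path is the default because it needs fewer operations and no stored
$D_{part}$.

### Finite-size-correction programs (`blastp`, `blastx`, `tblastn`)

The protein-level programs use Spouge's finite-size correction, in which the
edge-effect term ("area") depends only on the query and the scoring system,
not on the database length, and the e-value carries an explicit database
scale factor. Under a change of actual database length the entire correction
cancels in the ratio, leaving

$$\ln E_{total} = \ln E_{part} + \ln n_{total} - \ln n_{part},$$

exact in log space (`rescale_evalue_spouge()`). Nothing about the
finite-size correction itself ever needs to be computed — deliberately out
of scope here — because only the ratio survives.

### Log-space storage and the zero guard

E-values are stored exclusively as natural logs (`blast_evalue`); linear
values are produced only at serialization. This matters because upstream
tools round e-values below roughly $e^{-180}$ to `0.0` in their output,
destroying the value. A parsed `0` is therefore flagged `zero_rounded`:
rescaling such a value is refused (`rescale_evalue_spouge()` raises a typed
error directing to score-based recomputation), and recalibration regenerates
it from its raw score as $K \cdot D_{part} \cdot e^{-\lambda S}$ on the part
search space before applying the ratio. On the output side the writers
render tiny values by mantissa/exponent decomposition of the log, so nothing
this package writes ever collapses to `0` — including values far below the
double underflow range.

## Parameter provenance

$\lambda$, $K$ and $H$ travel inside every XML result's statistics block and
are taken from there. $\alpha$ and $\beta$ are serialized by no output
format, so they come from a bundled lookup table
(`inst/extdata/karlin_params.tsv`, user-overridable) keyed by program and
scoring scheme. The table entries were fitted against the installed NCBI
BLAST+ 2.17 binaries: for each scheme, blastn was run at five database sizes
and five query lengths, and $(\alpha,\beta)$ chosen to reproduce every
reported length adjustment exactly under the integer rule above. The fits
land on crisp values (for example $\alpha=1.5,\ \beta=-2$ for the megablast
1/−2 scheme; $\alpha=0.8,\ \beta=-2$ for the blastn default 2/−3 with gap
costs 5/2). Schemes missing from the table fall back, with a warning, to the
ungapped convention $\alpha = \lambda/H,\ \beta = 0$ — the same convention
NCBI applies to non-tabulated nucleotide gap costs, verified here for two
such schemes.

## Merging

`merge_results()` recalibrates every part against the same union database
and then performs one k-way merge — never a pairwise cascade of corrections —
so association order cannot affect the outcome. Hits are ranked by ascending
e-value with ties broken by descending raw score and then lexicographic
subject id. Tie detection uses `log E` rounded to six decimals: different
but mathematically equivalent computation routes (ratio rescaling versus
direct evaluation, or a serialization round trip) can differ by ~1e−12 in
the log, while distinct raw scores are separated by at least $\lambda$
(≥ 0.25 for every supported scheme), so the quantum can group only genuine
ties and never reorders genuinely different e-values.

The merged result retains twice the search's `max_target_seqs`. Retaining
only `max_target_seqs` would discard information: because each part was
searched and truncated independently, the merged pool legitimately contains
more strong candidates than any single truncated search reports, and the
upstream tools' known bias toward *first*-found rather than *best* hits
makes the extra pool valuable. Writers expose `ncbi_compatible = TRUE` to
emit only `max_target_seqs` hits when drop-in compatibility matters.

Duplicate subjects across supposedly disjoint parts indicate an overlap the
statistics do not model; the better hit is kept and a warning raised, never
a silent combination.

## Incremental orchestration

`incremental_search()` keys stored searches by (content digest of the query
set, logical database id, program, parameter digest). The query digest is
order-insensitive over (id, sequence) pairs, so a reformatted but identical
FASTA matches; changed search parameters are simply a different record. The
record store is a single JSON file holding metadata and result paths only —
never sequence data — and keeps one record per key, so it does not grow with
the database.

A repeat search against an unchanged database returns the stored result
without invoking the executor. Against a grown database, the volume-file
lists of the stored and present snapshots are differenced
(`compute_delta()`; sizes subtract exactly), the executor runs on the delta
volumes only — for the NCBI adapter through a standard `.nal`/`.pal` alias
file whose `DBLIST` enumerates the delta volumes (`write_alias()`, byte-stable
output) — and the stored and delta results are recalibrated and merged. A
database that *shrank* is a hard error resolved by a full re-search:
correction to a smaller search space is undefined in both families.

`partition_queries()` covers the complementary workload-splitting task:
queries are shuffled under a seed and greedily assigned to the partition
with the smallest running residue total, which bounds every partition within
one maximum query length of the mean — markedly better than count-balanced
splitting under heavy-tailed length distributions.

## The synthetic-data generator, and what passing tests mean

Real validation of this method was done upstream against live NCBI
databases; at desk scale the package ships a generator
(`generate_scenario()`) that emulates the *structure* of those experiments:

* database timelines (strictly nested snapshots) and disjoint partitions;
* a deterministic score model — the score of a (query, subject) pair is a
  seeded hash, identical however the database is partitioned — which is
  exactly the property that makes split-versus-whole comparisons meaningful;
* result files whose statistics blocks are internally consistent, computed
  by brute-force oracles (exhaustive-scan length adjustment, direct formula
  evaluation) independent of the production solver;
* optional emulation of upstream zero-rounding in part results, with the
  reference kept at full precision so corrections remain verifiable.

Defaults are desk scale — a few queries of 200–800 residues, volumes of
6–12 subjects of 0.3–3 kb, scores uniform on [30, 150] with hit probability
0.6 — chosen so that scenario suites run in seconds while still producing
e-values spanning ~40 orders of magnitude. Protein-family scenarios model
the finite-size correction through its surviving ratio only: e-values are
proportional to the database length and the statistics block's `eff_space`
records the part search space, which is precisely the information the
recalibration path consumes.

The generator deliberately does **not** simulate: alignment content
(alignment strings are schematic, since no operation consumes them);
BLAST's seed-and-extend heuristic and its context-dependent score choices;
sum statistics for linked HSPs; compositional adjustment; or biological
sequence evolution. Consequently a passing suite demonstrates that
recalibration and merging are *mathematically* faithful — hit-for-hit,
order-for-order, e-values to 1e−10 relative — under the stated statistical
models, not that a real heuristic search of the parts finds the same
alignments as a search of the whole. The bundled integration test against
the installed NCBI binaries probes that gap directly: hit sets and ranking
agree, and most e-values match to serialization precision. The residual
differences are bounded by one score unit of log e-value and originate
upstream — BLAST occasionally prints an e-value consistent with a score one
unit below the raw score it prints alongside it (its preliminary-stage score
can differ from the final traceback's), in which case the value recomputed
here from the printed score is the formula-consistent one. For the same reason the upstream
observation that merging over parts surfaces better-scoring hits missed by
single truncated searches is demonstrated here only as a mechanism (the
merged pool retains 2× `max_target_seqs`), not as a reproduced percentage.

## Numerical and design choices

* **Truncation, not rounding, for growth percentages.**
  `growth_fraction()` floors to one decimal, matching the convention of the
  reported database-growth figures it reproduces (e.g. 44.5 → 62.7 units is
  40.8%, although the unrounded value is 40.899…%).
* **Ranking tie quantum** of 1e−6 in log e-value, as motivated above.
* **Solver degenerate inputs**: a query of length 1 yields $\ell = 0$ with
  $m' = 1$ (clamping rule) rather than an error; nonpositive $m$, $n$, $N$
  raise typed domain errors naming the violated bound.
* **Coordinates are never re-based**: 1-based inclusive, minus-strand
  conventions untouched, so round trips are bit-exact.
* **Tabular dialect**: the conventional 12 columns extended with raw score
  and query/subject lengths; the 6th column carries total gaps (declared in
  the `outfmt 7` header) because the model tracks the XML `Hsp_gaps`
  quantity and alignment strings are optional. Standard 12-column input
  parses, but lacks raw scores, so Karlin–Altschul recalibration of it fails
  with a capability error rather than a wrong answer.
* **Problem sizes in the shipped suites**: scenario fidelity sweeps use 50
  seeded scenarios (2–4 snapshots temporal, 2–7 parts spatial, both
  families, 3 queries, 4–8 subjects per volume); oracle equivalence uses
  1000 random instances with $m \le 10^3$, $n \le 10^7$, $N \le 10^3$;
  round trips use 200 random results per dialect. These sizes exercise every
  code path while keeping the default test run within a couple of minutes on
  one CPU.

## Limitations

* Statistics blocks (or explicit part-database metadata) are required for
  recalibration; bare 12-column tabular input can be merged only for the
  protein family if sizes are supplied, and not at all for the
  Karlin–Altschul family (no raw scores).
* `max_target_seqs` is not representable in the NCBI XML DTD, so it lives in
  the in-memory parameters (default 500) rather than the serialized file.
* The package corrects statistics; it inherits whatever alignments the
  executor found. If the upstream heuristic misses an alignment in a small
  delta database that it would have found in the whole database (or vice
  versa), no statistical correction can restore it.
* Sum statistics for linked ungapped HSPs are not modelled; per-HSP
  e-values are assumed, as is the case for all gapped searches.
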