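# incblast

Incremental local-alignment searching for R: recalibrate the e-values of
stored NCBI BLAST results when the reference database grows or is searched in
disjoint partitions, and merge per-part results into a single result
equivalent to a from-scratch search of the combined database — without
rerunning the search on sequences that were already searched.

## Who this is for

Annotation and re-annotation projects that BLAST large query sets against
`nt`/`nr`-scale databases repeatedly over months, and taxon-centric projects
that search many small databases and need results ranked against their
union. In both settings the expensive part — the alignment search — has
already been paid for on most of the database; only the statistics are
stale. For a database that grew by a fraction δ, searching only the new
sequences and correcting the statistics is projected to be **(1 + δ)/δ
times faster** than a full rerun (10% growth ⇒ 11×).

## The statistics at the core

BLAST e-values depend on database size through one of two models:

* **Karlin–Altschul** (`blastn`, `tblastx`):
  `E = K·m′·n′·exp(−λS)` with `m′ = m − ℓ`, `n′ = n − Nℓ`, where the length
  adjustment ℓ solves the fixed point
  `ℓ = (α/λ)·ln(K(m−ℓ)(n−Nℓ)) + β`. Recalibration re-solves ℓ for the union
  database and recomputes every e-value from its stored raw score. The
  integer semantics of the solver (largest ℓ with ℓ ≤ f(ℓ)) reproduce the
  length adjustments reported by NCBI BLAST+ exactly; α/β come from a
  bundled table validated against the installed binaries.

* **Finite-size correction / Spouge** (`blastp`, `blastx`, `tblastn`): the
  edge correction depends only on the query and scoring system, so e-values
  rescale by the ratio of actual database lengths:
  `ln E_total = ln E_part + ln n_total − ln n_part`, exact in log space.

All e-values live on the natural-log scale internally. Inputs that upstream
tools rounded to `0.0` (anything below ~e⁻¹⁸⁰) are flagged and regenerated
from their raw scores — never rescaled — and nothing this package writes
ever serializes as `0`.

Merging recalibrates every part against the same union database, pools the
hits (ascending e-value, ties by descending score then subject id), and
retains `2 × max_target_seqs` so that strong candidates surfaced by the
per-part searches are not lost to truncation.

## Worked example

A toy growing nucleotide database: snapshot 1 is searched and stored; later
the database gains a volume, only the delta is "searched", and the stored
result is recalibrated and merged.

```r
library(incblast)

sc <- generate_scenario(scenario_spec(seed = 43, type = "temporal", n_parts = 2))
sc$profiles[[1]]
#> <db_profile> 'toy_nt' @t0: n=16,371 residues, N=10 sequences, 1 volume(s) [nucleotide]
sc$profiles[[2]]
#> <db_profile> 'toy_nt' @t1: n=33,753 residues, N=18 sequences, 2 volume(s) [nucleotide]

compute_delta(sc$profiles[[1]], sc$profiles[[2]])
#> <delta_spec> +1 volume(s), delta_n=17,382, delta_N=8
growth_fraction(sc$profiles[[1]]$n, sc$profiles[[2]]$n)   # percent growth
#> [1] 106.1
projected_speedup(1.061)                                  # vs a full rerun
#> [1] 1.942507

old_result   <- parse_result(sc$part_paths[1], "xml")[[1]]
delta_result <- parse_result(sc$part_paths[2], "xml")[[1]]
merged <- merge_results(list(old_result, delta_result),
                        union_db = sc$profiles[[2]])
merged
#> <search_result> blastn: query 'query_01' (m=243) vs db 'toy_nt' (n=33753, N=18); 9 hit(s)

# identical to a from-scratch search of the grown database:
reference <- parse_result(sc$reference_paths[2], "xml")[[1]]
compare_results(merged, reference, rel_tol = 1e-10)
#> <fidelity_report> hit match 100.0%, e-value match 100.0% (rel tol 1e-10),
#>   order agreement 100.0% [9 vs 9 hits, 9 shared]
```

The e-value of the best stored hit moves exactly as the larger search space
dictates — here from `3.45e-41` against snapshot 1 to `7.08e-41` against the
grown database — while its raw and bit scores are untouched.

The growth here is deliberately large for a two-snapshot toy; real update
cycles see small δ, where the projected speedup is largest.

For end-to-end orchestration (record store, delta databases, executors) see
`?incremental_search`; for the statistics, `?length_adjustment`,
`?evalue_from_score` and `?rescale_evalue_spouge`; for the science and the
design decisions, the vignette in `vignettes/evalue-recalibration.Rmd`. A
thin command-line front end over the same functions ships in
`inst/cli/incblast.R` (subcommands `merge`, `delta`, `record`, `search`).

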