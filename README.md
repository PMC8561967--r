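# capss

Profiling and genome-anchoring of BAC end sequences from pooled shotgun
sequencing of a clone array.

## The problem

A BAC library stores a genome as tens of thousands of large (50–300 kb)
inserts, one clone per well of 384-well plates. The library becomes a
physical map — usable for gap filling, FISH probes, or targeted
re-sequencing — only once each clone's position on a reference genome is
known, and Sanger-sequencing two ends per clone does not scale. Clone-array
pooled shotgun sequencing (CAPSS) solves this combinatorially: plates are
arranged in a grid (the *superpool*, canonically 24 plates in a 6 × 4 grid
of 16 × 24 wells), each row of wells across a plate-grid row is pooled and
each column likewise, giving `6×16 = 96` row pools and `4×24 = 96` column
pools (192 secondary pools, 9216 wells, 96 clones per pool). Every well is
the unique intersection of one row pool and one column pool, so an insert
end sequence recovered from exactly one pool of each axis identifies one
well:

```
well(row_pool r, col_pool c)  =  plate(⌊r/16⌋·4 + ⌊c/24⌋), well_row r mod 16, well_col c mod 24
```

This package is for people building or exploiting BAC physical maps: it
implements the whole computational pipeline — demultiplexing indexed pool
reads, recovering vector-junction end sequences (every trimmed end starts
with the HindIII site `AAGCTT`), deconvolving them to wells, anchoring
clones on a genome under a strict `identity ≥ 0.99 ∧ query-coverage ≥ 0.99`
alignment contract with paired placements (opposite strands, inward-facing,
span < 250 kb), organelle screening, sorted GFF3 output, and gap-coverage
accounting — plus a full simulator (genome, HindIII-bounded clone array,
indexed paired-end pool reads with errors and host contamination, and
ground-truth tables), so every stage is testable against known truth.

## Worked example

A six-well superpool end to end (about half a minute):

```r
library(capss)

cfg <- capss_config("toy", seed = 42,
                    plate_grid_rows = 1, plate_grid_cols = 1,
                    well_rows = 2, well_cols = 3,
                    chrom_length = 1e5, n_gaps = 1, gap_length = 300,
                    insert_mean = 3000, insert_sd = 800,
                    insert_min = 1000, insert_max = 5000,
                    host_length = 2e4)
run <- run_pipeline(cfg, outdir = "example_run")
print(run)
#> CAPSS pipeline run (preset toy, seed 42)
#> Superpool layout: 1 plates (1x1 grid) of 2x3 wells
#>   2 row pools + 3 column pools = 5 secondary pools; 6 wells
#>   clones simulated: 6
#>   short BESs: 23; long BESs: 32
#>   SHORT assignment: 5 wells with forward, 6 with reverse, 5 paired
#>   LONG assignment: 6 wells with forward, 6 with reverse, 6 paired
#>   final placements: 6 (PAIRED 6)
#>   gaps covered: 0 of 1
#>   paired insert size: mean 3353 bp (n = 6)

evaluate_against_truth(run)$placement_rate
#> [1] 1
```

Reading the output: the simulator put one HindIII-bounded clone in each of
the 6 wells and sequenced the 5 secondary pools; the short pathway
recovered 23 junction-read consensus end sequences and the long pathway 32
trimmed contig ends; assignment put a forward and a reverse end sequence
on every well (the short pathway missed one forward, which the long
pathway supplied); genome mapping paired all 6 clones (both ends on one
chromosome, opposite strands facing inward), and every placed interval
equals the simulated clone's true interval. `example_run/` holds every
intermediate artifact in plain formats (FASTQ, FASTA, TSV, GFF3, BED).

The shipped presets are `"toy"` (96 clones on a 500 kb genome, the
configuration the test suite exercises end to end) and `"production"` (the
24-plate production geometry with 123.48 kb mean inserts). Individual
stages are exported (`demultiplex()`, `extract_short_bes()`,
`assemble_pool()`, `match_pools()`, `align_bes()`, `pair_and_place()`,
`integrate_sources()`, `find_gaps()`, …) and compose on plain tables and
named sequence vectors; `inst/scripts/capss.R` is a command-line wrapper
over `run_pipeline()`.

## See also

The methods vignette (`vignettes/capss-methods.Rmd`) describes the pooling
model, both end-sequence pathways, the assignment conflict policies, the
alignment and pairing contracts, every tunable threshold, and what the
simulator does and does not emulate.
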