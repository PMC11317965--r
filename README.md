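# doublebox

Region calling and double DnaA box motif analysis for bacterial
ChIP-seq data.

## The problem

DnaA, the bacterial replication initiator, binds 9 bp DNA sites called
DnaA boxes (consensus `TTATCCACA`). Genome-wide mapping of *E. coli*
DnaA binding shows that the single 9-mer is a poor predictor of in vivo
binding: most perfect consensus boxes in the genome are unbound, while
nearly every bound region carries a **double DnaA box** — two 9-mer
boxes whose cores sit 2 or 3 bp apart, the footprint expected for a
DnaA dimer. `doublebox` implements the analysis that supports this
model, for anyone who wants to call protein-bound regions from
signal/control coverage and compare the predictive power of single-site
versus spaced-pair motif models:

* **Region calling** — peaks < 100 bp apart merge into regions; each
  region is scored by *coverage relative to control* (mean normalized
  signal over a 201 bp window around the region centre, divided by the
  control mean plus a pseudocount); regions with ratio < 3 are dropped.
* **Motif modelling** — a width-11 single-box PWM (one flank column per
  side of the 9-mer core), built by a seeded EM finder or from a
  user-supplied alignment, with column probabilities
  `(count + 0.1·bg) / (n + 0.1)`. Double-box PWMs are composed by
  tandem concatenation (cores 2 bp apart) or concatenation with one
  background column inserted (3 bp apart).
* **Scanning** — both strands, log-odds score
  `Σᵢ log2(pᵢ(base)/bg(base))` in bits, with exact p-values from a
  dynamic program over the discretized null score distribution
  (0.001-bit bins); hits reported at p ≤ 1e-4.
* **Recovery analysis** — hits ranked by score; each bound region keeps
  its best-ranked hit within 100 bp of the region centre; the
  cumulative recovery curve (fraction of regions recovered at each
  rank) compares motif models.

A synthetic-data module plants single and double boxes of known
spacing, mismatch load, and binding strength in a random genome and
simulates replicate negative-binomial coverage with Gaussian enrichment
bumps, so the entire pipeline is testable against ground truth with no
downloads.

## Worked example

The bundled table of 16 experimentally mapped DnaA-bound regions
carries the annotated double box at each locus. The *purH* upstream
region illustrates the pattern — a degenerate upstream box and a
perfect downstream box, 3 bp apart:

```r
library(doublebox)
tab <- bound_regions_table()
pb  <- parse_double_box(tab$double_box[tab$locus == "purH"])
count_consensus_matches(pb$upstream)    # 7   (TTACGCACA: 7/9 matches)
count_consensus_matches(pb$downstream)  # 9   (TTATCCACA: perfect)
pb$spacing                              # 3   (bp between the cores)
```

End to end on synthetic data with known truth:

```r
ds  <- simulate_dataset("small", seed = 7)   # 50 kb, 8 planted sites
res <- run_pipeline(ds$genome, ds$chip, ds$control)

res$retained[, c("centre", "n_peaks", "relative_coverage")]
#>   centre n_peaks relative_coverage
#> 1   5547       1          7.084946
#> 2  11122       1          7.308271
#> 3  22213       1          4.677695
#> 4  27773       1          4.798007

res$pwm_single
#> <pwm> single_box: width 11, IC 14.82 bits, consensus TGTGGATAACT
res$pwm_double$spacing_3
#> <pwm> single_box_double_s3: width 23, IC 29.63 bits,
#>       consensus TGTGGATAACTATGTGGATAACT (double box, core spacing 3 bp)
```

The four retained regions sit within 25 bp of the four strong planted
double boxes (true centres 5556, 11111, 22222, 27778; the weak single
boxes and the spacing-4 pair are correctly not called). The discovered
motif is the box in reverse-complement orientation (orientation is
arbitrary for a both-strand scanner). Ranking the double-box scan hits
recovers every region at the top of the list:

```r
res$assoc_double[, c("centre", "best_rank", "best_hit_motif")]
#>   centre best_rank       best_hit_motif
#> 1   5547         1 single_box_double_s2
#> 2  11122         2 single_box_double_s3
#> 3  22213         3 single_box_double_s3
#> 4  27773         4 single_box_double_s2

res$comparison$summary
#>   threshold rank_a rank_b
#> 1       0.5      2      2
#> 2       0.8      6      4
#> 3       1.0      6      4
```

`rank_a`/`rank_b` are the ranks at which the single-box and double-box
models reach each recovery fraction: the double-box model recovers all
regions by rank 4, the single-box model needs rank 6 (its top ranks are
spent on isolated boxes that are not bound).

## Package layout

| Area | Functions |
|---|---|
| I/O and sequences | `read_fasta`, `write_fasta`, `read_bedgraph`, `write_bedgraph`, `read_bed`, `write_bed`, `read_tsv`, `write_tsv`, `reverse_complement`, `extract_window` |
| Synthetic data | `plant_spec`, `generate_genome`, `generate_coverage`, `fixture_profile`, `simulate_dataset`, `make_fixture` |
| Region calling | `detect_peaks`, `aggregate_peaks`, `score_regions`, `filter_regions`, `call_regions` |
| Motif model | `count_consensus_matches`, `parse_double_box`, `build_pwm`, `discover_motif`, `make_double_pwm`, `read_meme`, `write_meme` |
| Scanning | `log_odds`, `score_distribution`, `score_pvalue`, `scan_genome`, `count_exact` |
| Recovery analysis | `rank_hits`, `associate_hits`, `recovery_curve`, `compare_motifs` |
| Pipeline | `pipeline_config`, `run_pipeline`, `bound_regions_table` |

See the vignette (`vignettes/double-dnaa-box-analysis.Rmd`) for the
model, parameter choices, and known limitations.
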