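# spotcall

Spot-based barcode decoding and automated quality control for
combinatorially barcoded FISH experiments (seqFISH-style).

In these assays a transcript molecule emits one fluorescent spot per
hybridization round, and the sequence of channels across rounds — the
barcode — identifies the gene through a codebook. `spotcall` links
detected spots across rounds into transcript calls with an exhaustive
decoder: for every spot it enumerates **all** one-spot-per-round
combinations within a search radius, scores each candidate by

    Score = Q + Sv * C
    Q  = log(1 + (R - QualSum))           # rewards bright member spots
    Sv = log(1 + var_x + var_y + var_z)   # rewards tight co-location

(`R` = rounds, `QualSum` = summed normalized intensities, `C = 2`),
selects each spot's best candidate, keeps barcodes supported by enough
of their own member spots, and resolves spot-sharing conflicts with a
greedy maximum-independent-set heuristic (highest-degree elimination,
ties removed by worse score). Decoding is staged over increasing radii,
with a high-precision *filter-first* pass before a high-recall
*decode-first* pass at each stage, and a `high`/`medium`/`low` mode knob
trading precision against recall. For codebooks whose entries all
differ in ≥ 2 rounds, an `error_rounds = 1` sweep recovers barcodes
missing one round, labeled by `rounds_used`.

The package also ships:

- the QC metric suite: off-target (blank) count thresholds via a 95%
  normal CI, per-cell false-positive rates, per-round/channel spot
  tallies with sd + skew, transcript source-spot tallies, a
  transcripts-per-cell low-count cutoff (`median − 1.5·IQR`), a Ripley's
  K Monte-Carlo test of complete spatial randomness, spots-per-barcode,
  and fraction of spots used;
- a synthetic-data generator with known ground truth (drift, dropout,
  background spots, clustering, grid cells) plus precision/recall
  scoring, and the multiplicative Gaussian noise model
  `out = in + n·in`, `n ~ N(1.5, var 3)`;
- smFISH threshold selection: elbow point of a spot-count-vs-threshold
  curve and its normalized Simpson AUC;
- a CLI and a multi-FOV pipeline with per-FOV and combined QC reports.

## Worked example

```r
library(spotcall)

cb  <- generate_codebook(20, n_rounds = 4, n_channels = 4,
                         min_hamming = 2, seed = 7)
cb  <- insert_off_target_barcodes(cb, 3, min_distance = 2, seed = 8)
sim <- simulate_spots(cb, 200, fov_dims = c(100, 100), drift_sigma = 1,
                      dropout_rate = 0.1, noise_rate = 0.005,
                      cell_grid = 4, seed = 11)
nrow(sim$spots)
#> [1] 924

tx <- decode(sim$spots, cb,
             decode_config(3, mode = "medium", error_rounds = 1))
head(tx[, c("target", "x", "y", "rounds_used", "is_off_target")], 4)
#>     target      x     y rounds_used is_off_target
#> 1 gene_018 30.760 29.76           4         FALSE
#> 2 gene_008 75.091 91.95           4         FALSE
#> 3 gene_016 89.203 18.75           4         FALSE
#> 4 gene_019  3.312 54.02           4         FALSE

ev <- evaluate_decoding(tx, sim$truth, match_radius = 3)
sprintf("precision = %.3f, recall = %.3f (%d calls, %d corrected)",
        ev$precision, ev$recall, ev$n_calls, ev$ec$n_calls)
#> [1] "precision = 0.958, recall = 0.805 (168 calls, 85 corrected)"

qc <- compute_qc(sim$spots, tx, cb, c(100, 100), seed = 12)
qc
#> QC report: 924 spots, 168 transcripts
#>   fraction of spots used: 0.6352814
#>   spots per barcode: 40.17391
qc$offtarget_threshold$threshold_nc_ec  # blank-count cutoff, NC + EC
#> [1] 0
qc$fpr_per_cell$mean_fpr
#> [1] 0
```

924 detected spots (720 true + background) yield 168 non-overlapping
transcript calls: 80.5% of the simulated transcripts are recovered at
95.8% precision, with 85 calls rescued by single-round error
correction. None of the three inserted blank barcodes was ever called,
so the proposed on-target count cutoff and the per-cell FPR are both 0.

## Command line

```sh
Rscript inst/cli/spotcall.R simulate --n-targets=20 --n-transcripts=200 \
    --min-hamming=2 --seed=5 --out-prefix=sim
Rscript inst/cli/spotcall.R decode --spots=sim_spots.csv \
    --codebook=sim_codebook.json --radius=2 --mode=medium --out=tx.csv
Rscript inst/cli/spotcall.R qc --spots=sim_spots.csv --transcripts=tx.csv \
    --codebook=sim_codebook.json --fov=100,100 --out=qc.yml
Rscript inst/cli/spotcall.R threshold --curve=curve.csv --out=thr.json
Rscript inst/cli/spotcall.R run --config=run.json   # full pipeline
```

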