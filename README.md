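# gminscan

Genome scans for **recent introgression** after secondary contact, for
population geneticists working with phased haplotype data from two
populations (resequenced inbred lines, phased diploids, or any haploid
genome panels).

## The statistic

When a haplotype has recently introgressed from one population into the
other, the *minimum* between-population distance in the window carrying
it collapses while the *mean* between-population distance — set by the
original divergence — stays large. The window statistic

```
G_min = min(d_XY) / mean(d_XY)
```

(over all n1 × n2 cross-population haplotype pairs, uncorrected
Hamming or p-distance) lies in [0, 1] and drops toward 0 exactly where
recent gene flow happened. It is computed alongside Hudson's

```
F_ST = 1 − (mean(d_XX) + mean(d_YY)) / (2 · mean(d_XY))
```

which needs allele *frequencies* to converge and therefore reacts far
more slowly to rare, recent introgression. Windows are flagged as
candidates when their Z-score (against the chromosome-wide mean) falls
below −1.645 (−2.326 and −3.090 as stricter levels) — an operational
screen, not a formal test.

The package contains four parts:

* **Haplotype statistics** — `hap_window()`, `distance_summary()`,
  `gmin()`, `fst_hudson()`: distances with pairwise deletion of missing
  data; undefined values (no between-population signal) are NA, never a
  made-up number.
* **Coalescent simulator** — `simulate_window()`, `simulate_batch()`,
  `simulate_stats()`: a two-population structured coalescent with
  Hudson-style recombination and an instantaneous migration **pulse**:
  at time `tau_m`, each lineage in the recipient population switches to
  the source population with probability `lambda` (binomial with
  expectation k·lambda over k resident lineages). Windows whose
  genealogy contains a migrant lineage are flagged — the ground truth
  for the classifier.
* **Sweep evaluation** — `run_grid()`, `sensitivity()`,
  `specificity()`, `variance_partition()`: per-cell Z-classification,
  sensitivity `|M∩Q|/|M|` and specificity `|M∩Q|/|Q|` at each
  threshold, and percent-of-variance attribution across model
  parameters on balanced grids.
* **Genome scanner** — `scan_fasta()`, `scan_vcf()`,
  `nj_window_tree()`: non-overlapping windows (50 kb default) over a
  multi-FASTA alignment or a phased VCF plus population map, a 25%
  minimum-callable filter, BED-convention coordinates, and per-window
  neighbor-joining trees for vetting candidates.

## Worked example

Simulate a secondary-contact parameter cell (recent small pulse:
divergence 0.5 N generations, pulse at 5% of that, lambda = 0.01) and
compare the two statistics:

```r
library(gminscan)
g <- param_grid(theta = 100, rho = 10, tau_d = 0.5,
                tau_m_fraction = 0.05, lam = 0.01)
run_grid(g, 1000, seed = 1)
#>   mean_gmin sd_gmin n_true_migrant phi_gmin_1.645 phi_fst_1.645
#> 1    0.3401  0.1534             97         0.4227        0.0103
#>   psi_gmin_1.645 psi_fst_1.645
#> 1         0.9762        0.1667
```

Of the 97 windows that truly contain a migrant genealogy, G_min flags
42% at Z < −1.645 and 98% of its calls are correct; F_ST finds 1% of
them with 17% precision.

Scan a synthetic chromosome with three migrant windows injected at
known coordinates:

```r
fx <- make_fixtures(tempfile(), seed = 7)   # 40 windows, 3 migrant
sc <- scan_fasta(fx$fasta, fx$pop_map,
                 scan_config(window_size = fx$window_size))
sc[which(sc$outlier_gmin), c("start", "end", "gmin", "z_gmin", "z_fst")]
#>     start    end       gmin    z_gmin      z_fst
#> 8  140000 160000 0.13600573 -1.957385  0.1569400
#> 21 400000 420000 0.03075504 -2.534570 -0.4111016
#> 34 660000 680000 0.06962576 -2.321406 -0.6988956
```

The three G_min outliers are exactly the three injected windows (the
truth sidecar `fx$truth` confirms the coordinates); their F_ST
Z-scores are unremarkable. `nj_window_tree()` on an outlier window
shows the introgressed haplotypes nesting inside the donor clade.

A thin command line wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","gminscan.R",package="gminscan"))')" \
    simulate --theta 100 --rho 10 --tau-d 0.5 --tau-m 0.025 \
    --lambda 0.01 --reps 1000 --seed 1 --out batch.tsv
```

Subcommands: `simulate`, `sweep` (YAML config, checkpointed/resumable),
`scan`, `trees`, `fixtures`. Exit codes: 0 ok, 2 usage, 3 data error,
4 internal guard.

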