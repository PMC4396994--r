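---
title: "Detecting recent introgression with G_min: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent introgression with G_min: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gminscan)
```

## The problem and the statistic

After secondary contact, two diverging populations may exchange genomic
material. A recently introgressed haplotype is nearly identical to
haplotypes in its donor population, so within the genomic window that
carries it, the *minimum* between-population sequence distance collapses
while the *mean* between-population distance — set by the original
divergence time — stays large. `gminscan` is built around the ratio that
captures this bimodality:

$$G_{\min} = \frac{\min(d_{XY})}{\bar d_{XY}},$$

where $d_{XY}$ is the Hamming (or p-) distance between one haplotype
from each population and $\bar d_{XY}$ averages over all
$n_1 \times n_2$ cross-population pairs. $G_{\min}$ lies in $[0, 1]$;
under strict isolation its lower bound is set by the divergence time,
while any recent gene-flow event drags it towards zero. It is compared
throughout with Hudson's
$F_{ST} = 1 - (\bar d_{XX} + \bar d_{YY}) / (2\,\bar d_{XY})$, the
classical differentiation index, which requires allele *frequencies* to
differ and therefore reacts only slowly to rare, recent introgression.

Windows are classified by their standardized deviation from the
chromosome- (or batch-) wide mean: a window is an outlier when its
Z-score falls below a fixed threshold (−1.645 by default; −2.326 and
−3.090 as stricter levels). This is deliberately *not* a formal test —
no null distribution is asserted and no multiple-testing correction is
applied; it is an operational screen whose sensitivity
$\varphi = |M \cap Q| / |M|$ and specificity
$\psi = |M \cap Q| / |Q|$ are measured by simulation, with $M$ the true
migrant windows and $Q$ the called outliers.

## The secondary-contact simulator

`simulate_window()` runs a two-population structured coalescent with
recombination backwards in time:

* Two populations of equal size $N$ merge into their common ancestor at
  divergence time $\tau_D$ (public API in units of $N$ generations).
* At the pulse time $\tau_M \le \tau_D$, every lineage then residing in
  the recipient population independently switches to the source
  population with probability $\lambda$ — with $k$ resident lineages
  the number moved is binomial with expectation $k\lambda$. This is the
  backward-time image of an instantaneous burst of unidirectional gene
  flow. There is no other migration.
* Recombination follows Hudson-style ancestral-recombination-graph
  semantics on a continuous $[0,1)$ window: a lineage recombines at
  rate $\rho$ times the span between its outermost ancestral
  endpoints, splitting at a uniform breakpoint. Intervals whose
  descendant set reaches the full sample have found their local MRCA
  and stop being tracked.
* Infinite-sites mutations are laid down as a Poisson process along
  branches and emitted as biallelic 0/1 columns in positional order
  (ancestral state 0). Hamming distances ignore polarity, so this
  representation is sufficient.

A window is flagged *migrant* iff at least one lineage moved at the
pulse. Only lineages carrying ancestral material are ever represented,
so the flag cannot be triggered by bookkeeping-only lineages; the flag
is per window, matching how whole simulated windows are classified as
true gene-flow windows. A pulse scheduled exactly at $\tau_D$ is a
no-op (the demes are one population from then on) and never sets the
flag.

### Time and rate conventions

The public API takes times in units of $N$ generations. Internally
times are divided by 4 (one internal unit = $4N$ generations) and a
pair of lineages within a deme coalesces at rate 2 per internal unit,
so the expected within-population pairwise coalescence time is 0.5
units = $2N$ generations. Mutations accrue at rate $\theta$ per unit
branch length per unit of ancestral span. These two conventions pin the
verifiable anchors

$$E[\pi] = \theta, \qquad E[S] = \theta \sum_{i=1}^{n-1} 1/i,$$

so a panmictic sample of 10 has an expected 28.3 segregating sites at
$\theta = 10$ and 424.3 at $\theta = 150$ — the frame of reference used
for interpreting $\theta$ as a window size. Both anchors are asserted
in the test suite against Monte-Carlo standard errors, and the
$\lambda = 0$ model is cross-validated against msprime (two-sample
Kolmogorov–Smirnov on the $S$ and $\pi$ distributions).

### Numerical guards

* Every window simulation carries an event ceiling of $10^7$; exceeding
  it raises an error naming the parameters and seed rather than
  silently truncating.
* Reproducibility: a batch derives one sub-seed per window index from
  the root seed, so batches are deterministic, order-independent, and a
  longer batch extends a shorter one without changing shared windows.

## Undefined values and conventions

* When $\bar d_{XY} = 0$ the window carries no between-population
  signal; $G_{\min}$ and $F_{ST}$ are NA (undefined), never an
  arbitrary number. Undefined windows are excluded from Z-score
  standardization and from both $M$ and $Q$.
* Within-population means use unordered pairs without self-comparison
  (the standard nucleotide-diversity convention). A single-member
  population has no observable within-population diversity: its within
  term contributes 0 to $F_{ST}$ and the summary flags it as NA. This
  convention is a documented choice — reporting $F_{ST}$ with
  $n_2 = 1$ is supported because the single-source-sequence sampling
  configuration is a first-class use case, even though a
  frequency-based index is conceptually strained there.
* Z-scores use the sample standard deviation ($n-1$) of the defined
  values in the batch. A batch with zero spread cannot be standardized;
  in a parameter sweep such a cell keeps its summary statistics but has
  NA sensitivity/specificity. (This genuinely occurs: at very small
  $\tau_D$ with moderate $\theta$, $G_{\min}$ can be identically 0
  across a whole batch because some cross-population pair is always
  identical.)
* Hudson's $F_{ST}$ as a ratio estimator carries a small negative
  $O(1/n)$ finite-sample bias under panmixia (about −0.01 at
  $n_1 = n_2 = 5$, independent of $\theta$); the expectations of the
  within- and between-distances themselves are exactly equal, so the
  bias is Jensen's inequality on the ratio, not an implementation
  artifact. The panmixia test therefore uses a small absolute band
  rather than the Monte-Carlo standard error alone.

## Parameter sweeps and variance partitioning

`run_grid()` crosses the model parameters, simulates a batch per cell,
standardizes within the cell (the analogue of "genome-wide" inside one
simulated genome), and reports per-threshold $\varphi$ and $\psi$ for
both statistics. Cells are checkpointed so interrupted sweeps resume.

`variance_partition()` quantifies how much of the simulated variance
each parameter explains, as percent of total sum of squares from a
least-squares ANOVA on a balanced product grid, where the partition is
orthogonal and therefore order-invariant (asserted by refitting with
permuted term order). Two covariate classes are offered, and the choice
matters:

* `covariate_class = "numeric"` fits the parameters as linear
  covariates. A term's share is then the variance explained by the
  linear trend, and curvature — e.g. the saturating approach of
  $G_{\min}$ to unity with divergence time — remains in the residual
  together with the within-window coalescent noise. With per-window
  responses this is the reading consistent with reporting roughly half
  of the simulated variance for the divergence time and a large
  "coalescent processes" residual, and it is the default analysis for
  the isolation sweep in this package's own checks.
* `covariate_class = "factor"` (default for the generic function) fits
  every level freely; a single-parameter deterministic signal is then
  attributed 100% to that parameter, which is the natural reading for
  small designed tables.

For the statistic *means*, the response is the per-window value (the
residual absorbs coalescent noise); for their *SDs*, the response is
the per-cell standard deviation.

At the desk scale used in the test suite — 20 divergence times on
$[1/25, 8]$, $\theta \in \{10, 50, 150\}$, $\rho \in \{0, 10, 150\}$,
$n_2 \in \{1, 10\}$, 500 windows per cell — the divergence time is the
dominant term for both statistics (about 41% for $G_{\min}$ and 47%
for $F_{ST}$ under the numeric-linear reading). The full-scale grids
(5 mutation rates, 7 recombination rates, 200 divergence times,
$10^4$ windows per cell) refine these shares but change no ordering.

## The genome scanner

`scan_fasta()` / `scan_vcf()` tile a phased haplotype alignment into
non-overlapping windows (50 kb by default), compute the statistics in
p-distance mode with pairwise deletion, filter windows whose callable
fraction is below 0.25, standardize chromosome-wide over the surviving
defined windows and flag outliers. Conventions:

* Coordinates are 0-based half-open (BED) in every output; the last,
  short window of a chromosome is retained — telomeric regions are
  where new signal is most likely to appear — and is identifiable by
  `end - start < window_size`.
* FASTA mode: a site is callable for a sequence when it is an
  unambiguous base; the window's callable fraction is the mean over
  sequences of per-sequence callable fractions. This is a
  sequence-level proxy for read-level quality filters, which are out of
  scope: the scanner consumes already-called haplotypes.
* VCF mode: sites between variant records are materialized as
  monomorphic callable columns (a declared chromosome length is
  required), so p-distances are on the per-site scale; missing
  genotypes yield missing states at that site only; unphased diploid
  genotypes are rejected. Diploid samples contribute both haplotypes to
  their population; haploid genotypes (inbred-line data) contribute one
  row.
* p-distance with pairwise deletion is the scan default so that
  coverage differences cannot masquerade as low distances; count mode
  is available for complete-data sensitivity analysis.

`nj_window_tree()` builds the neighbor-joining tree of a window from
the uncorrected distance matrix (via `ape::nj`), for visual vetting of
candidates: a truly introgressed haplotype nests inside the donor
population's clade. Negative branch lengths, which NJ can produce, are
clamped to zero with the deficit transferred to the sister branch so
path lengths are preserved; the number of adjustments is recorded on
the returned tree. Ties in the join criterion are resolved by the
algorithm's scan order, which is deterministic given the input order.

## What the synthetic data does and does not emulate

`make_fixtures()` assembles a scan-ready chromosome from simulator
output: isolation-model background windows with a known subset replaced
by secondary-contact windows whose genealogy verifiably contains a
migrant lineage (rejection sampling on the migrant flag). Defaults
($\theta = 100$, $\rho = 10$, $\tau_D = 1$, $\tau_M = 0.05\,\tau_D$,
$\lambda = 0.01$, $n_1 = n_2 = 10$) describe a recent, limited pulse
after substantial divergence — the regime the ratio statistic is
designed for, with window-scale mutation and recombination inputs in
the mid-range of the simulation grids.

The generator emulates: window-scale variation in genealogies,
independent windows, complete phased haplotypes. It does not emulate:
sequencing error, missing data or coverage variation (add N's for
that), linkage between adjacent windows, population-size change,
selection, or continuous migration. Passing the end-to-end recovery
test therefore demonstrates that the scanner's statistics, filtering,
standardization and outlier logic are correct on clean data — not that
the method is robust to artifacts real resequencing data may carry.

## Problem sizes used in the checks

The package's own verification uses: $10^4$ windows for the
segregating-sites anchors; 5000 replicates for the msprime
cross-validation; 2000 windows per point for the divergence-response
properties; 2000 windows per cell on a $3\times3$
$(\lambda, \tau_M/\tau_D)$ grid for the sensitivity/specificity
comparison; 500 windows per cell on the 360-cell isolation grid for
variance partitioning; and a 40-window fixture chromosome with three
injected migrant windows for end-to-end recovery. These sizes were
chosen so each check resolves its effect well beyond its Monte-Carlo
error.

## Known limitations

* The expectation of $G_{\min}$ is provided only as a Monte-Carlo
  estimate (`expected_gmin_mc()`); no closed form is implemented, and
  none is attempted for the variance (the numerator and denominator are
  positively correlated).
* $G_{\min}$ loses sensitivity when gene flow is old
  ($\tau_M > \tau_D/2$) or massive (large $\lambda$ pulls the mean
  down toward the minimum); candidate windows should be vetted for
  unusually low absolute $\bar d_{XY}$.
* At $\theta \lesssim 10$ the statistic is downwardly biased: with few
  mutations the observed minimum may reflect a randomly favored pair
  rather than the truly most recent between-population coalescence.
* The model is two populations of constant equal size; no growth,
  bottlenecks, gene conversion, selection, or more than one pulse.

## A worked example

```{r example, eval = FALSE}
library(gminscan)

# a recent, limited pulse after substantial divergence
p <- demographic_params(theta = 100, rho = 10, tau_d = 0.5,
                        tau_m = 0.025, lam = 0.01, n1 = 10, n2 = 10)
st <- simulate_stats(p, 1000, seed = 1)
mean(st$migrant_flag)          # fraction of true migrant windows

g <- param_grid(theta = 100, rho = 10, tau_d = 0.5,
                tau_m_fraction = 0.05, lam = 0.01)
run_grid(g, 1000, seed = 1)[, c("phi_gmin_1.645", "phi_fst_1.645",
                                "psi_gmin_1.645", "psi_fst_1.645")]

# scan a fixture chromosome with known injected migrant windows
fx <- make_fixtures(tempfile(), seed = 7)
sc <- scan_fasta(fx$fasta, fx$pop_map,
                 scan_config(window_size = fx$window_size))
sc[which(sc$outlier_gmin), c("start", "end", "gmin", "z_gmin")]
```
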