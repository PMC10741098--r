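# polyratio

Are miRNA-targeted mRNAs held back on translationally less-active **light
polysomes**? Comparative polysome profiling of wild-type (WT) cells and an
isogenic miRNA-deficient mutant (MT, DICER1 knockout) can answer this, but
the natural per-gene statistic — the light-to-heavy polysome abundance
log-ratio `R = log2(A_light / A_heavy)` — is strongly confounded by ORF
length: long ORFs carry more ribosomes and sink into heavy polysomes
regardless of regulation, and heavily miRNA-targeted genes tend to have
long ORFs.

`polyratio` implements the full analysis for this design, for
transcriptomics researchers working with polysome-profiling RNA-seq:

* **Ratios** — per-gene light/heavy log2 ratios from four HTSeq-count
  tables (WT light/heavy, MT light/heavy), pseudocounted CPM, expression
  filter.
* **ORF-length adjustment** — a from-scratch local regression
  (`local_fit`: tricube weights, direct evaluation, validated against a
  brute-force weighted-least-squares oracle to ~1e-14) of `R` on
  log2 ORF length; the **residuals** are the adjusted ratios:
  `adj = R − R̂(log2 ORF)`.
* **Double adjustment** — `Δ = adj_WT − adj_MT`, cancelling
  miRNA-independent regulation shared by the isogenic lines.
* **Statistics** — targeted (>50 binding sites) vs untargeted (no site)
  Welch t and variance-ratio F tests; a 1000-sample resampling null for
  the targeted-group mean; binding-site-count trend tables and their
  linearity; mean ORF length per site count.
* **Enrichment** — standardized mean-rank gene-set enrichment of the
  double-adjusted ratio against GMT collections, with permutation
  p-values.
* **Synthetic data** — a negative-binomial generator with planted,
  recoverable effects (site-count effect present only in WT, lower MT
  dispersion, scale-free site counts coupled to ORF length), used to
  validate every stage.

Binding-site counts are the number of *distinct* miRNA families with
conserved 3′-UTR sites per gene, derivable from a TargetScan-style table
via `read_target_sites()` + `count_sites()`.

## Worked example

A full synthetic experiment at transcriptome scale, with the default
planted effect (`beta_mirna = 0.5` per unit log2(sites+1), WT noise sd
0.35 vs MT 0.2):

```r
library(polyratio)

cfg <- sim_config(n_genes = 12000, seed = 42)
exp1 <- simulate_experiment(cfg)

rt <- compute_ratios(exp1$counts, exp1$genes)   # raw log-ratios, CPM + filter
rt <- adjust_by_orf(rt)                         # LOESS residuals per line
rt <- double_adjust(rt)                         # adj_wt - adj_mt

compare_groups(rt$adj_wt, rt$site_count)
#> Targeted vs untargeted group comparison
#>   > 50 sites: n = 62, mean = 1.4828
#>   no site: n = 1644, mean = -1.0985
#>   Welch t-test: t = 28.672, p = 1.32e-38
#>   F-test (variance ratio 1.167): p = 0.36
```

Targeted genes sit 2.58 log2 units above untargeted genes after
adjustment. The same comparison on the *raw* ratio (`rt$raw_wt`) gives
p = 9.2e-34 — the ORF-length adjustment strictly sharpens the separation.
The resampling null shows the targeted-group mean is far outside anything
random sampling produces:

```r
sampling_null(rt$adj_wt, which(rt$site_count > 50), seed = 42)
#> Resampling null of the target-group mean
#>   1000 samples of size 62
#>   observed mean = 1.4828, max sample mean = 0.3650
#>   empirical p = 0.000999
```

And the double-adjusted ratio climbs almost perfectly linearly with
log2(sites + 1), recovering the planted effect size (part of the planted
0.5 is absorbed by the ORF fit because site count and ORF length are
coupled):

```r
tr <- trend_by_site_count(rt, "double_adj")
trend_linearity(tr[tr$site_count <= 20, ], weighting = "by_n")
#> $slope
#> [1] 0.4588467
#> $intercept
#> [1] -1.081092
#> $pearson_r
#> [1] 0.9965104
```

Real data enters through the readers: `read_counts()` (four two-column
HTSeq-count files), `read_target_sites()`/`count_sites()` (conserved-site
table to per-gene family counts), `read_gmt()` (MSigDB-style gene sets),
then the same pipeline. `run_pipeline()` chains every stage and writes
TSV/JSON outputs plus a provenance record; `inst/scripts/polyratio.R` is a
command-line wrapper with per-stage subcommands.

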