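# minepop

Population-genomic tools for asking whether derived populations that
colonized a patchy, hostile habitat — the motivating case is a coastal
plant that repeatedly invaded zinc-contaminated mine spoils — descend
from **one** colonization event or from **multiple independent** ones,
and whether their adaptation shows molecular parallelism.

The package bundles the full computational chain around that question:

* a forward-in-time diploid **Wright–Fisher colonization simulator**
  (compiled core) implementing a burn-in ancestral population,
  stepping-stone colonization of four coastal demes, and founding of
  four mine demes either independently from the matched coastal deme
  (*multiple origin*) or all from one randomly drawn coastal deme
  (*single origin*), with exact diffusion-scale rescaling
  (`rescale_Q` preserves 4Nμ, 4Nr, Nm, t/N);
* the **isolation-by-distance contrast**: per-replicate OLS fits of
  pairwise F<sub>ST</sub> on distance within each habitat class and a
  paired *t*-test of mine vs. coastal slopes and intercepts across
  replicates — the statistic that discriminates the two histories;
* core estimators: **Weir–Cockerham F<sub>ST</sub>** variance
  components (a, b, c; multilocus ratio of sums
  Σa / Σ(a+b+c)), per-variant-site nucleotide diversity
  π = (n/(n−1))·2p(1−p), windowed **Tajima's D** (20 kb bins),
  genotypic **LD pruning** (r² > 0.1 removed, MAF ≥ 0.05), haversine
  distances, Welch and paired *t*-tests;
* **f4 quartet tests**: f4 = mean over sites of
  (p<sub>A</sub>−p<sub>B</sub>)(p<sub>C</sub>−p<sub>D</sub>) for every
  population quartet and all three tree arrangements, weighted
  block-jackknife standard errors over 500-SNP blocks,
  z = f4/SE, mine/coast quartet-type classification (types 1–6) and
  the Dunn–Bonferroni threshold (z = 3.67 for 210 tests);
* an **F<sub>ST</sub>-outlier scan** per mine–coast pair (top-5%
  percentile, ties included), upset-style intersection counts across
  comparisons, and an **exact multi-set intersection test** (iterated
  hypergeometric compounding; reduces to Fisher's exact tail for two
  sets);
* a calibrated hierarchical **Balding–Nichols genotype generator**
  with planted selection outliers, admixture edges and known truth, so
  every stage is testable offline;
* VCF / popmap I/O and ggplot2 helpers (`plot_ibd()`,
  `plot_intersections()`, `autoplot()` methods), with broom-style
  `tidy()` / `glance()` methods on every result type.

## Worked example

Generate a synthetic eight-population dataset with 25 outlier SNPs
planted across all four mine–coast comparisons, then run the empirical
analyses:

```r
library(minepop)

planted <- tibble::tibble(comparisons = list(paste0("R", 1:4)),
                          n_snps = 25, effect = 1)
ds <- gen_dataset(generator_config(n_snps = 5000, n_scaffolds = 250,
                                   n_per_pop = 20, seed = 7,
                                   planted_outliers = planted))

glance(wc_fst(ds$gm, ds$pm, "R1-M", "R1-C"))
#> # A tibble: 1 × 4
#>   pop_a pop_b multilocus_fst n_sites_used
#> 1 R1-M  R1-C           0.356         4496

observed_ibd(ds$gm, ds$pm)$fits
#> # A tibble: 3 × 6
#>   pair_class        slope intercept     r2 n_pairs distance_metric
#> 1 coast-coast -0.0000266      0.256 0.951        6 km
#> 2 mine-coast   0.00000508     0.363 0.0417      16 km
#> 3 mine-mine   -0.00000819     0.467 0.0823       6 km

scan <- scan_all_pairs(ds$gm, ds$pm)
dplyr::arrange(scan$scaffold_tests, p)
#> # A tibble: 11 × 6
#>   subset      degree inclusive exclusive expected        p
#> 1 R1&R2&R3&R4      4        54        54     20.6 2.06e-17
#> 2 R2&R3&R4         3        67        13     37.4 1.84e-12
#> ...
```

Reading the output: the local mine–coast pair sits at multilocus
F<sub>ST</sub> ≈ 0.36 (the generator's calibration target); the class
fits show coastal populations following a clean distance trend
(r² = 0.95) while mine–mine differentiation is elevated overall
(higher intercept, 0.47 vs. 0.26); and the overlap scan finds the
four-way intersection of outlier scaffolds far larger than its
expectation under independence (54 observed vs. 20.6 expected,
exact p ≈ 2×10⁻¹⁷) — exactly the planted parallelism.

Simulating the two colonization histories and contrasting them:

```r
cfg <- sim_config(n_replicates = 100, rescale_Q = 10, seed = 1)
ctr <- scenario_contrast(run_experiment(cfg, "single_origin"))
glance(ctr)   # coastal slope > mine slope, paired p << 0.001
```

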