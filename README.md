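# volescape

Landscape genetics of pest vole demes in enclosed-field (bocage)
agricultural mosaics.

Fossorial water voles (*Arvicola scherman*) are grassland crop pests whose
outbreaks are regional in homogeneous farmland but may fragment into local
sub-populations where hedgerows, woodlots and crops interleave at a fine
grain. volescape is a complete, tested R toolchain for asking that question
with microsatellite data: it reads diploid genotypes grouped into
georeferenced demes together with a categorical land-cover raster, and
quantifies (i) within-deme diversity, (ii) between-deme differentiation,
(iii) landscape resistance between demes, and (iv) the association between
the two — isolation by distance (IBD), isolation by resistance (IBR) and
habitat suitability — plus clustering, hierarchical AMOVA, individual
spatial autocorrelation and first-generation migrant detection.

It is aimed at landscape geneticists and pest-management researchers who
want the full pipeline of the classical microsatellite toolbox (Genepop /
FSTAT / Structure / Arlequin / IBD / GenAlEx / GeneClass style analyses) as
one scriptable, seedable package with a built-in simulator for validation.

## The statistics at its core

* **Diversity**: Nei's unbiased H_E; hypergeometric rarefaction of allelic
  richness, A_R = Σ_a [1 − C(2n−N_a, g)/C(2n, g)], averaged over loci.
* **Differentiation**: Weir–Cockerham variance components; multilocus
  θ = Σa / Σ(a+b+c) with permutation p-values per deme pair and a
  bootstrap-over-loci CI overall; F_IS with within-deme allele permutation;
  exact (probability-ordering) Hardy–Weinberg tests; genotypic LD G-tests
  combined across demes by Fisher's method, feeding a locus filter.
* **Landscape model**: cost values per land-cover category (1 / 25 / 50 /
  1000 from suitable habitat to barriers), least-cost paths on the
  8-neighbour lattice with edge weight = step length × mean cell cost;
  effective distance (path length, km), resistance distance Σ m_i·CV_i over
  crossed patches (m_i in km), and a lens-buffer suitability statistic
  (SH/TL within the intersection of two discs, per km).
* **Structure**: no-admixture Gibbs clustering with ΔK model choice;
  three-level AMOVA (clusters / demes in clusters / within demes) under the
  infinite-alleles metric with level-specific permutation tests.
* **Association**: Mantel and residual-permutation partial Mantel tests on
  linearized θ/(1−θ) versus log10 landscape distances, reduced-major-axis
  regression, Smouse–Peakall multilocus autocorrelation in 100-m classes.
* **Migrants**: leave-one-out L_home likelihood with an exchangeable
  Monte-Carlo null (gene copies resampled without replacement from the
  deme).

A forward Wright–Fisher simulator (island / stepping-stone / cost-decay
migration on generated category mosaics, stepwise mutation) provides data
with known truth for every stage.

## Worked example

Simulate the study-shaped system — ten demes with the published sample
sizes and plot coordinates on a generated fine-grained mosaic — and run the
core analyses:

```r
library(volescape)

fx <- fixtureTable1(seed = 1)
fx$dataset
#> GenotypeDataset: 137 individuals, 10 demes, 11 loci
#>   missing calls: 0.0%
#>   demes: 1-Vegadali, 2-Ceceda, 3-Fresnadiello, 4-Poreño, 5-Serida, ...

diversityStats(fx$dataset, g = 22)[1:4, c("deme","N","NA_","AR","HO","HE","FIS")]
#>             deme  N  NA_   AR    HO    HE     FIS
#> 1     1-Vegadali 18 4.64 4.36 0.682 0.668 -0.0209
#> 2       2-Ceceda 14 4.64 4.42 0.649 0.681  0.0476
#> 3 3-Fresnadiello 14 4.36 4.16 0.578 0.619  0.0692
#> 4       4-Poreño 11 5.36 5.36 0.711 0.687 -0.0368

ov <- fstOverall(fx$dataset, n_boot = 1000, seed = 2)
sprintf("overall theta %.3f (95%% CI %.3f-%.3f)", ov$theta, ov$ci[1], ov$ci[2])
#> "overall theta 0.111 (95% CI 0.102-0.121)"

pw  <- fstMatrix(fx$dataset, n_perm = 199, seed = 3)
eu  <- distanceMatrix(fx$bundle, "euclidean")
lin <- linearizedFst(pw$theta)
logd <- log10(eu); diag(logd) <- 0
mt <- mantelTest(lin, logd, n_perm = 999, seed = 4)
sprintf("IBD Mantel: r = %.3f, one-sided p = %.3f", mt$r, mt$p)
#> "IBD Mantel: r = 0.230, one-sided p = 0.027"
```

Reading: A_R equals N_A for Poreño because its n = 11 sets the rarefaction
size (g = 22 gene copies) — the identity the rarefaction must satisfy at
the minimum sample. The overall θ of 0.111 with a tight bootstrap CI says
about 11% of allelic variance lies between demes, and the positive Mantel r
on log distance is the isolation-by-distance signal the cost-decay
simulation plants.

`runPipeline(runConfig(seed = 1))` runs all stages (filter → diversity →
θ → clustering → AMOVA → distances → Mantel suite → autocorrelation →
migrants) and writes one TSV per stage plus a JSON run report;
`inst/scripts/volescape-run.R` wraps it for the shell with a YAML config.

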