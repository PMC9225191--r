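---
title: "Models and methods behind volescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind volescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

volescape analyses diploid microsatellite genotypes sampled from discrete
demes — here, fossorial water voles (*Arvicola scherman*) trapped in apple
orchards scattered through an enclosed-field (bocage) agricultural mosaic —
and asks how the landscape between the demes shapes their genetic structure.
This vignette is the package's own account of the statistical machinery: the
estimators, the graph-based landscape model, the simulation engine used to
validate everything, and the numerical decisions taken where the design was
genuinely open.

## 1. Data model

A `GenotypeDataset` holds diploid, codominant multilocus genotypes.
Allele codes are kept verbatim as integers (microsatellite fragment sizes);
nothing is recoded at the I/O layer, so Genepop files written by the package
diff cleanly against their sources. A call is missing only when *both*
alleles carry the missing code; half-missing calls are rejected as malformed,
because fragment scoring yields both alleles or neither. Deme metadata
(planar UTM coordinates in metres, plot area, sampling date) come from a CSV
whose row order is authoritative for deme indexing; a Genepop file whose POP
sections disagree with it raises a named error rather than silently
reordering. Coordinates are treated as planar throughout — a single UTM zone
is assumed and no geodesy is attempted.

## 2. Diversity and differentiation

* **Expected heterozygosity** is Nei's unbiased estimator
  $\hat H_E = \frac{2n}{2n-1}\,(1-\sum_a p_a^2)$ per locus, averaged over
  loci; observed heterozygosity is the fraction of heterozygous non-missing
  calls.
* **Allelic richness** uses hypergeometric rarefaction to a fixed number of
  gene copies $g$:
  $A_R = \sum_a \left[1 - \binom{2n-N_a}{g}\big/\binom{2n}{g}\right]$,
  averaged over loci. By default $g$ is the smallest gene-copy count over
  demes and loci, which reproduces the identity $A_R = N_A$ for the deme at
  the minimum sample size — the same identity visible in the published
  per-deme table, implying the study rarefied to $g = 22$.
* **F-statistics** are Weir–Cockerham variance-component estimators.
  Multilocus $\theta$ is $\sum a / \sum(a+b+c)$ over alleles and loci — the
  ratio of summed components, not the mean of per-locus ratios, matching the
  behaviour of the classical F-statistics software. Negative estimates are
  reported as computed; truncating them at zero would bias the downstream
  Mantel regressions. Pairwise significance permutes individuals between
  the two demes; the overall confidence interval bootstraps loci.
  Within-deme $f$ ($F_{IS}$) uses the single-population variance components,
  with a two-sided permutation test that shuffles gene copies among a deme's
  individuals within each locus.
* **Hardy–Weinberg exact test**: the probability-ordering (conditional)
  exact test. All genotype tables compatible with the observed allele counts
  are enumerated when feasible and the p-value sums the probabilities of
  tables no more probable than the observed one; otherwise a Monte-Carlo
  version pairs the gene copies at random (add-one rule, seed mandatory).
  The switch uses a cheap product bound on the number of tables rather than
  a counting pass, so the decision itself is O(cells).
* **Linkage disequilibrium** is tested per deme on the genotype-by-genotype
  contingency table with a log-likelihood-ratio G statistic and a
  permutation p; demes are combined by Fisher's method (which reduces
  exactly to the per-deme p when only one deme is informative). The locus
  filter removes, for every pair with combined $p < 0.001$, the member with
  fewer distinct alleles (ties: the later locus), in one pass over pairs
  sorted by p — the rule the study applied when its two linked loci were
  resolved by dropping the less polymorphic one.

All permutation p-values use the add-one rule $(1+k)/(B+1)$ and can never be
zero.

## 3. The graph-based landscape model

Land cover is a categorical raster (nine categories; ESRI ASCII exchange
format) with a cost value per category: 1 for hay meadows, grasslands and
orchards; 25 for annual crops and shrubs; 50 for settlements and roads;
1000 for deciduous woodlots, eucalyptus plantations and water. Movement is
modelled on the 8-neighbour lattice; stepping between adjacent cells costs
the step length times the mean of the two cell cost values (length =
cell size, or cell size$\times\sqrt2$ diagonally). Least-cost paths are
shortest paths in this weighted graph (computed via igraph).

Three pairwise deme statistics derive from the path:

* **Effective distance** — the metric length of the least-cost path, in km;
  with an elevation model each step becomes the 3-D hypotenuse.
* **Resistance distance** — the path is segmented into maximal runs of
  constant category and $\sum_i m_i\,CV_i$ is returned with the run lengths
  $m_i$ *in kilometres*. The source material describes the lengths as
  metres, but the resistance values it reports (roughly 7–170 between demes
  1–20 km apart) are only attainable with kilometre lengths — metre lengths
  would put a floor of ~1000 under every pair. The kilometre reading is a
  deliberate, documented choice; the printed magnitudes reproduce under it.
  Each step's length is split half-and-half between its end cells, so the
  run decomposition equals a per-cell sum exactly.
* **Lens suitability** — around each deme of a pair a disc of radius equal
  to their separation is drawn; within the lens-shaped intersection the
  fraction of cell centres carrying suitable habitat (meadow, orchard,
  pasture) is the SH/TL ratio, and the statistic is (SH/TL)/distance in
  per-km units. This operationalises the ratio-of-optimal-habitat idea that
  links habitat density to connection probability.

Numerical details: grids store row 1 at the northern edge (file order) with
a lower-left georeferenced origin; deme locations snap to the nearest cell
centre, ties toward smaller indices. Exactly tied least-cost paths are
resolved by the graph library's deterministic search; the accumulated cost —
the quantity used downstream — is tie-free, and only the cell trace of a
tied path (hence, rarely, the resistance decomposition) can differ between
equally-cheap routes. Masked/NoData cost cells are rejected at load rather
than handled.

## 4. Clustering and AMOVA

Genetic clusters are fitted with a no-admixture Gibbs sampler on the mixture
model in which each cluster is at Hardy–Weinberg proportions with its own
allele frequencies: sweeps alternate Dirichlet(1 + counts) draws of cluster
frequencies with categorical draws of individual labels proportional to the
genotype likelihood. Assignment probabilities are conditional membership
probabilities averaged over post-burn-in sweeps, and the log model evidence
is the usual harmonic-style estimate mean(logL) − var(logL)/2. The
admixture and correlated-frequency options of the well-known Bayesian
clustering program are deliberately out of scope: every deme-level
deliverable (labels, membership matrix, AMOVA grouping) needs modal
assignments only. K is selected by the second-difference statistic
$\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)|\,/\,\mathrm{sd}\,L(K)$
over replicate runs. Label switching is resolved only at comparison time by
the best label permutation, never inside the sampler.

The three-level AMOVA partitions gene-copy variance under the
infinite-alleles metric (distance 0 between identical alleles, 1 otherwise)
into between clusters, between demes within clusters, and within demes,
using the classical unequal-size coefficients; components are computed per
locus (missing calls drop out per locus) and summed. Percentages retain
negative components, so the three levels always sum to 100%. Each fixation
index gets its own permutation scheme: individuals among demes within
clusters ($F_{SC}$), whole demes among clusters ($F_{CT}$), individuals
among all demes ($F_{ST}$). The published three-row AMOVA table this mirrors
evidently omitted its within-individual residual level; the package's
three-level gene-copy decomposition is self-consistent instead.

## 5. Mantel suite and spatial autocorrelation

Mantel r is the Pearson correlation of strict lower triangles with
simultaneous row/column permutation of one matrix; the p-value is one-sided
in the direction of the observed r (the convention of the classical
isolation-by-distance software), with a two-sided option. The partial
Mantel test computes the first-order partial correlation and permutes
residuals of the focal matrix on the conditioning matrix (the source
material does not name a variant; residual permutation is the default
here). "Least major axis" regression is read as reduced major axis:
slope $= \mathrm{sign}(r)\,s_y/s_x$ on the triangles, intercept through the
means, x log10-transformed for the landscape variables. Genetic distance is
linearized $\theta/(1-\theta)$ before all matrix tests, and the suitability
matrix is log-transformed like the other landscape variables.

Individual-level spatial autocorrelation uses the standard codominant
squared genotypic distance (half the squared Euclidean distance between
allele-count vectors: 0/1/2/3/4 per locus), summed over loci,
double-centred into a covariance matrix; the class statistic r relates
within-class covariance to the mean self-covariance of the participating
individuals. Distance classes are half-open [lower, upper) and 100 m wide
by default, so co-located same-deme individuals fall in the first class;
self-pairs are excluded; the final class absorbs the remainder of the data
span. The null band permutes genotypes among individuals (999 by default);
the per-class CI bootstraps pairs within the class (1000 by default). The
omnibus multi-class heterogeneity test reported alongside such analyses is
not implemented — the method behind the published overall p-value is not
identified in the source — and classes with fewer than two pairs return NA
with a warning.

## 6. Migrant detection

$L_{home}$ is the product over loci of Hardy–Weinberg genotype
probabilities under the individual's home-deme allele frequencies, reported
as $-\log_{10}$. Home frequencies are leave-one-out — the focal
individual's own copies are removed — which prevents self-assignment bias
in demes of 11–18 animals; alleles absent from the reference get frequency
0.01 (the conventional default). Significance is Monte-Carlo: for each deme
the package simulates genotypes by drawing, at every locus, two gene copies
*without replacement* from the deme's sampled copies and scoring them with
their own copies removed, exactly as observed members are scored. Given the
sample, a resident member's two copies are an exchangeable size-2 subset of
it, so observed and simulated scores are exchangeable under the null and
the flag rate is calibrated at the nominal level; drawing with replacement
(plug-in frequencies) breaks this exchangeability measurably. An individual
is flagged when its rank falls below the type-I level (0.01 by default).
Source attribution is descriptive only — the deme with the maximum plug-in
likelihood — with no test attached.

## 7. The synthetic-data engine

The generator exists so that every stage can be tested against known truth
without any downloads. It emulates the study conditions: ten demes of 11–18
individuals at the published plot coordinates, 11 loci, a nine-category
mosaic with 30% suitable habitat, and differentiation spanning roughly
0–0.3 with isolation by distance.

* **Landscape**: Poisson-seeded nearest-seed tessellation with intensity
  matched to a target patch diameter, seed categories drawn from the cover
  mixture. The default patch diameter is ~300 m (3–6 cells depending on
  resolution): the bocage grain, where single plots span 1–7.6 ha. This
  grain matters — with kilometre-scale patches the least-cost resistance
  between demes decorrelates from their separation and the simulated system
  loses its isolation-by-distance signal, which is not the regime the
  enclosed-field landscape represents.
* **Genotypes**: forward Wright–Fisher simulation, 2·N~e~ gene copies per
  deme per locus, migration by a deme-to-deme matrix, stepwise mutation
  (±1 repeat unit, rate 5·10⁻⁴ per copy per generation, fragment-size-like
  codes). Three migration models: island; linear stepping-stone; and cost
  decay, $m_{ij}\propto m_0 e^{-c\,d_{ij}}$ on the resistance distances of
  a landscape, rows rescaled so total emigration never exceeds $m_0$.
  Defaults $m_0 = 0.2$, $c = 0.1$ per resistance unit, $N_e = 150$, 100
  generations from a common ancestral pool: nearby demes then exchange
  $N_e m \approx 9$ migrants per generation (θ ≈ 0.02) while the most
  separated pairs are effectively drift-limited
  (θ ≈ 1 − e^{−t/2N_e} ≈ 0.28), spanning the intended range.
* **Truth values**: for the island model the recorded equilibrium
  expectation is $\theta = 1/(1 + 4N_e m\,d/(d-1))$. This comes from the
  structured coalescent for the simulator's migration scheme (emigration
  probability m, source uniform among the other demes): within-deme pairs
  coalesce in $2N_e d$ generations on average, between-deme pairs add
  $(d-1)/2m$, and θ contrasts the two. Note the single factor $d/(d-1)$ —
  the textbook finite-island correction with the squared factor describes a
  different parametrization and does not match what the Weir–Cockerham
  estimator measures here, as replicate simulations confirm.
* Sampling is allowed off equilibrium deliberately (the truth object records
  the generations run); the study system itself is a non-equilibrium
  metapopulation.

What the generator does **not** emulate: demographic cycles and outbreaks,
sex-biased dispersal, kin-structured trapping within plots, null alleles
and scoring error, and mutation-model misspecification. Tests passing on
synthetic data therefore validate the estimators and their calibration, not
these field complications.

## 8. Validation strategy and problem sizes

Published quantities recomputable from printed inputs (deme geometry from
the coordinate table, the rarefaction identity, pair counts) are asserted
directly. Study-scale results that depend on the deposited genotypes are
recomputed by `realDataReproduction()` when a local copy of the deposited
data is present. Everything else is covered by three substitute layers,
sized to run comfortably on one CPU:

1. *Oracle equivalence* — least-cost paths against a brute-force Dijkstra
   on 1000 random grids; AMOVA against an explicit pairwise
   sums-of-squares oracle; Mantel p against exhaustive enumeration of all
   24 relabellings of 4 demes; autocorrelation r against a literal
   transcription of the cross-product formula; θ against an independently
   coded nested-ANOVA route.
2. *Type-I calibration* — HWE, LD, Mantel, autocorrelation band escape and
   migrant flagging under null simulations (200–500 replicates each), all
   required to sit within three binomial standard errors of their nominal
   levels.
3. *Parameter recovery* — a two-island dataset at θ ≈ 0.2 (ΔK selects
   K = 2; ≥95% of individuals assigned to their island), island-model θ
   within 30% of the coalescent closed form over 20 replicates, significant
   positive Mantel IBD in ≥80% of 50 stepping-stone replicates, and a
   high-cost barrier raising across-barrier θ above within-side θ over 20
   replicates.

MCMC defaults are scaled for interactive use (a few hundred to a few
thousand sweeps in the tests; 20,000/5,000 as function defaults); the
half-million-sweep regime of the original analysis remains available
through the configuration.

## 9. Known limitations

* Resistance is evaluated along the least-cost path only; circuit-theory
  (commute-time) distances, which integrate over all paths, are out of
  scope.
* The no-admixture sampler gives modal assignments, not admixture fractions;
  Q-matrices for highly admixed individuals will look artificially crisp.
* The LD test conditions on genotype tables and loses power in tiny demes
  with many alleles (saturated tables); this mirrors its classical
  behaviour.
* Exactly tied least-cost paths are resolved by graph-library order, not
  the lexicographic rule; costs are unaffected.
* The Fisher combination of permutation p-values is slightly conservative
  because permutation p's are discrete.
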