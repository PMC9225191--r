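test_that("allele frequencies count gene copies and exclude missing", {
  g <- list(list(matrix(c(101, 101), 1, 2), matrix(c(101, 102), 1, 2)),
            list(matrix(c(NA_integer_, NA_integer_), 1, 2)))
  ds <- mkExplicit(g)
  af <- alleleFrequencies(ds, "demes")
  expect_equal(af$freq[[1]][[1]], c("101" = 0.75, "102" = 0.25))
  expect_equal(af$size[1, 1], 4)
  expect_equal(af$size[2, 1], 0)
  expect_length(af$freq[[2]][[1]], 0)
})

test_that("pooled frequencies equal the copy-weighted mean of deme frequencies", {
  ds <- mkDataset(n_demes = 3, n_ind = 5, n_loci = 3, seed = 42,
                  missing_rate = 0.15)
  afd <- alleleFrequencies(ds, "demes")
  afp <- alleleFrequencies(ds, "pooled")
  for (l in 1:3) {
    pooled <- afp$freq[[1]][[l]]
    weighted <- numeric()
    for (d in 1:3) {
      f <- afd$freq[[d]][[l]] * afd$size[d, l]
      for (al in names(f)) {
        weighted[al] <- (if (is.na(weighted[al])) 0 else weighted[al]) + f[al]
      }
    }
    weighted <- weighted / sum(afd$size[, l])
    expect_equal(pooled[sort(names(pooled))], weighted[sort(names(weighted))],
                 tolerance = 1e-9)
  }
})

test_that("monomorphic loci give zero heterozygosity and richness one", {
  g <- replicate(4, matrix(c(101, 101), 1, 2), simplify = FALSE)
  ds <- mkExplicit(list(g, g))
  dv <- diversityStats(ds, g = 4)
  expect_equal(dv$HE, c(0, 0))
  expect_equal(dv$HO, c(0, 0))
  expect_equal(dv$AR, c(1, 1))
  expect_equal(dv$NA_, c(1, 1))
})

test_that("rarefied richness matches exhaustive subsample enumeration", {
  # tiny demes so all C(2n, g) subsamples can be enumerated
  for (seed in 1:5) {
    ds <- mkDataset(n_demes = 2, n_ind = 4, n_loci = 2, n_alleles = 4,
                    seed = seed)
    g <- 4
    dv <- diversityStats(ds, g = g)
    a <- alleleCalls(ds)
    for (d in 1:2) {
      expected <- mean(sapply(1:2, function(l) {
        copies <- c(a[indInfo(ds)$deme == d, l, ])
        rarefactionOracle(copies, g)
      }))
      expect_equal(dv$AR[d], expected, tolerance = 1e-9)
    }
  }
})

test_that("richness at the full sample size equals the allele count", {
  ds <- mkDataset(n_demes = 2, n_ind = 5, n_loci = 3, seed = 3)
  dv <- diversityStats(ds, g = 10)   # 2n of the smallest deme
  expect_equal(dv$AR, dv$NA_, tolerance = 1e-9)
})

test_that("expected heterozygosity uses Nei's unbiased estimator", {
  g <- list(list(matrix(c(101, 101), 1, 2), matrix(c(101, 102), 1, 2)))
  ds <- mkExplicit(g)
  dv <- diversityStats(ds, g = 2)
  # n = 2 ind, p = (3/4, 1/4): (2n/(2n-1)) (1 - p^2 - q^2) = (4/3)(0.375)
  expect_equal(dv$HE, 0.5)
  expect_equal(dv$HO, 0.5)
})

test_that("theta is ~0 for demes with identical frequencies and 1 for fixed demes", {
  ds0 <- mkDataset(n_demes = 2, n_ind = 50, n_loci = 8, n_alleles = 5,
                   seed = 9, shared = TRUE)
  th0 <- fstOverall(ds0, n_boot = 1)$theta
  expect_lt(abs(th0), 0.02)

  gA <- replicate(5, matrix(c(101, 101), 1, 2), simplify = FALSE)
  gB <- replicate(5, matrix(c(102, 102), 1, 2), simplify = FALSE)
  dsF <- mkExplicit(list(gA, gB))
  expect_equal(fstOverall(dsF, n_boot = 1)$theta, 1)
  expect_equal(fstMatrix(dsF, n_perm = 19, seed = 1)$theta[1, 2], 1)
})

test_that("theta equals an independent variance-component oracle", {
  for (seed in 1:8) {
    ds <- mkDataset(n_demes = 3, n_ind = 6, n_loci = 4, n_alleles = 4,
                    seed = 100 + seed,
                    missing_rate = ifelse(seed %% 2, 0, 0.1))
    expect_equal(fstOverall(ds, n_boot = 1)$theta, wcThetaOracle(ds),
                 tolerance = 1e-9)
  }
})

test_that("theta is invariant under locus order and allele relabelling", {
  ds <- mkDataset(n_demes = 3, n_ind = 8, n_loci = 5, seed = 17)
  th <- fstOverall(ds, n_boot = 1)$theta
  perm <- subsetDataset(ds, loci = c(4, 2, 5, 1, 3))
  expect_equal(fstOverall(perm, n_boot = 1)$theta, th, tolerance = 1e-12)
  relab <- ds
  arr <- alleleCalls(ds) + 1000L   # order-preserving relabel
  relab@alleles <- arr
  expect_equal(fstOverall(relab, n_boot = 1)$theta, th, tolerance = 1e-12)
  dv <- diversityStats(ds, g = 4); dv2 <- diversityStats(relab, g = 4)
  expect_equal(dv2$HE, dv$HE); expect_equal(dv2$HO, dv$HO)
})

test_that("pairwise permutation p-values detect differentiation and obey add-one", {
  ds <- mkDataset(n_demes = 2, n_ind = 12, n_loci = 6, seed = 5)  # divergent
  fs <- fstMatrix(ds, n_perm = 99, seed = 2)
  expect_true(all(fs$p[upper.tri(fs$p)] > 0))
  expect_gte(min(fs$p, na.rm = TRUE), 1 / 100)
  expect_equal(fs$theta, t(fs$theta))
  expect_equal(diag(fs$theta), rep(0, 2), ignore_attr = TRUE)
})

test_that("bootstrap CI over loci behaves at the edges", {
  ds <- mkDataset(n_demes = 3, n_ind = 8, n_loci = 5, seed = 21)
  ov1 <- fstOverall(ds, n_boot = 1, seed = 4)
  expect_equal(ov1$ci[1], ov1$ci[2])    # single replicate: degenerate CI
  single <- subsetDataset(ds, loci = 1)
  expect_true(all(is.na(fstOverall(single, n_boot = 100, seed = 1)$ci)))
})

test_that("linearization is x/(1-x), passes negatives, rejects >= 1", {
  expect_equal(linearizedFst(0.5), 1.0)
  expect_equal(linearizedFst(0), 0)
  expect_equal(linearizedFst(-0.01), -0.01 / 1.01)
  m <- matrix(c(0, 0.25, 0.25, 0), 2)
  expect_equal(linearizedFst(m), m / (1 - m))
  expect_error(linearizedFst(matrix(1, 1, 1)),
               class = "volescape_linearize_error")
})

test_that("HWE exact test matches complete-enumeration oracle on 2 alleles", {
  cases <- list(c(0, 5, 0), c(3, 1, 2), c(2, 4, 2), c(6, 0, 3))
  for (cs in cases) {
    geno <- c(replicate(cs[1], c(101, 101), simplify = FALSE),
              replicate(cs[2], c(101, 102), simplify = FALSE),
              replicate(cs[3], c(102, 102), simplify = FALSE))
    g <- lapply(geno, function(x) matrix(x, 1, 2))
    ds <- mkExplicit(list(g, list(matrix(c(101, 101), 1, 2),
                                  matrix(c(101, 102), 1, 2))))
    res <- hweTest(ds, 1, 1, method = "enum")
    expect_equal(res$p, hweEnumOracle2(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
})

test_that("HWE: monomorphic data give p = 1 and MC agrees with enumeration", {
  g <- replicate(5, matrix(c(101, 101), 1, 2), simplify = FALSE)
  ds <- mkExplicit(list(g, g))
  expect_equal(hweTest(ds, 1, 1)$p, 1)

  ds2 <- mkDataset(n_demes = 1, n_ind = 10, n_loci = 1, n_alleles = 3,
                   seed = 8)
  pe <- hweTest(ds2, 1, 1, method = "enum")$p
  pm <- hweTest(ds2, 1, 1, method = "mc", n_mc = 20000, seed = 3)$p
  se <- sqrt(pe * (1 - pe) / 20000)
  expect_lt(abs(pm - pe), 3 * se + 1e-4)
  expect_error(hweTest(ds2, 1, 1, method = "mc"),
               class = "volescape_seed_error")
})

test_that("a duplicated locus is perfect disequilibrium; single deme p = per-deme p", {
  ds <- mkDataset(n_demes = 1, n_ind = 12, n_loci = 1, n_alleles = 4, seed = 11)
  dup <- ds
  arr <- array(NA_integer_, c(nInd(ds), 2, 2))
  arr[, 1, ] <- alleleCalls(ds)[, 1, ]
  arr[, 2, ] <- alleleCalls(ds)[, 1, ]
  dup <- genotypeDataset(c("L1", "L1copy"), demeInfo(ds), indInfo(ds), arr)
  res <- ldTest(dup, 1, 2, n_perm = 200, seed = 2)
  expect_equal(res$p, res$perDeme$p[1], tolerance = 1e-12)
  expect_equal(res$p, 1 / 201, tolerance = 1e-12)   # permutation minimum
})

test_that("LD filter drops the lower-allele member of a significant pair only", {
  base <- mkDataset(n_demes = 3, n_ind = 12, n_loci = 3, n_alleles = 4,
                    seed = 30)
  # engineer a duplicated pair: locus 4 = two-allele collapse of locus 1
  a <- alleleCalls(base)
  arr <- array(NA_integer_, c(nInd(base), 4, 2))
  arr[, 1:3, ] <- a
  collapsed <- ifelse(a[, 1, ] <= 112L, 111L, 114L)
  arr[, 4, ] <- collapsed
  ds <- genotypeDataset(c("A1", "A2", "A3", "A4dup"), demeInfo(base),
                        indInfo(base), arr)
  nall <- function(l) length(unique(c(alleleCalls(ds)[, l, ])))
  expect_lt(nall(4), nall(1))
  res <- ldFilter(ds, alpha = 0.001, n_perm = 400, seed = 9)
  expect_equal(res$dropped, "A4dup")
  expect_equal(nLoci(res$dataset), 3)

  # independent loci: nothing dropped
  indep <- mkDataset(n_demes = 2, n_ind = 10, n_loci = 3, seed = 31)
  res2 <- ldFilter(indep, alpha = 0.001, n_perm = 200, seed = 10)
  expect_length(res2$dropped, 0)
  expect_equal(nLoci(res2$dataset), 3)
})

test_that("within-deme f detects engineered heterozygote deficit", {
  # all homozygotes at a polymorphic locus: strong positive f
  g <- c(replicate(6, matrix(c(101, 101), 1, 2), simplify = FALSE),
         replicate(6, matrix(c(102, 102), 1, 2), simplify = FALSE))
  ds <- mkExplicit(list(g))
  ft <- fisTest(ds, 1, n_perm = 200, seed = 1)
  expect_equal(ft$fis, 1)
  expect_lt(ft$p, 0.05)
})
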