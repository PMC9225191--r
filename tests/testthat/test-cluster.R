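# shared 2-island dataset with equilibrium theta ~ 0.2 (1/(1+8*Ne*m) with
# Ne = 100, m = 0.005), reused by several blocks
twoIsland <- local({
  cfg <- simConfig(n_demes = 2, sample_sizes = c(30, 30), n_loci = 20,
                   n_alleles = 8, N_e = 100, migration = "island",
                   m0 = 0.005, n_generations = 300, mutation_rate = 5e-4,
                   seed = 77)
  demes <- data.frame(name = c("A", "B"), easting = c(0, 5000),
                      northing = c(0, 0))
  simulateGenotypes(demes, config = cfg)
})

test_that("K = 1 gives certain assignment and the single-population likelihood", {
  ds <- mkDataset(n_demes = 2, n_ind = 8, n_loci = 4, seed = 3)
  m <- gibbsCluster(ds, K = 1, n_iter = 200, burnin = 50, seed = 1)
  expect_true(all(assignmentProbs(m) == 1))
  expect_true(is.finite(logEvidence(m)))
  expect_lt(logEvidence(m), 0)
})

test_that("two islands at theta ~ 0.2 are recovered almost perfectly at K = 2", {
  ds <- twoIsland$dataset
  th <- fstOverall(ds, n_boot = 1)$theta
  expect_gt(th, 0.1); expect_lt(th, 0.35)
  m <- gibbsCluster(ds, K = 2, n_iter = 800, burnin = 300, seed = 5)
  z <- max.col(assignmentProbs(m))
  truth <- indInfo(ds)$deme
  acc <- max(mean(z == truth), mean(z == 3 - truth))  # label switching
  expect_gte(acc, 0.95)
})

test_that("assignments are reproducible and exchangeable over individual order", {
  ds <- twoIsland$dataset
  m1 <- gibbsCluster(ds, K = 2, n_iter = 400, burnin = 150, seed = 11)
  m2 <- gibbsCluster(ds, K = 2, n_iter = 400, burnin = 150, seed = 11)
  expect_identical(assignmentProbs(m1), assignmentProbs(m2))

  # permute individual order: modal deme-level structure is unchanged
  perm <- sample(nInd(ds))
  arr <- alleleCalls(ds)[perm, , , drop = FALSE]
  ind <- indInfo(ds)[perm, ]; rownames(ind) <- NULL
  dsP <- genotypeDataset(lociNames(ds), demeInfo(ds), ind, arr)
  m3 <- gibbsCluster(dsP, K = 2, n_iter = 400, burnin = 150, seed = 12)
  z1 <- max.col(assignmentProbs(m1)); z3 <- max.col(assignmentProbs(m3))
  agree <- max(mean(z1[perm] == z3), mean(z1[perm] == 3 - z3))
  expect_gte(agree, 0.95)
})

test_that("DeltaK selects K = 2 for the two-island data; edge rules hold", {
  ds <- twoIsland$dataset
  ks <- selectK(ds, Kmax = 4, n_reps = 3, n_iter = 400, burnin = 150,
                seed = 21)
  expect_equal(ks$bestK, 2L)
  expect_true(all(is.na(ks$table$deltaK[c(1, 4)])))
  expect_true(all(ks$table$deltaK[2:3] >= 0, na.rm = TRUE))
  expect_error(selectK(ds, Kmax = 4, n_reps = 1, seed = 1),
               class = "volescape_cluster_error")
  expect_error(selectK(ds, Kmax = 2, n_reps = 2, seed = 1),
               class = "volescape_cluster_error")
})

test_that("deme labels follow the highest mean probability, ties to lower index", {
  ds <- mkDataset(n_demes = 2, n_ind = 4, n_loci = 2, seed = 2)
  # deme 1: all probability on cluster 1; deme 2: tied
  Q <- rbind(matrix(c(1, 0), 4, 2, byrow = TRUE),
             matrix(c(0.5, 0.5), 4, 2, byrow = TRUE))
  m <- new("ClusterModel", K = 2L, Q = Q, logLik = 0, logEvidence = 0,
           burnin = 0L, seed = 1L)
  expect_warning(lab <- demeClusterLabels(m, ds), "tied")
  expect_equal(unname(lab), c(1L, 1L))
})

test_that("degenerate AMOVA: fixed demes in separate clusters put 100% between clusters", {
  gA <- replicate(5, matrix(c(101, 101), 2, 2), simplify = FALSE)
  gB <- replicate(5, matrix(c(105, 105), 2, 2), simplify = FALSE)
  ds <- mkExplicit(list(gA, gB))
  am <- amova(ds, c(d1 = 1, d2 = 2), n_perm = 99, seed = 1)
  expect_equal(am$table$percent, c(100, 0, 0), tolerance = 1e-9)
  expect_equal(am$table$value[1], 1)
})

test_that("AMOVA components equal the brute-force pairwise oracle", {
  for (seed in 1:5) {
    ds <- mkDataset(n_demes = 4, n_ind = 3, n_loci = 2, n_alleles = 3,
                    seed = 200 + seed,
                    missing_rate = ifelse(seed %% 2, 0, 0.15))
    labels <- c(1, 1, 2, 2)
    got <- amova(ds, labels, n_perm = 1, seed = 1)$components
    want <- amovaOracle(ds, labels)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("AMOVA percentages sum to 100 and survive deme reordering", {
  ds <- mkDataset(n_demes = 4, n_ind = 6, n_loci = 3, seed = 33)
  labels <- c(1, 2, 1, 2)
  am <- amova(ds, labels, n_perm = 49, seed = 2)
  expect_equal(sum(am$table$percent), 100, tolerance = 1e-6)
  dsR <- subsetDataset(ds, demes = c(3, 1, 4, 2))
  amR <- amova(dsR, labels[c(3, 1, 4, 2)], n_perm = 49, seed = 2)
  expect_equal(amR$components, am$components, tolerance = 1e-9)
  expect_error(amova(ds, rep(1, 4), n_perm = 9, seed = 1),
               class = "volescape_amova_error")
})

test_that("panmictic null: cluster-level AMOVA p-values are roughly uniform", {
  set.seed(61)
  ps <- replicate(40, {
    ds <- mkDataset(n_demes = 4, n_ind = 6, n_loci = 4, n_alleles = 5,
                    seed = sample.int(1e6, 1), shared = TRUE)
    amova(ds, c(1, 1, 2, 2), n_perm = 59,
          seed = sample.int(1e6, 1))$table$p[1]
  })
  expect_lt(mean(ps < 0.05), 0.25)   # no gross anti-conservatism
  expect_gt(mean(ps), 0.3)           # centred well away from 0
})

test_that("recovered between-cluster structure rises as migration falls", {
  demes <- data.frame(name = paste0("d", 1:4),
                      easting = c(0, 1000, 50000, 51000), northing = 0)
  fct <- sapply(c(0.2, 0.02, 0.002), function(m) {
    mean(sapply(1:3, function(r) {
      cfg <- simConfig(n_demes = 4, sample_sizes = 10, n_loci = 8,
                       migration = "island", m0 = m, N_e = 80,
                       n_generations = 150, seed = 7000 + round(1e4 * m) + r)
      sim <- simulateGenotypes(demes, config = cfg)
      amova(sim$dataset, c(1, 1, 2, 2), n_perm = 1, seed = 1)$table$value[3]
    }))
  })
  # F_ST-like total differentiation decreases with migration rate
  expect_true(all(diff(fct) > 0))
})
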