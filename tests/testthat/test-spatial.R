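test_that("Mantel self-correlation is exactly 1; constant matrix gives NA", {
  A <- rndSymMatrix(6, 1)
  expect_equal(mantelTest(A, A, n_perm = 49, seed = 1)$r, 1)
  B <- matrix(2, 6, 6); diag(B) <- 0   # constant triangle
  expect_true(is.na(mantelTest(A, B, n_perm = 49, seed = 1)$r))
})

test_that("Mantel p on 4x4 matrices matches exhaustive enumeration", {
  for (seed in 1:8) {
    A <- rndSymMatrix(4, seed)
    B <- rndSymMatrix(4, seed + 100)
    exact <- mantelExactP(A, B)
    got <- mantelTest(A, B, n_perm = 4999, seed = seed)$p
    # permutation p concentrates on the exact enumeration value
    expect_lt(abs(got - exact), 3 * sqrt(exact * (1 - exact) / 5000) + 2e-3)
  }
})

test_that("Mantel is symmetric in its arguments", {
  A <- rndSymMatrix(7, 5); B <- rndSymMatrix(7, 6)
  r1 <- mantelTest(A, B, n_perm = 999, seed = 3)
  r2 <- mantelTest(B, A, n_perm = 999, seed = 3)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_lt(abs(r1$p - r2$p), 0.06)
})

test_that("partial Mantel reduces to plain Mantel when the covariate is noise", {
  A <- rndSymMatrix(8, 11); B <- A + rndSymMatrix(8, 12) * 0.3
  C <- rndSymMatrix(8, 13)        # unrelated
  rAB <- mantelTest(A, B, n_perm = 99, seed = 1)$r
  rp <- partialMantelTest(A, B, C, n_perm = 99, seed = 1)$r
  expect_lt(abs(rp - rAB), 0.15)
})

test_that("partialling a matrix out of itself gives r = 0", {
  A <- rndSymMatrix(6, 21); B <- rndSymMatrix(6, 22)
  expect_equal(partialMantelTest(A, B, B, n_perm = 49, seed = 1)$r, 0)
})

test_that("partial r equals the closed-form first-order partial correlation", {
  A <- rndSymMatrix(5, 31); B <- rndSymMatrix(5, 32); C <- rndSymMatrix(5, 33)
  x <- A[lower.tri(A)]; y <- B[lower.tri(B)]; z <- C[lower.tri(C)]
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partialMantelTest(A, B, C, n_perm = 9, seed = 1)$r, want,
               tolerance = 1e-12)
})

test_that("RMA fit: exact line recovered; slope is sd ratio regardless of noise side", {
  A <- rndSymMatrix(6, 41)
  fit <- rmaFit(A, 2 * A)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  # symmetry: unlike OLS, RMA |slope| is sd(y)/sd(x) whichever side is noisy
  set.seed(42)
  X <- rndSymMatrix(10, 43)
  noise <- rndSymMatrix(10, 44) * 0.2
  Y <- 3 * X + noise
  f1 <- rmaFit(X, Y)
  f2 <- rmaFit(Y, X)
  expect_equal(abs(f1$slope), 1 / abs(f2$slope), tolerance = 1e-9)
  x <- X[lower.tri(X)]; y <- Y[lower.tri(Y)]
  expect_equal(abs(f1$slope), sd(y) / sd(x), tolerance = 1e-12)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_gt(abs(f1$slope), abs(ols))   # RMA exceeds OLS under noise in x, y

  Z <- X; Z[1, 2] <- Z[2, 1] <- 0
  expect_error(rmaFit(Z, Y, log_x = TRUE), class = "volescape_rma_error")
})

test_that("membership matrix is the same-cluster indicator", {
  lab <- c(A = 1, B = 1, C = 2)
  M <- membershipMatrix(lab)
  expect_equal(M["A", "B"], 1)
  expect_equal(M["A", "C"], 0)
  expect_equal(diag(M), c(A = 1, B = 1, C = 1))
  expect_true(all(membershipMatrix(c(a = 1, b = 1)) == 1))
  expect_equal(membershipMatrix(c(a = 1, b = 2, c = 3)), diag(3),
               ignore_attr = TRUE)
})

test_that("autocorrelation r matches an independent formula implementation", {
  # 6 individuals, 2 loci, hand-laid coordinates
  g <- list(list(matrix(c(101, 101, 201, 202), 2, 2, byrow = TRUE),
                 matrix(c(101, 102, 201, 201), 2, 2, byrow = TRUE),
                 matrix(c(102, 102, 202, 202), 2, 2, byrow = TRUE)),
            list(matrix(c(103, 101, 203, 202), 2, 2, byrow = TRUE),
                 matrix(c(103, 103, 203, 203), 2, 2, byrow = TRUE),
                 matrix(c(101, 103, 201, 203), 2, 2, byrow = TRUE)))
  coords <- cbind(c(0, 0), c(350, 0))
  ds <- mkExplicit(g, coords = coords)
  indXY <- cbind(c(0, 30, 60, 350, 380, 410), 0)
  res <- suppressWarnings(
    spatialAutocorr(ds, class_width = 100, n_perm = 0, n_boot = 0,
                    coords = indXY))   # a sparse class is expected here
  # oracle: explicit pairwise distance matrix + literal formula
  D <- matrix(0, 6, 6)
  flat <- do.call(rbind, lapply(g, function(dd) dd))
  gl <- c(g[[1]], g[[2]])
  for (i in 1:5) for (j in (i + 1):6) {
    d <- 0
    for (l in 1:2) d <- d + genoDistOracle(gl[[i]][l, ], gl[[j]][l, ])
    D[i, j] <- D[j, i] <- d
  }
  geo <- as.matrix(dist(indXY))
  for (k in seq_len(nrow(res))) {
    if (res$n_pairs[k] >= 2) {
      want <- autocorrOracleR(D, geo, res$lower[k], res$upper[k])
      expect_equal(res$r[k], want, tolerance = 1e-9)
    }
  }
  expect_equal(sum(res$n_pairs), choose(6, 2))
})

test_that("clones in one deme push the first-class r above the null band", {
  clone <- matrix(c(101, 102, 203, 203, 305, 306), 3, 2, byrow = TRUE)
  others <- lapply(1:8, function(i)
    matrix(c(100 + 2 * i, 101 + 2 * i, 200 + 2 * i, 201 + 2 * i,
             300 + 2 * i, 301 + 2 * i), 3, 2, byrow = TRUE))
  g <- list(replicate(4, clone, simplify = FALSE), others[1:4], others[5:8])
  ds <- mkExplicit(g, coords = cbind(c(0, 2000, 4000), 0))
  res <- spatialAutocorr(ds, class_width = 100, n_perm = 199, n_boot = 99,
                         seed = 5)
  expect_gt(res$r[1], 0)
  expect_gt(res$r[1], res$null_hi[1])
})

test_that("distance classes are half-open and conserve the pair count", {
  ds <- mkDataset(n_demes = 3, n_ind = 5, n_loci = 3, seed = 55)
  # demes at 1000, 2000, 3000 m: between-deme pairs sit exactly on bounds
  res <- spatialAutocorr(ds, class_width = 1000, n_perm = 0, n_boot = 0)
  expect_equal(sum(res$n_pairs), choose(15, 2))
  # same-deme pairs (distance 0) are in [0, 1000); 1000 m pairs in the next
  expect_equal(res$n_pairs[1], 3 * choose(5, 2))
  expect_equal(res$n_pairs[2], 2 * 25)
})

test_that("Mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  A <- rndSymMatrix(8, 71); B <- rndSymMatrix(8, 72)
  ours <- mantelTest(A, B, n_perm = 999, seed = 2)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.06)
})
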