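# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct transcriptions of textbook formulas (loops, explicit edge lists,
# exhaustive enumeration), independent of the package's implementations.

# random multinomial dataset: demes drawn from independent random frequency
# vectors (alpha controls how divergent demes are; alpha = NULL -> shared)
mkDataset <- function(n_demes = 3, n_ind = 6, n_loci = 4, n_alleles = 4,
                      seed = 1, shared = FALSE, missing_rate = 0) {
  set.seed(seed)
  n <- n_demes * n_ind
  a <- array(NA_integer_, c(n, n_loci, 2))
  for (l in seq_len(n_loci)) {
    base <- 100 + 10 * l
    if (shared) p0 <- rgamma(n_alleles, 1)
    for (d in seq_len(n_demes)) {
      p <- if (shared) p0 else rgamma(n_alleles, 1)
      p <- p / sum(p)
      idx <- which(rep(seq_len(n_demes), each = n_ind) == d)
      a[idx, l, 1] <- base + sample.int(n_alleles, length(idx), TRUE, prob = p)
      a[idx, l, 2] <- base + sample.int(n_alleles, length(idx), TRUE, prob = p)
    }
  }
  if (missing_rate > 0) {
    drop <- which(matrix(runif(n * n_loci) < missing_rate, n, n_loci))
    for (k in drop) a[((k - 1) %% n) + 1, ((k - 1) %/% n) + 1, ] <- NA
  }
  genotypeDataset(
    loci = paste0("L", seq_len(n_loci)),
    demes = data.frame(name = paste0("d", seq_len(n_demes)),
                       easting = seq_len(n_demes) * 1000,
                       northing = rep(0, n_demes)),
    indiv = data.frame(id = paste0("i", seq_len(n)),
                       deme = rep(seq_len(n_demes), each = n_ind)),
    alleles = a)
}

# dataset built from explicit genotype lists: geno[[deme]][[ind]] is a
# matrix n_loci x 2 of allele codes (NA rows = missing)
mkExplicit <- function(geno, coords = NULL) {
  n_demes <- length(geno)
  n_loci <- nrow(geno[[1]][[1]])
  sizes <- vapply(geno, length, integer(1))
  n <- sum(sizes)
  a <- array(NA_integer_, c(n, n_loci, 2))
  i <- 0
  for (d in seq_len(n_demes)) for (g in geno[[d]]) {
    i <- i + 1
    a[i, , ] <- g
  }
  if (is.null(coords))
    coords <- cbind(seq_len(n_demes) * 1000, rep(0, n_demes))
  genotypeDataset(
    loci = paste0("L", seq_len(n_loci)),
    demes = data.frame(name = paste0("d", seq_len(n_demes)),
                       easting = coords[, 1], northing = coords[, 2]),
    indiv = data.frame(id = paste0("i", seq_len(n)),
                       deme = rep(seq_len(n_demes), sizes)),
    alleles = a)
}

# ---------------------------------------------------------------------------
# Weir-Cockerham theta oracle: classical nested-ANOVA mean-squares route
# (copies within individuals within populations), per allele, summed.
# ---------------------------------------------------------------------------
wcThetaOracle <- function(dataset) {
  a <- alleleCalls(dataset)
  demeIdx <- indInfo(dataset)$deme
  sP <- sI <- sG <- 0
  for (l in seq_len(nLoci(dataset))) {
    a1 <- a[, l, 1]; a2 <- a[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) == 0) next
    d <- demeIdx[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(d)
    ni <- sapply(pops, function(p) sum(d == p))
    if (length(pops) < 2) next
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    n <- length(x1); r <- length(pops)
    nbar <- n / r
    nc <- (n - sum(ni^2) / n) / (r - 1)
    for (al in alleles) {
      y <- cbind(x1 == al, x2 == al) * 1      # copy indicators
      pij <- rowMeans(y)                       # per-individual freq
      pi_ <- sapply(pops, function(p) mean(pij[d == p]))
      pbar <- sum(ni * pi_) / n
      SSG <- sum((y[, 1] - pij)^2 + (y[, 2] - pij)^2)
      SSI <- 2 * sum((pij - pi_[match(d, pops)])^2)
      SSP <- 2 * sum(ni * (pi_ - pbar)^2)
      MSG <- SSG / n
      MSI <- SSI / (n - r)
      MSP <- SSP / (r - 1)
      sG <- sG + MSG
      sI <- sI + (MSI - MSG) / 2
      sP <- sP + (MSP - MSI) / (2 * nc)
    }
  }
  sP / (sP + sI + sG)
}

# ---------------------------------------------------------------------------
# Dijkstra oracle: O(V^2) over an explicit edge list of the 8-neighbour grid
# ---------------------------------------------------------------------------
dijkstraOracle <- function(cv, cellSize, src, dst) {
  nr <- nrow(cv); nc <- ncol(cv)
  id <- function(r, c) (c - 1) * nr + r
  V <- nr * nc
  distv <- rep(Inf, V); distv[id(src[1], src[2])] <- 0
  done <- rep(FALSE, V)
  moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  for (iter in seq_len(V)) {
    u <- which.min(ifelse(done, Inf, distv))
    if (!is.finite(distv[u])) break
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    if (ur == dst[1] && uc == dst[2]) break
    for (k in seq_len(8)) {
      vr <- ur + moves[k, 1]; vc <- uc + moves[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- id(vr, vc)
      if (done[v]) next
      d <- cellSize * (if (abs(moves[k, 1]) + abs(moves[k, 2]) == 2)
        sqrt(2) else 1) * (cv[ur, uc] + cv[vr, vc]) / 2
      if (distv[u] + d < distv[v]) distv[v] <- distv[u] + d
    }
  }
  distv[id(dst[1], dst[2])]
}

# ---------------------------------------------------------------------------
# AMOVA oracle: sums of squares by explicit loops over gene-copy pairs
# (allele-identity distance), converted to components with the textbook
# unequal-size coefficients.
# ---------------------------------------------------------------------------
amovaOracle <- function(dataset, labels) {
  a <- alleleCalls(dataset)
  demeIdx <- indInfo(dataset)$deme
  total <- c(sa = 0, sb = 0, sc = 0)
  for (l in seq_len(nLoci(dataset))) {
    copies <- c(a[, l, 1], a[, l, 2])
    demeOf <- rep(demeIdx, 2)
    ok <- !is.na(copies)
    copies <- copies[ok]; demeOf <- demeOf[ok]
    N <- length(copies)
    demes <- sort(unique(demeOf))
    clus <- labels[demes]
    G <- length(unique(clus)); P <- length(demes)
    if (G < 2 || P < 2) next
    pairSS <- function(sel) {
      v <- copies[sel]; s <- 0
      if (length(v) < 2) return(0)
      for (i in 1:(length(v) - 1)) for (j in (i + 1):length(v))
        s <- s + (v[i] != v[j])
      s
    }
    SS_T <- pairSS(rep(TRUE, N)) / N
    SS_WP <- sum(sapply(demes, function(d) pairSS(demeOf == d) / sum(demeOf == d)))
    SS_WG <- sum(sapply(unique(clus), function(g) {
      sel <- demeOf %in% demes[clus == g]
      pairSS(sel) / sum(sel)
    }))
    Np <- sapply(demes, function(d) sum(demeOf == d))
    Ng <- sapply(unique(clus), function(g) sum(Np[clus == g]))
    MS_WP <- (SS_WP) / (N - P)
    df_AP <- P - G
    sumNp2Ng <- sum(sapply(unique(clus), function(g)
      sum(Np[clus == g]^2) / sum(Np[clus == g])))
    n1 <- if (df_AP > 0) (N - sumNp2Ng) / df_AP else NA
    n2 <- (sumNp2Ng - sum(Np^2) / N) / (G - 1)
    n3 <- (N - sum(Ng^2) / N) / (G - 1)
    sc <- MS_WP
    sb <- if (df_AP > 0) ((SS_WG - SS_WP) / df_AP - sc) / n1 else 0
    sa <- ((SS_T - SS_WG) / (G - 1) - sc - n2 * sb) / n3
    total <- total + c(sa = sa, sb = sb, sc = sc)
  }
  total
}

# ---------------------------------------------------------------------------
# exact Mantel p for 4x4 matrices: all 24 relabellings
# ---------------------------------------------------------------------------
mantelExactP <- function(A, B) {
  perms <- rbind(c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),
                 c(1,4,3,2),c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),
                 c(2,4,1,3),c(2,4,3,1),c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),
                 c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),c(4,1,2,3),c(4,1,3,2),
                 c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
  x <- A[lower.tri(A)]
  r0 <- cor(x, B[lower.tri(B)])
  rs <- apply(perms, 1, function(p) {
    Bp <- B[p, p]
    cor(x, Bp[lower.tri(Bp)])
  })
  if (r0 >= 0) mean(rs >= r0 - 1e-12) else mean(rs <= r0 + 1e-12)
}

# ---------------------------------------------------------------------------
# autocorrelation oracle: literal double-centred cross-product formula with
# explicit loops
# ---------------------------------------------------------------------------
autocorrOracleR <- function(D, geo, lower, upper) {
  n <- nrow(D)
  C <- matrix(0, n, n)
  rm <- rowMeans(D); gm <- mean(D)
  for (i in 1:n) for (j in 1:n)
    C[i, j] <- -0.5 * (D[i, j] - rm[i] - rm[j] + gm)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (geo[i, j] >= lower && geo[i, j] < upper) {
      num <- num + 2 * C[i, j]
      den <- den + C[i, i] + C[j, j]
    }
  }
  num / den
}

# squared genotypic distance oracle for a single pair at one locus, from the
# published case table of the codominant metric
genoDistOracle <- function(g1, g2) {
  cnt <- function(g) {
    al <- unique(c(g1, g2))
    sapply(al, function(a) sum(g == a))
  }
  sum((cnt(g1) - cnt(g2))^2) / 2
}

# ---------------------------------------------------------------------------
# HWE exact-test oracle for two alleles: enumerate heterozygote counts
# ---------------------------------------------------------------------------
hweEnumOracle2 <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  prob <- sapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
        h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
        lgamma(2 * n + 1))
  })
  pObs <- prob[match(nAa, hets)]
  sum(prob[prob <= pObs + 1e-12])
}

# exhaustive rarefaction oracle: mean allele count over all subsets of g
# gene copies (tiny samples only)
rarefactionOracle <- function(copies, g) {
  idx <- combn(length(copies), g)
  mean(apply(idx, 2, function(s) length(unique(copies[s]))))
}

# random symmetric "distance-like" matrix
rndSymMatrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- m + t(m); diag(m) <- 0
  m
}
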