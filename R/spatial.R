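## Matrix correlation (Mantel / partial Mantel), reduced-major-axis
## regression on distance-matrix triangles, cluster-membership matrices, and
## individual-level spatial autocorrelation in distance classes.

checkSquareSym <- function(m, nm) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    vlError("volescape_matrix_error", paste(nm, "must be a square matrix"))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    vlError("volescape_matrix_error", paste(nm, "must be symmetric"))
}

#' Mantel test
#'
#' Pearson correlation over the strict lower triangles of two symmetric
#' distance matrices; the null distribution permutes the rows and columns of
#' \code{B} simultaneously. The p-value is one-sided in the direction of the
#' observed r (add-one rule); set \code{two_sided = TRUE} for a two-sided p.
#'
#' @param A,B symmetric matrices of identical dimension (>= 4 demes).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param two_sided two-sided p instead of the one-sided default.
#' @return list with \code{r}, \code{p}, \code{n_perm}, \code{tail}. \code{r}
#'   and \code{p} are \code{NA} when a triangle has zero variance.
#' @export
mantelTest <- function(A, B, n_perm = 1000, seed = NULL, two_sided = FALSE) {
  checkSquareSym(A, "A"); checkSquareSym(B, "B")
  n <- nrow(A)
  if (n < 4) vlError("volescape_matrix_error", "need >= 4 demes")
  if (nrow(B) != n) vlError("volescape_matrix_error", "A and B sizes differ")
  x <- lowerTri(A); y <- lowerTri(B)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, tail = NA))
  r <- cor(x, y)
  tail <- if (two_sided) "two-sided" else if (r >= 0) "greater" else "less"
  hits <- withSeed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample.int(n)
      rb <- cor(x, lowerTri(B[pi, pi]))
      ex <- if (two_sided) abs(rb) >= abs(r) - 1e-12
            else if (r >= 0) rb >= r - 1e-12 else rb <= r + 1e-12
      if (ex) h <- h + 1L
    }
    h
  })
  list(r = r, p = addOneP(hits, n_perm), n_perm = n_perm, tail = tail)
}

#' Partial Mantel test
#'
#' First-order partial correlation r_AB.C from the three triangle
#' correlations. The null permutes the residuals of A on C (residual
#' permutation): A's triangle is regressed on C's, the residuals are
#' permuted among pairs, and the partial correlation is recomputed.
#' One-sided p in the direction of the observed r.
#'
#' @param A,B,C conformable symmetric matrices.
#' @param n_perm,seed,two_sided as in \code{\link{mantelTest}}.
#' @return list with \code{r}, \code{p}, \code{n_perm}, \code{tail};
#'   \code{NA} when |r_AC| or |r_BC| = 1 (degenerate partialling).
#' @export
partialMantelTest <- function(A, B, C, n_perm = 1000, seed = NULL,
                              two_sided = FALSE) {
  checkSquareSym(A, "A"); checkSquareSym(B, "B"); checkSquareSym(C, "C")
  n <- nrow(A)
  if (nrow(B) != n || nrow(C) != n)
    vlError("volescape_matrix_error", "matrices must be conformable")
  x <- lowerTri(A); y <- lowerTri(B); z <- lowerTri(C)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, tail = NA))
  pcor <- function(xx) {
    rxy <- cor(xx, y); rxz <- cor(xx, z); ryz <- cor(y, z)
    num <- rxy - rxz * ryz
    den <- sqrt(max(0, (1 - rxz^2) * (1 - ryz^2)))
    ## B identical to C: numerator vanishes too -- fully partialled, r = 0
    if (den < 1e-12) return(if (abs(num) < 1e-9) 0 else NA_real_)
    num / den
  }
  r <- pcor(x)
  if (is.na(r) || abs(cor(x, z)) >= 1 - 1e-12)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, tail = NA))
  tail <- if (two_sided) "two-sided" else if (r >= 0) "greater" else "less"
  fit <- lm.fit(cbind(1, z), x)
  fitted <- fit$fitted.values; resid <- fit$residuals
  hits <- withSeed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      xStar <- fitted + sample(resid)
      rb <- pcor(xStar)
      if (is.na(rb)) next
      ex <- if (two_sided) abs(rb) >= abs(r) - 1e-12
            else if (r >= 0) rb >= r - 1e-12 else rb <= r + 1e-12
      if (ex) h <- h + 1L
    }
    h
  })
  list(r = r, p = addOneP(hits, n_perm), n_perm = n_perm, tail = tail)
}

#' Reduced-major-axis regression on matrix triangles
#'
#' slope = sign(r) * sd(y)/sd(x), intercept through the means; x optionally
#' log10-transformed first (entries must then be positive).
#'
#' @param x_matrix,y_matrix symmetric matrices.
#' @param log_x log10-transform x before fitting.
#' @return list with \code{slope}, \code{intercept}, \code{r},
#'   \code{transform}.
#' @export
rmaFit <- function(x_matrix, y_matrix, log_x = FALSE) {
  checkSquareSym(x_matrix, "x"); checkSquareSym(y_matrix, "y")
  x <- lowerTri(x_matrix); y <- lowerTri(y_matrix)
  if (log_x) {
    if (any(x <= 0))
      vlError("volescape_rma_error", "log_x needs strictly positive x")
    x <- log10(x)
  }
  if (sd(x) == 0 || sd(y) == 0)
    vlError("volescape_rma_error", "zero variance in a triangle")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (slope == 0) slope <- sd(y) / sd(x)   # r exactly 0: report magnitude
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r,
       transform = if (log_x) "log10(x)" else "none")
}

#' Cluster membership matrix
#'
#' 1 for same-cluster deme pairs, 0 for different-cluster pairs; diagonal 1.
#'
#' @param labels named vector deme -> cluster.
#' @return symmetric 0/1 matrix with deme names.
#' @export
membershipMatrix <- function(labels) {
  if (anyNA(labels)) vlError("volescape_cluster_error", "unlabelled deme")
  m <- outer(labels, labels, "==") * 1
  dimnames(m) <- list(names(labels), names(labels))
  m
}

## ---------------------------------------------------------------------------
## Spatial autocorrelation
## ---------------------------------------------------------------------------

## Squared codominant genotypic distance between all individual pairs,
## summed over loci: half the squared Euclidean distance between allele
## count vectors (0 same genotype, 1 one shared allele, 2 het/het disjoint,
## 3 hom vs disjoint het, 4 opposite homozygotes). Missing: locus skipped
## for that pair.
genotypicDistance <- function(dataset) {
  n <- nInd(dataset)
  D <- matrix(0, n, n)
  for (l in seq_len(nLoci(dataset))) {
    a1 <- dataset@alleles[, l, 1]; a2 <- dataset@alleles[, l, 2]
    ok <- !is.na(a1)
    if (!any(ok)) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    X <- matrix(0, n, length(alleles))
    okw <- which(ok)
    X[cbind(okw, match(a1[ok], alleles))] <- 1
    i2 <- cbind(okw, match(a2[ok], alleles))
    X[i2] <- X[i2] + 1
    ## half squared Euclidean between allele-count vectors
    sq <- rowSums(X^2)
    d_l <- outer(sq, sq, "+") / 2 - X %*% t(X)
    d_l[!(ok %o% ok)] <- 0    # pairs with a missing member contribute 0
    D <- D + d_l
  }
  D
}

## double-centred covariance matrix from a squared-distance matrix
gowerCentre <- function(D) {
  rm <- rowMeans(D); gm <- mean(D)
  -0.5 * (D - outer(rm, rep(1, ncol(D))) - outer(rep(1, nrow(D)), rm) + gm)
}

## class autocorrelation r for given centred matrix and pair index matrix
classR <- function(C, pairs) {
  if (!ncol(pairs)) return(NA_real_)
  num <- 2 * sum(C[cbind(pairs[1, ], pairs[2, ])])
  den <- sum(diag(C)[pairs[1, ]] + diag(C)[pairs[2, ]])
  if (den == 0) return(NA_real_)
  num / den
}

#' Multilocus spatial autocorrelation in distance classes
#'
#' Squared genotypic distances between individuals (codominant microsatellite
#' metric summed over loci) are double-centred into a covariance matrix; the
#' autocorrelation r of each geographic distance class compares within-class
#' genetic similarity to the overall mean. Individuals inherit their deme's
#' coordinates unless per-individual coordinates are supplied. Classes are
#' half-open [lower, upper) so same-deme pairs land in the first class.
#'
#' The permutation null shuffles genotypes among individuals (999 by
#' default) giving a 95\% band per class; a bootstrap over pairs within each
#' class gives a 95\% CI for r.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param class_width class width in metres (default 100).
#' @param n_perm permutations for the null band.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed RNG seed.
#' @param coords optional per-individual matrix/data.frame with easting,
#'   northing (metres).
#' @param max_classes cap on the number of classes (the last class absorbs
#'   the remainder when capped; default covers the data span).
#' @return data.frame per class: \code{lower}, \code{upper}, \code{n_pairs},
#'   \code{r}, \code{null_lo}, \code{null_hi}, \code{ci_lo}, \code{ci_hi}.
#'   Classes with < 2 pairs give \code{NA} r with a warning.
#' @export
spatialAutocorr <- function(dataset, class_width = 100, n_perm = 999,
                            n_boot = 1000, seed = NULL, coords = NULL,
                            max_classes = NULL) {
  n <- nInd(dataset)
  if (is.null(coords)) {
    coords <- cbind(dataset@demes$easting[dataset@indiv$deme],
                    dataset@demes$northing[dataset@indiv$deme])
  } else coords <- as.matrix(coords)
  geo <- as.matrix(dist(coords))
  D <- genotypicDistance(dataset)
  C <- gowerCentre(D)
  maxd <- max(geo)
  nClass <- ceiling((maxd + 1e-9) / class_width)
  if (!is.null(max_classes)) nClass <- min(nClass, max_classes)
  lower <- (seq_len(nClass) - 1) * class_width
  upper <- lower + class_width
  upper[nClass] <- max(upper[nClass], maxd + 1e-9)   # absorb remainder
  prs <- allPairs(n)
  pd <- geo[cbind(prs[1, ], prs[2, ])]
  classOf <- pmin(findInterval(pd, lower), nClass)
  res <- data.frame(lower = lower, upper = upper,
                    n_pairs = as.integer(tabulate(classOf, nClass)),
                    r = NA_real_, null_lo = NA_real_, null_hi = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_)
  pairsOf <- lapply(seq_len(nClass),
                    function(k) prs[, classOf == k, drop = FALSE])
  for (k in seq_len(nClass)) {
    if (res$n_pairs[k] < 2) {
      if (res$n_pairs[k] > 0)
        warning("distance class ", lower[k], "-", upper[k],
                " has < 2 pairs; r set to NA")
      next
    }
    res$r[k] <- classR(C, pairsOf[[k]])
  }
  withSeed(seed, {
    if (n_perm > 0) {
      permR <- matrix(NA_real_, n_perm, nClass)
      for (b in seq_len(n_perm)) {
        pi <- sample.int(n)
        Cp <- C[pi, pi]
        for (k in seq_len(nClass))
          if (res$n_pairs[k] >= 2) permR[b, k] <- classR(Cp, pairsOf[[k]])
      }
      res$null_lo <- apply(permR, 2, quantile, 0.025, na.rm = TRUE)
      res$null_hi <- apply(permR, 2, quantile, 0.975, na.rm = TRUE)
    }
    if (n_boot > 0) {
      for (k in seq_len(nClass)) {
        if (res$n_pairs[k] < 2) next
        pk <- pairsOf[[k]]
        bs <- vapply(seq_len(n_boot), function(b) {
          sel <- sample.int(ncol(pk), replace = TRUE)
          classR(C, pk[, sel, drop = FALSE])
        }, numeric(1))
        res$ci_lo[k] <- quantile(bs, 0.025, na.rm = TRUE)
        res$ci_hi[k] <- quantile(bs, 0.975, na.rm = TRUE)
      }
    }
  })
  res
}
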