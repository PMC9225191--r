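## Diversity and differentiation statistics.
##
## F-statistics use the Weir & Cockerham (1984) variance-component estimators:
## theta (F_ST analogue) is Sum(a) / Sum(a+b+c) over alleles and loci -- the
## ratio of summed components, not the mean of per-locus ratios.

## ---------------------------------------------------------------------------
## Allele frequencies
## ---------------------------------------------------------------------------

#' Allele frequency tables
#'
#' Relative allele frequencies and gene-copy sample sizes per group and locus,
#' excluding missing calls. Groups are the demes, or a single pooled group.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param grouping \code{"demes"} or \code{"pooled"}.
#' @return A list with \code{freq} (list over groups of lists over loci of
#'   named frequency vectors; empty numeric for cells with no data),
#'   \code{size} (gene-copy counts, groups x loci matrix), \code{groups} and
#'   \code{loci}.
#' @export
alleleFrequencies <- function(dataset, grouping = c("demes", "pooled")) {
  grouping <- match.arg(grouping)
  if (grouping == "pooled") {
    groups <- "pooled"; gidx <- rep(1L, nInd(dataset))
  } else {
    groups <- demeNames(dataset); gidx <- dataset@indiv$deme
  }
  L <- nLoci(dataset)
  size <- matrix(0L, length(groups), L, dimnames = list(groups, dataset@loci))
  freq <- lapply(seq_along(groups), function(g) {
    idx <- which(gidx == g)
    lapply(seq_len(L), function(l) {
      al <- c(dataset@alleles[idx, l, 1], dataset@alleles[idx, l, 2])
      al <- al[!is.na(al)]
      size[g, l] <<- length(al)
      if (!length(al)) return(numeric())
      tab <- table(al)
      setNames(as.numeric(tab) / length(al), names(tab))
    })
  })
  names(freq) <- groups
  for (g in seq_along(groups)) names(freq[[g]]) <- dataset@loci
  list(freq = freq, size = size, groups = groups, loci = dataset@loci)
}

## ---------------------------------------------------------------------------
## Weir-Cockerham variance components
## ---------------------------------------------------------------------------

## Components for one locus. a1, a2: allele code vectors per individual;
## deme: integer group index. Returns c(a, b, c) summed over alleles.
## Demes with < 1 complete genotype at the locus are dropped; needs >= 2
## demes with data and >= 2 alleles, else contributes zeros.
wcLocusComponents <- function(a1, a2, deme) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; deme <- deme[ok]
  if (!length(a1)) return(c(a = 0, b = 0, c = 0))
  demeF <- factor(deme)
  ni <- as.numeric(table(demeF))
  r <- length(ni)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  het <- a1 != a2
  for (al in alleles) {
    x <- (a1 == al) + (a2 == al)                # copies per individual
    p_i <- tapply(x, demeF, sum) / (2 * ni)
    h_i <- tapply(het & x == 1L, demeF, sum) / ni
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

## Per-locus components over a set of demes; rows = loci.
wcComponents <- function(dataset, demeSubset = NULL) {
  idx <- if (is.null(demeSubset)) seq_len(nInd(dataset)) else
    which(dataset@indiv$deme %in% demeSubset)
  deme <- dataset@indiv$deme[idx]
  t(vapply(seq_len(nLoci(dataset)), function(l)
    wcLocusComponents(dataset@alleles[idx, l, 1],
                      dataset@alleles[idx, l, 2], deme),
    numeric(3)))
}

wcThetaFromComponents <- function(comp) {
  tot <- sum(comp)
  if (tot == 0) return(NA_real_)
  sum(comp[, 1]) / tot
}

## Single-deme Weir-Cockerham f (F_IS): 1 - sum(c)/sum(b+c) over alleles/loci.
wcFisDeme <- function(dataset, deme) {
  idx <- which(dataset@indiv$deme == deme)
  B <- 0; C <- 0
  for (l in seq_len(nLoci(dataset))) {
    a1 <- dataset@alleles[idx, l, 1]; a2 <- dataset@alleles[idx, l, 2]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1)
    if (n < 2) next
    alleles <- unique(c(a1, a2))
    if (length(alleles) < 2) next
    het <- a1 != a2
    for (al in alleles) {
      x <- (a1 == al) + (a2 == al)
      p <- sum(x) / (2 * n)
      h <- sum(het & x == 1L) / n
      B <- B + (n / (n - 1)) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
      C <- C + h / 2
    }
  }
  if (B + C == 0) return(NA_real_)
  1 - C / (B + C)
}

## ---------------------------------------------------------------------------
## Diversity statistics
## ---------------------------------------------------------------------------

#' Per-deme diversity statistics
#'
#' Mean number of alleles per locus (\code{NA_}), rarefied allelic richness
#' \code{AR} at \code{g} gene copies (hypergeometric rarefaction, averaged
#' over loci), observed heterozygosity \code{HO}, Nei's unbiased expected
#' heterozygosity \code{HE}, Weir-Cockerham \code{FIS}, and (optionally) a
#' per-deme Hardy-Weinberg exact p combined over loci by Fisher's method.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param g rarefaction size in gene copies; default the minimum gene-copy
#'   count over demes and loci. Cells with fewer than \code{g} copies give
#'   \code{NA} and propagate to the deme mean.
#' @param hwe if \code{TRUE}, run \code{\link{hweTest}} per deme x locus and
#'   combine over loci.
#' @param n_mc,seed Monte-Carlo settings forwarded to \code{\link{hweTest}}.
#' @return data.frame with one row per deme: \code{deme}, \code{N},
#'   \code{NA_}, \code{AR}, \code{HO}, \code{HE}, \code{FIS}, \code{HWE_p}.
#' @export
diversityStats <- function(dataset, g = NULL, hwe = FALSE, n_mc = 10000,
                           seed = NULL) {
  D <- nDemes(dataset); L <- nLoci(dataset)
  af <- alleleFrequencies(dataset, "demes")
  if (is.null(g)) g <- min(af$size)
  if (g < 2) vlError("volescape_rarefaction_error", "rarefaction size g must be >= 2")
  res <- data.frame(deme = demeNames(dataset), N = dataset@demes$n,
                    NA_ = NA_real_, AR = NA_real_, HO = NA_real_,
                    HE = NA_real_, FIS = NA_real_, HWE_p = NA_real_)
  for (d in seq_len(D)) {
    idx <- which(dataset@indiv$deme == d)
    na_l <- ar_l <- ho_l <- he_l <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      a1 <- dataset@alleles[idx, l, 1]; a2 <- dataset@alleles[idx, l, 2]
      ok <- !is.na(a1)
      if (!any(ok)) next
      a1 <- a1[ok]; a2 <- a2[ok]
      copies <- c(a1, a2); n2 <- length(copies)
      cnt <- table(copies)
      na_l[l] <- length(cnt)
      ho_l[l] <- mean(a1 != a2)
      p <- as.numeric(cnt) / n2
      he_l[l] <- (n2 / (n2 - 1)) * (1 - sum(p^2))
      if (n2 >= g)
        ar_l[l] <- sum(1 - exp(lchoose(n2 - as.numeric(cnt), g) - lchoose(n2, g)))
    }
    res$NA_[d] <- mean(na_l, na.rm = TRUE)
    res$AR[d] <- mean(ar_l)              # NA propagates when any cell < g
    res$HO[d] <- mean(ho_l, na.rm = TRUE)
    res$HE[d] <- mean(he_l, na.rm = TRUE)
    res$FIS[d] <- wcFisDeme(dataset, d)
    if (hwe) {
      ps <- vapply(seq_len(L), function(l) {
        sd_l <- if (is.null(seed)) NULL else deriveSeed(seed, paste0("hwe", d, "_", l))
        hweTest(dataset, d, l, n_mc = n_mc, seed = sd_l)$p
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      res$HWE_p[d] <- if (length(ps))
        pchisq(-2 * sum(log(ps)), df = 2 * length(ps), lower.tail = FALSE)
      else NA_real_
    }
  }
  attr(res, "g") <- g
  res
}

#' Permutation test of the within-deme inbreeding coefficient
#'
#' Two-sided test of Weir-Cockerham f for one deme: alleles are shuffled
#' among that deme's gene copies independently at each locus, breaking the
#' within-individual association while preserving allele frequencies.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param deme deme index or name.
#' @param n_perm number of permutations.
#' @param seed RNG seed (required).
#' @return list with \code{fis} and two-sided \code{p}.
#' @export
fisTest <- function(dataset, deme, n_perm = 10000, seed) {
  if (is.character(deme)) deme <- match(deme, demeNames(dataset))
  obs <- wcFisDeme(dataset, deme)
  if (is.na(obs)) return(list(fis = NA_real_, p = NA_real_))
  idx <- which(dataset@indiv$deme == deme)
  sub <- dataset@alleles[idx, , , drop = FALSE]
  withSeed(seed, {
    hits <- 0L
    perm <- dataset
    for (b in seq_len(n_perm)) {
      arr <- sub
      for (l in seq_len(nLoci(dataset))) {
        copies <- c(arr[, l, 1], arr[, l, 2])
        ok <- !is.na(copies)
        copies[ok] <- sample(copies[ok])
        m <- matrix(copies, ncol = 2)
        arr[, l, 1] <- m[, 1]; arr[, l, 2] <- m[, 2]
      }
      perm@alleles[idx, , ] <- arr
      if (abs(wcFisDeme(perm, deme)) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    list(fis = obs, p = addOneP(hits, n_perm))
  })
}

## ---------------------------------------------------------------------------
## F_ST
## ---------------------------------------------------------------------------

#' Pairwise Weir-Cockerham theta with permutation p-values
#'
#' Theta per deme pair from variance components summed over loci; the null is
#' generated by permuting individuals between the two demes.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param n_perm permutations per pair (>= 1).
#' @param seed RNG seed.
#' @return list with \code{theta} (symmetric matrix, zero diagonal), \code{p}
#'   (permutation p-values, one-sided for theta* >= theta), \code{n_perm}.
#'   Pairs involving a deme with < 2 individuals are \code{NA}.
#' @export
fstMatrix <- function(dataset, n_perm = 999, seed = NULL) {
  D <- nDemes(dataset)
  if (D < 2) vlError("volescape_deme_error", "need >= 2 demes")
  th <- pairMatrix(D, demeNames(dataset))
  pm <- pairMatrix(D, demeNames(dataset), diag = NA)
  diag(pm) <- NA_real_
  pairs <- allPairs(D)
  withSeed(seed, {
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (dataset@demes$n[i] < 2 || dataset@demes$n[j] < 2) {
        th[i, j] <- th[j, i] <- NA_real_
        next
      }
      idx <- which(dataset@indiv$deme %in% c(i, j))
      deme <- dataset@indiv$deme[idx]
      a1m <- dataset@alleles[idx, , 1, drop = FALSE]
      a2m <- dataset@alleles[idx, , 2, drop = FALSE]
      thetaOf <- function(dm) {
        comp <- t(vapply(seq_len(nLoci(dataset)), function(l)
          wcLocusComponents(a1m[, l, 1], a2m[, l, 1], dm), numeric(3)))
        wcThetaFromComponents(comp)
      }
      obs <- thetaOf(deme)
      th[i, j] <- th[j, i] <- obs
      if (!is.na(obs) && n_perm >= 1) {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          tb <- thetaOf(sample(deme))
          if (!is.na(tb) && tb >= obs - 1e-12) hits <- hits + 1L
        }
        pm[i, j] <- pm[j, i] <- addOneP(hits, n_perm)
      }
    }
  })
  list(theta = th, p = pm, n_perm = n_perm)
}

#' Overall Weir-Cockerham theta with a bootstrap-over-loci CI
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param n_boot bootstrap replicates (loci resampled with replacement).
#' @param seed RNG seed.
#' @param level CI level.
#' @return list with \code{theta}, \code{ci} (percentile bounds, \code{NA}
#'   with a single locus), \code{level}, \code{perLocus} data.frame of
#'   components.
#' @export
fstOverall <- function(dataset, n_boot = 1000, seed = NULL, level = 0.95) {
  comp <- wcComponents(dataset)
  theta <- wcThetaFromComponents(comp)
  ci <- c(NA_real_, NA_real_)
  if (nLoci(dataset) >= 2 && n_boot >= 1) {
    boot <- withSeed(seed, vapply(seq_len(n_boot), function(b) {
      li <- sample.int(nLoci(dataset), replace = TRUE)
      wcThetaFromComponents(comp[li, , drop = FALSE])
    }, numeric(1)))
    alpha <- (1 - level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(theta = theta, ci = ci, level = level,
       perLocus = data.frame(locus = lociNames(dataset), a = comp[, 1],
                             b = comp[, 2], c = comp[, 3]))
}

#' Linearize a differentiation matrix
#'
#' Elementwise \code{x / (1 - x)}; negative entries pass through the same
#' formula unchanged (no truncation). Entries >= 1 are an error.
#'
#' @param m numeric matrix (or vector).
#' @return transformed object of the same shape.
#' @export
linearizedFst <- function(m) {
  if (any(m >= 1, na.rm = TRUE))
    vlError("volescape_linearize_error", "entries must be < 1")
  m / (1 - m)
}

## ---------------------------------------------------------------------------
## Hardy-Weinberg exact test
## ---------------------------------------------------------------------------

## log-probability of a genotype-count table conditional on allele counts:
## log[ n! 2^H prod(m_a!) / ( (2n)! prod(n_ab!) ) ]
hweLogProb <- function(counts, alleleCounts, n) {
  het <- counts[upper.tri(counts)]
  hom <- diag(counts)
  lgamma(n + 1) + sum(het) * log(2) + sum(lgamma(alleleCounts + 1)) -
    lgamma(2 * n + 1) - sum(lgamma(het + 1)) - sum(lgamma(hom + 1))
}

## Enumerate genotype tables with the given allele-count margins, calling
## fun(logprob) for each. Returns the number of tables, or -1 if the visit
## cap was exceeded (enumeration aborted).
hweEnumerate <- function(alleleCounts, cap = 1e5, fun = NULL) {
  k <- length(alleleCounts)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  n <- sum(alleleCounts) / 2
  count <- 0L
  tab <- matrix(0L, k, k)
  rem <- as.integer(alleleCounts)
  nCells <- nrow(cells)
  recurse <- function(ci) {
    if (count < 0) return()
    if (ci > nCells) {
      if (all(rem == 0L)) {
        count <<- count + 1L
        if (count > cap) { count <<- -1L; return() }
        if (!is.null(fun)) fun(hweLogProb(tab, alleleCounts, n))
      }
      return()
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    maxv <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    ## cells are ordered so that (i,i) comes before (i, j>i); after the last
    ## cell of row i no more copies of allele i can be placed
    lastOfRow <- ci == nCells || cells[ci + 1, 1] > i
    for (v in 0:maxv) {
      if (i == j) rem[i] <<- rem[i] - 2L * v else {
        rem[i] <<- rem[i] - v; rem[j] <<- rem[j] - v
      }
      tab[i, j] <<- v
      if (!(lastOfRow && rem[i] != 0L)) recurse(ci + 1L)
      if (i == j) rem[i] <<- rem[i] + 2L * v else {
        rem[i] <<- rem[i] + v; rem[j] <<- rem[j] + v
      }
      tab[i, j] <<- 0L
      if (count < 0) return()
    }
  }
  recurse(1L)
  count
}

## cheap upper bound on the number of genotype tables with these margins:
## product over upper-triangle cells of (1 + max cell value). Used only to
## decide whether complete enumeration is worth attempting.
hweTableBound <- function(alleleCounts) {
  k <- length(alleleCounts)
  b <- 1
  for (i in seq_len(k)) for (j in i:k) {
    b <- b * (1 + if (i == j) alleleCounts[i] %/% 2 else
      min(alleleCounts[i], alleleCounts[j]))
    if (b > 1e12) return(Inf)
  }
  b
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Probability-ordering exact test conditional on allele counts: the p-value
#' sums the conditional probabilities of all genotype tables no more probable
#' than the observed one. Complete enumeration is used while the table count
#' stays below \code{enum_cap}; beyond that a Monte-Carlo version pairs the
#' gene copies at random (add-one rule).
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param deme deme index or name.
#' @param locus locus index or name.
#' @param method \code{"auto"}, \code{"enum"} or \code{"mc"}.
#' @param n_mc Monte-Carlo draws (>= 1e4 recommended).
#' @param seed RNG seed; required whenever the Monte-Carlo path runs.
#' @param enum_cap maximum number of tables for complete enumeration.
#' @return list with \code{p}, \code{method} ("enum" or "mc"), and
#'   \code{statistic} (log conditional probability of the observed table).
#'   Monomorphic data give p = 1 by convention.
#' @export
hweTest <- function(dataset, deme, locus, method = c("auto", "enum", "mc"),
                    n_mc = 10000, seed = NULL, enum_cap = 1e5) {
  method <- match.arg(method)
  if (is.character(deme)) deme <- match(deme, demeNames(dataset))
  calls <- locusCalls(dataset, locus)[dataset@indiv$deme == deme, , drop = FALSE]
  calls <- calls[!is.na(calls[, 1]), , drop = FALSE]
  if (nrow(calls) < 2)
    vlError("volescape_hwe_error", "need >= 2 non-missing calls")
  alleles <- sort(unique(c(calls)))
  k <- length(alleles)
  if (k < 2) return(list(p = 1, method = "enum", statistic = 0))
  ai <- matrix(match(calls, alleles), ncol = 2)
  n <- nrow(ai)
  tab <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    a <- min(ai[i, ]); b <- max(ai[i, ])
    tab[a, b] <- tab[a, b] + 1L
  }
  m <- tabulate(c(ai), nbins = k)
  obsLog <- hweLogProb(tab, m, n)
  eps <- 1e-9

  tryEnum <- method == "enum" ||
    (method == "auto" && hweTableBound(m) <= 50 * enum_cap)
  if (tryEnum) {
    ## single pass: accumulate the p-sum while enumerating; abort at the cap
    psum <- 0
    cnt <- hweEnumerate(m, cap = if (method == "enum") Inf else enum_cap,
                        fun = function(lp) if (lp <= obsLog + eps)
                          psum <<- psum + exp(lp))
    if (cnt > 0)
      return(list(p = min(psum, 1), method = "enum", statistic = obsLog))
  }
  if (is.null(seed))
    vlError("volescape_seed_error", "Monte-Carlo HWE test needs a seed")
  copies <- c(ai)
  ## log constant part: n! + sum(m_a!) - (2n)!
  constLog <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1)
  withSeed(seed, {
    hits <- 0L
    nc2 <- 2L * n
    for (b in seq_len(n_mc)) {
      perm <- copies[sample.int(nc2)]
      lo <- pmin(perm[1:n], perm[(n + 1):nc2])
      hi <- pmax(perm[1:n], perm[(n + 1):nc2])
      het <- sum(lo != hi)
      cellCnt <- tabulate((lo - 1L) * k + hi, nbins = k * k)
      lp <- constLog + het * log(2) - sum(lgamma(cellCnt[cellCnt > 0L] + 1))
      if (lp <= obsLog + eps) hits <- hits + 1L
    }
    list(p = addOneP(hits, n_mc), method = "mc", statistic = obsLog)
  })
}

## ---------------------------------------------------------------------------
## Linkage disequilibrium
## ---------------------------------------------------------------------------

gStatistic <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / E[nz]))
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Per deme, a log-likelihood-ratio G statistic on the genotype x genotype
#' contingency table with a permutation p-value (locus-B genotypes shuffled
#' among that deme's individuals); informative demes are combined into a
#' global p by Fisher's method.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param locusA,locusB locus names or indices.
#' @param n_perm permutations per deme.
#' @param seed RNG seed.
#' @return list with global \code{p} (\code{NA} if no deme is informative),
#'   \code{perDeme} data.frame (deme, G, p), \code{method = "MC"}.
#' @export
ldTest <- function(dataset, locusA, locusB, n_perm = 1000, seed = NULL) {
  cA <- locusCalls(dataset, locusA); cB <- locusCalls(dataset, locusB)
  gA <- paste(pmin(cA[, 1], cA[, 2]), pmax(cA[, 1], cA[, 2]), sep = "/")
  gB <- paste(pmin(cB[, 1], cB[, 2]), pmax(cB[, 1], cB[, 2]), sep = "/")
  okAll <- !is.na(cA[, 1]) & !is.na(cB[, 1])
  per <- data.frame(deme = demeNames(dataset), G = NA_real_, p = NA_real_)
  withSeed(seed, {
    for (d in seq_len(nDemes(dataset))) {
      idx <- which(dataset@indiv$deme == d & okAll)
      if (length(idx) < 2) next
      fa <- factor(gA[idx]); fb <- factor(gB[idx])
      if (nlevels(fa) < 2 || nlevels(fb) < 2) next
      tab <- table(fa, fb)
      obs <- gStatistic(tab)
      if (is.na(obs)) next
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gs <- gStatistic(table(fa, sample(fb)))
        if (!is.na(gs) && gs >= obs - 1e-9) hits <- hits + 1L
      }
      per$G[d] <- obs
      per$p[d] <- addOneP(hits, n_perm)
    }
  })
  ps <- per$p[!is.na(per$p)]
  globalP <- if (!length(ps)) NA_real_ else
    pchisq(-2 * sum(log(ps)), df = 2 * length(ps), lower.tail = FALSE)
  list(p = globalP, perDeme = per, method = "MC")
}

#' Drop loci in strong linkage disequilibrium
#'
#' Tests every locus pair with \code{\link{ldTest}}; for each pair with a
#' global p below \code{alpha} the member with fewer distinct alleles is
#' removed (ties: the later locus in file order). Removal is applied in one
#' pass over the pairs sorted by p ascending, skipping pairs already broken
#' by an earlier removal.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param alpha significance level (default 0.001).
#' @param n_perm,seed forwarded to \code{\link{ldTest}}.
#' @return list with \code{dataset} (filtered), \code{dropped} (locus names),
#'   \code{pairs} (data.frame of all tested pairs and global p).
#' @export
ldFilter <- function(dataset, alpha = 0.001, n_perm = 1000, seed = NULL) {
  L <- nLoci(dataset)
  prs <- allPairs(L)
  if (!ncol(prs))
    return(list(dataset = dataset, dropped = character(),
                pairs = data.frame()))
  res <- data.frame(locusA = dataset@loci[prs[1, ]],
                    locusB = dataset@loci[prs[2, ]], p = NA_real_)
  for (k in seq_len(ncol(prs))) {
    sd_k <- if (is.null(seed)) NULL else deriveSeed(seed, paste0("ld", k))
    res$p[k] <- ldTest(dataset, prs[1, k], prs[2, k], n_perm = n_perm,
                       seed = sd_k)$p
  }
  nAll <- vapply(seq_len(L), function(l) {
    v <- c(dataset@alleles[, l, ])
    length(unique(v[!is.na(v)]))
  }, integer(1))
  present <- rep(TRUE, L)
  ord <- order(res$p)
  for (k in ord) {
    if (is.na(res$p[k]) || res$p[k] >= alpha) next
    i <- prs[1, k]; j <- prs[2, k]
    if (!present[i] || !present[j]) next
    drop <- if (nAll[i] < nAll[j]) i else if (nAll[j] < nAll[i]) j else max(i, j)
    present[drop] <- FALSE
  }
  dropped <- dataset@loci[!present]
  out <- if (length(dropped)) subsetDataset(dataset, loci = which(present))
         else dataset
  list(dataset = out, dropped = dropped, pairs = res)
}
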