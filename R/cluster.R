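## Model-based genetic clustering (no-admixture Gibbs sampler on the
## HWE-within-cluster mixture model) with Delta-K selection, plus a
## three-level hierarchical AMOVA on allele-identity distances.

## integer-recoded alleles per locus: list over loci of n x 2 matrices with
## codes 1..A_l (NA for missing), plus allele counts A_l.
recodeAlleles <- function(dataset) {
  lapply(seq_len(nLoci(dataset)), function(l) {
    m <- cbind(dataset@alleles[, l, 1], dataset@alleles[, l, 2])
    lev <- sort(unique(c(m[!is.na(m)])))
    list(codes = matrix(match(m, lev), ncol = 2), nAlleles = length(lev))
  })
}

#' No-admixture Gibbs clustering
#'
#' Alternates two conditional draws: cluster allele frequencies from
#' Dirichlet(1 + counts), and individual cluster labels proportional to the
#' multilocus genotype likelihood under Hardy-Weinberg proportions within
#' each cluster. Assignment probabilities are the conditional membership
#' probabilities averaged over post-burn-in sweeps; the log model evidence is
#' estimated as mean(logL) - var(logL)/2 over the same sweeps.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param K number of clusters (>= 1, <= number of individuals).
#' @param n_iter total Gibbs sweeps.
#' @param burnin sweeps discarded (< n_iter).
#' @param seed RNG seed.
#' @return a \linkS4class{ClusterModel}.
#' @export
gibbsCluster <- function(dataset, K, n_iter = 20000, burnin = 5000,
                         seed = NULL) {
  n <- nInd(dataset); L <- nLoci(dataset)
  K <- as.integer(K)
  if (K < 1) vlError("volescape_cluster_error", "K must be >= 1")
  if (K > n) vlError("volescape_cluster_error", "K exceeds number of individuals")
  if (n_iter <= burnin)
    vlError("volescape_cluster_error", "n_iter must exceed burnin")
  rec <- recodeAlleles(dataset)
  het <- vapply(rec, function(r) {
    h <- r$codes[, 1] != r$codes[, 2]
    h[is.na(h)] <- FALSE
    h
  }, logical(n))
  het <- matrix(het, nrow = n)
  withSeed(seed, {
    z <- sample.int(K, n, replace = TRUE)
    Qsum <- matrix(0, n, K)
    logLik <- numeric(n_iter)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      ## genotype log-likelihood of each individual under each cluster
      M <- matrix(0, n, K)
      for (l in seq_len(L)) {
        cd <- rec[[l]]$codes; A <- rec[[l]]$nAlleles
        ok <- !is.na(cd[, 1])
        ## allele counts per cluster (current z), Dirichlet(1 + counts) draw
        logp <- matrix(0, A, K)
        for (k in seq_len(K)) {
          sel <- ok & z == k
          cnt <- tabulate(c(cd[sel, 1], cd[sel, 2]), nbins = A)
          gm <- rgamma(A, shape = 1 + cnt)
          logp[, k] <- log(gm / sum(gm))
        }
        contrib <- logp[cd[ok, 1], , drop = FALSE] +
                   logp[cd[ok, 2], , drop = FALSE] +
                   log(2) * het[ok, l]
        M[ok, ] <- M[ok, ] + contrib
      }
      ## sample labels by the Gumbel-max trick (exact categorical draw)
      if (K > 1) {
        gum <- -log(-log(matrix(runif(n * K), n, K)))
        z <- max.col(M + gum, ties.method = "first")
      }
      logLik[it] <- sum(M[cbind(seq_len(n), z)])
      if (it > burnin) {
        Mm <- M - apply(M, 1, max)
        P <- exp(Mm); P <- P / rowSums(P)
        Qsum <- Qsum + P
        kept <- kept + 1L
      }
    }
    post <- logLik[(burnin + 1):n_iter]
    new("ClusterModel", K = K, Q = Qsum / kept, logLik = logLik,
        logEvidence = mean(post) - var(post) / 2,
        burnin = as.integer(burnin),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Select K by the rate of change of the log evidence
#'
#' Runs \code{\link{gibbsCluster}} \code{n_reps} times per K = 1..Kmax and
#' computes, for interior K, DeltaK = |mean L(K+1) - 2 mean L(K) +
#' mean L(K-1)| / sd L(K).
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param Kmax largest K (>= 3 for DeltaK to exist).
#' @param n_reps replicate runs per K (>= 2).
#' @param n_iter,burnin forwarded to \code{\link{gibbsCluster}}.
#' @param seed master seed; replicate seeds are derived from it.
#' @return list with \code{table} (K, meanL, sdL, deltaK; deltaK is NA at the
#'   boundary K and when sd = 0), \code{bestK} (argmax deltaK) and
#'   \code{models} (the fitted models of the best replicate per K).
#' @export
selectK <- function(dataset, Kmax, n_reps = 10, n_iter = 20000,
                    burnin = 5000, seed = NULL) {
  if (Kmax < 3) vlError("volescape_cluster_error", "Kmax must be >= 3 for DeltaK")
  if (n_reps < 2) vlError("volescape_cluster_error", "need n_reps >= 2")
  Ls <- matrix(NA_real_, Kmax, n_reps)
  best <- vector("list", Kmax)
  for (K in seq_len(Kmax)) {
    for (r in seq_len(n_reps)) {
      sd_r <- if (is.null(seed)) NULL else deriveSeed(seed, paste0("K", K, "r", r))
      m <- gibbsCluster(dataset, K, n_iter = n_iter, burnin = burnin,
                        seed = sd_r)
      Ls[K, r] <- logEvidence(m)
      if (is.null(best[[K]]) || Ls[K, r] >= max(Ls[K, seq_len(r - 1)], -Inf))
        best[[K]] <- m
    }
  }
  meanL <- rowMeans(Ls); sdL <- apply(Ls, 1, sd)
  deltaK <- rep(NA_real_, Kmax)
  for (K in 2:(Kmax - 1)) {
    if (sdL[K] > 0)
      deltaK[K] <- abs(meanL[K + 1] - 2 * meanL[K] + meanL[K - 1]) / sdL[K]
  }
  tab <- data.frame(K = seq_len(Kmax), meanL = meanL, sdL = sdL,
                    deltaK = deltaK)
  bestK <- if (all(is.na(deltaK))) NA_integer_ else which.max(deltaK)
  list(table = tab, bestK = bestK, models = best)
}

#' Deme-level cluster labels
#'
#' Labels each deme by the cluster with the highest mean assignment
#' probability over its members; ties go to the lower cluster index with a
#' warning.
#'
#' @param model a fitted \linkS4class{ClusterModel}.
#' @param dataset the \linkS4class{GenotypeDataset} the model was fitted to.
#' @return named integer vector, deme name -> cluster index.
#' @export
demeClusterLabels <- function(model, dataset) {
  Q <- assignmentProbs(model)
  out <- integer(nDemes(dataset))
  for (d in seq_len(nDemes(dataset))) {
    qm <- colMeans(Q[dataset@indiv$deme == d, , drop = FALSE])
    top <- which(qm >= max(qm) - 1e-12)
    if (length(top) > 1)
      warning("deme ", demeNames(dataset)[d], ": tied cluster probabilities, ",
              "taking the lower index")
    out[d] <- min(top)
  }
  setNames(out, demeNames(dataset))
}

## ---------------------------------------------------------------------------
## AMOVA
## ---------------------------------------------------------------------------

## Sum over unordered pairs within a set of gene copies of the allele-identity
## distance (0 same allele, 1 different) = C(N,2) - sum_a C(n_a, 2).
ssPairs <- function(alleleCounts) {
  N <- sum(alleleCounts)
  choose(N, 2) - sum(choose(alleleCounts, 2))
}

## Per-locus AMOVA pieces for a deme->cluster grouping. `copies` is a vector
## of allele codes for one locus; demeOf the deme of each copy. Returns the
## three variance components.
amovaLocus <- function(copies, demeOf, clusterOfDeme) {
  ok <- !is.na(copies)
  copies <- copies[ok]; demeOf <- demeOf[ok]
  demes <- sort(unique(demeOf))
  clusters <- clusterOfDeme[demes]
  G <- length(unique(clusters)); P <- length(demes); N <- length(copies)
  if (G < 2 || P < 2 || N < 2) return(NULL)
  Np <- vapply(demes, function(d) sum(demeOf == d), numeric(1))
  names(Np) <- demes
  Ng <- tapply(Np, clusters, sum)
  ## pairwise-difference sums from allele-count tables
  ssWithin <- function(sel) ssPairs(table(copies[sel]))
  SS_T <- ssWithin(rep(TRUE, N)) / N
  SS_WP <- sum(vapply(demes, function(d) {
    sel <- demeOf == d
    ssWithin(sel) / sum(sel)
  }, numeric(1)))
  SS_g <- sum(vapply(unique(clusters), function(g) {
    sel <- demeOf %in% demes[clusters == g]
    ssWithin(sel) / sum(sel)
  }, numeric(1)))
  SS_AP <- SS_g - SS_WP
  SS_AG <- SS_T - SS_g
  df_AG <- G - 1; df_AP <- P - G; df_WP <- N - P
  MS_WP <- SS_WP / df_WP
  MS_AP <- if (df_AP > 0) SS_AP / df_AP else NA_real_
  MS_AG <- SS_AG / df_AG
  ## coefficients for unequal sizes
  sumNp2byNg <- sum(tapply(Np^2, clusters, sum) / Ng)
  n1 <- if (df_AP > 0) (N - sumNp2byNg) / df_AP else NA_real_
  n2 <- (sumNp2byNg - sum(Np^2) / N) / df_AG
  n3 <- (N - sum(Ng^2) / N) / df_AG
  sc <- MS_WP
  sb <- if (df_AP > 0) (MS_AP - sc) / n1 else 0
  sa <- (MS_AG - sc - n2 * sb) / n3
  c(sa = sa, sb = sb, sc = sc)
}

amovaComponents <- function(dataset, clusterOfDeme) {
  n <- nInd(dataset)
  demeOfCopy <- rep(dataset@indiv$deme, 2)
  tot <- c(sa = 0, sb = 0, sc = 0)
  for (l in seq_len(nLoci(dataset))) {
    copies <- c(dataset@alleles[, l, 1], dataset@alleles[, l, 2])
    comp <- amovaLocus(copies, demeOfCopy, clusterOfDeme)
    if (!is.null(comp)) tot <- tot + comp
  }
  tot
}

#' Three-level hierarchical AMOVA
#'
#' Partitions gene-copy variance (allele-identity distance: 0 if the same
#' allele, 1 otherwise -- the infinite-alleles metric) into between clusters,
#' between demes within clusters, and between gene copies within demes.
#' Components are computed per locus (missing calls excluded per locus) and
#' summed over loci. Negative components are retained.
#'
#' Significance by permutation: F_SC permutes individuals among demes within
#' their cluster; F_CT permutes whole demes among clusters (preserving
#' cluster sizes in demes); F_ST permutes individuals among all demes.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param labels named integer vector deme name (or index order) -> cluster.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list with \code{table} (data.frame: level, sigma2, percent, index
#'   name, index value, p), \code{components}, \code{nPerm}.
#' @export
amova <- function(dataset, labels, n_perm = 10000, seed = NULL) {
  D <- nDemes(dataset)
  if (!is.null(names(labels)))
    labels <- labels[match(demeNames(dataset), names(labels))]
  if (anyNA(labels) || length(labels) != D)
    vlError("volescape_amova_error", "every deme needs a cluster label")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    vlError("volescape_amova_error",
            "between-cluster level undefined with a single cluster")
  ratio <- function(num, den) if (!is.finite(den) || den == 0) NA_real_
                              else num / den
  obs <- amovaComponents(dataset, labels)
  tot <- sum(obs)
  fct <- ratio(obs[["sa"]], tot)
  fsc <- ratio(obs[["sb"]], obs[["sb"]] + obs[["sc"]])
  fst <- ratio(obs[["sa"]] + obs[["sb"]], tot)

  hitsCT <- hitsSC <- hitsST <- 0L
  withSeed(seed, {
    indDeme <- dataset@indiv$deme
    for (b in seq_len(n_perm)) {
      ## F_SC: individuals among demes within clusters
      if (!is.na(fsc)) {
        permDeme <- indDeme
        for (g in unique(labels)) {
          demesIn <- which(labels == g)
          sel <- indDeme %in% demesIn
          permDeme[sel] <- sample(indDeme[sel])
        }
        cSC <- amovaPermComponents(dataset, permDeme, labels)
        if (isTRUE(ratio(cSC[["sb"]], cSC[["sb"]] + cSC[["sc"]]) >=
                   fsc - 1e-12)) hitsSC <- hitsSC + 1L
      }
      ## F_CT: demes among clusters
      if (!is.na(fct)) {
        cCT <- amovaComponents(dataset, sample(labels))
        if (isTRUE(ratio(cCT[["sa"]], sum(cCT)) >= fct - 1e-12))
          hitsCT <- hitsCT + 1L
      }
      ## F_ST: individuals among all demes
      if (!is.na(fst)) {
        cST <- amovaPermComponents(dataset, sample(indDeme), labels)
        if (isTRUE(ratio(cST[["sa"]] + cST[["sb"]], sum(cST)) >=
                   fst - 1e-12)) hitsST <- hitsST + 1L
      }
    }
  })
  pct <- 100 * obs / tot
  tab <- data.frame(
    level = c("between clusters", "between demes within clusters",
              "within demes"),
    sigma2 = as.numeric(obs),
    percent = as.numeric(pct),
    index = c("F_CT", "F_SC", "F_ST"),
    value = as.numeric(c(fct, fsc, fst)),
    p = c(if (is.na(fct)) NA_real_ else addOneP(hitsCT, n_perm),
          if (is.na(fsc)) NA_real_ else addOneP(hitsSC, n_perm),
          if (is.na(fst)) NA_real_ else addOneP(hitsST, n_perm)))
  list(table = tab, components = obs, nPerm = n_perm)
}

## components under a permuted individual->deme map
amovaPermComponents <- function(dataset, permDeme, labels) {
  ds <- dataset
  ds@indiv$deme <- permDeme
  amovaComponents(ds, labels)
}
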