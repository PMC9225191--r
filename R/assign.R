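## First-generation migrant detection by home-deme likelihood (L_home):
## the likelihood of an individual's multilocus genotype given its sampling
## deme's allele frequencies, with Monte-Carlo significance.

## -log10 genotype likelihood for one individual given per-locus frequency
## vectors (named by allele code). Alleles absent from the reference get
## `missing_allele_freq`. Missing calls contribute factor 1.
lhomeFromFreqs <- function(a1, a2, freqs, missing_allele_freq = 0.01) {
  tot <- 0
  for (l in seq_along(freqs)) {
    if (is.na(a1[l])) next
    f <- freqs[[l]]
    p <- f[as.character(a1[l])]; q <- f[as.character(a2[l])]
    if (is.na(p) || p <= 0) p <- missing_allele_freq
    if (is.na(q) || q <= 0) q <- missing_allele_freq
    g <- if (a1[l] == a2[l]) p * q else 2 * p * q
    tot <- tot - log10(g)
  }
  unname(tot)
}

## leave-one-out allele frequencies of one deme for one individual
looFreqs <- function(dataset, ind) {
  d <- dataset@indiv$deme[ind]
  idx <- setdiff(which(dataset@indiv$deme == d), ind)
  lapply(seq_len(nLoci(dataset)), function(l) {
    al <- c(dataset@alleles[idx, l, 1], dataset@alleles[idx, l, 2])
    al <- al[!is.na(al)]
    if (!length(al)) return(setNames(numeric(), character()))
    tab <- table(al)
    setNames(as.numeric(tab) / length(al), names(tab))
  })
}

#' Home-deme likelihood of one individual
#'
#' -log10 of the product over loci of Hardy-Weinberg genotype probabilities
#' (2pq heterozygote, p^2 homozygote) under the individual's home-deme allele
#' frequencies, computed leave-one-out (the focal individual's own alleles
#' are removed from the reference counts). Alleles absent from the home deme
#' are given \code{missing_allele_freq}.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param ind individual row index.
#' @param missing_allele_freq substitute frequency for unseen alleles.
#' @return -log10 L_home (0 = perfectly typical genotype).
#' @export
lhomeScore <- function(dataset, ind, missing_allele_freq = 0.01) {
  lhomeFromFreqs(dataset@alleles[ind, , 1], dataset@alleles[ind, , 2],
                 looFreqs(dataset, ind), missing_allele_freq)
}

#' Detect first-generation migrants
#'
#' For each deme, \code{n_mc} genotypes are simulated by drawing two alleles
#' per locus from the deme's (plug-in) allele frequencies; an individual is
#' flagged as a non-resident when its leave-one-out L_home falls below the
#' \code{alpha} quantile of its deme's simulated L_home distribution
#' (add-one percentile rank). The genetically closest deme (maximum plug-in
#' likelihood) is reported descriptively.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param n_mc Monte-Carlo genotypes per deme.
#' @param alpha flagging level (default 0.01).
#' @param missing_allele_freq substitute frequency for unseen alleles.
#' @param seed RNG seed.
#' @return data.frame per individual: \code{id}, \code{deme},
#'   \code{neg_log10_lhome}, \code{percentile} (add-one MC rank of the
#'   likelihood), \code{flagged}, \code{closest_deme}. Attribute
#'   \code{"deme_flags"}: flag counts per deme.
#' @export
detectMigrants <- function(dataset, n_mc = 10000, alpha = 0.01,
                           missing_allele_freq = 0.01, seed = NULL) {
  n <- nInd(dataset); L <- nLoci(dataset); D <- nDemes(dataset)
  af <- alleleFrequencies(dataset, "demes")
  ## allele-count tables per deme x locus
  cnts <- lapply(seq_len(D), function(d)
    lapply(seq_len(L), function(l) {
      f <- af$freq[[d]][[l]]
      list(codes = as.integer(names(f)),
           cnt = round(f * af$size[d, l]), tot = af$size[d, l])
    }))
  ## -log10 likelihood of genotype matrices under deme d. With loo = TRUE
  ## the genotype's own two copies are removed from the reference counts
  ## first -- the same leave-one-out scoring applied to sampled individuals,
  ## so observed and simulated scores are exchangeable under the null.
  scoreUnder <- function(a1m, a2m, d, loo) {
    out <- numeric(nrow(a1m))
    for (l in seq_len(L)) {
      ct <- cnts[[d]][[l]]
      c1 <- ct$cnt[match(a1m[, l], ct$codes)]
      c2 <- ct$cnt[match(a2m[, l], ct$codes)]
      c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
      hom <- !is.na(a1m[, l]) & a1m[, l] == a2m[, l]
      if (loo) {
        tot <- ct$tot - 2
        c1 <- pmax(c1 - ifelse(hom, 2, 1), 0)
        c2 <- pmax(c2 - ifelse(hom, 2, 1), 0)
      } else tot <- ct$tot
      p <- c1 / max(tot, 1); q <- c2 / max(tot, 1)
      p[p <= 0] <- missing_allele_freq
      q[q <= 0] <- missing_allele_freq
      g <- ifelse(is.na(a1m[, l]), 1, ifelse(hom, p * q, 2 * p * q))
      out <- out - log10(g)
    }
    out
  }
  a1o <- matrix(dataset@alleles[, , 1], n, L)
  a2o <- matrix(dataset@alleles[, , 2], n, L)
  obs <- vapply(seq_len(n), function(i)
    lhomeScore(dataset, i, missing_allele_freq), numeric(1))
  allScores <- sapply(seq_len(D), function(d) scoreUnder(a1o, a2o, d, FALSE))
  allScores <- matrix(allScores, nrow = n)
  closest <- demeNames(dataset)[max.col(-allScores, ties.method = "first")]
  percentile <- numeric(n)
  withSeed(seed, {
    for (d in seq_len(D)) {
      ## simulate n_mc genotypes from deme d: two gene copies drawn without
      ## replacement per locus, the conditional law of one member's copies
      ## given the sample -- so simulated and observed scores are
      ## exchangeable under the resident null
      sim1 <- matrix(NA_integer_, n_mc, L); sim2 <- matrix(NA_integer_, n_mc, L)
      for (l in seq_len(L)) {
        ct <- cnts[[d]][[l]]
        if (!length(ct$codes) || ct$tot < 2) next
        copyPool <- rep(ct$codes, ct$cnt)
        i1 <- sample.int(ct$tot, n_mc, replace = TRUE)
        i2 <- sample.int(ct$tot - 1, n_mc, replace = TRUE)
        i2 <- i2 + (i2 >= i1)
        sim1[, l] <- copyPool[i1]
        sim2[, l] <- copyPool[i2]
      }
      simScore <- scoreUnder(sim1, sim2, d, TRUE)
      for (i in which(dataset@indiv$deme == d)) {
        ## rank of the observed likelihood among simulated ones:
        ## low percentile = genotype less likely than most residents
        percentile[i] <- addOneP(sum(simScore >= obs[i]), n_mc)
      }
    }
  })
  res <- data.frame(id = dataset@indiv$id,
                    deme = demeNames(dataset)[dataset@indiv$deme],
                    neg_log10_lhome = obs,
                    percentile = percentile,
                    flagged = percentile < alpha,
                    closest_deme = closest)
  flags <- tapply(res$flagged, factor(res$deme, levels = demeNames(dataset)),
                  sum, default = 0L)
  attr(res, "deme_flags") <- flags
  attr(res, "alpha") <- alpha
  res
}
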