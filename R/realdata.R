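## Reproduction of the published deme-level statistics from the deposited
## genotype data. The deposited files are NOT shipped with the package; point
## `dir` (or the option `volescape.dryad_dir`) at a local copy containing the
## Genepop genotype file of the 137 individuals at 12 loci.

#' Locate a local copy of the deposited genotype data
#'
#' Looks in \code{dir}, then \code{getOption("volescape.dryad_dir")}, then
#' \code{inst/extdata/dryad}, for a Genepop file (.gen/.txt/.genepop).
#'
#' @param dir optional directory to search first.
#' @return path to the Genepop file, or \code{NA_character_}.
#' @export
findDepositedData <- function(dir = NULL) {
  dirs <- c(dir, getOption("volescape.dryad_dir"),
            system.file("extdata", "dryad", package = "volescape"))
  dirs <- dirs[!is.na(dirs) & nzchar(dirs)]
  for (d in dirs) {
    if (!dir.exists(d)) next
    hits <- list.files(d, pattern = "\\.(gen|genepop|txt)$", full.names = TRUE,
                       ignore.case = TRUE)
    if (length(hits)) return(hits[1])
  }
  NA_character_
}

#' Recompute the published population-genetic summary from deposited data
#'
#' Runs the deme-level analysis on the deposited 137-vole genotype file:
#' linkage-disequilibrium locus filter (alpha = 0.001), per-locus mean
#' observed and expected heterozygosity on the retained loci, per-deme
#' inbreeding coefficients, overall and pairwise Weir-Cockerham theta with
#' permutation significance.
#'
#' @param dir directory with the deposited Genepop file (see
#'   \code{\link{findDepositedData}}).
#' @param n_perm permutations for the pairwise tests.
#' @param seed RNG seed.
#' @return list with \code{dropped} (filtered loci), \code{overall_theta},
#'   \code{mean_HO}, \code{mean_HE} (per-locus means over the pooled sample),
#'   \code{fis} (per-deme), \code{pairwise} (theta and p matrices),
#'   \code{max_pairwise_theta}, \code{n_significant_pairs} (p < 0.05).
#' @export
realDataReproduction <- function(dir = NULL, n_perm = 999, seed = 1) {
  path <- findDepositedData(dir)
  if (is.na(path))
    vlError("volescape_data_unavailable",
            paste("deposited genotype data not found locally; supply `dir`",
                  "or set options(volescape.dryad_dir = ...)"))
  ds <- readGenepop(path)
  filt <- ldFilter(ds, alpha = 0.001, n_perm = 1000,
                   seed = deriveSeed(seed, "ldfilter"))
  ds2 <- filt$dataset
  ## per-locus H_O / H_E over the pooled sample, averaged across loci
  pooledHet <- function(d) {
    ho <- he <- numeric(nLoci(d))
    for (l in seq_len(nLoci(d))) {
      a1 <- d@alleles[, l, 1]; a2 <- d@alleles[, l, 2]
      ok <- !is.na(a1)
      ho[l] <- mean(a1[ok] != a2[ok])
      copies <- c(a1[ok], a2[ok])
      p <- as.numeric(table(copies)) / length(copies)
      he[l] <- (length(copies) / (length(copies) - 1)) * (1 - sum(p^2))
    }
    c(HO = mean(ho), HE = mean(he))
  }
  het <- pooledHet(ds)          # published means are over all 12 typed loci
  ov <- fstOverall(ds2, n_boot = 1000, seed = deriveSeed(seed, "boot"))
  pw <- fstMatrix(ds2, n_perm = n_perm, seed = deriveSeed(seed, "pairwise"))
  fis <- vapply(seq_len(nDemes(ds2)), function(d) wcFisDeme(ds2, d),
                numeric(1))
  names(fis) <- demeNames(ds2)
  up <- upper.tri(pw$theta)
  list(dropped = filt$dropped,
       overall_theta = ov$theta, theta_ci = ov$ci,
       mean_HO = unname(het["HO"]), mean_HE = unname(het["HE"]),
       fis = fis, pairwise = pw,
       max_pairwise_theta = max(pw$theta[up], na.rm = TRUE),
       n_significant_pairs = sum(pw$p[up] < 0.05, na.rm = TRUE))
}
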