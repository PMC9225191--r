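#' @import methods
#' @importFrom stats cor dist lm.fit pchisq quantile rbinom rgamma rmultinom
#'   rpois runif sd setNames var
#' @importFrom utils combn head read.csv write.table
NULL

## ---------------------------------------------------------------------------
## GenotypeDataset
## ---------------------------------------------------------------------------

#' Diploid multilocus genotypes grouped into demes
#'
#' The universal input container of the package: codominant diploid genotypes
#' (microsatellite allele codes kept verbatim as integers, typically fragment
#' sizes) for individuals assigned to georeferenced demes.
#'
#' @slot loci character vector of unique locus names.
#' @slot demes data.frame with one row per deme, columns \code{name},
#'   \code{easting}, \code{northing} (planar metres, single UTM zone assumed),
#'   \code{area} (hectares), \code{date} (character, year-month) and \code{n}
#'   (individual count). Row order defines the 0-based deme index + 1.
#' @slot indiv data.frame with columns \code{id}, \code{deme} (integer index
#'   into \code{demes}) and \code{sex} (character, may be \code{NA}; stored,
#'   unused by the statistics).
#' @slot alleles integer array \code{[nInd, nLoci, 2]}; a missing call is
#'   \code{NA} in both allele positions (half-missing calls are invalid).
#'
#' @export
setClass("GenotypeDataset",
  representation(loci = "character", demes = "data.frame",
                 indiv = "data.frame", alleles = "array"))

setValidity("GenotypeDataset", function(object) {
  msg <- character()
  if (anyDuplicated(object@loci))
    msg <- c(msg, "locus names must be unique")
  need <- c("name", "easting", "northing", "area", "date", "n")
  if (!all(need %in% names(object@demes)))
    msg <- c(msg, paste("demes needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@demes$name))
      msg <- c(msg, "deme names must be unique")
    if (!all(is.finite(object@demes$easting)) ||
        !all(is.finite(object@demes$northing)))
      msg <- c(msg, "deme coordinates must be finite")
    if (any(object@demes$n < 1))
      msg <- c(msg, "every deme needs n >= 1")
  }
  d <- dim(object@alleles)
  if (length(d) != 3L || d[3] != 2L)
    msg <- c(msg, "alleles must be an [nInd, nLoci, 2] array")
  else {
    if (d[1] != nrow(object@indiv))
      msg <- c(msg, "allele array rows must match individuals")
    if (d[2] != length(object@loci))
      msg <- c(msg, "allele array columns must match loci")
    half <- xor(is.na(object@alleles[, , 1, drop = FALSE]),
                is.na(object@alleles[, , 2, drop = FALSE]))
    if (any(half))
      msg <- c(msg, "half-missing calls are not allowed (both alleles or neither)")
    ok <- object@alleles[!is.na(object@alleles)]
    if (length(ok) && any(ok <= 0))
      msg <- c(msg, "allele codes must be positive integers")
  }
  if (nrow(object@indiv)) {
    if (any(object@indiv$deme < 1L | object@indiv$deme > nrow(object@demes)))
      msg <- c(msg, "individual deme index out of range")
    cnt <- tabulate(object@indiv$deme, nbins = nrow(object@demes))
    if (!all(cnt == object@demes$n))
      msg <- c(msg, "per-deme individual counts must equal demes$n")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param loci character vector of locus names.
#' @param demes deme data.frame (see \linkS4class{GenotypeDataset}); a missing
#'   \code{n} column is filled from the individual table.
#' @param indiv data.frame with \code{id}, \code{deme} index and optional
#'   \code{sex}.
#' @param alleles integer array \code{[nInd, nLoci, 2]}.
#' @return A validated \linkS4class{GenotypeDataset}.
#' @export
genotypeDataset <- function(loci, demes, indiv, alleles) {
  if (is.null(indiv$sex)) indiv$sex <- NA_character_
  if (is.null(demes$n))
    demes$n <- tabulate(indiv$deme, nbins = nrow(demes))
  for (col in c("area", "date"))
    if (is.null(demes[[col]])) demes[[col]] <- NA
  demes <- demes[, c("name", "easting", "northing", "area", "date", "n")]
  storage.mode(alleles) <- "integer"
  new("GenotypeDataset", loci = as.character(loci), demes = demes,
      indiv = indiv, alleles = alleles)
}

## ---------------------------------------------------------------------------
## Grids
## ---------------------------------------------------------------------------

#' Gridded landscape layers
#'
#' \code{LandGrid} is the virtual parent of the three raster layers used by the
#' landscape model. \code{values} is a numeric matrix in file order (row 1 is
#' the northern edge); \code{origin} is the easting/northing of the lower-left
#' cell corner so cell centres can be georeferenced.
#'
#' \code{CategoryGrid} holds land-cover category codes 1-9 (1 meadow,
#' 2 orchard, 3 pasture/grassland, 4 annual crop, 5 shrub, 6 eucalyptus,
#' 7 deciduous woodlot, 8 settlement/road, 9 water). \code{ResistanceGrid}
#' holds dimensionless cost values (all >= 1). \code{ElevationGrid} holds
#' elevation in metres.
#'
#' @slot values numeric matrix.
#' @slot cellSize cell edge length in metres.
#' @slot origin numeric length-2, (easting, northing) of lower-left corner.
#' @aliases CategoryGrid-class ResistanceGrid-class ElevationGrid-class
#' @export
setClass("LandGrid",
  representation("VIRTUAL", values = "matrix", cellSize = "numeric",
                 origin = "numeric"))

setValidity("LandGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite numbers")
  if (length(msg)) msg else TRUE
})

#' @export
setClass("CategoryGrid", contains = "LandGrid")
setValidity("CategoryGrid", function(object) {
  v <- object@values
  if (anyNA(v)) return("NoData cells are not supported in category grids")
  if (!all(v %in% 1:9)) return("category codes must be integers 1-9")
  TRUE
})

#' @export
setClass("ResistanceGrid", contains = "LandGrid")
setValidity("ResistanceGrid", function(object) {
  if (any(object@values < 1)) "all cost values must be >= 1" else TRUE
})

#' @export
setClass("ElevationGrid", contains = "LandGrid")

#' Construct grid layers
#'
#' @param values numeric matrix in file order (row 1 = north edge).
#' @param cellSize cell edge in metres.
#' @param origin (easting, northing) of the lower-left corner, metres.
#' @return A grid object of the requested class.
#' @rdname gridConstructors
#' @export
categoryGrid <- function(values, cellSize, origin = c(0, 0))
  new("CategoryGrid", values = as.matrix(values), cellSize = cellSize,
      origin = as.numeric(origin))

#' @rdname gridConstructors
#' @export
resistanceGrid <- function(values, cellSize, origin = c(0, 0))
  new("ResistanceGrid", values = as.matrix(values), cellSize = cellSize,
      origin = as.numeric(origin))

#' @rdname gridConstructors
#' @export
elevationGrid <- function(values, cellSize, origin = c(0, 0))
  new("ElevationGrid", values = as.matrix(values), cellSize = cellSize,
      origin = as.numeric(origin))

## ---------------------------------------------------------------------------
## DistanceBundle
## ---------------------------------------------------------------------------

#' Pairwise deme distance matrices
#'
#' Symmetric deme-by-deme matrices produced by \code{\link{distanceBundle}}:
#' straight-line distance (km), effective distance (least-cost-path length,
#' km), resistance distance (dimensionless, sum over crossed patches of
#' patch length in km times its cost value) and landscape suitability
#' (suitable-habitat fraction of the lens between the two demes divided by
#' their Euclidean distance, per km; diagonal \code{NA}).
#'
#' @slot euclidean,effective,resistance,suitability numeric matrices with deme
#'   names as dimnames.
#' @export
setClass("DistanceBundle",
  representation(euclidean = "matrix", effective = "matrix",
                 resistance = "matrix", suitability = "matrix"))

setValidity("DistanceBundle", function(object) {
  msg <- character()
  chk <- function(m, nm, diagZero = TRUE) {
    out <- character()
    if (nrow(m) != ncol(m)) out <- c(out, paste(nm, "must be square"))
    else {
      if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
        out <- c(out, paste(nm, "must be symmetric"))
      if (diagZero && any(abs(diag(m)) > 1e-9, na.rm = TRUE))
        out <- c(out, paste(nm, "must have zero diagonal"))
      if (any(m < 0, na.rm = TRUE))
        out <- c(out, paste(nm, "entries must be >= 0"))
    }
    out
  }
  msg <- c(msg, chk(object@euclidean, "euclidean"),
           chk(object@effective, "effective"),
           chk(object@resistance, "resistance"),
           chk(object@suitability, "suitability", diagZero = FALSE))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ClusterModel
## ---------------------------------------------------------------------------

#' Fitted model-based clustering
#'
#' Result of the no-admixture Gibbs sampler of \code{\link{gibbsCluster}}.
#'
#' @slot K number of clusters.
#' @slot Q numeric matrix \code{[nInd, K]} of posterior assignment
#'   probabilities averaged over post-burn-in sweeps.
#' @slot logLik numeric per-sweep log-likelihood trace (all sweeps).
#' @slot logEvidence estimated log model evidence,
#'   \code{mean(logL) - var(logL)/2} over post-burn-in sweeps.
#' @slot burnin,seed integers recording the run.
#' @export
setClass("ClusterModel",
  representation(K = "integer", Q = "matrix", logLik = "numeric",
                 logEvidence = "numeric", burnin = "integer", seed = "integer"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (ncol(object@Q) != object@K) msg <- c(msg, "Q must have K columns")
  if (nrow(object@Q) &&
      any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "assignment probabilities must sum to 1 per individual")
  if (length(msg)) msg else TRUE
})
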