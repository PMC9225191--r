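#' Accessors for package classes
#'
#' Small accessor generics in the Bioconductor idiom; user code should use
#' these rather than reaching into slots.
#'
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("nDemes", function(x) standardGeneric("nDemes"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("demeNames", function(x) standardGeneric("demeNames"))
#' @rdname accessors
#' @export
setGeneric("demeInfo", function(x) standardGeneric("demeInfo"))
#' @rdname accessors
#' @export
setGeneric("indInfo", function(x) standardGeneric("indInfo"))
#' @rdname accessors
#' @export
setGeneric("alleleCalls", function(x) standardGeneric("alleleCalls"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setMethod("nInd", "GenotypeDataset", function(x) nrow(x@indiv))
#' @rdname accessors
#' @export
setMethod("nLoci", "GenotypeDataset", function(x) length(x@loci))
#' @rdname accessors
#' @export
setMethod("nDemes", "GenotypeDataset", function(x) nrow(x@demes))
#' @rdname accessors
#' @export
setMethod("lociNames", "GenotypeDataset", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("demeNames", "GenotypeDataset", function(x) x@demes$name)
#' @rdname accessors
#' @export
setMethod("demeInfo", "GenotypeDataset", function(x) x@demes)
#' @rdname accessors
#' @export
setMethod("indInfo", "GenotypeDataset", function(x) x@indiv)
#' @rdname accessors
#' @export
setMethod("alleleCalls", "GenotypeDataset", function(x) x@alleles)

#' @rdname accessors
#' @export
setMethod("gridValues", "LandGrid", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("cellSize", "LandGrid", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "LandGrid", function(x) x@origin)

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nInd(object), "individuals,",
      nDemes(object), "demes,", nLoci(object), "loci\n")
  miss <- mean(is.na(object@alleles[, , 1]))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  cat("  demes:", paste(utils::head(demeNames(object), 10), collapse = ", "),
      if (nDemes(object) > 10) "..." else "", "\n")
})

setMethod("show", "LandGrid", function(object) {
  cat(class(object), ": ", nrow(object@values), " x ", ncol(object@values),
      " cells of ", object@cellSize, " m, lower-left corner (",
      object@origin[1], ", ", object@origin[2], ")\n", sep = "")
})

setMethod("show", "DistanceBundle", function(object) {
  n <- nrow(object@euclidean)
  cat("DistanceBundle:", n, "demes,", n * (n - 1) / 2, "pairs\n")
  up <- upper.tri(object@euclidean)
  cat(sprintf("  euclidean km: %.2f-%.2f  effective km: %.2f-%.2f\n",
              min(object@euclidean[up]), max(object@euclidean[up]),
              min(object@effective[up]), max(object@effective[up])))
  cat(sprintf("  resistance: %.2f-%.2f\n",
              min(object@resistance[up]), max(object@resistance[up])))
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: K =", object@K, "over", nrow(object@Q), "individuals;",
      "log evidence", format(object@logEvidence, digits = 6), "\n")
})

## Extra accessors for results

#' @rdname accessors
#' @export
setGeneric("assignmentProbs", function(x) standardGeneric("assignmentProbs"))
#' @rdname accessors
#' @export
setMethod("assignmentProbs", "ClusterModel", function(x) x@Q)
#' @rdname accessors
#' @export
setGeneric("logEvidence", function(x) standardGeneric("logEvidence"))
#' @rdname accessors
#' @export
setMethod("logEvidence", "ClusterModel", function(x) x@logEvidence)

#' @rdname accessors
#' @param which one of "euclidean", "effective", "resistance", "suitability".
#' @export
setGeneric("distanceMatrix", function(x, which) standardGeneric("distanceMatrix"))
#' @rdname accessors
#' @export
setMethod("distanceMatrix", "DistanceBundle", function(x, which) {
  which <- match.arg(which, c("euclidean", "effective", "resistance",
                              "suitability"))
  slot(x, which)
})
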