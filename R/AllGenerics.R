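#' @include AllClasses.R
NULL

#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @export
setGeneric("resolutionBp", function(x) standardGeneric("resolutionBp"))
#' @export
setGeneric("contactState", function(x) standardGeneric("contactState"))
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))
#' @export
setGeneric("offsetBin", function(x) standardGeneric("offsetBin"))
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @export
setGeneric("contactMatrix", function(x, ...) standardGeneric("contactMatrix"))
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setGeneric("structureCalls", function(x) standardGeneric("structureCalls"))
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("targetMatrix", function(x) standardGeneric("targetMatrix"))
#' @export
setGeneric("attributionMatrix", function(x) standardGeneric("attributionMatrix"))
#' @export
setGeneric("pileupMatrix", function(x) standardGeneric("pileupMatrix"))
#' @export
setGeneric("centerScore", function(x) standardGeneric("centerScore"))
#' @export
setGeneric("sccValue", function(x) standardGeneric("sccValue"))
#' @export
setGeneric("sccStrata", function(x) standardGeneric("sccStrata"))

# ---- accessors ------------------------------------------------------------

#' @describeIn BinTrack-class chromosome name
#' @param x object
#' @export
setMethod("chromName", "BinTrack", function(x) x@chrom)
#' @export
setMethod("chromName", "ContactMap", function(x) x@chrom)
#' @export
setMethod("chromName", "StructureCallSet", function(x) x@chrom)
#' @export
setMethod("chromName", "WindowSample", function(x) x@chrom)

#' @export
setMethod("resolutionBp", "BinTrack", function(x) x@resolution)
#' @export
setMethod("resolutionBp", "ContactMap", function(x) x@resolution)
#' @export
setMethod("resolutionBp", "StructureCallSet", function(x) x@resolution)
#' @export
setMethod("resolutionBp", "WindowSample", function(x) x@resolution)

#' @export
setMethod("contactState", "ContactMap", function(x) x@state)
#' @export
setMethod("totalContacts", "ContactMap", function(x) x@totalContacts)
#' @export
setMethod("offsetBin", "ContactMap", function(x) x@offsetBin)
#' @export
setMethod("nBins", "ContactMap", function(x) nrow(x@matrix))
#' @export
setMethod("nBins", "BinTrack", function(x) length(x@values))

#' Contact matrix accessor
#'
#' Returns the contact matrix with the lower triangle mirrored from the
#' stored upper triangle, so that entry (i, j) always equals entry (j, i).
#'
#' @param x a ContactMap.
#' @param dense return a base dense matrix instead of a sparse Matrix.
#' @export
setMethod("contactMatrix", "ContactMap", function(x, dense = FALSE) {
  m <- x@matrix
  full <- m + Matrix::t(m) - Diagonal(nrow(m), Matrix::diag(m))
  if (dense) as.matrix(full) else full
})

#' @export
setMethod("trackValues", "BinTrack", function(x) x@values)
#' @export
setMethod("featureName", "BinTrack", function(x) x@feature)
#' @export
setMethod("isNormalized", "BinTrack", function(x) x@normalized)
#' @export
setMethod("structureCalls", "StructureCallSet", function(x) x@calls)
#' @export
setMethod("adjacencyMatrix", "ChromGraph", function(x) x@adjacency)
#' @export
setMethod("nodeFeatures", "ChromGraph", function(x) x@nodeFeatures)
#' @export
setMethod("featureMatrix", "WindowSample", function(x) x@X)
#' @export
setMethod("targetMatrix", "WindowSample", function(x) x@Y)
#' @export
setMethod("attributionMatrix", "AttributionMap", function(x) x@A)
#' @export
setMethod("pileupMatrix", "PileupResult", function(x) x@matrix)
#' @export
setMethod("centerScore", "PileupResult", function(x) x@centerScore)
#' @export
setMethod("sccValue", "SCCReport", function(x) x@scc)
#' @export
setMethod("sccStrata", "SCCReport", function(x) x@strata)

#' @export
setMethod("length", "StructureCallSet", function(x) nrow(x@calls))

# ---- show methods ---------------------------------------------------------

setMethod("show", "BinTrack", function(object) {
  cat(sprintf("BinTrack '%s' on %s: %d bins @ %g bp (start bin %g)%s\n",
              object@feature, object@chrom, length(object@values),
              object@resolution, object@startBin,
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap %s: %d bins @ %g bp, state=%s, nnz=%d%s\n",
              object@chrom, nrow(object@matrix), object@resolution,
              object@state, length(object@matrix@x),
              if (object@state == "raw")
                sprintf(", total=%g", object@totalContacts) else ""))
})

setMethod("show", "StructureCallSet", function(object) {
  tab <- table(object@calls$kind)
  cat(sprintf("StructureCallSet %s @ %g bp: %s\n", object@chrom,
              object@resolution,
              if (nrow(object@calls))
                paste(names(tab), as.integer(tab), collapse = ", ")
              else "empty"))
})

setMethod("show", "ChromGraph", function(object) {
  cat(sprintf("ChromGraph: %g nodes, %d edges (nnz), %d node-feature rows\n",
              object@nNodes, length(object@adjacency@x),
              nrow(object@nodeFeatures)))
})

setMethod("show", "WindowSample", function(object) {
  cat(sprintf("WindowSample %s:%g-%g (%d bins @ %g bp, band %g bp)%s\n",
              object@chrom, object@startBp, object@startBp + object@windowBp,
              ncol(object@X), object@resolution, object@bandBp,
              if (is.null(object@Y)) "" else " + target"))
})

setMethod("show", "ImputationModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("ImputationModel: %d features, band %g bp, %g parameters\n",
              object@config$nFeatures, object@config$bandBp, np))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf("TrainState: phase '%s', %g epochs, last MSE %.6g\n",
              object@phase, object@epoch,
              if (nrow(object@history)) utils::tail(object@history$mse, 1) else NA))
})

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf("AttributionMap: %d features x %d bins, %g steps, completeness gap %.3g\n",
              nrow(object@A), ncol(object@A), object@steps, object@completenessGap))
})

setMethod("show", "PileupResult", function(object) {
  cat(sprintf("PileupResult: %dx%d mean over %g regions, center 5x5 = %.4g\n",
              nrow(object@matrix), ncol(object@matrix), object@nRegions,
              object@centerScore))
})

setMethod("show", "SCCReport", function(object) {
  cat(sprintf("SCCReport: scc = %.4f over %d strata (h = %g)\n",
              object@scc, nrow(object@strata), object@h))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %g bp @ %g bp, alpha=%g, %d loops, ",
                     "%d stripes, seed=%g\n"),
              object@lengthBp, object@resolution, object@alpha,
              nrow(object@loops), nrow(object@stripes), object@seed))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %d features [%s], window/step/band = %g/%g/%g bp\n",
              length(object@features), paste(object@features, collapse = ", "),
              object@windowBp, object@stepBp, object@bandBp))
})
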