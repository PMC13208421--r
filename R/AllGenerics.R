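#' Accessors for SporeHull objects
#'
#' Small accessor generics for the package's S4 containers; use these instead
#' of reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The corresponding component (see the method descriptions).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "SporeContour", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("vertices", "GeometryResult", function(x) x@contour@vertices)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "SporeContour", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setMethod("maskPixels", "SporeMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("maskScale", function(x) standardGeneric("maskScale"))
#' @rdname accessors
#' @export
setMethod("maskScale", "SporeMask", function(x) x@scaleUmPerPx)

#' Foreground area of a mask in µm²
#' @param x a [SporeMask-class].
#' @return Foreground pixel count times the squared pixel scale (µm²).
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname maskArea
#' @export
setMethod("maskArea", "SporeMask",
          function(x) sum(x@pixels) * x@scaleUmPerPx^2)

#' @rdname accessors
#' @export
setGeneric("sporeLength", function(x) standardGeneric("sporeLength"))
#' @rdname accessors
#' @export
setMethod("sporeLength", "GeometryResult", function(x) x@LUm)

#' @rdname accessors
#' @export
setGeneric("sporeWidth", function(x) standardGeneric("sporeWidth"))
#' @rdname accessors
#' @export
setMethod("sporeWidth", "GeometryResult", function(x) x@WUm)

#' @rdname accessors
#' @export
setGeneric("shapeArea", function(x) standardGeneric("shapeArea"))
#' @rdname accessors
#' @export
setMethod("shapeArea", "GeometryResult", function(x) x@shapeAreaUm2)

#' @rdname accessors
#' @export
setGeneric("hullArea", function(x) standardGeneric("hullArea"))
#' @rdname accessors
#' @export
setMethod("hullArea", "GeometryResult", function(x) x@hullAreaUm2)

#' @rdname accessors
#' @export
setGeneric("depressionPct", function(x) standardGeneric("depressionPct"))
#' @rdname accessors
#' @export
setMethod("depressionPct", "GeometryResult", function(x) x@depressionPct)

#' @rdname accessors
#' @export
setGeneric("keyLabel", function(x) standardGeneric("keyLabel"))
#' @rdname accessors
#' @export
setMethod("keyLabel", "KeyOutcome", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("keyCandidates", function(x) standardGeneric("keyCandidates"))
#' @rdname accessors
#' @export
setMethod("keyCandidates", "KeyOutcome", function(x) x@candidates)

#' @rdname accessors
#' @export
setGeneric("keyPath", function(x) standardGeneric("keyPath"))
#' @rdname accessors
#' @export
setMethod("keyPath", "KeyOutcome", function(x) x@path)

#' Decision path of a key outcome as a single string
#' @param x a [KeyOutcome-class].
#' @return A string such as \code{"1b→4b→5b"}.
#' @export
pathString <- function(x) paste(keyPath(x), collapse = "→")

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname accessors
#' @export
setMethod("testStatistic", "TestResult", function(x) x@statistic)

#' @rdname accessors
#' @export
setGeneric("stars", function(x) standardGeneric("stars"))
#' @rdname accessors
#' @export
setMethod("stars", "TestResult", function(x) x@stars)

setMethod("show", "SporeContour", function(object) {
  v <- object@vertices
  cat(sprintf("SporeContour: %d vertices, area %.3f um^2, depression %.3f%%\n",
              nrow(v), polygonArea(v),
              suprahilarDepression(v, check = FALSE)))
  if (length(object@provenance))
    cat("  generated from", object@provenance$params@profileFamily,
        "shape parameters\n")
})

setMethod("show", "SporeMask", function(object) {
  cat(sprintf("SporeMask: %d x %d px at %.4g um/px, foreground %d px (%.2f um^2)\n",
              nrow(object@pixels), ncol(object@pixels), object@scaleUmPerPx,
              sum(object@pixels), maskArea(object)))
})

setMethod("show", "GeometryResult", function(object) {
  cat(sprintf(paste0("GeometryResult: L %.2f um, W %.2f um, area %.2f um^2, ",
                     "hull %.2f um^2, depression %.3f%%\n"),
              object@LUm, object@WUm, object@shapeAreaUm2, object@hullAreaUm2,
              object@depressionPct))
})

setMethod("show", "RangeSummary", function(object) {
  cat("RangeSummary of", object@variable, "over",
      object@nCollections, "collection means:\n ", formatSummary(object), "\n")
})

setMethod("show", "KeyOutcome", function(object) {
  cat("KeyOutcome:", object@label, "\n  path:", pathString(object), "\n")
  if (object@label == "indeterminate")
    cat("  candidates:", paste(object@candidates, collapse = ", "), "\n")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult (%s): statistic %.4g, p = %.4g [%s], n = %d vs %d\n",
              object@method, object@statistic, object@pValue, object@stars,
              object@groupSizes[1], object@groupSizes[2]))
})

setMethod("show", "EllipseParams", function(object) {
  cat(sprintf(paste0("EllipseParams (%.0f%%): centre (%.3f, %.3f), ",
                     "semi-axes %.3f x %.3f, angle %.1f deg\n"),
              100 * object@probLevel, object@center[1], object@center[2],
              object@semiMajor, object@semiMinor, object@angleDeg))
})

setMethod("show", "SiteCounts", function(object) {
  cat(sprintf(paste0("SiteCounts: length %d | constant %d, variable %d ",
                     "(informative %d, singleton %d), all-missing %d | ",
                     "%.2f%% parsimony informative\n"),
              object@alignmentLength, object@nConstant, object@nVariable,
              object@nParsimonyInformative, object@nSingleton,
              object@nAllMissing, object@pctParsimonyInformative))
})

setMethod("show", "PopulationConfig", function(object) {
  cat(sprintf(paste0("PopulationConfig '%s': L %.2f +/- %.2f, W %.2f +/- %.2f um ",
                     "(between collections), %d/%d/%d spores/basidiomes/collections\n"),
              object@speciesLabel, object@meanL, object@sdLBetween,
              object@meanW, object@sdWBetween,
              object@nPerBasidiome * object@mBasidiomes * object@pCollections,
              object@mBasidiomes * object@pCollections, object@pCollections))
})
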