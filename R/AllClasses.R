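#' @import methods
NULL

#' Parameters of a synthetic spore silhouette
#'
#' Describes one side-view basidiospore profile for the parametric generator:
#' the profile family (ellipsoid, subamygdaliform or amygdaliform), the nominal
#' long-axis length and short-axis width in micrometres, the apical sharpness
#' (0 = blunt, elliptic apex; 1 = acute), the lateral offset of the apiculus
#' attachment point (signed fraction of the width), the target suprahilar
#' concavity as a fraction of convex-hull area, and the chord of the suprahilar
#' notch as a fraction of the length.
#'
#' @slot profileFamily character, one of \code{"ellipsoid"},
#'   \code{"subamygdaliform"}, \code{"amygdaliform"}.
#' @slot lengthUm,widthUm numeric, long-axis length and short-axis width (µm);
#'   \code{lengthUm >= widthUm > 0}.
#' @slot apexSharpness numeric in \code{[0, 1]}.
#' @slot apiculusOffset numeric, signed fraction of the width.
#' @slot targetConcavity numeric in \code{[0, 0.2]}, desired fraction of the
#'   convex-hull area occupied by concavity.
#' @slot notchWidthFrac numeric in \code{(0, 0.6)}, notch chord / length.
#' @seealso [sporeShapeParams()], [generateContour()]
#' @export
setClass("SporeShapeParams",
  representation(
    profileFamily = "character",
    lengthUm = "numeric",
    widthUm = "numeric",
    apexSharpness = "numeric",
    apiculusOffset = "numeric",
    targetConcavity = "numeric",
    notchWidthFrac = "numeric"
  )
)

setValidity("SporeShapeParams", function(object) {
  msg <- character(0)
  fam <- c("ellipsoid", "subamygdaliform", "amygdaliform")
  if (length(object@profileFamily) != 1L || !object@profileFamily %in% fam)
    msg <- c(msg, sprintf("profileFamily must be one of %s",
                          paste(fam, collapse = ", ")))
  if (!isScalarFinite(object@lengthUm) || !isScalarFinite(object@widthUm) ||
      object@widthUm <= 0 || object@lengthUm < object@widthUm)
    msg <- c(msg, "need lengthUm >= widthUm > 0")
  if (!isScalarFinite(object@apexSharpness) ||
      object@apexSharpness < 0 || object@apexSharpness > 1)
    msg <- c(msg, "apexSharpness must be in [0, 1]")
  if (!isScalarFinite(object@apiculusOffset) || abs(object@apiculusOffset) > 1)
    msg <- c(msg, "apiculusOffset must be a signed fraction in [-1, 1]")
  if (!isScalarFinite(object@targetConcavity) ||
      object@targetConcavity < 0 || object@targetConcavity > 0.2)
    msg <- c(msg, "targetConcavity must be in [0, 0.2]")
  if (!isScalarFinite(object@notchWidthFrac) ||
      object@notchWidthFrac <= 0 || object@notchWidthFrac >= 0.6)
    msg <- c(msg, "notchWidthFrac must be in (0, 0.6)")
  if (length(msg)) msg else TRUE
})

#' Construct spore shape parameters
#'
#' @param profileFamily profile class of the silhouette.
#' @param lengthUm,widthUm nominal spore length and width (µm).
#' @param apexSharpness apical sharpness in \code{[0, 1]}.
#' @param apiculusOffset lateralisation of the apiculus attachment point,
#'   as a signed fraction of the width.
#' @param targetConcavity suprahilar concavity to calibrate to, as a fraction
#'   of the convex-hull area (0–0.2).
#' @param notchWidthFrac chord of the suprahilar notch as a fraction of the
#'   spore length.
#' @return A [SporeShapeParams-class] object.
#' @examples
#' sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.04)
#' @export
sporeShapeParams <- function(profileFamily = c("ellipsoid", "subamygdaliform",
                                               "amygdaliform"),
                             lengthUm, widthUm,
                             apexSharpness = 0.3,
                             apiculusOffset = 0.2,
                             targetConcavity = 0,
                             notchWidthFrac = 0.45) {
  profileFamily <- match.arg(profileFamily)
  new("SporeShapeParams",
      profileFamily = profileFamily,
      lengthUm = as.numeric(lengthUm), widthUm = as.numeric(widthUm),
      apexSharpness = as.numeric(apexSharpness),
      apiculusOffset = as.numeric(apiculusOffset),
      targetConcavity = as.numeric(targetConcavity),
      notchWidthFrac = as.numeric(notchWidthFrac))
}

#' Closed spore silhouette polygon
#'
#' An ordered, counterclockwise, closed polygon in micrometre coordinates
#' describing a basidiospore silhouette in side view. The polygon is stored
#' open (the closing edge from the last to the first vertex is implicit).
#'
#' @slot vertices two-column numeric matrix of (x, y) coordinates in µm,
#'   counterclockwise, at least 64 vertices.
#' @slot provenance list; for generated contours, carries the
#'   [SporeShapeParams-class] used and the calibrated notch depth. Empty for
#'   contours extracted from images.
#' @seealso [generateContour()], [extractContour()], [suprahilarDepression()]
#' @export
setClass("SporeContour",
  representation(vertices = "matrix", provenance = "list"))

setValidity("SporeContour", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be a two-column numeric matrix")
  if (nrow(v) < 64L)
    return("a spore contour needs at least 64 vertices")
  if (!all(is.finite(v)))
    return("vertices must be finite")
  if (polygonArea(v) <= 0)
    return("enclosed area must be positive")
  TRUE
})

#' Construct a spore contour
#'
#' Normalises the vertex matrix (drops a repeated closing vertex and
#' consecutive duplicates, enforces counterclockwise orientation) and, by
#' default, verifies that the polygon is simple.
#'
#' @param vertices two-column numeric matrix of (x, y) vertices in µm.
#' @param provenance optional list of generator metadata.
#' @param checkSimple verify that the polygon has no self-intersections.
#'   Contours produced by the marching-squares extractor are simple by
#'   construction and skip this check internally.
#' @return A [SporeContour-class] object.
#' @export
SporeContour <- function(vertices, provenance = list(), checkSimple = TRUE) {
  v <- normalizeVertices(vertices)
  if (checkSimple && !isSimplePolygon(v))
    stop("polygon is self-intersecting")
  new("SporeContour", vertices = v, provenance = provenance)
}

#' Binary raster mask of one spore
#'
#' A binary raster with a physical scale. \code{pixels[i, j]} covers the pixel
#' whose centre is at \code{offset + (c(j, i) - 0.5) * scale} µm, i.e. rows
#' index y (increasing upwards) and columns index x. A valid mask holds exactly
#' one foreground connected component and no interior holes.
#'
#' @slot pixels numeric 0/1 matrix (rows = y, columns = x).
#' @slot scaleUmPerPx positive scalar, µm per pixel.
#' @slot offset numeric length-2, µm coordinates of the lower-left corner of
#'   the raster.
#' @seealso [rasterize()], [extractContour()], [segmentImage()]
#' @export
setClass("SporeMask",
  representation(pixels = "matrix", scaleUmPerPx = "numeric",
                 offset = "numeric"))

setValidity("SporeMask", function(object) {
  msg <- character(0)
  if (!isScalarFinite(object@scaleUmPerPx) || object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be a positive scalar")
  if (length(object@offset) != 2L || !all(is.finite(object@offset)))
    msg <- c(msg, "offset must be two finite numbers")
  p <- object@pixels
  if (!is.numeric(p) || !all(p %in% c(0, 1)))
    msg <- c(msg, "pixels must be a 0/1 matrix")
  if (!length(msg)) {
    lab <- EBImage::bwlabel(p)
    ncomp <- max(lab)
    if (ncomp != 1L)
      msg <- c(msg, sprintf("mask must have exactly one foreground component (found %d)", ncomp))
    filled <- EBImage::fillHull(p)
    if (any(filled != p))
      msg <- c(msg, "mask must have no interior holes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a spore mask
#'
#' @param pixels logical or 0/1 numeric matrix (rows = y, columns = x).
#' @param scaleUmPerPx µm per pixel.
#' @param offset µm coordinates of the lower-left raster corner.
#' @return A [SporeMask-class] object.
#' @export
SporeMask <- function(pixels, scaleUmPerPx, offset = c(0, 0)) {
  storage.mode(pixels) <- "double"
  new("SporeMask", pixels = pixels, scaleUmPerPx = as.numeric(scaleUmPerPx),
      offset = as.numeric(offset))
}

#' Geometric measurement of one silhouette
#'
#' Bundle of the geometric primitives measured on one spore silhouette:
#' the contour, its convex hull, both areas, the suprahilar-depression
#' percentage \eqn{100 (A_{hull} - A) / A_{hull}}, the Feret length and the
#' perpendicular width, and the orientation of the long axis.
#'
#' @slot contour the measured [SporeContour-class].
#' @slot hull two-column matrix, convex hull vertices (µm, counterclockwise).
#' @slot shapeAreaUm2,hullAreaUm2 numeric, silhouette and hull areas (µm²).
#' @slot depressionPct numeric in \code{[0, 100)}.
#' @slot LUm,WUm numeric, Feret length and perpendicular width (µm).
#' @slot orientationDeg numeric, long-axis orientation in degrees.
#' @seealso [measureContour()]
#' @export
setClass("GeometryResult",
  representation(contour = "SporeContour", hull = "matrix",
                 shapeAreaUm2 = "numeric", hullAreaUm2 = "numeric",
                 depressionPct = "numeric", LUm = "numeric", WUm = "numeric",
                 orientationDeg = "numeric"))

setValidity("GeometryResult", function(object) {
  msg <- character(0)
  if (!(object@shapeAreaUm2 > 0))
    msg <- c(msg, "shape area must be positive")
  if (object@hullAreaUm2 < object@shapeAreaUm2 * (1 - 1e-9))
    msg <- c(msg, "hull area must be >= shape area")
  if (object@depressionPct < 0 || object@depressionPct >= 100)
    msg <- c(msg, "depressionPct must be in [0, 100)")
  if (!(object@WUm > 0) || object@LUm < object@WUm * (1 - 1e-9))
    msg <- c(msg, "need L >= W > 0")
  if (length(msg)) msg else TRUE
})

#' Hierarchical population sampling configuration
#'
#' Configuration of one simulated species population in the standard
#' n-spores / m-basidiomes / p-collections hierarchy: collection-level
#' length/width means are drawn from a bivariate normal with the stated
#' between-collection means, SDs and correlation; per-spore values are drawn
#' around their collection mean with SD = \code{withinSdFactor} times the
#' between-collection SD; the per-spore suprahilar concavity fraction is
#' lognormal.
#'
#' @slot speciesLabel character.
#' @slot meanL,sdLBetween,meanW,sdWBetween numeric, collection-level mean and
#'   SD of length and width (µm).
#' @slot withinSdFactor numeric, ratio of within- to between-collection SD.
#' @slot corrLW numeric in \code{(-1, 1)}, length–width correlation.
#' @slot concavityLogMean,concavityLogSd numeric, lognormal parameters of the
#'   per-spore concavity fraction.
#' @slot nPerBasidiome,mBasidiomes,pCollections integer counts (>= 1).
#' @slot shape a [SporeShapeParams-class] template giving the profile family,
#'   apex sharpness, apiculus offset and notch chord used for every spore.
#' @slot seed integer RNG seed.
#' @seealso [populationConfig()], [speciesPreset()], [samplePopulation()]
#' @export
setClass("PopulationConfig",
  representation(speciesLabel = "character",
                 meanL = "numeric", sdLBetween = "numeric",
                 meanW = "numeric", sdWBetween = "numeric",
                 withinSdFactor = "numeric", corrLW = "numeric",
                 concavityLogMean = "numeric", concavityLogSd = "numeric",
                 nPerBasidiome = "integer", mBasidiomes = "integer",
                 pCollections = "integer", shape = "SporeShapeParams",
                 seed = "integer"))

setValidity("PopulationConfig", function(object) {
  msg <- character(0)
  if (object@sdLBetween < 0 || object@sdWBetween < 0 ||
      object@withinSdFactor < 0 || object@concavityLogSd < 0)
    msg <- c(msg, "all SDs must be >= 0")
  if (object@meanL < object@meanW || object@meanW <= 0)
    msg <- c(msg, "need meanL >= meanW > 0")
  if (abs(object@corrLW) >= 1)
    msg <- c(msg, "corrLW must be in (-1, 1)")
  if (object@nPerBasidiome < 1L || object@mBasidiomes < 1L ||
      object@pCollections < 1L)
    msg <- c(msg, "hierarchy counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Collection-level range summary of one variable
#'
#' The classical sporological "(minimum) mean ± SD (maximum)" summary:
#' per-collection arithmetic means are computed first and the minimum, mean,
#' sample SD and maximum are then taken over those collection means. The SD is
#' absent (NA) for a single collection.
#'
#' @slot variable character, the summarised variable name.
#' @slot minimum,mean,sd,maximum numeric.
#' @slot nCollections,nSpores,nBasidiomes integer counts.
#' @seealso [summarizeByCollection()], [formatSummary()]
#' @export
setClass("RangeSummary",
  representation(variable = "character", minimum = "numeric", mean = "numeric",
                 sd = "numeric", maximum = "numeric", nCollections = "integer",
                 nSpores = "integer", nBasidiomes = "integer"))

setValidity("RangeSummary", function(object) {
  msg <- character(0)
  if (object@minimum > object@mean + 1e-12 || object@mean > object@maximum + 1e-12)
    msg <- c(msg, "need minimum <= mean <= maximum")
  if (!is.na(object@sd) && object@sd < 0)
    msg <- c(msg, "sd must be >= 0")
  if (object@nCollections == 1L && !is.na(object@sd))
    msg <- c(msg, "sd must be NA for a single collection")
  if (length(msg)) msg else TRUE
})

#' Construct a range summary directly
#'
#' @param variable variable name.
#' @param minimum,mean,sd,maximum summary statistics over collection means;
#'   \code{sd} may be \code{NA} for a single collection.
#' @param nCollections,nSpores,nBasidiomes hierarchy counts.
#' @return A [RangeSummary-class] object.
#' @export
rangeSummary <- function(variable, minimum, mean, sd, maximum,
                         nCollections, nSpores = NA_integer_,
                         nBasidiomes = NA_integer_) {
  new("RangeSummary", variable = variable, minimum = as.numeric(minimum),
      mean = as.numeric(mean), sd = as.numeric(sd),
      maximum = as.numeric(maximum), nCollections = as.integer(nCollections),
      nSpores = as.integer(nSpores), nBasidiomes = as.integer(nBasidiomes))
}

#' Outcome of the microscopy identification key
#'
#' The species label decided by the dichotomous microscopy key (or
#' \code{"indeterminate"} with the set of candidate species of the unresolved
#' couplet), together with the full decision path, e.g.
#' \code{c("1a", "2b", "3b")}.
#'
#' @slot label character, one of the species labels or \code{"indeterminate"}.
#' @slot candidates character vector of candidate species labels.
#' @slot path character vector of couplet branches taken.
#' @seealso [classifyMicroscopy()]
#' @export
setClass("KeyOutcome",
  representation(label = "character", candidates = "character",
                 path = "character"))

setValidity("KeyOutcome", function(object) {
  msg <- character(0)
  if (length(object@path) == 0L)
    msg <- c(msg, "path must be non-empty")
  if (object@label != "indeterminate" &&
      !identical(object@candidates, object@label))
    msg <- c(msg, "a determinate label must have itself as single candidate")
  if (length(msg)) msg else TRUE
})

#' Two-sample comparison result
#'
#' @slot method character: \code{"welch_t"}, \code{"student_t"},
#'   \code{"mann_whitney"} (the routing Shapiro–Wilk p-values are kept in
#'   \code{details}).
#' @slot statistic numeric test statistic (t, or Mann–Whitney U).
#' @slot pValue numeric in \code{[0, 1]}.
#' @slot stars character: \code{"ns"}, \code{"*"}, \code{"**"}, \code{"***"}
#'   at the 0.05 / 0.01 / 0.001 thresholds.
#' @slot groupSizes integer length-2.
#' @slot details list of method internals (exact vs approximate Mann–Whitney,
#'   Shapiro–Wilk p-values in auto mode).
#' @seealso [compareGroups()]
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", stars = "character",
                 groupSizes = "integer", details = "list"))

setValidity("TestResult", function(object) {
  msg <- character(0)
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be in [0, 1]")
  if (!identical(object@stars, assignStars(object@pValue)))
    msg <- c(msg, "stars inconsistent with p-value thresholds")
  if (length(msg)) msg else TRUE
})

#' Isoprobability ellipse parameters
#'
#' Parameters of the ellipse of a fitted bivariate normal containing a chosen
#' probability mass: centre at the sample mean, axes from the eigen
#' decomposition of the sample covariance scaled by the square root of the
#' chi-square (2 df) quantile at \code{probLevel}.
#'
#' @slot center numeric length-2.
#' @slot semiMajor,semiMinor numeric semi-axes (same units as the data).
#' @slot angleDeg numeric, major-axis orientation in degrees in \code{[0, 180)}.
#' @slot probLevel numeric in \code{(0, 1)}.
#' @seealso [isoEllipse()]
#' @export
setClass("EllipseParams",
  representation(center = "numeric", semiMajor = "numeric",
                 semiMinor = "numeric", angleDeg = "numeric",
                 probLevel = "numeric"))

setValidity("EllipseParams", function(object) {
  msg <- character(0)
  if (!(object@semiMinor > 0) || object@semiMajor < object@semiMinor)
    msg <- c(msg, "need semiMajor >= semiMinor > 0")
  if (object@probLevel <= 0 || object@probLevel >= 1)
    msg <- c(msg, "probLevel must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Alignment site-category tally
#'
#' Per-column classification of a nucleotide multiple alignment: constant
#' (exactly one distinct resolved base), variable (two or more), parsimony
#' informative (at least two distinct bases each present in at least two
#' sequences), singleton (variable but not informative); gaps and IUPAC
#' ambiguity codes count as missing, and all-missing columns are tallied
#' separately.
#'
#' @slot alignmentLength,nVariable,nParsimonyInformative,nSingleton,nConstant,nAllMissing integer tallies.
#' @slot pctParsimonyInformative numeric, \code{100 * informative / length}.
#' @seealso [tallySites()]
#' @export
setClass("SiteCounts",
  representation(alignmentLength = "integer", nVariable = "integer",
                 nParsimonyInformative = "integer", nSingleton = "integer",
                 nConstant = "integer", nAllMissing = "integer",
                 pctParsimonyInformative = "numeric"))

setValidity("SiteCounts", function(object) {
  msg <- character(0)
  if (object@nConstant + object@nVariable + object@nAllMissing !=
      object@alignmentLength)
    msg <- c(msg, "constant + variable + all-missing must equal the length")
  if (object@nSingleton + object@nParsimonyInformative != object@nVariable)
    msg <- c(msg, "singleton + informative must equal variable")
  if (object@pctParsimonyInformative < 0 ||
      object@pctParsimonyInformative > 100)
    msg <- c(msg, "percentage must be in [0, 100]")
  if (length(msg)) msg else TRUE
})
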