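# Parametric side-view spore silhouette generator.
#
# The base ovoid is built from two half-superellipses sharing the width axis:
# the proximal (hilar) half has exponent 2 (elliptic), the apical half has an
# exponent mapped from apexSharpness (sharper apex = lower exponent). For
# amygdaliform profiles a small ventral bump (<= 0.5 µm) renders the
# lateralised apiculus; it is part of the silhouette but placed so that it
# does not extend the long-axis caliper. The suprahilar notch is a
# raised-cosine inward indentation of chord notchWidthFrac * L on the
# proximal ventral flank, and its depth is calibrated by bisection so that
# the measured concavity fraction hits targetConcavity.

baseOvoid <- function(params, resolution) {
  a <- params@lengthUm / 2
  b <- params@widthUm / 2
  pApex <- 2 - 0.9 * params@apexSharpness
  t <- seq(0, 2 * pi, length.out = resolution + 1L)[-(resolution + 1L)]
  ct <- cos(t); st <- sin(t)
  p <- ifelse(ct >= 0, pApex, 2)
  x <- a * sign(ct) * abs(ct)^(2 / p)
  y <- b * sign(st) * abs(st)^(2 / p)
  cbind(x, y)
}

# Apiculus: ventral raised-cosine bump at the attachment point, rendered only
# for amygdaliform profiles. Height is capped at 0.35 µm so the caliper
# length stays that of the ovoid.
addApiculus <- function(v, params) {
  if (params@profileFamily != "amygdaliform") return(v)
  a <- params@lengthUm / 2
  b <- params@widthUm / 2
  yA <- -min(abs(params@apiculusOffset) * params@widthUm, 0.8 * b)
  xA <- -a * sqrt(max(0, 1 - (yA / b)^2))
  chord <- 0.9
  height <- 0.35
  sel <- v[, 2] < 0 & abs(v[, 1] - xA) <= chord / 2
  if (any(sel)) {
    w <- 0.5 * (1 + cos(2 * pi * (v[sel, 1] - xA) / chord))
    v[sel, 2] <- v[sel, 2] - height * w
  }
  v
}

notchCenter <- function(params) {
  L <- params@lengthUm
  -L / 2 + 0.06 * L + params@notchWidthFrac * L / 2
}

applyNotch <- function(v, depth, params) {
  if (depth <= 0) return(v)
  L <- params@lengthUm
  chord <- params@notchWidthFrac * L
  x0 <- notchCenter(params)
  sel <- v[, 2] < 0 & abs(v[, 1] - x0) <= chord / 2
  if (any(sel)) {
    w <- 0.5 * (1 + cos(2 * pi * (v[sel, 1] - x0) / chord))
    v[sel, 2] <- pmin(v[sel, 2] + depth * w, -1e-6 * L)
  }
  v
}

concavityFraction <- function(v) suprahilarDepression(v, check = FALSE) / 100

#' Generate a synthetic spore silhouette
#'
#' Builds the parametric side-view silhouette described by a
#' [SporeShapeParams-class] object: a two-half-superellipse ovoid, an optional
#' ventral apiculus bump (amygdaliform profiles only), and a raised-cosine
#' suprahilar notch whose depth is calibrated by bisection so that the
#' measured concavity fraction (hull area − polygon area) / hull area equals
#' \code{targetConcavity} within ±0.0005. The returned polygon is simple and
#' deterministic for fixed inputs; its maximum caliper length and
#' perpendicular width equal the nominal length and width within 1%.
#'
#' If the requested concavity is not attainable for the given notch chord
#' (or, for amygdaliform profiles, is below the concavity contributed by the
#' apiculus alone) an error of class \code{"sporeHullInfeasibleConcavity"}
#' is signalled whose \code{attainable} field names the attainable bound.
#'
#' @param params a [SporeShapeParams-class].
#' @param resolution number of contour vertices (>= 64; multiples of 4 place
#'   vertices exactly on the axis extremes).
#' @return A [SporeContour-class] whose provenance carries \code{params} and
#'   the calibrated notch depth.
#' @examples
#' p <- sporeShapeParams("ellipsoid", 12, 5, targetConcavity = 0.04)
#' suprahilarDepression(generateContour(p))  # ~4
#' @export
generateContour <- function(params, resolution = 256) {
  stopifnot(is(params, "SporeShapeParams"))
  validObject(params)
  resolution <- as.integer(resolution)
  if (resolution < 64L) stop("resolution must be at least 64 vertices")

  v0 <- addApiculus(baseOvoid(params, resolution), params)
  target <- params@targetConcavity
  tol <- 2e-4

  f <- function(d) concavityFraction(applyNotch(v0, d, params))
  c0 <- f(0)
  depth <- 0
  if (target > c0 + tol) {
    # feasible depth range: up to 95% of the local half-width at the notch
    lower <- v0[v0[, 2] < 0, , drop = FALSE]
    lower <- lower[order(lower[, 1]), , drop = FALSE]
    hw <- -stats::approx(lower[, 1], lower[, 2], xout = notchCenter(params),
                         rule = 2)$y
    dMax <- 0.95 * hw
    cMax <- f(dMax)
    if (target > cMax + tol)
      stop(errorCondition(
        sprintf(paste0("target concavity %.4f is not attainable with ",
                       "notchWidthFrac = %.2f; attainable maximum is %.4f"),
                target, params@notchWidthFrac, cMax),
        attainable = cMax,
        class = c("sporeHullInfeasibleConcavity", "error", "condition")))
    lo <- 0; hi <- dMax
    for (i in seq_len(80L)) {
      depth <- (lo + hi) / 2
      cm <- f(depth)
      if (abs(cm - target) <= tol / 2) break
      if (cm < target) lo <- depth else hi <- depth
    }
  } else if (target < c0 - tol) {
    stop(errorCondition(
      sprintf(paste0("target concavity %.4f is below the %.4f contributed ",
                     "by the apiculus; attainable minimum is %.4f"),
              target, c0, c0),
      attainable = c0,
      class = c("sporeHullInfeasibleConcavity", "error", "condition")))
  }

  SporeContour(applyNotch(v0, depth, params),
               provenance = list(params = params, notchDepth = depth),
               checkSimple = TRUE)
}

# Species-level silhouette templates: profile family and shape coefficients
# used both by the packaged fixtures and by the population sampler.
speciesShapeTemplate <- function(species) {
  switch(species,
    pulverulentus = list(profileFamily = "amygdaliform",
                         apexSharpness = 0.7, apiculusOffset = 0.30,
                         lengthUm = 12.29, widthUm = 4.87,
                         targetConcavity = 0.040),
    mediterraneensis = list(profileFamily = "subamygdaliform",
                            apexSharpness = 0.5, apiculusOffset = 0.15,
                            lengthUm = 12.67, widthUm = 5.33,
                            targetConcavity = 0.015),
    poikilochromus = list(profileFamily = "ellipsoid",
                          apexSharpness = 0.2, apiculusOffset = 0.10,
                          lengthUm = 11.83, widthUm = 5.03,
                          targetConcavity = 0.010),
    stop("unknown species: ", species))
}

#' Packaged species-like contour fixtures
#'
#' Deterministic silhouettes built from the species mean length and width and
#' the preset concavity level of each of the three Mediterranean species:
#' an amygdaliform contour with a pronounced suprahilar notch
#' (\emph{C. pulverulentus}-like, 4% of hull area), a subamygdaliform contour
#' with a shallow notch (\emph{C. mediterraneensis}-like, 1.5%), and a blunt
#' ellipsoid contour with a minimal notch (\emph{C. poikilochromus}-like, 1%).
#'
#' @param species one of \code{"pulverulentus"}, \code{"mediterraneensis"},
#'   \code{"poikilochromus"}.
#' @param resolution contour vertex count.
#' @return A [SporeContour-class].
#' @examples
#' suprahilarDepression(sporeContourFixture("pulverulentus"))  # > 3
#' @export
sporeContourFixture <- function(species = c("pulverulentus",
                                            "mediterraneensis",
                                            "poikilochromus"),
                                resolution = 256) {
  species <- match.arg(species)
  tpl <- speciesShapeTemplate(species)
  generateContour(do.call(sporeShapeParams, tpl), resolution = resolution)
}
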