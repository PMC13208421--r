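# The quantitative microscopy identification key as a deterministic,
# auditable rule engine. Thresholds are read from the packaged key schema
# (inst/extdata/identification_key.yaml); strict inequalities are applied
# exactly as the key states them, so its boundary gaps (average width exactly
# 5 µm, depression between 2.5 and 3% of hull area) are preserved and route
# to an indeterminate outcome rather than being rounded into a branch.

keySchemaCache <- new.env(parent = emptyenv())

#' The packaged identification-key schema
#'
#' Versioned structured encoding of the identification keys: the microscopy
#' key (couplet thresholds used by [classifyMicroscopy()]) and a data-only
#' encoding of the macromorphological/ecological field key (experimental,
#' not evaluated by the package).
#'
#' @return The schema as a nested list.
#' @export
keySchema <- function() {
  if (is.null(keySchemaCache$schema)) {
    path <- system.file("extdata", "identification_key.yaml",
                        package = "SporeHull", mustWork = TRUE)
    keySchemaCache$schema <- yaml::read_yaml(path)
  }
  keySchemaCache$schema
}

amygdaloidShapes <- c("narrowly_amygdaliform", "narrowly_subamygdaliform")

#' Classify collection-average microscopy features with the dichotomous key
#'
#' Traverses the microscopy key exactly as printed, recording the branch
#' taken at every couplet. Couplet 1 splits on average spore width (< 5 µm
#' vs > 5 µm); couplet 2 on average length > 12.5 µm (to
#' \emph{pulverulentus}) vs < 12.5 µm (to couplet 3); couplet 3 separates
#' blunt-ellipsoid spores with abundant gloeocystidia
#' (\emph{poikilochromus}) from amygdaliform spores with pronounced
#' depression and sparse gloeocystidia (\emph{pulverulentus}); couplet 4
#' separates short ellipsoidal spores with abundant gloeocystidia
#' (\emph{poikilochromus}) from longer sub/amygdaliform spores with sparse
#' gloeocystidia (to couplet 5), resolving its overlapping length conditions
#' by the categorical characters first; couplet 5 splits on the
#' suprahilar-depression percentage (> 3% of hull area to
#' \emph{pulverulentus}, < 2.5% to \emph{mediterraneensis}).
#'
#' Inputs falling into the key's own gaps (width exactly 5 µm, length
#' exactly 12.5 µm, depression in [2.5, 3]%), conflicting character
#' combinations, and unknown/missing characters all yield
#' \code{"indeterminate"} with the candidate species of the unresolved
#' couplet — never a guess.
#'
#' @param avgWidthUm,avgLengthUm collection-average spore width and length
#'   (µm).
#' @param dominantShape one of \code{"ellipsoid_blunt"},
#'   \code{"narrowly_amygdaliform"}, \code{"narrowly_subamygdaliform"},
#'   \code{"other"}.
#' @param depressionPct average suprahilar depression (% of hull area), may
#'   be \code{NA}.
#' @param gloeocystidia \code{"sparse"}, \code{"abundant"} or
#'   \code{"unknown"}.
#' @return A [KeyOutcome-class] with the label, candidate set and full
#'   decision path.
#' @examples
#' keyLabel(classifyMicroscopy(4.87, 12.29, "narrowly_amygdaliform",
#'                             3.5, "sparse"))  # pulverulentus
#' @export
classifyMicroscopy <- function(avgWidthUm, avgLengthUm,
                               dominantShape = c("other", "ellipsoid_blunt",
                                                 "narrowly_amygdaliform",
                                                 "narrowly_subamygdaliform"),
                               depressionPct = NA_real_,
                               gloeocystidia = c("unknown", "sparse",
                                                 "abundant")) {
  dominantShape <- match.arg(dominantShape)
  gloeocystidia <- match.arg(gloeocystidia)
  if (!isScalarFinite(avgWidthUm) || !isScalarFinite(avgLengthUm) ||
      avgWidthUm <= 0 || avgLengthUm <= 0)
    stop("average width and length must be positive scalars")
  if (!is.na(depressionPct) && (depressionPct < 0 || depressionPct >= 100))
    stop("depressionPct must be in [0, 100)")
  thr <- keySchema()$microscopy_key$thresholds
  species <- c("pulverulentus", "mediterraneensis", "poikilochromus")
  W <- avgWidthUm; L <- avgLengthUm
  dep <- depressionPct

  outcome <- function(label, path, candidates = label)
    new("KeyOutcome", label = label, candidates = candidates, path = path)
  indet <- function(path, candidates)
    outcome("indeterminate", path, candidates = sort(candidates))

  # couplet 5: depression regimes
  couplet5 <- function(path) {
    if (!is.na(dep) && dep > thr$depression_pronounced_pct)
      outcome("pulverulentus", c(path, "5a"))
    else if (!is.na(dep) && dep < thr$depression_shallow_pct)
      outcome("mediterraneensis", c(path, "5b"))
    else indet(c(path, "5?"), c("pulverulentus", "mediterraneensis"))
  }
  # couplet 4: categorical characters first, length second
  couplet4 <- function(path) {
    isA <- dominantShape == "ellipsoid_blunt" && gloeocystidia == "abundant"
    isB <- dominantShape %in% amygdaloidShapes && gloeocystidia == "sparse"
    if (isA && !isB) {
      if (L < thr$length_upper_um) return(outcome("poikilochromus",
                                                  c(path, "4a")))
      return(indet(c(path, "4?"), species))
    }
    if (isB && !isA) {
      if (L > thr$length_lower_um) return(couplet5(c(path, "4b")))
      return(indet(c(path, "4?"), species))
    }
    indet(c(path, "4?"), species)
  }
  # couplet 3: short narrow spores
  couplet3 <- function(path) {
    isA <- dominantShape == "ellipsoid_blunt" && gloeocystidia == "abundant"
    isB <- dominantShape %in% amygdaloidShapes &&
      gloeocystidia == "sparse" && !is.na(dep) &&
      dep > thr$depression_pronounced_pct
    if (isA && !isB) return(outcome("poikilochromus", c(path, "3a")))
    if (isB && !isA) return(outcome("pulverulentus", c(path, "3b")))
    indet(c(path, "3?"), c("poikilochromus", "pulverulentus"))
  }
  # couplet 2: long narrow spores
  couplet2 <- function(path) {
    if (L > thr$length_upper_um) outcome("pulverulentus", c(path, "2a"))
    else if (L < thr$length_upper_um) couplet3(c(path, "2b"))
    else indet(c(path, "2?"), c("pulverulentus", "poikilochromus"))
  }

  # couplet 1: width split
  if (W < thr$width_split_um) couplet2("1a")
  else if (W > thr$width_split_um) couplet4("1b")
  else indet("1?", species)
}

#' Classify a table of collection-level features
#'
#' Vectorised wrapper around [classifyMicroscopy()].
#'
#' @param features data.frame with columns \code{avg_width_um},
#'   \code{avg_length_um}, \code{dominant_shape}, \code{depression_pct},
#'   \code{gloeocystidia}.
#' @return The input with added columns \code{key_label}, \code{key_path}
#'   and \code{key_candidates}.
#' @export
classifyFeatures <- function(features) {
  stopifnot(is.data.frame(features))
  out <- lapply(seq_len(nrow(features)), function(i) {
    classifyMicroscopy(features$avg_width_um[i], features$avg_length_um[i],
                       features$dominant_shape[i],
                       features$depression_pct[i],
                       features$gloeocystidia[i])
  })
  features$key_label <- vapply(out, keyLabel, character(1))
  features$key_path <- vapply(out, pathString, character(1))
  features$key_candidates <- vapply(out, function(o)
    paste(keyCandidates(o), collapse = "+"), character(1))
  features
}

#' Collection-level key features of a measured population
#'
#' Aggregates per-spore measurements (from [measurePopulation()]) to the
#' collection level and attaches the categorical characters of the species
#' template, producing the feature table expected by [classifyFeatures()].
#'
#' @param measurements data.frame of per-spore measurements with
#'   \code{collection_id}, \code{L_um}, \code{W_um}, \code{depression_pct}.
#' @param dominantShape,gloeocystidia categorical characters of the
#'   collections (recycled).
#' @return One row per collection.
#' @export
collectionFeatures <- function(measurements, dominantShape = "other",
                               gloeocystidia = "unknown") {
  agg <- stats::aggregate(
    measurements[c("L_um", "W_um", "depression_pct")],
    by = list(collection_id = measurements$collection_id), FUN = mean)
  data.frame(collection_id = agg$collection_id,
             avg_width_um = agg$W_um, avg_length_um = agg$L_um,
             depression_pct = agg$depression_pct,
             dominant_shape = dominantShape,
             gloeocystidia = gloeocystidia, stringsAsFactors = FALSE)
}

# Map a species label to its categorical key characters.
speciesKeyCharacters <- function(species) {
  switch(species,
    pulverulentus = list(shape = "narrowly_amygdaliform",
                         gloeo = "sparse"),
    mediterraneensis = list(shape = "narrowly_subamygdaliform",
                            gloeo = "sparse"),
    poikilochromus = list(shape = "ellipsoid_blunt", gloeo = "abundant"),
    stop("unknown species: ", species))
}
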