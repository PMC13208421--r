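# Arsenic mass-fraction summaries and hyperaccumulation flagging.

#' Arsenic records of the Mediterranean Cyanoboletus collections
#'
#' Reads a CSV of per-sample arsenic mass fractions (mg per kg dry matter,
#' columns \code{species}, \code{origin_country}, \code{fungarium_id},
#' \code{as_mg_per_kg}). The default is the packaged table of 13 fungarium
#' collections of \emph{C. mediterraneensis} and \emph{C. poikilochromus}.
#'
#' @param file CSV path; \code{NULL} for the packaged table.
#' @return A data.frame of arsenic records.
#' @export
arsenicRecords <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "cyanoboletus_arsenic.csv",
                        package = "SporeHull", mustWork = TRUE)
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "origin_country", "fungarium_id", "as_mg_per_kg")
  if (!all(need %in% names(rec)))
    stop("arsenic CSV needs columns: ", paste(need, collapse = ", "))
  rec
}

#' Summarise arsenic mass fractions per species
#'
#' Per-species order-statistic median (mean of the central pair for even n),
#' minimum and maximum, plus an overall row across all records, with the
#' hyperaccumulation flag of [flagHyperaccumulator()]. Values are kept at
#' full precision; use [formatHalfUp()] for the two-decimal display
#' convention.
#'
#' @param records data.frame as returned by [arsenicRecords()].
#' @param thresholdMgPerKg hyperaccumulation threshold (mg/kg dry matter).
#' @return A data.frame with one row per species plus a row
#'   \code{species = "all"}: \code{n}, \code{median}, \code{minimum},
#'   \code{maximum}, \code{hyperaccumulator}, \code{threshold_used}.
#' @examples
#' summarizeArsenic(arsenicRecords())
#' @export
summarizeArsenic <- function(records, thresholdMgPerKg = 50) {
  if (!is.data.frame(records) || nrow(records) == 0L) stop("empty input")
  x <- records$as_mg_per_kg
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("non-positive arsenic value in record(s): ",
         paste(records$fungarium_id[bad], collapse = ", "))
  one <- function(label, v) {
    data.frame(species = label, n = length(v),
               median = stats::median(v), minimum = min(v), maximum = max(v),
               hyperaccumulator = flagHyperaccumulator(stats::median(v),
                                                       thresholdMgPerKg),
               threshold_used = thresholdMgPerKg, stringsAsFactors = FALSE)
  }
  sp <- split(x, records$species)
  out <- do.call(rbind, c(lapply(names(sp), function(s) one(s, sp[[s]])),
                          list(one("all", x))))
  rownames(out) <- NULL
  out
}

#' Flag a species as an arsenic hyperaccumulator
#'
#' A species is flagged when its median arsenic mass fraction reaches the
#' threshold; the default of 50 mg/kg dry matter reflects the level that the
#' one known hyperaccumulating species of the genus
#' (\emph{C. pulverulentus}, median 160 mg/kg in the literature) exceeds in
#' the vast majority of analysed collections. The boundary is inclusive
#' (median exactly at the threshold flags true).
#'
#' @param medianMgPerKg species median arsenic mass fraction (mg/kg dry).
#' @param thresholdMgPerKg flagging threshold, always echoed in outputs.
#' @return Logical.
#' @examples
#' flagHyperaccumulator(1.56)  # FALSE
#' flagHyperaccumulator(160)   # TRUE
#' @export
flagHyperaccumulator <- function(medianMgPerKg, thresholdMgPerKg = 50) {
  stopifnot(isScalarFinite(medianMgPerKg), isScalarFinite(thresholdMgPerKg))
  medianMgPerKg >= thresholdMgPerKg
}

#' Check a reference-material measurement against its certified interval
#'
#' Quality-control hook for digestion/ICP-MS runs: the measured value passes
#' when it lies within \code{certified ± tolerance}. The default interval is
#' the arsenic certificate of NIST SRM 1566b oyster tissue
#' (7.65 ± 0.65 mg/kg).
#'
#' @param measured measured mass fraction (mg/kg dry).
#' @param certified,tolerance certified value and its tolerance.
#' @return A list with \code{pass}, \code{measured}, \code{certified},
#'   \code{tolerance}, \code{deviation}.
#' @examples
#' qcReferenceCheck(7.72)$pass  # TRUE
#' @export
qcReferenceCheck <- function(measured, certified = 7.65, tolerance = 0.65) {
  dev <- measured - certified
  list(pass = abs(dev) <= tolerance, measured = measured,
       certified = certified, tolerance = tolerance, deviation = dev)
}
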