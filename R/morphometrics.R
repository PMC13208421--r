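# Classical spore descriptors and the hierarchical "(min) mean ± sd (max)"
# summaries used in taxonomic descriptions.

#' Derived spore metrics: Q ratio and rotation-ellipsoid volume
#'
#' \eqn{Q = L / W} and the approximate spore volume treating the spore as an
#' ellipsoid of rotation about its long axis, \eqn{apV = \pi L W^2 / 6}.
#' Vectorised over spores.
#'
#' @param L,W spore length and width (µm), positive.
#' @return A data.frame with columns \code{Q} (dimensionless) and \code{apV}
#'   (µm³).
#' @examples
#' sporeMetrics(12, 5)  # Q = 2.4, apV = 50*pi
#' @export
sporeMetrics <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0))
    stop("L and W must be positive")
  data.frame(Q = L / W, apV = pi * L * W^2 / 6)
}

#' Collection-level range summary of one variable
#'
#' Implements the convention of classical spore descriptions: the arithmetic
#' mean of the variable is computed for each collection first, and the
#' minimum, mean, sample SD (n − 1 denominator) and maximum are then taken
#' over those collection means. This differs from pooled-spore summaries
#' whenever collections are unbalanced.
#'
#' @param measurements data.frame with a \code{collection_id} column (and
#'   optionally \code{basidiome_id} for the count).
#' @param variable name of the numeric column to summarise.
#' @return A [RangeSummary-class].
#' @examples
#' df <- data.frame(collection_id = rep(c("a", "b", "c"), each = 2),
#'                  L = c(10, 10, 12, 12, 14, 14))
#' formatSummary(summarizeByCollection(df, "L"))  # (10) 12 +/- 2 (14)
#' @export
summarizeByCollection <- function(measurements, variable) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("empty input")
  if (!variable %in% names(measurements))
    stop("no column named '", variable, "'")
  if (!"collection_id" %in% names(measurements))
    stop("measurements need a collection_id column")
  cid <- measurements$collection_id
  bad <- which(is.na(cid) | !nzchar(as.character(cid)))
  if (length(bad))
    stop("missing collection_id in record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x <- measurements[[variable]]
  if (any(!is.finite(x))) stop("non-finite values in '", variable, "'")
  collMeans <- tapply(x, cid, mean)
  nc <- length(collMeans)
  nb <- if ("basidiome_id" %in% names(measurements))
    length(unique(paste(cid, measurements$basidiome_id))) else NA_integer_
  rangeSummary(variable,
               minimum = min(collMeans), mean = mean(collMeans),
               sd = if (nc > 1L) stats::sd(collMeans) else NA_real_,
               maximum = max(collMeans),
               nCollections = nc, nSpores = nrow(measurements),
               nBasidiomes = nb)
}

#' Decimal round-half-up rendering
#'
#' Formats numbers by rounding half-up on their decimal representation
#' (shortest 15-significant-digit form), so 1.555 renders "1.56" rather
#' than the "1.55" that binary-float rounding would give. Used for all
#' display rounding; internal arithmetic stays at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Character vector.
#' @examples
#' formatHalfUp(1.555, 2)  # "1.56"
#' @export
formatHalfUp <- function(x, digits = 2) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NA_character_)
    neg <- xi < 0
    s <- format(abs(xi), digits = 15, scientific = FALSE, trim = TRUE)
    if (!grepl(".", s, fixed = TRUE)) s <- paste0(s, ".")
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    intPart <- parts[1]
    frac <- if (length(parts) > 1L) parts[2] else ""
    frac <- substr(paste0(frac, strrep("0", digits + 1L)), 1L, digits + 1L)
    d <- as.integer(strsplit(paste0(intPart, substr(frac, 1L, digits)),
                             "")[[1]])
    if (as.integer(substr(frac, digits + 1L, digits + 1L)) >= 5L) {
      i <- length(d)
      repeat {
        if (i == 0L) { d <- c(1L, d); break }
        d[i] <- d[i] + 1L
        if (d[i] < 10L) break
        d[i] <- 0L
        i <- i - 1L
      }
    }
    nInt <- length(d) - digits
    out <- paste0(paste(d[seq_len(nInt)], collapse = ""),
                  if (digits > 0L)
                    paste0(".", paste(d[(nInt + 1L):length(d)],
                                      collapse = "")))
    paste0(if (neg) "-", out)
  }, character(1))
}

#' Format a range summary as a description string
#'
#' Renders the standard taxonomic notation
#' \code{"[n/m/p] (min) mean ± sd (max) unit"}, where n/m/p are the spore,
#' basidiome and collection counts. Values are rounded half-up on their
#' decimal representation; rounding is display-only.
#'
#' @param summary a [RangeSummary-class].
#' @param digits decimal places.
#' @param unit unit string appended to the values ("" for none).
#' @return A single string, e.g.
#'   \code{"[703/14/17] (12.01) 12.67 ± 0.74 (13.63) μm"}.
#' @export
formatSummary <- function(summary, digits = 2, unit = "μm") {
  stopifnot(is(summary, "RangeSummary"))
  counts <- c(summary@nSpores, summary@nBasidiomes, summary@nCollections)
  prefix <- if (all(!is.na(counts)))
    sprintf("[%d/%d/%d] ", counts[1], counts[2], counts[3]) else ""
  f <- function(v) formatHalfUp(v, digits)
  mid <- if (is.na(summary@sd)) f(summary@mean)
         else paste0(f(summary@mean), " ± ", f(summary@sd))
  paste0(prefix, "(", f(summary@minimum), ") ", mid,
         " (", f(summary@maximum), ")",
         if (nzchar(unit)) paste0(" ", unit))
}
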