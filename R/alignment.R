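# Alignment site-category tallies (constant / variable / parsimony
# informative / singleton), with gaps and IUPAC ambiguity codes treated as
# missing data — the common tallying convention.

alignmentMissing <- c("-", ".", "?", "N", "R", "Y", "S", "W", "K", "M",
                      "B", "D", "H", "V")
alignmentResolved <- c("A", "C", "G", "T")

# Coerce input to an upper-case character matrix (sequences x columns).
alignmentMatrix <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "RNAStringSet"))
    x <- as.character(x)
  if (is.character(x)) {
    w <- nchar(x)
    if (length(x) < 2L) stop("need at least 2 sequences")
    if (any(w != w[1]) || w[1] == 0L)
      stop("sequences must have equal, positive lengths")
    x <- do.call(rbind, strsplit(toupper(x), ""))
  } else if (is.matrix(x)) {
    x <- toupper(x)
    if (nrow(x) < 2L || ncol(x) == 0L)
      stop("need at least 2 sequences of positive length")
  } else stop("expected a DNAStringSet, character vector or matrix")
  x[x == "U"] <- "T"
  known <- c(alignmentResolved, alignmentMissing)
  offenders <- setdiff(unique(as.vector(x)), known)
  if (length(offenders))
    stop("non-nucleotide symbols in alignment: ",
         paste(offenders, collapse = ", "))
  x
}

#' Tally alignment site categories
#'
#' Classifies every column of a nucleotide multiple alignment. Gaps and
#' IUPAC ambiguity codes (including N) are treated as missing. A column is
#' constant when exactly one distinct resolved base occurs, variable when at
#' least two occur, parsimony informative when at least two distinct bases
#' are each present in at least two sequences, and singleton when variable
#' but not informative; all-missing columns are tallied separately. The
#' percentage of parsimony-informative sites is taken over the full
#' alignment length.
#'
#' @param x a \code{Biostrings::DNAStringSet}, a character vector of aligned
#'   sequences, or a character matrix (sequences in rows).
#' @return A [SiteCounts-class].
#' @examples
#' tallySites(c("AAAAA", "AAAAR", "AACCC", "ACC-C"))
#' @export
tallySites <- function(x) {
  m <- alignmentMatrix(x)
  len <- ncol(m)
  cls <- vapply(seq_len(len), function(j) {
    col <- m[, j]
    col <- col[col %in% alignmentResolved]
    if (!length(col)) return("missing")
    counts <- table(col)
    if (length(counts) == 1L) return("constant")
    if (sum(counts >= 2L) >= 2L) return("informative")
    "singleton"
  }, character(1))
  nInf <- sum(cls == "informative")
  nSing <- sum(cls == "singleton")
  new("SiteCounts",
      alignmentLength = len,
      nVariable = nInf + nSing,
      nParsimonyInformative = nInf,
      nSingleton = nSing,
      nConstant = sum(cls == "constant"),
      nAllMissing = sum(cls == "missing"),
      pctParsimonyInformative = 100 * nInf / len)
}

#' Read an aligned FASTA file for site tallying
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}.
#'
#' @param file FASTA path.
#' @return A \code{DNAStringSet}.
#' @export
readAlignment <- function(file) Biostrings::readDNAStringSet(file)
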