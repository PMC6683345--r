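#' @import methods
#' @importFrom stats median quantile rbinom rpois runif setNames t.test dnorm
#' @importFrom utils combn head
NULL

DNA_BASES <- c("A", "C", "G", "T")

.checkDna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains characters outside A/C/G/T: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Reverse complement of character DNA sequences
#'
#' Thin character-vector wrapper used throughout the package; sequences are
#' kept as plain strings internally for speed and converted to
#' \code{DNAStringSet} only at object boundaries.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.revChr <- function(x) {
  # plain reversal (no complement)
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' GC fraction of DNA strings
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in [0, 1].
#' @export
gcFraction <- function(x) {
  (nchar(x) - nchar(gsub("[GC]", "", x))) / nchar(x)
}

# Hamming distance between each string of `x` and a single `pattern`
# of the same width. Strings of differing width get NA.
.hammingToPattern <- function(x, pattern) {
  w <- nchar(pattern)
  d <- integer(length(x))
  ok <- nchar(x) == w
  d[!ok] <- NA_integer_
  if (any(ok)) {
    xs <- x[ok]
    mm <- integer(sum(ok))
    for (p in seq_len(w)) {
      mm <- mm + (substr(xs, p, p) != substr(pattern, p, p))
    }
    d[ok] <- mm
  }
  d
}

# All-pairs Hamming distances for equal-width strings.
.hammingMatrix <- function(x) {
  n <- length(x)
  m <- matrix(0L, n, n, dimnames = list(x, x))
  for (i in seq_len(n)) m[, i] <- .hammingToPattern(x, x[i])
  m
}

#' Random DNA sequences
#' @param n number of sequences.
#' @param width sequence length.
#' @return character vector of random A/C/G/T strings (uses the current RNG
#'   stream; call \code{set.seed} for reproducibility).
#' @export
randomDna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
    character(1))
}

# substitute a single base at position p
.substituteBase <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

.padTo <- function(x, width, pad = "A") {
  short <- nchar(x) < width
  if (any(short)) {
    x[short] <- paste0(x[short],
                       strrep(pad, width - nchar(x[short])))
  }
  substr(x, 1L, width)
}
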