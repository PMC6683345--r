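# Nearest-neighbor DNA duplex thermodynamics (unified Watson-Crick
# parameter set, 1 M NaCl reference): delta-G at 37 C in kcal/mol for the
# ten distinct dinucleotide stacks, plus per-terminal initiation terms.
.NN_DG37 <- c(
  AA = -1.00, AT = -0.88, TA = -0.58,
  CA = -1.45, GT = -1.44, CT = -1.28, GA = -1.30,
  CG = -2.17, GC = -2.24, GG = -1.84,
  # complements (reading the same stack from the other strand)
  TT = -1.00, TG = -1.45, AC = -1.44, AG = -1.28, TC = -1.30, CC = -1.84
)
.NN_INIT <- c(A = 1.03, T = 1.03, C = 0.98, G = 0.98)

# delta-H (kcal/mol) and delta-S (cal/mol/K) for melting-temperature
# estimates, same parameter family.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
.NN_INIT_H <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
.NN_INIT_S <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)

.dinucs <- function(x) {
  n <- nchar(x)
  if (n < 2L) return(character())
  substring(x, 1:(n - 1L), 2:n)
}

#' Nearest-neighbor melting temperature estimate
#'
#' Two-state nearest-neighbor Tm for a primer annealed to its perfect
#' complement, with a single default condition set (250 nM oligo, 50 mM
#' monovalent salt via a logarithmic correction).
#'
#' @param x character vector of primer sequences.
#' @param oligoConc total oligo concentration in M.
#' @param na monovalent cation concentration in M.
#' @return numeric vector of Tm estimates in degrees Celsius.
#' @export
tmEstimate <- function(x, oligoConc = 250e-9, na = 0.05) {
  vapply(x, function(s) {
    steps <- .dinucs(s)
    dh <- sum(.NN_DH[steps]) +
      .NN_INIT_H[substr(s, 1, 1)] + .NN_INIT_H[substr(s, nchar(s), nchar(s))]
    ds <- sum(.NN_DS[steps]) +
      .NN_INIT_S[substr(s, 1, 1)] + .NN_INIT_S[substr(s, nchar(s), nchar(s))]
    tm <- 1000 * dh / (ds + 1.987 * log(oligoConc / 4)) - 273.15
    tm + 16.6 * log10(na)
  }, numeric(1), USE.NAMES = FALSE)
}

# Best (most negative) duplex energy for one fixed orientation of a vs b:
# antiparallel complementary stretches between a and b correspond to exact
# common substrings of a and revcomp(b). Scans all diagonals, scoring each
# maximal complementary run as the sum of its interior stacks plus the two
# terminal initiation penalties. Runs of length < 2 carry no stack and are
# ignored (energy 0 = no stable duplex).
.duplexOneOrientation <- function(a, bRC) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(bRC, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  for (off in (-(m - 1L)):(n - 1L)) {
    ia <- max(1L, 1L + off):min(n, m + off)
    ib <- ia - off
    eq <- av[ia] == bv[ib]
    if (!any(eq)) next
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 2L)) {
      s <- ia[starts[j]]; e <- ia[ends[j]]
      stacks <- sum(.NN_DG37[.dinucs(substr(a, s, e))])
      en <- stacks + .NN_INIT[av[s]] + .NN_INIT[av[e]]
      if (en < best) best <- en
    }
  }
  best
}

.duplexBackends <- new.env(parent = emptyenv())
.duplexBackends$nn <- function(a, b) {
  .duplexOneOrientation(a, revComp(b))
}

#' Register a duplex-energy backend
#'
#' The default backend (\code{"nn"}) is a nearest-neighbor Watson-Crick
#' stacking model; an external thermodynamic tool can be plugged in by
#' registering a function \code{f(a, b)} returning the best duplex energy of
#' the two sequences as given (one fixed orientation each).
#'
#' @param name backend identifier.
#' @param fun function of two DNA strings returning kcal/mol.
#' @export
registerDuplexBackend <- function(name, fun) {
  stopifnot(is.function(fun))
  assign(name, fun, envir = .duplexBackends)
  invisible(name)
}

#' Minimal duplex free energy of two oligos
#'
#' Best (most negative) predicted duplex energy over all orientation
#' combinations of the two sequences, i.e. including both reverse
#' complements; more negative means a more stable cross-dimer. Symmetric in
#' its arguments; returns 0 when no complementary stretch of at least two
#' base pairs exists.
#'
#' @param a,b DNA strings.
#' @param backend backend identifier (see
#'   \code{\link{registerDuplexBackend}}); default \code{"nn"}.
#' @return numeric, kcal/mol.
#' @examples
#' duplexEnergy("ACGTACGTAC", revComp("ACGTACGTAC"))
#' @export
duplexEnergy <- function(a, b, backend = "nn") {
  if (!exists(backend, envir = .duplexBackends, inherits = FALSE))
    stop("unknown duplex-energy backend: ", backend, call. = FALSE)
  stopifnot(nzchar(a), nzchar(b))
  f <- get(backend, envir = .duplexBackends)
  # reverse-complementing both sequences leaves a duplex (and its energy)
  # unchanged, so two backend calls cover all four orientation combinations
  min(f(a, b), f(a, revComp(b)))
}
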