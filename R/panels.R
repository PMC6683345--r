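#' Configuration for barcode/adapter panel design
#'
#' Bundles the enumeration filters and simulated-annealing schedule used by
#' \code{\link{enumerateCandidates}} and \code{\link{annealPanel}}.
#'
#' The defaults encode the standard design conditions: candidate oligos of
#' 50--60\% GC with tandem repeats forbidden, and an annealing schedule that
#' scans temperatures from 10,000 down to 0 over 300 cooling iterations with
#' shrink/exchange/grow move probabilities of 10\%/36\%/54\%.
#'
#' @param length candidate oligo length in nt (8 for barcodes, 10 for
#'   adapters).
#' @param gcMin,gcMax GC-content window as fractions; a candidate with GC
#'   count \code{c} is admissible when
#'   \code{ceiling(gcMin*length) <= c <= floor(gcMax*length)}.
#' @param repeatRules named integer vector: maximum number of immediate
#'   tandem copies allowed for motifs of size 1, 2 and 3. The default
#'   \code{c("1"=2, "2"=1, "3"=1)} forbids homopolymer runs of 3+ and any
#'   immediate duplication of a di- or trinucleotide. \code{NULL} disables
#'   repeat filtering.
#' @param scoring list with integer \code{match}, \code{mismatch},
#'   \code{gapOpening}, \code{gapExtension} used for global alignment.
#' @param tInit starting annealing temperature.
#' @param nIterations number of cooling steps (temperature decreases
#'   linearly from \code{tInit} to 0).
#' @param pShrink,pExchange,pGrow move probabilities; must sum to 1.
#' @param targetSizeMin,targetSizeMax bounds on the selected set size.
#' @param normalizeObjective if \code{TRUE} (default) the objective is the
#'   mean pairwise score rather than the raw sum, so that grow moves are not
#'   self-penalizing; \code{FALSE} restores the raw-sum objective.
#' @param demuxSafe if \code{TRUE}, every pair within the selected set must
#'   be at Hamming distance >= 3, guaranteeing unambiguous single-mismatch
#'   demultiplexing.
#' @param polish if \code{TRUE} (default) the annealing run ends with a
#'   deterministic best-improvement exchange descent from the best state
#'   encountered, so the returned set is a local optimum of the exchange
#'   neighborhood.
#' @param seed integer RNG seed for the annealing run (\code{NULL} to use
#'   the current RNG state).
#' @return a list of class \code{"PanelDesignConfig"}.
#' @export
panelDesignConfig <- function(length = 8L, gcMin = 0.5, gcMax = 0.6,
                              repeatRules = c("1" = 2L, "2" = 1L, "3" = 1L),
                              scoring = list(match = 1L, mismatch = 0L,
                                             gapOpening = 0L,
                                             gapExtension = 0L),
                              tInit = 10000, nIterations = 300L,
                              pShrink = 0.10, pExchange = 0.36, pGrow = 0.54,
                              targetSizeMin = 8L, targetSizeMax = 24L,
                              normalizeObjective = TRUE, demuxSafe = FALSE,
                              polish = TRUE, seed = NULL) {
  stopifnot(gcMin >= 0, gcMax <= 1, gcMin <= gcMax,
            tInit > 0, nIterations >= 1,
            targetSizeMin >= 2, targetSizeMin <= targetSizeMax)
  if (abs(pShrink + pExchange + pGrow - 1) > 1e-8)
    stop("move probabilities must sum to 1", call. = FALSE)
  structure(list(length = as.integer(length), gcMin = gcMin, gcMax = gcMax,
                 repeatRules = repeatRules, scoring = scoring, tInit = tInit,
                 nIterations = as.integer(nIterations), pShrink = pShrink,
                 pExchange = pExchange, pGrow = pGrow,
                 targetSizeMin = as.integer(targetSizeMin),
                 targetSizeMax = as.integer(targetSizeMax),
                 normalizeObjective = normalizeObjective,
                 demuxSafe = demuxSafe, polish = polish, seed = seed),
            class = "PanelDesignConfig")
}

.hasForbiddenRepeat <- function(x, repeatRules) {
  if (is.null(repeatRules) || !length(repeatRules)) return(rep(FALSE, length(x)))
  bad <- rep(FALSE, length(x))
  for (k in names(repeatRules)) {
    maxCopies <- repeatRules[[k]]
    if (is.na(maxCopies)) next
    pat <- sprintf("([ACGT]{%s})\\1{%d,}", k, as.integer(maxCopies))
    bad <- bad | grepl(pat, x, perl = TRUE)
  }
  bad
}

#' Enumerate admissible barcode/adapter candidates
#'
#' Generates every DNA sequence of the configured length whose GC count lies
#' in the integer window \code{[ceiling(gcMin*L), floor(gcMax*L)]} and which
#' contains no forbidden tandem repeat. Output is deterministic and in
#' lexicographic order.
#'
#' @param config a \code{\link{panelDesignConfig}}.
#' @return character vector of candidate sequences.
#' @examples
#' length(enumerateCandidates(panelDesignConfig(length = 8)))
#' @export
enumerateCandidates <- function(config = panelDesignConfig()) {
  L <- config$length
  lo <- ceiling(config$gcMin * L)
  hi <- floor(config$gcMax * L)
  if (lo > hi)
    stop("no admissible candidates: GC window [", config$gcMin, ", ",
         config$gcMax, "] admits no integer GC count at length ", L,
         call. = FALSE)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), L), list(stringsAsFactors = FALSE)))
  # expand.grid varies the first column fastest; reverse for lexicographic order
  seqs <- do.call(paste0, rev(grid))
  gc <- round(gcFraction(seqs) * L)
  seqs <- seqs[gc >= lo & gc <= hi]
  if (!length(seqs))
    stop("no admissible candidates: GC filter removed all sequences",
         call. = FALSE)
  seqs <- seqs[!.hasForbiddenRepeat(seqs, config$repeatRules)]
  if (!length(seqs))
    stop("no admissible candidates: repeat rules removed all sequences",
         call. = FALSE)
  sort(seqs)
}

.substitutionMatrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

#' Orientation-maximal global alignment score of two oligos
#'
#' Global (Needleman-Wunsch) alignment score maximized over the four
#' orientation combinations \{a, revcomp(a)\} x \{b, revcomp(b)\}; this is
#' the similarity that the panel optimizer minimizes between selected
#' barcodes. Symmetric in its arguments.
#'
#' @param a,b DNA strings.
#' @param scoring list with \code{match}, \code{mismatch}, \code{gapOpening},
#'   \code{gapExtension}; the default (1/0/0/0) scores the longest common
#'   subsequence.
#' @return numeric alignment score.
#' @examples
#' pairwiseScore("ACGTACGT", "ACGTACGT")
#' @export
pairwiseScore <- function(a, b, scoring = list(match = 1L, mismatch = 0L,
                                               gapOpening = 0L,
                                               gapExtension = 0L)) {
  stopifnot(nzchar(a), nzchar(b))
  .checkDna(c(a, b))
  sub <- .substitutionMatrix(scoring)
  combos <- expand.grid(p = c(a, revComp(a)), s = c(b, revComp(b)),
                        stringsAsFactors = FALSE)
  max(vapply(seq_len(nrow(combos)), function(i)
    Biostrings::pairwiseAlignment(combos$p[i], combos$s[i],
                                  type = "global", substitutionMatrix = sub,
                                  gapOpening = scoring$gapOpening,
                                  gapExtension = scoring$gapExtension,
                                  scoreOnly = TRUE),
    numeric(1)))
}

#' All-pairs orientation-maximal alignment scores
#'
#' Precomputes the symmetric matrix of \code{\link{pairwiseScore}} values for
#' a candidate pool, so that annealing moves only index into it. Only two of
#' the four orientation combinations are computed per pair, since global
#' alignment scores are invariant under reverse-complementing both sequences.
#'
#' @param seqs character vector of candidate sequences.
#' @param scoring see \code{\link{pairwiseScore}}.
#' @return numeric \code{length(seqs)} square matrix.
#' @export
pairwiseScoreMatrix <- function(seqs, scoring = list(match = 1L, mismatch = 0L,
                                                     gapOpening = 0L,
                                                     gapExtension = 0L)) {
  n <- length(seqs)
  sub <- .substitutionMatrix(scoring)
  m <- matrix(0, n, n, dimnames = list(seqs, seqs))
  sets <- Biostrings::DNAStringSet(seqs)
  rcs <- Biostrings::reverseComplement(sets)
  for (i in seq_len(n)) {
    js <- seq_len(n) >= i
    s1 <- Biostrings::pairwiseAlignment(sets[js], seqs[i], type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = scoring$gapOpening,
                                        gapExtension = scoring$gapExtension,
                                        scoreOnly = TRUE)
    s2 <- Biostrings::pairwiseAlignment(rcs[js], seqs[i], type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = scoring$gapOpening,
                                        gapExtension = scoring$gapExtension,
                                        scoreOnly = TRUE)
    m[which(js), i] <- pmax(s1, s2)
    m[i, which(js)] <- m[which(js), i]
  }
  m
}

.objectiveFromMatrix <- function(idx, scoreMat, normalize = TRUE) {
  k <- length(idx)
  s <- (sum(scoreMat[idx, idx]) - sum(diag(scoreMat)[idx])) / 2
  if (normalize) s / (k * (k - 1) / 2) else s
}

#' Dissimilarity objective of a candidate set
#'
#' Sum of orientation-maximal pairwise alignment scores over all unordered
#' pairs, by default normalized by the number of pairs so that the objective
#' is comparable across set sizes. Lower is better (more mutually dissimilar
#' sequences).
#'
#' @param seqs character vector, length >= 2.
#' @param scoring see \code{\link{pairwiseScore}}.
#' @param normalize divide by the pair count (default \code{TRUE}).
#' @return numeric objective value.
#' @export
panelObjective <- function(seqs, scoring = list(match = 1L, mismatch = 0L,
                                                gapOpening = 0L,
                                                gapExtension = 0L),
                           normalize = TRUE) {
  if (length(seqs) < 2L)
    stop("panelObjective needs at least 2 sequences", call. = FALSE)
  m <- pairwiseScoreMatrix(seqs, scoring)
  .objectiveFromMatrix(seq_along(seqs), m, normalize)
}

# best-improvement exchange descent on the cached score matrix
.exchangeDescent <- function(idx, scoreMat, normalize, feasible) {
  n <- nrow(scoreMat)
  repeat {
    cur <- .objectiveFromMatrix(idx, scoreMat, normalize)
    best <- cur
    bestIdx <- NULL
    outside <- setdiff(seq_len(n), idx)
    for (pos in seq_along(idx)) {
      for (cand in outside) {
        trial <- idx
        trial[pos] <- cand
        if (!feasible(trial)) next
        o <- .objectiveFromMatrix(trial, scoreMat, normalize)
        if (o < best - 1e-12) {
          best <- o
          bestIdx <- trial
        }
      }
    }
    if (is.null(bestIdx)) return(idx)
    idx <- bestIdx
  }
}

#' Select a mutually dissimilar oligo set by simulated annealing
#'
#' Starting from a random subset of the candidate pool, repeatedly proposes
#' shrink (probability \code{pShrink}), exchange (\code{pExchange}) or grow
#' (\code{pGrow}) moves, accepting improvements always and worsening moves
#' with Metropolis probability \code{exp(-delta/T)} while the temperature
#' decreases linearly from \code{tInit} to 0 over \code{nIterations} steps.
#' The best set encountered anywhere along the run is returned (optionally
#' after a final greedy exchange descent, see \code{polish} in
#' \code{\link{panelDesignConfig}}).
#'
#' @param candidates character vector of admissible candidate sequences.
#' @param config a \code{\link{panelDesignConfig}}.
#' @param scoreMat optional precomputed \code{\link{pairwiseScoreMatrix}} of
#'   \code{candidates}.
#' @return list with \code{selection} (character vector), \code{objective},
#'   \code{initialObjective} and \code{trace} (objective per iteration).
#' @export
annealPanel <- function(candidates, config = panelDesignConfig(),
                        scoreMat = NULL) {
  n <- length(candidates)
  kmin <- config$targetSizeMin
  kmax <- min(config$targetSizeMax, n)
  if (n < kmin)
    stop("candidate pool (", n, ") smaller than targetSizeMin (", kmin, ")",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(scoreMat)) scoreMat <- pairwiseScoreMatrix(candidates,
                                                         config$scoring)
  norm <- config$normalizeObjective

  feasible <- function(idx) TRUE
  if (config$demuxSafe) {
    hm <- .hammingMatrix(candidates)
    feasible <- function(idx) {
      if (length(idx) < 2L) return(TRUE)
      sub <- hm[idx, idx]
      all(sub[upper.tri(sub)] >= 3L)
    }
  }

  # random initial state within the size bounds (retry under demuxSafe)
  k0 <- if (kmin == kmax) kmin else sample(kmin:kmax, 1L)
  idx <- sample.int(n, k0)
  if (config$demuxSafe) {
    tries <- 0L
    while (!feasible(idx)) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("could not build a demux-safe initial set (Hamming >= 3); ",
             "candidate pool too similar", call. = FALSE)
      idx <- sample.int(n, k0)
    }
  }

  cur <- .objectiveFromMatrix(idx, scoreMat, norm)
  initialObjective <- cur
  bestIdx <- idx
  bestObj <- cur
  nIter <- config$nIterations
  trace <- numeric(nIter)
  # elite pool: the best distinct states seen, used as descent starts
  eliteSize <- 10L
  elite <- list(list(idx = idx, obj = cur))

  for (it in seq_len(nIter)) {
    temp <- config$tInit * (nIter - it) / nIter
    u <- runif(1)
    move <- if (u < config$pShrink) "shrink"
            else if (u < config$pShrink + config$pExchange) "exchange"
            else "grow"
    # fall back to exchange at the size bounds
    if (move == "shrink" && length(idx) <= kmin) move <- "exchange"
    if (move == "grow" && (length(idx) >= kmax || length(idx) >= n))
      move <- "exchange"

    outside <- setdiff(seq_len(n), idx)
    if (!length(outside) && move != "shrink") { trace[it] <- cur; next }
    prop <- switch(move,
      shrink = idx[-sample.int(length(idx), 1L)],
      exchange = {
        p <- idx
        p[sample.int(length(p), 1L)] <- outside[sample.int(length(outside), 1L)]
        p
      },
      grow = c(idx, outside[sample.int(length(outside), 1L)]))
    if (!feasible(prop)) { trace[it] <- cur; next }
    obj <- .objectiveFromMatrix(prop, scoreMat, norm)
    delta <- obj - cur
    accept <- delta <= 0 ||
      (temp > 0 && runif(1) < exp(-delta / temp))
    if (accept) {
      idx <- prop
      cur <- obj
      if (cur < bestObj - 1e-12 ||
          (abs(cur - bestObj) <= 1e-12 && length(idx) > length(bestIdx))) {
        bestObj <- cur
        bestIdx <- idx
      }
      worst <- if (length(elite) < eliteSize) Inf
               else max(vapply(elite, `[[`, numeric(1), "obj"))
      if (cur < worst &&
          !any(vapply(elite, function(e)
            setequal(e$idx, idx), logical(1)))) {
        elite[[length(elite) + 1L]] <- list(idx = idx, obj = cur)
        if (length(elite) > eliteSize) {
          objs <- vapply(elite, `[[`, numeric(1), "obj")
          elite <- elite[order(objs)][seq_len(eliteSize)]
        }
      }
    }
    trace[it] <- cur
  }

  if (config$polish) {
    starts <- c(list(bestIdx), lapply(elite, `[[`, "idx"))
    for (st in starts) {
      cand <- .exchangeDescent(st, scoreMat, norm, feasible)
      obj <- .objectiveFromMatrix(cand, scoreMat, norm)
      if (obj < bestObj - 1e-12) {
        bestObj <- obj
        bestIdx <- cand
      }
    }
  }

  list(selection = candidates[sort(bestIdx)], objective = bestObj,
       initialObjective = initialObjective, trace = trace)
}

#' Design a complete dual-index barcode panel
#'
#' Runs candidate enumeration and simulated annealing for barcodes and for
#' adapters, splits the optimized barcode set into forward and reverse roles,
#' and assembles a \code{\link{BarcodePanel}}. The split is deterministic by
#' default: barcodes are sorted by their summed similarity to the rest of the
#' set and dealt alternately to the two roles, balancing the roles'
#' within-set similarity; \code{splitMethod = "random"} reproduces a seeded
#' random division instead.
#'
#' @param nFwd,nRev numbers of forward and reverse barcodes.
#' @param config barcode design configuration (\code{\link{panelDesignConfig}});
#'   its size bounds are overridden to \code{nFwd + nRev}.
#' @param adapterConfig adapter design configuration; defaults to 10-mers
#'   selected with the same schedule, two of them (one per role).
#' @param protectionGroup protection-group prefix for the panel.
#' @param splitMethod \code{"alternating"} (default) or \code{"random"}.
#' @param candidates optional pre-enumerated barcode candidate pool.
#' @return a \code{BarcodePanel}.
#' @export
designBarcodePanel <- function(nFwd = 12L, nRev = 8L,
                               config = panelDesignConfig(),
                               adapterConfig = panelDesignConfig(length = 10L,
                                 targetSizeMin = 2L, targetSizeMax = 2L,
                                 seed = if (is.null(config$seed)) NULL
                                        else config$seed + 1L),
                               protectionGroup = "CCA",
                               splitMethod = c("alternating", "random"),
                               candidates = NULL) {
  splitMethod <- match.arg(splitMethod)
  k <- nFwd + nRev
  config$targetSizeMin <- config$targetSizeMax <- as.integer(k)
  if (is.null(candidates)) candidates <- enumerateCandidates(config)
  # large enumerations are annealed over a seeded random subsample for speed
  maxPool <- 400L
  if (length(candidates) > maxPool) {
    if (!is.null(config$seed)) set.seed(config$seed)
    candidates <- sort(sample(candidates, maxPool))
  }
  run <- annealPanel(candidates, config)
  sel <- run$selection

  contrib <- rowSums(pairwiseScoreMatrix(sel, config$scoring)) # incl. self
  ord <- order(contrib, sel, decreasing = TRUE)
  if (splitMethod == "random") {
    ord <- sample(seq_along(sel))
  }
  dealt <- rep(c("fwd", "rev"), length.out = k)
  # alternate until one role is full, then fill the other
  fwd <- character(0); rev_ <- character(0)
  for (i in seq_len(k)) {
    if ((dealt[i] == "fwd" && length(fwd) < nFwd) || length(rev_) >= nRev)
      fwd <- c(fwd, sel[ord[i]])
    else rev_ <- c(rev_, sel[ord[i]])
  }

  adCand <- enumerateCandidates(adapterConfig)
  if (length(adCand) > maxPool) {
    if (!is.null(adapterConfig$seed)) set.seed(adapterConfig$seed)
    adCand <- sort(sample(adCand, maxPool))
  }
  adRun <- annealPanel(adCand, adapterConfig)
  ads <- adRun$selection

  BarcodePanel(fwd, rev_, ads[1], ads[2],
               protectionGroup = protectionGroup,
               objectiveScore = run$objective)
}

#' Screen panel ligations against a reference sequence set
#'
#' Removes every barcode whose barcode+adapter ligation (or its reverse
#' complement) shares an exact k-mer (default k = 14) with any sequence in
#' the reference; this is an internal seed screen standing in for a full
#' off-target alignment search, with the reference (e.g. a genome or
#' transcriptome FASTA) supplied by the user.
#'
#' @param panel a \code{\link{BarcodePanel}}.
#' @param reference \code{DNAStringSet} or path to a (optionally gzipped)
#'   FASTA file.
#' @param k seed length for the exact-substring screen.
#' @param enabled set \code{FALSE} to skip the screen (the panel is returned
#'   unchanged); screening with a missing or empty reference is an error.
#' @return the screened \code{BarcodePanel}.
#' @export
screenAgainstReference <- function(panel, reference, k = 14L, enabled = TRUE) {
  if (!enabled) return(panel)
  if (missing(reference) || is.null(reference))
    stop("reference is required (or disable the screen explicitly)",
         call. = FALSE)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (!length(reference) || sum(Biostrings::width(reference)) == 0)
    stop("reference is empty", call. = FALSE)

  keepRole <- function(lig) {
    ligs <- as.character(lig)
    keep <- logical(length(ligs))
    for (i in seq_along(ligs)) {
      s <- ligs[i]
      kmers <- substring(s, seq_len(nchar(s) - k + 1L),
                         seq_len(nchar(s) - k + 1L) + k - 1L)
      pats <- unique(c(kmers, revComp(kmers)))
      pd <- Biostrings::PDict(pats)
      hits <- sum(Biostrings::vcountPDict(pd, reference))
      keep[i] <- hits == 0L
    }
    keep
  }
  keepF <- keepRole(ligations(panel, "fwd"))
  keepR <- keepRole(ligations(panel, "rev"))
  if (!all(keepF) || !all(keepR))
    message(sum(!keepF) + sum(!keepR),
            " barcode(s) removed by the reference screen")
  methods::initialize(panel,
                      barcodesFwd = panel@barcodesFwd[keepF],
                      barcodesRev = panel@barcodesRev[keepR])
}
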