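#' Define an amplicon target
#'
#' @param geneId locus identifier.
#' @param template template DNA sequence (character).
#' @param targetInterval integer length-2, 0-based half-open interval on the
#'   template that the amplicon must span (e.g. the mutation site).
#' @param ampliconSizeRange allowed amplicon length range in nt.
#' @return list of class \code{"AmpliconTarget"}.
#' @export
ampliconTarget <- function(geneId, template, targetInterval,
                           ampliconSizeRange = c(80L, 250L)) {
  .checkDna(template, "template")
  stopifnot(length(targetInterval) == 2L,
            targetInterval[1] >= 0, targetInterval[2] <= nchar(template),
            targetInterval[1] < targetInterval[2],
            ampliconSizeRange[1] <= ampliconSizeRange[2])
  structure(list(geneId = geneId, template = template,
                 targetInterval = as.integer(targetInterval),
                 ampliconSizeRange = as.integer(ampliconSizeRange)),
            class = "AmpliconTarget")
}

#' Primer design configuration
#'
#' @param lengthRange primer length bounds in nt.
#' @param gcMin,gcMax preferred primer GC window (soft constraint entering
#'   the ranking penalty).
#' @param tmOpt target melting temperature in degrees Celsius.
#' @param maxPairs maximum number of candidate pairs per locus.
#' @return list of class \code{"PrimerDesignConfig"}.
#' @export
primerDesignConfig <- function(lengthRange = c(18L, 27L), gcMin = 0.4,
                               gcMax = 0.6, tmOpt = 60, maxPairs = 5L) {
  structure(list(lengthRange = as.integer(lengthRange), gcMin = gcMin,
                 gcMax = gcMax, tmOpt = tmOpt, maxPairs = as.integer(maxPairs)),
            class = "PrimerDesignConfig")
}

.primerPenalty <- function(seqs, config) {
  tm <- tmEstimate(seqs)
  gc <- gcFraction(seqs)
  gcDev <- pmax(0, config$gcMin - gc, gc - config$gcMax)
  lenDev <- abs(nchar(seqs) - mean(config$lengthRange))
  abs(tm - config$tmOpt) + 50 * gcDev + 0.5 * lenDev
}

#' Generate ranked primer pairs for one target
#'
#' Enumerates all primer windows on both strands whose 3' base is a thymine
#' (so that the template-independent adenine appended by the fill-in
#' polymerase completes a correct 3' end), pairs forward and reverse windows
#' that flank the target interval with an amplicon length inside the
#' configured range, and ranks pairs by a penalty summing melting-temperature
#' deviation, GC deviation and length deviation of both primers. At most
#' \code{maxPairs} (default 5) pairs are returned, deterministically.
#'
#' @param target an \code{\link{ampliconTarget}}.
#' @param config a \code{\link{primerDesignConfig}}.
#' @return data.frame with one row per pair: \code{gene_id}, \code{rank},
#'   \code{fwd_seq}, \code{fwd_start}, \code{rev_seq}, \code{rev_start}
#'   (0-based template coordinates of each primer's 5'-most template base),
#'   \code{amplicon_seq}, \code{amplicon_length}, \code{penalty}.
#' @export
generatePrimerCandidates <- function(target, config = primerDesignConfig()) {
  tpl <- target$template
  L <- nchar(tpl)
  lo <- config$lengthRange[1]; hi <- config$lengthRange[2]
  if (L <= target$ampliconSizeRange[1])
    stop("template shorter than the minimum amplicon size", call. = FALSE)
  iv <- target$targetInterval

  chars <- strsplit(tpl, "", fixed = TRUE)[[1]]
  # forward primers: windows ending in T, 3' end at or before the interval
  fwdEnd <- which(chars == "T")                       # 1-based end position
  fwdEnd <- fwdEnd[fwdEnd >= lo & fwdEnd <= iv[1]]
  fwd <- do.call(rbind, lapply(fwdEnd, function(e) {
    lens <- lo:min(hi, e)
    data.frame(start = e - lens, end = e, stringsAsFactors = FALSE) # 0-based start
  }))
  # reverse primers: template windows starting with A at/after the interval
  revStart <- which(chars == "A")                     # 1-based start position
  revStart <- revStart[revStart > iv[2] & revStart + lo - 1L <= L]
  rev_ <- do.call(rbind, lapply(revStart, function(s) {
    lens <- lo:min(hi, L - s + 1L)
    data.frame(start = s - 1L, end = s - 1L + lens, stringsAsFactors = FALSE)
  }))
  if (is.null(fwd) || !nrow(fwd) || is.null(rev_) || !nrow(rev_))
    stop("no valid primer pair for ", target$geneId,
         ": no 3'-T primer window flanking the target interval on ",
         if (is.null(fwd) || !nrow(fwd)) "the forward" else "the reverse",
         " side", call. = FALSE)

  fwd$seq <- substring(tpl, fwd$start + 1L, fwd$end)
  rev_$seq <- revComp(substring(tpl, rev_$start + 1L, rev_$end))
  fwd$pen <- .primerPenalty(fwd$seq, config)
  rev_$pen <- .primerPenalty(rev_$seq, config)
  # keep the best windows only, to bound the pairing step
  fwd <- fwd[order(fwd$pen, fwd$start, fwd$end), , drop = FALSE]
  rev_ <- rev_[order(rev_$pen, rev_$start, rev_$end), , drop = FALSE]
  fwd <- utils::head(fwd, 50L)
  rev_ <- utils::head(rev_, 50L)

  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  ampLen <- rev_$end[grid$r] - fwd$start[grid$f]
  ok <- ampLen >= target$ampliconSizeRange[1] &
        ampLen <= target$ampliconSizeRange[2]
  if (!any(ok))
    stop("no valid primer pair for ", target$geneId,
         ": no flanking pair yields an amplicon within [",
         target$ampliconSizeRange[1], ", ", target$ampliconSizeRange[2],
         "] nt", call. = FALSE)
  grid <- grid[ok, , drop = FALSE]
  ampLen <- ampLen[ok]
  pen <- fwd$pen[grid$f] + rev_$pen[grid$r]
  ord <- order(pen, fwd$start[grid$f], rev_$end[grid$r], ampLen)
  grid <- grid[ord, , drop = FALSE]
  ampLen <- ampLen[ord]
  pen <- pen[ord]

  # greedily take the top pairs with distinct primers on both sides
  keep <- integer(0)
  usedF <- integer(0); usedR <- integer(0)
  for (i in seq_len(nrow(grid))) {
    if (grid$f[i] %in% usedF || grid$r[i] %in% usedR) next
    keep <- c(keep, i)
    usedF <- c(usedF, grid$f[i]); usedR <- c(usedR, grid$r[i])
    if (length(keep) >= config$maxPairs) break
  }
  grid <- grid[keep, , drop = FALSE]
  data.frame(
    gene_id = target$geneId,
    rank = seq_along(keep),
    fwd_seq = fwd$seq[grid$f],
    fwd_start = fwd$start[grid$f],
    rev_seq = rev_$seq[grid$r],
    rev_start = rev_$start[grid$r],
    amplicon_seq = substring(tpl, fwd$start[grid$f] + 1L, rev_$end[grid$r]),
    amplicon_length = ampLen[keep],
    penalty = pen[keep],
    stringsAsFactors = FALSE)
}

#' In-silico ligation of primers to barcode-adapter oligos
#'
#' Forms every \code{protection + barcode + adapter + primer} full-length
#' sequence for the given role; the output has exactly
#' \code{length(barcodes) * length(primers)} elements.
#'
#' @param primers character vector of gene-specific primers (5' to 3').
#' @param panel a \code{\link{BarcodePanel}}.
#' @param role \code{"fwd"} or \code{"rev"}; the barcodes and adapter of
#'   this role are used.
#' @return character vector named \code{<barcodeId>.<primerIndex>}.
#' @export
inSilicoLigation <- function(primers, panel, role = c("fwd", "rev")) {
  role <- match.arg(role)
  .checkDna(primers, "primer")
  bc <- if (role == "fwd") barcodesFwd(panel) else barcodesRev(panel)
  ad <- as.character(if (role == "fwd") adapterFwd(panel)
                     else adapterRev(panel))
  if (!length(bc)) stop("panel has no ", role, " barcodes", call. = FALSE)
  grid <- expand.grid(b = seq_along(bc), p = seq_along(primers))
  out <- paste0(protectionGroup(panel), as.character(bc)[grid$b], ad,
                primers[grid$p])
  names(out) <- paste(names(bc)[grid$b], grid$p, sep = ".")
  out
}

#' Primer-set annealing configuration
#'
#' Defaults encode the standard schedule for per-locus primer-pair selection:
#' temperatures scanned from 15,000 to 0 over 500 cooling iterations, with an
#' 80\% probability of altering a single locus per move.
#'
#' @param tInit starting temperature.
#' @param nIterations cooling steps.
#' @param pAlter probability that a move alters one locus's candidate (the
#'   complementary move re-draws the whole selection).
#' @param energyBackend duplex-energy backend identifier.
#' @param literalObjective if \code{TRUE}, minimize the summed minimum free
#'   energies directly (which prefers the most stable dimers); the default
#'   \code{FALSE} minimizes dimer stability, i.e. maximizes the summed
#'   duplex delta-G.
#' @param polish end with a deterministic per-locus best-improvement descent.
#' @param seed RNG seed.
#' @return list of class \code{"PrimerAnnealConfig"}.
#' @export
primerAnnealConfig <- function(tInit = 15000, nIterations = 500L,
                               pAlter = 0.80, energyBackend = "nn",
                               literalObjective = FALSE, polish = TRUE,
                               seed = NULL) {
  stopifnot(pAlter > 0, pAlter <= 1, tInit > 0, nIterations >= 1)
  structure(list(tInit = tInit, nIterations = as.integer(nIterations),
                 pAlter = pAlter, energyBackend = energyBackend,
                 literalObjective = literalObjective, polish = polish,
                 seed = seed),
            class = "PrimerAnnealConfig")
}

# Cross-dimer interaction between two candidate primer pairs, computed on
# the full ligated sequences (all barcode versions of the forward and
# reverse full-length primers): sum of pairwise duplex energies over all
# unordered sequence pairs, including self-interactions when c == d.
.candidateEnergy <- function(seqsC, seqsD, same, backend) {
  tot <- 0
  if (same) {
    n <- length(seqsC)
    for (i in seq_len(n)) for (j in i:n)
      tot <- tot + duplexEnergy(seqsC[i], seqsC[j], backend)
  } else {
    for (x in seqsC) for (y in seqsD)
      tot <- tot + duplexEnergy(x, y, backend)
  }
  tot
}

#' Select one primer pair per locus by simulated annealing
#'
#' Minimizes the cross-dimer potential of the multiplexed set. Each
#' candidate pair contributes its fully ligated sequences (every barcode
#' with the matching adapter and primer, for both roles), and the objective
#' sums the minimal duplex free energies over all sequence pairs of the
#' selected set. By default the optimizer minimizes dimer stability
#' (maximizes the summed delta-G); \code{literalObjective = TRUE} inverts
#' this. Move proposals alter one locus with probability \code{pAlter} and
#' otherwise re-draw the whole selection; acceptance is Metropolis with a
#' linear cooling schedule, and the best selection encountered is returned.
#'
#' @param candidates named list, one element per locus, each a data.frame
#'   from \code{\link{generatePrimerCandidates}}.
#' @param panel a \code{\link{BarcodePanel}}.
#' @param config a \code{\link{primerAnnealConfig}}.
#' @return list with \code{selection} (data.frame, one chosen pair per
#'   locus), \code{objective}, \code{energySum} (summed delta-G of the
#'   selection) and \code{initialObjective}.
#' @export
annealPrimerSets <- function(candidates, panel,
                             config = primerAnnealConfig()) {
  if (!length(candidates)) stop("no loci supplied", call. = FALSE)
  nCand <- vapply(candidates, nrow, integer(1))
  if (any(nCand == 0L))
    stop("locus with no candidate pairs: ",
         paste(names(candidates)[nCand == 0L], collapse = ", "),
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  backend <- config$energyBackend
  nLoci <- length(candidates)

  # ligated sequence sets per (locus, candidate)
  ligSets <- lapply(candidates, function(df) {
    lapply(seq_len(nrow(df)), function(i)
      c(inSilicoLigation(df$fwd_seq[i], panel, "fwd"),
        inSilicoLigation(df$rev_seq[i], panel, "rev")))
  })

  # precompute candidate-pair interaction energies
  flat <- do.call(rbind, lapply(seq_len(nLoci), function(l)
    data.frame(locus = l, cand = seq_len(nCand[l]))))
  nf <- nrow(flat)
  E <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in i:nf) {
      si <- ligSets[[flat$locus[i]]][[flat$cand[i]]]
      sj <- ligSets[[flat$locus[j]]][[flat$cand[j]]]
      E[i, j] <- E[j, i] <- .candidateEnergy(si, sj, i == j, backend)
    }
  }
  flatIdx <- function(l, c) which(flat$locus == l & flat$cand == c)
  sign <- if (config$literalObjective) 1 else -1
  objectiveOf <- function(sel) { # sel: candidate index per locus
    ids <- vapply(seq_len(nLoci), function(l) flatIdx(l, sel[l]), integer(1))
    tot <- 0
    for (i in seq_len(nLoci)) for (j in i:nLoci)
      tot <- tot + E[ids[i], ids[j]]
    sign * tot
  }

  sel <- vapply(nCand, function(k) sample.int(k, 1L), integer(1))
  cur <- objectiveOf(sel)
  initialObjective <- cur
  bestSel <- sel; bestObj <- cur
  nIter <- config$nIterations
  for (it in seq_len(nIter)) {
    temp <- config$tInit * (nIter - it) / nIter
    prop <- sel
    if (runif(1) < config$pAlter) {
      l <- sample.int(nLoci, 1L)
      if (nCand[l] > 1L) {
        alt <- setdiff(seq_len(nCand[l]), sel[l])
        prop[l] <- alt[sample.int(length(alt), 1L)]
      }
    } else {
      prop <- vapply(nCand, function(k) sample.int(k, 1L), integer(1))
    }
    obj <- objectiveOf(prop)
    delta <- obj - cur
    if (delta <= 0 || (temp > 0 && runif(1) < exp(-delta / temp))) {
      sel <- prop; cur <- obj
      if (cur < bestObj - 1e-12) { bestObj <- cur; bestSel <- sel }
    }
  }

  if (config$polish) {
    repeat {
      improved <- FALSE
      for (l in seq_len(nLoci)) {
        for (c in seq_len(nCand[l])) {
          if (c == bestSel[l]) next
          trial <- bestSel; trial[l] <- c
          o <- objectiveOf(trial)
          if (o < bestObj - 1e-12) {
            bestObj <- o; bestSel <- trial; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }

  selection <- do.call(rbind, lapply(seq_len(nLoci), function(l)
    candidates[[l]][bestSel[l], , drop = FALSE]))
  rownames(selection) <- NULL
  list(selection = selection, objective = bestObj,
       energySum = sign * bestObj, initialObjective = initialObjective)
}

#' Emit assembly-ready oligos for a primer selection
#'
#' For every barcode, a barcode oligo \code{protection + barcode + adapter};
#' for every selected primer, an rc-primer oligo
#' \code{revcomp(adapter + primer)} carrying a 5'-phosphate (the preferred
#' exonuclease substrate, so the rc strand is removed after fill-in). The
#' two oligo types hybridize via the shared adapter and reconstruct the
#' barcoded primer \code{protection + barcode + adapter + primer} after
#' fill-in and digestion (see \code{\link{simulateAssembly}}).
#'
#' @param selection data.frame with \code{gene_id}, \code{fwd_seq},
#'   \code{rev_seq} (e.g. from \code{\link{annealPrimerSets}}).
#' @param panel a \code{\link{BarcodePanel}}.
#' @return data.frame ordering sheet with columns \code{id}, \code{kind},
#'   \code{role}, \code{sequence}, \code{has_5prime_phosphate},
#'   \code{protection_group}; one row per barcode plus one per primer.
#' @export
emitAssemblyOligos <- function(selection, panel) {
  pg <- protectionGroup(panel)
  rows <- list()
  for (role in c("fwd", "rev")) {
    bc <- if (role == "fwd") barcodesFwd(panel) else barcodesRev(panel)
    ad <- as.character(if (role == "fwd") adapterFwd(panel)
                       else adapterRev(panel))
    rows[[role]] <- data.frame(
      id = names(bc), kind = "barcode_oligo", role = role,
      sequence = paste0(pg, as.character(bc), ad),
      has_5prime_phosphate = FALSE, protection_group = pg,
      stringsAsFactors = FALSE)
    prim <- if (role == "fwd") selection$fwd_seq else selection$rev_seq
    rows[[paste0(role, "_p")]] <- data.frame(
      id = paste0(selection$gene_id, "_", role, "_rc"),
      kind = "rc_primer_oligo", role = role,
      sequence = revComp(paste0(ad, prim)),
      has_5prime_phosphate = TRUE, protection_group = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate fill-in and exonuclease digestion of an oligo pair
#'
#' Anneals a barcode oligo to an rc-primer oligo at their 3'-terminal
#' adapter duplex, extends the barcode strand across the rc template
#' (fill-in), and removes the 5'-phosphorylated rc strand (digestion),
#' returning the single-stranded barcoded primer. Errors if the two 3' ends
#' are not complementary over \code{adapterLength} bases.
#'
#' @param barcodeOligo \code{protection + barcode + adapter} sequence.
#' @param rcPrimerOligo \code{revcomp(adapter + primer)} sequence.
#' @param adapterLength length of the annealing adapter duplex.
#' @return the assembled barcoded primer sequence.
#' @export
simulateAssembly <- function(barcodeOligo, rcPrimerOligo, adapterLength = 10L) {
  nB <- nchar(barcodeOligo); nR <- nchar(rcPrimerOligo)
  adB <- substr(barcodeOligo, nB - adapterLength + 1L, nB)
  adR <- substr(rcPrimerOligo, nR - adapterLength + 1L, nR)
  if (adB != revComp(adR))
    stop("oligo 3' ends do not anneal over ", adapterLength, " bases",
         call. = FALSE)
  template <- substr(rcPrimerOligo, 1L, nR - adapterLength)
  paste0(barcodeOligo, revComp(template))
}
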