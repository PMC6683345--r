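#' Sequencing error model for the read simulator
#'
#' @param substitutionRate per-base substitution probability.
#' @param truncationProb probability that a read loses bases from its 5'
#'   end (emulating exonuclease trimming of unprotected barcodes).
#' @param truncationMax maximum number of 5' bases removed.
#' @param indexSwitchRate probability that a read's forward or reverse
#'   barcode is replaced by another barcode active on the plate (index
#'   switching); because each read switches independently, the artifact
#'   spreads in proportion to a well's read count, i.e. primarily from the
#'   most concentrated wells.
#' @param quality constant Phred quality assigned to all bases.
#' @return list of class \code{"ErrorModel"}.
#' @export
errorModel <- function(substitutionRate = 0, truncationProb = 0,
                       truncationMax = 4L, indexSwitchRate = 0,
                       quality = 37L) {
  stopifnot(substitutionRate >= 0, substitutionRate <= 1,
            truncationProb >= 0, truncationProb <= 1,
            indexSwitchRate >= 0, indexSwitchRate <= 1)
  structure(list(substitutionRate = substitutionRate,
                 truncationProb = truncationProb,
                 truncationMax = as.integer(truncationMax),
                 indexSwitchRate = indexSwitchRate,
                 quality = as.integer(quality)),
            class = "ErrorModel")
}

#' Plate design: wells, amplicons, abundances and genotypes
#'
#' The ground-truth description of a plate-structured experiment that
#' \code{\link{simulateReads}} turns into paired reads.
#'
#' @param wells data.frame with columns \code{well_id}, \code{fwd_id},
#'   \code{rev_id} (barcode ids, each combination unique),
#'   \code{cell_count} (sorted cells, 0 for negative controls) and
#'   optionally \code{is_negative_control}.
#' @param amplicons data.frame with columns \code{amplicon_id},
#'   \code{fwd_primer}, \code{rev_primer}, \code{insert} (sense sequence
#'   between the primers) and optionally \code{mut_insert} (mutant allele,
#'   NA when none) and \code{is_spike}.
#' @param abundance numeric matrix of expected read counts,
#'   wells x amplicons (dimnames must match ids).
#' @param genotypes optional character matrix wells x amplicons with values
#'   \code{"wt"}, \code{"het"}, \code{"hom"}; default all-\code{"wt"}.
#' @return list of class \code{"PlateDesign"}.
#' @export
plateDesign <- function(wells, amplicons, abundance, genotypes = NULL) {
  stopifnot(all(c("well_id", "fwd_id", "rev_id", "cell_count") %in%
                  names(wells)),
            all(c("amplicon_id", "fwd_primer", "rev_primer", "insert") %in%
                  names(amplicons)))
  if (anyDuplicated(paste(wells$fwd_id, wells$rev_id)))
    stop("barcode combinations must be unique per well", call. = FALSE)
  if (is.null(wells$is_negative_control))
    wells$is_negative_control <- wells$cell_count == 0L
  if (is.null(amplicons$mut_insert)) amplicons$mut_insert <- NA_character_
  if (is.null(amplicons$is_spike)) amplicons$is_spike <- FALSE
  abundance <- as.matrix(abundance)
  stopifnot(identical(rownames(abundance), wells$well_id),
            identical(colnames(abundance), amplicons$amplicon_id),
            all(abundance >= 0))
  neg <- wells$is_negative_control
  geneCols <- !amplicons$is_spike
  if (any(neg) && any(geneCols) &&
      any(abundance[neg, geneCols, drop = FALSE] > 0))
    stop("negative-control wells must have zero gene abundance (spikes only)",
         call. = FALSE)
  if (is.null(genotypes)) {
    genotypes <- matrix("wt", nrow(wells), nrow(amplicons),
                        dimnames = list(wells$well_id, amplicons$amplicon_id))
  }
  stopifnot(all(genotypes %in% c("wt", "het", "hom")))
  structure(list(wells = wells, amplicons = amplicons,
                 abundance = abundance, genotypes = genotypes),
            class = "PlateDesign")
}

#' Build a serial-dilution plate design
#'
#' Gene abundances fall by \code{fold} at each dilution step while spike-in
#' abundances stay constant across all wells, emulating a dilution series of
#' bulk RNA combined with a fixed spike-in mixture, plus spike-only negative
#' control wells.
#'
#' @param baseCounts named numeric vector: expected read counts per gene
#'   amplicon in the most concentrated well.
#' @param fold dilution factor between adjacent steps (> 1, default 4).
#' @param nSteps number of dilution steps.
#' @param replicates wells per step.
#' @param spikeLevels named numeric vector of constant spike-in expected
#'   counts.
#' @param amplicons amplicon table as in \code{\link{plateDesign}} covering
#'   \code{names(baseCounts)} and \code{names(spikeLevels)}.
#' @param fwdIds,revIds barcode id pools used to assign one unique
#'   combination per well.
#' @param negControls number of spike-only wells.
#' @return a \code{\link{plateDesign}}.
#' @export
simulateDilutionSeries <- function(baseCounts, fold = 4, nSteps = 4L,
                                   replicates = 9L, spikeLevels,
                                   amplicons, fwdIds, revIds,
                                   negControls = 1L) {
  stopifnot(fold > 1)
  nWells <- nSteps * replicates + negControls
  combos <- expand.grid(rev = revIds, fwd = fwdIds,
                        stringsAsFactors = FALSE)[, c("fwd", "rev")]
  if (nrow(combos) < nWells)
    stop("not enough barcode combinations for ", nWells, " wells",
         call. = FALSE)
  step <- c(rep(seq_len(nSteps), each = replicates), rep(NA, negControls))
  wells <- data.frame(
    well_id = sprintf("W%03d", seq_len(nWells)),
    fwd_id = combos$fwd[seq_len(nWells)],
    rev_id = combos$rev[seq_len(nWells)],
    cell_count = ifelse(is.na(step), 0L, 1L),
    is_negative_control = is.na(step),
    dilution_step = step,
    stringsAsFactors = FALSE)
  ampIds <- amplicons$amplicon_id
  ab <- matrix(0, nWells, length(ampIds),
               dimnames = list(wells$well_id, ampIds))
  for (g in names(baseCounts)) {
    ab[!is.na(step), g] <- baseCounts[[g]] * fold^(-(step[!is.na(step)] - 1))
  }
  for (s in names(spikeLevels)) ab[, s] <- spikeLevels[[s]]
  amplicons$is_spike <- ampIds %in% names(spikeLevels)
  plateDesign(wells, amplicons, ab)
}

.senseSequence <- function(fwdPrimer, insert, revPrimer) {
  paste0(fwdPrimer, insert, revComp(revPrimer))
}

#' Simulate paired-end reads from a plate design
#'
#' Emits read pairs with the dual-index structure
#' \code{R1 = protection + fwd barcode + fwd adapter + fwd primer + insert...}
#' and \code{R2 = protection + rev barcode + rev adapter + rev primer +
#' revcomp(insert)...}, each padded/truncated to \code{readLength}. Read
#' counts per (well, amplicon, allele) are Poisson around the design
#' abundances, or exactly equal to them in \code{fixedCounts} mode.
#' Substitution errors, 5' truncation and index switching are applied per
#' the \code{\link{errorModel}}; every read's true provenance is recorded.
#'
#' @param design a \code{\link{plateDesign}}.
#' @param panel a \code{\link{BarcodePanel}} containing (at least) every
#'   barcode id referenced by the design.
#' @param errors an \code{\link{errorModel}}.
#' @param seed integer RNG seed.
#' @param readLength fixed read length in nt.
#' @param fixedCounts if \code{TRUE}, emit exactly \code{round(abundance)}
#'   reads per cell (heterozygous wells: an even wt/mut split of the total).
#' @return list of class \code{"BartSim"}: \code{r1}, \code{r2} (character
#'   read vectors), \code{quality} (single Phred+33 quality string template),
#'   \code{truth} (per-read provenance data.frame), \code{wellCounts}
#'   (true per (well, amplicon, allele) counts), \code{design}, plus the
#'   panel.
#' @export
simulateReads <- function(design, panel, errors = errorModel(), seed = NULL,
                          readLength = 150L, fixedCounts = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  wells <- design$wells
  amps <- design$amplicons
  pg <- protectionGroup(panel)
  bcF <- setNames(as.character(barcodesFwd(panel)),
                  names(barcodesFwd(panel)))
  bcR <- setNames(as.character(barcodesRev(panel)),
                  names(barcodesRev(panel)))
  adF <- as.character(adapterFwd(panel))
  adR <- as.character(adapterRev(panel))
  missF <- setdiff(wells$fwd_id, names(bcF))
  missR <- setdiff(wells$rev_id, names(bcR))
  if (length(missF) || length(missR))
    stop("design references barcode ids absent from the panel: ",
         paste(c(missF, missR), collapse = ", "), call. = FALSE)
  structLen <- nchar(pg) + nchar(bcF[1]) + nchar(adF) +
    max(nchar(amps$fwd_primer))
  if (readLength < structLen)
    stop("readLength (", readLength,
         ") shorter than the structural prefix (", structLen, ")",
         call. = FALSE)

  # expected counts per (well, amplicon, allele)
  grid <- expand.grid(w = seq_len(nrow(wells)), a = seq_len(nrow(amps)))
  lam <- design$abundance[cbind(grid$w, grid$a)]
  geno <- design$genotypes[cbind(grid$w, grid$a)]
  hasMut <- !is.na(amps$mut_insert[grid$a])
  mutFrac <- ifelse(geno == "hom" & hasMut, 1,
                    ifelse(geno == "het" & hasMut, 0.5, 0))
  if (fixedCounts) {
    nTot <- round(lam)
    nMut <- round(nTot * mutFrac)
  } else {
    nTot <- rpois(length(lam), lam)
    nMut <- rbinom(length(lam), nTot, mutFrac)
  }
  nWt <- nTot - nMut

  blocks <- data.frame(
    w = rep(grid$w, 2L), a = rep(grid$a, 2L),
    allele = rep(c("wt", "mut"), each = length(nTot)),
    n = c(nWt, nMut), stringsAsFactors = FALSE)
  blocks <- blocks[blocks$n > 0L, , drop = FALSE]

  widx <- rep(blocks$w, blocks$n)
  aidx <- rep(blocks$a, blocks$n)
  allele <- rep(blocks$allele, blocks$n)
  nReads <- length(widx)

  insert <- ifelse(allele == "mut", amps$mut_insert[aidx], amps$insert[aidx])
  sense <- .senseSequence(amps$fwd_primer[aidx], insert,
                          amps$rev_primer[aidx])
  fwdId <- wells$fwd_id[widx]
  revId <- wells$rev_id[widx]

  # index switching: replace one mate's barcode by another active barcode
  switched <- rep(FALSE, nReads)
  if (errors$indexSwitchRate > 0 && nReads > 0) {
    switched <- runif(nReads) < errors$indexSwitchRate
    which_ <- which(switched)
    pickOther <- function(id, pool) {
      alt <- setdiff(pool, id)
      alt[sample.int(length(alt), 1L)]
    }
    for (i in which_) {
      if (runif(1) < 0.5) {
        fwdId[i] <- pickOther(fwdId[i], unique(wells$fwd_id))
      } else {
        revId[i] <- pickOther(revId[i], unique(wells$rev_id))
      }
    }
  }

  r1 <- .padTo(paste0(pg, bcF[fwdId], adF, sense), readLength)
  # R2 carries the antisense strand: rev primer then revcomp of the insert
  r2 <- .padTo(paste0(pg, bcR[revId], adR, revComp(sense)), readLength)

  truncated <- rep(0L, nReads)
  if (errors$truncationProb > 0 && nReads > 0) {
    doTrunc <- runif(nReads) < errors$truncationProb
    k <- integer(nReads)
    k[doTrunc] <- sample.int(errors$truncationMax, sum(doTrunc),
                             replace = TRUE)
    truncated <- k
    if (any(doTrunc)) {
      r1[doTrunc] <- .padTo(substr(r1[doTrunc], k[doTrunc] + 1L, readLength),
                            readLength)
    }
  }

  nsub <- rep(0L, nReads)
  if (errors$substitutionRate > 0 && nReads > 0) {
    applySubs <- function(reads) {
      ns <- rbinom(length(reads), readLength, errors$substitutionRate)
      for (i in which(ns > 0L)) {
        pos <- sample.int(readLength, ns[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        }
      }
      list(reads = reads, n = ns)
    }
    s1 <- applySubs(r1)
    s2 <- applySubs(r2)
    r1 <- s1$reads; r2 <- s2$reads
    nsub <- s1$n + s2$n
  }

  truth <- data.frame(
    read = if (nReads) sprintf("read%06d", seq_len(nReads)) else character(),
    well = wells$well_id[widx],
    fwd_id = wells$fwd_id[widx], rev_id = wells$rev_id[widx],
    amplicon = amps$amplicon_id[aidx],
    allele = allele, switched = switched, truncated = truncated,
    nsub = nsub, stringsAsFactors = FALSE)
  wellCounts <- as.data.frame(
    table(well = truth$well, amplicon = truth$amplicon,
          allele = truth$allele),
    stringsAsFactors = FALSE)
  names(wellCounts)[4] <- "count"

  structure(list(r1 = r1, r2 = r2,
                 quality = strrep(rawToChar(as.raw(errors$quality + 33L)),
                                  readLength),
                 truth = truth, wellCounts = wellCounts,
                 design = design, panel = panel,
                 readLength = as.integer(readLength)),
            class = "BartSim")
}

#' Write simulated reads as paired FASTQ files
#'
#' @param sim a \code{"BartSim"} object from \code{\link{simulateReads}}.
#' @param prefix output path prefix; files \code{<prefix>_R1.fastq.gz} and
#'   \code{<prefix>_R2.fastq.gz} are written.
#' @param compress write gzipped FASTQ (default \code{TRUE}).
#' @return invisibly, the two file paths.
#' @export
writeSimFastq <- function(sim, prefix, compress = TRUE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (i in 1:2) {
    reads <- if (i == 1) sim$r1 else sim$r2
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sim$truth$read
    q <- Biostrings::PhredQuality(rep(sim$quality, length(x)))
    qx <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(qx, paths[i],
                                             compress = compress)
  }
  invisible(paths)
}
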