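#' Assign reads to wild-type or mutant alleles
#'
#' Each read is assigned to the allele reference (wild type or mutant) at
#' the smaller edit distance; ties leave the read unassigned. This replaces
#' an alignment-based top-hit assignment, which is equivalent for short,
#' fully known amplicons.
#'
#' @param reads character vector of read-derived amplicon sequences for one
#'   sample x amplicon.
#' @param wt,mut allele reference sequences (must differ).
#' @return list with \code{wt_count}, \code{mut_count}, \code{unassigned}.
#' @export
callAlleles <- function(reads, wt, mut) {
  stopifnot(!identical(wt, mut))
  if (!length(reads))
    return(list(wt_count = 0L, mut_count = 0L, unassigned = 0L))
  # compare over the read length so partial reads are scored fairly
  dWt <- as.integer(utils::adist(reads, wt))
  dMut <- as.integer(utils::adist(reads, mut))
  list(wt_count = sum(dWt < dMut),
       mut_count = sum(dMut < dWt),
       unassigned = sum(dWt == dMut))
}

#' Call a genotype from allele counts by the ratio rule
#'
#' The mutation is called when the mutant-to-wild-type read ratio strictly
#' exceeds the threshold (default 0.20) and the total depth reaches
#' \code{minDepth}; below the depth floor no call is made. A wild-type well
#' with zero wild-type but positive mutant reads has ratio +Inf.
#'
#' @param wtCount,mutCount integer vectors of allele read counts.
#' @param threshold ratio threshold (strict inequality), default 0.20.
#' @param minDepth minimum total reads for a call (default 20; set 0 for
#'   the literal thresholding behavior with no depth floor).
#' @return data.frame with \code{wt_count}, \code{mut_count}, \code{ratio},
#'   \code{call} (\code{"wt"}, \code{"mutation"} or \code{"no_call"}).
#' @examples
#' callGenotype(100, 21)$call  # "mutation": 0.21 > 0.20
#' callGenotype(100, 20)$call  # "wt": the inequality is strict
#' @export
callGenotype <- function(wtCount, mutCount, threshold = 0.20,
                         minDepth = 20L) {
  stopifnot(length(wtCount) == length(mutCount))
  ratio <- ifelse(wtCount == 0,
                  ifelse(mutCount > 0, Inf, NA_real_),
                  mutCount / wtCount)
  depth <- wtCount + mutCount
  call <- ifelse(depth < minDepth, "no_call",
                 ifelse(!is.na(ratio) & ratio > threshold, "mutation", "wt"))
  data.frame(wt_count = wtCount, mut_count = mutCount, ratio = ratio,
             call = call, stringsAsFactors = FALSE)
}

#' Genotype a demultiplexed plate
#'
#' Convenience wrapper: groups simulated/demultiplexed reads by well and
#' amplicon, extracts the amplicon portion of mate 1, assigns alleles and
#' applies the ratio rule.
#'
#' @param sim a \code{"BartSim"} object.
#' @param annotations data.frame from \code{\link{demuxReads}} for the same
#'   reads.
#' @param threshold,minDepth see \code{\link{callGenotype}}.
#' @return data.frame with one row per (well, amplicon) carrying allele
#'   counts, ratio and call.
#' @export
genotypePlate <- function(sim, annotations, threshold = 0.20,
                          minDepth = 20L) {
  amps <- sim$design$amplicons
  wells <- sim$design$wells
  panel <- sim$panel
  prefixLen <- nchar(protectionGroup(panel)) +
    unique(Biostrings::width(barcodesFwd(panel))) +
    nchar(as.character(adapterFwd(panel)))
  ok <- annotations$category == "assigned"
  key <- paste(annotations$fwd_id, annotations$rev_id, sep = "x")
  wellKey <- setNames(wells$well_id, paste(wells$fwd_id, wells$rev_id,
                                           sep = "x"))
  wellOf <- unname(wellKey[key])
  out <- list()
  for (a in which(!is.na(amps$mut_insert))) {
    aid <- amps$amplicon_id[a]
    wtRef <- .senseSequence(amps$fwd_primer[a], amps$insert[a],
                            amps$rev_primer[a])
    mutRef <- .senseSequence(amps$fwd_primer[a], amps$mut_insert[a],
                             amps$rev_primer[a])
    sel <- ok & !is.na(wellOf) & annotations$amplicon_id == aid
    for (w in unique(wellOf[sel])) {
      rows <- which(sel & wellOf == w)
      frag <- substr(sim$r1[rows], prefixLen + 1L, sim$readLength)
      L <- min(nchar(frag))
      cc <- callAlleles(substr(frag, 1L, L),
                        substr(wtRef, 1L, L), substr(mutRef, 1L, L))
      out[[length(out) + 1L]] <- data.frame(
        well = w, amplicon = aid, wt_count = cc$wt_count,
        mut_count = cc$mut_count, unassigned = cc$unassigned,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  cbind(res, callGenotype(res$wt_count, res$mut_count, threshold,
                          minDepth)[, c("ratio", "call")])
}

#' Tabulate 5' protection-group trinucleotides per barcode
#'
#' Locates each barcode within the read 5' region allowing at most one
#' mismatch and records the trinucleotide immediately 5' of it; frequencies
#' are tabulated per barcode over all 64 trinucleotides and summed across
#' reads of all alleles. Used to rank candidate protection groups by how
#' well they survive assembly.
#'
#' @param reads character vector of reads whose structure is
#'   \code{NNN + barcode + ...}.
#' @param barcodes named character vector of barcodes to scan for.
#' @param maxOffset additional offsets (beyond the trinucleotide) to scan.
#' @return list with \code{table} (data.frame \code{barcode_id},
#'   \code{trinucleotide}, \code{count}; 64 rows per barcode),
#'   \code{totals} (named numeric, per-trinucleotide counts summed over
#'   barcodes, decreasing), \code{skipped} (reads too short to carry a 5'
#'   trinucleotide).
#' @export
protectionScan <- function(reads, barcodes, maxOffset = 0L) {
  w <- unique(nchar(barcodes))
  stopifnot(length(w) == 1L)
  tris <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES)[
    , 3:1, drop = FALSE])
  tris <- sort(tris)
  counts <- matrix(0L, length(barcodes), 64L,
                   dimnames = list(names(barcodes), tris))
  skipped <- 0L
  idx <- buildVariantIndex(barcodes)
  n <- length(reads)
  assigned <- rep(NA_character_, n)
  triOf <- rep(NA_character_, n)
  for (off in 0:maxOffset) {
    start <- 3L + off + 1L
    todo <- is.na(assigned)
    if (!any(todo)) break
    win <- substr(reads[todo], start, start + w - 1L)
    full <- nchar(win) == w
    hit <- rep(NA_character_, sum(todo))
    hit[full] <- ifelse(!is.na(idx$exact[win[full]]),
                        unname(idx$exact[win[full]]),
                        unname(idx$variants[win[full]]))
    tri <- substr(reads[todo], off + 1L, off + 3L)
    setRows <- which(todo)[!is.na(hit)]
    assigned[setRows] <- hit[!is.na(hit)]
    triOf[setRows] <- tri[!is.na(hit)]
  }
  short <- nchar(reads) < 3L + w
  skipped <- sum(short)
  ok <- !is.na(assigned) & !short & !grepl("[^ACGT]", triOf)
  if (any(ok)) {
    tab <- table(factor(assigned[ok], levels = names(barcodes)),
                 factor(triOf[ok], levels = tris))
    counts <- counts + as.matrix(tab)
  }
  long <- data.frame(
    barcode_id = rep(rownames(counts), times = 64L),
    trinucleotide = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts), stringsAsFactors = FALSE)
  totals <- sort(colSums(counts), decreasing = TRUE)
  list(table = long, totals = totals, skipped = skipped,
       matrix = counts)
}
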