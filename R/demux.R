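#' Quality-trim read 3' ends
#'
#' Sliding-window trimmer: each read is cut at the start of the first window
#' (moving 5' to 3') whose mean Phred quality falls below the threshold.
#' The structural prefix (protection + barcode + adapter + primer region)
#' can be protected from trimming via \code{protectLen}.
#'
#' @param seqs character vector of reads.
#' @param quals character vector of Phred+33 quality strings (same widths).
#' @param window window size in nt.
#' @param qThreshold minimum mean window quality.
#' @param protectLen never trim to a length below this prefix length.
#' @return list with \code{seqs}, \code{quals} (trimmed) and \code{empty}
#'   (logical: read empty after trimming).
#' @export
trimQuality <- function(seqs, quals, window = 5L, qThreshold = 20,
                        protectLen = 0L) {
  stopifnot(length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  n <- length(seqs)
  cut <- nchar(seqs)
  for (i in seq_len(n)) {
    q <- as.integer(charToRaw(quals[i])) - 33L
    L <- length(q)
    if (L < window) next
    cs <- cumsum(c(0L, q))
    means <- (cs[(window + 1L):(L + 1L)] - cs[1L:(L - window + 1L)]) / window
    bad <- which(means < qThreshold)
    if (length(bad)) cut[i] <- max(bad[1L] - 1L, protectLen)
  }
  list(seqs = substr(seqs, 1L, cut), quals = substr(quals, 1L, cut),
       empty = cut == 0L)
}

#' Build a single-mismatch barcode variant index
#'
#' For each barcode, enumerates the barcode itself and all its
#' single-substitution variants (optionally also single-indel variants),
#' then removes every variant generated by two or more different barcodes:
#' such variants are ambiguous and must not be assigned. Exact barcode
#' sequences are always retained (an exact hit beats any variant hit).
#'
#' @param barcodes named character vector of barcodes (uniform width,
#'   pairwise distinct).
#' @param allowIndels also index single-deletion and single-insertion
#'   variants (width differs by one; default \code{FALSE}).
#' @return list of class \code{"VariantIndex"}: \code{exact} and
#'   \code{variants} (named character: sequence -> barcode id),
#'   \code{width}, \code{allowIndels}, \code{barcodes}.
#' @export
buildVariantIndex <- function(barcodes, allowIndels = FALSE) {
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in panel role", call. = FALSE)
  .checkDna(barcodes, "barcode")
  w <- unique(nchar(barcodes))
  if (length(w) != 1L)
    stop("barcodes must have uniform width", call. = FALSE)
  if (is.null(names(barcodes)))
    names(barcodes) <- sprintf("B%02d", seq_along(barcodes))

  variantsOf <- function(bc) {
    out <- character()
    for (p in seq_len(w)) {
      for (b in setdiff(DNA_BASES, substr(bc, p, p))) {
        out <- c(out, .substituteBase(bc, p, b))
      }
    }
    if (allowIndels) {
      dels <- vapply(seq_len(w), function(p)
        paste0(substr(bc, 1L, p - 1L), substr(bc, p + 1L, w)), character(1))
      ins <- unlist(lapply(seq_len(w + 1L), function(p)
        paste0(substr(bc, 1L, p - 1L), DNA_BASES, substr(bc, p, w))))
      out <- c(out, unique(c(dels, ins)))
    }
    unique(c(bc, out))
  }
  varList <- lapply(barcodes, variantsOf)
  allVar <- unlist(varList, use.names = FALSE)
  owner <- rep(names(barcodes), lengths(varList))
  shared <- unique(allVar[duplicated(allVar)])
  keep <- !(allVar %in% shared) | allVar %in% barcodes
  variants <- setNames(owner[keep], allVar[keep])
  # exact sequences map to their own barcode even if they collide with a
  # variant of another barcode
  variants[barcodes] <- names(barcodes)
  structure(list(exact = setNames(names(barcodes), barcodes),
                 variants = variants, width = w,
                 allowIndels = allowIndels, barcodes = barcodes),
            class = "VariantIndex")
}

#' Assign barcodes to reads with at most one unambiguous mismatch
#'
#' Scans the expected barcode region of each read (after the protection
#' group, allowing up to \code{maxOffset} extra leading bases) against a
#' \code{\link{buildVariantIndex}}. Exact hits are preferred over
#' single-mismatch variant hits; two distinct barcodes hit at the same rank
#' leave the read unassigned with the \code{multiple_barcodes} flag.
#'
#' @param reads character vector of read sequences.
#' @param index a \code{\link{buildVariantIndex}}.
#' @param protection protection-group prefix expected before the barcode
#'   (may be \code{""}).
#' @param maxOffset maximum number of unexpected bases tolerated before the
#'   protection group.
#' @return data.frame with \code{barcode_id} (NA when unassigned) and flag
#'   columns \code{no_barcode}, \code{multiple_barcodes},
#'   \code{barcode_mismatch}, \code{bases_before_protection}.
#' @export
matchBarcode <- function(reads, index, protection = "CCA", maxOffset = 3L) {
  n <- length(reads)
  w <- index$width
  pgLen <- nchar(protection)
  K <- maxOffset + 1L

  idM <- matrix(NA_character_, n, K)
  exM <- matrix(FALSE, n, K)
  for (off in 0:maxOffset) {
    win <- substr(reads, off + pgLen + 1L, off + pgLen + w)
    win[nchar(win) < w] <- NA_character_
    exb <- unname(index$exact[win])
    vrb <- unname(index$variants[win])
    idM[, off + 1L] <- ifelse(!is.na(exb), exb, vrb)
    exM[, off + 1L] <- !is.na(exb)
  }

  # exact hits outrank variant hits: when a read has any exact hit, only
  # exact hits form the candidate pool
  anyEx <- rowSums(exM & !is.na(idM)) > 0L
  pool <- idM
  pool[matrix(anyEx, n, K) & !exM] <- NA_character_

  hasHit <- rowSums(!is.na(pool)) > 0L
  firstCol <- max.col(!is.na(pool), ties.method = "first")
  first <- pool[cbind(seq_len(n), firstCol)]
  conflict <- !is.na(pool) & pool != first
  multiple <- rowSums(conflict) > 0L
  ids <- ifelse(hasHit & !multiple, first, NA_character_)

  offM <- matrix(rep(0:maxOffset, each = n), n, K)
  offCols <- lapply(seq_len(K), function(k)
    ifelse(is.na(pool[, k]), NA_integer_, offM[, k]))
  offsetUsed <- do.call(pmin, c(offCols, list(na.rm = TRUE)))
  offsetUsed[is.na(ids)] <- NA_integer_

  data.frame(
    barcode_id = ids,
    no_barcode = is.na(ids) & !multiple,
    multiple_barcodes = multiple,
    barcode_mismatch = !is.na(ids) & !anyEx,
    bases_before_protection = !is.na(offsetUsed) & offsetUsed > 0L,
    offset = offsetUsed,
    stringsAsFactors = FALSE)
}

#' Brute-force Hamming barcode matcher
#'
#' Reference implementation used to validate \code{\link{matchBarcode}}:
#' for every read, offset and barcode, computes the Hamming distance of the
#' candidate window to the barcode and applies the same rules (exact beats
#' one mismatch; a distance-1 window whose sequence is reachable from two
#' barcodes is ambiguous; two distinct hits at equal rank leave the read
#' unassigned).
#'
#' @inheritParams matchBarcode
#' @param barcodes named character vector of barcodes.
#' @return same shape as \code{\link{matchBarcode}}.
#' @export
matchBarcodeBrute <- function(reads, barcodes, protection = "CCA",
                              maxOffset = 3L) {
  w <- unique(nchar(barcodes))
  pgLen <- nchar(protection)
  n <- length(reads)
  ids <- rep(NA_character_, n)
  multiple <- rep(FALSE, n); mismatch <- rep(FALSE, n)
  offUsed <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hits <- data.frame(id = character(), exact = logical(), off = integer(),
                       stringsAsFactors = FALSE)
    for (off in 0:maxOffset) {
      win <- substr(reads[i], off + pgLen + 1L, off + pgLen + w)
      if (nchar(win) < w) next
      d <- vapply(barcodes, function(b) .hammingToPattern(win, b), integer(1))
      for (j in which(d <= 1L)) {
        if (d[j] == 1L && sum(d <= 1L) > 1L) next # window reachable from >= 2
        hits <- rbind(hits, data.frame(id = names(barcodes)[j],
                                       exact = d[j] == 0L, off = off,
                                       stringsAsFactors = FALSE))
      }
    }
    if (!nrow(hits)) next
    pool <- if (any(hits$exact)) hits[hits$exact, , drop = FALSE] else hits
    if (length(unique(pool$id)) > 1L) { multiple[i] <- TRUE; next }
    ids[i] <- pool$id[1L]
    mismatch[i] <- !any(pool$exact)
    offUsed[i] <- min(pool$off)
  }
  data.frame(barcode_id = ids,
             no_barcode = is.na(ids) & !multiple,
             multiple_barcodes = multiple,
             barcode_mismatch = mismatch,
             bases_before_protection = !is.na(offUsed) & offUsed > 0L,
             offset = offUsed, stringsAsFactors = FALSE)
}

.hammingWindows <- function(reads, start, pattern) {
  win <- substr(reads, start, start + nchar(pattern) - 1L)
  .hammingToPattern(win, pattern)
}

#' Assign read pairs to amplicons
#'
#' Matches each amplicon's gene-specific primers against the post-adapter
#' region of both mates with a bounded mismatch count, and checks a k-mer
#' seed of the amplicon insert immediately after the primer. The amplicon
#' with the unique smallest total primer mismatch count (within the bound)
#' wins; ties leave the pair unassigned. A pair whose primers match but
#' whose insert seed matches on neither mate is flagged \code{primer_only}
#' (it is still assigned when the primer hit is unambiguous).
#'
#' @param r1,r2 character vectors of mate sequences.
#' @param amplicons amplicon table (see \code{\link{plateDesign}}).
#' @param panel a \code{\link{BarcodePanel}} (defines the structural prefix
#'   length of each mate).
#' @param maxMismatch maximum mismatches tolerated per primer.
#' @param seedK insert seed length in nt.
#' @param offset1,offset2 optional per-read extra offsets from barcode
#'   matching (e.g. bases before the protection group); default 0.
#' @return data.frame with \code{amplicon_id} (NA if unassigned) and
#'   \code{primer_only} flag.
#' @export
assignAmplicon <- function(r1, r2, amplicons, panel, maxMismatch = 2L,
                           seedK = 12L, offset1 = 0L, offset2 = 0L) {
  n <- length(r1)
  pgLen <- nchar(protectionGroup(panel))
  wF <- unique(Biostrings::width(barcodesFwd(panel)))
  wR <- unique(Biostrings::width(barcodesRev(panel)))
  adF <- nchar(as.character(adapterFwd(panel)))
  adR <- nchar(as.character(adapterRev(panel)))
  start1 <- pgLen + wF + adF + 1L + offset1
  start2 <- pgLen + wR + adR + 1L + offset2

  nA <- nrow(amplicons)
  mmTot <- matrix(NA_integer_, n, nA)
  seedOk <- matrix(FALSE, n, nA)
  for (a in seq_len(nA)) {
    fp <- amplicons$fwd_primer[a]
    rp <- amplicons$rev_primer[a]
    m1 <- .hammingToPattern(substr(r1, start1, start1 + nchar(fp) - 1L), fp)
    m2 <- .hammingToPattern(substr(r2, start2, start2 + nchar(rp) - 1L), rp)
    ok <- !is.na(m1) & !is.na(m2) & m1 <= maxMismatch & m2 <= maxMismatch
    mmTot[, a] <- ifelse(ok, m1 + m2, NA_integer_)
    ins <- amplicons$insert[a]
    mutIns <- if (is.null(amplicons$mut_insert)) NA_character_
              else amplicons$mut_insert[a]
    k1 <- substr(r1, start1 + nchar(fp), start1 + nchar(fp) + seedK - 1L)
    k2 <- substr(r2, start2 + nchar(rp), start2 + nchar(rp) + seedK - 1L)
    seeds1 <- substr(ins, 1L, seedK)
    seeds2 <- substr(revComp(ins), 1L, seedK)
    sOk <- (k1 == seeds1) | (k2 == seeds2)
    if (!is.na(mutIns)) {
      sOk <- sOk | (k1 == substr(mutIns, 1L, seedK)) |
        (k2 == substr(revComp(mutIns), 1L, seedK))
    }
    seedOk[, a] <- sOk
  }

  best <- rep(NA_integer_, n)
  primerOnly <- rep(FALSE, n)
  anyHit <- rowSums(!is.na(mmTot)) > 0L
  for (i in which(anyHit)) {
    mm <- mmTot[i, ]
    # prefer seed-confirmed hits; fall back to primer-only hits
    cand <- which(!is.na(mm) & seedOk[i, ])
    po <- FALSE
    if (!length(cand)) { cand <- which(!is.na(mm)); po <- TRUE }
    mn <- min(mm[cand])
    winners <- cand[mm[cand] == mn]
    if (length(winners) == 1L) {
      best[i] <- winners
      primerOnly[i] <- po
    }
  }
  data.frame(amplicon_id = amplicons$amplicon_id[best],
             primer_only = primerOnly, stringsAsFactors = FALSE)
}

#' Demultiplex read pairs
#'
#' Full per-read pipeline: optional quality trimming, forward-barcode
#' matching on mate 1, reverse-barcode matching on mate 2 (each with at
#' most one unambiguous mismatch), and amplicon assignment. Every read pair
#' ends up either fully assigned or in exactly one failure category.
#'
#' @param r1,r2 character vectors of mate sequences (or a \code{"BartSim"}
#'   object passed as \code{r1}).
#' @param panel a \code{\link{BarcodePanel}}.
#' @param amplicons amplicon reference table.
#' @param maxOffset,maxMismatch,seedK see \code{\link{matchBarcode}} and
#'   \code{\link{assignAmplicon}}.
#' @param quals1,quals2 optional quality strings enabling quality trimming.
#' @param trimWindow,trimThreshold trimming parameters.
#' @return data.frame of per-pair annotations: barcode ids, flags, amplicon
#'   id and a \code{category} column (\code{assigned},
#'   \code{barcode_unassigned}, \code{amplicon_unassigned}).
#' @export
demuxReads <- function(r1, r2, panel, amplicons, maxOffset = 3L,
                       maxMismatch = 2L, seedK = 12L,
                       quals1 = NULL, quals2 = NULL,
                       trimWindow = 5L, trimThreshold = 20) {
  if (inherits(r1, "BartSim")) {
    sim <- r1
    r2 <- sim$r2
    r1 <- sim$r1
  }
  pg <- protectionGroup(panel)
  structLen1 <- nchar(pg) + unique(Biostrings::width(barcodesFwd(panel))) +
    nchar(as.character(adapterFwd(panel)))
  if (!is.null(quals1)) {
    t1 <- trimQuality(r1, quals1, trimWindow, trimThreshold,
                      protectLen = structLen1)
    r1 <- t1$seqs
  }
  if (!is.null(quals2)) {
    structLen2 <- nchar(pg) + unique(Biostrings::width(barcodesRev(panel))) +
      nchar(as.character(adapterRev(panel)))
    t2 <- trimQuality(r2, quals2, trimWindow, trimThreshold,
                      protectLen = structLen2)
    r2 <- t2$seqs
  }

  idxF <- buildVariantIndex(setNames(as.character(barcodesFwd(panel)),
                                     names(barcodesFwd(panel))))
  idxR <- buildVariantIndex(setNames(as.character(barcodesRev(panel)),
                                     names(barcodesRev(panel))))
  mF <- matchBarcode(r1, idxF, protection = pg, maxOffset = maxOffset)
  mR <- matchBarcode(r2, idxR, protection = pg, maxOffset = maxOffset)

  off1 <- ifelse(is.na(mF$offset), 0L, mF$offset)
  off2 <- ifelse(is.na(mR$offset), 0L, mR$offset)
  amp <- assignAmplicon(r1, r2, amplicons, panel, maxMismatch = maxMismatch,
                        seedK = seedK, offset1 = off1, offset2 = off2)

  bcOk <- !is.na(mF$barcode_id) & !is.na(mR$barcode_id)
  category <- ifelse(!bcOk, "barcode_unassigned",
                     ifelse(is.na(amp$amplicon_id), "amplicon_unassigned",
                            "assigned"))
  data.frame(
    fwd_id = mF$barcode_id, rev_id = mR$barcode_id,
    fwd_mismatch = mF$barcode_mismatch, rev_mismatch = mR$barcode_mismatch,
    no_barcode = mF$no_barcode | mR$no_barcode,
    multiple_barcodes = mF$multiple_barcodes | mR$multiple_barcodes,
    bases_before_protection = mF$bases_before_protection |
      mR$bases_before_protection,
    amplicon_id = amp$amplicon_id,
    primer_only = amp$primer_only,
    category = category,
    stringsAsFactors = FALSE)
}

#' Per-amplicon count matrices from demultiplexed annotations
#'
#' Builds one forward x reverse barcode count grid per amplicon over the
#' full panel grid -- including panel barcodes never used on the plate
#' ("dummy" barcodes, whose near-zero counts validate demultiplexing
#' specificity -- and a read-statistics table.
#'
#' @param annotations data.frame from \code{\link{demuxReads}}.
#' @param panel a \code{\link{BarcodePanel}}; its barcode ids define the
#'   grid.
#' @param ampliconIds amplicon ids to tabulate (default: those observed).
#' @return a \code{SummarizedExperiment}: rows = amplicons, columns = all
#'   forward x reverse barcode combinations (colData \code{fwd_id},
#'   \code{rev_id}), assay \code{"counts"}; read statistics in
#'   \code{metadata()$stats}. See \code{\link{countGrid}} and
#'   \code{\link{longCounts}}.
#' @export
countMatrices <- function(annotations, panel, ampliconIds = NULL) {
  fids <- names(barcodesFwd(panel))
  rids <- names(barcodesRev(panel))
  if (is.null(ampliconIds))
    ampliconIds <- sort(unique(stats::na.omit(annotations$amplicon_id)))
  combos <- expand.grid(rev_id = rids, fwd_id = fids,
                        stringsAsFactors = FALSE)[, c("fwd_id", "rev_id")]
  comboKey <- paste(combos$fwd_id, combos$rev_id, sep = "x")
  counts <- matrix(0L, length(ampliconIds), nrow(combos),
                   dimnames = list(ampliconIds, comboKey))
  ok <- annotations$category == "assigned"
  if (any(ok)) {
    key <- paste(annotations$fwd_id[ok], annotations$rev_id[ok], sep = "x")
    tab <- table(amplicon = annotations$amplicon_id[ok], combo = key)
    counts[rownames(tab), colnames(tab)] <-
      counts[rownames(tab), colnames(tab)] + as.matrix(tab)
  }
  stats <- data.frame(
    n_total = nrow(annotations),
    n_assigned = sum(ok),
    n_barcode_unassigned = sum(annotations$category == "barcode_unassigned"),
    n_amplicon_unassigned = sum(annotations$category ==
                                  "amplicon_unassigned"),
    n_no_barcode = sum(annotations$no_barcode),
    n_multiple_barcodes = sum(annotations$multiple_barcodes),
    n_barcode_mismatch = sum(annotations$fwd_mismatch |
                               annotations$rev_mismatch),
    n_bases_before_protection = sum(annotations$bases_before_protection),
    n_primer_only = sum(annotations$primer_only, na.rm = TRUE))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(combos, row.names = comboKey),
    metadata = list(stats = stats))
  se
}

#' Extract one amplicon's forward x reverse count grid
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countMatrices}}.
#' @param ampliconId amplicon row to extract.
#' @return integer matrix, rows = forward barcode ids, columns = reverse
#'   barcode ids.
#' @export
countGrid <- function(se, ampliconId) {
  cd <- SummarizedExperiment::colData(se)
  v <- SummarizedExperiment::assay(se, "counts")[ampliconId, ]
  fids <- unique(cd$fwd_id); rids <- unique(cd$rev_id)
  m <- matrix(v, nrow = length(fids), ncol = length(rids), byrow = TRUE,
              dimnames = list(fids, rids))
  m
}

#' Long-format counts from a count container
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countMatrices}}.
#' @return data.frame \code{amplicon}, \code{fwd_id}, \code{rev_id},
#'   \code{count}.
#' @export
longCounts <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  m <- SummarizedExperiment::assay(se, "counts")
  out <- expand.grid(amplicon = rownames(m), combo = colnames(m),
                     stringsAsFactors = FALSE)
  out$fwd_id <- cd[out$combo, "fwd_id"]
  out$rev_id <- cd[out$combo, "rev_id"]
  out$count <- as.vector(m)
  out[, c("amplicon", "fwd_id", "rev_id", "count")]
}
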