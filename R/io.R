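#' Write a panel definition to TSV
#'
#' One row per barcode with its role, id, sequence, adapter, in-silico
#' ligation and protection group.
#'
#' @param panel a \code{\link{BarcodePanel}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePanel <- function(panel, path) {
  rows <- lapply(c("fwd", "rev"), function(role) {
    bc <- if (role == "fwd") barcodesFwd(panel) else barcodesRev(panel)
    ad <- as.character(if (role == "fwd") adapterFwd(panel)
                       else adapterRev(panel))
    data.frame(role = role, id = names(bc), barcode = as.character(bc),
               adapter = ad,
               ligation = paste0(as.character(bc), ad),
               protection_group = protectionGroup(panel),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel definition from TSV
#'
#' @param path file written by \code{\link{writePanel}}.
#' @return a \code{\link{BarcodePanel}}.
#' @export
readPanel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  f <- df[df$role == "fwd", ]
  r <- df[df$role == "rev", ]
  pg <- unique(df$protection_group)
  if (is.na(pg[1]) || !length(pg)) pg <- ""
  BarcodePanel(setNames(f$barcode, f$id), setNames(r$barcode, r$id),
               f$adapter[1], r$adapter[1], protectionGroup = pg[1])
}

#' Read paired FASTQ files into plain character vectors
#'
#' @param r1Path,r2Path FASTQ(.gz) paths.
#' @return list with \code{r1}, \code{r2} (character sequences) and
#'   \code{q1}, \code{q2} (Phred+33 quality strings).
#' @export
readPairedFastq <- function(r1Path, r2Path) {
  rd <- function(p) {
    # names-only metadata is dropped on re-wrapping; silence that notice
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
  }
  a <- rd(r1Path); b <- rd(r2Path)
  list(r1 = unname(a$seq), r2 = unname(b$seq),
       q1 = unname(a$qual), q2 = unname(b$qual))
}

#' Write per-amplicon count matrices and statistics as TSV files
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countMatrices}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeCountMatrices <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (a in rownames(se)) {
    p <- file.path(dir, paste0("counts_", a, ".tsv"))
    utils::write.table(countGrid(se, a), p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "counts_long.tsv")
  utils::write.table(longCounts(se), lp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- file.path(dir, "read_stats.tsv")
  utils::write.table(S4Vectors::metadata(se)$stats, sp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, lp, sp))
}
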