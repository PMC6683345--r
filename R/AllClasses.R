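#' BarcodePanel: a dual-index barcode/adapter panel
#'
#' Container for a combinatorial dual-indexing panel: a set of forward and a
#' set of reverse sample barcodes (default 8-mers), one adapter per role
#' (default 10-mers) shared by all barcodes of that role, and an optional
#' 5' protection-group trinucleotide prepended to every barcode during
#' oligo assembly. The full 5' structure of a read is
#' \code{protection + barcode + adapter + gene-specific primer}.
#'
#' @slot barcodesFwd named \code{DNAStringSet} of forward barcodes.
#' @slot barcodesRev named \code{DNAStringSet} of reverse barcodes.
#' @slot adapterFwd \code{DNAString}, adapter shared by forward barcodes.
#' @slot adapterRev \code{DNAString}, adapter shared by reverse barcodes.
#' @slot protectionGroup single character string (possibly \code{""}),
#'   e.g. \code{"CCA"}; shields barcode 5' ends from exonuclease trimming.
#' @slot objectiveScore numeric(1); mean pairwise alignment score of the
#'   barcode set at selection time (NA if not produced by the optimizer).
#'
#' @aliases BarcodePanel-class
#' @importClassesFrom Biostrings DNAStringSet DNAString
#' @export
setClass("BarcodePanel",
  slots = c(
    barcodesFwd = "DNAStringSet",
    barcodesRev = "DNAStringSet",
    adapterFwd = "DNAString",
    adapterRev = "DNAString",
    protectionGroup = "character",
    objectiveScore = "numeric"
  )
)

setValidity("BarcodePanel", function(object) {
  msg <- character()
  bf <- as.character(object@barcodesFwd)
  br <- as.character(object@barcodesRev)
  all4 <- c(bf, br,
            as.character(object@adapterFwd), as.character(object@adapterRev))
  if (any(grepl("[^ACGT]", all4)))
    msg <- c(msg, "sequences must contain only A/C/G/T")
  if (length(bf) && length(unique(nchar(bf))) > 1L)
    msg <- c(msg, "forward barcodes must have uniform length")
  if (length(br) && length(unique(nchar(br))) > 1L)
    msg <- c(msg, "reverse barcodes must have uniform length")
  if (anyDuplicated(bf)) msg <- c(msg, "duplicated forward barcodes")
  if (anyDuplicated(br)) msg <- c(msg, "duplicated reverse barcodes")
  if (length(intersect(bf, br)))
    msg <- c(msg, "a barcode appears in both roles")
  if (length(object@protectionGroup) != 1L ||
      grepl("[^ACGT]", object@protectionGroup))
    msg <- c(msg, "protectionGroup must be one (possibly empty) A/C/G/T string")
  if (is.null(names(object@barcodesFwd)) && length(bf))
    msg <- c(msg, "forward barcodes must be named")
  if (is.null(names(object@barcodesRev)) && length(br))
    msg <- c(msg, "reverse barcodes must be named")
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodePanel
#'
#' @param barcodesFwd,barcodesRev character vectors (or \code{DNAStringSet})
#'   of barcodes; if unnamed, ids \code{L01, L02, ...} / \code{R01, ...}
#'   are assigned.
#' @param adapterFwd,adapterRev single adapter sequences.
#' @param protectionGroup protection-group prefix, default \code{"CCA"};
#'   use \code{""} for unprotected panels.
#' @param objectiveScore optional optimizer score annotation.
#' @return a \code{BarcodePanel}.
#' @examples
#' p <- BarcodePanel(c("ACGTTGCA", "TTGACGCA"), c("CATGGTAC", "GATCCATG"),
#'                   "ATCGATCGAT", "CGATTGCAGT")
#' barcodesFwd(p)
#' @export
BarcodePanel <- function(barcodesFwd, barcodesRev, adapterFwd, adapterRev,
                         protectionGroup = "CCA", objectiveScore = NA_real_) {
  bf <- as.character(barcodesFwd)
  br <- as.character(barcodesRev)
  if (is.null(names(bf)) || !any(nzchar(names(bf))))
    names(bf) <- sprintf("L%02d", seq_along(bf))
  if (is.null(names(br)) || !any(nzchar(names(br))))
    names(br) <- sprintf("R%02d", seq_along(br))
  new("BarcodePanel",
      barcodesFwd = Biostrings::DNAStringSet(bf),
      barcodesRev = Biostrings::DNAStringSet(br),
      adapterFwd = Biostrings::DNAString(as.character(adapterFwd)),
      adapterRev = Biostrings::DNAString(as.character(adapterRev)),
      protectionGroup = protectionGroup,
      objectiveScore = objectiveScore)
}

#' @describeIn BarcodePanel forward barcodes as a named \code{DNAStringSet}.
#' @param x,object a \code{BarcodePanel}.
#' @export
setGeneric("barcodesFwd", function(x) standardGeneric("barcodesFwd"))
#' @export
setMethod("barcodesFwd", "BarcodePanel", function(x) x@barcodesFwd)

#' @describeIn BarcodePanel reverse barcodes as a named \code{DNAStringSet}.
#' @export
setGeneric("barcodesRev", function(x) standardGeneric("barcodesRev"))
#' @export
setMethod("barcodesRev", "BarcodePanel", function(x) x@barcodesRev)

#' @describeIn BarcodePanel forward adapter.
#' @export
setGeneric("adapterFwd", function(x) standardGeneric("adapterFwd"))
#' @export
setMethod("adapterFwd", "BarcodePanel", function(x) x@adapterFwd)

#' @describeIn BarcodePanel reverse adapter.
#' @export
setGeneric("adapterRev", function(x) standardGeneric("adapterRev"))
#' @export
setMethod("adapterRev", "BarcodePanel", function(x) x@adapterRev)

#' @describeIn BarcodePanel protection-group prefix.
#' @export
setGeneric("protectionGroup", function(x) standardGeneric("protectionGroup"))
#' @export
setMethod("protectionGroup", "BarcodePanel", function(x) x@protectionGroup)

#' Barcode-adapter ligations of one panel role
#'
#' Returns the in-silico 3' ligation of each barcode to its role's adapter
#' (18 nt at the default 8+10 lengths); these are the sequences screened
#' against a reference and, with the protection group prepended, the barcode
#' oligos ordered for assembly.
#'
#' @param x a \code{BarcodePanel}.
#' @param role \code{"fwd"} or \code{"rev"}.
#' @return named \code{DNAStringSet} of \code{barcode + adapter} sequences.
#' @export
setGeneric("ligations", function(x, role = c("fwd", "rev"))
  standardGeneric("ligations"))
#' @export
setMethod("ligations", "BarcodePanel", function(x, role = c("fwd", "rev")) {
  role <- match.arg(role)
  bc <- if (role == "fwd") x@barcodesFwd else x@barcodesRev
  ad <- if (role == "fwd") x@adapterFwd else x@adapterRev
  out <- Biostrings::DNAStringSet(paste0(as.character(bc), as.character(ad)))
  names(out) <- names(bc)
  out
})

setMethod("show", "BarcodePanel", function(object) {
  cat("BarcodePanel\n")
  cat(sprintf("  %d forward barcodes (%s nt), %d reverse barcodes (%s nt)\n",
              length(object@barcodesFwd),
              paste(unique(Biostrings::width(object@barcodesFwd)),
                    collapse = "/"),
              length(object@barcodesRev),
              paste(unique(Biostrings::width(object@barcodesRev)),
                    collapse = "/")))
  cat(sprintf("  adapters: fwd %s, rev %s\n",
              as.character(object@adapterFwd),
              as.character(object@adapterRev)))
  pg <- object@protectionGroup
  cat(sprintf("  protection group: %s\n", if (nzchar(pg)) pg else "<none>"))
  if (!is.na(object@objectiveScore))
    cat(sprintf("  selection objective: %.4f\n", object@objectiveScore))
  invisible(NULL)
})
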