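#' @importFrom mclust Mclust mclustBIC
NULL

#' Quantification / normalization configuration
#'
#' @param alpha p-value threshold of the per-barcode spike t test.
#' @param trimPercentiles data window used by the t test, as fractions
#'   (default 5th to 95th percentile).
#' @param factorFoldLimit wells whose scaling factor differs from the
#'   median by more than this fold are removed (default 10).
#' @param outlierFoldLimit wells whose total spike signal differs from the
#'   plate mean by more than this fold are removed before testing; this
#'   automates the manual heatmap-inspection step (default 100).
#' @param scalingMode \code{"spikes"} or \code{"spikes_and_genes"}.
#' @param emptyRule reference statistic over negative controls for the
#'   empty-well rule: \code{"min"} (default, strictest reading of "same or
#'   higher than the negative controls") or a quantile in (0,1].
#' @param doubletThreshold \code{"auto"} or a manual numeric threshold on
#'   the log2 gene sum.
#' @return list of class \code{"QuantConfig"}.
#' @export
quantConfig <- function(alpha = 0.05, trimPercentiles = c(0.05, 0.95),
                        factorFoldLimit = 10, outlierFoldLimit = 100,
                        scalingMode = c("spikes", "spikes_and_genes"),
                        emptyRule = "min", doubletThreshold = "auto") {
  stopifnot(alpha > 0, alpha < 1,
            trimPercentiles[1] < trimPercentiles[2])
  structure(list(alpha = alpha, trimPercentiles = trimPercentiles,
                 factorFoldLimit = factorFoldLimit,
                 outlierFoldLimit = outlierFoldLimit,
                 scalingMode = match.arg(scalingMode),
                 emptyRule = emptyRule,
                 doubletThreshold = doubletThreshold),
            class = "QuantConfig")
}

#' Assemble a per-well table from long-format counts and a plate layout
#'
#' @param counts data.frame \code{amplicon}, \code{fwd_id}, \code{rev_id},
#'   \code{count} (e.g. \code{\link{longCounts}} output).
#' @param layout data.frame \code{well_id}, \code{fwd_id}, \code{rev_id},
#'   \code{cell_count}, optional \code{is_negative_control}.
#' @param spikeIds amplicon ids that are spike-ins.
#' @return list of class \code{"WellTable"} with \code{wells} (layout plus
#'   flag columns), \code{genes} and \code{spikes} (wells x amplicon count
#'   matrices), \code{spikeIds}.
#' @export
buildWellTable <- function(counts, layout, spikeIds) {
  if (is.null(layout$is_negative_control))
    layout$is_negative_control <- layout$cell_count == 0L
  key <- paste(layout$fwd_id, layout$rev_id, sep = "x")
  amps <- sort(unique(counts$amplicon))
  m <- matrix(0, nrow(layout), length(amps),
              dimnames = list(layout$well_id, amps))
  ckey <- paste(counts$fwd_id, counts$rev_id, sep = "x")
  sel <- ckey %in% key
  m[cbind(layout$well_id[match(ckey[sel], key)], counts$amplicon[sel])] <-
    counts$count[sel]
  isSpike <- colnames(m) %in% spikeIds
  layout$outlier_removed <- FALSE
  layout$factor_outlier <- FALSE
  layout$empty <- FALSE
  layout$doublet <- FALSE
  layout$scaling_factor <- NA_real_
  structure(list(wells = layout,
                 genes = m[, !isSpike, drop = FALSE],
                 spikes = m[, isSpike, drop = FALSE],
                 normalized = NULL,
                 spikeIds = colnames(m)[isSpike]),
            class = "WellTable")
}

#' @export
print.WellTable <- function(x, ...) {
  cat(sprintf("WellTable: %d wells, %d genes, %d spike-ins\n",
              nrow(x$wells), ncol(x$genes), ncol(x$spikes)))
  flags <- c(outlier = sum(x$wells$outlier_removed),
             factor_outlier = sum(x$wells$factor_outlier),
             empty = sum(x$wells$empty), doublet = sum(x$wells$doublet))
  cat("  flags:", paste(names(flags), flags, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

.trimToPercentiles <- function(x, p) {
  q <- quantile(x, p, names = FALSE, type = 7)
  x[x >= q[1] & x <= q[2]]
}

#' Correct systematic per-barcode spike-in biases
#'
#' For every spike-in and every barcode (forward and reverse axes treated
#' separately), a two-sided Welch t test compares that barcode's wells
#' against all other wells of the same axis, both groups restricted to
#' values between the configured percentiles of the spike's pooled
#' distribution (default 5th-95th). When the
#' test rejects at \code{alpha}, the barcode-spike combination's values are
#' replaced by the median of the remaining barcodes' wells. Wells whose
#' total spike signal deviates from the plate mean by more than
#' \code{outlierFoldLimit} are flagged \code{outlier_removed} first and take
#' no further part in the analysis.
#'
#' @param wt a \code{\link{buildWellTable}}.
#' @param config a \code{\link{quantConfig}}.
#' @return the updated \code{WellTable}; replacement events are recorded in
#'   \code{wt$spikeCorrections}.
#' @export
correctSpikeOutliers <- function(wt, config = quantConfig()) {
  sp0 <- wt$spikes          # all tests run against the original data
  sp <- sp0
  wells <- wt$wells
  tot <- rowSums(sp0)
  ref <- median(tot[tot > 0])
  if (is.finite(ref) && ref > 0) {
    lim <- config$outlierFoldLimit
    out <- tot > 0 & (tot > ref * lim | tot < ref / lim)
    wells$outlier_removed <- wells$outlier_removed | out
  }
  use <- !wells$outlier_removed
  events <- list()
  for (axis in c("fwd_id", "rev_id")) {
    ids <- unique(wells[[axis]][use])
    if (length(ids) < 2L) next
    for (s in colnames(sp0)) {
      # percentile window computed on the pooled per-spike data, applied
      # to both groups; per-group trimming would bias the variance
      # estimates and inflate the rejection rate
      q <- quantile(sp0[use, s], config$trimPercentiles, names = FALSE)
      inWin <- use & sp0[, s] >= q[1] & sp0[, s] <= q[2]
      for (b in ids) {
        inGrp <- inWin & wells[[axis]] == b
        outGrp <- inWin & wells[[axis]] != b
        x <- sp0[inGrp, s]
        y <- sp0[outGrp, s]
        if (length(x) < 2L || length(y) < 2L ||
            (stats::var(x) == 0 && stats::var(y) == 0)) {
          if (length(x) < 2L || length(y) < 2L)
            warning("skipping spike test for ", s, " x ", b,
                    ": degenerate group size", call. = FALSE)
          next
        }
        p <- t.test(x, y)$p.value
        if (!is.na(p) && p < config$alpha) {
          repl <- median(sp0[use & wells[[axis]] != b, s])
          sp[use & wells[[axis]] == b, s] <- repl
          events[[length(events) + 1L]] <- data.frame(
            axis = axis, barcode = b, spike = s, p = p,
            replacement = repl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  wt$spikes <- sp
  wt$wells <- wells
  wt$spikeCorrections <- if (length(events)) do.call(rbind, events)
                         else data.frame(axis = character(),
                                         barcode = character(),
                                         spike = character(), p = numeric(),
                                         replacement = numeric())
  wt
}

#' Spike-in scaling factors and normalized counts
#'
#' Per well, the scaling factor is the geometric mean of the pseudocounted
#' spike reads:
#' \deqn{RNA_x = 2^{\frac{1}{n}\sum_{1}^{n} \log_2(spike_n + 1)}}
#' (in \code{"spikes_and_genes"} mode the mean runs over spikes and genes
#' together). Wells whose factor is more than \code{factorFoldLimit}-fold
#' above or below the median factor are flagged and removed; the remaining
#' factors are median-centered by division (so the median retained factor
#' is exactly 1) and the raw counts divided by them.
#'
#' @param wt a \code{WellTable}.
#' @param config a \code{\link{quantConfig}} (uses \code{scalingMode} and
#'   \code{factorFoldLimit}).
#' @return the \code{WellTable} with \code{wells$scaling_factor} (centered),
#'   \code{wells$factor_outlier} and \code{normalized} (genes and spikes)
#'   filled in.
#' @export
scalingFactors <- function(wt, config = quantConfig()) {
  mat <- if (config$scalingMode == "spikes_and_genes")
    cbind(wt$spikes, wt$genes) else wt$spikes
  raw <- 2^rowMeans(log2(mat + 1))
  use <- !wt$wells$outlier_removed
  med <- median(raw[use])
  lim <- config$factorFoldLimit
  fo <- use & (raw > med * lim | raw < med / lim)
  wt$wells$factor_outlier <- fo
  keep <- use & !fo
  centered <- raw / median(raw[keep])
  wt$wells$scaling_factor <- ifelse(keep, centered, NA_real_)
  wt$wells$raw_factor <- raw
  norm <- cbind(wt$genes, wt$spikes) / centered
  norm[!keep, ] <- NA_real_
  wt$normalized <- list(
    genes = norm[, colnames(wt$genes), drop = FALSE],
    spikes = norm[, colnames(wt$spikes), drop = FALSE])
  wt
}

#' Flag operationally empty wells
#'
#' A well is called empty when its log-transformed spike-to-total read
#' ratio, computed on normalized counts, is the same or higher than the
#' negative-control reference (no cell sorted, spikes only); the reference
#' is the minimum over negative controls by default, or a configurable
#' quantile.
#'
#' @param wt a \code{WellTable} after \code{\link{scalingFactors}}.
#' @param config a \code{\link{quantConfig}} (uses \code{emptyRule}).
#' @return the \code{WellTable} with \code{wells$empty} set.
#' @export
flagEmptyWells <- function(wt, config = quantConfig()) {
  if (is.null(wt$normalized))
    stop("run scalingFactors() first", call. = FALSE)
  neg <- wt$wells$is_negative_control
  if (!any(neg))
    stop("empty-well rule requires at least one negative-control well",
         call. = FALSE)
  spikeSum <- rowSums(wt$normalized$spikes)
  total <- spikeSum + rowSums(wt$normalized$genes)
  stat <- log2((spikeSum + 1) / (total + 1))
  ref <- if (identical(config$emptyRule, "min")) {
    min(stat[neg], na.rm = TRUE)
  } else {
    quantile(stat[neg], as.numeric(config$emptyRule), names = FALSE,
             na.rm = TRUE)
  }
  wt$wells$empty <- !is.na(stat) & stat >= ref
  wt$emptyReference <- ref
  wt
}

#' Flag doublet wells on the bimodal log2 gene-sum distribution
#'
#' Wells sorted as single cells but carrying two (or more) cells show up as
#' a second mode at roughly twice the gene sum. In automatic mode a
#' two-component Gaussian mixture is fitted to the log2-transformed gene
#' sums of single-cell wells and the threshold placed at the density valley
#' between the two component means; a manual threshold can be supplied
#' instead. If the fitted components are not separated (unimodal data) a
#' warning is emitted and nothing is flagged.
#'
#' @param wt a \code{WellTable} after \code{\link{scalingFactors}}.
#' @param config a \code{\link{quantConfig}} (uses \code{doubletThreshold}).
#' @param genes optional subset of gene columns to sum (e.g. housekeeping
#'   genes only).
#' @return the \code{WellTable} with \code{wells$doublet} set and
#'   \code{doubletThreshold} recorded.
#' @export
filterDoublets <- function(wt, config = quantConfig(), genes = NULL) {
  if (is.null(wt$normalized))
    stop("run scalingFactors() first", call. = FALSE)
  gm <- wt$normalized$genes
  if (!is.null(genes)) gm <- gm[, genes, drop = FALSE]
  single <- wt$wells$cell_count == 1L & !wt$wells$empty &
    !wt$wells$outlier_removed & !wt$wells$factor_outlier
  s <- log2(rowSums(gm) + 1)
  thr <- config$doubletThreshold
  if (identical(thr, "auto")) {
    x <- s[single & !is.na(s)]
    if (length(x) < 10L) {
      warning("too few single-cell wells for automatic doublet threshold",
              call. = FALSE)
      return(wt)
    }
    fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    sd_ <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd_) == 1L) sd_ <- rep(sd_, 2L)
    pro <- fit$parameters$pro
    sep <- abs(diff(mu)) / sqrt(mean(sd_^2))
    if (is.na(sep) || sep < 2 || min(pro) < 0.02) {
      warning("log2 gene sums look unimodal; no doublets flagged",
              call. = FALSE)
      return(wt)
    }
    grid <- seq(min(mu), max(mu), length.out = 512L)
    dens <- pro[1] * dnorm(grid, mu[1], sd_[1]) +
      pro[2] * dnorm(grid, mu[2], sd_[2])
    thr <- grid[which.min(dens)]
  }
  wt$wells$doublet <- single & !is.na(s) & s > thr
  wt$doubletThreshold <- thr
  wt
}

#' Per-well one-cell expression estimates
#'
#' Divides normalized counts by the number of sorted cells, yielding
#' comparable one-cell values for multi-cell wells. Filtered wells and
#' wells without cells are excluded.
#'
#' @param wt a \code{WellTable} after \code{\link{scalingFactors}}.
#' @return matrix of one-cell values (rows = retained wells).
#' @export
oneCellValues <- function(wt) {
  if (is.null(wt$normalized))
    stop("run scalingFactors() first", call. = FALSE)
  keep <- wt$wells$cell_count >= 1L & !wt$wells$outlier_removed &
    !wt$wells$factor_outlier & !wt$wells$empty & !wt$wells$doublet
  m <- wt$normalized$genes[keep, , drop = FALSE] /
    wt$wells$cell_count[keep]
  m
}
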