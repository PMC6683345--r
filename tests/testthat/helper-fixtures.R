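# Shared fixture builders. All fixtures are generated in code; seeds are
# set by the calling test.

fixturePanel <- function(nFwd = 3L, nRev = 3L, protection = "CCA",
                         seed = 101L) {
  set.seed(seed)
  cand <- enumerateCandidates(panelDesignConfig(length = 8))
  # draw until pairwise Hamming >= 3 so single-mismatch demux is unambiguous
  repeat {
    bcs <- sample(cand, nFwd + nRev)
    d <- as.matrix(utils::adist(bcs))
    if (min(d[upper.tri(d)]) >= 3) break
  }
  BarcodePanel(bcs[seq_len(nFwd)], bcs[nFwd + seq_len(nRev)],
               "ATCGATCGAT", "CGATTGCAGT", protectionGroup = protection)
}

fixtureAmplicons <- function(n = 2L, insertLen = 80L, withMut = FALSE,
                             seed = 202L) {
  set.seed(seed)
  mkPrimer <- function() paste0(randomDna(1, 18), "T")
  ins <- vapply(seq_len(n), function(i) randomDna(1, insertLen), "")
  mut <- rep(NA_character_, n)
  if (withMut) {
    for (i in seq_len(n)) {
      m <- ins[i]
      p <- insertLen %/% 2
      substr(m, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ins[i], p, p))[1]
      mut[i] <- m
    }
  }
  data.frame(amplicon_id = sprintf("Amp%d", seq_len(n)),
             fwd_primer = vapply(seq_len(n), function(i) mkPrimer(), ""),
             rev_primer = vapply(seq_len(n), function(i) mkPrimer(), ""),
             insert = ins, mut_insert = mut, stringsAsFactors = FALSE)
}

fixturePlate <- function(panel, amplicons, nWells = NULL, abundance = 25,
                         genotype = NULL) {
  fids <- names(barcodesFwd(panel))
  rids <- names(barcodesRev(panel))
  combos <- expand.grid(rev_id = rids, fwd_id = fids,
                        stringsAsFactors = FALSE)[, c("fwd_id", "rev_id")]
  if (is.null(nWells)) nWells <- nrow(combos)
  stopifnot(nWells <= nrow(combos))
  wells <- data.frame(well_id = sprintf("W%03d", seq_len(nWells)),
                      fwd_id = combos$fwd_id[seq_len(nWells)],
                      rev_id = combos$rev_id[seq_len(nWells)],
                      cell_count = 1L, stringsAsFactors = FALSE)
  ab <- matrix(abundance, nWells, nrow(amplicons),
               dimnames = list(wells$well_id, amplicons$amplicon_id))
  gt <- NULL
  if (!is.null(genotype)) {
    gt <- matrix(genotype, nWells, nrow(amplicons),
                 dimnames = dimnames(ab))
  }
  plateDesign(wells, amplicons, ab, gt)
}

# builds a synthetic plate: 8 forward x 12 reverse barcodes = 96 wells,
# lognormal per-well capture factors, Poisson spike counts
quantFixture <- function(nSpikes = 4, spikeMean = 200, sdlog = 0.5,
                         geneMean = 100, nGenes = 3, seed = 1,
                         negControls = 4) {
  set.seed(seed)
  layout <- expand.grid(rev_id = sprintf("R%02d", 1:12),
                        fwd_id = sprintf("L%02d", 1:8),
                        stringsAsFactors = FALSE)[, c("fwd_id", "rev_id")]
  layout$well_id <- sprintf("W%03d", seq_len(nrow(layout)))
  layout$cell_count <- 1L
  layout$cell_count[seq_len(negControls)] <- 0L
  layout$is_negative_control <- layout$cell_count == 0L
  f <- exp(rnorm(nrow(layout), 0, sdlog))
  spikes <- matrix(rpois(nrow(layout) * nSpikes, outer(f, rep(spikeMean,
                                                              nSpikes))),
                   nrow(layout),
                   dimnames = list(layout$well_id,
                                   sprintf("Spike%d", seq_len(nSpikes))))
  genes <- matrix(rpois(nrow(layout) * nGenes, outer(f, rep(geneMean,
                                                            nGenes))),
                  nrow(layout),
                  dimnames = list(layout$well_id,
                                  sprintf("Gene%d", seq_len(nGenes))))
  genes[layout$is_negative_control, ] <- 0L
  long <- rbind(
    data.frame(amplicon = rep(colnames(spikes), each = nrow(layout)),
               fwd_id = layout$fwd_id, rev_id = layout$rev_id,
               count = as.vector(spikes)),
    data.frame(amplicon = rep(colnames(genes), each = nrow(layout)),
               fwd_id = layout$fwd_id, rev_id = layout$rev_id,
               count = as.vector(genes)))
  wt <- buildWellTable(long, layout[, c("well_id", "fwd_id", "rev_id",
                                        "cell_count",
                                        "is_negative_control")],
                       spikeIds = colnames(spikes))
  list(wt = wt, f = f, layout = layout)
}
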