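test_that("quality trimming removes low-quality tails only", {
  q40 <- strrep("I", 60)                       # Q40
  hi <- randomDna(1, 60)
  t1 <- trimQuality(hi, q40)
  expect_identical(t1$seqs, hi)
  # 40 good bases then a Q2 tail of 20
  qmix <- paste0(strrep("I", 40), strrep("#", 20))
  t2 <- trimQuality(hi, qmix, window = 5, qThreshold = 20)
  # the Q2 tail is removed; window averaging may take a few good bases too
  expect_lte(nchar(t2$seqs), 40L)
  expect_gte(nchar(t2$seqs), 36L)
  # protected prefix is never trimmed into
  t3 <- trimQuality(hi, paste0(strrep("#", 60)), protectLen = 21)
  expect_identical(nchar(t3$seqs), 21L)
  # fully bad read with no protection ends empty and is flagged
  t4 <- trimQuality(hi, strrep("#", 60))
  expect_true(t4$empty)
})

test_that("variant index counts and exclusions match enumeration", {
  # one 8-mer: itself plus 8 x 3 substitution variants
  idx <- buildVariantIndex(c(B1 = "ACGTTGCA"))
  expect_identical(length(idx$variants), 25L)
  # two barcodes at Hamming distance 2: midpoint variants are excluded
  b <- c(B1 = "AAAAAAAA", B2 = "AACCAAAA")
  idx2 <- buildVariantIndex(b)
  # enumerate-and-intersect oracle
  vars <- function(bc) {
    out <- character()
    for (p in 1:8) for (x in setdiff(c("A", "C", "G", "T"),
                                     substr(bc, p, p))) {
      v <- bc
      substr(v, p, p) <- x
      out <- c(out, v)
    }
    unique(c(bc, out))
  }
  shared <- intersect(vars(b[1]), vars(b[2]))
  expect_gt(length(shared), 0)
  expect_false(any(shared %in% names(idx2$variants)))
  onlyB1 <- setdiff(vars(b[1]), shared)
  expect_true(all(onlyB1 %in% names(idx2$variants)))
  expect_true(all(idx2$variants[onlyB1] == "B1"))
  expect_error(buildVariantIndex(c(A = "ACGTACGT", B = "ACGTACGT")),
               "duplicate")
})

test_that("indel variants are indexed when enabled", {
  idx <- buildVariantIndex(c(B1 = "ACGTTGCA"), allowIndels = TRUE)
  expect_true("CGTTGCA" %in% names(idx$variants))     # deletion
  expect_true("AACGTTGCA" %in% names(idx$variants))   # insertion
})

test_that("barcode matching applies the unambiguity rules", {
  b <- c(B1 = "ACGTTGCA", B2 = "TTGACGGA")
  idx <- buildVariantIndex(b)
  reads <- c(
    paste0("CCA", "ACGTTGCA", strrep("G", 20)),   # exact
    paste0("CCA", "ACGTTGCC", strrep("G", 20)),   # one substitution
    paste0("T", "CCA", "ACGTTGCA", strrep("G", 20)), # base before protection
    paste0("CCA", "AAAAAAAA", strrep("G", 20)))   # no barcode
  m <- matchBarcode(reads, idx)
  expect_identical(m$barcode_id, c("B1", "B1", "B1", NA))
  expect_identical(m$barcode_mismatch, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(m$bases_before_protection, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(m$no_barcode, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("automaton-style matcher equals the brute-force matcher", {
  set.seed(201)
  panel <- fixturePanel(nFwd = 8, nRev = 8, seed = 300)
  b <- setNames(as.character(barcodesFwd(panel)),
                names(barcodesFwd(panel)))
  idx <- buildVariantIndex(b)
  # adversarial reads: exact prefixes, mutated prefixes, shifted prefixes,
  # random junk
  mkRead <- function() {
    bc <- sample(b, 1)
    type <- sample(4, 1)
    if (type == 1) paste0("CCA", bc, randomDna(1, 30))
    else if (type == 2) {
      p <- sample(8, 1)
      v <- bc
      substr(v, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(bc, p, p)), 1)
      paste0("CCA", v, randomDna(1, 30))
    } else if (type == 3) paste0(randomDna(1, sample(0:3, 1)), "CCA", bc,
                                 randomDna(1, 30))
    else randomDna(1, 41)
  }
  reads <- vapply(seq_len(500), function(i) mkRead(), "")
  a <- matchBarcode(reads, idx)
  o <- matchBarcodeBrute(reads, b)
  expect_identical(a$barcode_id, o$barcode_id)
  expect_identical(a$barcode_mismatch, o$barcode_mismatch)
  expect_identical(a$multiple_barcodes, o$multiple_barcodes)
  expect_identical(a$offset, o$offset)
})

test_that("amplicon assignment resolves mismatches and ambiguity", {
  panel <- fixturePanel(nFwd = 2, nRev = 2)
  amps <- fixtureAmplicons(2)
  pd <- fixturePlate(panel, amps, abundance = 5)
  sim <- simulateReads(pd, panel, errorModel(), seed = 3, fixedCounts = TRUE)
  a <- assignAmplicon(sim$r1, sim$r2, amps, panel)
  expect_identical(a$amplicon_id, sim$truth$amplicon)
  expect_false(any(a$primer_only))

  # two amplicons with identical primers and inserts differing only deep in
  # the read: the primer match is ambiguous, the seed resolves it; making
  # the seeds identical too leaves the pair unassigned
  amb <- amps
  amb$fwd_primer[2] <- amb$fwd_primer[1]
  amb$rev_primer[2] <- amb$rev_primer[1]
  amb$insert[2] <- amb$insert[1]
  a2 <- assignAmplicon(sim$r1[1], sim$r2[1], amb, panel)
  expect_true(is.na(a2$amplicon_id))

  # primer-only read: primer present, insert garbage
  pg <- "CCA"
  r1 <- paste0(pg, as.character(barcodesFwd(panel))[1],
               as.character(adapterFwd(panel)), amps$fwd_primer[1],
               strrep("A", 100))
  r2 <- paste0(pg, as.character(barcodesRev(panel))[1],
               as.character(adapterRev(panel)), amps$rev_primer[1],
               strrep("A", 100))
  a3 <- assignAmplicon(r1, r2, amps, panel)
  expect_identical(a3$amplicon_id, "Amp1")
  expect_true(a3$primer_only)
})

test_that("every read pair lands in exactly one category", {
  panel <- fixturePanel(nFwd = 3, nRev = 3, seed = 301)
  amps <- fixtureAmplicons(2)
  pd <- fixturePlate(panel, amps, abundance = 20)
  sim <- simulateReads(pd, panel,
                       errorModel(substitutionRate = 0.01,
                                  truncationProb = 0.05),
                       seed = 4)
  ann <- demuxReads(sim$r1, sim$r2, panel, amps)
  expect_identical(nrow(ann), length(sim$r1))
  expect_true(all(ann$category %in% c("assigned", "barcode_unassigned",
                                      "amplicon_unassigned")))
  se <- countMatrices(ann, panel, amps$amplicon_id)
  stats <- S4Vectors::metadata(se)$stats
  expect_identical(stats$n_total,
                   stats$n_assigned + stats$n_barcode_unassigned +
                     stats$n_amplicon_unassigned)
  expect_identical(sum(SummarizedExperiment::assay(se)), stats$n_assigned)
})

test_that("error-free demux reproduces the simulation truth exactly", {
  panel <- fixturePanel(nFwd = 4, nRev = 4, seed = 302)
  amps <- fixtureAmplicons(3)
  pd <- fixturePlate(panel, amps, nWells = 12, abundance = 8)
  sim <- simulateReads(pd, panel, errorModel(), seed = 6, fixedCounts = TRUE)
  ann <- demuxReads(sim$r1, sim$r2, panel, amps)
  expect_true(all(ann$category == "assigned"))
  se <- countMatrices(ann, panel, amps$amplicon_id)
  wells <- pd$wells
  for (a in amps$amplicon_id) {
    g <- countGrid(se, a)
    truth <- matrix(0, nrow(g), ncol(g), dimnames = dimnames(g))
    wc <- sim$wellCounts[sim$wellCounts$amplicon == a, ]
    agg <- stats::aggregate(count ~ well, wc, sum)
    truth[cbind(wells$fwd_id[match(agg$well, wells$well_id)],
                wells$rev_id[match(agg$well, wells$well_id)])] <- agg$count
    expect_equal(unclass(g), truth, ignore_attr = TRUE)
  }
})

test_that("substitution recovery matches the variant-index prediction", {
  panel <- fixturePanel(nFwd = 4, nRev = 4, seed = 303)
  b <- setNames(as.character(barcodesFwd(panel)),
                names(barcodesFwd(panel)))
  idx <- buildVariantIndex(b)
  # every single-substitution read, exhaustively
  rows <- list()
  for (id in names(b)) {
    bc <- b[[id]]
    for (p in 1:8) for (x in setdiff(c("A", "C", "G", "T"),
                                     substr(bc, p, p))) {
      v <- bc
      substr(v, p, p) <- x
      rows[[length(rows) + 1L]] <- data.frame(id = id, var = v,
                                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  reads <- paste0("CCA", df$var, strrep("G", 20))
  # offset 0 only: the prediction below reads the index directly
  m <- matchBarcode(reads, idx, maxOffset = 0L)
  predicted <- ifelse(df$var %in% names(idx$exact),
                      unname(idx$exact[df$var]),
                      unname(idx$variants[df$var]))
  expect_identical(m$barcode_id, unname(predicted))
  recovered <- !is.na(predicted) & predicted == df$id
  expect_identical(m$barcode_id == df$id & !is.na(m$barcode_id),
                   unname(recovered))
})

test_that("count matrices include all-zero dummy barcode cells", {
  panel <- fixturePanel(nFwd = 4, nRev = 4, seed = 304)
  amps <- fixtureAmplicons(1)
  # only 2x2 barcodes are active on the plate; the rest are dummies
  pd <- fixturePlate(panel, amps, nWells = 4, abundance = 10)
  activeF <- unique(pd$wells$fwd_id)
  sim <- simulateReads(pd, panel, errorModel(), seed = 9, fixedCounts = TRUE)
  ann <- demuxReads(sim$r1, sim$r2, panel, amps)
  g <- countGrid(countMatrices(ann, panel, amps$amplicon_id), "Amp1")
  dummyF <- setdiff(rownames(g), pd$wells$fwd_id)
  dummyR <- setdiff(colnames(g), pd$wells$rev_id)
  expect_gt(length(dummyF), 0)
  expect_true(all(g[dummyF, ] == 0))
  expect_true(all(g[, dummyR] == 0))
})
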