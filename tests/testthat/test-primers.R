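test_that("primer candidates end in 3'-T and respect the amplicon range", {
  set.seed(50)
  tpl <- randomDna(1, 400)
  target <- ampliconTarget("G1", tpl, c(180, 200))
  pairs <- generatePrimerCandidates(target)
  expect_gt(nrow(pairs), 0)
  expect_lte(nrow(pairs), 5)
  expect_true(all(substr(pairs$fwd_seq, nchar(pairs$fwd_seq),
                         nchar(pairs$fwd_seq)) == "T"))
  expect_true(all(substr(pairs$rev_seq, nchar(pairs$rev_seq),
                         nchar(pairs$rev_seq)) == "T"))
  expect_true(all(pairs$amplicon_length >= 80 &
                    pairs$amplicon_length <= 250))
  # the amplicon spans the target interval
  expect_true(all(pairs$fwd_start <= 180 &
                    pairs$fwd_start + pairs$amplicon_length >= 200))
  # rev primer maps to the reverse strand: its sequence is the revcomp of a
  # template window downstream of the interval
  w <- substring(tpl, pairs$rev_start + 1,
                 pairs$rev_start + nchar(pairs$rev_seq))
  expect_identical(pairs$rev_seq, revComp(w))
  # deterministic
  expect_identical(pairs, generatePrimerCandidates(target))
})

test_that("a template without usable 3'-T windows errors", {
  tpl <- strrep("C", 300)  # no T on plus strand, no A for the minus strand
  expect_error(generatePrimerCandidates(
    ampliconTarget("G1", tpl, c(140, 160))), "no valid primer pair")
})

test_that("a planted ideal primer site is ranked first", {
  set.seed(51)
  # GC-only flanks leave the planted sites as the only balanced windows;
  # both planted primers have matched Tm, so with tmOpt set there they are
  # the unique zero-penalty windows
  flank <- function(n) paste(sample(c("G", "C"), n, TRUE), collapse = "")
  goodF <- "ACGTTGACCATGGATCAGT"   # 19 nt, ends T, balanced GC
  goodRrc <- "GACTTGAACTACAGGCCCT" # Tm-matched to goodF
  goodRtpl <- revComp(goodRrc)     # template window (starts with A)
  insert <- sub("A$", "C", randomDna(1, 80)) # no A adjoining the site
  tpl <- paste0(flank(40), goodF, insert, goodRtpl, flank(40))
  iv <- c(40 + 19 + 10, 40 + 19 + 70)
  cfg <- primerDesignConfig(lengthRange = c(19L, 19L),
                            tmOpt = tmEstimate(goodF))
  pairs <- generatePrimerCandidates(ampliconTarget("G1", tpl, iv), cfg)
  expect_identical(pairs$fwd_seq[1], goodF)
  expect_identical(pairs$rev_seq[1], goodRrc)
})

test_that("in-silico ligation enumerates the full product set", {
  panel <- fixturePanel(nFwd = 2, nRev = 3)
  primers <- c("ACGGATTACCAGGATCAGT", "TGCCATTAGACCAGTAGCT",
               "GGATTACGTTAGGACCAGT")
  lig <- inSilicoLigation(primers, panel, "fwd")
  expect_length(lig, 6L)
  bc <- as.character(barcodesFwd(panel))
  ad <- as.character(adapterFwd(panel))
  # equals brute-force nested-loop concatenation
  brute <- sort(as.vector(outer(paste0("CCA", bc, ad), primers, paste0)))
  expect_identical(sort(unname(lig)), brute)
  expect_true(all(nchar(lig) == 3 + 8 + 10 + nchar(primers[1])))
  expect_error(inSilicoLigation("ACGT", BarcodePanel(character(), "ACGTTGCA",
                                                     "ATCGATCGAT",
                                                     "CGATTGCAGT"), "fwd"))
})

test_that("duplex energy reproduces hand-summed nearest-neighbor stacks", {
  # ACGTACGTAC vs its perfect complement: stacks AC x3, CG x2, GT x2,
  # TA x2 (= -12.70) plus terminal initiations A (+1.03) and C (+0.98)
  expect_equal(duplexEnergy("ACGTACGTAC", revComp("ACGTACGTAC")), -10.69)
  expect_error(duplexEnergy("ACGT", "ACGT", backend = "nope"),
               "unknown duplex-energy backend")
})

test_that("duplex energy is symmetric and minimal for the perfect complement", {
  set.seed(60)
  for (i in 1:10) {
    a <- randomDna(1, sample(8:15, 1))
    b <- randomDna(1, sample(8:15, 1))
    expect_equal(duplexEnergy(a, b), duplexEnergy(b, a))
  }
  for (i in 1:10) {
    a <- randomDna(1, 10)
    ePerfect <- duplexEnergy(a, revComp(a))
    others <- randomDna(15, 10)
    expect_true(all(duplexEnergy(a, others[1]) >= ePerfect))
    for (o in others) expect_gte(duplexEnergy(a, o), ePerfect)
  }
})

test_that("a custom backend can be registered and used", {
  registerDuplexBackend("flat", function(a, b) 0)
  expect_equal(duplexEnergy("ACGT", "ACGT", backend = "flat"), 0)
})

test_that("primer-set annealing matches exhaustive search on small instances", {
  panel <- fixturePanel(nFwd = 2, nRev = 2)
  set.seed(71)
  mkPair <- function(g, r) data.frame(
    gene_id = g, rank = r,
    fwd_seq = paste0(randomDna(1, 17), "T"),
    rev_seq = paste0(randomDna(1, 17), "T"),
    stringsAsFactors = FALSE)
  cands <- list(G1 = rbind(mkPair("G1", 1), mkPair("G1", 2)),
                G2 = rbind(mkPair("G2", 1), mkPair("G2", 2)),
                G3 = rbind(mkPair("G3", 1), mkPair("G3", 2)))

  # independent exhaustive optimum over the 8 selections
  allObj <- sapply(1:8, function(code) {
    sel <- c((code - 1) %/% 4 + 1, ((code - 1) %/% 2) %% 2 + 1,
             (code - 1) %% 2 + 1)
    seqs <- unlist(lapply(1:3, function(l) {
      row <- cands[[l]][sel[l], ]
      c(inSilicoLigation(row$fwd_seq, panel, "fwd"),
        inSilicoLigation(row$rev_seq, panel, "rev"))
    }))
    tot <- 0
    for (i in seq_along(seqs)) for (j in i:length(seqs))
      tot <- tot + duplexEnergy(seqs[i], seqs[j])
    -tot  # default objective minimizes dimer stability
  })

  hits <- 0L
  for (s in 1:10) {
    run <- annealPrimerSets(cands, panel,
                            primerAnnealConfig(nIterations = 100L, seed = s))
    expect_lte(run$objective, run$initialObjective + 1e-9)
    if (abs(run$objective - min(allObj)) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("single-candidate loci are returned trivially and empty loci error", {
  panel <- fixturePanel(nFwd = 2, nRev = 2)
  set.seed(72)
  one <- data.frame(gene_id = "G1", rank = 1,
                    fwd_seq = paste0(randomDna(1, 17), "T"),
                    rev_seq = paste0(randomDna(1, 17), "T"),
                    stringsAsFactors = FALSE)
  run <- annealPrimerSets(list(G1 = one), panel,
                          primerAnnealConfig(nIterations = 10L, seed = 1))
  expect_identical(run$selection$fwd_seq, one$fwd_seq)
  expect_error(annealPrimerSets(list(G1 = one[0, ]), panel),
               "no candidate pairs")
})

test_that("assembly oligos round-trip to the barcoded primer", {
  set.seed(80)
  for (rep in 1:5) {
    panel <- fixturePanel(nFwd = 2, nRev = 2, seed = 100 + rep)
    sel <- data.frame(gene_id = c("G1", "G2"),
                      fwd_seq = paste0(randomDna(2, 19), "T"),
                      rev_seq = paste0(randomDna(2, 19), "T"),
                      stringsAsFactors = FALSE)
    sheet <- emitAssemblyOligos(sel, panel)
    # one row per barcode plus one per primer
    expect_identical(nrow(sheet), 4L + 4L)
    expect_true(all(sheet$has_5prime_phosphate[sheet$kind ==
                                                 "rc_primer_oligo"]))
    expect_false(any(sheet$has_5prime_phosphate[sheet$kind ==
                                                  "barcode_oligo"]))
    for (role in c("fwd", "rev")) {
      bcRows <- sheet[sheet$kind == "barcode_oligo" & sheet$role == role, ]
      pRows <- sheet[sheet$kind == "rc_primer_oligo" & sheet$role == role, ]
      bcs <- if (role == "fwd") barcodesFwd(panel) else barcodesRev(panel)
      ad <- as.character(if (role == "fwd") adapterFwd(panel)
                         else adapterRev(panel))
      prim <- if (role == "fwd") sel$fwd_seq else sel$rev_seq
      for (i in seq_len(nrow(bcRows))) for (j in seq_len(nrow(pRows))) {
        assembled <- simulateAssembly(bcRows$sequence[i], pRows$sequence[j])
        expect_identical(assembled,
                         paste0("CCA", as.character(bcs)[i], ad, prim[j]))
      }
    }
  }
  # non-annealing ends are rejected
  expect_error(simulateAssembly("CCAACGTACGTATCGATCGAT", "ACGTACGTACGT"),
               "do not anneal")
})
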