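test_that("the scaling factor formula matches its printed arithmetic", {
  # spikes (3, 7, 15, 31): RNA_x = 2^((2+3+4+5)/4) = 2^3.5
  layout <- data.frame(well_id = "W1", fwd_id = "L01", rev_id = "R01",
                       cell_count = 1L, is_negative_control = FALSE)
  long <- data.frame(amplicon = sprintf("S%d", 1:4), fwd_id = "L01",
                     rev_id = "R01", count = c(3, 7, 15, 31))
  wt <- buildWellTable(long, layout, spikeIds = sprintf("S%d", 1:4))
  raw <- 2^rowMeans(log2(wt$spikes + 1))
  expect_equal(unname(raw), 2^3.5)
  expect_equal(unname(raw), 11.3137, tolerance = 1e-4)
})

test_that("centered factors have median exactly 1 and preserve zeros", {
  fx <- quantFixture(seed = 2)
  wt <- scalingFactors(fx$wt)
  sf <- wt$wells$scaling_factor
  expect_equal(median(sf, na.rm = TRUE), 1)
  zero <- fx$wt$genes == 0
  expect_true(all(wt$normalized$genes[zero][
    !is.na(wt$normalized$genes[zero])] == 0))
  # normalized = raw / factor wherever a factor exists
  keep <- !is.na(sf)
  expect_equal(wt$normalized$genes[keep, ],
               fx$wt$genes[keep, ] / sf[keep])
})

test_that("scaling a well's spikes by c scales its factor by about c", {
  fx <- quantFixture(seed = 3)
  wt1 <- scalingFactors(fx$wt)
  wt2 <- fx$wt
  wt2$spikes[5, ] <- wt2$spikes[5, ] * 4
  wt2 <- scalingFactors(wt2)
  r <- wt2$wells$raw_factor[5] / wt1$wells$raw_factor[5]
  expect_lt(abs(r - 4) / 4, 0.01)  # counts >= 100, +1 pseudocount
})

test_that("factors far from the median are removed before centering", {
  fx <- quantFixture(seed = 4)
  fx$wt$spikes[7, ] <- fx$wt$spikes[7, ] * 1000
  wt <- scalingFactors(fx$wt)
  expect_true(wt$wells$factor_outlier[7])
  expect_true(is.na(wt$wells$scaling_factor[7]))
  expect_true(all(is.na(wt$normalized$genes[7, ])))
  expect_equal(median(wt$wells$scaling_factor, na.rm = TRUE), 1)
})

test_that("estimated factors recover simulated capture factors (r > 0.99)", {
  fx <- quantFixture(nSpikes = 4, spikeMean = 400, seed = 5)
  wt <- scalingFactors(fx$wt)
  r <- stats::cor(log2(wt$wells$raw_factor), log2(fx$f))
  expect_gt(r, 0.99)
})

test_that("spikes_and_genes mode averages over both matrices", {
  fx <- quantFixture(seed = 6)
  wt <- scalingFactors(fx$wt, quantConfig(scalingMode = "spikes_and_genes"))
  expected <- 2^rowMeans(log2(cbind(fx$wt$spikes, fx$wt$genes) + 1))
  expect_equal(unname(wt$wells$raw_factor), unname(expected))
})

test_that("null spike data is replaced at about the alpha rate", {
  set.seed(7)
  nrep <- 12
  replaced <- 0L; tests <- 0L
  for (rep in seq_len(nrep)) {
    fx <- quantFixture(nSpikes = 5, sdlog = 0, seed = 100 + rep,
                       negControls = 0)
    wt <- correctSpikeOutliers(fx$wt, quantConfig(alpha = 0.05))
    replaced <- replaced + nrow(wt$spikeCorrections)
    tests <- tests + 5 * (8 + 12)
  }
  rate <- replaced / tests
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("a planted barcode shift is detected and replaced by the median", {
  fx <- quantFixture(nSpikes = 3, sdlog = 0, seed = 8, negControls = 0)
  shiftWells <- fx$wt$wells$fwd_id == "L03"
  fx$wt$spikes[shiftWells, "Spike2"] <-
    fx$wt$spikes[shiftWells, "Spike2"] * 2
  wt <- correctSpikeOutliers(fx$wt, quantConfig(alpha = 0.01))
  ev <- wt$spikeCorrections
  hit <- ev$axis == "fwd_id" & ev$barcode == "L03" & ev$spike == "Spike2"
  expect_true(any(hit))
  med <- median(fx$wt$spikes[!shiftWells, "Spike2"])
  expect_equal(ev$replacement[hit], med)
  # no shifted (doubled) value survives; cells may subsequently be touched
  # by collateral rev-axis detections, all close to the plate median
  expect_lt(max(wt$spikes[shiftWells, "Spike2"]), 300)
})

test_that("identical spike values everywhere produce no replacements", {
  fx <- quantFixture(seed = 9, negControls = 0)
  fx$wt$spikes[] <- 100
  wt <- correctSpikeOutliers(fx$wt)
  expect_identical(nrow(wt$spikeCorrections), 0L)
})

test_that("hundredfold outlier wells are flagged before spike testing", {
  fx <- quantFixture(seed = 10, negControls = 0)
  fx$wt$spikes[3, ] <- fx$wt$spikes[3, ] * 500
  wt <- correctSpikeOutliers(fx$wt)
  expect_true(wt$wells$outlier_removed[3])
})

test_that("empty wells are flagged by the negative-control ratio rule", {
  fx <- quantFixture(seed = 11)
  # planted empty wells: spikes only, like the negative controls
  emptyIdx <- c(10, 20)
  fx$wt$genes[emptyIdx, ] <- 0L
  wt <- flagEmptyWells(scalingFactors(fx$wt))
  expect_true(all(wt$wells$empty[emptyIdx]))
  # negative controls flag themselves (ratio "same or higher")
  expect_true(all(wt$wells$empty[fx$wt$wells$is_negative_control]))
  # expressing single-cell wells are retained
  expect_false(any(wt$wells$empty[setdiff(which(fx$layout$cell_count == 1),
                                          emptyIdx)]))
  # the rule requires negative controls
  fx2 <- quantFixture(seed = 12, negControls = 0)
  expect_error(flagEmptyWells(scalingFactors(fx2$wt)), "negative-control")
})

test_that("all wells identical to the controls are all flagged empty", {
  fx <- quantFixture(seed = 13)
  fx$wt$genes[] <- 0L
  fx$wt$spikes[] <- 100L
  wt <- flagEmptyWells(scalingFactors(fx$wt))
  expect_true(all(wt$wells$empty))
})

test_that("doublet detection separates a planted bimodal mixture", {
  fx <- quantFixture(seed = 14, geneMean = 60, negControls = 4)
  single <- fx$layout$cell_count == 1
  # plant doublets: double the gene content in 15 wells
  doubletIdx <- sample(which(single), 15)
  fx$wt$genes[doubletIdx, ] <- fx$wt$genes[doubletIdx, ] * 2L
  wt <- filterDoublets(flagEmptyWells(scalingFactors(fx$wt)))
  flagged <- which(wt$wells$doublet)
  planted <- doubletIdx
  sens <- mean(planted %in% flagged)
  fdrish <- length(setdiff(flagged, planted)) /
    max(1, sum(single) - length(planted))
  expect_gte(sens, 0.95)
  expect_lte(fdrish, 0.05)
})

test_that("manual doublet thresholds behave at the extremes", {
  fx <- quantFixture(seed = 15)
  wt <- scalingFactors(fx$wt)
  none <- filterDoublets(wt, quantConfig(doubletThreshold = Inf))
  expect_false(any(none$wells$doublet))
  all_ <- filterDoublets(wt, quantConfig(doubletThreshold = -Inf))
  single <- fx$layout$cell_count == 1
  expect_true(all(all_$wells$doublet[single & !all_$wells$empty]))
})

test_that("unimodal gene sums produce a warning and no doublet flags", {
  fx <- quantFixture(seed = 16, geneMean = 100)
  wt <- scalingFactors(fx$wt)
  expect_warning(res <- filterDoublets(wt), "unimodal")
  expect_false(any(res$wells$doublet))
})

test_that("one-cell values divide by the sorted cell count", {
  fx <- quantFixture(seed = 17)
  wt <- scalingFactors(fx$wt)
  wt$wells$cell_count[10] <- 4L
  ocv <- oneCellValues(wt)
  w10 <- fx$layout$well_id[10]
  expect_equal(ocv[w10, ], wt$normalized$genes[w10, ] / 4)
  w11 <- fx$layout$well_id[11]
  expect_equal(ocv[w11, ], wt$normalized$genes[w11, ])
  # dividing by 4 equals halving twice
  expect_equal(ocv[w10, ], wt$normalized$genes[w10, ] / 2 / 2)
  # cell_count 0 wells are excluded
  expect_false(any(fx$layout$well_id[fx$layout$cell_count == 0] %in%
                     rownames(ocv)))
})
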