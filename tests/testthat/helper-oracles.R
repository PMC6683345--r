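# Independent reference implementations used as oracles; deliberately
# naive and separate from the package code paths.

# Needleman-Wunsch global alignment score, linear gap penalty.
nwScore <- function(a, b, match = 1, mismatch = 0, gap = 0) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * gap
  D[1, ] <- (0:m) * gap
  for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- max(
      D[i, j] + if (av[i] == bv[j]) match else mismatch,
      D[i, j + 1] + gap,
      D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# orientation-maximal version mirroring the contract, via the naive DP
nwScoreAllOrients <- function(a, b, match = 1, mismatch = 0, gap = 0) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  max(nwScore(a, b, match, mismatch, gap),
      nwScore(a, rc(b), match, mismatch, gap),
      nwScore(rc(a), b, match, mismatch, gap),
      nwScore(rc(a), rc(b), match, mismatch, gap))
}

# brute-force candidate enumeration by filtering all 4^L sequences with
# independently written predicates
bruteEnumerate <- function(L, gcMin, gcMax, filterRepeats = TRUE) {
  seqs <- do.call(paste0,
                  rev(do.call(expand.grid,
                              c(rep(list(c("A", "C", "G", "T")), L),
                                list(stringsAsFactors = FALSE)))))
  gc <- vapply(strsplit(seqs, ""), function(s) sum(s %in% c("G", "C")),
               numeric(1))
  keep <- gc >= ceiling(gcMin * L) & gc <= floor(gcMax * L)
  if (filterRepeats) {
    noRep <- vapply(strsplit(seqs, ""), function(s) {
      n <- length(s)
      for (i in seq_len(n - 2))          # homopolymer run of 3
        if (s[i] == s[i + 1] && s[i + 1] == s[i + 2]) return(FALSE)
      for (i in seq_len(max(0, n - 3)))  # immediate 2-mer duplication
        if (s[i] == s[i + 2] && s[i + 1] == s[i + 3]) return(FALSE)
      for (i in seq_len(max(0, n - 5)))  # immediate 3-mer duplication
        if (s[i] == s[i + 3] && s[i + 1] == s[i + 4] &&
            s[i + 2] == s[i + 5]) return(FALSE)
      TRUE
    }, logical(1))
    keep <- keep & noRep
  }
  sort(seqs[keep])
}

# exhaustive best subset of size k under the mean-pairwise-score objective
exhaustiveBestSubset <- function(scoreMat, k) {
  n <- nrow(scoreMat)
  combs <- utils::combn(n, k)
  npairs <- k * (k - 1) / 2
  objs <- apply(combs, 2, function(idx)
    (sum(scoreMat[idx, idx]) - sum(diag(scoreMat)[idx])) / 2 / npairs)
  list(objective = min(objs), idx = combs[, which.min(objs)], all = objs)
}
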