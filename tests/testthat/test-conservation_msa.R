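# regex oracle for the heme-binding motif, independent of the scanner
regexMotifHits <- function(seq, plusTwo = "G") {
  pat <- sprintf("(?=(G.[HR].C[PLAV][%s]))", plusTwo)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

writeAlignedFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

writeClustal <- function(seqs, path = tempfile(fileext = ".aln")) {
  lines <- c("CLUSTAL O(1.2.4) multiple sequence alignment", "", "")
  width <- 60
  len <- nchar(seqs[[1]])
  for (start in seq(1, len, by = width)) {
    chunk <- vapply(names(seqs), function(n)
      sprintf("%-15s %s", n, substr(seqs[[n]], start,
                                    min(start + width - 1, len))), "")
    lines <- c(lines, chunk, "")
  }
  writeLines(lines, path)
  path
}

test_that("aligned FASTA and Clustal readers return identical content", {
  seqs <- list(ref = "GRHPCLG-AC", homo1 = "GRHPCLGWAC",
               homo2 = "GRHACVGWAC")
  fa <- readMSA(writeAlignedFasta(seqs), "fasta")
  cl <- readMSA(writeClustal(seqs), "clustal")
  expect_equal(length(fa@aln), 3L)
  expect_equal(as.character(fa@aln), as.character(cl@aln))
  expect_equal(refId(fa), "ref")

  ragged <- writeAlignedFasta(list(a = "ACDE", b = "ACD"))
  expect_error(readMSA(ragged, "fasta"), "ragged.*'b'")
})

test_that("mapPosition returns the column of the n-th non-gap residue", {
  m <- referenceMSA(c(ref = "A-CD", other = "AACD"))
  expect_equal(mapPosition(m, 2), 3L)
  expect_error(mapPosition(m, 9), "out of range")

  gapless <- referenceMSA(c(ref = "ACDEF", o = "ACDEF"))
  for (p in 1:5) expect_equal(mapPosition(gapless, p), p)

  # scan-count oracle on a random gapped reference
  set.seed(13)
  chars <- sample(c("A", "C", "G", "-"), 60, replace = TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.2))
  refRow <- paste(chars, collapse = "")
  msa <- referenceMSA(c(ref = refRow,
                        o = paste(rep("A", 60), collapse = "")))
  nRes <- sum(chars != "-")
  for (p in seq_len(nRes)) {
    col <- mapPosition(msa, p)
    # oracle: linear scan counting non-gaps up to the column
    expect_equal(sum(chars[seq_len(col)] != "-"), p)
    expect_true(chars[col] != "-")
  }
})

test_that("column conservation counts match and handle gaps per flag", {
  rows <- c(ref = "G", stats::setNames(rep("G", 18), paste0("s", 1:18)),
            sub = "A")
  msa <- referenceMSA(vapply(rows, function(ch) paste0(ch, "CC"), ""))
  rep1 <- columnConservation(msa, column = 1)
  expect_equal(conservedFraction(rep1), 0.95)
  expect_equal(conservationPercent(rep1), 95L)
  expect_equal(rep1@substitutionCounts, c(A = 1L))

  gapped <- referenceMSA(c(ref = "GCC", a = "GCC", b = "-CC", c = "ACC"))
  noGaps <- columnConservation(gapped, column = 1)
  expect_equal(noGaps@nSequences, 3L)
  expect_equal(conservedFraction(noGaps), 2 / 3)
  withGaps <- columnConservation(gapped, column = 1, countGaps = TRUE)
  expect_equal(withGaps@nSequences, 4L)
  expect_equal(conservedFraction(withGaps), 0.5)
  expect_equal(withGaps@substitutionCounts[["-"]], 1L)

  # a fully gapped column necessarily gaps the reference too
  allGap <- referenceMSA(c(ref = "G-", a = "G-", b = "G-"))
  expect_error(columnConservation(allGap, column = 2), "gap")
  expect_error(columnConservation(gapped, column = 99), "outside")
})

test_that("conservation is invariant under record reordering", {
  msa <- simulateMSA(40, 6, randomSeq(30, 2), 11, seed = 8)
  base <- conservedFraction(columnConservation(msa, refPosition = 11))
  set.seed(3)
  perm <- c(1L, 1L + sample(39L))  # keep the reference first
  shuffled <- referenceMSA(
    stats::setNames(as.character(msa@aln)[perm], names(msa@aln)[perm]),
    refId = "REF")
  expect_equal(
    conservedFraction(columnConservation(shuffled, refPosition = 11)),
    base)
})

test_that("the reference residue sits at every mapped column", {
  msa <- simulateMSA(10, 2, randomSeq(25, 5), 7, seed = 9)
  refRow <- as.character(msa@aln[["REF"]])
  for (p in c(1, 7, 13, 25)) {
    col <- mapPosition(msa, p)
    expect_equal(substr(refRow, col, col),
                 substr(gsub("-", "", refRow), p, p))
  }
})

test_that("motif scanning agrees with the regex oracle", {
  hits <- scanHemeMotif("GRHPCLG")
  expect_equal(hits$start, 1L)
  expect_equal(hits$cysPos, 5L)
  expect_equal(hits$plusTwoPos, 7L)
  expect_equal(hits$span, "GRHPCLG")

  expect_equal(nrow(scanHemeMotif("GRHPALGAAA")), 0L)  # no Cys

  tandem <- scanHemeMotif("GRHPCLGRHPCLG")
  expect_equal(tandem$start, c(1L, 7L))

  for (seed in 1:200) {
    seq <- randomSeq(80, seed)
    expect_equal(scanHemeMotif(seq)$start, regexMotifHits(seq),
                 info = paste("seed", seed))
  }
  expect_error(scanHemeMotif("GR-PCLG"), "ungapped")
})

test_that("the relaxed scan admits +2 variants and contains the strict scan", {
  expect_equal(nrow(scanHemeMotif("GRHPCLA")), 0L)
  relaxed <- relaxedMotifScan("GRHPCLA", c("A", "S", "K"))
  expect_equal(relaxed$start, 1L)

  # empty allowed set falls back to the strict pattern
  expect_equal(relaxedMotifScan("GRHPCLA", character(0))$start,
               scanHemeMotif("GRHPCLA")$start)

  # planted +2 variants are all recovered
  planted <- paste0(randomSeq(20, 3), "GRHPCLS", randomSeq(20, 4),
                    "GRHPCLK", randomSeq(10, 5))
  rel <- relaxedMotifScan(planted, c("A", "S", "K"))
  oracle <- regexMotifHits(planted, "GASK")
  expect_equal(rel$start, oracle)

  for (seed in 1:50) {
    seq <- randomSeq(80, seed + 500)
    strict <- scanHemeMotif(seq)$start
    expect_true(all(strict %in% relaxedMotifScan(seq)$start))
  }
})
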