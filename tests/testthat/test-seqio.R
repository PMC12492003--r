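test_that("FASTA parsing handles minimal records and line wrapping", {
  one <- parseFasta(text = ">a\nACGT")
  expect_equal(names(one), "a")
  expect_equal(as.character(one[[1]]), "ACGT")

  wrapped <- parseFasta(text = ">a\nAC\nGT")
  expect_equal(as.character(wrapped[[1]]), "ACGT")

  # header id stops at first whitespace; case is normalized
  rec <- parseFasta(text = ">id1 some description\nacgt")
  expect_equal(names(rec), "id1")
  expect_equal(as.character(rec[[1]]), "ACGT")
})

test_that("FASTA round-trip is lossless for ids and residues", {
  set.seed(7)
  seqs <- vapply(1:12, function(i) randomDNA(sample(40:120, 1), seed = i),
                 character(1))
  names(seqs) <- paste0("rec", 1:12)
  f <- tempfile(fileext = ".fasta")
  writeFasta(Biostrings::DNAStringSet(seqs), f, width = 17)
  back <- parseFasta(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), unname(seqs), ignore_attr = TRUE)
})

test_that("FASTA format errors name the offending line", {
  expect_error(parseFasta(text = ">\nACGT"), "empty id at line 1")
  expect_error(
    parseFasta(text = ">a\nACGT\n>b\nAC!T", alphabet = "nucleotide"),
    "line 4")
})

test_that("pairwise identity is a symmetric percentage with gap handling", {
  expect_equal(pairwiseIdentity("ACGT", "ACGT"), 100)
  expect_equal(pairwiseIdentity("AAAA", "TTTT"), 0)
  expect_equal(pairwiseIdentity("ACGT", "ACGA"), 75)
  # gap columns dropped by default, counted as mismatch-free columns never
  expect_equal(pairwiseIdentity("AC-T", "ACGT"), 100)
  expect_equal(pairwiseIdentity("AC-T", "ACGT", ignoreGapColumns = FALSE), 75)
  a <- randomDNA(100, 1); b <- randomDNA(100, 2)
  expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  expect_error(pairwiseIdentity("ACG", "ACGT"), "lengths differ")
})

test_that("dot plot reports the self-diagonal and planted shared words", {
  s <- randomDNA(80, seed = 3)
  dp <- dotPlot(s, s, window = 20, threshold = 70)
  diag_expected <- 0:(80 - 20)
  expect_true(all(diag_expected %in% dp$i[dp$i == dp$j]))

  # one exact 20-mer shared at offsets (5, 40) in otherwise unrelated seqs
  word <- randomDNA(20, seed = 4)
  set.seed(5)
  a <- paste0(randomDNA(5, 50), word, randomDNA(40, 51))
  b <- paste0(randomDNA(40, 52), word, randomDNA(10, 53))
  dp <- dotPlot(a, b, window = 20, threshold = 70)
  expect_true(any(dp$i == 5 & dp$j == 40))
})

test_that("dot plot scoring sits exactly at the 17/3 boundary", {
  # 17 matches, 3 mismatches: 17*5 - 3*4 = 73 >= 70 (kept)
  a <- strsplit(randomDNA(20, seed = 6), "")[[1]]
  b <- a
  flip <- function(x) setdiff(c("A", "C", "G", "T"), x)[1]
  for (k in c(3, 9, 15)) b[k] <- flip(b[k])
  dp <- dotPlot(paste(a, collapse = ""), paste(b, collapse = ""),
                window = 20, threshold = 70)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$score, 73)
  # a fourth mismatch drops the score to 64 (< 70)
  b[18] <- flip(b[18])
  dp <- dotPlot(paste(a, collapse = ""), paste(b, collapse = ""),
                window = 20, threshold = 70)
  expect_equal(nrow(dp), 0L)
})

test_that("dot plot equals the naive brute-force scorer", {
  a <- randomDNA(150, seed = 8)
  b <- paste0(substr(a, 30, 90), randomDNA(60, seed = 9))
  for (w in c(10, 20)) {
    got <- dotPlot(a, b, window = w, threshold = 3 * w)
    want <- oracleDotplot(a, b, w, thr = 3 * w)
    o1 <- got[order(got$i, got$j), ]; o2 <- want[order(want$i, want$j), ]
    expect_equal(o1$i, o2$i)
    expect_equal(o1$j, o2$j)
    expect_equal(o1$score, o2$score)
  }
  expect_error(dotPlot("ACGT", "ACGT", window = 10), "window")
})

test_that("in-silico PCR finds constructed amplicons with exact coordinates", {
  fwd <- randomDNA(20, seed = 10)
  rev <- randomDNA(20, seed = 11)
  rcrev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  tpl <- paste0(randomDNA(10, 12), fwd, randomDNA(60, 13), rcrev,
                randomDNA(10, 14))
  amp <- inSilicoPCR(tpl, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 10L)
  expect_equal(amp$end, 110L)
  expect_equal(amp$length, 100L)
  # product equals the template slice; reverse primer revcomp at its 3' end
  expect_equal(amp$sequence, substr(tpl, 11, 110))
  expect_equal(substr(amp$sequence, 81, 100), rcrev)
  # template lacking the forward primer gives no product
  expect_equal(nrow(inSilicoPCR(randomDNA(100, 15), fwd, rev)), 0L)
})

test_that("restriction digestion matches manual cut positions", {
  enz <- knownEnzymes()
  expect_equal(digestSequence("AAAACCATGGAAAA", enz$NcoI), c(5L, 9L))
  expect_equal(digestSequence("GCCTTTTAGGC", enz$BglI), c(7L, 4L))
  expect_equal(digestSequence("AAAATTTT", enz$NcoI), 8L)  # uncut
})

test_that("digest fragments always reconstitute the input", {
  enz <- knownEnzymes()$NcoI
  for (seed in 1:5) {
    s <- paste0(randomDNA(30, seed), "CCATGG", randomDNA(25, seed + 50),
                "CCATGG", randomDNA(10, seed + 100))
    fr <- digestSequence(s, enz)
    expect_equal(sum(fr), nchar(s))
    # cutting at the recorded boundaries reassembles the sequence
    ends <- cumsum(fr)
    starts <- c(1L, head(ends, -1) + 1L)
    expect_equal(paste(substring(s, starts, ends), collapse = ""), s)
  }
})
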