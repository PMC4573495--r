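test_that("six-frame translation covers both strands with correct frames", {
  ft <- sixFrameTranslate("ATGAAA")
  expect_equal(ft$peptide[ft$frame == 1], "MK")
  # reverse complement of ATGAAA read in frame -1 gives the same peptide
  ft2 <- sixFrameTranslate("TTTCAT")
  expect_equal(ft2$peptide[ft2$frame == -1], "MK")
  # frame sign flips under reverse complement
  set.seed(101)
  for (rep in 1:5) {
    s <- rdna(30 + rep)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- sixFrameTranslate(s)
    b <- sixFrameTranslate(rc)
    for (k in 1:3) {
      expect_equal(a$peptide[a$frame == k], b$peptide[b$frame == -k])
      expect_equal(a$peptide[a$frame == -k], b$peptide[b$frame == k])
    }
  }
})

test_that("six-frame peptide lengths follow floor((n - offset)/3)", {
  set.seed(7)
  for (n in c(3, 4, 5, 10, 31, 100)) {
    s <- rdna(n)
    ft <- sixFrameTranslate(s)
    for (k in 1:3) {
      expect_equal(nchar(ft$peptide[ft$frame == k]), (n - k + 1) %/% 3)
      expect_equal(nchar(ft$peptide[ft$frame == -k]), (n - k + 1) %/% 3)
    }
  }
  expect_warning(ft0 <- sixFrameTranslate("AT"), "shorter")
  expect_true(all(ft0$peptide == ""))
})

test_that("low-complexity masking removes repeats and keeps complex sequence", {
  # zero-entropy homopolymer is fully masked
  r1 <- maskLowComplexity(strrep("A", 60))
  expect_equal(as.integer(c(IRanges::start(r1$intervals),
                            IRanges::end(r1$intervals))), c(1L, 60L))
  # one-bit dinucleotide repeat falls below the trinucleotide threshold
  r2 <- maskLowComplexity(strrep("AC", 30))
  expect_equal(sum(IRanges::width(r2$intervals)), 60L)
  # high-complexity 64-nt window stays unmasked; certify with a direct
  # entropy oracle on the trinucleotide counts
  set.seed(33)
  repeat {
    s <- rdna(64)
    tri <- substring(s, 1:62, 3:64)
    f <- as.numeric(table(tri)) / 62
    if (-sum(f * log2(f)) > 1.6) break   # typical random draw: ~5.5 bits
  }
  expect_gt(-sum(f * log2(f)), 1.5)
  r3 <- maskLowComplexity(s)
  expect_equal(length(r3$intervals), 0L)
  expect_equal(r3$masked, s)
})

test_that("masking is idempotent on sequences with embedded repeats", {
  set.seed(9)
  for (rep in 1:10) {
    s <- paste0(rdna(300), strrep("AT", 60), rdna(200), strrep("G", 80),
                rdna(250))
    m1 <- maskLowComplexity(s)$masked
    m2 <- maskLowComplexity(m1)$masked
    expect_identical(m2, m1)
    expect_equal(nchar(m1), nchar(s))
  }
})

test_that("local alignment reproduces the classic textbook optimum", {
  # HEAGAWGHEE vs PAWHEAE under BLOSUM50 with linear gap penalty 8
  sp <- searchParams(matrixName = "BLOSUM50", gapOpen = 1e-9, gapExtend = 8)
  al <- localAlign("HEAGAWGHEE", "PAWHEAE", sp)
  expect_equal(al$score, 28, tolerance = 1e-6)
})

test_that("local alignment score equals the brute-force affine DP", {
  sp <- searchParams()
  mat <- eveSubstitutionMatrix("BLOSUM62")
  set.seed(2024)
  for (i in 1:60) {
    a <- rpep(sample(3:12, 1))
    b <- rpep(sample(3:12, 1))
    expect_equal(localAlign(a, b, sp)$score,
                 bruteLocalAlign(a, b, mat, sp@gapOpen, sp@gapExtend),
                 tolerance = 1e-6, label = paste(a, b))
  }
})

test_that("self-alignment scores the matrix diagonal and is symmetric", {
  sp <- searchParams()
  mat <- eveSubstitutionMatrix("BLOSUM62")
  set.seed(5)
  for (i in 1:10) {
    p <- rpep(8)
    expect_equal(localAlign(p, p, sp)$score,
                 sum(mat[cbind(strsplit(p, "")[[1]], strsplit(p, "")[[1]])]))
    q <- rpep(8)
    expect_equal(localAlign(p, q, sp)$score, localAlign(q, p, sp)$score)
  }
  expect_error(localAlign("", "MK", sp), "non-empty")
})

test_that("E-values follow the Karlin-Altschul formula", {
  sp <- searchParams()
  # direct evaluation: K=0.041, lambda=0.267, m=200, n=1e5, S=50 -> ~1.3
  expect_equal(estimateEvalue(50, 200, 100000, sp),
               0.041 * 200 * 1e5 * exp(-0.267 * 50), tolerance = 1e-12)
  expect_equal(round(estimateEvalue(50, 200, 100000, sp), 1), 1.3)
  # analytic identity: lambda * S = ln(K m n) gives E = 1
  s0 <- log(sp@K * 300 * 5000) / sp@lambda
  expect_equal(estimateEvalue(s0, 300, 5000, sp), 1, tolerance = 1e-9)
  # linear in n, strictly decreasing in score
  expect_equal(estimateEvalue(40, 100, 2e5, sp),
               2 * estimateEvalue(40, 100, 1e5, sp))
  sc <- seq(10, 100, by = 10)
  ev <- estimateEvalue(sc, 100, 1e5, sp)
  expect_true(all(diff(ev) < 0))
  expect_error(estimateEvalue(10, 0, 10, sp), ">= 1")
})
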