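test_that("flank extraction respects the minimum-length rule at boundaries", {
  run <- smallRun()
  db <- run$db
  set.seed(21)
  # a locus starting 100 bp into the scaffold has no upstream flank
  loci <- GenomicRanges::GRanges("s1", IRanges::IRanges(101, 400), "+")
  S4Vectors::mcols(loci)$locus_id <- "L1"
  g <- genomeAssembly(c(s1 = rdna(1000)))
  fl <- extractFlanks(loci, g, db)
  expect_equal(fl$side, "downstream")
  expect_equal(fl$length, 150L)
  # an interior locus gets two flanks of exactly 150 bp
  loci2 <- GenomicRanges::GRanges("s1", IRanges::IRanges(401, 600), "+")
  S4Vectors::mcols(loci2)$locus_id <- "L2"
  fl2 <- extractFlanks(loci2, g, db)
  expect_setequal(fl2$side, c("upstream", "downstream"))
  expect_true(all(fl2$length == 150L))
  expect_true(all(fl2$virus_free))
})

test_that("a flank containing a second viral fragment is not virus-free", {
  run <- smallRun()
  db <- run$db
  info <- as.data.frame(proteinInfo(db))
  vg <- as.character(viralGenomes(db)[[info$genome_id[1]]])
  frag <- substr(vg, info$orf_start[1], info$orf_start[1] + 149L)
  set.seed(22)
  s <- paste0(rdna(400), frag, rdna(300))   # viral fragment at 401..550
  g <- genomeAssembly(c(s1 = s))
  loci <- GenomicRanges::GRanges("s1", IRanges::IRanges(551, 700), "+")
  S4Vectors::mcols(loci)$locus_id <- "L1"
  fl <- extractFlanks(loci, g, db)
  up <- fl[fl$side == "upstream", ]
  expect_false(up$virus_free)
})

test_that("microsatellite detection hits the copy-number boundary exactly", {
  set.seed(31)
  bg1 <- rdna(40); bg2 <- rdna(40)
  # (AC)x6 embedded in random sequence -> one AC record with 6 copies
  hit6 <- detectMicrosatellites(paste0(bg1, strrep("AC", 6), bg2))
  expect_gte(nrow(hit6), 1L)
  ac <- hit6[hit6$motif == "AC", , drop = FALSE]
  expect_equal(nrow(ac), 1L)
  expect_equal(ac$copies, 6L)
  # (AC)x5 stays below threshold
  hit5 <- detectMicrosatellites(paste0(bg1, strrep("AC", 5), bg2))
  expect_false("AC" %in% hit5$motif)
  # a mismatched middle unit splits (ACG)x7 into two short arrays -> none
  arr <- paste0(strrep("ACG", 3), "ATG", strrep("ACG", 3))
  expect_equal(nrow(detectMicrosatellites(paste0(bg1, arr, bg2))), 0L)
})

test_that("microsatellite arrays are canonical, primitive and non-nested", {
  # homopolymer reports only at unit length 1
  r <- detectMicrosatellites(paste0("GTC", strrep("A", 12), "CTG"))
  expect_equal(r$unit_len, 1L)
  expect_equal(r$motif, "A")
  expect_equal(r$copies, 12L)
  # motif reported in canonical rotation regardless of phase
  r2 <- detectMicrosatellites(paste0("GG", strrep("CA", 7), "TT"))
  expect_true(all(r2$motif != "CA"))
  expect_true("AC" %in% r2$motif)
})

test_that("microsatellite detection matches the brute-force enumerator", {
  set.seed(314)
  for (i in 1:60) {
    s <- paste0(rdna(60), strrep(sample(c("A", "AC", "ACG", "AT"), 1),
                                 sample(4:9, 1)), rdna(60))
    got <- detectMicrosatellites(s)
    want <- bruteTandems(s)
    expect_equal(got, want, label = paste("case", i))
  }
})

test_that("interspersed repeats require both length and copy thresholds", {
  set.seed(41)
  elem <- rdna(120)
  plant <- function(nCopies, element) {
    scafs <- vapply(1:3, function(i) rdna(3000), character(1))
    for (k in seq_len(nCopies - 1L)) {
      tgt <- (k %% 3) + 1L
      at <- 200 + 700 * ((k - 1) %/% 3)
      scafs[tgt] <- paste0(substr(scafs[tgt], 1, at), element,
                           substr(scafs[tgt], at + 1, nchar(scafs[tgt])))
    }
    # one copy inside the "flank"
    flank <- paste0(rdna(15), element, rdna(15))
    scafs[1] <- paste0(scafs[1], flank, rdna(100))
    names(scafs) <- paste0("s", 1:3)
    list(genome = genomeAssembly(scafs), flank = flank)
  }
  p10 <- plant(10, elem)
  r10 <- detectInterspersedRepeats(p10$flank, p10$genome)
  expect_equal(nrow(r10), 1L)
  expect_equal(r10$copies, 10L)
  expect_gte(r10$element_len, 100L)
  # 9 copies genome-wide: below the copy threshold
  p9 <- plant(9, elem)
  expect_equal(nrow(detectInterspersedRepeats(p9$flank, p9$genome)), 0L)
  # an 80-bp element at 20 copies: below the length threshold
  p80 <- plant(20, rdna(80))
  expect_equal(nrow(detectInterspersedRepeats(p80$flank, p80$genome)), 0L)
})

test_that("host-origin verdict is monotone in repeat evidence", {
  run <- smallRun()
  set.seed(51)
  g <- genomeAssembly(c(s1 = rdna(2000)))
  base <- data.frame(locus_id = "L1", side = "upstream", start = 1L,
                     end = 150L, seq = rdna(150), scaffold = "s1",
                     length = 150L, virus_free = TRUE,
                     stringsAsFactors = FALSE)
  plain <- flankReports(base, g)
  expect_false(plain$host_origin)
  withMs <- base
  withMs$seq <- paste0(rdna(60), strrep("AG", 7), rdna(76))
  rep1 <- flankReports(withMs, g)
  expect_true(rep1$host_origin)
  # adding evidence never flips TRUE -> FALSE: a flank with both kinds of
  # evidence still passes
  expect_true(flankReports(withMs, g)$host_origin)
  # virus similarity vetoes regardless of repeats
  withMs$virus_free <- FALSE
  expect_false(flankReports(withMs, g)$host_origin)
})

test_that("shared-flank duplication grouping counts k-1 events", {
  set.seed(61)
  shared <- rdna(200)
  mk <- function(id, seq) {
    data.frame(locus_id = id, side = "upstream", start = 1L, end = 150L,
               seq = seq, scaffold = "s1", length = nchar(seq),
               virus_free = TRUE, stringsAsFactors = FALSE)
  }
  # two identical 200-bp flanks -> one group, one event
  fl2 <- rbind(mk("A", shared), mk("B", shared), mk("C", rdna(200)))
  d2 <- detectSharedFlankDuplications(fl2)
  expect_equal(length(d2$groups), 1L)
  expect_equal(sort(d2$groups[[1]]), c("A", "B"))
  expect_equal(d2$events, 1L)
  # all-unique flanks -> zero events
  fl0 <- rbind(mk("A", rdna(200)), mk("B", rdna(200)), mk("C", rdna(200)))
  expect_equal(detectSharedFlankDuplications(fl0)$events, 0L)
  # a trio sharing the flank -> single group, two events (single linkage)
  fl3 <- rbind(mk("A", shared), mk("B", shared), mk("C", shared))
  d3 <- detectSharedFlankDuplications(fl3)
  expect_equal(length(d3$groups), 1L)
  expect_equal(d3$events, 2L)
  # 2% divergence between copies still groups (within the 95% rule)
  div <- paleovirome:::mutateDNA(shared, 0.02)
  d4 <- detectSharedFlankDuplications(rbind(mk("A", shared), mk("B", div)))
  expect_equal(d4$events, 1L)
})

test_that("simulated duplication groups are recovered exactly", {
  cfg <- simConfig(seed = 19, nScaffolds = 4, scaffoldLen = 9000,
                   insertionsPerGroup = 2, nDuplicationGroups = 1,
                   nOrthologPairs = 2, nOrthologAbsent = 1,
                   degradationGrid = list(c(0, 0, 0)))
  db <- buildViralDb(cfg)
  sim <- simulateGenomePair(cfg, db)
  hits <- translatedScan(maskAssembly(sim$genomeA), db)
  ml <- mergeHitsToLoci(hits, 100)
  loci <- classifyViralGroup(ml$loci, ml$hits)
  fl <- flankReports(extractFlanks(loci, sim$genomeA, db), sim$genomeA)
  dup <- detectSharedFlankDuplications(fl)
  # translate called groups into truth ids via interval overlap
  ins <- trueInsertions(sim$truth)
  toTruth <- function(ids) {
    sort(vapply(ids, function(id) {
      k <- which(S4Vectors::mcols(loci)$locus_id == id)
      ov <- GenomicRanges::findOverlaps(loci[k], ins, ignore.strand = TRUE)
      S4Vectors::mcols(ins)$locus_id[S4Vectors::subjectHits(ov)[1]]
    }, character(1)))
  }
  called <- lapply(dup$groups, toTruth)
  expect_equal(length(called), 1L)
  expect_equal(unname(called[[1]]),
               sort(trueDuplicationGroups(sim$truth)[[1]]))
  expect_equal(dup$events, 1L)
})
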