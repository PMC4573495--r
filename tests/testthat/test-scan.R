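test_that("translated scan recovers planted fragments and nothing else", {
  run <- smallRun()
  ins <- trueInsertions(run$sim$truth)
  hits <- run$hits
  # every intact insertion yields a hit overlapping its interval with the
  # correct strand
  for (i in seq_along(ins)) {
    scaf <- as.character(GenomicRanges::seqnames(ins)[i])
    hh <- hits[hits$scaffold == scaf &
                 hits$start <= GenomicRanges::end(ins)[i] &
                 hits$end >= GenomicRanges::start(ins)[i], , drop = FALSE]
    expect_gte(nrow(hh), 1L)
    expect_true(all(hh$strand == as.character(GenomicRanges::strand(ins)[i])))
    expect_true(S4Vectors::mcols(ins)$protein_id[i] %in% hh$protein_id)
  }
  # no hit outside truth intervals
  gr <- GenomicRanges::GRanges(hits$scaffold,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- GenomicRanges::countOverlaps(gr, ins, ignore.strand = TRUE)
  expect_true(all(ov >= 1L))
  expect_error(translatedScan(run$sim$genomeA,
                              new("ViralRefDB",
                                  proteins = Biostrings::AAStringSet(),
                                  genomes = Biostrings::DNAStringSet(),
                                  proteinInfo = S4Vectors::DataFrame(
                                    protein_id = character(0),
                                    group = character(0),
                                    role = character(0),
                                    genome_id = character(0),
                                    orf_start = integer(0),
                                    orf_end = integer(0)))),
               "empty")
})

test_that("pure background yields zero hits at the E-value threshold", {
  run <- smallRun()
  set.seed(99)
  bg <- genomeAssembly(c(bg1 = rdna(8000, 0.42), bg2 = rdna(8000, 0.42)),
                       source = "background")
  hits <- translatedScan(maskAssembly(bg), run$db)
  expect_equal(nrow(hits), 0L)
})

test_that("reverse-complementing a scaffold flips only the reported strand", {
  run <- smallRun()
  ins <- trueInsertions(run$sim$truth)[1]
  scaf <- as.character(GenomicRanges::seqnames(ins))
  s <- as.character(scaffolds(run$sim$genomeA)[[scaf]])
  n <- nchar(s)
  fwd <- translatedScan(genomeAssembly(c(x = s)), run$db)
  rev <- translatedScan(
    genomeAssembly(c(x = paleovirome:::revcomp(s))), run$db)
  fwd <- fwd[order(fwd$start), ]; rev <- rev[order(rev$start), ]
  expect_equal(nrow(fwd), nrow(rev))
  # mirrored coordinates, opposite strands
  expect_setequal(n - rev$end + 1L, fwd$start)
  expect_true(all(sort(fwd$protein_id) == sort(rev$protein_id)))
  m <- match(n - rev$end + 1L, fwd$start)
  expect_true(all(fwd$strand[m] != rev$strand))
})

test_that("reciprocal filtering removes host-derived segments and ties", {
  run <- smallRun()
  db <- run$db
  decoys <- buildDecoyDb(run$cfg)
  set.seed(11)
  # plant a decoy-derived coding segment in background: best match is the
  # decoy, so the hit (simulated by scanning it directly) must be removed
  decoyNt <- paleovirome:::.reverseTranslate(
    as.character(decoys[[1]]))
  fakeHit <- data.frame(scaffold = "z", start = 1L,
                        end = nchar(decoyNt), strand = "+", frame = 1L,
                        protein_id = "whatever", group = "Bunyaviridae",
                        role = "polymerase", score = 50, evalue = 1e-6,
                        pident = 30, alen = 100, stringsAsFactors = FALSE)
  g <- genomeAssembly(c(z = decoyNt))
  expect_equal(nrow(reciprocalFilter(fakeHit, g, db, decoys)), 0L)
  # a verbatim viral segment is retained
  info <- as.data.frame(proteinInfo(db))
  vg <- as.character(viralGenomes(db)[[info$genome_id[1]]])
  cds <- substr(vg, info$orf_start[1], info$orf_end[1] - 3L)
  fakeHit2 <- fakeHit
  fakeHit2$end <- nchar(cds)
  g2 <- genomeAssembly(c(z = cds))
  expect_equal(nrow(reciprocalFilter(fakeHit2, g2, db, decoys)), 1L)
  # exact score tie between viral and decoy best -> removed (conservative)
  tiedDecoys <- c(decoys, viralProteins(db)[1])
  expect_equal(nrow(reciprocalFilter(fakeHit2, g2, db, tiedDecoys)), 0L)
  expect_error(reciprocalFilter(fakeHit2, g2, db,
                                Biostrings::AAStringSet()), "non-empty")
})

test_that("hit merging obeys the gap rule, strand barrier and transitivity", {
  h <- function(scaf, st, en, strand = "+") {
    data.frame(scaffold = scaf, start = st, end = en, strand = strand,
               frame = 1L, protein_id = "p", group = "Totiviridae",
               role = "polymerase", score = 100, evalue = 1e-9, pident = 90,
               alen = 30, stringsAsFactors = FALSE)
  }
  # two same-strand hits 50 bp apart merge at max_gap 100
  two <- rbind(h("s1", 100, 200), h("s1", 251, 350))
  expect_equal(length(mergeHitsToLoci(two, 100)$loci), 1L)
  # opposite strands never merge
  opp <- rbind(h("s1", 100, 200, "+"), h("s1", 251, 350, "-"))
  expect_equal(length(mergeHitsToLoci(opp, 100)$loci), 2L)
  # transitive chain collapses into a single spanning locus
  chain <- rbind(h("s1", 100, 200), h("s1", 290, 380), h("s1", 470, 560))
  ml <- mergeHitsToLoci(chain, 100)
  expect_equal(length(ml$loci), 1L)
  expect_equal(c(GenomicRanges::start(ml$loci),
                 GenomicRanges::end(ml$loci)), c(100L, 560L))
  # just over the gap stays split
  far <- rbind(h("s1", 100, 200), h("s1", 302, 400))
  expect_equal(length(mergeHitsToLoci(far, 100)$loci), 2L)
  # merging is independent of input order
  ml2 <- mergeHitsToLoci(chain[c(3, 1, 2), ], 100)
  expect_equal(as.data.frame(ml2$loci), as.data.frame(ml$loci))
  expect_error(mergeHitsToLoci(two, -1), "non-negative")
})

test_that("classification picks the lowest-E component hit with tie rules", {
  mk <- function(pid, grp, role, ev, sc) {
    data.frame(scaffold = "s1", start = 10L, end = 60L, strand = "+",
               frame = 1L, protein_id = pid, group = grp, role = role,
               score = sc, evalue = ev, pident = 80, alen = 20,
               locus_id = "EVE_01", stringsAsFactors = FALSE)
  }
  loci <- GenomicRanges::GRanges("s1", IRanges::IRanges(10, 60), "+")
  S4Vectors::mcols(loci)$locus_id <- "EVE_01"
  # single-hit locus inherits its group/role
  one <- classifyViralGroup(loci, mk("repA", "Circoviridae", "rep", 1e-8, 40))
  expect_equal(S4Vectors::mcols(one)$group, "Circoviridae")
  expect_equal(S4Vectors::mcols(one)$role, "rep")
  # lowest E-value wins over higher E
  two <- classifyViralGroup(loci, rbind(
    mk("nsP", "Parvoviridae", "NS", 1e-20, 90),
    mk("capD", "Parvoviridae", "capsid", 1e-5, 50)))
  expect_equal(S4Vectors::mcols(two)$role, "NS")
  # E tie -> higher score; full tie -> smallest protein id
  tie <- classifyViralGroup(loci, rbind(
    mk("bbb", "Totiviridae", "polymerase", 1e-10, 80),
    mk("aaa", "Bunyaviridae", "polymerase", 1e-10, 95)))
  expect_equal(S4Vectors::mcols(tie)$group, "Bunyaviridae")
  tie2 <- classifyViralGroup(loci, rbind(
    mk("bbb", "Totiviridae", "polymerase", 1e-10, 80),
    mk("aaa", "Bunyaviridae", "polymerase", 1e-10, 80)))
  expect_equal(S4Vectors::mcols(tie2)$best_protein, "aaa")
})

test_that("per-group locus counts equal truth at zero degradation", {
  run <- smallRun()
  loci <- run$loci
  ins <- trueInsertions(run$sim$truth)
  called <- table(S4Vectors::mcols(loci)$group)
  truthCounts <- table(S4Vectors::mcols(ins)$group)
  expect_equal(as.vector(called[names(truthCounts)]),
               as.vector(truthCounts))
  # locus count invariant to scaffold order
  sc <- scaffolds(run$sim$genomeA)
  shuffled <- genomeAssembly(sc[c(2, 3, 1)], source = "shuffled")
  hits2 <- translatedScan(maskAssembly(shuffled), run$db)
  ml2 <- mergeHitsToLoci(hits2, 100)
  expect_equal(length(ml2$loci), length(loci))
})
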