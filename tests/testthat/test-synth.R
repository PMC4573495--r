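test_that("viral database covers all groups with translatable ORFs", {
  cfg <- smallConfig()
  db <- buildViralDb(cfg)
  info <- as.data.frame(proteinInfo(db))
  expect_setequal(unique(info$group),
                  c("Bunyaviridae", "Circoviridae", "Mononegavirales",
                    "Parvoviridae", "Totiviridae"))
  expect_equal(length(unique(info$group)), 5L)
  # every protein translates from its ORF with no internal stop
  for (i in seq_len(nrow(info))) {
    g <- as.character(viralGenomes(db)[[info$genome_id[i]]])
    cds <- substr(g, info$orf_start[i], info$orf_end[i] - 3L)
    pep <- paleovirome:::translateNT(cds)
    expect_equal(pep, as.character(viralProteins(db)[[info$protein_id[i]]]))
    expect_false(grepl("*", pep, fixed = TRUE))
    stopCod <- substr(g, info$orf_end[i] - 2L, info$orf_end[i])
    expect_true(stopCod %in% c("TAA", "TAG", "TGA"))
  }
  expect_error(buildViralDb(simConfig(viralGroups = character(0))),
               "viral group")
})

test_that("same seed reproduces byte-identical FASTA output", {
  cfg <- smallConfig(seed = 77)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(viralProteins(buildViralDb(cfg)), f1)
  Biostrings::writeXStringSet(viralProteins(buildViralDb(cfg)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s1 <- simulateGenomePair(cfg, buildViralDb(cfg))
  s2 <- simulateGenomePair(cfg, buildViralDb(cfg))
  expect_identical(as.character(scaffolds(s1$genomeA)),
                   as.character(scaffolds(s2$genomeA)))
  expect_identical(as.character(scaffolds(s1$genomeB)),
                   as.character(scaffolds(s2$genomeB)))
  expect_identical(as.data.frame(trueInsertions(s1$truth)),
                   as.data.frame(trueInsertions(s2$truth)))
})

test_that("degradeOrf applies exactly the requested mutations", {
  set.seed(1)
  orf <- paste0("ATG", strrep("GCTGAAGTTCCATGG", 30))   # 453 nt, no stops
  # identity case
  d0 <- degradeOrf(orf, 0, 0, 0, seed = 3)
  expect_identical(d0$seq, orf)
  expect_equal(nrow(d0$record), 0L)
  # forced premature stops appear in the translation
  d2 <- degradeOrf(orf, 0, 2, 0, seed = 4)
  pep <- paleovirome:::translateNT(d2$seq)
  expect_equal(lengths(regmatches(pep, gregexpr("\\*", pep))), 2L)
  expect_equal(sum(d2$record$kind == "nonsense"), 2L)
  # single indel changes length by 1
  d1 <- degradeOrf(orf, 0, 0, 1, seed = 5)
  expect_true(abs(nchar(d1$seq) - nchar(orf)) == 1L)
  # background substitutions never create unrecorded stops
  d5 <- degradeOrf(orf, 0.08, 3, 0, seed = 6)
  pep5 <- paleovirome:::translateNT(d5$seq)
  expect_equal(lengths(regmatches(pep5, gregexpr("\\*", pep5))), 3L)
  # infeasible request errors
  expect_error(degradeOrf("ATGAAA", 0, 2, 0), "too short")
})

test_that("simulated pair echoes the configured truth structure", {
  cfg <- simConfig(seed = 8, nScaffolds = 4, scaffoldLen = 9000,
                   insertionsPerGroup = 2, nDuplicationGroups = 1,
                   nOrthologPairs = 3, nOrthologAbsent = 1,
                   degradationGrid = list(c(0, 0, 0), c(0.02, 2, 1)))
  db <- buildViralDb(cfg)
  sim <- simulateGenomePair(cfg, db)
  truth <- sim$truth
  ins <- trueInsertions(truth)
  # conservation: insertions = groups x insertionsPerGroup
  expect_equal(length(ins), 5L * 2L)
  # ortholog pairs echo config, with one flagged absent
  op <- trueOrthologPairs(truth)
  expect_equal(nrow(op), 3L)
  expect_equal(sum(!op$present_in_b), 1L)
  # duplication group members share an identical upstream 200 bp flank
  dg <- trueDuplicationGroups(truth)
  expect_equal(length(dg), 1L)
  expect_gte(length(dg[[1]]), 2L)
  up <- vapply(dg[[1]], function(id) {
    k <- which(S4Vectors::mcols(ins)$locus_id == id)
    scaf <- as.character(GenomicRanges::seqnames(ins)[k])
    st <- GenomicRanges::start(ins)[k]
    substr(as.character(scaffolds(sim$genomeA)[[scaf]]), st - 200L, st - 1L)
  }, character(1))
  expect_equal(length(unique(up)), 1L)
  # intervals lie within scaffold bounds
  w <- Biostrings::width(scaffolds(sim$genomeA))
  names(w) <- names(scaffolds(sim$genomeA))
  expect_true(all(GenomicRanges::start(ins) >= 1))
  expect_true(all(GenomicRanges::end(ins) <=
                    w[as.character(GenomicRanges::seqnames(ins))]))
})

test_that("re-deriving degradation counts from emitted sequences matches truth", {
  # independent recount: undo recorded indels, then translate and count stops
  cfg <- simConfig(seed = 13, nScaffolds = 3, scaffoldLen = 9000,
                   insertionsPerGroup = 1, nDuplicationGroups = 0,
                   nOrthologPairs = 0, nOrthologAbsent = 0,
                   degradationGrid = list(c(0, 4, 2)))
  db <- buildViralDb(cfg)
  sim <- simulateGenomePair(cfg, db)
  ins <- trueInsertions(sim$truth)
  for (i in seq_along(ins)) {
    scaf <- as.character(GenomicRanges::seqnames(ins)[i])
    seg <- substr(as.character(scaffolds(sim$genomeA)[[scaf]]),
                  GenomicRanges::start(ins)[i], GenomicRanges::end(ins)[i])
    if (as.character(GenomicRanges::strand(ins)[i]) == "-")
      seg <- paleovirome:::revcomp(seg)
    rec <- S4Vectors::mcols(ins)$mutations[[i]]
    fs <- rec[rec$kind == "frameshift", , drop = FALSE]
    expect_equal(nrow(fs), S4Vectors::mcols(ins)$n_frameshift[i])
    # reverse the indels (records are ordered right-to-left)
    x <- strsplit(seg, "", fixed = TRUE)[[1]]
    for (r in rev(seq_len(nrow(fs)))) {
      p <- fs$pos[r]
      if (startsWith(fs$detail[r], "del")) {
        x <- append(x, sub("del", "", fs$detail[r]), after = p - 1L)
      } else {
        x <- x[-(p + 1L)]
      }
    }
    pep <- paleovirome:::translateNT(paste0(x, collapse = ""))
    nStops <- lengths(regmatches(pep, gregexpr("\\*", pep)))
    expect_equal(nStops, S4Vectors::mcols(ins)$n_nonsense[i],
                 label = S4Vectors::mcols(ins)$locus_id[i])
  }
})
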