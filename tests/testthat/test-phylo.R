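test_that("progressive alignment handles identity, insertions and lengths", {
  # two identical sequences align gap-free
  a <- buildMsa(c(x = "MKEEWLAV", y = "MKEEWLAV"))
  expect_equal(as.character(a), c(x = "MKEEWLAV", y = "MKEEWLAV"))
  # a single inserted residue opens exactly one gap column in the others
  a3 <- buildMsa(c(s1 = "MKEEWLAV", s2 = "MKEEWLAV", s3 = "MKEEQWLAV"))
  m <- do.call(rbind, strsplit(as.character(a3), ""))
  expect_equal(ncol(m), 9L)
  expect_equal(sum(m == "-"), 2L)
  gapCol <- which(apply(m, 2, function(cl) any(cl == "-")))
  expect_equal(length(gapCol), 1L)
  expect_equal(unname(m[3, gapCol]), "Q")
  # alignment length >= longest input; degapping recovers inputs exactly
  set.seed(91)
  for (i in 1:8) {
    peps <- setNames(vapply(1:4, function(k) rpep(sample(15:30, 1)),
                            character(1)), paste0("p", 1:4))
    aln <- buildMsa(peps)
    w <- unique(nchar(as.character(aln)))
    expect_equal(length(w), 1L)
    expect_gte(w, max(nchar(peps)))
    expect_equal(gsub("-", "", as.character(aln)), peps)
  }
  expect_error(buildMsa(c(x = "MK")), "two sequences")
})

test_that("corrected distances follow the stated transform", {
  # identical rows are at distance zero
  same <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKLV"))
  expect_true(all(pairwiseDistances(same) == 0))
  # p = 0.2 maps to -ln(1 - 0.2 - 0.2 * 0.2^2) = 0.23319...
  pair <- Biostrings::AAStringSet(c(x = "AAAAAAAAAA", y = "AAAAAAAARR"))
  D <- pairwiseDistances(pair)
  expect_equal(D["x", "y"], -log(1 - 0.2 - 0.2 * 0.04), tolerance = 1e-9)
  expect_equal(D["x", "y"], 0.2331939, tolerance = 1e-6)
  # symmetric with zero diagonal; gaps excluded from shared columns
  trio <- Biostrings::AAStringSet(c(a = "MK-LV", b = "MKQLV", c = "MKQLF"))
  D3 <- pairwiseDistances(trio)
  expect_equal(D3, t(D3))
  expect_true(all(diag(D3) == 0))
  # no shared columns -> capped with a warning
  disj <- Biostrings::AAStringSet(c(a = "MK--", b = "--LV"))
  expect_warning(Dd <- pairwiseDistances(disj), "capped")
  expect_equal(Dd["a", "b"], 5)
})

test_that("neighbor-joining recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- phyloTree(njTree(D3))
  cp <- ape::cophenetic.phylo(t3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, D3, tolerance = 1e-9)
  # a frozen 4-taxon additive matrix (tree ((a:2,b:3):1,(c:4,d:4)) )
  D4 <- matrix(c(0, 5, 7, 7,
                 5, 0, 8, 8,
                 7, 8, 0, 8,
                 7, 8, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t4 <- phyloTree(njTree(D4))
  expect_equal(ape::cophenetic.phylo(t4)[letters[1:4], letters[1:4]], D4,
               tolerance = 1e-9)
  # permuting taxon order yields the same tree up to relabeling
  perm <- c(3, 1, 4, 2)
  t4p <- phyloTree(njTree(D4[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(t4p)),
               structure(0L, names = "PH85"), ignore_attr = TRUE)
  expect_error(njTree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  bad <- D4; bad[1, 2] <- 99
  expect_error(njTree(bad), "symmetric")
})

test_that("neighbor-joining is consistent over random additive matrices", {
  set.seed(97)
  for (i in 1:20) {
    tr <- ape::rtree(6, br = function(n) runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    got <- phyloTree(njTree(D))
    # path distances reconstruct the generating matrix exactly
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8, label = paste("tree", i))
  }
})

test_that("bootstrap supports are reproducible and saturate clear signal", {
  blocks <- Biostrings::AAStringSet(c(
    a1 = "MKLVWEEFGHMKLVWEEFGH", a2 = "MKLVWEEFGHMKLVWEEFGH",
    b1 = "QQPRSTNDYCQQPRSTNDYC", b2 = "QQPRSTNDYCQQPRSTNDYC"))
  bt <- bootstrapSupports(blocks, 100, seed = 5)
  sup <- edgeSupports(bt)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the edge separating the two blocks is recovered in every replicate
  expect_equal(sup[!is.na(sup)], 100)
  # byte-for-byte reproducibility under a fixed seed
  bt2 <- bootstrapSupports(blocks, 100, seed = 5)
  expect_identical(edgeSupports(bt), edgeSupports(bt2))
  expect_identical(phyloTree(bt)$edge, phyloTree(bt2)$edge)
  # default replicate count is 100
  expect_equal(eval(formals(bootstrapSupports)$nReplicates), 100L)
})

test_that("lineage assignment follows the smallest supported clade rule", {
  set.seed(96)
  ref <- rpep(40)
  mut <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    pos <- sample(length(x), k)
    x[pos] <- vapply(x[pos], function(a) {
      sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], a), 1)
    }, character(1))
    paste0(x, collapse = "")
  }
  taxa <- c(EVE_1 = mut(ref, 2), refA = ref, refB = rpep(40),
            out1 = rpep(40))
  bt <- bootstrapSupports(buildMsa(taxa), 100, seed = 9)
  asg <- assignLineages(bt, c(refA = "LineageA", refB = "LineageB",
                              out1 = "Out"), 70)
  # the EVE sister to refA with full support inherits refA's lineage
  expect_equal(unname(asg["EVE_1"]), "LineageA")
  # a threshold above every support leaves the EVE unassigned
  asg2 <- assignLineages(bt, c(refA = "LineageA", refB = "LineageB",
                               out1 = "Out"), 100)
  expect_equal(unname(asg2["EVE_1"]), "unassigned")
  # supports equal to the threshold do not qualify (strictly greater)
  sup <- edgeSupports(bt)
  sup[!is.na(sup)] <- 70
  bt70 <- new("LineageTree", tree = phyloTree(bt), edgeSupports = sup)
  asg3 <- assignLineages(bt70, c(refA = "LineageA", refB = "LineageB",
                                 out1 = "Out"), 70)
  expect_equal(unname(asg3["EVE_1"]), "unassigned")
})

test_that("distinct novel EVE clusters receive distinct labels", {
  set.seed(95)
  # two separated pure-EVE blocks plus a distant reference pair
  taxa <- c(EVE_1 = strrep("MKLVW", 8), EVE_2 = strrep("MKLVW", 8),
            EVE_3 = strrep("QPRST", 8), EVE_4 = strrep("QPRST", 8),
            refA = strrep("ACDEF", 8), refB = strrep("ACDEG", 8))
  bt <- bootstrapSupports(buildMsa(taxa), 100, seed = 10)
  asg <- assignLineages(bt, c(refA = "A", refB = "A"), 70)
  novel <- asg[startsWith(names(asg), "EVE")]
  expect_equal(unname(novel["EVE_1"]), unname(novel["EVE_2"]))
  expect_equal(unname(novel["EVE_3"]), unname(novel["EVE_4"]))
  expect_true(all(grepl("^novel-lineage-", novel)) ||
                any(novel == "unassigned"))
})
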