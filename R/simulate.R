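# Synthetic paleovirome generator: viral reference databases, host decoy
# proteins, ORF degradation, and ground-truthed host genome pairs carrying
# EVE insertions, repeats, shared-flank duplications and orthologous loci.

ROLE_MAP <- list(
  Bunyaviridae = c("polymerase", "nucleocapsid"),
  Circoviridae = c("rep", "capsid"),
  Mononegavirales = c("polymerase", "nucleocapsid"),
  Parvoviridae = c("NS", "capsid"),
  Totiviridae = c("polymerase", "capsid"))

PRIMARY_LEN <- 300L   # aa, polymerase-like genes
SECONDARY_LEN <- 180L # aa, structural genes

# Random peptide starting with M.
.randomProtein <- function(len) {
  paste0(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

# Reverse-translate a peptide with uniformly sampled synonymous codons.
.reverseTranslate <- function(pep) {
  inv <- codonsForAA()
  aa <- strsplit(pep, "", fixed = TRUE)[[1]]
  paste0(vapply(aa, function(a) {
    cs <- inv[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1)), collapse = "")
}

#' Build a synthetic viral reference database
#'
#' Generates \code{nVirusesPerGroup} viruses for each configured viral group.
#' Each virus carries two ORFs (a long polymerase-like gene and a shorter
#' structural gene, roles per group), embedded in a small genome with UTRs.
#' Protein and nucleotide records cross-reference via stable ids, and every
#' protein translates from its ORF with no internal stop.
#'
#' @param config A \linkS4class{SimConfig}; output is byte-identical for a
#'   fixed seed.
#' @return A \linkS4class{ViralRefDB}.
#' @examples
#' db <- buildViralDb(simConfig(seed = 1))
#' @export
buildViralDb <- function(config) {
  validObject(config)
  if (length(config@viralGroups) == 0L) stop("zero viral groups requested")
  withSeed(childSeed(config@seed, "viraldb"), {
    prot <- character(0); genomes <- character(0)
    rows <- list()
    for (g in config@viralGroups) {
      roles <- ROLE_MAP[[g]]
      for (v in seq_len(config@nVirusesPerGroup)) {
        virusId <- sprintf("%s_virus%d", g, v)
        parts <- randomDNA(50L, 0.45)
        for (ri in seq_along(roles)) {
          plen <- if (ri == 1L) PRIMARY_LEN else SECONDARY_LEN
          pep <- .randomProtein(plen)
          cds <- paste0(.reverseTranslate(pep), sample(STOP_CODONS, 1L))
          ostart <- nchar(parts) + 1L
          parts <- paste0(parts, cds)
          oend <- nchar(parts)
          if (ri < length(roles)) parts <- paste0(parts, randomDNA(30L, 0.45))
          pid <- paste0(virusId, "_", roles[ri])
          prot[pid] <- pep
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, group = g, role = roles[ri],
            genome_id = virusId, orf_start = ostart, orf_end = oend,
            stringsAsFactors = FALSE)
        }
        genomes[virusId] <- paste0(parts, randomDNA(50L, 0.45))
      }
    }
    new("ViralRefDB", proteins = AAStringSet(prot),
        genomes = DNAStringSet(genomes),
        proteinInfo = DataFrame(do.call(rbind, rows)))
  })
}

#' Build a host decoy protein set
#'
#' Random host-like proteins used as the comparison set in reciprocal
#' best-hit filtering (standing in for a general protein database).
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A named \link[Biostrings]{AAStringSet}.
#' @export
buildDecoyDb <- function(config) {
  validObject(config)
  withSeed(childSeed(config@seed, "decoys"), {
    lens <- sample(150:250, config@nDecoys, replace = TRUE)
    out <- vapply(lens, .randomProtein, character(1))
    names(out) <- sprintf("host_decoy_%02d", seq_along(out))
    AAStringSet(out)
  })
}

# pick n values from cand keeping pairwise distance >= minsep (relaxing the
# separation if necessary); error if impossible.
.pickSpaced <- function(cand, n, minsep) {
  if (n == 0L) return(integer(0))
  for (sep in unique(c(minsep, max(1L, minsep %/% 2L), 1L))) {
    for (try in 1:25) {
      pool <- sample(cand)
      chosen <- integer(0)
      for (p in pool) {
        if (all(abs(p - chosen) >= sep)) chosen <- c(chosen, p)
        if (length(chosen) == n) return(sort(chosen))
      }
    }
  }
  stop("cannot place ", n, " mutations with the requested spacing")
}

#' Degrade a viral ORF with recorded mutations
#'
#' Applies exactly \code{nNonsense} premature stop codons and
#' \code{nFrameshift} single-nucleotide indels at distinct, recorded
#' positions, plus background substitutions at \code{subRate} per site.
#' Background substitutions never create a stop codon in the original frame
#' (so every stop is recorded) and never touch a planted stop codon.
#'
#' @param orf In-frame coding nucleotide sequence (no terminal stop codon).
#' @param subRate Background substitution rate per site, in [0, 1].
#' @param nNonsense Number of codons to convert to stops.
#' @param nFrameshift Number of single-nucleotide indels.
#' @param seed Optional integer; when given, the operation runs on its own
#'   seeded stream, otherwise it consumes the caller's RNG stream.
#' @return A list: \code{seq} (degraded sequence) and \code{record}
#'   (data.frame of kind, pos, detail; positions are 1-based in the input).
#' @examples
#' orf <- paste0("ATG", strrep("GCTGAAGTT", 20))
#' degradeOrf(orf, 0, 2, 0, seed = 1)$record
#' @export
degradeOrf <- function(orf, subRate = 0, nNonsense = 0L, nFrameshift = 0L,
                       seed = NULL) {
  run <- function() {
    s <- toupper(as.character(orf))
    L <- nchar(s)
    if (L < 3L * (nNonsense + 1L))
      stop("ORF too short for ", nNonsense, " nonsense mutations")
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    nc <- L %/% 3L
    rec <- list()
    # nonsense: internal codons, kept apart from each other
    cand <- if (nc >= 10L) seq(4L, nc - 3L) else seq(2L, max(2L, nc - 1L))
    stopIdx <- .pickSpaced(cand, nNonsense, 3L)
    stopNt <- integer(0)
    for (ci in stopIdx) {
      ntr <- (3L * ci - 2L):(3L * ci)
      newStop <- sample(STOP_CODONS, 1L)
      rec[[length(rec) + 1L]] <- data.frame(
        kind = "nonsense", pos = 3L * ci - 2L,
        detail = paste0(paste0(x[ntr], collapse = ""), ">", newStop),
        stringsAsFactors = FALSE)
      x[ntr] <- strsplit(newStop, "", fixed = TRUE)[[1]]
      stopNt <- c(stopNt, ntr)
    }
    # background substitutions avoiding new in-frame stops
    if (subRate > 0) {
      eligible <- setdiff(seq_len(L), c(stopNt, 1:3))
      hit <- eligible[stats::runif(length(eligible)) < subRate]
      for (p in hit) {
        ci <- (p - 1L) %/% 3L + 1L
        ntr <- (3L * ci - 2L):(3L * ci)
        alts <- setdiff(DNA_BASES4, x[p])
        safe <- alts[vapply(alts, function(b) {
          cod <- x[ntr]; cod[p - ntr[1L] + 1L] <- b
          !(paste0(cod, collapse = "") %in% STOP_CODONS)
        }, logical(1))]
        if (!length(safe)) next
        b <- if (length(safe) == 1L) safe else sample(safe, 1L)
        rec[[length(rec) + 1L]] <- data.frame(
          kind = "substitution", pos = p, detail = paste0(x[p], ">", b),
          stringsAsFactors = FALSE)
        x[p] <- b
      }
    }
    # frameshifts: single-nt indels, away from ends and from planted stops
    if (nFrameshift > 0L) {
      fsCand <- setdiff(seq(min(45L, L %/% 4L), max(2L, L - min(45L, L %/% 4L))),
                        unlist(lapply(stopNt, function(p) (p - 12L):(p + 12L))))
      fsPos <- .pickSpaced(fsCand, nFrameshift, 30L)
      for (p in rev(fsPos)) {
        if (stats::runif(1) < 0.5) {
          rec[[length(rec) + 1L]] <- data.frame(
            kind = "frameshift", pos = p, detail = paste0("del", x[p]),
            stringsAsFactors = FALSE)
          x <- x[-p]
        } else {
          b <- sample(DNA_BASES4, 1L)
          rec[[length(rec) + 1L]] <- data.frame(
            kind = "frameshift", pos = p, detail = paste0("ins", b),
            stringsAsFactors = FALSE)
          x <- append(x, b, after = p)
        }
      }
    }
    record <- if (length(rec)) do.call(rbind, rec) else
      data.frame(kind = character(0), pos = integer(0),
                 detail = character(0), stringsAsFactors = FALSE)
    list(seq = paste0(x, collapse = ""), record = record)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

# Generate a primitive microsatellite motif of length 1..3 (never a
# homopolymer for lengths > 1 to keep the motif primitive).
.randomMotif <- function() {
  len <- sample(2:3, 1L)
  repeat {
    m <- paste0(sample(DNA_BASES4, len, replace = TRUE), collapse = "")
    x <- strsplit(m, "", fixed = TRUE)[[1]]
    if (length(unique(x)) > 1L &&
        !(len == 3L && x[1] == x[2] && x[2] == x[3])) return(m)
  }
}

# A host flank segment of length `len` with an embedded microsatellite in its
# last `window` bp; returns list(seq, msStart, msEnd, motif, copies).
.flankWithMicrosat <- function(len, gc, window = 130L) {
  motif <- .randomMotif()
  copies <- sample(6:9, 1L)
  arr <- strrep(motif, copies)
  alen <- nchar(arr)
  lo <- max(1L, len - window)
  st <- sample(lo:(len - alen - 5L), 1L)
  seqv <- paste0(randomDNA(st - 1L, gc), arr,
                 randomDNA(len - st + 1L - alen, gc))
  list(seq = seqv, msStart = st, msEnd = st + alen - 1L, motif = motif,
       copies = copies)
}

#' Simulate a ground-truthed host genome pair
#'
#' Generates genome A with all planned EVE insertions embedded in i.i.d.
#' background at the configured GC, each insertion preceded by a host flank
#' carrying a planted microsatellite. Duplication groups share an identical
#' 200-bp flank copied together with the EVE; one interspersed repeat family
#' (element of \code{interspersedLength} bp at \code{interspersedCopies}
#' genome-wide copies, one copy inside an EVE downstream flank) and scattered
#' microsatellites are planted as host features. Genome B derives from the
#' same pre-insertion host map point-mutated at \code{speciesDivergence};
#' ortholog-pair loci reappear at the homologous position in B (flagged
#' absence loci keep the empty pre-insertion site), while the flanks of
#' species-A-specific loci are replaced by B-private sequence so that no
#' spurious homologous flank exists.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param db The \linkS4class{ViralRefDB} built from the same config.
#' @return A list: \code{genomeA}, \code{genomeB}
#'   (\linkS4class{GenomeAssembly}) and \code{truth}
#'   (\linkS4class{SimTruth}).
#' @export
simulateGenomePair <- function(config, db) {
  validObject(config)
  withSeed(childSeed(config@seed, "genomes"), .simulatePair(config, db))
}

.simulatePair <- function(config, db) {
  gc <- config@gcContent
  info <- as.data.frame(proteinInfo(db))
  genomes <- viralGenomes(db)
  grid <- config@degradationGrid
  # ---- plan insertions ----------------------------------------------------
  plan <- list()
  for (g in config@viralGroups) {
    roles <- ROLE_MAP[[g]]
    for (j in seq_len(config@insertionsPerGroup)) {
      role <- if (j %% 3L == 0L) roles[2L] else roles[1L]
      v <- (j - 1L) %% config@nVirusesPerGroup + 1L
      virusId <- sprintf("%s_virus%d", g, v)
      pid <- paste0(virusId, "_", role)
      row <- info[info$protein_id == pid, , drop = FALSE]
      cds <- substr(as.character(genomes[[row$genome_id]]),
                    row$orf_start, row$orf_end - 3L)
      lvl <- grid[[(j - 1L) %% length(grid) + 1L]]
      deg <- degradeOrf(cds, lvl[1L], lvl[2L], lvl[3L])
      plan[[length(plan) + 1L]] <- list(
        group = g, role = role, protein_id = pid, virus_id = virusId,
        eve = deg$seq, record = deg$record, sub_rate = lvl[1L],
        n_nonsense = lvl[2L], n_frameshift = lvl[3L],
        strand = sample(c("+", "-"), 1L),
        dup_group = NA_character_, ortholog_id = NA_character_,
        present_in_b = NA)
    }
  }
  nIns <- length(plan)
  for (i in seq_len(nIns)) plan[[i]]$locus_id <- sprintf("trueEVE_%02d", i)
  # ---- duplication groups: later members become copies of the first ------
  dupFlanks <- character(0)
  dupMembers <- integer(0)
  k <- config@duplicationGroupSize
  if (config@nDuplicationGroups * k > nIns)
    stop("infeasible packing: more duplication members than insertions")
  for (d in seq_len(config@nDuplicationGroups)) {
    members <- ((d - 1L) * k + 1L):(d * k)
    dupMembers <- c(dupMembers, members)
    fl <- .flankWithMicrosat(200L, gc)
    dupFlanks[sprintf("dup_%d", d)] <- fl$seq
    attr(dupFlanks, sprintf("ms_%d", d)) <- fl
    lead <- plan[[members[1L]]]
    for (m in members) {
      plan[[m]]$dup_group <- sprintf("dup_%d", d)
      if (m != members[1L]) {
        for (f in c("group", "role", "protein_id", "virus_id", "eve",
                    "record", "sub_rate", "n_nonsense", "n_frameshift",
                    "strand")) {
          plan[[m]][[f]] <- lead[[f]]
        }
      }
    }
  }
  # ---- ortholog pairs (never duplication members) -------------------------
  cand <- setdiff(seq_len(nIns), dupMembers)
  if (config@nOrthologPairs > length(cand))
    stop("infeasible packing: not enough non-duplicated loci for orthologs")
  orthIdx <- sort(sample(cand, config@nOrthologPairs))
  absent <- orthIdx[seq_len(config@nOrthologAbsent)]
  for (ii in seq_along(orthIdx)) {
    i <- orthIdx[ii]
    plan[[i]]$ortholog_id <- sprintf("orth_%d", ii)
    plan[[i]]$present_in_b <- !(i %in% absent)
  }
  # host locus carrying the interspersed element in its downstream flank
  elemHost <- setdiff(cand, orthIdx)[1L]
  if (is.na(elemHost)) elemHost <- 0L
  element <- randomDNA(config@interspersedLength, gc)
  # ---- compose per-insertion host blocks ----------------------------------
  blocks <- list()   # site and feature blocks, later spread over scaffolds
  for (i in seq_len(nIns)) {
    p <- plan[[i]]
    if (!is.na(p$dup_group)) {
      fl <- attr(dupFlanks, sub("dup", "ms", p$dup_group))
      pre <- fl$seq
      ms <- list(start = fl$msStart, end = fl$msEnd, motif = fl$motif,
                 copies = fl$copies)
    } else {
      fl <- .flankWithMicrosat(150L, gc)
      pre <- fl$seq
      ms <- list(start = fl$msStart, end = fl$msEnd, motif = fl$motif,
                 copies = fl$copies)
    }
    post <- ""
    postElem <- NULL
    if (i == elemHost) {
      post <- paste0(randomDNA(15L, gc), element, randomDNA(15L, gc))
      postElem <- c(16L, 15L + nchar(element))
    }
    blocks[[length(blocks) + 1L]] <- list(
      type = "site", idx = i, pre = pre, ms = ms, post = post,
      postElem = postElem)
  }
  for (c2 in seq_len(max(0L, config@interspersedCopies - 1L))) {
    blocks[[length(blocks) + 1L]] <- list(type = "element", seq = element)
  }
  nScatter <- round(config@microsatDensity * config@nScaffolds *
                      config@scaffoldLen / 1000)
  for (s2 in seq_len(nScatter)) {
    motif <- .randomMotif()
    copies <- sample(6:10, 1L)
    blocks[[length(blocks) + 1L]] <- list(
      type = "microsat", seq = strrep(motif, copies), motif = motif,
      copies = copies)
  }
  # ---- spread blocks over scaffolds and check packing ---------------------
  ns <- config@nScaffolds
  assignment <- rep(seq_len(ns), length.out = length(blocks))
  hostLenOf <- function(b) {
    as.numeric(switch(b$type, site = nchar(b$pre) + nchar(b$post),
                      nchar(b$seq)))
  }
  minGap <- 500L
  for (s in seq_len(ns)) {
    bi <- which(assignment == s)
    used <- sum(vapply(blocks[bi], hostLenOf, numeric(1)))
    if (used + (length(bi) + 1L) * minGap > config@scaffoldLen)
      stop("infeasible packing: scaffold ", s, " needs ",
           used + (length(bi) + 1L) * minGap, " bp of host background but ",
           "scaffoldLen is ", config@scaffoldLen)
  }
  # ---- walk scaffolds, building A / B and the truth ledger ----------------
  aSeqs <- bSeqs <- character(ns)
  insRows <- list(); repRows <- list(); orthRows <- list()
  for (s in seq_len(ns)) {
    scafName <- sprintf("scaffold_%d", s)
    bi <- sample(which(assignment == s))  # shuffled order along the scaffold
    used <- sum(vapply(blocks[bi], hostLenOf, numeric(1)))
    remaining <- config@scaffoldLen - used
    w <- stats::runif(length(bi) + 1L, 0.8, 1.2)
    gaps <- floor(remaining * w / sum(w))
    gaps[1L] <- gaps[1L] + remaining - sum(gaps)
    aParts <- character(0); bParts <- character(0)
    aPos <- 0L; bPos <- 0L
    privHead <- 0L   # bp of the next gap to keep B-private (after an
                     # A-specific insertion, so its downstream flank has no
                     # homolog in B)
    emitHost <- function(seqA, seqB) {
      aParts[[length(aParts) + 1L]] <<- seqA
      bParts[[length(bParts) + 1L]] <<- seqB
      aPos <<- aPos + nchar(seqA)
      bPos <<- bPos + nchar(seqB)
    }
    emitGap <- function(len) {
      gseq <- randomDNA(len, gc)
      h <- min(privHead, len)
      privHead <<- 0L
      bseq <- paste0(randomDNA(h, gc),
                     mutateDNA(substr(gseq, h + 1L, len),
                               config@speciesDivergence))
      emitHost(gseq, bseq)
    }
    for (j in seq_along(bi)) {
      emitGap(gaps[j])
      b <- blocks[[bi[j]]]
      if (b$type == "site") {
        p <- plan[[b$idx]]
        shared <- !is.na(p$ortholog_id)
        mkB <- function(seqA) {
          if (shared) mutateDNA(seqA, config@speciesDivergence)
          else randomDNA(nchar(seqA), gc)
        }
        msA <- aPos + c(b$ms$start, b$ms$end)
        repRows[[length(repRows) + 1L]] <- data.frame(
          scaffold = scafName, start = msA[1L], end = msA[2L],
          class = "microsatellite", motif = b$ms$motif,
          copies = b$ms$copies, element_id = NA_character_,
          stringsAsFactors = FALSE)
        emitHost(b$pre, mkB(b$pre))
        oriented <- if (p$strand == "-") revcomp(p$eve) else p$eve
        aStart <- aPos + 1L
        aParts[[length(aParts) + 1L]] <- oriented
        aPos <- aPos + nchar(oriented)
        insRows[[length(insRows) + 1L]] <- data.frame(
          scaffold = scafName, start = aStart, end = aPos,
          strand = p$strand, locus_id = p$locus_id, group = p$group,
          role = p$role, protein_id = p$protein_id, virus_id = p$virus_id,
          sub_rate = p$sub_rate, n_nonsense = p$n_nonsense,
          n_frameshift = p$n_frameshift, dup_group = p$dup_group,
          ortholog_id = p$ortholog_id, stringsAsFactors = FALSE)
        insRows[[length(insRows)]]$mutations <- I(list(p$record))
        if (!is.na(p$ortholog_id)) {
          if (isTRUE(p$present_in_b)) {
            bStart <- bPos + 1L
            bParts[[length(bParts) + 1L]] <-
              mutateDNA(oriented, config@speciesDivergence)
            bPos <- bPos + nchar(oriented)
            orthRows[[length(orthRows) + 1L]] <- data.frame(
              ortholog_id = p$ortholog_id, locus_id = p$locus_id,
              scaffold_b = scafName, start_b = bStart, end_b = bPos,
              present_in_b = TRUE, stringsAsFactors = FALSE)
          } else {
            orthRows[[length(orthRows) + 1L]] <- data.frame(
              ortholog_id = p$ortholog_id, locus_id = p$locus_id,
              scaffold_b = scafName, start_b = bPos, end_b = bPos,
              present_in_b = FALSE, stringsAsFactors = FALSE)
          }
        }
        privHead <- if (shared) 0L else 200L
        if (nzchar(b$post)) {
          if (!is.null(b$postElem)) {
            repRows[[length(repRows) + 1L]] <- data.frame(
              scaffold = scafName, start = aPos + b$postElem[1L],
              end = aPos + b$postElem[2L], class = "interspersed",
              motif = NA_character_, copies = config@interspersedCopies,
              element_id = "element_1", stringsAsFactors = FALSE)
          }
          emitHost(b$post, mkB(b$post))
        }
      } else if (b$type == "element") {
        repRows[[length(repRows) + 1L]] <- data.frame(
          scaffold = scafName, start = aPos + 1L,
          end = aPos + nchar(b$seq), class = "interspersed",
          motif = NA_character_, copies = config@interspersedCopies,
          element_id = "element_1", stringsAsFactors = FALSE)
        emitHost(b$seq, mutateDNA(b$seq, config@speciesDivergence))
      } else {
        repRows[[length(repRows) + 1L]] <- data.frame(
          scaffold = scafName, start = aPos + 1L,
          end = aPos + nchar(b$seq), class = "microsatellite",
          motif = b$motif, copies = b$copies, element_id = NA_character_,
          stringsAsFactors = FALSE)
        emitHost(b$seq, mutateDNA(b$seq, config@speciesDivergence))
      }
    }
    emitGap(gaps[length(gaps)])
    aSeqs[s] <- paste0(aParts, collapse = "")
    bSeqs[s] <- paste0(bParts, collapse = "")
  }
  names(aSeqs) <- names(bSeqs) <- sprintf("scaffold_%d", seq_len(ns))
  insDf <- do.call(rbind, insRows)
  lv <- names(aSeqs)
  insGr <- GRanges(factor(insDf$scaffold, levels = lv),
                   IRanges(insDf$start, insDf$end), strand = insDf$strand)
  mcols(insGr) <- DataFrame(
    insDf[, c("locus_id", "group", "role", "protein_id", "virus_id",
              "sub_rate", "n_nonsense", "n_frameshift", "dup_group",
              "ortholog_id")],
    mutations = I(insDf$mutations))
  repDf <- do.call(rbind, repRows)
  repGr <- GRanges(factor(repDf$scaffold, levels = lv),
                   IRanges(repDf$start, repDf$end))
  mcols(repGr) <- DataFrame(repDf[, c("class", "motif", "copies",
                                      "element_id")])
  dupGroups <- list()
  for (d in seq_len(config@nDuplicationGroups)) {
    gid <- sprintf("dup_%d", d)
    dupGroups[[gid]] <- insDf$locus_id[!is.na(insDf$dup_group) &
                                         insDf$dup_group == gid]
  }
  orthDf <- if (length(orthRows)) do.call(rbind, orthRows) else
    data.frame(ortholog_id = character(0), locus_id = character(0),
               scaffold_b = character(0), start_b = integer(0),
               end_b = integer(0), present_in_b = logical(0))
  orthDf <- orthDf[order(orthDf$ortholog_id), , drop = FALSE]
  rownames(orthDf) <- NULL
  truth <- new("SimTruth", insertions = insGr,
               duplicationGroups = dupGroups, orthologPairs = orthDf,
               repeats = repGr)
  list(genomeA = genomeAssembly(aSeqs, source = "speciesA"),
       genomeB = genomeAssembly(bSeqs, source = "speciesB"),
       truth = truth)
}

#' Write simulation outputs to disk
#'
#' Emits genome FASTAs for both species, the viral protein and genome FASTAs,
#' the truth tables as GFF3 (insertions and repeats, 1-based inclusive) and
#' TSV (duplication groups, ortholog pairs, degradation counts).
#'
#' @param sim Result of \code{\link{simulateGenomePair}}.
#' @param db The \linkS4class{ViralRefDB}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulationOutputs <- function(sim, db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(scaffolds(sim$genomeA),
                              file.path(dir, "genomeA.fasta"))
  Biostrings::writeXStringSet(scaffolds(sim$genomeB),
                              file.path(dir, "genomeB.fasta"))
  Biostrings::writeXStringSet(viralProteins(db),
                              file.path(dir, "viral_proteins.fasta"))
  Biostrings::writeXStringSet(viralGenomes(db),
                              file.path(dir, "viral_genomes.fasta"))
  ins <- trueInsertions(sim$truth)
  gr <- GRanges(seqnames(ins), IRanges(start(ins), end(ins)),
                strand = strand(ins))
  mcols(gr) <- DataFrame(type = "endogenous_viral_element",
                         ID = mcols(ins)$locus_id,
                         viral_group = mcols(ins)$group,
                         gene_role = mcols(ins)$role)
  rtracklayer::export(gr, file.path(dir, "truth_insertions.gff3"),
                      format = "gff3")
  rep <- trueRepeats(sim$truth)
  gr2 <- GRanges(seqnames(rep), IRanges(start(rep), end(rep)))
  mcols(gr2) <- DataFrame(type = mcols(rep)$class,
                          copies = mcols(rep)$copies)
  rtracklayer::export(gr2, file.path(dir, "truth_repeats.gff3"),
                      format = "gff3")
  dg <- trueDuplicationGroups(sim$truth)
  dupDf <- data.frame(
    dup_group = rep(names(dg), lengths(dg)),
    locus_id = unlist(dg, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(dupDf, file.path(dir, "truth_duplications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trueOrthologPairs(sim$truth),
                     file.path(dir, "truth_orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  degDf <- as.data.frame(mcols(ins)[, c("locus_id", "sub_rate", "n_nonsense",
                                        "n_frameshift")])
  utils::write.table(degDf, file.path(dir, "truth_degradation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
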