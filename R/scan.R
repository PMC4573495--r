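# EVE calling: translated scan of an assembly against viral proteins,
# reciprocal best-hit filtering, merging of hits into loci, classification.

.emptyHits <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             protein_id = character(0), group = character(0),
             role = character(0), score = numeric(0), evalue = numeric(0),
             pident = numeric(0), alen = integer(0),
             stringsAsFactors = FALSE)
}

#' Translated scan of a genome against a viral protein database
#'
#' Seeds exact amino-acid word matches between the six-frame translation of
#' each scaffold and the database proteins, extends each seed cluster with a
#' local alignment in a window of \code{extendWindow} aa around the seeds,
#' and reports hits with Karlin-Altschul E-value at or below the threshold.
#' Genomic coordinates are back-mapped from peptide coordinates per frame.
#' The genome is expected to be low-complexity masked first (see
#' \code{\link{maskAssembly}}); masked positions translate to X and cannot
#' seed.
#'
#' @param genome A \linkS4class{GenomeAssembly}.
#' @param db A \linkS4class{ViralRefDB} (non-empty).
#' @param params A \linkS4class{SearchParams}.
#' @return A data.frame of hits: scaffold, start, end (1-based inclusive),
#'   strand, frame, protein_id, group, role, score, evalue, pident, alen.
#' @export
translatedScan <- function(genome, db, params = searchParams()) {
  if (length(viralProteins(db)) == 0L) stop("empty viral database")
  prots <- as.character(viralProteins(db))
  info <- as.data.frame(proteinInfo(db))
  index <- aaSeedIndex(prots, params@seedLength)
  sc <- scaffolds(genome)
  # database length for E-values: total aa across the six-frame translation
  nTotal <- sum(vapply(1:3, function(k) {
    sum(pmax(0L, (Biostrings::width(sc) - k + 1L) %/% 3L))
  }, numeric(1))) * 2
  nTotal <- max(1, nTotal)
  out <- list()
  for (si in seq_along(sc)) {
    s <- as.character(sc[[si]])
    n <- nchar(s)
    if (n < 3L) next
    ft <- sixFrameTranslate(s)
    for (r in seq_len(6L)) {
      pep <- ft$peptide[r]
      frame <- ft$frame[r]
      if (nchar(pep) < params@seedLength) next
      seeds <- .seedHits(aaKmerCodes(pep, params@seedLength), index)
      if (!nrow(seeds)) next
      pepChars <- strsplit(pep, "", fixed = TRUE)[[1]]
      M <- eveSubstitutionMatrix(params@matrixName)
      for (cl in .clusterSeeds(seeds, maxGap = params@extendWindow)) {
        pi <- cl$target[1L]
        prot <- prots[pi]
        # cheap ungapped pre-filter for sparse seed clusters: best ungapped
        # diagonal segment through the seed must reach a modest score before
        # the full affine extension is attempted
        if (nrow(cl) <= 2L) {
          protChars <- strsplit(prot, "", fixed = TRUE)[[1]]
          q0 <- cl$qpos[1L]; s0 <- cl$tpos[1L]
          off <- (-params@extendWindow):(params@extendWindow +
                                           params@seedLength - 1L)
          qdi <- q0 + off; sdi <- s0 + off
          okd <- qdi >= 1L & qdi <= length(pepChars) &
            sdi >= 1L & sdi <= length(protChars)
          a <- pepChars[qdi[okd]]; b <- protChars[sdi[okd]]
          ok2 <- a %in% rownames(M) & b %in% rownames(M)
          v <- numeric(sum(okd)); v[ok2] <- M[cbind(a[ok2], b[ok2])]
          # Kadane's maximum-subarray
          bestSeg <- 0; cur <- 0
          for (x in v) { cur <- max(0, cur + x); bestSeg <- max(bestSeg, cur) }
          if (bestSeg < 35) next
        }
        qlo <- max(1L, min(cl$qpos) - params@extendWindow)
        qhi <- min(nchar(pep),
                   max(cl$qpos) + params@seedLength - 1L + params@extendWindow)
        slo <- max(1L, min(cl$tpos) - params@extendWindow)
        shi <- min(nchar(prot),
                   max(cl$tpos) + params@seedLength - 1L + params@extendWindow)
        al <- localAlign(substr(pep, qlo, qhi), substr(prot, slo, shi), params)
        if (al$alen == 0L) next
        ev <- estimateEvalue(al$score, nchar(prot), nTotal, params)
        if (ev > params@evalueMax) next
        pepStart <- qlo + al$qstart - 1L
        pepEnd <- qlo + al$qend - 1L
        g <- frameToGenomic(pepStart, pepEnd, frame, n)
        out[[length(out) + 1L]] <- data.frame(
          scaffold = names(sc)[si], start = g[1L], end = g[2L],
          strand = if (frame > 0) "+" else "-", frame = frame,
          protein_id = info$protein_id[pi], group = info$group[pi],
          role = info$role[pi], score = al$score, evalue = ev,
          pident = al$pident, alen = al$alen, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.emptyHits())
  hits <- do.call(rbind, out)
  # collapse duplicate extensions of the same homology (same protein, frame,
  # overlapping genomic span), keeping the best-scoring one
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i] || i == nrow(hits)) next
    j <- (i + 1L):nrow(hits)
    ov <- hits$scaffold[j] == hits$scaffold[i] &
      hits$protein_id[j] == hits$protein_id[i] &
      hits$frame[j] == hits$frame[i] &
      pmin(hits$end[j], hits$end[i]) >= pmax(hits$start[j], hits$start[i])
    keep[j][ov] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$scaffold, hits$start, hits$end, hits$protein_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reciprocal best-hit filtering against a host decoy set
#'
#' Each hit's translated genomic segment is re-aligned against the union of
#' the viral proteins and a host decoy protein set; the hit is retained only
#' if the single best-scoring match is a viral protein. Exact score ties
#' between the best viral and best decoy match are removed (conservative
#' elimination of ambiguous sequences).
#'
#' @param hits A hit data.frame from \code{\link{translatedScan}}.
#' @param genome The scanned \linkS4class{GenomeAssembly}.
#' @param db The \linkS4class{ViralRefDB} used for the scan.
#' @param decoys A non-empty \link[Biostrings]{AAStringSet} of host proteins.
#' @param params A \linkS4class{SearchParams}.
#' @return The retained subset of \code{hits} (possibly empty).
#' @export
reciprocalFilter <- function(hits, genome, db, decoys,
                             params = searchParams()) {
  if (length(decoys) == 0L) stop("decoy protein set must be non-empty")
  if (!nrow(hits)) return(hits)
  sc <- scaffolds(genome)
  vir <- viralProteins(db)
  m <- eveSubstitutionMatrix(params@matrixName)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    seg <- substr(as.character(sc[[hits$scaffold[i]]]),
                  hits$start[i], hits$end[i])
    if (hits$frame[i] < 0) seg <- revcomp(seg)
    pep <- translateNT(seg)
    if (!nzchar(pep)) next
    scoreAgainst <- function(set) {
      max(Biostrings::pairwiseAlignment(
        pattern = set, subject = Biostrings::AAString(pep), type = "local",
        substitutionMatrix = m, gapOpening = params@gapOpen,
        gapExtension = params@gapExtend, scoreOnly = TRUE))
    }
    keep[i] <- scoreAgainst(vir) > scoreAgainst(decoys)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge retained hits into EVE loci
#'
#' Hits on the same scaffold and strand whose genomic intervals lie within
#' \code{maxGap} bp of each other are merged into one locus whose interval is
#' the union hull. Merging is a transitive closure and is independent of the
#' input order.
#'
#' @param hits A hit data.frame (retained hits).
#' @param maxGap Maximum merge gap in bp (>= 0).
#' @return A list: \code{loci} (a \link[GenomicRanges]{GRanges} with
#'   \code{locus_id} and \code{n_hits}) and \code{hits} (the input with a
#'   \code{locus_id} column).
#' @export
mergeHitsToLoci <- function(hits, maxGap = 100L) {
  if (maxGap < 0) stop("maxGap must be non-negative")
  if (!nrow(hits)) {
    loci <- GRanges()
    mcols(loci)$locus_id <- character(0)
    mcols(loci)$n_hits <- integer(0)
    return(list(loci = loci, hits = cbind(hits, locus_id = character(0))))
  }
  lv <- sort(unique(hits$scaffold))
  gr <- GRanges(factor(hits$scaffold, levels = lv),
                IRanges(hits$start, hits$end), strand = hits$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = maxGap + 1L,
                               with.revmap = TRUE, ignore.strand = FALSE)
  o <- order(as.integer(seqnames(red)), start(red), end(red),
             as.integer(strand(red)))
  red <- red[o]
  ids <- sprintf("EVE_%02d", seq_along(red))
  locusOf <- character(nrow(hits))
  for (i in seq_along(red)) locusOf[mcols(red)$revmap[[i]]] <- ids[i]
  loci <- GRanges(seqnames(red), IRanges(start(red), end(red)),
                  strand = strand(red))
  mcols(loci)$locus_id <- ids
  mcols(loci)$n_hits <- lengths(mcols(red)$revmap)
  hits$locus_id <- locusOf
  list(loci = loci, hits = hits)
}

#' Classify loci by viral group and gene role
#'
#' Each locus inherits the viral group and gene role of its component hit
#' with the lowest E-value (ties broken by highest raw score, then by
#' lexicographically smallest protein id).
#'
#' @param loci GRanges of loci from \code{\link{mergeHitsToLoci}}.
#' @param hits Hit data.frame carrying \code{locus_id}.
#' @param db Optional \linkS4class{ViralRefDB} (annotation already travels
#'   with the hits; accepted for interface completeness).
#' @return \code{loci} with added metadata columns \code{group}, \code{role},
#'   \code{best_protein}, \code{best_evalue}, \code{best_score},
#'   \code{best_pident}, \code{alen}.
#' @export
classifyViralGroup <- function(loci, hits, db = NULL) {
  n <- length(loci)
  grp <- role <- bp <- character(n)
  bev <- bsc <- bpi <- bal <- numeric(n)
  for (i in seq_len(n)) {
    hh <- hits[hits$locus_id == mcols(loci)$locus_id[i], , drop = FALSE]
    stopifnot(nrow(hh) >= 1L)
    hh <- hh[order(hh$evalue, -hh$score, hh$protein_id), , drop = FALSE]
    grp[i] <- hh$group[1L]; role[i] <- hh$role[1L]; bp[i] <- hh$protein_id[1L]
    bev[i] <- hh$evalue[1L]; bsc[i] <- hh$score[1L]
    bpi[i] <- hh$pident[1L]; bal[i] <- hh$alen[1L]
  }
  mcols(loci)$group <- grp
  mcols(loci)$role <- role
  mcols(loci)$best_protein <- bp
  mcols(loci)$best_evalue <- bev
  mcols(loci)$best_score <- bsc
  mcols(loci)$best_pident <- bpi
  mcols(loci)$alen <- bal
  loci
}
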