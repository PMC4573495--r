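# Flank validation: extraction of EVE flanking regions, host-origin evidence
# (microsatellites, interspersed repeats), and shared-flank duplication
# inference.

#' Extract EVE flanking regions
#'
#' Takes the \code{minFlankLen} bp adjacent to each side of every locus. A
#' flank is only emitted when the full minimum length is available on that
#' side (a locus too close to a scaffold end yields one flank or none). Each
#' flank is re-scanned against the viral database: any hit at the configured
#' E-value threshold marks it as not viral-similarity-free.
#'
#' @param loci GRanges of classified loci.
#' @param genome The (unmasked) \linkS4class{GenomeAssembly}.
#' @param db A \linkS4class{ViralRefDB}.
#' @param params A \linkS4class{FlankParams}.
#' @param searchParams A \linkS4class{SearchParams} for the viral re-scan.
#' @return A data.frame with one row per flank: \code{locus_id}, \code{side}
#'   (upstream/downstream), \code{start}, \code{end}, \code{seq},
#'   \code{length}, \code{virus_free}.
#' @export
extractFlanks <- function(loci, genome, db, params = flankParams(),
                          searchParams = paleovirome::searchParams()) {
  sc <- scaffolds(genome)
  L <- params@minFlankLen
  rows <- list()
  for (i in seq_along(loci)) {
    scaf <- as.character(seqnames(loci)[i])
    n <- nchar(as.character(sc[[scaf]]))
    st <- start(loci)[i]; en <- end(loci)[i]
    if (st - 1L >= L) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = mcols(loci)$locus_id[i], side = "upstream",
        start = st - L, end = st - 1L,
        seq = substr(as.character(sc[[scaf]]), st - L, st - 1L),
        scaffold = scaf, stringsAsFactors = FALSE)
    }
    if (n - en >= L) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = mcols(loci)$locus_id[i], side = "downstream",
        start = en + 1L, end = en + L,
        seq = substr(as.character(sc[[scaf]]), en + 1L, en + L),
        scaffold = scaf, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(locus_id = character(0), side = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0), scaffold = character(0),
                      length = integer(0), virus_free = logical(0)))
  }
  fl <- do.call(rbind, rows)
  fl$length <- nchar(fl$seq)
  # one combined viral re-scan over all flanks
  flankNames <- sprintf("flank_%03d", seq_len(nrow(fl)))
  mini <- genomeAssembly(stats::setNames(fl$seq, flankNames),
                         source = "flanks")
  hits <- translatedScan(mini, db, searchParams)
  fl$virus_free <- !(flankNames %in% hits$scaffold)
  rownames(fl) <- NULL
  fl
}

# canonical (lexicographically smallest) rotation of a motif
.canonicalRotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rot <- vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L))
  }, character(1))
  min(rot)
}

# TRUE if the motif is primitive (has no period dividing its length)
.isPrimitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  x <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && all(x == x[(seq_len(k) - 1L) %% p + 1L])) return(FALSE)
  }
  TRUE
}

#' Detect microsatellites (exact tandem arrays)
#'
#' Reports all maximal exact tandem arrays of primitive motifs of 1 to
#' \code{microsatMaxUnit} bp whose full copy number reaches
#' \code{microsatMinCopies}. Motifs are reported in canonical rotation;
#' nested reports are suppressed (an (AC)n array is not also reported as
#' (ACAC)n/2 because non-primitive motifs are skipped).
#'
#' @param seq Nucleotide string.
#' @param params A \linkS4class{FlankParams}.
#' @return A data.frame: \code{motif}, \code{unit_len}, \code{copies},
#'   \code{start}, \code{end} (the full maximal array, including any partial
#'   trailing copy).
#' @examples
#' detectMicrosatellites(paste0("GTTACG", strrep("AC", 6), "TGCATG"))
#' @export
detectMicrosatellites <- function(seq, params = flankParams()) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  out <- list()
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  for (k in seq_len(min(params@microsatMaxUnit, max(0L, n - 1L)))) {
    if (n < 2L * k) next
    eq <- x[seq_len(n - k)] == x[seq_len(n - k) + k]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (ri in seq_along(r$lengths)) {
      if (!r$values[ri]) next
      i <- pos[ri]
      m <- r$lengths[ri]
      total <- m + k          # length of the maximal period-k run
      copies <- total %/% k
      if (copies < params@microsatMinCopies) next
      motif <- substr(s, i, i + k - 1L)
      if (!.isPrimitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = .canonicalRotation(motif), unit_len = k, copies = copies,
        start = i, end = i + total - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect interspersed repeats in a flank by genome-wide self-comparison
#'
#' Counts genome-wide occurrences of flank segments via nucleotide local
#' alignment (at least \code{ntMinIdentity} identity over at least
#' \code{interspersedMinLen} bp) and reports segments whose occurrence count
#' reaches \code{interspersedMinCopies}. The flank's own genomic copy counts
#' as one occurrence.
#'
#' @param flankSeq The flank nucleotide string.
#' @param genome The \linkS4class{GenomeAssembly} to search.
#' @param params A \linkS4class{FlankParams}.
#' @param index Optional precomputed \code{ntSeedIndex(genome)} (built on the
#'   fly when NULL).
#' @return A data.frame: \code{start}, \code{end} (flank coordinates of the
#'   repeated segment), \code{element_len}, \code{copies}.
#' @export
detectInterspersedRepeats <- function(flankSeq, genome,
                                      params = flankParams(), index = NULL) {
  if (is.null(index)) index <- ntSeedIndex(genome)
  hits <- ntLocalHits(flankSeq, index, genome,
                      minLen = params@interspersedMinLen,
                      minIdent = params@ntMinIdentity)
  empty <- data.frame(start = integer(0), end = integer(0),
                      element_len = integer(0), copies = integer(0))
  if (!nrow(hits)) return(empty)
  # merge the flank-side intervals of all hits into candidate segments
  qr <- IRanges::reduce(IRanges(hits$qstart, hits$qend))
  out <- list()
  for (i in seq_along(qr)) {
    if (IRanges::width(qr)[i] < params@interspersedMinLen) next
    ov <- pmin(hits$qend, end(qr)[i]) - pmax(hits$qstart, start(qr)[i]) + 1L
    sup <- hits[ov >= params@interspersedMinLen, , drop = FALSE]
    # count distinct genomic locations
    lv <- unique(sup$scaffold)
    cnt <- 0L
    for (sc2 in lv) {
      gg <- sup[sup$scaffold == sc2, , drop = FALSE]
      cnt <- cnt + length(IRanges::reduce(IRanges(gg$start, gg$end)))
    }
    if (cnt >= params@interspersedMinCopies) {
      out[[length(out) + 1L]] <- data.frame(
        start = start(qr)[i], end = end(qr)[i],
        element_len = IRanges::width(qr)[i], copies = cnt)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Assemble flank reports with host-origin verdicts
#'
#' Runs microsatellite and interspersed-repeat detection on every flank and
#' issues the host-origin verdict: a flank certifies host origin when it is
#' viral-similarity-free AND carries either a microsatellite with at least
#' \code{microsatMinCopies} copies or an interspersed repeat of at least
#' \code{interspersedMinLen} bp with at least \code{interspersedMinCopies}
#' genome-wide copies.
#'
#' @param flanks Flank data.frame from \code{\link{extractFlanks}}.
#' @param genome The \linkS4class{GenomeAssembly}.
#' @param params A \linkS4class{FlankParams}.
#' @return \code{flanks} with added list-columns \code{microsatellites} and
#'   \code{interspersed}, plus logical \code{host_origin}.
#' @export
flankReports <- function(flanks, genome, params = flankParams()) {
  if (!nrow(flanks)) {
    flanks$microsatellites <- list()
    flanks$interspersed <- list()
    flanks$host_origin <- logical(0)
    return(flanks)
  }
  index <- ntSeedIndex(genome)
  ms <- vector("list", nrow(flanks))
  ir <- vector("list", nrow(flanks))
  verdict <- logical(nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    ms[[i]] <- detectMicrosatellites(flanks$seq[i], params)
    ir[[i]] <- detectInterspersedRepeats(flanks$seq[i], genome, params, index)
    verdict[i] <- isTRUE(flanks$virus_free[i]) &&
      (nrow(ms[[i]]) > 0L || nrow(ir[[i]]) > 0L)
  }
  flanks$microsatellites <- I(ms)
  flanks$interspersed <- I(ir)
  flanks$host_origin <- verdict
  flanks
}

#' Infer post-insertional duplications from shared flanks
#'
#' Loci whose flanks align at \code{sharedIdentity} identity or higher over
#' at least \code{sharedMinOverlap} bp are clustered by single linkage; each
#' group of size k contributes k - 1 duplication events (the minimum number
#' of duplication acts).
#'
#' @param flanks Flank data.frame (from \code{\link{extractFlanks}} or
#'   \code{\link{flankReports}}).
#' @param params A \linkS4class{FlankParams}.
#' @return A list: \code{groups} (list of locus-id character vectors, size
#'   >= 2) and \code{events} (total duplication event count).
#' @export
detectSharedFlankDuplications <- function(flanks, params = flankParams()) {
  ids <- unique(flanks$locus_id)
  if (length(ids) < 2L) return(list(groups = list(), events = 0L))
  parent <- seq_along(ids)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mat <- ntSubstitutionMatrix()
  for (a in seq_len(length(ids) - 1L)) {
    for (b in (a + 1L):length(ids)) {
      fa <- flanks[flanks$locus_id == ids[a], , drop = FALSE]
      fb <- flanks[flanks$locus_id == ids[b], , drop = FALSE]
      linked <- FALSE
      for (x in seq_len(nrow(fa))) {
        for (y in seq_len(nrow(fb))) {
          al <- Biostrings::pairwiseAlignment(
            pattern = Biostrings::DNAString(fa$seq[x]),
            subject = Biostrings::DNAString(fb$seq[y]), type = "local",
            substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
          alen <- nchar(as.character(al@pattern))
          if (alen >= params@sharedMinOverlap &&
              Biostrings::pid(al) >= params@sharedIdentity * 100) {
            linked <- TRUE
            break
          }
        }
        if (linked) break
      }
      if (linked) {
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(ids), findRoot, integer(1))
  groups <- split(ids, roots)
  groups <- unname(groups[lengths(groups) >= 2L])
  groups <- lapply(groups, sort)
  if (length(groups)) {
    groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  }
  list(groups = groups,
       events = sum(vapply(groups, length, integer(1)) - 1L))
}
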