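# Foundational sequence operations: six-frame translation, low-complexity
# masking, protein local alignment, Karlin-Altschul E-values.

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames: +1..+3 from the
#' given strand, -1..-3 from the reverse complement. Stop codons are rendered
#' as \code{*}; codons containing non-ACGT letters as \code{X}. Peptide
#' lengths obey \code{floor((n - offset) / 3)}.
#'
#' @param nt A \link[Biostrings]{DNAString} or character scalar.
#' @return A data.frame with columns \code{frame} (one of +1,+2,+3,-1,-2,-3)
#'   and \code{peptide}. Inputs shorter than 3 nt yield six empty peptides
#'   with a warning.
#' @examples
#' sixFrameTranslate("ATGAAA")
#' @export
sixFrameTranslate <- function(nt) {
  s <- toupper(as.character(nt))
  n <- nchar(s)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  if (n < 3L) {
    warning("sequence shorter than 3 nt: all frames empty")
    return(data.frame(frame = frames, peptide = rep("", 6L),
                      stringsAsFactors = FALSE))
  }
  rc <- revcomp(s)
  pep <- character(6L)
  for (k in 1:3) {
    pep[k] <- translateNT(substr(s, k, n))
    pep[k + 3L] <- translateNT(substr(rc, k, n))
  }
  data.frame(frame = frames, peptide = pep, stringsAsFactors = FALSE)
}

#' Map a peptide interval in a frame back to genomic coordinates
#'
#' @param pepStart,pepEnd 1-based peptide coordinates (inclusive).
#' @param frame Frame in {+1,+2,+3,-1,-2,-3}.
#' @param n Scaffold length (bp).
#' @return c(start, end) 1-based inclusive genomic coordinates.
#' @keywords internal
frameToGenomic <- function(pepStart, pepEnd, frame, n) {
  k <- abs(frame)
  ntStart <- k + 3L * (pepStart - 1L)
  ntEnd <- k + 3L * pepEnd - 1L
  if (frame > 0) c(ntStart, ntEnd) else c(n - ntEnd + 1L, n - ntStart + 1L)
}

# Sliding-window trinucleotide Shannon entropy (bits) over valid (non-N)
# trinucleotides. Returns NA when too few valid trinucleotides to judge.
.windowEntropy <- function(triCodes, from, to) {
  v <- triCodes[from:min(to, length(triCodes))]
  v <- v[!is.na(v)]
  wlen <- to - from + 1L
  if (length(v) < max(1L, (wlen) %/% 2L)) return(NA_real_)
  p <- tabulate(v, nbins = 64L)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' Mask low-complexity sequence
#'
#' Replaces windows whose trinucleotide Shannon entropy falls below a
#' threshold with N, over the merged union of offending windows. Windows of
#' \code{maskWindow} nt slide at half-window steps; length is preserved.
#' Windows dominated by already-masked (N) positions are left untouched,
#' which makes the operation idempotent.
#'
#' @param nt A \link[Biostrings]{DNAString} or character scalar.
#' @param params A \linkS4class{SearchParams}.
#' @return A list with \code{masked} (character), \code{intervals}
#'   (\link[IRanges]{IRanges} of masked regions).
#' @examples
#' maskLowComplexity(strrep("A", 60), searchParams())$intervals
#' @export
maskLowComplexity <- function(nt, params = searchParams()) {
  s <- toupper(as.character(nt))
  n <- nchar(s)
  if (n == 0L) return(list(masked = s, intervals = IRanges()))
  w <- min(params@maskWindow, n)
  if (n < 5L) return(list(masked = s, intervals = IRanges()))
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(x, DNA_BASES4) - 1L          # NA for N
  m <- n - 2L
  tri <- code[seq_len(m)] * 16L + code[seq_len(m) + 1L] * 4L +
    code[seq_len(m) + 2L] + 1L               # 1..64, NA if any N
  starts <- unique(c(seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L)),
                     n - w + 1L))
  bad <- logical(n)
  for (st in starts) {
    en <- st + w - 1L
    h <- .windowEntropy(tri, st, en - 2L)
    if (!is.na(h) && h < params@maskEntropy) bad[st:en] <- TRUE
  }
  if (!any(bad)) return(list(masked = s, intervals = IRanges()))
  x[bad] <- "N"
  r <- IRanges(bad)
  list(masked = paste0(x, collapse = ""), intervals = r)
}

#' Mask all scaffolds of an assembly
#'
#' @param genome A \linkS4class{GenomeAssembly}.
#' @param params A \linkS4class{SearchParams}.
#' @return A \linkS4class{GenomeAssembly} with low-complexity regions N-masked.
#' @export
maskAssembly <- function(genome, params = searchParams()) {
  sc <- scaffolds(genome)
  out <- vapply(seq_along(sc), function(i) {
    maskLowComplexity(as.character(sc[[i]]), params)$masked
  }, character(1))
  names(out) <- names(sc)
  genomeAssembly(out, source = sourceLabel(genome))
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman local alignment with affine gaps under the configured
#' substitution matrix (stop sentinels score as strong mismatches; see
#' \code{\link{eveSubstitutionMatrix}}). A gap of length L costs
#' \code{gapOpen + L * gapExtend}.
#'
#' @param a,b Peptide strings (non-empty).
#' @param params A \linkS4class{SearchParams}.
#' @return A one-row data.frame: \code{score}, \code{pident},
#'   \code{qstart}, \code{qend}, \code{sstart}, \code{send} (1-based
#'   inclusive), \code{alen} (alignment columns).
#' @examples
#' localAlign("HEAGAWGHEE", "PAWHEAE",
#'            searchParams(matrixName = "BLOSUM50", gapOpen = 1e-4,
#'                         gapExtend = 8))
#' @export
localAlign <- function(a, b, params = searchParams()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("localAlign requires non-empty peptides")
  m <- eveSubstitutionMatrix(params@matrixName)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "local", substitutionMatrix = m,
    gapOpening = params@gapOpen, gapExtension = params@gapExtend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(data.frame(score = max(0, sc), pident = 0, qstart = NA_integer_,
                      qend = NA_integer_, sstart = NA_integer_,
                      send = NA_integer_, alen = 0L))
  }
  pr <- al@pattern@range
  sr <- al@subject@range
  data.frame(score = sc, pident = Biostrings::pid(al),
             qstart = BiocGenerics::start(pr), qend = BiocGenerics::end(pr),
             sstart = BiocGenerics::start(sr), send = BiocGenerics::end(sr),
             alen = nchar(as.character(al@pattern)))
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}} for a raw local-alignment score S, query
#' length m (aa) and database length n (aa).
#'
#' @param score Raw alignment score.
#' @param m Query length in residues (>= 1).
#' @param n Database length in residues (>= 1).
#' @param params A \linkS4class{SearchParams} providing K and lambda.
#' @return The expected number of chance hits at or above \code{score}.
#' @examples
#' estimateEvalue(50, 200, 100000, searchParams())
#' @export
estimateEvalue <- function(score, m, n, params = searchParams()) {
  if (any(m < 1) || any(n < 1)) stop("sequence lengths must be >= 1")
  params@K * m * n * exp(-params@lambda * score)
}
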