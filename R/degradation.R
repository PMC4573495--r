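# Degradation profiling: frameshift-aware alignment of an EVE locus to its
# best viral reference protein, and classification of the degradation state.

#' Frameshift-aware alignment of a nucleotide fragment to a protein
#'
#' Aligns a coding-derived nucleotide sequence to a reference protein by
#' three-frame dynamic programming. Reference residues are normally consumed
#' together with 3-nt codons; consuming 2 or 4 nt instead incurs the
#' frameshift penalty and counts one frameshift event. Stops are counted on
#' regular (3-nt) aligned codons translating to \code{*}; a stop falling
#' beyond the reference C-terminus aligns to a reference gap and is not
#' counted (so the terminal stop of a complete ORF never counts).
#'
#' @param nt Nucleotide string (the locus, already oriented 5'->3' on the
#'   coding strand).
#' @param protein Reference peptide string.
#' @param params A \linkS4class{SearchParams} (matrix, frameshift penalty).
#' @return A list: \code{score}, \code{n_nonsense}, \code{n_frameshift},
#'   \code{aligned_codons}, \code{matches}, \code{pident}, \code{path}.
#' @export
frameshiftAlign <- function(nt, protein, params = searchParams()) {
  s <- toupper(as.character(nt))
  p <- toupper(as.character(protein))
  n <- nchar(s)
  m <- nchar(p)
  if (n < 3L || m < 1L) stop("need at least one codon and one residue")
  M <- eveSubstitutionMatrix(params@matrixName)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  # amino acid of the codon ending at nucleotide i (i >= 3)
  codAA <- rep("X", n)
  gcmap <- Biostrings::GENETIC_CODE
  for (i in 3:n) {
    cod <- paste0(x[(i - 2L):i], collapse = "")
    aa <- gcmap[cod]
    codAA[i] <- ifelse(is.na(aa), "X", aa)
  }
  refAA <- strsplit(p, "", fixed = TRUE)[[1]]
  refAA[!refAA %in% rownames(M)] <- "X"
  codKey <- codAA
  codKey[!codKey %in% rownames(M)] <- "X"
  S <- M[codKey, refAA, drop = FALSE]
  res <- frameshiftAlignC(S, params@frameshiftPenalty, 10, 10)
  path <- res$path
  consume <- path[, "move"] %in% c(1L, 2L, 3L)
  alignedCodons <- sum(consume)
  aaAtPath <- codAA[path[, "i"]]
  nNonsense <- sum(path[, "move"] == 1L & aaAtPath == "*")
  nFrameshift <- sum(path[, "move"] %in% c(2L, 3L))
  matches <- sum(consume & aaAtPath == refAA[path[, "j"]])
  list(score = res$score, n_nonsense = as.integer(nNonsense),
       n_frameshift = as.integer(nFrameshift),
       aligned_codons = as.integer(alignedCodons),
       matches = as.integer(matches),
       pident = if (alignedCodons > 0) 100 * matches / alignedCodons else 0,
       path = path)
}

#' Classify a degradation profile
#'
#' \code{intact} when both counts are zero, \code{heavily_degraded} when the
#' nonsense count exceeds 10, \code{disrupted} otherwise.
#'
#' @param nNonsense,nFrameshift Non-negative counts (vectorised).
#' @return Character vector of classes.
#' @examples
#' classifyDegradation(c(0, 10, 11), c(0, 0, 0))
#' @export
classifyDegradation <- function(nNonsense, nFrameshift) {
  if (any(nNonsense < 0) || any(nFrameshift < 0)) stop("counts must be >= 0")
  ifelse(nNonsense == 0 & nFrameshift == 0, "intact",
         ifelse(nNonsense > 10, "heavily_degraded", "disrupted"))
}

#' Profile the degradation of classified loci
#'
#' For each locus, extracts the genomic sequence (reverse-complemented for
#' minus-strand loci), aligns it to the best reference protein with
#' \code{\link{frameshiftAlign}}, and reports nonsense/frameshift counts,
#' amino-acid identity and the degradation class. Profiles with fewer than
#' 10 aligned codons are flagged low-confidence.
#'
#' @param loci Classified loci (GRanges with \code{best_protein}).
#' @param genome The \linkS4class{GenomeAssembly}.
#' @param db The \linkS4class{ViralRefDB}.
#' @param params A \linkS4class{SearchParams}.
#' @return A data.frame: \code{locus_id}, \code{protein_id},
#'   \code{n_nonsense}, \code{n_frameshift}, \code{pident_aa}, \code{class},
#'   \code{low_confidence}.
#' @export
profileDegradation <- function(loci, genome, db, params = searchParams()) {
  sc <- scaffolds(genome)
  prots <- viralProteins(db)
  rows <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    scaf <- as.character(seqnames(loci)[i])
    seg <- substr(as.character(sc[[scaf]]), start(loci)[i], end(loci)[i])
    if (as.character(strand(loci)[i]) == "-") seg <- revcomp(seg)
    pid <- mcols(loci)$best_protein[i]
    fa <- frameshiftAlign(seg, as.character(prots[[pid]]), params)
    rows[[i]] <- data.frame(
      locus_id = mcols(loci)$locus_id[i], protein_id = pid,
      n_nonsense = fa$n_nonsense, n_frameshift = fa$n_frameshift,
      pident_aa = fa$pident,
      class = classifyDegradation(fa$n_nonsense, fa$n_frameshift),
      low_confidence = fa$aligned_codons < 10L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
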