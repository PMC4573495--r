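# Orthologous-locus detection between two assemblies via flank matching, and
# divergence-based dating of endogenization events.

#' Find orthologous EVE loci in a second assembly
#'
#' Each locus flank that passed host-origin validation is searched against
#' genome B by nucleotide local alignment. A pair is called when at least one
#' flank matches uniquely (best local score at least
#' \code{orthologUniqueRatio} times the second best). The EVE is flagged
#' present in B when the region adjacent to the matched flank itself yields a
#' translated viral hit of the same viral group as the locus; otherwise the
#' pair records the empty pre-insertion site.
#'
#' @param loci Classified loci of species A (GRanges).
#' @param flanks Flank report data.frame (\code{\link{flankReports}});
#'   only flanks with \code{host_origin = TRUE} are used as queries.
#' @param genomeB The second species' \linkS4class{GenomeAssembly}.
#' @param db The \linkS4class{ViralRefDB}.
#' @param params A \linkS4class{FlankParams}.
#' @param searchParams A \linkS4class{SearchParams} for the presence check.
#' @return A data.frame: \code{locus_id}, \code{scaffold_b}, \code{start_b},
#'   \code{end_b}, \code{present_in_b}, \code{flank_identity},
#'   \code{support_len}.
#' @export
findOrthologousLoci <- function(loci, flanks, genomeB, db,
                                params = flankParams(),
                                searchParams = paleovirome::searchParams()) {
  empty <- data.frame(locus_id = character(0), scaffold_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      present_in_b = logical(0), flank_identity = numeric(0),
                      support_len = integer(0), stringsAsFactors = FALSE)
  use <- flanks[flanks$host_origin %in% TRUE, , drop = FALSE]
  if (!nrow(use)) return(empty)
  index <- ntSeedIndex(genomeB)
  scB <- scaffolds(genomeB)
  out <- list()
  for (id in unique(use$locus_id)) {
    li <- which(mcols(loci)$locus_id == id)
    if (!length(li)) next
    lwidth <- width(loci)[li]
    ff <- use[use$locus_id == id, , drop = FALSE]
    called <- FALSE
    for (x in seq_len(nrow(ff))) {
      hits <- ntLocalHits(ff$seq[x], index, genomeB,
                          minLen = min(params@sharedMinOverlap,
                                       nchar(ff$seq[x])),
                          minIdent = params@ntMinIdentity)
      if (!nrow(hits)) next
      hits <- hits[order(-hits$score), , drop = FALSE]
      if (nrow(hits) > 1L &&
          hits$score[1L] < params@orthologUniqueRatio * hits$score[2L]) next
      h <- hits[1L, ]
      n <- nchar(as.character(scB[[h$scaffold]]))
      if (ff$side[x] == "upstream") {
        winStart <- h$end + 1L
        winEnd <- min(n, h$end + lwidth + 200L)
        siteB <- h$end
      } else {
        winStart <- max(1L, h$start - lwidth - 200L)
        winEnd <- h$start - 1L
        siteB <- max(1L, h$start - 1L)
      }
      present <- FALSE
      bStart <- bEnd <- siteB
      if (winEnd - winStart + 1L >= 30L) {
        win <- substr(as.character(scB[[h$scaffold]]), winStart, winEnd)
        mini <- genomeAssembly(c(window = win), source = "orthology-window")
        vh <- translatedScan(mini, db, searchParams)
        vh <- vh[vh$group == mcols(loci)$group[li], , drop = FALSE]
        if (nrow(vh)) {
          present <- TRUE
          bStart <- winStart + min(vh$start) - 1L
          bEnd <- winStart + max(vh$end) - 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        locus_id = id, scaffold_b = h$scaffold, start_b = bStart,
        end_b = bEnd, present_in_b = present,
        flank_identity = h$pident / 100, support_len = h$alen,
        stringsAsFactors = FALSE)
      called <- TRUE
      break
    }
    if (!called) next
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Date an endogenization event from marker divergence
#'
#' Converts a pairwise marker divergence (percent) and a substitution rate
#' (percent per million years) into a minimum age: age = divergence / rate.
#' With the mitochondrial COI marker diverging 16 % between the two most
#' distant host relatives and a crustacean COI rate of 1.4 % per million
#' years, insertions shared by both species date back at least ~11.4 Myr.
#'
#' @param divergencePct Marker divergence, percent (>= 0).
#' @param ratePctPerMyr Substitution rate, percent per million years (> 0).
#' @return Age in million years.
#' @examples
#' dateEndogenization(16, 1.4)
#' @export
dateEndogenization <- function(divergencePct, ratePctPerMyr) {
  if (any(ratePctPerMyr <= 0)) stop("substitution rate must be > 0")
  if (any(divergencePct < 0)) stop("divergence must be >= 0")
  divergencePct / ratePctPerMyr
}
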