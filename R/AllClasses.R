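#' @importFrom methods new validObject setClass setGeneric setMethod is slot
#' @importFrom methods slotNames show
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet AAStringSet width
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges IRanges
NULL

setOldClass("phylo")

# ---------------------------------------------------------------------------
# GenomeAssembly

#' Multi-scaffold genome assembly
#'
#' A light container for a set of named nucleotide scaffolds (alphabet
#' A, C, G, T, N) together with a source label, as produced by the simulator
#' or read from a FASTA file.
#'
#' @slot scaffolds A \link[Biostrings]{DNAStringSet} with unique, non-empty
#'   names and non-empty sequences.
#' @slot source A single character label for provenance.
#' @export
setClass("GenomeAssembly",
  representation(scaffolds = "DNAStringSet", source = "character"))

setValidity("GenomeAssembly", function(object) {
  sc <- object@scaffolds
  msg <- character()
  if (length(sc) == 0L) msg <- c(msg, "assembly has no scaffolds")
  nm <- names(sc)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "scaffold names must be unique and non-empty")
  if (length(sc) && any(Biostrings::width(sc) == 0L))
    msg <- c(msg, "scaffold sequences must be non-empty")
  if (length(sc)) {
    freq <- Biostrings::alphabetFrequency(sc, collapse = TRUE)
    bad <- sum(freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))])
    if (bad > 0) msg <- c(msg, "alphabet restricted to A,C,G,T,N")
  }
  if (length(object@source) != 1L) msg <- c(msg, "source must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param scaffolds A named \link[Biostrings]{DNAStringSet} or named character
#'   vector of scaffold sequences.
#' @param source Source label.
#' @return A \linkS4class{GenomeAssembly}.
#' @examples
#' genomeAssembly(c(scf1 = "ACGTACGTAC"), source = "toy")
#' @export
genomeAssembly <- function(scaffolds, source = "unknown") {
  if (is.character(scaffolds) && any(grepl("[^ACGTN]", scaffolds)))
    stop("scaffolds must use the A/C/G/T/N alphabet")
  if (!is(scaffolds, "DNAStringSet")) scaffolds <- DNAStringSet(scaffolds)
  new("GenomeAssembly", scaffolds = scaffolds, source = source)
}

#' @describeIn genomeAssembly Number of scaffolds.
#' @param x A GenomeAssembly.
#' @export
setMethod("length", "GenomeAssembly", function(x) length(x@scaffolds))

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly:", object@source, "\n")
  cat(" ", length(object@scaffolds), "scaffold(s),",
      sum(Biostrings::width(object@scaffolds)), "bp total\n")
})

#' Scaffold sequences of an assembly
#' @param x A \linkS4class{GenomeAssembly}.
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
scaffolds <- function(x) x@scaffolds

#' Source label of an assembly
#' @param x A \linkS4class{GenomeAssembly}.
#' @return Character scalar.
#' @export
sourceLabel <- function(x) x@source

# ---------------------------------------------------------------------------
# ViralRefDB

#' Viral reference database
#'
#' Synthetic viral proteins plus their source genomes, annotated with viral
#' group and gene role. Every protein cross-references exactly one ORF on one
#' genome via \code{proteinInfo}.
#'
#' @slot proteins \link[Biostrings]{AAStringSet} of viral proteins.
#' @slot genomes \link[Biostrings]{DNAStringSet} of viral genomes.
#' @slot proteinInfo \link[S4Vectors]{DataFrame} with one row per protein:
#'   \code{protein_id}, \code{group}, \code{role}, \code{genome_id},
#'   \code{orf_start}, \code{orf_end} (1-based inclusive, stop codon included).
#' @export
setClass("ViralRefDB",
  representation(proteins = "AAStringSet", genomes = "DNAStringSet",
                 proteinInfo = "DataFrame"))

VIRAL_GROUPS <- c("Bunyaviridae", "Circoviridae", "Mononegavirales",
                  "Parvoviridae", "Totiviridae")

setValidity("ViralRefDB", function(object) {
  info <- object@proteinInfo
  msg <- character()
  need <- c("protein_id", "group", "role", "genome_id", "orf_start", "orf_end")
  if (!all(need %in% colnames(info)))
    return(paste("proteinInfo must have columns:", paste(need, collapse = ", ")))
  if (nrow(info) != length(object@proteins))
    msg <- c(msg, "one proteinInfo row per protein required")
  if (!all(info$protein_id == names(object@proteins)))
    msg <- c(msg, "protein ids must match protein names, in order")
  if (!all(info$group %in% VIRAL_GROUPS))
    msg <- c(msg, "groups must come from the closed viral-group vocabulary")
  if (!all(info$genome_id %in% names(object@genomes)))
    msg <- c(msg, "every protein must map to a bundled genome")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ViralRefDB", function(object) {
  cat("ViralRefDB:", length(object@proteins), "proteins from",
      length(object@genomes), "genomes\n")
  print(table(object@proteinInfo$group))
})

#' Proteins of a viral reference database
#' @param db A \linkS4class{ViralRefDB}.
#' @return An \link[Biostrings]{AAStringSet}.
#' @export
viralProteins <- function(db) db@proteins

#' Genomes of a viral reference database
#' @param db A \linkS4class{ViralRefDB}.
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
viralGenomes <- function(db) db@genomes

#' Per-protein annotation of a viral reference database
#' @param db A \linkS4class{ViralRefDB}.
#' @return A \link[S4Vectors]{DataFrame}.
#' @export
proteinInfo <- function(db) db@proteinInfo

# ---------------------------------------------------------------------------
# SimTruth

#' Ground truth of a simulated genome pair
#'
#' The simulator's ledger: where every viral fragment was inserted, how it was
#' degraded, which loci are post-insertional duplicates, which loci have
#' orthologous sites in the second species, and where host repeats were
#' planted.
#'
#' @slot insertions \link[GenomicRanges]{GRanges} on genome A with metadata
#'   columns \code{locus_id}, \code{group}, \code{role}, \code{protein_id},
#'   \code{virus_id}, \code{sub_rate}, \code{n_nonsense}, \code{n_frameshift},
#'   \code{dup_group}, \code{ortholog_id}, \code{mutations} (list).
#' @slot duplicationGroups list of character vectors of locus ids (size >= 2).
#' @slot orthologPairs data.frame with \code{ortholog_id}, \code{locus_id},
#'   \code{scaffold_b}, \code{start_b}, \code{end_b}, \code{present_in_b}.
#' @slot repeats \link[GenomicRanges]{GRanges} on genome A with metadata
#'   \code{class} (microsatellite / interspersed), \code{motif}, \code{copies},
#'   \code{element_id}.
#' @export
setClass("SimTruth",
  representation(insertions = "GRanges", duplicationGroups = "list",
                 orthologPairs = "data.frame", repeats = "GRanges"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@duplicationGroups) &&
      any(lengths(object@duplicationGroups) < 2L))
    msg <- c(msg, "duplication groups must have size >= 2")
  op <- object@orthologPairs
  if (nrow(op) && !all(c("ortholog_id", "locus_id", "scaffold_b", "start_b",
                         "end_b", "present_in_b") %in% colnames(op)))
    msg <- c(msg, "orthologPairs is missing required columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@insertions), "insertions,",
      length(object@duplicationGroups), "duplication group(s),",
      nrow(object@orthologPairs), "ortholog pair(s),",
      length(object@repeats), "planted repeat(s)\n")
})

#' True insertions of a simulation
#' @param truth A \linkS4class{SimTruth}.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
trueInsertions <- function(truth) truth@insertions

#' True duplication groups of a simulation
#' @param truth A \linkS4class{SimTruth}.
#' @return A list of character vectors.
#' @export
trueDuplicationGroups <- function(truth) truth@duplicationGroups

#' True ortholog pairs of a simulation
#' @param truth A \linkS4class{SimTruth}.
#' @return A data.frame.
#' @export
trueOrthologPairs <- function(truth) truth@orthologPairs

#' True planted repeats of a simulation
#' @param truth A \linkS4class{SimTruth}.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
trueRepeats <- function(truth) truth@repeats

# ---------------------------------------------------------------------------
# LineageTree

#' Phylogenetic tree with bootstrap supports
#'
#' An unrooted neighbor-joining tree over EVE and reference leaves, with
#' per-edge nonparametric bootstrap supports (percent). Supports are defined
#' for internal edges only; all other entries are NA.
#'
#' @slot tree An \link[ape]{ape} \code{phylo} object.
#' @slot edgeSupports Numeric vector parallel to \code{tree$edge} rows.
#' @export
setClass("LineageTree",
  representation(tree = "phylo", edgeSupports = "numeric"))

setValidity("LineageTree", function(object) {
  msg <- character()
  if (length(object@edgeSupports) != nrow(object@tree$edge))
    msg <- c(msg, "edgeSupports must align with tree edges")
  sup <- object@edgeSupports[!is.na(object@edgeSupports)]
  if (length(sup) && (any(sup < 0) || any(sup > 100)))
    msg <- c(msg, "supports must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree:", length(object@tree$tip.label), "leaves;",
      sum(!is.na(object@edgeSupports)), "supported internal edge(s)\n")
})

#' Underlying phylo object of a LineageTree
#' @param x A \linkS4class{LineageTree}.
#' @return An ape \code{phylo}.
#' @export
phyloTree <- function(x) x@tree

#' Edge supports of a LineageTree
#' @param x A \linkS4class{LineageTree}.
#' @return Numeric vector parallel to \code{phyloTree(x)$edge} rows (percent;
#'   NA on terminal edges or when bootstrap was not run).
#' @export
edgeSupports <- function(x) x@edgeSupports
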