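# Parameter containers: simulation config, search params, flank params.

#' Simulation configuration
#'
#' All tunables of the synthetic paleovirome generator. The defaults define
#' the standard desk-scale study conditions used throughout the test suite:
#' five viral groups, three insertions per group spread over a degradation
#' grid from intact to heavily degraded, one duplication group, three
#' ortholog pairs (one flagged absent in species B), and 5 % species
#' divergence.
#'
#' @slot seed Integer master seed; a fixed config reproduces byte-identical
#'   outputs.
#' @slot nScaffolds Number of scaffolds per genome.
#' @slot scaffoldLen Host (pre-insertion) length of each scaffold, bp.
#' @slot gcContent Background GC fraction in [0, 1].
#' @slot viralGroups Closed vocabulary of viral groups to simulate.
#' @slot nVirusesPerGroup Synthetic viruses generated per group.
#' @slot insertionsPerGroup EVE insertions planted per group in genome A.
#' @slot degradationGrid List of numeric triples
#'   (substitution rate per site, n_nonsense, n_frameshift), cycled across
#'   each group's insertions.
#' @slot nDuplicationGroups Number of shared-flank duplication groups.
#' @slot duplicationGroupSize Loci per duplication group (>= 2).
#' @slot nOrthologPairs Loci with an orthologous site in genome B.
#' @slot nOrthologAbsent How many ortholog pairs have an empty site in B.
#' @slot speciesDivergence Substitutions per site separating genome B from
#'   the shared ancestral background.
#' @slot microsatDensity Scattered microsatellites per kb of host background.
#' @slot interspersedLength Length (bp) of the planted interspersed element.
#' @slot interspersedCopies Genome-wide copy number of that element.
#' @slot nDecoys Number of host decoy proteins generated for the reciprocal
#'   filter.
#' @export
setClass("SimConfig",
  representation(seed = "integer", nScaffolds = "integer",
                 scaffoldLen = "integer", gcContent = "numeric",
                 viralGroups = "character", nVirusesPerGroup = "integer",
                 insertionsPerGroup = "integer", degradationGrid = "list",
                 nDuplicationGroups = "integer",
                 duplicationGroupSize = "integer",
                 nOrthologPairs = "integer", nOrthologAbsent = "integer",
                 speciesDivergence = "numeric", microsatDensity = "numeric",
                 interspersedLength = "integer",
                 interspersedCopies = "integer", nDecoys = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rate01 <- function(x) all(x >= 0 & x <= 1)
  if (!rate01(object@gcContent)) msg <- c(msg, "gcContent must be in [0,1]")
  if (!rate01(object@speciesDivergence))
    msg <- c(msg, "speciesDivergence must be in [0,1]")
  counts <- c(object@nScaffolds, object@scaffoldLen, object@nVirusesPerGroup,
              object@insertionsPerGroup, object@nDuplicationGroups,
              object@nOrthologPairs, object@nOrthologAbsent, object@nDecoys)
  if (any(counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (length(object@viralGroups) == 0L)
    msg <- c(msg, "at least one viral group is required")
  if (!all(object@viralGroups %in% VIRAL_GROUPS))
    msg <- c(msg, "viralGroups must come from the closed vocabulary")
  for (lvl in object@degradationGrid) {
    if (length(lvl) != 3L || lvl[1] < 0 || lvl[1] > 1 || any(lvl[2:3] < 0))
      msg <- c(msg, "degradationGrid entries must be (rate in [0,1], n>=0, n>=0)")
  }
  if (object@duplicationGroupSize < 2L)
    msg <- c(msg, "duplicationGroupSize must be >= 2")
  if (object@nOrthologAbsent > object@nOrthologPairs)
    msg <- c(msg, "nOrthologAbsent cannot exceed nOrthologPairs")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed Master seed (integer).
#' @param nScaffolds,scaffoldLen,gcContent,viralGroups,nVirusesPerGroup
#'   See \linkS4class{SimConfig}.
#' @param insertionsPerGroup,degradationGrid,nDuplicationGroups See
#'   \linkS4class{SimConfig}.
#' @param duplicationGroupSize,nOrthologPairs,nOrthologAbsent See
#'   \linkS4class{SimConfig}.
#' @param speciesDivergence,microsatDensity,interspersedLength See
#'   \linkS4class{SimConfig}.
#' @param interspersedCopies,nDecoys See \linkS4class{SimConfig}.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' @export
simConfig <- function(seed = 1L,
                      nScaffolds = 5L,
                      scaffoldLen = 10000L,
                      gcContent = 0.42,
                      viralGroups = VIRAL_GROUPS,
                      nVirusesPerGroup = 2L,
                      insertionsPerGroup = 3L,
                      degradationGrid = list(c(0, 0, 0),
                                             c(0.02, 2, 1),
                                             c(0.05, 12, 2)),
                      nDuplicationGroups = 1L,
                      duplicationGroupSize = 2L,
                      nOrthologPairs = 3L,
                      nOrthologAbsent = 1L,
                      speciesDivergence = 0.05,
                      microsatDensity = 0.15,
                      interspersedLength = 120L,
                      interspersedCopies = 10L,
                      nDecoys = 20L) {
  new("SimConfig", seed = as.integer(seed), nScaffolds = as.integer(nScaffolds),
      scaffoldLen = as.integer(scaffoldLen), gcContent = gcContent,
      viralGroups = viralGroups, nVirusesPerGroup = as.integer(nVirusesPerGroup),
      insertionsPerGroup = as.integer(insertionsPerGroup),
      degradationGrid = degradationGrid,
      nDuplicationGroups = as.integer(nDuplicationGroups),
      duplicationGroupSize = as.integer(duplicationGroupSize),
      nOrthologPairs = as.integer(nOrthologPairs),
      nOrthologAbsent = as.integer(nOrthologAbsent),
      speciesDivergence = speciesDivergence,
      microsatDensity = microsatDensity,
      interspersedLength = as.integer(interspersedLength),
      interspersedCopies = as.integer(interspersedCopies),
      nDecoys = as.integer(nDecoys))
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors \linkS4class{SimConfig} field-for-field; missing fields
#' fall back to the defaults of \code{\link{simConfig}}.
#'
#' @param path Path to a YAML file.
#' @return A \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if ("degradationGrid" %in% names(vals))
    vals$degradationGrid <- lapply(vals$degradationGrid, as.numeric)
  do.call(simConfig, vals)
}

#' Write a simulation configuration to a YAML file
#'
#' @param config A \linkS4class{SimConfig}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  fields <- slotNames(config)
  vals <- lapply(fields, function(f) slot(config, f))
  names(vals) <- fields
  yaml::write_yaml(vals, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Translated-search parameters
#'
#' Statistical and heuristic parameters of the translated homology search.
#' Defaults follow the canonical gapped protein-search parameterisation:
#' BLOSUM62, gap open 11 / extend 1, Karlin-Altschul K = 0.041 and
#' lambda = 0.267 per score unit, E-value threshold 1e-3. Masking defaults
#' give DUST-like behaviour: 64-nt windows, 1.5-bit trinucleotide entropy.
#'
#' @slot matrixName Substitution matrix name.
#' @slot gapOpen,gapExtend Affine gap penalties (score units, > 0).
#' @slot K,lambda Karlin-Altschul parameters (> 0).
#' @slot evalueMax E-value acceptance threshold (> 0).
#' @slot seedLength Exact-word seed length (aa) for the scan heuristic.
#' @slot extendWindow Half-width (aa) of the seed extension window.
#' @slot maskWindow Masking window length (nt).
#' @slot maskEntropy Trinucleotide Shannon-entropy threshold (bits).
#' @slot mergeGap Maximum genomic gap (bp) when merging hits into loci.
#' @slot frameshiftPenalty Frame-transition penalty (score units) in the
#'   degradation alignment.
#' @export
setClass("SearchParams",
  representation(matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric", K = "numeric", lambda = "numeric",
                 evalueMax = "numeric", seedLength = "integer",
                 extendWindow = "integer", maskWindow = "integer",
                 maskEntropy = "numeric", mergeGap = "integer",
                 frameshiftPenalty = "numeric"))

setValidity("SearchParams", function(object) {
  msg <- character()
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    msg <- c(msg, "gap penalties must be > 0")
  if (object@K <= 0 || object@lambda <= 0)
    msg <- c(msg, "K and lambda must be > 0")
  if (object@evalueMax <= 0) msg <- c(msg, "E-value threshold must be > 0")
  if (object@maskWindow < 4L) msg <- c(msg, "mask window must be >= 4 nt")
  if (length(msg)) msg else TRUE
})

#' Construct translated-search parameters
#'
#' @param matrixName,gapOpen,gapExtend,K,lambda,evalueMax,seedLength See
#'   \linkS4class{SearchParams}.
#' @param extendWindow,maskWindow,maskEntropy,mergeGap,frameshiftPenalty See
#'   \linkS4class{SearchParams}.
#' @return A validated \linkS4class{SearchParams}.
#' @examples
#' sp <- searchParams()
#' @export
searchParams <- function(matrixName = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                         K = 0.041, lambda = 0.267, evalueMax = 1e-3,
                         seedLength = 4L, extendWindow = 90L,
                         maskWindow = 64L, maskEntropy = 1.5,
                         mergeGap = 100L, frameshiftPenalty = 12) {
  new("SearchParams", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend, K = K, lambda = lambda, evalueMax = evalueMax,
      seedLength = as.integer(seedLength),
      extendWindow = as.integer(extendWindow),
      maskWindow = as.integer(maskWindow), maskEntropy = maskEntropy,
      mergeGap = as.integer(mergeGap), frameshiftPenalty = frameshiftPenalty)
}

# ---------------------------------------------------------------------------

#' Flank-validation parameters
#'
#' Thresholds for host-origin certification of EVE flanking regions and for
#' shared-flank duplication inference. Defaults encode the screening rules:
#' flanks of at least 150 bp free of viral similarity; microsatellites
#' repeated at least 6 times; interspersed repeats longer than 100 bp with at
#' least 10 genome-wide copies; "same flanking region" operationalised as
#' >= 95 % identity over >= 100 bp.
#'
#' @slot minFlankLen Minimum flank length, bp.
#' @slot microsatMinCopies Minimum tandem copy number.
#' @slot microsatMaxUnit Maximum microsatellite motif length, bp.
#' @slot interspersedMinLen Minimum interspersed element length, bp.
#' @slot interspersedMinCopies Minimum genome-wide copy count.
#' @slot sharedIdentity Identity fraction for shared-flank duplication calls.
#' @slot sharedMinOverlap Minimum aligned overlap (bp) for shared flanks.
#' @slot ntMinIdentity Identity fraction for nucleotide repeat/ortholog hits.
#' @slot orthologUniqueRatio Best/second-best score ratio required to call a
#'   flank match unique in the second genome.
#' @export
setClass("FlankParams",
  representation(minFlankLen = "integer", microsatMinCopies = "integer",
                 microsatMaxUnit = "integer", interspersedMinLen = "integer",
                 interspersedMinCopies = "integer", sharedIdentity = "numeric",
                 sharedMinOverlap = "integer", ntMinIdentity = "numeric",
                 orthologUniqueRatio = "numeric"))

setValidity("FlankParams", function(object) {
  vals <- c(object@minFlankLen, object@microsatMinCopies,
            object@microsatMaxUnit, object@interspersedMinLen,
            object@interspersedMinCopies, object@sharedIdentity,
            object@sharedMinOverlap, object@ntMinIdentity,
            object@orthologUniqueRatio)
  if (any(vals <= 0)) "all thresholds must be positive" else TRUE
})

#' Construct flank-validation parameters
#'
#' @param minFlankLen,microsatMinCopies,microsatMaxUnit See
#'   \linkS4class{FlankParams}.
#' @param interspersedMinLen,interspersedMinCopies,sharedIdentity See
#'   \linkS4class{FlankParams}.
#' @param sharedMinOverlap,ntMinIdentity,orthologUniqueRatio See
#'   \linkS4class{FlankParams}.
#' @return A validated \linkS4class{FlankParams}.
#' @examples
#' fp <- flankParams()
#' @export
flankParams <- function(minFlankLen = 150L, microsatMinCopies = 6L,
                        microsatMaxUnit = 6L, interspersedMinLen = 100L,
                        interspersedMinCopies = 10L, sharedIdentity = 0.95,
                        sharedMinOverlap = 100L, ntMinIdentity = 0.80,
                        orthologUniqueRatio = 1.5) {
  new("FlankParams", minFlankLen = as.integer(minFlankLen),
      microsatMinCopies = as.integer(microsatMinCopies),
      microsatMaxUnit = as.integer(microsatMaxUnit),
      interspersedMinLen = as.integer(interspersedMinLen),
      interspersedMinCopies = as.integer(interspersedMinCopies),
      sharedIdentity = sharedIdentity,
      sharedMinOverlap = as.integer(sharedMinOverlap),
      ntMinIdentity = ntMinIdentity,
      orthologUniqueRatio = orthologUniqueRatio)
}
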