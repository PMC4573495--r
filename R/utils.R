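# Internal helpers shared across the package.

.pkgCache <- new.env(parent = emptyenv())

DNA_BASES4 <- c("A", "C", "G", "T")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Derive a stage-local child seed from a master seed
#'
#' Fans a single master seed out to per-stage streams by hashing the stage
#' name, so that every pipeline stage is reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param tag Character stage name.
#' @return An integer seed in [0, 2^31).
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 31 + v) %% 1013904223
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded at `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# i.i.d. nucleotide background at a given GC content, as a character string
randomDNA <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

# Point-mutate a nucleotide string at per-site rate `rate` (substitutions only,
# coordinates preserved). Returns the mutated string.
mutateDNA <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0L) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) {
    x[i] <- sample(setdiff(DNA_BASES4, x[i]), 1L)
  }
  paste0(x, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Translate an in-frame nucleotide string to a peptide string ('*' for stops,
# 'X' for codons containing non-ACGT letters).
translateNT <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

#' Scoring matrix with stop codons forced to strong mismatches
#'
#' Returns a copy of a Biostrings substitution matrix (BLOSUM62 by default) in
#' which every entry involving the stop sentinel \code{*} is set to -4, so that
#' degenerate reading frames full of stops can never extend an alignment.
#'
#' @param name Matrix name available in Biostrings (e.g. "BLOSUM62", "BLOSUM50").
#' @return A numeric substitution matrix.
#' @export
eveSubstitutionMatrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (!is.null(.pkgCache[[key]])) return(.pkgCache[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  if ("*" %in% rownames(m)) {
    m["*", ] <- -4
    m[, "*"] <- -4
  }
  .pkgCache[[key]] <- m
  m
}

# DNA local-alignment scoring matrix (blastn-like).
ntSubstitutionMatrix <- function() {
  if (is.null(.pkgCache[["mat_nt"]])) {
    .pkgCache[["mat_nt"]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE)
  }
  .pkgCache[["mat_nt"]]
}

# Inverse genetic code: list mapping amino acid -> codons (standard code).
codonsForAA <- function() {
  if (is.null(.pkgCache[["inv_code"]])) {
    gc <- Biostrings::GENETIC_CODE
    .pkgCache[["inv_code"]] <- split(names(gc), unname(gc))
  }
  .pkgCache[["inv_code"]]
}
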