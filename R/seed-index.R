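# Exact-word seed indexes for the translated protein scan and for nucleotide
# self/cross searches. Seeds are clustered by diagonal and extended with
# banded windows around the seed span.

# Rolling k-mer codes of a peptide over the 20-letter alphabet (NA where the
# window contains X, * or any non-standard letter).
aaKmerCodes <- function(pep, k) {
  L <- nchar(pep)
  if (L < k) return(numeric(0))
  v <- match(strsplit(pep, "", fixed = TRUE)[[1]], AA20) - 1
  m <- L - k + 1L
  code <- numeric(m)
  ok <- !logical(m)
  for (j in seq_len(k)) {
    vj <- v[seq_len(m) + j - 1L]
    ok <- ok & !is.na(vj)
    vj[is.na(vj)] <- 0
    code <- code * 20 + vj
  }
  code[!ok] <- NA
  code
}

# Rolling k-mer codes of a DNA string (NA where the window contains N).
ntKmerCodes <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(numeric(0))
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES4) - 1
  m <- L - k + 1L
  code <- numeric(m)
  ok <- !logical(m)
  for (j in seq_len(k)) {
    vj <- v[seq_len(m) + j - 1L]
    ok <- ok & !is.na(vj)
    vj[is.na(vj)] <- 0
    code <- code * 4 + vj
  }
  code[!ok] <- NA
  code
}

# Build an environment mapping k-mer code -> matrix (seqIdx, pos) over a
# character vector of sequences, using the supplied code function.
.buildSeedIndex <- function(seqs, k, codeFun) {
  seqIdx <- integer(0); pos <- integer(0); codes <- numeric(0)
  for (i in seq_along(seqs)) {
    ci <- codeFun(seqs[[i]], k)
    keep <- which(!is.na(ci))
    seqIdx <- c(seqIdx, rep.int(i, length(keep)))
    pos <- c(pos, keep)
    codes <- c(codes, ci[keep])
  }
  env <- new.env(parent = emptyenv(), size = max(16L, length(codes)))
  if (length(codes)) {
    sp <- split(seq_along(codes), codes)
    for (key in names(sp)) {
      ii <- sp[[key]]
      assign(key, cbind(seqIdx[ii], pos[ii]), envir = env)
    }
  }
  list(env = env, k = k, names = names(seqs))
}

aaSeedIndex <- function(proteins, k) .buildSeedIndex(proteins, k, aaKmerCodes)

# Index all scaffolds of a genome for nucleotide seed lookup.
ntSeedIndex <- function(genome, k = 12L) {
  sc <- scaffolds(genome)
  seqs <- as.character(sc)
  names(seqs) <- names(sc)
  .buildSeedIndex(seqs, k, ntKmerCodes)
}

# Look up seed matches of a query code vector in an index.
# Returns data.frame(qpos, target, tpos).
.seedHits <- function(codes, index) {
  keep <- which(!is.na(codes))
  if (!length(keep)) {
    return(data.frame(qpos = integer(0), target = integer(0),
                      tpos = integer(0)))
  }
  keys <- as.character(codes[keep])
  found <- mget(keys, envir = index$env, ifnotfound = list(NULL))
  nper <- vapply(found, function(x) if (is.null(x)) 0L else nrow(x),
                 integer(1))
  if (sum(nper) == 0L) {
    return(data.frame(qpos = integer(0), target = integer(0),
                      tpos = integer(0)))
  }
  mat <- do.call(rbind, found[nper > 0L])
  data.frame(qpos = rep.int(keep[nper > 0L], nper[nper > 0L]),
             target = mat[, 1L], tpos = mat[, 2L])
}

# Cluster seeds (within one target) into candidate regions: consecutive seeds
# (by query position) stay in one cluster while the query gap is at most
# `maxGap` and the diagonal drifts by at most `maxDrift`.
.clusterSeeds <- function(seeds, maxGap, maxDrift = 25L) {
  out <- list()
  for (tg in unique(seeds$target)) {
    ss <- seeds[seeds$target == tg, , drop = FALSE]
    ss$diag <- ss$qpos - ss$tpos
    ss <- ss[order(ss$diag, ss$qpos), , drop = FALSE]
    newc <- c(TRUE, diff(ss$diag) > maxDrift |
                abs(diff(ss$qpos)) > maxGap)
    cid <- cumsum(newc)
    for (g in split(seq_len(nrow(ss)), cid)) {
      out[[length(out) + 1L]] <- ss[g, , drop = FALSE]
    }
  }
  out
}

# Nucleotide local hits of `query` against an indexed genome.
# Returns data.frame(scaffold, start, end, qstart, qend, score, pident, alen).
ntLocalHits <- function(query, index, genome, minLen = 100L,
                        minIdent = 0.80, pad = 60L) {
  sc <- scaffolds(genome)
  codes <- ntKmerCodes(query, index$k)
  seeds <- .seedHits(codes, index)
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), qstart = integer(0),
                      qend = integer(0), score = numeric(0),
                      pident = numeric(0), alen = integer(0))
  if (!nrow(seeds)) return(empty)
  mat <- ntSubstitutionMatrix()
  res <- list()
  for (cl in .clusterSeeds(seeds, maxGap = 200L)) {
    tg <- cl$target[1L]
    scafName <- index$names[tg]
    s <- as.character(sc[[scafName]])
    n <- nchar(s)
    qlo <- max(1L, min(cl$qpos) - pad)
    qhi <- min(nchar(query), max(cl$qpos) + index$k - 1L + pad)
    slo <- max(1L, min(cl$tpos) - pad)
    shi <- min(n, max(cl$tpos) + index$k - 1L + pad)
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(substr(query, qlo, qhi)),
      subject = Biostrings::DNAString(substr(s, slo, shi)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    alen <- nchar(as.character(al@pattern))
    pidv <- if (alen > 0) Biostrings::pid(al) else 0
    if (alen >= minLen && pidv >= minIdent * 100) {
      pr <- al@pattern@range; sr <- al@subject@range
      res[[length(res) + 1L]] <- data.frame(
        scaffold = scafName,
        start = slo + BiocGenerics::start(sr) - 1L,
        end = slo + BiocGenerics::end(sr) - 1L,
        qstart = qlo + BiocGenerics::start(pr) - 1L,
        qend = qlo + BiocGenerics::end(pr) - 1L,
        score = Biostrings::score(al), pident = pidv, alen = alen)
    }
  }
  if (!length(res)) return(empty)
  hits <- do.call(rbind, res)
  # deduplicate overlapping genomic intervals, keeping the best score
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      j <- (i + 1L):nrow(hits)
      ov <- hits$scaffold[j] == hits$scaffold[i] &
        pmin(hits$end[j], hits$end[i]) - pmax(hits$start[j], hits$start[i]) >=
          0.5 * pmin(hits$end[j] - hits$start[j], hits$end[i] - hits$start[i])
      keep[j][ov] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$scaffold, hits$start), , drop = FALSE]
}
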