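# Independent oracles and shared fixtures for the test suite.

# Brute-force Smith-Waterman with affine gaps (gap of length L costs
# gapOpen + L * gapExt). Plain three-state DP over full matrices, written
# independently of the package's alignment path.
bruteLocalAlign <- function(a, b, mat, gapOpen, gapExt) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  open <- gapOpen + gapExt
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(H[i - 1, j] - open, X[i - 1, j] - gapExt,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(H[i, j - 1] - open, Y[i, j - 1] - gapExt,
                     X[i, j - 1] - open)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     X[i, j], Y[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Brute-force enumeration of maximal exact tandem arrays (primitive motifs,
# canonical rotation), by direct left-to-right scanning.
bruteTandems <- function(s, minCopies = 6, maxUnit = 6) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(x)
  rot <- function(m) {
    k <- nchar(m)
    if (k == 1) return(m)
    min(vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1))
    }, character(1)))
  }
  prim <- function(m) {
    k <- nchar(m)
    if (k == 1) return(TRUE)
    v <- strsplit(m, "", fixed = TRUE)[[1]]
    for (p in seq_len(k - 1)) {
      if (k %% p == 0 && all(v == v[(seq_len(k) - 1) %% p + 1])) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (k in seq_len(maxUnit)) {
    if (n < 2 * k) next
    for (i in seq_len(n - 2 * k + 1)) {
      # left-maximality of the period-k run starting at i
      if (i > 1 && x[i - 1] == x[i + k - 1]) next
      motif <- paste0(x[i:(i + k - 1)], collapse = "")
      if (!prim(motif)) next
      tot <- k
      while (i + tot <= n && x[i + tot] == x[i + tot - k]) tot <- tot + 1
      copies <- tot %/% k
      if (copies < minCopies) next
      if (tot < k + 1) next   # no repetition at all
      out[[length(out) + 1]] <- data.frame(
        motif = rot(motif), unit_len = k, copies = copies, start = i,
        end = i + tot - 1, stringsAsFactors = FALSE)
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

# Pure-R reference of the three-frame frameshift DP recurrence (same scoring
# model, independent implementation) returning the optimal score only.
refFrameshiftScore <- function(S, fs, gapAA, gapCodon) {
  n <- nrow(S); m <- ncol(S)
  D <- matrix(-Inf, n + 1, m + 1)   # D[i + 1, j + 1] <=> DP cell (i, j)
  for (i in 0:min(2, n)) D[i + 1, ] <- 0
  for (i in 3:n) D[i + 1, 1] <- D[i - 2, 1] - gapCodon
  for (i in 3:n) {
    for (j in 1:m) {
      s <- S[i, j]
      cand <- c(D[i - 2, j] + s,
                D[i - 1, j] + s - fs,
                if (i >= 4) D[i - 3, j] + s - fs else -Inf,
                D[i - 2, j + 1] - gapCodon,
                D[i + 1, j] - gapAA)
      D[i + 1, j + 1] <- max(cand)
    }
  }
  max(D[(max(0, n - 2):n) + 1, ])
}

# random DNA/peptide helpers (plain sampling; tests control the RNG)
rdna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}
rpep <- function(n) {
  paste0(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n,
                replace = TRUE), collapse = "")
}

# Small, fast simulation config used across unit tests.
smallConfig <- function(seed = 42, ...) {
  simConfig(seed = seed, nScaffolds = 3, scaffoldLen = 8000,
            insertionsPerGroup = 1, nDuplicationGroups = 0,
            nOrthologPairs = 2, nOrthologAbsent = 1,
            degradationGrid = list(c(0, 0, 0)), ...)
}

# Cached small end-to-end run shared by several test files.
.testCache <- new.env()
smallRun <- function() {
  if (is.null(.testCache$run)) {
    cfg <- smallConfig()
    db <- buildViralDb(cfg)
    sim <- simulateGenomePair(cfg, db)
    masked <- maskAssembly(sim$genomeA)
    hits <- translatedScan(masked, db)
    kept <- reciprocalFilter(hits, sim$genomeA, db, buildDecoyDb(cfg))
    ml <- mergeHitsToLoci(kept, 100)
    loci <- classifyViralGroup(ml$loci, ml$hits)
    .testCache$run <- list(cfg = cfg, db = db, sim = sim, hits = hits,
                           kept = kept, ml = ml, loci = loci)
  }
  .testCache$run
}
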