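# Lineage placement: progressive protein MSA, corrected distances,
# neighbor-joining, nonparametric bootstrap, lineage assignment.

.alnLetters <- c(AA20, "*", "X")

# character matrix (rows = sequences) -> per-column count matrix over
# .alnLetters (gaps excluded)
.profileCounts <- function(mat) {
  L <- ncol(mat)
  f <- matrix(0, nrow = length(.alnLetters), ncol = L,
              dimnames = list(.alnLetters, NULL))
  for (a in .alnLetters) f[a, ] <- colSums(mat == a)
  f
}

# Align two profiles (character matrices); returns the merged matrix.
.mergeProfiles <- function(m1, m2, M, gapOpen, gapExt) {
  f1 <- .profileCounts(m1)
  f2 <- .profileCounts(m2)
  Msub <- M[.alnLetters, .alnLetters]
  S <- t(f1) %*% Msub %*% f2
  n1 <- pmax(1, colSums(f1)); n2 <- pmax(1, colSums(f2))
  S <- S / outer(n1, n2)                 # average-of-pairs column score
  res <- nwProfileAlign(S, gapOpen, gapExt)
  moves <- res$moves
  out <- matrix("-", nrow = nrow(m1) + nrow(m2), ncol = length(moves))
  rownames(out) <- c(rownames(m1), rownames(m2))
  i <- 0L; j <- 0L
  r1 <- seq_len(nrow(m1)); r2 <- nrow(m1) + seq_len(nrow(m2))
  for (c2 in seq_along(moves)) {
    mv <- moves[c2]
    if (mv != 3L) { i <- i + 1L; out[r1, c2] <- m1[, i] }
    if (mv != 2L) { j <- j + 1L; out[r2, c2] <- m2[, j] }
  }
  out
}

#' Progressive multiple alignment of peptides
#'
#' Builds a guide tree by average-linkage clustering of pairwise alignment
#' distances, then merges sequences and profiles by progressive dynamic
#' programming (affine gaps, average-of-pairs column scoring under the
#' configured matrix). Removing gaps from any row recovers the input
#' sequence exactly.
#'
#' @param peptides A named character vector or \link[Biostrings]{AAStringSet}
#'   (at least two sequences).
#' @param params A \linkS4class{SearchParams}.
#' @return An \link[Biostrings]{AAStringSet} of equal-width gapped rows, in
#'   input order.
#' @export
buildMsa <- function(peptides, params = searchParams()) {
  if (is(peptides, "AAStringSet")) peptides <- as.character(peptides)
  if (length(peptides) < 2L) stop("need at least two sequences")
  if (is.null(names(peptides)) || anyDuplicated(names(peptides)))
    stop("sequences must carry unique names")
  M <- eveSubstitutionMatrix(params@matrixName)
  n <- length(peptides)
  # guide distances from pairwise global alignments
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(peptides[a]),
        subject = Biostrings::AAString(peptides[b]), type = "global",
        substitutionMatrix = M, gapOpening = params@gapOpen,
        gapExtension = params@gapExtend)
      D[a, b] <- D[b, a] <- 1 - Biostrings::pid(al) / 100
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(peptides[i], "", fixed = TRUE)[[1]], nrow = 1L)
    rownames(m) <- names(peptides)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
    merged[[s]] <- .mergeProfiles(pick(hc$merge[s, 1L]),
                                  pick(hc$merge[s, 2L]),
                                  M, params@gapOpen, params@gapExtend)
  }
  final <- merged[[n - 1L]]
  final <- final[names(peptides), , drop = FALSE]
  AAStringSet(apply(final, 1L, paste0, collapse = ""))
}

#' Corrected pairwise distances from a protein alignment
#'
#' For each pair, p = mismatches / shared ungapped columns; the reported
#' distance is the scoredist-style correction
#' \eqn{d = -\ln(1 - p - 0.2 p^2)}, capped at \code{maxDist}. Pairs sharing
#' no ungapped columns receive the cap with a warning.
#'
#' @param aln Equal-width gapped \link[Biostrings]{AAStringSet} (>= 2 rows).
#' @param maxDist Distance cap (substitutions per site).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwiseDistances <- function(aln, maxDist = 5) {
  if (length(aln) < 2L) stop("need at least two rows")
  chars <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  n <- nrow(chars)
  D <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  floorArg <- exp(-maxDist)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      ok <- chars[a, ] != "-" & chars[b, ] != "-"
      if (!any(ok)) {
        warning("no shared ungapped columns for pair (", rownames(chars)[a],
                ", ", rownames(chars)[b], "); distance capped")
        D[a, b] <- D[b, a] <- maxDist
        next
      }
      p <- sum(chars[a, ok] != chars[b, ok]) / sum(ok)
      arg <- 1 - p - 0.2 * p^2
      D[a, b] <- D[b, a] <- if (arg <= floorArg) maxDist else
        min(maxDist, -log(arg))
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical neighbor-joining agglomeration with deterministic tie-breaking
#' (smallest index pair in the Q matrix) and negative branch lengths clamped
#' to zero with the deficit transferred to the sister edge. Exact for
#' additive distance matrices.
#'
#' @param D Symmetric, non-negative distance matrix with zero diagonal and
#'   at least 3 taxa (dimnames give leaf labels).
#' @return A \linkS4class{LineageTree} (supports all NA).
#' @export
njTree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node bookkeeping: tips 1..n, internal nodes appended after
  nodeIds <- seq_len(n)
  nextNode <- 2L * n - 2L            # ape convention: root gets n+1 below
  edges <- NULL; lens <- NULL
  internalCount <- 0L
  newNodeId <- function() {
    internalCount <<- internalCount + 1L
    n + 1L + internalCount           # n+1 reserved for the final join (root)
  }
  act <- D
  while (nrow(act) > 3L) {
    na <- nrow(act)
    r <- rowSums(act)
    Q <- (na - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(na - 1L)) {
      for (j in (i + 1L):na) {
        if (Q[i, j] < best[1L] - 1e-12) best <- c(Q[i, j], i, j)
      }
    }
    i <- best[2L]; j <- best[3L]
    li <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (na - 2))
    lj <- act[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(0, li); lj <- max(0, lj)
    u <- newNodeId()
    edges <- rbind(edges, c(u, nodeIds[i]), c(u, nodeIds[j]))
    lens <- c(lens, li, lj)
    duk <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    act2 <- rbind(cbind(act[keep, keep, drop = FALSE], duk[keep]),
                  c(duk[keep], 0))
    nodeIds <- c(nodeIds[keep], u)
    act <- act2
  }
  # final 3-way join at the (unrooted) root
  root <- n + 1L
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  edges <- rbind(edges, c(root, nodeIds[1L]), c(root, nodeIds[2L]),
                 c(root, nodeIds[3L]))
  lens <- c(lens, max(0, l1), max(0, l2), max(0, l3))
  tree <- list(edge = edges, edge.length = unname(lens),
               tip.label = labels, Nnode = internalCount + 1L)
  class(tree) <- "phylo"
  tree <- stats::reorder(tree, "cladewise")
  new("LineageTree", tree = tree,
      edgeSupports = rep(NA_real_, nrow(tree$edge)))
}

# Leaf-name bipartition key for every edge of a phylo tree; trivial edges
# (to a tip) get NA. The side not containing tip 1 is canonical.
.edgeBipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder accumulation of descendant tips
  po <- stats::reorder(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  vapply(seq_len(nrow(tree$edge)), function(r) {
    ch <- tree$edge[r, 2L]
    if (ch <= ntip) return(NA_character_)
    side <- sort(desc[[ch]])
    if (1L %in% side) side <- setdiff(seq_len(ntip), side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(tree$tip.label[side]), collapse = "|")
  }, character(1))
}

# tip sets (as label vectors) on the child side of each internal edge
.edgeCladeSides <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- stats::reorder(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) {
    ch <- tree$edge[r, 2L]
    if (ch <= ntip) return(NULL)
    tree$tip.label[sort(desc[[ch]])]
  })
}

#' Nonparametric bootstrap supports on the NJ tree
#'
#' Resamples alignment columns with replacement \code{nReplicates} times,
#' recomputes distances and the NJ tree per replicate, and reports for each
#' internal edge of the original tree the percentage of replicates containing
#' the same bipartition (branch lengths ignored).
#'
#' @param aln Equal-width gapped \link[Biostrings]{AAStringSet}.
#' @param nReplicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed; supports are byte-for-byte reproducible.
#' @return A \linkS4class{LineageTree} with supports on internal edges.
#' @export
bootstrapSupports <- function(aln, nReplicates = 100L, seed = 1L) {
  if (nReplicates < 1L) stop("need at least one replicate")
  base <- njTree(pairwiseDistances(aln))
  tree <- phyloTree(base)
  keys <- .edgeBipartitions(tree)
  counts <- stats::setNames(rep(0L, sum(!is.na(keys))),
                            keys[!is.na(keys)])
  chars <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  L <- ncol(chars)
  withSeed(seed, {
    for (b in seq_len(nReplicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep <- AAStringSet(apply(chars[, cols, drop = FALSE], 1L,
                               paste0, collapse = ""))
      repKeys <- tryCatch({
        rt <- suppressWarnings(njTree(pairwiseDistances(rep)))
        .edgeBipartitions(phyloTree(rt))
      }, error = function(e) character(0))
      hit <- unique(repKeys[!is.na(repKeys)])
      hit <- hit[hit %in% names(counts)]
      counts[hit] <- counts[hit] + 1L
    }
  })
  sup <- rep(NA_real_, length(keys))
  sup[!is.na(keys)] <- 100 * counts[keys[!is.na(keys)]] / nReplicates
  new("LineageTree", tree = tree, edgeSupports = unname(sup))
}

#' Assign viral lineages to EVE leaves
#'
#' Each EVE leaf receives the lineage of the smallest supported clade
#' (support strictly greater than \code{supportThreshold}) containing it and
#' at least one reference leaf. EVE leaves whose smallest supported clade
#' contains no reference are grouped into novel clusters labelled
#' \code{novel-lineage-k}; EVEs attached only through unsupported edges stay
#' \code{unassigned}.
#'
#' @param ltree A \linkS4class{LineageTree} with bootstrap supports.
#' @param referenceLineages Named character vector: reference leaf label ->
#'   lineage label. All other leaves are treated as EVEs.
#' @param supportThreshold Support display/acceptance threshold (percent;
#'   default 70, strictly greater).
#' @return A named character vector: EVE leaf -> lineage label.
#' @export
assignLineages <- function(ltree, referenceLineages, supportThreshold = 70) {
  tree <- phyloTree(ltree)
  sup <- edgeSupports(ltree)
  tips <- tree$tip.label
  refs <- intersect(tips, names(referenceLineages))
  eves <- setdiff(tips, refs)
  if (!length(eves) || !length(refs))
    stop("tree must contain at least one EVE and one reference leaf")
  sides <- .edgeCladeSides(tree)
  ntip <- length(tips)
  # candidate supported clades: both sides of each supported internal edge
  clades <- list()
  for (r in seq_along(sides)) {
    if (is.null(sides[[r]]) || is.na(sup[r])) next
    if (sup[r] > supportThreshold) {
      clades[[length(clades) + 1L]] <- sides[[r]]
      clades[[length(clades) + 1L]] <- setdiff(tips, sides[[r]])
    }
  }
  out <- stats::setNames(rep("unassigned", length(eves)), eves)
  novelClades <- list()
  for (ev in eves) {
    containing <- Filter(function(cl) ev %in% cl, clades)
    if (!length(containing)) next
    # the smallest supported clade containing the EVE decides; among ties,
    # one holding a reference beats a pure-EVE one
    sizes <- vapply(containing, length, integer(1))
    tied <- containing[sizes == min(sizes)]
    withRef <- Filter(function(cl) any(cl %in% refs), tied)
    if (length(withRef)) {
      keys <- vapply(withRef, function(cl) paste(sort(cl), collapse = "|"),
                     character(1))
      best <- withRef[[order(keys)[1L]]]
      labs <- sort(unname(referenceLineages[intersect(best, refs)]))
      tl <- table(labs)
      out[ev] <- names(tl)[which.max(tl)]
    } else {
      key <- paste(sort(tied[[1L]]), collapse = "|")
      if (!key %in% names(novelClades)) {
        novelClades[[key]] <- sprintf("novel-lineage-%d",
                                      length(novelClades) + 1L)
      }
      out[ev] <- novelClades[[key]]
    }
  }
  out
}

#' Write a LineageTree to Newick
#'
#' Supports are attached as internal node labels before export.
#'
#' @param ltree A \linkS4class{LineageTree}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeLineageTree <- function(ltree, path) {
  tree <- phyloTree(ltree)
  sup <- edgeSupports(ltree)
  ntip <- length(tree$tip.label)
  nl <- rep("", tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[r, 2L]
    if (ch > ntip && !is.na(sup[r])) nl[ch - ntip] <- format(sup[r])
  }
  tree$node.label <- nl
  ape::write.tree(tree, file = path)
  invisible(path)
}
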