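# End-to-end pipeline: simulate -> mask -> scan -> filter -> merge ->
# validate -> profile -> orthology -> phylogeny -> report.

#' Pipeline report
#'
#' Aggregated results of one pipeline run. Group counts always sum to the
#' total number of called loci.
#'
#' @slot groupCounts Named integer: EVE loci per viral group.
#' @slot degradationTally Named integer: loci per degradation class.
#' @slot duplicationGroups List of locus-id vectors.
#' @slot duplicationEvents Integer: total shared-flank duplication events.
#' @slot orthologs data.frame of ortholog pairs.
#' @slot lineages data.frame: locus_id, lineage.
#' @slot loci GRanges of classified loci.
#' @slot hits data.frame of retained hits.
#' @slot flanks Flank report data.frame.
#' @slot profiles Degradation profile data.frame.
#' @slot truthComparison List of truth-recovery metrics (simulated runs).
#' @slot screen Parsed presence/absence screen (list) or NULL.
#' @export
setClass("PipelineReport",
  representation(groupCounts = "integer", degradationTally = "integer",
                 duplicationGroups = "list", duplicationEvents = "integer",
                 orthologs = "data.frame", lineages = "data.frame",
                 loci = "GRanges", hits = "data.frame", flanks = "data.frame",
                 profiles = "data.frame", truthComparison = "list",
                 screen = "ANY"))

setValidity("PipelineReport", function(object) {
  if (sum(object@groupCounts) != length(object@loci))
    return("group counts must sum to the total number of loci")
  if (any(object@groupCounts < 0) || any(object@degradationTally < 0))
    return("tallies must be non-negative")
  TRUE
})

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport:", length(object@loci), "EVE loci\n")
  if (length(object@groupCounts)) {
    for (g in names(object@groupCounts))
      cat(sprintf("  %-16s %d\n", g, object@groupCounts[[g]]))
  }
  cat("  duplication events:", object@duplicationEvents, "\n")
  cat("  ortholog pairs:", nrow(object@orthologs), "\n")
})

#' EVE counts per viral group
#' @param report A \linkS4class{PipelineReport}.
#' @return Named integer vector.
#' @export
groupCounts <- function(report) report@groupCounts

#' Called loci of a pipeline run
#' @param report A \linkS4class{PipelineReport}.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
reportLoci <- function(report) report@loci

#' Truth-recovery metrics of a simulated run
#' @param report A \linkS4class{PipelineReport}.
#' @return A list (empty for non-simulated runs).
#' @export
truthComparison <- function(report) report@truthComparison

# best hit row of each locus, ordered as classifyViralGroup orders
.bestHitRows <- function(loci, hits) {
  idx <- integer(length(loci))
  for (i in seq_along(loci)) {
    hh <- which(hits$locus_id == mcols(loci)$locus_id[i])
    hh <- hh[order(hits$evalue[hh], -hits$score[hh], hits$protein_id[hh])]
    idx[i] <- hh[1L]
  }
  idx
}

# EVE peptide of each locus: translation of the best hit's genomic interval
# in its frame
.evePeptides <- function(loci, hits, genome) {
  sc <- scaffolds(genome)
  rows <- .bestHitRows(loci, hits)
  out <- character(length(loci))
  for (i in seq_along(loci)) {
    h <- hits[rows[i], ]
    seg <- substr(as.character(sc[[h$scaffold]]), h$start, h$end)
    if (h$frame < 0) seg <- revcomp(seg)
    out[i] <- translateNT(seg)
  }
  stats::setNames(out, mcols(loci)$locus_id)
}

# compare pipeline calls with simulator truth
.compareTruth <- function(loci, profiles, dup, orth, truth) {
  ins <- trueInsertions(truth)
  det <- rep(FALSE, length(ins))
  mapCalled <- stats::setNames(rep(NA_character_,
                                   length(mcols(loci)$locus_id)),
                               mcols(loci)$locus_id)
  if (length(loci)) {
    ov <- GenomicRanges::findOverlaps(ins, loci, ignore.strand = TRUE)
    for (k in seq_along(ov)) {
      qi <- S4Vectors::queryHits(ov)[k]; sj <- S4Vectors::subjectHits(ov)[k]
      if (mcols(ins)$group[qi] == mcols(loci)$group[sj]) {
        det[qi] <- TRUE
        mapCalled[mcols(loci)$locus_id[sj]] <- mcols(ins)$locus_id[qi]
      }
    }
  }
  lvl <- paste0(mcols(ins)$sub_rate, "/", mcols(ins)$n_nonsense, "/",
                mcols(ins)$n_frameshift)
  byLevel <- data.frame(sub_rate = mcols(ins)$sub_rate,
                        level = lvl, detected = det)
  intact <- mcols(ins)$sub_rate == 0 & mcols(ins)$n_nonsense == 0 &
    mcols(ins)$n_frameshift == 0
  recallIntact <- if (any(intact)) 100 * mean(det[intact]) else NA_real_
  # degradation counts: truth vs called profile, per mapped locus
  degCmp <- NULL
  if (nrow(profiles)) {
    tid <- mapCalled[profiles$locus_id]
    ti <- match(tid, mcols(ins)$locus_id)
    keep <- !is.na(ti)
    degCmp <- data.frame(
      locus_id = profiles$locus_id[keep], truth_id = tid[keep],
      sub_rate = mcols(ins)$sub_rate[ti[keep]],
      true_nonsense = mcols(ins)$n_nonsense[ti[keep]],
      called_nonsense = profiles$n_nonsense[keep],
      true_frameshift = mcols(ins)$n_frameshift[ti[keep]],
      called_frameshift = profiles$n_frameshift[keep],
      stringsAsFactors = FALSE)
  }
  # duplication groups as sets of truth ids
  calledDup <- lapply(dup$groups, function(g) sort(unname(mapCalled[g])))
  trueDup <- lapply(trueDuplicationGroups(truth), sort)
  dupExact <- length(calledDup) == length(trueDup) &&
    all(vapply(trueDup, function(g) {
      any(vapply(calledDup, function(h) identical(unname(h), unname(g)),
                 logical(1)))
    }, logical(1)))
  # orthologs vs truth
  to <- trueOrthologPairs(truth)
  orthCmp <- NULL
  if (nrow(to)) {
    calledTid <- unname(mapCalled[orth$locus_id])
    m <- match(to$locus_id, calledTid)
    orthCmp <- data.frame(
      truth_locus = to$locus_id, present_true = to$present_in_b,
      recovered = !is.na(m),
      present_called = ifelse(is.na(m), NA, orth$present_in_b[m]),
      pos_error = ifelse(is.na(m), NA,
                         abs(orth$start_b[m] - to$start_b)),
      stringsAsFactors = FALSE)
  }
  list(recall_by_level = byLevel, recall_intact_pct = recallIntact,
       recall_overall_pct = 100 * mean(det),
       degradation = degCmp, duplication_exact = dupExact,
       orthologs = orthCmp, locus_map = mapCalled)
}

#' Run the full pipeline on a simulated genome pair
#'
#' Executes simulate, mask, translated scan, reciprocal filtering, locus
#' merging and classification, flank validation, duplication inference,
#' degradation profiling, orthology against species B, and per-group
#' phylogenetic lineage assignment, all driven by a single master seed
#' (stage seeds derive from it by stage-name hashing). Optionally writes all
#' standard-format outputs.
#'
#' @param config A \linkS4class{SimConfig} (or path to its YAML form).
#' @param outdir Optional output directory; when given, FASTA/GFF3/TSV/
#'   Newick outputs and a plain-text report are written.
#' @param screenTable Optional path to a presence/absence screen TSV
#'   (see \code{\link{parseScreenTable}}).
#' @param search A \linkS4class{SearchParams}.
#' @param flank A \linkS4class{FlankParams}.
#' @return A \linkS4class{PipelineReport}.
#' @export
runPipeline <- function(config = simConfig(), outdir = NULL,
                        screenTable = NULL, search = searchParams(),
                        flank = flankParams()) {
  if (is.character(config)) config <- readSimConfig(config)
  db <- buildViralDb(config)
  decoys <- buildDecoyDb(config)
  sim <- simulateGenomePair(config, db)
  masked <- maskAssembly(sim$genomeA, search)
  hits <- translatedScan(masked, db, search)
  kept <- reciprocalFilter(hits, sim$genomeA, db, decoys, search)
  ml <- mergeHitsToLoci(kept, search@mergeGap)
  loci <- classifyViralGroup(ml$loci, ml$hits)
  flanks <- extractFlanks(loci, sim$genomeA, db, flank, search)
  flanks <- flankReports(flanks, sim$genomeA, flank)
  dup <- detectSharedFlankDuplications(flanks, flank)
  profiles <- profileDegradation(loci, sim$genomeA, db, search)
  orth <- findOrthologousLoci(loci, flanks, sim$genomeB, db, flank, search)
  # lineage assignment per (group, role)
  lineages <- data.frame(locus_id = character(0), lineage = character(0),
                         stringsAsFactors = FALSE)
  trees <- list()
  if (length(loci)) {
    peps <- .evePeptides(loci, ml$hits, sim$genomeA)
    info <- as.data.frame(proteinInfo(db))
    combos <- unique(data.frame(group = mcols(loci)$group,
                                role = mcols(loci)$role))
    for (ci in seq_len(nrow(combos))) {
      sel <- mcols(loci)$group == combos$group[ci] &
        mcols(loci)$role == combos$role[ci]
      refSel <- info$group == combos$group[ci] & info$role == combos$role[ci]
      evePeps <- peps[mcols(loci)$locus_id[sel]]
      refPeps <- stats::setNames(
        as.character(viralProteins(db))[refSel], info$protein_id[refSel])
      taxa <- c(evePeps, refPeps)
      taxa <- taxa[nchar(taxa) > 0]
      if (length(taxa) < 3L || sum(names(taxa) %in% names(refPeps)) == 0L)
        next
      aln <- buildMsa(taxa, search)
      key <- paste0(combos$group[ci], "_", combos$role[ci])
      lt <- bootstrapSupports(aln, 100L,
                              seed = childSeed(config@seed,
                                               paste0("bootstrap:", key)))
      trees[[key]] <- lt
      refLin <- stats::setNames(info$genome_id[refSel],
                                info$protein_id[refSel])
      asg <- assignLineages(lt, refLin, 70)
      asg <- asg[names(asg) %in% mcols(loci)$locus_id]
      if (length(asg)) {
        lineages <- rbind(lineages, data.frame(
          locus_id = names(asg), lineage = unname(asg),
          stringsAsFactors = FALSE))
      }
    }
  }
  lineages <- lineages[order(lineages$locus_id), , drop = FALSE]
  rownames(lineages) <- NULL
  gc2 <- table(factor(mcols(loci)$group, levels = config@viralGroups))
  groupCounts <- stats::setNames(as.integer(gc2), names(gc2))
  dt <- table(factor(profiles$class,
                     levels = c("intact", "disrupted", "heavily_degraded")))
  degTally <- stats::setNames(as.integer(dt), names(dt))
  screen <- if (!is.null(screenTable)) parseScreenTable(screenTable) else NULL
  cmp <- .compareTruth(loci, profiles, dup, orth, sim$truth)
  report <- new("PipelineReport", groupCounts = groupCounts,
                degradationTally = degTally,
                duplicationGroups = dup$groups,
                duplicationEvents = as.integer(dup$events),
                orthologs = orth, lineages = lineages, loci = loci,
                hits = ml$hits, flanks = flanks, profiles = profiles,
                truthComparison = cmp, screen = screen)
  if (!is.null(outdir)) {
    writePipelineOutputs(report, sim, db, trees, outdir)
  }
  report
}

#' Write pipeline outputs
#'
#' Emits the simulation inputs plus called loci as GFF3 (feature type
#' \code{endogenous_viral_element}, 1-based inclusive), hits / flanks /
#' profiles / duplications / orthologs / lineages as TSV, trees as Newick,
#' and a deterministic plain-text report.
#'
#' @param report A \linkS4class{PipelineReport}.
#' @param sim The simulation triple from \code{\link{simulateGenomePair}}.
#' @param db The \linkS4class{ViralRefDB}.
#' @param trees Named list of \linkS4class{LineageTree}.
#' @param outdir Output directory.
#' @return \code{outdir}, invisibly.
#' @export
writePipelineOutputs <- function(report, sim, db, trees, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSimulationOutputs(sim, db, file.path(outdir, "simulation"))
  loci <- report@loci
  gr <- GRanges(seqnames(loci), IRanges(start(loci), end(loci)),
                strand = strand(loci))
  mcols(gr) <- DataFrame(type = "endogenous_viral_element",
                         ID = mcols(loci)$locus_id,
                         viral_group = mcols(loci)$group,
                         gene_role = mcols(loci)$role,
                         best_protein = mcols(loci)$best_protein)
  rtracklayer::export(gr, file.path(outdir, "eve_loci.gff3"),
                      format = "gff3")
  wtsv <- function(df, name) {
    df2 <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df2, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(report@hits, "hits.tsv")
  wtsv(report@flanks, "flanks.tsv")
  wtsv(report@profiles, "degradation_profiles.tsv")
  wtsv(report@orthologs, "orthologs.tsv")
  wtsv(report@lineages, "lineages.tsv")
  dg <- report@duplicationGroups
  wtsv(data.frame(dup_group = rep(seq_along(dg), lengths(dg)),
                  locus_id = unlist(dg, use.names = FALSE)),
       "duplications.tsv")
  for (nm in names(trees)) {
    writeLineageTree(trees[[nm]], file.path(outdir, paste0(nm, ".nwk")))
  }
  writeReportText(report, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Write the plain-text pipeline report
#'
#' @param report A \linkS4class{PipelineReport}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeReportText <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("EVE pipeline report")
  w("===================")
  w("total loci\t", length(report@loci))
  for (g in names(report@groupCounts)) {
    w("group\t", g, "\t", report@groupCounts[[g]])
  }
  for (k in names(report@degradationTally)) {
    w("degradation\t", k, "\t", report@degradationTally[[k]])
  }
  w("duplication_events\t", report@duplicationEvents)
  w("ortholog_pairs\t", nrow(report@orthologs))
  if (nrow(report@orthologs)) {
    for (i in seq_len(nrow(report@orthologs))) {
      w("ortholog\t", report@orthologs$locus_id[i], "\t",
        report@orthologs$scaffold_b[i], ":", report@orthologs$start_b[i],
        "-", report@orthologs$end_b[i], "\tpresent=",
        report@orthologs$present_in_b[i])
    }
  }
  if (nrow(report@lineages)) {
    for (i in seq_len(nrow(report@lineages))) {
      w("lineage\t", report@lineages$locus_id[i], "\t",
        report@lineages$lineage[i])
    }
  }
  if (!is.null(report@screen)) {
    sm <- report@screen$matrix
    w("screen_loci\t", nrow(sm))
    w("screen_samples\t", ncol(sm))
    for (s in colnames(sm)) {
      w("screen_positive\t", s, "\t", sum(sm[, s] == "+", na.rm = TRUE))
    }
  }
  invisible(path)
}

#' Parse a presence/absence PCR screen table
#'
#' Reads a TSV whose header names the samples and whose body rows carry a
#' viral family, a locus number, and one \code{+}/\code{-} symbol per
#' sample. Rows are preserved verbatim: short rows are filled from the left
#' and missing trailing cells -- like any malformed symbol -- are recorded
#' as missing (NA), never guessed. A locus is flagged polymorphic when
#' within-species samples (columns starting with "An") show both presence
#' and absence.
#'
#' @param path Path to the TSV.
#' @return A list: \code{matrix} (loci x samples, values "+", "-", NA),
#'   \code{loci} (data.frame of family, eve, locus_id, polymorphic),
#'   \code{perSample} (positive counts), \code{perLocus} (positive counts).
#' @export
parseScreenTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-(1:2)]
  body <- fields[-1L]
  n <- length(body)
  mat <- matrix(NA_character_, nrow = n, ncol = length(samples))
  fam <- eve <- character(n)
  for (i in seq_len(n)) {
    f <- body[[i]]
    fam[i] <- f[1L]
    eve[i] <- f[2L]
    syms <- f[-(1:2)]
    if (length(syms) > length(samples))
      stop("row ", i, " has more cells than samples")
    syms[!(syms %in% c("+", "-"))] <- NA_character_
    mat[i, seq_along(syms)] <- syms
  }
  ids <- paste(fam, eve)
  if (anyDuplicated(ids)) stop("duplicate locus ids in screen table")
  rownames(mat) <- ids
  colnames(mat) <- samples
  anCols <- grep("^An", samples)
  polymorphic <- vapply(seq_len(n), function(i) {
    v <- mat[i, anCols]
    any(v == "+", na.rm = TRUE) && any(v == "-", na.rm = TRUE)
  }, logical(1))
  list(matrix = mat,
       loci = data.frame(family = fam, eve = eve, locus_id = ids,
                         polymorphic = polymorphic, stringsAsFactors = FALSE),
       perSample = colSums(mat == "+", na.rm = TRUE),
       perLocus = rowSums(mat == "+", na.rm = TRUE))
}

#' Reference tallies from the published crustacean EVE survey
#'
#' Bundled summary counts of a six-genome crustacean EVE survey: per viral
#' group the number of EVEs and distinct lineages, and per screened species
#' the number of EVEs and shared-flank duplication events. Totals are not
#' stored; they are obtained by summation.
#'
#' @return A list of two data.frames: \code{groups} (group, n_eves,
#'   n_lineages) and \code{species} (species, n_eves, n_duplication_events).
#' @export
surveyReferenceCounts <- function() {
  gpath <- system.file("extdata", "survey_group_counts.tsv",
                       package = "paleovirome", mustWork = TRUE)
  spath <- system.file("extdata", "survey_species_counts.tsv",
                       package = "paleovirome", mustWork = TRUE)
  list(groups = utils::read.delim(gpath, stringsAsFactors = FALSE),
       species = utils::read.delim(spath, stringsAsFactors = FALSE))
}
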