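Package: paleovirome
Title: Discovery, Validation and Dating of Endogenous Viral Elements in
    Host Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end paleovirology toolkit for mining endogenous viral
    elements (EVEs) from multi-scaffold genome assemblies. Provides
    low-complexity masking, a seeded six-frame translated homology search with
    Karlin-Altschul E-values, reciprocal best-hit filtering against a host
    decoy protein set, merging of hits into classified EVE loci, flank-based
    validation of host origin via microsatellite and interspersed-repeat
    evidence, inference of post-insertional duplications from shared flanks,
    frameshift-aware degradation profiling against viral reference ORFs,
    detection of orthologous insertions between two assemblies with
    divergence-based dating, and lineage placement by progressive protein
    alignment, neighbor-joining and nonparametric bootstrap. A fully
    ground-truthed synthetic genome-pair simulator makes every stage testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Phylogenetics
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'params.R'
    'sequence-core.R'
    'seed-index.R'
    'scan.R'
    'simulate.R'
    'flanks.R'
    'degradation.R'
    'ortholog.R'
    'phylo.R'
    'pipeline.R'
    'paleovirome-package.R'
    'RcppExports.R'
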