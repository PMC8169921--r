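#' @include simulate.R
NULL

#' Base-level agreement between two compartment labelings
#'
#' Fraction of reference bases whose label is reproduced by the query set
#' (labels mapped through `mapping` first). Reference bases the query
#' leaves uncovered count as disagreement, so the value also penalizes
#' under-calling.
#'
#' @param query,reference [CompartmentSet-class]s on the same genome.
#' @param mapping Named character vector sending query labels to
#'   reference labels; defaults to identity.
#' @return Fraction in `[0, 1]`.
#' @export
compartmentAgreement <- function(query, reference, mapping = NULL) {
  q <- regions(query); r <- regions(reference)
  qlab <- as.character(mcols(q)$label)
  if (!is.null(mapping)) qlab <- unname(mapping[qlab])
  hits <- findOverlaps(q, r, ignore.strand = TRUE)
  w <- width(pintersect(q[S4Vectors::queryHits(hits)],
                        r[S4Vectors::subjectHits(hits)],
                        ignore.strand = TRUE))
  match <- qlab[S4Vectors::queryHits(hits)] ==
    as.character(mcols(r)$label)[S4Vectors::subjectHits(hits)]
  sum(w[match]) / sum(as.numeric(width(r)))
}

pipelineDefaults <- function() {
  list(outDir = ".", seed = 1L, repeatBinSize = 10000L,
       callingBinSize = 100000L, minSize = 500000L,
       fL1 = 0.19, fB1 = 0.03, epsilon = 1e-4,
       excludeChroms = c("chrX", "chrY"),
       nQuantiles = 50L, cornerFraction = 0.2, minSeparation = 2L,
       simulate = TRUE,
       annotation = NULL, chromSizes = NULL, hicCompartments = NULL,
       matrices = NULL)
}

stageRun <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full repeat-to-compartment pipeline
#'
#' Executes density -> log-ratio -> compartment calling -> overlap
#' scoring, and contact matrix -> O/E -> correlation -> eigenvector ->
#' saddle -> segregation, writing tracks, BED files, tables and a
#' machine-readable JSON report to `outDir`. With `simulate = TRUE`
#' (default) the inputs come from the bundled generators, seeded from
#' `seed`, and the calls are additionally scored against the planted
#' truth; otherwise `annotation`, `chromSizes`, and per-chromosome dense
#' `matrices` paths (and optionally `hicCompartments`) must point at real
#' input files.
#'
#' @param config A named list overriding defaults (see details), or the
#'   path to a YAML file of the same. Any field not supplied keeps its
#'   default: `outDir`, `seed`, `repeatBinSize` (10 kb), `callingBinSize`
#'   (100 kb), `minSize` (500 kb), `fL1` (0.19), `fB1` (0.03), `epsilon`,
#'   `excludeChroms` (chrX, chrY), `nQuantiles`, `cornerFraction`,
#'   `minSeparation`, `simulate`, `annotation`, `chromSizes`,
#'   `hicCompartments`, `matrices`.
#' @return The report, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- stageRun("simulate-genome", {
      simulateRepeatGenome(SyntheticGenomeSpec(seed = cfg$seed))
    })
    annotation <- sim$annotation; genome <- sim$genome; truth <- sim$truth
  } else {
    genome <- stageRun("read-chrom-sizes", {
      if (is.null(cfg$chromSizes) || !file.exists(cfg$chromSizes))
        stop("missing chromSizes file")
      readChromSizes(cfg$chromSizes)
    })
    annotation <- stageRun("read-annotation", {
      if (is.null(cfg$annotation) || !file.exists(cfg$annotation))
        stop("missing annotation file")
      readRepeatMasker(cfg$annotation, genome)
    })
  }
  dens <- stageRun("repeat-density", {
    list(l1 = binCoverage(annotation, genome, cfg$callingBinSize, "L1",
                          prefix = TRUE),
         b1 = binCoverage(annotation, genome, cfg$callingBinSize, "B1",
                          prefix = TRUE),
         l1Fine = binCoverage(annotation, genome, cfg$repeatBinSize, "L1",
                              prefix = TRUE),
         b1Fine = binCoverage(annotation, genome, cfg$repeatBinSize, "B1",
                              prefix = TRUE))
  })
  ratio <- stageRun("log-ratio", {
    logRatioTrack(dens$b1, dens$l1, fB1 = cfg$fB1, fL1 = cfg$fL1,
                  epsilon = cfg$epsilon)
  })
  called <- stageRun("compartment-calling", {
    callRepeatCompartments(ratio, minSize = cfg$minSize)
  })
  writeBedGraph(dens$l1Fine, file.path(cfg$outDir, "l1_density.bedgraph"))
  writeBedGraph(dens$b1Fine, file.path(cfg$outDir, "b1_density.bedgraph"))
  writeBedGraph(ratio, file.path(cfg$outDir, "log2_b1_l1.bedgraph"))
  writeCompartmentBED(called, file.path(cfg$outDir, "compartments.bed"))

  hic <- if (!is.null(cfg$hicCompartments)) {
    stageRun("read-hic-compartments",
             readCompartmentBED(cfg$hicCompartments, genome))
  } else if (!is.null(truth)) truth else NULL
  overlap <- NULL
  if (!is.null(hic)) {
    mapping <- if (all(c("A", "B") %in% hic@alphabet))
      c("B1-rich" = "A", "L1-rich" = "B")
    else c("B1-rich" = "B1-rich", "L1-rich" = "L1-rich")
    overlap <- stageRun("overlap-scoring", overlapScore(called, hic, mapping))
  }

  matrices <- stageRun("contact-matrices", {
    if (isTRUE(cfg$simulate)) {
      lapply(seqnames(genome), function(ch)
        simulateContactMatrix(truth, SyntheticHiCSpec(
          binSize = cfg$callingBinSize,
          seed = cfg$seed + match(ch, seqnames(genome))), chrom = ch))
    } else if (!is.null(cfg$matrices)) {
      lapply(names(cfg$matrices), function(ch) {
        if (!file.exists(cfg$matrices[[ch]]))
          stop("missing matrix file for ", ch)
        readDenseMatrix(cfg$matrices[[ch]], ch, cfg$callingBinSize)
      })
    } else list()
  })

  hicStats <- NULL
  if (length(matrices)) {
    hicStats <- stageRun("hic-statistics", {
      oes <- lapply(matrices, observedOverExpected)
      strengths <- numeric(0); evAcc <- numeric(0)
      for (i in seq_along(oes)) {
        ch <- oes[[i]]@chrom
        corr <- correlationMatrix(oes[[i]])
        anchor <- BinnedTrack(
          Seqinfo(ch, seqlengths(genome)[[ch]]), cfg$callingBinSize,
          stats::setNames(list(dens$b1@values[[ch]]), ch),
          "coverage_fraction")
        ev <- compartmentEigenvector(corr, anchor, chrom = ch)
        writeBedGraph(ev, file.path(cfg$outDir,
                                    paste0("eigenvector_", ch, ".bedgraph")))
        sad <- saddleStrength(oes[[i]], ev, nQuantiles = cfg$nQuantiles,
                              cornerFraction = cfg$cornerFraction,
                              minSeparation = cfg$minSeparation)
        if (i == 1L) writeSaddle(sad, file.path(cfg$outDir, "chr1"))
        strengths[ch] <- strength(sad)
      }
      seg <- segregationIndex(oes, if (!is.null(hic)) hic else called,
                              minSeparation = cfg$minSeparation,
                              excludeChroms = cfg$excludeChroms)
      writeSegregation(seg, file.path(cfg$outDir, "segregation.tsv"))
      list(strengths = strengths, segregation = seg)
    })
  }

  report <- list(
    package = as.character(utils::packageVersion("repeatcomp")),
    seed = cfg$seed,
    callingBinSize = cfg$callingBinSize,
    nCompartments = as.list(table(compartmentLabels(called))),
    medianCompartmentSizeBp =
      if (length(regions(called))) stats::median(width(regions(called)))
      else NA,
    overlapConsistent = if (!is.null(overlap))
      as.list(overlap@consistentFraction) else NULL,
    baseAgreement = if (!is.null(truth))
      compartmentAgreement(called, truth) else NULL,
    compartmentStrength = if (!is.null(hicStats))
      as.list(hicStats$strengths) else NULL,
    segregationIndex = if (!is.null(hicStats))
      segIndex(hicStats$segregation) else NULL)
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
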