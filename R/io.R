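# TSV interchange: datasets, results, configuration.
#
# All tables are tab-separated with a header row and "NA" for missing
# values.  Segment and gene coordinates are written 0-based half-open
# (BED convention) and converted to the in-memory 1-based closed GRanges
# representation on load.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, colClasses = NA,
                    comment.char = "")
}

#' Write a dataset to a directory of TSV files
#'
#' Emits cohort.tsv, drivers.tsv, snv.tsv, segments.tsv (BED-like,
#' 0-based half-open), clonality.tsv, timing.tsv, signatures.tsv,
#' signature_classes.tsv, truth.tsv, genome_chromosomes.tsv,
#' genome_genes.tsv and genome_meta.tsv.  Components that are empty are
#' skipped.
#'
#' @param dataset A \linkS4class{SexBiasDataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  .writeTsv(donorTable(dataset), p("cohort.tsv"))
  gm <- genomeModel(dataset)
  cl <- chromLengths(gm)
  .writeTsv(data.frame(chrom = names(cl), length_bp = unname(cl)),
            p("genome_chromosomes.tsv"))
  .writeTsv(data.frame(coding_size_bp = codingSize(gm)),
            p("genome_meta.tsv"))
  genes <- geneCatalogue(gm)
  if (length(genes))
    .writeTsv(data.frame(gene_id = genes$gene_id,
                         chrom = as.character(seqnames(genes)),
                         start = start(genes) - 1L, end = end(genes)),
              p("genome_genes.tsv"))
  if (ncol(driverMatrix(dataset))) {
    dm <- as.data.frame(driverMatrix(dataset))
    dm <- cbind(donor_id = rownames(dm), dm)
    .writeTsv(dm, p("drivers.tsv"))
  }
  if (nrow(snvTable(dataset))) .writeTsv(snvTable(dataset), p("snv.tsv"))
  seg <- segmentTable(dataset)
  if (length(seg))
    .writeTsv(data.frame(donor_id = seg$donor_id,
                         chrom = as.character(seqnames(seg)),
                         start = start(seg) - 1L, end = end(seg),
                         call = seg$call),
              p("segments.tsv"))
  if (nrow(clonalityTable(dataset)))
    .writeTsv(clonalityTable(dataset), p("clonality.tsv"))
  if (nrow(timingTable(dataset)))
    .writeTsv(timingTable(dataset), p("timing.tsv"))
  if (ncol(signatureCounts(dataset))) {
    sm <- as.data.frame(signatureCounts(dataset))
    sm <- cbind(donor_id = rownames(sm), sm)
    .writeTsv(sm, p("signatures.tsv"))
    sc <- signatureClasses(dataset)
    .writeTsv(data.frame(signature = names(sc), class = unname(sc)),
              p("signature_classes.tsv"))
  }
  if (nrow(plantedTruth(dataset)))
    .writeTsv(plantedTruth(dataset), p("truth.tsv"))
  invisible(dir)
}

#' Read a dataset from a directory of TSV files
#'
#' The inverse of [writeDataset()], with validation: duplicate donor ids,
#' unknown chromosomes, non-positive intervals and donors missing from
#' the cohort are rejected with the offending file (and row, where
#' applicable) named.
#'
#' @param dir Directory written by [writeDataset()] (or assembled by
#'   hand in the same layout).
#' @param require Component names whose files must be present
#'   (e.g. `"segments"` when a CNA analysis is planned); a missing file
#'   is an error naming the file.
#' @return A \linkS4class{SexBiasDataset}.
#' @export
readDataset <- function(dir, require = character()) {
  p <- function(f) file.path(dir, f)
  for (comp in require) {
    f <- p(paste0(comp, ".tsv"))
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  cohort <- .readTsv(p("cohort.tsv"))
  cohort$donor_id <- as.character(cohort$donor_id)
  for (col in c("stage", "grade", "sex", "ancestry", "subtype"))
    cohort[[col]] <- as.character(cohort[[col]])
  if (anyDuplicated(cohort$donor_id))
    stop("cohort.tsv: duplicate donor ids")
  chroms <- .readTsv(p("genome_chromosomes.tsv"))
  meta <- .readTsv(p("genome_meta.tsv"))
  si <- Seqinfo(seqnames = as.character(chroms$chrom),
                seqlengths = as.integer(chroms$length_bp))
  genes <- GRanges(seqinfo = si)
  if (file.exists(p("genome_genes.tsv"))) {
    gdf <- .readTsv(p("genome_genes.tsv"))
    genes <- GRanges(as.character(gdf$chrom),
                     IRanges(start = gdf$start + 1L, end = gdf$end),
                     gene_id = gdf$gene_id, seqinfo = si)
  }
  genome <- new("GenomeModel", genes = genes,
                codingSize = meta$coding_size_bp)
  readIf <- function(f) if (file.exists(p(f))) .readTsv(p(f)) else NULL
  toMatrix <- function(df, what) {
    if (is.null(df)) return(matrix(integer(), 0L, 0L))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$donor_id)
    storage.mode(m) <- "integer"
    bad <- which(!rownames(m) %in% cohort$donor_id)
    if (length(bad))
      stop(what, ": donor absent from cohort in row ", bad[1])
    m
  }
  drivers <- toMatrix(readIf("drivers.tsv"), "drivers.tsv")
  snv <- readIf("snv.tsv")
  if (is.null(snv))
    snv <- .emptyDf(donor_id = "character", coding_count = "integer",
                    noncoding_count = "integer")
  else snv$donor_id <- as.character(snv$donor_id)
  segments <- GRanges(seqinfo = si)
  sdf <- readIf("segments.tsv")
  if (!is.null(sdf)) {
    bad <- which(!as.character(sdf$chrom) %in% names(chromLengths(genome)))
    if (length(bad))
      stop("segments.tsv: unknown chromosome in row ", bad[1])
    bad <- which(sdf$start < 0)
    if (length(bad))
      stop("segments.tsv: negative coordinate in row ", bad[1])
    bad <- which(sdf$end <= sdf$start)
    if (length(bad))
      stop("segments.tsv: end <= start in row ", bad[1])
    lim <- chromLengths(genome)[as.character(sdf$chrom)]
    bad <- which(sdf$end > lim)
    if (length(bad))
      stop("segments.tsv: segment beyond chromosome end in row ", bad[1])
    segments <- sort(GRanges(as.character(sdf$chrom),
                             IRanges(start = sdf$start + 1L,
                                     end = sdf$end),
                             donor_id = as.character(sdf$donor_id),
                             call = as.character(sdf$call),
                             seqinfo = si))
  }
  clonality <- readIf("clonality.tsv") %||%
    .emptyDf(donor_id = "character", n_clusters = "integer")
  clonality$donor_id <- as.character(clonality$donor_id)
  timing <- readIf("timing.tsv") %||%
    .emptyDf(donor_id = "character", variant_class = "character",
             n_truncal = "integer", n_subclonal = "integer")
  timing$donor_id <- as.character(timing$donor_id)
  signatures <- toMatrix(readIf("signatures.tsv"), "signatures.tsv")
  sigClass <- character()
  scf <- readIf("signature_classes.tsv")
  if (!is.null(scf))
    sigClass <- stats::setNames(as.character(scf$class),
                                as.character(scf$signature))
  truth <- readIf("truth.tsv") %||% assembleTruth(list())
  new("SexBiasDataset", cohort = cohort, drivers = drivers, snv = snv,
      segments = segments, clonality = clonality, timing = timing,
      signatures = signatures, signatureClass = sigClass,
      genome = genome, truth = truth)
}

# tiny deterministic content hash (polynomial rolling hash over the
# serialized object), enough to fingerprint a configuration in a manifest
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write pipeline results to a directory
#'
#' One TSV per stage (stage1.tsv, stage2.tsv, robustness.tsv,
#' extended.tsv), the combined findings.tsv, truth_comparison.tsv when
#' planted truth was available, and a machine-readable manifest.yaml with
#' the configuration hash, seed and package version.
#'
#' @param report A \linkS4class{SexBiasReport}.
#' @param dir Output directory.
#' @param seed The master seed of the run (recorded in the manifest).
#' @return Invisibly, the directory.
#' @export
writeResults <- function(report, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  .writeTsv(stage1Results(report), p("stage1.tsv"))
  .writeTsv(stage2Results(report), p("stage2.tsv"))
  .writeTsv(robustnessResults(report), p("robustness.tsv"))
  .writeTsv(extendedResults(report), p("extended.tsv"))
  .writeTsv(findingsTable(report), p("findings.tsv"))
  if (nrow(truthComparison(report)))
    .writeTsv(truthComparison(report), p("truth_comparison.tsv"))
  manifest <- list(
    package = "SomaticSexBias",
    version = as.character(utils::packageVersion("SomaticSexBias")),
    config_hash = .configHash(report@config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(dir)
}

#' Write a pipeline configuration to YAML
#'
#' Named atomic vectors (chromosome lengths, per-subtype rates, category
#' probabilities) are emitted as YAML maps so their names survive the
#' round trip; [readPipelineConfig()] reverses the conversion.
#'
#' @param config A [pipelineConfig()] list.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writePipelineConfig <- function(config, path) {
  mapify <- function(x) {
    if (is.data.frame(x)) return(lapply(x, mapify))
    if (is.list(x)) return(lapply(x, mapify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(mapify(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document mirrors the [pipelineConfig()] list structure; any
#' omitted entry falls back to the package default.  Named lists under
#' `simulation` are passed through unchanged, so the full simulator
#' surface is reachable from a plain-text configuration.
#'
#' @param path Path to a YAML file.
#' @return A PipelineConfig list.
#' @export
readPipelineConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  sim <- doc$simulation %||% demoSimulationConfig()
  # YAML maps come back as named lists; the simulator expects named
  # numeric vectors for these fields
  unl <- function(x) if (is.list(x)) unlist(x) else x
  sim$genome$chromLengths <- unl(sim$genome$chromLengths)
  if (!is.null(sim$genome$chromLengths) &&
      is.null(names(sim$genome$chromLengths)))
    names(sim$genome$chromLengths) <-
      as.character(seq_along(sim$genome$chromLengths))
  sim$cohort$ancestryProbs <- unl(sim$cohort$ancestryProbs)
  sim$cohort$stageProbs <- unl(sim$cohort$stageProbs)
  sim$cohort$gradeProbs <- unl(sim$cohort$gradeProbs)
  sim$cohort$missing <- unl(sim$cohort$missing)
  sim$snv$ratePerMbp <- unl(sim$snv$ratePerMbp)
  sim$cna$gainProb <- unl(sim$cna$gainProb)
  sim$cna$lossProb <- unl(sim$cna$lossProb)
  sim$cna$lenShape <- unl(sim$cna$lenShape)
  if (!is.null(sim$signatures$classTotals))
    sim$signatures$classTotals <- lapply(sim$signatures$classTotals, unl)
  if (!is.null(sim$signatures$catalogue) &&
      !is.data.frame(sim$signatures$catalogue))
    sim$signatures$catalogue <-
      as.data.frame(lapply(sim$signatures$catalogue, unlist),
                    stringsAsFactors = FALSE)
  args <- doc[setdiff(names(doc), "simulation")]
  do.call(pipelineConfig, c(list(simulation = sim), args))
}
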