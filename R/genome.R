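# Autosomal genome model construction.

#' Default genome configuration
#'
#' Chromosome sizes approximate the GRCh37 autosomes (2.88 Gbp total).  The
#' coding size defaults to 34 Mbp, roughly 1.2% of the autosomes, matching
#' the order of magnitude of consensus exome annotations.  The gene
#' catalogue is synthetic: `genesPerChrom` non-overlapping intervals are
#' placed per chromosome purely to support gene-level copy number calling;
#' it is a stand-in, not a real annotation.
#'
#' @param genesPerChrom Number of genes to place on each chromosome.
#' @param geneSize Target gene length in bp.
#' @return A list understood by [makeGenomeModel()].
#' @export
defaultGenomeConfig <- function(genesPerChrom = 10L, geneSize = 1e5) {
  lengths <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
               115, 107, 102, 90, 81, 78, 59, 63, 48, 51) * 1e6
  names(lengths) <- as.character(1:22)
  list(chromLengths = lengths, codingSize = 34e6,
       genesPerChrom = genesPerChrom, geneSize = geneSize)
}

#' Build a GenomeModel
#'
#' Places `genesPerChrom` non-overlapping genes on each chromosome by
#' dividing the chromosome into equal bins and sampling one sub-interval
#' per bin, which guarantees disjointness by construction.  Deterministic
#' given `(config, seed)`.
#'
#' @param config List with `chromLengths` (named by chromosome, subset of
#'   "1".."22"), `codingSize` (bp), `genesPerChrom` and optionally
#'   `geneSize` (bp).
#' @param seed Integer seed for gene placement.
#' @return A \linkS4class{GenomeModel}.
#' @export
#' @examples
#' gm <- makeGenomeModel(defaultGenomeConfig(), seed = 1)
#' length(geneCatalogue(gm))
makeGenomeModel <- function(config, seed = 1L) {
  cl <- config$chromLengths
  if (is.null(names(cl)) || !all(names(cl) %in% as.character(1:22)))
    stop("chromLengths must be named by autosome ('1'..'22')")
  if (any(!is.finite(cl)) || any(cl <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(config$codingSize) || config$codingSize <= 0)
    stop("codingSize must be positive")
  nGenes <- as.integer(config$genesPerChrom %||% 0L)
  geneSize <- as.double(config$geneSize %||% 1e5)
  si <- Seqinfo(seqnames = names(cl), seqlengths = as.integer(round(cl)))
  genes <- GRanges(seqinfo = si)
  if (nGenes > 0L) {
    genes <- withSeed(childSeed(seed, .seedStreams[["genome"]]), {
      pieces <- lapply(names(cl), function(ch) {
        L <- as.integer(round(cl[[ch]]))
        bin <- L %/% nGenes
        if (bin < 2L)
          stop("gene count infeasible for chromosome ", ch)
        len <- pmax(1L, pmin(as.integer(geneSize), bin - 1L))
        maxStart <- bin - len        # per-bin slack for random placement
        off <- (seq_len(nGenes) - 1L) * bin
        st <- off + 1L + floor(stats::runif(nGenes) * (maxStart + 1L))
        GRanges(ch, IRanges(start = st, width = len),
                gene_id = sprintf("g%s_%02d", ch, seq_len(nGenes)),
                seqinfo = si)
      })
      sort(do.call(c, pieces))
    })
  }
  new("GenomeModel", genes = genes, codingSize = as.double(config$codingSize))
}
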