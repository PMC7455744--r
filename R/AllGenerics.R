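# Generics for the package's accessor surface.  Slot access from user code
# is discouraged; these are the supported entry points.

#' @rdname GenomeModel-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("chromLengths", function(object) standardGeneric("chromLengths"))

#' @rdname GenomeModel-class
#' @export
setGeneric("codingSize", function(object) standardGeneric("codingSize"))

#' @rdname GenomeModel-class
#' @export
setGeneric("autosomeSize", function(object) standardGeneric("autosomeSize"))

#' @rdname GenomeModel-class
#' @export
setGeneric("geneCatalogue", function(object) standardGeneric("geneCatalogue"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("donorTable", function(object) standardGeneric("donorTable"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("driverMatrix", function(object) standardGeneric("driverMatrix"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("snvTable", function(object) standardGeneric("snvTable"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("clonalityTable",
           function(object) standardGeneric("clonalityTable"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("timingTable", function(object) standardGeneric("timingTable"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("signatureCounts",
           function(object) standardGeneric("signatureCounts"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("signatureClasses",
           function(object) standardGeneric("signatureClasses"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("genomeModel", function(object) standardGeneric("genomeModel"))

#' @rdname SexBiasDataset-class
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("stage1Results", function(object) standardGeneric("stage1Results"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("stage2Results", function(object) standardGeneric("stage2Results"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("robustnessResults",
           function(object) standardGeneric("robustnessResults"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("extendedResults",
           function(object) standardGeneric("extendedResults"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("findingsTable", function(object) standardGeneric("findingsTable"))

#' @rdname SexBiasReport-class
#' @export
setGeneric("truthComparison",
           function(object) standardGeneric("truthComparison"))
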