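#' Accessors for bayesrmap classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object a bayesrmap object.
#' @name accessors
NULL

#' @describeIn accessors allele-count matrix (SNPs x samples) of a panel.
#' @export
setGeneric("alleleCounts", function(object) standardGeneric("alleleCounts"))
#' @export
setMethod("alleleCounts", "GenotypePanel",
          function(object) assay(object, "counts"))

#' @describeIn accessors per-SNP metadata (id, chrom, pos, freq) as a data.frame.
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))
#' @export
setMethod("snpInfo", "GenotypePanel", function(object) {
  rr <- rowRanges(object)
  data.frame(id = names(rr), chrom = as.character(seqnames(rr)),
             pos = start(rr), freq = mcols(rr)$freq,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @describeIn accessors age-rank permutation (1 = oldest).
#' @export
setGeneric("sampleOrder", function(object) standardGeneric("sampleOrder"))
#' @export
setMethod("sampleOrder", "GenotypePanel",
          function(object) colData(object)$sampleOrder)

#' @describeIn accessors counted-allele frequencies f_j.
#' @export
setGeneric("snpFrequencies", function(object) standardGeneric("snpFrequencies"))
#' @export
setMethod("snpFrequencies", "GenotypePanel",
          function(object) mcols(rowRanges(object))$freq)

#' @describeIn accessors phased haplotype array (p x n x 2) or NULL.
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))
#' @export
setMethod("haplotypes", "GenotypePanel",
          function(object) metadata(object)$haplotypes)

#' @describeIn accessors read-time import report (imputed genotype and
#'   skipped record counts), or NULL for panels not built by [readGenotypes()].
#' @export
setGeneric("importReport", function(object) standardGeneric("importReport"))
#' @export
setMethod("importReport", "GenotypePanel",
          function(object) metadata(object)$importReport)

#' @describeIn accessors n x p standardized design matrix.
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @export
setMethod("designMatrix", "StandardizedGenotypes", function(object) object@values)

#' @describeIn accessors learning-set sample indices.
#' @export
setGeneric("learningSet", function(object) standardGeneric("learningSet"))
#' @export
setMethod("learningSet", "SplitSpec", function(object) object@learning)
#' @export
setMethod("learningSet", "SimulatedDataset",
          function(object) learningSet(object@split))

#' @describeIn accessors validation-set sample indices.
#' @export
setGeneric("validationSet", function(object) standardGeneric("validationSet"))
#' @export
setMethod("validationSet", "SplitSpec", function(object) object@validation)
#' @export
setMethod("validationSet", "SimulatedDataset",
          function(object) validationSet(object@split))

#' @describeIn accessors p x 4 posterior class-inclusion probability matrix.
#' @export
setGeneric("pipMatrix", function(object) standardGeneric("pipMatrix"))
#' @export
setMethod("pipMatrix", "PosteriorSummary", function(object) object@pip)

#' @describeIn accessors posterior mean SNP effects.
#' @export
setGeneric("betaMean", function(object) standardGeneric("betaMean"))
#' @export
setMethod("betaMean", "PosteriorSummary", function(object) object@betaMean)

#' @describeIn accessors posterior mean of squared SNP effects.
#' @export
setGeneric("betaSqMean", function(object) standardGeneric("betaSqMean"))
#' @export
setMethod("betaSqMean", "PosteriorSummary", function(object) object@betaSqMean)

#' @describeIn accessors posterior mean additive genetic variance.
#' @export
setGeneric("sigmaG2Mean", function(object) standardGeneric("sigmaG2Mean"))
#' @export
setMethod("sigmaG2Mean", "PosteriorSummary", function(object) object@sigmaG2Mean)

#' @describeIn accessors posterior mean residual variance.
#' @export
setGeneric("sigmaE2Mean", function(object) standardGeneric("sigmaE2Mean"))
#' @export
setMethod("sigmaE2Mean", "PosteriorSummary", function(object) object@sigmaE2Mean)

#' @describeIn accessors posterior mean intercept.
#' @export
setGeneric("muMean", function(object) standardGeneric("muMean"))
#' @export
setMethod("muMean", "PosteriorSummary", function(object) object@muMean)

#' @describeIn accessors posterior mean class cardinalities.
#' @export
setGeneric("classCountsMean", function(object) standardGeneric("classCountsMean"))
#' @export
setMethod("classCountsMean", "PosteriorSummary",
          function(object) object@classCountsMean)

#' @describeIn accessors posterior mean mixing proportions.
#' @export
setGeneric("piMean", function(object) standardGeneric("piMean"))
#' @export
setMethod("piMean", "PosteriorSummary", function(object) object@piMean)

#' @describeIn accessors the generating Scenario of a SimulatedDataset.
#' @export
setGeneric("scenarioOf", function(object) standardGeneric("scenarioOf"))
#' @export
setMethod("scenarioOf", "SimulatedDataset", function(object) object@scenario)

#' @describeIn accessors per-QTL truth windows (list of index vectors).
#' @export
setGeneric("truthWindows", function(object) standardGeneric("truthWindows"))
#' @export
setMethod("truthWindows", "SimulatedDataset", function(object) object@truthWindows)

#' @describeIn accessors the TraitArchitecture of a SimulatedDataset.
#' @export
setGeneric("architecture", function(object) standardGeneric("architecture"))
#' @export
setMethod("architecture", "SimulatedDataset", function(object) object@architecture)

#' @describeIn accessors simulated phenotypes of a SimulatedDataset.
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @export
setMethod("phenotypes", "SimulatedDataset", function(object) object@y)
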