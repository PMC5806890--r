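#' @describeIn ExpressionMatrix expression values matrix
#' @param x object.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @describeIn ExpressionMatrix data-kind tag
#' @export
exprKind <- function(x) x@kind

#' @describeIn ExpressionMatrix gene ids
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn ExpressionMatrix sample ids
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn ScoredNetwork edge table (geneA, geneB, score, ...)
#' @param x object.
#' @export
edgeTable <- function(x) x@edges

#' @describeIn ScoredNetwork node universe
#' @export
nodeUniverse <- function(x) x@nodes

#' @describeIn ScoredNetwork number of edges
#' @export
edgeCount <- function(x) nrow(x@edges)

#' @describeIn ScoredNetwork method provenance tag
#' @export
methodTag <- function(x) x@method

#' @describeIn ScoredNetwork dataset provenance tag
#' @export
datasetTag <- function(x) x@dataset

#' @describeIn GoldStandard positive pair set
#' @param x object.
#' @export
positivePairs <- function(x) x@positives

#' @describeIn GoldStandard negative pair set
#' @export
negativePairs <- function(x) x@negatives

#' @describeIn GoldStandard size of the gene universe
#' @export
universeSize <- function(x) x@universeN

#' @describeIn OntologyDAG term ids
#' @param x object.
#' @export
ontologyTerms <- function(x) x@terms

#' @describeIn OntologyDAG direct gene annotations (named list)
#' @export
geneAnnotations <- function(x) x@annotations

setMethod("show", "ExpressionMatrix", function(object) {
  v <- exprValues(object)
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              object@kind, nrow(v), ncol(v)))
})

setMethod("show", "ScoredNetwork", function(object) {
  tags <- paste0(
    if (nzchar(object@method)) paste0("method=", object@method) else NULL,
    if (nzchar(object@method) && nzchar(object@dataset)) ", " else "",
    if (nzchar(object@dataset)) paste0("dataset=", object@dataset) else NULL)
  cat(sprintf("ScoredNetwork: %d edges over %d nodes%s\n",
              nrow(object@edges), length(object@nodes),
              if (nzchar(tags)) paste0(" (", tags, ")") else ""))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork [%s]: %d edges over %d nodes\n",
              object@level, nrow(object@edges), length(object@nodes)))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d namespaces, %d annotated genes\n",
              length(object@terms), length(unique(object@namespace)),
              length(object@annotations)))
})

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d positives, %d negatives, universe N = %g\n",
              nrow(object@positives), nrow(object@negatives),
              object@universeN))
})
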