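#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

.EXPR_KINDS <- c("raw_counts", "fpkm", "uq", "tmm", "rle", "vst")
.METHOD_TAGS <- c("wgcna", "ggm", "bc3net")
.DATASET_TAGS <- c("raw", "fpkm", "uq", "tmm", "rle", "vst")

#' ExpressionMatrix: a gene x sample expression matrix with a data-kind tag
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"values"} (genes in rows, samples in columns) plus a
#' \code{kind} tag recording whether the values are raw counts or one of the
#' normalized representations the pipeline works with.
#'
#' @slot kind one of \code{"raw_counts"}, \code{"fpkm"}, \code{"uq"},
#'   \code{"tmm"}, \code{"rle"}, \code{"vst"}.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(kind = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  v <- SummarizedExperiment::assay(object, "values")
  if (length(object@kind) != 1L || !(object@kind %in% .EXPR_KINDS)) {
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.EXPR_KINDS, collapse = ", ")))
  }
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    msgs <- c(msgs, "gene and sample ids (dimnames) are required")
  } else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate sample ids")
  }
  if (!all(is.finite(v))) msgs <- c(msgs, "values must be finite")
  if (identical(object@kind, "raw_counts")) {
    if (any(v < 0)) msgs <- c(msgs, "raw counts must be non-negative")
    if (any(abs(v - round(v)) > 1e-8)) {
      msgs <- c(msgs, "raw_counts requires integer-valued entries")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param kind data-kind tag; \code{"raw_counts"} entries must be
#'   integer-valued.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ExpressionMatrix(m, "raw_counts")
#' @export
ExpressionMatrix <- function(values, kind = "raw_counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values))
  new("ExpressionMatrix", se, kind = kind)
}

#' ScoredNetwork: an undirected, scored gene network
#'
#' Holds a set of unordered gene pairs with non-negative confidence scores,
#' the node universe the network was inferred over, and provenance tags
#' (inference method and source dataset).
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{score} (plus optional extra columns); \code{geneA < geneB}
#'   lexicographically in every row.
#' @slot nodes character vector of the gene universe.
#' @slot method method tag (\code{"wgcna"}, \code{"ggm"}, \code{"bc3net"}
#'   or \code{""} when not applicable).
#' @slot dataset dataset tag (\code{"raw"}, \code{"fpkm"}, \code{"uq"},
#'   \code{"tmm"}, \code{"rle"}, \code{"vst"} or \code{""}).
#' @export
setClass("ScoredNetwork",
  representation(edges = "data.frame", nodes = "character",
                 method = "character", dataset = "character")
)

setValidity("ScoredNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  need <- c("geneA", "geneB", "score")
  if (!all(need %in% names(e))) {
    return(sprintf("edges needs columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(e$geneA == e$geneB)) msgs <- c(msgs, "self-loops not allowed")
    if (any(e$geneA > e$geneB)) {
      msgs <- c(msgs, "edges must be canonical: geneA < geneB")
    }
    if (anyDuplicated(paste(e$geneA, e$geneB))) {
      msgs <- c(msgs, "duplicate gene pairs")
    }
    if (!all(c(e$geneA, e$geneB) %in% object@nodes)) {
      msgs <- c(msgs, "edge endpoints must belong to the node universe")
    }
    if (!all(is.finite(e$score))) msgs <- c(msgs, "scores must be finite")
  }
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicate node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScoredNetwork
#'
#' Pairs are canonicalized (geneA < geneB) and deduplicated is an error, not
#' silent; scores must be finite.
#'
#' @param edges data.frame with columns geneA, geneB, score.
#' @param nodes node universe; defaults to the genes appearing in edges.
#' @param method,dataset provenance tags.
#' @return a \linkS4class{ScoredNetwork}.
#' @export
ScoredNetwork <- function(edges, nodes = NULL, method = "", dataset = "") {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    a <- pmin(as.character(edges$geneA), as.character(edges$geneB))
    b <- pmax(as.character(edges$geneA), as.character(edges$geneB))
    edges$geneA <- a
    edges$geneB <- b
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$geneA, edges$geneB)))
  new("ScoredNetwork", edges = edges, nodes = as.character(nodes),
      method = method, dataset = dataset)
}

#' ConsensusNetwork: a voted ensemble network
#'
#' A \linkS4class{ScoredNetwork} whose \code{edges} carry an integer
#' \code{support} column (number of contributing source networks) and whose
#' \code{level} records the voting stage.
#'
#' @slot level \code{"intra_method"} or \code{"final"}.
#' @export
setClass("ConsensusNetwork",
  contains = "ScoredNetwork",
  representation(level = "character")
)

setValidity("ConsensusNetwork", function(object) {
  msgs <- character()
  if (!(object@level %in% c("intra_method", "final"))) {
    msgs <- c(msgs, "level must be 'intra_method' or 'final'")
  }
  if (!"support" %in% names(object@edges)) {
    msgs <- c(msgs, "edges needs a 'support' column")
  }
  if (nrow(object@edges) &&
      (any(object@edges$score < 0) || any(object@edges$score > 1))) {
    msgs <- c(msgs, "consensus scores must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' OntologyDAG: a rooted acyclic is-a ontology with gene annotations
#'
#' @slot terms character vector of term ids.
#' @slot parents named list: term id -> character vector of is-a parents
#'   (empty vector for roots).
#' @slot namespace named character: term id -> namespace label.
#' @slot annotations named list: gene id -> character vector of directly
#'   annotated term ids.
#' @export
setClass("OntologyDAG",
  representation(terms = "character", parents = "list",
                 namespace = "character", annotations = "list")
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  trm <- object@terms
  if (anyDuplicated(trm)) msgs <- c(msgs, "duplicate term ids")
  if (!all(names(object@parents) %in% trm)) {
    msgs <- c(msgs, "parents map refers to unknown child terms")
  }
  allpar <- unlist(object@parents, use.names = FALSE)
  if (length(allpar) && !all(allpar %in% trm)) {
    msgs <- c(msgs, "parents map refers to unknown parent terms")
  }
  ann <- unlist(object@annotations, use.names = FALSE)
  if (length(ann) && !all(ann %in% trm)) {
    msgs <- c(msgs, "annotations refer to unknown terms")
  }
  # acyclicity via topological sort
  if (!length(msgs) && length(trm)) {
    if (is.null(.topoOrder(object))) msgs <- c(msgs, "ontology contains a cycle")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OntologyDAG
#'
#' @param terms term ids.
#' @param parents named list mapping each term to its is-a parents; terms
#'   missing from the list are roots.
#' @param namespace named character of namespace labels per term; defaults
#'   to a single namespace \code{"all"}.
#' @param annotations named list mapping genes to their directly annotated
#'   terms.
#' @return an \linkS4class{OntologyDAG}.
#' @export
OntologyDAG <- function(terms, parents = list(), namespace = NULL,
                        annotations = list()) {
  terms <- as.character(terms)
  full <- setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) full[[t]] <- as.character(parents[[t]])
  for (t in terms) if (is.null(full[[t]])) full[[t]] <- character()
  if (is.null(namespace)) namespace <- setNames(rep("all", length(terms)), terms)
  new("OntologyDAG", terms = terms, parents = full,
      namespace = namespace, annotations = annotations)
}

#' GoldStandard: positive and negative functional gene-link sets
#'
#' @slot positives data.frame of unordered gene pairs (geneA < geneB)
#'   assumed functionally linked.
#' @slot negatives data.frame of unordered gene pairs assumed unlinked;
#'   disjoint from positives.
#' @slot universeN number of genes in the reference space.
#' @export
setClass("GoldStandard",
  representation(positives = "data.frame", negatives = "data.frame",
                 universeN = "numeric")
)

setValidity("GoldStandard", function(object) {
  msgs <- character()
  for (nm in c("positives", "negatives")) {
    e <- slot(object, nm)
    if (!all(c("geneA", "geneB") %in% names(e))) {
      msgs <- c(msgs, sprintf("%s needs geneA/geneB columns", nm))
    } else if (nrow(e)) {
      if (any(e$geneA == e$geneB)) msgs <- c(msgs, sprintf("%s has self-pairs", nm))
      if (any(e$geneA > e$geneB)) msgs <- c(msgs, sprintf("%s not canonical", nm))
    }
  }
  if (!length(msgs)) {
    pk <- paste(object@positives$geneA, object@positives$geneB)
    nk <- paste(object@negatives$geneA, object@negatives$geneB)
    if (length(intersect(pk, nk))) {
      msgs <- c(msgs, "positives and negatives must be disjoint")
    }
  }
  if (object@universeN <= 0) msgs <- c(msgs, "universeN must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GoldStandard
#'
#' Pairs are canonicalized; any pair present in both sets is dropped from
#' the negatives (with a message), mirroring how curated positives take
#' precedence over similarity-derived negatives.
#'
#' @param positives,negatives data.frames with geneA/geneB columns.
#' @param universeN total number of genes in the reference space.
#' @return a \linkS4class{GoldStandard}.
#' @export
GoldStandard <- function(positives, negatives, universeN) {
  canon <- function(e) {
    e <- as.data.frame(e)
    if (!nrow(e)) return(data.frame(geneA = character(), geneB = character()))
    a <- pmin(as.character(e$geneA), as.character(e$geneB))
    b <- pmax(as.character(e$geneA), as.character(e$geneB))
    e <- data.frame(geneA = a, geneB = b)
    e[!duplicated(paste(e$geneA, e$geneB)) & e$geneA != e$geneB, , drop = FALSE]
  }
  pos <- canon(positives)
  neg <- canon(negatives)
  overlap <- paste(neg$geneA, neg$geneB) %in% paste(pos$geneA, pos$geneB)
  if (any(overlap)) {
    message(sum(overlap), " pair(s) in both sets dropped from negatives")
    neg <- neg[!overlap, , drop = FALSE]
  }
  rownames(pos) <- rownames(neg) <- NULL
  new("GoldStandard", positives = pos, negatives = neg,
      universeN = as.numeric(universeN))
}
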