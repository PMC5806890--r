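#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of gene ids. The
#' reader validates rectangularity and numeric parsing; raw counts written
#' with \code{\link{writeExpressionMatrix}} round-trip bit-identically.
#'
#' @param path file path.
#' @param kind data-kind tag for the result (default \code{"raw_counts"}).
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, kind = "raw_counts") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1L,
                          colClasses = "character", comment.char = "")
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric entries in expression matrix: ", path)
  ExpressionMatrix(m, kind = kind)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  v <- exprValues(m)
  if (exprKind(m) == "raw_counts") storage.mode(v) <- "integer"
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scored network as a tab-separated edge list
#'
#' Edges are written as \code{geneA geneB score} (plus any extra columns,
#' e.g. \code{support}), with \code{geneA < geneB} lexicographically, sorted
#' by descending score then lexicographic pair. Provenance tags go into a
#' \code{#} comment header line.
#'
#' @param net a \linkS4class{ScoredNetwork}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- edgeTable(net)
  if (nrow(e)) {
    e <- e[order(-e$score, e$geneA, e$geneB), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s dataset=%s nodes=%d",
                     methodTag(net), datasetTag(net),
                     length(nodeUniverse(net))), con)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two- or three-column edge list
#'
#' Lines starting with \code{#} are ignored. A third column, when present,
#' is taken as the score (otherwise score 1). A header line whose first two
#' fields are \code{geneA geneB} is skipped.
#'
#' @param path file path.
#' @param nodes optional node universe; defaults to the genes seen.
#' @return a \linkS4class{ScoredNetwork}.
#' @export
readEdgeList <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) && grepl("^geneA\tgeneB", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) {
    return(ScoredNetwork(data.frame(geneA = character(), geneB = character(),
                                    score = numeric()), nodes = nodes))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) stop("edge list rows need at least two columns")
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 3L) p[[3L]] else "1", "")))
  if (anyNA(s)) stop("non-numeric scores in edge list")
  e <- data.frame(geneA = a, geneB = b, score = s)
  e <- e[!duplicated(.pairKeys(e$geneA, e$geneB)), , drop = FALSE]
  ScoredNetwork(e, nodes = nodes)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> members).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("GMT rows need name, description, members")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional descriptions (default \code{"na"}).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal OBO ontology (is_a relationships)
#'
#' Parses \code{[Term]} stanzas for \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and (optionally) \code{part_of}
#' relationships; obsolete terms are skipped. This is a deliberately small
#' subset of OBO sufficient for is-a DAGs.
#'
#' @param path file path.
#' @param part_of treat \code{relationship: part_of} as a parent link too.
#' @return an \linkS4class{OntologyDAG} with no annotations.
#' @export
readObo <- function(path, part_of = FALSE) {
  lines <- readLines(path)
  terms <- character()
  parents <- list()
  namespace <- character()
  cur <- NULL
  cur_parents <- character()
  cur_ns <- "all"
  obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      parents[[cur]] <<- cur_parents
      namespace[cur] <<- cur_ns
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL
      cur_parents <- character()
      cur_ns <- "all"
      obsolete <- FALSE
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL
      in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "namespace:")) {
        cur_ns <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
      } else if (part_of && grepl("^relationship:\\s*part_of", ln)) {
        cur_parents <- c(cur_parents,
                         trimws(sub("^relationship:\\s*part_of", "", ln)))
      } else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
    }
  }
  flush()
  OntologyDAG(terms, parents, namespace)
}

#' Write a minimal OBO file
#'
#' @param dag an \linkS4class{OntologyDAG} (annotations are not written;
#'   see \code{\link{writeAnnotations}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag@terms) {
    ps <- dag@parents[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ", dag@namespace[[t]]),
                 if (length(ps)) paste0("is_a: ", ps)), con)
  }
  invisible(path)
}

#' Read gene-to-term annotations (two-column tab-separated)
#'
#' @param path file path with columns gene id, term id (no header).
#' @return named list gene -> term ids.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  split(df[[2L]], df[[1L]])
}

#' Write gene-to-term annotations
#'
#' @param annotations named list gene -> term ids.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach annotations to an ontology
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param annotations named list gene -> term ids.
#' @return the annotated \linkS4class{OntologyDAG}.
#' @export
setAnnotations <- function(dag, annotations) {
  dag@annotations <- lapply(annotations, function(x) unique(as.character(x)))
  methods::validObject(dag)
  dag
}
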