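# internal helpers shared across modules

# canonical "a|b" keys for unordered pairs
.pairKeys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.edgeKeys <- function(edges) {
  if (!nrow(edges)) return(character())
  .pairKeys(edges$geneA, edges$geneB)
}

# upper-triangle entries of a symmetric score matrix as a canonical edge
# data.frame, optionally thresholded (inclusive)
.matrixToEdges <- function(s, min_score = -Inf) {
  stopifnot(!is.null(rownames(s)))
  ut <- upper.tri(s)
  keep <- ut & s >= min_score
  idx <- which(keep, arr.ind = TRUE)
  g <- rownames(s)
  a <- g[idx[, 1L]]
  b <- g[idx[, 2L]]
  data.frame(geneA = pmin(a, b), geneB = pmax(a, b),
             score = s[keep], stringsAsFactors = FALSE)
}

# all unordered pairs within a gene set, canonical order
.setPairs <- function(genes) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n < 2L) return(data.frame(geneA = character(), geneB = character()))
  idx <- utils::combn(n, 2L)
  data.frame(geneA = genes[idx[1L, ]], geneB = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

.geomMean <- function(x) exp(mean(log(x)))

# FNV-1a hash of a character scalar; used for config manifests. The state
# is kept in a double (exact below 2^53); xor only ever touches the low
# byte, so it stays within bitwXor's integer range.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# topological order of an OntologyDAG (children after parents); NULL if cyclic
.topoOrder <- function(dag) {
  terms <- dag@terms
  nparents <- vapply(dag@parents[terms], length, integer(1))
  children <- .childrenMap(dag)
  order <- character(0)
  queue <- terms[nparents == 0L]
  indeg <- nparents
  names(indeg) <- terms
  while (length(queue)) {
    t <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(terms)) NULL else order
}

# term -> direct children map
.childrenMap <- function(dag) {
  children <- setNames(vector("list", length(dag@terms)), dag@terms)
  for (t in names(dag@parents)) {
    for (p in dag@parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

# term -> all ancestors (excluding the term itself), memoized over the DAG
.ancestorsMap <- function(dag) {
  ord <- .topoOrder(dag)
  anc <- setNames(vector("list", length(ord)), ord)
  for (t in ord) {
    ps <- dag@parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

# gene -> annotated terms propagated to the root (direct terms + ancestors)
.propagatedAnnotations <- function(dag, anc = NULL) {
  if (is.null(anc)) anc <- .ancestorsMap(dag)
  lapply(dag@annotations, function(ts) {
    unique(c(ts, unlist(anc[ts], use.names = FALSE)))
  })
}

# linear-interpolation percentile (stats::quantile type 7)
.percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

.assertScoreMatrix <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1) stop("adjacency entries must lie in [0, 1]")
  invisible(TRUE)
}
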