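# fixtures shared across test files; everything is generated in code

# small integer count matrix with dimnames
makeCounts <- function(p = 20, n = 10, seed = 1, lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(p * n, lambda), p, n,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(n))))
  })
  ExpressionMatrix(m, kind = "raw_counts")
}

# continuous matrix of independent gaussians
makeGaussian <- function(p = 20, n = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(p * n, mean = 100, sd = 10), p, n,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(n))))
  })
  ExpressionMatrix(round(m), kind = "raw_counts")
}

# tiny scored network from a vector spec: list of c(a, b, score)
makeNetwork <- function(..., nodes = NULL, method = "", dataset = "") {
  rows <- list(...)
  e <- data.frame(geneA = vapply(rows, `[[`, "", 1L),
                  geneB = vapply(rows, `[[`, "", 2L),
                  score = as.numeric(vapply(rows, `[[`, "", 3L)))
  ScoredNetwork(e, nodes = nodes, method = method, dataset = dataset)
}

# 7-term toy ontology used by the similarity tests:
#   root -> a, b ; a -> a1, a2 ; b -> b1 ; a1 -> a1x
# annotations chosen so term gene counts are easy to enumerate by hand
makeToyDag <- function() {
  dag <- OntologyDAG(
    terms = c("root", "a", "b", "a1", "a2", "b1", "a1x"),
    parents = list(a = "root", b = "root", a1 = "a", a2 = "a",
                   b1 = "b", a1x = "a1"))
  setAnnotations(dag, list(
    g1 = c("a1x"),
    g2 = c("a1"),
    g3 = c("a2"),
    g4 = c("b1"),
    g5 = c("b1", "a2"),
    g6 = c("b"),
    g7 = c("root"),
    g8 = c("a")))
}

# all unordered pairs of a gene vector (test-local re-derivation)
.setPairsForTest <- function(genes) {
  idx <- t(combn(sort(genes), 2))
  data.frame(geneA = idx[, 1], geneB = idx[, 2])
}

# brute-force F1 of a network's edges against a reference pair set
edgeF1 <- function(net, ref_pairs) {
  e <- edgeTable(net)
  keys <- paste(e$geneA, e$geneB)
  ref <- paste(ref_pairs$geneA, ref_pairs$geneB)
  tp <- sum(keys %in% ref)
  prec <- if (length(keys)) tp / length(keys) else 0
  rec <- if (length(ref)) tp / length(ref) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
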