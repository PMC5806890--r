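# ontology information content, semantic similarity and gold standards
#
# the toy DAG (helper-fixtures.R) has propagated gene counts, enumerable by
# hand: a1x {g1}, a1 {g1,g2}, a2 {g3,g5}, b1 {g4,g5}, a {g1,g2,g3,g5,g8},
# b {g4,g5,g6}, root all 8

test_that("term information content matches hand-computed counts", {
  dag <- makeToyDag()
  ic <- termIC(dag)
  expect_equal(ic[["root"]], 0)
  expect_equal(ic[["a"]], -log(5 / 8), tolerance = 1e-12)
  expect_equal(ic[["b"]], -log(3 / 8), tolerance = 1e-12)
  expect_equal(ic[["a1"]], log(4), tolerance = 1e-12)
  expect_equal(ic[["a1x"]], log(8), tolerance = 1e-12)
  # a term covering half the genes would have IC ln 2 by the same formula
  expect_equal(-log(4 / 8), log(2))
  expect_error(termIC(OntologyDAG("t1")), "no annotations")
})

test_that("term similarity follows Lin / normalized-Resnik hand computations", {
  dag <- makeToyDag()
  ica <- -log(5 / 8)
  # siblings under a: MICA = a
  expect_equal(termSemanticSimilarity(dag, "a1", "a2"),
               2 * ica / (2 * log(4)), tolerance = 1e-12)
  # identity with positive IC -> 1
  expect_equal(termSemanticSimilarity(dag, "a1", "a1"), 1)
  # only the root in common -> 0
  expect_equal(termSemanticSimilarity(dag, "a1", "b1"), 0)
  # normalized Resnik divides by the namespace maximum (IC of a1x)
  expect_equal(termSemanticSimilarity(dag, "a1", "a2", "resnik_norm"),
               ica / log(8), tolerance = 1e-12)
  # symmetry
  expect_equal(termSemanticSimilarity(dag, "a2", "a1"),
               termSemanticSimilarity(dag, "a1", "a2"))
  expect_error(termSemanticSimilarity(dag, "a1", "zzz"), "unknown term")
})

test_that("gene functional similarity is the best-match average", {
  dag <- makeToyDag()
  lin <- function(t1, t2) termSemanticSimilarity(dag, t1, t2)
  # single-term genes: BMA reduces to the term similarity
  expect_equal(geneFunctionalSimilarity(dag, "g1", "g2"), lin("a1x", "a1"),
               tolerance = 1e-12)
  expect_equal(geneFunctionalSimilarity(dag, "g1", "g2"), 0.8,
               tolerance = 1e-12)
  # sharing only root ancestors -> 0
  expect_equal(geneFunctionalSimilarity(dag, "g1", "g4"), 0)
  # identical annotation sets -> 1
  expect_equal(geneFunctionalSimilarity(dag, "g3", "g3"), 1)
  # multi-term gene vs single-term gene: brute-force double loop
  bma <- function(ta, tb) {
    smat <- outer(ta, tb, Vectorize(lin))
    (mean(apply(smat, 1, max)) + mean(apply(smat, 2, max))) / 2
  }
  expect_equal(geneFunctionalSimilarity(dag, "g5", "g1"),
               bma(c("b1", "a2"), "a1x"), tolerance = 1e-12)
  expect_equal(geneFunctionalSimilarity(dag, "g5", "g3"),
               bma(c("b1", "a2"), "a2"), tolerance = 1e-12)
  # symmetry
  expect_equal(geneFunctionalSimilarity(dag, "g5", "g1"),
               geneFunctionalSimilarity(dag, "g1", "g5"))
  # unannotated gene is an error, not similarity 0
  expect_error(geneFunctionalSimilarity(dag, "g1", "g99"), "no annotation")
})

test_that("positive standard is the deduplicated union of all sources", {
  # one GO set {a,b,c} -> its three pairs
  pos <- buildPositiveStandard(go_sets = list(s1 = c("a", "b", "c")))
  expect_equal(paste(pos$geneA, pos$geneB), c("a b", "a c", "b c"))
  # overlapping sources union without duplicates
  pos2 <- buildPositiveStandard(
    go_sets = list(s1 = c("a", "b", "c")),
    pathways = list(p1 = c("b", "c", "d")),
    ppi = data.frame(geneA = "c", geneB = "a"))
  keys <- paste(pos2$geneA, pos2$geneB)
  expect_equal(anyDuplicated(keys), 0)
  expect_setequal(keys, c("a b", "a c", "b c", "b d", "c d"))
  # random fixture equals a brute-force union oracle
  set.seed(40)
  genes <- sprintf("g%02d", 1:15)
  gsets <- lapply(1:3, function(i) sample(genes, sample(3:6, 1)))
  names(gsets) <- paste0("s", 1:3)
  ppi <- .setPairsForTest(genes)[sample(105, 10), ]
  got <- buildPositiveStandard(go_sets = gsets, ppi = ppi)
  oracle <- character()
  for (s in gsets) {
    for (i in seq_along(s)) for (j in seq_along(s)) {
      if (s[i] < s[j]) oracle <- c(oracle, paste(s[i], s[j]))
    }
  }
  oracle <- union(oracle, paste(ppi$geneA, ppi$geneB))
  expect_setequal(paste(got$geneA, got$geneB), oracle)
  # oversized GO sets are excluded; universe restriction applies
  pos3 <- buildPositiveStandard(
    go_sets = list(huge = as.character(1:600), s1 = c("a", "b")),
    universe = c("a", "b"))
  expect_equal(nrow(pos3), 1)
})

test_that("negative standard follows the four-step procedure", {
  # two disjoint branches; per-branch terms annotated to 6+ genes each so
  # they fall in the (5, 50) size window; a broad near-root term keeps the
  # background percentile positive
  genes_x <- sprintf("x%02d", 1:8)
  genes_y <- sprintf("y%02d", 1:9)
  # filler genes push the branch, broad and root terms above the 50-gene
  # window so only tx (8) and ty (9) are candidate terms
  fill_x <- sprintf("fx%02d", 1:44)
  fill_y <- sprintf("fy%02d", 1:44)
  dag <- OntologyDAG(
    terms = c("root", "bx", "by", "tx", "ty", "broad"),
    parents = list(bx = "root", by = "root", tx = "bx", ty = "by",
                   broad = "root"))
  ann <- c(
    setNames(lapply(genes_x, function(g) c("tx", "broad")), genes_x),
    setNames(lapply(genes_y, function(g) c("ty", "broad")), genes_y),
    setNames(lapply(fill_x, function(g) c("bx", "broad")), fill_x),
    setNames(lapply(fill_y, function(g) c("by", "broad")), fill_y))
  # two genes without the broad term so zero-similarity pairs exist
  ann[["x01"]] <- "tx"
  ann[["y01"]] <- "ty"
  dag <- setAnnotations(dag, ann)
  cfg <- NegativeStandardConfig(n_backgrounds = 20,
                                pairs_per_background = 40, seed = 7)
  neg <- buildNegativeStandard(dag, cfg)
  expect_gt(nrow(neg), 0)
  thr <- attr(neg, "threshold")
  expect_gt(thr, 0)
  # every final negative is below the threshold by construction
  sims <- mapply(function(a, b) geneFunctionalSimilarity(dag, a, b),
                 neg$geneA, neg$geneB)
  expect_true(all(sims < thr))
  # candidate terms: tx-ty is the only same-size zero-similarity pair
  expect_equal(attr(neg, "n_candidate_term_pairs"), 1L)

  # slow four-step reference implementation with the same seed
  refNegatives <- function(dag, cfg) {
    cross <- expand.grid(a = genes_x, b = genes_y, stringsAsFactors = FALSE)
    init <- data.frame(geneA = pmin(cross$a, cross$b),
                       geneB = pmax(cross$a, cross$b))
    annotated <- names(ann)
    thr <- withr::with_seed(cfg$seed, {
      mean(vapply(seq_len(cfg$n_backgrounds), function(i) {
        a <- sample(annotated, cfg$pairs_per_background, replace = TRUE)
        b <- sample(annotated, cfg$pairs_per_background, replace = TRUE)
        same <- a == b
        while (any(same)) {
          b[same] <- sample(annotated, sum(same), replace = TRUE)
          same <- a == b
        }
        sims <- mapply(function(x, y) geneFunctionalSimilarity(dag, x, y),
                       a, b)
        unname(quantile(sims, cfg$background_percentile / 100, names = FALSE))
      }, numeric(1)))
    })
    sims <- mapply(function(x, y) geneFunctionalSimilarity(dag, x, y),
                   init$geneA, init$geneB)
    list(pairs = init[sims < thr, ], threshold = thr)
  }
  ref <- refNegatives(dag, cfg)
  expect_equal(thr, ref$threshold, tolerance = 1e-12)
  expect_setequal(paste(neg$geneA, neg$geneB),
                  paste(ref$pairs$geneA, ref$pairs$geneB))

  # a DAG whose term pairs all share an informative ancestor yields none
  # root-only annotations keep mid informative (IC > 0), so the sibling
  # terms share an informative ancestor; the only zero-similarity pairs
  # are ancestor-nested and yield no cross genes
  dag2 <- OntologyDAG(c("root", "mid", "t1", "t2"),
                      list(mid = "root", t1 = "mid", t2 = "mid"))
  g <- sprintf("z%02d", 1:20)
  dag2 <- setAnnotations(dag2, c(
    setNames(lapply(g[1:7], function(x) "t1"), g[1:7]),
    setNames(lapply(g[8:14], function(x) "t2"), g[8:14]),
    setNames(lapply(g[15:20], function(x) "root"), g[15:20])))
  expect_gt(termSemanticSimilarity(dag2, "t1", "t2"), 0)
  expect_warning(neg2 <- buildNegativeStandard(dag2, cfg),
                 "no zero-similarity|no gene pairs")
  expect_equal(nrow(neg2), 0)
})

test_that("gold standard assembly enforces disjointness", {
  pos <- data.frame(geneA = c("a", "b"), geneB = c("b", "c"))
  neg <- data.frame(geneA = c("a", "c"), geneB = c("b", "d"))
  expect_message(gs <- assembleGoldStandard(pos, neg, letters[1:5]),
                 "dropped")
  expect_equal(nrow(negativePairs(gs)), 1)
  expect_equal(universeSize(gs), 5)
  pk <- paste(positivePairs(gs)$geneA, positivePairs(gs)$geneB)
  nk <- paste(negativePairs(gs)$geneA, negativePairs(gs)$geneB)
  expect_length(intersect(pk, nk), 0)
})

test_that("gmt, obo and annotation files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  p1 <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, p1)
  expect_identical(readGmt(p1), sets)

  dag <- makeToyDag()
  p2 <- withr::local_tempfile(fileext = ".obo")
  writeObo(dag, p2)
  back <- readObo(p2)
  expect_setequal(ontologyTerms(back), ontologyTerms(dag))
  expect_identical(back@parents[sort(ontologyTerms(dag))],
                   dag@parents[sort(ontologyTerms(dag))])

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(geneAnnotations(dag), p3)
  back_ann <- readAnnotations(p3)
  expect_identical(lapply(back_ann, sort)[sort(names(back_ann))],
                   lapply(geneAnnotations(dag), sort)[sort(names(back_ann))])
})
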