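# fold enrichment, function prediction, topology and trait-link analysis

test_that("fold enrichment is the ratio of gold-link rates", {
  # identity: fold * (M/N) = n/m exactly
  set.seed(50)
  for (i in 1:20) {
    m <- sample(1:1000, 1)
    n <- sample(0:m, 1)
    N <- sample(1000:100000, 1)
    M <- sample(1:N, 1)
    expect_equal(foldEnrichment(n, m, M, N) * (M / N), n / m,
                 tolerance = 1e-12)
  }
  expect_equal(foldEnrichment(10, 100, 100, 1000), 1.0)
  expect_error(foldEnrichment(0, 0, 10, 100), "m_k")
})

test_that("enrichment curve counts gold hits per cutoff", {
  set.seed(51)
  genes <- sprintf("g%02d", 1:12)
  prs <- .setPairsForTest(genes)
  e <- data.frame(prs[sample(nrow(prs), 30), ], score = runif(30))
  net <- ScoredNetwork(e, nodes = genes)
  gold <- prs[sample(nrow(prs), 20), ]
  M <- nrow(gold)
  N <- nrow(prs)
  curve <- enrichmentCurve(net, gold, M, N, cutoffs = c(5, 10, 20, 30))
  # brute-force oracle on the rank-ordered edge list
  eo <- e[order(-e$score, e$geneA, e$geneB), ]
  gk <- paste(gold$geneA, gold$geneB)
  for (r in seq_len(nrow(curve))) {
    k <- curve$cutoff[r]
    top <- eo[seq_len(k), ]
    n_k <- sum(paste(top$geneA, top$geneB) %in% gk)
    expect_equal(curve$n_k[r], n_k)
    expect_equal(curve$fold[r], (n_k / k) / (M / N), tolerance = 1e-12)
  }
  # gold = all pairs -> fold 1 everywhere
  c1 <- enrichmentCurve(net, prs, nrow(prs), nrow(prs),
                        cutoffs = c(10, 30))
  expect_equal(c1$fold, c(1, 1))
  # all top edges gold -> first-cutoff fold = N/M
  c2 <- enrichmentCurve(net, e[, c("geneA", "geneB")], 30, N, cutoffs = 5)
  expect_equal(c2$fold, N / 30, tolerance = 1e-12)
  expect_error(enrichmentCurve(net, gold, M, N, cutoffs = numeric()),
               "empty")
})

test_that("neighborhood enrichment reproduces the hypergeometric tail", {
  # hub with 20 neighbors in a 1000-gene universe; term annotates 50
  # genes, 10 of them neighbors
  universe <- sprintf("u%04d", 1:1000)
  hub <- "hub"
  nbrs <- universe[1:20]
  net <- ScoredNetwork(data.frame(geneA = hub, geneB = nbrs, score = 1),
                       nodes = c(hub, universe))
  dag <- OntologyDAG(c("root", "t"), list(t = "root"))
  ann_genes <- c(nbrs[1:10], universe[900:939])   # 50 annotated genes
  dag <- setAnnotations(dag, setNames(lapply(ann_genes, function(g) "t"),
                                      ann_genes))
  rec <- neighborhoodEnrichment(net, hub, dag, universe = universe)
  row <- rec$table[rec$table$term == "t", ]
  # oracle: explicit hypergeometric tail sum P(X >= 10)
  oracle <- sum(dhyper(10:20, 50, 950, 20))
  expect_equal(row$p, oracle, tolerance = 1e-12)
  # and equals one-sided Fisher on the same 2x2 table
  fisher <- fisher.test(matrix(c(10, 10, 40, 940), 2), alternative = "greater")
  expect_equal(row$p, fisher$p.value, tolerance = 1e-9)
  expect_true("t" %in% names(rec$predicted))
  expect_equal(unname(rec$predicted["t"]),
               -log10(rec$table$q[rec$table$term == "t"]))

  # a neighborhood mirroring genome frequencies predicts nothing
  set.seed(52)
  hits <- 0
  for (i in 1:5) {
    ann2 <- sample(universe, 200)   # 20% everywhere
    dag2 <- OntologyDAG(c("root", "t"), list(t = "root"))
    dag2 <- setAnnotations(dag2, setNames(lapply(ann2, function(g) "t"),
                                          ann2))
    r2 <- neighborhoodEnrichment(net, hub, dag2, universe = universe)
    hits <- hits + length(r2$predicted)
  }
  expect_lte(hits, 1)

  # isolated gene -> empty prediction
  iso <- ScoredNetwork(data.frame(geneA = "a", geneB = "b", score = 1),
                       nodes = c("a", "b", "c"))
  expect_message(r3 <- neighborhoodEnrichment(iso, "c", dag,
                                              universe = c("a", "b", "c")),
                 "no neighbors")
  expect_length(r3$predicted, 0)
})

test_that("true-positive rule accepts equal or more specific predictions", {
  dag <- makeToyDag()
  expect_true(isTruePositive("a1", c("a1", "b"), dag))
  # parent of a known term (less specific) is not a true positive
  expect_false(isTruePositive("a", "a1", dag))
  # grandchild of a known term is
  expect_true(isTruePositive("a1x", "a", dag))
  expect_false(isTruePositive("b1", "a", dag))
  expect_error(isTruePositive("zzz", "a", dag), "unknown")
})

test_that("score propagation takes the descendant maximum and is idempotent", {
  dag <- makeToyDag()
  # single scored leaf reaches every ancestor
  up <- propagateScores(dag, c(a1x = 2))
  expect_equal(up[["a1"]], 2)
  expect_equal(up[["a"]], 2)
  expect_equal(up[["root"]], 2)
  # parent takes the max of its children
  up2 <- propagateScores(dag, c(a1 = 2, a2 = 3))
  expect_equal(up2[["a"]], 3)
  # idempotent
  expect_equal(propagateScores(dag, up2), up2)
  # brute-force descendant-max oracle on a random DAG
  set.seed(53)
  terms <- sprintf("t%02d", 1:12)
  parents <- list()
  for (i in 2:12) {
    parents[[terms[i]]] <- sample(terms[seq_len(i - 1)],
                                  sample(1:min(2, i - 1), 1))
  }
  rdag <- OntologyDAG(terms, parents)
  scores <- setNames(round(runif(5), 3), sample(terms, 5))
  got <- propagateScores(rdag, scores)
  anc <- coexEnsemble:::.ancestorsMap(rdag)
  for (t in names(got)) {
    below <- c(t, names(Filter(function(a) t %in% a, anc)))
    expected <- max(c(0, scores[intersect(names(scores), below)]),
                    na.rm = TRUE)
    expect_equal(unname(got[[t]]), unname(expected))
  }
})

test_that("cafa metrics match a hand-computed 3-gene fixture", {
  dag <- OntologyDAG(c("root", "A", "B", "A1", "A2", "B1"),
                     list(A = "root", B = "root", A1 = "A", A2 = "A",
                          B1 = "B"))
  dag <- setAnnotations(dag, list(gx = "A1", gy = "B1", gz = "A"))
  rec <- function(gene, predicted, known) {
    r <- list(gene = gene, predicted = predicted, known = known)
    class(r) <- "PredictionRecord"
    r
  }
  records <- list(
    rec("gx", c(A1 = 2), c("A1", "A", "root")),
    rec("gy", c(A2 = 1), c("B1", "B", "root")),
    rec("gz", setNames(numeric(0), character(0)), c("A", "root")))
  got <- cafaMetrics(records, dag)
  cv <- got$curve
  # t = 1: gx predicts {A1,A,root} all true (P=1, R=1); gy predicts
  # {A2,A,root}, only root true (P=1/3, R=1/3); gz predicts nothing (R=0)
  r1 <- cv[cv$threshold == 1, ]
  expect_equal(r1$precision, mean(c(1, 1 / 3)), tolerance = 1e-12)
  expect_equal(r1$recall, mean(c(1, 1 / 3, 0)), tolerance = 1e-12)
  # t = 2: only gx still predicts
  r2 <- cv[cv$threshold == 2, ]
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, mean(c(1, 0, 0)), tolerance = 1e-12)
  pr <- mean(c(1, 1 / 3))
  rr <- mean(c(1, 1 / 3, 0))
  expect_equal(got$f_max, 2 * pr * rr / (pr + rr), tolerance = 1e-12)

  # perfect predictions at any positive score -> F_max 1
  perfect <- list(rec("gx", c(A1 = 1, A = 1, root = 1), c("A1", "A", "root")),
                  rec("gy", c(B1 = 5, B = 5, root = 5), c("B1", "B", "root")))
  expect_equal(cafaMetrics(perfect, dag)$f_max, 1)

  # empty predictions -> recall 0 at every threshold
  empty <- list(rec("gx", setNames(numeric(0), character(0)),
                    c("A1", "A", "root")))
  ge <- cafaMetrics(empty, dag)
  expect_true(all(ge$curve$recall == 0))
  expect_equal(ge$f_max, 0)

  # precision/recall bounded, recall non-increasing in the threshold
  expect_true(all(cv$recall >= 0 & cv$recall <= 1))
  expect_true(all(na.omit(cv$precision) >= 0 & na.omit(cv$precision) <= 1))
  expect_true(all(diff(cv$recall) <= 1e-12))
})

test_that("evaluable-gene filter applies the count and CV rules", {
  rec <- function(nk, np) {
    r <- list(gene = "g", predicted = setNames(rep(1, np),
                                               paste0("p", seq_len(np))),
              known = paste0("k", seq_len(nk)))
    class(r) <- "PredictionRecord"
    r
  }
  recs <- list(rec(3, 3), rec(2, 3), rec(3, 2), rec(3, 9), rec(4, 5))
  kept <- filterEvaluableGenes(recs)
  # (3,3): CV 0 ok; (2,3),(3,2): too few; (3,9): CV 0.707 > 0.5; (4,5): 0.157
  expect_length(kept, 2)
})

test_that("topology statistics match hand values and a BFS oracle", {
  tri <- makeNetwork(c("a", "b", "1"), c("b", "c", "1"), c("a", "c", "1"))
  ts <- topologyStats(tri)
  expect_true(all(ts$clustering == 1))
  expect_equal(ts$avg_path_length, 1)

  path <- makeNetwork(c("a", "b", "1"), c("b", "c", "1"))
  expect_equal(topologyStats(path)$avg_path_length, (1 + 1 + 2) / 3,
               tolerance = 1e-12)

  # random graph vs brute-force BFS
  set.seed(54)
  genes <- sprintf("g%02d", 1:50)
  prs <- .setPairsForTest(genes)
  e <- prs[runif(nrow(prs)) < 0.06, ]
  net <- ScoredNetwork(data.frame(e, score = 1), nodes = genes)
  ts2 <- topologyStats(net)
  adj <- matrix(FALSE, 50, 50, dimnames = list(genes, genes))
  for (r in seq_len(nrow(e))) {
    adj[e$geneA[r], e$geneB[r]] <- adj[e$geneB[r], e$geneA[r]] <- TRUE
  }
  bfs <- function(src) {
    d <- setNames(rep(Inf, 50), genes)
    d[src] <- 0
    q <- src
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in genes[adj[u, ]]) if (is.infinite(d[v])) {
        d[v] <- d[u] + 1
        q <- c(q, v)
      }
    }
    d
  }
  dmat <- t(sapply(genes, bfs))
  # degrees
  expect_equal(unname(ts2$degree[genes]), unname(rowSums(adj)))
  # average path length over reachable pairs in the largest component
  comp_sizes <- table(sapply(genes, function(g) {
    min(names(which(is.finite(dmat[g, ]))))
  }))
  big_rep <- names(comp_sizes)[which.max(comp_sizes)]
  members <- genes[is.finite(dmat[big_rep, ])]
  dd <- dmat[members, members]
  expect_equal(ts2$avg_path_length, mean(dd[upper.tri(dd)]),
               tolerance = 1e-12)
  expect_equal(ts2$largest_component_size, length(members))
})

test_that("guide subnetworks are BFS neighborhoods of the guides", {
  chain <- makeNetwork(c("a", "b", "1"), c("b", "c", "1"), c("c", "d", "1"))
  sub <- guideSubnetwork(chain, "a", layers = 2)
  expect_setequal(nodeUniverse(sub), c("a", "b", "c"))
  sub0 <- guideSubnetwork(chain, c("a", "b"), layers = 0)
  expect_setequal(nodeUniverse(sub0), c("a", "b"))
  expect_equal(edgeCount(sub0), 1)   # the induced a-b edge
  expect_message(guideSubnetwork(chain, c("a", "zz")), "not in network")
  expect_error(guideSubnetwork(chain, "zz"), "no guide")

  # random graph vs BFS oracle
  set.seed(55)
  genes <- sprintf("g%02d", 1:30)
  prs <- .setPairsForTest(genes)
  e <- prs[runif(nrow(prs)) < 0.08, ]
  net <- ScoredNetwork(data.frame(e, score = 1), nodes = genes)
  guides <- c("g01", "g07")
  sub2 <- guideSubnetwork(net, guides, layers = 2)
  g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
                                     vertices = genes)
  d <- igraph::distances(g, v = guides)
  expect_setequal(nodeUniverse(sub2),
                  colnames(d)[apply(d, 2, min) <= 2])
})

test_that("trait link density classifies pairs like a brute-force oracle", {
  genes <- sprintf("g%02d", 1:12)
  traits <- list(t1 = c("g01", "g02", "g03", "g04"),
                 t2 = c("g03", "g05", "g06"),
                 t3 = c("g07", "g08"))
  set.seed(56)
  prs <- .setPairsForTest(genes)
  e <- prs[runif(nrow(prs)) < 0.35, ]
  net <- ScoredNetwork(data.frame(e, score = 1), nodes = genes)
  res <- traitLinkDensity(net, traits, n_perm = 50, seed = 3)
  # brute force over all pairs of trait genes
  tg <- sort(unique(unlist(traits)))
  within_links <- between_links <- within_possible <- between_possible <- 0
  ek <- paste(e$geneA, e$geneB)
  for (i in seq_along(tg)) for (j in seq_along(tg)) {
    if (tg[i] >= tg[j]) next
    share <- length(intersect(
      names(Filter(function(s) tg[i] %in% s, traits)),
      names(Filter(function(s) tg[j] %in% s, traits)))) > 0
    linked <- paste(tg[i], tg[j]) %in% ek
    if (share) {
      within_possible <- within_possible + 1
      within_links <- within_links + linked
    } else {
      between_possible <- between_possible + 1
      between_links <- between_links + linked
    }
  }
  expect_equal(res$within_links, within_links)
  expect_equal(res$within_possible, within_possible)
  expect_equal(res$between_links, between_links)
  expect_equal(res$between_possible, between_possible)
  expect_equal(res$fold,
               linkDensityFold(within_links, within_possible,
                               between_links, between_possible))
  expect_true(all(res$per_trait$p > 0 & res$per_trait$p <= 1))

  # identical within/between densities -> fold 1 (complete network)
  full <- ScoredNetwork(data.frame(prs, score = 1), nodes = genes)
  expect_equal(traitLinkDensity(full, traits, n_perm = 0)$fold, 1)
})
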