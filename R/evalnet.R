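#' Fold enrichment of gold links among selected edges
#'
#' fold = (n_k / m_k) / (M / N): how much more often the selected edges hit
#' the gold standard than a random draw from the whole pair universe would.
#' (Writing it as a ratio of rates makes the two published worked examples
#' come out right; see the methods vignette for the sign convention.)
#'
#' @param n_k gold links among the selected edges.
#' @param m_k number of selected edges (> 0).
#' @param M gold links in the standard.
#' @param N size of the reference space (all possible pairs, or genes when
#'   enriching gene sets).
#' @return the fold enrichment.
#' @examples
#' foldEnrichment(33, 1093, 180, 55986)   # ~9.4
#' foldEnrichment(88, 1329, 996, 55986)   # ~3.72
#' @export
foldEnrichment <- function(n_k, m_k, M, N) {
  stopifnot(n_k >= 0, n_k <= m_k, M > 0, M <= N)
  if (m_k == 0) stop("fold enrichment undefined for m_k = 0")
  (n_k / m_k) / (M / N)
}

#' Fold-enrichment curve over edge-list cutoffs
#'
#' Sweeps cutoffs down the confidence-ranked edge list; at each cutoff k,
#' n_k is the number of top edges that are gold links and m_k the number of
#' top edges.
#'
#' @param ranked a \linkS4class{ScoredNetwork} (edges are sorted by
#'   descending score internally; ties broken by pair id).
#' @param gold_pairs data.frame of gold gene pairs (geneA/geneB).
#' @param M,N gold-standard size and reference-space size for
#'   \code{\link{foldEnrichment}}.
#' @param cutoffs numeric grid: ranks (default) or score thresholds.
#' @param type \code{"rank"} (top-k edges) or \code{"score"}
#'   (edges with score >= cutoff).
#' @return data.frame with columns cutoff, m_k, n_k, fold (fold is NA where
#'   m_k = 0).
#' @export
enrichmentCurve <- function(ranked, gold_pairs, M, N,
                            cutoffs = NULL, type = c("rank", "score")) {
  type <- match.arg(type)
  e <- edgeTable(ranked)
  e <- e[order(-e$score, e$geneA, e$geneB), , drop = FALSE]
  if (is.null(cutoffs)) {
    cutoffs <- if (type == "rank") {
      unique(round(seq(1, max(1, nrow(e)), length.out = 20)))
    } else {
      sort(unique(e$score), decreasing = TRUE)
    }
  }
  if (!length(cutoffs)) stop("empty cutoff grid")
  gold <- .pairKeys(gold_pairs$geneA, gold_pairs$geneB)
  hit <- .edgeKeys(e) %in% gold
  cumhit <- cumsum(hit)
  rows <- lapply(cutoffs, function(k) {
    m_k <- if (type == "rank") min(k, nrow(e)) else sum(e$score >= k)
    n_k <- if (m_k == 0) 0 else cumhit[m_k]
    data.frame(cutoff = k, m_k = m_k, n_k = n_k,
               fold = if (m_k > 0) foldEnrichment(n_k, m_k, M, N) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Function prediction for one gene from its co-expression neighborhood
#'
#' For each ontology term, a one-sided Fisher's exact test (hypergeometric
#' tail) compares the term's frequency among the gene's direct network
#' neighbors with its frequency in the rest of the gene universe, on
#' propagated annotations. P-values are Benjamini-Hochberg adjusted across
#' terms within the gene; terms with q < \code{q_threshold} are predicted
#' with score -log10(q).
#'
#' @param net a \linkS4class{ScoredNetwork} containing \code{gene}.
#' @param gene the gene whose neighborhood is tested.
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param q_threshold BH-adjusted significance level (default 0.05).
#' @param universe gene universe (default: the network's node universe).
#' @param distance neighborhood radius in hops (default 1).
#' @return list of class \code{PredictionRecord}: \code{gene},
#'   \code{predicted} (named score vector, -log10 q), \code{known}
#'   (propagated known terms), \code{table} (per-term test results).
#' @export
neighborhoodEnrichment <- function(net, gene, dag, q_threshold = 0.05,
                                   universe = NULL, distance = 1L) {
  if (!(gene %in% nodeUniverse(net))) stop("gene not in network: ", gene)
  if (is.null(universe)) universe <- nodeUniverse(net)
  g <- .asIgraph(net)
  nb <- names(igraph::ego(g, order = distance,
                          nodes = gene, mindist = 1L)[[1L]])
  prop <- .propagatedAnnotations(dag)
  known <- prop[[gene]]
  if (is.null(known)) known <- character()
  rec <- list(gene = gene, predicted = setNames(numeric(0), character(0)),
              known = known,
              table = data.frame(term = character(), p = numeric(),
                                 q = numeric()))
  class(rec) <- "PredictionRecord"
  if (!length(nb)) {
    message("gene ", gene, " has no neighbors; empty prediction")
    return(rec)
  }
  prop_in_universe <- prop[intersect(names(prop), universe)]
  term_genes <- split(rep(names(prop_in_universe),
                          lengths(prop_in_universe)),
                      unlist(prop_in_universe, use.names = FALSE))
  n_universe <- length(universe)
  n_nb <- length(nb)
  res <- lapply(names(term_genes), function(t) {
    ann <- term_genes[[t]]
    k <- sum(nb %in% ann)
    if (k == 0L) return(NULL)
    K <- length(unique(ann))
    # P(X >= k), X ~ Hypergeom(K annotated, n_universe - K, n_nb drawn)
    p <- stats::phyper(k - 1L, K, n_universe - K, n_nb, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, p = p)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(rec)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  sigs <- res[res$q < q_threshold, , drop = FALSE]
  rec$predicted <- setNames(-log10(sigs$q), sigs$term)
  rec$table <- res
  rec
}

#' Is a predicted term a true positive?
#'
#' TRUE iff the predicted term equals a known term or is a descendant of
#' one (i.e. it is at least as specific as something known). A parent of a
#' known term — less specific than the annotation — is not a true positive.
#'
#' @param pred_term predicted term id.
#' @param known_terms character vector of known term ids.
#' @param dag an \linkS4class{OntologyDAG}.
#' @return logical.
#' @export
isTruePositive <- function(pred_term, known_terms, dag) {
  if (!(pred_term %in% dag@terms) || !all(known_terms %in% dag@terms)) {
    stop("unknown term id")
  }
  if (pred_term %in% known_terms) return(TRUE)
  anc <- .ancestorsMap(dag)
  any(known_terms %in% anc[[pred_term]])
}

#' Propagate term scores up the ontology
#'
#' Every ancestor receives the maximum of its own score and its
#' descendants' scores, so predicting a specific term implies (at least as
#' strongly) its more general parents. Idempotent.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param term_scores named non-negative numeric vector.
#' @return named numeric vector over the closure of the scored terms.
#' @export
propagateScores <- function(dag, term_scores) {
  stopifnot(all(term_scores >= 0))
  if (!all(names(term_scores) %in% dag@terms)) stop("unknown term id")
  ord <- .topoOrder(dag)
  out <- setNames(rep(0, length(ord)), ord)
  out[names(term_scores)] <- term_scores
  for (t in rev(ord)) {          # children before parents
    for (p in dag@parents[[t]]) out[p] <- max(out[p], out[t])
  }
  out[out > 0 | names(out) %in% names(term_scores)]
}

# per-record propagated prediction scores and known term sets
.preparedRecords <- function(records, dag) {
  lapply(records, function(r) {
    pred <- r$predicted
    if (length(pred)) pred <- propagateScores(dag, pred)
    known <- unique(r$known)
    list(gene = r$gene, pred = pred, known = known)
  })
}

#' Gene-centric function-prediction metrics (CAFA style)
#'
#' Sweeps a threshold over the prediction scores; at each threshold t the
#' per-gene precision is |predicted above t intersect known| / |predicted
#' above t|, averaged over genes with at least one prediction, and the
#' per-gene recall is the same intersection over |known|, averaged over all
#' genes with known terms. F-max is the maximum harmonic mean over the
#' sweep. ROC points use the per-gene false-positive rate over the term
#' universe. With \code{weighting = "ic"}, terms are weighted by
#' information content in all counts.
#'
#' @param records list of prediction records (see
#'   \code{\link{neighborhoodEnrichment}}); known and predicted term sets
#'   are propagated internally.
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param weighting \code{"none"} (default) or \code{"ic"}.
#' @param thresholds score grid; default: all distinct prediction scores.
#' @return list with \code{curve} (threshold, precision, recall, fpr),
#'   \code{f_max}, \code{auroc}, \code{auprc}.
#' @export
cafaMetrics <- function(records, dag, weighting = c("none", "ic"),
                        thresholds = NULL) {
  weighting <- match.arg(weighting)
  if (!length(records)) stop("no prediction records")
  prep <- .preparedRecords(records, dag)
  prep <- Filter(function(r) length(r$known) > 0, prep)
  if (!length(prep)) stop("no gene with known terms")
  w <- if (weighting == "ic") {
    ic <- termIC(dag)
    ic[is.na(ic)] <- 0
    ic
  } else {
    setNames(rep(1, length(dag@terms)), dag@terms)
  }
  wsum <- function(ts) if (length(ts)) sum(w[ts]) else 0
  all_scores <- unlist(lapply(prep, function(r) r$pred), use.names = FALSE)
  if (is.null(thresholds)) {
    thresholds <- if (length(all_scores)) {
      sort(unique(c(0, all_scores)))
    } else 0
  }
  n_terms_total <- length(dag@terms)
  rows <- lapply(thresholds, function(t) {
    precs <- numeric(0)
    recs <- numeric(0)
    fprs <- numeric(0)
    for (r in prep) {
      above <- names(r$pred)[r$pred >= t & r$pred > 0]
      tpw <- wsum(intersect(above, r$known))
      recs <- c(recs, if (wsum(r$known) > 0) tpw / wsum(r$known) else 0)
      negw <- wsum(setdiff(dag@terms, r$known))
      fprs <- c(fprs, if (negw > 0) wsum(setdiff(above, r$known)) / negw
                else 0)
      if (length(above)) precs <- c(precs, tpw / wsum(above))
    }
    data.frame(threshold = t,
               precision = if (length(precs)) mean(precs) else NA_real_,
               recall = mean(recs), fpr = mean(fprs))
  })
  curve <- do.call(rbind, rows)
  f <- with(curve, ifelse(!is.na(precision) & precision + recall > 0,
                          2 * precision * recall / (precision + recall), 0))
  f_max <- if (all(is.na(f))) 0 else max(f, na.rm = TRUE)
  trap <- function(x, y) {
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (length(x) < 2L) return(0)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  roc_x <- c(0, rev(curve$fpr), 1)
  roc_y <- c(0, rev(curve$recall), 1)
  auroc <- trap(roc_x, roc_y)
  ok <- !is.na(curve$precision)
  auprc <- if (sum(ok) >= 2L) trap(curve$recall[ok], curve$precision[ok])
           else 0
  list(curve = curve, f_max = f_max, auroc = auroc, auprc = auprc)
}

#' Eligibility filter for function-prediction evaluation
#'
#' Keeps genes with at least \code{min_known} known and \code{min_pred}
#' predicted annotations whose two counts have a coefficient of variation
#' at most \code{max_cv} — i.e. genes where the prediction is neither
#' starved nor wildly out of proportion with what is known.
#'
#' @param records list of prediction records.
#' @param min_known,min_pred minimum counts (default 3 each).
#' @param max_cv maximum CV of the two counts (default 0.5).
#' @return the filtered record list.
#' @export
filterEvaluableGenes <- function(records, min_known = 3L, min_pred = 3L,
                                 max_cv = 0.5) {
  Filter(function(r) {
    nk <- length(r$known)
    np <- length(r$predicted)
    if (nk < min_known || np < min_pred) return(FALSE)
    x <- c(nk, np)
    stats::sd(x) / mean(x) <= max_cv
  }, records)
}

.asIgraph <- function(net) {
  e <- edgeTable(net)
  igraph::graph_from_data_frame(
    e[, c("geneA", "geneB"), drop = FALSE], directed = FALSE,
    vertices = nodeUniverse(net))
}

#' Topology statistics of a network
#'
#' Unweighted degree distribution, per-node clustering coefficients (0 for
#' nodes of degree < 2), mean clustering, and the average shortest path
#' length over reachable pairs in the largest connected component.
#'
#' @param net a nonempty \linkS4class{ScoredNetwork}.
#' @return list with \code{degree} (named), \code{degree_histogram},
#'   \code{clustering} (named), \code{mean_clustering},
#'   \code{avg_path_length}, \code{n_components},
#'   \code{largest_component_size}.
#' @export
topologyStats <- function(net) {
  if (!edgeCount(net)) stop("empty network")
  g <- .asIgraph(net)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- igraph::mean_distance(sub, directed = FALSE)
  list(degree = deg,
       degree_histogram = table(deg),
       clustering = cc,
       mean_clustering = mean(cc),
       avg_path_length = apl,
       n_components = comp$no,
       largest_component_size = max(comp$csize))
}

#' Guide-gene subnetwork
#'
#' Induced subgraph on all nodes within \code{layers} hops of any guide
#' gene — the standard bait-and-neighborhood view used to transfer function
#' from characterized guides to their co-expressed partners.
#'
#' @param net a \linkS4class{ScoredNetwork}.
#' @param guides character vector of guide genes; guides missing from the
#'   network are reported (all missing is an error).
#' @param layers neighborhood depth in hops (default 2).
#' @return a \linkS4class{ScoredNetwork} restricted to the neighborhood.
#' @export
guideSubnetwork <- function(net, guides, layers = 2L) {
  present <- intersect(guides, nodeUniverse(net))
  missing <- setdiff(guides, present)
  if (length(missing)) {
    message("guide gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  if (!length(present)) stop("no guide gene present in the network")
  g <- .asIgraph(net)
  d <- igraph::distances(g, v = present)
  keep <- colnames(d)[apply(d, 2L, min) <= layers]
  e <- edgeTable(net)
  e <- e[e$geneA %in% keep & e$geneB %in% keep, , drop = FALSE]
  ScoredNetwork(e, nodes = keep, method = methodTag(net),
                dataset = datasetTag(net))
}

#' Link-density fold from within/between counts
#'
#' fold = (within_links / within_possible) / (between_links /
#' between_possible); the arithmetic behind
#' \code{\link{traitLinkDensity}}, exposed for pre-tabulated counts.
#'
#' @param within_links,within_possible links and possible pairs within
#'   trait sets.
#' @param between_links,between_possible links and possible pairs between
#'   trait sets.
#' @return the fold (NA when between_links = 0).
#' @export
linkDensityFold <- function(within_links, within_possible,
                            between_links, between_possible) {
  stopifnot(within_possible > 0, between_possible > 0)
  if (between_links == 0) return(NA_real_)
  (within_links / within_possible) / (between_links / between_possible)
}

#' Link-density contrast within versus between trait gene sets
#'
#' Classifies all unordered pairs of trait-annotated network genes as
#' "within" (sharing at least one trait) or "between" (disjoint trait
#' memberships), counts how many of each are network edges, and reports
#' fold = (within density) / (between density). Significance is assessed by
#' permuting the trait-set gene labels over the network universe
#' (preserving set sizes).
#'
#' @param net a \linkS4class{ScoredNetwork}.
#' @param trait_sets named list of trait gene sets.
#' @param n_perm number of label permutations (default 100; 0 skips the
#'   test).
#' @param seed integer seed for the permutations.
#' @return list with the within/between link and pair counts, \code{fold}
#'   (NA when no between links), \code{p_overall}, and \code{per_trait}
#'   (data.frame with per-trait link counts, densities and permutation p).
#' @export
traitLinkDensity <- function(net, trait_sets, n_perm = 100L, seed = 1L) {
  if (!length(trait_sets)) stop("trait sets must be nonempty")
  nodes <- nodeUniverse(net)
  sets <- lapply(trait_sets, intersect, y = nodes)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no trait gene maps into the network universe")
  edge_keys <- .edgeKeys(edgeTable(net))
  classify <- function(sets) {
    genes <- sort(unique(unlist(sets)))
    membership <- lapply(genes, function(g)
      names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
    names(membership) <- genes
    prs <- .setPairs(genes)
    share <- mapply(function(a, b)
      length(intersect(membership[[a]], membership[[b]])) > 0,
      prs$geneA, prs$geneB)
    keys <- .pairKeys(prs$geneA, prs$geneB)
    linked <- keys %in% edge_keys
    list(within_links = sum(linked[share]), within_possible = sum(share),
         between_links = sum(linked[!share]), between_possible = sum(!share))
  }
  obs <- classify(sets)
  fold <- if (obs$between_links > 0 && obs$within_possible > 0) {
    (obs$within_links / obs$within_possible) /
      (obs$between_links / obs$between_possible)
  } else NA_real_
  per_trait_links <- function(sets) {
    vapply(sets, function(s) {
      prs <- .setPairs(s)
      if (!nrow(prs)) return(0L)
      sum(.pairKeys(prs$geneA, prs$geneB) %in% edge_keys)
    }, integer(1))
  }
  obs_trait <- per_trait_links(sets)
  p_overall <- NA_real_
  p_trait <- rep(NA_real_, length(sets))
  if (n_perm > 0) {
    ge_overall <- 0L
    ge_trait <- integer(length(sets))
    .withSeed(seed, {
      for (b in seq_len(n_perm)) {
        perm_sets <- lapply(sets, function(s) sample(nodes, length(s)))
        names(perm_sets) <- names(sets)
        pc <- classify(perm_sets)
        pfold <- if (pc$between_links > 0 && pc$within_possible > 0) {
          (pc$within_links / pc$within_possible) /
            (pc$between_links / pc$between_possible)
        } else Inf
        if (!is.na(fold) && pfold >= fold) ge_overall <- ge_overall + 1L
        pt <- per_trait_links(perm_sets)
        ge_trait <- ge_trait + as.integer(pt >= obs_trait)
      }
    })
    p_overall <- (1 + ge_overall) / (1 + n_perm)
    p_trait <- (1 + ge_trait) / (1 + n_perm)
  }
  list(within_links = obs$within_links,
       within_possible = obs$within_possible,
       between_links = obs$between_links,
       between_possible = obs$between_possible,
       fold = fold, p_overall = p_overall,
       per_trait = data.frame(trait = names(sets), n_genes = lengths(sets),
                              links = obs_trait, p = p_trait,
                              row.names = NULL))
}
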