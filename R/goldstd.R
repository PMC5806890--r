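#' Negative-standard construction configuration
#'
#' Defaults follow the published procedure: candidate term pairs must have
#' semantic similarity exactly 0 and gene counts strictly between
#' \code{min_go_size} and \code{max_go_size}; the similarity threshold is
#' the mean of the 5th percentiles of 10000 background distributions, each
#' of 1000 randomly sampled gene pairs. Scale \code{n_backgrounds} /
#' \code{pairs_per_background} down for desk-size data.
#'
#' @param min_go_size exclusive lower bound on term gene count (default 5).
#' @param max_go_size exclusive upper bound on term gene count (default 50).
#' @param n_backgrounds number of background distributions (default 10000).
#' @param pairs_per_background gene pairs per background (default 1000).
#' @param background_percentile percentile taken per background (default 5).
#' @param seed integer seed for the background sampling.
#' @return a list of class \code{NegativeStandardConfig}.
#' @export
NegativeStandardConfig <- function(min_go_size = 5L, max_go_size = 50L,
                                   n_backgrounds = 10000L,
                                   pairs_per_background = 1000L,
                                   background_percentile = 5,
                                   seed = 1L) {
  stopifnot(min_go_size > 0, max_go_size > min_go_size,
            n_backgrounds > 0, pairs_per_background > 0,
            background_percentile > 0, background_percentile < 100)
  structure(list(min_go_size = as.integer(min_go_size),
                 max_go_size = as.integer(max_go_size),
                 n_backgrounds = as.integer(n_backgrounds),
                 pairs_per_background = as.integer(pairs_per_background),
                 background_percentile = background_percentile,
                 seed = as.integer(seed)),
            class = "NegativeStandardConfig")
}

# term -> propagated annotated gene count and gene sets, per the closure
# "annotating a term implies all ancestors"
.termGeneSets <- function(dag, anc = NULL) {
  prop <- .propagatedAnnotations(dag, anc)
  genes <- rep(names(prop), lengths(prop))
  terms <- unlist(prop, use.names = FALSE)
  split(genes, factor(terms, levels = dag@terms))
}

#' Information content of ontology terms
#'
#' IC(t) = -ln p(t) where p(t) is the fraction of the namespace's annotated
#' genes annotated (after propagation) to t or a descendant of t. Roots
#' have IC 0; terms with no annotated genes are excluded (NA).
#'
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @return named numeric vector of IC values per term (NA when undefined).
#' @export
termIC <- function(dag) {
  if (!length(dag@annotations)) stop("ontology has no annotations")
  sets <- .termGeneSets(dag)
  counts <- vapply(sets, function(g) length(unique(g)), integer(1))
  ic <- setNames(rep(NA_real_, length(dag@terms)), dag@terms)
  for (ns in unique(dag@namespace)) {
    in_ns <- names(dag@namespace)[dag@namespace == ns]
    ns_genes <- unique(unlist(sets[in_ns], use.names = FALSE))
    n_ns <- length(ns_genes)
    if (!n_ns) next
    ic[in_ns] <- ifelse(counts[in_ns] > 0,
                        -log(counts[in_ns] / n_ns), NA_real_)
  }
  ic
}

# environment caching IC / ancestors for repeated similarity queries
.simContext <- function(dag) {
  ctx <- new.env(parent = emptyenv())
  ctx$dag <- dag
  ctx$anc <- .ancestorsMap(dag)
  ctx$ic <- termIC(dag)
  ctx$maxic <- tapply(ctx$ic, dag@namespace[names(ctx$ic)],
                      function(x) suppressWarnings(max(x, na.rm = TRUE)))
  ctx$paircache <- new.env(parent = emptyenv())
  ctx
}

.termSimCtx <- function(ctx, t1, t2, method = "lin") {
  dag <- ctx$dag
  if (dag@namespace[[t1]] != dag@namespace[[t2]]) return(0)
  ic <- ctx$ic
  common <- intersect(c(t1, ctx$anc[[t1]]), c(t2, ctx$anc[[t2]]))
  common <- common[!is.na(ic[common])]
  if (!length(common)) return(0)
  mica <- max(ic[common])
  if (mica <= 0) return(0)
  if (method == "lin") {
    denom <- ic[[t1]] + ic[[t2]]
    if (is.na(denom) || denom <= 0) return(0)
    min(1, 2 * mica / denom)
  } else {
    mx <- ctx$maxic[[dag@namespace[[t1]]]]
    if (!is.finite(mx) || mx <= 0) return(0)
    min(1, mica / mx)
  }
}

#' Semantic similarity between two ontology terms
#'
#' \code{"lin"}: 2 IC(MICA) / (IC(t1) + IC(t2)); \code{"resnik_norm"}:
#' IC(MICA) / max IC in the namespace. MICA is the common ancestor
#' (including the terms themselves) with maximal information content. A
#' cross-namespace pair has similarity 0.
#'
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param t1,t2 term ids.
#' @param method \code{"lin"} (default) or \code{"resnik_norm"}.
#' @return similarity in [0, 1].
#' @export
termSemanticSimilarity <- function(dag, t1, t2,
                                   method = c("lin", "resnik_norm")) {
  method <- match.arg(method)
  if (!all(c(t1, t2) %in% dag@terms)) stop("unknown term id")
  ctx <- .simContext(dag)
  .termSimCtx(ctx, t1, t2, method)
}

.geneSimCtx <- function(ctx, gene_a, gene_b, method = "lin") {
  key <- paste(sort(c(gene_a, gene_b)), collapse = "\r")
  hit <- ctx$paircache[[key]]
  if (!is.null(hit)) return(hit)
  ann <- ctx$dag@annotations
  ta <- ann[[gene_a]]
  tb <- ann[[gene_b]]
  if (is.null(ta) || is.null(tb) || !length(ta) || !length(tb)) {
    stop("gene without annotation: ",
         if (is.null(ta) || !length(ta)) gene_a else gene_b,
         " (no annotation is not the same as similarity 0)")
  }
  smat <- matrix(0, length(ta), length(tb))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      smat[i, j] <- .termSimCtx(ctx, ta[i], tb[j], method)
    }
  }
  val <- (mean(apply(smat, 1L, max)) + mean(apply(smat, 2L, max))) / 2
  ctx$paircache[[key]] <- val
  val
}

#' Functional similarity between two genes (best-match average)
#'
#' Mean over both directions of, for each term of one gene, the maximum
#' Lin similarity to the other gene's terms.
#'
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param gene_a,gene_b gene ids (must be annotated; an unannotated gene is
#'   an error, distinguished from similarity 0).
#' @param method term-similarity flavour (see
#'   \code{\link{termSemanticSimilarity}}).
#' @return similarity in [0, 1].
#' @export
geneFunctionalSimilarity <- function(dag, gene_a, gene_b, method = "lin") {
  ctx <- .simContext(dag)
  .geneSimCtx(ctx, gene_a, gene_b, method)
}

#' Build the positive gold standard
#'
#' Union of (i) all unordered within-set pairs of each GO category, (ii)
#' within-set pairs of each pathway, (iii) protein-protein interaction
#' edges and (iv) probabilistic functional network links, restricted to the
#' analysis gene universe and deduplicated. GO categories larger than
#' \code{max_set_size} genes are skipped so root-like terms do not flood
#' the standard.
#'
#' @param go_sets named list of GO category gene sets (may be empty).
#' @param pathways named list of pathway gene sets (may be empty).
#' @param ppi,pfn \linkS4class{ScoredNetwork}s or data.frames with
#'   geneA/geneB columns (may be NULL).
#' @param universe gene universe to restrict to (NULL = no restriction).
#' @param max_set_size skip GO sets with more members (default 500).
#' @return data.frame of canonical positive pairs.
#' @export
buildPositiveStandard <- function(go_sets = list(), pathways = list(),
                                  ppi = NULL, pfn = NULL, universe = NULL,
                                  max_set_size = 500L) {
  restrict <- function(genes) {
    if (is.null(universe)) genes else intersect(genes, universe)
  }
  parts <- list()
  for (s in go_sets) {
    g <- restrict(s)
    if (length(g) >= 2L && length(s) <= max_set_size) {
      parts[[length(parts) + 1L]] <- .setPairs(g)
    }
  }
  for (s in pathways) {
    g <- restrict(s)
    if (length(g) >= 2L) parts[[length(parts) + 1L]] <- .setPairs(g)
  }
  for (net in list(ppi, pfn)) {
    if (is.null(net)) next
    e <- if (methods::is(net, "ScoredNetwork")) edgeTable(net) else
      as.data.frame(net)
    if (!nrow(e)) next
    a <- pmin(as.character(e$geneA), as.character(e$geneB))
    b <- pmax(as.character(e$geneA), as.character(e$geneB))
    keep <- a != b
    if (!is.null(universe)) keep <- keep & a %in% universe & b %in% universe
    parts[[length(parts) + 1L]] <- data.frame(geneA = a[keep],
                                              geneB = b[keep])
  }
  if (!length(parts)) stop("at least one positive-link source must be nonempty")
  all <- do.call(rbind, parts)
  all <- all[!duplicated(paste(all$geneA, all$geneB)), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Build the negative gold standard
#'
#' Four steps: (1) candidate term pairs are same-namespace pairs with
#' semantic similarity exactly 0 whose propagated gene counts lie strictly
#' between \code{min_go_size} and \code{max_go_size}; (2) initial negatives
#' are all cross pairs (one gene from each term of a candidate pair), genes
#' shared by both terms excluded; (3) the similarity threshold is the mean
#' over \code{n_backgrounds} repetitions of the
#' \code{background_percentile}th percentile of the functional similarities
#' of \code{pairs_per_background} randomly sampled annotated gene pairs;
#' (4) final negatives are the initial negatives with functional
#' similarity strictly below the threshold.
#'
#' @param dag an annotated \linkS4class{OntologyDAG}.
#' @param cfg a \code{\link{NegativeStandardConfig}}.
#' @param universe optional gene universe to restrict pairs to.
#' @return data.frame of canonical negative pairs; attributes
#'   \code{"threshold"} and \code{"n_candidate_term_pairs"} record the
#'   construction.
#' @export
buildNegativeStandard <- function(dag, cfg = NegativeStandardConfig(),
                                  universe = NULL) {
  ctx <- .simContext(dag)
  sets <- .termGeneSets(dag)
  counts <- vapply(sets, function(g) length(unique(g)), integer(1))
  eligible <- names(counts)[counts > cfg$min_go_size &
                            counts < cfg$max_go_size]
  cand <- list()
  if (length(eligible) >= 2L) {
    cmb <- utils::combn(eligible, 2L)
    for (k in seq_len(ncol(cmb))) {
      t1 <- cmb[1L, k]; t2 <- cmb[2L, k]
      if (ctx$dag@namespace[[t1]] != ctx$dag@namespace[[t2]]) next
      if (.termSimCtx(ctx, t1, t2, "lin") == 0) {
        cand[[length(cand) + 1L]] <- c(t1, t2)
      }
    }
  }
  empty <- data.frame(geneA = character(), geneB = character())
  if (!length(cand)) {
    warning("no zero-similarity candidate term pairs; negative set is empty")
    attr(empty, "threshold") <- NA_real_
    attr(empty, "n_candidate_term_pairs") <- 0L
    return(empty)
  }
  annotated <- names(dag@annotations)[lengths(dag@annotations) > 0]
  if (!is.null(universe)) annotated <- intersect(annotated, universe)
  pairs <- list()
  for (tp in cand) {
    ga <- unique(sets[[tp[1L]]])
    gb <- unique(sets[[tp[2L]]])
    shared <- intersect(ga, gb)
    ga <- setdiff(ga, shared)
    gb <- setdiff(gb, shared)
    if (!is.null(universe)) {
      ga <- intersect(ga, universe)
      gb <- intersect(gb, universe)
    }
    if (!length(ga) || !length(gb)) next
    grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    pairs[[length(pairs) + 1L]] <-
      data.frame(geneA = pmin(grid$a, grid$b), geneB = pmax(grid$a, grid$b))
  }
  if (!length(pairs)) {
    warning("candidate term pairs yielded no gene pairs")
    attr(empty, "threshold") <- NA_real_
    attr(empty, "n_candidate_term_pairs") <- length(cand)
    return(empty)
  }
  initial <- do.call(rbind, pairs)
  initial <- initial[initial$geneA != initial$geneB, , drop = FALSE]
  initial <- initial[!duplicated(paste(initial$geneA, initial$geneB)), ,
                     drop = FALSE]
  # background threshold: mean of per-repetition percentiles
  threshold <- .withSeed(cfg$seed, {
    percs <- vapply(seq_len(cfg$n_backgrounds), function(i) {
      a <- sample(annotated, cfg$pairs_per_background, replace = TRUE)
      b <- sample(annotated, cfg$pairs_per_background, replace = TRUE)
      same <- a == b
      while (any(same)) {     # self-pairs carry no dissimilarity signal
        b[same] <- sample(annotated, sum(same), replace = TRUE)
        same <- a == b
      }
      sims <- vapply(seq_along(a), function(k)
        .geneSimCtx(ctx, a[k], b[k]), numeric(1))
      .percentile(sims, cfg$background_percentile)
    }, numeric(1))
    mean(percs)
  })
  sims <- vapply(seq_len(nrow(initial)), function(k)
    .geneSimCtx(ctx, initial$geneA[k], initial$geneB[k]), numeric(1))
  out <- initial[sims < threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_candidate_term_pairs") <- length(cand)
  out
}

#' Assemble a GoldStandard from positive and negative pair sets
#'
#' Thin wrapper around the \code{\link{GoldStandard}} constructor that
#' computes the universe size from a gene universe.
#'
#' @param positives,negatives data.frames of gene pairs.
#' @param universe character vector of genes in the reference space.
#' @return a \linkS4class{GoldStandard}.
#' @export
assembleGoldStandard <- function(positives, negatives, universe) {
  GoldStandard(positives, negatives, universeN = length(universe))
}
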