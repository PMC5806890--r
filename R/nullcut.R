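#' Configuration for the permutation-derived score cutoff
#'
#' @param n_permutations number of random datasets (default 100).
#' @param percentile percentile of each null score distribution (default
#'   99.99).
#' @param seed integer seed for the permutations.
#' @param joint permute all genes with one shared sample permutation
#'   (\code{TRUE}) instead of independently per gene (default \code{FALSE}).
#' @return a list of class \code{NullCutoffConfig}.
#' @export
NullCutoffConfig <- function(n_permutations = 100L, percentile = 99.99,
                             seed = 1L, joint = FALSE) {
  stopifnot(n_permutations >= 1, percentile > 0, percentile < 100)
  structure(list(n_permutations = as.integer(n_permutations),
                 percentile = percentile, seed = as.integer(seed),
                 joint = joint),
            class = "NullCutoffConfig")
}

#' Permute an expression matrix to destroy co-expression
#'
#' Each gene's values are permuted across samples (independently per gene
#' by default), which preserves every gene's marginal value multiset while
#' destroying inter-gene correlation. With \code{joint = TRUE} a single
#' permutation is reused across genes (which preserves correlations; only
#' useful as a control).
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param seed integer seed.
#' @param joint reuse one sample permutation across all genes.
#' @return a permuted \linkS4class{ExpressionMatrix} of the same kind.
#' @export
permuteMatrix <- function(m, seed = 1L, joint = FALSE) {
  v <- exprValues(m)
  .withSeed(seed, {
    if (joint) {
      v <- v[, sample.int(ncol(v)), drop = FALSE]
      colnames(v) <- sampleIds(m)
    } else {
      for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(ncol(v))]
    }
  })
  ExpressionMatrix(v, kind = exprKind(m))
}

#' Permutation-null confidence-score cutoff
#'
#' Generates \code{n_permutations} randomized datasets, computes the full
#' distribution of pairwise confidence scores on each with \code{score_fn},
#' takes the configured percentile of each null distribution, and returns
#' the arithmetic mean of those percentiles. Filtering a real network at
#' this cutoff retains only links stronger than virtually everything the
#' null produces.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param score_fn function mapping an \linkS4class{ExpressionMatrix} to a
#'   numeric vector of pairwise confidence scores (e.g. the upper triangle
#'   of \code{\link{methodScoreMatrix}}).
#' @param cfg a \code{\link{NullCutoffConfig}}.
#' @return list with \code{cutoff} (the mean of per-permutation
#'   percentiles) and \code{percentiles} (one per permutation).
#' @export
permutationCutoff <- function(m, score_fn, cfg = NullCutoffConfig()) {
  need <- 1e4 / (100 - cfg$percentile)
  percs <- vapply(seq_len(cfg$n_permutations), function(i) {
    mp <- permuteMatrix(m, seed = cfg$seed + i - 1L, joint = cfg$joint)
    scores <- score_fn(mp)
    if (i == 1L && length(scores) < need) {
      warning(sprintf(
        "only %d null scores per permutation; the %.2fth percentile is noisy",
        length(scores), cfg$percentile))
    }
    .percentile(scores, cfg$percentile)
  }, numeric(1))
  list(cutoff = mean(percs), percentiles = percs)
}

#' Upper-triangle score distribution for a method
#'
#' Builds the \code{score_fn} that \code{\link{permutationCutoff}} expects
#' from an inference method name.
#'
#' @param method \code{"wgcna"} or \code{"ggm"}.
#' @param wgcna_cfg,cor_method passed to \code{\link{methodScoreMatrix}}.
#' @param ggm_lambda fixed shrinkage intensity for \code{"ggm"} nulls;
#'   pass the intensity estimated on the observed data so null and
#'   observed scores share a scale (see
#'   \code{\link{methodScoreMatrix}}).
#' @return function of an \linkS4class{ExpressionMatrix} returning the
#'   pairwise score vector.
#' @export
methodScoreFn <- function(method, wgcna_cfg = WgcnaConfig(),
                          cor_method = "pearson", ggm_lambda = NULL) {
  force(method); force(wgcna_cfg); force(cor_method); force(ggm_lambda)
  function(m) {
    s <- methodScoreMatrix(m, method, wgcna_cfg, cor_method, ggm_lambda)
    s[upper.tri(s)]
  }
}

#' Filter a network at a score cutoff
#'
#' Keeps edges with score >= cutoff (boundary inclusive).
#'
#' @param net a \linkS4class{ScoredNetwork}.
#' @param cutoff numeric score cutoff.
#' @return the filtered \linkS4class{ScoredNetwork}.
#' @export
applyCutoff <- function(net, cutoff) {
  e <- edgeTable(net)
  ScoredNetwork(e[e$score >= cutoff, , drop = FALSE],
                nodes = nodeUniverse(net),
                method = methodTag(net), dataset = datasetTag(net))
}

#' Write a permutation-cutoff audit report
#'
#' Emits the per-permutation percentiles and the final cutoff as a small
#' tab-separated table.
#'
#' @param cut result of \code{\link{permutationCutoff}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCutoffReport <- function(cut, path) {
  df <- data.frame(permutation = seq_along(cut$percentiles),
                   percentile_score = cut$percentiles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff\t%.10g", cut$cutoff), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
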