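# run expr with a private, restored RNG stream seeded from `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the weighted-correlation (soft threshold) method
#'
#' @param beta soft-threshold power (positive integer, default 6).
#' @param beta_selection \code{"fixed"} uses \code{beta} as given;
#'   \code{"scale_free_fit"} picks the smallest power in
#'   \code{candidate_betas} whose scale-free topology fit reaches
#'   \code{target_r2}, falling back to the best-fitting power.
#' @param target_r2 target scale-free model fit R^2 (default 0.8).
#' @param candidate_betas powers scanned under \code{"scale_free_fit"}.
#' @return a list of class \code{WgcnaConfig}.
#' @export
WgcnaConfig <- function(beta = 6L, beta_selection = c("fixed", "scale_free_fit"),
                        target_r2 = 0.8, candidate_betas = 1:20) {
  stopifnot(beta >= 1)
  structure(list(beta = as.integer(beta),
                 beta_selection = match.arg(beta_selection),
                 target_r2 = target_r2,
                 candidate_betas = as.integer(candidate_betas)),
            class = "WgcnaConfig")
}

#' Configuration for the bagged conservative-core MI method
#'
#' @param n_bootstrap number of bootstrap resamples B (default 100).
#' @param mi_alpha significance level for the per-resample MI null test
#'   (default 0.05).
#' @param edge_alpha BH-adjusted significance level for the edge-frequency
#'   binomial test (default 0.05).
#' @param mi_estimator \code{"gaussian"} (closed form from correlation) or
#'   \code{"binned"} (plug-in estimator on equal-frequency bins).
#' @param n_null number of permutation draws for the MI null, pooled across
#'   gene pairs and shared by all bootstrap resamples (default 20000). The
#'   empirical p-value floor is 1/(n_null + 1); it must stay below the BH
#'   threshold alpha * k / n_pairs for true edges to remain detectable, so
#'   large gene sets need a large null.
#' @return a list of class \code{Bc3netConfig}.
#' @export
Bc3netConfig <- function(n_bootstrap = 100L, mi_alpha = 0.05,
                         edge_alpha = 0.05,
                         mi_estimator = c("gaussian", "binned"),
                         n_null = 20000L) {
  stopifnot(mi_alpha > 0, mi_alpha < 1, edge_alpha > 0, edge_alpha < 1,
            n_bootstrap >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap), mi_alpha = mi_alpha,
                 edge_alpha = edge_alpha,
                 mi_estimator = match.arg(mi_estimator),
                 n_null = as.integer(n_null)),
            class = "Bc3netConfig")
}

# scale-free topology fit R^2 for a soft adjacency (log-log regression of
# binned degree frequency on degree)
.scaleFreeFitR2 <- function(a, n_breaks = 10L) {
  k <- rowSums(a)
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  cuts <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3L) return(0)
  summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted adjacency a_ij = |cor(i, j)|^beta with zero diagonal.
#' Constant genes (undefined correlation) get adjacency 0 against every
#' other gene, with a warning.
#'
#' @param m an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param cfg a \code{\link{WgcnaConfig}}.
#' @param cor_method correlation flavour fed to the power (default
#'   \code{"pearson"}; \code{"spearman"} available for count data).
#' @return symmetric adjacency matrix with entries in [0, 1] and zero
#'   diagonal; attribute \code{"beta"} records the power used.
#' @export
softAdjacency <- function(m, cfg = WgcnaConfig(),
                          cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  v <- exprValues(m)
  if (ncol(v) < 3L) stop("soft adjacency needs at least 3 samples")
  r <- suppressWarnings(stats::cor(t(v), method = cor_method))
  if (anyNA(r)) {
    warning("constant genes present; their adjacencies are set to 0")
    r[is.na(r)] <- 0
  }
  absr <- pmin(abs(r), 1)
  beta <- cfg$beta
  if (cfg$beta_selection == "scale_free_fit") {
    fits <- vapply(cfg$candidate_betas, function(b) {
      a <- absr^b
      diag(a) <- 0
      .scaleFreeFitR2(a)
    }, numeric(1))
    hit <- which(fits >= cfg$target_r2)
    beta <- if (length(hit)) cfg$candidate_betas[hit[1L]] else
      cfg$candidate_betas[which.max(fits)]
  }
  a <- absr^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i = sum_u a_iu; the diagonal is defined as 1. High overlap means the
#' two genes share much of their weighted neighborhood as well as a direct
#' connection.
#'
#' @param a symmetric adjacency matrix with entries in [0, 1] and zero
#'   diagonal (see \code{\link{softAdjacency}}).
#' @return symmetric matrix of topological overlaps in [0, 1].
#' @export
topologicalOverlap <- function(a) {
  beta <- attr(a, "beta")
  attr(a, "beta") <- NULL
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  .assertScoreMatrix(a)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  attr(tom, "beta") <- beta
  tom
}

#' Shrinkage-regularized partial correlations (Gaussian graphical model)
#'
#' The sample correlation matrix is shrunk toward the identity with the
#' analytic optimal intensity lambda* (ratio of summed estimated variances
#' of the off-diagonal correlations to their summed squares, clamped to
#' [0, 1]). Partial correlations come from the inverse Omega of the shrunk
#' correlation matrix: pcor_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj).
#' Shrinkage keeps the estimate invertible when genes outnumber samples.
#'
#' @param m an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param lambda optional fixed shrinkage intensity in [0, 1]; by default
#'   the analytic estimate is used.
#' @return list with \code{pcor} (symmetric matrix, unit diagonal) and
#'   \code{lambda} (the intensity used).
#' @export
ggmPartialCorrelation <- function(m, lambda = NULL) {
  v <- exprValues(m)
  n <- ncol(v)
  p <- nrow(v)
  if (n < 3L) stop("partial correlation needs at least 3 samples")
  x <- t(v)                     # samples x genes
  x <- scale(x)                 # unit (n-1) variance
  if (anyNA(x)) stop("constant genes are not allowed; prefilter first")
  r <- crossprod(x) / (n - 1)
  if (is.null(lambda)) {
    w2sum <- crossprod(x^2)               # sum_k w_kij^2
    wsum <- crossprod(x)                  # sum_k w_kij
    varr <- (n / (n - 1)^3) * (w2sum - wsum^2 / n)
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom > 0) sum(varr[off]) / denom else 1
    lambda <- min(1, max(0, lambda))
  }
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- tryCatch(solve(rs), error = function(e)
    stop("shrunk correlation matrix is singular; increase lambda"))
  d <- sqrt(diag(omega))
  pcor <- -omega / outer(d, d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- list(rownames(v), rownames(v))
  list(pcor = pcor, lambda = lambda)
}

# equal-frequency binning into ceiling(sqrt(n)) bins
.binEqualFreq <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  ceiling(n_bins * r / length(x))
}

# plug-in MI with Miller-Madow bias correction (the plug-in estimator is
# biased upward by ~ (B-1)^2 / 2n, which is substantial at B = sqrt(n))
.binnedMiPair <- function(bi, bj, n_bins) {
  n <- length(bi)
  tab <- table(factor(bi, levels = seq_len(n_bins)),
               factor(bj, levels = seq_len(n_bins))) / n
  pi <- rowSums(tab)
  pj <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pi, pj)[nz]))
  max(0, mi - (n_bins - 1)^2 / (2 * n))
}

#' Pairwise mutual information matrix
#'
#' The \code{"gaussian"} estimator uses the closed form
#' MI = -0.5 * ln(1 - rho^2) (in nats) with Pearson (or Spearman)
#' correlation rho; perfectly correlated pairs are capped at \code{mi_cap}
#' with a warning. The \code{"binned"} estimator is the plug-in estimate on
#' equal-frequency bins (ceiling(sqrt(n)) bins per variable).
#'
#' @param m an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param estimator \code{"gaussian"} (default) or \code{"binned"}.
#' @param cor_method correlation for the gaussian estimator.
#' @param mi_cap finite cap used when |rho| = 1 (default 50 nats).
#' @return symmetric non-negative MI matrix (nats) with zero diagonal.
#' @export
mutualInformation <- function(m, estimator = c("gaussian", "binned"),
                              cor_method = c("pearson", "spearman"),
                              mi_cap = 50) {
  estimator <- match.arg(estimator)
  cor_method <- match.arg(cor_method)
  v <- exprValues(m)
  n <- ncol(v)
  if (n < 3L) stop("mutual information needs at least 3 samples")
  if (estimator == "gaussian") {
    r <- suppressWarnings(stats::cor(t(v), method = cor_method))
    r[is.na(r)] <- 0
    r2 <- pmin(r^2, 1)
    mi <- -0.5 * log1p(-r2)
    sat <- r2 >= 1 - 1e-12          # |rho| = 1 up to floating point
    diag(sat) <- FALSE
    if (any(sat)) {
      warning("perfectly correlated gene pairs; MI capped at ", mi_cap)
      mi[sat] <- mi_cap
    }
  } else {
    n_bins <- ceiling(sqrt(n))
    bins <- apply(v, 1L, .binEqualFreq, n_bins = n_bins)  # samples x genes
    p <- nrow(v)
    mi <- matrix(0, p, p)
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        mi[i, j] <- mi[j, i] <- .binnedMiPair(bins[, i], bins[, j], n_bins)
      }
    }
  }
  diag(mi) <- 0
  mi[mi < 0] <- 0
  dimnames(mi) <- list(rownames(v), rownames(v))
  mi
}

# permutation null MI values pooled across gene pairs: each draw permutes
# one profile of a randomly chosen pair, destroying the dependence. With
# boot = TRUE each draw is taken on a bootstrap resample of the samples,
# matching the duplication-driven inflation of bootstrap MI values.
.nullMi <- function(v, n_null, estimator, cor_method, boot = FALSE) {
  p <- nrow(v)
  n <- ncol(v)
  i <- sample.int(p, n_null, replace = TRUE)
  j <- sample.int(p - 1L, n_null, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  vapply(seq_len(n_null), function(k) {
    # permute one profile (independence), then draw both through one
    # shared bootstrap index so duplicate alignment matches the real
    # bootstrap MI distribution
    idx <- if (boot) sample.int(n, n, replace = TRUE) else seq_len(n)
    perm <- sample.int(n)
    a <- v[i[k], idx]
    b <- v[j[k], perm[idx]]
    if (estimator == "gaussian") {
      r <- suppressWarnings(stats::cor(a, b, method = cor_method))
      if (is.na(r)) r <- 0
      -0.5 * log1p(-min(r^2, 1 - 1e-12))
    } else {
      nb <- ceiling(sqrt(n))
      .binnedMiPair(.binEqualFreq(a, nb), .binEqualFreq(b, nb), nb)
    }
  }, numeric(1))
}

#' Conservative causal core of a mutual-information matrix
#'
#' Pairwise MI values are assigned pooled-permutation empirical p-values,
#' adjusted for multiple testing across pairs (BH by default, as in the
#' bagged conservative-core algorithm); values not significant at
#' \code{alpha} are zeroed. Each gene then nominates its single maximum-MI
#' significant neighbor, and the network is the undirected, deduplicated
#' union of the nominations. Argmax ties are broken by lexicographic gene
#' id. Note the empirical p-value floor 1/(length(null_mi) + 1): with BH
#' adjustment, a small null makes every pair non-significant on large gene
#' sets.
#'
#' @param mi symmetric MI matrix with gene dimnames.
#' @param alpha significance level for the (adjusted) MI test.
#' @param null_mi nonempty numeric vector of null MI draws (see
#'   \code{\link{bc3net}} for how they are generated).
#' @param p_adjust multiple-testing correction across pairs
#'   (\code{"BH"} default; \code{"none"} gives the uncorrected rule).
#' @return a \linkS4class{ScoredNetwork} with MI edge scores.
#' @export
c3net <- function(mi, alpha = 0.05, null_mi, p_adjust = "BH") {
  if (!length(null_mi)) stop("null_mi must be nonempty")
  genes <- rownames(mi)
  if (is.null(genes)) stop("mi matrix needs gene dimnames")
  nn <- length(null_mi)
  null_sorted <- sort(null_mi)
  # empirical p of each MI value: (1 + #null >= x) / (1 + n_null)
  cnt_ge <- function(x) nn - findInterval(x - 1e-15, null_sorted)
  ut <- upper.tri(mi)
  p_ut <- (1 + cnt_ge(mi[ut])) / (1 + nn)
  if (p_adjust != "none") p_ut <- stats::p.adjust(p_ut, method = p_adjust)
  pmat <- matrix(1, nrow(mi), ncol(mi))
  pmat[ut] <- p_ut
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  sig <- pmat < alpha
  diag(sig) <- FALSE
  p <- nrow(mi)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(p)) {
    cand <- which(sig[i, ])
    if (!length(cand)) next
    best <- cand[mi[i, cand] == max(mi[i, cand])]
    if (length(best) > 1L) best <- best[order(genes[best])][1L]
    from <- c(from, i)
    to <- c(to, best[1L])
  }
  if (!length(from)) {
    edges <- data.frame(geneA = character(), geneB = character(),
                        score = numeric())
  } else {
    a <- pmin(genes[from], genes[to])
    b <- pmax(genes[from], genes[to])
    keep <- !duplicated(paste(a, b))
    edges <- data.frame(geneA = a[keep], geneB = b[keep],
                        score = mi[cbind(from, to)][keep])
  }
  ScoredNetwork(edges, nodes = genes, method = "bc3net")
}

#' Bagged conservative causal core network
#'
#' Draws B bootstrap resamples of the samples, runs \code{\link{c3net}} on
#' each, and aggregates: the edge frequency f_e is the fraction of
#' resamples whose core network contains e, and edges survive when a
#' one-sided binomial test of their count against the global mean
#' nomination rate is significant after Benjamini-Hochberg correction at
#' \code{edge_alpha}. Surviving edges are scored by f_e.
#'
#' @param m an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param cfg a \code{\link{Bc3netConfig}}.
#' @param seed integer seed; the run is bit-reproducible under it.
#' @param dataset dataset provenance tag for the result.
#' @return a \linkS4class{ScoredNetwork} with bootstrap-frequency scores.
#' @export
bc3net <- function(m, cfg = Bc3netConfig(), seed = 1L, dataset = "") {
  v <- exprValues(m)
  n <- ncol(v)
  if (n < 3L) stop("bc3net needs at least 3 samples")
  if (cfg$n_bootstrap < 2L) stop("n_bootstrap must be >= 2")
  if (cfg$n_bootstrap < 10L) warning("n_bootstrap < 10 is unreliable")
  genes <- rownames(v)
  counts <- new.env(parent = emptyenv())
  total_nominations <- 0
  .withSeed(seed, {
    # one pooled null shared by all bootstrap cores (affordable at the
    # size the BH-corrected empirical p-values need)
    null_mi <- .nullMi(v, cfg$n_null, cfg$mi_estimator, "pearson",
                       boot = TRUE)
    for (b in seq_len(cfg$n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- ExpressionMatrix(`colnames<-`(v[, idx, drop = FALSE],
                                          paste0("b", seq_len(n))),
                             kind = exprKind(m))
      mi <- mutualInformation(mb, estimator = cfg$mi_estimator)
      net <- c3net(mi, alpha = cfg$mi_alpha, null_mi = null_mi)
      e <- edgeTable(net)
      total_nominations <- total_nominations + nrow(e)
      if (nrow(e)) {
        keys <- .edgeKeys(e)
        for (k in keys) {
          counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
        }
      }
    }
  })
  keys <- ls(counts)
  if (!length(keys)) {
    return(ScoredNetwork(data.frame(geneA = character(), geneB = character(),
                                    score = numeric()),
                         nodes = genes, method = "bc3net", dataset = dataset))
  }
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  n_pairs <- choose(length(genes), 2)
  p0 <- total_nominations / (cfg$n_bootstrap * n_pairs)
  pval <- stats::pbinom(cnt - 1L, cfg$n_bootstrap, p0, lower.tail = FALSE)
  qval <- stats::p.adjust(pval, method = "BH")
  keep <- qval < cfg$edge_alpha
  ab <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
  edges <- if (any(keep)) {
    data.frame(geneA = ab[, 1L], geneB = ab[, 2L],
               score = cnt[keep] / cfg$n_bootstrap)
  } else {
    data.frame(geneA = character(), geneB = character(), score = numeric())
  }
  ScoredNetwork(edges, nodes = genes, method = "bc3net", dataset = dataset)
}

#' Score matrix for one inference method
#'
#' Convenience wrapper used by the pipeline and the permutation-cutoff
#' machinery: returns the full symmetric confidence-score matrix (TOM for
#' \code{"wgcna"}, |partial correlation| for \code{"ggm"}).
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param method \code{"wgcna"} or \code{"ggm"} (bc3net has no dense score
#'   matrix; see \code{\link{bc3net}}).
#' @param wgcna_cfg,cor_method passed to \code{\link{softAdjacency}}.
#' @param ggm_lambda optional fixed shrinkage intensity for \code{"ggm"};
#'   used by the permutation-null machinery so null scores share the
#'   observed data's scale (the analytic intensity approaches 1 on
#'   permuted data, which would collapse the null toward zero).
#' @return symmetric score matrix with zero diagonal.
#' @export
methodScoreMatrix <- function(m, method = c("wgcna", "ggm"),
                              wgcna_cfg = WgcnaConfig(),
                              cor_method = "pearson",
                              ggm_lambda = NULL) {
  method <- match.arg(method)
  if (method == "wgcna") {
    s <- topologicalOverlap(softAdjacency(m, wgcna_cfg, cor_method))
  } else {
    s <- abs(ggmPartialCorrelation(m, lambda = ggm_lambda)$pcor)
  }
  diag(s) <- 0
  attr(s, "beta") <- NULL
  s
}
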