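#' Filtering configuration for samples and genes
#'
#' Three criteria are applied to a raw count matrix before network
#' inference: (I) samples in which more than \code{sample_low_fraction} of
#' genes have fewer than \code{low_count_threshold} reads are dropped; (II)
#' genes with fewer than \code{low_count_threshold} reads in more than
#' \code{gene_low_fraction} of samples are dropped; (III) genes whose
#' coefficient of variation (sd/mean, sample sd) is below \code{min_cv} are
#' dropped. Boundaries are strict: removal requires the fraction to exceed
#' the threshold, and CV strictly below \code{min_cv}.
#'
#' @param low_count_threshold count below which a gene is "not expressed"
#'   in a sample (default 10 reads).
#' @param sample_low_fraction fraction of low-count genes above which a
#'   sample is removed (default 0.90).
#' @param gene_low_fraction fraction of low-count samples above which a
#'   gene is removed (default 0.80).
#' @param min_cv minimum coefficient of variation (default 0.5).
#' @param cv_on compute the CV on \code{"raw"} counts (default) or on a
#'   \code{"normalized"} matrix supplied to \code{\link{filterGenes}}.
#' @return a list of class \code{FilterConfig}.
#' @export
FilterConfig <- function(low_count_threshold = 10, sample_low_fraction = 0.90,
                         gene_low_fraction = 0.80, min_cv = 0.5,
                         cv_on = c("raw", "normalized")) {
  stopifnot(low_count_threshold >= 0, min_cv >= 0,
            sample_low_fraction > 0, sample_low_fraction <= 1,
            gene_low_fraction > 0, gene_low_fraction <= 1)
  structure(list(low_count_threshold = low_count_threshold,
                 sample_low_fraction = sample_low_fraction,
                 gene_low_fraction = gene_low_fraction,
                 min_cv = min_cv, cv_on = match.arg(cv_on)),
            class = "FilterConfig")
}

#' Remove unreliable samples from a raw count matrix
#'
#' Drops every sample in which the fraction of genes with counts below the
#' low-count threshold exceeds \code{sample_low_fraction} (criterion I).
#' Gene set and original ordering are preserved.
#'
#' @param m an \linkS4class{ExpressionMatrix} of kind \code{"raw_counts"}.
#' @param cfg a \code{\link{FilterConfig}}.
#' @return the filtered \linkS4class{ExpressionMatrix}.
#' @export
filterSamples <- function(m, cfg = FilterConfig()) {
  stopifnot(exprKind(m) == "raw_counts")
  v <- exprValues(m)
  lowfrac <- colMeans(v < cfg$low_count_threshold)
  keep <- lowfrac <= cfg$sample_low_fraction
  if (!any(keep)) stop("no samples survive the low-count filter")
  ExpressionMatrix(v[, keep, drop = FALSE], kind = "raw_counts")
}

#' Remove unreliable genes from a raw count matrix
#'
#' Applies criterion II (low counts in more than \code{gene_low_fraction}
#' of samples) and then criterion III (coefficient of variation below
#' \code{min_cv}). A gene with mean zero is removed by criterion II before
#' the CV is ever evaluated, so the CV is always defined. The CV is
#' computed on raw counts by default (\code{cfg$cv_on}); pass a normalized
#' matrix via \code{cv_matrix} to compute it there instead.
#'
#' @param m an \linkS4class{ExpressionMatrix} of kind \code{"raw_counts"}.
#' @param cfg a \code{\link{FilterConfig}}.
#' @param cv_matrix optional matrix (same genes) on which to evaluate
#'   criterion III when \code{cfg$cv_on == "normalized"}.
#' @return the filtered \linkS4class{ExpressionMatrix}.
#' @export
filterGenes <- function(m, cfg = FilterConfig(), cv_matrix = NULL) {
  stopifnot(exprKind(m) == "raw_counts")
  v <- exprValues(m)
  if (ncol(v) < 2L) stop("gene filtering needs at least 2 samples")
  lowfrac <- rowMeans(v < cfg$low_count_threshold)
  keep2 <- lowfrac <= cfg$gene_low_fraction
  v2 <- v[keep2, , drop = FALSE]
  if (!nrow(v2)) stop("no genes survive the low-count filter")
  cvsrc <- v2
  if (cfg$cv_on == "normalized") {
    if (is.null(cv_matrix)) stop("cv_on='normalized' requires cv_matrix")
    cvsrc <- cv_matrix[rownames(v2), , drop = FALSE]
  }
  mu <- rowMeans(cvsrc)
  sdv <- apply(cvsrc, 1L, stats::sd)
  cv <- sdv / mu
  keep3 <- cv >= cfg$min_cv
  out <- v2[keep3, , drop = FALSE]
  if (!nrow(out)) stop("no genes survive the CV filter")
  ExpressionMatrix(out, kind = "raw_counts")
}

# upper-quartile factors: 75th percentile of each sample's nonzero counts,
# scaled to geometric mean one
.uqFactors <- function(v) {
  q <- apply(v, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("a sample has no nonzero counts; prefilter first")
    .percentile(nz, 75)
  })
  q / .geomMean(q)
}

# median-of-ratios size factors (DESeq-style); reference = per-gene
# geometric mean over samples, genes containing any zero excluded
.rleFactors <- function(v) {
  sf <- tryCatch(
    DESeq2::estimateSizeFactorsForMatrix(v),
    error = function(e) {
      stop("RLE size factors undefined (likely every gene contains a zero); ",
           "prefilter low-count genes first [", conditionMessage(e), "]")
    })
  unname(sf)
}

# TMM scaling factors via edgeR (trimmed mean of M-values; 30% M-trim, 5%
# A-trim, precision weights, reference sample = upper quartile closest to
# the mean, factors normalized to geometric mean one)
.tmmFactors <- function(v, logratioTrim = 0.3, sumTrim = 0.05) {
  f <- edgeR::calcNormFactors(v, method = "TMM",
                              logratioTrim = logratioTrim, sumTrim = sumTrim)
  lib <- colSums(v)
  eff <- f * lib
  unname(eff / .geomMean(eff))
}

# closed-form NB variance-stabilizing transform via DESeq2's parametric
# dispersion trend; falls back to log2(x/sf + 1) when the fit fails
.vstTransform <- function(v) {
  vi <- round(v)
  storage.mode(vi) <- "integer"
  out <- tryCatch(
    suppressMessages(
      DESeq2::varianceStabilizingTransformation(vi, fitType = "parametric")),
    error = function(e) NULL)
  if (is.null(out)) {
    warning("parametric dispersion fit failed; using log2(x/sizefactor + 1)")
    sf <- .rleFactors(v)
    out <- log2(sweep(v, 2L, sf, "/") + 1)
  }
  dimnames(out) <- dimnames(v)
  out
}

#' Normalize a raw count matrix
#'
#' Produces one of the six expression datasets the ensemble votes over:
#' \describe{
#'   \item{uq}{each sample divided by the 75th percentile of its nonzero
#'     counts, rescaled so the factors have geometric mean one.}
#'   \item{tmm}{trimmed mean of M-values scaling factors (via edgeR)
#'     applied to library sizes; values divided by the effective factor.}
#'   \item{rle}{median-of-ratios size factors against the per-gene
#'     geometric-mean pseudo-reference; genes containing any zero are
#'     excluded from the reference.}
#'   \item{vst}{negative-binomial variance-stabilizing transform with a
#'     parametric dispersion trend a(mu) = a0/mu + a1 (via DESeq2), after
#'     size-factor normalization; documented fallback is
#'     log2(x/sizefactor + 1) when the parametric fit fails.}
#'   \item{fpkm_passthrough}{accepts a pre-computed FPKM matrix unchanged
#'     (gene lengths are never recomputed here).}
#'   \item{raw_passthrough}{the counts themselves, retagged.}
#' }
#'
#' @param m an \linkS4class{ExpressionMatrix}; kind \code{"raw_counts"} for
#'   uq/tmm/rle/vst, \code{"fpkm"} for \code{fpkm_passthrough}.
#' @param method normalization method.
#' @return an \linkS4class{ExpressionMatrix} with \code{kind} set to the
#'   produced dataset tag.
#' @examples
#' m <- ExpressionMatrix(matrix(rpois(600, 50), 20, 30,
#'        dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30))))
#' normalizeExpression(m, "uq")
#' @export
normalizeExpression <- function(m, method = c("uq", "tmm", "rle", "vst",
                                              "fpkm_passthrough",
                                              "raw_passthrough")) {
  method <- match.arg(method)
  v <- exprValues(m)
  if (method == "raw_passthrough") {
    stopifnot(exprKind(m) == "raw_counts")
    return(m)
  }
  if (method == "fpkm_passthrough") {
    if (exprKind(m) != "fpkm") stop("fpkm_passthrough expects an FPKM matrix")
    return(m)
  }
  if (exprKind(m) != "raw_counts") {
    stop("normalization method '", method, "' requires raw counts")
  }
  if (any(colSums(v) <= 0)) stop("all library sizes must be positive")
  out <- switch(method,
    uq = sweep(v, 2L, .uqFactors(v), "/"),
    tmm = sweep(v, 2L, .tmmFactors(v), "/"),
    rle = sweep(v, 2L, .rleFactors(v), "/"),
    vst = .vstTransform(v))
  ExpressionMatrix(out, kind = method)
}

#' Produce the six datasets the ensemble is inferred over
#'
#' Raw counts plus (optionally) a matched FPKM matrix, and the four
#' normalized datasets uq/tmm/rle/vst. When no FPKM matrix is available the
#' raw counts stand in for that slot so the ensemble still votes over six
#' datasets of five distinct representations.
#'
#' @param counts filtered raw-count \linkS4class{ExpressionMatrix}.
#' @param fpkm optional \linkS4class{ExpressionMatrix} of kind
#'   \code{"fpkm"} over the same genes.
#' @return named list of six \linkS4class{ExpressionMatrix} objects with
#'   dataset tags \code{raw, fpkm, uq, tmm, rle, vst}.
#' @export
normalizedDatasets <- function(counts, fpkm = NULL) {
  stopifnot(exprKind(counts) == "raw_counts")
  if (is.null(fpkm)) {
    fp <- ExpressionMatrix(exprValues(counts), kind = "fpkm")
  } else {
    stopifnot(exprKind(fpkm) == "fpkm")
    fp <- fpkm
  }
  list(raw = counts,
       fpkm = fp,
       uq = normalizeExpression(counts, "uq"),
       tmm = normalizeExpression(counts, "tmm"),
       rle = normalizeExpression(counts, "rle"),
       vst = normalizeExpression(counts, "vst"))
}
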