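#' Whole-pipeline configuration
#'
#' Bundles the per-stage configurations and the global seed. Every source
#' of randomness in \code{\link{runPipeline}} (permutation cutoffs,
#' bootstrap bagging) is derived from \code{seed}, so a rerun with the same
#' configuration reproduces the final edge list bit-identically.
#'
#' @param filter a \code{\link{FilterConfig}}.
#' @param wgcna a \code{\link{WgcnaConfig}}.
#' @param bc3net a \code{\link{Bc3netConfig}}.
#' @param cutoff a \code{\link{NullCutoffConfig}}.
#' @param voting a \code{\link{VotingConfig}}.
#' @param datasets dataset tags to infer over (default all six).
#' @param methods inference methods (default all three).
#' @param cor_method correlation fed to the correlation-based methods.
#' @param apply_filters run the sample/gene filters first (default TRUE;
#'   disable when the matrix is prefiltered).
#' @param seed global integer seed.
#' @return a list of class \code{PipelineConfig}.
#' @export
PipelineConfig <- function(filter = FilterConfig(),
                           wgcna = WgcnaConfig(),
                           bc3net = Bc3netConfig(),
                           cutoff = NullCutoffConfig(),
                           voting = VotingConfig(),
                           datasets = c("raw", "fpkm", "uq", "tmm",
                                        "rle", "vst"),
                           methods = c("wgcna", "ggm", "bc3net"),
                           cor_method = "pearson",
                           apply_filters = TRUE,
                           seed = 1L) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(filter = filter, wgcna = wgcna, bc3net = bc3net,
                 cutoff = cutoff, voting = voting,
                 datasets = datasets, methods = methods,
                 cor_method = cor_method, apply_filters = apply_filters,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

# stable small hash of a config for manifests
.configHash <- function(cfg) {
  .fnv1a(paste(deparse(cfg), collapse = "\n"))
}

#' Build the 18 initial networks for one expression corpus
#'
#' For every (method, dataset) combination: the correlation-based methods
#' get a permutation-derived score cutoff (mean of per-permutation
#' 99.99th percentiles by default) and keep only links at or above it; the
#' bagged MI method filters internally through its bootstrap edge test and
#' receives no cutoff.
#'
#' @param datasets named list of \linkS4class{ExpressionMatrix} objects
#'   (see \code{\link{normalizedDatasets}}).
#' @param cfg a \code{\link{PipelineConfig}}.
#' @param verbose log per-network edge counts (default FALSE).
#' @return list with \code{networks} (per-method lists of filtered
#'   \linkS4class{ScoredNetwork}s) and \code{cutoffs} (per-network cutoff
#'   reports).
#' @export
inferInitialNetworks <- function(datasets, cfg = PipelineConfig(),
                                 verbose = FALSE) {
  networks <- list()
  cutoffs <- list()
  for (mi in seq_along(cfg$methods)) {
    method <- cfg$methods[mi]
    nets <- list()
    for (di in seq_along(cfg$datasets)) {
      ds <- cfg$datasets[di]
      m <- datasets[[ds]]
      stage_seed <- cfg$seed + 1000L * mi + 10L * di
      if (method == "bc3net") {
        net <- bc3net(m, cfg$bc3net, seed = stage_seed, dataset = ds)
      } else {
        lam <- NULL
        if (method == "ggm") {
          fit <- ggmPartialCorrelation(m)
          s <- abs(fit$pcor)
          diag(s) <- 0
          lam <- fit$lambda
        } else {
          s <- methodScoreMatrix(m, method, cfg$wgcna, cfg$cor_method)
        }
        ccfg <- cfg$cutoff
        ccfg$seed <- stage_seed
        cut <- permutationCutoff(
          m, methodScoreFn(method, cfg$wgcna, cfg$cor_method,
                           ggm_lambda = lam), ccfg)
        cutoffs[[paste(method, ds, sep = ".")]] <- cut
        net <- ScoredNetwork(.matrixToEdges(s, min_score = cut$cutoff),
                             nodes = rownames(s), method = method,
                             dataset = ds)
      }
      if (verbose) {
        message(sprintf("[%s/%s] %d edges", method, ds, edgeCount(net)))
      }
      nets[[ds]] <- net
    }
    networks[[method]] <- nets
  }
  list(networks = networks, cutoffs = cutoffs)
}

#' Vote the initial networks into the final consensus network
#'
#' Min-max normalizes every nonempty initial network, applies the
#' intra-method dataset vote, then the inter-method vote, and returns the
#' final network with its two-step re-scored confidences, edges sorted by
#' descending confidence.
#'
#' @param networks per-method lists of \linkS4class{ScoredNetwork}s (see
#'   \code{\link{inferInitialNetworks}}).
#' @param cfg a \code{\link{VotingConfig}}.
#' @return list with \code{final} (\linkS4class{ConsensusNetwork}) and
#'   \code{intra} (per-method \linkS4class{ConsensusNetwork}s).
#' @export
voteNetworks <- function(networks, cfg = VotingConfig()) {
  normed <- lapply(networks, function(nets) {
    lapply(nets, function(nt) {
      if (edgeCount(nt)) suppressMessages(minmaxNormalize(nt)) else nt
    })
  })
  intra <- lapply(normed, intraMethodConsensus, cfg = cfg)
  final <- interMethodConsensus(unname(intra), cfg = cfg)
  e <- edgeTable(final)
  if (nrow(e)) {
    e <- e[order(-e$score, e$geneA, e$geneB), , drop = FALSE]
    rownames(e) <- NULL
    final@edges <- e
  }
  list(final = final, intra = intra)
}

#' Run the full ensemble co-expression pipeline
#'
#' filter -> normalize (six datasets) -> infer (three methods per dataset)
#' -> permutation-cutoff filter -> two-step vote and re-score ->
#' (optionally) evaluate against a gold standard. Every intermediate
#' network, the cutoff reports, the final confidence-ranked edge list and a
#' JSON manifest (package version, seed, config hash, stage counts) are
#' written under \code{out_dir} when it is non-NULL.
#'
#' @param counts raw-count \linkS4class{ExpressionMatrix}.
#' @param cfg a \code{\link{PipelineConfig}}.
#' @param fpkm optional FPKM \linkS4class{ExpressionMatrix}.
#' @param gold optional \linkS4class{GoldStandard} for the evaluation
#'   stage.
#' @param out_dir output directory (NULL = keep everything in memory).
#' @param verbose log stage-by-stage gene/edge counts (default TRUE).
#' @return list with \code{final}, \code{intra}, \code{initial},
#'   \code{cutoffs}, \code{datasets}, \code{evaluation} (enrichment curves
#'   or NULL) and \code{manifest}.
#' @export
runPipeline <- function(counts, cfg = PipelineConfig(), fpkm = NULL,
                        gold = NULL, out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  filtered <- counts
  if (cfg$apply_filters) {
    filtered <- stage("filter", {
      x <- filterSamples(counts, cfg$filter)
      filterGenes(x, cfg$filter)
    })
  }
  say("filter: %d genes x %d samples retained", nrow(filtered),
      ncol(filtered))
  if (!is.null(fpkm)) {
    fpkm <- ExpressionMatrix(
      exprValues(fpkm)[geneIds(filtered), sampleIds(filtered), drop = FALSE],
      kind = "fpkm")
  }
  datasets <- stage("normalize", normalizedDatasets(filtered, fpkm))
  datasets <- datasets[cfg$datasets]
  say("normalize: %d datasets (%s)", length(datasets),
      paste(names(datasets), collapse = ", "))
  inferred <- stage("infer",
                    inferInitialNetworks(datasets, cfg, verbose = verbose))
  voted <- stage("vote", voteNetworks(inferred$networks, cfg$voting))
  say("vote: final network has %d edges over %d nodes",
      edgeCount(voted$final), length(nodeUniverse(voted$final)))
  evaluation <- NULL
  if (!is.null(gold)) {
    evaluation <- stage("evaluate", {
      N <- choose(universeSize(gold), 2)
      list(
        positive = enrichmentCurve(voted$final, positivePairs(gold),
                                   M = nrow(positivePairs(gold)), N = N),
        negative = enrichmentCurve(voted$final, negativePairs(gold),
                                   M = max(1L, nrow(negativePairs(gold))),
                                   N = N))
    })
  }
  manifest <- list(
    package = "coexEnsemble",
    version = as.character(utils::packageVersion("coexEnsemble")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = .configHash(cfg),
    n_genes = nrow(filtered),
    n_samples = ncol(filtered),
    n_initial_networks = sum(lengths(inferred$networks)),
    initial_edge_counts = lapply(inferred$networks, function(nets)
      vapply(nets, edgeCount, integer(1))),
    final_edges = edgeCount(voted$final))
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeExpressionMatrix(filtered, file.path(out_dir,
                                                "filtered_counts.tsv"))
      for (method in names(inferred$networks)) {
        for (ds in names(inferred$networks[[method]])) {
          writeEdgeList(inferred$networks[[method]][[ds]],
                        file.path(out_dir,
                                  sprintf("initial_%s_%s.tsv", method, ds)))
        }
      }
      for (nm in names(inferred$cutoffs)) {
        writeCutoffReport(inferred$cutoffs[[nm]],
                          file.path(out_dir,
                                    sprintf("cutoff_%s.tsv", nm)))
      }
      for (method in names(voted$intra)) {
        writeEdgeList(voted$intra[[method]],
                      file.path(out_dir,
                                sprintf("consensus_%s.tsv", method)))
      }
      writeEdgeList(voted$final, file.path(out_dir, "final_network.tsv"))
      if (!is.null(evaluation)) {
        utils::write.table(evaluation$positive,
                           file.path(out_dir, "enrichment_positive.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(evaluation$negative,
                           file.path(out_dir, "enrichment_negative.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  list(final = voted$final, intra = voted$intra,
       initial = inferred$networks, cutoffs = inferred$cutoffs,
       datasets = datasets, evaluation = evaluation, manifest = manifest)
}
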