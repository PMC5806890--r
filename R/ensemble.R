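#' Two-step voting configuration
#'
#' The defaults encode the published rule: an edge enters an intra-method
#' consensus network when it appears in more than two of the six per-dataset
#' networks (support >= 3), and enters the final network when it appears in
#' more than one of the three intra-method consensus networks (support >=
#' 2). Both thresholds are configurable because they were tuned against the
#' gold standards. The one-dataset circRNA-style configuration is
#' \code{VotingConfig(n_datasets = 1, intra_min_support = 1,
#' inter_min_support = 2)}.
#'
#' @param intra_min_support minimum per-method dataset support (default 3).
#' @param inter_min_support minimum cross-method support (default 2).
#' @param n_datasets number of datasets per method (default 6).
#' @param n_methods number of inference methods (default 3).
#' @return a list of class \code{VotingConfig}.
#' @export
VotingConfig <- function(intra_min_support = 3L, inter_min_support = 2L,
                         n_datasets = 6L, n_methods = 3L) {
  stopifnot(intra_min_support >= 1, intra_min_support <= n_datasets,
            inter_min_support >= 1, inter_min_support <= n_methods)
  structure(list(intra_min_support = as.integer(intra_min_support),
                 inter_min_support = as.integer(inter_min_support),
                 n_datasets = as.integer(n_datasets),
                 n_methods = as.integer(n_methods)),
            class = "VotingConfig")
}

#' Min-max normalize a network's confidence scores
#'
#' score' = (s - min) / (max - min), mapping each network's scores onto
#' [0, 1] so different methods' scales are comparable before averaging.
#' When all scores are equal (max = min) every score is set to 1 — uniform
#' confidence is treated as full confidence — with a message.
#'
#' @param net a nonempty \linkS4class{ScoredNetwork}.
#' @return the rescored \linkS4class{ScoredNetwork}.
#' @export
minmaxNormalize <- function(net) {
  e <- edgeTable(net)
  if (!nrow(e)) stop("cannot min-max normalize an empty network")
  lo <- min(e$score)
  hi <- max(e$score)
  if (hi == lo) {
    message("degenerate min-max (all scores equal); all scores set to 1")
    e$score <- 1
  } else {
    e$score <- (e$score - lo) / (hi - lo)
  }
  ScoredNetwork(e, nodes = nodeUniverse(net),
                method = methodTag(net), dataset = datasetTag(net))
}

# edge keys + per-network normalized scores in a long data.frame
.stackNetworks <- function(nets) {
  do.call(rbind, lapply(seq_along(nets), function(i) {
    e <- edgeTable(nets[[i]])
    if (!nrow(e)) return(NULL)
    data.frame(key = .edgeKeys(e), score = e$score, src = i)
  }))
}

.keysToEdges <- function(keys) {
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(geneA = ab[, 1L], geneB = ab[, 2L])
}

#' Intra-method consensus by dataset voting
#'
#' Keeps the edges present in at least \code{intra_min_support} of one
#' method's per-dataset networks and scores each kept edge by the mean of
#' its min-max-normalized scores over all \code{n_datasets} networks, a
#' missing edge contributing 0.
#'
#' @param nets list of \linkS4class{ScoredNetwork}s from one method (their
#'   method tags must agree), scores already min-max normalized.
#' @param cfg a \code{\link{VotingConfig}}.
#' @return a \linkS4class{ConsensusNetwork} with level
#'   \code{"intra_method"}.
#' @export
intraMethodConsensus <- function(nets, cfg = VotingConfig()) {
  tags <- vapply(nets, methodTag, "")
  if (length(unique(tags)) != 1L) {
    stop("intra-method consensus requires a single method tag; got: ",
         paste(unique(tags), collapse = ", "))
  }
  if (length(nets) != cfg$n_datasets) {
    stop("expected ", cfg$n_datasets, " networks, got ", length(nets))
  }
  long <- .stackNetworks(nets)
  nodes <- sort(unique(unlist(lapply(nets, nodeUniverse))))
  if (is.null(long)) {
    e <- data.frame(geneA = character(), geneB = character(),
                    score = numeric(), support = integer())
    return(new("ConsensusNetwork",
               ScoredNetwork(e, nodes = nodes, method = tags[1L]),
               level = "intra_method"))
  }
  support <- tapply(long$src, long$key, function(s) length(unique(s)))
  total <- tapply(long$score, long$key, sum)
  keep <- support >= cfg$intra_min_support
  keys <- names(support)[keep]
  e <- if (length(keys)) {
    cbind(.keysToEdges(keys),
          data.frame(score = unname(total[keys]) / cfg$n_datasets,
                     support = as.integer(support[keys])))
  } else {
    data.frame(geneA = character(), geneB = character(),
               score = numeric(), support = integer())
  }
  new("ConsensusNetwork", ScoredNetwork(e, nodes = nodes, method = tags[1L]),
      level = "intra_method")
}

#' Final consensus by method voting
#'
#' Keeps the edges present in at least \code{inter_min_support} of the
#' intra-method consensus networks; the final confidence is the mean of the
#' \code{n_methods} consensus scores, a missing edge contributing 0.
#'
#' @param nets list of exactly \code{n_methods}
#'   \linkS4class{ConsensusNetwork}s, one per method (distinct tags).
#' @param cfg a \code{\link{VotingConfig}}.
#' @return a \linkS4class{ConsensusNetwork} with level \code{"final"}.
#' @export
interMethodConsensus <- function(nets, cfg = VotingConfig()) {
  tags <- vapply(nets, methodTag, "")
  if (length(nets) != cfg$n_methods) {
    stop("expected ", cfg$n_methods, " consensus networks")
  }
  if (anyDuplicated(tags)) stop("duplicate method tags: ",
                                paste(tags, collapse = ", "))
  long <- .stackNetworks(nets)
  nodes <- sort(unique(unlist(lapply(nets, nodeUniverse))))
  if (is.null(long)) {
    e <- data.frame(geneA = character(), geneB = character(),
                    score = numeric(), support = integer())
    return(new("ConsensusNetwork", ScoredNetwork(e, nodes = nodes),
               level = "final"))
  }
  support <- tapply(long$src, long$key, function(s) length(unique(s)))
  total <- tapply(long$score, long$key, sum)
  keep <- support >= cfg$inter_min_support
  keys <- names(support)[keep]
  e <- if (length(keys)) {
    cbind(.keysToEdges(keys),
          data.frame(score = unname(total[keys]) / cfg$n_methods,
                     support = as.integer(support[keys])))
  } else {
    data.frame(geneA = character(), geneB = character(),
               score = numeric(), support = integer())
  }
  new("ConsensusNetwork", ScoredNetwork(e, nodes = nodes), level = "final")
}

#' Alternative network combiners
#'
#' The combiners the two-step unweighted vote was compared against:
#' \describe{
#'   \item{weighted_vote}{two-step voting in which the second-step support
#'     is the sum of per-method weights of the methods containing the edge,
#'     kept when it reaches \code{inter_min_support} times the mean weight
#'     (so equal weights reduce exactly to the unweighted vote). Weights
#'     are intended to be performance folds computed upstream (positive
#'     enrichment / negative enrichment).}
#'   \item{score_average}{per-edge mean of min-max-normalized scores over
#'     all input networks, a missing edge contributing 0; no voting
#'     filter.}
#'   \item{rank_average}{per-edge mean of normalized ranks
#'     (rank - 1)/(n - 1) within each network, missing edges contributing
#'     0; no voting filter.}
#' }
#'
#' @param nets for \code{weighted_vote}: a list of per-method lists of
#'   \linkS4class{ScoredNetwork}s (min-max normalized); for the averaging
#'   modes: a flat list of \linkS4class{ScoredNetwork}s.
#' @param mode combiner mode.
#' @param weights named non-negative weights, one per method
#'   (weighted_vote only).
#' @param cfg a \code{\link{VotingConfig}} (weighted_vote only).
#' @return a \linkS4class{ScoredNetwork} (weighted_vote returns a
#'   \linkS4class{ConsensusNetwork}).
#' @export
combineAlternative <- function(nets, mode = c("weighted_vote",
                                              "score_average",
                                              "rank_average"),
                               weights = NULL, cfg = VotingConfig()) {
  mode <- match.arg(mode)
  if (mode == "weighted_vote") {
    if (is.null(weights) || is.null(names(weights))) {
      stop("weighted_vote requires named per-method weights")
    }
    if (any(weights < 0)) stop("weights must be non-negative")
    intra <- lapply(nets, intraMethodConsensus, cfg = cfg)
    tags <- vapply(intra, methodTag, "")
    if (!all(tags %in% names(weights))) stop("missing weight for a method")
    w <- weights[tags]
    long <- .stackNetworks(intra)
    nodes <- sort(unique(unlist(lapply(intra, nodeUniverse))))
    wsupport <- tapply(long$src, long$key,
                       function(s) sum(w[unique(s)]))
    support <- tapply(long$src, long$key, function(s) length(unique(s)))
    total <- tapply(long$score, long$key, sum)
    keep <- wsupport >= cfg$inter_min_support * mean(w)
    keys <- names(wsupport)[keep]
    e <- if (length(keys)) {
      cbind(.keysToEdges(keys),
            data.frame(score = unname(total[keys]) / cfg$n_methods,
                       support = as.integer(support[keys])))
    } else {
      data.frame(geneA = character(), geneB = character(),
                 score = numeric(), support = integer())
    }
    return(new("ConsensusNetwork", ScoredNetwork(e, nodes = nodes),
               level = "final"))
  }
  n_inputs <- length(nets)
  prepped <- lapply(nets, function(nt) {
    e <- edgeTable(nt)
    if (!nrow(e)) return(nt)
    if (mode == "rank_average") {
      r <- rank(e$score, ties.method = "average")
      e$score <- if (nrow(e) > 1L) (r - 1) / (nrow(e) - 1) else 1
      ScoredNetwork(e, nodes = nodeUniverse(nt), method = methodTag(nt),
                    dataset = datasetTag(nt))
    } else {
      minmaxNormalize(nt)
    }
  })
  long <- .stackNetworks(prepped)
  nodes <- sort(unique(unlist(lapply(nets, nodeUniverse))))
  if (is.null(long)) {
    return(ScoredNetwork(data.frame(geneA = character(), geneB = character(),
                                    score = numeric()), nodes = nodes))
  }
  total <- tapply(long$score, long$key, sum)
  keys <- names(total)
  e <- cbind(.keysToEdges(keys),
             data.frame(score = unname(total) / n_inputs))
  ScoredNetwork(e, nodes = nodes)
}
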