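#' Synthetic-data configuration
#'
#' The defaults describe the desk-scale stand-in for a large RNA-seq
#' corpus: 600 genes over 120 samples with 6 planted co-expression modules
#' of 20 genes each (so 80% of genes are independent noise), a target
#' within-module correlation of 0.8, negative-binomial counts with
#' dispersion 0.1, and library sizes between 0.5 and 1.5 million reads.
#'
#' @param n_genes total genes (default 600).
#' @param n_samples samples (default 120).
#' @param n_modules planted modules (default 6).
#' @param module_size_range (min, max) module size (default c(20, 20)).
#' @param within_module_cor target within-module correlation of log counts
#'   (default 0.8).
#' @param library_size_range (min, max) total counts per sample (default
#'   c(5e5, 1.5e6)).
#' @param nb_dispersion negative-binomial dispersion phi, var = mu + phi
#'   mu^2 (default 0.1).
#' @param fraction_noise_genes fraction of genes outside any module; only
#'   consulted when the module sizes do not already determine it (default
#'   NA = derive from modules).
#' @param seed integer seed.
#' @return a list of class \code{SimConfig}.
#' @export
SimConfig <- function(n_genes = 600L, n_samples = 120L, n_modules = 6L,
                      module_size_range = c(20L, 20L),
                      within_module_cor = 0.8,
                      library_size_range = c(5e5, 1.5e6),
                      nb_dispersion = 0.1,
                      fraction_noise_genes = NA_real_,
                      seed = 1L) {
  stopifnot(n_genes > 0, n_samples > 1, n_modules >= 0,
            within_module_cor > 0, within_module_cor < 1,
            nb_dispersion > 0,
            module_size_range[1L] <= module_size_range[2L])
  if (!is.na(fraction_noise_genes)) {
    n_module_genes <- round(n_genes * (1 - fraction_noise_genes))
  } else {
    n_module_genes <- NA_integer_
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_modules = as.integer(n_modules),
                 module_size_range = as.integer(module_size_range),
                 within_module_cor = within_module_cor,
                 library_size_range = library_size_range,
                 nb_dispersion = nb_dispersion,
                 fraction_noise_genes = fraction_noise_genes,
                 n_module_genes = n_module_genes,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate an RNA-seq count matrix with planted co-expression modules
#'
#' Genes in a module share a latent per-sample factor: the log mean of gene
#' g in sample s is a lognormal baseline plus loading * factor_{m(g), s},
#' with the loading chosen so that the correlation of log counts between
#' module mates approaches \code{within_module_cor} given the
#' negative-binomial noise level. Counts are drawn NB with dispersion
#' \code{nb_dispersion} and per-sample library-size scaling; noise genes
#' are independent.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @return list with \code{matrix} (an \linkS4class{ExpressionMatrix} of
#'   raw counts), \code{planted_edges} (data.frame of all within-module
#'   pairs), and \code{module_map} (named character, gene -> module id or
#'   NA for noise genes).
#' @export
simulateCounts <- function(cfg = SimConfig()) {
  sizes <- .withSeed(cfg$seed, {
    if (cfg$module_size_range[1L] == cfg$module_size_range[2L]) {
      rep(cfg$module_size_range[1L], cfg$n_modules)
    } else {
      sample(seq(cfg$module_size_range[1L], cfg$module_size_range[2L]),
             cfg$n_modules, replace = TRUE)
    }
  })
  if (sum(sizes) > cfg$n_genes) {
    stop("module sizes exceed n_genes; infeasible configuration")
  }
  if (!is.na(cfg$n_module_genes) && sum(sizes) > cfg$n_module_genes) {
    stop("module sizes exceed the non-noise gene budget")
  }
  p <- cfg$n_genes
  n <- cfg$n_samples
  genes <- sprintf("g%04d", seq_len(p))
  samples <- sprintf("s%04d", seq_len(n))
  module_map <- setNames(rep(NA_character_, p), genes)
  idx <- 1L
  for (m in seq_len(cfg$n_modules)) {
    module_map[idx:(idx + sizes[m] - 1L)] <- sprintf("M%d", m)
    idx <- idx + sizes[m]
  }
  counts <- .withSeed(cfg$seed + 1L, {
    base <- exp(stats::rnorm(p, mean = log(50), sd = 1))
    lib <- stats::runif(n, cfg$library_size_range[1L],
                        cfg$library_size_range[2L])
    factors <- matrix(stats::rnorm(cfg$n_modules * n), cfg$n_modules, n)
    # expected per-gene mean once columns are rescaled to the library size
    mean_scale <- mean(lib) / sum(base)
    mu <- matrix(0, p, n)
    for (g in seq_len(p)) {
      m <- module_map[g]
      if (!is.na(m)) {
        mi <- as.integer(sub("M", "", m))
        # loading sized so signal/(signal+NB log-noise) hits the target
        noise_var <- 1 / (base[g] * mean_scale) + cfg$nb_dispersion
        load <- sqrt(cfg$within_module_cor / (1 - cfg$within_module_cor) *
                       noise_var)
        mu[g, ] <- base[g] * exp(load * factors[mi, ] - load^2 / 2)
      } else {
        mu[g, ] <- base[g]
      }
    }
    mu <- sweep(mu, 2L, lib / colSums(mu), "*")
    matrix(stats::rnbinom(p * n, mu = mu, size = 1 / cfg$nb_dispersion),
           p, n, dimnames = list(genes, samples))
  })
  planted <- do.call(rbind, lapply(split(names(module_map), module_map),
                                   .setPairs))
  if (is.null(planted)) {
    planted <- data.frame(geneA = character(), geneB = character())
  }
  rownames(planted) <- NULL
  list(matrix = ExpressionMatrix(counts, kind = "raw_counts"),
       planted_edges = planted,
       module_map = module_map)
}

#' Simulate a toy ontology aligned with the planted modules
#'
#' Builds a rooted is-a DAG: the root has two branch terms; module terms
#' hang alternately off the branches, and each module term has two leaf
#' terms. Module genes are annotated to their module's leaves (each gene to
#' one leaf, a fraction to both), so within-module pairs share informative
#' ancestors while modules on different branches share only the root (term
#' similarity 0 by construction). A fraction of random noise annotations is
#' added, and unassigned (noise) genes get random leaf annotations so the
#' annotated universe is wider than the modules.
#'
#' @param module_map named character gene -> module id (NA = noise gene),
#'   as produced by \code{\link{simulateCounts}}.
#' @param noise_fraction fraction of genes receiving one random extra
#'   annotation (default 0.05).
#' @param annotate_noise_genes fraction of noise genes annotated to random
#'   leaves (default 0.3).
#' @param broad_fraction fraction of genes annotated to a broad near-root
#'   term (default 0.98). Mirrors real ontologies, where almost every gene
#'   pair shares some informative ancestor: pairs lacking the broad term
#'   across branches keep similarity exactly 0, so zero-similarity pairs
#'   exist but are rare and the background percentile threshold stays
#'   positive.
#' @param seed integer seed.
#' @return an annotated \linkS4class{OntologyDAG}.
#' @export
simulateOntology <- function(module_map, noise_fraction = 0.05,
                             annotate_noise_genes = 0.3,
                             broad_fraction = 0.98, seed = 1L) {
  modules <- sort(unique(stats::na.omit(module_map)))
  if (!length(modules)) stop("no modules to build an ontology over")
  root <- "T:root"
  branches <- c("T:branchA", "T:branchB")
  broad <- "T:general"
  terms <- c(root, branches, broad)
  parents <- list()
  parents[[branches[1L]]] <- root
  parents[[branches[2L]]] <- root
  parents[[broad]] <- root
  leaves <- list()
  for (i in seq_along(modules)) {
    m <- modules[i]
    tm <- paste0("T:", m)
    l1 <- paste0("T:", m, ".leaf1")
    l2 <- paste0("T:", m, ".leaf2")
    terms <- c(terms, tm, l1, l2)
    parents[[tm]] <- branches[(i %% 2L) + 1L]
    parents[[l1]] <- tm
    parents[[l2]] <- tm
    leaves[[m]] <- c(l1, l2)
  }
  all_leaves <- unlist(leaves, use.names = FALSE)
  annotations <- .withSeed(seed, {
    ann <- list()
    for (g in names(module_map)) {
      m <- module_map[[g]]
      if (!is.na(m)) {
        pick <- sample(leaves[[m]], 1L)
        ts <- if (stats::runif(1) < 0.3) leaves[[m]] else pick
        ann[[g]] <- ts
      } else if (stats::runif(1) < annotate_noise_genes) {
        ann[[g]] <- sample(all_leaves, 1L)
      }
    }
    if (noise_fraction > 0) {
      extra <- names(ann)[stats::runif(length(ann)) < noise_fraction]
      for (g in extra) ann[[g]] <- unique(c(ann[[g]], sample(all_leaves, 1L)))
    }
    # exactly this share of annotated genes gets the broad term, so at
    # least one gene always lacks it and the broad term keeps IC > 0
    n_broad <- min(length(ann) - 1L, round(broad_fraction * length(ann)))
    for (g in sample(names(ann), max(0L, n_broad))) {
      ann[[g]] <- c(ann[[g]], broad)
    }
    ann
  })
  dag <- OntologyDAG(terms, parents)
  setAnnotations(dag, annotations)
}

#' Simulate gold standards from the synthetic ontology and modules
#'
#' Runs the real gold-standard constructors on the synthetic inputs:
#' positives from the ontology's propagated term gene sets plus the module
#' gene sets as pathways and a thinned sample of within-module pairs as a
#' stand-in interaction network; negatives from the zero-similarity term
#' pair procedure (scaled-down backgrounds by default, suitable for desk
#' runs).
#'
#' @param dag an annotated \linkS4class{OntologyDAG} (see
#'   \code{\link{simulateOntology}}).
#' @param module_map named character gene -> module id.
#' @param cfg a \code{\link{NegativeStandardConfig}}; the default here uses
#'   200 backgrounds of 100 pairs to keep desk runs fast.
#' @param max_set_size GO categories larger than this are excluded from the
#'   positives; NULL (default) uses a quarter of the annotated genes — the
#'   genome-scale 500-gene cap rescaled to the toy universe, so the broad
#'   and root-like terms never flood the standard while module-sized terms
#'   always pass.
#' @param seed integer seed for the interaction-network thinning.
#' @return a \linkS4class{GoldStandard} over the genes of
#'   \code{module_map}.
#' @export
simulateStandards <- function(dag, module_map,
                              cfg = NegativeStandardConfig(
                                n_backgrounds = 200L,
                                pairs_per_background = 100L),
                              max_set_size = NULL,
                              seed = 1L) {
  universe <- names(module_map)
  sets <- .termGeneSets(dag)
  sets <- sets[lengths(sets) > 0]
  go_sets <- lapply(sets, unique)
  if (is.null(max_set_size)) {
    max_set_size <- max(1L, round(length(dag@annotations) / 4))
  }
  pathways <- split(names(module_map), module_map)
  ppi <- .withSeed(seed, {
    prs <- do.call(rbind, lapply(pathways, .setPairs))
    if (!is.null(prs) && nrow(prs) > 1L) {
      prs[sample.int(nrow(prs), max(1L, nrow(prs) %/% 5L)), , drop = FALSE]
    } else prs
  })
  pos <- buildPositiveStandard(go_sets = go_sets, pathways = pathways,
                               ppi = ppi, universe = universe,
                               max_set_size = max_set_size)
  neg <- buildNegativeStandard(dag, cfg = cfg, universe = universe)
  gs <- assembleGoldStandard(pos, neg, universe)
  if (!nrow(positivePairs(gs)) || !nrow(negativePairs(gs))) {
    stop("synthetic gold standard unexpectedly empty")
  }
  gs
}
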