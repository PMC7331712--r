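#' Build a synthetic-study configuration
#'
#' Defaults emulate the multi-condition soil study design the package targets:
#' four conditions (dry, wet, glycine, control), three field sites, three
#' replicate microcosms per condition and site, log2-scale expression with
#' planted co-expression modules, and a master metabolic network with planted
#' condition-specific reaction chains.
#'
#' @param seed integer seed; every generator derives its own stream from it.
#' @param nGenes,conditions,control,nSites,nReplicates study layout.
#' @param nModules,moduleSize,latentStrength planted co-expression modules.
#' @param responsiveFoldChange,noiseSd planted differential signal and
#'   replicate noise (log2 scale).
#' @param nMetabolites,nReactions,meanReactionDegree master-network shape.
#' @param metaboliteDetectionRate,nCoreMetabolites detected-metabolite model.
#' @param nResponsivePerCondition planted pathway length per condition.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, nGenes = 100)
#' cfg
#' @export
syntheticConfig <- function(seed = 1L,
                            nGenes = 300L,
                            conditions = c("dry", "wet", "glycine", "control"),
                            control = "control",
                            nSites = 3L,
                            nReplicates = 3L,
                            nModules = 5L,
                            moduleSize = 10L,
                            latentStrength = 2,
                            responsiveFoldChange = 4,
                            noiseSd = 0.5,
                            nMetabolites = 80L,
                            nReactions = 90L,
                            meanReactionDegree = 2,
                            metaboliteDetectionRate = 0.9,
                            nCoreMetabolites = 20L,
                            nResponsivePerCondition = 6L) {
  new("SyntheticConfig",
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    conditions = as.character(conditions), control = as.character(control),
    nSites = as.integer(nSites), nReplicates = as.integer(nReplicates),
    nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
    latentStrength = as.numeric(latentStrength),
    responsiveFoldChange = as.numeric(responsiveFoldChange),
    noiseSd = as.numeric(noiseSd),
    nMetabolites = as.integer(nMetabolites),
    nReactions = as.integer(nReactions),
    meanReactionDegree = as.numeric(meanReactionDegree),
    metaboliteDetectionRate = as.numeric(metaboliteDetectionRate),
    nCoreMetabolites = as.integer(nCoreMetabolites),
    nResponsivePerCondition = as.integer(nResponsivePerCondition)
  )
}

#' Build an over-expression calling configuration
#'
#' @param fcThreshold minimal linear fold change, > 1 (default 2).
#' @param qThreshold maximal adjusted p-value, in (0, 1] (default 0.05).
#' @param test two-sample test; "welch" (Welch t on log2 values).
#' @param adjustment multiple-testing method (default "BH").
#' @return A validated \linkS4class{DifferentialConfig}.
#' @export
differentialConfig <- function(fcThreshold = 2, qThreshold = 0.05,
                               test = "welch", adjustment = "BH") {
  new("DifferentialConfig",
    fcThreshold = as.numeric(fcThreshold),
    qThreshold = as.numeric(qThreshold),
    test = as.character(test), adjustment = as.character(adjustment)
  )
}

#' Build a CLR inference configuration
#'
#' @param miEstimator "bspline" or "equal_width_bins".
#' @param nBins number of bins (default 10).
#' @param splineOrder B-spline order (default 3).
#' @param backgroundMode "per_gene" (canonical CLR) or "global".
#' @param zThreshold Z cutoff for edge inclusion (default 4.20).
#' @param targetEdges optional top-k edge count (NA = threshold mode).
#' @param rankTransform rank-transform profiles before MI (default TRUE).
#' @return A validated \linkS4class{ClrConfig}.
#' @export
clrConfig <- function(miEstimator = "bspline", nBins = 10L, splineOrder = 3L,
                      backgroundMode = "per_gene", zThreshold = 4.20,
                      targetEdges = NA_integer_, rankTransform = TRUE) {
  new("ClrConfig",
    miEstimator = as.character(miEstimator), nBins = as.integer(nBins),
    splineOrder = as.integer(splineOrder),
    backgroundMode = as.character(backgroundMode),
    zThreshold = as.numeric(zThreshold),
    targetEdges = as.integer(targetEdges),
    rankTransform = isTRUE(rankTransform)
  )
}

#' Assemble a metabolic network from node and edge descriptions
#'
#' @param metabolites,reactions node id vectors.
#' @param substrates,products,ec lists parallel to \code{reactions}.
#' @return A validated \linkS4class{MetabolicNetwork}.
#' @export
metabolicNetwork <- function(metabolites, reactions, substrates, products,
                             ec) {
  new("MetabolicNetwork",
    metabolites = as.character(metabolites),
    reactions = as.character(reactions),
    substrates = lapply(substrates, as.character),
    products = lapply(products, as.character),
    ec = lapply(ec, as.character)
  )
}

.geneNetwork <- function(edges, provenance = list()) {
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- unique(edges[, c("from", "to")])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    edges <- data.frame(from = character(), to = character())
    nodes <- character()
  }
  new("GeneNetwork", nodes = nodes, edges = edges, provenance = provenance)
}

#' Build a gene network directly from an edge table
#'
#' @param edges data.frame with columns \code{from} and \code{to}; undirected,
#'   stored canonically with \code{from < to}.
#' @param provenance optional list describing how the edges were obtained.
#' @return A \linkS4class{GeneNetwork}.
#' @export
geneNetwork <- function(edges, provenance = list(method = "user")) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  .geneNetwork(edges, provenance)
}
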