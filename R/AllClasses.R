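#' @import methods
#' @importFrom stats median p.adjust pnorm pt rnorm rpois rbinom runif sd
#'   quantile complete.cases lm coef var
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

#' Configuration for the synthetic multi-omics generator
#'
#' Holds every knob of the synthetic study: the experimental layout
#' (conditions, sites, replicates), the planted co-expression modules, the
#' planted condition-responsive pathways, the shape of the master metabolic
#' network, and the metabolite detection rate. All generator outputs are pure
#' functions of this object, so a config plus its seed fully reproduces a
#' simulated study.
#'
#' @slot seed integer seed from which all per-artifact RNG streams derive.
#' @slot nGenes total number of gene functions (EC identifiers) in the
#'   expression matrix, network-derived ECs plus fillers.
#' @slot conditions character vector of condition names; must contain
#'   \code{control}.
#' @slot control name of the baseline condition.
#' @slot nSites,nReplicates sites and replicates per condition by site.
#' @slot nModules,moduleSize planted disjoint co-expression modules.
#' @slot latentStrength weight of the shared per-module latent factor
#'   (log2 units).
#' @slot responsiveFoldChange linear fold change of planted responsive genes
#'   in their condition versus control (> 1).
#' @slot noiseSd replicate noise standard deviation on the log2 scale.
#' @slot nMetabolites,nReactions,meanReactionDegree master-network shape;
#'   \code{meanReactionDegree} is the expected number of metabolite edges per
#'   reaction (>= 2: at least one substrate and one product).
#' @slot metaboliteDetectionRate probability that a core metabolite is
#'   detected by the simulated metabolomics assay.
#' @slot nCoreMetabolites size of the common detected-metabolite core shared
#'   across conditions (the hub metabolite is extra and always detected).
#' @slot nResponsivePerCondition length of each planted condition-specific
#'   reaction chain; its EC labels are the planted responsive genes.
#' @export
setClass("SyntheticConfig", representation(
  seed = "integer",
  nGenes = "integer",
  conditions = "character",
  control = "character",
  nSites = "integer",
  nReplicates = "integer",
  nModules = "integer",
  moduleSize = "integer",
  latentStrength = "numeric",
  responsiveFoldChange = "numeric",
  noiseSd = "numeric",
  nMetabolites = "integer",
  nReactions = "integer",
  meanReactionDegree = "numeric",
  metaboliteDetectionRate = "numeric",
  nCoreMetabolites = "integer",
  nResponsivePerCondition = "integer"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(
    nGenes = object@nGenes, nSites = object@nSites,
    nReplicates = object@nReplicates,
    nMetabolites = object@nMetabolites, nReactions = object@nReactions
  )
  if (any(cnt < 1L)) {
    msg <- c(msg, paste0(
      "counts must be positive: ",
      paste(names(cnt)[cnt < 1L], collapse = ", ")
    ))
  }
  if (object@nModules < 0L || object@moduleSize < 0L ||
    object@nCoreMetabolites < 0L || object@nResponsivePerCondition < 0L) {
    msg <- c(msg, "module, core and responsive counts must be non-negative")
  }
  if (object@nModules * object@moduleSize > object@nGenes) {
    msg <- c(msg, "nModules * moduleSize exceeds nGenes")
  }
  if (!(object@control %in% object@conditions)) {
    msg <- c(msg, "control must be one of the conditions")
  }
  if (anyDuplicated(object@conditions)) {
    msg <- c(msg, "condition names must be unique")
  }
  if (object@metaboliteDetectionRate < 0 ||
    object@metaboliteDetectionRate > 1) {
    msg <- c(msg, "metaboliteDetectionRate must be in [0, 1]")
  }
  if (object@responsiveFoldChange <= 1) {
    msg <- c(msg, "responsiveFoldChange must be > 1")
  }
  if (object@noiseSd < 0 || object@latentStrength < 0) {
    msg <- c(msg, "noiseSd and latentStrength must be >= 0")
  }
  if (object@meanReactionDegree < 2) {
    msg <- c(msg, "meanReactionDegree must be >= 2 (one substrate, one product)")
  }
  nTreat <- length(setdiff(object@conditions, object@control))
  needMet <- 1L + object@nCoreMetabolites +
    nTreat * object@nResponsivePerCondition
  needRxn <- object@nCoreMetabolites + nTreat * object@nResponsivePerCondition
  if (needMet > object@nMetabolites || needRxn > object@nReactions) {
    msg <- c(msg, sprintf(
      "infeasible network shape: planted layout needs %d metabolites and %d reactions but only %d / %d are available",
      needMet, needRxn, object@nMetabolites, object@nReactions
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth planted by the synthetic generator
#'
#' @slot moduleMembership named integer vector over gene ids; NA for genes in
#'   no module.
#' @slot responsiveGenes named list, condition -> character vector of planted
#'   responsive EC ids (disjoint across non-control conditions).
#' @slot terminalMetabolites named list, condition -> planted
#'   condition-specific terminal metabolite ids.
#' @slot plantedReactions named list, condition -> planted reaction ids whose
#'   EC labels are the responsive genes.
#' @export
setClass("PlantedTruth", representation(
  moduleMembership = "integer",
  responsiveGenes = "list",
  terminalMetabolites = "list",
  plantedReactions = "list"
))

setValidity("PlantedTruth", function(object) {
  sets <- object@responsiveGenes
  all_g <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_g)) {
    return("responsive gene sets must be disjoint across conditions")
  }
  TRUE
})

#' Bipartite metabolite-reaction network with EC annotations
#'
#' A stand-in for a curated master metabolic map: metabolite nodes, reaction
#' nodes, undirected metabolite-reaction edges, and one or more EC identifiers
#' per reaction. One EC may label several reactions and one reaction may carry
#' several ECs.
#'
#' @slot metabolites metabolite node ids.
#' @slot reactions reaction node ids.
#' @slot substrates,products lists parallel to \code{reactions}; each element
#'   a character vector of metabolite ids (>= 1 each).
#' @slot ec list parallel to \code{reactions}; each element >= 1 EC id.
#' @export
setClass("MetabolicNetwork", representation(
  metabolites = "character",
  reactions = "character",
  substrates = "list",
  products = "list",
  ec = "list"
))

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  nr <- length(object@reactions)
  if (length(object@substrates) != nr || length(object@products) != nr ||
    length(object@ec) != nr) {
    return("substrates, products and ec must be parallel to reactions")
  }
  if (length(intersect(object@metabolites, object@reactions))) {
    msg <- c(msg, "metabolite and reaction ids must be disjoint")
  }
  if (anyDuplicated(object@metabolites) || anyDuplicated(object@reactions)) {
    msg <- c(msg, "node ids must be unique")
  }
  if (nr > 0) {
    nSub <- lengths(object@substrates)
    nProd <- lengths(object@products)
    if (any(nSub < 1L) || any(nProd < 1L)) {
      msg <- c(msg, "every reaction needs >= 1 substrate and >= 1 product")
    }
    touched <- unique(unlist(c(object@substrates, object@products),
      use.names = FALSE
    ))
    if (!all(touched %in% object@metabolites)) {
      msg <- c(msg, "reaction edges reference unknown metabolites")
    }
    if (any(lengths(object@ec) < 1L)) {
      msg <- c(msg, "every reaction needs >= 1 EC annotation")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Terminal set for minimal-subnetwork extraction
#'
#' @slot metaboliteTerminals detected metabolites present in the network.
#' @slot reactionTerminals reactions carrying an over-expressed EC.
#' @slot provenance named character: terminal id -> "metabolite" or "gene".
#' @slot unmatchedMetabolites detected metabolites absent from the network
#'   (reported, never silently dropped).
#' @export
setClass("TerminalSet", representation(
  metaboliteTerminals = "character",
  reactionTerminals = "character",
  provenance = "character",
  unmatchedMetabolites = "character"
))

#' Minimal connecting subnetwork for one condition/site
#'
#' @slot nodes node ids (metabolites and reactions) of the subnetwork.
#' @slot edges two-column data.frame (from = metabolite, to = reaction).
#' @slot genes all EC ids carried by included reactions.
#' @slot edgeCount the objective value (number of edges).
#' @slot condition,site labels for bookkeeping.
#' @slot nTrees number of trees returned (> 1 means a Steiner forest because
#'   terminals spanned several master components).
#' @slot nothingToConnect TRUE when the terminal set was empty.
#' @export
setClass("SubnetworkResult", representation(
  nodes = "character",
  edges = "data.frame",
  genes = "character",
  edgeCount = "integer",
  condition = "character",
  site = "character",
  nTrees = "integer",
  nothingToConnect = "logical"
))

#' Configuration for over-expression calling
#'
#' @slot fcThreshold minimal linear fold change (> 1); genes are called when
#'   log2FC >= log2(fcThreshold) (inclusive).
#' @slot qThreshold maximal BH-adjusted p-value (inclusive), in (0, 1].
#' @slot test two-sample location test; currently "welch".
#' @slot adjustment multiple-testing procedure passed to
#'   \code{\link[stats]{p.adjust}}.
#' @export
setClass("DifferentialConfig", representation(
  fcThreshold = "numeric",
  qThreshold = "numeric",
  test = "character",
  adjustment = "character"
))

setValidity("DifferentialConfig", function(object) {
  msg <- character()
  if (object@fcThreshold <= 1) msg <- c(msg, "fcThreshold must be > 1")
  if (object@qThreshold <= 0 || object@qThreshold > 1) {
    msg <- c(msg, "qThreshold must be in (0, 1]")
  }
  if (!object@test %in% "welch") msg <- c(msg, "unknown test")
  if (!object@adjustment %in% p.adjust.methods) {
    msg <- c(msg, "unknown adjustment method")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration for CLR network inference
#'
#' @slot miEstimator "bspline" (fuzzy B-spline bin memberships, the canonical
#'   CLR default) or "equal_width_bins" (hard binning).
#' @slot nBins number of bins (>= 2).
#' @slot splineOrder B-spline order (< nBins).
#' @slot backgroundMode "per_gene" (canonical CLR: each score standardised
#'   against both genes' own background) or "global" (standardised against
#'   the mean and sd of all off-diagonal mutual-information scores).
#' @slot zThreshold Z cutoff for \code{\link{thresholdNetwork}}.
#' @slot targetEdges optional top-k edge count for \code{\link{topKNetwork}}.
#' @slot rankTransform rank-transform each gene's profile before estimating
#'   mutual information (robust to outliers).
#' @export
setClass("ClrConfig", representation(
  miEstimator = "character",
  nBins = "integer",
  splineOrder = "integer",
  backgroundMode = "character",
  zThreshold = "numeric",
  targetEdges = "integer",
  rankTransform = "logical"
))

setValidity("ClrConfig", function(object) {
  msg <- character()
  if (!object@miEstimator %in% c("bspline", "equal_width_bins")) {
    msg <- c(msg, "miEstimator must be 'bspline' or 'equal_width_bins'")
  }
  if (!object@backgroundMode %in% c("per_gene", "global")) {
    msg <- c(msg, "backgroundMode must be 'per_gene' or 'global'")
  }
  if (object@zThreshold <= 0) msg <- c(msg, "zThreshold must be > 0")
  if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
  if (object@splineOrder >= object@nBins) {
    msg <- c(msg, "splineOrder must be < nBins")
  }
  if (object@splineOrder < 1L) msg <- c(msg, "splineOrder must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Mutual-information and CLR Z-score matrices
#'
#' @slot genes gene ids of the retained (non-constant) genes.
#' @slot mi symmetric non-negative mutual-information matrix (bits); the
#'   diagonal is set to NA and ignored downstream.
#' @slot z symmetric CLR Z-score matrix, diagonal NA.
#' @slot excluded genes dropped for zero variance.
#' @slot backgroundMode the mode used to compute \code{z}.
#' @export
setClass("CoexpressionScores", representation(
  genes = "character",
  mi = "matrix",
  z = "matrix",
  excluded = "character",
  backgroundMode = "character"
))

setValidity("CoexpressionScores", function(object) {
  n <- length(object@genes)
  if (!all(dim(object@mi) == n) || !all(dim(object@z) == n)) {
    return("matrix dimensions must match the gene list")
  }
  off <- row(object@mi) != col(object@mi)
  if (any(object@mi[off] < -1e-9, na.rm = TRUE)) {
    return("mutual information must be non-negative")
  }
  asym <- function(m) {
    d <- abs(m[off] - t(m)[off])
    any(d > 1e-8, na.rm = TRUE)
  }
  if (asym(object@mi) || asym(object@z)) {
    return("score matrices must be symmetric")
  }
  TRUE
})

#' Unweighted, undirected gene co-expression network
#'
#' Nodes are the genes incident to at least one retained edge (isolated genes
#' are dropped at construction and recorded in \code{provenance$dropped}).
#'
#' @slot nodes gene ids, sorted.
#' @slot edges data.frame with character columns \code{from} and \code{to},
#'   \code{from < to}, no duplicates, no self-loops.
#' @slot provenance list recording how the network was built (cutoff or k,
#'   number of isolated genes dropped).
#' @export
setClass("GeneNetwork", representation(
  nodes = "character",
  edges = "data.frame",
  provenance = "list"
))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to") %in% names(e))) {
    return("edges needs 'from' and 'to' columns")
  }
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$from > e$to)) return("edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to))) {
      return("duplicate edges are not allowed")
    }
    incident <- sort(unique(c(e$from, e$to)))
    if (!identical(object@nodes, incident)) {
      return("nodes must be exactly the genes incident to an edge")
    }
  } else if (length(object@nodes)) {
    return("an edgeless network has no nodes")
  }
  TRUE
})
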