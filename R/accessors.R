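#' @name accessors
#' @title Accessors for metaphenet S4 objects
#' @description Slot access for the package's network and score containers;
#'   user code should use these rather than \code{@}.
#' @param x a metaphenet S4 object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x, ...) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x, ...) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("reactionEC", function(x, ...) standardGeneric("reactionEC"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("implicatedGenes", function(x, ...) {
  standardGeneric("implicatedGenes")
})

#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setGeneric("miMatrix", function(x, ...) standardGeneric("miMatrix"))

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x, ...) standardGeneric("zMatrix"))

#' @rdname accessors
setMethod("metabolites", "MetabolicNetwork", function(x, ...) x@metabolites)

#' @rdname accessors
setMethod("reactions", "MetabolicNetwork", function(x, ...) x@reactions)

#' @rdname accessors
setMethod("reactionEC", "MetabolicNetwork", function(x, ...) {
  stats::setNames(x@ec, x@reactions)
})

#' @rdname accessors
setMethod("networkNodes", "MetabolicNetwork", function(x, ...) {
  c(sort(x@metabolites), sort(x@reactions))
})

#' @rdname accessors
setMethod("edgeTable", "MetabolicNetwork", function(x, ...) {
  nSub <- lengths(x@substrates)
  nProd <- lengths(x@products)
  e <- data.frame(
    metabolite = c(
      unlist(x@substrates, use.names = FALSE),
      unlist(x@products, use.names = FALSE)
    ),
    reaction = c(rep(x@reactions, nSub), rep(x@reactions, nProd)),
    role = c(rep("substrate", sum(nSub)), rep("product", sum(nProd))),
    stringsAsFactors = FALSE
  )
  # a metabolite can be both substrate and product of one reaction; the graph
  # is undirected so collapse to one edge per (metabolite, reaction)
  e <- e[!duplicated(e[, c("metabolite", "reaction")]), , drop = FALSE]
  e <- e[order(e$metabolite, e$reaction), , drop = FALSE]
  rownames(e) <- NULL
  e
})

#' @rdname accessors
setMethod("asIgraph", "MetabolicNetwork", function(x, ...) {
  nodes <- networkNodes(x)
  e <- edgeTable(x)
  g <- igraph::graph_from_data_frame(
    e[, c("metabolite", "reaction")],
    directed = FALSE,
    vertices = data.frame(
      name = nodes,
      type = nodes %in% x@reactions
    )
  )
  igraph::E(g)$role <- e$role
  g
})

#' @rdname accessors
setMethod("networkNodes", "GeneNetwork", function(x, ...) x@nodes)

#' @rdname accessors
setMethod("edgeTable", "GeneNetwork", function(x, ...) x@edges)

#' @rdname accessors
setMethod("asIgraph", "GeneNetwork", function(x, ...) {
  igraph::graph_from_data_frame(x@edges,
    directed = FALSE,
    vertices = data.frame(name = x@nodes)
  )
})

#' @rdname accessors
setMethod("networkNodes", "SubnetworkResult", function(x, ...) x@nodes)

#' @rdname accessors
setMethod("edgeTable", "SubnetworkResult", function(x, ...) x@edges)

#' @rdname accessors
setMethod("implicatedGenes", "SubnetworkResult", function(x, ...) x@genes)

#' @rdname accessors
setMethod("miMatrix", "CoexpressionScores", function(x, ...) x@mi)

#' @rdname accessors
setMethod("zMatrix", "CoexpressionScores", function(x, ...) x@z)

setMethod("show", "SyntheticConfig", function(object) {
  cat(
    "SyntheticConfig:", object@nGenes, "genes,",
    length(object@conditions), "conditions x", object@nSites, "sites x",
    object@nReplicates, "replicates\n  modules:", object@nModules, "x",
    object@moduleSize, " latent", object@latentStrength,
    " fold", object@responsiveFoldChange, " noiseSd", object@noiseSd,
    "\n  network:", object@nMetabolites, "metabolites,",
    object@nReactions, "reactions; seed", object@seed, "\n"
  )
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat(
    "MetabolicNetwork:", length(object@metabolites), "metabolites,",
    length(object@reactions), "reactions,",
    nrow(edgeTable(object)), "edges,",
    length(unique(unlist(object@ec))), "distinct EC annotations\n"
  )
})

setMethod("show", "GeneNetwork", function(object) {
  cat(
    "GeneNetwork:", length(object@nodes), "nodes,",
    nrow(object@edges), "edges"
  )
  if (!is.null(object@provenance$method)) {
    cat(" (", object@provenance$method, ")", sep = "")
  }
  cat("\n")
})

setMethod("show", "SubnetworkResult", function(object) {
  if (isTRUE(object@nothingToConnect)) {
    cat("SubnetworkResult: nothing to connect\n")
    return(invisible(NULL))
  }
  cat(
    "SubnetworkResult [", object@condition, "/", object@site, "]: ",
    length(object@nodes), " nodes, ", object@edgeCount, " edges, ",
    length(object@genes), " implicated genes",
    if (object@nTrees > 1L) sprintf(" (forest of %d trees)", object@nTrees),
    "\n",
    sep = ""
  )
})

setMethod("show", "CoexpressionScores", function(object) {
  cat(
    "CoexpressionScores:", length(object@genes), "genes,",
    "background", object@backgroundMode
  )
  if (length(object@excluded)) {
    cat(";", length(object@excluded), "constant genes excluded")
  }
  cat("\n")
})
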