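#' Build the terminal set for one condition/site
#'
#' Terminals are (1) detected metabolites present in the master network and
#' (2) every reaction whose EC annotation intersects the over-expressed gene
#' set (one EC labelling several reactions makes all of them terminals).
#' Detected metabolites absent from the network are reported in the result,
#' never silently dropped.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param metabolites character vector of detected metabolite ids.
#' @param overexpressed character vector of over-expressed EC ids.
#' @return A \linkS4class{TerminalSet}; an empty terminal set is a valid
#'   "nothing to connect" result, not an error.
#' @export
buildTerminals <- function(network, metabolites, overexpressed) {
  stopifnot(is(network, "MetabolicNetwork"))
  metabolites <- unique(as.character(metabolites))
  overexpressed <- unique(as.character(overexpressed))
  hit <- metabolites %in% network@metabolites
  metTerm <- sort(metabolites[hit])
  unmatched <- sort(metabolites[!hit])
  rxnTerm <- sort(network@reactions[
    vapply(network@ec, function(e) any(e %in% overexpressed), logical(1))
  ])
  prov <- c(
    stats::setNames(rep("metabolite", length(metTerm)), metTerm),
    stats::setNames(rep("gene", length(rxnTerm)), rxnTerm)
  )
  new("TerminalSet",
    metaboliteTerminals = metTerm, reactionTerminals = rxnTerm,
    provenance = prov, unmatchedMetabolites = unmatched
  )
}

# Deterministic Kruskal MST over the metric closure of the terminals:
# pairs sorted by (distance, lexicographic pair).
.metricClosureMst <- function(d, terms) {
  n <- length(terms)
  if (n < 2L) {
    return(data.frame(a = character(), b = character()))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pa <- terms[pairs[, 1L]]
  pb <- terms[pairs[, 2L]]
  lo <- pmin(pa, pb)
  hi <- pmax(pa, pb)
  w <- d[pairs]
  o <- order(w, lo, hi)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(length(o))
  for (k in o) {
    ra <- find(pairs[k, 1L])
    rb <- find(pairs[k, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
    }
  }
  data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
}

.pruneLeaves <- function(edgeMat, terminals) {
  repeat {
    if (!nrow(edgeMat)) break
    deg <- table(c(edgeMat[, 1L], edgeMat[, 2L]))
    leaves <- names(deg)[deg == 1L]
    drop <- setdiff(leaves, terminals)
    if (!length(drop)) break
    keep <- !(edgeMat[, 1L] %in% drop | edgeMat[, 2L] %in% drop)
    edgeMat <- edgeMat[keep, , drop = FALSE]
  }
  edgeMat
}

.subnetworkFromEdges <- function(network, nodes, edgeMat, condition, site,
                                 nTrees, nothing = FALSE) {
  if (nrow(edgeMat)) {
    isRxn1 <- edgeMat[, 1L] %in% network@reactions
    e <- data.frame(
      from = ifelse(isRxn1, edgeMat[, 2L], edgeMat[, 1L]),
      to = ifelse(isRxn1, edgeMat[, 1L], edgeMat[, 2L]),
      stringsAsFactors = FALSE
    )
    e <- unique(e)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(from = character(), to = character())
  }
  rxns <- intersect(network@reactions, nodes)
  genes <- sort(unique(unlist(network@ec[match(rxns, network@reactions)],
    use.names = FALSE
  )))
  if (!length(rxns)) genes <- character()
  new("SubnetworkResult",
    nodes = sort(nodes), edges = e, genes = genes,
    edgeCount = nrow(e), condition = condition, site = site,
    nTrees = as.integer(nTrees), nothingToConnect = nothing
  )
}

#' Minimal connecting subnetwork (approximate Steiner tree)
#'
#' Formalises the minimal-subnetwork extraction as a minimum-edge Steiner
#' tree on the undirected bipartite graph and solves it with the
#' metric-closure 2-approximation: all-pairs shortest distances between
#' terminals, deterministic Kruskal minimum spanning tree of that closure,
#' expansion of each closure edge into an actual shortest path, and iterative
#' pruning of non-terminal leaves. Terminals split across several master
#' components yield one tree per occupied component (a Steiner forest) with a
#' warning. Output is deterministic for a fixed input.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param terminals a \linkS4class{TerminalSet} from
#'   \code{\link{buildTerminals}}.
#' @param condition,site labels recorded in the result.
#' @return A \linkS4class{SubnetworkResult}.
#' @export
minimalSubnetwork <- function(network, terminals, condition = NA_character_,
                              site = NA_character_) {
  stopifnot(is(network, "MetabolicNetwork"), is(terminals, "TerminalSet"))
  terms <- sort(unique(c(
    terminals@metaboliteTerminals, terminals@reactionTerminals
  )))
  if (!length(terms)) {
    return(.subnetworkFromEdges(network, character(),
      matrix(character(), 0L, 2L), condition, site,
      nTrees = 0L, nothing = TRUE
    ))
  }
  known <- c(network@metabolites, network@reactions)
  if (!all(terms %in% known)) {
    stop("terminal not present in the network: ", paste(
      setdiff(terms, known),
      collapse = ", "
    ))
  }
  g <- asIgraph(network)
  comp <- igraph::components(g)
  memb <- comp$membership[terms]
  groups <- split(terms, memb)
  if (length(groups) > 1L) {
    warning(
      "terminals span ", length(groups),
      " master-network components; returning a Steiner forest"
    )
  }
  allNodes <- character()
  allEdges <- matrix(character(), 0L, 2L)
  for (grp in groups) {
    grp <- sort(grp)
    if (length(grp) == 1L) {
      allNodes <- c(allNodes, grp)
      next
    }
    d <- igraph::distances(g, v = grp, to = grp)
    mst <- .metricClosureMst(d, grp)
    for (i in seq_len(nrow(mst))) {
      vp <- igraph::shortest_paths(g,
        from = mst$a[i], to = mst$b[i],
        output = "vpath"
      )$vpath[[1L]]
      vn <- names(vp)
      if (length(vn) > 1L) {
        allEdges <- rbind(
          allEdges,
          cbind(vn[-length(vn)], vn[-1L])
        )
      }
    }
    allNodes <- c(allNodes, grp)
  }
  if (nrow(allEdges)) {
    key <- paste(pmin(allEdges[, 1L], allEdges[, 2L]),
      pmax(allEdges[, 1L], allEdges[, 2L]),
      sep = "\r"
    )
    allEdges <- allEdges[!duplicated(key), , drop = FALSE]
    allEdges <- .pruneLeaves(allEdges, terms)
    allNodes <- unique(c(allNodes, c(allEdges)))
  }
  .subnetworkFromEdges(network, allNodes, allEdges, condition, site,
    nTrees = length(groups)
  )
}

.lexicoSpanningEdges <- function(g, nodes) {
  sg <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_edgelist(sg)
  if (!nrow(el)) {
    return(character())
  }
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  o <- order(lo, hi)
  vnames <- igraph::V(sg)$name
  parent <- stats::setNames(vnames, vnames)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  out <- character()
  for (k in o) {
    ra <- find(lo[k])
    rb <- find(hi[k])
    if (ra != rb) {
      parent[[ra]] <- rb
      out <- c(out, paste(lo[k], hi[k], sep = "\t"))
    }
  }
  sort(out)
}

#' Exact minimum-edge Steiner tree by exhaustive search
#'
#' Test oracle: enumerates non-terminal node subsets in increasing size and
#' returns the first size whose induced subgraph connects all terminals (a
#' spanning tree of that node set is a minimum-edge Steiner tree). Among
#' co-optimal solutions the lexicographically smallest sorted edge list is
#' returned. Exponential: instances with more than \code{maxNonTerminals}
#' candidate Steiner vertices per component are refused.
#'
#' @inheritParams minimalSubnetwork
#' @param maxNonTerminals size guard (default 16).
#' @return A \linkS4class{SubnetworkResult}.
#' @export
exactSteinerOracle <- function(network, terminals, condition = NA_character_,
                               site = NA_character_, maxNonTerminals = 16L) {
  stopifnot(is(network, "MetabolicNetwork"), is(terminals, "TerminalSet"))
  terms <- sort(unique(c(
    terminals@metaboliteTerminals, terminals@reactionTerminals
  )))
  if (!length(terms)) {
    return(.subnetworkFromEdges(network, character(),
      matrix(character(), 0L, 2L), condition, site,
      nTrees = 0L, nothing = TRUE
    ))
  }
  g <- asIgraph(network)
  comp <- igraph::components(g)
  memb <- comp$membership[terms]
  groups <- split(terms, memb)
  allNodes <- character()
  edgeKeys <- character()
  for (ci in names(groups)) {
    grp <- sort(groups[[ci]])
    compNodes <- names(comp$membership)[comp$membership == as.integer(ci)]
    nonT <- sort(setdiff(compNodes, grp))
    if (length(nonT) > maxNonTerminals) {
      stop(
        "exact oracle refused: ", length(nonT),
        " candidate Steiner vertices exceed the size guard (",
        maxNonTerminals, ")"
      )
    }
    if (length(grp) == 1L) {
      allNodes <- c(allNodes, grp)
      next
    }
    best <- NULL
    for (k in 0:length(nonT)) {
      subs <- if (k == 0L) {
        list(character())
      } else {
        asplit(combn(nonT, k), 2L)
      }
      for (s in subs) {
        nodes <- c(grp, as.character(s))
        sg <- igraph::induced_subgraph(g, nodes)
        if (igraph::is_connected(sg)) {
          cand <- .lexicoSpanningEdges(g, nodes)
          if (is.null(best) ||
            paste(cand, collapse = "\n") < paste(best, collapse = "\n")) {
            best <- cand
          }
        }
      }
      if (!is.null(best)) break
    }
    allNodes <- c(allNodes, grp)
    edgeKeys <- c(edgeKeys, best)
  }
  if (length(edgeKeys)) {
    em <- do.call(rbind, strsplit(edgeKeys, "\t", fixed = TRUE))
    allNodes <- unique(c(allNodes, c(em)))
  } else {
    em <- matrix(character(), 0L, 2L)
  }
  .subnetworkFromEdges(network, allNodes, em, condition, site,
    nTrees = length(groups)
  )
}

#' Combine per-site subnetworks into per-condition gene sets
#'
#' Each condition's gene set is the union of implicated gene sets over its
#' sites; a gene is flagged unique when it occurs in exactly one condition's
#' set.
#'
#' @param results list of \linkS4class{SubnetworkResult} objects with
#'   condition labels set.
#' @return data.frame with columns \code{condition}, \code{gene},
#'   \code{unique}.
#' @export
conditionGeneSets <- function(results) {
  stopifnot(length(results) >= 1L)
  conds <- vapply(results, function(r) r@condition, character(1))
  if (anyNA(conds)) stop("every result needs a condition label")
  sets <- lapply(split(results, conds), function(rs) {
    sort(unique(unlist(lapply(rs, implicatedGenes), use.names = FALSE)))
  })
  tab <- data.frame(
    condition = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  counts <- table(tab$gene)
  tab$unique <- counts[tab$gene] == 1L
  rownames(tab) <- NULL
  tab
}

#' Condition-unique genes
#'
#' @param table output of \code{\link{conditionGeneSets}}.
#' @return Named list, condition -> sorted character vector of genes that
#'   appear in that condition's set and in no other condition's set.
#' @export
uniqueGenes <- function(table) {
  stopifnot(all(c("condition", "gene", "unique") %in% names(table)))
  conds <- unique(table$condition)
  out <- lapply(conds, function(cn) {
    sort(table$gene[table$condition == cn & table$unique])
  })
  names(out) <- conds
  out
}

#' Group genes by pathway via a user-supplied EC-to-pathway mapping
#'
#' Multi-mapping is allowed (a gene listed in two pathways appears in both
#' groups); genes without any mapping are reported under \code{"unmapped"}.
#'
#' @param genes character vector of EC ids.
#' @param mapping data.frame with columns \code{ec} and \code{pathway}, e.g.
#'   from \code{\link{readPathwayMapping}}.
#' @return Named list, pathway -> sorted gene vector (plus "unmapped").
#' @export
pathwayAnnotation <- function(genes, mapping) {
  if (!is.data.frame(mapping) ||
    !all(c("ec", "pathway") %in% names(mapping))) {
    stop("mapping must be a data.frame with 'ec' and 'pathway' columns")
  }
  genes <- unique(as.character(genes))
  hits <- mapping[mapping$ec %in% genes, , drop = FALSE]
  out <- lapply(
    split(hits$ec, hits$pathway),
    function(g) sort(unique(g))
  )
  unmapped <- sort(setdiff(genes, mapping$ec))
  out <- out[order(names(out))]
  out$unmapped <- unmapped
  out
}
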