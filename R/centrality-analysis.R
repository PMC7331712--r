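#' Betweenness and degree centralities of a gene network
#'
#' Degree is the incident edge count; betweenness is Brandes shortest-path
#' betweenness on the undirected unweighted graph, normalised by
#' (n-1)(n-2)/2 so values lie in [0, 1] (endpoint pairs excluded, the
#' standard convention). Intended to run on \code{\link{largestComponent}}
#' output; with fewer than 3 nodes betweenness is defined as 0.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param labels optional named list, condition -> gene set, recorded in a
#'   \code{condition} column ("none" for unlabelled genes).
#' @return data.frame with columns \code{gene}, \code{betweenness},
#'   \code{degree} (and \code{condition} when labels are given), one row per
#'   node, ordered by gene id.
#' @export
computeCentralities <- function(net, labels = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  g <- asIgraph(net)
  n <- length(net@nodes)
  btw <- if (n < 3L) {
    stats::setNames(rep(0, n), net@nodes)
  } else {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  }
  deg <- igraph::degree(g)
  out <- data.frame(
    gene = net@nodes,
    betweenness = unname(btw[net@nodes]),
    degree = unname(deg[net@nodes]),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    cond <- rep("none", nrow(out))
    for (cn in names(labels)) {
      cond[out$gene %in% labels[[cn]]] <- cn
    }
    out$condition <- cond
  }
  out
}

#' Rank genes by a centrality metric
#'
#' Descending order; ties broken lexicographically by gene id; 1-based ranks.
#'
#' @param table a centrality table from \code{\link{computeCentralities}}.
#' @param metric "betweenness" or "degree".
#' @return The table reordered, with a \code{rank} column prepended.
#' @export
rankGenes <- function(table, metric = c("betweenness", "degree")) {
  if (!nrow(table)) stop("empty centrality table")
  metric <- match.arg(metric)
  o <- order(-table[[metric]], table$gene)
  out <- table[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Per-condition centrality summaries
#'
#' Arithmetic group means of betweenness and degree, fold over the
#' network-wide mean, and counts of group genes strictly below the network
#' mean. Labelled genes absent from the table are excluded from the means
#' and reported in the \code{"missing"} attribute.
#'
#' @param table a centrality table (columns gene, betweenness, degree).
#' @param labels named list, condition -> gene set.
#' @param networkMeans optional list/vector with elements \code{betweenness}
#'   and \code{degree} overriding the baseline means (e.g. published
#'   network-wide values when only the group rows are available); default is
#'   to compute them from \code{table}.
#' @return data.frame, one row per condition: n, meanBetweenness, meanDegree,
#'   foldBetweenness, foldDegree, belowMeanBetweenness, belowMeanDegree.
#' @export
groupSummary <- function(table, labels, networkMeans = NULL) {
  stopifnot(all(c("gene", "betweenness", "degree") %in% names(table)))
  if (is.null(networkMeans)) {
    networkMeans <- list(
      betweenness = mean(table$betweenness),
      degree = mean(table$degree)
    )
  }
  nb <- networkMeans[["betweenness"]]
  nd <- networkMeans[["degree"]]
  missing <- list()
  rows <- lapply(names(labels), function(cn) {
    genes <- labels[[cn]]
    hit <- table[table$gene %in% genes, , drop = FALSE]
    missing[[cn]] <<- setdiff(genes, table$gene)
    if (!nrow(hit)) {
      return(data.frame(
        condition = cn, n = 0L, meanBetweenness = NA_real_,
        meanDegree = NA_real_, foldBetweenness = NA_real_,
        foldDegree = NA_real_, belowMeanBetweenness = NA_integer_,
        belowMeanDegree = NA_integer_, stringsAsFactors = FALSE
      ))
    }
    mb <- mean(hit$betweenness)
    md <- mean(hit$degree)
    data.frame(
      condition = cn, n = nrow(hit), meanBetweenness = mb, meanDegree = md,
      foldBetweenness = mb / nb, foldDegree = md / nd,
      belowMeanBetweenness = sum(hit$betweenness < nb),
      belowMeanDegree = sum(hit$degree < nd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "networkMeans") <- list(betweenness = nb, degree = nd)
  attr(out, "missing") <- missing
  out
}

#' Centrality ratios to the network median
#'
#' Per gene: log2 of the ratio of betweenness to the median betweenness, and
#' the (untransformed) ratio of degree to the median degree - the two axes of
#' the condition-overlay centrality scatter. Genes with zero betweenness are
#' flagged and floored at (smallest positive betweenness) / 10 before the
#' log; a zero median is replaced by the same floor.
#'
#' @param table a centrality table.
#' @return data.frame with gene, log2BetweennessRatio, degreeRatio,
#'   flooredBetweenness.
#' @export
ratioToMedian <- function(table) {
  stopifnot(all(c("gene", "betweenness", "degree") %in% names(table)))
  b <- table$betweenness
  posMin <- suppressWarnings(min(b[b > 0]))
  if (!is.finite(posMin)) stop("all betweenness values are zero")
  floorB <- posMin / 10
  medB <- median(b)
  if (medB <= 0) {
    message("zero median betweenness; using floor ", signif(floorB, 3))
    medB <- floorB
  }
  flo <- b <= 0
  data.frame(
    gene = table$gene,
    log2BetweennessRatio = log2(pmax(b, floorB) / medB),
    degreeRatio = table$degree / median(table$degree),
    flooredBetweenness = flo,
    stringsAsFactors = FALSE
  )
}

#' Neighbourhood subnetwork of seed genes
#'
#' Members are the seeds plus every gene adjacent to at least one seed, with
#' the induced edge set. With \code{dropIsolatedSeeds}, a seed whose closed
#' neighbourhood shares no node with any other seed's closed neighbourhood is
#' excluded together with its exclusive neighbours - the rule used to drop a
#' seed gene that is not in proximity to the rest of the seed cluster.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   network are reported in the \code{"missingSeeds"} attribute.
#' @param dropIsolatedSeeds drop seeds unconnected to the seed cluster.
#' @return list with \code{seeds} (retained seeds), \code{members},
#'   \code{edges} (induced edge data.frame) and \code{droppedSeeds}.
#' @export
neighborhoodSubnetwork <- function(net, seeds, dropIsolatedSeeds = FALSE) {
  stopifnot(is(net, "GeneNetwork"))
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, net@nodes)
  seeds <- sort(intersect(seeds, net@nodes))
  if (!length(seeds)) {
    warning("no seeds present in the network")
    out <- list(
      seeds = character(), members = character(),
      edges = data.frame(from = character(), to = character()),
      droppedSeeds = character()
    )
    attr(out, "missingSeeds") <- missing
    return(out)
  }
  e <- net@edges
  nbrs <- function(s) {
    unique(c(e$to[e$from == s], e$from[e$to == s]))
  }
  closed <- lapply(seeds, function(s) c(s, nbrs(s)))
  names(closed) <- seeds
  dropped <- character()
  if (dropIsolatedSeeds && length(seeds) > 1L) {
    dropped <- seeds[vapply(seq_along(seeds), function(i) {
      others <- unique(unlist(closed[-i], use.names = FALSE))
      !any(closed[[i]] %in% others)
    }, logical(1))]
    seeds <- setdiff(seeds, dropped)
    closed <- closed[seeds]
  }
  members <- sort(unique(unlist(closed, use.names = FALSE)))
  keep <- e$from %in% members & e$to %in% members
  out <- list(
    seeds = seeds, members = members,
    edges = {
      ed <- e[keep, , drop = FALSE]
      rownames(ed) <- NULL
      ed
    },
    droppedSeeds = dropped
  )
  attr(out, "missingSeeds") <- missing
  out
}
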