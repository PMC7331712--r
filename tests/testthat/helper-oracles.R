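# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph, where igraph is the implementation).

# Shortest-path betweenness by explicit BFS path counting from every source:
# for node v, sum over unordered pairs {s,t} (v not an endpoint) of
# sigma_st(v) / sigma_st, normalised by (n-1)(n-2)/2.
oracleBetweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  bfs <- function(s) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    sigma <- stats::setNames(rep(0, n), nodes)
    dist[s] <- 0
    sigma[s] <- 1
    queue <- s
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[u]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[u] + 1) sigma[w] <- sigma[w] + sigma[u]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  info <- lapply(stats::setNames(nodes, nodes), bfs)
  btw <- stats::setNames(rep(0, n), nodes)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- nodes[i]
      t <- nodes[j]
      dst <- info[[s]]$dist[t]
      if (!is.finite(dst)) next
      tot <- info[[s]]$sigma[t]
      for (v in nodes) {
        if (v == s || v == t) next
        if (info[[s]]$dist[v] + info[[v]]$dist[t] == dst) {
          btw[v] <- btw[v] + info[[s]]$sigma[v] * info[[v]]$sigma[t] / tot
        }
      }
    }
  }
  if (n < 3L) return(btw * 0)
  btw / ((n - 1) * (n - 2) / 2)
}

# Connected-component labelling by plain breadth-first search.
oracleComponents <- function(nodes, edges) {
  lab <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (s in nodes) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      nb <- c(edges$to[edges$from == u], edges$from[edges$to == u])
      new <- nb[is.na(lab[nb])]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

# Plug-in mutual information of two discrete vectors from the closed form
# sum p(x,y) log2(p(x,y) / (p(x) p(y))).
oracleDiscreteMi <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) s <- s + p * log2(p / (px[i] * py[j]))
    }
  }
  as.numeric(s)
}

# Exact two-sided permutation p-value for a difference in means, enumerating
# all assignments of the pooled values into the two groups.
oraclePermutationP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  idx <- combn(length(pool), n1)
  diffs <- apply(idx, 2L, function(ii) {
    abs(mean(pool[ii]) - mean(pool[-ii]))
  })
  mean(diffs >= obs - 1e-12)
}

# Random connected bipartite metabolite-reaction instance with <= 12 nodes
# and <= maxTerminals terminals, for Steiner heuristic-vs-oracle comparison.
randomBipartiteInstance <- function(seed, maxTerminals = 4L) {
  set.seed(seed)
  repeat {
    nM <- sample(2:6, 1L)
    nR <- sample(2:6, 1L)
    mets <- sprintf("m%02d", seq_len(nM))
    rxns <- sprintf("r%02d", seq_len(nR))
    subs <- vector("list", nR)
    prods <- vector("list", nR)
    for (i in seq_len(nR)) {
      subs[[i]] <- sample(mets, sample(1:2, 1L))
      rest <- setdiff(mets, subs[[i]])
      if (!length(rest)) rest <- mets
      prods[[i]] <- sample(rest, min(sample(1:2, 1L), length(rest)))
    }
    net <- metabolicNetwork(mets, rxns, subs, prods,
      ec = as.list(sprintf("1.1.1.%d", seq_len(nR)))
    )
    g <- asIgraph(net)
    if (!igraph::is_connected(g)) next
    nodes <- c(mets, rxns)
    nT <- sample(2:maxTerminals, 1L)
    terms <- sample(nodes, min(nT, length(nodes)))
    ts <- new("TerminalSet",
      metaboliteTerminals = sort(intersect(terms, mets)),
      reactionTerminals = sort(intersect(terms, rxns)),
      provenance = stats::setNames(
        ifelse(terms %in% mets, "metabolite", "gene"), terms
      ),
      unmatchedMetabolites = character()
    )
    return(list(network = net, terminals = ts))
  }
}

# Small, fast synthetic config used throughout the suite.
smallConfig <- function(seed, ...) {
  defaults <- list(
    seed = seed, nGenes = 80L, nMetabolites = 30L, nReactions = 25L,
    nCoreMetabolites = 8L, nResponsivePerCondition = 3L,
    nModules = 4L, moduleSize = 8L
  )
  do.call(syntheticConfig, utils::modifyList(defaults, list(...)))
}

# Run differential calling + integration for every condition and return the
# condition-unique gene sets.
runIntegration <- function(cfg, deConfig = differentialConfig()) {
  net <- generateMasterNetwork(cfg)
  sim <- generateExpression(cfg, net)
  det <- generateMetaboliteDetections(net, sim$truth, cfg)
  ctrl <- cfg@control
  res <- lapply(cfg@conditions, function(cond) {
    oe <- if (cond == ctrl) {
      character()
    } else {
      callOverexpressed(
        differentialExpression(sim$expr, cond, ctrl, deConfig), deConfig
      )
    }
    minimalSubnetwork(
      net, buildTerminals(net, det[[cond]], oe),
      condition = cond, site = "all"
    )
  })
  list(
    unique = uniqueGenes(conditionGeneSets(res)),
    truth = sim$truth, network = net
  )
}
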