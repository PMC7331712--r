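.starNetwork <- function() {
  geneNetwork(data.frame(
    from = rep("hub", 5), to = paste0("leaf", 1:5)
  ))
}

.pathNet <- function() {
  geneNetwork(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
}

test_that("closed-form centralities: star and path", {
  cent <- computeCentralities(.starNetwork())
  hub <- cent[cent$gene == "hub", ]
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$degree, 5L)
  leaves <- cent[cent$gene != "hub", ]
  expect_equal(leaves$betweenness, rep(0, 5))
  expect_equal(leaves$degree, rep(1L, 5))

  # path a-b-c-d: b bridges {a,c} and {a,d} of the 3 pairs excluding it
  pc <- computeCentralities(.pathNet())
  expect_equal(pc$betweenness[pc$gene == "b"], 2 / 3, tolerance = 1e-12)
  expect_equal(pc$degree[pc$gene == "b"], 2L)
})

test_that("betweenness matches the path-enumeration oracle on random graphs", {
  set.seed(31)
  checked <- 0L
  while (checked < 50L) {
    n <- sample(5:20, 1)
    nodes <- sprintf("g%02d", 1:n)
    e <- unique(data.frame(
      from = sample(nodes, 3 * n, replace = TRUE),
      to = sample(nodes, 3 * n, replace = TRUE)
    ))
    e <- e[e$from != e$to, ]
    if (!nrow(e)) next
    net <- largestComponent(geneNetwork(e))
    if (length(networkNodes(net)) < 3) next
    cent <- computeCentralities(net)
    oracle <- oracleBetweenness(networkNodes(net), edgeTable(net))
    expect_equal(cent$betweenness, unname(oracle[cent$gene]),
      tolerance = 1e-9
    )
    # degree sum identity
    expect_equal(sum(cent$degree), 2L * nrow(edgeTable(net)))
    checked <- checked + 1L
  }
})

test_that("tiny networks define betweenness as zero", {
  net <- geneNetwork(data.frame(from = "a", to = "b"))
  cent <- computeCentralities(net)
  expect_equal(cent$betweenness, c(0, 0))
})

test_that("ranking is descending, 1-based, with lexicographic ties", {
  tab <- data.frame(
    gene = c("z", "a", "m"),
    betweenness = c(0.5, 0.5, 0.9),
    degree = c(1L, 2L, 3L)
  )
  r <- rankGenes(tab, "betweenness")
  expect_equal(r$rank, 1:3)
  expect_equal(r$gene, c("m", "a", "z"))
  single <- rankGenes(tab[1, ], "degree")
  expect_equal(single$rank, 1L)
  expect_error(rankGenes(tab, "closeness"), "arg")
  # agreement with an independent sort on random tables
  set.seed(5)
  for (i in 1:20) {
    rt <- data.frame(
      gene = sample(sprintf("g%02d", 1:8)),
      betweenness = round(runif(8), 2), degree = sample(1:4, 8, TRUE)
    )
    r2 <- rankGenes(rt, "degree")
    o <- rt[order(-rt$degree, rt$gene), ]
    expect_equal(r2$gene, o$gene)
  }
})

test_that("group summaries reproduce the published condition aggregates", {
  tab2 <- read.delim(
    system.file("extdata", "condition_gene_centralities.tsv",
      package = "metaphenet"
    ),
    stringsAsFactors = FALSE
  )
  labels <- split(tab2$gene, tab2$condition)
  # network-wide baselines reported for the full 1,061-gene component
  gs <- groupSummary(tab2, labels,
    networkMeans = list(betweenness = 0.006, degree = 3.72)
  )
  wet <- gs[gs$condition == "wet", ]
  gly <- gs[gs$condition == "glycine", ]
  expect_equal(round(wet$meanBetweenness, 3), 0.007)
  expect_equal(wet$meanDegree, 6)
  expect_equal(wet$belowMeanBetweenness, 2L) # 2 of 3 wet genes
  expect_equal(round(wet$foldDegree, 1), 1.6)
  expect_equal(round(gly$meanBetweenness, 3), 0.008)
  expect_equal(gly$meanDegree, 3)
  expect_equal(gly$belowMeanBetweenness, 4L) # 4 of 8 glycine genes
  expect_equal(gly$belowMeanDegree, 5L) # 5 of 8 glycine genes
})

test_that("group summary handles missing labels and empty groups", {
  tab <- data.frame(
    gene = c("a", "b"), betweenness = c(0.1, 0.3), degree = c(1L, 3L)
  )
  gs <- groupSummary(tab, list(x = c("a", "ghost"), y = "nope"))
  expect_equal(gs$n[gs$condition == "x"], 1L)
  expect_true(is.na(gs$meanBetweenness[gs$condition == "y"]))
  expect_equal(attr(gs, "missing")$x, "ghost")
})

test_that("ratios to the median follow their closed forms and floor zeros", {
  tab <- data.frame(
    gene = c("lo", "med", "hi", "zero"),
    betweenness = c(0.01, 0.02, 0.04, 0),
    degree = c(1L, 2L, 4L, 2L)
  )
  # median betweenness = 0.015, median degree = 2
  rt <- ratioToMedian(tab)
  expect_equal(
    rt$log2BetweennessRatio[rt$gene == "hi"],
    log2(0.04 / 0.015)
  )
  expect_equal(rt$degreeRatio[rt$gene == "med"], 1)
  expect_true(rt$flooredBetweenness[rt$gene == "zero"])
  expect_equal(
    rt$log2BetweennessRatio[rt$gene == "zero"],
    log2((0.01 / 10) / 0.015)
  )
  # gene at both medians maps to (0, 1)
  tab2 <- data.frame(
    gene = c("a", "b", "c"), betweenness = c(0.1, 0.2, 0.4),
    degree = c(1L, 2L, 4L)
  )
  rt2 <- ratioToMedian(tab2)
  expect_equal(rt2$log2BetweennessRatio[rt2$gene == "b"], 0)
  expect_equal(rt2$degreeRatio[rt2$gene == "b"], 1)
})

test_that("neighbourhoods are closed seed neighbourhoods with induced edges", {
  # star centre as sole seed captures the whole star
  nb <- neighborhoodSubnetwork(.starNetwork(), "hub")
  expect_setequal(nb$members, c("hub", paste0("leaf", 1:5)))
  expect_equal(nrow(nb$edges), 5L)
  # random graphs vs brute-force adjacency scan
  set.seed(41)
  for (i in 1:30) {
    n <- sample(6:14, 1)
    nodes <- sprintf("g%02d", 1:n)
    e <- unique(data.frame(
      from = sample(nodes, 2 * n, replace = TRUE),
      to = sample(nodes, 2 * n, replace = TRUE)
    ))
    e <- e[e$from != e$to, ]
    if (!nrow(e)) next
    net <- geneNetwork(e)
    seeds <- sample(networkNodes(net), min(3, length(networkNodes(net))))
    nb2 <- neighborhoodSubnetwork(net, seeds)
    ed <- edgeTable(net)
    adj <- unique(unlist(lapply(seeds, function(s) {
      c(ed$to[ed$from == s], ed$from[ed$to == s])
    })))
    expect_setequal(nb2$members, union(seeds, adj))
    # every non-seed member touches a seed
    nonSeed <- setdiff(nb2$members, seeds)
    for (v in nonSeed) {
      expect_true(any(
        (ed$from == v & ed$to %in% seeds) | (ed$to == v & ed$from %in% seeds)
      ))
    }
  }
})

test_that("isolated seeds are dropped only when the flag is set", {
  net <- geneNetwork(data.frame(
    from = c("s1", "s2", "x", "far"),
    to = c("x", "x", "y", "z")
  ))
  # far's neighbourhood {far, z} shares nothing with the s1/s2 cluster
  keep <- neighborhoodSubnetwork(net, c("s1", "s2", "far"),
    dropIsolatedSeeds = FALSE
  )
  expect_true("far" %in% keep$members)
  drop <- neighborhoodSubnetwork(net, c("s1", "s2", "far"),
    dropIsolatedSeeds = TRUE
  )
  expect_false("far" %in% drop$members)
  expect_equal(drop$droppedSeeds, "far")
  expect_setequal(drop$members, c("s1", "s2", "x"))
})

test_that("unnormalised betweenness sums to total intermediate appearances", {
  set.seed(51)
  for (i in 1:10) {
    nodes <- sprintf("g%d", 1:8)
    e <- unique(data.frame(
      from = sample(nodes, 14, replace = TRUE),
      to = sample(nodes, 14, replace = TRUE)
    ))
    e <- e[e$from != e$to, ]
    if (!nrow(e)) next
    net <- largestComponent(geneNetwork(e))
    n <- length(networkNodes(net))
    if (n < 3) next
    cent <- computeCentralities(net)
    # oracle total: sum over pairs of expected intermediate counts
    oracle <- oracleBetweenness(networkNodes(net), edgeTable(net))
    expect_equal(sum(cent$betweenness), sum(oracle), tolerance = 1e-9)
  }
})
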