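# Hand-built path network m1 - r1 - m2 - r2 - m3, with an extra branch
# reaction r3 (m2 <-> m4) for pruning checks.
.pathNetwork <- function() {
  metabolicNetwork(
    metabolites = c("m1", "m2", "m3", "m4"),
    reactions = c("r1", "r2", "r3"),
    substrates = list("m1", "m2", "m2"),
    products = list("m2", "m3", "m4"),
    ec = list("1.1.1.1", "2.2.2.2", c("2.2.2.2", "3.3.3.3"))
  )
}

test_that("terminal construction maps metabolites and over-expressed ECs", {
  net <- .pathNetwork()
  t1 <- buildTerminals(net, "m1", character())
  expect_equal(t1@metaboliteTerminals, "m1")
  expect_length(t1@reactionTerminals, 0L)
  # one EC labelling two reactions makes both reactions terminals
  t2 <- buildTerminals(net, character(), "2.2.2.2")
  expect_equal(t2@reactionTerminals, c("r2", "r3"))
  # unknown metabolites are reported, not dropped silently
  t3 <- buildTerminals(net, c("m1", "mX"), character())
  expect_equal(t3@metaboliteTerminals, "m1")
  expect_equal(t3@unmatchedMetabolites, "mX")
  expect_equal(unname(t3@provenance["m1"]), "metabolite")
})

test_that("unique path between terminals is returned exactly", {
  net <- .pathNetwork()
  ts <- buildTerminals(net, c("m1", "m3"), character())
  sub <- minimalSubnetwork(net, ts)
  expect_equal(sub@edgeCount, 4L)
  expect_setequal(sub@nodes, c("m1", "r1", "m2", "r2", "m3"))
  expect_setequal(implicatedGenes(sub), c("1.1.1.1", "2.2.2.2"))
  # deterministic repeat
  expect_identical(edgeTable(minimalSubnetwork(net, ts)), edgeTable(sub))
})

test_that("single terminal yields a zero-edge subnetwork; empty set is flagged", {
  net <- .pathNetwork()
  one <- minimalSubnetwork(net, buildTerminals(net, "m2", character()))
  expect_equal(one@nodes, "m2")
  expect_equal(one@edgeCount, 0L)
  expect_false(one@nothingToConnect)
  none <- minimalSubnetwork(net, buildTerminals(net, character(), character()))
  expect_true(none@nothingToConnect)
  expect_length(none@nodes, 0L)
})

test_that("disconnected terminals give a Steiner forest with a warning", {
  net <- metabolicNetwork(
    metabolites = c("a1", "a2", "b1", "b2"),
    reactions = c("ra", "rb"),
    substrates = list("a1", "b1"),
    products = list("a2", "b2"),
    ec = list("1.1.1.1", "2.2.2.2")
  )
  ts <- buildTerminals(net, c("a1", "a2", "b1", "b2"), character())
  expect_warning(sub <- minimalSubnetwork(net, ts), "forest")
  expect_equal(sub@nTrees, 2L)
  expect_equal(sub@edgeCount, 4L)
})

test_that("exact oracle solves closed-form cases", {
  net <- .pathNetwork()
  # endpoints of a path: the path itself
  sub <- exactSteinerOracle(net, buildTerminals(net, c("m1", "m3"), character()))
  expect_equal(sub@edgeCount, 4L)
  # all nodes terminal on a tree-shaped network: the tree itself (7 nodes)
  all7 <- new("TerminalSet",
    metaboliteTerminals = c("m1", "m2", "m3", "m4"),
    reactionTerminals = c("r1", "r2", "r3"),
    provenance = character(), unmatchedMetabolites = character()
  )
  expect_equal(exactSteinerOracle(net, all7)@edgeCount, 6L)
  # 4-cycle with opposite terminals: two co-optimal sides; the lexicographic
  # tie-break picks the side through the smaller reaction id
  cyc <- metabolicNetwork(
    metabolites = c("mA", "mB"), reactions = c("rA", "rB"),
    substrates = list("mA", "mA"), products = list("mB", "mB"),
    ec = list("1.1.1.1", "2.2.2.2")
  )
  ts <- buildTerminals(cyc, c("mA", "mB"), character())
  sub2 <- exactSteinerOracle(cyc, ts)
  expect_equal(sub2@edgeCount, 2L)
  expect_setequal(sub2@nodes, c("mA", "mB", "rA"))
  expect_error(
    exactSteinerOracle(net, buildTerminals(net, c("m1", "m3"), character()),
      maxNonTerminals = 1L
    ),
    "size guard"
  )
})

test_that("heuristic is never better than the oracle and within 2x optimum", {
  worst <- 0
  for (seed in 1:100) {
    inst <- randomBipartiteInstance(seed)
    h <- minimalSubnetwork(inst$network, inst$terminals)
    o <- exactSteinerOracle(inst$network, inst$terminals)
    expect_gte(h@edgeCount, o@edgeCount)
    if (o@edgeCount > 0L) {
      ratio <- h@edgeCount / o@edgeCount
      expect_lte(ratio, 2)
      worst <- max(worst, ratio)
    }
    # heuristic result contains every terminal
    terms <- c(
      inst$terminals@metaboliteTerminals,
      inst$terminals@reactionTerminals
    )
    expect_true(all(terms %in% h@nodes))
  }
  expect_lte(worst, 2)
})

test_that("adding a terminal never shrinks the optimal subnetwork", {
  for (seed in 1:25) {
    inst <- randomBipartiteInstance(seed, maxTerminals = 3L)
    base <- exactSteinerOracle(inst$network, inst$terminals)
    terms <- c(
      inst$terminals@metaboliteTerminals,
      inst$terminals@reactionTerminals
    )
    extraPool <- setdiff(
      c(metabolites(inst$network), reactions(inst$network)), terms
    )
    if (!length(extraPool)) next
    extra <- extraPool[1L]
    grown <- new("TerminalSet",
      metaboliteTerminals = sort(union(
        inst$terminals@metaboliteTerminals,
        intersect(extra, metabolites(inst$network))
      )),
      reactionTerminals = sort(union(
        inst$terminals@reactionTerminals,
        intersect(extra, reactions(inst$network))
      )),
      provenance = character(), unmatchedMetabolites = character()
    )
    expect_gte(
      exactSteinerOracle(inst$network, grown)@edgeCount,
      base@edgeCount
    )
  }
})

test_that("condition gene tables union sites and flag uniqueness", {
  mk <- function(cond, site, genes) {
    new("SubnetworkResult",
      nodes = character(), edges = data.frame(from = character(), to = character()),
      genes = genes, edgeCount = 0L, condition = cond, site = site,
      nTrees = 1L, nothingToConnect = FALSE
    )
  }
  tab <- conditionGeneSets(list(
    mk("dry", "A", c("E1")), mk("dry", "C", c("E1", "E3")),
    mk("wet", "A", c("E2")), mk("gly", "A", c("E3"))
  ))
  expect_setequal(tab$gene[tab$condition == "dry"], c("E1", "E3"))
  ug <- uniqueGenes(tab)
  expect_equal(ug$dry, "E1")
  expect_equal(ug$wet, "E2")
  expect_length(ug$gly, 0L) # E3 is shared with dry
})

test_that("uniqueness matches brute-force membership counting", {
  set.seed(99)
  for (i in 1:50) {
    conds <- c("c1", "c2", "c3")
    sets <- lapply(conds, function(x) {
      sample(sprintf("E%d", 1:12), sample(0:6, 1))
    })
    names(sets) <- conds
    results <- lapply(conds, function(cn) {
      new("SubnetworkResult",
        nodes = character(),
        edges = data.frame(from = character(), to = character()),
        genes = sets[[cn]], edgeCount = 0L, condition = cn, site = "A",
        nTrees = 1L, nothingToConnect = FALSE
      )
    })
    keep <- lengths(sets) > 0
    if (!any(keep)) next
    ug <- uniqueGenes(conditionGeneSets(results[keep]))
    for (cn in conds[keep]) {
      counts <- table(unlist(lapply(sets[keep], unique)))
      expected <- sort(intersect(
        sets[[cn]], names(counts)[counts == 1L]
      ))
      expect_equal(ug[[cn]], expected)
    }
  }
})

test_that("pathway annotation groups by lookup with multi-mapping", {
  mapping <- data.frame(
    ec = c("1.1.1.1", "2.2.2.2", "2.2.2.2"),
    pathway = c("glycolysis", "glycolysis", "ppp")
  )
  out <- pathwayAnnotation(c("1.1.1.1", "2.2.2.2", "9.9.9.9"), mapping)
  expect_setequal(out$glycolysis, c("1.1.1.1", "2.2.2.2"))
  expect_equal(out$ppp, "2.2.2.2")
  expect_equal(out$unmapped, "9.9.9.9")
  empty <- pathwayAnnotation(c("1.1.1.1"), mapping[0, ])
  expect_equal(empty$unmapped, "1.1.1.1")
})

test_that("malformed pathway mapping rows are reported with line numbers", {
  f <- tempfile()
  writeLines(c("ec\tpathway", "1.1.1.1\tglycolysis", "brokenline"), f)
  expect_error(readPathwayMapping(f), "line 3")
  f2 <- tempfile()
  writeLines(c("ec\tpathway", "1.1.1.1\tglycolysis"), f2)
  expect_equal(nrow(readPathwayMapping(f2)), 1L)
})
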