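.exprMatrix <- function(m) {
  colnames(m) <- paste0("c_A_", seq_len(ncol(m)))
  m
}

test_that("hard-binned MI of a discrete joint matches the closed form", {
  # p(0,0) = p(1,1) = 0.5 encoded as two-level expression: MI = 1 bit
  x <- rep(c(0, 1), each = 20)
  m <- .exprMatrix(rbind(a = x, b = x, c = rep(c(0, 1), 20)))
  cfg <- clrConfig(miEstimator = "equal_width_bins", nBins = 2, splineOrder = 1)
  mi <- miMatrix(mutualInformationMatrix(m, cfg))
  expect_equal(mi["a", "b"], 1, tolerance = 1e-12)
  expect_equal(mi["a", "b"], oracleDiscreteMi(x, x), tolerance = 1e-12)
  expect_equal(mi["a", "c"], oracleDiscreteMi(x, rep(c(0, 1), 20)),
    tolerance = 1e-12
  )
})

test_that("a gene paired with its own copy attains its marginal entropy", {
  set.seed(4)
  x <- rnorm(200)
  m <- .exprMatrix(rbind(a = x, b = x, c = rnorm(200)))
  cfg <- clrConfig(miEstimator = "equal_width_bins", nBins = 10, splineOrder = 3)
  sc <- mutualInformationMatrix(m, cfg)
  mi <- miMatrix(sc)
  # I(X;X) = H(X): recompute the plug-in marginal entropy independently from
  # the same equal-width binning of the ranked profile
  u <- (rank(x) - 1) / (length(x) - 1)
  idx <- pmin(floor(u * 10) + 1, 10)
  p <- as.numeric(table(idx)) / length(x)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mi["a", "b"], h, tolerance = 1e-10)
  expect_gt(mi["a", "b"], mi["a", "c"])
})

test_that("MI under independence shrinks toward zero with sample size", {
  miBig <- miSmall <- numeric()
  for (seed in 1:50) {
    set.seed(seed)
    small <- .exprMatrix(rbind(a = runif(30), b = runif(30)))
    big <- .exprMatrix(rbind(a = runif(400), b = runif(400)))
    miSmall <- c(miSmall, miMatrix(mutualInformationMatrix(small))["a", "b"])
    miBig <- c(miBig, miMatrix(mutualInformationMatrix(big))["a", "b"])
  }
  expect_lt(mean(miBig), mean(miSmall)) # estimator bias decays with n
  expect_lt(mean(miBig), 0.05)
})

test_that("constant genes are excluded with a warning, not NaN-propagated", {
  set.seed(1)
  m <- .exprMatrix(rbind(a = rnorm(30), b = rep(5, 30), c = rnorm(30)))
  expect_warning(sc <- mutualInformationMatrix(m), "constant")
  expect_equal(sc@excluded, "b")
  expect_false(anyNA(miMatrix(sc)[upper.tri(miMatrix(sc))]))
})

test_that("CLR Z-scores match hand arithmetic on a 3x3 MI matrix", {
  mi <- matrix(
    c(
      NA, 0.8, 0.2,
      0.8, NA, 0.4,
      0.2, 0.4, NA
    ), 3, 3,
    byrow = TRUE, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  z <- clrZscores(mi, clrConfig(backgroundMode = "per_gene"))
  # row a: mean .5 sd sqrt(.18); row b: mean .6; row c: mean .3
  expect_equal(z["a", "b"], 1, tolerance = 1e-12)
  expect_equal(z["a", "c"], 0, tolerance = 1e-12)
  expect_equal(z["b", "c"], 1 / sqrt(2), tolerance = 1e-12)
})

test_that("flat MI background gives all-zero Z in both modes", {
  mi <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(mi) <- NA
  suppressMessages({
    zp <- clrZscores(mi, clrConfig(backgroundMode = "per_gene"))
    zg <- clrZscores(mi, clrConfig(backgroundMode = "global"))
  })
  expect_equal(max(abs(zp), na.rm = TRUE), 0)
  expect_equal(max(abs(zg), na.rm = TRUE), 0)
})

test_that("raising one pair's MI raises only that pair's global Z", {
  set.seed(7)
  base <- matrix(runif(25, 0.1, 0.5), 5, 5)
  base <- (base + t(base)) / 2
  dimnames(base) <- list(letters[1:5], letters[1:5])
  diag(base) <- NA
  bumped <- base
  bumped["a", "b"] <- bumped["b", "a"] <- base["a", "b"] + 0.2
  cfg <- clrConfig(backgroundMode = "global")
  z0 <- clrZscores(base, cfg)
  z1 <- clrZscores(bumped, cfg)
  # standardisation recentres everything, but the bumped pair's z moves up
  # relative to every other pair
  delta <- (z1 - z0)
  expect_gt(delta["a", "b"], max(delta[upper.tri(delta)][-1], na.rm = TRUE))
})

test_that("Z matrices are invariant to gene reordering", {
  cfg <- smallConfig(seed = 13)
  sim <- generateExpression(cfg, generateMasterNetwork(cfg))
  m <- SummarizedExperiment::assay(sim$expr)[1:25, ]
  perm <- sample(nrow(m))
  z1 <- zMatrix(clrZscores(mutualInformationMatrix(m)))
  z2 <- zMatrix(clrZscores(mutualInformationMatrix(m[perm, ])))
  expect_equal(z2[rownames(z1), colnames(z1)], z1, tolerance = 1e-12)
})

test_that("thresholding is inclusive and matches a brute-force count", {
  set.seed(21)
  z <- matrix(runif(100, 0, 6), 10, 10)
  z <- (z + t(z)) / 2
  dimnames(z) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
  diag(z) <- NA
  z["g01", "g02"] <- z["g02", "g01"] <- 4.2 # exact-threshold pair
  net <- thresholdNetwork(z, 4.2)
  e <- edgeTable(net)
  expect_true(any(e$from == "g01" & e$to == "g02")) # >= is inclusive
  expect_equal(nrow(e), sum(z[upper.tri(z)] >= 4.2, na.rm = TRUE))
  empty <- thresholdNetwork(z, 100)
  expect_length(networkNodes(empty), 0L)
})

test_that("top-k selection matches an independent sort and breaks ties fixedly", {
  set.seed(22)
  z <- matrix(runif(64, 0, 5), 8, 8)
  z <- (z + t(z)) / 2
  dimnames(z) <- list(letters[1:8], letters[1:8])
  diag(z) <- NA
  expect_error(topKNetwork(z, 0), "positive")
  expect_error(topKNetwork(z, 1000), "exceeds")
  one <- edgeTable(topKNetwork(z, 1))
  expect_equal(z[one$from, one$to], max(z, na.rm = TRUE))
  # independent sort oracle
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ut]
  o <- order(-vals)
  k <- 10
  topOracle <- sort(paste(
    pmin(letters[ut[o[1:k], 1]], letters[ut[o[1:k], 2]]),
    pmax(letters[ut[o[1:k], 1]], letters[ut[o[1:k], 2]])
  ))
  e <- edgeTable(topKNetwork(z, k))
  expect_equal(sort(paste(e$from, e$to)), topOracle)
  # all pairs -> complete graph
  expect_equal(nrow(edgeTable(topKNetwork(z, 28))), 28L)
  # threshold edges are a subset of top-k at the matching k
  t <- 3
  kThr <- sum(vals >= t)
  thrE <- edgeTable(thresholdNetwork(z, t))
  topE <- edgeTable(topKNetwork(z, kThr))
  expect_true(all(paste(thrE$from, thrE$to) %in% paste(topE$from, topE$to)))
})

test_that("largest component agrees with a BFS labelling oracle", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    nodes <- sprintf("g%02d", 1:n)
    ne <- sample(3:(2 * n), 1)
    e <- unique(data.frame(
      from = sample(nodes, ne, replace = TRUE),
      to = sample(nodes, ne, replace = TRUE)
    ))
    e <- e[e$from != e$to, ]
    if (!nrow(e)) next
    net <- geneNetwork(e)
    lab <- oracleComponents(networkNodes(net), edgeTable(net))
    sizes <- table(lab)
    expected <- names(lab)[lab %in% names(sizes)[sizes == max(sizes)]]
    main <- largestComponent(net)
    expect_true(all(networkNodes(main) %in% expected))
    expect_equal(
      length(networkNodes(main)), as.integer(max(sizes))
    )
  }
})

test_that("upper-tail probabilities are exact where closed forms exist", {
  expect_equal(zscoreToPvalue(0), 0.5)
  quad <- integrate(dnorm, 4.20, Inf, rel.tol = 1e-12)$value
  expect_equal(zscoreToPvalue(4.20), quad, tolerance = 1e-9)
  expect_lt(zscoreToPvalue(4.20), 5e-5)
  expect_equal(zscoreToPvalue(-1e6), 1)
})

test_that("power-law fit is exact on an exact log-log line and errors on regular graphs", {
  degrees <- rep(c(1L, 2L, 4L, 8L), c(64L, 16L, 4L, 1L)) # f(d) = 64 d^-2
  fit <- powerlawFit(degrees)
  expect_equal(fit$exponent, 2, tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
  expect_error(powerlawFit(rep(3L, 10)), "fewer than 3 distinct")
})

test_that("preferential-attachment networks fit a power law well", {
  r2 <- vapply(1:20, function(seed) {
    set.seed(seed)
    g <- igraph::sample_pa(1000, directed = FALSE)
    powerlawFit(as.integer(igraph::degree(g)))$r.squared
  }, numeric(1))
  expect_true(all(r2 > 0.8))
})
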