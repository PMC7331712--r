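# Per-gene bin membership weights for the plug-in MI estimator.
# "bspline": fuzzy membership over nBins B-spline basis functions of order
# splineOrder (each sample spreads mass over up to splineOrder bins; rows sum
# to one). "equal_width_bins": hard one-hot membership over equal-width bins.
.binWeights <- function(x, config) {
  n <- length(x)
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) stop("constant profile reached .binWeights")
  u <- (x - rng[1]) / (rng[2] - rng[1])
  M <- config@nBins
  if (config@miEstimator == "equal_width_bins") {
    idx <- pmin(floor(u * M) + 1L, M)
    W <- matrix(0, n, M)
    W[cbind(seq_len(n), idx)] <- 1
    return(W)
  }
  k <- config@splineOrder
  top <- M - k + 1L
  knots <- c(rep(0, k), seq_len(top - 1L), rep(top, k))
  z <- pmin(u * top, top - 1e-9)
  splines::splineDesign(knots, z, ord = k)
}

.plugInEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual-information matrix over gene pairs
#'
#' Plug-in mutual information (bits) for all gene pairs from fuzzy B-spline
#' bin memberships (the canonical CLR estimator) or hard equal-width binning.
#' Profiles are rank-transformed per gene first when
#' \code{config@rankTransform} is TRUE (default), stabilising the estimate
#' against outliers. Genes with zero variance are excluded with a warning
#' rather than propagating NaNs.
#'
#' All pairwise joint distributions are obtained in one cross-product of the
#' stacked weight matrices, so memory grows with (genes x bins)^2.
#'
#' @param expr SummarizedExperiment (assay 1, log2 scale) or numeric matrix,
#'   genes in rows; at least 3 samples.
#' @param config a \linkS4class{ClrConfig}.
#' @return A \linkS4class{CoexpressionScores} with the MI matrix filled and
#'   the Z matrix still empty (see \code{\link{clrZscores}}).
#' @export
mutualInformationMatrix <- function(expr, config = clrConfig()) {
  stopifnot(is(config, "ClrConfig"))
  validObject(config)
  m <- .assayMatrix(expr)
  if (ncol(m) < 3L) stop("need at least 3 samples to estimate MI")
  v <- apply(m, 1L, var)
  excluded <- rownames(m)[v <= 0]
  if (length(excluded)) {
    warning(
      length(excluded),
      " constant gene(s) excluded from MI estimation"
    )
    m <- m[v > 0, , drop = FALSE]
  }
  genes <- rownames(m)
  G <- length(genes)
  if (G < 2L) stop("fewer than 2 variable genes")
  n <- ncol(m)
  M <- config@nBins

  W <- matrix(0, n, G * M)
  for (i in seq_len(G)) {
    x <- m[i, ]
    if (config@rankTransform) x <- rank(x, ties.method = "average")
    W[, (i - 1L) * M + seq_len(M)] <- .binWeights(x, config)
  }
  marg <- colMeans(W)
  H <- vapply(seq_len(G), function(i) {
    .plugInEntropy(marg[(i - 1L) * M + seq_len(M)])
  }, numeric(1))

  P <- crossprod(W) / n
  Ep <- matrix(0, nrow(P), ncol(P))
  pos <- P > 0
  Ep[pos] <- P[pos] * log2(P[pos])
  blk <- matrix(0, G * M, G)
  blk[cbind(seq_len(G * M), rep(seq_len(G), each = M))] <- 1
  Hjoint <- -crossprod(blk, Ep %*% blk)

  mi <- outer(H, H, "+") - Hjoint
  mi <- pmax(mi, 0)
  mi <- (mi + t(mi)) / 2
  diag(mi) <- NA_real_
  dimnames(mi) <- list(genes, genes)

  new("CoexpressionScores",
    genes = genes, mi = mi,
    z = matrix(NA_real_, G, G, dimnames = list(genes, genes)),
    excluded = excluded, backgroundMode = config@backgroundMode
  )
}

#' CLR Z-scores from a mutual-information matrix
#'
#' \code{per_gene} (canonical CLR): each gene's off-diagonal MI row is its
#' background; z_i(j) = max(0, (MI_ij - mean_i) / sd_i) and the pair score is
#' Z_ij = sqrt(z_i(j)^2 + z_j(i)^2). \code{global}: every score is
#' standardised against the mean and sd of all off-diagonal MI values, the
#' whole-matrix reading of a cutoff "standard deviations above the mean of
#' all mutual information scores".
#'
#' @param scores a \linkS4class{CoexpressionScores} (or plain symmetric MI
#'   matrix with NA diagonal).
#' @param config a \linkS4class{ClrConfig}; \code{backgroundMode} selects the
#'   standardisation.
#' @return The \linkS4class{CoexpressionScores} with the Z matrix filled (a
#'   plain matrix input returns the Z matrix directly).
#' @export
clrZscores <- function(scores, config = clrConfig()) {
  stopifnot(is(config, "ClrConfig"))
  mi <- if (is(scores, "CoexpressionScores")) miMatrix(scores) else scores
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  if (config@backgroundMode == "per_gene") {
    mu <- rowMeans(mi, na.rm = TRUE)
    sdv <- apply(mi, 1L, sd, na.rm = TRUE)
    zero <- sdv <= 0 | !is.finite(sdv)
    if (any(zero)) {
      message(
        sum(zero), " gene background(s) with zero sd; ",
        "their z contributions set to 0"
      )
      sdv[zero] <- Inf
    }
    zrow <- pmax((mi - mu) / sdv, 0)
    z <- sqrt(zrow^2 + t(zrow)^2)
  } else {
    off <- mi[row(mi) != col(mi)]
    mu <- mean(off, na.rm = TRUE)
    sg <- sd(off, na.rm = TRUE)
    if (!is.finite(sg) || sg <= 0) {
      message("flat global background; all Z set to 0")
      z <- matrix(0, nrow(mi), ncol(mi))
    } else {
      z <- (mi - mu) / sg
    }
  }
  diag(z) <- NA_real_
  dimnames(z) <- dimnames(mi)
  if (is(scores, "CoexpressionScores")) {
    scores@z <- z
    scores@backgroundMode <- config@backgroundMode
    scores
  } else {
    z
  }
}

.zInput <- function(z) {
  if (is(z, "CoexpressionScores")) z <- zMatrix(z)
  stopifnot(is.matrix(z), nrow(z) == ncol(z), !is.null(rownames(z)))
  z
}

.pairTable <- function(z) {
  ut <- which(upper.tri(z), arr.ind = TRUE)
  g <- rownames(z)
  a <- g[ut[, 1L]]
  b <- g[ut[, 2L]]
  data.frame(
    from = pmin(a, b), to = pmax(a, b), z = z[ut],
    stringsAsFactors = FALSE
  )
}

#' Threshold a Z matrix into an unweighted network
#'
#' An edge joins genes i and j iff Z_ij >= \code{zThreshold} (inclusive).
#'
#' @param z Z matrix or \linkS4class{CoexpressionScores}.
#' @param zThreshold the cutoff (default 4.20).
#' @return A \linkS4class{GeneNetwork}; genes with no retained edge are
#'   dropped and counted in \code{provenance$isolatedDropped}.
#' @export
thresholdNetwork <- function(z, zThreshold = 4.20) {
  z <- .zInput(z)
  pairs <- .pairTable(z)
  keep <- !is.na(pairs$z) & pairs$z >= zThreshold
  .geneNetwork(
    pairs[keep, c("from", "to")],
    provenance = list(
      method = "threshold", zThreshold = zThreshold,
      isolatedDropped = nrow(z) - length(unique(c(
        pairs$from[keep], pairs$to[keep]
      )))
    )
  )
}

#' Top-k network from a Z matrix
#'
#' The k highest-Z gene pairs become edges; ties at the boundary are broken
#' lexicographically by the sorted gene-id pair, so the network is
#' bit-reproducible.
#'
#' @param z Z matrix or \linkS4class{CoexpressionScores}.
#' @param k number of edges to retain (1 <= k <= number of gene pairs).
#' @return A \linkS4class{GeneNetwork}.
#' @export
topKNetwork <- function(z, k) {
  z <- .zInput(z)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("k must be a positive count")
  }
  k <- as.integer(k)
  pairs <- .pairTable(z)
  pairs <- pairs[!is.na(pairs$z), , drop = FALSE]
  if (k > nrow(pairs)) stop("k exceeds the number of gene pairs")
  o <- order(-pairs$z, pairs$from, pairs$to)
  .geneNetwork(
    pairs[o[seq_len(k)], c("from", "to")],
    provenance = list(method = "top_k", k = k)
  )
}

#' Largest connected component of a gene network
#'
#' The main connected cluster, the component on which centrality analysis is
#' run. A size tie is broken in favour of the component containing the
#' lexicographically smallest gene id.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return A \linkS4class{GeneNetwork} induced on the largest component.
#' @export
largestComponent <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  if (!length(net@nodes)) {
    warning("empty network; returning it unchanged")
    return(net)
  }
  g <- asIgraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    firstNode <- vapply(cand, function(ci) {
      min(names(comp$membership)[comp$membership == ci])
    }, character(1))
    cand <- cand[order(firstNode)[1L]]
  }
  keep <- names(comp$membership)[comp$membership == cand]
  e <- net@edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  prov <- net@provenance
  prov$largestComponentOf <- length(net@nodes)
  .geneNetwork(e, provenance = prov)
}

#' Upper-tail standard-normal probability of a Z-score
#'
#' P(Z >= z) for standard normal Z, computed on the complementary tail so it
#' stays accurate for large z.
#'
#' @param z numeric vector of Z-scores.
#' @return Upper-tail probabilities in [0, 1].
#' @examples
#' zscoreToPvalue(4.20) # ~1.3e-5
#' @export
zscoreToPvalue <- function(z) {
  stopifnot(is.numeric(z))
  pnorm(z, lower.tail = FALSE)
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line on (log10 degree, log10 frequency) over degrees with
#' nonzero frequency; the slope estimates the negative power-law exponent and
#' R-squared summarises scale-free structure.
#'
#' @param net a \linkS4class{GeneNetwork} (or an integer degree vector).
#' @return list with \code{exponent} (positive for a decaying law),
#'   \code{r.squared}, and the underlying \code{data.frame}.
#' @export
powerlawFit <- function(net) {
  deg <- if (is(net, "GeneNetwork")) {
    e <- net@edges
    as.integer(table(factor(c(e$from, e$to), levels = net@nodes)))
  } else {
    as.integer(net)
  }
  tab <- table(deg[deg > 0])
  if (length(tab) < 3L) {
    stop("degree distribution has fewer than 3 distinct degrees; fit undefined")
  }
  df <- data.frame(
    degree = as.integer(names(tab)),
    frequency = as.integer(tab)
  )
  fit <- lm(log10(frequency) ~ log10(degree), data = df)
  list(
    exponent = -unname(coef(fit)[2L]),
    r.squared = suppressWarnings(summary(fit)$r.squared),
    data = df
  )
}
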