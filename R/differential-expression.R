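.groupColumns <- function(expr, condition, control) {
  if (!is(expr, "SummarizedExperiment")) {
    stop("expression must be a SummarizedExperiment with a 'condition' column")
  }
  cond <- SummarizedExperiment::colData(expr)$condition
  if (is.null(cond)) stop("colData needs a 'condition' column")
  for (lab in c(condition, control)) {
    if (!lab %in% cond) stop("unknown condition label: ", lab)
  }
  list(
    treat = which(cond == condition),
    ctrl = which(cond == control)
  )
}

#' Per-gene log2 fold changes between a condition and its control
#'
#' The difference of group means on the log2 scale; swapping the groups
#' negates the result.
#'
#' @param expr a SummarizedExperiment with log2-scale expression in assay 1
#'   and a \code{condition} column in its colData.
#' @param condition,control condition labels of the two groups.
#' @return Named numeric vector of log2 fold changes (condition - control).
#' @export
log2FoldChanges <- function(expr, condition, control) {
  idx <- .groupColumns(expr, condition, control)
  m <- .assayMatrix(expr)
  rowMeans(m[, idx$treat, drop = FALSE]) -
    rowMeans(m[, idx$ctrl, drop = FALSE])
}

#' Welch two-sample test per gene
#'
#' Welch t-test on log2 values, robust to unequal group variances. Degenerate
#' cases follow documented conventions: fewer than two replicates in either
#' group gives p = 1 with an insufficient-replication flag; zero within-group
#' variance is floored at 1e-12, so two groups that are exactly constant and
#' equal give p = 1 while constant unequal groups give a vanishing p.
#'
#' @inheritParams log2FoldChanges
#' @return data.frame with columns \code{gene}, \code{p},
#'   \code{insufficientReplication}.
#' @export
testDifferential <- function(expr, condition, control) {
  idx <- .groupColumns(expr, condition, control)
  m <- .assayMatrix(expr)
  x <- m[, idx$treat, drop = FALSE]
  y <- m[, idx$ctrl, drop = FALSE]
  n1 <- ncol(x)
  n2 <- ncol(y)
  genes <- rownames(m)
  if (n1 < 2L || n2 < 2L) {
    return(data.frame(
      gene = genes, p = rep(1, length(genes)),
      insufficientReplication = TRUE, stringsAsFactors = FALSE
    ))
  }
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- pmax(apply(x, 1L, var), 1e-12)
  v2 <- pmax(apply(y, 1L, var), 1e-12)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(
    gene = genes, p = pmin(p, 1),
    insufficientReplication = FALSE, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validated wrapper over \code{\link[stats]{p.adjust}}: monotone step-up
#' values in [0, 1], order-preserving.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param method adjustment method (default "BH").
#' @return Adjusted p-values, same length and names as \code{p}.
#' @export
adjustPvalues <- function(p, method = "BH") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = method)
}

#' Run the full per-condition over-expression analysis
#'
#' @inheritParams log2FoldChanges
#' @param config a \linkS4class{DifferentialConfig}.
#' @return data.frame with columns gene, log2fc, p, q,
#'   insufficientReplication, overExpressed; the config is attached as the
#'   \code{"config"} attribute so the flags are reproducible from the table.
#' @examples
#' cfg <- syntheticConfig(seed = 3, nGenes = 120)
#' sim <- generateExpression(cfg, generateMasterNetwork(cfg))
#' res <- differentialExpression(sim$expr, "dry", "control")
#' head(res[res$overExpressed, ])
#' @export
differentialExpression <- function(expr, condition, control,
                                   config = differentialConfig()) {
  stopifnot(is(config, "DifferentialConfig"))
  validObject(config)
  lfc <- log2FoldChanges(expr, condition, control)
  tst <- testDifferential(expr, condition, control)
  q <- adjustPvalues(tst$p, method = config@adjustment)
  res <- data.frame(
    gene = tst$gene, log2fc = unname(lfc[tst$gene]), p = tst$p, q = q,
    insufficientReplication = tst$insufficientReplication,
    stringsAsFactors = FALSE
  )
  res$overExpressed <- res$log2fc >= log2(config@fcThreshold) &
    res$q <= config@qThreshold & !res$insufficientReplication
  attr(res, "config") <- config
  res
}

#' Over-expressed gene set from a differential result
#'
#' Thresholds are inclusive: a gene is called when log2FC >=
#' log2(fcThreshold) and adjusted p <= qThreshold.
#'
#' @param result output of \code{\link{differentialExpression}} (or any
#'   data.frame with gene/log2fc/q columns).
#' @param config a \linkS4class{DifferentialConfig}.
#' @return Sorted character vector of over-expressed gene ids.
#' @export
callOverexpressed <- function(result, config = differentialConfig()) {
  stopifnot(is(config, "DifferentialConfig"))
  validObject(config)
  keep <- result$log2fc >= log2(config@fcThreshold) &
    result$q <= config@qThreshold
  if (!is.null(result$insufficientReplication)) {
    keep <- keep & !result$insufficientReplication
  }
  sort(result$gene[keep])
}
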