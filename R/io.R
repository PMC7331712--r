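#' Read and write pipeline file formats
#'
#' Plain-text interchange used across the pipeline: expression TSV (genes in
#' rows, sample columns named \code{<condition>_<site>_<replicate>}),
#' metabolite lists (columns condition, metabolite_id), a reaction table
#' (reaction_id plus \code{;}-joined substrates, products and ec_numbers),
#' SIF and GraphML network exports, and a two-column EC-to-pathway mapping.
#'
#' @param path file path.
#' @param expr,network,net,detections,truth objects to serialise.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeExpression <- function(expr, path) {
  m <- .assayMatrix(expr)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene") stop("expression TSV must start with 'gene'")
  if (anyDuplicated(df$gene)) {
    stop(
      "duplicated gene row(s): ",
      paste(unique(df$gene[duplicated(df$gene)]), collapse = ", ")
    )
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("sample columns must be named <condition>_<site>_<replicate>")
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = m),
    colData = S4Vectors::DataFrame(
      condition = vapply(parts, `[`, "", 1L),
      site = vapply(parts, `[`, "", 2L),
      replicate = as.integer(vapply(parts, `[`, "", 3L)),
      row.names = colnames(m)
    )
  )
}

#' @rdname pipeline-io
#' @export
writeMetaboliteLists <- function(detections, path) {
  df <- data.frame(
    condition = rep(names(detections), lengths(detections)),
    metabolite_id = unlist(detections, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readMetaboliteLists <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "metabolite_id") %in% names(df))) {
    stop("metabolite TSV needs 'condition' and 'metabolite_id' columns")
  }
  lapply(split(df$metabolite_id, df$condition), function(x) sort(unique(x)))
}

#' @rdname pipeline-io
#' @export
writeReactionTable <- function(network, path) {
  stopifnot(is(network, "MetabolicNetwork"))
  join <- function(l) vapply(l, paste, "", collapse = ";")
  df <- data.frame(
    reaction_id = network@reactions,
    substrates = join(network@substrates),
    products = join(network@products),
    ec_numbers = join(network@ec)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readReactionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "substrates", "products", "ec_numbers")
  if (!all(need %in% names(df))) {
    stop("reaction TSV needs columns: ", paste(need, collapse = ", "))
  }
  splitCol <- function(x) strsplit(x, ";", fixed = TRUE)
  subs <- splitCol(df$substrates)
  prods <- splitCol(df$products)
  metabolicNetwork(
    metabolites = sort(unique(unlist(c(subs, prods), use.names = FALSE))),
    reactions = df$reaction_id,
    substrates = subs, products = prods, ec = splitCol(df$ec_numbers)
  )
}

#' @rdname pipeline-io
#' @param interactionFor named interaction labels per edge role (SIF column 2).
#' @export
writeSif <- function(net, path,
                     interactionFor = c(
                       substrate = "substrate-of", product = "product-of",
                       coexpression = "coexpressed"
                     )) {
  if (is(net, "MetabolicNetwork")) {
    e <- edgeTable(net)
    df <- data.frame(
      a = e$metabolite,
      interaction = unname(interactionFor[e$role]),
      b = e$reaction
    )
  } else if (is(net, "GeneNetwork") || is(net, "SubnetworkResult")) {
    e <- edgeTable(net)
    lab <- if (is(net, "GeneNetwork")) {
      interactionFor[["coexpression"]]
    } else {
      "reaction-edge"
    }
    df <- data.frame(a = e$from, interaction = lab, b = e$to)
  } else {
    stop("unsupported object for SIF export")
  }
  write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname pipeline-io
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
writeEdgeTable <- function(net, path) {
  write.table(edgeTable(net), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname pipeline-io
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "PlantedTruth"))
  mm <- truth@moduleMembership
  jsonlite::write_json(
    list(
      moduleMembership = as.list(mm[!is.na(mm)]),
      responsiveGenes = truth@responsiveGenes,
      terminalMetabolites = truth@terminalMetabolites,
      plantedReactions = truth@plantedReactions
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read an EC-to-pathway mapping table
#'
#' Two tab-separated columns, \code{ec} and \code{pathway}; a malformed row
#' raises a parse error naming its line number.
#'
#' @param path file path.
#' @return data.frame with columns \code{ec}, \code{pathway}.
#' @export
readPathwayMapping <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(ec = character(), pathway = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("malformed mapping row at line ", bad[1L], ": ", lines[bad[1L]])
  }
  hasHeader <- identical(tolower(fields[[1L]]), c("ec", "pathway"))
  if (hasHeader) fields <- fields[-1L]
  data.frame(
    ec = vapply(fields, `[`, "", 1L),
    pathway = vapply(fields, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}
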