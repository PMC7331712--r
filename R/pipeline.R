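.subsetSite <- function(expr, site) {
  keep <- SummarizedExperiment::colData(expr)$site == site
  expr[, keep]
}

#' Validate a trio of pipeline input files
#'
#' Schema checks for the expression, metabolite and reaction tables: required
#' columns, duplicated gene rows (error level, with the row number), EC-id
#' syntax of gene identifiers, and cross-references (metabolite ids that are
#' absent from the reaction network are warning-level issues naming the id).
#'
#' @param paths named list with elements \code{expression},
#'   \code{metabolites}, \code{reactions}.
#' @return data.frame with columns \code{level} ("error"/"warning") and
#'   \code{message}; zero rows for a well-formed trio.
#' @export
validateInputs <- function(paths) {
  issues <- data.frame(level = character(), message = character())
  note <- function(level, message) {
    issues <<- rbind(issues, data.frame(level = level, message = message))
  }
  need <- c("expression", "metabolites", "reactions")
  for (nm in need) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      stop("unreadable or missing ", nm, " file: ", if (is.null(p)) "<unset>" else p)
    }
  }
  exprDf <- read.delim(paths$expression,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (names(exprDf)[1L] != "gene") {
    note("error", "expression: first column must be 'gene'")
  } else {
    dup <- which(duplicated(exprDf$gene))
    for (d in dup) {
      note("error", sprintf(
        "expression: duplicated gene '%s' at row %d", exprDf$gene[d], d
      ))
    }
    badEc <- !grepl("^\\d+(\\.\\d+){3}$", exprDf$gene)
    if (any(badEc)) {
      note("warning", sprintf(
        "expression: %d gene id(s) not in EC a.b.c.d syntax (e.g. '%s')",
        sum(badEc), exprDf$gene[which(badEc)[1L]]
      ))
    }
  }
  net <- tryCatch(readReactionTable(paths$reactions), error = function(e) {
    note("error", paste("reactions:", conditionMessage(e)))
    NULL
  })
  mets <- tryCatch(readMetaboliteLists(paths$metabolites), error = function(e) {
    note("error", paste("metabolites:", conditionMessage(e)))
    NULL
  })
  if (!is.null(net) && !is.null(mets)) {
    unknown <- setdiff(unlist(mets, use.names = FALSE), metabolites(net))
    for (u in unknown) {
      note("warning", sprintf(
        "metabolites: id '%s' is absent from the reaction network", u
      ))
    }
  }
  rownames(issues) <- NULL
  issues
}

.writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(path)
}

#' Run the five-stage analysis end to end
#'
#' Sequences simulate (optional) -> over-expression calling -> metabolic
#' integration -> CLR network inference -> centrality analysis, writing every
#' stage's outputs under \code{outputDir} and a run manifest
#' (\code{manifest.json}) last. The manifest echoes the configuration, hashes
#' every output file, and records stage timings, warnings and the package
#' version; re-running with the same configuration reproduces identical
#' output hashes. A stage failure keeps partial outputs and records the
#' failure point in the manifest.
#'
#' @param synthetic a \linkS4class{SyntheticConfig} to simulate inputs, or
#'   NULL to read real inputs from \code{inputs}.
#' @param inputs named list of paths (expression, metabolites, reactions)
#'   when \code{synthetic} is NULL.
#' @param outputDir output directory (created if needed).
#' @param control baseline condition label.
#' @param differential a \linkS4class{DifferentialConfig}.
#' @param clr a \linkS4class{ClrConfig}; \code{targetEdges} (when set)
#'   selects the top-k network, otherwise the Z threshold is applied.
#' @param seed optional integer overriding the synthetic config's seed.
#' @return The manifest, invisibly (a list; element \code{failedStage} is
#'   non-NULL if a stage failed).
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "mpn-run")
#' man <- runPipeline(syntheticConfig(seed = 11, nGenes = 120),
#'   outputDir = out,
#'   clr = clrConfig(targetEdges = 150)
#' )
#' names(man$stages)
#' }
#' @export
runPipeline <- function(synthetic = NULL, inputs = NULL, outputDir,
                        control = "control",
                        differential = differentialConfig(),
                        clr = clrConfig(), seed = NULL) {
  if (is.null(synthetic) && is.null(inputs)) {
    stop("either a synthetic config or real input paths must be given")
  }
  if (!is.null(synthetic) && !is.null(inputs)) {
    stop("give either a synthetic config or input paths, not both")
  }
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(synthetic)) {
    stopifnot(is(synthetic, "SyntheticConfig"))
    if (!is.null(seed)) synthetic@seed <- as.integer(seed)
    validObject(synthetic)
  }
  manifest <- list(
    package = "metaphenet",
    version = as.character(packageVersion("metaphenet")),
    seed = if (!is.null(synthetic)) synthetic@seed else seed,
    config = list(
      synthetic = if (!is.null(synthetic)) {
        sl <- slotNames(synthetic)
        stats::setNames(lapply(sl, function(s) slot(synthetic, s)), sl)
      },
      inputs = inputs,
      control = control,
      differential = list(
        fcThreshold = differential@fcThreshold,
        qThreshold = differential@qThreshold,
        test = differential@test, adjustment = differential@adjustment
      ),
      clr = list(
        miEstimator = clr@miEstimator, nBins = clr@nBins,
        splineOrder = clr@splineOrder, backgroundMode = clr@backgroundMode,
        zThreshold = clr@zThreshold,
        targetEdges = if (is.na(clr@targetEdges)) NULL else clr@targetEdges,
        rankTransform = clr@rankTransform
      )
    ),
    stages = list(), timings = list(), warnings = list(),
    failedStage = NULL
  )
  warned <- character()
  out <- function(...) file.path(outputDir, paste0(...))
  finish <- function() {
    files <- sort(setdiff(list.files(outputDir), "manifest.json"))
    manifest$hashes <- as.list(stats::setNames(
      unname(tools::md5sum(file.path(outputDir, files))), files
    ))
    manifest$warnings <- as.list(warned)
    .writeManifest(manifest, out("manifest.json"))
    manifest
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warned <<- c(warned, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      manifest$failedStage <<- list(
        stage = name,
        message = conditionMessage(res)
      )
      NULL
    } else {
      manifest$stages[[name]] <<- res$summary
      res$value
    }
  }

  # stage 1: simulate or load
  st1 <- runStage("simulate", function() {
    if (!is.null(synthetic)) {
      network <- generateMasterNetwork(synthetic)
      sim <- generateExpression(synthetic, network)
      detections <- generateMetaboliteDetections(network, sim$truth, synthetic)
      writeReactionTable(network, out("reactions.tsv"))
      writeExpression(sim$expr, out("expression.tsv"))
      writeMetaboliteLists(detections, out("metabolites.tsv"))
      writeTruth(sim$truth, out("truth.json"))
      list(
        value = list(expr = sim$expr, network = network, detections = detections),
        summary = list(
          genes = nrow(sim$expr), samples = ncol(sim$expr),
          metabolites = length(metabolites(network)),
          reactions = length(reactions(network))
        )
      )
    } else {
      expr <- readExpression(inputs$expression)
      network <- readReactionTable(inputs$reactions)
      detections <- readMetaboliteLists(inputs$metabolites)
      list(
        value = list(expr = expr, network = network, detections = detections),
        summary = list(genes = nrow(expr), samples = ncol(expr))
      )
    }
  })
  if (is.null(st1)) {
    return(invisible(finish()))
  }
  expr <- st1$expr
  network <- st1$network
  detections <- st1$detections
  conditions <- unique(SummarizedExperiment::colData(expr)$condition)
  if (!control %in% conditions) {
    manifest$failedStage <- list(
      stage = "differential",
      message = paste("control condition absent:", control)
    )
    return(invisible(finish()))
  }
  treatments <- setdiff(conditions, control)
  sites <- unique(SummarizedExperiment::colData(expr)$site)

  # stage 2: over-expression per condition (all sites pooled, written out)
  st2 <- runStage("differential", function() {
    res <- lapply(treatments, function(cond) {
      de <- differentialExpression(expr, cond, control, differential)
      de$flag <- de$overExpressed
      write.table(
        de[, c("gene", "log2fc", "p", "q", "flag")],
        out("differential_", cond, ".tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      de
    })
    names(res) <- treatments
    list(
      value = res,
      summary = lapply(res, function(d) sum(d$overExpressed))
    )
  })
  if (is.null(st2)) {
    return(invisible(finish()))
  }

  # stage 3: metabolic integration per condition x site
  st3 <- runStage("integrate", function() {
    results <- list()
    for (cond in treatments) {
      for (s in sites) {
        de <- differentialExpression(
          .subsetSite(expr, s), cond, control, differential
        )
        terms <- buildTerminals(
          network, detections[[cond]],
          callOverexpressed(de, differential)
        )
        results[[paste(cond, s, sep = "_")]] <-
          minimalSubnetwork(network, terms, condition = cond, site = s)
      }
    }
    # control subnetworks anchor the uniqueness call: genes reachable from
    # the shared metabolite core alone are not condition-specific
    for (s in sites) {
      terms <- buildTerminals(network, detections[[control]], character())
      results[[paste(control, s, sep = "_")]] <-
        minimalSubnetwork(network, terms, condition = control, site = s)
    }
    tab <- conditionGeneSets(results)
    write.table(tab, out("condition_genes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    for (cond in treatments) {
      first <- results[[paste(cond, sites[1L], sep = "_")]]
      writeSif(first, out("subnetwork_", cond, "_", sites[1L], ".sif"))
    }
    list(
      value = list(table = tab, unique = uniqueGenes(tab)),
      summary = lapply(
        uniqueGenes(tab)[treatments],
        length
      )
    )
  })
  if (is.null(st3)) {
    return(invisible(finish()))
  }

  # stage 4: CLR co-expression network
  st4 <- runStage("network", function() {
    scores <- mutualInformationMatrix(expr, clr)
    scores <- clrZscores(scores, clr)
    net <- if (!is.na(clr@targetEdges)) {
      topKNetwork(scores, clr@targetEdges)
    } else {
      thresholdNetwork(scores, clr@zThreshold)
    }
    main <- largestComponent(net)
    pl <- tryCatch(powerlawFit(main), error = function(e) NULL)
    writeEdgeTable(net, out("network_edges.tsv"))
    writeSif(net, out("network.sif"))
    writeGraphML(net, out("network.graphml"))
    summaryJson <- list(
      nodes = length(networkNodes(net)),
      edges = nrow(edgeTable(net)),
      mainComponentNodes = length(networkNodes(main)),
      mainComponentEdges = nrow(edgeTable(main)),
      powerLawExponent = if (!is.null(pl)) pl$exponent else NA,
      powerLawR2 = if (!is.null(pl)) pl$r.squared else NA
    )
    jsonlite::write_json(summaryJson, out("network_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    list(value = list(net = net, main = main), summary = summaryJson)
  })
  if (is.null(st4)) {
    return(invisible(finish()))
  }

  # stage 5: centrality of condition-specific genes
  st5 <- runStage("centrality", function() {
    main <- st4$main
    labels <- st3$unique[treatments]
    cent <- computeCentralities(main, labels = labels)
    write.table(cent, out("centrality.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    gs <- groupSummary(cent, labels)
    write.table(gs, out("group_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    rt <- ratioToMedian(cent)
    write.table(rt, out("centrality_ratios.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    for (cond in treatments) {
      seeds <- intersect(labels[[cond]], networkNodes(main))
      if (length(seeds)) {
        nb <- neighborhoodSubnetwork(main, seeds, dropIsolatedSeeds = TRUE)
        if (nrow(nb$edges)) {
          writeSif(
            geneNetwork(nb$edges, provenance = list(method = "neighborhood")),
            out("neighborhood_", cond, ".sif")
          )
        }
      }
    }
    list(
      value = list(centrality = cent, groups = gs),
      summary = list(
        nodes = nrow(cent),
        meanBetweenness = mean(cent$betweenness),
        meanDegree = mean(cent$degree)
      )
    )
  })
  invisible(finish())
}
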