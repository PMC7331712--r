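# Deterministic planted layout shared by all generators.
#
# The master network is built around a hub metabolite (the common currency
# metabolite of the simulated community): every core metabolite is linked to
# the hub by a dedicated linker reaction, and each non-control condition gets
# a chain of reactions walking away from the hub. The chain reactions carry
# unique EC labels (the planted responsive genes) and the chain metabolites
# are the planted condition-specific terminals. Remaining reactions and
# metabolites form random pendant background structure; background reactions
# never connect two infrastructure nodes, so planted shortest paths are
# unique and minimal-subnetwork recovery of the planted pathways is exact in
# the noiseless limit.
.plantedLayout <- function(config) {
  treat <- setdiff(config@conditions, config@control)
  nCore <- config@nCoreMetabolites
  nResp <- config@nResponsivePerCondition
  nChain <- length(treat) * nResp

  metIds <- sprintf("M%05d", seq_len(config@nMetabolites))
  rxnIds <- sprintf("R%05d", seq_len(config@nReactions))

  hub <- metIds[1L]
  coreMet <- if (nCore > 0L) metIds[1L + seq_len(nCore)] else character()
  chainMet <- list()
  idx <- 1L + nCore
  for (cond in treat) {
    chainMet[[cond]] <- if (nResp > 0L) metIds[idx + seq_len(nResp)] else character()
    idx <- idx + nResp
  }
  backgroundMet <- if (idx < config@nMetabolites) {
    metIds[(idx + 1L):config@nMetabolites]
  } else {
    character()
  }

  linkerRxn <- if (nCore > 0L) rxnIds[seq_len(nCore)] else character()
  chainRxn <- list()
  idx <- nCore
  for (cond in treat) {
    chainRxn[[cond]] <- if (nResp > 0L) rxnIds[idx + seq_len(nResp)] else character()
    idx <- idx + nResp
  }
  backgroundRxn <- if (idx < config@nReactions) {
    rxnIds[(idx + 1L):config@nReactions]
  } else {
    character()
  }

  .withSeed(.deriveSeed(config@seed, "layout"), {
    pool <- .randomEcIds(config@nReactions)
    chainEC <- list()
    if (nChain > 0L) {
      take <- pool[seq_len(nChain)]
      k <- 0L
      for (cond in treat) {
        chainEC[[cond]] <- take[k + seq_len(nResp)]
        k <- k + nResp
      }
      otherPool <- pool[(nChain + 1L):length(pool)]
    } else {
      otherPool <- pool
    }
    otherRxn <- c(linkerRxn, backgroundRxn)
    otherEC <- list()
    if (length(otherRxn)) {
      primary <- sample(otherPool, length(otherRxn), replace = TRUE)
      second <- runif(length(otherRxn)) < 0.1
      otherEC <- lapply(seq_along(otherRxn), function(i) {
        if (second[i]) {
          unique(c(primary[i], sample(otherPool, 1L)))
        } else {
          primary[i]
        }
      })
      names(otherEC) <- otherRxn
    }
    list(
      treatments = treat, hub = hub, coreMet = coreMet, chainMet = chainMet,
      backgroundMet = backgroundMet, linkerRxn = linkerRxn,
      chainRxn = chainRxn, backgroundRxn = backgroundRxn,
      chainEC = chainEC, otherEC = otherEC
    )
  })
}

#' Generate the synthetic master metabolic network
#'
#' Builds a connected bipartite metabolite-reaction network emulating a
#' curated biochemical reaction map: a hub metabolite joined to a core of
#' commonly detected metabolites via linker reactions, one planted reaction
#' chain per non-control condition (each chain reaction carrying a unique EC
#' label), and random background reactions whose products hang off the rest
#' of the graph as pendant structure. Output is a pure function of
#' \code{config}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A validated \linkS4class{MetabolicNetwork}.
#' @examples
#' net <- generateMasterNetwork(syntheticConfig(seed = 7))
#' net
#' @export
generateMasterNetwork <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  lay <- .plantedLayout(config)

  rxn <- character()
  subs <- list()
  prods <- list()
  ecs <- list()
  addRxn <- function(id, s, p, e) {
    rxn[[length(rxn) + 1L]] <<- id
    subs[[length(subs) + 1L]] <<- s
    prods[[length(prods) + 1L]] <<- p
    ecs[[length(ecs) + 1L]] <<- e
  }

  for (i in seq_along(lay$linkerRxn)) {
    addRxn(
      lay$linkerRxn[i], lay$hub, lay$coreMet[i],
      lay$otherEC[[lay$linkerRxn[i]]]
    )
  }
  for (cond in lay$treatments) {
    mets <- lay$chainMet[[cond]]
    rids <- lay$chainRxn[[cond]]
    for (k in seq_along(rids)) {
      from <- if (k == 1L) lay$hub else mets[k - 1L]
      addRxn(rids[k], from, mets[k], lay$chainEC[[cond]][k])
    }
  }

  infraMet <- c(
    lay$hub, lay$coreMet,
    unlist(lay$chainMet, use.names = FALSE)
  )
  .withSeed(.deriveSeed(config@seed, "network"), {
    attached <- infraMet
    unattached <- lay$backgroundMet
    lambda <- config@meanReactionDegree / 2 - 1
    bgProducts <- vector("list", length(lay$backgroundRxn))
    bgSubstrates <- vector("list", length(lay$backgroundRxn))
    for (i in seq_along(lay$backgroundRxn)) {
      nSub <- 1L + rpois(1L, lambda)
      nProd <- 1L + rpois(1L, lambda)
      s1 <- if (length(attached) == 1L) attached else sample(attached, 1L)
      # slots beyond the anchoring substrate stay inside the background pool,
      # so background never shortcuts two infrastructure nodes
      bgPool <- setdiff(lay$backgroundMet, s1)
      extraSub <- character()
      if (nSub > 1L && length(bgPool)) {
        extraSub <- sample(bgPool, min(nSub - 1L, length(bgPool)))
      }
      prod <- character()
      for (j in seq_len(nProd)) {
        fresh <- setdiff(unattached, c(s1, extraSub, prod))
        cand <- if (length(fresh)) {
          fresh
        } else {
          setdiff(bgPool, c(prod, extraSub))
        }
        if (!length(cand)) cand <- setdiff(attached, c(s1, prod))
        if (!length(cand)) break
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        prod <- c(prod, pick)
        unattached <- setdiff(unattached, pick)
      }
      if (!length(prod)) prod <- s1 # degenerate single-metabolite fallback
      bgSubstrates[[i]] <- c(s1, extraSub)
      bgProducts[[i]] <- prod
      attached <- unique(c(attached, s1, extraSub, prod))
      unattached <- setdiff(unattached, c(extraSub))
    }
    # any background metabolite never drawn becomes an extra product of a
    # cyclically chosen reaction so the map covers every metabolite
    if (length(unattached)) {
      targets <- if (length(lay$backgroundRxn)) {
        seq_along(lay$backgroundRxn)
      } else {
        integer()
      }
      for (j in seq_along(unattached)) {
        if (length(targets)) {
          k <- targets[((j - 1L) %% length(targets)) + 1L]
          bgProducts[[k]] <- unique(c(bgProducts[[k]], unattached[j]))
        }
      }
    }
    for (i in seq_along(lay$backgroundRxn)) {
      addRxn(
        lay$backgroundRxn[i], bgSubstrates[[i]], bgProducts[[i]],
        lay$otherEC[[lay$backgroundRxn[i]]]
      )
    }
  })

  metabolicNetwork(
    metabolites = sprintf("M%05d", seq_len(config@nMetabolites)),
    reactions = rxn, substrates = subs, products = prods, ec = ecs
  )
}

#' Generate the synthetic expression matrix with planted ground truth
#'
#' Gene identifiers are the EC annotations of the master network plus
#' EC-style fillers up to \code{nGenes}. Baseline log2 abundance is drawn
#' normal (mean 6, sd 1), matching the skewed linear-scale abundances of
#' community transcriptomes. Genes of a planted module share a latent factor
#' with weight \code{latentStrength}; planted responsive genes (the EC labels
#' of each condition's reaction chain) gain \code{log2(responsiveFoldChange)}
#' in their condition; independent replicate noise has sd \code{noiseSd}.
#' Values are truncated at zero.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param network the matching \code{\link{generateMasterNetwork}} output.
#' @return A list with elements \code{expr} (a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{log2expr} and colData condition/site/replicate) and \code{truth}
#'   (a \linkS4class{PlantedTruth}).
#' @examples
#' cfg <- syntheticConfig(seed = 7, nGenes = 150)
#' sim <- generateExpression(cfg, generateMasterNetwork(cfg))
#' sim$expr
#' @export
generateExpression <- function(config, network) {
  stopifnot(is(config, "SyntheticConfig"), is(network, "MetabolicNetwork"))
  lay <- .plantedLayout(config)
  netEC <- sort(unique(unlist(network@ec, use.names = FALSE)))
  respEC <- unlist(lay$chainEC, use.names = FALSE)
  if (!all(respEC %in% netEC)) {
    stop("network does not match config: planted ECs missing")
  }
  nFill <- config@nGenes - length(netEC)
  if (nFill < 0L) {
    stop(
      "nGenes (", config@nGenes, ") is smaller than the number of EC ",
      "annotations in the network (", length(netEC), ")"
    )
  }
  nModGenes <- config@nModules * config@moduleSize
  if (nModGenes > nFill) {
    stop(
      "cannot plant ", config@nModules, " disjoint modules of size ",
      config@moduleSize, ": only ", nFill,
      " filler genes are free of planted responsive signal"
    )
  }

  conditions <- config@conditions
  sites <- LETTERS[seq_len(config@nSites)]
  samples <- expand.grid(
    replicate = seq_len(config@nReplicates), site = sites,
    condition = conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples <- samples[, c("condition", "site", "replicate")]
  sampleIds <- paste(samples$condition, samples$site, samples$replicate,
    sep = "_"
  )
  nS <- nrow(samples)

  .withSeed(.deriveSeed(config@seed, "expression"), {
    fillers <- if (nFill > 0L) .randomEcIds(nFill, avoid = netEC) else character()
    genes <- c(netEC, fillers)
    membership <- rep(NA_integer_, config@nGenes)
    names(membership) <- genes
    if (nModGenes > 0L) {
      modGenes <- fillers[seq_len(nModGenes)]
      membership[modGenes] <- rep(seq_len(config@nModules),
        each = config@moduleSize
      )
    }

    baseline <- rnorm(config@nGenes, mean = 6, sd = 1)
    latent <- if (config@nModules > 0L) {
      matrix(rnorm(config@nModules * nS), config@nModules, nS)
    } else {
      matrix(0, 0L, nS)
    }
    noise <- matrix(
      rnorm(config@nGenes * nS, sd = config@noiseSd),
      config@nGenes, nS
    )

    mat <- matrix(baseline, config@nGenes, nS) + noise
    inMod <- which(!is.na(membership))
    if (length(inMod)) {
      mat[inMod, ] <- mat[inMod, ] +
        config@latentStrength * latent[membership[inMod], , drop = FALSE]
    }
    shift <- log2(config@responsiveFoldChange)
    for (cond in lay$treatments) {
      gi <- match(lay$chainEC[[cond]], genes)
      si <- which(samples$condition == cond)
      if (length(gi) && length(si)) mat[gi, si] <- mat[gi, si] + shift
    }
    mat <- pmax(mat, 0)
    dimnames(mat) <- list(genes, sampleIds)

    truth <- new("PlantedTruth",
      moduleMembership = membership,
      responsiveGenes = lay$chainEC,
      terminalMetabolites = lay$chainMet,
      plantedReactions = lay$chainRxn
    )
    respCond <- rep(NA_character_, config@nGenes)
    for (cond in names(lay$chainEC)) {
      respCond[match(lay$chainEC[[cond]], genes)] <- cond
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = mat),
      rowData = S4Vectors::DataFrame(
        module = unname(membership), responsiveCondition = respCond
      ),
      colData = S4Vectors::DataFrame(samples, row.names = sampleIds)
    )
    S4Vectors::metadata(se)$seed <- config@seed
    list(expr = se, truth = truth)
  })
}

#' Generate per-condition detected-metabolite lists
#'
#' Emulates a targeted community metabolomics assay: a common core of
#' metabolites is drawn once (each core metabolite detected with probability
#' \code{metaboliteDetectionRate}) and shared by every condition, and each
#' condition additionally always contains its planted condition-specific
#' terminal metabolites. All listed metabolites exist in the network.
#'
#' @param network the master \linkS4class{MetabolicNetwork}.
#' @param truth the matching \linkS4class{PlantedTruth}.
#' @param config the \linkS4class{SyntheticConfig} used throughout.
#' @return Named list, condition -> sorted character vector of metabolite ids.
#' @export
generateMetaboliteDetections <- function(network, truth, config) {
  stopifnot(
    is(network, "MetabolicNetwork"), is(truth, "PlantedTruth"),
    is(config, "SyntheticConfig")
  )
  validObject(config)
  planted <- unlist(truth@terminalMetabolites, use.names = FALSE)
  if (!all(planted %in% network@metabolites)) {
    stop("planted terminal metabolites missing from the network")
  }
  lay <- .plantedLayout(config)
  .withSeed(.deriveSeed(config@seed, "detections"), {
    core <- lay$coreMet[
      runif(length(lay$coreMet)) < config@metaboliteDetectionRate
    ]
    out <- lapply(config@conditions, function(cond) {
      extra <- truth@terminalMetabolites[[cond]]
      sort(unique(c(core, extra)))
    })
    names(out) <- config@conditions
    out
  })
}
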