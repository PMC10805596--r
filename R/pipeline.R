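pipelineDefaults <- function() {
  list(
    seed = 1L,
    stats = list(adjust = "bonferroni"),
    coexpression = list(quantile = 0.05, min_ratio = 1.2,
                        motif_filter = TRUE, n_random = 1000L),
    conservation = list(quantile = 0.20, n_random = 1000L))
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

requireField <- function(config, path) {
  node <- config
  for (p in path) {
    node <- node[[p]]
    if (is.null(node))
      stop(sprintf("config validation: missing field '%s'",
                   paste(path, collapse = ".")), call. = FALSE)
  }
  node
}

configToSimulation <- function(sim, seed) {
  modules <- lapply(sim$modules %||% list(), function(m)
    list(genes = unlist(m$genes), effectSize = m$effect_size %||% m$effectSize))
  over <- lapply(sim$overexpressed_sets %||% list(), function(s)
    list(genes = unlist(s$genes), class = s$class, fold = s$fold))
  simulationConfig(
    nGenes = requireField(sim, "n_genes"),
    nCells = requireField(sim, "n_cells"),
    nClusters = requireField(sim, "n_clusters"),
    classOfCluster = unlist(sim$class_of_cluster) %||% NULL,
    baselineMean = sim$baseline_mean %||% 5,
    dispersion = sim$dispersion %||% 2,
    dropoutRate = sim$dropout_rate %||% 0.3,
    modules = modules, overexpressedSets = over,
    seed = sim$seed %||% seed)
}

#' Run the full analysis pipeline from a single configuration
#'
#' Executes normalize -> cluster profiles -> class differential expression
#' and variability -> coexpression (full + selective + motif-filtered +
#' modules + connectivity) -> conservation (when a species triplet is
#' configured), writing every stage output plus a `manifest.json` that
#' records parameters, seeds, output checksums and row counts. Two runs of
#' one configuration produce byte-identical outputs and manifests.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks `simulation:` (or `input:` file paths), optional `gene_sets:`
#' paths, and stage parameter blocks `stats:`, `coexpression:`
#' (`quantile`, `target_class`, `control_class`, `min_ratio`,
#' `motif_filter`, `n_random`) and `conservation:` (`triplet:` with
#' `n_conserved`, `n_species_private`, `effect_size`; `quantile`,
#' `n_random`). Stage defaults follow the study settings: quantile 0.05
#' for the full network and 0.20 for species networks, minimum
#' overexpression ratio 1.2, 1000 randomizations.
#'
#' @param config path to a YAML config file, or a named list
#' @param outputDir output directory (overrides `config$output_dir`)
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  cfg <- mergeConfig(pipelineDefaults(), config)
  outDir <- outputDir %||% cfg$output_dir
  if (is.null(outDir)) stop("config validation: missing field 'output_dir'")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = as.character(packageVersion("scProteoNet")),
                   parameters = cfg, stages = list(), status = "incomplete")
  outputs <- character()
  stageName <- "setup"
  writeManifest <- function() {
    manifest$checksums <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  runStage <- function(name, expr) {
    stageName <<- name
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e) {
      manifest$stages[[stageName]] <<- list(status = "failed",
                                            error = conditionMessage(e))
      writeManifest()
      stop(sprintf("stage '%s' failed: %s", stageName, conditionMessage(e)),
           call. = FALSE)
    })
  }
  addOutput <- function(path, rows = NA) {
    outputs <<- c(outputs, path)
    manifest$stages[[stageName]]$outputs <<-
      c(manifest$stages[[stageName]]$outputs %||% list(),
        setNames(list(rows), basename(path)))
  }

  ## ---- input / simulation -------------------------------------------------
  sce <- runStage("input", {
    if (!is.null(cfg$simulation)) {
      sc <- configToSimulation(cfg$simulation, cfg$seed)
      ds <- simulateDataset(sc)
      paths <- writeDataset(ds, file.path(outDir, "dataset"))
      for (p in paths) addOutput(p)
      ds
    } else if (!is.null(cfg$input)) {
      readExpression(requireField(cfg, c("input", "matrix")),
                     requireField(cfg, c("input", "genes")),
                     requireField(cfg, c("input", "cells")),
                     cfg$input$clusters)
    } else stop("config needs a 'simulation' or 'input' block")
  })
  catalog <- NULL
  if (!is.null(cfg$gene_sets)) {
    catalog <- runStage("gene_sets",
      readGeneSets(unlist(cfg$gene_sets)))
  }

  ## ---- normalize ----------------------------------------------------------
  sce <- runStage("normalize", cpmNormalize(sce))
  profiles <- runStage("profiles", clusterProfiles(sce))

  ## ---- stats --------------------------------------------------------------
  runStage("stats", {
    classes <- clusterClasses(sce)
    cls <- sort(unique(unname(classes)))
    deAll <- list()
    for (pr in utils::combn(cls, 2, simplify = FALSE)) {
      a <- cellsOfClass(sce, pr[1]); b <- cellsOfClass(sce, pr[2])
      de <- differentialExpression(sce, a, b, adjust = cfg$stats$adjust)
      de$comparison <- paste(pr, collapse = "_vs_")
      deAll[[length(deAll) + 1L]] <- de
    }
    de <- do.call(rbind, deAll)
    p <- file.path(outDir, "de_results.tsv")
    write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput(p, nrow(de))
    flags <- variabilityFlags(profiles)
    vp <- variabilityPercentages(flags, classes)
    p <- file.path(outDir, "variability.tsv")
    write.table(data.frame(gene = rownames(vp), vp, check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput(p, nrow(vp))
    if (!is.null(catalog)) {
      fam <- familyCumulativeExpression(profiles, catalog)
      p <- file.path(outDir, "family_cumulative.tsv")
      write.table(data.frame(family = rownames(fam), fam, check.names = FALSE),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      addOutput(p, nrow(fam))
      comp <- compositionStats(profiles, catalog, classes)
      p <- file.path(outDir, "composition.tsv")
      write.table(comp, p, sep = "\t", quote = FALSE, row.names = FALSE)
      addOutput(p, nrow(comp))
    }
    p <- file.path(outDir, "cluster_dendrogram.nwk")
    writeDendrogram(cosineLinkage(profiles), p)
    addOutput(p)
  })

  ## ---- coexpression -------------------------------------------------------
  net <- runStage("coexpression", {
    fcp <- foldChangeProfiles(profiles)
    nw <- coexpressionEdges(fcp, quantile = cfg$coexpression$quantile)
    p <- file.path(outDir, "network.tsv")
    writeNetwork(nw, p)
    addOutput(p, nrow(networkEdges(nw)))
    nw
  })
  if (!is.null(cfg$coexpression$target_class)) {
    net <- runStage("selective", {
      sel <- selectiveGenes(
        sce,
        cellsOfClass(sce, cfg$coexpression$target_class),
        cellsOfClass(sce, requireField(cfg, c("coexpression", "control_class"))),
        minRatio = cfg$coexpression$min_ratio)
      e <- networkEdges(net)
      keep <- e$gene_a %in% sel & e$gene_b %in% sel
      nw <- coexNetwork(e[keep, , drop = FALSE],
                        nodes = intersect(networkNodes(net), sel),
                        meta = c(networkMeta(net),
                                 list(target_class = cfg$coexpression$target_class,
                                      control_class = cfg$coexpression$control_class,
                                      min_ratio = cfg$coexpression$min_ratio)))
      p <- file.path(outDir, "selective_network.tsv")
      writeNetwork(nw, p)
      addOutput(p, nrow(networkEdges(nw)))
      nw
    })
  }
  if (isTRUE(cfg$coexpression$motif_filter)) {
    net <- runStage("motif_filter", {
      nw <- motifFilter(net)
      p <- file.path(outDir, "filtered_network.tsv")
      writeNetwork(nw, p)
      addOutput(p, nrow(networkEdges(nw)))
      nw
    })
  }
  runStage("modules", {
    if (nrow(networkEdges(net))) {
      part <- detectModules(net)
      tab <- data.frame(gene = names(moduleAssignments(part)),
                        module = unname(moduleAssignments(part)))
      tab <- tab[order(tab$module, tab$gene), ]
      p <- file.path(outDir, "modules.tsv")
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      addOutput(p, nrow(tab))
    }
  })
  conn <- runStage("connectivity", {
    if (nrow(networkEdges(net))) {
      gs <- if (!is.null(catalog)) unique(unlist(geneSets(catalog)))
            else networkNodes(net)
      cc <- relativeConnectivity(net, gs,
                                 nRandom = cfg$coexpression$n_random,
                                 seed = cfg$seed)
      p <- file.path(outDir, "connectivity.tsv")
      write.table(cc$perGene, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      addOutput(p, nrow(cc$perGene))
      cc
    }
  })
  if (!is.null(conn))
    manifest$stages$connectivity$set_relative <- conn$setRelative

  ## ---- conservation (optional) -------------------------------------------
  if (!is.null(cfg$conservation$triplet)) {
    runStage("conservation", {
      tr <- cfg$conservation$triplet
      if (is.null(cfg$simulation))
        stop("conservation.triplet needs a simulation block")
      simBlock <- mergeConfig(cfg$simulation, tr$simulation %||% list())
      # the triplet plants its own conserved/private modules
      simBlock$modules <- (tr$simulation %||% list())$modules %||% list()
      baseCfg <- configToSimulation(simBlock, cfg$seed)
      triplet <- simulateSpeciesTriplet(
        baseCfg,
        nConserved = requireField(tr, "n_conserved"),
        nSpeciesPrivate = requireField(tr, "n_species_private"),
        effectSize = tr$effect_size %||% 2)
      nets <- lapply(speciesDatasets(triplet), function(d)
        coexpressionEdges(foldChangeProfiles(clusterProfiles(cpmNormalize(d))),
                          quantile = cfg$conservation$quantile))
      res <- conservationAnalysis(nets, orthologueMap(triplet),
                                  nRandom = cfg$conservation$n_random,
                                  seed = cfg$seed)
      p <- file.path(outDir, "conserved_edges.tsv")
      writeNetwork(conservedNetwork(res), p)
      addOutput(p, res@nTrue)
      p <- file.path(outDir, "per_gene_conservation.tsv")
      write.table(perGeneConservation(res), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      addOutput(p, nrow(perGeneConservation(res)))
      summary <- list(n_true = res@nTrue,
                      null_mean = mean(nullConservedCounts(res)),
                      null_sd = stats::sd(nullConservedCounts(res)),
                      score = conservationScoreValue(res))
      p <- file.path(outDir, "conservation_summary.json")
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
      addOutput(p)
    })
  }

  manifest$status <- "complete"
  stageName <- "manifest"
  writeManifest()
  message(sprintf("pipeline complete; outputs in %s", outDir))
  invisible(manifest)
}
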