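#' @describeIn CoexNetwork-class edge table accessor
#' @param x a `CoexNetwork`
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoexNetwork"))
  x@edges
}

#' @describeIn CoexNetwork-class node accessor
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CoexNetwork"))
  x@nodes
}

#' @describeIn CoexNetwork-class provenance metadata accessor
#' @export
networkMeta <- function(x) {
  stopifnot(is(x, "CoexNetwork"))
  x@meta
}

#' Node degrees of a coexpression network
#'
#' @param x a [CoexNetwork-class]
#' @return named integer vector over all network nodes (0 for edgeless nodes).
#' @export
networkDegrees <- function(x) {
  stopifnot(is(x, "CoexNetwork"))
  d <- setNames(integer(length(x@nodes)), x@nodes)
  if (nrow(x@edges)) {
    tab <- table(c(x@edges$gene_a, x@edges$gene_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

setMethod("show", "CoexNetwork", function(object) {
  cat(sprintf("CoexNetwork: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (length(object@meta)) {
    flat <- vapply(object@meta, function(v)
      paste(format(v), collapse = ","), character(1))
    keep <- nchar(flat) <= 40
    cat("  meta:", paste(sprintf("%s=%s", names(flat)[keep], flat[keep]),
                         collapse = " "), "\n")
  }
})

#' @describeIn FoldChangeProfiles-class the genes x pairs matrix
#' @param x a `FoldChangeProfiles`
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "FoldChangeProfiles"))
  x@profiles
}

#' @describeIn FoldChangeProfiles-class the cluster pair table
#' @export
clusterPairs <- function(x) {
  stopifnot(is(x, "FoldChangeProfiles"))
  x@clusterPairs
}

#' @describeIn FoldChangeProfiles-class genes dropped for all-zero profiles
#' @export
droppedGenes <- function(x) {
  stopifnot(is(x, "FoldChangeProfiles"))
  x@dropped
}

setMethod("show", "FoldChangeProfiles", function(object) {
  cat(sprintf("FoldChangeProfiles: %d genes x %d cluster pairs (%d dropped)\n",
              nrow(object@profiles), ncol(object@profiles),
              length(object@dropped)))
})

#' @describeIn GeneSetCatalog-class named list of gene sets
#' @param x a `GeneSetCatalog`
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCatalog"))
  x@sets
}

#' @describeIn GeneSetCatalog-class subfamily -> parent map
#' @export
setParents <- function(x) {
  stopifnot(is(x, "GeneSetCatalog"))
  x@parents
}

setMethod("show", "GeneSetCatalog", function(object) {
  cat(sprintf("GeneSetCatalog: %d sets (%d subfamilies)\n",
              length(object@sets), length(object@parents)))
  for (nm in names(object@sets))
    cat(sprintf("  %s%s: %d genes\n", nm,
                if (nm %in% names(object@parents))
                  sprintf(" [%s]", object@parents[[nm]]) else "",
                length(object@sets[[nm]])))
})

#' @describeIn SpeciesTriplet-class per-species datasets
#' @param x a `SpeciesTriplet`
#' @export
speciesDatasets <- function(x) {
  stopifnot(is(x, "SpeciesTriplet"))
  x@datasets
}

#' @describeIn SpeciesTriplet-class the orthologue table
#' @export
orthologueMap <- function(x) {
  stopifnot(is(x, "SpeciesTriplet"))
  x@orthologueMap
}

#' @describeIn SpeciesTriplet-class planted conserved edges (human ids)
#' @export
truthConservedEdges <- function(x) {
  stopifnot(is(x, "SpeciesTriplet"))
  x@truthConservedEdges
}

setMethod("show", "SpeciesTriplet", function(object) {
  cat(sprintf("SpeciesTriplet: %d orthologue triples, %d planted conserved edges\n",
              nrow(object@orthologueMap), nrow(object@truthConservedEdges)))
})

#' @describeIn ModulePartition-class node -> module assignments
#' @param x a `ModulePartition`
#' @export
moduleAssignments <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  x@membership
}

#' @describeIn ModulePartition-class modularity of the partition
#' @export
partitionModularity <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  x@modularity
}

#' @describeIn ModulePartition-class edgeless nodes reported separately
#' @export
moduleSingletons <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  x@singletons
}

#' Module membership as a list of gene vectors
#'
#' @param x a [ModulePartition-class]
#' @return list of character vectors, one per module, largest first.
#' @export
moduleList <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  sp <- split(names(x@membership), x@membership)
  sp[order(-lengths(sp))]
}

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d nodes in %d modules (Q = %.3f, %d singletons)\n",
              length(object@membership),
              length(unique(object@membership)),
              object@modularity, length(object@singletons)))
})

#' @describeIn ConservationResult-class conserved edges as a network
#' @param x a `ConservationResult`
#' @export
conservedNetwork <- function(x) {
  stopifnot(is(x, "ConservationResult"))
  x@conservedEdges
}

#' @describeIn ConservationResult-class the conservation score (percent)
#' @export
conservationScoreValue <- function(x) {
  stopifnot(is(x, "ConservationResult"))
  x@score
}

#' @describeIn ConservationResult-class per-replicate null conserved counts
#' @export
nullConservedCounts <- function(x) {
  stopifnot(is(x, "ConservationResult"))
  x@nullCounts
}

#' @describeIn ConservationResult-class per-gene observed/expected table
#' @export
perGeneConservation <- function(x) {
  stopifnot(is(x, "ConservationResult"))
  x@perGene
}

setMethod("show", "ConservationResult", function(object) {
  cat(sprintf(paste0("ConservationResult: N_true = %d, mean null = %.2f ",
                     "(%d replicates), score = %s%%\n"),
              object@nTrue, mean(object@nullCounts),
              length(object@nullCounts),
              ifelse(is.na(object@score), "NA",
                     sprintf("%.1f", object@score))))
})
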