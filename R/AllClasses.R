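#' Simulation configuration for synthetic single-cell data
#'
#' Holds every parameter of the negative-binomial single-cell count generator:
#' dimensions, cluster class labels, baseline expression, dispersion, dropout,
#' planted coregulated modules and planted class-specific overexpression.
#' Objects are created with [simulationConfig()], which validates all
#' invariants (disjoint modules, at least 20 cells per cluster, all three cell
#' classes represented).
#'
#' @slot nGenes,nCells,nClusters integer dimensions.
#' @slot classOfCluster character vector (length `nClusters`) of cell-class
#'   labels, each one of `"Exc"`, `"Inh"`, `"non"`.
#' @slot baselineMean expected counts per gene per cell before any factor.
#' @slot dispersion negative-binomial size parameter (smaller = noisier).
#' @slot dropoutRate probability that any count is independently zeroed.
#' @slot modules list of `list(genes = <integer indices>, effectSize = <fold>)`
#'   planted coregulated modules; gene sets must be disjoint.
#' @slot overexpressedSets list of
#'   `list(genes = <integer indices>, class = <label>, fold = <numeric >= 1>)`.
#' @slot seed integer RNG seed; the generator is bit-reproducible given it.
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer", nCells = "integer", nClusters = "integer",
    classOfCluster = "character",
    baselineMean = "numeric", dispersion = "numeric", dropoutRate = "numeric",
    modules = "list", overexpressedSets = "list", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nClusters < 3L)
    msg <- c(msg, "invariant violated: n_clusters >= 3")
  if (length(object@classOfCluster) != object@nClusters)
    msg <- c(msg, "classOfCluster must have one label per cluster")
  if (!all(object@classOfCluster %in% CELL_CLASSES))
    msg <- c(msg, sprintf("cluster classes must be in {%s}",
                          paste(CELL_CLASSES, collapse = ", ")))
  if (!all(CELL_CLASSES %in% object@classOfCluster))
    msg <- c(msg, "invariant violated: at least one cluster per class (Exc, Inh, non)")
  if (object@nClusters >= 1L &&
      floor(object@nCells / object@nClusters) < 20L)
    msg <- c(msg, "invariant violated: every cluster must have >= 20 cells")
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must be in [0, 1]")
  allGenes <- integer()
  for (k in seq_along(object@modules)) {
    m <- object@modules[[k]]
    if (!is.list(m) || is.null(m$genes) || is.null(m$effectSize)) {
      msg <- c(msg, sprintf("module %d must be list(genes=, effectSize=)", k))
      next
    }
    if (any(m$genes < 1L | m$genes > object@nGenes))
      msg <- c(msg, sprintf("module %d has gene indices outside 1..nGenes", k))
    if (m$effectSize <= 0)
      msg <- c(msg, sprintf("module %d effectSize must be > 0", k))
    allGenes <- c(allGenes, m$genes)
  }
  if (anyDuplicated(allGenes))
    msg <- c(msg, "invariant violated: module gene sets must be disjoint")
  for (k in seq_along(object@overexpressedSets)) {
    s <- object@overexpressedSets[[k]]
    if (!is.list(s) || is.null(s$genes) || is.null(s$class) || is.null(s$fold)) {
      msg <- c(msg, sprintf("overexpressedSets[[%d]] must be list(genes=, class=, fold=)", k))
      next
    }
    if (!s$class %in% CELL_CLASSES)
      msg <- c(msg, sprintf("overexpressedSets[[%d]] class must be in {%s}",
                            k, paste(CELL_CLASSES, collapse = ", ")))
    if (s$fold < 1)
      msg <- c(msg, sprintf("overexpressedSets[[%d]] fold must be >= 1", k))
    if (any(s$genes < 1L | s$genes > object@nGenes))
      msg <- c(msg, sprintf("overexpressedSets[[%d]] has gene indices outside 1..nGenes", k))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Undirected weighted gene coexpression network
#'
#' Edge set over gene identifiers with correlation weights and provenance
#' metadata (threshold quantile, selection, species). Edges are stored once,
#' under canonical lexicographic node order (`gene_a < gene_b`), with no
#' self-edges. Construct with [coexNetwork()] or [readNetwork()].
#'
#' @slot nodes character vector of gene identifiers in the network universe
#'   (may include edgeless genes that entered pairing).
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @slot meta list of provenance fields.
#' @export
setClass("CoexNetwork",
  representation(nodes = "character", edges = "data.frame", meta = "list"))

setValidity("CoexNetwork", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
  if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) return("self-edges are not allowed")
    if (any(e$gene_b < e$gene_a))
      return("edges must be canonically ordered (gene_a < gene_b)")
    if (anyDuplicated(pairKey(e$gene_a, e$gene_b)))
      return("duplicate edges")
    if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
  }
  TRUE
})

#' Per-gene fold-change profiles over cluster pairs
#'
#' For n clusters each gene carries a vector of n(n-1)/2 log2 fold changes
#' between cluster mean CPM values (pseudocount 1), ordered by ascending
#' cluster-index pairs (i < j). This transform is the robust substrate on
#' which pairwise Pearson correlation defines coexpression.
#'
#' @slot profiles numeric matrix, genes x pairs.
#' @slot clusterPairs data.frame with columns `cluster_a`, `cluster_b`.
#' @slot dropped character: genes removed because all cluster means were zero.
#' @export
setClass("FoldChangeProfiles",
  representation(profiles = "matrix", clusterPairs = "data.frame",
                 dropped = "character"))

setValidity("FoldChangeProfiles", function(object) {
  p <- ncol(object@profiles)
  if (nrow(object@clusterPairs) != p)
    return("clusterPairs must describe every profile column")
  n <- length(unique(c(object@clusterPairs$cluster_a,
                       object@clusterPairs$cluster_b)))
  if (n * (n - 1L) / 2L != p)
    return("number of columns must equal n_clusters*(n_clusters-1)/2")
  TRUE
})

#' Catalog of named gene sets with optional subfamily structure
#'
#' Top-level sets (e.g. chaperones, ubiquitin_enzymes, synaptome,
#' ion_channels) plus named subfamily sets (HSP70, E2, DUB, ...) that must be
#' subsets of their declared parent. A gene may belong to several top-level
#' sets. Construct with [geneSetCatalog()] or [readGeneSets()].
#'
#' @slot sets named list of character vectors.
#' @slot parents named character vector mapping a subfamily set name to its
#'   parent set name.
#' @export
setClass("GeneSetCatalog",
  representation(sets = "list", parents = "character"))

setValidity("GeneSetCatalog", function(object) {
  if (length(object@sets) && is.null(names(object@sets)))
    return("sets must be named")
  if (anyDuplicated(names(object@sets))) return("duplicate set names")
  for (nm in names(object@parents)) {
    par <- object@parents[[nm]]
    if (!nm %in% names(object@sets))
      return(sprintf("subfamily '%s' is not a set in the catalog", nm))
    if (!par %in% names(object@sets))
      return(sprintf("parent '%s' of subfamily '%s' is not in the catalog", par, nm))
    if (!all(object@sets[[nm]] %in% object@sets[[par]]))
      return(sprintf("invariant violated: subfamily '%s' is not a subset of '%s'",
                     nm, par))
  }
  TRUE
})

#' Three-species synthetic expression datasets with planted conservation
#'
#' One simulated dataset per species (human, macaque, mouse) sharing planted
#' coregulated modules (the source of conserved coexpression edges), a
#' one-to-one-to-one orthologue table, and the ground-truth conserved edge
#' set in human identifiers. Produced by [simulateSpeciesTriplet()].
#'
#' @slot datasets named list of three SingleCellExperiment objects.
#' @slot orthologueMap data.frame with columns `human`, `macaque`, `mouse`.
#' @slot truthConservedEdges data.frame (`gene_a`, `gene_b`) of planted
#'   conserved pairs, canonical order, human identifiers.
#' @export
setClass("SpeciesTriplet",
  representation(datasets = "list", orthologueMap = "data.frame",
                 truthConservedEdges = "data.frame"))

setValidity("SpeciesTriplet", function(object) {
  if (!identical(sort(names(object@datasets)),
                 sort(c("human", "macaque", "mouse"))))
    return("datasets must be named human, macaque, mouse")
  om <- object@orthologueMap
  if (!all(c("human", "macaque", "mouse") %in% names(om)))
    return("orthologueMap needs columns human, macaque, mouse")
  for (cl in c("human", "macaque", "mouse"))
    if (anyDuplicated(om[[cl]]))
      return(sprintf("invariant violated: orthologue column '%s' has duplicates", cl))
  te <- object@truthConservedEdges
  if (nrow(te) &&
      !all(c(te$gene_a, te$gene_b) %in% om$human))
    return("planted conserved edges must join genes present in the orthologue map")
  TRUE
})

#' Module partition of a coexpression network
#'
#' Result of greedy-modularity community detection: every node carried by at
#' least one edge belongs to exactly one module; edgeless nodes are reported
#' separately as singletons.
#'
#' @slot membership named integer vector, node -> module id.
#' @slot modularity modularity of the partition on the unweighted graph.
#' @slot singletons character vector of edgeless nodes.
#' @export
setClass("ModulePartition",
  representation(membership = "integer", modularity = "numeric",
                 singletons = "character"))

setValidity("ModulePartition", function(object) {
  if (length(object@membership) && is.null(names(object@membership)))
    return("membership must be named by node")
  if (anyDuplicated(names(object@membership)))
    return("a node cannot belong to two modules")
  if (any(is.na(object@membership))) return("membership must not contain NA")
  TRUE
})

#' Cross-species conservation analysis result
#'
#' The conserved edge set (reference-species identifiers), the observed count
#' of conserved interactions, the per-replicate conserved counts from
#' degree-preserving randomizations of all species networks, the conservation
#' score `((N_true / mean(null)) - 1) * 100`, and per-gene observed/expected
#' conserved degrees with empirical significance. The per-replicate conserved
#' edge keys are retained so gene-set densities can be computed against the
#' identical null ([genesetDensity()]).
#'
#' @slot conservedEdges [CoexNetwork-class] of conserved interactions.
#' @slot nTrue integer observed conserved interaction count.
#' @slot nullCounts numeric vector of conserved counts per null replicate.
#' @slot score conservation score in percent (NA when the null mean is 0).
#' @slot perGene data.frame: gene, observed, expected, ratio, empirical_p,
#'   significant.
#' @slot nullEdgeKeys list of per-replicate conserved edge key vectors.
#' @slot meta list of parameters (n_random, seed, universe size).
#' @export
setClass("ConservationResult",
  representation(conservedEdges = "CoexNetwork", nTrue = "integer",
                 nullCounts = "numeric", score = "numeric",
                 perGene = "data.frame", nullEdgeKeys = "list", meta = "list"))

setValidity("ConservationResult", function(object) {
  nr <- mean(object@nullCounts)
  if (is.finite(nr) && nr > 0) {
    expect <- (object@nTrue / nr - 1) * 100
    if (!isTRUE(all.equal(expect, object@score, tolerance = 1e-12)))
      return("score must equal ((N_true/N_random) - 1) * 100")
  } else if (!is.na(object@score)) {
    return("score must be NA when the null mean is zero")
  }
  TRUE
})
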