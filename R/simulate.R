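#' Build a validated simulation configuration
#'
#' The generator draws counts per gene and cell as negative binomial with
#' mean `baselineMean * clusterFactor * moduleFactor * overexpressionFactor`,
#' then zeroes entries independently with probability `dropoutRate`.
#' Background cluster factors are log-normal(0, 0.3) per gene per cluster;
#' each planted module shares one log-normal(0, log(effectSize)) latent
#' factor per cluster, which is what makes module genes' cluster-mean
#' profiles correlate. `effectSize = 1` plants no signal.
#'
#' @param nGenes,nCells,nClusters dimensions; cells are assigned to clusters
#'   round-robin so every cluster receives at least 20 cells.
#' @param classOfCluster character vector of per-cluster class labels from
#'   `"Exc"`, `"Inh"`, `"non"`; default cycles through the three classes.
#' @param baselineMean expected counts per gene per cell (default 5).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param dropoutRate independent zeroing probability (default 0.3).
#' @param modules list of `list(genes=, effectSize=)` planted modules.
#' @param overexpressedSets list of `list(genes=, class=, fold=)`.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class]
#' @examples
#' cfg <- simulationConfig(nGenes = 100, nCells = 120, nClusters = 4,
#'   modules = list(list(genes = 1:10, effectSize = 2)), seed = 1)
#' @export
simulationConfig <- function(nGenes, nCells, nClusters,
                             classOfCluster = NULL,
                             baselineMean = 5, dispersion = 2,
                             dropoutRate = 0.3,
                             modules = list(), overexpressedSets = list(),
                             seed = 1L) {
  if (is.null(classOfCluster))
    classOfCluster <- rep_len(CELL_CLASSES, nClusters)
  modules <- lapply(modules, function(m)
    list(genes = as.integer(m$genes), effectSize = as.numeric(m$effectSize)))
  overexpressedSets <- lapply(overexpressedSets, function(s)
    list(genes = as.integer(s$genes), class = as.character(s$class),
         fold = as.numeric(s$fold)))
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nCells = as.integer(nCells),
      nClusters = as.integer(nClusters),
      classOfCluster = as.character(classOfCluster),
      baselineMean = as.numeric(baselineMean),
      dispersion = as.numeric(dispersion),
      dropoutRate = as.numeric(dropoutRate),
      modules = modules, overexpressedSets = overexpressedSets,
      seed = as.integer(seed))
}

geneIds <- function(n, prefix = "") sprintf("%sg%04d", prefix, seq_len(n))
clusterIds <- function(n) sprintf("cl%02d", seq_len(n))

# Per-cluster expected expression (genes x clusters) given the config's
# factors; separated from count drawing so truth structure is inspectable.
latentClusterMeans <- function(config) {
  G <- config@nGenes; K <- config@nClusters
  clusterFactor <- matrix(exp(rnorm(G * K, 0, 0.3)), G, K)
  moduleFactor <- matrix(1, G, K)
  for (m in config@modules) {
    sdlog <- log(m$effectSize)
    latent <- if (sdlog > 0) exp(rnorm(K, 0, sdlog)) else rep(1, K)
    moduleFactor[m$genes, ] <- rep(latent, each = length(m$genes))
  }
  overFactor <- matrix(1, G, K)
  for (s in config@overexpressedSets) {
    target <- which(config@classOfCluster == s$class)
    if (length(target)) overFactor[s$genes, target] <- s$fold
  }
  config@baselineMean * clusterFactor * moduleFactor * overFactor
}

#' Simulate a clustered single-cell expression dataset
#'
#' Draws sparse negative-binomial counts with independent dropout under the
#' configuration's planted structure. The result is a
#' `SingleCellExperiment` with a `"counts"` assay, the per-cell cluster in
#' `colData()$cluster`, the cluster class map in `metadata()$clusterClass`,
#' and ground truth (`truthModules`, `truthOverexpressed`) in metadata.
#' Bit-identical outputs are guaranteed for identical `config` (including
#' its seed).
#'
#' @param config a [SimulationConfig-class]
#' @param idPrefix prefix prepended to gene identifiers (used for species).
#' @return a `SingleCellExperiment`
#' @export
simulateDataset <- function(config, idPrefix = "") {
  validObject(config)
  G <- config@nGenes; N <- config@nCells; K <- config@nClusters
  cluster <- rep_len(seq_len(K), N)
  withSeed(config@seed, {
    mu <- latentClusterMeans(config)
    counts <- matrix(
      rnbinom(G * N, size = config@dispersion, mu = mu[, cluster]), G, N)
    if (config@dropoutRate > 0)
      counts <- counts * matrix(
        rbinom(G * N, 1L, 1 - config@dropoutRate), G, N)
  })
  gids <- geneIds(G, idPrefix)
  cids <- sprintf("cell%05d", seq_len(N))
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(m) <- list(gids, cids)
  clIds <- clusterIds(K)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cluster = clIds[cluster], row.names = cids))
  S4Vectors::metadata(sce) <- list(
    clusterClass = setNames(config@classOfCluster, clIds),
    truthModules = lapply(config@modules, function(mm) gids[mm$genes]),
    truthOverexpressed = lapply(config@overexpressedSets, function(s)
      list(genes = gids[s$genes], class = s$class, fold = s$fold)),
    simulationSeed = config@seed)
  sce
}

#' Per-cell cluster assignments
#' @param sce a `SingleCellExperiment` from this package (or any with a
#'   `cluster` column in `colData`)
#' @return named character vector cell -> cluster
#' @export
clusterAssignments <- function(sce) {
  cl <- SummarizedExperiment::colData(sce)$cluster
  if (is.null(cl)) stop("no 'cluster' column in colData")
  setNames(as.character(cl), colnames(sce))
}

#' Cluster to cell-class map
#' @param sce a `SingleCellExperiment` carrying `metadata()$clusterClass`
#' @return named character vector cluster -> class
#' @export
clusterClasses <- function(sce) {
  cc <- S4Vectors::metadata(sce)$clusterClass
  if (is.null(cc)) stop("no 'clusterClass' entry in metadata")
  cc
}

#' Planted coregulated modules of a simulated dataset
#' @param sce a simulated `SingleCellExperiment`
#' @return list of character gene-id vectors
#' @export
truthModules <- function(sce) S4Vectors::metadata(sce)$truthModules

#' Cells belonging to a cell class
#' @param sce a `SingleCellExperiment` with cluster and class annotation
#' @param class one of `"Exc"`, `"Inh"`, `"non"`
#' @return character vector of cell identifiers
#' @export
cellsOfClass <- function(sce, class) {
  cc <- clusterClasses(sce)
  cl <- clusterAssignments(sce)
  names(cl)[cc[cl] %in% class]
}

# Greedy decomposition of a pair count into disjoint module sizes:
# repeatedly take the largest s with choose(s,2) <= remaining, so the
# planted within-module pair count is exactly `nPairs`.
moduleSizesForPairs <- function(nPairs) {
  sizes <- integer()
  rem <- nPairs
  while (rem > 0) {
    s <- 2L
    while (choose(s + 1L, 2L) <= rem) s <- s + 1L
    sizes <- c(sizes, s)
    rem <- rem - choose(s, 2L)
  }
  sizes
}

# Module sizes partitioning `pool` genes into exactly `nPairs` within-module
# pairs while covering as many pool genes as possible. Mixes sizes 5 and 4
# with a triple/double tail; leftover genes stay singletons (no pairs).
privatePartitionSizes <- function(nPairs, pool) {
  if (nPairs == 0) return(integer())
  best <- NULL
  for (a in 0:(pool %/% 5)) {       # modules of 5 (10 pairs each)
    for (b in 0:((pool - 5 * a) %/% 4)) {  # modules of 4 (6 pairs each)
      p <- nPairs - 10 * a - 6 * b
      if (p < 0) break
      g <- pool - 5 * a - 4 * b
      # tail of t triples (3 pairs... no: C(3,2)=3) and d doubles: 3t + d = p
      tmin <- max(0, ceiling((2 * p - g) / 3))
      tmax <- p %/% 3
      if (tmin > tmax) next
      t <- tmin                      # smallest t spreads over the most genes
      d <- p - 3 * t
      covered <- 5 * a + 4 * b + 3 * t + 2 * d
      if (covered > pool) next
      if (is.null(best) || covered > best$covered)
        best <- list(sizes = c(rep(5L, a), rep(4L, b), rep(3L, t), rep(2L, d)),
                     covered = covered)
    }
  }
  if (is.null(best))
    stop(sprintf("cannot plant %d private pairs within %d genes", nPairs, pool))
  best$sizes
}

# Cut the first sum(sizes) elements of `order` into consecutive groups.
cutIntoModules <- function(order, sizes) {
  out <- vector("list", length(sizes))
  at <- 1L
  for (k in seq_along(sizes)) {
    out[[k]] <- sort(order[seq.int(at, at + sizes[k] - 1L)])
    at <- at + sizes[k]
  }
  out
}

modulePairKeys <- function(modules) {
  unlist(lapply(modules, function(g) {
    if (length(g) < 2L) return(character())
    ij <- indexPairs(length(g))
    pairKey(g[ij$i], g[ij$j])
  }))
}

# Three mutually pair-disjoint partitions of the pool: species s orders the
# pool by a strided permutation (stride coprime with the pool size) and cuts
# consecutive runs. Strides are searched deterministically and the
# disjointness of the three planted pair sets is verified.
disjointPrivateModules <- function(poolIdx, sizes) {
  P <- length(poolIdx)
  if (!length(sizes)) return(list(list(), list(), list()))
  strideOrder <- function(m) poolIdx[((seq_len(P) - 1L) * m) %% P + 1L]
  candidates <- Filter(function(m) {
    m > 1 && m < P && gcd2(m, P) == 1L
  }, seq_len(P))
  first <- cutIntoModules(strideOrder(1L), sizes)
  k1 <- modulePairKeys(first)
  for (m2 in candidates) {
    second <- cutIntoModules(strideOrder(m2), sizes)
    k2 <- modulePairKeys(second)
    if (length(intersect(k1, k2))) next
    for (m3 in setdiff(candidates, m2)) {
      third <- cutIntoModules(strideOrder(m3), sizes)
      k3 <- modulePairKeys(third)
      if (!length(intersect(k1, k3)) && !length(intersect(k2, k3)))
        return(list(first, second, third))
    }
  }
  stop("could not construct pair-disjoint species-private modules")
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

SPECIES_PREFIX <- c(human = "hs_", macaque = "mq_", mouse = "mm_")

#' Simulate a three-species expression triplet with planted conservation
#'
#' Builds one dataset per species (human, macaque, mouse) from a shared
#' configuration. Conserved structure enters only through shared planted
#' module membership: a block of modules (sizes chosen so that within-module
#' pairs total exactly `nConserved`) is planted identically in all three
#' species. Each species additionally receives exactly `nSpeciesPrivate`
#' planted pairs absent in the other two: the remaining genes form a common
#' pool that every species partitions into its own planted modules, the
#' three partitions mutually pair-disjoint, so every gene participates in
#' some regulatory program in every species (a gene left structureless in
#' two species would have artificially deflated profile variance and attract
#' spurious edges there). Noise is independent per species (seeds
#' `config@seed`, `+1`, `+2`). Orthologue identifiers differ only by species
#' prefix and map one-to-one.
#'
#' @param config a [SimulationConfig-class]; its `modules` slot must be empty
#'   (the triplet plants its own structure).
#' @param nConserved number of conserved gene pairs to plant.
#' @param nSpeciesPrivate number of species-private pairs per species.
#' @param effectSize multiplicative amplitude of planted module factors.
#' @return a [SpeciesTriplet-class]
#' @export
simulateSpeciesTriplet <- function(config, nConserved, nSpeciesPrivate,
                                   effectSize = 2) {
  validObject(config)
  if (length(config@modules))
    stop("config@modules must be empty; the triplet plants its own modules")
  consSizes <- moduleSizesForPairs(nConserved)
  nCons <- sum(consSizes)
  pool <- config@nGenes - nCons
  if (pool < 0 || (nSpeciesPrivate > 0 && pool < 2))
    stop(sprintf("planted structure does not fit: %d conserved-module genes but nGenes = %d",
                 nCons, config@nGenes))
  privSizes <- privatePartitionSizes(nSpeciesPrivate, pool)
  consModules <- cutIntoModules(seq_len(nCons), consSizes)
  privModules <- disjointPrivateModules(seq.int(nCons + 1L, length.out = pool),
                                        privSizes)
  species <- names(SPECIES_PREFIX)
  datasets <- setNames(vector("list", 3L), species)
  for (i in seq_along(species)) {
    mods <- c(lapply(consModules, function(g) list(genes = g, effectSize = effectSize)),
              lapply(privModules[[i]], function(g) list(genes = g, effectSize = effectSize)))
    cfg <- config
    cfg@modules <- mods
    cfg@seed <- config@seed + (i - 1L)
    validObject(cfg)
    datasets[[species[i]]] <- simulateDataset(cfg, idPrefix = SPECIES_PREFIX[i])
  }
  base <- geneIds(config@nGenes)
  om <- data.frame(human = paste0(SPECIES_PREFIX["human"], base),
                   macaque = paste0(SPECIES_PREFIX["macaque"], base),
                   mouse = paste0(SPECIES_PREFIX["mouse"], base),
                   stringsAsFactors = FALSE)
  hsIds <- om$human
  edges <- do.call(rbind, lapply(consModules, function(g) {
    if (length(g) < 2L) return(NULL)
    ij <- indexPairs(length(g))
    data.frame(gene_a = hsIds[g[ij$i]], gene_b = hsIds[g[ij$j]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  cp <- canonicalPairs(edges$gene_a, edges$gene_b)
  edges$gene_a <- cp$a; edges$gene_b <- cp$b
  new("SpeciesTriplet", datasets = datasets, orthologueMap = om,
      truthConservedEdges = edges)
}
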