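#' Fold-change profiles over all cluster pairs
#'
#' Replaces each gene's expression profile across n clusters by the vector
#' of n(n-1)/2 pairwise log2 fold changes between cluster mean CPM values
#' (pseudocount 1), ordered by ascending cluster-index pairs (i < j). The
#' transform is robust to the missing-value structure of single-cell data:
#' a dropout-heavy cluster perturbs only the entries involving it, not the
#' whole profile. Swapping clusters i and j negates the corresponding
#' entry. Genes whose cluster means are all zero carry no information and
#' are dropped (reported via [droppedGenes()]).
#'
#' @param profiles genes x clusters mean-CPM matrix from [clusterProfiles()]
#' @return a [FoldChangeProfiles-class]
#' @examples
#' p <- matrix(c(3, 7, 15), 1, dimnames = list("g1", c("c1", "c2", "c3")))
#' profileMatrix(foldChangeProfiles(p))  # (-1, -2, -1)
#' @export
foldChangeProfiles <- function(profiles) {
  K <- ncol(profiles)
  if (K < 3L)
    stop("need at least 3 clusters for a meaningful correlation dimension")
  dropped <- rownames(profiles)[rowSums(profiles) == 0]
  keep <- rowSums(profiles) > 0
  L <- log2(profiles[keep, , drop = FALSE] + 1)
  ij <- indexPairs(K)
  fc <- L[, ij$i, drop = FALSE] - L[, ij$j, drop = FALSE]
  cn <- colnames(profiles)
  colnames(fc) <- paste(cn[ij$i], cn[ij$j], sep = "|")
  new("FoldChangeProfiles", profiles = fc,
      clusterPairs = data.frame(cluster_a = cn[ij$i], cluster_b = cn[ij$j],
                                stringsAsFactors = FALSE),
      dropped = dropped)
}

#' Call coexpression edges at a correlation-rank quantile
#'
#' Pearson correlations over the fold-change profiles are computed for all
#' gene pairs, and the `ceiling(quantile * n_pairs)` pairs with the largest
#' signed correlation become edges (positive coregulation semantics:
#' anti-correlated pairs are never called). Genes with zero-variance
#' profiles cannot be correlated and are excluded from pairing (reported in
#' the network metadata). Ties at the cutoff are broken by canonical pair
#' order so edge calling is fully deterministic.
#'
#' @param fcp a [FoldChangeProfiles-class]
#' @param quantile fraction of gene pairs to call, in (0, 1); 0.05 for the
#'   full network, 0.20 for the smaller species-specific networks
#' @return a [CoexNetwork-class]; nodes are all paired genes
#' @export
coexpressionEdges <- function(fcp, quantile = 0.05) {
  stopifnot(is(fcp, "FoldChangeProfiles"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  X <- fcp@profiles
  v <- apply(X, 1L, stats::var)
  excluded <- rownames(X)[v == 0]
  X <- X[v > 0, , drop = FALSE]
  g <- nrow(X)
  if (g < 2L) stop("need at least 2 genes with non-constant profiles")
  R <- cor(t(X))
  ij <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ij]
  a <- rownames(R)[ij[, 1L]]
  b <- rownames(R)[ij[, 2L]]
  cp <- canonicalPairs(a, b)
  k <- ceiling(quantile * choose(g, 2))
  ord <- order(-r, cp$a, cp$b, method = "radix")
  take <- ord[seq_len(k)]
  edges <- data.frame(gene_a = cp$a[take], gene_b = cp$b[take],
                      weight = r[take], stringsAsFactors = FALSE)
  coexNetwork(edges, nodes = sort(rownames(X)),
              meta = list(quantile = quantile, n_pairs = choose(g, 2),
                          n_edges = k, excluded_zero_variance = excluded))
}

#' Genes systematically overexpressed in a target cell selection
#'
#' Retains genes whose mean CPM over the target cells is at least
#' `minRatio` times the mean over the control cells (boundary inclusive:
#' "at least 20%" keeps a gene at exactly 1.2x). Means are compared raw by
#' default; `pseudocount` can stabilize the ratio for very low expression.
#' Genes with zero mean in both selections are never retained. Restricting
#' a coexpression network to this set yields a selective network.
#'
#' @param sce a normalized `SingleCellExperiment`
#' @param targetCells,controlCells disjoint nonempty cell-identifier vectors
#' @param minRatio minimum target/control mean ratio, default 1.2
#' @param pseudocount added to both means before the ratio, default 0
#' @param assayName assay holding normalized values, default `"cpm"`
#' @return character vector of retained genes with attributes `minRatio`,
#'   `nTarget`, `nControl`; empty (with a warning) when nothing passes
#' @export
selectiveGenes <- function(sce, targetCells, controlCells, minRatio = 1.2,
                           pseudocount = 0, assayName = "cpm") {
  if (!length(targetCells) || !length(controlCells))
    stop("target and control selections must be nonempty")
  if (length(intersect(targetCells, controlCells)))
    stop("target and control selections must be disjoint")
  m <- SummarizedExperiment::assay(sce, assayName)
  mt <- Matrix::rowMeans(m[, targetCells, drop = FALSE]) + pseudocount
  mc <- Matrix::rowMeans(m[, controlCells, drop = FALSE]) + pseudocount
  keep <- mt >= minRatio * mc & mt > 0
  genes <- rownames(sce)[keep]
  if (!length(genes))
    warning("no gene passes the overexpression filter; returning empty set")
  structure(genes, minRatio = minRatio,
            nTarget = length(targetCells), nControl = length(controlCells))
}

#' Enumerate all connected 3-node subgraphs
#'
#' Lists every node triple inducing a connected subgraph: open 2-paths
#' (type `"path"`, `gene_2` is the center) and triangles (type
#' `"triangle"`, nodes in sorted order). Each triad is reported exactly
#' once. Enumeration walks neighbor pairs around each center, so it scales
#' with the number of triads rather than with `choose(n, 3)`.
#'
#' @param network a [CoexNetwork-class]
#' @return data.frame: gene_1, gene_2, gene_3, type
#' @export
enumerateTriads <- function(network) {
  stopifnot(is(network, "CoexNetwork"))
  e <- networkEdges(network)
  if (!nrow(e))
    return(data.frame(gene_1 = character(), gene_2 = character(),
                      gene_3 = character(), type = character(),
                      stringsAsFactors = FALSE))
  adj <- split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
  edgeSet <- pairKey(e$gene_a, e$gene_b)
  out <- vector("list", length(adj))
  k <- 0L
  for (b in names(adj)) {
    nb <- sort(adj[[b]])
    if (length(nb) < 2L) next
    pr <- indexPairs(length(nb))
    a <- nb[pr$i]; c2 <- nb[pr$j]
    closed <- pairKey(a, c2) %in% edgeSet
    # triangles: keep only when the center is the smallest node, so each
    # triangle (seen from all three centers) is reported once
    tri <- closed & b < a
    open <- !closed
    if (any(tri) || any(open)) {
      k <- k + 1L
      out[[k]] <- rbind(
        if (any(tri)) data.frame(gene_1 = rep(b, sum(tri)), gene_2 = a[tri],
                                 gene_3 = c2[tri], type = "triangle",
                                 stringsAsFactors = FALSE),
        if (any(open)) data.frame(gene_1 = a[open], gene_2 = rep(b, sum(open)),
                                  gene_3 = c2[open], type = "path",
                                  stringsAsFactors = FALSE))
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res))
    res <- data.frame(gene_1 = character(), gene_2 = character(),
                      gene_3 = character(), type = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Motif-filter a network to genes with multiple systematic interactions
#'
#' Retains the genes that occur in a connected size-3 motif with degree at
#' least 2 (for a simple graph these coincide: any node with two neighbors
#' centers an open 2-path), then keeps only the edges among retained genes
#' and drops retained genes left without incident edges, so the result is a
#' well-formed network. A bare path A-B-C therefore filters to an empty
#' network: only B has degree 2, and it keeps no edge to another retained
#' gene.
#'
#' @param network a [CoexNetwork-class]
#' @return the filtered [CoexNetwork-class]
#' @export
motifFilter <- function(network) {
  stopifnot(is(network, "CoexNetwork"))
  deg <- networkDegrees(network)
  retained <- names(deg)[deg >= 2L]
  e <- networkEdges(network)
  e <- e[e$gene_a %in% retained & e$gene_b %in% retained, , drop = FALSE]
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  coexNetwork(e, nodes = nodes,
              meta = c(networkMeta(network), list(motif_filtered = TRUE)))
}

#' Detect network modules by greedy modularity maximization
#'
#' Communities of the unweighted graph found by hierarchical greedy
#' modularity optimization (Clauset-Newman-Moore, via igraph). The node
#' order is canonicalized before clustering, so the partition is
#' deterministic. Edgeless nodes are reported as singletons, not modules.
#' Module ids are assigned by decreasing module size.
#'
#' @param network a [CoexNetwork-class] with at least one edge
#' @return a [ModulePartition-class]
#' @export
detectModules <- function(network) {
  stopifnot(is(network, "CoexNetwork"))
  if (!nrow(networkEdges(network))) stop("cannot partition an edgeless network")
  deg <- networkDegrees(network)
  singles <- names(deg)[deg == 0L]
  g <- asIgraph(network, weighted = FALSE)
  if (length(singles)) g <- igraph::delete_vertices(g, singles)
  fg <- igraph::cluster_fast_greedy(g)
  # cut the merge dendrogram at maximal modularity, breaking ties toward
  # fewer communities (plain CNM stalls on zero-gain merges, e.g. cliques)
  qs <- fg$modularity
  cutIdx <- max(which(qs >= max(qs) - 1e-12))
  noMin <- igraph::vcount(g) - nrow(fg$merges)   # disconnected graphs cannot
  no <- max(length(qs) - cutIdx + 1L, noMin)     # merge below one/component
  mem <- igraph::cut_at(fg, no = no)
  names(mem) <- igraph::V(g)$name
  Q <- igraph::modularity(g, mem)
  sizes <- table(mem)
  relabel <- setNames(rank(-as.vector(sizes), ties.method = "first"),
                      names(sizes))
  membership <- setNames(as.integer(relabel[as.character(mem)]),
                         names(mem))
  new("ModulePartition", membership = membership, modularity = Q,
      singletons = singles)
}

#' Relative connectivity against uniform random-graph nulls
#'
#' Compares each gene's observed degree with its mean degree across
#' `nRandom` uniform random graphs on the same node and edge counts
#' (Erdos-Renyi G(n, m)); the ratio is the relative connectivity, and the
#' per-set value averages it over a gene set's members. The null is
#' size-matched, not degree-preserving: a degree-preserving null would
#' force every ratio to 1.
#'
#' @param network a [CoexNetwork-class]
#' @param geneset gene identifiers; must intersect the network nodes
#' @param nRandom number of null replicates (>= 1), default 1000
#' @param seed RNG seed; replicate r uses seed + r
#' @return list with `perGene` (data.frame gene, degree, mean_null_degree,
#'   relative) over the full node set and `setRelative` (mean over the
#'   gene set)
#' @export
relativeConnectivity <- function(network, geneset, nRandom = 1000L,
                                 seed = 1L) {
  stopifnot(is(network, "CoexNetwork"))
  if (nRandom < 1L) stop("nRandom must be >= 1")
  nodes <- sort(networkNodes(network))
  members <- intersect(geneset, nodes)
  if (!length(members)) stop("gene set does not intersect the network nodes")
  obs <- networkDegrees(network)[nodes]
  n <- length(nodes)
  m <- nrow(networkEdges(network))
  acc <- numeric(n)
  for (r in seq_len(nRandom)) {
    gr <- withSeed(seed + r, igraph::sample_gnm(n, m))
    acc <- acc + igraph::degree(gr)
  }
  meanNull <- acc / nRandom
  rel <- ifelse(meanNull > 0, obs / meanNull, NA_real_)
  perGene <- data.frame(gene = nodes, degree = as.integer(obs),
                        mean_null_degree = meanNull, relative = rel,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(perGene = perGene,
       setRelative = mean(rel[match(members, nodes)], na.rm = TRUE))
}
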