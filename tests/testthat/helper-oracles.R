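# Independent oracles and fixture builders shared across tests.

# Exact two-sided rank-sum p-value by complete enumeration of group
# assignments, computed from pairwise dominance counts (Mann-Whitney U)
# rather than rank sums, so it shares no code path with the package.
oracleRankSumP <- function(x, y) {
  v <- c(x, y)
  m <- length(x); N <- length(v)
  C <- outer(v, v, function(a, b) (a > b) + 0.5 * (a == b))
  diag(C) <- 0
  rowTot <- rowSums(C)
  idx <- combn(N, m)
  U <- colSums(matrix(rowTot[idx], nrow = m)) - choose(m, 2)
  u <- sum(rowTot[seq_len(m)]) - choose(m, 2)
  eps <- 1e-9
  min(1, 2 * min(mean(U <= u + eps), mean(U >= u - eps)))
}

# Brute-force triad enumeration over all C(n,3) node triples.
oracleTriads <- function(network) {
  e <- networkEdges(network)
  keys <- pairKeyOracle(e$gene_a, e$gene_b)
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  if (length(nodes) < 3)
    return(data.frame(gene_1 = character(), gene_2 = character(),
                      gene_3 = character(), type = character()))
  trip <- combn(nodes, 3)
  out <- lapply(seq_len(ncol(trip)), function(k) {
    t3 <- trip[, k]
    has <- c(pairKeyOracle(t3[1], t3[2]) %in% keys,
             pairKeyOracle(t3[1], t3[3]) %in% keys,
             pairKeyOracle(t3[2], t3[3]) %in% keys)
    ne <- sum(has)
    if (ne == 3)
      return(data.frame(gene_1 = t3[1], gene_2 = t3[2], gene_3 = t3[3],
                        type = "triangle"))
    if (ne == 2) {
      # center = the node on both present edges
      ends <- rbind(c(1, 2), c(1, 3), c(2, 3))[has, ]
      center <- t3[c(ends)[duplicated(c(ends))]]
      wings <- sort(setdiff(t3, center))
      return(data.frame(gene_1 = wings[1], gene_2 = center,
                        gene_3 = wings[2], type = "path"))
    }
    NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_1 = character(), gene_2 = character(),
                      gene_3 = character(), type = character())
  res
}

pairKeyOracle <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

triadKey <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$type, df$gene_1, df$gene_2, df$gene_3))
}

# Random simple graph as a CoexNetwork, sampled without igraph.
makeRandomNetwork <- function(n, m, seed) {
  nodes <- sprintf("n%03d", seq_len(n))
  ij <- combn(n, 2)
  stopifnot(m <= ncol(ij))
  pick <- withr::with_seed(seed, sample(ncol(ij), m))
  coexNetwork(data.frame(gene_a = nodes[ij[1, pick]],
                         gene_b = nodes[ij[2, pick]],
                         weight = 1, stringsAsFactors = FALSE),
              nodes = nodes)
}

# Minimal SingleCellExperiment with a cpm assay built by hand.
makeToySCE <- function(cpm, clusters, classes = NULL) {
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cpm, cpm = cpm),
    colData = S4Vectors::DataFrame(cluster = clusters,
                                   row.names = colnames(cpm)))
  if (!is.null(classes))
    S4Vectors::metadata(sce)$clusterClass <- classes
  sce
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

bestJaccard <- function(truth, modules)
  vapply(truth, function(t)
    max(vapply(modules, jaccard, numeric(1), a = t)), numeric(1))

edgeKeys <- function(network) {
  e <- networkEdges(network)
  paste(e$gene_a, e$gene_b)
}
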