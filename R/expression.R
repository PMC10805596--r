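#' Counts-per-million normalization
#'
#' Scales every cell column of the raw `"counts"` assay so it sums to 1e6
#' and stores the result as a `"cpm"` assay. Cells with zero total counts
#' stay all-zero and are reported in a warning and in
#' `metadata()$zeroCountCells`. Re-normalizing an already normalized object
#' is an error (double normalization would silently corrupt units).
#'
#' @param sce a `SingleCellExperiment` with a raw `"counts"` assay
#' @return the object with an added `"cpm"` assay
#' @export
cpmNormalize <- function(sce) {
  anames <- SummarizedExperiment::assayNames(sce)
  if (!"counts" %in% anames) stop("no 'counts' assay to normalize")
  if ("cpm" %in% anames)
    stop("object already carries a 'cpm' assay; refusing to normalize twice")
  m <- SummarizedExperiment::assay(sce, "counts")
  libs <- Matrix::colSums(m)
  zero <- colnames(sce)[libs == 0]
  if (length(zero))
    warning(sprintf("%d cell(s) with zero total counts left all-zero: %s",
                    length(zero), paste(utils::head(zero, 5), collapse = ", ")))
  scale <- ifelse(libs > 0, 1e6 / libs, 0)
  cpm <- m %*% Matrix::Diagonal(x = scale)
  dimnames(cpm) <- dimnames(m)
  SummarizedExperiment::assay(sce, "cpm") <- cpm
  S4Vectors::metadata(sce)$zeroCountCells <- zero
  sce
}

#' Mean CPM per cluster
#'
#' @param sce a normalized `SingleCellExperiment` (after [cpmNormalize()])
#' @param assayName assay to average, default `"cpm"`
#' @return numeric matrix genes x clusters, columns in sorted cluster order
#' @export
clusterProfiles <- function(sce, assayName = "cpm") {
  if (!assayName %in% SummarizedExperiment::assayNames(sce))
    stop(sprintf("no '%s' assay; run cpmNormalize() first", assayName))
  m <- SummarizedExperiment::assay(sce, assayName)
  cl <- clusterAssignments(sce)
  lev <- sort(unique(cl))
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = match(cl, lev),
                              x = 1, dims = c(length(cl), length(lev)))
  prof <- as.matrix(m %*% ind %*% Matrix::Diagonal(x = 1 / tabulate(
    match(cl, lev), length(lev))))
  dimnames(prof) <- list(rownames(sce), lev)
  prof
}

#' Pairwise differential expression by rank-sum test
#'
#' Per gene: two-sided Wilcoxon-Mann-Whitney rank-sum test on CPM values
#' (exact enumeration when both groups have at most 8 cells, otherwise
#' normal approximation with tie correction), log2 fold change of group
#' means with pseudocount 1 CPM, and multiple-testing adjusted p-values.
#' A gene is flagged significant at adjusted p < 0.05 and |log2FC| > 0.25.
#'
#' @param sce a normalized `SingleCellExperiment`
#' @param cellsA,cellsB disjoint nonempty cell-identifier vectors
#' @param adjust `"bonferroni"` (default) or `"BH"`
#' @param assayName assay to test, default `"cpm"`
#' @return data.frame: gene, log2fc, stat, p, p_adj, direction, significant
#' @export
differentialExpression <- function(sce, cellsA, cellsB,
                                   adjust = c("bonferroni", "BH"),
                                   assayName = "cpm") {
  adjust <- match.arg(adjust)
  if (length(cellsA) == 0L || length(cellsB) == 0L)
    stop("both cell groups must be nonempty")
  if (length(intersect(cellsA, cellsB)))
    stop("cell groups must be disjoint")
  missing <- setdiff(c(cellsA, cellsB), colnames(sce))
  if (length(missing))
    stop(sprintf("unknown cell identifier '%s'", missing[1L]))
  m <- SummarizedExperiment::assay(sce, assayName)
  A <- as.matrix(m[, cellsA, drop = FALSE])
  B <- as.matrix(m[, cellsB, drop = FALSE])
  log2fc <- log2((rowMeans(A) + 1) / (rowMeans(B) + 1))
  res <- t(vapply(seq_len(nrow(m)), function(g) {
    t <- rankSumTest(A[g, ], B[g, ])
    c(t$statistic, t$p.value)
  }, numeric(2)))
  padj <- p.adjust(res[, 2], method = adjust)
  data.frame(
    gene = rownames(m),
    log2fc = log2fc,
    stat = res[, 1],
    p = res[, 2],
    p_adj = padj,
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none")),
    significant = padj < 0.05 & abs(log2fc) > 0.25,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent of genes differentially expressed
#'
#' Fraction (in percent) of the tested gene set that is significant and up-
#' or downregulated.
#'
#' @param de a data.frame from [differentialExpression()]
#' @return named numeric `c(pct_up, pct_down)`
#' @export
percentDE <- function(de) {
  if (is.null(de) || nrow(de) == 0L) stop("empty gene set")
  c(pct_up = 100 * mean(de$significant & de$direction == "up"),
    pct_down = 100 * mean(de$significant & de$direction == "down"))
}

#' Twofold-versus-median variability flags
#'
#' A gene is flagged `"up"` in a cluster when its mean CPM there exceeds
#' twice its median over all cluster means, `"down"` when below half that
#' median, `"neutral"` otherwise. Flags are invariant under joint positive
#' rescaling of all clusters. Genes with an all-zero profile are neutral
#' everywhere and reported in `attr(, "allZeroGenes")`.
#'
#' @param profiles genes x clusters matrix from [clusterProfiles()]
#' @return character matrix of the same shape with entries up/down/neutral
#' @export
variabilityFlags <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least 2 clusters")
  med <- apply(profiles, 1L, median)
  up <- profiles > 2 * med
  down <- profiles < 0.5 * med
  flags <- matrix("neutral", nrow(profiles), ncol(profiles),
                  dimnames = dimnames(profiles))
  flags[up] <- "up"
  flags[down] <- "down"
  attr(flags, "allZeroGenes") <- rownames(profiles)[rowSums(profiles) == 0]
  flags
}

#' Per-gene percentage of variable clusters by cell class
#'
#' For each gene and cell class, the percentage of that class's clusters in
#' which the gene is flagged variable (up or down by default; restrict with
#' `direction`).
#'
#' @param flags matrix from [variabilityFlags()]
#' @param classes named character vector cluster -> class
#' @param geneset optional gene identifiers to restrict to
#' @param direction `"both"` (default), `"up"` or `"down"`
#' @return numeric matrix genes x classes of percentages
#' @export
variabilityPercentages <- function(flags, classes, geneset = NULL,
                                   direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  want <- switch(direction, both = c("up", "down"), up = "up", down = "down")
  if (!is.null(geneset)) {
    keep <- intersect(rownames(flags), geneset)
    flags <- flags[keep, , drop = FALSE]
  }
  cls <- sort(unique(unname(classes[colnames(flags)])))
  out <- sapply(cls, function(cc) {
    cols <- colnames(flags)[classes[colnames(flags)] == cc]
    100 * rowMeans(matrix(flags[, cols, drop = FALSE] %in% want,
                          nrow = nrow(flags)))
  })
  out <- matrix(out, nrow = nrow(flags),
                dimnames = list(rownames(flags), cls))
  out
}

#' Cumulative expression of gene families across clusters
#'
#' Sums member-gene mean CPM per cluster for every set in the catalog
#' (top-level sets and subfamilies alike); a proxy for the total capacity
#' of a functional system, e.g. folding or degradation. Families with no
#' gene present in the matrix are reported in a warning and omitted.
#'
#' @param profiles genes x clusters matrix from [clusterProfiles()]
#' @param catalog a [GeneSetCatalog-class]
#' @return numeric matrix families x clusters
#' @export
familyCumulativeExpression <- function(profiles, catalog) {
  stopifnot(is(catalog, "GeneSetCatalog"))
  sets <- geneSets(catalog)
  if (!length(sets)) stop("catalog has no gene sets")
  rows <- list()
  absent <- character()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], rownames(profiles))
    if (!length(members)) { absent <- c(absent, nm); next }
    rows[[nm]] <- colSums(profiles[members, , drop = FALSE])
  }
  if (length(absent))
    warning(sprintf("families with no genes in the matrix omitted: %s",
                    paste(absent, collapse = ", ")))
  if (!length(rows)) stop("no catalog family has genes in the matrix")
  do.call(rbind, rows)
}

#' Proteostasis composition statistics per cluster
#'
#' The proteostasis-network (PN) fraction is the cumulative chaperone plus
#' Ubiquitin-enzyme expression over the total expression of the cluster;
#' the chaperone/Ub ratio compares folding to degradation capacity. Both
#' are ratios and therefore invariant under rescaling a cluster's profile.
#'
#' @param profiles genes x clusters matrix from [clusterProfiles()]
#' @param catalog a [GeneSetCatalog-class] containing sets named
#'   `chaperones` and `ubiquitin_enzymes`
#' @param classes optional named cluster -> class vector to annotate rows
#' @return data.frame: cluster, (class), pn_fraction, chap_ub_ratio
#' @export
compositionStats <- function(profiles, catalog, classes = NULL) {
  sets <- geneSets(catalog)
  need <- c("chaperones", "ubiquitin_enzymes")
  if (!all(need %in% names(sets)))
    stop("catalog must contain sets 'chaperones' and 'ubiquitin_enzymes'")
  chap <- colSums(profiles[intersect(sets$chaperones, rownames(profiles)), ,
                           drop = FALSE])
  ub <- colSums(profiles[intersect(sets$ubiquitin_enzymes, rownames(profiles)), ,
                         drop = FALSE])
  total <- colSums(profiles)
  out <- data.frame(cluster = colnames(profiles),
                    pn_fraction = (chap + ub) / total,
                    chap_ub_ratio = chap / ub,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(classes)) out$class <- unname(classes[out$cluster])
  out
}

#' Hierarchical clustering of clusters by cosine distance
#'
#' Agglomerative average-linkage clustering of cluster columns using cosine
#' distance, optionally restricted to a gene set. Cosine distance is
#' scale-invariant, so library-size differences between clusters do not
#' reshape the dendrogram.
#'
#' @param profiles genes x clusters matrix from [clusterProfiles()]
#' @param geneset optional gene identifiers to restrict to
#' @return an `hclust` object over clusters
#' @export
cosineLinkage <- function(profiles, geneset = NULL) {
  if (ncol(profiles) < 2L) stop("need at least 2 clusters")
  X <- profiles
  if (!is.null(geneset))
    X <- X[intersect(rownames(X), geneset), , drop = FALSE]
  nrm <- sqrt(colSums(X^2))
  zero <- colnames(X)[nrm == 0]
  if (length(zero))
    stop(sprintf("cosine distance undefined for zero-vector cluster '%s'",
                 zero[1L]))
  Xn <- sweep(X, 2L, nrm, "/")
  D <- 1 - crossprod(Xn)
  D[D < 0] <- 0
  hclust(as.dist(D), method = "average")
}

#' Write a dendrogram as Newick text
#' @param hc an `hclust` object (e.g. from [cosineLinkage()])
#' @param path output path
#' @return invisibly, `path`
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Between-class comparison of variability percentages
#'
#' For every pair of cell classes, a two-sided Wilcoxon-Mann-Whitney test
#' comparing the distributions of per-gene variability percentages
#' (columns of [variabilityPercentages()]). Identical constant
#' distributions give p = 1, not an error.
#'
#' @param varPct genes x classes matrix from [variabilityPercentages()]
#' @return data.frame: class_a, class_b, p
#' @export
classVariabilityComparison <- function(varPct) {
  if (nrow(varPct) < 2L) stop("need at least 2 genes per set")
  cls <- colnames(varPct)
  ij <- indexPairs(length(cls))
  data.frame(
    class_a = cls[ij$i], class_b = cls[ij$j],
    p = mapply(function(a, b)
      rankSumTest(varPct[, a], varPct[, b])$p.value, ij$i, ij$j),
    row.names = NULL, stringsAsFactors = FALSE)
}
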