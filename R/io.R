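stopIO <- function(path, line, fmt, ...) {
  where <- if (is.null(line)) path else sprintf("%s, line %d", path, line)
  stop(sprintf("%s: %s", where, sprintf(fmt, ...)), call. = FALSE)
}

#' Read a raw-count expression matrix with sidecar identifier files
#'
#' Expects a MatrixMarket coordinate file (genes as rows, 1-based
#' coordinates per the format standard), a gene identifier file (one per
#' line), a cell file (`cell_id TAB cluster_id`) and optionally a cluster
#' class file (`cluster_id TAB class`). All validation is strict: dimension
#' mismatches, duplicate identifiers and negative values are rejected with
#' the offending identifier or coordinate named, never repaired.
#'
#' @param matrixPath,genesPath,cellsPath,clustersPath input file paths;
#'   `clustersPath` may be `NULL` if no class annotation exists.
#' @return a `SingleCellExperiment` with a raw `"counts"` assay.
#' @export
readExpression <- function(matrixPath, genesPath, cellsPath,
                           clustersPath = NULL) {
  for (p in c(matrixPath, genesPath, cellsPath, clustersPath))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  m <- methods::as(Matrix::readMM(matrixPath), "CsparseMatrix")
  if (any(m@x < 0)) {
    bad <- which(m@x < 0)[1L]
    col <- findInterval(bad - 0.5, m@p)
    stopIO(matrixPath, NULL, "negative value at (row %d, col %d)",
           m@i[bad] + 1L, col)
  }
  genes <- readLines(genesPath)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes))
    stopIO(genesPath, which(duplicated(genes))[1L],
           "duplicate gene identifier '%s'", genes[duplicated(genes)][1L])
  cells <- read.delim(cellsPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(cells) < 2L)
    stopIO(cellsPath, NULL, "expected two tab-separated columns (cell_id, cluster_id)")
  names(cells)[1:2] <- c("cell_id", "cluster_id")
  if (anyDuplicated(cells$cell_id))
    stopIO(cellsPath, which(duplicated(cells$cell_id))[1L],
           "duplicate cell identifier '%s'",
           cells$cell_id[duplicated(cells$cell_id)][1L])
  if (nrow(m) != length(genes))
    stopIO(matrixPath, NULL, "matrix has %d rows but %s lists %d genes",
           nrow(m), genesPath, length(genes))
  if (ncol(m) != nrow(cells))
    stopIO(matrixPath, NULL, "matrix has %d columns but %s lists %d cells",
           ncol(m), cellsPath, nrow(cells))
  dimnames(m) <- list(genes, cells$cell_id)
  meta <- list()
  if (!is.null(clustersPath)) {
    cl <- read.delim(clustersPath, header = FALSE, stringsAsFactors = FALSE)
    names(cl)[1:2] <- c("cluster_id", "class")
    if (anyDuplicated(cl$cluster_id))
      stopIO(clustersPath, which(duplicated(cl$cluster_id))[1L],
             "duplicate cluster identifier '%s'",
             cl$cluster_id[duplicated(cl$cluster_id)][1L])
    missing <- setdiff(unique(cells$cluster_id), cl$cluster_id)
    if (length(missing))
      stopIO(clustersPath, NULL, "cluster '%s' has no class assignment",
             missing[1L])
    bad <- setdiff(cl$class, CELL_CLASSES)
    if (length(bad))
      stopIO(clustersPath, NULL, "unknown cell class '%s'", bad[1L])
    meta$clusterClass <- setNames(cl$class, cl$cluster_id)
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cluster = cells$cluster_id,
                                   row.names = cells$cell_id))
  S4Vectors::metadata(sce) <- meta
  sce
}

#' Write a dataset as MatrixMarket plus TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, `cells.tsv`, `clusters.tsv` and (when
#' simulation ground truth is present) `truth_modules.json` into `dir`.
#' [readExpression()] on the written files reproduces the matrix exactly.
#'
#' @param sce a `SingleCellExperiment` with a `"counts"` assay
#' @param dir output directory (created if missing)
#' @return invisibly, the named vector of written paths
#' @export
writeDataset <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cells.tsv"),
             clusters = file.path(dir, "clusters.tsv"))
  Matrix::writeMM(methods::as(SummarizedExperiment::assay(sce, "counts"),
                              "generalMatrix"), paths["matrix"])
  writeLines(rownames(sce), paths["genes"])
  write.table(data.frame(colnames(sce), clusterAssignments(sce)),
              paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cc <- S4Vectors::metadata(sce)$clusterClass
  if (!is.null(cc))
    write.table(data.frame(names(cc), unname(cc)), paths["clusters"],
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  tm <- S4Vectors::metadata(sce)$truthModules
  if (!is.null(tm) && length(tm)) {
    paths["truth_modules"] <- file.path(dir, "truth_modules.json")
    jsonlite::write_json(tm, paths["truth_modules"])
  }
  invisible(paths)
}

#' Construct a validated coexpression network
#'
#' Edge endpoints are canonicalized to lexicographic order; self-edges and
#' duplicate pairs are rejected.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#' @param nodes node universe (defaults to the genes carried by edges)
#' @param meta named list of provenance fields
#' @return a [CoexNetwork-class]
#' @export
coexNetwork <- function(edges, nodes = NULL, meta = list()) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    cp <- canonicalPairs(as.character(edges$gene_a),
                         as.character(edges$gene_b))
    edges <- data.frame(gene_a = cp$a, gene_b = cp$b,
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new("CoexNetwork", nodes = as.character(nodes), edges = edges, meta = meta)
}

#' Read a network from an edge-list TSV
#'
#' The file must have a header `gene_a  gene_b  weight`. Rows are
#' canonicalized; self-edges and pairs present twice (in either order) are
#' rejected with the offending line named.
#'
#' @param path edge-list TSV path
#' @return a [CoexNetwork-class]
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(e)))
    stopIO(path, NULL, "expected columns %s", paste(need, collapse = ", "))
  self <- which(e$gene_a == e$gene_b)
  if (length(self))
    stopIO(path, self[1L] + 1L, "self-edge on '%s'", e$gene_a[self[1L]])
  cp <- canonicalPairs(e$gene_a, e$gene_b)
  dup <- which(duplicated(pairKey(cp$a, cp$b)))
  if (length(dup))
    stopIO(path, dup[1L] + 1L, "duplicate pair (%s, %s)",
           cp$a[dup[1L]], cp$b[dup[1L]])
  coexNetwork(data.frame(gene_a = cp$a, gene_b = cp$b, weight = e$weight,
                         stringsAsFactors = FALSE),
              meta = list(source = path))
}

#' Write a network as TSV (authoritative) or GraphML
#'
#' @param network a [CoexNetwork-class]
#' @param path output path
#' @param format `"tsv"` (default) or `"graphml"` for graph viewers
#' @return invisibly, `path`
#' @export
writeNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(network, "CoexNetwork"))
  if (format == "tsv") {
    write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    igraph::write_graph(asIgraph(network, weighted = TRUE), path,
                        format = "graphml")
  }
  invisible(path)
}

# igraph view of a network (all nodes, including edgeless ones).
asIgraph <- function(network, weighted = FALSE) {
  e <- networkEdges(network)
  g <- igraph::graph_from_data_frame(
    if (weighted) e else e[, c("gene_a", "gene_b")],
    directed = FALSE, vertices = sort(networkNodes(network)))
  g
}

#' Read plain-text gene sets into a catalog
#'
#' Each file contributes one set (one identifier per line); the set name is
#' the file name without extension unless `paths` is named. Subfamily
#' relations are declared through `parents`.
#'
#' @param paths character vector of file paths, optionally named
#' @param parents named character vector: subfamily set name -> parent name
#' @return a [GeneSetCatalog-class]
#' @export
readGeneSets <- function(paths, parents = character()) {
  nms <- names(paths)
  if (is.null(nms)) nms <- rep("", length(paths))
  sets <- list()
  for (k in seq_along(paths)) {
    nm <- if (nzchar(nms[k])) nms[k] else
      sub("\\.[^.]*$", "", basename(paths[k]))
    ids <- trimws(readLines(paths[k]))
    ids <- ids[nzchar(ids)]
    if (anyDuplicated(ids))
      stopIO(paths[k], which(duplicated(ids))[1L],
             "duplicate identifier '%s'", ids[duplicated(ids)][1L])
    sets[[nm]] <- ids
  }
  geneSetCatalog(sets, parents)
}

#' Construct a gene-set catalog
#' @param sets named list of character identifier vectors
#' @param parents named character vector declaring subfamily -> parent links
#' @return a [GeneSetCatalog-class]
#' @export
geneSetCatalog <- function(sets, parents = character()) {
  new("GeneSetCatalog", sets = sets,
      parents = if (length(parents)) parents else
        setNames(character(), character()))
}

#' Read a three-species orthologue table
#'
#' Tab-separated with a header of three identifier columns (reference
#' species first). Rows must be one-to-one-to-one: any duplicate within a
#' column is rejected with its line named.
#'
#' @param path orthologue TSV path
#' @param speciesNames column names to impose, default
#'   `c("human", "macaque", "mouse")`
#' @return data.frame with the three species columns
#' @export
readOrthologues <- function(path,
                            speciesNames = c("human", "macaque", "mouse")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  om <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(om) < 3L)
    stopIO(path, NULL, "expected three identifier columns")
  om <- om[, 1:3]
  names(om) <- speciesNames
  for (cl in speciesNames) {
    dup <- which(duplicated(om[[cl]]))
    if (length(dup))
      stopIO(path, dup[1L] + 1L,
             "duplicate identifier '%s' in column '%s' (map must be one-to-one)",
             om[[cl]][dup[1L]], cl)
  }
  om
}

#' Write an orthologue table
#' @param om data.frame with three identifier columns
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
writeOrthologues <- function(om, path) {
  write.table(om, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
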