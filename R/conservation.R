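validateOrthomap <- function(orthomap) {
  need <- c("human", "macaque", "mouse")
  if (!all(need %in% names(orthomap)))
    stop("orthologue map needs columns human, macaque, mouse")
  for (cl in need)
    if (anyDuplicated(orthomap[[cl]]))
      stop(sprintf("orthologue map column '%s' has duplicates (must be one-to-one)",
                   cl))
  orthomap
}

# Translate a species network's edges into reference (human) identifiers,
# keeping only edges whose both endpoints carry a complete orthologue triple.
mappedEdgeKeys <- function(edges, toHuman) {
  a <- toHuman[edges$gene_a]
  b <- toHuman[edges$gene_b]
  ok <- !is.na(a) & !is.na(b)
  cp <- canonicalPairs(a[ok], b[ok])
  pairKey(cp$a, cp$b)
}

#' Conserved coexpression interactions across three species
#'
#' An interaction is conserved when its orthologue-mapped counterpart is
#' present in all three species-specific networks. Genes without a complete
#' orthologue triple are ignored. The result is reported in reference
#' (human) identifiers; weights are taken from the human network.
#'
#' @param networks named list of three [CoexNetwork-class] objects
#'   (`human`, `macaque`, `mouse`)
#' @param orthomap data.frame with one-to-one columns `human`, `macaque`,
#'   `mouse`
#' @return a [CoexNetwork-class] of conserved edges; nodes are the
#'   orthologue-mapped genes common to all three networks
#' @export
conservedEdges <- function(networks, orthomap) {
  need <- c("human", "macaque", "mouse")
  if (!all(need %in% names(networks)))
    stop("networks must be a named list with human, macaque, mouse")
  orthomap <- validateOrthomap(orthomap)
  keys <- lapply(need, function(sp) {
    toHuman <- setNames(orthomap$human, orthomap[[sp]])
    mappedEdgeKeys(networkEdges(networks[[sp]]), toHuman)
  })
  conserved <- Reduce(intersect, keys)
  he <- networkEdges(networks$human)
  # universe: orthologue-mapped genes present as nodes in every species network
  uni <- orthomap$human
  for (sp in need) {
    mapped <- setNames(orthomap$human, orthomap[[sp]])
    uni <- intersect(uni, unname(mapped[intersect(names(mapped),
                                                  networkNodes(networks[[sp]]))]))
  }
  if (length(conserved)) {
    parts <- strsplit(conserved, "\t", fixed = TRUE)
    ed <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                     gene_b = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
    # per-row human edge keys (NA for rows outside the orthologue set) so
    # match() returns row indices into the human edge table
    th <- setNames(orthomap$human, orthomap$human)
    ha <- unname(th[he$gene_a]); hb <- unname(th[he$gene_b])
    cp <- canonicalPairs(ha, hb)
    hk <- ifelse(is.na(cp$a) | is.na(cp$b), NA_character_,
                 pairKey(cp$a, cp$b))
    ed$weight <- he$weight[match(conserved, hk)]
  } else {
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  }
  coexNetwork(ed, nodes = sort(uni),
              meta = list(species = need, n_universe = length(uni)))
}

#' Degree-preserving randomization of a network
#'
#' Repeated double-edge swaps (10 times the edge count attempted swaps,
#' rejecting any swap creating a self-loop or duplicate edge) produce a
#' simple graph with exactly the original degree sequence. Graphs whose
#' degree sequence admits no legal swap (e.g. a triangle) come back
#' unchanged with a message. Deterministic given `seed`.
#'
#' @param network a [CoexNetwork-class] with at least 2 edges
#' @param seed RNG seed
#' @return a randomized [CoexNetwork-class] (weights dropped)
#' @export
degreePreservingRandomize <- function(network, seed = 1L) {
  stopifnot(is(network, "CoexNetwork"))
  e <- networkEdges(network)
  if (nrow(e) < 2L) stop("need at least 2 edges to attempt swaps")
  g <- asIgraph(network)
  rg <- withSeed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = 10L * nrow(e))))
  ne <- igraph::as_data_frame(rg, what = "edges")
  names(ne) <- c("gene_a", "gene_b")
  ne$weight <- NA_real_
  out <- coexNetwork(ne, nodes = networkNodes(network),
                     meta = c(networkMeta(network),
                              list(randomized = TRUE, seed = seed)))
  if (setequal(pairKey(e$gene_a, e$gene_b),
               pairKey(out@edges$gene_a, out@edges$gene_b)))
    message("degree sequence admits no legal swap; network returned unchanged")
  out
}

#' Conservation score from observed and null conserved counts
#'
#' The percent excess of truly conserved interactions over the
#' randomization null: `((nTrue / nullMean) - 1) * 100`. `NA` when the
#' null mean is zero (the score is undefined, not infinite).
#'
#' @param nTrue observed conserved interaction count
#' @param nullMean mean conserved count over null replicates
#' @return numeric score in percent
#' @export
conservationScore <- function(nTrue, nullMean) {
  ifelse(is.finite(nullMean) & nullMean > 0,
         (nTrue / nullMean - 1) * 100, NA_real_)
}

#' Cross-species conservation analysis with a degree-preserving null
#'
#' Counts conserved interactions in the real species networks, then for
#' each of `nRandom` replicates independently randomizes all three species
#' networks degree-preservingly (replicate r uses seed + r) and recounts.
#' Reports the conservation score, per-gene observed and expected (mean
#' over replicates) conserved degrees, their ratio, and an add-one
#' empirical p-value; a gene is significantly conserved at empirical
#' p < 0.05.
#'
#' @param networks named list of [CoexNetwork-class] (`human`, `macaque`,
#'   `mouse`)
#' @param orthomap one-to-one orthologue data.frame
#' @param nRandom number of null replicates (default 1000)
#' @param seed base RNG seed
#' @return a [ConservationResult-class]
#' @export
conservationAnalysis <- function(networks, orthomap, nRandom = 1000L,
                                 seed = 1L) {
  if (nRandom < 1L) stop("nRandom must be >= 1")
  orthomap <- validateOrthomap(orthomap)
  observed <- conservedEdges(networks, orthomap)
  uni <- networkNodes(observed)
  nTrue <- nrow(networkEdges(observed))
  obsDeg <- networkDegrees(observed)[uni]
  need <- c("human", "macaque", "mouse")
  graphs <- lapply(networks[need], asIgraph)
  toHuman <- lapply(need, function(sp)
    setNames(orthomap$human, orthomap[[sp]]))
  names(toHuman) <- need
  nullCounts <- numeric(nRandom)
  nullKeys <- vector("list", nRandom)
  geDeg <- matrix(0L, length(uni), nRandom, dimnames = list(uni, NULL))
  for (r in seq_len(nRandom)) {
    keys <- withSeed(seed + r, {
      lapply(need, function(sp) {
        rg <- igraph::rewire(
          graphs[[sp]],
          igraph::keeping_degseq(loops = FALSE,
                                 niter = 10L * igraph::ecount(graphs[[sp]])))
        ne <- igraph::as_data_frame(rg, what = "edges")
        names(ne) <- c("gene_a", "gene_b")
        mappedEdgeKeys(ne, toHuman[[sp]])
      })
    })
    cons <- Reduce(intersect, keys)
    nullCounts[r] <- length(cons)
    nullKeys[[r]] <- cons
    if (length(cons)) {
      gtab <- table(unlist(strsplit(cons, "\t", fixed = TRUE)))
      hit <- intersect(names(gtab), uni)
      geDeg[hit, r] <- as.integer(gtab[hit])
    }
  }
  expected <- rowMeans(geDeg)
  empP <- (1 + rowSums(geDeg >= obsDeg)) / (1 + nRandom)
  perGene <- data.frame(
    gene = uni,
    observed = as.integer(obsDeg),
    expected = expected,
    ratio = ifelse(expected > 0, obsDeg / expected, NA_real_),
    empirical_p = empP,
    significant = empP < 0.05,
    row.names = NULL, stringsAsFactors = FALSE)
  new("ConservationResult",
      conservedEdges = observed, nTrue = as.integer(nTrue),
      nullCounts = nullCounts,
      score = conservationScore(nTrue, mean(nullCounts)),
      perGene = perGene, nullEdgeKeys = nullKeys,
      meta = list(n_random = nRandom, seed = seed,
                  n_universe = length(uni)))
}

#' Conserved-interaction density of gene sets versus the null
#'
#' Observed density is the fraction of a set's possible within-set pairs
#' that are conserved edges; null densities come from the identical
#' randomization replicates stored in the [ConservationResult-class], and
#' relative density is observed over the null mean. Sets with fewer than 2
#' genes in the conservation universe are rejected.
#'
#' @param result a [ConservationResult-class]
#' @param genesets named list of gene-identifier vectors (reference ids)
#' @return data.frame: set, size, observed_density, mean_null_density,
#'   relative_density, empirical_p
#' @export
genesetDensity <- function(result, genesets) {
  stopifnot(is(result, "ConservationResult"))
  if (!length(genesets) || is.null(names(genesets)))
    stop("genesets must be a named list")
  uni <- networkNodes(conservedNetwork(result))
  e <- networkEdges(conservedNetwork(result))
  obsKeys <- pairKey(e$gene_a, e$gene_b)
  nullKeys <- result@nullEdgeKeys
  nRandom <- length(nullKeys)
  rows <- lapply(names(genesets), function(nm) {
    s <- intersect(genesets[[nm]], uni)
    if (length(s) < 2L)
      stop(sprintf("gene set '%s' has fewer than 2 genes in the universe", nm))
    npairs <- choose(length(s), 2)
    inSet <- function(keys) {
      if (!length(keys)) return(0L)
      parts <- strsplit(keys, "\t", fixed = TRUE)
      a <- vapply(parts, `[`, "", 1L)
      b <- vapply(parts, `[`, "", 2L)
      sum(a %in% s & b %in% s)
    }
    obs <- inSet(obsKeys) / npairs
    nulls <- vapply(nullKeys, inSet, integer(1)) / npairs
    mn <- mean(nulls)
    data.frame(set = nm, size = length(s), observed_density = obs,
               mean_null_density = mn,
               relative_density = if (obs == 0) 0 else
                 if (mn > 0) obs / mn else NA_real_,
               empirical_p = (1 + sum(nulls >= obs)) / (1 + nRandom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
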