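test_that("fold-change profiles have the pairwise length and exact values", {
  prof <- matrix(c(3, 7, 15), 1, dimnames = list("g1", c("c1", "c2", "c3")))
  prof <- rbind(prof, g2 = c(5, 5, 5))
  fcp <- foldChangeProfiles(prof)
  expect_equal(unname(profileMatrix(fcp)["g1", ]), c(-1, -2, -1))
  expect_equal(unname(profileMatrix(fcp)["g2", ]), c(0, 0, 0))
  # 131 clusters give vectors of length 131*130/2
  big <- matrix(withr::with_seed(1, runif(2 * 131)), 2,
                dimnames = list(c("a", "b"), sprintf("k%03d", 1:131)))
  expect_equal(ncol(profileMatrix(foldChangeProfiles(big))), 8515)
  expect_error(foldChangeProfiles(prof[, 1:2]), "3 clusters")
})

test_that("swapping two clusters negates the corresponding profile entry", {
  prof <- matrix(withr::with_seed(2, rexp(5 * 4, 1 / 50)), 5,
                 dimnames = list(paste0("g", 1:5), paste0("k", 1:4)))
  f12 <- profileMatrix(foldChangeProfiles(prof))[, 1]        # pair (k1,k2)
  swapped <- prof[, c(2, 1, 3, 4)]
  colnames(swapped) <- colnames(prof)
  g12 <- profileMatrix(foldChangeProfiles(swapped))[, 1]
  expect_equal(g12, -f12)
})

test_that("all-zero genes are dropped from profiles and reported", {
  prof <- rbind(g1 = c(1, 2, 3), g2 = c(0, 0, 0))
  colnames(prof) <- paste0("k", 1:3)
  fcp <- foldChangeProfiles(prof)
  expect_equal(droppedGenes(fcp), "g2")
  expect_equal(rownames(profileMatrix(fcp)), "g1")
})

test_that("edge calling returns exactly the ceiling-quantile count", {
  for (g in c(10, 47, 120)) {
    prof <- matrix(withr::with_seed(g, rnorm(g * 12)), g,
                   dimnames = list(sprintf("g%03d", 1:g), sprintf("k%02d", 1:12)))
    fcp <- foldChangeProfiles(abs(prof) + 1)
    for (q in c(0.05, 0.20)) {
      nw <- coexpressionEdges(fcp, quantile = q)
      expect_equal(nrow(networkEdges(nw)), ceiling(q * choose(g, 2)))
    }
  }
})

test_that("retained edges are exactly the top correlations, ranked by signed r", {
  prof <- matrix(withr::with_seed(5, rnorm(10 * 8)), 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("k%02d", 1:8)))
  fcp <- foldChangeProfiles(abs(prof) + 1)
  nw <- coexpressionEdges(fcp, quantile = 0.05)   # ceil(0.05*45) = 3 edges
  R <- cor(t(profileMatrix(fcp)))
  vals <- sort(R[upper.tri(R)], decreasing = TRUE)
  expect_equal(nrow(networkEdges(nw)), 3)
  expect_equal(sort(networkEdges(nw)$weight, decreasing = TRUE), vals[1:3])
  # identical profiles always make the cut
  prof2 <- rbind(prof, twin1 = prof[1, ] + 100, twin2 = prof[1, ] + 100)
  fcp2 <- foldChangeProfiles(abs(prof2[, ]) + 1)
  expect_true(any(grepl("twin", edgeKeys(coexpressionEdges(fcp2, 0.05)))))
})

test_that("lower quantiles call nested edge subsets", {
  prof <- matrix(withr::with_seed(8, rnorm(40 * 10)), 40,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("k%02d", 1:10)))
  fcp <- foldChangeProfiles(abs(prof) + 1)
  e05 <- edgeKeys(coexpressionEdges(fcp, 0.05))
  e20 <- edgeKeys(coexpressionEdges(fcp, 0.20))
  expect_true(all(e05 %in% e20))
})

test_that("zero-variance profiles are excluded from pairing and reported", {
  prof <- rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(8, 4, 2),
                flat = c(3, 3, 3))
  colnames(prof) <- paste0("k", 1:3)
  fcp <- foldChangeProfiles(prof)
  nw <- coexpressionEdges(fcp, quantile = 0.5)
  expect_equal(networkMeta(nw)$excluded_zero_variance, "flat")
  expect_false("flat" %in% networkNodes(nw))
})

test_that("the overexpression filter keeps the boundary and drops below it", {
  cpm <- Matrix::Matrix(rbind(hit = c(120, 120, 100, 100),
                              miss = c(119, 119, 100, 100),
                              flat0 = c(0, 0, 0, 0)), sparse = TRUE)
  colnames(cpm) <- paste0("c", 1:4)
  sce <- makeToySCE(cpm, rep("k1", 4))
  sel <- selectiveGenes(sce, c("c1", "c2"), c("c3", "c4"), minRatio = 1.2)
  expect_true("hit" %in% sel)
  expect_false("miss" %in% sel)
  expect_false("flat0" %in% sel)
  sel1 <- selectiveGenes(sce, c("c1", "c2"), c("c3", "c4"), minRatio = 1)
  expect_setequal(as.character(sel1), c("hit", "miss"))
  expect_error(selectiveGenes(sce, c("c1"), c("c1", "c4")), "disjoint")
})

test_that("triads are enumerated exactly on canonical small graphs", {
  tri <- coexNetwork(data.frame(gene_a = c("A", "B", "A"),
                                gene_b = c("B", "C", "C"), weight = 1))
  t1 <- enumerateTriads(tri)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$type, "triangle")
  path <- coexNetwork(data.frame(gene_a = c("A", "B"),
                                 gene_b = c("B", "C"), weight = 1))
  t2 <- enumerateTriads(path)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$type, "path")
  expect_equal(t2$gene_2, "B")
  # motif filtering the bare path leaves nothing
  filtered <- motifFilter(path)
  expect_equal(nrow(networkEdges(filtered)), 0)
  expect_length(networkNodes(filtered), 0)
  # the triangle survives whole
  expect_setequal(networkNodes(motifFilter(tri)), c("A", "B", "C"))
})

test_that("triad enumeration matches brute force on random graphs", {
  for (seed in 1:5) {
    n <- 10 + 5 * seed
    nw <- makeRandomNetwork(n, min(3 * n, choose(n, 2)), seed = seed)
    expect_identical(triadKey(enumerateTriads(nw)), triadKey(oracleTriads(nw)))
  }
})

test_that("module detection separates components and finds planted blocks", {
  twoTri <- coexNetwork(data.frame(
    gene_a = c("A", "B", "A", "X", "Y", "X"),
    gene_b = c("B", "C", "C", "Y", "Z", "Z"), weight = 1))
  part <- detectModules(twoTri)
  expect_equal(length(unique(moduleAssignments(part))), 2)
  expect_equal(length(unique(moduleAssignments(part)[c("A", "B", "C")])), 1)
  clique <- makeRandomNetwork(6, 15, seed = 1)  # K6
  expect_equal(length(unique(moduleAssignments(detectModules(clique)))), 1)
  expect_error(detectModules(coexNetwork(NULL, nodes = c("A", "B"))),
               "edgeless")
  # planted two-block graph: 20+20 nodes, p_in 0.8, p_out 0.05
  nodes <- sprintf("v%02d", 1:40)
  ij <- t(combn(40, 2))
  pin <- (ij[, 1] <= 20) == (ij[, 2] <= 20)
  keep <- withr::with_seed(99, runif(nrow(ij)) < ifelse(pin, 0.8, 0.05))
  nw <- coexNetwork(data.frame(gene_a = nodes[ij[keep, 1]],
                               gene_b = nodes[ij[keep, 2]], weight = 1),
                    nodes = nodes)
  mem <- moduleAssignments(detectModules(nw))
  truth <- rep(1:2, each = 20)[match(names(mem), nodes)]
  agree <- max(mean((mem == 1) == (truth == 1)),
               mean((mem == 1) == (truth == 2)))
  expect_gte(agree, 0.95)
})

test_that("relative connectivity recovers the star-center excess degree", {
  star <- coexNetwork(data.frame(gene_a = rep("hub", 9),
                                 gene_b = sprintf("s%d", 1:9), weight = 1))
  rc <- relativeConnectivity(star, "hub", nRandom = 400, seed = 3)
  hub <- rc$perGene[rc$perGene$gene == "hub", ]
  expect_equal(hub$degree, 9)
  expect_equal(hub$relative, 5, tolerance = 0.1)
  expect_equal(rc$setRelative, hub$relative)
  expect_error(relativeConnectivity(star, "absent", nRandom = 10),
               "does not intersect")
})

test_that("a uniform random network has relative connectivity near one", {
  nw <- makeRandomNetwork(50, 150, seed = 12)
  rc <- relativeConnectivity(nw, networkNodes(nw), nRandom = 500, seed = 5)
  expect_equal(rc$setRelative, 1, tolerance = 0.05)
})
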