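toyCounts <- function() {
  m <- Matrix::Matrix(c(2, 3, 5, 0, 0, 0, 1, 1, 2), 3, 3, sparse = TRUE)
  dimnames(m) <- list(c("g1", "g2", "g3"), c("c1", "c2", "c3"))
  m
}

test_that("CPM normalization scales columns to one million and flags empties", {
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = toyCounts()),
    colData = S4Vectors::DataFrame(cluster = c("k1", "k1", "k2"),
                                   row.names = c("c1", "c2", "c3")))
  expect_warning(norm <- cpmNormalize(sce), "zero total counts")
  cpm <- SummarizedExperiment::assay(norm, "cpm")
  expect_equal(unname(cpm[, "c1"]), c(200000, 300000, 500000))
  expect_equal(sum(cpm[, "c2"]), 0)
  cs <- Matrix::colSums(cpm)[c("c1", "c3")]
  expect_true(all(abs(cs - 1e6) <= 1e-9 * 1e6))
  expect_error(cpmNormalize(norm), "twice")
})

test_that("rank-sum DE matches symmetry and the exact small-sample tail", {
  cpm <- Matrix::Matrix(rbind(g1 = c(10, 11, 12, 0, 0, 0),
                              g2 = c(5, 5, 5, 5, 5, 5)), sparse = TRUE)
  colnames(cpm) <- paste0("c", 1:6)
  sce <- makeToySCE(cpm, rep("k1", 6))
  de <- differentialExpression(sce, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(de$log2fc[1], log2(12) - log2(1))
  expect_equal(de$p[1], 2 / 20)
  expect_equal(de$log2fc[2], 0)
  expect_equal(de$p[2], 1)
  expect_error(differentialExpression(sce, character(), paste0("c", 4:6)),
               "nonempty")
  expect_error(differentialExpression(sce, paste0("c", 1:3), paste0("c", 3:6)),
               "disjoint")
})

test_that("DE p-values agree with the enumeration oracle, ties included", {
  withr::with_seed(42, {
    for (m in c(2, 4, 7)) {
      for (n in c(3, 6, 8)) {
        x <- sample(0:6, m, replace = TRUE)
        y <- sample(0:6, n, replace = TRUE)
        expect_equal(rankSumTest(x, y)$p.value, oracleRankSumP(x, y),
                     tolerance = 1e-12,
                     label = sprintf("p for m=%d n=%d", m, n))
      }
    }
  })
})

test_that("percent DE is antisymmetric between the two group orders", {
  cfg <- simulationConfig(nGenes = 80, nCells = 180, nClusters = 3,
                          overexpressedSets = list(
                            list(genes = 1:15, class = "Exc", fold = 3)),
                          seed = 21)
  ds <- cpmNormalize(simulateDataset(cfg))
  a <- cellsOfClass(ds, "Exc"); b <- cellsOfClass(ds, "non")
  deAB <- differentialExpression(ds, a, b)
  deBA <- differentialExpression(ds, b, a)
  pAB <- percentDE(deAB); pBA <- percentDE(deBA)
  expect_equal(unname(pAB["pct_up"]), unname(pBA["pct_down"]))
  expect_equal(unname(pAB["pct_down"]), unname(pBA["pct_up"]))
  expect_lte(pAB["pct_up"] + pAB["pct_down"], 100)
  expect_gt(pAB["pct_up"], 0)  # planted overexpression must surface
  expect_error(percentDE(deAB[0, ]), "empty")
})

test_that("twofold-versus-median flags follow the rule and are scale-free", {
  prof <- rbind(gA = c(1, 1, 1, 9), gB = c(4, 4, 4, 4), gC = c(0, 0, 0, 0))
  colnames(prof) <- paste0("k", 1:4)
  fl <- variabilityFlags(prof)
  expect_equal(unname(fl["gA", ]), c("neutral", "neutral", "neutral", "up"))
  expect_equal(unname(fl["gB", ]), rep("neutral", 4))
  expect_equal(attr(fl, "allZeroGenes"), "gC")
  expect_equal(variabilityFlags(prof * 7)[, ], fl[, ])
  classes <- setNames(rep("Exc", 4), colnames(prof))
  vp <- variabilityPercentages(fl, classes)
  expect_equal(unname(vp["gA", "Exc"]), 25)
  expect_equal(unname(vp["gB", "Exc"]), 0)
})

test_that("family summaries and composition ratios behave as ratios should", {
  prof <- rbind(chap1 = c(10, 20), chap2 = c(5, 5), ub1 = c(10, 10),
                other = c(100, 100))
  colnames(prof) <- c("k1", "k2")
  cat1 <- geneSetCatalog(list(chaperones = c("chap1", "chap2"),
                              ubiquitin_enzymes = "ub1",
                              singleton = "chap2",
                              ghost = "absent"))
  expect_warning(fam <- familyCumulativeExpression(prof, cat1), "ghost")
  expect_equal(unname(fam["singleton", ]), unname(prof["chap2", ]))
  expect_equal(unname(fam["chaperones", ]), c(15, 25))
  comp <- compositionStats(prof, cat1)
  expect_equal(comp$chap_ub_ratio, c(1.5, 2.5))
  comp2 <- compositionStats(cbind(k1 = prof[, 1] * 10, k2 = prof[, 2]), cat1)
  expect_equal(comp2$pn_fraction, comp$pn_fraction)
  expect_equal(comp2$chap_ub_ratio, comp$chap_ub_ratio)
})

test_that("planted chaperone overexpression raises the Inh chaperone/Ub ratio", {
  cfg <- simulationConfig(nGenes = 120, nCells = 240, nClusters = 6,
                          classOfCluster = rep(c("Exc", "Inh", "non"), 2),
                          overexpressedSets = list(
                            list(genes = 1:25, class = "Inh", fold = 2)),
                          seed = 13)
  ds <- cpmNormalize(simulateDataset(cfg))
  prof <- clusterProfiles(ds)
  gids <- rownames(prof)
  cat1 <- geneSetCatalog(list(chaperones = gids[1:25],
                              ubiquitin_enzymes = gids[26:50]))
  comp <- compositionStats(prof, cat1, clusterClasses(ds))
  expect_gt(mean(comp$chap_ub_ratio[comp$class == "Inh"]),
            mean(comp$chap_ub_ratio[comp$class == "Exc"]))
})

test_that("cosine linkage is scale-invariant and joins orthogonal pairs last", {
  prof <- cbind(k1 = c(1, 0, 0), k2 = c(2, 0, 0),
                k3 = c(0, 1, 0), k4 = c(0, 3, 0))
  rownames(prof) <- c("g1", "g2", "g3")
  hc <- cosineLinkage(prof)
  expect_equal(hc$height[1:2], c(0, 0))
  first2 <- sapply(1:2, function(i)
    paste(sort(hc$labels[-hc$merge[i, ]]), collapse = "+"))
  expect_setequal(first2, c("k1+k2", "k3+k4"))
  hcScaled <- cosineLinkage(prof %*% diag(c(5, 1, 3, 11)) |>
                              `colnames<-`(colnames(prof)))
  expect_equal(hcScaled$height, hc$height)
  expect_error(cosineLinkage(cbind(prof, k5 = c(0, 0, 0))), "zero-vector")
})

test_that("between-class variability comparisons use the exact rank test", {
  vp <- cbind(Exc = c(60, 70, 80, 90, 95), non = c(5, 10, 15, 20, 25))
  res <- classVariabilityComparison(vp)
  expect_equal(res$p, 2 / 252)
  swapped <- classVariabilityComparison(vp[, c(2, 1)])
  expect_equal(swapped$p, res$p)
  same <- cbind(Exc = rep(50, 5), Inh = rep(50, 5))
  expect_equal(classVariabilityComparison(same)$p, 1)
})
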