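identityMap <- function(genes)
  data.frame(human = genes, macaque = genes, mouse = genes,
             stringsAsFactors = FALSE)

test_that("an interaction present in only two species is not conserved", {
  e <- function(...) coexNetwork(data.frame(gene_a = c(...)[c(TRUE, FALSE)],
                                            gene_b = c(...)[c(FALSE, TRUE)],
                                            weight = 1))
  nets <- list(human = e("A", "B", "B", "C"),
               macaque = e("A", "B"),
               mouse = e("A", "B", "A", "C"))
  cons <- conservedEdges(nets, identityMap(c("A", "B", "C")))
  expect_equal(edgeKeys(cons), "A B")
})

test_that("identical networks under the identity map are wholly conserved", {
  nw <- makeRandomNetwork(20, 50, seed = 6)
  nets <- list(human = nw, macaque = nw, mouse = nw)
  cons <- conservedEdges(nets, identityMap(networkNodes(nw)))
  expect_setequal(edgeKeys(cons), edgeKeys(nw))
  wref <- setNames(networkEdges(nw)$weight, edgeKeys(nw))
  expect_equal(networkEdges(cons)$weight, unname(wref[edgeKeys(cons)]))
  badMap <- identityMap(networkNodes(nw))
  badMap$macaque[2] <- badMap$macaque[1]
  expect_error(conservedEdges(nets, badMap), "one-to-one")
})

test_that("degree-preserving randomization preserves exactly the degrees", {
  for (seed in 1:4) {
    nw <- makeRandomNetwork(40, 90, seed = seed)
    rnd <- degreePreservingRandomize(nw, seed = seed + 100)
    expect_identical(networkDegrees(rnd), networkDegrees(nw))
    e <- networkEdges(rnd)
    expect_false(any(e$gene_a == e$gene_b))
    expect_false(anyDuplicated(edgeKeys(rnd)) > 0)
  }
})

test_that("rigid graphs come back unchanged with a notice", {
  k3 <- coexNetwork(data.frame(gene_a = c("A", "A", "B"),
                               gene_b = c("B", "C", "C"), weight = 1))
  expect_message(r3 <- degreePreservingRandomize(k3, seed = 1),
                 "unchanged")
  expect_setequal(edgeKeys(r3), edgeKeys(k3))
  # a 4-cycle stays 2-regular and simple under any amount of swapping
  c4 <- coexNetwork(data.frame(gene_a = c("A", "B", "C", "A"),
                               gene_b = c("B", "C", "D", "D"), weight = 1))
  r4 <- degreePreservingRandomize(c4, seed = 9)
  expect_equal(unname(networkDegrees(r4)), rep(2L, 4))
  expect_false(anyDuplicated(edgeKeys(r4)) > 0)
})

test_that("the conservation score follows its closed formula", {
  expect_equal(conservationScore(20, 16), 25)
  expect_equal(conservationScore(16, 16), 0)
  expect_true(is.na(conservationScore(5, 0)))
})

test_that("conservation analysis recovers planted structure and obeys its identities", {
  cfg <- simulationConfig(nGenes = 40, nCells = 320, nClusters = 16, seed = 4)
  tr <- simulateSpeciesTriplet(cfg, nConserved = 15, nSpeciesPrivate = 15,
                               effectSize = 2.5)
  nets <- lapply(speciesDatasets(tr), function(d)
    coexpressionEdges(foldChangeProfiles(clusterProfiles(cpmNormalize(d))),
                      quantile = 0.2))
  res <- conservationAnalysis(nets, orthologueMap(tr), nRandom = 50, seed = 2)
  # subset law: conserved edges exist in every species network (mapped)
  for (sp in names(nets)) {
    spBase <- gsub("(hs|mq|mm)_", "", edgeKeys(nets[[sp]]))
    consBase <- gsub("hs_", "", edgeKeys(conservedNetwork(res)), fixed = TRUE)
    expect_true(all(consBase %in% spBase))
  }
  # score identity to machine precision
  expect_equal(conservationScoreValue(res),
               (res@nTrue / mean(nullConservedCounts(res)) - 1) * 100,
               tolerance = 1e-12)
  pg <- perGeneConservation(res)
  expect_true(all(pg$empirical_p > 0 & pg$empirical_p <= 1))
  expect_equal(sum(pg$observed), 2 * res@nTrue)
  # determinism
  res2 <- conservationAnalysis(nets, orthologueMap(tr), nRandom = 50, seed = 2)
  expect_identical(nullConservedCounts(res2), nullConservedCounts(res))
  # planted recovery, permissive: most truth pairs conserved, private ones not
  te <- truthConservedEdges(tr)
  tkeys <- paste(te$gene_a, te$gene_b)
  ckeys <- edgeKeys(conservedNetwork(res))
  expect_gte(mean(tkeys %in% ckeys), 0.8)
})

test_that("gene-set conservation density separates planted from background", {
  cfg <- simulationConfig(nGenes = 40, nCells = 320, nClusters = 16, seed = 4)
  tr <- simulateSpeciesTriplet(cfg, nConserved = 15, nSpeciesPrivate = 15,
                               effectSize = 2.5)
  nets <- lapply(speciesDatasets(tr), function(d)
    coexpressionEdges(foldChangeProfiles(clusterProfiles(cpmNormalize(d))),
                      quantile = 0.2))
  res <- conservationAnalysis(nets, orthologueMap(tr), nRandom = 30, seed = 2)
  te <- truthConservedEdges(tr)
  planted <- sort(unique(c(te$gene_a, te$gene_b)))
  background <- setdiff(orthologueMap(tr)$human, planted)[seq_along(planted)]
  dens <- genesetDensity(res, list(planted = planted, background = background))
  expect_true(all(dens$observed_density >= 0 & dens$observed_density <= 1))
  expect_gt(dens$relative_density[dens$set == "planted"],
            dens$relative_density[dens$set == "background"])
  expect_error(genesetDensity(res, list(tiny = planted[1])), "fewer than 2")
})

test_that("two genes joined by a conserved edge have density one", {
  nw <- coexNetwork(data.frame(gene_a = "A", gene_b = "B", weight = 1),
                    nodes = c("A", "B", "C", "D"))
  nets <- list(human = nw, macaque = nw, mouse = nw)
  res <- conservationAnalysis(nets, identityMap(c("A", "B", "C", "D")),
                              nRandom = 5, seed = 1)
  dens <- genesetDensity(res, list(pair = c("A", "B"), empty = c("C", "D")))
  expect_equal(dens$observed_density[dens$set == "pair"], 1)
  expect_equal(dens$observed_density[dens$set == "empty"], 0)
  expect_equal(dens$relative_density[dens$set == "empty"], 0)
})
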