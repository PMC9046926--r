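test_that("invalid simulation configurations are rejected", {
  expect_error(simParams(deFraction = 1.2), "\\[0, 1\\]")
  expect_error(simParams(nPerCell = 1), ">= 2")
  expect_error(simParams(dispersionA0 = 0), "strictly positive")
})

test_that("a null configuration forces all true effects to zero", {
  tr <- simulateTruth(tinyParams(deFraction = 0, interactionFraction = 0))
  expect_true(all(tr$lfcG1 == 0))
  expect_true(all(tr$lfcG2 == 0))
  expect_false(any(tr$isDE))
})

test_that("zero interaction means identical per-group true LFCs", {
  tr <- simulateTruth(tinyParams(deFraction = 0.3, interactionFraction = 0))
  expect_identical(tr$lfcG1, tr$lfcG2)
  expect_true(all(tr$lfcG1[!tr$isDE] == 0))
})

test_that("same config and seed give identical datasets, shifted seeds differ", {
  p <- tinyParams(deFraction = 0.2)
  se1 <- simulateDataset(p)
  se2 <- simulateDataset(p)
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))
  se3 <- simulateDataset(p, seed = p@seed + 2L)
  expect_false(identical(SummarizedExperiment::assay(se1),
                         SummarizedExperiment::assay(se3)))
})

test_that("the design is a balanced 2x2 with annotated cells", {
  p <- tinyParams()
  se <- simulateDataset(p)
  cd <- SummarizedExperiment::colData(se)
  expect_equal(dim(se), c(200L, 20L))
  expect_true(all(table(cd$group, cd$condition) == 5L))
  expect_true(all(SummarizedExperiment::assay(se) >= 0))
})

test_that("simulated counts recover the NB mean and variance", {
  # one gene pinned at mu = 100, unit size factors, 10000 samples
  p <- simParams(nGenes = 1L, nPerCell = 2500L, deFraction = 0,
                 baselineLogMeanLocation = log(100),
                 baselineLogMeanScale = 0, sizeFactorLogSd = 0, seed = 21L)
  se <- simulateDataset(p)
  y <- as.numeric(SummarizedExperiment::assay(se))
  alpha <- groundTruth(se)$dispersion
  trueVar <- 100 + alpha * 100^2
  mcse <- sqrt(trueVar / length(y))
  expect_lt(abs(mean(y) - 100), 3 * mcse)
  expect_lt(abs(var(y) - trueVar) / trueVar, 0.10)
})

test_that("true size factors are median-centred", {
  se <- simulateDataset(tinyParams(sizeFactorLogSd = 0.4))
  expect_equal(median(SummarizedExperiment::colData(se)$trueSizeFactor), 1)
})

test_that("gene set catalogs respect counts, labels and purity", {
  tr <- simulateTruth(tinyParams(deFraction = 0.4))
  db0 <- makeGeneSets(tr, nResponse = 0L, nBackground = 3L, seed = 2)
  expect_equal(length(db0), 3L)
  expect_true(all(setLabels(db0) == "background"))

  # fixed size 30, purity 0.8: mean truly-DE members per response set ~ 24
  db <- makeGeneSets(tr, nResponse = 50L, nBackground = 0L,
                     sizeRange = c(30L, 30L), purity = 0.8, seed = 3)
  deGenes <- tr$gene_id[tr$isDE]
  hits <- vapply(geneSetList(db),
                 function(m) sum(m %in% deGenes), 0L)
  expect_lt(abs(mean(hits) - 24), 1.5)

  # purity 0 draws from the same pool as background sets
  dbp0 <- makeGeneSets(tr, nResponse = 10L, nBackground = 0L, purity = 0,
                       seed = 4)
  expect_true(all(unlist(geneSetList(dbp0)) %in% tr$gene_id))
})

test_that("an infeasible catalog request errors", {
  tr <- simulateTruth(tinyParams(deFraction = 0))
  expect_error(makeGeneSets(tr, nResponse = 2L, sizeRange = c(10L, 50L)),
               "infeasible")
})
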