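test_that("median-of-ratios size factors match hand computations", {
  m <- rbind(g1 = c(2, 8), g2 = c(2, 8))
  expect_equal(unname(estimateSizeFactorsMoR(m)), c(0.5, 2.0))

  flat <- matrix(7L, 5, 4)
  expect_equal(unname(estimateSizeFactorsMoR(flat)), rep(1, 4))

  # scaling one column by 3 multiplies its factor by 3 (others rescale
  # through the geometric mean but ratios of factors are preserved)
  set.seed(1)
  m2 <- matrix(rpois(60, 50), 10, 6)
  sf <- estimateSizeFactorsMoR(m2)
  m3 <- m2
  m3[, 2] <- m2[, 2] * 3L
  sf3 <- estimateSizeFactorsMoR(m3)
  expect_equal(sf3[2] / sf3[1], 3 * sf[2] / sf[1], tolerance = 1e-8)
})

test_that("size factors fail informatively with no always-positive gene", {
  m <- rbind(c(0, 5), c(5, 0))
  expect_error(estimateSizeFactorsMoR(m), "strictly positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  se <- simulateDataset(tinyParams(deFraction = 0.2))
  m <- SummarizedExperiment::assay(se)
  expect_equal(unname(estimateSizeFactorsMoR(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("the NB GLM solver matches stats::glm at fixed dispersion", {
  skip_if_not_installed("MASS")
  p <- simParams(nGenes = 20L, nPerCell = 6L, deFraction = 0.5, seed = 31L)
  se <- simulateDataset(p)
  counts <- SummarizedExperiment::assay(se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- rowSums(counts) >= 10 & rowSums(counts > 0) > 12
  counts <- counts[keep, , drop = FALSE]
  sf <- estimateSizeFactorsMoR(counts)
  alpha <- 0.1
  fit <- fitNBGLM(counts, cd, sizeFactors = sf,
                  dispersions = rep(alpha, nrow(counts)))
  df <- data.frame(group = factor(cd$group), condition = factor(cd$condition))
  for (g in seq_len(nrow(counts))) {
    ref <- suppressWarnings(glm(
      counts[g, ] ~ group * condition + offset(log(sf)), data = df,
      family = MASS::negative.binomial(theta = 1 / alpha)))
    expect_equal(unname(fit$beta[g, ]), unname(coef(ref)), tolerance = 1e-4)
    # fixed-dispersion SEs from the unscaled Fisher information
    refSe <- summary(ref, dispersion = 1)$coefficients[, "Std. Error"]
    expect_equal(unname(fit$est[g, "trt_in_G1"]),
                 unname(coef(ref)["conditionTreated"]) / log(2),
                 tolerance = 1e-4)
    expect_equal(unname(fit$se[g, "interaction"]),
                 unname(refSe["groupG2:conditionTreated"]) / log(2),
                 tolerance = 1e-3)
  }
})

test_that("dispersion estimation recovers Poisson-like data as near zero", {
  p <- simParams(nGenes = 300L, nPerCell = 20L, deFraction = 0,
                 dispersionA0 = 1e-6, dispersionA1 = 0, seed = 43L)
  se <- simulateDataset(p)
  a <- estimateDispersionsML(
    SummarizedExperiment::assay(se),
    as.data.frame(SummarizedExperiment::colData(se)))
  expect_lt(median(a, na.rm = TRUE), 0.01)
})

test_that("constant-zero genes are filtered, not fitted", {
  se <- simulateDataset(tinyParams())
  counts <- SummarizedExperiment::assay(se)
  counts[1, ] <- 0L
  SummarizedExperiment::assay(se) <- counts
  res <- suppressWarnings(runDiffExp(se))
  tab <- deTable(res, "trt_in_G1")
  expect_true(tab$filtered[1])
  expect_true(is.na(tab$pvalue[1]))
  expect_true(is.na(tab$fdr[1]))
  expect_false(rownames(se)[1] %in% testedGenes(res))
})

test_that("swapping group labels swaps contrasts and negates the interaction", {
  p <- simParams(nGenes = 120L, nPerCell = 6L, deFraction = 0.3,
                 interactionFraction = 0.1, interactionLfc = 1.5, seed = 8L)
  se <- simulateDataset(p)
  res <- suppressWarnings(runDiffExp(se))
  seSwap <- se
  cd <- SummarizedExperiment::colData(seSwap)
  cd$group <- ifelse(cd$group == "G1", "G2", "G1")
  SummarizedExperiment::colData(seSwap) <- cd
  resSwap <- suppressWarnings(runDiffExp(seSwap))
  ok <- !deTable(res, "trt_in_G1")$filtered
  expect_equal(deTable(res, "trt_in_G1")$lfc[ok],
               deTable(resSwap, "trt_in_G2")$lfc[ok], tolerance = 1e-4)
  expect_equal(deTable(res, "interaction")$lfc[ok],
               -deTable(resSwap, "interaction")$lfc[ok], tolerance = 1e-4)
})

test_that("BH adjustment matches the step-up formula and its oracle", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA entries are excluded from the family
  expect_equal(bhAdjust(c(0.01, NA, 0.04))[c(1, 3)],
               bhAdjust(c(0.01, 0.04)))
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("DEG calling uses strict inequalities on both thresholds", {
  res <- new("DEResults",
             results = list(trt_in_G1 = data.frame(
               gene_id = c("a", "b", "c", "d"),
               baseMean = 1, lfc = c(1.5, 1.0, 3.0, -1.2),
               se = 1, stat = 1,
               pvalue = c(0.001, 0.001, 0.02, 0.001),
               fdr = c(0.04, 0.04, 0.05, 0.04),
               filtered = FALSE)),
             contrasts = "trt_in_G1",
             filtered = c(a = FALSE, b = FALSE, c = FALSE, d = FALSE),
             sizeFactors = c(s = 1), dispersions = c(a = 0.1),
             dispConverged = c(a = TRUE), criteria = degCriteria())
  degs <- callDEGs(res, "trt_in_G1")
  expect_true("a" %in% degs)       # fdr 0.04, |lfc| 1.5
  expect_false("b" %in% degs)      # |lfc| exactly 1 -> excluded
  expect_false("c" %in% degs)      # fdr exactly 0.05 -> excluded
  expect_true("d" %in% degs)       # negative lfc counts by magnitude
  expect_error(callDEGs(res, "nope"), "unknown contrast")
})

test_that("venn partition is exact set algebra over the universe", {
  u <- letters[1:5]
  vp <- vennPartition(c("a", "b", "c"), c("b", "c", "d"), u)
  expect_equal(vp$only_A, "a")
  expect_equal(sort(vp$both), c("b", "c"))
  expect_equal(vp$only_B, "d")
  expect_equal(vp$neither, "e")
  expect_equal(sum(vp$counts), length(u))

  same <- vennPartition(c("a", "b"), c("a", "b"), u)
  expect_length(same$only_A, 0)
  expect_length(same$only_B, 0)

  empty <- vennPartition(character(0), c("a"), u)
  expect_length(empty$both, 0)
  expect_equal(empty$only_B, "a")

  expect_error(vennPartition(c("z"), character(0), u), "outside")
})

test_that("realized false discovery proportion stays controlled", {
  # 50 regenerated cohorts with abundant shared signal; FDP among
  # FDR < 0.05 calls, averaged over replicates, stays near nominal
  fdps <- vapply(1:50, function(i) {
    p <- simParams(nGenes = 1000L, nPerCell = 10L, deFraction = 0.3,
                   seed = 500L + i)
    truth <- simulateTruth(p)
    se <- simulateCounts(truth, p, seed = 600L + i)
    res <- suppressWarnings(runDiffExp(se))
    vapply(c("trt_in_G1", "trt_in_G2"), function(cn) {
      tab <- deTable(res, cn)
      called <- !is.na(tab$fdr) & tab$fdr < 0.05
      if (!sum(called)) return(NA_real_)
      trueLfc <- if (cn == "trt_in_G1") truth$lfcG1 else truth$lfcG2
      mean(trueLfc[match(tab$gene_id[called], truth$gene_id)] == 0)
    }, 0.0)
  }, c(trt_in_G1 = 0.0, trt_in_G2 = 0.0))
  expect_lte(mean(fdps["trt_in_G1", ], na.rm = TRUE), 0.075)
  expect_lte(mean(fdps["trt_in_G2", ], na.rm = TRUE), 0.075)
})
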