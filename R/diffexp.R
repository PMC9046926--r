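# Negative binomial GLM differential expression for the 2x2 design:
# median-of-ratios size factors, Cox-Reid adjusted per-gene dispersion MLE,
# Wald tests for the within-group treatment contrasts and the interaction.

.CONTRASTS <- list(
  trt_in_G1   = c(0, 0, 1, 0),
  trt_in_G2   = c(0, 0, 1, 1),
  interaction = c(0, 0, 0, 1)
)

.designMatrix <- function(colData) {
  group <- factor(colData$group, levels = c("G1", "G2"))
  condition <- factor(colData$condition, levels = c("Ctrl", "Treated"))
  if (anyNA(group) || anyNA(condition))
    stop("group must be G1/G2 and condition Ctrl/Treated")
  if (any(table(group, condition) == 0))
    stop("all four group-by-condition cells must be non-empty")
  model.matrix(~ group * condition,
               data = data.frame(group = group, condition = condition))
}

#' Median-of-ratios size factors
#'
#' The classical count normalisation: per sample, the median over genes of
#' the ratio between the count and the gene's geometric mean across samples.
#' Only genes with strictly positive counts in every sample enter the
#' median.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- rbind(g1 = c(2, 8), g2 = c(2, 8))
#' estimateSizeFactorsMoR(m)  # 0.5, 2
#' @export
estimateSizeFactorsMoR <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stop("no gene has strictly positive counts in every sample; ",
         "relax the count filter or remove empty samples")
  logGeo <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2,
              function(col) exp(median(log(col) - logGeo)))
  setNames(sf, colnames(counts))
}

.nbglmCall <- function(counts, X, sizeFactors, dispersions = NULL,
                       ridge = 1e-6) {
  Cmat <- do.call(cbind, .CONTRASTS)
  if (is.null(dispersions)) dispersions <- rep(NA_real_, nrow(counts))
  nbglm_fit_cpp(as.matrix(counts), X, log(sizeFactors), Cmat,
                ridge, 1e-8, 10, as.numeric(dispersions))
}

#' Per-gene maximum likelihood dispersion estimates
#'
#' Maximises the Cox-Reid adjusted negative binomial profile likelihood per
#' gene under the fitted 2x2 group-by-condition means, clamped to
#' `[1e-8, 10]`. Genes whose optimisation fails fall back to a
#' method-of-moments estimate (flagged with a warning). No shrinkage toward
#' the trend is applied.
#'
#' @param counts integer matrix, genes x samples (already filtered; rows
#'   with all-zero counts are returned as `NA`).
#' @param colData data frame with `group` and `condition` per sample.
#' @param sizeFactors per-sample size factors; estimated by
#'   [estimateSizeFactorsMoR()] when missing.
#' @return Named numeric vector of dispersions (`NA` for all-zero genes).
#' @export
estimateDispersionsML <- function(counts, colData,
                                  sizeFactors = estimateSizeFactorsMoR(counts)) {
  counts <- as.matrix(counts)
  X <- .designMatrix(colData)
  ok <- rowSums(counts) > 0
  alpha <- rep(NA_real_, nrow(counts))
  if (any(ok)) {
    fit <- .nbglmCall(counts[ok, , drop = FALSE], X, sizeFactors)
    alpha[ok] <- fit$alpha
    if (!all(fit$disp_ok))
      warning(sum(!fit$disp_ok), " gene(s) used the method-of-moments ",
              "fallback dispersion")
  }
  setNames(alpha, rownames(counts))
}

#' Low-level NB GLM fit with fixed or estimated dispersions
#'
#' Fits, per gene, the log-link negative binomial GLM with design
#' `~ group * condition` and log size factor offsets, using a
#' ridge-stabilised (penalty `1e-6`) iteratively reweighted least squares
#' solver, and returns Wald statistics for the three canonical contrasts.
#'
#' @inheritParams estimateDispersionsML
#' @param dispersions optional per-gene dispersions; `NA` entries are
#'   estimated by Cox-Reid adjusted MLE.
#' @return List with per-gene `alpha`, coefficient matrix `beta` (natural
#'   log scale), and per-contrast matrices `est`, `se` (log2 units) and
#'   `stat`, plus logical vectors `disp_ok`, `fit_ok`.
#' @export
fitNBGLM <- function(counts, colData,
                     sizeFactors = estimateSizeFactorsMoR(counts),
                     dispersions = NULL) {
  counts <- as.matrix(counts)
  X <- .designMatrix(colData)
  fit <- .nbglmCall(counts, X, sizeFactors, dispersions)
  cn <- names(.CONTRASTS)
  for (nm in c("est", "se", "stat")) colnames(fit[[nm]]) <- cn
  colnames(fit$beta) <- colnames(X)
  fit
}

#' Fit the 2x2 NB model and test all three contrasts
#'
#' The full differential expression pass: genes with fewer than
#' `minTotalCount` reads in total are filtered before testing;
#' median-of-ratios size factors and Cox-Reid adjusted dispersion MLEs are
#' computed on the remaining genes; one joint NB GLM per gene yields Wald
#' tests (standard normal reference) for the treatment effect within G1,
#' within G2, and their difference (the interaction). BH adjustment is
#' applied per contrast across the unfiltered genes.
#'
#' @param se a `SummarizedExperiment` with assay `counts` and `colData`
#'   columns `group` (G1/G2) and `condition` (Ctrl/Treated), e.g. from
#'   [simulateDataset()] or [readDataset()].
#' @param criteria a [DEGCriteria-class], attached to the result and used
#'   by [callDEGs()].
#' @param minTotalCount pre-filter: minimum total count across samples,
#'   default 10.
#' @param dispersions optional named per-gene dispersions to fix.
#' @return A [DEResults-class] object.
#' @examples
#' se <- simulateDataset(simParams(nGenes = 60, nPerCell = 4, seed = 5))
#' res <- runDiffExp(se)
#' head(deTable(res, "interaction"))
#' @export
runDiffExp <- function(se, criteria = degCriteria(), minTotalCount = 10,
                       dispersions = NULL) {
  stopifnot(is(se, "SummarizedExperiment"), is(criteria, "DEGCriteria"))
  validObject(criteria)
  counts <- as.matrix(SummarizedExperiment::assay(se, "counts"))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(counts)))
  filtered <- rowSums(counts) < minTotalCount
  if (all(filtered)) stop("all genes removed by the count pre-filter")
  sf <- estimateSizeFactorsMoR(counts)
  baseMean <- rowMeans(sweep(counts, 2, sf, "/"))

  keep <- which(!filtered)
  dispIn <- NULL
  if (!is.null(dispersions)) dispIn <- unname(dispersions[genes[keep]])
  fit <- fitNBGLM(counts[keep, , drop = FALSE], cd, sizeFactors = sf,
                  dispersions = dispIn)
  if (!all(fit$disp_ok))
    warning(sum(!fit$disp_ok), " gene(s) used the method-of-moments ",
            "fallback dispersion")

  alpha <- rep(NA_real_, length(genes))
  alpha[keep] <- fit$alpha
  dispOk <- rep(NA, length(genes))
  dispOk[keep] <- fit$disp_ok

  results <- lapply(names(.CONTRASTS), function(cn) {
    lfc <- se_ <- stat <- pvalue <- rep(NA_real_, length(genes))
    lfc[keep] <- fit$est[, cn]
    se_[keep] <- fit$se[, cn]
    stat[keep] <- fit$stat[, cn]
    pvalue[keep] <- 2 * pnorm(-abs(fit$stat[, cn]))
    data.frame(gene_id = genes, baseMean = baseMean, lfc = lfc, se = se_,
               stat = stat, pvalue = pvalue, fdr = bhAdjust(pvalue),
               filtered = filtered, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  names(results) <- names(.CONTRASTS)
  new("DEResults", results = results, contrasts = names(.CONTRASTS),
      filtered = setNames(filtered, genes), sizeFactors = sf,
      dispersions = setNames(alpha, genes),
      dispConverged = setNames(as.logical(dispOk), genes),
      criteria = criteria)
}

#' Benjamini-Hochberg adjustment with validation
#'
#' Step-up adjusted p-values, capped at 1. `NA` entries are excluded from
#' the family and returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bhAdjust(c(0.005, 0.01, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes for one contrast
#'
#' A gene is a DEG when its BH-adjusted p is strictly below the FDR
#' threshold and its absolute log2 fold change strictly above the LFC
#' threshold; both inequalities are strict, so a gene at exactly the
#' threshold is excluded.
#'
#' @param res a [DEResults-class].
#' @param contrast contrast name.
#' @param criteria a [DEGCriteria-class]; defaults to the one attached to
#'   `res`.
#' @return Character vector of gene identifiers.
#' @export
callDEGs <- function(res, contrast, criteria = res@criteria) {
  tab <- deTable(res, contrast)
  sel <- !is.na(tab$fdr) & tab$fdr < criteria@fdrThreshold &
    abs(tab$lfc) > criteria@lfcThreshold
  tab$gene_id[sel]
}

#' Partition two DEG lists over a universe
#'
#' The Venn decomposition behind "group-specific" gene claims: genes
#' exclusive to each list, shared, and in neither.
#'
#' @param degsA,degsB character vectors of gene identifiers; must be
#'   subsets of `universe`.
#' @param universe character vector of all tested genes.
#' @return List with elements `only_A`, `only_B`, `both`, `neither`
#'   (disjoint; union equals `universe`) and a `counts` integer vector.
#' @examples
#' vennPartition(c("a", "b", "c"), c("b", "c", "d"), letters[1:5])$counts
#' @export
vennPartition <- function(degsA, degsB, universe) {
  degsA <- unique(degsA); degsB <- unique(degsB)
  out <- setdiff(union(degsA, degsB), universe)
  if (length(out))
    stop("DEGs outside the universe: ", paste(head(out, 5), collapse = ", "))
  both <- intersect(degsA, degsB)
  onlyA <- setdiff(degsA, both)
  onlyB <- setdiff(degsB, both)
  neither <- setdiff(universe, union(degsA, degsB))
  list(only_A = onlyA, only_B = onlyB, both = both, neither = neither,
       counts = c(only_A = length(onlyA), only_B = length(onlyB),
                  both = length(both), neither = length(neither)))
}

#' Rank tested genes by p-value for one contrast
#'
#' Total order used by the CERNO test: ascending raw p, ties broken by
#' descending absolute log2 fold change, then lexicographic gene id.
#' Filtered genes are excluded.
#'
#' @param res a [DEResults-class].
#' @param contrast contrast name, default `"interaction"`.
#' @return Character vector of gene identifiers, best-ranked first.
#' @export
rankGenesByP <- function(res, contrast = "interaction") {
  tab <- deTable(res, contrast)
  tab <- tab[!tab$filtered & !is.na(tab$pvalue), ]
  tab$gene_id[order(tab$pvalue, -abs(tab$lfc), tab$gene_id)]
}
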