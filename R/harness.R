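# Replication harness: per-replicate incorrect-vs-correct analyses, the
# threshold-by-sample-size grid, false-negative composition accounting, and
# the paired log2-fold-change scatter export.

# One fitted replicate summarised at one set of DEG criteria.
.summarizeFit <- function(res, truth, db, criteria, replicateId, seed,
                          nTotal) {
  universe <- testedGenes(res)
  dG1 <- callDEGs(res, "trt_in_G1", criteria)
  dG2 <- callDEGs(res, "trt_in_G2", criteria)
  vp <- vennPartition(dG1, dG2, universe)
  fdb <- filterGeneSets(db, universe)
  labels <- setLabels(fdb)

  sigSets <- function(fg) {
    if (length(fg) == 0 || length(fdb) == 0) return(character(0))
    tab <- suppressWarnings(runORA(fg, universe, fdb))
    tab$set_name[tab$fdr < 0.05]
  }
  sg1 <- sigSets(vp$only_A)
  sg2 <- sigSets(vp$only_B)

  intTab <- deTable(res, "interaction")
  nIntDeg <- sum(intTab$fdr < 0.05, na.rm = TRUE)
  ranked <- rankGenesByP(res, "interaction")
  ctab <- runCERNO(ranked, fdb)
  nCerno <- if (nrow(ctab)) sum(ctab$fdr < 0.05) else 0L

  specific <- union(vp$only_A, vp$only_B)
  trulyBoth <- truth$gene_id[truth$isDE & !truth$hasInteraction]
  fnFrac <- if (length(specific))
    mean(specific %in% trulyBoth) else NA_real_

  sigBoth <- c(sg1, sg2)
  data.frame(
    replicate_id = replicateId, seed = seed,
    lfc_threshold = criteria@lfcThreshold, n_total_samples = nTotal,
    degs_G1 = length(dG1), degs_G2 = length(dG2),
    degs_both = length(vp$both),
    degs_only_G1 = length(vp$only_A), degs_only_G2 = length(vp$only_B),
    ora_sig_G1 = length(sg1), ora_sig_G2 = length(sg2),
    ora_sig_response = sum(labels[sigBoth] == "response"),
    ora_sig_background = sum(labels[sigBoth] == "background"),
    interaction_degs = nIntDeg, cerno_sig = nCerno,
    fn_fraction = fnFrac, stringsAsFactors = FALSE)
}

#' Run one replicate of the incorrect-vs-correct comparison
#'
#' Simulates counts for fixed gene-level truth, fits the 2x2 NB model,
#' calls DEGs per group, partitions them Venn-style, runs hypergeometric
#' ORA on each "specific" list (the statistically incorrect analysis), and
#' in parallel counts interaction-significant genes and
#' interaction-CERNO-significant sets (the correct analysis). The
#' false-negative composition of the "specific" lists is computed from the
#' ground truth.
#'
#' @param params a [SimParams-class].
#' @param criteria a [DEGCriteria-class].
#' @param db a [GeneSetDb-class] catalog over the simulated gene universe.
#' @param seed RNG seed for this replicate's count draw.
#' @param truth gene-level truth table; generated from `params` when `NULL`.
#' @param replicateId identifier recorded in the summary row.
#' @return One-row data frame: DEG counts per group and Venn part,
#'   significant "specific" ORA terms per side (and their response /
#'   background split), interaction DEGs at FDR < 0.05, significant
#'   interaction-CERNO sets, and `fn_fraction`, the fraction of "specific"
#'   DEGs that are truly DE in both groups.
#' @export
runReplicate <- function(params, criteria, db, seed = params@seed,
                         truth = NULL, replicateId = 1L) {
  stopifnot(is(params, "SimParams"), is(criteria, "DEGCriteria"),
            is(db, "GeneSetDb"))
  if (is.null(truth)) truth <- simulateTruth(params)
  se <- simulateCounts(truth, params, seed = seed)
  res <- suppressWarnings(runDiffExp(se, criteria))
  .summarizeFit(res, truth, db, criteria, replicateId, seed,
                4L * params@nPerCell)
}

#' Sweep LFC thresholds and sample sizes over replicates
#'
#' Full factorial sweep of the replicate analysis over log2 fold change
#' thresholds and total sample sizes (divisible by 4, balanced cells).
#' Gene-level truth and the gene set catalog are fixed across the sweep;
#' counts are regenerated per (size, replicate) with seed
#' `baseSeed + running index`, and all thresholds are evaluated on the same
#' fit since the threshold only affects DEG calling.
#'
#' @param params base [SimParams-class] (its `nPerCell` is overridden by
#'   `totalSizes`).
#' @param thresholds nonnegative log2 fold change thresholds; the study
#'   default is `c(0, 0.5, 1, 1.5, 2, 2.5, 3)`.
#' @param totalSizes total sample sizes, each divisible by 4; the study
#'   default is `c(40, 80, 160)`.
#' @param nReplicates replicates per (threshold, size) cell.
#' @param baseSeed seed root; default `params@seed`.
#' @param fdrThreshold FDR cutoff for DEG calling, default 0.05.
#' @param db optional [GeneSetDb-class]; built with [makeGeneSets()]
#'   defaults when `NULL`.
#' @return A [GridResult-class]: per-replicate rows and per-cell aggregates
#'   (mean/median specific DEG and spurious-term counts, and the fractions
#'   of replicates with at least 1 and at least 5 spurious terms).
#' @export
runGrid <- function(params, thresholds = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                    totalSizes = c(40, 80, 160), nReplicates = 100L,
                    baseSeed = params@seed, fdrThreshold = 0.05,
                    db = NULL) {
  stopifnot(all(thresholds >= 0))
  if (any(totalSizes %% 4 != 0))
    stop("total sample sizes must be divisible by 4 (balanced 2x2 cells)")
  if (any(totalSizes / 4 < 2))
    stop("total sample sizes must give at least 2 samples per cell")
  truth <- simulateTruth(params)
  if (is.null(db)) db <- makeGeneSets(truth, seed = baseSeed)
  rows <- list()
  idx <- 0L
  for (size in totalSizes) {
    p2 <- params
    p2@nPerCell <- as.integer(size / 4)
    for (rep_ in seq_len(nReplicates)) {
      idx <- idx + 1L
      seed <- as.integer(baseSeed + idx)
      se <- simulateCounts(truth, p2, seed = seed)
      res <- suppressWarnings(
        runDiffExp(se, degCriteria(fdrThreshold, thresholds[1])))
      for (th in thresholds) {
        crit <- degCriteria(fdrThreshold, th)
        rows[[length(rows) + 1L]] <-
          .summarizeFit(res, truth, db, crit, rep_, seed, size)
      }
    }
  }
  reps <- do.call(rbind, rows)
  reps$specific_degs <- reps$degs_only_G1 + reps$degs_only_G2
  reps$spurious_terms <- reps$ora_sig_G1 + reps$ora_sig_G2
  agg <- do.call(rbind, lapply(
    split(reps, list(reps$lfc_threshold, reps$n_total_samples),
          drop = TRUE),
    function(d) data.frame(
      lfc_threshold = d$lfc_threshold[1],
      n_total_samples = d$n_total_samples[1],
      n_replicates = nrow(d),
      mean_specific_degs = mean(d$specific_degs),
      median_specific_degs = median(d$specific_degs),
      mean_spurious_terms = mean(d$spurious_terms),
      median_spurious_terms = median(d$spurious_terms),
      frac_ge1_spurious = mean(d$spurious_terms >= 1),
      frac_ge5_spurious = mean(d$spurious_terms >= 5),
      median_interaction_degs = median(d$interaction_degs),
      mean_fn_fraction = mean(d$fn_fraction, na.rm = TRUE),
      stringsAsFactors = FALSE)))
  agg <- agg[order(agg$n_total_samples, agg$lfc_threshold), ]
  rownames(agg) <- NULL
  new("GridResult", replicates = reps, aggregate = agg)
}

#' Paired log2-fold-change scatter table
#'
#' The recommended overview alternative to a Venn diagram: per tested gene,
#' the estimated log2 fold change in each group, the significance class of
#' the Venn partition, and the disco score, together with Pearson
#' correlations overall and per class.
#'
#' @param res a [DEResults-class].
#' @param criteria a [DEGCriteria-class]; defaults to the one attached to
#'   `res`.
#' @return List with `table` (data frame: `gene_id`, `lfc_G1`, `lfc_G2`,
#'   `p_G1`, `p_G2`, `class`, `disco`) and `correlations` (data frame:
#'   `class`, `n`, `pearson_r`; first row `overall`).
#' @export
exportLfcScatter <- function(res, criteria = res@criteria) {
  t1 <- deTable(res, "trt_in_G1")
  t2 <- deTable(res, "trt_in_G2")
  keep <- !t1$filtered & !is.na(t1$lfc) & !is.na(t2$lfc)
  t1 <- t1[keep, ]; t2 <- t2[keep, ]
  universe <- t1$gene_id
  vp <- vennPartition(callDEGs(res, "trt_in_G1", criteria),
                      callDEGs(res, "trt_in_G2", criteria), universe)
  cls <- rep("neither", length(universe))
  cls[universe %in% vp$only_A] <- "only_G1"
  cls[universe %in% vp$only_B] <- "only_G2"
  cls[universe %in% vp$both] <- "both"
  tab <- data.frame(
    gene_id = universe, lfc_G1 = t1$lfc, lfc_G2 = t2$lfc,
    p_G1 = t1$pvalue, p_G2 = t2$pvalue, class = cls,
    disco = suppressWarnings(
      discoScore(t1$lfc, t2$lfc, t1$pvalue, t2$pvalue)),
    stringsAsFactors = FALSE)
  corFor <- function(d) {
    if (nrow(d) < 3 || var(d$lfc_G1) == 0 || var(d$lfc_G2) == 0)
      return(NA_real_)
    cor(d$lfc_G1, d$lfc_G2)
  }
  classes <- c("only_G1", "only_G2", "both", "neither")
  cors <- data.frame(
    class = c("overall", classes),
    n = c(nrow(tab), vapply(classes,
                            function(cl) sum(tab$class == cl), 0L)),
    pearson_r = c(corFor(tab),
                  vapply(classes,
                         function(cl) corFor(tab[tab$class == cl, ]),
                         0.0)),
    stringsAsFactors = FALSE)
  list(table = tab, correlations = cors)
}
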