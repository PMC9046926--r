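#' Simulation parameters for the 2x2 group-by-condition design
#'
#' Holds all tunables of the synthetic count generator: a balanced factorial
#' layout (two patient groups crossed with control/treated), negative
#' binomial counts with a per-gene dispersion-mean trend, log-normal
#' per-sample size factors, a configurable fraction of genes with a shared
#' treatment effect, and an (optional, default zero) true group-by-condition
#' interaction.
#'
#' @slot nGenes number of genes.
#' @slot nPerCell samples per group-by-condition cell (four cells in total).
#' @slot deFraction fraction of genes with a nonzero shared treatment log2
#'   fold change.
#' @slot lfcLocation,lfcScale location and scale of the half-normal magnitude
#'   of treatment log2 fold changes; the sign is drawn uniformly.
#' @slot interactionFraction,interactionLfc fraction of genes with a true
#'   group-by-condition effect and its log2 magnitude (defaults 0, 0).
#' @slot baselineLogMeanLocation,baselineLogMeanScale natural-log location
#'   and scale of the per-gene baseline mean distribution.
#' @slot dispersionA0,dispersionA1 dispersion trend alpha = a0 + a1/mu.
#' @slot sizeFactorLogSd standard deviation of log size factors (median
#'   centred to 1).
#' @slot seed integer RNG seed.
#' @seealso [simParams()], [simulateDataset()]
#' @export
setClass("SimParams", representation(
  nGenes = "integer", nPerCell = "integer",
  deFraction = "numeric", lfcLocation = "numeric", lfcScale = "numeric",
  interactionFraction = "numeric", interactionLfc = "numeric",
  baselineLogMeanLocation = "numeric", baselineLogMeanScale = "numeric",
  dispersionA0 = "numeric", dispersionA1 = "numeric",
  sizeFactorLogSd = "numeric", seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character(0)
  frac <- c(deFraction = object@deFraction,
            interactionFraction = object@interactionFraction)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    msg <- c(msg, paste0(names(frac)[bad], " must lie in [0, 1]"))
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nPerCell < 2L) msg <- c(msg, "nPerCell must be >= 2")
  if (object@dispersionA0 <= 0)
    msg <- c(msg, "dispersionA0 must be strictly positive")
  if (object@dispersionA1 < 0) msg <- c(msg, "dispersionA1 must be >= 0")
  if (object@lfcScale < 0 || object@baselineLogMeanScale < 0 ||
      object@sizeFactorLogSd < 0)
    msg <- c(msg, "scale parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults describe a bulk RNA-seq cohort of the size used throughout the
#' package's demonstrations: 5000 genes, 20 samples per group-by-condition
#' cell (80 samples), 10% of genes carrying a shared treatment response
#' whose log2 magnitude is half-normal with mode zero (most responsive genes
#' change modestly, a few strongly), and no true group-by-condition
#' interaction.
#'
#' @param nGenes,nPerCell design dimensions.
#' @param deFraction,lfcLocation,lfcScale shared treatment effect settings.
#' @param interactionFraction,interactionLfc true interaction settings.
#' @param baselineLogMeanLocation,baselineLogMeanScale baseline mean
#'   distribution (natural log scale).
#' @param dispersionA0,dispersionA1 dispersion-mean trend coefficients.
#' @param sizeFactorLogSd log-scale spread of per-sample size factors.
#' @param seed integer RNG seed.
#' @return A [SimParams-class] object.
#' @examples
#' simParams(nGenes = 100, nPerCell = 5, seed = 7)
#' @export
simParams <- function(nGenes = 5000L, nPerCell = 20L, deFraction = 0.1,
                      lfcLocation = 0, lfcScale = 1,
                      interactionFraction = 0, interactionLfc = 0,
                      baselineLogMeanLocation = 5,
                      baselineLogMeanScale = 1.5,
                      dispersionA0 = 0.05, dispersionA1 = 5,
                      sizeFactorLogSd = 0.15, seed = 1L) {
  new("SimParams",
      nGenes = as.integer(nGenes), nPerCell = as.integer(nPerCell),
      deFraction = deFraction, lfcLocation = lfcLocation,
      lfcScale = lfcScale, interactionFraction = interactionFraction,
      interactionLfc = interactionLfc,
      baselineLogMeanLocation = baselineLogMeanLocation,
      baselineLogMeanScale = baselineLogMeanScale,
      dispersionA0 = dispersionA0, dispersionA1 = dispersionA1,
      sizeFactorLogSd = sizeFactorLogSd, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nGenes, "genes,", object@nPerCell,
      "samples per cell (", 4L * object@nPerCell, "total )\n")
  cat("  deFraction =", object@deFraction,
      " lfc ~ sign * |N(", object@lfcLocation, ",", object@lfcScale, ")|\n")
  cat("  interaction:", object@interactionFraction, "of genes at lfc",
      object@interactionLfc, "\n")
  cat("  dispersion trend a0 =", object@dispersionA0, ", a1 =",
      object@dispersionA1, "; seed =", object@seed, "\n")
})

#' Collection of named gene sets
#'
#' A light-weight GMT-shaped container: named member lists, a free-text
#' description per set, and (for synthetic catalogs) a truth label marking
#' sets built around truly treatment-responsive genes (`"response"`) versus
#' sets with uniformly drawn members (`"background"`).
#'
#' @slot sets named list of character vectors of gene identifiers; members
#'   are unique within a set.
#' @slot description character vector parallel to `sets`.
#' @slot label character vector parallel to `sets`; one of `"response"`,
#'   `"background"`, `"none"`.
#' @seealso [GeneSetDb()], [makeGeneSets()], [readGMT()]
#' @export
setClass("GeneSetDb", representation(
  sets = "list", description = "character", label = "character"
))

setValidity("GeneSetDb", function(object) {
  msg <- character(0)
  n <- length(object@sets)
  if (is.null(names(object@sets)) && n > 0)
    msg <- c(msg, "sets must be named")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be unique")
  if (length(object@description) != n || length(object@label) != n)
    msg <- c(msg, "description and label must parallel sets")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "members must be unique within a set")
  if (n > 0 && !all(object@label %in% c("response", "background", "none")))
    msg <- c(msg, "labels must be 'response', 'background' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (members per set).
#' @param description optional character vector of descriptions.
#' @param label optional character vector of truth labels
#'   (`"response"`/`"background"`/`"none"`).
#' @return A [GeneSetDb-class] object.
#' @export
GeneSetDb <- function(sets, description = NULL, label = NULL) {
  sets <- lapply(sets, function(m) unique(as.character(m)))
  n <- length(sets)
  if (is.null(description)) description <- rep("", n)
  if (is.null(label)) label <- rep("none", n)
  new("GeneSetDb", sets = sets, description = as.character(description),
      label = as.character(label))
}

#' @describeIn GeneSetDb-class number of sets.
#' @param x a `GeneSetDb`.
#' @export
setMethod("length", "GeneSetDb", function(x) length(x@sets))

#' @describeIn GeneSetDb-class set names.
#' @export
setMethod("names", "GeneSetDb", function(x) names(x@sets))

#' @describeIn GeneSetDb-class subset by index or name.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneSetDb", function(x, i, j, ..., drop = FALSE) {
  new("GeneSetDb", sets = x@sets[i], description = x@description[i],
      label = x@label[i])
})

setMethod("show", "GeneSetDb", function(object) {
  sizes <- lengths(object@sets)
  cat("GeneSetDb with", length(object@sets), "sets")
  if (length(sizes))
    cat(" (sizes ", min(sizes), "-", max(sizes), ")", sep = "")
  cat("\n")
  tab <- table(object@label)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Member lists of a gene set collection
#' @param db a [GeneSetDb-class].
#' @return Named list of character vectors.
#' @export
geneSetList <- function(db) db@sets

#' Truth labels of a gene set collection
#' @param db a [GeneSetDb-class].
#' @return Named character vector of labels.
#' @export
setLabels <- function(db) setNames(db@label, names(db@sets))

#' Descriptions of a gene set collection
#' @param db a [GeneSetDb-class].
#' @return Named character vector.
#' @export
setDescriptions <- function(db) setNames(db@description, names(db@sets))

#' DEG calling criteria
#'
#' Thresholds defining a differentially expressed gene for one contrast:
#' BH-adjusted p strictly below `fdrThreshold` and absolute log2 fold change
#' strictly above `lfcThreshold`.
#'
#' @slot fdrThreshold FDR cutoff (strict `<`).
#' @slot lfcThreshold absolute log2 fold change cutoff (strict `>`).
#' @export
setClass("DEGCriteria", representation(
  fdrThreshold = "numeric", lfcThreshold = "numeric"
))

setValidity("DEGCriteria", function(object) {
  msg <- character(0)
  if (object@fdrThreshold <= 0 || object@fdrThreshold > 1)
    msg <- c(msg, "fdrThreshold must be in (0, 1]")
  if (object@lfcThreshold < 0)
    msg <- c(msg, "lfcThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct DEG calling criteria
#' @param fdrThreshold FDR cutoff, default 0.05.
#' @param lfcThreshold absolute log2 fold change cutoff, default 1.
#' @return A [DEGCriteria-class] object.
#' @export
degCriteria <- function(fdrThreshold = 0.05, lfcThreshold = 1) {
  new("DEGCriteria", fdrThreshold = fdrThreshold,
      lfcThreshold = lfcThreshold)
}

setMethod("show", "DEGCriteria", function(object) {
  cat("DEGCriteria: fdr <", object@fdrThreshold, "and |log2FC| >",
      object@lfcThreshold, "\n")
})

#' Differential expression results for the 2x2 design
#'
#' Per-gene Wald results for the three canonical contrasts of the
#' group-by-condition model: treatment effect within each group and their
#' difference (the interaction). Filtered genes (low total count) are kept
#' in the tables with `NA` statistics and `filtered = TRUE`.
#'
#' @slot results named list of per-contrast data frames with columns
#'   `gene_id`, `baseMean`, `lfc`, `se`, `stat`, `pvalue`, `fdr`, `filtered`.
#' @slot contrasts contrast names.
#' @slot filtered named logical vector, `TRUE` for genes excluded before
#'   testing.
#' @slot sizeFactors named per-sample size factors.
#' @slot dispersions named per-gene dispersion estimates (`NA` when
#'   filtered).
#' @slot dispConverged named logical; `FALSE` where the dispersion optimiser
#'   fell back to a method-of-moments estimate.
#' @slot criteria the [DEGCriteria-class] attached at fit time.
#' @seealso [runDiffExp()], [deTable()], [callDEGs()]
#' @export
setClass("DEResults", representation(
  results = "list", contrasts = "character", filtered = "logical",
  sizeFactors = "numeric", dispersions = "numeric",
  dispConverged = "logical", criteria = "DEGCriteria"
))

setValidity("DEResults", function(object) {
  msg <- character(0)
  if (!identical(names(object@results), object@contrasts))
    msg <- c(msg, "results names must match contrasts")
  need <- c("gene_id", "baseMean", "lfc", "se", "stat", "pvalue", "fdr",
            "filtered")
  for (tab in object@results)
    if (!all(need %in% names(tab)))
      msg <- c(msg, "result tables must have the canonical columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DEResults", function(object) {
  nG <- length(object@filtered)
  cat("DEResults:", nG, "genes (", sum(object@filtered), "filtered ),",
      length(object@sizeFactors), "samples\n")
  cat("  contrasts:", paste(object@contrasts, collapse = ", "), "\n")
  for (cn in object@contrasts) {
    tab <- object@results[[cn]]
    nsig <- sum(tab$fdr < object@criteria@fdrThreshold &
                  abs(tab$lfc) > object@criteria@lfcThreshold, na.rm = TRUE)
    cat(sprintf("  %-12s %d DEGs (fdr < %g, |lfc| > %g)\n", cn, nsig,
                object@criteria@fdrThreshold, object@criteria@lfcThreshold))
  }
})

#' Contrast names available in a result object
#' @param res a [DEResults-class].
#' @return Character vector of contrast names.
#' @export
contrastNames <- function(res) res@contrasts

#' Extract the per-gene table for one contrast
#' @param res a [DEResults-class].
#' @param contrast one of `contrastNames(res)`.
#' @return A data frame with columns `gene_id`, `baseMean`, `lfc`, `se`,
#'   `stat`, `pvalue`, `fdr`, `filtered`.
#' @export
deTable <- function(res, contrast) {
  if (!contrast %in% res@contrasts)
    stop("unknown contrast '", contrast, "'; available: ",
         paste(res@contrasts, collapse = ", "))
  res@results[[contrast]]
}

#' Genes that entered testing (pre-filter survivors)
#' @param res a [DEResults-class].
#' @return Character vector of gene identifiers.
#' @export
testedGenes <- function(res) names(res@filtered)[!res@filtered]

#' Per-sample size factors used in a fit
#' @param res a [DEResults-class].
#' @return Named numeric vector.
#' @export
deSizeFactors <- function(res) res@sizeFactors

#' Per-gene dispersion estimates from a fit
#' @param res a [DEResults-class].
#' @return Named numeric vector (`NA` for filtered genes).
#' @export
deDispersions <- function(res) res@dispersions

#' Grid sweep results
#'
#' Container for a factorial sweep over log2 fold change thresholds and
#' total sample sizes, holding one row per (threshold, size, replicate) plus
#' per-cell aggregates.
#'
#' @slot replicates data frame of per-replicate summaries.
#' @slot aggregate data frame of per-(threshold, size) aggregates.
#' @seealso [runGrid()]
#' @export
setClass("GridResult",
         representation(replicates = "data.frame", aggregate = "data.frame"))

setMethod("show", "GridResult", function(object) {
  cat("GridResult:", nrow(object@replicates), "replicate summaries over",
      nrow(object@aggregate), "grid cells\n")
  print(head(object@aggregate, 10))
})

#' Per-replicate rows of a grid sweep
#' @param x a [GridResult-class].
#' @return Data frame.
#' @export
gridReplicates <- function(x) x@replicates

#' Per-cell aggregates of a grid sweep
#' @param x a [GridResult-class].
#' @return Data frame.
#' @export
gridAggregate <- function(x) x@aggregate
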