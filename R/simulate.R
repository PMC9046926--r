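# Synthetic 2x2 negative binomial count generator with known ground truth.
# The design mirrors a two-group infection study: groups G1/G2 crossed with
# conditions Ctrl/Treated, balanced cells, shared treatment effects and an
# optional true group-by-condition interaction.

.cellLayout <- function(nPerCell) {
  group <- factor(rep(c("G1", "G1", "G2", "G2"), each = nPerCell),
                  levels = c("G1", "G2"))
  condition <- factor(rep(rep(c("Ctrl", "Treated"), each = nPerCell), 2),
                      levels = c("Ctrl", "Treated"))
  n <- 4L * nPerCell
  data.frame(
    sample_id = sprintf("S%03d_%s_%s", seq_len(n), group, condition),
    group = group, condition = condition, stringsAsFactors = FALSE)
}

#' Draw gene-level ground truth
#'
#' Samples the fixed, gene-level part of the simulation: baseline means,
#' dispersions from the trend `a0 + a1/mu`, shared treatment log2 fold
#' changes for a `deFraction` of genes (sign uniform, magnitude half-normal)
#' and, for an `interactionFraction` of genes, an additional
#' group-by-condition effect of size `interactionLfc`. In a replicated
#' study this truth is drawn once and counts are regenerated per replicate,
#' the synthetic analogue of repeatedly splitting one cohort.
#'
#' @param params a [SimParams-class]; `params@seed` fixes the draw.
#' @return A data frame with one row per gene: `gene_id`, `mu` (baseline
#'   mean), `dispersion`, `lfcG1`, `lfcG2` (true treatment log2 fold change
#'   per group), `isDE`, `hasInteraction`.
#' @examples
#' tr <- simulateTruth(simParams(nGenes = 50, seed = 3))
#' table(tr$isDE)
#' @export
simulateTruth <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  G <- params@nGenes
  mu <- exp(rnorm(G, params@baselineLogMeanLocation,
                  params@baselineLogMeanScale))
  dispersion <- params@dispersionA0 + params@dispersionA1 / mu
  isDE <- runif(G) < params@deFraction
  lfc <- numeric(G)
  lfc[isDE] <- sample(c(-1, 1), sum(isDE), replace = TRUE) *
    abs(rnorm(sum(isDE), params@lfcLocation, params@lfcScale))
  hasInt <- runif(G) < params@interactionFraction
  intLfc <- numeric(G)
  intLfc[hasInt] <- sample(c(-1, 1), sum(hasInt), replace = TRUE) *
    params@interactionLfc
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(G)),
    mu = mu, dispersion = dispersion,
    lfcG1 = lfc, lfcG2 = lfc + intLfc,
    isDE = isDE, hasInteraction = hasInt,
    stringsAsFactors = FALSE)
}

#' Simulate a count matrix for fixed gene-level truth
#'
#' Draws per-sample size factors (log-normal, median centred to 1) and
#' negative binomial counts with mean `s_j * mu_g * 2^eta` where `eta` is
#' the true treatment log2 fold change of the sample's group (zero for
#' controls), and per-gene dispersion from the truth table.
#'
#' @param truth a truth table from [simulateTruth()].
#' @param params the [SimParams-class] used to draw `truth` (supplies the
#'   design dimensions and size factor spread).
#' @param seed RNG seed for this draw; vary it across replicates.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` columns `sample_id`, `group`, `condition`,
#'   `trueSizeFactor`, `rowData` carrying the truth table, and the
#'   parameters and seed in `metadata()`.
#' @export
simulateCounts <- function(truth, params, seed = params@seed) {
  stopifnot(is(params, "SimParams"), is.data.frame(truth))
  validObject(params)
  set.seed(as.integer(seed))
  layout <- .cellLayout(params@nPerCell)
  N <- nrow(layout)
  G <- nrow(truth)
  sf <- exp(rnorm(N, 0, params@sizeFactorLogSd))
  sf <- sf / median(sf)
  eff <- matrix(0, G, N)
  treatedG1 <- layout$condition == "Treated" & layout$group == "G1"
  treatedG2 <- layout$condition == "Treated" & layout$group == "G2"
  eff[, treatedG1] <- truth$lfcG1
  eff[, treatedG2] <- truth$lfcG2
  mu <- outer(truth$mu, sf) * 2^eff
  counts <- matrix(
    rnbinom(G * N, mu = mu, size = rep(1 / truth$dispersion, N)), G, N)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth$gene_id, layout$sample_id)
  cd <- S4Vectors::DataFrame(layout, trueSizeFactor = sf,
                             row.names = layout$sample_id)
  rd <- S4Vectors::DataFrame(truth[, setdiff(names(truth), "gene_id")],
                             row.names = truth$gene_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = list(params = params, seed = as.integer(seed)))
}

#' Simulate a full dataset (truth plus counts)
#'
#' Convenience wrapper: draws the gene-level truth from `params@seed` and a
#' count matrix from `seed` (default: the same stream, continued).
#'
#' @param params a [SimParams-class].
#' @param seed seed for the count draw; defaults to `params@seed + 1L`.
#' @return A `SummarizedExperiment`; see [simulateCounts()].
#' @examples
#' se <- simulateDataset(simParams(nGenes = 100, nPerCell = 3, seed = 2))
#' dim(se)
#' @export
simulateDataset <- function(params, seed = params@seed + 1L) {
  truth <- simulateTruth(params)
  simulateCounts(truth, params, seed = seed)
}

#' Ground truth of a simulated dataset
#' @param se a `SummarizedExperiment` from [simulateDataset()].
#' @return Data frame with `gene_id` plus the truth columns.
#' @export
groundTruth <- function(se) {
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  cbind(gene_id = rownames(se), rd, stringsAsFactors = FALSE)
}

#' Build a synthetic gene set catalog around the simulation truth
#'
#' Response sets draw (on average) `purity` of their members from the truly
#' treatment-responsive genes and the rest from the unresponsive pool;
#' background sets draw uniformly from all genes. Set sizes are uniform on
#' `sizeRange`. Catalogs built this way make downstream enrichment
#' artifacts look biologically relevant: a list contaminated with shared
#' true responders will light up the response-labelled sets.
#'
#' @param truth truth table from [simulateTruth()] (or [groundTruth()]).
#' @param nResponse,nBackground numbers of sets of each flavour.
#' @param sizeRange integer range of set sizes, default `c(10, 50)`.
#' @param purity probability that a response-set member is drawn from the
#'   truly-DE pool, default 0.8.
#' @param seed RNG seed.
#' @return A [GeneSetDb-class] with labels `"response"`/`"background"`.
#' @export
makeGeneSets <- function(truth, nResponse = 20L, nBackground = 80L,
                         sizeRange = c(10L, 50L), purity = 0.8, seed = 1L) {
  stopifnot(is.data.frame(truth), purity >= 0, purity <= 1,
            length(sizeRange) == 2L, sizeRange[1] >= 1,
            sizeRange[2] >= sizeRange[1])
  set.seed(as.integer(seed))
  allGenes <- truth$gene_id
  dePool <- truth$gene_id[truth$isDE]
  otherPool <- truth$gene_id[!truth$isDE]
  if (nResponse > 0 && purity > 0 && length(dePool) < sizeRange[2])
    stop("infeasible catalog: ", length(dePool),
         " truly-DE genes cannot populate response sets of size up to ",
         sizeRange[2], " at purity ", purity)
  drawSet <- function(fromDE) {
    size <- sizeRange[1] + sample.int(sizeRange[2] - sizeRange[1] + 1L, 1L) - 1L
    if (fromDE) {
      nDE <- rbinom(1L, size, purity)
      nDE <- min(nDE, length(dePool))
      members <- c(sample(dePool, nDE),
                   sample(otherPool, min(size - nDE, length(otherPool))))
    } else {
      members <- sample(allGenes, min(size, length(allGenes)))
    }
    unique(members)
  }
  sets <- c(lapply(seq_len(nResponse), function(i) drawSet(TRUE)),
            lapply(seq_len(nBackground), function(i) drawSet(FALSE)))
  names(sets) <- c(sprintf("response_%02d", seq_len(nResponse)),
                   sprintf("background_%02d", seq_len(nBackground)))
  GeneSetDb(
    sets,
    description = c(rep("synthetic treatment-response set", nResponse),
                    rep("synthetic background set", nBackground)),
    label = c(rep("response", nResponse), rep("background", nBackground)))
}
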