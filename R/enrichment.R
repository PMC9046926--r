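# Gene set statistics: size filtering, hypergeometric overrepresentation,
# the CERNO rank test, and the disco concordance score.

#' Filter a gene set collection against a universe
#'
#' Memberships are first intersected with the universe; a set is retained
#' iff its in-universe size lies in `[minSize, maxSize]` (inclusive bounds:
#' sets with fewer than `minSize` or more than `maxSize` in-universe members
#' are removed).
#'
#' @param db a [GeneSetDb-class].
#' @param universe character vector of gene identifiers.
#' @param minSize,maxSize inclusive size bounds, defaults 10 and 50.
#' @return A filtered [GeneSetDb-class] (possibly empty) whose memberships
#'   are restricted to the universe.
#' @export
filterGeneSets <- function(db, universe, minSize = 10, maxSize = 50) {
  stopifnot(is(db, "GeneSetDb"))
  sets <- lapply(db@sets, intersect, y = universe)
  keep <- lengths(sets) >= minSize & lengths(sets) <= maxSize
  new("GeneSetDb", sets = sets[keep], description = db@description[keep],
      label = db@label[keep])
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability `P(X >= overlap)` of the hypergeometric
#' distribution for the overlap between a foreground list and a gene set,
#' drawn from a finite universe. The gene set is intersected with the
#' universe first.
#'
#' @param foreground character vector, must be a subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param geneSet character vector of set members.
#' @return List with `p_value`, `overlap`, `expected`, `set_size` (in
#'   universe) and `foreground_size`.
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' hypergeomTest(u[1:5], u, u[3:7])$p_value  # exact tail probability
#' @export
hypergeomTest <- function(foreground, universe, geneSet) {
  foreground <- unique(foreground)
  universe <- unique(universe)
  if (length(setdiff(foreground, universe)))
    stop("foreground must be a subset of the universe")
  set <- intersect(unique(geneSet), universe)
  if (length(foreground) == 0) {
    warning("empty foreground; returning p = 1")
    return(list(p_value = 1, overlap = 0L, expected = 0,
                set_size = length(set), foreground_size = 0L))
  }
  k <- length(intersect(foreground, set))
  N <- length(universe); m <- length(set); n <- length(foreground)
  p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  list(p_value = p, overlap = k, expected = n * m / N,
       set_size = m, foreground_size = n)
}

#' Overrepresentation analysis over a collection
#'
#' Runs [hypergeomTest()] for every set, applies BH adjustment across the
#' sets of this run, and sorts by p-value.
#'
#' @inheritParams hypergeomTest
#' @param db a [GeneSetDb-class], already size-filtered (see
#'   [filterGeneSets()]).
#' @return Data frame with columns `set_name`, `label`, `set_size`,
#'   `overlap`, `expected`, `p_value`, `fdr`.
#' @export
runORA <- function(foreground, universe, db) {
  stopifnot(is(db, "GeneSetDb"))
  if (length(db) == 0)
    return(data.frame(set_name = character(0), label = character(0),
                      set_size = integer(0), overlap = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(names(db), function(nm) {
    h <- hypergeomTest(foreground, universe, db@sets[[nm]])
    data.frame(set_name = nm, set_size = h$set_size, overlap = h$overlap,
               expected = h$expected, p_value = h$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$label <- setLabels(db)[tab$set_name]
  tab$fdr <- bhAdjust(tab$p_value)
  tab <- tab[order(tab$p_value, tab$set_name),
             c("set_name", "label", "set_size", "overlap", "expected",
               "p_value", "fdr")]
  rownames(tab) <- NULL
  tab
}

#' CERNO rank-based gene set test
#'
#' For a total ordering of `N` genes (best first) and a set `S`, the
#' statistic is `-2 * sum over S of log(r_i / N)` where `r_i` is the 1-based
#' rank; under the null of exchangeable ranks it is approximately
#' chi-squared with `2 * |S|` degrees of freedom. For a singleton set at
#' rank `r` the p-value is exactly `r / N`.
#'
#' @param rankedGenes character vector, a total order of the universe.
#' @param geneSet character vector of set members (intersected with
#'   `rankedGenes`).
#' @return List with `statistic`, `df`, `p_value`, `n_set`; `NULL` fields
#'   (and a message) when the intersection is empty.
#' @examples
#' cernoTest(sprintf("g%03d", 1:100), "g001")$p_value  # 0.01
#' @export
cernoTest <- function(rankedGenes, geneSet) {
  N <- length(rankedGenes)
  r <- match(intersect(unique(geneSet), rankedGenes), rankedGenes)
  if (length(r) == 0) {
    message("gene set has no member in the ranked list; skipped")
    return(list(statistic = NULL, df = NULL, p_value = NULL, n_set = 0L))
  }
  stat <- -2 * sum(log(r / N))
  df <- 2L * length(r)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), n_set = length(r))
}

#' CERNO test over a collection
#'
#' @param rankedGenes total order of the universe, e.g. from
#'   [rankGenesByP()].
#' @param db a [GeneSetDb-class].
#' @return Data frame with `set_name`, `label`, `n_set`, `statistic`, `df`,
#'   `p_value`, `fdr` (BH across the collection), sorted by p. Sets with no
#'   member in the ranked list are dropped.
#' @export
runCERNO <- function(rankedGenes, db) {
  stopifnot(is(db, "GeneSetDb"))
  rows <- lapply(names(db), function(nm) {
    ct <- suppressMessages(cernoTest(rankedGenes, db@sets[[nm]]))
    if (ct$n_set == 0L) return(NULL)
    data.frame(set_name = nm, n_set = ct$n_set, statistic = ct$statistic,
               df = ct$df, p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set_name = character(0), label = character(0),
                      n_set = integer(0), statistic = numeric(0),
                      df = integer(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab$label <- setLabels(db)[tab$set_name]
  tab$fdr <- bhAdjust(tab$p_value)
  tab <- tab[order(tab$p_value, tab$set_name),
             c("set_name", "label", "n_set", "statistic", "df", "p_value",
               "fdr")]
  rownames(tab) <- NULL
  tab
}

#' Disco concordance/discordance score
#'
#' Signed, unitless heuristic combining effect sizes and evidence from two
#' comparisons: `lfcA * lfcB * (|log10 pA| + |log10 pB|)`. Positive scores
#' mark concordant regulation (same sign in both comparisons), negative
#' scores discordant regulation; the magnitude grows with effect sizes and
#' with the strength of evidence. It carries no p-value and does not
#' replace an interaction test.
#'
#' @param lfcA,lfcB log2 fold changes from the two comparisons.
#' @param pA,pB p-values in `(0, 1]`; zeros are clamped to the smallest
#'   positive double with a warning.
#' @return Numeric vector of signed scores.
#' @examples
#' discoScore(2, 1, 0.01, 0.02)    # concordant, positive
#' discoScore(2, -1, 0.01, 0.02)   # discordant, negative
#' @export
discoScore <- function(lfcA, lfcB, pA, pB) {
  if (any(c(pA, pB) < 0 | c(pA, pB) > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  clamp <- function(p) {
    if (any(p == 0, na.rm = TRUE)) {
      warning("p-value of 0 clamped to smallest positive double")
      p[!is.na(p) & p == 0] <- .Machine$double.xmin
    }
    p
  }
  pA <- clamp(pA); pB <- clamp(pB)
  lfcA * lfcB * (abs(log10(pA)) + abs(log10(pB)))
}
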