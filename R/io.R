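# Plain-text interchange: count and annotation TSVs, GMT gene sets,
# results tables and run manifests. All tables are tab-separated, UTF-8,
# '.' decimal separator.

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header with `gene_id` followed by sample identifiers; cells
#' must be nonnegative integers. Duplicate gene or sample identifiers and
#' non-integer cells are rejected with the offending row/column named.
#'
#' @param path file path.
#' @return Integer matrix with gene row names and sample column names.
#' @export
readCountMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || names(tab)[1] != "gene_id")
    stop("count file must have a 'gene_id' first column: ", path)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(head(genes[duplicated(genes)], 3), collapse = ", "))
  samples <- names(tab)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at row '", genes[bad[1, 1]],
         "', column '", samples[bad[1, 2]], "' in ", path)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a count matrix to TSV
#' @param counts integer matrix with gene row names.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Requires columns `sample_id`, `group`, `condition`; duplicate sample ids
#' are rejected.
#'
#' @param path file path.
#' @return Data frame.
#' @export
readAnnotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "condition")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in ", path)
  tab
}

#' Write a sample annotation table to TSV
#' @param annotation data frame with `sample_id`, `group`, `condition`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assemble a SummarizedExperiment from count and annotation files
#'
#' Cross-validates the two files: every annotated sample must appear in the
#' count header and vice versa; columns are reordered to the annotation.
#'
#' @param countPath,annotationPath file paths.
#' @return A `SummarizedExperiment` with assay `counts`.
#' @export
readDataset <- function(countPath, annotationPath) {
  counts <- readCountMatrix(countPath)
  anno <- readAnnotation(annotationPath)
  miss <- setdiff(anno$sample_id, colnames(counts))
  extra <- setdiff(colnames(counts), anno$sample_id)
  if (length(miss) || length(extra))
    stop("sample mismatch between count and annotation files; ",
         "missing from counts: ", paste(miss, collapse = ", "),
         "; unannotated: ", paste(extra, collapse = ", "))
  counts <- counts[, anno$sample_id, drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(anno, row.names = anno$sample_id))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated. Lines
#' with no member are rejected with their line number; duplicate members
#' within a set are dropped.
#'
#' @param path file path.
#' @return A [GeneSetDb-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " in ", path,
           ": need name, description and at least one member")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("malformed GMT line ", i, " in ", path, ": no members")
    sets[[f[1]]] <- members
    desc <- c(desc, f[2])
  }
  GeneSetDb(sets, description = desc)
}

#' Write gene sets in GMT format
#' @param db a [GeneSetDb-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(db, path) {
  stopifnot(is(db, "GeneSetDb"))
  lines <- vapply(seq_along(db@sets), function(i) {
    paste(c(names(db@sets)[i], db@description[i], db@sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-contrast results table to TSV
#' @param res a [DEResults-class].
#' @param contrast contrast name.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDEResults <- function(res, contrast, path) {
  write.table(deTable(res, contrast), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, the resolved configuration (with an md5 hash of its
#' serialised form), the seed and the package version next to every output.
#'
#' @param path JSON file path.
#' @param config named list of configuration values.
#' @param seed integer seed used for the run.
#' @param inputs named list/vector of input paths or descriptions.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, config, seed, inputs = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  manifest <- list(
    package = "vennfallacy",
    version = as.character(utils::packageVersion("vennfallacy")),
    seed = as.integer(seed),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = inputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json: ", path)
  }
}
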