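#' Construct an OTU count table
#'
#' The universal currency of the pipeline: a non-negative integer matrix of
#' OTU counts (OTUs in rows, samples in columns) together with per-sample
#' metadata. Every sample must carry at least an `experiment` and a
#' `condition` label; `species`, `cultivar` and `genotype` are optional and
#' may be `NA` (e.g. for bare-soil samples).
#'
#' @param counts non-negative integer matrix, OTUs x samples, with unique
#'   rownames (OTU ids) and colnames (sample ids).
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `experiment`, `condition` (plus optional `species`,
#'   `cultivar`, `genotype`).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have OTU ids as rownames")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; first offending cell: OTU '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "experiment", "condition")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("species", "cultivar", "genotype"))
    if (!col %in% names(metadata)) metadata[[col]] <- NA_character_
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  unknown <- setdiff(colnames(counts), metadata$sample_id)
  if (length(unknown) > 0)
    stop("samples missing from metadata: ", paste(unknown, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples\n", nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts) > 0) {
    cat("experiments:", paste(unique(x$metadata$experiment), collapse = ", "), "\n")
    cat("conditions: ", paste(unique(x$metadata$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Number of OTUs / samples
#' @param table a `count_table`.
#' @return integer.
#' @export
n_otus <- function(table) nrow(table$counts)

#' @rdname n_otus
#' @export
n_samples <- function(table) ncol(table$counts)

#' Subset a count table by OTUs and/or samples
#'
#' @param table a `count_table`.
#' @param otus,samples character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @return a `count_table`.
#' @export
subset_table <- function(table, otus = NULL, samples = NULL) {
  counts <- table$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  count_table(counts, table$metadata[table$metadata$sample_id %in% colnames(counts), , drop = FALSE])
}

#' Read a count table and its sample metadata from TSV files
#'
#' Count TSV dialect: first column `otu_id`, remaining columns one per sample
#' (header = sample ids), integer cells. Metadata TSV: columns `sample_id`,
#' `experiment`, `condition` and optionally `species`, `cultivar`, `genotype`.
#'
#' @param path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, metadata_path) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 1) stop("count table has no columns")
  otu_ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 ncol = ncol(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row %d (OTU '%s'), column '%s'",
                 bad[1, 1], otu_ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(num) <- otu_ids
  count_table(num, meta)
}

#' Write a count table and its metadata to TSV files
#'
#' @param table a `count_table`.
#' @param path output path for counts.
#' @param metadata_path output path for metadata.
#' @return invisibly, the paths written.
#' @export
write_count_table <- function(table, path, metadata_path) {
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}
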