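#' Prevalence filter: keep OTUs present in a minimum fraction of all samples
#'
#' An OTU is retained iff its count is positive in at least
#' `min_fraction` of ALL samples of the table (inclusive boundary; e.g. an
#' OTU seen in exactly half the samples survives `min_fraction = 0.5`).
#' Prevalence is computed on the entire table, all conditions together.
#'
#' @param table a `count_table`.
#' @param min_fraction required fraction of samples with a positive count,
#'   in (0, 1]. Default 0.5.
#' @return a `count_table` with the same samples and the retained OTUs, in
#'   the original order.
#' @export
prevalence_filter <- function(table, min_fraction = 0.5) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  if (n_otus(table) == 0 || n_samples(table) == 0) return(table)
  keep <- rowMeans(table$counts > 0) >= min_fraction
  count_table(table$counts[keep, , drop = FALSE], table$metadata)
}

#' Pool experiments, keeping only OTUs occurring in every experiment
#'
#' Samples are concatenated with their experiment labels preserved. An OTU
#' "occurs" in an experiment if its count is positive in at least one sample
#' there; only OTUs occurring in every input table (strict intersection) are
#' kept, so OTUs seen in just one experiment are eliminated.
#'
#' @param tables list of `count_table`s, one per experiment, with distinct
#'   experiment labels and disjoint sample ids.
#' @return pooled `count_table`.
#' @export
pool_experiments <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  lapply(tables, function(t) stopifnot(inherits(t, "count_table")))
  labels <- unlist(lapply(tables, function(t) unique(t$metadata$experiment)))
  if (length(unique(labels)) < 2)
    stop("pooling requires tables from at least two distinct experiments")
  ids <- unlist(lapply(tables, function(t) colnames(t$counts)))
  if (anyDuplicated(ids))
    stop("duplicate sample ids across experiments: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  occurring <- lapply(tables, function(t)
    rownames(t$counts)[rowSums(t$counts > 0) > 0])
  common <- Reduce(intersect, occurring)
  # preserve the OTU order of the first table
  common <- rownames(tables[[1]]$counts)[rownames(tables[[1]]$counts) %in% common]
  counts <- do.call(cbind, lapply(tables, function(t)
    t$counts[common, , drop = FALSE]))
  meta <- do.call(rbind, lapply(tables, function(t) t$metadata))
  count_table(counts, meta)
}

#' Rarefy every sample to an even sequencing depth
#'
#' Each sample is subsampled without replacement (a multivariate
#' hypergeometric draw) to exactly `depth` total counts. Samples whose total
#' is below `depth` are dropped with a warning; OTUs left with all-zero
#' counts are removed.
#'
#' @param table a `count_table`.
#' @param depth target total count per sample (positive integer).
#' @param seed integer seed; identical (table, depth, seed) give identical
#'   output.
#' @return a rarefied `count_table`.
#' @export
rarefy_even_depth <- function(table, depth, seed) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a positive integer")
  totals <- colSums(table$counts)
  drop <- totals < depth
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(table$counts)[drop], collapse = ", "))
  keep_samples <- colnames(table$counts)[!drop]
  if (length(keep_samples) == 0)
    stop("no sample reaches the requested depth")
  counts <- table$counts[, keep_samples, drop = FALSE]
  out <- with_seed(seed, {
    cols <- lapply(seq_len(ncol(counts)), function(ci) {
      col <- counts[, ci]
      total <- sum(col)
      if (total == depth) return(unname(col))
      # draw `depth` reads without replacement from the pool of `total`
      picked <- sample.int(total, depth)
      breaks <- cumsum(col)
      tabulate(findInterval(picked, breaks + 0.5) + 1L, nbins = length(col))
    })
    matrix(unlist(cols), nrow = nrow(counts), ncol = ncol(counts))
  })
  dimnames(out) <- dimnames(counts)
  keep_otus <- rowSums(out) > 0
  count_table(out[keep_otus, , drop = FALSE],
              table$metadata[table$metadata$sample_id %in% keep_samples, , drop = FALSE])
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
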