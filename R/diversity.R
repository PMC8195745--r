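#' Per-sample alpha diversity
#'
#' Observed richness (# OTUs with positive count), Shannon index (natural
#' logarithm) and Gini-Simpson index (1 - sum p^2), the standard
#' richness-and-evenness trio for OTU tables.
#'
#' @param table a `count_table`; every sample must have a positive total.
#' @return data.frame with columns `sample_id`, `observed`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "))
  comm <- t(table$counts)   # vegan convention: samples x species
  data.frame(
    sample_id = colnames(table$counts),
    observed = as.numeric(rowSums(comm > 0)),
    shannon = as.numeric(vegan::diversity(comm, index = "shannon")),
    simpson = as.numeric(vegan::diversity(comm, index = "simpson")),
    stringsAsFactors = FALSE)
}

#' Unweighted UniFrac distances between samples
#'
#' Pairwise distance = branch length unique to either sample's presence set
#' divided by the total branch length spanned by their union (presence =
#' count > 0), on a rooted phylogeny of the OTUs.
#'
#' @param table a `count_table`.
#' @param tree rooted `phylo` tree (e.g. from [ape::read.tree()]) whose tips
#'   cover all table OTUs; branch lengths must be non-negative.
#' @return a `dist`-like symmetric matrix of class `distance_matrix` with
#'   sample ids.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "count_table"), inherits(tree, "phylo"))
  missing <- setdiff(rownames(table$counts), tree$tip.label)
  if (length(missing) > 0)
    stop("OTUs missing from the tree: ", paste(missing, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths in the tree")
  # basal polytomies (e.g. star trees) are resolved with zero-length
  # branches, which leaves every UniFrac distance unchanged
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  comm <- t(table$counts)
  d <- picante::unifrac(comm, tree)
  as_distance_matrix(as.matrix(d))
}

as_distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  diag(m) <- 0
  class(m) <- c("distance_matrix", "matrix")
  m
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -0.5 * D^2, eigendecomposes it, and scales coordinates by
#' the square root of the (positive) eigenvalues. Axes are ordered by
#' eigenvalue; negative eigenvalues are reported but carry no coordinates.
#'
#' @param dist symmetric distance matrix (a `distance_matrix`, `dist`, or
#'   plain symmetric matrix).
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, all of them including negatives), and
#'   `relative_eig` (fractions of the positive total).
#' @export
pcoa_ordination <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  m <- as_distance_matrix(unclass(dist))
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; the full
  # spectrum (including negatives) is reported below regardless
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = max(n - 1, 1), eig = TRUE))
  ev <- sort(sc$eig, decreasing = TRUE)
  coords <- sc$points
  if (is.null(coords) || ncol(coords) == 0)
    coords <- matrix(0, n, 1, dimnames = list(rownames(m), "Axis1"))
  else colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pos <- ev[ev > 0]
  list(coordinates = coords, eigenvalues = ev,
       relative_eig = if (length(pos) > 0) ev / sum(pos) else ev)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the squared inter-sample distances by one or two factors
#' (additive main effects only; no interaction term is fitted and this is
#' flagged in the result) and tests the pseudo-F statistic by label
#' permutation. p = (1 + #\{permuted F >= observed F\}) / (1 + n_permutations),
#' so p can never be 0. With `strata`, labels are permuted only within
#' strata; a stratum holding a single factor level is unpermutable within
#' itself and triggers a warning (permutations then leave the labels
#' partially or fully invariant, and with all strata degenerate p = 1).
#'
#' @param dist distance matrix.
#' @param factor sample labels (vector aligned with the distance matrix).
#' @param n_permutations number of permutations (default 999).
#' @param strata optional blocking labels restricting permutations.
#' @param factor2 optional second factor (additive two-way model).
#' @param seed integer seed.
#' @return for the one-way model, a `permanova_result` (fields `pseudo_F`,
#'   `p_value`, `r2`, `n_permutations`, `strata`, `terms`); the two-way
#'   model returns the same object with one row per term in `terms`.
#' @export
permanova <- function(dist, factor, n_permutations = 999, strata = NULL,
                      factor2 = NULL, seed = 1) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  m <- as_distance_matrix(unclass(dist))
  f1 <- base::factor(factor)
  stopifnot(length(f1) == nrow(m))
  if (nlevels(f1) < 2) stop("need at least 2 groups")
  if (min(table(f1)) < 2) stop("every group needs at least 2 samples")
  dat <- data.frame(f1 = f1)
  form <- stats::as.formula("d ~ f1")
  if (!is.null(factor2)) {
    dat$f2 <- base::factor(factor2)
    form <- stats::as.formula("d ~ f1 + f2")
  }
  if (!is.null(strata)) {
    strata <- base::factor(strata)
    stopifnot(length(strata) == nrow(m))
    degenerate <- tapply(f1, strata, function(g) length(unique(g)) < 2)
    if (any(degenerate))
      warning("stratum(s) with a single factor level (unpermutable within): ",
              paste(names(degenerate)[degenerate], collapse = ", "))
    ctrl <- permute::how(nperm = n_permutations, blocks = strata)
  } else {
    ctrl <- permute::how(nperm = n_permutations)
  }
  d <- stats::as.dist(m)
  res <- with_seed(seed,
    vegan::adonis2(form, data = dat, permutations = ctrl, by = "terms"))
  terms <- data.frame(term = rownames(res), df = res$Df, r2 = res$R2,
                      pseudo_F = res$F, p_value = res$`Pr(>F)`,
                      stringsAsFactors = FALSE)
  terms <- terms[!terms$term %in% c("Residual", "Total"), , drop = FALSE]
  structure(list(pseudo_F = terms$pseudo_F[1], p_value = terms$p_value[1],
                 r2 = terms$r2[1], n_permutations = n_permutations,
                 strata = strata, terms = terms,
                 interaction_included = FALSE), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (additive main effects, no interaction term)\n")
  print(x$terms, row.names = FALSE)
  cat(sprintf("%d permutations%s\n", x$n_permutations,
              if (!is.null(x$strata)) ", restricted within strata" else ""))
  invisible(x)
}

#' Rank-based group comparisons of diversity indices
#'
#' Thin reporting wrapper around the standard routines: Wilcoxon-Mann-
#' Whitney for two groups, Kruskal-Wallis for more (with pairwise Wilcoxon
#' follow-ups, Holm-adjusted).
#'
#' @param values numeric vector (e.g. a diversity index per sample).
#' @param groups group labels.
#' @return list with `test`, `p_value`, and (for >2 groups) `pairwise`
#'   (the p-value matrix of [stats::pairwise.wilcox.test()]).
#' @export
diversity_group_test <- function(values, groups) {
  g <- base::factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  if (nlevels(g) == 2) {
    p <- suppressWarnings(
      stats::wilcox.test(values ~ g, exact = FALSE)$p.value)
    list(test = "wilcoxon-mann-whitney", p_value = p)
  } else {
    kw <- stats::kruskal.test(values, g)
    pw <- suppressWarnings(stats::pairwise.wilcox.test(values, g, exact = FALSE))
    list(test = "kruskal-wallis", p_value = kw$p.value, pairwise = pw$p.value)
  }
}

#' Write a distance matrix as square TSV with sample-id header row/column
#' @param dist a distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(dist, path) {
  m <- as.matrix(unclass(dist))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
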