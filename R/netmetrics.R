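#' Node and edge counts and mean degree
#'
#' Mean degree (node connectivity) is 2E/N; a 0-node network reports
#' (0, 0, 0).
#'
#' @param net a `signed_network`.
#' @return list with `n_nodes`, `n_edges`, `mean_degree`.
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  nn <- length(network_nodes(net))
  ne <- n_edges(net)
  list(n_nodes = nn, n_edges = ne,
       mean_degree = if (nn > 0) 2 * ne / nn else 0)
}

#' Shortest-path betweenness centrality of nodes and edges
#'
#' Computed on the unweighted undirected topology (signs and partial
#' correlation magnitudes are ignored for path finding), as unnormalised
#' pair counts with even splitting across equal-length shortest paths,
#' per connected component.
#'
#' @param net a `signed_network`.
#' @return list with `node` (named vector), `edge` (vector, edge order of
#'   `net$edges`), `mean_node`, `mean_edge`.
#' @export
betweenness_stats <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (n_edges(net) == 0)
    return(list(node = numeric(0), edge = numeric(0),
                mean_node = 0, mean_edge = 0))
  g <- as_igraph(net)
  nb <- igraph::betweenness(g, directed = FALSE, weights = NA)
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  list(node = nb, edge = eb, mean_node = mean(nb), mean_edge = mean(eb))
}

#' Positive-to-negative edge ratio
#'
#' @param net a `signed_network`.
#' @return n_positive / n_negative; `Inf` when there are no negative edges
#'   (flagged, not an error).
#' @export
sign_ratio <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  npos <- sum(net$edges$sign > 0)
  nneg <- sum(net$edges$sign < 0)
  if (nneg == 0) return(Inf)
  npos / nneg
}

#' Keystone OTUs by outstanding degree
#'
#' Keystones are nodes whose degree exceeds mean + k * SD of the network's
#' degree distribution, sorted by degree (descending).
#'
#' @param net a `signed_network` with at least 3 nodes.
#' @param k number of standard deviations above the mean (default 3).
#' @return data.frame with columns `otu_id`, `degree`.
#' @export
keystone_otus <- function(net, k = 3) {
  stopifnot(inherits(net, "signed_network"))
  nodes <- network_nodes(net)
  if (length(nodes) < 3) stop("keystone detection needs at least 3 nodes")
  deg <- table(factor(c(net$edges$otu_a, net$edges$otu_b), levels = nodes))
  deg <- stats::setNames(as.numeric(deg), nodes)
  thr <- mean(deg) + k * stats::sd(deg)
  key <- deg[deg > thr]
  key <- sort(key, decreasing = TRUE)
  data.frame(otu_id = names(key), degree = as.numeric(key),
             stringsAsFactors = FALSE)
}

#' Module detection by greedy modularity maximisation
#'
#' Modularity is maximised on the absolute edge weights (fast-greedy
#' agglomeration); the partition covers all network nodes.
#'
#' @param net a `signed_network`.
#' @param seed integer seed (the greedy algorithm is deterministic; the
#'   seed is accepted for interface uniformity and recorded).
#' @return list with `membership` (named integer vector), `modularity`,
#'   `n_modules`.
#' @export
detect_modules <- function(net, seed = 1) {
  stopifnot(inherits(net, "signed_network"))
  if (n_edges(net) == 0)
    return(list(membership = integer(0), modularity = NA_real_,
                n_modules = 0, seed = seed))
  g <- as_igraph(net)
  cl <- with_seed(seed,
    igraph::cluster_fast_greedy(g, weights = abs(igraph::E(g)$weight)))
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(cl), n_modules = length(unique(memb)),
       seed = seed)
}

#' Taxonomic composition of network nodes
#'
#' Fraction of network nodes per taxon at the requested rank; nodes missing
#' from the taxonomy are reported as "Unassigned". Fractions sum to 1.
#'
#' @param net a `signed_network`.
#' @param taxonomy data.frame with column `otu_id` and rank columns, or a
#'   named character vector (OTU id -> taxon).
#' @param rank rank column to use when `taxonomy` is a data.frame (default
#'   "phylum").
#' @return named numeric vector of fractions, decreasing.
#' @export
taxon_composition <- function(net, taxonomy, rank = "phylum") {
  stopifnot(inherits(net, "signed_network"))
  nodes <- network_nodes(net)
  if (length(nodes) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.data.frame(taxonomy)) {
    stopifnot("otu_id" %in% names(taxonomy), rank %in% names(taxonomy))
    tax <- stats::setNames(as.character(taxonomy[[rank]]), taxonomy$otu_id)
  } else tax <- taxonomy
  lab <- tax[nodes]
  lab[is.na(lab)] <- "Unassigned"
  frac <- sort(table(lab) / length(nodes), decreasing = TRUE)
  stats::setNames(as.numeric(frac), names(frac))
}

#' Compare two networks' degree and betweenness distributions
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum tests on the degree, node
#' betweenness and edge betweenness distributions of the two networks,
#' with the means and the direction of the difference.
#'
#' @param a,b non-empty `signed_network`s.
#' @return data.frame with one row per metric: means, direction, p-value,
#'   and a `tied` flag for degenerate all-tied comparisons (p reported 1).
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "signed_network"), inherits(b, "signed_network"),
            n_edges(a) > 0, n_edges(b) > 0)
  vals <- function(net) {
    bw <- betweenness_stats(net)
    nodes <- network_nodes(net)
    deg <- as.numeric(table(factor(c(net$edges$otu_a, net$edges$otu_b),
                                   levels = nodes)))
    list(degree = deg, node_betweenness = as.numeric(bw$node),
         edge_betweenness = as.numeric(bw$edge))
  }
  va <- vals(a); vb <- vals(b)
  rows <- lapply(names(va), function(m) {
    x <- va[[m]]; y <- vb[[m]]
    tied <- length(unique(c(x, y))) == 1
    p <- if (tied) 1 else
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(metric = m, mean_a = mean(x), mean_b = mean(y),
               direction = if (mean(x) > mean(y)) "a > b"
                           else if (mean(x) < mean(y)) "a < b" else "a = b",
               p_value = p, tied = tied, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full metrics report for a signed network
#'
#' @param net a `signed_network`.
#' @param taxonomy optional taxonomy (see [taxon_composition()]).
#' @param keystone_k keystone threshold in degree SDs (default 3).
#' @param seed seed for module detection.
#' @return object of class `metrics_report`: node/edge counts, mean degree,
#'   sign counts and ratio, mean node/edge betweenness, keystones, modules,
#'   taxon composition.
#' @export
network_metrics <- function(net, taxonomy = NULL, keystone_k = 3, seed = 1) {
  ds <- degree_stats(net)
  bw <- betweenness_stats(net)
  mods <- detect_modules(net, seed = seed)
  rep <- list(
    label = net$label,
    n_nodes = ds$n_nodes, n_edges = ds$n_edges,
    n_positive = sum(net$edges$sign > 0),
    n_negative = sum(net$edges$sign < 0),
    mean_degree = ds$mean_degree,
    pos_neg_ratio = sign_ratio(net),
    mean_node_betweenness = bw$mean_node,
    mean_edge_betweenness = bw$mean_edge,
    keystones = if (ds$n_nodes >= 3) keystone_otus(net, k = keystone_k)
                else data.frame(otu_id = character(0), degree = numeric(0)),
    modules = mods,
    taxon_composition = if (!is.null(taxonomy))
      taxon_composition(net, taxonomy) else NULL)
  stopifnot(rep$n_edges == rep$n_positive + rep$n_negative)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report '%s'\n", x$label))
  cat(sprintf("  nodes %d, edges %d (%d+/%d-), mean degree %.1f\n",
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative,
              round(x$mean_degree, 1)))
  cat(sprintf("  pos:neg ratio %s, mean node betweenness %.1f, mean edge betweenness %.1f\n",
              if (is.infinite(x$pos_neg_ratio)) "Inf (no negative edges)"
              else sprintf("%.1f", round(x$pos_neg_ratio, 1)),
              round(x$mean_node_betweenness, 1),
              round(x$mean_edge_betweenness, 1)))
  cat(sprintf("  modules: %d, keystones: %d\n", x$modules$n_modules,
              nrow(x$keystones)))
  invisible(x)
}

#' Serialise a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  out <- unclass(report)
  out$modules <- list(n_modules = report$modules$n_modules,
                      modularity = report$modules$modularity,
                      membership = as.list(report$modules$membership))
  out$pos_neg_ratio <- if (is.infinite(out$pos_neg_ratio)) "Inf" else out$pos_neg_ratio
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
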