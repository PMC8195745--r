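#' Construct a signed, weighted, undirected network over OTU identifiers
#'
#' Edges are unordered OTU pairs with a real weight (a partial correlation)
#' and its sign. Self-loops and duplicate pairs are rejected; pairs are
#' stored canonically with `otu_a < otu_b`. By convention the node set of a
#' signed network is the set of edge endpoints, so isolated nodes do not
#' exist.
#'
#' @param edges data.frame with character columns `otu_a`, `otu_b` and a
#'   numeric `weight` column (nonzero). Extra columns (e.g. stability
#'   frequencies) are carried along.
#' @param label provenance label (condition or fraction name).
#' @return object of class `signed_network`.
#' @export
signed_network <- function(edges = NULL, label = NA_character_) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(otu_a = character(0), otu_b = character(0),
                        weight = numeric(0), sign = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("otu_a", "otu_b", "weight") %in% names(edges)))
    edges$otu_a <- as.character(edges$otu_a)
    edges$otu_b <- as.character(edges$otu_b)
    if (any(edges$otu_a == edges$otu_b))
      stop("self-loops are not allowed")
    if (any(edges$weight == 0) || any(!is.finite(edges$weight)))
      stop("edge weights must be finite and nonzero")
    swap <- edges$otu_a > edges$otu_b
    tmp <- edges$otu_a[swap]
    edges$otu_a[swap] <- edges$otu_b[swap]
    edges$otu_b[swap] <- tmp
    if (anyDuplicated(paste(edges$otu_a, edges$otu_b)))
      stop("duplicate edges for the same OTU pair")
    edges$sign <- sign(edges$weight)
    edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, label = label), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network '%s': %d nodes, %d edges (%d+, %d-)\n",
              x$label, length(network_nodes(x)), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Node set of a signed network (endpoints of its edges)
#' @param net a `signed_network`.
#' @return character vector of OTU ids.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$edges$otu_a, net$edges$otu_b)))
}

#' Number of edges
#' @param net a `signed_network`.
#' @export
n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) paste(net$edges$otu_a, net$edges$otu_b, sep = "\r")

#' Random signed network with exact node and sign counts
#'
#' Builds a network with exactly `n_nodes` nodes (all of them edge
#' endpoints: a random spanning cycle guarantees minimum degree 1) and
#' exactly `n_positive` + `n_negative` edges with the requested signs.
#' Useful for reconstructing networks whose published summary gives only
#' node/edge/sign counts.
#'
#' @param n_nodes number of nodes.
#' @param n_positive,n_negative numbers of positive / negative edges; their
#'   sum must be at least `n_nodes` (so the spanning cycle fits) and at most
#'   `choose(n_nodes, 2)`.
#' @param seed integer seed.
#' @param label provenance label.
#' @return a `signed_network`.
#' @export
sample_signed_network <- function(n_nodes, n_positive, n_negative = 0,
                                  seed = 1, label = NA_character_) {
  n_e <- n_positive + n_negative
  stopifnot(n_nodes >= 3, n_e >= n_nodes, n_e <= choose(n_nodes, 2))
  ids <- sprintf("OTU_%05d", seq_len(n_nodes))
  with_seed(seed, {
    ring <- sample(ids)
    a <- ring; b <- c(ring[-1], ring[1])
    used <- new.env(hash = TRUE)
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    for (k in key(a, b)) assign(k, TRUE, envir = used)
    need <- n_e - n_nodes
    while (need > 0) {
      pr <- sample(ids, 2)
      k <- key(pr[1], pr[2])
      if (!is.null(used[[k]])) next
      assign(k, TRUE, envir = used)
      a <- c(a, pr[1]); b <- c(b, pr[2])
      need <- need - 1
    }
    w <- 0.2 * c(rep(1, n_positive), rep(-1, n_negative))
    signed_network(data.frame(otu_a = a, otu_b = b, weight = w,
                              stringsAsFactors = FALSE), label = label)
  })
}

#' Convert a signed network to an igraph graph
#'
#' The graph is undirected; `weight` and `sign` become edge attributes.
#'
#' @param net a `signed_network`.
#' @return an `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (nrow(net$edges) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    net$edges[, c("otu_a", "otu_b", "weight", "sign")],
    directed = FALSE)
}

#' Write a signed network as an edge-list TSV
#'
#' Columns: otu_a, otu_b, partial_r, sign, plus any extra edge columns
#' (e.g. stability_frequency).
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  names(df)[names(df) == "weight"] <- "partial_r"
  df$sign <- ifelse(df$sign > 0, "+", "-")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed network from an edge-list TSV written by [write_edge_list()]
#' @param path input path.
#' @param label provenance label.
#' @return a `signed_network`.
#' @export
read_edge_list <- function(path, label = NA_character_) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(signed_network(label = label))
  names(df)[names(df) == "partial_r"] <- "weight"
  df$sign <- NULL
  signed_network(df, label = label)
}

#' Write a signed network in GraphML format
#' @param net a `signed_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
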