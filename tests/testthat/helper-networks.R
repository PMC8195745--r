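# Shorthand builder: net("A-B", "B-C:-0.2") -> signed_network
net <- function(..., label = "t") {
  specs <- c(...)
  if (length(specs) == 0) return(signed_network(label = label))
  parts <- strsplit(specs, ":", fixed = TRUE)
  pairs <- strsplit(vapply(parts, `[`, "", 1), "-", fixed = TRUE)
  w <- vapply(parts, function(x) if (length(x) > 1) as.numeric(x[2]) else 0.5,
              numeric(1))
  signed_network(data.frame(otu_a = vapply(pairs, `[`, "", 1),
                            otu_b = vapply(pairs, `[`, "", 2),
                            weight = w, stringsAsFactors = FALSE),
                 label = label)
}

edge_key_set <- function(x) sort(paste(x$edges$otu_a, x$edges$otu_b))

# Random signed network over given node names
random_net <- function(nodes, n_edges, seed) {
  all_pairs <- t(combn(nodes, 2))
  stopifnot(n_edges <= nrow(all_pairs))
  rows <- withr::with_seed(seed, sample.int(nrow(all_pairs), n_edges))
  w <- withr::with_seed(seed + 1,
                        sample(c(-1, 1), n_edges, TRUE) * runif(n_edges, 0.1, 0.9))
  signed_network(data.frame(otu_a = all_pairs[rows, 1],
                            otu_b = all_pairs[rows, 2],
                            weight = w, stringsAsFactors = FALSE))
}

# Brute-force betweenness by explicit enumeration of all shortest paths,
# independent of igraph: BFS from every node, count paths pair by pair.
brute_betweenness <- function(net) {
  nodes <- network_nodes(net)
  nn <- length(nodes)
  adj <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    adj[net$edges$otu_a[r], net$edges$otu_b[r]] <- TRUE
    adj[net$edges$otu_b[r], net$edges$otu_a[r]] <- TRUE
  }
  node_b <- stats::setNames(numeric(nn), nodes)
  ekey <- paste(net$edges$otu_a, net$edges$otu_b)
  edge_b <- stats::setNames(numeric(length(ekey)), ekey)
  all_paths <- function(s, t) {
    # enumerate all shortest s-t paths by recursive backtracking over a BFS
    # distance labelling
    dist <- rep(Inf, nn); names(dist) <- nodes
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nodes[adj[v, ]])
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
    if (is.infinite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- rev(acc); return() }
      for (u in nodes[adj[v, ]])
        if (dist[u] == dist[v] - 1) walk(u, c(acc, u))
    }
    walk(t, t)
    paths
  }
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    ps <- all_paths(nodes[i], nodes[j])
    if (length(ps) == 0) next
    for (p in ps) {
      inner <- p[-c(1, length(p))]
      for (v in inner) node_b[v] <- node_b[v] + 1 / length(ps)
      for (k in seq_len(length(p) - 1)) {
        a <- min(p[k], p[k + 1]); b <- max(p[k], p[k + 1])
        edge_b[paste(a, b)] <- edge_b[paste(a, b)] + 1 / length(ps)
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

# Tiny study design used by fast pipeline tests
tiny_design <- function(seed = 9, n_sc = 3, n_ic_specific = 3,
                        n_common_ic = 3) {
  study_design(n_otus = 40, n_samples_per_condition = 12, n_backbone = 6,
               n_sc = n_sc, n_ic_specific = n_ic_specific,
               n_common_ic = n_common_ic, seed = seed)
}
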