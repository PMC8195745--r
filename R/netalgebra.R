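#' Edge difference between two signed networks
#'
#' Returns the edges of `a` whose OTU pair does not occur in `b`. Edge
#' identity is the unordered OTU pair, sign-insensitive by default: a pair
#' present in both networks is removed regardless of sign. With
#' `sign_sensitive = TRUE`, a pair present in both but with opposite signs
#' is retained in the result. Weights are inherited from `a`; the node set
#' is recomputed from the surviving edges.
#'
#' @param a,b `signed_network` objects.
#' @param sign_sensitive match edges by (pair, sign) instead of pair only.
#' @param label provenance label for the result.
#' @return a `signed_network`.
#' @export
edge_difference <- function(a, b, sign_sensitive = FALSE, label = NA_character_) {
  stopifnot(inherits(a, "signed_network"), inherits(b, "signed_network"))
  if (nrow(a$edges) == 0) return(signed_network(label = label))
  hit <- match(edge_keys(a), edge_keys(b))
  drop <- !is.na(hit)
  if (sign_sensitive && any(drop)) {
    same_sign <- a$edges$sign[drop] == b$edges$sign[hit[drop]]
    drop[drop] <- same_sign
  }
  signed_network(a$edges[!drop, , drop = FALSE], label = label)
}

#' Edge intersection of two signed networks
#'
#' Returns the OTU pairs present in both networks. The weight of a common
#' edge is the mean of the two weights and its sign is taken from `a`; pairs
#' whose signs disagree between the two networks are flagged in a
#' `sign_conflict` column (and excluded when `sign_sensitive = TRUE`).
#'
#' @param a,b `signed_network` objects.
#' @param sign_sensitive require matching signs for a pair to intersect.
#' @param label provenance label for the result.
#' @return a `signed_network` with a `sign_conflict` edge column.
#' @export
edge_intersection <- function(a, b, sign_sensitive = FALSE, label = NA_character_) {
  stopifnot(inherits(a, "signed_network"), inherits(b, "signed_network"))
  hit <- match(edge_keys(a), edge_keys(b))
  keep <- !is.na(hit)
  if (!any(keep)) return(signed_network(label = label))
  ea <- a$edges[keep, , drop = FALSE]
  eb <- b$edges[hit[keep], , drop = FALSE]
  conflict <- ea$sign != eb$sign
  if (sign_sensitive) {
    ea <- ea[!conflict, , drop = FALSE]
    eb <- eb[!conflict, , drop = FALSE]
    conflict <- conflict[!conflict]
  }
  if (nrow(ea) == 0) return(signed_network(label = label))
  out <- data.frame(otu_a = ea$otu_a, otu_b = ea$otu_b,
                    weight = ifelse(conflict, ea$weight,
                                    (ea$weight + eb$weight) / 2),
                    sign_conflict = conflict, stringsAsFactors = FALSE)
  signed_network(out, label = label)
}

#' Clean an intercrop network of interference edges
#'
#' Sequentially removes from the intercrop network every edge whose OTU pair
#' occurs in any of the interference networks (bare soil, the two sole
#' crops). The result is independent of the order of the interference list
#' (set semantics); this is asserted.
#'
#' @param ic intercrop `signed_network`.
#' @param interference non-empty list of `signed_network`s to subtract.
#' @param sign_sensitive passed to [edge_difference()].
#' @param label provenance label for the result.
#' @return cleaned `signed_network`.
#' @export
clean_ic_network <- function(ic, interference, sign_sensitive = FALSE,
                             label = NA_character_) {
  stopifnot(inherits(ic, "signed_network"), is.list(interference),
            length(interference) >= 1)
  if (is.na(label)) label <- paste0(ic$label, "_cleaned")
  res <- Reduce(function(x, y) edge_difference(x, y, sign_sensitive, label),
                interference, ic)
  chk <- Reduce(function(x, y) edge_difference(x, y, sign_sensitive, label),
                rev(interference), ic)
  stopifnot(identical(edge_keys(res), edge_keys(chk)))
  res$label <- label
  res
}

#' Split two cleaned intercrop networks into unique and common fractions
#'
#' `common` is the edge intersection of the two cleaned networks;
#' `unique_wheat` / `unique_pea` are each network's edges absent from the
#' other. The three edge sets partition the union of the two inputs'
#' pairs; this partition property is asserted.
#'
#' @param cleaned_wheat,cleaned_pea cleaned intercrop `signed_network`s.
#' @param sign_sensitive passed to the underlying set operations.
#' @return list with `signed_network`s `unique_wheat`, `unique_pea`,
#'   `common`.
#' @export
split_fractions <- function(cleaned_wheat, cleaned_pea, sign_sensitive = FALSE) {
  common <- edge_intersection(cleaned_wheat, cleaned_pea,
                              sign_sensitive = sign_sensitive, label = "common")
  uw <- edge_difference(cleaned_wheat, cleaned_pea,
                        sign_sensitive = sign_sensitive, label = "unique_wheat")
  up <- edge_difference(cleaned_pea, cleaned_wheat,
                        sign_sensitive = sign_sensitive, label = "unique_pea")
  if (!sign_sensitive) {
    all_pairs <- sort(unique(c(edge_keys(cleaned_wheat), edge_keys(cleaned_pea))))
    got <- sort(c(edge_keys(common), edge_keys(uw), edge_keys(up)))
    stopifnot(identical(all_pairs, got))
  }
  list(unique_wheat = uw, unique_pea = up, common = common)
}

#' Precision / recall / F1 of an estimated network against a reference
#'
#' Edge sets are compared as unordered OTU pairs (sign-insensitive).
#'
#' @param estimated,reference `signed_network` objects.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (f1 = 0 when both networks are empty-free of true positives).
#' @export
network_f1 <- function(estimated, reference) {
  ke <- edge_keys(estimated); kr <- edge_keys(reference)
  tp <- sum(ke %in% kr)
  fp <- length(ke) - tp
  fn <- length(kr) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
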