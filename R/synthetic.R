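#' Build a sparse ground-truth precision matrix with planted edges
#'
#' Off-diagonal entries of the latent-Gaussian precision matrix Theta are
#' nonzero exactly at the planted OTU pairs. An edge planted with a positive
#' sign gets Theta_jk = -strength so that its partial correlation
#' (-Theta_jk / sqrt(Theta_jj Theta_kk)) is +strength. If the resulting
#' matrix is not positive definite it is repaired by uniform diagonal
#' inflation (add delta * I with the smallest delta clearing the eigenvalue
#' bound), which preserves the signs of all planted partial correlations;
#' the applied delta is recorded in the `diag_inflation` attribute.
#'
#' @param n_otus number of OTUs (matrix dimension).
#' @param edges data.frame with integer columns `i`, `j` (1-based OTU
#'   indices, i != j) and numeric column `sign` (+1 / -1); or `NULL` for no
#'   edges.
#' @param strength absolute partial-correlation magnitude in (0, 1).
#' @return precision matrix with attributes `diag_inflation` (the delta
#'   added to the diagonal, 0 if none) and `edges` (the planted edges).
#' @export
build_precision <- function(n_otus, edges = NULL, strength = 0.35) {
  stopifnot(is.numeric(n_otus), n_otus >= 1)
  if (!is.numeric(strength) || strength <= 0 || strength >= 1)
    stop("strength must be in (0, 1)")
  theta <- diag(n_otus)
  if (!is.null(edges) && nrow(edges) > 0) {
    stopifnot(all(c("i", "j") %in% names(edges)))
    if (is.null(edges$sign)) edges$sign <- 1
    if (any(edges$i < 1 | edges$i > n_otus | edges$j < 1 | edges$j > n_otus))
      stop("edge indices out of range")
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    if (anyDuplicated(key)) stop("duplicate planted edges")
    for (r in seq_len(nrow(edges))) {
      v <- -edges$sign[r] * strength
      theta[edges$i[r], edges$j[r]] <- v
      theta[edges$j[r], edges$i[r]] <- v
    }
  }
  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  delta <- 0
  if (ev_min <= 1e-8) {
    delta <- 1e-6 - ev_min
    theta <- theta + delta * diag(n_otus)
    # achieved partial correlations shrink by 1/(1 + delta); refuse designs
    # where repair halves the planted magnitude
    if (strength / (1 + delta) < strength / 2) {
      dens <- if (is.null(edges)) 0 else nrow(edges) / choose(n_otus, 2)
      stop(sprintf(
        "cannot plant edges of strength %.3f at density %.3f and stay positive definite",
        strength, dens))
    }
  }
  attr(theta, "diag_inflation") <- delta
  attr(theta, "edges") <- edges
  theta
}

#' Simulate Poisson log-normal counts from a precision matrix
#'
#' For each sample i a log-depth offset o_i is drawn from
#' Normal(depth_log_mean, depth_log_sd), a latent vector
#' Z_i ~ MVN(mu, Sigma = Theta^-1) is drawn, and counts are emitted as
#' Y_ij ~ Poisson(exp(o_i + Z_ij)).
#'
#' @param precision positive-definite latent precision matrix (OTUs x OTUs).
#' @param mu vector of latent log-means (one per OTU).
#' @param n_samples number of samples to draw.
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth model.
#' @param seed integer seed; identical arguments give identical tables.
#' @param experiment,condition metadata labels for the generated samples.
#' @param otu_ids,sample_ids optional identifier vectors.
#' @return a `count_table` with attribute `offsets` (the true per-sample
#'   log-depth offsets).
#' @export
simulate_pln_counts <- function(precision, mu, n_samples,
                                depth_log_mean = 0, depth_log_sd = 0.3,
                                seed = 1, experiment = "E1", condition = "sim",
                                otu_ids = NULL, sample_ids = NULL) {
  p <- nrow(precision)
  stopifnot(length(mu) == p, n_samples >= 1)
  ch <- tryCatch(chol(precision), error = function(e)
    stop("precision matrix is not positive definite"))
  # Sigma = Theta^-1 via the Cholesky factor of Theta
  sigma_chol <- backsolve(ch, diag(p))      # Theta^-1 = L^-1 L^-T with ch = R
  if (is.null(otu_ids)) otu_ids <- sprintf("OTU_%04d", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- sprintf("%s_%s_%02d", experiment, condition, seq_len(n_samples))
  out <- with_seed(seed, {
    offsets <- stats::rnorm(n_samples, depth_log_mean, depth_log_sd)
    zn <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    z <- sweep(zn %*% t(sigma_chol), 2, mu, "+")     # rows ~ MVN(mu, Sigma)
    lambda <- exp(sweep(z, 1, offsets, "+"))
    y <- matrix(stats::rpois(n_samples * p, lambda), n_samples, p)
    list(y = t(y), offsets = offsets)
  })
  counts <- out$y
  dimnames(counts) <- list(otu_ids, sample_ids)
  meta <- data.frame(sample_id = sample_ids, experiment = experiment,
                     condition = condition, stringsAsFactors = FALSE)
  tab <- count_table(counts, meta)
  attr(tab, "offsets") <- stats::setNames(out$offsets, sample_ids)
  tab
}

#' Default study design for the five-condition, two-experiment layout
#'
#' Encodes the synthetic counterpart of a bare soil / sole crop / intercrop
#' rhizosphere study: five conditions share a backbone of soil edges; each
#' crop adds its own sole-crop edges (present in SC and IC of that species),
#' its intercrop-specific edges (IC only), and both intercrop conditions
#' additionally share a common-IC edge set. Planted edges live on the OTUs
#' shared between the two experiments; experiment-specific OTUs are
#' independent. Edge sets are sampled with a per-node degree cap so the
#' planted precision matrices stay diagonally dominant and the planted
#' partial correlations equal exactly +/- `edge_strength`.
#'
#' @param n_otus total number of OTUs across the study (default 200).
#' @param n_samples_per_condition samples per condition per experiment
#'   (default 35).
#' @param edge_strength absolute planted partial correlation (default 0.35).
#' @param negative_fraction fraction of planted edges given a negative sign
#'   (default 0.1).
#' @param n_backbone,n_sc,n_ic_specific,n_common_ic planted edge-set sizes
#'   (backbone shared by all conditions; per-species SC; per-species
#'   IC-specific; common to both IC conditions).
#' @param depth_log_mean,depth_log_sd sequencing-depth offset model.
#' @param latent_mean_mean,latent_mean_sd distribution of per-OTU latent
#'   log-means.
#' @param n_experiments number of experiments (default 2).
#' @param experiment_otu_overlap fraction of OTUs shared between experiments
#'   (default 0.8).
#' @param seed integer seed controlling edge placement and simulation.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_otus = 200, n_samples_per_condition = 35,
                         edge_strength = 0.35, negative_fraction = 0.1,
                         n_backbone = 40, n_sc = 15, n_ic_specific = 15,
                         n_common_ic = 15,
                         depth_log_mean = 0, depth_log_sd = 0.3,
                         latent_mean_mean = 3, latent_mean_sd = 0.5,
                         n_experiments = 2, experiment_otu_overlap = 0.8,
                         seed = 1) {
  stopifnot(n_otus >= 10, n_samples_per_condition >= 1,
            edge_strength > 0, edge_strength < 1,
            negative_fraction >= 0, negative_fraction <= 1,
            n_experiments >= 1,
            experiment_otu_overlap > 0, experiment_otu_overlap <= 1)
  n_shared <- round(experiment_otu_overlap * n_otus)
  sizes <- c(backbone = n_backbone,
             sc_wheat = n_sc, sc_pea = n_sc,
             ic_wheat = n_ic_specific, ic_pea = n_ic_specific,
             common_ic = n_common_ic)
  sets <- with_seed(seed, {
    es <- sample_edge_sets(n_shared, sizes, max_degree = 2)
    for (nm in names(es)) {
      k <- nrow(es[[nm]])
      es[[nm]]$sign <- ifelse(stats::runif(k) < negative_fraction, -1, 1)
    }
    mu <- stats::rnorm(n_shared, latent_mean_mean, latent_mean_sd)
    list(edges = es, mu_shared = mu)
  })
  design <- list(
    n_otus = n_otus, n_samples_per_condition = n_samples_per_condition,
    conditions = c("bare_soil", "wheat_SC", "wheat_IC", "pea_SC", "pea_IC"),
    backbone_edges = sets$edges$backbone,
    sc_edges = list(wheat = sets$edges$sc_wheat, pea = sets$edges$sc_pea),
    ic_specific_edges = list(wheat = sets$edges$ic_wheat, pea = sets$edges$ic_pea),
    common_ic_edges = sets$edges$common_ic,
    edge_strength = edge_strength, negative_fraction = negative_fraction,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    latent_mean = sets$mu_shared,
    n_experiments = n_experiments,
    experiment_otu_overlap = experiment_otu_overlap,
    n_shared = n_shared, seed = seed)
  class(design) <- "study_design"
  validate_design(design)
  design
}

# Sample disjoint edge sets over 1..n with a global per-node degree cap.
sample_edge_sets <- function(n, sizes, max_degree = 2) {
  deg <- integer(n)
  used <- character(0)
  out <- list()
  for (nm in names(sizes)) {
    k <- sizes[[nm]]
    ii <- integer(k); jj <- integer(k)
    got <- 0; tries <- 0
    while (got < k) {
      tries <- tries + 1
      if (tries > 10000 * max(k, 1))
        stop("cannot place ", k, " edges for set '", nm, "' under the degree cap")
      pr <- sample.int(n, 2)
      a <- min(pr); b <- max(pr)
      key <- paste(a, b)
      if (key %in% used || deg[a] >= max_degree || deg[b] >= max_degree) next
      got <- got + 1
      ii[got] <- a; jj[got] <- b
      used <- c(used, key)
      deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    }
    out[[nm]] <- data.frame(i = ii, j = jj)
  }
  out
}

validate_design <- function(design) {
  keys <- function(e) if (is.null(e) || nrow(e) == 0) character(0) else
    paste(pmin(e$i, e$j), pmax(e$i, e$j))
  sets <- list(backbone = keys(design$backbone_edges),
               sc_wheat = keys(design$sc_edges$wheat),
               sc_pea = keys(design$sc_edges$pea),
               ic_wheat = keys(design$ic_specific_edges$wheat),
               ic_pea = keys(design$ic_specific_edges$pea),
               common_ic = keys(design$common_ic_edges))
  all_keys <- unlist(sets)
  if (anyDuplicated(all_keys)) {
    dup <- unique(all_keys[duplicated(all_keys)])
    stop("planted edge sets overlap on pairs: ", paste(dup, collapse = "; "))
  }
  invisible(design)
}

# Per-condition planted edge table (indices into the shared OTU block).
condition_edges <- function(design, condition) {
  pick <- switch(condition,
    bare_soil = list(design$backbone_edges),
    wheat_SC = list(design$backbone_edges, design$sc_edges$wheat),
    wheat_IC = list(design$backbone_edges, design$sc_edges$wheat,
                    design$ic_specific_edges$wheat, design$common_ic_edges),
    pea_SC = list(design$backbone_edges, design$sc_edges$pea),
    pea_IC = list(design$backbone_edges, design$sc_edges$pea,
                  design$ic_specific_edges$pea, design$common_ic_edges),
    stop("unknown condition: ", condition))
  pick <- pick[!vapply(pick, function(e) is.null(e) || nrow(e) == 0, logical(1))]
  if (length(pick) == 0) return(data.frame(i = integer(0), j = integer(0), sign = numeric(0)))
  do.call(rbind, pick)
}

#' Simulate the full multi-condition, multi-experiment study
#'
#' Generates one count table per experiment x condition from
#' condition-specific latent precision matrices, together with the ground
#' truth: per-condition precision matrices, per-condition signed edge lists
#' (as [signed_network] objects over OTU identifiers), and the three target
#' network fractions (wheat-IC-unique, pea-IC-unique, common-IC) implied by
#' the design.
#'
#' @param design a [study_design()].
#' @return list with elements `tables` (list indexed
#'   `<experiment>.<condition>`), `truth` (list: `precisions`, `networks`,
#'   `fractions`, `otu_ids`), and `design`.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  validate_design(design)
  n <- design$n_otus
  n_shared <- design$n_shared
  otu_ids <- sprintf("OTU_%04d", seq_len(n))
  shared_ids <- otu_ids[seq_len(n_shared)]
  extras <- otu_ids[setdiff(seq_len(n), seq_len(n_shared))]
  # split experiment-specific OTUs evenly among experiments
  extra_split <- split(extras, rep(seq_len(design$n_experiments),
                                   length.out = length(extras)))
  precisions <- list(); networks <- list()
  for (cond in design$conditions) {
    ed <- condition_edges(design, cond)
    prec <- build_precision(n_shared, ed, design$edge_strength)
    dimnames(prec) <- list(shared_ids, shared_ids)
    precisions[[cond]] <- prec
    networks[[cond]] <- edges_to_network(ed, shared_ids, design$edge_strength, cond)
  }
  tables <- list()
  k <- 0
  mu_extra <- with_seed(design$seed + 7, stats::rnorm(length(extras), 3, 0.5))
  names(mu_extra) <- extras
  for (e in seq_len(design$n_experiments)) {
    exp_label <- paste0("E", e)
    exp_extras <- if (length(extra_split) >= e) extra_split[[e]] else character(0)
    for (cond in design$conditions) {
      k <- k + 1
      p_tot <- n_shared + length(exp_extras)
      prec <- diag(p_tot)
      prec[seq_len(n_shared), seq_len(n_shared)] <- precisions[[cond]]
      mu <- c(design$latent_mean, mu_extra[exp_extras])
      ids <- c(shared_ids, exp_extras)
      sub_seed <- (design$seed * 1000L + k * 37L) %% .Machine$integer.max
      tab <- simulate_pln_counts(prec, mu, design$n_samples_per_condition,
                                 design$depth_log_mean, design$depth_log_sd,
                                 seed = sub_seed, experiment = exp_label,
                                 condition = cond, otu_ids = ids)
      tab$metadata$species <- switch(substr(cond, 1, 4),
                                     bare = NA_character_,
                                     whea = "wheat", pea_ = "pea")
      tables[[paste(exp_label, cond, sep = ".")]] <- tab
    }
  }
  fractions <- list(
    unique_wheat = edges_to_network(design$ic_specific_edges$wheat, shared_ids,
                                    design$edge_strength, "unique_wheat"),
    unique_pea = edges_to_network(design$ic_specific_edges$pea, shared_ids,
                                  design$edge_strength, "unique_pea"),
    common = edges_to_network(design$common_ic_edges, shared_ids,
                              design$edge_strength, "common"))
  list(tables = tables,
       truth = list(precisions = precisions, networks = networks,
                    fractions = fractions, otu_ids = shared_ids),
       design = design)
}

edges_to_network <- function(edges, otu_ids, strength, label) {
  if (is.null(edges) || nrow(edges) == 0)
    return(signed_network(label = label))
  sg <- if (is.null(edges$sign)) rep(1, nrow(edges)) else edges$sign
  signed_network(data.frame(otu_a = otu_ids[edges$i], otu_b = otu_ids[edges$j],
                            weight = sg * strength,
                            stringsAsFactors = FALSE),
                 label = label)
}
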