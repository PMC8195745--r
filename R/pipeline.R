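#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole workflow. Defaults follow
#' the study conventions: 50% prevalence, |r| > 0.06 for per-condition
#' networks, |r| > 0.03 for the common fraction (applied after the
#' intersection), 30 StARS subsamples at instability threshold 0.05,
#' keystone threshold 3 degree-SDs.
#'
#' @param prevalence_fraction prevalence filter fraction (default 0.5).
#' @param rarefaction_depth even depth for diversity analyses; `NULL`
#'   defaults to the smallest sample total.
#' @param min_abs_r per-condition partial-correlation threshold.
#' @param min_abs_r_common threshold applied to the common fraction after
#'   intersection.
#' @param min_frequency StARS edge-frequency threshold (default 0.9).
#' @param n_penalties penalty-grid size (default 30).
#' @param n_subsamples StARS subsamples (default 30).
#' @param instability_threshold StARS instability target (default 0.05).
#' @param keystone_k keystone degree threshold in SDs (default 3).
#' @param conditions the five condition labels, in order.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(prevalence_fraction = 0.5,
                            rarefaction_depth = NULL,
                            min_abs_r = 0.06, min_abs_r_common = 0.03,
                            min_frequency = 0.9, n_penalties = 30,
                            n_subsamples = 30, instability_threshold = 0.05,
                            keystone_k = 3,
                            conditions = c("bare_soil", "wheat_SC", "wheat_IC",
                                           "pea_SC", "pea_IC"),
                            seed = 1) {
  stopifnot(prevalence_fraction > 0, prevalence_fraction <= 1,
            min_abs_r >= 0, min_abs_r < 1,
            min_abs_r_common >= 0, min_abs_r_common < 1,
            min_frequency >= 0, min_frequency <= 1,
            n_penalties >= 2, n_subsamples >= 2,
            instability_threshold > 0, instability_threshold < 0.5)
  structure(list(prevalence_fraction = prevalence_fraction,
                 rarefaction_depth = rarefaction_depth,
                 min_abs_r = min_abs_r, min_abs_r_common = min_abs_r_common,
                 min_frequency = min_frequency, n_penalties = n_penalties,
                 n_subsamples = n_subsamples,
                 instability_threshold = instability_threshold,
                 keystone_k = keystone_k, conditions = conditions,
                 seed = seed), class = "pipeline_config")
}

#' Run the condition-network workflow on a set of per-experiment tables
#'
#' Stage order: pool experiments (strict OTU intersection), prevalence
#' filter on the entire pooled dataset, per-condition sparse PLN network
#' inference with StARS, cleaning of the two intercrop networks against
#' bare soil and the two sole crops, intersection into unique and common
#' fractions (the common fraction re-thresholded at
#' `min_abs_r_common`), and metrics. Networks are fitted on unrarefied
#' counts with log-total offsets; diversity indices use rarefied counts.
#'
#' @param tables list of `count_table`s (one per experiment x condition, or
#'   one per experiment; conditions are read from the metadata).
#' @param config a [pipeline_config()].
#' @param taxonomy optional taxonomy for composition summaries.
#' @param output_dir optional directory; when given, all networks, metrics,
#'   diversity tables and a manifest JSON are written there.
#' @return list: `networks` (per condition), `cleaned` (wheat_IC, pea_IC),
#'   `fractions` (unique_wheat, unique_pea, common), `metrics`,
#'   `diversity`, `criteria` (per-condition model criteria), `pooled`
#'   (the pooled filtered table), `config`, `manifest`.
#' @export
run_pipeline <- function(tables, config = pipeline_config(), taxonomy = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "pool"
  result <- list(config = config)
  manifest <- list(config = unclass(config), stages = list())
  tryCatch({
    pooled <- pool_experiments(tables)
    manifest$stages$pool <- list(n_otus = n_otus(pooled),
                                 n_samples = n_samples(pooled))
    stage <- "prevalence_filter"
    pooled <- prevalence_filter(pooled, config$prevalence_fraction)
    manifest$stages$prevalence_filter <- list(n_otus = n_otus(pooled))
    result$pooled <- pooled

    stage <- "condition_split"
    missing <- setdiff(config$conditions, unique(pooled$metadata$condition))
    if (length(missing) > 0)
      stop("condition(s) missing from metadata: ",
           paste(missing, collapse = ", "))

    stage <- "network_inference"
    networks <- list(); criteria <- list()
    for (cond in config$conditions) {
      sel <- pooled$metadata$sample_id[pooled$metadata$condition == cond]
      tab <- subset_table(pooled, samples = sel)
      inf <- infer_network(
        tab, min_abs_r = config$min_abs_r,
        min_frequency = config$min_frequency,
        config = stars_config(n_subsamples = config$n_subsamples,
                              instability_threshold = config$instability_threshold,
                              seed = config$seed),
        n_penalties = config$n_penalties, label = cond)
      networks[[cond]] <- inf$network
      criteria[[cond]] <- c(inf$criteria,
                            selected_penalty = inf$stars$selected_penalty)
    }
    result$networks <- networks
    result$criteria <- criteria
    manifest$stages$networks <- lapply(networks, function(nw)
      list(n_nodes = length(network_nodes(nw)), n_edges = n_edges(nw)))

    stage <- "edge_arithmetic"
    interference <- networks[c("bare_soil", "wheat_SC", "pea_SC")]
    cleaned <- list(
      wheat_IC = clean_ic_network(networks$wheat_IC, interference),
      pea_IC = clean_ic_network(networks$pea_IC, interference))
    fractions <- split_fractions(cleaned$wheat_IC, cleaned$pea_IC)
    # the common fraction is re-thresholded at the (laxer) common cutoff
    keep <- abs(fractions$common$edges$weight) > config$min_abs_r_common
    fractions$common <- signed_network(
      fractions$common$edges[keep, , drop = FALSE], label = "common")
    result$cleaned <- cleaned
    result$fractions <- fractions
    manifest$stages$fractions <- lapply(fractions, function(nw)
      list(n_nodes = length(network_nodes(nw)), n_edges = n_edges(nw)))

    stage <- "metrics"
    nets_all <- c(networks, cleaned = NULL)
    result$metrics <- lapply(
      c(cleaned, fractions),
      function(nw) network_metrics(nw, taxonomy = taxonomy,
                                   keystone_k = config$keystone_k,
                                   seed = config$seed))
    stage <- "diversity"
    depth <- config$rarefaction_depth
    if (is.null(depth)) depth <- min(colSums(pooled$counts))
    rare <- rarefy_even_depth(pooled, depth, seed = config$seed)
    result$diversity <- alpha_diversity(rare)
    manifest$stages$diversity <- list(rarefaction_depth = depth,
                                      n_samples = nrow(result$diversity))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$seed <- config$seed
  result$manifest <- manifest
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  all_nets <- c(result$networks,
                stats::setNames(result$cleaned,
                                paste0(names(result$cleaned), "_cleaned")),
                result$fractions)
  for (nm in names(all_nets)) {
    write_edge_list(all_nets[[nm]], file.path(output_dir, paste0(nm, "_edges.tsv")))
    write_graphml(all_nets[[nm]], file.path(output_dir, paste0(nm, ".graphml")))
  }
  for (nm in names(result$metrics))
    write_metrics_json(result$metrics[[nm]],
                       file.path(output_dir, paste0(nm, "_metrics.json")))
  utils::write.table(result$diversity,
                     file.path(output_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(output_dir)
}

#' Simulate a study and run the full recovery pipeline against its truth
#'
#' Convenience wrapper used for end-to-end validation: simulates the
#' five-condition, two-experiment study from a [study_design()], runs
#' [run_pipeline()], and scores the recovered fractions against the planted
#' ground truth by edge-set F1.
#'
#' @param design a [study_design()].
#' @param config a [pipeline_config()]; its seed defaults to the design's.
#' @return list: `pipeline` (the [run_pipeline()] result), `truth`, and
#'   `scores` (per-fraction precision/recall/F1, plus per-condition network
#'   F1 against the planted condition networks).
#' @export
run_synthetic_study <- function(design, config = NULL) {
  if (is.null(config)) config <- pipeline_config(seed = design$seed)
  sim <- simulate_study(design)
  pipe <- run_pipeline(sim$tables, config = config)
  scores <- list(
    fractions = lapply(
      stats::setNames(names(sim$truth$fractions), names(sim$truth$fractions)),
      function(nm) network_f1(pipe$fractions[[switch(nm,
        unique_wheat = "unique_wheat", unique_pea = "unique_pea",
        common = "common")]], sim$truth$fractions[[nm]])),
    conditions = lapply(
      stats::setNames(names(sim$truth$networks), names(sim$truth$networks)),
      function(cond) network_f1(pipe$networks[[cond]],
                                sim$truth$networks[[cond]])))
  list(pipeline = pipe, truth = sim$truth, design = design, scores = scores)
}
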