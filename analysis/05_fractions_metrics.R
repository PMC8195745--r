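#!/usr/bin/env Rscript
# Edge arithmetic and network summaries: clean each intercrop network of
# bare-soil and sole-crop edges, intersect the two cleaned networks into
# unique and common fractions (common re-thresholded at |r| > 0.03), report
# metrics, and score the fractions against the planted ground truth.

suppressPackageStartupMessages(library(rhizonet))

ind <- "results/04_networks"
out <- "results/05_fractions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

nets <- lapply(stats::setNames(nm = c("bare_soil", "wheat_SC", "wheat_IC",
                                      "pea_SC", "pea_IC")),
               function(cond) read_edge_list(
                 file.path(ind, paste0(cond, "_edges.tsv")), label = cond))

interference <- nets[c("bare_soil", "wheat_SC", "pea_SC")]
cleaned <- list(wheat_IC = clean_ic_network(nets$wheat_IC, interference),
                pea_IC = clean_ic_network(nets$pea_IC, interference))
fractions <- split_fractions(cleaned$wheat_IC, cleaned$pea_IC)
keep <- abs(fractions$common$edges$weight) > 0.03
fractions$common <- signed_network(fractions$common$edges[keep, , drop = FALSE],
                                   label = "common")

for (nm in names(cleaned))
  write_edge_list(cleaned[[nm]], file.path(out, paste0(nm, "_cleaned_edges.tsv")))
for (nm in names(fractions)) {
  write_edge_list(fractions[[nm]], file.path(out, paste0(nm, "_edges.tsv")))
  rep <- network_metrics(fractions[[nm]])
  write_metrics_json(rep, file.path(out, paste0(nm, "_metrics.json")))
  message(sprintf("%-12s: %d nodes, %d edges (%d+/%d-), mean degree %.1f",
                  nm, rep$n_nodes, rep$n_edges, rep$n_positive,
                  rep$n_negative, round(rep$mean_degree, 1)))
}

if (n_edges(cleaned$wheat_IC) > 0 && n_edges(cleaned$pea_IC) > 0) {
  cmp <- compare_networks(cleaned$wheat_IC, cleaned$pea_IC)
  utils::write.table(cmp, file.path(out, "cleaned_network_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# recovery against the planted truth from step 01
truth_dir <- "results/01_simulation"
scores <- lapply(stats::setNames(nm = c("unique_wheat", "unique_pea", "common")),
                 function(nm) {
  truth <- read_edge_list(
    file.path(truth_dir, paste0("truth_fraction_", nm, "_edges.tsv")), nm)
  s <- network_f1(fractions[[nm]], truth)
  message(sprintf("%-12s vs truth: precision %.2f, recall %.2f, F1 %.2f",
                  nm, s$precision, s$recall, s$f1))
  s
})
jsonlite::write_json(scores, file.path(out, "recovery_scores.json"),
                     auto_unbox = TRUE, digits = NA)
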