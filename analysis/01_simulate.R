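#!/usr/bin/env Rscript
# Simulate the five-condition, two-experiment rhizosphere study from the
# default ground-truth design: a backbone of soil edges shared by all
# conditions, per-crop sole-crop edges, intercrop-specific edges, and a
# common-intercrop edge set shared by the two intercropped rhizospheres.
# Writes one count/metadata TSV pair per experiment and the true
# per-condition and fraction edge lists.

suppressPackageStartupMessages(library(rhizonet))
seed <- if (length(commandArgs(TRUE)) > 0) as.integer(commandArgs(TRUE)[1]) else 1L

out <- "results/01_simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- study_design(seed = seed)
sim <- simulate_study(design)

# one table per experiment (conditions stacked), the pipeline's input shape
for (e in paste0("E", seq_len(design$n_experiments))) {
  tabs <- sim$tables[grep(paste0("^", e, "\\."), names(sim$tables))]
  counts <- do.call(cbind, lapply(tabs, function(t) t$counts[
    rownames(tabs[[1]]$counts), , drop = FALSE]))
  meta <- do.call(rbind, lapply(tabs, `[[`, "metadata"))
  tab <- count_table(counts, meta)
  write_count_table(tab, file.path(out, paste0(e, "_counts.tsv")),
                    file.path(out, paste0(e, "_metadata.tsv")))
}
for (nm in names(sim$truth$networks))
  write_edge_list(sim$truth$networks[[nm]],
                  file.path(out, paste0("truth_", nm, "_edges.tsv")))
for (nm in names(sim$truth$fractions))
  write_edge_list(sim$truth$fractions[[nm]],
                  file.path(out, paste0("truth_fraction_", nm, "_edges.tsv")))

message(sprintf(
  "simulated %d OTUs (%d shared between experiments), %d samples/condition/experiment",
  design$n_otus, design$n_shared, design$n_samples_per_condition))
message(sprintf(
  "planted edges: %d backbone, %d SC per crop, %d IC-specific per crop, %d common-IC",
  nrow(design$backbone_edges), nrow(design$sc_edges$wheat),
  nrow(design$ic_specific_edges$wheat), nrow(design$common_ic_edges)))
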