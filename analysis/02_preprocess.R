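#!/usr/bin/env Rscript
# Pool the two experiments (strict OTU intersection: anything seen in only
# one experiment is dropped) and apply the 50%-prevalence filter on the
# entire pooled dataset. Writes the pooled filtered table.

suppressPackageStartupMessages(library(rhizonet))

ind <- "results/01_simulation"
out <- "results/02_pooled"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tables <- lapply(c("E1", "E2"), function(e)
  read_count_table(file.path(ind, paste0(e, "_counts.tsv")),
                   file.path(ind, paste0(e, "_metadata.tsv"))))

pooled <- pool_experiments(tables)
n_before <- n_otus(pooled)
pooled <- prevalence_filter(pooled, min_fraction = 0.5)

write_count_table(pooled, file.path(out, "pooled_counts.tsv"),
                  file.path(out, "pooled_metadata.tsv"))

message(sprintf("pooled %d samples; %d OTUs common to both experiments, %d after the 50%% prevalence filter",
                n_samples(pooled), n_before, n_otus(pooled)))
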