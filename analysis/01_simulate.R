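#!/usr/bin/env Rscript
# Stage 1: generate a synthetic cohort with ground-truth plasmid labels
# and write it in the same file shapes a STRING-derived cohort would
# arrive in: one edge list per sample, one plasmid gene catalog, a
# sample manifest, and the planted fragile/robust ground truth.
#
# The cohort emulates the structure the downstream analysis assumes:
# plasmid-encoded proteins are a small minority, most samples carry
# them only at the network periphery (robust), and a small fraction
# carry disconnected loop-bearing plasmid components (fragile).

suppressPackageStartupMessages(library(plasmidPPI))
set.seed(1)

out_dir <- "results/cohort_inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_samples <- 40
# 12 plasmid proteins per sample so the peripheral samples clear the
# default rate-test eligibility (>= 10 plasmid-related PPIs)
tmpl <- generator_params(n_chromosomal = 60, n_plasmid = 12,
                         p_within_chrom = 0.028, p_between = 0.03)
cohort <- generate_cohort(n_samples, tmpl, fragile_fraction = 0.10)

manifest <- data.frame(sample_id = character(), species = character(),
                       edges = character(), stringsAsFactors = FALSE)
catalog_rows <- list()
for (i in seq_along(cohort$samples)) {
  s <- cohort$samples[[i]]
  id <- s$network$sample_id
  edge_path <- file.path(out_dir, paste0(id, "_edges.tsv"))
  write_edge_list(s$network, edge_path)
  manifest <- rbind(manifest,
                    data.frame(sample_id = id,
                               species = s$network$species,
                               edges = edge_path,
                               stringsAsFactors = FALSE))
  catalog_rows[[i]] <- s$catalog$provenance
}
catalog <- unique(do.call(rbind, catalog_rows))
write.csv(catalog[, c("gene_name", "plasmid_id", "species")],
          file.path(out_dir, "plasmid_genes.csv"), row.names = FALSE)
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
write.csv(data.frame(sample_id = manifest$sample_id,
                     fragile = cohort$fragile),
          file.path(out_dir, "ground_truth.csv"), row.names = FALSE)

n_edges <- vapply(cohort$samples,
                  function(s) nrow(s$network$edges), integer(1))
cat(sprintf("wrote %d samples to %s\n", n_samples, out_dir))
cat(sprintf("  edges per sample: median %d (range %d-%d)\n",
            as.integer(median(n_edges)), min(n_edges), max(n_edges)))
cat(sprintf("  planted fragile samples: %d (%.0f%%)\n",
            sum(cohort$fragile), 100 * mean(cohort$fragile)))
cat(sprintf("  catalog: %d gene-plasmid records\n", nrow(catalog)))
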