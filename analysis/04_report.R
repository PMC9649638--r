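#!/usr/bin/env Rscript
# Stage 4: cohort report. Joins the per-sample summaries, per-sample
# rate comparisons (Welch t-test on per-protein degree lists,
# Benjamini-Hochberg corrected across the cohort) and robustness flags
# into one table and a human-readable report.

suppressPackageStartupMessages(library(plasmidPPI))

in_dir <- "results/cohort_inputs"
manifest <- read.csv(file.path(in_dir, "manifest.csv"),
                     stringsAsFactors = FALSE)
catalog <- read_plasmid_gene_table(file.path(in_dir, "plasmid_genes.csv"))

samples <- lapply(seq_len(nrow(manifest)), function(i) {
  net <- read_edge_list(manifest$edges[i], min_score = 400,
                        sample_id = manifest$sample_id[i],
                        species = manifest$species[i])
  list(network = net, catalog = catalog)
})
out <- run_cohort(samples, pipeline_config())

report <- merge(out$summaries,
                out$robustness[, c("sample_id", "apmnle_full",
                                   "apmnle_chrom", "delta",
                                   "component_growth", "robust_flag")],
                by = "sample_id")
report <- merge(report,
                out$rate_comparisons[, c("sample_id", "fold", "p_value",
                                         "p_adjusted", "eligible")],
                by = "sample_id")
write.csv(report, "results/cohort_report.csv", row.names = FALSE)

lines <- c(
  sprintf("cohort report: %d samples (%d failed)",
          nrow(report), length(out$failed)),
  sprintf("plasmid gene fraction: median %.2f%%",
          100 * median(report$plasmid_gene_fraction)),
  sprintf("plasmid-related PPI fraction: median %.2f%%",
          100 * median(report$frac_plasmid_related)),
  sprintf("per-group PPI rate fold (plasmid/chromosomal): median %.2f",
          median(report$fold[report$eligible], na.rm = TRUE)),
  sprintf("samples with different plasmid rates (BH-adjusted p < 0.05): %d/%d tested (%d higher, %d lower)",
          sum(report$p_adjusted < 0.05, na.rm = TRUE),
          sum(!is.na(report$p_adjusted)),
          sum(report$p_adjusted < 0.05 & report$fold > 1, na.rm = TRUE),
          sum(report$p_adjusted < 0.05 & report$fold < 1, na.rm = TRUE)),
  sprintf("robust to plasmid-protein removal: %d/%d (%.1f%%)",
          sum(report$robust_flag), nrow(report),
          100 * mean(report$robust_flag)),
  sprintf("flagged samples: %s",
          if (any(!report$robust_flag))
            paste(report$sample_id[!report$robust_flag], collapse = ", ")
          else "none"))
writeLines(lines, "results/cohort_report.txt")
cat(paste(lines, collapse = "\n"), "\n")
cat("wrote results/cohort_report.csv and results/cohort_report.txt\n")
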