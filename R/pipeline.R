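#' Pipeline configuration
#'
#' All tunable settings of the per-sample and cohort pipelines, with
#' defaults matching the conventional analysis settings: STRING score
#' cut of 400 (strict), aPMNLE sweep 400..900 step 20, persistence span
#' 100 score units, and rate-test eligibility of at least 3 plasmid
#' proteins and 10 plasmid-related PPIs per sample.
#'
#' @param min_score score threshold for edge inclusion (strict `>`).
#' @param sweep_start,sweep_stop,sweep_step aPMNLE threshold grid.
#' @param min_span minimum persistence window span (score units).
#' @param min_plasmid_proteins,min_plasmid_ppis eligibility thresholds
#'   for the per-sample rate comparison.
#' @param sd_rule `"unscaled"` or `"scaled"`: which aPMNLE difference
#'   feeds the cohort 2-SD robustness rule.
#' @param output_dir optional directory for per-sample and cohort CSVs;
#'   `NULL` keeps everything in memory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_score = 400, sweep_start = 400,
                            sweep_stop = 900, sweep_step = 20,
                            min_span = 100, min_plasmid_proteins = 3,
                            min_plasmid_ppis = 10,
                            sd_rule = c("unscaled", "scaled"),
                            output_dir = NULL) {
  sd_rule <- match.arg(sd_rule)
  structure(list(min_score = min_score, sweep_start = sweep_start,
                 sweep_stop = sweep_stop, sweep_step = sweep_step,
                 min_span = min_span,
                 min_plasmid_proteins = min_plasmid_proteins,
                 min_plasmid_ppis = min_plasmid_ppis,
                 sd_rule = sd_rule, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full per-sample pipeline
#'
#' classify -> categorize -> summarize -> per-group rates and rate
#' comparison (when the sample meets the eligibility thresholds) ->
#' topology sweep on the full and chromosomal-only networks with the
#' robustness comparison. Inputs may be objects or file paths (edge
#' list and catalog files are read with the package readers).
#'
#' @param network a [ppi_network()] or path to a STRING-style edge
#'   list.
#' @param catalog a [plasmid_catalog()] or path to a plasmid gene
#'   table.
#' @param config a [pipeline_config()].
#' @return List of class `sample_result`: `network` (labeled and
#'   categorized), `summary` (one row, including aPMNLE fields),
#'   `rate_comparison`, `robustness`, `sweep_full`, `sweep_chrom`.
#' @export
run_sample <- function(network, catalog, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(network))
    network <- read_edge_list(network, min_score = config$min_score)
  if (is.character(catalog))
    catalog <- read_plasmid_gene_table(catalog)
  network <- classify_proteins(network, catalog)
  network <- categorize_edges(network)
  summary <- summarize_sample(network)

  deg <- protein_degrees(network)
  eligible <- summary$n_plasmid_proteins >= config$min_plasmid_proteins &&
    (summary$e_mixed + summary$e_plasmid) >= config$min_plasmid_ppis
  rate_cmp <- compare_group_rates(
    if (eligible) deg$plasmid else numeric(0),
    if (eligible) deg$chromosomal else numeric(0),
    sample_id = network$sample_id)
  rate_cmp$eligible <- eligible

  rob <- robustness_compare(network, config$sweep_start,
                            config$sweep_stop, config$sweep_step,
                            config$min_span)
  summary$apmnle_full <- rob$apmnle_full
  summary$apmnle_chrom <- rob$apmnle_chrom
  summary$scaled_delta <- rob$scaled_delta
  summary$component_growth <- rob$component_growth

  out <- structure(
    list(network = network, summary = summary,
         rate_comparison = rate_cmp, robustness = rob,
         sweep_full = attr(rob, "sweep_full"),
         sweep_chrom = attr(rob, "sweep_chrom")),
    class = "sample_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(config$output_dir, network$sample_id)
    write_edge_list(network, paste0(base, "_edges.tsv"))
    utils::write.csv(out$sweep_full$results,
                     paste0(base, "_sweep_full.csv"), row.names = FALSE)
    utils::write.csv(out$sweep_chrom$results,
                     paste0(base, "_sweep_chrom.csv"), row.names = FALSE)
  }
  out
}

#' Run the pipeline over a cohort
#'
#' Applies [run_sample()] to every (network, catalog) pair, continuing
#' past failed samples with a logged reason, then aggregates: BH
#' adjustment of the rate-comparison p-values across samples and the
#' cohort 2-SD robustness flags.
#'
#' @param samples a `synthetic_cohort`, or a list whose elements are
#'   `synthetic_sample`s or lists with `network` and `catalog`.
#' @param config a [pipeline_config()].
#' @return List of class `cohort_result`: `summaries`,
#'   `rate_comparisons` (with `p_adjusted` filled),
#'   `robustness` (with `robust_flag` filled), `failed` (named
#'   character vector of error messages), `results` (per-sample
#'   `sample_result`s).
#' @export
run_cohort <- function(samples, config = pipeline_config()) {
  if (inherits(samples, "synthetic_cohort")) samples <- samples$samples
  if (length(samples) == 0L) stop("empty cohort manifest")
  results <- list()
  failed <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    res <- tryCatch(run_sample(s$network, s$catalog, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      id <- tryCatch(s$network$sample_id, error = function(e) as.character(i))
      failed[id] <- conditionMessage(res)
      message(sprintf("sample %s failed: %s", id, conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0L) stop("all samples failed")
  summaries <- do.call(rbind, lapply(results, `[[`, "summary"))
  rate_cmp <- do.call(rbind, lapply(results, `[[`, "rate_comparison"))
  rate_cmp$p_adjusted <- adjust_pvalues(rate_cmp$p_value)
  robustness <- do.call(rbind, lapply(results, `[[`, "robustness"))
  robustness <- flag_cohort(robustness,
                            scaled = config$sd_rule == "scaled")
  rownames(summaries) <- rownames(rate_cmp) <- rownames(robustness) <- NULL
  out <- structure(list(summaries = summaries,
                        rate_comparisons = rate_cmp,
                        robustness = robustness,
                        failed = failed, results = results),
                   class = "cohort_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_sample_summary(summaries,
                         file.path(config$output_dir, "cohort_summary.csv"))
    utils::write.csv(rate_cmp,
                     file.path(config$output_dir, "rate_comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(robustness,
                     file.path(config$output_dir, "robustness.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  n <- nrow(x$summaries)
  cat(sprintf("<cohort_result> %d samples (%d failed)\n",
              n, length(x$failed)))
  cat(sprintf("  plasmid-related PPI fraction: median %.4g\n",
              stats::median(x$summaries$frac_plasmid_related)))
  flags <- x$robustness$robust_flag
  if (any(!is.na(flags)))
    cat(sprintf("  robust samples: %d/%d (%.1f%%)\n",
                sum(flags, na.rm = TRUE), sum(!is.na(flags)),
                100 * mean(flags, na.rm = TRUE)))
  invisible(x)
}
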