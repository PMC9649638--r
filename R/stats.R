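#' Per-group PPI rate
#'
#' PPIs per protein for one origin group. Each qualifying edge counts
#' once per group (not once per endpoint): the plasmid rate is
#' (plasmid-plasmid + plasmid-chromosome edges) / plasmid proteins, and
#' the chromosomal rate is chromosomal-only edges / chromosomal
#' proteins. For the published Serratia marcescens Db11 counts this
#' gives (92 + 2214)/69 = 33.4 and 58857/4614 = 12.8.
#'
#' @param summary a one-row [sample_summary()] data.frame.
#' @param group `"plasmid"` or `"chromosomal"`.
#' @return The rate, or `NA` (with a warning) when the group is empty.
#' @export
group_ppi_rate <- function(summary, group = c("plasmid", "chromosomal")) {
  group <- match.arg(group)
  if (group == "plasmid") {
    if (summary$n_plasmid_proteins <= 0) {
      warning("undefined rate: no plasmid proteins")
      return(NA_real_)
    }
    (summary$e_plasmid + summary$e_mixed) / summary$n_plasmid_proteins
  } else {
    if (summary$n_chromosomal_proteins <= 0) {
      warning("undefined rate: no chromosomal proteins")
      return(NA_real_)
    }
    summary$e_chrom / summary$n_chromosomal_proteins
  }
}

#' F-statistic analog for plasmid/chromosome PPI mixing
#'
#' Treats the plasmid-protein frequency p like an allele frequency and
#' compares the observed fraction of mixed (plasmid-chromosome) PPIs,
#' obs, against the random-mixing expectation exp = 2 p (1 - p):
#' F = 1 - obs/exp. F = 0 under random mixing, F > 0 when mixed edges
#' are rarer than expected (the two groups keep to themselves), F = 1
#' at complete separation, and F < 0 under excess mixing.
#'
#' @param n_plasmid,n_chrom protein counts per group.
#' @param e_chrom,e_mixed,e_plasmid edge counts by category.
#' @return An object of class `f_stat_result`: list with `p_plasmid`,
#'   `obs`, `expected`, `f_value` and `defined`. `f_value` is `NA`
#'   (with `defined = FALSE`) when either group is empty or there are
#'   no edges.
#' @export
f_statistic <- function(n_plasmid, n_chrom, e_chrom, e_mixed, e_plasmid) {
  stopifnot(n_plasmid >= 0, n_chrom >= 0,
            e_chrom >= 0, e_mixed >= 0, e_plasmid >= 0)
  total_e <- e_chrom + e_mixed + e_plasmid
  n <- n_plasmid + n_chrom
  p <- if (n > 0) n_plasmid / n else NA_real_
  expected <- if (!is.na(p)) 2 * p * (1 - p) else NA_real_
  obs <- if (total_e > 0) e_mixed / total_e else NA_real_
  defined <- !is.na(expected) && expected > 0 && total_e > 0
  f <- if (defined) 1 - obs / expected else NA_real_
  structure(list(p_plasmid = p, obs = obs, expected = expected,
                 f_value = f, defined = defined),
            class = "f_stat_result")
}

#' @export
print.f_stat_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("F = %.4f (p_plasmid = %.4f, obs = %.4f, exp = %.4f)\n",
                x$f_value, x$p_plasmid, x$obs, x$expected))
  } else {
    cat("F undefined (empty group or no edges)\n")
  }
  invisible(x)
}

#' Per-protein degrees by origin group
#'
#' Degree of every protein in the network's edge set, split by origin
#' label — the inputs for [compare_group_rates()].
#'
#' @param network a labeled [ppi_network()].
#' @return List with numeric vectors `plasmid` and `chromosomal`.
#' @export
protein_degrees <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  if (anyNA(network$proteins$origin))
    stop("network must be classified first")
  ends <- c(network$edges$protein_a, network$edges$protein_b)
  deg <- table(factor(ends, levels = network$proteins$protein))
  deg <- as.numeric(deg)
  list(plasmid = deg[network$proteins$origin == "plasmid"],
       chromosomal = deg[network$proteins$origin == "chromosomal"])
}

#' Compare per-protein PPI rates between groups
#'
#' Welch two-sample t-test on the per-protein degree lists of the
#' plasmid-encoded and chromosomal groups, with the fold difference of
#' means. Welch is used because the two groups' degree variances differ
#' strongly in practice. With fewer than two entries per group, or
#' zero variance in both groups, only the descriptive fields are
#' returned (`tested = FALSE`).
#'
#' @param plasmid_degrees,chrom_degrees numeric vectors of per-protein
#'   degrees.
#' @param sample_id identifier carried into the output row.
#' @return One-row data.frame: `sample_id`, `n_plasmid`, `n_chrom`,
#'   `mean_rate_plasmid`, `mean_rate_chrom`, `fold`, `p_value`,
#'   `p_adjusted` (`NA` until [adjust_pvalues()] is applied across a
#'   cohort), `tested`.
#' @export
compare_group_rates <- function(plasmid_degrees, chrom_degrees,
                                sample_id = "sample") {
  mp <- if (length(plasmid_degrees) > 0) mean(plasmid_degrees) else NA_real_
  mc <- if (length(chrom_degrees) > 0) mean(chrom_degrees) else NA_real_
  fold <- if (!is.na(mp) && !is.na(mc) && mc > 0) mp / mc else NA_real_
  p <- NA_real_
  tested <- FALSE
  if (length(plasmid_degrees) >= 2L && length(chrom_degrees) >= 2L) {
    if (stats::sd(plasmid_degrees) == 0 && stats::sd(chrom_degrees) == 0) {
      # degenerate: both groups constant, no variance to test against
      tested <- FALSE
    } else {
      p <- stats::t.test(plasmid_degrees, chrom_degrees,
                         var.equal = FALSE)$p.value
      tested <- TRUE
    }
  }
  data.frame(sample_id = sample_id,
             n_plasmid = length(plasmid_degrees),
             n_chrom = length(chrom_degrees),
             mean_rate_plasmid = mp, mean_rate_chrom = mc,
             fold = fold, p_value = p, p_adjusted = NA_real_,
             tested = tested, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a cohort's tests.
#'
#' @param p_values numeric vector in \[0, 1\]; `NA`s pass through.
#' @return Adjusted p-values, each >= its raw value.
#' @export
adjust_pvalues <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
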