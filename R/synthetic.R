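#' Generator parameters for synthetic PPI samples
#'
#' Defaults emulate the cohort structure the analysis assumes: plasmid
#' genes are a small minority (~0.65% of proteins), plasmid-related
#' PPIs are a small minority of all PPIs, and scores sit on the STRING
#' 0-999 scale above the conventional 400 cut. The default score
#' distribution is uniform on 401..999 (every edge survives the default
#' threshold); the `"decreasing"` family (linearly decreasing density
#' over 401..999) makes threshold sweeps informative.
#'
#' @param n_chromosomal,n_plasmid protein counts per origin group.
#' @param p_within_chrom,p_within_plasmid,p_between block edge
#'   probabilities of the two-block random graph.
#' @param score_distribution list with `family` ("uniform" or
#'   "decreasing") and integer `min`, `max` on 0..999.
#' @param attachment_mode `"mixed"` (plain two-block model),
#'   `"peripheral"` (plasmid proteins pendant on chromosomal ones: no
#'   plasmid-plasmid edges) or `"disconnected"` (plasmid proteins form
#'   separate loop-bearing components with high-score edges).
#' @param species species name stamped on the sample and its catalog.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_chromosomal = 1530, n_plasmid = 10,
                             p_within_chrom = 0.01,
                             p_within_plasmid = 0.01,
                             p_between = 0.01,
                             score_distribution = list(family = "uniform",
                                                       min = 401, max = 999),
                             attachment_mode = c("mixed", "peripheral",
                                                 "disconnected"),
                             species = "Synthetica exemplaris") {
  attachment_mode <- match.arg(attachment_mode)
  stopifnot(n_chromosomal >= 0, n_plasmid >= 0,
            p_within_chrom >= 0, p_within_chrom <= 1,
            p_within_plasmid >= 0, p_within_plasmid <= 1,
            p_between >= 0, p_between <= 1,
            score_distribution$min >= 0, score_distribution$max <= 999,
            score_distribution$min <= score_distribution$max)
  structure(list(n_chromosomal = n_chromosomal, n_plasmid = n_plasmid,
                 p_within_chrom = p_within_chrom,
                 p_within_plasmid = p_within_plasmid,
                 p_between = p_between,
                 score_distribution = score_distribution,
                 attachment_mode = attachment_mode,
                 species = species),
            class = "generator_params")
}

draw_scores <- function(n, dist) {
  if (n == 0L) return(integer(0))
  lo <- dist$min; hi <- dist$max
  if (identical(dist$family, "decreasing")) {
    # linearly decreasing density over lo..hi
    vals <- lo:hi
    w <- (hi - vals + 1)
    sample(vals, n, replace = TRUE, prob = w / sum(w))
  } else {
    sample(lo:hi, n, replace = TRUE)
  }
}

# all unordered pairs within `ids` kept with probability p
er_pairs <- function(ids, p) {
  n <- length(ids)
  if (n < 2L || p <= 0) return(NULL)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  if (!any(keep)) return(NULL)
  cbind(ids[idx[keep, 1L]], ids[idx[keep, 2L]])
}

# bipartite pairs between `a` and `b` kept with probability p
bi_pairs <- function(a, b, p) {
  if (length(a) == 0L || length(b) == 0L || p <= 0) return(NULL)
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) return(NULL)
  cbind(grid$a[keep], grid$b[keep])
}

#' Generate one synthetic PPI sample
#'
#' Two-block random graph over chromosomal and plasmid proteins with
#' the given block probabilities. `peripheral` mode makes each plasmid
#' protein pendant on one chromosomal protein (no plasmid-plasmid
#' edges, and no effect on loops or components); `disconnected` mode wires plasmid
#' proteins into their own components, chunked into 4-cycles (loop
#' bearing) with a trailing triangle or single edge, carrying
#' high scores (901..999) so the planted components persist across the
#' whole default threshold sweep. The sample's plasmid gene catalog is
#' generated from the true labels (genes chunked 12 per plasmid, the
#' typical plasmid gene content), so catalog-driven classification
#' recovers the ground truth exactly.
#'
#' @param params a [generator_params()].
#' @param sample_id identifier stamped on the network.
#' @return List of class `synthetic_sample`: `network` (classified is
#'   up to the caller), `catalog`, `true_labels` (named character
#'   vector protein -> "plasmid"/"chromosomal").
#' @export
generate_sample <- function(params = generator_params(),
                            sample_id = "synthetic") {
  stopifnot(inherits(params, "generator_params"))
  # protein identifiers double as gene names, as in STRING exports,
  # so classification survives an edge-list file round trip
  chrom_ids <- sprintf("cg%05d", seq_len(params$n_chromosomal))
  plas_ids <- if (params$n_plasmid > 0)
    sprintf("pg%05d", seq_len(params$n_plasmid)) else character(0)
  chrom_genes <- chrom_ids
  plas_genes <- plas_ids

  pairs <- list(er_pairs(chrom_ids, params$p_within_chrom))
  scores_extra <- NULL
  if (params$attachment_mode == "mixed") {
    pairs <- c(pairs, list(er_pairs(plas_ids, params$p_within_plasmid),
                           bi_pairs(plas_ids, chrom_ids, params$p_between)))
  } else if (params$attachment_mode == "peripheral") {
    # each plasmid protein pendant on exactly one chromosomal anchor:
    # pendant vertices change neither the cycle space nor b0, so this
    # attachment is topology-neutral by construction
    bp <- NULL
    if (length(chrom_ids) > 0L && length(plas_ids) > 0L)
      bp <- cbind(plas_ids,
                  sample(chrom_ids, length(plas_ids), replace = TRUE))
    pairs <- c(pairs, list(bp))
  } else { # disconnected: plasmid-only loop-bearing components
    comp_pairs <- NULL
    rest <- plas_ids
    while (length(rest) >= 4L) {
      ring <- rest[1:4]
      rest <- rest[-(1:4)]
      comp_pairs <- rbind(comp_pairs,
                          cbind(ring, ring[c(2:4, 1L)]))
    }
    if (length(rest) == 3L)
      comp_pairs <- rbind(comp_pairs, cbind(rest, rest[c(2L, 3L, 1L)]))
    else if (length(rest) == 2L)
      comp_pairs <- rbind(comp_pairs, cbind(rest[1L], rest[2L]))
    if (!is.null(comp_pairs))
      scores_extra <- sample(901:999, nrow(comp_pairs), replace = TRUE)
    pairs <- c(pairs, list(comp_pairs))
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- matrix(character(0), ncol = 2L)
  n_base <- nrow(pairs) - length(scores_extra)
  scores <- c(draw_scores(n_base, params$score_distribution), scores_extra)

  all_ids <- c(chrom_ids, plas_ids)
  all_genes <- c(chrom_genes, plas_genes)
  proteins <- data.frame(protein = all_ids, gene_name = all_genes,
                         stringsAsFactors = FALSE)
  net <- ppi_network(
    data.frame(protein_a = pairs[, 1L], protein_b = pairs[, 2L],
               combined_score = scores, stringsAsFactors = FALSE),
    proteins = proteins, sample_id = sample_id, species = params$species)

  catalog <- if (params$n_plasmid > 0) {
    plasmid_catalog(data.frame(
      gene_name = plas_genes,
      plasmid_id = sprintf("plasmid%03d",
                           (seq_along(plas_genes) - 1L) %/% 12L + 1L),
      species = params$species, stringsAsFactors = FALSE))
  } else plasmid_catalog()

  true_labels <- setNames(
    c(rep("chromosomal", length(chrom_ids)),
      rep("plasmid", length(plas_ids))), all_ids)
  structure(list(network = net, catalog = catalog,
                 true_labels = true_labels, params = params),
            class = "synthetic_sample")
}

#' Generate a synthetic cohort with planted fragile samples
#'
#' A `fragile_fraction` of samples (Bernoulli per sample) use the
#' `disconnected` attachment mode, planting persistent plasmid-only
#' loops so that removing plasmid proteins changes the aPMNLE; the
#' rest use `peripheral` attachment, which leaves the loop structure
#' untouched. Chromosomal network size is jittered +-10% per sample.
#'
#' @param n_samples cohort size.
#' @param params template [generator_params()].
#' @param fragile_fraction proportion of fragile samples in \[0, 1\].
#' @return List of class `synthetic_cohort`: `samples` (list of
#'   [generate_sample()] outputs) and `fragile` (logical ground-truth
#'   vector).
#' @export
generate_cohort <- function(n_samples, params = generator_params(),
                            fragile_fraction = 0.05) {
  stopifnot(n_samples >= 1, fragile_fraction >= 0, fragile_fraction <= 1)
  fragile <- stats::runif(n_samples) < fragile_fraction
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p <- params
    p$n_chromosomal <- max(4L, round(params$n_chromosomal *
                                       stats::runif(1, 0.9, 1.1)))
    p$attachment_mode <- if (fragile[i]) "disconnected" else "peripheral"
    samples[[i]] <- generate_sample(p, sample_id = sprintf("s%03d", i))
  }
  structure(list(samples = samples, fragile = fragile),
            class = "synthetic_cohort")
}

#' Named deterministic fixtures with known topology
#'
#' Small networks whose Betti numbers are known analytically, used
#' throughout the tests: `cycle4` (the four proteins A-B-C-D in a
#' square: one indirect connection), `cone4` (the square plus an apex
#' P joined to all four: the loop is filled by four trios, b1 = 0),
#' `k4` (complete graph, b1 = 0), `two_triangles` (disjoint, b0 = 2),
#' `tree10` (a 10-vertex path, b1 = 0), `empty5` (5 isolated proteins,
#' b0 = 5). All edge scores are 999 so any threshold keeps them.
#'
#' @param name fixture name.
#' @return A [ppi_network()] with attribute `expected` = list(v, e,
#'   b0, b1).
#' @export
generate_fixture <- function(name = c("cycle4", "cone4", "k4",
                                      "two_triangles", "tree10",
                                      "empty5")) {
  name <- match.arg(name)
  mk <- function(a, b, proteins = NULL) {
    ppi_network(data.frame(protein_a = a, protein_b = b,
                           combined_score = rep(999L, length(a)),
                           stringsAsFactors = FALSE),
                proteins = proteins, sample_id = name,
                species = "fixture")
  }
  net <- switch(name,
    cycle4 = mk(c("A", "B", "C", "A"), c("B", "C", "D", "D")),
    cone4 = mk(c("A", "B", "C", "A", "P", "P", "P", "P"),
               c("B", "C", "D", "D", "A", "B", "C", "D")),
    k4 = mk(c("A", "A", "A", "B", "B", "C"),
            c("B", "C", "D", "C", "D", "D")),
    two_triangles = mk(c("A", "A", "B", "X", "X", "Y"),
                       c("B", "C", "C", "Y", "Z", "Z")),
    tree10 = mk(sprintf("n%02d", 1:9), sprintf("n%02d", 2:10)),
    empty5 = mk(character(0), character(0),
                proteins = data.frame(protein = sprintf("i%d", 1:5),
                                      stringsAsFactors = FALSE)))
  expected <- switch(name,
    cycle4 = list(v = 4L, e = 4L, b0 = 1L, b1 = 1L),
    cone4 = list(v = 5L, e = 8L, b0 = 1L, b1 = 0L),
    k4 = list(v = 4L, e = 6L, b0 = 1L, b1 = 0L),
    two_triangles = list(v = 6L, e = 6L, b0 = 2L, b1 = 0L),
    tree10 = list(v = 10L, e = 9L, b0 = 1L, b1 = 0L),
    empty5 = list(v = 5L, e = 0L, b0 = 5L, b1 = 0L))
  attr(net, "expected") <- expected
  net
}
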