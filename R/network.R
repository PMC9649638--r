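#' Construct a PPI network
#'
#' A `ppi_network` holds one sample's undirected protein-protein
#' interaction network: a protein table (identifier, gene name, origin
#' label) and a canonicalized edge table (unordered pair, STRING combined
#' score on the 0-999 integer scale, interaction category).
#'
#' Edges are canonicalized so that `protein_a < protein_b`
#' lexicographically; duplicate records for the two directions collapse
#' to one undirected edge keeping the maximum score; self-loops are
#' dropped (their count is reported via `message()` and stored in the
#' `n_self_loops` attribute).
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (integer, 0-999). May have zero rows.
#' @param proteins optional data.frame with columns `protein` and
#'   optionally `gene_name`, `origin`. When supplied it acts as a node
#'   manifest: proteins without surviving edges are retained (needed for
#'   per-protein denominators). When `NULL`, proteins are the union of
#'   edge endpoints and the gene name defaults to the protein identifier.
#' @param sample_id,species character scalars identifying the sample.
#' @return An object of class `ppi_network` with elements `sample_id`,
#'   `species`, `proteins` and `edges`.
#' @export
ppi_network <- function(edges, proteins = NULL, sample_id = "sample",
                        species = "unknown") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(protein_a = character(), protein_b = character(),
                        combined_score = integer(),
                        stringsAsFactors = FALSE)
  }
  req <- c("protein_a", "protein_b", "combined_score")
  if (!all(req %in% names(edges)))
    stop("edges must have columns protein_a, protein_b, combined_score")
  edges$protein_a <- as.character(edges$protein_a)
  edges$protein_b <- as.character(edges$protein_b)
  edges$combined_score <- as.integer(edges$combined_score)
  if (nrow(edges) > 0L &&
      (anyNA(edges$combined_score) ||
       any(edges$combined_score < 0L | edges$combined_score > 999L)))
    stop("combined_score must be an integer in [0, 999]")

  self <- edges$protein_a == edges$protein_b
  n_self <- sum(self)
  if (n_self > 0L) {
    message(sprintf("dropped %d self-loop(s)", n_self))
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) > 0L) {
    swap <- edges$protein_a > edges$protein_b
    tmp <- edges$protein_a[swap]
    edges$protein_a[swap] <- edges$protein_b[swap]
    edges$protein_b[swap] <- tmp
    # directed duplicates keep the maximum score (conservative inclusion)
    key <- paste(edges$protein_a, edges$protein_b, sep = "\r")
    ord <- order(key, -edges$combined_score)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  }
  if (!"category" %in% names(edges))
    edges$category <- rep(NA_character_, nrow(edges))
  rownames(edges) <- NULL

  endpoint_ids <- sort(unique(c(edges$protein_a, edges$protein_b)))
  if (is.null(proteins)) {
    proteins <- data.frame(protein = endpoint_ids, stringsAsFactors = FALSE)
  } else {
    if (!"protein" %in% names(proteins))
      stop("proteins manifest must have a 'protein' column")
    proteins$protein <- as.character(proteins$protein)
    missing <- setdiff(endpoint_ids, proteins$protein)
    if (length(missing) > 0L)
      proteins <- rbind(proteins[, "protein", drop = FALSE],
                        data.frame(protein = missing,
                                   stringsAsFactors = FALSE))
    proteins <- proteins[!duplicated(proteins$protein), , drop = FALSE]
    proteins <- proteins[order(proteins$protein), , drop = FALSE]
  }
  if (!"gene_name" %in% names(proteins))
    proteins$gene_name <- proteins$protein
  if (!"origin" %in% names(proteins))
    proteins$origin <- rep(NA_character_, nrow(proteins))
  rownames(proteins) <- NULL

  structure(
    list(sample_id = sample_id, species = species,
         proteins = proteins, edges = edges),
    n_self_loops = n_self,
    class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> sample '%s' (%s): %d proteins, %d edges\n",
              x$sample_id, x$species, nrow(x$proteins), nrow(x$edges)))
  if (any(!is.na(x$proteins$origin))) {
    np <- sum(x$proteins$origin == "plasmid", na.rm = TRUE)
    cat(sprintf("  %d plasmid-encoded, %d chromosomal\n",
                np, nrow(x$proteins) - np))
  }
  invisible(x)
}

#' Filter network edges by combined score
#'
#' Keeps edges with `combined_score > min_score` (strict, matching the
#' STRING convention of "score threshold of > 400"). Proteins with no
#' surviving edge are dropped unless the network was built from a node
#' manifest (`keep_isolated = TRUE`).
#'
#' @param network a [ppi_network()].
#' @param min_score integer threshold; edges must strictly exceed it.
#' @param keep_isolated keep proteins that lose all their edges.
#' @return A filtered `ppi_network`.
#' @export
filter_edges <- function(network, min_score, keep_isolated = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  edges <- network$edges[network$edges$combined_score > min_score, ,
                         drop = FALSE]
  rownames(edges) <- NULL
  proteins <- network$proteins
  if (!keep_isolated) {
    keep <- proteins$protein %in% c(edges$protein_a, edges$protein_b)
    proteins <- proteins[keep, , drop = FALSE]
    rownames(proteins) <- NULL
  }
  out <- network
  out$edges <- edges
  out$proteins <- proteins
  out
}

# igraph view of the edge set; vertices are the network's protein table
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE,
    vertices = network$proteins[, "protein", drop = FALSE])
}
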