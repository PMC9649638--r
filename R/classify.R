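#' Clean a gene name
#'
#' Case-folds gene names and rejects locus-tag-like names: any name
#' ending in an underscore, dash or dot followed by digits (e.g.
#' `group_1`, `ybt.2`) is uninformative for cross-sample matching and is
#' returned as `NA` (the REJECTED marker). Rejected names take no part
#' in either the name-length profile or catalog matching.
#'
#' @param raw character vector of raw gene names; empty strings are a
#'   validation error.
#' @return Character vector: cleaned lower-case names, `NA` where
#'   rejected.
#' @examples
#' clean_gene_name(c("RepA", "sfmC"))   # "repa" "sfmc"
#' clean_gene_name("group_1")           # NA (rejected)
#' @export
clean_gene_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  raw <- as.character(raw)
  if (anyNA(raw) || any(!nzchar(trimws(raw))))
    stop("gene names must be non-empty strings")
  cleaned <- tolower(trimws(raw))
  rejected <- grepl("[._-][0-9]+$", cleaned)
  cleaned[rejected] <- NA_character_
  cleaned
}

#' Profile gene-name lengths
#'
#' Counts short (exactly four characters) versus long (five or more
#' characters) gene names, a proxy for informative annotation: canonical
#' bacterial gene symbols like `sfmC` are four characters, while longer
#' names tend to be descriptive identifiers. Names of three characters
#' or fewer fall in neither class; `NA` (rejected) entries are ignored.
#'
#' @param names character vector of cleaned names (see
#'   [clean_gene_name()]).
#' @return Named integer vector `c(n_short = ..., n_long = ...)`.
#' @export
name_length_profile <- function(names) {
  names <- names[!is.na(names)]
  len <- nchar(names)
  c(n_short = sum(len == 4L), n_long = sum(len >= 5L))
}

#' Construct a plasmid gene catalog
#'
#' Maps each species to the set of cleaned gene names observed on any
#' plasmid of that species, keeping gene-to-plasmid provenance.
#' Duplicate (species, gene) observations collapse; a gene observed on
#' several plasmids keeps all of them in the provenance table.
#'
#' @param df data.frame with columns `gene_name`, `plasmid_id`,
#'   `species`.
#' @return An object of class `plasmid_catalog` with elements `genes`
#'   (data.frame species/gene_name, cleaned, unique) and `provenance`
#'   (data.frame species/gene_name/plasmid_id).
#' @export
plasmid_catalog <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    genes <- data.frame(species = character(), gene_name = character(),
                        stringsAsFactors = FALSE)
    prov <- data.frame(species = character(), gene_name = character(),
                       plasmid_id = character(), stringsAsFactors = FALSE)
    return(structure(list(genes = genes, provenance = prov),
                     class = "plasmid_catalog"))
  }
  req <- c("gene_name", "plasmid_id", "species")
  if (!all(req %in% names(df)))
    stop("catalog input needs columns gene_name, plasmid_id, species")
  cleaned <- clean_gene_name(df$gene_name)
  keep <- !is.na(cleaned)
  prov <- data.frame(species = as.character(df$species)[keep],
                     gene_name = cleaned[keep],
                     plasmid_id = as.character(df$plasmid_id)[keep],
                     stringsAsFactors = FALSE)
  prov <- unique(prov)
  prov <- prov[order(prov$species, prov$gene_name, prov$plasmid_id), ,
               drop = FALSE]
  rownames(prov) <- NULL
  genes <- unique(prov[, c("species", "gene_name")])
  rownames(genes) <- NULL
  structure(list(genes = genes, provenance = prov),
            class = "plasmid_catalog")
}

#' @export
print.plasmid_catalog <- function(x, ...) {
  cat(sprintf(
    "<plasmid_catalog> %d species, %d unique (species, gene) pairs, %d provenance records\n",
    length(unique(x$genes$species)), nrow(x$genes), nrow(x$provenance)))
  invisible(x)
}

#' Genes cataloged for one species
#'
#' @param catalog a [plasmid_catalog()].
#' @param species species name; absent species yield an empty set.
#' @return Character vector of cleaned gene names.
#' @export
catalog_genes <- function(catalog, species) {
  stopifnot(inherits(catalog, "plasmid_catalog"))
  catalog$genes$gene_name[catalog$genes$species == species]
}

#' Label proteins as plasmid-encoded or chromosomal
#'
#' A protein is plasmid-encoded iff its cleaned gene name has been
#' observed on a plasmid originating in the same species; everything
#' else (including proteins whose name is rejected or missing) is
#' chromosomal — plasmid assignment requires positive evidence.
#' Matching is case-insensitive exact match on cleaned names.
#'
#' @param network a [ppi_network()]; its `species` field scopes the
#'   catalog lookup.
#' @param catalog a [plasmid_catalog()]; a species absent from the
#'   catalog behaves as an empty gene set.
#' @return The network with `proteins$origin` filled with
#'   `"plasmid"` / `"chromosomal"`.
#' @export
classify_proteins <- function(network, catalog) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(catalog, "plasmid_catalog"))
  gene_set <- catalog_genes(catalog, network$species)
  nm <- network$proteins$gene_name
  cleaned <- rep(NA_character_, length(nm))
  ok <- !is.na(nm) & nzchar(trimws(nm))
  if (any(ok)) cleaned[ok] <- clean_gene_name(nm[ok])
  origin <- ifelse(!is.na(cleaned) & cleaned %in% gene_set,
                   "plasmid", "chromosomal")
  network$proteins$origin <- origin
  network
}

#' Categorize edges by endpoint origin
#'
#' Edge category is `plasmid_plasmid` when both endpoints are
#' plasmid-encoded, `plasmid_chromosome` when exactly one is, and
#' `chromosomal_only` otherwise. All endpoints must already be labeled
#' (see [classify_proteins()]).
#'
#' @param network a labeled [ppi_network()].
#' @return The network with `edges$category` filled; the three category
#'   counts partition the edge set.
#' @export
categorize_edges <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  origin <- setNames(network$proteins$origin, network$proteins$protein)
  if (anyNA(origin))
    stop("all proteins must be labeled before categorizing edges")
  oa <- origin[network$edges$protein_a] == "plasmid"
  ob <- origin[network$edges$protein_b] == "plasmid"
  n_plasmid_ends <- as.integer(oa) + as.integer(ob)
  network$edges$category <- c("chromosomal_only", "plasmid_chromosome",
                              "plasmid_plasmid")[n_plasmid_ends + 1L]
  network
}

#' Build a per-sample summary from category counts
#'
#' Derived fields are computed from the raw counts: fraction of
#' plasmid-related PPIs (at least one plasmid endpoint), fraction of
#' exclusively plasmid PPIs, plasmid gene fraction, per-group PPI rates
#' and the F-statistic analog. With zero edges the fractions are set to
#' 0 and `zero_edges` flags the degeneracy.
#'
#' @param sample_id sample identifier(s).
#' @param n_plasmid_proteins,n_chromosomal_proteins protein counts.
#' @param e_chrom,e_mixed,e_plasmid edge counts by category
#'   (chromosomal-only, plasmid-chromosome, plasmid-plasmid).
#' @return A data.frame with one row per sample.
#' @export
sample_summary <- function(sample_id, n_plasmid_proteins,
                           n_chromosomal_proteins,
                           e_chrom, e_mixed, e_plasmid) {
  n <- length(sample_id)
  stopifnot(length(n_plasmid_proteins) == n,
            length(n_chromosomal_proteins) == n,
            length(e_chrom) == n, length(e_mixed) == n,
            length(e_plasmid) == n)
  if (n > 0L &&
      (any(n_plasmid_proteins < 0) || any(n_chromosomal_proteins < 0) ||
       any(e_chrom < 0) || any(e_mixed < 0) || any(e_plasmid < 0)))
    stop("counts must be non-negative")
  total_e <- e_chrom + e_mixed + e_plasmid
  n_prot <- n_plasmid_proteins + n_chromosomal_proteins
  zero_edges <- total_e == 0
  frac_rel <- ifelse(zero_edges, 0, (e_mixed + e_plasmid) / total_e)
  frac_excl <- ifelse(zero_edges, 0, e_plasmid / total_e)
  gene_frac <- ifelse(n_prot == 0, 0, n_plasmid_proteins / n_prot)
  rate_p <- ifelse(n_plasmid_proteins > 0,
                   (e_plasmid + e_mixed) / n_plasmid_proteins, NA_real_)
  rate_c <- ifelse(n_chromosomal_proteins > 0,
                   e_chrom / n_chromosomal_proteins, NA_real_)
  f_val <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fs <- f_statistic(n_plasmid_proteins[i], n_chromosomal_proteins[i],
                      e_chrom[i], e_mixed[i], e_plasmid[i])
    f_val[i] <- fs$f_value
  }
  data.frame(sample_id = as.character(sample_id),
             n_plasmid_proteins = as.integer(n_plasmid_proteins),
             n_chromosomal_proteins = as.integer(n_chromosomal_proteins),
             e_chrom = e_chrom, e_mixed = e_mixed, e_plasmid = e_plasmid,
             n_edges = total_e,
             plasmid_gene_fraction = gene_frac,
             frac_plasmid_related = frac_rel,
             frac_exclusive_plasmid = frac_excl,
             rate_plasmid = rate_p, rate_chrom = rate_c,
             f_stat = f_val, zero_edges = zero_edges,
             stringsAsFactors = FALSE)
}

#' Summarize a categorized network
#'
#' Tallies proteins by origin and edges by category and derives all
#' [sample_summary()] fields.
#'
#' @param network a [ppi_network()] with origin labels and edge
#'   categories assigned.
#' @return A one-row data.frame.
#' @export
summarize_sample <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  if (anyNA(network$proteins$origin))
    stop("network must be classified first (classify_proteins)")
  if (nrow(network$edges) > 0L && anyNA(network$edges$category))
    stop("network edges must be categorized first (categorize_edges)")
  np <- sum(network$proteins$origin == "plasmid")
  nc <- sum(network$proteins$origin == "chromosomal")
  cat_counts <- table(factor(network$edges$category,
                             levels = c("chromosomal_only",
                                        "plasmid_chromosome",
                                        "plasmid_plasmid")))
  sample_summary(sample_id = network$sample_id,
                 n_plasmid_proteins = np, n_chromosomal_proteins = nc,
                 e_chrom = as.integer(cat_counts[["chromosomal_only"]]),
                 e_mixed = as.integer(cat_counts[["plasmid_chromosome"]]),
                 e_plasmid = as.integer(cat_counts[["plasmid_plasmid"]]))
}
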