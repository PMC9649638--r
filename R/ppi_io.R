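#' Read a STRING-style protein links file
#'
#' Parses an edge list in the STRING protein-links dialect: three columns
#' `protein1 protein2 combined_score`, separated by tabs or single
#' spaces, with an optional header line; extra trailing columns (such
#' as the category label written by [write_edge_list()]) are ignored.
#' Gzip-compressed files are read
#' transparently. Directed duplicate records collapse to one undirected
#' edge (maximum score kept when the two directions disagree); self-loops
#' are dropped with a logged count; edges must strictly exceed
#' `min_score` to survive.
#'
#' @param path file path (optionally .gz).
#' @param min_score integer; edges with `combined_score > min_score` are
#'   kept (default 400, the conventional STRING medium-confidence cut).
#' @param node_manifest optional character vector or data.frame (column
#'   `protein`) of proteins to retain even when all their edges are
#'   filtered out, so per-protein denominators stay computable.
#' @param sample_id,species sample identifiers stored on the network.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, min_score = 400, node_manifest = NULL,
                           sample_id = basename(path),
                           species = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(make_network_from_fields(character(), character(), integer(),
                                    min_score, node_manifest,
                                    sample_id, species))
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  first <- fields[[1L]]
  if (length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3L]))))
    start <- 2L  # header line
  if (start > length(fields))
    return(make_network_from_fields(character(), character(), integer(),
                                    min_score, node_manifest,
                                    sample_id, species))
  fields <- fields[start:length(fields)]
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed record at line %d: expected 3 columns, found %d",
                 bad[1L] + start - 1L, nf[bad[1L]]))
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  s_chr <- vapply(fields, `[[`, character(1L), 3L)
  s <- suppressWarnings(as.numeric(s_chr))
  bad <- which(is.na(s) | s != floor(s))
  if (length(bad) > 0L)
    stop(sprintf("malformed record at line %d: non-integer score '%s'",
                 bad[1L] + start - 1L, s_chr[bad[1L]]))
  make_network_from_fields(a, b, as.integer(s), min_score, node_manifest,
                           sample_id, species)
}

make_network_from_fields <- function(a, b, s, min_score, node_manifest,
                                     sample_id, species) {
  manifest <- NULL
  if (!is.null(node_manifest)) {
    manifest <- if (is.data.frame(node_manifest)) node_manifest else
      data.frame(protein = as.character(node_manifest),
                 stringsAsFactors = FALSE)
  }
  net <- ppi_network(
    data.frame(protein_a = a, protein_b = b, combined_score = s,
               stringsAsFactors = FALSE),
    proteins = manifest, sample_id = sample_id, species = species)
  filter_edges(net, min_score, keep_isolated = !is.null(manifest))
}

#' Write a network's edge list
#'
#' Writes the canonical undirected edge list (with category column when
#' assigned) as tab-separated text with a header, readable by
#' [read_edge_list()].
#'
#' @param network a [ppi_network()].
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  df <- network$edges
  names(df)[names(df) == "protein_a"] <- "protein1"
  names(df)[names(df) == "protein_b"] <- "protein2"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plasmid gene catalog table
#'
#' Reads a delimited table (comma or tab, autodetected from the header
#' line) with columns `gene_name`, `plasmid_id`, `species` and builds a
#' [plasmid_catalog()]: per species, the set of cleaned gene names ever
#' observed on a plasmid of that species, with gene-to-plasmid
#' provenance. Locus-tag-like names (rejected by [clean_gene_name()])
#' are excluded from the matchable gene sets.
#'
#' @param path file path.
#' @return A `plasmid_catalog`.
#' @export
read_plasmid_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  req <- c("gene_name", "plasmid_id", "species")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    stop("plasmid gene table is missing column(s): ",
         paste(missing, collapse = ", "))
  plasmid_catalog(df)
}

#' Write per-sample summaries
#'
#' One CSV row per sample with all counts, fractions, per-group PPI
#' rates, the F statistic and (when present) topology fields, in a
#' stable column order. Round-trips through [read_sample_summary()].
#'
#' @param summaries a data.frame of summary rows (e.g. rbind of
#'   [summarize_sample()] outputs) or a list of such rows.
#' @param path output path.
#' @export
write_sample_summary <- function(summaries, path) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  if (is.null(summaries))
    summaries <- summarize_skeleton()
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_summary
#' @export
read_sample_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

summarize_skeleton <- function() {
  sample_summary(sample_id = character(0), n_plasmid_proteins = integer(0),
                 n_chromosomal_proteins = integer(0), e_chrom = integer(0),
                 e_mixed = integer(0), e_plasmid = integer(0))
}
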