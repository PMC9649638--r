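# random Erdos-Renyi ppi_network with fixed score, for topology tests
rand_net <- function(v, p, score = 999L, id = "rand") {
  ids <- LETTERS[seq_len(v)]
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(
    data.frame(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L],
               combined_score = rep(score, sum(keep)),
               stringsAsFactors = FALSE),
    proteins = data.frame(protein = ids, stringsAsFactors = FALSE),
    sample_id = id, species = "fixture")
}

# network from a plain edge matrix, scores all 999
net_from_pairs <- function(a, b, scores = rep(999L, length(a)),
                           proteins = NULL, species = "fixture") {
  ppi_network(data.frame(protein_a = a, protein_b = b,
                         combined_score = scores,
                         stringsAsFactors = FALSE),
              proteins = proteins, species = species)
}

# catalog declaring the given gene names plasmid-borne for a species
catalog_for <- function(genes, species = "fixture") {
  if (length(genes) == 0L) return(plasmid_catalog())
  plasmid_catalog(data.frame(gene_name = genes,
                             plasmid_id = "p1", species = species,
                             stringsAsFactors = FALSE))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
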