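test_that("gene names are case-folded and locus-tag-like names rejected", {
  expect_equal(clean_gene_name("RepA"), "repa")
  expect_equal(clean_gene_name("sfmC"), "sfmc")
  expect_true(is.na(clean_gene_name("group_1")))
  expect_true(is.na(clean_gene_name("ybt.2")))
  expect_true(is.na(clean_gene_name("tag-007")))
  # trailing digits without a separator are informative and kept
  expect_equal(clean_gene_name("rpoB2"), "rpob2")
  expect_error(clean_gene_name(""), "non-empty")
})

test_that("name length profile counts 4-char vs >=5-char names only", {
  expect_equal(name_length_profile("sfmc"), c(n_short = 1L, n_long = 0L))
  expect_equal(name_length_profile("repab"), c(n_short = 0L, n_long = 1L))
  expect_equal(name_length_profile("ab"), c(n_short = 0L, n_long = 0L))
  expect_equal(name_length_profile(c("sfmc", "repab", "ab", NA)),
               c(n_short = 1L, n_long = 1L))
})

test_that("classification is species-scoped and needs positive evidence", {
  net <- net_from_pairs(c("x", "x"), c("y", "z"), species = "E. coli")
  net$proteins$gene_name <- c("RepA", "dnaA", "gyrB")

  cat_same <- catalog_for("repa", "E. coli")
  lab <- classify_proteins(net, cat_same)$proteins
  expect_equal(lab$origin[lab$gene_name == "RepA"], "plasmid")
  expect_equal(sum(lab$origin == "plasmid"), 1L)

  # same gene on a plasmid of a different species does not count
  cat_other <- catalog_for("repa", "Serratia")
  lab2 <- classify_proteins(net, cat_other)$proteins
  expect_true(all(lab2$origin == "chromosomal"))

  lab3 <- classify_proteins(net, plasmid_catalog())$proteins
  expect_true(all(lab3$origin == "chromosomal"))

  # case-insensitive match; monotone under catalog growth
  cat_upper <- catalog_for("REPA", "E. coli")
  lab4 <- classify_proteins(net, cat_upper)$proteins
  expect_equal(lab4$origin, lab$origin)
  cat_more <- catalog_for(c("repa", "dnaa"), "E. coli")
  lab5 <- classify_proteins(net, cat_more)$proteins
  expect_gte(sum(lab5$origin == "plasmid"), sum(lab$origin == "plasmid"))
})

test_that("edge categories follow endpoint origins and partition edges", {
  net <- net_from_pairs(c("P", "P", "A"), c("A", "B", "B"))
  net$proteins$origin <-
    ifelse(net$proteins$protein == "P", "plasmid", "chromosomal")
  net <- categorize_edges(net)
  cats <- setNames(net$edges$category,
                   paste(net$edges$protein_a, net$edges$protein_b))
  expect_equal(unname(cats[c("A P", "B P", "A B")]),
               c("plasmid_chromosome", "plasmid_chromosome",
                 "chromosomal_only"))

  s <- summarize_sample(net)
  expect_equal(s$e_mixed, 2)
  expect_equal(s$e_chrom, 1)
  expect_equal(s$e_plasmid, 0)
  expect_equal(s$frac_plasmid_related, 2 / 3)
  expect_equal(s$e_chrom + s$e_mixed + s$e_plasmid, nrow(net$edges))

  net$proteins$origin[1] <- NA
  expect_error(categorize_edges(net), "labeled")
})

test_that("category partition holds on random labeled networks", {
  set.seed(42)
  for (i in 1:20) {
    net <- rand_net(8, 0.4)
    net$proteins$origin <- sample(c("plasmid", "chromosomal"),
                                  nrow(net$proteins), replace = TRUE)
    net <- categorize_edges(net)
    s <- summarize_sample(net)
    expect_equal(s$e_chrom + s$e_mixed + s$e_plasmid, nrow(net$edges))
    expect_true(s$frac_plasmid_related >= 0 &&
                  s$frac_plasmid_related <= 1)
  }
})

test_that("cohort-scale fractions and degenerate summaries behave", {
  # aggregation of the published cohort totals
  s <- sample_summary("cohort", 1L, 1L,
                      e_chrom = 286364425, e_mixed = 390592 - 46772,
                      e_plasmid = 46772)
  expect_equal(round(100 * s$frac_plasmid_related, 3), 0.136)
  expect_equal(round(100 * s$frac_exclusive_plasmid, 3), 0.016)

  # zero plasmid proteins
  net <- net_from_pairs("A", "B")
  net$proteins$origin <- "chromosomal"
  net <- categorize_edges(net)
  s2 <- summarize_sample(net)
  expect_equal(s2$e_mixed + s2$e_plasmid, 0)

  # zero edges: fractions 0, flagged, no division error
  net0 <- ppi_network(NULL,
                      proteins = data.frame(protein = c("A", "B")))
  net0$proteins$origin <- "chromosomal"
  s3 <- summarize_sample(net0)
  expect_true(s3$zero_edges)
  expect_equal(s3$frac_plasmid_related, 0)
})
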