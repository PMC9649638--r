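test_that("edge list reading canonicalizes, dedups and drops self-loops", {
  path <- write_lines_tmp(c("A B 500", "B A 500", "C C 900"))
  expect_message(net <- read_edge_list(path, min_score = 400),
                 "1 self-loop")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$protein_a, "A")
  expect_equal(net$edges$protein_b, "B")
  expect_equal(sort(net$proteins$protein), c("A", "B"))

  # C kept as isolated node only with a manifest
  suppressMessages(
    net2 <- read_edge_list(path, min_score = 400,
                           node_manifest = c("A", "B", "C")))
  expect_true("C" %in% net2$proteins$protein)

  # conflicting directed scores keep the maximum
  p2 <- write_lines_tmp(c("A\tB\t500", "B\tA\t700"))
  net3 <- read_edge_list(p2, min_score = 400)
  expect_equal(net3$edges$combined_score, 700L)
})

test_that("score filtering is strict and composes idempotently", {
  path <- write_lines_tmp(c("A B 400", "C D 401"))
  net <- read_edge_list(path, min_score = 400)
  expect_equal(nrow(net$edges), 1L)      # 400 excluded: strict >
  expect_equal(net$edges$protein_a, "C")

  set.seed(7)
  lows <- sprintf("x%d y%d %d", 1:10, 1:10, sample(0:399, 10))
  net0 <- read_edge_list(write_lines_tmp(lows), min_score = 400)
  expect_equal(nrow(net0$edges), 0L)

  # filter at t1 then t2 == filter at max(t1, t2)
  p3 <- write_lines_tmp(sprintf("a%d b%d %d", 1:50, 1:50,
                                sample(0:999, 50)))
  full <- read_edge_list(p3, min_score = 0)
  once <- filter_edges(full, 700)
  twice <- filter_edges(filter_edges(full, 300), 700)
  expect_equal(twice$edges, once$edges)
})

test_that("reading is deterministic and tolerates headers, gz, empties", {
  lines <- c("protein1 protein2 combined_score", "A B 900", "B C 800")
  path <- write_lines_tmp(lines)
  net1 <- read_edge_list(path, min_score = 400)
  net2 <- read_edge_list(path, min_score = 400)
  expect_identical(net1$edges, net2$edges)
  expect_equal(nrow(net1$edges), 2L)

  gz <- tempfile(fileext = ".gz")
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  netgz <- read_edge_list(gz, min_score = 400)
  expect_equal(netgz$edges$combined_score, net1$edges$combined_score)

  empty <- write_lines_tmp(character(0))
  net0 <- read_edge_list(empty, min_score = 400)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(nrow(net0$proteins), 0L)
})

test_that("malformed records raise parse errors naming the line", {
  p1 <- write_lines_tmp(c("A B 500", "A B"))
  expect_error(read_edge_list(p1), "line 2")
  p2 <- write_lines_tmp(c("A B 500", "C D high"))
  expect_error(read_edge_list(p2), "line 2")
  p3 <- write_lines_tmp(c("A B 12.5"))
  expect_error(read_edge_list(p3), "non-integer")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("plasmid gene tables dedup and scope by species", {
  path <- write_lines_tmp(c("gene_name,plasmid_id,species",
                            "repA,p1,Escherichia coli",
                            "repA,p2,Escherichia coli",
                            "traB,p3,Serratia marcescens"), ".csv")
  cat <- read_plasmid_gene_table(path)
  expect_equal(catalog_genes(cat, "Escherichia coli"), "repa")
  expect_equal(catalog_genes(cat, "Serratia marcescens"), "trab")
  expect_equal(catalog_genes(cat, "absent species"), character(0))
  prov <- cat$provenance[cat$provenance$gene_name == "repa", ]
  expect_setequal(prov$plasmid_id, c("p1", "p2"))

  bad <- write_lines_tmp(c("gene,plasmid,taxon", "repA,p1,x"), ".csv")
  expect_error(read_plasmid_gene_table(bad), "missing column")
})

test_that("sample summaries round-trip through write/read", {
  path <- tempfile(fileext = ".csv")
  write_sample_summary(list(), path)
  expect_equal(length(readLines(path)), 1L)   # header only

  s <- sample_summary(c("s1", "s2"), c(3L, 0L), c(10L, 12L),
                      c(20L, 15L), c(4L, 0L), c(1L, 0L))
  write_sample_summary(s, path)
  back <- read_sample_summary(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$e_chrom, s$e_chrom)
  expect_equal(back$frac_plasmid_related, s$frac_plasmid_related)
  expect_equal(back$f_stat, s$f_stat, tolerance = 1e-12)
})
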