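test_that("connected components count isolated proteins", {
  expect_equal(connected_components(generate_fixture("empty5"))$b0, 5L)
  expect_equal(connected_components(generate_fixture("cycle4"))$b0, 1L)
  two <- generate_fixture("two_triangles")
  expect_equal(connected_components(two)$b0, 2L)
  expect_equal(oracle_betti(two$edges)$b0, 2L)
})

test_that("trio enumeration reports each triangle once, deterministically", {
  tri <- net_from_pairs(c("A", "B", "A"), c("B", "C", "C"))
  expect_equal(nrow(enumerate_trios(tri)), 1L)
  expect_equal(unname(enumerate_trios(tri)[1, ]), c("A", "B", "C"))

  expect_equal(nrow(enumerate_trios(generate_fixture("cycle4"))), 0L)
  expect_equal(nrow(enumerate_trios(generate_fixture("k4"))), 4L)

  # invariant under edge input order
  set.seed(5)
  net <- rand_net(8, 0.5)
  perm <- net
  idx <- sample(nrow(net$edges))
  perm$edges <- net$edges[idx, , drop = FALSE]
  rownames(perm$edges) <- NULL
  expect_identical(enumerate_trios(net), enumerate_trios(perm))
  expect_identical(topology_summary(net), topology_summary(perm))
})

test_that("GF(2) rank handles canonical and random matrices", {
  expect_equal(gf2_rank(diag(1, 7)), 7L)
  expect_equal(gf2_rank(matrix(0, 4, 6)), 0L)
  # duplicated rows collapse
  m <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_equal(gf2_rank(m), 2L)
  # boundary of the cone over the 4-cycle: 8 edges x 4 trios, rank 4
  cone <- generate_fixture("cone4")
  d2 <- plasmidPPI:::boundary2_matrix(cone)
  expect_equal(dim(d2), c(8L, 4L))
  expect_equal(gf2_rank(d2), 4L)
  # wide matrices exercise the multi-word packing (>31 columns)
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rbinom(12 * 40, 1, 0.4), 12, 40)
    expect_equal(gf2_rank(m), oracle_gf2_rank(m))
  }
})

test_that("betti1 reproduces the worked example and the known fixtures", {
  for (f in c("cycle4", "cone4", "k4", "two_triangles", "tree10",
              "empty5")) {
    net <- generate_fixture(f)
    ex <- attr(net, "expected")
    expect_equal(connected_components(net)$b0, ex$b0, label = f)
    expect_equal(betti1(net), ex$b1, label = f)
    expect_equal(betti1(net, method = "rational"), ex$b1, label = f)
  }
})

test_that("betti1 agrees with the full-boundary-matrix oracle", {
  set.seed(101)
  for (i in 1:120) {
    net <- rand_net(sample(4:8, 1), runif(1, 0.2, 0.8))
    ora <- oracle_betti(net$edges, net$proteins$protein)
    ts <- topology_summary(net)
    expect_equal(ts$b0, ora$b0)
    expect_equal(ts$b1, ora$b1)
    expect_equal(betti1(net, method = "rational"), ora$b1)
    # Euler / cycle-space bound, with equality when there is no trio
    bound <- ts$e - ts$v + ts$b0
    expect_true(ts$b1 >= 0 && ts$b1 <= bound)
    if (ts$trios == 0L) expect_equal(ts$b1, bound)
  }
})

test_that("closed forms: cycles, trees, cliques, disjoint unions, pendants", {
  for (n in c(4, 5, 8)) {
    ids <- sprintf("v%d", seq_len(n))
    cyc <- net_from_pairs(ids, ids[c(2:n, 1)])
    expect_equal(betti1(cyc), 1L)
  }
  set.seed(21)
  # random tree: connect each vertex to an earlier one
  parents <- c(NA, vapply(2:12, function(i) sample(i - 1, 1), 1))
  tree <- net_from_pairs(sprintf("t%02d", 2:12),
                         sprintf("t%02d", parents[-1]))
  expect_equal(betti1(tree), 0L)
  for (n in 4:6) {
    cmb <- utils::combn(sprintf("k%d", 1:n), 2)
    expect_equal(betti1(net_from_pairs(cmb[1, ], cmb[2, ])), 0L)
  }
  # disjoint copies double b0 and b1
  two_cycles <- net_from_pairs(c("A", "B", "C", "D", "W", "X", "Y", "Z"),
                               c("B", "C", "D", "A", "X", "Y", "Z", "W"))
  ts <- topology_summary(two_cycles)
  expect_equal(ts$b0, 2L)
  expect_equal(ts$b1, 2L)
  expect_equal(ts$ratio, 1 / 4)  # unchanged by doubling
  # adding a pendant vertex never changes b1
  set.seed(33)
  for (i in 1:10) {
    net <- rand_net(7, 0.4)
    if (nrow(net$edges) == 0) next
    pend <- net
    pend$edges <- rbind(pend$edges,
                        data.frame(protein_a = "A", protein_b = "zz",
                                   combined_score = 999L,
                                   category = NA_character_))
    pend$proteins <- rbind(pend$proteins,
                           data.frame(protein = "zz", gene_name = "zz",
                                      origin = NA_character_))
    expect_equal(betti1(pend), betti1(net))
  }
})

test_that("loops-per-edge ratio is total, including degenerate inputs", {
  expect_equal(topology_summary(generate_fixture("cycle4"))$ratio, 0.25)
  expect_equal(topology_summary(generate_fixture("tree10"))$ratio, 0)
  expect_equal(loops_per_edge(list(b1 = 0, e = 0)), 0)
})

test_that("threshold sweep grid, monotone edge counts, constant case", {
  set.seed(55)
  scores <- sample(0:999, 300, replace = TRUE)
  a <- sprintf("n%03d", sample(1:40, 300, replace = TRUE))
  b <- sprintf("m%03d", sample(1:40, 300, replace = TRUE))
  keep <- a != b
  net <- net_from_pairs(a[keep], b[keep], scores[keep])
  sw <- threshold_sweep(net)
  expect_equal(sw$thresholds, seq(400, 900, 20))
  expect_equal(length(sw$thresholds), 26L)
  expect_true(all(diff(sw$results$e) <= 0))

  # all scores maximal: identical topology at every threshold
  allhi <- generate_fixture("cycle4")
  sw2 <- threshold_sweep(allhi)
  expect_equal(unique(sw2$results$b1), 1L)
  expect_equal(sw2$apmnle, 0.25)
})

test_that("pmnle equals the exhaustive window oracle", {
  th <- seq(400, 900, 20)
  mk <- function(r) list(thresholds = th,
                         results = data.frame(ratio = r))
  # constant ratio comes back unchanged
  expect_equal(pmnle(mk(rep(0.3, 26))), 0.3)
  # a single spike never persists over a 100-score window
  spike <- rep(0, 26); spike[13] <- 1
  expect_equal(pmnle(mk(spike)), 0)
  expect_equal(oracle_pmnle(th, spike), 0)
  # decreasing staircase from the module contract
  stair <- c(0.5, 0.4, 0.3, 0.2, 0.1, rep(0.05, 21))
  expect_equal(pmnle(mk(stair)), oracle_pmnle(th, stair))
  # random ratio profiles
  set.seed(77)
  for (i in 1:50) {
    r <- round(runif(26), 3)
    expect_equal(pmnle(mk(r)), oracle_pmnle(th, r))
  }
  # span too large for the sweep: undefined
  expect_true(is.na(pmnle(mk(rep(0.2, 26)), min_span = 1000)))
  short <- list(thresholds = c(400, 420),
                results = data.frame(ratio = c(0.1, 0.2)))
  expect_true(is.na(pmnle(short, min_span = 100)))
})

test_that("robustness comparison distinguishes pendant from loop-bearing
           plasmid attachment", {
  # no plasmid proteins: identical networks
  net <- generate_fixture("cycle4")
  net$proteins$origin <- "chromosomal"
  r0 <- robustness_compare(net)
  expect_equal(r0$scaled_delta, 0)
  expect_equal(r0$component_growth, 0)

  # pendant plasmid proteins: b1 and b0 unchanged by removal
  pend <- net_from_pairs(c("A", "B", "C", "A", "P1", "P2"),
                         c("B", "C", "D", "D", "A", "C"))
  pend$proteins$origin <- ifelse(grepl("^P", pend$proteins$protein),
                                 "plasmid", "chromosomal")
  rp <- robustness_compare(pend)
  sw_f <- attr(rp, "sweep_full")$results
  sw_c <- attr(rp, "sweep_chrom")$results
  expect_equal(sw_f$b1, sw_c$b1)
  expect_equal(rp$component_growth, 0)

  # disconnected plasmid triangles add components
  tri <- net_from_pairs(c("A", "B", "P1", "P2", "P1"),
                        c("B", "C", "P2", "P3", "P3"))
  tri$proteins$origin <- ifelse(grepl("^P", tri$proteins$protein),
                                "plasmid", "chromosomal")
  rt <- robustness_compare(tri)
  expect_gt(rt$b0_full, rt$b0_chrom)
  expect_gt(rt$component_growth, 0)
})

test_that("cohort flagging uses a strict 2-SD exceedance", {
  base <- data.frame(sample_id = sprintf("s%02d", 1:50),
                     delta = rep(0.2, 50), scaled_delta = rep(0.2, 50))
  same <- flag_cohort(base)
  expect_true(all(same$robust_flag))   # SD = 0, strict: nobody flagged

  out <- base
  out$delta[7] <- 5
  flagged <- flag_cohort(out)
  expect_false(flagged$robust_flag[7])
  expect_true(all(flagged$robust_flag[-7]))

  few <- flag_cohort(base[1, ])
  expect_true(is.na(few$robust_flag))
})
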