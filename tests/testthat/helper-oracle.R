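# Independent homology oracle: full dense boundary matrices d1 and d2,
# plain logical Gaussian elimination (no bit packing), brute-force
# triangle enumeration over all vertex triples. Deliberately shares no
# code with the package's betti1()/gf2_rank() path.

oracle_gf2_rank <- function(m) {
  m <- (m != 0)
  nr <- nrow(m); nc <- ncol(m)
  rank <- 0L
  for (j in seq_len(nc)) {
    piv <- which(m[, j])
    piv <- piv[piv > rank]
    if (length(piv) == 0L) next
    rank <- rank + 1L
    if (piv[1L] != rank) {
      tmp <- m[piv[1L], ]; m[piv[1L], ] <- m[rank, ]; m[rank, ] <- tmp
    }
    for (i in seq_len(nr)) {
      if (i != rank && m[i, j]) m[i, ] <- xor(m[i, ], m[rank, ])
    }
  }
  rank
}

# b0, b1 of the clique 2-complex of an undirected edge list, from
# b0 = v - rank(d1), b1 = (e - rank(d1)) - rank(d2)
oracle_betti <- function(edges, vertices = NULL) {
  if (is.null(vertices))
    vertices <- sort(unique(c(edges$protein_a, edges$protein_b)))
  v <- length(vertices); e <- nrow(edges)
  if (v == 0L) return(list(b0 = 0L, b1 = 0L))
  if (e == 0L) return(list(b0 = v, b1 = 0L))
  d1 <- matrix(0L, v, e)
  for (k in seq_len(e)) {
    d1[match(edges$protein_a[k], vertices), k] <- 1L
    d1[match(edges$protein_b[k], vertices), k] <- 1L
  }
  r1 <- oracle_gf2_rank(d1)
  has_edge <- function(x, y) {
    any((edges$protein_a == x & edges$protein_b == y) |
          (edges$protein_a == y & edges$protein_b == x))
  }
  tris <- list()
  if (v >= 3L) {
    for (cmb in asplit(utils::combn(vertices, 3L), 2L)) {
      if (has_edge(cmb[1], cmb[2]) && has_edge(cmb[2], cmb[3]) &&
          has_edge(cmb[1], cmb[3]))
        tris[[length(tris) + 1L]] <- cmb
    }
  }
  r2 <- 0L
  if (length(tris) > 0L) {
    ekey <- function(x, y) {
      which((edges$protein_a == x & edges$protein_b == y) |
              (edges$protein_a == y & edges$protein_b == x))
    }
    d2 <- matrix(0L, e, length(tris))
    for (j in seq_along(tris)) {
      tr <- tris[[j]]
      d2[ekey(tr[1], tr[2]), j] <- 1L
      d2[ekey(tr[2], tr[3]), j] <- 1L
      d2[ekey(tr[1], tr[3]), j] <- 1L
    }
    r2 <- oracle_gf2_rank(d2)
  }
  list(b0 = v - r1, b1 = (e - r1) - r2)
}

# exhaustive PMNLE oracle: every (i, j) window with span >= min_span
oracle_pmnle <- function(thresholds, ratios, min_span = 100) {
  k <- length(thresholds)
  best <- NA_real_
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      if (thresholds[j] - thresholds[i] < min_span) next
      w <- min(ratios[i:j])
      if (is.na(best) || w > best) best <- w
    }
  }
  best
}
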