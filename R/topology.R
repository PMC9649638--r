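#' Connected components (Betti 0)
#'
#' Number of connected components of the network's current edge set;
#' isolated proteins each count as their own component. An empty
#' network (no proteins) has b0 = 0.
#'
#' @param network a [ppi_network()].
#' @return List with `b0` and `membership` (named integer vector,
#'   component id per protein).
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  if (nrow(network$proteins) == 0L)
    return(list(b0 = 0L, membership = setNames(integer(0), character(0))))
  comp <- igraph::components(as_igraph(network))
  list(b0 = comp$no, membership = comp$membership)
}

#' Enumerate trios (triangles) of the Vietoris-Rips 2-skeleton
#'
#' Every unordered protein triple \{a, b, c\} whose three pairwise PPIs
#' are all present, reported once in a deterministic order. These are
#' the 2-simplices of the clique complex; enumeration iterates over
#' edges and intersects the endpoint neighbour sets, keeping only the
#' third vertex above the edge's endpoints in sort order so each trio
#' appears exactly once.
#'
#' @param network a [ppi_network()].
#' @return Character matrix with 3 columns (`a`, `b`, `c`, sorted
#'   within and across rows); zero rows when the network has no
#'   triangle.
#' @export
enumerate_trios <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  empty <- matrix(character(0), ncol = 3L,
                  dimnames = list(NULL, c("a", "b", "c")))
  if (nrow(network$edges) == 0L) return(empty)
  ids <- sort(unique(c(network$edges$protein_a, network$edges$protein_b)))
  ia <- match(network$edges$protein_a, ids)
  ib <- match(network$edges$protein_b, ids)
  # neighbour sets over vertex indices (ids are sorted, so index order
  # is lexicographic id order)
  nb <- vector("list", length(ids))
  for (k in seq_along(ia)) {
    nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
    nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
  }
  out <- vector("list", length(ia))
  for (k in seq_along(ia)) {
    u <- min(ia[k], ib[k]); v <- max(ia[k], ib[k])
    common <- intersect(nb[[u]], nb[[v]])
    common <- common[common > v]
    if (length(common) > 0L)
      out[[k]] <- cbind(u, v, sort(common))
  }
  tri <- do.call(rbind, out)
  if (is.null(tri) || nrow(tri) == 0L) return(empty)
  tri <- tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
  structure(matrix(ids[tri], ncol = 3L),
            dimnames = list(NULL, c("a", "b", "c")))
}

#' Rank of a binary matrix over GF(2)
#'
#' Gaussian elimination over the two-element field, with rows packed
#' into 31-bit integer words so the elimination XORs whole rows at
#' once. Deterministic: the pivot is always the first eligible row.
#'
#' @param m numeric/logical matrix with entries 0/1 (or `TRUE`/`FALSE`).
#' @return Integer rank.
#' @export
gf2_rank <- function(m) {
  if (is.null(m) || length(m) == 0L) return(0L)
  if (!is.matrix(m)) stop("gf2_rank expects a matrix")
  nr <- nrow(m); nc <- ncol(m)
  if (nr == 0L || nc == 0L) return(0L)
  mode(m) <- "integer"
  if (any(m != 0L & m != 1L)) stop("matrix entries must be 0/1")
  nw <- (nc + 30L) %/% 31L
  W <- matrix(0L, nr, nw)
  for (w in seq_len(nw)) {
    cols <- ((w - 1L) * 31L + 1L):min(w * 31L, nc)
    W[, w] <- as.integer(m[, cols, drop = FALSE] %*%
                           2^(seq_along(cols) - 1L))
  }
  rank <- 0L
  for (col in seq_len(nc)) {
    w <- (col - 1L) %/% 31L + 1L
    mask <- bitwShiftL(1L, (col - 1L) %% 31L)
    rows <- which(bitwAnd(W[, w], mask) != 0L)
    rows <- rows[rows > rank]
    if (length(rows) == 0L) next
    piv <- rows[1L]
    rank <- rank + 1L
    if (piv != rank) {
      tmp <- W[piv, ]; W[piv, ] <- W[rank, ]; W[rank, ] <- tmp
    }
    hit <- which(bitwAnd(W[, w], mask) != 0L)
    hit <- hit[hit != rank]
    if (length(hit) > 0L)
      W[hit, ] <- bitwXor(W[hit, , drop = FALSE],
                          matrix(W[rank, ], length(hit), nw, byrow = TRUE))
    if (rank == min(nr, nc)) break
  }
  rank
}

# triangle boundary matrix: rows = edges (canonical a<b keys),
# columns = trios; entry 1 iff the edge bounds the trio.
# oriented = TRUE gives the signed version (+1, +1, -1) used by the
# rational-rank cross-check.
boundary2_matrix <- function(network, trios = NULL, oriented = FALSE) {
  if (is.null(trios)) trios <- enumerate_trios(network)
  e_key <- paste(network$edges$protein_a, network$edges$protein_b,
                 sep = "\r")
  nt <- nrow(trios)
  d2 <- matrix(if (oriented) 0 else 0L, nrow(network$edges), max(nt, 0L))
  if (nt > 0L) {
    ab <- match(paste(trios[, 1L], trios[, 2L], sep = "\r"), e_key)
    bc <- match(paste(trios[, 2L], trios[, 3L], sep = "\r"), e_key)
    ac <- match(paste(trios[, 1L], trios[, 3L], sep = "\r"), e_key)
    cols <- seq_len(nt)
    d2[cbind(ab, cols)] <- 1
    d2[cbind(bc, cols)] <- 1
    d2[cbind(ac, cols)] <- if (oriented) -1 else 1
  }
  d2
}

#' First Betti number (indirect connections)
#'
#' Number of independent non-trivial loops of the Vietoris-Rips
#' 2-skeleton: cycles of PPIs not filled in by trios. Computed as the
#' cycle-space dimension e - v + b0 minus the GF(2) rank of the
#' triangle boundary matrix. A rational-arithmetic route (QR rank of
#' the oriented boundary) is available as a cross-check; the two agree
#' in the absence of 2-torsion, which clique complexes of the sizes
#' handled here do not exhibit in practice.
#'
#' @param network a [ppi_network()].
#' @param method `"gf2"` (default) or `"rational"`.
#' @return Integer b1 >= 0.
#' @export
betti1 <- function(network, method = c("gf2", "rational")) {
  method <- match.arg(method)
  stopifnot(inherits(network, "ppi_network"))
  e <- nrow(network$edges)
  if (e == 0L) return(0L)
  v <- nrow(network$proteins)
  b0 <- connected_components(network)$b0
  cycle_dim <- e - v + b0
  if (cycle_dim == 0L) return(0L)
  trios <- enumerate_trios(network)
  if (nrow(trios) == 0L) return(as.integer(cycle_dim))
  if (method == "gf2") {
    r2 <- gf2_rank(boundary2_matrix(network, trios))
  } else {
    d2 <- boundary2_matrix(network, trios, oriented = TRUE)
    r2 <- qr(d2)$rank
  }
  as.integer(cycle_dim - r2)
}

#' Topology summary of a network
#'
#' Vertex, edge and trio counts, Betti 0 and 1, and the loops-per-edge
#' ratio, as one row of a threshold sweep table.
#'
#' @param network a [ppi_network()].
#' @return One-row data.frame `v, e, trios, b0, b1, ratio`.
#' @export
topology_summary <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  v <- nrow(network$proteins)
  e <- nrow(network$edges)
  b0 <- connected_components(network)$b0
  trios <- enumerate_trios(network)
  b1 <- betti1(network)
  data.frame(v = v, e = e, trios = nrow(trios), b0 = b0, b1 = b1,
             ratio = loops_per_edge(list(b1 = b1, e = e)))
}

#' Loops-per-edge ratio
#'
#' b1 divided by the edge count; defined as 0 on an edgeless network so
#' sweeps over sparse high thresholds remain total.
#'
#' @param result a list or one-row data.frame with fields `b1` and `e`.
#' @return Numeric ratio.
#' @export
loops_per_edge <- function(result) {
  if (result$e == 0) return(0)
  result$b1 / result$e
}

#' Topology across a score-threshold sweep
#'
#' Filters the network at each threshold of the inclusive sequence
#' `seq(start, stop, step)` (edges must strictly exceed the threshold;
#' proteins with no surviving edge drop out) and records a topology
#' summary per threshold, plus the persistent maximum of non-trivial
#' loops per edge over the grid (the aPMNLE at the default 400..900
#' step-20 grid of 26 thresholds).
#'
#' @param network a [ppi_network()].
#' @param start,stop,step integer sweep grid (defaults 400, 900, 20).
#' @param min_span minimum score span for the persistence window
#'   (default 100).
#' @return An object of class `threshold_sweep`: list with
#'   `thresholds`, `results` (data.frame threshold, v, e, trios, b0,
#'   b1, ratio) and `apmnle`.
#' @export
threshold_sweep <- function(network, start = 400, stop = 900, step = 20,
                            min_span = 100) {
  stopifnot(inherits(network, "ppi_network"), start <= stop, step > 0)
  thresholds <- seq(start, stop, by = step)
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    sub <- filter_edges(network, thresholds[i])
    rows[[i]] <- cbind(threshold = thresholds[i], topology_summary(sub))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  sweep <- structure(list(thresholds = thresholds, results = results,
                          apmnle = NA_real_, min_span = min_span),
                     class = "threshold_sweep")
  sweep$apmnle <- pmnle(sweep, min_span)
  sweep
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf(
    "<threshold_sweep> %d thresholds (%d..%d), aPMNLE = %s\n",
    length(x$thresholds), min(x$thresholds), max(x$thresholds),
    if (is.na(x$apmnle)) "undefined" else format(x$apmnle, digits = 4)))
  invisible(x)
}

#' Persistent maximum of non-trivial loops per edge (PMNLE)
#'
#' The largest loops-per-edge ratio reached or exceeded across a
#' contiguous threshold window whose score span (last minus first
#' threshold) is at least `min_span`: over every qualifying window,
#' take the minimum ratio inside it, and return the maximum of those
#' window minima. A single-threshold spike therefore never persists.
#' On the default 400..900 step-20 grid this is the aPMNLE; `min_span`
#' of 100 score units means windows of at least 6 consecutive grid
#' points.
#'
#' @param sweep a [threshold_sweep()] (or list with `thresholds` and
#'   `results$ratio`).
#' @param min_span minimum score span of the window.
#' @return The PMNLE value, or `NA` when no window spans `min_span`.
#' @export
pmnle <- function(sweep, min_span = 100) {
  th <- sweep$thresholds
  ratio <- sweep$results$ratio
  k <- length(th)
  if (k == 0L) return(NA_real_)
  best <- NA_real_
  for (i in seq_len(k)) {
    j <- which(th - th[i] >= min_span)
    j <- j[j >= i]
    if (length(j) == 0L) next
    # the tightest qualifying window starting at i; wider windows can
    # only have smaller minima, so they never beat it
    w_min <- min(ratio[i:j[1L]])
    if (is.na(best) || w_min > best) best <- w_min
  }
  best
}

#' Robustness of network topology to plasmid-protein removal
#'
#' Runs the threshold sweep on the full network and on the
#' chromosomal-only induced subnetwork (plasmid-encoded proteins and
#' all their edges removed), and compares the two aPMNLE values: their
#' difference, the difference scaled by the full-network aPMNLE, and
#' the growth in connected components (at the first sweep threshold)
#' when plasmid proteins are included. The cohort-level robustness flag
#' is assigned afterwards by [flag_cohort()].
#'
#' @param network a classified [ppi_network()].
#' @param start,stop,step,min_span sweep parameters, see
#'   [threshold_sweep()].
#' @return One-row data.frame: `sample_id`, `apmnle_full`,
#'   `apmnle_chrom`, `delta` (full minus chromosomal), `scaled_delta`
#'   (`NA` when the full aPMNLE is 0 or undefined, except that two
#'   identical aPMNLEs give 0), `b0_full`, `b0_chrom`,
#'   `component_growth` (percent), `robust_flag` (`NA` here).
#' @export
robustness_compare <- function(network, start = 400, stop = 900,
                               step = 20, min_span = 100) {
  stopifnot(inherits(network, "ppi_network"))
  if (anyNA(network$proteins$origin))
    stop("network must be classified first")
  chrom <- network
  keep <- chrom$proteins$origin == "chromosomal"
  chrom$proteins <- chrom$proteins[keep, , drop = FALSE]
  keep_e <- chrom$edges$protein_a %in% chrom$proteins$protein &
    chrom$edges$protein_b %in% chrom$proteins$protein
  chrom$edges <- chrom$edges[keep_e, , drop = FALSE]
  rownames(chrom$proteins) <- rownames(chrom$edges) <- NULL

  sw_full <- threshold_sweep(network, start, stop, step, min_span)
  sw_chrom <- threshold_sweep(chrom, start, stop, step, min_span)
  af <- sw_full$apmnle
  ac <- sw_chrom$apmnle
  delta <- af - ac
  scaled <- if (!is.na(af) && !is.na(ac) && af == ac) 0
  else if (is.na(af) || af <= 0) NA_real_
  else (af - ac) / af
  b0f <- sw_full$results$b0[1L]
  b0c <- sw_chrom$results$b0[1L]
  growth <- if (b0c > 0) 100 * (b0f - b0c) / b0c else NA_real_
  out <- data.frame(sample_id = network$sample_id,
                    apmnle_full = af, apmnle_chrom = ac,
                    delta = delta, scaled_delta = scaled,
                    b0_full = b0f, b0_chrom = b0c,
                    component_growth = growth,
                    robust_flag = NA, stringsAsFactors = FALSE)
  attr(out, "sweep_full") <- sw_full
  attr(out, "sweep_chrom") <- sw_chrom
  out
}

#' Cohort-level robustness flagging
#'
#' Flags samples whose aPMNLE difference (full minus chromosomal-only)
#' stands out from the cohort: the standard deviation of the cohort's
#' differences is computed, and a sample is non-robust when its
#' difference exceeds the cohort mean by strictly more than `k_sd`
#' standard deviations. With all differences equal the SD is 0 and no
#' sample is flagged. The difference used is unscaled by default; set
#' `scaled = TRUE` to use the scaled deltas instead.
#'
#' @param results data.frame of [robustness_compare()] rows.
#' @param k_sd flagging multiplier (default 2).
#' @param scaled use `scaled_delta` instead of `delta`.
#' @return `results` with `robust_flag` filled (`TRUE` = robust,
#'   `FALSE` = flagged, `NA` when fewer than 2 defined differences).
#' @export
flag_cohort <- function(results, k_sd = 2, scaled = FALSE) {
  d <- if (scaled) results$scaled_delta else results$delta
  ok <- !is.na(d)
  if (sum(ok) < 2L) {
    results$robust_flag <- NA
    return(results)
  }
  mu <- mean(d[ok])
  s <- stats::sd(d[ok])
  flag <- rep(NA, length(d))
  flag[ok] <- !(d[ok] - mu > k_sd * s)
  results$robust_flag <- flag
  results
}
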