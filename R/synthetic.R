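# draw one size-s edge: with prob p_in all nodes from one community (chosen
# proportional to community size), else uniformly from the whole node set
draw_edge <- function(nodes, s, membership, p_in) {
  if (p_in > 0 && stats::runif(1) < p_in) {
    comms <- split(nodes, membership)
    sizes <- vapply(comms, length, 1L)
    ok <- sizes >= s
    if (!any(ok)) {
      stop("no community large enough for an edge of size ", s,
           " with p_in > 0")
    }
    comm <- comms[ok][[sample.int(sum(ok), 1, prob = sizes[ok])]]
    sample(comm, s)
  } else {
    sample(nodes, s)
  }
}

# rejection-sample `counts[size]` distinct edges per size, distinct across
# the whole hypergraph, so generated hypergraphs pass preprocess() unchanged
sample_edges <- function(nodes, counts, membership, p_in) {
  seen <- character(0)
  edges <- list()
  for (s in as.integer(names(counts))) {
    if (s > length(nodes)) stop("edge size ", s, " exceeds node count")
    n_wanted <- counts[[as.character(s)]]
    got <- 0L
    tries <- 0L
    max_tries <- 1000L * n_wanted + 1000L
    while (got < n_wanted) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not draw ", n_wanted, " distinct edges of size ", s,
             "; requested count too close to the number of possibilities")
      }
      e <- draw_edge(nodes, s, membership, p_in)
      key <- edge_key(e)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        edges <- c(edges, list(sort(e)))
        got <- got + 1L
      }
    }
  }
  edges
}

#' Random k-uniform hypergraph
#'
#' Draws `m` distinct hyperedges of size `k` uniformly without replacement
#' from all `choose(n, k)` possibilities on nodes `1..n`. Deterministic
#' given `seed`.
#'
#' @param n number of nodes.
#' @param m number of hyperedges; must not exceed `choose(n, k)`.
#' @param k hyperedge size (`k <= n`).
#' @param seed integer seed.
#' @return a [hypergraph()] on nodes `"1".."n"`.
#' @export
random_uniform_hypergraph <- function(n, m, k, seed = 1L) {
  stopifnot(k <= n, m >= 1)
  if (m > choose(n, k)) {
    stop("m = ", m, " exceeds the number of distinct size-", k,
         " edges on ", n, " nodes (", choose(n, k), ")")
  }
  nodes <- as.character(seq_len(n))
  withr_seed(seed)
  counts <- stats::setNames(list(m), k)
  edges <- sample_edges(nodes, counts, membership = rep(1L, n), p_in = 0)
  hypergraph(edges, nodes = nodes)
}

# seed the RNG for a generator call
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

# balanced membership vector: c communities over n nodes
balanced_membership <- function(n, c, interleave = FALSE) {
  if (interleave) ((seq_len(n) - 1L) %% c) else
    ((seq_len(n) - 1L) %/% ceiling(n / c))
}

#' Planted-partition hypergraph
#'
#' Generates a hypergraph with a planted community structure: for each
#' requested edge of size s, with probability `p_in` all s nodes are drawn
#' from a single community (chosen with probability proportional to
#' community size, so per-node edge exposure stays roughly uniform);
#' otherwise the nodes are drawn uniformly from the whole node set. Edges
#' are distinct (rejection sampling), so the result passes [preprocess()]
#' unchanged whenever the size spectrum excludes 1.
#'
#' @param n number of nodes.
#' @param sizes named integer vector mapping edge size to count,
#'   e.g. `c("2" = 40, "3" = 40)`.
#' @param c number of planted communities (default 2).
#' @param p_in within-community bias in `[0, 1]`; `p_in = 0` reduces to
#'   size-wise uniform sampling.
#' @param membership optional integer membership vector (length n, labels
#'   `0:(c-1)`); default: contiguous balanced blocks.
#' @param seed integer seed.
#' @return list with `hypergraph` and `labels` (named ground-truth vector).
#' @export
planted_partition_hypergraph <- function(n, sizes, c = 2, p_in = 0.95,
                                         membership = NULL, seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, length(sizes) >= 1)
  if (is.null(names(sizes))) stop("`sizes` must be named by edge size")
  nodes <- as.character(seq_len(n))
  if (is.null(membership)) membership <- balanced_membership(n, c)
  stopifnot(length(membership) == n)
  withr_seed(seed)
  edges <- sample_edges(nodes, as.list(sizes), membership, p_in)
  list(hypergraph = hypergraph(edges, nodes = nodes),
       labels = stats::setNames(as.integer(membership), nodes))
}

#' Size-stratified hypergraph with two planted partitions
#'
#' The generator operationalizes the premise that connection patterns are
#' stratified by interaction size: small edges (size <= `k0`) are planted on
#' partition A and large edges (size > `k0`) on a different partition B, so
#' the community structure visible at small interaction sizes differs from
#' the one visible at large sizes. Filtering by size (LEQ `k0` vs GEQ
#' `k0 + 1`) then recovers A and B respectively, while clustering the whole
#' hypergraph cannot match both.
#'
#' Defaults define the generator's reference conditions: 40 nodes, 40 edges
#' each of sizes 2, 3, 5 and 6, threshold `k0 = 3`, bias `p_in = 0.95`, two
#' communities per partition, partition A splitting the nodes into
#' contiguous halves and partition B into an interleaved (odd/even) split.
#'
#' @param n number of nodes.
#' @param sizes named integer vector mapping edge size to count.
#' @param k0 size threshold separating the small and large strata; must lie
#'   within the size spectrum.
#' @param p_in within-community bias applied in both strata.
#' @param c number of communities in each partition.
#' @param membership_small,membership_large optional membership vectors for
#'   the two partitions (labels `0:(c-1)`).
#' @param seed integer seed.
#' @return list with `hypergraph`, `labels_small` (partition A) and
#'   `labels_large` (partition B).
#' @export
size_stratified_hypergraph <- function(n = 40,
                                       sizes = c("2" = 40, "3" = 40,
                                                 "5" = 40, "6" = 40),
                                       k0 = 3, p_in = 0.95, c = 2,
                                       membership_small = NULL,
                                       membership_large = NULL,
                                       seed = 1L) {
  stopifnot(length(sizes) >= 1, p_in >= 0, p_in <= 1)
  if (is.null(names(sizes))) stop("`sizes` must be named by edge size")
  szs <- as.integer(names(sizes))
  if (k0 < min(szs) || k0 >= max(szs)) {
    stop("`k0` must split the size spectrum: min size <= k0 < max size")
  }
  nodes <- as.character(seq_len(n))
  if (is.null(membership_small)) membership_small <- balanced_membership(n, c)
  if (is.null(membership_large)) {
    membership_large <- balanced_membership(n, c, interleave = TRUE)
  }
  withr_seed(seed)
  small <- sizes[szs <= k0]
  large <- sizes[szs > k0]
  edges_small <- sample_edges(nodes, as.list(small), membership_small, p_in)
  edges_large <- sample_edges(nodes, as.list(large), membership_large, p_in)
  list(hypergraph = hypergraph(c(edges_small, edges_large), nodes = nodes),
       labels_small = stats::setNames(as.integer(membership_small), nodes),
       labels_large = stats::setNames(as.integer(membership_large), nodes))
}
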