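# Shannon entropy in bits of a probability vector (zeros contribute 0)
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Effective information of a hypergraph
#'
#' Effective information (EI) quantifies the strength of unique associations
#' in a network: how far individual nodes' out-transition profiles deviate
#' from the network-average profile. It is computed on the weighted clique
#' projection. Writing `W_i_out` for row i of the projection weight matrix
#' normalized to sum 1 (the out-transition distribution of a random walker
#' at node i),
#'
#' `EI = H(<W_i_out>) - <H(W_i_out)>`
#'
#' where `H` is the Shannon entropy in bits and `< >` averages over the
#' active (non-isolated in the projection) nodes. EI lies in
#' `[0, log2(n_active)]`; a single hyperedge on n nodes (a complete clique)
#' gives the closed form `log2(n) - log2(n - 1)`.
#'
#' @param H a [hypergraph()].
#' @param normalized if `TRUE`, divide by `log2(n_active)` (the maximum
#'   attainable entropy of the average profile), mapping EI to `[0, 1]`.
#' @return a single numeric value, or `NA` when undefined (no hyperedge of
#'   size >= 2, e.g. an empty-edge filtering). Attributes `n_active` and
#'   `normalized` record the computation.
#' @export
effective_information <- function(H, normalized = FALSE) {
  stopifnot(is_hypergraph(H))
  if (!any(edge_sizes(H) >= 2)) {
    return(structure(NA_real_, n_active = 0L, normalized = normalized))
  }
  W <- as.matrix(clique_projection(H))
  P <- W / rowSums(W)           # every projected node has positive row sum
  n_active <- nrow(P)
  ei <- shannon_entropy(colMeans(P)) - mean(apply(P, 1, shannon_entropy))
  ei <- max(ei, 0)              # clamp tiny negative rounding residue
  if (normalized) ei <- ei / log2(n_active)
  structure(ei, n_active = n_active, normalized = normalized)
}

#' Dynamical degree assortativity
#'
#' A degree-correlation measure defined directly on hyperedges:
#'
#' `rho = <k>^2 <k k1>_E / <k^2>^2 - 1`
#'
#' where `<k^r>` is the r-th moment of the degree sequence over non-isolated
#' nodes and `<k k1>_E` is the expected pairwise product of degrees over
#' hyperedges: by default the mean over hyperedges of the mean over
#' unordered distinct node pairs within the edge of `deg(u) * deg(v)`
#' (`pair_weighting = "edge_mean"`); `"pooled"` instead averages over all
#' within-edge pairs pooled across edges, weighting larger edges by their
#' pair count. Full degrees (not excess degrees) are used. `rho` is exactly
#' 0 for degree-regular hypergraphs and is bounded below by -1.
#'
#' @param H a [hypergraph()].
#' @param pair_weighting `"edge_mean"` (default) or `"pooled"`.
#' @return numeric value, or `NA` when no edge has size >= 2.
#' @export
dynamical_assortativity <- function(H,
                                    pair_weighting = c("edge_mean", "pooled")) {
  stopifnot(is_hypergraph(H))
  pair_weighting <- match.arg(pair_weighting)
  if (!any(edge_sizes(H) >= 2)) return(NA_real_)
  deg <- degrees(H)
  deg <- deg[deg > 0]
  k1 <- mean(deg)
  k2 <- mean(deg^2)
  per_edge <- lapply(H$edges[edge_sizes(H) >= 2], function(e) {
    d <- deg[e]
    s1 <- sum(d); s2 <- sum(d^2)
    npair <- length(d) * (length(d) - 1) / 2
    c(mean = (s1^2 - s2) / 2 / npair, sum = (s1^2 - s2) / 2, npair = npair)
  })
  pe <- do.call(rbind, per_edge)
  kk1 <- if (pair_weighting == "edge_mean") mean(pe[, "mean"])
         else sum(pe[, "sum"]) / sum(pe[, "npair"])
  k1^2 * kk1 / k2^2 - 1
}

#' Pearson degree assortativity of hyperedges
#'
#' Generalizes pairwise degree assortativity to hypergraphs by selecting,
#' for every hyperedge, one or more (degree, degree) observations and
#' reporting the Pearson correlation over the collected observations:
#'
#' * `top_bottom`: the pair (max degree in e, min degree in e);
#' * `top_2`: the two largest degrees in e (ties broken by sorting on
#'   (degree, label) for determinism);
#' * `uniform`: every unordered distinct node pair within e contributes one
#'   observation.
#'
#' The observation list is symmetrized (each pair enters in both orders), so
#' the result is invariant to within-pair order. Degrees are full degrees by
#' default; set `excess = TRUE` to subtract 1.
#'
#' @param H a [hypergraph()] with at least 2 edges of size >= 2.
#' @param rule `"top_bottom"`, `"top_2"` or `"uniform"`.
#' @param excess use excess degrees (degree - 1) instead of full degrees.
#' @return Pearson correlation in `[-1, 1]`, or `NA` when undefined (fewer
#'   than two qualifying edges, or zero degree variance among the selected
#'   observations, as in a degree-regular hypergraph).
#' @export
degree_assortativity <- function(H, rule = c("top_bottom", "top_2", "uniform"),
                                 excess = FALSE) {
  stopifnot(is_hypergraph(H))
  rule <- match.arg(rule)
  qual <- H$edges[edge_sizes(H) >= 2]
  if (length(qual) < 2) return(NA_real_)
  deg <- degrees(H)
  if (excess) deg <- deg - 1L
  xs <- numeric(0); ys <- numeric(0)
  for (e in qual) {
    d <- deg[e]
    if (rule == "top_bottom") {
      xs <- c(xs, max(d)); ys <- c(ys, min(d))
    } else if (rule == "top_2") {
      ord <- order(d, names(d), decreasing = TRUE)
      xs <- c(xs, d[ord[1]]); ys <- c(ys, d[ord[2]])
    } else {
      idx <- utils::combn(length(d), 2)
      xs <- c(xs, d[idx[1, ]]); ys <- c(ys, d[idx[2, ]])
    }
  }
  x <- c(xs, ys); y <- c(ys, xs)   # symmetrize
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
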