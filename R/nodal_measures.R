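#' Hypergraph betweenness centrality
#'
#' The node-based betweenness centrality for hypergraphs:
#'
#' `BC(n) = sum_{u != v != n} sigma_uv(n) / sigma_uv`
#'
#' where `sigma_uv` counts the shortest paths between u and v and
#' `sigma_uv(n)` those passing through n. Paths are walks in which
#' consecutive nodes share at least one hyperedge — equivalently unweighted
#' shortest paths on the binarized clique projection — and the sum runs over
#' unordered pairs within the same connected component (no cross-component
#' terms, so disconnected filterings are handled per component). Computed by
#' Brandes' accumulation on the projection.
#'
#' @param H a [hypergraph()]; connectivity is not required. An empty-edge
#'   filtering yields the all-zero vector.
#' @param normalized if `TRUE`, each node's value is divided by
#'   `(N - 1) * (N - 2) / 2` where N is the size of its connected component
#'   (0 for components with N < 3).
#' @return named non-negative numeric vector over all nodes of `H`; nodes
#'   isolated in the filtering have value 0.
#' @export
hypergraph_betweenness <- function(H, normalized = FALSE) {
  stopifnot(is_hypergraph(H))
  bc <- stats::setNames(numeric(n_nodes(H)), H$nodes)
  if (!any(edge_sizes(H) >= 2)) return(bc)
  g <- projection_graph(H)
  vals <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalized) {
    comp <- igraph::components(g)
    csize <- comp$csize[comp$membership]
    denom <- (csize - 1) * (csize - 2) / 2
    vals <- ifelse(denom > 0, vals / denom, 0)
    names(vals) <- igraph::V(g)$name
  }
  bc[names(vals)] <- vals
  bc
}

#' Normalized hypergraph Laplacian
#'
#' The symmetric normalized Laplacian built from the node-edge incidence
#' structure with unit edge weights:
#'
#' `L = I - D_v^{-1/2} B D_e^{-1} B^T D_v^{-1/2}`
#'
#' with B the incidence matrix over non-isolated nodes, `D_v` the diagonal
#' of node degrees and `D_e` the diagonal of edge sizes. L is positive
#' semi-definite with eigenvalues in `[0, 2]` (in fact `[0, 1]` for unit
#' weights) and the multiplicity of eigenvalue 0 equals the number of
#' connected components.
#'
#' @param H a [hypergraph()] with at least one edge.
#' @return symmetric sparse matrix with row/column names the non-isolated
#'   node labels.
#' @export
hypergraph_laplacian <- function(H) {
  stopifnot(is_hypergraph(H), n_edges(H) > 0)
  B <- incidence_matrix(H, drop_isolated = TRUE)
  dv <- Matrix::rowSums(B)
  de <- Matrix::colSums(B)
  Bn <- Matrix::Diagonal(x = 1 / sqrt(dv)) %*% B %*% Matrix::Diagonal(x = 1 / de)
  A <- Matrix::tcrossprod(Bn %*% Matrix::Diagonal(x = sqrt(de)))
  L <- Matrix::Diagonal(nrow(B)) - A
  dimnames(L) <- list(rownames(B), rownames(B))
  L
}

#' Spectral community detection on a hypergraph
#'
#' Performs spectral clustering on the normalized hypergraph Laplacian
#' ([hypergraph_laplacian()]): the eigenvectors of the `c` smallest
#' eigenvalues form an embedding of the non-isolated nodes, whose rows are
#' clustered with k-means (seeded, 20 restarts, best inertia kept, so the
#' result is deterministic given `(H, c, seed)`). Nodes isolated in the
#' filtering receive the sentinel label -1.
#'
#' @param H a [hypergraph()] with at least one edge of size >= 2.
#' @param c number of communities (>= 2); must not exceed the number of
#'   non-isolated nodes.
#' @param seed integer seed for the k-means restarts.
#' @return named integer vector over all nodes of `H` with labels in
#'   `0:(c-1)` and -1 for isolated nodes; attributes `c` and `seed`.
#' @export
spectral_communities <- function(H, c, seed = 1L) {
  stopifnot(is_hypergraph(H))
  c <- as.integer(c)
  if (c < 2) stop("`c` must be >= 2")
  if (!any(edge_sizes(H) >= 2)) {
    stop("spectral clustering undefined: no hyperedge of size >= 2")
  }
  L <- hypergraph_laplacian(H)
  n_active <- nrow(L)
  if (c > n_active) {
    stop("requested ", c, " communities but only ", n_active,
         " non-isolated nodes")
  }
  es <- eigen(as.matrix(L), symmetric = TRUE)
  # eigen() returns eigenvalues in decreasing order; smallest c are the last
  X <- es$vectors[, seq(n_active, n_active - c + 1L), drop = FALSE]
  labels <- stats::setNames(rep(-1L, n_nodes(H)), H$nodes)
  distinct <- unique(round(X, 10))
  if (nrow(distinct) <= c) {
    # degenerate embedding: fewer distinct rows than clusters requested;
    # identical rows must share a label, so cluster by row identity
    key <- apply(round(X, 10), 1, paste, collapse = ",")
    labels[rownames(L)] <- as.integer(factor(key, levels = unique(key))) - 1L
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    km <- stats::kmeans(X, centers = c, nstart = 20, iter.max = 100)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    labels[rownames(L)] <- km$cluster - 1L
  }
  structure(labels, c = c, seed = as.integer(seed))
}

# Hungarian (shortest augmenting path) solver for the linear assignment
# problem: returns, for each row of `cost` (nrow <= ncol), the column index
# of a minimum-total-cost perfect matching of rows into columns.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("solve_assignment needs nrow <= ncol")
  VIRT <- m + 1L                       # virtual start column
  u <- numeric(n); v <- numeric(VIRT)
  p <- integer(VIRT)                   # p[j]: row matched to column j (0 = none)
  way <- integer(VIRT)
  for (i in seq_len(n)) {
    p[VIRT] <- i
    j0 <- VIRT
    minv <- rep(Inf, m)
    used <- rep(FALSE, VIRT)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(VIRT)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == VIRT) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Match two community labelings by Hungarian assignment
#'
#' Aligns the labels of `other` with those of `reference` so the labelings
#' become directly comparable (e.g. across filterings of one hypergraph). A
#' confusion matrix is built over the nodes that carry a non-sentinel label
#' in both labelings; the assignment problem maximizing total overlap is
#' solved exactly (Hungarian algorithm); `other` is relabeled by the optimal
#' matching, with unmatched `other` labels given fresh indices above the
#' reference's label range. Sentinel (-1) labels are left untouched.
#'
#' @param reference named integer label vector (sentinel -1 allowed).
#' @param other named integer label vector over the same node set.
#' @return list with `labels` (the relabeled `other`) and `agreement`
#'   (matched overlap divided by the number of co-labeled nodes; `NA` when
#'   there are none).
#' @export
match_labels <- function(reference, other) {
  if (is.null(names(reference)) || is.null(names(other))) {
    stop("labelings must be named by node")
  }
  if (!setequal(names(reference), names(other))) {
    stop("labelings must cover the same node set")
  }
  other <- other[names(reference)]
  both <- reference >= 0 & other >= 0
  if (!any(both)) {
    return(list(labels = other, agreement = NA_real_))
  }
  ref_lv <- sort(unique(reference[both]))
  oth_lv <- sort(unique(other[both]))
  conf <- table(factor(other[both], levels = oth_lv),
                factor(reference[both], levels = ref_lv))
  conf <- matrix(as.numeric(conf), nrow = length(oth_lv))
  # maximize overlap == minimize negated overlap; pad with zero-overlap
  # dummy reference columns so every `other` label gets an assignment slot
  n_dummy <- max(0L, length(oth_lv) - length(ref_lv))
  cost <- cbind(-conf, matrix(0, nrow = length(oth_lv), ncol = n_dummy))
  assign <- solve_assignment(cost)
  mapping <- integer(length(oth_lv))
  fresh <- max(ref_lv) + 1L
  matched_overlap <- 0
  for (r in seq_along(oth_lv)) {
    if (assign[r] <= length(ref_lv)) {
      mapping[r] <- ref_lv[assign[r]]
      matched_overlap <- matched_overlap + conf[r, assign[r]]
    } else {
      mapping[r] <- fresh
      fresh <- fresh + 1L
    }
  }
  relabeled <- other
  idx <- match(other, oth_lv)
  relabeled[!is.na(idx)] <- mapping[idx[!is.na(idx)]]
  relabeled[other < 0] <- other[other < 0]
  list(labels = relabeled, agreement = matched_overlap / sum(both))
}
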