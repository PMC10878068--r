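#' Construct a hypergraph
#'
#' A hypergraph is a pair (V, E): a set of nodes V and a collection of
#' hyperedges E, each hyperedge an arbitrary non-empty subset of V. Edge
#' multiplicity (repeated hyperedges) is permitted at the level of this
#' container; [preprocess()] removes it. Nodes may be isolated, i.e. present
#' in `nodes` but in no edge — this is essential because size-dependent
#' filterings retain the full node set.
#'
#' Node labels are treated as opaque strings; numeric labels are coerced.
#' Repeated node labels within a single edge are collapsed with a warning,
#' since hyperedges are sets.
#'
#' @param edges list of character (or coercible) vectors, one per hyperedge;
#'   each must be non-empty.
#' @param nodes optional character vector fixing the node set and its order.
#'   Must contain every node appearing in an edge. Defaults to the nodes in
#'   first-appearance order over `edges`.
#' @param name optional character name for the hypergraph.
#' @return an object of class `hypergraph` with fields `nodes` (character
#'   vector) and `edges` (list of character vectors).
#' @examples
#' H <- hypergraph(list(c("a", "b"), c("a", "b", "c")))
#' n_nodes(H); n_edges(H)
#' @export
hypergraph <- function(edges, nodes = NULL, name = NULL) {
  if (!is.list(edges)) stop("`edges` must be a list of node-label vectors")
  edges <- lapply(edges, function(e) as.character(e))
  if (any(vapply(edges, length, 1L) == 0L)) {
    stop("hyperedges must be non-empty")
  }
  had_dup <- FALSE
  edges <- lapply(edges, function(e) {
    u <- unique(e)
    if (length(u) < length(e)) had_dup <<- TRUE
    u
  })
  if (had_dup) {
    warning("repeated node labels within a hyperedge collapsed (edges are sets)")
  }
  edge_nodes <- unique(unlist(edges, use.names = FALSE))
  if (is.null(edge_nodes)) edge_nodes <- character(0)
  if (is.null(nodes)) {
    nodes <- edge_nodes
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate labels in `nodes`")
    missing <- setdiff(edge_nodes, nodes)
    if (length(missing) > 0) {
      stop("edges reference nodes absent from `nodes`: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  sz <- edge_sizes(x)
  cat(sprintf("Hypergraph%s: %d nodes, %d hyperedges\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              n_nodes(x), n_edges(x)))
  if (n_edges(x) > 0) {
    cat("  edge sizes:", paste(sprintf("%d:%d", as.integer(names(table(sz))),
                                       as.integer(table(sz))), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @rdname hypergraph
#' @param x object to test / print.
#' @export
is_hypergraph <- function(x) inherits(x, "hypergraph")

#' @rdname hypergraph
#' @param H a `hypergraph`.
#' @export
n_nodes <- function(H) length(H$nodes)

#' @rdname hypergraph
#' @export
n_edges <- function(H) length(H$edges)

# canonical multiset key of an edge: sorted labels, used for set-equality
edge_key <- function(e) paste(sort(e), collapse = "\r")

#' Node degrees
#'
#' The degree of a node is the number of hyperedges that contain it.
#' Isolated nodes have degree 0. Satisfies the handshake identity
#' `sum(degrees(H)) == sum(edge_sizes(H))`.
#'
#' @param H a `hypergraph`.
#' @return named integer vector over all nodes of `H`, in node order.
#' @export
degrees <- function(H) {
  d <- integer(n_nodes(H))
  names(d) <- H$nodes
  if (n_edges(H) > 0) {
    tab <- table(factor(unlist(H$edges, use.names = FALSE), levels = H$nodes))
    d[] <- as.integer(tab)
  }
  d
}

#' Hyperedge sizes and their distribution
#'
#' @param H a `hypergraph`.
#' @return `edge_sizes()`: integer vector of edge cardinalities in edge order.
#'   `edge_size_distribution()`: named integer vector mapping size to count;
#'   counts sum to the number of edges.
#' @export
edge_sizes <- function(H) vapply(H$edges, length, integer(1))

#' @rdname edge_sizes
#' @export
edge_size_distribution <- function(H) {
  sz <- edge_sizes(H)
  if (length(sz) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(sz)
  stats::setNames(as.integer(tab), names(tab))
}

#' Preprocess a hypergraph
#'
#' Standard cleaning applied to raw higher-order interaction data before
#' analysis: remove multi-edges (duplicate hyperedges under set equality of
#' node membership, keeping the first occurrence), remove singleton edges
#' (size 1), and finally remove nodes left isolated by the edge removals.
#' The surviving node and edge orders are preserved. Idempotent.
#'
#' The order is fixed: deduplicate, then drop singletons, then drop isolated
#' nodes. Counts of removed items are attached as attribute `"removed"`.
#'
#' @param H a `hypergraph`.
#' @return the cleaned `hypergraph`.
#' @export
preprocess <- function(H) {
  stopifnot(is_hypergraph(H))
  keys <- vapply(H$edges, edge_key, character(1))
  keep <- !duplicated(keys)
  n_multi <- sum(!keep)
  edges <- H$edges[keep]
  sz1 <- vapply(edges, length, 1L) == 1L
  n_singleton <- sum(sz1)
  edges <- edges[!sz1]
  if (length(edges) == 0) stop("empty after preprocessing")
  used <- unique(unlist(edges, use.names = FALSE))
  nodes <- H$nodes[H$nodes %in% used]
  n_isolated <- n_nodes(H) - length(nodes)
  out <- hypergraph(edges, nodes = nodes, name = H$name)
  attr(out, "removed") <- c(multi_edges = n_multi, singletons = n_singleton,
                            isolated_nodes = n_isolated)
  out
}

#' Node-edge incidence matrix
#'
#' @param H a `hypergraph`.
#' @param drop_isolated drop rows of isolated nodes (default `TRUE`).
#' @return sparse logical incidence matrix (nodes x edges).
#' @export
incidence_matrix <- function(H, drop_isolated = TRUE) {
  nodes <- H$nodes
  if (drop_isolated) {
    used <- unique(unlist(H$edges, use.names = FALSE))
    nodes <- nodes[nodes %in% used]
  }
  m <- n_edges(H)
  i <- match(unlist(H$edges, use.names = FALSE), nodes)
  j <- rep(seq_len(m), times = vapply(H$edges, length, 1L))
  keep <- !is.na(i)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(nodes), m),
                       dimnames = list(nodes, NULL))
}

#' Weighted clique projection
#'
#' Projects the hypergraph onto the pairwise graph in which two nodes are
#' adjacent iff they co-occur in at least one hyperedge. The default weight
#' w(i, j) counts the number of hyperedges containing both i and j, so edge
#' multiplicity feeds through to the transition probabilities used by
#' [effective_information()]. Isolated nodes are excluded.
#'
#' @param H a `hypergraph` with at least one edge of size >= 2.
#' @param binarize if `TRUE`, weights are clipped to 0/1 (co-occurrence
#'   indicator rather than count).
#' @return a symmetric sparse weight matrix with zero diagonal; row/column
#'   names are the non-isolated node labels.
#' @export
clique_projection <- function(H, binarize = FALSE) {
  stopifnot(is_hypergraph(H))
  if (!any(edge_sizes(H) >= 2)) {
    stop("clique projection undefined: no hyperedge of size >= 2")
  }
  B <- incidence_matrix(H, drop_isolated = TRUE)
  W <- Matrix::tcrossprod(B)
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  # nodes whose only memberships are singleton edges have no co-members and
  # are excluded (every projected node must have positive row sum)
  active <- Matrix::rowSums(W) > 0
  W <- W[active, active, drop = FALSE]
  if (binarize) W@x[] <- 1
  W
}

# igraph view of the binarized projection; attaches isolated-in-projection
# nodes (degree > 0 but no size>=2 edge) as isolated vertices when asked.
projection_graph <- function(H, include_all_nodes = FALSE) {
  has_pair <- any(edge_sizes(H) >= 2)
  if (!has_pair) {
    g0 <- igraph::make_empty_graph(n = if (include_all_nodes) n_nodes(H) else 0,
                                   directed = FALSE)
    g0 <- igraph::set_vertex_attr(g0, "name",
                                  value = if (include_all_nodes) H$nodes else character(0))
    return(g0)
  }
  W <- clique_projection(H, binarize = TRUE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           diag = FALSE)
  if (include_all_nodes) {
    extra <- setdiff(H$nodes, igraph::V(g)$name)
    if (length(extra) > 0) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

#' Connected components of a hypergraph
#'
#' Two nodes are connected when a chain of pairwise co-memberships links
#' them (connectivity of the clique projection). Isolated nodes form their
#' own singleton components.
#'
#' @param H a `hypergraph`.
#' @return named integer vector of component ids (1-based) over all nodes.
#' @export
hypergraph_components <- function(H) {
  g <- projection_graph(H, include_all_nodes = TRUE)
  comp <- igraph::components(g)$membership
  comp[H$nodes]
}
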