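#' Size-dependent filtering of a hypergraph
#'
#' A size-dependent filtering keeps the hyperedges whose cardinality |e|
#' satisfies `|e| op k`, where k is the filtering parameter, and keeps the
#' full node set (so nodal measures remain comparable across filterings;
#' nodes that lose all their edges become isolated). The four comparison
#' operators are:
#'
#' * `eq`  — uniform filtering: isolate the structure of one hyperedge size;
#' * `geq` — "higher-order" filtering: exclude interactions smaller than k;
#' * `leq` — "lower-order" filtering: exclude interactions larger than k;
#' * `neq` — exclusion filtering: drop one particular interaction size.
#'
#' @param H a [hypergraph()].
#' @param op one of `"eq"`, `"geq"`, `"leq"`, `"neq"`.
#' @param k positive integer filtering parameter.
#' @return a `hypergraph` with the same node set and the surviving edges in
#'   their original order; attribute `"filter"` records `op` and `k`, and
#'   attribute `"empty"` flags a legal empty-edge result.
#' @examples
#' H <- hypergraph(list(c("1","2"), c("1","2","3"), c("2","3","4","5")))
#' n_edges(size_filter(H, "geq", 3))  # 2
#' @export
size_filter <- function(H, op = c("eq", "geq", "leq", "neq"), k) {
  stopifnot(is_hypergraph(H))
  op <- match.arg(op)
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1) stop("`k` must be a positive integer")
  sz <- edge_sizes(H)
  keep <- switch(op,
                 eq  = sz == k,
                 geq = sz >= k,
                 leq = sz <= k,
                 neq = sz != k)
  out <- hypergraph(H$edges[keep], nodes = H$nodes, name = H$name)
  attr(out, "filter") <- list(op = op, k = k)
  attr(out, "empty") <- !any(keep)
  out
}

#' Parse a filter designation string
#'
#' CLI/config shorthand `"<op><k>"`, e.g. `"geq5"` or `"eq3"`.
#'
#' @param spec a string like `"leq4"`.
#' @return list with elements `op` and `k`.
#' @export
parse_filter <- function(spec) {
  m <- regmatches(spec, regexec("^(eq|geq|leq|neq)([0-9]+)$", spec))[[1]]
  if (length(m) == 0) {
    stop("invalid filter designation '", spec,
         "'; expected <op><k> with op in {eq, geq, leq, neq}, e.g. 'geq5'")
  }
  list(op = m[2], k = as.integer(m[3]))
}

#' Generate a set of filterings
#'
#' Applies [size_filter()] with a fixed operator over a set of filtering
#' parameters. Every member filtering shares the base hypergraph's node set.
#'
#' @param H a [hypergraph()].
#' @param op comparison operator, as in [size_filter()].
#' @param K non-empty integer vector of filtering parameters.
#' @return object of class `filtering_set`: a list of `hypergraph`s named by
#'   k, with attributes `base` (the input hypergraph) and `op`.
#' @export
filtering_set <- function(H, op = c("eq", "geq", "leq", "neq"), K) {
  op <- match.arg(op)
  K <- as.integer(K)
  if (length(K) == 0) stop("`K` must be non-empty")
  members <- lapply(K, function(k) size_filter(H, op, k))
  names(members) <- K
  structure(members, base = H, op = op, class = "filtering_set")
}

#' @export
print.filtering_set <- function(x, ...) {
  cat(sprintf("Filtering set (op = %s) with %d members: k = %s\n",
              attr(x, "op"), length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Is a filtering set disjoint?
#'
#' A set of filterings is disjoint when the edge multisets of its members
#' are pairwise non-overlapping. The complete uniform filtering set is
#' always disjoint; complete LEQ, GEQ and exclusion sets are overlapping.
#'
#' @param FS a [filtering_set()].
#' @return `TRUE` iff members share no edge.
#' @export
is_disjoint <- function(FS) {
  stopifnot(inherits(FS, "filtering_set"))
  counts <- lapply(FS, function(Hk) {
    keys <- vapply(Hk$edges, edge_key, character(1))
    table(keys)
  })
  all_keys <- unique(unlist(lapply(counts, names), use.names = FALSE))
  if (length(all_keys) == 0) return(TRUE)
  for (key in all_keys) {
    present <- sum(vapply(counts, function(tb) !is.na(tb[key]) && tb[key] > 0,
                          logical(1)))
    if (present > 1) return(FALSE)
  }
  TRUE
}

#' Union of a filtering set
#'
#' Reassembles a hypergraph from the members of a filtering set: node set is
#' the union of member node sets and the edge list is the union of member
#' edge lists with cross-member duplicates removed. Because edge membership
#' in a size filter depends only on edge size, an edge (with all its copies)
#' either enters a member wholesale or not at all; the union therefore keeps
#' each distinct edge at its maximum multiplicity over members, and the
#' complete uniform (or exclusion, with >= 2 sizes present) filtering set
#' reconstructs the original hypergraph exactly.
#'
#' @param FS a [filtering_set()].
#' @return a `hypergraph`.
#' @export
union_filterings <- function(FS) {
  stopifnot(inherits(FS, "filtering_set"))
  nodes <- unique(unlist(lapply(FS, function(Hk) Hk$nodes), use.names = FALSE))
  edges <- list()
  mult <- integer(0)   # multiplicity per edge key already collected
  first <- list()      # representative edges per key in first-seen order
  order_keys <- character(0)
  for (Hk in FS) {
    keys <- vapply(Hk$edges, edge_key, character(1))
    tb <- table(keys)
    for (key in names(tb)) {
      if (is.na(mult[key])) {
        mult[key] <- tb[key]
        first[[key]] <- Hk$edges[[match(key, keys)]]
        order_keys <- c(order_keys, key)
      } else {
        mult[key] <- max(mult[key], tb[key])
      }
    }
  }
  out_edges <- list()
  for (key in order_keys) {
    out_edges <- c(out_edges, rep(list(first[[key]]), mult[key]))
  }
  hypergraph(out_edges, nodes = nodes, name = attr(FS, "base")$name)
}
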