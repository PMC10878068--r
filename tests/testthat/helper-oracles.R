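# Independent brute-force oracles and random-instance helpers. These are
# deliberately naive (double loops, exhaustive enumeration) and share no code
# with the package implementations they check.

# random hypergraph for property tests: sizes 2..smax, optional duplicate
# edges and singletons to exercise preprocessing paths
rand_hypergraph <- function(n, m, seed, smax = min(n, 5), allow_junk = FALSE) {
  set.seed(seed)
  nodes <- as.character(seq_len(n))
  edges <- lapply(seq_len(m), function(i) {
    s <- sample(2:smax, 1)
    sample(nodes, s)
  })
  if (allow_junk && m >= 2) {
    edges <- c(edges, edges[sample.int(m, 1)],            # a multi-edge
               list(sample(nodes, 1)))                    # a singleton
  }
  hypergraph(edges, nodes = nodes)
}

# pair co-membership counts by explicit double loop over edges and pairs
brute_projection <- function(H) {
  nodes <- sort(unique(unlist(H$edges)))
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in H$edges) {
    if (length(e) < 2) next
    for (a in seq_along(e)) {
      for (b in seq_along(e)) {
        if (a != b) w[e[a], e[b]] <- w[e[a], e[b]] + 1
      }
    }
  }
  w
}

brute_entropy <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

brute_ei <- function(H, normalized = FALSE) {
  w <- brute_projection(H)
  active <- rowSums(w) > 0
  w <- w[active, active, drop = FALSE]
  if (nrow(w) == 0) return(NA_real_)
  P <- sweep(w, 1, rowSums(w), "/")
  ei <- brute_entropy(colMeans(P)) - mean(apply(P, 1, brute_entropy))
  ei <- max(ei, 0)
  if (normalized) ei / log2(nrow(w)) else ei
}

# dynamical assortativity by explicit enumeration of every within-edge pair
brute_rho <- function(H, pair_weighting = "edge_mean") {
  deg <- sapply(H$nodes, function(v) sum(vapply(H$edges, function(e) v %in% e, TRUE)))
  names(deg) <- H$nodes
  deg <- deg[deg > 0]
  edges <- Filter(function(e) length(e) >= 2, H$edges)
  if (length(edges) == 0) return(NA_real_)
  per_edge_means <- c(); all_products <- c()
  for (e in edges) {
    prods <- c()
    for (a in seq_along(e)) for (b in seq_along(e)) {
      if (a < b) prods <- c(prods, deg[e[a]] * deg[e[b]])
    }
    per_edge_means <- c(per_edge_means, mean(prods))
    all_products <- c(all_products, prods)
  }
  kk1 <- if (pair_weighting == "edge_mean") mean(per_edge_means) else mean(all_products)
  mean(deg)^2 * kk1 / mean(deg^2)^2 - 1
}

# Pearson assortativity by explicit observation-list construction
brute_pearson <- function(H, rule) {
  deg <- sapply(H$nodes, function(v) sum(vapply(H$edges, function(e) v %in% e, TRUE)))
  names(deg) <- H$nodes
  edges <- Filter(function(e) length(e) >= 2, H$edges)
  if (length(edges) < 2) return(NA_real_)
  xs <- c(); ys <- c()
  for (e in edges) {
    d <- deg[e]
    if (rule == "top_bottom") {
      xs <- c(xs, max(d)); ys <- c(ys, min(d))
    } else if (rule == "top_2") {
      srt <- d[order(d, names(d), decreasing = TRUE)]
      xs <- c(xs, srt[1]); ys <- c(ys, srt[2])
    } else {
      for (a in seq_along(e)) for (b in seq_along(e)) {
        if (a < b) { xs <- c(xs, d[e[a]]); ys <- c(ys, d[e[b]]) }
      }
    }
  }
  x <- c(xs, ys); y <- c(ys, xs)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# all-pairs BFS shortest-path counting on the binarized co-membership graph;
# betweenness from the path-counting identity sigma_uv(n) = sigma_un * sigma_nv
# when d(u,n) + d(n,v) == d(u,v)
brute_betweenness <- function(H) {
  nodes <- H$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (e in H$edges) {
    if (length(e) < 2) next
    for (a in e) for (b in e) if (a != b) adj[a, b] <- TRUE
  }
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in nodes[adj[v, ]]) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d + 1) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt); d <- d + 1
    }
  }
  bc <- stats::setNames(numeric(n), nodes)
  for (ui in seq_len(n)) for (vi in seq_len(n)) {
    if (ui >= vi) next
    u <- nodes[ui]; v <- nodes[vi]
    if (is.infinite(dist[u, v])) next
    for (w in nodes) {
      if (w == u || w == v) next
      if (is.finite(dist[u, w]) && is.finite(dist[w, v]) &&
          dist[u, w] + dist[w, v] == dist[u, v]) {
        bc[w] <- bc[w] + sigma[u, w] * sigma[w, v] / sigma[u, v]
      }
    }
  }
  bc
}

# best label-mapping agreement by exhaustive search over all injections of
# `other` labels into reference labels (for small label counts)
brute_match_agreement <- function(reference, other) {
  both <- reference >= 0 & other >= 0
  if (!any(both)) return(NA_real_)
  ref_lv <- sort(unique(reference[both]))
  oth_lv <- sort(unique(other[both]))
  k <- length(oth_lv); r <- length(ref_lv)
  slots <- max(k, r)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- 0
  # pad reference slots with "no label" (-Inf agreement contribution = 0)
  targets <- c(ref_lv, rep(NA, slots - r))
  for (p in perms(seq_len(slots))) {
    mapping <- targets[p[seq_len(k)]]
    agree <- 0
    for (i in seq_len(k)) {
      if (!is.na(mapping[i])) {
        agree <- agree + sum(other[both] == oth_lv[i] &
                             reference[both] == mapping[i])
      }
    }
    best <- max(best, agree)
  }
  best / sum(both)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_num_equal <- function(x, y, tol = 1e-10) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
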