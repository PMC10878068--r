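test_that("betweenness matches path-counting hand values and conventions", {
  path <- hypergraph(list(c("1", "2"), c("2", "3")))
  expect_equal(hypergraph_betweenness(path),
               c("1" = 0, "2" = 1, "3" = 0))

  clique <- hypergraph(list(c("1", "2", "3")))
  expect_equal(unname(hypergraph_betweenness(clique)), c(0, 0, 0))

  # empty-edge filtering: all-zero vector over the full node set
  empty <- size_filter(path, "eq", 7)
  expect_equal(unname(hypergraph_betweenness(empty)), c(0, 0, 0))

  # normalization by (N-1)(N-2)/2 per component
  p5 <- hypergraph(list(c("1", "2"), c("2", "3"), c("3", "4")))
  bn <- hypergraph_betweenness(p5, normalized = TRUE)
  expect_equal(unname(bn["2"]), 2 / 3)
})

test_that("betweenness equals the BFS path-counting oracle, including disconnected cases", {
  for (s in 1:60) {
    n <- sample(4:7, 1)
    H <- rand_hypergraph(n = n, m = sample(2:8, 1), seed = 500 + s,
                         allow_junk = s %% 4 == 0)
    expect_equal(hypergraph_betweenness(H), brute_betweenness(H),
                 tolerance = 1e-10)
  }
  # explicitly disconnected: two components, no cross terms
  H2 <- hypergraph(list(c("a", "b"), c("b", "c"), c("x", "y"), c("y", "z")))
  expect_equal(hypergraph_betweenness(H2), brute_betweenness(H2),
               tolerance = 1e-12)
  expect_equal(unname(hypergraph_betweenness(H2)[c("b", "y")]), c(1, 1))
})

test_that("the normalized hypergraph Laplacian has the expected spectrum", {
  for (s in 1:20) {
    H <- rand_hypergraph(n = sample(4:10, 1), m = sample(2:10, 1), seed = 600 + s)
    L <- hypergraph_laplacian(H)
    ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
    comp <- hypergraph_components(H)
    comp <- comp[rownames(L)]                     # non-isolated nodes only
    expect_equal(sum(abs(ev) < 1e-8), length(unique(comp)))
  }
})

test_that("spectral clustering separates disjoint cliques and is deterministic", {
  H <- hypergraph(list(as.character(1:4), as.character(5:8)))
  lab <- spectral_communities(H, c = 2, seed = 1)
  truth <- stats::setNames(rep(0:1, each = 4), as.character(1:8))
  expect_equal(ari(lab, truth), 1)

  lab2 <- spectral_communities(H, c = 2, seed = 1)
  expect_identical(lab, lab2)

  # isolated nodes get the sentinel
  Hi <- hypergraph(list(c("a", "b"), c("c", "d")), nodes = c("a", "b", "c", "d", "z"))
  li <- spectral_communities(Hi, c = 2, seed = 1)
  expect_equal(unname(li["z"]), -1L)
  expect_true(all(li[c("a", "b", "c", "d")] >= 0))

  expect_error(spectral_communities(hypergraph(list(c("a", "b"))), c = 5, seed = 1),
               "non-isolated")
})

test_that("planted partitions are recovered at strong within-community bias", {
  # recovery is judged on assignable nodes: a node that drew no edge is
  # isolated and carries the sentinel, which says nothing about clustering
  aris <- vapply(1:10, function(s) {
    g <- planted_partition_hypergraph(n = 30, sizes = c("3" = 60), c = 2,
                                      p_in = 1, seed = s)
    lab <- spectral_communities(g$hypergraph, c = 2, seed = s)
    ari(lab[lab >= 0], g$labels[lab >= 0])
  }, numeric(1))
  expect_equal(min(aris), 1)
})

test_that("recovery improves monotonically with the planted bias", {
  grid <- c(0.2, 0.6, 1)
  med <- vapply(grid, function(p) {
    stats::median(vapply(1:10, function(s) {
      g <- planted_partition_hypergraph(n = 30, sizes = c("3" = 60), c = 2,
                                        p_in = p, seed = 40 + s)
      ari(spectral_communities(g$hypergraph, c = 2, seed = s), g$labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_equal(med[length(med)], 1)
})

test_that("the assignment solver is exact against exhaustive permutation search", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (s in 1:30) {
    set.seed(700 + s)
    n <- sample(2:5, 1); m <- n + sample(0:(5 - n), 1)
    cost <- matrix(stats::runif(n * m), n, m)
    a <- hyperfilter:::solve_assignment(cost)
    expect_equal(length(unique(a)), n)            # a valid injection
    best <- min(vapply(perms(seq_len(m)), function(p) {
      sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    }, numeric(1)))
    expect_equal(sum(cost[cbind(seq_len(n), a)]), best, tolerance = 1e-12)
  }
})

test_that("Hungarian label matching recovers permutations and maximizes agreement", {
  ref <- stats::setNames(c(0L, 0L, 1L, 1L), letters[1:4])
  perm <- stats::setNames(c(1L, 1L, 0L, 0L), letters[1:4])
  m <- match_labels(ref, perm)
  expect_equal(m$labels, ref)
  expect_equal(m$agreement, 1)

  ident <- match_labels(ref, ref)
  expect_equal(ident$labels, ref)
  expect_equal(ident$agreement, 1)

  cross <- stats::setNames(c(0L, 1L, 0L, 1L), letters[1:4])
  expect_equal(match_labels(ref, cross)$agreement, 0.5)

  # no co-labeled nodes -> undefined agreement
  allsent <- stats::setNames(rep(-1L, 4), letters[1:4])
  expect_true(is.na(match_labels(ref, allsent)$agreement))
})

test_that("matched agreement equals exhaustive search and dominates the unpermuted overlap", {
  for (s in 1:40) {
    set.seed(800 + s)
    n <- sample(5:12, 1)
    cref <- sample(2:4, 1); coth <- sample(2:5, 1)
    nodes <- paste0("v", seq_len(n))
    ref <- stats::setNames(sample(0:(cref - 1), n, replace = TRUE), nodes)
    oth <- stats::setNames(sample(0:(coth - 1), n, replace = TRUE), nodes)
    if (s %% 5 == 0) ref[1] <- -1L                # exercise the sentinel path
    m <- match_labels(ref, oth)
    expect_equal(m$agreement, brute_match_agreement(ref, oth),
                 tolerance = 1e-12)
    both <- ref >= 0 & oth >= 0
    unperm <- sum(ref[both] == oth[both]) / sum(both)
    expect_true(m$agreement >= unperm - 1e-12)
    # invariance under relabeling of the non-reference input
    shuffle <- sample(0:(coth - 1))
    oth2 <- stats::setNames(ifelse(oth >= 0, shuffle[oth + 1], oth), nodes)
    expect_equal(match_labels(ref, oth2)$agreement, m$agreement,
                 tolerance = 1e-12)
  }
})
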