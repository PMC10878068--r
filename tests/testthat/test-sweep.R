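toy_sweep_h <- hypergraph(list(c("1", "2"), c("2", "3"), c("1", "2", "3"),
                               c("1", "3", "4"), c("1", "2", "3", "4"),
                               c("2", "3", "4", "5"), c("1", "2", "3", "4", "5")))

test_that("sweep emits one record per (filter, k, metric, scope)", {
  tab <- sweep_metrics(toy_sweep_h, filters = c("eq", "geq"), k_range = 2:5,
                       metrics = c("ei_norm", "rho_dyn", "betweenness"))
  # 2 filters x 4 k x (2 global + 5 nodal) records
  expect_equal(nrow(tab), 2 * 4 * (2 + 5))
  expect_false(any(duplicated(tab[, c("filter_type", "k", "metric", "scope")])))
  expect_setequal(unique(tab$scope[tab$metric == "betweenness"]),
                  paste0("node:", toy_sweep_h$nodes))
})

test_that("geq at k = 2 reproduces the unfiltered metrics", {
  tab <- sweep_metrics(toy_sweep_h, filters = "geq", k_range = 2,
                       metrics = c("ei", "rho_dyn", "assort_unif"))
  expect_equal(tab$value[tab$metric == "ei"],
               as.numeric(effective_information(toy_sweep_h)))
  expect_equal(tab$value[tab$metric == "rho_dyn"],
               dynamical_assortativity(toy_sweep_h))
  expect_equal(tab$value[tab$metric == "assort_unif"],
               degree_assortativity(toy_sweep_h, "uniform"))
})

test_that("absent sizes yield explicit NA globals, zero centrality and sentinel labels", {
  H <- hypergraph(list(c("1", "2"), c("1", "2", "3", "4")))
  tab <- sweep_metrics(H, filters = "eq", k_range = 2:4,
                       metrics = c("ei", "betweenness", "community"),
                       c = 2, seed = 1)
  # k = 3 has no edges: EI undefined, never zero
  expect_true(is.na(tab$value[tab$metric == "ei" & tab$k == 3]))
  expect_false(is.na(tab$value[tab$metric == "ei" & tab$k == 4]))
  bc3 <- tab$value[tab$metric == "betweenness" & tab$k == 3]
  expect_equal(bc3, rep(0, 4))
  lab3 <- tab$value[tab$metric == "community" & tab$k == 3]
  expect_equal(lab3, rep(-1, 4))
  # NA rows are retained, not dropped
  expect_equal(nrow(tab), 3 * (1 + 4 + 4))
})

test_that("sweep community labels are aligned to the full-hypergraph reference", {
  g <- size_stratified_hypergraph(seed = 21)
  H <- g$hypergraph
  tab <- sweep_metrics(H, filters = "leq", k_range = 6,
                       metrics = "community", c = 2, seed = 3)
  ref <- spectral_communities(H, c = 2, seed = 3)
  got <- stats::setNames(tab$value, sub("^node:", "", tab$scope))
  # leq at the max size is the identity filter; after matching, labels equal
  # the reference exactly
  expect_equal(got[names(ref)], as.numeric(ref), ignore_attr = TRUE)
})

test_that("unknown metric names fail loudly with the valid list", {
  expect_error(sweep_metrics(toy_sweep_h, metrics = "eigenvalueish"),
               "valid names")
})

cli_path <- system.file("cli", "hyperfilter.R", package = "hyperfilter")
rscript <- file.path(R.home("bin"), "Rscript")

test_that("CLI subcommands wrap the module operations and are reproducible", {
  expect_true(nzchar(cli_path))
  tmp <- withr::local_tempdir()
  out1 <- file.path(tmp, "g1.json"); out2 <- file.path(tmp, "g2.json")
  st1 <- system2(rscript, c(cli_path, "generate", "--type", "stratified",
                            "--output", out1, "--seed", "7"), stderr = FALSE)
  st2 <- system2(rscript, c(cli_path, "generate", "--type", "stratified",
                            "--output", out2, "--seed", "7"), stderr = FALSE)
  expect_equal(c(st1, st2), c(0, 0))
  expect_identical(readLines(out1), readLines(out2))   # byte-identical

  raw <- file.path(tmp, "raw.txt")
  writeLines(c("1,2", "2,1", "3", "1,2,3,4,5"), raw)
  clean <- file.path(tmp, "clean.txt")
  expect_equal(system2(rscript, c(cli_path, "preprocess", "--input", raw,
                                  "--output", clean), stderr = FALSE), 0)
  expect_equal(n_edges(read_hypergraph(clean)), 2)

  part <- file.path(tmp, "part.txt")
  expect_equal(system2(rscript, c(cli_path, "filter", "--input", clean,
                                  "--filter", "geq5", "--output", part),
                       stderr = FALSE), 0)
  Hp <- read_hypergraph(part)
  expect_true(all(edge_sizes(Hp) >= 5))

  tab_csv <- file.path(tmp, "table.csv")
  expect_equal(system2(rscript, c(cli_path, "sweep", "--input", out1,
                                  "--output", tab_csv,
                                  "--filters", "eq,geq",
                                  "--metrics", "ei_norm,rho_dyn",
                                  "--kmin", "2", "--kmax", "6"),
                       stderr = FALSE), 0)
  tab <- utils::read.csv(tab_csv)
  expect_equal(nrow(tab), 2 * 5 * 2)
  # uniform filtering at the absent size 4 is undefined, serialized as NA
  expect_true(all(is.na(tab$value[tab$filter_type == "eq" & tab$k == 4])))

  # nonzero exit with a message on error
  expect_false(system2(rscript, c(cli_path, "filter", "--input", clean,
                                  "--filter", "bogus", "--output", part),
                       stderr = FALSE) == 0)
})
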