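GLOBAL_METRICS <- c("ei", "ei_norm", "rho_dyn",
                    "assort_tb", "assort_t2", "assort_unif")
NODAL_METRICS <- c("betweenness", "community")

compute_global_metric <- function(Hk, metric) {
  v <- switch(metric,
              ei = effective_information(Hk, normalized = FALSE),
              ei_norm = effective_information(Hk, normalized = TRUE),
              rho_dyn = dynamical_assortativity(Hk),
              assort_tb = degree_assortativity(Hk, "top_bottom"),
              assort_t2 = degree_assortativity(Hk, "top_2"),
              assort_unif = degree_assortativity(Hk, "uniform"))
  as.numeric(v)
}

#' Sweep structural metrics over size-dependent filterings
#'
#' The central analysis driver: for every requested filter type and every
#' filtering parameter k in the range, apply [size_filter()], compute the
#' requested global and nodal metrics on the filtering, and collect the
#' results in one tidy long-format table (one row per
#' `(filter_type, k, metric, scope)`).
#'
#' Conventions for sparse filterings: a filtering with no edges of the
#' qualifying size yields `NA` for global metrics — the measures are
#' undefined there, which is distinct from zero — all-zero betweenness, and
#' sentinel (-1) community labels. `NA` rows are retained, never dropped.
#' Community labels of every filtering are aligned to the labels of the
#' unfiltered hypergraph via [match_labels()] so they are comparable across
#' k.
#'
#' @param H a preprocessed [hypergraph()].
#' @param filters subset of `c("eq", "geq", "leq", "neq")`.
#' @param k_range integer vector of filtering parameters; default `2` up to
#'   the maximum edge size of `H`.
#' @param metrics metric names among `ei`, `ei_norm`, `rho_dyn`,
#'   `assort_tb`, `assort_t2`, `assort_unif` (global, one row each) and
#'   `betweenness`, `community` (nodal, one row per node).
#' @param c number of communities for `community` (default 2, fixed across
#'   the sweep so labels are comparable).
#' @param seed seed for spectral clustering.
#' @return data.frame with columns `filter_type`, `k`, `metric`, `scope`
#'   (`"global"` or `"node:<label>"`), `value`, `seed`, `c`.
#' @export
sweep_metrics <- function(H,
                          filters = c("eq", "geq", "leq", "neq"),
                          k_range = NULL,
                          metrics = c("ei_norm", "rho_dyn"),
                          c = 2, seed = 1L) {
  stopifnot(is_hypergraph(H), length(metrics) >= 1)
  filters <- match.arg(filters, several.ok = TRUE)
  valid <- c(GLOBAL_METRICS, NODAL_METRICS)
  bad <- setdiff(metrics, valid)
  if (length(bad) > 0) {
    stop("unknown metric(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "))
  }
  if (is.null(k_range)) k_range <- 2:max(edge_sizes(H))
  reference <- if ("community" %in% metrics) {
    spectral_communities(H, c = c, seed = seed)
  } else NULL
  rows <- list()
  add <- function(filter_type, k, metric, scope, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      filter_type = filter_type, k = k, metric = metric, scope = scope,
      value = value, seed = as.integer(seed), c = as.integer(c),
      stringsAsFactors = FALSE)
  }
  for (ft in filters) {
    for (k in k_range) {
      Hk <- size_filter(H, ft, k)
      empty <- !any(edge_sizes(Hk) >= 2)
      for (metric in metrics) {
        if (metric %in% GLOBAL_METRICS) {
          add(ft, k, metric, "global", compute_global_metric(Hk, metric))
        } else if (metric == "betweenness") {
          bc <- hypergraph_betweenness(Hk)
          add(ft, k, metric, paste0("node:", names(bc)), unname(bc))
        } else {
          lab <- if (empty) NULL else tryCatch(
            spectral_communities(Hk, c = c, seed = seed),
            error = function(e) NULL)  # e.g. fewer active nodes than c
          lab <- if (is.null(lab)) {
            stats::setNames(rep(-1L, n_nodes(Hk)), Hk$nodes)
          } else {
            match_labels(reference, lab)$labels
          }
          add(ft, k, metric, paste0("node:", names(lab)),
              as.numeric(unname(lab)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
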