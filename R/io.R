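#' Read a hypergraph from a file
#'
#' Two plain-text formats are supported.
#'
#' * `edgelist`: UTF-8 text, one hyperedge per line, node labels separated by
#'   `sep` (default comma). Lines starting with `#` and blank lines are
#'   skipped. This format cannot represent isolated nodes.
#' * `json`: an object with `"nodes"` (list of labels) and `"edges"` (list of
#'   lists of labels), plus optional `"name"`. Files in the hypergraph-JSON
#'   dialect used by public higher-order dataset collections (an
#'   `"edge-dict"` keyed by edge id, with `"node-data"` carrying the node
#'   list) are also recognised, so such datasets load unmodified.
#'
#' Duplicate hyperedges are preserved as read; within-edge duplicate labels
#' are collapsed with a warning. Node order is first-appearance order for
#' edgelists and declared order for JSON.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"json"`; default guesses from the file
#'   extension (`.json` -> json, otherwise edgelist).
#' @param sep field delimiter for the edgelist format.
#' @return a [hypergraph()].
#' @export
read_hypergraph <- function(path, format = c("auto", "edgelist", "json"),
                            sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "edgelist"
  }
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0) stop("empty edgelist file: ", path)
    edges <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      parts <- trimws(strsplit(lines[idx[i]], sep, fixed = TRUE)[[1]])
      parts <- parts[nzchar(parts)]
      if (length(parts) == 0) {
        stop(sprintf("malformed edgelist line %d in %s", idx[i], path))
      }
      edges[[i]] <- parts
    }
    hypergraph(edges)
  } else {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) stop("malformed JSON in ", path, ": ",
                                             conditionMessage(e)))
    if (!is.null(obj[["edge-dict"]])) {
      edges <- lapply(obj[["edge-dict"]], function(e) as.character(unlist(e)))
      nodes <- if (!is.null(obj[["node-data"]])) names(obj[["node-data"]]) else NULL
      name <- if (!is.null(obj[["hypergraph-data"]])) obj[["hypergraph-data"]][["name"]] else NULL
      return(hypergraph(unname(edges), nodes = nodes, name = name))
    }
    if (is.null(obj$nodes) || is.null(obj$edges)) {
      stop("JSON hypergraph in ", path,
           " must have keys 'nodes' and 'edges' (or an 'edge-dict')")
    }
    if (length(obj$edges) == 0) stop("JSON hypergraph has no edges: ", path)
    hypergraph(lapply(obj$edges, function(e) as.character(unlist(e))),
               nodes = as.character(unlist(obj$nodes)),
               name = obj$name)
  }
}

#' Write a hypergraph to a file
#'
#' Round-trip guarantee: `read_hypergraph(write_hypergraph(H, ...))`
#' reproduces the node set and edge multiset of `H` (for the edgelist
#' format, modulo isolated nodes, which the format cannot carry — a warning
#' is emitted when they would be lost).
#'
#' @param H a [hypergraph()].
#' @param path output file path.
#' @param format `"edgelist"` or `"json"` (default from extension).
#' @param sep field delimiter for the edgelist format.
#' @return `path`, invisibly.
#' @export
write_hypergraph <- function(H, path, format = c("auto", "edgelist", "json"),
                             sep = ",") {
  stopifnot(is_hypergraph(H))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "edgelist"
  }
  if (format == "edgelist") {
    used <- unique(unlist(H$edges, use.names = FALSE))
    if (length(setdiff(H$nodes, used)) > 0) {
      warning("edgelist format cannot carry isolated nodes; ",
              "they are dropped on write (use json to keep them)")
    }
    lines <- vapply(H$edges, paste, character(1), collapse = sep)
    writeLines(lines, path, useBytes = TRUE)
  } else {
    obj <- list(nodes = as.list(H$nodes),
                edges = lapply(H$edges, as.list))
    if (!is.null(H$name)) obj$name <- H$name
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = FALSE)
  }
  invisible(path)
}
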