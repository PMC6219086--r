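#' Per-node topology metrics
#'
#' Degree, local clustering coefficient and connected-component membership,
#' computed on the undirected simple view of the network (parallel edges
#' collapsed, self-loops dropped). Clustering is the fraction of realized
#' edges among a node's neighbour pairs, `2 e_N / (k (k - 1))`; nodes with
#' degree < 2 get 0. Isolated nodes form their own component.
#'
#' @param net An `rg_network`.
#' @return A data frame with columns `shared_name`, `degree`, `clustering`,
#'   `component`.
#' @export
node_metrics <- function(net) {
  g <- as_igraph_simple(net)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  comp <- igraph::components(g)$membership
  data.frame(shared_name = igraph::V(g)$name,
             degree = as.integer(deg),
             clustering = as.numeric(cc),
             component = as.integer(comp),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_igraph_simple <- function(net) {
  e <- net$edges
  e <- e[e$source != e$target, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = pmin(e$source, e$target),
                      to = pmax(e$source, e$target),
                      stringsAsFactors = FALSE)),
    directed = FALSE, vertices = data.frame(name = node_names(net)))
  igraph::simplify(g)
}

#' Partition two networks' edge sets into exclusive and shared edges
#'
#' Edge identity is the unordered shared-name pair (interaction labels and
#' multiplicities are ignored): the comparison answers which associations
#' are present exclusively in one condition and which are common.
#'
#' @param a,b `rg_network` objects.
#' @return A list with data frames `only_a`, `only_b`, `shared`, each with
#'   columns `source`, `target` (source <= target lexicographically).
#' @export
exclusive_edges <- function(a, b) {
  key <- function(net) {
    e <- net$edges
    unique(paste(pmin(e$source, e$target), pmax(e$source, e$target), sep = "\r"))
  }
  ka <- key(a); kb <- key(b)
  unkey <- function(k) {
    if (!length(k)) return(data.frame(source = character(), target = character(),
                                      stringsAsFactors = FALSE))
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(source = vapply(parts, `[[`, "", 1L),
               target = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
  }
  list(only_a = unkey(sort(setdiff(ka, kb))),
       only_b = unkey(sort(setdiff(kb, ka))),
       shared = unkey(sort(intersect(ka, kb))))
}

#' Cross-network comparison table for a set of nodes
#'
#' One row per (shared name, network): a presence flag plus that network's
#' degree and clustering coefficient for the node, `NA` when absent.
#'
#' @param sess An `rg_session`.
#' @param names Character vector of shared names.
#' @return A data frame with columns `network`, `shared_name`, `present`,
#'   `degree`, `clustering`, `component`.
#' @export
compare_table <- function(sess, names) {
  names <- unique(as.character(names))
  if (!length(names))
    return(data.frame(network = character(), shared_name = character(),
                      present = logical(), degree = integer(),
                      clustering = numeric(), component = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(sess$networks, function(net) {
    m <- node_metrics(net)
    idx <- match(names, m$shared_name)
    data.frame(network = net$name, shared_name = names,
               present = !is.na(idx),
               degree = m$degree[idx],
               clustering = m$clustering[idx],
               component = m$component[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(network = character(), shared_name = character(),
                      present = logical(), degree = integer(),
                      clustering = numeric(), component = integer())
  out
}

#' Write a per-node metric table for every network of a session
#'
#' @param sess An `rg_session`.
#' @param path Output TSV path.
#' @return The combined data frame, invisibly.
#' @export
write_metrics <- function(sess, path) {
  tabs <- lapply(sess$networks, function(net) {
    m <- node_metrics(net)
    cbind(network = net$name, m)
  })
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  invisible(out)
}
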