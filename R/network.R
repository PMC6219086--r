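#' Networks keyed by shared node names
#'
#' A network is a named graph whose nodes are identified by a "shared name":
#' the cross-network identity key (typically a gene symbol or locus tag).
#' Two nodes in different networks are considered the same entity iff their
#' shared names match, directly or through an [identity_map()]. Nodes carry
#' a free-form attribute map (e.g. log2 fold change); edges carry an
#' interaction label, a directedness flag and a parallel-edge count.
#'
#' @param name Network name (unique within a session).
#' @param nodes Character vector of shared names, or a named list of
#'   attribute lists keyed by shared name.
#' @param edges A data frame with columns `source`, `target` and optionally
#'   `interaction`, `directed`, `count`.
#' @param metadata Free-form list.
#' @return An object of class `rg_network`.
#' @examples
#' net <- network("toy", nodes = c("A", "B"),
#'                edges = data.frame(source = "A", target = "B"))
#' n_nodes(net); n_edges(net)
#' @export
network <- function(name, nodes = character(), edges = NULL, metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(nodes)) {
    nodes <- setNames(rep(list(list()), length(nodes)), nodes)
  }
  nn <- names(nodes)
  if (length(nodes) && (is.null(nn) || any(!nzchar(nn))))
    stop("every node needs a non-empty shared name")
  if (anyDuplicated(nn))
    stop("duplicate shared name in network '", name, "': ",
         paste(unique(nn[duplicated(nn)]), collapse = ", "))
  edges <- normalize_edges(edges)
  bad <- setdiff(c(edges$source, edges$target), nn)
  if (length(bad))
    stop("edge endpoint(s) not present as nodes: ", paste(bad, collapse = ", "))
  structure(list(name = name, nodes = nodes, edges = edges, metadata = metadata),
            class = "rg_network")
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(data.frame(source = character(), target = character(),
                      interaction = character(), directed = logical(),
                      count = integer(), stringsAsFactors = FALSE))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$interaction)) edges$interaction <- "interacts"
  if (is.null(edges$directed)) edges$directed <- FALSE
  if (is.null(edges$count)) edges$count <- 1L
  edges[c("source", "target", "interaction", "directed", "count")]
}

#' @rdname network
#' @param x,net An `rg_network`.
#' @export
n_nodes <- function(x) length(x$nodes)

#' @rdname network
#' @export
n_edges <- function(x) sum(x$edges$count)

#' @rdname network
#' @export
node_names <- function(x) names(x$nodes)

#' @export
print.rg_network <- function(x, ...) {
  cat(sprintf("<network '%s': %d nodes, %d edges>\n",
              x$name, n_nodes(x), n_edges(x)))
  invisible(x)
}

# Collapse parallel undirected edges: identity = unordered endpoint pair plus
# interaction label; the multiplicity is kept in `count`.
collapse_edges <- function(df) {
  if (!nrow(df)) return(normalize_edges(NULL))
  a <- pmin(df$source, df$target)
  b <- pmax(df$source, df$target)
  key <- paste(a, b, df$interaction, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.integer(tabulate(match(key, key[first]), sum(first)))
  out$directed <- FALSE
  rownames(out) <- NULL
  normalize_edges(out)
}

#' Read and write Simple Interaction Format (SIF) files
#'
#' SIF is a line-oriented format: `source interaction target [target...]`.
#' A line with a single token declares an isolated node; a line with two
#' tokens is malformed. Multi-target lines expand to one edge per
#' (source, target) pair. Edges are undirected; duplicate lines are
#' collapsed on import with their multiplicity kept in the `count` edge
#' column, and re-expanded on export so write/read round-trips preserve the
#' edge multiset.
#'
#' @param path File path.
#' @param name Network name; defaults to the file base name.
#' @return `read_sif()` returns an `rg_network`; `write_sif()` returns the
#'   path, invisibly.
#' @export
read_sif <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  name <- name %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  toks <- strsplit(trimws(lines), "[ \t]+")
  keep <- lengths(toks) > 0L & vapply(toks, function(t) any(nzchar(t)), TRUE)
  idx <- which(keep)
  toks <- toks[keep]
  nt <- lengths(toks)
  if (any(nt == 2L))
    stop("malformed SIF line ", idx[which(nt == 2L)[1L]],
         ": expected 1 or >=3 tokens")
  singles <- unlist(lapply(toks[nt == 1L], `[[`, 1L))
  multi <- toks[nt >= 3L]
  if (length(multi)) {
    src <- rep(vapply(multi, `[[`, "", 1L), vapply(multi, length, 1L) - 2L)
    int <- rep(vapply(multi, `[[`, "", 2L), vapply(multi, length, 1L) - 2L)
    tgt <- unlist(lapply(multi, function(t) t[-(1:2)]))
    edf <- data.frame(source = src, target = tgt, interaction = int,
                      stringsAsFactors = FALSE)
  } else {
    edf <- NULL
  }
  nodes <- unique(c(singles, if (!is.null(edf)) c(edf$source, edf$target)))
  network(name, nodes = nodes,
          edges = if (is.null(edf)) NULL else collapse_edges(edf))
}

#' @rdname read_sif
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  lines <- character()
  if (nrow(e)) {
    lines <- rep(paste(e$source, e$interaction, e$target), e$count)
  }
  iso <- setdiff(node_names(net), c(e$source, e$target))
  write_atomic(c(lines, iso), path)
}

xgmml_ns <- "http://www.cs.rpi.edu/XGMML"

#' Read and write XGMML network documents
#'
#' XGMML is the XML graph format used for network interchange. On read, a
#' node's shared name is taken from its `label` attribute, falling back to
#' an `att` child named "shared name", then to its `id`. Typed `att`
#' children (`real`, `integer`) are coerced to numbers; `graphics` x/y
#' coordinates become `x`/`y` node attributes. On write, node attributes,
#' edge interaction labels, directedness and parallel-edge counts are all
#' serialized, so a write/read round trip reproduces the network exactly.
#'
#' @param x A file path or a string containing an XGMML document.
#' @param name Optional network name override (default: the graph label).
#' @param net An `rg_network`.
#' @param path Output file path.
#' @return `read_xgmml()` returns an `rg_network`.
#' @export
read_xgmml <- function(x, name = NULL) {
  doc <- xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "graph") stop("not an XGMML document: root is <",
                                           xml2::xml_name(doc), ">")
  gname <- name %||% xml2::xml_attr(doc, "label") %||% "network"
  if (is.na(gname)) gname <- "network"

  nodexml <- xml2::xml_find_all(doc, "./node")
  ids <- xml2::xml_attr(nodexml, "id")
  labels <- xml2::xml_attr(nodexml, "label")
  nodes <- vector("list", length(nodexml))
  shared <- character(length(nodexml))
  for (i in seq_along(nodexml)) {
    atts <- read_atts(nodexml[[i]])
    sn <- labels[i]
    if (is.na(sn) || !nzchar(sn)) sn <- atts[["shared name"]] %||% ids[i]
    if (is.null(sn) || is.na(sn)) stop("node without label, shared name or id")
    atts[["shared name"]] <- NULL
    gr <- xml2::xml_find_first(nodexml[[i]], "./graphics")
    if (!inherits(gr, "xml_missing")) {
      xx <- suppressWarnings(as.numeric(xml2::xml_attr(gr, "x")))
      yy <- suppressWarnings(as.numeric(xml2::xml_attr(gr, "y")))
      if (!is.na(xx)) atts$x <- xx
      if (!is.na(yy)) atts$y <- yy
    }
    shared[i] <- as.character(sn)
    nodes[[i]] <- atts
  }
  names(nodes) <- shared
  id2name <- setNames(shared, ids)

  edgexml <- xml2::xml_find_all(doc, "./edge")
  edf <- NULL
  if (length(edgexml)) {
    esrc <- xml2::xml_attr(edgexml, "source")
    etgt <- xml2::xml_attr(edgexml, "target")
    unknown <- setdiff(c(esrc, etgt), ids)
    if (length(unknown))
      stop("edge references unknown node id(s): ",
           paste(unknown, collapse = ", "))
    ints <- character(length(edgexml)); dirs <- logical(length(edgexml))
    cnts <- integer(length(edgexml))
    for (i in seq_along(edgexml)) {
      atts <- read_atts(edgexml[[i]])
      ints[i] <- atts$interaction %||% "interacts"
      dirs[i] <- isTRUE(as.logical(atts$directed %||% FALSE)) ||
        identical(atts$directed, 1)
      cnts[i] <- as.integer(atts$count %||% 1L)
    }
    edf <- data.frame(source = unname(id2name[esrc]),
                      target = unname(id2name[etgt]),
                      interaction = ints, directed = dirs, count = cnts,
                      stringsAsFactors = FALSE)
  }
  network(gname, nodes = nodes, edges = edf)
}

read_atts <- function(node) {
  attxml <- xml2::xml_find_all(node, "./att")
  out <- list()
  for (a in attxml) {
    nm <- xml2::xml_attr(a, "name")
    if (is.na(nm)) next
    val <- xml2::xml_attr(a, "value")
    ty <- xml2::xml_attr(a, "type")
    if (!is.na(ty) && ty %in% c("real", "integer"))
      val <- suppressWarnings(as.numeric(val))
    out[[nm]] <- val
  }
  out
}

#' @rdname read_xgmml
#' @export
write_xgmml <- function(net, path) {
  doc <- xml2::xml_new_root("graph", label = net$name, directed = "0",
                            xmlns = xgmml_ns)
  ids <- setNames(seq_along(net$nodes), node_names(net))
  for (nm in node_names(net)) {
    nd <- xml2::xml_add_child(doc, "node", id = as.character(ids[[nm]]),
                              label = nm)
    add_atts(nd, net$nodes[[nm]])
  }
  e <- net$edges
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(doc, "edge",
                              label = paste0(e$source[i], " (",
                                             e$interaction[i], ") ", e$target[i]),
                              source = as.character(ids[[e$source[i]]]),
                              target = as.character(ids[[e$target[i]]]))
    add_atts(ed, list(interaction = e$interaction[i],
                      directed = as.numeric(e$directed[i]),
                      count = e$count[i]))
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  xml2::write_xml(doc, tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  invisible(path)
}

add_atts <- function(parent, atts) {
  for (nm in names(atts)) {
    v <- atts[[nm]]
    ty <- if (is.numeric(v)) {
      if (is.integer(v) || isTRUE(all.equal(v, round(v)))) "integer" else "real"
    } else "string"
    xml2::xml_add_child(parent, "att", name = nm, value = as.character(v),
                        type = ty)
  }
}

#' Sessions: ordered collections of networks plus identity maps
#'
#' A session is the headless stand-in for a multi-network canvas: an ordered
#' list of uniquely named networks together with a registry of
#' [identity_map()]s used during selection propagation.
#'
#' @param networks List of `rg_network` objects with unique names.
#' @param identity_maps List of `rg_idmap` objects.
#' @return An object of class `rg_session`.
#' @export
session <- function(networks = list(), identity_maps = list()) {
  if (inherits(networks, "rg_network")) networks <- list(networks)
  nms <- vapply(networks, function(n) n$name, "")
  if (anyDuplicated(nms))
    stop("duplicate network names: ", paste(nms[duplicated(nms)], collapse = ", "))
  structure(list(networks = setNames(networks, nms),
                 identity_maps = identity_maps),
            class = "rg_session")
}

#' @export
print.rg_session <- function(x, ...) {
  cat(sprintf("<session: %d networks, %d identity maps>\n",
              length(x$networks), length(x$identity_maps)))
  for (n in x$networks) print(n)
  invisible(x)
}

#' Read a zipped session archive of XGMML documents
#'
#' Extracts a zip archive and loads every member that parses as an XGMML
#' graph as one network. View-only documents — members that duplicate an
#' already-loaded network's node set while carrying layout coordinates —
#' are folded into that network as `x`/`y` node attributes instead of
#' becoming separate networks. All other members (tables, properties) are
#' ignored with a message.
#'
#' @param path Path to a zip archive (e.g. a Cytoscape session file).
#' @return An `rg_session`.
#' @export
read_session_archive <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  exdir <- tempfile("session_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[!dir.exists(files)])
  nets <- list()
  for (f in files) {
    net <- tryCatch(read_xgmml(f), error = function(e) NULL)
    if (is.null(net)) {
      message("session archive: ignoring non-XGMML member ", basename(f))
      next
    }
    folded <- FALSE
    for (k in seq_along(nets)) {
      if (setequal(node_names(net), node_names(nets[[k]])) &&
          any(vapply(net$nodes, function(a) !is.null(a$x), TRUE))) {
        for (nm in node_names(net)) {
          nets[[k]]$nodes[[nm]]$x <- net$nodes[[nm]]$x
          nets[[k]]$nodes[[nm]]$y <- net$nodes[[nm]]$y
        }
        folded <- TRUE
        break
      }
    }
    if (!folded) {
      if (net$name %in% vapply(nets, function(n) n$name, ""))
        net$name <- paste0(net$name, "_", length(nets) + 1L)
      nets[[length(nets) + 1L]] <- net
    }
  }
  if (!length(nets)) stop("archive contains no XGMML network documents: ", path)
  session(nets)
}

#' Attach a node-attribute table to a network
#'
#' The headless equivalent of importing a table onto a network: rows whose
#' key matches a node's shared name merge their remaining columns into that
#' node's attribute map (overwriting on collision). Fully numeric values are
#' stored as numbers. Unmatched rows are counted, reported with a message
#' and recorded in `metadata$unmatched_rows`.
#'
#' @param net An `rg_network`.
#' @param table A data frame, or path to a tab-delimited file with a header.
#' @param key_column Name of the column holding shared names.
#' @return A new `rg_network`; the input is not modified.
#' @export
attach_attributes <- function(net, table, key_column) {
  if (is.character(table))
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               check.names = FALSE)
  if (!key_column %in% names(table))
    stop("key column '", key_column, "' not found in attribute table")
  keys <- as.character(table[[key_column]])
  cols <- setdiff(names(table), key_column)
  hit <- keys %in% node_names(net)
  for (i in which(hit)) {
    for (cl in cols) {
      v <- table[[cl]][i]
      if (is.character(v)) {
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num) && nzchar(trimws(v))) v <- num
      }
      net$nodes[[keys[i]]][[cl]] <- v
    }
  }
  unmatched <- sum(!hit)
  if (unmatched) message(unmatched, " attribute row(s) had no matching node")
  net$metadata$unmatched_rows <- unmatched
  net
}
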