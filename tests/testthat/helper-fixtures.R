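# Shared fixture builders. Everything is generated in code at test time; the
# only external helper is python's zipfile module (part of the same image),
# used to assemble zip archives because no zip binary ships with R here.

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Minimal XGMML document string for a network.
xgmml_doc <- function(name, nodes, edges = NULL, coords = NULL) {
  doc <- xml2::xml_new_root("graph", label = name,
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  for (i in seq_along(nodes)) {
    nd <- xml2::xml_add_child(doc, "node", id = as.character(i),
                              label = nodes[i])
    if (!is.null(coords))
      xml2::xml_add_child(nd, "graphics", x = as.character(coords[i, 1]),
                          y = as.character(coords[i, 2]))
  }
  if (!is.null(edges)) {
    for (k in seq_len(nrow(edges))) {
      xml2::xml_add_child(doc, "edge",
                          source = as.character(match(edges$source[k], nodes)),
                          target = as.character(match(edges$target[k], nodes)))
    }
  }
  as.character(doc)
}

make_zip <- function(files, zipfile = tempfile(fileext = ".zip")) {
  out <- system2("python", c("-m", "zipfile", "-c", shQuote(zipfile),
                             vapply(files, shQuote, "")),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(zipfile))
    stop("python -m zipfile failed: ", paste(out, collapse = "\n"))
  zipfile
}

# Brute-force local clustering coefficient: count realized edges among all
# neighbour pairs, straight from the definition.
brute_clustering <- function(net) {
  e <- net$edges[net$edges$source != net$edges$target, , drop = FALSE]
  key <- unique(paste(pmin(e$source, e$target), pmax(e$source, e$target)))
  has_edge <- function(a, b) paste(min(a, b), max(a, b)) %in% key
  vapply(node_names(net), function(v) {
    nb <- unique(c(e$target[e$source == v], e$source[e$target == v]))
    nb <- setdiff(nb, v)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (has_edge(nb[i], nb[j])) links <- links + 1L
    2 * links / (k * (k - 1))
  }, 0)
}

# Does `word` occur inside `cons` (either orientation, ungapped) with at most
# `maxmis` mismatches? Unaligned word positions count as mismatches, so a
# consensus shorter than the word can never pass with maxmis < length gap.
consensus_matches <- function(cons, word, maxmis = 1) {
  cand <- c(cons, revcomp(cons))
  wv <- strsplit(word, "")[[1]]
  for (cs in cand) {
    cv <- strsplit(cs, "")[[1]]
    if (length(cv) < length(wv)) next
    for (off in 0:(length(cv) - length(wv))) {
      mis <- sum(cv[off + seq_along(wv)] != wv)
      if (mis <= maxmis) return(TRUE)
    }
  }
  FALSE
}

# A network with exactly n_nodes nodes and n_edges distinct undirected edges
# (remaining nodes isolated), for scalability checks.
with_large_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  names <- sprintf("N%05d", seq_len(n_nodes))
  src <- integer(0); tgt <- integer(0)
  while (length(src) < n_edges) {
    a <- sample.int(n_nodes, n_edges * 2, replace = TRUE)
    b <- sample.int(n_nodes, n_edges * 2, replace = TRUE)
    keep <- a != b
    lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
    key <- paste(c(src, lo), c(tgt, hi))
    first <- !duplicated(key)
    src <- c(src, lo)[first]; tgt <- c(tgt, hi)[first]
  }
  src <- src[seq_len(n_edges)]; tgt <- tgt[seq_len(n_edges)]
  network(sprintf("large_%d", seed), nodes = names,
          edges = data.frame(source = names[src], target = names[tgt],
                             interaction = "pp", stringsAsFactors = FALSE))
}

# Deterministic small genome with a planted palindromic regulon.
planted_fixture <- function(n_genes = 20, regulon = NULL, seed = 1,
                            mutation_rate = 0.05, intergenic_len = 200) {
  g <- generate_genome(n_genes, gene_len = 300, intergenic_len = intergenic_len,
                       seed = seed)
  if (is.null(regulon)) regulon <- g$genes$locus_tag
  plant_motif(g, planted_motif_spec(regulon = regulon,
                                    mutation_rate = mutation_rate),
              seed = seed + 1000)
}
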