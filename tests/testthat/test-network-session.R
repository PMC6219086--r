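test_that("read_sif handles minimal, empty and multi-target lines", {
  net <- read_sif(write_tmp("A pp B", ".sif"))
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)

  empty <- read_sif(write_tmp(character(), ".sif"))
  expect_equal(n_nodes(empty), 0L)
  expect_equal(n_edges(empty), 0L)

  # SIF multi-target rule: source pairs with each target
  multi <- read_sif(write_tmp("A pp B C", ".sif"))
  expect_setequal(node_names(multi), c("A", "B", "C"))
  pairs <- paste(pmin(multi$edges$source, multi$edges$target),
                 pmax(multi$edges$source, multi$edges$target))
  expect_setequal(pairs, c("A B", "A C"))

  iso <- read_sif(write_tmp(c("A pp B", "LONER"), ".sif"))
  expect_true("LONER" %in% node_names(iso))
  expect_equal(n_edges(iso), 1L)
})

test_that("read_sif rejects 2-token lines with the line number", {
  p <- write_tmp(c("A pp B", "A B"), ".sif")
  expect_error(read_sif(p), "line 2")
})

test_that("duplicate SIF lines collapse into an edge count and round-trip", {
  p <- write_tmp(c("A pp B", "A pp B", "B pp C"), ".sif")
  net <- read_sif(p)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(n_edges(net), 3L)
  ab <- net$edges$count[net$edges$source == "A" | net$edges$target == "A"]
  expect_equal(ab, 2L)

  out <- tempfile(fileext = ".sif")
  write_sif(net, out)
  back <- read_sif(out)
  expect_setequal(node_names(back), node_names(net))
  expect_equal(n_edges(back), n_edges(net))
  key <- function(n) sort(paste(pmin(n$edges$source, n$edges$target),
                                pmax(n$edges$source, n$edges$target),
                                n$edges$count))
  expect_equal(key(back), key(net))
})

test_that("read_xgmml extracts nodes, edges and typed attributes", {
  doc <- xgmml_doc("toy", c("A", "B"),
                   data.frame(source = "A", target = "B"))
  net <- read_xgmml(doc)
  expect_equal(net$name, "toy")
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)

  withatt <- paste0('<graph label="g" xmlns="http://www.cs.rpi.edu/XGMML">',
                    '<node id="1" label="F5">',
                    '<att name="log2fc" value="0.7" type="real"/></node></graph>')
  net2 <- read_xgmml(withatt)
  expect_identical(net2$nodes[["F5"]]$log2fc, 0.7)
})

test_that("read_xgmml flags edges that reference unknown node ids", {
  bad <- paste0('<graph label="g" xmlns="http://www.cs.rpi.edu/XGMML">',
                '<node id="1" label="A"/>',
                '<edge source="1" target="99"/></graph>')
  expect_error(read_xgmml(bad), "unknown node id")
})

test_that("write_xgmml / read_xgmml round-trips nodes, edges and attributes", {
  net <- network("rt", nodes = list(A = list(log2fc = 0.7, note = "up"),
                                    B = list(), C = list(score = 2)),
                 edges = data.frame(source = c("A", "A"), target = c("B", "C"),
                                    interaction = c("pp", "pd"),
                                    count = c(2L, 1L)))
  p <- tempfile(fileext = ".xgmml")
  write_xgmml(net, p)
  back <- read_xgmml(p)
  expect_setequal(node_names(back), node_names(net))
  expect_equal(back$nodes[["A"]]$log2fc, 0.7)
  expect_equal(back$nodes[["A"]]$note, "up")
  ek <- function(n) sort(paste(pmin(n$edges$source, n$edges$target),
                               pmax(n$edges$source, n$edges$target),
                               n$edges$interaction, n$edges$count))
  expect_equal(ek(back), ek(net))
})

test_that("session archives load each XGMML member and fold view documents", {
  d <- tempfile(); dir.create(d)
  writeLines(xgmml_doc("net1", c("A", "B"),
                       data.frame(source = "A", target = "B")),
             file.path(d, "a_net1.xgmml"))
  writeLines(xgmml_doc("net2", c("X", "Y", "Z")), file.path(d, "b_net2.xgmml"))
  zip2 <- make_zip(c(file.path(d, "a_net1.xgmml"), file.path(d, "b_net2.xgmml")))
  sess <- read_session_archive(zip2)
  expect_length(sess$networks, 2L)
  expect_setequal(vapply(sess$networks, n_nodes, 0L), c(2L, 3L))

  # a view document duplicating net1's nodes with coordinates is folded in
  writeLines(xgmml_doc("net1_view", c("A", "B"),
                       coords = cbind(c(10, 20), c(30, 40))),
             file.path(d, "c_view.xgmml"))
  writeLines("just text, not xml", file.path(d, "notes.props"))
  zip3 <- make_zip(file.path(d, c("a_net1.xgmml", "b_net2.xgmml",
                                  "c_view.xgmml", "notes.props")))
  sess3 <- suppressMessages(read_session_archive(zip3))
  expect_length(sess3$networks, 2L)
  n1 <- sess3$networks[[which(vapply(sess3$networks, n_nodes, 0L) == 2L)]]
  expect_equal(n1$nodes[["A"]]$x, 10)
  expect_equal(n1$nodes[["B"]]$y, 40)
})

test_that("archives without any XGMML member are an error", {
  d <- tempfile(); dir.create(d)
  writeLines("nothing here", file.path(d, "readme.txt"))
  z <- make_zip(file.path(d, "readme.txt"))
  expect_error(suppressMessages(read_session_archive(z)), "no XGMML")
})

test_that("attach_attributes merges matching rows and is idempotent", {
  net <- network("n", nodes = c("F5", "C3"))
  tab <- data.frame(gene = c("F5", "ABSENT"), value = c("1.3", "9"),
                    stringsAsFactors = FALSE)
  out <- suppressMessages(attach_attributes(net, tab, "gene"))
  expect_identical(out$nodes[["F5"]]$value, 1.3)  # numeric coercion
  expect_equal(out$metadata$unmatched_rows, 1L)
  expect_setequal(node_names(out), node_names(net))  # node set unchanged
  expect_length(net$nodes[["F5"]], 0L)               # input not mutated

  twice <- suppressMessages(attach_attributes(out, tab, "gene"))
  expect_identical(twice$nodes, out$nodes)
  expect_error(attach_attributes(net, tab, "nope"), "key column")
})

test_that("network constructor enforces identity invariants", {
  expect_error(network("n", nodes = c("A", "A")), "duplicate shared name")
  expect_error(network("n", nodes = "A",
                       edges = data.frame(source = "A", target = "B")),
               "not present")
})
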