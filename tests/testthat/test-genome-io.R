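gbk_lines <- function(seq = strrep("ACGT", 25),
                      features = c("     gene            10..30",
                                   "                     /locus_tag=\"g1\"")) {
  c(sprintf("LOCUS       TESTSEQ          %d bp    DNA     linear   UNA 01-JAN-2000",
            nchar(seq)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    features,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(substr(seq, 1, 60))),
    if (nchar(seq) > 60) sprintf("%9d %s", 61, tolower(substr(seq, 61, nchar(seq)))),
    "//")
}

test_that("read_genbank converts coordinates and strands", {
  g <- read_genbank(write_tmp(gbk_lines(), ".gbk"))
  expect_equal(g$id, "TESTSEQ")
  expect_equal(genome_length(g), 100L)
  # 1-based inclusive 10..30 -> 0-based half-open [9, 30), forward strand
  expect_equal(g$genes$start, 9L)
  expect_equal(g$genes$end, 30L)
  expect_equal(g$genes$strand, 1L)

  gc <- read_genbank(write_tmp(gbk_lines(
    features = c("     gene            complement(10..30)",
                 "                     /locus_tag=\"g1\"")), ".gbk"))
  expect_equal(gc$genes$strand, -1L)
  expect_equal(gc$genes[c("start", "end")], g$genes[c("start", "end")])
})

test_that("read_genbank rejects broken records", {
  no_origin <- c("LOCUS       X  10 bp", "FEATURES", "//")
  expect_error(read_genbank(write_tmp(no_origin, ".gbk")), "ORIGIN")

  dup <- gbk_lines(features = c(
    "     gene            10..30", "                     /locus_tag=\"g1\"",
    "     gene            40..60", "                     /locus_tag=\"g1\""))
  expect_error(read_genbank(write_tmp(dup, ".gbk")), "duplicate locus_tag")
})

test_that("write_genbank round-trips through read_genbank", {
  g <- generate_genome(5, gene_len = 120, intergenic_len = 80, seed = 9)
  p <- tempfile(fileext = ".gbk")
  write_genbank(g, p)
  back <- read_genbank(p)
  expect_identical(back$sequence, g$sequence)
  expect_equal(back$genes, g$genes)
})

test_that("write_genbank output parses identically under biopython", {
  g <- generate_genome(3, gene_len = 90, intergenic_len = 50, seed = 4)
  p <- tempfile(fileext = ".gbk")
  write_genbank(g, p)
  script <- write_tmp(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "print(len(rec.seq))",
    "print(str(rec.seq[:50]))",
    "for f in rec.features:",
    "    if f.type == 'gene':",
    "        lt = f.qualifiers['locus_tag'][0]",
    "        print(lt, int(f.location.start), int(f.location.end), f.location.strand)"),
    ".py")
  out <- system2("python", c(script, p), stdout = TRUE, stderr = FALSE)
  expect_null(attr(out, "status"))  # biopython parsed the record
  expect_equal(as.integer(out[1]), genome_length(g))
  expect_equal(out[2], substr(g$sequence, 1, 50))
  got <- read.table(text = out[-(1:2)], stringsAsFactors = FALSE,
                    col.names = c("locus_tag", "start", "end", "strand"))
  expect_equal(got$locus_tag, g$genes$locus_tag)
  expect_equal(got$start, g$genes$start)
  expect_equal(got$end, g$genes$end)
  expect_equal(got$strand, g$genes$strand)
})

test_that("extract_upstream is strand-aware and clips at edges and neighbours", {
  # layout from the generator: intergenic 200, genes 300
  g0 <- generate_genome(4, gene_len = 300, intergenic_len = 200, seed = 2)
  genes <- g0$genes
  genes$strand <- c(1L, -1L, 1L, -1L)
  g <- genome(g0$id, g0$sequence, genes)

  up <- extract_upstream(g, g$genes$locus_tag, length = 300)
  expect_true(all(nchar(up$sequence) <= 300))
  # neighbour truncation caps regions at the 200 nt intergenic spacer
  expect_true(all(nchar(up$sequence) == 200))

  # forward strand: region ends at gene start, read forward
  g1 <- up[up$locus_tag == "g0001", ]
  expect_equal(g1$sequence,
               substring(g$sequence, g$genes$start[1] - 199, g$genes$start[1]))
  # reverse strand: reverse complement of the forward slice after gene end
  g2 <- up[up$locus_tag == "g0002", ]
  fwd <- substring(g$sequence, g$genes$end[2] + 1, g$genes$end[2] + 200)
  expect_equal(g2$sequence, revcomp(fwd))

  # without truncation the window extends into the neighbour
  full <- extract_upstream(g, "g0002", length = 300,
                           truncate_at_neighbor = FALSE)
  expect_equal(nchar(full$sequence), 300L)

  # contig edge clipping: gene near the start gets a short region
  ge <- genome("e", strrep("ACGT", 100),
               data.frame(locus_tag = "gA", start = 50L, end = 120L,
                          strand = 1L))
  upe <- extract_upstream(ge, "gA", length = 300)
  expect_equal(nchar(upe$sequence), 50L)

  expect_error(extract_upstream(g, "nope"), "unknown locus_tag")
})

test_that("zero-length upstream regions are omitted with a warning", {
  g <- genome("z", strrep("ACGT", 50),
              data.frame(locus_tag = c("gA", "gB"),
                         start = c(0L, 50L), end = c(40L, 90L),
                         strand = c(1L, 1L)))
  expect_warning(up <- extract_upstream(g, c("gA", "gB")), "zero-length")
  expect_equal(up$locus_tag, "gB")
  expect_equal(nchar(up$sequence), 10L)  # clipped at gA's end
})

test_that("build_background conditional probabilities behave", {
  homo <- genome("h", strrep("A", 200), data.frame(
    locus_tag = character(), start = integer(), end = integer(),
    strand = integer()))
  bg <- build_background(homo, order = 3)
  expect_gt(bg$cond["AAA", "A"], 0.99)
  expect_equal(unname(rowSums(bg$cond)), rep(1, 64), tolerance = 1e-9)
  expect_equal(nrow(bg$cond), 64L)  # all contexts present via pseudocount

  expect_error(build_background(homo, order = -1), "order")
})

test_that("background counts equal a hand-enumerated sliding tally", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  k <- 3  # order 2, (k)-mers of length 3
  # brute-force: slide over the string and its reverse complement
  tally <- function(str) {
    words <- substring(str, 1:(nchar(str) - k + 1), k:nchar(str))
    table(factor(words, levels = apply(
      expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1],
      1, paste, collapse = "")))
  }
  counts <- tally(s) + tally(revcomp(s))
  bg <- build_background(s, order = 2)
  manual <- (as.numeric(counts) + 0.1)
  manual_mat <- matrix(manual, nrow = 16, byrow = TRUE)
  expect_equal(unname(bg$cond), manual_mat / rowSums(manual_mat),
               tolerance = 1e-12)
})

test_that("background is strand-symmetric and round-trips through its file", {
  g <- generate_genome(3, gene_len = 90, intergenic_len = 60, seed = 11)
  bg <- build_background(g, order = 3)
  bg_rc <- build_background(revcomp(g$sequence), order = 3)
  expect_equal(bg$cond, bg_rc$cond, tolerance = 1e-12)
  expect_equal(bg$freq0, bg_rc$freq0, tolerance = 1e-12)

  p <- tempfile()
  write_background(bg, p)
  back <- read_background(p)
  expect_equal(back$order, bg$order)
  expect_equal(back$freq0, bg$freq0, tolerance = 1e-5)
  expect_equal(back$cond, bg$cond, tolerance = 1e-4)
})

test_that("revcomp handles IUPAC codes, palindromes and involutions", {
  expect_identical(revcomp("ACGT"), "ACGT")
  # the dormancy-regulator consensus is its own reverse complement
  expect_identical(revcomp("GGGNCNNNNGNCCC"), "GGGNCNNNNGNCCC")
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE),
               collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACGU"), "non-IUPAC")
})

test_that("FASTA read/write round-trips", {
  seqs <- c(one = "ACGTACGT", two = "GGGCCC")
  p <- tempfile(fileext = ".fasta")
  write_fasta(seqs, p)
  expect_equal(read_fasta(p), seqs)
})
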