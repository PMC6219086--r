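# Exhaustive enumeration oracle for the PWM score null distribution: score
# every possible word with the same integer score matrix and weight it by the
# background.
enumerate_tail <- function(p, bg0, scores) {
  S <- regulonet:::score_matrix_int(p, bg0)
  w <- p$width
  words <- expand.grid(rep(list(1:4), w))
  tot <- apply(words, 1, function(bs) sum(S[cbind(seq_len(w), bs)]))
  prob <- apply(words, 1, function(bs) prod(bg0[bs]))
  vapply(scores, function(s) sum(prob[tot >= s]), 0)
}

test_that("score_distribution DP equals exhaustive enumeration", {
  set.seed(7)
  for (w in 2:5) {
    probs <- matrix(rexp(4 * w), ncol = 4)
    probs <- probs / rowSums(probs)
    p <- pwm(probs)
    bg0 <- c(0.3, 0.2, 0.2, 0.3)
    d <- score_distribution(p, bg0)
    expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
    scores <- d$min_score + seq_along(d$tail) - 1L
    expect_equal(d$tail, enumerate_tail(p, bg0, scores), tolerance = 1e-12)
  }
})

test_that("width-1 PWM against uniform background has tail 0.25 at the max", {
  p <- pwm(matrix(c(1, 0, 0, 0), 1, 4))
  d <- score_distribution(p, rep(0.25, 4))
  expect_equal(d$tail[length(d$tail)], 0.25, tolerance = 1e-12)
  expect_equal(pwm_pvalue(d, d$min_score), 1)
})

test_that("bh_qvalues implements the step-up formula", {
  expect_equal(bh_qvalues(0.04, m = 1), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03), m = 3), rep(0.03, 3))

  set.seed(3)
  p <- sort(runif(40))
  q <- bh_qvalues(p)
  expect_false(is.unsorted(q))            # step-up monotone
  expect_equal(q, p.adjust(p, "BH"))      # m = n reduces to p.adjust
  qm <- bh_qvalues(p, m = 1000)
  expect_true(all(qm >= q - 1e-12))

  expect_error(bh_qvalues(c(0.5, -0.1)), "0, 1")
  expect_error(bh_qvalues(c(0.5, 0.1)), "ascending")
  expect_error(bh_qvalues(c(0.1, 0.5), m = 1), "m must be")
})

test_that("consensus calls bases above threshold and N otherwise", {
  p <- pwm(rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), c(0, 0, 0.71, 0.29)))
  expect_equal(consensus(p), "ANG")
  palpwm <- pwm_from_consensus("GGGNCNNNNGNCCC")
  expect_equal(consensus(palpwm), "GGGNCNNNNGNCCC")
  # palindromic pattern: PWM equals its own reverse complement
  expect_equal(revcomp_pwm(palpwm)$probs, palpwm$probs, tolerance = 1e-12)
})

test_that("scan_pwm finds planted sites and respects thresholds", {
  pl <- planted_fixture(n_genes = 10, seed = 21)
  bg <- build_background(pl$genome, 3)
  p <- pwm_from_consensus("GGGACTTAAGTCCC")
  occ <- scan_pwm(pl$genome, p, bg)
  expect_true(all(pl$sites$start %in% occ$start))
  expect_false(is.unsorted(occ$pvalue))
  expect_true(all(occ$qvalue >= occ$pvalue - 1e-12))

  none <- scan_pwm(pl$genome, p, bg, p_threshold = 0)
  expect_equal(nrow(none), 0L)
})

test_that("palindromic PWM hits both strands at equal scores", {
  pl <- planted_fixture(n_genes = 8, seed = 22, mutation_rate = 0)
  bg <- build_background(pl$genome, 3)
  p <- pwm_from_consensus("GGGACTTAAGTCCC")  # self-reverse-complementary
  occ <- scan_pwm(pl$genome, p, bg)
  plus <- occ[occ$strand == 1, c("start", "score")]
  minus <- occ[occ$strand == -1, c("start", "score")]
  expect_equal(plus[order(plus$start), ], minus[order(minus$start), ],
               ignore_attr = TRUE)
})

test_that("scanning a genome and its reverse complement gives the same (score, p) multiset", {
  pl <- planted_fixture(n_genes = 6, seed = 23)
  g <- pl$genome
  grc <- genome(g$id, revcomp(g$sequence), data.frame(
    locus_tag = g$genes$locus_tag,
    start = genome_length(g) - g$genes$end,
    end = genome_length(g) - g$genes$start,
    strand = -g$genes$strand))
  bg <- build_background(g, 3)
  p <- pwm_from_consensus("GGGACTTAAGTCC")  # non-palindromic width 13
  o1 <- scan_pwm(g, p, bg)
  o2 <- scan_pwm(grc, p, bg)
  k <- function(o) sort(paste(o$score, signif(o$pvalue, 12)))
  expect_equal(k(o1), k(o2))
})

test_that("discover_zoops recovers a strongly planted motif", {
  pl <- planted_fixture(n_genes = 12, seed = 31)
  up <- extract_upstream(pl$genome, pl$genome$genes$locus_tag)
  mo <- discover_zoops(up, nmotifs = 1, seed = 5)
  expect_length(mo, 1L)
  m <- mo[[1]]
  expect_true(consensus_matches(consensus(m$pwm), "GGGACTTAAGTCCC", maxmis = 1))
  expect_lt(m$evalue, 1)

  # site_scores contract: one row per input sequence, ordered by score
  ss <- m$site_scores
  expect_setequal(ss$locus_tag, up$locus_tag)
  sc <- ss$score[!is.na(ss$score)]
  expect_false(is.unsorted(rev(sc)))
  expect_true(all(which(is.na(ss$score)) > length(sc)))
})

test_that("discover_zoops input and threshold contracts", {
  expect_error(discover_zoops(character()), "empty")
  expect_error(discover_zoops(c(a = "ACGTACGTACGTACGTACGTACGT")),
               "at least 2")

  pl <- planted_fixture(n_genes = 8, seed = 32)
  up <- extract_upstream(pl$genome, pl$genome$genes$locus_tag)
  expect_length(discover_zoops(up, nmotifs = 2, evalue_threshold = 0,
                               seed = 3), 0L)
})

test_that("discovery is deterministic under a fixed seed", {
  pl <- planted_fixture(n_genes = 8, seed = 33)
  up <- extract_upstream(pl$genome, pl$genome$genes$locus_tag)
  m1 <- discover_zoops(up, nmotifs = 1, seed = 17)
  m2 <- discover_zoops(up, nmotifs = 1, seed = 17)
  expect_equal(m1[[1]]$pwm$probs, m2[[1]]$pwm$probs)
  expect_equal(m1[[1]]$evalue, m2[[1]]$evalue)
})

test_that("motif_evalue separates planted signal from uninformative matrices", {
  pl <- planted_fixture(n_genes = 12, seed = 34)
  up <- extract_upstream(pl$genome, pl$genome$genes$locus_tag)
  strong <- pwm_from_consensus("GGGACTTAAGTCCC")
  ev <- motif_evalue(strong, up, seed = 9)
  expect_lt(ev, 1)

  flat <- pwm(matrix(0.25, nrow = 14, ncol = 4))
  ev0 <- motif_evalue(flat, up, seed = 9)
  expect_gte(ev0, 1)

  expect_identical(motif_evalue(strong, up, seed = 9), ev)  # determinism
  expect_error(motif_evalue(strong, up, n_shuffles = 0), "n_shuffles")
})

test_that("write_meme emits a parseable minimal motif file", {
  p <- pwm_from_consensus("GGGACTTAAGTCCC")
  f <- tempfile(fileext = ".meme")
  write_meme(list(p), f)
  lines <- readLines(f)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 14", lines)))
  mat <- read.table(text = lines[grep("^0|^1", lines)])
  expect_equal(nrow(mat), 14L)
  expect_equal(rowSums(mat), rep(1, 14), tolerance = 1e-5)
})
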