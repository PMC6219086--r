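#' Position weight matrices
#'
#' A PWM holds per-position base probabilities over \{A,C,G,T\}. Rows are
#' motif positions, columns the four bases; every row must sum to 1 within
#' 1e-9. The pseudocount recorded here (default 0.01) is added to each cell
#' (and the row renormalized) before log-odds scores are formed, so no score
#' is ever -Inf.
#'
#' @param probs Numeric matrix, width x 4 (columns A, C, G, T).
#' @param pseudocount Pseudocount used when forming log-odds scores.
#' @return An object of class `rg_pwm`.
#' @export
pwm <- function(probs, pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(probs) <- base_alphabet
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("every PWM row must sum to 1")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  structure(list(probs = probs, width = nrow(probs), pseudocount = pseudocount),
            class = "rg_pwm")
}

#' @export
print.rg_pwm <- function(x, ...) {
  cat(sprintf("<pwm: width %d, consensus %s>\n", x$width, consensus(x)))
  invisible(x)
}

#' Build a PWM from an IUPAC consensus string
#'
#' N positions become uniform; a concrete base gets probability `strength`
#' with the remainder spread over the other bases; two-fold ambiguity codes
#' split `strength` between their bases.
#'
#' @param cons IUPAC consensus string.
#' @param strength Probability mass on the consensus base(s) (default 0.97).
#' @return An `rg_pwm`.
#' @export
pwm_from_consensus <- function(cons, strength = 0.97) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
                H = "ACT", V = "ACG", N = "ACGT")
  chars <- strsplit(toupper(cons), "", fixed = TRUE)[[1L]]
  rows <- lapply(chars, function(ch) {
    bases <- iupac[[ch]]
    if (is.null(bases)) stop("not an IUPAC code: ", ch)
    bset <- strsplit(bases, "", fixed = TRUE)[[1L]]
    if (length(bset) == 4L) return(rep(0.25, 4L))
    p <- rep((1 - strength) / (4 - length(bset)), 4L)
    p[match(bset, base_alphabet)] <- strength / length(bset)
    p
  })
  pwm(do.call(rbind, rows))
}

#' IUPAC consensus of a PWM
#'
#' Per column: the single base whose probability reaches `threshold`,
#' otherwise N.
#'
#' @param x An `rg_pwm`.
#' @param threshold Probability needed to call a base (default 0.7).
#' @return A consensus string.
#' @export
consensus <- function(x, threshold = 0.7) {
  p <- x$probs
  calls <- apply(p, 1L, function(row) {
    b <- which.max(row)
    if (row[b] >= threshold) base_alphabet[b] else "N"
  })
  paste(calls, collapse = "")
}

#' Reverse complement of a PWM
#' @param x An `rg_pwm`.
#' @export
revcomp_pwm <- function(x) {
  p <- x$probs[x$width:1L, 4L:1L, drop = FALSE]
  colnames(p) <- base_alphabet
  pwm(p, x$pseudocount)
}

# Integer-scaled log2-odds score matrix (width x 4): pseudocount added and
# row renormalized first, then log2(p/bg) * 1000 rounded to integers. All
# downstream p-value machinery operates on these integers, which makes the
# DP tail exactly reproducible by brute-force enumeration.
score_matrix_int <- function(x, bg0, scale = 1000) {
  if (any(bg0 <= 0)) stop("background assigns zero probability to a base")
  p <- x$probs + x$pseudocount
  p <- p / rowSums(p)
  round(scale * log2(sweep(p, 2L, bg0, "/")))
}

#' Exact null distribution of integer-scaled PWM scores
#'
#' Dynamic-programming convolution, position by position, of the discrete
#' log-odds score distribution of a random word drawn from the background's
#' order-0 marginal. Scores are log2-odds scaled by 1000 and rounded to
#' integers; the returned object supports exact `Pr(score >= s)` lookups,
#' which is what turns a scan score into a p-value.
#'
#' @param x An `rg_pwm`.
#' @param background An `rg_background` (its `freq0` marginal is used) or a
#'   numeric vector of 4 base probabilities.
#' @return An `rg_scoredist`: list with the integer score matrix, the pmf
#'   over total scores, its minimum score and the tail vector.
#' @export
score_distribution <- function(x, background) {
  bg0 <- if (inherits(background, "rg_background")) background$freq0
         else background / sum(background)
  S <- score_matrix_int(x, bg0)
  cur <- 1
  cur_min <- 0L
  for (j in seq_len(x$width)) {
    smin <- min(S[j, ]); smax <- max(S[j, ])
    new <- numeric(length(cur) + smax - smin)
    for (b in 1:4) {
      off <- S[j, b] - smin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg0[b] * cur
    }
    cur <- new
    cur_min <- cur_min + smin
  }
  structure(list(score_matrix = S, pmf = cur, min_score = cur_min,
                 tail = rev(cumsum(rev(cur)))),
            class = "rg_scoredist")
}

#' @rdname score_distribution
#' @param dist An `rg_scoredist`.
#' @param scores Integer total scores.
#' @return `pwm_pvalue()`: `Pr(score >= s)` for each score.
#' @export
pwm_pvalue <- function(dist, scores) {
  i <- scores - dist$min_score + 1L
  out <- numeric(length(scores))
  out[i < 1L] <- 1
  inb <- i >= 1L & i <= length(dist$tail)
  out[inb] <- dist$tail[i[inb]]
  out[i > length(dist$tail)] <- 0
  pmin(out, 1)
}

#' Benjamini-Hochberg q-values with an explicit test count
#'
#' Step-up q-values `q_(i) = min_(j >= i) m p_(j) / j`, clipped to 1. Unlike
#' `p.adjust`, the number of tests `m` is passed explicitly: a scan reports
#' only occurrences below a p-value threshold, but its q-values must be
#' computed against all scored windows so they do not depend on the report
#' threshold.
#'
#' @param pvalues P-values sorted ascending.
#' @param m Total number of tests, `m >= length(pvalues)`.
#' @return Vector of q-values, same length and order as `pvalues`.
#' @export
bh_qvalues <- function(pvalues, m = length(pvalues)) {
  if (!length(pvalues)) return(numeric())
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (is.unsorted(pvalues)) stop("p-values must be sorted ascending")
  if (m < length(pvalues)) stop("m must be >= length(pvalues)")
  pmin(rev(cummin(rev(m * pvalues / seq_along(pvalues)))), 1)
}

#' Scan a genome with a PWM on both strands
#'
#' Every window on both strands is scored with the integer-scaled log2-odds
#' of [score_distribution()]; windows whose exact p-value is at most
#' `p_threshold` are reported. Q-values are Benjamini-Hochberg over the
#' emitted p-values with `m` equal to the number of scored windows on both
#' strands. Windows containing N are not scored. The result is sorted
#' ascending by p-value, ties by start then strand (+ before -).
#'
#' @param g An `rg_genome`.
#' @param x An `rg_pwm`.
#' @param background An `rg_background` (see [build_background()]).
#' @param p_threshold Report threshold on the p-value (default 1e-4, the
#'   conventional scanner default; the source narrative states none).
#' @return A data frame of occurrences: `start` (0-based), `strand` (+1/-1),
#'   `sequence` (matched word, motif orientation), `score` (log2-odds),
#'   `pvalue`, `qvalue`.
#' @export
scan_pwm <- function(g, x, background, p_threshold = 1e-4) {
  w <- x$width
  L <- genome_length(g)
  if (L < w) stop("genome shorter than PWM width")
  dist <- score_distribution(x, background)
  S <- dist$score_matrix
  Src <- S[w:1L, 4L:1L, drop = FALSE]  # reverse-strand scores on forward bases
  code <- encode_dna(g$sequence)
  nwin <- L - w + 1L
  fwd <- integer(nwin); rev_ <- integer(nwin)
  ok <- rep(TRUE, nwin)
  for (j in seq_len(w)) {
    b <- code[j:(nwin + j - 1L)]
    ok <- ok & b >= 0L
    bi <- pmax(b, 0L) + 1L
    fwd <- fwd + S[j, bi]
    rev_ <- rev_ + Src[j, bi]
  }
  m <- 2L * sum(ok)
  starts <- which(ok) - 1L
  occ <- data.frame(start = rep(starts, 2L),
                    strand = rep(c(1L, -1L), each = length(starts)),
                    score_int = c(fwd[ok], rev_[ok]))
  occ$pvalue <- pwm_pvalue(dist, occ$score_int)
  occ <- occ[occ$pvalue <= p_threshold, , drop = FALSE]
  occ <- occ[order(occ$pvalue, occ$start, -occ$strand), , drop = FALSE]
  occ$qvalue <- bh_qvalues(occ$pvalue, m)
  if (nrow(occ)) {
    fwdseq <- substring(g$sequence, occ$start + 1L, occ$start + w)
    occ$sequence <- ifelse(occ$strand == 1L, fwdseq,
                           vapply(fwdseq, revcomp, "", USE.NAMES = FALSE))
  } else {
    occ$sequence <- character()
  }
  occ$score <- occ$score_int / 1000
  rownames(occ) <- NULL
  attr(occ, "width") <- w
  attr(occ, "n_tests") <- m
  occ[c("start", "strand", "sequence", "score", "pvalue", "qvalue")]
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs A list of `rg_motif` (or `rg_pwm`) objects.
#' @param path Output path.
#' @param background Optional `rg_background` for the frequency header.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  bg0 <- if (!is.null(background)) background$freq0 else rep(0.25, 4)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", base_alphabet, bg0), collapse = " "), "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    p <- if (inherits(m, "rg_motif")) m$pwm else m
    ev <- if (inherits(m, "rg_motif")) m$evalue else 0
    ns <- if (inherits(m, "rg_motif")) m$nsites else nrow(p$probs)
    lines <- c(lines,
               sprintf("MOTIF m%d %s", i, consensus(p)),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
                       p$width, ns, ev),
               apply(p$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  write_atomic(lines, path)
}
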