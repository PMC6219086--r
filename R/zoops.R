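#' ZOOPS motif discovery
#'
#' Discovers up to `nmotifs` motifs in a set of (promoter) sequences under
#' the zero-or-one-occurrence-per-sequence model: each sequence holds at
#' most one site; the site prior gamma is re-estimated in every M-step;
#' candidate widths are searched independently and the best width is kept.
#' Seeds are the input w-mers themselves (subsampled deterministically by
#' stride to at most `max_seeds`), each given one EM step; the best seed is
#' refined until the log-likelihood-ratio gain drops below `tol` or
#' `refine_maxiter` iterations. After a motif is accepted its sites are
#' probabilistically erased (per-position weights scaled by one minus the
#' site posterior) before the next motif is searched. Motif significance is
#' a seeded Monte-Carlo E-value (see [motif_evalue()]); candidates above
#' `evalue_threshold` are discarded and the search stops.
#'
#' The defaults mirror a conventional discovery call on bacterial
#' promoters: both strands, up to 5 motifs, E-value cutoff 1000.
#'
#' @param sequences Named character vector of DNA sequences, or a data frame
#'   with columns `locus_tag` and `sequence` (as returned by
#'   [extract_upstream()]). At least 2 sequences are required.
#' @param nmotifs Maximum number of motifs to return (default 5).
#' @param both_strands Search both orientations (default TRUE).
#' @param evalue_threshold Discard motifs with E-value above this
#'   (default 1000).
#' @param widths Candidate motif widths (default 8, 10, ..., 20). Widths
#'   longer than the shortest sequence are dropped.
#' @param seed Integer seed controlling the shuffle null; the EM itself is
#'   deterministic.
#' @param n_shuffles Shuffles per E-value estimate (default 20).
#' @param max_seeds Maximum number of seed w-mers per width (default 500).
#' @param refine_maxiter,tol EM convergence controls (default 200, 1e-4).
#' @return A list of `rg_motif` objects ordered by (E-value, -LLR). Each has
#'   elements `pwm`, `evalue`, `llr`, `gamma`, `width`, `nsites` and
#'   `site_scores` — one row per input sequence (`locus_tag`, `score` in
#'   log2-odds or NA when the ZOOPS posterior says no site, `psite`,
#'   `position`, `strand`), sorted descending by score, NA last, ties by
#'   locus_tag. The row order of `site_scores` defines the index space used
#'   by [aggregate_occurrences()].
#' @export
discover_zoops <- function(sequences, nmotifs = 5L, both_strands = TRUE,
                           evalue_threshold = 1000, widths = seq(8L, 20L, 2L),
                           seed = 1L, n_shuffles = 20L, max_seeds = 500L,
                           refine_maxiter = 200L, tol = 1e-4) {
  seqs <- as_seqset(sequences)
  if (length(seqs) < 2L) stop("motif discovery needs at least 2 sequences")
  widths <- sort(as.integer(widths))
  widths <- widths[widths <= min(nchar(seqs))]
  if (!length(widths)) stop("no candidate width fits the shortest sequence")
  codes <- lapply(seqs, encode_dna)
  bg <- em_background(codes)
  erase_pos <- lapply(codes, function(cd) numeric(length(cd)))  # log weights

  motifs <- list()
  for (pass in seq_len(nmotifs)) {
    cands <- list()
    for (w in widths) {
      el <- lapply(erase_pos, window_logsum, w = w)
      fit <- zoops_seed_search_cpp(codes, w, bg, el, both_strands,
                                   as.integer(max_seeds), 0.7, 0.5,
                                   as.integer(refine_maxiter), tol, 0.1)
      if (!isTRUE(fit$ok)) next
      ev <- shuffle_evalue(fit$llr, codes, w, bg, both_strands,
                           n_shuffles = n_shuffles,
                           seed = evalue_seed(seed, pass, w))
      cands[[length(cands) + 1L]] <-
        list(fit = fit, w = w, evalue = ev,
             penalized = fit$llr - 1.5 * w * log(length(seqs)))
    }
    if (!length(cands)) break
    evs <- vapply(cands, `[[`, 0, "evalue")
    pen <- vapply(cands, `[[`, 0, "penalized")
    best <- order(evs, -pen)[1L]
    cand <- cands[[best]]
    if (cand$evalue > evalue_threshold) break
    w <- cand$w
    el <- lapply(erase_pos, window_logsum, w = w)
    post <- zoops_posterior_cpp(codes, cand$fit$pwm, cand$fit$gamma, bg,
                                el, both_strands)
    motifs[[length(motifs) + 1L]] <-
      new_motif(cand, post, names(seqs))
    erase_pos <- erase_update(erase_pos, post$z, w)
  }
  ord <- order(vapply(motifs, `[[`, 0, "evalue"),
               -vapply(motifs, `[[`, 0, "llr"))
  motifs[ord]
}

as_seqset <- function(sequences) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("locus_tag", "sequence") %in% names(sequences)))
    seqs <- setNames(toupper(sequences$sequence), sequences$locus_tag)
  } else {
    if (!length(sequences)) stop("empty sequence set")
    seqs <- toupper(as.character(sequences))
    names(seqs) <- names(sequences) %||% paste0("seq", seq_along(seqs))
  }
  if (!length(seqs)) stop("empty sequence set")
  seqs
}

# 0-order background from the input sequences plus their reverse complements
# (i.e. strand-symmetric), lightly smoothed.
em_background <- function(codes) {
  tab <- numeric(4)
  for (cd in codes) {
    t1 <- tabulate(cd + 1L, nbins = 4L)
    tab <- tab + t1 + rev(t1)  # revcomp mirrors A<->T, C<->G counts
  }
  tab <- tab + 0.1
  tab / sum(tab)
}

# per-window sums of per-position log erase weights
window_logsum <- function(pos_log, w) {
  n <- length(pos_log) - w + 1L
  if (n < 1L) return(numeric())
  cs <- c(0, cumsum(pos_log))
  cs[(w + 1L):(length(pos_log) + 1L)] - cs[1:n]
}

# After accepting a motif, scale each covered position's erase weight by
# (1 - site posterior) per window and strand.
erase_update <- function(erase_pos, zmats, w) {
  for (t in seq_along(erase_pos)) {
    z <- zmats[[t]]
    if (!length(z)) next
    ztot <- pmin(colSums(z), 0.9999)
    lw <- log1p(-ztot)
    delta <- numeric(length(erase_pos[[t]]) + 1L)
    n <- length(lw)
    delta[seq_len(n)] <- delta[seq_len(n)] + lw
    delta[seq_len(n) + w] <- delta[seq_len(n) + w] - lw
    erase_pos[[t]] <- erase_pos[[t]] + cumsum(delta)[seq_along(erase_pos[[t]])]
  }
  erase_pos
}

evalue_seed <- function(seed, pass, w) {
  (as.integer(seed) * 7L + pass * 131L + w * 17L) %% 2147483399L + 1L
}

shuffle_evalue <- function(observed_llr, codes, w, bg, both_strands,
                           n_shuffles, seed, null_seeds = 100L,
                           null_refine = 30L) {
  exceed <- 0L
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      shuf <- lapply(codes, function(cd) cd[sample.int(length(cd))])
      fit <- zoops_seed_search_cpp(shuf, w, bg, list(), both_strands,
                                   as.integer(null_seeds), 0.7, 0.5,
                                   as.integer(null_refine), 1e-4, 0.1)
      if (isTRUE(fit$ok) && fit$llr >= observed_llr) exceed <- exceed + 1L
    }
  })
  (exceed + 1) / n_shuffles
}

new_motif <- function(cand, post, locus_tags) {
  p <- pwm(t(cand$fit$pwm))
  score <- ifelse(post$qsite >= 0.5, post$best_score / log(2), NA_real_)
  ss <- data.frame(locus_tag = locus_tags,
                   score = score,
                   psite = post$qsite,
                   position = post$best_pos,
                   strand = post$best_strand,
                   stringsAsFactors = FALSE)
  skey <- ifelse(is.na(ss$score), -Inf, ss$score)
  ss <- ss[order(-skey, ss$locus_tag), , drop = FALSE]
  rownames(ss) <- NULL
  structure(list(pwm = p, evalue = cand$evalue, llr = cand$fit$llr,
                 gamma = cand$fit$gamma, width = cand$w,
                 nsites = sum(post$qsite >= 0.5), site_scores = ss),
            class = "rg_motif")
}

#' @export
print.rg_motif <- function(x, ...) {
  cat(sprintf("<motif: width %d, consensus %s, E-value %.3g, %d/%d sites>\n",
              x$width, consensus(x$pwm), x$evalue, x$nsites,
              nrow(x$site_scores)))
  invisible(x)
}

#' Monte-Carlo motif E-value
#'
#' The expected number of equally good motifs under a null input, estimated
#' by composition-preserving shuffling: each input sequence is permuted,
#' the shuffled set is re-searched for the best single ZOOPS motif of the
#' same width (one motif per shuffle), and the E-value is
#' `(exceedances + 1) / n_shuffles` where an exceedance is a shuffle whose
#' best log-likelihood ratio reaches the observed one. Deterministic given
#' `seed`. A strongly supported motif scores below 1; a motif no better
#' than what shuffled sequences yield scores >= 1.
#'
#' @param x An `rg_motif` (uses its fitted gamma), or an `rg_pwm`.
#' @param sequences Same formats as [discover_zoops()].
#' @param n_shuffles Number of shuffles (default 20).
#' @param seed Integer seed.
#' @param gamma Site prior used to evaluate the observed LLR when `x` is a
#'   bare PWM (default 0.5).
#' @param both_strands Search both orientations (default TRUE).
#' @return A single number, the E-value.
#' @export
motif_evalue <- function(x, sequences, n_shuffles = 20L, seed = 1L,
                         gamma = 0.5, both_strands = TRUE) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  seqs <- as_seqset(sequences)
  codes <- lapply(seqs, encode_dna)
  bg <- em_background(codes)
  if (inherits(x, "rg_motif")) {
    gamma <- x$gamma
    x <- x$pwm
  }
  stopifnot(inherits(x, "rg_pwm"))
  obs <- zoops_em_cpp(codes, t(x$probs), gamma, bg, list(), both_strands,
                      0L, 1e-4, 0.1)
  shuffle_evalue(obs$llr, codes, x$width, bg, both_strands,
                 n_shuffles = n_shuffles, seed = seed)
}
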