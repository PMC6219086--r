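#' Reject occurrences that fall within annotated genes
#'
#' Only intergenic sites are candidate regulatory elements: any occurrence
#' whose interval overlaps a gene interval by at least one nucleotide, on
#' either strand, is removed. Order is preserved.
#'
#' @param occurrences Occurrence data frame from [scan_pwm()] (sorted
#'   ascending by p-value).
#' @param g An `rg_genome`.
#' @return The intergenic subset of `occurrences`.
#' @export
reject_genic <- function(occurrences, g) {
  if (!nrow(occurrences)) return(occurrences)
  w <- occ_width(occurrences)
  s <- occurrences$start
  e <- s + w
  genic <- rep(FALSE, nrow(occurrences))
  for (i in seq_len(nrow(g$genes)))
    genic <- genic | (g$genes$start[i] < e & g$genes$end[i] > s)
  out <- occurrences[!genic, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "width") <- w
  attr(out, "n_tests") <- attr(occurrences, "n_tests")
  out
}

occ_width <- function(occurrences) {
  w <- attr(occurrences, "width")
  if (is.null(w)) w <- nchar(occurrences$sequence[1L])
  as.integer(w)
}

#' Flanking genes of an intergenic occurrence
#'
#' Determines which neighbouring gene an intergenic site putatively
#' regulates. The downstream gene is the flanking gene the occurrence
#' *faces* — the site lies on the 5' side of that gene's start given the
#' gene's strand. For a divergent flank pair (both face the site) the gene
#' with the nearer start wins; for a convergent pair (neither faces it) the
#' nearer gene wins; at a contig edge a missing flank is `NA`. The upstream
#' gene is the other flank. `relative_position` is `occ_start - gene_start`
#' for a forward-strand downstream gene and `gene_end - (occ_start + width)`
#' for a reverse-strand one, so negative values mean the site lies upstream
#' of the start.
#'
#' @param occurrence One occurrence: a one-row data frame (or list) with at
#'   least `start`, plus `sequence` or a `width` attribute.
#' @param g An `rg_genome`.
#' @param width Motif width; inferred from the occurrence if omitted.
#' @return A list with `downstream`, `upstream` (locus tags or NA) and
#'   `relative_position`.
#' @export
flanking_genes <- function(occurrence, g, width = NULL) {
  start <- occurrence$start
  w <- width %||% nchar(occurrence$sequence)
  end <- start + w
  genes <- g$genes
  if (any(genes$start < end & genes$end > start))
    stop("occurrence at ", start, " is not intergenic")
  li <- which(genes$end <= start)
  ri <- which(genes$start >= end)
  left <- if (length(li)) li[which.max(genes$end[li])] else NA_integer_
  right <- if (length(ri)) ri[which.min(genes$start[ri])] else NA_integer_
  d_left <- if (!is.na(left)) start - genes$end[left] else Inf
  d_right <- if (!is.na(right)) genes$start[right] - end else Inf
  faces_left <- !is.na(left) && genes$strand[left] == -1L
  faces_right <- !is.na(right) && genes$strand[right] == 1L

  down <- if (faces_right && faces_left) {
    if (d_right <= d_left) right else left
  } else if (faces_right) right
  else if (faces_left) left
  else if (!is.na(right) && !is.na(left)) {
    if (d_right <= d_left) right else left
  } else if (!is.na(right)) right
  else if (!is.na(left)) left
  else NA_integer_

  up <- if (is.na(down)) NA_integer_
        else if (identical(down, right)) left else right
  relpos <- if (is.na(down)) NA_integer_
  else if (genes$strand[down] == 1L) start - genes$start[down]
  else genes$end[down] - (start + w)
  list(downstream = if (is.na(down)) NA_character_ else genes$locus_tag[down],
       upstream = if (is.na(up)) NA_character_ else genes$locus_tag[up],
       relative_position = as.integer(relpos))
}

#' Aggregate scan occurrences per downstream gene
#'
#' Walks the (p-value ordered) intergenic occurrences of one motif. The
#' first occurrence seen for a downstream gene creates that gene's row,
#' keeping its sequence, p-value, q-value and relative position; every
#' later occurrence with the same downstream gene only increments the row's
#' hit count. Occurrences with no downstream gene are dropped. Row order is
#' creation order, i.e. ascending best p-value per gene.
#'
#' The two index columns locate the downstream and upstream gene in the
#' discovery stage's ordered per-sequence score list (`site_scores` of the
#' motif), 0-based; -1 marks genes absent from the discovery input — these
#' are the candidates for regulon expansion.
#'
#' @param occurrences Intergenic occurrences sorted ascending by p-value
#'   (apply [reject_genic()] first).
#' @param g An `rg_genome`.
#' @param motif The `rg_motif` the occurrences belong to.
#' @return A data frame with columns `downstream_gene`, `sequence`,
#'   `index_downstream`, `index_upstream`, `pvalue`, `qvalue`, `hit_count`,
#'   `relative_position`.
#' @export
aggregate_occurrences <- function(occurrences, g, motif) {
  w <- occ_width(occurrences)
  idx_of <- function(tag) {
    if (is.na(tag)) return(-1L)
    i <- match(tag, motif$site_scores$locus_tag)
    if (is.na(i)) -1L else i - 1L
  }
  rows <- list()
  pos <- list()  # downstream gene -> row index
  for (i in seq_len(nrow(occurrences))) {
    occ <- occurrences[i, ]
    fl <- flanking_genes(occ, g, width = w)
    dg <- fl$downstream
    if (is.na(dg)) next
    if (!is.null(pos[[dg]])) {
      rows[[pos[[dg]]]]$hit_count <- rows[[pos[[dg]]]]$hit_count + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      downstream_gene = dg, sequence = occ$sequence,
      index_downstream = idx_of(dg), index_upstream = idx_of(fl$upstream),
      pvalue = occ$pvalue, qvalue = occ$qvalue, hit_count = 1L,
      relative_position = fl$relative_position, stringsAsFactors = FALSE)
    pos[[dg]] <- length(rows)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(downstream_gene = character(), sequence = character(),
                      index_downstream = integer(), index_upstream = integer(),
                      pvalue = numeric(), qvalue = numeric(),
                      hit_count = integer(), relative_position = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One round of the motif exploration pipeline
#'
#' From a gene selection: extract upstream regions, discover ZOOPS motifs,
#' then for each motif scan the whole genome against its order-3 Markov
#' background, reject genic occurrences and aggregate the rest per
#' downstream gene. Discovery failure (fewer than 2 usable sequences, or no
#' motif passing the E-value threshold) is reported through `status`, not
#' as an error.
#'
#' @param g An `rg_genome`.
#' @param selection Character vector of locus tags (or an `rg_selection`).
#' @param nmotifs,evalue_threshold,widths,seed Passed to [discover_zoops()].
#' @param order Markov order of the scan background (default 3).
#' @param p_threshold Scan report threshold (default 1e-4).
#' @param upstream_length,truncate_at_neighbor Passed to
#'   [extract_upstream()].
#' @param background Optional precomputed `rg_background`; it depends only
#'   on the genome, so callers iterating on one genome should build it once.
#' @param ... Further arguments to [discover_zoops()].
#' @return A list: `status` ("ok", "input_error" or "no_motif"), `message`,
#'   `motifs` (list of `rg_motif`), `tables` (one aggregated data frame per
#'   motif, named m1, m2, ...), `background`.
#' @export
motif_pipeline <- function(g, selection, nmotifs = 5L, evalue_threshold = 1000,
                           widths = seq(8L, 20L, 2L), seed = 1L, order = 3L,
                           p_threshold = 1e-4, upstream_length = 300L,
                           truncate_at_neighbor = TRUE, background = NULL,
                           ...) {
  if (inherits(selection, "rg_selection")) selection <- selection$names
  up <- extract_upstream(g, selection, length = upstream_length,
                         truncate_at_neighbor = truncate_at_neighbor)
  bg <- background %||% build_background(g, order)
  res <- list(status = "ok", message = "", motifs = list(), tables = list(),
              background = bg)
  motifs <- tryCatch(
    discover_zoops(up, nmotifs = nmotifs, evalue_threshold = evalue_threshold,
                   widths = widths, seed = seed, ...),
    error = function(e) conditionMessage(e))
  if (is.character(motifs)) {
    res$status <- "input_error"; res$message <- motifs
    return(res)
  }
  if (!length(motifs)) {
    res$status <- "no_motif"
    res$message <- "no motif passed the E-value threshold"
    return(res)
  }
  res$motifs <- motifs
  res$tables <- setNames(lapply(motifs, function(m) {
    occ <- scan_pwm(g, m$pwm, bg, p_threshold = p_threshold)
    aggregate_occurrences(reject_genic(occ, g), g, m)
  }), paste0("m", seq_along(motifs)))
  res
}

#' Iterative regulon expansion to convergence
#'
#' Runs [motif_pipeline()], inspects the best motif's aggregated table and
#' adds every downstream gene among its `top_k` rows whose
#' `index_downstream` is -1 (i.e. not part of the discovery input) to the
#' selection, then repeats. The procedure stops converged when the top-k
#' window contains no -1 index, and unconverged when the selection stops
#' changing or after `max_iter` expansion rounds. The selection can only
#' grow.
#'
#' @param g An `rg_genome`.
#' @param initial_selection Non-empty character vector of locus tags.
#' @param top_k Size of the convergence window over each table
#'   (default 20).
#' @param max_iter Maximum number of expansion rounds (default 10);
#'   `max_iter = 0` evaluates the initial selection without expanding.
#' @param all_motifs Expand from every motif's table instead of only the
#'   best (lowest E-value) motif (default FALSE).
#' @param ... Passed to [motif_pipeline()] (seed, thresholds, ...).
#' @return An `rg_exploration`: list with `selection`, `iteration`,
#'   `tables`, `motifs`, `converged`, `history` (selection size per round),
#'   `status`.
#' @export
expand_regulon <- function(g, initial_selection, top_k = 20L, max_iter = 10L,
                           all_motifs = FALSE, ...) {
  if (inherits(initial_selection, "rg_selection"))
    initial_selection <- initial_selection$names
  sel <- sort(unique(as.character(initial_selection)))
  if (!length(sel)) stop("initial selection is empty")
  args <- list(...)
  if (is.null(args$background)) args$background <- build_background(g)
  history <- integer()
  converged <- FALSE
  iter <- 0L
  res <- NULL
  repeat {
    res <- do.call(motif_pipeline, c(list(g = g, selection = sel), args))
    history <- c(history, length(sel))
    if (res$status != "ok") break
    tabs <- if (all_motifs) res$tables else res$tables[1L]
    missing <- unique(unlist(lapply(tabs, function(tab) {
      top <- utils::head(tab, top_k)
      top$downstream_gene[top$index_downstream == -1L]
    })))
    if (!length(missing)) { converged <- TRUE; break }
    if (iter >= max_iter) break
    newsel <- sort(union(sel, missing))
    if (identical(newsel, sel)) break
    sel <- newsel
    iter <- iter + 1L
  }
  structure(list(selection = sel, iteration = iter, tables = res$tables,
                 motifs = res$motifs, converged = converged,
                 history = history, status = res$status),
            class = "rg_exploration")
}

#' @export
print.rg_exploration <- function(x, ...) {
  cat(sprintf("<exploration: %d genes after %d expansion round(s), %s>\n",
              length(x$selection), x$iteration,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Write aggregated motif tables and a run summary
#'
#' One TSV per motif with the eight aggregation columns, plus a plain-text
#' summary (iterations, selection sizes, convergence).
#'
#' @param state An `rg_exploration` (or the result of [motif_pipeline()]).
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_regulon_tables <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(state$tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    utils::write.table(state$tables[[nm]], tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.rename(tmp, p)
    paths <- c(paths, p)
  }
  sm <- file.path(dir, "summary.txt")
  lines <- c(sprintf("status: %s", state$status %||% "ok"),
             sprintf("motifs: %d", length(state$motifs)))
  if (inherits(state, "rg_exploration")) {
    lines <- c(lines,
               sprintf("iterations: %d", state$iteration),
               sprintf("converged: %s", tolower(as.character(state$converged))),
               sprintf("selection_size: %d", length(state$selection)),
               sprintf("history: %s", paste(state$history, collapse = " ")),
               sprintf("selection: %s", paste(state$selection, collapse = " ")))
  }
  write_atomic(lines, sm)
  invisible(c(paths, sm))
}
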