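#' Genome objects
#'
#' A genome is a single DNA sequence over \{A,C,G,T,N\} plus a strand-aware
#' gene table. Intervals are 0-based half-open on the forward strand
#' internally; 1-based inclusive coordinates appear only at the GenBank I/O
#' boundary.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string (coerced to upper case).
#' @param genes Data frame with columns `locus_tag`, `start`, `end`
#'   (0-based half-open) and `strand` (+1 / -1).
#' @return An object of class `rg_genome`.
#' @export
genome <- function(id, sequence, genes) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("genome sequence contains non-ACGTN characters")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_tag", "start", "end", "strand") %in% names(genes)))
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  L <- nchar(sequence)
  if (nrow(genes)) {
    if (any(genes$start < 0 | genes$start >= genes$end | genes$end > L))
      stop("gene interval outside [0, genome length)")
    if (anyDuplicated(genes$locus_tag))
      stop("duplicate locus_tag: ",
           paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]), collapse = ", "))
    if (!all(genes$strand %in% c(-1L, 1L))) stop("strand must be +1 or -1")
  }
  structure(list(id = id, sequence = sequence, genes = genes),
            class = "rg_genome")
}

#' @rdname genome
#' @param x An `rg_genome`.
#' @export
genome_length <- function(x) nchar(x$sequence)

#' @export
print.rg_genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d bp, %d genes>\n", x$id, genome_length(x),
              nrow(x$genes)))
  invisible(x)
}

#' Reverse complement with IUPAC ambiguity support
#'
#' @param seq A DNA string; the full IUPAC nucleotide alphabet is accepted
#'   (N maps to N, R to Y, ...). Any other character is an error.
#' @return The reverse complement.
#' @examples
#' revcomp("ACGT")            # "ACGT"
#' revcomp("GGGNCNNNNGNCCC")  # palindromic consensus: returns itself
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seq))
    stop("non-IUPAC character in sequence")
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# ---- GenBank flat files -----------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses a single-record flat file: the ORIGIN sequence plus `gene`
#' features (and `CDS` features whose locus_tag has no gene counterpart).
#' GenBank 1-based inclusive locations become 0-based half-open intervals;
#' `complement(...)` locations get strand -1. Compound (join) locations are
#' skipped with a warning — multi-exon features do not occur in the
#' bacterial genomes this package targets.
#'
#' @param path Path to a GenBank file.
#' @return An `rg_genome`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else "genome"

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank record without ORIGIN sequence: ", path)
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1L]][1L] else length(lines) + 1L
  seqlines <- lines[(ostart[1L] + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seqlines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record without sequence data: ", path)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    # feature headers sit at column 6; qualifiers at column 22
    hdr <- grep("^ {4,5}\\S", block)
    for (i in seq_along(hdr)) {
      from <- hdr[i]
      to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(block)
      key <- strsplit(trimws(block[from]), "\\s+")[[1L]]
      ftype <- key[1L]
      loc <- paste(trimws(c(sub("^\\s*\\S+\\s*", "", block[from]),
                            grep("^\\s+[^/[:space:]]", block[(from):(to)][-1L],
                                 value = TRUE))),
                   collapse = "")
      quals <- block[from:to]
      lt <- sub('.*?/locus_tag="([^"]*)".*', "\\1",
                paste(quals[grepl("/locus_tag=", quals)], collapse = " "))
      if (!any(grepl("/locus_tag=", quals))) lt <- NA_character_
      feats[[length(feats) + 1L]] <- list(type = ftype, loc = loc, locus_tag = lt)
    }
  }
  gene_rows <- list()
  seen <- character()
  for (f in feats) {
    if (!f$type %in% c("gene", "CDS")) next
    if (is.na(f$locus_tag)) next
    if (f$type == "CDS" && f$locus_tag %in% seen) next
    if (f$type == "gene" && f$locus_tag %in% seen)
      stop("duplicate locus_tag in GenBank record: ", f$locus_tag)
    loc <- f$loc
    strand <- 1L
    if (grepl("^complement\\(", loc)) {
      strand <- -1L
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order|complement", loc)) {
      warning("skipping compound location for ", f$locus_tag, ": ", f$loc)
      next
    }
    m <- regmatches(loc, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc))[[1L]]
    if (length(m) != 3L) {
      warning("skipping unparseable location for ", f$locus_tag, ": ", f$loc)
      next
    }
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(locus_tag = f$locus_tag,
                 start = as.integer(m[2L]) - 1L, end = as.integer(m[3L]),
                 strand = strand, stringsAsFactors = FALSE)
    seen <- c(seen, f$locus_tag)
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(locus_tag = character(), start = integer(), end = integer(),
               strand = integer(), stringsAsFactors = FALSE)
  genome(id, sequence, genes)
}

#' @rdname read_genbank
#' @param g An `rg_genome`.
#' @export
write_genbank <- function(g, path) {
  L <- genome_length(g)
  lines <- c(sprintf("LOCUS       %-17s%11d bp    DNA     linear   BCT 01-JAN-2000",
                     g$id, L),
             sprintf("DEFINITION  %s synthetic record.", g$id),
             sprintf("ACCESSION   %s", g$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    loc <- sprintf("%d..%d", gn$start + 1L, gn$end)
    if (gn$strand == -1L) loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     gene            %s", loc),
               sprintf("                     /locus_tag=\"%s\"", gn$locus_tag))
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, L), by = 10L)
    chunk <- substring(g$sequence, starts, pmin(starts + 9L, L))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))))
  }
  lines <- c(lines, "//")
  write_atomic(lines, path)
}

# ---- FASTA ------------------------------------------------------------------

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings returning plain named character vectors.
#'
#' @param path File path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- upstream extraction ----------------------------------------------------

#' Extract upstream (promoter) regions of selected genes
#'
#' For a forward-strand gene the region is `[max(0, start - length), start)`
#' read forward; for a reverse-strand gene it is `[end, min(L, end + length))`
#' reverse-complemented, so the returned string always reads 5'→3' toward
#' the gene start. With `truncate_at_neighbor` the region is clipped so it
#' never overlaps another gene's interval (motif discovery should not see
#' coding sequence). Zero-length regions are omitted with a warning.
#'
#' @param g An `rg_genome`.
#' @param locus_tags Genes to extract; all must exist.
#' @param length Maximum region length in nt (default 300, a standard
#'   bacterial promoter window).
#' @param truncate_at_neighbor Clip at neighbouring gene boundaries
#'   (default TRUE).
#' @return A data frame with columns `locus_tag`, `sequence`, `start`,
#'   `end`, `strand` (region coordinates on the forward strand).
#' @export
extract_upstream <- function(g, locus_tags, length = 300L,
                             truncate_at_neighbor = TRUE) {
  locus_tags <- unique(as.character(locus_tags))
  idx <- match(locus_tags, g$genes$locus_tag)
  if (anyNA(idx))
    stop("unknown locus_tag(s): ", paste(locus_tags[is.na(idx)], collapse = ", "))
  L <- genome_length(g)
  rows <- list()
  for (k in seq_along(idx)) {
    gn <- g$genes[idx[k], ]
    others <- g$genes[-idx[k], , drop = FALSE]
    if (gn$strand == 1L) {
      lo <- max(0L, gn$start - length); hi <- gn$start
      if (truncate_at_neighbor && nrow(others)) {
        ov <- others$end > lo & others$start < hi
        if (any(ov)) lo <- max(lo, max(pmin(others$end[ov], hi)))
      }
      if (hi <= lo) { warning("zero-length upstream region for ", gn$locus_tag); next }
      s <- substring(g$sequence, lo + 1L, hi)
    } else {
      lo <- gn$end; hi <- min(L, gn$end + length)
      if (truncate_at_neighbor && nrow(others)) {
        ov <- others$end > lo & others$start < hi
        if (any(ov)) hi <- min(hi, min(pmax(others$start[ov], lo)))
      }
      if (hi <= lo) { warning("zero-length upstream region for ", gn$locus_tag); next }
      s <- revcomp(substring(g$sequence, lo + 1L, hi))
    }
    rows[[k]] <- data.frame(locus_tag = gn$locus_tag, sequence = s,
                            start = lo, end = hi, strand = gn$strand,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_tag = character(), sequence = character(),
                      start = integer(), end = integer(), strand = integer())
  rownames(out) <- NULL
  out
}

# ---- Markov background ------------------------------------------------------

base_alphabet <- c("A", "C", "G", "T")

#' Estimate an order-k Markov background from a genome
#'
#' Counts (k+1)-mers on both strands (windows containing N are skipped),
#' smooths every cell with a pseudocount of 0.1 and normalizes per context,
#' mirroring the background model a motif scanner conditions on. The
#' order-0 marginal is retained alongside — PWM p-values use it.
#'
#' @param g An `rg_genome` (or a plain DNA string).
#' @param order Markov order, >= 0 (default 3).
#' @return An `rg_background`: list with `order`, `cond` (4^order x 4 matrix
#'   of conditional probabilities, rownames = contexts) and `freq0` (order-0
#'   marginal over ACGT).
#' @export
build_background <- function(g, order = 3L) {
  if (inherits(g, "rg_genome")) g <- g$sequence
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop("order must be >= 0")
  if (nchar(g) <= order) stop("sequence shorter than the Markov order")
  counts <- kmer_counts(g, order + 1L) + kmer_counts(revcomp(g), order + 1L)
  counts <- counts + 0.1
  contexts <- if (order == 0L) "" else
    apply(expand.grid(rep(list(base_alphabet), order),
                      stringsAsFactors = FALSE)[, order:1, drop = FALSE],
          1, paste, collapse = "")
  mat <- matrix(counts, nrow = length(contexts), ncol = 4L, byrow = TRUE,
                dimnames = list(contexts, base_alphabet))
  cond <- mat / rowSums(mat)
  c0 <- kmer_counts(g, 1L) + kmer_counts(revcomp(g), 1L) + 0.1
  structure(list(order = order, cond = cond,
                 freq0 = setNames(c0 / sum(c0), base_alphabet)),
            class = "rg_background")
}

# Vector of 4^k counts in lexicographic A<C<G<T order; N-containing windows
# are excluded.
kmer_counts <- function(seq, k) {
  code <- encode_dna(seq)
  n <- length(code)
  counts <- numeric(4^k)
  if (n < k) return(counts)
  idx <- numeric(n - k + 1L)
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    b <- code[j:(n - k + j)]
    ok <- ok & b >= 0L
    idx <- idx * 4 + pmax(b, 0L)
  }
  tab <- tabulate(idx[ok] + 1L, nbins = 4^k)
  as.numeric(tab)
}

# A=0 C=1 G=2 T=3, N (or other) = -1
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  out <- rep(-1L, length(v))
  out[v == 65L] <- 0L; out[v == 67L] <- 1L
  out[v == 71L] <- 2L; out[v == 84L] <- 3L
  out
}

decode_dna <- function(code) {
  paste(c("N", base_alphabet)[code + 2L], collapse = "")
}

#' Write / read a Markov background in the k-mer frequency text format
#'
#' The classic background text format: for every order 0..k, one line per
#' word with its joint frequency. `read_background()` reconstructs the
#' conditional model from the highest order present.
#'
#' @param bg An `rg_background`.
#' @param path File path.
#' @export
write_background <- function(bg, path) {
  lines <- character()
  # joint frequencies per order, rebuilt from the conditionals
  joint <- bg$freq0
  names(joint) <- base_alphabet
  lines <- c(lines, "# order 0",
             sprintf("%s %.6e", names(joint), joint))
  if (bg$order >= 1L) {
    for (k in seq_len(bg$order)) {
      newjoint <- numeric(0)
      for (ctx in names(joint)) {
        pctx <- if (k <= bg$order) {
          cond_ctx <- substring(ctx, max(1L, k - bg$order + 1L), k)
          row <- if (nchar(cond_ctx) == bg$order) bg$cond[cond_ctx, ] else NULL
          if (is.null(row)) {
            # marginalize the conditionals down to shorter contexts
            sel <- substring(rownames(bg$cond),
                             bg$order - nchar(cond_ctx) + 1L) == cond_ctx
            colSums(bg$cond[sel, , drop = FALSE]) / sum(sel)
          } else row
        }
        nj <- joint[ctx] * pctx
        names(nj) <- paste0(ctx, base_alphabet)
        newjoint <- c(newjoint, nj)
      }
      joint <- newjoint
      lines <- c(lines, sprintf("# order %d", k),
                 sprintf("%s %.6e", names(joint), joint))
    }
  }
  write_atomic(lines, path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, "", 1L)
  freqs <- as.numeric(vapply(parts, `[[`, "", 2L))
  kmax <- max(nchar(words))
  top <- freqs[nchar(words) == kmax]
  names(top) <- words[nchar(words) == kmax]
  order <- kmax - 1L
  contexts <- unique(substring(names(top), 1L, order))
  cond <- t(vapply(contexts, function(ctx) {
    v <- top[paste0(ctx, base_alphabet)]
    v / sum(v)
  }, numeric(4)))
  colnames(cond) <- base_alphabet
  f0 <- freqs[nchar(words) == 1L]
  names(f0) <- words[nchar(words) == 1L]
  f0 <- f0[base_alphabet] / sum(f0[base_alphabet])
  if (order == 0L) cond <- matrix(f0, 1L, 4L, dimnames = list("", base_alphabet))
  structure(list(order = order, cond = cond, freq0 = f0),
            class = "rg_background")
}
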