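#' Generate a synthetic bacterial genome
#'
#' Alternating intergenic/gene layout: `n_genes` genes of `gene_len` nt
#' separated (and flanked) by `intergenic_len` nt of intergenic sequence,
#' so the genome is `n_genes * gene_len + (n_genes + 1) * intergenic_len`
#' nt long. Strands are random, locus tags g0001, g0002, ... The sequence
#' is sampled from a uniform base distribution or, when `bg` is an
#' `rg_background`, from its order-k Markov chain. Pure function of
#' (parameters, seed).
#'
#' @param n_genes Number of genes.
#' @param gene_len Gene length in nt (default 300).
#' @param intergenic_len Intergenic spacer length in nt (default 200).
#' @param bg `NULL` for uniform composition, or an `rg_background`.
#' @param seed Integer seed.
#' @return An `rg_genome`.
#' @export
generate_genome <- function(n_genes, gene_len = 300L, intergenic_len = 200L,
                            bg = NULL, seed = 1L) {
  stopifnot(n_genes > 0L, gene_len > 0L, intergenic_len > 0L)
  L <- n_genes * gene_len + (n_genes + 1L) * intergenic_len
  with_seed(seed, {
    seqc <- if (is.null(bg)) {
      sample(base_alphabet, L, replace = TRUE)
    } else {
      sample_markov(bg, L)
    }
    starts <- intergenic_len + (seq_len(n_genes) - 1L) * (gene_len + intergenic_len)
    genes <- data.frame(locus_tag = sprintf("g%04d", seq_len(n_genes)),
                        start = starts, end = starts + gene_len,
                        strand = sample(c(1L, -1L), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    genome("synthetic", paste(seqc, collapse = ""), genes)
  })
}

sample_markov <- function(bg, L) {
  k <- bg$order
  out <- character(L)
  if (k == 0L) return(sample(base_alphabet, L, replace = TRUE, prob = bg$freq0))
  out[seq_len(k)] <- sample(base_alphabet, k, replace = TRUE, prob = bg$freq0)
  for (i in (k + 1L):L) {
    ctx <- paste(out[(i - k):(i - 1L)], collapse = "")
    out[i] <- sample(base_alphabet, 1L, prob = bg$cond[ctx, ])
  }
  out
}

#' Specification of a planted motif
#'
#' @param consensus IUPAC consensus; N positions are wildcards sampled from
#'   the background, concrete positions are copied and then mutated at
#'   `mutation_rate`. The default is a 14-nt near-palindromic word of the
#'   kind dormancy-regulator binding sites exhibit.
#' @param regulon Locus tags that receive one planted instance each.
#' @param offset_range Distance (nt) from the gene start to the motif start,
#'   sampled uniformly from the feasible subset of this interval. The default
#'   20-100 nt keeps sites promoter-proximal (within half the default
#'   intergenic spacer), so a planted site is always nearer its own gene's
#'   start than a divergent neighbour's and downstream-gene assignment is
#'   unambiguous.
#' @param mutation_rate Per-base substitution probability at non-N
#'   positions, in [0, 0.5).
#' @return An object of class `rg_motifspec`.
#' @export
planted_motif_spec <- function(consensus = "GGGACTTAAGTCCC", regulon,
                               offset_range = c(20L, 100L),
                               mutation_rate = 0.05) {
  stopifnot(mutation_rate >= 0, mutation_rate < 0.5,
            length(offset_range) == 2L, offset_range[1L] <= offset_range[2L])
  structure(list(consensus = toupper(consensus), regulon = unique(regulon),
                 offset_range = as.integer(offset_range),
                 mutation_rate = mutation_rate),
            class = "rg_motifspec")
}

#' Plant motif instances upstream of a regulon
#'
#' Writes one motif instance on the sense strand upstream of each regulon
#' gene, entirely inside the intergenic region (coding intervals are never
#' altered), at an offset sampled from the feasible part of
#' `spec$offset_range`. Returns the modified genome and the ground-truth
#' site list.
#'
#' @param g An `rg_genome`.
#' @param spec An `rg_motifspec` (see [planted_motif_spec()]).
#' @param seed Integer seed.
#' @return A list: `genome` (modified `rg_genome`) and `sites` (data frame
#'   `locus_tag`, `start` — 0-based forward-strand coordinate of the
#'   planted window — and `strand`).
#' @export
plant_motif <- function(g, spec, seed = 1L) {
  w <- nchar(spec$consensus)
  cons <- strsplit(spec$consensus, "", fixed = TRUE)[[1L]]
  L <- genome_length(g)
  seqc <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  genes <- g$genes
  idx <- match(spec$regulon, genes$locus_tag)
  if (anyNA(idx))
    stop("regulon gene(s) absent from genome: ",
         paste(spec$regulon[is.na(idx)], collapse = ", "))
  sites <- list()
  occupied <- matrix(integer(), ncol = 2L)  # already-planted windows
  with_seed(seed, {
    for (k in seq_along(idx)) {
      gn <- genes[idx[k], ]
      others <- genes[-idx[k], , drop = FALSE]
      offs <- spec$offset_range[1L]:spec$offset_range[2L]
      offs <- offs[offs >= w]
      starts <- if (gn$strand == 1L) gn$start - offs else gn$end + offs - w
      okfun <- function(s) {
        s >= 0L && s + w <= L &&
          !any(others$start < s + w & others$end > s) &&
          !(gn$start < s + w & gn$end > s) &&
          !any(occupied[, 1L] < s + w & occupied[, 2L] > s)
      }
      feas <- vapply(starts, okfun, TRUE)
      if (!any(feas))
        stop("no feasible motif placement upstream of ", gn$locus_tag)
      site <- starts[feas][sample.int(sum(feas), 1L)]
      inst <- cons
      nmask <- inst == "N"
      inst[nmask] <- sample(base_alphabet, sum(nmask), replace = TRUE)
      mut <- !nmask & runif(w) < spec$mutation_rate
      for (j in which(mut))
        inst[j] <- sample(setdiff(base_alphabet, inst[j]), 1L)
      written <- if (gn$strand == 1L) inst else
        strsplit(revcomp(paste(inst, collapse = "")), "", fixed = TRUE)[[1L]]
      seqc[(site + 1L):(site + w)] <- written
      occupied <- rbind(occupied, c(site, site + w))
      sites[[k]] <- data.frame(locus_tag = gn$locus_tag, start = site,
                               strand = gn$strand, stringsAsFactors = FALSE)
    }
  })
  list(genome = genome(g$id, paste(seqc, collapse = ""), genes),
       sites = do.call(rbind, sites))
}

#' Generate a homologous network pair with an identity map
#'
#' Emulates two species' versions of the same pathway: `n_shared` nodes
#' appear in both networks, plus species-specific nodes; each network gets
#' independent random (Erdos-Renyi) edges. With `homolog_rename` the shared
#' nodes are renamed in network b by case change (SG001 vs Sg001, the way
#' human and mouse gene symbols differ) and the returned identity map
#' records the correspondences; otherwise the map is empty.
#'
#' @param n_shared,n_only_a,n_only_b Node counts.
#' @param edge_prob Edge probability per node pair.
#' @param homolog_rename Rename shared nodes in network b (default FALSE).
#' @param seed Integer seed.
#' @return A list: networks `a`, `b` and identity map `map`.
#' @export
generate_network_pair <- function(n_shared, n_only_a = 0L, n_only_b = 0L,
                                  edge_prob = 0.05, homolog_rename = FALSE,
                                  seed = 1L) {
  stopifnot(n_shared >= 0L, n_only_a >= 0L, n_only_b >= 0L)
  shared <- sprintf("SG%03d", seq_len(n_shared))
  only_a <- sprintf("AG%03d", seq_len(n_only_a))
  only_b <- sprintf("BG%03d", seq_len(n_only_b))
  shared_b <- if (homolog_rename)
    paste0(substr(shared, 1L, 1L), tolower(substring(shared, 2L))) else shared
  with_seed(seed, {
    a <- network("net_a", nodes = c(shared, only_a),
                 edges = random_edges(c(shared, only_a), edge_prob))
    b <- network("net_b", nodes = c(shared_b, only_b),
                 edges = random_edges(c(shared_b, only_b), edge_prob))
    map <- if (homolog_rename)
      identity_map(data.frame(name_a = shared, name_b = shared_b,
                              stringsAsFactors = FALSE),
                   spaces = c("a", "b"))
    else identity_map(data.frame(name_a = character(), name_b = character()),
                      spaces = c("a", "b"))
    list(a = a, b = b, map = map)
  })
}

# Sample Binomial(choose(n,2), p) distinct unordered pairs by index, so large
# sparse networks are generated without materializing all pairs.
random_edges <- function(nodes, p) {
  n <- length(nodes)
  npairs <- n * (n - 1) / 2
  if (npairs < 1) return(NULL)
  m <- stats::rbinom(1L, as.integer(npairs), p)
  if (m == 0L) return(NULL)
  idx <- sort(sample.int(npairs, m))
  # decode pair index (1-based, row-major over i<j): row i holds pairs
  # (cum(i-1), cum(i)] with cum(i) = i*n - i*(i+1)/2
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  cum <- function(r) r * n - r * (r + 1) / 2
  # one floating-point correction step in either direction
  i <- ifelse(cum(i) < idx, i + 1, i)
  i <- ifelse(cum(i - 1) >= idx, i - 1, i)
  j <- idx - cum(i - 1) + i
  stopifnot(all(i >= 1), all(j > i), all(j <= n))
  data.frame(source = nodes[i], target = nodes[j], interaction = "pp",
             stringsAsFactors = FALSE)
}

#' Write a planted-motif fixture to disk
#'
#' Emits the genome as GenBank and FASTA plus the ground-truth site list as
#' TSV — the standard bundle for an offline motif-recovery benchmark.
#'
#' @param planted Result of [plant_motif()].
#' @param dir Output directory.
#' @export
write_motif_fixture <- function(planted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(planted$genome, file.path(dir, "genome.gbk"))
  write_fasta(setNames(planted$genome$sequence, planted$genome$id),
              file.path(dir, "genome.fasta"))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  utils::write.table(planted$sites, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, file.path(dir, "sites.tsv"))
  invisible(dir)
}
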