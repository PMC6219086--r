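#' Selections and identity maps
#'
#' A selection is a set of shared names with optional provenance (the
#' network it originated in). An identity map is a many-to-many
#' correspondence between two name spaces — typically homologous gene
#' symbols of two species — applied symmetrically during propagation.
#'
#' @param names Character vector of shared names (de-duplicated).
#' @param source_network Optional name of the originating network.
#' @return `selection()` returns an `rg_selection`.
#' @export
selection <- function(names = character(), source_network = NULL) {
  names <- as.character(names)
  if (any(!nzchar(names) | is.na(names))) stop("selection names must be non-empty")
  structure(list(names = sort(unique(names)), source_network = source_network),
            class = "rg_selection")
}

#' @rdname selection
#' @param pairs Two-column data frame (or matrix) of corresponding names.
#' @param spaces Character vector of length 2 labelling the two name spaces.
#' @return `identity_map()` returns an `rg_idmap`.
#' @export
identity_map <- function(pairs, spaces = c("a", "b")) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 2L) stop("identity map needs exactly 2 columns")
  names(pairs) <- c("name_a", "name_b")
  pairs <- unique(pairs[nzchar(pairs$name_a) & nzchar(pairs$name_b), ])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, spaces = spaces), class = "rg_idmap")
}

#' Load an identity-mapping file
#'
#' Reads a two-column delimited file (tab or whitespace separated), one
#' correspondence per row; blank lines and `#` comments are skipped. A
#' header row is auto-detected and skipped iff its two cells equal the
#' declared space labels (case-insensitively) — so headers are never
#' silently treated as gene names.
#'
#' @param path Path to the mapping file.
#' @param spaces Labels of the two name spaces, e.g. `c("human", "mouse")`.
#' @return An `rg_idmap`.
#' @export
load_mapping <- function(path, spaces = c("a", "b")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- lengths(toks) != 2L
  if (any(bad))
    stop("mapping file line ", idx[which(bad)[1L]], ": expected 2 columns, got ",
         lengths(toks)[which(bad)[1L]])
  if (length(toks) &&
      all(tolower(toks[[1L]]) == tolower(spaces)))
    toks <- toks[-1L]
  pairs <- data.frame(name_a = vapply(toks, `[[`, "", 1L),
                      name_b = vapply(toks, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  identity_map(pairs, spaces)
}

# Transitive closure of a name set under a list of identity maps, applied in
# both directions until a fixed point.
closure_names <- function(names, maps, ignore_case = FALSE) {
  out <- unique(names)
  key <- if (ignore_case) tolower else identity
  repeat {
    added <- character()
    for (m in maps) {
      p <- m$pairs
      hit_a <- p$name_a[key(p$name_b) %in% key(out)]
      hit_b <- p$name_b[key(p$name_a) %in% key(out)]
      added <- c(added, hit_a, hit_b)
    }
    new <- setdiff(unique(added), out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

#' Propagate a node selection across all networks of a session
#'
#' Expands the selected shared names to their closure under every registered
#' identity map (both directions, transitively, to a fixed point) and
#' intersects the closure with each network's node set. Names absent
#' everywhere simply select nothing.
#'
#' @param sess An `rg_session`.
#' @param sel An `rg_selection` (or character vector of shared names).
#' @param ignore_case Match names case-insensitively. Off by default:
#'   human/mouse symbols differ only by case and implicit folding would hide
#'   that a homolog map is in use.
#' @return Named list (one element per network) of sorted character vectors.
#' @export
propagate <- function(sess, sel, ignore_case = FALSE) {
  if (!inherits(sess, "rg_session")) stop("'sess' must be an rg_session")
  if (!inherits(sel, "rg_selection")) sel <- selection(sel)
  cl <- closure_names(sel$names, sess$identity_maps, ignore_case)
  key <- if (ignore_case) tolower else identity
  lapply(sess$networks, function(net) {
    nm <- node_names(net)
    sort(nm[key(nm) %in% key(cl)])
  })
}

#' Export and re-import flat selection files
#'
#' The flat selection file is the interchange format between the network
#' side and the motif side: one shared name per line, lexicographically
#' sorted, with a trailing newline. `read_selection()` reads the same
#' format back (blank lines skipped).
#'
#' @param sel An `rg_selection` or character vector.
#' @param path Output path.
#' @export
export_selection <- function(sel, path) {
  if (!inherits(sel, "rg_selection")) sel <- selection(sel)
  write_atomic(sel$names, path)
}

#' @rdname export_selection
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  selection(lines[nzchar(trimws(lines))])
}
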