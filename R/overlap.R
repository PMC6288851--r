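#' Overlap parameters
#'
#' `b` is the minimum exact-match length, in bases: two reads are linked in
#' the overlap graph when they share an exact common substring of at least
#' `b` bases anywhere in either read, in forward or (when `include_revcomp`)
#' reverse-complement orientation. Typical values: 70 for 454-style long
#' reads, 100 for merged Illumina pairs, 15 for a low-coverage residual pass.
#'
#' @param b integer minimum exact-match length (>= 2).
#' @param include_revcomp also match against reverse complements
#'   (default `TRUE`; both strands of a molecule are sequenced).
#' @return an `overlap_params` object.
#' @export
overlap_params <- function(b, include_revcomp = TRUE) {
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 2L)
    stop("b must be a single integer >= 2")
  structure(list(b = b, include_revcomp = isTRUE(include_revcomp)),
            class = "overlap_params")
}

as_overlap_params <- function(params) {
  if (inherits(params, "overlap_params")) return(params)
  if (is.numeric(params) && length(params) == 1L) return(overlap_params(params))
  stop("params must be an overlap_params object or a single integer b")
}

#' Build a searchable exact-substring index over a read set
#'
#' Indexes every length-`b` window of every read (windows containing `N` are
#' skipped, so `N` breaks matches; orientation is folded in by canonical
#' windows when `include_revcomp`). The index answers neighbor queries and
#' exact-pattern location queries; matches can never span two reads.
#'
#' @param readset a [read_set()].
#' @param params an [overlap_params()] (or a bare integer `b`).
#' @return an `overlap_index` handle.
#' @export
build_index <- function(readset, params) {
  params <- as_overlap_params(params)
  stopifnot(inherits(readset, "read_set"))
  if (length(readset) > 0L && params$b > max(read_lengths(readset)))
    warning("b = ", params$b, " exceeds every read length; ",
            "the overlap graph will have no edges")
  ptr <- .ob_index_build(readset$seqs, params$b, params$include_revcomp)
  structure(list(ptr = ptr, b = params$b,
                 include_revcomp = params$include_revcomp,
                 n_reads = length(readset)),
            class = "overlap_index")
}

#' @export
print.overlap_index <- function(x, ...) {
  cat(sprintf("overlap_index over %d reads (b = %d, revcomp = %s)\n",
              x$n_reads, x$b, x$include_revcomp))
  invisible(x)
}

#' Neighbors of one read in the overlap graph
#'
#' All reads j != i sharing an exact substring of >= `b` bases with read i
#' (either orientation when the index includes reverse complements). A read
#' shorter than `b` has no neighbors; a read never neighbors itself, even
#' through a palindromic window.
#'
#' @param index an [build_index()] result.
#' @param read_ordinal 1-based read ordinal.
#' @return sorted integer vector of neighbor ordinals (1-based).
#' @export
find_neighbors <- function(index, read_ordinal) {
  stopifnot(inherits(index, "overlap_index"))
  read_ordinal <- as.integer(read_ordinal)
  if (length(read_ordinal) != 1L || is.na(read_ordinal) ||
      read_ordinal < 1L || read_ordinal > index$n_reads)
    stop("read_ordinal out of range 1..", index$n_reads)
  .ob_index_neighbors(index$ptr, read_ordinal - 1L)
}

#' Locate reads containing an exact pattern
#'
#' @param index an [build_index()] result.
#' @param pattern DNA string of length >= `b`.
#' @return sorted 1-based ordinals of reads containing `pattern` (or, when
#'   the index includes reverse complements, its reverse complement).
#' @export
locate_reads <- function(index, pattern) {
  stopifnot(inherits(index, "overlap_index"))
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1L) stop("pattern must be a single string")
  .ob_index_locate(index$ptr, pattern)
}

new_overlap_graph <- function(adjacency) {
  structure(list(n_nodes = length(adjacency),
                 adjacency = adjacency,
                 degree = vapply(adjacency, length, integer(1))),
            class = "overlap_graph")
}

#' Build the exact-overlap graph of a read set
#'
#' Nodes are reads (1-based ordinals in file order); an undirected edge links
#' two distinct reads sharing an exact common substring of at least `b`
#' bases in either orientation. Edge multiplicity is collapsed: however many
#' substrings a pair shares, it contributes one edge, so a node's degree is
#' its number of distinct neighboring reads -- the abundance proxy the
#' degree histogram is built from. The construction is deterministic for a
#' fixed read order and parameters.
#'
#' @param readset a [read_set()].
#' @param params an [overlap_params()] (or a bare integer `b`).
#' @return an `overlap_graph` with fields `n_nodes`, `adjacency` (list of
#'   sorted 1-based neighbor vectors) and `degree`.
#' @export
build_graph <- function(readset, params) {
  params <- as_overlap_params(params)
  stopifnot(inherits(readset, "read_set"))
  if (length(readset) == 0L) return(new_overlap_graph(list()))
  if (params$b > max(read_lengths(readset)))
    warning("b = ", params$b, " exceeds every read length; ",
            "the overlap graph has no edges")
  adj <- .ob_build_adjacency(readset$seqs, params$b, params$include_revcomp)
  new_overlap_graph(adj)
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d nodes, %d edges\n",
              x$n_nodes, n_edges(x)))
  invisible(x)
}

#' Number of (undirected) edges of an overlap graph
#' @param graph an `overlap_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "overlap_graph"))
  sum(graph$degree) %/% 2L
}

#' Export an adjacency list as plain text
#'
#' One line per node: `node<TAB>comma-separated neighbors` (1-based
#' ordinals; isolated nodes get an empty second column). Mirrors the
#' two-column adjacency-list representation of the read-alignment stage.
#'
#' @param graph an `overlap_graph`.
#' @param path output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
export_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "overlap_graph"))
  lines <- vapply(seq_len(graph$n_nodes), function(i) {
    paste0(i, "\t", paste(graph$adjacency[[i]], collapse = ","))
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
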