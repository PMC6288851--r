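# Independent oracles and fixture builders for the test suite.
# The oracles deliberately avoid the package's indexed code path: edges are
# decided per pair by enumerating raw substrings in R, and (on tiny inputs)
# by a longest-common-substring dynamic program.

# All length-b substrings of s that contain no N (N never matches).
windows_of <- function(s, b) {
  n <- nchar(s)
  if (n < b) return(character(0))
  w <- substring(s, 1:(n - b + 1L), b:n)
  w[!grepl("N", w, fixed = TRUE)]
}

# Brute-force per-pair edge oracle: i-j linked iff they share a length-b
# substring, read i forward against read j forward or reverse complement.
oracle_adjacency <- function(seqs, b, include_revcomp = TRUE) {
  n <- length(seqs)
  wf <- lapply(seqs, windows_of, b = b)
  wb <- if (include_revcomp)
    lapply(reverse_complement(seqs), windows_of, b = b)
  else
    vector("list", n)
  adj <- replicate(n, integer(0), simplify = FALSE)
  if (n < 2L) return(adj)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      hit <- any(wf[[i]] %in% wf[[j]]) ||
        (include_revcomp && any(wf[[i]] %in% wb[[j]]))
      if (hit) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  lapply(adj, sort)
}

# Longest common substring length by dynamic programming (O(|a||b|)).
lcs_length <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  prev <- integer(length(y))
  best <- 0L
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match_row <- x[i] == y & y != "N"
    for (j in seq_along(y)) {
      if (match_row[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

random_genome <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# Reads drawn from a genome (both strands), exact substrings.
reads_from_genome <- function(genome, n, len_range = c(80, 160),
                              prefix = "r") {
  glen <- nchar(genome)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  len <- pmin(len, glen)
  start <- vapply(len, function(l) sample.int(glen - l + 1L, 1L), integer(1))
  seqs <- substring(genome, start, start + len - 1L)
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  seqs[flip] <- reverse_complement(seqs[flip])
  read_set(sprintf("%s%d", prefix, seq_len(n)), seqs)
}

# Fully random (mostly non-overlapping) reads, optionally salted with N.
random_reads <- function(n, len_range = c(30, 300), n_rate = 0,
                         prefix = "q") {
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  if (n_rate > 0) {
    for (i in seq_len(n)) {
      k <- stats::rbinom(1L, len[i], n_rate)
      if (k > 0L) {
        s <- strsplit(seqs[i], "")[[1L]]
        s[sample.int(len[i], k)] <- "N"
        seqs[i] <- paste(s, collapse = "")
      }
    }
  }
  read_set(sprintf("%s%d", prefix, seq_len(n)), seqs)
}

# Connected-component oracle via igraph (never used in the implementation).
igraph_components <- function(graph) {
  edges <- do.call(rbind, lapply(seq_len(graph$n_nodes), function(i) {
    nb <- graph$adjacency[[i]]
    nb <- nb[nb > i]
    if (length(nb) == 0L) NULL else cbind(i, nb)
  }))
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_bins <- function(bins) {
  bins <- lapply(bins, sort)
  bins[order(vapply(bins, function(b) b[1L], integer(1)))]
}

# TRUE iff genomes a and b share no exact k-mer in either orientation.
genomes_share_kmer <- function(a, b, k) {
  any(windows_of(a, k) %in% c(windows_of(b, k),
                              windows_of(reverse_complement(b), k)))
}

graph_from_edges <- function(n, edges) {
  adj <- replicate(n, integer(0), simplify = FALSE)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  overbin:::new_overlap_graph(lapply(adj, function(v)
    sort(unique(as.integer(v)))))
}
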