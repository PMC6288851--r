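#' Degree histogram of an overlap graph
#'
#' Exact integer counts of nodes per degree value. The degree of a read is a
#' proxy for the local abundance of its sequence, so reads of one genome at
#' one depth produce a roughly normal-shaped peak; conserved-region hubs sit
#' far to the right of the peak and chimera-suspect reads to its left. The
#' histogram is what the user inspects to choose degree thresholds.
#'
#' @param graph an `overlap_graph`.
#' @return a `degree_histogram`: data frame with integer columns `degree`
#'   and `count`, sorted by degree, with attribute `n_nodes`.
#' @export
degree_histogram <- function(graph) {
  stopifnot(inherits(graph, "overlap_graph"))
  if (graph$n_nodes == 0L) {
    h <- data.frame(degree = integer(0), count = integer(0))
  } else {
    tab <- table(graph$degree)
    h <- data.frame(degree = as.integer(names(tab)),
                    count = as.integer(tab))
    h <- h[order(h$degree), , drop = FALSE]
    rownames(h) <- NULL
  }
  attr(h, "n_nodes") <- graph$n_nodes
  class(h) <- c("degree_histogram", "data.frame")
  h
}

#' Write a degree histogram as TSV
#' @param hist a [degree_histogram()].
#' @param path output path; columns `degree<TAB>count`, raw integer counts.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  utils::write.table(as.data.frame(hist)[, c("degree", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a degree histogram, optionally split by truth label
#'
#' Base-graphics line plot of node counts per degree (the whole-metagenome
#' curve), with one overlay curve per truth label when `truth` is supplied --
#' the per-species view used to judge where one genome's normal-shaped peak
#' ends and conserved-region hubs begin.
#'
#' @param graph an `overlap_graph`.
#' @param readset the matching `read_set` (needed for `truth` overlays).
#' @param truth optional named character vector `read_id -> label`.
#' @param log_y log-scale the y axis (counts); default `TRUE`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of plotted counts (long format:
#'   `label`, `degree`, `count`).
#' @export
plot_degree_histogram <- function(graph, readset = NULL, truth = NULL,
                                  log_y = TRUE, ...) {
  stopifnot(inherits(graph, "overlap_graph"))
  h <- degree_histogram(graph)
  long <- data.frame(label = "all", degree = h$degree, count = h$count,
                     stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    stopifnot(inherits(readset, "read_set"))
    labels <- as.character(truth[readset$ids])
    for (lab in sort(unique(labels))) {
      tab <- table(graph$degree[labels == lab])
      long <- rbind(long, data.frame(label = lab,
                                     degree = as.integer(names(tab)),
                                     count = as.integer(tab),
                                     stringsAsFactors = FALSE))
    }
  }
  labs <- unique(long$label)
  cols <- stats::setNames(grDevices::hcl.colors(max(2L, length(labs)),
                                                "Dark 3")[seq_along(labs)],
                          labs)
  cols["all"] <- "black"
  graphics::plot(NA, xlim = range(long$degree), ylim = c(1, max(long$count)),
                 log = if (log_y) "y" else "", xlab = "degree (edges)",
                 ylab = "reads", ...)
  for (lab in labs) {
    d <- long[long$label == lab, ]
    graphics::lines(d$degree, pmax(d$count, 1L), col = cols[[lab]],
                    lwd = if (lab == "all") 2 else 1)
  }
  graphics::legend("topright", legend = labs, col = cols[labs], lwd = 1,
                   bty = "n", cex = 0.8)
  invisible(long)
}

#' Threshold configuration for degree filtering and bin reporting
#'
#' Inclusive degree band `[lower, upper]` applied once to the degrees of the
#' unfiltered graph (the ones the histogram shows), plus the minimum number
#' of reads a connected component must have to be reported as a bin.
#'
#' @param lower minimum retained degree (inclusive), default 0.
#' @param upper maximum retained degree (inclusive), default `Inf`.
#' @param min_bin_size smallest reported bin, default 2 (singletons are
#'   never reported as bins).
#' @return a `threshold_config`.
#' @export
threshold_config <- function(lower = 0, upper = Inf, min_bin_size = 2) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower < 0)
    stop("thresholds must be non-negative numbers")
  if (lower > upper) stop("lower threshold exceeds upper threshold")
  if (min_bin_size < 1) stop("min_bin_size must be >= 1")
  structure(list(lower = lower, upper = upper,
                 min_bin_size = as.integer(min_bin_size)),
            class = "threshold_config")
}

#' Remove hub and low-connectivity nodes by degree band
#'
#' Single-pass filter: nodes whose degree in the ORIGINAL graph falls outside
#' `[lower, upper]` are dropped with all incident edges; surviving nodes keep
#' only edges to surviving nodes. Degrees are not recomputed iteratively --
#' the band refers to the histogram the user inspected. High-degree nodes are
#' conserved-region suspects, low-degree nodes chimera suspects.
#'
#' @param graph an `overlap_graph`.
#' @param cfg a [threshold_config()] (its `lower`/`upper` are used).
#' @return a `filtered_graph`: list with the filtered `graph`, logical
#'   `retained`, and integer ordinal vectors `excluded_low`, `excluded_high`.
#' @export
filter_by_degree <- function(graph, cfg) {
  stopifnot(inherits(graph, "overlap_graph"),
            inherits(cfg, "threshold_config"))
  deg <- graph$degree
  retained <- deg >= cfg$lower & deg <= cfg$upper
  adj <- vector("list", graph$n_nodes)
  for (i in seq_len(graph$n_nodes)) {
    adj[[i]] <- if (retained[i]) {
      nb <- graph$adjacency[[i]]
      nb[retained[nb]]
    } else integer(0)
  }
  structure(list(graph = new_overlap_graph(adj),
                 retained = retained,
                 excluded_low = which(deg < cfg$lower),
                 excluded_high = which(deg > cfg$upper)),
            class = "filtered_graph")
}

# Breadth-first component labelling restricted to active nodes.
# Returns an integer vector: component id per node, 0 for inactive nodes.
bfs_components <- function(adjacency, active) {
  n <- length(adjacency)
  comp <- integer(n)
  queue <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!active[s] || comp[s] > 0L) next
    cid <- cid + 1L
    comp[s] <- cid
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nb <- adjacency[[v]]
      nb <- nb[active[nb] & comp[nb] == 0L]
      if (length(nb) > 0L) {
        comp[nb] <- cid
        queue[(tail + 1L):(tail + length(nb))] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  comp
}

#' Extract bins as connected components of the filtered graph
#'
#' Breadth-first traversal reports every connected component of the filtered
#' graph with at least `min_bin_size` reads as one bin; smaller components
#' (including singletons) go to `small_or_singleton`. Membership depends only
#' on graph connectivity, never on seed choice or traversal order. Bins are
#' sorted by size descending, ties broken by smallest member ordinal.
#'
#' @param fgraph a [filter_by_degree()] result (or a bare `overlap_graph`,
#'   meaning no degree exclusions).
#' @param cfg a [threshold_config()] (its `min_bin_size` is used).
#' @return a `bin_set`: `bins` (list of sorted ordinal vectors),
#'   `excluded_low`, `excluded_high`, `small_or_singleton`, `n_reads`.
#' @export
extract_bins <- function(fgraph, cfg = threshold_config()) {
  if (inherits(fgraph, "overlap_graph")) {
    fgraph <- structure(list(graph = fgraph,
                             retained = rep(TRUE, fgraph$n_nodes),
                             excluded_low = integer(0),
                             excluded_high = integer(0)),
                        class = "filtered_graph")
  }
  stopifnot(inherits(fgraph, "filtered_graph"),
            inherits(cfg, "threshold_config"))
  g <- fgraph$graph
  comp <- bfs_components(g$adjacency, fgraph$retained)
  members <- split(seq_len(g$n_nodes)[comp > 0L], comp[comp > 0L])
  sizes <- vapply(members, length, integer(1))
  keep <- sizes >= cfg$min_bin_size
  small <- sort(as.integer(unlist(members[!keep], use.names = FALSE)))
  bins <- members[keep]
  if (length(bins) > 0L) {
    first <- vapply(bins, min, integer(1))
    ord <- order(-vapply(bins, length, integer(1)), first)
    bins <- lapply(unname(bins[ord]), sort)
  } else {
    bins <- list()
  }
  structure(list(bins = bins,
                 excluded_low = fgraph$excluded_low,
                 excluded_high = fgraph$excluded_high,
                 small_or_singleton = small,
                 n_reads = g$n_nodes),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  sizes <- vapply(x$bins, length, integer(1))
  cat(sprintf(paste0("bin_set: %d bins over %d reads ",
                     "(excluded low/high: %d/%d, small/singleton: %d)\n"),
              length(x$bins), x$n_reads,
              length(x$excluded_low), length(x$excluded_high),
              length(x$small_or_singleton)))
  if (length(sizes) > 0L)
    cat("bin sizes:", paste(utils::head(sizes, 20L), collapse = ", "),
        if (length(sizes) > 20L) "..." else "", "\n")
  invisible(x)
}

#' Run the full binning pipeline
#'
#' Composition of the three stages: build the exact-overlap graph, compute
#' its degree histogram, drop nodes outside the degree band, and report the
#' connected components of what remains as bins. Deterministic end to end
#' for a fixed read order and parameters.
#'
#' @param readset a [read_set()].
#' @param params an [overlap_params()] (or a bare integer `b`).
#' @param cfg a [threshold_config()].
#' @return a `binning_result`: `bin_set`, `histogram`, `graph`, and a
#'   `report` list (node/edge totals, bin sizes, exclusion counts,
#'   parameters).
#' @export
run_binning <- function(readset, params, cfg = threshold_config()) {
  params <- as_overlap_params(params)
  graph <- build_graph(readset, params)
  hist <- degree_histogram(graph)
  fgraph <- filter_by_degree(graph, cfg)
  bins <- extract_bins(fgraph, cfg)
  report <- list(
    n_reads = graph$n_nodes,
    n_edges = n_edges(graph),
    n_bins = length(bins$bins),
    bin_sizes = vapply(bins$bins, length, integer(1)),
    n_excluded_low = length(bins$excluded_low),
    n_excluded_high = length(bins$excluded_high),
    n_small_or_singleton = length(bins$small_or_singleton),
    b = params$b,
    include_revcomp = params$include_revcomp,
    lower = cfg$lower, upper = cfg$upper,
    min_bin_size = cfg$min_bin_size
  )
  structure(list(bin_set = bins, histogram = hist, graph = graph,
                 report = report),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("binning_result: b = %d, band [%s, %s], min bin %d\n",
              r$b, format(r$lower), format(r$upper), r$min_bin_size))
  cat(sprintf("  %d reads, %d edges -> %d bins\n",
              r$n_reads, r$n_edges, r$n_bins))
  print(x$bin_set)
  invisible(x)
}

#' Run several degree bands independently
#'
#' Users sometimes want more than one degree band (for example one band
#' around a low-abundance peak and one around a high-abundance peak). Each
#' `[lower, upper]` band is run independently against the same graph and the
#' resulting bins are labelled by band.
#'
#' @param readset a [read_set()].
#' @param params an [overlap_params()] (or a bare integer `b`).
#' @param bands list of `c(lower, upper)` pairs.
#' @param min_bin_size smallest reported bin per band.
#' @return list of `binning_result`, one per band, names `"lower-upper"`.
#' @export
run_binning_bands <- function(readset, params, bands, min_bin_size = 2) {
  params <- as_overlap_params(params)
  graph <- build_graph(readset, params)
  hist <- degree_histogram(graph)
  out <- lapply(bands, function(band) {
    cfg <- threshold_config(band[1], band[2], min_bin_size)
    fgraph <- filter_by_degree(graph, cfg)
    bins <- extract_bins(fgraph, cfg)
    structure(list(bin_set = bins, histogram = hist, graph = graph,
                   report = list(n_reads = graph$n_nodes,
                                 n_edges = n_edges(graph),
                                 n_bins = length(bins$bins),
                                 bin_sizes = vapply(bins$bins, length,
                                                    integer(1)),
                                 n_excluded_low = length(bins$excluded_low),
                                 n_excluded_high = length(bins$excluded_high),
                                 n_small_or_singleton =
                                   length(bins$small_or_singleton),
                                 b = params$b,
                                 include_revcomp = params$include_revcomp,
                                 lower = cfg$lower, upper = cfg$upper,
                                 min_bin_size = cfg$min_bin_size)),
              class = "binning_result")
  })
  names(out) <- vapply(bands, function(band)
    paste0(format(band[1]), "-", format(band[2])), character(1))
  out
}
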