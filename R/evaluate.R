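#' Score bins against a ground-truth read labelling
#'
#' Exact integer contingency of each bin against the truth labels: per-bin
#' composition, purity (reads of the dominant label / bin size) and per-
#' genome recall. A bin's dominant label is its most frequent truth label
#' (ties broken lexicographically and flagged); a genome's recall is the
#' fraction of its reads recovered into bins dominated by it. Because reads
#' shorter than `b` can never be binned, recall is reported against the
#' >=`min_len` denominator, with the all-reads denominator alongside.
#' The `"chimera"` label participates like any genome.
#'
#' @param bins a `bin_set`.
#' @param readset the `read_set` the bin ordinals refer to.
#' @param truth named character vector `read_id -> label` (see
#'   [read_truth()]), covering every binned read.
#' @param min_len length cutoff used for the binnable-read denominator
#'   (normally the `b` the graph was built with; default 0 = all reads).
#' @return a `bin_scores` list: `scores` (one row per bin: `bin_id`
#'   starting at 0, `size`, `dominant`, `purity`, `tie`, one count column
#'   per label) and `recall` (one row per label: `total_reads`,
#'   `total_reads_minlen`, `binned_in_dominant_bins`, `recall`,
#'   `recall_all`).
#' @export
score_bins <- function(bins, readset, truth, min_len = 0) {
  stopifnot(inherits(bins, "bin_set"), inherits(readset, "read_set"))
  if (is.data.frame(truth))
    truth <- stats::setNames(as.character(truth[[2L]]),
                             as.character(truth[[1L]]))
  binned_ids <- readset$ids[unlist(bins$bins, use.names = FALSE)]
  missing <- setdiff(binned_ids, names(truth))
  if (length(missing) > 0L)
    stop("read id(s) missing from truth table: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  labels <- sort(unique(as.character(truth)))
  scores <- data.frame(bin_id = integer(0), size = integer(0),
                       dominant = character(0), purity = numeric(0),
                       tie = logical(0), stringsAsFactors = FALSE)
  for (lab in labels) scores[[lab]] <- integer(0)
  for (k in seq_along(bins$bins)) {
    ids <- readset$ids[bins$bins[[k]]]
    comp <- table(factor(truth[ids], levels = labels))
    top <- max(comp)
    dominant <- names(comp)[comp == top][1L]
    row <- data.frame(bin_id = k - 1L, size = length(ids),
                      dominant = dominant, purity = top / length(ids),
                      tie = sum(comp == top) > 1L, stringsAsFactors = FALSE)
    for (lab in labels) row[[lab]] <- as.integer(comp[[lab]])
    scores <- rbind(scores, row)
  }
  in_set <- readset$ids %in% names(truth)
  lens <- stats::setNames(read_lengths(readset), readset$ids)
  recall <- do.call(rbind, lapply(labels, function(lab) {
    lab_ids <- names(truth)[truth == lab]
    total <- length(lab_ids)
    long_ids <- lab_ids[lab_ids %in% names(lens) & lens[lab_ids] >= min_len]
    total_long <- length(long_ids)
    dom_bins <- which(scores$dominant == lab & !scores$tie)
    got <- if (length(dom_bins) > 0L)
      sum(vapply(dom_bins, function(kk) {
        ids <- readset$ids[bins$bins[[kk]]]
        sum(truth[ids] == lab)
      }, numeric(1)))
    else 0L
    data.frame(genome = lab, total_reads = total,
               total_reads_minlen = total_long,
               binned_in_dominant_bins = as.integer(got),
               recall = if (total_long > 0L) got / total_long else NA_real_,
               recall_all = if (total > 0L) got / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(recall) <- NULL
  structure(list(scores = scores, recall = recall, min_len = min_len),
            class = "bin_scores")
}

#' @export
print.bin_scores <- function(x, ...) {
  cat("Per-bin composition (counts per truth label):\n")
  print(x$scores, row.names = FALSE)
  cat(sprintf("\nPer-genome recall (denominator: reads >= %d bp):\n",
              x$min_len))
  print(x$recall, row.names = FALSE)
  invisible(x)
}

#' Write bin scores as TSV reports
#'
#' Writes `scores.tsv` (one row per bin, stable column order: bin_id, size,
#' dominant, purity, tie, then one count column per label) and `recall.tsv`
#' (one row per genome).
#'
#' @param scores a [score_bins()] result.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the two paths.
#' @export
render_report <- function(scores, out_dir) {
  stopifnot(inherits(scores, "bin_scores"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create ", out_dir)
  sp <- file.path(out_dir, "scores.tsv")
  rp <- file.path(out_dir, "recall.tsv")
  utils::write.table(scores$scores, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scores$recall, rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(scores = sp, recall = rp)
}
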