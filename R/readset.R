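#' @useDynLib overbin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a read set
#'
#' A `read_set` is the universe of overlap-graph nodes: an ordered collection
#' of uniquely named DNA reads. Iteration order is the file order and is the
#' determinism anchor for everything downstream; read i of the set is node i
#' (1-based) of the graph.
#'
#' @param ids character vector of unique read identifiers.
#' @param seqs character vector of sequences over \{A,C,G,T,N\} (uppercased
#'   on construction).
#' @return An object of class `read_set` with elements `ids` and `seqs`.
#' @export
read_set <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate read id(s): ", paste(utils::head(dup, 10L), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence at record ", which(!nzchar(seqs))[1L])
  seqs <- normalize_alphabet(seqs)
  structure(list(ids = ids, seqs = seqs), class = "read_set")
}

# Map IUPAC ambiguity codes to N (with a warning); reject anything else
# outside {A,C,G,T,N} so the index alphabet is predictable.
normalize_alphabet <- function(seqs) {
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(letters_used, c("A", "C", "G", "T", "N"))
  if (length(bad) == 0L) return(seqs)
  ambig <- intersect(bad, IUPAC_AMBIG)
  other <- setdiff(bad, IUPAC_AMBIG)
  if (length(other) > 0L)
    stop("invalid sequence character(s): ", paste(other, collapse = ", "))
  warning("IUPAC ambiguity code(s) ", paste(ambig, collapse = ", "),
          " mapped to N")
  chartr(paste(ambig, collapse = ""),
         strrep("N", length(ambig)), seqs)
}

#' @export
length.read_set <- function(x) length(x$ids)

#' @export
print.read_set <- function(x, ...) {
  n <- length(x)
  len <- read_lengths(x)
  cat(sprintf("read_set with %d reads (length %d-%d, mean %.1f)\n",
              n, if (n) min(len) else 0L, if (n) max(len) else 0L,
              if (n) mean(len) else 0))
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$ids[i], x$seqs[i])
}

#' Read lengths of a read set
#' @param readset a `read_set`.
#' @return integer vector of read lengths, in file order.
#' @export
read_lengths <- function(readset) nchar(readset$seqs)

#' Load reads from FASTA or FASTQ
#'
#' Parses a (multi-line) FASTA or 4-line FASTQ file into a [read_set()].
#' FASTQ qualities are discarded: quality control is assumed to have happened
#' upstream, before binning. Read ids are the header token up to the first
#' whitespace; sequences are uppercased and soft-masked (lowercase) bases are
#' treated as their uppercase equivalents.
#'
#' @param path input file.
#' @param format `"auto"` (default; sniffed from the first non-empty byte,
#'   falling back to the extension), `"fasta"` or `"fastq"`.
#' @return a `read_set` in file order.
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", format, " file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(x) == 0L) stop("no sequence records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, as.character(x))
}

sniff_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  first <- ""
  while (!nzchar(first)) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("no sequence records in ", path)
    first <- trimws(line)
  }
  ch <- substr(first, 1L, 1L)
  if (ch == ">") return("fasta")
  if (ch == "@") return("fastq")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("fq", "fastq")) return("fastq")
  if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
  stop("cannot determine sequence format of ", path)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorized.
#'
#' @param sequence character vector over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("non-ACGTN character in sequence ", which(bad)[1L])
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Write bins to per-bin FASTA files
#'
#' Writes one 80-column multi-FASTA per bin, numbered `bin0, bin1, ...` in
#' descending size order (bin 0 is the largest), preserving the original read
#' ids and sequences verbatim, plus a TSV manifest
#' (`bin_id`, `n_reads`, `file`).
#'
#' @param bins a [bin_set] (or plain list of 1-based ordinal vectors).
#' @param readset the `read_set` the ordinals refer to.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix, default `"bins"`.
#' @return character vector of FASTA paths, in bin order (invisibly the
#'   manifest path is attached as attribute `manifest`).
#' @export
write_bins <- function(bins, readset, out_dir, prefix = "bins") {
  members <- if (inherits(bins, "bin_set")) bins$bins else bins
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  n <- length(readset)
  paths <- character(length(members))
  for (k in seq_along(members)) {
    idx <- members[[k]]
    if (any(idx < 1L | idx > n)) stop("bin ", k, " has out-of-range ordinals")
    path <- file.path(out_dir, sprintf("%s_bin%d.fasta", prefix, k - 1L))
    dss <- Biostrings::DNAStringSet(readset$seqs[idx])
    names(dss) <- readset$ids[idx]
    Biostrings::writeXStringSet(dss, path, width = 80L)
    paths[k] <- path
  }
  manifest <- data.frame(
    bin_id = seq_along(members) - 1L,
    n_reads = vapply(members, length, integer(1)),
    file = basename(paths),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, sprintf("%s_manifest.tsv", prefix))
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(paths, "manifest") <- manifest_path
  paths
}
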