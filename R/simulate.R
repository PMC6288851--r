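# Run code under a private RNG state: set.seed(seed) if given, and restore
# the caller's .Random.seed afterwards so simulation never perturbs it.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

#' Genome specification for the synthetic metagenome generator
#'
#' @param name genome label (becomes the truth label of its reads).
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param depth target fold-coverage (total simulated bases / genome length).
#' @return a `genome_spec`.
#' @export
genome_spec <- function(name, length, gc = 0.5, depth = 10) {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (depth <= 0) stop("depth must be positive")
  structure(list(name = as.character(name), length = length,
                 gc = gc, depth = depth),
            class = "genome_spec")
}

#' Simulate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; optional conserved inserts are
#' spliced in verbatim, overwriting the window starting at each offset, so
#' the genome length equals `length`. Reproducible for a fixed seed.
#'
#' @param length genome length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @param insert optional DNA string spliced at `insert_at`.
#' @param insert_at 1-based offset(s); `insert` is written at each.
#' @return a DNA string of length `length`.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL,
                            insert = NULL, insert_at = NULL) {
  length <- as.integer(length)
  g <- with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  if (!is.null(insert)) {
    insert <- toupper(insert)
    li <- nchar(insert)
    if (li > length) stop("insert longer than genome")
    for (off in insert_at) {
      if (off < 1L || off + li - 1L > length)
        stop("insert at offset ", off, " does not fit in the genome")
      substr(g, off, off + li - 1L) <- insert
    }
  }
  g
}

#' Simulate shotgun reads from one genome
#'
#' Read count is `round(depth * genome_length / mean_length)`; start
#' positions are uniform, strands uniform, lengths normal truncated to
#' `[min_len, genome length]`, substitution errors i.i.d. per base at
#' `error_rate` (no indels: substitutions are the only error mechanism an
#' exact-match graph can see). Every read's origin is recorded as truth.
#'
#' @param genome DNA string.
#' @param depth target fold-coverage.
#' @param read_len `c(mean, sd)` of read length in bp.
#' @param error_rate substitution probability per base.
#' @param seed integer seed (or `NULL`).
#' @param label truth label, used as read-id prefix.
#' @param min_len lower truncation of read length (default 30).
#' @return a `simulated_reads` data frame: `read_id`, `sequence`, `truth`,
#'   `start`, `strand`, `length`.
#' @export
simulate_reads <- function(genome, depth, read_len = c(300, 25),
                           error_rate = 0, seed = NULL, label = "genome",
                           min_len = 30) {
  glen <- nchar(genome)
  if (depth <= 0) stop("depth must be positive")
  if (read_len[1] < 1) stop("mean read length must be >= 1")
  if (read_len[1] > glen) stop("mean read length exceeds genome length")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  n <- max(1L, as.integer(round(depth * glen / read_len[1])))
  with_seed(seed, {
    len <- as.integer(round(stats::rnorm(n, read_len[1], read_len[2])))
    len <- pmin(pmax(len, as.integer(min_len)), glen)
    start <- as.integer(floor(stats::runif(n, 1, glen - len + 1 + 1)))
    start <- pmin(start, glen - len + 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome, start, start + len - 1L)
    rc <- strand == "-"
    if (any(rc)) seqs[rc] <- reverse_complement(seqs[rc])
    if (error_rate > 0) {
      nmut <- stats::rbinom(n, len, error_rate)
      for (i in which(nmut > 0L)) {
        pos <- sample.int(len[i], nmut[i])
        s <- strsplit(seqs[i], "")[[1L]]
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    data.frame(read_id = sprintf("%s_r%d", label, seq_len(n)),
               sequence = seqs, truth = label,
               start = start, strand = strand, length = len,
               stringsAsFactors = FALSE)
  })
}

#' Create chimeric reads from a pool of simulated reads
#'
#' Each chimera joins the first half of one read to the second half of a
#' read from a DIFFERENT truth genome -- the library artifact that produces
#' atypically connected nodes. Chimeras are additional reads (donors are
#' kept) labelled `"chimera"`, with both origins recorded.
#'
#' @param reads a `simulated_reads` data frame from >= 2 genomes.
#' @param fraction chimeras to create, as a fraction of `nrow(reads)`,
#'   in `[0, 1)`.
#' @param seed integer seed (or `NULL`).
#' @return a `simulated_reads` data frame of chimeras (possibly 0 rows) with
#'   extra columns `origin1`, `origin2`.
#' @export
make_chimeras <- function(reads, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  genomes <- unique(reads$truth)
  if (length(genomes) < 2L) stop("chimeras need reads from >= 2 genomes")
  k <- as.integer(round(fraction * nrow(reads)))
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      truth = character(0), start = integer(0),
                      strand = character(0), length = integer(0),
                      origin1 = character(0), origin2 = character(0),
                      stringsAsFactors = FALSE)
  if (k == 0L) return(empty)
  with_seed(seed, {
    i <- sample.int(nrow(reads), k, replace = TRUE)
    j <- vapply(i, function(a) {
      cand <- which(reads$truth != reads$truth[a])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    half1 <- substr(reads$sequence[i], 1L, nchar(reads$sequence[i]) %/% 2L)
    half2 <- substr(reads$sequence[j],
                    nchar(reads$sequence[j]) %/% 2L + 1L,
                    nchar(reads$sequence[j]))
    seqs <- paste0(half1, half2)
    data.frame(read_id = sprintf("chimera_r%d", seq_len(k)),
               sequence = seqs, truth = "chimera",
               start = NA_integer_, strand = "+",
               length = nchar(seqs),
               origin1 = reads$read_id[i], origin2 = reads$read_id[j],
               stringsAsFactors = FALSE)
  })
}

#' Build a ground-truth-labelled benchmark metagenome
#'
#' Simulates one genome per [genome_spec()], optionally splices a shared
#' conserved region into designated carriers, draws reads at each genome's
#' depth, optionally adds chimeras, shuffles everything, and (when
#' `out_dir` is given) writes `reads.fasta`, `truth.tsv` (two columns:
#' `read_id<TAB>genome`) and `spec.json` (the full parameter record,
#' including the seed). Fixed seed gives byte-identical outputs.
#'
#' The shared region emulates a multi-copy conserved element (an rRNA-
#' operon-like repeat): by default it is spliced as `shared_copies` tandem
#' copies ending at the tail of each carrier genome, which makes every read
#' carrying >= b conserved bases a pronounced hub (its windows occur at
#' `shared_copies * n_carriers` sites) while hub removal cuts nothing out
#' of the single-copy flank.
#'
#' @param specs list of [genome_spec()].
#' @param shared_len length of the shared conserved region in bp
#'   (0 = none; default 0). The region itself is simulated at GC 0.5.
#' @param shared_carriers names of carrier genomes (default: all).
#' @param shared_copies tandem copies per carrier (default 4).
#' @param chimera_fraction chimeras as a fraction of total reads.
#' @param error_rate substitution probability per base.
#' @param read_len `c(mean, sd)` read length in bp.
#' @param min_read_len lower read-length truncation.
#' @param seed integer seed controlling everything.
#' @param out_dir optional output directory.
#' @return list: `reads` (a [read_set()], shuffled), `truth` (named
#'   character vector `read_id -> label`), `genomes` (named list of DNA
#'   strings), `shared` (the region or `NULL`), `tables` (per-read metadata),
#'   `files` (paths, or `NULL`).
#' @export
build_benchmark <- function(specs, shared_len = 0, shared_carriers = NULL,
                            shared_copies = 4, chimera_fraction = 0,
                            error_rate = 0, read_len = c(300, 25),
                            min_read_len = 70, seed = 1, out_dir = NULL) {
  if (length(specs) < 1L) stop("need at least one genome_spec")
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (is.null(shared_carriers)) shared_carriers <- names(specs)
  with_seed(seed, {
    shared <- NULL
    if (shared_len > 0) {
      shared <- simulate_genome(max(1000L, shared_len), gc = 0.5)
      shared <- substr(shared, 1L, shared_len)
    }
    genomes <- lapply(specs, function(sp) {
      g <- simulate_genome(sp$length, gc = sp$gc)
      if (!is.null(shared) && sp$name %in% shared_carriers) {
        block <- strrep(shared, shared_copies)
        if (nchar(block) > sp$length)
          stop("shared region copies do not fit in genome ", sp$name)
        substr(g, sp$length - nchar(block) + 1L, sp$length) <- block
      }
      g
    })
    tables <- lapply(specs, function(sp) {
      simulate_reads(genomes[[sp$name]], depth = sp$depth,
                     read_len = read_len, error_rate = error_rate,
                     label = sp$name, min_len = min_read_len)
    })
    all <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
    if (chimera_fraction > 0) {
      ch <- make_chimeras(all, chimera_fraction)
      all <- rbind(cbind(all, origin1 = NA_character_,
                         origin2 = NA_character_), ch)
    }
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    rownames(all) <- NULL
    reads <- read_set(all$read_id, all$sequence)
    truth <- stats::setNames(all$truth, all$read_id)
    files <- NULL
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
        stop("cannot create ", out_dir)
      fasta <- file.path(out_dir, "reads.fasta")
      dss <- Biostrings::DNAStringSet(reads$seqs)
      names(dss) <- reads$ids
      Biostrings::writeXStringSet(dss, fasta, width = 80L)
      truth_path <- file.path(out_dir, "truth.tsv")
      utils::write.table(data.frame(read_id = names(truth), genome = truth),
                         truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      spec_path <- file.path(out_dir, "spec.json")
      rec <- list(genomes = lapply(specs, unclass),
                  shared_len = shared_len, shared_carriers = shared_carriers,
                  shared_copies = shared_copies,
                  chimera_fraction = chimera_fraction,
                  error_rate = error_rate, read_len = read_len,
                  min_read_len = min_read_len, seed = seed)
      jsonlite::write_json(rec, spec_path, auto_unbox = TRUE, pretty = TRUE)
      files <- list(fasta = fasta, truth = truth_path, spec = spec_path)
    }
    list(reads = reads, truth = truth, genomes = genomes, shared = shared,
         tables = all, files = files)
  })
}

#' Read a truth table (read_id -> genome label) from TSV
#' @param path two-column TSV with header `read_id<TAB>genome`.
#' @return named character vector `read_id -> label`.
#' @export
read_truth <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("truth table needs two columns: read_id, genome")
  stats::setNames(as.character(d[[2L]]), as.character(d[[1L]]))
}
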