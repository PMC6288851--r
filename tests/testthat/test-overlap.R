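test_that("identical and repeated reads form complete graphs", {
  seqs <- rep(strrep("ACGGTTCAAG", 10), 5) # one 100-mer repeated 5x
  rs <- read_set(sprintf("r%d", 1:5), seqs)
  g <- build_graph(rs, overlap_params(70))
  expect_identical(g$n_nodes, 5L)
  expect_true(all(g$degree == 4L)) # K5: duplicates stay distinct nodes
  for (i in 1:5) expect_identical(g$adjacency[[i]], setdiff(1:5, i))
})

test_that("two identical reads and a revcomp pair are neighbors; self never is", {
  rs <- read_set(c("a", "b"), c(strrep("A", 100), strrep("T", 100)))
  g <- build_graph(rs, overlap_params(70))
  expect_identical(g$adjacency[[1]], 2L) # matches only via revcomp
  g2 <- build_graph(rs, overlap_params(b = 70, include_revcomp = FALSE))
  expect_identical(n_edges(g2), 0L)
  # palindromic self-hit must not create a self-edge or an edge
  pal <- read_set("p", paste0(strrep("G", 20), "ACGT",
                              reverse_complement(strrep("G", 20))))
  gp <- build_graph(pal, overlap_params(10))
  expect_identical(gp$adjacency[[1]], integer(0))
})

test_that("reads shorter than b are isolated; oversized b warns of empty graph", {
  set.seed(3)
  genome <- random_genome(2000)
  rs <- reads_from_genome(genome, 30, len_range = c(40, 60))
  g <- suppressWarnings(build_graph(rs, overlap_params(70)))
  expect_true(all(g$degree == 0L))
  expect_warning(build_graph(rs, overlap_params(70)), "no edges")
  ix <- suppressWarnings(build_index(rs, overlap_params(70)))
  expect_identical(find_neighbors(ix, 1), integer(0))
})

test_that("N acts as a match breaker", {
  core <- strrep("ACGTTGCA", 10) # 80 bases shared
  a <- read_set(c("x", "y"), c(core, core))
  expect_identical(n_edges(build_graph(a, overlap_params(70))), 1L)
  broken <- core
  substr(broken, 40, 40) <- "N" # leaves runs of 39 and 40 clean bases
  b <- read_set(c("x", "y"), c(core, broken))
  expect_identical(n_edges(build_graph(b, overlap_params(70))), 0L)
  # and N never matches N
  nn <- read_set(c("x", "y"), rep(strrep("N", 100), 2))
  expect_identical(n_edges(build_graph(nn, overlap_params(10))), 0L)
})

test_that("matches never span read boundaries", {
  # concatenating r1+r2 would contain CCCCGGGG, but no single read does
  rs <- read_set(c("r1", "r2", "r3"),
                 c("AAAATTTTCCCC", "GGGGAAAATTTT", "TTTTAAAACCCC"))
  ix <- build_index(rs, overlap_params(4))
  expect_identical(locate_reads(ix, "CCCCGGGG"), integer(0))
  # exhaustive: every 6-mer the index locates is found by per-read scanning
  for (i in 1:3) {
    s <- rs$seqs[i]
    for (p in windows_of(s, 6)) {
      naive <- which(vapply(rs$seqs, function(x) {
        grepl(p, x, fixed = TRUE) ||
          grepl(reverse_complement(p), x, fixed = TRUE)
      }, logical(1)))
      expect_identical(locate_reads(ix, p), as.integer(naive))
    }
  }
})

test_that("find_neighbors agrees with build_graph adjacency", {
  set.seed(7)
  genome <- random_genome(3000)
  rs <- reads_from_genome(genome, 60, len_range = c(60, 140))
  params <- overlap_params(30)
  g <- build_graph(rs, params)
  ix <- build_index(rs, params)
  for (i in seq_len(length(rs)))
    expect_identical(find_neighbors(ix, i), g$adjacency[[i]])
  expect_error(find_neighbors(ix, 0), "out of range")
  expect_error(find_neighbors(ix, 61), "out of range")
})

test_that("edge sets equal the brute-force oracle on overlapping read sets", {
  set.seed(13)
  for (rep in 1:6) {
    b <- sample(c(15, 25, 40), 1)
    genome <- random_genome(sample(1500:4000, 1))
    rs <- reads_from_genome(genome, sample(30:70, 1),
                            len_range = c(30, 200))
    g <- build_graph(rs, overlap_params(b))
    expect_identical(g$adjacency, oracle_adjacency(rs$seqs, b))
  }
  # reads salted with N: oracle skips N windows exactly like the index
  rs <- reads_from_genome(random_genome(2000), 40, len_range = c(60, 120))
  seqs <- rs$seqs
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    s[sample.int(length(s), 2)] <- "N"
    seqs[i] <- paste(s, collapse = "")
  }
  rsn <- read_set(rs$ids, seqs)
  g <- build_graph(rsn, overlap_params(25))
  expect_identical(g$adjacency, oracle_adjacency(rsn$seqs, 25))
})

test_that("edges agree with a longest-common-substring dynamic program", {
  set.seed(17)
  genome <- random_genome(600)
  rs <- reads_from_genome(genome, 12, len_range = c(40, 80))
  b <- 12
  g <- build_graph(rs, overlap_params(b))
  for (i in 1:11) {
    for (j in (i + 1):12) {
      shared <- max(lcs_length(rs$seqs[i], rs$seqs[j]),
                    lcs_length(rs$seqs[i], reverse_complement(rs$seqs[j])))
      expect_identical(j %in% g$adjacency[[i]], shared >= b,
                       label = sprintf("pair %d-%d (lcs %d)", i, j, shared))
    }
  }
})

test_that("edge set shrinks monotonically in b and is revcomp-closed", {
  set.seed(19)
  genome <- random_genome(2500)
  rs <- reads_from_genome(genome, 50, len_range = c(50, 150))
  edge_set <- function(g) {
    do.call(rbind, lapply(seq_len(g$n_nodes), function(i) {
      nb <- g$adjacency[[i]]
      nb <- nb[nb > i]
      if (length(nb)) cbind(i, nb) else NULL
    }))
  }
  gs <- lapply(c(20, 35, 60), function(b) build_graph(rs, overlap_params(b)))
  e <- lapply(gs, function(g) {
    m <- edge_set(g)
    if (is.null(m)) character(0) else paste(m[, 1], m[, 2])
  })
  expect_true(all(e[[2]] %in% e[[1]]))
  expect_true(all(e[[3]] %in% e[[2]]))
  # flipping any read to its reverse complement leaves the edge set unchanged
  flipped <- rs$seqs
  k <- sample.int(length(flipped), 10)
  flipped[k] <- reverse_complement(flipped[k])
  gf <- build_graph(read_set(rs$ids, flipped), overlap_params(35))
  expect_identical(gf$adjacency, gs[[2]]$adjacency)
})

test_that("locate_reads finds planted patterns in both orientations", {
  set.seed(23)
  pat <- random_genome(30)
  host1 <- paste0(random_genome(50), pat, random_genome(50))
  host2 <- paste0(random_genome(40), reverse_complement(pat),
                  random_genome(60))
  decoy <- random_genome(130)
  rs <- read_set(c("h1", "h2", "d"), c(host1, host2, decoy))
  ix <- build_index(rs, overlap_params(20))
  expect_identical(locate_reads(ix, pat), c(1L, 2L))
  expect_error(locate_reads(ix, "ACGT"), "shorter than")
  ix_f <- build_index(rs, overlap_params(b = 20, include_revcomp = FALSE))
  expect_identical(locate_reads(ix_f, pat), 1L)
})

test_that("empty read sets and adjacency export behave", {
  g0 <- build_graph(read_set(character(0), character(0)), overlap_params(10))
  expect_identical(g0$n_nodes, 0L)
  set.seed(29)
  rs <- reads_from_genome(random_genome(1200), 15, len_range = c(60, 90))
  g <- build_graph(rs, overlap_params(30))
  path <- withr::local_tempfile(fileext = ".txt")
  export_adjacency(g, path)
  lines <- readLines(path)
  expect_length(lines, 15L)
  parsed <- strsplit(lines, "\t")
  for (i in seq_along(parsed)) {
    expect_identical(parsed[[i]][1], as.character(i))
    nb <- if (length(parsed[[i]]) > 1 && nzchar(parsed[[i]][2]))
      as.integer(strsplit(parsed[[i]][2], ",")[[1]]) else integer(0)
    expect_identical(nb, g$adjacency[[i]])
  }
})
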