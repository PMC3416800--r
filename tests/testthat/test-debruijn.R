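test_that("graph construction matches the kmer/node definition", {
  g <- build_graph("ACGTG", 5)
  expect_equal(g$k, 5L)
  expect_identical(names(g$edges), "ACGTG")
  expect_equal(unname(g$edges[["ACGTG"]]), 1L)
  expect_setequal(graph_nodes(g), c("ACGT", "CACG"))  # CACG = canon of CGTG
  expect_true(all(nchar(graph_nodes(g)) == 4L))
})

test_that("parameter and input errors are reported", {
  expect_error(build_graph(character(), 5), "empty input")
  expect_error(build_graph("ACGT", 5), "exceeds")
  expect_error(build_graph("ACGTACGT", 6), "odd")
  expect_error(build_graph("ACGTACGT", 3), "at least 5")
})

test_that("edge coverage is conserved and N-containing kmers are skipped", {
  seqs <- vapply(1:20, function(i) rand_dna(60, i), "")
  k <- 15L
  g <- build_graph(seqs, k)
  expect_equal(sum(g$edges), sum(nchar(seqs) - k + 1L))
  # an N voids exactly the kmers that cover it
  s <- rand_dna(60, 99)
  sN <- paste0(substr(s, 1, 29), "N", substr(s, 31, 60))
  gN <- build_graph(sN, k)
  expect_equal(sum(gN$edges), (60L - k + 1L) - k)
})

test_that("the canonical graph is reverse-complement invariant", {
  seqs <- vapply(1:10, function(i) rand_dna(80, i), "")
  g1 <- build_graph(seqs, 21)
  g2 <- build_graph(revcomp(seqs), 21)
  expect_identical(g1$edges, g2$edges)
})

test_that("simplification clips short spurs hanging off a covered path", {
  s <- rand_dna(60, 5)
  spur <- paste0(substr(s, 1, 20), "A")
  if (substr(s, 21, 21) == "A") spur <- paste0(substr(s, 1, 20), "C")
  g <- build_graph(c(rep(s, 5), spur), 15)
  gs <- simplify_graph(g, simplify_params(min_edge_coverage = 1))
  ct <- extract_contigs(gs)
  expect_equal(nrow(ct), 1L)
  expect_identical(ct$sequence, min(s, revcomp(s)))
})

test_that("bubble merging keeps the higher-coverage branch", {
  s <- rand_dna(100, 6)
  chars <- strsplit(s, "")[[1]]
  chars[50] <- setdiff(c("A", "C", "G", "T"), chars[50])[1]
  variant <- paste(chars, collapse = "")
  g <- build_graph(c(rep(s, 10), variant), 15)
  gs <- simplify_graph(g, simplify_params(min_edge_coverage = 1))
  ct <- extract_contigs(gs)
  expect_equal(nrow(ct), 1L)
  expect_identical(ct$sequence, min(s, revcomp(s)))  # consensus = majority
})

test_that("low-coverage edges are removed at the configured floor", {
  s1 <- rand_dna(40, 7)
  s2 <- rand_dna(40, 8)
  g <- build_graph(c(rep(s1, 3), s2), 21)
  gs <- simplify_graph(g, simplify_params(min_edge_coverage = 2))
  expect_true(all(gs$edges >= 2))
  ct <- extract_contigs(gs)
  expect_equal(nrow(ct), 1L)  # only the covered genome survives
})

test_that("simplify is idempotent and passes empty graphs through", {
  reads <- tile_reads(rand_dna(1500, 11), circular = FALSE, coverage = 10,
                      seed = 11)
  g <- build_graph(reads, 21)
  g1 <- simplify_graph(g)
  g2 <- simplify_graph(g1)
  expect_identical(g1$edges, g2$edges)
  empty <- structure(list(k = 21L, edges = stats::setNames(integer(), character())),
                     class = "DeBruijnGraph")
  expect_equal(length(simplify_graph(empty)$edges), 0L)
})

test_that("a clean circular genome assembles to one closed contig", {
  genome <- withr::with_seed(21, virocycle:::random_genome(2500))
  reads <- tile_reads(genome, circular = TRUE, coverage = 20, seed = 21)
  ct <- extract_contigs(simplify_graph(build_graph(reads, 31)))
  expect_equal(nrow(ct), 1L)
  expect_true(ct$is_circular)
  expect_equal(nchar(ct$sequence), nchar(genome))
  # identical to the genome up to rotation and reverse complement
  expect_identical(normalize_circular(ct$sequence),
                   normalize_circular(genome))
})

test_that("the same genome made linear yields one linear contig", {
  genome <- withr::with_seed(22, virocycle:::random_genome(2500))
  reads <- tile_reads(genome, circular = FALSE, coverage = 20, seed = 22)
  ct <- extract_contigs(simplify_graph(build_graph(reads, 31)))
  expect_equal(nrow(ct), 1L)
  expect_false(ct$is_circular)
  # interior recovered; at most the terminal low-coverage fringe may be lost
  expect_gte(nchar(ct$sequence), nchar(genome) - 200L)
  expect_true(grepl(ct$sequence, paste0(genome, "|", revcomp(genome)),
                    fixed = TRUE) ||
                grepl(ct$sequence, genome, fixed = TRUE) ||
                grepl(ct$sequence, revcomp(genome), fixed = TRUE))
})

test_that("two unrelated genomes assemble to two contigs", {
  g1 <- withr::with_seed(23, virocycle:::random_genome(2000))
  g2 <- withr::with_seed(24, virocycle:::random_genome(2000))
  reads <- rbind(tile_reads(g1, FALSE, 20, 23), tile_reads(g2, FALSE, 20, 24))
  reads$read_id <- sprintf("p%04d", seq_len(nrow(reads)))
  class(reads) <- c("ReadSet", "data.frame")
  ct <- extract_contigs(simplify_graph(build_graph(reads, 31)))
  expect_equal(nrow(ct), 2L)
})

test_that("polymorphic sites form isolated bubbles only below the spacing", {
  haps <- snp_haplotypes()
  g23 <- build_graph(haps, 23)
  expect_equal(count_bubbles(g23), 3L)
  # at k = 27 the 26-base nodes span adjacent sites: no 3 simple bubbles
  g27 <- build_graph(haps, 27)
  expect_false(count_bubbles(g27) == 3L)
  # no polymorphism, no bubbles
  expect_equal(count_bubbles(build_graph(haps[1], 23)), 0L)
})

test_that("a short shared segment joins genomes only at small k", {
  pair <- shared_segment_pair()
  expect_equal(connected_components(build_graph(pair, 23)), 1L)
  expect_equal(connected_components(build_graph(pair, 27)), 2L)
  empty <- structure(list(k = 23L, edges = stats::setNames(integer(), character())),
                     class = "DeBruijnGraph")
  expect_equal(connected_components(empty), 0L)
})

test_that("repeat-free single genomes are recovered whole across kmers", {
  genome <- withr::with_seed(31, virocycle:::random_genome(1500))
  for (k in c(19L, 31L, 63L)) {
    reads <- tile_reads(genome, circular = TRUE, coverage = 30, seed = 31L + k)
    ct <- extract_contigs(simplify_graph(build_graph(reads, k)))
    expect_equal(nrow(ct), 1L)
    expect_identical(normalize_circular(ct$sequence),
                     normalize_circular(genome))
  }
})
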