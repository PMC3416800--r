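simple_contigs <- function(seqs, circular = FALSE, k = 21L) {
  data.frame(contig_id = sprintf("ctg%02d", seq_along(seqs)),
             sequence = seqs, is_circular = rep_len(circular, length(seqs)),
             kmer_used = k, read_support = NA_integer_,
             iteration = NA_integer_, mean_coverage = 1,
             stringsAsFactors = FALSE)
}

test_that("reads map by identity with strand and threshold semantics", {
  ctg <- simple_contigs(rand_dna(1000, 51))
  sub <- substr(ctg$sequence, 101, 200)
  m <- map_reads(c(r1 = sub), ctg, map_params(seed_length = 21))
  expect_equal(nrow(m), 1L)
  expect_equal(m$identity, 1.0)
  # 10 mismatches in 100 bp: identity 0.90 < 0.95 floor
  chars <- strsplit(sub, "")[[1]]
  pos <- seq(5, 95, by = 10)
  chars[pos] <- vapply(chars[pos],
                       function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  noisy <- paste(chars, collapse = "")
  m2 <- map_reads(c(r1 = noisy), ctg, map_params(seed_length = 21))
  expect_equal(nrow(m2), 0L)
  # reverse complement maps only when allowed
  m3 <- map_reads(c(r1 = revcomp(sub)), ctg, map_params(seed_length = 21))
  expect_equal(nrow(m3), 1L)
  m4 <- map_reads(c(r1 = revcomp(sub)), ctg,
                  map_params(seed_length = 21, allow_rc = FALSE))
  expect_equal(nrow(m4), 0L)
})

test_that("circular contigs recruit reads across the junction", {
  genome <- withr::with_seed(52, virocycle:::random_genome(1000))
  ctg <- simple_contigs(genome, circular = TRUE)
  junction_read <- paste0(substr(genome, 951, 1000), substr(genome, 1, 50))
  m <- map_reads(c(r1 = junction_read), ctg, map_params(seed_length = 21))
  expect_equal(nrow(m), 1L)
  expect_equal(m$identity, 1.0)
  # the same contig declared linear does not recruit it
  ctg$is_circular <- FALSE
  m2 <- map_reads(c(r1 = junction_read), ctg, map_params(seed_length = 21))
  expect_equal(nrow(m2), 0L)
})

test_that("pair subtraction removes a pair when either mate maps", {
  genome <- withr::with_seed(53, virocycle:::random_genome(2000))
  other <- withr::with_seed(54, virocycle:::random_genome(400))
  ctg <- simple_contigs(genome)
  rs <- read_set(
    c("both", "one", "none"),
    c(substr(genome, 1, 100), substr(genome, 301, 400), substr(other, 1, 100)),
    c(revcomp(substr(genome, 201, 300)), substr(other, 101, 200),
      substr(other, 201, 300))
  )
  m <- map_reads(rs, ctg, map_params(seed_length = 21))
  kept <- subtract_pairs(rs, m)
  expect_identical(kept$read_id, "none")
  expect_equal(nrow(kept) + length(unique(m$read_id)), nrow(rs))
})

test_that("the iterative loop assembles a skewed two-genome community", {
  spec <- community_spec(n_genomes = 2, length_range = c(3000L, 6000L),
                         circular_fraction = 0.5,
                         abundance_model = "powerlaw", power_exponent = 3.3,
                         error_rate = 0, seed = 7)
  com <- generate_community(spec)
  reads <- simulate_reads(com$genomes, com$abundances, 2500, spec)
  res <- run_iterative_assembly(reads, assembly_config(seed = 7))
  # read conservation over the whole loop
  expect_equal(res$n_input_reads,
               sum(res$iterations$reads_mapped) + 2L * nrow(res$unassembled))
  # reads_remaining is strictly decreasing and internally consistent
  rem <- res$iterations$reads_remaining
  expect_true(all(diff(c(res$n_input_reads, rem)) < 0))
  expect_equal(rem, res$n_input_reads - cumsum(res$iterations$reads_mapped))
  # both genomes recovered; the abundant one at an earlier iteration
  hit_iter <- vapply(seq_len(2), function(i) {
    recs <- vapply(split(res$contigs, res$contigs$iteration), function(cc)
      recovery_fraction(cc, com$genomes$sequence[i],
                        circular_reference = com$genomes$circular[i]),
      numeric(1))
    as.integer(names(recs)[which(recs > 0.9)[1]])
  }, integer(1))
  expect_false(anyNA(hit_iter))
  expect_lt(hit_iter[1], hit_iter[2])
  # earlier iterations carry more read support on average
  sup <- tapply(res$contigs$read_support, res$contigs$iteration, mean)
  expect_gt(sup[[1]], sup[[length(sup)]])
})

test_that("a single clean circular genome terminates in one iteration", {
  genome <- withr::with_seed(55, virocycle:::random_genome(3000))
  reads <- tile_reads(genome, circular = TRUE, coverage = 25, seed = 55)
  res <- run_iterative_assembly(reads, assembly_config(seed = 55))
  expect_equal(nrow(res$iterations), 1L)
  expect_equal(res$iterations$n_circular, 1L)
  expect_equal(nrow(res$unassembled), 0L)
  circ <- res$contigs[res$contigs$is_circular, ]
  expect_identical(normalize_circular(circ$sequence[1]),
                   normalize_circular(genome))
})

test_that("unassemblable noise terminates with all reads unassembled", {
  seqs1 <- vapply(1:200, function(i) rand_dna(100, i), "")
  seqs2 <- vapply(201:400, function(i) rand_dna(100, i), "")
  rs <- read_set(sprintf("n%03d", 1:200), seqs1, seqs2)
  res <- run_iterative_assembly(rs, assembly_config(seed = 1))
  expect_equal(nrow(res$contigs), 0L)
  expect_equal(nrow(res$unassembled), 200L)
  expect_equal(res$n_input_reads, 2L * nrow(res$unassembled))
})

test_that("a fixed seed and input reproduce the assembly exactly", {
  spec <- community_spec(n_genomes = 2, length_range = c(2000L, 3000L),
                         circular_fraction = 0, error_rate = 0.002, seed = 66)
  com <- generate_community(spec)
  reads <- simulate_reads(com$genomes, com$abundances, 1200, spec)
  r1 <- run_iterative_assembly(reads, assembly_config(seed = 3))
  r2 <- run_iterative_assembly(reads, assembly_config(seed = 3))
  expect_identical(r1$contigs, r2$contigs)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$unassembled, r2$unassembled)
})

test_that("recruitment profiles respect the half-open size classes", {
  genome <- withr::with_seed(57, virocycle:::random_genome(5000))
  reads <- tile_reads(genome, circular = FALSE, coverage = 10, seed = 57)
  whole <- simple_contigs(genome)
  prof <- recruit_profile(reads, whole, map_params(seed_length = 21))
  expect_identical(prof$size_class, c("<1kb", "1-3kb", "3-10kb", ">10kb"))
  expect_lte(sum(prof$reads), 2L * nrow(reads))
  expect_equal(sum(prof$reads), prof$reads[prof$size_class == "3-10kb"])
  # fragmenting the contig moves the recruits down a class
  pieces <- substring(genome, seq(1, 4001, by = 1000),
                      seq(1000, 5000, by = 1000))
  frag <- simple_contigs(pieces)
  prof2 <- recruit_profile(reads, frag, map_params(seed_length = 21))
  expect_gt(prof2$reads[prof2$size_class == "1-3kb"], 0)
  expect_equal(prof2$reads[prof2$size_class == "3-10kb"], 0L)
  # exactly 1000 bp sits in the 1-3 kb class (half-open boundaries)
  exact <- simple_contigs(substr(genome, 1, 1000))
  prof3 <- recruit_profile(reads, exact, map_params(seed_length = 21))
  expect_equal(prof3$reads[prof3$size_class == "<1kb"], 0L)
})
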