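fam_table <- function(sets) {
  do.call(rbind, lapply(names(sets), function(f) {
    data.frame(family_id = f,
               orf_id = sprintf("%s_%s", f, sets[[f]]),
               contig_id = sets[[f]], is_centroid = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("overlap fraction is shared count over the smaller set", {
  expect_equal(overlap_fraction(as.character(1:5), as.character(1:4)), 1.0)
  expect_equal(overlap_fraction(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(overlap_fraction(as.character(1:4), as.character(c(1, 2, 5, 6))),
               0.5)
  expect_equal(overlap_fraction(c("a"), c("a", "b")),
               overlap_fraction(c("a", "b"), c("a")))
  expect_error(overlap_fraction(character(), "a"), "non-empty")
})

test_that("fully co-occurring families merge into one cassette", {
  sets <- list(family_A = sprintf("c%02d", 1:10),
               family_B = sprintf("c%02d", 1:10))
  cs <- discover_cassettes(fam_table(sets))
  expect_length(cs, 1L)
  expect_setequal(cs[[1]]$families, c("family_A", "family_B"))
  expect_setequal(cs[[1]]$contig_set, sprintf("c%02d", 1:10))
})

test_that("a nested family merges while an unrelated one stays out", {
  sets <- list(family_A = sprintf("c%02d", 1:10),
               family_B = sprintf("c%02d", 1:5),
               family_C = sprintf("c%02d", 11:20))
  cs <- discover_cassettes(fam_table(sets))
  expect_length(cs, 1L)
  expect_setequal(cs[[1]]$families, c("family_A", "family_B"))
  # intersection semantics: the cassette lives where both families do
  expect_setequal(cs[[1]]$contig_set, sprintf("c%02d", 1:5))
})

test_that("overlap below the threshold never merges", {
  sets <- list(family_A = sprintf("c%02d", 1:4),
               family_B = sprintf("c%02d", c(1, 2, 5, 6)))
  expect_length(discover_cassettes(fam_table(sets)), 0L)
})

test_that("agglomeration recalculates overlaps and chains merges", {
  # B joins A; C overlaps the merged AB unit (intersection c1..c8) at 1.0
  sets <- list(family_A = sprintf("c%02d", 1:10),
               family_B = sprintf("c%02d", 1:8),
               family_C = sprintf("c%02d", 1:6))
  cs <- discover_cassettes(fam_table(sets))
  expect_length(cs, 1L)
  expect_setequal(cs[[1]]$families, c("family_A", "family_B", "family_C"))
  expect_setequal(cs[[1]]$contig_set, sprintf("c%02d", 1:6))
})

test_that("discovery is invariant to family input order", {
  sets <- list(family_A = sprintf("c%02d", 1:10),
               family_B = sprintf("c%02d", 1:8),
               family_C = sprintf("c%02d", 11:20),
               family_D = sprintf("c%02d", 11:18))
  tab <- fam_table(sets)
  ref <- discover_cassettes(tab)
  for (i in 1:5) {
    perm <- withr::with_seed(i, tab[sample(nrow(tab)), ])
    expect_identical(discover_cassettes(perm), ref)
  }
})

test_that("relative orientation has exactly four states", {
  states <- orientation_states()
  expect_length(states, 4L)
  expect_setequal(states, c("++", "+-", "-+", "--"))
})

test_that("the modal orientation proportion scores a family pair", {
  orfs <- planted_cassette_orfs(n_contigs = 3, n_fam = 2, n_decoys = 0,
                                strands = c("+", "+"))
  # flip the second family on the third contig: orientations ++, ++, +-
  orfs$strand[orfs$orf_id == "c03_f2"] <- "-"
  fams <- fam_table(list(family_1 = sprintf("ctg%02d", 1:3),
                         family_2 = sprintf("ctg%02d", 1:3)))
  fams$orf_id <- c(sprintf("c%02d_f1", 1:3), sprintf("c%02d_f2", 1:3))
  cs <- discover_cassettes(fams)
  expect_equal(co_orientation_score(cs[[1]], orfs, fams), 2 / 3)
})

test_that("a planted co-oriented cassette scores 1 and recovers whole", {
  orfs <- planted_cassette_orfs(n_contigs = 20, n_fam = 3, n_decoys = 2)
  fams <- cluster_families(orfs)
  expect_equal(length(unique(fams$family_id)), 3L)
  cs <- discover_cassettes(fams)
  expect_length(cs, 1L)
  expect_length(cs[[1]]$families, 3L)
  expect_length(cs[[1]]$contig_set, 20L)
  expect_equal(co_orientation_score(cs[[1]], orfs, fams), 1.0)
})

test_that("paralogs on one contig are represented by the longest ORF", {
  p <- random_protein(80, 12)
  orfs <- rbind(
    data.frame(orf_id = "o1", contig_id = "c1", start = 0L, end = 243L,
               strand = "+", aa_seq = p),
    data.frame(orf_id = "o1b", contig_id = "c1", start = 400L, end = 580L,
               strand = "-", aa_seq = substr(p, 1, 59)),
    data.frame(orf_id = "o2", contig_id = "c2", start = 0L, end = 243L,
               strand = "+", aa_seq = p),
    data.frame(orf_id = "q1", contig_id = "c1", start = 700L, end = 943L,
               strand = "+", aa_seq = random_protein(80, 13)),
    data.frame(orf_id = "q2", contig_id = "c2", start = 700L, end = 943L,
               strand = "+", aa_seq = random_protein(80, 13))
  )
  fams <- cluster_families(orfs)
  cs <- discover_cassettes(fams)
  expect_length(cs, 1L)
  # the short minus-strand paralog must not disturb the orientation score
  expect_equal(co_orientation_score(cs[[1]], orfs, fams), 1.0)
})

test_that("span statistics take interval unions per contig", {
  orfs <- rbind(
    data.frame(orf_id = "a1", contig_id = "c1", start = 0L, end = 300L,
               strand = "+", aa_seq = "M"),
    data.frame(orf_id = "b1", contig_id = "c1", start = 900L, end = 1200L,
               strand = "+", aa_seq = "M"),
    data.frame(orf_id = "a2", contig_id = "c2", start = 0L, end = 300L,
               strand = "+", aa_seq = "M"),
    data.frame(orf_id = "b2", contig_id = "c2", start = 150L, end = 450L,
               strand = "+", aa_seq = "M")
  )
  fams <- data.frame(family_id = c("fa", "fb", "fa", "fb"),
                     orf_id = c("a1", "b1", "a2", "b2"),
                     contig_id = c("c1", "c1", "c2", "c2"),
                     is_centroid = FALSE, stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = c("c1", "c2"),
                        sequence = c(strrep("A", 2000), strrep("A", 2000)),
                        stringsAsFactors = FALSE)
  cs <- list(structure(list(cassette_id = "cassette_01",
                            families = c("fa", "fb"),
                            contig_set = c("c1", "c2")), class = "Cassette"))
  span <- cassette_span_stats(cs[[1]], orfs, fams, contigs)
  expect_equal(span$covered_bp, c(600L, 450L))  # disjoint sum; union overlap
  expect_equal(span$covered_fraction, c(0.30, 0.225))
  expect_equal(attr(span, "mean_covered_bp"), 525)
})

test_that("cassette summaries and JSON export are well formed", {
  orfs <- planted_cassette_orfs(n_contigs = 6, n_fam = 2, n_decoys = 1)
  fams <- cluster_families(orfs)
  cs <- discover_cassettes(fams)
  contigs <- data.frame(contig_id = sprintf("ctg%02d", 1:6),
                        sequence = strrep("A", 3000),
                        stringsAsFactors = FALSE)
  summ <- cassette_summary(cs, orfs, fams, contigs)
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$n_families, 2L)
  expect_equal(summ$co_orientation, 1.0)
  tf <- withr::local_tempfile(fileext = ".json")
  write_cassette_json(cs, orfs, fams, tf)
  parsed <- jsonlite::read_json(tf)
  expect_length(parsed, 1L)
  expect_length(parsed[[1]]$contigs, 6L)
})
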