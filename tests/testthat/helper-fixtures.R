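# Shared fixture builders. Everything is generated in code under fixed seeds.

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# four haplotypes of one genome differing at three biallelic sites spaced
# 25 bp apart; adjacent-site allele combinations cover all four states so
# that long kmers braid the bubbles together
snp_haplotypes <- function(seed = 101, len = 240L,
                           sites = c(81L, 106L, 131L)) {
  withr::with_seed(seed, {
    base <- strsplit(rand_dna(len), "")[[1L]]
    alt <- vapply(base[sites],
                  function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
    mk <- function(flags) {
      s <- base
      s[sites[flags]] <- alt[flags]
      paste(s, collapse = "")
    }
    c(mk(c(FALSE, FALSE, FALSE)), mk(c(FALSE, TRUE, TRUE)),
      mk(c(TRUE, FALSE, TRUE)), mk(c(TRUE, TRUE, FALSE)))
  })
}

# two unrelated genomes sharing exactly one 25 bp segment; the bases
# flanking the planted segment are forced to differ so the share cannot
# extend past 25 bp by chance
shared_segment_pair <- function(seed = 202, len = 200L, seg_at = 88L,
                                seg_len = 25L) {
  withr::with_seed(seed, {
    g1c <- strsplit(rand_dna(len), "")[[1L]]
    g2 <- strsplit(rand_dna(len), "")[[1L]]
    g2[seg_at:(seg_at + seg_len - 1L)] <- g1c[seg_at:(seg_at + seg_len - 1L)]
    for (p in c(seg_at - 1L, seg_at + seg_len)) {
      if (p >= 1L && p <= len && g2[p] == g1c[p]) {
        g2[p] <- setdiff(c("A", "C", "G", "T"), g1c[p])[1L]
      }
    }
    c(paste(g1c, collapse = ""), paste(g2, collapse = ""))
  })
}

# error-free read pairs tiling a single genome at a target coverage
tile_reads <- function(genome, circular, coverage, seed,
                       read_length = 100L) {
  n_pairs <- ceiling(coverage * nchar(genome) / (2 * read_length))
  spec <- community_spec(
    n_genomes = 1L, length_range = rep(nchar(genome), 2L),
    circular_fraction = as.numeric(circular), error_rate = 0, seed = seed
  )
  genomes <- data.frame(genome_id = "g1", sequence = genome,
                        circular = circular, stringsAsFactors = FALSE)
  simulate_reads(genomes, c(g1 = 1), n_pairs, spec)
}

random_protein <- function(n, seed = NULL) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  gen <- function() paste(sample(aas, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

mutate_protein <- function(aa, rate, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withr::with_seed(seed, {
    chars <- strsplit(aa, "")[[1L]]
    hit <- which(stats::runif(length(chars)) < rate)
    for (p in hit) chars[p] <- sample(setdiff(aas, chars[p]), 1L)
    paste(chars, collapse = "")
  })
}

# ORF/family tables for a planted cassette: n_contigs contigs all carrying
# the same n_fam families (mutated copies of one ancestor each) in fixed
# order and orientation, plus decoy proteins unique to each contig
planted_cassette_orfs <- function(n_contigs = 20L, n_fam = 3L,
                                  n_decoys = 1L, aa_len = 120L,
                                  strands = c("+", "+", "-"), seed = 7L,
                                  scramble_strands = FALSE) {
  ancestors <- vapply(seq_len(n_fam) * 1000L + seed, function(s)
    random_protein(aa_len, s), "")
  rows <- list()
  for (ci in seq_len(n_contigs)) {
    for (fi in seq_len(n_fam)) {
      strand <- if (scramble_strands) {
        withr::with_seed(seed + ci * 100L + fi,
                         sample(c("+", "-"), 1L))
      } else {
        strands[fi]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = sprintf("c%02d_f%d", ci, fi),
        contig_id = sprintf("ctg%02d", ci),
        start = (fi - 1L) * 400L, end = (fi - 1L) * 400L + 363L,
        strand = strand,
        aa_seq = mutate_protein(ancestors[fi], 0.2, seed + ci * 10L + fi),
        stringsAsFactors = FALSE
      )
    }
    for (di in seq_len(n_decoys)) {
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = sprintf("c%02d_d%d", ci, di),
        contig_id = sprintf("ctg%02d", ci),
        start = 1600L + (di - 1L) * 400L,
        end = 1600L + (di - 1L) * 400L + 363L,
        strand = "+",
        aa_seq = random_protein(aa_len, seed * 31L + ci * 7L + di),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
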