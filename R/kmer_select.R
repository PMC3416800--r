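#' Assembly configuration
#'
#' The kmer ladder defaults to 63, 59, ..., 19 (odd, descending). At each
#' iteration trial assemblies are run over the ladder; a kmer that closes a
#' circular contig of at least `circular_min_len` bp wins (largest such k),
#' otherwise the k maximizing the cumulative length of the `top_n` contigs of
#' at least `min_contig_len` bp, ranked by read support, is chosen. When more
#' than `trial_subsample` reads are present, trials run on a seeded uniform
#' subsample that preserves pairs.
#'
#' @param kmer_range ordered odd integers, descending.
#' @param top_n number of contigs whose cumulative length is scored.
#' @param min_contig_len contigs shorter than this (bp) are excluded from
#'   scoring and retention.
#' @param circular_min_len minimum length (bp) for a circular contig to count
#'   as a closed genome.
#' @param trial_subsample read cap for kmer-selection trials.
#' @param seed master seed for subsampling.
#' @return an `AssemblyConfig` list.
#' @export
assembly_config <- function(kmer_range = seq(63L, 19L, by = -4L),
                            top_n = 20L, min_contig_len = 1000L,
                            circular_min_len = 2000L,
                            trial_subsample = 1e6, seed = 1L) {
  kmer_range <- as.integer(kmer_range)
  stopifnot(all(kmer_range %% 2L == 1L), !is.unsorted(rev(kmer_range)),
            top_n >= 1, min_contig_len > 0, circular_min_len > 0,
            trial_subsample >= 2)
  structure(list(kmer_range = kmer_range, top_n = as.integer(top_n),
                 min_contig_len = as.integer(min_contig_len),
                 circular_min_len = as.integer(circular_min_len),
                 trial_subsample = as.numeric(trial_subsample),
                 seed = as.integer(seed)),
            class = "AssemblyConfig")
}

#' Trial assembly at one kmer
#'
#' Assembles the reads at `k` (build, simplify, extract) and attaches per
#' contig read support: the number of reads whose best mapping hits that
#' contig (each read supports at most one contig).
#'
#' @param reads a [read_set()].
#' @param k kmer value.
#' @param simplify_params a [simplify_params()].
#' @param map_params a [map_params()]; `seed_length` defaults to `k`.
#' @return contig data frame with `read_support` filled in.
#' @export
trial_assemble <- function(reads, k, simplify_params = NULL,
                           map_params = NULL) {
  if (is.null(simplify_params)) simplify_params <- simplify_params()
  if (is.null(map_params)) map_params <- map_params()
  k <- as.integer(k)
  if (k > min(nchar(c(reads$seq1, reads$seq2)))) {
    stop(sprintf("k = %d exceeds the read length", k), call. = FALSE)
  }
  p <- resolve_simplify(simplify_params, k)
  res <- cpp_assemble(c(reads$seq1, reads$seq2), k, p$min_cov, p$max_tip,
                      p$bubble_max)
  contigs <- contig_frame(res$sequence, res$is_circular, res$mean_coverage,
                          k, NA_integer_)
  if (nrow(contigs) == 0) return(contigs)
  mp <- map_params
  if (is.null(mp$seed_length)) mp$seed_length <- k
  m <- map_reads(reads, contigs, mp)
  tab <- table(factor(m$contig_id, levels = contigs$contig_id))
  contigs$read_support <- as.integer(tab[contigs$contig_id])
  contigs
}

#' Score one trial assembly
#'
#' @param contigs contig data frame carrying `read_support`.
#' @param config an [assembly_config()].
#' @return a `KmerScore`: list with `k`, `has_circular`, `n_contigs` and
#'   `top_cumulative_length`.
#' @export
score_assembly <- function(contigs, config = assembly_config()) {
  k <- if (nrow(contigs)) contigs$kmer_used[1L] else NA_integer_
  if (nrow(contigs) == 0) {
    return(structure(list(k = k, has_circular = FALSE, n_contigs = 0L,
                          top_cumulative_length = 0L), class = "KmerScore"))
  }
  has_circ <- any(contigs$is_circular &
                    nchar(contigs$sequence) >= config$circular_min_len)
  keep <- contigs[nchar(contigs$sequence) >= config$min_contig_len, ,
                  drop = FALSE]
  ord <- order(-ifelse(is.na(keep$read_support), 0L, keep$read_support),
               -nchar(keep$sequence), keep$contig_id)
  top <- utils::head(keep[ord, , drop = FALSE], config$top_n)
  structure(list(k = k, has_circular = has_circ, n_contigs = nrow(keep),
                 top_cumulative_length = sum(nchar(top$sequence))),
            class = "KmerScore")
}

#' Choose the optimal kmer from a set of trial scores
#'
#' If any kmer produced a sufficiently long circular contig, the largest such
#' kmer is selected (a closed circle signals a complete circular genome).
#' Otherwise the kmer with the longest cumulative top-contig length wins,
#' ties breaking to the larger k. When every score is empty the function
#' signals a `virocycle_no_assembly` condition, which drives loop
#' termination.
#'
#' @param scores list of `KmerScore` objects.
#' @return the chosen kmer (integer).
#' @export
choose_kmer <- function(scores) {
  stopifnot(length(scores) >= 1)
  ks <- vapply(scores, function(s) s$k, integer(1))
  circ <- vapply(scores, function(s) isTRUE(s$has_circular), logical(1))
  len <- vapply(scores, function(s) as.numeric(s$top_cumulative_length),
                numeric(1))
  if (any(circ)) return(max(ks[circ]))
  if (all(len == 0)) {
    stop(structure(class = c("virocycle_no_assembly", "error", "condition"),
                   list(message = "no usable assembly at any kmer value",
                        call = sys.call(-1))))
  }
  best <- len == max(len)
  max(ks[best])
}

# seeded uniform subsample of read pairs, capped at n_reads reads
subsample_pairs <- function(reads, n_reads, seed) {
  n_pairs_keep <- floor(n_reads / 2)
  if (nrow(reads) <= n_pairs_keep) return(reads)
  idx <- with_seed(seed, sort(sample.int(nrow(reads), n_pairs_keep)))
  out <- reads[idx, , drop = FALSE]
  class(out) <- class(reads)
  out
}

# run the kmer scan and return list(scores=..., k=chosen or NULL)
scan_kmers <- function(reads, config, simplify_params, map_params) {
  read_len <- min(nchar(c(reads$seq1, reads$seq2)))
  ks <- config$kmer_range[config$kmer_range <= read_len]
  if (length(ks) == 0) {
    stop("all kmer values exceed the read length", call. = FALSE)
  }
  scores <- lapply(ks, function(k) {
    score_assembly(trial_assemble(reads, k, simplify_params, map_params),
                   config)
  })
  chosen <- tryCatch(choose_kmer(scores),
                     virocycle_no_assembly = function(e) NULL)
  list(scores = scores, k = chosen)
}

# per-iteration score table, TSV-ready
score_table <- function(scores) {
  do.call(rbind, lapply(scores, function(s) {
    data.frame(k = s$k, has_circular = s$has_circular,
               n_contigs = s$n_contigs,
               top_cumulative_length = s$top_cumulative_length)
  }))
}
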