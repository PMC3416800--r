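#' Read-mapping parameters
#'
#' The built-in mapper is a seed-and-extend gapped aligner: a read maps to a
#' contig iff it shares an exact `seed_length` match (on either strand when
#' `allow_rc`) and its best alignment identity reaches `min_identity`. Each
#' read keeps only its best contig. Circular contigs are virtually extended
#' across the junction so junction-spanning reads map.
#'
#' @param min_identity minimum alignment identity (fraction).
#' @param seed_length exact-seed length; `NULL` means use the current
#'   assembly kmer.
#' @param allow_rc also try the reverse complement of each read.
#' @param band half-width of the banded gapped alignment.
#' @return a `MapParams` list.
#' @export
map_params <- function(min_identity = 0.95, seed_length = NULL,
                       allow_rc = TRUE, band = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1)
  structure(list(min_identity = min_identity, seed_length = seed_length,
                 allow_rc = isTRUE(allow_rc), band = as.integer(band)),
            class = "MapParams")
}

#' Map reads to contigs
#'
#' @param reads a [read_set()] (both mates are mapped independently) or a
#'   character vector of sequences.
#' @param contigs contig data frame with `contig_id`, `sequence`,
#'   `is_circular`.
#' @param params a [map_params()]; when `seed_length` is `NULL` it defaults
#'   to the contigs' `kmer_used` (or 31 if absent).
#' @return data frame of mapped reads only: `read_id`, `mate` (1/2, or NA for
#'   unpaired input), `contig_id`, `identity`.
#' @export
map_reads <- function(reads, contigs, params = map_params()) {
  stopifnot(nrow(contigs) > 0)
  if (inherits(reads, "ReadSet")) {
    seqs <- c(reads$seq1, reads$seq2)
    ids <- c(reads$read_id, reads$read_id)
    mate <- rep(c(1L, 2L), each = nrow(reads))
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(reads))) names(reads)
           else sprintf("read_%d", seq_along(seqs))
    mate <- rep(NA_integer_, length(seqs))
  }
  seed_len <- params$seed_length
  if (is.null(seed_len)) {
    seed_len <- if (!is.null(contigs$kmer_used) &&
                    !is.na(contigs$kmer_used[1L])) contigs$kmer_used[1L]
                else 31L
  }
  res <- cpp_map_reads(seqs, contigs$sequence, contigs$is_circular,
                       as.integer(seed_len), params$min_identity,
                       params$allow_rc, params$band)
  hit <- res$contig > 0L
  data.frame(
    read_id = ids[hit],
    mate = mate[hit],
    contig_id = contigs$contig_id[res$contig[hit]],
    identity = res$identity[hit],
    stringsAsFactors = FALSE
  )
}

#' Remove read pairs recruited by contigs
#'
#' A pair is removed when either mate maps: a mate left behind by its partner
#' often spans a circular-contig junction or an assembly gap, so dropping the
#' whole pair avoids re-assembling it.
#'
#' @param reads a [read_set()].
#' @param mapping output of [map_reads()] on the same reads.
#' @return the retained [read_set()], in the original order.
#' @export
subtract_pairs <- function(reads, mapping) {
  if (!all(mapping$read_id %in% reads$read_id)) {
    stop("mapping refers to read ids absent from the ReadSet", call. = FALSE)
  }
  keep <- !(reads$read_id %in% mapping$read_id)
  out <- reads[keep, , drop = FALSE]
  class(out) <- class(reads)
  out
}

#' Run the iterative kmer-optimized assembly loop
#'
#' Each iteration: (1) choose the optimal kmer on the current reads (on a
#' seeded subsample when more than `trial_subsample` reads remain); (2)
#' assemble all current reads at that kmer; (3) retain the `top_n` contigs of
#' at least `min_contig_len` bp ranked by read support, plus every circular
#' contig of at least `circular_min_len` bp (circles do not count against
#' `top_n`); (4) map the full current read set to the retained contigs; (5)
#' remove every pair with a mapped mate. The loop ends when zero reads map or
#' no contig reaches `min_contig_len`; any remaining reads then get one final
#' assembly at the last chosen kmer, whose contigs are all reported.
#'
#' @param reads a non-empty paired [read_set()].
#' @param config an [assembly_config()].
#' @param simplify_params a [simplify_params()].
#' @param map_params a [map_params()].
#' @param verbose print one line per iteration.
#' @return an `AssemblyResult`: list with `contigs` (iteration-tagged contig
#'   data frame), `iterations` (per-iteration records), `unassembled`
#'   (remaining [read_set()]) and `score_tables` (per-iteration kmer scan
#'   logs).
#' @export
run_iterative_assembly <- function(reads, config = assembly_config(),
                                   simplify_params = NULL,
                                   map_params = NULL, verbose = FALSE) {
  if (!inherits(reads, "ReadSet") || nrow(reads) == 0) {
    stop("empty input: a non-empty paired ReadSet is required", call. = FALSE)
  }
  if (is.null(simplify_params)) simplify_params <- simplify_params()
  if (is.null(map_params)) map_params <- map_params()
  remaining <- reads
  all_contigs <- list()
  records <- list()
  tables <- list()
  last_k <- NULL
  iter <- 0L
  while (nrow(remaining) > 0 && iter < 100L) {
    iter <- iter + 1L
    trial_reads <- subsample_pairs(remaining, config$trial_subsample,
                                   derive_seed(config$seed, iter))
    scan <- scan_kmers(trial_reads, config, simplify_params, map_params)
    tables[[iter]] <- cbind(iteration = iter, score_table(scan$scores))
    if (is.null(scan$k)) break  # no usable assembly: zero contigs >= 1 kb
    k <- scan$k
    last_k <- k
    contigs <- trial_assemble(remaining, k, simplify_params, map_params)
    retained <- retain_contigs(contigs, config)
    if (nrow(retained) == 0) break  # zero contigs >= min_contig_len
    mp <- map_params
    if (is.null(mp$seed_length)) mp$seed_length <- k
    mapping <- map_reads(remaining, retained, mp)
    n_before <- 2L * nrow(remaining)
    remaining <- subtract_pairs(remaining, mapping)
    n_mapped <- n_before - 2L * nrow(remaining)
    if (n_mapped == 0L) break  # zero reads map
    retained$iteration <- iter
    retained$contig_id <- sprintf("iter%d_%s", iter, retained$contig_id)
    all_contigs[[length(all_contigs) + 1L]] <- retained
    records[[length(records) + 1L]] <- data.frame(
      iteration = iter, k_chosen = k, n_contigs_retained = nrow(retained),
      n_circular = sum(retained$is_circular), reads_mapped = n_mapped,
      reads_remaining = 2L * nrow(remaining)
    )
    if (verbose) {
      message(sprintf("iteration %d: k=%d, %d contigs (%d circular), %d reads mapped, %d remaining",
                      iter, k, nrow(retained), sum(retained$is_circular),
                      n_mapped, 2L * nrow(remaining)))
    }
  }
  # final sweep: assemble whatever is left at the last optimal kmer
  if (nrow(remaining) > 0 && !is.null(last_k)) {
    iter <- iter + 1L
    contigs <- trial_assemble(remaining, last_k, simplify_params, map_params)
    if (nrow(contigs) > 0) {
      mp <- map_params
      if (is.null(mp$seed_length)) mp$seed_length <- last_k
      mapping <- map_reads(remaining, contigs, mp)
      n_before <- 2L * nrow(remaining)
      remaining <- subtract_pairs(remaining, mapping)
      n_mapped <- n_before - 2L * nrow(remaining)
      contigs$iteration <- iter
      contigs$contig_id <- sprintf("final_%s", contigs$contig_id)
      all_contigs[[length(all_contigs) + 1L]] <- contigs
      records[[length(records) + 1L]] <- data.frame(
        iteration = iter, k_chosen = last_k,
        n_contigs_retained = nrow(contigs),
        n_circular = sum(contigs$is_circular), reads_mapped = n_mapped,
        reads_remaining = 2L * nrow(remaining)
      )
    }
  }
  contigs_out <- if (length(all_contigs)) do.call(rbind, all_contigs)
                 else contig_frame(character(), logical(), numeric(), NA, NA)
  structure(list(
    contigs = contigs_out,
    iterations = if (length(records)) do.call(rbind, records)
                 else data.frame(iteration = integer(), k_chosen = integer(),
                                 n_contigs_retained = integer(),
                                 n_circular = integer(),
                                 reads_mapped = integer(),
                                 reads_remaining = integer()),
    unassembled = remaining,
    score_tables = if (length(tables)) do.call(rbind, tables) else NULL,
    n_input_reads = 2L * nrow(reads)
  ), class = "AssemblyResult")
}

retain_contigs <- function(contigs, config) {
  circ <- contigs$is_circular &
    nchar(contigs$sequence) >= config$circular_min_len
  long <- !circ & nchar(contigs$sequence) >= config$min_contig_len
  cand <- contigs[long, , drop = FALSE]
  ord <- order(-ifelse(is.na(cand$read_support), 0L, cand$read_support),
               -nchar(cand$sequence), cand$contig_id)
  top <- utils::head(cand[ord, , drop = FALSE], config$top_n)
  out <- rbind(contigs[circ, , drop = FALSE], top)
  out[order(out$contig_id), , drop = FALSE]
}

#' @export
print.AssemblyResult <- function(x, ...) {
  cat(sprintf("AssemblyResult: %d contigs (%d circular) over %d iterations\n",
              nrow(x$contigs), sum(x$contigs$is_circular),
              nrow(x$iterations)))
  cat(sprintf("  input reads: %d; unassembled: %d\n", x$n_input_reads,
              2L * nrow(x$unassembled)))
  invisible(x)
}

#' Read-recruitment profile by contig size class
#'
#' Maps reads back to contigs and counts each mapped read once, in the size
#' class of its best contig. Classes are half-open in bp:
#' `[0,1000)`, `[1000,3000)`, `[3000,10000)`, `[10000,Inf)`. This measures
#' how completely an assembly explains its input data, which is a more
#' faithful quality signal than N50 for mixed communities.
#'
#' @param reads a [read_set()].
#' @param contigs contig data frame.
#' @param params a [map_params()].
#' @return data frame with `size_class` and `reads` columns.
#' @export
recruit_profile <- function(reads, contigs, params = map_params()) {
  stopifnot(nrow(contigs) > 0)
  m <- map_reads(reads, contigs, params)
  len <- nchar(contigs$sequence)[match(m$contig_id, contigs$contig_id)]
  breaks <- c(0, 1000, 3000, 10000, Inf)
  labels <- c("<1kb", "1-3kb", "3-10kb", ">10kb")
  cls <- cut(len, breaks = breaks, labels = labels, right = FALSE)
  data.frame(size_class = labels,
             reads = as.integer(table(factor(cls, levels = labels))),
             stringsAsFactors = FALSE)
}
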