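#' Build a de Bruijn graph from reads or sequences
#'
#' Every length-k substring of every input sequence contributes one count to
#' exactly one edge, after collapsing each kmer with its reverse complement
#' onto the lexicographically smaller (canonical) form. Nodes are the implied
#' (k-1)-mers. Kmers containing N are skipped. Because shotgun reads come
#' from both strands, the canonical graph is invariant to reverse
#' complementing any input read.
#'
#' @param x a [read_set()] (both mates are used) or a character vector of
#'   sequences.
#' @param k kmer (edge) length; odd, between 5 and the shortest read.
#' @return a `DeBruijnGraph`: list with `k` and `edges` (named integer vector
#'   of coverage counts keyed by canonical kmer, sorted).
#' @export
build_graph <- function(x, k) {
  seqs <- if (inherits(x, "ReadSet")) c(x$seq1, x$seq2) else as.character(x)
  if (length(seqs) == 0) stop("empty input: no reads to build from",
                              call. = FALSE)
  k <- as.integer(k)
  if (k < 5L || k %% 2L == 0L) {
    stop("k must be odd and at least 5", call. = FALSE)
  }
  if (k > 63L) stop("k must be at most 63", call. = FALSE)
  if (k > min(nchar(seqs))) {
    stop(sprintf("k = %d exceeds the shortest input length (%d)",
                 k, min(nchar(seqs))), call. = FALSE)
  }
  res <- cpp_build_edges(seqs, k)
  new_dbg(k, res)
}

new_dbg <- function(k, res) {
  edges <- res$count
  names(edges) <- res$kmer
  structure(list(k = as.integer(k), edges = edges), class = "DeBruijnGraph")
}

#' @export
print.DeBruijnGraph <- function(x, ...) {
  cat(sprintf("DeBruijnGraph: k = %d, %d edges, %d nodes\n",
              x$k, length(x$edges), length(graph_nodes(x))))
  invisible(x)
}

#' Canonical node labels of a de Bruijn graph
#'
#' @param graph a `DeBruijnGraph`.
#' @return sorted character vector of canonical (k-1)-mers.
#' @export
graph_nodes <- function(graph) {
  km <- names(graph$edges)
  if (length(km) == 0) return(character())
  n <- graph$k - 1L
  nodes <- c(substr(km, 1L, n), substr(km, 2L, graph$k))
  rc <- revcomp(nodes)
  sort(unique(pmin(nodes, rc)))
}

#' Graph simplification parameters
#'
#' Mirrors the usual cleanup steps of short-read assemblers: clipping short
#' dead-end tips, removing low-coverage edges, and merging small bubbles onto
#' their higher-coverage branch. Tip and bubble limits default to 2k edges
#' when left `NULL`.
#'
#' @param min_edge_coverage edges observed fewer times are removed.
#' @param max_tip_length maximum dead-end branch length, in edges.
#' @param bubble_max_len maximum bubble branch length, in edges.
#' @return a `SimplifyParams` list.
#' @export
simplify_params <- function(min_edge_coverage = 2L, max_tip_length = NULL,
                            bubble_max_len = NULL) {
  stopifnot(min_edge_coverage >= 1)
  structure(list(min_edge_coverage = as.integer(min_edge_coverage),
                 max_tip_length = max_tip_length,
                 bubble_max_len = bubble_max_len),
            class = "SimplifyParams")
}

resolve_simplify <- function(params, k) {
  list(
    min_cov = params$min_edge_coverage,
    max_tip = as.integer(if (is.null(params$max_tip_length)) 2L * k
                         else params$max_tip_length),
    bubble_max = as.integer(if (is.null(params$bubble_max_len)) 2L * k
                            else params$bubble_max_len)
  )
}

#' Simplify a de Bruijn graph
#'
#' Repeats tip clipping, low-coverage edge removal and bubble merging until a
#' fixed point, so the operation is idempotent. Bubble merging keeps the
#' higher-coverage branch (ties break to the lexicographically smaller
#' sequence) and adds the removed branch's mean edge coverage to the kept one.
#'
#' @param graph a `DeBruijnGraph`.
#' @param params a [simplify_params()].
#' @return the simplified `DeBruijnGraph`.
#' @export
simplify_graph <- function(graph, params = simplify_params()) {
  if (length(graph$edges) == 0) return(graph)
  p <- resolve_simplify(params, graph$k)
  res <- cpp_simplify(names(graph$edges), unname(graph$edges), graph$k,
                      p$min_cov, p$max_tip, p$bubble_max)
  new_dbg(graph$k, res)
}

#' Extract contigs from a (simplified) de Bruijn graph
#'
#' Maximal non-branching paths become contigs. A non-branching cycle (every
#' node on it with in-degree = out-degree = 1) closes on itself and is
#' reported as circular, without duplicating the closing (k-1)-mer; circular
#' sequences are normalized to the smallest rotation of the canonical strand
#' and linear ones to the canonical strand, so output is deterministic.
#'
#' @param graph a `DeBruijnGraph`.
#' @param kmer_used recorded in the output (defaults to `graph$k`).
#' @param iteration optional iteration tag.
#' @return data frame with columns `contig_id`, `sequence`, `is_circular`,
#'   `kmer_used`, `read_support` (NA until reads are mapped), `iteration`,
#'   `mean_coverage`.
#' @export
extract_contigs <- function(graph, kmer_used = graph$k, iteration = NA_integer_) {
  if (length(graph$edges) == 0) {
    return(contig_frame(character(), logical(), numeric(), kmer_used,
                        iteration))
  }
  res <- cpp_extract_contigs(names(graph$edges), unname(graph$edges), graph$k)
  contig_frame(res$sequence, res$is_circular, res$mean_coverage, kmer_used,
               iteration)
}

contig_frame <- function(sequence, is_circular, mean_coverage, kmer_used,
                         iteration) {
  n <- length(sequence)
  data.frame(
    contig_id = if (n) sprintf("k%d_c%04d", kmer_used, seq_len(n))
                else character(),
    sequence = as.character(sequence),
    is_circular = as.logical(is_circular),
    kmer_used = rep(as.integer(kmer_used), n),
    read_support = rep(NA_integer_, n),
    iteration = rep(as.integer(iteration), n),
    mean_coverage = as.numeric(mean_coverage),
    stringsAsFactors = FALSE
  )
}

#' Count simple bubbles in a de Bruijn graph
#'
#' A bubble is a pair of nodes joined by exactly two internally disjoint
#' non-branching paths — the signature of a biallelic polymorphism (or a
#' sequencing error) in the read population. Each bubble is counted once
#' (strand mirror images are deduplicated).
#'
#' @param graph a `DeBruijnGraph`.
#' @return integer bubble count.
#' @export
count_bubbles <- function(graph) {
  if (length(graph$edges) == 0) return(0L)
  cpp_count_bubbles(names(graph$edges), unname(graph$edges), graph$k)
}

#' Number of weakly connected components of a de Bruijn graph
#'
#' Genomes sharing no (k-1)-mer occupy disjoint subgraphs, so the component
#' count shows whether a short region of similarity joins otherwise unrelated
#' genomes at the chosen k.
#'
#' @param graph a `DeBruijnGraph`.
#' @return integer component count (0 for an empty graph).
#' @export
connected_components <- function(graph) {
  if (length(graph$edges) == 0) return(0L)
  cpp_components(names(graph$edges), unname(graph$edges), graph$k)
}
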