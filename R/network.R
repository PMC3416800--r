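#' Build the bipartite contig-to-reference-protein network
#'
#' An edge joins a contig to a reference protein when some ORF on the contig
#' hits that protein more significantly than `evalue_max` (strict
#' inequality). Contigs shorter than `min_contig_len` or with fewer than
#' `min_hits` distinct qualifying protein partners are removed, then orphan
#' proteins are dropped; multiple ORFs hitting the same protein collapse to
#' one edge keeping the best e-value. The two filters commute because hit
#' counts are computed on qualifying edges only.
#'
#' @param contigs contig data frame (`contig_id`, `sequence`).
#' @param orfs ORF data frame (`orf_id`, `contig_id`).
#' @param hits hit table from [read_hits_table()].
#' @param evalue_max strict e-value ceiling for an edge.
#' @param min_contig_len minimum contig length in bp.
#' @param min_hits minimum number of distinct reference proteins hit.
#' @return a `BipartiteNetwork`: list with `contig_nodes`, `protein_nodes`
#'   and `edges` (data frame `contig_id`, `protein_id`, `evalue`).
#' @export
build_bipartite <- function(contigs, orfs, hits, evalue_max = 1e-50,
                            min_contig_len = 3000L, min_hits = 5L) {
  unknown <- setdiff(hits$orf_id, orfs$orf_id)
  if (length(unknown) > 0) {
    stop(sprintf("hit table references unknown ORF '%s'", unknown[1L]),
         call. = FALSE)
  }
  h <- hits[hits$evalue < evalue_max, , drop = FALSE]
  h$contig_id <- orfs$contig_id[match(h$orf_id, orfs$orf_id)]
  # collapse multiple ORF hits on one protein to the best e-value
  if (nrow(h) > 0) {
    h <- h[order(h$contig_id, h$protein_id, h$evalue), , drop = FALSE]
    h <- h[!duplicated(h[, c("contig_id", "protein_id")]), , drop = FALSE]
  }
  clen <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  n_hits <- table(h$contig_id)
  ok_contig <- names(n_hits)[n_hits >= min_hits]
  ok_contig <- ok_contig[clen[ok_contig] >= min_contig_len]
  h <- h[h$contig_id %in% ok_contig, , drop = FALSE]
  edges <- h[order(h$contig_id, h$protein_id),
             c("contig_id", "protein_id", "evalue")]
  rownames(edges) <- NULL
  structure(list(contig_nodes = sort(unique(edges$contig_id)),
                 protein_nodes = sort(unique(edges$protein_id)),
                 edges = edges),
            class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork: %d contigs, %d proteins, %d edges\n",
              length(x$contig_nodes), length(x$protein_nodes),
              nrow(x$edges)))
  invisible(x)
}

network_to_igraph <- function(network) {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(network$contig_nodes),
                            name = network$contig_nodes,
                            class = "contig")
  g <- igraph::add_vertices(g, length(network$protein_nodes),
                            name = network$protein_nodes,
                            class = "protein")
  if (nrow(network$edges) > 0) {
    pairs <- rbind(network$edges$contig_id, network$edges$protein_id)
    g <- igraph::add_edges(g, as.vector(pairs),
                           evalue = network$edges$evalue)
  }
  g
}

#' Export a bipartite network for Cytoscape
#'
#' SIF lines read `contig_id hits protein_id`; GraphML additionally carries
#' the node class and edge e-value attributes. Output is sorted, hence
#' deterministic.
#'
#' @param network a `BipartiteNetwork`.
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop(sprintf("unknown network format '%s'", format[1L]), call. = FALSE)
  })
  if (format == "sif") {
    lines <- sprintf("%s hits %s", network$edges$contig_id,
                     network$edges$protein_id)
    writeLines(sort(lines), path)
  } else {
    igraph::write_graph(network_to_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Import a GraphML bipartite network
#'
#' Inverse of [export_network()] with `format = "graphml"`.
#'
#' @param path path to a GraphML file written by this package.
#' @return a `BipartiteNetwork`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  cls <- igraph::vertex_attr(g, "class")
  nms <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g, names = TRUE)
  ev <- igraph::edge_attr(g, "evalue")
  is_contig <- cls[match(el[, 1L], nms)] == "contig"
  edges <- data.frame(
    contig_id = ifelse(is_contig, el[, 1L], el[, 2L]),
    protein_id = ifelse(is_contig, el[, 2L], el[, 1L]),
    evalue = if (is.null(ev)) rep(NA_real_, nrow(el)) else ev,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$contig_id, edges$protein_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(contig_nodes = sort(nms[cls == "contig"]),
                 protein_nodes = sort(nms[cls == "protein"]),
                 edges = edges),
            class = "BipartiteNetwork")
}
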