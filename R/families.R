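#' Global-alignment identity between two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62; identity is the number
#' of identical columns divided by the total number of alignment columns
#' (gap columns count in the denominator). Symmetric in its arguments.
#'
#' @param aa_a,aa_b non-empty amino-acid strings.
#' @return identity fraction in \[0, 1\].
#' @export
align_identity <- function(aa_a, aa_b) {
  if (!nzchar(aa_a) || !nzchar(aa_b)) {
    stop("empty sequence in identity computation", call. = FALSE)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  a_chars <- strsplit(pa, "", fixed = TRUE)[[1L]]
  b_chars <- strsplit(ps, "", fixed = TRUE)[[1L]]
  sum(a_chars == b_chars & a_chars != "-") / length(a_chars)
}

# identities of one sequence against a vector of centroids (vectorized)
identity_vs_centroids <- function(aa, centroids) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(centroids),
    Biostrings::AAString(aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  vapply(seq_along(pa), function(i) {
    a <- strsplit(pa[i], "", fixed = TRUE)[[1L]]
    b <- strsplit(ps[i], "", fixed = TRUE)[[1L]]
    sum(a == b & a != "-") / length(a)
  }, numeric(1))
}

#' Cluster ORF translations into protein-coding families
#'
#' Greedy centroid clustering: ORFs are processed in deterministic order
#' (translation length descending, then `orf_id`); each ORF joins the first
#' existing centroid it matches at `identity_threshold` or above, otherwise
#' it founds a new centroid. Clusters whose members sit on at least two
#' distinct contigs become families — repeated proteins on a single contig
#' do not, by themselves, demonstrate conservation across genomes. The 30%
#' default sits near the limit of detectable homology, deliberately
#' inclusive of dissimilar but related proteins.
#'
#' @param orfs ORF data frame with `orf_id`, `contig_id`, `aa_seq`.
#' @param identity_threshold minimum [align_identity()] to join a family.
#' @return data frame: `family_id`, `orf_id`, `contig_id`, `is_centroid`.
#'   Families partition a subset of the ORFs; singletons and single-contig
#'   clusters are discarded.
#' @export
cluster_families <- function(orfs, identity_threshold = 0.30) {
  stopifnot(nrow(orfs) >= 1)
  ord <- order(-nchar(orfs$aa_seq), orfs$orf_id)
  o <- orfs[ord, , drop = FALSE]
  centroid_seq <- character()
  assignment <- integer(nrow(o))
  for (i in seq_len(nrow(o))) {
    if (length(centroid_seq) > 0) {
      ids <- identity_vs_centroids(o$aa_seq[i], centroid_seq)
      hit <- which(ids >= identity_threshold)
    } else {
      hit <- integer()
    }
    if (length(hit) > 0) {
      assignment[i] <- hit[1L]
    } else {
      centroid_seq <- c(centroid_seq, o$aa_seq[i])
      assignment[i] <- length(centroid_seq)
    }
  }
  res <- data.frame(cluster = assignment, orf_id = o$orf_id,
                    contig_id = o$contig_id,
                    is_centroid = !duplicated(assignment),
                    stringsAsFactors = FALSE)
  # a family needs members on at least two distinct contigs
  n_contigs <- tapply(res$contig_id, res$cluster,
                      function(x) length(unique(x)))
  keep <- as.integer(names(n_contigs)[n_contigs >= 2])
  res <- res[res$cluster %in% keep, , drop = FALSE]
  if (nrow(res) == 0) {
    return(data.frame(family_id = character(), orf_id = character(),
                      contig_id = character(), is_centroid = logical(),
                      stringsAsFactors = FALSE))
  }
  fam_rank <- match(res$cluster, sort(unique(res$cluster)))
  res$family_id <- sprintf("family_%03d", fam_rank)
  rownames(res) <- NULL
  res[order(res$family_id, res$orf_id),
      c("family_id", "orf_id", "contig_id", "is_centroid")]
}

#' Contig sets of protein families
#'
#' @param families data frame from [cluster_families()].
#' @return named list of character contig-id sets, one per family.
#' @export
family_contig_sets <- function(families) {
  lapply(split(families$contig_id, families$family_id), unique)
}

#' Write a family table as TSV
#'
#' @param families data frame from [cluster_families()].
#' @param path output path.
#' @export
write_families_tsv <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
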