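#' Cassette discovery configuration
#'
#' @param overlap_threshold two units merge when the smaller one shares a
#'   contig with the other at least this fraction of the time.
#' @param merge_rule contig set of a merged unit: `"intersection"` (the
#'   conservative default — a cassette's contigs all carry every member
#'   family) or `"union"`.
#' @return a `CassetteConfig` list.
#' @export
cassette_config <- function(overlap_threshold = 0.80,
                            merge_rule = c("intersection", "union")) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(overlap_threshold = overlap_threshold,
                 merge_rule = match.arg(merge_rule)),
            class = "CassetteConfig")
}

#' Shared-contig overlap between two contig sets
#'
#' The number of shared contigs divided by the size of the smaller set: the
#' fraction of the time the smaller family is found on a shared contig.
#'
#' @param set_a,set_b non-empty character vectors of contig ids.
#' @return fraction in \[0, 1\]; symmetric.
#' @export
overlap_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("overlap_fraction requires non-empty contig sets", call. = FALSE)
  }
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Discover gene cassettes by iterative family agglomeration
#'
#' Repeatedly merges the pair of units (families, or cassettes formed
#' earlier) with the highest shared-contig overlap at or above the
#' threshold, recalculating all overlaps after every merge. A merged unit's
#' contig set is, under the default rule, the intersection of its parts'
#' sets. Ties break toward the pair with the larger smaller-set, then by
#' unit ids. Units holding at least two families are reported as cassettes;
#' every family belongs to at most one cassette, and the result does not
#' depend on the input order of the families.
#'
#' @param families data frame from [cluster_families()], or a named list of
#'   contig-id sets.
#' @param config a [cassette_config()].
#' @return list of cassettes; each is a list with `cassette_id`, `families`
#'   (sorted family ids) and `contig_set` (sorted contig ids).
#' @export
discover_cassettes <- function(families, config = cassette_config()) {
  sets <- if (is.data.frame(families)) family_contig_sets(families)
          else lapply(families, unique)
  stopifnot(length(sets) >= 2)
  units <- lapply(sort(names(sets)), function(f) {
    list(families = f, contigs = sort(sets[[f]]))
  })
  repeat {
    n <- length(units)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (length(units[[i]]$contigs) == 0 ||
            length(units[[j]]$contigs) == 0) next
        ov <- overlap_fraction(units[[i]]$contigs, units[[j]]$contigs)
        if (ov < config$overlap_threshold) next
        smaller <- min(length(units[[i]]$contigs),
                       length(units[[j]]$contigs))
        key <- list(ov = ov, smaller = smaller,
                    ids = c(units[[i]]$families[1L], units[[j]]$families[1L]))
        if (is.null(best) || ov > best$key$ov ||
            (ov == best$key$ov && smaller > best$key$smaller) ||
            (ov == best$key$ov && smaller == best$key$smaller &&
             paste(key$ids, collapse = "\r") <
               paste(best$key$ids, collapse = "\r"))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    if (is.null(best)) break
    a <- units[[best$i]]
    b <- units[[best$j]]
    merged <- list(
      families = sort(c(a$families, b$families)),
      contigs = if (config$merge_rule == "intersection") {
        sort(intersect(a$contigs, b$contigs))
      } else {
        sort(union(a$contigs, b$contigs))
      }
    )
    units <- units[-c(best$i, best$j)]
    units[[length(units) + 1L]] <- merged
  }
  units <- Filter(function(u) length(u$families) >= 2, units)
  # deterministic report order by first member family
  units <- units[order(vapply(units, function(u) u$families[1L], ""))]
  lapply(seq_along(units), function(i) {
    structure(list(cassette_id = sprintf("cassette_%02d", i),
                   families = units[[i]]$families,
                   contig_set = units[[i]]$contigs),
              class = "Cassette")
  })
}

#' Relative orientation of a gene pair on a contig
#'
#' With two strands per gene there are exactly four relative orientations
#' for an (ordered) gene pair; gene order on the contig is not part of the
#' state.
#'
#' @param strand_a,strand_b strands (`"+"` or `"-"`) of the two genes, the
#'   pair ordered by family id.
#' @return orientation state, one of [orientation_states()].
#' @export
relative_orientation <- function(strand_a, strand_b) {
  stopifnot(all(strand_a %in% c("+", "-")), all(strand_b %in% c("+", "-")))
  paste0(strand_a, strand_b)
}

#' Enumerate the possible relative orientations of a gene pair
#'
#' @return character vector of the distinct orientation states.
#' @export
orientation_states <- function() {
  g <- expand.grid(a = c("+", "-"), b = c("+", "-"),
                   stringsAsFactors = FALSE)
  sort(unique(relative_orientation(g$a, g$b)))
}

# one representative ORF per family per contig: the longest, ties by orf_id
representative_orfs <- function(families, orfs) {
  m <- merge(families[, c("family_id", "orf_id")], orfs, by = "orf_id")
  m <- m[order(m$family_id, m$contig_id, -(m$end - m$start), m$orf_id), ,
         drop = FALSE]
  m[!duplicated(m[, c("family_id", "contig_id")]), , drop = FALSE]
}

#' Co-orientation score of a cassette
#'
#' For each unordered family pair in the cassette, every shared contig is
#' classified into one of the four relative orientations (strand of the
#' lower-id family first, read on the contig's forward strand); the pair's
#' score is the proportion of contigs showing the modal orientation, and the
#' cassette score is the mean over pairs. With orientations uniform at
#' random the score tends to 0.25 — the chance level against which observed
#' co-orientation is judged.
#'
#' @param cassette a cassette from [discover_cassettes()].
#' @param orfs ORF data frame; families need `family_id`/`orf_id` via the
#'   `families` argument.
#' @param families data frame from [cluster_families()].
#' @return score in \[0.25, 1\] (for >= 1 shared contig).
#' @export
co_orientation_score <- function(cassette, orfs, families) {
  reps <- representative_orfs(families, orfs)
  reps <- reps[reps$family_id %in% cassette$families &
                 reps$contig_id %in% cassette$contig_set, , drop = FALSE]
  fams <- sort(cassette$families)
  pair_scores <- c()
  for (i in seq_len(length(fams) - 1)) {
    for (j in (i + 1):length(fams)) {
      a <- reps[reps$family_id == fams[i], , drop = FALSE]
      b <- reps[reps$family_id == fams[j], , drop = FALSE]
      shared <- intersect(a$contig_id, b$contig_id)
      if (length(shared) < 1) {
        stop(sprintf("families %s and %s share no contig inside the cassette",
                     fams[i], fams[j]), call. = FALSE)
      }
      sa <- a$strand[match(shared, a$contig_id)]
      sb <- b$strand[match(shared, b$contig_id)]
      states <- relative_orientation(sa, sb)
      pair_scores <- c(pair_scores, max(table(states)) / length(states))
    }
  }
  mean(pair_scores)
}

#' Per-contig span statistics of a cassette
#'
#' For every contig the cassette occupies, the length of the union of its
#' member ORF intervals (overlaps counted once) and the fraction of the
#' contig covered.
#'
#' @param cassette a cassette from [discover_cassettes()].
#' @param orfs ORF data frame.
#' @param families data frame from [cluster_families()].
#' @param contigs contig data frame (for contig lengths).
#' @return data frame: `contig_id`, `covered_bp`, `covered_fraction`; the
#'   means across contigs are attached as attributes `mean_covered_bp` and
#'   `mean_covered_fraction`.
#' @export
cassette_span_stats <- function(cassette, orfs, families, contigs) {
  m <- merge(families[families$family_id %in% cassette$families,
                      c("family_id", "orf_id")], orfs, by = "orf_id")
  m <- m[m$contig_id %in% cassette$contig_set, , drop = FALSE]
  clen <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  rows <- lapply(sort(cassette$contig_set), function(cid) {
    iv <- m[m$contig_id == cid, , drop = FALSE]
    covered <- if (nrow(iv) == 0) 0L else {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = iv$start + 1L, end = iv$end)
      )))
    }
    data.frame(contig_id = cid, covered_bp = covered,
               covered_fraction = covered / clen[[cid]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_covered_bp") <- mean(out$covered_bp)
  attr(out, "mean_covered_fraction") <- mean(out$covered_fraction)
  out
}

#' Summarize cassettes as a table
#'
#' @param cassettes list from [discover_cassettes()].
#' @param orfs ORF data frame.
#' @param families data frame from [cluster_families()].
#' @param contigs contig data frame.
#' @return data frame: one row per cassette with family/contig counts,
#'   co-orientation score and mean span.
#' @export
cassette_summary <- function(cassettes, orfs, families, contigs) {
  do.call(rbind, lapply(cassettes, function(cs) {
    span <- cassette_span_stats(cs, orfs, families, contigs)
    data.frame(
      cassette_id = cs$cassette_id,
      n_families = length(cs$families),
      n_contigs = length(cs$contig_set),
      co_orientation = co_orientation_score(cs, orfs, families),
      mean_covered_bp = attr(span, "mean_covered_bp"),
      mean_covered_fraction = attr(span, "mean_covered_fraction"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Export per-cassette diagram data as JSON
#'
#' Per contig: the ORF intervals of each member family with strand, for
#' drawing genome-organization diagrams.
#'
#' @param cassettes list from [discover_cassettes()].
#' @param orfs ORF data frame.
#' @param families data frame from [cluster_families()].
#' @param path output path.
#' @export
write_cassette_json <- function(cassettes, orfs, families, path) {
  payload <- lapply(cassettes, function(cs) {
    reps <- representative_orfs(families, orfs)
    reps <- reps[reps$family_id %in% cs$families &
                   reps$contig_id %in% cs$contig_set, , drop = FALSE]
    list(cassette_id = cs$cassette_id, families = cs$families,
         contigs = lapply(sort(cs$contig_set), function(cid) {
           iv <- reps[reps$contig_id == cid, , drop = FALSE]
           list(contig_id = cid,
                orfs = lapply(seq_len(nrow(iv)), function(r) {
                  list(family = iv$family_id[r], start = iv$start[r],
                       end = iv$end[r], strand = iv$strand[r])
                }))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
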