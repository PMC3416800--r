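#' Translate a nucleotide sequence
#'
#' Standard genetic code; a terminal stop codon is dropped, internal stops
#' translate to `*`.
#'
#' @param nt_seq nucleotide string, length divisible by 3, ACGT only.
#' @return amino-acid string.
#' @export
translate_nt <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  if (nchar(nt_seq) %% 3 != 0) {
    stop("sequence length is not divisible by 3", call. = FALSE)
  }
  nt_seq <- check_nucleotides(nt_seq, "sequence")
  if (grepl("N", nt_seq, fixed = TRUE)) {
    stop("sequence contains N; only ACGT can be translated", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt_seq)))
  sub("\\*$", "", aa)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs on the forward strand of one linear-scanned sequence; returns
# 0-based half-open [start, end) on that sequence's own axis
scan_frames <- function(seq, min_orf_len, start_codons) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    n_codons <- (n - f) %/% 3
    if (n_codons < 2) next
    starts <- f + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, starts + 1L, starts + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% start_codons
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (si in stop_idx) {
      if (si - prev_stop < 2L) { prev_stop <- si; next }
      cand <- which(is_start[(prev_stop + 1L):(si - 1L)])
      if (length(cand) > 0) {
        atg <- prev_stop + cand[1L]  # maximal span: first start after a stop
        len_nt <- (si - atg + 1L) * 3L
        if (len_nt >= min_orf_len) {
          out[[length(out) + 1L]] <- c(start = starts[atg], end = starts[si] + 3L)
        }
      }
      prev_stop <- si
    }
  }
  out
}

#' Call ORFs on contigs
#'
#' A deterministic six-frame caller: every maximal start-to-stop span of at
#' least `min_orf_len` nucleotides (stop included) in any of the six reading
#' frames, under the standard genetic code. On circular contigs frames are
#' read across the junction; a wrapped ORF is reported with `end` past the
#' contig length. Minus-strand ORFs are reported on the forward axis with
#' `start < end`. Coordinates are 0-based half-open.
#'
#' @param contigs contig data frame (`contig_id`, `sequence`, `is_circular`).
#' @param min_orf_len minimum ORF length in nucleotides, stop codon included.
#' @param start_codons allowed start codons (ATG only by default, for
#'   determinism over sensitivity).
#' @return data frame: `orf_id`, `contig_id`, `start`, `end`, `strand`,
#'   `length_nt`, `aa_seq`.
#' @export
call_orfs <- function(contigs, min_orf_len = 100L, start_codons = "ATG") {
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$sequence[i]
    L <- nchar(s)
    circ <- isTRUE(contigs$is_circular[i])
    scan_seq <- if (circ) paste0(s, s) else s
    found <- list()
    # forward strand
    for (h in scan_frames(scan_seq, min_orf_len, start_codons)) {
      st <- unname(h["start"]); en <- unname(h["end"])
      if (circ && (st >= L || en - st > L)) next
      found[[length(found) + 1L]] <- list(start = st, end = en, strand = "+")
    }
    # reverse strand: scan the reverse complement, map back to forward axis
    rc <- revcomp(scan_seq)
    RL <- nchar(scan_seq)
    for (h in scan_frames(rc, min_orf_len, start_codons)) {
      st_rc <- unname(h["start"]); en_rc <- unname(h["end"])
      st <- RL - en_rc
      en <- RL - st_rc
      if (circ) {
        if (en - st > L) next
        st_m <- st %% L
        found[[length(found) + 1L]] <- list(start = st_m,
                                            end = st_m + (en - st),
                                            strand = "-")
      } else {
        found[[length(found) + 1L]] <- list(start = st, end = en,
                                            strand = "-")
      }
    }
    if (length(found) == 0) next
    df <- do.call(rbind, lapply(found, function(x) {
      data.frame(start = x$start, end = x$end, strand = x$strand,
                 stringsAsFactors = FALSE)
    }))
    df <- unique(df)
    df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
    df$contig_id <- contigs$contig_id[i]
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), length_nt = integer(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  seq_by_id <- stats::setNames(contigs$sequence, contigs$contig_id)
  circ_by_id <- stats::setNames(contigs$is_circular, contigs$contig_id)
  nt <- vapply(seq_len(nrow(orfs)), function(j) {
    orf_nt_seq(seq_by_id[[orfs$contig_id[j]]], orfs$start[j], orfs$end[j],
               orfs$strand[j], circ_by_id[[orfs$contig_id[j]]])
  }, "")
  orfs$length_nt <- orfs$end - orfs$start
  orfs$aa_seq <- vapply(nt, translate_nt, "", USE.NAMES = FALSE)
  orfs$orf_id <- sprintf("%s_orf%03d", orfs$contig_id,
                         stats::ave(seq_len(nrow(orfs)), orfs$contig_id,
                                    FUN = seq_along))
  rownames(orfs) <- NULL
  orfs[, c("orf_id", "contig_id", "start", "end", "strand", "length_nt",
           "aa_seq")]
}

# forward-strand nucleotide sequence of an ORF interval, then orient by strand
orf_nt_seq <- function(contig_seq, start, end, strand, circular) {
  L <- nchar(contig_seq)
  src <- if (isTRUE(circular)) paste0(contig_seq, contig_seq) else contig_seq
  s <- substr(src, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Export ORFs as a BED file
#'
#' 0-based half-open intervals with a strand column.
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @param path output path.
#' @export
write_orfs_bed <- function(orfs, path) {
  bed <- data.frame(orfs$contig_id, orfs$start, orfs$end, orfs$orf_id,
                    0L, orfs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export ORF translations as protein FASTA
#'
#' Headers carry the contig, coordinates and strand.
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @param path output path.
#' @export
write_orfs_faa <- function(orfs, path) {
  set <- Biostrings::AAStringSet(orfs$aa_seq)
  names(set) <- sprintf("%s %s:%d-%d(%s)", orfs$orf_id, orfs$contig_id,
                        orfs$start, orfs$end, orfs$strand)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
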