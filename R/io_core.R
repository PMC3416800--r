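#' Construct a set of read pairs
#'
#' A `ReadSet` is a data frame with one row per read pair: `read_id`, the two
#' mate sequences `seq1`/`seq2` (ACGTN, uppercased on ingest) and optional
#' phred quality strings `qual1`/`qual2`. Extra columns (e.g. the simulator's
#' `origin`) are carried along untouched.
#'
#' @param read_id character vector of unique pair identifiers.
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 optional quality strings, same lengths as the mates.
#' @return a `ReadSet` data frame.
#' @export
read_set <- function(read_id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  if (anyDuplicated(read_id)) {
    stop("read ids must be unique within a ReadSet", call. = FALSE)
  }
  seq1 <- check_nucleotides(seq1, "read")
  seq2 <- check_nucleotides(seq2, "read")
  if (length(seq1) != length(read_id) || length(seq2) != length(read_id)) {
    stop("read_id, seq1 and seq2 must have equal lengths", call. = FALSE)
  }
  if (!is.null(qual1) && any(nchar(qual1) != nchar(seq1))) {
    stop("qual1 lengths do not match seq1 lengths", call. = FALSE)
  }
  if (!is.null(qual2) && any(nchar(qual2) != nchar(seq2))) {
    stop("qual2 lengths do not match seq2 lengths", call. = FALSE)
  }
  out <- data.frame(
    read_id = as.character(read_id),
    seq1 = seq1, seq2 = seq2,
    qual1 = if (is.null(qual1)) NA_character_ else as.character(qual1),
    qual2 = if (is.null(qual2)) NA_character_ else as.character(qual2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ReadSet", "data.frame")
  out
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d read pairs (%d reads)\n", nrow(x), 2L * nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  read length range: %d-%d\n",
                min(nchar(x$seq1), nchar(x$seq2)),
                max(nchar(x$seq1), nchar(x$seq2))))
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0) {
    stop(sprintf("empty FASTA file: '%s' (no records at line 1)", path),
         call. = FALSE)
  }
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# parse one FASTQ file into a data.frame(id, seq, qual)
parse_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    seq = toupper(as.character(set)),
    qual = as.character(S4Vectors::mcols(set)$qualities),
    stringsAsFactors = FALSE
  )
}

strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

#' Read paired-end FASTQ
#'
#' Reads either two matched files (mates pair by order; `/1`,`/2` id suffixes
#' are stripped) or a single interleaved file (odd records are first mates).
#'
#' @param path1 first-mate FASTQ, or the interleaved file.
#' @param path2 second-mate FASTQ; omit when `interleaved = TRUE`.
#' @param interleaved set to `TRUE` for a single interleaved file. Layout is
#'   declared by this flag, never sniffed from content.
#' @return a [read_set()].
#' @export
read_fastq_pairs <- function(path1, path2 = NULL, interleaved = FALSE) {
  if (interleaved) {
    rec <- parse_fastq(path1)
    if (nrow(rec) %% 2 != 0) {
      stop(sprintf("pairing error: interleaved file '%s' has %d records (odd)",
                   path1, nrow(rec)), call. = FALSE)
    }
    i1 <- seq(1L, nrow(rec), by = 2L)
    r1 <- rec[i1, ]
    r2 <- rec[i1 + 1L, ]
  } else {
    if (is.null(path2)) stop("path2 required unless interleaved", call. = FALSE)
    r1 <- parse_fastq(path1)
    r2 <- parse_fastq(path2)
    if (nrow(r1) != nrow(r2)) {
      stop(sprintf("pairing error: %d records in '%s' vs %d in '%s'",
                   nrow(r1), path1, nrow(r2), path2), call. = FALSE)
    }
  }
  read_set(strip_mate_suffix(r1$id), r1$seq, r2$seq, r1$qual, r2$qual)
}

#' Write a ReadSet as paired FASTQ
#'
#' @param reads a [read_set()].
#' @param path1,path2 output paths for the two mate files.
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  write_one <- function(seqs, quals, ids, path) {
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- ids
    if (all(is.na(quals))) quals <- strrep("I", nchar(seqs))
    Biostrings::writeXStringSet(
      set, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals)
    )
  }
  write_one(reads$seq1, reads$qual1, paste0(reads$read_id, "/1"), path1)
  write_one(reads$seq2, reads$qual2, paste0(reads$read_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read a tab-separated homology hit table
#'
#' Consumes the 4-column subset of tabular protein-search output
#' (`orf_id`, `protein_id`, `evalue`, `bitscore`); extra columns are ignored
#' and `#` comment lines skipped. This table is the product of an external
#' search program; the package never produces it.
#'
#' @param path path to the TSV file.
#' @return data frame of hit records with non-negative numeric e-values.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(orf_id = character(), protein_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop(sprintf("parse error at line %d: fewer than 4 tab-separated fields",
                 lineno[which(nf < 4)[1L]]), call. = FALSE)
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  bs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L)))
  if (anyNA(ev)) {
    stop(sprintf("parse error at line %d: non-numeric e-value",
                 lineno[which(is.na(ev))[1L]]), call. = FALSE)
  }
  if (anyNA(bs)) {
    stop(sprintf("parse error at line %d: non-numeric bit score",
                 lineno[which(is.na(bs))[1L]]), call. = FALSE)
  }
  if (any(ev < 0)) {
    stop(sprintf("parse error at line %d: negative e-value",
                 lineno[which(ev < 0)[1L]]), call. = FALSE)
  }
  data.frame(
    orf_id = vapply(parts, `[`, "", 1L),
    protein_id = vapply(parts, `[`, "", 2L),
    evalue = ev, bitscore = bs,
    stringsAsFactors = FALSE
  )
}

#' Write contigs as FASTA with assembly metadata in the headers
#'
#' Headers carry `circular=`, `kmer=`, `reads=` and `iter=` tokens so the
#' provenance of each contig survives a round trip through FASTA.
#'
#' @param contigs a contig data frame (see [extract_contigs()]).
#' @param path output path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  hdr <- sprintf("%s circular=%s kmer=%s reads=%s iter=%s",
                 contigs$contig_id,
                 tolower(as.character(contigs$is_circular)),
                 contigs$kmer_used, contigs$read_support, contigs$iteration)
  seqs <- contigs$sequence
  names(seqs) <- hdr
  write_fasta(seqs, path)
}
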