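#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

normalize_read_id <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

#' Read short reads from FASTQ
#'
#' Reads one (single-end) or two (paired-end) Sanger Phred+33 FASTQ files
#' into a data frame with columns `id`, `mate`, `seq`, `qual`.  Mate IDs are
#' normalized so both mates of a pair share an `id` (trailing `/1`, `/2`
#' stripped) and carry mate numbers 1 and 2; single-end reads have mate 0.
#'
#' @param path FASTQ file (read 1 of a pair in paired mode).
#' @param path2 optional FASTQ file with the second mates.
#' @return data frame with columns `id`, `mate`, `seq`, `qual`.
#' @export
read_fastq <- function(path, path2 = NULL) {
  # records are read line-wise (4-line records) so that truncated records
  # and sequence/quality length mismatches can be rejected explicitly
  one <- function(p, mate) {
    lines <- readLines(p)
    if (length(lines) %% 4 != 0)
      stop("truncated FASTQ record in ", p)
    ids <- lines[seq_along(lines) %% 4 == 1]
    seq <- toupper(lines[seq_along(lines) %% 4 == 2])
    plus <- lines[seq_along(lines) %% 4 == 3]
    qual <- lines[seq_along(lines) %% 4 == 0]
    if (length(ids) &&
        (!all(startsWith(ids, "@")) || !all(startsWith(plus, "+"))))
      stop("malformed FASTQ record in ", p)
    if (any(nchar(seq) != nchar(qual)))
      stop("FASTQ record with differing sequence and quality lengths in ", p)
    if (any(grepl("[^\x21-\x7e]", qual)))
      stop("quality characters outside the Phred+33 range in ", p)
    data.frame(id = normalize_read_id(sub("^@", "", ids)), mate = mate,
               seq = seq, qual = qual, stringsAsFactors = FALSE)
  }
  if (is.null(path2)) return(one(path, 0L))
  r1 <- one(path, 1L)
  r2 <- one(path2, 2L)
  if (nrow(r1) != nrow(r2) || any(r1$id != r2$id))
    stop("paired FASTQ files do not correspond record-by-record")
  rbind(r1, r2)
}

#' Write reads to FASTQ
#'
#' @param reads data frame with columns `id`, `seq`, `qual` (and optionally
#'   `mate`; mate numbers are appended to IDs as `/1`, `/2`).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  ids <- reads$id
  if (!is.null(reads$mate)) {
    tag <- ifelse(reads$mate %in% c(1L, 2L), paste0("/", reads$mate), "")
    ids <- paste0(ids, tag)
  }
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# ---- insertion report ----------------------------------------------------

insertion_table_cols <- c("te_name", "chrom", "position", "tsd_seq",
                          "left_flankers", "right_flankers", "read_ids",
                          "upstream_seq", "downstream_seq")

#' Write the non-reference insertion report
#'
#' One row per insertion call: TE name, chromosome, the 1-based inclusive
#' TSD span rendered `chrom:start..end`, the TSD sequence, left/right
#' flanker counts, the supporting read IDs, and `flank_len` bp of reference
#' sequence on each side of the target site (clipped at contig ends) for
#' primer design.
#'
#' @param calls insertion calls as returned by [call_insertions()].
#' @param reference named character vector of reference sequences.
#' @param path output file.
#' @param flank_len bp of flanking reference sequence to report per side.
#' @return the path, invisibly.
#' @export
write_insertion_table <- function(calls, reference, path, flank_len = 100) {
  if (is.null(calls) || nrow(calls) == 0) {
    out <- setNames(as.data.frame(matrix(character(0), 0,
                                         length(insertion_table_cols))),
                    insertion_table_cols)
  } else {
    bad <- !(calls$chrom %in% names(reference)) |
      calls$tsd_start < 1 |
      calls$tsd_end > nchar(reference)[match(calls$chrom, names(reference))]
    bad[is.na(bad)] <- TRUE
    if (any(bad))
      stop("call coordinates outside reference: ",
           paste0(calls$chrom[bad], ":", calls$tsd_start[bad], "..",
                  calls$tsd_end[bad], collapse = ", "))
    up <- substr(reference[calls$chrom],
                 pmax(1, calls$tsd_start - flank_len), calls$tsd_start - 1)
    dn <- substr(reference[calls$chrom], calls$tsd_end + 1,
                 pmin(nchar(reference[calls$chrom]), calls$tsd_end + flank_len))
    out <- data.frame(
      te_name = calls$te_name,
      chrom = calls$chrom,
      position = sprintf("%s:%d..%d", calls$chrom, calls$tsd_start,
                         calls$tsd_end),
      tsd_seq = calls$tsd_seq,
      left_flankers = calls$left_count,
      right_flankers = calls$right_count,
      read_ids = calls$read_ids,
      upstream_seq = unname(up),
      downstream_seq = unname(dn),
      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a non-reference insertion report
#'
#' @param path a file written by [write_insertion_table()].
#' @return data frame of insertion calls with the TSD span split back into
#'   `chrom`, `tsd_start`, `tsd_end` plus counts and read IDs.
#' @export
read_insertion_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(position = "character"))
  if (nrow(tab) == 0) {
    return(empty_df(te_name = character(0), chrom = character(0),
                    tsd_start = integer(0), tsd_end = integer(0),
                    tsd_seq = character(0), left_count = integer(0),
                    right_count = integer(0), te_strand = character(0),
                    read_ids = character(0)))
  }
  m <- regmatches(tab$position,
                  regexec("^(.+):([0-9]+)\\.\\.([0-9]+)$", tab$position))
  if (any(lengths(m) != 4))
    stop("malformed position field in ", path)
  data.frame(
    te_name = tab$te_name,
    chrom = vapply(m, `[`, "", 2),
    tsd_start = as.integer(vapply(m, `[`, "", 3)),
    tsd_end = as.integer(vapply(m, `[`, "", 4)),
    tsd_seq = tab$tsd_seq,
    left_count = as.numeric(tab$left_flankers),
    right_count = as.numeric(tab$right_flankers),
    te_strand = ".",
    read_ids = tab$read_ids,
    stringsAsFactors = FALSE)
}

# ---- GFF3 ----------------------------------------------------------------

#' Write TE features to GFF3
#'
#' Features (reference/shared/reference-only TE copies and non-reference
#' insertion calls) are written as valid GFF3 with 1-based inclusive
#' coordinates, the TE name as the source column and the class label in the
#' attributes, in a stable order (chromosome, then start).
#'
#' @param features data frame with columns `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `.`), `class` and `te_name` (optionally `type`).
#' @param path output GFF3 file.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = strand)
  S4Vectors::mcols(gr)$source <- features$te_name
  S4Vectors::mcols(gr)$type <-
    features$type %||% rep("transposable_element_insertion_site",
                           nrow(features))
  S4Vectors::mcols(gr)$class <- features$class
  S4Vectors::mcols(gr)$ID <-
    sprintf("%s_%s_%d_%d", features$te_name, features$chrom,
            features$start, features$end)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- alignment records (SAM dialect) -------------------------------------

#' Write alignment records as SAM
#'
#' @param aln alignment data frame (columns `id`, `chrom`, `pos`, `strand`,
#'   `cigar`, `edit`, `ambiguous`; optionally `seq` and `qual`).
#' @param ref_lengths named integer vector of reference sequence lengths.
#' @param path output `.sam` file.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  if (nrow(aln) > 0) {
    aln <- aln[order(match(aln$chrom, names(ref_lengths)), aln$pos), ,
               drop = FALSE]
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    mapq <- ifelse(aln$ambiguous, 0L, 60L)
    seq <- if (!is.null(aln$seq)) {
      ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq)
    } else rep("*", nrow(aln))
    qual <- if (!is.null(aln$qual)) {
      ifelse(aln$strand == "-",
             vapply(strsplit(aln$qual, ""), function(q)
               paste(rev(q), collapse = ""), ""),
             aln$qual)
    } else rep("*", nrow(aln))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       aln$id, flag, aln$chrom, aln$pos, mapq, aln$cigar,
                       seq, qual, as.integer(aln$edit)), con)
  }
  invisible(path)
}

#' Read alignment records from SAM or BAM
#'
#' Ingests a coordinate-sorted alignment file into the internal alignment
#' data frame used for spanner counting and footprint detection.  Records
#' with mapping quality 0 are flagged ambiguous and excluded from spanner
#' counts.
#'
#' @param path a `.sam` or `.bam` file.
#' @return data frame with columns `id`, `chrom`, `pos`, `end`, `strand`,
#'   `cigar`, `ambiguous`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq")))
  data.frame(
    id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    ambiguous = !is.na(S4Vectors::mcols(ga)$mapq) &
      S4Vectors::mcols(ga)$mapq == 0L,
    stringsAsFactors = FALSE)
}
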