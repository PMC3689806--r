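#' Quality-trim reads from the 3' end
#'
#' Removes the maximal 3' suffix of low-quality bases: trimming stops at
#' the first base from the 3' end whose Phred score is at least
#' `trim_threshold`.  Reads shorter than `min_len` after trimming are
#' discarded.
#'
#' @param reads data frame with `seq` and `qual` (Phred+33).
#' @param trim_threshold Phred threshold (default 20).
#' @param min_len minimum retained length (default 50).
#' @return trimmed subset of `reads`.
#' @export
quality_trim <- function(reads, trim_threshold = 20, min_len = 50) {
  if (nrow(reads) == 0) return(reads)
  keep_len <- vapply(phred_scores(reads$qual), function(q) {
    hi <- which(q >= trim_threshold)
    if (length(hi) == 0) 0L else max(hi)
  }, 0L)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  out <- reads[keep_len >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quality-filter reads by the fraction of high-quality bases
#'
#' Keeps a read iff at least `min_fraction` percent of its bases have Phred
#' score `filter_threshold` or higher (boundary inclusive).  Empty reads
#' are discarded.
#'
#' @param reads data frame with `seq` and `qual`.
#' @param filter_threshold Phred threshold (default 20).
#' @param min_fraction minimum percentage of bases at or above the
#'   threshold (default 80).
#' @return the surviving subset of `reads`.
#' @export
quality_filter <- function(reads, filter_threshold = 20, min_fraction = 80) {
  if (nrow(reads) == 0) return(reads)
  frac <- vapply(phred_scores(reads$qual), function(q) {
    if (length(q) == 0) return(-1)
    100 * sum(q >= filter_threshold) / length(q)
  }, 0)
  out <- reads[frac >= min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-synchronize mates after per-read filtering
#'
#' Pairs where both mates survived are returned as the paired stream;
#' survivors whose mate was discarded become singletons.
#'
#' @param reads data frame with `id` and `mate` (1/2) columns.
#' @return list with elements `paired` and `singletons`.
#' @export
sync_mates <- function(reads) {
  stopifnot(all(reads$mate %in% c(1L, 2L)))
  for (m in c(1L, 2L)) {
    ids <- reads$id[reads$mate == m]
    if (anyDuplicated(ids))
      stop("duplicate read IDs within mate ", m, " file: ",
           paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  ids1 <- reads$id[reads$mate == 1L]
  ids2 <- reads$id[reads$mate == 2L]
  both <- intersect(ids1, ids2)
  paired <- reads[reads$id %in% both, , drop = FALSE]
  paired <- paired[order(match(paired$id, both), paired$mate), , drop = FALSE]
  singles <- reads[!(reads$id %in% both), , drop = FALSE]
  rownames(paired) <- rownames(singles) <- NULL
  list(paired = paired, singletons = singles)
}

#' Align whole reads to the reference with small-indel support
#'
#' Places each read at its best location on the reference, allowing
#' mismatches and short indels within a band wide enough to represent
#' excision footprints.  Reads with more than one best placement are kept
#' but flagged `ambiguous` (they are excluded from spanner counting);
#' reads whose best alignment exceeds `max_edit` edits are dropped.
#' Alignments record matches and mismatches separately (`=`/`X` CIGAR
#' ops), which downstream spanner counting exploits.
#' The result is coordinate-sorted.
#'
#' @param reads data frame with `id`, `seq`, `qual` (and optionally
#'   `mate`).
#' @param reference named character vector of reference sequences.
#' @param band maximum indel extent representable (default 12; keep at
#'   least TSD width + 3).
#' @param max_edit maximum edit distance of a retained alignment
#'   (default 5, the conventional short-read budget for a 100-bp read;
#'   also bounds the largest representable footprint).
#' @param kmer seed length for candidate lookup (default 16).
#' @return coordinate-sorted alignment data frame: `id`, `chrom`, `pos`,
#'   `end`, `strand`, `cigar`, `edit`, `ambiguous`, `seq`, `qual`.
#' @export
align_whole_reads <- function(reads, reference, band = 12, max_edit = 5,
                              kmer = 16) {
  max_edit <- max_edit %||% band
  empty <- empty_df(id = character(0), chrom = character(0),
                    pos = integer(0), end = integer(0),
                    strand = character(0), cigar = character(0),
                    edit = integer(0), ambiguous = logical(0),
                    seq = character(0), qual = character(0))
  if (nrow(reads) == 0) return(empty)
  hits <- align_gapped_cpp(toupper(reads$seq), unname(reference),
                           as.integer(kmer), as.integer(band),
                           as.integer(max_edit))
  keep <- !is.na(hits$pos)
  if (!any(keep)) return(empty)
  r <- reads[keep, , drop = FALSE]
  h <- hits[keep, , drop = FALSE]
  mate_tag <- if (!is.null(r$mate)) {
    ifelse(r$mate %in% c(1L, 2L), paste0("/", r$mate), "")
  } else ""
  out <- data.frame(
    id = paste0(r$id, mate_tag),
    chrom = names(reference)[h$chrom],
    pos = h$pos,
    end = h$pos +
      GenomicAlignments::cigarWidthAlongReferenceSpace(h$cigar) - 1L,
    strand = h$strand,
    cigar = h$cigar,
    edit = h$edit,
    ambiguous = h$n_best > 1L,
    seq = r$seq,
    qual = r$qual,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split FASTQ input into fixed-size partitions
#'
#' Sequential chunking that preserves read order and mate adjacency (paired
#' files are chunked in lockstep), so that processing the partitions and
#' concatenating results is identical to processing the whole input.
#'
#' @param path FASTQ file.
#' @param chunk reads per partition (default 1e6).
#' @param outdir directory for partition files (default: a temp dir).
#' @param path2 optional second-mate FASTQ, chunked in lockstep.
#' @return data frame with columns `file1` (and `file2` in paired mode).
#' @export
partition_reads <- function(path, chunk = 1e6, outdir = tempfile("parts"),
                            path2 = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  split_one <- function(p, tag) {
    lines <- readLines(p)
    if (length(lines) %% 4 != 0)
      stop("truncated FASTQ record in ", p)
    n_reads <- length(lines) / 4
    n_parts <- max(1L, ceiling(n_reads / chunk))
    part <- rep(seq_len(n_parts), each = chunk * 4)[seq_along(lines)]
    vapply(seq_len(n_parts), function(i) {
      f <- file.path(outdir, sprintf("%s_part%03d%s.fastq",
                                     sub("\\.f(ast)?q$", "", basename(p)),
                                     i, tag))
      writeLines(lines[part == i], f)
      f
    }, "")
  }
  f1 <- split_one(path, "")
  if (is.null(path2)) return(data.frame(file1 = f1, stringsAsFactors = FALSE))
  f2 <- split_one(path2, "")
  if (length(f1) != length(f2))
    stop("paired FASTQ files have different read counts")
  data.frame(file1 = f1, file2 = f2, stringsAsFactors = FALSE)
}

#' Quality-process raw reads and align them to the reference
#'
#' The preprocessing stage: 3'-quality trimming, quality filtering, mate
#' re-synchronization (paired input), and whole-read alignment to the
#' reference for spanner counting and footprint detection.  Singletons
#' whose mate was discarded are retained for alignment.
#'
#' @param reads data frame from [read_fastq()].
#' @param reference named character vector of reference sequences.
#' @param trim_threshold,min_len,filter_threshold,min_fraction quality
#'   parameters (defaults 20, 50, 20, 80).
#' @param band,max_edit,kmer see [align_whole_reads()].
#' @return list with `reads` (the surviving reads) and `alignments`
#'   (coordinate-sorted alignment data frame).
#' @export
preprocess_reads <- function(reads, reference, trim_threshold = 20,
                             min_len = 50, filter_threshold = 20,
                             min_fraction = 80, band = 12, max_edit = 5,
                             kmer = 16) {
  surv <- quality_filter(quality_trim(reads, trim_threshold, min_len),
                         filter_threshold, min_fraction)
  if (!is.null(surv$mate) && any(surv$mate %in% c(1L, 2L))) {
    sync <- sync_mates(surv)
    surv <- rbind(sync$paired, sync$singletons)
  }
  aln <- align_whole_reads(surv, reference, band = band,
                           max_edit = max_edit, kmer = kmer)
  list(reads = surv, alignments = aln)
}
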