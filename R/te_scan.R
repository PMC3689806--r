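#' Scan a single read for TE-matching segments
#'
#' Finds every maximal ungapped match between a read and the TE in both
#' orientations.  Matching is seeded by exact `seed_len`-mers taken at every
#' read position and extended in both directions; mismatches are extended
#' through as long as the final mismatch fraction of the committed window
#' stays within `allowance`.  Only matches of at least `min_aligned`
#' aligned bases are returned.  `N` bases never match.
#'
#' @param read a single read sequence (character) or one-row data frame with
#'   a `seq` column.
#' @param te a [te_model()].
#' @param seed_len exact seed length (default 7).
#' @param min_aligned minimum aligned length to report a match (default 10).
#' @param allowance maximum mismatch fraction, mismatches divided by aligned
#'   length (default 0: perfect matches only).
#' @return data frame of matches: `r_start`, `r_end` (1-based inclusive on
#'   the read), `t_start`, `t_end` (on the TE, forward coordinates),
#'   `strand` (`+` forward, `-` reverse complement), `mismatches`,
#'   `aligned_len`.
#' @export
scan_read_for_te <- function(read, te, seed_len = 7, min_aligned = 10,
                             allowance = 0) {
  seq <- if (is.data.frame(read)) read$seq else as.character(read)
  stopifnot(length(seq) == 1)
  out <- scan_reads_for_te(data.frame(id = "read", seq = seq,
                                      stringsAsFactors = FALSE),
                           te, seed_len, min_aligned, allowance)
  out[setdiff(names(out), c("read", "id"))]
}

#' Scan a set of reads for TE-matching segments
#'
#' Vectorized form of [scan_read_for_te()] over a read set.
#'
#' @param reads data frame with columns `id` and `seq` (e.g. from
#'   [read_fastq()]).
#' @inheritParams scan_read_for_te
#' @return data frame of matches with leading `read` (row index into
#'   `reads`) and `id` columns.
#' @export
scan_reads_for_te <- function(reads, te, seed_len = 7, min_aligned = 10,
                              allowance = 0) {
  stopifnot(inherits(te, "te_model"))
  m <- scan_reads_te_cpp(toupper(reads$seq), te$sequence,
                         as.integer(seed_len), as.integer(min_aligned),
                         as.numeric(allowance))
  m$id <- reads$id[m$read]
  m[c("read", "id", "r_start", "r_end", "t_start", "t_end", "strand",
      "mismatches", "aligned_len")]
}

#' Keep only TE matches anchored at a TE end
#'
#' A junction read must overlap the first or the last nucleotide of the TE;
#' internal matches carry no insertion-site information and are removed.
#' The retained matches are annotated with which TE end they touch
#' (`te_end`: `5p`, `3p`, or `both` for matches spanning the whole element).
#'
#' @param matches data frame from [scan_reads_for_te()].
#' @param te a [te_model()].
#' @return the end-anchored subset with a `te_end` column.
#' @export
end_anchor_filter <- function(matches, te) {
  stopifnot(inherits(te, "te_model"))
  at5 <- matches$t_start == 1L
  at3 <- matches$t_end == te$length
  keep <- matches[at5 | at3, , drop = FALSE]
  keep$te_end <- ifelse(at5[at5 | at3] & at3[at5 | at3], "both",
                        ifelse(at5[at5 | at3], "5p", "3p"))
  keep
}

#' Mismatch fraction of a TE match
#'
#' Mismatches divided by the number of aligned bases (matches plus
#' mismatches).  The caller filters matches whose fraction exceeds the
#' allowance; a fraction exactly equal to the allowance is retained.
#'
#' @param match data frame of matches with `mismatches` and `aligned_len`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
mismatch_fraction <- function(match) {
  stopifnot(all(match$aligned_len > 0))
  match$mismatches / match$aligned_len
}

#' Trim the TE-matching portion from a read
#'
#' Removes the matched interval and everything beyond it toward the TE-side
#' read end, retaining the contiguous genomic flank.  Reads that are all TE
#' are discarded (no flanking information); trimmed flanks must be strictly
#' longer than `min_len` to be retained.  A match internal to the read
#' (genomic sequence on both sides) is inconsistent with a junction read and
#' is rejected.
#'
#' @param read one-row data frame with `id`, `seq` (and optionally `qual`).
#' @param match one row of an end-anchored match table (with `te_end`).
#' @param min_len flanks must be strictly longer than this (default 10).
#' @return a one-row trimmed-read data frame (`id`, `seq`, `qual`,
#'   `trimmed_end`, `te_end`, `strand`), or `NULL` if discarded.
#' @export
trim_te_sequence <- function(read, match, min_len = 10) {
  L <- nchar(read$seq)
  r_start <- match$r_start
  r_end <- match$r_end
  if (r_start == 1L && r_end == L) return(NULL)        # all TE
  if (r_start > 1L && r_end < L) return(NULL)          # internal: not a junction
  if (r_start > 1L) {                                  # TE at read 3' end
    flank <- substr(read$seq, 1L, r_start - 1L)
    qual <- if (!is.null(read$qual)) substr(read$qual, 1L, r_start - 1L) else ""
    trimmed_end <- "end"
    # TE end adjacent to the flank: position t_start on + strand, t_end on -
    te_end <- adjacent_te_end(match, trimmed_end)
  } else {                                             # TE at read 5' end
    flank <- substr(read$seq, r_end + 1L, L)
    qual <- if (!is.null(read$qual)) substr(read$qual, r_end + 1L, L) else ""
    trimmed_end <- "start"
    te_end <- adjacent_te_end(match, trimmed_end)
  }
  if (nchar(flank) <= min_len) return(NULL)
  data.frame(id = read$id, seq = flank, qual = qual,
             trimmed_end = trimmed_end, te_end = te_end,
             strand = match$strand, stringsAsFactors = FALSE)
}

# which TE end sits against the retained flank
adjacent_te_end <- function(match, trimmed_end) {
  if (match$te_end != "both") return(match$te_end)
  if (trimmed_end == "end") {
    if (match$strand == "+") "5p" else "3p"
  } else {
    if (match$strand == "+") "3p" else "5p"
  }
}

#' Run the full TE scan/trim stage over a read set
#'
#' Scans reads for end-anchored TE matches, applies the mismatch-fraction
#' filter, and trims the TE-matching portion, producing the junction flanks
#' that are subsequently mapped to the reference.  A read with end-anchored
#' matches to both TE ends (a very short element) yields one trimmed read
#' per junction.
#'
#' @param reads data frame from [read_fastq()].
#' @param te a [te_model()].
#' @param seed_len,min_aligned,allowance see [scan_read_for_te()].
#' @param min_trimmed_len trimmed flanks must be strictly longer than this.
#' @return data frame of trimmed reads (`id`, `seq`, `qual`, `trimmed_end`,
#'   `te_end`, `strand`) with a `stats` attribute of per-stage counts.
#' @export
te_scan <- function(reads, te, seed_len = 7, min_aligned = 10,
                    allowance = 0, min_trimmed_len = 10) {
  matches <- scan_reads_for_te(reads, te, seed_len, min_aligned, allowance)
  anchored <- end_anchor_filter(matches, te)
  anchored <- anchored[mismatch_fraction(anchored) <= allowance, ,
                       drop = FALSE]
  out <- vector("list", nrow(anchored))
  for (k in seq_len(nrow(anchored))) {
    out[[k]] <- trim_te_sequence(reads[anchored$read[k], , drop = FALSE],
                                 anchored[k, , drop = FALSE],
                                 min_len = min_trimmed_len)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  trimmed <- if (length(out)) do.call(rbind, out) else
    empty_df(id = character(0), seq = character(0), qual = character(0),
             trimmed_end = character(0), te_end = character(0),
             strand = character(0))
  trimmed <- unique(trimmed)
  attr(trimmed, "stats") <- c(
    reads = nrow(reads), matched = length(unique(matches$read)),
    end_anchored = length(unique(anchored$read)), trimmed = nrow(trimmed))
  trimmed
}

#' Write trimmed reads as FASTA, tagging the trimmed read end
#'
#' Read names carry a `:start` / `:end` suffix recording which read end was
#' trimmed of TE sequence.
#'
#' @param trimmed data frame from [te_scan()].
#' @param path output FASTA file.
#' @export
write_trimmed_fasta <- function(trimmed, path) {
  seqs <- setNames(trimmed$seq, paste0(trimmed$id, ":", trimmed$trimmed_end))
  write_fasta(seqs, path)
}
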