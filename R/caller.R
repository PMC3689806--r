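#' Map trimmed junction flanks to the reference
#'
#' Each trimmed read is placed at its best-scoring ungapped location on the
#' reference (both strands, exhaustive).  Reads with more than one
#' best-scoring location are dropped (unique mapping required), as are
#' placements with more than `max_mismatch` mismatches.  The junction side
#' each flank supports is a pure function of which read end was trimmed and
#' the alignment strand: a read trimmed at its end aligning `+` (or trimmed
#' at its start aligning `-`) sits to the LEFT of the insertion point; the
#' mirror cases are RIGHT flankers.
#'
#' In paired mode, a read whose own placement is ambiguous can be rescued by
#' its mate: if `mate_anchor` supplies a unique position for the mate, the
#' ambiguous read is kept only when re-evaluation finds a single best
#' placement within `insert_max` of the mate.  Duplicate placements of the
#' same read are collapsed.
#'
#' @param trimmed trimmed reads from [te_scan()].
#' @param reference named character vector of reference sequences.
#' @param max_mismatch maximum mismatches for a retained placement
#'   (default 3).
#' @param mate_anchor optional data frame (`id`, `chrom`, `pos`) of unique
#'   mate placements for paired rescue.
#' @param insert_max maximum read-to-mate distance for rescue (default 500).
#' @return data frame of flanker alignments: `id`, `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `side` (`left`/`right`), `te_end`,
#'   `trimmed_end`.
#' @export
align_trimmed_reads <- function(trimmed, reference, max_mismatch = 3,
                                mate_anchor = NULL, insert_max = 500) {
  empty <- empty_df(id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), mismatches = integer(0),
                    side = character(0), te_end = character(0),
                    trimmed_end = character(0))
  if (nrow(trimmed) == 0) return(empty)
  hits <- align_ungapped_cpp(toupper(trimmed$seq), unname(reference),
                             as.integer(max_mismatch))
  keep <- !is.na(hits$pos) & hits$n_best == 1L
  rescued <- rescue_by_mate(trimmed, hits, reference, max_mismatch,
                            mate_anchor, insert_max)
  if (!is.null(rescued)) {
    hits[rescued$row, c("chrom", "pos", "strand", "mismatches", "n_best")] <-
      rescued[c("chrom", "pos", "strand", "mismatches", "n_best")]
    keep[rescued$row] <- TRUE
  }
  if (!any(keep)) return(empty)
  t <- trimmed[keep, , drop = FALSE]
  h <- hits[keep, , drop = FALSE]
  out <- data.frame(
    id = t$id,
    chrom = names(reference)[h$chrom],
    start = h$pos,
    end = h$pos + nchar(t$seq) - 1L,
    strand = h$strand,
    mismatches = h$mismatches,
    side = flanker_side(t$trimmed_end, h$strand),
    te_end = t$te_end,
    trimmed_end = t$trimmed_end,
    stringsAsFactors = FALSE)
  unique(out)
}

flanker_side <- function(trimmed_end, strand) {
  ifelse((trimmed_end == "end" & strand == "+") |
           (trimmed_end == "start" & strand == "-"), "left", "right")
}

# paired rescue: re-place multi-best reads restricted to a window around the
# unique placement of their mate
rescue_by_mate <- function(trimmed, hits, reference, max_mismatch,
                           mate_anchor, insert_max) {
  if (is.null(mate_anchor) || nrow(mate_anchor) == 0) return(NULL)
  amb <- which(!is.na(hits$pos) & hits$n_best > 1L)
  amb <- amb[trimmed$id[amb] %in% mate_anchor$id]
  if (length(amb) == 0) return(NULL)
  res <- lapply(amb, function(k) {
    anchor <- mate_anchor[match(trimmed$id[k], mate_anchor$id), ]
    g <- reference[[anchor$chrom]]
    lo <- max(1L, anchor$pos - insert_max)
    hi <- min(nchar(g), anchor$pos + insert_max)
    win <- substr(g, lo, hi)
    sub <- align_ungapped_cpp(toupper(trimmed$seq[k]), win,
                              as.integer(max_mismatch))
    if (is.na(sub$pos[1]) || sub$n_best[1] != 1L) return(NULL)
    data.frame(row = k, chrom = match(anchor$chrom, names(reference)),
               pos = lo + sub$pos[1] - 1L, strand = sub$strand[1],
               mismatches = sub$mismatches[1], n_best = 1L,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

#' Cluster flanker alignments by interval overlap
#'
#' Single-linkage clustering over alignment overlap on the reference:
#' alignments sharing at least one base (directly or transitively) form one
#' cluster, labelled as putatively belonging to a single insertion event.
#'
#' @param alignments flanker alignments from [align_trimmed_reads()].
#' @return the alignments sorted by chromosome then start, with an integer
#'   `cluster` column.
#' @export
cluster_flankers <- function(alignments) {
  if (nrow(alignments) == 0) {
    alignments$cluster <- integer(0)
    return(alignments)
  }
  a <- alignments[order(alignments$chrom, alignments$start,
                        alignments$end), , drop = FALSE]
  cl <- integer(nrow(a))
  cur <- 0L
  max_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(a))) {
    if (a$chrom[i] != last_chrom || a$start[i] > max_end) {
      cur <- cur + 1L
      max_end <- a$end[i]
      last_chrom <- a$chrom[i]
    } else {
      max_end <- max(max_end, a$end[i])
    }
    cl[i] <- cur
  }
  a$cluster <- cl
  rownames(a) <- NULL
  a
}

#' Find perfect TSD overlaps within a flanker cluster
#'
#' Only the TE-trimmed end of each flank is informative: a left flanker's
#' terminal TSD-width window at its high-coordinate (TE-adjacent) end and a
#' right flanker's initial window at its low-coordinate end must occupy the
#' identical reference interval, and the reference sequence there must
#' satisfy the TSD matcher (for exact/pattern TSDs, either strand rendering
#' is accepted).
#'
#' @param cluster one cluster's rows from [cluster_flankers()].
#' @param tsd a `tsd_matcher` (see [parse_tsd_spec()]).
#' @param reference named character vector of reference sequences.
#' @return data frame of satisfying TSD windows (`chrom`, `tsd_start`,
#'   `tsd_end`, `tsd_seq`, `left_count`, `right_count`, `read_ids`,
#'   `te_strand`), zero rows when no perfect overlap exists.
#' @export
find_tsd_overlap <- function(cluster, tsd, reference) {
  w <- tsd$width
  empty <- empty_df(chrom = character(0), tsd_start = integer(0),
                    tsd_end = integer(0), tsd_seq = character(0),
                    left_count = integer(0), right_count = integer(0),
                    read_ids = character(0), te_strand = character(0))
  left <- cluster[cluster$side == "left", , drop = FALSE]
  right <- cluster[cluster$side == "right", , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  # TE-adjacent windows, only valid when the flank is at least TSD wide
  left <- left[left$end - left$start + 1L >= w, , drop = FALSE]
  right <- right[right$end - right$start + 1L >= w, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(empty)
  left$win_start <- left$end - w + 1L
  right$win_start <- right$start
  starts <- sort(intersect(left$win_start, right$win_start))
  if (length(starts) == 0) return(empty)
  chrom <- cluster$chrom[1]
  out <- lapply(starts, function(s) {
    seq <- substr(reference[[chrom]], s, s + w - 1L)
    if (nchar(seq) < w) return(NULL)
    if (!tsd_matches(tsd, seq, both_strands = TRUE)) return(NULL)
    l <- left[left$win_start == s, , drop = FALSE]
    r <- right[right$win_start == s, , drop = FALSE]
    strands <- unique(c(te_strand_of(l$side, l$te_end),
                        te_strand_of(r$side, r$te_end)))
    strands <- strands[!is.na(strands)]
    data.frame(chrom = chrom, tsd_start = s, tsd_end = s + w - 1L,
               tsd_seq = seq, left_count = nrow(l), right_count = nrow(r),
               read_ids = paste(sort(unique(c(l$id, r$id))), collapse = ","),
               te_strand = if (length(strands) == 1) strands else ".",
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

# orientation of the inserted element implied by (junction side, TE end)
te_strand_of <- function(side, te_end) {
  ifelse(te_end == "both", NA_character_,
         ifelse((side == "left" & te_end == "5p") |
                  (side == "right" & te_end == "3p"), "+", "-"))
}

#' Call non-reference insertions from flanker clusters
#'
#' A non-reference insertion is emitted for every TSD window supported by
#' two or more reads, at least one left and one right flanker, in perfect
#' TSD overlap.  A cluster containing several disjoint satisfying windows
#' (tandem events) yields one call per window.  The insertion position is
#' the full target-site span; `last_base` additionally exposes the
#' coordinate of the last base of the target site.
#'
#' @param clusters clustered alignments from [cluster_flankers()].
#' @param tsd a `tsd_matcher`.
#' @param reference named character vector of reference sequences.
#' @param te_name element name stamped on each call.
#' @return data frame of insertion calls (`te_name`, `chrom`, `tsd_start`,
#'   `tsd_end`, `tsd_seq`, `left_count`, `right_count`, `te_strand`,
#'   `read_ids`, `last_base`).
#' @export
call_insertions <- function(clusters, tsd, reference, te_name = "TE") {
  empty <- empty_df(te_name = character(0), chrom = character(0),
                    tsd_start = integer(0), tsd_end = integer(0),
                    tsd_seq = character(0), left_count = integer(0),
                    right_count = integer(0), te_strand = character(0),
                    read_ids = character(0), last_base = integer(0))
  if (nrow(clusters) == 0) return(empty)
  out <- lapply(split(clusters, clusters$cluster), find_tsd_overlap,
                tsd = tsd, reference = reference)
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0) return(empty)
  calls <- do.call(rbind, out)
  calls <- cbind(te_name = te_name, calls, last_base = calls$tsd_end,
                 stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$tsd_start), , drop = FALSE]
  rownames(calls) <- NULL
  stopifnot(all(calls$left_count >= 1), all(calls$right_count >= 1))
  calls
}

#' Locate full-length TE copies in the reference genome
#'
#' Scans both strands of the reference for copies of the element that are
#' very similar in length to the query (at least 90% of it present,
#' ungapped) with under 10% mismatches across the element.
#'
#' @param reference named character vector of reference sequences.
#' @param te a [te_model()].
#' @param max_mismatch_frac maximum mismatch fraction (default 0.10,
#'   exclusive).
#' @param min_length_frac minimum fraction of the TE length present
#'   (default 0.9, exclusive bound mirrored at 1.1 by the ungapped model).
#' @return data frame of reference copies: `chrom`, `start`, `end`,
#'   `strand`, `identity`, `length_fraction`.
#' @export
scan_reference_for_te <- function(reference, te, max_mismatch_frac = 0.10,
                                  min_length_frac = 0.9) {
  stopifnot(inherits(te, "te_model"))
  L <- te$length
  max_mm <- ceiling(max_mismatch_frac * L) - 1L
  pats <- list(`+` = te$sequence, `-` = revcomp(te$sequence))
  out <- list()
  for (chrom in names(reference)) {
    subj <- Biostrings::DNAString(reference[[chrom]])
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(pats[[strand]], subj,
                                    max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      mm <- vapply(as.character(m), function(s) {
        sum(strsplit(s, "")[[1]] != strsplit(pats[[strand]], "")[[1]])
      }, 0L)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = Biostrings::start(m),
        end = Biostrings::end(m), strand = strand,
        identity = 1 - mm / L,
        length_fraction = Biostrings::width(m) / L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(empty_df(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    identity = numeric(0), length_fraction = numeric(0)))
  copies <- do.call(rbind, out)
  copies <- copies[copies$length_fraction > min_length_frac &
                     copies$length_fraction < 2 - min_length_frac, ,
                   drop = FALSE]
  copies <- copies[order(copies$chrom, copies$start), , drop = FALSE]
  rownames(copies) <- NULL
  copies
}

#' Classify reference TE copies as shared or reference-only
#'
#' A reference copy is "shared" (present in the sequenced individual too) if
#' at least one TE-trimmed read aligns flanking either end of the copy;
#' complete lack of such reads marks it "reference-only", which may reflect
#' excision in the compared strain, a reference-specific insertion, or lack
#' of coverage.  Copies supported at only one end are classed shared and
#' flagged `one_ended`.
#'
#' @param copies reference copies from [scan_reference_for_te()].
#' @param flanker_aln flanker alignments from [align_trimmed_reads()].
#' @param tol maximum distance (bp) between a flank's TE-adjacent boundary
#'   and the copy boundary (default 1).
#' @return `copies` with `class`, `left_support`, `right_support`,
#'   `one_ended` columns.
#' @export
classify_reference_sites <- function(copies, flanker_aln, tol = 1) {
  n <- nrow(copies)
  copies$left_support <- integer(n)
  copies$right_support <- integer(n)
  for (i in seq_len(n)) {
    a <- flanker_aln[flanker_aln$chrom == copies$chrom[i], , drop = FALSE]
    copies$left_support[i] <-
      sum(a$side == "left" & abs(a$end - (copies$start[i] - 1L)) <= tol)
    copies$right_support[i] <-
      sum(a$side == "right" & abs(a$start - (copies$end[i] + 1L)) <= tol)
  }
  supported <- copies$left_support + copies$right_support > 0
  copies$class <- ifelse(supported, "shared", "reference-only")
  copies$one_ended <- supported &
    (copies$left_support == 0 | copies$right_support == 0)
  copies
}
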