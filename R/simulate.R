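#' Generate a pseudo-random reference genome
#'
#' @param seed RNG seed (reproducible output).
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome length(s), recycled to `n_chrom`.
#' @param gc GC content (default 0.5).
#' @param te optional [te_model()]; if given, `n_te_copies` full-length
#'   copies are planted at random non-overlapping positions (for
#'   reference-scan tests), recorded in the `te_copies` attribute.
#' @param n_te_copies number of reference TE copies to plant.
#' @return named character vector of chromosome sequences (`chr1`, ...),
#'   with a `te_copies` data frame attribute when copies were planted.
#' @export
generate_reference <- function(seed, n_chrom = 1, lengths = 1e5, gc = 0.5,
                               te = NULL, n_te_copies = 0) {
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_chrom)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""), "")
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  copies <- NULL
  if (!is.null(te) && n_te_copies > 0) {
    rows <- list()
    for (k in seq_len(n_te_copies)) {
      chrom <- sample(names(seqs), 1)
      repeat {
        pos <- sample.int(nchar(seqs[[chrom]]) - te$length, 1)
        clash <- FALSE
        for (r in rows)
          if (r$chrom == chrom && pos <= r$end + 200 &&
              pos + te$length - 1 >= r$start - 200) clash <- TRUE
        if (!clash) break
      }
      seqs[[chrom]] <- paste0(substr(seqs[[chrom]], 1, pos - 1), te$sequence,
                              substr(seqs[[chrom]], pos + te$length,
                                     nchar(seqs[[chrom]])))
      rows[[k]] <- data.frame(chrom = chrom, start = pos,
                              end = pos + te$length - 1L,
                              stringsAsFactors = FALSE)
    }
    copies <- do.call(rbind, rows)
  }
  attr(seqs, "te_copies") <- copies
  seqs
}

#' Find reference positions whose sequence satisfies the TSD matcher
#'
#' @param reference named character vector of reference sequences.
#' @param tsd a `tsd_matcher`.
#' @param min_gap minimum distance between reported sites (keeps planted
#'   events well separated; default 300).
#' @return data frame (`chrom`, `tsd_start`, `tsd_end`).
#' @export
find_tsd_sites <- function(reference, tsd, min_gap = 300) {
  out <- list()
  for (chrom in names(reference)) {
    g <- reference[[chrom]]
    w <- tsd$width
    starts <- seq_len(max(0, nchar(g) - w + 1L))
    wins <- substring(g, starts, starts + w - 1L)
    hit <- which(tsd_matches(tsd, wins))
    hit <- hit[hit > min_gap & hit < nchar(g) - min_gap]
    keep <- integer(0)
    last <- -Inf
    for (h in hit) {
      if (h - last >= min_gap) { keep <- c(keep, h); last <- h }
    }
    if (length(keep))
      out[[chrom]] <- data.frame(chrom = chrom, tsd_start = keep,
                                 tsd_end = keep + w - 1L,
                                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(empty_df(chrom = character(0), tsd_start = integer(0),
                    tsd_end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant a TSD-duplicating TE insertion into a haplotype
#'
#' Insertion at a target site duplicates it: the haplotype becomes
#' `left...TSD + TE + TSD...right`.  The reference bases at the target site
#' must satisfy the element's TSD matcher.  With `footprint`, an excision
#' footprint is planted instead of the element (`TSD + footprint + TSD`).
#'
#' @param haplotype named character vector of chromosome sequences.
#' @param te a [te_model()].
#' @param chrom chromosome name.
#' @param tsd_start 1-based start of the target site in the *current*
#'   haplotype coordinates (apply multiple events from the highest
#'   coordinate downward, as [simulate_individual()] does).
#' @param footprint optional footprint sequence replacing the element.
#' @return the modified haplotype.
#' @export
plant_insertion <- function(haplotype, te, chrom, tsd_start,
                            footprint = NULL) {
  stopifnot(chrom %in% names(haplotype))
  w <- te$tsd$width
  g <- haplotype[[chrom]]
  t2 <- tsd_start + w - 1L
  site <- substr(g, tsd_start, t2)
  if (!tsd_matches(te$tsd, site))
    stop("target site ", chrom, ":", tsd_start, " (", site,
         ") does not satisfy the TSD matcher")
  insert <- if (is.null(footprint)) te$sequence else toupper(footprint)
  haplotype[[chrom]] <- paste0(substr(g, 1, t2), insert,
                               substr(g, tsd_start, nchar(g)))
  haplotype
}

# build one lineage's haplotype from the reference and its event subset
build_haplotype <- function(reference, te, events) {
  hap <- reference
  if (is.null(events) || nrow(events) == 0) return(hap)
  events <- events[order(events$chrom, -events$tsd_start), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    fp <- if (!is.na(events$footprint_seq[i]) &&
              nzchar(events$footprint_seq[i])) events$footprint_seq[i]
          else NULL
    hap <- plant_insertion(hap, te, events$chrom[i], events$tsd_start[i],
                           footprint = fp)
  }
  hap
}

#' Construct a diploid individual with planted TE events
#'
#' Builds the cell lineages of a simulated individual.  Germline events are
#' homozygous (on both haplotypes) or heterozygous (haplotype A only);
#' somatic insertions exist on haplotype A of a lineage comprising
#' `cell_fraction` of cells; somatic excisions remove a homozygous
#' insertion from haplotype A of their lineage, either precisely (reference
#' restored) or leaving a footprint (`TSD + footprint_seq + TSD`).
#'
#' @param reference named character vector of reference sequences.
#' @param te a [te_model()].
#' @param events data frame with columns `chrom`, `tsd_start`, `genotype`
#'   (`homozygous` / `heterozygous` / `somatic`), `cell_fraction` (1 for
#'   germline rows), `excision` (`none` / `precise` / `footprint`) and
#'   `footprint_seq` (NA unless `excision == "footprint"`).  Events must
#'   not overlap; somatic rows need `cell_fraction < 1`.
#' @return an object of class `sim_individual`: list with `reference`,
#'   `te`, `lineages` (each `hapA`, `hapB`, `weight`) and `truth` (the
#'   event manifest with TSD spans in reference coordinates).
#' @export
simulate_individual <- function(reference, te, events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  n_ev <- nrow(events)
  if (is.null(events$cell_fraction)) events$cell_fraction <- rep(1, n_ev)
  if (is.null(events$excision)) events$excision <- rep("none", n_ev)
  if (is.null(events$footprint_seq))
    events$footprint_seq <- rep(NA_character_, n_ev)
  w <- te$tsd$width
  events$tsd_end <- events$tsd_start + w - 1L
  stopifnot(all(events$genotype %in%
                  c("homozygous", "heterozygous", "somatic")),
            all(events$excision %in% c("none", "precise", "footprint")))
  somatic_rows <- which(events$genotype == "somatic" |
                          events$excision != "none")
  if (any(events$cell_fraction[somatic_rows] >= 1))
    stop("somatic events must have cell_fraction < 1")
  # overlap check in reference coordinates (pad by one TE length)
  ev <- events[order(events$chrom, events$tsd_start), ]
  same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
  if (nrow(ev) > 1 &&
      any(same & (ev$tsd_start[-1] - ev$tsd_end[-nrow(ev)]) < 1))
    stop("planted events overlap")

  germ_idx <- setdiff(seq_len(nrow(events)), which(events$genotype == "somatic"))
  germ <- events[germ_idx, , drop = FALSE]
  insA <- germ                                  # all germline events on hap A
  insB <- germ[germ$genotype == "homozygous", , drop = FALSE]
  no_fp <- function(e) {
    e$footprint_seq <- rep(NA_character_, nrow(e))
    e
  }
  lineages <- list()
  som_w <- 0
  # somatic insertion lineages
  for (i in which(events$genotype == "somatic")) {
    f <- events$cell_fraction[i]
    som_w <- som_w + f
    lineages[[length(lineages) + 1]] <- list(
      hapA = build_haplotype(reference, te, no_fp(rbind(insA, events[i, ]))),
      hapB = build_haplotype(reference, te, no_fp(insB)),
      weight = f)
  }
  # somatic excision lineages (event present in germline, lost on hap A)
  for (i in which(events$genotype != "somatic" & events$excision != "none")) {
    f <- events$cell_fraction[i]
    som_w <- som_w + f
    evA <- insA[insA$tsd_start != events$tsd_start[i] |
                  insA$chrom != events$chrom[i], , drop = FALSE]
    if (events$excision[i] == "footprint")
      evA <- rbind(no_fp(evA), events[i, ])     # footprint replaces the TE
    else
      evA <- no_fp(evA)
    lineages[[length(lineages) + 1]] <- list(
      hapA = build_haplotype(reference, te, evA),
      hapB = build_haplotype(reference, te, no_fp(insB)),
      weight = f)
  }
  if (som_w >= 1) stop("somatic cell fractions sum to >= 1")
  lineages <- c(list(list(hapA = build_haplotype(reference, te, no_fp(insA)),
                          hapB = build_haplotype(reference, te, no_fp(insB)),
                          weight = 1 - som_w)),
                lineages)
  structure(list(reference = reference, te = te, lineages = lineages,
                 truth = events),
            class = "sim_individual")
}

#' Simulate short reads from a diploid individual
#'
#' Fragments are sampled uniformly across lineages (weighted by cell
#' fraction) and haplotypes (1:1), with normal fragment lengths for paired
#' reads and substitution sequencing errors at `error_rate` (errored bases
#' get a matching low quality score).  Deterministic under `seed`.
#'
#' @param individual a `sim_individual` from [simulate_individual()].
#' @param coverage mean fold coverage of the reference.
#' @param read_len read length in bp (default 100).
#' @param paired paired-end fragments (default TRUE).
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param insert_mean,insert_sd fragment length distribution for paired
#'   reads (defaults 350, 50).
#' @param seed RNG seed.
#' @param qual_high,qual_err Phred scores assigned to correct/errored
#'   bases (defaults 37, 14).
#' @return read data frame (`id`, `mate`, `seq`, `qual`) as from
#'   [read_fastq()].
#' @export
simulate_reads <- function(individual, coverage, read_len = 100,
                           paired = TRUE, error_rate = 0.002,
                           insert_mean = 350, insert_sd = 50, seed = 1,
                           qual_high = 37, qual_err = 14) {
  stopifnot(inherits(individual, "sim_individual"), coverage > 0)
  set.seed(seed)
  G <- sum(nchar(individual$reference))
  n_frag <- round(coverage * G / (if (paired) 2 * read_len else read_len))
  weights <- vapply(individual$lineages, `[[`, 0, "weight")
  lin_idx <- sample.int(length(weights), n_frag, replace = TRUE,
                        prob = weights)
  hap_idx <- sample(c("hapA", "hapB"), n_frag, replace = TRUE)
  chroms <- names(individual$reference)
  chrom_w <- nchar(individual$reference)
  chrom_idx <- sample(chroms, n_frag, replace = TRUE, prob = chrom_w)
  ins_len <- if (paired) {
    pmax(2L * read_len,
         as.integer(round(rnorm(n_frag, insert_mean, insert_sd))))
  } else rep(read_len, n_frag)

  # fragment start positions, grouped so substring() is vectorized per
  # (lineage, haplotype, chromosome) source sequence
  ids <- sprintf("sim%06d", seq_len(n_frag))
  starts <- integer(n_frag)
  il_used <- integer(n_frag)
  grp <- paste(lin_idx, hap_idx, chrom_idx)
  r1 <- character(n_frag)
  r2 <- character(n_frag)
  for (g_key in unique(grp)) {
    k <- which(grp == g_key)
    hap <- individual$lineages[[lin_idx[k[1]]]][[hap_idx[k[1]]]]
    g <- hap[[chrom_idx[k[1]]]]
    L <- nchar(g)
    il <- pmin(ins_len[k], L)
    s <- 1L + as.integer(floor(runif(length(k)) * (L - il + 1L)))
    starts[k] <- s
    il_used[k] <- il
    r1[k] <- substring(g, s, s + read_len - 1L)
    if (paired) r2[k] <- revcomp(substring(g, s + il - read_len, s + il - 1L))
  }

  add_errors <- function(seqs) {
    n <- nchar(seqs)
    base_qual <- intToUtf8(rep(qual_high + 33L, read_len), multiple = FALSE)
    quals <- substring(base_qual, 1L, n)
    if (error_rate > 0) {
      nerr <- stats::rbinom(length(seqs), n, error_rate)
      for (k in which(nerr > 0)) {
        at <- sample.int(n[k], nerr[k])
        bases <- strsplit(seqs[k], "")[[1]]
        q <- strsplit(quals[k], "")[[1]]
        for (p in at) {
          bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
          q[p] <- intToUtf8(qual_err + 33L)
        }
        seqs[k] <- paste(bases, collapse = "")
        quals[k] <- paste(q, collapse = "")
      }
    }
    list(seq = seqs, qual = quals)
  }

  e1 <- add_errors(r1)
  if (paired) {
    e2 <- add_errors(r2)
    reads <- data.frame(
      id = c(ids, ids), mate = rep(c(1L, 2L), each = n_frag),
      seq = c(e1$seq, e2$seq), qual = c(e1$qual, e2$qual),
      stringsAsFactors = FALSE)
    reads <- reads[order(reads$mate, reads$id), , drop = FALSE]
  } else {
    reads <- data.frame(id = ids, mate = 0L, seq = e1$seq, qual = e1$qual,
                        stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL
  reads
}

#' Write / read the simulation truth manifest
#'
#' One row per planted event: reference-coordinate TSD span, genotype,
#' cell fraction, excision type and footprint sequence.
#'
#' @param individual a `sim_individual` (or its `truth` data frame).
#' @param path tab-delimited output file.
#' @export
write_truth <- function(individual, path) {
  truth <- if (inherits(individual, "sim_individual")) individual$truth
           else individual
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
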