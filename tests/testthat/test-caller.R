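te <- fixture_te()

test_that("trimmed reads map uniquely within the mismatch budget", {
  set.seed(31)
  ref <- c(chr1 = random_dna(5000))
  piece <- substr(ref, 2001, 2040)
  mutate <- function(s, n) {
    b <- strsplit(s, "")[[1]]
    at <- sample(seq_along(b), n)
    for (p in at) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    paste(b, collapse = "")
  }
  trimmed <- data.frame(
    id = c("u0", "u3", "u4"), qual = "",
    seq = c(piece, mutate(piece, 3), mutate(piece, 4)),
    trimmed_end = "end", te_end = "5p", strand = "+",
    stringsAsFactors = FALSE)
  fl <- align_trimmed_reads(trimmed, ref, max_mismatch = 3)
  expect_setequal(fl$id, c("u0", "u3"))
  expect_equal(fl$start[fl$id == "u0"], 2001L)
  expect_equal(fl$mismatches[fl$id == "u3"], 3L)

  # a read present at two genome positions is dropped as non-unique
  ref2 <- c(chr1 = paste0(ref, substr(ref, 1901, 2100)))
  fl2 <- align_trimmed_reads(trimmed[1, ], ref2, max_mismatch = 3)
  expect_equal(nrow(fl2), 0L)
})

test_that("junction side follows the trim-tag/strand table", {
  set.seed(32)
  ref <- c(chr1 = random_dna(3000))
  piece <- substr(ref, 1001, 1040)
  base <- data.frame(id = "r", seq = piece, qual = "", te_end = "5p",
                     stringsAsFactors = FALSE)
  cases <- list(list(seq = piece, trimmed_end = "end", side = "left"),
                list(seq = piece, trimmed_end = "start", side = "right"),
                list(seq = revcomp(piece), trimmed_end = "end",
                     side = "right"),
                list(seq = revcomp(piece), trimmed_end = "start",
                     side = "left"))
  for (cs in cases) {
    tr <- base
    tr$seq <- cs$seq
    tr$trimmed_end <- cs$trimmed_end
    fl <- align_trimmed_reads(tr, ref)
    expect_equal(fl$side, cs$side,
                 info = paste(cs$trimmed_end, "strand",
                              if (cs$seq == piece) "+" else "-"))
  }
})

test_that("flank placement matches exhaustive enumeration on small genomes", {
  set.seed(33)
  for (k in 1:15) {
    ref <- c(chrA = random_dna(800), chrB = random_dna(600))
    sq <- if (k %% 3 == 0) random_dna(25) else {
      chrom <- sample(names(ref), 1)
      p <- sample.int(nchar(ref[[chrom]]) - 24, 1)
      s <- substr(ref[[chrom]], p, p + 24)
      if (runif(1) < 0.5) revcomp(s) else s
    }
    trimmed <- data.frame(id = "r", seq = sq, qual = "", trimmed_end = "end",
                          te_end = "5p", strand = "+",
                          stringsAsFactors = FALSE)
    got <- align_trimmed_reads(trimmed, ref, max_mismatch = 3)
    want <- oracle_place(sq, ref, max_mismatch = 3)
    if (is.null(want) || want$n_best > 1) {
      expect_equal(nrow(got), 0L, info = paste("case", k))
    } else {
      expect_equal(nrow(got), 1L, info = paste("case", k))
      expect_equal(got$chrom, want$hits[[1]]$chrom)
      expect_equal(got$start, want$hits[[1]]$pos)
      expect_equal(got$mismatches, want$best)
    }
  }
})

test_that("clustering is single-linkage over interval overlap", {
  aln <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 150L, 190L, 400L, 100L),
    end = c(160L, 200L, 250L, 460L, 160L),
    strand = "+", mismatches = 0L, side = "left", te_end = "5p",
    trimmed_end = "end", stringsAsFactors = FALSE)
  cl <- cluster_flankers(aln)
  # a overlaps b, b overlaps c, a disjoint c: one cluster of three
  expect_equal(cl$cluster[cl$id %in% c("a", "b", "c")], rep(1L, 3))
  expect_equal(cl$cluster[cl$id == "d"], 2L)
  # different chromosome always separates
  expect_equal(cl$cluster[cl$id == "e"], 3L)
})

test_that("clustering equals brute-force transitive closure on random input", {
  set.seed(34)
  for (k in 1:20) {
    n <- sample(3:25, 1)
    start <- sample.int(500, n, replace = TRUE)
    aln <- data.frame(
      id = sprintf("r%d", seq_len(n)),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = start, end = start + sample(10:80, n, replace = TRUE),
      strand = "+", mismatches = 0L, side = "left", te_end = "5p",
      trimmed_end = "end", stringsAsFactors = FALSE)
    cl <- cluster_flankers(aln)
    want <- oracle_clusters(cl$chrom, cl$start, cl$end)
    # same partition: equal label co-membership matrices
    expect_equal(outer(cl$cluster, cl$cluster, "=="),
                 outer(want, want, "=="), info = paste("case", k))
  }
})

test_that("TSD overlap requires the identical interval and a matching sequence", {
  ref <- c(chr1 = paste0(random_dna(127), "TAA", random_dna(120)))
  tsd <- parse_tsd_spec("TSD=TAA")
  mk <- function(side, start, end, id) {
    data.frame(id = id, chrom = "chr1", start = start, end = end,
               strand = "+", mismatches = 0L, side = side, te_end = "5p",
               trimmed_end = "end", cluster = 1L, stringsAsFactors = FALSE)
  }
  # left flanker ends at 128..130 = TAA, right flanker starts there
  cl <- rbind(mk("left", 90L, 130L, "l1"), mk("right", 128L, 170L, "r1"))
  ov <- find_tsd_overlap(cl, tsd, ref)
  expect_equal(nrow(ov), 1L)
  expect_equal(c(ov$tsd_start, ov$tsd_end), c(128L, 130L))
  expect_equal(ov$tsd_seq, "TAA")

  # adjacent but not overlapping: no call
  cl2 <- rbind(mk("left", 90L, 130L, "l1"), mk("right", 131L, 170L, "r1"))
  expect_equal(nrow(find_tsd_overlap(cl2, tsd, ref)), 0L)

  # reference shows the reverse-complement rendering TTA: accepted
  ref_rc <- c(chr1 = paste0(random_dna(127), "TTA", random_dna(120)))
  expect_equal(nrow(find_tsd_overlap(cl, tsd, ref_rc)), 1L)
  # but a non-TSD triplet is not
  ref_no <- c(chr1 = paste0(random_dna(127), "CCG", random_dna(120)))
  expect_equal(nrow(find_tsd_overlap(cl, tsd, ref_no)), 0L)
})

test_that("insertion calls need one left plus one right flanker minimum", {
  ref <- c(chr1 = paste0(random_dna(127), "TAA", random_dna(120)))
  tsd <- parse_tsd_spec("TSD=TAA")
  mk <- function(side, start, end, id) {
    data.frame(id = id, chrom = "chr1", start = start, end = end,
               strand = "+", mismatches = 0L, side = side, te_end = "5p",
               trimmed_end = "end", stringsAsFactors = FALSE)
  }
  # two left + one right sharing the TAA window
  cl <- cluster_flankers(rbind(mk("left", 90L, 130L, "l1"),
                               mk("left", 85L, 130L, "l2"),
                               mk("right", 128L, 170L, "r1")))
  calls <- call_insertions(cl, tsd, ref, te_name = "el")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$left_count, 2L)
  expect_equal(calls$right_count, 1L)
  expect_equal(calls$last_base, 130L)
  expect_setequal(strsplit(calls$read_ids, ",")[[1]], c("l1", "l2", "r1"))

  # three left, zero right: no call
  cl2 <- cluster_flankers(rbind(mk("left", 90L, 130L, "l1"),
                                mk("left", 85L, 130L, "l2"),
                                mk("left", 95L, 130L, "l3")))
  expect_equal(nrow(call_insertions(cl2, tsd, ref)), 0L)

  # one left + one right in perfect overlap: the printed minimum of two reads
  cl3 <- cluster_flankers(rbind(mk("left", 90L, 130L, "l1"),
                                mk("right", 128L, 170L, "r1")))
  calls3 <- call_insertions(cl3, tsd, ref)
  expect_equal(nrow(calls3), 1L)
  expect_equal(calls3$left_count + calls3$right_count, 2L)
})

test_that("reference copies are found within length and identity bounds", {
  set.seed(35)
  ref <- generate_reference(101, lengths = 20000, te = te, n_te_copies = 2)
  copies <- scan_reference_for_te(ref, te)
  truth <- attr(ref, "te_copies")
  expect_equal(nrow(copies), 2L)
  expect_setequal(copies$start, truth$start)
  expect_true(all(copies$identity == 1))

  # truncated copy (350 of 430 bp, 81%): rejected
  ref_tr <- c(chr1 = paste0(random_dna(1000),
                            substr(te$sequence, 1, 350), random_dna(1000)))
  expect_equal(nrow(scan_reference_for_te(ref_tr, te)), 0L)

  # copy with 5 mismatches (1.2%): detected, on either strand
  b <- strsplit(te$sequence, "")[[1]]
  for (p in c(50, 150, 250, 300, 400))
    b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  ref_mm <- c(chr1 = paste0(random_dna(800),
                            revcomp(paste(b, collapse = "")),
                            random_dna(800)))
  copies_mm <- scan_reference_for_te(ref_mm, te)
  expect_equal(nrow(copies_mm), 1L)
  expect_equal(copies_mm$strand, "-")
  expect_equal(copies_mm$identity, 1 - 5 / 430)
})

test_that("reference copies classify as shared or reference-only by flank support", {
  copies <- data.frame(chrom = "chr1", start = c(1000L, 5000L, 9000L),
                       end = c(1429L, 5429L, 9429L), strand = "+",
                       identity = 1, length_fraction = 1,
                       stringsAsFactors = FALSE)
  mk <- function(side, start, end, id) {
    data.frame(id = id, chrom = "chr1", start = start, end = end,
               strand = "+", mismatches = 0L, side = side, te_end = "5p",
               trimmed_end = "end", stringsAsFactors = FALSE)
  }
  fl <- rbind(mk("left", 960L, 999L, "a"),     # abuts copy 1 left end
              mk("right", 1430L, 1469L, "b"),  # abuts copy 1 right end
              mk("left", 4960L, 4999L, "c"))   # copy 2, one end only
  cls <- classify_reference_sites(copies, fl)
  expect_equal(cls$class, c("shared", "shared", "reference-only"))
  expect_equal(cls$one_ended, c(FALSE, TRUE, FALSE))
})

test_that("every reported TSD equals the reference bases and satisfies the matcher", {
  sim <- simulate_dataset(te, seed = 41, genome_length = 30000,
                          n_homozygous = 4, n_heterozygous = 2, n_somatic = 0)
  reads <- simulate_reads(sim, coverage = 20, seed = 42)
  res <- relocate(te, sim$reference, reads)
  expect_gt(nrow(res$calls), 0)
  for (i in seq_len(nrow(res$calls))) {
    seq <- substr(sim$reference[[res$calls$chrom[i]]],
                  res$calls$tsd_start[i], res$calls$tsd_end[i])
    expect_equal(res$calls$tsd_seq[i], seq)
    expect_true(tsd_matches(te$tsd, seq, both_strands = TRUE))
  }
})

test_that("planted germline insertions are recovered and a TE-free genome is silent", {
  sim <- simulate_dataset(te, seed = 43, genome_length = 40000,
                          n_homozygous = 5, n_heterozygous = 3, n_somatic = 0)
  reads <- simulate_reads(sim, coverage = 25, seed = 44)
  res <- relocate(te, sim$reference, reads)
  key <- function(df, s, e) paste(df$chrom, s, e)
  expect_true(all(key(sim$truth, sim$truth$tsd_start, sim$truth$tsd_end) %in%
                    key(res$calls, res$calls$tsd_start, res$calls$tsd_end)))

  # no insertions planted: no junction reads exist, zero calls
  ref0 <- generate_reference(45, lengths = 20000)
  ind0 <- simulate_individual(ref0, te,
                              data.frame(chrom = character(0),
                                         tsd_start = integer(0),
                                         genotype = character(0)))
  reads0 <- simulate_reads(ind0, coverage = 15, seed = 46)
  res0 <- relocate(te, ref0, reads0)
  expect_equal(nrow(res0$calls), 0L)
})

test_that("calls are monotone under read subsetting", {
  sim <- simulate_dataset(te, seed = 47, genome_length = 30000,
                          n_homozygous = 3, n_heterozygous = 3, n_somatic = 0)
  reads <- simulate_reads(sim, coverage = 20, seed = 48)
  full <- relocate(te, sim$reference, reads)
  full_key <- paste(full$calls$chrom, full$calls$tsd_start)
  set.seed(49)
  for (frac in c(0.75, 0.5, 0.25)) {
    sub <- reads[sample.int(nrow(reads), round(frac * nrow(reads))), ]
    part <- relocate(te, sim$reference, sub)
    expect_true(all(paste(part$calls$chrom, part$calls$tsd_start) %in%
                      full_key), info = paste("fraction", frac))
  }
})

test_that("calls never fall inside reference TE copies", {
  ref <- generate_reference(51, lengths = 40000, te = te, n_te_copies = 2)
  sites <- find_tsd_sites(ref, te$tsd, min_gap = 400)
  rc <- attr(ref, "te_copies")
  # keep planted events away from the reference copies
  ok <- !vapply(seq_len(nrow(sites)), function(i)
    any(rc$chrom == sites$chrom[i] & sites$tsd_start[i] >= rc$start - 500 &
          sites$tsd_start[i] <= rc$end + 500), TRUE)
  sites <- sites[ok, ][1:4, ]
  ind <- simulate_individual(ref, te, data.frame(
    chrom = sites$chrom, tsd_start = sites$tsd_start,
    genotype = "homozygous", stringsAsFactors = FALSE))
  reads <- simulate_reads(ind, coverage = 20, seed = 52)
  res <- relocate(te, ref, reads, reference_scan = TRUE)
  for (i in seq_len(nrow(res$calls)))
    expect_false(any(rc$chrom == res$calls$chrom[i] &
                       res$calls$tsd_start[i] >= rc$start &
                       res$calls$tsd_end[i] <= rc$end))
  # the planted reference copies are classed shared (junction reads exist)
  expect_true(all(res$ref_copies$class == "shared"))
})
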