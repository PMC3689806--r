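te <- fixture_te()

test_that("reads containing TE ends are found with exact coordinates", {
  set.seed(21)
  flank <- random_dna(60)
  read <- paste0(flank, substr(te$sequence, 1, 40))
  m <- scan_read_for_te(read, te)
  expect_equal(nrow(m), 1L)
  expect_equal(m$r_start, 61L)
  expect_equal(m$r_end, 100L)
  expect_equal(m$t_start, 1L)
  expect_equal(m$t_end, 40L)
  expect_equal(m$strand, "+")
  expect_equal(m$mismatches, 0L)
  expect_equal(m$aligned_len, 40L)
})

test_that("reverse-complement matches touching the TE 3' end are reported", {
  set.seed(22)
  te_tail <- substr(te$sequence, te$length - 39, te$length)  # last 40 bases
  read <- paste0(revcomp(te_tail), random_dna(60))
  m <- scan_read_for_te(read, te)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(m$t_end, te$length)
  anchored <- end_anchor_filter(cbind(read = 1L, id = "r", m), te)
  expect_equal(anchored$te_end, "3p")
})

test_that("a 9-mer shared with the TE is below the minimum aligned length", {
  set.seed(23)
  repeat {
    read <- paste0(random_dna(30), substr(te$sequence, 100, 108),
                   random_dna(21))
    if (nrow(oracle_te_matches(read, te$sequence, min_aligned = 10)) == 0)
      break
  }
  expect_gte(max(oracle_te_matches(read, te$sequence,
                                   min_aligned = 9)$r_end -
                   oracle_te_matches(read, te$sequence,
                                     min_aligned = 9)$r_start) + 1L, 9L)
  expect_equal(nrow(scan_read_for_te(read, te)), 0L)
})

test_that("end-anchor filter keeps only matches touching a TE terminus", {
  matches <- data.frame(
    read = 1:3, id = c("a", "b", "c"),
    r_start = 1L, r_end = c(40L, 60L, 100L),
    t_start = c(1L, 101L, 1L), t_end = c(40L, 160L, 430L),
    strand = "+", mismatches = 0L, aligned_len = c(40L, 60L, 430L),
    stringsAsFactors = FALSE)
  kept <- end_anchor_filter(matches, te)
  expect_equal(kept$id, c("a", "c"))
  expect_equal(kept$te_end, c("5p", "both"))
})

test_that("mismatch fraction is mismatches over aligned bases, boundary inclusive", {
  m <- data.frame(mismatches = c(1L, 0L), aligned_len = c(50L, 30L))
  expect_equal(mismatch_fraction(m), c(0.02, 0))
  # a fraction exactly at the allowance is retained, not dropped
  expect_true(all(mismatch_fraction(m)[1] <= 0.02))

  set.seed(24)
  flank <- random_dna(50)
  te_part <- substr(te$sequence, 1, 50)
  substr(te_part, 25, 25) <- if (substr(te_part, 25, 25) == "A") "C" else "A"
  read <- paste0(flank, te_part)
  # allowance 0: the mismatch truncates the match below the TE start
  m0 <- scan_read_for_te(read, te, allowance = 0)
  expect_false(any(m0$t_start == 1 & m0$t_end >= 50))
  # allowance 0.02 (1/50): the full 50-base match is recovered
  m2 <- scan_read_for_te(read, te, allowance = 0.02)
  expect_true(any(m2$t_start == 1 & m2$t_end == 50 & m2$mismatches == 1))
})

test_that("trimming removes the TE portion and applies the length rules", {
  set.seed(25)
  flank <- random_dna(60)
  read <- data.frame(id = "r", seq = paste0(flank, substr(te$sequence, 1, 40)),
                     qual = strrep("I", 100), stringsAsFactors = FALSE)
  match <- data.frame(r_start = 61L, r_end = 100L, t_start = 1L, t_end = 40L,
                      strand = "+", te_end = "5p", stringsAsFactors = FALSE)
  tr <- trim_te_sequence(read, match)
  expect_equal(tr$seq, flank)
  expect_equal(tr$trimmed_end, "end")
  expect_equal(tr$te_end, "5p")
  expect_equal(nchar(tr$qual), 60L)

  # all-TE read: no flanking information, discarded
  allte <- data.frame(id = "r", seq = substr(te$sequence, 1, 100),
                      stringsAsFactors = FALSE)
  expect_null(trim_te_sequence(allte,
                               data.frame(r_start = 1L, r_end = 100L,
                                          t_start = 1L, t_end = 100L,
                                          strand = "+", te_end = "5p")))

  # flank of exactly 10 bp is discarded ('longer than' is strict); 11 kept
  mk <- function(flank_len) {
    rd <- data.frame(id = "r",
                     seq = paste0(random_dna(flank_len),
                                  substr(te$sequence, 1, 40)),
                     stringsAsFactors = FALSE)
    trim_te_sequence(rd, data.frame(r_start = flank_len + 1L,
                                    r_end = flank_len + 40L,
                                    t_start = 1L, t_end = 40L,
                                    strand = "+", te_end = "5p"))
  }
  expect_null(mk(10))
  expect_equal(nchar(mk(11)$seq), 11L)

  # a TE match internal to the read is inconsistent with a junction read
  internal <- data.frame(id = "r",
                         seq = paste0(random_dna(20),
                                      substr(te$sequence, 1, 40),
                                      random_dna(20)),
                         stringsAsFactors = FALSE)
  expect_null(trim_te_sequence(internal,
                               data.frame(r_start = 21L, r_end = 60L,
                                          t_start = 1L, t_end = 40L,
                                          strand = "+", te_end = "5p")))
})

test_that("trim geometry conserves every read base", {
  set.seed(26)
  for (k in 1:20) {
    flank_len <- sample(12:60, 1)
    te_len <- sample(10:60, 1)
    at_end <- runif(1) < 0.5
    flank <- random_dna(flank_len)
    tepart <- substr(te$sequence, 1, te_len)
    read <- data.frame(id = "r",
                       seq = if (at_end) paste0(flank, tepart)
                             else paste0(tepart, flank),
                       stringsAsFactors = FALSE)
    m <- scan_read_for_te(read$seq, te)
    # the exact match may extend by chance into the random flank
    m <- m[m$t_start == 1 & m$aligned_len >= te_len, , drop = FALSE]
    expect_equal(nrow(m), 1L)
    m$te_end <- "5p"
    tr <- trim_te_sequence(read, m[1, ])
    expect_equal(nchar(tr$seq) + m$aligned_len, flank_len + te_len)
    expect_equal(tr$trimmed_end, if (at_end) "end" else "start")
  }
})

test_that("the scanner agrees with brute-force enumeration on small instances", {
  set.seed(27)
  for (k in 1:40) {
    small_te <- te_model("t", random_dna(sample(40:80, 1)), "TSD=2")
    read <- random_dna(sample(30:60, 1))
    # embed a TE fragment half the time so matches actually occur
    if (k %% 2 == 0) {
      frag_len <- sample(10:25, 1)
      ts <- sample(seq_len(small_te$length - frag_len + 1), 1)
      frag <- substr(small_te$sequence, ts, ts + frag_len - 1)
      if (runif(1) < 0.5) frag <- revcomp(frag)
      pos <- sample(seq_len(nchar(read) - frag_len + 1), 1)
      substr(read, pos, pos + frag_len - 1) <- frag
    }
    got <- scan_read_for_te(read, small_te)
    got <- got[order(got$strand, got$r_start, got$t_start),
               c("r_start", "r_end", "t_start", "t_end", "strand")]
    want <- oracle_te_matches(read, small_te$sequence)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("case", k))
  }
})

test_that("with zero allowance every retained match is an exact substring", {
  set.seed(28)
  reads <- data.frame(id = sprintf("r%d", 1:50), mate = 0L,
                      seq = vapply(1:50, function(i) {
                        base <- random_dna(80)
                        ts <- sample(c(1, te$length - 29), 1)
                        substr(base, 21, 50) <-
                          substr(te$sequence, ts, ts + 29)
                        base
                      }, ""),
                      qual = strrep("I", 80), stringsAsFactors = FALSE)
  m <- scan_reads_for_te(reads, te)
  for (i in seq_len(nrow(m))) {
    piece <- substr(reads$seq[m$read[i]], m$r_start[i], m$r_end[i])
    if (m$strand[i] == "-") piece <- revcomp(piece)
    expect_equal(piece, substr(te$sequence, m$t_start[i], m$t_end[i]))
  }
})
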