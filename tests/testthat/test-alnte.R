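test_that("self-alignment scores matches with no gaps", {
  al <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(al$score, 8)
  expect_equal(al$aligned_a, al$aligned_b)
  expect_equal(nrow(call_indels(al)), 0)
})

test_that("a length-2 terminal deletion costs open plus two extends", {
  al <- global_align("AAAA", "AA")
  expect_equal(al$score, 2 - 5 - 2)
  calls <- call_indels(al)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion_in_B")
  expect_equal(calls$length, 2)
  expect_equal(calls$pos_a, 0)   # left-normalized into the homopolymer
})

test_that("scores equal the exhaustive-enumeration optimum on short pairs", {
  withr::with_seed(61, {
    for (k in 1:30) {
      sa <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE),
                  collapse = "")
      sb <- paste(sample(c("A", "C", "G", "T", "N"), sample(2:6, 1), TRUE),
                  collapse = "")
      expect_equal(global_align(sa, sb)$score, brute_align_score(sa, sb),
                   info = paste(sa, sb))
    }
  })
})

test_that("scores equal an independent aligner's optimum on 12 bp pairs", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  withr::with_seed(62, {
    for (k in 1:200) {
      sa <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), TRUE),
                  collapse = "")
      sb <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), TRUE),
                  collapse = "")
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        sa, sb, substitutionMatrix = mat, gapOpening = 5, gapExtension = 1,
        type = "global"))
      expect_equal(global_align(sa, sb)$score, ref, info = paste(sa, sb))
    }
  })
})

test_that("alignment score is symmetric with indel types swapped", {
  p <- sim_insertion_pair(120, tibble::tibble(pos = 60, len = 15), seed = 63)
  ab <- global_align(p$seq_a, p$seq_b)
  ba <- global_align(p$seq_b, p$seq_a)
  expect_equal(ab$score, ba$score)
  expect_equal(call_indels(ab)$type, "insertion_in_B")
  expect_equal(call_indels(ba)$type, "deletion_in_B")
  expect_equal(call_indels(ab)$length, call_indels(ba)$length)
})

test_that("planted insertions are recovered at exact position and length", {
  for (seed in 1:10) {
    pos <- 40 + seed * 13
    len <- 10 + seed * 7
    p <- sim_insertion_pair(400, tibble::tibble(pos = pos, len = len),
                            seed = 600 + seed)
    calls <- call_indels(global_align(p$seq_a, p$seq_b))
    calls <- calls[calls$length >= 5, ]  # ignore incidental 1 bp wobble
    expect_equal(nrow(calls), 1)
    expect_equal(calls$type, "insertion_in_B")
    expect_equal(calls$length, len)
    # positions are left-normalized, so a planted site can shift left by a
    # base or two when the flank happens to extend the inserted segment
    expect_lte(abs(calls$pos_a - pos), 2)
  }
  # two TE-scale insertions in one pair, both exact
  p2 <- sim_insertion_pair(1200, tibble::tibble(pos = c(300, 800),
                                                len = c(690, 163)), seed = 64)
  calls2 <- call_indels(global_align(p2$seq_a, p2$seq_b), min_len = 50)
  expect_equal(calls2$length, c(690, 163))
  expect_true(all(abs(calls2$pos_a - c(300, 800)) <= 2))
})

test_that("illegal inputs are rejected", {
  expect_error(global_align("", "ACGT"), "nonempty")
  expect_error(global_align("ACGT", "ACXT"), "A/C/G/T/N")
})

test_that("windowed identity counts gaps against and thresholds correctly", {
  al <- global_align("ACGTACGTAC", "ACGTACGTAC")
  wi <- windowed_identity(al, window_bp = 5)
  expect_true(all(wi$track$identity == 1))
  expect_equal(nrow(wi$intervals), 1)

  # construct a 60%-identity stretch: below the 0.75 threshold
  a <- strrep("ACGTACGTAC", 4)
  b <- paste0(strrep("ACGTACGTAC", 2), "ACGGAGGTTC", "ACGTACGTAC")
  al2 <- global_align(a, b)
  wi2 <- windowed_identity(al2, window_bp = 10, threshold = 0.75)
  expect_true(any(wi2$track$identity < 0.75))
  expect_lt(sum(wi2$intervals$end - wi2$intervals$start), nchar(a))

  # a fully gapped window scores zero
  al3 <- global_align(paste0(strrep("A", 12), strrep("C", 12), strrep("G", 12)),
                      paste0(strrep("A", 12), strrep("G", 12)))
  wi3 <- windowed_identity(al3, window_bp = 12)
  expect_true(any(wi3$track$identity == 0))
})
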