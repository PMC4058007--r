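test_that("six_frame_orfs finds the planted coding ORF with hand-checked
          properties", {
  nt <- paste0("ATG", strrep("GCT", 29), "TAA")
  orfs <- six_frame_orfs(nt, min_len = 90)
  f1 <- orfs[orfs$frame == 1L, ]
  expect_equal(nrow(f1), 1L)
  expect_equal(nchar(f1$aa_seq), 30L)
  expect_match(f1$aa_seq, "^M")
  expect_equal(f1$nt_start, 0L)
  expect_equal(f1$nt_end, 90L)
  expect_true(f1$bounded_3p)
  expect_false(f1$bounded_5p)
})

test_that("all-stop and empty sequences give no ORFs", {
  expect_equal(nrow(six_frame_orfs("TAATAATAA")), 0L)
  expect_equal(nrow(six_frame_orfs("")), 0L)
})

test_that("codons containing N translate to X and never terminate", {
  nt <- paste0("ATG", strrep("GCN", 29), "TAA")
  orfs <- six_frame_orfs(nt, min_len = 90)
  f1 <- orfs[orfs$frame == 1L, ]
  expect_equal(f1$aa_seq, paste0("M", strrep("X", 29)))
})

test_that("six_frame_orfs matches the brute-force oracle on random
          sequences", {
  set.seed(101)
  for (k in 1:60) {
    nt <- random_dna(sample(50:600, 1),
                     alphabet = c("A", "C", "G", "T", "N"))
    got <- six_frame_orfs(nt, min_len = 90)
    want <- oracle_orfs(nt, min_len = 90)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("predictions are substrings of a six-frame translation", {
  set.seed(7)
  for (k in 1:20) {
    nt <- random_dna(600)
    orfs <- six_frame_orfs(nt, min_len = 90)
    if (!nrow(orfs)) next
    pred <- select_best_protein(orfs)
    expect_true(any(vapply(orfs$aa_seq, grepl, logical(1),
                           pattern = pred$aa_seq, fixed = TRUE)))
  }
})

# hand-built ORF tables exercising the selection rules
mk_orf <- function(frame, len, m_at = NA, b5 = TRUE, b3 = TRUE,
                   start = 0L) {
  aa <- strrep("A", len)
  if (!is.na(m_at)) substr(aa, m_at, m_at) <- "M"
  data.frame(frame = frame, nt_start = start, nt_end = start + 3L * len,
             aa_seq = aa, has_internal_mstart = !is.na(m_at),
             bounded_5p = b5, bounded_3p = b3, stringsAsFactors = FALSE)
}

test_that("frame-of-best-hit beats a longer ORF in another frame", {
  orfs <- rbind(mk_orf(1L, 120, b5 = FALSE, b3 = FALSE),
                mk_orf(2L, 150, b5 = FALSE, b3 = FALSE))
  p <- select_best_protein(orfs, best_hit_frame = 1L)
  expect_equal(nchar(p$aa_seq), 120L)
  expect_equal(p$rule, "frame-of-best-hit")
  # no hit frame: longest overall
  p2 <- select_best_protein(orfs)
  expect_equal(nchar(p2$aa_seq), 150L)
  expect_equal(p2$rule, "longest-overall")
})

test_that("a stop-bounded M-start ORF at 75% of the longest overrides", {
  orfs <- rbind(mk_orf(1L, 100, b5 = FALSE, b3 = FALSE),
                mk_orf(2L, 80, m_at = 1, b5 = TRUE, b3 = TRUE))
  p <- select_best_protein(orfs)
  expect_equal(nchar(p$aa_seq), 80L)
  expect_equal(p$rule, "mstart-override")
  expect_true(p$is_mstart)
  # at 74% it must not override
  orfs2 <- rbind(mk_orf(1L, 100, b5 = FALSE, b3 = FALSE),
                 mk_orf(2L, 74, m_at = 1, b5 = TRUE, b3 = TRUE))
  expect_equal(select_best_protein(orfs2)$rule, "longest-overall")
})

test_that("M-start override demands stop bounds on both sides", {
  for (bounds in list(c(FALSE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))) {
    orfs <- rbind(mk_orf(1L, 100, b5 = FALSE, b3 = FALSE),
                  mk_orf(2L, 90, m_at = 1, b5 = bounds[1],
                         b3 = bounds[2]))
    expect_equal(select_best_protein(orfs)$rule, "longest-overall")
  }
})

test_that("M-start length is measured from the first methionine", {
  # 100 aa ORF whose M sits at position 20: M-start variant is 81 aa,
  # which clears 0.75 * 100
  orfs <- rbind(mk_orf(1L, 90, b5 = FALSE, b3 = FALSE),
                mk_orf(2L, 100, m_at = 20, b5 = TRUE, b3 = TRUE))
  p <- select_best_protein(orfs)
  expect_equal(p$rule, "mstart-override")
  expect_equal(nchar(p$aa_seq), 81L)
  expect_match(p$aa_seq, "^M")
  # M at 30 gives 71 aa < 75: no override
  orfs$aa_seq[2] <- sub("M", "A", orfs$aa_seq[2], fixed = TRUE)
  substr(orfs$aa_seq[2], 30, 30) <- "M"
  expect_equal(select_best_protein(orfs)$rule, "longest-overall")
})

test_that("ties break by frame order then position", {
  orfs <- rbind(mk_orf(-1L, 50, b5 = FALSE, b3 = FALSE, start = 0L),
                mk_orf(2L, 50, b5 = FALSE, b3 = FALSE, start = 30L),
                mk_orf(2L, 50, b5 = FALSE, b3 = FALSE, start = 6L))
  p <- select_best_protein(orfs)
  expect_equal(p$frame, 2L)
  # among co-longest in the same frame, smaller nt_start wins: check via
  # distinct sequences
  orfs$aa_seq[2] <- strrep("B", 50); orfs$aa_seq[3] <- strrep("D", 50)
  expect_equal(select_best_protein(orfs)$aa_seq, strrep("D", 50))
})

test_that("single ORF and degenerate inputs", {
  one <- mk_orf(3L, 40, b5 = FALSE, b3 = FALSE)
  p <- select_best_protein(one)
  expect_equal(p$rule, "longest-overall")
  expect_error(select_best_protein(one[0, ]), "no ORFs")
  # hit frame with no ORFs in it falls back to longest overall
  expect_equal(select_best_protein(one, best_hit_frame = 1L)$rule,
               "longest-overall")
})

test_that("min_len must be a codon multiple and alphabet is enforced", {
  expect_error(six_frame_orfs("ATGAAA", min_len = 10), "multiple of 3")
  expect_error(six_frame_orfs("ATGU"), "alphabet")
})
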