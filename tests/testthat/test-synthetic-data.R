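small_cfg <- function(seed = 11L, ...) {
  synthetic_config(n_background = 150L, n_silk_specific = 15L,
                   n_venom_families = 4L, family_size_range = c(2L, 4L),
                   seed = seed, ...)
}

test_that("config validation rejects out-of-range values", {
  expect_error(synthetic_config(ick_fraction = 1.5))
  expect_error(synthetic_config(venom_fold = 0.5))
  expect_error(synthetic_config(detect_prob = -0.1))
  expect_error(synthetic_config(nb_dispersion = 0))
  expect_error(generate_bundle(synthetic_config(
    n_background = 0L, n_silk_specific = 0L, n_venom_families = 0L)),
    "zero transcripts")
})

test_that("nothing planted means every label is broad", {
  b <- generate_bundle(synthetic_config(n_background = 40L,
                                        n_silk_specific = 0L,
                                        n_venom_families = 0L,
                                        seed = 3L))
  expect_true(all(b$truth$label == "broad"))
  expect_false(any(b$truth$secreted))
})

test_that("the same config and seed give a byte-identical bundle", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(cfg), d1)
  write_bundle(generate_bundle(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # and a different seed changes the sequences
  b3 <- generate_bundle(small_cfg(seed = 12L))
  expect_false(identical(b3$transcripts,
                         generate_bundle(cfg)$transcripts))
})

test_that("counts are non-negative integers with totals near the
          configured library sizes", {
  cfg <- small_cfg()
  b <- generate_bundle(cfg)
  cm <- as.matrix(b$counts[, c("venom", "silk", "ceph")])
  expect_true(all(cm >= 0))
  expect_true(all(cm == round(cm)))
  # NB total: var = sum(mu) + dispersion * sum(mu^2); the observed
  # counts estimate mu, giving a slightly inflated (conservative) SD
  for (t in colnames(cm)) {
    lib <- cfg$library_sizes[[t]]
    sd_est <- sqrt(sum(cm[, t]) +
                     cfg$nb_dispersion * sum(as.numeric(cm[, t])^2))
    expect_lt(abs(sum(cm[, t]) - lib), 3 * sd_est)
  }
})

test_that("transcripts encode the truth protein in frame +1", {
  b <- generate_bundle(small_cfg())
  idx <- sample(seq_len(nrow(b$truth)), 20)
  for (i in idx) {
    orfs <- six_frame_orfs(b$transcripts[[b$truth$transcript_id[i]]])
    f1 <- orfs[orfs$frame == 1L & orfs$bounded_5p & orfs$bounded_3p, ]
    expect_true(b$truth$protein[i] %in%
                  substring(f1$aa_seq,
                            regexpr("M", f1$aa_seq, fixed = TRUE)))
  }
})

test_that("ICK-like proteins carry the planted framework", {
  set.seed(1)
  for (len in c(40, 60, 90, 120, 199)) {
    p <- make_ick_protein(len)
    expect_equal(nchar(p), len)
    expect_lt(nchar(p), 200)
    expect_match(p, "^M")
    mature <- substring(p, attr(p, "signal_end") + 1L)
    expect_equal(nchar(mature) - nchar(gsub("C", "", mature)), 8L)
    # signal segment is cysteine-free so the whole-protein count is 8
    expect_equal(nchar(p) - nchar(gsub("C", "", p)), 8L)
  }
  expect_error(make_ick_protein(39), "too small")
  expect_error(make_ick_protein(200), "< 200")
})

test_that("every generated ICK protein passes the cysteine screen and
          the framework rule", {
  set.seed(2)
  for (k in 1:50) {
    len <- sample(40:199, 1)
    p <- make_ick_protein(len)
    expect_equal(screen_cysteine_rich(setNames(as.character(p), "x")),
                 "x")
    fw <- extract_framework(as.character(p),
                            cleavage_pos = attr(p, "signal_end"))
    expect_true(fw$ick_candidate)
  }
})

test_that("tryptic digest follows cleave-after-K/R-not-before-P", {
  frags <- tryptic_digest("MKRAAAKPLLLR", min_len = 1)
  expect_equal(frags, c("MK", "R", "AAAKPLLLR"))
  expect_true("AAAKPLLLR" %in% tryptic_digest("MKRAAAKPLLLR"))
  # no cleavage sites: whole protein
  expect_equal(tryptic_digest("MAAAAAAA"), "MAAAAAAA")
})

test_that("peptide identifications honour detect_prob and cover
          secreted proteins", {
  cfg0 <- small_cfg(detect_prob = 0)
  b0 <- generate_bundle(cfg0)
  expect_equal(nrow(b0$peptides), 0L)

  cfg1 <- small_cfg(detect_prob = 1, decoy_fraction = 0)
  b1 <- generate_bundle(cfg1)
  expect_true(all(b1$peptides$peptide_prob >= 0.95))
  sec <- b1$truth[b1$truth$secreted, ]
  for (i in seq_len(nrow(sec))) {
    frags <- tryptic_digest(sec$protein[i])
    if (length(unique(frags)) >= 2) {
      expect_gte(sum(unique(frags) %in% b1$peptides$peptide_seq), 2)
    }
  }
})

test_that("secreted truth implies a signal interval", {
  b <- generate_bundle(small_cfg())
  expect_false(anyDuplicated(b$truth$transcript_id) > 0)
  expect_true(all(!b$truth$secreted | !is.na(b$truth$signal_end)))
  expect_true(all(b$signal$has_signal == !is.na(b$signal$cleavage_pos)))
})
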