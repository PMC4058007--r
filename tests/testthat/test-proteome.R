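test_that("peptide placement hand cases and the I/L rule", {
  pl <- map_peptides("AAK", c(p1 = "MAAKQ"))
  expect_equal(pl$start, 1L)
  expect_equal(pl$end, 4L)
  expect_false(pl$il_equivalent_match)

  pl2 <- map_peptides("PILK", c(p1 = "AAPLLKDD"))
  expect_equal(nrow(pl2), 1L)
  expect_true(pl2$il_equivalent_match)
  expect_equal(nrow(map_peptides("PILK", c(p1 = "AAPLLKDD"),
                                 il_equivalent = FALSE)), 0L)
  # repeated occurrences are all reported
  pl3 <- map_peptides("AAK", c(p1 = "AAKXAAK"))
  expect_equal(pl3$start, c(0L, 4L))
})

test_that("placements equal the all-substrings oracle on random input", {
  set.seed(17)
  prot <- setNames(vapply(1:8, function(i) random_protein(60),
                          character(1)), sprintf("p%d", 1:8))
  peps <- c(vapply(1:10, function(i) random_protein(5), character(1)),
            substring(prot[[1]], 11, 18), substring(prot[[3]], 40, 50))
  got <- map_peptides(peps, prot)
  got <- got[order(got$peptide, got$protein_id, got$start),
             c("peptide", "protein_id", "start", "end")]
  rownames(got) <- NULL
  want <- oracle_placements(peps, prot)
  want <- want[order(want$peptide, want$protein_id, want$start), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("coverage equals the interval-union oracle, with hand cases", {
  prot <- strrep("A", 10)
  pl <- data.frame(start = c(0L, 3L), end = c(5L, 8L))
  expect_equal(coverage(prot, pl), 80)
  expect_equal(coverage(prot, pl[0, ]), 0)
  expect_equal(coverage(prot, data.frame(start = 0L, end = 10L)), 100)
  expect_error(coverage(prot, data.frame(start = 5L, end = 12L)),
               "bounds")
  set.seed(23)
  for (k in 1:50) {
    L <- sample(20:200, 1)
    n <- sample(1:8, 1)
    s <- sample(0:(L - 2), n, replace = TRUE)
    e <- pmin(L, s + sample(1:30, n, replace = TRUE))
    got <- coverage(strrep("G", L), data.frame(start = s, end = e))
    expect_equal(got, 100 * oracle_union_len(s, e) / L)
  }
  # monotone as placements accumulate
  c1 <- coverage(prot, pl[1, , drop = FALSE])
  expect_gte(coverage(prot, pl), c1)
})

test_that("evidence filters: unique-peptide and probability rules", {
  prot <- c(pA = "MKAAAWDDKEEEFFRGGGK", pB = "MWWWHHHKDDDD")
  peps <- c("AAAWDDK", "EEEFFR", "GGGK", "WWWHHHK", "DDDD")
  pl <- map_peptides(peps, prot)
  pep_probs <- setNames(c(0.99, 0.99, 0.99, 0.99, 0.99), peps)
  # pA: protein prob high, 3 unique peptides -> confirmed
  # pB: 2 peptides but protein prob 0.90 -> rejected
  ev <- filter_evidence(pl, prot, pep_probs,
                        c(pA = 0.99, pB = 0.90))
  expect_true(ev$venom_confirmed[ev$protein_id == "pA"])
  expect_false(ev$venom_confirmed[ev$protein_id == "pB"])
  # one unique peptide at high probability is not enough
  ev1 <- filter_evidence(pl[pl$peptide == "AAAWDDK", ], prot,
                         pep_probs, c(pA = 0.99))
  expect_false(ev1$venom_confirmed)
  expect_equal(ev1$n_unique_peptides, 1L)
  # low-probability peptides are discarded before counting
  lowp <- setNames(rep(0.5, length(peps)), peps)
  expect_equal(nrow(filter_evidence(pl, prot, lowp, c(pA = 0.99))), 0L)
  # order invariance
  ev_rev <- filter_evidence(pl[rev(seq_len(nrow(pl))), ], prot,
                            pep_probs, c(pA = 0.99, pB = 0.90))
  expect_equal(ev_rev[order(ev_rev$protein_id), ],
               ev[order(ev$protein_id), ], ignore_attr = TRUE)
})

test_that("I/L variants collapse to one unique peptide", {
  prot <- c(pA = "MKAAAILDDKEEE")
  pl <- map_peptides(c("AAAILDDK", "AAALLDDK"), prot)
  ev <- filter_evidence(pl, prot,
                        c(AAAILDDK = 0.99, AAALLDDK = 0.99),
                        c(pA = 0.99))
  expect_equal(ev$n_unique_peptides, 1L)
  expect_false(ev$venom_confirmed)
})

test_that("secretome report partitions confirmed proteins", {
  ev <- data.frame(protein_id = c("a", "b", "c", "d"),
                   n_unique_peptides = c(3L, 2L, 5L, 1L),
                   pct_coverage = c(40, 20, 60, 5),
                   protein_prob = c(0.99, 0.99, 0.99, 0.99),
                   venom_confirmed = c(TRUE, TRUE, TRUE, FALSE))
  sig <- data.frame(protein_id = c("a", "b", "c"),
                    has_signal = c(TRUE, FALSE, TRUE))
  expect_warning(res <- classify_secretome(ev, sig, vst_ids = c("a", "b")),
                 "non-VST")
  expect_equal(res$n_confirmed, 3L)
  expect_equal(res$counts["VST", "signal"], 1L)
  expect_equal(res$counts["VST", "no_signal"], 1L)
  expect_equal(res$counts["non_VST", "signal"], 1L)
  expect_equal(res$pct_signal, 100 * 2 / 3)
  # empty confirmed set
  empty <- classify_secretome(ev[ev$protein_id == "d", ], sig, "a")
  expect_equal(sum(empty$counts), 0L)
})
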