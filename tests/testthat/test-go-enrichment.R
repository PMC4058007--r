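test_that("PWF is flat on a null, monotone under planted length bias,
          and 1 when everything is selected", {
  set.seed(21)
  n <- 2000
  lens <- round(rlnorm(n, log(800), 0.6))
  names(lens) <- sprintf("g%04d", 1:n)
  # null: selection independent of length
  vst <- rep(FALSE, n); vst[sample(n, 200)] <- TRUE
  w <- fit_pwf(lens, vst)
  expect_equal(sum(w), 200, tolerance = 1e-9)
  expect_lt(sd(w) / mean(w), 0.1)
  # planted bias: P(select) increases with length
  p_sel <- pmin(0.9, lens / max(lens))
  vst2 <- runif(n) < p_sel
  w2 <- fit_pwf(lens, vst2)
  ord <- order(lens)
  expect_true(all(diff(w2[ord]) >= -1e-12))
  expect_gt(cor(lens, w2), 0.5)
  # all selected
  expect_equal(unname(fit_pwf(lens, rep(TRUE, n))), rep(1, n))
  # degenerate lengths: uniform
  expect_equal(unname(fit_pwf(rep(100, 50),
                              c(rep(TRUE, 10), rep(FALSE, 40)))),
               rep(0.2, 50))
})

test_that("with uniform weights the resampling p-value matches the
          hypergeometric tail", {
  set.seed(31)
  n_bg <- 1000; term_size <- 200; n_vst <- 20
  bg <- sprintf("g%04d", 1:n_bg)
  term <- sample(bg, term_size)
  vst <- sample(bg, n_vst)
  go_tab <- data.frame(transcript_id = term, go_id = "GO:0000001")
  w <- setNames(rep(1, n_bg), bg)
  res <- weighted_resampling_test(go_tab, vst, w, n_resamples = 10000,
                                  seed = 99)
  obs <- sum(vst %in% term)
  expect_equal(res$n_vst, obs)
  expect_equal(res$n_bg, term_size)
  p_exact <- phyper(obs - 1, term_size, n_bg - term_size, n_vst,
                    lower.tail = FALSE)
  expect_lt(abs(res$p - p_exact), 0.01)
})

test_that("a term with no VST members has p near 1 and terms outside
          the background are skipped", {
  set.seed(41)
  bg <- sprintf("g%03d", 1:300)
  vst <- bg[1:30]
  go_tab <- data.frame(transcript_id = bg[101:150], go_id = "GO:1")
  w <- setNames(rep(1, 300), bg)
  res <- weighted_resampling_test(go_tab, vst, w, n_resamples = 500,
                                  seed = 2)
  expect_gt(res$p, 0.9)
  bad <- rbind(go_tab, data.frame(transcript_id = "missing",
                                  go_id = "GO:2"))
  expect_warning(
    res2 <- weighted_resampling_test(bad, vst, w, n_resamples = 50,
                                     seed = 2),
    "outside the background")
  expect_false("GO:2" %in% res2$go_id)
})

test_that("resampling is seed-reproducible", {
  set.seed(61)
  bg <- sprintf("g%03d", 1:200)
  go_tab <- data.frame(transcript_id = sample(bg, 120, replace = TRUE),
                       go_id = sample(paste0("GO:", 1:8), 120,
                                      replace = TRUE))
  w <- setNames(runif(200, 0.5, 2), bg)
  a <- weighted_resampling_test(go_tab, bg[1:25], w, 400, seed = 7)
  b <- weighted_resampling_test(go_tab, bg[1:25], w, 400, seed = 7)
  expect_identical(a, b)
})

test_that("null GO assignments give approximately uniform p-values", {
  # term sizes are kept large so the null count distribution is
  # fine-grained; with small terms the discreteness of the resampling
  # p-value dominates any KS comparison against a continuous uniform
  set.seed(71)
  n_bg <- 2000
  bg <- sprintf("g%04d", 1:n_bg)
  terms <- sprintf("GO:%03d", 1:80)
  go_tab <- data.frame(
    transcript_id = unlist(lapply(terms, function(t) sample(bg, 200))),
    go_id = rep(terms, each = 200))
  vst <- sample(bg, 400)
  w <- setNames(rep(1, n_bg), bg)
  res <- weighted_resampling_test(go_tab, vst, w, n_resamples = 2000,
                                  seed = 3)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  # critical value at alpha = 0.01 for n = 80 is ~0.182
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(res$p)))
})

test_that("BH step-up hand cases", {
  r <- bh_fdr(0.04)
  expect_equal(r$q, 0.04)
  expect_true(r$flagged)
  r3 <- bh_fdr(c(0.01, 0.02, 0.9))
  expect_equal(r3$q, c(0.03, 0.03, 0.9))
  expect_equal(r3$flagged, c(TRUE, TRUE, FALSE))
  rall <- bh_fdr(rep(1, 5))
  expect_false(any(rall$flagged))
  expect_equal(nrow(bh_fdr(numeric(0))), 0L)
})

test_that("a planted enriched term is flagged with high power", {
  set.seed(81)
  n_bg <- 1200
  bg <- sprintf("g%04d", 1:n_bg)
  lens <- setNames(round(rlnorm(n_bg, log(800), 0.5)), bg)
  hits <- 0
  n_rep <- 10
  for (r in 1:n_rep) {
    vst <- sample(bg, 80)
    # planted term: covers half the VSTs but only 4% of the rest
    planted <- union(sample(vst, 40), sample(setdiff(bg, vst), 45))
    null_terms <- sprintf("GO:%03d", 1:20)
    go_tab <- rbind(
      data.frame(transcript_id = planted, go_id = "GO:PLANT"),
      data.frame(
        transcript_id = unlist(lapply(null_terms,
                                      function(t) sample(bg, 40))),
        go_id = rep(null_terms, each = 40)))
    res <- go_enrichment(go_tab, vst, lens, n_resamples = 1500,
                         seed = 100 + r)
    if (res$flagged[res$go_id == "GO:PLANT"]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
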