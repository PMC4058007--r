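# Length-bias-corrected GO overrepresentation of the VST set.
#
# Long transcripts are more likely to reach detection/classification
# thresholds in count-based RNA-seq, which inflates GO categories rich in
# long genes. The correction fits a probability-weighting function (PWF):
# the probability of VST membership as a smoothed, monotone function of
# transcript length; the null distribution of each GO category count is
# then obtained by resampling VST-sized sets with those selection weights
# (explicit weighted resampling rather than a Wallenius approximation).
# The background/reference set is the caller's choice; the intended use is
# all transcripts above the expression floor (venom eCPM > 1).

#' Fit the length-bias probability weighting function
#'
#' Bins the background transcripts by length (quantile bins), computes
#' the VST proportion per bin, regularises it to be monotone in length
#' (isotonic regression, in the direction of the observed
#' length-membership correlation), and rescales so the weights sum to the
#' number of VSTs. Degenerate input (a single distinct length, or all
#' transcripts VST) yields uniform weights.
#'
#' @param lengths per-transcript length in nt (background set).
#' @param is_vst logical flags, same order.
#' @param n_bins number of length bins; default 20.
#' @return positive numeric vector of selection weights, named after
#'   `names(lengths)` when present; `sum(weights) == sum(is_vst)`.
#' @export
fit_pwf <- function(lengths, is_vst, n_bins = 20L) {
  stopifnot(length(lengths) == length(is_vst), length(lengths) > 0)
  n <- length(lengths)
  n_vst <- sum(is_vst)
  if (n_vst == 0) stop("no VST members in the background")
  uniform <- rep(n_vst / n, n)
  names(uniform) <- names(lengths)
  if (length(unique(lengths)) == 1L || n_vst == n) {
    if (n_vst == n) uniform[] <- 1
    return(uniform)
  }
  brk <- unique(stats::quantile(lengths, probs = seq(0, 1,
                                                     length.out = n_bins + 1)))
  if (length(brk) < 3L) return(uniform)
  bin <- cut(lengths, breaks = brk, include.lowest = TRUE, labels = FALSE)
  prop <- tapply(as.numeric(is_vst), bin, mean)
  mid <- tapply(lengths, bin, mean)
  increasing <- stats::cor(lengths, as.numeric(is_vst)) >= 0
  ord <- order(mid)
  y <- as.numeric(prop)[ord]
  fit <- if (increasing) stats::isoreg(y)$yf else rev(stats::isoreg(rev(y))$yf)
  fit <- pmax(fit, 1e-8)
  w <- fit[match(bin, sort(unique(bin))[ord])]
  w <- w * n_vst / sum(w)
  names(w) <- names(lengths)
  w
}

# Efraimidis-Spirakis weighted sampling without replacement: the m
# smallest exponential keys scaled by 1/weight form a draw with
# probability proportional to the weights.
.weighted_draw <- function(n, m, w) {
  keys <- stats::rexp(n) / w
  thr <- sort(keys, partial = m)[m]
  which(keys <= thr)[seq_len(m)]
}

#' Weighted-resampling overrepresentation test
#'
#' For each GO term, the observed VST member count is compared with its
#' null distribution over `n_resamples` draws of `|VST|` background
#' transcripts without replacement with probability proportional to the
#' PWF weights:
#' `p = (1 + #resamples with count >= observed) / (1 + n_resamples)`.
#'
#' @param go_table data.frame with columns `transcript_id`, `go_id`
#'   (optionally `ontology`).
#' @param vst_ids character vector of VST transcript ids (must lie in the
#'   background).
#' @param weights named selection weights over the background (from
#'   [fit_pwf()]).
#' @param n_resamples number of resamples; default 10000.
#' @param seed RNG seed for the resampling.
#' @return data.frame: `go_id` (plus `ontology` when supplied), `n_vst`,
#'   `n_bg`, `p`.
#' @export
weighted_resampling_test <- function(go_table, vst_ids, weights,
                                     n_resamples = 10000L, seed = 1L) {
  bg_ids <- names(weights)
  stopifnot(!is.null(bg_ids), all(vst_ids %in% bg_ids))
  known <- go_table$transcript_id %in% bg_ids
  if (!all(known)) {
    warning(sum(!known), " GO annotation rows refer to transcripts ",
            "outside the background; skipped")
    go_table <- go_table[known, , drop = FALSE]
  }
  if (!nrow(go_table)) {
    return(data.frame(go_id = character(0), n_vst = integer(0),
                      n_bg = integer(0), p = numeric(0)))
  }
  terms <- sort(unique(go_table$go_id))
  t_idx <- match(go_table$go_id, terms)
  x_idx <- match(go_table$transcript_id, bg_ids)
  M <- Matrix::sparseMatrix(i = t_idx, j = x_idx, x = 1,
                            dims = c(length(terms), length(bg_ids)))
  is_vst <- bg_ids %in% vst_ids
  obs <- as.numeric(M %*% is_vst)
  n_bg_term <- as.numeric(M %*% rep(1, length(bg_ids)))

  m <- sum(is_vst)
  sel <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(k)
      .weighted_draw(length(bg_ids), m, weights))
  })
  S <- Matrix::sparseMatrix(i = unlist(sel),
                            j = rep(seq_len(n_resamples), each = m),
                            x = 1,
                            dims = c(length(bg_ids), n_resamples))
  counts <- as.matrix(M %*% S)
  ge <- rowSums(counts >= obs)
  p <- (1 + ge) / (1 + n_resamples)

  out <- data.frame(go_id = terms, n_vst = as.integer(obs),
                    n_bg = as.integer(n_bg_term), p = p,
                    stringsAsFactors = FALSE)
  if ("ontology" %in% names(go_table)) {
    out$ontology <- go_table$ontology[match(terms, go_table$go_id)]
    out <- out[, c("go_id", "ontology", "n_vst", "n_bg", "p")]
  }
  out
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p p-values in (0, 1].
#' @param alpha FDR threshold for flagging; default 0.05.
#' @return data.frame `p`, `q`, `flagged` in input order (empty input
#'   gives an empty frame).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!length(p)) {
    return(data.frame(p = numeric(0), q = numeric(0),
                      flagged = logical(0)))
  }
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  data.frame(p = p, q = q, flagged = q <= alpha)
}

#' GO overrepresentation of the VST set, length-bias corrected
#'
#' Convenience wrapper: fits the PWF on the background, runs the weighted
#' resampling test, and applies BH FDR.
#'
#' @param go_table data.frame (`transcript_id`, `go_id`).
#' @param vst_ids VST transcript ids.
#' @param lengths named per-transcript lengths over the background set.
#' @param n_bins,n_resamples,seed,alpha passed through.
#' @return data.frame: `go_id`, `n_vst`, `n_bg`, `p`, `q`, `flagged`,
#'   sorted by `p`.
#' @export
go_enrichment <- function(go_table, vst_ids, lengths, n_bins = 20L,
                          n_resamples = 10000L, seed = 1L, alpha = 0.05) {
  stopifnot(!is.null(names(lengths)))
  w <- fit_pwf(lengths, names(lengths) %in% vst_ids, n_bins = n_bins)
  res <- weighted_resampling_test(go_table, vst_ids, w,
                                  n_resamples = n_resamples, seed = seed)
  fdr <- bh_fdr(res$p, alpha = alpha)
  res$q <- fdr$q
  res$flagged <- fdr$flagged
  res[order(res$p, res$go_id), , drop = FALSE]
}
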