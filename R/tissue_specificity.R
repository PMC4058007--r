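# Expression normalisation (eCPM, FPKM) and venom-gland-specific
# transcript (VST) classification.
#
# A transcript is a VST when it is either exclusively expressed in the
# venom gland (eCPM > min_ecpm in venom, zero in both other tissues) or
# falls in the upper tail (default 2.5%) of BOTH venom/silk and
# venom/cephalothorax eCPM ratio distributions over the remaining
# transcripts, with at least one eCPM in venom.

#' Expected counts per million
#'
#' `eCPM[t,i] = counts[t,i] / sum_i(counts[t,i]) * 1e6` per tissue column.
#'
#' @param counts numeric matrix or data.frame, transcripts x tissues;
#'   rownames are transcript ids.
#' @return matrix of eCPM values, same shape.
#' @export
compute_ecpm <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("tissue has zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 2L, tot, "/") * 1e6
}

#' Fragments per kilobase per million
#'
#' `FPKM[t,i] = counts[t,i] / (effective_length_kb[i] * total[t]/1e6)`.
#'
#' @param counts transcripts x tissues matrix of expected counts.
#' @param effective_lengths per-transcript effective length in nt (> 0).
#' @return matrix of FPKM values.
#' @export
compute_fpkm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(effective_lengths) == nrow(counts))
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("tissue has zero total counts")
  len_kb <- effective_lengths / 1000
  sweep(sweep(counts, 2L, tot / 1e6, "/"), 1L, len_kb, "/")
}

# nearest-rank upper quantile: value at ascending position ceil(p * n)
nearest_rank_quantile <- function(x, p) {
  n <- length(x)
  stopifnot(n > 0, p > 0, p <= 1)
  sort(x)[ceiling(p * n)]
}

#' Classify venom-gland-specific transcripts
#'
#' Implements the two-part VST rule. Exclusive: venom eCPM > `min_ecpm`
#' and zero eCPM in silk and cephalothorax. Ratio: among the remaining
#' transcripts with venom eCPM > 0, both per-tissue eCPM ratios
#' (venom/silk, venom/cephalothorax; a zero denominator gives `Inf`,
#' ranked above all finite values) must reach the nearest-rank
#' `1 - quantile` cutoff of their respective distributions, and venom
#' eCPM must be at least 1.
#'
#' @param ecpm eCPM matrix with columns `venom`, `silk`, `ceph` and
#'   transcript ids as rownames.
#' @param quantile upper-tail fraction for the ratio rule; default 0.025.
#' @param min_ecpm venom eCPM threshold for the exclusive rule (strict
#'   inequality); default 1.
#' @return object of class `vst_result`: list with `table` (data.frame:
#'   `transcript_id`, eCPM per tissue, `ratio_silk`, `ratio_ceph`,
#'   `class` in `{exclusive, ratio_vst, background}`), realized
#'   `fold_cutoff_silk` / `fold_cutoff_ceph`, and the parameters used.
#' @export
classify_vst <- function(ecpm, quantile = 0.025, min_ecpm = 1) {
  ecpm <- as.matrix(ecpm)
  stopifnot(all(c("venom", "silk", "ceph") %in% colnames(ecpm)),
            !is.null(rownames(ecpm)))
  v <- ecpm[, "venom"]; s <- ecpm[, "silk"]; cph <- ecpm[, "ceph"]

  exclusive <- v > min_ecpm & s == 0 & cph == 0
  remaining <- v > 0 & !exclusive
  r_s <- ifelse(s == 0, Inf, v / s)
  r_c <- ifelse(cph == 0, Inf, v / cph)

  n_rem <- sum(remaining)
  if (n_rem == 0) {
    cut_s <- cut_c <- Inf
  } else {
    if (n_rem < 40) {
      warning("only ", n_rem, " transcripts in the ratio reference ",
              "distribution; the ", quantile * 100,
              "% upper-tail cutoff is unstable")
    }
    cut_s <- nearest_rank_quantile(r_s[remaining], 1 - quantile)
    cut_c <- nearest_rank_quantile(r_c[remaining], 1 - quantile)
  }

  ratio_vst <- remaining & r_s >= cut_s & r_c >= cut_c & v >= 1
  cls <- ifelse(exclusive, "exclusive",
                ifelse(ratio_vst, "ratio_vst", "background"))

  structure(list(
    table = data.frame(
      transcript_id = rownames(ecpm),
      eCPM_venom = unname(v), eCPM_silk = unname(s),
      eCPM_ceph = unname(cph),
      ratio_silk = unname(r_s), ratio_ceph = unname(r_c),
      class = unname(cls), stringsAsFactors = FALSE),
    fold_cutoff_silk = unname(cut_s),
    fold_cutoff_ceph = unname(cut_c),
    quantile = quantile, min_ecpm = min_ecpm),
    class = "vst_result")
}

#' @export
print.vst_result <- function(x, ...) {
  tab <- table(factor(x$table$class,
                      levels = c("exclusive", "ratio_vst", "background")))
  cat("VST classification over", nrow(x$table), "transcripts\n")
  cat("  exclusive:", tab[["exclusive"]],
      " ratio_vst:", tab[["ratio_vst"]],
      " background:", tab[["background"]], "\n")
  cat(sprintf("  realized fold cutoffs: silk %.3g, cephalothorax %.3g\n",
              x$fold_cutoff_silk, x$fold_cutoff_ceph))
  cat(sprintf("  (upper %.3g%% ratio rule, exclusive rule eCPM > %g)\n",
              x$quantile * 100, x$min_ecpm))
  invisible(x)
}

#' VST ids from a classification result
#' @param x a `vst_result`.
#' @return character vector of transcript ids classified `exclusive` or
#'   `ratio_vst`.
#' @export
vst_ids <- function(x) {
  stopifnot(inherits(x, "vst_result"))
  x$table$transcript_id[x$table$class != "background"]
}
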