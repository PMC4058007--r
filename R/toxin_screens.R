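# Toxin candidate screens over the VST set: keyword category tagging from
# homology annotations, the small cysteine-rich protein screen, cysteine
# framework extraction for inhibitor-cystine-knot (ICK) candidacy, and
# category-wise expression summaries.

#' Load toxin category keyword rules
#'
#' Rules are an ordered list (order = priority): each has a `name`, a
#' non-empty case-insensitive `keywords` list matched as substrings of the
#' hit description, and optionally `max_evalue` (default 1e-5). The
#' package ships an editable default rule set covering the classic black
#' widow venom categories (latrotoxin, ICK/CSTX, latrodectin, CRISP,
#' venom enzymes, leucine-rich repeat proteins).
#'
#' @param path YAML rules file; defaults to the shipped rule set.
#' @return list of rules.
#' @export
load_category_rules <- function(path = system.file(
    "extdata", "toxin_categories.yaml", package = "arachnotox")) {
  rules <- yaml::read_yaml(path)
  for (r in rules) {
    if (is.null(r$name) || !length(r$keywords) ||
        !all(nzchar(unlist(r$keywords)))) {
      stop("each rule needs a name and a non-empty keyword list")
    }
  }
  rules
}

#' Assign a toxin category to every transcript
#'
#' The first rule (in priority order) with a keyword occurring
#' case-insensitively in the transcript's hit description assigns the
#' category. Transcripts with no annotation row, or whose hit e-value
#' exceeds the rule-set e-value cutoff, get `no_hit`; annotated
#' transcripts matching no rule get `other`.
#'
#' @param annotations data.frame with columns `transcript_id`,
#'   `hit_description`, `evalue`; at most one row per transcript.
#' @param transcripts character vector of transcript ids to categorise.
#' @param rules list from [load_category_rules()].
#' @param max_evalue e-value cutoff applied to all hits; default 1e-5.
#' @return named character vector: transcript id -> category.
#' @export
tag_categories <- function(annotations, transcripts,
                           rules = load_category_rules(),
                           max_evalue = 1e-5) {
  if (anyDuplicated(annotations$transcript_id)) {
    stop("duplicate transcript rows in annotation table")
  }
  ann <- annotations[match(transcripts, annotations$transcript_id), ,
                     drop = FALSE]
  out <- rep("no_hit", length(transcripts))
  has_hit <- !is.na(ann$hit_description) & !is.na(ann$evalue) &
    ann$evalue <= max_evalue
  desc <- tolower(ann$hit_description[has_hit])
  cat_hit <- rep("other", length(desc))
  unmatched <- rep(TRUE, length(desc))
  for (r in rules) {
    ev_ok <- if (is.null(r$max_evalue)) TRUE
             else ann$evalue[has_hit] <= r$max_evalue
    for (kw in unlist(r$keywords)) {
      m <- unmatched & ev_ok & grepl(tolower(kw), desc, fixed = TRUE)
      cat_hit[m] <- r$name
      unmatched[m] <- FALSE
    }
  }
  out[has_hit] <- cat_hit
  stats::setNames(out, transcripts)
}

#' Screen for small cysteine-rich proteins
#'
#' Candidate novel knottin-type toxins: proteins strictly shorter than
#' `max_len` residues with at least `min_cys` cysteines (six are needed
#' for the three disulfide bonds of the ICK fold), and, by default, an
#' N-terminal methionine.
#'
#' @param proteins named character vector of best protein predictions.
#' @param max_len exclusive length bound in residues; default 200.
#' @param min_cys minimum cysteine count; default 6.
#' @param require_mstart require `M` at position 1; default TRUE.
#' @return character vector of candidate protein ids (input order).
#' @export
screen_cysteine_rich <- function(proteins, max_len = 200L, min_cys = 6L,
                                 require_mstart = TRUE) {
  stopifnot(!is.null(names(proteins)))
  len <- nchar(proteins)
  ncys <- nchar(proteins) - nchar(gsub("C", "", proteins, fixed = TRUE))
  ok <- len < max_len & ncys >= min_cys
  if (require_mstart) ok <- ok & startsWith(proteins, "M")
  names(proteins)[ok]
}

#' Extract the cysteine framework of a (mature) protein
#'
#' Computes cysteine positions and inter-cysteine spacings on the mature
#' region (after the signal-peptide cleavage site when one is annotated,
#' else the whole sequence) and applies a transparent rule-based ICK
#' screen: at least `min_cys` cysteines, at least one adjacent or
#' near-adjacent cysteine pair (spacing <= `near_adjacent_max`) among
#' cysteines 3-6, and the first two spacings each at most
#' `max_first_spacing` residues.
#'
#' @param protein protein sequence.
#' @param cleavage_pos 1-based position of the last signal-peptide
#'   residue, or `NULL`/`NA` when no signal is annotated; must be smaller
#'   than the sequence length.
#' @param min_cys,near_adjacent_max,max_first_spacing screen parameters.
#' @return list: `mature_start` (1-based), `cys_positions` (relative to
#'   the mature region), `n_cys`, `spacings` (residues between
#'   consecutive cysteines; length `n_cys - 1`), `ick_candidate`.
#' @export
extract_framework <- function(protein, cleavage_pos = NULL, min_cys = 6L,
                              near_adjacent_max = 1L,
                              max_first_spacing = 16L) {
  stopifnot(nzchar(protein))
  if (is.null(cleavage_pos) || is.na(cleavage_pos)) cleavage_pos <- 0L
  if (cleavage_pos >= nchar(protein)) {
    stop("cleavage position must lie within the sequence")
  }
  mature <- substring(protein, cleavage_pos + 1L)
  pos <- as.integer(gregexpr("C", mature, fixed = TRUE)[[1L]])
  if (length(pos) == 1L && pos[1L] == -1L) pos <- integer(0)
  n_cys <- length(pos)
  spacings <- if (n_cys > 1L) diff(pos) - 1L else integer(0)

  ick <- FALSE
  if (n_cys >= min_cys) {
    # pairs among cysteines 3-6 are spacings 3..5
    pair_idx <- 3:min(5L, length(spacings))
    ick <- any(spacings[pair_idx] <= near_adjacent_max) &&
      all(spacings[1:2] <= max_first_spacing)
  }
  list(mature_start = cleavage_pos + 1L, cys_positions = pos,
       n_cys = n_cys, spacings = spacings, ick_candidate = ick)
}

#' Summarise expression by toxin category
#'
#' For a set of venom-gland-specific transcripts, reports per category the
#' transcript count and the share of summed venom-gland FPKM, mirroring a
#' "number / % expression" toxin summary table.
#'
#' @param fpkm_venom named numeric vector: venom-gland FPKM per VST.
#' @param categories named character vector covering the same ids.
#' @return data.frame (`category`, `n`, `pct_expression`) sorted by
#'   decreasing expression share; percentages sum to 100.
#' @export
summarize_category_expression <- function(fpkm_venom, categories) {
  if (!length(fpkm_venom)) stop("empty VST set")
  ids <- names(fpkm_venom)
  stopifnot(!is.null(ids), all(ids %in% names(categories)))
  cat_of <- categories[ids]
  tot <- sum(fpkm_venom)
  if (tot <= 0) stop("summed FPKM is zero")
  agg <- tapply(fpkm_venom, cat_of, sum)
  cnt <- tapply(fpkm_venom, cat_of, length)
  out <- data.frame(category = names(agg), n = as.integer(cnt),
                    pct_expression = 100 * as.numeric(agg) / tot,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_expression, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
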