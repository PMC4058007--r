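# Six-frame ORF enumeration and best-protein selection.
#
# An ORF here is a maximal stop-free translated stretch within one reading
# frame (stop-to-stop, GetORF-style), reported in forward-strand 0-based
# half-open nucleotide coordinates. The M-start variant of an ORF (sequence
# from its first methionine) is derived secondarily during best-protein
# selection.

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

# codon -> amino acid lookup; any codon containing a non-ACGT base
# translates to X (never to stop), so ambiguous bases cannot fragment ORFs.
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
})

translate_frame <- function(nt, offset) {
  n <- nchar(nt)
  if (n - offset < 3L) return(character(0))
  n_codon <- (n - offset) %/% 3L
  starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

revcomp <- function(nt) {
  x <- chartr("ACGTN", "TGCAN", nt)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Enumerate open reading frames in all six frames
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code and returns every maximal stop-free stretch of at
#' least `min_len` nucleotides. Codons containing `N` translate to `X` and
#' never terminate an ORF.
#'
#' @param nt_seq a single nucleotide sequence over `A,C,G,T,N`
#'   (case-insensitive).
#' @param min_len minimum ORF length in nucleotides (multiple of 3);
#'   default 90, i.e. 30 residues.
#' @return a data.frame with one row per ORF, sorted by frame
#'   (`+1,+2,+3,-1,-2,-3`) then start: columns `frame` (integer in
#'   `{1,2,3,-1,-2,-3}`), `nt_start`, `nt_end` (0-based half-open on the
#'   forward strand), `aa_seq`, `has_internal_mstart` (TRUE if the ORF
#'   contains a methionine), `bounded_5p`, `bounded_3p` (TRUE when the ORF
#'   is flanked by a literal stop codon on that side, in reading
#'   direction; FALSE at a sequence end).
#' @export
#' @examples
#' six_frame_orfs(paste0("ATG", strrep("GCT", 29), "TAA"), min_len = 90)
six_frame_orfs <- function(nt_seq, min_len = 90L) {
  stopifnot(length(nt_seq) == 1L, is.character(nt_seq))
  if (min_len %% 3L != 0L) stop("min_len must be a multiple of 3")
  nt_seq <- toupper(nt_seq)
  if (!grepl("^[ACGTN]*$", nt_seq)) {
    stop("sequence must be over the alphabet {A,C,G,T,N}")
  }
  L <- nchar(nt_seq)
  out <- list()
  if (L >= 3L) {
    rc <- revcomp(nt_seq)
    for (fr in FRAME_ORDER) {
      seq_used <- if (fr > 0L) nt_seq else rc
      offset <- abs(fr) - 1L
      aa <- translate_frame(seq_used, offset)
      if (!length(aa)) next
      is_stop <- aa == "*"
      # maximal stop-free runs of codons
      run_id <- cumsum(is_stop)
      for (rid in unique(run_id[!is_stop])) {
        idx <- which(run_id == rid & !is_stop)
        aa_seq <- paste(aa[idx], collapse = "")
        if (3L * length(idx) < min_len) next
        # codon coordinates (0-based) on the strand actually read
        c0 <- offset + 3L * (idx[1L] - 1L)
        c1 <- offset + 3L * idx[length(idx)]
        bounded_5p <- idx[1L] > 1L && is_stop[idx[1L] - 1L]
        bounded_3p <- idx[length(idx)] < length(aa) &&
          is_stop[idx[length(idx)] + 1L]
        if (fr > 0L) {
          nt_start <- c0; nt_end <- c1
        } else {
          nt_start <- L - c1; nt_end <- L - c0
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = fr, nt_start = nt_start, nt_end = nt_end,
          aa_seq = aa_seq,
          has_internal_mstart = grepl("M", aa_seq, fixed = TRUE),
          bounded_5p = bounded_5p, bounded_3p = bounded_3p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), aa_seq = character(0),
                      has_internal_mstart = logical(0),
                      bounded_5p = logical(0), bounded_3p = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$frame, FRAME_ORDER), res$nt_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# index of the preferred ORF among rows of `orfs` ranked by aa length
# (desc), then frame order, then nt_start
.pick_longest <- function(orfs, lens = nchar(orfs$aa_seq)) {
  ord <- order(-lens, match(orfs$frame, FRAME_ORDER), orfs$nt_start)
  ord[1L]
}

#' Select the best protein prediction for a transcript
#'
#' Applies the best-protein rule: take the longest ORF in the frame of the
#' transcript's best homology hit (or the longest ORF overall when no hit
#' frame is supplied), but prefer a methionine-initiated ORF when one is
#' bounded by stop codons on both sides and reaches at least
#' `mstart_ratio` of the longest predicted ORF's length.
#'
#' @param orfs data.frame from [six_frame_orfs()]; must be non-empty.
#' @param best_hit_frame frame of the best homology hit (`1,2,3,-1,-2,-3`)
#'   or `NULL` when the transcript has no hit.
#' @param mstart_ratio minimum fraction of the longest ORF's length an
#'   M-start ORF must reach to override the default choice; default 0.75.
#' @param transcript_id optional id carried into the result.
#' @return one-row data.frame: `transcript_id`, `aa_seq`, `frame`,
#'   `is_mstart`, `rule` (one of `frame-of-best-hit`, `longest-overall`,
#'   `mstart-override`).
#' @export
select_best_protein <- function(orfs, best_hit_frame = NULL,
                                mstart_ratio = 0.75,
                                transcript_id = NA_character_) {
  if (!nrow(orfs)) stop("no ORFs: no protein prediction possible")
  lens <- nchar(orfs$aa_seq)
  longest_len <- max(lens)

  # M-start override: ORF truncated to its first methionine, eligible only
  # when the parent ORF is stop-bounded on both sides (full-length signal)
  elig <- orfs$has_internal_mstart & orfs$bounded_5p & orfs$bounded_3p
  if (any(elig)) {
    m_pos <- regexpr("M", orfs$aa_seq[elig], fixed = TRUE)
    m_seq <- substring(orfs$aa_seq[elig], m_pos)
    m_len <- nchar(m_seq)
    ok <- m_len >= mstart_ratio * longest_len
    if (any(ok)) {
      cand <- orfs[elig, , drop = FALSE][ok, , drop = FALSE]
      i <- .pick_longest(cand, m_len[ok])
      return(data.frame(transcript_id = transcript_id,
                        aa_seq = m_seq[ok][i], frame = cand$frame[i],
                        is_mstart = TRUE, rule = "mstart-override",
                        stringsAsFactors = FALSE))
    }
  }

  in_frame <- if (!is.null(best_hit_frame)) orfs$frame == best_hit_frame
              else rep(FALSE, nrow(orfs))
  if (any(in_frame)) {
    cand <- orfs[in_frame, , drop = FALSE]
    rule <- "frame-of-best-hit"
  } else {
    cand <- orfs
    rule <- "longest-overall"
  }
  i <- .pick_longest(cand)
  data.frame(transcript_id = transcript_id, aa_seq = cand$aa_seq[i],
             frame = cand$frame[i],
             is_mstart = startsWith(cand$aa_seq[i], "M"),
             rule = rule, stringsAsFactors = FALSE)
}

#' Predict best proteins for a set of transcripts
#'
#' Convenience wrapper running [six_frame_orfs()] and
#' [select_best_protein()] over a named vector of transcript sequences.
#' Transcripts with no ORF of at least `min_len` nucleotides are dropped.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param hit_frames optional named integer vector mapping transcript ids
#'   to the frame of their best homology hit.
#' @param min_len,mstart_ratio passed through.
#' @return data.frame of predictions (one row per retained transcript)
#'   with an `aa_length` column appended.
#' @export
predict_best_proteins <- function(seqs, hit_frames = NULL, min_len = 90L,
                                  mstart_ratio = 0.75) {
  stopifnot(!is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    orfs <- six_frame_orfs(seqs[[id]], min_len = min_len)
    if (!nrow(orfs)) return(NULL)
    bhf <- if (!is.null(hit_frames) && id %in% names(hit_frames)) {
      hit_frames[[id]]
    } else NULL
    select_best_protein(orfs, best_hit_frame = bhf,
                        mstart_ratio = mstart_ratio, transcript_id = id)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(transcript_id = character(0), aa_seq = character(0),
                      frame = integer(0), is_mstart = logical(0),
                      rule = character(0), stringsAsFactors = FALSE)
  }
  res$aa_length <- nchar(res$aa_seq)
  res
}
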