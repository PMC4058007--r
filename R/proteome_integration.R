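# Integration of venom shotgun-proteomics peptide identifications with
# the predicted proteins: peptide-to-protein placement (optionally
# treating the mass-indistinguishable residues I and L as equivalent),
# the evidence filters (probability >= 95%, >= 2 unique peptides),
# sequence coverage, and the 2x2 secretome report (VST x signal peptide).

.canon_il <- function(x) chartr("I", "L", x)

#' Map peptides onto predicted proteins
#'
#' Reports every occurrence of every peptide in every protein. With
#' `il_equivalent` (default), isoleucine and leucine are interchangeable
#' during matching; placements that required the equivalence are flagged.
#'
#' @param peptides character vector of non-empty peptide sequences.
#' @param proteins named character vector of protein sequences.
#' @param il_equivalent treat I and L as equal; default TRUE.
#' @return data.frame: `peptide`, `protein_id`, `start`, `end` (0-based
#'   half-open residue coordinates), `il_equivalent_match`.
#' @export
map_peptides <- function(peptides, proteins, il_equivalent = TRUE) {
  stopifnot(all(nzchar(peptides)), !is.null(names(proteins)))
  peptides <- unique(peptides)
  pat <- if (il_equivalent) .canon_il(peptides) else peptides
  subj <- if (il_equivalent) .canon_il(proteins) else proteins
  rows <- list()
  for (pi in seq_along(proteins)) {
    for (qi in seq_along(peptides)) {
      hit <- gregexpr(pat[qi], subj[[pi]], fixed = TRUE)[[1L]]
      if (hit[1L] == -1L) next
      starts <- as.integer(hit) - 1L
      ends <- starts + nchar(peptides[qi])
      exact <- vapply(starts, function(s) {
        substring(proteins[[pi]], s + 1L, s + nchar(peptides[qi])) ==
          peptides[qi]
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = peptides[qi], protein_id = names(proteins)[pi],
        start = starts, end = ends, il_equivalent_match = !exact,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      il_equivalent_match = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent sequence coverage of a protein by peptide placements
#'
#' @param protein the protein sequence.
#' @param placements data.frame with `start`, `end` (0-based half-open)
#'   placements on this protein.
#' @return percent of residues covered by the union of the placement
#'   intervals.
#' @export
coverage <- function(protein, placements) {
  L <- nchar(protein)
  if (!nrow(placements)) return(0)
  if (any(placements$start < 0) || any(placements$end > L) ||
      any(placements$end <= placements$start)) {
    stop("placement interval out of bounds")
  }
  covered <- logical(L)
  for (k in seq_len(nrow(placements))) {
    covered[(placements$start[k] + 1L):placements$end[k]] <- TRUE
  }
  100 * sum(covered) / L
}

#' Apply the venom-evidence filters
#'
#' Discards peptides whose peptide probability is below `min_prob`,
#' counts unique peptides per protein (distinct sequences after I/L
#' canonicalisation when that matching rule was used), and confirms a
#' protein as present in venom when its protein probability exceeds
#' `min_prob` and it has at least `min_unique` unique peptides.
#'
#' @param placements data.frame from [map_peptides()].
#' @param proteins named character vector (used for coverage).
#' @param peptide_probs named numeric vector: peptide sequence ->
#'   identification probability.
#' @param protein_probs named numeric vector: protein id -> probability.
#' @param min_prob probability threshold; default 0.95 (peptides kept at
#'   `>=`, proteins require strictly greater).
#' @param min_unique minimum unique peptides; default 2.
#' @param il_equivalent peptides were matched under I/L equivalence.
#' @return data.frame, one row per protein with any surviving placement:
#'   `protein_id`, `n_unique_peptides`, `pct_coverage`, `protein_prob`,
#'   `venom_confirmed`.
#' @export
filter_evidence <- function(placements, proteins, peptide_probs,
                            protein_probs, min_prob = 0.95,
                            min_unique = 2L, il_equivalent = TRUE) {
  stopifnot(all(peptide_probs >= 0 & peptide_probs <= 1),
            all(protein_probs >= 0 & protein_probs <= 1))
  pp <- peptide_probs[placements$peptide]
  keep <- !is.na(pp) & pp >= min_prob
  placements <- placements[keep, , drop = FALSE]
  prot_ids <- sort(unique(placements$protein_id))
  rows <- lapply(prot_ids, function(id) {
    pl <- placements[placements$protein_id == id, , drop = FALSE]
    key <- if (il_equivalent) .canon_il(pl$peptide) else pl$peptide
    n_unique <- length(unique(key))
    prob <- protein_probs[[id]]
    if (is.null(prob) || is.na(prob)) prob <- 0
    data.frame(protein_id = id, n_unique_peptides = n_unique,
               pct_coverage = coverage(proteins[[id]], pl),
               protein_prob = prob,
               venom_confirmed = prob > min_prob & n_unique >= min_unique,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0),
                      n_unique_peptides = integer(0),
                      pct_coverage = numeric(0), protein_prob = numeric(0),
                      venom_confirmed = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Partition confirmed proteins by VST membership and signal peptide
#'
#' Cross-tabulates the venom-confirmed proteins into the 2x2 of
#' (predicted from a VST or not) x (signal peptide predicted or not) —
#' the proteome-confirmed secretome report.
#'
#' @param evidence data.frame from [filter_evidence()].
#' @param signal_table data.frame with `protein_id`, `has_signal`.
#' @param vst_ids transcript/protein ids classified venom-gland-specific.
#' @return list: `counts` (2x2 integer matrix, rows VST/non-VST, columns
#'   signal/no_signal), `n_confirmed`, `pct_signal` (percent of confirmed
#'   proteins with a signal), `table` (per-protein assignments).
#' @export
classify_secretome <- function(evidence, signal_table, vst_ids) {
  conf <- evidence[evidence$venom_confirmed, , drop = FALSE]
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("VST", "non_VST"),
                                   c("signal", "no_signal")))
  if (nrow(conf)) {
    in_vst <- conf$protein_id %in% vst_ids
    if (any(!in_vst)) {
      warning(sum(!in_vst), " confirmed protein(s) absent from the VST ",
              "classification; counted as non-VST")
    }
    sig <- signal_table$has_signal[match(conf$protein_id,
                                         signal_table$protein_id)]
    sig[is.na(sig)] <- FALSE
    for (k in seq_len(nrow(conf))) {
      counts[if (in_vst[k]) 1L else 2L, if (sig[k]) 1L else 2L] <-
        counts[if (in_vst[k]) 1L else 2L, if (sig[k]) 1L else 2L] + 1L
    }
    tab <- data.frame(protein_id = conf$protein_id, is_vst = in_vst,
                      has_signal = sig, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(protein_id = character(0), is_vst = logical(0),
                      has_signal = logical(0), stringsAsFactors = FALSE)
  }
  n_conf <- nrow(conf)
  list(counts = counts, n_confirmed = n_conf,
       pct_signal = if (n_conf) 100 * sum(counts[, "signal"]) / n_conf
                    else 0,
       table = tab)
}
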