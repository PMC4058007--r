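# Seeded synthetic three-tissue transcriptome bundle with known ground
# truth. The generator emulates the design of a black-widow venom study:
# one RNA-seq library each from venom gland, silk gland and cephalothorax
# (venom gland removed); planted venom-specific gene families — long
# ankyrin-repeat latrotoxin-like proteins and short signal-peptide
# 8-cysteine ICK-like proteins — over broadly expressed and silk-specific
# background transcripts; negative-binomial counts; and in-silico tryptic
# peptide identifications for the secreted (ICK-like) proteins.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_NO_C <- setdiff(AA20, "C")
HYDROPHOBIC <- c("A", "L", "V", "I", "F", "W")

# amino acid -> synonymous codons (stops excluded)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[setdiff(unique(gc), "*")]
})

#' Configuration for the synthetic transcriptome bundle
#'
#' Defaults describe the emulated study design at desk scale: 2,000
#' broadly expressed transcripts, 100 silk-specific, 12 venom-specific
#' families of 4-8 paralogs (half short secreted ICK-like, half long
#' latrotoxin-like), 500-fold venom enrichment, 55% of venom transcripts
#' exclusively expressed (matching the observed exclusive/ratio mix),
#' negative-binomial dispersion 0.05, and library sizes 5M/1.5M/5M
#' mirroring the study's venom/silk/cephalothorax read-depth ratios at
#' roughly one tenth scale.
#'
#' @param n_background broadly expressed transcripts.
#' @param n_silk_specific silk-gland-specific transcripts.
#' @param n_venom_families planted venom-specific families.
#' @param family_size_range integer (min, max) paralogs per family.
#' @param ick_fraction fraction of venom families that are ICK-like (the
#'   rest are latrotoxin-like).
#' @param venom_fold mean fold enrichment of venom families in venom
#'   tissue (also used for silk-specific transcripts in silk); >= 1.
#' @param exclusive_fraction fraction of venom-family transcripts planted
#'   with zero expression outside the venom gland.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param library_sizes named numeric: expected total counts per tissue.
#' @param detect_prob probability a tryptic peptide of a secreted protein
#'   is detected.
#' @param decoy_fraction decoy (shuffled) peptides as a fraction of true
#'   detections.
#' @param paralog_divergence per-residue substitution rate between a
#'   family ancestor and each paralog.
#' @param n_reps libraries per tissue (1 emulates the study design).
#' @param seed random seed; the same config and seed give a
#'   byte-identical bundle.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_background = 2000L, n_silk_specific = 100L,
                             n_venom_families = 12L,
                             family_size_range = c(4L, 8L),
                             ick_fraction = 0.5, venom_fold = 500,
                             exclusive_fraction = 0.55,
                             nb_dispersion = 0.05,
                             library_sizes = c(venom = 5e6, silk = 1.5e6,
                                               ceph = 5e6),
                             detect_prob = 0.9, decoy_fraction = 0.1,
                             paralog_divergence = 0.10, n_reps = 1L,
                             seed = 1L) {
  cfg <- list(n_background = as.integer(n_background),
              n_silk_specific = as.integer(n_silk_specific),
              n_venom_families = as.integer(n_venom_families),
              family_size_range = as.integer(family_size_range),
              ick_fraction = ick_fraction, venom_fold = venom_fold,
              exclusive_fraction = exclusive_fraction,
              nb_dispersion = nb_dispersion,
              library_sizes = library_sizes,
              detect_prob = detect_prob,
              decoy_fraction = decoy_fraction,
              paralog_divergence = paralog_divergence,
              n_reps = as.integer(n_reps), seed = as.integer(seed))
  stopifnot(cfg$n_background >= 0L, cfg$n_silk_specific >= 0L,
            cfg$n_venom_families >= 0L,
            length(cfg$family_size_range) == 2L,
            cfg$family_size_range[1L] >= 1L,
            cfg$family_size_range[2L] >= cfg$family_size_range[1L],
            cfg$ick_fraction >= 0, cfg$ick_fraction <= 1,
            cfg$venom_fold >= 1,
            cfg$exclusive_fraction >= 0, cfg$exclusive_fraction <= 1,
            cfg$nb_dispersion > 0,
            all(c("venom", "silk", "ceph") %in% names(cfg$library_sizes)),
            all(cfg$library_sizes > 0),
            cfg$detect_prob >= 0, cfg$detect_prob <= 1,
            cfg$decoy_fraction >= 0, cfg$n_reps >= 1L)
  structure(cfg, class = "synthetic_config")
}

#' Generate a short secreted 8-cysteine ICK-like protein
#'
#' Builds an N-terminal hydrophobic signal-like segment followed by a
#' mature region with exactly eight cysteines whose spacing satisfies the
#' default ICK framework screen (a near-adjacent pair among cysteines
#' 3-6; first two spacings short). Draws from the current RNG state —
#' seed externally for reproducibility.
#'
#' @param length total protein length in residues (>= 40 and < 200).
#' @return the protein sequence, with attribute `signal_end` (1-based
#'   position of the last signal residue).
#' @export
make_ick_protein <- function(length) {
  if (length < 40L) stop("length too small to place 8 cysteines")
  if (length >= 200L) stop("ICK-like proteins must be < 200 residues")
  signal_len <- max(12L, min(20L, length - 26L))
  mature_len <- length - signal_len
  s3 <- sample(0:1, 1L)
  smin <- c(1L, 1L, s3, 1L, 1L, 1L, 1L)
  pre <- 1L
  budget <- mature_len - 8L - sum(smin) - pre
  if (budget < 0L) stop("length too small to place 8 cysteines")
  # distribute the slack over pre, flexible spacings and the tail,
  # keeping the first two spacings <= 16 so the screen's rule holds
  sp <- smin
  tail_len <- 0L
  if (budget > 0L) {
    slots <- sample(c(1L, 2L, 4L, 6L, 7L, 8L, 9L), budget, replace = TRUE,
                    prob = c(1, 1, 2, 2, 2, 1, 4))
    for (sl in slots) {
      if (sl <= 7L) {
        if (sl <= 2L && sp[sl] >= 8L) { tail_len <- tail_len + 1L; next }
        sp[sl] <- sp[sl] + 1L
      } else if (sl == 8L) pre <- pre + 1L
      else tail_len <- tail_len + 1L
    }
  }
  fill <- function(k) if (k > 0L) sample(AA_NO_C, k, replace = TRUE)
                      else character(0)
  signal <- c("M", sample(HYDROPHOBIC, signal_len - 1L, replace = TRUE))
  mature <- c(fill(pre))
  for (k in 1:8) {
    mature <- c(mature, "C", if (k < 8L) fill(sp[k]) else fill(tail_len))
  }
  structure(paste(c(signal, mature), collapse = ""),
            signal_end = signal_len)
}

# latrotoxin-like: conserved N-terminus + tandem array of a
# family-specific ankyrin-like 33-residue unit (no cysteine constraint)
make_latrotoxin_protein <- function(n_units = sample(12:18, 1L)) {
  unit <- sample(AA20, 33L, replace = TRUE)
  nterm <- c("M", sample(AA20, 59L, replace = TRUE))
  paste(c(nterm, rep(unit, n_units)), collapse = "")
}

# substitute residues at rate `rate`, never touching position 1 (the M)
# or any cysteine, and never introducing a cysteine — framework-preserving
mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  can <- which(aa != "C" & seq_along(aa) > 1L)
  hit <- can[stats::runif(length(can)) < rate]
  if (length(hit)) {
    aa[hit] <- vapply(aa[hit], function(old)
      sample(setdiff(AA_NO_C, old), 1L), character(1))
  }
  paste(aa, collapse = "")
}

# reverse-translate with uniform synonymous codon choice
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cods <- .codons_by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# transcript = 5'UTR (ending with an in-frame stop) + CDS + stop + 3'UTR;
# UTR lengths uniform over multiples of 3 in [30, 300] keep the CDS in
# frame +1 and make the true protein the first M of its stop-bounded ORF
build_transcript <- function(protein) {
  utr5_len <- 3L * sample(10:100, 1L)
  utr3_len <- 3L * sample(10:100, 1L)
  utr5 <- paste(sample(c("A", "C", "G", "T"), utr5_len - 3L,
                       replace = TRUE), collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
                collapse = "")
  paste0(utr5, "TAA", reverse_translate(protein), "TAA", utr3)
}

#' In-silico tryptic digest
#'
#' Cleaves C-terminal of K or R except before P; fragments shorter than
#' `min_len` residues are discarded.
#'
#' @param protein protein sequence.
#' @param min_len minimum peptide length; default 7.
#' @return character vector of peptides (N- to C-terminal order).
#' @export
tryptic_digest <- function(protein, min_len = 7L) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  frags <- substring(protein, head(bounds, -1L) + 1L, bounds[-1L])
  frags[nchar(frags) >= min_len]
}

#' Generate the synthetic transcriptome bundle
#'
#' Produces transcripts (encoding the truth proteins in frame +1 with
#' UTRs), negative-binomial per-tissue counts scaled to the configured
#' library sizes, a homology annotation table (toxin-keyword descriptions
#' for planted families, neutral ones for background, a fraction with no
#' hit), a GO table with a toxin-activity term enriched in venom
#' families, signal-peptide calls, peptide identifications, and the
#' per-transcript ground truth. Fully determined by the config and its
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle`: `transcripts` (named
#'   character), `counts`, `annotations`, `go`, `signal`, `peptides`
#'   (data.frames) and `truth` (data.frame with per-transcript label,
#'   family, ICK flag, signal interval, protein, secreted and
#'   planted-exclusive flags).
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n_total <- config$n_background + config$n_silk_specific +
    config$n_venom_families
  if (n_total == 0L) stop("zero transcripts requested")

  core <- with_seed(config$seed, .generate_core(config))
  core$peptides <- generate_peptide_ids(core$truth, config)
  structure(core, class = "synthetic_bundle")
}

.generate_core <- function(config) {
  fams <- list()
  n_ick_fam <- round(config$ick_fraction * config$n_venom_families)
  truth_rows <- list()
  proteins <- character(0)

  # --- venom families -------------------------------------------------
  for (f in seq_len(config$n_venom_families)) {
    is_ick <- f <= n_ick_fam
    size <- sample(config$family_size_range[1L]:config$family_size_range[2L],
                   1L)
    if (is_ick) {
      anc <- make_ick_protein(sample(80:120, 1L))
      signal_end <- attr(anc, "signal_end")
    } else {
      anc <- make_latrotoxin_protein()
      signal_end <- NA_integer_
    }
    for (j in seq_len(size)) {
      id <- sprintf("venom_comp%03d_c0_seq%d", f, j)
      prot <- mutate_protein(as.character(anc), config$paralog_divergence)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = id, label = "venom-specific",
        family_id = sprintf("fam%03d", f), is_ick_like = is_ick,
        signal_end = signal_end, secreted = is_ick,
        exclusive_planted = stats::runif(1L) < config$exclusive_fraction,
        protein = prot, stringsAsFactors = FALSE)
    }
  }

  # --- silk-specific and broad background -----------------------------
  for (k in seq_len(config$n_silk_specific)) {
    id <- sprintf("silk_Contig%05d", k)
    len <- sample(120:400, 1L)
    prot <- paste(c("M", sample(AA20, len - 1L, replace = TRUE)),
                  collapse = "")
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript_id = id, label = "silk-specific",
      family_id = NA_character_, is_ick_like = FALSE,
      signal_end = NA_integer_, secreted = FALSE,
      exclusive_planted = FALSE, protein = prot, stringsAsFactors = FALSE)
  }
  for (k in seq_len(config$n_background)) {
    id <- sprintf("Contig%05d", k)
    len <- sample(120:400, 1L)
    prot <- paste(c("M", sample(AA20, len - 1L, replace = TRUE)),
                  collapse = "")
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript_id = id, label = "broad", family_id = NA_character_,
      is_ick_like = FALSE, signal_end = NA_integer_, secreted = FALSE,
      exclusive_planted = FALSE, protein = prot, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)

  # --- transcripts ----------------------------------------------------
  transcripts <- vapply(truth$protein, build_transcript, character(1))
  names(transcripts) <- truth$transcript_id
  eff_len <- pmax(nchar(transcripts) - 199L, 1L)

  # --- expression profile and counts ----------------------------------
  n <- nrow(truth)
  rel <- matrix(0, n, 3L, dimnames = list(truth$transcript_id,
                                          c("venom", "silk", "ceph")))
  for (i in seq_len(n)) {
    if (truth$label[i] == "broad") {
      base <- stats::rlnorm(1L, log(50), 1)
      rel[i, ] <- base
    } else if (truth$label[i] == "silk-specific") {
      hi <- stats::rlnorm(1L, log(200), 0.5)
      rel[i, ] <- c(hi / config$venom_fold, hi, hi / config$venom_fold)
    } else {
      hi <- stats::rlnorm(1L, log(200), 0.5)
      lo <- if (truth$exclusive_planted[i]) 0 else hi / config$venom_fold
      rel[i, ] <- c(hi, lo, lo)
    }
  }
  tissues <- c("venom", "silk", "ceph")
  size_nb <- 1 / config$nb_dispersion
  count_cols <- list()
  for (t in tissues) {
    mu <- rel[, t] / sum(rel[, t]) * config$library_sizes[[t]]
    for (r in seq_len(config$n_reps)) {
      cn <- if (config$n_reps == 1L) t else paste0(t, "_", r)
      count_cols[[cn]] <- stats::rnbinom(n, mu = mu, size = size_nb)
    }
  }
  counts <- data.frame(transcript_id = truth$transcript_id,
                       count_cols, effective_length_nt = eff_len,
                       stringsAsFactors = FALSE, check.names = FALSE)

  # --- annotations ----------------------------------------------------
  latro_desc <- c("alpha-latrotoxin precursor",
                  "delta-latroinsectotoxin",
                  "latrotoxin-like ankyrin repeat protein")
  ick_desc <- c("CSTX toxin superfamily member", "omega-ctenitoxin",
                "knottin family venom peptide")
  neutral_desc <- c("actin", "40S ribosomal protein", "elongation factor",
                    "heat shock protein 70", "tubulin beta chain",
                    "ATP synthase subunit", "cytochrome c oxidase",
                    "ubiquitin-conjugating enzyme")
  ann_rows <- list()
  for (i in seq_len(n)) {
    lab <- truth$label[i]
    if (lab == "venom-specific") {
      desc <- if (truth$is_ick_like[i]) sample(ick_desc, 1L)
              else sample(latro_desc, 1L)
      ev <- 10^(-sample(30:120, 1L))
    } else if (lab == "silk-specific") {
      desc <- sample(c("major ampullate spidroin 1",
                       "fibroin heavy chain"), 1L)
      ev <- 10^(-sample(20:80, 1L))
    } else {
      if (stats::runif(1L) < 0.4) next  # no significant hit
      desc <- sample(neutral_desc, 1L)
      ev <- 10^(-sample(6:80, 1L))
    }
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      transcript_id = truth$transcript_id[i], hit_description = desc,
      evalue = ev, hit_frame = 1L, stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(transcript_id = character(0),
               hit_description = character(0), evalue = numeric(0),
               hit_frame = integer(0), stringsAsFactors = FALSE)

  # --- GO table (toxin-activity term enriched in venom families) ------
  go_pool <- sprintf("GO:%07d", seq(5000, 5000 + 29) * 10)
  go_rows <- list()
  for (i in seq_len(n)) {
    terms <- character(0)
    k <- sample(0:3, 1L)
    if (k > 0L) terms <- sample(go_pool, k)
    if (truth$label[i] == "venom-specific" && stats::runif(1L) < 0.6) {
      terms <- union(terms, "GO:0090729")
    }
    if (length(terms)) {
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        transcript_id = truth$transcript_id[i], go_id = terms,
        stringsAsFactors = FALSE)
    }
  }
  go <- do.call(rbind, go_rows)

  signal <- data.frame(
    protein_id = truth$transcript_id,
    has_signal = !is.na(truth$signal_end),
    cleavage_pos = truth$signal_end, stringsAsFactors = FALSE)

  list(transcripts = transcripts, counts = counts,
       annotations = annotations, go = go, signal = signal,
       truth = truth, config = config)
}

#' Generate in-silico peptide identifications
#'
#' Tryptic fragments of the secreted truth proteins, each detected with
#' probability `detect_prob`, with true-placement probabilities >= 0.95,
#' plus shuffled decoy peptides at low probability (`decoy_fraction`
#' decoys per true detection).
#'
#' @param truth truth data.frame from [generate_bundle()].
#' @param config the [synthetic_config()] used.
#' @return data.frame: `peptide_seq`, `peptide_prob`, `protein_prob`.
#' @export
generate_peptide_ids <- function(truth, config) {
  stopifnot(nrow(truth) > 0)
  with_seed(config$seed + 1L, {
    rows <- list()
    sec <- truth[truth$secreted, , drop = FALSE]
    for (i in seq_len(nrow(sec))) {
      frags <- tryptic_digest(sec$protein[i])
      if (!length(frags)) next
      det <- stats::runif(length(frags)) < config$detect_prob
      if (!any(det)) next
      prot_prob <- stats::runif(1L, 0.96, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_seq = frags[det],
        peptide_prob = stats::runif(sum(det), 0.95, 1),
        protein_prob = prot_prob, stringsAsFactors = FALSE)
    }
    peptides <- if (length(rows)) do.call(rbind, rows) else
      data.frame(peptide_seq = character(0), peptide_prob = numeric(0),
                 protein_prob = numeric(0), stringsAsFactors = FALSE)
    n_decoy <- round(config$decoy_fraction * nrow(peptides))
    if (n_decoy > 0L) {
      src <- sample(peptides$peptide_seq, n_decoy, replace = TRUE)
      decoys <- vapply(src, function(s)
        paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
        character(1))
      peptides <- rbind(peptides, data.frame(
        peptide_seq = unname(decoys),
        peptide_prob = stats::runif(n_decoy, 0.1, 0.5),
        protein_prob = stats::runif(n_decoy, 0.1, 0.5),
        stringsAsFactors = FALSE))
    }
    rownames(peptides) <- NULL
    peptides
  })
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits `transcripts.fasta`, `counts.tsv`, `annotations.tsv`, `go.tsv`,
#' `signal.tsv`, `peptides.tsv` and `truth.tsv`. Identical bundles write
#' byte-identical files.
#'
#' @param bundle from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$transcripts, file.path(dir, "transcripts.fasta"))
  write_tsv(bundle$counts, file.path(dir, "counts.tsv"))
  write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(bundle$go, file.path(dir, "go.tsv"))
  write_tsv(bundle$signal, file.path(dir, "signal.tsv"))
  write_tsv(bundle$peptides, file.path(dir, "peptides.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
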