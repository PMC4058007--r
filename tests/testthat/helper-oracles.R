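# Independent oracles. Each re-derives an expected result by a different
# route than the implementation (brute force, closed form, or a
# structurally different algorithm following the same stated conventions).

# --- six-frame ORF oracle --------------------------------------------
# translate each frame into one amino-acid string, then locate stop-free
# stretches with a regex (the implementation walks codon runs instead)
oracle_orfs <- function(nt, min_len = 90L) {
  nt <- toupper(nt)
  gc_tab <- Biostrings::GENETIC_CODE
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]),
              collapse = "")
  L <- nchar(nt)
  out <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0) nt else rc
    off <- abs(fr) - 1L
    body <- substring(s, off + 1L)
    nc <- nchar(body) %/% 3L
    if (nc == 0L) next
    cods <- substring(body, 3L * (seq_len(nc) - 1L) + 1L,
                      3L * seq_len(nc))
    aa <- unname(gc_tab[cods])
    aa[is.na(aa)] <- "X"
    aastr <- paste(aa, collapse = "")
    m <- gregexpr("[^*]+", aastr)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      p1 <- as.integer(m[k])
      len <- attr(m, "match.length")[k]
      if (3L * len < min_len) next
      c0 <- off + 3L * (p1 - 1L)
      c1 <- off + 3L * (p1 + len - 1L)
      seq_aa <- substring(aastr, p1, p1 + len - 1L)
      b5 <- p1 > 1L
      b3 <- (p1 + len - 1L) < nchar(aastr)
      out[[length(out) + 1L]] <- data.frame(
        frame = fr,
        nt_start = if (fr > 0) c0 else L - c1,
        nt_end = if (fr > 0) c1 else L - c0,
        aa_seq = seq_aa,
        has_internal_mstart = grepl("M", seq_aa, fixed = TRUE),
        bounded_5p = b5, bounded_3p = b3, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(match(res$frame, c(1, 2, 3, -1, -2, -3)),
                   res$nt_start), ]
  rownames(res) <- NULL
  res
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# --- affine Smith-Waterman oracle ------------------------------------
# plain-R Gotoh DP with the package's stated conventions: gap of length k
# costs open + k*ext; H tie-break diagonal > vertical > horizontal; E/F
# prefer closing the gap; end cell = smallest i then j among maxima.
oracle_sw <- function(a, b, gap_open = 11, gap_ext = 1) {
  # same pair-order canonicalisation convention as the implementation
  if (a > b) {
    r <- oracle_sw(b, a, gap_open, gap_ext)
    return(list(score = r$score, identity = r$identity,
                coverage_a = r$coverage_b, coverage_b = r$coverage_a))
  }
  data(BLOSUM62, package = "Biostrings",
       envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  TH <- matrix(0L, n + 1, m + 1)
  TE <- matrix(0L, n + 1, m + 1)
  TF <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- -1; bj <- -1
  for (i in 1:n) for (j in 1:m) {
    eo <- H[i + 1, j] - gap_open - gap_ext
    ee <- E[i + 1, j] - gap_ext
    if (eo >= ee) { E[i + 1, j + 1] <- eo; TE[i + 1, j + 1] <- 1L }
    else { E[i + 1, j + 1] <- ee; TE[i + 1, j + 1] <- 0L }
    fo <- H[i, j + 1] - gap_open - gap_ext
    fe <- F[i, j + 1] - gap_ext
    if (fo >= fe) { F[i + 1, j + 1] <- fo; TF[i + 1, j + 1] <- 1L }
    else { F[i + 1, j + 1] <- fe; TF[i + 1, j + 1] <- 0L }
    dg <- H[i, j] + S[av[i], bv[j]]
    h <- 0; t <- 0L
    if (dg >= h) { h <- dg; t <- 1L }
    if (F[i + 1, j + 1] > h) { h <- F[i + 1, j + 1]; t <- 2L }
    if (E[i + 1, j + 1] > h) { h <- E[i + 1, j + 1]; t <- 3L }
    H[i + 1, j + 1] <- h; TH[i + 1, j + 1] <- t
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best <= 0) {
    return(list(score = 0, identity = 0, coverage_a = 0, coverage_b = 0))
  }
  i <- bi; j <- bj; state <- 0L
  matches <- 0L; cols <- 0L; acols <- 0L; bcols <- 0L
  repeat {
    if (state == 0L) {
      t <- TH[i + 1, j + 1]
      if (t == 0L) break
      if (t == 1L) {
        cols <- cols + 1L; acols <- acols + 1L; bcols <- bcols + 1L
        if (av[i] == bv[j]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (t == 2L) state <- 2L else state <- 1L
    } else if (state == 1L) {
      cols <- cols + 1L; bcols <- bcols + 1L
      t <- TE[i + 1, j + 1]; j <- j - 1L
      state <- if (t == 1L) 0L else 1L
    } else {
      cols <- cols + 1L; acols <- acols + 1L
      t <- TF[i + 1, j + 1]; i <- i - 1L
      state <- if (t == 1L) 0L else 2L
    }
  }
  list(score = best, identity = 100 * matches / cols,
       coverage_a = acols / n, coverage_b = bcols / m)
}

# --- VST classification oracle ---------------------------------------
# stats::quantile type 1 is the nearest-rank inverse CDF; membership by
# direct re-application of the stated rules
oracle_vst <- function(ecpm, q = 0.025, min_ecpm = 1) {
  v <- ecpm[, "venom"]; s <- ecpm[, "silk"]; cc <- ecpm[, "ceph"]
  excl <- v > min_ecpm & s == 0 & cc == 0
  rem <- v > 0 & !excl
  rs <- ifelse(s == 0, Inf, v / s)
  rc <- ifelse(cc == 0, Inf, v / cc)
  cut_s <- stats::quantile(rs[rem], probs = 1 - q, type = 1,
                           names = FALSE)
  cut_c <- stats::quantile(rc[rem], probs = 1 - q, type = 1,
                           names = FALSE)
  ratio <- rem & rs >= cut_s & rc >= cut_c & v >= 1
  list(cut_s = cut_s, cut_c = cut_c,
       class = ifelse(excl, "exclusive",
                      ifelse(ratio, "ratio_vst", "background")))
}

# --- interval union oracle (merge sorted intervals) ------------------
oracle_union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e) cur_e <- max(cur_e, ends[k])
    else { tot <- tot + cur_e - cur_s; cur_s <- starts[k]; cur_e <- ends[k] }
  }
  tot + cur_e - cur_s
}

# --- peptide placement oracle (all substrings) -----------------------
oracle_placements <- function(peptides, proteins, il = TRUE) {
  canon <- function(x) if (il) chartr("I", "L", x) else x
  rows <- list()
  for (id in names(proteins)) {
    prot <- proteins[[id]]
    for (pep in unique(peptides)) {
      k <- nchar(pep)
      if (k > nchar(prot)) next
      for (s in 0:(nchar(prot) - k)) {
        sub <- substring(prot, s + 1, s + k)
        if (canon(sub) == canon(pep)) {
          rows[[length(rows) + 1]] <- data.frame(
            peptide = pep, protein_id = id, start = s, end = s + k,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
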