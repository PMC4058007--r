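# BLASTclust-style gene-family analysis: pairwise local-alignment
# similarity, single-linkage clustering at an identity/coverage threshold,
# and a sweep over a grid of thresholds.
#
# Scoring is fixed and logged (BLOSUM62, gap open 11, extension 1, a gap
# of length k costing 11 + k) with a deterministic traceback, so the same
# inputs always yield the same identity/coverage values.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

.encode_aa <- function(x, alphabet) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1L]], alphabet)
  if (anyNA(v)) stop("sequence contains residues outside the scoring matrix")
  v
}

#' Pairwise local-alignment similarity of two proteins
#'
#' Optimal Smith-Waterman local alignment under affine gap costs; percent
#' identity is matches over aligned columns (gap columns included) and
#' coverage of each sequence is its aligned (non-gap) columns over its
#' full length. A pair with no positive-scoring local alignment reports
#' identity 0 and coverage 0 and never forms a cluster edge.
#'
#' @param a,b non-empty protein sequences.
#' @param gap_open,gap_ext affine gap parameters (defaults 11 and 1).
#' @param matrix substitution matrix; default BLOSUM62.
#' @return list: `score`, `identity` (percent), `coverage_a`,
#'   `coverage_b` (fractions), `aligned_columns`.
#' @details Among co-optimal alignments the traceback is deterministic
#'   but depends on which sequence is which; to make the reported
#'   identity/coverage independent of pair order, the pair is
#'   canonicalised internally (lexicographically smaller sequence
#'   first) and the coverages mapped back.
#' @export
pairwise_similarity <- function(a, b, gap_open = 11, gap_ext = 1,
                                matrix = .blosum62) {
  stopifnot(nzchar(a), nzchar(b))
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  alphabet <- rownames(matrix)
  res <- sw_align_cpp(.encode_aa(a, alphabet), .encode_aa(b, alphabet),
                      matrix, gap_open, gap_ext)
  if (res$score <= 0) {
    return(list(score = 0, identity = 0, coverage_a = 0, coverage_b = 0,
                aligned_columns = 0L))
  }
  cov_a <- res$a_cols / nchar(a)
  cov_b <- res$b_cols / nchar(b)
  list(score = res$score,
       identity = 100 * res$matches / res$columns,
       coverage_a = if (swapped) cov_b else cov_a,
       coverage_b = if (swapped) cov_a else cov_b,
       aligned_columns = res$columns)
}

#' All-vs-all pairwise similarities
#'
#' @param proteins named character vector (>= 2 sequences).
#' @inheritParams pairwise_similarity
#' @return data.frame with one row per unordered pair: `id_a`, `id_b`,
#'   `identity`, `coverage_a`, `coverage_b`, `score`.
#' @export
all_pairwise_similarities <- function(proteins, gap_open = 11,
                                      gap_ext = 1, matrix = .blosum62) {
  ids <- names(proteins)
  stopifnot(!is.null(ids), length(ids) >= 2L, !anyDuplicated(ids))
  alphabet <- rownames(matrix)
  enc <- lapply(proteins, .encode_aa, alphabet = alphabet)
  lens <- nchar(proteins)
  pairs <- utils::combn(length(ids), 2L)
  n_pair <- ncol(pairs)
  out <- data.frame(id_a = ids[pairs[1L, ]], id_b = ids[pairs[2L, ]],
                    identity = numeric(n_pair),
                    coverage_a = numeric(n_pair),
                    coverage_b = numeric(n_pair),
                    score = numeric(n_pair), stringsAsFactors = FALSE)
  for (k in seq_len(n_pair)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    # same pair-order canonicalisation as pairwise_similarity()
    if (proteins[[i]] > proteins[[j]]) { tmp <- i; i <- j; j <- tmp }
    res <- sw_align_cpp(enc[[i]], enc[[j]], matrix, gap_open, gap_ext)
    if (res$score > 0) {
      ka <- if (i == pairs[1L, k]) "coverage_a" else "coverage_b"
      kb <- if (i == pairs[1L, k]) "coverage_b" else "coverage_a"
      out$identity[k] <- 100 * res$matches / res$columns
      out[[ka]][k] <- res$a_cols / lens[i]
      out[[kb]][k] <- res$b_cols / lens[j]
      out$score[k] <- res$score
    }
  }
  out
}

#' Single-linkage clusters at an identity/coverage threshold
#'
#' An edge joins a pair when identity >= `min_identity` and the coverage
#' of BOTH sequences >= `min_coverage`; clusters are the connected
#' components, singletons included.
#'
#' @param similarities data.frame from [all_pairwise_similarities()]
#'   (absent pairs mean no edge).
#' @param ids all sequence ids to partition.
#' @param min_identity percent identity threshold.
#' @param min_coverage percent coverage threshold (applied to both
#'   sequences).
#' @return named integer vector: id -> cluster index (1-based, ordered by
#'   first appearance).
#' @export
cluster_at <- function(similarities, ids, min_identity, min_coverage) {
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pass <- similarities$identity >= min_identity &
    similarities$coverage_a * 100 >= min_coverage &
    similarities$coverage_b * 100 >= min_coverage &
    similarities$score > 0
  ia <- match(similarities$id_a[pass], ids)
  ib <- match(similarities$id_b[pass], ids)
  if (anyNA(ia) || anyNA(ib)) stop("similarity table names unknown ids")
  for (k in seq_along(ia)) {
    ri <- find(ia[k]); rj <- find(ib[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), ids)
}

#' Cluster-size sweep across an identity/coverage grid
#'
#' Computes all pairwise similarities once, then thresholds them at every
#' grid point, reporting per cell the number of clusters with at least
#' two members, the number of sequences in such clusters, and the largest
#' cluster size — the inputs for a cluster-growth heat map.
#'
#' @param proteins named character vector (>= 2 sequences).
#' @param identity_grid,coverage_grid percent thresholds
#'   (defaults `seq(30, 95, by = 5)`).
#' @inheritParams pairwise_similarity
#' @return list with `grid` (data.frame: `identity`, `coverage`,
#'   `n_clusters_ge2`, `n_seqs_clustered`, `max_size`) and
#'   `similarities` (the pairwise table).
#' @export
sweep_clusters <- function(proteins,
                           identity_grid = seq(30, 95, by = 5),
                           coverage_grid = seq(30, 95, by = 5),
                           gap_open = 11, gap_ext = 1,
                           matrix = .blosum62) {
  stopifnot(length(proteins) >= 2L)
  sims <- all_pairwise_similarities(proteins, gap_open, gap_ext, matrix)
  ids <- names(proteins)
  cells <- expand.grid(identity = identity_grid, coverage = coverage_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    part <- cluster_at(sims, ids, cells$identity[k], cells$coverage[k])
    sz <- table(part)
    big <- sz[sz >= 2L]
    data.frame(identity = cells$identity[k], coverage = cells$coverage[k],
               n_clusters_ge2 = length(big),
               n_seqs_clustered = sum(big),
               max_size = max(as.integer(sz)), stringsAsFactors = FALSE)
  })
  list(grid = do.call(rbind, res), similarities = sims)
}
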