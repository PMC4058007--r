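# Redundancy collapse: proteins identical over their entire region of
# overlap form single-linkage clusters; one representative (the longest,
# ties broken by input order) is kept per cluster.

#' Are two proteins identical over their entire region of overlap?
#'
#' True when the shorter sequence occurs as an exact contiguous substring
#' of the longer (equal-length sequences must be equal).
#'
#' @param a,b non-empty protein sequences.
#' @return logical flag.
#' @export
identical_over_overlap <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  grepl(a, b, fixed = TRUE)
}

#' Collapse a protein set to non-redundant representatives
#'
#' Builds single-linkage clusters under [identical_over_overlap()] and
#' keeps one representative per cluster: the unique longest member, or the
#' first-encountered member (input order) among co-longest members.
#' Collapsing the kept set again changes nothing.
#'
#' @param proteins named character vector (id -> sequence); ids unique.
#' @return list with `kept` (named character vector of representatives, in
#'   input order) and `clusters` (data.frame: `cluster_id`, `member_id`,
#'   `is_representative`, `rule_used` in `{longest, first}`).
#' @export
collapse_redundant <- function(proteins) {
  ids <- names(proteins)
  stopifnot(!is.null(ids), !anyDuplicated(ids), all(nzchar(proteins)))
  n <- length(proteins)
  # union-find over pairs; substring containment is cheap enough at the
  # scales this stage sees (post-assembly protein sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (identical_over_overlap(proteins[[i]], proteins[[j]])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp_ids <- unique(comp)  # in input order of first member
  rows <- vector("list", length(comp_ids))
  kept_idx <- integer(length(comp_ids))
  for (k in seq_along(comp_ids)) {
    members <- which(comp == comp_ids[k])
    lens <- nchar(proteins[members])
    longest <- members[lens == max(lens)]
    rep_idx <- longest[1L]  # input order breaks ties
    rule <- if (length(longest) > 1L) "first" else "longest"
    kept_idx[k] <- rep_idx
    rows[[k]] <- data.frame(
      cluster_id = k, member_id = ids[members],
      is_representative = members == rep_idx,
      rule_used = rule, stringsAsFactors = FALSE)
  }
  kept_idx <- sort(kept_idx)
  list(kept = proteins[kept_idx], clusters = do.call(rbind, rows))
}
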