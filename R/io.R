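# Small I/O helpers shared across stages. All tables are plain TSV with a
# header row; sequences travel as named character vectors internally and as
# FASTA on disk (via Biostrings).

#' Read a FASTA file as a named character vector
#'
#' @param path path to a (plain-text) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences as FASTA
#'
#' Sequences are written unwrapped (one line per record) so that identical
#' inputs yield byte-identical files.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(names(seqs)) == length(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as tab-separated text
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Run `expr` under a temporarily seeded RNG without disturbing the caller's
# RNG state. All package randomness flows through this.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}
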