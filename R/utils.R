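# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG with `seed`, runs `code`, and restores the previous
#' RNG state afterwards so simulation calls do not perturb the caller's
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random DNA strings
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste0, collapse = "")
}

#' Random DNA strings, all distinct
#' @noRd
random_dna_unique <- function(n, len) {
  out <- unique(random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out[seq_len(n)]
}

#' Split equal-length strings into a character matrix (length x n)
#' @noRd
seq_char_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  len <- unique(nchar(x))
  stopifnot(length(len) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE), nrow = len)
}

#' Apply independent per-base substitution errors to a character vector
#'
#' Each base is replaced, with probability `rate`, by one of the three other
#' bases chosen uniformly. Fully vectorised across sequences.
#' @noRd
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    # draw a uniformly random *different* base by offsetting 1..3 in base order
    cur <- match(flat[hit], DNA_BASES)
    cur[is.na(cur)] <- 1L  # non-ACGT characters mutate from A's offset
    flat[hit] <- DNA_BASES[((cur - 1L + sample(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)), paste0, "", collapse = "")
}

#' Write a 4-line FASTQ file with constant "I" qualities
#' @noRd
write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @noRd
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Reverse complement of a character vector of DNA strings
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA string to amino acids
#' @noRd
translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE))
}

#' Strict scalar checks
#' @noRd
stop_unless <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Write a TSV without quoting or row names
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by write_tsv
#' @noRd
read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
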