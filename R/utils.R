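#' Reverse complement of character sequences
#'
#' Thin wrapper around \code{Biostrings::reverseComplement} that keeps
#' plain character vectors as plain character vectors.
#'
#' @param x character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into a character matrix (rows = sequences, cols = positions).
# All sequences must have equal length.
seq_matrix <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("empty alignment")
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("sequences have unequal lengths: ", paste(lens, collapse = ", "))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = lens, byrow = TRUE)
}

# Per-column base counts of an alignment, rows A,C,G,T (+ N row if present).
column_base_counts <- function(seqs, bases = ALPHA_BASES) {
  m <- seq_matrix(seqs)
  vapply(seq_len(ncol(m)),
         function(j) {
           tab <- table(factor(m[, j], levels = bases))
           as.integer(tab)
         },
         integer(length(bases))) |>
    matrix(nrow = length(bases), dimnames = list(bases, NULL))
}

stopifnot_acgt <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("sequences contain non-ACGT characters (first offender: sequence ",
         which(bad)[1L], "); filter Ns before counting")
  invisible(seqs)
}

# All 4^k k-mers in the alphabetical order used by
# Biostrings::oligonucleotideFrequency.
all_kmers <- function(k) {
  stopifnot(k >= 1L)
  grid <- expand.grid(rep(list(ALPHA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; alphabetical order needs
  # the last position fastest.
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}
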