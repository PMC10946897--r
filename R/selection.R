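#' Scaled selection coefficient of a motif from two region proportions
#'
#' gamma(M) = log[ (f3/(1-f3)) / (f5/(1-f5)) ]: the log-odds of the
#' motif's proportion in the selected region (3PT) against the neutral
#' reference (5LR).  Under a mutation-selection-drift equilibrium this
#' log-odds equals the scaled selection strength gamma = 4*Ne*s acting
#' on the motif, with non-selective forces (mutation bias, gBGC,
#' transcription-associated asymmetry) cancelling between the regions.
#'
#' @param f3 motif proportion in the 3PT, in (0, 1).
#' @param f5 motif proportion in the 5LR, in (0, 1).
#' @return numeric vector of scaled selection coefficients; negative
#'   values mean depletion in the 3PT.
#' @examples
#' gamma_logodds(0.1, 0.2)   # ln(4/9) ~ -0.8109
#' @export
gamma_logodds <- function(f3, f5) {
  if (any(f3 <= 0 | f3 >= 1 | f5 <= 0 | f5 >= 1))
    stop("proportions must lie strictly in (0, 1); ",
         "apply the pseudocount rule to zero-count motifs first")
  log((f3 / (1 - f3)) / (f5 / (1 - f5)))
}

# motif proportions with the Haldane-Anscombe pseudocount: 0.5 added to
# every motif's count, 0.5 * 4^k to the total, so no proportion is 0 or 1.
motif_proportions <- function(counts, k) {
  (counts + 0.5) / (sum(counts) + 0.5 * 4^k)
}

# per-sequence k-mer count matrix (rows = sequences, cols = 4^k motifs)
kmer_count_matrix <- function(seqs, k) {
  stopifnot_acgt(as.character(seqs))
  Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(as.character(seqs)), width = k)
}

#' Per-motif selection coefficients of the 3PT against the 5LR
#'
#' Counts all 4^k motifs in both region sets, forms pseudocounted
#' proportions (each motif's share of all k-mer windows of the region)
#' and returns the per-motif log-odds selection coefficient
#' [gamma_logodds()].
#'
#' @param seqs3,seqs5 character vectors of region sequences, one per
#'   intron, for the 3PT and the 5LR respectively.
#' @param k motif length 1..4.
#' @return data.frame with columns \code{motif}, \code{f5}, \code{f3},
#'   \code{gamma}.
#' @seealso [gamma_bootstrap()] for confidence intervals.
#' @export
motif_selection <- function(seqs3, seqs5, k) {
  c3 <- colSums(kmer_count_matrix(seqs3, k))
  c5 <- colSums(kmer_count_matrix(seqs5, k))
  f3 <- motif_proportions(c3, k)
  f5 <- motif_proportions(c5, k)
  data.frame(motif = names(c3), f5 = unname(f5), f3 = unname(f3),
             gamma = unname(gamma_logodds(f3, f5)), row.names = NULL)
}

#' Bootstrap confidence intervals for motif selection coefficients
#'
#' Resamples introns (not sites) with replacement, independently in the
#' 3PT and 5LR datasets since the two region sets differ after
#' filtering, recomputes gamma(M) for every motif in each resample, and
#' reports percentile confidence intervals.  With a fixed seed the
#' intervals are bit-identical across runs.
#'
#' @inheritParams motif_selection
#' @param B number of bootstrap resamples (the resample size equals the
#'   original dataset size).
#' @param seed integer seed (required).
#' @param level confidence level (default 0.95: the 2.5\% and 97.5\%
#'   quantiles).
#' @return data.frame with columns \code{motif}, \code{f5}, \code{f3},
#'   \code{gamma}, \code{ci_low}, \code{ci_high},
#'   \code{n_degenerate} (resamples in which the motif had a zero raw
#'   count in either region and the pseudocount carried the estimate).
#' @export
gamma_bootstrap <- function(seqs3, seqs5, k, B = 1000L, seed, level = 0.95) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  M3 <- kmer_count_matrix(seqs3, k)
  M5 <- kmer_count_matrix(seqs5, k)
  point <- motif_selection(seqs3, seqs5, k)
  n3 <- nrow(M3); n5 <- nrow(M5)
  nm <- ncol(M3)
  draws <- matrix(NA_real_, B, nm)
  degen <- integer(nm)
  for (b in seq_len(B)) {
    c3 <- colSums(M3[sample.int(n3, n3, replace = TRUE), , drop = FALSE])
    c5 <- colSums(M5[sample.int(n5, n5, replace = TRUE), , drop = FALSE])
    degen <- degen + as.integer(c3 == 0 | c5 == 0)
    draws[b, ] <- gamma_logodds(motif_proportions(c3, k),
                                motif_proportions(c5, k))
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha))
  cbind(point,
        data.frame(ci_low = qs[1L, ], ci_high = qs[2L, ],
                   n_degenerate = degen, row.names = NULL))
}
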