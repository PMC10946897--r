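#' Exhaustive k-mer counts with reverse-complement pairing
#'
#' Counts every one of the 4^k k-mers (overlapping windows, pooled across
#' sequences) and pairs each motif with the count of its reverse
#' complement on the same strand: \code{N_F} is the motif's own count,
#' \code{N_R} the count of its reverse complement, and \code{N} the total
#' number of k-mer windows.  By construction
#' \code{N_F(M) == N_R(revcomp(M))}, and self-reverse-complementary
#' motifs have \code{N_F == N_R}.
#'
#' @param seqs character vector (or \code{DNAStringSet}) of sequences
#'   over \{A,C,G,T\}; Ns must have been filtered out upstream.
#' @param k motif length, 1 to 4.
#' @return data.frame with one row per motif (alphabetical order) and
#'   columns \code{motif}, \code{N_F}, \code{N_R}, \code{N}.
#' @examples
#' count_kmers("AAAA", 2)   # N("AA") = 3, all other dimers 0
#' @export
count_kmers <- function(seqs, k) {
  stopifnot(k >= 1L, k <= 4L)
  seqs <- as.character(seqs)
  stopifnot_acgt(seqs)
  if (any(nchar(seqs) < k)) stop("k exceeds the shortest sequence length")
  cnt <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k))
  motifs <- names(cnt)
  data.frame(motif = motifs,
             N_F = unname(cnt),
             N_R = unname(cnt[revcomp(motifs)]),
             N = sum(cnt),
             row.names = NULL)
}

#' Expected motif proportion from base composition
#'
#' Independence-model probability of a motif: the product of the
#' per-base frequencies of its letters.  Summed over all 4^k motifs this
#' is 1.
#'
#' @param base_freqs named numeric vector of base frequencies (names
#'   must cover A, C, G, T; must sum to 1).
#' @param motif character vector of motifs.
#' @return numeric vector of probabilities.
#' @export
expected_proportion <- function(base_freqs, motif) {
  stopifnot(all(ALPHA_BASES %in% names(base_freqs)))
  if (abs(sum(base_freqs[ALPHA_BASES]) - 1) > 1e-6)
    stop("base frequencies must sum to 1")
  vapply(strsplit(motif, "", fixed = TRUE),
         function(ch) prod(base_freqs[ch]), numeric(1))
}

#' Strand asymmetry score
#'
#' S = (N_F - N_R) / (N_F + N_R), the normalised excess of a motif over
#' its reverse complement on the same strand.  S is in [-1, 1],
#' antisymmetric under reverse complementation
#' (S(M) = -S(revcomp(M))), zero for self-reverse-complementary motifs,
#' and scale-invariant (counts, proportions or percentages give the same
#' value).  Mononucleotide scores S_TA and S_CG use N_F = T, N_R = A and
#' N_F = C, N_R = G respectively.
#'
#' @param N_F,N_R numeric vectors of forward and reverse-complement
#'   counts (or proportions).
#' @return numeric vector of scores; \code{NA} where
#'   \code{N_F + N_R == 0} (undefined), with a message.
#' @examples
#' asymmetry_score(46.95, 21.12)  # S_TA of a pyrimidine-rich tract
#' @export
asymmetry_score <- function(N_F, N_R) {
  tot <- N_F + N_R
  s <- ifelse(tot > 0, (N_F - N_R) / tot, NA_real_)
  if (anyNA(s))
    message(sum(is.na(s)), " score(s) undefined (N_F + N_R = 0)")
  s
}

#' Expected asymmetry scores from base composition
#'
#' The asymmetry score each motif would have if k-mer proportions were
#' the independence-model products of the region's base composition.
#'
#' @inheritParams expected_proportion
#' @return numeric vector of expected scores, one per motif.
#' @export
expected_asymmetry <- function(base_freqs, motif) {
  pF <- expected_proportion(base_freqs, motif)
  pR <- expected_proportion(base_freqs, revcomp(motif))
  asymmetry_score(pF, pR)
}

#' Per-position mononucleotide asymmetry profile with trend test
#'
#' Computes S_TA = (T - A)/(T + A) and S_CG = (C - G)/(C + G) for every
#' column of a set of equal-length region sequences from the pooled
#' column base counts, then regresses each score on the position index
#' (ordinary least squares) and reports the slope with its two-sided
#' t-test p-value -- a positive S_TA slope means pyrimidine skew
#' increasing towards the 3' end.
#'
#' @param seqs character vector of equal-length sequences (e.g. the 3PT
#'   consensus of every intron).
#' @return list with \code{profile} (data.frame: position, S_TA, S_CG),
#'   and \code{trend} (data.frame: score, slope, p).  Columns with no
#'   informative bases yield \code{NA} and are dropped from the
#'   regression.
#' @export
per_position_profile <- function(seqs) {
  counts <- column_base_counts(seqs)
  S_TA <- asymmetry_score(counts["T", ], counts["A", ])
  S_CG <- asymmetry_score(counts["C", ], counts["G", ])
  prof <- data.frame(position = seq_len(ncol(counts)),
                     S_TA = S_TA, S_CG = S_CG)
  trend_row <- function(score, name) {
    ok <- !is.na(score)
    if (sum(ok) < 3L)
      return(data.frame(score = name, slope = NA_real_, p = NA_real_))
    fit <- lm(score[ok] ~ prof$position[ok])
    cf <- summary(fit)$coefficients
    data.frame(score = name, slope = cf[2L, 1L], p = cf[2L, 4L])
  }
  list(profile = prof,
       trend = rbind(trend_row(S_TA, "S_TA"), trend_row(S_CG, "S_CG")))
}

#' Chi-square test of strand symmetry
#'
#' One-degree-of-freedom goodness-of-fit test of N_F = N_R against the
#' expectation (N_F + N_R)/2 for each, without continuity correction;
#' the statistic reduces to (N_F - N_R)^2 / (N_F + N_R).
#'
#' @param N_F,N_R numeric count vectors.
#' @return data.frame with columns \code{statistic} and \code{p}.
#' @export
chi_square_symmetry <- function(N_F, N_R) {
  tot <- N_F + N_R
  if (any(tot <= 0)) stop("N_F + N_R must be positive")
  stat <- (N_F - N_R)^2 / tot
  data.frame(statistic = stat,
             p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Equivalence test for the forward/reverse motif ratio
#'
#' Tests \emph{practical} strand symmetry: a Katz log-scale confidence
#' interval for the ratio of forward to reverse-complement proportions
#' is computed as
#' \deqn{L, U = (N_F/N_R) \exp(\mp z \sqrt{1/N_F - 1/N + 1/N_R - 1/N})}
#' and equivalence is concluded when the whole interval lies inside the
#' tolerance range (1/delta, delta).  Unlike the chi-square test, this
#' can positively support symmetry.
#'
#' @param N_F,N_R forward and reverse-complement counts (> 0 for a
#'   testable motif).
#' @param N total number of k-mer occurrences in the region.
#' @param delta tolerance for practical equivalence (default 1.1, a
#'   stringent 10\%).
#' @param z normal quantile of the confidence level (default the
#'   two-sided 95\% value 1.959964).
#' @return data.frame with columns \code{ratio}, \code{L}, \code{U},
#'   \code{verdict} (\code{"equivalent"}, \code{"not-equivalent"} or
#'   \code{"not-testable"} for zero counts).
#' @export
equivalence_test <- function(N_F, N_R, N, delta = 1.1, z = qnorm(0.975)) {
  stopifnot(delta > 1, all(N >= N_F + N_R))
  ok <- N_F > 0 & N_R > 0
  ratio <- ifelse(ok, N_F / N_R, NA_real_)
  se <- ifelse(ok, sqrt(1 / N_F - 1 / N + 1 / N_R - 1 / N), NA_real_)
  L <- ratio * exp(-z * se)
  U <- ratio * exp(z * se)
  verdict <- ifelse(!ok, "not-testable",
                    ifelse(L > 1 / delta & U < delta,
                           "equivalent", "not-equivalent"))
  data.frame(ratio = ratio, L = L, U = U, verdict = verdict)
}

#' Correlation of observed and composition-expected asymmetry scores
#'
#' Pearson product-moment correlation between per-motif observed
#' asymmetry scores and the scores expected from the region's base
#' composition alone; a high R-squared means the motif-level skew is
#' largely a consequence of the monomer composition.
#'
#' @param observed,expected paired numeric vectors in the same motif
#'   order.
#' @return list with \code{r}, \code{r_squared}, \code{p}, \code{n}.
#'   Zero variance in either vector gives \code{NA} results.
#' @export
observed_vs_expected <- function(observed, expected) {
  ok <- is.finite(observed) & is.finite(expected)
  if (sum(ok) < 3L || var(observed[ok]) == 0 || var(expected[ok]) == 0) {
    warning("correlation undefined (fewer than 3 pairs or zero variance)")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = sum(ok)))
  }
  ct <- cor.test(observed[ok], expected[ok], method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = sum(ok))
}

#' Full per-motif asymmetry table for a region
#'
#' Convenience wrapper assembling, for every k-mer of a region's
#' consensus sequences: counts, asymmetry score, composition-expected
#' score, chi-square symmetry test, and the ratio-equivalence test.
#'
#' @param seqs consensus sequences of the region (character vector).
#' @param k motif length 1..4.
#' @inheritParams equivalence_test
#' @param p_adjust if TRUE, append a Benjamini-Hochberg adjusted
#'   p-value column for the chi-square tests.
#' @return data.frame with columns \code{motif}, \code{N_F}, \code{N_R},
#'   \code{S}, \code{expected_S}, \code{chi2}, \code{p}, \code{ratio},
#'   \code{L}, \code{U}, \code{verdict} (and \code{p_BH}).
#' @export
asymmetry_table <- function(seqs, k, delta = 1.1, z = qnorm(0.975),
                            p_adjust = FALSE) {
  kc <- count_kmers(seqs, k)
  comp <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(as.character(seqs)), width = 1L))
  comp <- comp / sum(comp)
  testable <- kc$N_F + kc$N_R > 0
  chi <- data.frame(statistic = rep(NA_real_, nrow(kc)),
                    p = NA_real_)
  chi[testable, ] <- chi_square_symmetry(kc$N_F[testable], kc$N_R[testable])
  eqv <- equivalence_test(kc$N_F, kc$N_R, kc$N, delta, z)
  out <- data.frame(kc[c("motif", "N_F", "N_R")],
                    S = asymmetry_score(kc$N_F, kc$N_R),
                    expected_S = expected_asymmetry(comp, kc$motif),
                    chi2 = chi$statistic, p = chi$p,
                    eqv)
  if (p_adjust) out$p_BH <- p.adjust(out$p, method = "BH")
  out
}
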