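#' Classify a biallelic mutation as GC-changing or GC-conservative
#'
#' GC-biased gene conversion acts only on strong/weak heteroduplex
#' mismatches: pairs between a weak base (A or T) and a strong base
#' (G or C) are \emph{GC-changing}; within-class pairs (A/T or G/C) are
#' \emph{GC-conservative} and serve as the neutral control.
#'
#' @param a1,a2 character vectors of the two distinct alleles (recycled).
#' @return character vector, \code{"GC-changing"} or
#'   \code{"GC-conservative"}.
#' @examples
#' classify_mutation("A", "G")  # GC-changing
#' classify_mutation("A", "T")  # GC-conservative
#' @export
classify_mutation <- function(a1, a2) {
  ok <- a1 %in% ALPHA_BASES & a2 %in% ALPHA_BASES
  if (!all(ok)) stop("alleles must be in A, C, G, T")
  if (any(a1 == a2)) stop("alleles must be distinct")
  strong <- function(b) b %in% c("G", "C")
  ifelse(strong(a1) == strong(a2), "GC-conservative", "GC-changing")
}

#' Site-frequency spectrum constructor
#'
#' @param counts numeric vector of length n-1: number of segregating
#'   sites with focal-allele count y = 1 .. n-1.
#' @param n haploid sample size.
#' @param mclass mutation class label.
#' @return object of class \code{sfs}.
#' @export
sfs <- function(counts, n, mclass = c("GC-changing", "GC-conservative")) {
  mclass <- match.arg(mclass)
  stopifnot(length(counts) == n - 1L, all(counts >= 0))
  structure(list(n = as.integer(n), counts = as.numeric(counts),
                 mclass = mclass), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("sfs [%s]: n = %d, %d segregating sites\n",
              x$mclass, x$n, round(sum(x$counts))))
  invisible(x)
}

#' Build site-frequency spectra from alignment columns
#'
#' Scans alignment columns, keeps biallelic sites, classifies them as
#' GC-changing or GC-conservative, and counts focal alleles: for
#' GC-changing sites the focal allele is the strong (G or C) allele; for
#' conservative sites it is T (A/T pairs) or C (G/C pairs) by a fixed
#' convention (the neutral expectation is orientation-robust).  Sites
#' with missing data are downsampled without replacement to
#' \code{n_target} haplotypes; sites with fewer complete haplotypes, or
#' with more than two alleles, are excluded and counted in the
#' \code{dropped} attribute.
#'
#' @param alignments list of character vectors (each an intron region
#'   alignment, rows = individuals) or a single character vector.
#' @param n_target haplotypes per site after downsampling.  Default:
#'   the largest n for which at least 90\% of biallelic sites have
#'   complete data.
#' @param seed integer seed for the downsampling draws.
#' @return list with elements \code{changing} and \code{conservative},
#'   both [sfs()] objects, with attribute \code{dropped} (named counts).
#' @export
build_sfs <- function(alignments, n_target = NULL, seed = 1L) {
  if (is.character(alignments)) alignments <- list(alignments)
  set.seed(seed)
  cols <- list()
  for (aln in alignments) {
    m <- seq_matrix(aln)
    cols <- c(cols, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  n_all <- lengths(cols)
  complete <- vapply(cols, function(cc) sum(cc %in% ALPHA_BASES), integer(1))
  if (is.null(n_target)) {
    cand <- sort(unique(complete), decreasing = TRUE)
    frac <- vapply(cand, function(nt) mean(complete >= nt), numeric(1))
    n_target <- max(cand[frac >= 0.9], 2L)
  }
  n_target <- as.integer(n_target)
  stopifnot(n_target >= 2L)
  dropped <- c(incomplete = 0L, multiallelic = 0L)
  cc_counts <- numeric(n_target - 1L)
  ch_counts <- numeric(n_target - 1L)
  for (cc in cols) {
    cc <- cc[cc %in% ALPHA_BASES]
    if (length(cc) < n_target) {
      dropped["incomplete"] <- dropped["incomplete"] + 1L
      next
    }
    if (length(cc) > n_target) cc <- sample(cc, n_target)
    alleles <- unique(cc)
    if (length(alleles) == 1L) next          # monomorphic after sampling
    if (length(alleles) > 2L) {
      dropped["multiallelic"] <- dropped["multiallelic"] + 1L
      next
    }
    cls <- classify_mutation(alleles[1L], alleles[2L])
    if (cls == "GC-changing") {
      focal <- alleles[alleles %in% c("G", "C")]
      y <- sum(cc == focal)
      ch_counts[y] <- ch_counts[y] + 1
    } else {
      focal <- if (all(alleles %in% c("A", "T"))) "T" else "C"
      y <- sum(cc == focal)
      cc_counts[y] <- cc_counts[y] + 1
    }
  }
  structure(list(
    changing = sfs(ch_counts, n_target, "GC-changing"),
    conservative = sfs(cc_counts, n_target, "GC-conservative")),
    dropped = dropped, n_target = n_target)
}

# Sojourn-density SFS probability phi(y; n, gamma): expected (relative)
# number of biallelic sites with y copies of the favoured allele under a
# directional force gamma, from the diffusion sojourn density weighted by
# binomial sampling:
#   phi(y; n, gamma) = C(n,y) Int_0^1 x^(y-1) (1-x)^(n-y-1)
#                      (1 - e^(-gamma(1-x)))/(1 - e^(-gamma)) dx
# with the analytic gamma -> 0 limit 1/y.  Adaptive quadrature; the
# binomial coefficient is folded into the integrand on the log scale.
phi_sojourn <- function(y, n, gamma) {
  vapply(y, function(yy) {
    if (abs(gamma) < 1e-8) return(1 / yy)
    f <- function(x) {
      # guard the 0 * log(0) corners at y = 1 and y = n-1
      t1 <- if (yy == 1L) 0 else (yy - 1) * log(x)
      t2 <- if (yy == n - 1L) 0 else (n - yy - 1) * log1p(-x)
      exp(lchoose(n, yy) + t1 + t2) * expm1(-gamma * (1 - x)) / expm1(-gamma)
    }
    integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
}

#' Expected site-frequency-spectrum probabilities under gBGC
#'
#' Probability that a segregating site carries y = 1 .. n-1 copies of the
#' GC (strong) allele, under directional force \code{B} and a fraction
#' \code{beta} of polymorphisms originating as weak-to-strong mutations:
#' p_y proportional to beta * phi(y; n, B) + (1-beta) * phi(n-y; n, -B),
#' where phi is the binomially sampled diffusion sojourn density
#' (analytic 1/y limit at B = 0).  Satisfies the mirror symmetry
#' p_y(B, beta) = p_(n-y)(-B, 1-beta).
#'
#' @param n haploid sample size.
#' @param B scaled conversion bias (product of effective population size
#'   and conversion bias b; only the product is identifiable).
#' @param beta fraction of polymorphisms of weak-to-strong origin.
#' @return numeric probability vector over y = 1 .. n-1, summing to 1.
#' @export
sfs_probs <- function(n, B, beta) {
  stopifnot(n >= 2L, beta >= 0, beta <= 1)
  y <- seq_len(n - 1L)
  p <- beta * phi_sojourn(y, n, B) + (1 - beta) * phi_sojourn(n - y, n, -B)
  p / sum(p)
}

sfs_loglik <- function(counts, n, B, beta) {
  p <- sfs_probs(n, B, beta)
  if (any(p <= 0)) return(-Inf)
  sum(counts * log(p))
}

#' Maximum-likelihood estimate of the gBGC strength B
#'
#' Fits the two-parameter model of [sfs_probs()] to an observed
#' site-frequency spectrum by multinomial maximum likelihood over
#' (B, beta), with multi-start L-BFGS-B.  \code{beta} is a free nuisance
#' parameter; only B carries the gBGC signal.
#'
#' @param x an [sfs()] object.
#' @param B_box search box half-width for B.
#' @param n_starts number of optimiser restarts (1-5); the default 5
#'   covers both signs and magnitudes of B.
#' @return object of class \code{gbgc_fit}: \code{B}, \code{beta},
#'   \code{logL}, \code{converged}, \code{n}, \code{sfs}.
#' @export
estimate_B <- function(x, B_box = 20, n_starts = 5L) {
  stopifnot(inherits(x, "sfs"))
  if (sum(x$counts) < 1) stop("spectrum has no segregating sites")
  nll <- function(par) -sfs_loglik(x$counts, x$n, par[1L], par[2L])
  starts <- list(c(0, 0.5), c(0.5, 0.5), c(-0.5, 0.5), c(2, 0.5), c(-2, 0.5))
  starts <- starts[seq_len(max(1L, min(n_starts, 5L)))]
  fits <- lapply(starts, function(s0)
    tryCatch(optim(s0, nll, method = "L-BFGS-B",
                   lower = c(-B_box, 1e-6), upper = c(B_box, 1 - 1e-6),
                   control = list(factr = 1e5)),
             error = function(e) list(value = Inf, convergence = 99L)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  structure(list(B = best$par[1L], beta = best$par[2L],
                 logL = -best$value,
                 converged = is.finite(best$value) && best$convergence == 0L,
                 n = x$n, sfs = x), class = "gbgc_fit")
}

#' @export
print.gbgc_fit <- function(x, ...) {
  cat(sprintf("gbgc_fit: B = %.4f, beta = %.4f, logL = %.3f (n = %d)\n",
              x$B, x$beta, x$logL, x$n))
  invisible(x)
}

# profile log-likelihood at B = 0: p_y prop. to beta/y + (1-beta)/(n-y)
sfs_loglik_null <- function(counts, n) {
  y <- seq_len(n - 1L)
  ll <- function(beta) {
    p <- beta / y + (1 - beta) / (n - y)
    p <- p / sum(p)
    sum(counts * log(p))
  }
  opt <- optimize(ll, c(1e-6, 1 - 1e-6), maximum = TRUE)
  list(logL = opt$objective, beta = opt$maximum)
}

#' Likelihood-ratio test of B = 0
#'
#' Compares the full (B, beta) fit against the nested neutral model with
#' B fixed at 0 and beta re-optimised (p_y proportional to
#' beta/y + (1-beta)/(n-y)); the statistic 2 * delta logL is referred to
#' chi-square with 1 df.
#'
#' @param fit a [estimate_B()] result.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{logL_null}.
#' @export
lrt_vs_zero <- function(fit) {
  stopifnot(inherits(fit, "gbgc_fit"))
  null <- sfs_loglik_null(fit$sfs$counts, fit$n)
  stat <- 2 * (fit$logL - null$logL)
  if (stat < -1e-6) stop("negative LRT: full fit below the null optimum")
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, 1L, lower.tail = FALSE),
       logL_null = null$logL)
}

# Expected hypergeometric projection of an SFS to a smaller sample size
# (standard downsampling of spectra; keeps the multinomial likelihood
# valid with fractional weights).
project_sfs <- function(x, n_to) {
  if (x$n == n_to) return(x)
  stopifnot(n_to < x$n, n_to >= 2L)
  newc <- numeric(n_to - 1L)
  for (y in seq_len(x$n - 1L)) {
    if (x$counts[y] == 0) next
    j <- 0:n_to
    w <- exp(lchoose(y, j) + lchoose(x$n - y, n_to - j) - lchoose(x$n, n_to))
    keep <- j >= 1L & j <= n_to - 1L
    newc[j[keep]] <- newc[j[keep]] + x$counts[y] * w[keep]
  }
  sfs(newc, n_to, x$mclass)
}

#' Pooled versus separate gBGC strength across two datasets
#'
#' Tests whether two spectra (e.g. autosomes versus the X chromosome)
#' require different values of B.  Under the null a single shared B is
#' fitted while beta remains free per dataset (3 parameters); under the
#' alternative each dataset gets its own (B, beta) (4 parameters), so
#' the likelihood-ratio statistic
#' 2 * ((logL_A + logL_B) - logL_pooled) has 1 df.  Spectra with
#' different sample sizes are first projected down to the smaller n by
#' expected hypergeometric downsampling.
#'
#' @param sfs_A,sfs_B two [sfs()] objects.
#' @param B_box search box half-width for B.
#' @param n_starts optimiser restarts per fit (see [estimate_B()]).
#' @return list with \code{statistic}, \code{df}, \code{p}, the separate
#'   fits and the pooled-B parameters.
#' @export
lrt_pooled_vs_separate <- function(sfs_A, sfs_B, B_box = 20, n_starts = 5L) {
  n <- min(sfs_A$n, sfs_B$n)
  sfs_A <- project_sfs(sfs_A, n)
  sfs_B <- project_sfs(sfs_B, n)
  fit_A <- estimate_B(sfs_A, B_box, n_starts)
  fit_B <- estimate_B(sfs_B, B_box, n_starts)
  nll0 <- function(par)
    -(sfs_loglik(sfs_A$counts, n, par[1L], par[2L]) +
      sfs_loglik(sfs_B$counts, n, par[1L], par[3L]))
  starts <- list(c(0, 0.5, 0.5),
                 c(mean(c(fit_A$B, fit_B$B)), fit_A$beta, fit_B$beta))
  fits0 <- lapply(starts, function(s0)
    optim(s0, nll0, method = "L-BFGS-B",
          lower = c(-B_box, 1e-6, 1e-6),
          upper = c(B_box, 1 - 1e-6, 1 - 1e-6),
          control = list(factr = 1e5)))
  best0 <- fits0[[which.min(vapply(fits0, `[[`, numeric(1), "value"))]]
  logL0 <- -best0$value
  stat <- 2 * ((fit_A$logL + fit_B$logL) - logL0)
  if (stat < -1e-6) stop("negative LRT: separate fits below the pooled optimum")
  stat <- max(stat, 0)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, 1L, lower.tail = FALSE),
       fit_A = fit_A, fit_B = fit_B,
       B_pooled = best0$par[1L],
       beta_A = best0$par[2L], beta_B = best0$par[3L],
       logL_pooled = logL0)
}
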