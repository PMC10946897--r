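#' Fixation rate under weak directional selection
#'
#' Rate at which a new mutation with scaled selection coefficient
#' \code{gamma} = 4*Ne*s fixes, relative to a neutral mutation, in the
#' large-population limit of Kimura's fixation probability:
#' r(gamma) = gamma / (1 - exp(-gamma)), with r(0) = 1 by continuity.
#'
#' The implementation is overflow-safe for arbitrarily large |gamma|:
#' for gamma >> 0, r(gamma) ~ gamma; for gamma << 0,
#' r(gamma) ~ -gamma * exp(gamma) which underflows gracefully to 0.
#' The identity r(gamma)/r(-gamma) = exp(gamma) holds to close to
#' machine precision.
#'
#' @param gamma numeric vector of scaled selection coefficients.
#' @return numeric vector of positive fixation rates.
#' @examples
#' fixation_rate(0)               # 1
#' fixation_rate(1)               # 1/(1 - exp(-1)) ~ 1.58198
#' @export
fixation_rate <- function(gamma) {
  r <- numeric(length(gamma))
  small <- abs(gamma) < 1e-8
  # second-order expansion around 0: gamma/(1-e^-gamma) = 1 + gamma/2 + O(g^2)
  r[small] <- 1 + gamma[small] / 2
  hi <- !small & gamma > 500
  r[hi] <- gamma[hi]
  lo <- !small & gamma < -500
  r[lo] <- -gamma[lo] * exp(gamma[lo])
  mid <- !(small | hi | lo)
  r[mid] <- gamma[mid] / (-expm1(-gamma[mid]))
  r
}

#' Construct a strand-symmetric mutation rate matrix
#'
#' Builds the 4x4 neutral mutation rate matrix over bases (A, T, G, C)
#' from its six free exchange rates under strand symmetry, where a rate
#' and its reverse-complement image are equal:
#' mu_AT = mu_TA, mu_GC = mu_CG, mu_AG = mu_TC, mu_GA = mu_CT,
#' mu_AC = mu_TG, mu_CA = mu_GT.
#' Diagonal entries are minus the row sums of the off-diagonals.
#'
#' @param rates named numeric vector with elements
#'   \code{AT, GC, AG, GA, AC, CA}: the rate from the first to the second
#'   base of each name (its complement partner is implied).
#' @param normalize if \code{TRUE} (default), rescale so that the total
#'   substitution flow at the stationary distribution is 1 per unit time
#'   (the time scale is unidentifiable from stationary frequencies).
#' @return a 4x4 matrix of class \code{mutation_matrix} with
#'   \code{dimnames} (A,T,G,C) and attribute \code{stationary}, the
#'   stationary base distribution.
#' @seealso [estimate_mutation_matrix()] to infer the rates from 5LR
#'   polymorphism data, [validate_mutation_matrix()].
#' @export
mutation_matrix <- function(rates, normalize = TRUE) {
  need <- c("AT", "GC", "AG", "GA", "AC", "CA")
  if (!all(need %in% names(rates)))
    stop("rates must be named with all of: ", paste(need, collapse = ", "))
  rates <- rates[need]
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("exchange rates must be finite and non-negative")
  Q <- matrix(0, 4, 4, dimnames = list(MUTSEL_BASES, MUTSEL_BASES))
  Q["A", "T"] <- Q["T", "A"] <- rates[["AT"]]
  Q["G", "C"] <- Q["C", "G"] <- rates[["GC"]]
  Q["A", "G"] <- Q["T", "C"] <- rates[["AG"]]
  Q["G", "A"] <- Q["C", "T"] <- rates[["GA"]]
  Q["A", "C"] <- Q["T", "G"] <- rates[["AC"]]
  Q["C", "A"] <- Q["G", "T"] <- rates[["CA"]]
  diag(Q) <- -rowSums(Q)
  pi <- stationary_dist(Q)
  if (normalize) {
    flow <- sum(pi * -diag(Q))
    if (flow <= 0) stop("degenerate matrix: zero total flow")
    Q <- Q / flow
  }
  structure(Q, stationary = pi, class = c("mutation_matrix", "matrix"))
}

#' Validate the strand-symmetry constraints of a mutation matrix
#'
#' @param Q 4x4 numeric matrix with rows/columns ordered or named (A,T,G,C).
#' @param tol numeric tolerance for the equality constraints.
#' @return \code{Q}, as a \code{mutation_matrix}, invisibly on success;
#'   an error describing the violated constraint otherwise.
#' @export
validate_mutation_matrix <- function(Q, tol = 1e-8) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(4L, 4L))) stop("Q must be 4x4")
  if (!is.null(rownames(Q))) {
    if (!setequal(rownames(Q), MUTSEL_BASES))
      stop("row names must be A, T, G, C")
    Q <- Q[MUTSEL_BASES, MUTSEL_BASES]
  } else {
    dimnames(Q) <- list(MUTSEL_BASES, MUTSEL_BASES)
  }
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  pairs <- list(c("A", "T", "T", "A"), c("G", "C", "C", "G"),
                c("A", "G", "T", "C"), c("G", "A", "C", "T"),
                c("A", "C", "T", "G"), c("C", "A", "G", "T"))
  for (p in pairs) {
    a <- Q[p[1], p[2]]; b <- Q[p[3], p[4]]
    if (abs(a - b) > tol * max(1, abs(a), abs(b)))
      stop(sprintf("strand symmetry violated: mu_%s%s = %g != mu_%s%s = %g",
                   p[1], p[2], a, p[3], p[4], b))
  }
  if (any(abs(rowSums(Q)) > 1e-6))
    diag(Q) <- diag(Q) - rowSums(Q)
  invisible(structure(Q, stationary = stationary_dist(Q),
                      class = c("mutation_matrix", "matrix")))
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi Q = 0, sum(pi) = 1 for an irreducible generator \code{Q}
#' of any size (4 states for a single site, 16 for a site pair).
#'
#' @param Q square rate matrix (rows sum to zero).
#' @return named numeric probability vector.
#' @export
stationary_dist <- function(Q) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  if (any(pi < -1e-9)) stop("generator appears non-ergodic (negative pi)")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- rownames(Q)
  pi
}

#' Selection parameters of the context-dependent model
#'
#' Bundles the monomer scaled selection coefficients
#' (gamma_A, gamma_T, gamma_G, gamma_C), constrained to sum to zero, with
#' the AG-dimer coefficient gamma_AG, tagged by hypothesis:
#' \code{HI} monomer selection only (gamma_AG = 0), \code{HII} dimer
#' selection only (all monomer gammas = 0), \code{HIII} both.
#'
#' The supplied monomer vector is projected onto the sum-zero subspace by
#' subtracting its mean; only rate differences enter the model, so this
#' projection never changes the likelihood.
#'
#' @param gamma numeric vector of length 4, monomer coefficients in base
#'   order (A, T, G, C).
#' @param gamma_AG numeric scalar, coefficient of the AG dimer.
#' @param hypothesis one of \code{"HI"}, \code{"HII"}, \code{"HIII"}.
#' @return object of class \code{selection_params}.
#' @export
selection_params <- function(gamma = c(0, 0, 0, 0), gamma_AG = 0,
                             hypothesis = c("HIII", "HI", "HII")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(length(gamma) == 4L, is.finite(gamma), is.finite(gamma_AG),
            length(gamma_AG) == 1L)
  gamma <- gamma - mean(gamma)
  names(gamma) <- MUTSEL_BASES
  if (hypothesis == "HI") gamma_AG <- 0
  if (hypothesis == "HII") gamma[] <- 0
  structure(list(gamma = gamma, gamma_AG = gamma_AG,
                 hypothesis = hypothesis),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat("selection_params [", x$hypothesis, "]\n", sep = "")
  cat("  gamma   :", paste(sprintf("%s=%+.4f", names(x$gamma), x$gamma),
                           collapse = "  "), "\n")
  cat("  gamma_AG:", sprintf("%+.4f", x$gamma_AG), "\n")
  invisible(x)
}

# Fitness of each base at the focal site given the neighbouring bases:
# gamma_b, plus gamma_AG if the base completes an AG dimer with the left
# neighbour (left == A and b == G) or the right neighbour (b == A and
# right == G).  Rate differences of this fitness reproduce the
# column/row modifications of the mutation-selection matrix under
# AG-dimer context, and handle the doubly-conditioned case (left A and
# right G) consistently.
context_fitness <- function(params, left = NA, right = NA) {
  s <- params$gamma
  if (!is.na(left) && left == "A") s["G"] <- s["G"] + params$gamma_AG
  if (!is.na(right) && right == "G") s["A"] <- s["A"] + params$gamma_AG
  s
}

#' Context-dependent mutation-selection rate matrix for one site
#'
#' Builds the 4x4 substitution rate matrix of a focal site: each neutral
#' rate mu_ij is weighted by the fixation rate of the fitness difference,
#' r(gamma_j - gamma_i), where the per-base fitness includes the AG-dimer
#' coefficient gamma_AG whenever the base completes an AG dimer with the
#' left neighbour (an A before a focal G) or the right neighbour (a focal
#' A before a G).  With all selection coefficients zero the neutral matrix
#' is returned unchanged.
#'
#' @param Q_mut neutral mutation rate matrix (see [mutation_matrix()]).
#' @param params [selection_params()] object.
#' @param left,right neighbouring bases (single characters) or \code{NA}
#'   when the neighbour is unknown or absent.
#' @return 4x4 rate matrix over (A, T, G, C), rows summing to zero.
#' @export
build_context_rates <- function(Q_mut, params, left = NA, right = NA) {
  s <- context_fitness(params, left, right)
  # r(s_j - s_i) factor for every ordered pair
  D <- outer(s, s, function(si, sj) fixation_rate(sj - si))
  R <- unclass(Q_mut) * D
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  dimnames(R) <- list(MUTSEL_BASES, MUTSEL_BASES)
  R
}

#' Stationary distribution of an adjacent site pair
#'
#' Treats two adjacent sites as a 16-state continuous-time Markov chain
#' in which site 1 evolves with right-neighbour context given by site 2
#' and site 2 with left-neighbour context given by site 1, and solves the
#' stationary equations pi G = 0, sum(pi) = 1.  This two-site closure is
#' the likelihood building block of [fit_position()]: the observed joint
#' base counts at positions (i, i+1) are modelled as multinomial draws
#' from this distribution.
#'
#' @inheritParams build_context_rates
#' @return 4x4 joint probability matrix \code{pi[b1, b2]} over (A,T,G,C),
#'   summing to 1.
#' @export
pair_stationary <- function(Q_mut, params) {
  G <- pair_generator(Q_mut, params)
  pi <- stationary_dist(G)
  matrix(pi, 4, 4, byrow = TRUE,
         dimnames = list(MUTSEL_BASES, MUTSEL_BASES))
}

# 16x16 generator of the two-site chain; state order is
# (b1, b2) with b1 varying slowest, bases in (A,T,G,C) order.
pair_generator <- function(Q_mut, params) {
  # site-1 rates depend on its right neighbour (site 2);
  # site-2 rates depend on its left neighbour (site 1)
  R_right <- lapply(MUTSEL_BASES, function(b2)
    build_context_rates(Q_mut, params, left = NA, right = b2))
  R_left <- lapply(MUTSEL_BASES, function(b1)
    build_context_rates(Q_mut, params, left = b1, right = NA))
  names(R_right) <- names(R_left) <- MUTSEL_BASES
  G <- matrix(0, 16L, 16L)
  states <- expand.grid(b2 = 1:4, b1 = 1:4)[, c("b1", "b2")]
  idx <- function(i, j) (i - 1L) * 4L + j
  for (k in seq_len(16L)) {
    i <- states$b1[k]; j <- states$b2[k]
    for (i2 in 1:4) if (i2 != i)
      G[k, idx(i2, j)] <- R_right[[j]][i, i2]
    for (j2 in 1:4) if (j2 != j)
      G[k, idx(i, j2)] <- R_left[[i]][j, j2]
  }
  diag(G) <- -rowSums(G)
  lab <- as.vector(t(outer(MUTSEL_BASES, MUTSEL_BASES, paste0)))
  dimnames(G) <- list(lab, lab)
  G
}

#' Adjacent-pair base counts from aligned sequences
#'
#' Tabulates the joint occurrence of the four bases at positions
#' (i, i+1), for every i, across a set of equal-length sequences --
#' the sufficient statistic of the per-position mutation-selection fit.
#'
#' @param seqs character vector of equal-length sequences over
#'   \{A,C,G,T\} (typically the 3PT windows of many introns, one per
#'   intron).
#' @return list of 4x4 integer matrices (rows: base at i, cols: base at
#'   i+1, order A,T,G,C), one per position pair i = 1 .. L-1, of class
#'   \code{pair_counts}.
#' @export
pair_counts <- function(seqs) {
  stopifnot_acgt(seqs)
  m <- seq_matrix(seqs)
  L <- ncol(m)
  if (L < 2L) stop("sequences must have length >= 2")
  out <- lapply(seq_len(L - 1L), function(i) {
    t1 <- factor(m[, i], levels = MUTSEL_BASES)
    t2 <- factor(m[, i + 1L], levels = MUTSEL_BASES)
    unclass(table(t1, t2, dnn = NULL))
  })
  structure(out, class = "pair_counts")
}

## ---- maximum-likelihood fitting -------------------------------------

# free-parameter <-> selection_params mapping per hypothesis
par_to_params <- function(par, hypothesis) {
  switch(hypothesis,
    HI = selection_params(gamma = c(par[1:3], -sum(par[1:3])),
                          gamma_AG = 0, hypothesis = "HI"),
    HII = selection_params(gamma_AG = par[1], hypothesis = "HII"),
    HIII = selection_params(gamma = c(par[1:3], -sum(par[1:3])),
                            gamma_AG = par[4], hypothesis = "HIII"))
}

n_free <- function(hypothesis) c(HI = 3L, HII = 1L, HIII = 4L)[[hypothesis]]

# deterministic multi-start set: zero vector plus small displaced starts
fit_starts <- function(p) {
  starts <- list(rep(0, p))
  if (p > 1L) {
    starts <- c(starts,
                list(rep(0.5, p), rep(-0.5, p)),
                lapply(seq_len(p), function(i) { s <- rep(0, p); s[i] <- 1; s }))
  } else {
    starts <- c(starts, list(1, -1, 0.5, -0.5))
  }
  starts[seq_len(min(length(starts), max(5L, p + 1L)))]
}

#' Fit the mutation-selection model to one position's pair counts
#'
#' Maximises the multinomial log-likelihood
#' sum_xy counts[x, y] * log pi[x, y](params), where pi is the two-site
#' stationary distribution of [pair_stationary()], over the free
#' parameters of the chosen hypothesis: \code{HI} three free monomer
#' coefficients (the fourth is minus their sum), \code{HII} the single
#' AG-dimer coefficient, \code{HIII} all four.  Optimisation is
#' multi-start L-BFGS-B on the box [-10, 10] per free parameter; the
#' \code{converged} flag additionally requires the best restarts to agree
#' within \code{1e-4} log-likelihood units.
#'
#' @param counts 4x4 matrix of joint base counts at (i, i+1) in base
#'   order (A, T, G, C), e.g. one element of [pair_counts()].
#' @param Q_mut neutral mutation matrix, held fixed during the fit.
#' @param hypothesis \code{"HI"}, \code{"HII"} or \code{"HIII"}.
#' @param n_starts number of deterministic restarts (>= 1).
#' @param box half-width of the parameter box.
#' @return list of class \code{mutsel_fit}: \code{params}
#'   ([selection_params()]), \code{logL}, \code{converged},
#'   \code{n_restarts_agreeing}, \code{hypothesis}, \code{counts}.
#' @export
fit_position <- function(counts, Q_mut, hypothesis = c("HIII", "HI", "HII"),
                         n_starts = 5L, box = 10) {
  hypothesis <- match.arg(hypothesis)
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(4L, 4L)), all(counts >= 0),
            sum(counts) > 0)
  p <- n_free(hypothesis)
  nll <- function(par) {
    pars <- par_to_params(par, hypothesis)
    pi <- pair_stationary(Q_mut, pars)
    if (any(pi <= 0)) return(1e12)
    -sum(counts * log(pi))
  }
  starts <- fit_starts(p)[seq_len(max(1L, min(n_starts, length(fit_starts(p)))))]
  fits <- lapply(starts, function(s0) {
    tryCatch(
      optim(s0, nll, method = "L-BFGS-B",
            lower = rep(-box, p), upper = rep(box, p),
            control = list(factr = 1e4, maxit = 500L)),
      error = function(e) list(value = Inf, par = s0, convergence = 99L))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  agree <- sum(vals <= min(vals) + 1e-4)
  structure(list(
    params = par_to_params(best$par, hypothesis),
    logL = -best$value,
    converged = is.finite(best$value) && best$convergence == 0L &&
      (length(vals) < 2L || agree >= 2L),
    n_restarts_agreeing = agree,
    hypothesis = hypothesis,
    counts = counts), class = "mutsel_fit")
}

#' @export
print.mutsel_fit <- function(x, ...) {
  cat(sprintf("mutsel_fit [%s]  logL = %.4f  converged = %s\n",
              x$hypothesis, x$logL, x$converged))
  print(x$params)
  invisible(x)
}

#' Likelihood-ratio comparison of the three selection hypotheses
#'
#' Compares nested fits on identical pair counts: HIII vs HI tests the
#' AG-dimer coefficient (df = 1); HIII vs HII tests the three free
#' monomer coefficients (df = 3).  Statistics are 2 * delta logL with
#' chi-square p-values.
#'
#' @param fits named list with elements \code{HI}, \code{HII},
#'   \code{HIII}, each a [fit_position()] result on the same counts.
#' @return data.frame with columns \code{comparison}, \code{statistic},
#'   \code{df}, \code{p}.
#' @export
compare_models <- function(fits) {
  stopifnot(all(c("HI", "HII", "HIII") %in% names(fits)))
  lrt1 <- 2 * (fits$HIII$logL - fits$HI$logL)
  lrt3 <- 2 * (fits$HIII$logL - fits$HII$logL)
  if (min(lrt1, lrt3) < -1e-6)
    stop("negative LRT statistic: optimiser failed to reach the HIII optimum")
  lrt1 <- max(lrt1, 0); lrt3 <- max(lrt3, 0)
  data.frame(
    comparison = c("HIII_vs_HI", "HIII_vs_HII"),
    statistic = c(lrt1, lrt3),
    df = c(1L, 3L),
    p = pchisq(c(lrt1, lrt3), df = c(1L, 3L), lower.tail = FALSE))
}

#' Bootstrap confidence intervals for per-position selection coefficients
#'
#' Resamples whole sequences (introns) with replacement \code{B} times,
#' rebuilds the pair counts at each position, refits the chosen
#' hypothesis, and reports percentile confidence intervals per parameter
#' and position.
#'
#' @param seqs character vector of equal-length region sequences, one per
#'   intron.
#' @param Q_mut neutral mutation matrix.
#' @param hypothesis model to refit (typically the best one).
#' @param B number of bootstrap resamples.
#' @param seed integer seed (mandatory: resampling is the only source of
#'   randomness, and results are bit-reproducible under a fixed seed).
#' @param positions which position pairs i to bootstrap (default all).
#' @param level confidence level of the percentile interval.
#' @param n_starts restarts per refit (fewer than for the point fit; each
#'   refit starts additionally from the point estimate).
#' @return data.frame with columns \code{position}, \code{parameter},
#'   \code{estimate}, \code{ci_low}, \code{ci_high}.
#' @export
bootstrap_params <- function(seqs, Q_mut, hypothesis = "HIII", B = 1000L,
                             seed, positions = NULL, level = 0.95,
                             n_starts = 1L) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  pc <- pair_counts(seqs)
  if (is.null(positions)) positions <- seq_along(pc)
  n <- length(seqs)
  alpha <- (1 - level) / 2
  out <- list()
  for (i in positions) {
    fit0 <- fit_position(pc[[i]], Q_mut, hypothesis)
    est <- c(fit0$params$gamma, AG = fit0$params$gamma_AG)
    draws <- matrix(NA_real_, B, 5L,
                    dimnames = list(NULL, c(MUTSEL_BASES, "AG")))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cnt <- pair_counts(seqs[idx])[[i]]
      fb <- fit_position(cnt, Q_mut, hypothesis, n_starts = n_starts)
      draws[b, ] <- c(fb$params$gamma, fb$params$gamma_AG)
    }
    qs <- apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      position = i,
      parameter = colnames(draws),
      estimate = unname(est),
      ci_low = qs[1L, ],
      ci_high = qs[2L, ],
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Estimate the neutral mutation matrix from 5LR polymorphism
#'
#' Pools biallelic segregating sites of the putatively neutral 5' region
#' by unordered base-pair class, merges reverse-complement classes under
#' strand symmetry (A/G with T/C, A/C with T/G), divides each class count
#' by the pooled frequency of the originating bases, and splits each
#' weak/strong class into its two directions by per-class flux balance so
#' that the observed (complement-averaged) base composition is stationary.
#' The returned matrix is normalised to unit total flow.
#'
#' Supplying \code{config} instead bypasses estimation: the matrix (or
#' named 6-vector of exchange rates, see [mutation_matrix()]) is
#' validated against the symmetry constraints and returned.
#'
#' @param alignments list of character vectors; each element is one
#'   intron's 5LR alignment (rows = individuals).  Ns are tolerated and
#'   excluded per column.
#' @param config optional pre-specified matrix or named rate vector.
#' @return \code{mutation_matrix}.
#' @export
estimate_mutation_matrix <- function(alignments = NULL, config = NULL) {
  if (!is.null(config)) {
    if (is.matrix(config)) return(validate_mutation_matrix(config))
    return(mutation_matrix(config))
  }
  if (is.null(alignments) || length(alignments) == 0L)
    stop("supply alignments or a config matrix")
  base_tot <- c(A = 0, T = 0, G = 0, C = 0)
  # unordered biallelic pair class counts
  pair_tot <- c(AT = 0, GC = 0, AG = 0, TC = 0, AC = 0, TG = 0)
  for (aln in alignments) {
    m <- seq_matrix(aln)
    # per-column base counts, vectorised over columns
    cnt <- vapply(MUTSEL_BASES, function(b) colSums(m == b),
                  numeric(ncol(m)))
    if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                     dimnames = list(NULL, MUTSEL_BASES))
    base_tot <- base_tot + colSums(cnt)
    present <- cnt > 0
    biallelic <- rowSums(present) == 2L
    if (!any(biallelic)) next
    keys <- apply(present[biallelic, , drop = FALSE], 1L,
                  function(p) paste0(MUTSEL_BASES[p], collapse = ""))
    tab <- table(keys)
    hit <- intersect(names(tab), names(pair_tot))
    pair_tot[hit] <- pair_tot[hit] + as.numeric(tab[hit])
  }
  n_tot <- sum(base_tot)
  if (n_tot == 0) stop("no ACGT bases in the alignments")
  # complement-averaged composition: pi_A = pi_T = a, pi_G = pi_C = g
  a <- (base_tot[["A"]] + base_tot[["T"]]) / (2 * n_tot)
  g <- (base_tot[["G"]] + base_tot[["C"]]) / (2 * n_tot)
  n_at <- pair_tot[["AT"]]
  n_gc <- pair_tot[["GC"]]
  n_agtc <- pair_tot[["AG"]] + pair_tot[["TC"]]
  n_actg <- pair_tot[["AC"]] + pair_tot[["TG"]]
  if (any(c(n_at, n_gc, n_agtc, n_actg) < 1))
    stop("insufficient polymorphism (a pair class has no segregating ",
         "sites); supply a config matrix instead")
  # class flux = sum of pi_origin * rate over the class members; the
  # weak/strong classes are split so each class is individually balanced
  # (a * mu_WS = g * mu_SW), which makes (a, a, g, g) stationary.
  rates <- c(AT = n_at / (2 * a),
             GC = n_gc / (2 * g),
             AG = n_agtc / (4 * a), GA = n_agtc / (4 * g),
             AC = n_actg / (4 * a), CA = n_actg / (4 * g))
  mutation_matrix(rates)
}
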