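test_that("k-mer counting is exhaustive with overlapping windows", {
  kc <- count_kmers("AAAA", 2)
  expect_identical(nrow(kc), 16L)
  expect_identical(kc$N_F[kc$motif == "AA"], 3)
  expect_identical(sum(kc$N_F), 3)

  kc3 <- count_kmers(random_seqs(5, 20, seed = 1), 3)
  expect_identical(nrow(kc3), 64L)              # all trimer types reported
  # (L - k + 1) x n_seq windows
  seqs <- random_seqs(100, 10, seed = 2)
  kc2 <- count_kmers(seqs, 2)
  expect_identical(unique(kc2$N), 900)
  expect_identical(sum(kc2$N_F), 900)
  # N_F(M) == N_R(revcomp(M)) by construction
  expect_identical(kc2$N_F,
                   kc2$N_R[match(revcomp(kc2$motif), kc2$motif)])
  expect_error(count_kmers("ACGNT", 2), "non-ACGT")
})

test_that("expected proportions follow the independence model", {
  unif <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(expected_proportion(unif, "ACG"), 1 / 64)
  # pyrimidine-rich tract composition: direct product oracle
  bf <- c(A = 0.2112, T = 0.4695, G = 0.0866, C = 0.2327)
  expect_equal(expected_proportion(bf, "TAG"),
               0.4695 * 0.2112 * 0.0866, tolerance = 1e-12)
  dimers <- count_kmers("ACGT", 2)$motif
  expect_equal(sum(expected_proportion(bf, dimers)), 1, tolerance = 1e-12)
})

test_that("asymmetry scores are antisymmetric, bounded and scale-free", {
  expect_equal(asymmetry_score(46.95, 21.12) * 100, 37.95, tolerance = 0.005)
  expect_identical(asymmetry_score(50, 50), 0)
  expect_equal(asymmetry_score(30, 10), 0.5)
  # proportions and counts give the same score
  expect_equal(asymmetry_score(0.3, 0.1), asymmetry_score(30, 10))
  expect_message(s <- asymmetry_score(0, 0), "undefined")
  expect_true(is.na(s))

  # S(M) = -S(revcomp(M)) for every motif; self-RC motifs exactly 0
  # (or undefined when the motif never occurs)
  for (k in 2:4) {
    kc <- count_kmers(random_seqs(50, 25, seed = 100 + k), k)
    S <- suppressMessages(asymmetry_score(kc$N_F, kc$N_R))
    Srev <- S[match(revcomp(kc$motif), kc$motif)]
    expect_equal(S, -Srev)
    self_rc <- kc$motif == revcomp(kc$motif)
    expect_true(all(is.na(S[self_rc]) | S[self_rc] == 0))
    if (any(self_rc))   # no self-RC motifs exist at odd k
      expect_true(any(S[self_rc] == 0, na.rm = TRUE))
  }
})

test_that("per-position profiles match single-column scores and OLS", {
  # single column: same value as asymmetry_score on the pooled counts
  col <- c(rep("T", 47), rep("A", 21), rep("G", 9), rep("C", 23))
  prof1 <- per_position_profile(col)
  expect_equal(prof1$profile$S_TA, asymmetry_score(47, 21))
  expect_equal(prof1$profile$S_CG, asymmetry_score(23, 9))

  # deterministic gradient: T count rises linearly with position
  L <- 10
  cols <- lapply(seq_len(L), function(j) {
    c(rep("T", 20 + 2 * j), rep("A", 40 - 2 * j), rep("G", 20), rep("C", 20))
  })
  seqs <- apply(do.call(cbind, cols), 1, paste0, collapse = "")
  # (the flat S_CG series fits perfectly; silence the lm note)
  prof <- suppressWarnings(per_position_profile(seqs))
  # closed-form OLS oracle
  x <- seq_len(L)
  y <- vapply(seq_len(L), function(j)
    ((20 + 2 * j) - (40 - 2 * j)) / 60, numeric(1))
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  tr <- prof$trend
  expect_equal(tr$slope[tr$score == "S_TA"], slope_oracle, tolerance = 1e-10)
  expect_true(tr$slope[tr$score == "S_TA"] > 0)
  expect_lt(tr$p[tr$score == "S_TA"], 1e-6)
  # constant C/G composition: flat profile
  expect_equal(tr$slope[tr$score == "S_CG"], 0, tolerance = 1e-10)

  # null: constant composition, seeded sampling noise only
  null_seqs <- random_seqs(300, 12, seed = 7)
  tr0 <- per_position_profile(null_seqs)$trend
  expect_gt(min(tr0$p), 0.001)
})

test_that("chi-square symmetry test has the closed form", {
  z <- chi_square_symmetry(50, 50)
  expect_identical(z$statistic, 0)
  expect_identical(z$p, 1)
  expect_equal(chi_square_symmetry(60, 40)$statistic, 4)
  set.seed(5)
  nf <- rpois(20, 80) + 1; nr <- rpois(20, 80) + 1
  expect_equal(chi_square_symmetry(nf, nr)$statistic,
               (nf - nr)^2 / (nf + nr))
})

test_that("equivalence test matches the Katz interval and is monotone", {
  eq <- equivalence_test(100, 100, 1000)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$L * eq$U, 1, tolerance = 1e-12)  # log-symmetric about 1

  # high-precision evaluation oracle
  z <- qnorm(0.975)
  se <- sqrt(1 / 110 - 1 / 1000 + 1 / 90 - 1 / 1000)
  eq2 <- equivalence_test(110, 90, 1000)
  expect_equal(eq2$L, (110 / 90) * exp(-z * se), tolerance = 1e-12)
  expect_equal(eq2$U, (110 / 90) * exp(z * se), tolerance = 1e-12)
  expect_gt(eq2$U, 1.1)
  expect_identical(eq2$verdict, "not-equivalent")

  # widening the tolerance never flips equivalent -> not-equivalent
  set.seed(6)
  nf <- rpois(50, 200) + 1; nr <- rpois(50, 200) + 1
  v1 <- equivalence_test(nf, nr, 5000, delta = 1.1)$verdict
  v2 <- equivalence_test(nf, nr, 5000, delta = 2.0)$verdict
  expect_false(any(v1 == "equivalent" & v2 == "not-equivalent"))

  expect_identical(equivalence_test(0, 5, 100)$verdict, "not-testable")
})

test_that("chi-square p and equivalence interval agree with a Monte-Carlo
           binomial null", {
  set.seed(8)
  for (case in 1:20) {
    tot <- sample(50:400, 1)
    nf <- rbinom(1, tot, 0.5)
    if (nf == 0 || nf == tot) nf <- round(tot / 2)
    nr <- tot - nf
    stat <- chi_square_symmetry(nf, nr)$statistic
    p_chi <- chi_square_symmetry(nf, nr)$p
    # Monte-Carlo of the exact (discrete) binomial null; the mid-p
    # convention halves the atom at the observed statistic, and the
    # comparison allows the Berry-Esseen-scale discreteness error of
    # the continuous chi-square approximation, O(1/sqrt(tot))
    draws <- rbinom(1e6, tot, 0.5)
    mc_stat <- (2 * draws - tot)^2 / tot
    p_mc <- mean(mc_stat > stat + 1e-9) + 0.5 * mean(abs(mc_stat - stat) <= 1e-9)
    tol <- 4 * sqrt(max(p_mc * (1 - p_mc), 1e-6) / 1e6) + 0.8 / sqrt(tot)
    expect_lt(abs(p_mc - p_chi), tol)
  }
  # parametric Monte-Carlo check of the ratio interval on one case
  N <- 2000; nf <- 220; nr <- 180
  reps <- matrix(rmultinom(2e5, N, c(nf, nr, N - nf - nr) / N), nrow = 3)
  ratio_mc <- reps[1, ] / reps[2, ]
  qs <- quantile(ratio_mc, c(0.025, 0.975))
  eq <- equivalence_test(nf, nr, N)
  expect_lt(abs(qs[[1]] - eq$L), 0.05)
  expect_lt(abs(qs[[2]] - eq$U), 0.05)
})

test_that("strand-symmetric sequences reject symmetry at the nominal rate", {
  # iid uniform bases: a strand-symmetric process
  seqs <- random_seqs(1500, 30, seed = 9)
  tab <- asymmetry_table(seqs, k = 3)
  rej <- mean(tab$p < 0.05, na.rm = TRUE)
  # 32 independent motif pairs: 0.05 +/- ~3 binomial SD
  expect_lt(rej, 0.17)
})

test_that("observed-vs-expected correlation matches the covariance formula", {
  x <- runif(64, -1, 1)
  r1 <- observed_vs_expected(x, x)
  expect_equal(r1$r_squared, 1)
  r2 <- observed_vs_expected(-x, x)
  expect_equal(r2$r, -1)
  expect_equal(r2$r_squared, 1)

  set.seed(10)
  obs <- runif(64, -1, 1); expd <- obs + rnorm(64, 0, 0.3)
  res <- observed_vs_expected(obs, expd)
  # brute-force covariance oracle
  r_oracle <- sum((obs - mean(obs)) * (expd - mean(expd))) /
    sqrt(sum((obs - mean(obs))^2) * sum((expd - mean(expd))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_warning(observed_vs_expected(rep(1, 10), runif(10)), "undefined")
})
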