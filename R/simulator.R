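#' Initialise a circular sequence from the neutral stationary distribution
#'
#' Draws \code{L} independent bases from the stationary distribution of
#' the neutral mutation matrix; the starting state of [simulate_ctx()].
#'
#' @param Q_mut neutral [mutation_matrix()].
#' @param L sequence length.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length L with values 1..4 indexing
#'   (A, T, G, C); the base characters are in the \code{"bases"}
#'   attribute-free mapping \code{MUTSEL} order.
#' @export
init_sequence <- function(Q_mut, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pi <- attr(Q_mut, "stationary")
  if (is.null(pi)) pi <- stationary_dist(Q_mut)
  sample.int(4L, L, replace = TRUE, prob = pi)
}

# Precompute the away-rate table for every (left, focal, right) context:
# a (64 x 4) matrix, row index (left-1)*16 + (focal-1)*4 + right, column
# = target base, zero on the focal base itself.
context_rate_table <- function(Q_mut, params) {
  tab <- matrix(0, 64L, 4L)
  for (l in 1:4) for (r in 1:4) {
    R <- build_context_rates(Q_mut, params,
                             left = MUTSEL_BASES[l], right = MUTSEL_BASES[r])
    diag(R) <- 0
    for (f in 1:4)
      tab[(l - 1L) * 16L + (f - 1L) * 4L + r, ] <- R[f, ]
  }
  tab
}

#' Gillespie simulation of a circular sequence under mutation-selection
#'
#' Exact stochastic simulation of a circular L-base sequence evolving
#' under the origin-fixation model: at each event an L x 4 table of
#' context-dependent substitution rates (neutral mutation rates weighted
#' by fixation rates given both neighbours; see
#' [build_context_rates()]) is formed, the waiting time is exponential
#' with the table total, the changing position is drawn proportional to
#' its row sum and the new base proportional to its rate.  The sequence
#' is circular: position L neighbours position 1.
#'
#' \code{iterations} counts accepted substitution events.  After
#' \code{burnin} discarded events, per-position base occupancy and
#' adjacent-pair joint occupancy (including the wrap-around pair L-1)
#' are accumulated, either weighted by sojourn time
#' (\code{averaging = "time"}, the statistically correct occupancy of a
#' continuous-time chain) or by event (\code{"event"}, one count per
#' visited state).
#'
#' @param Q_mut neutral [mutation_matrix()].
#' @param params [selection_params()], or a list of L of them for
#'   position-specific selection (default homogeneous).
#' @param L sequence length (>= 2).
#' @param iterations substitution events after burn-in.
#' @param burnin events discarded before accumulation.
#' @param seed integer seed (required; the simulation is fully
#'   reproducible under it).
#' @param averaging \code{"time"} (default) or \code{"event"}.
#' @param n_batches number of consecutive event batches for Monte-Carlo
#'   standard errors of the composition (batch means).
#' @param snapshot_every if not \code{NULL}, record the sequence state
#'   every this many post-burn-in events (used by
#'   [synth_region_set()]).
#' @return object of class \code{ctx_sim}: list with
#'   \code{composition} (L x 4 frequencies over A,T,G,C),
#'   \code{pair_freq} (L x 4 x 4 array; slice i is the joint table of
#'   positions (i, i+1), wrapping at L), \code{batch_composition}
#'   (n_batches x 4 pooled composition per batch), \code{events},
#'   \code{total_time}, \code{snapshots} (character vector or NULL),
#'   \code{averaging}.
#' @export
simulate_ctx <- function(Q_mut, params, L = 10L, iterations = 1e5L,
                         burnin = 1e3L, seed, averaging = c("time", "event"),
                         n_batches = 20L, snapshot_every = NULL) {
  averaging <- match.arg(averaging)
  if (missing(seed)) stop("seed is required")
  stopifnot(L >= 2L, burnin >= 0L, iterations >= 1L, n_batches >= 1L)
  set.seed(seed)
  homogeneous <- inherits(params, "selection_params")
  if (homogeneous) {
    tab <- context_rate_table(Q_mut, params)
    tabs <- NULL
  } else {
    stopifnot(length(params) == L)
    tabs <- lapply(params, function(p) context_rate_table(Q_mut, p))
  }
  s <- init_sequence(Q_mut, L)
  left_of <- c(L, seq_len(L - 1L))
  right_of <- c(seq_len(L)[-1L], 1L)
  ctx_ids <- function(st) (st[left_of] - 1L) * 16L + (st - 1L) * 4L + st[right_of]
  get_rates <- function(st) {
    ids <- ctx_ids(st)
    if (homogeneous) tab[ids, , drop = FALSE]
    else t(vapply(seq_len(L), function(l) tabs[[l]][ids[l], ], numeric(4)))
  }
  occ <- matrix(0, L, 4L)
  pair_occ <- array(0, c(L, 4L, 4L))
  batch_occ <- matrix(0, n_batches, 4L)
  batch_size <- ceiling(iterations / n_batches)
  pos_seq <- seq_len(L)
  snaps <- if (!is.null(snapshot_every))
    matrix(NA_integer_, nrow = floor(iterations / snapshot_every), ncol = L)
  n_snap <- 0L
  total_time <- 0
  rates <- get_rates(s)
  for (ev in seq_len(burnin + iterations)) {
    row_tot <- rowSums(rates)
    tot <- sum(row_tot)
    if (tot <= 0) stop("zero total substitution rate")
    dt <- rexp(1L, tot)
    if (ev > burnin) {
      w <- if (averaging == "time") dt else 1
      occ[cbind(pos_seq, s)] <- occ[cbind(pos_seq, s)] + w
      pair_occ[cbind(pos_seq, s, s[right_of])] <-
        pair_occ[cbind(pos_seq, s, s[right_of])] + w
      bi <- min(n_batches, (ev - burnin - 1L) %/% batch_size + 1L)
      tb <- tabulate(s, 4L)
      batch_occ[bi, ] <- batch_occ[bi, ] + w * tb / L
      total_time <- total_time + dt
      if (!is.null(snapshot_every) &&
          (ev - burnin) %% snapshot_every == 0L && n_snap < nrow(snaps)) {
        n_snap <- n_snap + 1L
        snaps[n_snap, ] <- s
      }
    }
    pos <- sample.int(L, 1L, prob = row_tot)
    s[pos] <- sample.int(4L, 1L, prob = rates[pos, ])
    # only the chosen position and its neighbours change context
    upd <- unique(c(left_of[pos], pos, right_of[pos]))
    ids <- ctx_ids(s)
    for (l in upd)
      rates[l, ] <- if (homogeneous) tab[ids[l], ] else tabs[[l]][ids[l], ]
  }
  norm_w <- sum(occ[1L, ])
  pair_freq <- pair_occ / norm_w
  dimnames(pair_freq) <- list(NULL, MUTSEL_BASES, MUTSEL_BASES)
  snapshots <- NULL
  if (!is.null(snapshot_every) && n_snap > 0L) {
    snaps <- snaps[seq_len(n_snap), , drop = FALSE]
    snapshots <- apply(snaps, 1L,
                       function(r) paste0(MUTSEL_BASES[r], collapse = ""))
  }
  structure(list(
    composition = {
      cm <- occ / norm_w
      colnames(cm) <- MUTSEL_BASES
      cm
    },
    pair_freq = pair_freq,
    batch_composition = {
      bc <- batch_occ / rowSums(batch_occ)
      colnames(bc) <- MUTSEL_BASES
      bc
    },
    events = iterations,
    total_time = total_time,
    snapshots = snapshots,
    averaging = averaging,
    L = L), class = "ctx_sim")
}

#' @export
print.ctx_sim <- function(x, ...) {
  cat(sprintf("ctx_sim: L = %d, %d events (%s-weighted), total time %.3f\n",
              x$L, x$events, x$averaging, x$total_time))
  cat("overall composition (A,T,G,C):",
      sprintf("%.4f", colMeans(x$composition)), "\n")
  invisible(x)
}

#' Chi-square-inspired deviation of simulated from empirical pair tables
#'
#' For each cell of the empirical 4x4 adjacent-pair count table, computes
#' (observed - expected)^2 / expected where the expected count is the
#' simulated joint frequency times the empirical total.  Large totals of
#' this table identify models whose simulated equilibrium fails to
#' reproduce the observed dinucleotide structure.
#'
#' @param sim_freq simulated 4x4 joint frequency table (sums to 1), or
#'   the L x 4 x 4 \code{pair_freq} array of a [simulate_ctx()] run, in
#'   which case positions are averaged (homogeneous parameters make them
#'   exchangeable).
#' @param empirical 4x4 matrix of observed pair counts (base order
#'   A,T,G,C).
#' @return 4x4 matrix of per-cell deviations; cells with expected count
#'   below 1e-8 are \code{NA}.  The sum (ignoring \code{NA}) is the
#'   total deviation statistic.
#' @export
chi2_deviation <- function(sim_freq, empirical) {
  if (length(dim(sim_freq)) == 3L)
    sim_freq <- apply(sim_freq, c(2L, 3L), mean)
  sim_freq <- as.matrix(sim_freq)
  empirical <- as.matrix(empirical)
  stopifnot(all(dim(sim_freq) == c(4L, 4L)),
            all(dim(empirical) == c(4L, 4L)))
  n <- sum(empirical)
  if (n <= 0) stop("empirical totals must be positive")
  expected <- sim_freq * n
  dev <- (empirical - expected)^2 / expected
  dev[expected < 1e-8] <- NA_real_
  dimnames(dev) <- list(MUTSEL_BASES, MUTSEL_BASES)
  dev
}
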