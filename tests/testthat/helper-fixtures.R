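# Shared fixtures: everything is generated in code, nothing read from disk.

# neutral matrix with AT:GC = 2:1 stationary composition
fix_Q <- function() default_Q()

# the canonical joint-selection truth used across recovery tests
fix_truth <- function() {
  selection_params(gamma = c(-0.5, 0.5, 0, 0), gamma_AG = -2,
                   hypothesis = "HIII")
}

# multinomial pair counts drawn from a 4x4 probability table
draw_pair_counts <- function(pi, N, seed) {
  set.seed(seed)
  matrix(rmultinom(1L, N, as.vector(t(pi))), 4L, 4L, byrow = TRUE,
         dimnames = dimnames(pi))
}

# low-theta 5LR-like population alignment simulated from a mutation
# matrix: monomorphic sites from the stationary composition, polymorphic
# sites with ordered mutation pair drawn proportional to stationary flux
# and derived count ~ 1/y
sim_5lr_alignment <- function(Q, n_sites, n_ind, p_poly, seed) {
  set.seed(seed)
  pi <- attr(Q, "stationary")
  bases <- c("A", "T", "G", "C")
  flux <- unclass(Q) * pi
  diag(flux) <- 0
  ij <- which(flux > 0, arr.ind = TRUE)
  w <- flux[ij]
  cols <- character(n_sites)
  poly <- runif(n_sites) < p_poly
  nm <- sum(!poly)
  cols[!poly] <- strrep(bases[sample.int(4L, nm, TRUE, prob = pi)], n_ind)
  np <- sum(poly)
  if (np > 0) {
    pick <- sample.int(nrow(ij), np, TRUE, prob = w)
    yv <- sample.int(n_ind - 1L, np, TRUE, prob = 1 / seq_len(n_ind - 1L))
    anc <- bases[ij[pick, 1L]]
    der <- bases[ij[pick, 2L]]
    cols[poly] <- vapply(seq_len(np), function(s)
      paste0(c(rep(der[s], yv[s]), rep(anc[s], n_ind - yv[s])),
             collapse = ""), character(1))
  }
  colmat <- do.call(rbind, strsplit(cols, "", fixed = TRUE))
  apply(colmat, 2L, paste0, collapse = "")
}

# construct a bare intron_record without going through a GFF file
make_intron <- function(seq, chrom = "chr1", start0 = 100L, strand = "+",
                        id = NULL, n_ind = 1L, exon3 = "ACGT") {
  len <- nchar(seq)
  aln <- rep(seq, n_ind)
  names(aln) <- paste0("ind", seq_len(n_ind))
  ex <- rep(exon3, n_ind)
  names(ex) <- names(aln)
  structure(list(
    id = if (is.null(id))
      paste0(chrom, ":", start0 + 1L, "-", start0 + len, "(", strand, ")")
      else id,
    chrom = chrom, start = start0, end = start0 + len,
    strand = strand, length = len,
    phase_class = if (len %% 3L == 0L) "phase0" else "nonphase0",
    alignment = aln, exon3 = ex), class = "intron_record")
}

# random ACGT sequences
random_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = ""), character(1))
}
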