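#' Default neutral mutation matrix of the synthetic generators
#'
#' Strand-symmetric matrix whose stationary composition has the
#' AT:GC = 2:1 ratio characteristic of the neutral 5' region of short
#' Drosophila introns, with a mild transition:transversion excess.
#'
#' @return a [mutation_matrix()].
#' @export
default_Q <- function() {
  # flux-balanced W<->S rates with a*mu_WS = g*mu_SW give stationary
  # (1/3, 1/3, 1/6, 1/6); transitions twice the transversions
  mutation_matrix(c(AT = 1, GC = 1, AG = 1, GA = 2, AC = 0.5, CA = 1))
}

#' Synthetic-genome configuration
#'
#' Bundles every knob of [synth_genome()].  Defaults emulate the data
#' structure of a population sample of short-intron-rich genes: genes on
#' both strands, intron lengths uniform on 45-75 bp, a neutral 5' region
#' at AT:GC = 2:1, and a 3PT generated under joint monomer + AG-dimer
#' selection (gamma_T = 0.5, gamma_A = -0.5, gamma_AG = -2).
#'
#' @param n_genes number of genes.
#' @param introns_per_gene introns in each gene.
#' @param intron_lengths integer vector to sample intron lengths from
#'   (uniformly).
#' @param n_individuals population sample size.
#' @param p_poly per-site probability that a site is polymorphic in the
#'   sample.
#' @param Q_mut neutral [mutation_matrix()].
#' @param params_3pt [selection_params()] generating the 3PT.
#' @param strand_mix fraction of genes on the minus strand.
#' @param exon_len length of each exon (all exons are CDS).
#' @param spacer_len intergenic spacer length.
#' @param seed integer seed (mandatory).
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 30L, introns_per_gene = 2L,
                         intron_lengths = 45:75, n_individuals = 8L,
                         p_poly = 0.01, Q_mut = default_Q(),
                         params_3pt = selection_params(
                           gamma = c(-0.5, 0.5, 0, 0), gamma_AG = -2,
                           hypothesis = "HIII"),
                         strand_mix = 0.5, exon_len = 90L,
                         spacer_len = 50L, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(p_poly >= 0, p_poly <= 1, strand_mix >= 0, strand_mix <= 1,
            all(intron_lengths >= 45L))
  structure(as.list(environment()), class = "synth_config")
}

# sample n bases iid from the stationary distribution of Q
stationary_bases <- function(Q, n) {
  pi <- attr(Q, "stationary")
  MUTSEL_BASES[sample.int(4L, n, replace = TRUE, prob = pi)]
}

# one intron in transcript orientation: GT + 5 neutral | 5LR(23 neutral)
# | neutral filler | 3PT(10 under selection) | TTAG
synth_intron_seq <- function(len, Q, tract10) {
  stopifnot(len >= 45L, nchar(tract10) == 10L)
  mid <- len - 44L
  paste0("GT", paste0(stationary_bases(Q, 5L), collapse = ""),
         paste0(stationary_bases(Q, 23L), collapse = ""),
         paste0(stationary_bases(Q, mid), collapse = ""),
         tract10, "TTAG")
}

#' Generate a synthetic annotated genome with a population sample
#'
#' Builds a single synthetic chromosome of protein-coding genes on both
#' strands, each with short introns whose 5' region is neutral
#' (stationary composition of \code{Q_mut}) and whose polypyrimidine
#' tract is drawn from the stationary regime of the context-dependent
#' mutation-selection simulator under \code{params_3pt}.  Splice
#' boundaries are canonical (GT ... AG).  Per-individual consensus
#' genomes are derived from the reference by injecting biallelic
#' polymorphisms (derived-allele count ~ 1/y, the neutral frequency
#' spectrum).  A ground-truth manifest records every intron.
#'
#' @param config a [synth_config()].
#' @param out_dir directory for the FASTA/GFF3 files; \code{NULL}
#'   (default) keeps everything in memory.
#' @return list with \code{reference} (named character, chromosomes),
#'   \code{individuals} (list of named character vectors),
#'   \code{annotation} (\code{GRanges} with gene/mRNA/exon/CDS/intron
#'   features), \code{manifest} (data.frame: intron coordinates
#'   1-based, strand, length, phase, true 5LR and 3PT sequences), and,
#'   when written, \code{paths}.
#' @export
synth_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_intr_total <- config$n_genes * config$introns_per_gene
  # pool of 3PT sequences from the simulator's stationary regime
  tracts <- synth_region_set(config$params_3pt, config$Q_mut,
                             n_sequences = n_intr_total, length = 10L,
                             seed = config$seed + 1L)
  chrom_parts <- character()
  feat <- list()
  manifest <- list()
  pos <- 1L   # next free 1-based position on the chromosome
  ti <- 0L
  for (gi in seq_len(config$n_genes)) {
    spacer <- paste0(stationary_bases(config$Q_mut, config$spacer_len),
                     collapse = "")
    chrom_parts <- c(chrom_parts, spacer)
    pos <- pos + config$spacer_len
    strand <- if (runif(1) < config$strand_mix) "-" else "+"
    n_ex <- config$introns_per_gene + 1L
    exons <- replicate(n_ex, paste0(
      stationary_bases(config$Q_mut, config$exon_len), collapse = ""))
    ilens <- sample(config$intron_lengths, config$introns_per_gene,
                    replace = TRUE)
    intr_seqs <- character(config$introns_per_gene)
    for (k in seq_len(config$introns_per_gene)) {
      ti <- ti + 1L
      intr_seqs[k] <- synth_intron_seq(ilens[k], config$Q_mut, tracts[ti])
    }
    # transcript-oriented block: E1 I1 E2 I2 ... En
    block_parts <- character(0)
    part_type <- character(0)
    for (k in seq_len(n_ex)) {
      block_parts <- c(block_parts, exons[k])
      part_type <- c(part_type, "exon")
      if (k <= config$introns_per_gene) {
        block_parts <- c(block_parts, intr_seqs[k])
        part_type <- c(part_type, "intron")
      }
    }
    block <- paste0(block_parts, collapse = "")
    W <- nchar(block)
    genomic_block <- if (strand == "-") revcomp(block) else block
    chrom_parts <- c(chrom_parts, genomic_block)
    gstart <- pos; gend <- pos + W - 1L
    # transcript position t (1..W) -> genomic 1-based coordinate
    t2g <- function(t) if (strand == "-") gend - t + 1L else gstart + t - 1L
    gene_id <- sprintf("gene%03d", gi)
    tx_id <- sprintf("tx%03d", gi)
    feat[[length(feat) + 1L]] <- data.frame(
      type = c("gene", "mRNA"), start = gstart, end = gend,
      strand = strand, ID = c(gene_id, tx_id),
      Parent = c(NA, gene_id))
    toff <- 0L
    intr_no <- 0L
    for (k in seq_along(block_parts)) {
      plen <- nchar(block_parts[k])
      t_a <- toff + 1L; t_b <- toff + plen
      g1 <- t2g(t_a); g2 <- t2g(t_b)
      lo <- min(g1, g2); hi <- max(g1, g2)
      if (part_type[k] == "exon") {
        feat[[length(feat) + 1L]] <- data.frame(
          type = c("exon", "CDS"), start = lo, end = hi, strand = strand,
          ID = c(NA, NA), Parent = tx_id)
      } else {
        intr_no <- intr_no + 1L
        feat[[length(feat) + 1L]] <- data.frame(
          type = "intron", start = lo, end = hi, strand = strand,
          ID = NA, Parent = tx_id)
        iseq <- block_parts[k]
        manifest[[length(manifest) + 1L]] <- data.frame(
          chrom = "chr1", start = lo, end = hi, strand = strand,
          length = plen,
          phase_class = if (plen %% 3L == 0L) "phase0" else "nonphase0",
          gene = gene_id,
          sequence = iseq,
          fiveLR = substr(iseq, 8L, 30L),
          threePT = substr(iseq, plen - 13L, plen - 4L))
      }
      toff <- toff + plen
    }
    pos <- pos + W
  }
  chrom <- paste0(chrom_parts, collapse = "")
  reference <- c(chr1 = chrom)
  manifest <- do.call(rbind, manifest)
  feats <- do.call(rbind, feat)
  annotation <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = feats$type, ID = feats$ID, Parent = feats$Parent,
    phase = ifelse(feats$type == "CDS", 0L, NA_integer_))
  individuals <- synth_population(reference, config)
  out <- list(reference = reference, individuals = individuals,
              annotation = annotation, manifest = manifest)
  if (!is.null(out_dir)) out$paths <- write_synth_genome(out, out_dir)
  out
}

# inject biallelic polymorphism columns into copies of the reference
synth_population <- function(reference, config) {
  n <- config$n_individuals
  inds <- replicate(n, reference, simplify = FALSE)
  names(inds) <- sprintf("ind%02d", seq_len(n))
  if (config$p_poly <= 0 || n < 2L) return(inds)
  for (chrom in names(reference)) {
    chars <- strsplit(reference[[chrom]], "", fixed = TRUE)[[1L]]
    L <- length(chars)
    sites <- which(runif(L) < config$p_poly)
    if (length(sites) == 0L) next
    mat <- matrix(rep(chars, n), nrow = n, byrow = TRUE)
    y_probs <- 1 / seq_len(n - 1L)
    for (s in sites) {
      ref_b <- chars[s]
      alt <- sample(setdiff(ALPHA_BASES, ref_b), 1L)
      y <- sample.int(n - 1L, 1L, prob = y_probs)
      carriers <- sample.int(n, y)
      mat[carriers, s] <- alt
    }
    rows <- apply(mat, 1L, paste0, collapse = "")
    for (i in seq_len(n)) inds[[i]][[chrom]] <- rows[i]
  }
  inds
}

write_synth_genome <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$reference), ref_path)
  ind_paths <- character()
  for (nm in names(x$individuals)) {
    p <- file.path(out_dir, paste0(nm, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(x$individuals[[nm]]), p)
    ind_paths[nm] <- p
  }
  gff_path <- file.path(out_dir, "annotation.gff3")
  rtracklayer::export(x$annotation, gff_path, format = "gff3")
  man_path <- file.path(out_dir, "manifest.tsv")
  write.table(x$manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(reference = ref_path, individuals = ind_paths,
       annotation = gff_path, manifest = man_path)
}

#' Sample region sequences from the simulator's stationary regime
#'
#' Runs the circular Gillespie simulator under the given parameters and
#' records the sequence state every \code{thin} accepted substitutions
#' after burn-in, yielding approximately independent draws from the
#' model's stationary distribution.  Under neutral parameters, every
#' motif asymmetry score is 0 up to sampling error.
#'
#' @param params [selection_params()].
#' @param Q_mut neutral [mutation_matrix()].
#' @param n_sequences number of sequences to return.
#' @param length sequence length (the simulator ring size).
#' @param seed integer seed (required).
#' @param thin accepted events between snapshots (default 2 * length:
#'   on average two substitutions per site between draws).
#' @param burnin discarded initial events.
#' @return character vector of \code{n_sequences} sequences.
#' @export
synth_region_set <- function(params, Q_mut = default_Q(), n_sequences,
                             length = 10L, seed, thin = 2L * length,
                             burnin = 1000L) {
  if (missing(seed)) stop("seed is required")
  sim <- simulate_ctx(Q_mut, params, L = length,
                      iterations = n_sequences * thin, burnin = burnin,
                      seed = seed, snapshot_every = thin)
  sim$snapshots
}

#' Simulate a site-frequency spectrum under known gBGC strength
#'
#' Draws site counts from the multinomial with class probabilities
#' [sfs_probs()] -- the same probability function the estimator uses, so
#' recovery tests exercise the optimiser; an independent check of the
#' probabilities themselves (Monte-Carlo integration of the sojourn
#' density) guards against shared-bug circularity.
#'
#' @param n haploid sample size.
#' @param B true scaled conversion bias.
#' @param beta true weak-to-strong origin fraction.
#' @param n_sites number of segregating sites.
#' @param seed integer seed (required).
#' @param mclass class label for the returned spectrum.
#' @return an [sfs()] object.
#' @export
synth_sfs <- function(n, B, beta, n_sites, seed,
                      mclass = "GC-changing") {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  p <- sfs_probs(n, B, beta)
  sfs(as.numeric(rmultinom(1L, n_sites, p)), n, mclass)
}
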