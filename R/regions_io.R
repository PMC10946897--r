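#' Load oriented, de-duplicated intron alignments from FASTA + GFF3
#'
#' Reads a GFF3 annotation and a reference genome, together with
#' optional per-individual consensus genomes aligned to reference
#' coordinates (equal length per chromosome), and returns one alignment
#' per unique intron.  Explicit \code{intron} features are used when
#' present; otherwise introns are derived as the gaps between
#' consecutive \code{exon} features of the same transcript.  Introns
#' listed by several isoforms with identical coordinates are collapsed
#' to a single record.  Minus-strand introns are reverse-complemented
#' exactly once, so every alignment runs 5' to 3' of the transcript.
#'
#' @param gff3 path to a GFF3 file (1-based inclusive coordinates).
#' @param genome_fasta path to the reference genome FASTA.
#' @param individual_fastas character vector of per-individual FASTA
#'   paths (named, or named by file base name), or a named list of
#'   \code{DNAStringSet}s.  \code{NULL} uses the reference as the single
#'   alignment row.
#' @return list of \code{intron_record} objects: each a list with
#'   \code{id}, \code{chrom}, \code{start} (0-based), \code{end}
#'   (half-open), \code{strand}, \code{length}, \code{phase_class}
#'   (\code{"phase0"} iff length \%\% 3 == 0), \code{alignment} (named
#'   character vector, one oriented sequence per individual) and
#'   \code{exon3} (the 4 downstream-exon bases per individual, oriented;
#'   \code{NA} at a chromosome edge).
#' @export
load_introns <- function(gff3, genome_fasta, individual_fastas = NULL) {
  gr <- rtracklayer::import(gff3)
  introns <- gr[gr$type == "intron"]
  if (length(introns) == 0L)
    introns <- derive_introns_from_exons(gr)
  if (length(introns) == 0L) stop("no intron or exon features in ", gff3)
  key <- paste0(GenomicRanges::seqnames(introns), ":",
                GenomicRanges::start(introns), "-",
                GenomicRanges::end(introns),
                "(", GenomicRanges::strand(introns), ")")
  introns <- introns[!duplicated(key)]
  key <- key[!duplicated(key)]

  ref <- read_genome(genome_fasta)
  genomes <- load_individual_genomes(individual_fastas, ref)

  out <- vector("list", length(introns))
  for (i in seq_along(introns)) {
    chrom <- as.character(GenomicRanges::seqnames(introns))[i]
    s1 <- GenomicRanges::start(introns)[i]   # 1-based inclusive
    e1 <- GenomicRanges::end(introns)[i]
    strand <- as.character(GenomicRanges::strand(introns))[i]
    if (!chrom %in% names(ref))
      stop("feature ", key[i], ": chromosome ", chrom, " not in the genome")
    clen <- Biostrings::width(ref[chrom])
    if (s1 < 1L || e1 > clen)
      stop("feature ", key[i], ": coordinates outside chromosome ",
           chrom, " (length ", clen, ")")
    aln <- vapply(genomes, function(g)
      as.character(Biostrings::subseq(g[[chrom]], s1, e1)), character(1))
    # downstream-exon bases in transcript orientation
    ex <- vapply(genomes, function(g) {
      if (strand == "-") {
        if (s1 - 4L < 1L) return(NA_character_)
        as.character(Biostrings::subseq(g[[chrom]], s1 - 4L, s1 - 1L))
      } else {
        if (e1 + 4L > clen) return(NA_character_)
        as.character(Biostrings::subseq(g[[chrom]], e1 + 1L, e1 + 4L))
      }
    }, character(1))
    if (strand == "-") {
      aln <- revcomp(aln)
      ex[!is.na(ex)] <- revcomp(ex[!is.na(ex)])
    }
    len <- e1 - s1 + 1L
    out[[i]] <- structure(list(
      id = key[i], chrom = chrom,
      start = s1 - 1L, end = e1,          # 0-based half-open internally
      strand = strand, length = len,
      phase_class = if (len %% 3L == 0L) "phase0" else "nonphase0",
      alignment = aln, exon3 = ex), class = "intron_record")
  }
  out
}

# introns = gaps between consecutive exons of one transcript (Parent)
derive_introns_from_exons <- function(gr) {
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0L) return(exons)
  parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
  pieces <- split(seq_along(exons), parent)
  res <- list()
  for (idx in pieces) {
    e <- exons[idx]
    e <- e[order(GenomicRanges::start(e))]
    if (length(e) < 2L) next
    st <- GenomicRanges::end(e)[-length(e)] + 1L
    en <- GenomicRanges::start(e)[-1L] - 1L
    keep <- en >= st
    if (!any(keep)) next
    res[[length(res) + 1L]] <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(e))[1L],
      ranges = IRanges::IRanges(st[keep], en[keep]),
      strand = as.character(GenomicRanges::strand(e))[1L])
  }
  if (length(res) == 0L)
    return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, res))
}

read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

load_individual_genomes <- function(individual_fastas, ref) {
  if (is.null(individual_fastas) || length(individual_fastas) == 0L)
    return(list(ref = ref))
  if (is.character(individual_fastas)) {
    nm <- names(individual_fastas)
    if (is.null(nm))
      nm <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(individual_fastas))
    genomes <- lapply(individual_fastas, read_genome)
    names(genomes) <- nm
  } else {
    genomes <- individual_fastas
    if (is.null(names(genomes)))
      names(genomes) <- paste0("ind", seq_along(genomes))
  }
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    common <- intersect(names(ref), names(g))
    if (length(common) == 0L)
      stop("individual ", nm, " shares no chromosome names with the reference")
    bad <- common[Biostrings::width(g[common]) !=
                    Biostrings::width(ref[common])]
    if (length(bad) > 0L)
      stop("individual ", nm, " is not reference-coordinate aligned: ",
           "length mismatch on ", paste(bad, collapse = ", "))
  }
  genomes
}

#' Short-intron classification
#'
#' TRUE iff the intron length is within [min_len, max_len].  The upper
#' default of 75 bp marks where the neutral AT:GC = 2:1 composition of
#' intron positions 8-30 gives way to selection-driven GC enrichment;
#' the lower default of 45 bp is the shortest length at which the 5LR
#' (ending at position 30) and the 3PT (starting at length - 13) are
#' disjoint.
#'
#' @param intron an \code{intron_record}, or a numeric length vector.
#' @param max_len,min_len inclusive bounds in bases.
#' @return logical vector.
#' @export
classify_short <- function(intron, max_len = 75L, min_len = 45L) {
  len <- if (inherits(intron, "intron_record")) intron$length
         else if (is.list(intron)) vapply(intron, `[[`, numeric(1), "length")
         else intron
  stopifnot(all(len >= 1))
  len >= min_len & len <= max_len
}

#' Partition introns by phase
#'
#' Phase-0 introns have length 3n + 0 and sit between complete codons;
#' the partition is exhaustive and disjoint.
#'
#' @param introns list of \code{intron_record}s.
#' @return list with elements \code{phase0} and \code{nonphase0}.
#' @export
bin_by_phase <- function(introns) {
  ph <- vapply(introns, `[[`, character(1), "phase_class")
  list(phase0 = introns[ph == "phase0"],
       nonphase0 = introns[ph == "nonphase0"])
}

#' Consensus sequence and position-weight matrix of an alignment
#'
#' Per column, the consensus is the most frequent base; ties are broken
#' deterministically by the fixed base order A < C < G < T and flagged.
#' The PWM holds the per-column relative base frequencies (rows A, C, G,
#' T; columns sum to 1).
#'
#' @param alignment character vector of equal-length sequences over
#'   \{A,C,G,T\} (no Ns: filter first).
#' @return list with \code{consensus} (string), \code{pwm} (4 x L
#'   matrix) and \code{ties} (logical per column).
#' @export
consensus_and_pwm <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  stopifnot_acgt(alignment)
  counts <- column_base_counts(alignment)
  pwm <- sweep(counts, 2L, colSums(counts), "/")
  win <- apply(counts, 2L, function(col) {
    m <- unname(which(col == max(col)))
    c(m[1L], length(m) > 1L)
  })
  list(consensus = paste0(ALPHA_BASES[win[1L, ]], collapse = ""),
       pwm = pwm,
       ties = as.logical(win[2L, ]))
}

REGION_LENGTHS <- c(fiveLR = 23L, threePT = 10L, junction3 = 8L)

# map an intron-relative window [a, b] (1-based, transcript orientation,
# may extend past the intron end into the exon) to a genomic 0-based
# half-open footprint
window_footprint <- function(intron, a, b) {
  if (intron$strand == "-") c(intron$end - b, intron$end - a + 1L)
  else c(intron$start + a - 1L, intron$start + b)
}

#' Cut the 5LR, 3PT and 3'-junction windows of one intron
#'
#' Window definitions (intron-relative, 1-based, transcript
#' orientation):
#' \itemize{
#'   \item 5LR: positions 8-30 (23 bases) -- the presumably neutral
#'     stretch between the donor signal and the branch point;
#'   \item 3PT: positions (length-13) to (length-4) (10 bases) -- the
#'     polypyrimidine tract, excluding the last four bases that belong
#'     to the acceptor signal;
#'   \item junction3: the last 4 intronic bases plus the first 4 bases
#'     of the downstream exon (8 bases straddling the 3' junction).
#' }
#'
#' @param intron an \code{intron_record} (see [load_introns()]),
#'   expected to have passed [classify_short()].
#' @return named list of three \code{region_set} objects (fields:
#'   \code{label}, \code{window}, \code{alignment}, \code{consensus},
#'   \code{pwm}, \code{ties}, \code{chrom}, \code{strand},
#'   \code{footprint} genomic 0-based half-open, \code{intron_id}), or
#'   an empty object of class \code{region_skip} with a \code{reason}
#'   attribute when the intron is too short to host disjoint windows.
#' @export
extract_regions <- function(intron) {
  stopifnot(inherits(intron, "intron_record"))
  len <- intron$length
  if (len < 44L)
    return(structure(list(), class = "region_skip",
                     reason = "too_short_for_disjoint_windows"))
  windows <- list(fiveLR = c(8L, 30L),
                  threePT = c(len - 13L, len - 4L),
                  junction3 = c(len - 3L, len + 4L))
  out <- lapply(names(windows), function(lab) {
    w <- windows[[lab]]
    if (lab == "junction3") {
      tail4 <- substr(intron$alignment, len - 3L, len)
      aln <- ifelse(is.na(intron$exon3), NA_character_,
                    paste0(tail4, intron$exon3))
      names(aln) <- names(intron$alignment)
    } else {
      aln <- substr(intron$alignment, w[1L], w[2L])
    }
    cp <- if (!anyNA(aln) && !any(grepl("[^ACGT]", aln)) &&
              all(nchar(aln) == REGION_LENGTHS[[lab]]))
      consensus_and_pwm(aln) else list(consensus = NA, pwm = NULL, ties = NULL)
    structure(list(label = lab, window = w, alignment = aln,
                   consensus = cp$consensus, pwm = cp$pwm, ties = cp$ties,
                   chrom = intron$chrom, strand = intron$strand,
                   footprint = window_footprint(intron, w[1L], w[2L]),
                   intron_id = intron$id), class = "region_set")
  })
  names(out) <- names(windows)
  out
}

#' Filter region windows against CDS overlap, Ns and truncation
#'
#' A region is dropped when (a) its genomic footprint intersects an
#' annotated coding interval -- except \code{junction3}, whose exonic
#' half is coding by construction and is exempt; (b) any individual
#' carries an N (or any non-ACGT character) anywhere in the window; or
#' (c) the window is not full length.  Drops are logged, never silent.
#'
#' @param regions list of \code{region_set} objects (e.g. the
#'   concatenated results of [extract_regions()] over many introns).
#' @param cds_intervals coding intervals: a \code{GRanges}, or a
#'   data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive).
#' @return list with \code{kept} (the surviving \code{region_set}s) and
#'   \code{drop_log} (data.frame: \code{intron_id}, \code{label},
#'   \code{reason}).
#' @export
filter_regions <- function(regions, cds_intervals = NULL) {
  if (!is.null(cds_intervals) && !inherits(cds_intervals, "GRanges")) {
    cds_intervals <- GenomicRanges::GRanges(
      seqnames = cds_intervals$chrom,
      ranges = IRanges::IRanges(cds_intervals$start, cds_intervals$end))
  }
  keep <- logical(length(regions))
  log_rows <- list()
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    reason <- NULL
    if (anyNA(r$alignment) ||
        any(nchar(r$alignment) != REGION_LENGTHS[[r$label]])) {
      reason <- "truncated"
    } else if (any(grepl("[^ACGT]", r$alignment))) {
      reason <- "contains_N"
    } else if (!is.null(cds_intervals) && r$label != "junction3") {
      fp <- GenomicRanges::GRanges(
        seqnames = r$chrom,
        ranges = IRanges::IRanges(r$footprint[1L] + 1L, r$footprint[2L]))
      if (length(GenomicRanges::findOverlaps(fp, cds_intervals)) > 0L)
        reason <- "cds_overlap"
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(intron_id = r$intron_id, label = r$label, reason = reason)
    }
  }
  drop_log <- if (length(log_rows)) do.call(rbind, log_rows)
              else data.frame(intron_id = character(), label = character(),
                              reason = character())
  list(kept = regions[keep], drop_log = drop_log)
}

#' Run the full region-extraction pipeline
#'
#' Convenience wrapper: classify short introns, cut the three windows of
#' each, filter against CDS overlap / Ns / truncation, and collect the
#' survivors by region label.
#'
#' @param introns list of \code{intron_record}s from [load_introns()].
#' @param cds_intervals see [filter_regions()].
#' @param max_len,min_len short-intron bounds, see [classify_short()].
#' @return list with \code{fiveLR}, \code{threePT}, \code{junction3}
#'   (lists of kept \code{region_set}s), \code{drop_log}, and
#'   \code{n_short} (introns passing the length filter).
#' @export
extract_region_sets <- function(introns, cds_intervals = NULL,
                                max_len = 75L, min_len = 45L) {
  short <- introns[classify_short(introns, max_len, min_len)]
  all_regions <- list()
  skip_rows <- list()
  for (intr in short) {
    regs <- extract_regions(intr)
    if (inherits(regs, "region_skip")) {
      skip_rows[[length(skip_rows) + 1L]] <-
        data.frame(intron_id = intr$id, label = "all",
                   reason = attr(regs, "reason"))
      next
    }
    all_regions <- c(all_regions, unname(regs))
  }
  filt <- filter_regions(all_regions, cds_intervals)
  drop_log <- rbind(if (length(skip_rows)) do.call(rbind, skip_rows),
                    filt$drop_log)
  labs <- vapply(filt$kept, `[[`, character(1), "label")
  list(fiveLR = filt$kept[labs == "fiveLR"],
       threePT = filt$kept[labs == "threePT"],
       junction3 = filt$kept[labs == "junction3"],
       drop_log = drop_log,
       n_short = length(short))
}

#' Consensus sequences of a list of region sets
#'
#' @param regions list of \code{region_set}s of one label.
#' @return named character vector of consensus sequences (names =
#'   intron ids).
#' @export
region_consensus <- function(regions) {
  out <- vapply(regions, `[[`, character(1), "consensus")
  names(out) <- vapply(regions, `[[`, character(1), "intron_id")
  out
}

#' Write region outputs to disk
#'
#' Writes, per region label: the alignments as a multi-FASTA (rows named
#' \code{intronid|individual}), the consensus sequences as a FASTA, and
#' the PWMs as a TSV (rows A, C, G, T per intron); plus the drop log as
#' a TSV.  Everything round-trips byte-identically through
#' \code{Biostrings}.
#'
#' @param region_sets result of [extract_region_sets()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_regions <- function(region_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (lab in c("fiveLR", "threePT", "junction3")) {
    regs <- region_sets[[lab]]
    if (length(regs) == 0L) next
    aln <- unlist(lapply(regs, function(r) {
      s <- r$alignment
      names(s) <- paste0(r$intron_id, "|", names(s))
      s
    }))
    p1 <- file.path(dir, paste0(lab, "_alignment.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln), p1)
    cons <- region_consensus(regs)
    p2 <- file.path(dir, paste0(lab, "_consensus.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cons), p2)
    pwm_tab <- do.call(rbind, lapply(regs, function(r) {
      data.frame(intron_id = r$intron_id, base = rownames(r$pwm),
                 r$pwm, check.names = FALSE)
    }))
    p3 <- file.path(dir, paste0(lab, "_pwm.tsv"))
    write.table(pwm_tab, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p1, p2, p3)
  }
  p4 <- file.path(dir, "drop_log.tsv")
  write.table(region_sets$drop_log, p4, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, p4))
}
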