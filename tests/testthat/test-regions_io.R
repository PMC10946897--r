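test_that("GFF3 conventions, isoform de-duplication and orientation", {
  # 300 bp chromosome with a plus intron at 101..160 (listed by two
  # isoforms) and a minus intron at 201..260
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  chrom <- sample(bases, 300, replace = TRUE)
  plus_intron <- paste0("GT", paste0(sample(bases, 56, TRUE), collapse = ""),
                        "AG")
  minus_oriented <- paste0("GT", paste0(sample(bases, 56, TRUE), collapse = ""),
                           "AG")
  chrom[101:160] <- strsplit(plus_intron, "")[[1]]
  chrom[201:260] <- strsplit(revcomp(minus_oriented), "")[[1]]
  ref <- paste0(chrom, collapse = "")

  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(chrT = ref)), fa)
  gr <- GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(c(101, 101, 201), c(160, 160, 260)),
    strand = c("+", "+", "-"),
    type = "intron",
    Parent = c("txA", "txB", "txC"))   # two isoforms share the first intron
  gff <- file.path(dir, "ann.gff3")
  rtracklayer::export(gr, gff, format = "gff3")

  introns <- load_introns(gff, fa)
  expect_length(introns, 2L)           # duplicate entry collapsed
  plus <- introns[[which(vapply(introns, `[[`, character(1), "strand") == "+")]]
  minus <- introns[[which(vapply(introns, `[[`, character(1), "strand") == "-")]]
  # 1-based inclusive 101..160 -> 0-based half-open (100, 160), length 60
  expect_identical(plus$start, 100L)
  expect_identical(plus$end, 160L)
  expect_identical(plus$length, 60L)
  expect_identical(unname(plus$alignment[1]), plus_intron)
  # minus-strand record reverse-complemented exactly once
  expect_identical(unname(minus$alignment[1]), minus_oriented)
  # involution: re-complementing twice returns the genomic text
  expect_identical(unname(revcomp(revcomp(minus$alignment[1]))),
                   unname(minus$alignment[1]))

  # coordinates beyond the chromosome end are a hard error naming the feature
  bad <- GenomicRanges::GRanges("chrT", IRanges::IRanges(290, 310),
                                strand = "+", type = "intron", Parent = "txZ")
  gff_bad <- file.path(dir, "bad.gff3")
  rtracklayer::export(bad, gff_bad, format = "gff3")
  expect_error(load_introns(gff_bad, fa), "outside chromosome")

  # a mis-aligned individual (different chromosome length) is a hard error
  fa_short <- file.path(dir, "short.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrT = substr(ref, 1, 299))), fa_short)
  expect_error(load_introns(gff, fa, individual_fastas = c(s1 = fa_short)),
               "length mismatch")
})

test_that("introns are derived from consecutive exons when not annotated", {
  set.seed(12)
  ref <- paste0(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(c1 = ref)), fa)
  # exons 51..110 and 171..230: the gap 111..170 is the intron
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(51, 171), c(110, 230)), strand = "+",
    type = "exon", Parent = c("tx1", "tx1"))
  gff <- file.path(dir, "exons.gff3")
  rtracklayer::export(gr, gff, format = "gff3")
  introns <- load_introns(gff, fa)
  expect_length(introns, 1L)
  expect_identical(introns[[1]]$start, 110L)
  expect_identical(introns[[1]]$end, 170L)
  expect_identical(introns[[1]]$length, 60L)
})

test_that("short-intron length bounds are inclusive and configurable", {
  expect_true(classify_short(75))
  expect_false(classify_short(76))
  expect_true(classify_short(45))
  expect_false(classify_short(44))
  expect_true(classify_short(80, max_len = 100))
  expect_true(classify_short(make_intron(strrep("A", 60))))
})

test_that("region windows follow the stated arithmetic", {
  seqs60 <- random_seqs(1, 60, seed = 21)
  intr <- make_intron(seqs60)
  regs <- extract_regions(intr)
  expect_identical(regs$fiveLR$window, c(8L, 30L))
  expect_identical(nchar(regs$fiveLR$alignment[[1]]), 23L)
  expect_identical(regs$threePT$window, c(47L, 56L))
  expect_identical(nchar(regs$threePT$alignment[[1]]), 10L)
  expect_identical(nchar(regs$junction3$alignment[[1]]), 8L)
  expect_identical(unname(regs$fiveLR$alignment[1]), substr(seqs60, 8, 30))
  expect_identical(unname(regs$threePT$alignment[1]), substr(seqs60, 47, 56))
  expect_identical(unname(regs$junction3$alignment[1]),
                   paste0(substr(seqs60, 57, 60), "ACGT"))

  # minimum length 45: 5LR ends at 30, 3PT starts at 32, disjoint
  intr45 <- make_intron(random_seqs(1, 45, seed = 22))
  regs45 <- extract_regions(intr45)
  expect_identical(regs45$threePT$window, c(32L, 41L))
  expect_true(regs45$threePT$window[1] > regs45$fiveLR$window[2])

  # below 44 the windows cannot be disjoint: skipped with a reason
  too_short <- extract_regions(make_intron(random_seqs(1, 40, seed = 23)))
  expect_s3_class(too_short, "region_skip")
  expect_match(attr(too_short, "reason"), "too_short")

  # genomic footprint maps back onto the genome for both strands
  expect_identical(regs$fiveLR$footprint, c(100L + 7L, 100L + 30L))
  intr_m <- make_intron(seqs60, strand = "-")
  regs_m <- extract_regions(intr_m)
  expect_identical(regs_m$fiveLR$footprint,
                   c(intr_m$end - 30L, intr_m$end - 7L))
})

test_that("filtering drops CDS overlap, Ns and truncation, with a log", {
  seqs <- random_seqs(5, 60, seed = 31)
  introns <- lapply(seq_len(5), function(i)
    make_intron(seqs[i], start0 = 1000L * i, id = paste0("i", i)))
  # intron 2 carries an N inside its 3PT window (position 50)
  introns[[2]]$alignment[1] <- paste0(substr(seqs[2], 1, 49), "N",
                                      substr(seqs[2], 51, 60))
  # a CDS interval overlapping intron 4's footprint
  cds <- data.frame(chrom = "chr1", start = 4001, end = 4060)
  regions <- unlist(lapply(introns, function(x)
    unname(extract_regions(x)["threePT"])), recursive = FALSE)
  filt <- filter_regions(regions, cds)

  # brute-force oracle: interval intersection + character scan
  expect_kept <- vapply(seq_len(5), function(i) {
    fp <- regions[[i]]$footprint
    no_cds <- (fp[2] < cds$start) || (fp[1] + 1 > cds$end)
    no_n <- !grepl("[^ACGT]", regions[[i]]$alignment[1])
    no_cds && no_n
  }, logical(1))
  expect_identical(length(filt$kept), sum(expect_kept))
  expect_identical(sum(expect_kept), 3L)
  expect_setequal(filt$drop_log$reason, c("contains_N", "cds_overlap"))
  # junction3 windows are exempt from the CDS filter
  j3 <- extract_regions(introns[[4]])["junction3"]
  expect_length(filter_regions(unname(j3), cds)$kept, 1L)
})

test_that("consensus is the column mode with a deterministic tie rule", {
  cp <- consensus_and_pwm(c("A", "A", "A", "T"))
  expect_identical(cp$consensus, "A")
  expect_equal(unname(cp$pwm[, 1]), c(0.75, 0, 0, 0.25))
  expect_false(cp$ties[1])

  tie <- consensus_and_pwm(c("A", "T"))
  expect_identical(tie$consensus, "A")   # A < C < G < T
  expect_true(tie$ties[1])
  tie2 <- consensus_and_pwm(c("G", "C"))
  expect_identical(tie2$consensus, "C")

  # 3-row x 4-column toy alignment: exhaustive per-column tally oracle
  aln <- c("ACGT", "ACGA", "TCGA")
  cp3 <- consensus_and_pwm(aln)
  oracle <- vapply(1:4, function(j) {
    col <- substr(aln, j, j)
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  }, character(1))
  expect_identical(cp3$consensus, paste0(oracle, collapse = ""))
  expect_true(all(abs(colSums(cp3$pwm) - 1) < 1e-12))
  expect_error(consensus_and_pwm(character(0)), "empty")
})

test_that("phase binning is exhaustive and disjoint", {
  expect_identical(make_intron(strrep("A", 60))$phase_class, "phase0")
  expect_identical(make_intron(strrep("A", 61))$phase_class, "nonphase0")
  introns <- lapply(45:75, function(l) make_intron(strrep("A", l)))
  bins <- bin_by_phase(introns)
  expect_length(bins$phase0, 11L)       # multiples of 3 in 45..75
  expect_length(bins$nonphase0, 20L)
  expect_identical(length(bins$phase0) + length(bins$nonphase0),
                   length(introns))
})

test_that("reverse complement is an involution", {
  seqs <- random_seqs(20, 17, seed = 41)
  expect_identical(revcomp(revcomp(seqs)), seqs)
  expect_identical(revcomp("CTAC"), "GTAG")
})
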