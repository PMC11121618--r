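test_that("reference loading normalizes case and validates contigs", {
  fa <- write_fasta(c(chr1 = "ACGT", chr2 = "GGGG"))
  ref <- load_reference(fa)
  expect_setequal(names(ref), c("chr1", "chr2"))
  expect_equal(unname(Biostrings::width(ref)), c(4L, 4L))

  lc <- write_fasta(c(chr1 = "acgt"))
  expect_equal(as.character(load_reference(lc)[["chr1"]]), "ACGT")

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), dup)
  expect_error(load_reference(dup), "duplicate contig")

  expect_error(load_reference(tempfile()), "not found")
  bad <- write_fasta(c(chr1 = "ACXT"))
  expect_error(load_reference(bad), "non-ACGTN.*chr1.*3")
})

test_that("panel reading merges overlapping intervals and reports bad rows", {
  bed <- write_bed(data.frame(c("chr1", "chr1"), c(10L, 15L), c(20L, 30L)))
  p <- read_panel(bed)
  expect_length(p, 1L)
  # BED (10,30) half-open == 1-based [11,30], total length 20
  expect_equal(GenomicRanges::start(p), 11L)
  expect_equal(GenomicRanges::end(p), 30L)
  expect_equal(sum(GenomicRanges::width(p)), 20L)

  two <- write_bed(data.frame(c("chr2", "chr1"), c(0L, 5L), c(10L, 9L)))
  p2 <- read_panel(two)
  expect_equal(as.character(GenomicRanges::seqnames(p2)), c("chr1", "chr2"))

  bad <- write_bed(data.frame("chr1", 20L, 10L))
  expect_error(read_panel(bad), "line 1")
})

test_that("panel write/read round trip is idempotent", {
  bed <- write_bed(data.frame(c("chr1", "chr1", "chr2"),
                              c(100L, 150L, 0L), c(160L, 300L, 50L)))
  p1 <- read_panel(bed)
  p2 <- read_panel(write_panel(p1, tempfile(fileext = ".bed")))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("VCF reading splits multiallelics, derives classes, honors FILTER", {
  vcf <- write_vcf_text(c(
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t0/1:20:12,8",
    "chr1\t201\trs42\tA\tG,T\t.\tPASS\tAF=0.25;CSQ=intron_variant\tGT\t0/1",
    "chr1\t301\t.\tC\tT\t.\tLowQual\t.\tGT\t0/1",
    "chr1\t401\t.\tCTT\tC\t.\tPASS\t.\tGT\t0/1",
    "chr1\t501\t.\tG\tGAA\t.\tPASS\t.\tGT\t0/1"))
  v <- read_variants(vcf, "S1", "SOMATIC")
  expect_equal(nrow(v), 5L)  # multiallelic split, LowQual dropped
  expect_equal(v$pos[v$vclass == "SNV"], c(101L, 201L, 201L))
  expect_setequal(v$alt[v$pos == 201L], c("G", "T"))
  expect_equal(v$af_pop[v$pos == 201L], c(0.25, 0.25))
  expect_equal(v$consequence[v$pos == 201L][1], "intron_variant")
  expect_equal(v$rsid[v$pos == 201L][1], "rs42")
  expect_equal(v$vclass[v$pos == 401L], "DEL")
  expect_equal(v$vclass[v$pos == 501L], "INS")
  expect_equal(v$dp[v$pos == 101L], 20L)
  expect_equal(v$ad_alt[v$pos == 101L], 8L)

  v2 <- read_variants(vcf, "S1", "SOMATIC", keep_nonpass = TRUE)
  expect_equal(nrow(v2), 6L)
})

test_that("germline depth filter is strict and tallies unscored variants", {
  v <- rbind(make_variant(pos = 1, dp = 11L, ad_alt = 6L),
             make_variant(pos = 2, dp = 10L, ad_alt = 6L),
             make_variant(pos = 3, dp = 11L, ad_alt = 5L),
             make_variant(pos = 4),
             make_variant(pos = 5, dp = 50L, ad_alt = 20L))
  out <- filter_germline(v)
  expect_equal(out$pos, c(1L, 5L))
  rep <- attr(out, "germline_filter_report")
  expect_equal(rep$n_in, 5L)
  expect_equal(rep$n_kept, 2L)
  expect_equal(rep$n_failed, 2L)
  expect_equal(rep$n_unscored, 1L)
})

test_that("window extraction follows the +/-70 convention and clips at edges", {
  ref <- load_reference(write_fasta(c(chr1 = random_dna(1000))))
  w <- extract_window(ref, make_variant(pos = 100), flank = 70)
  # spec's 0-based (29, 170) == 1-based [30, 170]
  expect_equal(w$start, 30L)
  expect_equal(w$end, 170L)
  expect_equal(nchar(w$seq), 141L)
  expect_equal(w$clipped_left, 0L)

  w2 <- extract_window(ref, make_variant(pos = 10), flank = 70)
  expect_equal(w2$clipped_left, 61L)
  expect_equal(nchar(w2$seq), 80L)

  refseq <- as.character(ref[["chr1"]])
  del <- make_variant(pos = 100, ref = substr(refseq, 100, 102), alt = "A")
  w3 <- extract_window(ref, del, flank = 70)
  expect_equal(w3$start, 30L)
  expect_equal(w3$end, 172L)
  expect_equal(nchar(w3$seq), 143L)

  expect_error(extract_window(ref, make_variant(chrom = "chrX")), "absent")
})

test_that("anchor base of an unclipped SNV window equals the reference allele", {
  set.seed(401)
  ref <- load_reference(write_fasta(c(chr1 = random_dna(500))))
  refseq <- as.character(ref[["chr1"]])
  for (pos in sample(100:400, 20)) {
    v <- make_variant(pos = pos, ref = substr(refseq, pos, pos), alt = "N")
    w <- extract_window(ref, v, flank = 70)
    expect_equal(substr(w$seq, w$flank + 1L, w$flank + 1L), v$ref)
  }
})

test_that("variant application splices correctly and validates edits", {
  ref <- load_reference(write_fasta(c(chr1 = "AAAAA")))
  w <- extract_window(ref, make_variant(pos = 3, ref = "A", alt = "A"), flank = 2)
  expect_equal(w$seq, "AAAAA")

  snv <- make_variant(pos = 3, ref = "A", alt = "G", origin = "GERMLINE")
  expect_equal(apply_variants(w, snv)$seq, "AAGAA")

  del <- make_variant(pos = 2, ref = "AA", alt = "A", origin = "GERMLINE")
  expect_equal(apply_variants(w, del)$seq, "AAAA")

  two <- rbind(make_variant(pos = 3, ref = "A", alt = "G"),
               make_variant(pos = 3, ref = "A", alt = "T"))
  expect_error(apply_variants(w, two), "overlapping")

  bad <- make_variant(pos = 3, ref = "C", alt = "G")
  expect_error(apply_variants(w, bad), "mismatch")

  outside <- make_variant(chrom = "chr2", pos = 3, ref = "A", alt = "G")
  w_out <- apply_variants(w, outside)
  expect_equal(w_out$seq, "AAAAA")
  expect_equal(attr(w_out, "skipped_edits"), 1L)
})

test_that("applying zero edits is the identity on the sequence", {
  ref <- load_reference(write_fasta(c(chr1 = random_dna(300))))
  w <- extract_window(ref, make_variant(pos = 150,
                                        ref = substr(as.character(ref[[1]]), 150, 150),
                                        alt = "N"))
  expect_identical(apply_variants(w, empty_edits <- make_variant()[0, ])$seq, w$seq)
})

test_that("insertion then matching deletion restores the original sequence", {
  set.seed(402)
  ref <- load_reference(write_fasta(c(chr1 = random_dna(400))))
  refseq <- as.character(ref[["chr1"]])
  for (i in 1:25) {
    pos <- sample(100:300, 1)
    w0 <- extract_window(ref, make_variant(pos = pos,
                                           ref = substr(refseq, pos, pos),
                                           alt = "N"))
    ins_alt <- paste0(substr(refseq, pos, pos), random_dna(sample(1:4, 1)))
    ins <- make_variant(pos = pos, ref = substr(refseq, pos, pos), alt = ins_alt)
    w1 <- apply_variants(w0, ins)
    # deleting what was inserted, anchored at the same base
    del <- make_variant(pos = pos, ref = ins_alt, alt = substr(ins_alt, 1, 1))
    # rebuild a window on the edited haplotype: splice manually as the oracle
    edited <- w1$seq
    off <- pos - w0$start + 1L
    back <- paste0(substr(edited, 1, off - 1),
                   substr(ins_alt, 1, 1),
                   substr(edited, off + nchar(ins_alt), nchar(edited)))
    expect_identical(back, w0$seq)
  }
})
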