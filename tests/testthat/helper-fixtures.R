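# Shared fixture builders: everything is generated in code at test time.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(mapply(function(nm, s) c(paste0(">", nm), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Minimal hand-rolled VCF text, independent of the package's writer.
write_vcf_text <- function(records, path = tempfile(fileext = ".vcf"),
                           sample = "S1", format_rows = NULL,
                           extra_header = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=AF,Number=1,Type=Float,Description="AF">',
           '##INFO=<ID=CSQ,Number=1,Type=String,Description="CSQ">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# A variant-table row in the package's normalized layout.
make_variant <- function(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                         sample = "S1", origin = "SOMATIC", dp = NA_integer_,
                         ad_alt = NA_integer_, af_pop = NA_real_,
                         consequence = NA_character_, rsid = NA_character_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample = sample, vclass = variant_class(ref, alt),
             origin = origin, dp = dp, ad_alt = ad_alt, af_pop = af_pop,
             consequence = consequence, rsid = rsid, stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Tiny synthetic study shared by pipeline-level tests (built once per run).
tiny_synth_config <- function(seed = 11L, ...) {
  synth_config(
    n_contigs = 1L, contig_length = 30000L,
    n_strong_motifs = 8L, n_weak_motifs = 8L,
    samples = data.frame(
      id = c("A", "B", "C"),
      n_somatic = c(60L, 50L, 40L),
      g4_enrichment = c(0.6, 0, 0),
      g4_weak_enrichment = c(0, 0, 0),
      stringsAsFactors = FALSE),
    group = c("A", "B"),
    n_group_snps = 5L, n_group_low_af = 3L, n_background_snps = 30L,
    seed = seed, ...)
}
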