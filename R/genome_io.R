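#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-contig) FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing all bases. `N` is preserved; any other non-ACGTN character is an
#' error naming the offending contig and position.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `DNAStringSet` keyed by contig name.
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  validate_fasta_alphabet(fasta_path)
  ref <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ref) == 0L) {
    stop("empty FASTA: ", fasta_path)
  }
  # keep only the first whitespace-delimited token of each header
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(names(ref))) {
    dup <- names(ref)[duplicated(names(ref))][1L]
    stop("duplicate contig name in FASTA: ", dup)
  }
  Biostrings::DNAStringSet(toupper(as.character(ref)))
}

# Biostrings drops invalid one-letter codes with only a warning; scan the raw
# text so a corrupt reference fails loudly with contig and position.
validate_fasta_alphabet <- function(fasta_path) {
  lines <- readLines(fasta_path)
  contig <- NA_character_
  offset <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      contig <- sub("\\s.*$", "", substring(ln, 2L))
      offset <- 0L
      next
    }
    bad <- regexpr("[^ACGTNacgtn]", ln)
    if (bad > 0L) {
      stop(sprintf("non-ACGTN character '%s' in contig %s at position %d",
                   substr(ln, bad, bad), contig, offset + bad))
    }
    offset <- offset + nchar(ln)
  }
  invisible(fasta_path)
}

#' Read a capture panel from BED
#'
#' Reads a BED3+ file, converts to 1-based closed coordinates, sorts by
#' (contig, start) and merges overlapping or book-ended intervals.
#'
#' @param bed_path Path to a BED file (0-based half-open rows).
#' @return A sorted, reduced [GenomicRanges::GRanges].
#' @export
read_panel <- function(bed_path) {
  if (!file.exists(bed_path)) stop("panel BED not found: ", bed_path)
  raw <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = list(V1 = "character"))
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", bed_path)
  bad <- which(raw[[2]] >= raw[[3]])
  if (length(bad)) {
    stop(sprintf("invalid BED interval (start >= end) at line %d of %s",
                 bad[1L], bed_path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = raw[[1]],
    ranges = IRanges::IRanges(start = raw[[2]] + 1L, end = raw[[3]])
  )
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::reduce(sort(gr))
}

#' Write a panel back to BED
#'
#' @param panel A `GRanges` of panel intervals.
#' @param bed_path Output path.
#' @return `bed_path`, invisibly.
#' @export
write_panel <- function(panel, bed_path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(panel)),
    start = GenomicRanges::start(panel) - 1L,
    end = GenomicRanges::end(panel)
  )
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

#' Derive the variant class from allele lengths
#'
#' Equal length 1 is an SNV, equal length >1 an MNV, longer alt an insertion,
#' otherwise a deletion.
#'
#' @param ref,alt Allele strings.
#' @return Character vector over `c("SNV","MNV","INS","DEL")`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la & lr == 1L, "SNV",
    ifelse(lr == la, "MNV",
      ifelse(la > lr, "INS", "DEL")))
}

#' Read variants from a VCF into a normalized table
#'
#' Parses a VCF 4.x file with [vcfR::read.vcfR] and returns one row per
#' (record, alt allele); multiallelic records are split. Per-sample `DP` and
#' alt-allele `AD` are taken from the FORMAT fields when present, a population
#' allele frequency from the INFO field named by `af_field`, and a consequence
#' label from the INFO field named by `csq_field`. Records with a FILTER other
#' than `PASS` or `.` are excluded unless `keep_nonpass = TRUE`.
#'
#' @param vcf_path Path to a VCF file.
#' @param sample Sample identifier to attribute variants to. When the VCF has
#'   genotype columns the column of this name is used for DP/AD; otherwise the
#'   label is attached as-is.
#' @param origin `"SOMATIC"` or `"GERMLINE"`.
#' @param keep_nonpass Keep records failing FILTER? Default `FALSE`.
#' @param af_field INFO key holding the population allele frequency
#'   (default `"AF"`).
#' @param csq_field INFO key holding a consequence label (default `"CSQ"`).
#' @return A data.frame with columns `chrom, pos, ref, alt, sample, vclass,
#'   origin, dp, ad_alt, af_pop, consequence, rsid`.
#' @export
read_variants <- function(vcf_path, sample, origin = c("SOMATIC", "GERMLINE"),
                          keep_nonpass = FALSE,
                          af_field = "AF", csq_field = "CSQ") {
  origin <- match.arg(origin)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_variant_table(sample, origin))
  }
  keep <- rep(TRUE, nrow(fix))
  if (!keep_nonpass) {
    filt <- fix$FILTER
    keep <- is.na(filt) | filt == "PASS" | filt == "."
  }
  dp <- rep(NA_integer_, nrow(fix))
  ad_alt_raw <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) > 1L) {
    samples_in_vcf <- colnames(v@gt)[-1L]
    col <- if (sample %in% samples_in_vcf) sample else samples_in_vcf[1L]
    dpm <- try(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
               silent = TRUE)
    if (!inherits(dpm, "try-error") && col %in% colnames(dpm)) {
      dp <- as.integer(dpm[, col])
    }
    adm <- try(vcfR::extract.gt(v, element = "AD"), silent = TRUE)
    if (!inherits(adm, "try-error") && col %in% colnames(adm)) {
      ad_alt_raw <- adm[, col]
    }
  }
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  af <- suppressWarnings(as.numeric(info_field(af_field)))
  csq <- info_field(csq_field)

  rows <- lapply(which(keep), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    # AD is REF followed by one depth per alt allele
    ad_parts <- if (!is.na(ad_alt_raw[i])) {
      suppressWarnings(as.integer(strsplit(ad_alt_raw[i], ",")[[1L]]))
    } else NULL
    data.frame(
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      sample = sample,
      origin = origin,
      dp = dp[i],
      ad_alt = if (is.null(ad_parts)) NA_integer_ else {
        a <- ad_parts[seq_along(alts) + 1L]
        if (length(a) < length(alts)) a <- c(a, rep(NA_integer_, length(alts) - length(a)))
        a
      },
      af_pop = af[i],
      consequence = csq[i],
      rsid = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", NA_character_, fix$ID[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_variant_table(sample, origin))
  bad <- which(out$ref == out$alt | nchar(out$ref) == 0L | nchar(out$alt) == 0L)
  if (length(bad)) {
    stop(sprintf("malformed record in %s: %s:%d %s>%s", vcf_path,
                 out$chrom[bad[1L]], out$pos[bad[1L]],
                 out$ref[bad[1L]], out$alt[bad[1L]]))
  }
  out$vclass <- variant_class(out$ref, out$alt)
  rownames(out) <- NULL
  out[, variant_columns()]
}

variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "sample", "vclass", "origin",
    "dp", "ad_alt", "af_pop", "consequence", "rsid")
}

empty_variant_table <- function(sample = character(), origin = character()) {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample = character(), vclass = character(),
             origin = character(), dp = integer(), ad_alt = integer(),
             af_pop = numeric(), consequence = character(),
             rsid = character(), stringsAsFactors = FALSE)
}

#' Filter germline variants on read depth and alt-allele depth
#'
#' Keeps variants with `dp > min_dp` and `ad_alt > min_ad` (both strict).
#' Variants lacking either field are dropped and tallied as unscored in the
#' attached report.
#'
#' @param variants Variant table as from [read_variants()].
#' @param min_dp Read-depth threshold (strictly exceeded; default 10).
#' @param min_ad Alt-allele-depth threshold (strictly exceeded; default 5).
#' @return The filtered table, with a `germline_filter_report` attribute
#'   listing `n_in`, `n_kept`, `n_failed` and `n_unscored`.
#' @export
filter_germline <- function(variants, min_dp = 10L, min_ad = 5L) {
  stopifnot(min_dp >= 0, min_ad >= 0)
  unscored <- is.na(variants$dp) | is.na(variants$ad_alt)
  pass <- !unscored & variants$dp > min_dp & variants$ad_alt > min_ad
  out <- variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "germline_filter_report") <- list(
    n_in = nrow(variants),
    n_kept = sum(pass),
    n_failed = sum(!pass & !unscored),
    n_unscored = sum(unscored)
  )
  out
}

#' Extract the sequence window around a variant
#'
#' For an SNV at 1-based position `p` the window covers
#' `[p - flank, p + flank]` (1-based closed), a nominal `2*flank + 1` bases;
#' for longer reference alleles the anchor span is `nchar(ref)` bases starting
#' at `p`, giving `2*flank + nchar(ref)`. Windows running off a contig end are
#' clipped and the clipped lengths recorded, never an error.
#'
#' @param reference A `DNAStringSet` from [load_reference()].
#' @param variants One-or-more-row variant table.
#' @param flank Flank length in nt (default 70).
#' @return A data.frame with one row per variant: `chrom, start, end, seq,
#'   flank, clipped_left, clipped_right` plus the variant columns, and an
#'   `applied_edits` character column (empty; see [apply_variants()]).
#' @export
extract_windows <- function(reference, variants, flank = 70L) {
  missing_contig <- setdiff(unique(variants$chrom), names(reference))
  if (length(missing_contig)) {
    stop("contig absent from reference: ", missing_contig[1L])
  }
  clen <- stats::setNames(Biostrings::width(reference), names(reference))
  anchor_len <- nchar(variants$ref)
  want_start <- variants$pos - flank
  want_end <- variants$pos + anchor_len - 1L + flank
  start <- pmax(want_start, 1L)
  end <- pmin(want_end, clen[variants$chrom])
  seqs <- as.character(Biostrings::subseq(
    reference[variants$chrom], start = start, end = end))
  out <- variants
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  out$seq <- unname(seqs)
  out$flank <- as.integer(flank)
  out$clipped_left <- as.integer(start - want_start)
  out$clipped_right <- as.integer(want_end - end)
  out$applied_edits <- ""
  rownames(out) <- NULL
  out
}

#' @rdname extract_windows
#' @param variant A single-row variant table.
#' @export
extract_window <- function(reference, variant, flank = 70L) {
  extract_windows(reference, variant[1L, , drop = FALSE], flank = flank)
}

#' Apply variants to a window sequence
#'
#' Splices each edit into the window sequence. Edits are applied right-to-left
#' so earlier coordinates never shift. Edits whose reference allele does not
#' match the window, or that overlap one another, are errors; edits falling
#' outside the window interval are skipped and reported via the
#' `skipped_edits` attribute.
#'
#' @param window A single-row window as from [extract_windows()].
#' @param edits Variant table of edits (typically germline) to apply.
#' @return The window row with `seq` modified and `applied_edits` holding a
#'   semicolon-separated list of `chrom:pos:ref>alt` keys.
#' @export
apply_variants <- function(window, edits) {
  stopifnot(nrow(window) == 1L)
  if (is.null(edits) || nrow(edits) == 0L) return(window)
  inside <- edits$chrom == window$chrom &
    edits$pos >= window$start &
    (edits$pos + nchar(edits$ref) - 1L) <= window$end
  skipped <- edits[!inside, , drop = FALSE]
  edits <- edits[inside, , drop = FALSE]
  if (nrow(edits) > 1L) {
    o <- order(edits$pos)
    edits <- edits[o, , drop = FALSE]
    e_end <- edits$pos + nchar(edits$ref) - 1L
    if (any(edits$pos[-1L] <= e_end[-nrow(edits)])) {
      stop("overlapping edits in window at ", window$chrom, ":", window$start)
    }
  }
  s <- window$seq
  for (i in rev(seq_len(nrow(edits)))) {
    off <- edits$pos[i] - window$start + 1L  # 1-based offset into seq
    rlen <- nchar(edits$ref[i])
    have <- substr(s, off, off + rlen - 1L)
    if (have != edits$ref[i]) {
      stop(sprintf("edit ref mismatch at %s:%d: window has '%s', edit ref '%s'",
                   edits$chrom[i], edits$pos[i], have, edits$ref[i]))
    }
    s <- paste0(substr(s, 1L, off - 1L), edits$alt[i],
                substr(s, off + rlen, nchar(s)))
  }
  window$seq <- s
  keys <- sprintf("%s:%d:%s>%s", edits$chrom, edits$pos, edits$ref, edits$alt)
  window$applied_edits <- paste(
    c(if (nzchar(window$applied_edits)) window$applied_edits, keys),
    collapse = ";")
  attr(window, "skipped_edits") <- nrow(skipped)
  window
}

#' Apply per-sample germline edits to a set of windows
#'
#' Convenience wrapper over [apply_variants()]: for each window, applies the
#' subset of `edits` that falls fully inside it.
#'
#' @param windows Window table from [extract_windows()].
#' @param edits Germline variant table for the same sample.
#' @return The window table with edited sequences.
#' @export
apply_germline <- function(windows, edits) {
  if (is.null(edits) || nrow(edits) == 0L || nrow(windows) == 0L) return(windows)
  for (i in seq_len(nrow(windows))) {
    w <- apply_variants(windows[i, , drop = FALSE], edits)
    windows$seq[i] <- w$seq
    windows$applied_edits[i] <- w$applied_edits
  }
  windows
}
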