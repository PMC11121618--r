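#' Configuration for a synthetic G4 study
#'
#' Defaults emulate the design of an 11-patient tumor-exome study: per-sample
#' somatic-mutation counts matching the published per-patient totals, three
#' samples with a strong planted G4-proximity enrichment, one with a moderate
#' one, group-exclusive germline SNPs (15 keys, 8 of them with population
#' frequency below 0.1) restricted to the enriched samples, and germline DP/AD
#' fields spanning the depth filter so the filter is exercised.
#'
#' @param n_contigs Number of contigs (default 2).
#' @param contig_length Length of each contig in nt (default 1e5).
#' @param gc_background Background GC fraction (default 0.45).
#' @param n_strong_motifs,n_weak_motifs Planted motifs per contig
#'   (default 25 each).
#' @param panel_fraction Fraction of the genome covered by the capture panel
#'   (default 0.5).
#' @param samples data.frame with `id`, `n_somatic`, `g4_enrichment` (fraction
#'   of somatic sites forced within 70 nt of a planted strong motif) and
#'   optionally `g4_weak_enrichment` (same, for weak motifs; default 0).
#' @param indel_fraction Fraction of somatic calls emitted as small indels
#'   (default 0.05).
#' @param motif_exclusion Minimum distance (nt) of background somatic sites
#'   from any planted motif (default 200; set 0 for placement uniform over the
#'   panel, i.e. the same generator as the random controls).
#' @param group Character vector of sample ids carrying the group-exclusive
#'   germline SNPs.
#' @param n_group_snps Total group-exclusive SNPs (default 15).
#' @param n_group_low_af How many of those have `af_pop < 0.1` (default 8).
#' @param n_background_snps Shared background germline SNPs (default 200).
#' @param flank Analysis flank in nt (default 70).
#' @param seed Master seed; every output derives a private substream from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_contigs = 2L,
                         contig_length = 100000L,
                         gc_background = 0.45,
                         n_strong_motifs = 25L,
                         n_weak_motifs = 25L,
                         panel_fraction = 0.5,
                         samples = default_synth_samples(),
                         indel_fraction = 0.05,
                         motif_exclusion = 200L,
                         group = c("S12", "P23", "P37"),
                         n_group_snps = 15L,
                         n_group_low_af = 8L,
                         n_background_snps = 200L,
                         flank = 70L,
                         seed = 1L) {
  stopifnot(gc_background >= 0, gc_background <= 1,
            all(samples$g4_enrichment >= 0), all(samples$g4_enrichment <= 1),
            motif_exclusion >= 0,
            panel_fraction > 0, panel_fraction <= 1,
            all(group %in% samples$id),
            n_group_low_af <= n_group_snps)
  structure(list(n_contigs = n_contigs, contig_length = contig_length,
                 gc_background = gc_background,
                 n_strong_motifs = n_strong_motifs,
                 n_weak_motifs = n_weak_motifs,
                 panel_fraction = panel_fraction, samples = samples,
                 indel_fraction = indel_fraction,
                 motif_exclusion = as.integer(motif_exclusion), group = group,
                 n_group_snps = n_group_snps,
                 n_group_low_af = n_group_low_af,
                 n_background_snps = n_background_snps,
                 flank = flank, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default synthetic sample sheet
#'
#' Eleven samples with the published per-patient somatic totals; the three
#' G4-strong samples get a planted enrichment of 0.6, the combined
#' weak-plus-strong sample 0.3, the rest 0.
#'
#' @return data.frame with `id`, `n_somatic`, `g4_enrichment`.
#' @export
default_synth_samples <- function() {
  data.frame(
    id = c("S7", "S12", "P1", "P14", "P20", "P22",
           "P23", "P30", "P34", "P37", "P48"),
    n_somatic = c(115L, 63L, 87L, 234L, 182L, 191L,
                  119L, 662L, 267L, 82L, 227L),
    g4_enrichment = c(0, 0.6, 0, 0, 0, 0, 0.6, 0, 0, 0.6, 0),
    g4_weak_enrichment = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.45),
    stringsAsFactors = FALSE
  )
}

# Independent per-purpose RNG substreams off the master seed (kept < 2^31).
substream_seed <- function(seed, purpose, index = 0L) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + index * 31) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

random_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

# One planted motif sequence: four runs with random 1-10 nt loops.
random_motif_seq <- function(strength, gc) {
  run_len <- if (strength == "STRONG") sample(3:4, 4L, replace = TRUE)
             else rep(2L, 4L)
  base <- if (stats::runif(1) < 0.5) "G" else "C"
  parts <- character(7L)
  parts[c(1, 3, 5, 7)] <- strrep(base, run_len)
  for (j in c(2, 4, 6)) {
    parts[j] <- paste0(random_bases(sample(1:10, 1L), gc), collapse = "")
  }
  paste0(parts, collapse = "")
}

#' Generate a synthetic reference with planted G4 motifs and a capture panel
#'
#' Background bases are i.i.d. at the configured GC; the panel tiles each
#' contig in 2 kb chunks with a random subset kept at `panel_fraction`;
#' strong and weak motifs are spliced inside panel intervals, pairwise
#' separated by at least 300 nt. Every planted locus is re-checked with
#' [classify_window()] before being accepted (a weak plant that accidentally
#' forms a strong match is re-drawn).
#'
#' @param config A [synth_config()].
#' @return List: `reference` (`DNAStringSet`), `panel` (`GRanges`),
#'   `motifs` (data.frame `chrom, start, end, strength`, 1-based closed).
#' @export
generate_reference <- function(config) {
  with_seed(substream_seed(config$seed, "reference"), {
    contigs <- sprintf("chr%d", seq_len(config$n_contigs))
    seqs <- character(config$n_contigs)
    motif_rows <- list()
    panel_rows <- list()
    chunk <- 2000L
    for (ci in seq_along(contigs)) {
      s <- random_bases(config$contig_length, config$gc_background)
      # panel: keep a random panel_fraction of 2 kb tiles
      n_tiles <- config$contig_length %/% chunk
      keep <- sort(sample.int(n_tiles, max(1L, round(config$panel_fraction * n_tiles))))
      p_start <- (keep - 1L) * chunk + 1L
      p_end <- keep * chunk
      panel_rows[[ci]] <- data.frame(chrom = contigs[ci],
                                     start = p_start, end = p_end)
      # motif placement inside panel tiles, >= 300 nt apart
      want <- c(rep("STRONG", config$n_strong_motifs),
                rep("WEAK", config$n_weak_motifs))
      placed_mid <- numeric(0)
      for (strength in want) {
        ok <- FALSE
        for (try in 1:200) {
          mseq <- random_motif_seq(strength, config$gc_background)
          L <- nchar(mseq)
          tile <- sample(seq_along(keep), 1L)
          pos <- p_start[tile] + sample.int(chunk - L, 1L) - 1L
          mid <- pos + L / 2
          if (length(placed_mid) && min(abs(placed_mid - mid)) < 300) next
          cand <- s
          cand[pos:(pos + L - 1L)] <- strsplit(mseq, "")[[1L]]
          locus <- paste0(cand[pos:(pos + L - 1L)], collapse = "")
          if (classify_window(locus) != strength) next
          s <- cand
          placed_mid <- c(placed_mid, mid)
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            chrom = contigs[ci], start = pos, end = pos + L - 1L,
            strength = strength, stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place a ", strength,
                      " motif without overlap after bounded retries")
      }
      seqs[ci] <- paste0(s, collapse = "")
    }
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- contigs
    pdf <- do.call(rbind, panel_rows)
    panel <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = pdf$chrom,
      ranges = IRanges::IRanges(start = pdf$start, end = pdf$end)))
    motifs <- do.call(rbind, motif_rows)
    rownames(motifs) <- NULL
    list(reference = reference, panel = panel, motifs = motifs)
  })
}

positions_in_panel <- function(panel, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  S4Vectors::countQueryHits(GenomicRanges::findOverlaps(q, panel)) > 0L
}

synth_consequences <- function() {
  c("5_prime_UTR_variant", "3_prime_UTR_variant", "intron_variant",
    "missense_variant", "synonymous_variant", "upstream_gene_variant")
}

#' Generate somatic variants for one synthetic sample
#'
#' `round(f * n_somatic)` sites are placed uniformly within 70 nt of a
#' uniformly chosen planted strong motif (restricted to panel bases); the rest
#' uniformly over panel bases at least 200 nt from any planted motif. A
#' configurable fraction of calls are emitted as 1-3 nt indels, the rest as
#' SNVs with the alternate base uniform over the three non-reference bases.
#' Each variant carries a consequence label drawn from a small VEP-style
#' vocabulary.
#'
#' @param config A [synth_config()].
#' @param sample_id Sample to generate (a row of `config$samples`).
#' @param ref_obj Result of [generate_reference()] for the same config.
#' @return Variant table with an extra column `near_motif` — the placement
#'   truth, `"STRONG"`, `"WEAK"` or `"NONE"`.
#' @export
generate_somatic <- function(config, sample_id, ref_obj) {
  row <- config$samples[config$samples$id == sample_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown sample: ", sample_id)
  with_seed(substream_seed(config$seed, "somatic",
                           match(sample_id, config$samples$id)), {
    n <- row$n_somatic
    n_near_strong <- round(row$g4_enrichment * n)
    weak_f <- if ("g4_weak_enrichment" %in% names(row)) row$g4_weak_enrichment else 0
    n_near_weak <- round(weak_f * n)
    if (n_near_strong + n_near_weak > n) stop("enrichment fractions exceed 1")
    contig_len <- stats::setNames(Biostrings::width(ref_obj$reference),
                                  names(ref_obj$reference))
    draw_near <- function(n_want, strength) {
      motifs <- ref_obj$motifs[ref_obj$motifs$strength == strength, , drop = FALSE]
      if (nrow(motifs) == 0L) stop("no planted ", strength, " motifs")
      out <- NULL
      while (is.null(out) || nrow(out) < n_want) {
        mi <- sample.int(nrow(motifs), 3L * n_want, replace = TRUE)
        lo <- pmax(1L, motifs$start[mi] - config$flank)
        hi <- pmin(motifs$end[mi] + config$flank, contig_len[motifs$chrom[mi]])
        pos <- lo + as.integer(floor(stats::runif(length(mi)) * (hi - lo + 1L)))
        keep <- positions_in_panel(ref_obj$panel, motifs$chrom[mi], pos)
        out <- rbind(out, data.frame(chrom = motifs$chrom[mi][keep],
                                     pos = pos[keep],
                                     stringsAsFactors = FALSE))
      }
      out[seq_len(n_want), , drop = FALSE]
    }
    excl <- config$motif_exclusion %||% 200L
    motif_gr <- GenomicRanges::GRanges(
      ref_obj$motifs$chrom,
      IRanges::IRanges(pmax(1L, ref_obj$motifs$start - excl),
                       ref_obj$motifs$end + excl))
    draw_far <- function(n_want) {
      out <- NULL
      while (is.null(out) || nrow(out) < n_want) {
        p <- sample_panel_positions(ref_obj$panel, 3L * n_want)
        if (excl > 0L) {
          q <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos, p$pos))
          keep <- S4Vectors::countQueryHits(
            GenomicRanges::findOverlaps(q, motif_gr)) == 0L
          p <- p[keep, , drop = FALSE]
        }
        out <- rbind(out, p)
      }
      out[seq_len(n_want), , drop = FALSE]
    }
    # over-draw, dedupe on position, refill until n unique sites
    sites <- NULL
    repeat {
      ns <- rbind(
        if (n_near_strong > 0L) cbind(draw_near(n_near_strong, "STRONG"),
                                      near_motif = "STRONG"),
        if (n_near_weak > 0L) cbind(draw_near(n_near_weak, "WEAK"),
                                    near_motif = "WEAK"),
        cbind(draw_far(n - n_near_strong - n_near_weak), near_motif = "NONE"))
      sites <- if (is.null(sites)) ns else rbind(sites, ns)
      dup <- duplicated(paste0(sites$chrom, ":", sites$pos))
      sites <- sites[!dup, , drop = FALSE]
      have <- table(factor(sites$near_motif, c("STRONG", "WEAK", "NONE")))
      want <- c(STRONG = n_near_strong, WEAK = n_near_weak,
                NONE = n - n_near_strong - n_near_weak)
      if (all(have >= want)) {
        keep <- unlist(lapply(names(want), function(k)
          which(sites$near_motif == k)[seq_len(want[[k]])]))
        sites <- sites[sort(keep), , drop = FALSE]
        break
      }
    }
    contig_seq <- lapply(ref_obj$reference, as.character)
    base_at <- function(chrom, pos, len = 1L) {
      substr(contig_seq[[chrom]], pos, pos + len - 1L)
    }
    is_indel <- stats::runif(n) < config$indel_fraction
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      if (!is_indel[i]) {
        r <- base_at(sites$chrom[i], sites$pos[i])
        ref[i] <- r
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      } else if (stats::runif(1) < 0.5) {  # insertion
        r <- base_at(sites$chrom[i], sites$pos[i])
        ref[i] <- r
        alt[i] <- paste0(r, paste0(random_bases(sample(1:3, 1L),
                                                config$gc_background),
                                   collapse = ""))
      } else {                              # deletion
        dlen <- sample(1:3, 1L)
        r <- base_at(sites$chrom[i], sites$pos[i], dlen + 1L)
        ref[i] <- r
        alt[i] <- substr(r, 1L, 1L)
      }
    }
    out <- data.frame(
      chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
      sample = sample_id, vclass = variant_class(ref, alt),
      origin = "SOMATIC", dp = NA_integer_, ad_alt = NA_integer_,
      af_pop = NA_real_,
      consequence = sample(synth_consequences(), n, replace = TRUE),
      rsid = NA_character_, near_motif = sites$near_motif,
      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate the cohort's germline variants
#'
#' Builds one shared catalogue: `n_group_snps` keys written to exactly the
#' group samples (of which `n_group_low_af` get `af_pop` below 0.1, the rest
#' above), and `n_background_snps` keys each carried by a random subset of all
#' samples. Group SNPs get depths that always pass the DP/AD filter; the
#' background depth range deliberately straddles the filter thresholds.
#'
#' @param config A [synth_config()].
#' @param ref_obj Result of [generate_reference()].
#' @return Named list (sample id -> variant table). The truth catalogue is
#'   attached as attribute `catalogue`.
#' @export
generate_germline <- function(config, ref_obj) {
  with_seed(substream_seed(config$seed, "germline"), {
    contig_seq <- lapply(ref_obj$reference, as.character)
    n_cat <- config$n_group_snps + config$n_background_snps
    pos <- sample_panel_positions(ref_obj$panel, 4L * n_cat)
    pos <- pos[!duplicated(paste0(pos$chrom, ":", pos$pos)), ][seq_len(n_cat), ]
    ref <- mapply(function(ch, p) substr(contig_seq[[ch]], p, p),
                  pos$chrom, pos$pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1L))
    is_group <- seq_len(n_cat) <= config$n_group_snps
    af <- numeric(n_cat)
    af[is_group] <- c(stats::runif(config$n_group_low_af, 0.01, 0.09),
                      stats::runif(config$n_group_snps - config$n_group_low_af,
                                   0.15, 0.5))
    af[!is_group] <- stats::runif(sum(!is_group), 0.05, 0.6)
    catalogue <- data.frame(
      chrom = pos$chrom, pos = pos$pos, ref = unname(ref), alt = unname(alt),
      af_pop = round(af, 4), group_only = is_group,
      rsid = sprintf("rs%06d", seq_len(n_cat) + 100000L),
      stringsAsFactors = FALSE)
    samples <- config$samples$id
    carrier <- matrix(FALSE, n_cat, length(samples),
                      dimnames = list(NULL, samples))
    carrier[is_group, samples %in% config$group] <- TRUE
    bg <- which(!is_group)
    carrier[bg, ] <- matrix(stats::runif(length(bg) * length(samples)) < 0.4,
                            length(bg), length(samples))
    # a background SNP carried by everyone-in-group-and-nobody-else would fake
    # a group-exclusive hit; re-draw such rows
    grp_mask <- samples %in% config$group
    for (i in bg) {
      while (all(carrier[i, grp_mask]) && !any(carrier[i, !grp_mask])) {
        carrier[i, ] <- stats::runif(length(samples)) < 0.4
      }
    }
    out <- lapply(samples, function(sid) {
      idx <- which(carrier[, sid])
      if (length(idx) == 0L) return(empty_variant_table())
      grp <- catalogue$group_only[idx]
      dp <- integer(length(idx))
      dp[grp] <- sample(30:60, sum(grp), replace = TRUE)
      dp[!grp] <- sample(5:60, sum(!grp), replace = TRUE)
      ad <- vapply(dp, function(d) {
        a <- stats::rbinom(1L, d, 0.5)
        max(1L, a)
      }, integer(1L))
      ad[grp] <- pmax(ad[grp], 6L)
      df <- data.frame(
        chrom = catalogue$chrom[idx], pos = catalogue$pos[idx],
        ref = catalogue$ref[idx], alt = catalogue$alt[idx],
        sample = sid, vclass = "SNV", origin = "GERMLINE",
        dp = dp, ad_alt = ad, af_pop = catalogue$af_pop[idx],
        consequence = NA_character_, rsid = catalogue$rsid[idx],
        stringsAsFactors = FALSE)
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      rownames(df) <- NULL
      df
    })
    names(out) <- samples
    attr(out, "catalogue") <- catalogue
    out
  })
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Emits a plain-text single-sample VCF with `AF` and `CSQ` INFO fields and
#' `GT:DP:AD` genotype fields when depths are present. The output is read back
#' by [read_variants()].
#'
#' @param variants Variant table.
#' @param path Output path.
#' @param reference Optional `DNAStringSet` for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_simple_vcf <- function(variants, path, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=g4context-synth")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), Biostrings::width(reference)))
  }
  hdr <- c(hdr,
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence label">',
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  sample_name <- if (nrow(variants)) variants$sample[1L] else "SAMPLE"
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample_name), collapse = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    info <- mapply(function(af, csq) {
      parts <- character(0)
      if (!is.na(af)) parts <- c(parts, sprintf("AF=%s", format(af, scientific = FALSE)))
      if (!is.na(csq)) parts <- c(parts, paste0("CSQ=", csq))
      if (length(parts) == 0L) "." else paste(parts, collapse = ";")
    }, variants$af_pop, variants$consequence)
    has_depth <- !is.na(variants$dp) & !is.na(variants$ad_alt)
    gt <- ifelse(has_depth,
                 sprintf("0/1:%d:%d,%d", variants$dp,
                         pmax(variants$dp - variants$ad_alt, 0L),
                         variants$ad_alt),
                 "0/1")
    fmt <- ifelse(has_depth, "GT:DP:AD", "GT")
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\t%s\t%s",
                    variants$chrom, variants$pos,
                    ifelse(is.na(variants$rsid), ".", variants$rsid),
                    variants$ref, variants$alt, info, fmt, gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate and write a complete synthetic study
#'
#' Writes `reference.fa`, `panel.bed`, `truth_motifs.bed`,
#' `truth_somatic.tsv`, `germline_catalogue.tsv` and per-sample
#' `<id>.somatic.vcf` / `<id>.germline.vcf` under `dir`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
generate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_obj <- generate_reference(config)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref_obj$reference, fa)
  bed <- file.path(dir, "panel.bed")
  write_panel(ref_obj$panel, bed)
  utils::write.table(
    data.frame(chrom = ref_obj$motifs$chrom,
               start = ref_obj$motifs$start - 1L,
               end = ref_obj$motifs$end,
               name = ref_obj$motifs$strength),
    file.path(dir, "truth_motifs.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  somatic <- lapply(config$samples$id, function(sid)
    generate_somatic(config, sid, ref_obj))
  names(somatic) <- config$samples$id
  truth <- do.call(rbind, lapply(somatic, function(v)
    v[, c("sample", "chrom", "pos", "ref", "alt", "vclass", "near_motif")]))
  utils::write.table(truth, file.path(dir, "truth_somatic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  germline <- generate_germline(config, ref_obj)
  utils::write.table(attr(germline, "catalogue"),
                     file.path(dir, "germline_catalogue.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list()
  for (sid in config$samples$id) {
    sp <- file.path(dir, paste0(sid, ".somatic.vcf"))
    gp <- file.path(dir, paste0(sid, ".germline.vcf"))
    write_simple_vcf(somatic[[sid]], sp, ref_obj$reference)
    write_simple_vcf(germline[[sid]], gp, ref_obj$reference)
    paths[[sid]] <- list(somatic = sp, germline = gp)
  }
  invisible(list(config = config, reference = ref_obj$reference,
                 panel = ref_obj$panel, motifs = ref_obj$motifs,
                 somatic = somatic, germline = germline,
                 dir = dir, files = paths))
}
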