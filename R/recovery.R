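#' Precompute G4 categories for every panel position
#'
#' Classifies the analysis window anchored at each base of the panel once, so
#' that repeated simulations over the same reference can score tumor and
#' control windows by lookup instead of re-scanning. Pure memoisation of
#' [extract_windows()] + [classify_window()] for SNV-length anchors.
#'
#' @param reference `DNAStringSet`.
#' @param panel `GRanges` of panel intervals.
#' @param flank Flank length in nt (default 70).
#' @param strict_loops See [g4_pattern()].
#' @return A `g4_index` list: `key` (`chrom:pos` strings) and `category`.
#' @export
panel_g4_index <- function(reference, panel, flank = 70L, strict_loops = FALSE) {
  chroms <- rep(as.character(GenomicRanges::seqnames(panel)),
                GenomicRanges::width(panel))
  pos <- unlist(lapply(seq_along(panel), function(i) {
    seq.int(GenomicRanges::start(panel)[i], GenomicRanges::end(panel)[i])
  }))
  clen <- stats::setNames(Biostrings::width(reference), names(reference))
  start <- pmax(pos - flank, 1L)
  end <- pmin(pos + flank, clen[chroms])
  seqs <- as.character(Biostrings::subseq(reference[chroms], start, end))
  structure(list(key = paste0(chroms, ":", pos),
                 category = classify_window(unname(seqs), strict_loops)),
            class = "g4_index")
}

index_lookup <- function(index, chrom, pos) {
  i <- match(paste0(chrom, ":", pos), index$key)
  if (anyNA(i)) stop("position outside the indexed panel")
  index$category[i]
}

#' Simulate enrichment labelling over replicate synthetic samples
#'
#' For each replicate: somatic sites are drawn by [generate_somatic()] for a
#' single sample with planted strong-motif enrichment `f`, a fresh control set
#' of `n_controls` anchors is drawn uniformly from the panel, both are scored
#' against a precomputed [panel_g4_index()], and [evaluate_sample()] assigns
#' the label. With `motif_exclusion = 0` and `f = 0` the somatic generator is
#' distributionally identical to the control draw, which is the null needed
#' for type-I calibration; the default 200 nt exclusion instead yields
#' unambiguous truth labels for power runs.
#'
#' @param ref_obj Result of [generate_reference()].
#' @param index Result of [panel_g4_index()] for the same reference/panel.
#' @param f Planted enrichment fraction in `[0, 1]`.
#' @param n_reps Number of replicate samples.
#' @param n_somatic Somatic sites per replicate (default 100).
#' @param n_controls Control windows per replicate (default 2000).
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed; replicate r uses substream `seed + r`.
#' @param motif_exclusion Background exclusion distance in nt (default 0,
#'   the calibration null; use 200 for truth-labelled power runs).
#' @param flank Flank length (default 70), must match the index.
#' @return Character vector of `n_reps` labels.
#' @export
simulate_enrichment_labels <- function(ref_obj, index, f, n_reps,
                                       n_somatic = 100L, n_controls = 2000L,
                                       alpha = 0.05, seed = 1L,
                                       motif_exclusion = 0L, flank = 70L) {
  vapply(seq_len(n_reps), function(r) {
    cfg_r <- synth_config(
      samples = data.frame(id = "SIM", n_somatic = as.integer(n_somatic),
                           g4_enrichment = f, g4_weak_enrichment = 0,
                           stringsAsFactors = FALSE),
      group = "SIM", indel_fraction = 0,
      motif_exclusion = motif_exclusion, flank = flank,
      seed = substream_seed(seed, "replicate", r))
    som <- generate_somatic(cfg_r, "SIM", ref_obj)
    tumor_cat <- index_lookup(index, som$chrom, som$pos)
    ctrl <- with_seed(substream_seed(seed, "replicate-ctrl", r),
                      sample_panel_positions(ref_obj$panel, n_controls))
    ctrl_cat <- index_lookup(index, ctrl$chrom, ctrl$pos)
    evaluate_sample(tumor_cat, ctrl_cat, alpha = alpha, sample = "SIM")$label
  }, character(1L))
}
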