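#' Draw random control windows from a capture panel
#'
#' Anchors are drawn uniformly over the union of panel bases — an interval is
#' chosen with probability proportional to its length, then a base uniformly
#' within it — with replacement. Each anchor is expanded to a `2*flank + 1`
#' window, clipped at contig edges. Deterministic for a fixed seed.
#'
#' @param reference `DNAStringSet` from [load_reference()].
#' @param panel `GRanges` from [read_panel()].
#' @param n Number of windows (default 2000).
#' @param flank Flank length in nt (default 70).
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @return Window table as from [extract_windows()] (anchor columns
#'   `chrom, pos`, `ref`/`alt` set to the anchor base / `NA`).
#' @export
sample_random_windows <- function(reference, panel, n = 2000L, flank = 70L,
                                  seed = NULL) {
  if (length(panel) == 0L) stop("empty panel")
  if (n <= 0L) stop("n must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  anchors <- sample_panel_positions(panel, n)
  ref_base <- as.character(Biostrings::subseq(
    reference[anchors$chrom], start = anchors$pos, end = anchors$pos))
  v <- empty_variant_table()[rep(1L, 0L), ]
  v <- data.frame(chrom = anchors$chrom, pos = anchors$pos,
                  ref = unname(ref_base), alt = NA_character_,
                  sample = "control", vclass = "SNV", origin = "CONTROL",
                  dp = NA_integer_, ad_alt = NA_integer_, af_pop = NA_real_,
                  consequence = NA_character_, rsid = NA_character_,
                  stringsAsFactors = FALSE)
  extract_windows(reference, v, flank = flank)
}

#' Sample 1-based genomic positions uniformly from a panel
#'
#' @param panel `GRanges`.
#' @param n Number of positions.
#' @return data.frame with `chrom` and `pos` (1-based).
#' @export
sample_panel_positions <- function(panel, n) {
  w <- GenomicRanges::width(panel)
  if (sum(w) < 1L) stop("panel has zero total length")
  iv <- sample.int(length(panel), n, replace = TRUE, prob = w)
  off <- floor(stats::runif(n) * w[iv])  # 0 .. width-1
  data.frame(chrom = as.character(GenomicRanges::seqnames(panel))[iv],
             pos = as.integer(GenomicRanges::start(panel)[iv] + off),
             stringsAsFactors = FALSE)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, `> 0`.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`, both in `[0, 1]`, containing `k/n`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the bounds are exactly 0 / 1 at the extremes; guard against rounding
  lo <- if (k == 0L) 0 else max(0, centre - half)
  hi <- if (k == n) 1 else min(1, centre + half)
  c(lo = lo, hi = hi)
}

#' Chi-square test of independence on a 2x2 context table
#'
#' Pearson chi-square on `[[k1, n1-k1], [k2, n2-k2]]` with 1 degree of
#' freedom, optionally Yates-corrected. Thin wrapper over
#' [stats::chisq.test()].
#'
#' @param k1,n1 Context count and total in the tumor set.
#' @param k2,n2 Context count and total in the control set.
#' @param continuity Apply the Yates continuity correction (default `FALSE`).
#' @return List with `stat`, `p`, `dof`.
#' @export
chi_square_independence <- function(k1, n1, k2, n2, continuity = FALSE) {
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate 2x2 table (zero marginal)")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  list(stat = unname(res$statistic), p = unname(res$p.value),
       dof = unname(res$parameter))
}

#' Pooled two-proportion z-test
#'
#' Pooled-variance z statistic for `k1/n1` vs `k2/n2`, two-sided normal
#' p-value. `z > 0` when the first proportion exceeds the second. When the
#' pooled proportion is 0 or 1 the statistic is undefined; the test returns
#' `stat = 0, p = 1` with `degenerate = TRUE`.
#'
#' @param k1,n1,k2,n2 Successes and trials of the two samples.
#' @return List with `z`, `p`, `degenerate`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(z = 0, p = 1, degenerate = TRUE))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Evaluate one sample's G4-context enrichment against a control set
#'
#' Computes, for the `STRONG` context and for the combined `WEAK_PLUS_STRONG`
#' context, the contingency table against the control, both tests (chi-square
#' without continuity correction, pooled two-proportion z) and Wilson
#' intervals, and assigns the sample label: `G4_STRONG` when the strong
#' context passes both tests at `alpha` with the tumor proportion above the
#' control; else `G4_WEAK_PLUS_STRONG` when the combined context passes the
#' same rule; else `NONE`. Enrichment is one-directional — a significant
#' deficit never labels.
#'
#' @param tumor_categories Character vector of per-window categories for the
#'   sample (from [classify_window()]), or a window table with a `category`
#'   column.
#' @param control_categories Same for the control windows.
#' @param alpha Significance level (default 0.05).
#' @param sample Sample id attached to the result rows.
#' @return List with `results` (two-row data.frame: context, counts,
#'   proportions, Wilson bounds, chi2/z statistics and p-values) and `label`.
#' @export
evaluate_sample <- function(tumor_categories, control_categories,
                            alpha = 0.05, sample = NA_character_) {
  cat_of <- function(x) {
    if (is.data.frame(x)) x$category else x
  }
  tc <- cat_of(tumor_categories)
  cc <- cat_of(control_categories)
  if (length(tc) == 0L || length(cc) == 0L) stop("empty window set")
  one <- function(context) {
    members <- if (context == "STRONG") "STRONG" else c("WEAK", "STRONG")
    k1 <- sum(tc %in% members); n1 <- length(tc)
    k2 <- sum(cc %in% members); n2 <- length(cc)
    chi <- tryCatch(chi_square_independence(k1, n1, k2, n2),
                    error = function(e) list(stat = 0, p = 1, dof = 1))
    zt <- two_proportion_z(k1, n1, k2, n2)
    wt <- wilson_interval(k1, n1)
    wc <- wilson_interval(k2, n2)
    data.frame(sample = sample, context = context,
               k_tumor = k1, n_tumor = n1, k_control = k2, n_control = n2,
               prop_tumor = k1 / n1, prop_control = k2 / n2,
               wilson_tumor_lo = wt[["lo"]], wilson_tumor_hi = wt[["hi"]],
               wilson_control_lo = wc[["lo"]], wilson_control_hi = wc[["hi"]],
               chi2_stat = chi$stat, chi2_p = chi$p,
               z_stat = zt$z, z_p = zt$p,
               stringsAsFactors = FALSE)
  }
  res <- rbind(one("STRONG"), one("WEAK_PLUS_STRONG"))
  passes <- function(row) {
    row$prop_tumor > row$prop_control &&
      row$chi2_p < alpha && row$z_p < alpha
  }
  label <- if (passes(res[1L, ])) "G4_STRONG"
           else if (passes(res[2L, ])) "G4_WEAK_PLUS_STRONG"
           else "NONE"
  res$label <- label
  list(results = res, label = label)
}

#' Group mean mutation counts by enrichment label
#'
#' Pools `NONE` and `G4_WEAK_PLUS_STRONG` samples as the group without G4
#' strong enrichment and reports the arithmetic mean somatic-mutation count
#' per group, alongside a per-sample table.
#'
#' @param labels Named character vector, sample id -> label
#'   (`G4_STRONG`, `G4_WEAK_PLUS_STRONG`, `NONE`).
#' @param mutation_counts Named numeric vector, sample id -> somatic count.
#' @return List with `per_sample` (sample, count, label, group) and
#'   `group_means` (group, n_samples, mean_mutations; `NA` mean for an empty
#'   group).
#' @export
summarize_groups <- function(labels, mutation_counts) {
  ids <- names(labels)
  if (is.null(ids) || !setequal(ids, names(mutation_counts))) {
    stop("labels and mutation_counts must be named by the same samples")
  }
  counts <- mutation_counts[ids]
  group <- ifelse(labels == "G4_STRONG", "G4_strong_enriched",
                  "without_G4_strong_enrichment")
  per_sample <- data.frame(sample = ids, mutation_count = as.numeric(counts),
                           label = unname(labels), group = unname(group),
                           stringsAsFactors = FALSE)
  lvl <- c("G4_strong_enriched", "without_G4_strong_enrichment")
  group_means <- data.frame(
    group = lvl,
    n_samples = vapply(lvl, function(g) sum(group == g), integer(1L)),
    mean_mutations = vapply(lvl, function(g) {
      x <- counts[group == g]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_sample = per_sample, group_means = group_means)
}
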