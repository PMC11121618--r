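#' Variant identity key
#'
#' SNP identity for cohort presence/absence is `(chrom, pos, ref, alt)`;
#' rsid is display-only so unannotated variants participate.
#'
#' @param variants Variant table.
#' @return Character vector of `chrom:pos:ref>alt` keys.
#' @export
variant_key <- function(variants) {
  sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
          variants$ref, variants$alt)
}

#' Germline SNPs exclusive to a sample group
#'
#' Returns the variant keys present in EVERY sample of `group` and in NO
#' sample outside it.
#'
#' @param germline Named list, sample id -> character vector of variant keys
#'   (see [variant_key()]).
#' @param group Character vector of sample ids; non-empty strict subset of
#'   `names(germline)`.
#' @return Character vector of exclusive keys (possibly empty).
#' @export
group_exclusive_snps <- function(germline, group) {
  all_samples <- names(germline)
  if (length(group) == 0L) stop("group is empty")
  if (!all(group %in% all_samples)) {
    stop("group contains unknown samples: ",
         paste(setdiff(group, all_samples), collapse = ", "))
  }
  others <- setdiff(all_samples, group)
  if (length(others) == 0L) stop("group equals the full cohort; complement is empty")
  shared <- Reduce(intersect, germline[group])
  setdiff(shared, unique(unlist(germline[others], use.names = FALSE)))
}

#' Filter SNPs on population allele frequency
#'
#' Keeps variants with `af_pop < max_af` (strict). Variants lacking `af_pop`
#' are routed to the `unknown_af` attribute rather than kept or dropped
#' silently.
#'
#' @param snps Variant table (or any data.frame) with an `af_pop` column.
#' @param max_af Frequency cutoff (default 0.1, exclusive).
#' @return Filtered table with attribute `unknown_af` holding the rows
#'   without a frequency.
#' @export
filter_by_population_frequency <- function(snps, max_af = 0.1) {
  unknown <- is.na(snps$af_pop)
  out <- snps[!unknown & snps$af_pop < max_af, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unknown_af") <- snps[unknown, , drop = FALSE]
  out
}

#' Cohort summary statistics
#'
#' Median and range of age and sex counts/percentages for a per-patient
#' characteristics table.
#'
#' @param table data.frame with at least `sample`, `sex` (`"F"`/`"M"`) and
#'   `age` columns; sample ids unique, ages positive.
#' @return List: `n`, `median_age`, `age_min`, `age_max`, `sex_counts`,
#'   `sex_percent` (to 1 decimal place).
#' @export
cohort_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty cohort table")
  if (anyDuplicated(table$sample)) stop("duplicate sample ids")
  if (any(table$age <= 0)) stop("non-positive age")
  sx <- table(factor(table$sex, levels = c("F", "M")))
  list(
    n = nrow(table),
    median_age = stats::median(table$age),
    age_min = min(table$age),
    age_max = max(table$age),
    sex_counts = c(F = unname(sx[["F"]]), M = unname(sx[["M"]])),
    sex_percent = c(F = round(100 * sx[["F"]] / nrow(table), 1),
                    M = round(100 * sx[["M"]] / nrow(table), 1))
  )
}
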