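#' Bundled myeloma cohort tables
#'
#' The package ships the printed per-patient tables of the 11-patient multiple
#' myeloma exome study that this analysis design mirrors: patient
#' characteristics (sex, age, paraprotein, R-ISS stage, ECOG performance) and
#' the per-tumor somatic mutation totals with each tumor's G4-enrichment
#' call. They serve as worked-example inputs for [cohort_summary()] and
#' [summarize_groups()].
#'
#' @return A data.frame.
#' @export
mm_cohort_table <- function() {
  utils::read.table(system.file("extdata", "mm_cohort.tsv",
                                package = "g4context"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname mm_cohort_table
#' @export
mm_somatic_counts <- function() {
  utils::read.table(system.file("extdata", "mm_somatic_counts.tsv",
                                package = "g4context"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Map a printed enrichment call to the package's label vocabulary
#'
#' `"G4 strong"` becomes `G4_STRONG`, `"G4 weak + G4 strong"` becomes
#' `G4_WEAK_PLUS_STRONG`, anything else `NONE`.
#'
#' @param x Character vector of printed calls.
#' @return Character vector of labels.
#' @export
enrichment_call_to_label <- function(x) {
  ifelse(x == "G4 strong", "G4_STRONG",
    ifelse(grepl("weak", x, ignore.case = TRUE), "G4_WEAK_PLUS_STRONG", "NONE"))
}
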