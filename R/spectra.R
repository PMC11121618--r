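#' The 12 strand-specific substitution types
#'
#' Reference-strand types; complements are NOT merged (C->A and G->T are
#' distinct), matching the strand-specific convention used for the stratified
#' spectra.
#'
#' @return Character vector of the 12 types, e.g. `"C>A"`.
#' @export
substitution_types <- function() {
  bases <- c("A", "C", "G", "T")
  out <- c(outer(bases, bases, function(r, a) paste0(r, ">", a)))
  out[substr(out, 1, 1) != substr(out, 3, 3)]
}

#' Classify a single-base substitution
#'
#' @param ref,alt Single bases in `A,C,G,T`, `ref != alt`. Vectorized.
#' @return Character vector of types like `"C>A"`; no pyrimidine collapsing.
#' @export
classify_substitution <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt & nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(ok)) {
    stop("not a classifiable substitution: ",
         paste0(ref[!ok][1L], ">", alt[!ok][1L]))
  }
  paste0(ref, ">", alt)
}

#' Build stratified mutation spectra
#'
#' One spectrum per (enrichment group, G4 stratum) cell: counts, proportions
#' and the binomial standard deviation of each proportion,
#' `sqrt(p * (1 - p) / n)` with `n` the cell total. Non-SNV variants are
#' excluded and tallied in the `excluded` attribute.
#'
#' @param variants Variant table with `sample, ref, alt, vclass` and a
#'   `category` column (the window's G4 category).
#' @param group_of Named character vector sample -> group
#'   (`"ENRICHED"` / `"NOT_ENRICHED"`, or any labels).
#' @return Long-format data.frame: `group, stratum, type, count, proportion,
#'   sd`. Cells with zero total have `NA` proportions and are flagged via the
#'   `empty_cells` attribute.
#' @export
build_spectra <- function(variants, group_of) {
  snv <- variants[variants$vclass == "SNV", , drop = FALSE]
  n_excluded <- nrow(variants) - nrow(snv)
  if (nrow(snv) > 0L && !all(snv$sample %in% names(group_of))) {
    stop("every sample needs a group in group_of")
  }
  types <- substitution_types()
  groups <- sort(unique(unname(group_of)))
  strata <- g4_levels()
  rows <- list()
  for (g in groups) {
    for (st in strata) {
      cell <- snv[group_of[snv$sample] == g & snv$category == st, , drop = FALSE]
      n <- nrow(cell)
      cnt <- if (n > 0L) {
        table(factor(classify_substitution(cell$ref, cell$alt), levels = types))
      } else {
        table(factor(character(), levels = types))
      }
      p <- if (n > 0L) as.numeric(cnt) / n else rep(NA_real_, length(types))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, stratum = st, type = types,
        count = as.integer(cnt),
        proportion = p,
        sd = if (n > 0L) sqrt(p * (1 - p) / n) else rep(NA_real_, length(types)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cell_tot <- stats::aggregate(count ~ group + stratum, out, sum)
  attr(out, "empty_cells") <- cell_tot[cell_tot$count == 0L, c("group", "stratum")]
  attr(out, "excluded_non_snv") <- n_excluded
  out
}

#' Tabulate consequence labels by G4 category
#'
#' Counts of each consequence label within each G4 category, with
#' within-category proportions. Labels are passed through verbatim; variants
#' without a label are bucketed as `"unannotated"`.
#'
#' @param variants Variant table with `consequence` and `category` columns.
#' @return data.frame `category, consequence, count, proportion`.
#' @export
consequence_by_g4 <- function(variants) {
  if (nrow(variants) == 0L) {
    return(data.frame(category = character(), consequence = character(),
                      count = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE))
  }
  csq <- variants$consequence
  csq[is.na(csq) | csq == ""] <- "unannotated"
  tab <- as.data.frame(table(category = variants$category, consequence = csq),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  tot <- stats::ave(tab$count, tab$category, FUN = sum)
  tab$proportion <- tab$count / tot
  tab <- tab[order(tab$category, -tab$count, tab$consequence), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
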