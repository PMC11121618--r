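#!/usr/bin/env Rscript
# Downstream characterization from the enrichment report: strand-specific
# substitution spectra stratified by enrichment group and G4 category,
# somatic mutations that flip the predicted G4 category of their window,
# and the consequence-label distribution by G4 context.

report <- "results/report"
if (!dir.exists(report)) stop("run analysis/02_enrichment.R first")
tsv <- function(f) utils::read.table(file.path(report, f), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)

spectra <- tsv("spectra_by_group_stratum.tsv")
strong_cells <- spectra[spectra$stratum == "STRONG" & spectra$count > 0, ]
cat("Substitution spectrum inside STRONG-context windows, by group:\n")
print(strong_cells[order(strong_cells$group, -strong_cells$proportion),
                   c("group", "type", "count", "proportion", "sd")],
      row.names = FALSE, digits = 3)

changes <- tsv("g4_changes.tsv")
flips <- changes[changes$changed, ]
cat(sprintf("\nSomatic mutations changing the predicted G4 category: %d of %d\n",
            nrow(flips), nrow(changes)))
print(table(flips$transition))

csq <- tsv("consequence_by_g4.tsv")
cat("\nConsequence labels within STRONG-context windows:\n")
print(csq[csq$category == "STRONG", ], row.names = FALSE, digits = 3)
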