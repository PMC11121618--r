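#!/usr/bin/env Rscript
# Cohort-level germline analysis: depth-filter each sample's germline VCF
# (DP > 10, AD > 5), find SNPs carried by every sample of the enriched group
# and by nobody else, and keep those with population frequency below 0.1.
# Also reproduces the cohort summary from the bundled patient table.

library(g4context)

study_dir <- "results/study"
if (!dir.exists(study_dir)) stop("run analysis/01_simulate_study.R first")

cfg <- synth_config(seed = 1L)
germ <- lapply(setNames(cfg$samples$id, cfg$samples$id), function(sid) {
  v <- read_variants(file.path(study_dir, paste0(sid, ".germline.vcf")),
                     sid, "GERMLINE")
  filter_germline(v)
})
drops <- vapply(germ, function(v)
  attr(v, "germline_filter_report")$n_failed, integer(1))
cat(sprintf("Depth filter removed %d variants across %d samples\n",
            sum(drops), length(germ)))

keys <- lapply(germ, variant_key)
ex <- group_exclusive_snps(keys, cfg$group)
cat(sprintf("\nSNPs carried by all of {%s} and no other sample: %d\n",
            paste(cfg$group, collapse = ", "), length(ex)))

all_v <- do.call(rbind, germ)
uniq <- all_v[!duplicated(variant_key(all_v)), ]
low <- filter_by_population_frequency(uniq[variant_key(uniq) %in% ex, ])
cat(sprintf("Of these, %d have population allele frequency < 0.1:\n", nrow(low)))
print(low[, c("chrom", "pos", "ref", "alt", "af_pop", "rsid")], row.names = FALSE)
dir.create("results", showWarnings = FALSE)
utils::write.table(low, "results/group_exclusive_low_af_snps.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nCohort characteristics (bundled 11-patient table):\n")
s <- cohort_summary(mm_cohort_table())
cat(sprintf("  n = %d; median age %s (range %s-%s); %s%% female / %s%% male\n",
            s$n, s$median_age, s$age_min, s$age_max,
            s$sex_percent[["F"]], s$sex_percent[["M"]]))
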