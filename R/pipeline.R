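#' Build a run configuration
#'
#' @param reference Path to the reference FASTA.
#' @param samples data.frame with columns `id`, `somatic_vcf`,
#'   `germline_vcf` (may be `NA`), `panel` (a panel id).
#' @param panels Named list/character vector, panel id -> BED path.
#' @param n_controls Random control windows per panel (default 2000).
#' @param flank Window flank in nt (default 70).
#' @param seed Master seed for control sampling.
#' @param alpha Significance level (default 0.05).
#' @param continuity Yates correction in the chi-square test (default FALSE).
#' @param strict_loops Restricted G4 loop class (default FALSE).
#' @param keep_nonpass Keep non-PASS VCF records (default FALSE).
#' @param min_dp,min_ad Germline depth filters (defaults 10 and 5, strict).
#' @return A validated `g4_run_config` list.
#' @export
run_config <- function(reference, samples, panels, n_controls = 2000L,
                       flank = 70L, seed = 1L, alpha = 0.05,
                       continuity = FALSE, strict_loops = FALSE,
                       keep_nonpass = FALSE, min_dp = 10L, min_ad = 5L) {
  cfg <- list(reference = reference, samples = samples,
              panels = as.list(panels), n_controls = n_controls,
              flank = flank, seed = as.integer(seed), alpha = alpha,
              continuity = continuity, strict_loops = strict_loops,
              keep_nonpass = keep_nonpass, min_dp = min_dp, min_ad = min_ad)
  validate_run_config(cfg)
  structure(cfg, class = "g4_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()]; `samples` is a
#'   list of per-sample mappings.
#' @return A `g4_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(y$samples, function(s) {
    data.frame(id = s$id, somatic_vcf = s$somatic_vcf,
               germline_vcf = if (is.null(s$germline_vcf)) NA_character_ else s$germline_vcf,
               panel = s$panel, stringsAsFactors = FALSE)
  }))
  run_config(reference = y$reference, samples = samples, panels = y$panels,
             n_controls = y$n_controls %||% 2000L,
             flank = y$flank %||% 70L, seed = y$seed %||% 1L,
             alpha = y$alpha %||% 0.05,
             continuity = isTRUE(y$continuity),
             strict_loops = isTRUE(y$strict_loops),
             keep_nonpass = isTRUE(y$keep_nonpass),
             min_dp = y$min_dp %||% 10L, min_ad = y$min_ad %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  req <- c("id", "somatic_vcf", "panel")
  if (!all(req %in% names(cfg$samples))) {
    stop("samples table needs columns: ", paste(req, collapse = ", "))
  }
  if (!file.exists(cfg$reference)) stop("missing reference: ", cfg$reference)
  missing_panel <- setdiff(unique(cfg$samples$panel), names(cfg$panels))
  if (length(missing_panel)) {
    stop("panel id not defined: ", paste(missing_panel, collapse = ", "))
  }
  for (p in unlist(cfg$panels)) {
    if (!file.exists(p)) stop("missing panel BED: ", p)
  }
  for (i in seq_len(nrow(cfg$samples))) {
    if (!file.exists(cfg$samples$somatic_vcf[i])) {
      stop("missing somatic VCF for ", cfg$samples$id[i])
    }
    gv <- cfg$samples$germline_vcf[i]
    if (!is.na(gv) && !file.exists(gv)) {
      stop("missing germline VCF for ", cfg$samples$id[i])
    }
  }
  invisible(cfg)
}

#' Run the full G4-context analysis
#'
#' Orchestrates ingest, window extraction, germline application, G4
#' classification, per-sample enrichment against panel-matched random
#' controls, the group summary, stratified mutation spectra, per-mutation
#' G4-change prediction and the consequence-by-context table, writing
#' tab-separated reports plus a JSON run manifest under `out_dir`.
#' Reruns with identical inputs and seed are byte-identical.
#'
#' @param config A `g4_run_config` (see [run_config()] / [read_run_config()]).
#' @param out_dir Report directory, created if needed.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_g4_analysis <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[g4context] ", sprintf(...))

  log_msg("loading reference %s", config$reference)
  reference <- load_reference(config$reference)
  panels <- lapply(config$panels, read_panel)

  log_msg("sampling %d control windows per panel", config$n_controls)
  controls <- list()
  for (pi in seq_along(panels)) {
    pid <- names(panels)[pi]
    cw <- sample_random_windows(reference, panels[[pid]],
                                n = config$n_controls, flank = config$flank,
                                seed = substream_seed(config$seed, "controls", pi))
    cw$category <- classify_window(cw$seq, config$strict_loops)
    controls[[pid]] <- cw
  }

  sample_results <- list()
  labels <- character(0)
  mutation_counts <- numeric(0)
  all_snv <- list()
  changes <- list()
  audit <- list()
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$id[i]
    log_msg("sample %s: reading variants", sid)
    somatic <- read_variants(config$samples$somatic_vcf[i], sid, "SOMATIC",
                             keep_nonpass = config$keep_nonpass)
    germline <- NULL
    if (!is.na(config$samples$germline_vcf[i])) {
      germline <- read_variants(config$samples$germline_vcf[i], sid, "GERMLINE",
                                keep_nonpass = config$keep_nonpass)
      germline <- filter_germline(germline, config$min_dp, config$min_ad)
    }
    windows <- extract_windows(reference, somatic, flank = config$flank)
    edited <- apply_germline(windows, germline)
    edited$category <- classify_window(edited$seq, config$strict_loops)
    ev <- evaluate_sample(edited$category, controls[[config$samples$panel[i]]]$category,
                          alpha = config$alpha, sample = sid)
    log_msg("sample %s: %d somatic windows, label %s", sid, nrow(edited), ev$label)
    sample_results[[sid]] <- ev
    labels[sid] <- ev$label
    mutation_counts[sid] <- nrow(somatic)
    all_snv[[sid]] <- edited
    # per-mutation G4 change prediction (germline-aware before/after)
    ch <- lapply(seq_len(nrow(windows)), function(j) {
      g_in <- NULL
      if (!is.null(germline) && nrow(germline) > 0L) {
        w <- windows[j, ]
        inside <- germline$chrom == w$chrom & germline$pos >= w$start &
          (germline$pos + nchar(germline$ref) - 1L) <= w$end
        # an edit colliding with the somatic anchor cannot be co-applied
        anchor_lo <- w$pos; anchor_hi <- w$pos + nchar(w$ref) - 1L
        collide <- germline$pos <= anchor_hi &
          (germline$pos + nchar(germline$ref) - 1L) >= anchor_lo
        g_in <- germline[inside & !collide, , drop = FALSE]
        if (nrow(g_in) == 0L) g_in <- NULL
      }
      cbind(sample = sid, chrom = windows$chrom[j], pos = windows$pos[j],
            ref = windows$ref[j], alt = windows$alt[j],
            consequence = windows$consequence[j],
            g4_change_on_mutation(windows[j, ], windows[j, variant_columns()],
                                  germline = g_in,
                                  strict_loops = config$strict_loops),
            stringsAsFactors = FALSE)
    })
    changes[[sid]] <- do.call(rbind, ch)
    audit[[sid]] <- data.frame(
      sample = sid, n_somatic_in = nrow(somatic),
      n_windows = nrow(edited),
      n_germline_applied = if (is.null(germline)) 0L else nrow(germline),
      stringsAsFactors = FALSE)
  }

  groups <- summarize_groups(labels, mutation_counts)
  snv_all <- do.call(rbind, all_snv)
  group_of <- ifelse(labels == "G4_STRONG", "ENRICHED", "NOT_ENRICHED")
  names(group_of) <- names(labels)
  spectra <- build_spectra(snv_all, group_of)
  changes_all <- do.call(rbind, changes)
  rownames(changes_all) <- NULL
  csq_tab <- consequence_by_g4(snv_all)

  enr_rows <- do.call(rbind, lapply(sample_results, `[[`, "results"))
  rownames(enr_rows) <- NULL
  fig1 <- enr_rows[enr_rows$context == "STRONG",
                   c("sample", "prop_tumor", "wilson_tumor_lo", "wilson_tumor_hi")]
  names(fig1) <- c("sample", "percent", "ci_lo", "ci_hi")
  fig1[, 2:4] <- 100 * fig1[, 2:4]
  ctrl_rows <- do.call(rbind, lapply(names(controls), function(pid) {
    k <- sum(controls[[pid]]$category == "STRONG"); n <- nrow(controls[[pid]])
    w <- wilson_interval(k, n)
    data.frame(sample = paste0("random_", pid), percent = 100 * k / n,
               ci_lo = 100 * w[["lo"]], ci_hi = 100 * w[["hi"]],
               stringsAsFactors = FALSE)
  }))
  fig1 <- rbind(fig1, ctrl_rows)

  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(enr_rows, "enrichment_per_sample.tsv")
  tsv(cbind(groups$per_sample), "summary_table2_style.tsv")
  tsv(groups$group_means, "group_means.tsv")
  tsv(fig1, "strong_context_percent_ci.tsv")
  tsv(spectra, "spectra_by_group_stratum.tsv")
  tsv(changes_all, "g4_changes.tsv")
  tsv(csq_tab, "consequence_by_g4.tsv")
  tsv(do.call(rbind, audit), "counts_audit.tsv")

  manifest <- list(
    package = "g4context",
    version = as.character(utils::packageVersion("g4context")),
    seed = config$seed, alpha = config$alpha,
    n_controls = config$n_controls, flank = config$flank,
    n_samples = nrow(config$samples),
    config_hash = digest_config(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(labels = labels, enrichment = enr_rows, groups = groups,
                 spectra = spectra, changes = changes_all,
                 consequences = csq_tab, controls = controls,
                 windows = all_snv, out_dir = out_dir))
}

digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
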