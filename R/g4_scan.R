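#' G4 motif regular expressions
#'
#' Two motif classes are scanned, each on both strands of the duplex:
#' *weak* motifs are four runs of exactly two G (or, for quadruplex potential
#' on the complementary strand, two C), *strong* motifs four runs of three to
#' four G (or C), with loops of 1-10 characters between consecutive runs.
#' The loop element matches ANY character: on a nucleotide string the
#' non-digit class `\D` admits every base, including G, C and N. This loose
#' loop semantics is deliberate and is what the headline counts are built on;
#' `strict_loops = TRUE` switches the loop class so it cannot extend a run
#' (no G in G-pattern loops, no C in C-pattern loops), for sensitivity
#' analysis only.
#'
#' @param strength `"WEAK"` or `"STRONG"`.
#' @param strand_pattern `"G_PATTERN"` or `"C_PATTERN"`.
#' @param strict_loops Use the restricted loop class. Default `FALSE`.
#' @return A PCRE pattern string.
#' @export
g4_pattern <- function(strength = c("WEAK", "STRONG"),
                       strand_pattern = c("G_PATTERN", "C_PATTERN"),
                       strict_loops = FALSE) {
  strength <- match.arg(strength)
  strand_pattern <- match.arg(strand_pattern)
  base <- if (strand_pattern == "G_PATTERN") "G" else "C"
  run <- if (strength == "WEAK") sprintf("%s{2}", base) else sprintf("%s{3,4}", base)
  loop <- if (strict_loops) sprintf("[^%s]{1,10}", base) else "\\D{1,10}"
  paste0(run, paste0(rep(paste0(loop, run), 3L), collapse = ""))
}

min_motif_width <- function(strength) {
  if (strength == "WEAK") 4L * 2L + 3L else 4L * 3L + 3L
}

check_scan_seq <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[a-z]", seq)) stop("sequence must be uppercase")
  invisible(seq)
}

#' Find G4 motifs in a sequence
#'
#' Scans `seq` with the weak or strong pattern in both its G-run and C-run
#' forms, returning non-overlapping leftmost matches per pattern (standard
#' regex scan semantics). Coordinates are 1-based closed offsets into `seq`.
#'
#' @param seq Uppercase nucleotide string over `A,C,G,T,N`.
#' @inheritParams g4_pattern
#' @return data.frame with columns `start, end, strength, strand_pattern`.
#' @export
find_g4_motifs <- function(seq, strength = c("WEAK", "STRONG"),
                           strict_loops = FALSE) {
  strength <- match.arg(strength)
  check_scan_seq(seq)
  out <- lapply(c("G_PATTERN", "C_PATTERN"), function(sp) {
    pat <- g4_pattern(strength, sp, strict_loops)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               strength = strength, strand_pattern = sp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strength = character(), strand_pattern = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Does a sequence contain a G4 motif of the given strength?
#'
#' Existence check used for window classification; faster than
#' [find_g4_motifs()] because no match positions are materialized.
#'
#' @inheritParams find_g4_motifs
#' @return Logical vector along `seq` (vectorized over sequences).
#' @export
has_g4 <- function(seq, strength = c("WEAK", "STRONG"), strict_loops = FALSE) {
  strength <- match.arg(strength)
  grepl(g4_pattern(strength, "G_PATTERN", strict_loops), seq, perl = TRUE) |
    grepl(g4_pattern(strength, "C_PATTERN", strict_loops), seq, perl = TRUE)
}

#' Classify a window into a three-level G4 category
#'
#' `STRONG` if any strong motif matches (either strand form), else `WEAK` if a
#' weak motif matches, else `NONE`. Strong dominates weak so the categories
#' are mutually exclusive.
#'
#' @param seq Uppercase nucleotide string, or a character vector of them.
#' @param strict_loops See [g4_pattern()].
#' @return Character vector over `c("NONE","WEAK","STRONG")`.
#' @export
classify_window <- function(seq, strict_loops = FALSE) {
  if (length(seq) == 0L) return(character())
  for (s in seq) check_scan_seq(s)
  ifelse(has_g4(seq, "STRONG", strict_loops), "STRONG",
         ifelse(has_g4(seq, "WEAK", strict_loops), "WEAK", "NONE"))
}

#' G4 category levels in increasing order
#' @return `c("NONE","WEAK","STRONG")`
#' @export
g4_levels <- function() c("NONE", "WEAK", "STRONG")

#' Predict the G4-category change caused by a somatic mutation
#'
#' Classifies the window before and after splicing in the somatic variant.
#' `window` should be the reference-sequence window; germline edits for the
#' patient, when available, are passed via `germline` and applied to both the
#' before- and after-states (both states are rebuilt from the reference window
#' by genomic coordinates, so indel shifts cannot corrupt offsets).
#'
#' @param window Single-row window from [extract_windows()].
#' @param somatic Single-row variant table with the somatic change.
#' @param germline Optional variant table of germline edits.
#' @param strict_loops See [g4_pattern()].
#' @return A one-row data.frame: `before`, `after`, `changed`, `transition`.
#' @export
g4_change_on_mutation <- function(window, somatic, germline = NULL,
                                  strict_loops = FALSE) {
  stopifnot(nrow(window) == 1L, nrow(somatic) == 1L)
  if (somatic$chrom != window$chrom || somatic$pos < window$start ||
      somatic$pos + nchar(somatic$ref) - 1L > window$end) {
    stop("somatic variant lies outside the window interval")
  }
  base <- window
  base$applied_edits <- ""
  w_before <- if (is.null(germline)) base else apply_variants(base, germline)
  edits_after <- if (is.null(germline)) somatic else {
    rbind(germline[, variant_columns()], somatic[, variant_columns()])
  }
  w_after <- apply_variants(base, edits_after)
  before <- classify_window(w_before$seq, strict_loops)
  after <- classify_window(w_after$seq, strict_loops)
  data.frame(before = before, after = after,
             changed = before != after,
             transition = paste0(before, "->", after),
             stringsAsFactors = FALSE)
}

#' Brute-force G4 motif enumerator (verification oracle)
#'
#' Decides motif presence by exhaustively considering every decomposition of
#' the sequence into four base runs separated by three loops: run lengths are
#' exactly 2 (weak) or 3-4 (strong), loops are 1-10 characters of any kind.
#' The search is organized as a reachability sweep over run end positions,
#' which enumerates the same decomposition space as explicit nesting without
#' the combinatorial blowup. Independent of the regex engine; used in tests to
#' certify [find_g4_motifs()] presence/absence.
#'
#' @param seq Uppercase nucleotide string, at most 1000 nt.
#' @param strength `"WEAK"` or `"STRONG"`.
#' @return `TRUE` if at least one motif (G-form or C-form) exists.
#' @export
oracle_has_g4 <- function(seq, strength = c("WEAK", "STRONG")) {
  strength <- match.arg(strength)
  check_scan_seq(seq)
  if (nchar(seq) > 1000L) stop("oracle guard: sequence longer than 1000 nt")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  oracle_chain(chars == "G", strength) || oracle_chain(chars == "C", strength)
}

# Reachability over run-end positions: ends[k][i] == TRUE when the k-th run of
# a candidate motif can end at position i with all run/loop constraints met.
oracle_chain <- function(is_base, strength) {
  n <- length(is_base)
  run_lens <- if (strength == "WEAK") 2L else c(3L, 4L)
  if (n < min_motif_width(strength)) return(FALSE)
  # run_end_ok[[l]][i]: positions i-l+1 .. i are all the base
  run_end_ok <- lapply(run_lens, function(l) {
    ok <- rep(FALSE, n)
    if (n >= l) {
      cs <- cumsum(is_base)
      ok[l:n] <- (cs[l:n] - c(0L, cs)[(l:n) - l + 1L]) == l
    }
    ok
  })
  # a run of length l ending at i starts at i-l+1
  starts_for <- function(reachable_prev_end) {
    # loop of 1..10 after a previous run ending at e allows next run start in
    # e+2 .. e+11
    ok_start <- rep(FALSE, n)
    idx <- which(reachable_prev_end)
    for (e in idx) {
      lo <- e + 2L; hi <- min(e + 11L, n)
      if (lo <= n) ok_start[lo:hi] <- TRUE
    }
    ok_start
  }
  ends_k <- rep(FALSE, n)
  for (j in seq_along(run_lens)) ends_k <- ends_k | run_end_ok[[j]]
  first_ends <- ends_k
  reach <- first_ends
  for (k in 2:4) {
    ok_start <- starts_for(reach)
    reach <- rep(FALSE, n)
    for (j in seq_along(run_lens)) {
      l <- run_lens[j]
      # run starts at i-l+1 must be an allowed start and run_end_ok at i
      cand <- run_end_ok[[j]]
      idx <- which(cand)
      idx <- idx[idx - l + 1L >= 1L & ok_start[idx - l + 1L]]
      reach[idx] <- TRUE
    }
    if (!any(reach)) return(FALSE)
  }
  TRUE
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Uppercase nucleotide string(s).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
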