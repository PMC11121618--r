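test_that("strong and weak patterns match their defining examples", {
  s <- "GGGATGGGTTGGGCAGGG"
  m <- find_g4_motifs(s, "STRONG")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, nchar(s)))

  w <- "GGATGGTTGGCAGG"
  expect_equal(nrow(find_g4_motifs(w, "STRONG")), 0L)
  expect_equal(nrow(find_g4_motifs(w, "WEAK")), 1L)

  cc <- "CCCACCCACCCACCC"
  mc <- find_g4_motifs(cc, "STRONG")
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$strand_pattern, "C_PATTERN")

  # loops match ANY character, so a pure-G stretch satisfies the pattern
  expect_true(has_g4(strrep("G", 16), "STRONG"))

  # single-base loops are fine, but one loop of 11 nt breaks the match
  expect_true(has_g4("GGGGAGGGGAGGGGAGGGG", "STRONG"))
  expect_false(has_g4(paste0("GGGG", strrep("A", 11), "GGGGAGGGGAGGGG"), "STRONG"))

  expect_error(find_g4_motifs("ggg", "STRONG"), "uppercase")
  expect_error(find_g4_motifs("", "STRONG"), "non-empty")
})

test_that("motif widths respect the minimal run/loop footprint", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_dna(141, gc = 0.7)
    for (st in c("WEAK", "STRONG")) {
      m <- find_g4_motifs(s, st)
      if (nrow(m)) {
        expect_true(all(m$end - m$start + 1L >= if (st == "WEAK") 11L else 15L))
        # every reported match satisfies its own pattern when re-checked
        for (j in seq_len(nrow(m))) {
          sub <- substr(s, m$start[j], m$end[j])
          expect_true(grepl(g4_pattern(st, m$strand_pattern[j]), sub, perl = TRUE))
        }
      }
    }
  }
})

test_that("window classification applies strong-over-weak precedence", {
  expect_equal(classify_window("GGGATGGGTTGGGCAGGG"), "STRONG")
  expect_equal(classify_window("GGATGGTTGGCAGG"), "WEAK")
  expect_equal(classify_window("ATATATATATATAT"), "NONE")
  # vectorized form keeps order
  expect_equal(classify_window(c("ATATATATATATAT", "GGGATGGGTTGGGCAGGG")),
               c("NONE", "STRONG"))
})

test_that("classification is strand symmetric on random sequences", {
  set.seed(8)
  for (i in 1:300) {
    s <- random_dna(sample(50:141, 1), gc = sample(c(0.4, 0.6, 0.75), 1))
    expect_identical(classify_window(s), classify_window(reverse_complement(s)))
  }
})

test_that("any strong sequence also carries a weak match (monotonicity)", {
  set.seed(9)
  n_strong <- 0
  for (i in 1:400) {
    s <- random_dna(141, gc = 0.75)
    if (has_g4(s, "STRONG")) {
      n_strong <- n_strong + 1
      expect_true(has_g4(s, "WEAK"))
    }
  }
  expect_gt(n_strong, 10)  # the property must actually have been exercised
})

test_that("scanning engine agrees with the brute-force enumerator", {
  set.seed(10)
  gcs <- c(0.4, 0.55, 0.7, 0.85)
  for (i in 1:500) {
    s <- random_dna(141, gc = gcs[1 + (i %% 4)])
    for (st in c("WEAK", "STRONG")) {
      expect_identical(has_g4(s, st), oracle_has_g4(s, st),
                       label = sprintf("%s on %s", st, s))
    }
  }
  # targeted corners where regex semantics are subtle
  corners <- c(strrep("G", 16), strrep("G", 11), strrep("C", 16),
               "GGGGAGGGGAGGGGAGGGG", "GGATGGTTGGCAGG",
               paste0("GG", strrep("T", 10), "GG", strrep("T", 10),
                      "GG", strrep("T", 10), "GG"),
               paste0("GG", strrep("T", 11), "GGTGGTGG"))
  for (s in corners) {
    for (st in c("WEAK", "STRONG")) {
      expect_identical(has_g4(s, st), oracle_has_g4(s, st), label = s)
    }
  }
  expect_error(oracle_has_g4("", "WEAK"))
  expect_error(oracle_has_g4(strrep("A", 1200), "WEAK"), "guard")
})

test_that("somatic mutations can create, destroy or silently pass G4 motifs", {
  ref <- load_reference(write_fasta(c(
    chr1 = paste0(strrep("T", 60), "AAGGGAGGGAGGGAGGAAA", strrep("T", 60)))))
  # window around the GG run's final base; the motif region sits at 61..79
  v_gain <- make_variant(pos = 77, ref = "A", alt = "G")  # GG -> GGG
  w <- extract_window(ref, v_gain, flank = 70)
  expect_equal(classify_window(w$seq), "WEAK")
  ch <- g4_change_on_mutation(w, v_gain)
  expect_equal(ch$before, "WEAK")
  expect_equal(ch$after, "STRONG")
  expect_true(ch$changed)
  expect_equal(ch$transition, "WEAK->STRONG")

  # loop substitution inside a strong motif changes nothing
  ref2 <- load_reference(write_fasta(c(
    chr1 = paste0(strrep("T", 60), "GGGATGGGTTGGGCAGGG", strrep("T", 60)))))
  v_loop <- make_variant(pos = 64, ref = "A", alt = "T")
  w2 <- extract_window(ref2, v_loop, flank = 70)
  ch2 <- g4_change_on_mutation(w2, v_loop)
  expect_equal(ch2$before, "STRONG")
  expect_false(ch2$changed)

  # destroying one run of the only strong motif drops to the weak remnant,
  # and in a weak-free context all the way to NONE
  v_break <- make_variant(pos = 62, ref = "G", alt = "A")
  ch3 <- g4_change_on_mutation(w2, v_break)
  expect_equal(ch3$before, "STRONG")
  expect_false(ch3$after == "STRONG")

  expect_error(g4_change_on_mutation(w2, make_variant(pos = 500)), "outside")
})

test_that("germline edits shift coordinates without corrupting the prediction", {
  base <- paste0(strrep("T", 80), "GGGATGGGTTGGGCAGG", strrep("T", 80))
  ref <- load_reference(write_fasta(c(chr1 = base)))
  # germline insertion upstream of the motif start; somatic completes the
  # fourth run (GG -> GGG) downstream of it
  som <- make_variant(pos = 98, ref = "T", alt = "G")
  w <- extract_window(ref, som, flank = 70)
  germ <- make_variant(pos = 40, ref = "T", alt = "TAC", origin = "GERMLINE")
  ch <- g4_change_on_mutation(w, som, germline = germ)
  expect_equal(ch$before, "WEAK")
  expect_equal(ch$after, "STRONG")
})

test_that("strict loop mode rejects run-extending loops", {
  # all-G stretch is a motif under loose loops but not under strict loops
  expect_true(has_g4(strrep("G", 16), "STRONG", strict_loops = FALSE))
  expect_false(has_g4(strrep("G", 16), "STRONG", strict_loops = TRUE))
  expect_true(has_g4("GGGATGGGTTGGGCAGGG", "STRONG", strict_loops = TRUE))
})
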