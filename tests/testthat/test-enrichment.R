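test_that("Wilson interval matches closed-form and boundary behavior", {
  w <- wilson_interval(50, 100, 0.95)
  expect_lt(max(abs(unname(w) - c(0.4038, 0.5962))), 5e-5)
  expect_identical(wilson_interval(0, 50)[["lo"]], 0)
  expect_identical(wilson_interval(50, 50)[["hi"]], 1)
  expect_error(wilson_interval(5, 0))
})

test_that("Wilson interval agrees with prop.test and always contains k/n", {
  for (n in c(1L, 7L, 33L, 200L)) {
    for (k in unique(c(0L, 1L, n %/% 2, n))) {
      w <- wilson_interval(k, n)
      expect_lte(w[["lo"]], k / n)
      expect_gte(w[["hi"]], k / n)
      if (k > 0 && k < n) {
        ci <- suppressWarnings(stats::prop.test(k, n, correct = FALSE))$conf.int
        expect_equal(unname(w), as.numeric(ci), tolerance = 1e-10)
      }
    }
  }
})

test_that("chi-square independence matches hand-computed 2x2 values", {
  r <- chi_square_independence(10, 20, 10, 20)
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)

  r2 <- chi_square_independence(30, 100, 10, 100)
  expect_equal(r2$stat, 12.5)
  expect_equal(r2$p, 4.07e-4, tolerance = 1e-2)
  expect_equal(r2$dof, 1)

  r3 <- chi_square_independence(30, 100, 10, 100, continuity = TRUE)
  expect_equal(r3$stat, 11.28125, tolerance = 1e-6)

  expect_error(chi_square_independence(0, 10, 0, 10), "degenerate")
})

test_that("two-proportion z-test matches the pooled closed form", {
  r <- two_proportion_z(10, 100, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  r2 <- two_proportion_z(20, 100, 10, 100)
  expect_equal(r2$z, 1.980, tolerance = 1e-3)
  expect_equal(r2$p, 0.0477, tolerance = 1e-3)
  expect_gt(r2$z, 0)  # first proportion larger -> positive sign

  r3 <- two_proportion_z(0, 100, 0, 2000)
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
})

test_that("z squared equals the chi-square statistic on small tables", {
  for (n1 in 2:8) for (n2 in 2:8) {
    for (k1 in 0:n1) for (k2 in 0:n2) {
      if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
      z <- two_proportion_z(k1, n1, k2, n2)
      chi <- chi_square_independence(k1, n1, k2, n2)
      expect_equal(z$z^2, chi$stat, tolerance = 1e-10,
                   label = sprintf("(%d/%d vs %d/%d)", k1, n1, k2, n2))
      expect_equal(z$p, chi$p, tolerance = 1e-10)
    }
  }
})

test_that("random control windows are deterministic and panel-bounded", {
  ref <- load_reference(write_fasta(c(chr1 = random_dna(2000, gc = 0.6))))
  panel <- read_panel(write_bed(data.frame("chr1", 500L, 1500L)))
  w1 <- sample_random_windows(ref, panel, n = 200, seed = 99)
  w2 <- sample_random_windows(ref, panel, n = 200, seed = 99)
  expect_identical(w1, w2)
  expect_true(all(w1$pos >= 501 & w1$pos <= 1500))
  expect_true(all(nchar(w1$seq) == 141L | w1$clipped_left + w1$clipped_right > 0L))
  expect_error(sample_random_windows(ref, panel[0], n = 10), "empty")
  expect_error(sample_random_windows(ref, panel, n = 0), "positive")
})

test_that("anchor sampling is proportional to interval length", {
  panel <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(1L, 2001L), c(100L, 2900L)))
  set.seed(123)
  pos <- sample_panel_positions(panel, 100000L)
  frac_small <- mean(pos$pos <= 100)
  # 100 of 1000 bases; binomial 99.99% band around 0.1 at n = 1e5
  expect_lt(abs(frac_small - 0.1), 4 * sqrt(0.1 * 0.9 / 1e5))
})

test_that("sample evaluation labels follow the two-test direction-gated rule", {
  tumor <- c(rep("STRONG", 40), rep("NONE", 23))
  control <- c(rep("STRONG", 300), rep("NONE", 1700))
  ev <- evaluate_sample(tumor, control, sample = "T1")
  expect_equal(ev$label, "G4_STRONG")
  st <- ev$results[ev$results$context == "STRONG", ]
  expect_lt(st$chi2_p, 1e-10)
  expect_lt(st$z_p, 1e-10)
  expect_equal(st$k_tumor, 40)
  expect_equal(st$n_control, 2000)

  # equal proportions -> NONE
  ev2 <- evaluate_sample(c(rep("STRONG", 15), rep("NONE", 85)),
                         c(rep("STRONG", 300), rep("NONE", 1700)))
  expect_equal(ev2$label, "NONE")

  # strong deficit with tiny p stays NONE: enrichment is one-directional
  ev3 <- evaluate_sample(c(rep("STRONG", 0), rep("NONE", 200)),
                         c(rep("STRONG", 600), rep("NONE", 1400)))
  expect_equal(ev3$label, "NONE")

  # combined weak+strong signal without strong signal
  ev4 <- evaluate_sample(c(rep("WEAK", 120), rep("NONE", 80)),
                         c(rep("WEAK", 600), rep("STRONG", 100), rep("NONE", 1300)))
  expect_equal(ev4$label, "G4_WEAK_PLUS_STRONG")

  expect_error(evaluate_sample(character(), control), "empty")
})

test_that("group summary pools weak-plus-strong with the unenriched group", {
  labels <- c(S12 = "G4_STRONG", P23 = "G4_STRONG", P37 = "G4_STRONG",
              S7 = "NONE", P1 = "NONE", P14 = "NONE", P20 = "NONE",
              P22 = "NONE", P30 = "NONE", P34 = "NONE",
              P48 = "G4_WEAK_PLUS_STRONG")
  counts <- c(S12 = 63, P23 = 119, P37 = 82, S7 = 115, P1 = 87, P14 = 234,
              P20 = 182, P22 = 191, P30 = 662, P34 = 267, P48 = 227)
  g <- summarize_groups(labels, counts)
  gm <- g$group_means
  expect_equal(gm$mean_mutations[gm$group == "G4_strong_enriched"], 88)
  expect_equal(gm$mean_mutations[gm$group == "without_G4_strong_enrichment"],
               245.625)
  expect_equal(gm$n_samples, c(3L, 8L))
  expect_true("P48" %in%
    g$per_sample$sample[g$per_sample$group == "without_G4_strong_enrichment"])

  single <- summarize_groups(c(A = "G4_STRONG"), c(A = 42))
  expect_equal(single$group_means$mean_mutations[1], 42)
  expect_true(is.na(single$group_means$mean_mutations[2]))
})
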