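test_that("tract-G positions are extracted from motifs, loops excluded", {
  s3 <- "GGGAGGGAGGGAGGG"
  m3 <- scan_rg4(s3)
  expect_equal(gtract_g_positions(m3[1, ], s3),
               c(0L, 1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L, 12L, 13L, 14L))
  s2 <- "GGAGGAGGAGG"
  m2 <- scan_rg4(s2)
  expect_length(gtract_g_positions(m2[1, ], s2), 8L)

  past_end <- m3[1, ]
  expect_error(gtract_g_positions(past_end, substr(s3, 1, 10)), "past")
  shifted <- m3[1, ]
  shifted$tract_starts <- list(c(0L, 3L, 8L, 12L))   # tract 2 covers an A
  expect_error(gtract_g_positions(shifted, s3), "Non-G")
})

test_that("Gini index equals the literal double sum and its worked points", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(0, 10)), 0.5)
  expect_equal(gini_index(c(1, 1, 1, 97)), 0.72)
  expect_error(gini_index(5), "at least 2")
  expect_error(gini_index(c(-1, 2)), "non-negative")
  expect_warning(g0 <- gini_index(c(0, 0, 0)), "undefined")
  expect_true(is.na(g0))

  set.seed(8)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    r <- rpois(n, lambda = sample(c(1, 20, 200), 1)) + runif(n)
    expect_equal(gini_index(r), gini_bruteforce(r), tolerance = 1e-12)
  }
})

test_that("Gini is scale-invariant and bounded by (n-1)/n", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    r <- rgamma(n, 1)
    g <- gini_index(r)
    expect_equal(gini_index(17.3 * r), g, tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, (n - 1) / n + 1e-12)
  }
  # upper bound attained only by a single-position point mass
  expect_equal(gini_index(c(0, 0, 0, 12)), 3 / 4)
})

test_that("eligibility applies the benchmark ratio and read-depth filters", {
  expect_true(eligibility(0.22, 0.20, c(50, 50, 50, 50))$eligible)
  expect_false(eligibility(0.218, 0.20, c(50, 50))$eligible)  # ratio 1.09
  e <- eligibility(0.40, 0.20, c(50, 9.9))
  expect_false(e$eligible)
  expect_equal(e$reason, "low_reads")
  e0 <- eligibility(0.40, 0, c(50, 50))
  expect_false(e0$eligible)
  expect_equal(e0$reason, "zero_li_gini")
  expect_equal(eligibility(NA, 0.2, 50)$reason, "missing_gini")
})

test_that("folding score anchors at the benchmarks and is monotone in vivo", {
  expect_equal(folding_score(0.2, 0.6, 0.2), 0)
  expect_equal(folding_score(0.6, 0.6, 0.2), 1)
  expect_equal(folding_score(0.5, 0.6, 0.2), 0.75)
  expect_error(folding_score(0.5, 0.2, 0.6), "Gini")
  g <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(folding_score(g, 0.7, 0.05)) > 0))
  expect_equal(folding_score(1.5, 0.6, 0.2, clamp = TRUE), 1)
})

test_that("score differences flow through the per-site pipeline", {
  ex <- simulate_shalipe_experiment(n_sites = 20, seed = 21)
  fs <- compute_folding_scores(ex$stop_counts, ex$sites)
  expect_equal(nrow(fs), 20L)
  expect_true(all(fs$delta_score[fs$eligible] ==
                    fs$score_4C[fs$eligible] - fs$score_22C[fs$eligible]))
  expect_true(all(c("quartet_class", "loop_bin", "region") %in% names(fs)))

  # identical in vivo conditions give a zero difference
  same <- ex$stop_counts
  vivo4 <- same[same$condition == "in_vivo_22C", ]
  vivo4$condition <- "in_vivo_4C"
  same <- dplyr::bind_rows(same[same$condition != "in_vivo_4C", ], vivo4)
  fs0 <- compute_folding_scores(same)
  expect_true(all(abs(fs0$delta_score[fs0$eligible]) < 1e-12))

  # a missing in vivo condition is skipped, not fatal
  partial <- ex$stop_counts[ex$stop_counts$condition != "in_vivo_4C", ]
  expect_message(fsp <- compute_folding_scores(partial), "lack one")
  expect_true(all(is.na(fsp$delta_score)))
  expect_false(any(fsp$cold_responsive))
})

test_that("replicate libraries are summed before the Gini calculation", {
  counts <- tibble::tibble(
    site_id = "s", condition = "in_vitro_K",
    position = rep(0:3, 2), count = c(1, 2, 3, 4, 9, 8, 7, 6),
    library = rep(c("rep1", "rep2"), each = 4)
  )
  merged <- merge_replicates(counts)
  expect_equal(merged$count, rep(10, 4))
  g <- gini_by_condition(counts)
  expect_equal(g$gini, 0)
  expect_equal(g$mean_reads, 10)
})

test_that("stratified comparisons report group summaries and t tests", {
  x <- rnorm(30)
  rec <- tibble::tibble(quartet_class = rep(c("G2", "G3"), each = 30),
                        delta_score = c(x, x))
  out <- stratify_and_compare(rec, "quartet_class")
  expect_equal(out$tests$t, 0, tolerance = 1e-12)
  expect_equal(out$tests$p_value, 0.5, tolerance = 1e-12)

  set.seed(31)
  rec2 <- tibble::tibble(group = rep(c("high", "low"), each = 50),
                         delta_score = c(rnorm(50, 1, 0.1), rnorm(50, 0, 0.1)))
  out2 <- stratify_and_compare(rec2, "group", alternative = "greater")
  expect_identical(c(out2$tests$stratum_a, out2$tests$stratum_b),
                   c("high", "low"))
  expect_gt(out2$tests$t, 0)
  expect_lt(out2$tests$p_value, 0.001)
  expect_equal(out2$summary$n, c(50L, 50L))

  rec3 <- tibble::tibble(region = c("CDS", "CDS", "CDS", "FIVE_UTR"),
                         delta_score = c(0.1, 0.2, 0.3, 0.5))
  expect_warning(out3 <- stratify_and_compare(rec3, "region"), "FIVE_UTR")
  expect_equal(out3$summary$stratum, "CDS")
})
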