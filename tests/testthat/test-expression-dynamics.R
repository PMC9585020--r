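mk_series <- function(id, condition, times, abundance, replicate = 1L) {
  tibble::tibble(transcript_id = id, condition = condition, time = times,
                 replicate = replicate, abundance = abundance)
}

test_that("time courses are anchored at their t = 0 point", {
  pts <- mk_series("a", "22C", c(0, 60), c(100, 50))
  norm <- normalize_timecourse(pts)
  expect_equal(norm$abundance, c(1, 0.5))

  # a flat internal reference changes nothing beyond t = 0 scaling
  pts2 <- dplyr::bind_rows(pts, mk_series("ref", "22C", c(0, 60), c(7, 7)))
  norm2 <- normalize_timecourse(pts2, reference_transcript = "ref")
  expect_equal(norm2$abundance[norm2$transcript_id == "a"], c(1, 0.5))

  no_t0 <- mk_series("b", "22C", c(15, 60), c(80, 40))
  expect_message(out <- normalize_timecourse(dplyr::bind_rows(pts, no_t0)), "b")
  expect_false("b" %in% out$transcript_id)
  expect_error(normalize_timecourse(mk_series("a", "22C", 0, -1)), "positive")
})

test_that("noiseless exponential decay is recovered exactly", {
  times <- c(0, 15, 30, 60, 120, 240)
  for (k in c(0, 0.001, 0.01, 0.05)) {
    fit <- fit_decay_rate(times, exp(-k * times))
    expect_equal(fit$rate, k, tolerance = 1e-10)
    if (k > 0) expect_equal(fit$half_life, log(2) / k, tolerance = 1e-8)
  }
  flat <- fit_decay_rate(times, rep(1, 6))
  expect_equal(flat$rate, 0)
  expect_equal(flat$half_life, Inf)
  expect_false(flat$stabilized)

  grows <- fit_decay_rate(times, exp(0.002 * times))
  expect_true(grows$stabilized)
  expect_equal(grows$rate, -0.002, tolerance = 1e-10)
  expect_equal(grows$half_life, Inf)

  expect_error(fit_decay_rate(c(0, 15), c(1, 0.9)), "3 distinct")
  expect_warning(fit_decay_rate(times, c(1, 0.9, 0.8, -0.1, 0.5, 0.4)),
                 "non-positive")
})

test_that("the fitted rate scales exactly with the time unit", {
  set.seed(40)
  times <- c(0, 15, 30, 60, 120, 240)
  ab <- exp(-0.008 * times) * exp(rnorm(6, 0, 0.1))
  k_min <- fit_decay_rate(times, ab)$rate
  k_hr <- fit_decay_rate(times / 60, ab)$rate
  expect_equal(k_hr, 60 * k_min, tolerance = 1e-10)
})

test_that("noisy decay series recover the true rate within 10% (median)", {
  set.seed(41)
  times <- rep(c(0, 15, 30, 60, 120, 240), times = 3)
  k_true <- 0.005
  khat <- vapply(1:100, function(i) {
    rep_id <- rep(1:3, each = 6)
    ab <- exp(-k_true * times) * exp(rnorm(18, 0, 0.1))
    # per-replicate anchoring, as in the pipeline
    for (r in 1:3) {
      sel <- rep_id == r
      ab[sel] <- ab[sel] / ab[sel & times == 0]
    }
    fit_decay_rate(times, ab)$rate
  }, numeric(1))
  expect_lt(abs(stats::median(khat) - k_true) / k_true, 0.10)
})

test_that("decay-rate differences and category summaries track planted rates", {
  fits <- tibble::tibble(
    transcript_id = c("a", "a", "b", "b", "c"),
    condition = c("22C", "4C", "22C", "4C", "22C"),
    rate = c(0.010, 0.002, 0.01, 0.01, 0.02)
  )
  expect_message(dk <- decay_rate_difference(fits), "Skipping 1")
  expect_equal(dk$per_transcript$delta_k[dk$per_transcript$transcript_id == "a"],
               -0.008)
  expect_equal(dk$per_transcript$delta_k[dk$per_transcript$transcript_id == "b"], 0)

  sim <- simulate_decay_and_te(seed = 42)
  fits <- fit_decay_rates(normalize_timecourse(sim$timecourse))
  dk <- decay_rate_difference(fits, sim$categories)
  by_cat <- dk$by_category
  third <- by_cat$mean_delta_k[by_cat$category == "THREE_UTR"]
  expect_true(all(third < by_cat$mean_delta_k[by_cat$category != "THREE_UTR"]))
  expect_equal(third, -0.008, tolerance = 0.1)
})

test_that("relative abundance curves report mean and SE across transcripts", {
  pts <- dplyr::bind_rows(
    mk_series("a", "22C", c(0, 60), c(1, 0.4)),
    mk_series("b", "22C", c(0, 60), c(1, 0.6)),
    mk_series("c", "4C", c(0, 60), c(1, 0.9))
  )
  groups <- tibble::tibble(transcript_id = c("a", "b", "c"),
                           group = c("g1", "g1", "g2"))
  curve <- relative_abundance_curve(pts, groups)
  r <- curve[curve$group == "g1" & curve$time == 60, ]
  expect_equal(r$mean, 0.5)
  expect_equal(r$se, 0.1)
  r0 <- curve[curve$group == "g1" & curve$time == 0, ]
  expect_equal(r0$mean, 1)
  expect_equal(r0$se, 0)
  single <- curve[curve$group == "g2" & curve$time == 60, ]
  expect_true(single$singleton)
  expect_true(is.na(single$se))
})

test_that("translation efficiency is the polysome/total ratio", {
  expr <- tibble::tibble(
    transcript_id = c("a", "b", "a", "b"),
    condition = c("22C", "22C", "4C", "4C"),
    polysome_abundance = c(10, 30, 10, 15),
    total_abundance = c(10, 30, 10, 30)
  )
  te <- translation_efficiency(expr, normalize = FALSE)
  expect_equal(te$te$te, c(1, 1, 1, 0.5))

  zero <- expr
  zero$total_abundance[1] <- 0
  expect_message(tez <- translation_efficiency(zero, normalize = FALSE),
                 "non-positive total")
  expect_equal(nrow(tez$te), 3L)

  sim <- simulate_decay_and_te(seed = 43)
  comp <- translation_efficiency(sim$expression)$comparison
  expect_gt(comp$pcc, 0.98)
  expect_lt(abs(comp$mean_relative_difference - 0.02), 0.015)
})

test_that("steady-state ratios identify the cold-enriched category", {
  ab <- tibble::tibble(
    transcript_id = c("a", "a", "b", "b"),
    condition = c("22C", "4C", "22C", "4C"),
    abundance = c(5, 5, 3, 6)
  )
  ss <- steady_state_ratio(ab)
  expect_equal(ss$per_transcript$ratio, c(1, 2))

  set.seed(44)
  ids <- sprintf("t%03d", 1:60)
  cats <- tibble::tibble(transcript_id = ids,
                         category = rep(c("nonRG4", "THREE_UTR"), each = 30))
  base <- exp(rnorm(60, 0, 0.05))
  lift <- ifelse(cats$category == "THREE_UTR", 1.6, 1.0)
  ab2 <- dplyr::bind_rows(
    tibble::tibble(transcript_id = ids, condition = "22C", abundance = base),
    tibble::tibble(transcript_id = ids, condition = "4C",
                   abundance = base * lift * exp(rnorm(60, 0, 0.05)))
  )
  ss2 <- steady_state_ratio(ab2, cats)
  bc <- ss2$by_category
  expect_gt(bc$mean_ratio[bc$category == "THREE_UTR"],
            bc$mean_ratio[bc$category == "nonRG4"])
  expect_lt(bc$p_vs_nonRG4[bc$category == "THREE_UTR"], 0.001)
})
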