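RG4_CATEGORIES <- c("nonRG4", "FIVE_UTR", "CDS", "THREE_UTR")

#' Normalize a transcription-arrest time course to its t = 0 point
#'
#' Scales every (transcript, condition, replicate) series so that its
#' abundance is 1 at time 0; optionally further divides by an internal
#' reference transcript at each time point (the reference is normalized
#' to its own t = 0 first). Series lacking a t = 0 point are dropped
#' with a message.
#'
#' @param points Tibble: `transcript_id`, `condition`, `time`,
#'   `replicate`, `abundance` (positive).
#' @param reference_transcript Optional id of an internal-control
#'   transcript.
#' @return The input tibble with `abundance` replaced by the normalized
#'   value (reference rows removed when a reference is used).
#' @export
normalize_timecourse <- function(points, reference_transcript = NULL) {
  if (any(points$abundance <= 0)) stop("Abundances must be positive")
  key <- paste(points$transcript_id, points$condition, points$replicate)
  t0 <- points$time == 0
  base <- stats::setNames(points$abundance[t0], key[t0])
  missing <- !key %in% names(base)
  if (any(missing)) {
    dropped <- unique(points$transcript_id[missing])
    message("Dropping series without t = 0: ", paste(dropped, collapse = ", "))
    points <- points[!missing, ]
    key <- key[!missing]
  }
  points$abundance <- unname(points$abundance / base[key])
  if (!is.null(reference_transcript)) {
    ref <- points[points$transcript_id == reference_transcript, ]
    if (nrow(ref) == 0L) stop("Reference transcript not found: ", reference_transcript)
    rkey <- paste(ref$condition, ref$time, ref$replicate)
    rmap <- stats::setNames(ref$abundance, rkey)
    points <- points[points$transcript_id != reference_transcript, ]
    pkey <- paste(points$condition, points$time, points$replicate)
    if (any(!pkey %in% names(rmap))) {
      stop("Reference transcript missing time points required for normalization")
    }
    points$abundance <- unname(points$abundance / rmap[pkey])
  }
  points
}

#' Fit a first-order decay rate to one normalized series
#'
#' Ordinary least squares of `ln(abundance) = -k * t` (no intercept; the
#' series is anchored at 1 by t = 0 normalization) pooled over all
#' replicate points. Negative fitted rates are reported as-is and
#' flagged `stabilized` rather than truncated, so downstream rate
#' differences stay unbiased.
#'
#' @param time Numeric vector of times (same unit throughout; the rate
#'   is per unit of this vector).
#' @param abundance Matched normalized abundances (> 0; non-positive
#'   points are excluded with a warning).
#' @param with_intercept Fit an intercept as well (off by default).
#' @return One-row tibble: `rate` (k), `half_life` (`ln 2 / k`, `Inf`
#'   when k <= 0), `r_squared`, `n_points`, `stabilized`.
#' @export
fit_decay_rate <- function(time, abundance, with_intercept = FALSE) {
  bad <- !is.finite(abundance) | abundance <= 0
  if (any(bad)) {
    warning("Excluding ", sum(bad), " non-positive abundance point(s)")
    time <- time[!bad]
    abundance <- abundance[!bad]
  }
  if (length(unique(time)) < 3L) {
    stop("Decay fit needs at least 3 distinct time points")
  }
  y <- log(abundance)
  fit <- if (with_intercept) {
    stats::lm(y ~ time)
  } else {
    stats::lm(y ~ 0 + time)
  }
  slope <- unname(stats::coef(fit)[["time"]])
  k <- -slope
  # summary.lm warns on exact (noiseless) fits; that case is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble::tibble(
    rate = k,
    half_life = ifelse(k > 0, log(2) / k, Inf),
    r_squared = max(0, min(1, r2)),
    n_points = length(y),
    stabilized = k < 0
  )
}

#' Decay fits for every (transcript, condition) series
#'
#' @param points Normalized time-course tibble (see
#'   [normalize_timecourse()]).
#' @param with_intercept Passed to [fit_decay_rate()].
#' @return Tibble with one row per transcript x condition: `rate`,
#'   `half_life`, `r_squared`, `n_points`, `stabilized`.
#' @export
fit_decay_rates <- function(points, with_intercept = FALSE) {
  groups <- split(points, paste(points$transcript_id, points$condition, sep = "\r"))
  dplyr::bind_rows(lapply(groups, function(g) {
    fit <- fit_decay_rate(g$time, g$abundance, with_intercept)
    dplyr::bind_cols(
      tibble::tibble(transcript_id = g$transcript_id[1], condition = g$condition[1]),
      fit
    )
  }))
}

#' Cold-minus-control decay-rate differences
#'
#' Computes `delta_k = k(4C) - k(22C)` per transcript (negative values
#' mean the transcript is stabilized in the cold) and, when a category
#' map is supplied, per-category group summaries.
#'
#' @param fits Output of [fit_decay_rates()] containing both conditions
#'   (`"22C"`, `"4C"`).
#' @param categories Optional tibble `transcript_id`, `category`
#'   (nonRG4 / FIVE_UTR / CDS / THREE_UTR); a transcript may appear in
#'   several categories.
#' @return List with `per_transcript` (`transcript_id`, `k_22C`,
#'   `k_4C`, `delta_k`) and, with categories, `by_category` (`category`,
#'   `n`, `mean_delta_k`, `se`). Transcripts with one condition missing
#'   are skipped with a message.
#' @export
decay_rate_difference <- function(fits, categories = NULL) {
  wide <- tidyr::pivot_wider(
    fits[, c("transcript_id", "condition", "rate")],
    names_from = "condition", values_from = "rate", names_prefix = "k_"
  )
  if (!all(c("k_22C", "k_4C") %in% names(wide))) {
    stop("Fits must cover both the 22C and 4C conditions")
  }
  incomplete <- is.na(wide$k_22C) | is.na(wide$k_4C)
  if (any(incomplete)) {
    message("Skipping ", sum(incomplete), " transcript(s) missing one condition")
    wide <- wide[!incomplete, ]
  }
  wide$delta_k <- wide$k_4C - wide$k_22C
  by_category <- NULL
  if (!is.null(categories)) {
    merged <- dplyr::inner_join(wide, categories, by = "transcript_id")
    by_category <- dplyr::summarise(
      dplyr::group_by(merged, .data$category),
      n = dplyr::n(),
      mean_delta_k = mean(.data$delta_k),
      se = stats::sd(.data$delta_k) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  }
  list(per_transcript = wide, by_category = by_category)
}

#' Mean relative-abundance curves per group
#'
#' Averages normalized abundance across the transcripts of a group at
#' each (condition, time), with the standard error across transcripts
#' (replicates are averaged within transcript first).
#'
#' @param points Normalized time-course tibble.
#' @param groups Tibble `transcript_id`, `group` (e.g. RG4 category).
#' @return Tibble: `group`, `condition`, `time`, `n`, `mean`, `se`
#'   (`se` is `NA` and flagged by `singleton` for single-transcript
#'   groups).
#' @export
relative_abundance_curve <- function(points, groups) {
  merged <- dplyr::inner_join(points, groups, by = "transcript_id")
  per_tx <- dplyr::summarise(
    dplyr::group_by(merged, .data$group, .data$condition, .data$time,
                    .data$transcript_id),
    abundance = mean(.data$abundance), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_tx, .data$group, .data$condition, .data$time),
    n = dplyr::n(),
    mean = mean(.data$abundance),
    se = ifelse(dplyr::n() > 1L,
                stats::sd(.data$abundance) / sqrt(dplyr::n()), NA_real_),
    .groups = "drop"
  )
  out$singleton <- out$n == 1L
  out
}

#' Translation efficiency per transcript and condition
#'
#' TE is polysome-associated abundance divided by total abundance, after
#' per-million library-size scaling of each abundance column. The
#' condition comparison reports the Pearson correlation between TE at
#' 4C and 22C and the mean relative difference.
#'
#' @param expression Tibble: `transcript_id`, `condition`,
#'   `polysome_abundance`, `total_abundance`.
#' @param normalize Apply per-million scaling within each condition
#'   (default `TRUE`).
#' @return List with `te` (`transcript_id`, `condition`, `te`) and
#'   `comparison` (`pcc`, `p_value`, `mean_relative_difference`, `n`),
#'   the latter `NULL` unless both conditions are present. Transcripts
#'   with zero total abundance are excluded.
#' @export
translation_efficiency <- function(expression, normalize = TRUE) {
  expr <- expression
  zero <- expr$total_abundance <= 0
  if (any(zero)) {
    message("Excluding ", sum(zero), " row(s) with non-positive total abundance")
    expr <- expr[!zero, ]
  }
  if (normalize) {
    expr <- dplyr::mutate(
      dplyr::group_by(expr, .data$condition),
      polysome_abundance = .data$polysome_abundance /
        sum(.data$polysome_abundance) * 1e6,
      total_abundance = .data$total_abundance /
        sum(.data$total_abundance) * 1e6
    )
    expr <- dplyr::ungroup(expr)
  }
  te <- tibble::tibble(
    transcript_id = expr$transcript_id,
    condition = expr$condition,
    te = expr$polysome_abundance / expr$total_abundance
  )
  comparison <- NULL
  wide <- tidyr::pivot_wider(te, names_from = "condition",
                             values_from = "te", names_prefix = "te_")
  if (all(c("te_22C", "te_4C") %in% names(wide))) {
    ok <- stats::complete.cases(wide[, c("te_22C", "te_4C")])
    if (sum(ok) >= 3L) {
      ct <- pearson_with_p(wide$te_22C[ok], wide$te_4C[ok])
      comparison <- tibble::tibble(
        pcc = ct$pcc,
        p_value = ct$p_value,
        mean_relative_difference =
          mean(abs(wide$te_4C[ok] - wide$te_22C[ok]) / wide$te_22C[ok]),
        n = sum(ok)
      )
    }
  }
  list(te = te, comparison = comparison)
}

#' Steady-state abundance ratio 4C / 22C per transcript
#'
#' @param abundance Tibble: `transcript_id`, `condition`, `abundance`
#'   (positive, both conditions per transcript).
#' @param categories Optional category map as in
#'   [decay_rate_difference()]; adds per-category means and a t test of
#'   each category against the `nonRG4` baseline.
#' @return List with `per_transcript` (`transcript_id`, `ratio`) and
#'   optionally `by_category` (`category`, `n`, `mean_ratio`, `se`,
#'   `p_vs_nonRG4`).
#' @export
steady_state_ratio <- function(abundance, categories = NULL) {
  wide <- tidyr::pivot_wider(
    abundance[, c("transcript_id", "condition", "abundance")],
    names_from = "condition", values_from = "abundance", names_prefix = "ab_"
  )
  if (!all(c("ab_22C", "ab_4C") %in% names(wide))) {
    stop("Abundance table must cover both the 22C and 4C conditions")
  }
  ok <- stats::complete.cases(wide[, c("ab_22C", "ab_4C")]) & wide$ab_22C > 0
  if (any(!ok)) message("Skipping ", sum(!ok), " transcript(s) without a matched pair")
  out <- tibble::tibble(
    transcript_id = wide$transcript_id[ok],
    ratio = wide$ab_4C[ok] / wide$ab_22C[ok]
  )
  by_category <- NULL
  if (!is.null(categories)) {
    merged <- dplyr::inner_join(out, categories, by = "transcript_id")
    base <- merged$ratio[merged$category == "nonRG4"]
    by_category <- dplyr::summarise(
      dplyr::group_by(merged, .data$category),
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      se = stats::sd(.data$ratio) / sqrt(dplyr::n()),
      .groups = "drop"
    )
    by_category$p_vs_nonRG4 <- vapply(by_category$category, function(cat) {
      if (cat == "nonRG4" || length(base) < 2L) return(NA_real_)
      vals <- merged$ratio[merged$category == cat]
      if (length(vals) < 2L) return(NA_real_)
      stats::t.test(vals, base)$p.value
    }, numeric(1))
  }
  list(per_transcript = out, by_category = by_category)
}
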