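SHALIPE_CONDITIONS <- c("in_vitro_K", "in_vitro_Li", "in_vivo_22C", "in_vivo_4C")

#' Transcript offsets of the tract guanines of a motif
#'
#' Returns the 0-based offsets of every G inside the motif's four
#' G-tracts (loop guanines excluded), in ascending order. These are the
#' positions whose SHALiPE stop counts enter the Gini index.
#'
#' @param motif One motif row (from [scan_rg4()]): needs `tract_starts`
#'   (list of four 0-based offsets) and `tract_length`.
#' @param sequence The transcript sequence the motif was called on.
#' @return Integer vector of 0-based offsets.
#' @export
gtract_g_positions <- function(motif, sequence) {
  starts <- motif$tract_starts[[1]]
  x <- motif$tract_length[[1]]
  pos <- as.integer(unlist(lapply(starts, function(s) s + seq_len(x) - 1L)))
  if (max(pos) >= nchar(sequence)) {
    stop("Motif extends past the end of the sequence")
  }
  chars <- substring(sequence, pos + 1L, pos + 1L)
  if (any(chars != "G")) {
    stop("Non-G base at tract position(s) ",
         paste(pos[chars != "G"], collapse = ", "))
  }
  pos
}

#' Gini index of a stop-count profile
#'
#' Dispersion of SHALiPE stop counts over the tract guanines of one RG4
#' site: the mean absolute difference between all ordered pairs of
#' counts, normalized by twice the mean,
#' `Gini = sum_i sum_j |r_i - r_j| / (2 n^2 rbar)`.
#' A high value means reads concentrate on few positions (folded
#' signature); 0 means a perfectly even profile (unfolded). Computed via
#' the sorted-weights identity, which equals the literal double sum.
#'
#' @param counts Non-negative numeric vector of per-position stop
#'   counts, length >= 2.
#' @return Gini index in `[0, (n-1)/n]`, or `NA` (with a warning) when
#'   all counts are zero.
#' @examples
#' gini_index(c(0, 10))   # 0.5
#' @export
gini_index <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("Gini index needs at least 2 positions")
  if (any(counts < 0)) stop("Stop counts must be non-negative")
  total <- sum(counts)
  if (total == 0) {
    warning("All-zero stop-count profile: Gini undefined")
    return(NA_real_)
  }
  s <- sort(counts)
  sum((2 * seq_len(n) - n - 1) * s) / (n * total)
}

#' Eligibility of an RG4 site for folding-score calculation
#'
#' A site enters the folding-score analysis only when its in vitro
#' benchmarks separate (`Gini(K+) / Gini(Li+) >= ratio_threshold`) and
#' every contributing condition has average reads >= `min_mean_reads`.
#'
#' @param gini_K,gini_Li In vitro Gini benchmarks (K+ folded, Li+
#'   unfolded).
#' @param mean_reads Named or unnamed numeric vector of the mean
#'   per-position reads of every contributing condition.
#' @param ratio_threshold Minimum benchmark Gini ratio (default 1.1).
#' @param min_mean_reads Minimum average reads per condition (default 10).
#' @return List with logical `eligible` and character `reason`
#'   (`"ok"`, `"zero_li_gini"`, `"gini_ratio"`, `"low_reads"`,
#'   `"missing_gini"`).
#' @export
eligibility <- function(gini_K, gini_Li, mean_reads,
                        ratio_threshold = 1.1, min_mean_reads = 10) {
  if (is.na(gini_K) || is.na(gini_Li)) {
    return(list(eligible = FALSE, reason = "missing_gini"))
  }
  if (gini_Li <= 0) {
    return(list(eligible = FALSE, reason = "zero_li_gini"))
  }
  if (any(is.na(mean_reads)) || any(mean_reads < min_mean_reads)) {
    return(list(eligible = FALSE, reason = "low_reads"))
  }
  # tolerance keeps sites exactly at the printed threshold (e.g.
  # 0.22/0.20 = 1.1) eligible despite floating-point division
  if (gini_K / gini_Li < ratio_threshold - 1e-9) {
    return(list(eligible = FALSE, reason = "gini_ratio"))
  }
  list(eligible = TRUE, reason = "ok")
}

#' Folding score of an in vivo profile against in vitro benchmarks
#'
#' Rescales the in vivo Gini between the unfolded Li+ benchmark (score
#' 0) and the folded K+ benchmark (score 1):
#' `(Gini(vivo) - Gini(Li+)) / (Gini(K+) - Gini(Li+))`.
#' The raw ratio is returned unclamped and may fall outside `[0, 1]`.
#'
#' @param gini_vivo,gini_K,gini_Li Gini indices of the in vivo profile
#'   and the two benchmarks; requires `gini_K > gini_Li` (guaranteed for
#'   eligible sites).
#' @param clamp Clamp the score into `[0, 1]` (off by default).
#' @return Numeric folding score.
#' @export
folding_score <- function(gini_vivo, gini_K, gini_Li, clamp = FALSE) {
  if (any(gini_K <= gini_Li)) {
    stop("folding_score requires Gini(K+) > Gini(Li+); filter by eligibility first")
  }
  s <- (gini_vivo - gini_Li) / (gini_K - gini_Li)
  if (clamp) s <- pmin(1, pmax(0, s))
  s
}

#' Merge replicate SHALiPE libraries
#'
#' Sums stop counts of replicate libraries position-wise, so each
#' (site, condition, position) keeps a single merged count.
#'
#' @param stop_counts Tibble with `site_id`, `condition`, `position`,
#'   `count` and optionally `library`.
#' @return Tibble with one row per (site, condition, position).
#' @export
merge_replicates <- function(stop_counts) {
  dplyr::summarise(
    dplyr::group_by(stop_counts, .data$site_id, .data$condition, .data$position),
    count = sum(.data$count), .groups = "drop"
  )
}

#' Per-site Gini indices across conditions
#'
#' @param stop_counts Stop-count tibble (replicates merged or carrying a
#'   `library` column, which is merged first).
#' @return Tibble: `site_id`, `condition`, `gini`, `mean_reads`, `n`.
#' @export
gini_by_condition <- function(stop_counts) {
  if ("library" %in% names(stop_counts)) {
    stop_counts <- merge_replicates(stop_counts)
  }
  out <- dplyr::summarise(
    dplyr::group_by(stop_counts, .data$site_id, .data$condition),
    gini = suppressWarnings(gini_index(.data$count)),
    mean_reads = mean(.data$count),
    n = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Folding scores, eligibility and cold response per RG4 site
#'
#' Full SHALiPE quantification: per-condition Gini indices, benchmark
#' eligibility, folding scores for each in vivo condition, and the
#' cold-minus-control score difference `delta_score = score(4C) -
#' score(22C)`. When a motif table is supplied, each site inherits its
#' `quartet_class`, `loop_bin` and `region` strata (motif tables are
#' matched on `site_id`).
#'
#' @param stop_counts Stop-count tibble: `site_id`, `condition`
#'   (`in_vitro_K`, `in_vitro_Li`, `in_vivo_22C`, `in_vivo_4C`),
#'   `position`, `count`, optional `library`.
#' @param motifs Optional motif tibble carrying a `site_id` column.
#' @param ratio_threshold,min_mean_reads Eligibility parameters.
#' @param cold_threshold A site is `cold_responsive` when eligible and
#'   `delta_score` exceeds this value (default 0).
#' @return Tibble with one row per site: Gini per condition, `eligible`,
#'   `reason`, `score_22C`, `score_4C`, `delta_score`,
#'   `cold_responsive`, plus any strata columns.
#' @export
compute_folding_scores <- function(stop_counts, motifs = NULL,
                                   ratio_threshold = 1.1,
                                   min_mean_reads = 10,
                                   cold_threshold = 0) {
  gini <- gini_by_condition(stop_counts)
  wide_g <- tidyr::pivot_wider(
    gini[, c("site_id", "condition", "gini")],
    names_from = "condition", values_from = "gini", names_prefix = "gini_"
  )
  wide_m <- tidyr::pivot_wider(
    gini[, c("site_id", "condition", "mean_reads")],
    names_from = "condition", values_from = "mean_reads", names_prefix = "reads_"
  )
  out <- dplyr::left_join(wide_g, wide_m, by = "site_id")
  need <- c("gini_in_vitro_K", "gini_in_vitro_Li")
  if (!all(need %in% names(out))) {
    stop("Stop counts must include both in vitro benchmark conditions")
  }
  n_sites <- nrow(out)
  out$eligible <- logical(n_sites)
  out$reason <- character(n_sites)
  read_cols <- grep("^reads_", names(out), value = TRUE)
  for (i in seq_len(n_sites)) {
    e <- eligibility(
      out$gini_in_vitro_K[i], out$gini_in_vitro_Li[i],
      unlist(out[i, read_cols]),
      ratio_threshold = ratio_threshold, min_mean_reads = min_mean_reads
    )
    out$eligible[i] <- e$eligible
    out$reason[i] <- e$reason
  }
  score_for <- function(col) {
    s <- rep(NA_real_, n_sites)
    if (col %in% names(out)) {
      ok <- out$eligible & !is.na(out[[col]])
      s[ok] <- folding_score(out[[col]][ok], out$gini_in_vitro_K[ok],
                             out$gini_in_vitro_Li[ok])
    }
    s
  }
  out$score_22C <- score_for("gini_in_vivo_22C")
  out$score_4C <- score_for("gini_in_vivo_4C")
  out$delta_score <- out$score_4C - out$score_22C
  skipped <- out$eligible & is.na(out$delta_score)
  if (any(skipped)) {
    message(sum(skipped), " eligible site(s) lack one in vivo condition; ",
            "delta_score left NA")
  }
  out$cold_responsive <- !is.na(out$delta_score) & out$eligible &
    out$delta_score > cold_threshold
  if (!is.null(motifs) && "site_id" %in% names(motifs)) {
    strata <- motifs[, intersect(
      c("site_id", "transcript_id", "quartet_class", "loop_bin", "region"),
      names(motifs)
    )]
    out <- dplyr::left_join(out, strata, by = "site_id")
  }
  out
}

#' Stratified summaries and pairwise comparisons of score differences
#'
#' Summarizes `delta_score` (or another value column) per stratum
#' (quartet class, loop bin, or genic region) and runs pairwise
#' two-sample Student's t tests between strata.
#'
#' @param records Per-site tibble from [compute_folding_scores()] (or
#'   any tibble with the stratum and value columns).
#' @param stratum Name of the stratifying column, e.g. `"quartet_class"`,
#'   `"loop_bin"`, `"region"`.
#' @param value Name of the value column (default `"delta_score"`).
#' @param alternative Alternative hypothesis for the pairwise tests
#'   (first-named stratum minus second), default one-sided `"greater"`.
#' @return List with `summary` (per-stratum `n`, `mean`, `se`) and
#'   `tests` (pairwise `t`, `p_value`). Strata with fewer than 2
#'   non-missing values are omitted with a warning.
#' @export
stratify_and_compare <- function(records, stratum, value = "delta_score",
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  vals <- records[[value]]
  keep <- !is.na(vals) & !is.na(records[[stratum]])
  groups <- split(vals[keep], records[[stratum]][keep])
  small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(small)) {
    warning("Omitting stratum/strata with < 2 records: ",
            paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) == 0L) stop("No stratum has >= 2 records")
  summary <- tibble::tibble(
    stratum = names(groups),
    n = unname(vapply(groups, length, integer(1))),
    mean = unname(vapply(groups, mean, numeric(1))),
    se = unname(vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                       numeric(1)))
  )
  tests <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(names(groups), 2L)
    tests <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tt <- stats::t.test(groups[[a]], groups[[b]], alternative = alternative)
      tibble::tibble(stratum_a = a, stratum_b = b,
                     t = unname(tt$statistic), p_value = tt$p.value,
                     alternative = alternative)
    }))
  }
  list(summary = summary, tests = tests)
}
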