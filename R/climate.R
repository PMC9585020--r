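BIOCLIM_VARS <- paste0("BIO", 1:19)
TEMPERATURE_VARS <- paste0("BIO", 1:11)
PRECIPITATION_VARS <- paste0("BIO", 12:19)
CLIMATE_QUANTILES <- c(10, 25, 50, 75, 90)

#' Filter species by occurrence support
#'
#' Retains species with strictly more than `min_occurrences` occurrence
#' records, sorted lexicographically.
#'
#' @param occurrences Tibble with at least a `species` column (one row
#'   per occurrence record).
#' @param min_occurrences Occurrence threshold; species must exceed it.
#' @return Character vector of retained species names.
#' @export
filter_species <- function(occurrences, min_occurrences = 100L) {
  counts <- table(occurrences$species)
  sort(as.character(names(counts)[counts > min_occurrences]))
}

#' Quantile profile of per-occurrence bioclimatic values
#'
#' Summarizes the occurrence-level values of one species x variable as
#' linear-interpolation quantiles at the 10/25/50/75/90 percent points.
#'
#' @param values Numeric vector of per-occurrence values (length >= 1).
#' @param quantiles Percent points to evaluate.
#' @return Tibble with columns `quantile` and `value`.
#' @export
quantile_profile <- function(values, quantiles = CLIMATE_QUANTILES) {
  if (length(values) == 0L) stop("Cannot take quantiles of an empty vector")
  q <- stats::quantile(values, probs = quantiles / 100, names = FALSE, type = 7)
  tibble::tibble(quantile = as.integer(quantiles), value = q)
}

#' Quantile profiles for a full occurrence-level bioclim table
#'
#' @param occ_bioclim Tibble with `species` plus bioclim value columns
#'   (`BIO1`..`BIO19` or any subset), one row per occurrence.
#' @param variables Bioclim columns to profile (defaults to those present).
#' @param quantiles Percent points to evaluate.
#' @return Long tibble: `species`, `variable`, `quantile`, `value`.
#' @export
bioclim_quantile_profiles <- function(occ_bioclim,
                                      variables = NULL,
                                      quantiles = CLIMATE_QUANTILES) {
  if (is.null(variables)) {
    variables <- intersect(BIOCLIM_VARS, names(occ_bioclim))
  }
  if (length(variables) == 0L) stop("No bioclim variable columns found")
  probs <- quantiles / 100
  sp <- split(occ_bioclim[variables], occ_bioclim$species)
  rows <- lapply(names(sp), function(s) {
    block <- sp[[s]]
    qmat <- vapply(variables, function(v) {
      stats::quantile(block[[v]], probs = probs, names = FALSE, type = 7)
    }, numeric(length(probs)))
    tibble::tibble(
      species = s,
      variable = rep(variables, each = length(probs)),
      quantile = rep(as.integer(quantiles), times = length(variables)),
      value = as.vector(qmat)
    )
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson correlation with the usual t transform on n - 2
#' degrees of freedom (as in [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return A list with elements `pcc` and `p_value`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("Need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Constant vector: Pearson correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(pcc = unname(ct$estimate), p_value = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p values (monotone-enforced, capped at 1), in the
#' input order. Inputs outside (0, 1] are rejected.
#'
#' @param p_values Numeric vector of raw p values.
#' @return Numeric vector of adjusted values (FDR).
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate species features against bioclim quantile profiles
#'
#' For every feature x bioclim variable pair, the per-species feature
#' vector is correlated (Pearson) with each of the five quantile columns
#' of the variable; p values are BH-adjusted within the variable's five
#' quantiles, and the minimum-FDR quantile row is flagged as the
#' variable's representative.
#'
#' @param features Tibble with `species` plus numeric feature columns.
#' @param profiles Long quantile-profile tibble from
#'   [bioclim_quantile_profiles()].
#' @param fdr_family `"quantiles"` (default) adjusts within the five
#'   quantiles of one (feature, variable) pair; `"all"` adjusts across
#'   every variable x quantile of a feature at once.
#' @return Tibble: `feature`, `variable`, `quantile`, `pcc`, `p_value`,
#'   `fdr`, `is_representative`, `n`. Pairs with a constant vector are
#'   recorded with `NA` statistics rather than failing.
#' @export
correlate_climate <- function(features, profiles,
                              fdr_family = c("quantiles", "all")) {
  fdr_family <- match.arg(fdr_family)
  feature_cols <- setdiff(names(features), "species")
  species <- sort(intersect(features$species, unique(profiles$species)))
  if (length(species) < 3L) stop("Need at least 3 shared species")
  features <- features[match(species, features$species), ]
  wide <- tidyr::pivot_wider(
    profiles[profiles$species %in% species, ],
    names_from = c("variable", "quantile"), values_from = "value",
    names_sep = "_q"
  )
  wide <- wide[match(species, wide$species), ]
  variables <- unique(profiles$variable)
  quantiles <- sort(unique(profiles$quantile))

  rows <- list()
  for (f in feature_cols) {
    x <- features[[f]]
    for (v in variables) {
      for (q in quantiles) {
        y <- wide[[paste0(v, "_q", q)]]
        ok <- stats::sd(x) > 0 && !is.null(y) && stats::sd(y) > 0
        res <- if (ok) pearson_with_p(x, y) else list(pcc = NA_real_, p_value = NA_real_)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature = f, variable = v, quantile = as.integer(q),
          pcc = res$pcc, p_value = res$p_value, n = length(x)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  group <- if (fdr_family == "quantiles") {
    paste(out$feature, out$variable)
  } else {
    out$feature
  }
  out$fdr <- NA_real_
  for (g in unique(group)) {
    idx <- which(group == g & !is.na(out$p_value))
    if (length(idx)) out$fdr[idx] <- bh_adjust(out$p_value[idx])
  }
  select_representative(out)
}

#' Flag the representative quantile per (feature, variable)
#'
#' The row with the lowest FDR among a variable's quantiles represents
#' the variable; ties are broken by larger absolute correlation, then by
#' the lower quantile.
#'
#' @param results Correlation tibble with `feature`, `variable`,
#'   `quantile`, `pcc`, `fdr` (five quantile rows per pair).
#' @return The input with a logical `is_representative` column.
#' @export
select_representative <- function(results) {
  key <- paste(results$feature, results$variable)
  results$is_representative <- FALSE
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) != length(CLIMATE_QUANTILES)) {
      stop("Expected ", length(CLIMATE_QUANTILES), " quantile rows for ", g,
           ", found ", length(idx))
    }
    sub <- results[idx, ]
    if (all(is.na(sub$fdr))) next
    ord <- order(sub$fdr, -abs(sub$pcc), sub$quantile, na.last = TRUE)
    results$is_representative[idx[ord[1]]] <- TRUE
  }
  results
}

#' Count significant representative correlations by variable family
#'
#' Tallies, per feature and variable family (temperature BIO1-BIO11 vs
#' precipitation BIO12-BIO19), how many representative correlations pass
#' the significance threshold, split by correlation sign.
#'
#' @param results Output of [correlate_climate()].
#' @param p_threshold Significance threshold (default 0.01).
#' @param use Which statistic to threshold: raw `"p_value"` or `"fdr"`.
#' @return Tibble: `feature`, `family`, `n_positive`, `n_negative`,
#'   `criterion` (records which statistic and threshold were applied).
#' @export
count_significant <- function(results, p_threshold = 0.01,
                              use = c("p_value", "fdr")) {
  use <- match.arg(use)
  reps <- results[results$is_representative, ]
  reps$family <- ifelse(reps$variable %in% TEMPERATURE_VARS, "temperature",
                        ifelse(reps$variable %in% PRECIPITATION_VARS,
                               "precipitation", "other"))
  sig <- !is.na(reps[[use]]) & reps[[use]] < p_threshold
  grid <- expand.grid(
    feature = unique(reps$feature),
    family = intersect(c("temperature", "precipitation", "other"),
                       unique(reps$family)),
    stringsAsFactors = FALSE
  )
  grid$n_positive <- mapply(function(f, fam) {
    sum(sig & reps$feature == f & reps$family == fam & reps$pcc > 0)
  }, grid$feature, grid$family)
  grid$n_negative <- mapply(function(f, fam) {
    sum(sig & reps$feature == f & reps$family == fam & reps$pcc < 0)
  }, grid$feature, grid$family)
  grid$criterion <- paste0(use, "<", p_threshold)
  tibble::as_tibble(grid)
}
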