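#' Derive a child seed for one generator stream
#'
#' Every generator consumes its own child seed derived from a single
#' global seed and a fixed stream number (transcriptome = 1, climate =
#' 2, SHALiPE = 3, decay/TE = 4, with further streams free for user
#' code). Adding a new generator therefore never perturbs the output of
#' existing ones.
#'
#' @param seed Global integer seed.
#' @param stream Fixed stream id of the generator.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 77003) %% 2147483629)
}

sample_probs <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# break every G run of >= 2 so the background carries no scannable tract
break_g_runs <- function(chars) {
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= 2L)) {
    idx <- seq(starts[k] + 1L, ends[k], by = 2L)
    chars[idx] <- sample(c("A", "C", "U"), length(idx), replace = TRUE)
  }
  chars
}

build_motif_string <- function(quartet_class, loop_lengths) {
  x <- if (quartet_class == "G3") 3L else 2L
  tract <- strrep("G", x)
  loops <- vapply(loop_lengths, function(l) {
    paste(sample(c("A", "C", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(tract, loops[1], tract, loops[2], tract, loops[3], tract)
}

#' Simulate a transcriptome with planted RG4 motifs
#'
#' Generates i.i.d. background transcript sequences (plant-like base
#' composition by default), annotates 5'-UTR/CDS/3'-UTR boundaries, and
#' inserts RG4 motif strings with known spans, classes and regions.
#' With `background_clean = TRUE` (default) every background G run of
#' two or more is broken by substitution, so the planted motifs are the
#' only scannable RG4s. Planted loops are drawn from `{A,C,U}` and
#' insertion sites are flanked by non-G bases, so each motif is
#' recovered with its exact span.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Min/max transcript length (nt), drawn uniformly.
#' @param base_probs Named background base probabilities (A/C/G/U).
#' @param planted Tibble `region`, `quartet_class`, `count` of motifs to
#'   insert (default: 2 per region and class, 12 motifs in total).
#' @param loop_range Per-loop length range of planted motifs.
#' @param background_clean Break background G runs (default `TRUE`).
#' @param utr5_frac,cds_frac Boundary placement as fractions of length.
#' @param seed Integer seed; fully determines the output.
#' @return List with `transcripts` (tibble as [load_transcripts()])
#'   and `truth` (planted motif table: `transcript_id`, `start`, `end`,
#'   `quartet_class`, `loop1..3`, `total_loop_length`, `region`).
#' @export
simulate_transcriptome <- function(n_transcripts = 30L,
                                   length_range = c(900L, 2400L),
                                   base_probs = c(A = 0.31, C = 0.20,
                                                  G = 0.19, U = 0.30),
                                   planted = NULL,
                                   loop_range = c(1L, 7L),
                                   background_clean = TRUE,
                                   utr5_frac = 0.12, cds_frac = 0.75,
                                   seed = 1L) {
  set.seed(seed)
  stopifnot(abs(sum(base_probs) - 1) < 1e-9)
  if (is.null(planted)) {
    planted <- tidyr::expand_grid(
      region = c("FIVE_UTR", "CDS", "THREE_UTR"),
      quartet_class = c("G2", "G3")
    )
    planted$count <- 2L
  }
  lens <- sample(seq(length_range[1], length_range[2]), n_transcripts,
                 replace = TRUE)
  ids <- sprintf("tx%04d", seq_len(n_transcripts))
  u5 <- as.integer(round(utr5_frac * lens))
  cd <- as.integer(round(cds_frac * lens))
  seqs <- lapply(lens, function(L) {
    chars <- sample_probs(L, base_probs)
    if (background_clean) chars <- break_g_runs(chars)
    chars
  })
  # expand the planting plan to one row per motif and assign transcripts
  plan <- planted[rep(seq_len(nrow(planted)), planted$count), c("region", "quartet_class")]
  truth <- list()
  occupied <- lapply(seq_len(n_transcripts), function(i) integer(0))
  for (m in seq_len(nrow(plan))) {
    region <- plan$region[m]
    cls <- plan$quartet_class[m]
    loops <- sample(seq(loop_range[1], loop_range[2]), 3L, replace = TRUE)
    motif <- build_motif_string(cls, loops)
    w <- nchar(motif)
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      i <- sample.int(n_transcripts, 1L)
      bounds <- switch(region,
        FIVE_UTR = c(0L, u5[i]),
        CDS = c(u5[i], cd[i]),
        THREE_UTR = c(cd[i], lens[i])
      )
      # keep one flanking base inside the region on each side
      lo <- bounds[1] + 1L
      hi <- bounds[2] - w - 1L
      if (hi < lo) next
      start <- sample(seq(lo, hi), 1L)
      span <- seq(start - 1L, start + w)          # motif plus flanks, 0-based
      if (any(span %in% occupied[[i]])) next
      chars <- seqs[[i]]
      chars[(start + 1L):(start + w)] <- strsplit(motif, "")[[1]]
      for (fl in c(start, start + w + 1L)) {      # 1-based flank positions
        if (fl >= 1L && fl <= lens[i] && chars[fl] == "G") chars[fl] <- "A"
      }
      seqs[[i]] <- chars
      occupied[[i]] <- c(occupied[[i]], span)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        transcript_id = ids[i], start = start, end = start + w,
        quartet_class = cls, loop1 = loops[1], loop2 = loops[2],
        loop3 = loops[3], total_loop_length = sum(loops), region = region
      )
      placed <- TRUE
      break
    }
    if (!placed) stop("Could not place a planted ", cls, " motif in region ", region)
  }
  transcripts <- tibble::tibble(
    id = ids,
    sequence = vapply(seqs, paste, character(1), collapse = ""),
    length = lens,
    utr5_end = u5,
    cds_end = cd
  )
  truth <- if (length(truth)) dplyr::arrange(dplyr::bind_rows(truth),
                                             .data$transcript_id, .data$start)
           else tibble::tibble()
  list(transcripts = transcripts, truth = truth)
}

# plausible per-variable species-level means/sds and occurrence jitter;
# temperature variables on the degree-C scale, precipitation in mm
bioclim_param_table <- function() {
  tibble::tibble(
    variable = BIOCLIM_VARS,
    mean = c(12, 10, 40, 600, 26, -2, 28, 14, 10, 22, 2,
             900, 120, 30, 40, 320, 110, 250, 180),
    sd = c(6, 2, 8, 150, 4, 5, 4, 5, 6, 4, 7,
           350, 45, 18, 12, 120, 60, 110, 90),
    jitter_sd = c(1, 0.5, 2, 40, 1, 1.2, 1, 1.2, 1.5, 1, 1.5,
                  60, 12, 6, 4, 30, 18, 28, 22)
  )
}

#' Simulate species features and occurrence-level climate tables
#'
#' Builds a species panel whose G frequency and BIO1 (annual mean
#' temperature) species-level medians follow a bivariate normal with a
#' chosen population correlation; the remaining bioclim variables are
#' independent of the feature. Per-occurrence values jitter around each
#' species median, and occurrence counts are drawn so that a configured
#' fraction of species falls below the occurrence filter.
#'
#' @param n_species Number of species passing the occurrence filter.
#' @param target_pcc Planted population correlation between G frequency
#'   and the species-level BIO1 value (|target_pcc| < 1).
#' @param occurrence_range Occurrence-count range of retained species
#'   (all above 100).
#' @param frac_below_filter Fraction of extra species generated with
#'   fewer than 100 occurrences (they appear in the occurrence tables
#'   but should be removed by [filter_species()]).
#' @param g_mean,g_sd Species-level G-frequency distribution.
#' @param seed Integer seed.
#' @return List: `features` (`species`, `G_frequency`), `occurrences`
#'   (`species`, `latitude`, `longitude`), `occ_bioclim` (occurrence
#'   rows with `BIO1`..`BIO19`), `truth` (`species`, `bio1_true`,
#'   `g_true`, `target_pcc`, `retained`).
#' @export
simulate_species_climate <- function(n_species = 200L,
                                     target_pcc = -0.6,
                                     occurrence_range = c(110L, 180L),
                                     frac_below_filter = 0.05,
                                     g_mean = 0.19, g_sd = 0.012,
                                     seed = 1L) {
  if (abs(target_pcc) >= 1) stop("target_pcc must satisfy |target_pcc| < 1")
  set.seed(seed)
  pars <- bioclim_param_table()
  n_low <- as.integer(round(frac_below_filter * n_species))
  n_total <- n_species + n_low
  species <- sprintf("species_%03d", seq_len(n_total))
  retained <- c(rep(TRUE, n_species), rep(FALSE, n_low))

  z1 <- stats::rnorm(n_total)
  z2 <- target_pcc * z1 + sqrt(1 - target_pcc^2) * stats::rnorm(n_total)
  g_true <- g_mean + g_sd * z1
  bio1_true <- pars$mean[1] + pars$sd[1] * z2
  other <- sapply(2:19, function(v) {
    stats::rnorm(n_total, pars$mean[v], pars$sd[v])
  })
  species_values <- cbind(BIO1 = bio1_true, other)
  colnames(species_values) <- BIOCLIM_VARS

  n_occ <- ifelse(
    retained,
    sample(seq(occurrence_range[1], occurrence_range[2]), n_total, replace = TRUE),
    sample(20:99, n_total, replace = TRUE)
  )
  sp_idx <- rep(seq_len(n_total), n_occ)
  total_occ <- length(sp_idx)
  occ_values <- sapply(seq_along(BIOCLIM_VARS), function(v) {
    species_values[sp_idx, v] + stats::rnorm(total_occ, 0, pars$jitter_sd[v])
  })
  colnames(occ_values) <- BIOCLIM_VARS
  occurrences <- tibble::tibble(
    species = species[sp_idx],
    latitude = stats::runif(total_occ, -60, 70),
    longitude = stats::runif(total_occ, -180, 180)
  )
  occ_bioclim <- dplyr::bind_cols(occurrences, tibble::as_tibble(occ_values))
  list(
    features = tibble::tibble(species = species[retained],
                              G_frequency = g_true[retained]),
    occurrences = occurrences,
    occ_bioclim = occ_bioclim,
    truth = tibble::tibble(species = species, bio1_true = bio1_true,
                           g_true = g_true, target_pcc = target_pcc,
                           retained = retained)
  )
}

#' Simulate a SHALiPE stop-count profile for one RG4 site
#'
#' Draws `depth` reverse-transcription stops over the tract-G positions
#' of a site from a multinomial whose weights mix the folded signature
#' (weight `lambda` concentrated on each tract's 3'-most G, split evenly
#' across the four tracts, remainder even over the other tract Gs) with
#' a uniform unfolded profile:
#' `w = folded_fraction * last_G_profile + (1 - folded_fraction) * uniform`.
#'
#' @param tract_lengths Four tract lengths (defines the G positions).
#' @param folded_fraction Fraction of molecules in the folded state.
#' @param depth Total stop count to distribute (>= 1).
#' @param lambda Weight put on the 3'-most G of each tract in the folded
#'   profile (default 0.85).
#' @param positions Optional explicit position labels (defaults to
#'   `0..n-1` over the tract Gs).
#' @param site_id,condition Identifiers recorded in the output rows.
#' @param seed Optional integer seed (set only when supplied, so the
#'   function can also run inside a larger seeded generator).
#' @return Tibble: `site_id`, `condition`, `position`, `count`.
#' @export
simulate_stop_counts <- function(tract_lengths = c(3L, 3L, 3L, 3L),
                                 folded_fraction = 0.5,
                                 depth = 1000L, lambda = 0.85,
                                 positions = NULL,
                                 site_id = "site1", condition = "in_vivo_22C",
                                 seed = NULL) {
  if (depth < 1L) stop("depth must be >= 1")
  stopifnot(length(tract_lengths) == 4L, all(tract_lengths >= 2L),
            folded_fraction >= 0, folded_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(tract_lengths)
  last_g <- cumsum(tract_lengths)             # 1-based index of each tract's 3'-most G
  folded <- rep((1 - lambda) / (n - 4L), n)
  folded[last_g] <- lambda / 4
  w <- folded_fraction * folded + (1 - folded_fraction) / n
  counts <- as.integer(stats::rmultinom(1L, depth, w))
  if (is.null(positions)) positions <- seq_len(n) - 1L
  tibble::tibble(site_id = site_id, condition = condition,
                 position = positions, count = counts)
}

#' Simulate a full SHALiPE experiment over many RG4 sites
#'
#' For each site, draws one stop-count profile per condition: in vitro
#' K+ (fully folded benchmark), in vitro Li+ (fully unfolded), and the
#' two in vivo conditions with configurable folded fractions (defaults:
#' 0.3 at 22 C, 0.8 at 4 C — a cold-enhanced folding scenario). Sites
#' are randomly G2 or G3 with random loop lengths and regions, giving
#' strata for downstream comparisons.
#'
#' @param n_sites Number of RG4 sites.
#' @param folded_22C,folded_4C In vivo folded fractions.
#' @param folded_K,folded_Li Benchmark folded fractions (1 and 0).
#' @param depth Stops per site and condition.
#' @param lambda Last-G concentration weight.
#' @param g3_frac Fraction of G3 sites.
#' @param seed Integer seed.
#' @return List: `stop_counts` (long tibble over all sites and
#'   conditions), `sites` (`site_id`, `quartet_class`, `loop_bin`,
#'   `region`), `truth` (per site and condition folded fraction).
#' @export
simulate_shalipe_experiment <- function(n_sites = 50L,
                                        folded_22C = 0.3, folded_4C = 0.8,
                                        folded_K = 1, folded_Li = 0,
                                        depth = 1000L, lambda = 0.85,
                                        g3_frac = 0.3, seed = 1L) {
  set.seed(seed)
  fractions <- c(in_vitro_K = folded_K, in_vitro_Li = folded_Li,
                 in_vivo_22C = folded_22C, in_vivo_4C = folded_4C)
  sites <- list(); counts <- list(); truth <- list()
  for (s in seq_len(n_sites)) {
    id <- sprintf("site%04d", s)
    cls <- if (stats::runif(1) < g3_frac) "G3" else "G2"
    x <- if (cls == "G3") 3L else 2L
    tracts <- rep(x, 4L)
    loops <- sample(1:7, 3L, replace = TRUE)
    region <- sample(c("FIVE_UTR", "CDS", "THREE_UTR"), 1L,
                     prob = c(0.1, 0.6, 0.3))
    sites[[s]] <- tibble::tibble(
      site_id = id, quartet_class = cls,
      loop_bin = assign_loop_bin(sum(loops)), region = region
    )
    for (cond in names(fractions)) {
      counts[[length(counts) + 1L]] <- simulate_stop_counts(
        tract_lengths = tracts, folded_fraction = fractions[[cond]],
        depth = depth, lambda = lambda, site_id = id, condition = cond
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        site_id = id, condition = cond, folded_fraction = fractions[[cond]]
      )
    }
  }
  list(stop_counts = dplyr::bind_rows(counts),
       sites = dplyr::bind_rows(sites),
       truth = dplyr::bind_rows(truth))
}

#' Simulate transcription-arrest time courses and TE tables
#'
#' First-order decay with multiplicative lognormal noise:
#' `abundance(t) = A0 * exp(-k t) * exp(N(0, sigma))` per replicate, at
#' the cordycepin time grid 0/15/30/60/120/240 min, for four transcript
#' categories with category- and condition-specific true rates. The
#' defaults plant the cold-stabilization scenario: a common control
#' rate of 0.010 per min at 22 C and 4 C rates that leave the 3'-UTR
#' category most stabilized (delta k = -0.008 per min). TE tables pair
#' a 22 C TE with a 4 C TE differing by a configurable relative noise.
#'
#' @param n_per_category Transcripts per category.
#' @param k22 Named per-category true decay rates at 22 C (per minute).
#' @param k4 Named per-category true decay rates at 4 C.
#' @param sigma Lognormal noise sd on the natural-log scale.
#' @param replicates Biological replicates per condition.
#' @param times Time grid in minutes (must include 0).
#' @param te_sd Relative sd of TE(4C) around TE(22C) (default 0.02).
#' @param seed Integer seed.
#' @return List: `timecourse` (`transcript_id`, `condition`, `time`,
#'   `replicate`, `abundance`), `expression` (`transcript_id`,
#'   `condition`, `polysome_abundance`, `total_abundance`),
#'   `categories` (`transcript_id`, `category`), `truth` (per
#'   transcript true rates and TE).
#' @export
simulate_decay_and_te <- function(n_per_category = 30L,
                                  k22 = c(nonRG4 = 0.010, FIVE_UTR = 0.010,
                                          CDS = 0.010, THREE_UTR = 0.010),
                                  k4 = c(nonRG4 = 0.009, FIVE_UTR = 0.006,
                                         CDS = 0.006, THREE_UTR = 0.002),
                                  sigma = 0.1, replicates = 3L,
                                  times = c(0, 15, 30, 60, 120, 240),
                                  te_sd = 0.02, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!0 %in% times) stop("Time grid must include 0")
  if (any(k22 < 0) || any(k4 < 0)) stop("Decay rates must be non-negative")
  set.seed(seed)
  cats <- names(k22)
  stopifnot(identical(sort(cats), sort(names(k4))))
  ids <- sprintf("tx_%s_%02d", rep(cats, each = n_per_category),
                 rep(seq_len(n_per_category), times = length(cats)))
  categories <- tibble::tibble(
    transcript_id = ids, category = rep(cats, each = n_per_category)
  )
  grid <- tidyr::expand_grid(
    transcript_id = ids, condition = c("22C", "4C"),
    replicate = seq_len(replicates), time = times
  )
  grid <- dplyr::left_join(grid, categories, by = "transcript_id")
  k_true <- ifelse(grid$condition == "22C",
                   k22[grid$category], k4[grid$category])
  A0 <- 100
  noise <- if (sigma > 0) exp(stats::rnorm(nrow(grid), 0, sigma)) else 1
  grid$abundance <- A0 * exp(-k_true * grid$time) * noise
  timecourse <- grid[, c("transcript_id", "condition", "time",
                         "replicate", "abundance")]

  te22 <- exp(stats::rnorm(length(ids), 0, 0.3))
  te4 <- te22 * (1 + stats::rnorm(length(ids), 0, te_sd))
  total <- exp(stats::rnorm(length(ids), 3, 0.5))
  expression <- dplyr::bind_rows(
    tibble::tibble(transcript_id = ids, condition = "22C",
                   polysome_abundance = te22 * total, total_abundance = total),
    tibble::tibble(transcript_id = ids, condition = "4C",
                   polysome_abundance = te4 * total, total_abundance = total)
  )
  truth <- tibble::tibble(
    transcript_id = ids, category = rep(cats, each = n_per_category),
    k22_true = unname(k22[rep(cats, each = n_per_category)]),
    k4_true = unname(k4[rep(cats, each = n_per_category)]),
    te22_true = te22, te4_true = te4
  )
  list(timecourse = timecourse, expression = expression,
       categories = categories, truth = truth)
}
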