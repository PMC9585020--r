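#' Predict RNA G-quadruplex (RG4) motifs in one sequence
#'
#' Scans an RNA sequence for quadruplex-forming motifs of the form
#' `Gx - loop - Gx - loop - Gx - loop - Gx`, where each of the four
#' G-tracts has at least `x` guanines and each of the three loops is
#' `loop_min`..`loop_max` nt. Three-quartet motifs (G3, `x = g3_tract`)
#' are matched first; a second pass then matches two-quartet motifs
#' (G2, `x = g2_tract`) on sequence not already covered by a G3 motif.
#' Within a pass matches are leftmost and non-overlapping with minimal
#' (non-greedy) loop extension.
#'
#' Candidate tracts are maximal runs of G with length >= `x`, clipped to
#' the class length from the 5' end; leftover guanines of a longer run
#' fall into the adjacent loop, so loops may contain G. Any `N` inside a
#' candidate span vetoes the match, and a G run used by a G3 motif can
#' not seed a G2 motif.
#'
#' @param sequence Character scalar over `{A,C,G,U,N}`.
#' @param g2_tract,g3_tract Minimum tract lengths of the two classes.
#' @param loop_min,loop_max Allowed loop length range (nt).
#' @param transcript_id Optional id recorded in the output.
#' @return A tibble sorted by `start` with columns `transcript_id`,
#'   `start`, `end` (0-based half-open), `quartet_class`, `tract_length`,
#'   `tract_starts` (list of 4 offsets), `loop1`, `loop2`, `loop3`,
#'   `total_loop_length`, `loop_bin` and `region` (initially `"WHOLE"`).
#' @examples
#' scan_rg4("GGGAGGGAGGGAGGG")
#' @export
scan_rg4 <- function(sequence, g2_tract = 2L, g3_tract = 3L,
                     loop_min = 1L, loop_max = 7L,
                     transcript_id = NA_character_) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (loop_min > loop_max) stop("loop_min must not exceed loop_max")
  if (loop_min < 1L) stop("loop_min must be >= 1")
  if (grepl("[^ACGUN]", sequence)) {
    stop("Sequence contains characters outside {A,C,G,U,N}")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- g_runs(chars)
  g3 <- scan_pass(chars, runs, g3_tract, loop_min, loop_max,
                  barriers = NULL, used = rep(FALSE, nrow(runs)))
  used <- rep(FALSE, nrow(runs))
  used[unlist(lapply(g3, `[[`, "run_idx"))] <- TRUE
  barriers <- if (length(g3)) {
    cbind(
      vapply(g3, `[[`, numeric(1), "start"),
      vapply(g3, `[[`, numeric(1), "end")
    )
  } else NULL
  g2 <- scan_pass(chars, runs, g2_tract, loop_min, loop_max,
                  barriers = barriers, used = used)
  motifs_to_tibble(c(g3, g2), c(rep("G3", length(g3)), rep("G2", length(g2))),
                   transcript_id)
}

# maximal runs of G: 0-based start offsets and lengths
g_runs <- function(chars) {
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], len = r$lengths[keep])
}

# One class pass. Runs with len >= x (and not previously used, not
# overlapping a barrier span) seed tracts clipped to x guanines. A
# motif is four tracts chained left-to-right with loops in range;
# depth-first extension prefers the nearest eligible run, so the first
# completed chain is the lexicographically minimal (non-greedy) one.
scan_pass <- function(chars, runs, x, loop_min, loop_max, barriers, used) {
  if (nrow(runs) == 0L) return(list())
  cand <- which(runs$len >= x & !used)
  if (!is.null(barriers) && length(cand)) {
    cand <- cand[!vapply(cand, function(k) {
      any(runs$start[k] < barriers[, 2] & runs$start[k] + runs$len[k] > barriers[, 1])
    }, logical(1))]
  }
  if (length(cand) < 4L) return(list())
  starts <- runs$start[cand]
  motifs <- list()
  pos <- 0L
  i <- 1L
  while (i <= length(cand) - 3L) {
    if (starts[i] < pos) {
      i <- i + 1L
      next
    }
    chain <- extend_chain(chars, starts, i, x, loop_min, loop_max, barriers)
    if (is.null(chain)) {
      i <- i + 1L
      next
    }
    motifs[[length(motifs) + 1L]] <- list(
      start = starts[chain[1]],
      end = starts[chain[4]] + x,
      tract_starts = starts[chain],
      tract_length = x,
      run_idx = cand[chain]
    )
    pos <- starts[chain[4]] + x
    i <- chain[4] + 1L
  }
  motifs
}

# DFS over candidate tract starts; returns indices (into `starts`) of
# the first complete 4-tract chain, or NULL.
extend_chain <- function(chars, starts, i, x, loop_min, loop_max, barriers,
                         chain = i) {
  if (length(chain) == 4L) return(chain)
  cur_end <- starts[chain[length(chain)]] + x   # 0-based end of current tract
  j <- chain[length(chain)] + 1L
  while (j <= length(starts)) {
    gap <- starts[j] - cur_end
    if (gap > loop_max) break
    if (gap >= loop_min &&
        loop_valid(chars, cur_end, starts[j], barriers)) {
      res <- extend_chain(chars, starts, i, x, loop_min, loop_max, barriers,
                          c(chain, j))
      if (!is.null(res)) return(res)
    }
    j <- j + 1L
  }
  NULL
}

loop_valid <- function(chars, from, to, barriers) {
  if (any(chars[(from + 1L):to] == "N")) return(FALSE)
  if (!is.null(barriers) &&
      any(from < barriers[, 2] & to > barriers[, 1])) {
    return(FALSE)
  }
  TRUE
}

motifs_to_tibble <- function(motifs, classes, transcript_id) {
  if (length(motifs) == 0L) {
    return(tibble::tibble(
      transcript_id = character(), start = integer(), end = integer(),
      quartet_class = character(), tract_length = integer(),
      tract_starts = list(), loop1 = integer(), loop2 = integer(),
      loop3 = integer(), total_loop_length = integer(),
      loop_bin = integer(), region = character()
    ))
  }
  loops <- t(vapply(motifs, function(m) {
    diff(m$tract_starts) - m$tract_length
  }, integer(3)))
  total <- rowSums(loops)
  out <- tibble::tibble(
    transcript_id = transcript_id,
    start = vapply(motifs, function(m) as.integer(m$start), integer(1)),
    end = vapply(motifs, function(m) as.integer(m$end), integer(1)),
    quartet_class = classes,
    tract_length = vapply(motifs, function(m) as.integer(m$tract_length), integer(1)),
    tract_starts = lapply(motifs, function(m) as.integer(m$tract_starts)),
    loop1 = loops[, 1],
    loop2 = loops[, 2],
    loop3 = loops[, 3],
    total_loop_length = as.integer(total),
    loop_bin = assign_loop_bin(total),
    region = "WHOLE"
  )
  out[order(out$start), ]
}

#' Bin a motif's total loop length
#'
#' Maps total loop length (sum of the three loops) onto the discrete
#' loop-length classes 2/4/6/8/10 nt: totals of at most 3 nt fall in
#' bin 2, 4-5 in bin 4, 6-7 in bin 6, 8-9 in bin 8, and 10 nt or more
#' in bin 10. The bin edges are configurable.
#'
#' @param total_loop_length Integer vector of total loop lengths.
#' @param edges Upper edges (inclusive) of the first four bins.
#' @param bins Bin labels, one more than `edges`.
#' @return Integer vector of bin labels.
#' @export
assign_loop_bin <- function(total_loop_length, edges = c(3, 5, 7, 9),
                            bins = c(2L, 4L, 6L, 8L, 10L)) {
  stopifnot(length(bins) == length(edges) + 1L)
  idx <- findInterval(total_loop_length, edges + 1L) + 1L
  bins[idx]
}

#' Assign a motif to a genic region
#'
#' A motif is labelled with the region containing its larger overlap;
#' ties go to the downstream (more 3') region. Without boundaries the
#' label is `WHOLE`.
#'
#' @param start,end Motif span, 0-based half-open.
#' @param utr5_end,cds_end Transcript boundaries (may be `NA`).
#' @param length Transcript length.
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"WHOLE"`.
#' @export
assign_region <- function(start, end, utr5_end, cds_end, length) {
  if (is.na(utr5_end) || is.na(cds_end)) return("WHOLE")
  bounds <- rbind(
    c(0L, utr5_end),
    c(utr5_end, cds_end),
    c(cds_end, length)
  )
  overlap <- pmax(0L, pmin(end, bounds[, 2]) - pmax(start, bounds[, 1]))
  # which.max on the reversed vector implements the downstream tie-break
  REGION_LEVELS[4L - which.max(rev(overlap))]
}

#' Scan a transcript set for RG4 motifs
#'
#' Runs [scan_rg4()] on every transcript and assigns each motif to a
#' genic region when boundaries are available.
#'
#' @param transcripts Tibble from [load_transcripts()].
#' @inheritParams scan_rg4
#' @return A motif tibble (see [scan_rg4()]) over all transcripts.
#' @export
scan_transcripts <- function(transcripts, g2_tract = 2L, g3_tract = 3L,
                             loop_min = 1L, loop_max = 7L) {
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    m <- scan_rg4(transcripts$sequence[i], g2_tract, g3_tract,
                  loop_min, loop_max, transcript_id = transcripts$id[i])
    if (nrow(m)) {
      m$region <- vapply(seq_len(nrow(m)), function(j) {
        assign_region(m$start[j], m$end[j],
                      transcripts$utr5_end[i], transcripts$cds_end[i],
                      transcripts$length[i])
      }, character(1))
    }
    m
  })
  dplyr::bind_rows(res)
}

#' RG4 density per kilobase
#'
#' Density is the predicted motif count normalized to the total number
#' of bases, reported per 1000 nt. When motifs carry region labels the
#' summary contains one row per region (denominated by `region_bases`
#' when supplied, otherwise by the whole-transcriptome `total_bases`)
#' plus an overall row.
#'
#' @param motifs Motif tibble from [scan_transcripts()] or [scan_rg4()].
#' @param total_bases Total bases of the scanned transcript set.
#' @param region_bases Optional named vector of per-region base totals.
#' @return Tibble with `region`, `motif_count`, `total_bases`,
#'   `density_per_kb`.
#' @export
rg4_density <- function(motifs, total_bases, region_bases = NULL) {
  if (total_bases <= 0) stop("total_bases must be positive")
  regions <- setdiff(unique(motifs$region), "WHOLE")
  rows <- lapply(regions, function(r) {
    n <- sum(motifs$region == r)
    denom <- if (!is.null(region_bases) && r %in% names(region_bases)) {
      region_bases[[r]]
    } else {
      total_bases
    }
    if (denom <= 0) stop("Zero bases for region ", r)
    tibble::tibble(region = r, motif_count = n, total_bases = denom,
                   density_per_kb = 1000 * n / denom)
  })
  overall <- tibble::tibble(
    region = "WHOLE", motif_count = nrow(motifs), total_bases = total_bases,
    density_per_kb = 1000 * nrow(motifs) / total_bases
  )
  dplyr::bind_rows(c(rows, list(overall)))
}
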