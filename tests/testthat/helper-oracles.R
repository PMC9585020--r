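# Independent oracles: literal, enumeration-based implementations used
# only to cross-check the package's fast code paths.

# Gini as the literal double sum over all ordered pairs.
gini_bruteforce <- function(r) {
  n <- length(r)
  sum(abs(outer(r, r, "-"))) / (2 * n^2 * mean(r))
}

# Step-up Benjamini-Hochberg written out literally: sort ascending,
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1, back in input order.
bh_stepup_manual <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Maximal G runs of a character vector (0-based starts).
oracle_g_runs <- function(chars) {
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], len = r$lengths[keep])
}

# Enumerate every valid 4-tract placement for one quartet class, then
# resolve leftmost/non-overlapping by repeatedly taking the motif with
# the lexicographically smallest tract-start vector. Tracts are maximal
# G runs clipped to the class length from the 5' end; loops must lie in
# [loop_min, loop_max] and contain no N; spans must avoid `barriers`
# and candidate runs listed in `exclude_runs` are unusable.
oracle_pass <- function(chars, runs, x, loop_min, loop_max,
                        barriers = NULL, exclude_runs = integer(0)) {
  cand <- setdiff(which(runs$len >= x), exclude_runs)
  if (!is.null(barriers)) {
    cand <- cand[!vapply(cand, function(k) {
      any(runs$start[k] < barriers[, 2] &
            runs$start[k] + runs$len[k] > barriers[, 1])
    }, logical(1))]
  }
  if (length(cand) < 4L) return(list())
  s <- runs$start[cand]
  step_ok <- function(a, b) {
    gap <- s[b] - (s[a] + x)
    if (gap < loop_min || gap > loop_max) return(FALSE)
    loop <- chars[(s[a] + x + 1L):s[b]]
    if (any(loop == "N")) return(FALSE)
    if (!is.null(barriers) &&
        any((s[a] + x) < barriers[, 2] & s[b] > barriers[, 1])) {
      return(FALSE)
    }
    TRUE
  }
  quads <- list()
  nc <- length(cand)
  for (a in seq_len(nc - 3L)) for (b in (a + 1L):(nc - 2L)) {
    if (!step_ok(a, b)) next
    for (d in (b + 1L):(nc - 1L)) {
      if (!step_ok(b, d)) next
      for (e in (d + 1L):nc) {
        if (step_ok(d, e)) quads[[length(quads) + 1L]] <- c(a, b, d, e)
      }
    }
  }
  if (!length(quads)) return(list())
  starts_mat <- t(vapply(quads, function(q) s[q], numeric(4)))
  chosen <- list()
  pos <- 0
  repeat {
    avail <- which(starts_mat[, 1] >= pos)
    if (!length(avail)) break
    ord <- avail[do.call(order, as.data.frame(starts_mat[avail, , drop = FALSE]))]
    q <- quads[[ord[1]]]
    chosen[[length(chosen) + 1L]] <- list(
      start = s[q[1]], end = s[q[4]] + x,
      tract_starts = s[q], run_idx = cand[q]
    )
    pos <- s[q[4]] + x
  }
  chosen
}

# Full two-pass oracle scanner; returns the same columns scan_rg4 uses
# for comparison.
rg4_oracle <- function(sequence, g2_tract = 2L, g3_tract = 3L,
                       loop_min = 1L, loop_max = 7L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- oracle_g_runs(chars)
  g3 <- oracle_pass(chars, runs, g3_tract, loop_min, loop_max)
  barriers <- if (length(g3)) {
    cbind(vapply(g3, `[[`, numeric(1), "start"),
          vapply(g3, `[[`, numeric(1), "end"))
  } else NULL
  used <- unlist(lapply(g3, `[[`, "run_idx"))
  g2 <- oracle_pass(chars, runs, g2_tract, loop_min, loop_max,
                    barriers = barriers, exclude_runs = used)
  all <- c(g3, g2)
  cls <- c(rep("G3", length(g3)), rep("G2", length(g2)))
  if (!length(all)) {
    return(data.frame(start = integer(0), end = integer(0),
                      quartet_class = character(0)))
  }
  out <- data.frame(
    start = vapply(all, `[[`, numeric(1), "start"),
    end = vapply(all, `[[`, numeric(1), "end"),
    quartet_class = cls
  )
  out[order(out$start), ]
}

# random test sequence with a G-rich alphabet (and optional N)
random_rna <- function(len, n_prob = 0) {
  probs <- c(A = 0.24, C = 0.18, G = 0.34, U = 0.24)
  probs <- c(probs * (1 - n_prob), N = n_prob)
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

# compare scanner output with the oracle on one sequence
expect_scan_matches_oracle <- function(seq, ...) {
  got <- scan_rg4(seq, ...)
  want <- rg4_oracle(seq, ...)
  expect_equal(nrow(got), nrow(want), info = substr(seq, 1, 60))
  if (nrow(want)) {
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
    expect_equal(got$quartet_class, want$quartet_class)
  }
}

# self-validation: a motif's own slice must satisfy its pattern
expect_motif_self_consistent <- function(motifs, sequence,
                                         loop_min = 1L, loop_max = 7L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (j in seq_len(nrow(motifs))) {
    ts <- motifs$tract_starts[[j]]
    x <- motifs$tract_length[j]
    for (t in ts) expect_true(all(chars[(t + 1L):(t + x)] == "G"))
    loops <- diff(ts) - x
    expect_true(all(loops >= loop_min & loops <= loop_max))
    span <- chars[(motifs$start[j] + 1L):motifs$end[j]]
    expect_false(any(span == "N"))
    expect_equal(motifs$end[j] - motifs$start[j],
                 4L * x + motifs$total_loop_length[j])
  }
}
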