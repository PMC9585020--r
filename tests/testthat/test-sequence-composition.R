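write_fasta_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_ann_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

test_that("FASTA loading normalizes T to U and enforces region boundaries", {
  fa <- write_fasta_tmp(c(">tx1", "GGTACG"))
  tx <- load_transcripts(fa)
  expect_equal(tx$sequence, "GGUACG")
  expect_equal(tx$length, 6L)

  ann <- write_ann_tmp(tibble::tibble(transcript_id = "tx1",
                                      utr5_end = 2L, cds_end = 5L))
  tx <- load_transcripts(fa, ann)
  expect_equal(nchar(region_slice(tx[1, ], "FIVE_UTR")), 2L)
  expect_equal(region_slice(tx[1, ], "CDS"), "UAC")
  expect_equal(nchar(region_slice(tx[1, ], "THREE_UTR")), 1L)
  expect_equal(region_slice(tx[1, ], "WHOLE"), "GGUACG")

  bad <- write_ann_tmp(tibble::tibble(transcript_id = "tx1",
                                      utr5_end = 5L, cds_end = 2L))
  expect_error(load_transcripts(fa, bad), "boundaries")

  orphan <- write_ann_tmp(tibble::tibble(transcript_id = c("tx1", "txZ"),
                                         utr5_end = c(2L, 1L),
                                         cds_end = c(5L, 2L)))
  expect_warning(load_transcripts(fa, orphan), "txZ")
})

test_that("malformed or invalid FASTA input is rejected with a clear message", {
  noheader <- write_fasta_tmp(c("GGUACG", ">tx1"))
  expect_error(load_transcripts(noheader), "line 1")
  badchar <- write_fasta_tmp(c(">tx1", "GGXACG"))
  expect_error(load_transcripts(badchar), "tx1")
  fa <- write_fasta_tmp(c(">tx1", "ACGU"))
  tx <- load_transcripts(fa)
  expect_error(region_slice(tx[1, ], "FIVE_UTR"), "boundaries")
})

test_that("nucleotide frequencies pool counts and exclude N bases", {
  tx1 <- tibble::tibble(id = "a", sequence = "GGCC", length = 4L,
                        utr5_end = NA_integer_, cds_end = NA_integer_)
  f <- nucleotide_frequency(tx1)
  expect_equal(f$frequency[f$base == "G"], 0.5)
  expect_equal(f$frequency[f$base == "C"], 0.5)
  expect_equal(f$frequency[f$base == "A"], 0)

  tx2 <- tibble::tibble(id = "b", sequence = "AUGC", length = 4L,
                        utr5_end = NA_integer_, cds_end = NA_integer_)
  expect_equal(nucleotide_frequency(tx2)$frequency, rep(0.25, 4))

  pair <- tibble::tibble(id = c("a", "b"), sequence = c("GG", "AANN"),
                         length = c(2L, 4L),
                         utr5_end = NA_integer_, cds_end = NA_integer_)
  f <- nucleotide_frequency(pair)
  expect_equal(f$frequency[f$base == "G"], 0.5)
  expect_equal(f$frequency[f$base == "A"], 0.5)
  expect_equal(unique(f$total_unambiguous_bases), 4L)

  allN <- tibble::tibble(id = "n", sequence = "NNNN", length = 4L,
                         utr5_end = NA_integer_, cds_end = NA_integer_)
  expect_error(nucleotide_frequency(allN), "undefined")
})

test_that("composition is order-invariant and consistent under concatenation", {
  set.seed(42)
  for (rep in 1:10) {
    seqs <- vapply(1:5, function(i) random_rna(sample(50:200, 1), n_prob = 0.02),
                   character(1))
    tx <- tibble::tibble(id = paste0("t", 1:5), sequence = seqs,
                         length = nchar(seqs),
                         utr5_end = NA_integer_, cds_end = NA_integer_)
    f1 <- nucleotide_frequency(tx)
    perm <- tx[sample(5), ]
    f2 <- nucleotide_frequency(perm)
    expect_equal(f1$frequency, f2$frequency)
    expect_equal(sum(f1$frequency), 1, tolerance = 1e-9)

    concat <- tibble::tibble(id = "cat", sequence = paste(seqs, collapse = ""),
                             length = sum(nchar(seqs)),
                             utr5_end = NA_integer_, cds_end = NA_integer_)
    expect_equal(f1$frequency, nucleotide_frequency(concat)$frequency)
  }
})

test_that("per-transcript averaging is exposed as an alternative to pooling", {
  tx <- tibble::tibble(id = c("short", "long"), sequence = c("GG", "AAAAAAAA"),
                       length = c(2L, 8L),
                       utr5_end = NA_integer_, cds_end = NA_integer_)
  pooled <- nucleotide_frequency(tx)
  averaged <- nucleotide_frequency(tx, per_transcript_mean = TRUE)
  expect_equal(pooled$frequency[pooled$base == "G"], 0.2)
  expect_equal(averaged$frequency[averaged$base == "G"], 0.5)
})
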