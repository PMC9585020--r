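#' @importFrom rlang .data
NULL

RNA_ALPHABET <- c("A", "C", "G", "U", "N")
REGION_LEVELS <- c("FIVE_UTR", "CDS", "THREE_UTR", "WHOLE")

#' Load transcript sequences and optional genic-region annotation
#'
#' Reads a (multi-record) FASTA file of transcript sequences, normalizes
#' T to U, and optionally attaches transcript-relative 5'-UTR/CDS/3'-UTR
#' boundaries from a tab-separated annotation file. All coordinates are
#' 0-based, half-open: the 5'-UTR is `[0, utr5_end)`, the CDS is
#' `[utr5_end, cds_end)` and the 3'-UTR is `[cds_end, length)`.
#'
#' @param fasta_path Path to a FASTA file. Sequences may use T or U;
#'   `N` is accepted as the only ambiguity code.
#' @param annotation_path Optional path to a TSV with header columns
#'   `transcript_id`, `utr5_end`, `cds_end` (0-based half-open boundary
#'   offsets). Annotation rows whose ids are absent from the FASTA are
#'   reported with a warning and dropped.
#' @return A tibble with one row per FASTA record and columns `id`,
#'   `sequence` (over A/C/G/U/N), `length`, `utr5_end`, `cds_end`
#'   (the latter two `NA` when unannotated).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "GGTACG"), fa)
#' load_transcripts(fa)
#' @export
load_transcripts <- function(fasta_path, annotation_path = NULL) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  validate_fasta_lines(fasta_path)
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", fasta_path)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  bad <- vapply(seqs, function(s) grepl("[^ACGUN]", s), logical(1))
  if (any(bad)) {
    stop(
      "Sequence characters outside {A,C,G,U,N} in transcript(s): ",
      paste(ids[bad], collapse = ", ")
    )
  }
  if (anyDuplicated(ids)) {
    stop("Duplicated FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tx <- tibble::tibble(
    id = ids,
    sequence = unname(seqs),
    length = nchar(unname(seqs)),
    utr5_end = NA_integer_,
    cds_end = NA_integer_
  )
  if (any(tx$length < 1L)) {
    stop("Empty sequence for transcript(s): ", paste(tx$id[tx$length < 1L], collapse = ", "))
  }
  if (!is.null(annotation_path)) {
    ann <- read_region_annotation(annotation_path)
    missing <- setdiff(ann$transcript_id, tx$id)
    if (length(missing) > 0L) {
      warning(
        "Annotation ids absent from FASTA (dropped): ",
        paste(missing, collapse = ", ")
      )
      ann <- ann[!ann$transcript_id %in% missing, ]
    }
    idx <- match(tx$id, ann$transcript_id)
    tx$utr5_end <- ann$utr5_end[idx]
    tx$cds_end <- ann$cds_end[idx]
    validate_boundaries(tx)
  }
  tx
}

# Cheap structural check so a malformed FASTA fails with a line number
# instead of an opaque parser error.
validate_fasta_lines <- function(fasta_path) {
  lines <- readLines(fasta_path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: file is empty: ", fasta_path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("FASTA parse error at line ", first, ": expected header starting with '>'")
  }
  invisible(TRUE)
}

read_region_annotation <- function(annotation_path) {
  ann <- readr::read_tsv(
    annotation_path,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      utr5_end = readr::col_integer(),
      cds_end = readr::col_integer()
    ),
    progress = FALSE
  )
  required <- c("transcript_id", "utr5_end", "cds_end")
  if (!all(required %in% names(ann))) {
    stop(
      "Annotation must have header columns ",
      paste(required, collapse = ", ")
    )
  }
  ann
}

validate_boundaries <- function(tx) {
  has <- !is.na(tx$utr5_end)
  bad <- has & (
    tx$utr5_end < 0L |
      tx$utr5_end > tx$cds_end |
      tx$cds_end > tx$length |
      is.na(tx$cds_end)
  )
  if (any(bad)) {
    stop(
      "Invalid region boundaries (need 0 <= utr5_end <= cds_end <= length) for: ",
      paste(tx$id[bad], collapse = ", ")
    )
  }
  invisible(tx)
}

#' Extract one genic region from a transcript record
#'
#' @param transcript A single transcript: either a one-row tibble from
#'   [load_transcripts()] or a list with `sequence` and (for regions other
#'   than `"WHOLE"`) `utr5_end`, `cds_end`.
#' @param region One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"WHOLE"`.
#' @return The region subsequence as a character scalar (possibly `""`).
#' @export
region_slice <- function(transcript, region = "WHOLE") {
  region <- match.arg(region, REGION_LEVELS)
  seq <- transcript$sequence
  if (length(seq) != 1L) stop("region_slice() expects a single transcript")
  if (region == "WHOLE") return(seq)
  u5 <- transcript$utr5_end
  cd <- transcript$cds_end
  if (is.null(u5) || is.null(cd) || is.na(u5) || is.na(cd)) {
    stop("Region ", region, " requested but transcript has no boundaries")
  }
  len <- nchar(seq)
  # 0-based half-open bounds -> substr's 1-based closed coordinates
  bounds <- switch(region,
    FIVE_UTR = c(0L, u5),
    CDS = c(u5, cd),
    THREE_UTR = c(cd, len)
  )
  if (bounds[1] >= bounds[2]) return("")
  substr(seq, bounds[1] + 1L, bounds[2])
}

#' Pooled nucleotide composition of a transcript set
#'
#' Counts A/C/G/U over the requested genic region of every transcript and
#' returns transcriptome-level frequencies. `N` bases are excluded from
#' both the numerator and the denominator. By default counts are pooled
#' over all concatenated bases; `per_transcript_mean = TRUE` instead
#' averages per-transcript frequency vectors (transcripts with an empty
#' region are skipped).
#'
#' @param transcripts Tibble from [load_transcripts()].
#' @param region Region label; non-`WHOLE` regions require boundaries.
#' @param per_transcript_mean Average per-transcript frequencies instead
#'   of pooling counts.
#' @return A tibble with columns `region`, `base`, `count`, `frequency`,
#'   `total_unambiguous_bases`. Under `per_transcript_mean` the `count`
#'   column still holds pooled counts; only `frequency` changes meaning.
#' @examples
#' tx <- tibble::tibble(id = "t1", sequence = "AUGC", length = 4L,
#'                      utr5_end = NA_integer_, cds_end = NA_integer_)
#' nucleotide_frequency(tx)
#' @export
nucleotide_frequency <- function(transcripts, region = "WHOLE",
                                 per_transcript_mean = FALSE) {
  region <- match.arg(region, REGION_LEVELS)
  slices <- vapply(
    seq_len(nrow(transcripts)),
    function(i) region_slice(transcripts[i, ], region),
    character(1)
  )
  counts <- base_count_matrix(slices)
  pooled <- colSums(counts)
  total <- sum(pooled)
  if (total == 0L) {
    stop("No unambiguous bases in region ", region, "; frequencies undefined")
  }
  if (per_transcript_mean) {
    rowtot <- rowSums(counts)
    keep <- rowtot > 0
    freq <- colMeans(counts[keep, , drop = FALSE] / rowtot[keep])
  } else {
    freq <- pooled / total
  }
  tibble::tibble(
    region = region,
    base = c("A", "C", "G", "U"),
    count = as.integer(pooled),
    frequency = unname(freq),
    total_unambiguous_bases = as.integer(total)
  )
}

# per-sequence counts of the four unambiguous bases (rows = sequences)
base_count_matrix <- function(seqs) {
  bases <- c("A", "C", "G", "U")
  out <- sapply(bases, function(b) {
    vapply(seqs, function(s) {
      if (!nzchar(s)) 0L else sum(charToRaw(s) == charToRaw(b))
    }, integer(1), USE.NAMES = FALSE)
  })
  matrix(out, ncol = 4L, dimnames = list(NULL, bases))
}

#' Composition profiles for all regions of an annotated transcript set
#'
#' Convenience wrapper running [nucleotide_frequency()] for each region
#' (plus `WHOLE`) and binding the results into one tidy table.
#'
#' @inheritParams nucleotide_frequency
#' @param regions Regions to profile; defaults to all four labels when
#'   boundaries are present, otherwise `WHOLE` only.
#' @export
composition_profile <- function(transcripts, regions = NULL,
                                per_transcript_mean = FALSE) {
  if (is.null(regions)) {
    regions <- if (all(is.na(transcripts$utr5_end))) "WHOLE" else REGION_LEVELS
  }
  dplyr::bind_rows(lapply(regions, function(r) {
    nucleotide_frequency(transcripts, r, per_transcript_mean)
  }))
}
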