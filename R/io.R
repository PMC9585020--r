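#' Write transcripts to FASTA and annotation TSV
#'
#' @param transcripts Tibble as produced by [load_transcripts()] or
#'   [simulate_transcriptome()].
#' @param fasta_path Output FASTA path.
#' @param annotation_path Optional output TSV path for the boundary
#'   annotation (`transcript_id`, `utr5_end`, `cds_end`).
#' @return Invisibly, the FASTA path.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path = NULL) {
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(annotation_path)) {
    ann <- tibble::tibble(
      transcript_id = transcripts$id,
      utr5_end = transcripts$utr5_end,
      cds_end = transcripts$cds_end
    )
    readr::write_tsv(ann[!is.na(ann$utr5_end), ], annotation_path)
  }
  invisible(fasta_path)
}

#' Read a SHALiPE stop-count table
#'
#' Expects a TSV with columns `site_id`, `condition`, `position`,
#' `count` and optionally `library` (replicate libraries are merged
#' downstream by [merge_replicates()]).
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_stop_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("site_id", "condition", "position", "count")
  if (!all(required %in% names(out))) {
    stop("Stop-count table needs columns ", paste(required, collapse = ", "))
  }
  out
}

#' Read a transcription-arrest time-course table
#'
#' TSV columns: `transcript_id`, `condition`, `time`, `replicate`,
#' `abundance` (a `time_min` column is accepted and renamed).
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_timecourse <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("time_min" %in% names(out) && !"time" %in% names(out)) {
    names(out)[names(out) == "time_min"] <- "time"
  }
  required <- c("transcript_id", "condition", "time", "replicate", "abundance")
  if (!all(required %in% names(out))) {
    stop("Time-course table needs columns ", paste(required, collapse = ", "))
  }
  out
}

#' Read an occurrence-level bioclim table
#'
#' CSV columns: `species`, `latitude`, `longitude`, plus any of
#' `BIO1`..`BIO19` (values as supplied upstream; no unit rescaling).
#'
#' @param path Input CSV path.
#' @return A tibble.
#' @export
read_occurrence_bioclim <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"species" %in% names(out)) stop("Bioclim table needs a species column")
  if (!any(BIOCLIM_VARS %in% names(out))) {
    stop("Bioclim table carries none of BIO1..BIO19")
  }
  out
}
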