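# Kdm8 targeted quantification: positional trimming, best-window transcript
# assignment, UMI collapse, zero imputation and bimodal status calling.

#' Positional trimming of Kdm8-assay reads
#'
#' Removes the constant first `prefix_length` bases of read 2; reads not
#' longer than the prefix are dropped (`NA`).
#'
#' @param read2 Character vector of read-2 sequences.
#' @param prefix_length Number of leading bases to remove (default 26).
#' @return Character vector of payloads, `NA` for dropped reads.
#' @export
trim_kdm8 <- function(read2, prefix_length = 26L) {
  out <- rep(NA_character_, length(read2))
  keep <- nchar(read2) > prefix_length
  out[keep] <- substring(read2[keep], prefix_length + 1L)
  out
}

# Minimal substitution distance of each payload to any contiguous window of
# the transcript. Vectorised over the windows for each unique payload.
best_window_distance <- function(payloads, transcript) {
  t_chars <- strsplit(transcript, "", fixed = TRUE)[[1]]
  Lt <- length(t_chars)
  vapply(payloads, function(p) {
    pc <- strsplit(p, "", fixed = TRUE)[[1]]
    Lp <- length(pc)
    if (Lp > Lt) return(min_window_distance(pc, t_chars))
    nwin <- Lt - Lp + 1L
    # windows as a Lp x nwin matrix of transcript characters
    W <- matrix(t_chars[outer(seq_len(Lp), 0:(nwin - 1L), `+`)], nrow = Lp)
    min(colSums(W != pc))
  }, 0)
}

#' Quantify Kdm8 expression per cell with zero imputation
#'
#' Assigns each payload to the Kdm8 transcript when its best-window
#' substitution distance is at most `max_mismatch_rate` of the payload
#' length, collapses assigned reads into distinct (cell barcode, UMI) pairs,
#' and reports every cell of the experiment: cells without any assigned
#' signal are imputed as zero. Normalised abundance is the UMI count divided
#' by the cell's transcriptome UMI count, scaled by `depth_scale`.
#'
#' @param tags data.frame with columns `cell_barcode`, `umi`, `payload`
#'   (`NA` payloads ignored).
#' @param transcript Kdm8 transcript sequence (character scalar).
#' @param all_cells Character vector of every cell barcode in the experiment.
#' @param transcriptome data.frame with `cell_barcode` and
#'   `transcriptome_umis`.
#' @param max_mismatch_rate Maximum tolerated mismatch fraction (default
#'   0.1).
#' @param depth_scale Depth scale factor; default is the median transcriptome
#'   UMI count.
#' @param threshold_umis Positive/negative threshold passed to
#'   [classify_status()].
#' @return data.frame of class `kdm8_calls` with one row per cell in
#'   `all_cells`: `cell_barcode`, `kdm8_umis`, `normalized_abundance`,
#'   `status`.
#' @export
quantify_kdm8 <- function(tags, transcript, all_cells, transcriptome,
                          max_mismatch_rate = 0.1, depth_scale = NULL,
                          threshold_umis = 1L) {
  stop_unless(length(all_cells) > 0, "all_cells must be non-empty")
  stop_unless(!anyDuplicated(all_cells), "all_cells must be unique")
  if (is.null(depth_scale)) {
    depth_scale <- median(transcriptome$transcriptome_umis)
  }
  x <- tags[!is.na(tags$payload) & nchar(tags$payload) > 0, , drop = FALSE]
  umis <- setNames(integer(length(all_cells)), all_cells)
  if (nrow(x)) {
    up <- unique(x$payload)
    d <- best_window_distance(up, transcript)
    assigned_payload <- up[d <= max_mismatch_rate * nchar(up)]
    x <- x[x$payload %in% assigned_payload, , drop = FALSE]
    x <- x[x$cell_barcode %in% all_cells, , drop = FALSE]
    if (nrow(x)) {
      pairs <- unique(x[c("cell_barcode", "umi")])
      tab <- table(pairs$cell_barcode)
      umis[names(tab)] <- as.integer(tab)
    }
  }
  tu <- transcriptome$transcriptome_umis[match(all_cells,
                                               transcriptome$cell_barcode)]
  norm <- ifelse(!is.na(tu) & tu > 0, umis / tu * depth_scale, NA_real_)
  norm[umis == 0] <- 0
  calls <- structure(
    data.frame(cell_barcode = all_cells,
               kdm8_umis = unname(umis),
               normalized_abundance = unname(norm),
               status = NA_character_,
               stringsAsFactors = FALSE),
    class = c("kdm8_calls", "data.frame")
  )
  classify_status(calls, threshold_umis)
}

#' Set the positive/negative Kdm8 status
#'
#' A cell is Kdm8-positive iff it has at least `threshold_umis` collapsed
#' UMIs. The positive fraction is monotone non-increasing in the threshold.
#'
#' @param calls A `kdm8_calls` data.frame from [quantify_kdm8()].
#' @param threshold_umis Minimum UMI count for a positive call (>= 1).
#' @return `calls` with the `status` column set.
#' @export
classify_status <- function(calls, threshold_umis = 1L) {
  if (threshold_umis < 1) {
    stop("invalid threshold: threshold_umis must be >= 1", call. = FALSE)
  }
  calls$status <- ifelse(calls$kdm8_umis >= threshold_umis,
                         "positive", "negative")
  calls
}

#' Run the Kdm8 quantification pipeline on paired FASTQ
#'
#' @param r1_path,r2_path Paired FASTQ paths.
#' @param transcript_path Kdm8 transcript FASTA.
#' @param cells_path TSV with `cell_barcode` and `transcriptome_umis`
#'   covering all cells of the experiment.
#' @param out_path Optional path for the per-cell call TSV.
#' @param prefix_length Positional trim length (default 26).
#' @param ... Further arguments passed to [quantify_kdm8()].
#' @return A `kdm8_calls` data.frame.
#' @export
kdm8_pipeline <- function(r1_path, r2_path, transcript_path, cells_path,
                          out_path = NULL, prefix_length = 26L, ...) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  transcript <- unname(read_reference(transcript_path)[1])
  cells <- read_tsv(cells_path)
  tags <- tag_reads(unname(r1), unname(r2))
  tags$payload <- trim_kdm8(tags$read2, prefix_length = prefix_length)
  calls <- quantify_kdm8(tags, transcript, cells$cell_barcode, cells, ...)
  if (!is.null(out_path)) write_tsv(calls, out_path)
  calls
}
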