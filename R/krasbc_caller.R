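# Kras barcode (KrasBC) caller: error-tolerant anchored trimming, allele
# assignment by substitution distance, UMI collapse, near-identical barcode
# merging, clonotype calling and allelic-imbalance classification.

KRASBC_ADAPTER_5P <- "CTCTATCGTAGGGTCATA"
KRASBC_ADAPTER_3P <- "CATTTTCAGCAGGCCT"

# Best substitution-only alignment of `pattern` as a contiguous window inside
# each of `reads`. Returns list(offset, mismatches) per read; offset is the
# 0-based window start of the leftmost minimal-mismatch window with
# mismatches <= max_mm, or NA if none qualifies. Vectorised across reads.
scan_anchor <- function(reads, pattern, max_mm) {
  n <- length(reads)
  lens <- nchar(reads)
  L <- nchar(pattern)
  W <- max(lens, L)
  padded <- paste0(reads, strrep("N", W - lens))
  M <- seq_char_matrix(padded)           # W x n
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  best_mm <- rep(Inf, n)
  best_off <- rep(NA_integer_, n)
  for (off in 0:(W - L)) {
    mm <- colSums(M[(off + 1L):(off + L), , drop = FALSE] != pat)
    ok <- lens >= off + L & mm <= max_mm & mm < best_mm
    best_mm[ok] <- mm[ok]
    best_off[ok] <- off
  }
  list(offset = best_off, mismatches = ifelse(is.finite(best_mm), best_mm, NA))
}

#' Error-tolerant anchored trimming of barcode-assay reads
#'
#' Removes a required 5' anchor (matched anywhere in the read with up to
#' `floor(max_error_rate * nchar(anchor))` substitutions; leftmost minimal-
#' mismatch window wins) and, if present under the same error rate, an
#' optional 3' anchor, truncating the payload before it. Reads without a 5'
#' anchor match, or whose payload is empty after trimming, are dropped
#' (returned as `NA`).
#'
#' @param read2 Character vector of read-2 sequences.
#' @param max_error_rate Allowed substitution rate within an anchor
#'   (default 0.2, i.e. 3 errors in the 18-nt 5' anchor).
#' @param adapter_5p,adapter_3p Anchor sequences.
#' @return Character vector of payloads, `NA` for dropped reads.
#' @examples
#' trim_krasbc(paste0("CTCTATCGTAGGGTCATA", "ACGTACGT", "CATTTTCAGCAGGCCT"))
#' @export
trim_krasbc <- function(read2, max_error_rate = 0.2,
                        adapter_5p = KRASBC_ADAPTER_5P,
                        adapter_3p = KRASBC_ADAPTER_3P) {
  if (!length(read2)) return(character(0))
  stop_unless(all(nchar(read2) > 0), "reads must be non-empty")
  reads <- toupper(read2)
  hit5 <- scan_anchor(reads, toupper(adapter_5p),
                      floor(max_error_rate * nchar(adapter_5p)))
  payload <- rep(NA_character_, length(reads))
  keep <- !is.na(hit5$offset)
  payload[keep] <- substring(reads[keep],
                             hit5$offset[keep] + nchar(adapter_5p) + 1L)
  nz <- which(!is.na(payload) & nchar(payload) > 0)
  if (length(nz)) {
    hit3 <- scan_anchor(payload[nz], toupper(adapter_3p),
                        floor(max_error_rate * nchar(adapter_3p)))
    found <- !is.na(hit3$offset)
    payload[nz[found]] <- substring(payload[nz[found]], 1L,
                                    hit3$offset[found])
  }
  payload[!is.na(payload) & nchar(payload) == 0] <- NA_character_
  payload
}

# Minimal substitution distance between one payload and one reference,
# sliding the shorter sequence along the longer.
min_window_distance <- function(a_chars, b_chars) {
  if (length(a_chars) > length(b_chars)) {
    tmp <- a_chars; a_chars <- b_chars; b_chars <- tmp
  }
  La <- length(a_chars); Lb <- length(b_chars)
  best <- Inf
  for (off in 0:(Lb - La)) {
    d <- sum(a_chars != b_chars[(off + 1L):(off + La)])
    if (d < best) best <- d
  }
  best
}

#' Assign payloads to wildtype or barcode alleles
#'
#' Each payload is assigned to the reference sequence with minimal
#' substitution distance, provided that distance is at most
#' `ceiling(max_mismatch_rate * nchar(payload))` and the best reference beats
#' the runner-up by at least one mismatch; otherwise the read is unassigned
#' (`NA`). Payloads whose length differs from a reference are compared over
#' the best contiguous window of the shorter within the longer.
#'
#' @param payload Character vector of trimmed payloads (`NA` allowed).
#' @param reference Named character vector of reference sequences, the
#'   wildtype record being named `Kras_WT` (see [write_reference()]).
#' @param max_mismatch_rate Maximum tolerated mismatch fraction.
#' @return Character vector of labels (`"Kras_WT"`, a `barcode_id`, or `NA`).
#' @export
assign_allele <- function(payload, reference, max_mismatch_rate = 0.1) {
  stop_unless(length(reference) > 0, "reference must be non-empty")
  stop_unless(!is.null(names(reference)) && all(nzchar(names(reference))),
              "reference must be named")
  out <- rep(NA_character_, length(payload))
  ok <- which(!is.na(payload) & nchar(payload) > 0)
  if (!length(ok)) return(out)
  up <- unique(payload[ok])
  ref_chars <- lapply(reference, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ref_len <- nchar(reference)
  labels <- rep(NA_character_, length(up))
  for (len in unique(nchar(up))) {
    sel <- which(nchar(up) == len)
    P <- seq_char_matrix(up[sel])               # len x n
    D <- matrix(Inf, nrow = length(sel), ncol = length(reference))
    for (r in seq_along(reference)) {
      if (ref_len[r] == len) {
        D[, r] <- colSums(P != ref_chars[[r]])
      } else {
        D[, r] <- apply(P, 2, function(p) min_window_distance(p, ref_chars[[r]]))
      }
    }
    max_d <- ceiling(max_mismatch_rate * len)
    for (i in seq_along(sel)) {
      d <- D[i, ]
      b <- which.min(d)
      second <- if (length(d) > 1L) min(d[-b]) else Inf
      if (d[b] <= max_d && second - d[b] >= 1) {
        labels[sel[i]] <- names(reference)[b]
      }
    }
  }
  out[ok] <- labels[match(payload[ok], up)]
  out
}

#' Split read-1 sequences into cell barcode and UMI
#'
#' @param r1 Character vector of read-1 sequences (cell barcode + UMI).
#' @param r2 Parallel character vector of read-2 sequences.
#' @param cellbc_length,umi_length Cell-barcode and UMI lengths.
#' @return data.frame with `cell_barcode`, `umi`, `read2`.
#' @export
tag_reads <- function(r1, r2, cellbc_length = 16L, umi_length = 10L) {
  stop_unless(length(r1) == length(r2), "r1 and r2 must be parallel")
  stop_unless(all(nchar(r1) >= cellbc_length + umi_length),
              "read 1 shorter than cell barcode + UMI")
  data.frame(cell_barcode = substr(r1, 1L, cellbc_length),
             umi = substr(r1, cellbc_length + 1L, cellbc_length + umi_length),
             read2 = r2, stringsAsFactors = FALSE)
}

#' Collapse assigned reads into per-cell, per-allele UMI counts
#'
#' One UMI is counted once per distinct (cell barcode, allele, UMI) triple;
#' the collapse key includes the allele, so the same UMI observed under
#' wildtype and under a barcode in one cell counts once under each.
#' Unassigned reads (`NA` allele) are ignored.
#'
#' @param assignments data.frame with columns `cell_barcode`, `umi`,
#'   `allele`.
#' @return data.frame with columns `cell_barcode`, `allele`, `umis`.
#' @export
collapse_umis <- function(assignments) {
  stop_unless(all(c("cell_barcode", "umi", "allele") %in% names(assignments)),
              "assignments must have cell_barcode, umi, allele")
  x <- assignments[!is.na(assignments$allele),
                   c("cell_barcode", "allele", "umi")]
  if (!nrow(x)) {
    return(data.frame(cell_barcode = character(0), allele = character(0),
                      umis = integer(0), stringsAsFactors = FALSE))
  }
  x <- unique(x)
  agg <- aggregate(list(umis = x$umi),
                   by = list(cell_barcode = x$cell_barcode, allele = x$allele),
                   FUN = length)
  agg[order(agg$cell_barcode, agg$allele), , drop = FALSE]
}

#' Merge near-identical barcodes within a cell
#'
#' Within one cell, any barcode whose edit distance to a higher-count barcode
#' is below `max_distance` donates its UMIs to that barcode (sequencing-error
#' absorption). Barcodes are processed greedily from highest pre-merge count
#' downward, ties broken lexicographically, so the result is deterministic.
#'
#' @param barcode_umis Named numeric vector: pre-merge UMI count per barcode.
#' @param max_distance Strict upper bound on the edit distance (`< 3` by
#'   default).
#' @param metric `"levenshtein"` (default) or `"hamming"` (equal lengths
#'   only).
#' @param seqs Optional named character vector mapping barcode names to the
#'   sequences distances are computed on; defaults to the names themselves.
#' @return Named numeric vector of merged counts (surviving barcodes only).
#' @examples
#' merge_barcodes(c(AAAA = 10, AAAT = 1))  # AAAT absorbed into AAAA
#' @export
merge_barcodes <- function(barcode_umis, max_distance = 3,
                           metric = c("levenshtein", "hamming"),
                           seqs = NULL) {
  metric <- match.arg(metric)
  if (length(barcode_umis) <= 1L) return(barcode_umis)
  ids <- names(barcode_umis)
  stop_unless(!is.null(ids) && !anyDuplicated(ids),
              "barcode_umis must have unique names")
  s <- if (is.null(seqs)) ids else unname(seqs[ids])
  d <- if (metric == "levenshtein") {
    adist(s, s)
  } else {
    stop_unless(length(unique(nchar(s))) == 1L,
                "hamming metric requires equal-length barcodes")
    M <- seq_char_matrix(s)
    n <- length(s)
    outer(seq_len(n), seq_len(n),
          Vectorize(function(i, j) sum(M[, i] != M[, j])))
  }
  ord <- order(-barcode_umis, ids)
  merged <- barcode_umis
  absorbed <- rep(FALSE, length(ids))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (absorbed[i]) next
    if (k < length(ord)) {
      lower <- ord[(k + 1L):length(ord)]
      take <- lower[!absorbed[lower] & d[i, lower] < max_distance]
      if (length(take)) {
        merged[i] <- merged[i] + sum(merged[take])
        absorbed[take] <- TRUE
      }
    }
  }
  merged[!absorbed]
}

#' Per-cell allele counts
#'
#' Container for one cell's targeted-assay counts, the input to
#' [call_clonotype()].
#'
#' @param cell_barcode Cell barcode string.
#' @param wt_umis Wildtype Kras UMI count.
#' @param barcode_umis Named numeric vector of per-barcode UMI counts
#'   (post-merge).
#' @param transcriptome_umis Whole-transcriptome UMI count of the cell.
#' @param depth_scale Positive sequencing-depth scale factor (the per-sample
#'   median transcriptome UMI count in the pipeline).
#' @return An object of class `cell_allele_counts`.
#' @export
cell_allele_counts <- function(cell_barcode, wt_umis, barcode_umis = numeric(0),
                               transcriptome_umis, depth_scale = 1) {
  stop_unless(wt_umis >= 0 && all(barcode_umis >= 0), "counts must be >= 0")
  stop_unless(depth_scale > 0, "depth_scale must be positive")
  structure(
    list(cell_barcode = cell_barcode, wt_umis = wt_umis,
         barcode_umis = barcode_umis,
         transcriptome_umis = transcriptome_umis, depth_scale = depth_scale),
    class = "cell_allele_counts"
  )
}

# vectorised imbalance rule on dominant-barcode and wildtype UMI counts
imbalance_state_from_counts <- function(g12d, wt, min_total = 4,
                                        high_fraction = 0.75) {
  t <- g12d + wt
  state <- rep("balanced", length(t))
  state[g12d / t >= high_fraction] <- "g12d_high"
  state[wt / t >= high_fraction] <- "wt_high"
  state[t < min_total] <- "indeterminate"
  state
}

#' Classify the allelic-imbalance state of a malignant cell
#'
#' With `t` the dominant-barcode plus wildtype UMI total: cells with
#' `t < min_total` are indeterminate; otherwise the cell is `g12d_high`
#' (mutant fraction >= `high_fraction`), `wt_high` (wildtype fraction >=
#' `high_fraction`) or `balanced`.
#'
#' @param call A `clonotype_call` with `cell_class == "malignant"`.
#' @param counts The matching [cell_allele_counts()].
#' @param min_total Minimum informative UMI total.
#' @param high_fraction Skew threshold.
#' @return One of `"balanced"`, `"g12d_high"`, `"wt_high"`,
#'   `"indeterminate"`.
#' @export
classify_imbalance <- function(call, counts, min_total = 4,
                               high_fraction = 0.75) {
  stop_unless(identical(call$cell_class, "malignant"),
              "classify_imbalance requires a malignant cell")
  g12d <- unname(counts$barcode_umis[call$dominant_barcode])
  imbalance_state_from_counts(g12d, counts$wt_umis, min_total, high_fraction)
}

#' Call the clonotype of one cell
#'
#' Applies the rule set of the barcode assay to post-merge counts: the
#' dominant barcode is the unique argmax of the barcode UMI counts (a tie
#' excludes the cell); a cell with no barcode UMIs is somatic if it has at
#' least `min_wt_somatic` wildtype UMIs and excluded otherwise; cells with a
#' unique dominant barcode are malignant. Kras abundance is the wildtype plus
#' barcode UMI total normalised by the transcriptome UMI count and scaled by
#' `depth_scale`; a cell with no transcriptome UMIs is excluded and its
#' abundance undefined.
#'
#' @param counts A [cell_allele_counts()] (post-merge).
#' @param min_wt_somatic Minimum wildtype UMIs for the somatic call
#'   ("more than one copy" = at least 2).
#' @param min_total,high_fraction Passed to [classify_imbalance()].
#' @return An object of class `clonotype_call`: list with `cell_barcode`,
#'   `dominant_barcode`, `cell_class`, `imbalance_state`, `wt_umis`,
#'   `g12d_umis`, `kras_abundance`.
#' @export
call_clonotype <- function(counts, min_wt_somatic = 2,
                           min_total = 4, high_fraction = 0.75) {
  bc <- counts$barcode_umis
  bc <- bc[bc > 0]
  wt <- counts$wt_umis
  tu <- counts$transcriptome_umis
  abundance <- if (!is.na(tu) && tu > 0) {
    (wt + sum(bc)) / tu * counts$depth_scale
  } else {
    NA_real_
  }
  dominant <- NA_character_
  state <- NA_character_
  g12d <- 0
  if (is.na(tu) || tu <= 0) {
    class <- "excluded"
    abundance <- NA_real_
  } else if (!length(bc)) {
    class <- if (wt >= min_wt_somatic) "somatic" else "excluded"
  } else {
    winners <- names(bc)[bc == max(bc)]
    if (length(winners) > 1L) {
      class <- "excluded"   # tied dominant barcode signals noise
    } else {
      class <- "malignant"
      dominant <- winners
      g12d <- unname(bc[dominant])
    }
  }
  call <- structure(
    list(cell_barcode = counts$cell_barcode, dominant_barcode = dominant,
         cell_class = class, imbalance_state = state,
         wt_umis = wt, g12d_umis = g12d, kras_abundance = abundance),
    class = "clonotype_call"
  )
  if (class == "malignant") {
    call$imbalance_state <- classify_imbalance(call, counts, min_total,
                                               high_fraction)
  }
  call
}

#' Call clonotypes for all cells of an experiment
#'
#' Merges near-identical barcodes within each cell, then applies
#' [call_clonotype()] to every cell in the transcriptome table (cells with no
#' targeted reads have zero counts and fall into the somatic/excluded rule).
#'
#' @param counts_table Long data.frame from [collapse_umis()]
#'   (`cell_barcode`, `allele`, `umis`).
#' @param transcriptome data.frame with `cell_barcode` and
#'   `transcriptome_umis` covering all cells of the experiment.
#' @param depth_scale Depth scale factor; default is the median transcriptome
#'   UMI count over all cells.
#' @param max_distance,metric Barcode-merging parameters
#'   (see [merge_barcodes()]).
#' @param min_wt_somatic,min_total,high_fraction Calling parameters
#'   (see [call_clonotype()]).
#' @return data.frame of class `clonotype_calls` with one row per cell:
#'   `cell_barcode`, `dominant_barcode`, `cell_class`, `imbalance_state`,
#'   `wt_umis`, `g12d_umis`, `kras_abundance`.
#' @export
call_clonotypes <- function(counts_table, transcriptome,
                            depth_scale = NULL,
                            max_distance = 3, metric = "levenshtein",
                            min_wt_somatic = 2, min_total = 4,
                            high_fraction = 0.75) {
  stop_unless(all(c("cell_barcode", "transcriptome_umis") %in%
                    names(transcriptome)),
              "transcriptome must have cell_barcode and transcriptome_umis")
  if (is.null(depth_scale)) {
    depth_scale <- median(transcriptome$transcriptome_umis)
  }
  by_cell <- split(counts_table[c("allele", "umis")],
                   counts_table$cell_barcode)
  rows <- lapply(seq_len(nrow(transcriptome)), function(i) {
    cb <- transcriptome$cell_barcode[i]
    tab <- by_cell[[cb]]
    wt <- 0
    bc <- numeric(0)
    if (!is.null(tab)) {
      wt <- sum(tab$umis[tab$allele == "Kras_WT"])
      is_bc <- tab$allele != "Kras_WT"
      if (any(is_bc)) {
        bc <- setNames(tab$umis[is_bc], tab$allele[is_bc])
        bc <- merge_barcodes(bc, max_distance = max_distance, metric = metric)
      }
    }
    counts <- cell_allele_counts(cb, wt, bc,
                                 transcriptome$transcriptome_umis[i],
                                 depth_scale)
    call <- call_clonotype(counts, min_wt_somatic, min_total, high_fraction)
    data.frame(cell_barcode = call$cell_barcode,
               dominant_barcode = call$dominant_barcode,
               cell_class = call$cell_class,
               imbalance_state = call$imbalance_state,
               wt_umis = call$wt_umis, g12d_umis = call$g12d_umis,
               kras_abundance = call$kras_abundance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clonotype_calls", "data.frame")
  out
}

#' Run the full barcode-calling pipeline on paired FASTQ
#'
#' Reads paired FASTQ, splits read 1 into cell barcode and UMI, trims read 2
#' ([trim_krasbc()]), assigns payloads to the allele reference
#' ([assign_allele()]), collapses UMIs ([collapse_umis()]) and calls
#' per-cell clonotypes ([call_clonotypes()]).
#'
#' @param r1_path,r2_path Paired FASTQ paths.
#' @param ref_path Allele reference FASTA from [write_reference()].
#' @param cells_path TSV with `cell_barcode` and `transcriptome_umis`.
#' @param out_path Optional path for the per-cell call TSV.
#' @param max_error_rate Trimming error tolerance.
#' @param max_mismatch_rate Assignment mismatch tolerance.
#' @param ... Further arguments passed to [call_clonotypes()].
#' @return List with `calls` (per-cell data.frame) and `clone_sizes`
#'   (data.frame `barcode_id`, `n_cells` over malignant cells).
#' @export
krasbc_pipeline <- function(r1_path, r2_path, ref_path, cells_path,
                            out_path = NULL, max_error_rate = 0.2,
                            max_mismatch_rate = 0.1, ...) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  reference <- read_reference(ref_path)
  cells <- read_tsv(cells_path)
  tags <- tag_reads(unname(r1), unname(r2))
  tags$payload <- trim_krasbc(tags$read2, max_error_rate = max_error_rate)
  tags$allele <- assign_allele(tags$payload, reference,
                               max_mismatch_rate = max_mismatch_rate)
  collapsed <- collapse_umis(tags)
  calls <- call_clonotypes(collapsed, cells, ...)
  mal <- calls[calls$cell_class == "malignant", , drop = FALSE]
  clone_sizes <- as.data.frame(table(barcode_id = mal$dominant_barcode),
                               stringsAsFactors = FALSE)
  names(clone_sizes) <- c("barcode_id", "n_cells")
  clone_sizes <- clone_sizes[order(-clone_sizes$n_cells,
                                   clone_sizes$barcode_id), , drop = FALSE]
  if (!is.null(out_path)) write_tsv(calls, out_path)
  list(calls = calls, clone_sizes = clone_sizes)
}
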