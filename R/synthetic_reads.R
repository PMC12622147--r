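# Read-level simulators: paired FASTQ for the Kras barcode assay and the
# Kdm8 targeted assay. Read 1 carries the 16-nt cell barcode + 10-nt UMI
# (droplet 5' chemistry); read 2 carries the cDNA payload.

# 26-nt constant prefix emitted at the start of Kdm8 assay read 2
# (template-switch/primer remnant removed by positional trimming).
KDM8_R2_PREFIX <- "AAGCAGTGGTATCAACGCAGAGTACA"

#' Read simulation configuration
#'
#' @param substitution_error_rate Per-base substitution probability applied
#'   to read 2 (read 1 cell barcodes and UMIs are emitted error-free; cell
#'   barcode correction is assumed upstream).
#' @param reads_per_umi Mean number of extra PCR duplicates per UMI; each
#'   ground-truth UMI is emitted `rpois(reads_per_umi) + 1` times, so every
#'   transcript is observed at least once.
#' @param adapter_5p,adapter_3p Constant sequences flanking the Kras payload
#'   on read 2 (defaults are the barcode-assay primer remnants).
#' @param umi_length,cellbc_length UMI and cell-barcode lengths (10 + 16 nt).
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(substitution_error_rate = 0.005,
                            reads_per_umi = 1,
                            adapter_5p = "CTCTATCGTAGGGTCATA",
                            adapter_3p = "CATTTTCAGCAGGCCT",
                            umi_length = 10L, cellbc_length = 16L,
                            seed = 1L) {
  stop_unless(substitution_error_rate >= 0 && substitution_error_rate <= 0.2,
              "substitution_error_rate must lie in [0, 0.2]")
  stop_unless(nzchar(adapter_5p) && nzchar(adapter_3p),
              "adapter strings must be non-empty")
  stop_unless(reads_per_umi >= 0, "reads_per_umi must be non-negative")
  structure(
    list(substitution_error_rate = substitution_error_rate,
         reads_per_umi = reads_per_umi,
         adapter_5p = toupper(adapter_5p), adapter_3p = toupper(adapter_3p),
         umi_length = as.integer(umi_length),
         cellbc_length = as.integer(cellbc_length),
         seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

# Expand per-cell/per-allele UMI counts into one row per sequenced read.
# Returns data.frame(cell_barcode, umi, sequence) before error injection.
expand_umis_to_reads <- function(cell_barcode, n_umis, sequence, cfg) {
  keep <- n_umis > 0
  cell_barcode <- cell_barcode[keep]
  n_umis <- n_umis[keep]
  sequence <- sequence[keep]
  if (!length(n_umis)) {
    return(data.frame(cell_barcode = character(0), umi = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  total_umis <- sum(n_umis)
  grp <- rep.int(seq_along(n_umis), n_umis)
  # UMIs must be distinct within a (cell, allele) group; collisions across
  # groups are harmless (collapse key includes cell and allele)
  umi <- random_dna(total_umis, cfg$umi_length)
  dup <- which(duplicated(paste(grp, umi)))
  while (length(dup)) {
    umi[dup] <- random_dna(length(dup), cfg$umi_length)
    dup <- which(duplicated(paste(grp, umi)))
  }
  dups <- rpois(total_umis, cfg$reads_per_umi) + 1L
  idx <- rep.int(seq_len(total_umis), dups)
  data.frame(cell_barcode = cell_barcode[grp][idx],
             umi = umi[idx],
             sequence = sequence[grp][idx],
             stringsAsFactors = FALSE)
}

emit_paired_fastq <- function(reads, cfg, r1_path, r2_path) {
  n <- nrow(reads)
  if (n) {
    ord <- sample.int(n)  # shuffle read order
    reads <- reads[ord, , drop = FALSE]
  }
  r1 <- paste0(reads$cell_barcode, reads$umi)
  r2 <- add_substitution_errors(reads$sequence, cfg$substitution_error_rate)
  ids <- sprintf("read_%06d", seq_len(n))
  write_fastq(ids, if (n) r1 else character(0), r1_path)
  write_fastq(ids, if (n) r2 else character(0), r2_path)
  invisible(c(r1 = r1_path, r2 = r2_path))
}

#' Emit paired FASTQ for the Kras barcode assay
#'
#' For every cell, each ground-truth wildtype UMI yields reads over the
#' wildtype coding sequence and each mutant UMI yields reads over the cell's
#' clone allele. Read 2 is `adapter_5p + coding sequence + adapter_3p` with
#' substitution errors; read 1 is the error-free 26-nt cell barcode + UMI.
#'
#' @param truth A `cell_ground_truth` data.frame from [simulate_tumor()].
#' @param alleles The `barcode_alleles` used to simulate the tumor.
#' @param cfg A [read_sim_config()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @param wildtype Wildtype coding sequence (90 nt).
#' @return Character vector of the two paths, invisibly.
#' @export
emit_krasbc_fastq <- function(truth, alleles, cfg, r1_path, r2_path,
                              wildtype = kras_wildtype_sequence()) {
  has_bc <- !is.na(truth$clone_barcode_id)
  bad <- setdiff(unique(truth$clone_barcode_id[has_bc]), alleles$barcode_id)
  stop_unless(length(bad) == 0,
              "clone barcode id(s) not present in allele set: %s",
              paste(bad, collapse = ", "))
  allele_seq <- setNames(alleles$coding_sequence, alleles$barcode_id)
  with_seed(cfg$seed, {
    wt <- expand_umis_to_reads(truth$cell_barcode, truth$kras_wt_umis,
                               rep(wildtype, nrow(truth)), cfg)
    mut_seq <- ifelse(has_bc, allele_seq[truth$clone_barcode_id], "")
    mut <- expand_umis_to_reads(truth$cell_barcode, truth$kras_g12d_umis,
                                mut_seq, cfg)
    reads <- rbind(wt, mut)
    reads$sequence <- paste0(cfg$adapter_5p, reads$sequence, cfg$adapter_3p)
    emit_paired_fastq(reads, cfg, r1_path, r2_path)
  })
}

#' Emit paired FASTQ for the Kdm8 targeted assay
#'
#' Each ground-truth Kdm8 UMI yields reads whose read 2 is a constant 26-nt
#' prefix followed by a random fragment of the Kdm8 transcript, with
#' substitution errors. Cells with zero Kdm8 UMIs emit no reads (their
#' absence is what zero imputation recovers downstream).
#'
#' @param truth A `cell_ground_truth` data.frame.
#' @param kdm8_transcript Kdm8 transcript sequence (character scalar).
#' @param cfg A [read_sim_config()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @param fragment_length Length of the transcript fragment on read 2.
#' @return Character vector of the two paths, invisibly.
#' @export
emit_kdm8_fastq <- function(truth, kdm8_transcript, cfg, r1_path, r2_path,
                            fragment_length = 74L) {
  stop_unless(nchar(kdm8_transcript) >= fragment_length,
              "transcript shorter than fragment_length")
  with_seed(cfg$seed + 1L, {
    reads <- expand_umis_to_reads(truth$cell_barcode, truth$kdm8_umis,
                                  rep("", nrow(truth)), cfg)
    n <- nrow(reads)
    if (n) {
      start <- sample.int(nchar(kdm8_transcript) - fragment_length + 1L, n,
                          replace = TRUE)
      frag <- substring(kdm8_transcript, start, start + fragment_length - 1L)
      reads$sequence <- paste0(KDM8_R2_PREFIX, frag)
    }
    emit_paired_fastq(reads, cfg, r1_path, r2_path)
  })
}

#' Read the bundled synthetic Kdm8 transcript
#'
#' A synthetic stand-in for the Kdm8 transcript reference (the real RefSeq
#' record is not bundled); its only role is to serve as assignment target and
#' fragment source for the Kdm8 assay.
#'
#' @param file FASTA path (defaults to the bundled synthetic transcript).
#' @return Transcript sequence as a character scalar.
#' @export
kdm8_transcript_synthetic <- function(file = system.file(
                                        "extdata", "kdm8_transcript_synthetic.fa",
                                        package = "clonotrace")) {
  unname(read_reference(file)[1])
}
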