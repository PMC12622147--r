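# Toy genome and single-cell WGS count simulators for the copy-number stage.

#' Simulate a toy multi-chromosome genome
#'
#' Generates a small genome with regional GC variation (a smooth sinusoidal
#' GC target between `gc_range`, so bins differ in GC content and the GC
#' correction has signal) and, optionally, planted exact repeats that render
#' part of the genome unmappable (the equal-mappability bin construction must
#' widen bins across them).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc_range Range of the regional GC target.
#' @param gc_period Period (bp) of the GC oscillation.
#' @param repeat_length,repeat_copies Length and total copy count of a planted
#'   exact repeat (0 copies disables planting). Copies are placed at fixed
#'   relative offsets across chromosomes.
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @export
simulate_toy_genome <- function(chrom_lengths = c(chr1 = 100000L,
                                                  chr2 = 100000L,
                                                  chr3 = 100000L),
                                gc_range = c(0.35, 0.65),
                                gc_period = 20000,
                                repeat_length = 1000L,
                                repeat_copies = 3L,
                                seed = 1L) {
  stop_unless(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  with_seed(seed, {
    genome <- vapply(chrom_lengths, function(L) {
      pos <- seq_len(L)
      gc <- mean(gc_range) + diff(gc_range) / 2 * sin(2 * pi * pos / gc_period)
      is_gc <- runif(L) < gc
      base <- ifelse(is_gc,
                     ifelse(runif(L) < 0.5, "G", "C"),
                     ifelse(runif(L) < 0.5, "A", "T"))
      paste0(base, collapse = "")
    }, "")
    if (repeat_copies > 0L && repeat_length > 0L) {
      rep_seq <- random_dna(1L, repeat_length)
      # place copies round-robin across chromosomes at staggered offsets
      for (i in seq_len(repeat_copies)) {
        ci <- ((i - 1L) %% length(genome)) + 1L
        at <- min(1L + i * 7919L, nchar(genome[ci]) - repeat_length + 1L)
        substr(genome[ci], at, at + repeat_length - 1L) <- rep_seq
      }
    }
    genome
  })
}

#' Write a genome to FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' scWGS count simulation configuration
#'
#' @param cn_states Named integer vector: copy-number state per chromosome
#'   (chromosome-level events, e.g. `c(chr1 = 2, chr2 = 2, chr3 = 4)`).
#' @param gc_bias_slope Linear coverage bias per unit GC deviation from the
#'   genome mean (0 = unbiased).
#' @param reads_total Total read count, distributed multinomially over bins.
#' @param seed Integer seed.
#' @return An object of class `scwgs_sim_config`.
#' @export
scwgs_sim_config <- function(cn_states, gc_bias_slope = 0,
                             reads_total = 1e6, seed = 1L) {
  stop_unless(!is.null(names(cn_states)), "cn_states must be named by chromosome")
  stop_unless(all(cn_states >= 0), "cn_states must be >= 0")
  structure(
    list(cn_states = cn_states, gc_bias_slope = gc_bias_slope,
         reads_total = as.integer(reads_total), seed = as.integer(seed)),
    class = "scwgs_sim_config"
  )
}

#' Simulate per-bin scWGS read counts
#'
#' Bin counts are drawn multinomially with weight proportional to
#' `copy_number x gc_weight(bin GC)`, where the GC weight is
#' `1 + slope * (gc - mean(gc))`, floored at 0.05. Equal-mappability bins
#' carry no additional size weight. The total equals `reads_total` exactly.
#'
#' @param cfg A [scwgs_sim_config()].
#' @param binmap A `binmap` data.frame from [build_binmap()].
#' @return Integer vector of per-bin counts (length `nrow(binmap)`).
#' @export
simulate_scwgs_counts <- function(cfg, binmap) {
  stop_unless(inherits(binmap, "binmap"), "binmap must come from build_binmap()")
  missing_cn <- setdiff(unique(binmap$chrom), names(cfg$cn_states))
  stop_unless(length(missing_cn) == 0, "cn_states missing chromosome(s): %s",
              paste(missing_cn, collapse = ", "))
  if (anyNA(binmap$gc_fraction)) {
    stop("invalid binmap: bin with undefined GC fraction", call. = FALSE)
  }
  cn <- cfg$cn_states[binmap$chrom]
  gcw <- pmax(1 + cfg$gc_bias_slope * (binmap$gc_fraction - mean(binmap$gc_fraction)),
              0.05)
  w <- cn * gcw
  stop_unless(sum(w) > 0, "all bin weights are zero")
  with_seed(cfg$seed, as.integer(rmultinom(1, cfg$reads_total, w)))
}

#' Expand bin counts into uniform read start positions
#'
#' Convenience generator for exercising [count_reads()]: places each bin's
#' reads uniformly at random within the bin interval.
#'
#' @param binmap A `binmap` data.frame.
#' @param counts Integer per-bin counts (e.g. from [simulate_scwgs_counts()]).
#' @param seed Integer seed.
#' @return data.frame with columns `chrom` and `pos` (0-based start).
#' @export
counts_to_read_starts <- function(binmap, counts, seed = 1L) {
  stop_unless(length(counts) == nrow(binmap), "counts must be one per bin")
  with_seed(seed, {
    idx <- rep.int(seq_len(nrow(binmap)), counts)
    width <- binmap$end - binmap$start
    pos <- binmap$start[idx] + floor(runif(length(idx)) * width[idx])
    df <- data.frame(chrom = binmap$chrom[idx], pos = as.integer(pos),
                     stringsAsFactors = FALSE)
    df[sample.int(nrow(df)), , drop = FALSE]
  })
}
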