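# Ground-truthed tumor simulator: clone structure, per-cell allele-level
# transcript counts, Kdm8 genotype and foreign spike-in cells.

#' Tumor simulation model
#'
#' Describes the cellular composition of a simulated barcoded tumor. Clone
#' sizes follow a truncated discrete power law (Zipf) so that a handful of
#' large clones dominate, matching the observation that metastases derive
#' mostly from the largest primary clonotypes. Each malignant cell carries
#' exactly one barcode allele; a configurable fraction expresses the mutant
#' allele in excess (allelic imbalance); Kdm8 expression is bimodal
#' (detected in a minority of cells after editing); and a small fraction of
#' cells are foreign spike-ins that yield no mouse Kras transcripts.
#'
#' @param n_cells Total number of cells.
#' @param n_clones Number of barcoded clones.
#' @param clone_size_alpha Power-law exponent of the clone-size distribution
#'   (larger = more skewed).
#' @param p_imbalanced Fraction of malignant cells with mutant-skewed
#'   (g12d_high) Kras expression.
#' @param p_somatic Fraction of non-malignant (somatic) mouse cells.
#' @param p_kdm8_positive Fraction of mouse cells with intact, expressed Kdm8
#'   (default 0.114, the observed positive fraction).
#' @param p_spikein Fraction of foreign spike-in cells.
#' @param kras_mean_umis,kras_size Negative-binomial mean/size of the
#'   per-cell total Kras UMI count from the targeted assay.
#' @param kdm8_mean_umis Mean Kdm8 UMI count of Kdm8-positive cells
#'   (positives draw `rpois(kdm8_mean_umis - 1) + 1`, so always >= 1).
#' @param transcriptome_mean_umis,transcriptome_size Negative-binomial
#'   mean/size of the whole-transcriptome UMI count per cell.
#' @param balanced_shape Beta(shape, shape) concentration of the mutant
#'   fraction in allelically balanced cells (sd ~ 3.5% at the default 100).
#' @param seed Integer seed.
#' @return An object of class `tumor_model`.
#' @export
tumor_model <- function(n_cells = 5000L, n_clones = 50L,
                        clone_size_alpha = 1.5,
                        p_imbalanced = 0.15, p_somatic = 0.2,
                        p_kdm8_positive = 0.114, p_spikein = 0.02,
                        kras_mean_umis = 20, kras_size = 10,
                        kdm8_mean_umis = 4,
                        transcriptome_mean_umis = 5000,
                        transcriptome_size = 10,
                        balanced_shape = 100,
                        seed = 1L) {
  fracs <- c(p_imbalanced = p_imbalanced, p_somatic = p_somatic,
             p_kdm8_positive = p_kdm8_positive, p_spikein = p_spikein)
  stop_unless(all(fracs >= 0 & fracs <= 1), "all fractions must lie in [0,1]")
  stop_unless(p_somatic + p_spikein < 1, "p_somatic + p_spikein must be < 1")
  stop_unless(n_clones <= n_cells, "n_clones must not exceed n_cells")
  structure(
    list(n_cells = as.integer(n_cells), n_clones = as.integer(n_clones),
         clone_size_alpha = clone_size_alpha,
         p_imbalanced = p_imbalanced, p_somatic = p_somatic,
         p_kdm8_positive = p_kdm8_positive, p_spikein = p_spikein,
         kras_mean_umis = kras_mean_umis, kras_size = kras_size,
         kdm8_mean_umis = kdm8_mean_umis,
         transcriptome_mean_umis = transcriptome_mean_umis,
         transcriptome_size = transcriptome_size,
         balanced_shape = balanced_shape,
         seed = as.integer(seed)),
    class = "tumor_model"
  )
}

#' Simulate a ground-truthed tumor
#'
#' Draws the per-cell ground truth for a barcoded tumor: cell class
#' (malignant / somatic / spike-in), founding clone, allele-level Kras UMI
#' counts, Kdm8 UMI count and whole-transcriptome UMI count. Mutant-skewed
#' cells draw their G12D transcript fraction uniformly from [0.75, 1];
#' balanced cells draw it from Beta(shape, shape) around 0.5.
#'
#' @param model A [tumor_model()].
#' @param alleles A `barcode_alleles` data.frame; the first
#'   `model$n_clones` rows found the clones.
#' @return A data.frame of class `cell_ground_truth` with one row per cell:
#'   `cell_barcode`, `cell_class`, `clone_barcode_id` (NA for non-malignant
#'   cells), `kras_g12d_umis`, `kras_wt_umis`, `kdm8_umis`,
#'   `transcriptome_umis`, `imbalance_state` (NA for non-malignant cells).
#' @examples
#' al <- sample_alleles(n = 5, seed = 1)
#' truth <- simulate_tumor(tumor_model(n_cells = 100, n_clones = 5), al)
#' table(truth$cell_class)
#' @export
simulate_tumor <- function(model, alleles) {
  if (model$n_clones > nrow(alleles)) {
    stop(sprintf("capacity error: n_clones = %d but only %d alleles supplied",
                 model$n_clones, nrow(alleles)), call. = FALSE)
  }
  n <- model$n_cells
  with_seed(model$seed, {
    p_mal <- 1 - model$p_somatic - model$p_spikein
    cell_class <- sample(c("malignant", "somatic", "spikein"), n,
                         replace = TRUE,
                         prob = c(p_mal, model$p_somatic, model$p_spikein))
    cell_barcode <- random_dna_unique(n, 16L)
    is_mal <- cell_class == "malignant"
    is_spike <- cell_class == "spikein"

    # clone assignment: Zipf weights over clone ranks
    clone_w <- seq_len(model$n_clones)^(-model$clone_size_alpha)
    clone <- rep(NA_integer_, n)
    clone[is_mal] <- sample.int(model$n_clones, sum(is_mal), replace = TRUE,
                                prob = clone_w)
    clone_barcode_id <- ifelse(is.na(clone), NA_character_,
                               alleles$barcode_id[clone])

    # per-cell total Kras UMIs from the targeted assay (0 for spike-ins)
    kras_total <- rnbinom(n, mu = model$kras_mean_umis, size = model$kras_size)
    kras_total[is_spike] <- 0L

    imbalance_state <- rep(NA_character_, n)
    imbalance_state[is_mal] <- ifelse(runif(sum(is_mal)) < model$p_imbalanced,
                                      "g12d_high", "balanced")
    g12d_frac <- rep(0, n)
    hi <- which(imbalance_state == "g12d_high")
    bal <- which(imbalance_state == "balanced")
    g12d_frac[hi] <- runif(length(hi), 0.75, 1)
    g12d_frac[bal] <- rbeta(length(bal), model$balanced_shape,
                            model$balanced_shape)
    kras_g12d <- rbinom(n, kras_total, g12d_frac)
    kras_g12d[!is_mal] <- 0L
    kras_wt <- kras_total - kras_g12d
    kras_wt[is_spike] <- 0L

    kdm8_pos <- runif(n) < model$p_kdm8_positive
    kdm8_pos[is_spike] <- FALSE
    kdm8_umis <- integer(n)
    kdm8_umis[kdm8_pos] <- rpois(sum(kdm8_pos),
                                 max(model$kdm8_mean_umis - 1, 0)) + 1L

    transcriptome_umis <- pmax(
      rnbinom(n, mu = model$transcriptome_mean_umis,
              size = model$transcriptome_size), 1L)

    structure(
      data.frame(cell_barcode = cell_barcode,
                 cell_class = cell_class,
                 clone_barcode_id = clone_barcode_id,
                 kras_g12d_umis = as.integer(kras_g12d),
                 kras_wt_umis = as.integer(kras_wt),
                 kdm8_umis = as.integer(kdm8_umis),
                 transcriptome_umis = as.integer(transcriptome_umis),
                 imbalance_state = imbalance_state,
                 stringsAsFactors = FALSE),
      class = c("cell_ground_truth", "data.frame")
    )
  })
}

#' Write the per-cell transcriptome UMI table used by the callers
#'
#' @param truth A `cell_ground_truth` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cells_tsv <- function(truth, path) {
  write_tsv(truth[, c("cell_barcode", "transcriptome_umis")], path)
}
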