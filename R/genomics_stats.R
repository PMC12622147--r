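# Region/gene annotation (TSS proximal/distal rule), gene-region contingency
# tables and the exact statistics behind incidence tallies.

#' Classify regions as TSS-proximal or distal
#'
#' For each region (0-based half-open interval) the distance to the nearest
#' transcription start site on the same chromosome is the gap between the
#' region interval and the TSS point (0 if the TSS lies inside the region).
#' Regions closer than `threshold_bp` are proximal; regions at least
#' `threshold_bp` away are distal. Equidistant genes are tie-broken by
#' lexicographic `gene_id`, so the result is invariant to gene and region
#' order. Regions on chromosomes without genes get `NA` locality and are
#' flagged.
#'
#' @param regions data.frame with columns `chromosome`, `start`, `end` and
#'   optionally `direction` (`"induced"`/`"suppressed"`), carried through.
#' @param genes data.frame with columns `gene_id`, `chromosome`,
#'   `tss_position` (0-based) and `strand`.
#' @param threshold_bp Proximal/distal cutoff (default 1000: "at least 1 kb
#'   away" is distal).
#' @return data.frame of class `region_calls`: the region columns plus
#'   `locality`, `nearest_gene_id`, `distance_bp` and `flag`.
#' @export
classify_locality <- function(regions, genes, threshold_bp = 1000) {
  stop_unless(all(c("chromosome", "start", "end") %in% names(regions)),
              "regions must have chromosome, start, end")
  stop_unless(all(c("gene_id", "chromosome", "tss_position") %in% names(genes)),
              "genes must have gene_id, chromosome, tss_position")
  stop_unless(all(regions$end > regions$start), "regions must have end > start")
  stop_unless(all(genes$tss_position >= 0), "tss_position must be >= 0")
  n <- nrow(regions)
  nearest <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chromosome == regions$chromosome[i], , drop = FALSE]
    if (!nrow(g)) next
    s <- regions$start[i]; e <- regions$end[i]
    t <- g$tss_position
    # bases strictly between the TSS base and the region interval
    d <- ifelse(t < s, s - t - 1, ifelse(t >= e, t - e, 0))
    best <- min(d)
    cand <- sort(g$gene_id[d == best])  # deterministic tie-break
    nearest[i] <- cand[1]
    dist[i] <- best
  }
  out <- regions
  out$locality <- ifelse(is.na(dist), NA_character_,
                         ifelse(dist < threshold_bp, "proximal", "distal"))
  out$nearest_gene_id <- nearest
  out$distance_bp <- dist
  out$flag <- ifelse(is.na(dist), "no_gene_on_chromosome", "")
  if (any(is.na(dist))) {
    warning(sum(is.na(dist)),
            " region(s) on chromosomes without genes: locality indeterminate")
  }
  class(out) <- c("region_calls", "data.frame")
  out
}

#' Gene-region association contingency table
#'
#' A gene is "associated" iff it is the nearest gene of at least one
#' TSS-proximal region of matching direction. Builds the 2x2 table of gene
#' set membership against association over a background gene universe, and
#' reports the associated fraction of the gene set as a percentage with one
#' decimal.
#'
#' @param gene_set Character vector of gene ids (e.g. co-regulated genes).
#' @param background Character vector of all gene ids under consideration
#'   (must contain `gene_set`).
#' @param region_calls A `region_calls` data.frame from
#'   [classify_locality()]; a `direction` column is required when
#'   `direction` is given.
#' @param direction Optional direction filter (`"induced"` or
#'   `"suppressed"`).
#' @return List with `table` (2x2 matrix: rows in/out of the gene set,
#'   columns associated/not), `associated` (gene ids of the set that are
#'   associated), and `fraction` (percentage with one decimal, via
#'   [fraction_report()]).
#' @export
gene_region_table <- function(gene_set, background, region_calls,
                              direction = NULL) {
  if (!length(gene_set)) {
    stop("undefined fraction: gene set is empty", call. = FALSE)
  }
  stop_unless(all(gene_set %in% background),
              "gene_set must be contained in background")
  rc <- region_calls[!is.na(region_calls$locality) &
                       region_calls$locality == "proximal", , drop = FALSE]
  if (!is.null(direction)) {
    stop_unless("direction" %in% names(rc),
                "region_calls lack a direction column")
    rc <- rc[rc$direction == direction, , drop = FALSE]
  }
  assoc_genes <- unique(rc$nearest_gene_id)
  in_set <- background %in% gene_set
  assoc <- background %in% assoc_genes
  tab <- matrix(c(sum(in_set & assoc), sum(in_set & !assoc),
                  sum(!in_set & assoc), sum(!in_set & !assoc)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("associated", "not_associated")))
  list(table = tab,
       associated = sort(intersect(gene_set, assoc_genes)),
       fraction = fraction_report(tab["in_set", "associated"],
                                  length(gene_set)))
}

#' Two-sided Fisher's exact test from the hypergeometric mass
#'
#' Computes the two-sided p-value of a 2x2 table by probability-mass
#' ordering: with margins fixed, the p-value is the sum of hypergeometric
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (with relative tolerance 1e-7 on the comparison, the
#' R/scipy convention).
#'
#' @param table 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`,
#'   or the vector `c(a, b, c, d)`.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(rbind(c(0, 13), c(6, 3)))  # 0.001 at 3 decimals
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.vector(t(table))
  stop_unless(length(x) == 4L, "table must be 2x2")
  stop_unless(all(x >= 0) && all(x == round(x)),
              "counts must be non-negative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n_total <- a + b + c + d
  if (n_total == 0) {
    stop("p undefined: table total is zero", call. = FALSE)
  }
  m <- a + b          # row-1 margin
  k <- a + c          # column-1 margin
  lo <- max(0, k - (c + d))
  hi <- min(m, k)
  support <- lo:hi
  probs <- dhyper(support, m, c + d, k)
  p_obs <- dhyper(a, m, c + d, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Report a fraction as a percentage with one decimal
#'
#' Round-half-up of `100 * numerator / denominator` to one decimal, computed
#' with exact integer arithmetic before rounding.
#'
#' @param numerator,denominator Non-negative integers; `denominator > 0`.
#' @return Numeric percentage with one decimal (e.g. `74.2`).
#' @examples
#' fraction_report(23, 31)    # 74.2
#' fraction_report(797, 6999) # 11.4
#' @export
fraction_report <- function(numerator, denominator) {
  stop_unless(denominator > 0, "denominator must be positive")
  stop_unless(numerator >= 0 && numerator == round(numerator) &&
                denominator == round(denominator),
              "numerator and denominator must be non-negative integers")
  # percentage * 10, rounded half-up, in integer arithmetic:
  # floor(1000 * num / den + 1/2) = (2000 * num + den) %/% (2 * den)
  tenths <- (2000 * numerator + denominator) %/% (2 * denominator)
  tenths / 10
}
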