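# Barcode library design: enumeration and sampling of the synonymous-mutation
# allele space over the murine Kras codon 2-31 template.

# Murine Kras codons 2-31 (90 nt). Codon 12 carries the glycine that is
# mutated to aspartate (G12D); codons 3-8 span the sgKras protospacer and are
# recoded synonymously to resist re-cutting.
KRAS_CODONS_2_31 <- c(
  "ACT", "GAG", "TAT", "AAA", "CTT", "GTG", "GTG", "GTT", "GGA", "GCT",
  "GGT", "GGC", "GTA", "GGC", "AAG", "AGC", "GCC", "TTG", "ACG", "ATA",
  "CAG", "CTA", "ATT", "CAG", "AAT", "CAT", "TTT", "GTT", "GAC", "GAA"
)
names(KRAS_CODONS_2_31) <- as.character(2:31)

# sgKras protospacer (5'->3') and the codon 3-8 recoding that disables it.
SGKRAS_PROTOSPACER <- "GACTGAGTATAAACTTGTGG"
SGKRAS_SENSITIVE_SEGMENT <- "GAGTATAAACTTGTGGTG"
SGKRAS_RESISTANT_SEGMENT <- "GAATACAAGCTAGTAGTC"
G12D_CODON <- "GAT"

#' Kras codon 2--31 template
#'
#' Returns the codon template used to design the barcoded Kras-G12D allele
#' library: the 30 codons spanning residues 2--31 of murine Kras, the set of
#' codon positions held fixed (codons 3--8, recoded for sgRNA resistance, and
#' codon 12, which carries the G12D substitution), and the G12D codon index.
#'
#' @param codons Named character vector of 30 codons (names are Kras codon
#'   numbers 2--31). Defaults to the murine Kras sequence.
#' @param fixed_codon_indices Codon numbers excluded from barcode variation.
#' @param g12d_index Codon number of the glycine-to-aspartate substitution.
#' @return An object of class `codon_template`.
#' @examples
#' tpl <- kras_codon_template()
#' nchar(kras_wildtype_sequence(tpl))  # 90
#' @export
kras_codon_template <- function(codons = KRAS_CODONS_2_31,
                                fixed_codon_indices = c(3:8, 12L),
                                g12d_index = 12L) {
  tpl <- structure(
    list(codons = codons,
         fixed_codon_indices = as.integer(sort(unique(fixed_codon_indices))),
         g12d_index = as.integer(g12d_index)),
    class = "codon_template"
  )
  validate_codon_template(tpl)
  tpl
}

validate_codon_template <- function(tpl) {
  stop_unless(length(tpl$codons) == 30L, "template must have exactly 30 codons")
  stop_unless(all(nchar(tpl$codons) == 3L), "every codon must be 3 nt")
  stop_unless(all(strsplit(paste0(tpl$codons, collapse = ""), "")[[1]] %in% DNA_BASES),
              "codons must be over {A,C,G,T}")
  stop_unless(tpl$g12d_index == 12L, "g12d_index must be Kras codon 12")
  stop_unless(all(c(3:8, 12L) %in% tpl$fixed_codon_indices),
              "fixed codons must include 3-8 and 12")
  stop_unless(all(tpl$fixed_codon_indices %in% 2:31),
              "fixed codon indices must lie in 2..31")
  invisible(tpl)
}

#' Wildtype coding sequence of the template
#'
#' @param template A [kras_codon_template()].
#' @return The 90-nt wildtype coding string (codons 2--31 concatenated).
#' @export
kras_wildtype_sequence <- function(template = kras_codon_template()) {
  paste0(template$codons, collapse = "")
}

#' Calibrated variable-position set
#'
#' Loads the set of wobble positions and allowed synonymous codons used to
#' build the barcode library. The shipped design varies 20 codons (2, 9--11,
#' 13--28): the two isoleucines carry all three synonymous codons and the
#' remaining 18 positions carry the wildtype codon plus one wobble variant,
#' for a combinatorial diversity of 2^18 x 3^2 = 2,359,296 distinct barcodes.
#'
#' @param file Path to a design TSV with columns `codon_index`,
#'   `wildtype_codon` and comma-separated `allowed_codons`.
#' @param template Template the design must be consistent with.
#' @return An object of class `variable_position_set`: a list with an
#'   `entries` element (one `list(codon_index, allowed)` per variable codon).
#' @examples
#' vps <- kras_variable_positions()
#' enumerate_diversity(kras_codon_template(), vps)  # 2359296
#' @export
kras_variable_positions <- function(file = system.file("extdata",
                                                       "kras_barcode_design.tsv",
                                                       package = "clonotrace"),
                                    template = kras_codon_template()) {
  df <- read_tsv(file, colClasses = c("integer", "character", "character"))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    list(codon_index = df$codon_index[i],
         allowed = strsplit(df$allowed_codons[i], ",", fixed = TRUE)[[1]])
  })
  vps <- structure(list(entries = entries), class = "variable_position_set")
  validate_variable_positions(vps, template)
  vps
}

#' Construct a variable-position set from scratch
#'
#' @param codon_index Integer vector of codon numbers.
#' @param allowed List of character vectors of allowed synonymous codons,
#'   parallel to `codon_index`.
#' @param template Template to validate against (NULL to skip validation).
#' @return A `variable_position_set`.
#' @export
variable_position_set <- function(codon_index, allowed, template = NULL) {
  stop_unless(length(codon_index) == length(allowed),
              "codon_index and allowed must be parallel")
  entries <- Map(function(i, a) list(codon_index = as.integer(i), allowed = a),
                 codon_index, allowed)
  vps <- structure(list(entries = unname(entries)),
                   class = "variable_position_set")
  if (!is.null(template)) validate_variable_positions(vps, template)
  vps
}

validate_variable_positions <- function(vps, template) {
  idx <- vapply(vps$entries, `[[`, 0L, "codon_index")
  stop_unless(!anyDuplicated(idx), "duplicate variable codon index")
  if (any(idx %in% template$fixed_codon_indices)) {
    stop("invalid design: variable positions overlap fixed codons (",
         paste(intersect(idx, template$fixed_codon_indices), collapse = ", "),
         ")", call. = FALSE)
  }
  stop_unless(all(idx %in% as.integer(names(template$codons))),
              "variable codon index outside the template")
  for (e in vps$entries) {
    wt <- template$codons[[as.character(e$codon_index)]]
    aas <- vapply(e$allowed, translate_dna, "")
    stop_unless(all(aas == translate_dna(wt)),
                "non-synonymous codon at position %d", e$codon_index)
  }
  invisible(vps)
}

#' Number of distinct barcodes in a design
#'
#' Computes the combinatorial diversity of the barcode library as the product
#' of per-position synonymous-codon degeneracies, without materialising any
#' allele.
#'
#' @param template A [kras_codon_template()].
#' @param varset A [kras_variable_positions()] set.
#' @return The number of distinct barcode alleles (numeric scalar).
#' @examples
#' enumerate_diversity(kras_codon_template(), kras_variable_positions())
#' @export
enumerate_diversity <- function(template, varset) {
  validate_variable_positions(varset, template)
  prod(vapply(varset$entries, function(e) length(e$allowed), 0))
}

#' Apply the fixed G12D and sgRNA-resistance substitutions
#'
#' Replaces the protospacer-spanning segment at codons 3--8
#' (`GAGTATAAACTTGTGGTG`) with its synonymous recoding
#' (`GAATACAAGCTAGTAGTC`) and mutates the codon-12 glycine codon to `GAT`
#' (G12D). The protein product differs from wildtype Kras only at residue 12.
#'
#' @param template A [kras_codon_template()].
#' @param g12d_codon Aspartate codon substituted at position 12 (`GAT` or
#'   `GAC`).
#' @return The mutated 90-nt coding string.
#' @export
apply_fixed_mutations <- function(template = kras_codon_template(),
                                  g12d_codon = G12D_CODON) {
  stop_unless(g12d_codon %in% c("GAT", "GAC"), "g12d_codon must encode aspartate")
  codons <- template$codons
  seg <- paste0(codons[as.character(3:8)], collapse = "")
  if (seg != SGKRAS_SENSITIVE_SEGMENT) {
    stop("template mismatch: codons 3-8 do not span the sgKras protospacer segment ",
         SGKRAS_SENSITIVE_SEGMENT, call. = FALSE)
  }
  recoded <- substring(SGKRAS_RESISTANT_SEGMENT,
                       seq(1, 16, by = 3), seq(3, 18, by = 3))
  codons[as.character(3:8)] <- recoded
  codons[as.character(template$g12d_index)] <- g12d_codon
  paste0(codons, collapse = "")
}

#' Sample distinct barcode alleles from the design space
#'
#' Draws `n` distinct alleles by index-based sampling from the mixed-radix
#' space of variable-codon choices, without materialising the full library.
#' Each allele starts from the fixed-mutation backbone
#' ([apply_fixed_mutations()]) and substitutes the chosen codon at every
#' variable position. The `barcode_id` is the dash-joined sequence of chosen
#' codons (invertible to the allele).
#'
#' @param template A [kras_codon_template()].
#' @param varset A [kras_variable_positions()] set.
#' @param n Number of distinct alleles to draw.
#' @param seed Integer seed; a fixed seed reproduces the same alleles.
#' @return A data.frame of class `barcode_alleles` with columns `barcode_id`,
#'   `barcode_string` (concatenated variable codons) and `coding_sequence`
#'   (90 nt).
#' @examples
#' al <- sample_alleles(n = 3, seed = 1)
#' al$barcode_id
#' @export
sample_alleles <- function(template = kras_codon_template(),
                           varset = kras_variable_positions(),
                           n, seed = 1L) {
  validate_variable_positions(varset, template)
  radices <- vapply(varset$entries, function(e) length(e$allowed), 0L)
  diversity <- prod(radices)
  stop_unless(n >= 1, "n must be positive")
  if (n > diversity) {
    stop(sprintf("capacity error: n = %d exceeds design diversity %.0f",
                 n, diversity), call. = FALSE)
  }
  idx0 <- with_seed(seed, sample.int(diversity, n)) - 1  # 0-based mixed-radix
  backbone <- apply_fixed_mutations(template)
  var_idx <- vapply(varset$entries, `[[`, 0L, "codon_index")
  # decode each index into per-position codon choices (least-significant first)
  choice <- matrix(0L, nrow = n, ncol = length(radices))
  rem <- idx0
  for (j in seq_along(radices)) {
    choice[, j] <- rem %% radices[j]
    rem <- rem %/% radices[j]
  }
  codon_at <- function(j) varset$entries[[j]]$allowed[choice[, j] + 1L]
  chosen <- vapply(seq_along(radices), codon_at, character(n))
  if (n == 1L) chosen <- matrix(chosen, nrow = 1L)
  barcode_string <- apply(chosen, 1, paste0, collapse = "")
  barcode_id <- apply(chosen, 1, paste0, collapse = "-")
  # substitute variable codons into the backbone
  # codon k of the template occupies characters 3(k-2)+1 .. 3(k-2)+3
  coding <- rep(backbone, n)
  for (j in seq_along(radices)) {
    at <- 3L * (var_idx[j] - 2L) + 1L
    substr(coding, at, at + 2L) <- chosen[, j]
  }
  structure(
    data.frame(barcode_id = barcode_id,
               barcode_string = barcode_string,
               coding_sequence = coding,
               stringsAsFactors = FALSE),
    class = c("barcode_alleles", "data.frame")
  )
}

#' Write the allele reference FASTA
#'
#' Emits one record per barcode allele plus one wildtype record named
#' `Kras_WT`, the reference used by the barcode caller.
#'
#' @param alleles A `barcode_alleles` data.frame from [sample_alleles()].
#' @param wildtype Wildtype 90-nt coding string.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(alleles, wildtype = kras_wildtype_sequence(),
                            path) {
  stop_unless(nrow(alleles) > 0, "allele list must be non-empty")
  ids <- c(alleles$barcode_id, "Kras_WT")
  if (anyDuplicated(ids)) {
    stop("duplicate record id in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(c(alleles$coding_sequence, wildtype))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an allele reference FASTA
#'
#' @param path FASTA written by [write_reference()].
#' @return Named character vector of sequences (includes `Kras_WT`).
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
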